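#' Predicate references for index-matrix cells
#'
#' A `predicate_ref` wraps a named Boolean evaluator used as one cell of a
#' transition-condition index matrix. The evaluator is called as
#' `evaluator(token, source, target, net, tick)` and must return a single
#' logical; it must never mutate net state (the engine's purity tests compare
#' a state digest before and after evaluation).
#'
#' Two reserved predicates exist: [ALWAYS_TRUE] and [ALWAYS_FALSE]. Every
#' index-matrix cell left unspecified defaults to [ALWAYS_FALSE], so tokens
#' can only move along arcs that were deliberately declared.
#'
#' @param id Short identifier string (e.g. `"W_1k2"`).
#' @param evaluator Function `(token, source, target, net, tick) -> logical(1)`.
#' @param description Free-text account of what the predicate tests.
#' @return An object of class `predicate_ref`.
#' @export
predicate_ref <- function(id, evaluator, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    fop_structural_error("predicate id must be a non-empty string")
  }
  if (!is.function(evaluator)) {
    fop_structural_error(sprintf("predicate '%s': evaluator must be a function", id))
  }
  structure(list(id = id, description = description, evaluator = evaluator),
            class = "predicate_ref")
}

#' @rdname predicate_ref
#' @format NULL
#' @export
ALWAYS_TRUE <- NULL   # initialized in .onLoad-free manner below

#' @rdname predicate_ref
#' @format NULL
#' @export
ALWAYS_FALSE <- NULL

# Reserved predicates are plain constants: building them at load time keeps
# them usable inside serialized specs by id.
ALWAYS_TRUE <- predicate_ref(
  "ALWAYS_TRUE",
  function(token, source, target, net, tick) TRUE,
  "unconditionally enabled arc"
)
ALWAYS_FALSE <- predicate_ref(
  "ALWAYS_FALSE",
  function(token, source, target, net, tick) FALSE,
  "unconditionally disabled arc"
)

is_predicate_ref <- function(x) inherits(x, "predicate_ref")

im_key <- function(row, col) paste0(row, "\r", col)

#' Construct a transition-condition index matrix
#'
#' An index matrix is the condition of a reduced-GN transition: rows are
#' labelled by input places, columns by output places, and each cell holds a
#' predicate that gates token transfer along that arc. Cells not listed in
#' `entries` default to [ALWAYS_FALSE].
#'
#' @param rows Character vector of input-place labels (duplicate-free).
#' @param cols Character vector of output-place labels (duplicate-free).
#' @param entries List of cells, each `list(row =, col =, predicate =)` where
#'   `predicate` is a [predicate_ref].
#' @return An object of class `index_matrix` with fields `rows`, `cols`,
#'   and a cell lookup.
#' @export
#' @examples
#' im <- make_index_matrix("a", "b",
#'   list(list(row = "a", col = "b", predicate = ALWAYS_TRUE)))
make_index_matrix <- function(rows, cols, entries = list()) {
  rows <- as.character(rows)
  cols <- as.character(cols)
  if (length(rows) == 0L) fop_structural_error("index matrix: rows must be non-empty")
  if (length(cols) == 0L) fop_structural_error("index matrix: cols must be non-empty")
  dup <- unique(rows[duplicated(rows)])
  if (length(dup)) fop_structural_error(sprintf("duplicate label %s", dup[1L]))
  dup <- unique(cols[duplicated(cols)])
  if (length(dup)) fop_structural_error(sprintf("duplicate label %s", dup[1L]))

  cells <- new.env(parent = emptyenv())
  for (e in entries) {
    if (!all(c("row", "col", "predicate") %in% names(e))) {
      fop_structural_error("index matrix entry needs fields row, col, predicate")
    }
    if (!e$row %in% rows) {
      fop_structural_error(sprintf("entry references unknown row label %s", e$row))
    }
    if (!e$col %in% cols) {
      fop_structural_error(sprintf("entry references unknown col label %s", e$col))
    }
    if (!is_predicate_ref(e$predicate)) {
      fop_structural_error(sprintf("entry (%s,%s): predicate must be a predicate_ref",
                                   e$row, e$col))
    }
    assign(im_key(e$row, e$col), e$predicate, envir = cells)
  }
  structure(list(rows = rows, cols = cols, cells = cells),
            class = "index_matrix")
}

#' Look up one cell of an index matrix
#'
#' @param im An [make_index_matrix] result.
#' @param row,col Place labels.
#' @return The cell's [predicate_ref]; [ALWAYS_FALSE] for unspecified cells.
#' @export
im_cell <- function(im, row, col) {
  if (!row %in% im$rows) fop_structural_error(sprintf("unknown row label %s", row))
  if (!col %in% im$cols) fop_structural_error(sprintf("unknown col label %s", col))
  key <- im_key(row, col)
  if (exists(key, envir = im$cells, inherits = FALSE)) {
    get(key, envir = im$cells, inherits = FALSE)
  } else {
    ALWAYS_FALSE
  }
}

#' Evaluate one row of an index matrix against a firing context
#'
#' Evaluates every cell of the given row, in declared column order, for the
#' token carried by `ctx`. Row evaluation is read-only: evaluators receive
#' the net but must not modify it.
#'
#' @param im An index matrix.
#' @param row The input-place label whose row to evaluate.
#' @param ctx Firing context: `list(token =, net =, tick =)`. `token` is the
#'   token record currently residing in the place named by `row`.
#' @return A data frame with columns `col` (output place, in declared order)
#'   and `enabled` (logical).
#' @export
im_evaluate_row <- function(im, row, ctx) {
  if (!row %in% im$rows) fop_structural_error(sprintf("unknown row label %s", row))
  enabled <- vapply(im$cols, function(col) {
    pred <- im_cell(im, row, col)
    val <- tryCatch(
      pred$evaluator(ctx$token, row, col, ctx$net, ctx$tick),
      error = function(e) {
        fop_evaluation_error(sprintf(
          "predicate %s at cell (%s,%s) failed: %s",
          pred$id, row, col, conditionMessage(e)))
      })
    if (!is.logical(val) || length(val) != 1L || is.na(val)) {
      fop_evaluation_error(sprintf(
        "predicate %s at cell (%s,%s) returned a non-Boolean", pred$id, row, col))
    }
    val
  }, logical(1))
  data.frame(col = im$cols, enabled = unname(enabled), stringsAsFactors = FALSE)
}

#' @export
print.index_matrix <- function(x, ...) {
  cat(sprintf("index_matrix: %d input place(s) x %d output place(s)\n",
              length(x$rows), length(x$cols)))
  m <- matrix("ALWAYS_FALSE", length(x$rows), length(x$cols),
              dimnames = list(x$rows, x$cols))
  for (r in x$rows) for (co in x$cols) m[r, co] <- im_cell(x, r, co)$id
  print(m, quote = FALSE)
  invisible(x)
}

# Serialized form used inside net-spec documents.
im_to_list <- function(im) {
  ents <- list()
  for (r in im$rows) for (co in im$cols) {
    p <- im_cell(im, r, co)
    if (!identical(p$id, "ALWAYS_FALSE")) {
      ents[[length(ents) + 1L]] <- list(row = r, col = co, predicate = p$id)
    }
  }
  list(rows = as.list(im$rows), cols = as.list(im$cols), entries = ents)
}
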