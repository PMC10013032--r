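# Shared test fixtures: random small nets, an engine-independent brute-force
# firing reference, and audit/exclusivity helpers. Everything is generated in
# code under fixed seeds.

# Description of a random small net as plain data: places, initial marking,
# and transitions with logical condition matrices (TRUE = ALWAYS_TRUE arc).
random_net_descriptor <- function() {
  n_places <- sample(2:8, 1)
  places <- sprintf("p%d", seq_len(n_places))
  n_tokens <- sample(0:6, 1)
  marking <- stats::setNames(rep(list(character()), n_places), places)
  # token_places[i] is where token i starts; ids mirror the engine's
  # "{type}-{counter}" naming (tokens are spawned in index order).
  token_places <- character(0)
  for (i in seq_len(n_tokens)) {
    pl <- sample(places, 1)
    token_places <- c(token_places, pl)
    marking[[pl]] <- c(marking[[pl]], sprintf("tok-%d", i))
  }
  n_trans <- sample(1:4, 1)
  transitions <- lapply(seq_len(n_trans), function(j) {
    ins <- sample(places, sample(1:min(3, n_places), 1))
    outs <- sample(places, sample(1:min(3, n_places), 1))
    cond <- matrix(stats::runif(length(ins) * length(outs)) < 0.5,
                   nrow = length(ins), dimnames = list(ins, outs))
    list(id = sprintf("T%d", j), inputs = ins, outputs = outs, cond = cond)
  })
  list(places = places, marking = marking, token_places = token_places,
       transitions = transitions)
}

# Materialize a descriptor as an engine net (default move policy only).
build_net_from_descriptor <- function(d) {
  net <- new_gnet()
  for (pl in d$places) add_place(net, pl)
  for (tr in d$transitions) {
    entries <- list()
    for (r in tr$inputs) for (co in tr$outputs) {
      if (tr$cond[r, co]) {
        entries[[length(entries) + 1L]] <-
          list(row = r, col = co, predicate = ALWAYS_TRUE)
      }
    }
    add_transition(net, tr$id, tr$inputs, tr$outputs,
                   make_index_matrix(tr$inputs, tr$outputs, entries))
  }
  for (pl in d$token_places) spawn_token(net, "tok", pl, initial = TRUE)
  net
}

# Brute-force reference for one synchronous tick: enumerates every
# (input place, token, output place) triple per transition, in declared
# order, and applies the default policy (first enabled column); tokens that
# moved during the tick are frozen for the rest of it. Operates on plain
# lists only, never on engine objects.
reference_tick_marking <- function(d) {
  marking <- d$marking
  moved <- character(0)
  for (tr in d$transitions) {
    snapshot <- lapply(tr$inputs, function(pl) setdiff(marking[[pl]], moved))
    names(snapshot) <- tr$inputs
    for (pl in tr$inputs) {
      for (tid in snapshot[[pl]]) {
        if (tid %in% moved) next
        if (!tid %in% marking[[pl]]) next  # moved earlier in this firing
        enabled <- tr$outputs[tr$cond[pl, tr$outputs]]
        if (!length(enabled)) next
        dest <- enabled[[1L]]
        marking[[pl]] <- setdiff(marking[[pl]], tid)
        marking[[dest]] <- c(marking[[dest]], tid)
        moved <- c(moved, tid)
      }
    }
  }
  marking
}

# Engine marking as place -> sorted token ids (descriptor token numbering
# matches the engine's spawn order, so ids line up directly).
engine_marking <- function(net) {
  snap <- net_snapshot(net)
  lapply(snap$places, function(x) sort(x))
}

expect_clean_audit <- function(trace) {
  rep <- audit_trace(trace)
  expect_true(rep$ok, info = paste(rep$violations, collapse = "\n"))
  invisible(rep)
}

# For every impact token a receptor transition processed, the branch counts:
# supra (transfer to i{k}_2) and sub (unite in i{k}_3). Returns a data frame
# with one row per processed impact token.
receptor_branches <- function(trace) {
  ev <- trace$events
  at_recp <- !is.na(ev$transition) & grepl("^I[0-9]+$", ev$transition)
  rows <- which(at_recp & ev$kind %in% c("TRANSFER", "UNITE"))
  out <- list()
  for (i in rows) {
    toks <- strsplit(ev$tokens[[i]], ",")[[1L]]
    eps <- toks[grepl("^eps-", toks)]
    for (e in eps) {
      key <- e
      rec <- out[[key]] %||% list(supra = 0L, sub = 0L)
      if (ev$kind[[i]] == "TRANSFER" && grepl("_2$", ev$target[[i]])) {
        rec$supra <- rec$supra + 1L
      } else if (ev$kind[[i]] == "UNITE") {
        rec$sub <- rec$sub + 1L
      }
      out[[key]] <- rec
    }
  }
  if (!length(out)) {
    return(data.frame(token = character(), supra = integer(), sub = integer()))
  }
  data.frame(token = names(out),
             supra = vapply(out, `[[`, integer(1), "supra"),
             sub = vapply(out, `[[`, integer(1), "sub"),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Path of the pre-registered pain-reflex hand trace (committed before the
# engine was implemented).
hand_trace_fixture <- function() {
  path <- system.file("extdata", "pain_reflex_hand_trace.json", package = "fopnet")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata",
                                       "pain_reflex_hand_trace.json")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# Number of total-reaction tokens minted during a scenario run.
zeta_count <- function(res) {
  sum(vapply(res$trace$raw_events, function(e)
    e$kind == "CHARACTERISTIC" &&
      identical(e$payload$record$kind, "total_reaction"), logical(1)))
}
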