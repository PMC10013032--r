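#' Create an empty reduced Generalized Net
#'
#' A reduced Generalized Net is formally the four-tuple of its transitions
#' `A`, token set `K`, initial characteristics `X`, and characteristic
#' function `Phi`; see [gn_components()]. The returned object is an
#' environment so that token movement mutates the net in place, the way a
#' discrete-event simulation state should. Operationally it also carries a
#' place registry, a global tick clock, and a trace buffer.
#'
#' @return An environment of class `gnet`.
#' @export
new_gnet <- function() {
  net <- new.env(parent = emptyenv())
  net$A <- list()                         # ordered transitions
  net$K <- new.env(parent = emptyenv())   # token registry: id -> record
  net$X <- list()                         # token id -> initial characteristic
  net$Phi <- list()                       # named characteristic hooks
  net$places <- new.env(parent = emptyenv())
  net$place_order <- character()
  net$clock <- 0L
  net$events <- list()
  net$seq <- 0L
  net$counter <- 0L
  net$state <- new.env(parent = emptyenv())  # model-specific scratch
  class(net) <- "gnet"
  net
}

#' The formal four-tuple of a reduced Generalized Net
#'
#' Exposes exactly the four top-level components of the reduced-net
#' definition: `A` (the set of transitions), `K` (the set of tokens), `X`
#' (the initial characteristics tokens obtain on entering the net), and
#' `Phi` (the named characteristic hooks that assign new characteristics on
#' transfer). Places are not a top-level component: in the reduced form they
#' live inside each transition's input/output sets.
#'
#' @param net A `gnet`.
#' @return A list with exactly the names `A`, `K`, `X`, `Phi`.
#' @export
gn_components <- function(net) {
  stopifnot(inherits(net, "gnet"))
  list(A = net$A, K = as.list(net$K), X = net$X, Phi = net$Phi)
}

#' Add a place to a net
#' @param net A `gnet`.
#' @param id Place id, unique within the net.
#' @param role Free-text tag (e.g. "environment", "receptor-loop").
#' @return `net`, invisibly.
#' @export
add_place <- function(net, id, role = "") {
  if (exists(id, envir = net$places, inherits = FALSE)) {
    fop_structural_error(sprintf("duplicate place id %s", id))
  }
  assign(id, list(id = id, role = role, tokens = character()), envir = net$places)
  net$place_order <- c(net$place_order, id)
  invisible(net)
}

#' @rdname get_token
#' @export
get_place <- function(net, id) {
  if (!exists(id, envir = net$places, inherits = FALSE)) {
    fop_structural_error(sprintf("unknown place %s", id))
  }
  get(id, envir = net$places, inherits = FALSE)
}

set_place_tokens <- function(net, id, tokens) {
  pl <- get_place(net, id)
  pl$tokens <- tokens
  assign(id, pl, envir = net$places)
}

#' Add a transition to a net
#'
#' @param net A `gnet`.
#' @param id Transition id.
#' @param inputs,outputs Character vectors of place ids (the transition's
#'   input set and output set).
#' @param condition An [make_index_matrix] whose rows equal `inputs` and
#'   whose columns equal `outputs`.
#' @param arc_policies Named list keyed by `"row -> col"` pairs (see
#'   [arc_policy()]); arcs without a policy use the default `"move"` policy.
#' @param on_fire Optional function `(net, transition, tick)` that replaces
#'   the default firing procedure entirely.
#' @param on_no_arc Optional function `(net, token, tick)` called when an
#'   eligible token's condition row has no enabled column (the net keeps the
#'   token in place and records nothing; the hook may log a warning).
#' @return `net`, invisibly.
#' @export
add_transition <- function(net, id, inputs, outputs, condition,
                           arc_policies = list(), on_fire = NULL,
                           on_no_arc = NULL) {
  if (id %in% names(net$A)) {
    fop_structural_error(sprintf("duplicate transition id %s", id))
  }
  tr <- list(id = id, inputs = as.character(inputs),
             outputs = as.character(outputs),
             condition = condition, arc_policies = arc_policies,
             on_fire = on_fire, on_no_arc = on_no_arc)
  net$A[[id]] <- tr
  invisible(net)
}

#' Declare the behaviour of one arc of a transition
#'
#' Arc policies refine the default transfer semantics where the modelled
#' process calls for it:
#' * `"move"` (default): the token transfers to the arc's output place.
#' * `"stay"`: an enabled loop arc keeps the resident token in place; no
#'   event is recorded.
#' * `"split"`: the resident token stays and spawns children into the arc's
#'   output place; `children(net, parent, tick)` returns a list of
#'   `list(type_tag =, characteristic =)` specs (possibly several, e.g. one
#'   per pending stimulus).
#' * `"unite"`: the token transfers and then unites with a resident host
#'   token (first live resident of `host_type`, or chosen by `host`);
#'   the moving token's identity stops, the host survives and may gain a
#'   characteristic.
#'
#' @param kind One of `"move"`, `"stay"`, `"split"`, `"unite"`.
#' @param children For `"split"`: function `(net, parent, tick)` returning
#'   child specs.
#' @param host_type For `"unite"`: type tag of the resident host.
#' @param host For `"unite"`: optional function `(net, place_id)` returning
#'   the host token id.
#' @param characteristic Optional function. For `"move"`:
#'   `(net, token, tick)` record appended to the mover on arrival. For
#'   `"unite"`: `(net, host, arriving, tick)` record appended to the host.
#' @param after Optional function `(net, token_id, tick)` run after the arc
#'   action, for model-state bookkeeping (e.g. starting a processing delay).
#' @return A policy object used by [add_transition()].
#' @export
arc_policy <- function(kind = c("move", "stay", "split", "unite"),
                       children = NULL, host_type = NULL, host = NULL,
                       characteristic = NULL, after = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, children = children, host_type = host_type,
                 host = host, characteristic = characteristic, after = after),
            class = "fop_arc_policy")
}

arc_key <- function(row, col) paste(row, "->", col)

get_arc_policy <- function(tr, row, col) {
  p <- tr$arc_policies[[arc_key(row, col)]]
  if (is.null(p)) arc_policy("move") else p
}

## ---- token lifecycle ------------------------------------------------------

#' Look up a token or place record
#'
#' @param net A `gnet`.
#' @param id Token id / place id.
#' @return The token record (id, type tag, history, liveness, provenance,
#'   place) or the place record (id, role, token multiset).
#' @export
get_token <- function(net, id) {
  if (!exists(id, envir = net$K, inherits = FALSE)) {
    fop_structural_error(sprintf("unknown token %s", id))
  }
  get(id, envir = net$K, inherits = FALSE)
}

put_token <- function(net, tok) assign(tok$id, tok, envir = net$K)

emit_event <- function(net, kind, transition_id = NULL, token_ids = character(),
                       source = NULL, target = NULL, payload = list()) {
  net$seq <- net$seq + 1L
  ev <- list(tick = net$clock, seq = net$seq, kind = kind,
             transition = transition_id, tokens = as.character(token_ids),
             source = source, target = target, payload = payload)
  net$events[[length(net$events) + 1L]] <- ev
  fop_log(sprintf("[t=%d #%d] %s %s", ev$tick, ev$seq, kind,
                  paste(ev$tokens, collapse = ",")))
  ev
}

#' Create a token in a place
#'
#' Token ids are `"{type_tag}-{counter}"` with a net-global counter, so
#' emission order is reproducible across runs.
#'
#' @param net A `gnet`.
#' @param type_tag Token role tag (e.g. `"eps"`, `"omega"`, `"tau"`).
#' @param place Place id the token starts in.
#' @param characteristic Optional initial characteristic record; recorded in
#'   the net's `X` component and as the first history entry.
#' @param parent_ids Provenance (ids of tokens this one was split from).
#' @param initial If `TRUE`, the token is part of the net's initial marking
#'   and is eligible to move at tick 0; otherwise it is frozen until the
#'   tick after its creation.
#' @return The new token id.
#' @export
spawn_token <- function(net, type_tag, place, characteristic = NULL,
                        parent_ids = character(), initial = FALSE) {
  get_place(net, place)  # existence check
  net$counter <- net$counter + 1L
  id <- paste0(type_tag, "-", net$counter)
  tick <- if (initial) 0L else net$clock
  hist <- list()
  if (!is.null(characteristic)) {
    hist <- list(list(tick = tick, record = characteristic))
    net$X[[id]] <- characteristic
  }
  tok <- list(id = id, type_tag = type_tag, history = hist,
              alive = TRUE, parent_ids = as.character(parent_ids),
              place = place, moved_tick = if (initial) -1L else net$clock)
  put_token(net, tok)
  pl <- get_place(net, place)
  set_place_tokens(net, place, c(pl$tokens, id))
  id
}

#' Append a characteristic record to a token's history
#'
#' This is the engine's realization of the characteristic function: every
#' record is timestamped with the current tick and mirrored by one
#' `CHARACTERISTIC` trace event.
#'
#' @param net A `gnet`.
#' @param token_id Token receiving the record.
#' @param record The characteristic (any R list/value).
#' @param hook_id Optional name of the `Phi` hook that produced the record.
#' @return The token id, invisibly.
#' @export
set_characteristic <- function(net, token_id, record, hook_id = NULL) {
  tok <- get_token(net, token_id)
  if (!tok$alive) fop_structural_error(sprintf("token %s is dead", token_id))
  tok$history[[length(tok$history) + 1L]] <- list(tick = net$clock, record = record)
  put_token(net, tok)
  emit_event(net, "CHARACTERISTIC", token_ids = token_id,
             source = tok$place, target = tok$place,
             payload = list(hook = hook_id, record = record))
  invisible(token_id)
}

#' Split a token into child tokens
#'
#' The parent keeps its place and history; each child is created with parent
#' provenance and an optional initial characteristic. One `SPLIT` event is
#' recorded carrying parent and children.
#'
#' @param net A `gnet`.
#' @param token_id The (live) parent token.
#' @param child_specs List of `list(type_tag =, characteristic =)`.
#' @param target_place Place the children are created in; defaults to the
#'   parent's place.
#' @param transition_id Optional transition attribution for the trace.
#' @return Character vector of child token ids.
#' @export
split_token <- function(net, token_id, child_specs, target_place = NULL,
                        transition_id = NULL) {
  tok <- get_token(net, token_id)
  if (!tok$alive) fop_structural_error(sprintf("cannot split dead token %s", token_id))
  if (length(child_specs) == 0L) {
    fop_structural_error("split requires at least one child spec")
  }
  if (is.null(target_place)) target_place <- tok$place
  children <- vapply(child_specs, function(sp) {
    spawn_token(net, sp$type_tag, target_place,
                characteristic = sp$characteristic, parent_ids = token_id)
  }, character(1))
  emit_event(net, "SPLIT", transition_id = transition_id,
             token_ids = c(token_id, children),
             source = tok$place, target = target_place,
             payload = list(parent = token_id, children = as.list(children)))
  children
}

#' Unite co-located tokens into a host token
#'
#' The host survives with the constituents' histories merged (stable merge
#' by tick); all other tokens die and are removed from their place. One
#' `UNITE` event is recorded; the audit counts its deaths there, not in any
#' accompanying `STOP`.
#'
#' @param net A `gnet`.
#' @param token_ids At least two live, co-located token ids.
#' @param host_id The surviving token; must be among `token_ids`.
#' @param transition_id Optional transition attribution for the trace.
#' @return The surviving token id.
#' @export
unite_tokens <- function(net, token_ids, host_id, transition_id = NULL) {
  token_ids <- as.character(token_ids)
  if (length(unique(token_ids)) < 2L) {
    fop_structural_error("unite requires at least two distinct tokens")
  }
  if (!host_id %in% token_ids) {
    fop_structural_error("unite host must be among the united tokens")
  }
  toks <- lapply(token_ids, get_token, net = net)
  places <- vapply(toks, `[[`, character(1), "place")
  alive <- vapply(toks, `[[`, logical(1), "alive")
  if (!all(alive)) fop_structural_error("unite requires live tokens")
  if (length(unique(places)) != 1L) {
    fop_structural_error("unite requires co-located tokens")
  }
  host <- get_token(net, host_id)
  # Stable merge: concatenate histories in constituent order, sort by tick.
  merged <- do.call(c, lapply(toks, `[[`, "history"))
  if (length(merged)) {
    ticks <- vapply(merged, `[[`, numeric(1), "tick")
    merged <- merged[order(ticks, method = "radix")]
  }
  host$history <- merged
  put_token(net, host)
  for (tok in toks) {
    if (tok$id == host_id) next
    tok$alive <- FALSE
    pl <- get_place(net, tok$place)
    set_place_tokens(net, tok$place, setdiff(pl$tokens, tok$id))
    tok$place <- NA_character_
    put_token(net, tok)
  }
  emit_event(net, "UNITE", transition_id = transition_id,
             token_ids = token_ids, source = places[[1L]], target = places[[1L]],
             payload = list(host = host_id))
  host_id
}

#' Stop a token (it ceases functioning)
#'
#' @param net A `gnet`.
#' @param token_id Live token to stop.
#' @param cause Optional cause tag. The cause `"united"` marks stops that
#'   merely mirror a death already counted by a `UNITE` event; the
#'   conservation audit skips those.
#' @param transition_id Optional transition attribution.
#' @return The token id, invisibly.
#' @export
stop_token <- function(net, token_id, cause = NULL, transition_id = NULL) {
  tok <- get_token(net, token_id)
  already_dead <- !tok$alive
  if (!already_dead) {
    tok$alive <- FALSE
    pl <- get_place(net, tok$place)
    set_place_tokens(net, tok$place, setdiff(pl$tokens, tok$id))
    tok$place <- NA_character_
    put_token(net, tok)
  } else if (!identical(cause, "united")) {
    fop_structural_error(sprintf("token %s is already dead", token_id))
  }
  emit_event(net, "STOP", transition_id = transition_id, token_ids = token_id,
             payload = list(cause = cause))
  invisible(token_id)
}

## ---- firing ---------------------------------------------------------------

# Tokens resident in `place` that are alive and not frozen this tick.
eligible_tokens <- function(net, place, tick) {
  ids <- get_place(net, place)$tokens
  keep <- vapply(ids, function(id) {
    tok <- get_token(net, id)
    tok$alive && tok$moved_tick < tick
  }, logical(1))
  ids[keep]
}

move_token <- function(net, token_id, from, to, transition_id) {
  tok <- get_token(net, token_id)
  pl <- get_place(net, from)
  set_place_tokens(net, from, setdiff(pl$tokens, token_id))
  to_pl <- get_place(net, to)
  set_place_tokens(net, to, c(to_pl$tokens, token_id))
  tok$place <- to
  tok$moved_tick <- net$clock
  put_token(net, tok)
  emit_event(net, "TRANSFER", transition_id = transition_id,
             token_ids = token_id, source = from, target = to)
}

find_host <- function(net, place, host_type) {
  ids <- get_place(net, place)$tokens
  for (id in ids) {
    tok <- get_token(net, id)
    if (tok$alive && identical(tok$type_tag, host_type)) return(id)
  }
  NULL
}

apply_arc <- function(net, tr, token_id, row, col, tick) {
  pol <- get_arc_policy(tr, row, col)
  switch(pol$kind,
    stay = invisible(NULL),
    move = {
      move_token(net, token_id, row, col, tr$id)
      if (!is.null(pol$characteristic)) {
        rec <- pol$characteristic(net, get_token(net, token_id), tick)
        if (!is.null(rec)) set_characteristic(net, token_id, rec)
      }
      if (!is.null(pol$after)) pol$after(net, token_id, tick)
    },
    split = {
      specs <- pol$children(net, get_token(net, token_id), tick)
      if (length(specs)) {
        split_token(net, token_id, specs, target_place = col,
                    transition_id = tr$id)
        if (!is.null(pol$after)) pol$after(net, token_id, tick)
      }
    },
    unite = {
      host_id <- if (!is.null(pol$host)) pol$host(net, col) else
        find_host(net, col, pol$host_type)
      move_token(net, token_id, row, col, tr$id)
      if (is.null(host_id)) {
        # No resident host: the arriving token becomes the resident.
        if (!is.null(pol$after)) pol$after(net, token_id, tick)
        return(invisible(NULL))
      }
      unite_tokens(net, c(token_id, host_id), host_id, transition_id = tr$id)
      if (!is.null(pol$characteristic)) {
        arriving <- get_token(net, token_id)
        rec <- pol$characteristic(net, get_token(net, host_id), arriving, tick)
        if (!is.null(rec)) set_characteristic(net, host_id, rec)
      }
      stop_token(net, token_id, cause = "united", transition_id = tr$id)
      if (!is.null(pol$after)) pol$after(net, host_id, tick)
    })
  invisible(NULL)
}

#' Fire one transition at the current tick
#'
#' For each token resident in each input place at the start of the firing
#' (input places scanned in declared order), its condition row is evaluated
#' and the token acts along enabled arcs: every enabled `split` arc emits
#' children, then the first enabled `move`/`unite` arc (in declared column
#' order) carries the token. Tokens produced by this firing are not
#' re-examined by it, and tokens that already moved this tick are frozen.
#'
#' @param net A `gnet`.
#' @param transition_id Id of the transition to fire.
#' @param tick Must equal the net's clock (a mismatch signals a scheduler
#'   bug).
#' @return The list of trace events recorded by this firing.
#' @export
fire_transition <- function(net, transition_id, tick = net$clock) {
  tr <- net$A[[transition_id]]
  if (is.null(tr)) fop_structural_error(sprintf("unknown transition %s", transition_id))
  if (!identical(as.integer(tick), net$clock)) {
    fop_structural_error(sprintf("clock mismatch firing %s: tick %d vs clock %d",
                                 transition_id, as.integer(tick), net$clock))
  }
  ev0 <- length(net$events)
  if (!is.null(tr$on_fire)) {
    tr$on_fire(net, tr, net$clock)
    return(invisible(net$events[seq_len(length(net$events) - ev0) + ev0]))
  }
  # Snapshot residents per input place before any movement.
  snapshot <- lapply(tr$inputs, eligible_tokens, net = net, tick = net$clock)
  names(snapshot) <- tr$inputs
  for (place in tr$inputs) {
    for (token_id in snapshot[[place]]) {
      tok <- get_token(net, token_id)
      # May have moved or died earlier in this same firing (e.g. united).
      if (!tok$alive || !identical(tok$place, place) || tok$moved_tick >= net$clock) next
      rowres <- im_evaluate_row(tr$condition, place,
                                list(token = tok, net = net, tick = net$clock))
      enabled <- rowres$col[rowres$enabled]
      if (!length(enabled)) {
        if (!is.null(tr$on_no_arc)) tr$on_no_arc(net, tok, net$clock)
        next
      }
      kinds <- vapply(enabled, function(co) get_arc_policy(tr, place, co)$kind,
                      character(1))
      for (co in enabled[kinds == "split"]) apply_arc(net, tr, token_id, place, co, net$clock)
      carriers <- enabled[kinds %in% c("move", "unite")]
      if (length(carriers)) apply_arc(net, tr, token_id, place, carriers[[1L]], net$clock)
    }
  }
  invisible(net$events[seq_len(length(net$events) - ev0) + ev0])
}

#' Advance the net by one tick
#'
#' Fires every transition once, in the net's declared order, then increments
#' the clock. Tokens moved or created during tick `t` become eligible for
#' further movement only at tick `t + 1`, so one token never crosses two
#' transitions within a tick.
#'
#' @param net A `gnet`.
#' @return The list of trace events recorded during this tick.
#' @export
step <- function(net) {
  ev0 <- length(net$events)
  for (tid in names(net$A)) fire_transition(net, tid, net$clock)
  net$clock <- net$clock + 1L
  invisible(net$events[seq_len(length(net$events) - ev0) + ev0])
}

#' Run a net for a number of ticks
#'
#' Deterministic given the net specification and seed: repeated runs produce
#' byte-identical serialized traces. All stochastic hooks must draw from the
#' run's seeded generator (R's global RNG, seeded here) and never create
#' their own entropy.
#'
#' @param net A freshly built `gnet`.
#' @param n_ticks Number of ticks to simulate (>= 0).
#' @param seed Optional integer seed applied before the first tick.
#' @return An object of class `fop_trace`: `events` (data frame),
#'   `final_state` (marking and token histories), `n_ticks`, `seed`.
#' @export
run_net <- function(net, n_ticks, seed = NULL) {
  if (n_ticks < 0) fop_structural_error("n_ticks must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  initial_state <- net_snapshot(net)
  for (i in seq_len(n_ticks)) step(net)
  structure(list(events = trace_events_df(net$events),
                 raw_events = net$events,
                 initial_state = initial_state,
                 final_state = net_snapshot(net),
                 n_ticks = as.integer(n_ticks),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "fop_trace")
}

#' Tabulate trace events
#' @param events List of raw event records (from `net$events`).
#' @return Data frame with one row per event: `tick`, `seq`, `kind`,
#'   `transition`, `tokens` (comma-joined), `source`, `target`.
#' @export
trace_events_df <- function(events) {
  if (!length(events)) {
    return(data.frame(tick = integer(), seq = integer(), kind = character(),
                      transition = character(), tokens = character(),
                      source = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    tick = vapply(events, function(e) as.integer(e$tick), integer(1)),
    seq = vapply(events, function(e) as.integer(e$seq), integer(1)),
    kind = vapply(events, `[[`, character(1), "kind"),
    transition = vapply(events, function(e) e$transition %||% NA_character_, character(1)),
    tokens = vapply(events, function(e) paste(e$tokens, collapse = ","), character(1)),
    source = vapply(events, function(e) e$source %||% NA_character_, character(1)),
    target = vapply(events, function(e) e$target %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)
  df$payload <- lapply(events, `[[`, "payload")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Snapshot the current marking and token histories
#' @param net A `gnet`.
#' @return List with `clock`, `places` (place id -> token ids) and `tokens`
#'   (token id -> type tag, liveness, place, history).
#' @export
net_snapshot <- function(net) {
  places <- lapply(net$place_order, function(pid) get_place(net, pid)$tokens)
  names(places) <- net$place_order
  tok_ids <- sort(ls(net$K))
  tokens <- lapply(tok_ids, function(id) {
    tok <- get_token(net, id)
    list(type_tag = tok$type_tag, alive = tok$alive, place = tok$place,
         parent_ids = tok$parent_ids, history = tok$history)
  })
  names(tokens) <- tok_ids
  list(clock = net$clock, places = places, tokens = tokens)
}

# Digest of net state, used to check that predicate evaluation is pure.
net_state_digest <- function(net) {
  serialize(net_snapshot(net), NULL, version = 3L)
}

#' Validate a net's structural invariants
#'
#' Violations are data, not exceptions: an empty character vector means the
#' net is well formed. Checked: non-empty input/output sets; condition
#' rows/columns matching the transition's input/output sets; all referenced
#' places registered; every live token resident in exactly one place;
#' non-decreasing history ticks.
#'
#' @param net A `gnet`.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_net <- function(net) {
  v <- character()
  for (tr in net$A) {
    if (!length(tr$inputs)) v <- c(v, sprintf("transition %s: empty input set", tr$id))
    if (!length(tr$outputs)) v <- c(v, sprintf("transition %s: empty output set", tr$id))
    if (!identical(tr$condition$rows, tr$inputs)) {
      v <- c(v, sprintf("transition %s: condition rows != inputs", tr$id))
    }
    if (!identical(tr$condition$cols, tr$outputs)) {
      v <- c(v, sprintf("transition %s: condition cols != outputs", tr$id))
    }
    for (pid in c(tr$inputs, tr$outputs)) {
      if (!exists(pid, envir = net$places, inherits = FALSE)) {
        v <- c(v, sprintf("transition %s references unknown place %s", tr$id, pid))
      }
    }
  }
  residence <- list()
  for (pid in net$place_order) {
    for (tid in get_place(net, pid)$tokens) {
      residence[[tid]] <- c(residence[[tid]], pid)
    }
  }
  for (tid in ls(net$K)) {
    tok <- get_token(net, tid)
    homes <- residence[[tid]] %||% character()
    if (tok$alive && length(homes) != 1L) {
      v <- c(v, sprintf("live token %s resides in %d places", tid, length(homes)))
    }
    if (!tok$alive && length(homes) != 0L) {
      v <- c(v, sprintf("dead token %s still placed", tid))
    }
    if (length(tok$history) > 1L) {
      ticks <- vapply(tok$history, `[[`, numeric(1), "tick")
      if (is.unsorted(ticks)) {
        v <- c(v, sprintf("token %s: history ticks decrease", tid))
      }
    }
  }
  v
}

#' @export
print.gnet <- function(x, ...) {
  n_live <- sum(vapply(ls(x$K), function(id) get_token(x, id)$alive, logical(1)))
  cat(sprintf("gnet: %d transition(s), %d place(s), %d live token(s), clock %d\n",
              length(x$A), length(x$place_order), n_live, x$clock))
  invisible(x)
}

#' @export
print.fop_trace <- function(x, ...) {
  cat(sprintf("fop_trace: %d event(s) over %d tick(s)\n",
              nrow(x$events), x$n_ticks))
  if (nrow(x$events)) print(utils::head(x$events[, 1:7], 10))
  invisible(x)
}
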