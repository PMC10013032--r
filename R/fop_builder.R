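#' Configuration for a Foreign-Object-Principle net
#'
#' Parameterizes the FOP net: a system with `m` thresholded receptors
#' (skin/sensor boundary), `n` internal processing components, and `p`
#' effectors emitting reactions back into the environment.
#'
#' @param m Receptor/sensor count (>= 1).
#' @param n System-component count (>= 1).
#' @param p Effector count (>= 1).
#' @param initial_thresholds Numeric vector of length `m`, non-negative:
#'   initial receptor thresholds (strength units; a stimulus passes a
#'   receptor only if strictly greater).
#' @param processing_delays Integer vector of length `n`, each >= 1: ticks a
#'   component needs before its response is ready.
#' @param effector_delays Integer vector of length `p`, each >= 1: ticks an
#'   effector needs before it emits.
#' @param routing Named integer map stimulus modality -> receptor index; the
#'   name `"*"` is a catch-all. Default: every modality to receptor 1.
#' @param component_policy Named integer map modality -> component index
#'   processing the registered impact; `"*"` catch-all. Default: component 1.
#' @param effector_policy Named integer map modality -> effector index
#'   emitting the response; `"*"` catch-all. Default: effector 1.
#' @param adaptation List describing receptor-threshold adaptation:
#'   `rule` is `"none"` or `"multiplicative"`; for the multiplicative rule,
#'   `gamma` (> 0) scales the threshold on each trigger and `trigger` is one
#'   of `"registered"` (every impact that reaches a receptor, supra- or
#'   sub-threshold), `"sub_threshold"`, `"supra_threshold"`.
#' @return An object of class `fop_config`.
#' @export
fop_config <- function(m = 1L, n = 1L, p = 1L,
                       initial_thresholds = rep(3.0, m),
                       processing_delays = rep(1L, n),
                       effector_delays = rep(1L, p),
                       routing = c("*" = 1L),
                       component_policy = c("*" = 1L),
                       effector_policy = c("*" = 1L),
                       adaptation = list(rule = "none")) {
  m <- as.integer(m); n <- as.integer(n); p <- as.integer(p)
  if (is.na(m) || m < 1L) fop_structural_error("fop_config: m must be >= 1")
  if (is.na(n) || n < 1L) fop_structural_error("fop_config: n must be >= 1")
  if (is.na(p) || p < 1L) fop_structural_error("fop_config: p must be >= 1")
  if (length(initial_thresholds) != m) {
    fop_structural_error("fop_config: initial_thresholds must have length m")
  }
  if (any(!is.finite(initial_thresholds)) || any(initial_thresholds < 0)) {
    fop_structural_error("fop_config: thresholds must be finite and >= 0")
  }
  if (length(processing_delays) != n) {
    fop_structural_error("fop_config: processing_delays must have length n")
  }
  if (length(effector_delays) != p) {
    fop_structural_error("fop_config: effector_delays must have length p")
  }
  if (any(processing_delays < 1L) || any(effector_delays < 1L)) {
    fop_structural_error("fop_config: delays must be >= 1 tick")
  }
  if (is.null(adaptation$rule)) adaptation$rule <- "none"
  if (!adaptation$rule %in% c("none", "multiplicative")) {
    fop_structural_error(sprintf("fop_config: unknown adaptation rule %s",
                                 adaptation$rule))
  }
  if (adaptation$rule == "multiplicative") {
    if (is.null(adaptation$gamma) || !is.finite(adaptation$gamma) ||
        adaptation$gamma <= 0) {
      fop_structural_error("fop_config: multiplicative adaptation needs gamma > 0")
    }
    if (is.null(adaptation$trigger)) adaptation$trigger <- "registered"
    if (!adaptation$trigger %in% c("registered", "sub_threshold", "supra_threshold")) {
      fop_structural_error(sprintf("fop_config: unknown adaptation trigger %s",
                                   adaptation$trigger))
    }
  }
  check_route_map <- function(map, upper, what) {
    if (!length(map)) fop_structural_error(sprintf("fop_config: empty %s", what))
    if (is.null(names(map)) || any(!nzchar(names(map)))) {
      fop_structural_error(sprintf("fop_config: %s must be a named map", what))
    }
    if (any(map < 1L | map > upper)) {
      fop_structural_error(sprintf("fop_config: %s index out of range 1..%d",
                                   what, upper))
    }
  }
  check_route_map(routing, m, "routing")
  check_route_map(component_policy, n, "component_policy")
  check_route_map(effector_policy, p, "effector_policy")
  structure(list(m = m, n = n, p = p,
                 initial_thresholds = as.numeric(initial_thresholds),
                 processing_delays = as.integer(processing_delays),
                 effector_delays = as.integer(effector_delays),
                 routing = routing, component_policy = component_policy,
                 effector_policy = effector_policy, adaptation = adaptation),
            class = "fop_config")
}

# Resolve a modality through a named routing map ("*" is the catch-all).
route_index <- function(map, modality) {
  if (!is.null(modality) && modality %in% names(map)) {
    as.integer(map[[modality]])
  } else if ("*" %in% names(map)) {
    as.integer(map[["*"]])
  } else {
    NA_integer_
  }
}

# Newest history record carrying `field`, scanned latest-first.
token_field <- function(tok, field) {
  for (i in rev(seq_along(tok$history))) {
    rec <- tok$history[[i]]$record
    if (is.list(rec) && field %in% names(rec)) return(rec[[field]])
  }
  NULL
}

#' Current threshold of the k-th receptor
#'
#' Read from the threshold token's characteristic history (the newest record
#' carrying a threshold value), which is where threshold updates land.
#'
#' @param net A FOP `gnet`.
#' @param k Receptor index.
#' @return The current threshold (numeric).
#' @export
current_threshold <- function(net, k) {
  tau <- get_token(net, net$state$tau_ids[[k]])
  val <- token_field(tau, "threshold")
  if (is.null(val)) fop_structural_error(sprintf("receptor %d has no threshold", k))
  as.numeric(val)
}

#' Validate a proposed receptor-threshold update
#'
#' Applied when a threshold-change token unites with the receptor's
#' threshold token: the newest history record of the threshold token then
#' holds the new value, and subsequent supra-threshold tests use it.
#'
#' @param tau_history The threshold token's history (list of tick/record
#'   pairs).
#' @param kappa_characteristic The threshold-change token's characteristic;
#'   must carry a finite, non-negative `new_threshold`.
#' @return The accepted new threshold value (numeric).
#' @export
threshold_update <- function(tau_history, kappa_characteristic) {
  val <- kappa_characteristic$new_threshold
  if (is.null(val) || !is.finite(val)) {
    fop_structural_error("threshold update: proposed value must be finite")
  }
  if (val < 0) {
    fop_structural_error("threshold update: proposed value must be >= 0")
  }
  as.numeric(val)
}

#' Stage a stimulus train into a FOP net
#'
#' Stimuli are the environment's impacts: each becomes one impact token
#' emitted into the environment boundary at its tick.
#'
#' @param net A FOP `gnet` built by [build_fop_net()].
#' @param stimuli Data frame with columns `tick` (integer, non-decreasing),
#'   `modality` (character) and `strength` (non-negative numeric).
#' @return `net`, invisibly.
#' @export
fop_stage_stimuli <- function(net, stimuli) {
  if (nrow(stimuli)) {
    if (is.unsorted(stimuli$tick)) {
      fop_structural_error("stimulus ticks must be non-decreasing")
    }
    if (any(stimuli$strength < 0)) {
      fop_structural_error("stimulus strengths must be >= 0")
    }
  }
  stimuli$index <- seq_len(nrow(stimuli))
  stimuli$emitted <- rep(FALSE, nrow(stimuli))
  net$state$stimuli <- stimuli
  invisible(net)
}

#' Build the Foreign-Object-Principle net
#'
#' Constructs the full net: environment boundary transitions (`En0`, `En1`,
#' `En2`), one receptor transition `I_k` per receptor with its threshold
#' token, the central system transition `S` with its status token, one
#' component transition `S_k` per component, and one effector transition
#' `O_k` per effector with its effector token. The net has
#' `m + n + p + 3` transitions and `4m + 3(n + p + 1) + 1` places.
#'
#' Initial marking: the environment token `eps_star` in `e0`, the system
#' status token `omega` in `s`, one threshold token `tau` per receptor in
#' `i{k}_3` (characteristic = initial threshold), one effector token `phi`
#' per effector in `o{k}_3`.
#'
#' @param config A [fop_config()].
#' @return A `gnet` ready for [fop_stage_stimuli()] and [run_net()].
#' @export
build_fop_net <- function(config) {
  if (!inherits(config, "fop_config")) config <- do.call(fop_config, config)
  net <- new_gnet()
  st <- net$state
  st$cfg <- config
  st$token_roles <- c("eps_star", "eps", "omega", "phi", "tau", "kappa")
  st$stimuli <- data.frame(tick = integer(), modality = character(),
                           strength = numeric(), index = integer(),
                           emitted = logical(), stringsAsFactors = FALSE)
  st$triggers_seen <- integer(config$m)
  st$kappas_emitted <- integer(config$m)
  st$pending_impacts <- list()
  st$pending_responses <- list()
  st$unrouted_warned <- character()
  st$comp_jobs <- vector("list", config$n)
  st$eff_jobs <- vector("list", config$p)

  m <- config$m; n <- config$n; p <- config$p

  add_place(net, "e0", "environment")
  add_place(net, "e1", "environment")
  add_place(net, "e2", "environment")
  add_place(net, "s", "system-core")
  for (k in seq_len(m)) {
    add_place(net, sprintf("i%d_1", k), "receptor-input")
    add_place(net, sprintf("i%d_2", k), "receptor-output")
    add_place(net, sprintf("i%d_3", k), "receptor-loop")
    add_place(net, sprintf("i%d", k), "threshold-control")
  }
  for (k in seq_len(n)) {
    add_place(net, sprintf("s%d_1", k), "component-input")
    add_place(net, sprintf("s%d_2", k), "component-output")
    add_place(net, sprintf("s%d_3", k), "component-loop")
  }
  for (k in seq_len(p)) {
    add_place(net, sprintf("o%d_1", k), "effector-input")
    add_place(net, sprintf("o%d_2", k), "effector-output")
    add_place(net, sprintf("o%d_3", k), "effector-loop")
  }

  hooks <- fop_default_hooks(config)
  net$Phi <- hooks$characteristics

  ## ---- En0: the environment emits impacts and absorbs the reaction ----
  add_transition(net, "En0",
    inputs = c("e0", "e2"), outputs = c("e0", "e1"),
    condition = make_index_matrix(c("e0", "e2"), c("e0", "e1"), list(
      # NOTE: the printed condition matrix for En0 is a figure placeholder in
      # the source text; the e0->e0 self-loop (the environment token stays)
      # is reconstructed, not forced by prose.
      list(row = "e0", col = "e0", predicate = ALWAYS_TRUE),
      list(row = "e0", col = "e1", predicate = hooks$predicates$W_0_1),
      list(row = "e2", col = "e0", predicate = ALWAYS_TRUE))))
  net$A[["En0"]]$arc_policies <- list()
  net$A[["En0"]]$arc_policies[[arc_key("e0", "e0")]] <- arc_policy("stay")
  net$A[["En0"]]$arc_policies[[arc_key("e0", "e1")]] <- arc_policy(
    "split", children = function(net, parent, tick) {
      stim <- net$state$stimuli
      due <- which(!stim$emitted & stim$tick <= tick)
      if (!length(due)) return(list())
      net$state$stimuli$emitted[due] <- TRUE
      lapply(due, function(i) list(
        type_tag = "eps",
        characteristic = list(
          kind = "impact",
          text = "information about the impact from the environment to the system",
          stimulus_index = stim$index[[i]], modality = stim$modality[[i]],
          strength = stim$strength[[i]], stimulus_tick = stim$tick[[i]])))
    })
  net$A[["En0"]]$arc_policies[[arc_key("e2", "e0")]] <- arc_policy(
    "unite", host_type = "eps_star",
    characteristic = function(net, host, arriving, tick) list(
      kind = "environment_result",
      text = "a result of the impact of the system over the environment",
      stimulus_indices = token_field(arriving, "stimulus_indices")))

  ## ---- En1: routing impacts to receptors ----
  i1_places <- sprintf("i%d_1", seq_len(m))
  en1_entries <- lapply(seq_len(m), function(k) list(
    row = "e1", col = i1_places[[k]], predicate = hooks$predicates[[sprintf("W_1_%d_1", k)]]))
  add_transition(net, "En1",
    inputs = "e1", outputs = i1_places,
    condition = make_index_matrix("e1", i1_places, en1_entries),
    on_no_arc = function(net, token, tick) {
      # Warn once per token: it stays at the boundary (no drop rule exists).
      if (token$id %in% net$state$unrouted_warned) return(invisible(NULL))
      net$state$unrouted_warned <- c(net$state$unrouted_warned, token$id)
      fop_warn(sprintf("stimulus token %s at tick %d matched no receptor; it stays in e1",
                       token$id, tick), "fop_unrouted_stimulus")
    })

  ## ---- I_k: receptor thresholding ----
  for (k in seq_len(m)) {
    ins <- c(sprintf("i%d_1", k), sprintf("i%d_3", k), sprintf("i%d", k))
    outs <- c(sprintf("i%d_2", k), sprintf("i%d_3", k))
    entries <- list(
      list(row = ins[1], col = outs[1], predicate = hooks$predicates[[sprintf("W_1_%d_2", k)]]),
      list(row = ins[1], col = outs[2], predicate = hooks$predicates[[sprintf("W_1_%d_3", k)]]),
      # NOTE: the I_k condition matrix is a figure placeholder in the source;
      # the i{k}_3 self-loop (threshold token stays) and the unconditional
      # i{k} -> i{k}_3 arc are reconstructed from prose.
      list(row = ins[2], col = outs[2], predicate = ALWAYS_TRUE),
      list(row = ins[3], col = outs[2], predicate = ALWAYS_TRUE))
    pol <- list()
    pol[[arc_key(ins[2], outs[2])]] <- arc_policy("stay")
    pol[[arc_key(ins[1], outs[2])]] <- arc_policy(
      "unite", host_type = "tau",
      characteristic = local({
        k_ <- k
        function(net, host, arriving, tick) {
          cfg <- net$state$cfg
          trig <- cfg$adaptation$trigger %||% "registered"
          if (cfg$adaptation$rule != "none" &&
              trig %in% c("registered", "sub_threshold")) {
            net$state$triggers_seen[[k_]] <- net$state$triggers_seen[[k_]] + 1L
          }
          list(kind = "registration",
               text = sprintf("an impact is registered by the %d-th receptor/sensor", k_),
               time_moment = tick,
               stimulus_index = token_field(arriving, "stimulus_index"),
               strength = token_field(arriving, "strength"),
               relation = "under")
        }
      }))
    pol[[arc_key(ins[3], outs[2])]] <- arc_policy(
      "unite", host_type = "tau",
      characteristic = local({
        k_ <- k
        function(net, host, arriving, tick) {
          proposal <- list(new_threshold = token_field(arriving, "new_threshold"))
          val <- threshold_update(host$history, proposal)
          list(kind = "threshold_update",
               text = sprintf("new value of the threshold of the %d-th receptor/sensor", k_),
               threshold = val)
        }
      }))
    add_transition(net, sprintf("I%d", k), ins, outs,
                   condition = make_index_matrix(ins, outs, entries),
                   arc_policies = pol)
  }

  ## ---- S: the system core (unite arrivals into omega, then dispatch) ----
  s_ins <- c(sprintf("i%d_2", seq_len(m)), sprintf("s%d_2", seq_len(n)), "s")
  s_outs <- c(sprintf("s%d_1", seq_len(n)), sprintf("o%d_1", seq_len(p)),
              sprintf("i%d", seq_len(m)), "s")
  s_entries <- list()
  s_pol <- list()
  for (k in seq_len(m)) {
    row <- sprintf("i%d_2", k)
    s_entries[[length(s_entries) + 1L]] <-
      list(row = row, col = "s", predicate = ALWAYS_TRUE)
    s_pol[[arc_key(row, "s")]] <- arc_policy(
      "unite", host_type = "omega",
      characteristic = function(net, host, arriving, tick) {
        cfg <- net$state$cfg
        modality <- token_field(arriving, "modality")
        rec <- list(kind = "impact_registration",
                    text = "registration of the impact, parameters",
                    stimulus_index = token_field(arriving, "stimulus_index"),
                    modality = modality,
                    strength = token_field(arriving, "strength"),
                    stimulus_tick = token_field(arriving, "stimulus_tick"),
                    time_moment = tick)
        net$state$pending_impacts[[length(net$state$pending_impacts) + 1L]] <- rec
        trig <- cfg$adaptation$trigger %||% "registered"
        if (cfg$adaptation$rule != "none" &&
            trig %in% c("registered", "supra_threshold")) {
          r <- route_index(cfg$routing, modality)
          if (!is.na(r)) {
            net$state$triggers_seen[[r]] <- net$state$triggers_seen[[r]] + 1L
          }
        }
        rec
      })
  }
  for (k in seq_len(n)) {
    row <- sprintf("s%d_2", k)
    s_entries[[length(s_entries) + 1L]] <-
      list(row = row, col = "s", predicate = ALWAYS_TRUE)
    s_pol[[arc_key(row, "s")]] <- arc_policy(
      "unite", host_type = "omega",
      characteristic = local({
        k_ <- k
        function(net, host, arriving, tick) {
          rec <- list(kind = "component_response",
                      text = "reaction of the respective part of the system to the corresponding impact",
                      component = k_,
                      stimulus_indices = token_field(arriving, "stimulus_indices"),
                      modality = token_field(arriving, "modality"),
                      time_moment = tick)
          net$state$pending_responses[[length(net$state$pending_responses) + 1L]] <- rec
          rec
        }
      }))
  }
  for (k in seq_len(n)) {
    col <- sprintf("s%d_1", k)
    s_entries[[length(s_entries) + 1L]] <-
      list(row = "s", col = col, predicate = hooks$predicates[[sprintf("V_s_%d", k)]])
    s_pol[[arc_key("s", col)]] <- arc_policy(
      "split", children = local({
        k_ <- k
        function(net, parent, tick) {
          cfg <- net$state$cfg
          mine <- vapply(net$state$pending_impacts, function(rec)
            identical(route_index(cfg$component_policy, rec$modality), k_), logical(1))
          picked <- net$state$pending_impacts[mine]
          net$state$pending_impacts <- net$state$pending_impacts[!mine]
          lapply(picked, function(rec) list(
            type_tag = "sigma",
            characteristic = list(
              kind = "process_impact",
              text = "the current impact must be processed by the respective part of the system",
              component = k_, stimulus_index = rec$stimulus_index,
              modality = rec$modality, strength = rec$strength,
              stimulus_tick = rec$stimulus_tick)))
        }
      }))
  }
  for (k in seq_len(p)) {
    col <- sprintf("o%d_1", k)
    s_entries[[length(s_entries) + 1L]] <-
      list(row = "s", col = col, predicate = hooks$predicates[[sprintf("V_o_%d", k)]])
    s_pol[[arc_key("s", col)]] <- arc_policy(
      "split", children = local({
        k_ <- k
        function(net, parent, tick) {
          cfg <- net$state$cfg
          mine <- vapply(net$state$pending_responses, function(rec)
            identical(route_index(cfg$effector_policy, rec$modality), k_), logical(1))
          picked <- net$state$pending_responses[mine]
          net$state$pending_responses <- net$state$pending_responses[!mine]
          lapply(picked, function(rec) list(
            type_tag = "pi",
            characteristic = list(
              kind = "direct_reaction",
              text = "the prepared by the system reaction must be directed to the respective effector",
              effector = k_, component = rec$component,
              stimulus_indices = rec$stimulus_indices,
              modality = rec$modality)))
        }
      }))
  }
  for (k in seq_len(m)) {
    col <- sprintf("i%d", k)
    s_entries[[length(s_entries) + 1L]] <-
      list(row = "s", col = col, predicate = hooks$predicates[[sprintf("V_i_%d", k)]])
    s_pol[[arc_key("s", col)]] <- arc_policy(
      "split", children = local({
        k_ <- k
        function(net, parent, tick) {
          cfg <- net$state$cfg
          outstanding <- net$state$triggers_seen[[k_]] - net$state$kappas_emitted[[k_]]
          if (outstanding <= 0L) return(list())
          net$state$kappas_emitted[[k_]] <- net$state$triggers_seen[[k_]]
          new_val <- current_threshold(net, k_) * cfg$adaptation$gamma ^ outstanding
          list(list(
            type_tag = "kappa",
            characteristic = list(
              kind = "threshold_change",
              text = sprintf("new value of the threshold of the %d-th receptor/sensor", k_),
              receptor = k_, new_threshold = new_val)))
        }
      }))
  }
  s_entries[[length(s_entries) + 1L]] <-
    list(row = "s", col = "s", predicate = ALWAYS_TRUE)
  s_pol[[arc_key("s", "s")]] <- arc_policy("stay")
  # Input order puts `s` last, so arrivals unite into omega before omega's
  # own row is evaluated: the two-phase convention within one tick.
  add_transition(net, "S", s_ins, s_outs,
                 condition = make_index_matrix(s_ins, s_outs, s_entries),
                 arc_policies = s_pol)

  ## ---- S_k: system components with processing delays ----
  for (k in seq_len(n)) {
    ins <- c(sprintf("s%d_1", k), sprintf("s%d_3", k))
    outs <- c(sprintf("s%d_2", k), sprintf("s%d_3", k))
    entries <- list(
      # NOTE: the S_k condition matrix is a figure placeholder in the source;
      # the s{k}_1 -> s{k}_3 intake arc and the s{k}_3 self-loop are
      # reconstructed from prose ("continues staying in place s_{k,3}").
      list(row = ins[1], col = outs[2], predicate = ALWAYS_TRUE),
      list(row = ins[2], col = outs[1], predicate = hooks$predicates[[sprintf("U_3_%d_2", k)]]),
      list(row = ins[2], col = outs[2], predicate = ALWAYS_TRUE))
    pol <- list()
    pol[[arc_key(ins[2], outs[2])]] <- arc_policy("stay")
    pol[[arc_key(ins[1], outs[2])]] <- arc_policy(
      "unite", host_type = "sigma",
      characteristic = function(net, host, arriving, tick) NULL,
      after = local({
        k_ <- k
        function(net, token_id, tick) {
          tok <- get_token(net, token_id)
          job <- net$state$comp_jobs[[k_]]
          if (is.null(job)) job <- list(arrival = tick, impacts = list())
          job$arrival <- tick
          job$impacts[[length(job$impacts) + 1L]] <- list(
            stimulus_index = token_field(tok, "stimulus_index"),
            modality = token_field(tok, "modality"),
            strength = token_field(tok, "strength"),
            stimulus_tick = token_field(tok, "stimulus_tick"))
          net$state$comp_jobs[[k_]] <- job
        }
      }))
    pol[[arc_key(ins[2], outs[1])]] <- arc_policy(
      "split", children = local({
        k_ <- k
        function(net, parent, tick) {
          job <- net$state$comp_jobs[[k_]]
          if (is.null(job)) return(list())
          net$state$comp_jobs[k_] <- list(NULL)
          idx <- unlist(lapply(job$impacts, `[[`, "stimulus_index"))
          modality <- job$impacts[[1L]]$modality
          list(list(
            type_tag = "sigma_prime",
            characteristic = list(
              kind = "response",
              text = "response to the registered impact, parameters",
              component = k_, stimulus_indices = as.list(idx),
              modality = modality, ready_tick = tick)))
        }
      }))
    add_transition(net, sprintf("S%d", k), ins, outs,
                   condition = make_index_matrix(ins, outs, entries),
                   arc_policies = pol)
  }

  ## ---- O_k: effectors with emission delays ----
  for (k in seq_len(p)) {
    ins <- c(sprintf("o%d_1", k), sprintf("o%d_3", k))
    outs <- c(sprintf("o%d_2", k), sprintf("o%d_3", k))
    entries <- list(
      # NOTE: the O_k condition matrix is a figure placeholder in the source;
      # the reaction token's path o{k}_1 -> o{k}_3 (uniting with the effector
      # token) and the o{k}_3 self-loop are reconstructed, not forced by prose.
      list(row = ins[1], col = outs[2], predicate = ALWAYS_TRUE),
      list(row = ins[2], col = outs[1], predicate = hooks$predicates[[sprintf("T_3_%d_2", k)]]),
      list(row = ins[2], col = outs[2], predicate = ALWAYS_TRUE))
    pol <- list()
    pol[[arc_key(ins[2], outs[2])]] <- arc_policy("stay")
    pol[[arc_key(ins[1], outs[2])]] <- arc_policy(
      "unite", host_type = "phi",
      characteristic = local({
        k_ <- k
        function(net, host, arriving, tick) list(
          kind = "reaction_received", effector = k_,
          stimulus_indices = token_field(arriving, "stimulus_indices"),
          modality = token_field(arriving, "modality"))
      }),
      after = local({
        k_ <- k
        function(net, token_id, tick) {
          tok <- get_token(net, token_id)
          net$state$eff_jobs[[k_]] <- list(
            arrival = tick,
            stimulus_indices = token_field(tok, "stimulus_indices"),
            modality = token_field(tok, "modality"))
        }
      }))
    pol[[arc_key(ins[2], outs[1])]] <- arc_policy(
      "split", children = local({
        k_ <- k
        function(net, parent, tick) {
          job <- net$state$eff_jobs[[k_]]
          if (is.null(job)) return(list())
          net$state$eff_jobs[k_] <- list(NULL)
          list(list(
            type_tag = "phi_prime",
            characteristic = list(
              kind = "effector_reaction",
              text = sprintf("system reaction for the %d-th effector, parameters", k_),
              effector = k_, stimulus_indices = job$stimulus_indices,
              modality = job$modality)))
        }
      }))
    add_transition(net, sprintf("O%d", k), ins, outs,
                   condition = make_index_matrix(ins, outs, entries),
                   arc_policies = pol)
  }

  ## ---- En2: all effector outputs unite into one total-reaction token ----
  o2_places <- sprintf("o%d_2", seq_len(p))
  en2_entries <- lapply(o2_places, function(pl) list(
    row = pl, col = "e2", predicate = ALWAYS_TRUE))
  add_transition(net, "En2", o2_places, "e2",
    condition = make_index_matrix(o2_places, "e2", en2_entries),
    on_fire = function(net, tr, tick) {
      movers <- unlist(lapply(tr$inputs, function(pl) {
        ids <- eligible_tokens(net, pl, tick)
        ids[vapply(ids, function(id) get_token(net, id)$type_tag == "phi_prime",
                   logical(1))]
      }))
      if (!length(movers)) return(invisible(NULL))
      for (id in movers) {
        move_token(net, id, get_token(net, id)$place, "e2", tr$id)
      }
      host <- movers[[1L]]
      idx <- unique(unlist(lapply(movers, function(id)
        token_field(get_token(net, id), "stimulus_indices"))))
      if (length(movers) > 1L) {
        unite_tokens(net, movers, host, transition_id = tr$id)
      }
      # The united token acquires the derived total-reaction role.
      tok <- get_token(net, host)
      tok$type_tag <- "zeta"
      put_token(net, tok)
      set_characteristic(net, host, list(
        kind = "total_reaction",
        text = "total system reaction, parameters",
        stimulus_indices = as.list(idx), retyped = "zeta"))
      invisible(NULL)
    })

  ## ---- initial marking ----
  st$eps_star_id <- spawn_token(net, "eps_star", "e0", initial = TRUE,
    characteristic = list(kind = "environment",
                          text = "information about the environment"))
  st$omega_id <- spawn_token(net, "omega", "s", initial = TRUE,
    characteristic = list(kind = "system_status",
                          text = "information about the system status"))
  st$tau_ids <- vapply(seq_len(m), function(k) {
    spawn_token(net, "tau", sprintf("i%d_3", k), initial = TRUE,
      characteristic = list(kind = "threshold",
                            text = sprintf("threshold of the %d-th receptor/sensor", k),
                            receptor = k,
                            threshold = config$initial_thresholds[[k]]))
  }, character(1))
  st$phi_ids <- vapply(seq_len(p), function(k) {
    spawn_token(net, "phi", sprintf("o%d_3", k), initial = TRUE,
      characteristic = list(kind = "effector",
                            text = sprintf("information about the %d-th effector", k),
                            effector = k))
  }, character(1))

  net
}

#' The default predicate and characteristic hooks of the FOP net
#'
#' One config-driven hook per predicate of the net:
#' * `W_0_1` — "there is an impact from the environment to the system".
#' * `W_1_k_1` — "the current impact is registered by the k-th
#'   receptor/sensor" (config `routing`).
#' * `W_1_k_2` — "the strength of the impact is greater than the threshold
#'   of the k-th receptor/sensor" (strict inequality; equality falls to the
#'   sub-threshold branch).
#' * `W_1_k_3` — the negation of `W_1_k_2`.
#' * `V_s_k` — "the registered impact must be processed by the k-th system
#'   component" (config `component_policy`).
#' * `V_o_k` — "a new impact of the system over the environment may occur
#'   through the k-th effector" (config `effector_policy`).
#' * `V_i_k` — "the value of the threshold of the k-th receptor/sensor must
#'   be changed" (config `adaptation`).
#' * `U_3_k_2` — "the k-th system component is ready with generated
#'   response" (true once `processing_delays[k]` ticks elapsed since intake).
#' * `T_3_k_2` — "there is a ready system reaction for the k-th effector"
#'   (true once `effector_delays[k]` ticks elapsed since receipt).
#'
#' @param config A [fop_config()].
#' @return List with `predicates` (named [predicate_ref]s) and
#'   `characteristics` (named characteristic hooks registered as the net's
#'   `Phi` component).
#' @export
fop_default_hooks <- function(config) {
  preds <- list()
  preds$W_0_1 <- predicate_ref("W_0_1",
    function(token, source, target, net, tick) {
      stim <- net$state$stimuli
      any(!stim$emitted & stim$tick <= tick)
    },
    "there is an impact from the environment to the system")
  for (k in seq_len(config$m)) {
    preds[[sprintf("W_1_%d_1", k)]] <- predicate_ref(sprintf("W_1_%d_1", k),
      local({
        k_ <- k
        function(token, source, target, net, tick) {
          identical(route_index(net$state$cfg$routing, token_field(token, "modality")), k_)
        }
      }),
      sprintf("the current impact is registered by the %d-th receptor/sensor", k))
    preds[[sprintf("W_1_%d_2", k)]] <- predicate_ref(sprintf("W_1_%d_2", k),
      local({
        k_ <- k
        function(token, source, target, net, tick) {
          strength <- token_field(token, "strength")
          !is.null(strength) && strength > current_threshold(net, k_)
        }
      }),
      sprintf("the strength of the impact is greater than the threshold of the %d-th receptor/sensor", k))
    preds[[sprintf("W_1_%d_3", k)]] <- predicate_ref(sprintf("W_1_%d_3", k),
      local({
        p2 <- preds[[sprintf("W_1_%d_2", k)]]
        function(token, source, target, net, tick) {
          !p2$evaluator(token, source, target, net, tick)
        }
      }),
      sprintf("negation of W_1_%d_2", k))
  }
  for (k in seq_len(config$n)) {
    preds[[sprintf("V_s_%d", k)]] <- predicate_ref(sprintf("V_s_%d", k),
      local({
        k_ <- k
        function(token, source, target, net, tick) {
          cfg <- net$state$cfg
          any(vapply(net$state$pending_impacts, function(rec)
            identical(route_index(cfg$component_policy, rec$modality), k_), logical(1)))
        }
      }),
      sprintf("the registered impact must be processed by the %d-th system component", k))
    preds[[sprintf("U_3_%d_2", k)]] <- predicate_ref(sprintf("U_3_%d_2", k),
      local({
        k_ <- k
        function(token, source, target, net, tick) {
          job <- net$state$comp_jobs[[k_]]
          !is.null(job) && (tick - job$arrival) >= net$state$cfg$processing_delays[[k_]]
        }
      }),
      sprintf("the %d-th system component is ready with generated response", k))
  }
  for (k in seq_len(config$p)) {
    preds[[sprintf("V_o_%d", k)]] <- predicate_ref(sprintf("V_o_%d", k),
      local({
        k_ <- k
        function(token, source, target, net, tick) {
          cfg <- net$state$cfg
          any(vapply(net$state$pending_responses, function(rec)
            identical(route_index(cfg$effector_policy, rec$modality), k_), logical(1)))
        }
      }),
      sprintf("a new impact of the system over the environment may occur through the %d-th effector", k))
    preds[[sprintf("T_3_%d_2", k)]] <- predicate_ref(sprintf("T_3_%d_2", k),
      local({
        k_ <- k
        function(token, source, target, net, tick) {
          job <- net$state$eff_jobs[[k_]]
          !is.null(job) && (tick - job$arrival) >= net$state$cfg$effector_delays[[k_]]
        }
      }),
      sprintf("there is a ready system reaction for the %d-th effector", k))
  }
  for (k in seq_len(config$m)) {
    preds[[sprintf("V_i_%d", k)]] <- predicate_ref(sprintf("V_i_%d", k),
      local({
        k_ <- k
        function(token, source, target, net, tick) {
          cfg <- net$state$cfg
          cfg$adaptation$rule != "none" &&
            net$state$triggers_seen[[k_]] > net$state$kappas_emitted[[k_]]
        }
      }),
      sprintf("the value of the threshold of the %d-th receptor/sensor must be changed", k))
  }
  characteristics <- list(
    impact_registration = "registration of the impact, parameters",
    component_response = "response to the registered impact, parameters",
    effector_reaction = "system reaction for the k-th effector, parameters",
    total_reaction = "total system reaction, parameters",
    threshold_update = "new value of the threshold of the respective receptor/sensor",
    environment_result = "a result of the impact of the system over the environment")
  list(predicates = preds, characteristics = characteristics)
}

#' Structural counts of a built FOP net
#'
#' Counts are obtained by enumeration of the built object (transitions in
#' the net, distinct places referenced by any transition, declared token
#' roles), not by the closed-form formulas — so they can be checked against
#' the formulas `m + n + p + 3` and `4m + 3(n + p + 1) + 1`.
#'
#' @param net A `gnet` built by [build_fop_net()].
#' @return Named list: `n_transitions`, `n_places`, `n_token_types`.
#' @export
structural_counts <- function(net) {
  place_ids <- unique(unlist(lapply(net$A, function(tr) c(tr$inputs, tr$outputs))))
  list(n_transitions = length(net$A),
       n_places = length(place_ids),
       n_token_types = length(net$state$token_roles))
}

#' @export
print.fop_config <- function(x, ...) {
  cat(sprintf("fop_config: m=%d receptor(s), n=%d component(s), p=%d effector(s)\n",
              x$m, x$n, x$p))
  cat(sprintf("  thresholds: %s; adaptation: %s\n",
              paste(x$initial_thresholds, collapse = ", "), x$adaptation$rule))
  invisible(x)
}
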