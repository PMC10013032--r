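#' Generate a seeded stochastic stimulus train
#'
#' A stand-in for the environment's impacts: stimulus counts per tick are
#' Poisson with the given rate, strengths are uniform within the stated
#' bounds, and modalities are drawn from the stated weights. Deterministic
#' given `seed`.
#'
#' @param params List: `horizon` (ticks, >= 1), `rate` (expected stimuli per
#'   tick, > 0), `strength_range` (length-2 ordered numeric),
#'   `modality_weights` (named positive numeric; names are modalities).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `stimulus_train`: data frame `stimuli` with
#'   columns `tick`, `modality`, `strength`, plus the generator params and
#'   seed.
#' @export
generate_stimuli <- function(params, seed = NULL) {
  horizon <- params$horizon %||% 30L
  rate <- params$rate %||% 0.2
  bounds <- params$strength_range %||% c(1, 5)
  weights <- params$modality_weights %||% c("*" = 1)
  if (!is.numeric(rate) || rate <= 0) {
    fop_structural_error("stimulus generator: rate must be > 0")
  }
  if (length(bounds) != 2L || bounds[1] > bounds[2] || any(bounds < 0)) {
    fop_structural_error("stimulus generator: strength bounds must be ordered and >= 0")
  }
  if (is.null(names(weights)) || any(weights < 0) || sum(weights) <= 0) {
    fop_structural_error("stimulus generator: modality weights must be named and positive")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- stats::rpois(horizon, rate)
  ticks <- rep(seq_len(horizon) - 1L, counts)
  total <- length(ticks)
  stimuli <- data.frame(
    tick = ticks,
    modality = if (total) sample(names(weights), total, replace = TRUE,
                                 prob = weights / sum(weights)) else character(),
    strength = if (total) stats::runif(total, bounds[1], bounds[2]) else numeric(),
    stringsAsFactors = FALSE)
  structure(list(stimuli = stimuli, seed = seed, params = params),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("stimulus_train: %d stimul%s over %d tick(s)\n",
              nrow(x$stimuli), if (nrow(x$stimuli) == 1) "us" else "i",
              x$params$horizon %||% NA))
  if (nrow(x$stimuli)) print(utils::head(x$stimuli, 10))
  invisible(x)
}

scenario_defaults <- function(name) {
  switch(name,
    pain_reflex = list(
      threshold = 3.0, strength = 5.0, stimulus_tick = 0L,
      processing_delay = 1L, effector_delay = 1L, ticks = 15L),
    chronic_pain = list(
      threshold = 3.0, gamma = 0.8, trigger = "registered",
      strength = 2.5, n_stimuli = 4L, period = 15L,
      processing_delay = 1L, effector_delay = 1L,
      adaptation = TRUE),
    exchange = list(
      m = 3L, n = 2L, p = 3L, thresholds = c(1, 1, 1),
      routing = c(food = 1L, drink = 2L, oxygen = 3L),
      component_policy = c(food = 1L, drink = 1L, oxygen = 2L),
      effector_policy = c(food = 2L, drink = 1L, oxygen = 3L),
      horizon = 30L, rate = 0.1, strength_range = c(0.5, 3),
      seed = 42L, ticks = 45L),
    fop_structural_error(sprintf("unknown scenario %s", name)))
}

#' Run a named physiological scenario on the FOP net
#'
#' Three concretizations of system-environment interaction:
#' * `pain_reflex` — acute pain from a pin prick: one receptor, one
#'   processing component (the spinal pathway), one effector (arm
#'   withdrawal); a single supra-threshold stimulus, no adaptation.
#' * `chronic_pain` — repeated stimulation with multiplicative
#'   threshold-reduction adaptation: every registered impact scales the
#'   receptor threshold by `gamma < 1`, so an initially sub-threshold
#'   strength eventually elicits responses (hypersensitivity).
#' * `exchange` — intake/excretion: distinct modalities (food, drink,
#'   oxygen) enter through distinct receptors, are processed by internal
#'   components, and leave through distinct effectors.
#'
#' Scenario magnitudes (threshold 3.0, gamma 0.8, strengths) are package
#' defaults chosen for legible hand traces; override via `config`.
#'
#' @param name One of `"pain_reflex"`, `"chronic_pain"`, `"exchange"`.
#' @param config Named list of overrides for the scenario defaults.
#' @return An object of class `scenario_result`: the trace, per-stimulus
#'   response latencies, per-receptor threshold trajectories, the count of
#'   stimuli that elicited no response, the staged stimuli, and the final
#'   net.
#' @export
run_scenario <- function(name, config = list()) {
  name <- match.arg(name, c("pain_reflex", "chronic_pain", "exchange"))
  cfg <- utils::modifyList(scenario_defaults(name), config)

  if (name == "pain_reflex") {
    fc <- fop_config(1, 1, 1,
                     initial_thresholds = cfg$threshold,
                     processing_delays = cfg$processing_delay,
                     effector_delays = cfg$effector_delay)
    stimuli <- data.frame(tick = as.integer(cfg$stimulus_tick),
                          modality = "pin_prick", strength = cfg$strength,
                          stringsAsFactors = FALSE)
    ticks <- cfg$ticks
  } else if (name == "chronic_pain") {
    adaptation <- if (isTRUE(cfg$adaptation)) {
      list(rule = "multiplicative", gamma = cfg$gamma, trigger = cfg$trigger)
    } else {
      list(rule = "none")
    }
    fc <- fop_config(1, 1, 1,
                     initial_thresholds = cfg$threshold,
                     processing_delays = cfg$processing_delay,
                     effector_delays = cfg$effector_delay,
                     adaptation = adaptation)
    stimuli <- data.frame(
      tick = as.integer(seq(0L, by = cfg$period, length.out = cfg$n_stimuli)),
      modality = "pressure", strength = rep(cfg$strength, cfg$n_stimuli),
      stringsAsFactors = FALSE)
    ticks <- max(stimuli$tick) + cfg$period
  } else {
    fc <- fop_config(cfg$m, cfg$n, cfg$p,
                     initial_thresholds = cfg$thresholds,
                     routing = cfg$routing,
                     component_policy = cfg$component_policy,
                     effector_policy = cfg$effector_policy)
    train <- generate_stimuli(list(
      horizon = cfg$horizon, rate = cfg$rate,
      strength_range = cfg$strength_range,
      modality_weights = stats::setNames(rep(1, length(cfg$routing)),
                                         names(cfg$routing))), seed = cfg$seed)
    stimuli <- train$stimuli
    ticks <- cfg$ticks
  }

  net <- build_fop_net(fc)
  fop_stage_stimuli(net, stimuli)
  trace <- run_net(net, ticks, seed = cfg$seed %||% NULL)
  build_scenario_result(name, cfg, net, trace, stimuli)
}

# Assemble latencies, threshold trajectories and response accounting from a
# finished run.
build_scenario_result <- function(name, cfg, net, trace, stimuli) {
  ev <- trace$events
  zeta <- zeta_emissions(ev)
  lat <- data.frame(stimulus_index = integer(), response_tick = integer(),
                    latency = integer())
  if (nrow(stimuli)) {
    resp_tick <- rep(NA_integer_, nrow(stimuli))
    for (i in seq_len(nrow(zeta))) {
      for (idx in zeta$stimulus_indices[[i]]) {
        if (!is.null(idx) && !is.na(idx) && idx <= length(resp_tick) &&
            is.na(resp_tick[[idx]])) {
          resp_tick[[idx]] <- zeta$tick[[i]]
        }
      }
    }
    responded <- which(!is.na(resp_tick))
    lat <- data.frame(stimulus_index = responded,
                      response_tick = resp_tick[responded],
                      latency = resp_tick[responded] - stimuli$tick[responded])
  }
  traj <- lapply(seq_along(net$state$tau_ids), function(k) {
    tau <- get_token(net, net$state$tau_ids[[k]])
    keep <- vapply(tau$history, function(h)
      is.list(h$record) && "threshold" %in% names(h$record), logical(1))
    recs <- tau$history[keep]
    data.frame(tick = vapply(recs, `[[`, numeric(1), "tick"),
               threshold = vapply(recs, function(h) h$record$threshold, numeric(1)))
  })
  structure(list(scenario = name, config = cfg, trace = trace, net = net,
                 stimuli = stimuli, response_latencies = lat,
                 threshold_trajectories = traj,
                 undelivered_count = nrow(stimuli) - nrow(lat)),
            class = "scenario_result")
}

# Ticks and stimulus attribution of every total-reaction emission.
zeta_emissions <- function(events) {
  if (!nrow(events)) {
    return(data.frame(tick = integer(), stimulus_indices = I(list())))
  }
  is_zeta <- events$kind == "CHARACTERISTIC" & vapply(events$payload, function(p)
    identical(p$record$kind, "total_reaction"), logical(1))
  rows <- which(is_zeta)
  data.frame(tick = events$tick[rows],
             stimulus_indices = I(lapply(events$payload[rows], function(p)
               unlist(p$record$stimulus_indices))))
}

#' Summarize a scenario run stimulus by stimulus
#'
#' One row per stimulus: its tick, modality and strength, the receptor it
#' routed to, the threshold in force when the receptor evaluated it,
#' whether a receptor registered it, whether a total reaction traceable to
#' it reached the environment, and the response latency in ticks. The
#' per-receptor threshold trajectories are attached as the
#' `"threshold_trajectories"` attribute.
#'
#' @param result A [run_scenario()] result.
#' @return A data frame (zero rows for an empty train).
#' @export
summarize_scenario <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  stimuli <- result$stimuli
  net <- result$net
  ev <- result$trace$events
  out <- data.frame(stimulus_index = integer(), tick = integer(),
                    modality = character(), strength = numeric(),
                    receptor = integer(), threshold_at_arrival = numeric(),
                    registered = logical(), responded = logical(),
                    latency = integer(), stringsAsFactors = FALSE)
  if (nrow(stimuli)) {
    eps_ids <- stimulus_token_ids(result)
    routing <- net$state$cfg$routing
    rows <- lapply(seq_len(nrow(stimuli)), function(i) {
      k <- route_index(routing, stimuli$modality[[i]])
      eid <- eps_ids[[i]]
      eval_tick <- receptor_eval_tick(ev, eid, k)
      thr <- if (is.na(k) || is.na(eval_tick)) NA_real_ else
        threshold_at(result$threshold_trajectories[[k]], eval_tick)
      li <- result$response_latencies
      hit <- li$stimulus_index == i
      data.frame(stimulus_index = i, tick = stimuli$tick[[i]],
                 modality = stimuli$modality[[i]],
                 strength = stimuli$strength[[i]],
                 receptor = k, threshold_at_arrival = thr,
                 registered = !is.na(eval_tick),
                 responded = any(hit),
                 latency = if (any(hit)) li$latency[hit][[1L]] else NA_integer_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  attr(out, "threshold_trajectories") <- result$threshold_trajectories
  out
}

# Map stimulus index -> the id of the impact token that carried it.
stimulus_token_ids <- function(result) {
  toks <- result$trace$final_state$tokens
  ids <- rep(NA_character_, nrow(result$stimuli))
  for (tid in names(toks)) {
    tok <- toks[[tid]]
    if (tok$type_tag != "eps") next
    for (h in tok$history) {
      if (is.list(h$record) && !is.null(h$record$stimulus_index)) {
        ids[[h$record$stimulus_index]] <- tid
        break
      }
    }
  }
  ids
}

# Tick at which receptor k's transition processed the impact token (either
# branch), NA if it never reached a receptor.
receptor_eval_tick <- function(events, eps_id, k) {
  if (is.na(eps_id) || is.na(k)) return(NA_integer_)
  tr_id <- sprintf("I%d", k)
  at_receptor <- !is.na(events$transition) & events$transition == tr_id &
    events$kind %in% c("TRANSFER", "UNITE") &
    vapply(strsplit(events$tokens, ","), function(x) eps_id %in% x, logical(1))
  if (!any(at_receptor)) return(NA_integer_)
  min(events$tick[at_receptor])
}

# Threshold in force when a receptor evaluates at `tick`: the newest
# trajectory record strictly before that tick (updates land after the
# impact row is evaluated within the same receptor firing).
threshold_at <- function(traj, tick) {
  prior <- traj$tick < tick
  if (!any(prior)) return(traj$threshold[[1L]])
  traj$threshold[max(which(prior))]
}

#' Write a scenario summary and trajectories as delimited text
#' @param result A [run_scenario()] result.
#' @param summary_path Output path for the per-stimulus table (TSV).
#' @param trajectory_path Optional output path for the per-receptor
#'   threshold trajectories (TSV with a `receptor` column).
#' @return `summary_path`, invisibly.
#' @export
write_scenario_summary <- function(result, summary_path, trajectory_path = NULL) {
  tab <- summarize_scenario(result)
  attr(tab, "threshold_trajectories") <- NULL
  utils::write.table(tab, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(trajectory_path)) {
    traj <- result$threshold_trajectories
    long <- do.call(rbind, lapply(seq_along(traj), function(k)
      cbind(receptor = k, traj[[k]])))
    utils::write.table(long, trajectory_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(summary_path)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario_result '%s': %d stimul%s, %d response(s), %d without response\n",
              x$scenario, nrow(x$stimuli),
              if (nrow(x$stimuli) == 1) "us" else "i",
              nrow(x$response_latencies), x$undelivered_count))
  if (nrow(x$response_latencies)) {
    cat("latencies (ticks):",
        paste(x$response_latencies$latency, collapse = ", "), "\n")
  }
  invisible(x)
}
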