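#' Abstract impact-reaction loop between an environment and a system
#'
#' A lightweight reference model of the same principle the net realizes,
#' kept deliberately independent of the engine so the two formalizations
#' can be cross-checked. The environment `E` impacts the system `S` through
#' `F_E` and the system reacts back through `F_S`; each side's reaction
#' changes at time-moments produced by its time-advance map (`tau_E` for
#' system reactions, `tau_S` for environment reactions).
#'
#' @param F_E Function `(E_state, S_state, tick) -> value`: the system's
#'   reaction to the environment's impact.
#' @param F_S Function `(S_state, E_state, tick) -> value`: the
#'   environment's reaction to the system's impact.
#' @param tau_E Function `(E_state, S_state, tick) -> tick'`: next
#'   time-moment at which the system reaction changes. Must advance time.
#' @param tau_S Function `(S_state, E_state, tick) -> tick'''`: next
#'   time-moment at which the environment reaction changes. Must advance
#'   time.
#' @param E_state,S_state Initial states (any R values).
#' @param apply_to_S Optional `(S_state, value) -> S_state`: how a delivered
#'   system-bound reaction perturbs the system. Default: no perturbation.
#' @param apply_to_E Optional `(E_state, value) -> E_state`.
#' @return An object of class `impact_spec`.
#' @export
impact_spec <- function(F_E, F_S, tau_E, tau_S,
                        E_state = list(), S_state = list(),
                        apply_to_S = NULL, apply_to_E = NULL) {
  stopifnot(is.function(F_E), is.function(F_S),
            is.function(tau_E), is.function(tau_S))
  structure(list(F_E = F_E, F_S = F_S, tau_E = tau_E, tau_S = tau_S,
                 E_state = E_state, S_state = S_state,
                 apply_to_S = apply_to_S %||% function(s, v) s,
                 apply_to_E = apply_to_E %||% function(e, v) e),
            class = "impact_spec")
}

#' Threshold gate for the complex impact-reaction model
#'
#' Magnitude hooks `sigma_S`/`sigma_E` give the size of a system-bound /
#' environment-bound impact; a reaction is delivered only if its magnitude
#' strictly exceeds the corresponding threshold (`pi_S` / `pi_E`),
#' mirroring the strict receptor-threshold convention of the net. An
#' undelivered reaction stops functioning: it is recorded but never
#' perturbs the receiving side.
#'
#' @param sigma_S,sigma_E Functions `(value) -> magnitude` for system-bound
#'   and environment-bound reactions.
#' @param pi_S,pi_E Non-negative finite thresholds.
#' @return An object of class `threshold_gate`.
#' @export
threshold_gate <- function(sigma_S = function(v) abs(v),
                           sigma_E = function(v) abs(v),
                           pi_S = 0, pi_E = 0) {
  if (!is.finite(pi_S) || pi_S < 0 || !is.finite(pi_E) || pi_E < 0) {
    fop_structural_error("thresholds must be finite and >= 0")
  }
  structure(list(sigma_S = sigma_S, sigma_E = sigma_E,
                 pi_S = pi_S, pi_E = pi_E),
            class = "threshold_gate")
}

# Shared core of the two simulators. `gate = NULL` means every reaction is
# delivered. Events on the two sides are merged chronologically; at equal
# time-moments the system-side entry is processed first (an interleaving
# the formal model leaves open; recorded as this package's convention).
simulate_ir <- function(spec, t_max, gate = NULL) {
  if (t_max < 0) fop_structural_error("t_max must be >= 0")
  advance <- function(fun, a, b, t, label) {
    t2 <- fun(a, b, t)
    if (!is.finite(t2) || t2 <= t) {
      fop_evaluation_error(sprintf("%s: time must advance (got %s from tick %s)",
                                   label, format(t2), format(t)))
    }
    t2
  }
  E <- spec$E_state; S <- spec$S_state
  next_sys <- advance(spec$tau_E, E, S, 0, "tau_E")
  next_env <- advance(spec$tau_S, S, E, 0, "tau_S")
  rows <- list()
  repeat {
    t <- min(next_sys, next_env)
    if (t > t_max) break
    if (next_sys <= next_env) {
      side <- "system"; tick <- next_sys
      value <- spec$F_E(E, S, tick)
      delivered <- is.null(gate) || gate$sigma_S(value) > gate$pi_S
      if (delivered) S <- spec$apply_to_S(S, value)
      next_sys <- advance(spec$tau_E, E, S, tick, "tau_E")
    } else {
      side <- "environment"; tick <- next_env
      value <- spec$F_S(S, E, tick)
      delivered <- is.null(gate) || gate$sigma_E(value) > gate$pi_E
      if (delivered) E <- spec$apply_to_E(E, value)
      next_env <- advance(spec$tau_S, S, E, tick, "tau_S")
    }
    rows[[length(rows) + 1L]] <- list(tick = tick, side = side,
                                      value = value, delivered = delivered)
  }
  sched <- if (length(rows)) {
    data.frame(tick = vapply(rows, `[[`, numeric(1), "tick"),
               side = vapply(rows, `[[`, character(1), "side"),
               value = vapply(rows, function(r) as.numeric(r$value[[1L]]), numeric(1)),
               delivered = vapply(rows, `[[`, logical(1), "delivered"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tick = numeric(), side = character(), value = numeric(),
               delivered = logical(), stringsAsFactors = FALSE)
  }
  structure(list(schedule = sched, t_max = t_max,
                 final_E = E, final_S = S),
            class = "reaction_schedule")
}

#' Simulate the simplified impact-reaction model
#'
#' Alternating evaluation of system and environment reactions at the
#' time-moments produced by the time-advance maps, starting from tick 0 up
#' to `t_max`. Every reaction is delivered.
#'
#' @param spec An [impact_spec()].
#' @param t_max Horizon (>= 0), on the same integer tick scale as the
#'   engine.
#' @return A `reaction_schedule`: data frame `schedule` with columns
#'   `tick`, `side`, `value`, `delivered`, plus final states.
#' @export
simulate_simplified <- function(spec, t_max) {
  simulate_ir(spec, t_max, gate = NULL)
}

#' Simulate the thresholded ("complex") impact-reaction model
#'
#' As [simulate_simplified()], except each reaction's magnitude is compared
#' to the receiving side's threshold: a reaction at or below the threshold
#' is recorded with `delivered = FALSE` (the signal stops functioning) and
#' does not perturb the receiving side's state.
#'
#' @param spec An [impact_spec()].
#' @param gate A [threshold_gate()].
#' @param t_max Horizon (>= 0).
#' @return A `reaction_schedule`.
#' @export
simulate_complex <- function(spec, gate, t_max) {
  stopifnot(inherits(gate, "threshold_gate"))
  simulate_ir(spec, t_max, gate = gate)
}

#' Write a reaction schedule as a delimited table
#' @param x A `reaction_schedule`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_reaction_schedule <- function(x, path) {
  utils::write.table(x$schedule, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.reaction_schedule <- function(x, ...) {
  cat(sprintf("reaction_schedule: %d entr%s up to tick %s (%d delivered)\n",
              nrow(x$schedule), if (nrow(x$schedule) == 1) "y" else "ies",
              format(x$t_max), sum(x$schedule$delivered)))
  if (nrow(x$schedule)) print(utils::head(x$schedule, 10))
  invisible(x)
}
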