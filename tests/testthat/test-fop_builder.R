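test_that("config validation rejects malformed parameters before any net exists", {
  expect_error(fop_config(0, 1, 1), "m must be >= 1", class = "fop_structural_error")
  expect_error(fop_config(1, 1, 1, initial_thresholds = c(1, 2)),
               "length m", class = "fop_structural_error")
  expect_error(fop_config(1, 1, 1, initial_thresholds = -1),
               "finite and >= 0", class = "fop_structural_error")
  expect_error(fop_config(1, 2, 1, processing_delays = c(0L, 1L)),
               ">= 1 tick", class = "fop_structural_error")
  expect_error(fop_config(1, 1, 1, routing = c("*" = 2L)),
               "out of range", class = "fop_structural_error")
  expect_error(fop_config(1, 1, 1, adaptation = list(rule = "multiplicative")),
               "gamma", class = "fop_structural_error")
})

test_that("enumerated structure follows the builder's wiring for all small sizes", {
  # Places follow 4m + 3(n+p+1) + 1 exactly; transitions enumerate to
  # m + n + p + 4 (En0, En1, En2, one per receptor, the system core, one per
  # component, one per effector). Token roles are always the six fixed ones.
  for (m in 1:3) for (n in 1:3) for (p in 1:3) {
    net <- build_fop_net(fop_config(m, n, p))
    sc <- structural_counts(net)
    expect_identical(sc$n_places, 4L * m + 3L * (n + p + 1L) + 1L)
    expect_identical(sc$n_transitions, m + n + p + 4L)
    expect_identical(sc$n_token_types, 6L)
    expect_identical(validate_net(net), character())
    expect_identical(names(net$A)[1:2], c("En0", "En1"))
    expect_identical(names(net$A)[length(net$A)], "En2")
  }
})

test_that("the declared token roles are the six fixed ones, independent of size", {
  roles <- build_fop_net(fop_config(4, 1, 2))$state$token_roles
  expect_identical(roles, c("eps_star", "eps", "omega", "phi", "tau", "kappa"))
})

test_that("initial marking places the persistent tokens where they are united with", {
  net <- build_fop_net(fop_config(2, 1, 2))
  snap <- net_snapshot(net)
  expect_identical(snap$places$e0, net$state$eps_star_id)
  expect_identical(snap$places$s, net$state$omega_id)
  expect_identical(snap$places$i1_3, net$state$tau_ids[[1]])
  expect_identical(snap$places$i2_3, net$state$tau_ids[[2]])
  expect_identical(snap$places$o1_3, net$state$phi_ids[[1]])
  expect_identical(snap$places$o2_3, net$state$phi_ids[[2]])
  expect_identical(current_threshold(net, 1), 3.0)
})

test_that("component readiness fires exactly after the configured processing delay", {
  # With a processing delay of d ticks the response leaves the component d
  # ticks after intake, stretching the reflex latency by d - 1.
  for (d in 1:3) {
    res <- run_scenario("pain_reflex", list(processing_delay = d, ticks = 20L))
    expect_identical(res$response_latencies$latency, 9L + (d - 1L))
    ev <- res$trace$events
    arrive <- ev$kind == "TRANSFER" & !is.na(ev$target) & ev$target == "s1_3"
    ready <- ev$kind == "SPLIT" & !is.na(ev$target) & ev$target == "s1_2"
    expect_identical(ev$tick[ready] - ev$tick[arrive], as.integer(d))
  }
})

test_that("threshold updates flow through the control-token pathway and validate", {
  expect_error(threshold_update(list(), list(new_threshold = -1)),
               ">= 0", class = "fop_structural_error")
  expect_error(threshold_update(list(), list(new_threshold = NaN)),
               "finite", class = "fop_structural_error")
  expect_error(threshold_update(list(), list()),
               "finite", class = "fop_structural_error")
  expect_identical(threshold_update(list(), list(new_threshold = 1.92)), 1.92)

  # Two registered impacts under the multiplicative rule: 3.0 * 0.8^2.
  res <- run_scenario("chronic_pain", list(n_stimuli = 2L))
  traj <- res$threshold_trajectories[[1]]
  expect_equal(traj$threshold, c(3.0, 2.4, 1.92))
  # Every update is carried by a control token that unites with the
  # threshold token at the receptor transition.
  kappa_unites <- Filter(function(e) e$kind == "UNITE" &&
                           any(grepl("^kappa-", e$tokens)), res$trace$raw_events)
  expect_length(kappa_unites, 2)
  expect_true(all(vapply(kappa_unites, function(e)
    identical(e$transition, "I1"), logical(1))))
})

test_that("with adaptation off the threshold trajectory is flat", {
  res <- run_scenario("pain_reflex")
  expect_identical(res$threshold_trajectories[[1]]$threshold, 3.0)
})

test_that("the system status token only splits: never moves, never dies", {
  for (nm in c("pain_reflex", "chronic_pain", "exchange")) {
    res <- run_scenario(nm)
    omega <- res$net$state$omega_id
    tok <- get_token(res$net, omega)
    expect_true(tok$alive)
    expect_identical(tok$place, "s")
    moves <- Filter(function(e) e$kind == "TRANSFER" && omega %in% e$tokens,
                    res$trace$raw_events)
    expect_length(moves, 0)
  }
})

test_that("total-reaction tokens are formed only at the environment-output transition", {
  res <- run_scenario("exchange")
  ev <- res$trace$raw_events
  zeta_marks <- Filter(function(e) e$kind == "CHARACTERISTIC" &&
                         identical(e$payload$record$kind, "total_reaction"), ev)
  expect_gt(length(zeta_marks), 0)
  # Each is minted from effector-output tokens moved into e2 by En2.
  for (z in zeta_marks) {
    host <- z$tokens
    expect_match(host, "^phi_prime-")
    mover <- Filter(function(e) e$kind == "TRANSFER" && host %in% e$tokens &&
                      identical(e$target, "e2"), ev)
    expect_true(all(vapply(mover, function(e) identical(e$transition, "En2"),
                           logical(1))))
  }
  # And the environment absorbs it: the total reaction unites with the
  # environment token at En0.
  absorb <- Filter(function(e) e$kind == "UNITE" && identical(e$transition, "En0"), ev)
  expect_gt(length(absorb), 0)
  expect_true(all(vapply(absorb, function(e)
    identical(e$payload$host, res$net$state$eps_star_id), logical(1))))
})

test_that("a stimulus no receptor registers stays at the boundary with a warning", {
  net <- build_fop_net(fop_config(1, 1, 1, routing = c(touch = 1L)))
  fop_stage_stimuli(net, data.frame(tick = 0L, modality = "noise",
                                    strength = 9.0))
  expect_warning(run_net(net, 3), class = "fop_unrouted_stimulus")
  eps <- Filter(function(id) get_token(net, id)$type_tag == "eps",
                ls(net$K))
  expect_length(eps, 1)
  expect_identical(get_token(net, eps[[1]])$place, "e1")
})

test_that("every processed impact takes exactly one receptor branch", {
  cfg <- fop_config(2, 2, 2, initial_thresholds = c(3, 3),
                    routing = c(touch = 1L, heat = 2L),
                    component_policy = c(touch = 1L, heat = 2L),
                    effector_policy = c(touch = 1L, heat = 2L))
  set.seed(99)
  for (i in 1:10) {
    net <- build_fop_net(cfg)
    train <- generate_stimuli(list(horizon = 15L, rate = 0.3,
                                   strength_range = c(1, 5),
                                   modality_weights = c(touch = 1, heat = 1)),
                              seed = 1000 + i)
    fop_stage_stimuli(net, train$stimuli)
    trace <- run_net(net, 20)
    br <- receptor_branches(trace)
    if (nrow(br)) expect_identical(br$supra + br$sub, rep(1L, nrow(br)))
    expect_clean_audit(trace)
  }
})
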