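test_that("the stimulus generator is seeded, bounded and validated", {
  params <- list(horizon = 50L, rate = 0.5, strength_range = c(1, 5),
                 modality_weights = c(touch = 1, heat = 3))
  a <- generate_stimuli(params, seed = 123)
  b <- generate_stimuli(params, seed = 123)
  expect_identical(a$stimuli, b$stimuli)
  expect_false(identical(a$stimuli, generate_stimuli(params, seed = 124)$stimuli))

  big <- generate_stimuli(list(horizon = 2000L, rate = 0.6,
                               strength_range = c(1, 5),
                               modality_weights = c(x = 1)), seed = 9)
  expect_gt(nrow(big$stimuli), 1000)
  expect_true(all(big$stimuli$strength >= 1 & big$stimuli$strength <= 5))
  expect_false(is.unsorted(big$stimuli$tick))

  none <- generate_stimuli(list(horizon = 10L, rate = 1e-9,
                                strength_range = c(1, 5),
                                modality_weights = c(x = 1)), seed = 1)
  expect_identical(nrow(none$stimuli), 0L)

  expect_error(generate_stimuli(list(rate = 0)), "rate",
               class = "fop_structural_error")
  expect_error(generate_stimuli(list(rate = 1, strength_range = c(5, 1))),
               "bounds", class = "fop_structural_error")
})

test_that("the acute reflex reproduces the pre-registered hand trace", {
  fixture <- hand_trace_fixture()
  res <- run_scenario("pain_reflex")
  expect_identical(nrow(res$response_latencies), 1L)
  expect_identical(res$response_latencies$response_tick,
                   as.integer(fixture$zeta_emission_tick))
  expect_identical(res$response_latencies$latency,
                   as.integer(fixture$response_latency))
  tab <- summarize_scenario(res)
  expect_identical(nrow(tab), 1L)
  expect_true(tab$registered && tab$responded)
  expect_identical(tab$threshold_at_arrival, 3.0)
  expect_clean_audit(res$trace)
})

test_that("reflex latency does not depend on supra-threshold strength", {
  lat <- vapply(c(3.5, 5.0, 50.0), function(s) {
    run_scenario("pain_reflex", list(strength = s))$response_latencies$latency
  }, integer(1))
  expect_identical(lat, rep(lat[[1]], 3))
})

test_that("chronic adaptation lowers the threshold until hypersensitivity onset", {
  res <- run_scenario("chronic_pain")
  tab <- summarize_scenario(res)
  # 3.0 * 0.8^j drops below the constant strength 2.5 first at j = 1, so the
  # first stimulus is unanswered and responses start with the second.
  expect_identical(tab$responded, c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(which(tab$responded)[1], 2L)
  traj <- res$threshold_trajectories[[1]]
  expect_true(all(diff(traj$threshold) < 0))
  expect_lt(traj$threshold[nrow(traj)], traj$threshold[1])
  expect_equal(traj$threshold, 3.0 * 0.8^(0:4))
  expect_clean_audit(res$trace)

  frozen <- run_scenario("chronic_pain", list(adaptation = FALSE))
  expect_identical(nrow(frozen$response_latencies), 0L)
  expect_identical(unique(frozen$threshold_trajectories[[1]]$threshold), 3.0)
})

test_that("the exchange scenario conserves responses and respects causality", {
  res <- run_scenario("exchange")
  tab <- summarize_scenario(res)
  supra <- sum(tab$registered & tab$strength > tab$threshold_at_arrival)
  zetas <- zeta_count(res)
  expect_lte(zetas, supra)
  expect_gt(zetas, 0)
  # Causality: every total reaction is preceded in trace order by at least
  # one supra-threshold receptor passage.
  ev <- res$trace$events
  first_zeta <- min(ev$seq[ev$kind == "CHARACTERISTIC" &
                             vapply(ev$payload, function(p)
                               identical(p$record$kind, "total_reaction"),
                               logical(1))])
  supra_pass <- ev$seq[ev$kind == "TRANSFER" & !is.na(ev$transition) &
                         grepl("^I[0-9]+$", ev$transition) &
                         grepl("_2$", ev$target)]
  expect_true(any(supra_pass < first_zeta))
  # Distinct modalities route through their own receptors and effectors.
  expect_setequal(unique(tab$receptor[tab$modality == "food"]), 1L)
  expect_setequal(unique(tab$receptor[tab$modality == "oxygen"]), 3L)
  expect_clean_audit(res$trace)
})

test_that("summaries handle an empty train and export as delimited text", {
  net <- build_fop_net(fop_config(1, 1, 1))
  fop_stage_stimuli(net, data.frame(tick = integer(), modality = character(),
                                    strength = numeric()))
  trace <- run_net(net, 5)
  res <- fopnet:::build_scenario_result("pain_reflex", list(), net, trace,
                                        net$state$stimuli[, 1:3])
  tab <- summarize_scenario(res)
  expect_identical(nrow(tab), 0L)

  res2 <- run_scenario("pain_reflex")
  s_path <- withr::local_tempfile(fileext = ".tsv")
  t_path <- withr::local_tempfile(fileext = ".tsv")
  write_scenario_summary(res2, s_path, t_path)
  expect_identical(nrow(utils::read.delim(s_path)), 1L)
  traj <- utils::read.delim(t_path)
  expect_identical(names(traj), c("receptor", "tick", "threshold"))

  expect_error(run_scenario("teleportation"), "unknown scenario|arg")
})

test_that("responses never arrive faster than the boundary path allows", {
  # The shortest stimulus-to-reaction path crosses En0, En1, I, S, S_k
  # (twice around the component loop), S again, O_k, En2: with unit delays
  # that is 9 ticks; no configuration may undercut it.
  for (nm in c("pain_reflex", "chronic_pain", "exchange")) {
    res <- run_scenario(nm)
    if (nrow(res$response_latencies)) {
      expect_true(all(res$response_latencies$latency >= 9L), info = nm)
    }
  }
})
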