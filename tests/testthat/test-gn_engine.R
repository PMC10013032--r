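simple_net <- function() {
  net <- new_gnet()
  add_place(net, "a")
  add_place(net, "b")
  add_transition(net, "T", "a", "b",
    make_index_matrix("a", "b",
      list(list(row = "a", col = "b", predicate = ALWAYS_TRUE))))
  net
}

test_that("validation reports violations as data, naming the element", {
  net <- simple_net()
  expect_identical(validate_net(net), character())

  bad <- new_gnet()
  add_place(bad, "a")
  add_place(bad, "b")
  add_transition(bad, "T", "a", "b",
    make_index_matrix("other", "b",
      list(list(row = "other", col = "b", predicate = ALWAYS_TRUE))))
  rep <- validate_net(bad)
  expect_true(any(grepl("transition T: condition rows != inputs", rep)))

  expect_identical(validate_net(build_fop_net(fop_config(2, 2, 1))), character())
})

test_that("firing transfers a token along its first enabled arc", {
  net <- simple_net()
  expect_length(fire_transition(net, "T"), 0)  # empty input place

  tid <- spawn_token(net, "tok", "a", initial = TRUE)
  ev <- fire_transition(net, "T")
  expect_length(ev, 1)
  expect_identical(ev[[1]]$kind, "TRANSFER")
  expect_identical(get_token(net, tid)$place, "b")

  expect_error(fire_transition(net, "nope"), "unknown transition",
               class = "fop_structural_error")
  expect_error(fire_transition(net, "T", tick = 5L), "clock mismatch",
               class = "fop_structural_error")
})

test_that("split keeps the parent in place and records provenance", {
  net <- simple_net()
  parent <- spawn_token(net, "omega", "a", initial = TRUE)
  expect_error(split_token(net, parent, list()), "at least one child",
               class = "fop_structural_error")
  kids <- split_token(net, parent, list(
    list(type_tag = "sigma", characteristic = list(note = "work")),
    list(type_tag = "pi", characteristic = list(note = "react")),
    list(type_tag = "kappa", characteristic = list(note = "adapt"))))
  expect_length(kids, 3)
  expect_identical(get_token(net, parent)$place, "a")
  for (k in kids) {
    tok <- get_token(net, k)
    expect_identical(tok$place, "a")
    expect_identical(tok$parent_ids, parent)
  }
  splits <- Filter(function(e) e$kind == "SPLIT", net$events)
  expect_length(splits, 1)
})

test_that("unite merges histories stably and kills non-hosts", {
  net <- simple_net()
  x <- spawn_token(net, "eps", "a", characteristic = list(v = 1), initial = TRUE)
  expect_error(unite_tokens(net, c(x, x), x), "at least two distinct",
               class = "fop_structural_error")
  y <- spawn_token(net, "omega", "a", characteristic = list(v = 2), initial = TRUE)
  z <- spawn_token(net, "eps", "b", initial = TRUE)
  expect_error(unite_tokens(net, c(x, z), x), "co-located",
               class = "fop_structural_error")
  expect_error(unite_tokens(net, c(x, y), z), "host must be among",
               class = "fop_structural_error")
  host <- unite_tokens(net, c(x, y), y)
  expect_identical(host, y)
  expect_false(get_token(net, x)$alive)
  expect_true(get_token(net, y)$alive)
  expect_length(get_token(net, y)$history, 2)
  ticks <- vapply(get_token(net, y)$history, `[[`, numeric(1), "tick")
  expect_false(is.unsorted(ticks))
  expect_identical(get_place(net, "a")$tokens, y)
})

test_that("stepping an empty net advances the clock without events", {
  net <- simple_net()
  ev <- step(net)
  expect_length(ev, 0)
  expect_identical(net$clock, 1L)
})

test_that("a token never crosses two transitions within one tick", {
  # Chain a -> b -> c through two transitions firing in declared order;
  # freezing must stop the token after the first hop of each tick.
  net <- new_gnet()
  for (pl in c("a", "b", "c")) add_place(net, pl)
  add_transition(net, "T1", "a", "b",
    make_index_matrix("a", "b", list(list(row = "a", col = "b",
                                          predicate = ALWAYS_TRUE))))
  add_transition(net, "T2", "b", "c",
    make_index_matrix("b", "c", list(list(row = "b", col = "c",
                                          predicate = ALWAYS_TRUE))))
  tid <- spawn_token(net, "tok", "a", initial = TRUE)
  step(net)
  expect_identical(get_token(net, tid)$place, "b")
  step(net)
  expect_identical(get_token(net, tid)$place, "c")

  # Property over a full scenario trace: no token id has two TRANSFERs at
  # the same tick via different transitions.
  res <- run_scenario("pain_reflex")
  ev <- res$trace$events
  tr <- ev[ev$kind == "TRANSFER", ]
  key <- split(tr$transition, paste(tr$tokens, tr$tick))
  expect_true(all(vapply(key, function(x) length(unique(x)) == 1L &&
                           length(x) == 1L, logical(1))))
})

test_that("running zero ticks yields an empty trace at clock zero", {
  net <- simple_net()
  tr <- run_net(net, 0)
  expect_identical(nrow(tr$events), 0L)
  expect_identical(tr$final_state$clock, 0L)
})

test_that("fire_transition agrees with the brute-force enumerator on random nets", {
  set.seed(20240)
  for (i in seq_len(100)) {
    d <- random_net_descriptor()
    net <- build_net_from_descriptor(d)
    step(net)
    expected <- lapply(reference_tick_marking(d), sort)
    expect_identical(engine_marking(net), expected,
                     info = sprintf("random net %d", i))
  }
})

test_that("random-net traces satisfy conservation, residence and history monotonicity", {
  set.seed(31337)
  for (i in seq_len(25)) {
    d <- random_net_descriptor()
    net <- build_net_from_descriptor(d)
    trace <- run_net(net, 5)
    expect_clean_audit(trace)
    expect_identical(validate_net(net), character(),
                     info = sprintf("random net %d", i))
    live <- Filter(function(t) t$alive, trace$final_state$tokens)
    homes <- unlist(trace$final_state$places)
    expect_setequal(names(live), homes)
    expect_identical(anyDuplicated(homes), 0L)
  }
})

test_that("sub-threshold impacts unite with the threshold token, mark it, and stop", {
  res <- run_scenario("pain_reflex", list(strength = 2.0))
  ev <- res$trace$raw_events
  i_unite <- which(vapply(ev, function(e) e$kind == "UNITE" &&
                            identical(e$transition, "I1"), logical(1)))
  expect_length(i_unite, 1)
  # The unite is followed by the registration characteristic on the
  # threshold token and the stop of the impact token's identity.
  follow <- ev[i_unite + c(1L, 2L)]
  expect_identical(vapply(follow, `[[`, character(1), "kind"),
                   c("CHARACTERISTIC", "STOP"))
  expect_match(follow[[1]]$tokens, "^tau-")
  expect_identical(follow[[1]]$payload$record$kind, "registration")
  expect_match(follow[[2]]$tokens, "^eps-")
  expect_identical(follow[[2]]$payload$cause, "united")
  # No total reaction is ever emitted for a sub-threshold impact.
  expect_identical(nrow(res$response_latencies), 0L)
  expect_clean_audit(res$trace)
})
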