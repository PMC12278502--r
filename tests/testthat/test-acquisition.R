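# Acquisition tests run with a reduced candidate pool; the pool size scales
# the search effort per proposal, not the contract being checked.
small_state <- function(explore_prob = 0.25, seed = 1,
                        selectivity = "beta_selectivity") {
  new_campaign(the_space, selectivity = selectivity,
               explore_prob = explore_prob, pool_size = 150L, seed = seed)
}

told_state <- function(explore_prob = 0.25, seed = 1, n = 10) {
  st <- small_state(explore_prob, seed)
  out <- ask(st)
  res <- simulate_reaction(lab_scenario(), out$proposals, space = the_space,
                           seed = seed + 10)
  tell(out$state, res[seq_len(n), ])
}

test_that("a fresh campaign asks for the random initiation batch", {
  out <- ask(small_state())
  expect_equal(nrow(out$proposals), 10L)
  expect_true(all(out$proposals$Mode == "random"))
  expect_true(validate_conditions(the_space, out$proposals)$ok)
  # seeded determinism
  out2 <- ask(small_state())
  expect_identical(out$proposals, out2$proposals)
})

test_that("exploration probability 0 gives pure Pareto exploitation", {
  st <- told_state(explore_prob = 0)
  out <- ask(st)
  expect_equal(nrow(out$proposals), 5L)
  expect_true(all(out$proposals$Mode == "pareto_exploit"))
})

test_that("per-experiment exploration draws match the Bernoulli rate", {
  st <- told_state(explore_prob = 0.25, seed = 3)
  n_explore <- 0L
  n_total <- 0L
  for (b in 1:40) {
    out <- ask(st)
    st <- out$state
    st$stale <- FALSE  # no new data between asks; keep the surrogates
    n_explore <- n_explore + sum(out$proposals$Mode ==
                                   "steinerberger_explore")
    n_total <- n_total + nrow(out$proposals)
  }
  ci <- stats::qbinom(c(0.005, 0.995), n_total, 0.25)
  expect_gte(n_explore, ci[1])
  expect_lte(n_explore, ci[2])
})

test_that("every proposal from every mode validates", {
  st <- told_state(seed = 5)
  n_checked <- 0L
  for (b in 1:6) {
    out <- ask(st)
    expect_true(validate_conditions(the_space, out$proposals)$ok)
    n_checked <- n_checked + nrow(out$proposals)
    res <- simulate_reaction(lab_scenario(), out$proposals,
                             space = the_space, seed = 100 + b)
    st <- tell(out$state, res)
  }
  expect_gte(n_checked, 30L)
})

test_that("tell accepts deviations, empty lists and duplicates", {
  st <- told_state(seed = 7)
  n0 <- nrow(st$observations)

  # human-in-the-loop deviation: executed equivalents differ from proposal
  out <- ask(st)
  res <- simulate_reaction(lab_scenario(), out$proposals, space = the_space,
                           seed = 1)
  res$LiSaltEq <- pmin(res$LiSaltEq + 0.2, 5)
  res$ConcM <- pmax(res$ConcM - 0.01, 0.03)
  st2 <- tell(out$state, res)
  expect_equal(nrow(st2$observations), n0 + 5L)

  expect_identical(tell(st2, st2$observations[0, ]), st2)

  st3 <- tell(tell(st, res), res)  # duplicates allowed, no dedup
  expect_equal(nrow(st3$observations), n0 + 10L)

  bad <- res
  bad$PartEt2O <- 2
  expect_error(tell(st, bad), "PartEt2O")
  expect_error(tell(st, res[, setdiff(names(res), "BetaPct")]), "BetaPct")
})

test_that("exploitation returns valid non-training points along the front", {
  st <- told_state(seed = 11)
  train_keys <- do.call(paste, st$observations[condition_names(the_space)])
  for (k in 1:8) {
    cand <- pareto_exploit(st, pool_size = 200, seed = 50 + k)
    expect_true(validate_conditions(the_space, cand)$ok)
    expect_false(do.call(paste, cand[condition_names(the_space)]) %in%
                   train_keys)
  }
})

test_that("constant surrogates make any pool member admissible", {
  st <- told_state(seed = 13)
  obs <- st$observations
  obs$YieldPct <- 50  # constant objectives -> constant (noise-only) GP
  obs$BetaPct <- 50
  st_const <- tell(small_state(seed = 13), obs)
  cand <- pareto_exploit(st_const, pool_size = 50, seed = 1)
  expect_true(validate_conditions(the_space, cand)$ok)
})

test_that("repulsive exploration avoids existing points", {
  center <- matrix(0.5, nrow = 1, ncol = 10)
  farther <- 0L
  for (s in 1:50) {
    cand <- steinerberger_sample(center, the_space, pool_size = 100,
                                 seed = s)
    pool <- sample_random(the_space, 100, seed = s)
    d_pool <- sqrt(rowSums((encode_conditions(the_space, pool) -
                              matrix(0.5, 100, 10, byrow = TRUE))^2))
    d_cand <- sqrt(sum((encode_conditions(the_space, cand) - 0.5)^2))
    if (d_cand > stats::median(d_pool)) farther <- farther + 1L
  }
  expect_gte(farther, 45L)

  # empty existing set: plain uniform draw
  expect_true(validate_conditions(
    the_space, steinerberger_sample(NULL, the_space, 50, seed = 2))$ok)

  # two opposite corners: candidate beats 90% of the pool on min-distance
  corners <- rbind(rep(0, 10), rep(1, 10))
  beat <- 0L
  for (s in 1:20) {
    cand <- steinerberger_sample(corners, the_space, pool_size = 200,
                                 seed = 200 + s)
    pool_enc <- encode_conditions(the_space,
                                  sample_random(the_space, 200,
                                                seed = 200 + s))
    mind <- function(m) pmin(sqrt(rowSums(sweep(m, 2, corners[1, ])^2)),
                             sqrt(rowSums(sweep(m, 2, corners[2, ])^2)))
    cand_min <- mind(encode_conditions(the_space, cand))
    if (cand_min >= stats::quantile(mind(pool_enc), 0.9)) beat <- beat + 1L
  }
  expect_gte(beat, 18L)
})

test_that("dual campaigns split proposals 2 + 3 and share all results", {
  st_b <- told_state(seed = 17, explore_prob = 0)
  st_a <- new_campaign(the_space, selectivity = "alpha_selectivity",
                       explore_prob = 0, pool_size = 150L, seed = 18)
  st_a <- tell(st_a, st_b$observations)

  out <- dual_ask(st_b, st_a)
  expect_equal(nrow(out$proposals), 5L)
  expect_equal(out$proposals$Provenance,
               c("beta", "beta", "alpha", "alpha", "alpha"))
  expect_true(all(out$proposals$Mode == "pareto_exploit"))
  expect_true(validate_conditions(the_space, out$proposals)$ok)

  res <- simulate_reaction(lab_scenario(), out$proposals, space = the_space,
                           seed = 5)
  both <- dual_tell(out$state_first, out$state_second, res)
  expect_equal(nrow(both$state_first$observations),
               nrow(st_b$observations) + 5L)
  expect_equal(nrow(both$state_second$observations),
               nrow(st_a$observations) + 5L)

  empty <- dual_ask(st_b, st_a, n_first = 0L, n_second = 0L)
  expect_equal(nrow(empty$proposals), 0L)

  st_other <- new_campaign(build_default_space(salt_ranks = c(
    LiI = 1L, LiBF4 = 2L, LiClO4 = 4L, LiOTf = 3L, LiNTf2 = 5L, LiPF6 = 6L,
    `LiB(C6F5)4` = 7L)))
  expect_error(dual_ask(st_b, st_other), "same reaction space")
})
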