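# A synthetic glycosylation-outcome oracle. It encodes the qualitative
# structure discovered in the campaigns -- salt-directed stereoselectivity,
# the sieve/solvent/acid interdependence of the hexafluorophosphate salt,
# capped yields without an acid catalyst -- so that the closed loop and the
# analytics can be exercised end to end without wet-lab experiments. It is a
# synthetic benchmark scenario, not a chemical prediction model.

#' Create a virtual-lab scenario
#'
#' The default trend weights reproduce, at zero noise, the hard qualitative
#' rules observed in the campaign data: LiI gives alpha-selectivity
#' (beta% < 25) under every condition; LiBF4 and LiNTf2 give
#' beta-selectivity (beta% > 55) under every condition; LiPF6 flips with
#' sieve presence and solvent (beta with sieves or acetonitrile-rich, alpha
#' without sieves in ether-rich conditions); without an acid catalyst the
#' yield is capped at 60%. Gaussian noise of standard deviation `noise_sd`
#' percent is added to both objectives, then outputs are clipped to
#' yield in [0, 105] and beta% in [0, 100].
#'
#' @param noise_sd Standard deviation of the additive observation noise in
#'   percent (default 5, the few-percent error scale of single NMR
#'   measurements).
#' @param no_acid_cap Yield cap in percent when no acid is present
#'   (default 60).
#'
#' @return An object of class `glyco_scenario`.
#' @export
lab_scenario <- function(noise_sd = 5, no_acid_cap = 60) {
  stopifnot(noise_sd >= 0)
  structure(
    list(noise_sd = noise_sd,
         no_acid_cap = no_acid_cap,
         # logit-scale base score of each salt for beta-selectivity
         salt_beta = c(LiI = -3.0, LiBF4 = 1.6, LiClO4 = 0.3, LiOTf = 0.2,
                       LiNTf2 = 1.6, LiPF6 = -1.3, `LiB(C6F5)4` = 0.0),
         # LiPF6 interactions: sieves and MeCN push it to beta
         pf6_sieve = 2.4, pf6_mecn = 3.0,
         # solvent effects: ether favors alpha, nitrile weakly favors beta
         w_et2o = -0.8, w_mecn = 0.6,
         # donor configuration and temperature nudges
         w_donor_beta = 0.2, w_cold = 0.15,
         # yield model (logit scale); the scale and weights put the
         # noiseless optimum near the best observed experiments (~90%)
         # rather than at a saturated ceiling
         y_scale = 102, y_base = -1.5, y_acid = 0.5, y_acceptor = 0.25,
         y_sieve = 0.3, y_conc = -1.0, y_warm = 0.1,
         salt_yield = c(LiI = -0.3, LiBF4 = 0, LiClO4 = 0.2, LiOTf = 0,
                        LiNTf2 = 0, LiPF6 = 0.4, `LiB(C6F5)4` = -3.0)),
    class = "glyco_scenario")
}

#' @export
print.glyco_scenario <- function(x, ...) {
  cat(sprintf(paste0("Synthetic virtual-lab scenario: noise sd %.1f%%, ",
                     "no-acid yield cap %.0f%%\n"), x$noise_sd, x$no_acid_cap))
  invisible(x)
}

# Noiseless mean response of the scenario, vectorized over condition rows.
scenario_mean <- function(scenario, conditions) {
  salt <- as.character(conditions$LiSalt)
  sieves_on <- as.character(conditions$MS) != "None"
  acid_code <- match(as.character(conditions$Acid),
                     c("None", "Acetic", "Formic", "Oxalic", "TFA")) - 1
  logit_beta <- scenario$salt_beta[salt] +
    ifelse(salt == "LiPF6",
           scenario$pf6_sieve * sieves_on +
             scenario$pf6_mecn * conditions$PartMeCN, 0) +
    scenario$w_et2o * conditions$PartEt2O +
    scenario$w_mecn * conditions$PartMeCN +
    scenario$w_donor_beta * (as.character(conditions$Conf) == "beta") +
    scenario$w_cold * (conditions$TempC == 0)
  beta_pct <- 100 * stats::plogis(unname(logit_beta))
  eta <- scenario$y_base + scenario$y_acid * acid_code +
    scenario$y_acceptor * conditions$AcceptorEq +
    scenario$y_sieve * sieves_on +
    scenario$y_conc * conditions$ConcM +
    scenario$y_warm * (conditions$TempC == 25) +
    scenario$salt_yield[salt]
  yield <- scenario$y_scale * stats::plogis(unname(eta))
  yield <- ifelse(acid_code == 0, pmin(yield, scenario$no_acid_cap), yield)
  data.frame(YieldPct = yield, BetaPct = beta_pct)
}

#' Simulate experiments with the virtual lab
#'
#' Computes the scenario's deterministic mean response for every condition
#' row, adds independent Gaussian observation noise on each objective, and
#' clips to the admissible output ranges. With `noise_sd = 0` the result is a
#' deterministic function of the conditions; with a seed the noisy result is
#' reproducible.
#'
#' @param scenario A `glyco_scenario`.
#' @param conditions Data frame of valid condition rows.
#' @param space A `glyco_space` used to validate the conditions (default the
#'   standard space).
#' @param seed Optional integer seed for the noise draw.
#'
#' @return The conditions with `YieldPct` and `BetaPct` columns appended.
#' @export
simulate_reaction <- function(scenario, conditions,
                              space = build_default_space(), seed = NULL) {
  stopifnot(inherits(scenario, "glyco_scenario"))
  v <- validate_conditions(space, conditions)
  if (!v$ok) stop("invalid conditions: ",
                  paste(v$violations, collapse = "; "))
  mu <- scenario_mean(scenario, conditions)
  n <- nrow(conditions)
  noise <- with_seed_if(seed, matrix(stats::rnorm(2 * n, 0,
                                                  scenario$noise_sd),
                                     ncol = 2))
  out <- conditions
  out$YieldPct <- pmin(pmax(mu$YieldPct + noise[, 1], 0), 105)
  out$BetaPct <- pmin(pmax(mu$BetaPct + noise[, 2], 0), 100)
  out
}

#' Run one closed-loop campaign against the virtual lab
#'
#' ask / simulate / tell until `budget` experiments have been executed.
#'
#' @param scenario A `glyco_scenario`.
#' @param space A `glyco_space`.
#' @param strategy `"bo"` for the Bayesian-optimization loop or `"random"`
#'   for uniform random sampling at the same budget.
#' @param budget Total number of experiments (>= the initiation batch).
#' @param selectivity Selectivity objective of the campaign.
#' @param explore_prob Exploration probability for the BO strategy.
#' @param pool_size Candidate pool size for the BO strategy.
#' @param seed Integer seed driving the whole replicate.
#'
#' @return List with `results` (all executed experiments, batch-labelled)
#'   and `convergence` (the [hv_convergence()] series).
#' @export
run_virtual_campaign <- function(scenario, space = build_default_space(),
                                 strategy = c("bo", "random"),
                                 budget = 55L, selectivity = "beta_selectivity",
                                 explore_prob = 0.25, pool_size = 2000L,
                                 seed = 1L) {
  strategy <- match.arg(strategy)
  state <- new_campaign(space, selectivity = selectivity,
                        explore_prob = explore_prob, pool_size = pool_size,
                        seed = seed)
  sim_seed <- seed + 500000L
  while (nrow(state$observations) < budget) {
    if (strategy == "bo") {
      out <- ask(state)
      state <- out$state
      prop <- out$proposals
    } else {
      # same batch structure, every proposal uniform random
      n <- if (nrow(state$observations) == 0L) state$init_batch_size else
        state$batch_size
      s <- next_op_seed(state); state <- s$state
      prop <- sample_random(space, n, seed = s$seed)
      prop$Mode <- "random"
      state$n_batches <- state$n_batches + 1L
    }
    take <- min(nrow(prop), budget - nrow(state$observations))
    prop <- prop[seq_len(take), , drop = FALSE]
    sim_seed <- sim_seed + 1L
    res <- simulate_reaction(scenario, prop[, condition_names(space)],
                             space = space, seed = sim_seed)
    res$Batch <- state$n_batches
    state <- tell(state, res)
  }
  list(results = state$observations,
       convergence = hv_convergence(state$observations,
                                    objective = selectivity))
}

#' Benchmark the optimizer against random sampling
#'
#' Runs the full closed loop on the virtual lab for each strategy over
#' several replicate seeds and reports the final total hypervolume of each
#' run together with the per-batch convergence series.
#'
#' @inheritParams run_virtual_campaign
#' @param replicates Number of replicate seeds per strategy.
#' @param strategies Strategies to compare.
#'
#' @return List with `summary` (data frame: `Strategy`, `Replicate`, `Seed`,
#'   `FinalHV`) and `series` (per-batch convergence of every run).
#' @export
benchmark_optimizer <- function(scenario, space = build_default_space(),
                                budget = 55L, replicates = 20L,
                                strategies = c("bo", "random"),
                                selectivity = "beta_selectivity",
                                explore_prob = 0.25, pool_size = 2000L,
                                seed = 1L) {
  stopifnot(budget >= 1L)
  summary <- list()
  series <- list()
  for (strat in strategies) {
    for (r in seq_len(replicates)) {
      rep_seed <- as.integer((seed + 1000L * r) %% .Machine$integer.max)
      run <- run_virtual_campaign(scenario, space, strategy = strat,
                                  budget = budget,
                                  selectivity = selectivity,
                                  explore_prob = explore_prob,
                                  pool_size = pool_size, seed = rep_seed)
      conv <- run$convergence
      summary[[paste(strat, r)]] <-
        data.frame(Strategy = strat, Replicate = r, Seed = rep_seed,
                   FinalHV = conv$TotalHV[nrow(conv)])
      conv$Strategy <- strat
      conv$Replicate <- r
      series[[paste(strat, r)]] <- conv
    }
  }
  list(summary = do.call(rbind, c(summary, list(make.row.names = FALSE))),
       series = do.call(rbind, c(series, list(make.row.names = FALSE))))
}
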