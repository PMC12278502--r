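# The ask/tell optimization loop: an initial random batch, then batches of
# five proposed by Pareto-front exploitation or repulsive-energy exploration,
# with a 25% per-experiment exploration chance; plus the dual-campaign
# protocol where two optimizers with different selectivity objectives share
# every observation.

#' Create a campaign state
#'
#' Holds the space, the (yield, selectivity) objective pair, all observations,
#' the surrogate pair, the batch log and the seed stream for one optimization
#' campaign. The state is a plain value: [ask()] and [tell()] return updated
#' copies.
#'
#' @param space A `glyco_space`.
#' @param selectivity Which selectivity objective to pair with yield:
#'   `"beta_selectivity"` or `"alpha_selectivity"`.
#' @param init_batch_size Size of the random initiation batch (default 10).
#' @param batch_size Size of every subsequent proposed batch (default 5).
#' @param explore_prob Per-experiment probability of the exploration arm
#'   (default 0.25); each proposal in a batch is independently flagged
#'   exploration by a Bernoulli draw.
#' @param pool_size Candidate pool size for both acquisition arms
#'   (default 2000).
#' @param seed Integer base seed; all randomness in the campaign derives from
#'   it.
#'
#' @return An object of class `glyco_state`.
#' @export
new_campaign <- function(space, selectivity = c("beta_selectivity",
                                                "alpha_selectivity"),
                         init_batch_size = 10L, batch_size = 5L,
                         explore_prob = 0.25, pool_size = 2000L, seed = 1L) {
  selectivity <- match.arg(selectivity)
  stopifnot(explore_prob >= 0, explore_prob <= 1)
  structure(
    list(space = space,
         objectives = list(yield = objective_spec("yield"),
                           selectivity = objective_spec(selectivity)),
         observations = empty_results(space),
         batch_log = data.frame(Batch = integer(0), Mode = character(0)),
         n_batches = 0L,
         init_batch_size = as.integer(init_batch_size),
         batch_size = as.integer(batch_size),
         explore_prob = explore_prob,
         pool_size = as.integer(pool_size),
         seed = as.integer(seed), op = 0L,
         surrogates = NULL, stale = TRUE),
    class = "glyco_state")
}

#' @export
print.glyco_state <- function(x, ...) {
  cat(sprintf(paste0("Campaign state: objectives (yield, %s), %d ",
                     "observations, %d batch(es) asked\n"),
              x$objectives$selectivity$name, nrow(x$observations),
              x$n_batches))
  invisible(x)
}

# Empty results frame with the condition columns plus outcome columns.
empty_results <- function(space) {
  out <- sample_random(space, 0)
  out$YieldPct <- numeric(0)
  out$BetaPct <- numeric(0)
  out$Batch <- integer(0)
  out
}

# Deterministic per-operation seed stream derived from the base seed.
next_op_seed <- function(state) {
  state$op <- state$op + 1L
  # mix in double precision to avoid integer overflow, keep below 2^31
  mixed <- (as.numeric(state$seed) * 2654435 + as.numeric(state$op) * 97) %%
    2147483629
  list(state = state, seed = as.integer(mixed))
}

# Refit both surrogates if observations changed since the last fit.
refresh_surrogates <- function(state) {
  if (!state$stale && !is.null(state$surrogates)) return(state)
  s <- next_op_seed(state); state <- s$state
  state$surrogates <- list(
    yield = fit_surrogate(state$observations, state$objectives$yield,
                          state$space, seed = s$seed),
    selectivity = fit_surrogate(state$observations,
                                state$objectives$selectivity,
                                state$space, seed = s$seed + 1L))
  state$stale <- FALSE
  state
}

#' Propose the next batch of experiments
#'
#' With no observations yet, returns the random initiation batch. Otherwise
#' each of the `batch_size` slots is independently assigned the exploration
#' arm with probability `explore_prob`; exploration slots come from
#' [steinerberger_sample()] (repulsive-energy space filling against
#' everything already observed or proposed), exploitation slots from
#' [pareto_exploit()] (model-estimated Pareto front, hypervolume-gain pick).
#' All proposals validate against the space, and proposal modes are recorded
#' in the batch log.
#'
#' @param state A `glyco_state`.
#' @return List with `proposals` (condition rows plus a `Mode` column:
#'   `"random"`, `"pareto_exploit"` or `"steinerberger_explore"`) and the
#'   updated `state`.
#' @export
ask <- function(state) {
  stopifnot(inherits(state, "glyco_state"))
  if (nrow(state$observations) == 0L) {
    s <- next_op_seed(state); state <- s$state
    prop <- sample_random(state$space, state$init_batch_size, seed = s$seed)
    prop$Mode <- rep("random", state$init_batch_size)
  } else {
    state <- refresh_surrogates(state)
    s <- next_op_seed(state); state <- s$state
    explore <- with_seed_if(s$seed,
                            stats::runif(state$batch_size) < state$explore_prob)
    rows <- vector("list", state$batch_size)
    pending <- NULL
    for (k in seq_len(state$batch_size)) {
      s <- next_op_seed(state); state <- s$state
      if (explore[k]) {
        existing <- rbind(encode_conditions(state$space, state$observations),
                          pending)
        cand <- steinerberger_sample(existing, state$space,
                                     pool_size = state$pool_size,
                                     seed = s$seed)
      } else {
        cand <- pareto_exploit(state, pool_size = state$pool_size,
                               seed = s$seed)
      }
      pending <- rbind(pending, encode_conditions(state$space, cand))
      rows[[k]] <- cand
    }
    prop <- do.call(rbind, rows)
    prop$Mode <- ifelse(explore, "steinerberger_explore", "pareto_exploit")
  }
  state$n_batches <- state$n_batches + 1L
  state$batch_log <- rbind(state$batch_log,
                           data.frame(Batch = state$n_batches,
                                      Mode = prop$Mode))
  list(proposals = prop, state = state)
}

#' Record executed experiments
#'
#' Appends measured results to the campaign. The conditions need not match
#' the proposals — deviations between proposed and actually executed
#' conditions (equivalents, concentration) are the norm in a human-in-the-loop
#' setting, and the executed conditions are what is recorded. Surrogates are
#' marked stale and refit lazily on the next [ask()].
#'
#' @param state A `glyco_state`.
#' @param results Data frame with the condition columns plus `YieldPct` and
#'   `BetaPct`. Rows failing validation are rejected with named violations.
#' @return The updated state.
#' @export
tell <- function(state, results) {
  stopifnot(inherits(state, "glyco_state"))
  if (is.null(results) || nrow(results) == 0L) return(state)
  need <- c("YieldPct", "BetaPct")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results are missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(results$YieldPct) || anyNA(results$BetaPct)) {
    stop("results contain missing objective values")
  }
  v <- validate_conditions(state$space, results)
  if (!v$ok) stop("invalid conditions in results: ",
                  paste(v$violations, collapse = "; "))
  add <- results[, c(condition_names(state$space), need)]
  add$Batch <- if ("Batch" %in% names(results)) results$Batch else
    max(state$n_batches, 1L)
  state$observations <- rbind(state$observations, add)
  state$stale <- TRUE
  state
}

#' Exploitation: sample from the model-estimated Pareto front
#'
#' Draws a random candidate pool, predicts both objectives with the
#' surrogates, keeps the non-dominated candidates in the predicted
#' (yield, selectivity) maximization plane, and returns the one whose
#' predicted point maximizes the hypervolume gain over the currently observed
#' front (ties broken by predicted rectangle area, then by the seeded RNG).
#'
#' @param state A `glyco_state` with >= 2 observations and fitted surrogates
#'   (refit automatically if stale).
#' @param pool_size Candidate pool size.
#' @param seed Integer seed for the pool draw and tie-break.
#' @return One condition row (data frame).
#' @export
pareto_exploit <- function(state, pool_size = state$pool_size, seed = NULL) {
  stopifnot(inherits(state, "glyco_state"))
  if (nrow(state$observations) < 2L) {
    stop("need >= 2 observations for exploitation")
  }
  state <- refresh_surrogates(state)
  pool <- sample_random(state$space, pool_size, seed = seed)
  # clamp predictions into the objective square; GP means can stray outside
  py <- pmin(pmax(predict(state$surrogates$yield, pool)$mean_value, 0), 105)
  ps <- pmin(pmax(predict(state$surrogates$selectivity, pool)$mean_value, 0),
             100)
  nd <- pareto_front(py, ps)$points$on_front
  idx <- which(nd)
  obs_y <- state$observations$YieldPct
  obs_s <- objective_values(state$observations,
                            state$objectives$selectivity)
  base_hv <- total_hypervolume(obs_y, obs_s)
  gain <- vapply(idx, function(i) {
    total_hypervolume(c(obs_y, py[i]), c(obs_s, ps[i])) - base_hv
  }, numeric(1))
  area <- py[idx] * ps[idx]
  tie <- with_seed_if(if (is.null(seed)) NULL else seed + 1L,
                      stats::runif(length(idx)))
  ord <- order(gain, area, tie, decreasing = TRUE)
  pool[idx[ord[1]], , drop = FALSE]
}

#' Exploration: repulsive-energy space filling
#'
#' Returns, from a random candidate pool, the candidate minimizing the
#' repulsive energy `E(x) = sum_i |x - x_i|^(-power)` against the existing
#' points in the encoded unit cube (a Steinerberger-style space-filling
#' criterion: candidates far from everything seen have low energy). The
#' steep default kernel (`power = 4`) is dominated by the nearest existing
#' point, so the argmin is close to a maximin space-filling pick. With no
#' existing points, a uniform random valid point is returned.
#'
#' @param existing Numeric matrix of encoded points (possibly 0 rows or
#'   `NULL`).
#' @param space A `glyco_space`.
#' @param pool_size Candidate pool size.
#' @param seed Integer seed.
#' @param power Exponent of the inverse-power repulsion kernel.
#' @return One condition row (data frame).
#' @export
steinerberger_sample <- function(existing, space, pool_size = 2000L,
                                 seed = NULL, power = 4) {
  pool <- sample_random(space, pool_size, seed = seed)
  if (is.null(existing) || nrow(existing) == 0L) {
    return(pool[1L, , drop = FALSE])
  }
  E <- steinerberger_energy(encode_conditions(space, pool), existing,
                            power = power)
  pool[which.min(E), , drop = FALSE]
}

# Repulsive energy of each candidate row against the existing point set.
steinerberger_energy <- function(cand, existing, power = 4) {
  d <- .cross_dist(cand, existing)
  rowSums(pmax(d, 1e-9)^(-power))
}

#' Propose a shared batch from two campaigns (dual protocol)
#'
#' The second study phase runs two optimizers over the same space — one for
#' (yield, beta-selectivity), one for (yield, alpha-selectivity) — sharing
#' all results. Each batch takes `n_first` exploitation proposals from the
#' first state and `n_second` from the second; exploration is off in dual
#' mode (all proposals use Pareto-front sampling).
#'
#' @param state_first,state_second `glyco_state` objects over the identical
#'   space (typically the beta- and alpha-selectivity campaigns).
#' @param n_first,n_second Number of proposals from each optimizer
#'   (defaults 2 and 3).
#' @return List with `proposals` (condition rows plus `Mode` and `Provenance`
#'   columns) and both updated states.
#' @export
dual_ask <- function(state_first, state_second, n_first = 2L, n_second = 3L) {
  stopifnot(inherits(state_first, "glyco_state"),
            inherits(state_second, "glyco_state"))
  if (!identical(state_first$space, state_second$space)) {
    stop("the two campaigns must share the same reaction space")
  }
  take <- function(state, n, who) {
    rows <- vector("list", n)
    if (n > 0) {
      state <- refresh_surrogates(state)
      for (k in seq_len(n)) {
        s <- next_op_seed(state); state <- s$state
        rows[[k]] <- pareto_exploit(state, seed = s$seed)
      }
    }
    prop <- if (n > 0) do.call(rbind, rows) else NULL
    if (!is.null(prop)) {
      prop$Mode <- "pareto_exploit"
      prop$Provenance <- who
    }
    list(state = state, prop = prop)
  }
  a <- take(state_first, n_first,
            sub("_selectivity", "", state_first$objectives$selectivity$name))
  b <- take(state_second, n_second,
            sub("_selectivity", "", state_second$objectives$selectivity$name))
  prop <- rbind(a$prop, b$prop)
  if (is.null(prop)) {
    prop <- sample_random(state_first$space, 0)
    prop$Mode <- character(0)
    prop$Provenance <- character(0)
  }
  list(proposals = prop, state_first = a$state, state_second = b$state)
}

#' Broadcast shared results to both campaigns
#'
#' @inheritParams dual_ask
#' @param results Data frame of executed experiments (see [tell()]).
#' @return List with both updated states.
#' @export
dual_tell <- function(state_first, state_second, results) {
  list(state_first = tell(state_first, results),
       state_second = tell(state_second, results))
}
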