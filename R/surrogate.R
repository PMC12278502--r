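# Gaussian-process surrogates over the encoded reaction space, one per
# objective. The optimizer is a minimizer, so objectives in percent are
# transformed to losses (100 - value) before fitting; predictions are
# back-transformed for reporting.

#' Objective specification
#'
#' Both campaign objectives are percentages to be maximized. `yield` uses the
#' measured yield column; `beta_selectivity` the percent beta-anomer;
#' `alpha_selectivity` its complement `100 - beta%`. Values are fitted on the
#' loss scale `100 - value`.
#'
#' @param name One of `"yield"`, `"beta_selectivity"`, `"alpha_selectivity"`.
#' @return An object of class `glyco_objective`.
#' @export
objective_spec <- function(name = c("yield", "beta_selectivity",
                                    "alpha_selectivity")) {
  name <- match.arg(name)
  structure(list(name = name, direction = "maximize"),
            class = "glyco_objective")
}

#' Extract an objective's values from campaign results
#'
#' For productive experiments the two anomer percentages are complements,
#' `alpha% = 100 - beta%`. A failed experiment (zero yield) forms no product
#' of either anomer: its recorded ratio is 0 and both selectivity objectives
#' are taken as 0, so that a reaction giving nothing is never scored as
#' perfectly selective.
#'
#' @param results Data frame with `YieldPct` and `BetaPct` columns.
#' @param objective A `glyco_objective` (or its name).
#' @return Numeric vector of objective values in percent.
#' @export
objective_values <- function(results, objective) {
  if (is.character(objective)) objective <- objective_spec(objective)
  switch(objective$name,
         yield = results$YieldPct,
         beta_selectivity = results$BetaPct,
         alpha_selectivity = ifelse(results$YieldPct > 0,
                                    100 - results$BetaPct, 0))
}

#' Minimizer transform of a percentage objective
#'
#' `loss = 100 - value`. Values above 100 percent (possible through NMR
#' integration error) are not clamped, so the loss may be negative; the
#' transform is exactly invertible via [inverse_transform_objective()].
#'
#' @param value Objective value(s) in percent.
#' @return Loss value(s).
#' @export
transform_objective <- function(value) 100 - value

#' @rdname transform_objective
#' @param loss Loss value(s).
#' @export
inverse_transform_objective <- function(loss) 100 - loss

# ---- internal Gaussian process (Matern-5/2 + nugget) -----------------------

# Squared cross-distance matrix between rows of a and b.
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Matern 5/2 kernel on distances r, unit signal variance.
.matern52 <- function(r, ell) {
  a <- sqrt(5) * r / ell
  (1 + a + a^2 / 3) * exp(-a)
}

# Negative log marginal likelihood on standardized targets y.
# theta = (log ell_1..d, log sf2, log sn2); ARD length scales, one per axis.
.gp_nll <- function(theta, X, y) {
  d <- ncol(X)
  ell <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1L]); sn2 <- exp(theta[d + 2L])
  n <- length(y)
  Xs <- sweep(X, 2, ell, `/`)
  K <- sf2 * .matern52(.cross_dist(Xs, Xs), 1)
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(ch))) +
               0.5 * n * log(2 * pi))
}

# Fit hyperparameters by L-BFGS-B with a fixed set of seeded restarts.
.gp_fit <- function(X, y, n_restarts = 5, seed = NULL) {
  d <- ncol(X)
  mu <- mean(y)
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  ys <- (y - mu) / sdy
  lower <- log(c(rep(0.05, d), 1e-3, 1e-6))
  upper <- log(c(rep(20, d), 1e3, 10))
  np <- d + 2L
  starts <- with_seed_if(if (is.null(seed)) 0L else seed, {
    s <- matrix(stats::runif(np * n_restarts, rep(lower, each = n_restarts),
                             rep(upper, each = n_restarts)),
                ncol = np)
    rbind(log(c(rep(1, d), 1, 0.01)), s)
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], .gp_nll, X = X, y = ys, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  theta <- best$par
  ell <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1L]); sn2 <- exp(theta[d + 2L])
  Xs <- sweep(X, 2, ell, `/`)
  K <- sf2 * .matern52(.cross_dist(Xs, Xs), 1)
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(X = X, Xs = Xs, mu = mu, sdy = sdy, ell = ell, sf2 = sf2, sn2 = sn2,
       chol = ch, alpha = alpha, nll = best$value)
}

.gp_predict <- function(gp, Xnew) {
  Xs <- sweep(Xnew, 2, gp$ell, `/`)
  ks <- gp$sf2 * .matern52(.cross_dist(Xs, gp$Xs), 1)
  mean_s <- as.numeric(ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(ks))
  var_s <- pmax(gp$sf2 - colSums(v^2), 0)
  data.frame(mean = gp$mu + gp$sdy * mean_s,
             sd = gp$sdy * sqrt(var_s))
}

# ---- public surrogate API ---------------------------------------------------

#' Fit a Gaussian-process surrogate for one objective
#'
#' Encodes the condition rows to the unit cube, transforms the objective to a
#' loss, and fits a Matern-5/2 Gaussian process with a fitted white-noise
#' term. Hyperparameters (length scale, signal variance, noise variance) are
#' chosen by marginal-likelihood optimization with a fixed number of seeded
#' restarts, so refitting identical data with the same seed is deterministic.
#'
#' @param results Data frame of observations: condition columns plus
#'   `YieldPct` and `BetaPct` (>= 2 rows).
#' @param objective A `glyco_objective` or objective name.
#' @param space A `glyco_space`.
#' @param seed Integer seed for the restart starting points.
#' @param n_restarts Number of random restarts on top of the default start.
#'
#' @return An object of class `glyco_surrogate`.
#' @export
fit_surrogate <- function(results, objective, space, seed = 1L,
                          n_restarts = 2) {
  if (is.character(objective)) objective <- objective_spec(objective)
  if (nrow(results) < 2L) {
    stop("need >= 2 observations to fit a surrogate; ",
         "use random sampling to initialize the campaign")
  }
  X <- encode_conditions(space, results)
  y <- transform_objective(objective_values(results, objective))
  gp <- .gp_fit(X, y, n_restarts = n_restarts, seed = seed)
  structure(list(gp = gp, objective = objective, space = space,
                 n_obs = nrow(results)),
            class = "glyco_surrogate")
}

#' Predict loss mean and uncertainty at new conditions
#'
#' @param object A `glyco_surrogate`.
#' @param newdata Data frame of valid condition rows.
#' @param ... Unused.
#'
#' @return Data frame with `mean_loss`, `sd` (posterior standard deviation of
#'   the latent loss) and `mean_value` (back-transformed percent scale).
#' @export
predict.glyco_surrogate <- function(object, newdata, ...) {
  v <- validate_conditions(object$space, newdata)
  if (!v$ok) {
    stop("invalid conditions: ", paste(v$violations, collapse = "; "))
  }
  X <- encode_conditions(object$space, newdata)
  p <- .gp_predict(object$gp, X)
  data.frame(mean_loss = p$mean, sd = p$sd,
             mean_value = inverse_transform_objective(p$mean))
}

#' @export
print.glyco_surrogate <- function(x, ...) {
  cat(sprintf(paste0("GP surrogate for %s: %d observations, Matern-5/2, ",
                     "mean length scale %.3f, signal var %.3f, noise var %.4f\n"),
              x$objective$name, x$n_obs, mean(x$gp$ell), x$gp$sf2, x$gp$sn2))
  invisible(x)
}
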