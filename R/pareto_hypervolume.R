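# Pareto-front and 2-D hypervolume analytics in the (yield %, selectivity %)
# maximization plane, reference point (0, 0), with the 100 x 100 square as
# 100% hypervolume.

#' Single-point hypervolume contribution
#'
#' The rectangle area spanned from the origin by one experiment's
#' (yield, selectivity) point, as percent of the full 100 x 100 objective
#' square: `yield * selectivity / 100`. 100% corresponds to 100% yield at
#' 100% selectivity. Yields slightly above 100 (NMR integration error) are
#' used as-is; negative inputs are an error.
#'
#' @param yield Yield(s) in percent (`>= 0`).
#' @param selectivity Selectivity in percent (`0..100`), beta% or alpha%
#'   depending on the campaign objective.
#' @return Numeric vector of contributions in percent.
#' @export
point_hypervolume <- function(yield, selectivity) {
  if (any(yield < 0) || any(selectivity < 0)) {
    stop("negative objective values have no dominated area")
  }
  yield * selectivity / 100
}

#' Total 2-D hypervolume of a point set
#'
#' Exact area of the union of the origin-anchored rectangles of all points,
#' computed by the descending-yield sweep, as percent of the 100 x 100
#' square. Monotone non-decreasing under set inclusion, and equal to the
#' hypervolume of the Pareto front alone.
#'
#' @inheritParams point_hypervolume
#' @return Single numeric value in percent; 0 for an empty set.
#' @export
total_hypervolume <- function(yield, selectivity) {
  if (length(yield) == 0L) return(0)
  stopifnot(length(yield) == length(selectivity))
  if (any(yield < 0) || any(selectivity < 0)) {
    stop("negative objective values have no dominated area")
  }
  o <- order(yield, decreasing = TRUE)
  best <- 0
  hv <- 0
  for (i in o) {
    if (selectivity[i] > best) {
      hv <- hv + yield[i] * (selectivity[i] - best) / 100
      best <- selectivity[i]
    }
  }
  hv
}

#' Pareto front of a 2-objective point set
#'
#' Flags the points not weakly dominated by any other (maximization in both
#' axes); among exact duplicates one representative is kept on the front.
#'
#' @inheritParams point_hypervolume
#' @return An object of class `glyco_front`: list with `points` (data frame
#'   `yield`, `selectivity`, `on_front`), `front` (the front rows, sorted by
#'   increasing yield) and `total_hv`.
#' @export
pareto_front <- function(yield, selectivity) {
  stopifnot(length(yield) >= 1L, length(yield) == length(selectivity))
  n <- length(yield)
  o <- order(yield, selectivity, decreasing = TRUE)
  on_front <- logical(n)
  best <- -Inf
  for (i in o) {
    # sorted by descending yield (ties by descending selectivity): a point is
    # non-dominated iff its selectivity strictly exceeds everything seen so
    # far; exact duplicates keep only the first representative
    if (selectivity[i] > best) {
      on_front[i] <- TRUE
      best <- selectivity[i]
    }
  }
  pts <- data.frame(yield = yield, selectivity = selectivity,
                    on_front = on_front)
  front <- pts[pts$on_front, , drop = FALSE]
  front <- front[order(front$yield), , drop = FALSE]
  structure(list(points = pts, front = front,
                 total_hv = total_hypervolume(yield, selectivity)),
            class = "glyco_front")
}

#' @export
print.glyco_front <- function(x, ...) {
  cat(sprintf("Pareto front: %d of %d points, total hypervolume %.2f%%\n",
              nrow(x$front), nrow(x$points), x$total_hv))
  print(x$front, row.names = FALSE)
  invisible(x)
}

#' Exclusive hypervolume contribution of each point
#'
#' The area each point adds on top of all the others:
#' `total_hv(S) - total_hv(S without the point)`. Zero for any dominated
#' point. This is the marginal notion of contribution, distinct from the
#' single-point rectangle area of [point_hypervolume()].
#'
#' @inheritParams point_hypervolume
#' @return Numeric vector of exclusive contributions in percent.
#' @export
exclusive_hypervolume <- function(yield, selectivity) {
  n <- length(yield)
  total <- total_hypervolume(yield, selectivity)
  vapply(seq_len(n), function(i) {
    total - total_hypervolume(yield[-i], selectivity[-i])
  }, numeric(1))
}

#' Batch-wise hypervolume convergence series
#'
#' Cumulative total hypervolume after each batch of a campaign, the
#' convergence diagnostic plotted after every loop.
#'
#' @param results Campaign data frame with `YieldPct`, `BetaPct` and a
#'   `Batch` column.
#' @param objective Objective pair selectivity: `"beta_selectivity"` or
#'   `"alpha_selectivity"` (or a `glyco_objective`).
#' @return Data frame with `Batch` (sorted unique labels) and `TotalHV`;
#'   the series is monotone non-decreasing.
#' @export
hv_convergence <- function(results, objective = "beta_selectivity") {
  if (!"Batch" %in% names(results) || anyNA(results$Batch)) {
    stop("results must carry a complete 'Batch' column")
  }
  sel <- objective_values(results, objective)
  batches <- sort(unique(results$Batch))
  hv <- vapply(batches, function(b) {
    keep <- results$Batch <= b
    total_hypervolume(results$YieldPct[keep], sel[keep])
  }, numeric(1))
  data.frame(Batch = batches, TotalHV = hv)
}

#' Round half away from zero
#'
#' The rounding convention used when comparing computed hypervolume
#' contributions with printed integer columns (base `round()` rounds half to
#' even).
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
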