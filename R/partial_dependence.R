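# Partial dependence of each objective on each reaction parameter, computed
# from the fitted surrogates: the average model prediction as one parameter
# sweeps its range with all other parameters held at observed background
# rows.

#' Partial dependence curve of one parameter
#'
#' For each grid value `g`, every background row has the parameter set to `g`
#' and the surrogate's predicted loss is averaged, then back-transformed to
#' the percent scale. Continuous parameters use an even grid over their
#' bounds; discrete parameters are evaluated at their registered levels only
#' (the curve may be drawn interpolated, but between-level values carry no
#' physical meaning).
#'
#' @param model A `glyco_surrogate`.
#' @param parameter Parameter name in the model's space.
#' @param background Data frame of condition rows to average over; defaults
#'   to the campaign's observed conditions (the empirical background). Must
#'   be supplied here since the surrogate stores only encoded inputs.
#' @param grid_size Grid points for continuous parameters (default 25).
#'
#' @return An object of class `glyco_pdp`: data frame with `Parameter`,
#'   `Grid` (native value; level code for discrete parameters), `Level`
#'   (label, discrete only), `Objective` and `Response` (percent).
#' @export
partial_dependence <- function(model, parameter, background,
                               grid_size = 25L) {
  stopifnot(inherits(model, "glyco_surrogate"))
  space <- model$space
  if (!parameter %in% condition_names(space)) {
    stop("'", parameter, "' is not a parameter of the space")
  }
  p <- space$parameters[[parameter]]
  if (p$kind == "continuous") {
    grid <- seq(p$bounds[1], p$bounds[2], length.out = grid_size)
    labels <- rep(NA_character_, length(grid))
    values <- grid
  } else {
    values <- p$levels
    grid <- p$codes
    labels <- as.character(p$levels)
  }
  resp <- vapply(seq_along(grid), function(i) {
    bg <- background
    bg[[parameter]] <- rep(values[i], nrow(bg))
    if (!is.null(space$constraint) &&
        parameter %in% space$constraint$vars) {
      # keep the solvent pair feasible while sweeping one fraction: shrink
      # the other fraction where the sum would exceed the cap
      other <- setdiff(space$constraint$vars, parameter)
      for (v in other) {
        bg[[v]] <- pmin(bg[[v]],
                        space$constraint$max - bg[[parameter]])
      }
    }
    mean(predict(model, bg)$mean_loss)
  }, numeric(1))
  structure(data.frame(Parameter = parameter, Grid = as.numeric(grid),
                       Level = labels, Objective = model$objective$name,
                       Response = inverse_transform_objective(resp)),
            class = c("glyco_pdp", "data.frame"))
}

#' Partial dependence of every parameter against every objective
#'
#' Fits (or reuses) one surrogate per objective and computes the full panel
#' of curves used to read per-parameter trends off a campaign.
#'
#' @param results Campaign results data frame.
#' @param space A `glyco_space`.
#' @param objectives Character vector of objective names (default all three:
#'   yield, beta- and alpha-selectivity).
#' @param grid_size Grid points for continuous parameters.
#' @param seed Seed passed to [fit_surrogate()].
#'
#' @return A `glyco_pdp` data frame with one row per (parameter, grid value,
#'   objective).
#' @export
partial_dependence_panel <- function(results, space,
                                     objectives = c("yield",
                                                    "beta_selectivity",
                                                    "alpha_selectivity"),
                                     grid_size = 25L, seed = 1L) {
  out <- list()
  for (obj in objectives) {
    model <- fit_surrogate(results, obj, space, seed = seed)
    for (pn in condition_names(space)) {
      out[[paste(obj, pn)]] <- partial_dependence(model, pn, results,
                                                  grid_size = grid_size)
    }
  }
  structure(do.call(rbind, c(out, list(make.row.names = FALSE))),
            class = c("glyco_pdp", "data.frame"))
}
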