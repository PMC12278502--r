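# Campaign CSV input/output in the canonical column schema, the bundled
# 75-experiment validation fixture, and the campaign-level analysis wrapper.

# canonical condition + outcome column names
.campaign_cols <- c("Conf", "LiSalt", "LiSaltEq", "Acid", "AcceptorEq",
                    "ConcM", "PartEt2O", "PartMeCN", "MS", "TempC")
.outcome_cols <- c("YieldPct", "BetaPct")

#' Read a campaign CSV
#'
#' The canonical schema has one row per experiment with the ten condition
#' columns (`Conf`, `LiSalt`, `LiSaltEq`, `Acid`, `AcceptorEq`, `ConcM`,
#' `PartEt2O`, `PartMeCN`, `MS`, `TempC`) plus `YieldPct` and `BetaPct`.
#' Unknown extra columns are preserved; any stored hypervolume column
#' (matching `HV`) is dropped, never read as an input — contributions are
#' always recomputed. Pending rows (proposed but not yet measured) carry
#' empty outcome cells.
#'
#' @param path Path to the CSV file.
#' @param require_outcomes If `TRUE` (default), missing `YieldPct`/`BetaPct`
#'   columns are an error; set `FALSE` for proposal-only files.
#'
#' @return Data frame of experiment rows.
#' @export
read_campaign <- function(path, require_outcomes = TRUE) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(.campaign_cols, if (require_outcomes) .outcome_cols)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("campaign file is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  hv_cols <- grep("^HV", names(d), value = TRUE)
  if (length(hv_cols)) d <- d[, setdiff(names(d), hv_cols), drop = FALSE]
  num_cols <- intersect(c("LiSaltEq", "AcceptorEq", "ConcM", "PartEt2O",
                          "PartMeCN", "TempC", .outcome_cols), names(d))
  for (cn in num_cols) {
    v <- d[[cn]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad)) {
        stop("unparsable numeric in column '", cn, "' at row ", bad[1])
      }
      d[[cn]] <- parsed
    }
  }
  d
}

#' Write a campaign CSV
#'
#' Exact inverse of [read_campaign()]: `read_campaign(write_campaign(x))`
#' round-trips all fields.
#'
#' @param results Data frame of experiment rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_campaign <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The bundled 75-experiment validation campaign
#'
#' The two optimization campaigns of the reference study, transcribed from
#' the published condition/result tables: campaign 1 (experiments 1-55, ten
#' batches, yield + beta-selectivity) and campaign 2 (experiments 56-75,
#' four batches of the dual protocol, each with two beta-objective and three
#' alpha-objective proposals, recorded in the `Objective` column). Labels are
#' ASCII-normalized (for example `3A` molecular sieves, `alpha`/`beta` donor
#' configuration). Printed hypervolume columns are not shipped; they are
#' recomputed by [analyze_campaign()].
#'
#' @param campaign `1`, `2`, or `"all"` for both.
#' @return Data frame of experiment rows with `ExpNo`, `Batch` and
#'   `Objective` columns in addition to the canonical schema.
#' @export
glyco_fixture <- function(campaign = "all") {
  pick <- as.character(campaign)
  stopifnot(pick %in% c("1", "2", "all"))
  get1 <- function(i) {
    read_campaign(system.file("extdata", paste0("campaign", i, ".csv"),
                              package = "glycobo", mustWork = TRUE))
  }
  switch(pick, "1" = get1(1), "2" = get1(2),
         all = rbind(get1(1), get1(2)))
}

#' Analyze a campaign: contributions, totals, fronts, convergence
#'
#' Recomputes every evaluation quantity from the raw yield/selectivity
#' columns: the per-experiment hypervolume contribution (rectangle area)
#' under both selectivity objectives, the total hypervolume, the Pareto
#' front, and (when batch labels are present) the batch-wise convergence
#' series.
#'
#' @param results Campaign data frame.
#' @param objective `"beta_selectivity"` or `"alpha_selectivity"`.
#' @return An object of class `glyco_analysis`: list with `table` (the input
#'   plus `Selectivity` and `HVContr` columns), `total_hv`, `front` (a
#'   `glyco_front`) and `convergence` (or `NULL` without batch labels).
#' @export
analyze_campaign <- function(results, objective = "beta_selectivity") {
  sel <- objective_values(results, objective)
  tab <- results
  tab$Selectivity <- sel
  tab$HVContr <- point_hypervolume(results$YieldPct, sel)
  conv <- if ("Batch" %in% names(results) && !anyNA(results$Batch)) {
    hv_convergence(results, objective)
  }
  structure(
    list(table = tab,
         objective = objective,
         total_hv = total_hypervolume(results$YieldPct, sel),
         front = pareto_front(results$YieldPct, sel),
         convergence = conv),
    class = "glyco_analysis")
}

#' @export
print.glyco_analysis <- function(x, ...) {
  cat(sprintf("Campaign analysis (%s): %d experiments\n", x$objective,
              nrow(x$table)))
  cat(sprintf("  total hypervolume: %.2f%%\n", x$total_hv))
  cat(sprintf("  Pareto front: %d points\n", nrow(x$front$front)))
  if (!is.null(x$convergence)) {
    cat(sprintf("  batches: %d (final batch HV %.2f%%)\n",
                nrow(x$convergence),
                x$convergence$TotalHV[nrow(x$convergence)]))
  }
  invisible(x)
}
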