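# PCA-based ordinal encoding of categorical reagents. The lithium-salt axis of
# the reaction space is an integer rank derived from the first principal
# component of a standardized anion-descriptor table.

#' Rank reagents by their first principal component
#'
#' Standardizes every descriptor column (zero mean, unit variance), runs PCA,
#' and assigns each reagent the rank of its score on the first principal
#' component. The sign of a principal component is arbitrary; it is oriented
#' so that `anchor` receives rank 1.
#'
#' @param descriptors Data frame: first column reagent labels, remaining
#'   columns numeric descriptors (no missing values, >= 2 reagents, >= 1
#'   descriptor).
#' @param anchor Reagent label that fixes the component orientation (rank 1).
#'   Defaults to the reagent with the most extreme PC1 score, making the
#'   result deterministic when no anchor is meaningful.
#'
#' @return Named integer vector: reagent label -> rank in `1..n`.
#' @export
pca_rank_encode <- function(descriptors, anchor = NULL) {
  descriptors <- as.data.frame(descriptors)
  if (nrow(descriptors) < 2L) stop("need >= 2 reagents")
  if (ncol(descriptors) < 2L) stop("need >= 1 descriptor column")
  labels <- as.character(descriptors[[1]])
  if (anyDuplicated(labels)) stop("reagent labels must be unique")
  x <- as.matrix(descriptors[, -1, drop = FALSE])
  if (!is.numeric(x) || anyNA(x)) stop("descriptors must be numeric with no ",
                                       "missing values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant descriptor column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  pc1 <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
  if (is.null(anchor)) {
    anchor <- labels[which.max(abs(pc1))]
  }
  if (!anchor %in% labels) stop("anchor '", anchor, "' is not a reagent label")
  if (pc1[match(anchor, labels)] > 0) pc1 <- -pc1
  tied <- labels[duplicated(pc1) | duplicated(pc1, fromLast = TRUE)]
  if (length(tied)) {
    stop("tied PC1 scores for: ", paste(sort(unique(tied)), collapse = ", "),
         "; add a descriptor column to break the tie")
  }
  ranks <- rank(pc1)
  stats::setNames(as.integer(ranks), labels)
}

#' Bundled synthetic lithium-salt descriptor table
#'
#' A small anion-descriptor table (donor ability, coordinating basicity, and
#' ion-pair dissociation proxies) for the seven lithium salts of the default
#' reaction space. The descriptor values are a synthetic reconstruction
#' calibrated so that the first-principal-component ranking reproduces the
#' four anchors fixed by the campaign analysis (LiI = 1, LiBF4 = 2,
#' LiNTf2 = 5, LiPF6 = 6); they are not measured reference data.
#'
#' @return Data frame with column `Reagent` and three numeric descriptors.
#' @export
default_salt_descriptors <- function() {
  path <- system.file("extdata", "salt_descriptors_synthetic.csv",
                      package = "glycobo", mustWork = TRUE)
  read_descriptor_table(path)
}

#' Read a reagent descriptor table from CSV
#'
#' First column: reagent label; remaining columns: numeric descriptors.
#'
#' @param path Path to a CSV file.
#' @return Data frame suitable for [pca_rank_encode()].
#' @export
read_descriptor_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2L) stop("descriptor table needs a label column and >= 1 ",
                         "descriptor column")
  for (j in seq(2L, ncol(d))) {
    if (!is.numeric(d[[j]])) {
      stop("descriptor column '", names(d)[j], "' is not numeric")
    }
  }
  d
}
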