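# Reaction-condition search space: parameter specs, validation, uniform
# sampling under the solvent constraint, and the numeric encoding used by the
# Gaussian-process surrogates.

#' Declare a single reaction parameter
#'
#' A parameter is one column of a campaign table. Discrete kinds carry an
#' ordered set of `levels` and matching integer `codes` (the representation
#' the surrogate sees); continuous kinds carry `bounds` in native units.
#'
#' @param name Column name of the parameter in campaign tables.
#' @param kind One of `"binary"`, `"ordinal-integer"`, `"discrete-set"`,
#'   `"continuous"`.
#' @param levels Ordered vector of admissible values (discrete kinds only).
#' @param codes Integer encoding of `levels`, same length (discrete kinds
#'   only). Defaults to `seq_along(levels) - 1`.
#' @param bounds Numeric `c(low, high)` in native units (continuous only).
#' @param units Free-text units, for printing.
#'
#' @return An object of class `glyco_param`.
#' @export
param_spec <- function(name, kind, levels = NULL, codes = NULL, bounds = NULL,
                       units = "") {
  kind <- match.arg(kind, c("binary", "ordinal-integer", "discrete-set",
                            "continuous"))
  if (kind == "continuous") {
    stopifnot(is.numeric(bounds), length(bounds) == 2L)
    if (!(bounds[1] < bounds[2])) {
      stop("continuous parameter '", name, "' needs bounds[1] < bounds[2]")
    }
    levels <- NULL
    codes <- NULL
  } else {
    if (is.null(levels) || length(levels) < 2L) {
      stop("discrete parameter '", name, "' needs >= 2 levels")
    }
    if (anyDuplicated(levels)) {
      stop("levels of '", name, "' must be distinct")
    }
    if (kind == "binary" && length(levels) != 2L) {
      stop("binary parameter '", name, "' must have exactly 2 levels")
    }
    if (is.null(codes)) codes <- seq_along(levels) - 1
    stopifnot(length(codes) == length(levels))
    bounds <- NULL
  }
  structure(
    list(name = name, kind = kind, levels = levels,
         codes = if (!is.null(codes)) as.numeric(codes), bounds = bounds,
         units = units),
    class = "glyco_param"
  )
}

#' @export
print.glyco_param <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("<%s> continuous [%g, %g] %s\n", x$name, x$bounds[1],
                x$bounds[2], x$units))
  } else {
    cat(sprintf("<%s> %s {%s} -> codes {%s}\n", x$name, x$kind,
                paste(x$levels, collapse = ", "),
                paste(x$codes, collapse = ", ")))
  }
  invisible(x)
}

#' Assemble a reaction space
#'
#' @param parameters List of [param_spec()] objects, in campaign-column order.
#' @param constraint Optional linear constraint: a list with `vars` (names of
#'   continuous parameters) and `max`; valid conditions satisfy
#'   `sum(vars) <= max`.
#'
#' @return An object of class `glyco_space`.
#' @export
reaction_space <- function(parameters, constraint = NULL) {
  nm <- vapply(parameters, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("parameter names must be unique")
  names(parameters) <- nm
  if (!is.null(constraint)) {
    stopifnot(is.list(constraint), all(c("vars", "max") %in% names(constraint)))
    for (v in constraint$vars) {
      if (!v %in% nm || parameters[[v]]$kind != "continuous") {
        stop("constraint variable '", v, "' is not a declared continuous ",
             "parameter")
      }
    }
  }
  structure(list(parameters = parameters, constraint = constraint),
            class = "glyco_space")
}

#' @export
print.glyco_space <- function(x, ...) {
  cat(sprintf("Reaction space: %d direct parameters\n", length(x$parameters)))
  for (p in x$parameters) print(p)
  if (!is.null(x$constraint)) {
    cat(sprintf("Constraint: %s <= %g\n",
                paste(x$constraint$vars, collapse = " + "), x$constraint$max))
  }
  invisible(x)
}

#' Default lithium-salt ordinal ranks
#'
#' The PCA-derived integer assignment of the seven lithium salts used as the
#' categorical-to-ordinal encoding of the salt axis. The four values fixed by
#' the campaign analysis are LiI = 1, LiBF4 = 2, LiNTf2 = 5, LiPF6 = 6; the
#' remaining three ranks are the ones produced by the bundled synthetic
#' descriptor table (see [default_salt_descriptors()]).
#'
#' @return Named integer vector mapping salt label to rank 1..7.
#' @export
default_salt_ranks <- function() {
  c(LiI = 1L, LiBF4 = 2L, LiClO4 = 3L, LiOTf = 4L, LiNTf2 = 5L,
    LiPF6 = 6L, `LiB(C6F5)4` = 7L)
}

#' Build the default glycosylation condition space
#'
#' Ten direct parameters (donor configuration, lithium salt, salt equivalents,
#' acid, acceptor equivalents, concentration, ether and acetonitrile solvent
#' fractions, molecular sieves, temperature) plus the derived DCM fraction
#' `1 - PartEt2O - PartMeCN`, with the solvent fractions constrained to sum to
#' at most 1. Acids are coded 0 (none) to 4 in order of increasing acid
#' strength, molecular sieves 0 (none) to 3 by pore size, salts by their
#' PCA-derived rank.
#'
#' @param salt_ranks Named integer vector assigning each salt label a rank
#'   (defaults to [default_salt_ranks()]; supply the output of
#'   [pca_rank_encode()] to use a custom descriptor table).
#'
#' @return A `glyco_space`.
#' @export
build_default_space <- function(salt_ranks = default_salt_ranks()) {
  salt_ranks <- sort(salt_ranks)
  reaction_space(
    parameters = list(
      param_spec("Conf", "binary", levels = c("alpha", "beta"), codes = 0:1),
      param_spec("LiSalt", "discrete-set", levels = names(salt_ranks),
                 codes = unname(salt_ranks)),
      param_spec("LiSaltEq", "continuous", bounds = c(0.5, 5),
                 units = "equiv"),
      param_spec("Acid", "ordinal-integer",
                 levels = c("None", "Acetic", "Formic", "Oxalic", "TFA"),
                 codes = 0:4),
      param_spec("AcceptorEq", "continuous", bounds = c(0.8, 3),
                 units = "equiv"),
      param_spec("ConcM", "continuous", bounds = c(0.03, 0.31),
                 units = "mol/L"),
      param_spec("PartEt2O", "continuous", bounds = c(0, 1),
                 units = "fraction"),
      param_spec("PartMeCN", "continuous", bounds = c(0, 1),
                 units = "fraction"),
      param_spec("MS", "ordinal-integer",
                 levels = c("None", "3A", "4A", "5A"), codes = 0:3),
      param_spec("TempC", "discrete-set", levels = c(0, 25), codes = c(0, 25))
    ),
    constraint = list(vars = c("PartEt2O", "PartMeCN"), max = 1)
  )
}

#' Names of the condition columns of a space
#' @param space A `glyco_space`.
#' @return Character vector of parameter names.
#' @export
condition_names <- function(space) {
  names(space$parameters)
}

#' Derived DCM solvent fraction
#'
#' The third solvent part is implicit: `1 - PartEt2O - PartMeCN`.
#'
#' @param conditions Data frame with `PartEt2O` and `PartMeCN` columns.
#' @return Numeric vector of DCM fractions.
#' @export
part_dcm <- function(conditions) {
  1 - conditions$PartEt2O - conditions$PartMeCN
}

# tolerance for boundary comparisons on continuous axes
.bound_eps <- 1e-9

#' Validate conditions against a space
#'
#' Checks every row of `conditions`: discrete values must be declared levels,
#' continuous values must lie within bounds, and the solvent-fraction
#' constraint must hold. Unknown labels are reported as violations, not
#' errors.
#'
#' @param space A `glyco_space`.
#' @param conditions Data frame with one column per space parameter (extra
#'   columns are ignored); any number of rows.
#'
#' @return An object of class `glyco_validation`: list with `ok` (single
#'   logical), `row_ok` (logical per row) and `violations` (character vector
#'   naming the offending row and field).
#' @export
validate_conditions <- function(space, conditions) {
  conditions <- as.data.frame(conditions)
  missing <- setdiff(condition_names(space), names(conditions))
  if (length(missing)) {
    stop("conditions are missing column(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(conditions)
  row_ok <- rep(TRUE, n)
  viol <- character(0)
  flag <- function(rows, msg) {
    rows <- which(rows)
    if (length(rows)) {
      row_ok[rows] <<- FALSE
      viol <<- c(viol, sprintf("row %d: %s", rows, msg))
    }
  }
  for (p in space$parameters) {
    v <- conditions[[p$name]]
    if (p$kind == "continuous") {
      bad <- !is.finite(v) | v < p$bounds[1] - .bound_eps |
        v > p$bounds[2] + .bound_eps
      flag(bad, sprintf("%s outside [%g, %g]", p$name, p$bounds[1],
                        p$bounds[2]))
    } else {
      bad <- if (is.numeric(p$levels)) {
        !(v %in% p$levels)
      } else {
        !(as.character(v) %in% p$levels)
      }
      flag(bad, sprintf("%s not one of {%s}", p$name,
                        paste(p$levels, collapse = ", ")))
    }
  }
  if (!is.null(space$constraint)) {
    s <- Reduce(`+`, lapply(space$constraint$vars,
                            function(v) conditions[[v]]))
    flag(is.finite(s) & s > space$constraint$max + .bound_eps,
         sprintf("%s exceeds %g", paste(space$constraint$vars,
                                        collapse = " + "),
                 space$constraint$max))
  }
  structure(list(ok = all(row_ok), row_ok = row_ok, violations = viol),
            class = "glyco_validation")
}

#' @export
print.glyco_validation <- function(x, ...) {
  if (x$ok) {
    cat("ok:", length(x$row_ok), "row(s) valid\n")
  } else {
    cat("invalid:\n")
    for (v in x$violations) cat(" -", v, "\n")
  }
  invisible(x)
}

#' Draw uniform random conditions
#'
#' Discrete parameters are uniform over their levels; continuous parameters
#' uniform within bounds; the solvent pair is uniform on the triangular region
#' `PartEt2O + PartMeCN <= 1` by rejection sampling (exactly uniform, ~50%
#' acceptance).
#'
#' @param space A `glyco_space`.
#' @param n Number of conditions to draw (`n >= 0`).
#' @param seed Optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#'
#' @return Data frame of `n` valid condition rows.
#' @export
sample_random <- function(space, n, seed = NULL) {
  stopifnot(n >= 0)
  with_seed_if(seed, {
    cols <- lapply(space$parameters, function(p) {
      if (p$kind == "continuous") {
        stats::runif(n, p$bounds[1], p$bounds[2])
      } else {
        p$levels[sample.int(length(p$levels), n, replace = TRUE)]
      }
    })
    out <- as.data.frame(cols, optional = TRUE, check.names = FALSE)
    names(out) <- condition_names(space)
    if (n > 0 && !is.null(space$constraint)) {
      vars <- space$constraint$vars
      cap <- space$constraint$max
      repeat {
        s <- Reduce(`+`, lapply(vars, function(v) out[[v]]))
        bad <- which(s > cap)
        if (!length(bad)) break
        for (v in vars) {
          p <- space$parameters[[v]]
          out[[v]][bad] <- stats::runif(length(bad), p$bounds[1], p$bounds[2])
        }
      }
    }
    out
  })
}

#' Encode conditions as normalized numeric vectors
#'
#' Discrete labels map to their registered integer codes, then every axis is
#' min-max scaled to `[0, 1]`. This is the representation the surrogate and
#' the exploration energy operate on.
#'
#' @param space A `glyco_space`.
#' @param conditions Data frame of valid condition rows.
#'
#' @return Numeric matrix, one row per condition, one column per parameter.
#' @export
encode_conditions <- function(space, conditions) {
  conditions <- as.data.frame(conditions)
  cols <- lapply(space$parameters, function(p) {
    v <- conditions[[p$name]]
    if (p$kind == "continuous") {
      (v - p$bounds[1]) / (p$bounds[2] - p$bounds[1])
    } else {
      idx <- if (is.numeric(p$levels)) match(v, p$levels) else
        match(as.character(v), p$levels)
      if (anyNA(idx)) {
        stop("unknown level in '", p$name, "': ",
             paste(unique(v[is.na(idx)]), collapse = ", "))
      }
      code <- p$codes[idx]
      (code - min(p$codes)) / (max(p$codes) - min(p$codes))
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- condition_names(space)
  rownames(m) <- NULL
  m
}

#' Decode normalized vectors back to conditions
#'
#' Inverse of [encode_conditions()]: continuous axes are rescaled to native
#' units; discrete axes snap to the nearest registered code's level. Vectors
#' outside the unit cube are rejected.
#'
#' @param space A `glyco_space`.
#' @param m Numeric matrix (or single vector) of encoded rows in `[0, 1]`.
#'
#' @return Data frame of condition rows.
#' @export
decode_conditions <- function(space, m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (ncol(m) != length(space$parameters)) {
    stop("encoded vector has ", ncol(m), " axes; space has ",
         length(space$parameters))
  }
  if (any(m < -.bound_eps | m > 1 + .bound_eps)) {
    stop("encoded values outside [0, 1]: out of domain")
  }
  cols <- lapply(seq_along(space$parameters), function(j) {
    p <- space$parameters[[j]]
    v <- pmin(pmax(m[, j], 0), 1)
    if (p$kind == "continuous") {
      p$bounds[1] + v * (p$bounds[2] - p$bounds[1])
    } else {
      code <- min(p$codes) + v * (max(p$codes) - min(p$codes))
      idx <- vapply(code, function(x) which.min(abs(p$codes - x)), integer(1))
      p$levels[idx]
    }
  })
  out <- as.data.frame(cols, optional = TRUE, check.names = FALSE)
  names(out) <- condition_names(space)
  out
}

# Run expr under a temporary seed when seed is non-NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
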