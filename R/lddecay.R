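#' Structure-corrected pairwise LD (partial r-squared)
#'
#' Squared Pearson correlation between the residuals of two marker dosage
#' vectors after linear regression on the covariates (typically the PC25
#' principal-component scores). Unlinked loci can show spurious LD purely
#' through population structure; partialling on structure removes that
#' component. With no covariates this is the plain allele-count r2.
#'
#' @param x1,x2 numeric dosage vectors of equal length, no missing values
#' @param covariates optional numeric matrix of covariates
#' @return partial r2 in \[0, 1\], or `NA` if either residual vector has
#'   zero variance (flagged undefined)
#' @export
partial_r2 <- function(x1, x2, covariates = NULL) {
  stopifnot(length(x1) == length(x2), !anyNA(x1), !anyNA(x2))
  if (is.null(covariates)) {
    r1 <- x1 - mean(x1); r2v <- x2 - mean(x2)
  } else {
    qw <- qr(cbind(1, covariates))
    r1 <- qr.resid(qw, x1)
    r2v <- qr.resid(qw, x2)
  }
  if (sum(r1^2) < 1e-12 || sum(r2v^2) < 1e-12) return(NA_real_)
  (sum(r1 * r2v)^2) / (sum(r1^2) * sum(r2v^2))
}

#' Expected r-squared under drift-recombination-sample-size equilibrium
#'
#' The closed-form expectation of r2 at population recombination parameter
#' C = rho * distance for a sample of n chromosomes, including the
#' low-sample-size inflation term:
#' E(r2) = \[(10+C)/((2+C)(11+C))\] * \[1 + ((3+C)(12+12C+C^2))/(n(2+C)(11+C))\].
#' As C grows the curve falls toward the sampling floor ~ 1/n.
#'
#' @param C non-negative population recombination parameter (rho * bp)
#' @param n sample size
#' @return expected r2
#' @export
expected_r2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Uniform random intra-chromosomal marker pairs
#'
#' Enumerates all same-chromosome marker pairs within `max_distance` and
#' returns a uniform random subset of at most `max_pairs` (all pairs, no
#' duplicates, if fewer are available). Deterministic under `seed`.
#'
#' @param g a [geno()] object
#' @param max_pairs maximum number of pairs to return
#' @param max_distance maximum pair distance in bp
#' @param seed optional integer seed
#' @return data.frame: `chrom`, `id1`, `id2`, `pos1`, `pos2`, `dist`
#' @export
sample_pairs <- function(g, max_pairs = 5000, max_distance = 1e7,
                         seed = NULL) {
  stopifnot(max_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  map <- g$map
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    hi <- findInterval(pos + max_distance, pos)
    cnt <- hi - seq_along(pos)
    if (sum(cnt) == 0) next
    i <- rep(seq_along(pos), cnt)
    j <- sequence(cnt) + i
    res[[ch]] <- data.frame(
      chrom = ch, id1 = map$id[idx[i]], id2 = map$id[idx[j]],
      pos1 = pos[i], pos2 = pos[j], dist = pos[j] - pos[i],
      stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(), id1 = character(),
                      id2 = character(), pos1 = integer(), pos2 = integer(),
                      dist = integer(), stringsAsFactors = FALSE))
  all <- do.call(rbind, res)
  rownames(all) <- NULL
  if (nrow(all) > max_pairs)
    all <- all[sort(sample.int(nrow(all), max_pairs)), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Attach partial r2 to sampled marker pairs
#'
#' @param g a [geno()] object (imputed)
#' @param pairs a [sample_pairs()] data.frame
#' @param covariates optional covariate matrix (PC scores) for partial r2
#' @return `pairs` with an `r2` column appended
#' @export
ld_pairs_r2 <- function(g, pairs, covariates = NULL) {
  d <- g$dosage
  if (anyNA(d)) stop("missing dosages; impute first (impute_mode)")
  # residualize all markers once
  if (is.null(covariates)) {
    rd <- scale(d, center = TRUE, scale = FALSE)
  } else {
    rd <- qr.resid(qr(cbind(1, covariates)), d)
  }
  ss <- colSums(rd^2)
  i1 <- match(pairs$id1, g$map$id)
  i2 <- match(pairs$id2, g$map$id)
  num <- colSums(rd[, i1, drop = FALSE] * rd[, i2, drop = FALSE])^2
  den <- ss[i1] * ss[i2]
  pairs$r2 <- ifelse(den < 1e-12, NA_real_, num / den)
  pairs
}

#' Fit the LD decay curve
#'
#' Least-squares fit of [expected_r2()] with C = rho * distance to observed
#' (distance, r2) pairs, rho being the single free parameter. The fit is a
#' multi-start search over a log-spaced rho grid followed by local
#' refinement. Also reports the distances at which the fitted curve crosses
#' the query r2 levels.
#'
#' @param pairs data.frame with columns `dist` and `r2` (NAs dropped)
#' @param n sample size used in the expectation
#' @param levels r2 levels whose crossing distances to report
#' @return object of class `decay_fit`: list with `rho`, `n`, `sse`,
#'   `crossings` (named numeric, bp; NA where the curve never reaches the
#'   level), and `predict(distance)` via [predict.decay_fit()]
#' @export
fit_decay <- function(pairs, n, levels = c(0.7, 0.2, 0.1)) {
  ok <- is.finite(pairs$r2) & is.finite(pairs$dist) & pairs$dist >= 0
  d <- pairs$dist[ok]; r2 <- pairs$r2[ok]
  if (length(d) < 10) stop("need at least 10 usable pairs")
  if (diff(range(log10(pmax(d, 1)))) < 2)
    warning("pair distances span < 2 orders of magnitude; fit may be weak")
  sse <- function(log10rho) {
    e <- expected_r2(10^log10rho * d, n)
    sum((r2 - e)^2)
  }
  grid <- seq(-12, -2, by = 0.5)
  vals <- vapply(grid, sse, numeric(1))
  if (all(!is.finite(vals))) stop("decay fit failed on the rho grid")
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(sse, c(lo, hi), tol = 1e-8)
  rho <- 10^opt$minimum
  crossings <- vapply(levels, function(lev) {
    at0 <- expected_r2(0, n)
    if (lev >= at0) return(0)
    f <- function(x) expected_r2(rho * x, n) - lev
    upper <- 1e3
    while (f(upper) > 0 && upper < 1e15) upper <- upper * 10
    if (f(upper) > 0) return(NA_real_)  # level below the 1/n floor
    stats::uniroot(f, c(0, upper), tol = 1)$root
  }, numeric(1))
  names(crossings) <- paste0("r2_", levels)
  structure(list(rho = rho, n = n, sse = opt$objective,
                 crossings = crossings),
            class = "decay_fit")
}

#' Predict expected r2 from a fitted decay curve
#' @param object a [fit_decay()] result
#' @param distance distances in bp
#' @param ... unused
#' @return expected r2 at each distance
#' @export
predict.decay_fit <- function(object, distance, ...) {
  expected_r2(object$rho * distance, object$n)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> rho =", format(x$rho, digits = 4),
      "per bp, n =", x$n, "\n")
  cat("  crossings (bp):",
      paste(names(x$crossings), "=", format(round(x$crossings)),
            collapse = ", "), "\n")
  invisible(x)
}
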