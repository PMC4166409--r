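#' @importFrom stats pf pt qchisq quantile median cor lm coef optimize
NULL

# smallest p-value reported, to keep -log10(p) finite in Manhattan output
P_FLOOR <- 1e-300

#' The six association models
#'
#' Marker-trait association is run under six models: three fixed-effect
#' models (naive, pc25, pc50) and three mixed models adding a centered
#' kinship random effect (kinship, pc25+kinship, pc50+kinship). The pc25 /
#' pc50 covariate sets are the principal components reaching 25% / 50%
#' cumulative variance.
#'
#' @return character vector of the six model names
#' @export
assoc_models <- function() {
  c("naive", "pc25", "pc50", "kinship", "pc25+kinship", "pc50+kinship")
}

#' Single-marker fixed-effect (OLS) test
#'
#' Ordinary least squares of `y` on an intercept, the covariates and the
#' marker, with a two-sided t-test on the marker coefficient. A marker
#' collinear with the covariates (or constant) is flagged degenerate and
#' reported with p = 1.
#'
#' @param y numeric response (adjusted IDC scores)
#' @param x numeric marker dosages
#' @param covariates optional numeric matrix of covariates (PC scores)
#' @return list with `beta`, `se`, `p`, `df`, `degenerate`
#' @export
fit_marker_fixed <- function(y, x, covariates = NULL) {
  stopifnot(length(y) == length(x), !anyNA(y), !anyNA(x))
  X <- cbind(`(Intercept)` = 1, covariates, marker = x)
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need n > number of covariates + 2")
  fit <- stats::lm.fit(X, y)
  if (is.na(fit$coefficients["marker"]) || fit$rank < p) {
    return(list(beta = NA_real_, se = NA_real_, p = 1, df = n - p,
                degenerate = TRUE))
  }
  rss <- sum(fit$residuals^2)
  df <- n - p
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtXinv[p, p])
  beta <- unname(fit$coefficients["marker"])
  tval <- beta / se
  pval <- max(2 * pt(-abs(tval), df), P_FLOOR)
  list(beta = beta, se = se, p = pval, df = df, degenerate = FALSE)
}

#' Eigendecomposition of a kinship matrix for mixed-model scans
#'
#' One-time spectral decomposition reused for every marker. Small negative
#' eigenvalues (numerical noise, down to -1e-8 relative) are clamped to 0;
#' anything more negative is rejected as non-PSD.
#'
#' @param K symmetric kinship matrix
#' @return list with `U` (eigenvectors) and `d` (eigenvalues)
#' @export
kinship_eigen <- function(K) {
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("kinship matrix not symmetric")
  e <- eigen(K, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (min(e$values) < -tol)
    stop("kinship matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  e$values[e$values < 0] <- 0
  list(U = e$vectors, d = e$values)
}

# REML criterion and GLS pieces for one lambda, in the rotated basis.
# Xt, yt are U'X, U'y; d the kinship eigenvalues. Returns the profiled
# -2 restricted log-likelihood up to a constant, plus the GLS fit.
.lmm_eval <- function(loglam, Xt, yt, d, n, p, fit = FALSE) {
  lam <- exp(loglam)
  v <- lam * d + 1
  w <- 1 / v
  Xw <- Xt * w
  A <- crossprod(Xt, Xw)
  b <- crossprod(Xw, yt)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(if (fit) NULL else Inf)
  coefs <- backsolve(ch, forwardsolve(t(ch), b))
  rss <- sum(w * yt^2) - sum(b * coefs)
  rss <- max(rss, 1e-12)
  crit <- (n - p) * log(rss) + sum(log(v)) + 2 * sum(log(diag(ch)))
  if (!fit) return(crit)
  Ainv <- chol2inv(ch)
  list(crit = crit, coefs = drop(coefs), rss = rss, Ainv = Ainv)
}

#' Single-marker exact mixed-model test
#'
#' Fits y = W a + x b + u + e with u ~ N(0, sg2 K) and e ~ N(0, se2 I).
#' The variance ratio lambda = sg2/se2 is re-optimized by REML for each
#' marker's alternative model (the "exact test" convention), via a one-time
#' eigendecomposition of K and one-dimensional optimization, followed by a
#' Wald test of the marker coefficient against F(1, n - c - 1).
#'
#' @param y numeric response
#' @param x numeric marker dosages
#' @param covariates optional covariate matrix (PC scores)
#' @param K kinship matrix (ignored if `eig` supplied)
#' @param eig optional precomputed [kinship_eigen()] result
#' @return list with `beta`, `se`, `p`, `lambda`, `sigma_g2`, `sigma_e2`,
#'   `df`, `boundary`, `degenerate`
#' @export
fit_marker_lmm <- function(y, x, covariates = NULL, K = NULL, eig = NULL) {
  stopifnot(length(y) == length(x))
  if (is.null(eig)) eig <- kinship_eigen(K)
  X <- cbind(`(Intercept)` = 1, covariates, marker = x)
  n <- length(y); p <- ncol(X)
  Xt <- crossprod(eig$U, X)
  yt <- drop(crossprod(eig$U, y))
  .lmm_wald(Xt, yt, eig$d, n, p)
}

# core LMM marker test in the rotated basis (shared by scan loop)
.lmm_wald <- function(Xt, yt, d, n, p,
                      loglam_range = log(c(1e-5, 1e5)), grid_n = 11) {
  degen <- list(beta = NA_real_, se = NA_real_, p = 1, lambda = NA_real_,
                sigma_g2 = NA_real_, sigma_e2 = NA_real_, df = n - p,
                boundary = FALSE, degenerate = TRUE)
  grid <- seq(loglam_range[1], loglam_range[2], length.out = grid_n)
  cr <- vapply(grid, .lmm_eval, numeric(1), Xt = Xt, yt = yt, d = d,
               n = n, p = p)
  if (all(!is.finite(cr))) return(degen)
  i <- which.min(cr)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(grid_n, i + 1)]
  opt <- optimize(.lmm_eval, c(lo, hi), Xt = Xt, yt = yt, d = d,
                  n = n, p = p, tol = 1e-4)
  f <- .lmm_eval(opt$minimum, Xt, yt, d, n, p, fit = TRUE)
  if (is.null(f)) return(degen)
  lam <- exp(opt$minimum)
  se2 <- f$rss / (n - p)
  beta <- f$coefs[p]
  var_b <- se2 * f$Ainv[p, p]
  if (!is.finite(var_b) || var_b <= 0) return(degen)
  Fstat <- beta^2 / var_b
  pval <- max(pf(Fstat, 1, n - p, lower.tail = FALSE), P_FLOOR)
  boundary <- opt$minimum <= loglam_range[1] + 1e-3 ||
    opt$minimum >= loglam_range[2] - 1e-3
  list(beta = unname(beta), se = sqrt(var_b), p = pval, lambda = lam,
       sigma_g2 = lam * se2, sigma_e2 = se2, df = n - p,
       boundary = boundary, degenerate = FALSE)
}

#' Genome scan under one association model
#'
#' Runs the single-marker test for every marker under one of the six models
#' (see [assoc_models()]). Fixed-effect models use a vectorized
#' Frisch-Waugh residualization; kinship models re-optimize the REML
#' variance ratio per marker.
#'
#' @param g a [geno()] object, imputed (no missing dosages)
#' @param y adjusted phenotype vector aligned with `rownames(g$dosage)`
#' @param model one of [assoc_models()]
#' @param structure a [geno_pca()] result (needed for pc models)
#' @param kinship kinship matrix (needed for kinship models)
#' @param pc_thresholds cumulative-variance thresholds for pc25/pc50
#' @return data.frame: `id`, `chrom`, `pos`, `beta`, `p`, `neglog10p`,
#'   plus `lambda` for mixed models; attribute `model`
#' @export
assoc_scan <- function(g, y, model = "pc50+kinship", structure = NULL,
                       kinship = NULL, pc_thresholds = c(0.25, 0.50)) {
  model <- match.arg(model, assoc_models())
  d <- g$dosage
  if (anyNA(d)) stop("missing dosages; impute first (impute_mode)")
  stopifnot(length(y) == nrow(d), !anyNA(y))
  covariates <- NULL
  if (model %in% c("pc25", "pc25+kinship")) {
    if (is.null(structure)) stop("model ", model, " needs a structure model")
    k <- select_pcs(structure, pc_thresholds[1])
    covariates <- structure$scores[, seq_len(k), drop = FALSE]
  } else if (model %in% c("pc50", "pc50+kinship")) {
    if (is.null(structure)) stop("model ", model, " needs a structure model")
    k <- select_pcs(structure, pc_thresholds[2])
    covariates <- structure$scores[, seq_len(k), drop = FALSE]
  }
  use_k <- grepl("kinship", model)
  m <- ncol(d); n <- nrow(d)
  out <- data.frame(id = g$map$id, chrom = g$map$chrom, pos = g$map$pos,
                    beta = NA_real_, p = 1, stringsAsFactors = FALSE)
  if (use_k) {
    if (is.null(kinship)) stop("model ", model, " needs a kinship matrix")
    eig <- kinship_eigen(kinship)
    W <- cbind(`(Intercept)` = rep(1, n), covariates)
    Wt <- crossprod(eig$U, W)
    yt <- drop(crossprod(eig$U, y))
    Dt <- crossprod(eig$U, d)   # rotated markers, n x m
    p_fixed <- ncol(W) + 1L
    lam <- numeric(m)
    for (j in seq_len(m)) {
      r <- .lmm_wald(cbind(Wt, marker = Dt[, j]), yt, eig$d, n, p_fixed)
      out$beta[j] <- r$beta; out$p[j] <- r$p; lam[j] <- r$lambda
    }
    out$lambda <- lam
  } else {
    # Frisch-Waugh: residualize y and every marker on [1, covariates]
    W <- cbind(rep(1, n), covariates)
    qw <- qr(W)
    ry <- qr.resid(qw, y)
    rx <- qr.resid(qw, d)
    df <- n - ncol(W) - 1L
    ssx <- colSums(rx^2)
    ok <- ssx > 1e-12 * n
    bet <- rep(NA_real_, m); pv <- rep(1, m)
    bet[ok] <- colSums(rx[, ok, drop = FALSE] * ry) / ssx[ok]
    rssy <- sum(ry^2)
    rss1 <- rssy - bet[ok]^2 * ssx[ok]
    rss1 <- pmax(rss1, 0)
    tv <- bet[ok] / sqrt(rss1 / df / ssx[ok])
    pv[ok] <- pmax(2 * pt(-abs(tv), df), P_FLOOR)
    out$beta <- bet; out$p <- pv
  }
  out$neglog10p <- -log10(out$p)
  attr(out, "model") <- model
  out
}

#' Per-marker allelic summaries (Table-style statistics)
#'
#' For each marker: phenotype means of the two homozygote classes
#' (reference = dosage 0, variant = dosage 2; heterozygotes are excluded
#' from the means), their absolute difference, the additive effect of the
#' variant allele = (variant mean - reference mean) / 2, the percent
#' variation explained by a simple one-marker regression (all called
#' samples, heterozygotes included), and MAF in percent. A marker missing
#' either homozygote class gets NA allelic statistics.
#'
#' @param g a [geno()] object
#' @param y_raw raw-scale phenotypes aligned with samples
#' @return data.frame: `id`, `chrom`, `pos`, `ref`, `alt`, `ref_mean`,
#'   `var_mean`, `mean_diff`, `additive_effect`, `r2_pct`, `maf_pct`
#' @export
marker_stats <- function(g, y_raw) {
  d <- g$dosage
  stopifnot(length(y_raw) == nrow(d))
  m <- ncol(d)
  ref_mean <- var_mean <- r2 <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    x <- d[, j]
    ok <- !is.na(x)
    i0 <- ok & x == 0; i2 <- ok & x == 2
    if (any(i0)) ref_mean[j] <- mean(y_raw[i0])
    if (any(i2)) var_mean[j] <- mean(y_raw[i2])
    if (sum(ok) > 2 && stats::var(x[ok]) > 0)
      r2[j] <- stats::cor(y_raw[ok], x[ok])^2
  }
  maf <- marker_summary(g)$maf
  data.frame(
    id = g$map$id, chrom = g$map$chrom, pos = g$map$pos,
    ref = g$map$ref, alt = g$map$alt,
    ref_mean = ref_mean, var_mean = var_mean,
    mean_diff = abs(var_mean - ref_mean),
    additive_effect = (var_mean - ref_mean) / 2,
    r2_pct = 100 * r2, maf_pct = 100 * maf,
    stringsAsFactors = FALSE
  )
}

#' Full association table for one model
#'
#' Joins the genome scan p-values with the allelic summary statistics into
#' one per-marker report table.
#'
#' @inheritParams assoc_scan
#' @param y_raw raw-scale phenotypes for the allelic means
#' @param ... passed to [assoc_scan()]
#' @return data.frame combining [assoc_scan()] and [marker_stats()] columns
#' @export
assoc_table <- function(g, y, y_raw, ...) {
  sc <- assoc_scan(g, y, ...)
  st <- marker_stats(g, y_raw)
  out <- cbind(st[c("id", "chrom", "pos", "ref", "alt")],
               p = sc$p, neglog10p = sc$neglog10p, beta = sc$beta,
               st[c("r2_pct", "maf_pct", "ref_mean", "var_mean",
                    "mean_diff", "additive_effect")])
  attr(out, "model") <- attr(sc, "model")
  out
}

#' Rank-based mean squared difference of a p-value vector
#'
#' Sorted observed p-values are compared with their uniform order-statistic
#' expectations i/(m+1): MSD = mean of squared differences. A perfectly
#' calibrated (uniform) p-value set gives 0.
#'
#' @param p numeric vector of p-values
#' @return the MSD statistic
#' @export
msd <- function(p) {
  m <- length(p)
  if (m == 0) stop("empty p-value vector")
  sp <- sort(p)
  expected <- seq_len(m) / (m + 1)
  mean((sp - expected)^2)
}

#' Model selection by rank-based MSD
#'
#' Computes [msd()] per model and selects the minimizer — the model whose
#' genome-wide p-value distribution best matches the uniform null.
#'
#' @param p_list named list of p-value vectors, one per model
#' @return list with `table` (data.frame model, msd) and `selected`
#' @export
msd_select <- function(p_list) {
  stopifnot(is.list(p_list), length(p_list) > 0, !is.null(names(p_list)))
  tab <- data.frame(model = names(p_list),
                    msd = vapply(p_list, msd, numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, selected = tab$model[which.min(tab$msd)])
}

#' Bootstrap empirical percentile significance thresholds
#'
#' Resamples the genome-wide p-value vector with replacement B times; for
#' each resample takes the `levels` quantiles (type-7 interpolation); the
#' cutoff per level is the mean (default) or median of the B resampled
#' quantiles. Levels 1e-4 and 1e-3 are the 0.01- and 0.1-percentile tails.
#'
#' @param p p-value vector (one per marker)
#' @param levels quantile fractions in (0,1); default `c(1e-4, 1e-3)`
#' @param B number of bootstrap resamples (default 10000)
#' @param seed optional integer seed for the resampling
#' @param aggregate `"mean"` (default) or `"median"` of the B quantiles
#' @return object of class `threshold_set`: data.frame `level`, `cutoff`
#'   with attributes `B`, `aggregate`, `quantile_type`
#' @export
bootstrap_thresholds <- function(p, levels = c(1e-4, 1e-3), B = 10000,
                                 seed = NULL, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(p) >= 1, B >= 1)
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  m <- length(p)
  if (m < 1 / min(levels))
    warning("fewer markers (", m, ") than 1/level; extreme quantiles are ",
            "interpolated near the minimum p-value")
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0, nrow = B, ncol = length(levels))
  for (b in seq_len(B)) {
    acc[b, ] <- quantile(p[sample.int(m, m, replace = TRUE)],
                         probs = levels, type = 7, names = FALSE)
  }
  cutoff <- if (aggregate == "mean") colMeans(acc)
            else apply(acc, 2, median)
  out <- data.frame(level = levels, cutoff = cutoff)
  out <- out[order(out$level), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("threshold_set", "data.frame"),
            B = B, aggregate = aggregate, quantile_type = 7)
}

#' Genomic-control inflation factor
#'
#' Median of the 1-df chi-square statistics implied by the p-values over the
#' null median 0.4549; 1 for a calibrated scan, > 1 under inflation.
#'
#' @param p p-value vector
#' @return the inflation factor lambda_GC
#' @export
lambda_gc <- function(p) {
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}
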