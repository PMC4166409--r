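#' Principal component analysis of the dosage matrix
#'
#' PCA of the column-centered (not variance-scaled) dosage matrix via
#' singular value decomposition, i.e. the covariance form. Variance
#' fractions are eigenvalues over total variance.
#'
#' @param g a [geno()] object with no missing dosages
#' @return an object of class `structure_model`: list with `scores`
#'   (samples x components), `var_frac`, `sdev`, and `scaling = "covariance"`
#' @export
geno_pca <- function(g) {
  d <- g$dosage
  if (anyNA(d)) stop("missing dosages; impute first (impute_mode)")
  if (nrow(d) < 3) stop("need at least 3 samples for PCA")
  xc <- scale(d, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12))
    stop("zero total variance: all marker columns constant")
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  rownames(scores) <- rownames(d)
  structure(list(scores = scores, var_frac = vf, sdev = pc$sdev,
                 scaling = "covariance"),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  k <- min(5, length(x$var_frac))
  cat("<structure_model> ", nrow(x$scores), " samples, ",
      length(x$var_frac), " components (", x$scaling, " PCA)\n", sep = "")
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$var_frac[seq_len(k)]), collapse = " "), "\n")
  invisible(x)
}

#' Number of components reaching a cumulative-variance threshold
#'
#' Returns the smallest k whose cumulative variance fraction is at least
#' `threshold` — the rule behind the PC25 / PC50 covariate sets.
#'
#' @param s a [geno_pca()] result
#' @param threshold cumulative variance fraction in (0, 1)
#' @return integer component count
#' @export
select_pcs <- function(s, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  cum <- cumsum(s$var_frac)
  k <- which(cum >= threshold - 1e-12)
  if (length(k) == 0)
    stop("cumulative variance never reaches ", threshold)
  k[1L]
}

#' Centered relatedness (kinship) matrix
#'
#' K = Xc Xc' / m over the m markers, with Xc the column-centered dosage
#' matrix — the "centered" kinship convention of mixed-model GWAS software.
#' Rows of K sum to zero by construction and K is positive semi-definite.
#'
#' @param g a [geno()] object with no missing dosages and >= 2 markers
#' @return an n x n symmetric matrix with sample ids as dimnames
#' @export
kinship_centered <- function(g) {
  d <- g$dosage
  if (anyNA(d)) stop("missing dosages; impute first (impute_mode)")
  if (ncol(d) < 2) stop("need at least 2 markers")
  xc <- scale(d, center = TRUE, scale = FALSE)
  # monomorphic columns contribute nothing; identical samples yield K = 0
  K <- tcrossprod(xc) / ncol(d)
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

#' Gower similarity between samples
#'
#' Interval-scaled Gower coefficient on dosages with a fixed range of 2:
#' s(i, j) = mean over markers of 1 - |d_i - d_j| / 2. The fixed range makes
#' the coefficient independent of panel composition. Identical samples score
#' 1; samples opposite-homozygous everywhere score 0.
#'
#' @param g a [geno()] object with no missing dosages
#' @return an n x n symmetric matrix with unit diagonal
#' @export
gower_similarity <- function(g) {
  d <- g$dosage
  if (anyNA(d)) stop("missing dosages; impute first (impute_mode)")
  m <- ncol(d)
  S <- 1 - as.matrix(stats::dist(d, method = "manhattan")) / (2 * m)
  dimnames(S) <- list(rownames(d), rownames(d))
  S
}
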