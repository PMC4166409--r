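test_that("fixed-effect marker test matches a normal-equations oracle", {
  set.seed(21)
  n <- 20
  x <- rbinom(n, 2, 0.4)
  z <- matrix(rnorm(2 * n), n)
  y <- 2.7 + 0.3 * x + 0.2 * z[, 1] + rnorm(n, 0, 0.4)
  fit <- fit_marker_fixed(y, x, z)
  # oracle: explicit normal equations + t distribution
  X <- cbind(1, z, x)
  bh <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% bh
  s2 <- sum(res^2) / (n - ncol(X))
  se <- sqrt(s2 * solve(crossprod(X))[4, 4])
  tt <- bh[4] / se
  expect_equal(fit$beta, bh[4], tolerance = 1e-10)
  expect_equal(fit$p, 2 * pt(-abs(tt), n - 4), tolerance = 1e-10)
  # exact linear response -> p at the floor
  y0 <- 1 + 0.5 * x
  expect_lt(fit_marker_fixed(y0, x)$p, 1e-200)
  # constant marker -> degenerate
  dg <- fit_marker_fixed(y, rep(2, n))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
})

test_that("mixed model collapses to OLS when K = I", {
  set.seed(4)
  n <- 60
  y <- rnorm(n); x <- rbinom(n, 2, 0.3); z <- matrix(rnorm(2 * n), n)
  a <- fit_marker_fixed(y, x, z)
  b <- fit_marker_lmm(y, x, z, K = diag(n))
  expect_equal(b$p, a$p, tolerance = 1e-6)
  expect_equal(b$beta, a$beta, tolerance = 1e-6)
  expect_error(fit_marker_lmm(y, x, z, K = -diag(n)), "positive semi-definite")
})

test_that("REML recovers the variance ratio from a known kinship", {
  cfg <- small_cfg(seed = 12, n = c(135, 135), n_chr = 2, m = 600, miss = 0)
  g <- impute_mode(filter_maf(simulate_population(cfg)$geno, 0.05))
  K <- kinship_centered(g)
  K <- K / mean(diag(K))          # unit-trace scaling so lambda = h2/(1-h2)
  eig <- kinship_eigen(K)
  R <- chol(K + 1e-8 * diag(nrow(K)))
  lam <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    u <- drop(crossprod(R, rnorm(nrow(K))))    # var sg2 = 1
    y <- u + rnorm(nrow(K))                    # var se2 = 1 -> lambda = 1
    x <- rbinom(nrow(K), 1, 0.5) * 2
    fit_marker_lmm(y, x, eig = eig)$lambda
  }, numeric(1))
  expect_gte(median(lam), 0.5)
  expect_lte(median(lam), 2.0)
})

test_that("naive scans inflate on structured panels, pc+kinship stays calibrated", {
  cfg <- small_cfg(seed = 3, n = c(135, 135), n_chr = 4, m = 1500,
                   miss = 0, shift = 0.3)
  pw <- panel_with_structure(cfg)
  y <- pw$pheno$adjusted + 0.25 * pw$pc$scores[, 1] / sd(pw$pc$scores[, 1])
  naive <- assoc_scan(pw$g, y, "naive")
  corr <- assoc_scan(pw$g, y, "pc25+kinship", structure = pw$pc,
                     kinship = pw$K)
  expect_gt(lambda_gc(naive$p), 1.05)
  expect_gt(lambda_gc(corr$p), 0.9)
  expect_lt(lambda_gc(corr$p), 1.1)
  expect_lt(msd(corr$p), msd(naive$p))
})

test_that("type-I error of the corrected model is near nominal on null panels", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    cfg <- small_cfg(seed = 300 + s, n = c(135, 135), n_chr = 2, m = 2000,
                     miss = 0)
    pw <- panel_with_structure(cfg)      # no planted QTL: phenotype is null
    sc <- assoc_scan(pw$g, pw$pheno$adjusted, "pc25+kinship",
                     structure = pw$pc, kinship = pw$K)
    hits <- hits + sum(sc$p <= 0.001)
    total <- total + length(sc$p)
  }
  rate <- hits / total
  expect_gte(rate, 0.0002)
  expect_lte(rate, 0.003)
})

test_that("marker statistics satisfy the half-difference identity", {
  # variant allele lowers IDC by 0.32 between homozygote classes
  y <- c(rep(3.0, 5), rep(2.68, 5), 2.9)          # last sample heterozygous
  d <- matrix(c(rep(0, 5), rep(2, 5), 1), ncol = 1)
  g <- toy_geno(d, ref = "C", alt = "T")
  st <- marker_stats(g, y)
  expect_equal(st$ref_mean, 3.0)
  expect_equal(st$var_mean, 2.68)
  expect_equal(st$mean_diff, 0.32)
  expect_equal(st$additive_effect, -0.16)
  # equal class means -> zero additive effect
  st0 <- marker_stats(toy_geno(matrix(c(0, 0, 2, 2), ncol = 1)),
                      c(2, 3, 2, 3))
  expect_equal(st0$additive_effect, 0)
  # identity across a whole simulated table
  cfg <- small_cfg(seed = 8, n = c(30, 30), n_chr = 2, m = 300)
  sim <- simulate_population(cfg)
  g2 <- impute_mode(filter_maf(sim$geno, 0.05))
  tab <- marker_stats(g2, sim$pheno$idc_score)
  ok <- !is.na(tab$additive_effect)
  expect_true(any(ok))
  expect_equal(abs(tab$additive_effect[ok]), tab$mean_diff[ok] / 2)
  expect_true(all(tab$r2_pct >= 0 & tab$r2_pct <= 100, na.rm = TRUE))
  # a marker with an empty homozygote class is flagged missing
  st1 <- marker_stats(toy_geno(matrix(c(0, 0, 1, 1), ncol = 1)), c(2, 3, 2, 3))
  expect_true(is.na(st1$var_mean) && is.na(st1$additive_effect))
})

test_that("rank-based MSD matches hand evaluation and selects the minimum", {
  m <- 200
  expect_equal(msd(seq_len(m) / (m + 1)), 0)
  expect_equal(msd(c(0.1, 0.5, 0.9)), 0.015)
  sel <- msd_select(list(a = c(0.1, 0.5, 0.9), b = c(0.25, 0.5, 0.75)))
  expect_equal(sel$selected, "b")
  expect_equal(sel$table$msd[sel$table$model == "a"], 0.015)
  expect_error(msd(numeric(0)), "empty")
})

test_that("bootstrap thresholds: degeneracy, ordering, determinism, oracle", {
  # degenerate distribution
  thr0 <- bootstrap_thresholds(rep(0.5, 2000), B = 50, seed = 1)
  expect_equal(thr0$cutoff, c(0.5, 0.5))
  # ordering of levels on any input
  set.seed(2)
  p <- runif(5000)
  thr <- suppressWarnings(
    bootstrap_thresholds(p, B = 300, seed = 3))
  expect_lte(thr$cutoff[thr$level == 1e-4], thr$cutoff[thr$level == 1e-3])
  # determinism
  thr2 <- suppressWarnings(bootstrap_thresholds(p, B = 300, seed = 3))
  expect_identical(thr$cutoff, thr2$cutoff)
  # independent resampling oracle, same seed and RNG stream
  pg <- seq_len(10000) / 10000
  B <- 200
  thr3 <- bootstrap_thresholds(pg, levels = 0.001, B = B, seed = 11)
  set.seed(11)
  qs <- vapply(seq_len(B), function(b)
    quantile(pg[sample.int(10000, 10000, replace = TRUE)], 0.001,
             type = 7, names = FALSE), numeric(1))
  expect_equal(thr3$cutoff, mean(qs), tolerance = 1e-12)
  expect_gt(thr3$cutoff, 0.0005); expect_lt(thr3$cutoff, 0.002)
  expect_error(bootstrap_thresholds(p, levels = 1.2), "levels")
})

test_that("genome scans agree with the single-marker fits", {
  cfg <- small_cfg(seed = 14, n = c(25, 25), n_chr = 1, m = 60, miss = 0)
  pw <- panel_with_structure(cfg)
  y <- pw$pheno$adjusted
  k25 <- select_pcs(pw$pc, 0.25)
  cov25 <- pw$pc$scores[, seq_len(k25), drop = FALSE]
  sc <- assoc_scan(pw$g, y, "pc25", structure = pw$pc)
  j <- which.min(sc$p)
  one <- fit_marker_fixed(y, pw$g$dosage[, j], cov25)
  expect_equal(sc$p[j], one$p, tolerance = 1e-10)
  scl <- assoc_scan(pw$g, y, "kinship", kinship = pw$K)
  jl <- which.min(scl$p)
  onel <- fit_marker_lmm(y, pw$g$dosage[, jl], K = pw$K)
  expect_equal(scl$p[jl], onel$p, tolerance = 1e-8)
})
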