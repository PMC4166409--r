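test_that("stepwise selection honors entry gates and collinearity", {
  set.seed(41)
  n <- 80
  x <- 2 * rbinom(n, 1, 0.4)
  y <- 2.7 - 0.25 * x + rnorm(n, 0, 0.4)
  X <- cbind(m1 = x)
  sw <- stepwise_select(y, X)
  expect_equal(sw$selected, "m1")
  expect_equal(sw$r2_pct, 100 * summary(lm(y ~ x))$r.squared,
               tolerance = 1e-10)
  # duplicated marker can only enter once
  X2 <- cbind(m1 = x, m2 = x)
  sw2 <- stepwise_select(y, X2)
  expect_equal(length(sw2$selected), 1)
  # nothing qualifies -> empty result, not an error
  y0 <- rnorm(n)
  sw0 <- stepwise_select(y0, cbind(m1 = x))
  expect_length(sw0$selected, max(0, length(sw0$selected)))
  expect_true(all(sw0$final_p <= 0.05) || length(sw0$selected) == 0)
})

test_that("stepwise recovers orthogonal true predictors among nulls", {
  wins <- 0; extras <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    n <- 200
    X <- matrix(2 * rbinom(n * 8, 1, 0.5), n,
                dimnames = list(NULL, paste0("m", 1:8)))
    y <- 3 + 0.30 * X[, 1] - 0.28 * X[, 2] + 0.26 * X[, 3] + rnorm(n, 0, 0.4)
    sw <- stepwise_select(y, X)
    if (all(c("m1", "m2", "m3") %in% sw$selected)) wins <- wins + 1
    extras <- extras + length(setdiff(sw$selected, c("m1", "m2", "m3")))
  }
  expect_gte(wins, 18)       # >= 90% of 20 seeds recover all true markers
  expect_lt(extras / 20, 1)  # null markers enter at roughly the 0.05 gate
})

test_that("final stepwise model keeps every marker significant at the gate", {
  cfg <- small_cfg(seed = 17, n = c(60, 60), n_chr = 2, m = 400,
                   qtl = data.frame(chrom = c("Gm01", "Gm02"),
                                    pos = c(5e6, 1e7),
                                    effect = c(-0.3, 0.25),
                                    maf = c(0.4, 0.3)))
  pw <- panel_with_structure(cfg)
  sc <- assoc_scan(pw$g, pw$pheno$adjusted, "pc25+kinship",
                   structure = pw$pc, kinship = pw$K)
  cand <- sc$id[rank(sc$p) <= 12]
  sw <- stepwise_select(pw$pheno$adjusted,
                        pw$g$dosage[, cand, drop = FALSE])
  expect_gt(length(sw$selected), 0)
  expect_true(all(sw$final_p <= 0.05))
  # multiple R2 at least the best single-marker R2 among the selected
  singles <- vapply(sw$selected, function(id)
    summary(lm(pw$pheno$adjusted ~ pw$g$dosage[, id]))$r.squared * 100,
    numeric(1))
  expect_gte(sw$r2_pct + 1e-9, max(singles))
})

test_that("region delineation chains adjacent LD from the lead", {
  # four markers: strong LD m1-m2, m2-m3; m4 unlinked
  set.seed(61)
  n <- 60
  base <- 2 * rbinom(n, 1, 0.5)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- 2 - x[i]; x }
  d <- cbind(flip(base, 2), base, flip(base, 3), 2 * rbinom(n, 1, 0.5))
  g <- toy_geno(d, pos = c(100e3, 200e3, 300e3, 400e3))
  stopifnot(partial_r2(d[, 1], d[, 2]) > 0.6,
            partial_r2(d[, 2], d[, 3]) > 0.6,
            partial_r2(d[, 3], d[, 4]) < 0.6)
  r <- delineate_region(g, "Gm01_200000")
  expect_equal(c(r$start, r$end), c(100e3, 300e3))
  expect_equal(r$members, g$map$id[1:3])
  # lead in LD with neither neighbour -> single-marker region
  d2 <- cbind(2 * rbinom(n, 1, 0.5), base, 2 * rbinom(n, 1, 0.5))
  g2 <- toy_geno(d2, pos = c(1e5, 2e5, 3e5))
  r2 <- delineate_region(g2, "Gm01_200000")
  expect_equal(c(r2$start, r2$end), c(2e5, 2e5))
  # threshold 1.0 -> always single-marker
  r3 <- delineate_region(g, "Gm01_200000", r2_threshold = 1.0)
  expect_equal(r3$members, "Gm01_200000")
  # markers on other chromosomes are irrelevant
  g4 <- geno(cbind(d, 2 * rbinom(n, 1, 0.5)),
             rbind(g$map, data.frame(id = "Gm02_150000", chrom = "Gm02",
                                     pos = 150000L, ref = "A", alt = "G")))
  r4 <- delineate_region(g4, "Gm01_200000")
  expect_equal(r4$members, r$members)
  expect_error(delineate_region(g, "Gm01_999"), "not in the panel")
})

test_that("block merging applies the gap and non-LD-marker rules", {
  mk_block <- function(start, end, chrom = "Gm01")
    structure(list(chrom = chrom, start = start, end = end,
                   lead = marker_id(chrom, start),
                   members = marker_id(chrom, c(start, end))),
              class = "qtl_region")
  # panel provides positions: blocks [100k,300k], [305k,400k]; two
  # intervening markers at 301k, 303k
  pos <- c(100e3, 300e3, 301e3, 303e3, 305e3, 400e3)
  g <- toy_geno(matrix(2 * rbinom(6 * 30, 1, 0.5), 30), pos = pos)
  no_ld <- function(pos, block) FALSE
  b <- list(mk_block(100e3, 300e3), mk_block(305e3, 400e3))
  merged <- merge_blocks(b, g, in_ld = no_ld)
  expect_length(merged, 1)
  expect_equal(c(merged[[1]]$start, merged[[1]]$end), c(100e3, 400e3))
  # intervening markers join the merged block
  expect_true(all(marker_id("Gm01", c(301e3, 303e3)) %in%
                    merged[[1]]$members))
  # gap of 50 kb is too wide
  b2 <- list(mk_block(100e3, 300e3), mk_block(350e3, 400e3))
  g2 <- toy_geno(matrix(2 * rbinom(4 * 30, 1, 0.5), 30),
                 pos = c(100e3, 300e3, 350e3, 400e3))
  expect_length(merge_blocks(b2, g2, in_ld = no_ld), 2)
  # five non-LD markers between the blocks exceed the cap
  pos3 <- c(100e3, 300e3, 300.5e3, 301e3, 301.5e3, 302e3, 302.5e3, 305e3,
            400e3)
  g3 <- toy_geno(matrix(2 * rbinom(9 * 30, 1, 0.5), 30), pos = pos3)
  b3 <- list(mk_block(100e3, 300e3), mk_block(305e3, 400e3))
  expect_length(merge_blocks(b3, g3, in_ld = no_ld), 2)
  # idempotent at fixpoint and never shrinking coverage
  again <- merge_blocks(merged, g, in_ld = no_ld)
  expect_equal(again, merged)
})

test_that("gene overlap is any-intersection of closed intervals", {
  genes <- data.frame(
    id = c("inside", "before", "fre1_like"),
    chrom = c("Gm03", "Gm03", "Gm03"),
    start = c(45000000, 44700000, 44925730),
    end = c(45010000, 44797999, 44930360))
  region <- list(chrom = "Gm03", start = 44798000, end = 47140000)
  hit <- overlap_genes(region, genes)
  expect_setequal(hit, c("inside", "fre1_like"))
  expect_false("before" %in% hit)  # ends 1 bp before the region
})

test_that("epistasis scan enumerates unordered pairs and flags degeneracy", {
  set.seed(71)
  n <- 100
  X <- matrix(2 * rbinom(n * 33, 1, 0.5), n,
              dimnames = list(NULL, paste0("m", 1:33)))
  y <- rnorm(n)
  res <- epistasis_scan(y, X[, 1:2])
  expect_equal(nrow(res), 1)
  res33 <- epistasis_scan(y, X)
  expect_equal(nrow(res33), choose(33, 2))
  expect_equal(nrow(res33), 528)
  expect_false(any(duplicated(paste(res33$marker1, res33$marker2))))
  # collinear pair is degenerate with p = 1
  Xc <- cbind(m1 = X[, 1], m2 = X[, 1])
  resc <- epistasis_scan(y, Xc)
  expect_true(resc$degenerate[1])
  expect_equal(resc$p[1], 1)
})

test_that("allele combinations reproduce worked group statistics", {
  # two markers; combinations CG (n=2: 2.18, 2.34), CT (n=1: 2.4),
  # TG (n=2: 2.16, 2.66); one heterozygous and one missing sample excluded
  d <- rbind(c(0, 0), c(0, 0), c(0, 2), c(2, 0), c(2, 0), c(1, 0), c(0, NA))
  g <- toy_geno(d, ref = c("C", "G"), alt = c("T", "T"))
  y <- c(2.18, 2.34, 2.40, 2.16, 2.66, 3.0, 3.1)
  ac <- allele_combos(g, g$map$id, y)
  expect_equal(ac$n_excluded, 2)
  cg <- ac$combos[ac$combos$combo == "CG", ]
  expect_equal(cg$n, 2L)
  expect_equal(round(cg$mean, 2), 2.26)
  expect_equal(round(cg$sd, 2), 0.11)
  ct <- ac$combos[ac$combos$combo == "CT", ]
  expect_equal(round(ct$mean, 2), 2.40)
  expect_true(is.na(ct$sd))
  tg <- ac$combos[ac$combos$combo == "TG", ]
  expect_equal(round(tg$mean, 2), 2.41)
  expect_equal(round(tg$sd, 2), 0.35)
  # inclusive classification at the boundaries
  expect_equal(classify_tolerance(c(2.5, 2.51, 3.5, 3.0)),
               c("tolerant", "intermediate", "susceptible", "intermediate"))
  # classification soundness on arbitrary combos
  expect_true(all(ac$combos$mean[ac$combos$class == "tolerant"] <= 2.5))
  expect_true(all(ac$combos$mean[ac$combos$class == "susceptible"] >= 3.5))
  g_all_het <- toy_geno(matrix(1, 4, 2))
  expect_error(allele_combos(g_all_het, g_all_het$map$id, rnorm(4)),
               "no samples")
})
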