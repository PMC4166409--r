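#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one list. Either supply
#' input paths (`vcf`, `pheno`, and optionally `gff3` + `fasta` for
#' annotation) or a [sim_config()] in `simulate` to run on a synthetic
#' panel. Defaults mirror the analysis the package implements: MAF > 0.05,
#' 10,000 bootstraps at the 1e-4 / 1e-3 quantile levels, PC sets at 25% and
#' 50% cumulative variance, LD chain threshold r2 > 0.6, 10-kb / 4-marker
#' block merging, epistasis gate 1e-3, tolerance thresholds 2.5 / 3.5.
#'
#' @param vcf,pheno,gff3,fasta,candidate_genes input paths (optional)
#' @param simulate optional [sim_config()] used instead of file inputs
#' @param maf_cutoff MAF filter cutoff
#' @param model one of [assoc_models()] or `"auto"` (rank-MSD selection)
#' @param boot_B bootstrap resample count
#' @param boot_levels quantile levels of the empirical p-value distribution
#' @param pc_thresholds cumulative-variance thresholds for the PC sets
#' @param ld_r2 LD chain threshold
#' @param merge_gap_bp,max_nonld_markers block-merge rule parameters
#' @param epistasis_alpha interaction significance gate
#' @param combo_low,combo_high tolerance classification thresholds
#' @param seed integer seed driving every stochastic stage
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(vcf = NULL, pheno = NULL, gff3 = NULL,
                            fasta = NULL, candidate_genes = NULL,
                            simulate = NULL, maf_cutoff = 0.05,
                            model = "auto", boot_B = 10000,
                            boot_levels = c(1e-4, 1e-3),
                            pc_thresholds = c(0.25, 0.50), ld_r2 = 0.6,
                            merge_gap_bp = 10000, max_nonld_markers = 4,
                            epistasis_alpha = 1e-3, combo_low = 2.5,
                            combo_high = 3.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(maf_cutoff >= 0, maf_cutoff <= 0.5,
            model %in% c("auto", assoc_models()),
            boot_B >= 1, all(boot_levels > 0 & boot_levels < 1),
            all(pc_thresholds > 0 & pc_thresholds < 1),
            ld_r2 > 0, ld_r2 <= 1, merge_gap_bp >= 0,
            max_nonld_markers >= 0, epistasis_alpha > 0,
            combo_low < combo_high)
  cfg$seed <- as.integer(seed)
  if (is.null(cfg$simulate) && (is.null(cfg$vcf) || is.null(cfg$pheno)))
    stop("either `simulate` or both `vcf` and `pheno` must be given")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys are [pipeline_config()] arguments (a
#'   `simulate` block is passed to [sim_config()])
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

.cfg_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

.write_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# idcqtl ", as.character(utils::packageVersion("idcqtl")),
                    " seed=", cfg$seed, " config=", .cfg_hash(cfg)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full GWAS-to-QTL pipeline
#'
#' Executes the stages in dependency order — input (or simulation), MAF
#' filter, mode imputation, phenotype adjustment, structure (PCA, kinship,
#' Gower), association under the requested model (or all six with rank-MSD
#' auto-selection), bootstrap percentile thresholds, stepwise selection
#' over the markers significant at the upper level, LD-chained QTL regions
#' with block merging, candidate-gene overlap (when gene models are
#' available), all-pairs epistasis among significant markers, allelic
#' combinations over the stepwise markers, LD decay (raw and
#' structure-corrected), and optional variant annotation — and writes every
#' result table (TSV with a provenance header) plus `log.txt` and
#' `results.json` into `out_dir`. A rerun with identical config and seed is
#' byte-identical.
#'
#' @param cfg a [pipeline_config()]
#' @param out_dir output directory (created)
#' @return invisibly, a list with all in-memory stage results
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  say <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  say("idcqtl pipeline, seed=", cfg$seed, ", config=", .cfg_hash(cfg))

  # --- input ---
  if (!is.null(cfg$simulate)) {
    sim <- simulate_population(
      cfg$simulate,
      seqs = if (!is.null(cfg$fasta)) read_fasta(cfg$fasta) else NULL)
    g <- sim$geno; pheno <- sim$pheno
    .write_tsv(sim$truth, file.path(out_dir, "truth.tsv"), cfg)
  } else {
    sim <- NULL
    g <- read_vcf_geno(cfg$vcf)
    pheno <- read_phenotypes(cfg$pheno)
  }
  pheno <- pheno[match(rownames(g$dosage), pheno$sample), , drop = FALSE]
  if (anyNA(pheno$sample)) stop("stage input: phenotype/genotype sample mismatch")
  say("markers in: ", ncol(g$dosage), "; samples: ", nrow(g$dosage))

  # --- filter + impute + adjust ---
  g <- filter_maf(g, cfg$maf_cutoff)
  say("markers surviving MAF>", cfg$maf_cutoff, ": ", ncol(g$dosage))
  g <- impute_mode(g)
  pheno <- adjust_phenotype(pheno)
  y <- pheno$adjusted
  y_raw <- pheno$idc_score

  # --- structure ---
  pc <- geno_pca(g)
  K <- kinship_centered(g)
  S <- gower_similarity(g)
  k25 <- select_pcs(pc, cfg$pc_thresholds[1])
  k50 <- select_pcs(pc, cfg$pc_thresholds[2])
  say("PC sets: ", k25, " PCs at ", cfg$pc_thresholds[1] * 100, "%, ",
      k50, " PCs at ", cfg$pc_thresholds[2] * 100, "%")
  scree <- data.frame(component = seq_along(pc$var_frac),
                      var_frac = pc$var_frac)
  .write_tsv(scree, file.path(out_dir, "scree.tsv"), cfg)
  .write_tsv(data.frame(sample = rownames(pc$scores),
                        pc$scores[, seq_len(min(20, ncol(pc$scores))),
                                  drop = FALSE]),
             file.path(out_dir, "pcs.tsv"), cfg)
  utils::write.table(round(K, 6), file.path(out_dir, "kinship.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(round(S, 6), file.path(out_dir, "gower.tsv"),
                     sep = "\t", quote = FALSE)

  # --- association + model selection ---
  cov25 <- pc$scores[, seq_len(k25), drop = FALSE]
  if (cfg$model == "auto") {
    scans <- lapply(assoc_models(), function(m)
      assoc_scan(g, y, m, structure = pc, kinship = K,
                 pc_thresholds = cfg$pc_thresholds))
    names(scans) <- assoc_models()
    sel <- msd_select(lapply(scans, `[[`, "p"))
    .write_tsv(sel$table, file.path(out_dir, "msd.tsv"), cfg)
    model <- sel$selected
    scan <- scans[[model]]
  } else {
    model <- cfg$model
    scan <- assoc_scan(g, y, model, structure = pc, kinship = K,
                       pc_thresholds = cfg$pc_thresholds)
  }
  say("association model: ", model)
  tab <- assoc_table(g, y, y_raw, model = model, structure = pc,
                     kinship = K, pc_thresholds = cfg$pc_thresholds)
  .write_tsv(tab, file.path(out_dir, "assoc.tsv"), cfg)
  .write_tsv(tab[c("chrom", "pos", "neglog10p")],
             file.path(out_dir, "manhattan.tsv"), cfg)
  m <- length(scan$p)
  qq <- data.frame(expected = -log10(seq_len(m) / (m + 1)),
                   observed = -log10(sort(scan$p)))
  .write_tsv(qq, file.path(out_dir, "qq.tsv"), cfg)

  # --- thresholds + significant markers ---
  thr <- bootstrap_thresholds(scan$p, levels = cfg$boot_levels,
                              B = cfg$boot_B, seed = cfg$seed)
  sig_hi <- scan$id[scan$p <= thr$cutoff[1]]           # 0.01 percentile
  sig_lo <- scan$id[scan$p <= thr$cutoff[nrow(thr)]]   # 0.1 percentile
  say("significant at levels (", paste(thr$level, collapse = ", "), "): ",
      length(sig_hi), ", ", length(sig_lo))

  # --- stepwise ---
  sw <- if (length(sig_lo) >= 1) {
    stepwise_select(y, g$dosage[, sig_lo, drop = FALSE])
  } else list(selected = character(0), steps = NULL, r2_pct = 0)
  say("stepwise markers: ", length(sw$selected),
      "; multiple R2 = ", round(sw$r2_pct, 1), "%")

  # --- QTL regions ---
  regions <- lapply(sw$selected, function(id)
    delineate_region(g, id, covariates = cov25, r2_threshold = cfg$ld_r2))
  if (length(regions)) {
    by_chr <- split(regions,
                    vapply(regions, `[[`, character(1), "chrom"))
    regions <- unlist(lapply(by_chr, function(bl)
      merge_blocks(bl, g, covariates = cov25, gap_bp = cfg$merge_gap_bp,
                   max_nonld_markers = cfg$max_nonld_markers,
                   r2_threshold = cfg$ld_r2)), recursive = FALSE)
  }
  genes <- if (!is.null(cfg$gff3)) read_gff3(cfg$gff3) else NULL
  if (!is.null(genes) && !is.null(cfg$candidate_genes)) {
    cand <- utils::read.delim(cfg$candidate_genes, stringsAsFactors = FALSE)
    genes <- genes[genes$type != "gene" | genes$ID %in% cand[[1]], ,
                   drop = FALSE]
  }
  reg_df <- if (length(regions)) do.call(rbind, lapply(regions, function(r)
    data.frame(chrom = r$chrom, start = r$start, end = r$end, lead = r$lead,
               n_markers = length(r$members),
               members = paste(r$members, collapse = ";"),
               genes = if (is.null(genes)) "" else
                 paste(overlap_genes(r, genes), collapse = ";"),
               stringsAsFactors = FALSE)))
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  lead = character(), n_markers = integer(),
                  members = character(), genes = character())
  .write_tsv(reg_df, file.path(out_dir, "qtl_regions.tsv"), cfg)
  if (nrow(reg_df)) {
    bed <- data.frame(chrom = reg_df$chrom, start = reg_df$start - 1L,
                      end = reg_df$end, name = reg_df$lead)
    utils::write.table(bed, file.path(out_dir, "qtl_regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  say("QTL regions: ", nrow(reg_df))

  # --- epistasis ---
  epi <- if (length(sig_lo) >= 2) {
    epistasis_scan(y, g$dosage[, sig_lo, drop = FALSE],
                   covariates = cov25, alpha = cfg$epistasis_alpha)
  } else NULL
  if (!is.null(epi)) {
    .write_tsv(epi, file.path(out_dir, "epistasis.tsv"), cfg)
    say("epistasis pairs tested: ", nrow(epi), "; significant: ",
        sum(epi$significant))
  }

  # --- allelic combinations ---
  combos <- if (length(sw$selected) >= 1) {
    allele_combos(g, sw$selected, y_raw,
                  t_low = cfg$combo_low, t_high = cfg$combo_high)
  } else NULL
  if (!is.null(combos))
    .write_tsv(combos$combos, file.path(out_dir, "allele_combos.tsv"), cfg)

  # --- LD decay ---
  pairs <- sample_pairs(g, max_pairs = 5000, max_distance = 1e7,
                        seed = cfg$seed)
  decay <- NULL
  if (nrow(pairs) >= 10) {
    raw <- ld_pairs_r2(g, pairs)
    part <- ld_pairs_r2(g, pairs, covariates = cov25)
    pairs$r2_raw <- raw$r2
    pairs$r2_partial <- part$r2
    .write_tsv(pairs, file.path(out_dir, "ld_pairs.tsv"), cfg)
    part$r2 <- part$r2
    decay <- tryCatch(fit_decay(part, n = nrow(g$dosage)),
                      error = function(e) NULL)
  }

  # --- annotation ---
  annot <- NULL
  if (!is.null(cfg$gff3) && !is.null(cfg$fasta)) {
    feats <- read_gff3(cfg$gff3)
    seqs <- read_fasta(cfg$fasta)
    sig_g <- subset_geno(g, markers = match(sig_lo, g$map$id))
    annot <- annotate_sites(sig_g, feats, seqs)
    .write_tsv(annot, file.path(out_dir, "annotation.tsv"), cfg)
  }

  results <- list(
    model = model,
    thresholds = as.list(stats::setNames(thr$cutoff,
                                         paste0("level_", thr$level))),
    n_markers = ncol(g$dosage),
    n_significant = stats::setNames(as.list(c(length(sig_hi),
                                              length(sig_lo))),
                                    paste0("level_", thr$level)),
    stepwise = list(selected = sw$selected, r2_pct = sw$r2_pct),
    n_regions = nrow(reg_df),
    epistasis = if (is.null(epi)) NULL else
      list(pairs = nrow(epi), significant = sum(epi$significant)),
    decay_rho = if (is.null(decay)) NULL else decay$rho
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(geno = g, pheno = pheno, pca = pc, kinship = K, gower = S,
                 scan = scan, table = tab, thresholds = thr,
                 sig_01 = sig_hi, sig_1 = sig_lo, stepwise = sw,
                 regions = regions, epistasis = epi, combos = combos,
                 decay = decay, annotation = annot, sim = sim,
                 results = results))
}
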