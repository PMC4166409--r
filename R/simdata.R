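#' Additive-effect profile of the eight stepwise IDC lead markers
#'
#' The default planted-QTL profile for the simulator: eight markers on eight
#' chromosomes with signed additive effects (IDC units per variant-allele
#' copy relative to the homozygote midpoint) between 0.08 and 0.19 in
#' magnitude and variant-allele frequencies between 0.07 and 0.46 — the
#' effect architecture of a polygenic visual-score trait in an advanced
#' breeding panel.
#'
#' @return data.frame with columns `chrom`, `pos`, `effect`, `maf`
#' @export
idc_qtl_profile <- function() {
  data.frame(
    chrom = c("Gm03", "Gm05", "Gm07", "Gm11", "Gm16", "Gm17", "Gm18", "Gm19"),
    pos = c(45031929L, 8877264L, 6397319L, 530116L, 27300116L, 25859992L,
            28141888L, 40193564L),
    effect = c(-0.19, 0.13, -0.16, 0.18, 0.18, 0.08, 0.11, -0.18),
    maf = c(0.3889, 0.4593, 0.2556, 0.0889, 0.0852, 0.0667, 0.2259, 0.4407),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a two-subpopulation breeding panel
#'
#' Defaults emulate the study panel the pipeline targets: two advanced
#' breeding subpopulations of 132 and 138 inbred lines, 20 chromosomes,
#' ~34,000 markers, strong relatedness from small founder pools, block LD
#' from a haplotype-copying process, a grand IDC mean of 2.76 on the 1-5
#' visual scale, and the eight-marker additive profile of
#' [idc_qtl_profile()].
#'
#' @param seed integer RNG seed (all randomness flows from it)
#' @param n_per_subpop sizes of the two subpopulations
#' @param n_chromosomes number of chromosomes (named Gm01, Gm02, ...)
#' @param chrom_length_bp length of each chromosome
#' @param n_markers total background marker count across the genome
#' @param founder_haplotypes_per_subpop founder pool size per subpopulation;
#'   pools are disjoint between subpopulations
#' @param copy_switch_rate_per_bp per-bp probability of switching founder
#'   template along a chromosome; smaller values give longer LD blocks
#' @param maf_floor lower bound of the ancestral allele-frequency draw
#' @param missing_rate fraction of genotype calls masked as missing
#' @param qtl_spec data.frame (`chrom`, `pos`, `effect`, optional `maf`) of
#'   planted additive QTL; positions absent from the random marker map are
#'   added to it. `NULL` for a null panel.
#' @param subpop_shift IDC units added to the second subpopulation
#' @param fst Balding-Nichols divergence of subpopulation allele frequencies
#' @param residual_sd residual standard deviation, IDC units
#' @param baseline grand IDC mean
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_per_subpop = c(132L, 138L),
                       n_chromosomes = 20L,
                       chrom_length_bp = 5e7,
                       n_markers = 34000L,
                       founder_haplotypes_per_subpop = 8L,
                       copy_switch_rate_per_bp = 1e-7,
                       maf_floor = 0.05,
                       missing_rate = 0.02,
                       qtl_spec = idc_qtl_profile(),
                       subpop_shift = 0.15,
                       fst = 0.15,
                       residual_sd = 0.30,
                       baseline = 2.76) {
  cfg <- list(seed = as.integer(seed), n_per_subpop = as.integer(n_per_subpop),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_markers = as.integer(n_markers),
              founder_haplotypes_per_subpop =
                as.integer(founder_haplotypes_per_subpop),
              copy_switch_rate_per_bp = copy_switch_rate_per_bp,
              maf_floor = maf_floor, missing_rate = missing_rate,
              qtl_spec = qtl_spec, subpop_shift = subpop_shift, fst = fst,
              residual_sd = residual_sd, baseline = baseline)
  stopifnot(length(cfg$n_per_subpop) == 2, all(cfg$n_per_subpop >= 1),
            cfg$n_chromosomes >= 1, cfg$chrom_length_bp >= 1000,
            cfg$n_markers >= cfg$n_chromosomes,
            cfg$founder_haplotypes_per_subpop >= 2,
            cfg$copy_switch_rate_per_bp >= 0, cfg$copy_switch_rate_per_bp <= 1,
            cfg$maf_floor >= 0, cfg$maf_floor < 0.5,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$fst >= 0, cfg$fst < 1,
            cfg$residual_sd >= 0, is.finite(cfg$baseline))
  if (!is.null(cfg$qtl_spec)) {
    q <- cfg$qtl_spec
    stopifnot(is.data.frame(q), all(c("chrom", "pos", "effect") %in% names(q)))
    if (!all(is.finite(q$effect))) stop("qtl effects must be finite")
    chroms <- sprintf("Gm%02d", seq_len(cfg$n_chromosomes))
    bad <- !(q$chrom %in% chroms)
    if (any(bad))
      stop("qtl on unknown chromosome: ", paste(q$chrom[bad], collapse = ", "))
    if (any(q$pos < 1 | q$pos > cfg$chrom_length_bp))
      stop("qtl position outside [1, chrom_length_bp]")
    if (any(duplicated(paste(q$chrom, q$pos))))
      stop("duplicated qtl positions in qtl_spec")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a two-subpopulation inbred breeding panel
#'
#' Genotypes arise from a haplotype-copying (mosaic) process: each inbred
#' line copies along each chromosome from one founder haplotype of its
#' subpopulation's pool, switching template with per-bp probability
#' `copy_switch_rate_per_bp`. This produces tunable block LD that decays
#' with distance, strong relatedness (small founder pools), and
#' subpopulation structure (disjoint pools with Balding-Nichols-diverged
#' allele frequencies). Lines are fully inbred: dosages are 0 or 2 before
#' missingness masking. Phenotype:
#' `baseline + subpop_shift * I(subpop 2) + sum_i effect_i * (dosage_i - 1)
#'  + Normal(0, residual_sd)`, clipped to the 1-5 visual scale (the number
#' of clipped scores is recorded in the `n_clipped` attribute).
#' Identical seeds give byte-identical output.
#'
#' @param config a [sim_config()]
#' @param seqs optional named character vector of reference sequences (e.g.
#'   from [simulate_annotation()]); when given, marker reference alleles are
#'   anchored to the reference base so the panel can be annotated against it
#' @return list with `geno` ([geno()] object, planted markers included),
#'   `pheno` (data.frame `sample`, `population`, `idc_score`), and `truth`
#'   (data.frame `id`, `chrom`, `pos`, `effect`, `freq_pop1`, `freq_pop2`
#'   of realized variant-allele frequencies; one row per planted QTL)
#' @export
simulate_population <- function(config, seqs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("Gm%02d", seq_len(config$n_chromosomes))
  L <- config$chrom_length_bp
  H <- config$founder_haplotypes_per_subpop
  n1 <- config$n_per_subpop[1]; n2 <- config$n_per_subpop[2]
  n <- n1 + n2
  per <- rep(config$n_markers %/% config$n_chromosomes, config$n_chromosomes)
  extra <- config$n_markers %% config$n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L

  q <- config$qtl_spec
  map_list <- vector("list", config$n_chromosomes)
  dos_list <- vector("list", config$n_chromosomes)
  gval <- numeric(n)
  truth <- list()
  pop <- rep(c("pop1", "pop2"), c(n1, n2))
  ids <- c(sprintf("pop1_%03d", seq_len(n1)), sprintf("pop2_%03d", seq_len(n2)))

  for (ci in seq_len(config$n_chromosomes)) {
    ch <- chroms[ci]
    pos <- sort(sample.int(L, per[ci]))
    qrows <- if (is.null(q)) integer(0) else which(q$chrom == ch)
    qpos <- if (length(qrows)) as.integer(q$pos[qrows]) else integer(0)
    pos <- sort(unique(c(pos, qpos)))
    M <- length(pos)
    is_q <- pos %in% qpos

    # ancestral and subpopulation variant-allele frequencies. Frequencies of
    # tightly linked markers are correlated in real haplotype blocks, so the
    # ancestral series follows the same AR(1) latent as the founder alleles;
    # each subpopulation perturbs it by an independent AR(1) stream scaled
    # by fst (drift divergence).
    ar0 <- exp(-config$copy_switch_rate_per_bp * diff(pos))
    ar1 <- function() {
      z <- stats::rnorm(M)
      if (M > 1) for (j in 2:M)
        z[j] <- ar0[j - 1] * z[j - 1] + sqrt(1 - ar0[j - 1]^2) * z[j]
      z
    }
    w0 <- ar1()
    to_p <- function(w) config$maf_floor +
      (1 - 2 * config$maf_floor) * stats::pnorm(w)
    if (config$fst > 0) {
      sq <- sqrt(1 - config$fst); sf <- sqrt(config$fst)
      pA <- to_p(sq * w0 + sf * ar1())
      pB <- to_p(sq * w0 + sf * ar1())
    } else {
      pA <- pB <- to_p(w0)
    }
    if (length(qrows)) {
      tgt <- if ("maf" %in% names(q)) q$maf[qrows] else rep(0.3, length(qrows))
      qi <- match(qpos, pos)
      pA[qi] <- tgt; pB[qi] <- tgt
    }

    # founder pools: disjoint per subpop. Alleles come from a latent AR(1)
    # (Gaussian copula) along the chromosome so the pools themselves carry
    # block LD whose extent the copy-switch rate controls; thresholding
    # preserves the marginal allele frequencies.
    ar <- exp(-config$copy_switch_rate_per_bp * diff(pos))
    pool <- function(pv) {
      Z <- matrix(stats::rnorm(M * H), nrow = M)
      if (M > 1) for (j in 2:M)
        Z[j, ] <- ar[j - 1] * Z[j - 1, ] +
          sqrt(1 - ar[j - 1]^2) * Z[j, ]
      FF <- (Z < stats::qnorm(pv)) * 1L
      list(F = FF, Z = Z)
    }
    plant <- function(pl, qi, pv) {
      # planted markers: exact carrier counts among the most-negative latent
      # values, keeping both the target frequency and the local LD
      for (k in seq_along(qi)) {
        cnt <- min(max(round(pv[qi[k]] * H), 1L), H - 1L)
        row <- rep(0L, H)
        row[order(pl$Z[qi[k], ])[seq_len(cnt)]] <- 1L
        pl$F[qi[k], ] <- row
      }
      pl$F
    }
    pa <- pool(pA); pb <- pool(pB)
    FA <- pa$F; FB <- pb$F
    if (length(qrows)) {
      qi <- match(qpos, pos)
      FA <- plant(pa, qi, pA)
      FB <- plant(pb, qi, pB)
    }

    # mosaic copying per line
    qsw <- -expm1(-config$copy_switch_rate_per_bp * diff(pos))
    d <- matrix(0L, nrow = n, ncol = M)
    for (i in seq_len(n)) {
      Fp <- if (pop[i] == "pop1") FA else FB
      if (M == 1) {
        seg <- 1L
      } else {
        sw <- stats::runif(M - 1) < qsw
        seg <- cumsum(c(1L, sw))
      }
      path <- sample.int(H, seg[M], replace = TRUE)[seg]
      d[i, ] <- 2L * Fp[cbind(seq_len(M), path)]
    }

    if (length(qrows)) {
      qi <- match(qpos, pos)
      for (k in seq_along(qi))
        gval <- gval + q$effect[qrows[k]] * (d[, qi[k]] - 1)
      truth[[ch]] <- data.frame(
        id = marker_id(ch, qpos), chrom = ch, pos = qpos,
        effect = q$effect[qrows],
        freq_pop1 = colMeans(d[pop == "pop1", qi, drop = FALSE]) / 2,
        freq_pop2 = colMeans(d[pop == "pop2", qi, drop = FALSE]) / 2,
        stringsAsFactors = FALSE
      )
    }

    if (!is.null(seqs) && ch %in% names(seqs)) {
      if (nchar(seqs[[ch]]) < max(pos))
        stop("reference sequence for ", ch, " shorter than marker positions")
      ref <- toupper(substring(seqs[[ch]], pos, pos))
    } else {
      ref <- sample(c("A", "C", "G", "T"), M, replace = TRUE)
    }
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    map_list[[ci]] <- data.frame(id = marker_id(ch, pos), chrom = ch,
                                 pos = pos, ref = ref, alt = unname(alt),
                                 stringsAsFactors = FALSE)
    dos_list[[ci]] <- d
  }

  dosage <- do.call(cbind, dos_list)
  map <- do.call(rbind, map_list)
  rownames(dosage) <- ids

  # phenotype from pre-missingness genotypes
  noise <- if (config$residual_sd > 0) {
    stats::rnorm(n, 0, config$residual_sd)
  } else numeric(n)
  y <- config$baseline + config$subpop_shift * (pop == "pop2") + gval + noise
  n_clipped <- sum(y < 1 | y > 5)
  y <- pmin(pmax(y, 1), 5)

  if (config$missing_rate > 0) {
    mask <- stats::runif(length(dosage)) < config$missing_rate
    dosage[mask] <- NA_integer_
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(), chrom = character(), pos = integer(),
               effect = numeric(), freq_pop1 = numeric(),
               freq_pop2 = numeric(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  pheno <- data.frame(sample = ids, population = pop, idc_score = y,
                      stringsAsFactors = FALSE)
  out <- list(geno = geno(dosage, map), pheno = pheno, truth = truth)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Write a simulated panel to standard files
#'
#' Emits `genotypes.vcf` (VCF v4.2), `phenotypes.tsv` and `truth.tsv`
#' into a directory.
#'
#' @param sim a [simulate_population()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf_geno(sim$geno, file.path(dir, "genotypes.vcf"))
  utils::write.table(sim$pheno, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# codons that do not terminate translation
.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Simulate a reference sequence with clean gene models
#'
#' Builds a random reference and, per chromosome, `genes_per_chrom`
#' non-overlapping genes with 5'UTR, multi-exon CDS (length divisible by 3,
#' ATG start, single terminal stop, no internal stops) and 3'UTR, on
#' alternating strands. CDS bases are written into the reference so every
#' gene translates cleanly. Intended as an annotation fixture; use a config
#' with compact chromosomes (the annotator only needs local codon context).
#'
#' @param config a [sim_config()] (chromosome count/length and seed are used)
#' @param genes_per_chrom genes per chromosome, >= 1
#' @return list with `seq` (named character vector of chromosome sequences)
#'   and `features` (GFF3-style data.frame: `seqid`, `type`, `start`, `end`,
#'   `strand`, `phase`, `ID`, `Parent`)
#' @export
simulate_annotation <- function(config, genes_per_chrom = 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (genes_per_chrom < 1) stop("genes_per_chrom must be >= 1")
  set.seed(config$seed)
  chroms <- sprintf("Gm%02d", seq_len(config$n_chromosomes))
  L <- as.integer(config$chrom_length_bp)
  slot <- L %/% genes_per_chrom
  if (slot < 2500)
    stop("chromosome too short for ", genes_per_chrom, " genes (need >= ",
         2500 * genes_per_chrom, " bp)")
  sense <- .sense_codons()
  seqs <- character(length(chroms))
  names(seqs) <- chroms
  feats <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (gk in seq_len(genes_per_chrom)) {
      gid <- gid + 1L
      strand <- if (gid %% 2L == 1L) "+" else "-"
      utr5 <- sample(60:120, 1); utr3 <- sample(60:120, 1)
      n_ex <- sample(2:3, 1)
      n_codons <- sample(60:150, 1)
      cds_len <- 3L * n_codons
      introns <- sample(60:150, n_ex - 1, replace = TRUE)
      # split CDS into n_ex pieces of >= 10 bp (not necessarily codon-aligned)
      cuts <- sort(sample(seq(10L, cds_len - 10L), n_ex - 1))
      piece <- diff(c(0L, cuts, cds_len))
      span <- utr5 + cds_len + sum(introns) + utr3
      slot_start <- (gk - 1L) * slot + 1L
      gstart <- slot_start + sample.int(max(slot - span - 200L, 1L), 1)
      cds_seq <- c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA")
      cds_chars <- strsplit(paste(cds_seq, collapse = ""), "")[[1]]

      # genomic blocks left-to-right
      if (strand == "+") {
        blocks <- list(c("five_prime_UTR", utr5))
        for (e in seq_len(n_ex)) {
          blocks <- c(blocks, list(c("CDS", piece[e])))
          if (e < n_ex) blocks <- c(blocks, list(c("intron", introns[e])))
        }
        blocks <- c(blocks, list(c("three_prime_UTR", utr3)))
        genomic_cds <- cds_chars
      } else {
        blocks <- list(c("three_prime_UTR", utr3))
        for (e in rev(seq_len(n_ex))) {
          blocks <- c(blocks, list(c("CDS", piece[e])))
          if (e > 1) blocks <- c(blocks, list(c("intron", introns[e - 1])))
        }
        blocks <- c(blocks, list(c("five_prime_UTR", utr5)))
        genomic_cds <- rev(chartr("ACGT", "TGCA", cds_chars))
      }

      gene_id <- sprintf("Sim%sg%04d", sub("^Gm", "", ch), gid)
      mrna_id <- paste0(gene_id, ".1")
      cur <- gstart
      cds_done <- 0L
      rows <- list()
      for (bl in blocks) {
        w <- as.integer(bl[2]); b_end <- cur + w - 1L
        if (bl[1] == "CDS") {
          s[cur:b_end] <- genomic_cds[(cds_done + 1L):(cds_done + w)]
          cds_done <- cds_done + w
        }
        rows <- c(rows, list(data.frame(
          seqid = ch, type = bl[1], start = cur, end = b_end,
          strand = strand, phase = NA_integer_, ID = NA_character_,
          Parent = mrna_id, stringsAsFactors = FALSE)))
        cur <- b_end + 1L
      }
      body <- do.call(rbind, rows)
      # exon features: transcribed blocks (adjacent non-intron blocks merged)
      tr <- body[body$type != "intron", , drop = FALSE]
      ex <- list()
      es <- tr$start[1]; ee <- tr$end[1]
      for (r in seq_len(nrow(tr))[-1]) {
        if (tr$start[r] == ee + 1L) ee <- tr$end[r]
        else { ex <- c(ex, list(c(es, ee))); es <- tr$start[r]; ee <- tr$end[r] }
      }
      ex <- c(ex, list(c(es, ee)))
      exons <- do.call(rbind, lapply(ex, function(z) data.frame(
        seqid = ch, type = "exon", start = z[1], end = z[2],
        strand = strand, phase = NA_integer_, ID = NA_character_,
        Parent = mrna_id, stringsAsFactors = FALSE)))
      body <- rbind(body, exons)
      body <- body[order(body$start, body$end), , drop = FALSE]
      # CDS phase in transcript order
      cds_i <- which(body$type == "CDS")
      tord <- if (strand == "+") cds_i else rev(cds_i)
      before <- cumsum(c(0L, body$end[tord] - body$start[tord] + 1L))
      body$phase[tord] <- (3L - before[seq_along(tord)] %% 3L) %% 3L
      gend <- cur - 1L
      head <- data.frame(
        seqid = ch, type = c("gene", "mRNA"), start = gstart, end = gend,
        strand = strand, phase = NA_integer_,
        ID = c(gene_id, mrna_id), Parent = c(NA_character_, gene_id),
        stringsAsFactors = FALSE)
      feats[[length(feats) + 1L]] <- rbind(head, body)
    }
    seqs[ch] <- paste(s, collapse = "")
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  list(seq = seqs, features = features)
}
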