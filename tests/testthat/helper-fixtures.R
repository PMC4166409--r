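# Shared fixtures, built in code at test time.

# small structured panel: 2 subpopulations, block LD, optional planted QTL
small_cfg <- function(seed = 1, n = c(60, 60), n_chr = 4, m = 1200,
                      qtl = NULL, miss = 0.02, shift = 0.15, fst = 0.15,
                      resid = 0.30, rate = 1e-7) {
  sim_config(seed = seed, n_per_subpop = n, n_chromosomes = n_chr,
             chrom_length_bp = 2e7, n_markers = m,
             copy_switch_rate_per_bp = rate, missing_rate = miss,
             qtl_spec = qtl, subpop_shift = shift, fst = fst,
             residual_sd = resid)
}

# imputed, MAF-filtered panel plus structure pieces, for reuse within a file
panel_with_structure <- function(cfg) {
  sim <- simulate_population(cfg)
  g <- impute_mode(filter_maf(sim$geno, 0.05))
  pc <- geno_pca(g)
  K <- kinship_centered(g)
  ph <- adjust_phenotype(sim$pheno)
  list(sim = sim, g = g, pc = pc, K = K, pheno = ph)
}

# build a geno object directly from a dosage matrix (markers get sequential
# positions on one chromosome unless a map is given)
toy_geno <- function(dosage, chrom = "Gm01", pos = NULL, ref = NULL,
                     alt = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  geno(dosage, data.frame(id = marker_id(chrom, pos), chrom = chrom,
                          pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE))
}

# minimal single-gene fixture for the annotator: one plus-strand gene with
# utr5 / two CDS exons split by an intron / utr3, CDS supplied as codons
plus_gene_fixture <- function(codons, chrom = "Gm01",
                              utr5 = 12L, intron = 30L, utr3 = 12L,
                              lead_pad = 50L, tail_pad = 50L, seed = 42L,
                              cut = NULL) {
  set.seed(seed)
  cds <- paste(codons, collapse = "")
  stopifnot(nchar(cds) %% 3 == 0)
  if (is.null(cut)) cut <- (nchar(cds) %/% 2) - (nchar(cds) %/% 2) %% 1L
  cds1 <- substr(cds, 1, cut); cds2 <- substr(cds, cut + 1, nchar(cds))
  pieces <- c(paste(sample(c("A", "C", "G", "T"), lead_pad, TRUE),
                    collapse = ""),
              paste(sample(c("A", "C", "G", "T"), utr5, TRUE), collapse = ""),
              cds1,
              paste(sample(c("A", "C", "G", "T"), intron, TRUE),
                    collapse = ""),
              cds2,
              paste(sample(c("A", "C", "G", "T"), utr3, TRUE), collapse = ""),
              paste(sample(c("A", "C", "G", "T"), tail_pad, TRUE),
                    collapse = ""))
  len <- nchar(pieces)
  start <- cumsum(c(1, len[-length(len)]))
  end <- start + len - 1
  seqs <- stats::setNames(paste(pieces, collapse = ""), chrom)
  f <- function(type, i, phase = NA_integer_, id = NA_character_,
                parent = "g1.1")
    data.frame(seqid = chrom, type = type, start = start[i], end = end[i],
               strand = "+", phase = phase, ID = id, Parent = parent,
               stringsAsFactors = FALSE)
  feats <- rbind(
    data.frame(seqid = chrom, type = "gene", start = start[2], end = end[6],
               strand = "+", phase = NA_integer_, ID = "g1",
               Parent = NA_character_, stringsAsFactors = FALSE),
    data.frame(seqid = chrom, type = "mRNA", start = start[2], end = end[6],
               strand = "+", phase = NA_integer_, ID = "g1.1",
               Parent = "g1", stringsAsFactors = FALSE),
    f("five_prime_UTR", 2),
    f("CDS", 3, phase = 0L),
    f("intron", 4),
    f("CDS", 5, phase = (3L - nchar(cds1) %% 3L) %% 3L),
    f("three_prime_UTR", 6),
    data.frame(seqid = chrom, type = "exon",
               start = c(start[2], start[5]), end = c(end[3], end[6]),
               strand = "+", phase = NA_integer_, ID = NA_character_,
               Parent = "g1.1", stringsAsFactors = FALSE)
  )
  list(seqs = seqs, features = feats,
       cds_start = start[3], cds1_end = end[3], cds2_start = start[5],
       cut = cut)
}

# mirror a plus-strand fixture: reverse-complement the chromosome and flip
# every feature interval and strand, so the same biology sits on the minus
# strand; a site at position p maps to L - p + 1 with complemented alleles
mirror_fixture <- function(fix) {
  L <- nchar(fix$seqs[[1]])
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", fix$seqs[[1]]),
                           "")[[1]]), collapse = "")
  fe <- fix$features
  news <- L - fe$end + 1L
  newe <- L - fe$start + 1L
  fe$start <- news; fe$end <- newe
  fe$strand <- ifelse(fe$strand == "+", "-", "+")
  list(seqs = stats::setNames(rc, names(fix$seqs)), features = fe, L = L)
}
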