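test_that("a first-position AAT>GAT change is called Asn>Asp missense", {
  fix <- plus_gene_fixture(c("ATG", "AAT", "GGA", "TCC", "AAA", "TAA"),
                           cut = 7)
  # codon 2 (AAT) starts 3 bp into the CDS, still inside the first CDS exon
  pos <- fix$cds_start + 3
  eff <- classify_site("Gm01", pos, "A", "G", fix$features, fix$seqs)
  expect_equal(eff$category, "coding")
  expect_equal(eff$subtype, "nonsynonymous")
  expect_equal(eff$aa_ref, "N")
  expect_equal(eff$aa_alt, "D")
  expect_equal(eff$substitution, "transition")
})

test_that("wobble-position changes are synonymous and UTR/intron sites typed", {
  fix <- plus_gene_fixture(c("ATG", "GGA", "AAT", "TCC", "AAA", "TAA"),
                           cut = 7)
  # codon 2 GGA -> GGG at its third base
  pos <- fix$cds_start + 5
  eff <- classify_site("Gm01", pos, "A", "G", fix$features, fix$seqs)
  expect_equal(eff$subtype, "synonymous")
  expect_equal(eff$aa_ref, "G"); expect_equal(eff$aa_alt, "G")
  # intron site (between the two CDS exons)
  ipos <- fix$cds1_end + 5
  ref <- substr(fix$seqs[[1]], ipos, ipos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_equal(classify_site("Gm01", ipos, ref, alt, fix$features,
                             fix$seqs)$category, "intron")
  # UTR sites
  u5 <- fix$features$start[fix$features$type == "five_prime_UTR"] + 2
  ref5 <- substr(fix$seqs[[1]], u5, u5)
  expect_equal(classify_site("Gm01", u5, ref5,
                             setdiff(c("A", "C", "G", "T"), ref5)[1],
                             fix$features, fix$seqs)$category, "utr5")
  # intergenic: before the gene
  ref0 <- substr(fix$seqs[[1]], 5, 5)
  expect_equal(classify_site("Gm01", 5, ref0,
                             setdiff(c("A", "C", "G", "T"), ref0)[1],
                             fix$features, fix$seqs)$category, "intergenic")
  # reference mismatch is an error naming the position
  wrong <- setdiff(c("A", "C", "G", "T"), ref0)[1]
  expect_error(classify_site("Gm01", 5, wrong, ref0, fix$features, fix$seqs),
               "Gm01:5")
})

test_that("annotation is strand-consistent under fixture mirroring", {
  fix <- plus_gene_fixture(c("ATG", "AAT", "GGA", "TGC", "CTT", "AAA", "TAA"),
                           cut = 10)
  mir <- mirror_fixture(fix)
  # probe every CDS base of the gene on both representations
  cds <- fix$features[fix$features$type == "CDS", ]
  for (r in seq_len(nrow(cds))) {
    for (pos in seq(cds$start[r], cds$end[r], by = 2)) {
      ref <- substr(fix$seqs[[1]], pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      eff <- classify_site("Gm01", pos, ref, alt, fix$features, fix$seqs)
      mpos <- mir$L - pos + 1
      mref <- chartr("ACGT", "TGCA", ref)
      malt <- chartr("ACGT", "TGCA", alt)
      meff <- classify_site("Gm01", mpos, mref, malt, mir$features, mir$seqs)
      expect_equal(meff$category, eff$category)
      expect_equal(meff$subtype, eff$subtype)
      expect_equal(meff$aa_ref, eff$aa_ref)
      expect_equal(meff$aa_alt, eff$aa_alt)
    }
  }
})

test_that("third-position transitions in generated CDS are synonymous", {
  cfg <- sim_config(seed = 19, n_chromosomes = 1, chrom_length_bp = 30000,
                    n_markers = 10, qtl_spec = NULL)
  ann <- simulate_annotation(cfg, genes_per_chrom = 3)
  feats <- ann$features
  checked <- 0
  for (tid in feats$ID[feats$type == "mRNA"]) {
    cds <- feats[!is.na(feats$Parent) & feats$Parent == tid &
                   feats$type == "CDS", ]
    ch <- cds$seqid[1]
    # walk third codon positions in transcript coordinates
    lens <- cds$end - cds$start + 1
    total <- sum(lens)
    for (off in seq(3, total - 3, by = 3)) {       # skip the stop codon
      # map transcript offset back to a genomic position
      ord <- order(cds$start)
      if (cds$strand[1] == "-") ord <- rev(ord)
      cum <- cumsum(lens[ord])
      seg <- which(off <= cum)[1]
      within <- off - c(0, cum)[seg]
      gpos <- if (cds$strand[1] == "+") cds$start[ord[seg]] + within - 1
              else cds$end[ord[seg]] - within + 1
      ref <- substr(ann$seq[[ch]], gpos, gpos)
      alt <- c(A = "G", G = "A", C = "T", T = "C")[[ref]]
      eff <- classify_site(ch, gpos, ref, alt, feats, ann$seq)
      expect_equal(eff$category, "coding")
      # third-position transitions are synonymous except where the codon
      # family is interrupted (ATG/ATA Met/Ile; TGG Trp -> TGA stop)
      if (!eff$aa_ref %in% c("M", "I", "W")) {
        expect_equal(eff$subtype, "synonymous")
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 50)
})

test_that("generated annotations round-trip through GFF3 and FASTA", {
  cfg <- sim_config(seed = 23, n_chromosomes = 2, chrom_length_bp = 20000,
                    n_markers = 10, qtl_spec = NULL)
  ann <- simulate_annotation(cfg, genes_per_chrom = 2)
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_gff3(ann$features, gff)
  write_fasta(ann$seq, fa)
  back <- read_gff3(gff)
  key <- function(d) {
    d <- d[order(d$seqid, d$start, d$end, d$type), ]
    paste(d$seqid, d$type, d$start, d$end, d$strand, sep = ":")
  }
  expect_setequal(key(back), key(ann$features))
  expect_identical(read_fasta(fa), ann$seq)
  # CDS phases survive the round trip
  cds_a <- ann$features[ann$features$type == "CDS", ]
  cds_b <- back[back$type == "CDS", ]
  expect_equal(cds_b$phase[order(cds_b$start)],
               cds_a$phase[order(cds_a$start)])
  expect_error(simulate_annotation(cfg, genes_per_chrom = 0), "genes_per_chrom")
  big <- sim_config(seed = 1, n_chromosomes = 1, chrom_length_bp = 3000,
                    n_markers = 5, qtl_spec = NULL)
  expect_error(simulate_annotation(big, genes_per_chrom = 4), "too short")
})

test_that("transition/transversion tabulation and conservation", {
  panel <- data.frame(ref = c("A", "C", "A", "G", "A", "C", "A", "G"),
                      alt = c("G", "T", "C", "T", "G", "T", "T", "C"))
  tt <- ts_tv(panel)
  expect_equal(tt$transitions, 4)
  expect_equal(tt$transversions, 4)
  expect_equal(tt$ts_tv, 1.00)
  # no transversions -> infinite flag
  tt2 <- ts_tv(data.frame(ref = c("A", "C"), alt = c("G", "T")))
  expect_true(tt2$ts_tv_infinite)
  expect_equal(tt2$ts_tv, Inf)
  # counts conserve over an annotated panel
  cfg <- sim_config(seed = 29, n_chromosomes = 1, chrom_length_bp = 15000,
                    n_markers = 30, missing_rate = 0, qtl_spec = NULL)
  ann <- simulate_annotation(cfg, genes_per_chrom = 3)
  sim <- simulate_population(cfg)
  g <- sim$geno
  # force ref alleles to match the reference sequence
  g$map$ref <- vapply(seq_len(nrow(g$map)), function(i)
    substr(ann$seq[[g$map$chrom[i]]], g$map$pos[i], g$map$pos[i]),
    character(1))
  g$map$alt <- vapply(g$map$ref, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  eff <- annotate_sites(g, ann$features, ann$seq)
  tt3 <- ts_tv(eff)
  expect_equal(sum(tt3$category_counts), nrow(g$map))
  expect_equal(tt3$transitions + tt3$transversions, nrow(g$map))
  expect_true(all(eff$subtype[eff$category == "coding"] %in%
                    c("synonymous", "nonsynonymous")))
  expect_true(all(eff$subtype[eff$category != "coding"] == "none"))
})
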