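#' Read gene models from a GFF3 file
#'
#' @param path GFF3 path
#' @return GFF3-style data.frame: `seqid`, `type`, `start`, `end`, `strand`,
#'   `phase`, `ID`, `Parent`
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(z)
      if (length(z)) z[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = if ("phase" %in% names(md)) as.integer(md$phase)
            else NA_integer_,
    ID = if ("ID" %in% names(md)) as.character(md$ID)
         else NA_character_,
    Parent = parent, stringsAsFactors = FALSE
  )
}

#' Write gene models to a GFF3 file
#'
#' @param features GFF3-style data.frame (see [read_gff3()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$phase <- features$phase
  S4Vectors::mcols(gr)$ID <- features$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(features$Parent), "",
                                        features$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write reference sequences as FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as a named character
#' vector (one element per chromosome).
#'
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

.complement <- function(b) chartr("ACGT", "TGCA", b)

.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# extract the CDS of one transcript in transcript orientation, plus a mapper
# from genomic position to CDS offset. cds: data.frame of that transcript's
# CDS rows; chromseq: full chromosome string.
.cds_context <- function(cds, chromseq) {
  strand <- cds$strand[1]
  ord <- order(cds$start)
  if (strand == "-") ord <- rev(ord)
  cds <- cds[ord, , drop = FALSE]
  segs <- substring(chromseq, cds$start, cds$end)
  if (strand == "-") segs <- vapply(segs, .revcomp, character(1))
  lens <- cds$end - cds$start + 1L
  before <- cumsum(c(0L, lens))[seq_along(lens)]
  list(seq = paste(segs, collapse = ""), cds = cds, before = before,
       strand = strand, total = sum(lens))
}

#' Classify a SNP by genic context and coding consequence
#'
#' Hierarchical assignment with precedence coding > UTR > intron >
#' intergenic over all overlapping transcripts; for a coding site the codon
#' is assembled from the CDS in transcript orientation (reverse-complemented
#' on the minus strand), the variant allele substituted, and both codons
#' translated. Start/stop gains and losses are folded into nonsynonymous.
#' Among multiple coding transcripts the most severe consequence is
#' reported, ties broken by lexicographically first transcript id. A
#' transcript whose CDS length is not divisible by 3 is skipped with a
#' warning.
#'
#' @param chrom,pos,ref,alt the SNP (1-based position; single A/C/G/T
#'   alleles; `ref` must match the reference base)
#' @param features gene models (see [read_gff3()])
#' @param seqs reference sequences (named character vector)
#' @return list: `category` (`"intergenic"`, `"intron"`, `"utr5"`, `"utr3"`,
#'   `"coding"`), `subtype` (`"synonymous"`, `"nonsynonymous"`, `"none"`),
#'   `aa_ref`, `aa_alt`, `transcript`, `substitution`
#'   (`"transition"`/`"transversion"`)
#' @export
classify_site <- function(chrom, pos, ref, alt, features, seqs) {
  if (!chrom %in% names(seqs)) stop("no reference sequence for ", chrom)
  chromseq <- seqs[[chrom]]
  obs <- toupper(substring(chromseq, pos, pos))
  if (obs != ref)
    stop("reference mismatch at ", chrom, ":", pos,
         " (reference has ", obs, ", marker says ", ref, ")")
  subst <- if (all(c(ref, alt) %in% c("A", "G")) ||
               all(c(ref, alt) %in% c("C", "T"))) "transition"
           else "transversion"
  out <- list(category = "intergenic", subtype = "none",
              aa_ref = NA_character_, aa_alt = NA_character_,
              transcript = NA_character_, substitution = subst)

  f <- features[features$seqid == chrom, , drop = FALSE]
  mrna <- f[f$type == "mRNA" & f$start <= pos & f$end >= pos, , drop = FALSE]
  if (nrow(mrna) == 0) return(out)

  rank <- c(intron = 1, utr3 = 2, utr5 = 2, coding_syn = 3, coding_nonsyn = 4)
  best <- NULL; best_rank <- 0
  for (tid in sort(mrna$ID)) {
    sub <- f[!is.na(f$Parent) & f$Parent == tid, , drop = FALSE]
    hit <- sub[sub$start <= pos & sub$end >= pos, , drop = FALSE]
    cand <- NULL
    if (any(hit$type == "CDS")) {
      cdsrows <- sub[sub$type == "CDS", , drop = FALSE]
      ctx <- .cds_context(cdsrows, chromseq)
      if (ctx$total %% 3L != 0L) {
        warning("CDS length of ", tid, " not divisible by 3; site skipped ",
                "for this transcript")
      } else {
        row <- which(ctx$cds$start <= pos & ctx$cds$end >= pos)[1]
        within_seg <- if (ctx$strand == "+") {
          pos - ctx$cds$start[row] + 1L
        } else {
          ctx$cds$end[row] - pos + 1L
        }
        off <- ctx$before[row] + within_seg
        ci <- (off - 1L) %/% 3L
        codon_ref <- substring(ctx$seq, 3L * ci + 1L, 3L * ci + 3L)
        within <- off - 3L * ci
        var_base <- if (ctx$strand == "+") alt else .complement(alt)
        codon_alt <- codon_ref
        substring(codon_alt, within, within) <- var_base
        aa_r <- .translate_codon(codon_ref)
        aa_a <- .translate_codon(codon_alt)
        sub_t <- if (identical(aa_r, aa_a)) "synonymous" else "nonsynonymous"
        cand <- list(category = "coding", subtype = sub_t, aa_ref = aa_r,
                     aa_alt = aa_a, transcript = tid, substitution = subst)
      }
    } else if (any(hit$type == "five_prime_UTR")) {
      cand <- list(category = "utr5", subtype = "none",
                   aa_ref = NA_character_, aa_alt = NA_character_,
                   transcript = tid, substitution = subst)
    } else if (any(hit$type == "three_prime_UTR")) {
      cand <- list(category = "utr3", subtype = "none",
                   aa_ref = NA_character_, aa_alt = NA_character_,
                   transcript = tid, substitution = subst)
    } else {
      cand <- list(category = "intron", subtype = "none",
                   aa_ref = NA_character_, aa_alt = NA_character_,
                   transcript = tid, substitution = subst)
    }
    if (!is.null(cand)) {
      r <- if (cand$category == "coding") {
        if (cand$subtype == "nonsynonymous") rank["coding_nonsyn"]
        else rank["coding_syn"]
      } else rank[cand$category]
      if (r > best_rank) { best <- cand; best_rank <- r }
    }
  }
  if (is.null(best)) out else best
}

#' Annotate all markers of a panel
#'
#' Vectorized driver over [classify_site()].
#'
#' @param g a [geno()] object (its marker map is annotated)
#' @param features gene models (see [read_gff3()])
#' @param seqs reference sequences (named character vector)
#' @return data.frame: map columns plus `category`, `subtype`, `aa_ref`,
#'   `aa_alt`, `transcript`, `substitution`
#' @export
annotate_sites <- function(g, features, seqs) {
  m <- g$map
  res <- lapply(seq_len(nrow(m)), function(i)
    classify_site(m$chrom[i], m$pos[i], m$ref[i], m$alt[i], features, seqs))
  cbind(m, do.call(rbind, lapply(res, function(r)
    data.frame(category = r$category, subtype = r$subtype,
               aa_ref = r$aa_ref, aa_alt = r$aa_alt,
               transcript = r$transcript, substitution = r$substitution,
               stringsAsFactors = FALSE))))
}

#' Annotation summary: category counts and the Ts/Tv ratio
#'
#' A transition keeps both alleles within the purines \{A, G\} or within the
#' pyrimidines \{C, T\}; every other substitution is a transversion.
#'
#' @param x either an [annotate_sites()] data.frame or any data.frame with
#'   `ref`/`alt` columns
#' @return list: `category_counts` (named, when categories are present),
#'   `transitions`, `transversions`, `ts_tv` (Inf when no transversions,
#'   with `ts_tv_infinite = TRUE`)
#' @export
ts_tv <- function(x) {
  stopifnot(all(c("ref", "alt") %in% names(x)))
  if (!all(x$ref %in% c("A", "C", "G", "T") & x$alt %in% c("A", "C", "G", "T")))
    stop("alleles must be single bases A/C/G/T")
  is_ts <- (x$ref %in% c("A", "G") & x$alt %in% c("A", "G")) |
    (x$ref %in% c("C", "T") & x$alt %in% c("C", "T"))
  ts <- sum(is_ts); tv <- sum(!is_ts)
  out <- list(
    category_counts = if ("category" %in% names(x))
      table(factor(x$category, levels = c("intergenic", "intron", "utr5",
                                          "utr3", "coding"))) else NULL,
    transitions = ts, transversions = tv,
    ts_tv = if (tv == 0) Inf else ts / tv,
    ts_tv_infinite = tv == 0
  )
  out
}
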