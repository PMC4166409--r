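#' Genotype matrix container
#'
#' Bundles a samples-by-markers variant-allele dosage matrix with its marker
#' map. Dosage is the count of the variant (ALT) allele per sample: 0, 1 or 2,
#' with `NA` for a missing call. Fully inbred material carries only 0/2, but
#' dosage 1 from real VCFs is accepted everywhere.
#'
#' @param dosage numeric matrix, samples in rows, markers in columns. Row
#'   names are sample ids; column names, when absent, are taken from the map.
#' @param map data.frame with columns `id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per marker, in column order of `dosage`.
#' @return An object of class `geno`: a list with elements `dosage` and `map`,
#'   markers sorted by (chromosome, position).
#' @export
geno <- function(dosage, map) {
  stopifnot(is.matrix(dosage), is.data.frame(map))
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(map)))
    stop("map must have columns: ", paste(req, collapse = ", "))
  if (ncol(dosage) != nrow(map))
    stop("dosage has ", ncol(dosage), " markers but map has ", nrow(map))
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (!all(map$ref %in% c("A", "C", "G", "T")) ||
      !all(map$alt %in% c("A", "C", "G", "T")))
    stop("alleles must be single bases A/C/G/T (biallelic SNPs only)")
  map$pos <- as.integer(map$pos)
  map$chrom <- as.character(map$chrom)
  dup <- duplicated(map[c("chrom", "pos")])
  if (any(dup))
    stop("duplicate marker position: ",
         paste(map$chrom[dup], map$pos[dup], sep = ":", collapse = ", "))
  # chromosome order: order of first appearance (zero-padded names such as
  # Gm01..Gm20 coincide with lexicographic order)
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  map <- map[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(map) <- NULL
  colnames(dosage) <- map$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, map = map), class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("<geno> ", nrow(x$dosage), " samples x ", ncol(x$dosage), " markers on ",
      length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat("  missing calls: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$dosage)

#' Subset a geno object by samples and/or markers
#'
#' @param x a [geno()] object
#' @param samples,markers index vectors (logical, integer or names/ids)
#' @return a `geno` object
#' @export
subset_geno <- function(x, samples = NULL, markers = NULL) {
  d <- x$dosage; m <- x$map
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, m$id)
    d <- d[, markers, drop = FALSE]
    m <- m[markers, , drop = FALSE]
  }
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  geno(d, m)
}

#' Marker id in canonical `<chrom>_<pos>` form
#' @param chrom,pos chromosome names and 1-based positions
#' @return character vector of ids
#' @export
marker_id <- function(chrom, pos) sprintf("%s_%d", chrom, as.integer(pos))

#' Per-marker summary: minor allele frequency and missingness
#'
#' MAF is computed on non-missing calls only, as the folded frequency of the
#' variant allele, so it always lies in \[0, 0.5\].
#'
#' @param g a [geno()] object
#' @return data.frame with columns `id`, `chrom`, `pos`, `maf`,
#'   `missing_frac`, `n_called`
#' @export
marker_summary <- function(g) {
  d <- g$dosage
  n <- nrow(d)
  called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  p <- ifelse(called > 0, alt / (2 * called), NA_real_)
  data.frame(
    id = g$map$id, chrom = g$map$chrom, pos = g$map$pos,
    maf = pmin(p, 1 - p),
    missing_frac = 1 - called / n,
    n_called = called,
    stringsAsFactors = FALSE
  )
}

#' Filter markers by minor allele frequency
#'
#' Retains exactly the markers with MAF strictly greater than `cutoff`
#' (computed on non-missing calls); marker order is preserved. The operation
#' is idempotent.
#'
#' @param g a [geno()] object
#' @param cutoff MAF cutoff in \[0, 0.5\]; default 0.05
#' @return a filtered `geno` object
#' @export
filter_maf <- function(g, cutoff = 0.05) {
  stopifnot(cutoff >= 0, cutoff <= 0.5)
  maf <- marker_summary(g)$maf
  keep <- !is.na(maf) & maf > cutoff
  if (!any(keep))
    stop("all markers removed at MAF cutoff ", cutoff,
         "; consider lowering the cutoff")
  subset_geno(g, markers = which(keep))
}

#' Impute missing dosages by the per-marker mode
#'
#' Each missing cell is replaced by that marker's most frequent observed
#' dosage; ties are broken toward the lower dosage (documented rule).
#' Non-missing cells are untouched. This is a deliberately simple frequency-
#' mode rule, not a haplotype-model imputation.
#'
#' @param g a [geno()] object; every marker needs at least one non-missing call
#' @return a `geno` object with no missing dosages
#' @export
impute_mode <- function(g) {
  d <- g$dosage
  full <- colSums(!is.na(d)) == 0
  if (any(full))
    stop("fully missing marker(s): ",
         paste(g$map$id[full], collapse = ", "))
  for (j in which(colSums(is.na(d)) > 0)) {
    x <- d[, j]
    cnt <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)  # counts of dosage 0,1,2
    mode <- which(cnt == max(cnt))[1L] - 1L         # ties -> lower dosage
    x[is.na(x)] <- mode
    d[, j] <- x
  }
  g$dosage <- d
  g
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.2) with vcfR and converts GT fields to variant-allele
#' dosages. Only biallelic SNP records with single-base REF/ALT in A/C/G/T
#' are usable; multi-allelic records are skipped with a warning or rejected,
#' per `multiallelic`.
#'
#' @param path VCF file path (plain text or bgzipped)
#' @param multiallelic `"skip"` (drop with a warning, default) or `"error"`
#' @return a [geno()] object
#' @export
read_vcf_geno <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snp <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  drop <- multi | (!snp & !multi)
  if (any(multi) && multiallelic == "error")
    stop(sum(multi), " multi-allelic record(s), e.g. at ",
         fix$CHROM[multi][1], ":", fix$POS[multi][1])
  if (any(drop))
    warning("skipping ", sum(drop),
            " record(s) that are not biallelic single-base SNPs")
  keep <- which(!drop)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dup <- duplicated(paste(fix$CHROM, fix$POS))
  if (any(dup))
    stop("duplicate position in VCF: ",
         paste(fix$CHROM[dup], fix$POS[dup], sep = ":", collapse = ", "))
  # map each distinct GT string to an ALT-allele count
  u <- unique(as.vector(gt))
  dos_of <- vapply(u, function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == "." | al == "")) return(NA_real_)
    sum(al == "1")
  }, numeric(1))
  d <- matrix(dos_of[match(as.vector(gt), u)], nrow = nrow(gt))
  d <- t(d)  # samples x markers
  rownames(d) <- colnames(gt)
  map <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                marker_id(fix$CHROM, fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  geno(d, map)
}

#' Write genotypes to a VCF v4.2 file
#'
#' Emits one GT-only sample column per line; dosage 0/1/2 become `0/0`,
#' `0/1`, `1/1` and missing becomes `./.`.
#'
#' @param g a [geno()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf_geno <- function(g, path) {
  d <- g$dosage; m <- g$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=idcqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t")
  ), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    gt <- ifelse(is.na(d[, j]), "./.", code[d[, j] + 1L])
    writeLines(paste(c(m$chrom[j], m$pos[j], m$id[j], m$ref[j], m$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a TSV with columns `sample`, `population`, `idc_score`
#' (1-5 visual chlorosis scale).
#'
#' @param path TSV path
#' @return data.frame with columns `sample`, `population`, `idc_score`
#' @export
read_phenotypes <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "population", "idc_score")
  if (!all(req %in% names(p)))
    stop("phenotype table must have columns: ", paste(req, collapse = ", "))
  if (any(p$idc_score < 1 | p$idc_score > 5, na.rm = TRUE))
    stop("idc_score outside the 1-5 scale")
  p[req]
}

#' Adjust phenotypes to least-squares means across populations
#'
#' Each score is re-expressed as its within-population deviation plus the
#' grand mean: `adjusted = raw - mean(population) + grand mean`. This removes
#' the population (e.g. trial-year) main effect so the two populations can be
#' analysed combined, while preserving within-population deviations and the
#' overall grand mean. With fewer than two populations, or any population of
#' fewer than two samples, the scores pass through unchanged.
#'
#' @param pheno data.frame with columns `sample`, `population`, `idc_score`
#' @return the input with an `adjusted` column appended
#' @export
adjust_phenotype <- function(pheno) {
  stopifnot(all(c("sample", "population", "idc_score") %in% names(pheno)))
  if (any(is.na(pheno$population))) stop("unknown (NA) population label")
  tab <- table(pheno$population)
  if (length(tab) < 2 || any(tab < 2)) {
    pheno$adjusted <- pheno$idc_score
    return(pheno)
  }
  grand <- mean(pheno$idc_score)
  popmean <- tapply(pheno$idc_score, pheno$population, mean)
  pheno$adjusted <- pheno$idc_score -
    as.numeric(popmean[pheno$population]) + grand
  pheno
}
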