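#' Forward stepwise marker selection with elimination
#'
#' Forward selection over candidate markers (typically those significant at
#' the 0.1-percentile bootstrap cutoff): at each step the candidate with the
#' smallest partial p-value enters if that p-value and the overall model
#' F-test p-value are both at or below the gates; after each entry any
#' included marker whose partial p-value has risen above the gate is dropped.
#' Stops when no candidate qualifies. Duplicated/collinear candidates can
#' never enter twice (their partial p is undefined once a copy is in).
#'
#' @param y numeric response (adjusted IDC scores)
#' @param X numeric matrix of candidate marker dosages (named columns)
#' @param p_enter partial p-value gate for entry and retention (0.05)
#' @param p_model overall model F-test p-value gate (0.05)
#' @param covariates optional covariate matrix always kept in the model
#' @return list: `selected` (ids in entry order), `steps` (data.frame
#'   `marker`, `p_entry`), `r2_pct` (multiple R-squared of the final model,
#'   percent), `final_p` (named partial p-values in the final joint model)
#' @export
stepwise_select <- function(y, X, p_enter = 0.05, p_model = 0.05,
                            covariates = NULL) {
  stopifnot(is.matrix(X), !is.null(colnames(X)), nrow(X) == length(y))
  covnames <- if (is.null(covariates)) character(0)
              else paste0(".cov", seq_len(ncol(covariates)))
  marker_p <- function(cols) {
    # partial p of every term in `cols`, fit jointly with covariates
    dat <- data.frame(.y = y)
    for (ci in seq_along(covnames)) dat[[covnames[ci]]] <- covariates[, ci]
    for (cn in cols) dat[[cn]] <- X[, cn]
    fit <- stats::lm(.y ~ ., data = dat)
    sm <- summary(fit)
    cf <- sm$coefficients
    rn <- rownames(cf)
    p <- stats::setNames(rep(NA_real_, length(cols)), cols)
    hit <- intersect(cols, rn)
    p[hit] <- cf[match(hit, rn), 4]
    list(p = p, fit = fit, sm = sm)
  }
  model_p <- function(sm) {
    fs <- sm$fstatistic
    if (is.null(fs)) return(1)
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  }
  included <- character(0)
  steps <- data.frame(marker = character(), p_entry = numeric(),
                      stringsAsFactors = FALSE)
  pool <- colnames(X)
  repeat {
    cand <- setdiff(pool, included)
    if (length(cand) == 0) break
    pvals <- vapply(cand, function(cn) {
      r <- marker_p(c(included, cn))
      unname(r$p[cn])
    }, numeric(1))
    pvals[is.na(pvals)] <- Inf   # collinear with current model
    best <- which.min(pvals)
    if (!is.finite(pvals[best]) || pvals[best] > p_enter) break
    trial <- c(included, cand[best])
    r <- marker_p(trial)
    if (model_p(r$sm) > p_model) break
    included <- trial
    steps <- rbind(steps, data.frame(marker = cand[best],
                                     p_entry = pvals[best],
                                     stringsAsFactors = FALSE))
    # elimination: drop markers whose partial p exceeded the gate
    repeat {
      r <- marker_p(included)
      pj <- r$p
      pj[is.na(pj)] <- Inf
      worst <- which.max(pj)
      if (length(included) == 0 || pj[worst] <= p_enter) break
      included <- included[-worst]
    }
  }
  if (length(included) == 0)
    return(list(selected = character(0), steps = steps, r2_pct = 0,
                final_p = numeric(0)))
  r <- marker_p(included)
  list(selected = included, steps = steps,
       r2_pct = 100 * r$sm$r.squared, final_p = r$p)
}

#' Delineate the QTL region around a stepwise lead marker
#'
#' Grows an LD block outward from the lead along its chromosome: the block
#' extends to the next adjacent marker while the partial r2 between the
#' current block edge and that marker exceeds `r2_threshold` (edge chaining;
#' `anchor = "lead"` instead compares every adjacent marker to the lead).
#' A lead in LD with neither neighbour yields a single-marker region with
#' start = end = the lead position.
#'
#' @param g a [geno()] object (imputed)
#' @param lead_id marker id of the stepwise lead
#' @param covariates optional covariate matrix (PC25 scores) for partial r2
#' @param r2_threshold LD chain threshold (default 0.6)
#' @param anchor `"edge"` (default) or `"lead"`
#' @return list of class `qtl_region`: `chrom`, `start`, `end`, `lead`,
#'   `members` (character vector of member marker ids)
#' @export
delineate_region <- function(g, lead_id, covariates = NULL,
                             r2_threshold = 0.6,
                             anchor = c("edge", "lead")) {
  anchor <- match.arg(anchor)
  i <- match(lead_id, g$map$id)
  if (is.na(i)) stop("lead marker ", lead_id, " not in the panel")
  ch <- g$map$chrom[i]
  idx <- which(g$map$chrom == ch)           # position-sorted by construction
  k <- match(i, idx)
  d <- g$dosage
  r2_adj <- function(a, b) {
    r <- partial_r2(d[, idx[a]], d[, idx[b]], covariates)
    !is.na(r) && r > r2_threshold
  }
  right <- k
  while (right < length(idx) &&
         r2_adj(if (anchor == "edge") right else k, right + 1))
    right <- right + 1
  left <- k
  while (left > 1 &&
         r2_adj(if (anchor == "edge") left else k, left - 1))
    left <- left - 1
  members <- g$map$id[idx[left:right]]
  structure(list(chrom = ch, start = g$map$pos[idx[left]],
                 end = g$map$pos[idx[right]], lead = lead_id,
                 members = members),
            class = "qtl_region")
}

#' @export
print.qtl_region <- function(x, ...) {
  cat("<qtl_region> ", x$chrom, ":", x$start, "-", x$end,
      " lead ", x$lead, " (", length(x$members), " markers)\n", sep = "")
  invisible(x)
}

#' Merge adjacent QTL blocks separated by short low-LD gaps
#'
#' Two adjacent blocks on the same chromosome merge when their end-to-start
#' gap is below `gap_bp` AND the markers strictly between them that are not
#' in LD with either block number at most `max_nonld_markers`; merging
#' repeats until a fixpoint. Whether a marker is "in LD with a block" is
#' decided by `in_ld(pos, block)`; the default tests partial r2 >
#' `r2_threshold` against the block's nearest edge marker.
#'
#' @param blocks list of [delineate_region()] regions, same chromosome,
#'   sorted by start
#' @param g a [geno()] object (for positions and the default LD test)
#' @param covariates optional covariate matrix for the default LD test
#' @param gap_bp maximum end-to-start gap (default 10 kb)
#' @param max_nonld_markers maximum count of intervening non-LD markers (4)
#' @param r2_threshold LD threshold for the default test (0.6)
#' @param in_ld optional function(pos, block) -> logical, overriding the
#'   default test
#' @return list of merged `qtl_region` blocks
#' @export
merge_blocks <- function(blocks, g, covariates = NULL, gap_bp = 10000,
                         max_nonld_markers = 4, r2_threshold = 0.6,
                         in_ld = NULL) {
  if (length(blocks) <= 1) return(blocks)
  stopifnot(length(unique(vapply(blocks, `[[`, character(1), "chrom"))) == 1)
  blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "start"))]
  d <- g$dosage
  if (is.null(in_ld)) {
    in_ld <- function(pos, block) {
      j <- match(marker_id(block$chrom, pos), g$map$id)
      edges <- match(c(block$members[1],
                       block$members[length(block$members)]), g$map$id)
      any(vapply(unique(edges), function(e) {
        r <- partial_r2(d[, j], d[, e], covariates)
        !is.na(r) && r > r2_threshold
      }, logical(1)))
    }
  }
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(blocks)) {
      b1 <- blocks[[i]]; b2 <- blocks[[i + 1]]
      gap <- b2$start - b1$end
      between <- g$map$pos[g$map$chrom == b1$chrom &
                             g$map$pos > b1$end & g$map$pos < b2$start]
      nonld <- if (length(between) == 0) 0 else
        sum(vapply(between, function(p)
          !in_ld(p, b1) && !in_ld(p, b2), logical(1)))
      if (gap < gap_bp && nonld <= max_nonld_markers) {
        nb <- structure(list(
          chrom = b1$chrom, start = b1$start, end = b2$end,
          lead = paste(unique(c(b1$lead, b2$lead)), collapse = ","),
          members = unique(c(b1$members,
                             marker_id(b1$chrom, between), b2$members))),
          class = "qtl_region")
        blocks <- c(blocks[seq_len(i - 1)], list(nb),
                    blocks[setdiff(seq_along(blocks), seq_len(i + 1))])
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  blocks
}

#' Genes overlapping a QTL region
#'
#' Any-intersection of closed 1-based intervals: a gene is reported when its
#' `[start, end]` intersects the region's `[start, end]` on the same
#' chromosome.
#'
#' @param region a [delineate_region()] region (or list with `chrom`,
#'   `start`, `end`)
#' @param genes either GFF3-style features (rows with `type == "gene"` are
#'   used; see [read_gff3()]) or a data.frame with columns `id`
#'   (or `ID`), `chrom` (or `seqid`), `start`, `end`
#' @return character vector of overlapping gene ids
#' @export
overlap_genes <- function(region, genes) {
  if ("type" %in% names(genes))
    genes <- genes[genes$type == "gene", , drop = FALSE]
  chrom <- if ("chrom" %in% names(genes)) genes$chrom else genes$seqid
  id <- if ("id" %in% names(genes)) genes$id else genes$ID
  hit <- chrom == region$chrom &
    genes$start <= region$end & genes$end >= region$start
  id[hit]
}

#' All-pairs epistasis scan
#'
#' For every unordered pair of markers fits
#' `y ~ covariates + m1 + m2 + m1:m2` and reports the interaction-term
#' p-value; pairs whose interaction is collinear (degenerate) get p = 1.
#'
#' @param y numeric response
#' @param X matrix of marker dosages (k >= 2 named columns)
#' @param covariates optional covariate matrix (PC25 scores)
#' @param alpha significance gate for the flag (default 1e-3)
#' @return data.frame: `marker1`, `marker2`, `coef`, `p`, `significant`,
#'   `degenerate`; one row per pair, k(k-1)/2 rows total
#' @export
epistasis_scan <- function(y, X, covariates = NULL, alpha = 1e-3) {
  stopifnot(is.matrix(X), ncol(X) >= 2, !is.null(colnames(X)))
  k <- ncol(X)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    x1 <- X[, ij[1]]; x2 <- X[, ij[2]]
    M <- cbind(1, covariates, x1, x2, x1 * x2)
    fit <- stats::lm.fit(M, y)
    p_int <- ncol(M)
    if (fit$rank < p_int || is.na(fit$coefficients[p_int]))
      return(c(NA_real_, 1, 1))
    rss <- sum(fit$residuals^2)
    df <- length(y) - p_int
    XtXinv <- tryCatch(chol2inv(chol(crossprod(M))), error = function(e) NULL)
    if (is.null(XtXinv)) return(c(NA_real_, 1, 1))
    se <- sqrt(rss / df * XtXinv[p_int, p_int])
    b <- fit$coefficients[p_int]
    pv <- max(2 * stats::pt(-abs(b / se), df), P_FLOOR)
    c(b, pv, 0)
  })
  data.frame(
    marker1 = colnames(X)[pairs[1, ]], marker2 = colnames(X)[pairs[2, ]],
    coef = res[1, ], p = res[2, ],
    significant = res[2, ] <= alpha & res[3, ] == 0,
    degenerate = res[3, ] == 1, stringsAsFactors = FALSE
  )
}

#' Classify an allelic-combination mean on the IDC scale
#'
#' Inclusive thresholds: tolerant when mean <= `t_low`, susceptible when
#' mean >= `t_high`, else intermediate. (A mean of exactly 2.50 is
#' tolerant.)
#'
#' @param mean_idc numeric vector of combination means
#' @param t_low,t_high class thresholds (2.5 and 3.5)
#' @return character vector in \{"tolerant", "intermediate", "susceptible"\}
#' @export
classify_tolerance <- function(mean_idc, t_low = 2.5, t_high = 3.5) {
  ifelse(mean_idc <= t_low, "tolerant",
         ifelse(mean_idc >= t_high, "susceptible", "intermediate"))
}

#' Allelic combinations over the stepwise markers
#'
#' Each sample homozygous at every selected marker contributes a
#' combination string: per marker, the reference letter at dosage 0 or the
#' variant letter at dosage 2, in the fixed marker order given. Samples
#' heterozygous or missing at any selected marker are excluded (their count
#' is reported). Per combination: group size, min, max, mean and sample SD
#' (n-1 denominator, absent when n < 2) of the raw IDC scores, and the
#' tolerance class of [classify_tolerance()].
#'
#' @param g a [geno()] object
#' @param marker_ids stepwise marker ids, in fixed order
#' @param y_raw raw IDC scores aligned with samples
#' @param t_low,t_high class thresholds (2.5, 3.5)
#' @return list: `combos` (data.frame `combo`, `n`, `min`, `max`, `mean`,
#'   `sd`, `class`, sorted by mean), `n_excluded`, `marker_order`
#' @export
allele_combos <- function(g, marker_ids, y_raw, t_low = 2.5, t_high = 3.5) {
  j <- match(marker_ids, g$map$id)
  if (anyNA(j)) stop("unknown marker id(s): ",
                     paste(marker_ids[is.na(j)], collapse = ", "))
  d <- g$dosage[, j, drop = FALSE]
  ref <- g$map$ref[j]; alt <- g$map$alt[j]
  eligible <- apply(d, 1, function(r) all(!is.na(r) & r %in% c(0, 2)))
  if (!any(eligible)) stop("no samples homozygous-called at all markers")
  letters_mat <- vapply(seq_along(j), function(k)
    ifelse(d[eligible, k] == 0, ref[k], alt[k]), character(sum(eligible)))
  combo <- apply(matrix(letters_mat, nrow = sum(eligible)), 1, paste,
                 collapse = "")
  yv <- y_raw[eligible]
  agg <- split(yv, combo)
  combos <- data.frame(
    combo = names(agg),
    n = vapply(agg, length, integer(1)),
    min = vapply(agg, min, numeric(1)),
    max = vapply(agg, max, numeric(1)),
    mean = vapply(agg, mean, numeric(1)),
    sd = vapply(agg, function(v) if (length(v) < 2) NA_real_ else
      stats::sd(v), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  combos$class <- classify_tolerance(combos$mean, t_low, t_high)
  combos <- combos[order(combos$mean), , drop = FALSE]
  rownames(combos) <- NULL
  list(combos = combos, n_excluded = sum(!eligible),
       marker_order = marker_ids)
}
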