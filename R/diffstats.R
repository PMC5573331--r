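#' Assign biomass groups from total root mass
#'
#' Thresholds are `mean - f*sd` and `mean + f*sd` of the reference TRM
#' values (sample standard deviation, n-1). Samples strictly below the
#' lower threshold are Small, strictly above the upper are Large, the
#' inclusive interval in between is Medium.
#'
#' @param trm TRM values (g) of the samples to label.
#' @param f sd multiplier (default 0.5).
#' @param reference_trm values the thresholds are computed from; defaults to
#'   `trm` itself, but a larger phenotype table can be supplied so its
#'   thresholds are applied to a sample subset.
#' @return list of class `group_assignment` with `labels` (factor
#'   Small/Medium/Large), `lo`, `hi`.
#' @export
assign_groups <- function(trm, f = 0.5, reference_trm = trm) {
  if (length(reference_trm) < 3) stop("at least 3 reference samples needed")
  m <- mean(reference_trm)
  s <- sd(reference_trm)
  if (s == 0) {
    warning("zero variance in reference TRM; all samples labeled Medium")
    labels <- factor(rep("Medium", length(trm)),
                     levels = c("Small", "Medium", "Large"))
    return(structure(list(labels = labels, lo = m, hi = m),
                     class = "group_assignment"))
  }
  lo <- m - f * s
  hi <- m + f * s
  labels <- factor(ifelse(trm < lo, "Small",
                          ifelse(trm > hi, "Large", "Medium")),
                   levels = c("Small", "Medium", "Large"))
  structure(list(labels = labels, lo = lo, hi = hi),
            class = "group_assignment")
}

#' Abundance floor filter
#'
#' Keeps a miRNA when its mean RPTM is at least `floor` in either the Small
#' or the Large group.
#'
#' @param rptm miRNA x sample RPTM matrix (see [rptm_matrix()]).
#' @param groups group labels per sample column (factor or character with
#'   levels Small/Medium/Large).
#' @param floor RPTM floor (default 10).
#' @return character vector of retained miRNA row names.
#' @export
filter_by_abundance <- function(rptm, groups, floor = 10) {
  groups <- as.character(groups)
  ms <- rowMeans(rptm[, groups == "Small", drop = FALSE])
  ml <- rowMeans(rptm[, groups == "Large", drop = FALSE])
  rownames(rptm)[ms >= floor | ml >= floor]
}

#' Differential abundance test between the Small and Large groups
#'
#' Counts are scaled to a common library size; a common negative-binomial
#' dispersion is estimated by moments (variance model `mu + phi * mu^2`,
#' averaging the per-miRNA excess-variance ratios over well-expressed
#' miRNAs), and each miRNA is tested with a Wald z statistic on the
#' difference of group means, with the null standard error evaluated at
#' the pooled mean. P-values are BH-adjusted.
#'
#' @param counts miRNA x sample raw count matrix.
#' @param library_sizes per-sample sequencing depths.
#' @param groups Small/Medium/Large label per sample; Medium samples are
#'   held out of the comparison.
#' @return data.frame sorted by adjusted P: `mirna_id`, `mean_rptm_small`,
#'   `mean_rptm_large`, `log2_fc`, `dispersion`, `p_value`, `p_adjusted`.
#' @export
test_differential <- function(counts, library_sizes, groups) {
  groups <- as.character(groups)
  sel_s <- groups == "Small"
  sel_l <- groups == "Large"
  if (sum(sel_s) < 2 || sum(sel_l) < 2) {
    stop("need at least 2 samples in each of the Small and Large groups")
  }
  sf <- library_sizes / mean(library_sizes)
  y <- sweep(counts, 2, sf, "/")        # depth-normalized counts
  ys <- y[, sel_s, drop = FALSE]
  yl <- y[, sel_l, drop = FALSE]
  ns <- ncol(ys); nl <- ncol(yl)
  ms <- rowMeans(ys); ml <- rowMeans(yl)
  # moment estimate of a common dispersion phi: var = mu + phi mu^2.
  # Averaging per-miRNA excess-variance ratios over well-expressed rows
  # keeps the estimate stable (a depth-weighted sum would be dominated by
  # a handful of extreme-abundance miRNAs).
  vs <- apply(ys, 1, var); vl <- apply(yl, 1, var)
  num <- (vs - ms) + (vl - ml)
  den <- ms^2 + ml^2
  mu0 <- (ns * ms + nl * ml) / (ns + nl)
  well <- den > 0 & mu0 >= 10
  if (sum(well) < 20) well <- den > 0
  phi <- max(0, mean(num[well] / den[well]))
  # null (score-type) standard error at the pooled mean
  se <- sqrt((mu0 + phi * mu0^2) * (1 / ns + 1 / nl))
  zstat <- ifelse(se > 0, (ml - ms) / se, 0)
  p <- 2 * pnorm(-abs(zstat))
  rptm_s <- rowMeans(rptm_matrix(counts[, sel_s, drop = FALSE],
                                 library_sizes[sel_s]))
  rptm_l <- rowMeans(rptm_matrix(counts[, sel_l, drop = FALSE],
                                 library_sizes[sel_l]))
  res <- data.frame(
    mirna_id = rownames(counts),
    mean_rptm_small = rptm_s,
    mean_rptm_large = rptm_l,
    log2_fc = log2((ml + 0.5) / (ms + 0.5)),
    dispersion = phi,
    p_value = p,
    p_adjusted = bh_adjust(p),
    row.names = NULL)
  res[order(res$p_adjusted, res$p_value), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (wraps
#' `stats::p.adjust(method = "BH")` after range validation).
#'
#' @param pvals raw P-values in \[0, 1\].
#' @return adjusted P-values, order-preserving.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Pairwise trait correlation matrix
#'
#' Pearson correlations with two-sided t-test P-values, pairwise-complete.
#' Pairs backed by fewer than 3 complete observations, or involving a
#' constant trait, are reported as `NA`.
#'
#' @param table data.frame of numeric trait columns (e.g. TRM, RM, HT, MLL,
#'   MLW, TLA, LN), one row per plant.
#' @return list with matrices `r`, `p` and `n` (complete pairs).
#' @export
trait_correlations <- function(table) {
  traits <- names(table)[vapply(table, is.numeric, logical(1))]
  k <- length(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      x <- table[[traits[i]]]; y <- table[[traits[j]]]
      cc <- complete.cases(x, y)
      n[i, j] <- n[j, i] <- sum(cc)
      if (sum(cc) < 3 || sd(x[cc]) == 0 || sd(y[cc]) == 0) next
      ct <- cor.test(x[cc], y[cc], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(n) <- vapply(table[traits], function(v) sum(!is.na(v)), numeric(1))
  list(r = r, p = p, n = n)
}

#' qPCR fold changes by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt = dCt -
#' dCt_calibrator`; `fold = 2^-ddCt`. The calibrator sample's fold change is
#' exactly 1.
#'
#' @param records data.frame with `sample_id`, `ct_target`, `ct_reference`.
#' @param calibrator sample id of the calibrator.
#' @return `records` with added `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(records, calibrator) {
  if (!calibrator %in% records$sample_id) {
    stop("calibrator sample '", calibrator, "' not found")
  }
  if (any(is.na(records$ct_target)) || any(is.na(records$ct_reference))) {
    stop("every sample needs target and reference Ct values")
  }
  records$dct <- records$ct_target - records$ct_reference
  cal_dct <- records$dct[records$sample_id == calibrator][1]
  records$ddct <- records$dct - cal_dct
  records$fold_change <- 2^(-records$ddct)
  records
}

#' Correlation between expression level and total root mass
#'
#' @param levels named per-sample expression values.
#' @param trm named per-sample TRM values (same sample ids).
#' @param groups optional Small/Medium/Large labels for group summaries.
#' @return list with `r`, `p`, `n` and (when groups are given)
#'   `group_summary` (mean and sd per group).
#' @export
expression_trm_correlation <- function(levels, trm, groups = NULL) {
  if (!is.null(names(levels)) && !is.null(names(trm))) {
    if (!setequal(names(levels), names(trm))) {
      stop("sample ids of expression levels and TRM values do not match")
    }
    trm <- trm[names(levels)]
    if (!is.null(groups) && !is.null(names(groups))) {
      groups <- groups[names(levels)]
    }
  } else if (length(levels) != length(trm)) {
    stop("expression levels and TRM values must be matched per sample")
  }
  if (length(levels) < 3) stop("need at least 3 matched samples")
  ct <- cor.test(levels, trm, method = "pearson")
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = length(levels))
  if (!is.null(groups)) {
    out$group_summary <- data.frame(
      group = levels(factor(groups)),
      mean = as.numeric(tapply(levels, groups, mean)),
      sd = as.numeric(tapply(levels, groups, sd)))
  }
  out
}
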