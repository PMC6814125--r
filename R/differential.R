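# TMM normalization, negative-binomial testing (quasi-likelihood F-test via
# edgeR), BH correction, replicate QC and contrast set logic.

#' TMM normalization factors
#'
#' Robinson-Oshlack weighted trimmed mean of M-values against a reference
#' library (30% M-trim, 5% A-trim, inverse-asymptotic-variance weights),
#' re-centered so the factors have geometric mean 1.
#'
#' @param counts Count matrix (features x libraries), at least 2 libraries.
#' @return List with `tmm_factor` (per library) and `effective_lib_size`
#'   (raw column total x factor).
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2L)
  lib_size <- colSums(counts)
  if (any(lib_size == 0)) stop("a library has zero total count")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  f <- f / exp(mean(log(f)))
  list(tmm_factor = setNames(f, colnames(counts)),
       effective_lib_size = setNames(lib_size * f, colnames(counts)))
}

#' Estimate negative-binomial dispersions
#'
#' Common dispersion by the (quantile-adjusted) conditional NB likelihood on
#' effective-library-size-equalized counts, and per-feature dispersions shrunk
#' toward the common value by empirical-Bayes weighting.
#'
#' @param counts Count matrix.
#' @param groups Group label per library (>= 2 replicates per group).
#' @param norm Output of [tmm_factors()] (computed if `NULL`).
#' @param prior_df Shrinkage strength toward the trended/common value.
#' @return List with `common_phi`, `phi` (per feature) and the underlying
#'   `DGEList` used by [nb_test()].
#' @export
estimate_dispersion <- function(counts, groups, norm = NULL, prior_df = 10) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  stopifnot(all(table(groups) >= 2L))
  if (is.null(norm)) norm <- tmm_factors(counts)
  y <- edgeR::DGEList(counts = counts, group = groups,
                      norm.factors = norm$tmm_factor)
  design <- stats::model.matrix(~groups)
  y <- edgeR::estimateDisp(y, design, prior.df = prior_df)
  list(common_phi = y$common.dispersion,
       phi = setNames(y$tagwise.dispersion, rownames(counts)),
       dge = y, design = design)
}

#' Two-group negative-binomial differential-abundance test
#'
#' Quasi-likelihood F-test on TMM-effective library sizes (the published
#' testing route), run on raw counts, never on RPTM. log2 fold changes are
#' computed from normalized group means with a prior count (default 0.125,
#' scaled by library size) so that all-zero groups give finite estimates.
#'
#' @param counts Count matrix.
#' @param groups Group label per library.
#' @param contrast Character vector `c(control, treatment)`; log2FC is
#'   treatment relative to control.
#' @param dispersion Output of [estimate_dispersion()] (computed if `NULL`).
#' @param prior_count Prior count for fold-change shrinkage (default 0.125).
#' @return Data frame `mirna_id`, `log2FC`, `pvalue`, `FDR`, `contrast`.
#' @export
nb_test <- function(counts, groups, contrast, dispersion = NULL,
                    prior_count = 0.125) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  stopifnot(length(contrast) == 2L, all(contrast %in% levels(groups)),
            contrast[1] != contrast[2])
  sel <- groups %in% contrast
  sub_groups <- factor(as.character(groups[sel]), levels = contrast)
  sub_counts <- counts[, sel, drop = FALSE]
  norm <- tmm_factors(sub_counts)
  y <- edgeR::DGEList(counts = sub_counts, group = sub_groups,
                      norm.factors = norm$tmm_factor)
  design <- stats::model.matrix(~sub_groups)
  if (is.null(dispersion)) {
    y <- edgeR::estimateDisp(y, design)
  } else {
    y$common.dispersion <- dispersion$common_phi
    y$tagwise.dispersion <- dispersion$phi[rownames(counts)]
    y$trended.dispersion <- dispersion$dge$trended.dispersion
  }
  fit <- edgeR::glmQLFit(y, design)
  qlf <- edgeR::glmQLFTest(fit, coef = 2L)
  lfc <- shrunken_log2fc(sub_counts, sub_groups, contrast,
                         norm$effective_lib_size, prior_count)
  data.frame(
    mirna_id = rownames(sub_counts),
    log2FC = lfc,
    edger_log2FC = qlf$table$logFC,
    pvalue = qlf$table$PValue,
    FDR = bh_adjust(qlf$table$PValue),
    contrast = paste0(contrast[2], "_vs_", contrast[1]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# log2FC from normalized group means with a library-size-scaled prior count;
# sign equals the sign of the normalized mean difference whenever both group
# means are nonzero.
shrunken_log2fc <- function(counts, groups, contrast, eff_size, prior_count) {
  pc <- prior_count * eff_size / mean(eff_size)
  rate <- function(g) {
    j <- which(groups == g)
    (rowSums(counts[, j, drop = FALSE]) + sum(pc[j])) / sum(eff_size[j])
  }
  log2(rate(contrast[2]) / rate(contrast[1]))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return FDR-adjusted values (monotone step-up).
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Set logic between two treatment contrasts
#'
#' Partitions significant miRNAs (FDR < `alpha`) into mild-only, severe-only
#' and shared sets, and counts shared miRNAs whose fold changes disagree in
#' sign between the contrasts.
#'
#' @param de_mild,de_severe Data frames with columns `mirna_id`, `log2FC`,
#'   `FDR`.
#' @param alpha Significance threshold on FDR (default 0.05).
#' @return List with `mild_only`, `severe_only`, `shared` (id vectors),
#'   `discordant_sign_count` and `union_count`.
#' @export
compare_contrasts <- function(de_mild, de_severe, alpha = 0.05) {
  sig_m <- unique(de_mild$mirna_id[de_mild$FDR < alpha])
  sig_s <- unique(de_severe$mirna_id[de_severe$FDR < alpha])
  shared <- intersect(sig_m, sig_s)
  disc <- 0L
  for (id in shared) {
    fm <- de_mild$log2FC[de_mild$mirna_id == id][1L]
    fs <- de_severe$log2FC[de_severe$mirna_id == id][1L]
    if (sign(fm) * sign(fs) < 0) disc <- disc + 1L
  }
  list(
    mild_only = setdiff(sig_m, sig_s),
    severe_only = setdiff(sig_s, sig_m),
    shared = shared,
    discordant_sign_count = disc,
    union_count = length(union(sig_m, sig_s))
  )
}

#' Replicate quality control: BCV, 2-D ordination and outlier flags
#'
#' Estimates the biological coefficient of variation (square root of the
#' common NB dispersion) on the `top_n` highest-count features of the
#' non-normalized counts, computes 2-D coordinates from leading log-fold-change
#' distances (MDS), and flags a library as an outlier when its median distance
#' to the other members of its group exceeds `k` MADs above the median of all
#' within-group distances and is more than 3x that median (the absolute guard
#' keeps ordinary replicate scatter from being flagged).
#'
#' @param counts Count matrix (>= 3 libraries).
#' @param groups Group label per library.
#' @param top_n Number of highest-count features used (default 100).
#' @param k Outlier threshold in MAD units (default 3).
#' @return List with `bcv`, `coords` (library x 2 matrix), `outliers`
#'   (character vector) and the within-group distance summary.
#' @export
replicate_qc <- function(counts, groups, top_n = 100L, k = 3) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 3L)
  groups <- as.factor(groups)
  top <- head(order(rowSums(counts), decreasing = TRUE), top_n)
  sub <- counts[top, , drop = FALSE]
  y <- edgeR::DGEList(counts = sub, group = groups)
  y <- edgeR::estimateCommonDisp(y)
  bcv <- sqrt(y$common.dispersion)
  mds <- limma::plotMDS(edgeR::cpm(y, log = TRUE), plot = FALSE)
  coords <- cbind(x = mds$x, y = mds$y)
  rownames(coords) <- colnames(counts)
  d <- as.matrix(stats::dist(coords))
  med_within <- vapply(seq_len(ncol(counts)), function(j) {
    peers <- setdiff(which(groups == groups[j]), j)
    if (!length(peers)) return(NA_real_)
    median(d[j, peers])
  }, numeric(1))
  m <- median(med_within, na.rm = TRUE)
  s <- stats::mad(med_within, na.rm = TRUE)
  # absolute guard (3x the typical within-group distance) keeps ordinary
  # replicate scatter from being flagged when the MAD happens to be tiny
  flag <- !is.na(med_within) & med_within > m + k * max(s, 1e-8) &
    med_within > 3 * m
  list(bcv = bcv, coords = coords,
       outliers = colnames(counts)[flag],
       within_group_distance = setNames(med_within, colnames(counts)))
}
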