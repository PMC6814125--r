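# Stem-loop RT-qPCR relative quantification by the ddCt method against
# invariant reference miRNAs.

# mean Ct per (target, treatment, bio_rep), collapsing technical replicates
collapse_tech <- function(ct_table) {
  stats::aggregate(ct ~ target_id + treatment + bio_rep, data = ct_table,
                   FUN = mean)
}

#' Select stable reference miRNAs from a Ct table
#'
#' Ranks candidates by the standard deviation of their treatment-mean Ct
#' values (after collapsing technical replicates) and returns those below the
#' stability threshold. Mirrors the study's choice of two miRNAs with stable
#' expression across water-deficit treatments as qPCR references.
#'
#' @param ct_table Data frame `target_id`, `treatment`, `bio_rep`, `tech_rep`,
#'   `ct`.
#' @param candidates Candidate target ids.
#' @param stability_sd Maximum SD of treatment means, in cycles (default 0.3).
#' @return Character vector of selected reference ids, most stable first.
#'   Errors (attaching the full ranking) when no candidate passes.
#' @export
select_reference <- function(ct_table, candidates, stability_sd = 0.3) {
  stopifnot(length(unique(ct_table$treatment)) >= 2L)
  ct <- collapse_tech(ct_table[ct_table$target_id %in% candidates, ,
                               drop = FALSE])
  means <- stats::aggregate(ct ~ target_id + treatment, data = ct, FUN = mean)
  sds <- tapply(means$ct, means$target_id, stats::sd)
  sds <- sort(sds)
  pass <- names(sds)[sds <= stability_sd]
  if (!length(pass)) {
    stop("no candidate passes the stability threshold; ranking (sd in cycles): ",
         paste(sprintf("%s=%.3f", names(sds), sds), collapse = ", "))
  }
  pass
}

#' Relative abundance by the ddCt method
#'
#' Technical replicates are collapsed by mean; per biological replicate,
#' dCt = Ct(target) - mean Ct over the reference miRNAs; ddCt subtracts the
#' calibrator-treatment mean dCt; RQ = 2^(-ddCt) (amplification efficiency
#' fixed at 2). The calibrator RQ is 1 by construction. The spread is the
#' standard error of per-replicate RQ values.
#'
#' @param ct_table Data frame `target_id`, `treatment`, `bio_rep`, `tech_rep`,
#'   `ct`.
#' @param reference_ids Reference miRNA ids present in all treatments.
#' @param calibrator Calibrator treatment (e.g. `"WW"`).
#' @return Data frame `target_id`, `treatment`, `RQ`, `se`, `n_bio`.
#' @export
ddct <- function(ct_table, reference_ids, calibrator) {
  stopifnot(all(reference_ids %in% ct_table$target_id))
  if (!calibrator %in% ct_table$treatment) stop("missing calibrator treatment")
  ct <- collapse_tech(ct_table)
  refs <- ct[ct$target_id %in% reference_ids, , drop = FALSE]
  ref_ct <- stats::aggregate(ct ~ treatment + bio_rep, data = refs, FUN = mean)
  names(ref_ct)[names(ref_ct) == "ct"] <- "ref_ct"
  targets <- setdiff(unique(ct$target_id), reference_ids)
  out <- list()
  for (tg in targets) {
    x <- merge(ct[ct$target_id == tg, , drop = FALSE], ref_ct,
               by = c("treatment", "bio_rep"))
    x$dct <- x$ct - x$ref_ct
    cal_dct <- mean(x$dct[x$treatment == calibrator])
    for (tr in unique(x$treatment)) {
      ddct_rep <- x$dct[x$treatment == tr] - cal_dct
      rq_rep <- 2^(-ddct_rep)
      out[[length(out) + 1L]] <- data.frame(
        target_id = tg, treatment = tr,
        RQ = 2^(-mean(ddct_rep)),
        se = stats::sd(rq_rep) / sqrt(length(rq_rep)),
        n_bio = length(rq_rep),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
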