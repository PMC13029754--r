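#' Welch's two-sample t-test
#'
#' Two-tailed unpaired t-test with the Welch-Satterthwaite degrees of
#' freedom, the test used for all phenotype and module-score group
#' comparisons. Degenerate inputs (both groups with zero variance) are
#' handled explicitly: equal means give t = 0, p = 1; unequal means give
#' p = 0.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return List: `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Acetylene-reduction (nitrogenase activity) rate
#'
#' Converts a measured ethylene amount to a production rate per unit
#' nodule fresh weight per hour: `amount / (incubation_h * nodule_fw_g)`.
#' Units are the caller's responsibility and propagate through; the
#' standard assay here uses 0.10 g of fresh nodules.
#'
#' @param ethylene_amount Ethylene produced (caller's units).
#' @param incubation_h Incubation time in hours, > 0.
#' @param nodule_fw_g Nodule fresh weight in grams, > 0.
#' @return Rate per gram per hour.
#' @examples
#' ara_rate(2.34, 1, 0.10)   # 23.4
#' @export
ara_rate <- function(ethylene_amount, incubation_h, nodule_fw_g) {
  if (any(incubation_h <= 0) || any(nodule_fw_g <= 0)) {
    stop("incubation time and nodule mass must be > 0", call. = FALSE)
  }
  if (any(ethylene_amount < 0)) stop("ethylene amount must be >= 0", call. = FALSE)
  ethylene_amount / (incubation_h * nodule_fw_g)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical-replicate Ct values are averaged first; per biological
#' replicate, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the mean
#' dCt of the calibrator treatment per gene; relative quantity is
#' `RQ = 2^-ddCt`. Summaries are mean +/- SEM (SD/sqrt(n)) over the
#' biological replicates of each treatment. Adding any constant to every
#' Ct (a machine offset) leaves the result unchanged.
#'
#' The input is long-format with columns `target_gene`, `reference_gene`,
#' `treatment`, `replicate`, `tech_rep`, `ct`; the reference gene's own
#' wells appear as rows with `target_gene == reference_gene`.
#'
#' @param qpcr Long-format qPCR data frame as above.
#' @param calibrator Treatment used as calibrator (default `"WE2"`; RQ
#'   ratios between treatments are calibrator-invariant).
#' @return List: `per_replicate` (gene x treatment x replicate dCt, ddCt,
#'   RQ) and `summary` (per gene and treatment: `mean_rq`, `sem_rq`, `n`).
#' @export
ddct <- function(qpcr, calibrator = "WE2") {
  need <- c("target_gene", "reference_gene", "treatment", "replicate", "ct")
  miss <- setdiff(need, names(qpcr))
  if (length(miss)) stop("qPCR table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(qpcr$ct <= 0 | qpcr$ct >= 45)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  if (!calibrator %in% qpcr$treatment) {
    stop("calibrator treatment '", calibrator, "' not present", call. = FALSE)
  }
  # mean over technical replicates
  agg <- stats::aggregate(ct ~ target_gene + reference_gene + treatment + replicate,
                          data = qpcr, FUN = mean)
  is_ref <- agg$target_gene == agg$reference_gene
  refs <- agg[is_ref, c("reference_gene", "treatment", "replicate", "ct")]
  names(refs)[4] <- "ct_ref"
  tg <- agg[!is_ref, , drop = FALSE]
  if (!nrow(tg)) stop("no target-gene rows in the qPCR table", call. = FALSE)
  dd <- merge(tg, refs, by = c("reference_gene", "treatment", "replicate"),
              all.x = TRUE)
  if (anyNA(dd$ct_ref)) {
    bad <- dd[is.na(dd$ct_ref), ]
    stop("missing reference Ct for replicate(s): ",
         paste(unique(paste0(bad$treatment, "_", bad$replicate)), collapse = ", "),
         call. = FALSE)
  }
  dd$dct <- dd$ct - dd$ct_ref
  cal_mean <- stats::aggregate(dct ~ target_gene,
                               data = dd[dd$treatment == calibrator, ],
                               FUN = mean)
  names(cal_mean)[2] <- "dct_cal"
  dd <- merge(dd, cal_mean, by = "target_gene")
  dd$ddct <- dd$dct - dd$dct_cal
  dd$rq <- 2^(-dd$ddct)
  summ <- do.call(rbind, lapply(split(dd, list(dd$target_gene, dd$treatment),
                                      drop = TRUE), function(s) {
    data.frame(target_gene = s$target_gene[1], treatment = s$treatment[1],
               mean_rq = mean(s$rq),
               sem_rq = stats::sd(s$rq) / sqrt(nrow(s)),
               n = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_replicate = dd[, c("target_gene", "reference_gene", "treatment",
                              "replicate", "dct", "ddct", "rq")],
       summary = summ)
}

#' Log2 RQ ratio between treatments from a ddCt summary
#'
#' `log2(mean RQ in numerator / mean RQ in denominator)` per gene; with
#' the default orientation (WE2 over WWL2) a positive value means higher
#' expression in WE2, i.e. the same direction as a *negative* RNA-seq
#' log2(WWL2/WE2) fold change.
#'
#' @param ddct_summary The `summary` element of [ddct()].
#' @param numerator,denominator Treatment labels.
#' @return Named numeric vector of log2 ratios per target gene.
#' @export
rq_log2_ratio <- function(ddct_summary, numerator = "WE2",
                          denominator = "WWL2") {
  num <- ddct_summary[ddct_summary$treatment == numerator, ]
  den <- ddct_summary[ddct_summary$treatment == denominator, ]
  shared <- intersect(num$target_gene, den$target_gene)
  if (!length(shared)) stop("no genes measured in both treatments", call. = FALSE)
  stats::setNames(
    log2(num$mean_rq[match(shared, num$target_gene)] /
           den$mean_rq[match(shared, den$target_gene)]),
    shared)
}

#' Direction concordance between qPCR and RNA-seq
#'
#' Fraction of shared genes whose qPCR between-treatment direction agrees
#' with RNA-seq: the qPCR log2 RQ ratio is oriented WE2/WWL2 (see
#' [rq_log2_ratio()]) while the RNA-seq fold change is log2(WWL2/WE2), so
#' agreement means `sign(qpcr_ratio) == sign(-log2fc)`.
#'
#' @param qpcr_log2_ratio Named vector of per-gene log2 RQ ratios
#'   (WE2/WWL2).
#' @param rnaseq_log2fc Named vector of per-gene RNA-seq log2 fold
#'   changes (WWL2/WE2).
#' @return List: `fraction` (agreement over shared genes) and `per_gene`
#'   data frame.
#' @export
concordance <- function(qpcr_log2_ratio, rnaseq_log2fc) {
  shared <- intersect(names(qpcr_log2_ratio), names(rnaseq_log2fc))
  if (!length(shared)) stop("no shared gene ids", call. = FALSE)
  q <- qpcr_log2_ratio[shared]
  r <- rnaseq_log2fc[shared]
  agree <- sign(q) == sign(-r)
  list(fraction = mean(agree),
       per_gene = data.frame(gene_id = shared, qpcr_log2_ratio = unname(q),
                             rnaseq_log2fc = unname(r), agree = unname(agree),
                             stringsAsFactors = FALSE))
}
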