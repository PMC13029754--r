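#' Method-of-moments negative-binomial dispersion with shrinkage
#'
#' Per-gene dispersion `phi_g` is estimated by method of moments on
#' effective-library-normalized counts: with pooled within-group sample
#' variance `s2_g` and grand mean `mu_g`,
#' `phi_g = max(0, (s2_g - mu_g) / mu_g^2)`. A common dispersion
#' `phi_bar` (median of the positive per-gene values) is blended in as
#' `phi* = (1 - w) * phi_g + w * phi_bar`, default `w = 0.3`, to stabilize
#' the noisy per-gene estimates at n = 3 per group.
#'
#' @param counts Gene-by-sample count matrix.
#' @param groups Sample table or group label vector (two groups, each with
#'   >= 2 replicates).
#' @param factors Optional TMM factors.
#' @param shrink_weight Weight `w` on the common dispersion, in `[0, 1]`.
#' @return List of class `dispersion_estimate`: `phi` (raw per-gene),
#'   `phi_shrunk`, `common`, `shrink_weight`.
#' @export
estimate_dispersion <- function(counts, groups, factors = NULL,
                                shrink_weight = 0.3) {
  m <- unclass(counts)
  g <- group_labels(groups, colnames(m))
  tab <- table(g)
  if (length(tab) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (any(tab < 2L)) {
    stop("each group needs >= 2 replicates for dispersion estimation",
         call. = FALSE)
  }
  eff <- colSums(m) * resolve_factors(factors, colnames(m))
  scale_to <- exp(mean(log(eff)))
  z <- sweep(m, 2L, eff, "/") * scale_to

  lv <- levels(g)
  idx1 <- which(g == lv[1]); idx2 <- which(g == lv[2])
  m1 <- rowMeans(z[, idx1, drop = FALSE])
  m2 <- rowMeans(z[, idx2, drop = FALSE])
  ss <- rowSums((z[, idx1, drop = FALSE] - m1)^2) +
    rowSums((z[, idx2, drop = FALSE] - m2)^2)
  s2 <- ss / (length(idx1) + length(idx2) - 2L)
  mu <- rowMeans(z)
  phi <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  pos <- phi[phi > 0]
  common <- if (length(pos)) stats::median(pos) else 0
  phi_star <- (1 - shrink_weight) * phi + shrink_weight * common
  structure(list(phi = phi, phi_shrunk = phi_star, common = common,
                 shrink_weight = shrink_weight),
            class = "dispersion_estimate")
}

#' Conditional exact negative-binomial test for one gene
#'
#' Two-group test on raw counts. Libraries are first equalized by scaling
#' each sample's count to the geometric mean of the effective library
#' sizes (rounded to the nearest integer, keeping the enumeration exact on
#' integers). Conditioning on the equalized total `t = A + B`, every split
#' `(s, t - s)` is enumerated under the null that both group sums are
#' negative-binomial (group of n replicates at common mean: mean `n*mu0`,
#' dispersion `phi/n`); the two-sided p-value is the total conditional
#' probability of splits no more likely than the observed one. `phi = 0`
#' reduces to the Poisson limit, i.e. a conditional binomial test.
#'
#' @param a,b Raw counts of the gene in groups A and B.
#' @param phi Shrunk dispersion for the gene, >= 0.
#' @param lib_a,lib_b Effective library sizes (library size times TMM
#'   factor) for the samples of each group.
#' @return Two-sided p-value in `(0, 1]`; `p = 1` when the total is 0.
#' @export
nb_exact_test <- function(a, b, phi, lib_a, lib_b) {
  if (any(c(a, b) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(c(lib_a, lib_b) <= 0)) stop("effective library sizes must be > 0",
                                      call. = FALSE)
  if (phi < 0) stop("dispersion must be >= 0", call. = FALSE)
  Nstar <- exp(mean(log(c(lib_a, lib_b))))
  A <- sum(round(a * Nstar / lib_a))
  B <- sum(round(b * Nstar / lib_b))
  t <- A + B
  if (t == 0) return(1)
  nA <- length(a); nB <- length(b)
  mu0 <- t / (nA + nB)
  s <- 0:t
  if (phi == 0) {
    lp <- stats::dpois(s, nA * mu0, log = TRUE) +
      stats::dpois(t - s, nB * mu0, log = TRUE)
  } else {
    lp <- stats::dnbinom(s, size = nA / phi, mu = nA * mu0, log = TRUE) +
      stats::dnbinom(t - s, size = nB / phi, mu = nB * mu0, log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / sum(p)
  min(1, sum(p[p <= p[A + 1L] * (1 + 1e-12)]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (same order as the input).
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Log2 fold change from group mean expression
#'
#' `log2((mean_WWL2 + pseudo) / (mean_WE2 + pseudo))`: the global
#' orientation is log2(WWL2/WE2), so negative values mean higher
#' expression in WE2. A pseudo-count (default 0.5 CPM) stabilizes genes
#' with zero means; it affects reported fold changes only, never the test
#' statistic.
#'
#' @param mean_a Mean expression in the reference group (WE2).
#' @param mean_b Mean expression in the comparison group (WWL2).
#' @param pseudo Pseudo-count added to both means.
#' @return Numeric log2 fold change(s).
#' @export
log2fc <- function(mean_a, mean_b, pseudo = 0.5) {
  if (any(c(mean_a, mean_b) < 0)) stop("means must be >= 0", call. = FALSE)
  log2((mean_b + pseudo) / (mean_a + pseudo))
}

#' Classify differentially expressed genes
#'
#' A gene is a DEG iff `fdr < fdr_threshold` (strict) and
#' `|log2fc| >= lfc_threshold` (inclusive); the direction label follows
#' the log2(WWL2/WE2) orientation.
#'
#' @param de Data frame with columns `log2fc` and `fdr` (e.g. from
#'   [de_analysis()]).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1).
#' @return The input with a `status` factor
#'   (`higher_in_WE2`/`higher_in_WWL2`/`ns`) and attribute `summary`, a
#'   named count vector `(n_total, n_higher_in_WE2, n_higher_in_WWL2)`.
#' @examples
#' call_degs(data.frame(gene_id = "ENOD93", log2fc = -2.079, fdr = 1.53e-10))
#' @export
call_degs <- function(de, fdr_threshold = 0.05, lfc_threshold = 1) {
  stopifnot(all(c("log2fc", "fdr") %in% names(de)))
  sig <- de$fdr < fdr_threshold & abs(de$log2fc) >= lfc_threshold
  status <- rep("ns", nrow(de))
  status[sig & de$log2fc <= -lfc_threshold] <- "higher_in_WE2"
  status[sig & de$log2fc >= lfc_threshold] <- "higher_in_WWL2"
  de$status <- factor(status, levels = c("higher_in_WE2", "higher_in_WWL2", "ns"))
  attr(de, "summary") <- c(n_total = sum(status != "ns"),
                           n_higher_in_WE2 = sum(status == "higher_in_WE2"),
                           n_higher_in_WWL2 = sum(status == "higher_in_WWL2"))
  de
}

#' Two-group differential expression on raw counts
#'
#' Runs the full DE stage for one partner: shrunk method-of-moments
#' dispersions ([estimate_dispersion()]), the conditional exact NB test
#' per gene ([nb_exact_test()]), BH-FDR ([bh_adjust()]), pseudo-counted
#' CPM fold changes oriented log2(WWL2/WE2), and DEG classification
#' ([call_degs()]). Counts are expected to be pre-filtered
#' ([filter_low_expression()]).
#'
#' @inheritParams estimate_dispersion
#' @param fdr_threshold,lfc_threshold DEG thresholds (0.05, 1).
#' @param pseudo Pseudo-count in CPM for the reported fold change.
#' @return Data frame: `gene_id`, `log2fc`, `pvalue`, `fdr`, `mean_cpm`,
#'   `status`; DEG summary in attribute `summary`.
#' @export
de_analysis <- function(counts, groups, factors = NULL, shrink_weight = 0.3,
                        fdr_threshold = 0.05, lfc_threshold = 1, pseudo = 0.5) {
  m <- unclass(counts)
  g <- group_labels(groups, colnames(m))
  if (nlevels(g) != 2L) stop("exactly two groups are required", call. = FALSE)
  disp <- estimate_dispersion(m, g, factors, shrink_weight)
  f <- resolve_factors(factors, colnames(m))
  eff <- colSums(m) * f
  ia <- which(g == levels(g)[1L])   # WE2 first by factor level convention
  ib <- which(g == levels(g)[2L])
  pv <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_test(m[i, ia], m[i, ib], disp$phi_shrunk[i], eff[ia], eff[ib])
  }, numeric(1))
  cpm_m <- cpm(m, factors)
  mean_a <- rowMeans(cpm_m[, ia, drop = FALSE])
  mean_b <- rowMeans(cpm_m[, ib, drop = FALSE])
  res <- data.frame(gene_id = rownames(m),
                    log2fc = log2fc(mean_a, mean_b, pseudo),
                    pvalue = pv,
                    fdr = bh_adjust(pv),
                    mean_cpm = rowMeans(cpm_m),
                    stringsAsFactors = FALSE, row.names = NULL)
  call_degs(res, fdr_threshold, lfc_threshold)
}

#' PCA of samples on log2(CPM + 1)
#'
#' Sample-level quality control: genes are centered and the principal
#' components of the sample covariance are returned, with the percent of
#' variance each explains. All (filtered) genes are used; there is no
#' variance pre-selection.
#'
#' @param log_expr Matrix of log-scale expression (genes x samples),
#'   typically `log2(cpm(counts, factors) + 1)`.
#' @param n_components Number of components to return (default all).
#' @return List: `coordinates` (samples x components) and
#'   `percent_variance`.
#' @export
pca_samples <- function(log_expr, n_components = NULL) {
  if (ncol(log_expr) < 3L) stop("PCA needs >= 3 samples", call. = FALSE)
  pc <- stats::prcomp(t(log_expr), center = TRUE, scale. = FALSE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_components)) length(pct) else min(n_components, length(pct))
  list(coordinates = pc$x[, seq_len(k), drop = FALSE],
       percent_variance = pct[seq_len(k)])
}
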