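#' Counts per million
#'
#' `CPM_gj = 1e6 * y_gj / (N_j * f_j)` with `N_j` the library size
#' (column sum) and `f_j` an optional TMM normalization factor.
#'
#' @param counts Gene-by-sample count matrix.
#' @param factors Optional [tmm_factors()] result or named numeric vector
#'   of per-sample factors; `NULL` means unit factors.
#' @return Numeric matrix of the same shape.
#' @export
cpm <- function(counts, factors = NULL) {
  m <- unclass(counts)
  N <- colSums(m)
  if (any(N <= 0)) stop("zero library size: CPM undefined", call. = FALSE)
  f <- resolve_factors(factors, colnames(m))
  sweep(m, 2L, N * f, "/") * 1e6
}

#' Fragments/reads per kilobase per million
#'
#' `FPKM_gj = 1e9 * y_gj / (N_j * f_j * len_g)`. Computed identically for
#' the host (FPKM) and the symbiont (RPKM); pass TMM factors for the
#' effective-library-size variant or `NULL` for the raw one.
#'
#' @inheritParams cpm
#' @param lengths Named numeric vector of gene lengths in bp, or an
#'   annotation data frame with columns `gene_id` and `length_bp`.
#' @return Numeric matrix of the same shape as `counts`.
#' @export
fpkm <- function(counts, lengths, factors = NULL) {
  m <- unclass(counts)
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length_bp, lengths$gene_id)
  }
  miss <- setdiff(rownames(m), names(lengths))
  if (length(miss)) {
    stop("missing gene length(s): ", paste(utils::head(miss, 10), collapse = ", "),
         call. = FALSE)
  }
  len <- lengths[rownames(m)]
  if (any(len < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  cpm(m, factors) * 1e3 / len
}

#' Filter lowly expressed genes
#'
#' Keeps gene g iff its CPM reaches `C = 10 / (median library size in
#' millions)` in at least `k` samples, where `k` is the smallest group
#' size, and its total count across samples is at least 15. This is the
#' library-size- and group-size-adjusted CPM rule used to suppress
#' low-count false positives in the sparse symbiont libraries (and applied
#' to both partners).
#'
#' @param counts Gene-by-sample count matrix.
#' @param groups Sample-table data frame (column `treatment`) or a
#'   factor/character vector of group labels aligned with columns.
#' @param min_count Minimum total count per gene (default 15).
#' @param min_cpm_numerator Numerator of the adaptive CPM cutoff (10).
#' @return Character vector of kept gene ids.
#' @export
filter_low_expression <- function(counts, groups, min_count = 15,
                                  min_cpm_numerator = 10) {
  m <- unclass(counts)
  if (ncol(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  g <- group_labels(groups, colnames(m))
  N <- colSums(m)
  C <- min_cpm_numerator / (stats::median(N) / 1e6)
  k <- min(table(g))
  cpm_m <- cpm(m)
  keep <- rowSums(cpm_m >= C) >= k & rowSums(m) >= min_count
  if (!any(keep)) stop("all genes removed by the expression filter", call. = FALSE)
  rownames(m)[keep]
}

group_labels <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    if (!is.null(groups$sample_id) && !is.null(sample_ids)) {
      idx <- match(sample_ids, groups$sample_id)
      if (anyNA(idx)) stop("sample id(s) missing from sample table", call. = FALSE)
      groups <- groups[idx, , drop = FALSE]
    }
    g <- groups$treatment
  } else {
    g <- groups
  }
  g <- factor(g)
  if (length(g) != length(sample_ids)) {
    stop("group labels do not match the sample columns", call. = FALSE)
  }
  g
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample normalization for compositional differences. The
#' reference is the sample whose upper quartile of nonzero CPM is closest
#' to the mean of those upper quartiles (lowest column index on ties). For
#' each sample k against the reference r, over genes with nonzero counts
#' in both, per-gene log ratios `M = log2((y_k/N_k)/(y_r/N_r))` and
#' average log abundances `A = 0.5*log2((y_k/N_k)*(y_r/N_r))` are formed;
#' the top and bottom 30% by M and 5% by A are discarded, and the factor
#' is `2^(sum(w*M)/sum(w))` with inverse-variance (delta-method) weights
#' `w = 1/((N_k - y_k)/(N_k y_k) + (N_r - y_r)/(N_r y_r))`. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Gene-by-sample count matrix (>= 2 samples, each with at
#'   least one nonzero gene).
#' @param logratio_trim,abs_trim Two-sided trim fractions for M and A.
#' @return Object of class `norm_factors`: named numeric vector of
#'   factors with attributes `reference` (reference sample id) and
#'   `lib_sizes`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  m <- unclass(counts)
  if (ncol(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  N <- colSums(m)
  if (any(N <= 0)) stop("sample with no nonzero gene", call. = FALSE)
  cpm_m <- sweep(m, 2L, N, "/") * 1e6
  uq <- apply(cpm_m, 2L, function(col) stats::quantile(col[col > 0], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(k) {
    tmm_pair_factor(m[, k], m[, ref], N[k], N[ref], logratio_trim, abs_trim,
                    colnames(m)[k])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(stats::setNames(f, colnames(m)), reference = colnames(m)[ref],
            lib_sizes = N, class = "norm_factors")
}

tmm_pair_factor <- function(yk, yr, Nk, Nr, logratio_trim, abs_trim, label) {
  ok <- yk > 0 & yr > 0
  yk <- yk[ok]; yr <- yr[ok]
  if (!length(yk)) {
    warning("no shared nonzero genes for sample ", label, "; factor set to 1",
            call. = FALSE)
    return(1)
  }
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  if (max(abs(M)) < 1e-6) return(1)   # identical composition
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) {
    warning("no genes survive TMM trimming for sample ", label,
            "; factor set to 1", call. = FALSE)
    return(1)
  }
  w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("TMM normalization factors (reference:", attr(x, "reference"), ")\n")
  print(round(unclass(x), 4))
  invisible(x)
}

resolve_factors <- function(factors, sample_ids) {
  if (is.null(factors)) return(rep(1, length(sample_ids)))
  f <- unclass(factors)
  if (!is.null(names(f)) && !is.null(sample_ids)) {
    idx <- match(sample_ids, names(f))
    if (anyNA(idx)) stop("normalization factors missing for some samples",
                         call. = FALSE)
    f <- f[idx]
  }
  if (length(f) != length(sample_ids)) {
    stop("factor length does not match sample count", call. = FALSE)
  }
  if (any(f <= 0)) stop("normalization factors must be > 0", call. = FALSE)
  unname(f)
}
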