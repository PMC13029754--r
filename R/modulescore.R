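#' Single-sample module scores (mean of per-gene z-scores)
#'
#' The core descriptive statistic of the analysis. Expression `x_ij`
#' (FPKM for the host, RPKM for the symbiont) is transformed to
#' `t_ij = log2(x_ij + 1)`, standardized per gene across samples
#' (`z_ij = (t_ij - mean_i) / sd_i`, sample SD with denominator n - 1),
#' and averaged over the genes of each predefined module:
#' `Score_j = mean_i(z_ij)`. By construction every module's scores sum to
#' zero across samples, so with equal group sizes the two treatment means
#' are exact negatives of each other. Scores are relative expression
#' tendencies, not absolute units.
#'
#' Genes absent from the expression matrix are ignored (a module with no
#' genes present is an error); genes with zero variance across samples
#' have undefined z-scores and are excluded with a warning rather than
#' imputed, so they cannot silently dilute the score.
#'
#' @param expr Expression matrix (genes x samples), linear scale unless
#'   `log_transform = FALSE`.
#' @param modules List of module definitions ([module_definition()] /
#'   [read_gene_sets()]).
#' @param log_transform Apply `log2(x + 1)` first (default TRUE).
#' @param sd_denom `"n-1"` (sample SD, default) or `"n"` (population SD);
#'   the zero-sum property holds either way.
#' @return Object of class `module_score_table`: modules x samples score
#'   matrix with attributes `n_genes` (genes used per module) and
#'   `excluded` (zero-variance genes per module).
#' @export
module_scores <- function(expr, modules, log_transform = TRUE,
                          sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  m <- as.matrix(expr)
  if (ncol(m) < 2L) stop("module scores need >= 2 samples", call. = FALSE)
  if (!is.list(modules[[1]])) modules <- list(modules)
  tmat <- if (log_transform) log2(m + 1) else m

  missing_mods <- Filter(function(mod) !any(mod$gene_ids %in% rownames(tmat)),
                         modules)
  if (length(missing_mods)) {
    stop("module(s) with no genes in the expression matrix: ",
         paste(vapply(missing_mods, `[[`, "", "module_id"), collapse = ", "),
         call. = FALSE)
  }

  n <- ncol(tmat)
  ctr <- tmat - rowMeans(tmat)
  denom <- if (sd_denom == "n-1") n - 1L else n
  sds <- sqrt(rowSums(ctr^2) / denom)

  scores <- matrix(NA_real_, nrow = length(modules), ncol = n,
                   dimnames = list(vapply(modules, `[[`, "", "module_id"),
                                   colnames(m)))
  n_genes <- integer(length(modules))
  excluded <- vector("list", length(modules))
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    present <- intersect(mod$gene_ids, rownames(tmat))
    zero_var <- present[sds[present] == 0]
    use <- setdiff(present, zero_var)
    if (length(zero_var)) {
      warning("module '", mod$module_id, "': ", length(zero_var),
              " zero-variance gene(s) excluded from the score", call. = FALSE)
    }
    if (!length(use)) {
      stop("module '", mod$module_id,
           "': all genes have zero variance, score undefined", call. = FALSE)
    }
    z <- ctr[use, , drop = FALSE] / sds[use]
    scores[i, ] <- colMeans(z)
    n_genes[i] <- length(use)
    excluded[[i]] <- zero_var
  }
  names(excluded) <- rownames(scores)
  structure(scores, n_genes = stats::setNames(n_genes, rownames(scores)),
            excluded = excluded, class = c("module_score_table", "matrix"))
}

#' Per-treatment module score summaries with significance letters
#'
#' Mean and SD of the per-sample scores per treatment, plus compact-letter
#' significance: the groups get different letters iff a two-tailed Welch
#' t-test on the per-sample scores has p < `alpha`; the higher-mean group
#' is lettered "a". With equal group sizes the two means are exact
#' negatives (consequence of the zero-sum construction).
#'
#' @param scores A [module_scores()] result (modules x samples).
#' @param groups Sample table or group label vector aligned with the
#'   score columns.
#' @param alpha Significance level for the letters (0.05).
#' @return Data frame: `module_id`, `mean_WE2`, `sd_WE2`, `letter_WE2`,
#'   `mean_WWL2`, `sd_WWL2`, `letter_WWL2`, `p_welch`.
#' @export
score_group_summary <- function(scores, groups, alpha = 0.05) {
  s <- unclass(scores)
  g <- group_labels(groups, colnames(s))
  if (nlevels(g) != 2L) stop("exactly two treatments are required", call. = FALSE)
  if (any(table(g) < 2L)) stop("each treatment needs >= 2 replicates", call. = FALSE)
  lv <- levels(g)
  out <- lapply(rownames(s), function(mod) {
    a <- s[mod, g == lv[1]]
    b <- s[mod, g == lv[2]]
    wt <- welch_t(a, b)
    diff_letters <- wt$p < alpha
    la <- "a"
    lb <- if (!diff_letters) "a" else "b"
    if (diff_letters && mean(b) > mean(a)) { la <- "b"; lb <- "a" }
    data.frame(module_id = mod,
               mean_WE2 = mean(a), sd_WE2 = stats::sd(a), letter_WE2 = la,
               mean_WWL2 = mean(b), sd_WWL2 = stats::sd(b), letter_WWL2 = lb,
               p_welch = wt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sided p-value for a Pearson correlation coefficient
#'
#' Exact t-transform: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a
#' Student t distribution with `n - 2` degrees of freedom. `|r| = 1` gives
#' p = 0 (degenerate).
#'
#' @param r Pearson coefficient in `[-1, 1]`.
#' @param n Number of paired observations, >= 3.
#' @return Two-sided p-value.
#' @examples
#' pearson_pvalue(0.923, 6)   # ~0.0087
#' @export
pearson_pvalue <- function(r, n) {
  if (abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Cross-partner module coupling test
#'
#' Pearson correlation between the per-sample scores of two modules
#' (typically one host and one symbiont module over the same samples),
#' with the exact t-transform p-value. Perfect collinearity is flagged
#' (`degenerate = TRUE`, p reported as 0).
#'
#' @param scores_m1,scores_m2 Aligned numeric score vectors over the same
#'   samples (n >= 3).
#' @return List of class `coupling_result`: `r`, `p`, `n`, `degenerate`.
#' @export
coupling <- function(scores_m1, scores_m2) {
  n <- length(scores_m1)
  if (length(scores_m2) != n) stop("score vectors must be aligned", call. = FALSE)
  if (n < 3) stop("coupling needs >= 3 samples", call. = FALSE)
  if (stats::sd(scores_m1) == 0 || stats::sd(scores_m2) == 0) {
    stop("undefined correlation: a score vector has zero variance", call. = FALSE)
  }
  r <- stats::cor(scores_m1, scores_m2)
  degenerate <- abs(r) >= 1 - 1e-12
  p <- if (degenerate) 0 else pearson_pvalue(r, n)
  structure(list(r = r, p = p, n = n, degenerate = degenerate),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("module coupling: Pearson r = %.3f, p = %.3g, n = %d%s\n",
              x$r, x$p, x$n, if (x$degenerate) " (degenerate: |r| = 1)" else ""))
  invisible(x)
}
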