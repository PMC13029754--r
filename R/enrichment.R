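#' Gene-set over-representation analysis (hypergeometric)
#'
#' One-sided over-representation of a DEG list against a user-supplied
#' term catalog. Each term is intersected with the universe first; terms
#' left empty are skipped. The p-value is the hypergeometric upper tail
#' `P(X >= k)` for drawing `n` DEGs from a universe of `N` genes of which
#' `K` carry the term; BH-FDR is computed across all tested terms and
#' significance is `fdr < 0.05` by convention. The recommended universe is
#' the set of genes surviving [filter_low_expression()], not the whole
#' annotation.
#'
#' @param de_genes Character vector of DEG ids (must be a subset of
#'   `universe`). Direction-specific lists (only up- or only
#'   down-regulated genes) partition the full list; record which via
#'   `direction`.
#' @param universe Character vector of background gene ids.
#' @param terms List of term definitions ([module_definition()] /
#'   [read_gene_sets()]).
#' @param direction Label stored with the result: `"all"`, `"up"` or
#'   `"down"`.
#' @return Data frame: `term_id`, `k`, `K`, `n`, `N`, `pvalue`, `fdr`,
#'   `direction`, `genes` (comma-joined DEG members), sorted by p-value.
#' @export
ora <- function(de_genes, universe, terms, direction = c("all", "up", "down")) {
  direction <- match.arg(direction)
  universe <- unique(as.character(universe))
  de_genes <- unique(as.character(de_genes))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  stray <- setdiff(de_genes, universe)
  if (length(stray)) {
    stop("DEG(s) not in the universe: ",
         paste(utils::head(stray, 10), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  n <- length(de_genes)
  rows <- lapply(terms, function(tm) {
    members <- intersect(tm$gene_ids, universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    hits <- intersect(members, de_genes)
    k <- length(hits)
    data.frame(term_id = tm$module_id, k = k, K = K, n = n, N = N,
               pvalue = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               genes = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      fdr = numeric(), direction = character(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$pvalue)
  res$direction <- direction
  res <- res[order(res$pvalue), c("term_id", "k", "K", "n", "N",
                                  "pvalue", "fdr", "direction", "genes")]
  rownames(res) <- NULL
  res
}
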