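# Desk-scale generator configuration used across tests: same structure as
# the default study design, reduced gene universe and depth for speed.
small_sim_config <- function(seed, ...) {
  args <- list(
    seed = seed,
    n_host_genes = 300L, n_symbiont_genes = 200L,
    total_reads_mean = 3e5,
    module_sizes = list(host = c(hostSupply = 25L),
                        symbiont = c(symbiontFix = 25L,
                                     nodulationSurface = 15L,
                                     chemotaxisMotility = 15L,
                                     transportNutrient = 15L)))
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# expression matrix whose log2(x + 1) equals a given matrix of log values
expr_from_log <- function(tmat) 2^tmat - 1

make_counts <- function(values, n_genes, sample_ids = NULL, genes = NULL) {
  m <- matrix(values, nrow = n_genes, byrow = TRUE)
  rownames(m) <- genes %||% paste0("g", seq_len(n_genes))
  colnames(m) <- sample_ids %||% paste0("s", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

two_groups <- function(n = 3) factor(rep(c("WE2", "WWL2"), each = n),
                                     levels = c("WE2", "WWL2"))
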