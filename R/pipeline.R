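#' Configuration for an end-to-end run
#'
#' Collects thresholds, input locations (or the simulate flag) and the
#' output directory for [run_all()].
#'
#' @param out_dir Output directory.
#' @param simulate Generate the input experiment with
#'   [simulate_experiment()] (default) instead of loading files.
#' @param seed RNG seed; mandatory when `simulate = TRUE`.
#' @param sim Named list of [sim_config()] overrides.
#' @param paths When `simulate = FALSE`: named list with `host_counts`,
#'   `symbiont_counts`, `samples`, `annotation`, `modules_gmt`, and
#'   optionally `phenotypes`, `qpcr` (the layout [write_experiment()]
#'   produces).
#' @param fdr_threshold,lfc_threshold DEG thresholds (0.05, 1).
#' @param enrich_fdr Enrichment significance threshold (0.05).
#' @param pseudo Pseudo-count (CPM) for reported fold changes.
#' @param coupled_pair Module pair tested for cross-partner coupling.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = TRUE, seed = NULL, sim = list(),
                       paths = list(), fdr_threshold = 0.05,
                       lfc_threshold = 1, enrich_fdr = 0.05, pseudo = 0.5,
                       coupled_pair = c("hostSupply", "symbiontFix")) {
  if (fdr_threshold <= 0 || lfc_threshold <= 0 || enrich_fdr <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (simulate && is.null(seed)) {
    stop("a seed is required when simulate = TRUE", call. = FALSE)
  }
  structure(list(out_dir = out_dir, simulate = simulate, seed = seed,
                 sim = sim, paths = paths, fdr_threshold = fdr_threshold,
                 lfc_threshold = lfc_threshold, enrich_fdr = enrich_fdr,
                 pseudo = pseudo, coupled_pair = coupled_pair),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path Path to a YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full dual-transcriptome analysis
#'
#' Orchestrates simulate-or-load, low-expression filtering, TMM
#' normalization, differential expression, PCA, over-representation,
#' module scoring, cross-partner coupling, candidate-gene screening,
#' phenotype tests and qPCR quantification, writing tab-separated outputs
#' (`de.tsv`, `enrichment.tsv`, `scores.tsv`, `scores_summary.tsv`,
#' `coupling.tsv`, `candidates.tsv`, `pca.tsv`, `pheno.tsv`, `qpcr.tsv`)
#' plus a machine-readable `summary.json` and a `run.log` to the output
#' directory. Candidate genes are DEGs that belong to a module and whose
#' direction matches the sign of that module's WE2 group-mean score.
#' Reruns with an identical config are identical (stochastic stages are
#' seeded).
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  cat("", file = logfile)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  dat <- stage("input", acquire_inputs(config))
  samples <- dat$samples
  tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  de_tabs <- list(); enr_tabs <- list(); pca_tabs <- list()
  score_rows <- list(); summ_rows <- list(); score_mats <- list()
  stage_counts <- list()

  for (partner in c("host", "symbiont")) {
    counts <- dat[[partner]]
    kept <- stage(paste0("filter_", partner),
                  filter_low_expression(counts, samples))
    cf <- unclass(counts)[kept, , drop = FALSE]
    factors <- stage(paste0("normalize_", partner), tmm_factors(cf))
    de <- stage(paste0("de_", partner),
                de_analysis(cf, samples, factors,
                            fdr_threshold = config$fdr_threshold,
                            lfc_threshold = config$lfc_threshold,
                            pseudo = config$pseudo))
    de$partner <- partner
    de_tabs[[partner]] <- de

    pca <- stage(paste0("pca_", partner),
                 pca_samples(log2(cpm(cf, factors) + 1), n_components = 2))
    pca_tabs[[partner]] <- data.frame(
      partner = partner, sample_id = rownames(pca$coordinates),
      PC1 = pca$coordinates[, 1], PC2 = pca$coordinates[, 2],
      pct_var_1 = pca$percent_variance[1], pct_var_2 = pca$percent_variance[2],
      stringsAsFactors = FALSE)

    mods <- Filter(function(m) identical(m$partner, partner), dat$modules)
    mods <- Filter(function(m) any(m$gene_ids %in% kept), mods)
    deg_all <- de$gene_id[de$status != "ns"]
    if (length(mods)) {
      enr <- stage(paste0("enrich_", partner), {
        up <- de$gene_id[de$status == "higher_in_WWL2"]
        down <- de$gene_id[de$status == "higher_in_WE2"]
        rbind(ora(deg_all, kept, mods, "all"),
              ora(up, kept, mods, "up"),
              ora(down, kept, mods, "down"))
      })
      enr$partner <- partner
      enr_tabs[[partner]] <- enr

      expr <- stage(paste0("expression_", partner),
                    fpkm(cf, dat$annotation, factors))
      sc <- stage(paste0("score_", partner), module_scores(expr, mods))
      score_mats[[partner]] <- sc
      score_rows[[partner]] <- data.frame(
        partner = partner,
        module_id = rep(rownames(sc), ncol(sc)),
        sample_id = rep(colnames(sc), each = nrow(sc)),
        score = as.vector(unclass(sc)), stringsAsFactors = FALSE)
      gs <- stage(paste0("score_summary_", partner),
                  score_group_summary(sc, samples))
      gs$partner <- partner
      summ_rows[[partner]] <- gs
    }
    stage_counts[[partner]] <- list(
      n_genes_input = nrow(counts), n_genes_kept = length(kept),
      n_deg = sum(de$status != "ns"),
      n_higher_in_WE2 = sum(de$status == "higher_in_WE2"),
      n_higher_in_WWL2 = sum(de$status == "higher_in_WWL2"),
      n_modules = length(mods),
      n_enriched_terms = if (length(mods))
        sum(enr_tabs[[partner]]$fdr < config$enrich_fdr) else 0L)
  }

  de_all <- do.call(rbind, de_tabs)
  tsv(de_all, "de.tsv")
  tsv(do.call(rbind, pca_tabs), "pca.tsv")
  if (length(enr_tabs)) tsv(do.call(rbind, enr_tabs), "enrichment.tsv")
  scores_long <- do.call(rbind, score_rows)
  score_summary <- do.call(rbind, summ_rows)
  if (!is.null(scores_long)) {
    tsv(scores_long, "scores.tsv")
    tsv(score_summary, "scores_summary.tsv")
  }

  # cross-partner coupling of the configured module pair
  coup <- NULL
  all_scores <- do.call(rbind, lapply(unname(score_mats), unclass))
  if (!is.null(all_scores) && all(config$coupled_pair %in% rownames(all_scores))) {
    coup <- stage("coupling",
                  coupling(all_scores[config$coupled_pair[1], ],
                           all_scores[config$coupled_pair[2], ]))
    tsv(data.frame(module_1 = config$coupled_pair[1],
                   module_2 = config$coupled_pair[2],
                   r = coup$r, p = coup$p, n = coup$n,
                   degenerate = coup$degenerate), "coupling.tsv")
  }

  # candidate nodes: DEG and module member and direction-consistent
  candidates <- stage("candidates",
                      screen_candidates(de_all, dat$modules, score_summary))
  tsv(candidates, "candidates.tsv")

  pheno_tab <- NULL
  if (!is.null(dat$phenotypes)) {
    pheno_tab <- stage("phenotypes", {
      ph <- dat$phenotypes
      do.call(rbind, lapply(c("shoot_fw", "ethylene_rate"), function(v) {
        a <- ph[[v]][ph$treatment == "WE2"]
        b <- ph[[v]][ph$treatment == "WWL2"]
        wt <- welch_t(a, b)
        data.frame(variable = v, mean_WE2 = mean(a), sd_WE2 = stats::sd(a),
                   mean_WWL2 = mean(b), sd_WWL2 = stats::sd(b),
                   t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
      }))
    })
    tsv(pheno_tab, "pheno.tsv")
  }

  qpcr_summary <- NULL; conc <- NULL
  if (!is.null(dat$qpcr)) {
    qpcr_summary <- stage("qpcr", ddct(dat$qpcr, calibrator = "WE2"))
    tsv(qpcr_summary$summary, "qpcr.tsv")
    ratios <- rq_log2_ratio(qpcr_summary$summary)
    lfc_vec <- stats::setNames(de_all$log2fc, de_all$gene_id)
    if (length(intersect(names(ratios), names(lfc_vec)))) {
      conc <- stage("concordance", concordance(ratios, lfc_vec))
    }
  }

  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], cfg_json,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  summary <- list(
    package_version = as.character(utils::packageVersion("dualnod")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    thresholds = list(fdr = config$fdr_threshold, lfc = config$lfc_threshold,
                      enrich_fdr = config$enrich_fdr),
    partners = stage_counts,
    n_candidates = nrow(candidates),
    coupling = if (!is.null(coup)) coup[c("r", "p", "n")] else NULL,
    qpcr_concordance = if (!is.null(conc)) conc$fraction else NULL)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line("done: ", sum(vapply(stage_counts, `[[`, 0L, "n_deg")),
           " DEGs, ", nrow(candidates), " candidates")
  invisible(summary)
}

acquire_inputs <- function(config) {
  if (config$simulate) {
    sim <- simulate_experiment(do.call(sim_config,
                                       c(list(seed = config$seed), config$sim)))
    return(sim)
  }
  p <- config$paths
  need <- c("host_counts", "symbiont_counts", "samples", "annotation",
            "modules_gmt")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("paths lack: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ann <- utils::read.delim(p$annotation, sep = "\t", stringsAsFactors = FALSE)
  mods <- read_gene_sets(p$modules_gmt)
  # partner of each module inferred from its genes' annotation
  mods <- lapply(mods, function(m) {
    hit <- ann$partner[match(m$gene_ids, ann$gene_id)]
    m$partner <- names(which.max(table(hit)))
    m
  })
  list(host = read_counts(p$host_counts, partner = "host"),
       symbiont = read_counts(p$symbiont_counts, partner = "symbiont"),
       samples = read_sample_table(p$samples),
       annotation = ann, modules = mods,
       phenotypes = if (!is.null(p$phenotypes))
         utils::read.delim(p$phenotypes, stringsAsFactors = FALSE) else NULL,
       qpcr = if (!is.null(p$qpcr))
         utils::read.delim(p$qpcr, stringsAsFactors = FALSE) else NULL)
}

# DEG x module-membership x direction-consistency intersection
screen_candidates <- function(de_all, modules, score_summary) {
  empty <- data.frame(gene_id = character(), module_id = character(),
                      partner = character(), log2fc = numeric(),
                      fdr = numeric(), status = character(),
                      stringsAsFactors = FALSE)
  if (is.null(score_summary) || !nrow(score_summary)) return(empty)
  rows <- lapply(seq_len(nrow(score_summary)), function(i) {
    mod_id <- score_summary$module_id[i]
    dir_we2 <- sign(score_summary$mean_WE2[i])
    want <- if (dir_we2 > 0) "higher_in_WE2" else "higher_in_WWL2"
    mod <- modules[[mod_id]]
    hit <- de_all[de_all$gene_id %in% mod$gene_ids &
                    de_all$status == want, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    data.frame(gene_id = hit$gene_id, module_id = mod_id,
               partner = hit$partner, log2fc = hit$log2fc, fdr = hit$fdr,
               status = as.character(hit$status), stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
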