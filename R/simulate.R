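#' Configuration for a synthetic dual-transcriptome experiment
#'
#' Defines the study conditions the generator emulates: a two-strain
#' comparison (treatments `WE2` vs `WWL2`) with three biological replicates
#' each, host-dominant mixed libraries in which the rhizobial mapped rate
#' falls in the 1.64-5.04% band, negative-binomial counts with
#' module-concentrated treatment effects, a latent factor coupling a host
#' "substrate supply / microaerobic homeostasis" module to a symbiont
#' "N-fixation / microaerobic respiration" module, and phenotypes
#' calibrated to the observed WE2 means (shoot fresh weight 0.243 g,
#' nitrogenase activity 23.4 by acetylene reduction).
#'
#' Counts for gene g in sample j are drawn
#' `y_gj ~ NB(mu_gj, phi_g)` with variance `mu + phi*mu^2`, where
#' `mu_gj = L_j * w_gj / sum_g(w_gj)` and
#' `w_gj = q_g * 2^(beta_g * x_j + rho * gamma_g * u_j)`:
#' `x_j` is the treatment indicator (1 = WWL2, so `beta_g` is oriented as
#' log2(WWL2/WE2)), `u_j ~ N(0,1)` is a per-sample latent factor shared by
#' the two coupled modules (`gamma_g = 1` for their members), and `rho` the
#' coupling strength. Per-column renormalization keeps the expected library
#' size at `L_j`.
#'
#' @param seed Integer RNG seed (mandatory; identical config + seed gives
#'   bit-identical output).
#' @param n_rep_per_group Biological replicates per treatment (default 3).
#' @param n_host_genes,n_symbiont_genes Genes per partner (5000 / 1500).
#' @param total_reads_mean,total_reads_cv Total clean reads per sample:
#'   normal with this mean and coefficient of variation (16e6, 0.08;
#'   roughly 2.5 Gb of 2x150 bp reads).
#' @param host_mapped_frac Expected fraction of clean reads mapping to the
#'   host (0.85).
#' @param symbiont_rate_band Percent band `[low, high]` the per-sample
#'   rhizobial mapped rate is drawn from (default `c(1.64, 5.04)`).
#' @param baseline_meanlog_sd SD of log baseline abundance across genes.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal NB dispersion
#'   (median 0.1 by default).
#' @param de_fraction Named fractions of genes per partner given a planted
#'   treatment effect (module members count toward it).
#' @param effect_size_log2_mean,effect_size_log2_sd Planted |log2FC|
#'   distribution (normal, clamped at 0.25; default mean 2).
#' @param coupling_strength `rho` in `[0, 1]` (default 0.9).
#' @param module_sizes Named list `host = c(...), symbiont = c(...)` of
#'   module sizes; defaults mirror the five functional modules of the
#'   nodule study design.
#' @param module_direction Named signs: -1 = higher in WE2, +1 = higher in
#'   WWL2 (on the log2(WWL2/WE2) scale).
#' @param coupled_pair Names of the host and symbiont modules tied to the
#'   latent factor.
#' @param phenotype_params Group means/SDs for shoot fresh weight (g) and
#'   ethylene production rate; WE2 defaults are the printed values with
#'   SEM converted to SD via `SD = SEM * sqrt(3)` for n = 3.
#' @param length_meanlog,length_sdlog Log-normal gene-length (bp)
#'   parameters per partner.
#' @param qpcr_c0 Baseline cycle threshold; per-well
#'   `Ct = c0 - log2(CPM + 1) + N(0, qpcr_noise_sd)`.
#' @param qpcr_noise_sd Technical Ct noise SD.
#' @param n_qpcr_genes Marker genes assayed per coupled module.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(seed,
                       n_rep_per_group = 3L,
                       n_host_genes = 5000L,
                       n_symbiont_genes = 1500L,
                       total_reads_mean = 16e6,
                       total_reads_cv = 0.08,
                       host_mapped_frac = 0.85,
                       symbiont_rate_band = c(1.64, 5.04),
                       baseline_meanlog_sd = 1.2,
                       dispersion_meanlog = log(0.1),
                       dispersion_sdlog = 0.5,
                       de_fraction = c(host = 0.10, symbiont = 0.10),
                       effect_size_log2_mean = 2,
                       effect_size_log2_sd = 0.5,
                       coupling_strength = 0.9,
                       module_sizes = list(
                         host = c(hostSupply = 40L),
                         symbiont = c(symbiontFix = 40L,
                                      nodulationSurface = 30L,
                                      chemotaxisMotility = 30L,
                                      transportNutrient = 30L)),
                       module_direction = c(hostSupply = -1,
                                            symbiontFix = -1,
                                            nodulationSurface = 1,
                                            chemotaxisMotility = 1,
                                            transportNutrient = 1),
                       coupled_pair = c("hostSupply", "symbiontFix"),
                       phenotype_params = list(
                         shoot_fw_mean = c(WE2 = 0.243, WWL2 = 0.185),
                         shoot_fw_sd = c(WE2 = 0.015, WWL2 = 0.012) * sqrt(3),
                         ara_mean = c(WE2 = 23.4, WWL2 = 15.6),
                         ara_sd = c(WE2 = 1.0, WWL2 = 1.2) * sqrt(3)),
                       length_meanlog = c(host = log(1200), symbiont = log(900)),
                       length_sdlog = c(host = 0.35, symbiont = 0.30),
                       qpcr_c0 = 32,
                       qpcr_noise_sd = 0.15,
                       n_qpcr_genes = 3L) {
  if (missing(seed)) stop("sim_config() requires an explicit seed", call. = FALSE)
  cfg <- list(seed = as.integer(seed),
              n_rep_per_group = as.integer(n_rep_per_group),
              n_host_genes = as.integer(n_host_genes),
              n_symbiont_genes = as.integer(n_symbiont_genes),
              total_reads_mean = total_reads_mean,
              total_reads_cv = total_reads_cv,
              host_mapped_frac = host_mapped_frac,
              symbiont_rate_band = symbiont_rate_band,
              baseline_meanlog_sd = baseline_meanlog_sd,
              dispersion_meanlog = dispersion_meanlog,
              dispersion_sdlog = dispersion_sdlog,
              de_fraction = de_fraction,
              effect_size_log2_mean = effect_size_log2_mean,
              effect_size_log2_sd = effect_size_log2_sd,
              coupling_strength = coupling_strength,
              module_sizes = module_sizes,
              module_direction = module_direction,
              coupled_pair = coupled_pair,
              phenotype_params = phenotype_params,
              length_meanlog = length_meanlog,
              length_sdlog = length_sdlog,
              qpcr_c0 = qpcr_c0,
              qpcr_noise_sd = qpcr_noise_sd,
              n_qpcr_genes = as.integer(n_qpcr_genes))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  band <- cfg$symbiont_rate_band
  if (length(band) != 2L || band[1] > band[2] || band[1] <= 0 || band[2] >= 100) {
    stop("symbiont_rate_band must be 0 < low <= high < 100 (percent)", call. = FALSE)
  }
  if (any(cfg$de_fraction < 0 | cfg$de_fraction > 1)) {
    stop("de_fraction entries must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$coupling_strength < 0 || cfg$coupling_strength > 1) {
    stop("coupling_strength must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_rep_per_group < 2L) stop("need >= 2 replicates per group", call. = FALSE)
  if (cfg$host_mapped_frac + band[2] / 100 >= 1) {
    stop("configuration infeasible: host fraction plus symbiont band exceed 1",
         call. = FALSE)
  }
  for (p in c("host", "symbiont")) {
    n <- if (p == "host") cfg$n_host_genes else cfg$n_symbiont_genes
    if (sum(cfg$module_sizes[[p]]) > n) {
      stop("module sizes exceed the ", p, " gene universe", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Negative-binomial counts parameterized by mean and dispersion
#'
#' Draws from `NB(mu, phi)` with `Var = mu + phi * mu^2`; `phi = 0` is the
#' Poisson limit. This is the count model shared by the generator and the
#' differential-expression test.
#'
#' @param n Number of draws.
#' @param mu Mean(s), recycled.
#' @param phi Dispersion(s) >= 0, recycled.
#' @return Integer vector of counts.
#' @export
rnb_counts <- function(n, mu, phi) {
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  if (any(phi < 0)) stop("dispersion must be >= 0", call. = FALSE)
  y <- integer(n)
  pois <- phi == 0
  if (any(pois)) y[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    y[!pois] <- stats::rnbinom(sum(!pois), size = 1 / phi[!pois], mu = mu[!pois])
  }
  y
}

#' Simulate a complete dual-transcriptome nodule experiment
#'
#' Generates paired host and symbiont count matrices, sample metadata with
#' exact read accounting, ground-truth labels, phenotypes and an RT-qPCR
#' table under the model described in [sim_config()]. The symbiont library
#' depth of each sample is set by drawing a target mapped rate uniformly in
#' the configured band and rescaling that sample's symbiont column sum to
#' it, so every sample's rhizobial mapped rate
#' (`100 * symbiont_mapped / total_clean_reads`) falls inside the band.
#'
#' @param config A [sim_config()].
#' @return A list of class `dualnod_sim` with elements `host` and
#'   `symbiont` ([count_matrix()]), `samples` (metadata data frame),
#'   `truth` (planted labels, true log2 fold changes oriented
#'   log2(WWL2/WE2), latent factor, module directions), `annotation`
#'   (gene lengths), `phenotypes`, `qpcr` (long format), `modules`
#'   (list of module definitions) and the `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 1, n_host_genes = 200,
#'                                       n_symbiont_genes = 100,
#'                                       total_reads_mean = 2e5))
#' mapped_rate(sim$samples$symbiont_mapped, sim$samples$total_clean_reads)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  nrep <- config$n_rep_per_group
  n_samp <- 2L * nrep
  sample_ids <- c(paste0("WE2_", seq_len(nrep)), paste0("WWL2_", seq_len(nrep)))
  treatment <- rep(c("WE2", "WWL2"), each = nrep)
  x <- as.numeric(treatment == "WWL2")
  u <- stats::rnorm(n_samp)
  names(u) <- sample_ids

  T0 <- pmax(1e4, round(stats::rnorm(n_samp, config$total_reads_mean,
                                     config$total_reads_cv * config$total_reads_mean)))
  band <- config$symbiont_rate_band
  target_rate <- stats::runif(n_samp, band[1], band[2])
  L_host <- round(config$host_mapped_frac * T0)
  L_sym <- pmax(1, round(target_rate / 100 * T0))

  host_ids <- sprintf("MsGsim%05d.01", seq_len(config$n_host_genes))
  sym_ids <- sprintf("SMsim_RS%05d", seq_len(config$n_symbiont_genes))

  host <- sim_partner(config, "host", host_ids, L_host, x, u, sample_ids)
  sym <- sim_partner(config, "symbiont", sym_ids, L_sym, x, u, sample_ids)

  # exact read accounting: rescale each symbiont column to its drawn
  # target depth, then nudge totals so per-gene rounding cannot push a
  # sample's rate outside the band
  S_raw <- colSums(sym$counts)
  target_S <- pmax(1, round(target_rate / 100 * T0))
  for (j in seq_len(n_samp)) {
    if (S_raw[j] > 0 && S_raw[j] != target_S[j]) {
      sym$counts[, j] <- as.integer(round(sym$counts[, j] * target_S[j] / S_raw[j]))
    }
  }
  S <- colSums(sym$counts)
  H <- colSums(host$counts)
  total <- T0
  for (j in seq_len(n_samp)) {
    floor_T <- H[j] + S[j]
    while (100 * S[j] / total[j] > band[2]) total[j] <- total[j] + 1
    while (100 * S[j] / total[j] < band[1] && total[j] > floor_T) {
      total[j] <- total[j] - 1
    }
    if (100 * S[j] / total[j] < band[1]) {
      stop("configuration infeasible: symbiont depth too low for the rate band",
           call. = FALSE)
    }
  }

  samples <- data.frame(sample_id = sample_ids,
                        treatment = factor(treatment, levels = c("WE2", "WWL2")),
                        replicate = rep(seq_len(nrep), 2L),
                        total_clean_reads = as.numeric(total),
                        host_mapped = as.numeric(H),
                        symbiont_mapped = as.numeric(S),
                        stringsAsFactors = FALSE)

  truth <- list(
    de_labels = c(host$labels, sym$labels),
    true_log2fc = c(host$beta, sym$beta),
    latent_factor = u,
    module_effect_direction = config$module_direction,
    coupled_pair = config$coupled_pair)

  annotation <- rbind(
    data.frame(gene_id = host_ids,
               length_bp = pmax(150, round(stats::rlnorm(
                 length(host_ids), config$length_meanlog[["host"]],
                 config$length_sdlog[["host"]]))),
               partner = "host", stringsAsFactors = FALSE),
    data.frame(gene_id = sym_ids,
               length_bp = pmax(150, round(stats::rlnorm(
                 length(sym_ids), config$length_meanlog[["symbiont"]],
                 config$length_sdlog[["symbiont"]]))),
               partner = "symbiont", stringsAsFactors = FALSE))

  pp <- config$phenotype_params
  phenotypes <- data.frame(
    replicate_id = sample_ids,
    treatment = factor(treatment, levels = c("WE2", "WWL2")),
    shoot_fw = pmax(0, stats::rnorm(n_samp, pp$shoot_fw_mean[treatment],
                                    pp$shoot_fw_sd[treatment])),
    ethylene_rate = pmax(0, stats::rnorm(n_samp, pp$ara_mean[treatment],
                                         pp$ara_sd[treatment])),
    stringsAsFactors = FALSE)

  modules <- c(host$modules, sym$modules)
  qpcr <- sim_qpcr(config, host$counts, sym$counts, modules, samples)

  structure(list(host = count_matrix(host$counts, "host"),
                 symbiont = count_matrix(sym$counts, "symbiont"),
                 samples = samples, truth = truth, annotation = annotation,
                 phenotypes = phenotypes, qpcr = qpcr, modules = modules,
                 config = config),
            class = "dualnod_sim")
}

# one partner's genes: module assignment, planted effects, NB counts
sim_partner <- function(config, partner, gene_ids, L, x, u, sample_ids) {
  n <- length(gene_ids)
  sizes <- config$module_sizes[[partner]]
  modules <- list()
  pool <- sample(gene_ids)        # random, seed-determined module membership
  taken <- 0L
  for (m in names(sizes)) {
    members <- pool[(taken + 1L):(taken + sizes[[m]])]
    taken <- taken + sizes[[m]]
    modules[[m]] <- module_definition(m, members, partner = partner)
  }
  module_gene <- unlist(lapply(modules, `[[`, "gene_ids"), use.names = FALSE)
  module_of <- rep(names(sizes), times = vapply(modules, function(m) length(m$gene_ids), 0L))

  beta <- stats::setNames(numeric(n), gene_ids)
  n_de <- round(config$de_fraction[[partner]] * n)
  draw_mag <- function(k) {
    pmax(0.25, stats::rnorm(k, config$effect_size_log2_mean,
                            config$effect_size_log2_sd))
  }
  if (n_de > 0) {
    sgn <- config$module_direction[module_of]
    beta[module_gene] <- sgn * draw_mag(length(module_gene))
    extra <- n_de - length(module_gene)
    if (extra > 0) {
      others <- sample(setdiff(gene_ids, module_gene), extra)
      beta[others] <- sample(c(-1, 1), extra, replace = TRUE) * draw_mag(extra)
    }
  }
  gamma <- as.numeric(gene_ids %in%
                        modules[[intersect(config$coupled_pair, names(sizes))[1]]]$gene_ids)
  if (!length(intersect(config$coupled_pair, names(sizes)))) gamma <- numeric(n)

  q <- exp(stats::rnorm(n, 0, config$baseline_meanlog_sd))
  phi <- stats::rlnorm(n, config$dispersion_meanlog, config$dispersion_sdlog)
  rho <- config$coupling_strength

  counts <- matrix(0L, nrow = n, ncol = length(L),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(L)) {
    w <- q * 2^(beta * x[j] + rho * gamma * u[j])
    mu <- L[j] * w / sum(w)
    counts[, j] <- rnb_counts(n, mu, phi)
  }

  labels <- ifelse(beta == 0, "null", ifelse(beta < 0, "up_in_WE2", "up_in_WWL2"))
  list(counts = counts, beta = beta, labels = labels, modules = modules)
}

# long-format qPCR table: marker genes of the two coupled modules plus a
# constant-expression reference gene per partner
sim_qpcr <- function(config, host_counts, sym_counts, modules, samples) {
  refs <- c(host = "MtACTIN", symbiont = "rpoD")
  ref_cpm <- c(host = 500, symbiont = 800)
  rows <- list()
  for (partner in c("host", "symbiont")) {
    cm <- if (partner == "host") host_counts else sym_counts
    mod_name <- intersect(config$coupled_pair,
                          names(config$module_sizes[[partner]]))
    if (!length(mod_name)) next
    targets <- utils::head(modules[[mod_name[1]]]$gene_ids, config$n_qpcr_genes)
    cpm_mat <- t(t(cm) / colSums(cm)) * 1e6
    for (g in c(targets, refs[[partner]])) {
      expr <- if (g == refs[[partner]]) {
        rep(ref_cpm[[partner]], ncol(cm))
      } else {
        cpm_mat[g, ]
      }
      ct_true <- config$qpcr_c0 - log2(expr + 1)
      for (j in seq_len(ncol(cm))) {
        for (tr in 1:3) {
          rows[[length(rows) + 1L]] <- data.frame(
            target_gene = g, reference_gene = refs[[partner]],
            partner = partner,
            treatment = as.character(samples$treatment[j]),
            replicate = samples$replicate[j], tech_rep = tr,
            ct = ct_true[j] + stats::rnorm(1, 0, config$qpcr_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated experiment to a directory of plain-text files
#'
#' Emits the on-disk artifacts the pipeline's load mode reads back:
#' `host_counts.tsv`, `symbiont_counts.tsv`, `samples.tsv`,
#' `annotation.tsv`, `modules.gmt`, `phenotypes.tsv`, `qpcr.tsv` and a
#' ground-truth table `truth.tsv`.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "dualnod_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$host, file.path(dir, "host_counts.tsv"))
  write_counts(sim$symbiont, file.path(dir, "symbiont_counts.tsv"))
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_sets(sim$modules, file.path(dir, "modules.gmt"))
  utils::write.table(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$qpcr, file.path(dir, "qpcr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(gene_id = names(sim$truth$de_labels),
                      de_label = unname(sim$truth$de_labels),
                      true_log2fc = unname(sim$truth$true_log2fc),
                      stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
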