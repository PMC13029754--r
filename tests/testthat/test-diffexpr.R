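test_that("dispersion is zero for counts constant within groups", {
  m <- rbind(g1 = c(10, 10, 10, 20, 20, 20),
             g2 = c(30, 20, 10, 5, 15, 25),
             filler = c(60, 70, 80, 75, 65, 55))   # equal library sizes
  colnames(m) <- paste0("s", 1:6)
  d <- estimate_dispersion(m, two_groups())
  expect_equal(unname(d$phi["g1"]), 0)
  expect_equal(unname(d$phi_shrunk["g1"]), 0.3 * d$common)
})

test_that("dispersion estimates are small under Poisson data", {
  set.seed(31)
  m <- matrix(rpois(2000 * 6, 100), nrow = 2000,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  d <- estimate_dispersion(m, two_groups())
  expect_lte(mean(d$phi_shrunk), 0.05)
})

test_that("dispersion recovery at phi = 0.4", {
  set.seed(32)
  m <- matrix(rnb_counts(2000 * 6, mu = 100, phi = 0.4), nrow = 2000,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  d <- estimate_dispersion(m, two_groups())
  med <- median(d$phi_shrunk)
  expect_gte(med, 0.2)
  expect_lte(med, 0.6)
})

test_that("dispersion estimation requires replicated groups", {
  m <- make_counts(rpois(9, 20), 3)
  expect_error(estimate_dispersion(m, factor(c("a", "b", "b"))),
               ">= 2 replicates")
})

test_that("exact test gives p = 1 for a perfectly symmetric split", {
  libs <- rep(1e5, 6)
  expect_equal(nb_exact_test(c(10, 12, 14), c(14, 12, 10), 0.1,
                             libs[1:3], libs[4:6]), 1)
  expect_equal(nb_exact_test(c(0, 0, 0), c(0, 0, 0), 0.1,
                             libs[1:3], libs[4:6]), 1)
})

test_that("extreme split example matches full enumeration", {
  # t = 6 all in group A, phi = 0: conditional binomial(6, 1/2);
  # only s = 0 and s = 6 are as unlikely as observed -> p = 2 * (1/2)^6
  p <- nb_exact_test(c(3, 3), c(0, 0), 0, rep(1e5, 2), rep(1e5, 2))
  expect_equal(p, 2 * 0.5^6, tolerance = 1e-10)
})

test_that("Poisson-limit exact test agrees with conditional binomial enumeration", {
  for (t in 1:50) {
    for (sizes in list(c(3L, 3L), c(2L, 3L))) {
      set.seed(t + 7 * sizes[2])
      A <- sample(0:t, 1)
      # spread A and t - A arbitrarily over the replicates
      a <- tabulate(sample(sizes[1], A, replace = TRUE), sizes[1])
      b <- tabulate(sample(sizes[2], t - A, replace = TRUE), sizes[2])
      p_pkg <- nb_exact_test(a, b, 0, rep(2e5, sizes[1]), rep(2e5, sizes[2]))
      db <- dbinom(0:t, t, sizes[1] / sum(sizes))
      p_oracle <- sum(db[db <= db[A + 1] * (1 + 1e-12)])
      expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  bh_oracle <- function(p) {   # literal min over j >= i of m p_(j) / j
    m <- length(p)
    o <- order(p)
    q_sorted <- vapply(seq_len(m), function(i) {
      min(1, min(m * p[o][i:m] / (i:m)))
    }, numeric(1))
    q <- numeric(m)
    q[o] <- q_sorted
    q
  }
  set.seed(33)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DEG classification reproduces the printed marker-gene calls", {
  markers <- data.frame(
    gene_id = c("ENOD93", "leghemoglobin", "nifH", "fixA", "ccoN"),
    log2fc = c(-2.079, -1.069, -1.341, -1.539, -1.815),
    fdr = c(1.53e-10, 3.84e-3, 2.19e-3, 1.47e-15, 4.63e-19))
  out <- call_degs(markers)
  expect_true(all(out$status == "higher_in_WE2"))
  expect_equal(unname(attr(out, "summary")["n_higher_in_WE2"]), 5)
})

test_that("DEG thresholds are inclusive on fold change, strict on FDR", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   log2fc = c(-0.9, -1.0, 1.0),
                   fdr = c(1e-20, 0.049, 0.05))
  out <- call_degs(de)
  expect_equal(as.character(out$status),
               c("ns", "higher_in_WE2", "ns"))
})

test_that("fold changes are oriented WWL2 over WE2 with a pseudo-count", {
  expect_equal(log2fc(10, 10), 0)
  expect_equal(log2fc(100, 400), 2, tolerance = 0.01)
  expect_equal(log2fc(0, 0), 0)
  expect_lt(log2fc(400, 100), 0)   # higher in WE2 is negative
})

test_that("sample PCA behaves on degenerate geometries", {
  set.seed(34)
  g <- rnorm(20)
  m <- outer(g, c(1, 2, 3, 4))
  dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:4))
  pc <- pca_samples(m)
  expect_equal(pc$percent_variance[1], 100, tolerance = 1e-8)
  expect_equal(sum(pc$percent_variance), 100, tolerance = 1e-8)

  m2 <- cbind(m, s5 = m[, 4])      # duplicated sample
  pc2 <- pca_samples(m2)
  expect_equal(pc2$coordinates["s5", ], pc2$coordinates["s4", ],
               tolerance = 1e-8)
  expect_error(pca_samples(m[, 1:2]), ">= 3 samples")
})

test_that("null simulations stay below the false-call ceiling", {
  for (seed in 1:5) {
    s <- simulate_experiment(small_sim_config(
      seed + 200, n_host_genes = 600L,
      de_fraction = c(host = 0, symbiont = 0), coupling_strength = 0))
    kept <- filter_low_expression(s$host, s$samples)
    cf <- unclass(s$host)[kept, ]
    de <- de_analysis(cf, s$samples, tmm_factors(cf))
    expect_lte(mean(de$status != "ns"), 0.10)
  }
})
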