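test_that("one-gene module score matches direct z-score arithmetic", {
  tmat <- matrix(c(2, 2, 2, 4, 4, 4), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  expr <- expr_from_log(tmat)
  sc <- module_scores(expr, list(module_definition("m", "g1")))
  z <- 1 / sqrt(1.2)   # sd with n-1 denominator is sqrt(1.2)
  expect_equal(unname(unclass(sc)[1, ]), c(-z, -z, -z, z, z, z),
               tolerance = 1e-10)
  gs <- score_group_summary(sc, two_groups())
  expect_equal(gs$mean_WE2, -0.9128709, tolerance = 1e-6)
  expect_equal(gs$mean_WE2 + gs$mean_WWL2, 0, tolerance = 1e-12)
})

test_that("module scores sum to zero and group means are exact negatives", {
  set.seed(51)
  for (i in 1:5) {
    expr <- matrix(rexp(40 * 6, 1 / 50), nrow = 40,
                   dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
    mods <- list(module_definition("a", paste0("g", 1:15)),
                 module_definition("b", paste0("g", 10:40)))
    sc <- module_scores(expr, mods)
    expect_lt(max(abs(rowSums(unclass(sc)))), 1e-10)
    gs <- score_group_summary(sc, two_groups())
    expect_lt(max(abs(gs$mean_WE2 + gs$mean_WWL2)), 1e-10)
  }
})

test_that("scores are invariant to per-gene affine maps after the log", {
  set.seed(52)
  tmat <- matrix(rnorm(30 * 6, 5, 2), nrow = 30,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
  mods <- list(module_definition("m", paste0("g", 1:12)))
  base <- module_scores(tmat, mods, log_transform = FALSE)
  a <- runif(30, 0.5, 3)
  b <- rnorm(30, 0, 4)
  warped <- tmat * a + b
  again <- module_scores(warped, mods, log_transform = FALSE)
  expect_equal(unclass(base)[, ], unclass(again)[, ], tolerance = 1e-10)
})

test_that("zero-variance genes are excluded, empty modules error", {
  expr <- rbind(flat = rep(7, 6),
                var1 = c(1, 2, 3, 4, 5, 6),
                var2 = c(6, 4, 2, 1, 3, 5))
  colnames(expr) <- paste0("s", 1:6)
  expect_warning(
    sc <- module_scores(expr, list(module_definition("m", c("flat", "var1")))),
    "zero-variance")
  expect_equal(attr(sc, "n_genes")[["m"]], 1L)
  expect_error(
    suppressWarnings(
      module_scores(expr, list(module_definition("m", "flat")))),
    "zero variance")
  expect_error(
    module_scores(expr, list(module_definition("ghost", c("nope1", "nope2")))),
    "ghost")
})

test_that("reordering samples permutes score columns identically", {
  set.seed(53)
  expr <- matrix(rexp(20 * 6, 1 / 30), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  mods <- list(module_definition("m", paste0("g", 1:8)))
  sc <- module_scores(expr, mods)
  perm <- c(4, 1, 6, 2, 5, 3)
  sc_perm <- module_scores(expr[, perm], mods)
  expect_equal(unclass(sc_perm)[, ], unclass(sc)[, perm], tolerance = 1e-12)
})

test_that("significance letters follow the Welch test on scores", {
  s_same <- matrix(rep(c(0.4, -0.1, 0.2), 2), nrow = 1,
                   dimnames = list("m", paste0("s", 1:6)))
  gs <- score_group_summary(s_same, two_groups())
  expect_identical(gs$letter_WE2, gs$letter_WWL2)

  s_diff <- matrix(c(0.9, 1.0, 0.89, -0.9, -1.0, -0.89), nrow = 1,
                   dimnames = list("m", paste0("s", 1:6)))
  gs2 <- score_group_summary(s_diff, two_groups())
  expect_lt(gs2$p_welch, 0.05)
  expect_identical(gs2$letter_WE2, "a")   # higher-mean group lettered first
  expect_identical(gs2$letter_WWL2, "b")
})

test_that("coupling test implements the exact t-transform", {
  expect_equal(coupling(c(1, 0, -1, 0), c(0, 1, 0, -1))$p, 1)
  s1 <- c(0.2, -0.5, 1.1, 0.7, -0.9, 0.3)
  res <- coupling(s1, 2 * s1)
  expect_true(res$degenerate)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  expect_error(coupling(s1, rep(1, 6)), "zero variance")
  # p-transform against stats::cor.test as an independent route
  set.seed(54)
  x <- rnorm(6); y <- x + rnorm(6)
  res2 <- coupling(x, y)
  ct <- cor.test(x, y)
  expect_equal(res2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res2$p, ct$p.value, tolerance = 1e-12)
})

test_that("latent coupling is recoverable from simulated module scores", {
  pos <- vapply(1:20, function(seed) {
    s <- simulate_experiment(small_sim_config(seed + 400))
    ann <- setNames(s$annotation$length_bp, s$annotation$gene_id)
    sc_h <- suppressWarnings(
      module_scores(fpkm(s$host, ann), s$modules["hostSupply"]))
    sc_s <- suppressWarnings(
      module_scores(fpkm(s$symbiont, ann), s$modules["symbiontFix"]))
    coupling(unclass(sc_h)[1, ], unclass(sc_s)[1, ])$r > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})
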