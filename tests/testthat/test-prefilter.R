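make_filter_fixture <- function() {
  # three focal genes plus a filler making every library exactly 1e6,
  # so the adaptive cutoff is C = 10 CPM and k = 3
  g1 <- c(12, 12, 12, 0, 0, 0)
  g2 <- c(20, 0, 0, 0, 0, 0)
  g3 <- rep(0, 6)
  filler <- 1e6 - (g1 + g2 + g3)
  m <- rbind(g1 = g1, g2 = g2, g3 = g3, filler = filler)
  colnames(m) <- paste0("s", 1:6)
  m
}

test_that("expression filter applies the adaptive CPM-and-total rule", {
  m <- make_filter_fixture()
  kept <- filter_low_expression(m, two_groups())
  expect_true("g1" %in% kept)      # 3 samples at >= 10 CPM, total 36 >= 15
  expect_false("g2" %in% kept)     # only 1 sample reaches the cutoff
  expect_false("g3" %in% kept)     # all-zero
  expect_true("filler" %in% kept)
})

test_that("expression filter is a subset operation and idempotent", {
  set.seed(4)
  m <- matrix(rnbinom(50 * 6, mu = 30, size = 5), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  kept <- filter_low_expression(m, two_groups())
  expect_true(all(kept %in% rownames(m)))
  again <- filter_low_expression(m[kept, ], two_groups())
  expect_identical(again, kept)
})

test_that("CPM satisfies its normalization identities", {
  set.seed(5)
  m <- matrix(rpois(60, 40), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  cc <- cpm(m)
  expect_equal(unname(colSums(cc)), rep(1e6, 6))
  m2 <- m
  m2[, 3] <- 2L * m2[, 3]
  expect_equal(cpm(m2)[, 3], cpm(m)[, 3])
  one <- matrix(c(50, 1e6 - 50, 50, 1e6 - 50), nrow = 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(cpm(one)["a", "s1"], 50, ignore_attr = TRUE)
})

test_that("FPKM arithmetic and length handling", {
  m <- matrix(c(100, 1e6 - 100, 100, 1e6 - 100), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  len <- c(a = 1000, b = 500)
  f <- fpkm(m, len)
  expect_equal(f["a", "s1"], 100, ignore_attr = TRUE)
  len2 <- c(a = 2000, b = 500)
  expect_equal(fpkm(m, len2)["a", ], f["a", ] / 2)
  m0 <- m; m0["a", ] <- 0L
  expect_equal(unname(fpkm(m0, len)["a", ]), c(0, 0))
  expect_error(fpkm(m, c(a = 1000)), "b")
  ann <- data.frame(gene_id = c("a", "b"), length_bp = c(1000, 500))
  expect_equal(fpkm(m, ann), f)
})

test_that("TMM factors are exactly one for depth-only differences", {
  set.seed(6)
  base <- rnbinom(40, mu = 100, size = 3) + 1L
  m <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(m) <- paste0("g", 1:40)
  expect_equal(unname(as.numeric(tmm_factors(m))), rep(1, 3))
  m2 <- cbind(s1 = base, s2 = 3L * base)
  rownames(m2) <- paste0("g", 1:40)
  expect_equal(unname(as.numeric(tmm_factors(m2))), rep(1, 2))
})

# independent re-derivation of the trim/weight recipe, written against the
# definition (order-statistic trimming) rather than the package code
tmm_oracle <- function(m) {
  N <- colSums(m)
  cpm0 <- sweep(m, 2, N, "/") * 1e6
  uq <- apply(cpm0, 2, function(col) quantile(col[col > 0], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(k) {
    yk <- m[, k]; yr <- m[, ref]
    ok <- yk > 0 & yr > 0
    yk <- yk[ok]; yr <- yr[ok]
    M <- log2((yk / N[k]) / (yr / N[ref]))
    if (max(abs(M)) < 1e-6) return(1)
    A <- 0.5 * log2((yk / N[k]) * (yr / N[ref]))
    n <- length(M)
    keepM <- order(M)[(floor(0.3 * n) + 1):(n - floor(0.3 * n))]
    keepA <- order(A)[(floor(0.05 * n) + 1):(n - floor(0.05 * n))]
    keep <- intersect(keepM, keepA)
    w <- 1 / ((N[k] - yk) / (N[k] * yk) + (N[ref] - yr) / (N[ref] * yr))
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

test_that("TMM matches an independent brute-force of the recipe", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnbinom(20 * 3, mu = 200, size = 5) + 1L, nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
    m[sample(20, 5), 2] <- m[sample(20, 5), 2] * 10L   # composition shift
    expect_equal(unname(as.numeric(tmm_factors(m))), unname(tmm_oracle(m)),
                 tolerance = 1e-10)
  }
})

test_that("TMM is stable under integer depth scaling of one sample", {
  # M, A and the trimmed gene set are exactly depth-invariant; only the
  # precision weights move, so factors agree closely but not bit-exactly
  set.seed(7)
  m <- matrix(rnbinom(30 * 4, mu = 150, size = 4) + 1L, nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  m[1:6, 2] <- m[1:6, 2] * 8L
  f1 <- as.numeric(tmm_factors(m))
  m2 <- m
  m2[, 3] <- m2[, 3] * 5L
  expect_equal(as.numeric(tmm_factors(m2)), f1, tolerance = 0.02)
})

test_that("TMM factors have geometric mean one", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    m <- matrix(rnbinom(25 * 5, mu = 80, size = 2) + 1L, nrow = 25,
                dimnames = list(paste0("g", 1:25), paste0("s", 1:5)))
    f <- as.numeric(tmm_factors(m))
    expect_lt(abs(mean(log(f))), 1e-12)
    expect_true(all(f > 0))
  }
})
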