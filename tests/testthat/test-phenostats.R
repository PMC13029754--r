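test_that("Welch t handles identical, shifted and degenerate groups", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shift <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p, 0.01)

  ab <- welch_t(c(1, 5, 2), c(4, 9, 8))
  ba <- welch_t(c(4, 9, 8), c(1, 5, 2))
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)

  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t(c(2, 2), c(3, 3))$p, 0)
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("Welch t matches the Satterthwaite formula", {
  set.seed(71)
  for (i in 1:50) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), 1, sd = runif(1, 0.5, 3))
    got <- welch_t(a, b)
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t_ref <- (mean(a) - mean(b)) / sqrt(va + vb)
    df_ref <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p_ref <- 2 * pt(-abs(t_ref), df_ref)
    expect_equal(got$t, t_ref, tolerance = 1e-12)
    expect_equal(got$df, df_ref, tolerance = 1e-12)
    expect_equal(got$p, p_ref, tolerance = 1e-12)
  }
})

test_that("acetylene reduction rate is amount per gram-hour", {
  expect_equal(ara_rate(2.34, 1, 0.10), 23.4)
  expect_equal(ara_rate(2.34, 1, 0.20), 23.4 / 2)
  expect_equal(ara_rate(2.34, 2, 0.10), 23.4 / 2)
  expect_error(ara_rate(1, 0, 0.1), "> 0")
  expect_error(ara_rate(1, 1, -0.1), "> 0")
})

make_qpcr <- function(target_ct_we2, target_ct_wwl2, ref_ct = 15) {
  rows <- list()
  for (tr in c("WE2", "WWL2")) {
    cts <- if (tr == "WE2") target_ct_we2 else target_ct_wwl2
    for (rep_i in 1:3) {
      rows[[length(rows) + 1]] <- data.frame(
        target_gene = "tg", reference_gene = "ref", treatment = tr,
        replicate = rep_i, tech_rep = 1:3, ct = cts[rep_i])
      rows[[length(rows) + 1]] <- data.frame(
        target_gene = "ref", reference_gene = "ref", treatment = tr,
        replicate = rep_i, tech_rep = 1:3, ct = ref_ct)
    }
  }
  do.call(rbind, rows)
}

test_that("2^-ddCt arithmetic and calibrator behavior", {
  q <- make_qpcr(c(20, 20, 20), c(22, 22, 22))
  res <- ddct(q, calibrator = "WE2")
  s <- res$summary
  expect_equal(s$mean_rq[s$treatment == "WE2"], 1)        # ddCt = 0 -> RQ 1
  expect_equal(s$mean_rq[s$treatment == "WWL2"], 0.25)    # +2 cycles -> 4x down
  expect_equal(unname(rq_log2_ratio(s)["tg"]), 2)

  # ddCt = -1 -> RQ = 2
  q2 <- make_qpcr(c(20, 20, 20), c(19, 19, 19))
  expect_equal(ddct(q2)$summary$mean_rq[2], 2)
})

test_that("ddCt is invariant to a constant machine offset", {
  set.seed(72)
  q <- make_qpcr(c(20.1, 19.8, 20.4), c(22.2, 21.7, 22.0))
  q_off <- q
  q_off$ct <- q_off$ct + 3
  expect_equal(ddct(q)$summary$mean_rq, ddct(q_off)$summary$mean_rq,
               tolerance = 1e-12)
})

test_that("missing reference wells are reported by replicate", {
  q <- make_qpcr(c(20, 20, 20), c(22, 22, 22))
  q <- q[!(q$target_gene == "ref" & q$treatment == "WWL2" & q$replicate == 2), ]
  expect_error(ddct(q), "WWL2_2")
})

test_that("concordance counts directional sign agreement", {
  qr <- c(a = 2, b = -1.5, c = 0.8)
  expect_equal(concordance(qr, c(a = -2, b = 1, c = -0.2))$fraction, 1)
  expect_equal(concordance(qr, c(a = 2, b = -1, c = 0.2))$fraction, 0)
  expect_error(concordance(qr, c(z = 1)), "shared")
})

test_that("simulated qPCR recovers the planted expression directions", {
  s <- simulate_experiment(small_sim_config(77))
  res <- ddct(s$qpcr, calibrator = "WE2")
  ratios <- rq_log2_ratio(res$summary)
  conc <- concordance(ratios, s$truth$true_log2fc)
  expect_gte(conc$fraction, 0.9)
})
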