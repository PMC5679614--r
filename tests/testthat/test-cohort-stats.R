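test_that("step-up FDR adjustment matches hand-worked cases and stays monotone", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  # equal p: q(i) = p*m/i is minimized at i = m, so all adjust to p
  expect_equal(bh_fdr(rep(0.05, 10)), rep(0.05, 10))

  set.seed(91)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p))
    expect_equal(adj, stats::p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
    # monotone: ordering of adjusted values follows ordering of raw values
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }

  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_equal(bh_fdr(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
})

test_that("partial Pearson matches the residualize-then-correlate oracle", {
  fx <- partial_fixture()

  # no covariates: plain Pearson, p from the same t reference
  res0 <- partial_pearson(fx$x, fx$y)
  or0 <- partial_cor_oracle(fx$x, fx$y)
  expect_equal(res0$r, or0$r, tolerance = 1e-12)
  expect_equal(res0$p, or0$p, tolerance = 1e-12)

  res <- partial_pearson(fx$x, fx$y, fx$covariates)
  orc <- partial_cor_oracle(fx$x, fx$y, fx$covariates)
  expect_equal(res$r, orc$r, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  expect_equal(res$df, orc$df)

  # perfect correlation
  resp <- partial_pearson(fx$x, fx$x, fx$covariates)
  expect_equal(resp$r, 1, tolerance = 1e-12)
  expect_lt(resp$p, 1e-12)

  # affine invariance in x, y and covariates
  res2 <- partial_pearson(3 * fx$x - 7, -2 * fx$y + 1,
                          cbind(fx$covariates[, 1] / 10 + 5,
                                fx$covariates[, 2] * 4 - 2))
  expect_equal(abs(res2$r), abs(res$r), tolerance = 1e-12)

  # collinear covariates are named in the error
  bad <- cbind(a = fx$covariates[, 1], b = 2 * fx$covariates[, 1])
  expect_error(partial_pearson(fx$x, fx$y, bad), "b")
  expect_error(partial_pearson(fx$x[1:4], fx$y[1:4], fx$covariates[1:4, ]),
               "n > k")
  expect_error(partial_pearson(c(fx$x[-1], NA), fx$y), "missing")
})

test_that("partial Spearman is the rank-transformed partial Pearson", {
  fx <- partial_fixture()

  # strictly monotone transform of x correlates perfectly, no covariates
  res <- partial_spearman(fx$x, exp(fx$x))
  expect_equal(res$rho, 1, tolerance = 1e-12)

  # average ranks for ties
  expect_equal(rank(c(1, 2, 2, 3), ties.method = "average"),
               c(1, 2.5, 2.5, 4))
  x_tied <- c(1, 2, 2, 3, 5, 5, 7, 9)
  res_t <- partial_spearman(x_tied, fx$y, fx$covariates)
  orc <- partial_cor_oracle(rank(x_tied), rank(fx$y), fx$covariates)
  expect_equal(res_t$rho, orc$r, tolerance = 1e-12)

  # invariance under strictly monotone transforms of both variables
  r1 <- partial_spearman(fx$x, fx$y, fx$covariates)
  r2 <- partial_spearman(log(fx$x), fx$y^3, fx$covariates)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
})

test_that("ANCOVA reduces to the t-test and recovers injected group shifts", {
  # balanced two-group, no covariates: identical to the pooled t-test
  set.seed(7)
  v <- rnorm(40)
  grp <- factor(rep(c("A", "B"), each = 20))
  res <- ancova_compare(v, grp)
  tt <- stats::t.test(v ~ grp, var.equal = TRUE)
  expect_equal(abs(res$contrasts$statistic), abs(unname(tt$statistic)),
               tolerance = 1e-10)
  expect_equal(res$contrasts$p_raw, tt$p.value, tolerance = 1e-10)

  # injected 1.0 shift with age/gender structure present: estimate within CI
  set.seed(8)
  n <- 150
  grp2 <- factor(rep(c("HC", "MS"), length.out = n))
  age <- rnorm(n, 50, 12)
  gender <- rbinom(n, 1, 0.5)
  y <- 17 - 1.0 * (grp2 == "MS") - 0.02 * (age - 50) + 0.3 * gender +
    rnorm(n, 0, 0.8)
  res2 <- ancova_compare(y, grp2, cbind(age = age, gender = gender),
                         ref = "HC")
  est <- res2$contrasts$estimate[res2$contrasts$contrast == "MS vs HC"]
  se <- abs(est / res2$contrasts$statistic[res2$contrasts$contrast == "MS vs HC"])
  expect_lt(abs(est - (-1.0)), 1.96 * se + 0.05)
  expect_lt(res2$omnibus$p, 1e-6)

  expect_error(ancova_compare(v[1:22], factor(c(rep("A", 20), "B", "B"))),
               ">= 3")
})

test_that("omnibus F agrees with anova() and is null-calibrated", {
  set.seed(12)
  n <- 60
  grp <- factor(rep(c("a", "b", "c"), each = 20))
  age <- rnorm(n, 50, 10)
  y <- 0.01 * age + rnorm(n)
  res <- ancova_compare(y, grp, cbind(age = age))
  ref <- stats::anova(stats::lm(y ~ age), stats::lm(y ~ grp + age))
  expect_equal(res$omnibus$F, ref$F[2], tolerance = 1e-10)
  expect_equal(res$omnibus$p, ref$`Pr(>F)`[2], tolerance = 1e-10)

  # quick null check: p roughly uniform (full calibration runs elsewhere)
  set.seed(13)
  ps <- replicate(200, {
    yy <- rnorm(n)
    ancova_compare(yy, grp, cbind(age = age))$omnibus$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("the correlation battery applies the lateralized peg-test rule and family-wise FDR", {
  cs <- make_cohort(cohort_spec(seed = 21))
  bt <- run_correlation_battery(cs$summaries, cs$cohort)

  # MS-only n for non-peg scores; right-handed-only for the peg test
  n_ms <- sum(cs$cohort$group != "HC")
  n_rh <- sum(cs$cohort$group != "HC" & cs$cohort$handedness == "right")
  expect_true(all(bt$n[bt$score == "SDMT"] == n_ms))
  expect_true(all(bt$n[bt$score == "NHPT"] == n_rh))
  expect_lt(n_rh, n_ms)

  # peg test only in the deep structures, lateralized dom->left
  nh <- bt[bt$score == "NHPT", ]
  expect_setequal(unique(nh$region_name), c("hippocampus", "amygdala"))

  # FDR applied once per family: within each family the adjusted values
  # equal a direct BH pass over that family's raw p-values
  for (fam in unique(bt$family)) {
    sel <- bt$family == fam
    expect_equal(bt$p_fdr[sel], bh_fdr(bt$p_raw[sel]))
  }
  expect_true(all(bt$p_fdr >= bt$p_raw - 1e-15, na.rm = TRUE))

  # designed coupling is recovered within its sampling CI (n = 80)
  cell <- bt[bt$region_name == "hippocampus" & bt$hemisphere == "left" &
             bt$measure == "R2t*" & bt$score == "SDMT", ]
  ci <- tanh(atanh(0.4) + c(-1, 1) * 1.96 / sqrt(cell$n - 4 - 3))
  expect_gt(cell$estimate, ci[1])
  expect_lt(cell$estimate, ci[2])

  expect_error(
    run_correlation_battery(cs$summaries, cs$cohort[, setdiff(names(cs$cohort),
                                                              "lesion_load")]),
    "lesion_load")
})
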