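# Two-factor ANOVA/MANOVA, Tukey-Kramer and paired t.

test_that("constant responses give zero F and p = 1", {
  fr <- make_frame(3)
  fr$y <- 5
  a <- two_way_anova(fr, "y")
  expect_equal(a$F[1:3], rep(0, 3))
  expect_equal(a$p[1:3], rep(1, 3))
})

test_that("balanced designs match the classical decomposition", {
  fr <- expand.grid(species = c("sp1", "sp2"), sex = c("f", "m"),
                    rep = 1:2, stringsAsFactors = FALSE)
  fr$y <- c(3, 7, 5, 11, 5, 9, 7, 13) # integers, exact arithmetic
  a <- two_way_anova(fr, "y")
  oracle <- oracle_balanced_ss(fr, "y")
  expect_equal(setNames(a$sum_sq, a$term), oracle, tolerance = 1e-10)
  # balanced Type III equals the sequential decomposition too
  seq_ss <- anova(lm(y ~ species * sex, fr))[["Sum Sq"]]
  expect_equal(a$sum_sq, seq_ss, tolerance = 1e-10)
})

test_that("unbalanced designs match the model-comparison oracle", {
  set.seed(7)
  fr <- make_frame(6, effects = c(species = 1, sex = 0.5, inter = 0.3))
  fr <- fr[-c(1, 2, 5), ] # unbalance the cells
  a <- two_way_anova(fr, "y")
  oracle <- oracle_type3_ss(fr, "y")
  expect_equal(setNames(a$sum_sq, a$term), oracle, tolerance = 1e-8)
  pv <- a$p[a$term != "Residuals"]
  expect_true(all(pv >= 0 & pv <= 1))
  # term df + error df account for every observation beyond the mean
  expect_equal(sum(a$df), nrow(fr) - 1)
})

test_that("designs with empty or thin cells are rejected", {
  fr <- make_frame(3)
  expect_error(two_way_anova(fr[fr$species == "sp1" | fr$sex == "f", ], "y"),
               "empty")
  expect_error(two_way_anova(make_frame(1), "y"), ">= 2 observations")
})

test_that("Wilks lambda reduces to the univariate F for one response", {
  set.seed(9)
  fr <- make_frame(5, effects = c(species = 1, sex = 0, inter = 0))
  mv <- manova_wilks(fr, "y")
  a <- two_way_anova(fr, "y")
  sse <- a$sum_sq[a$term == "Residuals"]
  for (tm in c("species", "sex", "species:sex")) {
    ssh <- a$sum_sq[a$term == tm]
    expect_equal(mv$wilks_lambda[mv$term == tm], sse / (sse + ssh),
                 tolerance = 1e-10)
    expect_equal(mv$F_approx[mv$term == tm], a$F[a$term == tm],
                 tolerance = 1e-10)
    expect_equal(mv$p[mv$term == tm], a$p[a$term == tm], tolerance = 1e-10)
  }
})

test_that("duplicated responses trigger a multicollinearity error", {
  fr <- make_frame(4)
  fr$y2 <- fr$y
  expect_error(manova_wilks(fr, c("y", "y2")), "singular|multicollinearity")
})

test_that("MANOVA null p-values are uniform", {
  set.seed(13)
  ps <- replicate(200, {
    fr <- make_frame(5)
    fr$y2 <- rnorm(nrow(fr))
    fr$y3 <- rnorm(nrow(fr))
    manova_wilks(fr, c("y", "y2", "y3"))$p[1]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Wilks lambda stays in (0, 1] and falls with effect size", {
  set.seed(17)
  lam <- vapply(c(0, 1, 2.5), function(eff) {
    mean(replicate(10, {
      fr <- make_frame(6, effects = c(species = eff, sex = 0, inter = 0))
      fr$y2 <- fr$y + rnorm(nrow(fr))
      mv <- manova_wilks(fr, c("y", "y2"))
      lamv <- mv$wilks_lambda[mv$term == "species"]
      expect_gt(lamv, 0); expect_lte(lamv, 1)
      lamv
    }))
  }, numeric(1))
  expect_true(all(diff(lam) < 0))
})

test_that("Tukey on two groups reduces to the two-sample t-test", {
  set.seed(19)
  y <- c(rnorm(8, 0), rnorm(10, 1))
  g <- rep(c("a", "b"), c(8, 10))
  tk <- tukey_hsd(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$comparisons$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$comparisons$q, sqrt(2) * abs(tt$statistic),
               tolerance = 1e-8, ignore_attr = TRUE)

  same <- tukey_hsd(c(y[1:8], y[1:8]), rep(c("a", "b"), each = 8))
  expect_equal(same$comparisons$difference, 0)
  expect_gt(same$comparisons$p_adj, 0.99)
})

test_that("letter display separates a shifted group", {
  set.seed(23)
  y <- c(rnorm(6, 0, 0.3), rnorm(6, 0.2, 0.3), rnorm(6, 50, 0.3))
  g <- rep(c("g1", "g2", "g3"), each = 6)
  tk <- tukey_hsd(y, g)
  expect_equal(tk$letters[["g1"]], tk$letters[["g2"]])
  expect_false(tk$letters[["g3"]] == tk$letters[["g1"]])
})

test_that("paired t follows the textbook formula", {
  bg <- c(0, 0, 0, 0)
  pt0 <- paired_t(c(1, -1, 1, -1), bg)
  expect_equal(pt0$t, 0)
  expect_equal(pt0$p, 1)

  pt1 <- paired_t(c(1, 2, 3, 4), bg)
  expect_equal(pt1$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-9)
  expect_equal(pt1$t, 3.872983, tolerance = 1e-6)
  expect_equal(pt1$df, 3)
  expect_equal(pt1$mean_target, 2.5)

  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(c(2, 2, 2), c(1, 1, 1)), "degenerate")
})

test_that("ANOVA and paired t hold their nominal size under the null", {
  set.seed(29)
  rej_anova <- mean(replicate(400, {
    fr <- make_frame(5)
    two_way_anova(fr, "y")$p[1] < 0.05
  }))
  expect_gt(rej_anova, 0.02)
  expect_lt(rej_anova, 0.08)

  rej_t <- mean(replicate(1000, {
    d <- rnorm(12)
    paired_t(d, rnorm(12))$p < 0.05
  }))
  expect_gt(rej_t, 0.03)
  expect_lt(rej_t, 0.07)
})
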