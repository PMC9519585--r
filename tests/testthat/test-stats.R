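test_that("one-sample t statistics match hand computation", {
  r0 <- one_sample_t(c(-1, 0, 1))
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)

  r <- one_sample_t(c(1, 2, 3))            # mean 2, sd 1
  expect_equal(r$t, 2 * sqrt(3))
  expect_equal(r$d_z, 2)
  expect_equal(r$df, 2)
  expect_error(one_sample_t(c(2, 2, 2)), "variance")
})

test_that("t-test p-value matches a Monte-Carlo null", {
  x <- c(0.3, -0.2, 0.9, 0.4, -0.1)
  obs <- one_sample_t(x)
  n <- length(x)
  t_null <- withr::with_seed(1, {
    draws <- matrix(rnorm(n * 2e5), n)
    mu <- colMeans(draws)
    sdv <- sqrt((colSums(draws^2) - n * mu^2) / (n - 1))
    mu / (sdv / sqrt(n))
  })
  expect_lt(abs(obs$p_value - mean(abs(t_null) >= abs(obs$t))), 0.01)
})

test_that("paired t equals one-sample t on differences", {
  x <- c(1.2, 0.8, 1.5, 0.3); y <- c(0.9, 1.0, 1.1, 0.2)
  expect_equal(paired_t(x, y), one_sample_t(x - y))
  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
})

test_that("Holm step-down rejects per the hand-traced rule", {
  expect_equal(holm_bonferroni(0.03)$p_adjusted, 0.03)
  res <- holm_bonferroni(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_true(all(res$reject))             # .01<.05/3, .02<.05/2, .04<.05
  expect_equal(res$p_adjusted, c(0.03, 0.04, 0.04))

  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(8))
    holm <- holm_bonferroni(p)$reject
    bonf <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(holm >= bonf))         # Holm rejects a superset
    expect_true(all(holm_bonferroni(p)$p_adjusted >= p))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("GG epsilon respects its bounds and closed forms", {
  expect_equal(gg_epsilon(diag(2) + 0.3, 2), 1)            # k = 2: always 1
  cs <- matrix(0.4, 4, 4); diag(cs) <- 1                   # compound symmetry
  expect_equal(gg_epsilon(cs, 4), 1)

  s <- withr::with_seed(2, crossprod(matrix(rnorm(40), 10, 4)) / 10)
  # independent evaluation with a different orthonormal contrast basis:
  # epsilon is basis-invariant
  cp <- contr.poly(4)
  sc <- t(cp) %*% s %*% cp
  eps_oracle <- sum(diag(sc))^2 / (3 * sum(sc^2))
  expect_equal(gg_epsilon(s, 4), eps_oracle, tolerance = 1e-10)

  for (seed in 1:200) {
    k <- 2 + seed %% 4
    ss <- withr::with_seed(seed, crossprod(matrix(rnorm((k + 3) * k), k + 3, k)))
    e <- gg_epsilon(ss, k)
    expect_gte(e, 1 / (k - 1)); expect_lte(e, 1)
  }
  expect_error(gg_epsilon(matrix(c(1, 2, 3, 4), 2), 2), "symmetric")
})

test_that("rm-ANOVA matches the aov error-strata decomposition", {
  set.seed(11)
  d <- tidyr::expand_grid(subject = factor(1:8), a = factor(c("x", "y")),
                          b = factor(c("p", "q", "r")))
  d$y <- rnorm(nrow(d)) + as.numeric(d$a) * 0.5 + as.numeric(d$b) * 0.2 +
    rep(rnorm(8), each = 6)
  fit <- rm_anova(d, dv = "y", within = c("a", "b"), subject = "subject")
  tab <- tidy(fit)

  ref <- summary(aov(y ~ a * b + Error(subject / (a * b)), data = d))
  ref_f <- c(ref[["Error: subject:a"]][[1]]["a", "F value"],
             ref[["Error: subject:b"]][[1]]["b", "F value"],
             ref[["Error: subject:a:b"]][[1]]["a:b", "F value"])
  expect_equal(tab$F, ref_f, tolerance = 1e-10)
  expect_equal(tab$df_num, c(1, 2, 2))
  expect_equal(tab$df_den, c(7, 14, 14))
  expect_true(all(tab$eta_p_sq >= 0 & tab$eta_p_sq <= 1))
  expect_true(all(tab$eta_g_sq <= tab$eta_p_sq))
})

test_that("rm-ANOVA GG correction matches the car reference", {
  set.seed(12)
  d <- tidyr::expand_grid(subject = factor(1:10), w = factor(c("l1", "l2", "l3", "l4")))
  d$y <- rnorm(nrow(d)) + rep(rnorm(10), each = 4) + as.numeric(d$w) * 0.3
  fit <- rm_anova(d, dv = "y", within = "w", subject = "subject")
  tab <- tidy(fit)

  wide <- matrix(d$y[order(d$subject, d$w)], 10, 4, byrow = TRUE)
  mod <- lm(wide ~ 1)
  idata <- data.frame(w = factor(paste0("l", 1:4)))
  av <- suppressWarnings(   # car warns about its HF (not GG) epsilon here
    summary(car::Anova(mod, idata = idata, idesign = ~w), multivariate = FALSE))
  expect_equal(tab$F, av$univariate.tests["w", "F value"], tolerance = 1e-10)
  expect_equal(tab$eps_gg, av$pval.adjustments["w", "GG eps"], tolerance = 1e-10)
  expect_equal(tab$p_gg, av$pval.adjustments["w", "Pr(>F[GG])"], tolerance = 1e-10)
})

test_that("two-level rm-ANOVA reproduces the paired t-test", {
  set.seed(13)
  x <- rnorm(9); y <- rnorm(9) + 0.4
  d <- tibble::tibble(subject = factor(rep(1:9, 2)),
                      cond = factor(rep(c("a", "b"), each = 9)),
                      score = c(x, y))
  fit <- tidy(rm_anova(d, dv = "score", within = "cond", subject = "subject"))
  tt <- paired_t(x, y)
  expect_equal(fit$F, tt$t^2, tolerance = 1e-8)
  expect_equal(fit$p_value, tt$p_value, tolerance = 1e-8)
  expect_equal(fit$eps_gg, 1)

  d$score <- 5                                             # constant outcome
  fit0 <- tidy(rm_anova(d, dv = "score", within = "cond", subject = "subject"))
  expect_equal(fit0$F, 0)

  expect_error(rm_anova(d[-1, ], dv = "score", within = "cond", subject = "subject"),
               "balanced")
})

test_that("Tukey contrasts reduce to t at k = 2 and match simulation at k = 3", {
  expect_equal(tukey_contrasts(c(a = 1, a2 = 1), 2, 10, 8)$p_value, 1)

  # k = 2: studentized range p equals the two-sided t p
  two <- tukey_contrasts(c(m1 = 0.1, m2 = 0.9), error_ms = 0.5, df_err = 12, n = 7)
  t_stat <- abs(0.1 - 0.9) / sqrt(2 * 0.5 / 7)
  expect_equal(two$p_value, 2 * pt(-t_stat, 12), tolerance = 1e-10)

  means <- c(m1 = 0, m2 = 0.45, m3 = 1)
  res <- tukey_contrasts(means, error_ms = 0.4, df_err = 14, n = 8)
  q_null <- withr::with_seed(3, {
    draws <- matrix(rnorm(3 * 1e5, sd = 1), ncol = 3)
    ms <- 0.4 * rchisq(1e5, 14) / 14
    apply(draws, 1, function(z) diff(range(z))) / sqrt(ms / 0.4)
  })
  for (j in seq_len(nrow(res))) {
    expect_lt(abs(res$p_value[j] - mean(q_null >= res$q[j])), 0.01)
  }
})

test_that("effect-size conversion and power functions match printed anchors", {
  expect_equal(cohens_f_from_partial_eta(0.64), 1.33, tolerance = 0.005)
  expect_equal(cohens_f_from_partial_eta(0), 0)
  expect_equal(cohens_f_from_partial_eta(0.5), 1)
  expect_error(cohens_f_from_partial_eta(1), "< 1")

  expect_equal(power_one_sample_t(0, 40), 0.05, tolerance = 1e-10)
  expect_gt(power_one_sample_t(1.76, 174), 1 - 1e-12)
  expect_equal(power_rm_anova_spss(0, 10, 174), 0.05, tolerance = 1e-10)
  expect_gt(power_rm_anova_spss(1.33, 10, 174), 1 - 1e-12)
})

test_that("power functions match Monte-Carlo rejection rates", {
  pw <- power_one_sample_t(0.5, 30)
  rej <- withr::with_seed(4, {
    mean(replicate(40, {
      draws <- matrix(rnorm(30 * 5000, mean = 0.5), 30)
      mu <- colMeans(draws)
      sdv <- sqrt((colSums(draws^2) - 30 * mu^2) / 29)
      mean(abs(mu / (sdv / sqrt(30))) > qt(0.975, 29))
    }))
  })
  expect_lt(abs(pw - rej), 0.005)

  # non-central F from its chi-squared definition
  f <- 0.25; m <- 4; n <- 20
  pw2 <- power_rm_anova_spss(f, m, n)
  rej2 <- withr::with_seed(5, {
    df1 <- m - 1; df2 <- (n - 1) * df1
    fstat <- (rchisq(2e5, df1, ncp = f^2 * n) / df1) / (rchisq(2e5, df2) / df2)
    mean(fstat > qf(0.95, df1, df2))
  })
  expect_lt(abs(pw2 - rej2), 0.005)
})

test_that("power is monotone in effect size, sample size and alpha", {
  expect_true(all(diff(vapply(c(0.1, 0.3, 0.5, 0.8), power_one_sample_t,
                              numeric(1), n = 20)) > 0))
  expect_true(all(diff(vapply(c(10, 20, 40, 80), function(n)
    power_one_sample_t(0.4, n), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.01, 0.05, 0.1), function(a)
    power_one_sample_t(0.4, 20, alpha = a), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0.1, 0.4, 0.8), function(f)
    power_rm_anova_spss(f, 5, 20), numeric(1))) > 0))
})
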