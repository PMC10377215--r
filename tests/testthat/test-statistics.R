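test_that("Pearson correlation matches hand formulas and brackets r", {
  expect_equal(pearson_r_ci(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r_ci(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(pearson_r_ci(c(1, 2, 3), c(1, 2, 4))$r, 3 / sqrt(2 * 42 / 9),
               tolerance = 1e-12)
  expect_equal(round(pearson_r_ci(c(1, 2, 3), c(1, 2, 4))$r, 4), 0.982)

  set.seed(13)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  cr <- pearson_r_ci(x, y)
  # independent Fisher-z oracle
  z <- atanh(cr$r); se <- 1 / sqrt(40 - 3)
  expect_equal(cr$ci_low, tanh(z - qnorm(0.975) * se), tolerance = 1e-10)
  expect_equal(cr$ci_high, tanh(z + qnorm(0.975) * se), tolerance = 1e-10)
  t_or <- cr$r * sqrt((40 - 2) / (1 - cr$r^2))
  expect_equal(cr$p, 2 * pt(-abs(t_or), 40 - 2), tolerance = 1e-10)
  expect_true(cr$ci_low <= cr$r && cr$r <= cr$ci_high)
  # cor.test as a second, independent implementation
  ct <- cor.test(x, y)
  expect_equal(cr$r, unname(ct$estimate))
  expect_equal(c(cr$ci_low, cr$ci_high), as.numeric(ct$conf.int), tolerance = 1e-10)
  expect_equal(cr$p, ct$p.value, tolerance = 1e-10)

  expect_error(pearson_r_ci(rep(1, 5), 1:5), class = "physari_validation_error")
  expect_error(pearson_r_ci(1:2, 1:2), class = "physari_validation_error")
})

test_that("Cohen's kappa matches hand arithmetic and its symmetries", {
  k <- kappa_from_table(40, 10, 10, 40)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$p_o, 0.8)
  expect_equal(k$p_e, 0.5)
  expect_true(k$ci_low < 0.6 && k$ci_high > 0.6)

  m <- matrix(as.integer(runif(400, 0, 1) < 0.3), 20, 20)
  expect_equal(cohen_kappa(m, m)$kappa, 1)
  set.seed(21)
  a <- matrix(as.integer(runif(400) < 0.4), 20, 20)
  b <- a; flip <- sample(400, 40); b[flip] <- 1L - b[flip]
  expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(1L - a, 1L - b)$kappa,
               tolerance = 1e-12)
  # kappa is symmetric in the raters
  expect_equal(cohen_kappa(a, b)$kappa, cohen_kappa(b, a)$kappa)
  # domain restriction only scores the selected pixels
  dom <- matrix(0L, 20, 20); dom[1:10, ] <- 1L
  kd <- cohen_kappa(a, b, domain = dom)
  expect_equal(kd$n, 200)

  expect_error(kappa_from_table(10, 0, 0, 0), class = "physari_undefined_kappa")
})

test_that("Mann-Whitney U equals the all-pairs counting oracle", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$U, 9)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U, 4.5)  # nA*nB/2
  set.seed(31)
  for (i in 1:20) {
    nA <- sample(3:20, 1); nB <- sample(3:20, 1)
    a <- sample.int(12, nA, replace = TRUE)  # ties likely
    b <- sample.int(12, nB, replace = TRUE)
    res <- mann_whitney_u(a, b)
    expect_equal(unname(res$U), oracle_u(a, b))
    expect_true(res$p >= 0 && res$p <= 1)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), class = "physari_validation_error")
})

test_that("normality screening flags uniform data and passes normal data", {
  set.seed(41)
  expect_gt(ks_normality(rnorm(200))$p, 0.05)
  expect_lt(ks_normality(runif(200))$p, 0.05)
  expect_error(ks_normality(rep(2, 10)), class = "physari_validation_error")
  expect_error(ks_normality(rnorm(3)), class = "physari_validation_error")
})

test_that("multiple regression matches an independent normal-equations solve", {
  set.seed(51)
  n <- 40
  X <- data.frame(a = rnorm(n), b = runif(n), c = rnorm(n, 2))
  y <- 1.5 + 2 * X$a - 0.5 * X$b + rnorm(n, sd = 0.3)
  reg <- multiple_regression(y, X)

  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(unname(reg$table$coefficient), unname(beta[, 1]), tolerance = 1e-8)
  resid <- y - Xm %*% beta
  s2 <- sum(resid^2) / (n - ncol(Xm))
  se <- sqrt(diag(s2 * solve(t(Xm) %*% Xm)))
  expect_equal(unname(reg$table$se), unname(se), tolerance = 1e-8)
  # partial correlation from t and residual df
  t_a <- reg$table$t[reg$table$term == "a"]
  expect_equal(reg$table$r_partial[reg$table$term == "a"],
               t_a / sqrt(t_a^2 + reg$df2))
  expect_true(reg$r_squared >= 0 && reg$r_squared <= 1)

  # row permutation leaves the table unchanged
  perm <- sample(n)
  reg2 <- multiple_regression(y[perm], X[perm, ])
  expect_equal(reg$table, reg2$table, tolerance = 1e-10)

  # exact linear response: R^2 = 1 and the predictor is overwhelmingly significant
  y_lin <- 3 + 2 * X$a
  reg3 <- suppressWarnings(multiple_regression(y_lin, X["a"]))  # perfect fit
  expect_equal(reg3$r_squared, 1)
  expect_lt(reg3$table$p[reg3$table$term == "a"], 1e-12)

  X_bad <- X; X_bad$dup <- 2 * X$a
  expect_error(multiple_regression(y, X_bad), "dup", class = "physari_rank_error")
  expect_error(multiple_regression(1:3, data.frame(a = 1:3, b = 4:6)),
               class = "physari_validation_error")
})

test_that("descriptive summaries use n-1 SD, t-based CI and midpoint median", {
  r <- cohort_summary(c(1, 2, 3), "demo")
  expect_equal(r$mean, 2); expect_equal(r$median, 2)
  expect_equal(r$min, 1); expect_equal(r$max, 3)
  expect_equal(r$sd, 1)
  expect_equal(r$sem, 1 / sqrt(3))
  expect_equal(r$ci_low, 2 - qt(0.975, 2) / sqrt(3))
  expect_equal(cohort_summary(c(1, 2, 3, 10), "even")$median, 2.5)
  expect_error(cohort_summary(5), class = "physari_validation_error")
})

test_that("observer averaging is the arithmetic mean and demands completeness", {
  tab <- data.frame(
    subject_id = rep(c("S1", "S2"), each = 3),
    observer_id = rep(c("Obs1", "Obs2", "Obs3"), 2),
    age = rep(c(12, 15), each = 3), sex = rep(c("F", "M"), each = 3),
    ARI = c(9, 10, 11, 20, 20, 20)
  )
  avg <- average_over_observers(tab)
  expect_equal(avg$ARI, c(10, 20))
  single <- tab[tab$observer_id == "Obs1", ]
  expect_equal(average_over_observers(single)$ARI, c(9, 20))
  expect_error(average_over_observers(tab[-1, ]),
               class = "physari_completeness_error")
})
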