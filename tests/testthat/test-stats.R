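# Statistical battery: RMA closed forms and equivariance, paired tests and
# their degenerate cases, type-I calibration, and factorial ANOVA.

test_that("model II regression reproduces exact lines", {
  x <- c(1, 2, 3, 5, 8)
  f <- model2_regression(x, x)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  f2 <- model2_regression(x, 2 * x + 3)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 3)
  expect_equal(tidy(f2)$estimate, c(3, 2))
  expect_equal(glance(f2)$r_squared, 1)
  expect_error(model2_regression(x, rep(1, 5)), "variance")
  expect_error(model2_regression(x[1:2], x[1:2]), "3")
})

test_that("RMA slope equals sign(r) sd(y)/sd(x) and is scale-equivariant", {
  withr::local_seed(5)
  x <- rnorm(1e4)
  y <- x + rnorm(1e4)
  f <- model2_regression(x, y)
  expect_equal(f$slope, sign(cor(x, y)) * sd(y) / sd(x))
  expect_equal(f$slope, sqrt(2), tolerance = 0.03)   # attenuation-free
  for (c_scale in c(0.2, 3, 10)) {
    expect_equal(model2_regression(c_scale * x, y)$slope,
                 f$slope / c_scale, tolerance = 1e-12)
  }
  # negative association carries a negative slope
  expect_lt(model2_regression(x, -y)$slope, 0)
})

test_that("paired tests handle identities and degenerate inputs", {
  a <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(a, a - 1), "undefined")
  expect_error(paired_t(a, a[1:3]), "equal length")
  w <- wilcoxon_signed_rank(a, rev(a))
  expect_true(w$p_value >= 0 && w$p_value <= 1)
  p <- pearson(a, 2 * a + 1)
  expect_equal(p$r, 1)
})

test_that("paired t and KS keep their nominal type-I error under the null", {
  withr::local_seed(6)
  reps <- 200
  t_p <- numeric(reps); ks_p <- numeric(reps)
  for (i in seq_len(reps)) {
    a <- rnorm(20); b <- rnorm(20)
    t_p[i] <- paired_t(a, b)$p_value
    ks_p[i] <- stats::ks.test(rnorm(50), rnorm(50))$p.value
  }
  expect_gt(mean(t_p < 0.05), 0.015)
  expect_lt(mean(t_p < 0.05), 0.10)
  expect_gt(mean(ks_p < 0.05), 0.005)
  expect_lt(mean(ks_p < 0.05), 0.10)
  # and the t p-values are uniform
  expect_gt(stats::ks.test(t_p, "punif")$p.value, 0.01)
})

test_that("factorial ANOVA covers degenerate, algebraic, and design cases", {
  tab <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:5)
  tab$response <- 1
  res <- factorial_anova(tab, c("a", "b"))
  expect_equal(res$statistic[1:2], c(0, 0))
  expect_equal(res$p_value[1:2], c(1, 1))

  # balanced two-level single factor: F = t^2
  withr::local_seed(7)
  tab2 <- tibble::tibble(a = rep(c("x", "y"), each = 12),
                         response = rnorm(24) + rep(c(0, 1), each = 12))
  res2 <- factorial_anova(tab2, "a")
  tt <- stats::t.test(response ~ a, data = tab2, var.equal = TRUE)
  expect_equal(res2$statistic[1], unname(tt$statistic)^2, tolerance = 1e-9)

  # empty cells are reported
  tab3 <- tab[tab$a != "x" | tab$b != "v", ]
  tab3$response <- rnorm(nrow(tab3))
  expect_error(factorial_anova(tab3, c("a", "b")), "empty design cells")
})

test_that("ANOVA detects only the factor with an injected effect", {
  withr::local_seed(8)
  hits <- matrix(0, 100, 3)
  for (i in 1:100) {
    tab <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"),
                              c = c("p", "q"), rep = 1:10)
    tab$response <- rnorm(nrow(tab)) + ifelse(tab$a == "y", 2, 0)
    res <- factorial_anova(tab, c("a", "b", "c"))
    hits[i, ] <- res$p_value[1:3] < 0.001
  }
  expect_gte(mean(hits[, 1]), 0.95)
  expect_lte(mean(hits[, 2]), 0.05)
  expect_lte(mean(hits[, 3]), 0.05)
})

test_that("ANOVA p-values are uniform under label permutation", {
  withr::local_seed(9)
  y <- rnorm(60)
  ps <- vapply(1:500, function(i) {
    tab <- tibble::tibble(a = sample(rep(c("x", "y", "z"), each = 20)),
                          response = y)
    factorial_anova(tab, "a")$p_value[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
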