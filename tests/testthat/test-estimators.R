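test_that("all six methods match the frozen worked example to 1e-6", {
  fit <- fit_pareto(worked_example$x)
  got <- tidy(fit)
  exp <- worked_example$expected
  expect_equal(got$method, exp$method)
  expect_equal(got$beta_hat, exp$beta_hat, tolerance = 1e-6)
  expect_equal(got$alpha_hat, exp$alpha_hat, tolerance = 1e-6)
})

test_that("fit_pareto agrees with a naive scalar re-derivation on random data", {
  for (s in 1:5) {
    x <- rpareto(30, 1.5, 1.2, seed = s)
    got <- tidy(fit_pareto(x))
    for (i in seq_len(nrow(got))) {
      o <- oracle_fit(x, got$method[i])
      expect_equal(got$beta_hat[i], unname(o[1]), tolerance = 1e-10)
      expect_equal(got$alpha_hat[i], unname(o[2]), tolerance = 1e-10)
    }
  }
})

test_that("population summaries are recovered exactly by every method", {
  for (i in seq_len(nrow(test_pairs))) {
    b <- test_pairs$beta[i]; a <- test_pairs$alpha[i]
    p25 <- qpareto(0.25, b, a); p75 <- qpareto(0.75, b, a)

    r <- est_pe(p25, p75)
    expect_equal(c(r$beta_hat, r$alpha_hat), c(b, a), tolerance = 1e-12)

    r <- est_pe1(pareto_median(b, a), p75)
    expect_equal(c(r$beta_hat, r$alpha_hat), c(b, a), tolerance = 1e-12)

    r <- est_pe2(pareto_gmean(b, a), p75)
    expect_equal(c(r$beta_hat, r$alpha_hat), c(b, a), tolerance = 1e-12)

    # minimum consistent with E[F(x(1))] = 1/(n+1)
    for (n in c(3, 10, 50)) {
      xmin <- qpareto(1 / (n + 1), b, a)
      r <- est_pe3(xmin, p75, n)
      expect_equal(c(r$beta_hat, r$alpha_hat), c(b, a), tolerance = 1e-12)
    }

    r <- est_ml(xmin = b, mean_log = log(b) + 1 / a, n = 25)
    expect_equal(c(r$beta_hat, r$alpha_hat), c(b, a), tolerance = 1e-12)
  }
  # method of moments needs a finite variance (alpha > 2)
  for (a in c(2.5, 3, 4.5)) {
    for (b in c(1, 2)) {
      m <- b * a / (a - 1)
      v <- b^2 * a / ((a - 1)^2 * (a - 2))
      r <- est_mm(m, sqrt(v))
      expect_equal(c(r$beta_hat, r$alpha_hat), c(b, a), tolerance = 1e-10)
    }
  }
})

test_that("estimates are scale-equivariant across 1000 random samples", {
  set.seed(1)
  worst <- 0
  for (r in 1:1000) {
    x <- qpareto(runif(20), 1, 0.8)
    c_scale <- exp(runif(1, -2, 4))
    f1 <- tidy(fit_pareto(x))
    f2 <- tidy(fit_pareto(c_scale * x))
    # a method degenerate on x must be degenerate on c*x and vice versa
    if (!identical(is.na(f1$beta_hat), is.na(f2$beta_hat))) worst <- Inf
    worst <- max(worst,
                 abs(f2$beta_hat - c_scale * f1$beta_hat) / c_scale,
                 abs(f2$alpha_hat - f1$alpha_hat), na.rm = TRUE)
  }
  expect_lt(worst, 1e-10)
})

test_that("structural properties: ML scale is the minimum, MM shape exceeds 2", {
  for (s in 1:20) {
    x <- rpareto(15, 2, 1.5, seed = 200 + s)
    got <- tidy(fit_pareto(x, methods = c("ml", "mm")))
    expect_identical(got$beta_hat[got$method == "ML"], min(x))
    expect_gt(got$alpha_hat[got$method == "ML"], 0)
    expect_gt(got$alpha_hat[got$method == "MM"], 2)
  }
})

test_that("estimation error shrinks with sample size for every method", {
  mean_abs_err <- function(n) {
    est <- attr(simulate_pareto_cell(
      1, 1, n, reps = 1000, seed = 77,
      methods = c("pe", "pe1", "pe2", "pe3", "ml", "mm"),
      keep_replicates = TRUE), "replicates")
    est |>
      dplyr::group_by(method) |>
      dplyr::summarise(err = mean(abs(beta_hat - 1) + abs(alpha_hat - 1),
                                  na.rm = TRUE))
  }
  small <- mean_abs_err(50)
  large <- mean_abs_err(2000)
  cmp <- dplyr::inner_join(small, large, by = "method",
                           suffix = c("_small", "_large"))
  expect_true(all(cmp$err_large < cmp$err_small))
})

test_that("degenerate samples are flagged, strict mode raises typed errors", {
  fit <- fit_pareto(c(2, 2, 2, 2))
  expect_true(all(is.na(fit$estimates$beta_hat)))
  expect_true(all(fit$estimates$note == "degenerate"))
  expect_error(fit_pareto(c(2, 2, 2, 2), strict = TRUE),
               class = "paretile_error_degenerate")
  expect_error(fit_pareto(3), class = "paretile_error_input")

  # tied summary inputs degenerate the kernels to NA, never to +-Inf
  expect_true(is.na(est_pe(2, 2)$alpha_hat))
  expect_true(is.na(est_pe1(4, 4)$alpha_hat))
  expect_true(is.na(est_pe2(4, 4)$alpha_hat))
  expect_true(is.na(est_pe3(4, 4, 10)$alpha_hat))
  expect_true(is.na(est_ml(2, log(2), 5)$alpha_hat))
  expect_true(is.na(est_mm(3, 0)$alpha_hat))
})

test_that("method labels accept codes and display names", {
  x <- c(1, 2, 3, 4, 5)
  a <- tidy(fit_pareto(x, methods = c("pe3", "ML")))
  expect_equal(a$method, c("PE-III", "ML"))
  expect_error(fit_pareto(x, methods = "nope"), class = "paretile_error_input")
})
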