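test_that("ppv reproduces the worked single-test updates", {
  # one positive 80/90 test lifts a 20% prior to 2/3
  expect_equal(ppv(0.20, make_test_matrix(0.80, 0.90)), 2 / 3,
               tolerance = 1e-12)
  # worthless test leaves the prior untouched
  expect_equal(ppv(0.20, make_test_matrix(0.5, 0.5)), 0.20,
               tolerance = 1e-15)
  # bias-inverted 80/95 test at a 50/50 prior
  inverted <- make_asymmetric_matrix(0.20, 0.95)
  expect_equal(ppv(0.50, inverted), 0.20 / 1.15, tolerance = 1e-12)
  expect_equal(round_percent(ppv(0.50, inverted)), 17L)
  # absorbing endpoints
  expect_equal(ppv(1, make_test_matrix(0.8, 0.9)), 1)
  expect_equal(ppv(0, make_test_matrix(0.8, 0.9)), 0)
})

test_that("alternative_ppv is the exact complement", {
  m <- make_test_matrix(0.80, 0.90)
  expect_equal(alternative_ppv(0.20, m), 1 / 3, tolerance = 1e-12)
  expect_equal(alternative_ppv(0.50, make_asymmetric_matrix(0.20, 0.95)),
               0.95 / 1.15, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:200) {
    mm <- random_matrix_pair()[[1]]
    p <- runif(1)
    if (p * mm$tp + (1 - p) * mm$fp <= 0) next
    expect_equal(ppv(p, mm) + alternative_ppv(p, mm), 1, tolerance = 1e-12)
  }
})

test_that("posterior_negative applies the complementary Bayes update", {
  # 0.2*0.2 / (0.2*0.2 + 0.8*0.9) = 0.04 / 0.76
  expect_equal(posterior_negative(0.20, make_test_matrix(0.8, 0.9)),
               0.04 / 0.76, tolerance = 1e-12)
  expect_equal(posterior_negative(0.20, make_test_matrix(0.5, 0.5)), 0.20,
               tolerance = 1e-15)
  expect_equal(posterior_negative(0, make_test_matrix(0.8, 0.9)), 0)
})

test_that("a zero-probability result raises an undefined-posterior error", {
  perfect <- make_test_matrix(1, 1)
  expect_error(ppv(0, perfect), class = "diagbias_undefined_posterior")
  expect_error(posterior_negative(1, perfect),
               class = "diagbias_undefined_posterior")
  expect_error(ppv(1.5, perfect), class = "diagbias_domain_error")
})

test_that("update_sequence iterates Bayes updates and records the trace", {
  m <- make_test_matrix(0.8, 0.9)
  tr <- update_sequence(0.20, m, c("+", "+"))
  expect_s3_class(tr, "update_trace")
  expect_length(tr$posteriors, 2L)
  expect_equal(tr$posteriors[1], 2 / 3, tolerance = 1e-12)
  expect_equal(tr$posteriors[2], 16 / 17, tolerance = 1e-12)  # 0.9412
  expect_gt(tr$posteriors[2], 0.90)

  empty <- update_sequence(0.20, m, character(0))
  expect_length(empty$posteriors, 0L)
  expect_equal(empty$prior, 0.20)

  mixed <- update_sequence(0.20, m, c("+", "-", "+"))
  expect_equal(mixed$posteriors[3], lr_posterior(0.20, m, c("+", "-", "+")),
               tolerance = 1e-12)

  expect_error(update_sequence(0.2, m, c("+", "x")),
               class = "diagbias_usage_error")

  df <- as.data.frame(tr)
  expect_identical(df$posterior_pct, c(67L, 94L))
})

test_that("a worthless or zero-Youden matrix leaves every posterior at the prior", {
  halfbias <- compose(make_bias_matrix(0.5), make_test_matrix(0.8, 0.9))
  tr <- update_sequence(0.20, halfbias, rep("+", 10))
  expect_equal(tr$posteriors, rep(0.20, 10), tolerance = 1e-12)
  set.seed(77)
  for (i in 1:100) {
    u <- runif(2)  # tp == fp gives Youden 0
    m0 <- make_asymmetric_matrix(u[1], u[1])
    p <- runif(1, 0.01, 0.99)
    res <- sample(c("+", "-"), 5, replace = TRUE)
    expect_equal(update_sequence(p, m0, res)$posteriors, rep(p, 5),
                 tolerance = 1e-12)
  }
})

test_that("positive updates are monotone in the sign of the Youden index", {
  set.seed(123)
  for (i in 1:200) {
    m <- random_matrix_pair()[[1]]
    p <- runif(1, 0.01, 0.99)
    J <- youden(m)
    if (abs(J) < 1e-9) next
    post <- ppv(p, m)
    if (J > 0) expect_gt(post, p) else expect_lt(post, p)
  }
  # ppv strictly increasing in the prior for a useful test
  m <- make_test_matrix(0.8, 0.9)
  ps <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(vapply(ps, ppv, 0, m = m)) > 0))
})

test_that("the final posterior is order-invariant and matches the likelihood-ratio oracle", {
  set.seed(2024)
  for (i in 1:100) {
    u <- runif(2, 0.05, 0.95)  # keep all four LRs finite
    m <- make_asymmetric_matrix(u[1], u[2])
    p <- runif(1, 0.05, 0.95)
    res <- sample(c("+", "-"), 6, replace = TRUE)
    final <- update_sequence(p, m, res)$posteriors[6]
    shuffled <- update_sequence(p, m, sample(res))$posteriors[6]
    expect_equal(final, shuffled, tolerance = 1e-12)
    expect_equal(final, lr_posterior(p, m, res), tolerance = 1e-12)
  }
})

test_that("iterated positive updates match the closed-form k-test posterior", {
  set.seed(404)
  for (i in 1:100) {
    m <- make_asymmetric_matrix(runif(1, 0.05, 1), runif(1, 0.05, 1))
    p <- runif(1, 0.01, 0.99)
    k <- sample(1:8, 1)
    tr <- update_sequence(p, m, rep("+", k))
    expect_equal(tr$posteriors[k], closed_form_k_posterior(p, m, k),
                 tolerance = 1e-12)
  }
})

test_that("min_positive_tests finds the threshold crossing and honours its contract", {
  m <- make_test_matrix(0.8, 0.9)
  res <- min_positive_tests(0.20, m, 0.90)
  expect_s3_class(res, "chain_search")
  expect_identical(res$n_tests, 2L)
  expect_true(res$reachable)
  # contract: crossing at n, not at n - 1
  expect_gt(res$trace$posteriors[res$n_tests], 0.90)
  expect_lte(res$trace$posteriors[res$n_tests - 1], 0.90)

  biased20 <- compose(make_bias_matrix(0.2), m)
  expect_identical(min_positive_tests(0.20, biased20, 0.90)$n_tests, 4L)

  # 30% bias: closed-form oracle locates the full-precision crossing
  biased30 <- compose(make_bias_matrix(0.3), m)
  want <- closed_form_min_tests(0.20, biased30, 0.90)
  got <- min_positive_tests(0.20, biased30, 0.90)
  expect_identical(got$n_tests, want)
  expect_identical(got$n_tests, 6L)

  expect_error(min_positive_tests(0.2, m, 1.5),
               class = "diagbias_usage_error")
  expect_error(min_positive_tests(0.2, m, 0.9, max_tests = 0),
               class = "diagbias_usage_error")
})

test_that("min_positive_tests reports the unreachable sentinel, not an error", {
  m <- make_test_matrix(0.8, 0.9)
  # 50% bias pins the posterior at the prior
  pinned <- min_positive_tests(0.20, compose(make_bias_matrix(0.5), m), 0.90)
  expect_false(pinned$reachable)
  expect_identical(pinned$n_tests, NA_integer_)

  # inverted tester can never rise either
  inv <- min_positive_tests(0.20, compose(make_bias_matrix(1), m), 0.90)
  expect_false(inv$reachable)

  # reachable in principle but not within max_tests
  slow <- min_positive_tests(0.20, compose(make_bias_matrix(0.45), m), 0.90,
                             max_tests = 10)
  expect_false(slow$reachable)
  expect_true(all(slow$trace$posteriors <= 0.90))
  out <- capture.output(print(pinned))
  expect_match(out, "unreachable")
})
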