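test_that("concordance index hits the closed-form extremes", {
  d <- tibble::tibble(time = c(1, 2, 3), status = c(1, 1, 1))
  expect_equal(concordance_index(d, c(1, 2, 3)), 1)
  expect_equal(concordance_index(d, c(3, 2, 1)), 0)
  expect_error(concordance_index(tibble::tibble(time = c(1, 1), status = c(1, 1)),
                                 c(1, 2)), "no comparable pairs")
})

test_that("tie policies differ only on tied scores", {
  d <- tibble::tibble(time = c(1, 2, 3), status = c(1, 1, 1))
  s <- c(1, 1, 2)
  expect_equal(concordance_index(d, s, tie_policy = "strict"), 2 / 3)
  expect_equal(concordance_index(d, s, tie_policy = "half"), 2.5 / 3)
})

test_that("concordance matches the nested-loop oracle on random instances", {
  for (seed in 1:10) {
    d <- random_cohort(25, seed = seed, tie_prob = if (seed %% 3 == 0) 0.3 else 0)
    s <- withr::with_seed(seed + 100, round(rnorm(25), if (seed %% 2) 1 else 6))
    for (tp in c("strict", "half")) {
      expect_identical(concordance_index(d, s, tie_policy = tp),
                       oracle_ci(d$time, d$status, s, tp))
    }
  }
})

test_that("concordance is invariant under strictly increasing transforms", {
  d <- random_cohort(30, seed = 3)
  s <- withr::with_seed(4, rnorm(30))
  ci <- concordance_index(d, s)
  expect_equal(concordance_index(d, exp(s)), ci)
  expect_equal(concordance_index(d, 5 * s - 2), ci)
})

test_that("smoothed concordance matches closed forms and stays bounded", {
  d <- random_cohort(20, seed = 5)
  expect_equal(smoothed_ci(d, rep(1.7, 20)), 0.5)

  d2 <- tibble::tibble(time = c(1, 2), status = c(1, 1))
  expect_equal(smoothed_ci(d2, c(0, 1), alpha = 1), 1 / (1 + exp(-1)),
               tolerance = 1e-12)

  # stable for |alpha * gap| up to 1e4: saturates cleanly, never NaN/Inf
  big <- smoothed_ci(d2, c(0, 1), alpha = 1e4)
  expect_true(is.finite(big) && big > 1 - 1e-10 && big <= 1)
  small <- smoothed_ci(d2, c(1, 0), alpha = 1e4)
  expect_true(is.finite(small) && small >= 0 && small < 1e-10)
})

test_that("smoothed concordance equals the term-by-term oracle", {
  for (seed in 1:6) {
    d <- random_cohort(25, seed = seed)
    s <- withr::with_seed(seed + 50, rnorm(25))
    for (a in c(0.5, 1, 10)) {
      expect_equal(smoothed_ci(d, s, alpha = a),
                   oracle_sci(d$time, d$status, s, a), tolerance = 1e-12)
    }
  }
})

test_that("smoothing limits: alpha large recovers CI, alpha small flattens to 0.5", {
  d <- random_cohort(30, seed = 11, censor_prob = 0.25)
  s <- withr::with_seed(12, {
    raw <- rnorm(30)
    rank(raw) * 0.25  # pairwise gaps >= 0.25
  })
  ci <- concordance_index(d, s)
  expect_lt(abs(smoothed_ci(d, s, alpha = 50) - ci), 1e-3)
  expect_lt(abs(smoothed_ci(d, s, alpha = 1e-4) - 0.5), 1e-3)
})

test_that("scale moves between alpha and scores; shifts are irrelevant", {
  d <- random_cohort(25, seed = 21)
  s <- withr::with_seed(22, rnorm(25))
  expect_equal(smoothed_ci(d, s + 3.7, alpha = 2), smoothed_ci(d, s, alpha = 2))
  expect_equal(smoothed_ci(d, 4 * s, alpha = 0.5), smoothed_ci(d, s, alpha = 2),
               tolerance = 1e-12)
})

test_that("analytic gradient matches the trivial uniform-score case", {
  d <- tibble::tibble(time = c(1, 2, 3), status = c(1, 1, 1))
  g <- sci_gradient(d, rep(0, 3), alpha = 1)
  expect_equal(g, c(-1 / 6, 0, 1 / 6), tolerance = 1e-14)
})

test_that("gradient matches finite differences, sums to zero, and respects its bound", {
  for (seed in 1:30) {
    n <- withr::with_seed(seed, sample(5:20, 1))
    d <- random_cohort(n, seed = seed + 400)
    if (nrow(comparable_pairs(d)) == 0) next
    s <- withr::with_seed(seed + 800, rnorm(n))
    a <- c(0.5, 1, 2)[seed %% 3 + 1]
    g <- sci_gradient(d, s, alpha = a)
    fd <- fd_gradient(function(v) smoothed_ci(d, v, alpha = a), s)
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-6)
    expect_lt(abs(sum(g)), 1e-12)
    p <- comparable_pairs(d)
    deg <- tabulate(c(p$i, p$j), nbins = n)
    expect_true(all(abs(g) <= a * deg / (4 * nrow(p)) + 1e-15))
  }
})

test_that("a small ascent step along the gradient increases the objective", {
  for (seed in 1:5) {
    d <- random_cohort(15, seed = seed + 60)
    s <- withr::with_seed(seed, rnorm(15))
    g <- sci_gradient(d, s, alpha = 1)
    if (max(abs(g)) == 0) next
    before <- smoothed_ci(d, s, alpha = 1)
    after <- smoothed_ci(d, s + 1e-4 * g, alpha = 1)
    expect_gt(after, before)
  }
})
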