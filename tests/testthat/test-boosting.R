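# Smaller problem sizes than the defaults throughout: the stage loop's
# correctness properties do not depend on cohort scale.

test_that("line search honors its contract on constructed objectives", {
  # zero direction: objective constant, rho 0 returned
  d <- random_cohort(20, seed = 7)
  s <- withr::with_seed(8, rnorm(20))
  ls <- line_search_rho(d, s, rep(0, 20))
  expect_equal(ls$rho, 0)
  expect_equal(ls$sci, smoothed_ci(d, s), tolerance = 1e-12)

  # monotone objective: boundary maximizer
  d2 <- tibble::tibble(time = c(1, 2), status = c(1, 1))
  ls2 <- line_search_rho(d2, scores = c(1, 0), tree_preds = c(-1, 1), alpha = 1)
  expect_equal(ls2$rho, 100)
  expect_equal(ls2$sci, 1 / (1 + exp(1 - 200)), tolerance = 1e-12)
})

test_that("line search result is never below the current objective or a dense grid", {
  grid <- seq(0, 100, length.out = 2001)
  for (seed in 1:8) {
    d <- random_cohort(30, seed = seed + 120)
    s <- withr::with_seed(seed, rnorm(30, sd = 2))
    g <- sci_gradient(d, s, alpha = 1)
    tr <- fit_tree(as.matrix(d[c("x1", "x2")]), g, depth = 2, min_obs = 3)
    preds <- predict(tr, as.matrix(d[c("x1", "x2")]))
    ls <- line_search_rho(d, s, preds, alpha = 1)
    expect_gte(ls$sci, smoothed_ci(d, s) - 1e-12)
    dense <- max(vapply(grid, function(r) smoothed_ci(d, s + r * preds),
                        numeric(1)))
    expect_gte(ls$sci, dense - 1e-9)
  }
})

test_that("an empty ensemble predicts the Cox initialization", {
  sim <- simulate_ph(n = 150, p = 2, beta = c(1, -0.5), censor_rate = 0.2, seed = 31)
  fit <- fit_gbmci(sim$data, n_trees = 0, cv_folds = 0, seed = 1)
  cox <- fit_coxph(sim$data)
  expect_equal(predict(fit, sim$data), predict(cox, sim$data), tolerance = 1e-12)
  expect_equal(concordance_index(sim$data, predict(fit, sim$data)),
               concordance_index(sim$data, predict(cox, sim$data)))
})

test_that("full-bag training keeps the smoothed concordance non-decreasing", {
  sim <- simulate_nonlinear(n = 120, censor_rate = 0.25, seed = 33)
  fit <- fit_gbmci(sim$data, n_trees = 40, depth = 2, bag_fraction = 1,
                   cv_folds = 0, seed = 2)
  expect_true(all(diff(c(smoothed_ci(sim$data,
                                     predict(fit, sim$data, n_stages = 0)),
                         fit$training_log)) >= -1e-12))
})

test_that("the additive decomposition holds stage by stage", {
  sim <- simulate_ph(n = 120, p = 2, beta = c(1, -1), censor_rate = 0.2, seed = 35)
  fit <- fit_gbmci(sim$data, n_trees = 8, depth = 2, cv_folds = 0, seed = 3)
  x <- as.matrix(sim$data[fit$feature_names])
  for (m in seq_along(fit$stages)) {
    delta <- predict(fit, sim$data, n_stages = m) -
      predict(fit, sim$data, n_stages = m - 1)
    st <- fit$stages[[m]]
    expect_equal(delta, fit$params$shrinkage * st$rho * predict(st$tree, x),
                 tolerance = 1e-12)
  }
  # trainer bookkeeping: full-stage prediction reproduces internal scores
  expect_lt(max(abs(predict(fit, sim$data, n_stages = length(fit$stages)) -
                    fit$final_training_scores)), 1e-10)
})

test_that("halving the shrinkage halves every replayed stage increment", {
  sim <- simulate_ph(n = 100, p = 2, beta = c(1, 0), censor_rate = 0.2, seed = 37)
  fit <- fit_gbmci(sim$data, n_trees = 5, depth = 1, cv_folds = 0, seed = 4)
  x <- as.matrix(sim$data[fit$feature_names])
  half <- fit
  half$params$shrinkage <- fit$params$shrinkage / 2
  for (m in seq_along(fit$stages)) {
    d_full <- predict(fit, sim$data, m) - predict(fit, sim$data, m - 1)
    d_half <- predict(half, sim$data, m) - predict(half, sim$data, m - 1)
    expect_equal(d_half, d_full / 2, tolerance = 1e-12)
  }
})

test_that("partial-likelihood boosting gradient matches finite differences", {
  for (seed in 1:30) {
    n <- withr::with_seed(seed, sample(6:20, 1))
    d <- random_cohort(n, seed = seed + 900,
                       tie_prob = if (seed %% 4 == 0) 0.3 else 0)
    if (sum(d$status) == 0) next
    f <- withr::with_seed(seed, rnorm(n, sd = 0.5))
    sd <- ciboost:::as_survdata(d)
    r <- ciboost:::coxph_gradient(sd, f)$residual
    fd <- fd_gradient(function(v) oracle_nlpl(d$time, d$status, v), f)
    # residual is the NEGATIVE gradient of the cost
    expect_lt(max(abs(r + fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("partial-likelihood boosting refuses an all-censored cohort", {
  d <- tibble::tibble(time = withr::with_seed(1, rexp(30, 0.1)) + 0.1,
                      status = rep(0L, 30),
                      x1 = withr::with_seed(2, rnorm(30)))
  expect_error(fit_gbmcox(d, n_trees = 5, cv_folds = 0), "censored")
})

test_that("boosted partial likelihood decreases and learns a linear signal", {
  sim <- simulate_ph(n = 250, p = 2, beta = c(1, -1), censor_rate = 0.25, seed = 41)
  fit <- fit_gbmcox(sim$data, n_trees = 120, depth = 2, shrinkage = 0.05,
                    cv_folds = 0, seed = 5)
  expect_true(all(diff(fit$training_log) <= 1e-8))
  expect_gt(concordance_index(sim$data, predict(fit, sim$data)), 0.65)
})

test_that("stage weight and orientation conventions hold for the coxph objective", {
  sim <- simulate_ph(n = 150, p = 2, beta = c(1, 0.5), censor_rate = 0.2, seed = 43)
  fit <- fit_gbmcox(sim$data, n_trees = 6, depth = 2, shrinkage = 0.05,
                    cv_folds = 0, seed = 6)
  expect_true(all(vapply(fit$stages, `[[`, numeric(1), "rho") == 1))
  # internal log-hazard scale is negated on prediction
  x <- as.matrix(sim$data[fit$feature_names])
  acc <- numeric(150)
  for (st in fit$stages) acc <- acc + fit$params$shrinkage * predict(st$tree, x)
  expect_equal(predict(fit, sim$data, n_stages = length(fit$stages)), -acc,
               tolerance = 1e-12)
})

test_that("identical seeds give bit-identical models; different seeds differ", {
  sim <- simulate_ph(n = 150, p = 2, beta = c(1, -1), censor_rate = 0.25, seed = 47)
  f1 <- fit_gbmci(sim$data, n_trees = 12, depth = 2, bag_fraction = 0.5,
                  cv_folds = 0, seed = 11)
  f2 <- fit_gbmci(sim$data, n_trees = 12, depth = 2, bag_fraction = 0.5,
                  cv_folds = 0, seed = 11)
  expect_identical(vapply(f1$stages, `[[`, numeric(1), "rho"),
                   vapply(f2$stages, `[[`, numeric(1), "rho"))
  expect_identical(predict(f1, sim$data), predict(f2, sim$data))
  f3 <- fit_gbmci(sim$data, n_trees = 12, depth = 2, bag_fraction = 0.5,
                  cv_folds = 0, seed = 12)
  expect_false(identical(predict(f1, sim$data), predict(f3, sim$data)))
  # the caller's RNG stream is untouched
  before <- withr::with_seed(99, rnorm(1))
  set.seed(99)
  invisible(fit_gbmci(sim$data, n_trees = 2, depth = 1, cv_folds = 0, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("cross-validation selection is seeded, averaged, and self-consistent", {
  sim <- simulate_ph(n = 160, p = 2, beta = c(1, -1), censor_rate = 0.25, seed = 53)
  cv <- select_stages_cv(sim$data, objective = "sci", n_trees = 1, depth = 1,
                         cv_folds = 3, seed = 9)
  expect_equal(cv$best_m, 1L)

  cv2 <- select_stages_cv(sim$data, objective = "sci", n_trees = 10, depth = 2,
                          cv_folds = 3, seed = 9)
  expect_equal(length(cv2$cv_curve), 10L)
  # refitting one fold standalone reproduces its stored curve entries
  fold_of <- withr::with_seed(9L, sample(rep_len(1:3, 160)))
  tr <- sim$data[fold_of != 2, ]
  te <- sim$data[fold_of == 2, ]
  sd_tr <- ciboost:::as_survdata(tr)
  sd_te <- ciboost:::as_survdata(te)
  out <- ciboost:::gbm_engine(sd_tr, "sci", alpha = 1, n_trees = 10, depth = 2,
                              min_obs = 10, shrinkage = 1, bag_fraction = 1,
                              rho_max = 100, seed = 9 + 2, test_sd = sd_te)
  curves <- lapply(1:3, function(f) {
    sdf <- ciboost:::as_survdata(sim$data[fold_of != f, ])
    sdt <- ciboost:::as_survdata(sim$data[fold_of == f, ])
    ciboost:::gbm_engine(sdf, "sci", alpha = 1, n_trees = 10, depth = 2,
                         min_obs = 10, shrinkage = 1, bag_fraction = 1,
                         rho_max = 100, seed = 9 + f, test_sd = sdt)$test_curve
  })
  expect_identical(out$test_curve, curves[[2]])
  expect_equal(cv2$cv_curve, Reduce(`+`, curves) / 3, tolerance = 1e-15)

  # a fitted model with CV stores the same selection
  fit <- fit_gbmci(sim$data, n_trees = 10, depth = 2, cv_folds = 3, seed = 9)
  expect_equal(fit$selected_stages, cv2$best_m)
})
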