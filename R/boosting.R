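# Gradient-boosted survival models sharing one stage loop:
#  * objective "sci":   maximize the smoothed concordance index; stages are
#    trees fitted to the analytic SCI ascent gradient, each scaled by a
#    line-searched weight rho in [0, rho_max]; initialized from a linear Cox
#    fit's risk scores.
#  * objective "coxph": minimize the negative log partial likelihood; stages
#    are trees fitted to the martingale-type negative gradient with terminal
#    nodes refitted by a single Newton step, rho fixed at 1; initialized at 0
#    on the log-relative-hazard scale (predictions are negated back to the
#    common survival-time score orientation).

check_boost_args <- function(alpha, n_trees, depth, min_obs, shrinkage,
                             bag_fraction, rho_max, cv_folds, seed) {
  check_alpha(alpha)
  if (n_trees < 0) abort("`n_trees` must be >= 0.")
  if (depth < 0) abort("`depth` must be >= 0.")
  if (min_obs < 1) abort("`min_obs` must be >= 1.")
  if (shrinkage <= 0 || shrinkage > 1) abort("`shrinkage` must be in (0, 1].")
  if (bag_fraction <= 0 || bag_fraction > 1) abort("`bag_fraction` must be in (0, 1].")
  if (rho_max <= 0) abort("`rho_max` must be positive.")
  if (cv_folds < 0 || cv_folds == 1) abort("`cv_folds` must be 0 (off) or >= 2.")
  if (!is.finite(seed)) abort("`seed` must be a finite integer.")
}

#' Line search for a boosting stage weight
#'
#' Maximizes the smoothed concordance index of `scores + rho * tree_preds`
#' over `rho` in `[0, rho_max]`: a uniform grid scan (the objective is
#' neither convex nor concave, so a global grid keeps the search robust)
#' followed by local refinement inside the best grid cell. Because 0 is
#' always a candidate, the returned objective is never below the current one.
#'
#' @inheritParams smoothed_ci
#' @param tree_preds Numeric vector: the stage tree's prediction per subject.
#' @param rho_max Upper bound of the search interval (default 100; the lower
#'   bound is always 0 so "no move" stays searchable).
#' @param n_grid Number of grid points (default 201).
#' @return A list with `rho` (the maximizer) and `sci` (the objective there).
#' @export
line_search_rho <- function(data, scores, tree_preds, alpha = 1,
                            rho_max = 100, n_grid = 201L,
                            time_col = "time", status_col = "status") {
  check_alpha(alpha)
  sd <- as_survdata(data, time_col, status_col)
  scores <- check_scores(scores, sd$n)
  tree_preds <- check_scores(tree_preds, sd$n)
  p <- pair_indices(sd)
  if (p$size == 0) abort("no comparable pairs in `data`.")
  line_search_core(scores[p$i] - scores[p$j],
                   tree_preds[p$i] - tree_preds[p$j],
                   alpha, rho_max, n_grid)
}

# d0, dt: per-pair score and tree-prediction differences (i minus j).
# Maximizing SCI == minimizing its deficit 1 - SCI; the deficit is scanned
# because it keeps resolving candidates after SCI itself rounds to 1.
# Ties (e.g. a zero direction) resolve to the first, i.e. smallest, rho.
line_search_core <- function(d0, dt, alpha, rho_max, n_grid = 201L) {
  grid <- seq(0, rho_max, length.out = n_grid)
  defs <- sci_deficit_scan_cpp(d0, dt, grid, alpha)
  k <- which.min(defs)
  best_rho <- grid[k]
  best_def <- defs[k]
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(n_grid, k + 1L)]
  if (hi > lo) {
    ref <- optimize(function(r) sci_deficit_at_rho_cpp(d0, dt, r, alpha),
                    interval = c(lo, hi), tol = 1e-10)
    if (ref$objective < best_def) {
      best_rho <- ref$minimum
      best_def <- ref$objective
    }
  }
  list(rho = best_rho, sci = sci_at_rho_cpp(d0, dt, best_rho, alpha))
}

# Negative gradient (and diagonal curvature) of the negative log partial
# likelihood with respect to the score vector F on the log-hazard scale:
#   r_i = delta_i - exp(F_i) * sum_{events k: t_k <= t_i} 1 / S0_k,
#   h_i = exp(F_i) * cumhaz_i - exp(2 F_i) * sum 1 / S0_k^2,
# with S0_k = sum_{j: t_j >= t_k} exp(F_j) (Breslow cumulative hazard).
coxph_gradient <- function(sd, f) {
  o <- order(sd$time)
  t_s <- sd$time[o]
  d_s <- sd$status[o]
  f_s <- f[o]
  cmax <- max(f_s)
  w <- exp(f_s - cmax)
  first <- match(t_s, t_s)
  s0 <- rev(cumsum(rev(w)))[first] * exp(cmax)
  # events with t_k <= t_i: prefix sums taken at the LAST index of each tied
  # block so ties at t_i are included
  last <- n_last_of_block(t_s)
  ch1 <- cumsum(d_s / s0)[last]
  ch2 <- cumsum(d_s / s0^2)[last]
  ef <- exp(f_s)
  r <- d_s - ef * ch1
  h <- ef * ch1 - ef^2 * ch2
  out_r <- numeric(sd$n)
  out_h <- numeric(sd$n)
  out_r[o] <- r
  out_h[o] <- h
  list(residual = out_r, curvature = out_h)
}

# index of the last element of each tied block in a sorted vector
n_last_of_block <- function(t_sorted) {
  n <- length(t_sorted)
  (n + 1L) - match(t_sorted, rev(t_sorted))
}

# Shared stage loop. sd: canonical survival data; test_*: optional held-out
# tracking (per-stage held-out C-index). Runs under its own RNG scope.
gbm_engine <- function(sd, objective, alpha, n_trees, depth, min_obs,
                       shrinkage, bag_fraction, rho_max, seed,
                       test_sd = NULL, quiet = TRUE) {
  n <- sd$n
  x <- sd$x
  full_pairs <- if (objective == "sci") pair_indices(sd) else NULL
  if (objective == "sci" && full_pairs$size == 0) {
    abort("no comparable pairs in the training data.")
  }
  if (objective == "coxph" && sum(sd$status) == 0) {
    abort("cannot boost the partial likelihood: all subjects are censored.")
  }

  withr::with_seed(as.integer(seed), {
    # -- initialization ------------------------------------------------------
    cox_init <- NULL
    if (objective == "sci") {
      if (ncol(x) >= 1) {
        fit <- withCallingHandlers(
          tryCatch(fit_coxph_sd(sd), error = function(e) NULL),
          warning = function(w) invokeRestart("muffleWarning"))
        if (!is.null(fit) && fit$converged) {
          cox_init <- fit
        }
      }
      if (is.null(cox_init)) {
        warn("Cox initialization unavailable; starting from zero scores.")
        scores <- numeric(n)
      } else {
        scores <- -drop(x %*% cox_init$theta)
      }
    } else {
      scores <- numeric(n)   # log relative hazard scale
    }

    test_scores <- NULL
    test_curve <- numeric(0)
    if (!is.null(test_sd)) {
      test_pairs <- pair_indices(test_sd)
      test_scores <- if (objective == "sci" && !is.null(cox_init)) {
        -drop(test_sd$x %*% cox_init$theta)
      } else {
        numeric(test_sd$n)
      }
    }

    objective_value <- function() {
      if (objective == "sci") {
        sci_mean_cpp(scores[full_pairs$i] - scores[full_pairs$j], alpha)
      } else {
        nlpl_eta(sd, scores)
      }
    }

    stages <- list()
    training_log <- numeric(0)
    n_skipped <- 0L
    bag_size <- min(n, as.integer(ceiling(bag_fraction * n)))

    for (m in seq_len(n_trees)) {
      # -- bag ---------------------------------------------------------------
      stage_data <- NULL
      for (attempt in 1:2) {
        bag <- if (bag_size >= n) seq_len(n) else sort(sample.int(n, bag_size))
        sub <- list(time = sd$time[bag], status = sd$status[bag],
                    x = x[bag, , drop = FALSE], n = bag_size)
        if (objective == "sci") {
          bp <- pair_indices(sub)
          if (bp$size > 0) {
            stage_data <- list(bag = bag, sub = sub, pairs = bp)
            break
          }
        } else {
          if (sum(sub$status) > 0) {
            stage_data <- list(bag = bag, sub = sub)
            break
          }
        }
      }
      if (is.null(stage_data)) {
        warn(sprintf("stage %d skipped: subsample carries no objective signal.", m))
        n_skipped <- n_skipped + 1L
        next
      }
      bag <- stage_data$bag
      sub <- stage_data$sub

      # -- pseudo-response, tree, weight --------------------------------------
      if (objective == "sci") {
        g <- sci_grad_cpp(scores[bag], stage_data$pairs$i, stage_data$pairs$j,
                          alpha, bag_size)
        tree <- fit_tree(sub$x, g, depth = depth, min_obs = min_obs)
        preds <- predict(tree, x)
        ls <- line_search_core(scores[full_pairs$i] - scores[full_pairs$j],
                               preds[full_pairs$i] - preds[full_pairs$j],
                               alpha, rho_max)
        rho <- ls$rho
      } else {
        gr <- coxph_gradient(sub, scores[bag])
        tree <- fit_tree(sub$x, gr$residual, depth = depth, min_obs = min_obs)
        leaf <- tree_leaf_ids(tree, sub$x)
        for (id in unique(leaf)) {
          members <- leaf == id
          denom <- sum(gr$curvature[members])
          val <- if (denom < 1e-12) 0 else sum(gr$residual[members]) / denom
          tree <- set_leaf_values(tree, id, val)
        }
        preds <- predict(tree, x)
        rho <- 1
      }

      scores <- scores + shrinkage * rho * preds
      stages[[length(stages) + 1L]] <- list(rho = rho, tree = tree)
      training_log <- c(training_log, objective_value())

      if (!is.null(test_scores)) {
        test_scores <- test_scores + shrinkage * rho * predict(tree, test_sd$x)
        ts <- if (objective == "coxph") -test_scores else test_scores
        test_curve <- c(test_curve,
                        if (test_pairs$size > 0) {
                          mean(ts[test_pairs$i] < ts[test_pairs$j])
                        } else NA_real_)
      }
      if (!quiet && m %% 100 == 0) {
        message(sprintf("stage %4d: training %s = %.6f", m,
                        if (objective == "sci") "SCI" else "neg log PL",
                        training_log[length(training_log)]))
      }
    }
    if (n_trees > 0 && length(stages) == 0) {
      abort("every boosting stage was skipped; no model could be fitted.")
    }
    list(stages = stages, cox_init = cox_init, final_scores = scores,
         training_log = training_log, test_curve = test_curve,
         n_skipped = n_skipped)
  })
}

# fit_coxph on canonical form (avoids rebuilding the data frame; column
# names chosen to never collide with user covariate names)
fit_coxph_sd <- function(sd, max_iter = 50L, tol = 1e-8) {
  df <- as.data.frame(sd$x)
  names(df) <- sd$feature_names
  df[[".ciboost_time"]] <- sd$time
  df[[".ciboost_status"]] <- sd$status
  fit_coxph(df, time_col = ".ciboost_time", status_col = ".ciboost_status",
            max_iter = max_iter, tol = tol)
}

build_gbm <- function(sd, objective, engine_out, selected, cv, params) {
  structure(list(
    objective = objective,
    stages = engine_out$stages,
    cox_init = engine_out$cox_init,
    selected_stages = selected,
    training_log = engine_out$training_log,
    final_training_scores = engine_out$final_scores,
    cv = cv,
    params = params,
    feature_names = sd$feature_names,
    n = sd$n, n_events = sum(sd$status),
    n_skipped = engine_out$n_skipped
  ), class = "ciboost_gbm")
}

#' Boost the smoothed concordance index with regression trees
#'
#' Fits an ensemble of shallow regression trees by gradient boosting on the
#' smoothed concordance index. Scores are initialized from an internal linear
#' Cox fit (falling back to zero, with a warning, if that fit is not
#' identifiable). Each stage draws a subsample of `bag_fraction * n` subjects
#' without replacement, computes the analytic ascent gradient over the
#' comparable pairs internal to the subsample, fits a least-squares tree to
#' it, picks the stage weight `rho` by a line search of the full-data
#' objective over `[0, rho_max]`, and updates all subjects' scores by
#' `shrinkage * rho * tree(x)`. Because `rho = 0` is always searchable and
#' the line search uses the full data, the training objective is
#' non-decreasing whenever `bag_fraction = 1`. When `cv_folds >= 2` the
#' number of stages actually used for prediction is chosen by seeded
#' cross-validation on held-out concordance (see [select_stages_cv()]);
#' otherwise all stages are used.
#'
#' @inheritParams validate_survival_data
#' @param alpha Sigmoid steepness of the smoothed concordance index
#'   (default 1).
#' @param n_trees Maximum number of boosting stages (default 1500).
#' @param depth Tree depth limit (default 6).
#' @param min_obs Minimum subjects per leaf (default 10).
#' @param shrinkage Stage step multiplier in (0, 1]. Default 1: the bounded
#'   line-search range already acts as implicit shrinkage for this objective.
#' @param bag_fraction Fraction of subjects subsampled (without replacement)
#'   per stage, in (0, 1]. Default 1 (no subsampling).
#' @param rho_max Upper bound of the stage-weight line search (default 100).
#' @param cv_folds Cross-validation folds for choosing the ensemble size:
#'   0 disables, otherwise >= 2 (default 5).
#' @param seed Integer seed controlling subsampling and fold assignment; the
#'   caller's RNG state is untouched. Identical inputs and seed reproduce the
#'   model bit-for-bit.
#' @param quiet Suppress per-100-stage progress messages (default TRUE).
#' @return An object of class `ciboost_gbm`; see [predict.ciboost_gbm()],
#'   [tidy.ciboost_gbm()], [glance.ciboost_gbm()], [autoplot.ciboost_gbm()],
#'   [write_gbm_model()].
#' @examples
#' sim <- simulate_ph(n = 120, beta = c(1, -1), censor_rate = 0.2, seed = 3)
#' fit <- fit_gbmci(sim$data, n_trees = 10, depth = 2, cv_folds = 0, seed = 3)
#' concordance_index(sim$data, predict(fit, sim$data))
#' @export
fit_gbmci <- function(data, time_col = "time", status_col = "status",
                      alpha = 1, n_trees = 1500L, depth = 6L, min_obs = 10L,
                      shrinkage = 1, bag_fraction = 1, rho_max = 100,
                      cv_folds = 5L, seed = 1L, quiet = TRUE) {
  fit_gbm_impl(data, "sci", time_col, status_col, alpha, n_trees, depth,
               min_obs, shrinkage, bag_fraction, rho_max, cv_folds, seed, quiet)
}

#' Boost the Cox partial likelihood with regression trees
#'
#' The boosted proportional-hazards comparator: same stage loop as
#' [fit_gbmci()] but the objective is the Breslow negative log partial
#' likelihood on the log-relative-hazard scale. Each stage fits a tree to the
#' martingale-type negative gradient on the subsample, then replaces every
#' terminal-node value with a single Newton step of the node-restricted
#' objective (guarded to 0 when the curvature sum is below 1e-12); the stage
#' weight is fixed at 1 and `shrinkage` does the damping (default 0.002).
#' Scores are initialized at zero. Predictions are negated back to the
#' package-wide survival-time orientation.
#'
#' @inheritParams fit_gbmci
#' @param shrinkage Stage step multiplier (default 0.002 for this objective).
#' @return An object of class `ciboost_gbm`.
#' @export
fit_gbmcox <- function(data, time_col = "time", status_col = "status",
                       n_trees = 1500L, depth = 6L, min_obs = 10L,
                       shrinkage = 0.002, bag_fraction = 1, cv_folds = 5L,
                       seed = 1L, quiet = TRUE) {
  fit_gbm_impl(data, "coxph", time_col, status_col, 1, n_trees, depth,
               min_obs, shrinkage, bag_fraction, 100, cv_folds, seed, quiet)
}

fit_gbm_impl <- function(data, objective, time_col, status_col, alpha,
                         n_trees, depth, min_obs, shrinkage, bag_fraction,
                         rho_max, cv_folds, seed, quiet) {
  check_boost_args(alpha, n_trees, depth, min_obs, shrinkage, bag_fraction,
                   rho_max, cv_folds, seed)
  sd <- as_survdata(data, time_col, status_col)
  params <- list(objective = objective, alpha = alpha, n_trees = n_trees,
                 depth = depth, min_obs = min_obs, shrinkage = shrinkage,
                 bag_fraction = bag_fraction, rho_max = rho_max,
                 cv_folds = cv_folds, seed = as.integer(seed))
  cv <- NULL
  if (cv_folds >= 2 && n_trees > 0) {
    cv <- cv_core(sd, params)
  }
  out <- gbm_engine(sd, objective, alpha, n_trees, depth, min_obs, shrinkage,
                    bag_fraction, rho_max, seed, quiet = quiet)
  selected <- if (!is.null(cv)) min(cv$best_m, length(out$stages)) else length(out$stages)
  build_gbm(sd, objective, out, selected, cv, params)
}

# Seeded k-fold CV over the number of stages; fold f's engine runs with seed
# seed + f so any fold is reproducible standalone.
cv_core <- function(sd, params) {
  n <- sd$n
  k <- params$cv_folds
  fold_of <- withr::with_seed(params$seed, sample(rep_len(seq_len(k), n)))
  curves <- list()
  for (f in seq_len(k)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    sd_tr <- list(time = sd$time[tr], status = sd$status[tr],
                  x = sd$x[tr, , drop = FALSE],
                  feature_names = sd$feature_names, n = length(tr))
    sd_te <- list(time = sd$time[te], status = sd$status[te],
                  x = sd$x[te, , drop = FALSE],
                  feature_names = sd$feature_names, n = length(te))
    if (pair_indices(sd_te)$size == 0) {
      warn(sprintf("CV fold %d dropped: no comparable validation pairs.", f))
      next
    }
    out <- gbm_engine(sd_tr, params$objective, params$alpha, params$n_trees,
                      params$depth, params$min_obs, params$shrinkage,
                      params$bag_fraction, params$rho_max,
                      seed = params$seed + f, test_sd = sd_te)
    curve <- out$test_curve
    if (length(curve) < params$n_trees) {  # skipped stages: carry forward
      curve <- c(curve, rep(curve[length(curve)],
                            params$n_trees - length(curve)))
    }
    curves[[length(curves) + 1L]] <- curve
  }
  if (!length(curves)) abort("all CV folds were dropped; cannot select stages.")
  avg <- Reduce(`+`, curves) / length(curves)
  list(best_m = which.max(avg), cv_curve = avg, n_folds_used = length(curves))
}

#' Select the boosting ensemble size by cross-validation
#'
#' Partitions the cohort into `cv_folds` seeded folds; for each fold, trains
#' the requested boosted model on the remaining data (fold f runs with seed
#' `seed + f`, so any fold's curve can be reproduced by a standalone refit)
#' and records the held-out concordance index after every stage. The selected
#' size is the argmax of the fold-averaged curve, ties going to the smallest
#' size. Folds without comparable validation pairs are dropped with a
#' warning.
#'
#' @inheritParams fit_gbmci
#' @param objective `"sci"` or `"coxph"`.
#' @return A list: `best_m` (selected number of stages), `cv_curve`
#'   (fold-averaged held-out concordance per stage), `n_folds_used`.
#' @export
select_stages_cv <- function(data, objective = c("sci", "coxph"),
                             time_col = "time", status_col = "status",
                             alpha = 1, n_trees = 1500L, depth = 6L,
                             min_obs = 10L, shrinkage = NULL,
                             bag_fraction = 1, rho_max = 100,
                             cv_folds = 5L, seed = 1L) {
  objective <- match.arg(objective)
  if (is.null(shrinkage)) shrinkage <- if (objective == "sci") 1 else 0.002
  check_boost_args(alpha, n_trees, depth, min_obs, shrinkage, bag_fraction,
                   rho_max, cv_folds, seed)
  if (cv_folds < 2) abort("`cv_folds` must be >= 2.")
  sd <- as_survdata(data, time_col, status_col)
  cv_core(sd, list(objective = objective, alpha = alpha, n_trees = n_trees,
                   depth = depth, min_obs = min_obs, shrinkage = shrinkage,
                   bag_fraction = bag_fraction, rho_max = rho_max,
                   cv_folds = cv_folds, seed = as.integer(seed)))
}

#' Predict survival-orientation scores from a boosted model
#'
#' Evaluates the additive expansion `init + shrinkage * sum_m rho_m tree_m(x)`
#' truncated at `n_stages` stages (default: the cross-validated selection).
#' For the `"coxph"` objective the internal scale is log relative hazard, so
#' the sum is negated; either way larger returned scores mean longer
#' predicted survival.
#'
#' @param object A `ciboost_gbm` model.
#' @param newdata Data frame containing the training covariate columns (or a
#'   numeric matrix with matching column count).
#' @param n_stages Number of stages to use, `0..length(object$stages)`.
#' @param ... Unused.
#' @return Numeric score vector, one per row of `newdata`.
#' @export
predict.ciboost_gbm <- function(object, newdata, n_stages = NULL, ...) {
  x <- covariate_matrix(newdata, object$feature_names)
  if (is.null(n_stages)) n_stages <- object$selected_stages
  if (n_stages < 0 || n_stages > length(object$stages)) {
    abort(sprintf("`n_stages` must be between 0 and %d.", length(object$stages)))
  }
  acc <- if (object$objective == "sci" && !is.null(object$cox_init)) {
    -drop(x %*% object$cox_init$theta)
  } else {
    numeric(nrow(x))
  }
  for (m in seq_len(n_stages)) {
    st <- object$stages[[m]]
    acc <- acc + object$params$shrinkage * st$rho * predict(st$tree, x)
  }
  if (object$objective == "coxph") -acc else acc
}

#' @export
print.ciboost_gbm <- function(x, ...) {
  cat(sprintf("<ciboost_gbm '%s': %d stages (%d selected), depth %d, shrinkage %g>\n",
              x$objective, length(x$stages), x$selected_stages,
              x$params$depth, x$params$shrinkage))
  cat(sprintf("  trained on %d subjects (%d events)", x$n, x$n_events))
  if (!is.null(x$cox_init)) cat("; Cox-initialized") else cat("; zero-initialized")
  cat("\n")
  if (length(x$training_log)) {
    cat(sprintf("  final training %s: %.6f\n",
                if (x$objective == "sci") "SCI" else "neg log PL",
                x$training_log[length(x$training_log)]))
  }
  invisible(x)
}

#' Per-stage summary of a boosted model
#' @param x A `ciboost_gbm` model.
#' @param ... Unused.
#' @return A tibble with one row per stage: `stage`, `rho`, `objective`
#'   (full-data training objective after the stage), and `cv_concordance`
#'   when cross-validation was run.
#' @export
tidy.ciboost_gbm <- function(x, ...) {
  out <- tibble(stage = seq_along(x$stages),
                rho = vapply(x$stages, `[[`, numeric(1), "rho"),
                objective = x$training_log)
  if (!is.null(x$cv)) {
    out$cv_concordance <- x$cv$cv_curve[seq_len(nrow(out))]
  }
  out
}

#' One-row summary of a boosted model
#' @param x A `ciboost_gbm` model.
#' @param ... Unused.
#' @return A one-row tibble: objective, stage counts, key hyperparameters,
#'   and the final training objective.
#' @export
glance.ciboost_gbm <- function(x, ...) {
  tibble(objective = x$objective, n = x$n, n_events = x$n_events,
         n_stages = length(x$stages), selected_stages = x$selected_stages,
         depth = x$params$depth, shrinkage = x$params$shrinkage,
         alpha = x$params$alpha, bag_fraction = x$params$bag_fraction,
         train_objective = if (length(x$training_log)) {
           x$training_log[length(x$training_log)]
         } else NA_real_)
}

#' Plot the training (and cross-validation) trajectory of a boosted model
#'
#' One line per available curve: the full-data training objective per stage
#' and, when cross-validation was run, the fold-averaged held-out concordance
#' with the selected stage marked.
#'
#' @param object A `ciboost_gbm` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ciboost_gbm <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    df[c("stage", "objective", intersect("cv_concordance", names(df)))],
    -"stage", names_to = "curve", values_to = "value")
  labels <- c(objective = if (object$objective == "sci") {
    "training SCI"
  } else {
    "training neg log PL"
  }, cv_concordance = "CV held-out C-index")
  long$curve <- labels[long$curve]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "boosting stage", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(object$cv)) {
    p <- p + ggplot2::geom_vline(xintercept = object$selected_stages,
                                 linetype = "dashed")
  }
  p
}
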