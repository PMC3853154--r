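# Linear Cox proportional-hazards baseline, fitted by Newton-Raphson with
# step-halving on the Breslow negative log partial likelihood. Serves both as
# the "cox" comparator and as the initialization of the boosted
# concordance-index model. The baseline hazard is never estimated: ranking
# predictions only need the linear predictor.

# Negative log partial likelihood for an arbitrary linear predictor eta
# (Breslow handling of tied event times: tied events share the inclusive
# risk-set denominator sum_{t_j >= t_i} exp(eta_j)).
nlpl_eta <- function(sd, eta) {
  if (sum(sd$status) == 0) abort("partial likelihood undefined: no events observed.")
  o <- order(sd$time)
  t_s <- sd$time[o]
  d_s <- sd$status[o]
  e_s <- eta[o]
  cmax <- max(e_s)
  suffix <- rev(cumsum(rev(exp(e_s - cmax))))
  first <- match(t_s, t_s)             # first index of each tied block
  log_s0 <- cmax + log(suffix[first])  # log sum over risk set {t_j >= t_i}
  -sum((e_s - log_s0)[d_s == 1])
}

# Gradient and Hessian of nlpl_eta with respect to theta at eta = x theta.
cox_derivs <- function(sd, theta) {
  x <- sd$x
  p <- ncol(x)
  eta <- drop(x %*% theta)
  o <- order(sd$time)
  t_s <- sd$time[o]
  d_s <- sd$status[o]
  x_s <- x[o, , drop = FALSE]
  w <- exp(eta[o] - max(eta))          # common shift cancels in all ratios
  first <- match(t_s, t_s)
  s0 <- rev(cumsum(rev(w)))[first]
  s1 <- apply(w * x_s, 2, function(v) rev(cumsum(rev(v))))[first, , drop = FALSE]
  ev <- which(d_s == 1)
  m <- s1[ev, , drop = FALSE] / s0[ev]
  grad <- -colSums(x_s[ev, , drop = FALSE] - m)
  hess <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in a:p) {
      s2ab <- rev(cumsum(rev(w * x_s[, a] * x_s[, b])))[first]
      h <- sum(s2ab[ev] / s0[ev] - m[, a] * m[, b])
      hess[a, b] <- h
      hess[b, a] <- h
    }
  }
  list(grad = grad, hess = hess)
}

#' Negative log Cox partial likelihood
#'
#' Evaluates the Breslow negative log partial likelihood
#' `-sum_{i in events} [theta' x_i - log sum_{j: t_j >= t_i} exp(theta' x_j)]`
#' at a given coefficient vector. The risk set is inclusive (`>=`), so tied
#' event times share a common denominator.
#'
#' @inheritParams validate_survival_data
#' @param theta Numeric coefficient vector, one entry per covariate column.
#' @return A single number.
#' @examples
#' d <- tibble::tibble(time = 1:3, status = c(1, 1, 1), x = c(0, 1, 2))
#' neg_log_partial_likelihood(d, theta = 0) # log 3 + log 2
#' @export
neg_log_partial_likelihood <- function(data, theta, time_col = "time",
                                       status_col = "status") {
  sd <- as_survdata(data, time_col, status_col)
  theta <- as.numeric(theta)
  if (length(theta) != ncol(sd$x)) {
    abort(sprintf("`theta` must have length %d (one per covariate).", ncol(sd$x)))
  }
  nlpl_eta(sd, drop(sd$x %*% theta))
}

#' Fit a linear Cox proportional-hazards model
#'
#' Newton-Raphson on the Breslow negative log partial likelihood, with
#' step-halving so the objective never increases across accepted iterations.
#' Iteration stops when the objective decrease falls below `tol`. The model
#' has no intercept (the partial likelihood is invariant to shifting all
#' linear predictors). Non-identifiable problems — all-constant covariates, a
#' singular information matrix, or coefficients diverging under separation —
#' yield a result flagged `converged = FALSE` rather than an error.
#'
#' @inheritParams validate_survival_data
#' @param max_iter Maximum Newton iterations (default 50).
#' @param tol Convergence tolerance on the objective decrease (default 1e-8).
#' @return An object of class `ciboost_cox` with elements `theta` (named
#'   coefficients), `converged`, `iterations`, `objective_path` (the accepted
#'   Newton objective values, non-increasing), `feature_names`, `n`,
#'   `n_events`.
#' @seealso [predict.ciboost_cox()] for risk scores, [tidy.ciboost_cox()].
#' @export
fit_coxph <- function(data, time_col = "time", status_col = "status",
                      max_iter = 50L, tol = 1e-8) {
  sd <- as_survdata(data, time_col, status_col)
  p <- ncol(sd$x)
  if (p < 1) abort("`data` must contain at least one covariate column.")
  if (sum(sd$status) == 0) abort("cannot fit: no events observed.")

  theta <- numeric(p)
  informative <- apply(sd$x, 2, function(v) diff(range(v)) > 0)
  converged <- FALSE
  iterations <- 0L
  path <- nlpl_eta(sd, drop(sd$x %*% theta))

  if (any(informative)) {
    for (it in seq_len(max_iter)) {
      iterations <- it
      obj <- path[length(path)]
      dv <- cox_derivs(sd, theta)
      step <- tryCatch(solve(dv$hess[informative, informative, drop = FALSE],
                             dv$grad[informative]),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break  # singular information
      new_obj <- Inf
      lambda <- 1
      for (h in 1:30) {
        cand <- theta
        cand[informative] <- theta[informative] - lambda * step
        new_obj <- nlpl_eta(sd, drop(sd$x %*% cand))
        if (is.finite(new_obj) && new_obj <= obj) break
        lambda <- lambda / 2
      }
      if (!is.finite(new_obj) || new_obj > obj) break  # no descent possible
      theta_new <- theta
      theta_new[informative] <- theta[informative] - lambda * step
      theta <- theta_new
      path <- c(path, new_obj)
      if (max(abs(theta)) > 1e3) break                 # separation/divergence
      if (obj - new_obj < tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warn("Cox fit did not converge (non-identifiable or iteration limit).")
  }
  structure(list(theta = setNames(theta, sd$feature_names),
                 converged = converged, iterations = iterations,
                 objective_path = path, feature_names = sd$feature_names,
                 n = sd$n, n_events = sum(sd$status)),
            class = "ciboost_cox")
}

#' Risk scores from a fitted Cox model
#'
#' Returns the negative linear predictor `-theta' x` per subject, i.e. the
#' negative log relative hazard, oriented so that a larger score means longer
#' predicted survival (the package-wide score convention).
#'
#' @param object A `ciboost_cox` fit.
#' @param newdata Data frame containing the training covariate columns, or a
#'   numeric matrix with matching column count.
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict.ciboost_cox <- function(object, newdata, ...) {
  x <- covariate_matrix(newdata, object$feature_names)
  -drop(x %*% object$theta)
}

# Resolve a covariate matrix from a data frame (by name) or matrix (by count).
covariate_matrix <- function(newdata, feature_names) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(feature_names, names(newdata))
    if (length(missing)) {
      abort(sprintf("`newdata` lacks covariate column(s): %s.",
                    paste(missing, collapse = ", ")))
    }
    x <- as.matrix(newdata[feature_names])
  } else {
    x <- as.matrix(newdata)
    if (ncol(x) != length(feature_names)) {
      abort(sprintf("`newdata` must have %d covariate columns, got %d.",
                    length(feature_names), ncol(x)))
    }
  }
  storage.mode(x) <- "double"
  x
}

#' @export
print.ciboost_cox <- function(x, ...) {
  cat(sprintf("<ciboost_cox: %d subjects, %d events, %s in %d iteration(s)>\n",
              x$n, x$n_events,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(x$theta)
  invisible(x)
}

#' Tidy a Cox fit into a coefficient tibble
#' @param x A `ciboost_cox` fit.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.ciboost_cox <- function(x, ...) {
  tibble(term = x$feature_names, estimate = unname(x$theta))
}

#' One-row summary of a Cox fit
#' @param x A `ciboost_cox` fit.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_events`, `neg_log_partial_lik`,
#'   `iterations`, `converged`.
#' @export
glance.ciboost_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         neg_log_partial_lik = x$objective_path[length(x$objective_path)],
         iterations = x$iterations, converged = x$converged)
}

#' Plot the Newton objective path of a Cox fit
#' @param object A `ciboost_cox` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ciboost_cox <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective_path) - 1L,
               objective = object$objective_path)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Newton iteration",
                  y = "negative log partial likelihood") +
    ggplot2::theme_minimal()
}
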