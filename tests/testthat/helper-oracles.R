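# Brute-force oracles and fixture generators shared across the suite.
# Oracles are deliberately naive (nested loops, finite differences) and
# independent of the package's vectorized/compiled paths.

# Random censored cohort as a plain tibble, with optional tied times.
random_cohort <- function(n, seed, censor_prob = 0.3, p = 2, tie_prob = 0) {
  withr::with_seed(seed, {
    time <- rexp(n, rate = 0.2)
    if (tie_prob > 0) {
      dup <- runif(n) < tie_prob
      time[dup] <- sample(round(time, 1), sum(dup), replace = TRUE) + 0.05
    }
    tibble::tibble(
      time = time,
      status = as.integer(runif(n) >= censor_prob),
      !!!stats::setNames(as.list(as.data.frame(matrix(rnorm(n * p), n, p))),
                         paste0("x", seq_len(p)))
    )
  })
}

# Nested double-loop enumeration of validly orderable pairs: i must be an
# observed event with strictly smaller time.
oracle_pairs <- function(time, status) {
  i_out <- integer(0)
  j_out <- integer(0)
  n <- length(time)
  for (i in seq_len(n)) {
    if (status[i] != 1) next
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        i_out <- c(i_out, i)
        j_out <- c(j_out, j)
      }
    }
  }
  o <- order(i_out, j_out)
  list(i = i_out[o], j = j_out[o])
}

# Indicator-sum concordance index over the oracle pair set.
oracle_ci <- function(time, status, scores, tie_policy = "strict") {
  p <- oracle_pairs(time, status)
  if (!length(p$i)) stop("oracle: no comparable pairs")
  num <- 0
  for (k in seq_along(p$i)) {
    d <- scores[p$i[k]] - scores[p$j[k]]
    num <- num + if (d < 0) 1 else if (d == 0 && tie_policy == "half") 0.5 else 0
  }
  num / length(p$i)
}

# Term-by-term smoothed concordance (plain R, plogis-based).
oracle_sci <- function(time, status, scores, alpha) {
  p <- oracle_pairs(time, status)
  mean(stats::plogis(-alpha * (scores[p$i] - scores[p$j])))
}

# Central finite differences of a scalar function of a score vector.
fd_gradient <- function(f, scores, h = 1e-5) {
  vapply(seq_along(scores), function(i) {
    up <- scores; up[i] <- up[i] + h
    dn <- scores; dn[i] <- dn[i] - h
    (f(up) - f(dn)) / (2 * h)
  }, numeric(1))
}

# Naive negative log partial likelihood (Breslow), term by term.
oracle_nlpl <- function(time, status, eta) {
  val <- 0
  for (i in seq_along(time)) {
    if (status[i] != 1) next
    val <- val - (eta[i] - log(sum(exp(eta[time >= time[i]]))))
  }
  val
}
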