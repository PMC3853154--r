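#' Fit a least-squares regression tree
#'
#' CART-style greedy recursive partitioning used as the base learner in the
#' boosting loop. Every candidate split is a (feature, threshold) pair with
#' thresholds at midpoints between consecutive sorted unique feature values;
#' the split minimizing the summed squared error of the two children is taken.
#' Splitting stops at the depth limit, when a child would fall below
#' `min_obs` subjects, or when no split reduces the squared error. Ties among
#' equal-error splits go to the lowest feature index, then the lowest
#' threshold, so the fit is invariant to row order. Leaf values are the means
#' of their training targets.
#'
#' @param x Numeric matrix (or data frame) of covariates, subjects in rows.
#' @param y Numeric response vector (finite), one value per row of `x`.
#' @param depth Maximum number of split levels below the root (0 = single
#'   leaf). Default 6.
#' @param min_obs Minimum number of training subjects in any leaf. Default 10.
#' @return An object of class `ciboost_tree`: a flat node table (`$nodes`)
#'   with one row per node; leaves have `NA` feature/children.
#' @examples
#' tr <- fit_tree(matrix(1:4), c(0, 0, 1, 1), depth = 1, min_obs = 1)
#' predict(tr, matrix(c(1.5, 3.7)))
#' @export
fit_tree <- function(x, y, depth = 6L, min_obs = 10L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) == 0) abort("cannot fit a tree to empty data.")
  if (length(y) != nrow(x)) abort("`y` must have one value per row of `x`.")
  if (any(!is.finite(y))) abort("tree targets must be finite.")
  depth <- as.integer(depth)
  min_obs <- as.integer(min_obs)
  if (depth < 0) abort("`depth` must be >= 0.")
  if (min_obs < 1) abort("`min_obs` must be >= 1.")

  acc <- new.env(parent = emptyenv())
  acc$rows <- list()

  build <- function(idx, lvl) {
    id <- length(acc$rows) + 1L
    node <- list(id = id, feature = NA_integer_, threshold = NA_real_,
                 value = mean(y[idx]), n_obs = length(idx),
                 left = NA_integer_, right = NA_integer_)
    acc$rows[[id]] <- node
    if (lvl < depth && length(idx) >= 2L * min_obs) {
      sp <- best_split(x, y, idx, min_obs)
      if (!is.null(sp)) {
        go_left <- x[idx, sp$feature] <= sp$threshold
        node$feature <- sp$feature
        node$threshold <- sp$threshold
        node$left <- build(idx[go_left], lvl + 1L)
        node$right <- build(idx[!go_left], lvl + 1L)
        acc$rows[[id]] <- node
      }
    }
    id
  }
  build(seq_len(nrow(x)), 0L)

  nodes <- do.call(rbind, lapply(acc$rows, function(r) {
    data.frame(id = r$id, feature = r$feature, threshold = r$threshold,
               value = r$value, n_obs = r$n_obs, left = r$left, right = r$right)
  }))
  structure(list(nodes = nodes, depth = depth, min_obs = min_obs,
                 p = ncol(x)),
            class = "ciboost_tree")
}

# Exhaustive best split over all features and midpoint thresholds.
# Returns NULL when no split strictly reduces the SSE (within floating
# tolerance) or satisfies min_obs on both sides.
best_split <- function(x, y, idx, min_obs) {
  n <- length(idx)
  yy <- y[idx]
  total <- sum(yy)
  sse_parent <- sum(yy * yy) - total * total / n
  best <- NULL
  # require a real reduction: floor scales with the response magnitude so
  # floating noise on constant/symmetric targets never triggers a split
  best_gain <- 1e-12 * (sse_parent + total * total / n) + 1e-300
  for (f in seq_len(ncol(x))) {
    xv <- x[idx, f]
    o <- order(xv, method = "radix")
    xs <- xv[o]
    ys <- yy[o]
    cs <- cumsum(ys)
    k <- seq_len(n - 1L)
    ok <- (xs[k] < xs[k + 1L]) & (k >= min_obs) & (n - k >= min_obs)
    if (!any(ok)) next
    k <- k[ok]
    sl <- cs[k]
    gain <- sl * sl / k + (total - sl)^2 / (n - k) - total * total / n
    b <- which.max(gain)  # first max = lowest threshold on ties
    if (gain[b] > best_gain) {
      best_gain <- gain[b]
      best <- list(feature = f, threshold = (xs[k[b]] + xs[k[b] + 1L]) / 2)
    }
  }
  best
}

#' Predict from a fitted regression tree
#'
#' Routes each row through the node table: go left iff the split feature's
#' value is `<=` the threshold; returns the reached leaf's value.
#'
#' @param object A `ciboost_tree`.
#' @param newdata Numeric matrix or data frame with the training feature count.
#' @param ... Unused.
#' @return Numeric vector of leaf values, one per row.
#' @export
predict.ciboost_tree <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != object$p) {
    abort(sprintf("tree was trained on %d features; `newdata` has %d.",
                  object$p, ncol(x)))
  }
  nodes <- object$nodes
  out <- numeric(nrow(x))
  route <- function(rows, id) {
    if (!length(rows)) return(invisible())
    f <- nodes$feature[id]
    if (is.na(f)) {
      out[rows] <<- nodes$value[id]
    } else {
      left <- x[rows, f] <= nodes$threshold[id]
      route(rows[left], nodes$left[id])
      route(rows[!left], nodes$right[id])
    }
  }
  route(seq_len(nrow(x)), 1L)
  out
}

# Leaf id reached by each row; used for the terminal-node Newton refit.
tree_leaf_ids <- function(tree, x) {
  x <- as.matrix(x)
  nodes <- tree$nodes
  out <- integer(nrow(x))
  route <- function(rows, id) {
    if (!length(rows)) return(invisible())
    f <- nodes$feature[id]
    if (is.na(f)) {
      out[rows] <<- id
    } else {
      left <- x[rows, f] <= nodes$threshold[id]
      route(rows[left], nodes$left[id])
      route(rows[!left], nodes$right[id])
    }
  }
  route(seq_len(nrow(x)), 1L)
  out
}

# Overwrite leaf values (named by node id or full vector over nodes).
set_leaf_values <- function(tree, ids, values) {
  tree$nodes$value[match(ids, tree$nodes$id)] <- values
  tree
}

#' @export
print.ciboost_tree <- function(x, ...) {
  n_leaves <- sum(is.na(x$nodes$feature))
  cat(sprintf("<ciboost_tree: %d nodes, %d leaves, depth limit %d, min_obs %d>\n",
              nrow(x$nodes), n_leaves, x$depth, x$min_obs))
  invisible(x)
}
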