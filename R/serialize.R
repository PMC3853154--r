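# JSON model persistence. Doubles are written with 17 significant digits,
# which round-trips IEEE doubles losslessly, so save -> load -> predict is
# bit-identical to in-memory predict. Files are written atomically (temp file
# in the target directory, then rename).

MODEL_SCHEMA_VERSION <- "1.0"

#' Write a boosted model to a JSON file
#'
#' Serializes a [fit_gbmci()] / [fit_gbmcox()] model — configuration echo,
#' Cox initialization coefficients, every stage's weight and node table,
#' training log, and cross-validation curve — to a versioned JSON document.
#' Numeric values keep full double precision, so a reloaded model predicts
#' bit-identically.
#'
#' @param model A `ciboost_gbm` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_gbm_model()]
#' @export
write_gbm_model <- function(model, path) {
  if (!inherits(model, "ciboost_gbm")) abort("`model` must be a ciboost_gbm object.")
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    objective = model$objective,
    params = model$params,
    feature_names = as.list(model$feature_names),
    n = model$n, n_events = model$n_events,
    init = if (!is.null(model$cox_init)) {
      list(type = "cox", coefficients = as.list(model$cox_init$theta))
    } else {
      list(type = "zero")
    },
    selected_stages = model$selected_stages,
    n_skipped = model$n_skipped,
    training_log = model$training_log,
    final_training_scores = model$final_training_scores,
    cv = if (!is.null(model$cv)) {
      list(best_m = model$cv$best_m, cv_curve = model$cv$cv_curve,
           n_folds_used = model$cv$n_folds_used)
    },
    stages = lapply(model$stages, function(st) {
      list(rho = st$rho,
           depth = st$tree$depth, min_obs = st$tree$min_obs, p = st$tree$p,
           nodes = st$tree$nodes)
    })
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null", dataframe = "columns")
  atomic_write(path, function(tmp) writeLines(json, tmp))
  invisible(path)
}

#' Read a boosted model from a JSON file
#'
#' Reconstructs a `ciboost_gbm` object written by [write_gbm_model()].
#'
#' @param path Path to a model JSON file.
#' @return A `ciboost_gbm` object.
#' @export
read_gbm_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file '%s' does not exist.", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version)) abort("not a ciboost model file.")
  feature_names <- as.character(unlist(doc$feature_names))
  cox_init <- NULL
  if (identical(doc$init$type, "cox")) {
    theta <- unlist(doc$init$coefficients)
    cox_init <- structure(list(theta = setNames(as.numeric(theta), names(theta)),
                               converged = TRUE, iterations = NA_integer_,
                               objective_path = numeric(0),
                               feature_names = feature_names,
                               n = doc$n, n_events = doc$n_events),
                          class = "ciboost_cox")
  }
  stages <- lapply(doc$stages, function(st) {
    nodes <- as.data.frame(lapply(st$nodes, function(col) {
      unlist(lapply(col, function(v) if (is.null(v)) NA else v))
    }))
    nodes$id <- as.integer(nodes$id)
    nodes$feature <- as.integer(nodes$feature)
    nodes$left <- as.integer(nodes$left)
    nodes$right <- as.integer(nodes$right)
    nodes$n_obs <- as.integer(nodes$n_obs)
    tree <- structure(list(nodes = nodes, depth = as.integer(st$depth),
                           min_obs = as.integer(st$min_obs),
                           p = as.integer(st$p)),
                      class = "ciboost_tree")
    list(rho = as.numeric(st$rho), tree = tree)
  })
  cv <- NULL
  if (!is.null(doc$cv)) {
    cv <- list(best_m = as.integer(doc$cv$best_m),
               cv_curve = as.numeric(unlist(doc$cv$cv_curve)),
               n_folds_used = as.integer(doc$cv$n_folds_used))
  }
  params <- doc$params
  params$seed <- as.integer(params$seed)
  structure(list(objective = doc$objective, stages = stages,
                 cox_init = cox_init,
                 selected_stages = as.integer(doc$selected_stages),
                 training_log = as.numeric(unlist(doc$training_log)),
                 final_training_scores = as.numeric(unlist(doc$final_training_scores)),
                 cv = cv, params = params, feature_names = feature_names,
                 n = as.integer(doc$n), n_events = as.integer(doc$n_events),
                 n_skipped = as.integer(doc$n_skipped)),
            class = "ciboost_gbm")
}

# write via temp file in the same directory + rename, so a failed write
# never leaves a partial output
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort(sprintf("could not write '%s'.", path))
  invisible(path)
}
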