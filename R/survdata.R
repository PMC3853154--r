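#' Validate a survival data frame
#'
#' Checks that a data frame is a well-formed right-censored survival dataset:
#' one row per subject, a positive follow-up time column, a 0/1 event status
#' column (1 = event observed, 0 = right-censored), and numeric covariate
#' columns with no missing values. Validation failures name the offending row
#' and column. All model-fitting and evaluation functions in ciboost call this
#' internally; it is exported so pipelines can fail early.
#'
#' @param data A data frame: one row per subject.
#' @param time_col Name of the observed follow-up time column (default
#'   `"time"`). Times must be strictly positive; units are arbitrary.
#' @param status_col Name of the event indicator column (default `"status"`);
#'   must contain only 0 (censored) and 1 (event).
#' @return `data`, invisibly, as a tibble (covariate column order preserved).
#' @examples
#' validate_survival_data(tibble::tibble(time = c(1, 2), status = c(1, 0), x = c(0.3, -1)))
#' @export
validate_survival_data <- function(data, time_col = "time", status_col = "status") {
  as_survdata(data, time_col, status_col)
  invisible(as_tibble(data))
}

# Internal canonical form: list(time, status, x, feature_names, n).
# All numerical routines work on this light structure.
as_survdata <- function(data, time_col = "time", status_col = "status") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(time_col, status_col)) {
    if (!col %in% names(data)) {
      abort(sprintf("column '%s' not found in `data`.", col))
    }
  }
  n <- nrow(data)
  if (n < 2) abort("survival data must contain at least 2 subjects.")

  time <- data[[time_col]]
  status <- data[[status_col]]
  if (!is.numeric(time)) abort(sprintf("column '%s' must be numeric.", time_col))
  if (!is.numeric(status)) abort(sprintf("column '%s' must be numeric.", status_col))
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad)) {
    abort(sprintf("column '%s' must be positive and finite (row %d has %s).",
                  time_col, bad[1], format(time[bad[1]])))
  }
  bad <- which(!(status %in% c(0, 1)))
  if (length(bad)) {
    abort(sprintf("column '%s' must be 0 or 1 (row %d has %s).",
                  status_col, bad[1], format(status[bad[1]])))
  }

  feature_names <- setdiff(names(data), c(time_col, status_col))
  x <- matrix(numeric(0), nrow = n, ncol = 0)
  if (length(feature_names)) {
    for (col in feature_names) {
      v <- data[[col]]
      if (!is.numeric(v)) abort(sprintf("covariate column '%s' must be numeric.", col))
      bad <- which(!is.finite(v))
      if (length(bad)) {
        abort(sprintf("covariate column '%s' has a missing or non-finite value (row %d).",
                      col, bad[1]))
      }
    }
    x <- as.matrix(data[feature_names])
    dimnames(x) <- list(NULL, feature_names)
  }
  list(time = as.numeric(time), status = as.integer(status), x = x,
       feature_names = feature_names, n = n)
}

#' Read survival data from CSV
#'
#' Reads a comma-separated file with a header row into a validated survival
#' tibble. Every column other than the time and status columns is treated as a
#' numeric covariate. Missing values are not accepted: the reader fails with a
#' message naming the row and column rather than imputing.
#'
#' @inheritParams validate_survival_data
#' @param path Path to a CSV file with a header row.
#' @return A tibble with the file's columns (order preserved).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time,status,age", "5,1,61", "8,0,48"), f)
#' read_survival_csv(f)
#' @export
read_survival_csv <- function(path, time_col = "time", status_col = "status") {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_survdata(data, time_col, status_col)
  as_tibble(data)
}

#' Enumerate comparable (validly orderable) subject pairs
#'
#' A pair (i, j) is comparable when subject i's event is observed
#' (`status == 1`) and its time is strictly smaller than subject j's observed
#' time. Only these pairs carry ranking information under right censoring: a
#' censored subject can appear only as the later member, and pairs with tied
#' times are excluded. These pairs are the denominator set of the concordance
#' index.
#'
#' @inheritParams validate_survival_data
#' @return A tibble with integer columns `i` (earlier, event observed) and `j`
#'   (later), ordered by `i` then `j`. Zero rows is a legal result.
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), status = c(1, 1, 1))
#' comparable_pairs(d) # all 3 ordered pairs
#' @export
comparable_pairs <- function(data, time_col = "time", status_col = "status") {
  sd <- as_survdata(data, time_col, status_col)
  p <- pair_indices(sd)
  tibble(i = p$i, j = p$j)
}

# Fast internal pair enumeration on the canonical form.
pair_indices <- function(sd) {
  ev <- which(sd$status == 1L)
  time <- sd$time
  out_i <- vector("list", length(ev))
  out_j <- vector("list", length(ev))
  for (k in seq_along(ev)) {
    i <- ev[k]
    j <- which(time > time[i])
    out_i[[k]] <- rep.int(i, length(j))
    out_j[[k]] <- j
  }
  i <- unlist(out_i, use.names = FALSE)
  j <- unlist(out_j, use.names = FALSE)
  if (is.null(i)) i <- integer(0)
  if (is.null(j)) j <- integer(0)
  o <- order(i, j)
  list(i = as.integer(i[o]), j = as.integer(j[o]), size = length(i))
}
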