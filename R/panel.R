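#' Longitudinal panel data
#'
#' A panel is a long-format data frame with one row per person-visit holding a
#' binary treatment, a continuous outcome (lung-function-like, percent units),
#' a bounded count outcome (annual treatment-days-like, 0--365) that also acts
#' as a time-dependent confounder, baseline covariates, and an observation
#' (censoring) indicator. Visits are integer-coded starting at 0; no one is
#' treated at visit 0, and once a person is censored they stay censored.
#'
#' `as_panel()` validates a data frame and attaches the `panel_df` class.
#' Unobserved rows (after censoring) may carry `NA` treatment and outcomes.
#'
#' @param data A data frame with columns `id`, `visit`, `x`, `y_cont`,
#'   `y_count`, `observed`, and one or more baseline covariate columns
#'   (by default `age`).
#' @param baseline Character vector naming the baseline covariate columns.
#' @return A `panel_df` data frame sorted by `(id, visit)` with attributes
#'   `baseline` (covariate names) and `n_visits` (the largest visit index).
#' @examples
#' pd <- data.frame(id = rep(1:2, each = 3), visit = rep(0:2, 2),
#'                  x = c(0, 1, 1, 0, 0, 1),
#'                  y_cont = rnorm(6, 85, 10), y_count = rpois(6, 3),
#'                  age = rep(c(12, 30), each = 3), observed = 1)
#' panel <- as_panel(pd)
#' @export
as_panel <- function(data, baseline = "age") {
  required <- c("id", "visit", "x", "y_cont", "y_count", "observed", baseline)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[order(data$id, data$visit), , drop = FALSE]
  rownames(data) <- NULL
  validate_panel(data)
  structure(data,
            baseline = baseline,
            n_visits = max(data$visit),
            class = c("panel_df", "data.frame"))
}

#' @keywords internal
validate_panel <- function(data) {
  if (any(data$visit != as.integer(data$visit))) {
    stop("non-integer visit values", call. = FALSE)
  }
  obs <- data$observed == 1
  bad_count <- obs & !is.na(data$y_count) &
    (data$y_count < 0 | data$y_count > 365 |
       data$y_count != floor(data$y_count))
  if (any(bad_count)) {
    i <- which(bad_count)[1]
    stop(sprintf("count outcome outside [0, 365] for person %s at visit %d",
                 data$id[i], data$visit[i]), call. = FALSE)
  }
  sp <- split(seq_len(nrow(data)), data$id)
  for (idx in sp) {
    v <- data$visit[idx]
    o <- data$observed[idx]
    person <- data$id[idx[1]]
    if (v[1] != 0) {
      stop(sprintf("person %s does not start at visit 0", person),
           call. = FALSE)
    }
    if (any(diff(v) != 1)) {
      gap_at <- v[which(diff(v) != 1)[1]]
      stop(sprintf("gap in visit sequence for person %s after visit %d",
                   person, gap_at), call. = FALSE)
    }
    if (o[1] == 1 && !is.na(data$x[idx[1]]) && data$x[idx[1]] != 0) {
      stop(sprintf("person %s is treated at visit 0", person), call. = FALSE)
    }
    # monotone censoring: once unobserved, always unobserved
    if (any(diff(o) > 0)) {
      stop(sprintf("person %s becomes observed again after censoring", person),
           call. = FALSE)
    }
  }
  invisible(data)
}

#' Read a long-format panel from CSV
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping panel column names to
#'   file column names, e.g. `c(id = "patient", x = "treated")`. Columns not
#'   mentioned are taken verbatim.
#' @param baseline Baseline covariate columns (panel-side names).
#' @return A validated [as_panel()] object.
#' @export
read_panel <- function(path, schema = NULL, baseline = "age") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(raw))
    if (length(miss) > 0) {
      stop("schema refers to absent file columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (panel_name in names(schema)) {
      names(raw)[names(raw) == schema[[panel_name]]] <- panel_name
    }
  }
  as_panel(raw, baseline = baseline)
}

#' Write a panel to CSV
#'
#' Writes all columns with full double precision so that a read/write
#' round-trip preserves values.
#'
#' @param panel A `panel_df`.
#' @param path Output file path.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Add lagged columns to a panel
#'
#' For each requested lag `k`, adds `x_lag<k>`, `y_cont_lag<k>` and
#' `y_count_lag<k>` holding the person's values `k` visits earlier. Lags that
#' would precede visit 0 are `NA`. Row count and ordering are unchanged.
#'
#' @param panel A `panel_df`.
#' @param lags Integer vector of lags (each >= 1).
#' @return The panel with additional lag columns.
#' @export
lagged_view <- function(panel, lags = 1L) {
  if (any(lags < 1) || any(lags != floor(lags))) {
    stop("lags must be positive integers", call. = FALSE)
  }
  out <- panel
  for (k in lags) {
    for (col in c("x", "y_cont", "y_count")) {
      out[[paste0(col, "_lag", k)]] <- lag_within(panel[[col]], panel$id, k)
    }
  }
  out
}

# shift a vector by k within person blocks (panel assumed sorted by id, visit)
#' @keywords internal
lag_within <- function(values, id, k, fill = NA) {
  n <- length(values)
  shifted <- c(rep(fill, k), values[seq_len(max(n - k, 0))])
  # invalidate positions that crossed a person boundary
  id_shift <- c(rep(NA, k), id[seq_len(max(n - k, 0))])
  shifted[is.na(id_shift) | id_shift != id] <- fill
  shifted
}

#' @export
print.panel_df <- function(x, ...) {
  cat(sprintf("panel: %d persons x visits 0..%d (%d rows, %.1f%% observed)\n",
              length(unique(x$id)), attr(x, "n_visits"), nrow(x),
              100 * mean(x$observed == 1)))
  NextMethod()
}

# Analysis view used by all estimators: rows at visits >= 1 with lagged
# treatment (zero-filled before visit 1, since x0 = 0 structurally) and lagged
# outcomes (NA before visit 0 never occurs for lag 1 at visit >= 1).
#' @keywords internal
analysis_view <- function(panel, n_lags = NULL) {
  if (is.null(n_lags)) n_lags <- attr(panel, "n_visits")
  out <- as.data.frame(panel)
  for (k in seq_len(n_lags)) {
    out[[paste0("x_lag", k)]] <- lag_within(panel$x, panel$id, k, fill = 0)
  }
  out$y_cont_lag1 <- lag_within(panel$y_cont, panel$id, 1)
  out$y_count_lag1 <- lag_within(panel$y_count, panel$id, 1)
  # integer person-visit key with a direct-index lookup table for fast
  # same-person shifts (visits fit in 6 bits)
  out$.id_ix <- match(out$id, unique(out$id))
  out$.key <- out$.id_ix * 64L + out$visit
  lookup <- rep(NA_integer_, max(out$.key))
  lookup[out$.key] <- seq_len(nrow(out))
  attr(out, "lookup") <- lookup
  out
}
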