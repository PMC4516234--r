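# Preprocessing: background subtraction, inter-plate QC, sparse-feature
# removal and the two-regime (train/test) imputation scheme.

#' Background-subtract stimulated well concentrations
#'
#' Net secretion = stimulated minus unstimulated concentration. Negative net
#' values are preserved by default; \code{clamp = TRUE} truncates them at
#' zero. Missing inputs propagate to missing outputs.
#'
#' @param stimulated,unstimulated numeric vectors (pg/ml), recycled.
#' @param clamp logical; truncate negative net values at zero.
#' @return Numeric vector of net concentrations.
#' @export
subtract_background <- function(stimulated, unstimulated, clamp = FALSE) {
  net <- stimulated - unstimulated
  if (clamp) net <- pmax(net, 0)
  net
}

#' Convert paired raw wells to a net cohort
#'
#' Applies \code{\link{subtract_background}} condition-wise to the output of
#' \code{\link{generate_raw_wells}} and reassembles the full cohort
#' (cytokine conditions plus clinical variables).
#'
#' @param raw a \code{raw_wells} object.
#' @param clamp passed to \code{subtract_background}.
#' @return A \code{cohort}.
#' @export
net_cohort <- function(raw, clamp = FALSE) {
  stopifnot(inherits(raw, "raw_wells"))
  net <- subtract_background(raw$stimulated, raw$unstimulated, clamp = clamp)
  values <- cbind(net, raw$clinical)
  cohort(values, rbind(raw$specs, raw$clinical_specs),
         as.character(raw$labels))
}

#' Inter-plate positive-control QC filter
#'
#' For each cytokine, outlying positive-control values are removed by the
#' 1.5 x IQR fence rule, and the cytokine is retained iff the max/min ratio
#' of the surviving controls is finite and at most \code{threshold}. A
#' cytokine whose surviving controls include zero (ratio undefined or
#' infinite) is dropped and flagged.
#'
#' @param controls named list; per cytokine, the numeric vector of per-plate
#'   positive-control values (length >= 2).
#' @param threshold maximum acceptable max/min ratio (default 5).
#' @return A data frame of class \code{qc_report} with columns
#'   \code{cytokine}, \code{ratio}, \code{retained}, \code{n_outliers},
#'   and attribute \code{threshold}.
#' @export
interplate_qc <- function(controls, threshold = 5) {
  stopifnot(is.list(controls), length(controls) > 0, threshold > 0)
  if (is.null(names(controls)) || any(names(controls) == ""))
    stop("controls must be a named list (one entry per cytokine)")
  rows <- lapply(names(controls), function(cy) {
    x <- controls[[cy]]
    if (length(x) < 2L)
      stop("cytokine ", cy, " has fewer than 2 control values")
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    fence <- 1.5 * (q[2] - q[1])
    keep <- x >= q[1] - fence & x <= q[2] + fence
    surv <- x[keep]
    ratio <- if (min(surv) > 0) max(surv) / min(surv) else Inf
    data.frame(cytokine = cy, ratio = ratio,
               retained = is.finite(ratio) && ratio <= threshold,
               n_outliers = sum(!keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$ratio)))
    warning("undefined max/min ratio (non-positive controls) for: ",
            paste(out$cytokine[!is.finite(out$ratio)], collapse = ", "),
            "; cytokine(s) dropped")
  attr(out, "threshold") <- threshold
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Drop variables with insufficient observed data
#'
#' A variable is kept only when strictly more than
#' \code{min_available_fraction} of patients have an observed value
#' (imputation is only trusted for variables with more than 50% available
#' data, the default).
#'
#' @param x a \code{cohort}.
#' @param min_available_fraction proportion in (0, 1]; default 0.5.
#' @return A list: \code{cohort} (survivors, original order preserved) and
#'   \code{dropped} (character vector of removed variable names).
#' @export
drop_sparse_features <- function(x, min_available_fraction = 0.5) {
  stopifnot(inherits(x, "cohort"),
            min_available_fraction > 0, min_available_fraction <= 1)
  avail <- colMeans(!is.na(x$values))
  keep <- avail > min_available_fraction
  if (!any(keep)) stop("all variables dropped: cohort would be empty")
  list(cohort = subset_cohort(x, variables = which(keep)),
       dropped = colnames(x$values)[!keep])
}

stat_mode <- function(v) {
  # most frequent value; ties broken toward the smallest value
  tab <- table(v)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

#' Class-conditional imputation of a training matrix
#'
#' Missing training cells are replaced by the mean (continuous variables) or
#' statistical mode (binary/ordinal/nominal) of the observed values of the
#' same class in the training set. The returned statistics also carry the
#' GLOBAL training mean/mode per variable, which is what the matching
#' test-set imputation uses so that test labels are never consulted. A class
#' with no observed value for some variable falls back to the global
#' training statistic.
#'
#' @param train numeric matrix (patients x variables), training rows only.
#' @param y binary integer labels aligned with the rows of \code{train}.
#' @param specs variable-specification rows aligned with the columns.
#' @return A list: \code{values} (completed matrix) and \code{stats} (an
#'   \code{imputation_stats} object for \code{\link{impute_test}}).
#' @export
impute_train <- function(train, y, specs) {
  stopifnot(is.matrix(train), nrow(train) == length(y),
            ncol(train) == nrow(specs), all(y %in% c(0L, 1L)))
  cont <- specs$vtype == "continuous"
  global <- numeric(ncol(train))
  class_stat <- matrix(NA_real_, 2L, ncol(train),
                       dimnames = list(c("0", "1"), specs$name))
  out <- train
  fallback <- character(0)
  for (j in seq_len(ncol(train))) {
    v <- train[, j]
    obs <- !is.na(v)
    if (!any(obs)) stop("variable ", specs$name[j],
                        " has no observed training value")
    global[j] <- if (cont[j]) mean(v[obs]) else stat_mode(v[obs])
    for (cl in 0:1) {
      sel <- obs & y == cl
      class_stat[cl + 1L, j] <- if (any(sel)) {
        if (cont[j]) mean(v[sel]) else stat_mode(v[sel])
      } else {
        fallback <- c(fallback, specs$name[j])
        global[j]
      }
      fill <- !obs & y == cl
      if (any(fill)) out[fill, j] <- class_stat[cl + 1L, j]
    }
  }
  if (length(fallback))
    message("global-statistic fallback used for: ",
            paste(unique(fallback), collapse = ", "))
  names(global) <- specs$name
  stats <- structure(list(global = global, class_stat = class_stat,
                          vtype = stats::setNames(specs$vtype, specs$name)),
                     class = "imputation_stats")
  list(values = out, stats = stats)
}

#' Impute a test matrix with training-set global statistics
#'
#' Every missing test cell is filled with the global training mean/mode of
#' its variable; test labels and other test rows are never consulted, so the
#' imputed value of a row is a pure function of that row and the training
#' statistics.
#'
#' @param test numeric matrix (patients x variables).
#' @param stats an \code{imputation_stats} object from
#'   \code{\link{impute_train}}.
#' @return The completed test matrix.
#' @export
impute_test <- function(test, stats) {
  stopifnot(is.matrix(test), inherits(stats, "imputation_stats"))
  miss <- setdiff(colnames(test), names(stats$global))
  if (length(miss))
    stop("variable(s) absent from training statistics: ",
         paste(miss, collapse = ", "))
  for (j in colnames(test)) {
    na <- is.na(test[, j])
    if (any(na)) test[na, j] <- stats$global[[j]]
  }
  test
}
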