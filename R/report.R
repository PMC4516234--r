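# Human-readable reporting: cohort summary counts and the descriptive
# univariate table.

#' Cohort summary counts and percentages
#'
#' Per-class counts with percentages of classified patients (rounded to
#' whole percent, so the shares sum on the classified denominator), plus an
#' optional dropout rate 100 (enrolled - retained) / enrolled (2 decimals)
#' and an optional atopic share among allergic children (whole percent).
#'
#' @param x a \code{cohort}, or a named vector of per-class counts.
#' @param enrolled,retained optional enrolment metadata for the dropout
#'   rate.
#' @param atopic optional \code{c(n_atopic, n_allergic)} pair.
#' @return A list of class \code{cohort_summary}: \code{counts},
#'   \code{percent}, and when supplied \code{dropout_pct},
#'   \code{atopic_pct}.
#' @export
cohort_summary <- function(x, enrolled = NULL, retained = NULL,
                           atopic = NULL) {
  counts <- if (inherits(x, "cohort")) {
    tab <- table(x$labels)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    x
  }
  out <- list(counts = counts,
              percent = round(100 * counts / sum(counts)))
  if (!is.null(enrolled)) {
    stopifnot(!is.null(retained), enrolled >= retained, enrolled > 0)
    out$enrolled <- enrolled
    out$retained <- retained
    out$dropout_pct <- round(100 * (enrolled - retained) / enrolled, 2)
  }
  if (!is.null(atopic)) {
    stopifnot(length(atopic) == 2L, atopic[1] <= atopic[2])
    out$atopic_pct <- round(100 * atopic[1] / atopic[2])
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (cl in names(x$counts))
    cat(sprintf("  %-22s %4d (%d%%)\n", cl, x$counts[[cl]],
                x$percent[[cl]]))
  cat("  (percentages of classified patients)\n")
  if (!is.null(x$dropout_pct))
    cat(sprintf("  dropout: %.2f%% (%d enrolled, %d retained)\n",
                x$dropout_pct, x$enrolled, x$retained))
  if (!is.null(x$atopic_pct))
    cat(sprintf("  atopic among allergic: %d%%\n", x$atopic_pct))
  invisible(x)
}

#' Descriptive univariate report
#'
#' One row per variable with the group summaries, a direction marker, the
#' raw p-value and the Benjamini-Hochberg corrected p-value computed over
#' ALL variables of the cohort (so the correction accounts for the 296
#' simultaneous tests in the standard layout), sorted by ascending raw p.
#'
#' @param x a \code{cohort} (all variables are tested; the univariate report
#'   is descriptive and uses pairwise-complete observations, no imputation).
#' @param task a \code{\link{label_task}}.
#' @param top_k optionally keep only the k best-ranked rows.
#' @param welch,yates passed to \code{\link{dispatch_test}}.
#' @return A data frame: \code{variable}, \code{test_used},
#'   \code{group_pos}, \code{group_neg} (means or positive shares),
#'   \code{direction}, \code{p_raw}, \code{p_adjusted}.
#' @export
univariate_report <- function(x, task, top_k = NULL, welch = FALSE,
                              yates = FALSE) {
  stopifnot(inherits(x, "cohort"), inherits(task, "label_task"))
  y <- suppressMessages(binarize(x, task))
  res <- univariate_tests(x, y, welch = welch, yates = yates)
  res$p_adjusted <- bh_adjust(res$p_raw, m = nrow(res))
  out <- data.frame(variable = res$variable, test_used = res$test_used,
                    group_pos = res$summary1, group_neg = res$summary0,
                    direction = ifelse(is.na(res$summary1), "",
                                       ifelse(res$summary1 < res$summary0,
                                              "<", ifelse(res$summary1 >
                                                          res$summary0,
                                                          ">", "="))),
                    p_raw = res$p_raw, p_adjusted = res$p_adjusted,
                    stringsAsFactors = FALSE)
  out <- out[order(is.na(out$p_raw), out$p_raw, out$variable), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Write a QC report to CSV
#'
#' @param report a \code{qc_report} from \code{\link{interplate_qc}}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
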