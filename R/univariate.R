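# Per-variable two-group testing, FDR correction and deterministic ranking.
#
# Dispatch follows variable type: continuous -> unpaired two-sample t-test
# (pooled variance by default, Welch optional); ordinal -> Mann-Whitney;
# binary/nominal -> chi-square, switching to Fisher's exact test when any
# expected cell count falls below 5. All tests two-sided; missing values
# are excluded pairwise.

# pooled-variance two-sample t for one or many columns; returns stat + p.
# Degenerate cases: zero pooled variance with equal means -> stat 0, p 1;
# zero pooled variance with unequal means -> p 0 (perfect separation);
# fewer than 2 observations in a group -> NA.
.t2_columns <- function(X, y) {
  X <- as.matrix(X)
  g1 <- y == 1L
  n1 <- colSums(!is.na(X[g1, , drop = FALSE]))
  n0 <- colSums(!is.na(X[!g1, , drop = FALSE]))
  m1 <- colMeans(X[g1, , drop = FALSE], na.rm = TRUE)
  m0 <- colMeans(X[!g1, , drop = FALSE], na.rm = TRUE)
  ss <- function(M, mu, n) {
    d <- sweep(M, 2L, mu)
    colSums(d * d, na.rm = TRUE)
  }
  s2p <- (ss(X[g1, , drop = FALSE], m1, n1) +
          ss(X[!g1, , drop = FALSE], m0, n0)) / (n1 + n0 - 2)
  se <- sqrt(s2p * (1 / n1 + 1 / n0))
  stat <- (m1 - m0) / se
  df <- n1 + n0 - 2
  p <- 2 * stats::pt(-abs(stat), df)
  zero <- is.finite(s2p) & s2p == 0
  stat[zero & (m1 == m0)] <- 0
  p[zero & (m1 == m0)] <- 1
  p[zero & (m1 != m0)] <- 0
  bad <- n1 < 2 | n0 < 2
  stat[bad] <- NA_real_
  p[bad] <- NA_real_
  list(statistic = stat, p = p, mean1 = m1, mean0 = m0, n1 = n1, n0 = n0)
}

#' Two-group test for a single variable, dispatched on type
#'
#' @param values numeric vector for one variable (missing allowed).
#' @param y binary labels (1 = positive group) aligned with \code{values}.
#' @param vtype one of \code{continuous}, \code{binary}, \code{ordinal},
#'   \code{nominal}.
#' @param name variable name carried into the result.
#' @param welch use Welch's unequal-variance t-test instead of the pooled
#'   test for continuous variables.
#' @param yates apply Yates continuity correction to the chi-square test.
#' @return A one-row data frame (class \code{test_result}): \code{variable},
#'   \code{test_used}, \code{statistic}, \code{p_raw}, group summaries
#'   (means for continuous/ordinal, positive-value counts for discrete).
#'   Groups with fewer than 2 observations yield \code{p_raw = NA} with a
#'   warning; such variables rank last.
#' @export
dispatch_test <- function(values, y, vtype, name = "x",
                          welch = FALSE, yates = FALSE) {
  stopifnot(length(values) == length(y), vtype %in% VTYPE_LEVELS,
            all(y %in% c(0L, 1L)))
  obs <- !is.na(values)
  v <- values[obs]; yy <- y[obs]
  n1 <- sum(yy == 1L); n0 <- sum(yy == 0L)
  res <- data.frame(variable = name, test_used = NA_character_,
                    statistic = NA_real_, p_raw = NA_real_,
                    summary1 = NA_real_, summary0 = NA_real_,
                    n1 = n1, n0 = n0, stringsAsFactors = FALSE)
  if (n1 < 2L || n0 < 2L) {
    warning("variable ", name, ": a group has fewer than 2 observations; ",
            "test undefined")
    class(res) <- c("test_result", "data.frame")
    return(res)
  }
  if (vtype == "continuous") {
    if (welch) {
      tt <- stats::t.test(v[yy == 1L], v[yy == 0L], var.equal = FALSE)
      res$test_used <- "t_test"
      res$statistic <- unname(tt$statistic); res$p_raw <- tt$p.value
    } else {
      tc <- .t2_columns(matrix(v, ncol = 1), yy)
      res$test_used <- "t_test"
      res$statistic <- tc$statistic; res$p_raw <- tc$p
    }
    res$summary1 <- mean(v[yy == 1L]); res$summary0 <- mean(v[yy == 0L])
  } else if (vtype == "ordinal") {
    exact <- (n1 + n0) <= 20L
    wt <- suppressWarnings(
      stats::wilcox.test(v[yy == 1L], v[yy == 0L], exact = exact))
    res$test_used <- "mann_whitney"
    res$statistic <- unname(wt$statistic); res$p_raw <- wt$p.value
    res$summary1 <- mean(v[yy == 1L]); res$summary0 <- mean(v[yy == 0L])
  } else { # binary / nominal
    tab <- table(factor(yy, levels = c(1, 0)), v)
    if (ncol(tab) < 2L) {
      # constant variable: no association, p = 1
      res$test_used <- "chi_square"; res$statistic <- 0; res$p_raw <- 1
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(tab)
        res$test_used <- "fisher_exact"
        res$statistic <- if (!is.null(ft$estimate))
          unname(ft$estimate) else NA_real_
        res$p_raw <- ft$p.value
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
        res$test_used <- "chi_square"
        res$statistic <- unname(ct$statistic); res$p_raw <- ct$p.value
      }
    }
    res$summary1 <- mean(v[yy == 1L]); res$summary0 <- mean(v[yy == 0L])
  }
  # exact-test p-values can exceed 1 by a rounding epsilon
  res$p_raw <- min(res$p_raw, 1)
  class(res) <- c("test_result", "data.frame")
  res
}

#' Run the dispatched test for every variable of a cohort
#'
#' @param x a \code{cohort} (or a numeric matrix with \code{specs}).
#' @param y binary labels aligned with the rows (see \code{\link{binarize}};
#'   if \code{y} carries a \code{keep} attribute the matrix rows are
#'   subset accordingly).
#' @param specs variable metadata (defaults to the cohort's).
#' @param welch,yates passed to \code{\link{dispatch_test}}.
#' @return A data frame with one \code{test_result} row per variable.
#' @export
univariate_tests <- function(x, y, specs = NULL, welch = FALSE,
                             yates = FALSE) {
  if (inherits(x, "cohort")) {
    if (is.null(specs)) specs <- x$specs
    x <- x$values
  }
  if (!is.null(attr(y, "keep"))) x <- x[attr(y, "keep"), , drop = FALSE]
  stopifnot(nrow(x) == length(y), ncol(x) == nrow(specs))
  p <- ncol(x)
  test_used <- character(p); statistic <- numeric(p)
  p_raw <- numeric(p); s1 <- numeric(p); s0 <- numeric(p)
  n1 <- integer(p); n0 <- integer(p)
  cont <- which(specs$vtype == "continuous")
  # vectorized pooled-t fast path for the continuous block
  if (length(cont) && !welch) {
    tc <- .t2_columns(x[, cont, drop = FALSE], y)
    bad <- tc$n1 < 2 | tc$n0 < 2
    test_used[cont] <- ifelse(bad, NA_character_, "t_test")
    statistic[cont] <- tc$statistic; p_raw[cont] <- tc$p
    s1[cont] <- tc$mean1; s0[cont] <- tc$mean0
    n1[cont] <- tc$n1; n0[cont] <- tc$n0
    rest <- setdiff(seq_len(p), cont)
  } else rest <- seq_len(p)
  for (j in rest) {
    r <- suppressWarnings(
      dispatch_test(x[, j], y, specs$vtype[j], name = specs$name[j],
                    welch = welch, yates = yates))
    test_used[j] <- r$test_used; statistic[j] <- r$statistic
    p_raw[j] <- r$p_raw; s1[j] <- r$summary1; s0[j] <- r$summary0
    n1[j] <- r$n1; n0[j] <- r$n0
  }
  data.frame(variable = specs$name, test_used = test_used,
             statistic = statistic, p_raw = p_raw,
             summary1 = s1, summary0 = s0, n1 = n1, n0 = n0,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts raw p-values controlling the false discovery rate, taking the
#' total variable count \code{m} into account even when it exceeds the
#' number of p-values supplied (so a report on a variable subset can still
#' correct over all variables of the analysis, e.g. all 296).
#'
#' @param p numeric vector of raw p-values in [0, 1] (\code{NA} allowed,
#'   returned as \code{NA}).
#' @param m total number of tests; defaults to the number of non-missing
#'   p-values and must be at least that.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p, m = sum(!is.na(p))) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < sum(!is.na(p)))
    stop("m must be at least the number of p-values")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Rank variables by ascending raw p-value
#'
#' Ties are broken lexicographically by variable name; variables whose test
#' is undefined (\code{p_raw = NA}) rank last (among themselves by name).
#'
#' @param results data frame from \code{\link{univariate_tests}}.
#' @return Character vector of variable names, best first.
#' @export
rank_features <- function(results) {
  stopifnot(all(c("variable", "p_raw") %in% names(results)))
  p <- results$p_raw
  p[is.na(p)] <- Inf
  results$variable[order(p, results$variable)]
}
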