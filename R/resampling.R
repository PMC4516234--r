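# Repeated random subsampling evaluation: J x (90% train / 10% test)
# with in-loop feature ranking and class-conditional imputation, scored by
# the Balanced Classification Rate with Nadeau-corrected confidence
# intervals.
#
# RNG discipline: the master seed draws one sub-seed per repeat up front;
# the split, ranking and imputation of a repeat are computed once from its
# sub-seed and shared across every classifier / signature size / feature
# set, so enlarging the model grid never perturbs the splits. Stochastic
# learners are re-seeded from the repeat sub-seed before each fit.

#' Configuration of the resampling protocol
#'
#' @param J number of random subsampling repeats (default 200).
#' @param train_fraction fraction of the cohort used for training (0.9).
#' @param signature_sizes signature sizes s to evaluate; the default grid
#'   includes s = 4 and covers the all-clinical case (s <= 8).
#' @param classifiers subset of \code{random_forest}, \code{svm},
#'   \code{one_nn}.
#' @param feature_sets subset of \code{cytokines_only}, \code{clinical_only},
#'   \code{all}.
#' @param task a \code{\link{label_task}}.
#' @param stratified draw class-stratified splits (default; with only 15
#'   positives an unstratified 10% test set frequently contains no positive,
#'   leaving the BCR undefined). Unstratified splits redraw degenerate
#'   draws, up to 10 J redraws.
#' @param hyper hyperparameter list (see \code{\link{train_predict}}).
#' @param alpha confidence-interval level complement (0.05 for 95% CIs).
#' @param seed master integer seed; results are bit-reproducible.
#' @return An object of class \code{protocol_config}.
#' @export
protocol_config <- function(J = 200L, train_fraction = 0.9,
                            signature_sizes = c(1L, 2L, 3L, 4L, 6L, 8L,
                                                12L, 16L, 24L, 32L),
                            classifiers = c("random_forest", "svm",
                                            "one_nn"),
                            feature_sets = c("cytokines_only",
                                             "clinical_only", "all"),
                            task = allergy_task(), stratified = TRUE,
                            hyper = list(), alpha = 0.05, seed = 1L) {
  stopifnot(J >= 2L, train_fraction > 0, train_fraction < 1,
            all(signature_sizes >= 1L), alpha > 0, alpha < 1)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  stopifnot(inherits(task, "label_task"))
  structure(list(J = as.integer(J), train_fraction = train_fraction,
                 signature_sizes = as.integer(signature_sizes),
                 classifiers = classifiers, feature_sets = feature_sets,
                 task = task, stratified = stratified, hyper = hyper,
                 alpha = alpha, seed = as.integer(seed)),
            class = "protocol_config")
}

# stratified (or redrawn unstratified) train/test split of y
draw_split <- function(y, train_fraction, stratified, max_redraws) {
  n <- length(y)
  if (stratified) {
    test <- integer(0)
    for (cl in unique(y)) {
      rows <- which(y == cl)
      n_te <- max(1L, round((1 - train_fraction) * length(rows)))
      test <- c(test, sample(rows, n_te))
    }
    return(list(test = sort(test), redraws = 0L))
  }
  for (k in 0:max_redraws) {
    test <- sort(sample.int(n, max(1L, round((1 - train_fraction) * n))))
    ok <- length(unique(y[test])) == 2L && length(unique(y[-test])) == 2L
    if (ok) return(list(test = test, redraws = k))
  }
  stop("protocol error: ", max_redraws, " redraws without a usable split")
}

#' Run the filter-then-classify resampling protocol
#'
#' For each of J repeats: draw a 90/10 split; rank all active variables on
#' the training rows only (type-dispatched univariate tests, pairwise
#' missing exclusion); class-conditionally impute the training rows; impute
#' the test rows with the global training statistics; for every classifier
#' and signature size, fit on the s best-ranked variables and record the
#' held-out BCR. Held-out rows never influence ranking or imputation.
#'
#' @param x a \code{cohort}, already passed through
#'   \code{\link{drop_sparse_features}}.
#' @param config a \code{\link{protocol_config}}.
#' @return An object of class \code{protocol_results}: a list of
#'   \code{resampling_result} objects (one per classifier x signature size x
#'   feature set), each holding per-repeat BCRs, the mean BCR, the
#'   Nadeau-corrected CI and the signature-frequency table.
#' @export
run_protocol <- function(x, config = protocol_config()) {
  stopifnot(inherits(x, "cohort"), inherits(config, "protocol_config"))
  y <- binarize(x, config$task)
  keep <- attr(y, "keep")
  values <- x$values[keep, , drop = FALSE]
  specs <- x$specs
  J <- config$J

  fs_cols <- list(
    cytokines_only = which(specs$provenance == "cytokine"),
    clinical_only = which(specs$provenance == "clinical"),
    all = seq_len(nrow(specs)))
  fs_cols <- fs_cols[config$feature_sets]
  max_s <- max(config$signature_sizes)
  for (fs in names(fs_cols))
    if (min(config$signature_sizes) > length(fs_cols[[fs]]))
      stop("feature set ", fs, " has fewer variables than every ",
           "signature size")

  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, J)

  combos <- expand.grid(classifier = config$classifiers,
                        s = config$signature_sizes,
                        feature_set = config$feature_sets,
                        stringsAsFactors = FALSE)
  # drop signature sizes larger than the feature set
  combos <- combos[combos$s <= vapply(combos$feature_set,
                                      function(f) length(fs_cols[[f]]),
                                      integer(1)), , drop = FALSE]
  res <- lapply(seq_len(nrow(combos)), function(i)
    list(bcrs = numeric(J), signatures = vector("list", J)))
  names(res) <- sprintf("%s_s%d_%s", combos$classifier, combos$s,
                        combos$feature_set)
  n_test <- NULL; n_train <- NULL; total_redraws <- 0L

  for (j in seq_len(J)) {
    set.seed(sub_seeds[j])
    sp <- draw_split(y, config$train_fraction, config$stratified, 10L * J)
    total_redraws <- total_redraws + sp$redraws
    te <- sp$test; tr <- setdiff(seq_along(y), te)
    n_test <- length(te); n_train <- length(tr)
    y_tr <- y[tr]; y_te <- y[te]

    # per-feature-set ranking and imputation on the training rows only
    for (fi in seq_along(fs_cols)) {
      cols <- fs_cols[[fi]]
      fs_name <- names(fs_cols)[fi]
      sub_specs <- specs[cols, , drop = FALSE]
      tr_vals <- values[tr, cols, drop = FALSE]
      te_vals <- values[te, cols, drop = FALSE]
      ranking <- rank_features(univariate_tests(tr_vals, y_tr, sub_specs))
      imp <- impute_train(tr_vals, y_tr, sub_specs)
      te_imp <- impute_test(te_vals, imp$stats)
      for (i in which(combos$feature_set == fs_name)) {
        sig <- ranking[seq_len(combos$s[i])]
        set.seed(sub_seeds[j])
        pred <- train_predict(combos$classifier[i], imp$values, te_imp,
                              y_tr, sig, sub_specs,
                              spec = kernel_spec(), hyper = config$hyper,
                              seed = sub_seeds[j])
        res[[i]]$bcrs[j] <- bcr(y_te, pred)
        res[[i]]$signatures[[j]] <- sig
      }
    }
  }

  out <- lapply(seq_len(nrow(combos)), function(i) {
    bcrs <- res[[i]]$bcrs
    ci <- nadeau_ci(bcrs, n_train, n_test, config$alpha)
    freq <- sort(table(unlist(res[[i]]$signatures)), decreasing = TRUE)
    structure(list(descriptor = list(classifier = combos$classifier[i],
                                     s = combos$s[i],
                                     feature_set = combos$feature_set[i],
                                     task = config$task$task_id),
                   bcrs = bcrs, mean_bcr = mean(bcrs),
                   ci_low = ci[1], ci_high = ci[2],
                   signatures = res[[i]]$signatures,
                   signature_frequency = freq,
                   n_train = n_train, n_test = n_test,
                   redraws = total_redraws, alpha = config$alpha),
              class = "resampling_result")
  })
  names(out) <- names(res)
  structure(list(results = out, config = config),
            class = "protocol_results")
}

#' Nadeau-corrected confidence interval for resampled performance
#'
#' The naive variance of the mean over J overlapping resamples is inflated
#' to \code{V = (1/J + n_test/n_train) * s^2} (s^2 the sample variance of
#' the per-repeat scores), acknowledging that resampled training sets
#' overlap; the CI is \code{mean +/- t(J-1, 1-alpha/2) * sqrt(V)}, clipped
#' to [0, 1].
#'
#' @param bcrs numeric vector of per-repeat scores (length J >= 2).
#' @param n_train,n_test split sizes.
#' @param alpha level complement (0.05 for a 95% CI).
#' @return Numeric \code{c(ci_low, ci_high)}.
#' @export
nadeau_ci <- function(bcrs, n_train, n_test, alpha = 0.05) {
  J <- length(bcrs)
  if (J < 2L) stop("need at least 2 repeats for a variance estimate")
  stopifnot(n_train >= 1, n_test >= 1)
  V <- (1 / J + n_test / n_train) * stats::var(bcrs)
  half <- stats::qt(1 - alpha / 2, df = J - 1) * sqrt(V)
  m <- mean(bcrs)
  c(max(0, m - half), min(1, m + half))
}

#' Signature inclusion frequencies of a resampling result
#'
#' @param result a \code{resampling_result}.
#' @return Data frame of variables sorted by descending inclusion count
#'   (ties by name), with the count of repeats in which each variable
#'   entered the signature.
#' @export
summarize_signatures <- function(result) {
  stopifnot(inherits(result, "resampling_result"))
  tab <- table(unlist(result$signatures))
  ord <- order(-as.integer(tab), names(tab))
  data.frame(variable = names(tab)[ord],
             frequency = as.integer(tab)[ord],
             stringsAsFactors = FALSE)
}

#' Select the best model over all evaluated combinations
#'
#' Maximal mean BCR; ties broken by smaller signature size, then classifier
#' name. The report notes which competing results have overlapping CIs
#' (differences within the CIs are not significant).
#'
#' @param results a \code{protocol_results} object (or list of
#'   \code{resampling_result}).
#' @return The winning \code{resampling_result}, with attribute
#'   \code{overlapping} naming the other combinations whose CI overlaps the
#'   winner's.
#' @export
select_best <- function(results) {
  if (inherits(results, "protocol_results")) results <- results$results
  stopifnot(length(results) >= 1)
  d <- data.frame(i = seq_along(results),
                  mean = vapply(results, function(r) r$mean_bcr, 0),
                  s = vapply(results, function(r) r$descriptor$s, 0L),
                  cls = vapply(results, function(r)
                    r$descriptor$classifier, ""))
  d <- d[order(-d$mean, d$s, d$cls), ]
  best <- results[[d$i[1]]]
  others <- results[d$i[-1]]
  overl <- vapply(others, function(r)
    r$ci_high >= best$ci_low && best$ci_high >= r$ci_low, logical(1))
  attr(best, "overlapping") <- names(others)[overl]
  best
}

#' @export
print.resampling_result <- function(x, ...) {
  d <- x$descriptor
  cat(sprintf("%s task | %s | s = %d | %s\n", d$task, d$classifier, d$s,
              d$feature_set))
  cat(sprintf("mean BCR %.3f  (%d%% CI %.3f - %.3f, J = %d)\n",
              x$mean_bcr, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              length(x$bcrs)))
  top <- utils::head(summarize_signatures(x), 5L)
  cat("top signature members:",
      paste(sprintf("%s (%d)", top$variable, top$frequency),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.protocol_results <- function(x, ...) {
  cat("Resampling protocol:", length(x$results), "combination(s), J =",
      x$config$J, "\n")
  for (r in x$results) {
    d <- r$descriptor
    cat(sprintf("  %-13s s=%-3d %-14s mean BCR %.3f [%.3f, %.3f]\n",
                d$classifier, d$s, d$feature_set, r$mean_bcr, r$ci_low,
                r$ci_high))
  }
  invisible(x)
}

#' @export
summary.protocol_results <- function(object, ...) {
  d <- do.call(rbind, lapply(object$results, function(r)
    data.frame(classifier = r$descriptor$classifier, s = r$descriptor$s,
               feature_set = r$descriptor$feature_set,
               mean_bcr = r$mean_bcr, ci_low = r$ci_low,
               ci_high = r$ci_high, stringsAsFactors = FALSE)))
  rownames(d) <- NULL
  d[order(-d$mean_bcr), ]
}

#' Plot per-repeat BCR distributions
#'
#' Boxplots of the per-repeat BCRs of every evaluated combination, with the
#' chance level 0.5 marked.
#'
#' @param x a \code{protocol_results} object.
#' @param ... passed to \code{boxplot}.
#' @export
plot.protocol_results <- function(x, ...) {
  bl <- lapply(x$results, function(r) r$bcrs)
  graphics::boxplot(bl, las = 2, ylab = "BCR per repeat",
                    cex.axis = 0.6, ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  invisible(x)
}
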