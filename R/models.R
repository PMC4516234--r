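# Classifiers and kernels.
#
# The SVM consumes a precomputed Gram matrix combining a cosine-normalised
# linear kernel on standardised cytokine features with a clinical kernel
# for mixed-type clinical variables; 1-NN classifies by the kernel-induced
# distance. Random Forest works directly on the (imputed) feature matrix.

#' Clinical kernel similarity between two profiles
#'
#' Per-variable similarity, averaged without weights over the clinical
#' variables: continuous/ordinal variables contribute
#' \code{(r - |x - z|)/r} where \code{r} is the training range (clipped into
#' [0, 1] when test values fall outside it; a degenerate range r = 0
#' contributes 1); binary/nominal variables contribute the equality
#' indicator.
#'
#' @param x,z numeric clinical profiles (no missing values; impute first).
#' @param specs variable-specification rows for the profile entries.
#' @param ranges 2 x p matrix of training minima (row 1) and maxima (row 2).
#' @return Similarity in [0, 1]; 1 iff the profiles agree on every variable
#'   (given positive ranges).
#' @export
clinical_kernel_value <- function(x, z, specs, ranges) {
  stopifnot(length(x) == nrow(specs), length(z) == nrow(specs),
            ncol(ranges) == nrow(specs))
  if (anyNA(x) || anyNA(z))
    stop("clinical kernel requires complete profiles; impute first")
  sims <- numeric(nrow(specs))
  for (j in seq_len(nrow(specs))) {
    if (specs$vtype[j] %in% c("continuous", "ordinal")) {
      r <- ranges[2L, j] - ranges[1L, j]
      sims[j] <- if (r <= 0) 1 else min(max((r - abs(x[j] - z[j])) / r, 0), 1)
    } else sims[j] <- as.numeric(x[j] == z[j])
  }
  mean(sims)
}

# training ranges per column (2 x p matrix)
train_ranges <- function(train) {
  rbind(apply(train, 2L, min), apply(train, 2L, max))
}

# clinical kernel matrix between rows of A and rows of B (vectorised)
clinical_kernel_matrix <- function(A, B, specs, ranges) {
  K <- matrix(0, nrow(A), nrow(B))
  p <- nrow(specs)
  for (j in seq_len(p)) {
    if (specs$vtype[j] %in% c("continuous", "ordinal")) {
      r <- ranges[2L, j] - ranges[1L, j]
      S <- if (r <= 0) matrix(1, nrow(A), nrow(B)) else
        pmin(pmax((r - abs(outer(A[, j], B[, j], "-"))) / r, 0), 1)
    } else S <- outer(A[, j], B[, j], "==") * 1
    K <- K + S
  }
  K / p
}

#' Kernel combination specification
#'
#' @param combination one of \code{"average"} (mean of the cytokine and
#'   clinical parts), \code{"cytokine_only"}, \code{"clinical_only"}.
#' @return An object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(combination = c("average", "cytokine_only",
                                        "clinical_only")) {
  structure(list(combination = match.arg(combination)),
            class = "kernel_spec")
}

#' Combined train/test kernel matrices
#'
#' The cytokine part is the cosine-normalised inner product of cytokine
#' features standardised with the TRAINING mean and SD; the clinical part is
#' the clinical kernel with TRAINING ranges. Active parts are averaged.
#' Zero-variance cytokine features are excluded from the linear part with a
#' warning. If the requested part has no variables the other part is used
#' alone (degenerate signatures happen when a signature is all-clinical or
#' all-cytokine).
#'
#' @param train,test complete numeric matrices over the same variables.
#' @param specs variable metadata rows aligned with the columns.
#' @param spec a \code{\link{kernel_spec}}.
#' @return List with \code{train} (n_tr x n_tr, symmetric, unit diagonal
#'   when any part is active) and \code{test} (n_te x n_tr) kernel matrices.
#' @export
combined_kernel_matrix <- function(train, test, specs,
                                   spec = kernel_spec()) {
  stopifnot(inherits(spec, "kernel_spec"),
            ncol(train) == nrow(specs), ncol(test) == nrow(specs))
  cyt <- which(specs$provenance == "cytokine")
  cli <- which(specs$provenance == "clinical")
  use_cyt <- spec$combination != "clinical_only" && length(cyt) > 0
  use_cli <- spec$combination != "cytokine_only" && length(cli) > 0
  if (!use_cyt && !use_cli)
    stop("no active kernel part for the selected variables")
  parts_tr <- list(); parts_te <- list()
  if (use_cyt) {
    mu <- colMeans(train[, cyt, drop = FALSE])
    sd <- apply(train[, cyt, drop = FALSE], 2L, stats::sd)
    keep <- sd > 0
    if (!all(keep))
      warning("zero-variance cytokine feature(s) excluded from the linear ",
              "kernel: ", paste(specs$name[cyt[!keep]], collapse = ", "))
    cytk <- cyt[keep]
    if (length(cytk)) {
      Ztr <- scale(train[, cytk, drop = FALSE], mu[keep], sd[keep])
      Zte <- scale(test[, cytk, drop = FALSE], mu[keep], sd[keep])
      ntr <- sqrt(pmax(rowSums(Ztr^2), .Machine$double.eps))
      nte <- sqrt(pmax(rowSums(Zte^2), .Machine$double.eps))
      parts_tr$cyt <- tcrossprod(Ztr / ntr)
      parts_te$cyt <- tcrossprod(Zte / nte, Ztr / ntr)
    }
  }
  if (use_cli) {
    ranges <- train_ranges(train[, cli, drop = FALSE])
    parts_tr$cli <- clinical_kernel_matrix(train[, cli, drop = FALSE],
                                           train[, cli, drop = FALSE],
                                           specs[cli, ], ranges)
    parts_te$cli <- clinical_kernel_matrix(test[, cli, drop = FALSE],
                                           train[, cli, drop = FALSE],
                                           specs[cli, ], ranges)
  }
  if (!length(parts_tr))
    stop("no active kernel part for the selected variables")
  Ktr <- Reduce(`+`, parts_tr) / length(parts_tr)
  Kte <- Reduce(`+`, parts_te) / length(parts_te)
  Ktr <- (Ktr + t(Ktr)) / 2
  list(train = Ktr, test = Kte)
}

# kernel-induced squared distance from test rows to training rows
kernel_distance2 <- function(K) {
  # K: list as returned by combined_kernel_matrix; diagonal entries are 1
  # for the cosine/clinical construction
  sweep(-2 * K$test, 2L, diag(K$train), `+`) + 1
}

#' Train a classifier on a signature and predict held-out samples
#'
#' @param classifier \code{"random_forest"}, \code{"svm"} or
#'   \code{"one_nn"}.
#' @param train,test complete (imputed) numeric matrices over the cohort
#'   variables.
#' @param y_train binary integer training labels.
#' @param signature character vector of variable names to use.
#' @param specs variable metadata for the full matrices.
#' @param spec a \code{\link{kernel_spec}} (SVM and 1-NN).
#' @param hyper list of hyperparameters: \code{rf_n_trees} (500),
#'   \code{rf_mtry} (floor(sqrt(p))), \code{svm_C} (1).
#' @param seed integer seed consumed by the stochastic learners; identical
#'   seeds give identical predictions.
#' @return Integer vector of predicted labels for the test rows.
#' @export
train_predict <- function(classifier = c("random_forest", "svm", "one_nn"),
                          train, test, y_train, signature, specs,
                          spec = kernel_spec(), hyper = list(),
                          seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(all(signature %in% colnames(train)),
            all(y_train %in% c(0L, 1L)))
  if (length(unique(y_train)) < 2L)
    stop("degenerate training labels: a single class")
  idx <- match(signature, colnames(train))
  tr <- train[, idx, drop = FALSE]
  te <- test[, idx, drop = FALSE]
  sp <- specs[match(signature, specs$name), , drop = FALSE]
  # canonicalize training-row order (content-based) so stochastic learners
  # see the training set as a set: predictions are then invariant under
  # permutations of the supplied training rows (given the seed)
  ord <- do.call(order, c(unname(as.data.frame(tr)), list(y_train)))
  if (classifier == "random_forest") {
    ntree <- hyper$rf_n_trees %||% 500L
    mtry <- hyper$rf_mtry %||% max(1L, floor(sqrt(ncol(tr))))
    set.seed(seed)
    fit <- randomForest::randomForest(x = tr[ord, , drop = FALSE],
                                      y = factor(y_train[ord],
                                                 levels = 0:1),
                                      ntree = ntree, mtry = mtry)
    as.integer(as.character(predict(fit, te)))
  } else if (classifier == "svm") {
    tr <- tr[ord, , drop = FALSE]
    y_train <- y_train[ord]
    K <- combined_kernel_matrix(tr, te, sp, spec)
    C <- hyper$svm_C %||% 1
    set.seed(seed)
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K$train),
                         factor(y_train, levels = 0:1),
                         type = "C-svc", C = C)
    sv <- kernlab::SVindex(fit)
    pred <- kernlab::predict(fit,
                             kernlab::as.kernelMatrix(K$test[, sv,
                                                             drop = FALSE]))

    as.integer(as.character(pred))
  } else { # one_nn
    K <- combined_kernel_matrix(tr, te, sp, spec)
    d2 <- kernel_distance2(K)
    # nearest training instance; ties resolved to the smallest index
    nn <- apply(d2, 1L, which.min)
    as.integer(y_train[nn])
  }
}

#' Confusion counts for binary predictions
#'
#' @param truth,pred integer vectors of 0/1 labels.
#' @return Named integer vector \code{TP}, \code{FN}, \code{TN}, \code{FP}.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(0L, 1L)), all(pred %in% c(0L, 1L)))
  c(TP = sum(truth == 1L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L),
    TN = sum(truth == 0L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L))
}

#' Balanced Classification Rate
#'
#' The average of sensitivity TP/(TP+FN) and specificity TN/(TN+FP); robust
#' to class imbalance (a constant classifier scores 0.5).
#'
#' @param counts named vector as from \code{\link{confusion_counts}}, or a
#'   truth vector when \code{pred} is supplied.
#' @param pred optional predictions; when given, \code{counts} is the truth.
#' @return BCR in [0, 1].
#' @export
bcr <- function(counts, pred = NULL) {
  if (!is.null(pred)) counts <- confusion_counts(counts, pred)
  counts <- counts[c("TP", "FN", "TN", "FP")]
  if (anyNA(counts)) stop("counts must contain TP, FN, TN, FP")
  if (counts["TP"] + counts["FN"] < 1 || counts["TN"] + counts["FP"] < 1)
    stop("undefined BCR: a truth class is absent")
  se <- counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
  sp <- counts[["TN"]] / (counts[["TN"]] + counts[["FP"]])
  (se + sp) / 2
}
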