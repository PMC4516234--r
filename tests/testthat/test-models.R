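clinical_only_specs <- function() {
  s <- tiny_specs()
  s[s$provenance == "clinical", , drop = FALSE]
}

test_that("clinical kernel follows the per-variable construction", {
  specs <- data.frame(name = c("age_like", "sex_like"),
                      vtype = c("continuous", "nominal"),
                      provenance = "clinical", cytokine = NA,
                      stimulation = NA, duration_h = NA, timepoint = NA,
                      stringsAsFactors = FALSE)
  ranges <- rbind(c(0, 0), c(10, 1))
  # identical profiles: similarity 1
  expect_equal(clinical_kernel_value(c(3, 1), c(3, 1), specs, ranges), 1)
  # single continuous variable at the range extremes: 0
  s1 <- specs[1, , drop = FALSE]
  r1 <- ranges[, 1, drop = FALSE]
  expect_equal(clinical_kernel_value(0, 10, s1, r1), 0)
  # hand evaluation: continuous (10 - 2)/10 = 0.8, nominal equal = 1
  expect_equal(clinical_kernel_value(c(2, 1), c(4, 1), specs, ranges), 0.9)
  # symmetry and [0, 1] bounds with out-of-range test values (clipped)
  expect_equal(clinical_kernel_value(c(2, 0), c(4, 1), specs, ranges),
               clinical_kernel_value(c(4, 1), c(2, 0), specs, ranges))
  expect_equal(clinical_kernel_value(c(-5, 1), c(25, 1), specs, ranges),
               0.5)  # clipped continuous part 0, nominal 1
  # degenerate range contributes similarity 1
  r0 <- rbind(c(5, 0), c(5, 1))
  expect_equal(clinical_kernel_value(c(5, 0), c(5, 1), specs, r0), 0.5)
  expect_error(clinical_kernel_value(c(NA, 1), c(4, 1), specs, ranges),
               "complete")
})

test_that("combined kernel matrices are symmetric, unit-diagonal and PSD", {
  set.seed(41)
  specs <- tiny_specs()
  for (i in 1:10) {
    n <- 5
    tr <- cbind(stats::rnorm(n, 10, 3), stats::rnorm(n, 100, 20),
                stats::rbinom(n, 1, 0.5), stats::rpois(n, 2))
    colnames(tr) <- specs$name
    te <- tr[1:2, , drop = FALSE]
    K <- combined_kernel_matrix(tr, te, specs)
    expect_equal(K$train, t(K$train), tolerance = 1e-12)
    expect_equal(unname(diag(K$train)), rep(1, n), tolerance = 1e-12)
    ev <- eigen(K$train, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("clinical_only combination reduces to pairwise kernel values", {
  set.seed(43)
  specs <- clinical_only_specs()
  tr <- cbind(stats::rbinom(6, 1, 0.5), stats::rpois(6, 2))
  colnames(tr) <- specs$name
  K <- combined_kernel_matrix(tr, tr, specs,
                              kernel_spec("clinical_only"))
  ranges <- rbind(apply(tr, 2, min), apply(tr, 2, max))
  for (i in 1:6) for (j in 1:6)
    expect_equal(K$train[i, j],
                 clinical_kernel_value(tr[i, ], tr[j, ], specs, ranges))
})

test_that("zero-variance cytokine features are excluded with a warning", {
  specs <- tiny_specs()
  tr <- cbind(rep(3, 5), stats::rnorm(5, 100, 5),
              stats::rbinom(5, 1, 0.5), stats::rpois(5, 1))
  colnames(tr) <- specs$name
  expect_warning(K <- combined_kernel_matrix(tr, tr[1:2, ], specs),
                 "zero-variance")
  expect_equal(unname(diag(K$train)), rep(1, 5))
})

test_that("1-NN returns the label of the nearest training instance", {
  specs <- tiny_specs()
  set.seed(47)
  tr <- cbind(stats::rnorm(8, 10, 3), stats::rnorm(8, 100, 20),
              stats::rbinom(8, 1, 0.5), stats::rpois(8, 2))
  colnames(tr) <- specs$name
  y <- c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 1L)
  # a test point identical to a training point takes that point's label
  pred <- train_predict("one_nn", tr, tr[c(3, 6), , drop = FALSE], y,
                        colnames(tr), specs)
  expect_equal(pred, y[c(3, 6)])
  # exact distance ties resolve to the smallest training index
  tr2 <- tr; tr2[5, ] <- tr2[2, ]   # rows 2 and 5 identical, labels differ
  y2 <- y; y2[5] <- 1L
  pred2 <- train_predict("one_nn", tr2, tr2[2, , drop = FALSE], y2,
                         colnames(tr2), specs)
  expect_equal(pred2, y2[2])
})

test_that("all three classifiers separate a cleanly separable cohort", {
  co <- separable_cohort()
  y <- binarize(co, ige_task())
  tr_idx <- c(1:7, 11:20); te_idx <- setdiff(1:24, tr_idx)
  tr <- co$values[tr_idx, ]; te <- co$values[te_idx, ]
  y_tr <- y[tr_idx]; y_te <- y[te_idx]
  for (cls in c("random_forest", "svm", "one_nn")) {
    pred <- train_predict(cls, tr, te, y_tr, "IL15_PHA_24h_CB",
                          co$specs, seed = 2L)
    expect_equal(bcr(y_te, pred), 1.0)
  }
})

test_that("predictions are deterministic and training-order invariant", {
  co <- separable_cohort(seed = 51)
  # add noise so the signature variables are informative but imperfect
  set.seed(52)
  vals <- co$values
  vals[, 1] <- vals[, 1] + stats::rnorm(24, 0, 4)
  co <- cohort(vals, co$specs, as.character(co$labels))
  y <- binarize(co, ige_task())
  tr_idx <- c(1:7, 11:20); te_idx <- setdiff(1:24, tr_idx)
  tr <- co$values[tr_idx, ]; te <- co$values[te_idx, ]
  y_tr <- y[tr_idx]
  sig <- colnames(tr)[1:2]
  perm <- sample(length(tr_idx))
  for (cls in c("random_forest", "svm", "one_nn")) {
    a <- train_predict(cls, tr, te, y_tr, sig, co$specs, seed = 7L)
    b <- train_predict(cls, tr, te, y_tr, sig, co$specs, seed = 7L)
    expect_identical(a, b)
    c_ <- train_predict(cls, tr[perm, ], te, y_tr[perm], sig, co$specs,
                        seed = 7L)
    expect_identical(c_, a)
  }
  expect_error(train_predict("one_nn", tr, te, rep(1L, length(y_tr)),
                             sig, co$specs), "single class")
})

test_that("BCR averages sensitivity and specificity", {
  expect_equal(bcr(c(TP = 3, FN = 1, TN = 2, FP = 2)), 0.625)
  expect_equal(bcr(c(TP = 5, FN = 0, TN = 7, FP = 0)), 1.0)
  # constant all-positive predictor: Se 1, Sp 0
  truth <- c(1L, 1L, 0L, 0L, 0L)
  expect_equal(bcr(truth, rep(1L, 5)), 0.5)
  # swapping class roles swaps Se and Sp, leaving BCR unchanged
  set.seed(53)
  for (i in 1:10) {
    truth <- stats::rbinom(20, 1, 0.4)
    pred <- stats::rbinom(20, 1, 0.5)
    if (length(unique(truth)) < 2) next
    expect_equal(bcr(truth, pred), bcr(1L - truth, 1L - pred))
  }
  expect_error(bcr(c(TP = 0, FN = 0, TN = 3, FP = 1)), "absent")
  cc <- confusion_counts(c(1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L))
  expect_equal(unname(cc), c(1L, 1L, 1L, 1L))
})
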