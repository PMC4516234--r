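test_that("Nadeau-corrected CI matches the closed form", {
  # all repeats equal: zero-width interval at the common value
  expect_equal(nadeau_ci(rep(0.7, 50), 118, 13), c(0.7, 0.7))
  # frozen hand computation: J = 200, s^2 = 0.01, n_test/n_train = 13/118
  x <- stats::rnorm(200)
  x <- 0.5 + 0.1 * (x - mean(x)) / stats::sd(x)   # mean 0.5, var 0.01
  ci <- nadeau_ci(x, 118, 13)
  half <- stats::qt(0.975, 199) * sqrt((1 / 200 + 13 / 118) * 0.01)
  expect_equal(half, 0.0669, tolerance = 2e-3)
  expect_equal(ci, c(0.5 - half, 0.5 + half), tolerance = 1e-10)
  # random inputs against the closed form, and clipping to [0, 1]
  set.seed(61)
  for (i in 1:20) {
    b <- stats::runif(sample(5:100, 1))
    n1 <- sample(50:200, 1); n2 <- sample(5:40, 1)
    J <- length(b)
    V <- (1 / J + n2 / n1) * stats::var(b)
    lo <- mean(b) - stats::qt(0.975, J - 1) * sqrt(V)
    hi <- mean(b) + stats::qt(0.975, J - 1) * sqrt(V)
    expect_equal(nadeau_ci(b, n1, n2),
                 c(max(0, lo), min(1, hi)), tolerance = 1e-12)
    # at least as wide as the naive t interval
    naive <- stats::qt(0.975, J - 1) * sqrt(stats::var(b) / J)
    expect_gte(hi - mean(b), naive - 1e-12)
  }
  # growing J with the same spread shrinks the interval
  s2 <- 0.01
  w <- function(J) stats::qt(0.975, J - 1) * sqrt((1 / J + 13 / 118) * s2)
  expect_lt(w(400), w(200))
  expect_error(nadeau_ci(0.5, 100, 10), "at least 2")
})

test_that("protocol draws stratified 90/10 splits of the expected size", {
  co <- generate_cohort(synthetic_config(seed = 71L))
  ds <- drop_sparse_features(co)$cohort
  pr <- suppressMessages(run_protocol(ds, protocol_config(
    J = 5L, signature_sizes = 2L, classifiers = "one_nn",
    feature_sets = "cytokines_only", task = ige_task(), seed = 5L)))
  r <- pr$results[[1]]
  expect_true(r$n_test %in% c(13L, 14L))
  expect_equal(r$n_train + r$n_test, 131L)
  expect_true(all(r$bcrs >= 0 & r$bcrs <= 1))
  expect_true(all(lengths(r$signatures) == 2L))
  expect_lte(r$ci_low, r$mean_bcr)
  expect_gte(r$ci_high, r$mean_bcr)
})

test_that("identical configurations reproduce results bit-for-bit", {
  co <- generate_cohort(synthetic_config(seed = 73L))
  ds <- drop_sparse_features(co)$cohort
  cfg <- protocol_config(J = 4L, signature_sizes = c(2L, 4L),
                         classifiers = c("one_nn", "random_forest"),
                         feature_sets = "cytokines_only",
                         task = ige_task(), seed = 99L)
  a <- suppressMessages(run_protocol(ds, cfg))
  b <- suppressMessages(run_protocol(ds, cfg))
  for (k in names(a$results)) {
    expect_identical(a$results[[k]]$bcrs, b$results[[k]]$bcrs)
    expect_identical(a$results[[k]]$signatures, b$results[[k]]$signatures)
  }
})

test_that("adding classifiers or signature sizes never perturbs the splits", {
  co <- generate_cohort(synthetic_config(seed = 73L))
  ds <- drop_sparse_features(co)$cohort
  small <- protocol_config(J = 4L, signature_sizes = 2L,
                           classifiers = "one_nn",
                           feature_sets = "cytokines_only",
                           task = ige_task(), seed = 99L)
  big <- protocol_config(J = 4L, signature_sizes = c(2L, 6L),
                         classifiers = c("one_nn", "svm"),
                         feature_sets = "cytokines_only",
                         task = ige_task(), seed = 99L)
  a <- suppressMessages(run_protocol(ds, small))
  b <- suppressMessages(run_protocol(ds, big))
  k <- "one_nn_s2_cytokines_only"
  expect_identical(a$results[[k]]$bcrs, b$results[[k]]$bcrs)
  expect_identical(a$results[[k]]$signatures, b$results[[k]]$signatures)
})

test_that("signature frequencies saturate when s spans all variables", {
  co <- tiny_cohort()
  vals <- co$values
  vals[is.na(vals)] <- 1   # complete tiny cohort
  co <- cohort(vals, co$specs, as.character(co$labels))
  # duplicate patients so stratified 75/25 splits keep both classes
  big <- cohort(do.call(rbind, lapply(1:6, function(i) {
    m <- vals; rownames(m) <- sprintf("%s_%d", rownames(m), i); m
  })), co$specs, rep(as.character(co$labels), 6))
  pr <- suppressMessages(run_protocol(big, protocol_config(
    J = 6L, train_fraction = 0.75, signature_sizes = 4L,
    classifiers = "one_nn", feature_sets = "all", task = ige_task(),
    seed = 3L)))
  freq <- summarize_signatures(pr$results[[1]])
  expect_equal(nrow(freq), 4L)
  expect_true(all(freq$frequency == 6L))
  # ties in the table are ordered by name
  expect_equal(freq$variable, sort(freq$variable))
})

test_that("select_best maximises mean BCR with deterministic tie-breaks", {
  mk <- function(mean, s, cls, lo = mean - 0.1, hi = mean + 0.1) {
    structure(list(descriptor = list(classifier = cls, s = s,
                                     feature_set = "all", task = "ALLERGY"),
                   bcrs = rep(mean, 3), mean_bcr = mean, ci_low = lo,
                   ci_high = hi, signatures = list(), alpha = 0.05,
                   signature_frequency = table(character(0)),
                   n_train = 10, n_test = 2),
              class = "resampling_result")
  }
  one <- list(a = mk(0.7, 4L, "svm"))
  expect_identical(select_best(one)$descriptor$classifier, "svm")
  two <- list(a = mk(0.7, 8L, "svm"), b = mk(0.7, 4L, "svm"))
  expect_equal(select_best(two)$descriptor$s, 4L)
  three <- list(a = mk(0.6, 4L, "one_nn", 0.5, 0.7),
                b = mk(0.7, 4L, "svm", 0.6, 0.8),
                c = mk(0.2, 4L, "random_forest", 0.1, 0.3))
  best <- select_best(three)
  expect_equal(best$descriptor$classifier, "svm")
  expect_identical(attr(best, "overlapping"), "a")
})

test_that("labels permuted at random give chance-level mean BCR", {
  co <- generate_cohort(synthetic_config(seed = 81L))
  null_co <- permute_labels(co, seed = 82)
  ds <- drop_sparse_features(null_co)$cohort
  pr <- suppressMessages(run_protocol(ds, protocol_config(
    J = 60L, signature_sizes = 4L, classifiers = "one_nn",
    feature_sets = "cytokines_only", task = ige_task(), seed = 83L)))
  r <- pr$results[[1]]
  expect_gt(r$mean_bcr, 0.40)
  expect_lt(r$mean_bcr, 0.60)
})
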