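# Shared fixtures: tiny in-code cohorts and independent oracles.

# a 4-variable spec: two cytokine conditions, one binary and one ordinal
# clinical variable
tiny_specs <- function() {
  rbind(
    data.frame(name = c("IL15_PHA_24h_CB", "TNFalpha_LPS_24h_CB"),
               vtype = "continuous", provenance = "cytokine",
               cytokine = c("IL15", "TNFalpha"),
               stimulation = c("PHA", "LPS"), duration_h = 24L,
               timepoint = "CB", stringsAsFactors = FALSE),
    data.frame(name = c("tobacco_pregnancy", "n_allergic_relatives"),
               vtype = c("binary", "ordinal"), provenance = "clinical",
               cytokine = NA_character_, stimulation = NA_character_,
               duration_h = NA_integer_, timepoint = NA_character_,
               stringsAsFactors = FALSE))
}

# 6 patients, 4 variables, a few missing cells, all three classes
tiny_cohort <- function() {
  m <- matrix(c(5.3, 19.2, 11.0, NA, 8.5, 14.1,
                3100, 6000, NA, 5500, 4800, 5100,
                0, 1, 0, NA, 1, 0,
                2, 0, 1, 3, NA, 1),
              nrow = 6,
              dimnames = list(sprintf("P%03d", 1:6), tiny_specs()$name))
  cohort(m, tiny_specs(),
         c("IGE", "NONALL", "NONALL", "NONIGE_OR_UNCERTAIN", "NONALL",
           "IGE"))
}

# literal Benjamini-Hochberg step-up re-implementation (independent oracle)
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  q <- p[o] * m / seq_along(p)
  for (i in rev(seq_len(length(p) - 1))) q[i] <- min(q[i], q[i + 1])
  out <- numeric(length(p))
  out[o] <- pmin(q, 1)
  out
}

# a perfectly separable cohort: one continuous feature with a clear margin
separable_cohort <- function(n_pos = 10, n_neg = 14, seed = 5) {
  set.seed(seed)
  specs <- tiny_specs()
  n <- n_pos + n_neg
  m <- cbind(c(stats::runif(n_pos, 10, 12), stats::runif(n_neg, 2, 4)),
             stats::rnorm(n, 100, 10),
             stats::rbinom(n, 1, 0.5),
             stats::rpois(n, 1))
  dimnames(m) <- list(sprintf("P%03d", 1:n), specs$name)
  cohort(m, specs, c(rep("IGE", n_pos), rep("NONALL", n_neg)))
}

# relabel a cohort with a seeded permutation of its labels (null cohort)
permute_labels <- function(x, seed = 1) {
  set.seed(seed)
  cohort(x$values, x$specs, sample(as.character(x$labels)))
}

# small synthetic config for fast tests
fast_config <- function(...) synthetic_config(...)
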