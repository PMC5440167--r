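#' Permutation (randomization) tests
#'
#' Monte-Carlo permutation tests: the pooled observations are randomly
#' re-split at the original sample sizes and the statistic recomputed; the
#' two-sided p-value uses the add-one rule
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + n_perm)`, which is never zero.
#'
#' @param x,y Numeric samples (for the correlation test, paired vectors of
#'   equal length; the null permutes `y`).
#' @param n_perm Number of random permutations.
#' @param seed Integer seed.
#' @return A `permutation_result` list: `statistic_observed`, `null_samples`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permutation_test_mean_diff <- function(x, y, n_perm = 10000, seed = 1) {
  if (length(x) < 2 || length(y) < 2) abort("both samples need >= 2 values")
  if (n_perm < 100) warn("fewer than 100 permutations: p-value is coarse")
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  obs <- mean(x) - mean(y)
  tot <- sum(pooled)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      s1 <- sum(pooled[sample.int(n, n1)])
      s1 / n1 - (tot - s1) / (n - n1)
    }, numeric(1))
  })
  new_permutation_result(obs, null, n_perm, seed)
}

#' @rdname permutation_test_mean_diff
#' @export
permutation_test_correlation <- function(x, y, n_perm = 10000, seed = 1) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  if (n_perm < 100) warn("fewer than 100 permutations: p-value is coarse")
  obs <- cor(x, y)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) cor(x, sample(y)), numeric(1))
  })
  new_permutation_result(obs, null, n_perm, seed)
}

new_permutation_result <- function(obs, null, n_perm, seed) {
  p <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm)
  structure(list(statistic_observed = obs, null_samples = null,
                 p_value = p, n_permutations = n_perm, seed = seed),
            class = "permutation_result")
}

#' @exportS3Method base::print
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> statistic = ",
      format(x$statistic_observed, digits = 4), ", p = ",
      format(x$p_value, digits = 4), " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic_observed, p_value = x$p_value,
                 n_permutations = x$n_permutations, seed = x$seed)
}

#' @export
glance.permutation_result <- tidy.permutation_result

#' Holm (step-down Bonferroni) correction
#'
#' Order-preserving adjusted p-values with monotonicity enforcement.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_correction <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

#' Shuffle synapse locations among a PN's connections
#'
#' Randomly re-allocates the pooled synapse locations of one PN to its ORN
#' axons, keeping each axon's synapse count fixed: the per-ORN counts are
#' preserved exactly and the pooled multiset of locations is a permutation of
#' the original. Used (over many repeats) to ask whether the real placement
#' of synapses on the dendrite is more or less variable than unbiased
#' placement.
#'
#' @param sites Site tibble for one PN (must include `orn_id`; all other
#'   columns are treated as the location and permuted as a block).
#' @param seed Integer seed.
#' @return `sites` with locations permuted across rows (`orn_id` fixed).
#' @export
shuffle_synapse_locations <- function(sites, seed = 1) {
  perm <- withr::with_seed(seed, sample.int(nrow(sites)))
  loc_cols <- setdiff(names(sites), c("orn_id", "pn_id", "site_id",
                                      "orn_side"))
  out <- sites
  out[loc_cols] <- sites[perm, loc_cols]
  out
}

#' Equalize synapse counts across axons
#'
#' Re-allocates a pool of synapse locations so that the axons have counts as
#' equal as possible: each axon receives `floor(N/k)` or `floor(N/k) + 1`
#' sites (remainders randomly assigned), drawn without replacement from the
#' pool. Intended to be re-drawn independently on every trial.
#'
#' @param sites Site tibble (the pool; `orn_id` column is replaced).
#' @param axon_ids Identifiers of the `k` axons to allocate to (defaults to
#'   the distinct `orn_id`s present).
#' @param seed Integer seed.
#' @return `sites` with a new `orn_id` assignment; locations untouched.
#' @export
equalize_synapse_counts <- function(sites, axon_ids = NULL, seed = 1) {
  axon_ids <- axon_ids %||% unique(sites$orn_id)
  n <- nrow(sites)
  k <- length(axon_ids)
  if (k > n) abort("more axons than synapse sites: cannot equalize")
  withr::with_seed(seed, {
    base <- n %/% k
    extra <- n %% k
    counts <- rep(base, k) + as.integer(seq_len(k) %in% sample.int(k, extra))
    assignment <- sample(rep(axon_ids, counts))
  })
  out <- sites
  out$orn_id <- assignment
  out
}
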