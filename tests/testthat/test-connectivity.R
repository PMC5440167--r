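toy_table <- function() {
  counts <- matrix(c(10L, 20L, 5L, 40L), 2, 2,
                   dimnames = list(c("ORN_L_01", "ORN_R_01"),
                                   c("PN_L_1", "PN_R_1")))
  connectivity_table(counts)
}

test_that("connectivity tables validate their cells and round-trip via CSV", {
  tb <- toy_table()
  expect_equal(connection_stats(tb)$n_connections, 4)
  expect_error(
    connectivity_table(matrix(c(-1L, 1L, 1L, 1L), 2, 2,
                              dimnames = list(c("ORN_L_01", "ORN_R_01"),
                                              c("PN_L_1", "PN_R_1")))),
    "non-negative")
  expect_error(
    connectivity_table(matrix(c(0.5, 1, 1, 1), 2, 2,
                              dimnames = list(c("ORN_L_01", "ORN_R_01"),
                                              c("PN_L_1", "PN_R_1")))),
    "integer")
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity(tb, path)
  tb2 <- load_connectivity(path)
  expect_identical(tb2$counts, tb$counts)
  expect_identical(tb2$orn_side, tb$orn_side)
})

test_that("connection stats aggregate over connected pairs only", {
  uniform <- connectivity_table(
    matrix(5L, 3, 3, dimnames = list(paste0("ORN_L_0", 1:3),
                                     paste0("PN_L_", 1:3))))
  cs <- connection_stats(uniform)
  expect_equal(cs$n_connections, 9)
  expect_equal(cs$mean_synapses, 5)
  # a zero cell is excluded from the mean
  m <- matrix(c(0L, 6L, 6L, 6L), 2, 2,
              dimnames = list(paste0("ORN_L_0", 1:2), paste0("PN_L_", 1:2)))
  cs2 <- connection_stats(connectivity_table(m))
  expect_equal(cs2$n_connections, 3)
  expect_equal(cs2$mean_synapses, 6)
  # mean x n_connections recovers the total synapse count
  tb <- generate_circuit(circuit_spec(seed = 2))
  cs3 <- connection_stats(tb)
  expect_equal(cs3$mean_synapses * cs3$n_connections, cs3$total_synapses)
})

test_that("normalized contributions reproduce the worked percentage", {
  # a PN receiving 893 synapses from its antenna, one ORN giving 34 of them
  counts <- matrix(c(34L, 859L), 2, 1,
                   dimnames = list(c("ORN_R_01", "ORN_R_02"), "PN_R_1"))
  tb <- connectivity_table(counts)
  contrib <- normalized_contributions(tb, pool = "per_antenna")
  expect_equal(contrib$pct[contrib$orn_id == "ORN_R_01"], 3.81,
               tolerance = 1e-3)
  # single-ORN pool is 100%
  single <- connectivity_table(matrix(12L, 1, 1,
                                      dimnames = list("ORN_L_01", "PN_L_1")))
  expect_equal(normalized_contributions(single)$pct, 100)
})

test_that("contributions sum to 100 within every pool", {
  tb <- generate_circuit(circuit_spec(seed = 11))
  for (pool in c("ipsilateral", "per_antenna")) {
    contrib <- normalized_contributions(tb, pool)
    sums <- dplyr::summarise(
      dplyr::group_by(contrib, .data$pn_id, .data$antenna),
      s = sum(.data$pct), .groups = "drop")
    if (pool == "ipsilateral") {
      expect_true(all(abs(sums$s - 100) < 1e-9))
    } else {
      expect_true(all(abs(sums$s - 100) < 1e-9))
    }
  }
})

test_that("contribution CV matches a hand-computed case and degenerate limits", {
  # values {1, 2, 3}: sample SD 1, mean 2 -> CV 0.5
  counts <- matrix(c(1L, 2L, 3L), 3, 1,
                   dimnames = list(paste0("ORN_L_0", 1:3), "PN_L_1"))
  expect_equal(contribution_cv(connectivity_table(counts)), 0.5)
  equal <- matrix(7L, 4, 1,
                  dimnames = list(paste0("ORN_L_0", 1:4), "PN_L_1"))
  expect_equal(contribution_cv(connectivity_table(equal)), 0)
})

test_that("ipsi/contra comparison recovers constructed surpluses", {
  sym <- connectivity_table(
    matrix(10L, 2, 2, dimnames = list(c("ORN_L_01", "ORN_R_01"),
                                      c("PN_L_1", "PN_R_1"))))
  expect_equal(ipsi_contra_comparison(sym)$surplus_pct_grand, 0)
  doubled <- connectivity_table(
    matrix(c(20L, 10L, 10L, 20L), 2, 2,
           dimnames = list(c("ORN_L_01", "ORN_R_01"),
                           c("PN_L_1", "PN_R_1"))))
  expect_equal(ipsi_contra_comparison(doubled)$surplus_pct_grand, 100)
  # scale invariance
  tb <- generate_circuit(circuit_spec(seed = 3))
  scaled <- connectivity_table(tb$counts * 3L, tb$orn_side, tb$pn_side,
                               tb$orn_bilateral)
  expect_equal(ipsi_contra_comparison(scaled)$surplus_pct_grand,
               ipsi_contra_comparison(tb)$surplus_pct_grand,
               tolerance = 1e-12)
})

test_that("left-right totals and densities follow their definitions", {
  tb <- toy_table()
  lr <- left_right_totals(tb)
  expect_equal(lr$per_pn$total_synapses, c(30, 45))
  expect_equal(lr$right_vs_left_pct, 50)
  sym <- connectivity_table(
    matrix(10L, 2, 2, dimnames = list(c("ORN_L_01", "ORN_R_01"),
                                      c("PN_L_1", "PN_R_1"))))
  expect_equal(left_right_totals(sym)$right_vs_left_pct, 0)
  lr2 <- left_right_totals(tb, path_lengths = c(PN_L_1 = 10, PN_R_1 = 45))
  expect_equal(lr2$per_pn$density_per_um, c(3, 1))
})

test_that("proportional PN columns give r = 1; tiny antennae are rejected", {
  counts <- cbind(PN_L_1 = c(10L, 20L, 30L, 5L, 10L, 20L),
                  PN_L_2 = c(20L, 40L, 60L, 10L, 20L, 40L))
  rownames(counts) <- c(paste0("ORN_L_0", 1:3), paste0("ORN_R_0", 1:3))
  tb <- connectivity_table(counts)
  rs <- cross_pn_weight_correlations(tb, n_perm = 200, seed = 1)
  expect_true(all(abs(rs$r - 1) < 1e-9))
  tiny <- connectivity_table(counts[c(1, 2, 4, 5), ])
  expect_error(cross_pn_weight_correlations(tiny), "fewer than 3")
})

test_that("constant contribution vectors are flagged as degenerate", {
  counts <- cbind(PN_L_1 = c(10L, 10L, 10L, 10L, 10L, 10L),
                  PN_L_2 = c(5L, 20L, 15L, 40L, 25L, 10L))
  rownames(counts) <- c(paste0("ORN_L_0", 1:3), paste0("ORN_R_0", 1:3))
  tb <- connectivity_table(counts)
  rs <- cross_pn_weight_correlations(tb, n_perm = 100, seed = 1)
  expect_true(all(is.na(rs$r)))
})
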