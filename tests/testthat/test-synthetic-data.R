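test_that("morphology generator hits the target length deterministically", {
  spec <- morphology_spec(target_path_length = 1000, seed = 1)
  m <- generate_morphology(spec)
  expect_gte(total_path_length(m), 950)
  expect_lte(total_path_length(m), 1050)
  expect_true(all(m$radius > 0))
  # same spec, same seed -> identical node tables
  m2 <- generate_morphology(spec)
  expect_identical(as.data.frame(m), as.data.frame(m2))
  # different seed -> different geometry
  m3 <- generate_morphology(morphology_spec(target_path_length = 1000,
                                            seed = 2))
  expect_false(identical(m$x, m3$x))
})

test_that("radii never increase away from the soma", {
  m <- generate_morphology(morphology_spec(seed = 4))
  pidx <- match(m$parent_id, m$id)
  neurite <- which(!is.na(pidx) & m$label == 3 & m$label[pidx] == 3)
  expect_true(all(m$radius[neurite] <= m$radius[pidx[neurite]] + 1e-12))
})

test_that("zero branch rate gives one unbranched cable of the target length", {
  m <- generate_morphology(morphology_spec(target_path_length = 1000,
                                           branch_rate = 0, seed = 1))
  cab <- inflate(m)
  expect_equal(nrow(cab), 1)
  expect_equal(cab$length, 1000, tolerance = 1e-6)
})

test_that("an aggressive taper makes the target length unreachable, loudly", {
  expect_error(
    generate_morphology(morphology_spec(target_path_length = 50000,
                                        branch_rate = 0.5,
                                        radius_root = 0.1,
                                        radius_taper = 0.5, seed = 1)),
    "unreachable")
})

test_that("default circuit has the DM6 shape: 53x5 with 260 connections", {
  tb <- generate_circuit(circuit_spec(seed = 7))
  expect_equal(dim(tb$counts), c(53, 5))
  expect_equal(sum(tb$counts > 0), 260)
  expect_equal(sum(!tb$orn_bilateral), 2)
  # unilateral ORNs connect only on their home side
  uni <- which(!tb$orn_bilateral)
  for (u in uni) {
    contra <- tb$pn_side != tb$orn_side[u]
    expect_true(all(tb$counts[u, contra] == 0))
    expect_true(all(tb$counts[u, !contra] > 0))
  }
  # determinism
  expect_identical(generate_circuit(circuit_spec(seed = 7))$counts, tb$counts)
})

test_that("degenerate homogeneous circuit yields equal counts within rounding", {
  tb <- generate_circuit(circuit_spec(ipsi_contra_ratio = 1,
                                      side_factor_sd = 0,
                                      connection_cv = 0,
                                      unilateral_orns_per_side = 0,
                                      pn_size_mode = "equal", seed = 1))
  expect_lte(diff(range(tb$counts)), 1)
})

test_that("infeasible CV below the latent-factor floor fails explicitly", {
  expect_error(generate_circuit(circuit_spec(connection_cv = 0.05,
                                             side_factor_sd = 0.3)),
               "infeasible")
})

test_that("generator calibration is recovered over many seeds", {
  stats <- purrr::map_dfr(1:100, function(s) {
    tb <- generate_circuit(circuit_spec(seed = s))
    cs <- connection_stats(tb)
    tibble::tibble(
      ipsi_mean = cs$mean_synapses_ipsi,
      ratio = cs$mean_synapses_ipsi / cs$mean_synapses_contra,
      cv = contribution_cv(tb)
    )
  })
  expect_lt(abs(mean(stats$ipsi_mean) / 26.3 - 1), 0.05)
  expect_lt(abs(mean(stats$ratio) / 1.35 - 1), 0.05)
  expect_lt(abs(mean(stats$cv) / 0.31 - 1), 0.05)
})

test_that("wiring noise is shared within a side but not across the midline", {
  rs <- purrr::map_dfr(1:25, function(s) {
    tb <- generate_circuit(circuit_spec(seed = s))
    cross_pn_weight_correlations(tb, n_perm = 200, seed = s)
  })
  same <- rs$r[rs$same_side]
  opp <- rs$r[!rs$same_side]
  expect_gt(median(same), 0.3)
  expect_lt(abs(median(opp)), 0.15)
})

test_that("synapse placement is uniform per unit path length", {
  # two-branch tree with arm lengths 300 and 700 um
  arm1 <- 300
  arm2 <- 700
  m <- morphology(tibble::tibble(
    id = 1:3, parent_id = c(-1L, 1L, 1L),
    x = c(0, arm1, -arm2), y = 0, z = 0, radius = 0.5, label = 3L))
  counts <- matrix(10000L, 1, 1,
                   dimnames = list("ORN_L_01", "PN_L_1"))
  tb <- connectivity_table(counts, orn_side = "L", pn_side = "L")
  sites <- place_synapses(m, tb, "PN_L_1", seed = 3)
  expect_equal(nrow(sites), 10000)
  on_arm1 <- mean(sites$child_node_id == 2)
  expect_lt(abs(on_arm1 - 0.3), 0.02)
  # determinism
  sites2 <- place_synapses(m, tb, "PN_L_1", seed = 3)
  expect_identical(sites, sites2)
  # exact per-connection counts
  small <- connectivity_table(matrix(10L, 1, 1,
                                     dimnames = list("ORN_L_01", "PN_L_1")),
                              orn_side = "L", pn_side = "L")
  expect_equal(nrow(place_synapses(m, small, "PN_L_1", seed = 1)), 10)
  expect_error(place_synapses(m, tb, "PN_X", seed = 1), "not present")
})

test_that("bound sites land in the compartment containing their position", {
  fx <- pn_fixture()
  expect_true(all(fx$sites$compartment >= 1 &
                  fx$sites$compartment <= nrow(fx$model$compartments)))
  # spot-check the arc-length bookkeeping
  cmp <- fx$model$compartments
  for (i in c(1, 50, 200)) {
    s <- fx$sites[i, ]
    rng <- fx$model$comp_range[[s$cable_id]]
    expect_gte(s$pos_um, (s$compartment - rng$comp0) * rng$clen - 1e-9)
    expect_lte(s$pos_um, (s$compartment - rng$comp0 + 1) * rng$clen + 1e-9)
  }
})

test_that("synapse size generator obeys the 1/sqrt(n) averaging law", {
  geom <- generate_synapse_sizes(400, 25, cv_syn = 0.5, seed = 2)
  st <- synapse_size_stats(geom)
  expect_lt(abs(st$cv_volume_synapse / 0.5 - 1), 0.1)
  expect_lt(abs(st$cv_volume_connection / 0.1 - 1), 0.2)
  expect_gt(st$r_volume_area, 0.3)   # positive coupling by construction

  # zero CV -> identical sizes
  g0 <- generate_synapse_sizes(10, 5, cv_syn = 0, seed = 1)
  expect_equal(sd(g0$tbar_volume_nm3), 0)

  # uncorrelated volumes and areas
  gu <- generate_synapse_sizes(40, 25, cv_syn = 0.5, rho = 0, seed = 3)
  expect_lt(abs(cor(gu$tbar_volume_nm3, gu$contact_area_nm2)), 0.1)
  expect_error(generate_synapse_sizes(10, 5, cv_syn = -1), "cv_syn")
})

test_that("synapse size is uncorrelated with synapse count by default", {
  n_syn <- withr::with_seed(9, sample(10:40, 100, replace = TRUE))
  geom <- generate_synapse_sizes(100, n_syn, cv_syn = 0.5, seed = 4)
  st <- synapse_size_stats(geom)
  expect_lt(abs(st$r_size_count), 0.2)
})
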