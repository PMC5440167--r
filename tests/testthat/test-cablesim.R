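test_that("conductance waveform peaks at the analytic time with exact normalization", {
  p <- synapse_params(g_max = 0.1, tau_rise = 0.2, tau_decay = 1.1)
  t_star <- conductance_peak_time(p)
  expect_equal(t_star, 0.417, tolerance = 1e-3)
  expect_equal(conductance_waveform(0, p), 0)
  expect_equal(conductance_waveform(t_star, p), p$g_max, tolerance = 1e-12)
  # peak really is the maximum
  tt <- seq(0, 10, by = 1e-3)
  expect_lte(max(conductance_waveform(tt, p)), p$g_max + 1e-12)
  # zero conductance stays zero
  expect_true(all(conductance_waveform(tt, synapse_params(g_max = 0)) == 0))
  # alpha-function limit at equal time constants
  pa <- synapse_params(tau_rise = 0.5, tau_decay = 0.5)
  expect_equal(conductance_waveform(0.5, pa), pa$g_max)
  expect_equal(conductance_peak_time(pa), 0.5)
})

test_that("no synaptic events leaves the membrane at rest", {
  mod <- cylinder_model(100)
  tr <- simulate_epsp(mod, events = NULL, duration = 10)
  expect_true(all(abs(tr[[2]] - (-60)) < 1e-9))
})

test_that("an isopotential compartment relaxes with tau = R_m C_m", {
  mod <- cylinder_model(5, diameter_um = 1, max_elec_length = 0.2)
  expect_equal(nrow(mod$compartments), 1)
  tr <- simulate_epsp(mod, events = NULL, duration = 200, dt = 0.01,
                      i_inj = 0.001)
  # fit the relaxation time constant from the charging curve
  dep <- tr[[2]] - (-60)
  v_inf <- dep[length(dep)]
  sel <- tr$time > 1 & dep < 0.9 * v_inf
  tau_fit <- -1 / coef(lm(log(1 - dep[sel] / v_inf) ~ tr$time[sel]))[2]
  expect_equal(unname(tau_fit), 20.8 * 0.8, tolerance = 0.01)   # 16.64 ms
})

test_that("halving dt changes the peak by <0.2% (time-step convergence)", {
  fx <- pn_fixture()
  site <- fx$sites$compartment[10]
  ev <- tibble::tibble(compartment = site, onset = 1)
  p1 <- glomsim:::trace_peak(simulate_epsp(fx$model, ev, duration = 30,
                                           dt = 0.025))
  p2 <- glomsim:::trace_peak(simulate_epsp(fx$model, ev, duration = 30,
                                           dt = 0.0125))
  expect_lt(abs(p1 / p2 - 1), 0.002)
})

test_that("the tree solver matches an independent dense ODE solver", {
  skip_if_not_installed("deSolve")
  mod <- cylinder_model(200, diameter_um = 1, max_elec_length = 0.25)
  n <- nrow(mod$compartments)
  expect_lte(n, 50)
  syn <- synapse_params()
  site <- n   # distal compartment
  ev <- tibble::tibble(compartment = site, onset = 0.5)

  # independent reference: stiff ODE solver on the identical system
  parent <- mod$compartments$parent
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (parent[i] > 0) {
      A[i, parent[i]] <- A[i, parent[i]] + mod$g_ax_uS[i]
      A[i, i] <- A[i, i] - mod$g_ax_uS[i]
      A[parent[i], i] <- A[parent[i], i] + mod$g_ax_uS[i]
      A[parent[i], parent[i]] <- A[parent[i], parent[i]] - mod$g_ax_uS[i]
    }
  }
  rhs <- function(t, v, parms) {
    g <- conductance_waveform(t - 0.5, syn) * 1e-3
    dv <- (A %*% v - mod$g_leak_uS * (v + 60)) / mod$cap_nF
    dv[site] <- dv[site] + g * (0 - v[site]) / mod$cap_nF[site]
    list(as.vector(dv))
  }
  times <- seq(0, 20, by = 0.01)
  ref <- deSolve::lsoda(rep(-60, n), times, rhs, NULL,
                        rtol = 1e-8, atol = 1e-10)
  ref_peak <- max(ref[, 2]) + 60

  tr <- simulate_epsp(mod, ev, syn, duration = 20, dt = 0.005, record_at = 1)
  expect_equal(glomsim:::trace_peak(tr), ref_peak, tolerance = 0.005)
})

test_that("sealed-cylinder input resistance matches the Rall closed form", {
  mb <- membrane_params()
  d_um <- 1
  for (L_elec in c(0.5, 1, 2)) {
    len <- L_elec * glomsim:::lambda_um(d_um, mb)
    mod <- cylinder_model(len, diameter_um = d_um, max_elec_length = 0.01)
    r_inf_mohm <- (2 / pi) * sqrt((mb$r_m * 1000) * mb$r_a) *
      (d_um * 1e-4)^(-3 / 2) / 1e6
    expect_equal(input_resistance(mod, 1), r_inf_mohm / tanh(L_elec),
                 tolerance = 0.01)
  }
})

test_that("input resistance decreases with diameter and rises toward the tip", {
  r_thin <- input_resistance(cylinder_model(200, diameter_um = 0.5), 1)
  r_thick <- input_resistance(cylinder_model(200, diameter_um = 2), 1)
  expect_gt(r_thin, r_thick)
  mod <- cylinder_model(400, diameter_um = 1)
  n <- nrow(mod$compartments)
  expect_gte(input_resistance(mod, n), input_resistance(mod, n %/% 2))
})

test_that("transfer resistance is reciprocal on a branched tree", {
  fx <- pn_fixture()
  n <- nrow(fx$model$compartments)
  pairs <- list(c(1, n), c(5, n %/% 2), c(10, n - 3))
  for (pr in pairs) {
    expect_equal(transfer_resistance(fx$model, pr[1], pr[2]),
                 transfer_resistance(fx$model, pr[2], pr[1]),
                 tolerance = 1e-3)
  }
})

test_that("time-averaged voltage behaves like a mean over the window", {
  mod <- cylinder_model(100)
  tr <- simulate_epsp(mod, events = NULL, duration = 10)
  expect_equal(time_averaged_voltage(tr, c(0, 10)), 0)
  # synthetic rectangular depolarization: additive and length-weighted
  fake <- tr
  fake[[2]] <- ifelse(fake$time <= 5, -59, -60)
  mu_full <- time_averaged_voltage(fake, c(0, 10))
  expect_equal(mu_full, 0.5, tolerance = 0.01)
  mu_a <- time_averaged_voltage(fake, c(0, 5))
  mu_b <- time_averaged_voltage(fake, c(5, 10))
  expect_equal((mu_a + mu_b) / 2, mu_full, tolerance = 0.01)
  expect_error(time_averaged_voltage(tr, c(50, 60)), "window")
})

test_that("mEPSP amplitudes attenuate from dendrite to soma", {
  fx <- pn_fixture()
  sites <- fx$sites[1:12, ]
  m <- measure_mepsps(fx$model, sites)
  expect_true(all(m$somatic_mv > 0))
  expect_true(all(m$dendritic_mv > 0))
  expect_true(all(m$attenuation > 0 & m$attenuation <= 1 + 1e-9))
  # a synapse on the soma compartment attenuates by definition not at all
  soma_site <- tibble::tibble(site_id = 1L, compartment = fx$model$soma_index)
  ms <- measure_mepsps(fx$model, soma_site)
  expect_equal(ms$attenuation, 1, tolerance = 1e-9)
})

test_that("somatic mEPSPs weakly decrease as the synapse moves distally", {
  mod <- cylinder_model(600, diameter_um = 1)
  n <- nrow(mod$compartments)
  comps <- unique(round(seq(1, n, length.out = 8)))
  amp <- measure_mepsps(mod, tibble::tibble(compartment = comps))$somatic_mv
  expect_true(all(diff(amp) <= 1e-9))
})

test_that("uEPSP is sublinear and efficacy behaves in its limits", {
  fx <- pn_fixture()
  one_orn <- fx$sites[fx$sites$orn_id == "ORN_L_02", ]
  expect_gt(nrow(one_orn), 3)
  m <- measure_mepsps(fx$model, one_orn)
  ue <- measure_uepsp(fx$model, one_orn)
  expect_lte(ue, sum(m$somatic_mv) + 1e-9)

  # single-synapse connection: uEPSP equals the mEPSP, efficacy exactly 1
  single <- one_orn[1, ]
  expect_equal(measure_uepsp(fx$model, single),
               measure_mepsps(fx$model, single)$somatic_mv, tolerance = 1e-9)
  expect_equal(summation_efficacy(fx$model, single), 1, tolerance = 1e-9)

  # linear limit: with co-located synapses (no temporal dispersion of the
  # somatic waveforms), efficacy -> 1 as g_max -> 0
  co <- tibble::tibble(compartment = rep(one_orn$compartment[1], 10))
  eff_small <- summation_efficacy(fx$model, co, synapse_params(g_max = 1e-3))
  expect_lt(abs(eff_small - 1), 0.01)
  expect_lt(summation_efficacy(fx$model, co), eff_small)
  eff_default <- summation_efficacy(fx$model, one_orn)
  expect_true(eff_default > 0 && eff_default <= 1)
})

test_that("co-located synapses sum less efficiently than dispersed ones", {
  fx <- pn_fixture()
  n <- nrow(fx$model$compartments)
  distal <- tibble::tibble(compartment = rep(n, 15))
  spread <- tibble::tibble(
    compartment = withr::with_seed(2, sample(2:n, 15)))
  expect_lt(summation_efficacy(fx$model, distal),
            summation_efficacy(fx$model, spread))
})
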