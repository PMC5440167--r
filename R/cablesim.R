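#' Synaptic conductance parameters
#'
#' A single ORN release event opens a conductance shaped as a difference of
#' two exponentials with rise time constant 0.2 ms and decay time constant
#' 1.1 ms, normalized so the peak equals `g_max`. The default peak conductance
#' is 0.1 nS, which yields unitary EPSPs of realistic size (~5 mV) in
#' calibrated models; the equalized-wiring protocol uses 0.0958 nS. The
#' synaptic reversal potential of 0 mV reflects the cholinergic ORN synapse.
#'
#' @param g_max Peak conductance, nS.
#' @param tau_rise,tau_decay Rise and decay time constants, ms.
#' @param e_syn Synaptic reversal potential, mV.
#' @return A `synapse_params` list.
#' @export
synapse_params <- function(g_max = 0.1, tau_rise = 0.2, tau_decay = 1.1,
                           e_syn = 0) {
  if (g_max < 0) abort("g_max must be non-negative")
  if (!(tau_decay >= tau_rise && tau_rise > 0)) {
    abort("need tau_decay >= tau_rise > 0")
  }
  structure(list(g_max = g_max, tau_rise = tau_rise, tau_decay = tau_decay,
                 e_syn = e_syn),
            class = "synapse_params")
}

#' Synaptic conductance waveform
#'
#' `g(t) = g_max * N * (exp(-t/tau_decay) - exp(-t/tau_rise))` with `N` chosen
#' so the peak equals `g_max`; `g(0) = 0`. When the two time constants
#' coincide the difference degenerates and the alpha-function limit
#' `g_max * (t/tau) * exp(1 - t/tau)` is used.
#'
#' @param t Time since event onset, ms (vectorized; negative times give 0).
#' @param p A [synapse_params()].
#' @return Conductance in nS.
#' @export
conductance_waveform <- function(t, p) {
  g <- numeric(length(t))
  pos <- t >= 0
  tr <- p$tau_rise
  td <- p$tau_decay
  if (tr == td) {
    g[pos] <- p$g_max * (t[pos] / tr) * exp(1 - t[pos] / tr)
  } else {
    t_peak <- tr * td / (td - tr) * log(td / tr)
    norm <- 1 / (exp(-t_peak / td) - exp(-t_peak / tr))
    g[pos] <- p$g_max * norm * (exp(-t[pos] / td) - exp(-t[pos] / tr))
  }
  g
}

#' Time of the conductance peak
#'
#' Closed form `t* = tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`
#' (equal time constants give `t* = tau`).
#'
#' @param p A [synapse_params()].
#' @return Peak time in ms.
#' @export
conductance_peak_time <- function(p) {
  if (p$tau_rise == p$tau_decay) return(p$tau_rise)
  p$tau_rise * p$tau_decay / (p$tau_decay - p$tau_rise) *
    log(p$tau_decay / p$tau_rise)
}

#' Simulate passive voltage responses on the compartment tree
#'
#' Integrates the passive cable equation
#' `C dV/dt = -(V - E_rest)/R_mem + axial coupling + sum_i g_i(t) (E_syn - V)`
#' with backward Euler and tree-ordered (Hines) elimination: unconditionally
#' stable at linear cost per step. Synaptic conductances are injected as true
#' conductances (driving force follows the local voltage), evaluated at the
#' start of each step.
#'
#' @param model A `compartmental_model` from [remesh()].
#' @param events Data frame of synaptic events with columns `compartment`
#'   (index) and `onset` (ms); may be empty.
#' @param syn A [synapse_params()].
#' @param duration Simulation length, ms.
#' @param dt Time step, ms (default 0.025 ms).
#' @param record_at Compartment indices to record (default: soma).
#' @param i_inj Optional constant injected current (nA): either a single value
#'   applied at the soma, or a vector over all compartments.
#' @return A `voltage_trace` tibble: `time` (ms) plus one `v_<index>` column
#'   per recorded compartment (mV), with the resting potential as an
#'   attribute.
#' @export
simulate_epsp <- function(model, events = NULL, syn = synapse_params(),
                          duration = 50, dt = 0.025, record_at = NULL,
                          i_inj = NULL) {
  if (dt <= 0) abort("dt must be positive")
  n <- nrow(model$compartments)
  record_at <- record_at %||% model$soma_index
  if (any(record_at < 1 | record_at > n)) abort("record_at out of range")
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble::tibble(compartment = integer(0), onset = numeric(0))
  }
  if (any(events$compartment < 1 | events$compartment > n)) {
    abort("synaptic event bound to an invalid compartment")
  }
  n_steps <- as.integer(ceiling(duration / dt))
  # waveform sampled on the dt grid; truncate where it has decayed to nothing
  wt <- seq(0, by = dt, length.out = n_steps + 1)
  wave_nS <- conductance_waveform(wt, syn)
  keep <- max(which(wave_nS > syn$g_max * 1e-9), 1L)
  wave_uS <- wave_nS[seq_len(min(keep + 2L, length(wave_nS)))] * 1e-3

  inj <- numeric(n)
  if (!is.null(i_inj)) {
    if (length(i_inj) == 1) inj[model$soma_index] <- i_inj else inj <- i_inj
  }
  vm <- hines_simulate(
    parent = as.integer(model$compartments$parent - 1L),
    cap = model$cap_nF,
    g_leak = model$g_leak_uS,
    g_ax = model$g_ax_uS,
    e_rest = model$membrane$e_rest,
    e_syn = syn$e_syn,
    syn_comp = as.integer(events$compartment - 1L),
    syn_onset = as.numeric(events$onset),
    wave = wave_uS,
    dt = dt,
    n_steps = n_steps,
    record = as.integer(record_at - 1L),
    i_inj = inj
  )
  out <- tibble::as_tibble(setNames(as.data.frame(vm),
                                    paste0("v_", record_at)))
  out <- dplyr::mutate(out, time = seq(0, by = dt, length.out = n_steps + 1),
                       .before = 1)
  structure(out, class = c("voltage_trace", class(out)),
            e_rest = model$membrane$e_rest, record_at = record_at, dt = dt)
}

# Peak depolarization (mV above rest) of one recorded column.
trace_peak <- function(trace, compartment = NULL) {
  col <- if (is.null(compartment)) 2L else which(names(trace) == paste0("v_", compartment))
  max(trace[[col]]) - attr(trace, "e_rest")
}

#' Time-averaged depolarization of a voltage trace
#'
#' Mean of `V - E_rest` over a time window, the scalar read out by the
#' classification tasks.
#'
#' @param trace A `voltage_trace`.
#' @param window Length-2 numeric, window in ms.
#' @param compartment Which recorded compartment (default: first recorded).
#' @return Mean depolarization in mV.
#' @export
time_averaged_voltage <- function(trace, window, compartment = NULL) {
  sel <- trace$time >= window[1] & trace$time <= window[2]
  if (!any(sel)) abort("window does not overlap the trace")
  col <- if (is.null(compartment)) 2L else which(names(trace) == paste0("v_", compartment))
  mean(trace[[col]][sel]) - attr(trace, "e_rest")
}

# Steady-state voltages under constant injected currents (nA), all
# compartments.
steady_state_voltage <- function(model, i_inj) {
  hines_steady_state(
    parent = as.integer(model$compartments$parent - 1L),
    g_leak = model$g_leak_uS,
    g_ax = model$g_ax_uS,
    e_rest = model$membrane$e_rest,
    i_inj = i_inj
  )
}

#' Input resistance at a compartment
#'
#' Steady-state voltage deflection per unit injected current at the same
#' compartment (mV / nA = megaohm).
#'
#' @param model A `compartmental_model`.
#' @param compartment Compartment index.
#' @return Input resistance in megaohms.
#' @export
input_resistance <- function(model, compartment) {
  n <- nrow(model$compartments)
  if (any(compartment < 1 | compartment > n)) abort("invalid compartment")
  vapply(compartment, function(cc) {
    inj <- numeric(n)
    inj[cc] <- 0.01
    v <- steady_state_voltage(model, inj)
    (v[cc] - model$membrane$e_rest) / 0.01
  }, numeric(1))
}

#' Transfer resistance between two compartments
#'
#' Steady-state voltage at `j` per unit current injected at `i` (megaohm).
#' For a passive tree this is symmetric in `i` and `j` (reciprocity).
#'
#' @param model A `compartmental_model`.
#' @param i,j Compartment indices.
#' @export
transfer_resistance <- function(model, i, j) {
  n <- nrow(model$compartments)
  inj <- numeric(n)
  inj[i] <- 0.01
  v <- steady_state_voltage(model, inj)
  (v[j] - model$membrane$e_rest) / 0.01
}

#' Input resistance at every cable's midpoint
#'
#' The per-cable input-resistance summary used for left-right comparisons of
#' dendritic excitability: one value per cable, measured at the compartment
#' containing the cable's midpoint.
#'
#' @param model A `compartmental_model`.
#' @return Tibble with `cable_id`, `compartment`, `r_in_mohm`.
#' @export
cable_input_resistance <- function(model) {
  cables <- which(!purrr::map_lgl(model$comp_range, is.null))
  mid <- purrr::map_int(model$comp_range[cables], function(r) {
    as.integer(r$comp0 + floor((r$n - 1) / 2))
  })
  tibble::tibble(
    cable_id = cables,
    compartment = mid,
    r_in_mohm = input_resistance(model, mid)
  )
}
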