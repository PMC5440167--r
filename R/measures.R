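#' Miniature EPSP amplitudes and attenuation per synapse
#'
#' Activates each synapse in isolation (one conductance event per simulation,
#' long enough for the membrane to relax) and measures the peak depolarization
#' at the soma and at the synapse's own compartment. Attenuation is the ratio
#' of somatic to dendritic amplitude, in (0, 1] for a passive tree.
#'
#' @param model A `compartmental_model`.
#' @param sites Data frame of synapse sites with at least a `compartment`
#'   column; extra identifier columns (`site_id`, `orn_id`, ...) are carried
#'   through.
#' @param syn A [synapse_params()].
#' @param duration,dt Simulation length and step, ms.
#' @return Tibble: the identifier columns plus `somatic_mv`, `dendritic_mv`,
#'   `attenuation`.
#' @export
measure_mepsps <- function(model, sites, syn = synapse_params(),
                           duration = 60, dt = 0.025) {
  if (nrow(sites) == 0) abort("sites must be non-empty")
  soma <- model$soma_index
  res <- purrr::map(unique(sites$compartment), function(cc) {
    rec <- unique(c(soma, cc))
    tr <- simulate_epsp(model,
                        events = tibble::tibble(compartment = cc, onset = 0),
                        syn = syn, duration = duration, dt = dt,
                        record_at = rec)
    tibble::tibble(compartment = cc,
                   somatic_mv = trace_peak(tr, soma),
                   dendritic_mv = trace_peak(tr, cc))
  })
  out <- dplyr::left_join(tibble::as_tibble(sites),
                          dplyr::bind_rows(res), by = "compartment")
  dplyr::mutate(out, attenuation = .data$somatic_mv / .data$dendritic_mv)
}

#' Unitary EPSP of one connection
#'
#' Synchronously activates all synapses of a single presynaptic axon and
#' returns the peak somatic depolarization.
#'
#' @inheritParams measure_mepsps
#' @param sites Synapse sites of one connection (one ORN onto this PN).
#' @return Peak somatic depolarization, mV.
#' @export
measure_uepsp <- function(model, sites, syn = synapse_params(),
                          duration = 60, dt = 0.025) {
  if (nrow(sites) == 0) abort("sites must be non-empty")
  tr <- simulate_epsp(model,
                      events = tibble::tibble(compartment = sites$compartment,
                                              onset = 0),
                      syn = syn, duration = duration, dt = dt,
                      record_at = model$soma_index)
  trace_peak(tr, model$soma_index)
}

#' Summation efficacy of a connection
#'
#' Unitary EPSP amplitude divided by the linear sum of the somatic mEPSP
#' amplitudes of the connection's synapses. Equal to 1 for a single synapse
#' and below 1 whenever concurrent conductances interact (local driving-force
#' saturation), approaching 1 in the small-conductance limit.
#'
#' @inheritParams measure_uepsp
#' @return Dimensionless efficacy in (0, 1].
#' @export
summation_efficacy <- function(model, sites, syn = synapse_params(),
                               duration = 60, dt = 0.025) {
  m <- measure_mepsps(model, sites, syn, duration, dt)
  measure_uepsp(model, sites, syn, duration, dt) / sum(m$somatic_mv)
}

#' Per-connection EPSP summary for a PN
#'
#' Groups a PN's synapse sites by presynaptic ORN and measures, per
#' connection, the number of synapses, mean somatic/dendritic mEPSP,
#' uEPSP and summation efficacy.
#'
#' @param model A `compartmental_model`.
#' @param sites Sites for one PN: columns `orn_id`, `compartment`.
#' @param syn A [synapse_params()].
#' @param duration,dt Simulation controls, ms.
#' @return Tibble with one row per connection.
#' @export
measure_connections <- function(model, sites, syn = synapse_params(),
                                duration = 60, dt = 0.025) {
  m <- measure_mepsps(model, sites, syn, duration, dt)
  per_syn <- dplyr::group_by(m, .data$orn_id)
  base <- dplyr::summarise(per_syn,
                           n_synapses = dplyr::n(),
                           mean_mepsp_somatic_mv = mean(.data$somatic_mv),
                           mean_mepsp_dendritic_mv = mean(.data$dendritic_mv),
                           mean_attenuation = mean(.data$attenuation),
                           sum_mepsp_somatic_mv = sum(.data$somatic_mv),
                           .groups = "drop")
  ue <- purrr::map_dbl(base$orn_id, function(o) {
    measure_uepsp(model, sites[sites$orn_id == o, , drop = FALSE], syn,
                  duration, dt)
  })
  dplyr::mutate(base,
                uepsp_mv = ue,
                efficacy = ue / .data$sum_mepsp_somatic_mv,
                sum_mepsp_somatic_mv = NULL)
}
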