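#' Shuffle control for per-connection EPSP consistency
#'
#' Asks whether the consistency of per-connection mean mEPSP amplitudes (and
#' optionally summation efficacy) across a PN's connections is explained by
#' unbiased synapse placement: synapse locations are repeatedly re-allocated
#' at random among the axons (each axon keeping its synapse count, the pooled
#' locations fixed), and the CV of per-connection means is compared between
#' the real and shuffled configurations.
#'
#' Per-site somatic amplitudes depend only on the site's compartment, so the
#' mEPSP part of the control reuses one set of measurements across all
#' shuffles; efficacy requires one unitary simulation per connection per
#' shuffle and is therefore optional.
#'
#' @param model A `compartmental_model`.
#' @param sites Site tibble for one PN (`orn_id`, `compartment`).
#' @param syn A [synapse_params()].
#' @param n_shuffles Number of random re-allocations.
#' @param include_efficacy Also compare summation efficacy CVs (slower).
#' @param seed Integer seed.
#' @param duration,dt Simulation controls, ms.
#' @return One-row tibble: `cv_mepsp_real`, `cv_mepsp_shuffled` (mean over
#'   shuffles), and the efficacy analogues when requested.
#' @export
shuffle_control <- function(model, sites, syn = synapse_params(),
                            n_shuffles = 100, include_efficacy = FALSE,
                            seed = 1, duration = 60, dt = 0.025) {
  amp <- measure_mepsps(model, sites, syn, duration, dt)
  cv <- function(x) sd(x) / mean(x)
  conn_cv <- function(orn, somatic) {
    cv(tapply(somatic, orn, mean))
  }
  cv_real <- conn_cv(amp$orn_id, amp$somatic_mv)
  cv_shuf <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      conn_cv(amp$orn_id, amp$somatic_mv[sample.int(nrow(amp))])
    }, numeric(1))
  })
  out <- tibble::tibble(cv_mepsp_real = cv_real,
                        cv_mepsp_shuffled = mean(cv_shuf))
  if (include_efficacy) {
    eff <- function(st) {
      conns <- measure_connections(model, st, syn, duration, dt)
      cv(conns$efficacy)
    }
    eff_shuf <- vapply(seq_len(n_shuffles), function(i) {
      eff(shuffle_synapse_locations(sites, seed = seed + i))
    }, numeric(1))
    out$cv_efficacy_real <- eff(sites)
    out$cv_efficacy_shuffled <- mean(eff_shuf)
  }
  out
}
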