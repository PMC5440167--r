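#' Spontaneous ORN rate arithmetic
#'
#' The baseline condition of the detection task comes from measured
#' spontaneous activity: a pooled spontaneous EPSC rate (58 Hz across one
#' antenna's ORN population) divided by the average ORN count (26.5) gives
#' the per-ORN spontaneous rate; multiplying by the counting window and the
#' population size and rounding gives the expected spontaneous population
#' spike count (12 in 200 ms).
#'
#' @param epsc_rate_hz Pooled spontaneous event rate, Hz.
#' @param n_orns Average number of ORNs per antenna.
#' @param rate_hz Per-ORN spontaneous rate, Hz.
#' @param window_ms Counting window, ms.
#' @return `estimate_spontaneous_rate()`: spikes/s/ORN;
#'   `baseline_spike_count()`: integer population spike count.
#' @export
estimate_spontaneous_rate <- function(epsc_rate_hz = 58, n_orns = 26.5) {
  epsc_rate_hz / n_orns
}

#' @rdname estimate_spontaneous_rate
#' @export
baseline_spike_count <- function(rate_hz = estimate_spontaneous_rate(),
                                 window_ms = 200, n_orns = 26.5) {
  as.integer(round(rate_hz * (window_ms / 1000) * n_orns))
}

#' Generate fixed-count Poisson population spike trains
#'
#' Conditioned Poisson scheme: each trial contains exactly `n_spikes` spike
#' times drawn uniformly on the window, each assigned to a uniformly random
#' ORN; trials in which any ORN fires twice within the refractory period are
#' rejected and redrawn whole. The trial window is followed by an equal
#' silent period in the simulations so the membrane can relax.
#'
#' @param n_spikes Population spike count per trial.
#' @param n_orns Number of ORNs in the population.
#' @param n_trials Number of trials.
#' @param window Window length, ms.
#' @param refractory Minimum same-ORN inter-spike interval, ms.
#' @param seed Integer seed.
#' @return Tibble: `trial`, `time` (ms), `orn` (index in `1:n_orns`).
#' @export
generate_population_spikes <- function(n_spikes, n_orns, n_trials = 1,
                                       window = 200, refractory = 4,
                                       seed = 1) {
  if (n_spikes < 0) abort("n_spikes must be >= 0")
  if (n_spikes > n_orns * window / refractory) {
    abort("infeasible: too many spikes for the refractory constraint")
  }
  if (n_spikes == 0) {
    return(tibble::tibble(trial = integer(0), time = numeric(0),
                          orn = integer(0)))
  }
  withr::with_seed(seed, {
    draw <- function(k) {
      tibble::tibble(
        trial = rep(seq_len(k), each = n_spikes),
        time = runif(k * n_spikes) * window,
        orn = sample.int(n_orns, k * n_spikes, replace = TRUE)
      )
    }
    trials <- draw(n_trials)
    repeat {
      viol <- dplyr::distinct(
        dplyr::filter(
          dplyr::mutate(
            dplyr::arrange(trials, .data$trial, .data$orn, .data$time),
            same = .data$trial == dplyr::lag(.data$trial) &
              .data$orn == dplyr::lag(.data$orn),
            isi = .data$time - dplyr::lag(.data$time)
          ),
          !is.na(.data$same) & .data$same & .data$isi < refractory
        ),
        .data$trial
      )$trial
      if (length(viol) == 0) break
      redraw <- draw(length(viol))
      redraw$trial <- viol[redraw$trial]
      trials <- dplyr::bind_rows(trials[!trials$trial %in% viol, ], redraw)
    }
    dplyr::arrange(trials, .data$trial, .data$time)
  })
}

#' Train a threshold classifier on a scalar
#'
#' The linear classifier of the decoding tasks: on one scalar it reduces to a
#' threshold. Orientation is taken from the class means; the threshold
#' minimizes training error, with ties broken toward the midpoint of the
#' class means.
#'
#' @param values Numeric training scalars.
#' @param labels Logical (or coercible) class labels; `TRUE` = target class.
#' @return A `threshold_classifier` with `threshold`, `direction` (+1 if the
#'   target class lies above), and `train_accuracy`.
#' @export
train_threshold_classifier <- function(values, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) abort("both classes must be present")
  direction <- if (mean(values[labels]) >= mean(values[!labels])) 1 else -1
  v <- direction * values
  ord <- order(v)
  vs <- v[ord]
  ls <- labels[ord]
  n <- length(vs)
  ct <- c(0, cumsum(ls))            # target-class counts at positions <= i
  total_true <- ct[n + 1]
  i <- 0:n
  # predict TRUE for (oriented) value > cut placed after position i
  errors <- ct[i + 1] + ((n - i) - (total_true - ct[i + 1]))
  best <- which(errors == min(errors)) - 1
  mid <- direction * (mean(values[labels]) + mean(values[!labels])) / 2
  cuts <- vapply(best, function(b) {
    if (b == 0) vs[1] - abs(vs[1]) * 1e-9 - 1e-12
    else if (b == n) vs[n] + abs(vs[n]) * 1e-9 + 1e-12
    else (vs[b] + vs[b + 1]) / 2
  }, numeric(1))
  thr <- cuts[which.min(abs(cuts - mid))]
  structure(list(threshold = direction * thr, direction = direction,
                 train_accuracy = 1 - min(errors) / n),
            class = "threshold_classifier")
}

#' @export
predict.threshold_classifier <- function(object, newdata, ...) {
  object$direction * newdata > object$direction * object$threshold
}

classifier_accuracy <- function(clf, values, labels) {
  mean(predict(clf, values) == as.logical(labels))
}

# --- fast linear path -------------------------------------------------------

# Cumulative time-integral of the somatic depolarization evoked by a single
# synaptic event at each listed compartment, sampled on a coarse grid.
# Returns a matrix [length(comps) x n_grid]; column i holds the integral up
# to time (i-1)*grid_dt after event onset. Valid for summing trial responses
# by linear superposition in the small-conductance regime.
site_integral_curves <- function(model, comps, syn, window = 200,
                                 dt = 0.025, grid_dt = 0.1) {
  ucomps <- unique(comps)
  n_grid <- as.integer(round(window / grid_dt)) + 1L
  pick <- as.integer(round(seq(0, window, by = grid_dt) / dt)) + 1L
  m <- matrix(0, nrow = length(ucomps), ncol = n_grid)
  for (k in seq_along(ucomps)) {
    tr <- simulate_epsp(model,
                        events = tibble::tibble(compartment = ucomps[k],
                                                onset = 0),
                        syn = syn, duration = window, dt = dt,
                        record_at = model$soma_index)
    dep <- tr[[2]] - attr(tr, "e_rest")
    cumint <- c(0, cumsum((dep[-1] + dep[-length(dep)]) / 2 * dt))
    m[k, ] <- cumint[pick]
  }
  rownames(m) <- as.character(ucomps)
  m[as.character(comps), , drop = FALSE]
}

# Time-averaged somatic depolarization per trial, by superposition of
# per-site integral curves. spikes: tibble (trial, time, orn_id);
# site_orn: character vector, owning ORN per row of curves.
mu_per_trial <- function(spikes, curves, site_orn, n_trials, window = 200,
                         grid_dt = 0.1) {
  mu <- numeric(n_trials)
  if (nrow(spikes) == 0) return(mu)
  idx <- pmax(1L, pmin(ncol(curves),
                       as.integer(round((window - spikes$time) / grid_dt)) + 1L))
  sites_by_orn <- split(seq_len(nrow(curves)), site_orn)
  sp <- split(tibble::tibble(trial = spikes$trial, idx = idx),
              spikes$orn_id)
  for (orn in names(sp)) {
    rows <- sites_by_orn[[orn]]
    if (is.null(rows)) next   # ORN has no synapses on this PN
    s <- sp[[orn]]
    contrib <- colSums(curves[rows, s$idx, drop = FALSE])
    agg <- rowsum(contrib, s$trial)
    mu[as.integer(rownames(agg))] <- mu[as.integer(rownames(agg))] + agg[, 1]
  }
  mu / window
}

# --- detection task ---------------------------------------------------------

#' Odor-detection classification experiment
#'
#' Measures how accurately a threshold classifier can detect a small increase
#' of the ipsilateral ORN population spike count above the spontaneous
#' baseline, from a PN's time-averaged somatic voltage. Each trial draws a
#' fixed-count population spike train (baseline or odor condition), drives
#' the PN model, and the classifier is trained and tested on independent
#' trials. With `wiring = "equalized"` the synapse locations are re-allocated
#' evenly across axons independently on every trial and the synaptic peak
#' conductance is reduced to 0.0958 nS so mean uEPSP amplitudes are
#' preserved.
#'
#' Trial responses are computed by linear superposition of precomputed
#' per-site somatic responses (valid in the small-conductance regime used
#' here); the full solver remains the reference implementation.
#'
#' @param models Output of [build_circuit_models()] (or a subset).
#' @param table The [connectivity_table()] the models were built from.
#' @param conditions Odor spike counts (per 200 ms window).
#' @param baseline Spontaneous spike count.
#' @param wiring `"real"` or `"equalized"`.
#' @param syn Synapse parameters for real wiring.
#' @param g_equalized Peak conductance (nS) used under equalized wiring.
#' @param n_train,n_test Training and held-out trials per class.
#' @param window Spike-counting window, ms.
#' @param refractory Same-ORN refractory period, ms.
#' @param seed Integer seed.
#' @param dt,grid_dt Solver step and response-curve grid, ms.
#' @return A `task_result` tibble: `pn_id`, `wiring`, `condition`,
#'   `accuracy`, `n_train`, `n_test`, `seed`.
#' @export
run_detection_task <- function(models, table, conditions = 13:20,
                               baseline = 12,
                               wiring = c("real", "equalized"),
                               syn = synapse_params(),
                               g_equalized = 0.0958,
                               n_train = 250, n_test = 250,
                               window = 200, refractory = 4, seed = 1,
                               dt = 0.025, grid_dt = 0.1) {
  wiring <- match.arg(wiring)
  syn_use <- if (wiring == "equalized") {
    synapse_params(g_max = g_equalized, tau_rise = syn$tau_rise,
                   tau_decay = syn$tau_decay, e_syn = syn$e_syn)
  } else {
    syn
  }
  n_per_class <- n_train + n_test
  out <- list()
  for (m in models) {
    sites <- m$sites[m$sites$orn_side == m$side, ]   # ipsilateral only
    orns <- rownames(table$counts)[table$orn_side == m$side]
    curves <- site_integral_curves(m$model, sites$compartment, syn_use,
                                   window = window, dt = dt,
                                   grid_dt = grid_dt)
    for (cond in conditions) {
      res <- detection_condition(
        curves, sites, orns, cond, baseline, wiring, n_per_class,
        n_train, window, refractory,
        seed = seed + 7919L * match(m$pn_id, names(models)) + 31L * cond,
        grid_dt = grid_dt
      )
      out[[length(out) + 1]] <- tibble::tibble(
        pn_id = m$pn_id, wiring = wiring, condition = cond,
        accuracy = res, n_train = n_train, n_test = n_test, seed = seed
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("task_result", class(res))
  res
}

detection_condition <- function(curves, sites, orns, cond, baseline, wiring,
                                n_per_class, n_train, window, refractory,
                                seed, grid_dt) {
  n_orns <- length(orns)
  sp0 <- generate_population_spikes(baseline, n_orns, n_per_class, window,
                                    refractory, seed)
  sp1 <- generate_population_spikes(cond, n_orns, n_per_class, window,
                                    refractory, seed + 1L)
  sp0$orn_id <- orns[sp0$orn]
  sp1$orn_id <- orns[sp1$orn]
  if (wiring == "real") {
    mu0 <- mu_per_trial(sp0, curves, sites$orn_id, n_per_class, window,
                        grid_dt)
    mu1 <- mu_per_trial(sp1, curves, sites$orn_id, n_per_class, window,
                        grid_dt)
  } else {
    mu0 <- mu_equalized(sp0, curves, orns, n_per_class, window, grid_dt,
                        seed + 2L)
    mu1 <- mu_equalized(sp1, curves, orns, n_per_class, window, grid_dt,
                        seed + 3L)
  }
  tr_idx <- seq_len(n_train)
  clf <- train_threshold_classifier(c(mu0[tr_idx], mu1[tr_idx]),
                                    rep(c(FALSE, TRUE), each = n_train))
  classifier_accuracy(clf, c(mu0[-tr_idx], mu1[-tr_idx]),
                      rep(c(FALSE, TRUE), each = n_per_class - n_train))
}

# Equalized wiring: synapse locations re-allocated evenly across axons,
# independently per trial.
mu_equalized <- function(spikes, curves, orns, n_trials, window, grid_dt,
                         seed) {
  n_sites <- nrow(curves)
  k <- length(orns)
  withr::with_seed(seed, {
    vapply(seq_len(n_trials), function(tr) {
      base <- n_sites %/% k
      extra <- n_sites %% k
      counts <- rep(base, k) + as.integer(seq_len(k) %in% sample.int(k, extra))
      assignment <- sample(rep(orns, counts))
      sp <- spikes[spikes$trial == tr, ]
      if (nrow(sp) == 0) return(0)
      idx <- pmax(1L, pmin(ncol(curves),
                           as.integer(round((window - sp$time) / grid_dt)) + 1L))
      tot <- 0
      for (s in seq_len(nrow(sp))) {
        rows <- which(assignment == sp$orn_id[s])
        tot <- tot + sum(curves[rows, idx[s]])
      }
      tot / window
    }, numeric(1))
  })
}

# --- lateralization task ----------------------------------------------------

#' Odor-lateralization classification experiment
#'
#' Both antennae fire on every trial and every PN receives both antennae's
#' input through its own synapses. In baseline trials both antennae fire the
#' spontaneous count; in odor trials one antenna is driven to the condition
#' count. The decision scalar is the cell-averaged time-averaged voltage of
#' left PNs minus that of right PNs. Under equalized wiring, synapse counts
#' are equalized independently within each PN-antenna pool on every trial
#' (preserving the average ipsi/contra asymmetry) and the peak conductance is
#' reduced to 0.0958 nS.
#'
#' @inheritParams run_detection_task
#' @param odor_sides Which antenna carries the odor (`"L"`, `"R"`, or both).
#' @return A `task_result` tibble: `odor_side`, `wiring`, `condition`,
#'   `accuracy`, `n_train`, `n_test`, `seed`.
#' @export
run_lateralization_task <- function(models, table, conditions = 13:20,
                                    baseline = 12,
                                    wiring = c("real", "equalized"),
                                    odor_sides = c("L", "R"),
                                    syn = synapse_params(),
                                    g_equalized = 0.0958,
                                    n_train = 250, n_test = 250,
                                    window = 200, refractory = 4, seed = 1,
                                    dt = 0.025, grid_dt = 0.1) {
  wiring <- match.arg(wiring)
  pn_sides <- purrr::map_chr(models, "side")
  if (!all(c("L", "R") %in% pn_sides)) {
    abort("lateralization needs PNs on both sides")
  }
  syn_use <- if (wiring == "equalized") {
    synapse_params(g_max = g_equalized, tau_rise = syn$tau_rise,
                   tau_decay = syn$tau_decay, e_syn = syn$e_syn)
  } else {
    syn
  }
  orns_by_ant <- list(
    L = rownames(table$counts)[table$orn_side == "L"],
    R = rownames(table$counts)[table$orn_side == "R"]
  )
  prepped <- purrr::map(models, function(m) {
    list(side = m$side,
         sites = m$sites,
         curves = site_integral_curves(m$model, m$sites$compartment, syn_use,
                                       window = window, dt = dt,
                                       grid_dt = grid_dt))
  })
  n_per_class <- n_train + n_test

  trial_scalars <- function(spL, spR, seed_eq) {
    # decision scalar per trial for a block of trials
    mus <- purrr::imap(prepped, function(p, nm) {
      mu_for <- function(sp, ant, eq_seed) {
        if (wiring == "real") {
          mu_per_trial(sp, p$curves, p$sites$orn_id, n_per_class, window,
                       grid_dt)
        } else {
          sel <- p$sites$orn_side == ant
          mu_equalized(sp, p$curves[sel, , drop = FALSE], orns_by_ant[[ant]],
                       n_per_class, window, grid_dt, eq_seed)
        }
      }
      k <- match(nm, names(prepped))
      mu_for(spL, "L", seed_eq + 2L * k) + mu_for(spR, "R", seed_eq + 2L * k + 1L)
    })
    mus <- do.call(cbind, mus)
    rowMeans(mus[, pn_sides == "L", drop = FALSE]) -
      rowMeans(mus[, pn_sides == "R", drop = FALSE])
  }

  out <- list()
  for (odor in odor_sides) {
    for (cond in conditions) {
      s0 <- seed + 7919L * cond + 13L * match(odor, c("L", "R"))
      spL0 <- generate_population_spikes(baseline, length(orns_by_ant$L),
                                         n_per_class, window, refractory, s0)
      spR0 <- generate_population_spikes(baseline, length(orns_by_ant$R),
                                         n_per_class, window, refractory,
                                         s0 + 1L)
      nL <- if (odor == "L") cond else baseline
      nR <- if (odor == "R") cond else baseline
      spL1 <- generate_population_spikes(nL, length(orns_by_ant$L),
                                         n_per_class, window, refractory,
                                         s0 + 2L)
      spR1 <- generate_population_spikes(nR, length(orns_by_ant$R),
                                         n_per_class, window, refractory,
                                         s0 + 3L)
      spL0$orn_id <- orns_by_ant$L[spL0$orn]
      spR0$orn_id <- orns_by_ant$R[spR0$orn]
      spL1$orn_id <- orns_by_ant$L[spL1$orn]
      spR1$orn_id <- orns_by_ant$R[spR1$orn]
      d0 <- trial_scalars(spL0, spR0, s0 + 100L)
      d1 <- trial_scalars(spL1, spR1, s0 + 200L)
      tr_idx <- seq_len(n_train)
      clf <- train_threshold_classifier(c(d0[tr_idx], d1[tr_idx]),
                                        rep(c(FALSE, TRUE), each = n_train))
      acc <- classifier_accuracy(clf, c(d0[-tr_idx], d1[-tr_idx]),
                                 rep(c(FALSE, TRUE), each = n_test))
      out[[length(out) + 1]] <- tibble::tibble(
        odor_side = odor, wiring = wiring, condition = cond,
        accuracy = acc, n_train = n_train, n_test = n_test, seed = seed
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("task_result", class(res))
  res
}
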