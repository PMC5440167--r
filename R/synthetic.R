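#' Specification of a synthetic glomerular circuit
#'
#' Parameters of the generative model for ORN-to-PN synapse-count matrices.
#' Defaults emulate the measured DM6 micro-circuit: 27 left and 26 right
#' ORNs (one per side unilateral, connecting only ipsilaterally), 3 left and
#' 2 right PNs, an ipsilateral surplus of 35% in synapses per connection, a
#' coefficient of variation of normalized contributions of 0.31, and
#' per-ORN latent strength factors drawn independently per target side so
#' that same-side PNs share wiring noise while opposite sides do not. The
#' default ipsilateral mean of 26.3 synapses/connection makes the grand mean
#' over all connections about 23.
#'
#' @param n_orns_left,n_orns_right ORNs per antenna.
#' @param n_pns_left,n_pns_right PNs per side.
#' @param mean_syn_ipsi Mean synapses per ipsilateral connection.
#' @param ipsi_contra_ratio Ratio of ipsi to contra mean synapses (>= 1).
#' @param connection_cv Target CV of normalized ipsilateral contributions.
#' @param side_factor_sd SD of the per-ORN, per-target-side latent
#'   log-strength factor (drives within-side correlations between PNs).
#' @param unilateral_orns_per_side ORNs per antenna that project only
#'   ipsilaterally.
#' @param pn_size_mode `"share"` scales each PN's counts by
#'   mean-PNs-per-side / PNs-on-its-side, conserving per-glomerulus synapse
#'   totals (so sides with fewer PNs have higher per-PN counts); `"equal"`
#'   gives every PN the same size factor.
#' @param seed Integer seed; the generator is a pure function of spec + seed.
#' @return A `circuit_spec` list.
#' @export
circuit_spec <- function(n_orns_left = 27, n_orns_right = 26,
                         n_pns_left = 3, n_pns_right = 2,
                         mean_syn_ipsi = 26.3, ipsi_contra_ratio = 1.35,
                         connection_cv = 0.31, side_factor_sd = 0.2,
                         unilateral_orns_per_side = 1,
                         pn_size_mode = c("share", "equal"),
                         seed = 1) {
  pn_size_mode <- match.arg(pn_size_mode)
  counts <- c(n_orns_left, n_orns_right, n_pns_left, n_pns_right)
  if (any(counts < 1)) abort("all cell counts must be >= 1")
  if (unilateral_orns_per_side < 0) abort("unilateral_orns_per_side must be >= 0")
  if (ipsi_contra_ratio < 1) abort("ipsi_contra_ratio must be >= 1")
  if (connection_cv < 0) abort("connection_cv must be >= 0")
  if (side_factor_sd < 0) abort("side_factor_sd must be >= 0")
  structure(list(n_orns_left = n_orns_left, n_orns_right = n_orns_right,
                 n_pns_left = n_pns_left, n_pns_right = n_pns_right,
                 mean_syn_ipsi = mean_syn_ipsi,
                 ipsi_contra_ratio = ipsi_contra_ratio,
                 connection_cv = connection_cv,
                 side_factor_sd = side_factor_sd,
                 unilateral_orns_per_side = unilateral_orns_per_side,
                 pn_size_mode = pn_size_mode,
                 seed = as.integer(seed)),
            class = "circuit_spec")
}

#' Specification of a synthetic PN dendrite
#'
#' Parameters of the random branched-tree generator standing in for
#' reconstructed dendritic arbors. Defaults are calibrated so that, with the
#' default membrane and synapse parameters and default circuit, the mean
#' unitary EPSP is about 5 mV.
#'
#' @param target_path_length Total dendritic path length, um.
#' @param branch_rate Branch points per um of dendrite (0 gives one cable).
#' @param radius_root Radius of the primary neurite, um.
#' @param radius_taper Multiplicative radius factor applied at each branch
#'   point (in (0, 1]); radii never increase away from the soma.
#' @param soma_radius Soma radius, um.
#' @param node_spacing Skeleton sampling interval, um.
#' @param seed Integer seed.
#' @return A `morphology_spec` list.
#' @export
morphology_spec <- function(target_path_length = 1500, branch_rate = 0.02,
                            radius_root = 0.6, radius_taper = 0.9,
                            soma_radius = 3, node_spacing = 2, seed = 1) {
  if (target_path_length <= 0) abort("target_path_length must be positive")
  if (radius_root <= 0 || soma_radius <= 0) abort("radii must be positive")
  if (radius_taper <= 0 || radius_taper > 1) {
    abort("radius_taper must be in (0, 1]")
  }
  if (branch_rate < 0) abort("branch_rate must be >= 0")
  structure(list(target_path_length = target_path_length,
                 branch_rate = branch_rate, radius_root = radius_root,
                 radius_taper = radius_taper, soma_radius = soma_radius,
                 node_spacing = node_spacing, seed = as.integer(seed)),
            class = "morphology_spec")
}

#' Generate a synthetic PN dendrite
#'
#' Grows a rooted tree (soma root, one primary neurite, binary branching with
#' exponentially distributed inter-branch intervals and a fixed radius taper
#' at branch points) until the summed inter-node path length reaches the
#' target, guaranteed within 5%. Growing tips whose radius falls below
#' 0.05 um are retired; if every tip retires before the target length is
#' reached the generator fails rather than silently truncating.
#'
#' @param spec A [morphology_spec()].
#' @return A [morphology()].
#' @export
generate_morphology <- function(spec) {
  stopifnot(inherits(spec, "morphology_spec"))
  withr::with_seed(spec$seed, generate_morphology_impl(spec))
}

generate_morphology_impl <- function(spec) {
  step <- spec$node_spacing
  target <- spec$target_path_length
  min_radius <- 0.05
  draw_branch_len <- function() {
    if (spec$branch_rate <= 0) Inf else rexp(1, spec$branch_rate)
  }
  rand_unit <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  n_guess <- ceiling(target / step) + 64
  xs <- numeric(n_guess); ys <- numeric(n_guess); zs <- numeric(n_guess)
  rad <- numeric(n_guess); par <- integer(n_guess); lab <- integer(n_guess)
  xs[1] <- ys[1] <- zs[1] <- 0
  rad[1] <- spec$soma_radius; par[1] <- -1L; lab[1] <- 1L
  n_nodes <- 1L

  tips <- list(list(node = 1L, dir = rand_unit(), radius = spec$radius_root,
                    to_branch = draw_branch_len()))
  total <- 0
  while (total < target - 1e-9) {
    if (length(tips) == 0) {
      abort(paste0("target path length unreachable: all growing tips ",
                   "tapered out at ", format(total, digits = 5), " of ",
                   target, " um; lower branch_rate or raise radius_taper"))
    }
    new_tips <- list()
    for (tip in tips) {
      if (total >= target - 1e-9) { new_tips <- c(new_tips, list(tip)); next }
      seg <- min(step, tip$to_branch, target - total)
      dir <- tip$dir + 0.25 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      if (n_nodes + 1L > length(xs)) {
        grow <- length(xs)
        xs <- c(xs, numeric(grow)); ys <- c(ys, numeric(grow))
        zs <- c(zs, numeric(grow)); rad <- c(rad, numeric(grow))
        par <- c(par, integer(grow)); lab <- c(lab, integer(grow))
      }
      n_nodes <- n_nodes + 1L
      xs[n_nodes] <- xs[tip$node] + seg * dir[1]
      ys[n_nodes] <- ys[tip$node] + seg * dir[2]
      zs[n_nodes] <- zs[tip$node] + seg * dir[3]
      rad[n_nodes] <- tip$radius
      par[n_nodes] <- tip$node
      lab[n_nodes] <- 3L
      total <- total + seg
      left <- tip$to_branch - seg
      if (left <= 1e-12 && is.finite(tip$to_branch)) {
        r_child <- tip$radius * spec$radius_taper
        if (r_child >= min_radius) {
          for (k in 1:2) {
            new_tips <- c(new_tips, list(list(
              node = n_nodes,
              dir = { d <- tip$dir + 0.9 * rand_unit(); d / sqrt(sum(d^2)) },
              radius = r_child,
              to_branch = draw_branch_len()
            )))
          }
        }
      } else {
        tip$node <- n_nodes
        tip$dir <- dir
        tip$to_branch <- left
        new_tips <- c(new_tips, list(tip))
      }
    }
    tips <- new_tips
  }
  morphology(tibble::tibble(
    id = seq_len(n_nodes),
    parent_id = par[seq_len(n_nodes)],
    x = xs[seq_len(n_nodes)], y = ys[seq_len(n_nodes)],
    z = zs[seq_len(n_nodes)],
    radius = rad[seq_len(n_nodes)],
    label = lab[seq_len(n_nodes)]
  ))
}

#' Generate a synthetic ORN-to-PN connectivity matrix
#'
#' Multiplicative count model: for ORN `i` (home side `s`) and PN `j`
#' (side `t`),
#' `count_ij = max(1, round(base * r^[s==t] * exp(f_i^t) * d_j * eps_ij))`
#' where `r` is the ipsi/contra ratio, `f_i^t` a per-ORN latent log-strength
#' drawn independently for each target side (SD `side_factor_sd`), `d_j` the
#' per-PN size factor, and `eps_ij` i.i.d. lognormal noise. `base` is
#' calibrated analytically so the expected ipsilateral mean equals
#' `mean_syn_ipsi`, and the noise variance is solved from
#' `sigma_f^2 + sigma_eps^2 = log(1 + connection_cv^2)` so the total CV of
#' normalized contributions matches `connection_cv`. Unilateral ORNs connect
#' only on their home side; every innervated pair has at least one synapse.
#'
#' @param spec A [circuit_spec()].
#' @return A [connectivity_table()].
#' @export
generate_circuit <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  withr::with_seed(spec$seed, generate_circuit_impl(spec))
}

generate_circuit_impl <- function(spec) {
  orn_side <- c(rep("L", spec$n_orns_left), rep("R", spec$n_orns_right))
  pn_side <- c(rep("L", spec$n_pns_left), rep("R", spec$n_pns_right))
  n_orn <- length(orn_side)
  n_pn <- length(pn_side)
  orn_ids <- paste0("ORN_", orn_side, "_",
                    formatC(c(seq_len(spec$n_orns_left),
                              seq_len(spec$n_orns_right)),
                            width = 2, flag = "0"))
  pn_ids <- paste0("PN_", pn_side, "_",
                   c(seq_len(spec$n_pns_left), seq_len(spec$n_pns_right)))

  bilateral <- rep(TRUE, n_orn)
  for (s in c("L", "R")) {
    on_side <- which(orn_side == s)
    k <- min(spec$unilateral_orns_per_side, length(on_side))
    if (k > 0) bilateral[sample(on_side, k)] <- FALSE
  }

  sigma_tot2 <- log(1 + spec$connection_cv^2)
  sigma_f2 <- spec$side_factor_sd^2
  if (sigma_f2 > sigma_tot2 + 1e-12) {
    abort(paste0("infeasible connection_cv: the side factor alone implies a ",
                 "CV of ", format(sqrt(exp(sigma_f2) - 1), digits = 3),
                 " > ", spec$connection_cv))
  }
  sigma_e <- sqrt(max(0, sigma_tot2 - sigma_f2))
  sigma_f <- spec$side_factor_sd

  d_pn <- if (spec$pn_size_mode == "share") {
    mean_pns <- (spec$n_pns_left + spec$n_pns_right) / 2
    ifelse(pn_side == "L", mean_pns / spec$n_pns_left,
           mean_pns / spec$n_pns_right)
  } else {
    rep(1, n_pn)
  }

  ipsi <- outer(orn_side, pn_side, "==")
  innervated <- ipsi | bilateral   # contra pairs exist only for bilateral ORNs
  # expected size factor over realized ipsilateral connections, so that the
  # ipsilateral mean count equals mean_syn_ipsi
  wmean_d_ipsi <- sum(t(ipsi) * d_pn) / sum(ipsi)
  base <- spec$mean_syn_ipsi / (spec$ipsi_contra_ratio * wmean_d_ipsi)

  f <- matrix(rnorm(n_orn * 2, mean = -sigma_f2 / 2, sd = sigma_f),
              nrow = n_orn, dimnames = list(NULL, c("L", "R")))
  eps <- matrix(rlnorm(n_orn * n_pn, meanlog = -sigma_e^2 / 2,
                       sdlog = sigma_e), nrow = n_orn)

  mu <- base * ifelse(ipsi, spec$ipsi_contra_ratio, 1) *
    exp(f[, pn_side, drop = FALSE]) *
    matrix(d_pn, n_orn, n_pn, byrow = TRUE) * eps
  counts <- pmax(1L, as.integer(round(mu)))
  counts <- matrix(counts, n_orn, n_pn)
  counts[!innervated] <- 0L
  dimnames(counts) <- list(orn_ids, pn_ids)
  connectivity_table(counts, orn_side = orn_side, pn_side = pn_side,
                     orn_bilateral = bilateral)
}

#' Place synapses uniformly along a dendrite
#'
#' For each ORN connected to the given PN, draws that connection's synapse
#' count of locations uniformly per unit dendritic path length, independently
#' across ORNs (edges are chosen with probability proportional to their
#' length, positions uniformly within the edge).
#'
#' @param morph The PN's [morphology()].
#' @param table A [connectivity_table()].
#' @param pn_id Column name of the PN in `table`.
#' @param seed Integer seed.
#' @return A tibble of synapse sites: `orn_id`, `pn_id`, `site_id`,
#'   `child_node_id` (the skeleton edge, identified by its distal node) and
#'   `offset_um` (distance from the edge's proximal end). Use [bind_sites()]
#'   to attach compartment indices after discretization.
#' @export
place_synapses <- function(morph, table, pn_id, seed = 1) {
  stopifnot(inherits(table, "connectivity_table"))
  if (!pn_id %in% colnames(table$counts)) {
    abort(paste0("pn_id ", pn_id, " not present in table"))
  }
  edges <- morphology_edges(morph)
  edges <- edges[edges$length > 0, ]
  if (nrow(edges) == 0) abort("morphology has no edges to place synapses on")
  counts <- table$counts[, pn_id]
  counts <- counts[counts > 0]
  withr::with_seed(seed, {
    sites <- purrr::imap(counts, function(n, orn) {
      e <- sample.int(nrow(edges), n, replace = TRUE,
                      prob = edges$length)
      tibble::tibble(
        orn_id = orn,
        pn_id = pn_id,
        child_node_id = edges$child_id[e],
        offset_um = runif(n) * edges$length[e]
      )
    })
    out <- dplyr::bind_rows(sites)
    dplyr::mutate(out, site_id = dplyr::row_number(), .before = 1)
  })
}

#' Bind synapse sites to model compartments
#'
#' Maps each site's skeleton position (edge + offset) to a compartment of the
#' discretized model via the cable arc-length bookkeeping produced by
#' [inflate()].
#'
#' @param sites Output of [place_synapses()].
#' @param cables The PN's `cable_set` (from [inflate()] of the same
#'   morphology).
#' @param model The PN's `compartmental_model` (from [remesh()] of those
#'   cables).
#' @return `sites` with `cable_id`, `pos_um` and `compartment` columns added.
#' @export
bind_sites <- function(sites, cables, model) {
  em <- attr(cables, "edge_map")
  out <- dplyr::left_join(sites, em, by = "child_node_id")
  if (any(is.na(out$cable_id))) {
    abort("some sites lie on edges not present in the cable set")
  }
  pos <- pmin(out$pos_start + out$offset_um, out$pos_end)
  out$pos_um <- pos
  out$compartment <- compartment_at(model, out$cable_id, pos)
  dplyr::select(out, -"pos_start", -"pos_end")
}

#' Generate per-synapse geometry (T-bar volumes and contact areas)
#'
#' Draws per-synapse presynaptic T-bar volumes and postsynaptic contact areas
#' from a correlated bivariate lognormal with a common per-synapse CV,
#' grouped into connections. Averaging within connections shrinks the CV of
#' per-connection means by roughly `1/sqrt(n)`, the property measured on the
#' real synapse-size data.
#'
#' @param n_connections Number of connections.
#' @param syn_per_connection Synapses per connection (scalar or vector).
#' @param cv_syn Per-synapse CV of both measures (>= 0).
#' @param rho Correlation between log volume and log area.
#' @param mean_tbar_nm3 Mean T-bar volume, nm^3.
#' @param mean_area_nm2 Mean postsynaptic contact area, nm^2.
#' @param seed Integer seed.
#' @return Tibble: `connection_id`, `synapse_id`, `tbar_volume_nm3`,
#'   `contact_area_nm2`.
#' @export
generate_synapse_sizes <- function(n_connections, syn_per_connection,
                                   cv_syn = 0.5, rho = 0.5,
                                   mean_tbar_nm3 = 2e6, mean_area_nm2 = 1e5,
                                   seed = 1) {
  if (n_connections < 1) abort("n_connections must be >= 1")
  if (cv_syn < 0) abort("cv_syn must be >= 0")
  if (abs(rho) > 1) abort("rho must be in [-1, 1]")
  n_syn <- rep_len(syn_per_connection, n_connections)
  total <- sum(n_syn)
  sigma <- sqrt(log(1 + cv_syn^2))
  withr::with_seed(seed, {
    z1 <- rnorm(total)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(total)
    tibble::tibble(
      connection_id = rep(seq_len(n_connections), n_syn),
      synapse_id = sequence(n_syn),
      tbar_volume_nm3 = mean_tbar_nm3 * exp(sigma * z1 - sigma^2 / 2),
      contact_area_nm2 = mean_area_nm2 * exp(sigma * z2 - sigma^2 / 2)
    )
  })
}

#' Build the full set of synthetic PN models for a circuit
#'
#' For every PN in the connectivity table, generates a dendrite (seeded
#' independently per PN), discretizes it, places all its synapses (from both
#' antennae) and binds them to compartments. The workhorse behind the
#' simulation and classification stages.
#'
#' @param table A [connectivity_table()].
#' @param morph_spec A [morphology_spec()] used as template (the per-PN seed
#'   is derived from `seed`).
#' @param membrane A [membrane_params()].
#' @param seed Integer seed.
#' @param max_elec_length Discretization bound passed to [remesh()].
#' @return Named list (one entry per PN) of lists with elements `pn_id`,
#'   `side`, `morphology`, `cables`, `model`, `sites`.
#' @export
build_circuit_models <- function(table, morph_spec = morphology_spec(),
                                 membrane = membrane_params(), seed = 1,
                                 max_elec_length = 0.1) {
  stopifnot(inherits(table, "connectivity_table"))
  pns <- colnames(table$counts)
  out <- purrr::map(seq_along(pns), function(k) {
    ms <- morph_spec
    ms$seed <- as.integer(seed + 1000L * k)
    morph <- generate_morphology(ms)
    cables <- inflate(morph)
    model <- remesh(cables, membrane, max_elec_length = max_elec_length)
    sites <- place_synapses(morph, table, pns[k], seed = seed + 1000L * k + 1L)
    sites <- bind_sites(sites, cables, model)
    sites$orn_side <- table$orn_side[match(sites$orn_id,
                                           rownames(table$counts))]
    list(pn_id = pns[k], side = table$pn_side[k], morphology = morph,
         cables = cables, model = model, sites = sites)
  })
  setNames(out, pns)
}
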