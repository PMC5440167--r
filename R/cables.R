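#' Passive membrane parameters
#'
#' Specific (size-independent) passive properties of the neuronal membrane.
#' The default preset `"cell3"` carries the values measured for antennal-lobe
#' projection neurons by whole-cell electrophysiology: specific membrane
#' resistance 20.8 kOhm cm^2, specific membrane capacitance 0.8 uF/cm^2 and
#' specific axial resistivity 266.1 Ohm cm. The presets `"alt_low"` and
#' `"alt_high"` are synthetic +/-20% variations of those values, provided for
#' robustness checks of downstream conclusions; any value can also be supplied
#' explicitly. The resting potential only anchors the voltage scale (all
#' amplitude measures are differences from rest); the synaptic reversal sets
#' the driving force.
#'
#' @param preset One of `"cell3"`, `"alt_low"`, `"alt_high"`.
#' @param r_m Specific membrane resistance, kOhm cm^2.
#' @param c_m Specific membrane capacitance, uF/cm^2.
#' @param r_a Specific axial resistivity, Ohm cm.
#' @param e_rest Resting potential, mV.
#' @return A `membrane_params` list.
#' @export
membrane_params <- function(preset = c("cell3", "alt_low", "alt_high"),
                            r_m = NULL, c_m = NULL, r_a = NULL,
                            e_rest = -60) {
  preset <- match.arg(preset)
  base <- switch(preset,
    cell3    = list(r_m = 20.8, c_m = 0.8, r_a = 266.1),
    alt_low  = list(r_m = 20.8 * 0.8, c_m = 0.8 * 1.2, r_a = 266.1 * 0.8),
    alt_high = list(r_m = 20.8 * 1.2, c_m = 0.8 * 0.8, r_a = 266.1 * 1.2)
  )
  p <- list(
    r_m = r_m %||% base$r_m,
    c_m = c_m %||% base$c_m,
    r_a = r_a %||% base$r_a,
    e_rest = e_rest,
    preset = preset
  )
  if (p$r_m <= 0 || p$c_m <= 0 || p$r_a <= 0) {
    abort("specific membrane parameters must be positive")
  }
  structure(p, class = "membrane_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cable space constant in um for a cylinder of diameter d um.
lambda_um <- function(d_um, membrane) {
  1e4 * sqrt((membrane$r_m * 1000) * (d_um * 1e-4) / (4 * membrane$r_a))
}

#' Inflate a skeleton into a cylinder-cable tree
#'
#' Converts a wire-frame morphology into unbranched cables: one cable per path
#' between branch points (or root/leaf), represented as a cylinder whose
#' diameter is twice the mean node radius along the path and whose length is
#' the summed inter-node Euclidean distance. The soma node (SWC label 1 at the
#' root) is held out of the cable radii and recorded separately so that
#' [remesh()] can attach it as its own compartment.
#'
#' @param morph A [morphology()].
#' @return A `cable_set`: a tibble with one row per cable (`cable_id`,
#'   `parent_cable`, `length`, `diameter`, `n_nodes`), carrying as attributes
#'   the soma radius (or `NA`) and an edge map binding every skeleton edge to
#'   a position along its cable (used to localize synapses after remeshing).
#' @export
inflate <- function(morph) {
  pidx <- match(morph$parent_id, morph$id)
  n_children <- tabulate(pidx[!is.na(pidx)], nbins = nrow(morph))
  root_row <- which(is.na(pidx))
  is_anchor <- n_children >= 2
  is_anchor[root_row] <- TRUE

  soma_radius <- if (morph$label[root_row] == 1) morph$radius[root_row] else NA_real_

  # walk each cable from its first node (child of an anchor) to the next
  # anchor or leaf
  children_of <- split(seq_len(nrow(morph)), pidx)
  starts <- which(!is.na(pidx) & is_anchor[pidx])

  cables <- list()
  edge_map <- list()
  cable_of_end_node <- integer(nrow(morph))  # cable whose distal node is row i
  cable_id <- 0L
  for (s in starts) {
    cable_id <- cable_id + 1L
    rows <- s
    repeat {
      last <- rows[length(rows)]
      if (is_anchor[last]) break
      kids <- children_of[[as.character(last)]]
      if (is.null(kids)) break
      rows <- c(rows, kids[1])
    }
    anchor <- pidx[s]
    seg <- sqrt(diff(c(morph$x[anchor], morph$x[rows]))^2 +
                diff(c(morph$y[anchor], morph$y[rows]))^2 +
                diff(c(morph$z[anchor], morph$z[rows]))^2)
    len <- sum(seg)
    radius_rows <- if (anchor == root_row && !is.na(soma_radius)) rows else c(anchor, rows)
    cables[[cable_id]] <- tibble::tibble(
      cable_id = cable_id,
      anchor_row = anchor,
      end_row = rows[length(rows)],
      length = len,
      diameter = 2 * mean(morph$radius[radius_rows]),
      n_nodes = length(rows)
    )
    edge_map[[cable_id]] <- tibble::tibble(
      child_node_id = morph$id[rows],
      cable_id = cable_id,
      pos_start = cumsum(seg) - seg,
      pos_end = cumsum(seg)
    )
    cable_of_end_node[rows[length(rows)]] <- cable_id
  }
  cables <- dplyr::bind_rows(cables)
  edge_map <- dplyr::bind_rows(edge_map)

  zero <- cables$length <= 0
  if (any(zero)) {
    warn(paste0(sum(zero), " zero-length cable(s) collapsed into parent"))
  }

  # parentage: a cable's parent is the cable that ends at its anchor node
  cables$parent_cable <- ifelse(cables$anchor_row == root_row, NA_integer_,
                                cable_of_end_node[cables$anchor_row])
  # collapse zero-length cables by re-pointing children at their parent
  while (any(zero)) {
    for (z in which(zero)) {
      kids <- which(!is.na(cables$parent_cable) &
                    cables$parent_cable == cables$cable_id[z])
      cables$parent_cable[kids] <- cables$parent_cable[z]
    }
    keep <- !zero
    edge_map <- edge_map[edge_map$cable_id %in% cables$cable_id[keep], ]
    cables <- cables[keep, ]
    zero <- rep(FALSE, nrow(cables))
  }

  out <- cables[, c("cable_id", "parent_cable", "length", "diameter",
                    "n_nodes")]
  structure(out,
            class = c("cable_set", class(out)),
            soma_radius = soma_radius,
            edge_map = edge_map)
}

#' Discretize cables into an electrical compartmental model
#'
#' Splits every cable into compartments of equal length such that each
#' compartment's electrotonic length (physical length over the space constant
#' `lambda = sqrt(R_m d / (4 R_a))`) falls below `max_elec_length`:
#' `n = max(1, ceiling(L_elec / max_elec_length))`. Cables whose total
#' electrotonic length falls below `min_elec_length` are merged upward into
#' their parent's distal compartment (with a message). If the source
#' morphology had a soma, it is attached as a single cylindrical compartment
#' with length = diameter = the soma diameter.
#'
#' @param cables A `cable_set` from [inflate()].
#' @param membrane A [membrane_params()].
#' @param max_elec_length Upper bound on per-compartment electrotonic length.
#' @param min_elec_length Lower bound below which a cable is merged upward.
#' @return A `compartmental_model` with a compartment tibble (`index`,
#'   `cable_id`, `pos_mid`, `length`, `diameter`, `area_um2`, `parent`), the
#'   soma index, the membrane parameters, and precomputed electrical vectors
#'   (capacitance nF, leak and axial conductances uS).
#' @export
remesh <- function(cables, membrane, max_elec_length = 0.1,
                   min_elec_length = 1e-4) {
  stopifnot(inherits(cables, "cable_set"))
  soma_radius <- attr(cables, "soma_radius")
  has_soma <- !is.na(soma_radius)

  comp <- list()
  if (has_soma) {
    d <- 2 * soma_radius
    comp[[1]] <- tibble::tibble(cable_id = 0L, pos_mid = 0, length = d,
                                diameter = d, parent = 0L)
  }
  # topological order over cables (parents first); simple repeated sweep,
  # cable counts are small
  ord <- integer(0)
  done <- rep(FALSE, nrow(cables))
  while (!all(done)) {
    ready <- !done & (is.na(cables$parent_cable) |
                      cables$parent_cable %in% cables$cable_id[done])
    if (!any(ready)) abort("cable parentage is cyclic")
    ord <- c(ord, which(ready))
    done[ready] <- TRUE
  }

  distal_comp_of_cable <- integer(max(cables$cable_id))
  comp_range <- vector("list", max(cables$cable_id))
  merged <- 0L
  rows <- if (has_soma) 1L else 0L
  extra_area <- list()   # compartment index -> folded-in membrane area (um^2)

  for (k in ord) {
    cb <- cables[k, ]
    lam <- lambda_um(cb$diameter, membrane)
    l_elec <- cb$length / lam
    parent_comp <- if (is.na(cb$parent_cable)) {
      if (has_soma) 1L else 0L
    } else {
      distal_comp_of_cable[cb$parent_cable]
    }
    if (l_elec < min_elec_length && parent_comp > 0L) {
      # merge upward: this cable's membrane joins the parent compartment
      merged <- merged + 1L
      distal_comp_of_cable[cb$cable_id] <- parent_comp
      comp_range[[cb$cable_id]] <- list(comp0 = parent_comp, n = 1L,
                                        clen = max(cb$length, 1e-9))
      key <- as.character(parent_comp)
      extra_area[[key]] <- (extra_area[[key]] %||% 0) +
        pi * cb$diameter * cb$length
      next
    }
    n <- max(1L, ceiling(l_elec / max_elec_length))
    clen <- cb$length / n
    idx <- rows + seq_len(n)
    comp[[length(comp) + 1]] <- tibble::tibble(
      cable_id = cb$cable_id,
      pos_mid = (seq_len(n) - 0.5) * clen,
      length = clen,
      diameter = cb$diameter,
      parent = c(parent_comp, idx[-n])
    )
    distal_comp_of_cable[cb$cable_id] <- idx[n]
    comp_range[[cb$cable_id]] <- list(comp0 = idx[1], n = n, clen = clen)
    rows <- rows + n
  }
  if (merged > 0) {
    message(merged, " cable(s) below the minimum electrotonic length were ",
            "merged into their parent compartment")
  }

  compartments <- dplyr::bind_rows(comp)
  compartments$area_um2 <- pi * compartments$diameter * compartments$length
  for (key in names(extra_area)) {
    i <- as.integer(key)
    compartments$area_um2[i] <- compartments$area_um2[i] + extra_area[[key]]
  }
  compartments <- dplyr::mutate(compartments,
                                index = dplyr::row_number(),
                                .before = 1)

  area_cm2 <- compartments$area_um2 * 1e-8
  cap_nF <- membrane$c_m * area_cm2 * 1e3
  g_leak_uS <- area_cm2 / membrane$r_m * 1e3
  # axial conductance to parent: two half-cylinder resistances in series
  half_r <- function(l_um, d_um) {
    membrane$r_a * (l_um * 1e-4 / 2) / (pi * (d_um * 1e-4)^2 / 4)
  }
  hr <- half_r(compartments$length, compartments$diameter)
  g_ax_uS <- numeric(nrow(compartments))
  pp <- compartments$parent
  nz <- pp > 0
  g_ax_uS[nz] <- 1e6 / (hr[nz] + hr[pp[nz]])

  structure(
    list(
      compartments = compartments,
      soma_index = if (has_soma) 1L else 1L,
      membrane = membrane,
      cap_nF = cap_nF,
      g_leak_uS = g_leak_uS,
      g_ax_uS = g_ax_uS,
      comp_range = comp_range,
      max_elec_length = max_elec_length
    ),
    class = "compartmental_model"
  )
}

#' @exportS3Method base::print
print.compartmental_model <- function(x, ...) {
  cat("<compartmental_model> ", nrow(x$compartments), " compartments, ",
      length(unique(x$compartments$cable_id)) - any(x$compartments$cable_id == 0),
      " cables, total membrane area ",
      format(sum(x$compartments$area_um2), digits = 6), " um^2\n", sep = "")
  invisible(x)
}

#' @export
glance.compartmental_model <- function(x, ...) {
  tibble::tibble(
    n_compartments = nrow(x$compartments),
    n_cables = length(x$comp_range) -
      sum(purrr::map_lgl(x$comp_range, is.null)),
    total_area_um2 = sum(x$compartments$area_um2),
    total_length_um = sum(x$compartments$length[x$compartments$cable_id > 0]),
    r_in_soma_mohm = input_resistance(x, x$soma_index)
  )
}

# Map a (cable_id, arc position) pair to a compartment index.
compartment_at <- function(model, cable_id, pos) {
  rng <- model$comp_range[cable_id]
  purrr::map2_int(rng, pos, function(r, p) {
    if (is.null(r)) abort("cable not present in model")
    k <- pmin(r$n, pmax(1L, ceiling(p / r$clen)))
    as.integer(r$comp0 + k - 1L)
  })
}

#' Build a compartmental model straight from a morphology
#'
#' Convenience wrapper: [inflate()] then [remesh()].
#'
#' @inheritParams inflate
#' @inheritParams remesh
#' @export
build_model <- function(morph, membrane = membrane_params(),
                        max_elec_length = 0.1) {
  remesh(inflate(morph), membrane, max_elec_length = max_elec_length)
}
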