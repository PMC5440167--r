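# Small fixtures shared across test files; everything built in code.

# Unbranched chain along x: n nodes, given spacing (um) and radius.
chain_morph <- function(n = 5, spacing = 10, radius = 0.5, soma = FALSE) {
  morphology(tibble::tibble(
    id = seq_len(n),
    parent_id = c(-1L, seq_len(n - 1)),
    x = (seq_len(n) - 1) * spacing,
    y = 0, z = 0,
    radius = radius,
    label = c(if (soma) 1L else 3L, rep(3L, n - 1))
  ))
}

# Y-shaped tree: stem along x then two arms, arm lengths in um.
y_tree_morph <- function(stem = 3, arm1 = 4, arm2 = 5, radius = 0.5) {
  morphology(tibble::tibble(
    id = 1:5,
    parent_id = c(-1L, 1L, 2L, 2L, 3L),
    x = c(0, stem, stem + arm1, stem, stem + arm1),
    y = c(0, 0, 0, arm2, 1e-12),
    z = 0,
    radius = radius,
    label = 3L
  ))
}

# A single sealed cylinder as a compartmental model (no soma).
cylinder_model <- function(length_um, diameter_um = 1,
                           membrane = membrane_params(),
                           max_elec_length = 0.1) {
  n <- max(3L, ceiling(length_um / 5))
  m <- chain_morph(n = n + 1, spacing = length_um / n,
                   radius = diameter_um / 2)
  remesh(inflate(m), membrane, max_elec_length = max_elec_length)
}

# Memoized medium-size synthetic PN used by several electrophysiology tests.
pn_fixture_env <- new.env(parent = emptyenv())
pn_fixture <- function() {
  if (is.null(pn_fixture_env$fx)) {
    tb <- generate_circuit(circuit_spec(seed = 7))
    mo <- generate_morphology(morphology_spec(seed = 3))
    cab <- inflate(mo)
    mod <- remesh(cab, membrane_params())
    sites <- bind_sites(place_synapses(mo, tb, "PN_L_1", seed = 11), cab, mod)
    sites$orn_side <- ifelse(grepl("_L_", sites$orn_id), "L", "R")
    pn_fixture_env$fx <- list(table = tb, morph = mo, cables = cab,
                              model = mod, sites = sites)
  }
  pn_fixture_env$fx
}

# Memoized full circuit (5 PN models) for the classification tasks.
circuit_fixture <- function() {
  if (is.null(pn_fixture_env$circuit)) {
    tb <- generate_circuit(circuit_spec(seed = 5))
    pn_fixture_env$circuit <- list(
      table = tb,
      models = build_circuit_models(tb, morphology_spec(),
                                    membrane_params(), seed = 5)
    )
  }
  pn_fixture_env$circuit
}
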