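test_that("SWC round trip is the identity up to float formatting", {
  m <- y_tree_morph()
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2$parent_id, m$parent_id)
  expect_equal(m2$x, m$x, tolerance = 1e-9)
  expect_equal(m2$radius, m$radius, tolerance = 1e-9)
  # write(read(f)) == read(f) structurally
  path2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(m2, path2)
  expect_equal(read_swc(path2), m2)
})

test_that("a 3-node toy SWC parses to a tree with 2 edges", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# toy", "1 1 0 0 0 1.0 -1", "2 3 5 0 0 0.5 1",
               "3 3 10 0 0 0.5 2"), path)
  m <- read_swc(path)
  expect_equal(nrow(m), 3)
  expect_equal(total_path_length(m), 10)
})

test_that("malformed skeletons fail loudly and name the offender", {
  bad_parent <- tibble::tibble(id = 1:2, parent_id = c(-1L, 99L),
                               x = 0, y = 0, z = 0, radius = 1, label = 3L)
  expect_error(morphology(bad_parent), "missing parent 99")
  dup <- tibble::tibble(id = c(1L, 1L), parent_id = c(-1L, 1L),
                        x = 0, y = 0, z = 0, radius = 1, label = 3L)
  expect_error(morphology(dup), "duplicate node id")
  cyc <- tibble::tibble(id = 1:3, parent_id = c(-1L, 3L, 2L),
                        x = 0, y = 0, z = 0, radius = 1, label = 3L)
  expect_error(morphology(cyc), "cyclic")
  two_roots <- tibble::tibble(id = 1:2, parent_id = c(-1L, -1L),
                              x = 0, y = 0, z = 0, radius = 1, label = 3L)
  expect_error(morphology(two_roots), "exactly one root")
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 1.0 -1", "2 3 5 0 0 0.5"), path)
  expect_error(read_swc(path), "line 2")
})

test_that("total path length sums Euclidean edges and respects subtrees", {
  expect_equal(total_path_length(chain_morph(2, spacing = 10)), 10)
  y <- y_tree_morph(stem = 3, arm1 = 4, arm2 = 5)
  expect_equal(total_path_length(y), 12)
  # subtree at the branch point excludes the upstream stem
  expect_equal(total_path_length(y, subtree_root = 2), 9)
})

test_that("inflate produces one cable per inter-branch path with mean-radius diameter", {
  one <- inflate(chain_morph(5, spacing = 10, radius = 0.5))
  expect_equal(nrow(one), 1)
  expect_equal(one$diameter, 1.0)
  expect_equal(one$length, 40)

  # two radii on one path average to diameter 1.0
  m <- morphology(tibble::tibble(id = 1:2, parent_id = c(-1L, 1L),
                                 x = c(0, 10), y = 0, z = 0,
                                 radius = c(0.4, 0.6), label = 3L))
  expect_equal(inflate(m)$diameter, 1.0)

  y <- inflate(y_tree_morph())
  expect_equal(nrow(y), 3)
  # the two arm cables hang off the stem cable
  stem_id <- y$cable_id[is.na(y$parent_cable)]
  expect_length(stem_id, 1)
  expect_true(all(y$parent_cable[!is.na(y$parent_cable)] == stem_id))
})

test_that("the space constant and compartment counts match the closed form", {
  mb <- membrane_params()
  expect_equal(glomsim:::lambda_um(1, mb), 442.06, tolerance = 1e-4)
  # a cable of one space constant (d = 1 um) -> 10 compartments
  lam <- glomsim:::lambda_um(1, mb)
  mod <- cylinder_model(0.995 * lam, diameter_um = 1)
  expect_equal(nrow(mod$compartments), 10)
  # a short cable (L_elec = 0.05) stays one compartment
  mod2 <- cylinder_model(0.05 * 442.06, diameter_um = 1)
  expect_equal(nrow(mod2$compartments), 1)
})

test_that("remeshing conserves cable length and membrane area", {
  mo <- generate_morphology(morphology_spec(seed = 21))
  cab <- inflate(mo)
  for (bound in c(0.1, 0.05)) {
    mod <- remesh(cab, membrane_params(), max_elec_length = bound)
    dend <- mod$compartments[mod$compartments$cable_id > 0, ]
    expect_equal(sum(dend$length), sum(cab$length), tolerance = 1e-3)
    expect_equal(sum(dend$area_um2), sum(pi * cab$diameter * cab$length),
                 tolerance = 1e-3)
  }
})

test_that("soma-labelled roots become their own compartment", {
  m <- chain_morph(5, spacing = 10, radius = 0.5, soma = TRUE)
  cab <- inflate(m)
  expect_equal(attr(cab, "soma_radius"), 0.5)
  mod <- remesh(cab, membrane_params())
  expect_equal(mod$compartments$cable_id[1], 0)
  expect_equal(mod$compartments$length[1], 1.0)   # length = diameter = 2r
})

test_that("potential connection length follows the geometric construction", {
  dend <- chain_morph(101, spacing = 1)     # 100 um along x
  # parallel axon at 0.3 um offset covering half the dendrite extent
  axon_half <- morphology(tibble::tibble(
    id = 1:51, parent_id = c(-1L, 1:50),
    x = 0:50, y = 0.3, z = 0, radius = 0.2, label = 2L))
  got <- potential_connection_length(dend, axon_half, radius = 0.5)
  expect_lt(abs(got - 50), 1)

  # coincident axon covers the whole dendrite
  axon_full <- chain_morph(101, spacing = 1)
  expect_equal(potential_connection_length(dend, axon_full, radius = 0.5),
               100, tolerance = 1e-6)

  # a far-away axon contributes nothing
  axon_far <- morphology(tibble::tibble(
    id = 1:11, parent_id = c(-1L, 1:10),
    x = 0:10, y = 50, z = 0, radius = 0.2, label = 2L))
  expect_equal(potential_connection_length(dend, axon_far, radius = 0.5), 0)

  # monotone non-decreasing in the criterion radius
  expect_gte(potential_connection_length(dend, axon_half, radius = 1.0), got)
})
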