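test_that("surface meshes sit on scaled spheres and exclude buried points", {
  one <- toy_topology(0, 0, 0, fragment = "W124")
  mesh <- build_surface(topo_coords(one), one, "W124", scale = 2,
                        points_per_atom = 100)
  expect_equal(nrow(mesh$points), 100)
  r <- sqrt(rowSums(mesh$points^2))
  expect_true(all(abs(r - 2 * 1.7) < 1e-9))  # carbon Bondi radius 1.7

  # two overlapping atoms: points inside the partner sphere are culled
  two <- toy_topology(c(0, 1.5), c(0, 0), c(0, 0),
                      fragment = c("W124", "W124"))
  m2 <- topo_coords(two)
  mesh2 <- build_surface(m2, two, "W124", scale = 2, points_per_atom = 100)
  expect_lt(nrow(mesh2$points), 200)
  d_to_1 <- sqrt(rowSums(sweep(mesh2$points, 2, m2[1, ])^2))
  d_to_2 <- sqrt(rowSums(sweep(mesh2$points, 2, m2[2, ])^2))
  own_1 <- mesh2$owner == 1
  expect_true(all(d_to_2[own_1] > 2 * 1.7))
  expect_true(all(d_to_1[!own_1] > 2 * 1.7))
  # deterministic under a fixed seed
  mesh2b <- build_surface(m2, two, "W124", scale = 2, points_per_atom = 100)
  expect_identical(mesh2$points, mesh2b$points)
  expect_error(build_surface(m2, two, "W124", points_per_atom = 8), ">= 16")
})

test_that("retained surface fraction agrees with dense sampling within 3%", {
  two <- toy_topology(c(0, 2.0), c(0, 0), c(0, 0),
                      fragment = c("W124", "W124"))
  m <- topo_coords(two)
  frac <- function(ppa) {
    nrow(build_surface(m, two, "W124", scale = 2,
                       points_per_atom = ppa)$points) / (2 * ppa)
  }
  expect_equal(frac(200), frac(2000), tolerance = 0.03)
})

test_that("surface potential reproduces the Coulomb closed form and superposes", {
  # one-point mesh 1 A from a unit charge
  topo <- toy_topology(c(0, 1), c(0, 0), c(0, 0),
                       fragment = c("W124", "protein_rest"),
                       charge = c(0, 1))
  m <- topo_coords(topo)
  mesh <- list(points = rbind(c(0, 0, 0)), owner = 1L,
               fragment = "W124", scale = 1)
  expect_equal(surface_potential(m, topo, mesh, source_atoms = 2),
               14.399645)

  # superposition of two sources
  topo2 <- toy_topology(c(0, 1, 0), c(0, 0, 2), c(0, 0, 0),
                        fragment = c("W124", "protein_rest",
                                     "protein_rest"),
                        charge = c(0, 1, -0.5))
  m2 <- topo_coords(topo2)
  p_both <- surface_potential(m2, topo2, mesh, source_atoms = c(2, 3))
  p_1 <- surface_potential(m2, topo2, mesh, source_atoms = 2)
  p_2 <- surface_potential(m2, topo2, mesh, source_atoms = 3)
  expect_equal(p_both, p_1 + p_2, tolerance = 1e-14)

  # degeneracy guard
  topo3 <- toy_topology(c(0, 0), c(0, 0), c(0, 0),
                        fragment = c("W124", "protein_rest"),
                        charge = c(0, 1))
  expect_error(surface_potential(topo_coords(topo3), topo3, mesh,
                                 source_atoms = 2), "coincides")
})

test_that("mesh-averaged potential equals a brute-force double loop to 1e-10 V", {
  set.seed(202)
  n_src <- 30
  frag <- toy_topology(
    x = c(rnorm(3, 0, 0.8), runif(n_src, 5, 15)),
    y = c(rnorm(3, 0, 0.8), runif(n_src, -10, 10)),
    z = c(rnorm(3, 0, 0.8), runif(n_src, -10, 10)),
    fragment = c(rep("W124", 3), rep("protein_rest", n_src)),
    charge = c(0, 0, 0, runif(n_src, -1, 1)))
  m <- topo_coords(frag)
  mesh <- build_surface(m, frag, "W124", scale = 2, points_per_atom = 17)
  expect_gte(nrow(mesh$points), 17)
  src <- 4:(3 + n_src)
  got <- surface_potential(m, frag, mesh, source_atoms = src)
  brute <- 0
  for (p in seq_len(nrow(mesh$points))) {
    for (s in src) {
      d <- sqrt(sum((mesh$points[p, ] - m[s, ])^2))
      brute <- brute + 14.399645 * frag$atoms$charge[s] / d
    }
  }
  brute <- brute / nrow(mesh$points)
  expect_equal(got, brute, tolerance = 1e-10)
})

test_that("doubling source charges doubles potentials and energies", {
  set.seed(7)
  topo <- toy_topology(
    x = c(0, 0.5, runif(10, 4, 9)), y = c(0, 0.5, runif(10, -3, 3)),
    z = c(0, 0, runif(10, -3, 3)),
    fragment = c("W124", "W124", rep("solvent_free_rest", 0),
                 rep("protein_rest", 10)),
    charge = c(0, 0, runif(10, -0.8, 0.8)))
  m <- topo_coords(topo)
  mesh <- build_surface(m, topo, "W124", points_per_atom = 32)
  p1 <- surface_potential(m, topo, mesh, source_atoms = 3:12)
  p2 <- surface_potential(m, topo, mesh, source_atoms = 3:12,
                          charges = 2 * topo$atoms$charge)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
  e1 <- stabilization_energy(c(W124 = 1), c(W124 = p1))
  e2 <- stabilization_energy(c(W124 = 1), c(W124 = p2))
  expect_equal(e2, 2 * e1)
})

test_that("far-field mesh average approaches the centroid point-charge limit", {
  # a compact 5-atom fragment probed by a unit charge 50 A away
  set.seed(91)
  topo <- toy_topology(
    x = c(rnorm(5, 0, 0.7), 50), y = c(rnorm(5, 0, 0.7), 0),
    z = c(rnorm(5, 0, 0.7), 0),
    fragment = c(rep("W124", 5), "protein_rest"),
    charge = c(rep(0, 5), 1))
  m <- topo_coords(topo)
  mesh <- build_surface(m, topo, "W124", points_per_atom = 64)
  got <- surface_potential(m, topo, mesh, source_atoms = 6)
  d_cen <- sqrt(sum((colMeans(m[1:5, ]) - m[6, ])^2))
  expect_equal(got, 14.399645 / d_cen, tolerance = 0.01)
})

test_that("partitioned traces are additive and exhaustively grouped", {
  sys <- generate_system(synthetic_config(n_frames = 6, n_waters = 12,
                                          seed = 19))
  pt <- partition_trace(sys$trajectory, sys$topology, frames = 1:6,
                        points_per_atom = 32)
  comp124 <- rowSums(as.data.frame(pt)[, grep("^phi124_", names(pt))])
  comp122 <- rowSums(as.data.frame(pt)[, grep("^phi122_", names(pt))])
  expect_equal(pt$phi124, comp124, tolerance = 1e-9)
  expect_equal(pt$phi122, comp122, tolerance = 1e-9)
  expect_equal(pt$dphi, pt$phi124 - pt$phi122, tolerance = 1e-12)
  expect_equal(pt$dphi, pt$dphi_solv + pt$dphi_prot, tolerance = 1e-9)

  # only-solvent charges: total equals the solvent component
  topo0 <- sys$topology
  zeroed <- topo0$atoms$charge
  zeroed[!topo0$atoms$is_solvent] <- 0
  topo0$atoms$charge <- zeroed
  pt0 <- partition_trace(sys$trajectory, topo0, frames = 1:2,
                         points_per_atom = 32)
  expect_equal(pt0$phi124, pt0$phi124_solvent, tolerance = 1e-12)
  expect_equal(pt0$dphi, pt0$dphi_solv, tolerance = 1e-12)
  expect_true(all(abs(pt0$phi124_protein_rest) < 1e-15))

  # overlapping partitions are rejected
  idx <- fragment_atoms(sys$topology, "solvent")
  expect_error(
    partition_trace(sys$trajectory, sys$topology,
                    partition = list(a = idx, b = idx)),
    "overlap")
})

test_that("stabilization energy is the potential-charge dot product", {
  expect_equal(stabilization_energy(c(W124 = 1), c(W124 = -0.18)), -0.18)
  expect_equal(stabilization_energy(c(W124 = 0, dmp = 0),
                                    c(W124 = 3, dmp = -2)), 0)
  q <- c(W124 = 0.7, W122 = 0.3, dmp = -0.45)
  phi <- c(W124 = -1.2, W122 = 0.4, dmp = 2.0)
  expect_equal(stabilization_energy(q, phi),
               0.7 * -1.2 + 0.3 * 0.4 + -0.45 * 2.0)
  expect_error(stabilization_energy(c(W124 = 1), c(W122 = 1)), "match")
})
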