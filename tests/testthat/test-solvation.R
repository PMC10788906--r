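test_that("waters go to the nearest residue with first-listed tie-breaks", {
  rows <- dplyr::bind_rows(
    tibble::tibble(element = "C", x = 0, y = 0, z = 0, fragment = "W122"),
    tibble::tibble(element = "C", x = 5, y = 0, z = 0, fragment = "W124"),
    water_rows(2, 0, 0, "WAT1"),   # 2 A from W122, 3 A from W124
    water_rows(2.5, 0, 0, "WAT2")  # equidistant
  )
  topo <- rows_topology(rows)
  m <- topo_coords(topo)
  asg <- proximal_assign(m, topo, c("W122", "W124"))
  expect_equal(asg$residue, c("W122", "W122"))
  expect_equal(asg$distance[1], 2.0)
  # swapping the priority order flips only the tie
  asg2 <- proximal_assign(m, topo, c("W124", "W122"))
  expect_equal(asg2$residue, c("W122", "W124"))
  expect_error(proximal_assign(m, topo, character()), "empty")
})

test_that("assignment matches exhaustive search and partitions all waters", {
  set.seed(13)
  solute <- dplyr::bind_rows(
    tibble::tibble(element = "C", x = rnorm(5), y = rnorm(5), z = rnorm(5),
                   fragment = "W124"),
    tibble::tibble(element = "C", x = rnorm(5, 4), y = rnorm(5),
                   z = rnorm(5), fragment = "W122"),
    tibble::tibble(element = "C", x = rnorm(5, 2), y = rnorm(5, 4),
                   z = rnorm(5), fragment = "Q107"))
  waters <- purrr::map_dfr(1:50, function(w)
    water_rows(runif(1, -4, 8), runif(1, -4, 8), runif(1, -4, 4),
               paste0("WAT", w)))
  topo <- rows_topology(dplyr::bind_rows(solute, waters))
  m <- topo_coords(topo)
  residues <- c("W124", "W122", "Q107")
  asg <- proximal_assign(m, topo, residues)
  expect_equal(nrow(asg), 50)

  ox <- which(topo$atoms$is_solvent & topo$atoms$element == "O")
  for (i in seq_along(ox)) {
    dists <- vapply(residues, function(res) {
      idx <- fragment_atoms(topo, res, heavy_only = TRUE)
      min(sqrt(rowSums(sweep(m[idx, , drop = FALSE], 2, m[ox[i], ])^2)))
    }, numeric(1))
    expect_equal(asg$residue[i], residues[which.min(dists)])
    expect_equal(asg$distance[i], min(dists))
  }
  # partition property: per-residue counts sum to the water total
  expect_equal(sum(table(asg$residue)), 50)
})

test_that("proximal g(r) is 1 for ideal-gas waters and scales with density", {
  # one residue atom at the origin, waters uniform in a box at density rho
  set.seed(31)
  box_half <- 9
  n_w <- 600
  rho <- n_w / (2 * box_half)^3
  waters <- purrr::map_dfr(seq_len(n_w), function(w)
    water_rows(runif(1, -box_half, box_half),
               runif(1, -box_half, box_half),
               runif(1, -box_half, box_half), paste0("WAT", w)))
  topo <- rows_topology(dplyr::bind_rows(
    tibble::tibble(element = "C", x = 0, y = 0, z = 0, fragment = "W124"),
    waters))
  m <- topo_coords(topo)
  prof <- proximal_gr(m, topo, "W124", bin_width = 0.5, r_max = 6,
                      bulk_density = rho,
                      box = cbind(rep(-box_half, 3), rep(box_half, 3)),
                      mc_samples = 1e5, seed = 8)
  # single-frame Poisson counts: compare the mean over bins beyond the
  # first (tiny-volume) shells
  usable <- prof$r_mid > 2
  expect_equal(mean(prof$g[usable]), 1, tolerance = 0.1)

  # doubling the density halves g exactly
  prof2 <- proximal_gr(m, topo, "W124", bin_width = 0.5, r_max = 6,
                       bulk_density = 2 * rho,
                       box = cbind(rep(-box_half, 3), rep(box_half, 3)),
                       mc_samples = 1e5, seed = 8)
  expect_equal(prof2$g, prof$g / 2, tolerance = 1e-12)

  # no waters at all: g = 0 wherever defined
  topo0 <- rows_topology(
    tibble::tibble(element = "C", x = 0, y = 0, z = 0, fragment = "W124"))
  prof0 <- proximal_gr(topo_coords(topo0), topo0, "W124", bin_width = 0.5,
                       r_max = 6, bulk_density = rho,
                       box = cbind(rep(-box_half, 3), rep(box_half, 3)),
                       mc_samples = 1e4, seed = 8)
  expect_true(all(prof0$g[!is.na(prof0$g)] == 0))
  expect_s3_class(prof0, "solvation_profile")
})

test_that("proximal volume estimator is seed-reproducible", {
  topo <- rows_topology(dplyr::bind_rows(
    tibble::tibble(element = "C", x = 0, y = 0, z = 0, fragment = "W124"),
    water_rows(2, 0, 0, "WAT1")))
  m <- topo_coords(topo)
  p1 <- proximal_gr(m, topo, "W124", mc_samples = 1e4, seed = 4,
                    box = cbind(rep(-5, 3), rep(5, 3)))
  p2 <- proximal_gr(m, topo, "W124", mc_samples = 1e4, seed = 4,
                    box = cbind(rep(-5, 3), rep(5, 3)))
  expect_identical(p1$volume, p2$volume)
})

test_that("coordination numbers count cutoff waters and partition at infinity", {
  rows <- dplyr::bind_rows(
    tibble::tibble(element = "C", x = 0, y = 0, z = 0, fragment = "W124"),
    tibble::tibble(element = "C", x = 6, y = 0, z = 0, fragment = "W122"),
    water_rows(0, 2, 0, "WAT1"))
  topo <- rows_topology(rows)
  m <- topo_coords(topo)
  expect_equal(coordination_number(m, topo, "W124",
                                   residues = c("W124", "W122"),
                                   r_cut = 2.5), 1)
  expect_equal(coordination_number(m, topo, "W124",
                                   residues = c("W124", "W122"),
                                   r_cut = 1.5), 0)

  # sum over residues of CN(infinity) equals the water count, every frame
  sys <- generate_system(synthetic_config(n_frames = 10, n_waters = 25,
                                          seed = 14))
  residues <- c("W124", "W122", "dmp", "Q107")
  for (k in c(1, 5, 10)) {
    cn_tot <- sum(vapply(residues, function(res)
      coordination_number(sys$trajectory, sys$topology, res,
                          residues = residues, r_cut = 1e6, frames = k),
      numeric(1)))
    expect_equal(cn_tot, 25)
  }
  # CN is monotone non-decreasing in the cutoff
  cns <- vapply(c(2, 3, 4, 6, 10), function(rc)
    coordination_number(sys$trajectory, sys$topology, "W124",
                        residues = residues, r_cut = rc, frames = 1:5),
    numeric(1))
  expect_true(all(diff(cns) >= 0))
})

test_that("hydrogen-bond bridges honor distance and angle criteria", {
  # direct N-H...O at 2.9 A, angle ~180
  rows <- tibble::tibble(
    element = c("N", "H", "O"),
    x = c(0, 1.0, 2.9), y = 0, z = 0,
    fragment = c("W122", "W122", "SAL"))
  topo <- rows_topology(rows)
  m <- topo_coords(topo)
  paths <- hbond_bridges(m, topo, donor = 1, acceptor = 3)
  expect_length(paths, 1)
  expect_equal(paths[[1]], c(1L, 3L))

  # bad angle: hydrogen off to the side (~90 degrees)
  m2 <- m
  m2[2, ] <- c(0, 1.0, 0)
  expect_length(hbond_bridges(m2, topo, donor = 1, acceptor = 3), 0)

  # beyond the distance cutoff
  m3 <- m
  m3[3, 1] <- 3.8
  expect_length(hbond_bridges(m3, topo, donor = 1, acceptor = 3), 0)

  expect_error(hbond_bridges(m, topo, donor = 3, acceptor = 1),
               "no attached hydrogen")
  expect_error(hbond_bridges(m, topo, donor = 1, acceptor = 3,
                             max_waters = 3), "max_waters")
})

test_that("two-water bridge chains match hand enumeration", {
  # amide O ... w1 ... w2 ... H-N chain on a line, 2.8 A spacing
  rows <- dplyr::bind_rows(
    tibble::tibble(element = c("N", "H"), x = c(0, 1.0), y = 0, z = 0,
                   fragment = "W122"),
    water_rows(2.8, 0, 0, "WAT1"),
    water_rows(5.6, 0, 0, "WAT2"),
    tibble::tibble(element = "O", x = 8.4, y = 0, z = 0, fragment = "SAL"))
  topo <- rows_topology(rows)
  m <- topo_coords(topo)
  donor <- 1L
  acceptor <- which(topo$atoms$fragment == "SAL")
  paths <- hbond_bridges(m, topo, donor = donor, acceptor = acceptor,
                         max_waters = 2)
  # exactly one path: N -> w1 -> w2 -> O (w2 alone is out of donor range,
  # w1 alone is out of acceptor range)
  expect_length(paths, 1)
  o1 <- which(topo$atoms$residue_tag == "WAT1" &
                topo$atoms$element == "O")
  o2 <- which(topo$atoms$residue_tag == "WAT2" &
                topo$atoms$element == "O")
  expect_equal(paths[[1]], c(donor, o1, o2, acceptor))
  # forbidding intervening waters removes it
  expect_length(hbond_bridges(m, topo, donor = donor, acceptor = acceptor,
                              max_waters = 0), 0)
})
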