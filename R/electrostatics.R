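#' Quasi-uniform points on a unit sphere
#'
#' Fibonacci lattice with a seeded random rigid rotation, so point sets are
#' quasi-uniform, deterministic for a fixed seed, and free of pole
#' alignment artifacts between atoms.
#'
#' @param n Number of points.
#' @param seed Integer seed for the rotation.
#' @return `n x 3` matrix of unit vectors.
#' @keywords internal
unit_sphere_points <- function(n, seed = 1) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  pts %*% t(.quat_rotation(q))
}

.quat_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Scaled van der Waals surface mesh of a fragment
#'
#' Distributes quasi-uniform points on spheres of radius
#' `scale * vdw_radius` around every heavy atom of the fragment and keeps
#' only the points lying strictly outside all other scaled spheres of the
#' fragment — the probe surface on which environment potentials are
#' averaged. Indole hydrogens are excluded from mesh construction.
#'
#' @param coords `n_atoms x 3` coordinate matrix for one frame.
#' @param topology A `topology`.
#' @param fragment Fragment name.
#' @param scale Dimensionless radius multiplier (default 2.0, probing the
#'   near-solvent region just outside the contact shell).
#' @param points_per_atom Points per atom sphere, at least 16 (default 64).
#' @param seed Seed for the lattice rotation (default 1).
#' @return A `surface_mesh`: list with `points` (`m x 3` matrix), `owner`
#'   (atom row index per point), `fragment`, `scale`.
#' @export
build_surface <- function(coords, topology, fragment, scale = 2.0,
                          points_per_atom = 64, seed = 1) {
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  if (points_per_atom < 16) stop("points_per_atom must be >= 16",
                                 call. = FALSE)
  idx <- fragment_atoms(topology, fragment, heavy_only = TRUE)
  if (!length(idx)) stop("fragment ", fragment, " has no heavy atoms",
                         call. = FALSE)
  radii <- scale * topology$atoms$vdw_radius[idx]
  centers <- coords[idx, , drop = FALSE]
  sphere <- unit_sphere_points(points_per_atom, seed = seed)
  pts <- list()
  owner <- list()
  for (k in seq_along(idx)) {
    p <- sweep(sphere * radii[k], 2, centers[k, ], "+")
    if (length(idx) > 1) {
      others <- setdiff(seq_along(idx), k)
      d <- .cross_dist(p, centers[others, , drop = FALSE])
      keep <- apply(d > rep(radii[others], each = nrow(d)), 1, all)
      # strict exteriority: a point on another sphere's surface is dropped
      p <- p[keep, , drop = FALSE]
    }
    pts[[k]] <- p
    owner[[k]] <- rep(idx[k], nrow(p))
  }
  structure(
    list(points = do.call(rbind, pts),
         owner = unlist(owner),
         fragment = fragment,
         scale = scale),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s: %d points (scale %.2f) on %d atoms\n",
              x$fragment, nrow(x$points), x$scale, length(unique(x$owner))))
  invisible(x)
}

#' Surface-averaged Coulomb potential
#'
#' Mean over mesh points of the point-charge potential
#' \eqn{k_e \sum_i q_i / d_i} with \eqn{k_e = 14.399645} V Angstrom / e.
#' Sources are restricted to `source_atoms` minus `exclude_atoms`; the
#' result is linear in the charges.
#'
#' @param coords `n_atoms x 3` coordinate matrix.
#' @param topology A `topology` (supplies charges).
#' @param mesh A `surface_mesh` from [build_surface()].
#' @param source_atoms Integer row indices of source atoms.
#' @param exclude_atoms Row indices removed from the sources
#'   (default none).
#' @param charges Optional numeric vector overriding
#'   `topology$atoms$charge` (length `n_atoms`).
#' @return Potential in volts.
#' @export
surface_potential <- function(coords, topology, mesh, source_atoms,
                              exclude_atoms = integer(), charges = NULL) {
  src <- setdiff(source_atoms, exclude_atoms)
  if (!length(src)) return(0)
  q <- (charges %||% topology$atoms$charge)[src]
  d <- .cross_dist(mesh$points, coords[src, , drop = FALSE])
  if (any(d < 1e-6)) {
    hit <- src[which(apply(d < 1e-6, 2, any))[1]]
    stop(sprintf("source atom %d coincides with a mesh point (d < 1e-6 A)",
                 topology$atoms$atom_id[hit]), call. = FALSE)
  }
  mean((1 / d) %*% q) * phys_constants$k_e
}

#' Partitioned surface-potential trace along a trajectory
#'
#' Per frame, rebuilds the scaled vdW meshes of both indoles on the current
#' coordinates and evaluates the potential generated by every source group
#' of a disjoint partition of the environment (all atoms except the two
#' indoles). The default partition separates solvent, the reduced
#' sensitizer (`Re_minus`), `SAL`, `Q107`, and the remaining protein;
#' "protein" aggregates (protein_rest + Re_minus + SAL + Q107), the
#' convention that the protein includes the reduced sensitizer.
#'
#' @param trajectory A `trajectory`.
#' @param topology A `topology`.
#' @param partition Named list of integer atom row-index vectors; groups
#'   must be disjoint and jointly cover all atoms except the two indoles.
#'   Default: solvent, Re_minus, SAL, Q107, protein_rest from the topology.
#' @param scale,points_per_atom,seed Mesh parameters (see
#'   [build_surface()]).
#' @param frames Frame indices (default all).
#' @return A `potential_trace` tibble: one row per frame with `time_fs`,
#'   `phi124`, `phi122` (totals, V), one `phi124_<group>` / `phi122_<group>`
#'   pair per partition group, `dphi` (= phi124 - phi122), `dphi_solv`, and
#'   `dphi_prot`.
#' @export
partition_trace <- function(trajectory, topology, partition = NULL,
                            scale = 2.0, points_per_atom = 64, seed = 1,
                            frames = NULL) {
  i124 <- fragment_atoms(topology, "W124")
  i122 <- fragment_atoms(topology, "W122")
  if (is.null(partition)) {
    partition <- list(
      solvent = fragment_atoms(topology, "solvent"),
      Re_minus = fragment_atoms(topology, "Re_minus"),
      SAL = fragment_atoms(topology, "SAL"),
      Q107 = fragment_atoms(topology, "Q107"),
      protein_rest = fragment_atoms(topology, "protein_rest")
    )
    partition <- partition[lengths(partition) > 0]
  }
  flat <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(flat)) {
    stop("partition groups overlap", call. = FALSE)
  }
  expected <- setdiff(seq_len(n_atoms(topology)), c(i124, i122))
  if (!setequal(flat, expected)) {
    stop("partition must cover exactly all atoms except the two indoles",
         call. = FALSE)
  }
  if (is.null(frames)) frames <- seq_len(n_frames(trajectory))

  solvent_groups <- names(partition)[vapply(partition, function(idx)
    all(topology$atoms$is_solvent[idx]), logical(1))]

  rows <- purrr::map_dfr(frames, function(k) {
    m <- trajectory$coords[[k]]
    mesh124 <- build_surface(m, topology, "W124", scale, points_per_atom,
                             seed)
    mesh122 <- build_surface(m, topology, "W122", scale, points_per_atom,
                             seed)
    comp <- purrr::map(partition, function(idx) {
      c(p124 = surface_potential(m, topology, mesh124, idx),
        p122 = surface_potential(m, topology, mesh122, idx))
    })
    tot124 <- sum(purrr::map_dbl(comp, "p124"))
    tot122 <- sum(purrr::map_dbl(comp, "p122"))
    solv124 <- sum(purrr::map_dbl(comp[solvent_groups], "p124"))
    solv122 <- sum(purrr::map_dbl(comp[solvent_groups], "p122"))
    row <- tibble::tibble(
      frame = k, time_fs = trajectory$times[k],
      phi124 = tot124, phi122 = tot122,
      dphi = tot124 - tot122,
      dphi_solv = solv124 - solv122,
      dphi_prot = (tot124 - solv124) - (tot122 - solv122)
    )
    for (g in names(comp)) {
      row[[paste0("phi124_", g)]] <- comp[[g]][["p124"]]
      row[[paste0("phi122_", g)]] <- comp[[g]][["p122"]]
    }
    row
  })
  class(rows) <- c("potential_trace", class(rows))
  attr(rows, "partition_groups") <- names(partition)
  rows
}

#' Electrostatic stabilization energy of a charge distribution
#'
#' Sum over fragments of (external potential at the fragment) x (fragment
#' charge): \eqn{E = \sum_f \phi_{ext}(f)\, q_f}, in eV when potentials are
#' volts and charges elementary charges. Linear in both arguments.
#'
#' @param fragment_charges Named numeric vector of fragment charges in e.
#' @param external_potentials Named numeric vector of external potentials
#'   in V; names must match `fragment_charges` exactly.
#' @return Energy in eV.
#' @export
#' @examples
#' stabilization_energy(c(W124 = 1), c(W124 = -0.18))  # -0.18 eV
stabilization_energy <- function(fragment_charges, external_potentials) {
  if (!setequal(names(fragment_charges), names(external_potentials)) ||
      length(fragment_charges) != length(external_potentials)) {
    stop("fragment lists of charges and potentials do not match",
         call. = FALSE)
  }
  sum(fragment_charges * external_potentials[names(fragment_charges)])
}
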