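#' Shortest heavy-atom distance between two fragments
#'
#' Minimum pairwise Euclidean distance over the heavy (non-hydrogen) atoms
#' of the two fragments — the contact measure used to follow, e.g., the
#' dmp--W124 approach or the indole--indole gap along a trajectory.
#'
#' @param coords `n_atoms x 3` coordinate matrix for one frame.
#' @param topology A `topology`.
#' @param frag_a,frag_b Fragment names (see [fragment_atoms()]).
#' @return Distance in Angstrom.
#' @export
shortest_heavy_distance <- function(coords, topology, frag_a, frag_b) {
  ia <- fragment_atoms(topology, frag_a, heavy_only = TRUE)
  ib <- fragment_atoms(topology, frag_b, heavy_only = TRUE)
  if (!length(ia) || !length(ib)) {
    stop("fragment without heavy atoms: ",
         if (!length(ia)) frag_a else frag_b, call. = FALSE)
  }
  min(.cross_dist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE]))
}

# all pairwise distances between two coordinate blocks
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# fast row-wise minimum of a matrix
.row_min <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmin(out, m[, j])
  out
}

#' Distance between fragment heavy-atom centroids
#'
#' Center-to-center distances fluctuate less than closest contacts and are
#' the natural abscissa for coupling--distance correlations.
#'
#' @inheritParams shortest_heavy_distance
#' @return Distance in Angstrom.
#' @export
centroid_distance <- function(coords, topology, frag_a, frag_b) {
  ia <- fragment_atoms(topology, frag_a, heavy_only = TRUE)
  ib <- fragment_atoms(topology, frag_b, heavy_only = TRUE)
  if (!length(ia) || !length(ib)) {
    stop("fragment without heavy atoms: ",
         if (!length(ia)) frag_a else frag_b, call. = FALSE)
  }
  ca <- colMeans(coords[ia, , drop = FALSE])
  cb <- colMeans(coords[ib, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Angle between best-fit fragment planes
#'
#' Fits a plane to the heavy atoms of each fragment (principal-axis
#' decomposition of the centered coordinates; the normal is the axis of
#' least variance) and returns the angle between the two normals folded to
#' \[0, 90\] degrees.
#'
#' @inheritParams shortest_heavy_distance
#' @return Angle in degrees in \[0, 90\].
#' @export
plane_angle <- function(coords, topology, frag_a, frag_b) {
  na <- .plane_normal(coords[fragment_atoms(topology, frag_a,
                                            heavy_only = TRUE), , drop = FALSE],
                      frag_a)
  nb <- .plane_normal(coords[fragment_atoms(topology, frag_b,
                                            heavy_only = TRUE), , drop = FALSE],
                      frag_b)
  cosang <- abs(sum(na * nb))
  acos(min(1, cosang)) * 180 / pi
}

.plane_normal <- function(m, tag) {
  if (nrow(m) < 3) {
    stop("fragment ", tag, " has fewer than 3 heavy atoms; no plane",
         call. = FALSE)
  }
  centered <- sweep(m, 2, colMeans(m))
  e <- eigen(crossprod(centered), symmetric = TRUE)
  # degenerate (collinear) sets have two near-zero eigenvalues
  if (e$values[2] < 1e-9 * max(e$values[1], 1e-300)) {
    stop("fragment ", tag, " heavy atoms are collinear; plane undefined",
         call. = FALSE)
  }
  e$vectors[, 3]
}

#' Per-frame geometry observables
#'
#' Maps the three geometric measures over all frames of a trajectory.
#'
#' @param trajectory A `trajectory`.
#' @param topology A `topology`.
#' @param pairs A list of 2-element character vectors naming fragment
#'   pairs; defaults to the dmp--W124 contact and the indole pair.
#' @return Tibble with one row per frame and pair: `frame`, `time_fs`,
#'   `pair`, `d_min` (shortest heavy), `d_cen` (centroid), and `angle_deg`
#'   (best-fit plane angle, NA for fragments with < 3 heavy atoms).
#' @export
geometry_series <- function(trajectory, topology,
                            pairs = list(c("dmp", "W124"),
                                         c("W124", "W122"))) {
  purrr::map_dfr(pairs, function(p) {
    purrr::map2_dfr(seq_along(trajectory$times), trajectory$times,
      function(i, t) {
        m <- trajectory$coords[[i]]
        ang <- tryCatch(plane_angle(m, topology, p[1], p[2]),
                        error = function(e) NA_real_)
        tibble::tibble(frame = i, time_fs = t,
                       pair = paste(p, collapse = "-"),
                       d_min = shortest_heavy_distance(m, topology, p[1], p[2]),
                       d_cen = centroid_distance(m, topology, p[1], p[2]),
                       angle_deg = ang)
      })
  })
}

#' Classify in/out conformers from a distance series
#'
#' Hysteresis thresholding of a contact-distance series (typically
#' dmp--W124): below `threshold - hysteresis` the chromophore is "in",
#' above `threshold + hysteresis` it is "out", and inside the dead band the
#' previous label persists. The first frame takes the nearest side of the
#' threshold.
#'
#' @param d_series Numeric distance series in Angstrom.
#' @param threshold Switching threshold in Angstrom (default 5.0, midway
#'   between the ~3.4 Angstrom "in" and 6-7 Angstrom "out" contact
#'   distances).
#' @param hysteresis Half-width of the dead band in Angstrom (default 0.3).
#' @return A list with `labels` (character vector, "in"/"out") and
#'   `occupancy` (named numeric, fractions summing to 1).
#' @export
#' @examples
#' classify_conformers(c(3.4, 3.5, 6.5, 6.4))$occupancy
classify_conformers <- function(d_series, threshold = 5.0, hysteresis = 0.3) {
  if (!length(d_series)) stop("empty distance series", call. = FALSE)
  if (hysteresis < 0) stop("hysteresis must be >= 0", call. = FALSE)
  lo <- threshold - hysteresis
  hi <- threshold + hysteresis
  labels <- character(length(d_series))
  prev <- if (d_series[1] < threshold) "in" else "out"
  for (i in seq_along(d_series)) {
    d <- d_series[i]
    prev <- if (d < lo) "in" else if (d > hi) "out" else prev
    labels[i] <- prev
  }
  occ <- c(`in` = mean(labels == "in"), out = mean(labels == "out"))
  list(labels = labels, occupancy = occ)
}
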