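#' Assign each water to its closest residue
#'
#' Proximal bookkeeping: every water molecule (located at its oxygen)
#' belongs solely to the residue whose nearest heavy atom is closest. Ties
#' go to the residue listed first.
#'
#' @param coords `n_atoms x 3` coordinate matrix for one frame.
#' @param topology A `topology`.
#' @param residues Character vector of fragment names competing for waters,
#'   in tie-break priority order.
#' @return Tibble with one row per water: `water_tag` (residue tag of the
#'   water), `oxygen_row` (row index of the O atom), `residue` (assigned
#'   fragment), `distance` (Angstrom to that fragment's nearest heavy atom).
#' @export
proximal_assign <- function(coords, topology, residues) {
  if (!length(residues)) stop("empty residue list", call. = FALSE)
  a <- topology$atoms
  ox <- which(a$is_solvent & a$element == "O")
  if (!length(ox)) {
    return(tibble::tibble(water_tag = character(), oxygen_row = integer(),
                          residue = character(), distance = numeric()))
  }
  wpos <- coords[ox, , drop = FALSE]
  dmat <- vapply(residues, function(res) {
    idx <- fragment_atoms(topology, res, heavy_only = TRUE)
    if (!length(idx)) stop("residue ", res, " has no heavy atoms",
                           call. = FALSE)
    .row_min(.cross_dist(wpos, coords[idx, , drop = FALSE]))
  }, numeric(length(ox)))
  dmat <- matrix(dmat, nrow = length(ox))
  best <- max.col(-dmat, ties.method = "first")  # first residue wins ties
  tibble::tibble(
    water_tag = a$residue_tag[ox],
    oxygen_row = ox,
    residue = residues[best],
    distance = dmat[cbind(seq_along(ox), best)]
  )
}

# Monte-Carlo proximal shell volumes: fraction of uniform points in `box`
# whose nearest heavy solute atom belongs to `residue` and lies in each bin.
.proximal_volumes <- function(coords, topology, residues, residue, edges,
                              box, n_samples) {
  pts <- cbind(stats::runif(n_samples, box[1, 1], box[1, 2]),
               stats::runif(n_samples, box[2, 1], box[2, 2]),
               stats::runif(n_samples, box[3, 1], box[3, 2]))
  dmat <- vapply(residues, function(res) {
    idx <- fragment_atoms(topology, res, heavy_only = TRUE)
    .row_min(.cross_dist(pts, coords[idx, , drop = FALSE]))
  }, numeric(n_samples))
  dmat <- matrix(dmat, nrow = n_samples)
  best <- max.col(-dmat, ties.method = "first")
  mine <- best == match(residue, residues)
  d <- dmat[cbind(seq_len(n_samples), best)]
  counts <- .bin_counts(d[mine], edges)
  vol_box <- prod(box[, 2] - box[, 1])
  counts / n_samples * vol_box
}

# counts per half-open bin [edges[i], edges[i+1])
.bin_counts <- function(x, edges) {
  x <- x[x >= edges[1] & x < edges[length(edges)]]
  tabulate(findInterval(x, edges), nbins = length(edges) - 1)
}

#' Proximal radial distribution function
#'
#' g(r) for waters assigned exclusively to one residue, normalized by the
#' Monte-Carlo-estimated volumes of the nonoverlapping proximal shells:
#' \deqn{g(r) = \frac{\langle N(r, r+\Delta r) \rangle}{\rho\, V_{prox}(r)}}
#' where \eqn{V_{prox}(r)} is the volume of space whose nearest solute
#' heavy atom belongs to the residue at distance in \eqn{[r, r+\Delta r)}.
#'
#' @param trajectory A `trajectory` (or a single coordinate matrix).
#' @param topology A `topology`.
#' @param residue Fragment whose solvation shell is profiled.
#' @param residues All fragments competing for water assignment (must
#'   include `residue`); defaults to `residue` alone.
#' @param bin_width Shell width in Angstrom (default 0.1).
#' @param r_max Outermost shell edge in Angstrom (default 6).
#' @param bulk_density Bulk water number density in Angstrom^-3
#'   (default 0.0334, ambient water).
#' @param box 3x2 matrix of box bounds (rows x,y,z); defaults to the
#'   bounding box of the first frame padded by `r_max`.
#' @param mc_samples Monte-Carlo points for shell volumes (default 1e5).
#' @param seed Integer seed making the volume estimate reproducible.
#' @param frames Frame indices to average over (default all).
#' @return A `solvation_profile` tibble: `r_lo`, `r_hi`, `r_mid`, `count`
#'   (mean waters per frame in the shell), `volume` (Angstrom^3), `g`
#'   (NA where the shell has zero estimated volume), `cn` (cumulative mean
#'   count within `r_hi`), plus attributes `residue` and `n_frames`.
#' @export
proximal_gr <- function(trajectory, topology, residue, residues = residue,
                        bin_width = 0.1, r_max = 6,
                        bulk_density = 0.0334, box = NULL,
                        mc_samples = 1e5, seed = 1, frames = NULL) {
  if (bulk_density <= 0) stop("bulk_density must be positive", call. = FALSE)
  if (mc_samples < 1e4) stop("mc_samples must be at least 1e4", call. = FALSE)
  if (!residue %in% residues) residues <- c(residue, residues)
  coords_list <- if (inherits(trajectory, "trajectory")) {
    trajectory$coords
  } else {
    list(trajectory)
  }
  if (is.null(frames)) frames <- seq_along(coords_list)
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1

  if (is.null(box)) {
    m <- coords_list[[frames[1]]]
    box <- cbind(apply(m, 2, min) - r_max, apply(m, 2, max) + r_max)
  }

  counts <- matrix(0, length(frames), nb)
  vols <- matrix(0, length(frames), nb)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (k in seq_along(frames)) {
    m <- coords_list[[frames[k]]]
    asg <- proximal_assign(m, topology, residues)
    mine <- asg[asg$residue == residue & asg$distance < r_max, ]
    counts[k, ] <- .bin_counts(mine$distance, edges)
    vols[k, ] <- .proximal_volumes(m, topology, residues, residue, edges,
                                   box, mc_samples)
  }
  mean_count <- colMeans(counts)
  mean_vol <- colMeans(vols)
  g <- ifelse(mean_vol > 0, mean_count / (bulk_density * mean_vol), NA_real_)
  out <- tibble::tibble(
    r_lo = edges[-length(edges)],
    r_hi = edges[-1],
    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
    count = mean_count,
    volume = mean_vol,
    g = g,
    cn = cumsum(mean_count)
  )
  attr(out, "residue") <- residue
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("solvation_profile", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mean water coordination number of a residue
#'
#' Mean over frames of the number of waters assigned to the residue whose
#' proximal distance is at most `r_cut` — the integral of the raw shell
#' counts, not of g(r).
#'
#' @inheritParams proximal_gr
#' @param r_cut Cutoff distance in Angstrom.
#' @return Mean count (numeric scalar).
#' @export
coordination_number <- function(trajectory, topology, residue,
                                residues = residue, r_cut, frames = NULL) {
  if (r_cut <= 0) stop("r_cut must be positive", call. = FALSE)
  if (!residue %in% residues) residues <- c(residue, residues)
  coords_list <- if (inherits(trajectory, "trajectory")) {
    trajectory$coords
  } else {
    list(trajectory)
  }
  if (is.null(frames)) frames <- seq_along(coords_list)
  per_frame <- vapply(frames, function(k) {
    asg <- proximal_assign(coords_list[[k]], topology, residues)
    sum(asg$residue == residue & asg$distance <= r_cut)
  }, numeric(1))
  mean(per_frame)
}

#' Hydrogen-bonded bridges between a donor and an acceptor
#'
#' Finds chains donor--(water)--(water)--acceptor of at most `max_waters`
#' intervening waters by breadth-first expansion over the hydrogen-bond
#' graph. An H-bond requires donor--acceptor heavy-atom distance at most
#' `d_cut` and a donor--H...acceptor angle of at least `angle_cut` degrees.
#' Waters donate through either hydrogen.
#'
#' @param coords `n_atoms x 3` coordinate matrix for one frame.
#' @param topology A `topology`.
#' @param donor Row index of the donor heavy atom (must have at least one
#'   attached hydrogen, identified as a hydrogen within 1.25 Angstrom).
#' @param acceptor Row index of the acceptor heavy atom.
#' @param max_waters Maximum intervening waters, 0, 1 or 2 (default 2).
#' @param d_cut Heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param angle_cut Donor--H...acceptor angle cutoff in degrees
#'   (default 120).
#' @return A list of integer vectors, each an ordered chain of heavy-atom
#'   row indices from donor to acceptor; empty list when no bridge exists.
#' @export
hbond_bridges <- function(coords, topology, donor, acceptor,
                          max_waters = 2, d_cut = 3.5, angle_cut = 120) {
  if (!max_waters %in% 0:2) stop("max_waters must be 0, 1 or 2",
                                 call. = FALSE)
  a <- topology$atoms
  hyd <- which(a$is_hydrogen)
  attached_h <- function(heavy) {
    if (!length(hyd)) return(integer())
    d <- .cross_dist(coords[heavy, , drop = FALSE],
                     coords[hyd, , drop = FALSE])
    hyd[d[1, ] <= 1.25]
  }
  if (!length(attached_h(donor))) {
    stop("donor atom has no attached hydrogen", call. = FALSE)
  }
  is_hbond <- function(d_heavy, a_heavy) {
    if (d_heavy == a_heavy) return(FALSE)
    dd <- sqrt(sum((coords[d_heavy, ] - coords[a_heavy, ])^2))
    if (dd > d_cut) return(FALSE)
    for (h in attached_h(d_heavy)) {
      v1 <- coords[d_heavy, ] - coords[h, ]
      v2 <- coords[a_heavy, ] - coords[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang >= angle_cut) return(TRUE)
    }
    FALSE
  }
  waters <- which(a$is_solvent & a$element == "O")
  paths <- list()
  # depth-limited enumeration: donor -> w1? -> w2? -> acceptor
  if (is_hbond(donor, acceptor)) paths <- c(paths, list(c(donor, acceptor)))
  if (max_waters >= 1) {
    for (w1 in waters) {
      if (!is_hbond(donor, w1)) next
      if (is_hbond(w1, acceptor)) {
        paths <- c(paths, list(c(donor, w1, acceptor)))
      }
      if (max_waters >= 2) {
        for (w2 in setdiff(waters, w1)) {
          if (is_hbond(w1, w2) && is_hbond(w2, acceptor)) {
            paths <- c(paths, list(c(donor, w1, w2, acceptor)))
          }
        }
      }
    }
  }
  paths
}
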