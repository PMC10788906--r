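#' Configuration for the synthetic two-state generator
#'
#' The generator emulates the statistical structure of QM/MM/MD output for
#' a photosensitized two-tryptophan hole-hopping system: a stochastic
#' diabatic energy gap drives hole transfer between two indoles, the
#' sensitizer toggles between "in" and "out" rotamers, and waters drift
#' toward whichever indole carries the cation.
#'
#' Defaults are the package's reference study conditions: a 1 fs step;
#' an Ornstein-Uhlenbeck gap (relaxation 100 fs, stationary sd 50 meV)
#' whose mean sits at +300 meV while the hole is on W124 (CS1) and at
#' -2.667 x the CS2 coupling mean while on W122 (CS2) — the operating
#' point at which the CS2 minority hole fraction is 0.10; couplings
#' log-normal around 40 meV in CS1 rising to 100 meV in CS2, anticorrelated
#' with the inter-indole distance; CS1<->CS2 switching rates in the 0.65
#' equilibrium ratio; conformer rates giving 63% "in"; the sensitizer
#' dianion split as -0.45 e on the diimine and -0.55 e on the Re(CO)3 core;
#' and a 5 fs lag between the gap driver and the charge response.
#'
#' @param n_frames Number of frames.
#' @param dt Time step in fs.
#' @param seed Integer seed; all generator randomness flows through it.
#' @param tau_gap OU relaxation time of the energy gap, fs.
#' @param sigma_gap Stationary standard deviation of the gap, meV.
#' @param gap_mean_cs1,gap_mean_cs2 Gap means in the two states, meV
#'   (positive = hole favored on W124).
#' @param coupling_mean,coupling_mean_cs2 Median |H_ab| in CS1 / CS2, meV.
#' @param coupling_sd Standard deviation of the coupling fluctuations, meV.
#' @param k_cs1_cs2,k_cs2_cs1 CS1->CS2 and CS2->CS1 switching rates of the
#'   gap mean, fs^-1.
#' @param k_in_out,k_out_in Conformer switching rates, fs^-1.
#' @param n_waters Water count.
#' @param box_edge Cubic box edge, Angstrom.
#' @param water_bias_strength Dimensionless drift strength; each step
#'   biased waters move `water_bias_strength * 0.05` Angstrom toward the
#'   cationic indole.
#' @param lag_fs Lag between the gap driver and the charge response, fs
#'   (a whole multiple of `dt`).
#' @param start_state Initial diabatic state, `"CS1"` or `"CS2"`.
#' @param start_conformer Initial rotamer, `"in"` or `"out"`.
#' @param dmp_charge Diimine share of the reduced-sensitizer charge, e.
#' @param forced_switch_time Optional time (fs) of a single deterministic
#'   CS1->CS2 mean switch; stochastic state switching is disabled when set.
#' @param back_et_time Optional time (fs) at which the hole starts
#'   recombining with the reduced sensitizer (total indole charge decays
#'   exponentially).
#' @param back_et_tau Decay constant of the recombination, fs.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_frames = 3000, dt = 1, seed = 1,
                             tau_gap = 100, sigma_gap = 50,
                             gap_mean_cs1 = 300,
                             gap_mean_cs2 = -2.667 * coupling_mean_cs2,
                             coupling_mean = 40, coupling_mean_cs2 = 100,
                             coupling_sd = 10,
                             k_cs1_cs2 = 0.65e-3, k_cs2_cs1 = 1.0e-3,
                             k_in_out = 0.37e-3, k_out_in = 0.63e-3,
                             n_waters = 100, box_edge = 30,
                             water_bias_strength = 1,
                             lag_fs = 5,
                             start_state = "CS1", start_conformer = "in",
                             dmp_charge = -0.45,
                             forced_switch_time = NULL,
                             back_et_time = NULL, back_et_tau = 200) {
  cfg <- as.list(environment())
  if (cfg$n_frames < 1 || cfg$dt <= 0) {
    stop("n_frames must be >= 1 and dt > 0", call. = FALSE)
  }
  if (cfg$tau_gap <= 0) stop("tau_gap must be positive", call. = FALSE)
  if (cfg$sigma_gap < 0) stop("sigma_gap must be >= 0", call. = FALSE)
  if (any(c(cfg$k_cs1_cs2, cfg$k_cs2_cs1, cfg$k_in_out, cfg$k_out_in) < 0)) {
    stop("switching rates must be >= 0", call. = FALSE)
  }
  if (cfg$lag_fs < 0 || abs(cfg$lag_fs / cfg$dt -
                            round(cfg$lag_fs / cfg$dt)) > 1e-9) {
    stop("lag_fs must be a non-negative multiple of dt", call. = FALSE)
  }
  if (!cfg$start_state %in% c("CS1", "CS2")) {
    stop("start_state must be CS1 or CS2", call. = FALSE)
  }
  if (!cfg$start_conformer %in% c("in", "out")) {
    stop("start_conformer must be 'in' or 'out'", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# two-state telegraph process; per-step switching probability 1 - exp(-k dt)
.telegraph <- function(n, dt, k_ab, k_ba, start, states) {
  out <- character(n)
  cur <- start
  p_ab <- 1 - exp(-k_ab * dt)
  p_ba <- 1 - exp(-k_ba * dt)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    out[i] <- cur
    p <- if (cur == states[1]) p_ab else p_ba
    if (u[i] < p) cur <- if (cur == states[1]) states[2] else states[1]
  }
  out
}

#' Simulate the diabatic energy-gap series
#'
#' Ornstein-Uhlenbeck process (exact discretization) whose mean follows a
#' two-state telegraph between the CS1- and CS2-biased values. Positive gap
#' favors the hole on W124. Stationary fluctuations have standard deviation
#' `sigma_gap`; with `sigma_gap = 0` the series relaxes deterministically
#' to the prevailing mean.
#'
#' @param config A `synthetic_config`.
#' @return Tibble `time_fs`, `state` (the driving diabatic state), and
#'   `gap_mev`.
#' @export
simulate_gap <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  .simulate_gap_impl(config)
}

.simulate_gap_impl <- function(config) {
  n <- config$n_frames
  dt <- config$dt
  times <- (seq_len(n) - 1) * dt
  if (!is.null(config$forced_switch_time)) {
    state <- ifelse(times < config$forced_switch_time, "CS1", "CS2")
    stats::runif(n)  # keep the RNG stream aligned with the stochastic path
  } else {
    state <- .telegraph(n, dt, config$k_cs1_cs2, config$k_cs2_cs1,
                        config$start_state, c("CS1", "CS2"))
  }
  mu <- ifelse(state == "CS1", config$gap_mean_cs1, config$gap_mean_cs2)
  a <- exp(-dt / config$tau_gap)
  innov_sd <- config$sigma_gap * sqrt(1 - a^2)
  gap <- numeric(n)
  gap[1] <- mu[1] + config$sigma_gap * stats::rnorm(1)
  eps <- stats::rnorm(n) * innov_sd
  for (i in seq_len(n - 1)) {
    gap[i + 1] <- mu[i + 1] + (gap[i] - mu[i + 1]) * a + eps[i + 1]
  }
  tibble::tibble(time_fs = times, state = state, gap_mev = gap)
}

#' Ground-state hole fractions of the two-state Hamiltonian
#'
#' Diagonalizes the 2x2 diabatic Hamiltonian with diagonal
#' \eqn{\pm\Delta E / 2} and off-diagonal \eqn{H_{ab}}; the ground
#' eigenvector gives the hole shares
#' \deqn{f_{124} = \tfrac12\left(1 + \Delta E / \sqrt{\Delta E^2 +
#' 4 H_{ab}^2}\right),\qquad f_{122} = 1 - f_{124},}
#' with the convention that positive gap puts the hole on W124.
#'
#' @param gap_mev Energy gap, meV (vectorized).
#' @param hab_mev Coupling |H_ab| >= 0, meV (vectorized).
#' @return Tibble `f124`, `f122`.
#' @export
#' @examples
#' gap_to_hole_fractions(0, 40)            # (0.5, 0.5)
#' gap_to_hole_fractions(2.667 * 40, 40)   # minority ~0.10
gap_to_hole_fractions <- function(gap_mev, hab_mev) {
  if (any(hab_mev < 0)) stop("H_ab must be >= 0", call. = FALSE)
  denom <- sqrt(gap_mev^2 + 4 * hab_mev^2)
  f124 <- ifelse(denom == 0, 0.5, 0.5 * (1 + gap_mev / denom))
  tibble::tibble(f124 = f124, f122 = 1 - f124)
}

# planar indole stand-in: fused hexagon + 3 extra heavy atoms + the N-H
# hydrogen. Returns list(xyz (10 x 3), element, heavy (logical))
.indole_template <- function() {
  ang <- (seq_len(6) - 0.5) * pi / 3
  hexagon <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  # fuse a five-ring on the hexagon edge between atoms 1 and 6 (x > 0 side)
  mid <- (hexagon[1, ] + hexagon[6, ]) / 2
  u <- mid / sqrt(sum(mid^2))
  v <- c(-u[2], u[1], 0)
  five <- rbind(mid + 1.9 * u,            # N
                mid + 1.15 * u + 1.1 * v, # C
                mid + 1.15 * u - 1.1 * v) # C
  xyz <- rbind(hexagon, five, five[1, ] + c(u * 1.0))  # N-H hydrogen
  list(xyz = xyz,
       element = c(rep("C", 6), "N", "C", "C", "H"),
       n_heavy = 9L)
}

# rotation about the x axis
.rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
         3, 3, byrow = TRUE)
}

# static reference geometry; returns list(atoms tibble, placement info)
.reference_geometry <- function(config) {
  ind <- .indole_template()
  place <- function(xyz, rot = diag(3), shift = c(0, 0, 0)) {
    sweep(xyz %*% t(rot), 2, shift, "+")
  }
  w124 <- place(ind$xyz)                                   # plane z = 0
  w122 <- place(ind$xyz, .rot_x(83), c(0, 5.0, 2.0))       # tilted neighbor

  hexagon <- .indole_template()$xyz[1:6, ]
  dmp_in <- place(hexagon, .rot_x(90), c(0, -4.8, 0))
  dmp_out <- place(hexagon, .rot_x(90), c(0, -7.9, 0))
  re_core <- rbind(c(0, -5.8, 1.5),
                   c(1.1, -6.5, 2.2), c(-1.1, -6.5, 2.2), c(0, -5.6, 3.0),
                   c(1.9, -7.0, 2.6), c(-1.9, -7.0, 2.6), c(0, -5.5, 4.1))
  sal <- rbind(c(0, 6.2, 3.0), c(1.2, 6.8, 3.2), c(-0.9, 6.9, 2.6),
               c(0.2, 6.1, 4.4))
  q107 <- rbind(c(4.2, -0.5, 0.3), c(5.0, 0.4, 0.9), c(5.9, 0.1, 1.4),
                c(4.9, 1.6, 0.8))
  rest <- rbind(c(-5.0, 2.0, -2.0), c(-5.8, 2.6, -1.2), c(-6.6, 1.8, -0.8),
                c(-5.2, 4.0, -1.0), c(6.5, -3.5, -2.5), c(7.3, -3.0, -1.8))

  frag <- function(xyz, element, fragment, tag_prefix, one_residue = TRUE) {
    n <- nrow(xyz)
    tibble::tibble(
      element = element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      residue_tag = if (one_residue) rep(tag_prefix, n) else
        paste0(tag_prefix, seq_len(n)),
      fragment = fragment
    )
  }
  atoms <- dplyr::bind_rows(
    frag(w124, ind$element, "W124", "TRP124"),
    frag(w122, ind$element, "W122", "TRP122"),
    frag(dmp_in, c("N", "C", "C", "C", "C", "N"), "dmp", "DMP1"),
    frag(re_core, c("Re", "C", "C", "C", "O", "O", "O"), "ReCO3", "REC1"),
    frag(sal, c("C", "C", "O", "N"), "SAL", "SAL1"),
    frag(q107, c("C", "C", "O", "N"), "Q107", "GLN107"),
    frag(rest, rep("C", 6), "protein_rest", "RST1")
  )
  list(atoms = atoms, dmp_in = dmp_in, dmp_out = dmp_out,
       w124_centroid = colMeans(w124[1:9, ]),
       w122_centroid = colMeans(w122[1:9, ]))
}

# initial water positions uniform in the box, avoiding solute clashes
.init_waters <- function(n_waters, box_edge, solute_xyz) {
  half <- box_edge / 2
  placed <- matrix(NA_real_, n_waters, 3)
  k <- 0
  while (k < n_waters) {
    cand <- stats::runif(3, -half, half)
    if (min(.cross_dist(matrix(cand, 1), solute_xyz)) > 2.4) {
      k <- k + 1
      placed[k, ] <- cand
    }
  }
  placed
}

.water_offsets <- rbind(c(0.9572, 0, 0),
                        c(-0.2399872, 0.9266272, 0))  # H positions rel. O

#' Generate a complete synthetic system
#'
#' Builds a topology (two indole stand-ins, a toggling diimine + Re(CO)3
#' sensitizer, SAL and Q107 stand-ins, waters in a cubic box), a
#' trajectory, the per-fragment charge/spin/coupling series produced by the
#' two-state diabatic model, and the ground truth behind them.
#'
#' Per frame: the diabatic gap follows [simulate_gap()]; hole fractions are
#' the two-state eigenvector shares of the lagged gap, mapped to a +1 total
#' hole split over the indoles (scaled down during recombination); the
#' diimine and Re(CO)3 carry the reduced-sensitizer charge; the sensitizer
#' toggles between its "in" and "out" poses; waters random-walk with a
#' drift of `water_bias_strength * 0.05` Angstrom per step toward the
#' cationic indole, reflected at the box walls.
#'
#' @param config A `synthetic_config`.
#' @return A list with elements `topology`, `trajectory`, `series` (a
#'   `fragment_series`), and `truth` (see Details). `truth` contains
#'   per-frame `state` and `conformer` labels, `onset_fs` (true hole
#'   crossing times from the continuous model), `lag_fs`, the switching
#'   rates, and the injected `driver_dphi_v` series.
#' @export
generate_system <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- config$n_frames
  dt <- config$dt
  times <- (seq_len(n) - 1) * dt

  gap <- .simulate_gap_impl(config)
  # inter-indole breathing: smoothed zero-mean displacement along the
  # centroid axis, shared between the coordinates and the coupling series
  dist_jitter <- stats::rnorm(n, 0, 0.12)
  if (n >= 8) {
    dist_jitter <- as.numeric(stats::filter(dist_jitter, rep(1 / 4, 4),
                                            sides = 1))
    dist_jitter[is.na(dist_jitter)] <- 0
  }
  chg <- .charge_tracks(config, gap, dist_jitter = dist_jitter)
  conformer <- .telegraph(n, dt, config$k_in_out, config$k_out_in,
                          config$start_conformer, c("in", "out"))

  geo <- .reference_geometry(config)
  ref <- geo$atoms
  solute_xyz <- as.matrix(ref[, c("x", "y", "z")])
  wat_o <- .init_waters(config$n_waters, config$box_edge, solute_xyz)

  water_atoms <- purrr::map_dfr(seq_len(config$n_waters), function(w) {
    tibble::tibble(
      element = c("O", "H", "H"),
      x = wat_o[w, 1] + c(0, .water_offsets[, 1]),
      y = wat_o[w, 2] + c(0, .water_offsets[, 2]),
      z = wat_o[w, 3] + c(0, 0, 0),
      residue_tag = paste0("WAT", w),
      fragment = "solvent"
    )
  })
  atoms <- dplyr::bind_rows(ref, water_atoms)
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$charge <- .static_charges(atoms, config)
  atoms$vdw_radius <- vdw_radius(atoms$element)
  topo <- topology(atoms[, c("atom_id", "element", "x", "y", "z", "charge",
                             "vdw_radius", "residue_tag", "fragment")])

  idx_dmp <- which(atoms$fragment == "dmp")
  idx_w122 <- which(atoms$fragment == "W122")
  axis122 <- geo$w122_centroid - geo$w124_centroid
  axis122 <- axis122 / sqrt(sum(axis122^2))
  idx_o <- which(atoms$fragment == "solvent" & atoms$element == "O")
  half <- config$box_edge / 2
  drift <- config$water_bias_strength * 0.05

  base <- as.matrix(atoms[, c("x", "y", "z")])
  owat <- wat_o
  coords <- vector("list", n)
  jitter_sd <- 0.03
  n_solute <- nrow(ref)
  for (i in seq_len(n)) {
    m <- base
    m[seq_len(n_solute), ] <- m[seq_len(n_solute), ] +
      matrix(stats::rnorm(n_solute * 3, sd = jitter_sd), ncol = 3)
    m[idx_dmp, ] <- (if (conformer[i] == "in") geo$dmp_in else geo$dmp_out) +
      matrix(stats::rnorm(length(idx_dmp) * 3, sd = jitter_sd), ncol = 3)
    m[idx_w122, ] <- sweep(m[idx_w122, , drop = FALSE], 2,
                           dist_jitter[i] * axis122, "+")
    # biased water walk toward the cationic indole
    target <- if (chg$f124[i] >= 0.5) geo$w124_centroid else geo$w122_centroid
    step <- matrix(stats::rnorm(config$n_waters * 3, sd = 0.1), ncol = 3)
    to <- sweep(-owat, 2, target, "+")
    nrm <- sqrt(rowSums(to^2))
    step <- step + drift * chg$hole_total[i] * to / pmax(nrm, 1e-6)
    trial <- .reflect_box(owat + step, half)
    # reject moves that clash with the solute (keeps biased waters in the
    # contact shell instead of collapsing onto the indole)
    dmin <- .row_min(.cross_dist(trial,
                                 m[seq_len(n_solute), , drop = FALSE]))
    ok <- dmin > 2.4
    owat[ok, ] <- trial[ok, ]
    m[idx_o, ] <- owat
    m[idx_o + 1, ] <- sweep(owat, 2, -c(.water_offsets[1, ]), "-")
    m[idx_o + 2, ] <- sweep(owat, 2, -c(.water_offsets[2, ]), "-")
    coords[[i]] <- m
  }
  traj <- trajectory(times, coords)

  series <- .emit_series(config, times, chg)
  truth <- list(
    state = chg$true_label,
    conformer = conformer,
    onset_fs = chg$onset_fs,
    lag_fs = config$lag_fs,
    rates = list(k_cs1_cs2 = config$k_cs1_cs2,
                 k_cs2_cs1 = config$k_cs2_cs1,
                 k_in_out = config$k_in_out,
                 k_out_in = config$k_out_in),
    driver_dphi_v = chg$driver_dphi_v,
    seed = config$seed
  )
  list(topology = topo, trajectory = traj, series = series, truth = truth)
}

.reflect_box <- function(m, half) {
  m <- abs(m + half) %% (4 * half)
  m <- ifelse(m > 2 * half, 4 * half - m, m)
  m - half
}

# per-frame charge bookkeeping shared by the full and series-only
# generators. Consumes RNG for couplings only. `dist_jitter` (Angstrom,
# zero-mean) modulates the coupling upward when the indoles approach.
.charge_tracks <- function(config, gap, dist_jitter = NULL) {
  n <- config$n_frames
  lagk <- as.integer(round(config$lag_fs / config$dt))
  lagged_gap <- c(rep(gap$gap_mev[1], lagk),
                  gap$gap_mev)[seq_len(n)]
  lagged_state <- c(rep(gap$state[1], lagk), gap$state)[seq_len(n)]

  h_med <- ifelse(lagged_state == "CS1", config$coupling_mean,
                  config$coupling_mean_cs2)
  sdlog <- sqrt(log(1 + (config$coupling_sd / h_med)^2))
  hab <- h_med * exp(stats::rnorm(n) * sdlog - sdlog^2 / 2)
  if (!is.null(dist_jitter)) {
    # ~2 per Angstrom decay of through-space coupling
    hab <- hab * exp(-2 * dist_jitter)
  }

  fr <- gap_to_hole_fractions(lagged_gap, hab)

  hole_total <- rep(1, n)
  times <- gap$time_fs
  if (!is.null(config$back_et_time)) {
    post <- times >= config$back_et_time
    hole_total[post] <- exp(-(times[post] - config$back_et_time) /
                              config$back_et_tau)
  }
  q124 <- fr$f124 * hole_total
  q122 <- fr$f122 * hole_total

  true_label <- lagged_state
  if (!is.null(config$back_et_time)) {
    true_label[hole_total < 0.5] <- "BACK_ET"
  }

  # true onsets: zero crossings of the continuous (lagged) gap while the
  # hole is present, by linear interpolation
  d <- lagged_gap
  onset_fs <- numeric()
  for (i in seq_len(n - 1)) {
    if (hole_total[i] < 0.5) break
    if (d[i] == 0 || d[i] * d[i + 1] < 0) {
      frac <- if (d[i] == 0) 0 else d[i] / (d[i] - d[i + 1])
      onset_fs <- c(onset_fs, times[i] + frac * (times[i + 1] - times[i]))
    }
  }
  list(f124 = fr$f124, q124 = q124, q122 = q122, hab = hab,
       hole_total = hole_total, true_label = true_label,
       onset_fs = onset_fs,
       driver_dphi_v = -gap$gap_mev / 250)
}

.emit_series <- function(config, times, chg) {
  q_dmp <- config$dmp_charge * chg$hole_total
  q_re <- (-1 - config$dmp_charge) * chg$hole_total
  fragment_series(dplyr::bind_rows(
    tibble::tibble(time_fs = times, fragment = "W124",
                   charge_e = chg$q124, spin = chg$q124,
                   hab_mev = chg$hab),
    tibble::tibble(time_fs = times, fragment = "W122",
                   charge_e = chg$q122, spin = chg$q122,
                   hab_mev = chg$hab),
    tibble::tibble(time_fs = times, fragment = "dmp",
                   charge_e = q_dmp, spin = -chg$hole_total * 0.45,
                   hab_mev = chg$hab),
    tibble::tibble(time_fs = times, fragment = "ReCO3",
                   charge_e = q_re, spin = -chg$hole_total * 0.55,
                   hab_mev = chg$hab)
  ))
}

.static_charges <- function(atoms, config) {
  ch <- numeric(nrow(atoms))
  solv <- atoms$fragment == "solvent"
  ch[solv & atoms$element == "O"] <- -0.834
  ch[solv & atoms$element == "H"] <- 0.417
  dmp <- atoms$fragment == "dmp"
  ch[dmp] <- config$dmp_charge / sum(dmp)
  re <- atoms$fragment == "ReCO3"
  ch[re] <- (-1 - config$dmp_charge) / sum(re)
  for (f in c("SAL", "Q107", "protein_rest")) {
    idx <- which(atoms$fragment == f)
    if (length(idx) >= 2) {
      ch[idx] <- rep_len(c(0.1, -0.1), length(idx))
      if (length(idx) %% 2 == 1) ch[idx[length(idx)]] <- 0
    }
  }
  ch
}

#' Generate the charge/coupling series only
#'
#' Fast path used for large-n statistics and ensembles: identical charge
#' model to [generate_system()] but without geometry or waters.
#'
#' @param config A `synthetic_config`.
#' @return List with `series` (a `fragment_series`) and `truth` (as in
#'   [generate_system()], without conformer labels).
#' @export
generate_charge_series <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  gap <- .simulate_gap_impl(config)
  chg <- .charge_tracks(config, gap)
  list(
    series = .emit_series(config, gap$time_fs, chg),
    truth = list(state = chg$true_label, onset_fs = chg$onset_fs,
                 lag_fs = config$lag_fs,
                 rates = list(k_cs1_cs2 = config$k_cs1_cs2,
                              k_cs2_cs1 = config$k_cs2_cs1),
                 driver_dphi_v = chg$driver_dphi_v,
                 seed = config$seed)
  )
}

#' Generate an ensemble of trajectories with known outcomes
#'
#' Emits `n_reactive` trajectories with one forced CS1->CS2 conversion,
#' `n_unreactive` trajectories that stay in CS1, and `n_back_et`
#' trajectories whose hole recombines with the reduced sensitizer —
#' mirroring an outcome census over a set of short hole-transfer runs.
#'
#' @param n_reactive,n_unreactive,n_back_et Trajectory counts per outcome.
#' @param config Base `synthetic_config`; per-trajectory seeds and event
#'   times are derived from `config$seed`.
#' @return A list of per-trajectory lists, each with `series`, `truth`,
#'   and `true_verdict`.
#' @export
generate_trajectory_ensemble <- function(n_reactive = 3, n_unreactive = 28,
                                         n_back_et = 2,
                                         config = synthetic_config()) {
  total <- n_reactive + n_unreactive + n_back_et
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 1, total)
  span <- (config$n_frames - 1) * config$dt
  event_times <- stats::runif(total, 0.25 * span, 0.5 * span)
  verdicts <- c(rep("reactive", n_reactive),
                rep("unreactive", n_unreactive),
                rep("back_ET", n_back_et))
  purrr::map(seq_len(total), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    cfg$k_cs1_cs2 <- 0
    cfg$k_cs2_cs1 <- 0
    cfg$start_state <- "CS1"
    cfg$forced_switch_time <- NULL
    cfg$back_et_time <- NULL
    if (verdicts[i] == "reactive") {
      cfg$forced_switch_time <- event_times[i]
    } else if (verdicts[i] == "back_ET") {
      cfg$back_et_time <- event_times[i]
    }
    out <- generate_charge_series(cfg)
    out$true_verdict <- verdicts[i]
    out
  })
}

#' Write a synthetic system to disk
#'
#' Emits exactly the formats the readers consume: a PDB + YAML fragment
#' map + charge sidecar (via [write_topology()]), a multi-frame XYZ
#' trajectory, the fragment series CSV, and `ground_truth.json`.
#'
#' @param system Output of [generate_system()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    pdb = file.path(dir, "topology.pdb"),
    config = file.path(dir, "topology.yaml"),
    xyz = file.path(dir, "trajectory.xyz"),
    series = file.path(dir, "fragment_series.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_topology(system$topology, paths$pdb, paths$config)
  write_xyz_trajectory(system$trajectory, system$topology, paths$xyz)
  write_fragment_series(system$series, paths$series)
  jsonlite::write_json(system$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
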