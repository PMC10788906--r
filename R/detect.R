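#' Hole fraction on W124
#'
#' Normalizes the two indole charges to a fraction
#' \eqn{f = q_{124} / (q_{124} + q_{122})}, defined only while the hole is
#' still present: when the summed indole charge drops below `floor` the
#' fraction is reported as `NA` (the hole has recombined or left the
#' indoles).
#'
#' @param q124,q122 Indole charges in e (vectors of equal length).
#' @param floor Minimum total indole charge for the fraction to be defined,
#'   in e (default 0.5).
#' @return Numeric vector in \[0, 1\] with `NA` where the hole vanished.
#' @export
hole_fraction <- function(q124, q122, floor = 0.5) {
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  tot <- q124 + q122
  ifelse(tot >= floor, q124 / tot, NA_real_)
}

#' Label frames as CS1 / DELOC / CS2 / BACK_ET
#'
#' CS1 holds the hole on W124 (fraction at least `f_hi`), CS2 on W122
#' (fraction at most `1 - f_hi`), DELOC is the near-degenerate region in
#' between, and BACK_ET marks frames where the summed indole charge fell
#' below `hole_floor` (hole recombination with the reduced sensitizer).
#'
#' @param charges Tibble from [indole_charges()] (columns `time_fs`,
#'   `q124`, `q122`), or a `fragment_series`.
#' @param f_hi Localization threshold in (0.5, 1) (default 0.8).
#' @param hole_floor Minimum total indole charge in e (default 0.5).
#' @return Tibble `time_fs`, `f` (hole fraction), `label` (factor with
#'   levels CS1, DELOC, CS2, BACK_ET).
#' @export
label_states <- function(charges, f_hi = 0.8, hole_floor = 0.5) {
  if (!(f_hi > 0.5 && f_hi < 1)) {
    stop("f_hi must lie in (0.5, 1)", call. = FALSE)
  }
  if (inherits(charges, "fragment_series")) charges <- indole_charges(charges)
  f_lo <- 1 - f_hi
  f <- hole_fraction(charges$q124, charges$q122, floor = hole_floor)
  label <- dplyr::case_when(
    is.na(f) ~ "BACK_ET",
    f >= f_hi ~ "CS1",
    f <= f_lo ~ "CS2",
    TRUE ~ "DELOC"
  )
  tibble::tibble(
    time_fs = charges$time_fs,
    f = f,
    label = factor(label, levels = c("CS1", "DELOC", "CS2", "BACK_ET"))
  )
}

#' Detect the electron-transfer onset
#'
#' The onset is the first time the two indole charges are equal: the
#' earliest sign change (or exact zero) of \eqn{q_{124} - q_{122}}, located
#' by linear interpolation between the bracketing frames. A crossing from
#' positive to negative (hole leaving W124) is a `forward` event; the
#' opposite direction is `reverse`.
#'
#' @param charges Tibble from [indole_charges()] or a `fragment_series`.
#' @param dphi Optional numeric vector (same length as frames) of potential
#'   differences; when given, the onset row reports `dphi_at_onset`
#'   interpolated to the onset time.
#' @return One-row tibble `onset_fs`, `type`, `dphi_at_onset`, or a
#'   zero-row tibble when no crossing occurs.
#' @export
detect_onset <- function(charges, dphi = NULL) {
  if (inherits(charges, "fragment_series")) charges <- indole_charges(charges)
  ok <- !is.na(charges$q124) & !is.na(charges$q122)
  ch <- charges[ok, ]
  if (nrow(ch) < 2) stop("need at least 2 frames with both charges",
                         call. = FALSE)
  if (!is.null(dphi)) dphi <- dphi[ok]
  delta <- ch$q124 - ch$q122
  t <- ch$time_fs
  empty <- tibble::tibble(onset_fs = numeric(), type = character(),
                          dphi_at_onset = numeric())

  onset <- NA_real_
  type <- NA_character_
  for (i in seq_len(length(delta) - 1)) {
    d0 <- delta[i]; d1 <- delta[i + 1]
    if (d0 == 0) {
      onset <- t[i]
      type <- if (d1 < 0) "forward" else "reverse"
      break
    }
    if (d0 * d1 < 0) {
      frac <- d0 / (d0 - d1)
      onset <- t[i] + frac * (t[i + 1] - t[i])
      type <- if (d0 > 0) "forward" else "reverse"
      break
    }
  }
  if (is.na(onset)) {
    if (delta[length(delta)] == 0) {
      # equality reached only at the final frame
      onset <- t[length(delta)]
      type <- if (delta[length(delta) - 1] > 0) "forward" else "reverse"
    } else {
      return(empty)
    }
  }
  dphi_on <- if (is.null(dphi)) {
    NA_real_
  } else {
    stats::approx(t, dphi, xout = onset, rule = 2)$y
  }
  tibble::tibble(onset_fs = onset, type = type, dphi_at_onset = dphi_on)
}

# run-length segments of a label vector with dwell times
.label_segments <- function(times, labels) {
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  dt <- if (length(times) > 1) stats::median(diff(times)) else 0
  tibble::tibble(
    label = r$values,
    start_fs = times[starts],
    end_fs = times[ends],
    dwell_fs = times[ends] - times[starts] + dt
  )
}

#' Classify the outcome of one trajectory
#'
#' A trajectory is `back_ET` when it holds a sustained (at least
#' `min_cs2_dwell` fs) BACK_ET segment — the hole recombined with the
#' reduced sensitizer; otherwise `reactive` when a forward onset is
#' followed by a sustained CS2 segment (completed hop to W122); otherwise
#' `unreactive`.
#'
#' @param charges Tibble from [indole_charges()] or a `fragment_series`.
#' @param min_cs2_dwell Minimum sustained dwell in fs (default 200).
#' @param f_hi,hole_floor Passed to [label_states()].
#' @return A `trajectory_outcome`: list with `verdict`, `events` (tibble of
#'   detected onsets), `deloc_fraction` (mean minority hole fraction over
#'   CS2 frames, NA when CS2 is never reached), `labels` (per-frame label
#'   tibble), and `segments`.
#' @export
classify_outcome <- function(charges, min_cs2_dwell = 200, f_hi = 0.8,
                             hole_floor = 0.5) {
  if (inherits(charges, "fragment_series")) charges <- indole_charges(charges)
  lab <- label_states(charges, f_hi = f_hi, hole_floor = hole_floor)
  seg <- .label_segments(lab$time_fs, lab$label)
  events <- detect_onset(charges)
  back <- seg$label == "BACK_ET" & seg$dwell_fs >= min_cs2_dwell
  sustained_cs2 <- seg$label == "CS2" & seg$dwell_fs >= min_cs2_dwell
  verdict <- if (any(back)) {
    "back_ET"
  } else if (nrow(events) && events$type[1] == "forward" &&
             any(sustained_cs2 & seg$end_fs >= events$onset_fs[1])) {
    "reactive"
  } else {
    "unreactive"
  }
  deloc <- if (any(lab$label == "CS2")) {
    mean(lab$f[lab$label == "CS2"])
  } else {
    NA_real_
  }
  structure(
    list(verdict = verdict, events = events, deloc_fraction = deloc,
         labels = lab, segments = seg),
    class = "trajectory_outcome"
  )
}

#' @export
print.trajectory_outcome <- function(x, ...) {
  cat(sprintf("<trajectory_outcome> %s", x$verdict))
  if (nrow(x$events)) {
    cat(sprintf(" (onset %.1f fs, %s)", x$events$onset_fs[1],
                x$events$type[1]))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a trajectory outcome
#' @param x A `trajectory_outcome`.
#' @param ... Unused.
#' @return One row per detected event plus the verdict.
#' @export
tidy.trajectory_outcome <- function(x, ...) {
  ev <- x$events
  if (!nrow(ev)) {
    ev <- tibble::tibble(onset_fs = NA_real_, type = NA_character_,
                         dphi_at_onset = NA_real_)
  }
  dplyr::mutate(ev, verdict = x$verdict,
                deloc_fraction = x$deloc_fraction)
}

#' @rdname tidy.trajectory_outcome
#' @export
glance.trajectory_outcome <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    n_events = nrow(x$events),
    onset_fs = if (nrow(x$events)) x$events$onset_fs[1] else NA_real_,
    deloc_fraction = x$deloc_fraction
  )
}

#' Mean CS2 delocalization fraction
#'
#' Mean minority hole fraction (the residual W124 share) over CS2-labeled
#' frames.
#'
#' @param charges Tibble from [indole_charges()] or a `fragment_series`.
#' @param labels Optional label tibble from [label_states()] (recomputed
#'   with defaults when absent).
#' @return Dimensionless fraction.
#' @export
delocalization_fraction <- function(charges, labels = NULL) {
  if (inherits(charges, "fragment_series")) charges <- indole_charges(charges)
  if (is.null(labels)) labels <- label_states(charges)
  cs2 <- labels$label == "CS2"
  if (!any(cs2)) stop("no CS2-labeled frames", call. = FALSE)
  mean(labels$f[cs2])
}

#' CS2/CS1 occupancy equilibrium constant
#'
#' Ratio of total dwell time in CS2 to total dwell time in CS1; DELOC and
#' BACK_ET frames are excluded from both.
#'
#' @param labels Label tibble from [label_states()], or a factor/character
#'   vector of labels.
#' @return K = time(CS2) / time(CS1).
#' @export
occupancy_equilibrium <- function(labels) {
  lab <- if (is.data.frame(labels)) labels$label else labels
  n1 <- sum(lab == "CS1")
  n2 <- sum(lab == "CS2")
  if (n1 == 0) stop("CS1 never visited; equilibrium undefined", call. = FALSE)
  n2 / n1
}

#' Lagged cross-correlation between two series
#'
#' Pearson correlation of `x(t - tau)` with `y(t)` over a grid of lags;
#' positive best lag means fluctuations of `x` precede those of `y` (e.g.
#' potential differences driving charge differences).
#'
#' @param x,y Numeric series sampled on the same uniform time grid.
#' @param dt Time step in fs (default 1).
#' @param max_lag Largest |lag| tested, in fs (default 50).
#' @param step Lag grid spacing in fs (default `dt`).
#' @return A list with `best_lag_fs`, `best_correlation`, and `table`
#'   (tibble `lag_fs`, `correlation`, `n`).
#' @export
lagged_correlation <- function(x, y, dt = 1, max_lag = 50, step = dt) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  lags <- seq(-max_lag, max_lag, by = step)
  shifts <- as.integer(round(lags / dt))
  n <- length(x)
  rows <- purrr::map_dfr(seq_along(lags), function(i) {
    s <- shifts[i]
    if (s >= 0) {
      xs <- x[seq_len(n - s)]
      ys <- y[seq_len(n - s) + s]
    } else {
      xs <- x[seq_len(n + s) - s]
      ys <- y[seq_len(n + s)]
    }
    if (length(xs) < 10) {
      stop("fewer than 10 overlapping frames at lag ", lags[i], " fs",
           call. = FALSE)
    }
    tibble::tibble(lag_fs = lags[i],
                   correlation = stats::cor(xs, ys),
                   n = length(xs))
  })
  best <- which.max(abs(rows$correlation))
  list(best_lag_fs = rows$lag_fs[best],
       best_correlation = rows$correlation[best],
       table = rows)
}

#' Coupling--distance Pearson correlation
#'
#' Correlation between |H_ab| and an inter-indole distance series; strong
#' negative values reflect the growth of through-space coupling as the
#' indoles approach.
#'
#' @param hab Coupling series in meV.
#' @param distance Distance series in Angstrom (same length).
#' @return Pearson r.
#' @export
coupling_distance_correlation <- function(hab, distance) {
  if (length(hab) != length(distance)) stop("series lengths differ",
                                            call. = FALSE)
  if (length(hab) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(hab) == 0 || stats::sd(distance) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(hab, distance)
}
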