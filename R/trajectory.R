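#' Construct a trajectory
#'
#' Time-ordered coordinate frames for a fixed atom set. Coordinates are
#' stored as one `n_atoms x 3` matrix per frame; times are femtoseconds and
#' must increase strictly.
#'
#' @param times Numeric vector of frame times in fs (non-negative, strictly
#'   increasing).
#' @param coords List of `n_atoms x 3` numeric matrices, one per frame.
#' @return A `trajectory` object.
#' @export
trajectory <- function(times, coords) {
  if (length(times) != length(coords)) {
    stop("times and coords must have equal length", call. = FALSE)
  }
  if (length(times) == 0) stop("trajectory needs at least one frame",
                               call. = FALSE)
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("frame times must be non-negative and strictly increasing",
         call. = FALSE)
  }
  n <- nrow(coords[[1]])
  ok <- vapply(coords, function(m) is.matrix(m) && nrow(m) == n &&
                 ncol(m) == 3 && all(is.finite(m)), logical(1))
  if (!all(ok)) {
    stop("every frame must be a finite n_atoms x 3 matrix with constant ",
         "atom count", call. = FALSE)
  }
  structure(list(times = as.numeric(times), coords = coords, n_atoms = n),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %g..%g fs\n",
              length(x$times), x$n_atoms, min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames
#' @param trajectory A `trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(trajectory) length(trajectory$times)

#' Trajectory frames as a long tibble
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `frame`, `time_fs`, `atom`, `x`, `y`, `z`.
#' @export
as_tibble.trajectory <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$times), x$times, function(i, t) {
    m <- x$coords[[i]]
    tibble::tibble(frame = i, time_fs = t, atom = seq_len(nrow(m)),
                   x = m[, 1], y = m[, 2], z = m[, 3])
  })
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ dialect: per frame an atom-count line, a comment line
#' carrying the time as a `t=<fs>` token, then one `element x y z` line per
#' atom. The atom count of every frame must match the topology.
#'
#' @param xyz_path Path to the XYZ file.
#' @param topology A `topology` the frames must be congruent with.
#' @return A `trajectory`.
#' @export
read_xyz_trajectory <- function(xyz_path, topology) {
  lines <- readLines(xyz_path)
  n_top <- n_atoms(topology)
  times <- numeric()
  coords <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) {
      stop(sprintf("frame %d: expected an atom-count line, got '%s'",
                   frame, lines[i]), call. = FALSE)
    }
    if (n != n_top) {
      stop(sprintf("frame %d: atom count %d does not match topology (%d)",
                   frame, n, n_top), call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop(sprintf("frame %d: truncated file", frame), call. = FALSE)
    }
    comment <- lines[i + 1L]
    tmatch <- regmatches(comment,
                         regexpr("t=\\s*[-+0-9.eE]+", comment))
    if (!length(tmatch)) {
      stop(sprintf("frame %d: comment line lacks a 't=<fs>' token", frame),
           call. = FALSE)
    }
    t <- as.numeric(sub("t=\\s*", "", tmatch))
    body <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(fields) < 4L)
    if (length(bad)) {
      stop(sprintf("frame %d: malformed atom line %d", frame, bad[1]),
           call. = FALSE)
    }
    m <- matrix(as.numeric(t(vapply(fields, function(f) f[2:4], character(3)))),
                ncol = 3, byrow = FALSE)
    if (any(!is.finite(m))) {
      stop(sprintf("frame %d: non-numeric coordinates", frame), call. = FALSE)
    }
    times <- c(times, t)
    if (length(times) > 1 && t <= times[length(times) - 1]) {
      stop(sprintf("frame %d: time %g fs does not increase", frame, t),
           call. = FALSE)
    }
    coords[[length(coords) + 1L]] <- m
    i <- i + 2L + n
  }
  if (!length(coords)) stop("no frames found in ", xyz_path, call. = FALSE)
  trajectory(times, coords)
}

#' Write a multi-frame XYZ trajectory
#'
#' @param trajectory A `trajectory`.
#' @param topology Matching `topology` (supplies element symbols).
#' @param xyz_path Output path.
#' @return Invisibly, `xyz_path`.
#' @export
write_xyz_trajectory <- function(trajectory, topology, xyz_path) {
  if (n_atoms(topology) != trajectory$n_atoms) {
    stop("topology and trajectory atom counts differ", call. = FALSE)
  }
  elem <- topology$atoms$element
  con <- file(xyz_path, "w")
  on.exit(close(con))
  for (i in seq_along(trajectory$times)) {
    m <- trajectory$coords[[i]]
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("t=%.6f fs", trajectory$times[i]), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f",
                       elem, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(xyz_path)
}

#' Read a per-fragment time series
#'
#' CSV with columns `time_fs`, `fragment`, `charge_e` and optional `spin`
#' and `hab_mev` (the inter-state coupling, constant across fragments within
#' a frame). Missing optional columns are reported absent, never
#' zero-filled.
#'
#' @param csv_path Path to the CSV file.
#' @return A `fragment_series`: a long tibble (`time_fs`, `fragment`,
#'   `charge_e`, optionally `spin`, `hab_mev`) sorted by time.
#' @export
read_fragment_series <- function(csv_path) {
  tab <- readr::read_csv(csv_path, show_col_types = FALSE)
  required <- c("time_fs", "fragment", "charge_e")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("fragment series lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fragment_series(tab)
}

#' Construct/validate a fragment series
#'
#' @param tab Data frame with the columns described in
#'   [read_fragment_series()].
#' @return A `fragment_series` tibble.
#' @export
fragment_series <- function(tab) {
  tab <- tibble::as_tibble(tab)
  if (anyDuplicated(tab[, c("time_fs", "fragment")])) {
    stop("duplicate (time_fs, fragment) rows in fragment series",
         call. = FALSE)
  }
  if (any(!is.finite(tab$charge_e))) {
    stop("fragment charges must be finite", call. = FALSE)
  }
  if ("hab_mev" %in% names(tab) && any(tab$hab_mev < 0, na.rm = TRUE)) {
    stop("|H_ab| must be non-negative", call. = FALSE)
  }
  tab <- dplyr::arrange(tab, .data$time_fs, .data$fragment)
  class(tab) <- c("fragment_series", class(tab))
  tab
}

#' Does a fragment series carry spin / coupling tracks?
#'
#' @param series A `fragment_series`.
#' @return Named logical vector with elements `spin` and `hab`.
#' @export
series_tracks <- function(series) {
  c(spin = "spin" %in% names(series),
    hab = "hab_mev" %in% names(series))
}

#' Write a fragment series to CSV
#'
#' @param series A `fragment_series`.
#' @param csv_path Output path.
#' @return Invisibly, `csv_path`.
#' @export
write_fragment_series <- function(series, csv_path) {
  readr::write_csv(series, csv_path)
  invisible(csv_path)
}

#' Indole charge tracks in wide form
#'
#' Convenience pivot used by the detection layer: one row per frame with
#' `q124`, `q122`, their difference, and the coupling when present.
#'
#' @param series A `fragment_series` containing fragments `W124` and `W122`.
#' @return Tibble with columns `time_fs`, `q124`, `q122`, `dq`
#'   (= q122 - q124), and `hab_mev` if available.
#' @export
indole_charges <- function(series) {
  sub <- dplyr::filter(series, .data$fragment %in% c("W124", "W122"))
  if (!nrow(sub)) stop("series contains no W124/W122 rows", call. = FALSE)
  wide <- tidyr::pivot_wider(
    sub[, c("time_fs", "fragment", "charge_e")],
    names_from = "fragment", values_from = "charge_e"
  )
  out <- tibble::tibble(
    time_fs = wide$time_fs,
    q124 = wide$W124,
    q122 = wide$W122,
    dq = wide$W122 - wide$W124
  )
  if ("hab_mev" %in% names(series)) {
    hab <- series |>
      dplyr::filter(!is.na(.data$hab_mev)) |>
      dplyr::distinct(.data$time_fs, .data$hab_mev)
    out <- dplyr::left_join(out, hab, by = "time_fs")
  }
  dplyr::arrange(out, .data$time_fs)
}
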