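#' Plot a partitioned potential trace
#'
#' Potential differences between the two indole surfaces against time:
#' the total environment difference plus the solvent and protein
#' components.
#'
#' @param object A `potential_trace` from [partition_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potential_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_fs", "dphi", "dphi_solv",
                                  "dphi_prot")],
    cols = -"time_fs", names_to = "component", values_to = "potential_v"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_fs,
                                     y = .data$potential_v,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (fs)",
                  y = expression(Delta * phi ~ "(V)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a proximal solvation profile
#'
#' g(r) with the running coordination number on a secondary panel style
#' (single panel, CN rescaled).
#'
#' @param object A `solvation_profile` from [proximal_gr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.solvation_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_mid)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$g), na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "r (Å)", y = "proximal g(r)",
                  title = attr(object, "residue")) +
    ggplot2::theme_minimal()
}

#' Plot indole charges and state labels
#'
#' Hole fraction on W124 against time, colored by the assigned state
#' label, with the localization thresholds drawn.
#'
#' @param object A `trajectory_outcome` from [classify_outcome()].
#' @param f_hi Threshold drawn as guide lines (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_outcome <- function(object, f_hi = 0.8, ...) {
  df <- object$labels
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_fs, y = .data$f,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(f_hi, 1 - f_hi),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "time (fs)", y = "hole fraction on W124",
                  colour = "state",
                  subtitle = paste("verdict:", object$verdict)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-fragment charge tracks
#'
#' @param object A `fragment_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fragment_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_fs, y = .data$charge_e,
                               colour = .data$fragment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (fs)", y = "fragment charge (e)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
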