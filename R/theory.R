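#' Marcus activation free energy
#'
#' Classical Marcus barrier for an electron-transfer step,
#' \eqn{\Delta G^\ddagger = (\lambda + \Delta G)^2 / (4 \lambda)}.
#'
#' @param lambda Reorganization energy in meV; must be positive.
#' @param delta_g Driving force in meV (positive = uphill).
#' @return Barrier height in meV.
#' @export
#' @examples
#' marcus_barrier(800, 11)   # ~205.5 meV, an uphill Trp->Trp hop
#' marcus_barrier(800, -800) # activationless point
marcus_barrier <- function(lambda, delta_g) {
  if (!is.numeric(lambda) || any(lambda <= 0)) {
    stop("`lambda` must be a positive reorganization energy (meV)", call. = FALSE)
  }
  (lambda + delta_g)^2 / (4 * lambda)
}

#' Adiabaticity-corrected activation energy
#'
#' Lowers a Marcus barrier by the strong-coupling correction
#' \eqn{H_{ab} - H_{ab}'^2 / \lambda}, where \eqn{H_{ab}} is the electronic
#' coupling in the crossing region and \eqn{H_{ab}'} the coupling near the
#' reactant minimum. The corrected barrier is floored at zero.
#'
#' @param barrier Uncorrected barrier in meV.
#' @param h_ab Coupling at the state crossing, meV (>= 0).
#' @param h_ab_min Coupling near the reactant (CS1) minimum, meV (>= 0).
#' @param lambda Reorganization energy in meV (> 0).
#' @return Corrected barrier in meV.
#' @export
#' @examples
#' adiabatic_corrected_barrier(marcus_barrier(800, 11), 40, 10, 800)
adiabatic_corrected_barrier <- function(barrier, h_ab, h_ab_min, lambda) {
  if (any(lambda <= 0)) stop("`lambda` must be > 0", call. = FALSE)
  if (any(h_ab < 0) || any(h_ab_min < 0)) {
    stop("couplings must be non-negative", call. = FALSE)
  }
  pmax(barrier - (h_ab - h_ab_min^2 / lambda), 0)
}

#' Landau-Zener adiabaticity parameter
#'
#' \eqn{2\pi\gamma = \pi^{3/2} \langle H_{ab}^2 \rangle /
#' (h \nu_{eff} \sqrt{\lambda k_B T})}. Values much larger than 1 indicate
#' adiabatic transfer controlled by nuclear/solvent motion.
#'
#' Internally all energies are converted to eV so the result is
#' dimensionless: \eqn{[\mathrm{eV}^2] / ([\mathrm{eV\,s}][\mathrm{s}^{-1}]
#' \sqrt{\mathrm{eV}\cdot\mathrm{eV}})}.
#'
#' @param h_ab_sq Mean squared coupling \eqn{\langle H_{ab}^2\rangle} in meV^2.
#' @param lambda Reorganization energy in meV.
#' @param temperature Temperature in K (default 298).
#' @param nu_eff Effective nuclear frequency in s^-1.
#' @return Dimensionless 2*pi*gamma.
#' @export
#' @examples
#' landau_zener_parameter(40^2, 800, 298, 1.5e13)  # ~1
landau_zener_parameter <- function(h_ab_sq, lambda, temperature = 298,
                                   nu_eff) {
  if (any(c(h_ab_sq, lambda, temperature, nu_eff) <= 0)) {
    stop("all Landau-Zener inputs must be positive", call. = FALSE)
  }
  h2_ev <- h_ab_sq * 1e-6    # meV^2 -> eV^2
  lam_ev <- lambda * 1e-3    # meV -> eV
  pi^1.5 * h2_ev /
    (phys_constants$h * nu_eff * sqrt(lam_ev * phys_constants$k_B * temperature))
}

#' Effective frequency at unit adiabaticity
#'
#' Inverts the Landau-Zener expression for the effective nuclear frequency at
#' which \eqn{2\pi\gamma = 1}: frequencies slower than this give
#' \eqn{2\pi\gamma > 1} (adiabatic regime).
#'
#' @inheritParams landau_zener_parameter
#' @return A list with `nu_eff` (s^-1) and `period_fs` (1/nu_eff in fs).
#' @export
#' @examples
#' nu_eff_for_unit_adiabaticity(40^2, 800, 298)  # ~1.5e13 s^-1, ~66 fs
nu_eff_for_unit_adiabaticity <- function(h_ab_sq, lambda, temperature = 298) {
  if (any(c(h_ab_sq, lambda, temperature) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  h2_ev <- h_ab_sq * 1e-6
  lam_ev <- lambda * 1e-3
  nu <- pi^1.5 * h2_ev /
    (phys_constants$h * sqrt(lam_ev * phys_constants$k_B * temperature))
  list(nu_eff = nu, period_fs = 1e15 / nu)
}

#' Adiabatic rate and lifetime
#'
#' Transition-state style rate \eqn{k = \nu_N \exp(-\Delta G^\ddagger /
#' k_B T)} with \eqn{\nu_N} the effective frequency of motion along the
#' reaction coordinate. Either supply a barrier and temperature, or a
#' pre-computed Boltzmann `activation_factor` directly.
#'
#' @param nu_n Effective nuclear frequency in s^-1.
#' @param barrier Activation energy in meV (ignored if `activation_factor`
#'   is given).
#' @param temperature Temperature in K (default 298).
#' @param activation_factor Optional dimensionless \eqn{\exp(-\Delta
#'   G^\ddagger/k_B T)} that bypasses the Boltzmann evaluation.
#' @return A list with `rate` (s^-1), `lifetime_s`, and `lifetime_ns`.
#' @export
#' @examples
#' adiabatic_rate(1e10, activation_factor = 1.2e-3)  # lifetime ~83 ns
adiabatic_rate <- function(nu_n, barrier = NULL, temperature = 298,
                           activation_factor = NULL) {
  if (nu_n <= 0) stop("`nu_n` must be positive", call. = FALSE)
  if (is.null(activation_factor)) {
    if (is.null(barrier)) {
      stop("supply either `barrier` or `activation_factor`", call. = FALSE)
    }
    activation_factor <-
      exp(-(barrier * 1e-3) / (phys_constants$k_B * temperature))
  }
  rate <- nu_n * activation_factor
  list(rate = rate, lifetime_s = 1 / rate, lifetime_ns = 1e9 / rate)
}

#' Electron-transfer parameter set
#'
#' Bundles the energetic parameters of one ET step and derives the full
#' theory block: Marcus barrier, adiabaticity-corrected barrier,
#' Landau-Zener parameter, the effective frequency giving unit
#' adiabaticity, and (when `nu_n` is supplied) the adiabatic rate and
#' lifetime.
#'
#' @param lambda Reorganization energy, meV.
#' @param delta_g Driving force, meV.
#' @param h_ab Coupling at the crossing, meV.
#' @param h_ab_min Coupling near the reactant minimum, meV (default 0).
#' @param h_ab_sq Mean squared coupling, meV^2 (default `h_ab^2`).
#' @param temperature K (default 298).
#' @param nu_eff Effective frequency for the LZ parameter, s^-1 (optional).
#' @param nu_n Effective frequency for the rate, s^-1 (optional).
#' @param activation_factor Optional dimensionless activation factor
#'   overriding the Boltzmann factor of the corrected barrier.
#' @return An object of class `et_report`; see [tidy.et_report()].
#' @export
#' @examples
#' rep <- et_parameters(lambda = 800, delta_g = 11, h_ab = 40, h_ab_min = 10,
#'                      nu_n = 1e10, activation_factor = 1.2e-3)
#' glance(rep)
et_parameters <- function(lambda, delta_g, h_ab, h_ab_min = 0,
                          h_ab_sq = h_ab^2, temperature = 298,
                          nu_eff = NULL, nu_n = NULL,
                          activation_factor = NULL) {
  barrier <- marcus_barrier(lambda, delta_g)
  corrected <- adiabatic_corrected_barrier(barrier, h_ab, h_ab_min, lambda)
  unit_nu <- nu_eff_for_unit_adiabaticity(h_ab_sq, lambda, temperature)
  lz <- if (!is.null(nu_eff)) {
    landau_zener_parameter(h_ab_sq, lambda, temperature, nu_eff)
  } else {
    NA_real_
  }
  rate <- if (!is.null(nu_n)) {
    adiabatic_rate(nu_n, barrier = corrected, temperature = temperature,
                   activation_factor = activation_factor)
  } else {
    NULL
  }
  structure(
    list(
      inputs = list(lambda = lambda, delta_g = delta_g, h_ab = h_ab,
                    h_ab_min = h_ab_min, h_ab_sq = h_ab_sq,
                    temperature = temperature, nu_eff = nu_eff, nu_n = nu_n,
                    activation_factor = activation_factor),
      barrier_mev = barrier,
      corrected_barrier_mev = corrected,
      landau_zener = lz,
      nu_eff_unit_adiabaticity = unit_nu$nu_eff,
      period_fs = unit_nu$period_fs,
      rate = rate
    ),
    class = "et_report"
  )
}

#' @export
print.et_report <- function(x, ...) {
  cat("Electron-transfer theory report\n")
  cat(sprintf("  lambda = %g meV, deltaG = %g meV, T = %g K\n",
              x$inputs$lambda, x$inputs$delta_g, x$inputs$temperature))
  cat(sprintf("  Marcus barrier:            %.2f meV\n", x$barrier_mev))
  cat(sprintf("  Coupling-corrected barrier: %.2f meV\n",
              x$corrected_barrier_mev))
  cat(sprintf("  nu_eff at 2*pi*gamma = 1:  %.3g s^-1 (period %.1f fs)\n",
              x$nu_eff_unit_adiabaticity, x$period_fs))
  if (!is.na(x$landau_zener)) {
    cat(sprintf("  2*pi*gamma at nu_eff = %.3g: %.3f\n",
                x$inputs$nu_eff, x$landau_zener))
  }
  if (!is.null(x$rate)) {
    cat(sprintf("  rate = %.3g s^-1, lifetime = %.3g ns\n",
                x$rate$rate, x$rate$lifetime_ns))
  }
  invisible(x)
}

#' Tidy an ET theory report
#'
#' One row per derived quantity, broom style.
#'
#' @param x An `et_report` from [et_parameters()].
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `value`, `unit`.
#' @export
tidy.et_report <- function(x, ...) {
  rows <- list(
    c("marcus_barrier", x$barrier_mev, "meV"),
    c("corrected_barrier", x$corrected_barrier_mev, "meV"),
    c("nu_eff_unit_adiabaticity", x$nu_eff_unit_adiabaticity, "s^-1"),
    c("period_unit_adiabaticity", x$period_fs, "fs")
  )
  if (!is.na(x$landau_zener)) {
    rows <- c(rows, list(c("landau_zener_2pigamma", x$landau_zener, "1")))
  }
  if (!is.null(x$rate)) {
    rows <- c(rows, list(c("rate", x$rate$rate, "s^-1"),
                         c("lifetime", x$rate$lifetime_ns, "ns")))
  }
  tibble::tibble(
    quantity = vapply(rows, `[`, "", 1L),
    value = as.numeric(vapply(rows, `[`, "", 2L)),
    unit = vapply(rows, `[`, "", 3L)
  )
}

#' One-row summary of an ET theory report
#'
#' @inheritParams tidy.et_report
#' @return A one-row tibble.
#' @export
glance.et_report <- function(x, ...) {
  tibble::tibble(
    lambda_mev = x$inputs$lambda,
    delta_g_mev = x$inputs$delta_g,
    barrier_mev = x$barrier_mev,
    corrected_barrier_mev = x$corrected_barrier_mev,
    nu_eff_unit_adiabaticity = x$nu_eff_unit_adiabaticity,
    lifetime_ns = if (is.null(x$rate)) NA_real_ else x$rate$lifetime_ns
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Round half-up to a multiple
#'
#' Rounds to the nearest multiple of `to`, with exact halves rounded away
#' from zero (the convention used when quoting barriers to the nearest
#' 10 meV).
#'
#' @param x Numeric vector.
#' @param to Positive multiple to round to.
#' @return Numeric vector.
#' @export
#' @examples
#' round_half_up(205.54, 10)  # 210
round_half_up <- function(x, to = 1) {
  stopifnot(to > 0)
  sign(x) * floor(abs(x) / to + 0.5) * to
}

#' Round to significant figures
#'
#' @param x Numeric vector.
#' @param digits Number of significant figures.
#' @return Numeric vector.
#' @export
signif_figs <- function(x, digits = 2) signif(x, digits)
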