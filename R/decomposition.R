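#' Electrostatic QM/MM interaction energy from total and gas-phase energies
#'
#' The probe energy computed in the embedding charges (E_total) contains the
#' probe's own gas-phase energy at the same geometry (E_self); their
#' difference is the electrostatic interaction energy E_EI = E_total -
#' E_self. The operation is exactly linear and gauge-invariant: adding any
#' constant to both inputs leaves it unchanged.
#'
#' @param e_total total embedded energy, kcal/mol (vectorized).
#' @param e_self gas-phase self energy at the same geometry, kcal/mol.
#' @return E_EI in kcal/mol.
#' @export
interaction_energy <- function(e_total, e_self) {
  if (!all(is.finite(e_total)) || !all(is.finite(e_self)))
    stop("non-finite energy: E_total/E_self columns contain bad values")
  e_total - e_self
}

#' Remove the linear bond-length component from a per-frame series
#'
#' Interaction energies and ESP charges fluctuate with the CO bond length as
#' well as with the field. This removes the linear bond-length component by
#' ordinary least squares on the centered bond length, preserving the series
#' mean, so downstream field regressions see a series free of that trend.
#'
#' @param values numeric series (kcal/mol or e), length >= 3.
#' @param bond_lengths matching bond lengths (Angstrom), not all identical.
#' @param frame_index optional integer labels.
#' @return An object of class \code{detrended_series}: \code{residuals}
#'   (same mean as \code{values}), \code{detrend_slope} (fitted linear
#'   coefficient, units of values per Angstrom), \code{regressor},
#'   \code{frame_index}.
#' @details Detrending is idempotent and its residuals are uncorrelated with
#'   the regressor by construction.
#' @export
detrend_on_bond_length <- function(values, bond_lengths, frame_index = NULL) {
  values <- as.numeric(values)
  bond_lengths <- as.numeric(bond_lengths)
  n <- length(values)
  if (length(bond_lengths) != n)
    stop("values and bond_lengths must have equal length")
  if (n < 3L) stop("need at least 3 samples to detrend")
  x <- bond_lengths - mean(bond_lengths)
  sxx <- sum(x^2)
  if (sxx == 0)
    stop("degenerate regressor: bond_lengths has zero variance")
  slope <- sum(x * values) / sxx
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  structure(
    list(frame_index = as.integer(frame_index),
         residuals = values - slope * x,
         detrend_slope = slope,
         regressor = bond_lengths),
    class = "detrended_series")
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf(
    "detrended series: n = %d, bond-length slope = %.4g per A\n",
    length(x$residuals), x$detrend_slope))
  invisible(x)
}

#' @export
residuals.detrended_series <- function(object, ...) object$residuals
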