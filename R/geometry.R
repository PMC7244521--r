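#' Fe...C=O angle
#'
#' The angle at the probe C atom between the ray toward the heme iron and
#' the ray toward the O atom, in degrees. Obtuse angles (mode near 115
#' degrees) correspond to the B1 orientation of photodissociated CO; acute
#' angles (mode near 50-55 degrees) to B2.
#'
#' @param fe_position,c_position,o_position numeric length-3 positions
#'   (Angstrom).
#' @return angle in degrees, in [0, 180].
#' @export
fe_co_angle <- function(fe_position, c_position, o_position) {
  fe_position <- as.numeric(fe_position)
  c_position <- as.numeric(c_position)
  o_position <- as.numeric(o_position)
  u <- fe_position - c_position
  v <- o_position - c_position
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-6 || nv < 1e-6)
    stop("coincident points: C must be > 1e-6 A from both Fe and O")
  ct <- sum(u * v) / (nu * nv)
  acos(min(max(ct, -1), 1)) * 180 / pi
}

#' Classify an Fe...C=O angle into the B1 or B2 orientational state
#'
#' B1 (O pointing away from the iron) shows obtuse angles, B2 acute ones.
#' The boundary sits at 90 degrees, far from both population modes, with the
#' boundary value itself assigned to B2 as a deterministic tie-break.
#'
#' @param angle angle in degrees, in [0, 180] (vectorized).
#' @return character vector of "B1" / "B2".
#' @export
classify_state <- function(angle) {
  if (any(!is.finite(angle)) || any(angle < 0) || any(angle > 180))
    stop("angles must lie in [0, 180] degrees")
  ifelse(angle > 90, "B1", "B2")
}

#' B1/B2 population counts and ratio for an angle series
#'
#' @param angles numeric vector of Fe...C=O angles (degrees) or a data.frame
#'   with an \code{angle} column.
#' @return A \code{state_counts} object: \code{n_b1}, \code{n_b2},
#'   \code{ratio} = n_b1/n_b2. If no frame is B2 the ratio is infinite and a
#'   warning is raised; the counts are still returned.
#' @export
state_ratio <- function(angles) {
  if (is.data.frame(angles)) angles <- angles$angle
  if (length(angles) == 0L) stop("empty angle series")
  st <- classify_state(angles)
  n_b1 <- sum(st == "B1")
  n_b2 <- sum(st == "B2")
  if (n_b2 == 0L) {
    warning("no B2 frames: B1/B2 ratio undefined (reported as Inf)")
    ratio <- Inf
  } else ratio <- n_b1 / n_b2
  structure(list(n_b1 = n_b1, n_b2 = n_b2, ratio = ratio),
            class = "state_counts")
}

#' @export
print.state_counts <- function(x, ...) {
  cat(sprintf("B1: %d  B2: %d  B1/B2 = %s\n", x$n_b1, x$n_b2,
              if (is.finite(x$ratio)) sprintf("%.3f", x$ratio) else "undefined"))
  invisible(x)
}

#' Normalized angle histogram over [0, 180] degrees
#'
#' Bins are half-open [lo, hi) with the last bin closed at 180. Densities
#' integrate to 1 (sum of density * bin width = 1).
#'
#' @param angles numeric angles in degrees, or a data.frame with an
#'   \code{angle} column.
#' @param bin_width bin width in degrees; must divide 180 evenly
#'   (default 2).
#' @return a data.frame with columns \code{lower}, \code{upper},
#'   \code{mid}, \code{count}, \code{density} (per degree).
#' @export
angle_histogram <- function(angles, bin_width = 2) {
  if (is.data.frame(angles)) angles <- angles$angle
  if (bin_width <= 0 || abs(180 / bin_width - round(180 / bin_width)) > 1e-9)
    stop("bin_width must be positive and divide 180 evenly")
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles > 180))
    stop("angles must lie in [0, 180] degrees")
  nbin <- as.integer(round(180 / bin_width))
  idx <- pmin(floor(angles / bin_width), nbin - 1L) + 1L
  count <- tabulate(idx, nbins = nbin)
  lower <- (seq_len(nbin) - 1L) * bin_width
  data.frame(
    lower = lower, upper = lower + bin_width, mid = lower + bin_width / 2,
    count = count,
    density = count / (length(angles) * bin_width))
}
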