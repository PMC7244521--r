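#' Coulomb energy conversion constant
#'
#' Converts the product of two elementary charges divided by a distance in
#' Angstrom into kcal/mol: \code{K_COUL} = 332.0636 kcal mol^-1 A e^-2.
#' Potentials and fields are kept in native units (e/A and e/A^2); the
#' constant is applied exactly once, at the energy level, so every
#' intermediate number stays auditable.
#'
#' @format A length-one numeric.
#' @export
K_COUL <- 332.0636

# Minimum allowed separation (A) between an environment charge and any
# evaluation point: converts a malformed input into a clear error rather
# than an enormous Coulomb term.
.SINGULARITY_GUARD <- 0.5

#' Construct a CO probe
#'
#' A diatomic probe defined by the positions of its C and O atoms. The bond
#' vector points from C to O; that direction defines the positive sign of the
#' electric field along the bond.
#'
#' @param c_position numeric length-3, position of the C atom (Angstrom).
#' @param o_position numeric length-3, position of the O atom (Angstrom).
#' @return An object of class \code{co_probe} with elements
#'   \code{c_position}, \code{o_position}, \code{bond_vector} (C to O) and
#'   \code{bond_length} (Angstrom).
#' @details A bond length outside [0.8, 1.6] Angstrom is physically
#'   implausible for CO and triggers a warning (not an error).
#' @examples
#' co_probe(c(0, 0, 0), c(1.14, 0, 0))
#' @export
co_probe <- function(c_position, o_position) {
  c_position <- as.numeric(c_position)
  o_position <- as.numeric(o_position)
  if (length(c_position) != 3L || length(o_position) != 3L)
    stop("probe positions must be length-3 numeric vectors")
  if (!all(is.finite(c_position)) || !all(is.finite(o_position)))
    stop("probe coordinates must be finite")
  bond_vector <- o_position - c_position
  bond_length <- sqrt(sum(bond_vector^2))
  if (bond_length <= 0)
    stop("probe C and O positions coincide: bond length must be > 0")
  if (bond_length < 0.8 || bond_length > 1.6)
    warning(sprintf(
      "CO bond length %.3f A outside plausible range [0.8, 1.6] A",
      bond_length))
  structure(
    list(c_position = c_position, o_position = o_position,
         bond_vector = bond_vector, bond_length = bond_length),
    class = "co_probe")
}

#' @export
print.co_probe <- function(x, ...) {
  cat(sprintf("CO probe: |r_CO| = %.4f A, C at (%.3f, %.3f, %.3f)\n",
              x$bond_length, x$c_position[1], x$c_position[2],
              x$c_position[3]))
  invisible(x)
}

#' Construct a point-charge environment
#'
#' The MM surroundings of the probe: an ordered collection of point charges
#' (protein, heme, solvent) with positions in Angstrom and charges in units
#' of the elementary charge.
#'
#' @param positions numeric matrix, n x 3 (Angstrom). A single atom may be
#'   given as a length-3 vector.
#' @param charges numeric length n, partial charges (e).
#' @param residue_index optional integer length n, residue labels.
#' @param atom_index optional integer length n, atom labels.
#' @return An object of class \code{charge_environment}.
#' @export
charge_environment <- function(positions, charges,
                               residue_index = NULL, atom_index = NULL) {
  if (is.null(dim(positions))) {
    positions <- matrix(as.numeric(positions), ncol = 3,
                        byrow = length(positions) > 3)
  }
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix")
  charges <- as.numeric(charges)
  n <- nrow(positions)
  if (length(charges) != n)
    stop("length(charges) must equal nrow(positions)")
  if (n > 0 && (!all(is.finite(positions)) || !all(is.finite(charges))))
    stop("positions and charges must be finite")
  if (is.null(residue_index)) residue_index <- rep.int(1L, n)
  if (is.null(atom_index)) atom_index <- seq_len(n)
  structure(
    list(positions = positions, charges = charges,
         residue_index = as.integer(residue_index),
         atom_index = as.integer(atom_index)),
    class = "charge_environment")
}

#' @export
print.charge_environment <- function(x, ...) {
  cat(sprintf("Charge environment: %d atoms, net charge %+.4f e\n",
              nrow(x$positions), sum(x$charges)))
  invisible(x)
}

#' Number of atoms in a charge environment
#' @param env a \code{charge_environment}.
#' @return integer count.
#' @export
n_atoms <- function(env) nrow(env$positions)

#' Merge two charge environments
#' @param a,b \code{charge_environment} objects.
#' @return their union as a \code{charge_environment}.
#' @export
merge_environments <- function(a, b) {
  charge_environment(rbind(a$positions, b$positions),
                     c(a$charges, b$charges),
                     c(a$residue_index, b$residue_index),
                     c(a$atom_index, b$atom_index))
}

# distances from every environment atom to a point, with an optional cutoff
# (atoms beyond the cutoff are dropped, mirroring the electrostatic cutoff
# used by QM/MM engines)
.env_distances <- function(env, point) {
  d <- env$positions - matrix(point, nrow = nrow(env$positions), ncol = 3,
                              byrow = TRUE)
  sqrt(rowSums(d * d))
}

#' Electrostatic potential of a point-charge environment
#'
#' Evaluates phi(r) = (1/eps_eff) * sum_j q_j / |r - r_j| over all
#' environment atoms, in native units of e/A. The 1/(4 pi eps0) factor is
#' absorbed into the unit convention and applied only when converting to
#' energies (see \code{\link{K_COUL}}).
#'
#' @param env a \code{\link{charge_environment}}.
#' @param point numeric length-3 evaluation point (Angstrom).
#' @param eps_eff effective dielectric constant (dimensionless divisor),
#'   default 1.0 as appropriate with explicit solvent.
#' @param cutoff optional radius (Angstrom); charges farther than this from
#'   the point are excluded. \code{NULL} (default) sums over all atoms.
#' @return potential in e/A. An empty environment gives 0.
#' @examples
#' env <- charge_environment(c(2, 0, 0), 1)
#' potential_at_point(env, c(0, 0, 0))  # 0.5 e/A
#' @export
potential_at_point <- function(env, point, eps_eff = 1.0, cutoff = NULL) {
  stopifnot(inherits(env, "charge_environment"))
  if (eps_eff <= 0) stop("eps_eff must be > 0")
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point)))
    stop("point must be a finite length-3 vector")
  if (nrow(env$positions) == 0L) return(0)
  r <- .env_distances(env, point)
  if (any(r < .SINGULARITY_GUARD))
    stop(sprintf(
      "singularity: environment atom within %.1f A of evaluation point (min distance %.3g A)",
      .SINGULARITY_GUARD, min(r)))
  q <- env$charges
  if (!is.null(cutoff)) {
    keep <- r <= cutoff
    r <- r[keep]; q <- q[keep]
    if (length(r) == 0L) return(0)
  }
  sum(q / r) / eps_eff
}

#' Mean electric field along the probe bond
#'
#' The field is the potential difference between the C and O atom centers
#' divided by the bond length: F = (phi(r_C) - phi(r_O)) / |r_CO|, in e/A^2.
#' The positive direction points from C toward O, so a configuration with
#' higher potential at C than at O gives a positive field.
#'
#' @inheritParams potential_at_point
#' @param probe a \code{\link{co_probe}}.
#' @param frame_index integer label stored with the sample (default 0).
#' @return A \code{field_sample}: list with \code{frame_index},
#'   \code{field} (e/A^2) and \code{bond_length} (Angstrom).
#' @export
field_along_bond <- function(env, probe, eps_eff = 1.0, cutoff = NULL,
                             frame_index = 0L) {
  stopifnot(inherits(probe, "co_probe"))
  phi_c <- potential_at_point(env, probe$c_position, eps_eff, cutoff)
  phi_o <- potential_at_point(env, probe$o_position, eps_eff, cutoff)
  structure(
    list(frame_index = as.integer(frame_index),
         field = (phi_c - phi_o) / probe$bond_length,
         bond_length = probe$bond_length),
    class = "field_sample")
}

#' @export
print.field_sample <- function(x, ...) {
  cat(sprintf("field sample [frame %d]: F = %+.6g e/A^2, |r_CO| = %.4f A\n",
              x$frame_index, x$field, x$bond_length))
  invisible(x)
}

#' Linear polarizable-charge model for the probe O atom
#'
#' The ESP charge of the O atom responds linearly to the field along the
#' bond: q_O = alpha * F + q0. The probe stays neutral, so q_C = -q_O. At
#' zero field the gas-phase ESP charge q0 of CO is very small.
#'
#' @param alpha linear response coefficient, e per (e/A^2).
#' @param q0 zero-field O charge (e), default 0.
#' @return An object of class \code{polarizable_charge_model}.
#' @export
polarizable_charge_model <- function(alpha, q0 = 0) {
  if (!is.finite(alpha) || !is.finite(q0))
    stop("alpha and q0 must be finite")
  structure(list(alpha = alpha, q0 = q0),
            class = "polarizable_charge_model")
}

#' O-atom charge under the linear polarizable model
#'
#' @param field field along the bond, e/A^2 (vectorized).
#' @param model a \code{\link{polarizable_charge_model}}.
#' @return q_O in e; a positive field gives a positive O charge (the C-O+
#'   state), a negative field a negative one (C+O-), when \code{q0 = 0}.
#' @export
polarizable_charge <- function(field, model) {
  stopifnot(inherits(model, "polarizable_charge_model"))
  model$alpha * field + model$q0
}

#' Classical point-charge interaction energy of the probe
#'
#' E = K_COUL * (q_C * phi(r_C) + q_O * phi(r_O)) in kcal/mol, with the
#' potentials from \code{\link{potential_at_point}}. By default the probe is
#' neutral (q_C = -q_O); pass \code{q_C} explicitly to override.
#'
#' @inheritParams field_along_bond
#' @param q_O charge on the O atom (e).
#' @param q_C charge on the C atom (e); default \code{-q_O}.
#' @return energy in kcal/mol.
#' @export
classical_interaction_energy <- function(env, probe, q_O, q_C = -q_O,
                                         eps_eff = 1.0, cutoff = NULL) {
  stopifnot(inherits(probe, "co_probe"))
  phi_c <- potential_at_point(env, probe$c_position, eps_eff, cutoff)
  phi_o <- potential_at_point(env, probe$o_position, eps_eff, cutoff)
  K_COUL * (q_C * phi_c + q_O * phi_o)
}

#' Polarization energy of the neutral probe in a uniform field
#'
#' Energy of the self-consistently polarized neutral probe whose O charge
#' follows the linear model: E = -K_COUL * (alpha * F + q0) * F * l, in
#' kcal/mol. For q0 = 0 this is an even (purely quadratic) function of the
#' field, stabilizing for alpha > 0; its extremum sits at F = -q0/(2 alpha).
#'
#' @param field field along the bond, e/A^2 (vectorized).
#' @param model a \code{\link{polarizable_charge_model}}.
#' @param bond_length probe bond length (Angstrom), > 0.
#' @return energy in kcal/mol.
#' @export
polarization_energy <- function(field, model, bond_length) {
  stopifnot(inherits(model, "polarizable_charge_model"))
  if (bond_length <= 0) stop("bond_length must be > 0")
  -K_COUL * (model$alpha * field + model$q0) * field * bond_length
}
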