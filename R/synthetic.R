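#' Specification of a synthetic point-charge scene
#'
#' Describes the random microscopic scenes used to exercise the
#' electrostatics stage: a CO probe with a fluctuating bond length, an iron
#' atom a few Angstrom away, and force-field-like point charges scattered in
#' a shell around the probe (the outer radius mirrors the 25 A electrostatic
#' cutoff typical of QM/MM engines).
#'
#' @param n_env_charges number of environment charges (the last one balances
#'   the net charge to zero); default 200.
#' @param r_min,r_max shell radii around the probe (Angstrom), defaults 3
#'   and 25.
#' @param charge_scale half-width of the uniform charge distribution (e),
#'   default 0.4 (force-field-like partial charges).
#' @param bond_mean,bond_sd CO bond length distribution (Angstrom), defaults
#'   1.14 and 0.02.
#' @return an object of class \code{scene_spec}.
#' @export
scene_spec <- function(n_env_charges = 200, r_min = 3, r_max = 25,
                       charge_scale = 0.4, bond_mean = 1.14,
                       bond_sd = 0.02) {
  if (r_min <= 0 || r_min >= r_max)
    stop("need 0 < r_min < r_max")
  if (bond_sd < 0) stop("bond_sd must be >= 0")
  structure(
    list(n_env_charges = as.integer(n_env_charges), r_min = r_min,
         r_max = r_max, charge_scale = charge_scale,
         bond_mean = bond_mean, bond_sd = bond_sd),
    class = "scene_spec")
}

# uniform directions on the unit sphere
.runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Generate one synthetic microscopic scene
#'
#' The probe sits at the origin along the x axis with a sampled bond length;
#' the iron is placed at a random direction 3-5 Angstrom from the C atom;
#' environment charges are uniform in the shell, with the final charge
#' chosen to bring the net charge to zero. Deterministic given a seed.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param seed optional integer seed.
#' @return list with \code{env} (a \code{charge_environment}), \code{probe}
#'   (a \code{co_probe}) and \code{fe_position}.
#' @export
generate_scene <- function(spec = scene_spec(), seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(seed)) set.seed(seed)
  l <- stats::rnorm(1, spec$bond_mean, spec$bond_sd)
  l <- max(l, 0.9)  # keep the probe physical even in the extreme tail
  probe <- co_probe(c(0, 0, 0), c(l, 0, 0))
  fe_position <- as.numeric(.runif_sphere(1)) * stats::runif(1, 3, 5)
  n <- spec$n_env_charges
  if (n == 0L) {
    env <- charge_environment(matrix(numeric(0), ncol = 3), numeric(0))
  } else {
    center <- (probe$c_position + probe$o_position) / 2
    r <- (stats::runif(n, spec$r_min^3, spec$r_max^3))^(1 / 3)
    pos <- .runif_sphere(n) * r +
      matrix(center, nrow = n, ncol = 3, byrow = TRUE)
    q <- stats::runif(n, -spec$charge_scale, spec$charge_scale)
    q[n] <- -sum(q[-n])
    env <- charge_environment(pos, q)
  }
  list(env = env, probe = probe, fe_position = fe_position)
}

#' Generate many scenes and their microscopically computed fields
#'
#' Each frame's field is computed by \code{\link{field_along_bond}} on the
#' generated charges (never shortcut from the generator parameters), so the
#' table exercises the same code path as real structures.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param n_scenes number of frames.
#' @param seed optional integer seed.
#' @param eps_eff effective dielectric constant.
#' @param keep_scenes keep the full scene objects (default FALSE).
#' @return a data.frame with columns \code{frame}, \code{field},
#'   \code{bond_length}, \code{angle} (Fe...C=O, degrees); if
#'   \code{keep_scenes}, the scenes are attached as attribute
#'   \code{"scenes"}.
#' @export
generate_scene_table <- function(spec = scene_spec(), n_scenes, seed = NULL,
                                 eps_eff = 1.0, keep_scenes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  field <- bond_length <- angle <- numeric(n_scenes)
  scenes <- if (keep_scenes) vector("list", n_scenes) else NULL
  for (i in seq_len(n_scenes)) {
    sc <- generate_scene(spec, seed = NULL)
    fs <- field_along_bond(sc$env, sc$probe, eps_eff, frame_index = i - 1L)
    field[i] <- fs$field
    bond_length[i] <- fs$bond_length
    angle[i] <- fe_co_angle(sc$fe_position, sc$probe$c_position,
                            sc$probe$o_position)
    if (keep_scenes) scenes[[i]] <- sc
  }
  out <- data.frame(frame = seq_len(n_scenes) - 1L, field = field,
                    bond_length = bond_length, angle = angle)
  if (keep_scenes) attr(out, "scenes") <- scenes
  out
}

#' Ground truth for the statistical trajectory generator
#'
#' Defines the statistical structure the generator emulates: per-method EAC
#' dipole models (defaulting to the published HF/B3LYP/MP2 charges), a
#' linear polarizable ESP charge for the O atom, Gaussian observation noise,
#' a two-component circular mixture of Fe...C=O angles peaked at the B1 and
#' B2 modes, and a weak linear coupling of energy to the CO bond length.
#'
#' @param models named list of \code{\link{eac_model}} objects; default
#'   built from \code{\link{mbco_eac_charges}} with l = 1.14 A.
#' @param alpha,q0 linear ESP-charge response (e per (e/A^2)) and zero-field
#'   O charge (e); defaults 2.0 and 0.005 (near-zero gas-phase charge).
#' @param field_sd scale of the field distribution (e/A^2), default 0.02 —
#'   paired with the default charges this puts interaction energies on the
#'   few-kcal/mol scale.
#' @param p_pos probability of a positive-field frame (default 0.5,
#'   symmetric two-sided distribution; real trajectories need not be
#'   balanced).
#' @param sd_energy,sd_charge Gaussian noise on energies (kcal/mol, default
#'   0.1) and ESP charges (e, default 0.005).
#' @param bond_mean,bond_sd CO bond length distribution (Angstrom).
#' @param bond_coupling linear energy/bond-length coupling (kcal/mol per
#'   Angstrom), default 0.3 — small relative to the field response.
#' @param angle_means B1/B2 mode locations (degrees), default c(115, 52.5).
#' @param angle_weights mixture weights (normalized internally), default
#'   c(3.45, 1).
#' @param angle_sd circular spread of each mode (degrees), default 10.
#' @param e_self named per-method gas-phase self energies (kcal/mol); any
#'   constants work since the decomposition is gauge-invariant.
#' @return an object of class \code{generator_truth}.
#' @export
generator_truth <- function(models = NULL, alpha = 2.0, q0 = 0.005,
                            field_sd = 0.02, p_pos = 0.5,
                            sd_energy = 0.1, sd_charge = 0.005,
                            bond_mean = 1.14, bond_sd = 0.02,
                            bond_coupling = 0.3,
                            angle_means = c(115, 52.5),
                            angle_weights = c(3.45, 1),
                            angle_sd = 10,
                            e_self = NULL) {
  if (is.null(models)) {
    ch <- mbco_eac_charges()
    models <- lapply(seq_len(nrow(ch)), function(i)
      eac_model(ch$q_pos[i], ch$q_neg[i], 1.14, ch$method[i]))
    names(models) <- ch$method
  }
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("models must be a named list")
  if (any(angle_weights <= 0)) stop("angle weights must be positive")
  if (length(angle_weights) != length(angle_means))
    stop("angle_means and angle_weights must match")
  if (any(angle_means <= 0) || any(angle_means >= 180))
    stop("angle mixture means must lie in (0, 180)")
  if (sd_energy < 0 || sd_charge < 0 || angle_sd < 0)
    stop("noise sds must be >= 0")
  if (is.null(e_self)) {
    e_self <- stats::setNames(
      -71000 - 100 * seq_along(models), names(models))
  }
  structure(
    list(models = models,
         charge_model = polarizable_charge_model(alpha, q0),
         field_sd = field_sd, p_pos = p_pos,
         sd_energy = sd_energy, sd_charge = sd_charge,
         bond_mean = bond_mean, bond_sd = bond_sd,
         bond_coupling = bond_coupling,
         angle_means = angle_means,
         angle_weights = angle_weights / sum(angle_weights),
         angle_sd = angle_sd,
         e_self = e_self),
    class = "generator_truth")
}

#' Generate a synthetic per-frame field/energy study
#'
#' Fields are drawn from a two-sided distribution (sign with probability
#' \code{p_pos}, magnitude half-normal with scale \code{field_sd}); per
#' method the true interaction energy is the EAC model energy plus the
#' bond-length coupling and Gaussian noise, and is emitted as
#' E_total = E_self + E_EI so the decomposition stage is genuinely
#' exercised. ESP O charges follow the linear polarizable model plus noise.
#'
#' @param truth a \code{\link{generator_truth}}.
#' @param n_frames number of frames (>= 1).
#' @param seed optional integer seed.
#' @return an object of class \code{synthetic_study}: \code{frames}
#'   (data.frame: frame, field, bond_length, q_O), \code{energies}
#'   (data.frame: frame, method, E_total, E_self) and the \code{truth}.
#' @export
generate_field_energy_table <- function(truth = generator_truth(), n_frames,
                                        seed = NULL) {
  stopifnot(inherits(truth, "generator_truth"), n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_frames)
  sgn <- ifelse(stats::runif(n) < truth$p_pos, 1, -1)
  field <- sgn * abs(stats::rnorm(n, 0, truth$field_sd))
  l <- stats::rnorm(n, truth$bond_mean, truth$bond_sd)
  q_o <- polarizable_charge(field, truth$charge_model) +
    stats::rnorm(n, 0, truth$sd_charge)
  frames <- data.frame(frame = seq_len(n) - 1L, field = field,
                       bond_length = l, q_O = q_o)
  energies <- do.call(rbind, lapply(names(truth$models), function(m) {
    e_ei <- eac_energy(truth$models[[m]], field) +
      truth$bond_coupling * (l - truth$bond_mean) +
      stats::rnorm(n, 0, truth$sd_energy)
    data.frame(frame = frames$frame, method = m,
               E_total = truth$e_self[[m]] + e_ei,
               E_self = truth$e_self[[m]],
               stringsAsFactors = FALSE)
  }))
  rownames(energies) <- NULL
  structure(list(frames = frames, energies = energies, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic study: %d frames x %d methods (%s)\n",
    nrow(x$frames), length(x$truth$models),
    paste(names(x$truth$models), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic Fe...C=O angle series
#'
#' Each frame's mixture component is chosen by weight and its angle drawn
#' from a wrapped-normal-style circular distribution (normal draw wrapped to
#' [0, 360) and folded into [0, 180]). Deterministic given a seed.
#'
#' @param truth a \code{\link{generator_truth}}.
#' @param n_frames number of frames.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{frame}, \code{angle} (degrees),
#'   \code{component} (1 = first mixture mode).
#' @export
generate_angle_series <- function(truth = generator_truth(), n_frames,
                                  seed = NULL) {
  stopifnot(inherits(truth, "generator_truth"), n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_frames)
  comp <- sample.int(length(truth$angle_weights), n, replace = TRUE,
                     prob = truth$angle_weights)
  raw <- stats::rnorm(n, truth$angle_means[comp], truth$angle_sd)
  a <- raw %% 360
  a <- ifelse(a > 180, 360 - a, a)
  data.frame(frame = seq_len(n) - 1L, angle = a, component = comp)
}
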