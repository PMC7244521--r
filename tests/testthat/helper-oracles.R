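# Independent naive Coulomb sum: explicit double loop over residues and
# atoms, kept deliberately separate from the vectorized implementation.
naive_potential <- function(env, point, eps_eff = 1.0) {
  total <- 0
  for (res in unique(env$residue_index)) {
    idx <- which(env$residue_index == res)
    for (j in idx) {
      rij <- sqrt(sum((point - env$positions[j, ])^2))
      total <- total + env$charges[j] / rij
    }
  }
  total / eps_eff
}

naive_field <- function(env, probe, eps_eff = 1.0) {
  (naive_potential(env, probe$c_position, eps_eff) -
     naive_potential(env, probe$o_position, eps_eff)) / probe$bond_length
}

# random charge scene guaranteed clear of the singularity guard around
# the probe/evaluation region near the origin
random_scene_env <- function(n, r_min = 2, r_max = 12) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- u * runif(n, r_min, r_max)
  charge_environment(pos, runif(n, -1, 1),
                     residue_index = sample.int(max(1, n %/% 4), n,
                                                replace = TRUE))
}

# binomial 3-sigma tolerance for a recovered two-state count ratio, by the
# delta method on the B1 proportion
ratio_tolerance_3se <- function(true_ratio, n) {
  p <- true_ratio / (1 + true_ratio)
  se_p <- sqrt(p * (1 - p) / n)
  3 * se_p / (1 - p)^2
}
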