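test_that("co_probe derives bond geometry and guards implausible lengths", {
  p <- co_probe(c(0, 0, 0), c(1.14, 0, 0))
  expect_equal(p$bond_vector, c(1.14, 0, 0))
  expect_equal(p$bond_length, 1.14)
  expect_warning(co_probe(c(0, 0, 0), c(2.5, 0, 0)), "plausible")
  expect_error(co_probe(c(1, 1, 1), c(1, 1, 1)), "coincide")
  expect_error(co_probe(c(0, 0, NA), c(1, 0, 0)), "finite")
})

test_that("potential_at_point matches hand-evaluated cases", {
  empty <- charge_environment(matrix(numeric(0), ncol = 3), numeric(0))
  expect_identical(potential_at_point(empty, c(1, 2, 3)), 0)

  # +1 and -1 at equal distance cancel
  env <- charge_environment(rbind(c(3, 0, 0), c(0, 3, 0)), c(1, -1))
  expect_equal(potential_at_point(env, c(0, 0, 0)), 0)

  # single +1 e at 2.0 A -> 0.5 e/A; eps_eff is a plain divisor
  env1 <- charge_environment(c(2, 0, 0), 1)
  expect_equal(potential_at_point(env1, c(0, 0, 0)), 0.5)
  expect_equal(potential_at_point(env1, c(0, 0, 0), eps_eff = 2), 0.25)
})

test_that("singularity guard and cutoff behave as specified", {
  env <- charge_environment(c(0.3, 0, 0), 1)
  expect_error(potential_at_point(env, c(0, 0, 0)), "singularity")
  far <- charge_environment(rbind(c(2, 0, 0), c(30, 0, 0)), c(1, 1))
  expect_equal(potential_at_point(far, c(0, 0, 0), cutoff = 25), 0.5)
  expect_equal(potential_at_point(far, c(0, 0, 0)), 0.5 + 1 / 30)
})

test_that("potential agrees with an independent naive double loop", {
  set.seed(42)
  for (k in 1:20) {
    env <- random_scene_env(sample(5:200, 1))
    point <- rnorm(3, sd = 0.3)
    expect_equal(potential_at_point(env, point),
                 naive_potential(env, point), tolerance = 1e-12)
  }
})

test_that("field along the bond follows the closed form and sign contract", {
  probe <- co_probe(c(0, 0, 0), c(1, 0, 0))
  empty <- charge_environment(matrix(numeric(0), ncol = 3), numeric(0))
  expect_identical(field_along_bond(empty, probe)$field, 0)

  # +1 e on the C->O axis, 2.0 A behind C: (1/2 - 1/3)/1
  env <- charge_environment(c(-2, 0, 0), 1)
  fs <- field_along_bond(env, probe, frame_index = 7L)
  expect_equal(fs$field, (1 / 2 - 1 / 3) / 1, tolerance = 1e-14)
  expect_identical(fs$frame_index, 7L)
  expect_equal(fs$bond_length, 1)

  # any positive charge nearer C than O gives a positive field
  set.seed(1)
  for (k in 1:10) {
    pos <- rnorm(3); pos <- pos / sqrt(sum(pos^2)) * runif(1, 2, 8)
    d_c <- sqrt(sum(pos^2)); d_o <- sqrt(sum((pos - c(1, 0, 0))^2))
    if (d_c < d_o)
      expect_gt(field_along_bond(charge_environment(pos, 1), probe)$field, 0)
  }
})

test_that("field is additive over environments and linear in charges", {
  set.seed(7)
  probe <- co_probe(c(0, 0, 0), c(1.14, 0, 0))
  for (k in 1:5) {
    a <- random_scene_env(40)
    b <- random_scene_env(60)
    f_union <- field_along_bond(merge_environments(a, b), probe)$field
    f_sum <- field_along_bond(a, probe)$field +
      field_along_bond(b, probe)$field
    expect_equal(f_union, f_sum, tolerance = 1e-10)

    scaled <- charge_environment(a$positions, 3.5 * a$charges)
    expect_equal(field_along_bond(scaled, probe)$field,
                 3.5 * field_along_bond(a, probe)$field, tolerance = 1e-12)
    expect_equal(
      classical_interaction_energy(scaled, probe, q_O = 0.1),
      3.5 * classical_interaction_energy(a, probe, q_O = 0.1),
      tolerance = 1e-12)
  }
})

test_that("polarizable charge is linear in the field with the stated signs", {
  m <- polarizable_charge_model(alpha = 0.5, q0 = 0)
  expect_identical(polarizable_charge(0, m), 0)
  expect_equal(polarizable_charge(0.2, m), 0.1)
  expect_gt(polarizable_charge(0.03, m), 0)   # C-O+ under positive field
  expect_lt(polarizable_charge(-0.03, m), 0)  # C+O- under negative field
})

test_that("classical interaction energy matches the hand sum", {
  probe <- co_probe(c(0, 0, 0), c(1, 0, 0))
  env <- charge_environment(c(-2, 0, 0), 1)  # 2 A from C, 3 A from O
  expect_identical(
    classical_interaction_energy(env, probe, q_O = 0, q_C = 0), 0)
  expect_equal(
    classical_interaction_energy(env, probe, q_O = 0.1),
    K_COUL * (-0.1 * 0.5 + 0.1 / 3), tolerance = 1e-12)

  # neutral probe equidistant from a single charge: potentials cancel
  eq_env <- charge_environment(c(0.5, 3, 0), 1)
  expect_equal(
    classical_interaction_energy(eq_env, probe, q_O = 0.2),
    0, tolerance = 1e-12)
})

test_that("polarization energy is an even quadratic with the stated vertex", {
  m0 <- polarizable_charge_model(alpha = 0.5, q0 = 0)
  expect_equal(polarization_energy(0.1, m0, 1.14),
               -332.0636 * 0.5 * 0.01 * 1.14, tolerance = 1e-12)
  f <- seq(-0.05, 0.05, length.out = 41)
  expect_equal(polarization_energy(f, m0, 1.14),
               polarization_energy(-f, m0, 1.14), tolerance = 1e-15)

  # pure quadratic: no residual once a degree-2 polynomial is removed
  qfit <- lm(polarization_energy(f, m0, 1.14) ~ f + I(f^2))
  expect_lt(max(abs(residuals(qfit))), 1e-12)

  # nonzero gas-phase charge shifts the extremum to -q0/(2 alpha)
  m1 <- polarizable_charge_model(alpha = 0.5, q0 = 0.004)
  qfit1 <- coef(lm(polarization_energy(f, m1, 1.14) ~ f + I(f^2)))
  vertex <- -qfit1[["f"]] / (2 * qfit1[["I(f^2)"]])
  expect_equal(vertex, -m1$q0 / (2 * m1$alpha), tolerance = 1e-10)
})

test_that("a positive charge nearer C stabilizes the polarized probe", {
  probe <- co_probe(c(0, 0, 0), c(1.14, 0, 0))
  env <- charge_environment(c(-3, 0, 0), 1)
  fs <- field_along_bond(env, probe)
  expect_gt(fs$field, 0)
  m <- polarizable_charge_model(alpha = 1.5, q0 = 0)
  expect_lt(polarization_energy(fs$field, m, fs$bond_length), 0)
})
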