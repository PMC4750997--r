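test_that("constraint stacks have the documented shape", {
  arm <- default_arm()
  tc <- task_constraints(arm, posture_01(), desired_stiffness(2, 30, 0.2))
  expect_equal(dim(tc$A_eq), c(5, 6))
  expect_equal(tc$b_eq[1:2], c(0, 0))
  expect_equal(tc$A_eq[1:2, ], arm$moment_arms %*% diag(arm$f_max))

  sj <- three_muscle_limb()
  tc1 <- task_constraints(sj, desired = 1)
  expect_equal(dim(tc1$A_eq), c(2, 3))
  expect_equal(tc1$A_eq, rbind(c(1, 2, -1), c(1, 4, 1)),
               ignore_attr = TRUE)
})

test_that("three-muscle limb: exact feasible segment and energy extremes", {
  tc <- task_constraints(three_muscle_limb(), desired = 1)
  seg <- feasible_segment(tc)
  expect_false(seg$empty)
  expect_equal(seg$null_dim, 1L)
  # endpoints must be {(0.5, 0, 0.5), (0, 1/6, 1/3)} (hand elimination)
  ends <- lapply(seg$t_range, function(t) seg$a0 + t * seg$direction)
  expect_same_set(ends, list(c(0.5, 0, 0.5), c(0, 1 / 6, 1 / 3)))
  # the whole segment satisfies the equalities
  for (t in seq(seg$t_range[1], seg$t_range[2], length.out = 7))
    expect_lt(max(abs(tc$A_eq %*% (seg$a0 + t * seg$direction) - tc$b_eq)),
              1e-10)

  lo <- min_energy(tc)
  expect_equal(lo$energy, 5 / 36, tolerance = 1e-10)
  expect_equal(lo$activation, c(0, 1 / 6, 1 / 3), tolerance = 1e-8)
  hi <- max_energy(tc)
  expect_equal(hi$energy, 0.5, tolerance = 1e-10)
  expect_equal(hi$activation, c(0.5, 0, 0.5), tolerance = 1e-8)
  er <- energy_range(tc)
  expect_equal(er$reduction_pct, 100 * 13 / 18, tolerance = 1e-8)
})

test_that("zero desired stiffness is trivially feasible at zero cost", {
  arm <- default_arm()
  tc <- task_constraints(arm, posture_01(), c(0, 0, 0))
  seg <- feasible_segment(tc)
  expect_false(seg$empty)
  expect_equal(min_energy(tc, seg)$energy, 0, tolerance = 1e-12)
})

test_that("a desired stiffness far beyond muscle strength is infeasible", {
  arm <- default_arm()
  tc <- task_constraints(arm, posture_01(), desired_stiffness(2, 30, 1000))
  expect_true(feasible_segment(tc)$empty)
  expect_equal(min_energy(tc)$status, "unrealizable")
  expect_equal(energy_range(tc)$status, "unrealizable")
})

test_that("generic postures give rank 5 and a one-dimensional null space", {
  arm <- default_arm()
  for (seed in 1:100) {
    th <- random_posture(arm, seed = seed)
    tc <- task_constraints(arm, th, desired_stiffness(2, 30, 0.1))
    sol <- qr(tc$A_eq)
    expect_equal(sol$rank, 5)
  }
})

test_that("segment extremization agrees with an independent QP solver", {
  arm <- default_arm()
  th <- posture_01()
  n_checked <- 0
  for (seed in 1:20) {
    prm <- withr::with_seed(seed, c(1 + runif(1, 0, 3), runif(1, 0, 180)))
    s <- auto_scale(arm, th, prm[1], prm[2])
    if (is.na(s)) next
    tc <- task_constraints(arm, th, desired_stiffness(prm[1], prm[2], s))
    seg <- feasible_segment(tc)
    if (seg$empty) next
    n_checked <- n_checked + 1
    qp <- pracma::quadprog(2 * diag(tc$f_max^2), rep(0, 6),
                           Aeq = tc$A_eq, beq = tc$b_eq,
                           lb = tc$lower, ub = tc$upper)
    expect_equal(min_energy(tc, seg)$energy,
                 sum((tc$f_max * qp$xmin)^2), tolerance = 1e-6)
  }
  expect_gte(n_checked, 10)
})

test_that("minimum-energy activations satisfy all constraints to tolerance", {
  arm <- default_arm()
  for (seed in 1:20) {
    th <- random_posture(arm, seed = seed)
    s <- auto_scale(arm, th, 2, 37)
    if (is.na(s)) next
    tc <- task_constraints(arm, th, desired_stiffness(2, 37, s))
    lo <- min_energy(tc)
    if (lo$status != "ok") next
    expect_lt(max(abs(tc$A_eq %*% lo$activation - tc$b_eq)), 1e-8)
    expect_true(all(lo$activation >= -1e-9 & lo$activation <= 1 + 1e-9))
  }
})

test_that("energy extremes do not depend on the segment parametrization", {
  tc <- task_constraints(three_muscle_limb(), desired = 1)
  seg <- feasible_segment(tc)
  # re-anchor the particular solution elsewhere on the line and flip the
  # direction: energies must be unchanged
  shifted <- seg
  shift <- 0.37 * (seg$t_range[2] - seg$t_range[1])
  shifted$a0 <- seg$a0 + shift * seg$direction
  shifted$direction <- -seg$direction
  shifted$t_range <- sort(-(seg$t_range - shift))
  expect_equal(min_energy(tc, shifted)$energy, min_energy(tc, seg)$energy,
               tolerance = 1e-10)
  expect_equal(max_energy(tc, shifted)$energy, max_energy(tc, seg)$energy,
               tolerance = 1e-10)
})

test_that("sampled energies stay inside the computed extremes", {
  tc <- task_constraints(three_muscle_limb(), desired = 1)
  er <- energy_range(tc)
  for (seed in c(1, 2, 99)) {
    br <- oracle_energy_bracket(tc, n_samples = 2000, seed = seed)
    expect_gte(br$min, er$e_min - 1e-9)
    expect_lte(br$max, er$e_max + 1e-9)
  }
  # determinism under a fixed seed
  expect_identical(oracle_energy_bracket(tc, 500, seed = 7),
                   oracle_energy_bracket(tc, 500, seed = 7))
})

test_that("realizability and energy reduction are invariant to stiffness scale", {
  arm <- default_arm()
  for (seed in 1:8) {
    th <- random_posture(arm, seed = seed)
    phi <- withr::with_seed(seed, runif(1, 0, 180))
    base <- auto_scale(arm, th, 2, phi)
    auto <- is_realizable(arm, th, 2, phi, "auto")
    if (is.na(base)) {
      expect_false(auto)
      next
    }
    expect_true(auto)
    reds <- sapply(c(base, base / 2), function(s) {
      tc <- task_constraints(arm, th, desired_stiffness(2, phi, s))
      expect_true(is_realizable(arm, th, 2, phi, s))
      energy_range(tc)$reduction_pct
    })
    expect_equal(reds[1], reds[2], tolerance = 1e-8)
  }
})

test_that("degenerate null spaces fall back to vertex enumeration and QP", {
  # duplicating the bi-articular pair gives an 8-muscle arm whose equality
  # system has a 3-dimensional null space
  arm6 <- default_arm()
  arm8 <- arm_model(c(1, 1), cbind(arm6$moment_arms, c(1, 1), c(-1, -1)))
  th <- posture_01(arm8)
  tc <- task_constraints(arm8, th, desired_stiffness(1.5, 90, 0.05))
  seg <- feasible_segment(tc)
  expect_false(seg$empty)
  expect_true(seg$degenerate)
  expect_equal(seg$null_dim, 3L)
  lo <- min_energy(tc, seg)
  hi <- max_energy(tc, seg)
  expect_lte(lo$energy, hi$energy)
  expect_lt(max(abs(tc$A_eq %*% lo$activation - tc$b_eq)), 1e-6)
  expect_lt(max(abs(tc$A_eq %*% hi$activation - tc$b_eq)), 1e-6)
  # random feasible points must lie between the computed extremes
  sol <- withr::with_seed(11, {
    replicate(200, {
      z <- lo$activation + (hi$activation - lo$activation) * runif(1)
      sum((tc$f_max * z)^2)
    })
  })
  expect_true(all(sol >= lo$energy - 1e-8))
})

test_that("reduction percent formula matches its definition", {
  expect_equal(energy_reduction_pct(0.35, 0.5), 30)
  expect_equal(energy_reduction_pct(0.2, 0.2), 0)
  expect_true(is.na(energy_reduction_pct(0, 0)))
  expect_error(energy_reduction_pct(0.5, 0.2), "e_min <= e_max")
})
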