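test_that("muscle stiffness is linear in activation, force scale and alpha", {
  arm <- default_arm()
  expect_equal(muscle_stiffness(arm, rep(0, 6)), rep(0, 6))
  expect_equal(muscle_stiffness(arm, rep(1, 6)), rep(1, 6))
  arm2 <- arm_model(c(1, 1), arm$moment_arms, f_max = 2, alpha = 1)
  expect_equal(muscle_stiffness(arm2, rep(0.5, 6)), rep(1, 6))
  expect_error(muscle_stiffness(arm, c(rep(0.5, 5), 1.5)), "\\[0, 1\\]")
})

test_that("joint stiffness has the shoulder/elbow/bi-articular block form", {
  arm <- default_arm()
  for (seed in 1:5) {
    v <- withr::with_seed(seed, runif(3))
    s <- v[1]; e <- v[2]; b <- v[3]
    K <- joint_stiffness(arm, c(s, s, e, e, b, b))
    expect_equal(K, matrix(c(2 * s + 2 * b, 2 * b, 2 * b, 2 * e + 2 * b),
                           2, 2), tolerance = 1e-12)
  }
  # shoulder-only activation leaves the off-diagonals exactly zero
  K <- joint_stiffness(arm, c(0.3, 0.7, 0, 0, 0, 0))
  expect_equal(K[1, 2], 0)
  expect_equal(joint_stiffness(arm, rep(0, 6)), matrix(0, 2, 2))
  # sum-of-outer-products oracle
  a <- withr::with_seed(1, runif(6))
  K_oracle <- Reduce(`+`, lapply(1:6, function(i)
    a[i] * arm$moment_arms[, i] %*% t(arm$moment_arms[, i])))
  expect_equal(joint_stiffness(arm, a), K_oracle, tolerance = 1e-12)
})

test_that("endpoint stiffness is the inverse-Jacobian congruence of joint stiffness", {
  arm <- default_arm()
  # activation making K_joint the identity: s = e = 0.5, b = 0
  a_id <- c(0.5, 0.5, 0.5, 0.5, 0, 0)
  expect_equal(joint_stiffness(arm, a_id), diag(2))
  for (seed in 1:5) {
    th <- random_posture(arm, seed = seed)
    J <- arm_jacobian(arm, th)
    expect_equal(endpoint_stiffness(arm, th, a_id), solve(J %*% t(J)),
                 tolerance = 1e-10)
  }
  expect_equal(endpoint_stiffness(arm, deg(c(30, 120)), rep(0, 6)),
               matrix(0, 2, 2))
  expect_error(endpoint_stiffness(arm, c(0.3, 0), rep(0.5, 6)), "singular")
})

test_that("endpoint stiffness is symmetric PSD for activations in [0,1]^M", {
  arm <- default_arm()
  withr::with_seed(42, {
    for (i in 1:200) {
      th <- random_posture(arm, seed = i)
      a <- runif(6)
      K <- endpoint_stiffness(arm, th, a)
      expect_equal(K[1, 2], K[2, 1])
      expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-10)
    }
  })
})

test_that("linear stiffness map reproduces the matrix formulation", {
  # the 3 x M operator and the congruence-transform formula agree for
  # randomized arms with 3-10 muscles, random postures and activations
  withr::with_seed(7, {
    for (i in 1:100) {
      arm <- random_arm(n_muscles = sample(3:10, 1), seed = i)
      th <- random_posture(arm, seed = i + 1000)
      M <- stiffness_linear_map(arm, th)
      a <- runif(arm$n_muscles)
      K <- endpoint_stiffness(arm, th, a)
      expect_lt(max(abs(M %*% a - c(K[1, 1], K[1, 2], K[2, 2]))), 1e-10)
    }
  })
})

test_that("linear stiffness map columns are single-muscle stiffnesses and scale with alpha", {
  arm <- default_arm()
  th <- posture_01()
  M <- stiffness_linear_map(arm, th)
  for (i in 1:6) {
    a <- rep(0, 6); a[i] <- 1
    K <- endpoint_stiffness(arm, th, a)
    expect_equal(M[, i], c(K[1, 1], K[1, 2], K[2, 2]), tolerance = 1e-12)
  }
  arm2 <- arm_model(c(1, 1), arm$moment_arms, alpha = 2)
  expect_equal(stiffness_linear_map(arm2, th), 2 * M, tolerance = 1e-12)
})

test_that("ellipse summary extracts size, condition number and orientation", {
  iso <- stiffness_ellipse(diag(2))
  expect_equal(iso$shape, 1)
  expect_false(iso$orientation_defined)
  expect_true(is.na(iso$orientation))

  e1 <- stiffness_ellipse(diag(c(4, 1)))
  expect_equal(e1$shape, 4)
  expect_equal(e1$orientation, 0)
  expect_equal(e1$size, 5)

  e2 <- stiffness_ellipse(matrix(c(2.5, 1.5, 1.5, 2.5), 2, 2))
  expect_equal(e2$shape, 4)
  expect_equal(e2$orientation, 45)

  expect_error(stiffness_ellipse(matrix(0, 2, 2)), "zero")
  expect_error(stiffness_ellipse(diag(c(1, -1))), "positive definite")
})

test_that("desired stiffness round-trips through the ellipse summary", {
  expect_equal(desired_stiffness(2, 0, 1), c(2, 0, 1))
  expect_equal(desired_stiffness(4, 45, 1), c(2.5, 1.5, 2.5))
  expect_error(desired_stiffness(0.5, 0), "shape")
  expect_error(desired_stiffness(2, 0, scale = -1), "scale")
  withr::with_seed(3, {
    for (i in 1:300) {
      cn <- 1 + rexp(1, 1 / 3)
      phi <- runif(1, 0, 180)
      s <- rexp(1) + 0.01
      ell <- stiffness_ellipse(desired_stiffness(cn, phi, s))
      expect_equal(ell$shape, cn, tolerance = 1e-8)
      d <- abs(ell$orientation - phi) %% 180
      expect_lt(min(d, 180 - d), 1e-6)
      expect_equal(min(ell$eigenvalues), s, tolerance = 1e-8)
    }
  })
})

test_that("scaling the activation scales the stiffness but not shape or orientation", {
  arm <- default_arm()
  th <- posture_01()
  a <- withr::with_seed(5, runif(6, 0.1, 0.9))
  K1 <- endpoint_stiffness(arm, th, a)
  K2 <- endpoint_stiffness(arm, th, 0.5 * a)
  expect_equal(K2, 0.5 * K1, tolerance = 1e-12)
  e1 <- stiffness_ellipse(K1); e2 <- stiffness_ellipse(K2)
  expect_equal(e1$shape, e2$shape)
  expect_equal(e1$orientation, e2$orientation)
  expect_equal(e2$size, 0.5 * e1$size)
})
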