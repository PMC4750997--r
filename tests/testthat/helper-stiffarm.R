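deg <- function(x) x * pi / 180

# the posture with the endpoint at (0, 1) for the unit-link arm
posture_01 <- function(arm = default_arm()) inverse_kinematics(arm, c(0, 1))

# minimal single-joint 3-muscle system with moment arms (1, 2, -1):
# equality system  a1 + 2 a2 -  a3 = 0   (torque)
#                  a1 + 4 a2 +  a3 = k   (joint stiffness)
# at k = 1 the feasible set is a(t) = (0.5 - 3t, t, 0.5 - t), t in [0, 1/6]
three_muscle_limb <- function() single_joint_arm(c(1, 2, -1))

expect_same_set <- function(got, want, tol = 1e-8) {
  got <- got[order(sapply(got, function(v) paste(round(v, 6),
                                                 collapse = ",")))]
  want <- want[order(sapply(want, function(v) paste(round(v, 6),
                                                    collapse = ",")))]
  for (i in seq_along(want))
    expect_equal(got[[i]], want[[i]], tolerance = tol)
}
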