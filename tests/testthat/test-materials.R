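test_that("stiffness map follows the linear LGE rule", {
  sc <- score_map17(lge = c(4, 0, 2, rep(0, 14)), sp = rep(0, 17))
  Cn <- passive_stiffness_map(0.192, sc)
  expect_equal(Cn[1] / 0.192, 10)          # transmural infarct: 10x
  expect_equal(Cn[2], 0.192)               # healthy sector unchanged
  expect_equal(Cn[3], 0.192 * (1 + 4.5))   # LGE = 2: C_H * 5.5 = 1.056
  expect_equal(Cn[3], 1.056)
  expect_error(passive_stiffness_map(-1, sc), "positive")
  expect_error(score_map17(lge = c(5, rep(0, 16)), sp = rep(0, 17)), "0..4")
})

test_that("contractility map is the product rule and alpha = 0 removes SP", {
  for (lge in 0:4) for (sp in 0:3) {
    sc <- score_map17(lge = c(lge, rep(0, 16)), sp = c(sp, rep(0, 16)))
    for (al in c(0, 0.44, 1)) {
      Tn <- contractility_map(336.8, al, sc)
      expect_equal(Tn[1], 336.8 * (1 - lge / 4) * (1 - al * sp / 3))
    }
    # alpha = 0: SP must not matter (the virtual-revascularization identity)
    expect_equal(contractility_map(336.8, 0, sc)[1], 336.8 * (1 - lge / 4))
  }
  sc <- score_map17(lge = c(4, rep(0, 16)), sp = c(3, rep(0, 16)))
  expect_equal(contractility_map(500, 0.7, sc)[1], 0)
  # hand-evaluated: Tmax_H = 336.8, LGE = 0, SP = 3, alpha = 0.44
  sc2 <- score_map17(lge = rep(0, 17), sp = rep(3, 17))
  expect_equal(contractility_map(336.8, 0.44, sc2)[1], 336.8 * 0.56,
               tolerance = 1e-12)
  expect_error(contractility_map(300, 1.2, sc), "alpha")
})

test_that("map monotonicities hold over the full score grid", {
  grid <- expand.grid(lge = 0:4, sp = 0:3)
  Cn <- sapply(seq_len(nrow(grid)), function(i)
    passive_stiffness_map(0.2, score_map17(rep(grid$lge[i], 17),
                                           rep(grid$sp[i], 17)))[1])
  # C nondecreasing in LGE at fixed SP
  for (sp in 0:3) {
    v <- Cn[grid$sp == sp][order(grid$lge[grid$sp == sp])]
    expect_true(all(diff(v) >= 0))
  }
  for (al in c(0.3, 1)) {
    Tn <- sapply(seq_len(nrow(grid)), function(i)
      contractility_map(350, al, score_map17(rep(grid$lge[i], 17),
                                             rep(grid$sp[i], 17)))[1])
    expect_true(all(Tn >= 0))
    for (sp in 0:3) {
      v <- Tn[grid$sp == sp][order(grid$lge[grid$sp == sp])]
      expect_true(all(diff(v) <= 0))
    }
    for (lge in 0:4) {
      v <- Tn[grid$lge == lge][order(grid$sp[grid$lge == lge])]
      expect_true(all(diff(v) <= 0))
    }
  }
  # nonincreasing in alpha
  sc <- score_map17(rep(1, 17), rep(2, 17))
  als <- seq(0, 1, by = 0.1)
  v <- sapply(als, function(a) contractility_map(350, a, sc)[1])
  expect_true(all(diff(v) <= 0))
})

test_that("passive stress matches a central finite difference of the energy", {
  set.seed(42)
  law <- passive_law(C = 0.2)
  h <- 1e-6
  worst <- 0
  for (r in 1:120) {
    E <- random_strain(0.05)
    S <- passive_stress(E, law)
    for (k in list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))) {
      i <- k[1]; j <- k[2]
      Ep <- E; Em <- E
      Ep[i, j] <- Ep[i, j] + h; Ep[j, i] <- Ep[i, j]
      Em[i, j] <- Em[i, j] - h; Em[j, i] <- Em[i, j]
      fd <- (passive_energy(Ep, law) - passive_energy(Em, law)) / (2 * h)
      # off-diagonal: symmetric perturbation hits two energy slots
      Sij <- if (i == j) S[i, j] else 2 * S[i, j]
      worst <- max(worst, abs(fd - Sij) / max(abs(fd), 1e-10))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("stress-free reference, zero stress and pure-fiber-strain closed form", {
  law <- passive_law(C = 0.15)
  expect_equal(passive_stress(matrix(0, 3, 3), law), matrix(0, 3, 3))
  # pure fiber strain: S11 = C bf eps exp(bf eps^2) plus volumetric part
  eps <- 0.04
  E <- diag(c(eps, 0, 0))
  S <- passive_stress(E, law, include_volumetric = FALSE)
  expect_equal(S[1, 1], law$C * law$b_f * eps * exp(law$b_f * eps^2),
               tolerance = 1e-12)
  expect_equal(S[2, 3], 0)
  expect_error(passive_stress(diag(c(-0.6, 0, 0)), law), "invertible")
})

test_that("R and C++ material-point implementations agree", {
  set.seed(7)
  law <- passive_law(C = 0.31, kappa = 800)
  for (r in 1:25) {
    E <- random_strain(0.06)
    S_r <- passive_stress(E, law)
    S_cpp <- cardiofem:::.pk2_point_cpp(E, law$C, law$b_f, law$b_t,
                                        law$b_fs, law$kappa, TRUE)
    expect_equal(S_r, (S_cpp + t(S_cpp)) / 2, tolerance = 1e-10)
  }
})

test_that("active tension: clamps, limits and basic shape", {
  law <- active_law(Tmax = 300)
  expect_equal(active_stress(0.1, 0, law), 0)       # no contractility
  expect_equal(active_stress(0.1, 300, law, ct = 0), 0) # pre-activation
  # sarcomere at/below the zero-tension length
  E_at_l0 <- ((law$l0 / law$lR)^2 - 1) / 2
  expect_equal(active_stress(E_at_l0, 300, law), 0)
  expect_equal(active_stress(E_at_l0 - 0.05, 300, law), 0)
  # tension vanishes continuously as l -> l0+ and increases with stretch
  eps_seq <- E_at_l0 + c(1e-6, 0.01, 0.05, 0.1, 0.2)
  T0 <- active_stress(eps_seq, 300, law)
  expect_lt(T0[1], 1e-2)
  expect_true(all(diff(T0) > 0))
  expect_true(all(T0 <= 300))
})

test_that("frame objectivity: rotated strain gives rotated stress", {
  set.seed(11)
  law <- passive_law(C = 0.2)
  th <- 0.7
  # rotation within the isotropic transverse (2-3) plane is a material
  # symmetry: S(Q E Q^T) = Q S(E) Q^T for rotations about the fiber axis
  Q <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  for (r in 1:20) {
    E <- random_strain(0.05)
    S1 <- passive_stress(Q %*% E %*% t(Q), law)
    S2 <- Q %*% passive_stress(E, law) %*% t(Q)
    expect_equal(S1, S2, tolerance = 1e-9)
  }
})

test_that("law constructors validate their invariants", {
  expect_error(passive_law(C = 0.5, kappa = 10), "kappa")
  expect_error(active_law(lR = 1.5, l0 = 1.58), "slack")
  expect_error(active_law(Ct_ES = 1.5), "Ct_ES")
  expect_error(global_parameters(0.2, 300, alpha = 1.2), "alpha")
  expect_error(pressure_set(20, 10, 3, 23), "exceed")
})
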