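test_that("objective is the documented MSE + weighted volume form", {
  st <- strain_table(E_cc = rep(-0.1, 17), E_ll = rep(-0.05, 17),
                     E_rr = rep(0.2, 17), edv = 150, esv = 100)
  expect_equal(strain_objective(st, st), 0)
  # only a 10% ESV mismatch with W = 10: 10 * 0.1^2 = 0.1
  st2 <- st; attr(st2, "esv") <- 110
  expect_equal(strain_objective(st2, st), 0.1)
  # one sector off by 0.2 in E_cc: (1/32) * 0.04
  st3 <- st; st3$E_cc[4] <- st3$E_cc[4] + 0.2
  expect_equal(strain_objective(st3, st), 0.04 / 32)
  # apex (sector 17) is excluded: changing it does not move the objective
  st4 <- st; st4$E_cc[17] <- 5
  expect_equal(strain_objective(st4, st), 0)
  # weight switch
  expect_equal(strain_objective(st2, st, W_vol = 0), 0)
  bad <- st; bad$sector[1] <- 3L
  expect_error(strain_objective(bad, st), "sector")
})

test_that("stage-1 calibration recovers a known stiffness from its own EDV", {
  m <- tiny_mesh()
  fx <- load_fixture("patient2")
  truth <- 0.3
  mod <- lv_model(m, fx$scores, global_parameters(truth, 300, 0.5),
                  fx$pressures)
  edv_star <- solve_passive_inflation(mod)$volume
  cal <- calibrate_CH(lv_model(m, fx$scores, global_parameters(1, 300, 0.5),
                               fx$pressures), edv_star)
  expect_lt(abs(cal$C_H - truth) / truth, 0.01)
  expect_lt(abs(cal$edv - edv_star) / edv_star, 1e-3)
  # monotonicity: a larger target EDV calibrates to a softer wall
  cal2 <- calibrate_CH(mod, edv_star * 1.1)
  expect_lt(cal2$C_H, cal$C_H)
  # infeasible target: below the reference cavity volume
  expect_error(calibrate_CH(mod, cavity_volume(m) * 0.9), "infeasible")
})

test_that("stage-2 recovers contractility and ischemia effect (tiny mesh)", {
  m <- tiny_mesh()
  fx <- load_fixture("patient2")
  case <- synthetic_case(density = mesh_density(1, 8, 4),
                         pressures = fx$pressures, scores = fx$scores,
                         truth = global_parameters(0.25, 336.8, 1))
  syn <- make_synthetic_case(case, mesh = m)
  mod <- lv_model(m, fx$scores, global_parameters(0.25, 350, 0.5),
                  fx$pressures)
  res <- optimize_contractility(mod, syn$targets, init = c(350, 0.5))
  expect_lt(abs(res$Tmax_H - 336.8) / 336.8, 0.014)
  expect_lt(abs(res$alpha - 1), 0.014)
  expect_false(res$alpha_frozen)
  # best-so-far objective history is monotone nonincreasing
  expect_true(all(diff(res$history$best) <= 1e-15))
  # every trial respected the alpha box
  expect_true(all(res$history$alpha >= 0 & res$history$alpha <= 1))
})

test_that("alpha is frozen when the score map has no perfusion defect", {
  m <- tiny_mesh()
  sc <- score_map17()  # all zero
  pr <- pressure_set(20, 140, 8, 28)
  truth <- global_parameters(0.25, 300, 0)
  syn <- make_synthetic_case(synthetic_case(density = mesh_density(1, 8, 4),
                                            pressures = pr, scores = sc,
                                            truth = truth), mesh = m)
  mod <- lv_model(m, sc, global_parameters(0.25, 350, 0), pr)
  res <- optimize_contractility(mod, syn$targets, init = c(350, 0))
  expect_true(res$alpha_frozen)
  expect_equal(res$alpha, 0)
  expect_lt(abs(res$Tmax_H - 300) / 300, 0.014)
})

test_that("identical densities give identical convergence-study rows", {
  m <- tiny_mesh()
  fx <- load_fixture("patient5")
  truth <- global_parameters(0.25, 401.4, 0)
  syn <- make_synthetic_case(synthetic_case(density = mesh_density(1, 8, 4),
                                            pressures = fx$pressures,
                                            scores = fx$scores,
                                            truth = truth), mesh = m)
  tab <- mesh_convergence_study(tiny_geom(),
                                list(mesh_density(1, 8, 4),
                                     mesh_density(1, 8, 4)),
                                fx$scores, fx$pressures, syn$targets,
                                init = c(350, 0.5))
  expect_equal(nrow(tab), 2)
  expect_identical(tab$Tmax_H[1], tab$Tmax_H[2])
  expect_identical(tab$C_H[1], tab$C_H[2])
  expect_equal(tab$dTmax_pct[2], 0)
  expect_true(all(c("n_elements", "evaluations") %in% names(tab)))
  expect_equal(tab$n_elements[1], 36)
})
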