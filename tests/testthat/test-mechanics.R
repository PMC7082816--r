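test_that("element assembly is consistent: residual = dEnergy/du, K = dR/du", {
  set.seed(3)
  m <- tiny_mesh()
  mod <- tiny_model(mesh = m)
  n <- 3 * nrow(m$nodes)
  u <- rnorm(n, sd = 0.04)
  asm <- function(uu, K = FALSE) cardiofem:::.assemble(mod, uu, 1.2, 0.6,
                                                       0.25, want_K = K)
  h <- 1e-6
  a0 <- asm(u, K = TRUE)
  K <- Matrix::sparseMatrix(i = a0$Ki, j = a0$Kj, x = a0$Kv, dims = c(n, n))
  dofs <- sample(n, 15)
  for (k in dofs) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    fd_col <- (asm(up)$R - asm(um)$R) / (2 * h)
    expect_lt(max(abs(fd_col - as.numeric(K[, k]))) / max(abs(fd_col)), 1e-5)
  }
  # passive-only residual is the gradient of the assembled strain energy
  mod0 <- tiny_model(Tmax_H = 0, mesh = m)
  asm0 <- function(uu) cardiofem:::.assemble(mod0, uu, 0, 0, 0, want_K = FALSE)
  a <- asm0(u)
  for (k in dofs[1:8]) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    fd <- (asm0(up)$energy - asm0(um)$energy) / (2 * h)
    expect_lt(abs(fd - a$R[k]) / max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("zero pressure and zero activation give the undeformed state", {
  m <- tiny_mesh()
  mod <- lv_model(m, score_map17(), global_parameters(0.25, 300, 0),
                  structure(list(lv_edp = 0, lv_esp = 0, rv_edp = 0,
                                 rv_esp = 0), class = "pressure_set"))
  ed <- solve_passive_inflation(mod)
  expect_true(ed$converged)
  expect_equal(max(abs(ed$u)), 0)
  expect_equal(ed$volume, cavity_volume(m))
})

test_that("passive inflation: EDV grows with pressure, shrinks with stiffness", {
  m <- tiny_mesh()
  edv <- function(C_H, edp) {
    mod <- tiny_model(C_H = C_H, pressures = pressure_set(edp, 140, 4, 28),
                      mesh = m)
    solve_passive_inflation(mod)$volume
  }
  ref <- cavity_volume(m)
  v1 <- edv(0.25, 10)
  v2 <- edv(0.25, 20)    # doubled EDP
  v3 <- edv(2.5, 20)     # stiffness x10
  expect_gt(v1, ref)
  expect_gt(v2, v1)
  expect_lt(v3, v2)
})

test_that("end systole: more contractility ejects more; ED=ES degenerate case", {
  m <- tiny_mesh()
  pr <- pressure_set(20, 140, 8, 28)
  esv <- function(Tm) {
    mod <- tiny_model(C_H = 0.25, Tmax_H = Tm, pressures = pr, mesh = m)
    ed <- solve_passive_inflation(mod)
    solve_end_systole(mod, ed)$volume
  }
  v150 <- esv(150); v350 <- esv(350); v600 <- esv(600)
  expect_gt(v150, v350)
  expect_gt(v350, v600)
  # no active stress + ES load = ED load: the ES state equals the ED state
  mod0 <- lv_model(m, score_map17(), global_parameters(0.25, 0, 0),
                   structure(list(lv_edp = 20, lv_esp = 20, rv_edp = 8,
                                  rv_esp = 8), class = "pressure_set"))
  ed <- solve_passive_inflation(mod0)
  es <- solve_end_systole(mod0, ed)
  expect_lt(max(abs(es$u - ed$u)), 1e-6)
  expect_equal(es$volume, ed$volume, tolerance = 1e-8)
})

test_that("sector strains: zero deformation, objectivity, physiologic signs", {
  m <- tiny_mesh()
  mod <- tiny_model(mesh = m)
  n <- nrow(m$nodes)
  ed <- structure(list(u = rnorm(3 * n, sd = 0.02), volume = 100,
                       converged = TRUE, steps = 0, rnorm = 0, phase = "ED"),
                  class = "sim_state")
  st0 <- sector_strains(mod, ed, ed)
  expect_equal(nrow(st0), 17)
  expect_true(all(abs(st0$E_cc) < 1e-12 & abs(st0$E_ll) < 1e-12 &
                    abs(st0$E_rr) < 1e-12))
  expect_equal(st0$excluded, c(rep(FALSE, 16), TRUE))
  # rigid rotation of the ES state leaves Green-Lagrange strain unchanged
  th <- 0.3
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  x_ed <- m$nodes + matrix(ed$u, ncol = 3, byrow = TRUE)
  u_rot <- as.vector(t(x_ed %*% t(Q) - m$nodes))
  es_rot <- ed; es_rot$u <- u_rot
  st_rot <- sector_strains(mod, ed, es_rot)
  expect_lt(max(abs(st_rot$E_cc)), 1e-9)
  expect_lt(max(abs(st_rot$E_ll)), 1e-9)
  expect_lt(max(abs(st_rot$E_rr)), 1e-9)
})

test_that("contracting healthy ventricle: shortening strains, wall thickening", {
  m <- tiny_mesh()
  mod <- tiny_model(C_H = 0.1, Tmax_H = 350,
                    pressures = pressure_set(20, 140, 8, 28), mesh = m)
  ed <- solve_passive_inflation(mod)
  es <- solve_end_systole(mod, ed)
  st <- sector_strains(mod, ed, es)
  ef <- (ed$volume - es$volume) / ed$volume
  expect_gt(ef, 0)
  expect_lt(ef, 1)
  expect_true(all(st$E_cc[1:16] < 0))        # circumferential shortening
  expect_true(all(st$E_rr[1:16] > 0))        # radial wall thickening
  # longitudinal shortening needs resolved transmural bending; the
  # single-layer mesh only shows it at the apex (full check runs on the
  # reference density in the acceptance suite)
  expect_lt(st$E_ll[17], 0)
  # near-incompressibility at the element level
  J <- element_jacobians(m, es$u)
  expect_true(all(J > 0.95 & J < 1.05))
})

test_that("solver is deterministic: identical inputs, bit-identical states", {
  m <- tiny_mesh()
  mod <- tiny_model(mesh = m)
  ed1 <- solve_passive_inflation(mod)
  ed2 <- solve_passive_inflation(mod)
  expect_identical(ed1$u, ed2$u)
  es1 <- solve_end_systole(mod, ed1)
  es2 <- solve_end_systole(mod, ed2)
  expect_identical(es1$u, es2$u)
})

test_that("basal boundary conditions hold: z fixed on the valve plane", {
  m <- tiny_mesh()
  mod <- tiny_model(mesh = m)
  ed <- solve_passive_inflation(mod)
  basal <- which(abs(m$nodes[, 3]) < 1e-9)
  uz <- ed$u[3 * (basal - 1) + 3]
  expect_equal(max(abs(uz)), 0)
  # basal nodes do slide in-plane
  uxy <- ed$u[c(3 * (basal - 1) + 1, 3 * (basal - 1) + 2)]
  expect_gt(max(abs(uxy)), 1e-3)
})
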