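#' Assemble an LV mechanics model
#'
#' Bundles a labeled, fibered mesh with the sector score map, global
#' parameters, material laws and loading, and precomputes the per-element
#' sector stiffness and contractility via [passive_stiffness_map()] and
#' [contractility_map()].
#'
#' @param mesh An `lv_mesh` with sectors and fibers assigned.
#' @param scores A [score_map17()].
#' @param params A [global_parameters()].
#' @param pressures A [pressure_set()].
#' @param passive A [passive_law()] (its `C` field is superseded by the
#'   sector map built from `params$C_H`).
#' @param active An [active_law()] (its `Tmax` is superseded by the sector
#'   map built from `params$Tmax_H` and `params$alpha`).
#' @return An object of class `lv_model`.
#' @export
lv_model <- function(mesh, scores, params, pressures,
                     passive = passive_law(C = params$C_H),
                     active = active_law(Tmax = params$Tmax_H),
                     kappa_stab_frac = 0.05) {
  stopifnot(inherits(mesh, "lv_mesh"), inherits(scores, "score_map17"),
            inherits(params, "global_parameters"),
            inherits(pressures, "pressure_set"))
  if (any(is.na(mesh$sector))) stop("mesh sectors unassigned: run partition_aha17()")
  if (is.null(mesh$fiber)) stop("mesh fibers unassigned: run assign_fibers()")
  if (is.null(mesh$facets$septal_epi))
    stop("septal facet set missing: run detect_septum() or septal_wedge_fallback()")
  m <- structure(list(mesh = mesh, scores = scores, params = params,
                      pressures = pressures, passive = passive,
                      active = active, kappa_stab_frac = kappa_stab_frac),
                 class = "lv_model")
  .model_refresh_maps(m)
}

.model_refresh_maps <- function(model) {
  p <- model$params
  Cn <- passive_stiffness_map(p$C_H, model$scores)
  Tn <- contractility_map(p$Tmax_H, p$alpha, model$scores)
  model$Cn_sector <- Cn
  model$Tmax_sector <- Tn
  model$Cn_elem <- Cn[model$mesh$sector]
  model$Tmax_elem <- Tn[model$mesh$sector]
  model
}

#' Update global parameters on a model
#'
#' @param model An `lv_model`.
#' @param C_H,Tmax_H,alpha Values to replace (others kept).
#' @return The updated model with refreshed sector maps.
#' @export
set_parameters <- function(model, C_H = NULL, Tmax_H = NULL, alpha = NULL) {
  stopifnot(inherits(model, "lv_model"))
  p <- model$params
  model$params <- global_parameters(
    C_H = if (is.null(C_H)) p$C_H else C_H,
    Tmax_H = if (is.null(Tmax_H)) p$Tmax_H else Tmax_H,
    alpha = if (is.null(alpha)) p$alpha else alpha,
    W_vol = p$W_vol)
  .model_refresh_maps(model)
}

#' @export
print.lv_model <- function(x, ...) {
  p <- x$params
  cat(sprintf("LV model: C_H = %.4g kPa, Tmax_H = %.4g kPa, alpha = %.3g\n",
              p$C_H, p$Tmax_H, p$alpha))
  print(x$mesh)
  print(x$pressures)
  invisible(x)
}

#' Solver control settings
#'
#' @param n_steps Initial number of equal load increments.
#' @param newton_tol Relative residual tolerance (scaled by the applied
#'   pressure load magnitude).
#' @param max_newton Maximum Newton iterations per increment.
#' @param min_dl Smallest allowed fractional load increment before the
#'   continuation gives up.
#' @param verbose Print per-increment convergence info.
#' @export
solver_control <- function(n_steps = 10, newton_tol = 1e-9, max_newton = 12,
                           min_dl = 1 / 320, verbose = FALSE) {
  list(n_steps = n_steps, newton_tol = newton_tol, max_newton = max_newton,
       min_dl = min_dl, verbose = verbose)
}

# fixed scalar DOFs: base plane z = 0 for every basal node, plus a minimal
# deterministic set of in-plane pins removing the three rigid modes the
# sliding base leaves (x/y translation and rotation about z)
.fixed_dofs <- function(mesh) {
  basal <- which(abs(mesh$nodes[, 3]) < 1e-9)
  if (!length(basal)) stop("no basal nodes found on z = 0")
  zdofs <- 3 * (basal - 1) + 3
  xpin <- basal[which.max(mesh$nodes[basal, 1])]
  xneg <- basal[which.min(mesh$nodes[basal, 1])]
  sort(unique(c(zdofs, 3 * (xpin - 1) + 1, 3 * (xpin - 1) + 2,
                3 * (xneg - 1) + 2)))
}

.model_faces <- function(model) {
  rbind(model$mesh$facets$endo, model$mesh$facets$septal_epi)
}

.assemble <- function(model, u, p_lv, p_rv, act, want_K = TRUE) {
  mesh <- model$mesh
  pas <- model$passive
  acl <- model$active
  faces <- .model_faces(model)
  face_p <- c(rep(p_lv, nrow(mesh$facets$endo)),
              rep(p_rv, nrow(mesh$facets$septal_epi)))
  ang <- mesh$fiber_angles
  if (is.null(ang)) stop("fiber angles missing: run assign_fibers()")
  .fem_assemble_cpp(mesh$nodes, u, mesh$elems, mesh$frames$e_c,
                    mesh$frames$e_l, mesh$frames$e_r, mesh$t_range[, 1],
                    mesh$t_range[, 2], ang[["endo"]] * pi / 180,
                    ang[["epi"]] * pi / 180, model$Cn_elem, pas$kappa,
                    pas$b_f, pas$b_t, pas$b_fs, model$Tmax_elem, act,
                    acl$lR, acl$l0, acl$B, acl$Ca0, acl$Ca0max,
                    acl$crossfiber_fraction, model$kappa_stab_frac, faces,
                    face_p, want_K)
}

# Newton solve at fixed load; returns list(u, converged, iterations, rnorm)
.newton <- function(model, u, p_lv, p_rv, act, free, scale, control) {
  n <- length(u)
  floor_rn <- 0
  rnorm_at <- function(uu) tryCatch({
    a <- .assemble(model, uu, p_lv, p_rv, act, want_K = FALSE)
    # roundoff floor: cancellations in the assembled residual cannot be
    # resolved below machine precision times the summed |contributions|
    floor_rn <<- 1e-13 * sqrt(sum(a$Rabs[free]^2))
    sqrt(sum(a$R[free]^2))
  }, error = function(e) Inf)
  rn <- rnorm_at(u)
  eps <- 0 # Levenberg-style diagonal shift, annealed away as steps succeed
  dscale <- NULL
  nf <- length(free)
  for (it in seq_len(control$max_newton)) {
    if (control$verbose)
      message(sprintf("    newton %2d  |R| = %.3e  eps = %.1e", it, rn, eps))
    if (!is.finite(rn))
      return(list(u = u, converged = FALSE, iterations = it, rnorm = rn))
    if (rn < max(control$newton_tol * scale, 30 * floor_rn))
      return(list(u = u, converged = TRUE, iterations = it - 1L, rnorm = rn))
    asm <- tryCatch(.assemble(model, u, p_lv, p_rv, act, want_K = TRUE),
                    error = function(e) NULL)
    if (is.null(asm))
      return(list(u = u, converged = FALSE, iterations = it, rnorm = rn))
    K <- Matrix::sparseMatrix(i = asm$Ki, j = asm$Kj, x = asm$Kv,
                              dims = c(n, n))[free, free, drop = FALSE]
    if (is.null(dscale)) dscale <- mean(abs(Matrix::diag(K)))
    accepted <- FALSE
    repeat {
      Keff <- if (eps > 0) K + Matrix::Diagonal(nf, eps * dscale) else K
      du <- tryCatch(as.numeric(Matrix::solve(Matrix::lu(Keff, order = 3L),
                                              -asm$R[free])),
                     error = function(e) NULL)
      if (!is.null(du) && all(is.finite(du))) {
        # backtracking line search on the residual norm
        step <- 1
        repeat {
          u_try <- u
          u_try[free] <- u[free] + step * du
          rn_try <- rnorm_at(u_try)
          if (rn_try < max(0.999 * rn,
                           max(control$newton_tol * scale, 30 * floor_rn))) {
            u <- u_try
            rn <- rn_try
            accepted <- TRUE
            break
          }
          step <- step / 2
          if (step < 1 / 16) break
        }
      }
      if (accepted) {
        eps <- if (eps > 1e-8) eps / 5 else 0
        break
      }
      eps <- if (eps == 0) 1e-4 else eps * 20
      if (eps > 1e4)
        return(list(u = u, converged = FALSE, iterations = it, rnorm = rn))
    }
  }
  list(u = u, converged = rn < max(control$newton_tol * scale, 30 * floor_rn),
       iterations = control$max_newton, rnorm = rn)
}

# Adaptive load continuation from lambda = 0 (equilibrium state u0) to 1.
# sched(lambda) must return list(p_lv, p_rv, act). If `direct`, a single
# Newton solve at lambda = 1 is attempted first (warm starts).
.continuation <- function(model, u0, sched, control, direct = FALSE,
                          direct_only = FALSE) {
  free <- setdiff(seq_along(u0), .fixed_dofs(model$mesh))
  s1 <- sched(1)
  area <- sum(abs(.facet_areas(model$mesh)))
  scale <- max(1e-6, (abs(s1$p_lv) + abs(s1$p_rv)) * area,
               max(model$Tmax_elem) * s1$act * 1e-3)
  steps <- 0L
  if (direct) {
    res <- tryCatch(.newton(model, u0, s1$p_lv, s1$p_rv, s1$act, free, scale,
                            control),
                    error = function(e) list(converged = FALSE))
    if (isTRUE(res$converged))
      return(list(u = res$u, converged = TRUE, steps = 1L,
                  rnorm = res$rnorm, direct = TRUE))
    if (direct_only)
      return(list(u = u0, converged = FALSE, steps = 1L, rnorm = NA_real_,
                  direct = FALSE))
  }
  u <- u0
  u_prev <- NULL
  dl_prev <- NA_real_
  lam <- 0
  dl <- 1 / control$n_steps
  dl0 <- dl
  while (lam < 1 - 1e-12) {
    dl_try <- min(dl, 1 - lam)
    s <- sched(lam + dl_try)
    # secant predictor from the previous two converged states
    u_start <- if (!is.null(u_prev) && is.finite(dl_prev) && dl_prev > 0)
      u + (u - u_prev) * (dl_try / dl_prev) else u
    res <- tryCatch(.newton(model, u_start, s$p_lv, s$p_rv, s$act, free,
                            scale, control),
                    error = function(e) list(converged = FALSE))
    if (!isTRUE(res$converged) && !identical(u_start, u))
      res <- tryCatch(.newton(model, u, s$p_lv, s$p_rv, s$act, free, scale,
                              control),
                      error = function(e) list(converged = FALSE))
    steps <- steps + 1L
    if (isTRUE(res$converged)) {
      u_prev <- u
      dl_prev <- dl_try
      u <- res$u
      lam <- lam + dl_try
      if (control$verbose)
        message(sprintf("  load step to lambda = %.4f (%d its)", lam,
                        res$iterations))
      dl <- min(dl * 1.5, dl0)
    } else {
      u_prev <- NULL
      dl <- dl_try / 2
      if (dl < control$min_dl)
        stop(sprintf(paste0("continuation failed to converge: lambda = %.4f,",
                            " residual = %.3e"), lam,
                     if (is.null(res$rnorm)) NA_real_ else res$rnorm))
    }
  }
  list(u = u, converged = TRUE, steps = steps, rnorm = res$rnorm,
       direct = FALSE)
}

.facet_areas <- function(mesh) {
  fa <- mesh$facets$endo
  vapply(seq_len(nrow(fa)), function(q) {
    p <- mesh$nodes[fa[q, ], ]
    sqrt(sum(.quad_normal(p)^2))
  }, numeric(1))
}

#' Passive inflation to end-diastole
#'
#' Quasi-static Newton solve with the end-diastolic LV pressure on the
#' endocardium and the end-diastolic RV pressure on the septal epicardium,
#' ramped with adaptive load stepping. Basal nodes are held on the valve
#' plane (z fixed, free to slide in x/y).
#'
#' @param model An [lv_model()].
#' @param control A [solver_control()].
#' @param u0 Optional displacement warm start.
#' @param direct Attempt a single full-load Newton solve from `u0` first.
#' @return A `sim_state` list: `u` (3N displacements, mm), `volume` (cavity
#'   volume, ml), `converged`, `steps`, `rnorm`.
#' @export
solve_passive_inflation <- function(model, control = solver_control(),
                                    u0 = NULL, direct = !is.null(u0)) {
  stopifnot(inherits(model, "lv_model"))
  pr <- model$pressures
  n <- 3 * nrow(model$mesh$nodes)
  if (is.null(u0)) u0 <- numeric(n)
  plv <- pr$lv_edp * .MMHG_KPA
  prv <- pr$rv_edp * .MMHG_KPA
  # LV pressure first (nearly axisymmetric, stiffens the wall), then the
  # one-sided septal RV pressure: the lateral RV load on a still-unstrained
  # exponential wall would otherwise drive a huge apex swing
  sched <- function(l) list(p_lv = min(2 * l, 1) * plv,
                            p_rv = max(2 * l - 1, 0) * prv, act = 0)
  if (direct) {
    res <- .continuation(model, u0, sched, control, direct = TRUE,
                         direct_only = TRUE)
    if (res$direct)
      return(structure(list(u = res$u,
                            volume = cavity_volume(model$mesh, res$u),
                            converged = TRUE, steps = res$steps,
                            rnorm = res$rnorm, phase = "ED"),
                       class = "sim_state"))
  }
  # very soft walls: inflate at a numerically comfortable stiffness first,
  # then anneal C_H down to the requested value at full load (the exponential
  # law has almost no small-strain stiffness when C_H is tiny, which makes a
  # cold Newton start from the stress-free state hopeless)
  C_safe <- 0.15
  if (model$params$C_H < C_safe) {
    m1 <- set_parameters(model, C_H = C_safe)
    res <- .continuation(m1, numeric(n), sched, control)
    res <- .anneal_stiffness(model, res$u, C_safe, sched, control)
  } else {
    res <- .continuation(model, u0, sched, control)
  }
  structure(list(u = res$u, volume = cavity_volume(model$mesh, res$u),
                 converged = res$converged, steps = res$steps,
                 rnorm = res$rnorm, phase = "ED"), class = "sim_state")
}

# geometric reduction of C_H at full load, Newton at each rung
.anneal_stiffness <- function(model, u, C_start, sched, control) {
  free <- setdiff(seq_along(u), .fixed_dofs(model$mesh))
  s1 <- sched(1)
  area <- sum(abs(.facet_areas(model$mesh)))
  scale <- max(1e-6, (abs(s1$p_lv) + abs(s1$p_rv)) * area)
  C_target <- model$params$C_H
  Cc <- C_start
  fac <- 0.35
  steps <- 0L
  while (Cc > C_target * (1 + 1e-12)) {
    C_next <- max(C_target, Cc * fac)
    m2 <- set_parameters(model, C_H = C_next)
    res <- tryCatch(.newton(m2, u, s1$p_lv, s1$p_rv, s1$act, free, scale,
                            control),
                    error = function(e) list(converged = FALSE))
    steps <- steps + 1L
    if (isTRUE(res$converged)) {
      u <- res$u
      Cc <- C_next
      fac <- max(fac * 0.7, 0.1)
    } else {
      fac <- sqrt(fac)
      if (fac > 0.97)
        stop(sprintf("stiffness annealing stalled at C_H = %.4g kPa", Cc))
    }
  }
  list(u = u, converged = TRUE, steps = steps, rnorm = res$rnorm,
       direct = FALSE)
}

#' Active contraction to end-systole
#'
#' Solves the end-systolic equilibrium with total stress = passive + active
#' at the end-systolic activation level, LV end-systolic pressure on the
#' endocardium and RV end-systolic pressure on the septal epicardium.
#' Pressure and activation are ramped jointly starting from the
#' end-diastolic state.
#'
#' @param model An [lv_model()].
#' @param ed_state The end-diastolic `sim_state` (continuation start and
#'   strain reference).
#' @param control A [solver_control()].
#' @param u0 Optional warm start (e.g. a previous end-systolic solution);
#'   when provided a direct full-load solve is attempted first.
#' @return A `sim_state` with the end-systolic displacement and volume.
#' @export
solve_end_systole <- function(model, ed_state, control = solver_control(),
                              u0 = NULL) {
  stopifnot(inherits(model, "lv_model"), inherits(ed_state, "sim_state"))
  pr <- model$pressures
  p0 <- c(pr$lv_edp, pr$rv_edp) * .MMHG_KPA
  p1 <- c(pr$lv_esp, pr$rv_esp) * .MMHG_KPA
  act1 <- model$active$Ct_ES
  # activation leads the pressure ramp (isovolumic-contraction-like path):
  # intermediate states are then stiffened by active tension instead of
  # ballooning under a rising pressure on a soft passive wall
  sched <- function(l) list(p_lv = p0[1] + l * (p1[1] - p0[1]),
                            p_rv = p0[2] + l * (p1[2] - p0[2]),
                            act = min(1, 3 * l) * act1)
  if (!is.null(u0)) {
    res <- .continuation(model, u0, sched, control, direct = TRUE,
                         direct_only = TRUE)
    if (res$direct)
      return(structure(list(u = res$u,
                            volume = cavity_volume(model$mesh, res$u),
                            converged = TRUE, steps = res$steps,
                            rnorm = res$rnorm, phase = "ES"),
                       class = "sim_state"))
  }
  C_safe <- 0.15
  if (model$params$C_H < C_safe) {
    # soft wall: traverse the contraction path at a comfortable stiffness,
    # then anneal C_H down at full end-systolic load + activation (the
    # activated wall is stiff, so the annealed solves are well conditioned)
    m1 <- set_parameters(model, C_H = C_safe)
    ed1 <- solve_passive_inflation(m1, control)
    res <- .continuation(m1, ed1$u, sched, control, direct = FALSE)
    res <- .anneal_stiffness(model, res$u, C_safe, sched, control)
  } else {
    res <- .continuation(model, ed_state$u, sched, control, direct = FALSE)
  }
  structure(list(u = res$u, volume = cavity_volume(model$mesh, res$u),
                 converged = res$converged, steps = res$steps,
                 rnorm = res$rnorm, phase = "ES"), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("%s state: cavity volume %.2f ml, %s after %d load steps\n",
              x$phase, x$volume,
              if (x$converged) "converged" else "NOT converged", x$steps))
  invisible(x)
}

#' Per-sector end-systolic strains
#'
#' Computes the element-centroid Green-Lagrange strain of the end-diastole
#' to end-systole deformation (`F_ES F_ED^-1` composition), rotates it into
#' the local circumferential/longitudinal/radial frame and volume-averages
#' it per AHA sector. The apex cap (sector 17) is flagged as excluded from
#' the optimization objective.
#'
#' @param model An [lv_model()].
#' @param ed_state,es_state Converged `sim_state`s.
#' @return A `strain_table`: data frame with columns `sector`, `E_cc`,
#'   `E_ll`, `E_rr`, `excluded`, with volumes attached as attributes `edv`
#'   and `esv` (ml).
#' @export
sector_strains <- function(model, ed_state, es_state) {
  stopifnot(inherits(model, "lv_model"))
  mesh <- model$mesh
  em <- .fem_rel_strains_cpp(mesh$nodes, mesh$elems, ed_state$u, es_state$u,
                             mesh$frames$e_c, mesh$frames$e_l,
                             mesh$frames$e_r)
  w <- mesh$elem_volume
  agg <- function(col) vapply(1:17, function(s) {
    i <- mesh$sector == s
    if (!any(i)) return(NA_real_)
    sum(col[i] * w[i]) / sum(w[i])
  }, numeric(1))
  st <- data.frame(sector = 1:17, E_cc = agg(em[, 1]), E_ll = agg(em[, 2]),
                   E_rr = agg(em[, 3]), excluded = c(rep(FALSE, 16), TRUE))
  attr(st, "edv") <- ed_state$volume
  attr(st, "esv") <- es_state$volume
  class(st) <- c("strain_table", "data.frame")
  st
}

#' Construct a strain table from raw values
#'
#' @param E_cc,E_ll,E_rr Length-17 numeric vectors.
#' @param edv,esv Volumes in ml.
#' @return A `strain_table`.
#' @export
strain_table <- function(E_cc, E_ll, E_rr = rep(NA_real_, 17), edv, esv) {
  stopifnot(length(E_cc) == 17, length(E_ll) == 17, length(E_rr) == 17)
  st <- data.frame(sector = 1:17, E_cc = E_cc, E_ll = E_ll, E_rr = E_rr,
                   excluded = c(rep(FALSE, 16), TRUE))
  attr(st, "edv") <- edv
  attr(st, "esv") <- esv
  class(st) <- c("strain_table", "data.frame")
  st
}

#' Forward simulation of one cardiac configuration pair
#'
#' Convenience wrapper: passive inflation, active contraction, sector
#' strain extraction.
#'
#' @param model An [lv_model()].
#' @param control A [solver_control()].
#' @param ed_state Optional precomputed end-diastolic state.
#' @param es_warm Optional displacement warm start for the end-systolic
#'   solve.
#' @return List with `ed`, `es` (`sim_state`s) and `strains`
#'   (`strain_table`).
#' @export
forward_simulate <- function(model, control = solver_control(),
                             ed_state = NULL, es_warm = NULL) {
  ed <- if (is.null(ed_state)) solve_passive_inflation(model, control)
        else ed_state
  es <- solve_end_systole(model, ed, control, u0 = es_warm)
  list(ed = ed, es = es, strains = sector_strains(model, ed, es))
}

#' Element-average volume ratio of a deformed state
#'
#' Mean determinant of the deformation gradient per element, for
#' incompressibility checks.
#'
#' @param mesh An `lv_mesh`.
#' @param u Displacement vector.
#' @return Numeric vector (one J per element).
#' @export
element_jacobians <- function(mesh, u) {
  q0 <- .fem_elem_quality_cpp(mesh$nodes, mesh$elems, numeric(length(u)))
  q1 <- .fem_elem_quality_cpp(mesh$nodes, mesh$elems, u)
  q1$volume / q0$volume
}
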