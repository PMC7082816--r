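#' Transversely isotropic exponential passive law
#'
#' Strain energy `W = C/2 (exp(Q) - 1)` with
#' `Q = b_f E11^2 + b_t (E22^2 + E33^2 + 2 E23^2) + b_fs (2 E12^2 + 2 E13^2)`
#' in the local fiber frame (1 = fiber, 2 = cross-fiber in-plane,
#' 3 = radial). Near-incompressibility is enforced by a volumetric penalty
#' `U(J) = kappa/2 (J - 1)^2`.
#'
#' @param C Stiffness scale, kPa.
#' @param b_f,b_t,b_fs Dimensionless exponents.
#' @param kappa Volumetric penalty modulus, kPa; must be at least `100 * C`.
#' @return An object of class `passive_law`.
#' @export
passive_law <- function(C = 0.2, b_f = 49.25, b_t = 19.25, b_fs = 17.44,
                        kappa = 1000) {
  if (C <= 0) stop("C must be positive")
  if (kappa < 100 * C) stop("kappa must be at least 100 * C")
  structure(list(C = C, b_f = b_f, b_t = b_t, b_fs = b_fs, kappa = kappa),
            class = "passive_law")
}

#' Time-varying-elastance active contraction law
#'
#' Peak fiber tension `T0 = Tmax Ca0^2 / (Ca0^2 + ECa50^2) Ct` with the
#' length-dependent calcium sensitivity
#' `ECa50 = Ca0max / sqrt(exp(B (l - l0)) - 1)` and sarcomere length
#' `l = lR sqrt(2 E11 + 1)`. The activation time course is collapsed to its
#' end-systolic value `Ct_ES` (peak activation by default), since only the
#' end-diastolic and end-systolic equilibria are solved.
#'
#' @param Tmax Maximum isometric tension, kPa.
#' @param Ca0,Ca0max Intracellular and maximum peak calcium, umol/L.
#' @param B Length-sensitivity constant, 1/um.
#' @param l0 Length below which no tension develops, um.
#' @param lR Slack (unloaded) sarcomere length, um; must exceed `l0`.
#' @param Ct_ES Activation level at end-systole, in `[0, 1]`.
#' @param crossfiber_fraction Fraction of `T0` also applied in the two
#'   transverse directions (0 = fiber-only active stress).
#' @return An object of class `active_law`.
#' @export
active_law <- function(Tmax = 350, Ca0 = 4.35, Ca0max = 4.35, B = 4.75,
                       l0 = 1.58, lR = 1.85, Ct_ES = 1,
                       crossfiber_fraction = 0) {
  if (Tmax < 0) stop("Tmax must be nonnegative")
  if (Ct_ES < 0 || Ct_ES > 1) stop("Ct_ES must lie in [0, 1]")
  if (lR <= l0) stop("slack length lR must exceed l0")
  if (crossfiber_fraction < 0 || crossfiber_fraction > 1)
    stop("crossfiber_fraction must lie in [0, 1]")
  structure(list(Tmax = Tmax, Ca0 = Ca0, Ca0max = Ca0max, B = B, l0 = l0,
                 lR = lR, Ct_ES = Ct_ES,
                 crossfiber_fraction = crossfiber_fraction),
            class = "active_law")
}

#' Per-sector LGE and stress-perfusion score map
#'
#' @param lge Integer vector of 17 late-gadolinium-enhancement scores
#'   (0-4; 4 = transmural infarct).
#' @param sp Integer vector of 17 stress-perfusion defect scores (0-3).
#' @return An object of class `score_map17`.
#' @export
score_map17 <- function(lge = rep(0L, 17), sp = rep(0L, 17)) {
  lge <- as.integer(lge); sp <- as.integer(sp)
  if (length(lge) != 17L || length(sp) != 17L)
    stop("score maps need exactly 17 sectors")
  if (any(is.na(lge)) || any(lge < 0L | lge > 4L))
    stop("LGE scores must be integers in 0..4")
  if (any(is.na(sp)) || any(sp < 0L | sp > 3L))
    stop("SP scores must be integers in 0..3")
  structure(list(lge = lge, sp = sp), class = "score_map17")
}

#' @export
print.score_map17 <- function(x, ...) {
  cat("17-sector score map (LGE 0-4, SP 0-3)\n")
  print(data.frame(sector = 1:17, LGE = x$lge, SP = x$sp), row.names = FALSE)
  invisible(x)
}

#' Global model parameters
#'
#' The three quantities the inverse problem estimates: healthy passive
#' stiffness `C_H`, healthy contractility `Tmax_H`, and the ischemia effect
#' `alpha` scaling how strongly perfusion defects depress contractility,
#' plus the volume weight of the strain/volume objective.
#'
#' @param C_H Healthy-sector passive stiffness, kPa.
#' @param Tmax_H Healthy-sector contractility, kPa.
#' @param alpha Ischemia effect, dimensionless in `[0, 1]`.
#' @param W_vol Objective weight on the end-systolic volume term.
#' @return An object of class `global_parameters`.
#' @export
global_parameters <- function(C_H, Tmax_H, alpha = 0, W_vol = 10) {
  if (C_H <= 0) stop("C_H must be positive")
  if (Tmax_H < 0) stop("Tmax_H must be nonnegative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (W_vol < 0) stop("W_vol must be nonnegative")
  structure(list(C_H = C_H, Tmax_H = Tmax_H, alpha = alpha, W_vol = W_vol),
            class = "global_parameters")
}

#' Sector passive-stiffness map
#'
#' Scales the healthy stiffness by the sector LGE score:
#' `C_n = C_H (1 + 9 LGE_n / 4)`, so a transmural infarct (LGE = 4) is ten
#' times stiffer than healthy myocardium.
#'
#' @param C_H Healthy stiffness, kPa.
#' @param scores A [score_map17()].
#' @return Numeric vector of 17 sector stiffnesses, kPa.
#' @export
passive_stiffness_map <- function(C_H, scores) {
  stopifnot(inherits(scores, "score_map17"))
  if (C_H <= 0) stop("C_H must be positive")
  C_H * (1 + 9 * scores$lge / 4)
}

#' Sector contractility map
#'
#' `Tmax_n = Tmax_H (1 - LGE_n / 4) (1 - alpha SP_n / 3)`: infarct scar
#' removes contractility in proportion to its transmural extent, and
#' perfusion defects depress it further by an amount controlled by the
#' ischemia effect `alpha`. With `alpha = 0` the map depends on LGE only
#' (the virtual-revascularization identity).
#'
#' @param Tmax_H Healthy contractility, kPa.
#' @param alpha Ischemia effect in `[0, 1]`.
#' @param scores A [score_map17()].
#' @return Numeric vector of 17 sector contractilities, kPa.
#' @export
contractility_map <- function(Tmax_H, alpha, scores) {
  stopifnot(inherits(scores, "score_map17"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (Tmax_H < 0) stop("Tmax_H must be nonnegative")
  Tmax_H * (1 - scores$lge / 4) * (1 - alpha * scores$sp / 3)
}

#' Passive second Piola-Kirchhoff stress at a material point
#'
#' Differentiates the exponential strain energy with respect to the
#' Green-Lagrange strain in the fiber frame, plus the volumetric penalty
#' contribution `kappa (J - 1) J C^-1` with `C = 2E + I`.
#'
#' @param E 3x3 symmetric Green-Lagrange strain, fiber frame.
#' @param law A [passive_law()].
#' @param include_volumetric Include the penalty term (default `TRUE`).
#' @return 3x3 symmetric stress, kPa, fiber frame.
#' @export
passive_stress <- function(E, law, include_volumetric = TRUE) {
  stopifnot(inherits(law, "passive_law"), is.matrix(E), all(dim(E) == 3))
  if (max(abs(E - t(E))) > 1e-10) stop("E must be symmetric")
  Cg <- 2 * E + diag(3)
  ev <- eigen(Cg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("non-invertible deformation: 2E + I not positive-definite")
  D <- matrix(c(law$b_f, law$b_fs, law$b_fs,
                law$b_fs, law$b_t, law$b_t,
                law$b_fs, law$b_t, law$b_t), 3, 3)
  Q <- sum(D * E * E)
  S <- law$C * exp(Q) * (D * E)
  if (include_volumetric) {
    J <- sqrt(det(Cg))
    S <- S + law$kappa * (J - 1) * J * solve(Cg)
  }
  (S + t(S)) / 2
}

#' Passive strain energy at a material point
#'
#' @inheritParams passive_stress
#' @return Energy density, kPa.
#' @export
passive_energy <- function(E, law, include_volumetric = TRUE) {
  stopifnot(inherits(law, "passive_law"))
  D <- matrix(c(law$b_f, law$b_fs, law$b_fs,
                law$b_fs, law$b_t, law$b_t,
                law$b_fs, law$b_t, law$b_t), 3, 3)
  Q <- sum(D * E * E)
  Wd <- 0.5 * law$C * (exp(Q) - 1)
  if (include_volumetric) {
    J <- sqrt(det(2 * E + diag(3)))
    Wd <- Wd + 0.5 * law$kappa * (J - 1)^2
  }
  Wd
}

#' Active fiber tension at a material point
#'
#' @param E11 Fiber Green-Lagrange strain.
#' @param Tmax_n Sector contractility, kPa.
#' @param law An [active_law()].
#' @param ct Activation level (defaults to the law's end-systolic value).
#' @return Tension `T0` in kPa (0 when the sarcomere is at or below the
#'   zero-tension length `l0`).
#' @export
active_stress <- function(E11, Tmax_n, law, ct = law$Ct_ES) {
  stopifnot(inherits(law, "active_law"))
  vapply(E11, function(e)
    .active_point_cpp(e, Tmax_n, ct, law$lR, law$l0, law$B,
                      law$Ca0, law$Ca0max), numeric(1))
}

#' End-diastolic / end-systolic pressure set
#'
#' @param lv_edp,lv_esp,rv_edp,rv_esp Pressures in mmHg.
#' @return An object of class `pressure_set`; pressures are converted to
#'   kPa internally at 0.133322 kPa/mmHg.
#' @export
pressure_set <- function(lv_edp, lv_esp, rv_edp, rv_esp) {
  p <- c(lv_edp = lv_edp, lv_esp = lv_esp, rv_edp = rv_edp, rv_esp = rv_esp)
  if (any(p < 0)) stop("pressures must be nonnegative")
  if (lv_esp <= lv_edp || rv_esp <= rv_edp)
    stop("end-systolic pressure must exceed end-diastolic pressure")
  structure(as.list(p), class = "pressure_set")
}

#' @export
print.pressure_set <- function(x, ...) {
  cat(sprintf("LV %g/%g mmHg, RV %g/%g mmHg (ES/ED)\n",
              x$lv_esp, x$lv_edp, x$rv_esp, x$rv_edp))
  invisible(x)
}

# mmHg -> kPa
.MMHG_KPA <- 0.133322
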