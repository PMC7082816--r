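#' Load a packaged study fixture
#'
#' Returns the printed per-subject inputs shipped with the package: the
#' end-diastolic/end-systolic LV and RV pressures, the 17-sector LGE and
#' stress-perfusion score map, and the baseline/follow-up wall-motion
#' scores. The healthy volunteer has all LGE and SP scores equal to zero.
#'
#' @param subject_id One of `"patient1"` ... `"patient5"`, `"volunteer"`.
#' @return List with `pressures` ([pressure_set()]), `scores`
#'   ([score_map17()]), `wm` ([wall_motion_scores()]) and `ef_pct` (measured
#'   ejection fraction, percent).
#' @export
load_fixture <- function(subject_id) {
  pr <- read.csv(system.file("extdata", "pressures.csv",
                             package = "cardiofem"))
  sc <- read.csv(system.file("extdata", "scores.csv", package = "cardiofem"))
  if (!subject_id %in% pr$subject)
    stop("unknown subject '", subject_id, "'; available: ",
         paste(pr$subject, collapse = ", "))
  p <- pr[pr$subject == subject_id, ]
  s <- sc[sc$subject == subject_id, ]
  s <- s[order(s$sector), ]
  list(pressures = pressure_set(p$lv_edp, p$lv_esp, p$rv_edp, p$rv_esp),
       scores = score_map17(s$lge, s$sp),
       wm = wall_motion_scores(s$wm_bl, s$wm_fu),
       ef_pct = p$ef_pct)
}

#' List available fixture subjects
#' @return Character vector of subject ids.
#' @export
list_fixtures <- function() {
  pr <- read.csv(system.file("extdata", "pressures.csv",
                             package = "cardiofem"))
  pr$subject
}

#' Specify a synthetic test case
#'
#' Bundles everything needed to forward-simulate "experimental" data with
#' known ground truth: geometry + density, pressures, score map, the
#' ground-truth global parameters, an optional strain noise level and a
#' seed.
#'
#' @param geom An [idealized_geometry()].
#' @param density A [mesh_density()].
#' @param pressures A [pressure_set()].
#' @param scores A [score_map17()].
#' @param truth A [global_parameters()] (the values to recover).
#' @param sigma_strain Standard deviation of i.i.d. Gaussian noise added to
#'   the target `E_cc`/`E_ll` (0 = noiseless, the study default).
#' @param seed Integer RNG seed for the noise.
#' @return An object of class `synthetic_case`.
#' @export
synthetic_case <- function(geom = idealized_geometry(),
                           density = mesh_density(2, 16, 8),
                           pressures, scores, truth,
                           sigma_strain = 0, seed = 1L) {
  stopifnot(inherits(truth, "global_parameters"), sigma_strain >= 0)
  structure(list(geom = geom, density = density, pressures = pressures,
                 scores = scores, truth = truth,
                 sigma_strain = sigma_strain, seed = as.integer(seed)),
            class = "synthetic_case")
}

#' Generate synthetic "experimental" targets
#'
#' Runs the forward pipeline (mesh, inflation, contraction, sector strains)
#' at the ground-truth parameters and returns the resulting strain table as
#' optimization targets, optionally with seeded Gaussian noise on the
#' per-sector strains. The ground truth is returned as a separate record so
#' estimation code never touches it.
#'
#' @param case A [synthetic_case()].
#' @param control A [solver_control()].
#' @param mesh Optional pre-built mesh (must match the case geometry).
#' @param ed_state Optional precomputed end-diastolic state at the
#'   ground-truth stiffness.
#' @param es_warm Optional end-systolic displacement warm start.
#' @return List with `targets` (`strain_table`), `truth`
#'   (ground-truth parameter record), `model`, `ed`, `es`.
#' @export
make_synthetic_case <- function(case, control = solver_control(),
                                mesh = NULL, ed_state = NULL,
                                es_warm = NULL) {
  stopifnot(inherits(case, "synthetic_case"))
  if (is.null(mesh)) mesh <- build_lv_mesh(case$geom, case$density)
  model <- lv_model(mesh, case$scores, case$truth, case$pressures)
  fw <- forward_simulate(model, control, ed_state = ed_state,
                         es_warm = es_warm)
  st <- fw$strains
  if (case$sigma_strain > 0) {
    set.seed(case$seed)
    st$E_cc <- st$E_cc + rnorm(17, sd = case$sigma_strain)
    st$E_ll <- st$E_ll + rnorm(17, sd = case$sigma_strain)
  }
  list(targets = st,
       truth = list(C_H = case$truth$C_H, Tmax_H = case$truth$Tmax_H,
                    alpha = case$truth$alpha, seed = case$seed,
                    sigma_strain = case$sigma_strain),
       model = model, ed = fw$ed, es = fw$es)
}

#' Wall-motion score pair (baseline / follow-up)
#'
#' Visual wall-thickening grades per sector: 0 = normal (at least 50%
#' thickening) through 4 = dyskinesis.
#'
#' @param bl,fu Integer vectors of 17 scores in 0..4.
#' @return An object of class `wall_motion_scores`.
#' @export
wall_motion_scores <- function(bl, fu) {
  bl <- as.integer(bl); fu <- as.integer(fu)
  if (length(bl) != 17L || length(fu) != 17L)
    stop("wall motion scores need exactly 17 sectors")
  if (any(c(bl, fu) < 0L) || any(c(bl, fu) > 4L))
    stop("wall motion scores must be integers in 0..4")
  structure(list(bl = bl, fu = fu), class = "wall_motion_scores")
}
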