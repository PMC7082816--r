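#' Write a mesh (optionally deformed) as a legacy-ASCII VTK unstructured grid
#'
#' Emits hex8 cells with cell-data arrays for the sector labels, fiber
#' vectors and local frame directions, and a point-data displacement array
#' when `u` is given. Readable by ParaView and meshio.
#'
#' @param mesh An `lv_mesh`.
#' @param path Output file path (`.vtk`).
#' @param u Optional displacement (length `3 * n_nodes` or `n x 3`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, u = NULL) {
  stopifnot(inherits(mesh, "lv_mesh"))
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("left-ventricle hex mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", n)
  writeLines(apply(format(mesh$nodes, digits = 10, scientific = FALSE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  w("CELLS %d %d", ne, 9 * ne)
  writeLines(apply(cbind(8L, mesh$elems - 1L), 1, paste, collapse = " "),
             con)
  w("CELL_TYPES %d", ne)
  writeLines(rep("12", ne), con)
  w("CELL_DATA %d", ne)
  w("SCALARS sector int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(ifelse(is.na(mesh$sector), -1L, mesh$sector)), con)
  vecfield <- function(name, v) {
    if (is.null(v)) return(invisible())
    w("VECTORS %s double", name)
    writeLines(apply(format(v, digits = 8, trim = TRUE), 1, paste,
                     collapse = " "), con)
  }
  vecfield("fiber", mesh$fiber)
  vecfield("frame_c", mesh$frames$e_c)
  vecfield("frame_l", mesh$frames$e_l)
  vecfield("frame_r", mesh$frames$e_r)
  if (!is.null(u)) {
    if (!is.matrix(u)) u <- matrix(u, ncol = 3, byrow = TRUE)
    w("POINT_DATA %d", n)
    w("VECTORS displacement double")
    writeLines(apply(format(u, digits = 10, trim = TRUE), 1, paste,
                     collapse = " "), con)
  }
  invisible(path)
}

#' Write / read a strain table as CSV
#'
#' The CSV mirrors the in-memory table (`sector`, `E_cc`, `E_ll`, `E_rr`,
#' `excluded`); the EDV/ESV attributes are stored as commented header
#' lines.
#'
#' @param st A `strain_table`.
#' @param path CSV path.
#' @return `path` / the `strain_table`, invisibly for the writer.
#' @export
write_strain_table <- function(st, path) {
  stopifnot(inherits(st, "strain_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# edv_ml=%.10g", attr(st, "edv")), con)
  writeLines(sprintf("# esv_ml=%.10g", attr(st, "esv")), con)
  write.csv(as.data.frame(st), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strain_table
#' @export
read_strain_table <- function(path) {
  hdr <- readLines(path, n = 2)
  edv <- as.numeric(sub("# edv_ml=", "", hdr[1]))
  esv <- as.numeric(sub("# esv_ml=", "", hdr[2]))
  df <- read.csv(path, comment.char = "#")
  strain_table(df$E_cc, df$E_ll, df$E_rr, edv = edv, esv = esv)
}

#' Read a 17-row score CSV
#'
#' Expects columns `sector`, `lge`, `sp` and optionally `wm_bl`, `wm_fu`.
#'
#' @param path CSV path.
#' @return List with `scores` ([score_map17()]) and, when present, `wm`
#'   ([wall_motion_scores()]).
#' @export
read_score_csv <- function(path) {
  df <- read.csv(path)
  df <- df[order(df$sector), ]
  out <- list(scores = score_map17(df$lge, df$sp))
  if (all(c("wm_bl", "wm_fu") %in% names(df)))
    out$wm <- wall_motion_scores(df$wm_bl, df$wm_fu)
  out
}

#' Load a case configuration from YAML
#'
#' Builds the geometry, mesh density, pressures, scores and (optionally)
#' ground-truth parameters from a YAML file with top-level sections
#' `geometry:` (`a_endo`, `c_endo`, `wall_thickness`, `apex_thickness`,
#' `truncation`, `density: [nt, nc, nl]`), `pressures:`, `scores:`
#' (either `subject: <fixture id>` or explicit `lge`/`sp` vectors),
#' `materials:` (overrides for the passive/active constants) and
#' `truth:`/`parameters:` (`C_H`, `Tmax_H`, `alpha`, `W_vol`).
#'
#' @param path YAML file path.
#' @return List with `geom`, `density`, `pressures`, `scores`, `wm`,
#'   `params`, `passive`, `active`.
#' @export
read_case_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$geometry
  geom <- idealized_geometry(
    a_endo = g$a_endo %||% 25, c_endo = g$c_endo %||% 60,
    wall_thickness = g$wall_thickness %||% 10,
    apex_thickness = g$apex_thickness %||% g$wall_thickness %||% 10,
    truncation = g$truncation %||% 0.5)
  density <- do.call(mesh_density, as.list(as.integer(
    g$density %||% c(2, 16, 8))))
  pr <- cfg$pressures
  wm <- NULL
  if (!is.null(cfg$scores$subject)) {
    fx <- load_fixture(cfg$scores$subject)
    scores <- fx$scores
    wm <- fx$wm
    if (is.null(pr)) pr <- list(lv_edp = fx$pressures$lv_edp,
                                lv_esp = fx$pressures$lv_esp,
                                rv_edp = fx$pressures$rv_edp,
                                rv_esp = fx$pressures$rv_esp)
  } else {
    scores <- score_map17(cfg$scores$lge %||% rep(0, 17),
                          cfg$scores$sp %||% rep(0, 17))
  }
  pressures <- pressure_set(pr$lv_edp, pr$lv_esp, pr$rv_edp, pr$rv_esp)
  pblock <- cfg$truth %||% cfg$parameters
  params <- if (!is.null(pblock))
    global_parameters(pblock$C_H %||% 0.2, pblock$Tmax_H %||% 350,
                      pblock$alpha %||% 0, pblock$W_vol %||% 10)
  mats <- cfg$materials %||% list()
  passive <- passive_law(
    C = if (!is.null(params)) params$C_H else 0.2,
    b_f = mats$b_f %||% 49.25, b_t = mats$b_t %||% 19.25,
    b_fs = mats$b_fs %||% 17.44, kappa = mats$kappa %||% 1000)
  active <- active_law(
    Tmax = if (!is.null(params)) params$Tmax_H else 350,
    Ca0 = mats$Ca0 %||% 4.35, Ca0max = mats$Ca0max %||% 4.35,
    B = mats$B %||% 4.75, l0 = mats$l0 %||% 1.58, lR = mats$lR %||% 1.85,
    Ct_ES = mats$Ct_ES %||% 1,
    crossfiber_fraction = mats$active_crossfiber_fraction %||% 0)
  list(geom = geom, density = density, pressures = pressures,
       scores = scores, wm = wm, params = params, passive = passive,
       active = active)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read back a legacy-ASCII VTK unstructured grid written by
#' [write_mesh_vtk()]
#'
#' Restores the node coordinates, hex connectivity and the `sector`,
#' `fiber` and frame cell arrays (not the facet sets, which are derived
#' structures of the generator).
#'
#' @param path `.vtk` file path.
#' @return List with `nodes`, `elems`, `sector`, `fiber`, `frames`,
#'   and `displacement` when present.
#' @export
read_mesh_vtk <- function(path) {
  txt <- readLines(path)
  grab <- function(pattern) which(grepl(pattern, txt))[1]
  np <- as.integer(strsplit(txt[grab("^POINTS ")], " ")[[1]][2])
  i0 <- grab("^POINTS ")
  nodes <- matrix(scan(text = txt[(i0 + 1):(i0 + np)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- grab("^CELLS ")
  ne <- as.integer(strsplit(txt[ic], " ")[[1]][2])
  cells <- matrix(scan(text = txt[(ic + 1):(ic + ne)], quiet = TRUE),
                  ncol = 9, byrow = TRUE)
  elems <- matrix(as.integer(cells[, -1] + 1L), ncol = 8)
  out <- list(nodes = nodes, elems = elems)
  is_ <- grab("^SCALARS sector ")
  if (!is.na(is_))
    out$sector <- as.integer(txt[(is_ + 2):(is_ + 1 + ne)])
  vec <- function(name) {
    iv <- grab(paste0("^VECTORS ", name, " "))
    if (is.na(iv)) return(NULL)
    matrix(scan(text = txt[(iv + 1):(iv + ne)], quiet = TRUE), ncol = 3,
           byrow = TRUE)
  }
  out$fiber <- vec("fiber")
  out$frames <- list(e_c = vec("frame_c"), e_l = vec("frame_l"),
                     e_r = vec("frame_r"))
  id <- grab("^VECTORS displacement ")
  if (!is.na(id))
    out$displacement <- matrix(scan(text = txt[(id + 1):(id + np)],
                                    quiet = TRUE), ncol = 3, byrow = TRUE)
  out
}
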