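#' Idealized left-ventricular geometry
#'
#' Describes a truncated prolate-spheroid LV: an endocardial ellipsoid of
#' revolution (short semi-axis `a_endo`, long semi-axis `c_endo`), a wall of
#' prescribed equatorial and apical thickness, truncated by the basal (valve)
#' plane. The long axis is aligned with +z, the base plane sits at z = 0 and
#' the apex points toward negative z; all lengths are in mm.
#'
#' @param a_endo Endocardial short (radial) semi-axis, mm.
#' @param c_endo Endocardial long semi-axis, mm.
#' @param wall_thickness Wall thickness at the equator, mm.
#' @param apex_thickness Wall thickness at the apex, mm.
#' @param truncation Height of the basal plane above the ellipsoid equator,
#'   as a fraction of `c_endo`. `0` truncates at the equator (a half
#'   ellipsoid), the default `0.5` keeps half of the upper portion.
#' @return An object of class `lv_geometry`.
#' @export
idealized_geometry <- function(a_endo = 25, c_endo = 60, wall_thickness = 10,
                               apex_thickness = wall_thickness,
                               truncation = 0.5) {
  if (a_endo <= 0 || c_endo <= 0 || wall_thickness <= 0 || apex_thickness <= 0)
    stop("all geometry dimensions must be positive")
  if (truncation < 0 || truncation >= 1)
    stop("truncation must lie in [0, 1)")
  structure(list(a_endo = a_endo, c_endo = c_endo,
                 a_epi = a_endo + wall_thickness,
                 c_epi = c_endo + apex_thickness,
                 wall_thickness = wall_thickness,
                 apex_thickness = apex_thickness,
                 truncation = truncation),
            class = "lv_geometry")
}

#' Structured mesh density
#'
#' @param n_transmural Number of element layers across the wall (>= 1).
#' @param n_circumferential Number of elements around the circumference;
#'   must be a multiple of 4 so the apex cap can be laid out as a mapped
#'   square block.
#' @param n_longitudinal Number of element rows from base to the cap rim.
#' @return An object of class `mesh_density`.
#' @export
mesh_density <- function(n_transmural, n_circumferential, n_longitudinal) {
  stopifnot(n_transmural >= 1, n_longitudinal >= 1, n_circumferential >= 4)
  if (n_circumferential %% 4 != 0)
    stop("n_circumferential must be a multiple of 4")
  structure(list(n_transmural = as.integer(n_transmural),
                 n_circumferential = as.integer(n_circumferential),
                 n_longitudinal = as.integer(n_longitudinal)),
            class = "mesh_density")
}

# point on one of the two wall surfaces; u is the polar-type parameter
# (u_base at the basal plane, pi at the pole), v the azimuth
.surf_point <- function(geom, surf, u, v) {
  a <- if (surf == "endo") geom$a_endo else geom$a_epi
  cc <- if (surf == "endo") geom$c_endo else geom$c_epi
  zc <- -geom$truncation * geom$c_endo
  cbind(a * sin(u) * cos(v), a * sin(u) * sin(v), zc + cc * cos(u))
}

.u_base <- function(geom, surf) {
  h <- geom$truncation * geom$c_endo
  cc <- if (surf == "endo") geom$c_endo else geom$c_epi
  acos(h / cc)
}

#' Generate an idealized LV hexahedral mesh
#'
#' Builds a structured hex8 mesh of the truncated prolate-spheroid wall: a
#' body block (transmural x circumferential x longitudinal) plus an apex cap
#' meshed as a mapped square block (no collapsed nodes at the pole). Facet
#' sets for the endocardium, epicardium and base are populated; local
#' cardiac frames (circumferential, longitudinal, radial) are attached per
#' element. Sector labels and fibers are assigned by [partition_aha17()] and
#' [assign_fibers()].
#'
#' @param geom An [idealized_geometry()].
#' @param density A [mesh_density()].
#' @param cap_angle Polar half-angle (radians) of the apex-cap region.
#' @return An object of class `lv_mesh`.
#' @export
generate_idealized_lv <- function(geom, density, cap_angle = 0.35) {
  stopifnot(inherits(geom, "lv_geometry"), inherits(density, "mesh_density"))
  nt <- density$n_transmural
  nc <- density$n_circumferential
  nl <- density$n_longitudinal
  m <- nc %/% 4L

  ub_en <- .u_base(geom, "endo"); ub_ep <- .u_base(geom, "epi")
  ucap <- pi - cap_angle
  if (ucap <= max(ub_en, ub_ep)) stop("cap_angle too large for this geometry")

  nbody <- (nt + 1L) * (nl + 1L) * nc
  body_id <- function(k, i, j) {
    # k transmural layer 0..nt, i longitudinal station 0..nl, j circ (mod nc)
    k * (nl + 1L) * nc + i * nc + (j %% nc) + 1L
  }

  v_j <- 2 * pi * (0:(nc - 1L)) / nc
  s_i <- (0:nl) / nl
  t_k <- (0:nt) / nt

  nodes <- matrix(0, nbody, 3L)
  for (k in 0:nt) {
    t <- t_k[k + 1L]
    for (i in 0:nl) {
      s <- s_i[i + 1L]
      pe <- .surf_point(geom, "endo", ub_en + s * (ucap - ub_en), v_j)
      pp <- .surf_point(geom, "epi", ub_ep + s * (ucap - ub_ep), v_j)
      nodes[body_id(k, i, 0:(nc - 1L)), ] <- (1 - t) * pe + t * pp
    }
  }

  # ---- apex cap: mapped square block ------------------------------------
  # boundary nodes of the (m+1)^2 grid are identified with the cap-rim ring
  # of the body mesh; interior nodes come from an elliptical square-to-disk
  # map so the pole is an ordinary grid vertex
  ring_id <- function(k, j) body_id(k, nl, j)
  cap_interior <- list()
  cap_ids <- array(NA_integer_, dim = c(nt + 1L, m + 1L, m + 1L))
  next_id <- nbody
  extra <- list()
  for (k in 0:nt) {
    t <- t_k[k + 1L]
    for (gi in 0:m) for (gj in 0:m) {
      if (gi == m) {
        cap_ids[k + 1L, gi + 1L, gj + 1L] <- ring_id(k, gj)
      } else if (gj == m) {
        cap_ids[k + 1L, gi + 1L, gj + 1L] <- ring_id(k, m + (m - gi))
      } else if (gi == 0L) {
        cap_ids[k + 1L, gi + 1L, gj + 1L] <- ring_id(k, 2L * m + (m - gj))
      } else if (gj == 0L) {
        cap_ids[k + 1L, gi + 1L, gj + 1L] <- ring_id(k, 3L * m + gi)
      } else {
        xi <- -1 + 2 * gi / m
        et <- -1 + 2 * gj / m
        p <- xi * sqrt(1 - et^2 / 2)
        q <- et * sqrt(1 - xi^2 / 2)
        r <- sqrt(p^2 + q^2)
        v <- atan2(q, p) + pi / 4
        pe <- .surf_point(geom, "endo", pi - r * (pi - ucap), v)
        pp <- .surf_point(geom, "epi", pi - r * (pi - ucap), v)
        next_id <- next_id + 1L
        cap_ids[k + 1L, gi + 1L, gj + 1L] <- next_id
        extra[[length(extra) + 1L]] <- (1 - t) * pe + t * pp
      }
    }
  }
  if (length(extra)) nodes <- rbind(nodes, do.call(rbind, extra))

  # ---- elements ----------------------------------------------------------
  body_el <- matrix(0L, nt * nl * nc, 8L)
  e <- 0L
  for (k in 0:(nt - 1L)) for (i in 0:(nl - 1L)) for (j in 0:(nc - 1L)) {
    e <- e + 1L
    body_el[e, ] <- c(body_id(k, i, j), body_id(k, i + 1L, j),
                      body_id(k, i + 1L, j + 1L), body_id(k, i, j + 1L),
                      body_id(k + 1L, i, j), body_id(k + 1L, i + 1L, j),
                      body_id(k + 1L, i + 1L, j + 1L), body_id(k + 1L, i, j + 1L))
  }
  cap_el <- matrix(0L, nt * m * m, 8L)
  e <- 0L
  for (k in 0:(nt - 1L)) for (gi in 0:(m - 1L)) for (gj in 0:(m - 1L)) {
    e <- e + 1L
    cap_el[e, ] <- c(cap_ids[k + 1L, gi + 1L, gj + 1L],
                     cap_ids[k + 1L, gi + 1L, gj + 2L],
                     cap_ids[k + 1L, gi + 2L, gj + 2L],
                     cap_ids[k + 1L, gi + 2L, gj + 1L],
                     cap_ids[k + 2L, gi + 1L, gj + 1L],
                     cap_ids[k + 2L, gi + 1L, gj + 2L],
                     cap_ids[k + 2L, gi + 2L, gj + 2L],
                     cap_ids[k + 2L, gi + 2L, gj + 1L])
  }
  elems <- rbind(body_el, cap_el)
  is_cap <- c(rep(FALSE, nrow(body_el)), rep(TRUE, nrow(cap_el)))

  qual <- .fem_elem_quality_cpp(nodes, elems, numeric(3 * nrow(nodes)))
  if (any(qual$min_detJ <= 0))
    stop("mesh generation produced ", sum(qual$min_detJ <= 0),
         " element(s) with non-positive Jacobian")

  # ---- facet sets (tissue-outward orientation fixed below) ---------------
  mk_face <- function(el, loc) cbind(el[, loc[1]], el[, loc[2]],
                                     el[, loc[3]], el[, loc[4]])
  body_idx <- which(!is_cap)
  cap_idx <- which(is_cap)
  # element grid coordinates for the body block
  body_k <- rep(0:(nt - 1L), each = nl * nc)
  body_i <- rep(rep(0:(nl - 1L), each = nc), times = nt)
  endo_own <- c(body_idx[body_k == 0L], cap_idx[seq_len(m * m)])
  endo <- mk_face(elems[endo_own, , drop = FALSE], c(1L, 2L, 3L, 4L))
  epi_own <- c(body_idx[body_k == nt - 1L],
               cap_idx[(nt - 1L) * m * m + seq_len(m * m)])
  epi <- mk_face(elems[epi_own, , drop = FALSE], c(5L, 6L, 7L, 8L))
  base_own <- body_idx[body_i == 0L]
  base <- mk_face(elems[base_own, , drop = FALSE], c(1L, 4L, 8L, 5L))

  centroid <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] + nodes[elems[, 3], ] +
               nodes[elems[, 4], ] + nodes[elems[, 5], ] + nodes[elems[, 6], ] +
               nodes[elems[, 7], ] + nodes[elems[, 8], ]) / 8

  orient <- function(fa, own) {
    for (q in seq_len(nrow(fa))) {
      p <- nodes[fa[q, ], ]
      nrm <- .quad_normal(p)
      if (sum(nrm * (colMeans(p) - centroid[own[q], ])) < 0)
        fa[q, ] <- fa[q, c(1L, 4L, 3L, 2L)]
    }
    fa
  }
  endo <- orient(endo, endo_own)
  epi <- orient(epi, epi_own)
  base <- orient(base, base_own)

  # ---- local cardiac frames ----------------------------------------------
  inner <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
            nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  outer <- (nodes[elems[, 5], ] + nodes[elems[, 6], ] +
            nodes[elems[, 7], ] + nodes[elems[, 8], ]) / 4
  e_r <- outer - inner
  e_r <- e_r / sqrt(rowSums(e_r^2))
  nel <- nrow(elems)
  e_l <- matrix(0, nel, 3); e_c <- matrix(0, nel, 3)
  for (q in seq_len(nel)) {
    er <- e_r[q, ]
    p <- c(0, 0, 1) - er[3] * er
    if (sqrt(sum(p^2)) > 1e-6) {
      el_ <- p / sqrt(sum(p^2))
      ec_ <- .cross3(el_, er)
    } else {
      v <- atan2(centroid[q, 2], centroid[q, 1])
      c0 <- c(-sin(v), cos(v), 0)
      c0 <- c0 - sum(c0 * er) * er
      ec_ <- c0 / sqrt(sum(c0^2))
      el_ <- .cross3(er, ec_)
    }
    e_l[q, ] <- el_; e_c[q, ] <- ec_
  }

  layer_k <- c(body_k, rep(0:(nt - 1L), each = m * m))
  t_mid <- (layer_k + 0.5) / nt
  t_range <- cbind(layer_k / nt, (layer_k + 1) / nt)

  mesh <- structure(list(
    nodes = nodes, elems = elems, is_cap = is_cap,
    facets = list(endo = endo, epi = epi, base = base, septal_epi = NULL),
    facet_owner = list(endo = endo_own, epi = epi_own, base = base_own),
    frames = list(e_c = e_c, e_l = e_l, e_r = e_r),
    fiber = NULL, sheet = NULL,
    sector = rep(NA_integer_, nel),
    t_mid = t_mid, t_range = t_range, centroid = centroid,
    elem_volume = qual$volume,
    endo_base_ring = vapply(0:(nc - 1L), function(j) body_id(0L, 0L, j),
                            integer(1)),
    density = density, geom = geom, cap_angle = cap_angle),
    class = "lv_mesh")
  mesh
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.quad_normal <- function(p) {
  # area-weighted normal of a (possibly non-planar) quad from its diagonals
  0.5 * .cross3(p[3, ] - p[1, ], p[4, ] - p[2, ])
}

#' @export
print.lv_mesh <- function(x, ...) {
  d <- x$density
  cat("Idealized LV hex mesh:", nrow(x$nodes), "nodes,", nrow(x$elems),
      "elements (", sum(!x$is_cap), "body +", sum(x$is_cap), "apex cap )\n")
  cat("  density", d$n_transmural, "x", d$n_circumferential, "x",
      d$n_longitudinal, "; sectors",
      if (all(is.na(x$sector))) "unassigned" else "assigned",
      "; fibers", if (is.null(x$fiber)) "unassigned" else "assigned", "\n")
  invisible(x)
}

#' Triangulated surrogate right-ventricular endocardial surface
#'
#' Builds a triangle-mesh shell a small distance outside the LV epicardium
#' over an azimuthal wedge, standing in for a segmented RV endocardial
#' surface when testing septum detection on idealized geometry. The default
#' wedge is centered on the -x side of the LV.
#'
#' @param geom An [idealized_geometry()].
#' @param azimuth_center,half_width Wedge center and half-width, radians.
#' @param s_max Fraction of the base-to-cap span covered by the shell.
#' @param offset Gap between epicardium and shell, mm.
#' @param n_u,n_v Surface grid resolution.
#' @return A list with `vertices` (V x 3) and `faces` (T x 3, 1-based).
#' @export
synthetic_rv_surface <- function(geom, azimuth_center = pi, half_width = 0.95,
                                 s_max = 0.55, offset = 2, n_u = 20, n_v = 24) {
  ub <- .u_base(geom, "epi")
  ucap <- pi - 0.35
  us <- ub + (ucap - ub) * seq(0, s_max, length.out = n_u)
  vs <- seq(azimuth_center - half_width, azimuth_center + half_width,
            length.out = n_v)
  g <- expand.grid(u = us, v = vs)
  p <- .surf_point(geom, "epi", g$u, g$v)
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  sc <- 1 + offset / pmax(rho, 1e-9)
  verts <- cbind(p[, 1] * sc, p[, 2] * sc, p[, 3])
  id <- function(iu, iv) (iv - 1L) * n_u + iu
  faces <- matrix(0L, 2L * (n_u - 1L) * (n_v - 1L), 3L)
  f <- 0L
  for (iv in 1:(n_v - 1L)) for (iu in 1:(n_u - 1L)) {
    a <- id(iu, iv); b <- id(iu + 1L, iv)
    cc <- id(iu + 1L, iv + 1L); d <- id(iu, iv + 1L)
    faces[f + 1L, ] <- c(a, b, cc)
    faces[f + 2L, ] <- c(a, cc, d)
    f <- f + 2L
  }
  list(vertices = verts, faces = faces)
}

.facet_centroids_normals <- function(mesh, set = "epi") {
  fa <- mesh$facets[[set]]
  ctr <- (mesh$nodes[fa[, 1], , drop = FALSE] +
          mesh$nodes[fa[, 2], , drop = FALSE] +
          mesh$nodes[fa[, 3], , drop = FALSE] +
          mesh$nodes[fa[, 4], , drop = FALSE]) / 4
  nr <- t(vapply(seq_len(nrow(fa)), function(q) {
    n <- .quad_normal(mesh$nodes[fa[q, ], ])
    n / sqrt(sum(n^2))
  }, numeric(3)))
  list(centroid = ctr, normal = nr)
}

#' Locate the interventricular septum by ray casting
#'
#' Casts a ray from each epicardial facet centroid along its outward normal
#' and keeps the facets whose ray hits the RV endocardial surface within
#' `max_distance`. The resulting facet set receives RV pressure loading and
#' anchors the AHA circumferential origin.
#'
#' @param mesh An `lv_mesh`.
#' @param rv_surface Triangle surface (`vertices`, `faces`), e.g. from
#'   [synthetic_rv_surface()].
#' @param max_distance Maximum ray length, mm.
#' @return The mesh with `facets$septal_epi` filled; the selected epicardial
#'   facet indices are attached as attribute `septal_facets`.
#' @export
detect_septum <- function(mesh, rv_surface, max_distance = 10) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(rv_surface) || nrow(rv_surface$faces) == 0L)
    stop("empty RV surface: use septal_wedge_fallback() instead")
  cn <- .facet_centroids_normals(mesh, "epi")
  v1 <- rv_surface$vertices[rv_surface$faces[, 1], , drop = FALSE]
  v2 <- rv_surface$vertices[rv_surface$faces[, 2], , drop = FALSE]
  v3 <- rv_surface$vertices[rv_surface$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  hit <- vapply(seq_len(nrow(cn$centroid)), function(q) {
    .ray_hits(cn$centroid[q, ], cn$normal[q, ], v1, e1, e2, max_distance)
  }, logical(1))
  idx <- which(hit)
  mesh$facets$septal_epi <- mesh$facets$epi[idx, , drop = FALSE]
  attr(mesh, "septal_facets") <- idx
  mesh
}

# Moller-Trumbore ray/triangle intersection, vectorized over triangles
.ray_hits <- function(orig, dir, v1, e1, e2, max_distance) {
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  ok <- abs(det) > 1e-12
  if (!any(ok)) return(FALSE)
  tv <- sweep(v1, 2, orig, "-") * -1
  uu <- rowSums(tv * pv) / det
  qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
              tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
              tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
  vv <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
  tt <- rowSums(e2 * qv) / det
  any(ok & uu >= 0 & vv >= 0 & (uu + vv) <= 1 & tt > 1e-9 & tt <= max_distance)
}

#' Angular-wedge fallback for septum localization
#'
#' Marks as septal every epicardial facet whose centroid azimuth lies within
#' an angular wedge, for use when no RV surface is available.
#'
#' @inheritParams detect_septum
#' @param azimuth_center,half_width Wedge center and half-width, radians
#'   (default: +/- 60 degrees about the -x direction).
#' @export
septal_wedge_fallback <- function(mesh, azimuth_center = pi,
                                  half_width = pi / 3) {
  cn <- .facet_centroids_normals(mesh, "epi")
  az <- atan2(cn$centroid[, 2], cn$centroid[, 1])
  d <- atan2(sin(az - azimuth_center), cos(az - azimuth_center))
  idx <- which(abs(d) <= half_width)
  mesh$facets$septal_epi <- mesh$facets$epi[idx, , drop = FALSE]
  attr(mesh, "septal_facets") <- idx
  mesh
}

# pick a circular-interval bin with an explicit lower-label tie-break
.circ_bin <- function(psi, width, labels, tol = 1e-9) {
  k <- floor(psi / width)
  if (abs(psi - k * width) < tol && psi > tol) {
    # centroid sits exactly on a boundary: take the lower-numbered neighbor
    lo <- labels[(k - 1L) %% length(labels) + 1L]
    hi <- labels[k %% length(labels) + 1L]
    return(min(lo, hi))
  }
  labels[(k %% length(labels)) + 1L]
}

#' Partition the mesh into the 17 AHA segments
#'
#' Splits the LV into basal/mid/apical thirds along the long axis (6/6/4
#' circumferential segments) plus the apex cap (segment 17). The
#' circumferential origin is the anterior RV insertion, taken as the
#' counter-clockwise edge (viewed from the base) of the septal facet set;
#' numbering proceeds through the septum so the basal anteroseptal and
#' inferoseptal segments (2, 3) cover it. Elements are labeled by centroid;
#' centroids falling exactly on a boundary go to the lower-numbered segment.
#'
#' @param mesh An `lv_mesh` with a septal facet set (see [detect_septum()]).
#' @param septal_facets Optional explicit epicardial facet indices; defaults
#'   to the set stored by [detect_septum()]/[septal_wedge_fallback()].
#' @return The mesh with `sector` filled (integer 1-17 per element).
#' @export
partition_aha17 <- function(mesh, septal_facets = attr(mesh, "septal_facets")) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(septal_facets) || length(septal_facets) == 0L)
    stop("no septal facets: run detect_septum() or septal_wedge_fallback()")
  cn <- .facet_centroids_normals(mesh, "epi")
  az <- atan2(cn$centroid[septal_facets, 2], cn$centroid[septal_facets, 1])
  mu <- atan2(mean(sin(az)), mean(cos(az)))
  dev <- atan2(sin(az - mu), cos(az - mu))
  v_edge <- mu + max(dev)

  z <- mesh$centroid[, 3]
  z_pole <- min(mesh$nodes[, 3])
  lambda <- pmin(pmax(-z / -z_pole, 0), 1)
  vq <- atan2(mesh$centroid[, 2], mesh$centroid[, 1])
  psi <- (v_edge - vq) %% (2 * pi)

  sec <- integer(nrow(mesh$elems))
  basal <- c(2L, 3L, 4L, 5L, 6L, 1L)
  midl <- c(8L, 9L, 10L, 11L, 12L, 7L)
  apic <- c(14L, 15L, 16L, 13L)
  for (q in seq_along(sec)) {
    if (mesh$is_cap[q]) { sec[q] <- 17L; next }
    if (lambda[q] <= 1 / 3 + 1e-12) {
      sec[q] <- .circ_bin(psi[q], pi / 3, basal)
    } else if (lambda[q] <= 2 / 3 + 1e-12) {
      sec[q] <- .circ_bin(psi[q], pi / 3, midl)
    } else {
      sec[q] <- .circ_bin((psi[q] + pi / 4) %% (2 * pi), pi / 2, apic)
    }
  }
  mesh$sector <- sec
  missing <- setdiff(1:17, unique(sec))
  if (length(missing))
    warning("mesh too coarse to populate all 17 sectors; empty: ",
            paste(missing, collapse = ", "))
  mesh
}

#' Assign the rule-based myofiber field
#'
#' The helix angle varies linearly across the wall from `endo_angle` at the
#' endocardium to `epi_angle` at the epicardium; the fiber lies in the plane
#' spanned by the local circumferential and longitudinal directions,
#' `f = cos(theta) e_c + sin(theta) e_l`, evaluated at the element
#' mid-wall coordinate. The in-plane cross-fiber (sheet) direction completes
#' a right-handed orthonormal triad with the radial normal.
#'
#' @param mesh An `lv_mesh`.
#' @param endo_angle,epi_angle Helix angles in degrees.
#' @return The mesh with `fiber` and `sheet` fields filled.
#' @export
assign_fibers <- function(mesh, endo_angle = 60, epi_angle = -60) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(mesh$frames)) stop("element frames missing")
  th <- (endo_angle + mesh$t_mid * (epi_angle - endo_angle)) * pi / 180
  f <- cos(th) * mesh$frames$e_c + sin(th) * mesh$frames$e_l
  f <- f / sqrt(rowSums(f^2))
  s <- t(vapply(seq_len(nrow(f)), function(q)
    .cross3(mesh$frames$e_r[q, ], f[q, ]), numeric(3)))
  mesh$fiber <- f
  mesh$sheet <- s
  mesh$fiber_angles <- c(endo = endo_angle, epi = epi_angle)
  mesh
}

#' Helix angle at a normalized wall depth
#'
#' @param t Transmural coordinate in `[0, 1]` (0 = endocardium).
#' @param endo_angle,epi_angle Helix angles in degrees.
#' @return Helix angle in degrees.
#' @export
helix_angle <- function(t, endo_angle = 60, epi_angle = -60) {
  stopifnot(all(t >= 0 & t <= 1))
  endo_angle + t * (epi_angle - endo_angle)
}

#' LV cavity volume
#'
#' Divergence-theorem volume of the (optionally deformed) endocardial
#' surface, closed by a planar cap fanned across the basal endocardial ring.
#'
#' @param mesh An `lv_mesh`.
#' @param u Optional nodal displacement vector (length `3 * n_nodes`) or
#'   matrix (`n_nodes x 3`); `NULL` gives the reference cavity volume.
#' @return Cavity volume in ml.
#' @export
cavity_volume <- function(mesh, u = NULL) {
  stopifnot(inherits(mesh, "lv_mesh"))
  x <- mesh$nodes
  if (!is.null(u)) {
    if (is.matrix(u)) x <- x + u
    else x <- x + matrix(u, ncol = 3, byrow = TRUE)
  }
  vol6 <- 0
  fa <- mesh$facets$endo
  for (q in seq_len(nrow(fa))) {
    # cavity-outward orientation = reverse of the tissue-outward quad
    p <- x[fa[q, c(1L, 4L, 3L, 2L)], ]
    ctr <- colMeans(p)
    for (s in 1:4) {
      a <- p[s, ]; b <- p[s %% 4 + 1, ]
      vol6 <- vol6 + sum(ctr * .cross3(a, b))
    }
  }
  ring <- x[mesh$endo_base_ring, , drop = FALSE]
  ctr <- colMeans(ring)
  nrg <- nrow(ring)
  for (j in seq_len(nrg)) {
    a <- ring[j, ]; b <- ring[j %% nrg + 1, ]
    vol6 <- vol6 + sum(ctr * .cross3(a, b))
  }
  vol6 / 6 / 1000
}
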