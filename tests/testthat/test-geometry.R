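test_that("idealized mesh has the constructed element counts and quality", {
  g <- tiny_geom()
  d <- mesh_density(3, 40, 22)
  m <- generate_idealized_lv(g, d)
  expect_equal(sum(!m$is_cap), 3 * 40 * 22)              # 2640 body elements
  expect_equal(sum(m$is_cap), 3 * (40 / 4)^2)            # mapped-square cap
  q <- cardiofem:::.fem_elem_quality_cpp(m$nodes, m$elems,
                                         numeric(3 * nrow(m$nodes)))
  expect_true(all(q$min_detJ > 0))
  # degenerate-coarse mesh still meshes with positive Jacobians
  m2 <- generate_idealized_lv(g, mesh_density(1, 4, 2))
  q2 <- cardiofem:::.fem_elem_quality_cpp(m2$nodes, m2$elems,
                                          numeric(3 * nrow(m2$nodes)))
  expect_true(all(q2$min_detJ > 0))
  expect_error(idealized_geometry(a_endo = -3), "positive")
})

test_that("endocardial surface nodes lie on the endocardial ellipsoid", {
  g <- idealized_geometry(a_endo = 25, c_endo = 60, wall_thickness = 10)
  m <- generate_idealized_lv(g, mesh_density(2, 16, 8))
  ids <- unique(as.vector(m$facets$endo))
  p <- m$nodes[ids, ]
  zc <- -g$truncation * g$c_endo
  resid <- (p[, 1] / g$a_endo)^2 + (p[, 2] / g$a_endo)^2 +
    ((p[, 3] - zc) / g$c_endo)^2 - 1
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("cavity volume matches the analytic half-ellipsoid and converges", {
  g <- idealized_geometry(a_endo = 25, c_endo = 60, wall_thickness = 10,
                          truncation = 0)
  exact <- 2 / 3 * pi * 25^2 * 60 / 1000
  errs <- sapply(list(mesh_density(1, 12, 6), mesh_density(2, 24, 12),
                      mesh_density(3, 48, 24)), function(d) {
    abs(cavity_volume(generate_idealized_lv(g, d)) - exact) / exact
  })
  expect_lt(errs[3], 0.01)            # <= 1% at the reference density
  expect_true(all(diff(errs) < 0))    # error decreases under refinement
  # observed convergence order at least ~1 (halving h at least halves err)
  expect_gt(errs[1] / errs[2], 2)
})

test_that("cavity volume is translation invariant and scales as k^3", {
  m <- tiny_mesh()
  v0 <- cavity_volume(m)
  u <- matrix(rep(c(3, -2, 5), each = nrow(m$nodes)), ncol = 3)
  expect_equal(cavity_volume(m, u), v0, tolerance = 1e-10)
  k <- 1.37
  u_scale <- (k - 1) * m$nodes
  expect_equal(cavity_volume(m, u_scale), k^3 * v0, tolerance = 1e-10)
})

test_that("septum detection finds facets facing the RV shell", {
  g <- tiny_geom()
  m <- generate_idealized_lv(g, mesh_density(2, 16, 8))
  rv <- synthetic_rv_surface(g)          # shell on the -x side
  ms <- detect_septum(m, rv)
  idx <- attr(ms, "septal_facets")
  expect_gt(length(idx), 0)
  cn <- cardiofem:::.facet_centroids_normals(ms, "epi")
  expect_true(all(cn$normal[idx, 1] < 0)) # outward normals point toward -x
  # far-away surface: no hits
  rv_far <- rv
  rv_far$vertices[, 1] <- rv_far$vertices[, 1] - 500
  mfar <- detect_septum(m, rv_far, max_distance = 10)
  expect_equal(length(attr(mfar, "septal_facets")), 0)
  expect_error(detect_septum(m, list(vertices = matrix(0, 0, 3),
                                     faces = matrix(0L, 0, 3))), "fallback")
})

test_that("septum detection is invariant under joint rigid rotation", {
  g <- tiny_geom()
  m <- generate_idealized_lv(g, mesh_density(1, 8, 4))
  rv <- synthetic_rv_surface(g)
  i0 <- attr(detect_septum(m, rv), "septal_facets")
  th <- 1.1
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- m; m2$nodes <- m$nodes %*% t(Q)
  rv2 <- rv; rv2$vertices <- rv$vertices %*% t(Q)
  expect_equal(attr(detect_septum(m2, rv2), "septal_facets"), i0)
})

test_that("wedge fallback selects by centroid azimuth", {
  m <- generate_idealized_lv(tiny_geom(), mesh_density(1, 8, 4))
  ms <- septal_wedge_fallback(m, azimuth_center = pi, half_width = pi / 3)
  cn <- cardiofem:::.facet_centroids_normals(ms, "epi")
  az <- atan2(cn$centroid[, 2], cn$centroid[, 1])
  d <- abs(atan2(sin(az - pi), cos(az - pi)))
  expect_true(all(d[attr(ms, "septal_facets")] <= pi / 3 + 1e-12))
  expect_true(all(d[-attr(ms, "septal_facets")] > pi / 3))
})

test_that("AHA partition labels every element, 17 only on the cap", {
  m <- ci_mesh()
  expect_equal(sort(unique(m$sector)), 1:17)
  expect_true(all(m$sector[m$is_cap] == 17L))
  expect_true(all(m$sector[!m$is_cap] != 17L))
  # septal facets' owning elements carry septal labels (2, 3, 8, 9, 14)
  sep_elems <- m$facet_owner$epi[attr(m, "septal_facets")]
  expect_true(mean(m$sector[sep_elems] %in% c(2, 3, 8, 9, 14)) > 0.8)
  expect_warning(
    partition_aha17(septal_wedge_fallback(
      generate_idealized_lv(tiny_geom(), mesh_density(1, 4, 2)))),
    "sector")
})

test_that("fiber rule: +60 at endo, -60 at epi, 0 and circumferential midwall", {
  expect_equal(helix_angle(0), 60)
  expect_equal(helix_angle(1), -60)
  expect_equal(helix_angle(0.5), 0)
  m <- build_lv_mesh(tiny_geom(), mesh_density(1, 8, 4))
  # single transmural layer: elements sit at t = 0.5, fiber along e_c
  expect_equal(m$t_mid, rep(0.5, nrow(m$elems)))
  expect_equal(m$fiber, m$frames$e_c, tolerance = 1e-12)
  m3 <- build_lv_mesh(tiny_geom(), mesh_density(3, 8, 4))
  # layers sit at t = 1/6, 3/6, 5/6: signed helix angles 40, 0, -40 degrees
  th <- atan2(rowSums(m3$fiber * m3$frames$e_l),
              rowSums(m3$fiber * m3$frames$e_c)) * 180 / pi
  expect_equal(round(th, 9), helix_angle(m3$t_mid))
})

test_that("fiber field is unit norm and orthogonal to the radial direction", {
  m <- ci_mesh()
  expect_equal(rowSums(m$fiber^2), rep(1, nrow(m$elems)), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(m$fiber * m$frames$e_r))), 1e-12)
  # frames are right-handed orthonormal triads
  d <- sapply(seq_len(nrow(m$elems)), function(q) {
    det(cbind(m$frames$e_c[q, ], m$frames$e_l[q, ], m$frames$e_r[q, ]))
  })
  expect_equal(d, rep(1, nrow(m$elems)), tolerance = 1e-10)
})
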