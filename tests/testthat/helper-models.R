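# small shared fixtures: a coarse labeled mesh is enough for most checks
tiny_geom <- function() idealized_geometry()

tiny_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_lv_mesh(tiny_geom(), mesh_density(1, 8, 4))
    cache
  }
})

ci_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_lv_mesh(tiny_geom(), mesh_density(2, 16, 8))
    cache
  }
})

tiny_model <- function(C_H = 0.25, Tmax_H = 300, alpha = 0,
                       pressures = pressure_set(20, 140, 8, 28),
                       scores = score_map17(), mesh = tiny_mesh()) {
  lv_model(mesh, scores, global_parameters(C_H, Tmax_H, alpha), pressures)
}

# random admissible Green-Lagrange strain (2E + I positive definite)
random_strain <- function(scale = 0.05) {
  A <- matrix(rnorm(9, sd = scale), 3, 3)
  (A + t(A)) / 2
}
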