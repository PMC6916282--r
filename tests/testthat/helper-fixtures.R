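# Shared small fixtures. Everything is generated in code; the coarse 10 mm
# phantom keeps the unit tests fast while the acceptance tests use the 5 mm
# scaled study.

tiny_phantom <- function(spacing = 10) {
  ph <- make_water_phantom(spacing = spacing)
  ph$centers <- voxel_centers(ph$grid)
  ph
}

default_bgrid <- function() bixel_grid(mlc_spec())

vertical_geom <- function(sad = 800) {
  cp_geometry(c(0, 0, -1), c(1, 0, 0), c(0, -1, 0), sad = sad)
}

random_aperture <- function(n_rows = 10, xmax = 40, wmin = 5, wmax = 35,
                            mu = 1) {
  l <- runif(n_rows, -xmax, 0)
  w <- runif(n_rows, wmin, wmax)
  aperture(l, pmin(l + w, xmax), mu)
}

# small 9-node arc problem used by the optimizer and DAO tests
mini_arc_problem <- function(n_fluence_iter = 20) {
  ph <- tiny_phantom()
  bg <- default_bgrid()
  kern <- beam_kernel()
  traj <- build_arc_trajectory(1, 9, 5)
  geoms <- traj$control_points
  infl <- assemble_influence(geoms, bg, ph, kern)
  presc <- 40
  obj <- phantom_objective(presc)
  fl_idx <- seq(2, 8, by = 3)
  fl <- optimize_fluence(infl[fl_idx], ph$structures, obj,
                         n_iter = n_fluence_iter)
  fmaps <- lapply(fl$weights, matrix, nrow = bg$n_rows)
  aps <- arc_distribute(fmaps, fl_idx, 9, bg, delivery_constraints(),
                        mlc_spec())
  plan <- plan_new("dynamic_arc", geoms, apertures = aps,
                   prescription = presc, scheme = "CKA4")
  list(phantom = ph, bgrid = bg, kernel = kern, geoms = geoms, infl = infl,
       objective = obj, fluence = fl, fmaps = fmaps, fl_idx = fl_idx,
       plan = plan, prescription = presc)
}
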