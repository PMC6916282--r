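test_that("plan interpolation arithmetic and MU conservation", {
  bg <- default_bgrid()
  pl <- make_two_cp_demo("crescent_pair", bg)
  ip <- interpolate_plan(pl, 5, 20)
  # 5 interpolated nodes per interval, 20 apertures coalesced on each
  expect_length(ip$nodes, 1 + 5)
  expect_true(all(vapply(ip$nodes[-1], function(nd) length(nd$apertures),
                         integer(1)) == 20))
  # 100 interpolated apertures per interval, each with MU/100
  mus <- unlist(lapply(ip$nodes[-1], function(nd)
    vapply(nd$apertures, `[[`, numeric(1), "mu")))
  expect_length(mus, 100)
  expect_true(all(mus == 5500 / 100))
  expect_equal(interp_plan_total_mu(ip), plan_total_mu(pl))
  # effective angular resolution 5 deg / 100 = 0.05 deg
  expect_equal(5 / (5 * 20), 0.05)
  # identical end apertures: every interpolated shape equals them
  pl2 <- pl; pl2$apertures[[2]] <- pl$apertures[[1]]
  pl2$apertures[[2]]$mu <- 100
  ip2 <- interpolate_plan(pl2, 5, 20)
  for (nd in ip2$nodes[-1]) for (a in nd$apertures) {
    expect_equal(a$left, pl$apertures[[1]]$left)
    expect_equal(a$right, pl$apertures[[1]]$right)
  }
  # last interpolated orientation is exactly the second node's
  gB <- pl$geometries[[2]]
  gl <- ip$nodes[[6]]$geometry
  expect_equal(gl$direction, gB$direction, tolerance = 1e-12)
  expect_equal(gl$u, gB$u, tolerance = 1e-12)
  expect_error(interpolate_plan(pl, 0, 20))
})

test_that("recalculated dose of a shape-constant plan matches unrecalculated", {
  ph <- tiny_phantom()
  bg <- default_bgrid()
  geoms <- build_arc_trajectory(1, 3, 5)$control_points
  ap <- aperture(rep(-15, 10), rep(15, 10), 500)
  pl <- plan_new("dynamic_arc", geoms, apertures = list(ap, ap, ap),
                 prescription = 10, scheme = "CKA1")
  d_disc <- evaluate_plan_dose(pl, ph, bg, model = "discrete")
  d_rec <- evaluate_plan_dose(interpolate_plan(pl, 5, 20), ph, bg)
  ptv <- ph$structures$ptv$idx
  expect_lt(max(abs(d_disc[ptv] - d_rec[ptv])) / max(d_disc[ptv]), 0.005)
})

test_that("dense-shape recalc at the plan's own orientations reproduces the
           effective-fluence dose", {
  set.seed(42)
  pr <- mini_arc_problem(n_fluence_iter = 10)
  dao <- optimize_apertures(pr$plan, pr$infl, pr$phantom$structures,
                            pr$objective, motion_model = "effective",
                            n_iter = 4, bgrid = pr$bgrid)
  # 1 interpolated node per interval = the terminal orientations themselves;
  # 100 shapes sample the same continuous leaf motion the effective model
  # integrates exactly
  ip <- interpolate_plan(dao$plan, 1L, 100L)
  d_dense <- evaluate_plan_dose(ip, pr$phantom, pr$bgrid, pr$kernel)
  ptv <- pr$phantom$structures$ptv$idx
  d95 <- dose_at_volume(d_dense[ptv], 0.95)
  expect_lt(abs(d95 - pr$prescription) / pr$prescription, 0.002)
})

test_that("DVH curves and point metrics", {
  grid <- voxel_grid(c(0, 0, 0), 10, c(10, 10, 1))
  s <- roi_structure("s", 1:100, grid)
  # uniform dose: step curve, D95 = the value
  cu <- dvh(rep(2, 100), s)
  expect_equal(dvh_metric(cu, "D95"), 2, tolerance = 0.051)
  expect_equal(cu$volume[1], 1)
  expect_true(all(diff(cu$volume) <= 0))
  # half at 1 Gy, half at 3 Gy: V(2) = 0.5
  d <- c(rep(1, 50), rep(3, 50))
  ch <- dvh(d, s)
  expect_equal(dvh_metric(ch, "V2"), 0.5)
  # D95 equals the direct 5th-percentile oracle within one bin
  set.seed(41)
  for (trial in 1:10) {
    dd <- runif(100, 0, 60)
    cv <- dvh(dd, s, bin_width = 0.05)
    expect_lt(abs(dvh_metric(cv, "D95") - dose_at_volume(dd, 0.95)), 0.3)
  }
  expect_error(dvh(rep(1, 10), roi_structure("e", integer(0), grid)))
  expect_error(dvh_metric(cu, "Q17"), "unknown")
})

test_that("conformity index follows its definition", {
  grid <- voxel_grid(c(0, 0, 0), 10, c(10, 10, 10))
  ptv <- roi_structure("ptv", 1:200, grid)
  presc <- 40
  # full coverage, no spill
  d <- numeric(1000); d[1:200] <- presc
  expect_equal(conformity_index(d, ptv, grid, presc)$ci, 1)
  # exactly 95% coverage, all inside the PTV -> CI = 0.95
  d2 <- numeric(1000); d2[1:190] <- presc
  r2 <- conformity_index(d2, ptv, grid, presc)
  expect_equal(r2$ci, 0.95)
  expect_equal(r2$ptv_pres_cc, r2$v_pres_cc)
  # 50% coverage with V_pres = PTV -> 0.25
  d3 <- numeric(1000); d3[1:100] <- presc; d3[201:300] <- presc
  expect_equal(conformity_index(d3, ptv, grid, presc)$ci, 0.25)
  # no prescription volume
  expect_equal(conformity_index(numeric(1000), ptv, grid, presc)$ci, 0)
})

test_that("delivery-time models match their worked examples", {
  bg <- default_bgrid()
  geoms <- build_arc_trajectory(1, 3, 5)$control_points
  mk <- function(mu) aperture(rep(-10, 10), rep(10, 10), mu)
  pl <- plan_new("dynamic_arc", geoms,
                 apertures = list(mk(0), mk(100), mk(10)),
                 prescription = 10, scheme = "CKA4")
  tm <- estimate_time_dynamic(pl)
  # zero-MU interval costs exactly T_R; 100 MU at 1000 MU/min costs 6 s
  expect_equal(tm$per_interval[[1]], 1.5)
  expect_equal(tm$per_interval[[2]], 6)
  expect_equal(tm$per_interval[[3]], 1.5)   # 10 MU < D*T_R
  expect_gte(tm$total, length(tm$per_interval) * 1.5)

  spl <- plan_new("static", geoms,
                  segments = list(list(), list(mk(50)), list(mk(50), mk(20))),
                  prescription = 10, scheme = "CKSB")
  ts <- estimate_time_static(spl)
  expect_equal(ts$per_node[[1]], 1.5)       # empty node: robot move only
  expect_equal(ts$per_node[[2]], 3.5 + 3)   # 50 MU -> 3 s beam-on
  expect_equal(ts$per_node[[3]], 3.5 + 3 + 3.5 + 1.2)  # two positioning charges
  expect_equal(ts$total, sum(ts$per_node))
})

test_that("goal checking reports pass/fail with margins", {
  grid <- voxel_grid(c(0, 0, 0), 10, c(10, 1, 1))
  s <- roi_structure("ptv", 1:10, grid)
  dvhs <- list(ptv = dvh(rep(40, 10), s))
  goals <- data.frame(structure = c("ptv", "ptv", "oar"),
                      metric = c("D95", "Dmax", "D50"),
                      bound = c(40, 45, 10),
                      type = c("min", "max", "max"))
  rep <- check_goals(dvhs, goals)
  expect_true(rep$pass[1])
  expect_equal(rep$margin[1], 0, tolerance = 0.06)
  expect_true(rep$pass[2])
  expect_true(is.na(rep$pass[3]))
  expect_match(rep$note[3], "not found")
  expect_equal(nrow(check_goals(dvhs, goals[0, ])), 0)
})
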