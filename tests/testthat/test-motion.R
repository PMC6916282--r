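test_that("effective fluence matches the ramp equations at key points", {
  # behind the left leaf's start: never exposed
  expect_equal(effective_fluence(0, 40, 10, 50, 1, 0), 0)
  # midpoint of the left ramp with the right leaf never covering
  expect_equal(effective_fluence(0, 40, 100, 100, 1, 20), 0.5)
  # overlapping ramps (Eq.-9 regime): worked example
  expect_equal(effective_fluence(0, 40, 10, 50, 1, 25), 0.25)
  # stationary aperture: static step function
  expect_equal(effective_fluence(-10, -10, 10, 10, 2, 5), 2)
  expect_equal(effective_fluence(-10, -10, 10, 10, 2, 15), 0)
})

test_that("effective fluence equals the time-integration oracle", {
  set.seed(31)
  tt <- seq(0.5 / 5000, 1 - 0.5 / 5000, length.out = 5000)
  for (i in 1:100) {
    a <- runif(1, -40, 40); b <- runif(1, -40, 40)
    cc <- runif(1, -40, 40); d <- runif(1, -40, 40)
    Phi <- runif(1, 0, 5); x <- runif(1, -50, 50)
    L <- a + tt * (b - a); R <- cc + tt * (d - cc)
    oracle <- Phi * mean(L <= x & x <= R)
    expect_lt(abs(effective_fluence(a, b, cc, d, Phi, x) - oracle),
              1e-3 * max(Phi, 1))
  }
})

test_that("phi bounds and ramp reductions hold on randomized cases", {
  set.seed(32)
  n <- 10000
  a <- runif(n, -40, 0); b <- a + runif(n, 0, 50)
  cc <- runif(n, 0, 40); d <- cc + runif(n, 0, 50)
  x <- runif(n, -60, 60); Phi <- runif(n, 0, 3)
  phi <- mapply(function(a, b, cc, d, Phi, x)
    effective_fluence(a, b, cc, d, Phi, x), a, b, cc, d, Phi, x)
  expect_true(all(phi >= -1e-12))
  expect_true(all(phi <= Phi + 1e-12))
  # combined form reduces to the single-leaf ramps when the other ramp is
  # inactive over the point
  clip01 <- function(z) pmin(pmax(z, 0), 1)
  rampL <- clip01((x - a) / (b - a))
  rampR <- clip01((x - cc) / (d - cc))
  right_inactive <- x <= cc        # right leaf never reaches down to x
  expect_equal(phi[right_inactive],
               (Phi * rampL)[right_inactive], tolerance = 1e-12)
  left_inactive <- x >= b          # left leaf ramp finished below x
  expect_equal(phi[left_inactive],
               (Phi * (1 - rampR))[left_inactive], tolerance = 1e-12)
  # general overlapping regime equals the clipped Eq.-9 difference
  expect_equal(phi, Phi * pmin(pmax(rampL - rampR, 0), 1), tolerance = 1e-12)
})

test_that("interval fluence map: static limit, zero map, and oracle", {
  bg <- default_bgrid()
  set.seed(33)
  ap <- random_aperture()
  expect_equal(interval_fluence_map(ap, ap, 3, bg),
               static_aperture_fluence(ap, 3, bg))
  cl <- closed_aperture(10, park = 0)
  expect_equal(interval_fluence_map(cl, cl, 5, bg),
               matrix(0, bg$n_rows, bg$n_cols))
  expect_error(interval_fluence_map(aperture(0, 1, 1), ap, 1, bg),
               "mismatch")
  # K-aperture static-interpolation oracle converges at O(1/K)
  a <- random_aperture(); b <- random_aperture()
  phi <- interval_fluence_map(a, b, 2, bg)
  orc <- function(K) {
    m <- matrix(0, bg$n_rows, bg$n_cols)
    for (j in 1:K) {
      s <- (j - 0.5) / K
      apk <- aperture(a$left + s * (b$left - a$left),
                      a$right + s * (b$right - a$right), 1)
      m <- m + static_aperture_fluence(apk, 2 / K, bg)
    }
    m
  }
  errs <- vapply(c(10, 20, 40), function(K) max(abs(orc(K) - phi)),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 2)   # at least first-order decay
})

test_that("static aperture fluence implements partial-bixel exposure", {
  bg <- default_bgrid()
  # leaf tip exactly at a bixel midpoint -> half the open-field fluence
  ap <- closed_aperture(10)
  ap$left[5] <- bg$xc[8]; ap$right[5] <- bg$xc[12] + bg$w / 2
  f <- static_aperture_fluence(ap, 2, bg)
  expect_equal(f[5, 8], 1)          # half of Phi = 2
  expect_equal(f[5, 10], 2)         # fully exposed
  expect_equal(f[5, 3], 0)          # fully covered
  expect_equal(sum(f[-5, ]), 0)
})

test_that("semicircle demo interval matches the dense interpolation oracle", {
  bg <- default_bgrid()
  pl <- make_two_cp_demo("semicircle_pair", bg)
  a <- pl$apertures[[1]]; b <- pl$apertures[[2]]
  phi <- interval_fluence_map(a, b, 1000, bg)
  m <- matrix(0, bg$n_rows, bg$n_cols)
  for (j in 1:100) {
    s <- (j - 0.5) / 100
    apk <- aperture(a$left + s * (b$left - a$left),
                    a$right + s * (b$right - a$right), 1)
    m <- m + static_aperture_fluence(apk, 10, bg)
  }
  expect_lt(max(abs(m - phi)), 0.01 * 1000)
})

test_that("DAO decreases the objective and keeps iterates deliverable", {
  set.seed(34)
  pr <- mini_arc_problem()
  cons <- delivery_constraints(); mlc <- mlc_spec()
  viol <- 0
  cb <- function(it, aps, f) {
    prev <- NULL
    for (a in aps) {
      ac <- apply_mlc_constraints(a, prev, cons, mlc, "arc")
      if (max(abs(ac$left - a$left), abs(ac$right - a$right)) > 1e-7)
        viol <<- viol + 1
      prev <- a
    }
  }
  for (mm in c("effective", "discrete")) {
    dao <- optimize_apertures(pr$plan, pr$infl, pr$phantom$structures,
                              pr$objective, motion_model = mm, n_iter = 8,
                              constraints = cons, mlc = mlc,
                              bgrid = pr$bgrid, callback = cb)
    expect_true(all(diff(dao$trace) <= 1e-9 * dao$trace[1] + 1e-12))
    expect_lt(tail(dao$trace, 1), dao$trace[1])
    # renormalized to prescription
    d95 <- dose_at_volume(dao$dose[pr$phantom$structures$ptv$idx], 0.95)
    expect_equal(d95, pr$prescription, tolerance = 1e-9)
  }
  expect_equal(viol, 0)
})

test_that("zero-iteration DAO only renormalizes", {
  pr <- mini_arc_problem(n_fluence_iter = 10)
  dao <- optimize_apertures(pr$plan, pr$infl, pr$phantom$structures,
                            pr$objective, motion_model = "effective",
                            n_iter = 0, bgrid = pr$bgrid)
  sc <- dao$plan$apertures[[2]]$mu / pr$plan$apertures[[2]]$mu
  for (k in seq_along(pr$plan$apertures)) {
    expect_equal(dao$plan$apertures[[k]]$left, pr$plan$apertures[[k]]$left)
    if (pr$plan$apertures[[k]]$mu > 0)
      expect_equal(dao$plan$apertures[[k]]$mu / pr$plan$apertures[[k]]$mu,
                   sc)
  }
  d95 <- dose_at_volume(dao$dose[pr$phantom$structures$ptv$idx], 0.95)
  expect_equal(d95, pr$prescription, tolerance = 1e-9)
})
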