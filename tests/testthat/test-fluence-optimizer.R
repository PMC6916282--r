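test_that("objective matches its closed form and flags empty structures", {
  grid <- voxel_grid(c(0, 0, 0), 1, c(10, 1, 1))
  s <- list(ptv = roi_structure("ptv", 1:10, grid))
  spec <- objective_spec(list(ptv = list(a = 2, b = 3, dmin = 1, dmax = 2)))
  # all doses inside the window -> F = 0
  r <- dose_objective(rep(1.5, 10), s, spec)
  expect_equal(r$F, 0)
  # one voxel exceeding dmax by delta contributes b * delta^2 exactly
  d <- rep(1.5, 10); d[4] <- 2 + 0.7
  expect_equal(dose_objective(d, s, spec)$F, 3 * 0.7^2)
  d2 <- rep(1.5, 10); d2[1] <- 1 - 0.25
  expect_equal(dose_objective(d2, s, spec)$F, 2 * 0.25^2)
  s$ptv$idx <- integer(0)
  expect_error(dose_objective(d, s, spec), "empty")
  expect_error(objective_spec(list(x = list(a = 1, b = 1, dmin = 3,
                                            dmax = 1))))
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(11)
  D <- Matrix::Matrix(matrix(runif(50 * 10), 50, 10), sparse = TRUE)
  grid <- voxel_grid(c(0, 0, 0), 1, c(50, 1, 1))
  strs <- list(ptv = roi_structure("ptv", 1:20, grid),
               body = roi_structure("body", 1:50, grid))
  spec <- objective_spec(list(ptv = list(a = 1, b = 1, dmin = 2, dmax = 2.1),
                              body = list(b = 0.5, dmax = 1)))
  f0 <- function(w) dose_objective(as.numeric(D %*% w), strs, spec)$F
  for (trial in 1:5) {
    w <- runif(10)
    ga <- as.numeric(Matrix::crossprod(
      D, dose_objective(as.numeric(D %*% w), strs, spec,
                        gradient = TRUE)$grad))
    gn <- vapply(1:10, function(i) {
      h <- 1e-6; e <- numeric(10); e[i] <- h
      (f0(w + e) - f0(w - e)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-5)
  }
})

test_that("projected L-BFGS solves the separable toy exactly", {
  set.seed(12)
  n <- 12
  tgt <- runif(n, 1, 3)
  # identity influence, single structure with dmin = dmax = target
  fn <- function(w) sum((w - tgt)^2)
  gr <- function(w) 2 * (w - tgt)
  st <- plbfgs(rep(0, n), fn, gr, project = function(x) pmax(x, 0),
               n_iter = 40)
  expect_lt(max(abs(st$x - tgt)), 1e-6)
  expect_true(all(diff(st$trace) <= 1e-12))
})

test_that("no negative weight appears in any accepted iterate", {
  set.seed(13)
  n <- 8
  A <- matrix(runif(n * n), n) + diag(n)
  tgt <- runif(n, -1, 2)       # some targets unreachable (negative)
  fn <- function(w) sum((A %*% w - tgt)^2)
  gr <- function(w) as.numeric(2 * t(A) %*% (A %*% w - tgt))
  seen_neg <- FALSE
  st <- plbfgs(rep(0.5, n), fn, gr, project = function(x) pmax(x, 0),
               n_iter = 30,
               callback = function(it, x, f) {
                 if (any(x < 0)) seen_neg <<- TRUE
               })
  expect_false(seen_neg)
  expect_true(all(st$x >= 0))
})

test_that("importance rescaling leaves the iterate sequence unchanged", {
  set.seed(14)
  D <- Matrix::Matrix(matrix(runif(30 * 6), 30, 6), sparse = TRUE)
  grid <- voxel_grid(c(0, 0, 0), 1, c(30, 1, 1))
  strs <- list(ptv = roi_structure("ptv", 1:15, grid),
               body = roi_structure("body", 1:30, grid))
  mk <- function(k) objective_spec(list(
    ptv = list(a = k, b = k, dmin = 2, dmax = 2.2),
    body = list(b = 0.1 * k, dmax = 1)))
  r1 <- optimize_fluence(list(D), strs, mk(1), n_iter = 15)
  r2 <- optimize_fluence(list(D), strs, mk(7.3), n_iter = 15)
  expect_equal(r1$weights[[1]], r2$weights[[1]], tolerance = 1e-8)
})

test_that("zero start with pure max objectives is a fixed point", {
  set.seed(15)
  D <- Matrix::Matrix(matrix(runif(20 * 5), 20, 5), sparse = TRUE)
  grid <- voxel_grid(c(0, 0, 0), 1, c(20, 1, 1))
  strs <- list(body = roi_structure("body", 1:20, grid))
  spec <- objective_spec(list(body = list(b = 1, dmax = 1)))
  r <- optimize_fluence(list(D), strs, spec, n_iter = 5,
                        w0 = list(numeric(5)))
  expect_equal(r$weights[[1]], numeric(5))
  expect_equal(r$trace, rep(0, 6))
})

test_that("with no curvature pairs the direction is steepest descent", {
  # first iteration of plbfgs moves along -g with step 1/|g|
  g0 <- c(3, -4)   # |g| = 5
  fn <- function(x) sum(g0 * x)          # linear: gradient constant
  gr <- function(x) g0
  tr <- list()
  st <- plbfgs(c(0, 0), fn, gr, n_iter = 1,
               callback = function(it, x, f) tr[[it]] <<- x)
  expect_equal(tr[[1]], -g0 / 5, tolerance = 1e-12)
})
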