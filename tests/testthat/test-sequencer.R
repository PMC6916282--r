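test_that("reducing-level sequencing matches worked examples", {
  # uniform positive map: one segment over the whole map, weight = value
  bg4 <- bixel_grid(mlc_spec(n_leaf_pairs = 8), half_width = 15,
                    bixel_width = 5)
  u <- matrix(3.7, 4, 6)
  su <- xia_verhey(u, 10, bg4)
  expect_length(su, 1)
  expect_equal(su[[1]]$weight, 3.7)
  expect_equal(su[[1]]$aperture$left, rep(min(bg4$xc) - 2.5, 4))
  expect_equal(su[[1]]$aperture$right, rep(max(bg4$xc) + 2.5, 4))
  # single-row map [1,1,2,2], two segments: level 2 over cols {3,4}, then
  # level 1 over cols {1,2}; exact reconstruction
  bg1 <- bixel_grid(mlc_spec(n_leaf_pairs = 2), half_width = 10,
                    bixel_width = 5)
  f <- matrix(c(1, 1, 2, 2), nrow = 1)
  segs <- xia_verhey(f, 2, bg1)
  expect_length(segs, 2)
  expect_equal(vapply(segs, `[[`, numeric(1), "weight"), c(2, 1))
  expect_equal(segs[[1]]$aperture$left, 0)
  expect_equal(segs[[1]]$aperture$right, 10)
  expect_equal(segs[[2]]$aperture$left, -10)
  expect_equal(segs[[2]]$aperture$right, 0)
  expect_equal(reconstruct_fluence(segs, bg1), f)
  # all-zero map: empty list
  expect_length(xia_verhey(matrix(0, 1, 4), 3, bg1), 0)
})

test_that("power-of-2 maps with rectifiable rows reconstruct exactly", {
  bg <- bixel_grid(mlc_spec(n_leaf_pairs = 6), half_width = 15,
                   bixel_width = 5)
  set.seed(21)
  # rows are non-decreasing dyadic staircases (values sums of distinct
  # powers of 2) and the global maximum is a power of 2, so every delivery
  # level's threshold set is one run per row and the decomposition is exact
  for (trial in 1:30) {
    f <- matrix(0, 3, 6)
    for (r in 1:3) {
      v <- cumsum(sample(c(0, 0, 1, 2, 4, 8), 6))
      f[r, ] <- sort(v)
    }
    f[sample(1:3, 1), 6] <- 16   # pin the global max to a power of 2
    segs <- xia_verhey(f, 64, bg)
    expect_lt(max(abs(reconstruct_fluence(segs, bg) - f)), 1e-9)
  }
})

test_that("two-segment decomposition tracks the brute-force pair oracle", {
  # The greedy reducing-level method is not sup-norm optimal among free
  # segment pairs (its open-where-above-level rule can be beaten by opening
  # below-level cells), so the honest, exhaustively verified bound is:
  # with the two delivery levels it chose, XV is within a factor 2 of the
  # best brute-force pair of single-interval segments, and exact whenever
  # the best pair is exact.
  intervals <- list()
  for (a in 1:4) for (b in a:4) intervals <- c(intervals, list(c(a, b)))
  intervals <- c(intervals, list(NULL))  # closed row
  bgr <- bixel_grid(mlc_spec(n_leaf_pairs = 2), half_width = 10,
                    bixel_width = 5)
  vals <- c(0, 1, 2, 4)
  grid4 <- expand.grid(vals, vals, vals, vals)
  for (row in seq_len(nrow(grid4))) {
    f <- matrix(as.numeric(grid4[row, ]), 1, 4)
    if (max(f) == 0) next
    segs <- xia_verhey(f, 2, bgr)
    err_xv <- max(abs(reconstruct_fluence(segs, bgr) - f))
    ws <- vapply(segs, `[[`, numeric(1), "weight")
    if (length(ws) == 1) ws <- c(ws, 0)
    best <- Inf
    for (i1 in seq_along(intervals)) for (i2 in seq_along(intervals)) {
      rec <- numeric(4)
      if (!is.null(intervals[[i1]]))
        rec[intervals[[i1]][1]:intervals[[i1]][2]] <-
          rec[intervals[[i1]][1]:intervals[[i1]][2]] + ws[1]
      if (!is.null(intervals[[i2]]))
        rec[intervals[[i2]][1]:intervals[[i2]][2]] <-
          rec[intervals[[i2]][1]:intervals[[i2]][2]] + ws[2]
      best <- min(best, max(abs(rec - f)))
    }
    expect_lte(err_xv, 2 * best + 1e-9)
    if (best < 1e-9) expect_lt(err_xv, 1e-9)
  }
})

test_that("arc redistribution covers every node and conserves MU", {
  bg <- default_bgrid()
  set.seed(23)
  fmaps <- lapply(1:3, function(i) {
    f <- matrix(0, bg$n_rows, bg$n_cols)
    f[3:8, 5:12] <- sample(c(1, 2, 4), 48, replace = TRUE)
    f
  })
  fl_idx <- c(2, 5, 8)
  aps <- arc_distribute(fmaps, fl_idx, 9, bg)
  expect_length(aps, 9)
  total_in <- sum(vapply(fmaps, function(m)
    sum(vapply(xia_verhey(m, 3, bg), `[[`, numeric(1), "weight")),
    numeric(1)))
  expect_equal(sum(vapply(aps, `[[`, numeric(1), "mu")), total_in)
  # every emitted aperture passes the static constraint projection unchanged
  cons <- delivery_constraints(); sp <- mlc_spec()
  for (a in aps) {
    ac <- apply_mlc_constraints(a, NULL, cons, sp, "static")
    expect_lt(max(abs(ac$left - a$left), abs(ac$right - a$right)), 1e-9)
  }
  # single-level map: one real aperture at the fluence node, closed
  # zero-MU apertures at its neighbours
  one <- matrix(0, bg$n_rows, bg$n_cols); one[4:6, 6:10] <- 2
  aps1 <- arc_distribute(list(one), 2L, 3L, bg)
  expect_equal(vapply(aps1, `[[`, numeric(1), "mu")[c(1, 3)], c(0, 0))
  expect_gt(aps1[[2]]$mu, 0)
  expect_false(any(aperture_open(aps1[[1]])))
})

test_that("static allocation respects the global budget and greedy rule", {
  bg <- default_bgrid()
  mk <- function(v) { f <- matrix(0, bg$n_rows, bg$n_cols)
    f[4:6, 6:10] <- v; f }
  # uniform maps, budget = node count: exactly one aperture each
  fmaps <- lapply(rep(2, 6), mk)
  out <- static_distribute(fmaps, 6, bg)
  expect_equal(vapply(out, length, integer(1)), rep(1L, 6))
  # budget 1: the single aperture goes to the most intense map
  fmaps2 <- lapply(c(1, 5, 2), mk)
  out2 <- static_distribute(fmaps2, 1, bg)
  expect_equal(vapply(out2, length, integer(1)), c(0L, 1L, 0L))
  # budget always respected
  set.seed(24)
  fmaps3 <- lapply(1:5, function(i) matrix(runif(bg$n), bg$n_rows))
  out3 <- static_distribute(fmaps3, 7, bg)
  expect_lte(sum(vapply(out3, length, integer(1))), 7)
  expect_error(static_distribute(fmaps3, 0, bg))
})
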