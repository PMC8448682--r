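test_that("response function matches closed-form kernel normalization", {
  g <- tuning_grid()$t
  expect_equal(response_function(list(numeric(0), numeric(0)), g),
               numeric(length(g)))
  expect_error(response_function(list()), "at least one trial")
  # single spike at t = 0: peak is the Gaussian mode in spikes/s
  r <- response_function(list(0), g)
  expect_equal(r[g == 0], 1000 / (20 * sqrt(2 * pi)), tolerance = 1e-9)
  expect_equal(r[abs(g) > 80], rep(0, sum(abs(g) > 80)))  # 4 sigma cut
  # law of large numbers: homogeneous Poisson at 30 spikes/s
  set.seed(21)
  trials <- lapply(1:500, function(i) {
    n <- rpois(1, 30 * 1.2)
    sort(runif(n, -600, 600))
  })
  rr <- response_function(trials, g)
  interior <- g > -350 & g < 300
  expect_equal(mean(rr[interior]), 30, tolerance = 1 / 30)
  expect_lt(max(abs(rr[interior] - 30)), 4)
})

test_that("tuning fields interpolate linearly inside, nearest outside", {
  lay <- as.matrix(stationary_target_layout()[, c("x", "y")])
  # constant anchors give a constant field
  f <- build_tuning_field(lay, rep(3.5, 17))
  expect_equal(range(f$activity), c(3.5, 3.5), tolerance = 1e-6)
  # values at the anchors themselves are reproduced
  set.seed(3)
  v <- runif(17, 0, 50)
  iw <- interp_weights(lay, lay[, 1], lay[, 2])
  expect_equal(as.numeric(iw$W %*% v), v, tolerance = 1e-4)
  # linear functions are reproduced inside the convex hull
  g <- tuning_grid()
  q <- expand.grid(x = g$x, y = g$y)
  iwg <- interp_weights(lay, q$x, q$y)
  lin <- 0.7 * lay[, 1] - 1.1 * lay[, 2] + 2
  got <- as.numeric(iwg$W %*% lin)
  want <- 0.7 * q$x - 1.1 * q$y + 2
  expect_equal(got[!iwg$outside], want[!iwg$outside], tolerance = 1e-4)
  # outside the hull: brute-force nearest-anchor oracle
  out_idx <- which(iwg$outside)[seq(1, sum(iwg$outside), length.out = 25)]
  for (i in out_idx) {
    d <- sqrt((lay[, 1] - q$x[i])^2 + (lay[, 2] - q$y[i])^2)
    expect_equal(as.numeric(iwg$W[i, ]),
                 as.numeric(seq_len(17) == which.min(d)))
  }
  expect_error(build_tuning_field(cbind(1:4, 2 * (1:4)), 1:4), "collinear")
})

test_that("window averaging is an inclusive time mean", {
  lay <- ring_positions(2)
  nt <- length(tuning_grid()$t)
  av <- matrix(rep(1:8, nt), nrow = 8)  # constant in t
  f <- build_tuning_field(lay, av)
  m <- window_average(f, -100, 100)
  expect_equal(dim(m), c(81, 81))
  expect_equal(window_average(f, 0, 0), f$activity[, , tuning_grid()$t == 0])
  # linear-in-t anchors over a symmetric window equal the midpoint slice
  avl <- outer(rep(1, 8), tuning_grid()$t / 100)
  fl <- build_tuning_field(lay, avl)
  expect_equal(window_average(fl, -100, 100),
               fl$activity[, , tuning_grid()$t == 0])
  expect_error(window_average(f, 500, 600), "empty")
})

test_that("similarity index matches hand-computed values and invariances", {
  m <- matrix(c(1, 3, 2, 4), 2)  # column-major: [[1,2],[3,4]]
  s <- similarity_index(m, m)
  expect_equal(s$si, 1)
  expect_equal(s$pearson_r, 1)
  # anti-correlated z-maps: numerator is 2 ||z(R)||_F
  s2 <- similarity_index(m, -m)
  expect_equal(s2$si, 0)
  expect_equal(s2$pearson_r, -1)
  # hand-expanded arithmetic oracle for R = [[1,2],[3,4]], I = [[1,2],[4,3]]
  R <- c(1, 3, 2, 4); I <- c(1, 4, 2, 3)
  zr <- (R - mean(R)) / sd(R); zi <- (I - mean(I)) / sd(I)
  si_hand <- 1 - sqrt(sum((zr - zi)^2)) /
    (sqrt(sum(zr^2)) + sqrt(sum(zi^2)))
  s3 <- similarity_index(matrix(R, 2), matrix(I, 2))
  expect_equal(s3$si, si_hand)
  expect_equal(s3$si, 1 - sqrt((1 - cor(R, I)) / 2))
  # invariance under positive affine rescaling, and symmetry
  set.seed(5)
  a <- matrix(rnorm(64), 8); b <- matrix(rnorm(64), 8)
  s_ab <- similarity_index(a, b)
  s_resc <- similarity_index(3.2 * a + 7, 0.4 * b - 2)
  expect_equal(s_ab$si, s_resc$si)
  expect_equal(s_ab$pearson_r, s_resc$pearson_r)
  s_ba <- similarity_index(b, a)
  expect_equal(s_ab$si, s_ba$si)
  expect_true(similarity_index(matrix(2, 8, 8), a)$degenerate)
  # center-only variant keeps amplitude sensitivity
  expect_lt(similarity_index(a, 5 * a, method = "center_only")$si, 1)
  expect_equal(similarity_index(a, 5 * a)$si, 1)
})

test_that("subpopulation selection uses strict thresholds", {
  tbl <- data.frame(
    neuron_id = c("a", "b", "c", "d"),
    pearson_r = c(0.6, 0.6, 0.5, NA),
    si = c(0.4, 0.2, 0.3, 0.5))
  expect_identical(select_subpopulation(tbl), "a")
})
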