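test_that("a lone DMU is its own frontier", {
  p <- panel_1x1(3, 5)
  r <- dea_efficiency(p, rts = "vrs")
  expect_equal(r$theta, 1)
  expect_equal(r$validity, "valid")
  expect_equal(r$slack_x, 0)
  expect_equal(r$total_slack_x, 0)
})

test_that("scores match the worked single-ratio and convex-hull examples", {
  # CRS: A(2,2), B(4,2) -> theta_B = 0.5
  p <- panel_1x1(c(2, 4), c(2, 2))
  r <- dea_efficiency(p, rts = "crs")
  expect_equal(r$theta, c(1, 0.5), tolerance = 1e-9)

  # VRS: A(2,1), B(4,3), C(6,3) -> theta_C = 2/3
  p2 <- panel_1x1(c(2, 4, 6), c(1, 3, 3))
  r2 <- dea_efficiency(p2, rts = "vrs")
  expect_equal(r2$theta[3], 2 / 3, tolerance = 1e-9)

  # decomposition of the CRS example: B has TE 0.5, PTE 0.5, SE 1
  d <- dea_decompose(p)
  expect_equal(d$TE[2], 0.5, tolerance = 1e-9)
  expect_equal(d$PTE[2], 0.5, tolerance = 1e-9)
  expect_equal(d$SE[2], 1, tolerance = 1e-9)
})

test_that("identical DMUs all sit on the frontier with TE = PTE = SE = 1", {
  p <- dmu_panel(data.frame(unit = letters[1:4], period = "t1",
                            x1 = 2, x2 = 3, y1 = 5),
                 inputs = c("x1", "x2"), outputs = "y1")
  d <- dea_decompose(p)
  expect_equal(d$TE, rep(1, 4), tolerance = 1e-9)
  expect_equal(d$PTE, rep(1, 4), tolerance = 1e-9)
  expect_equal(d$SE, rep(1, 4), tolerance = 1e-9)
})

test_that("validity follows the score/slack classification rules", {
  expect_equal(classify_validity(1, c(0, 0), 0), "valid")
  expect_equal(classify_validity(1, c(0.3, 0), 0), "weakly_valid")
  expect_equal(classify_validity(0.87, c(0, 0), 0), "invalid")
  expect_equal(classify_validity(1 - 1e-9, c(0, 0), 0), "valid")

  # constructed weakly-valid DMU: B matches A's output but wastes input 2
  p <- dmu_panel(data.frame(unit = c("A", "B"), period = "t1",
                            x1 = c(1, 1), x2 = c(1, 2), y = c(1, 1)),
                 inputs = c("x1", "x2"), outputs = "y")
  r <- dea_efficiency(p, rts = "vrs")
  expect_equal(r$theta[2], 1, tolerance = 1e-9)
  expect_equal(r$validity[2], "weakly_valid")
  expect_equal(r$slack_x2[2], 1, tolerance = 1e-9)
})

test_that("total slack equals x - X lambda and (1 - theta) x + s_in", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    d <- data.frame(unit = sprintf("d%d", 1:n), period = "t1",
                    x1 = runif(n, 1, 10), x2 = runif(n, 5, 50),
                    y1 = runif(n, 1, 10), y2 = runif(n, 2, 20))
    p <- dmu_panel(d, inputs = c("x1", "x2"), outputs = c("y1", "y2"))
    r <- dea_efficiency(p, rts = "vrs")
    X <- t(as.matrix(d[, c("x1", "x2")]))
    for (j in seq_len(n)) {
      lam <- r$lambda[[j]]
      ref <- drop(X %*% lam)
      expect_equal(c(r$total_slack_x1[j], r$total_slack_x2[j]),
                   unname(X[, j] - ref), tolerance = 1e-7)
      expect_equal(c(r$total_slack_x1[j], r$total_slack_x2[j]),
                   unname((1 - r$theta[j]) * X[, j] +
                            c(r$slack_x1[j], r$slack_x2[j])),
                   tolerance = 1e-7)
    }
    expect_equal(total_slack(0.5, 4, 0), 2)
    expect_equal(total_slack(1, c(3, 7), c(0, 0)), c(0, 0))
  }
})

test_that("scores are invariant to rescaling any input or output column", {
  set.seed(42)
  d <- data.frame(unit = sprintf("d%d", 1:8), period = "t1",
                  x1 = runif(8, 1, 10), x2 = runif(8, 1, 10),
                  y1 = runif(8, 1, 10))
  p <- dmu_panel(d, inputs = c("x1", "x2"), outputs = "y1")
  d2 <- d; d2$x2 <- d2$x2 * 1000
  d3 <- d; d3$y1 <- d3$y1 * 1e-3
  p2 <- dmu_panel(d2, inputs = c("x1", "x2"), outputs = "y1")
  p3 <- dmu_panel(d3, inputs = c("x1", "x2"), outputs = "y1")
  for (rts in c("crs", "vrs")) {
    t0 <- dea_efficiency(p, rts = rts)$theta
    expect_equal(dea_efficiency(p2, rts = rts)$theta, t0, tolerance = 1e-9)
    expect_equal(dea_efficiency(p3, rts = rts)$theta, t0, tolerance = 1e-9)
  }
})

test_that("adding a weakly dominated DMU never raises an incumbent's score", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    x <- runif(n, 1, 10); y <- runif(n, 1, 10)
    j <- sample(n, 1)
    # dominated: more input, less output than DMU j
    xd <- x[j] * runif(1, 1.01, 1.5)
    yd <- y[j] * runif(1, 0.5, 0.99)
    for (rts in c("crs", "vrs")) {
      t0 <- dea_efficiency(panel_1x1(x, y), rts = rts)$theta
      t1 <- dea_efficiency(panel_1x1(c(x, xd), c(y, yd)), rts = rts)$theta
      expect_true(all(t1[seq_len(n)] <= t0 + 1e-9))
    }
  }
})

test_that("each period is enveloped as its own cross-section", {
  set.seed(44)
  d1 <- data.frame(unit = sprintf("d%d", 1:5), period = "t1",
                   x = runif(5, 1, 10), y = runif(5, 1, 10))
  d2 <- data.frame(unit = sprintf("d%d", 1:5), period = "t2",
                   x = runif(5, 1, 10), y = runif(5, 1, 10))
  pool <- dmu_panel(rbind(d1, d2), inputs = "x", outputs = "y")
  r <- dea_efficiency(pool, rts = "vrs")
  r1 <- dea_efficiency(dmu_panel(d1, "x", "y"), rts = "vrs")
  r2 <- dea_efficiency(dmu_panel(d2, "x", "y"), rts = "vrs")
  expect_equal(r$theta[r$period == "t1"], r1$theta, tolerance = 1e-10)
  expect_equal(r$theta[r$period == "t2"], r2$theta, tolerance = 1e-10)
})

test_that("the epsilon and two-phase formulations agree on the score", {
  set.seed(45)
  for (rep in 1:15) {
    p <- rand_panel_1x1(sample(3:6, 1))
    for (rts in c("crs", "vrs")) {
      a <- dea_efficiency(p, rts = rts, config = dea_config("two_phase"))
      b <- dea_efficiency(p, rts = rts,
                          config = dea_config("epsilon", epsilon = 1e-6))
      expect_equal(a$theta, b$theta, tolerance = 1e-8)
    }
  }
})
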