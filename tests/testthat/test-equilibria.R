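test_that("nullcline minimum matches the calculus oracle", {
  # min over R1 of V/R1 + (beta - w) R1 - (1 + B_G - alpha), attained at
  # R1 = sqrt(V / (beta - w)) when beta > w
  p <- lddm_params(alpha = 15, beta = 2.5)
  nc <- nullcline_r(1, seq(0.5, 100, by = 0.001), c(250, 250), p,
                    gain_matrix(2))
  expect_equal(min(nc$r_other), 2 * sqrt(250 * 1.5) + 14, tolerance = 1e-4)
})

test_that("at beta = w the nullcline is a shifted hyperbola", {
  p <- lddm_params(alpha = 15, beta = 1)
  grid <- c(0.5, 1, 5, 20, 80)
  nc <- nullcline_r(1, grid, c(250, 250), p, gain_matrix(2))
  expect_equal(nc$r_other, 250 / grid - (1 - 15), tolerance = 1e-12)
})

test_that("without disinhibition the nullclines cross exactly once", {
  p <- lddm_params(alpha = 15, beta = 0, b_r = 70)
  eq <- find_equilibria(c(250, 250), p, gain_matrix(2), beta_now = 0)
  expect_equal(unname(eq$counts["n_equilibria"]), 1)
  expect_equal(unname(eq$counts["n_stable"]), 1)
})

test_that("equilibrium sets match the closed-form reduction on random draws", {
  set.seed(314)
  om <- gain_matrix(2)
  n_checked <- 0
  for (i in 1:200) {
    alpha <- runif(1, 0, 30)
    beta <- runif(1, 0, 3)
    V <- runif(1, 50, 500)
    # skip degenerate bands where a root sits on the scan-box edge
    oracle <- oracle_equilibria(alpha, beta, V)
    if (any(vapply(oracle, max, 0) > 9e3) ||
        any(vapply(oracle, min, 0) < 2e-3)) next
    p <- lddm_params(alpha = alpha, beta = beta)
    eq <- find_equilibria(rep(V, 2), p, om, beta_now = beta,
                          box = c(1e-3, 1e4))
    expect_equal(unname(eq$counts["n_equilibria"]), length(oracle),
                 info = sprintf("alpha=%.3f beta=%.3f V=%.1f", alpha,
                                beta, V))
    for (pt in eq$points) {
      dists <- vapply(oracle, function(o) max(abs(o - pt$R)), 0)
      expect_lt(min(dists), 1e-5)
    }
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
})

test_that("returned equilibria satisfy the steady-state residual bound", {
  p <- lddm_params(alpha = 15, beta = 0.9)
  eq <- find_equilibria(c(250, 250), p, gain_matrix(2))
  expect_true(all(vapply(eq$points, function(x) x$residual, 0) < 1e-8))
})

test_that("printed phase-plane equilibria are recovered", {
  p <- lddm_params(alpha = 15, beta = 0.9)
  om <- gain_matrix(2)
  eq <- find_equilibria(c(250, 250), p, om)
  expect_equal(unname(eq$counts), c(3, 2, 1, 0))
  Rs <- t(vapply(eq$points, function(x) sort(x$R), numeric(2)))
  sym <- which(abs(Rs[, 1] - Rs[, 2]) < 1e-6)
  expect_equal(Rs[sym, 1], 250 / 11, tolerance = 1e-6)
  expect_equal(vapply(eq$points, function(x) x$stability, "")[sym],
               "unstable")
  asym <- setdiff(seq_len(3), sym)
  expect_equal(sort(Rs[asym[1], ]),
               sort(oracle_asym_roots(15, 0.9, 250)[[1]]),
               tolerance = 1e-4)
})

test_that("extreme disinhibition leaves no equilibria", {
  p <- lddm_params(alpha = 15, beta = 2.5)
  eq <- find_equilibria(c(250, 250), p, gain_matrix(2),
                        box = c(1e-3, 1e4))
  expect_equal(unname(eq$counts["n_equilibria"]), 0)
})

test_that("the analytic Jacobian matches finite differences", {
  p <- lddm_params(alpha = 15, beta = 0.9, b_r = 12, b_g = 4)
  om <- gain_matrix(2, w = 1.3, v = 0.8)
  R <- c(23.7, 11.2)
  V <- c(260, 180)
  J <- lddm_jacobian(R, V, p, om)
  Jfd <- fd_jacobian(R, V, p, om, p$beta)
  expect_equal(J, Jfd, tolerance = 1e-5)
  expect_error(lddm_jacobian(c(0, 5), V, p, om), "positive")
})

test_that("stability flips between representation and choice regimes", {
  om <- gain_matrix(2)
  # representation: unique equilibrium is attracting
  p0 <- lddm_params(alpha = 15, beta = 0, b_r = 70)
  pt <- find_equilibria(c(250, 250), p0, om, beta_now = 0)$points[[1]]
  expect_equal(pt$stability, "stable")
  # choice: symmetric point at (250/11, 250/11) is repelling
  p9 <- lddm_params(alpha = 15, beta = 0.9)
  r <- 250 / 11
  ev <- eigen(lddm_jacobian(c(r, r), c(250, 250), p9, om),
              only.values = TRUE)$values
  expect_gt(max(Re(ev)), 0)
})

test_that("representative points map onto the five territories", {
  expect_equal(classify_regime(15, 0.9)$territory, "blue")
  expect_equal(classify_regime(15, 0.9)$func, "WTA")
  expect_equal(classify_regime(5, 0)$territory, "dark_green")
  expect_equal(classify_regime(5, 0)$func, "normalization")
  expect_equal(classify_regime(15, 2.5)$territory, "red")
  expect_equal(classify_regime(15, 1.5)$territory, "yellow")
  expect_equal(classify_regime(0.3, 1.02)$territory, "green")
  expect_equal(classify_regime(0.3, 1.02)$func, "normalization")
})

test_that("raising disinhibition at high recurrence crosses blue, yellow, red", {
  labs <- vapply(c(0.7, 0.9, 1.2, 1.7, 2.2, 2.6), function(b)
    classify_regime(15, b)$territory, "")
  runs <- rle(labs)$values
  expect_equal(runs, c("blue", "yellow", "red"))
})

test_that("a regime map labels every cell and finds multiple territories", {
  map <- regime_map(c(2, 10, 20), c(0.2, 0.9, 1.5, 2.6))
  expect_equal(nrow(map), 12)
  expect_true(all(map$territory %in% c("dark_green", "blue", "green",
                                       "yellow", "red", "unclassified")))
  expect_gt(length(unique(map$territory)), 2)
  # the winner-take-all region always needs positive disinhibition
  expect_true(all(map$territory[map$beta == 0.2 & map$alpha <= 10] ==
                    "dark_green"))
})

test_that("no-input fixed points follow the linear case analysis", {
  om <- gain_matrix(2)
  line <- persistent_equilibria(lddm_params(alpha = 15), om, 0)
  expect_equal(line$type, "line")
  expect_equal(line$sum_R, 14)
  none <- persistent_equilibria(lddm_params(alpha = 1), om, 0)
  expect_equal(none$type, "none")
  pt <- persistent_equilibria(lddm_params(alpha = 10),
                              gain_matrix(2, w = 1, v = 0.7), 0)
  expect_equal(pt$type, "point")
  expect_equal(pt$point_R, 9 / 1.7)
  wta <- persistent_equilibria(lddm_params(alpha = 15), om, 0.4)
  expect_equal(wta$type, "corner_wta")
  expect_equal(wta$winner_R, 14 / 0.6)
  unb <- persistent_equilibria(lddm_params(alpha = 15), om, 1.5)
  expect_equal(unb$winner_R, Inf)
  expect_error(persistent_equilibria(lddm_params(),
                                     gain_matrix(2, w = 0, v = 0)),
               "degenerate")
})

test_that("per-unit persistent share scales as 1/N at constant sum", {
  for (n in c(2, 5)) {
    om <- gain_matrix(n)
    pe <- persistent_equilibria(lddm_params(alpha = 15), om, 0)
    expect_equal(pe$sum_R, 14)
    expect_equal(pe$point_R, 14 / n)
  }
})

test_that("simulation probes recover line, point, corner and none", {
  om <- gain_matrix(2)
  p15 <- lddm_params(alpha = 15)
  expect_equal(attractor_type(p15, om, 0)$type, "line")
  expect_equal(attractor_type(p15, om, 0.4)$type, "corner_wta")
  expect_equal(attractor_type(lddm_params(alpha = 10),
                              gain_matrix(2, w = 1, v = 0.7), 0)$type,
               "point")
  expect_equal(attractor_type(lddm_params(alpha = 1), om, 0)$type, "none")
})

test_that("line-attractor endpoints conserve the sum and the start ratio", {
  at <- attractor_type(lddm_params(alpha = 15), gain_matrix(2), 0,
                       ratios = c(0.5, 1.5, 3))
  sums <- rowSums(at$endpoints)
  expect_lt(diff(range(sums)) / max(sums), 1e-3)
  expect_equal(sums[1], 14, tolerance = 1e-3)
  ratios_end <- at$endpoints[, 1] / at$endpoints[, 2]
  expect_equal(ratios_end, c(0.5, 1.5, 3), tolerance = 1e-3)
})
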