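test_that("parameter containers validate their invariants", {
  expect_error(lddm_params(tau_r = 0), "time constants")
  expect_error(lddm_params(sigma = -1), ">= 0")
  expect_error(gain_matrix(1), ">= 2")
  expect_error(gain_matrix(2, w = -1), ">= 0")
  om <- gain_matrix(3, w = 2, v = 0.5)
  expect_equal(diag(om$omega), rep(2, 3))
  expect_equal(om$omega[1, 2], 0.5)
  expect_error(motif_flags(eta = -1))
})

test_that("the origin is an equilibrium when all inputs vanish", {
  p <- lddm_params(alpha = 15, beta = 0.9, b_r = 0, b_g = 0)
  st <- circuit_state(c(0, 0), c(0, 0), c(0, 0))
  d <- lddm_derivs(st, c(0, 0), p, gain_matrix(2))
  expect_equal(c(d$R, d$G, d$D), rep(0, 6))
})

test_that("the symmetric closed-form fixed point zeroes the field", {
  # r solves 2 r^2 - 14 r - 250 = 0 at alpha = 15, beta = 0, V = 250
  r <- (14 + sqrt(2196)) / 4
  p <- lddm_params(alpha = 15, beta = 0)
  st <- circuit_state(c(r, r), c(2 * r, 2 * r), c(0, 0))
  d <- lddm_derivs(st, c(250, 250), p, gain_matrix(2), beta_now = 0)
  expect_lt(max(abs(c(d$R, d$G, d$D))), 1e-6)
})

test_that("with disinhibition on, the symmetric point is repelling", {
  p <- lddm_params(alpha = 15, beta = 0.9)
  r <- oracle_sym_root(15, 0.9, 250)
  J <- lddm_jacobian(c(r, r), c(250, 250), p, gain_matrix(2))
  expect_gt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
})

test_that("derivative functions reject malformed inputs", {
  p <- lddm_params()
  st <- circuit_state(c(1, 1), c(0, 0), c(0, 0))
  expect_error(lddm_derivs(st, c(1, 2, 3), p, gain_matrix(2)), "length")
  expect_error(lddm_derivs(st, c(-1, 1), p, gain_matrix(2)),
               "non-negative")
  expect_error(lddm_derivs(st, c(1, 1), p, gain_matrix(3)), "mismatch")
})

test_that("the motif field reduces exactly to the circuit field", {
  p <- lddm_params(alpha = 15, beta = 0.9, b_r = 5, b_g = 3)
  om <- gain_matrix(2)
  fl <- motif_flags(TRUE, TRUE, FALSE, FALSE)
  set.seed(42)
  for (i in 1:100) {
    st <- circuit_state(runif(2, 0, 60), runif(2, 0, 60), runif(2, 0, 30),
                        c(0, 0), c(0, 0))
    V <- runif(2, 0, 400)
    a <- lddm_derivs(st, V, p, om)
    b <- motif_derivs(st, V, p, om, fl)
    expect_equal(c(a$R, a$G, a$D), c(b$R, b$G, b$D), tolerance = 1e-12)
  }
})

test_that("with every loop removed the motif field is the normalization field", {
  p <- lddm_params(alpha = 0, beta = 0, b_r = 0, b_g = 0)
  om <- gain_matrix(2)
  fl <- motif_flags(FALSE, FALSE, FALSE, FALSE)
  st <- circuit_state(c(10, 20), c(5, 8), c(0, 0), c(0, 0), c(0, 0))
  a <- motif_derivs(st, c(100, 80), p, om, fl)
  b <- dnm_derivs(st, c(100, 80), p, om)
  expect_equal(a$R, b$R)
  expect_equal(a$G, b$G)
})

test_that("the four loop switches enumerate sixteen distinct variants", {
  motifs <- enumerate_motifs()
  expect_length(motifs, 16)
  keys <- vapply(motifs, function(m)
    paste(m$self_excitation, m$local_disinhibition, m$cross_inhibition,
          m$lateral_boost), "")
  expect_length(unique(keys), 16)
})

test_that("a normalization equilibrium zeroes the DNM field", {
  # R* solving R_i = V_i / (1 + sum R) for V = (100, 100)
  tot <- (-1 + sqrt(1 + 4 * 200)) / 2
  R <- c(100, 100) / (1 + tot)
  st <- circuit_state(R, c(sum(R), sum(R)))
  d <- dnm_derivs(st, c(100, 100), lddm_params(alpha = 0, beta = 0),
                  gain_matrix(2))
  expect_lt(max(abs(c(d$R, d$G))), 1e-10)
})

test_that("reduced recurrent network transfer handles its singularity", {
  p <- rnm_params()
  expect_equal(rnm_transfer(p$b / p$a, p), 1 / p$d, tolerance = 1e-7)
  # smooth across the singularity
  x <- seq(p$b / p$a - 1e-4, p$b / p$a + 1e-4, length.out = 11)
  expect_true(all(diff(rnm_transfer(x, p)) > 0))
  # with zero coupling and input, S decays
  d <- rnm_derivs(c(0.3, 0.3), c(0, 0),
                  rnm_params(jn_same = 1e-9, jn_diff = 1e-9, i0 = 0.1))
  expect_true(all(d$dS < 0))
})

test_that("leaky accumulator converges to rho / k without competition", {
  p <- lca_params(k = 1, beta_inh = 0, sigma = 0, thresh = 10)
  x <- c(0, 0)
  for (i in 1:20000) x <- pmax(x + 0.001 * lca_derivs(x, c(1, 1), p), 0)
  expect_equal(x, c(1, 1), tolerance = 1e-6)
})

test_that("stronger accumulator input wins deterministically", {
  d <- simulate_rt_trials(lca_params(k = 0.5, beta_inh = 2, sigma = 0,
                                     thresh = 1),
                          0.512, 5, seed = 1, model = "lca")
  expect_true(all(d$choice == 1))
  expect_equal(length(unique(d$rt_s)), 1)
})

test_that("OU noise decays deterministically at zero amplitude", {
  n <- 5
  x <- rep(3, n)
  for (i in 1:100) x <- ou_noise_step(x, 1e-3, 0, 2e-3)
  expect_equal(x, rep(3, n) * (1 - 0.5)^100)
})

test_that("OU noise is zero-mean with stationary SD sigma/sqrt(2)", {
  set.seed(7)
  dt <- 1e-4
  sig <- 3
  n <- 0
  path <- numeric(150000)
  for (i in seq_along(path)) {
    n <- ou_noise_step(n, dt, sig, 2e-3)
    path[i] <- n
  }
  stat <- path[-(1:1000)]
  expect_lt(abs(mean(stat)), 3 * sd(stat) / sqrt(length(stat) * dt / 2e-3))
  expect_equal(sd(stat), sig / sqrt(2), tolerance = 0.05)
})

test_that("a state started on an attracting equilibrium stays there", {
  p <- lddm_params(alpha = 15, beta = 0, b_r = 70)
  om <- gain_matrix(2)
  eq <- find_equilibria(c(250, 250), p, om, beta_now = 0)
  pt <- eq$points[[1]]
  proto <- stimulus_protocol(2, list(list(duration = 1, V = c(250, 250),
                                          beta_on = FALSE)))
  tr <- simulate_circuit(p, om, proto,
                         init = circuit_state(pt$R, pt$G, pt$D))
  expect_lt(max(abs(sweep(tr$R, 2, pt$R))), 1e-6)
})

test_that("halving the step leaves a noiseless endpoint unchanged to 1e-6", {
  p <- lddm_params(alpha = 15, beta = 0, b_r = 70)
  om <- gain_matrix(2)
  proto <- stimulus_protocol(2, list(list(duration = 1, V = c(250, 250),
                                          beta_on = FALSE)))
  a <- simulate_circuit(p, om, proto, dt = 1e-3)
  b <- simulate_circuit(p, om, proto, dt = 5e-4)
  expect_lt(max(abs(a$R[nrow(a$R), ] - b$R[nrow(b$R), ])), 1e-6)
})

test_that("stimulus onset produces a transient peak then a lower plateau", {
  ps <- protocol_preset("fig3")
  tr <- simulate_circuit(ps$params, ps$omega, ps$protocol)
  r1 <- tr$R[, 1]
  i_peak <- which.max(r1)
  expect_lt(tr$time[i_peak], 0.2)
  expect_gt(max(r1), 1.5 * r1[length(r1)])
  # plateau matches the closed-form symmetric root with B_R = 70
  expect_equal(r1[length(r1)], oracle_sym_root(15, 0, 250, b_r = 70),
               tolerance = 1e-4)
})

test_that("trajectories are non-negative and reproducible under a seed", {
  p <- lddm_params(alpha = 15, beta = 1.1, sigma = 10)
  om <- gain_matrix(2)
  proto <- make_protocol("rt_motion", coherence = 0.064, decision_dur = 1)
  a <- simulate_circuit(p, om, proto, seed = 99)
  b <- simulate_circuit(p, om, proto, seed = 99)
  expect_identical(a$R, b$R)
  expect_true(all(a$R >= 0 & a$G >= 0 & a$D >= 0))
  c2 <- simulate_circuit(p, om, proto, seed = 100)
  expect_false(identical(a$R, c2$R))
})

test_that("trajectories export to CSV with one column per unit", {
  ps <- protocol_preset("fig3")
  tr <- simulate_circuit(ps$params, ps$omega, ps$protocol)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  d <- utils::read.csv(path)
  expect_named(d, c("t", "R1", "R2", "G1", "G2", "D1", "D2"))
  expect_equal(nrow(d), length(tr$time))
})
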