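# Independent closed-form oracles for the two-alternative circuit with
# uniform gain weight w = v = 1.  Derived by eliminating G and D from the
# steady-state conditions, independent of the package's numeric scan path.

# Symmetric equilibrium r = R1 = R2 solves (2 - beta) r^2 + (1 + B_G -
# alpha) r - (V + B_R) = 0; returns the positive root or NULL.
oracle_sym_root <- function(alpha, beta, V, b_r = 0, b_g = 0) {
  a2 <- 2 - beta
  b1 <- 1 + b_g - alpha
  c0 <- -(V + b_r)
  if (abs(a2) < 1e-12) {
    if (abs(b1) < 1e-12) return(NULL)
    r <- -c0 / b1
    return(if (r > 0) r else NULL)
  }
  disc <- b1^2 - 4 * a2 * c0
  if (disc < 0) return(NULL)
  roots <- (-b1 + c(1, -1) * sqrt(disc)) / (2 * a2)
  roots <- roots[roots > 0]
  if (length(roots) == 0) NULL else max(roots)
}

# Asymmetric equilibria satisfy R1 R2 = (V + B_R) / beta together with
# (1 - beta) R1^2 + (1 + B_G - alpha) R1 - (V + B_R)(1 - 1/beta) = 0;
# returns a list of (R1, R2) pairs (both orderings) or an empty list.
oracle_asym_roots <- function(alpha, beta, V, b_r = 0, b_g = 0) {
  if (beta <= 0) return(list())
  a2 <- 1 - beta
  b1 <- 1 + b_g - alpha
  c0 <- -(V + b_r) * (1 - 1 / beta)
  if (abs(a2) < 1e-12) return(list())
  disc <- b1^2 - 4 * a2 * c0
  if (disc <= 0) return(list())
  r1 <- (-b1 + c(1, -1) * sqrt(disc)) / (2 * a2)
  r1 <- r1[r1 > 0]
  out <- list()
  for (r in r1) {
    r2 <- (V + b_r) / (beta * r)
    if (r2 > 0 && abs(r - r2) > 1e-9) out <- c(out, list(c(r, r2)))
  }
  out
}

# Full oracle equilibrium set (list of R vectors, deduplicated).
oracle_equilibria <- function(alpha, beta, V, b_r = 0, b_g = 0) {
  out <- list()
  s <- oracle_sym_root(alpha, beta, V, b_r, b_g)
  if (!is.null(s)) out <- c(out, list(c(s, s)))
  out <- c(out, oracle_asym_roots(alpha, beta, V, b_r, b_g))
  out
}

# Central finite-difference Jacobian of the full 3N field.
fd_jacobian <- function(R_star, V, params, omega, beta_now, h = 1e-6) {
  n <- length(R_star)
  D <- beta_now * R_star
  G <- as.numeric(omega$omega %*% R_star) + params$b_g - D
  y0 <- c(R_star, G, D)
  fl <- function(y) {
    st <- circuit_state(y[1:n], y[(n + 1):(2 * n)], y[(2 * n + 1):(3 * n)])
    d <- lddm_derivs(st, V, params, omega, beta_now)
    c(d$R, d$G, d$D)
  }
  J <- matrix(0, 3 * n, 3 * n)
  for (j in seq_len(3 * n)) {
    e <- rep(0, 3 * n); e[j] <- h
    J[, j] <- (fl(y0 + e) - fl(y0 - e)) / (2 * h)
  }
  J
}

# Equilibrium-consistency residual of a trajectory endpoint.
endpoint_residual <- function(traj, V, params, omega, beta_now) {
  i <- nrow(traj$R)
  st <- circuit_state(traj$R[i, ], traj$G[i, ], traj$D[i, ])
  d <- lddm_derivs(st, V, params, omega, beta_now)
  max(abs(c(d$R, d$G, d$D)))
}
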