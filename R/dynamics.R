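#' Circuit state
#'
#' Holds the instantaneous activities of the rate units.  `R` are the
#' option-selective excitatory units (Hz), `G` the gain-control units, `D`
#' the disinhibitory units; `I` and `E` only exist in the generalized motif
#' model.
#'
#' @param R,G,D,I,E Numeric activity vectors, one entry per option.
#' @return An object of class `circuit_state`.
#' @export
circuit_state <- function(R, G = rep(0, length(R)), D = rep(0, length(R)),
                          I = NULL, E = NULL) {
  n <- length(R)
  if (length(G) != n || length(D) != n)
    stop("R, G and D must have equal length")
  if (!is.null(I) && length(I) != n) stop("I must match length of R")
  if (!is.null(E) && length(E) != n) stop("E must match length of R")
  structure(list(R = as.numeric(R), G = as.numeric(G), D = as.numeric(D),
                 I = if (!is.null(I)) as.numeric(I),
                 E = if (!is.null(E)) as.numeric(E)),
            class = "circuit_state")
}

check_inputs <- function(V, n) {
  if (length(V) != n) stop("input vector V has length ", length(V),
                           " but the state has ", n, " options")
  if (any(V < 0)) stop("inputs V must be non-negative")
  invisible(TRUE)
}

#' Time derivatives of the local-disinhibition circuit
#'
#' The three-population field: excitatory units are divisively normalized by
#' their gain-control unit, gain-control units pool excitatory activity and
#' are suppressed by their local disinhibitory unit, and disinhibitory units
#' are driven by their local excitatory unit with the gated weight
#' `beta_now`.
#'
#' @param state A [circuit_state()] with `R`, `G`, `D`.
#' @param V Non-negative input vector (one value per option).
#' @param params [lddm_params()].
#' @param omega [gain_matrix()].
#' @param beta_now Effective disinhibition weight at this instant (defaults
#'   to `params$beta`; protocols pass 0 while the gate is off).
#' @return A `circuit_state` of derivatives (Hz/s).
#' @export
lddm_derivs <- function(state, V, params, omega, beta_now = params$beta) {
  n <- length(state$R)
  check_inputs(V, n)
  if (omega$n_options != n) stop("gain matrix dimension mismatch")
  dR <- (-state$R + (V + params$alpha * state$R + params$b_r) /
           (1 + state$G)) / params$tau_r
  dG <- (-state$G + as.numeric(omega$omega %*% state$R) + params$b_g -
           state$D) / params$tau_g
  dD <- (-state$D + beta_now * state$R) / params$tau_d
  circuit_state(dR, dG, dD)
}

#' Time derivatives of the dynamic normalization circuit
#'
#' The normalization backbone without recurrence or disinhibition: paired
#' excitatory and gain-control units only.
#'
#' @inheritParams lddm_derivs
#' @return A `circuit_state` of derivatives (`D` slot is zero).
#' @export
dnm_derivs <- function(state, V, params, omega) {
  n <- length(state$R)
  check_inputs(V, n)
  if (omega$n_options != n) stop("gain matrix dimension mismatch")
  dR <- (-state$R + (V + params$b_r) / (1 + state$G)) / params$tau_r
  dG <- (-state$G + as.numeric(omega$omega %*% state$R)) / params$tau_g
  circuit_state(dR, dG, rep(0, n))
}

#' Time derivatives of the generalized motif model
#'
#' Augments the normalization backbone with up to four loops controlled by
#' [motif_flags()]: recurrent self-excitation, local disinhibition, cross
#' inhibition via `I` units (each `I_i` follows its own `R_i` and subtracts
#' from the *other* options' excitatory drive), and a lateral gain-control
#' boost via `E` units (each `E_i` follows the other options' `R` and adds
#' to its own `G_i`).  With only the first two loops active the field
#' reduces exactly to [lddm_derivs()].
#'
#' @inheritParams lddm_derivs
#' @param flags A [motif_flags()] object.
#' @return A `circuit_state` of derivatives with `I` and `E` slots.
#' @export
motif_derivs <- function(state, V, params, omega, flags,
                         beta_now = params$beta) {
  n <- length(state$R)
  check_inputs(V, n)
  I <- if (is.null(state$I)) rep(0, n) else state$I
  E <- if (is.null(state$E)) rep(0, n) else state$E
  a <- if (flags$self_excitation) params$alpha else 0
  b <- if (flags$local_disinhibition) beta_now else 0
  eta <- if (flags$cross_inhibition) flags$eta else 0
  gam <- if (flags$lateral_boost) flags$gamma_lat else 0
  tau_i <- if (is.null(flags$tau_i)) params$tau_g else flags$tau_i
  tau_e <- if (is.null(flags$tau_e)) params$tau_g else flags$tau_e
  cross_I <- sum(I) - I      # inhibition from the other options' I units
  lateral_R <- sum(state$R) - state$R
  dR <- (-state$R + (V + a * state$R + params$b_r - cross_I) /
           (1 + state$G)) / params$tau_r
  dG <- (-state$G + as.numeric(omega$omega %*% state$R) + E + params$b_g -
           state$D) / params$tau_g
  dD <- (-state$D + b * state$R) / params$tau_d
  dI <- (-I + eta * state$R) / tau_i
  dE <- (-E + gam * lateral_R) / tau_e
  circuit_state(dR, dG, dD, dI, dE)
}

#' Transfer function of the reduced recurrent network
#'
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))` with the removable
#' singularity `H = 1/d` at `a x = b`.
#'
#' @param x Input current (nA).
#' @param params [rnm_params()] supplying `a`, `b`, `d`.
#' @return Firing rate (Hz).
#' @export
rnm_transfer <- function(x, params = rnm_params()) {
  u <- params$a * x - params$b
  h <- ifelse(abs(params$d * u) < 1e-9,
              1 / params$d + u / 2,
              u / (1 - exp(-params$d * u)))
  pmax(h, 0)
}

#' Time derivatives of the reduced recurrent network model
#'
#' Mean-field reduction to one synaptic gating variable per population:
#' `dS/dt = -S/tau_s + (1 - S) gamma_kin H(x)`, with input current
#' `x_i = jn_same S_i - jn_diff sum_{j != i} S_j + i0 + inputs_i`.
#'
#' @param S Vector of gating variables in `[0, 1]`.
#' @param inputs Vector of selective input currents (nA), e.g.
#'   `jaext * mu0 * (1 +/- cprime)`.
#' @param params [rnm_params()].
#' @return List with `dS` (1/s), currents `x` and rates `H` (Hz).
#' @export
rnm_derivs <- function(S, inputs, params) {
  if (length(inputs) != length(S)) stop("dimension mismatch")
  x <- params$jn_same * S - params$jn_diff * (sum(S) - S) + params$i0 +
    inputs
  H <- rnm_transfer(x, params)
  list(dS = -S / params$tau_s + (1 - S) * params$gamma_kin * H, x = x,
       H = H)
}

#' Time derivatives of the leaky competing accumulator (deterministic part)
#'
#' @param x Accumulator activities.
#' @param rho Input vector (conventionally `1 +/- cprime`).
#' @param params [lca_params()].
#' @return Derivative vector `(rho - k x - beta_inh sum_others) / tau`.
#' @export
lca_derivs <- function(x, rho, params) {
  if (length(rho) != length(x)) stop("dimension mismatch")
  (rho - params$k * x - params$beta_inh * (sum(x) - x)) / params$tau
}

#' One Euler-Maruyama step of the Ornstein-Uhlenbeck noise process
#'
#' `n <- n + (dt / tau_noise) * (-n) + sigma * sqrt(dt / tau_noise) * eta`
#' with `eta` standard normal, applied elementwise.  As `dt / tau_noise -> 0`
#' the stationary SD approaches `sigma / sqrt(2)`.
#'
#' @param noise Numeric vector of current noise states.
#' @param dt Time step (s).
#' @param sigma Noise amplitude.
#' @param tau_noise Noise time constant (s).
#' @return Updated noise vector.
#' @export
ou_noise_step <- function(noise, dt, sigma, tau_noise) {
  if (dt <= 0) stop("dt must be > 0")
  k <- dt / tau_noise
  noise - k * noise + sigma * sqrt(k) * stats::rnorm(length(noise))
}

# Internal flat-vector derivative closures used by the integrator.  Layout:
# lddm/dnm use y = c(R, G, D); motif adds I and E blocks.
deriv_flat <- function(model, params, omega, flags = NULL) {
  n <- omega$n_options
  om <- omega$omega
  switch(model,
    lddm = function(y, V, beta_now, nz) {
      R <- y[1:n]; G <- y[(n + 1):(2 * n)]; D <- y[(2 * n + 1):(3 * n)]
      c((-R + (V + params$alpha * R + params$b_r) / (1 + G) +
           nz[1:n]) / params$tau_r,
        (-G + as.numeric(om %*% R) + params$b_g - D +
           nz[(n + 1):(2 * n)]) / params$tau_g,
        (-D + beta_now * R + nz[(2 * n + 1):(3 * n)]) / params$tau_d)
    },
    dnm = function(y, V, beta_now, nz) {
      R <- y[1:n]; G <- y[(n + 1):(2 * n)]
      c((-R + (V + params$b_r) / (1 + G) + nz[1:n]) / params$tau_r,
        (-G + as.numeric(om %*% R) + nz[(n + 1):(2 * n)]) / params$tau_g,
        rep(0, n))
    },
    motif = {
      tau_i <- if (is.null(flags$tau_i)) params$tau_g else flags$tau_i
      tau_e <- if (is.null(flags$tau_e)) params$tau_g else flags$tau_e
      a <- if (flags$self_excitation) params$alpha else 0
      eta <- if (flags$cross_inhibition) flags$eta else 0
      gam <- if (flags$lateral_boost) flags$gamma_lat else 0
      use_b <- flags$local_disinhibition
      function(y, V, beta_now, nz) {
        R <- y[1:n]; G <- y[(n + 1):(2 * n)]; D <- y[(2 * n + 1):(3 * n)]
        I <- y[(3 * n + 1):(4 * n)]; E <- y[(4 * n + 1):(5 * n)]
        b <- if (use_b) beta_now else 0
        c((-R + (V + a * R + params$b_r - (sum(I) - I)) / (1 + G) +
             nz[1:n]) / params$tau_r,
          (-G + as.numeric(om %*% R) + E + params$b_g - D +
             nz[(n + 1):(2 * n)]) / params$tau_g,
          (-D + b * R + nz[(2 * n + 1):(3 * n)]) / params$tau_d,
          (-I + eta * R) / tau_i,
          (-E + gam * (sum(R) - R)) / tau_e)
      }
    },
    stop("unknown model '", model, "'"))
}

#' Integrate a circuit model over a stimulus protocol
#'
#' Fixed-step fourth-order Runge-Kutta with each unit receiving an additive
#' Ornstein-Uhlenbeck noise current, held constant within a step and updated
#' after it; activities are clamped at zero after each full step.  Identical
#' seeds give bit-identical trajectories.
#'
#' @param params [lddm_params()].
#' @param omega [gain_matrix()].
#' @param protocol A [stimulus_protocol()] defining piecewise-constant
#'   inputs `V(t)` and the disinhibition gate.
#' @param model One of `"lddm"`, `"dnm"`, `"motif"`.
#' @param flags [motif_flags()], required for `model = "motif"`.
#' @param dt Time step (s); default 0.001.
#' @param seed Optional integer seed for the noise stream.
#' @param init Initial [circuit_state()], or `NULL` for
#'   `R = 0, G = max(B_G, 0), D = 0`.
#' @param stop_tol If positive and the simulation is noiseless, integration
#'   of the final stage stops early once `max(abs(dy))` falls below this
#'   value (the state has reached an equilibrium); remaining samples repeat
#'   the steady state.
#' @return An object of class `lddm_trajectory`: time grid, one activity
#'   matrix per unit type, and stage-boundary event markers.
#' @export
simulate_circuit <- function(params, omega, protocol, model = "lddm",
                             flags = NULL, dt = 0.001, seed = NULL,
                             init = NULL, stop_tol = 0) {
  if (dt <= 0) stop("dt must be > 0")
  if (model == "motif" && is.null(flags))
    stop("'flags' is required for the motif model")
  n <- omega$n_options
  if (protocol$n_options != n) stop("protocol/gain-matrix dimension mismatch")
  if (!is.null(seed)) set.seed(seed)
  nblk <- if (model == "motif") 5L else 3L
  if (is.null(init))
    init <- circuit_state(rep(0, n), rep(max(params$b_g, 0), n), rep(0, n))
  y <- c(init$R, init$G, init$D)
  if (model == "motif")
    y <- c(y, if (is.null(init$I)) rep(0, n) else init$I,
           if (is.null(init$E)) rep(0, n) else init$E)
  f <- deriv_flat(model, params, omega, flags)
  stages <- protocol$stages
  n_steps_stage <- vapply(stages, function(s) round(s$duration / dt), 0)
  n_tot <- sum(n_steps_stage)
  Y <- matrix(NA_real_, n_tot + 1L, length(y))
  Y[1L, ] <- y
  nz <- rep(0, nblk * n)
  noisy <- params$sigma > 0
  k_noise <- dt / params$tau_noise
  amp <- params$sigma * sqrt(k_noise)
  row <- 1L
  t_off <- 0
  events <- data.frame(time = numeric(0), label = character(0))
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    events <- rbind(events, data.frame(time = t_off, label = st$label))
    V <- st$V
    beta_now <- if (st$beta_on) params$beta * st$beta_scale else 0
    for (s in seq_len(n_steps_stage[si])) {
      k1 <- f(y, V, beta_now, nz)
      k2 <- f(y + 0.5 * dt * k1, V, beta_now, nz)
      k3 <- f(y + 0.5 * dt * k2, V, beta_now, nz)
      k4 <- f(y + dt * k3, V, beta_now, nz)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y[y < 0] <- 0
      if (noisy)
        nz <- nz - k_noise * nz + amp * stats::rnorm(length(nz))
      row <- row + 1L
      Y[row, ] <- y
      if (!noisy && stop_tol > 0 && si == length(stages) &&
          max(abs(k1)) < stop_tol) {
        if (row <= n_tot) Y[(row + 1L):(n_tot + 1L), ] <-
            matrix(y, n_tot + 1L - row, length(y), byrow = TRUE)
        row <- n_tot + 1L
        break
      }
    }
    if (row == n_tot + 1L && si < length(stages)) break
    t_off <- t_off + n_steps_stage[si] * dt
  }
  if (anyNA(Y[n_tot + 1L, ])) Y <- Y[seq_len(row), , drop = FALSE]
  if (any(!is.finite(Y)))
    stop("integration diverged (non-finite state) at step ",
         which(rowSums(!is.finite(Y)) > 0)[1] - 1L)
  time <- seq(0, by = dt, length.out = nrow(Y))
  out <- list(time = time,
              R = Y[, 1:n, drop = FALSE],
              G = Y[, (n + 1):(2 * n), drop = FALSE],
              D = Y[, (2 * n + 1):(3 * n), drop = FALSE],
              I = if (nblk == 5L) Y[, (3 * n + 1):(4 * n), drop = FALSE],
              E = if (nblk == 5L) Y[, (4 * n + 1):(5 * n), drop = FALSE],
              dt = dt, n_options = n, model = model, events = events,
              params = params, omega = omega, protocol = protocol)
  class(out) <- "lddm_trajectory"
  out
}

#' @export
print.lddm_trajectory <- function(x, ...) {
  cat("<lddm_trajectory>", x$model, "model,", x$n_options, "options,",
      length(x$time), "samples, dt =", x$dt, "s\n")
  cat("stages:", paste(sprintf("%s@%gs", x$events$label, x$events$time),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.lddm_trajectory <- function(x, ...) {
  n <- x$n_options
  d <- data.frame(t = x$time)
  for (u in c("R", "G", "D", "I", "E")) {
    if (is.null(x[[u]])) next
    m <- x[[u]]
    colnames(m) <- paste0(u, seq_len(n))
    d <- cbind(d, m)
  }
  d
}

#' Write a trajectory to CSV
#'
#' Columns `t, R1..RN, G1..GN, D1..DN` (plus `I`/`E` for the motif model).
#'
#' @param traj An `lddm_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
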