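#' Circuit parameters for the local-disinhibition decision model
#'
#' Bundles the constants of the three-population rate circuit: excitatory
#' units `R` receive value input and recurrent self-excitation `alpha`,
#' gain-control units `G` divide the excitatory drive, and disinhibitory
#' units `D` release the local gain control with coupling `beta` (the value
#' used when the disinhibition gate is on; protocols switch the gate).
#'
#' @param alpha Recurrent self-excitation weight on `R` units (dimensionless).
#' @param beta Local disinhibition weight, the gated `R -> D` coupling
#'   (dimensionless); protocols decide when it is applied.
#' @param b_r Non-selective baseline input to `R` units (input units).
#' @param b_g Non-selective baseline input to `G` units.
#' @param sigma Ornstein-Uhlenbeck noise amplitude (model units); 0 disables
#'   noise.
#' @param tau_r,tau_g,tau_d Time constants of the `R`, `G` and `D` units (s).
#' @param tau_noise Noise time constant (s).
#' @param s_scale Input value scale: stimulus inputs are
#'   `s_scale * (1 + cprime)` for option 1 and `s_scale * (1 - cprime)` for
#'   the others.
#' @return An object of class `lddm_params` (a validated list).
#' @examples
#' p <- lddm_params(alpha = 15, beta = 0.9)
#' @export
lddm_params <- function(alpha = 15, beta = 1.1, b_r = 0, b_g = 0, sigma = 0,
                        tau_r = 0.1, tau_g = 0.1, tau_d = 0.1,
                        tau_noise = 0.002, s_scale = 250) {
  p <- list(alpha = alpha, beta = beta, b_r = b_r, b_g = b_g, sigma = sigma,
            tau_r = tau_r, tau_g = tau_g, tau_d = tau_d,
            tau_noise = tau_noise, s_scale = s_scale)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a finite numeric scalar")
  }
  if (any(unlist(p[c("tau_r", "tau_g", "tau_d", "tau_noise")]) <= 0))
    stop("all time constants must be > 0")
  if (any(unlist(p[c("alpha", "beta", "b_r", "b_g", "sigma")]) < 0))
    stop("alpha, beta, b_r, b_g and sigma must be >= 0")
  structure(p, class = "lddm_params")
}

#' Gain-control coupling matrix
#'
#' The `R -> G` coupling matrix omega with local weight `w` on the diagonal
#' and lateral weight `v` off the diagonal.  An arbitrary square matrix can
#' be supplied through `matrix`.
#'
#' @param n_options Number of choice alternatives (N >= 2).
#' @param w Local (diagonal) weight.
#' @param v Lateral (off-diagonal) weight.
#' @param matrix Optional full N x N matrix overriding `w`/`v`.
#' @return An object of class `gain_matrix` with fields `n_options`, `w`,
#'   `v` and `omega` (the full matrix).
#' @export
gain_matrix <- function(n_options = 2, w = 1, v = w, matrix = NULL) {
  if (!is.null(matrix)) {
    if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
      stop("'matrix' must be square")
    n_options <- nrow(matrix)
    om <- matrix
    w <- mean(diag(om))
    v <- if (n_options > 1) mean(om[row(om) != col(om)]) else w
  } else {
    if (n_options < 2) stop("'n_options' must be >= 2")
    if (w < 0 || v < 0) stop("'w' and 'v' must be >= 0")
    om <- base::matrix(v, n_options, n_options)
    diag(om) <- w
  }
  structure(list(n_options = n_options, w = w, v = v, omega = om),
            class = "gain_matrix")
}

#' Circuit-motif switches for the generalized model
#'
#' The generalized circuit augments the normalization backbone with four
#' optional loops: recurrent self-excitation (`alpha`), local disinhibition
#' (`beta`), cross inhibition through `I` units (weight `eta`) and a lateral
#' gain-control boost through `E` units (weight `gamma_lat`).  The four
#' on/off switches enumerate 2^4 = 16 model variants.
#'
#' @param self_excitation,local_disinhibition,cross_inhibition,lateral_boost
#'   Logical switches for the four loops.
#' @param eta Cross-inhibition weight (used when `cross_inhibition`).
#' @param gamma_lat Lateral-boost weight (used when `lateral_boost`).
#' @param tau_i,tau_e Time constants of the `I` and `E` interneurons (s);
#'   default `NULL` means "use the `G` time constant", as they play
#'   symmetric interneuron roles.
#' @return An object of class `motif_flags`.
#' @export
motif_flags <- function(self_excitation = TRUE, local_disinhibition = TRUE,
                        cross_inhibition = FALSE, lateral_boost = FALSE,
                        eta = 0, gamma_lat = 0, tau_i = NULL, tau_e = NULL) {
  if (eta < 0 || gamma_lat < 0) stop("'eta' and 'gamma_lat' must be >= 0")
  structure(list(self_excitation = isTRUE(self_excitation),
                 local_disinhibition = isTRUE(local_disinhibition),
                 cross_inhibition = isTRUE(cross_inhibition),
                 lateral_boost = isTRUE(lateral_boost),
                 eta = eta, gamma_lat = gamma_lat,
                 tau_i = tau_i, tau_e = tau_e),
            class = "motif_flags")
}

#' Enumerate the 16 motif variants
#'
#' @param eta,gamma_lat Weights attached to the cross-inhibition and
#'   lateral-boost loops when active.
#' @return A list of 16 `motif_flags` objects covering every on/off
#'   combination of the four loops.
#' @export
enumerate_motifs <- function(eta = 1, gamma_lat = 1) {
  grid <- expand.grid(se = c(FALSE, TRUE), ld = c(FALSE, TRUE),
                      ci = c(FALSE, TRUE), lb = c(FALSE, TRUE))
  lapply(seq_len(nrow(grid)), function(i)
    motif_flags(grid$se[i], grid$ld[i], grid$ci[i], grid$lb[i],
                eta = eta, gamma_lat = gamma_lat))
}

#' Parameters of the reduced two-variable recurrent network model
#'
#' The mean-field reduction of the recurrent attractor network: two synaptic
#' gating variables with an effective transfer function
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`.  The single-cell constants
#' `a`, `b`, `d` and the AMPA time constant are fixed at their standard
#' values; the remaining parameters are free when the model is fit.
#'
#' @param jn_same,jn_diff Self- and cross-population synaptic couplings (nA).
#' @param i0 Non-selective background current (nA).
#' @param mu0 Stimulus input scale (Hz); the effective current is
#'   `jaext * mu0 * (1 +/- cprime)`.
#' @param gamma_kin Synaptic kinetic rate (dimensionless factor on H).
#' @param s0 Initial value of the gating variables at stimulus onset.
#' @param tau_s NMDA gating time constant (s).
#' @param sigma_noise OU noise amplitude on the input currents (nA).
#' @param thresh Decision threshold on the population rate (Hz).
#' @param a,b,d,tau_ampa,jaext Fixed single-cell/input constants.
#' @return An object of class `rnm_params`.
#' @export
rnm_params <- function(jn_same = 0.2609, jn_diff = 0.0497, i0 = 0.3255,
                       mu0 = 30, gamma_kin = 0.641, s0 = 0.1, tau_s = 0.1,
                       sigma_noise = 0.02, thresh = 15,
                       a = 270, b = 108, d = 0.154, tau_ampa = 0.002,
                       jaext = 5.2e-4) {
  p <- list(jn_same = jn_same, jn_diff = jn_diff, i0 = i0, mu0 = mu0,
            gamma_kin = gamma_kin, s0 = s0, tau_s = tau_s,
            sigma_noise = sigma_noise, thresh = thresh, a = a, b = b, d = d,
            tau_ampa = tau_ampa, jaext = jaext)
  if (any(unlist(p[c("jn_same", "jn_diff", "mu0", "gamma_kin", "tau_s",
                     "thresh")]) <= 0) || sigma_noise < 0)
    stop("rnm parameters out of range")
  structure(p, class = "rnm_params")
}

#' Parameters of the leaky competing accumulator
#'
#' @param k Net leakage on each accumulator (after cancellation of recurrent
#'   excitation).
#' @param beta_inh Mutual inhibition weight.
#' @param sigma Noise SD (per sqrt of the tau-scaled time unit).
#' @param thresh Decision bound (arbitrary activity units).
#' @param tau Integration time constant (s); fixed by convention because it
#'   trades off against the threshold.
#' @param t0 Non-decision time (s), fixed.
#' @return An object of class `lca_params`.
#' @export
lca_params <- function(k = 1, beta_inh = 1.5, sigma = 0.3, thresh = 1,
                       tau = 0.1, t0 = 0.120) {
  p <- list(k = k, beta_inh = beta_inh, sigma = sigma, thresh = thresh,
            tau = tau, t0 = t0)
  if (any(unlist(p[c("k", "beta_inh", "sigma", "thresh")]) < 0) || tau <= 0)
    stop("lca parameters out of range")
  structure(p, class = "lca_params")
}
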