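#' Build a stimulus protocol from explicit stages
#'
#' A protocol is an ordered list of stages, each holding a duration (s), a
#' piecewise-constant input vector `V`, and the state of the disinhibition
#' gate.  `t_stim_onset` marks where reaction times are measured from and
#' `t_decision_start` where threshold crossings begin to count.
#'
#' @param n_options Number of alternatives.
#' @param stages List of stages; each a list with `duration`, `V`,
#'   `beta_on` (logical), optional `beta_scale` (multiplier on
#'   `params$beta`, default 1) and `label`.
#' @param coherence Stimulus coherence attached for bookkeeping.
#' @param t_stim_onset,t_decision_start Times (s) from protocol start.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(n_options, stages, coherence = NA_real_,
                              t_stim_onset = 0, t_decision_start = 0) {
  stages <- lapply(seq_along(stages), function(i) {
    s <- stages[[i]]
    if (is.null(s$beta_scale)) s$beta_scale <- 1
    if (is.null(s$label)) s$label <- paste0("stage", i)
    if (s$duration < 0) stop("stage durations must be >= 0")
    if (length(s$V) == 1) s$V <- rep(s$V, n_options)
    if (length(s$V) != n_options) stop("stage V has wrong length")
    if (any(s$V < 0)) stop("stage inputs must be non-negative")
    s
  })
  structure(list(n_options = n_options, stages = stages,
                 coherence = coherence, t_stim_onset = t_stim_onset,
                 t_decision_start = t_decision_start),
            class = "stimulus_protocol")
}

#' Build the stimulus/gating protocol for a task paradigm
#'
#' Input values follow the coherence rule `V_1 = S (1 + cprime)` and
#' `V_k = S (1 - cprime)` for the other options.  All paradigms measure
#' reaction time from stimulus onset; the reaction-time paradigm inserts a
#' gap (default 90 ms, zero input, gate off) at stimulus onset, after which
#' the stimulus appears together with the gate.
#'
#' @param paradigm One of `"representation"`, `"rt_motion"`,
#'   `"fixed_duration"`, `"delayed_response"`, `"multi_alternative"`,
#'   `"persistent"`.
#' @param coherence Stimulus coherence `cprime` in `[0, 1]`.
#' @param s_scale Input scale `S`.
#' @param n_options Number of alternatives (>= 2; `multi_alternative` is the
#'   same rule with `n_options > 2`).
#' @param premotion Duration of the equal-input target stage before stimulus
#'   onset (s).
#' @param gap Gap duration at stimulus onset (s), zero input and gate off.
#' @param stim_dur Stimulus duration for the non-reaction-time paradigms (s).
#' @param delay Delay duration for `delayed_response` (s).
#' @param decision_dur Duration of the gated decision stage (s).
#' @param gate_in_delay For `persistent`: gate state during the delay.
#' @return A [stimulus_protocol()].
#' @export
make_protocol <- function(paradigm = c("rt_motion", "representation",
                                       "fixed_duration", "delayed_response",
                                       "multi_alternative", "persistent"),
                          coherence = 0, s_scale = 250, n_options = 2,
                          premotion = 0, gap = 0.090, stim_dur = 1,
                          delay = 1, decision_dur = 5,
                          gate_in_delay = FALSE) {
  paradigm <- match.arg(paradigm)
  if (coherence < 0 || coherence > 1) stop("coherence must be in [0, 1]")
  if (n_options < 2) stop("n_options must be >= 2")
  V_stim <- s_scale * c(1 + coherence, rep(1 - coherence, n_options - 1))
  V_eq <- rep(s_scale, n_options)
  pre <- if (premotion > 0)
    list(list(duration = premotion, V = V_eq, beta_on = FALSE,
              label = "premotion"))
  gap_stage <- list(duration = gap, V = rep(0, n_options), beta_on = FALSE,
                    label = "gap")
  switch(paradigm,
    representation = stimulus_protocol(
      n_options,
      c(pre, list(list(duration = stim_dur, V = V_stim, beta_on = FALSE,
                       label = "stimulus"))),
      coherence, t_stim_onset = premotion, t_decision_start = Inf),
    rt_motion = ,
    multi_alternative = stimulus_protocol(
      n_options,
      c(pre, list(gap_stage,
                  list(duration = decision_dur, V = V_stim, beta_on = TRUE,
                       label = "motion"))),
      coherence, t_stim_onset = premotion,
      t_decision_start = premotion + gap),
    fixed_duration = stimulus_protocol(
      n_options,
      c(pre, list(gap_stage,
                  list(duration = stim_dur, V = V_stim, beta_on = FALSE,
                       label = "stimulus"),
                  list(duration = decision_dur, V = V_stim, beta_on = TRUE,
                       label = "cue"))),
      coherence, t_stim_onset = premotion,
      t_decision_start = premotion + gap + stim_dur),
    delayed_response = stimulus_protocol(
      n_options,
      c(pre, list(gap_stage,
                  list(duration = stim_dur, V = V_stim, beta_on = FALSE,
                       label = "stimulus"),
                  list(duration = delay, V = rep(0, n_options),
                       beta_on = FALSE, label = "delay"),
                  list(duration = decision_dur, V = rep(0, n_options),
                       beta_on = TRUE, label = "cue"))),
      coherence, t_stim_onset = premotion,
      t_decision_start = premotion + gap + stim_dur + delay),
    persistent = stimulus_protocol(
      n_options,
      c(pre, list(list(duration = stim_dur, V = V_stim, beta_on = FALSE,
                       label = "stimulus"),
                  list(duration = delay, V = rep(0, n_options),
                       beta_on = gate_in_delay, label = "delay"))),
      coherence, t_stim_onset = premotion, t_decision_start = Inf))
}

#' Named presets reproducing the published parameterizations
#'
#' Each preset bundles circuit parameters, a gain matrix and a protocol for
#' one of the illustrated simulations: `fig3` (normalized representation),
#' `fig5` (reaction-time winner-take-all), `fig7_2alt`/`fig7_4alt`
#' (multi-alternative choice with an initial input dip), `fig8_2item`/
#' `fig8_5item` (persistent activity), `fig9a`/`fig9b`/`fig9c`
#' (reaction-time, fixed-duration, delayed-response timing), `fig10_lddm`
#' and `fig10_rnm` (inhibitory potentiation contrasts).
#'
#' @param name Preset name.
#' @param coherence Stimulus coherence where applicable.
#' @param gate_in_delay For the persistent-activity presets.
#' @return List with elements `params`, `omega`, `protocol` (and for
#'   `fig10_rnm`, `rnm` parameters instead of circuit parameters).
#' @export
protocol_preset <- function(name, coherence = 0.128,
                            gate_in_delay = FALSE) {
  tau100 <- list(tau_r = 0.1, tau_g = 0.1, tau_d = 0.1)
  mk <- function(...) do.call(lddm_params, c(list(...), tau100))
  switch(name,
    fig3 = list(
      params = mk(alpha = 15, beta = 0, b_r = 70, s_scale = 250),
      omega = gain_matrix(2),
      protocol = make_protocol("representation", coherence = 0,
                               s_scale = 250, premotion = 0, stim_dur = 1.5)),
    fig5 = list(
      params = mk(alpha = 15, beta = 0.9, b_r = 0, s_scale = 250),
      omega = gain_matrix(2),
      protocol = make_protocol("rt_motion", coherence = coherence,
                               s_scale = 250, premotion = 0.5)),
    fig7_2alt = ,
    fig7_4alt = {
      n <- if (name == "fig7_2alt") 2L else 4L
      S <- 640
      dipV <- 427 * c(1 + coherence, rep(1 - coherence, n - 1))
      mainV <- S * c(1 + coherence, rep(1 - coherence, n - 1))
      list(params = mk(alpha = 0, beta = 1.5, s_scale = S),
           omega = gain_matrix(n),
           protocol = stimulus_protocol(
             n,
             list(list(duration = 0.75, V = rep(S, n), beta_on = FALSE,
                       label = "premotion"),
                  list(duration = 0.190, V = dipV, beta_on = TRUE,
                       label = "motion_dip"),
                  list(duration = 2, V = mainV, beta_on = TRUE,
                       label = "motion")),
             coherence, t_stim_onset = 0.75, t_decision_start = 0.75))
    },
    fig8_2item = list(
      params = mk(alpha = 15, beta = 0.4, s_scale = 250),
      omega = gain_matrix(2),
      protocol = make_protocol("persistent", coherence = coherence,
                               s_scale = 250, stim_dur = 1, delay = 3,
                               gate_in_delay = gate_in_delay)),
    fig8_5item = list(
      params = mk(alpha = 37.5, beta = 0.1, s_scale = 50),
      omega = gain_matrix(5),
      protocol = make_protocol("persistent", coherence = coherence,
                               s_scale = 50, n_options = 5, stim_dur = 1,
                               delay = 3, gate_in_delay = gate_in_delay)),
    fig9a = list(
      params = mk(alpha = 15, beta = 1.1, s_scale = 250),
      omega = gain_matrix(2),
      protocol = make_protocol("rt_motion", coherence = coherence,
                               premotion = 0.5)),
    fig9b = list(
      params = mk(alpha = 15, beta = 1.1, s_scale = 250),
      omega = gain_matrix(2),
      protocol = make_protocol("fixed_duration", coherence = coherence,
                               premotion = 0.5, stim_dur = 1)),
    fig9c = list(
      params = mk(alpha = 15, beta = 1.1, s_scale = 250),
      omega = gain_matrix(2),
      protocol = make_protocol("delayed_response", coherence = coherence,
                               premotion = 0.5, stim_dur = 1, delay = 1)),
    fig10_lddm = list(
      params = mk(alpha = 10, beta = 1.1, sigma = 2, s_scale = 256),
      omega = gain_matrix(2),
      protocol = make_protocol("rt_motion", coherence = coherence,
                               s_scale = 256)),
    fig10_rnm = list(
      rnm = rnm_params(),
      protocol = make_protocol("rt_motion", coherence = coherence)),
    stop("unknown preset '", name, "'"))
}

#' Convert a trajectory into a trial outcome
#'
#' The first excitatory unit whose activity reaches the threshold (resolved
#' to the first grid step at or above it, no interpolation) wins; the
#' reported reaction time is the crossing time relative to stimulus onset
#' plus a motor delay.  Crossings are only counted from the protocol's
#' decision stage onward.
#'
#' @param traj An `lddm_trajectory`.
#' @param threshold Decision threshold (Hz), default 70.
#' @param motor_delay Motor (post-threshold) delay added to RT (s).
#' @return List of class `trial_outcome` with `choice` (option index or
#'   `NA`), `rt` (s, `NA` if censored), `correct` (`TRUE` for option 1 when
#'   coherence > 0; `NA` at zero coherence or when censored) and `crossed`.
#' @export
detect_decision <- function(traj, threshold = 70, motor_delay = 0.030) {
  proto <- traj$protocol
  from <- proto$t_decision_start
  idx <- which(traj$time >= from)
  choice <- NA_integer_
  rt <- NA_real_
  crossed <- FALSE
  if (length(idx) > 0 && is.finite(from)) {
    Rm <- traj$R[idx, , drop = FALSE]
    hit <- which(apply(Rm >= threshold, 1, any))
    if (length(hit) > 0) {
      row <- idx[hit[1]]
      choice <- which.max(traj$R[row, ])
      rt <- traj$time[row] - proto$t_stim_onset + motor_delay
      crossed <- TRUE
    }
  }
  correct <- if (!crossed || is.na(proto$coherence) ||
                 proto$coherence == 0) NA else choice == 1L
  structure(list(choice = choice, rt = rt, correct = correct,
                 crossed = crossed, threshold = threshold),
            class = "trial_outcome")
}

#' Least-squares ramping rate of each unit over a time window
#'
#' @param traj An `lddm_trajectory`.
#' @param window Length-2 numeric, start and end time (s).
#' @param units Unit type to slope (default `"R"`).
#' @return Named vector of slopes (Hz/s), one per option.
#' @export
ramping_rate <- function(traj, window, units = "R") {
  if (window[1] < traj$time[1] || window[2] > traj$time[length(traj$time)])
    stop("window outside trajectory")
  sel <- traj$time >= window[1] & traj$time <= window[2]
  tt <- traj$time[sel]
  m <- traj[[units]][sel, , drop = FALSE]
  slopes <- apply(m, 2, function(y) stats::coef(stats::lm.fit(
    cbind(1, tt), y))[2])
  names(slopes) <- paste0(units, seq_along(slopes))
  slopes
}

#' Potentiate the inhibitory projections
#'
#' Scales the synaptic output of the inhibitory populations by a common
#' factor (emulating, e.g., a GABAergic agonist).  For the disinhibition
#' circuit the inhibitory synapses are the divisive `G -> R` gain and the
#' `D -> G` suppression; rescaling both is algebraically identical (via the
#' substitution `G -> factor * G`, `D -> factor^2 * D`) to scaling the gain
#' weights `omega` and the baseline `B_G` by the factor and the
#' disinhibition weight `beta` by the factor squared — which is how it is
#' applied here, so every analysis function remains valid on the
#' potentiated circuit.  Potentiation therefore suppresses activity during
#' representation but strengthens the disinhibitory release during choice,
#' speeding decisions at the cost of accuracy.  (Scaling only the
#' excitatory `R -> G` drive would instead lower the winner-take-all
#' activity ceiling below any realistic decision threshold and abolish
#' choices.)  For the reduced recurrent network the cross-population
#' coupling is scaled.
#'
#' @param x An [lddm_params()] (potentiated together with `omega`) or
#'   [rnm_params()].
#' @param factor Potentiation factor (1 = control).
#' @param omega [gain_matrix()], required for the circuit model.
#' @return For the circuit model a list with modified `params` and `omega`;
#'   for the recurrent network the modified parameter object.
#' @export
inhibitory_potentiation <- function(x, factor, omega = NULL) {
  if (factor < 0) stop("potentiation factor must be >= 0")
  if (inherits(x, "lddm_params")) {
    if (is.null(omega)) stop("omega is required for the circuit model")
    x$beta <- x$beta * factor^2
    x$b_g <- x$b_g * factor
    list(params = x, omega = gain_matrix(matrix = omega$omega * factor))
  } else if (inherits(x, "rnm_params")) {
    x$jn_diff <- x$jn_diff * factor
    x
  } else stop("x must be lddm_params or rnm_params")
}
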