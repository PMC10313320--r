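#' Simulate trial-level choice and reaction-time data
#'
#' Monte Carlo trials of a reaction-time protocol: a 90-ms gap (zero input,
#' gate off) at stimulus onset, then stimulus inputs `S (1 +/- cprime)` with
#' the disinhibition gate on, a fixed decision threshold on the excitatory
#' rates, and a motor delay added to the crossing time.  The excitatory
#' units start at `r0` (default 32 Hz) with the gain-control units at their
#' instantaneous equilibrium for that level.  The comparison models follow
#' their own conventions: the reduced recurrent network starts its gating
#' variables at `s0` and crosses on the population rate; the leaky
#' competing accumulator starts at zero with inputs `1 +/- cprime` and adds
#' its fixed non-decision time.
#'
#' @param params [lddm_params()], [rnm_params()] or [lca_params()], matching
#'   `model`.
#' @param coherences Vector of coherence levels.
#' @param n_reps Trials per coherence.
#' @param seed Integer seed (one stream across the whole batch).
#' @param model `"lddm"`, `"rnm"` or `"lca"`.
#' @param omega [gain_matrix()] for the circuit model.
#' @param threshold Decision threshold (Hz) for the circuit model.
#' @param gap Gap duration (s).
#' @param fixdur Fixed stimulus-viewing duration (s) with the gate off,
#'   inserted between the gap and the gated decision stage; 0 gives the
#'   reaction-time protocol, a positive value the fixed-duration protocol
#'   (the circuit settles onto its stimulus-driven normalization equilibrium
#'   before the gate opens).
#' @param motor_delay Motor delay (s).
#' @param cutoff Decision-stage cutoff (s); trials that never cross are
#'   returned censored.
#' @param r0 Initial excitatory rate (Hz).
#' @param g0_matched Start `G` at its instantaneous equilibrium for `r0`
#'   (recommended); `FALSE` starts `G = 0`.
#' @param dt Step (s).
#' @return Data frame with columns `trial`, `coherence`, `choice` (0 =
#'   censored), `correct`, `rt_s` (`NA` when censored), `censored`.
#' @export
simulate_rt_trials <- function(params, coherences, n_reps, seed = 1,
                               model = "lddm", omega = gain_matrix(2),
                               threshold = 70, gap = 0.090, fixdur = 0,
                               motor_delay = 0.030, cutoff = 5, r0 = 32,
                               g0_matched = TRUE, dt = 0.001) {
  seeds <- (as.numeric(seed) * 1000003 + 7919 * seq_along(coherences)) %%
    2147483647
  res <- lapply(seq_along(coherences), function(ci) {
    cp <- coherences[ci]
    cseed <- as.integer(seeds[ci])
    m <- switch(model,
      lddm = {
        V <- params$s_scale * c(1 + cp, 1 - cp)
        out <- cpp_lddm_trials(n_reps, V[1], V[2], params$alpha,
                               params$beta, params$b_r, params$b_g,
                               params$sigma, params$tau_r, params$tau_g,
                               params$tau_d, params$tau_noise, omega$w,
                               omega$v, dt, gap, fixdur, threshold, cutoff,
                               r0, g0_matched, cseed)
        out[, 1] <- out[, 1] + motor_delay
        out
      },
      rnm = {
        out <- cpp_rnm_trials(n_reps, cp, params$jn_same, params$jn_diff,
                              params$i0, params$sigma_noise,
                              params$jaext * params$mu0, params$gamma_kin,
                              params$s0, params$tau_s, params$a, params$b,
                              params$d, params$tau_ampa, dt, params$thresh,
                              cutoff, cseed)
        out[, 1] <- out[, 1] + gap + motor_delay
        out
      },
      lca = {
        out <- cpp_lca_trials(n_reps, 1 + cp, 1 - cp, params$k,
                              params$beta_inh, params$sigma, params$thresh,
                              params$tau, dt, cutoff, cseed)
        out[, 1] <- out[, 1] + params$t0
        out
      },
      stop("unknown model '", model, "'"))
    data.frame(trial = seq_len(n_reps), coherence = cp,
               choice = as.integer(m[, 2]),
               correct = m[, 2] == 1, rt_s = m[, 1],
               censored = m[, 2] == 0)
  })
  out <- do.call(rbind, res)
  out$correct[out$censored] <- NA
  rownames(out) <- NULL
  out
}

#' Empirical quantile binning of an RT dataset
#'
#' Per (coherence x correctness) cell: the empirical RT quantile edges
#' (type-7 interpolation) and the observed trial count per bin.  Nine
#' quantiles give ten bins whose counts sum to the cell count.
#'
#' @param data Data frame with `coherence`, `correct`, `rt_s` (decided
#'   trials only).
#' @param probs Quantile probabilities, default `seq(0.1, 0.9, 0.1)`.
#' @param warn Warn about empty cells.
#' @return Object of class `quantile_binning`.
#' @export
quantile_binning <- function(data, probs = seq(0.1, 0.9, 0.1),
                             warn = TRUE) {
  data <- data[!is.na(data$rt_s), , drop = FALSE]
  cohs <- sort(unique(data$coherence))
  cells <- lapply(cohs, function(cp) {
    sub <- data[data$coherence == cp, ]
    per_side <- lapply(c(TRUE, FALSE), function(side) {
      rts <- sub$rt_s[sub$correct == side & !is.na(sub$correct)]
      if (length(rts) == 0) {
        if (warn) warning("empty ", if (side) "correct" else "error",
                          " cell at coherence ", cp)
        return(NULL)
      }
      edges <- stats::quantile(rts, probs, type = 7, names = FALSE)
      counts <- tabulate(findInterval(rts, edges) + 1L,
                         nbins = length(probs) + 1L)
      list(edges = edges, counts = counts, n = length(rts))
    })
    names(per_side) <- c("correct", "error")
    list(coherence = cp, cells = per_side, n_total = nrow(sub))
  })
  structure(list(coherences = cohs, probs = probs, by_coherence = cells),
            class = "quantile_binning")
}

# Predicted per-bin probabilities for one coherence, jointly normalized over
# correct + error + censored mass.  pred is the cpp trial matrix (rt,
# choice); returns list(correct=, error=, censored=)
pred_bin_probs <- function(pred, binning_coh) {
  n_tot <- nrow(pred)
  sides <- list(correct = 1, error = 2)
  probs <- lapply(names(sides), function(s) {
    cell <- binning_coh$cells[[s]]
    if (is.null(cell)) return(NULL)
    rts <- pred[pred[, 2] == sides[[s]], 1]
    tabulate(findInterval(rts, cell$edges) + 1L,
             nbins = length(cell$edges) + 1L) / n_tot
  })
  names(probs) <- names(sides)
  probs$censored <- sum(pred[, 2] == 0) / n_tot
  probs
}

#' Quantile maximum likelihood: negative log-likelihood
#'
#' Multinomial likelihood of the observed per-bin trial counts under the
#' predicted bin probabilities, correct and error trials jointly normalized
#' at each coherence (so choice probability is implicitly fit), with
#' censored simulation mass absorbing the remainder.  Probabilities are
#' floored at `eps = 1/(10 n_pred)`.
#'
#' @param observed Data frame of decided trials (`coherence`, `correct`,
#'   `rt_s`), ignored if `binning` is given.
#' @param predicted Data frame from [simulate_rt_trials()] (may include
#'   censored trials).
#' @param probs Quantile probabilities.
#' @param binning Optional precomputed [quantile_binning()].
#' @return The negative log-likelihood (a scalar).
#' @export
qmle_nll <- function(observed, predicted, probs = seq(0.1, 0.9, 0.1),
                     binning = NULL) {
  if (is.null(binning)) binning <- quantile_binning(observed, probs)
  nll <- 0
  for (bc in binning$by_coherence) {
    pred <- predicted[predicted$coherence == bc$coherence, ]
    if (nrow(pred) == 0) stop("no predictions at coherence ", bc$coherence)
    pm <- cbind(pred$rt_s, ifelse(pred$censored, 0,
                                  ifelse(pred$correct, 1, 2)))
    eps <- 1 / (10 * nrow(pm))
    pp <- pred_bin_probs(pm, bc)
    for (s in c("correct", "error")) {
      cell <- bc$cells[[s]]
      if (is.null(cell)) next
      nll <- nll - sum(cell$counts * log(pmax(pp[[s]], eps)))
    }
  }
  nll
}

free_param_info <- function(model) {
  switch(model,
    lddm = list(
      names = c("alpha", "beta", "sigma", "s_scale", "tau_r", "tau_g",
                "tau_d"),
      lower = c(0, 0.01, 1, 100, 0.05, 0.05, 0.05),
      upper = c(30, 3, 80, 8000, 0.5, 0.5, 0.5)),
    rnm = list(
      names = c("jn_same", "jn_diff", "i0", "sigma_noise", "mu0",
                "gamma_kin", "s0", "tau_s"),
      lower = c(0.05, 5e-4, 0.1, 1e-3, 5, 0.1, 0.01, 0.03),
      upper = c(0.5, 0.3, 0.6, 0.1, 100, 2, 0.6, 0.3)),
    lca = list(
      names = c("k", "beta_inh", "sigma", "thresh"),
      lower = c(0, 0, 0.01, 0.1),
      upper = c(10, 10, 2, 10)),
    stop("unknown model '", model, "'"))
}

params_from_vector <- function(model, x) {
  switch(model,
    lddm = lddm_params(alpha = x[1], beta = x[2], sigma = x[3],
                       s_scale = x[4], tau_r = x[5], tau_g = x[6],
                       tau_d = x[7]),
    rnm = rnm_params(jn_same = x[1], jn_diff = x[2], i0 = x[3],
                     sigma_noise = x[4], mu0 = x[5], gamma_kin = x[6],
                     s0 = x[7], tau_s = x[8]),
    lca = lca_params(k = x[1], beta_inh = x[2], sigma = x[3],
                     thresh = x[4]))
}

# Pick one start per stratum: the strata tile the (possibly two)
# stratification coordinates; within each stratum the best screening value
# wins.  Falls back to global best-k for unused strata.
select_starts <- function(design, screen_val, n_starts, stratify_dims) {
  n <- nrow(design)
  if (is.null(stratify_dims))
    return(order(screen_val)[seq_len(min(n_starts, n))])
  d1 <- stratify_dims[1]
  n2 <- if (length(stratify_dims) > 1) 2L else 1L
  n1 <- max(1L, n_starts %/% n2)
  b1 <- pmin(floor(design[, d1] * n1) + 1L, n1)
  b2 <- if (n2 == 2L)
    ifelse(design[, stratify_dims[2]] < 0.5, 1L, 2L) else rep(1L, n)
  stratum <- (b1 - 1L) * n2 + b2
  picks <- integer(0)
  for (s in unique(sort(stratum))) {
    idx <- which(stratum == s)
    picks <- c(picks, idx[which.min(screen_val[idx])])
  }
  # top up or trim to n_starts by global ranking
  if (length(picks) < n_starts) {
    extra <- setdiff(order(screen_val), picks)
    picks <- c(picks, extra[seq_len(n_starts - length(picks))])
  }
  picks[seq_len(min(n_starts, length(picks)))]
}

#' Fit a decision model to choice/RT data by quantile maximum likelihood
#'
#' Simulation-based fitting: the objective is [qmle_nll()] of the observed
#' data against `n_reps` Monte Carlo trials per coherence, made exactly
#' deterministic by re-seeding the simulator identically at every
#' evaluation (common random numbers).  A Latin hypercube screen over the
#' parameter box supplies `n_starts` candidates; for the circuit model the
#' candidates are stratified over the recurrence weight and the gain-pool
#' time constant — the two coordinates along which the quantile-likelihood
#' surface is multimodal (recurrence trades off against disinhibition and
#' the time constants, producing near-degenerate competing modes) — so the
#' start set covers every mode's catchment.  Each start runs a coarse
#' Nelder-Mead at reduced replications with the recurrence weight frozen
#' at its start value (a conditional, better-conditioned search), then a
#' full-replication polish over all parameters; the winner gets a final
#' fresh-simplex restart.
#'
#' @param observed Data frame of decided trials (`coherence`, `correct`,
#'   `rt_s`).
#' @param model `"lddm"`, `"rnm"` or `"lca"`.
#' @param n_starts Local polish runs (default 8).
#' @param n_reps Simulated trials per coherence per evaluation
#'   (default 1024).
#' @param seed Master seed: controls the screening design and the common
#'   random numbers.
#' @param n_screen Latin hypercube screening evaluations (default
#'   `8 * n_starts`).
#' @param screen_reps Simulated trials per coherence during the screening
#'   and coarse-search phases (default `n_reps / 4`); the final polish runs
#'   at the full `n_reps`.
#' @param maxit Nelder-Mead evaluation cap for the full-replication polish
#'   of each start.
#' @param maxit_coarse Evaluation cap for the coarse Nelder-Mead phase run
#'   at `screen_reps` before each polish.
#' @param maxit_final Evaluation cap for the winner's fresh-simplex
#'   restart at full replications.
#' @param stratify_dims Parameter indices used to stratify the start set
#'   (default recurrence and gain time constant for the circuit model;
#'   `NULL` selects the `n_starts` best screen values instead).
#' @param bounds Optional list with `lower` and `upper` named vectors
#'   overriding the default parameter box.
#' @param probs Quantile probabilities for the binning.
#' @param ... Passed to [simulate_rt_trials()] (e.g. `threshold`, `cutoff`,
#'   `dt`).
#' @return Object of class `lddm_fit`: `par` (named vector), `params`
#'   (model parameter object), `nll`, `aic`, `k`, `n_starts`, `n_reps`,
#'   `seed`, `starts` (per-start diagnostics).
#' @export
fit_model <- function(observed, model = "lddm", n_starts = 8,
                      n_reps = 1024, seed = 1, n_screen = 24 * n_starts,
                      screen_reps = max(64, round(n_reps / 8)),
                      maxit = 80, maxit_coarse = 150, maxit_final = maxit,
                      stratify_dims = if (model == "lddm") c(1L, 6L),
                      bounds = NULL, probs = seq(0.1, 0.9, 0.1), ...) {
  info <- free_param_info(model)
  if (!is.null(bounds)) {
    info$lower[match(names(bounds$lower), info$names)] <- bounds$lower
    info$upper[match(names(bounds$upper), info$names)] <- bounds$upper
  }
  k <- length(info$names)
  binning <- quantile_binning(observed, probs, warn = TRUE)
  cohs <- binning$coherences
  crn_seed <- (seed * 7919L + 13L) %% .Machine$integer.max
  objective_at <- function(z, reps) {
    pen <- sum(pmax(z - 1, 0)^2 + pmax(-z, 0)^2)
    z <- pmin(pmax(z, 0), 1)
    x <- info$lower + z * (info$upper - info$lower)
    p <- params_from_vector(model, x)
    pred <- simulate_rt_trials(p, cohs, reps, seed = crn_seed,
                               model = model, ...)
    qmle_nll(NULL, pred, binning = binning) + 1e4 * pen
  }
  objective <- function(z) objective_at(z, n_reps)
  set.seed(seed)
  design <- lhs::randomLHS(n_screen, k)
  screen_val <- apply(design, 1, objective_at, reps = screen_reps)
  ord <- select_starts(design, screen_val, n_starts, stratify_dims)
  coarse_reps <- max(screen_reps, round(n_reps / 4))
  starts <- lapply(seq_along(ord), function(i) {
    z0 <- design[ord[i], ]
    freeze <- if (!is.null(stratify_dims)) stratify_dims[1]
    coarse <- if (!is.null(freeze)) {
      # conditional search: recurrence frozen at its start value
      o <- stats::optim(z0[-freeze], function(zf, reps) {
        z <- numeric(k); z[-freeze] <- zf; z[freeze] <- z0[freeze]
        objective_at(z, reps)
      }, reps = coarse_reps, method = "Nelder-Mead",
      control = list(maxit = maxit_coarse, reltol = 1e-8))
      z1 <- numeric(k); z1[-freeze] <- o$par; z1[freeze] <- z0[freeze]
      list(par = z1, value = o$value)
    } else {
      stats::optim(z0, objective_at, reps = coarse_reps,
                   method = "Nelder-Mead",
                   control = list(maxit = maxit_coarse, reltol = 1e-8))
    }
    opt <- stats::optim(coarse$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    list(start = i, value = opt$value, par_z = opt$par,
         convergence = opt$convergence, coarse_value = coarse$value,
         screen_value = screen_val[ord[i]])
  })
  vals <- vapply(starts, function(s) s$value, 0)
  best <- starts[[which.min(vals)]]
  # fresh-simplex restart of the winner
  fin <- stats::optim(best$par_z, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit_final, reltol = 1e-8))
  if (fin$value < best$value) {
    best$value <- fin$value
    best$par_z <- fin$par
    best$convergence <- fin$convergence
  }
  zb <- pmin(pmax(best$par_z, 0), 1)
  xb <- info$lower + zb * (info$upper - info$lower)
  names(xb) <- info$names
  nll <- best$value
  structure(list(model = model, par = xb,
                 params = params_from_vector(model, xb), nll = nll,
                 aic = 2 * k + 2 * nll, k = k, n_starts = n_starts,
                 n_reps = n_reps, seed = seed,
                 starts = data.frame(
                   start = seq_along(starts),
                   screen_value = vapply(starts, `[[`, 0, "screen_value"),
                   value = vals,
                   convergence = vapply(starts, `[[`, 0, "convergence"))),
            class = "lddm_fit")
}

#' @export
print.lddm_fit <- function(x, ...) {
  cat("<lddm_fit>", x$model, " nLL =", format(x$nll, digits = 6),
      " AIC =", format(x$aic, digits = 6), "\n")
  print(round(x$par, 4))
  invisible(x)
}

#' Psychometric, chronometric and quantile summaries of an RT dataset
#'
#' @param data Data frame with `coherence`, `correct`, `rt_s` (and
#'   optionally `censored`).
#' @param probs Quantile probabilities for the RT quantiles.
#' @return List with `psychometric` (coherence, n, accuracy),
#'   `chronometric` (coherence, mean/median RT by correctness),
#'   `quantiles` (long data frame coherence x correctness x prob) and
#'   `qp` (quantile-probability pairs).
#' @export
behavior_summaries <- function(data, probs = seq(0.1, 0.9, 0.1)) {
  dec <- data[!is.na(data$rt_s), , drop = FALSE]
  cohs <- sort(unique(data$coherence))
  psy <- do.call(rbind, lapply(cohs, function(cp) {
    sub <- data[data$coherence == cp, ]
    dd <- sub[!is.na(sub$correct), ]
    data.frame(coherence = cp, n = nrow(sub),
               n_censored = sum(is.na(sub$rt_s)),
               accuracy = if (nrow(dd)) mean(dd$correct) else NA_real_)
  }))
  chron <- do.call(rbind, lapply(cohs, function(cp) {
    sub <- dec[dec$coherence == cp & !is.na(dec$correct), ]
    do.call(rbind, lapply(c(TRUE, FALSE), function(side) {
      rts <- sub$rt_s[sub$correct == side]
      data.frame(coherence = cp, correct = side, n = length(rts),
                 mean_rt = if (length(rts)) mean(rts) else NA_real_,
                 median_rt = if (length(rts))
                   stats::median(rts) else NA_real_)
    }))
  }))
  quant <- do.call(rbind, lapply(cohs, function(cp) {
    sub <- dec[dec$coherence == cp & !is.na(dec$correct), ]
    do.call(rbind, lapply(c(TRUE, FALSE), function(side) {
      rts <- sub$rt_s[sub$correct == side]
      if (length(rts) == 0) return(NULL)
      data.frame(coherence = cp, correct = side, prob = probs,
                 rt_q = stats::quantile(rts, probs, type = 7,
                                        names = FALSE))
    }))
  }))
  qp <- if (!is.null(quant) && nrow(quant)) {
    acc <- psy$accuracy[match(quant$coherence, psy$coherence)]
    data.frame(quant,
               choice_prop = ifelse(quant$correct, acc, 1 - acc))
  } else NULL
  list(psychometric = psy, chronometric = chron, quantiles = quant,
       qp = qp)
}
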