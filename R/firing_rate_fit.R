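#' Equilibrium firing rates of the normalization circuits
#'
#' Steady-state rates for a single condition of the trinary
#' value-representation design.  With the disinhibition gate silent the
#' fixed point of the circuit satisfies, for every option,
#' `R_i (C + sum_j R_j) = Rmax (V_i + B_R)` where `C = 1` for the plain
#' normalization model and `C = 1 + B_G - alpha` for the disinhibition
#' circuit; summing over options gives a quadratic for the total, so the
#' solution is closed-form.  Only the combination `B_G - alpha` is
#' identifiable — the two constants enter through a single term.
#'
#' @param V Condition values (reward in microliters; omitted targets are 0
#'   and still contribute their unit to the sum).
#' @param model `"dnm"` or `"lddm"`.
#' @param b_r Baseline input.
#' @param rmax Arbitrary rate rescaling.
#' @param bg_minus_alpha The combined constant `B_G - alpha` (LDDM only).
#' @param alpha,b_g Alternative way to supply the combined constant; used
#'   only when `bg_minus_alpha` is `NULL`.
#' @return Vector of predicted rates, one per option.
#' @export
equilibrium_rates <- function(V, model = c("lddm", "dnm"), b_r = 0,
                              rmax = 1, bg_minus_alpha = NULL, alpha = 0,
                              b_g = 0) {
  model <- match.arg(model)
  if (any(V < 0)) stop("values must be non-negative")
  if (is.null(bg_minus_alpha)) bg_minus_alpha <- b_g - alpha
  C <- if (model == "dnm") 1 else 1 + bg_minus_alpha
  tot_in <- rmax * sum(V + b_r)
  T <- (-C + sqrt(C^2 + 4 * tot_in)) / 2
  R <- rmax * (V + b_r) / (C + T)
  resid <- R * (C + sum(R)) - rmax * (V + b_r)
  if (max(abs(resid)) > 1e-8 * max(1, tot_in))
    stop("no valid positive equilibrium for these parameters")
  R
}

#' Predicted rates of the recorded unit across a condition table
#'
#' @param conditions Data frame with columns `V1_ul`, `V2_ul`, `V3_ul`.
#' @inheritParams equilibrium_rates
#' @return Vector of predicted `R_1` rates, one per row.
#' @export
predict_norm_rates <- function(conditions, model = "lddm", b_r = 0,
                               rmax = 1, bg_minus_alpha = 0) {
  vapply(seq_len(nrow(conditions)), function(i)
    equilibrium_rates(as.numeric(conditions[i, c("V1_ul", "V2_ul",
                                                 "V3_ul")]),
                      model = model, b_r = b_r, rmax = rmax,
                      bg_minus_alpha = bg_minus_alpha)[1],
    0)
}

#' Steady-state rates of the trinary reduced recurrent network
#'
#' Expands the reduced two-population recurrent network to three selective
#' populations wired by the same rules (self coupling `jn_same`, cross
#' coupling `jn_diff`), integrates the noiseless system to steady state and
#' returns the population rates scaled by `rate_scale`.  Input currents are
#' `jaext * V_i` with `V_i` the condition values.
#'
#' @param V Condition values (microliters; omitted targets are 0).
#' @param jn_same,jn_diff,i0 Couplings and background current (nA).
#' @param rate_scale Output rate rescaling.
#' @param base [rnm_params()] supplying the fixed single-cell constants.
#' @param t_max Maximum integration time (s).
#' @param dt Step (s).
#' @return Vector of scaled steady rates (Hz), one per option.
#' @export
rnm_trinary_rates <- function(V, jn_same = 0.0055, jn_diff = 0.0861,
                              i0 = 0.3511, rate_scale = 1.074,
                              base = rnm_params(), t_max = 10,
                              dt = 0.001) {
  if (any(V < 0)) stop("values must be non-negative")
  out <- cpp_rnm_steady(base$jaext * V, jn_same, jn_diff, i0,
                        base$gamma_kin, base$s0, base$tau_s, base$a,
                        base$b, base$d, dt, t_max, 1e-9)
  n <- length(V)
  if (out[n + 1] != 1)
    stop("trinary network did not reach steady state within ", t_max, " s")
  rate_scale * out[seq_len(n)]
}

norm_fit_info <- function(model) {
  switch(model,
    dnm = list(names = c("b_r", "rmax"),
               lower = c(0, 1e-3), upper = c(500, 100),
               start = c(50, 1)),
    lddm = list(names = c("b_r", "rmax", "bg_minus_alpha"),
                lower = c(0, 1e-3, -20), upper = c(500, 100, 100),
                start = c(50, 1, 1)),
    rnm = list(names = c("jn_same", "jn_diff", "i0", "rate_scale"),
               lower = c(1e-4, 1e-4, 0.05, 1e-3),
               upper = c(0.4, 0.4, 0.6, 50),
               start = c(0.05, 0.05, 0.3, 1)),
    stop("unknown model '", model, "'"))
}

#' Fit equilibrium firing rates to a condition-mean dataset
#'
#' Ordinary least squares between the model's steady-state `R_1` rate and
#' the observed condition means, minimized by multi-start bounded
#' quasi-Newton optimization.
#'
#' @param data Data frame with `V1_ul`, `V2_ul`, `V3_ul`, `rate_hz`.
#' @param model `"dnm"` (2 free parameters), `"lddm"` (3) or `"rnm"` (4).
#' @param n_starts Number of optimization starts (Latin hypercube plus the
#'   default start).
#' @param seed Seed for the start design.
#' @return Object of class `norm_fit`: `par`, `sse`, `r2`, `model`,
#'   `fitted`, `n_starts`.
#' @export
fit_normalization <- function(data, model = c("lddm", "dnm", "rnm"),
                              n_starts = 10, seed = 1) {
  model <- match.arg(model)
  if (nrow(data) == 0) stop("empty dataset")
  info <- norm_fit_info(model)
  y <- data$rate_hz
  predfun <- function(x) {
    if (model == "rnm")
      vapply(seq_len(nrow(data)), function(i)
        rnm_trinary_rates(as.numeric(data[i, c("V1_ul", "V2_ul",
                                               "V3_ul")]),
                          jn_same = x[1], jn_diff = x[2], i0 = x[3],
                          rate_scale = x[4])[1], 0)
    else
      predict_norm_rates(data, model, b_r = x[1], rmax = x[2],
                         bg_minus_alpha = if (length(x) > 2) x[3] else 0)
  }
  sse_fun <- function(x) {
    p <- tryCatch(predfun(x), error = function(e) NULL)
    if (is.null(p) || any(!is.finite(p))) return(1e12)
    sum((y - p)^2)
  }
  set.seed(seed)
  k <- length(info$names)
  des <- lhs::randomLHS(max(n_starts - 1, 1), k)
  starts <- rbind(info$start,
                  t(info$lower + t(des) * (info$upper - info$lower)))
  fits <- lapply(seq_len(min(nrow(starts), n_starts)), function(i)
    tryCatch(stats::optim(starts[i, ], sse_fun, method = "L-BFGS-B",
                          lower = info$lower, upper = info$upper,
                          control = list(maxit = 500,
                                         parscale = pmax(abs(starts[i, ]),
                                                         1e-2))),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all optimization starts failed")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  par <- best$par
  names(par) <- info$names
  sse <- best$value
  sst <- sum((y - mean(y))^2)
  structure(list(model = model, par = par, sse = sse,
                 r2 = 1 - sse / sst, fitted = predfun(par),
                 n_starts = n_starts, seed = seed),
            class = "norm_fit")
}

#' @export
print.norm_fit <- function(x, ...) {
  cat("<norm_fit>", x$model, " SSE =", format(x$sse, digits = 6),
      " R^2 =", format(x$r2, digits = 4), "\n")
  print(round(x$par, 4))
  invisible(x)
}
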