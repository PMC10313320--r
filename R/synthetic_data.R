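#' Default coherence design of the motion-discrimination task
#'
#' @return The canonical coherence levels `c(0, .032, .064, .128, .256,
#'   .512)`.
#' @export
canonical_coherences <- function() c(0, 0.032, 0.064, 0.128, 0.256, 0.512)

#' Generator truth for reaction-time datasets
#'
#' The default parameter point for synthetic behavioral data.  `"best_fit"`
#' is the parameterization obtained when the circuit is fit to the classic
#' monkey motion-discrimination dataset; `"recovery"` is an interior point
#' of the parameter box with every parameter strictly positive, used for
#' recovery experiments where relative errors must be well defined
#' (recurrence is exactly zero in the best fit, so its relative recovery
#' error would be ill-posed there).
#'
#' @param which `"best_fit"` or `"recovery"`.
#' @return An [lddm_params()] object.
#' @export
rt_truth_params <- function(which = c("best_fit", "recovery")) {
  which <- match.arg(which)
  switch(which,
    best_fit = lddm_params(alpha = 0, beta = 1.434, sigma = 25.36,
                           s_scale = 3251, tau_r = 0.1853, tau_g = 0.2244,
                           tau_d = 0.3231),
    recovery = lddm_params(alpha = 6, beta = 1.2, sigma = 25,
                           s_scale = 3000, tau_r = 0.18, tau_g = 0.22,
                           tau_d = 0.28))
}

#' Generate a synthetic reaction-time dataset from known parameters
#'
#' Simulates trials of the reaction-time protocol at the given truth and
#' returns the decided trials together with a ground-truth record that
#' suffices to regenerate the file.
#'
#' @param params Generating [lddm_params()] (default the best-fit truth).
#' @param coherences Coherence levels.
#' @param n_per_coherence Trials per coherence.
#' @param seed Integer seed.
#' @param model Generating model (`"lddm"`, `"rnm"`, `"lca"`).
#' @param keep_censored Keep censored trials in the returned data (they are
#'   always counted in the truth record).
#' @param ... Passed to [simulate_rt_trials()].
#' @return List with `data` (data frame `trial_id`, `coherence`, `choice`,
#'   `correct`, `rt_s`) and `truth` (list of generating parameters, design
#'   and censoring rate).
#' @export
generate_rt_dataset <- function(params = rt_truth_params("best_fit"),
                                coherences = canonical_coherences(),
                                n_per_coherence = 600, seed = 1,
                                model = "lddm", keep_censored = FALSE,
                                ...) {
  raw <- simulate_rt_trials(params, coherences, n_per_coherence,
                            seed = seed, model = model, ...)
  cens_frac <- mean(raw$censored)
  if (cens_frac >= 1)
    stop("degenerate parameters: every trial censored (no decisions); ",
         "censored fraction = 1")
  data <- if (keep_censored) raw else raw[!raw$censored, , drop = FALSE]
  data <- data.frame(trial_id = seq_len(nrow(data)),
                     coherence = data$coherence, choice = data$choice,
                     correct = data$correct, rt_s = data$rt_s)
  truth <- list(kind = "rt", model = model, params = unclass(params),
                coherences = coherences,
                n_per_coherence = n_per_coherence, seed = seed,
                censored_fraction = cens_frac)
  list(data = data, truth = truth)
}

#' Default 28-condition trinary value design
#'
#' A plausible trinary design: the recorded option's value crossed with
#' seven contextual (V2, V3) combinations, values drawn from
#' `{0, 50, 100, 200, 250}` microliters with omitted targets coded 0.
#'
#' @return Data frame with 28 rows, columns `V1_ul`, `V2_ul`, `V3_ul`.
#' @export
trinary_design <- function() {
  v1 <- c(50, 100, 200, 250)
  ctx <- rbind(c(0, 0), c(50, 0), c(100, 0), c(250, 0),
               c(50, 50), c(100, 100), c(250, 250))
  out <- do.call(rbind, lapply(v1, function(a)
    data.frame(V1_ul = a, V2_ul = ctx[, 1], V3_ul = ctx[, 2])))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic condition-mean firing-rate dataset
#'
#' Mean rates come from the circuit's divisive-normalization equilibrium;
#' independent Gaussian noise emulates condition-mean measurement error.
#' Negative draws are clamped at zero and counted in the truth record.
#'
#' @param conditions Condition table (default [trinary_design()]).
#' @param b_r,rmax,bg_minus_alpha Generating equilibrium parameters
#'   (defaults follow the circuit's fit to the monkey value-coding data).
#' @param noise_sd Additive Gaussian SD in Hz.
#' @param seed Integer seed.
#' @param model Generating model (`"lddm"` or `"dnm"`).
#' @return List with `data` (conditions plus `rate_hz`) and `truth`.
#' @export
generate_rates_dataset <- function(conditions = trinary_design(),
                                   b_r = 71.53, rmax = 10,
                                   bg_minus_alpha = 3.82, noise_sd = 2,
                                   seed = 1, model = "lddm") {
  set.seed(seed)
  mu <- predict_norm_rates(conditions, model, b_r = b_r, rmax = rmax,
                           bg_minus_alpha = bg_minus_alpha)
  rate <- mu + stats::rnorm(length(mu), 0, noise_sd)
  n_clamped <- sum(rate < 0)
  rate <- pmax(rate, 0)
  data <- data.frame(conditions, rate_hz = rate)
  truth <- list(kind = "rates", model = model,
                params = list(b_r = b_r, rmax = rmax,
                              bg_minus_alpha = bg_minus_alpha),
                noise_sd = noise_sd, seed = seed, n_clamped = n_clamped)
  list(data = data, truth = truth)
}

#' Read/write the package's CSV and JSON data formats
#'
#' Reaction-time datasets are CSV with columns `trial_id`, `coherence`,
#' `choice`, `correct`, `rt_s`; firing-rate datasets are CSV with `V1_ul`,
#' `V2_ul`, `V3_ul`, `rate_hz`.  Ground-truth records round-trip as JSON.
#'
#' @param data,truth Objects produced by the generators.
#' @param path File path.
#' @name lddm_io
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
NULL

#' @rdname lddm_io
#' @export
write_rt_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname lddm_io
#' @export
read_rt_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("trial_id", "coherence", "choice", "correct", "rt_s")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)),
                                    collapse = ", "))
  d$correct <- as.logical(d$correct)
  d
}

#' @rdname lddm_io
#' @export
write_rates_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname lddm_io
#' @export
read_rates_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("V1_ul", "V2_ul", "V3_ul", "rate_hz")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)),
                                    collapse = ", "))
  d
}

#' @rdname lddm_io
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname lddm_io
#' @export
read_truth_json <- function(path) jsonlite::read_json(path,
                                                      simplifyVector = TRUE)

#' Re-run a generator from its truth record
#'
#' @param truth A truth record from one of the generators (or read back
#'   with [read_truth_json()]).
#' @return The regenerated dataset list.
#' @export
regenerate_from_truth <- function(truth) {
  if (truth$kind == "rt") {
    p <- do.call(lddm_params, truth$params[c("alpha", "beta", "b_r", "b_g",
                                             "sigma", "tau_r", "tau_g",
                                             "tau_d", "tau_noise",
                                             "s_scale")])
    generate_rt_dataset(p, unlist(truth$coherences),
                        truth$n_per_coherence, truth$seed, truth$model)
  } else if (truth$kind == "rates") {
    generate_rates_dataset(b_r = truth$params$b_r,
                           rmax = truth$params$rmax,
                           bg_minus_alpha = truth$params$bg_minus_alpha,
                           noise_sd = truth$noise_sd, seed = truth$seed,
                           model = truth$model)
  } else stop("unknown truth kind '", truth$kind, "'")
}
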