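best_fit <- rt_truth_params("best_fit")

test_that("noiseless trials are identical and all correct at fixed coherence", {
  p <- best_fit
  p$sigma <- 0
  d <- simulate_rt_trials(p, c(0.128, 0.512), 20, seed = 3)
  expect_true(all(d$correct))
  for (cp in unique(d$coherence))
    expect_equal(length(unique(d$rt_s[d$coherence == cp])), 1)
  # higher coherence decides faster
  expect_lt(d$rt_s[d$coherence == 0.512][1],
            d$rt_s[d$coherence == 0.128][1])
})

test_that("trial batches are a pure function of the seed", {
  d1 <- simulate_rt_trials(best_fit, c(0, 0.128), 50, seed = 9)
  d2 <- simulate_rt_trials(best_fit, c(0, 0.128), 50, seed = 9)
  expect_identical(d1, d2)
  d3 <- simulate_rt_trials(best_fit, c(0, 0.128), 50, seed = 10)
  expect_false(identical(d1$rt_s, d3$rt_s))
})

test_that("quantile bins partition each cell", {
  d <- simulate_rt_trials(best_fit, c(0, 0.032), 300, seed = 4)
  qb <- quantile_binning(d[!d$censored, ])
  for (bc in qb$by_coherence) {
    for (s in c("correct", "error")) {
      cell <- bc$cells[[s]]
      expect_length(cell$counts, 10)
      expect_equal(sum(cell$counts), cell$n)
    }
  }
  expect_warning(
    quantile_binning(data.frame(coherence = 0.5, correct = TRUE,
                                rt_s = c(0.4, 0.5))),
    "empty error cell")
})

test_that("the likelihood matches a hand-computed toy cell", {
  # 10 observed trials; prediction puts every decided trial in the same
  # bins as the observations -> each predicted bin probability equals the
  # observed fraction, and the nLL is the multinomial entropy bound.
  obs <- data.frame(coherence = 0.1, correct = TRUE,
                    rt_s = seq(0.4, 1.3, by = 0.1))
  pred <- data.frame(coherence = 0.1, correct = TRUE,
                     rt_s = seq(0.4, 1.3, by = 0.1), censored = FALSE)
  qb <- suppressWarnings(quantile_binning(obs))
  nll <- suppressWarnings(qmle_nll(obs, pred))
  counts <- qb$by_coherence[[1]]$cells$correct$counts
  expect_equal(nll, -sum(counts * log(counts / 10)))
})

test_that("any other prediction is less likely than the matching one", {
  # Gibbs inequality on the same toy cell
  obs <- data.frame(coherence = 0.1, correct = TRUE,
                    rt_s = seq(0.4, 1.3, by = 0.1))
  qb <- suppressWarnings(quantile_binning(obs))
  match_pred <- data.frame(coherence = 0.1, correct = TRUE,
                           rt_s = seq(0.4, 1.3, by = 0.1),
                           censored = FALSE)
  base <- qmle_nll(NULL, match_pred, binning = qb)
  shifted <- data.frame(coherence = 0.1, correct = TRUE,
                        rt_s = seq(0.4, 1.3, by = 0.1) + 0.25,
                        censored = FALSE)
  expect_gt(qmle_nll(NULL, shifted, binning = qb), base)
})

test_that("predicted cell probabilities sum to one with censored mass", {
  d <- simulate_rt_trials(best_fit, 0, 400, seed = 6, cutoff = 1.2)
  expect_gt(sum(d$censored), 0)
  qb <- quantile_binning(d[!d$censored, ])
  pm <- cbind(d$rt_s, ifelse(d$censored, 0, ifelse(d$correct, 1, 2)))
  pp <- lddm:::pred_bin_probs(pm, qb$by_coherence[[1]])
  expect_equal(sum(unlist(pp)), 1, tolerance = 1e-12)
})

test_that("without disinhibition the circuit never reaches threshold", {
  p <- best_fit
  p$beta <- 0
  d <- simulate_rt_trials(p, c(0, 0.256), 40, seed = 2, cutoff = 3)
  expect_true(all(d$censored))
})

test_that("summaries aggregate a toy table by hand count", {
  toy <- data.frame(coherence = rep(c(0.1, 0.2), each = 10),
                    correct = rep(c(TRUE, FALSE), times = 10),
                    rt_s = seq(0.5, 2.4, by = 0.1),
                    censored = FALSE)
  s <- behavior_summaries(toy)
  expect_equal(s$psychometric$accuracy, c(0.5, 0.5))
  expect_equal(s$psychometric$n, c(10, 10))
  m <- with(toy, tapply(rt_s, list(coherence, correct), mean))
  expect_equal(s$chronometric$mean_rt[s$chronometric$correct],
               unname(m[, "TRUE"]))
  all_correct <- data.frame(coherence = 0.1, correct = TRUE,
                            rt_s = c(0.5, 0.6), censored = FALSE)
  s2 <- behavior_summaries(all_correct)
  expect_equal(s2$psychometric$accuracy, 1)
  expect_equal(s2$chronometric$n[!s2$chronometric$correct], 0)
})

test_that("errors are slower than correct responses near threshold coherence", {
  d <- simulate_rt_trials(best_fit, 0.032, 2000, seed = 21)
  s <- behavior_summaries(d)
  ch <- s$chronometric
  expect_gt(ch$n[!ch$correct], 20)
  expect_gt(ch$mean_rt[!ch$correct], ch$mean_rt[ch$correct])
})

test_that("fitting the same data with the same master seed is reproducible", {
  gen <- generate_rt_dataset(n_per_coherence = 60, seed = 5,
                             coherences = c(0.128, 0.512))
  f1 <- suppressWarnings(fit_model(gen$data, "lddm", n_starts = 2,
                                   n_reps = 64, seed = 17, maxit = 8,
                                   maxit_coarse = 8, n_screen = 4))
  f2 <- suppressWarnings(fit_model(gen$data, "lddm", n_starts = 2,
                                   n_reps = 64, seed = 17, maxit = 8,
                                   maxit_coarse = 8, n_screen = 4))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$nll, f2$nll)
  expect_equal(f1$aic, 2 * 7 + 2 * f1$nll)
})

test_that("the generating model beats the accumulator in AIC on its own data", {
  gen <- generate_rt_dataset(n_per_coherence = 400, seed = 31)
  fl <- suppressWarnings(fit_model(gen$data, "lddm", n_starts = 2,
                                   n_reps = 384, seed = 7, maxit = 40,
                                   maxit_coarse = 80, n_screen = 24))
  fa <- suppressWarnings(fit_model(gen$data, "lca", n_starts = 2,
                                   n_reps = 384, seed = 7, maxit = 40,
                                   maxit_coarse = 80, n_screen = 24))
  expect_lt(fl$aic, fa$aic)
})
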