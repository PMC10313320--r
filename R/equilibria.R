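#' Nullcline of one excitatory unit (two-alternative circuit)
#'
#' Setting all derivatives of one option's `R`-`G`-`D` column to zero and
#' eliminating `G` and `D` expresses the opponent activity on the nullcline
#' of unit `which`:
#' `v R_other = (V + B_R) / R - (w - beta) R - (1 + B_G - alpha)`.
#'
#' @param which Option index (1 or 2).
#' @param r_grid Positive activities of unit `which` at which to evaluate.
#' @param V Length-2 input vector.
#' @param params [lddm_params()].
#' @param omega [gain_matrix()] (2 options).
#' @param beta_now Effective disinhibition weight (default `params$beta`).
#' @return Data frame with columns `r_self` and `r_other` (grid points where
#'   `r_self <= 0` are dropped as singular).
#' @export
nullcline_r <- function(which = 1, r_grid, V, params, omega,
                        beta_now = params$beta) {
  if (omega$n_options != 2) stop("nullcline_r is defined for 2 options")
  check_inputs(V, 2)
  r <- r_grid[r_grid > 0]
  other <- ((V[which] + params$b_r) / r - (omega$w - beta_now) * r -
              (1 + params$b_g - params$alpha)) / omega$v
  data.frame(r_self = r, r_other = other)
}

# g(R1) whose roots are nullcline intersections: substitute R2 from unit 1's
# nullcline into unit 2's nullcline equation.  Returns NA where R2 <= 0.
intersect_gap <- function(r1, V, params, omega, beta_now) {
  c0 <- 1 + params$b_g - params$alpha
  r2 <- ((V[1] + params$b_r) / r1 - (omega$w - beta_now) * r1 - c0) /
    omega$v
  ifelse(r2 > 0,
         (V[2] + params$b_r) / r2 - (omega$w - beta_now) * r2 - c0 -
           omega$v * r1,
         NA_real_)
}

#' Find all circuit equilibria
#'
#' For two alternatives the problem reduces to the intersections of the two
#' `R`-unit nullclines; these are located by a dense sign-change scan of the
#' intersection gap along a log-spaced grid, polished with [stats::uniroot()].
#' For more alternatives a multi-start Newton iteration on the reduced
#' `R`-system is used.  `G*` and `D*` are recovered as `D* = beta R*`,
#' `G* = omega R* + B_G - D*`, and each point is labelled by the eigenvalues
#' of the full Jacobian.
#'
#' Boundary (clamped, `R = 0`) states are not counted: the analysis concerns
#' the positive quadrant.  An empty set is a valid result, not an error.
#'
#' @param V Input vector.
#' @param params [lddm_params()].
#' @param omega [gain_matrix()].
#' @param beta_now Effective disinhibition weight.
#' @param box Search interval per dimension (Hz), default `c(1e-3, 300)`.
#' @param n_scan Number of scan points (default 2000).
#' @param stab_tol Eigenvalue real-part tolerance for stability labels.
#' @return An object of class `equilibrium_set`: list with `points` (each
#'   having `R`, `G`, `D`, `eigenvalues`, `stability`, `residual`) and
#'   `counts` (`n_equilibria`, `n_stable`, `n_unstable`, `n_marginal`).
#' @export
find_equilibria <- function(V, params, omega, beta_now = params$beta,
                            box = c(1e-3, 300), n_scan = 2000,
                            stab_tol = 1e-6) {
  check_inputs(V, omega$n_options)
  if (box[1] <= 0 || box[2] <= box[1]) stop("invalid search box")
  roots <- if (omega$n_options == 2)
    scan_roots_2(V, params, omega, beta_now, box, n_scan)
  else
    newton_roots_n(V, params, omega, beta_now, box)
  pts <- lapply(roots, function(R) {
    D <- beta_now * R
    G <- as.numeric(omega$omega %*% R) + params$b_g - D
    st <- circuit_state(R, G, D)
    dv <- lddm_derivs(st, V, params, omega, beta_now)
    J <- lddm_jacobian(R, V, params, omega, beta_now)
    ev <- eigen(J, only.values = TRUE)$values
    list(R = R, G = G, D = D, eigenvalues = ev,
         stability = stability_label(ev, stab_tol),
         residual = max(abs(c(dv$R, dv$G, dv$D))))
  })
  labs <- vapply(pts, function(p) p$stability, "")
  out <- list(points = pts,
              counts = c(n_equilibria = length(pts),
                         n_stable = sum(labs == "stable"),
                         n_unstable = sum(labs == "unstable"),
                         n_marginal = sum(labs == "marginal")),
              box = box, V = V, beta_now = beta_now)
  class(out) <- "equilibrium_set"
  out
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("<equilibrium_set>", x$counts["n_equilibria"], "equilibria (",
      x$counts["n_stable"], "stable,", x$counts["n_unstable"],
      "unstable,", x$counts["n_marginal"], "marginal )\n")
  for (p in x$points)
    cat(sprintf("  R* = (%s)  %s\n",
                paste(formatC(p$R, digits = 5, format = "fg"),
                      collapse = ", "), p$stability))
  invisible(x)
}

# One scanning pass: walk a log grid in the activity of unit `lead`,
# express the other unit through lead's nullcline, and find sign changes of
# the second nullcline's residual.  Extreme asymmetric equilibria hug one
# axis, so both passes are run and merged: each one resolves the branch
# whose lead activity is small.
scan_pass <- function(V, params, omega, beta_now, box, n_scan, lead) {
  Vo <- if (lead == 1) V else rev(V)
  gap <- function(r) intersect_gap(r, Vo, params, omega, beta_now)
  grid <- exp(seq(log(box[1]), log(box[2]), length.out = n_scan))
  g <- gap(grid)
  roots <- numeric(0)
  for (i in seq_len(n_scan - 1)) {
    g1 <- g[i]; g2 <- g[i + 1]
    if (is.na(g1) || is.na(g2) || !is.finite(g1) || !is.finite(g2)) next
    if (g1 == 0) {
      roots <- c(roots, grid[i])
    } else if (g1 * g2 < 0) {
      roots <- c(roots, stats::uniroot(gap, c(grid[i], grid[i + 1]),
                                       tol = 1e-12)$root)
    }
  }
  c0 <- 1 + params$b_g - params$alpha
  lapply(roots, function(r1) {
    r2 <- ((Vo[1] + params$b_r) / r1 - (omega$w - beta_now) * r1 - c0) /
      omega$v
    if (lead == 1) c(r1, r2) else c(r2, r1)
  })
}

scan_roots_2 <- function(V, params, omega, beta_now, box, n_scan) {
  dedup_roots(c(scan_pass(V, params, omega, beta_now, box, n_scan, 1L),
                scan_pass(V, params, omega, beta_now, box, n_scan, 2L)))
}

newton_roots_n <- function(V, params, omega, beta_now, box, n_starts = 60,
                           max_iter = 100) {
  n <- omega$n_options
  c0 <- 1 + params$b_g - params$alpha
  om <- omega$omega
  Ffun <- function(R) R * (c0 + as.numeric(om %*% R) - beta_now * R) -
    (V + params$b_r)
  Jfun <- function(R) {
    wr <- as.numeric(om %*% R)
    diag(c0 + wr - 2 * beta_now * R, n) + R * om
  }
  set <- list()
  # deterministic start battery: symmetric levels plus one-hot corners
  levels <- exp(seq(log(box[1] * 10), log(box[2] * 0.9), length.out = 6))
  starts <- c(lapply(levels, function(l) rep(l, n)),
              unlist(lapply(levels, function(l)
                lapply(seq_len(n), function(i) {
                  x <- rep(box[1] * 10, n); x[i] <- l; x
                })), recursive = FALSE))
  for (R in starts) {
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      Fv <- Ffun(R)
      if (max(abs(Fv)) < 1e-11) break
      step <- tryCatch(solve(Jfun(R), Fv), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      R <- R - step
      if (any(!is.finite(R)) || any(R <= 0) || any(R > box[2] * 100)) {
        ok <- FALSE; break
      }
    }
    if (ok && max(abs(Ffun(R))) < 1e-11 && all(R >= box[1]) &&
        all(R <= box[2]))
      set <- c(set, list(R))
  }
  dedup_roots(set)
}

dedup_roots <- function(roots, sep = 1e-4) {
  out <- list()
  for (r in roots) {
    dup <- any(vapply(out, function(o) max(abs(o - r)) < sep, TRUE))
    if (!dup) out <- c(out, list(r))
  }
  out
}

#' Analytic Jacobian of the circuit at a candidate equilibrium
#'
#' Linearization of the full `3N`-dimensional field, with each row scaled by
#' the corresponding `1/tau` (a true linearization; omitting the row scaling
#' would leave every stability sign unchanged but distort the eigenvalue
#' magnitudes).
#'
#' @param R_star Strictly positive `R` activities at the point.
#' @param V Input vector.
#' @param params [lddm_params()].
#' @param omega [gain_matrix()].
#' @param beta_now Effective disinhibition weight.
#' @return A `3N x 3N` matrix, unit order `(R_1..R_N, G_1..G_N, D_1..D_N)`.
#' @export
lddm_jacobian <- function(R_star, V, params, omega,
                          beta_now = params$beta) {
  n <- length(R_star)
  check_inputs(V, n)
  if (any(R_star <= 0))
    stop("Jacobian requires strictly positive R (clamp-free domain)")
  D <- beta_now * R_star
  G <- as.numeric(omega$omega %*% R_star) + params$b_g - D
  J <- matrix(0, 3 * n, 3 * n)
  iR <- seq_len(n); iG <- n + iR; iD <- 2 * n + iR
  for (i in seq_len(n)) {
    J[iR[i], iR[i]] <- (-1 + params$alpha / (1 + G[i])) / params$tau_r
    J[iR[i], iG[i]] <- -(V[i] + params$b_r + params$alpha * R_star[i]) /
      (1 + G[i])^2 / params$tau_r
    J[iG[i], iR] <- omega$omega[i, ] / params$tau_g
    J[iG[i], iG[i]] <- -1 / params$tau_g
    J[iG[i], iD[i]] <- -1 / params$tau_g
    J[iD[i], iR[i]] <- beta_now / params$tau_d
    J[iD[i], iD[i]] <- -1 / params$tau_d
  }
  J
}

stability_label <- function(ev, tol = 1e-6) {
  re <- Re(ev)
  if (all(re < -tol)) "stable"
  else if (any(re > tol)) "unstable"
  else "marginal"
}

territory_table <- data.frame(
  territory = c("dark_green", "blue", "green", "yellow", "red"),
  n_equilibria = c(1, 3, 3, 1, 0),
  n_stable = c(1, 2, 1, 0, 0),
  n_unstable = c(0, 1, 2, 1, 0),
  func = c("normalization", "WTA", "normalization", "WTA", "WTA"),
  stringsAsFactors = FALSE)

#' Classify the operating regime at one (alpha, beta) point
#'
#' Under equal inputs the circuit falls into one of five territories
#' distinguished by the number and stability of its equilibria:
#' `dark_green` (1 stable; normalized coding), `blue` (2 stable + 1
#' unstable; bistable winner-take-all), `green` (1 stable between 2
#' unstable; normalized coding), `yellow` (1 unstable; winner-take-all) and
#' `red` (no equilibria; winner-take-all).  A diagnostic tuple outside this
#' table is reported as `"unclassified"` rather than forced into a label.
#'
#' @param alpha,beta Recurrence and disinhibition weights to probe.
#' @param params Remaining circuit constants ([lddm_params()]).
#' @param omega [gain_matrix()].
#' @param V_equal Common input value per option (default `params$s_scale`).
#' @param box Search interval; the default upper bound `1e4` accommodates
#'   the diverging symmetric equilibrium as `beta` approaches the red
#'   boundary.
#' @param n_scan Scan resolution passed to [find_equilibria()].
#' @return List with `territory`, `func` (`"normalization"` or `"WTA"`) and
#'   the `diagnostic` tuple.
#' @export
classify_regime <- function(alpha, beta, params = lddm_params(),
                            omega = gain_matrix(2), V_equal = params$s_scale,
                            box = c(1e-3, 1e4), n_scan = 2000) {
  p <- params
  p$alpha <- alpha
  p$beta <- beta
  eq <- find_equilibria(rep(V_equal, omega$n_options), p, omega,
                        beta_now = beta, box = box, n_scan = n_scan)
  tup <- eq$counts[c("n_equilibria", "n_stable", "n_unstable")]
  hit <- which(territory_table$n_equilibria == tup[1] &
                 territory_table$n_stable == tup[2] &
                 territory_table$n_unstable == tup[3])
  if (length(hit) == 1) {
    list(territory = territory_table$territory[hit],
         func = territory_table$func[hit], diagnostic = tup)
  } else {
    list(territory = "unclassified", func = NA_character_,
         diagnostic = tup)
  }
}

#' Map operating regimes over a grid of (alpha, beta)
#'
#' @param alpha_grid,beta_grid Numeric vectors of weights to scan.
#' @inheritParams classify_regime
#' @return Data frame with columns `alpha`, `beta`, `territory`, `func`,
#'   `n_equilibria`, `n_stable`, `n_unstable`.
#' @export
regime_map <- function(alpha_grid, beta_grid, params = lddm_params(),
                       omega = gain_matrix(2), V_equal = params$s_scale,
                       box = c(1e-3, 1e4), n_scan = 1000) {
  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid)
  res <- lapply(seq_len(nrow(grid)), function(i)
    classify_regime(grid$alpha[i], grid$beta[i], params, omega, V_equal,
                    box, n_scan))
  grid$territory <- vapply(res, function(r) r$territory, "")
  grid$func <- vapply(res, function(r) r$func, "")
  grid$n_equilibria <- vapply(res, function(r) r$diagnostic[1], 0)
  grid$n_stable <- vapply(res, function(r) r$diagnostic[2], 0)
  grid$n_unstable <- vapply(res, function(r) r$diagnostic[3], 0)
  grid
}

#' Analytic fixed points of the circuit without input
#'
#' With inputs withdrawn the equilibrium condition becomes linear:
#' `(w - beta) R_i + v sum_{j != i} R_j = alpha - 1 - B_G`.  The attractor
#' structure then follows by case analysis on the excitation/gain balance
#' (`alpha` vs `1 + B_G`), the symmetry of the gain weights (`v` vs `w`) and
#' the disinhibition state.
#'
#' @param params [lddm_params()].
#' @param omega [gain_matrix()] (local weight `w`, lateral weight `v`).
#' @param beta_now Effective disinhibition weight during the delay.
#' @return List with `type` in `"none"`, `"line"`, `"point"`,
#'   `"corner_wta"`; `sum_R` (line: conserved total), `point_R` (point:
#'   per-unit level), `winner_R` (corner: winner level, `Inf` when
#'   disinhibition exceeds the gain weight so activity is unbounded), and a
#'   human-readable `description`.
#' @export
persistent_equilibria <- function(params, omega, beta_now = 0) {
  w <- omega$w; v <- omega$v; n <- omega$n_options
  if (w + v == 0) stop("degenerate gain weights: w + v = 0")
  excess <- params$alpha - 1 - params$b_g
  if (excess <= 0)
    return(list(type = "none", sum_R = 0, point_R = 0, winner_R = 0,
                description = "no elevated activity: alpha <= 1 + B_G"))
  if (beta_now == 0) {
    if (v == w)
      list(type = "line", sum_R = excess / w, point_R = excess / (w * n),
           winner_R = NA_real_,
           description = sprintf(
             "line attractor: sum(R*) = (alpha-1-B_G)/w = %.6g", excess / w))
    else if (v < w)
      list(type = "point", sum_R = n * excess / (w + (n - 1) * v),
           point_R = excess / (w + (n - 1) * v), winner_R = NA_real_,
           description = "point attractor with equal activities")
    else
      list(type = "corner_wta", sum_R = excess / w, point_R = NA_real_,
           winner_R = excess / w,
           description = "unstable interior point; corners win at (alpha-1-B_G)/w")
  } else {
    if (beta_now < w)
      list(type = "corner_wta", sum_R = excess / (w - beta_now),
           point_R = NA_real_, winner_R = excess / (w - beta_now),
           description = "corner attractors at (alpha-1-B_G)/(w-beta)")
    else
      list(type = "corner_wta", sum_R = Inf, point_R = NA_real_,
           winner_R = Inf,
           description = "disinhibition exceeds gain weight: unbounded winner")
  }
}

#' Probe the attractor structure by simulation
#'
#' Integrates the noiseless circuit without input from several initial
#' activity ratios and classifies the endpoint pattern: a line attractor
#' maps distinct ratios to distinct endpoints sharing a common sum, a point
#' attractor maps all of them to one point, and corner states keep a single
#' winner.
#'
#' @param params [lddm_params()].
#' @param omega [gain_matrix()].
#' @param beta_now Disinhibition weight during the probe.
#' @param start_sum Total initial activity shared by the probes (Hz).
#' @param ratios Initial `R_1 : R_2` ratios probed (first unit vs the
#'   rest).  Defaults avoid the exactly symmetric start, which lies on the
#'   invariant manifold of the interior point and never leaves it in a
#'   noiseless probe.
#' @param t_max Maximum simulated time (s).
#' @param dt Step (s).
#' @param rel_tol Relative tolerance for endpoint comparisons.
#' @return List with `type` in `"line"`, `"point"`, `"corner_wta"`,
#'   `"none"`, and the endpoint matrix `endpoints` (probes x units).
#' @export
attractor_type <- function(params, omega, beta_now = 0, start_sum = 20,
                           ratios = c(1 / 4, 1 / 2, 4 / 5, 5 / 4, 2, 4),
                           t_max = 20,
                           dt = 0.001, rel_tol = 1e-3) {
  n <- omega$n_options
  p <- params
  p$sigma <- 0
  proto <- stimulus_protocol(n, list(list(duration = t_max,
                                          V = rep(0, n),
                                          beta_on = beta_now > 0,
                                          label = "delay")))
  p$beta <- beta_now
  ends <- t(vapply(ratios, function(r) {
    R0 <- start_sum * c(r, rep(1, n - 1)) / (r + n - 1)
    G0 <- as.numeric(omega$omega %*% R0) + p$b_g
    tr <- simulate_circuit(p, omega, proto, dt = dt,
                           init = circuit_state(R0, G0, rep(0, n)),
                           stop_tol = 1e-8)
    tr$R[nrow(tr$R), ]
  }, numeric(n)))
  scale <- max(ends, 1e-9)
  sums <- rowSums(ends)
  if (all(ends < rel_tol * start_sum))
    return(list(type = "none", endpoints = ends))
  spread <- max(apply(ends, 2, function(col) diff(range(col))))
  onehot <- all(apply(ends, 1, function(e)
    sum(e > rel_tol * max(e)) == 1))
  if (spread < rel_tol * scale) {
    list(type = "point", endpoints = ends)
  } else if (onehot) {
    list(type = "corner_wta", endpoints = ends)
  } else if (diff(range(sums)) < rel_tol * max(sums)) {
    list(type = "line", endpoints = ends)
  } else {
    list(type = "none", endpoints = ends)
  }
}

#' Export a regime map or nullclines to CSV
#'
#' @param x A data frame from [regime_map()] or [nullcline_r()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
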