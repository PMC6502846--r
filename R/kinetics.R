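#' Fit the pore appearance curve
#'
#' With initiation much slower than completion, the number of visible
#' pores grows as \eqn{A (1 - \exp(-t/\tau_{init}))}; this fits that
#' saturating exponential to per-frame pore counts by least squares.
#' Initialization: `A` = max count, `tau` = the time at which counts first
#' reach `(1 - 1/e)` of the maximum.
#'
#' @param times frame times, s.
#' @param counts per-frame pore counts (non-negative).
#' @return Object of class `appearance_fit`: `A_sat`, `tau_init` (s),
#'   `cov` (2x2 covariance of the estimates), `residual_rms`, `boundary`
#'   (flag: saturated/degenerate time dependence, `tau_init` below the
#'   sampling interval).
#' @export
fit_appearance <- function(times, counts) {
  if (length(times) < 5L || length(times) != length(counts)) {
    stop(">= 5 matched time points required", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) {
    stop("degenerate fit: all counts are zero", call. = FALSE)
  }
  a0 <- max(counts)
  target <- (1 - exp(-1)) * a0
  i0 <- which(counts >= target)[1]
  tau0 <- max(times[i0], min(diff(sort(unique(times)))))
  fit <- minpack.lm::nlsLM(
    y ~ A * (1 - exp(-t / tau)),
    data = data.frame(t = times, y = counts),
    start = list(A = a0, tau = tau0),
    lower = c(A = 1e-12, tau = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- stats::coef(fit)
  covm <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  structure(list(A_sat = p[["A"]], tau_init = p[["tau"]], cov = covm,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 boundary = p[["tau"]] < min(diff(sort(unique(times))))),
            class = "appearance_fit")
}

#' Initiation probability of a single C5b-8 complex
#'
#' Probability that a given C5b-8 complex has bound its first C9 by time t:
#' \eqn{p_{init}(t) = 1 - \exp(-k_{init} [C9] t)}.
#'
#' @param t time since C9 addition, s (>= 0).
#' @param k_init initiation rate constant, s^-1 mM^-1.
#' @param c9 C9 concentration, mM.
#' @return Probability in \[0, 1\], vectorized over `t`.
#' @export
p_init <- function(t, k_init, c9) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  1 - exp(-k_init * c9 * t)
}

#' Convert a characteristic time to a rate constant
#'
#' Under the constant-excess-C9 assumption, \eqn{k = 1/(\tau [C9])}:
#' applied to \eqn{\tau_{init}} it gives \eqn{k_{init}}, to \eqn{\tau_+}
#' it gives \eqn{k_+}.
#'
#' @param tau characteristic time, s (> 0).
#' @param c9 C9 concentration, mM (> 0).
#' @return Rate constant, s^-1 mM^-1.
#' @export
rate_constant <- function(tau, c9) {
  if (any(tau <= 0) || any(c9 <= 0)) {
    stop("tau and c9 must be > 0", call. = FALSE)
  }
  1 / (tau * c9)
}

#' Mean time per C9 addition
#'
#' The oligomerization time covers the `n_additions` = 17 sequential C9
#' additions that complete the 18-subunit pore, so the average time per
#' addition is \eqn{\tau_+ = \tau_{olig} / 17}.
#'
#' @param tau_olig oligomerization (transition) time, s (> 0).
#' @param n_additions number of sequential additions (default 17).
#' @return \eqn{\tau_+}, s.
#' @export
tau_plus_from_olig <- function(tau_olig, n_additions = 17L) {
  if (any(tau_olig <= 0) || n_additions < 1L) {
    stop("tau_olig must be > 0 and n_additions >= 1", call. = FALSE)
  }
  tau_olig / n_additions
}

#' Solve the C9 occupancy distribution of a growing pore
#'
#' Integrates the linear birth chain for the probability \eqn{p_n(t)} that
#' a growing pore holds n C9 subunits:
#' \deqn{dp_1/dt = -\lambda p_1, \quad
#'       dp_n/dt = \lambda (p_{n-1} - p_n) \ (2 \le n < 18), \quad
#'       dp_{18}/dt = \lambda p_{17}}
#' with \eqn{\lambda = k_+ [C9]}, starting from \eqn{p_1(0) = 1}; n = 18
#' (the complete pore) is absorbing. Solved numerically with `lsoda` at
#' tight tolerances; the closed form is Poisson,
#' \eqn{p_{1+m}(t) = (\lambda t)^m e^{-\lambda t}/m!} for m <= 16 (see
#' [occupancy_closed_form()]).
#'
#' @param k_plus oligomerization rate constant, s^-1 mM^-1.
#' @param c9 C9 concentration, mM.
#' @param times strictly increasing time grid, s, starting at 0.
#' @param n_max number of states (default 18).
#' @return Object of class `occupancy_distribution`: `times`, `p`
#'   (length(times) x n_max matrix), `mean_n` = \eqn{\sum_n n p_n(t)},
#'   `lambda`.
#' @export
solve_occupancy <- function(k_plus, c9, times, n_max = 18L) {
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) {
    stop("time grid must start at 0 (initial condition p_1 = 1)",
         call. = FALSE)
  }
  lambda <- k_plus * c9
  y0 <- c(1, rep(0, n_max - 1L))
  rhs <- function(t, y, parms) {
    inflow <- c(0, y[-n_max])
    outflow <- c(y[-n_max], 0)   # state n_max is absorbing
    list(parms * (inflow - outflow))
  }
  sol <- deSolve::lsoda(y0, times, rhs, parms = lambda,
                        rtol = 1e-10, atol = 1e-12)
  p <- unname(sol[, -1, drop = FALSE])
  structure(list(times = times, p = p,
                 mean_n = as.numeric(p %*% seq_len(n_max)),
                 lambda = lambda),
            class = "occupancy_distribution")
}

#' Closed-form (Poisson) occupancy distribution
#'
#' @inheritParams solve_occupancy
#' @param lambda rate \eqn{k_+ [C9]}, s^-1.
#' @return Matrix of \eqn{p_n(t)}, length(times) x n_max; the absorbing
#'   last state holds the remaining probability.
#' @export
occupancy_closed_form <- function(lambda, times, n_max = 18L) {
  p <- sapply(0:(n_max - 2L), function(m) stats::dpois(m, lambda * times))
  p <- matrix(p, nrow = length(times))
  cbind(p, 1 - rowSums(p))
}

#' Mean oligomer size over time
#'
#' \eqn{\langle n \rangle(t) = \sum_n n p_n(t)}. While the absorbing state
#' is still nearly empty, the growth rate is constant:
#' \eqn{d\langle n \rangle/dt \approx k_+ [C9]}.
#'
#' @param occ an `occupancy_distribution` from [solve_occupancy()].
#' @return Numeric vector \eqn{\langle n \rangle(t)}.
#' @export
mean_oligomer_size <- function(occ) {
  stopifnot(inherits(occ, "occupancy_distribution"))
  occ$mean_n
}

#' Early-time oligomerization rate from the occupancy solution
#'
#' Linear regression slope of \eqn{\langle n \rangle(t)} restricted to the
#' times where the completed-pore probability `p_18` is below `p18_max`
#' (the regime in which the growth rate is constant and equals
#' \eqn{k_+ [C9]}).
#'
#' @param occ an `occupancy_distribution`.
#' @param p18_max inclusion cutoff on the absorbing-state probability
#'   (default 0.01).
#' @return Slope, subunits per second.
#' @export
mean_growth_slope <- function(occ, p18_max = 0.01) {
  stopifnot(inherits(occ, "occupancy_distribution"))
  keep <- occ$p[, ncol(occ$p)] < p18_max
  if (sum(keep) < 2L) stop("too few early-time points", call. = FALSE)
  unname(stats::coef(stats::lm(occ$mean_n[keep] ~ occ$times[keep]))[2])
}

#' Assemble the kinetic parameters of MAC assembly
#'
#' Combines the appearance-curve fit (initiation) and the aggregated
#' oligomerization times (propagation) into the two rate constants, using
#' \eqn{k = 1/(\tau [C9])} and \eqn{\tau_+ = \tau_{olig}/17}.
#'
#' @param appearance an `appearance_fit` from [fit_appearance()].
#' @param olig_summary result of [aggregate_oligomerization()] (or a list
#'   with a `mean` tau_olig in s).
#' @param c9 C9 concentration, mM.
#' @param n_additions sequential additions after the first insertion
#'   (default 17; the complete pore has `n_additions + 1` subunits).
#' @return Object of class `kinetic_parameters`: `c9_conc`, `tau_init`,
#'   `tau_olig`, `tau_plus` (s), `k_init`, `k_plus` (s^-1 mM^-1),
#'   `n_max`, `n_additions`, and `timescale_ratio` =
#'   \eqn{\tau_{init}/\tau_+}.
#' @export
estimate_kinetics <- function(appearance, olig_summary, c9,
                              n_additions = 17L) {
  if (!inherits(appearance, "appearance_fit")) {
    stop("appearance must be an appearance_fit", call. = FALSE)
  }
  if (is.null(olig_summary$mean) || !is.finite(olig_summary$mean)) {
    stop("olig_summary must carry a finite mean tau_olig", call. = FALSE)
  }
  tau_init <- appearance$tau_init
  tau_olig <- olig_summary$mean
  tau_plus <- tau_plus_from_olig(tau_olig, n_additions)
  structure(list(
    c9_conc = c9,
    tau_init = tau_init,
    tau_olig = tau_olig,
    tau_plus = tau_plus,
    k_init = rate_constant(tau_init, c9),
    k_plus = rate_constant(tau_plus, c9),
    n_max = n_additions + 1L,
    n_additions = as.integer(n_additions),
    timescale_ratio = tau_init / tau_plus
  ), class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("MAC assembly kinetics ([C9] =", format(x$c9_conc), "mM)\n")
  cat(sprintf("  tau_init = %.3g s   -> k_init = %.2g s^-1 mM^-1\n",
              x$tau_init, x$k_init))
  cat(sprintf("  tau_olig = %.3g s over %d additions -> tau_+ = %.2g s\n",
              x$tau_olig, x$n_additions, x$tau_plus))
  cat(sprintf("  k_+ = %.3g s^-1 mM^-1   (tau_init / tau_+ = %.3g)\n",
              x$k_plus, x$timescale_ratio))
  invisible(x)
}
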