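#' Exponential-Euler update of a gating variable
#'
#' Over one step the rates are frozen at their current values, making the
#' gating ODE linear; it is then relaxed exactly toward its instantaneous
#' steady state:
#' \deqn{x' = x_\infty + (x - x_\infty)\,e^{-dt(\alpha+\beta)},\qquad
#'   x_\infty = \alpha/(\alpha+\beta).}
#' When `alpha + beta == 0` the variable has no dynamics and is returned
#' unchanged.
#'
#' @param x Current gating value(s).
#' @param alpha,beta Opening/closing rates, 1/ms (non-negative).
#' @param dt Step size, ms (> 0).
#' @return Updated gating value(s).
#' @export
exp_euler_gating_step <- function(x, alpha, beta, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  if (any(alpha < 0) || any(beta < 0)) stop("rates must be non-negative")
  s <- alpha + beta
  x_inf <- ifelse(s > 0, alpha / ifelse(s > 0, s, 1), x)
  ifelse(s > 0, x_inf + (x - x_inf) * exp(-dt * s), x)
}

#' Classical 4th-order Runge-Kutta step
#'
#' One fixed step of the classical RK4 scheme for `dy/dt = f(t, y)`. `y` may
#' be any numeric structure (vector, matrix, or list of numeric vectors) for
#' which elementwise arithmetic is defined; `f` must return an object of the
#' same shape.
#'
#' @param f Derivative function `f(t, y)`.
#' @param y Current state.
#' @param t Current time.
#' @param dt Step size (> 0).
#' @return The state at `t + dt`.
#' @examples
#' rk4_step(function(t, y) -y, 1, 0, 0.1)  # ~exp(-0.1)
#' @export
rk4_step <- function(f, y, t, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  comb <- function(a, ka, fac) {
    if (is.list(a)) Map(function(u, v) u + fac * v, a, ka) else a + fac * ka
  }
  check <- function(k, label) {
    vals <- if (is.list(k)) unlist(k, use.names = FALSE) else k
    if (any(!is.finite(vals))) {
      nm <- if (is.list(k)) {
        bad <- vapply(k, function(u) any(!is.finite(u)), logical(1))
        paste(names(k)[bad], collapse = ", ")
      } else "y"
      stop(sprintf("non-finite value in RK4 stage %s (variable: %s)", label, nm))
    }
    k
  }
  k1 <- check(f(t, y), "k1")
  k2 <- check(f(t + dt / 2, comb(y, k1, dt / 2)), "k2")
  k3 <- check(f(t + dt / 2, comb(y, k2, dt / 2)), "k3")
  k4 <- check(f(t + dt, comb(y, k3, dt)), "k4")
  if (is.list(y))
    Map(function(y0, a, b, c2, d) y0 + dt / 6 * (a + 2 * b + 2 * c2 + d),
        y, k1, k2, k3, k4)
  else
    y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Tabulate a function on a uniform voltage grid
#'
#' Precomputing voltage-dependent right-hand sides into lookup tables and
#' interpolating at run time is a standard acceleration for conductance-based
#' models. The grid has `floor((v_max - v_min)/step) + 1` nodes starting at
#' `v_min`.
#'
#' @param fn Function of voltage, vectorized.
#' @param v_min,v_max Grid range, mV (`v_min < v_max`).
#' @param step Grid spacing, mV (> 0).
#' @return An object of class `"lookup_table"` with fields `v_min`, `v_max`,
#'   `step`, `samples`.
#' @examples
#' tab <- build_table(function(v) exp(v / 10), -100, 50, 1)
#' length(tab$samples)  # 151
#' @export
build_table <- function(fn, v_min, v_max, step) {
  if (!is.numeric(step) || step <= 0) stop("`step` must be positive")
  if (v_min >= v_max) stop("`v_min` must be below `v_max`")
  # tolerance keeps e.g. 150/0.1 from flooring to 1499 in floating point
  n <- floor((v_max - v_min) / step + 1e-9) + 1L
  grid <- v_min + (seq_len(n) - 1L) * step
  structure(list(v_min = v_min, v_max = v_max, step = step,
                 samples = fn(grid)),
            class = "lookup_table")
}

#' Linear interpolation in a lookup table
#'
#' Values between grid nodes are linearly interpolated from the two bracketing
#' samples; probes at a node return the stored sample exactly. No
#' extrapolation: probes outside the tabulated range raise an error.
#'
#' @param table A [build_table()] result.
#' @param v Probe voltage(s), mV.
#' @return Interpolated value(s).
#' @export
table_lookup <- function(table, v) {
  n <- length(table$samples)
  top <- table$v_min + (n - 1L) * table$step
  if (any(v < table$v_min - 1e-9) || any(v > top + 1e-9))
    stop(sprintf("probe outside tabulated range [%g, %g]", table$v_min, top))
  pos <- (v - table$v_min) / table$step
  i <- pmin(pmax(floor(pos), 0), n - 2L)
  frac <- pos - i
  table$samples[i + 1L] * (1 - frac) + table$samples[i + 2L] * frac
}

#' Maximum relative interpolation error of a table
#'
#' Probes the table on a dense uniform grid and reports the largest relative
#' deviation of the interpolated values from direct evaluation of `fn`, in
#' percent. `fn` must be nonzero at every probe (otherwise the relative error
#' is undefined).
#'
#' @param table A [build_table()] result.
#' @param fn The tabulated function.
#' @param n_probes Number of uniform probes (at least 10 per table entry).
#' @return Maximum relative error, percent.
#' @export
table_max_relative_error <- function(table, fn, n_probes = NULL) {
  n <- length(table$samples)
  if (is.null(n_probes)) n_probes <- 10L * n
  if (n_probes < 10L * n)
    stop("`n_probes` must be at least 10 per table entry")
  top <- table$v_min + (n - 1L) * table$step
  probes <- seq(table$v_min, top, length.out = n_probes)
  truth <- fn(probes)
  if (any(truth == 0)) stop("`fn` is zero at a probe; relative error undefined")
  max(abs(table_lookup(table, probes) - truth) / abs(truth)) * 100
}

#' Interpolation error of tabulated Hodgkin-Huxley rate functions
#'
#' Builds lookup tables for the six classical rate functions on a uniform
#' voltage grid and reports the maximum relative error of linear
#' interpolation against direct evaluation, per function.
#'
#' @param step Grid spacing, mV.
#' @param v_min,v_max Grid range, mV. The default \[-100, 50\] yields 151
#'   entries per function at a 1 mV step.
#' @param n_probes Number of uniform probe voltages (default `1e5`, raised to
#'   10 per entry if the table is finer).
#' @return Named numeric vector of maximum relative errors in percent, one
#'   entry per rate function.
#' @examples
#' max(rate_table_errors(step = 1))    # < 5 (percent)
#' @export
rate_table_errors <- function(step, v_min = -100, v_max = 50, n_probes = 1e5) {
  fns <- list(
    alpha_m = function(v) hh_rates(v)$alpha_m,
    beta_m  = function(v) hh_rates(v)$beta_m,
    alpha_h = function(v) hh_rates(v)$alpha_h,
    beta_h  = function(v) hh_rates(v)$beta_h,
    alpha_n = function(v) hh_rates(v)$alpha_n,
    beta_n  = function(v) hh_rates(v)$beta_n
  )
  vapply(fns, function(fn) {
    tab <- build_table(fn, v_min, v_max, step)
    table_max_relative_error(tab, fn,
                             n_probes = max(n_probes, 10L * length(tab$samples)))
  }, numeric(1))
}
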