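# Chaotic ODE benchmark generators: Thomas attractor and the two-level
# Lorenz'96 system, integrated with a fixed-step classical RK4 scheme.

# Strided RK4: advances `substeps` inner steps of size dt/substeps per
# recorded sample, keeping only the recorded states in memory.
rk4_integrate <- function(deriv, y0, dt, n_samples, substeps = 1,
                          transient = 0) {
  h <- dt / substeps
  y <- y0
  out <- matrix(NA_real_, n_samples, length(y0))
  total <- (transient + n_samples) * substeps
  rec <- 0L
  for (step in seq_len(total)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (step > transient * substeps && step %% substeps == 0L) {
      if (!all(is.finite(y))) {
        stopf("integration error: non-finite state at inner step %d (h = %g)",
              step, h)
      }
      rec <- rec + 1L
      out[rec, ] <- y
    }
  }
  out
}

lorenz96_deriv <- function(K, J, F, h, b, c) {
  JK <- J * K
  # cyclic index shifts, precomputed
  xm1 <- c(K, seq_len(K - 1))
  xp1 <- c(seq_len(K - 1) + 1, 1)
  xm2 <- c(K - 1, K, seq_len(K - 2))
  yp1 <- c(seq_len(JK - 1) + 1, 1)
  yp2 <- c(seq_len(JK - 2) + 2, 1, 2)
  ym1 <- c(JK, seq_len(JK - 1))
  ysum_group <- rep(seq_len(K), each = J)
  hcb <- h * c / b
  function(state) {
    x <- state[seq_len(K)]
    y <- state[K + seq_len(JK)]
    ysum <- as.vector(rowsum(y, ysum_group, reorder = TRUE))
    dx <- x[xm1] * (x[xp1] - x[xm2]) - x + F - hcb * ysum
    dy <- c * b * y[yp1] * (y[ym1] - y[yp2]) - c * y +
      hcb * x[ysum_group]
    c(dx, dy)
  }
}

#' Simulate the two-level (multiscale) Lorenz'96 system
#'
#' Integrates the standard two-level Lorenz'96 equations -- `K` slow
#' variables `x_k`, each coupled to `J` fast variables `y_{j,k}` arranged on
#' one cyclic chain:
#' \deqn{\dot x_k = x_{k-1}(x_{k+1} - x_{k-2}) - x_k + F
#'       - (hc/b) \sum_j y_{j,k},}
#' \deqn{\dot y_{j,k} = c b\, y_{j+1,k}(y_{j-1,k} - y_{j+2,k}) - c\, y_{j,k}
#'       + (hc/b)\, x_k,}
#' with a classical fixed-step RK4 scheme. The defaults (`K = 36`, `J = 10`,
#' `b = c = 10`, `h = 1`, sampling step `dt = 0.1`) give the
#' 396-dimensional benchmark (36 slow plus 360 fast dimensions). The fast
#' subsystem's timescale requires sub-stepping below the sampling interval;
#' `substeps` inner RK4 steps are taken per recorded sample.
#'
#' @param n_samples number of recorded states.
#' @param K slow variables; `J` fast variables per slow one.
#' @param J fast variables per slow variable.
#' @param F forcing of the slow system (chaotic regime at the default 10).
#' @param h,b,c coupling, spatial-scale and temporal-scale parameters.
#' @param dt sampling time step.
#' @param substeps inner RK4 steps per sample.
#' @param transient_frac fraction of `n_samples` integrated and discarded
#'   before recording.
#' @param seed integer seed for the random initial perturbation.
#' @return `n_samples x (K + J*K)` trajectory matrix, slow variables first.
#' @export
simulate_lorenz96 <- function(n_samples = 10000, K = 36, J = 10, F = 10,
                              h = 1, b = 10, c = 10, dt = 0.1,
                              substeps = 50, transient_frac = 0.1,
                              seed = NULL) {
  if (dt <= 0 || b <= 0 || c <= 0) {
    stopf("parameter error: dt, b, c must be positive")
  }
  deriv <- lorenz96_deriv(K, J, F, h, b, c)
  y0 <- with_seed(seed, {
    c(F + stats::rnorm(K, sd = 0.1), stats::rnorm(J * K, sd = 0.01))
  })
  rk4_integrate(deriv, y0, dt, n_samples, substeps = substeps,
                transient = ceiling(transient_frac * n_samples))
}

#' Simulate the Thomas cyclically symmetric attractor
#'
#' Integrates `dx/dt = b sin(y) - a x` and its cyclic permutations in three
#' dimensions with fixed-step RK4. Both parameters are exposed; the defaults
#' follow the benchmark setting `a = 1.85`, `b = 10`,
#' `dt = 0.0002882`. In the canonical one-parameter form (`b = 1`) the
#' origin is globally attracting for `a > 1`.
#'
#' @param n_samples number of recorded states.
#' @param a dissipation parameter.
#' @param b amplitude of the sinusoidal coupling.
#' @param dt sampling time step.
#' @param substeps inner RK4 steps per sample.
#' @param transient_frac fraction of `n_samples` discarded before recording.
#' @param x0 initial state; a seeded random state when `NULL`.
#' @param seed integer seed for the initial condition.
#' @return `n_samples x 3` trajectory matrix.
#' @export
simulate_thomas <- function(n_samples = 10000, a = 1.85, b = 10,
                            dt = 0.0002882, substeps = 1,
                            transient_frac = 0.1, x0 = NULL, seed = NULL) {
  if (dt <= 0) stopf("parameter error: dt must be positive")
  deriv <- function(s) {
    c(b * sin(s[2]) - a * s[1],
      b * sin(s[3]) - a * s[2],
      b * sin(s[1]) - a * s[3])
  }
  if (is.null(x0)) {
    x0 <- with_seed(seed, stats::runif(3, -1, 1))
  }
  rk4_integrate(deriv, x0, dt, n_samples, substeps = substeps,
                transient = ceiling(transient_frac * n_samples))
}
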