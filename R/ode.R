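# Adaptive Dormand-Prince RK45 integrator.
#
# The environment the package targets carries no general-purpose ODE solver,
# so a small one is provided here. It is used for the two-compartment PK
# model with Michaelis-Menten elimination (no closed form) and as the
# numerical cross-check route for the GH model, never inside the estimation
# hot loop (the GH model has an exact solution and the PRL pool model has a
# dedicated exponential integrator in compiled code).

# Butcher tableau (Dormand-Prince 5(4))
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84)
)
.dp_c <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)

#' Integrate an ODE system with an adaptive RK45 scheme
#'
#' Dormand-Prince 5(4) with proportional-integral step control. Solution
#' values are returned exactly at `times`; the integrator steps to each
#' requested time so no dense output interpolation is involved.
#'
#' @param rhs function `(t, y) -> dy/dt` returning a numeric vector.
#' @param y0 numeric initial state at `times[1]`.
#' @param times strictly increasing output times (h).
#' @param rtol,atol relative and absolute local error tolerances.
#' @param max_steps safety cap on accepted+rejected steps.
#' @return matrix with `length(times)` rows and `length(y0)` columns.
#' @keywords internal
#' @export
ode_rk45 <- function(rhs, y0, times, rtol = 1e-8, atol = 1e-10,
                     max_steps = 2e5) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  h <- min(diff(times)[1], 0.1)
  k1 <- rhs(t, y)
  steps <- 0L
  for (i in 2:length(times)) {
    tend <- times[i]
    while (t < tend) {
      steps <- steps + 1L
      if (steps > max_steps) {
        stop("ode_rk45: step limit exceeded at t = ", signif(t, 6),
             " (possible stiffness or bad parameters)")
      }
      h <- min(h, tend - t)
      ks <- matrix(0, 7, n)
      ks[1, ] <- k1
      for (s in 1:6) {
        ys <- y + h * as.vector(crossprod(ks[seq_len(s), , drop = FALSE],
                                          .dp_a[[s]]))
        ks[s + 1, ] <- rhs(t + .dp_c[s] * h, ys)
      }
      y5 <- y + h * as.vector(crossprod(ks, .dp_b5))
      y4 <- y + h * as.vector(crossprod(ks, .dp_b4))
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (!is.finite(err)) err <- 2
      if (err <= 1) {
        t <- t + h
        y <- y5
        k1 <- ks[7, ]  # FSAL
      }
      fac <- if (err == 0) 5 else 0.9 * err^(-0.2)
      h <- h * min(5, max(0.2, fac))
    }
    out[i, ] <- y
  }
  out
}
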