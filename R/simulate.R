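#' Numerically integrate the circuit dynamics
#'
#' Integrates the network equation from `x0` with an adaptive, stiff-capable
#' scheme (`deSolve`'s lsoda family; the steep sigmoid at `k = 20` makes the
#' system stiff near threshold). Integration can stop early once the system
#' has equilibrated, i.e. when the infinity norm of the derivative falls
#' below `eq_tol`.
#'
#' @param model A [circuit_model()].
#' @param x0 Initial state (length n).
#' @param input_fn Optional function of time returning the stimulus vector
#'   `u(t)`; `NULL` means no input.
#' @param t_end Final time (> 0).
#' @param dt Output grid step (> 0); the integrator chooses its own internal
#'   steps.
#' @param eq_tol Equilibration tolerance on the infinity norm of the
#'   derivative.
#' @param stop_at_equilibrium Stop as soon as the equilibration criterion is
#'   met.
#' @param atol,rtol Absolute/relative integrator tolerances.
#' @return An object of class `circuit_trajectory` with fields `times`
#'   (increasing grid), `states` (one row per time, columns named by neuron),
#'   `converged` and `terminal_state`.
#' @export
simulate_circuit <- function(model, x0, input_fn = NULL, t_end = 50,
                             dt = 0.1, eq_tol = 1e-7,
                             stop_at_equilibrium = TRUE,
                             atol = 1e-8, rtol = 1e-8) {
  if (!is.numeric(t_end) || t_end <= 0) stop_input("t_end must be positive")
  if (!is.numeric(dt) || dt <= 0) stop_input("dt must be positive")
  x0 <- align_state(x0, model$names)
  deriv <- function(t, y, parms) {
    u <- if (is.null(input_fn)) NULL else input_fn(t)
    list(as.numeric(dynamics_rhs(model, y, u)))
  }
  times <- unique(c(seq(0, t_end, by = dt), t_end))
  rootfn <- function(t, y, parms) {
    u <- if (is.null(input_fn)) NULL else input_fn(t)
    max(abs(dynamics_rhs(model, y, u))) - eq_tol
  }
  out <- if (stop_at_equilibrium) {
    deSolve::lsodar(y = x0, times = times, func = deriv, parms = NULL,
                    rootfunc = rootfn, atol = atol, rtol = rtol)
  } else {
    deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                 method = "lsoda", atol = atol, rtol = rtol)
  }
  states <- unname(as.matrix(out[, -1, drop = FALSE]))
  colnames(states) <- model$names
  if (any(!is.finite(states))) {
    bad <- which(!apply(is.finite(states), 1, all))[1]
    stop_input("integration diverged (non-finite state) at t = ",
               signif(out[bad, 1], 6))
  }
  terminal <- stats::setNames(states[nrow(states), ], model$names)
  u_end <- if (is.null(input_fn)) NULL else input_fn(out[nrow(out), 1])
  converged <- max(abs(dynamics_rhs(model, terminal, u_end))) < eq_tol
  structure(
    list(times = unname(out[, 1]), states = states,
         converged = converged, terminal_state = terminal),
    class = "circuit_trajectory"
  )
}

#' Simulate method for circuit models
#'
#' Thin wrapper so that `simulate(model, x0 = ...)` works with the base
#' generic; see [simulate_circuit()] for the full interface.
#'
#' @param object A [circuit_model()].
#' @param nsim Ignored (the dynamics are deterministic).
#' @param seed Ignored.
#' @param x0 Initial state.
#' @param ... Passed on to [simulate_circuit()].
#' @export
simulate.circuit_model <- function(object, nsim = 1, seed = NULL, x0, ...) {
  simulate_circuit(object, x0 = x0, ...)
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("<circuit_trajectory> %d time points over [0, %g], %s\n",
              length(x$times), max(x$times),
              if (x$converged) "equilibrated" else "not equilibrated"))
  cat("  terminal state:",
      paste(signif(x$terminal_state, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.circuit_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time (model units)",
                    ylab = "relative membrane potential", ...)
  graphics::legend("topright", legend = colnames(x$states), bty = "n",
                   col = seq_len(ncol(x$states)), lty = 1, cex = 0.7)
  invisible(x)
}
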