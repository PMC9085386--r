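#' Sigmoidal synaptic activation
#'
#' Graded chemical transmission is modelled as \eqn{\sigma(v) = 1/(1 +
#' e^{-k v})}. With a steep slope (the default used throughout the package is
#' `k = 20`) the function approximates a switch around zero, which is what
#' gives circuits with recurrent excitation their bistable character.
#'
#' @param v Numeric vector of potentials relative to the threshold.
#' @param k Slope of the sigmoid; must be positive.
#' @return Values in (0, 1), computed in a form that does not overflow for
#'   `|k * v|` up to at least 1000.
#' @examples
#' sigmoid(0, 20)        # 0.5
#' sigmoid(-0.5, 20)     # ~4.5e-5: well below threshold means silent
#' @export
sigmoid <- function(v, k = 20) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0) {
    stop_input("sigmoid slope k must be a single positive number")
  }
  z <- k * v
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Gap-junction Laplacian degree matrix
#'
#' Electrical coupling enters the network dynamics as `(G - L) x`, where `L`
#' is the diagonal matrix of summed conductances per neuron, so that the gap
#' term vanishes on any uniform state.
#'
#' @param G Symmetric nonnegative conductance matrix.
#' @return Diagonal matrix with entry `i` equal to the sum of column `i` of
#'   `G`.
#' @export
gap_laplacian <- function(G) {
  check_gap_matrix(G)
  diag(colSums(G), nrow(G))
}

check_gap_matrix <- function(G) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) {
    stop_input("gap matrix G must be square")
  }
  if (any(!is.finite(G))) stop_input("gap matrix G has non-finite entries")
  if (any(G < 0)) stop_input("gap-junction conductances must be nonnegative")
  if (max(abs(G - t(G))) > 0) {
    bad <- which(G != t(G), arr.ind = TRUE)[1, ]
    stop_input("gap matrix G must be symmetric (first asymmetric pair: ",
               bad[1], ", ", bad[2], ")")
  }
  invisible(G)
}

#' Construct a neuronal circuit model
#'
#' Bundles the signed chemical weight matrix, the symmetric gap-junction
#' conductance matrix and the shared dynamical parameters of the graded
#' membrane-potential model
#' \deqn{\tau \dot x = (G - L - E) x + W \sigma(x - \theta) + B u.}
#' `x` is the vector of membrane potentials relative to rest (dimensionless
#' model units; no millivolt scale is implied). All neurons share the same
#' time constant `tau`, threshold `theta` and sigmoid slope `k`; per-neuron
#' values are deliberately not supported.
#'
#' Matrix orientation: entry `W[i, j]` is the weight of the chemical synapse
#' from presynaptic neuron `j` onto postsynaptic neuron `i` (positive =
#' excitatory, negative = inhibitory). `G` is symmetric; diagonal entries
#' (self gap junctions) are physically inert because `x_l - x_i = 0`, and are
#' dropped with a warning.
#'
#' @param W n-by-n chemical weight matrix (postsynaptic rows).
#' @param G n-by-n gap-junction conductance matrix; defaults to no gaps.
#' @param names Neuron identifiers; taken from `rownames(W)` if present.
#' @param tau Shared time constant (> 0).
#' @param theta Shared chemical threshold.
#' @param k Sigmoid slope (> 0).
#' @param B Input matrix mapping external stimuli to neurons; defaults to the
#'   identity, so inputs address neurons directly.
#' @return An object of class `circuit_model`.
#' @examples
#' m <- circuit_model(W = matrix(2), names = "N1")  # bistable self-loop
#' dynamics_rhs(m, x = 2)                           # ~0: near a fixed point
#' @export
circuit_model <- function(W, G = NULL, names = NULL, tau = 1, theta = 0.5,
                          k = 20, B = NULL) {
  if (!is.matrix(W)) W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) stop_input("chemical weight matrix W must be square")
  if (any(!is.finite(W))) stop_input("W has non-finite entries")
  if (is.null(names)) names <- rownames(W) %||% paste0("n", seq_len(n))
  if (length(names) != n) stop_input("length of names must match nrow(W)")
  if (anyDuplicated(names)) stop_input("neuron names must be unique")
  if (is.null(G)) G <- matrix(0, n, n)
  if (!is.matrix(G)) G <- as.matrix(G)
  if (nrow(G) != n || ncol(G) != n) {
    stop_input("G must have the same dimensions as W")
  }
  check_gap_matrix(G)
  if (any(diag(G) != 0)) {
    warning("dropping inert self gap junctions on the diagonal of G",
            call. = FALSE)
    diag(G) <- 0
  }
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stop_input("tau must be a single positive number")
  }
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0) {
    stop_input("k must be a single positive number")
  }
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta)) {
    stop_input("theta must be a single finite number")
  }
  if (length(tau) > 1 || length(theta) > 1 || length(k) > 1) {
    stop_input("per-neuron tau/theta/k are not supported")
  }
  if (is.null(B)) B <- diag(n)
  if (!is.matrix(B)) B <- as.matrix(B)
  if (nrow(B) != n) stop_input("B must have one row per neuron")
  dimnames(W) <- list(names, names)
  dimnames(G) <- list(names, names)
  rownames(B) <- names
  structure(
    list(names = names, W = W, G = G, L = diag(colSums(G), n),
         tau = tau, theta = theta, k = k, B = B),
    class = "circuit_model"
  )
}

#' @export
print.circuit_model <- function(x, ...) {
  n <- length(x$names)
  cat(sprintf("<circuit_model> %d neuron%s: %s\n", n, if (n == 1) "" else "s",
              paste(utils::head(x$names, 10), collapse = ", ")))
  cat(sprintf("  chemical synapses: %d (%d excitatory, %d inhibitory)\n",
              sum(x$W != 0), sum(x$W > 0), sum(x$W < 0)))
  cat(sprintf("  gap junctions: %d\n", sum(x$G[upper.tri(x$G)] != 0)))
  cat(sprintf("  tau = %g, theta = %g, k = %g\n", x$tau, x$theta, x$k))
  invisible(x)
}

#' @export
summary.circuit_model <- function(object, ...) {
  print(object)
  cat("  |W| range:", paste(range(abs(object$W[object$W != 0])),
                            collapse = " .. "), "\n")
  invisible(object)
}

n_neurons <- function(model) length(model$names)

#' Time derivative of the network state
#'
#' Evaluates \eqn{\dot x = \frac{1}{\tau}[(G - L - E)x + W\sigma(x-\theta) +
#' B u]}. A pure function of its inputs: no state is kept.
#'
#' @param model A [circuit_model()].
#' @param x State vector (length n, optionally named by neuron).
#' @param u External stimulus vector (length `ncol(B)`); `NULL` means no
#'   input.
#' @return Numeric derivative vector named by neuron.
#' @export
dynamics_rhs <- function(model, x, u = NULL) {
  x <- align_state(x, model$names)
  if (any(!is.finite(x))) stop_input("state vector has non-finite entries")
  drive <- (model$G - model$L - diag(n_neurons(model))) %*% x +
    model$W %*% sigmoid(x - model$theta, model$k)
  if (!is.null(u)) {
    if (length(u) != ncol(model$B)) {
      stop_input("input u has length ", length(u), ", expected ",
                 ncol(model$B))
    }
    drive <- drive + model$B %*% u
  }
  stats::setNames(as.numeric(drive) / model$tau, model$names)
}

#' Analytic Jacobian of the network dynamics
#'
#' Returns \eqn{\frac{1}{\tau}[(G - L - E) + W \,\mathrm{diag}(k\,\sigma_j(1 -
#' \sigma_j))]} with \eqn{\sigma_j = \sigma(x_j - \theta)}. Used both for
#' Newton root finding and for eigenvalue-based stability classification.
#'
#' @inheritParams dynamics_rhs
#' @return n-by-n matrix.
#' @export
jacobian_matrix <- function(model, x) {
  x <- align_state(x, model$names)
  s <- sigmoid(x - model$theta, model$k)
  n <- n_neurons(model)
  J <- (model$G - model$L - diag(n)) +
    model$W %*% diag(as.numeric(model$k * s * (1 - s)), n)
  J / model$tau
}

## Residual of the fixed-point condition (tau cancels at equilibrium).
fixed_point_residual <- function(model, x) {
  x <- align_state(x, model$names)
  as.numeric((model$G - model$L - diag(n_neurons(model))) %*% x +
               model$W %*% sigmoid(x - model$theta, model$k))
}

#' Serialize a circuit model to JSON
#'
#' Writes `{names, W, G, tau, theta, k, B}` with `W` in row-major order
#' (postsynaptic rows), the same orientation the constructor expects.
#'
#' @param model A [circuit_model()].
#' @param path File path; if `NULL` the JSON string is returned.
#' @export
write_circuit_json <- function(model, path = NULL) {
  payload <- list(
    names = model$names,
    W = unname(model$W), G = unname(model$G),
    tau = model$tau, theta = model$theta, k = model$k,
    B = unname(model$B)
  )
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a circuit model from JSON
#'
#' Counterpart of [write_circuit_json()]; all `circuit_model` invariants are
#' re-validated on load.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A [circuit_model()].
#' @export
read_circuit_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  req <- c("names", "W", "G", "tau", "theta", "k")
  missing <- setdiff(req, names(obj))
  if (length(missing) > 0) {
    stop_input("circuit JSON is missing fields: ",
               paste(missing, collapse = ", "))
  }
  circuit_model(W = obj$W, G = obj$G, names = obj$names, tau = obj$tau,
                theta = obj$theta, k = obj$k, B = obj$B)
}
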