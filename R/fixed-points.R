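#' Find the fixed points of a circuit in a search box
#'
#' Solves the equilibrium condition \eqn{(G - L - E)x + W\sigma(x - \theta) =
#' 0} by damped Newton iteration with the analytic Jacobian, started from a
#' deterministic multi-start set: the zero vector, the corners of the search
#' box (all of them up to 4096; a seeded subsample beyond that), the 0/1
#' activation patterns of the box dimensions, and `n_starts` seeded
#' latin-hypercube points. Converged roots are kept if they lie inside the
#' box and have residual below `solver_tol`; roots closer than `dedup_tol`
#' in the infinity norm are merged, keeping the smallest residual. Every
#' retained root is classified by the real parts of its Jacobian eigenvalues.
#'
#' The full root set of a multistable circuit contains, besides the
#' attractors, saddle points on the basin boundaries; they are returned and
#' labelled, not hidden. Use [stable_points()] to extract the attractors.
#'
#' @param model A [circuit_model()].
#' @param box Search bounds: a length-2 vector applied to every dimension, or
#'   a 2-by-n matrix of per-dimension (low, high) bounds.
#' @param n_starts Number of latin-hypercube starts (>= 1).
#' @param solver_tol Residual tolerance (infinity norm) for accepting a root.
#' @param dedup_tol Merge radius between distinct roots.
#' @param seed Seed for the start-set generation; the result is reproducible
#'   per seed.
#' @return An object of class `fixed_point_set`.
#' @examples
#' m <- circuit_model(matrix(2), names = "N1")
#' find_fixed_points(m, box = c(-1, 3))  # quiescent, saddle, high state
#' @export
find_fixed_points <- function(model, box = c(-3, 3), n_starts = 500,
                              solver_tol = 1e-9, dedup_tol = 1e-3,
                              seed = 0) {
  n <- n_neurons(model)
  box <- expand_box(box, n)
  if (n_starts < 1) stop_input("n_starts must be at least 1")
  if (any(!is.finite(model$W)) || any(!is.finite(model$G))) {
    stop_input("model matrices contain non-finite entries")
  }
  starts <- fp_start_set(box, n_starts, seed)
  roots <- list()
  residuals <- numeric(0)
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(model, starts[i, ], tol = solver_tol)
    if (is.null(r)) next
    if (any(r < box[1, ] - 1e-6) || any(r > box[2, ] + 1e-6)) next
    res <- max(abs(fixed_point_residual(model, r)))
    dup <- FALSE
    for (j in seq_along(roots)) {
      if (max(abs(roots[[j]] - r)) < dedup_tol) {
        dup <- TRUE
        if (res < residuals[j]) {
          roots[[j]] <- r
          residuals[j] <- res
        }
        break
      }
    }
    if (!dup) {
      roots[[length(roots) + 1]] <- r
      residuals[length(roots)] <- res
    }
  }
  if (length(roots) == 0) {
    message("no fixed point converged in the search box; ",
            "returning an empty set")
  }
  ## deterministic ordering: lexicographic on rounded coordinates
  if (length(roots) > 1) {
    key <- vapply(roots, function(r) paste(sprintf("%+09.4f", r),
                                           collapse = ","), "")
    ord <- order(key)
    roots <- roots[ord]
    residuals <- residuals[ord]
  }
  points <- lapply(seq_along(roots), function(i) {
    new_fixed_point(model, roots[[i]], residuals[i])
  })
  structure(
    list(points = points, search_box = box, n_starts = n_starts,
         dedup_tol = dedup_tol, solver_tol = solver_tol, seed = seed,
         names = model$names),
    class = "fixed_point_set"
  )
}

expand_box <- function(box, n) {
  if (is.matrix(box)) {
    if (nrow(box) != 2 || ncol(box) != n) {
      stop_input("box matrix must be 2-by-n")
    }
  } else {
    if (length(box) != 2) stop_input("box must be c(low, high) or a 2-by-n matrix")
    box <- matrix(rep(box, n), nrow = 2)
  }
  if (any(!is.finite(box))) stop_input("box bounds must be finite")
  if (any(box[1, ] >= box[2, ])) stop_input("box must satisfy low < high")
  box
}

## Deterministic multi-start set: origin, box corners, 0/1 activation
## patterns, and a seeded latin hypercube.
fp_start_set <- function(box, n_starts, seed) {
  n <- ncol(box)
  width <- box[2, ] - box[1, ]
  corners <- if (n <= 12) {
    pat <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sweep(sweep(pat, 2, width, "*"), 2, box[1, ], "+")
  } else {
    pat <- with_seed(seed, matrix(stats::rbinom(4096 * n, 1, 0.5), ncol = n))
    sweep(sweep(pat, 2, width, "*"), 2, box[1, ], "+")
  }
  ## activation-pattern starts: each neuron off (0) or just above threshold
  acts <- if (n <= 12) {
    as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  } else {
    matrix(numeric(0), ncol = n)
  }
  latin <- with_seed(seed, lhs::randomLHS(n_starts, n))
  latin <- sweep(sweep(latin, 2, width, "*"), 2, box[1, ], "+")
  unname(rbind(rep(0, n), corners, acts, latin))
}

## Damped Newton with backtracking on the squared residual.
newton_root <- function(model, x0, tol = 1e-9, max_iter = 200) {
  x <- stats::setNames(as.numeric(x0), model$names)
  for (i in seq_len(max_iter)) {
    F <- fixed_point_residual(model, x)
    if (max(abs(F)) < tol) return(x)
    J <- model$tau * jacobian_matrix(model, x)
    dx <- tryCatch(solve(J, -F), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) return(NULL)
    f0 <- sum(F^2)
    step <- 1
    repeat {
      xn <- x + step * dx
      if (sum(fixed_point_residual(model, xn)^2) < f0 || step < 1e-8) break
      step <- step / 2
    }
    if (step < 1e-8) return(NULL)
    x <- x + step * dx
    if (any(abs(x) > 1e6)) return(NULL)
  }
  F <- fixed_point_residual(model, x)
  if (max(abs(F)) < tol) x else NULL
}

new_fixed_point <- function(model, x, residual) {
  ev <- eigen(jacobian_matrix(model, x), only.values = TRUE)$values
  cls <- stability_from_eigenvalues(ev)
  structure(
    list(x = stats::setNames(as.numeric(x), model$names),
         residual = residual, eigenvalues = ev,
         stability = cls$label, marginal = cls$marginal,
         rounded = round(as.numeric(x), 1)),
    class = "fixed_point"
  )
}

stability_from_eigenvalues <- function(ev, tol = 1e-9) {
  re <- Re(ev)
  marginal <- any(abs(re) < tol)
  label <- if (all(re < tol)) {
    "stable"
  } else if (all(re > -tol)) {
    "unstable"
  } else {
    "saddle"
  }
  list(label = label, marginal = marginal)
}

#' Classify the stability of a fixed point
#'
#' Labels a fixed point by the signs of the real parts of its Jacobian
#' eigenvalues: `stable` (all negative), `unstable` (all positive), `saddle`
#' (mixed). Eigenvalues with `|Re| < 1e-9` mark the point as marginal, in
#' which case a short simulation probe from a small random perturbation
#' decides between `stable` and `unstable`.
#'
#' @param model A [circuit_model()].
#' @param fp A `fixed_point` (from [find_fixed_points()]) or a state vector
#'   at equilibrium.
#' @param probe_radius Perturbation size of the simulation probe.
#' @return Character label with attribute `marginal`.
#' @export
classify_stability <- function(model, fp, probe_radius = 1e-3) {
  x <- if (inherits(fp, "fixed_point")) fp$x else align_state(fp, model$names)
  ev <- eigen(jacobian_matrix(model, x), only.values = TRUE)$values
  cls <- stability_from_eigenvalues(ev)
  label <- cls$label
  if (cls$marginal) {
    pert <- with_seed(7L, stats::runif(length(x), -probe_radius, probe_radius))
    traj <- simulate_circuit(model, x + pert, t_end = 50)
    label <- if (max(abs(traj$terminal_state - x)) < 10 * probe_radius) {
      "stable"
    } else {
      "unstable"
    }
  }
  structure(label, marginal = cls$marginal)
}

#' Extract the attractors of a fixed-point set
#'
#' @param fps A `fixed_point_set`.
#' @return The subset of points classified stable, as a `fixed_point_set`.
#' @export
stable_points <- function(fps) {
  stopifnot(inherits(fps, "fixed_point_set"))
  keep <- vapply(fps$points, function(p) p$stability == "stable", TRUE)
  out <- fps
  out$points <- fps$points[keep]
  out
}

#' @export
length.fixed_point_set <- function(x) length(x$points)

#' @export
print.fixed_point_set <- function(x, ...) {
  st <- vapply(x$points, function(p) p$stability, "")
  cat(sprintf("<fixed_point_set> %d root%s (%d stable, %d saddle, %d unstable)\n",
              length(x$points), if (length(x$points) == 1) "" else "s",
              sum(st == "stable"), sum(st == "saddle"), sum(st == "unstable")))
  for (p in x$points) {
    cat(sprintf("  [%-8s] %s\n", p$stability,
                paste(sprintf("%5.1f", p$rounded), collapse = " ")))
  }
  invisible(x)
}

#' @export
summary.fixed_point_set <- function(object, ...) {
  print(object)
  cat("  residual max:", format(max(c(0, vapply(object$points,
                                                function(p) p$residual, 0)))),
      "\n")
  invisible(object)
}

#' Tabulate a fixed-point set
#'
#' One row per neuron, one column per fixed point, values rounded to one
#' decimal (the reporting precision used throughout the package).
#'
#' @param x A `fixed_point_set`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @param digits Rounding for the reported coordinates.
#' @export
as.data.frame.fixed_point_set <- function(x, row.names = NULL,
                                          optional = FALSE, digits = 1, ...) {
  if (length(x$points) == 0) {
    return(data.frame(neuron = x$names))
  }
  cols <- lapply(x$points, function(p) round(p$x, digits))
  out <- data.frame(neuron = x$names, do.call(cbind, cols))
  names(out) <- c("neuron", paste0("fp", seq_along(x$points)))
  out
}

#' Write a fixed-point set as a tab-separated table
#'
#' Neurons in rows, fixed points in columns, one-decimal precision, plus a
#' stability row.
#'
#' @param fps A `fixed_point_set`.
#' @param path Output file.
#' @export
write_fixed_points_tsv <- function(fps, path) {
  df <- as.data.frame(fps)
  stab <- c("stability", vapply(fps$points, function(p) p$stability, ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(paste(stab, collapse = "\t"), con)
  invisible(path)
}

#' Sweep fixed-point structure along a parameter
#'
#' Calls a user-supplied builder over a grid of parameter values, solves each
#' resulting circuit with shared settings, and records the number of distinct
#' roots and their coordinates. Count transitions between consecutive grid
#' values bracket bifurcation points (for a single neuron with an excitatory
#' self-loop the count jumps from 1 to 3 as the weight grows).
#'
#' @param builder Function mapping a parameter value to a [circuit_model()].
#' @param values Numeric grid (strictly increasing, length >= 2).
#' @param box,n_starts,seed,solver_tol,dedup_tol Passed to
#'   [find_fixed_points()].
#' @return An object of class `bifurcation_trace`: a data frame with columns
#'   `value`, `n_roots`, `n_stable` and an attached list of root coordinate
#'   matrices; per-value builder failures are recorded in the `error` column
#'   and the sweep continues.
#' @export
bifurcation_sweep <- function(builder, values, box = c(-3, 3),
                              n_starts = 200, seed = 0, solver_tol = 1e-9,
                              dedup_tol = 1e-3) {
  if (length(values) < 2) stop_input("need at least two grid values")
  if (any(diff(values) <= 0)) stop_input("grid values must be strictly increasing")
  rows <- vector("list", length(values))
  roots <- vector("list", length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    res <- tryCatch({
      m <- builder(v)
      fps <- find_fixed_points(m, box = box, n_starts = n_starts, seed = seed,
                               solver_tol = solver_tol,
                               dedup_tol = dedup_tol)
      st <- vapply(fps$points, function(p) p$stability, "")
      roots[[i]] <- do.call(rbind, lapply(fps$points, function(p) p$x))
      data.frame(value = v, n_roots = length(fps$points),
                 n_stable = sum(st == "stable"), error = NA_character_)
    }, error = function(e) {
      data.frame(value = v, n_roots = NA_integer_, n_stable = NA_integer_,
                 error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "roots") <- roots
  class(out) <- c("bifurcation_trace", "data.frame")
  out
}

#' @export
plot.bifurcation_trace <- function(x, neuron = 1, ...) {
  roots <- attr(x, "roots")
  xs <- rep(x$value, vapply(roots, function(r) if (is.null(r)) 0L else nrow(r),
                            0L))
  ys <- unlist(lapply(roots, function(r) if (is.null(r)) NULL else r[, neuron]))
  graphics::plot(xs, ys, pch = 16, cex = 0.6,
                 xlab = "parameter value", ylab = "fixed-point coordinate",
                 ...)
  invisible(x)
}
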