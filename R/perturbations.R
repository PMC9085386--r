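#' Specify an in-silico perturbation condition
#'
#' A composable description of a perturbation: removal of whole neurons
#' (laser-ablation analogue), removal of every gap junction, and/or removal
#' of the gap junctions between named pairs.
#'
#' @param remove_neurons Neuron names to delete structurally.
#' @param remove_gap_all Zero the entire gap matrix.
#' @param remove_gap_pairs List of length-2 name vectors (unordered pairs).
#' @param label Condition label for reports.
#' @return An object of class `ablation_spec`.
#' @export
ablation_spec <- function(remove_neurons = character(0),
                          remove_gap_all = FALSE,
                          remove_gap_pairs = list(), label = NULL) {
  if (is.null(label)) {
    parts <- c(
      if (length(remove_neurons) > 0) {
        paste0("ablate ", paste(remove_neurons, collapse = "+"))
      },
      if (remove_gap_all) "all gaps removed",
      if (length(remove_gap_pairs) > 0) {
        paste0("gap ", paste(vapply(remove_gap_pairs, paste, "",
                                    collapse = "-"), collapse = ","),
               " removed")
      }
    )
    label <- if (length(parts) == 0) "normal" else paste(parts,
                                                         collapse = "; ")
  }
  structure(list(remove_neurons = remove_neurons,
                 remove_gap_all = remove_gap_all,
                 remove_gap_pairs = remove_gap_pairs, label = label),
            class = "ablation_spec")
}

#' Ablate neurons from a circuit
#'
#' Structural deletion: the corresponding rows and columns of `W`, `G` and
#' the rows of `B` are removed (the gap Laplacian is recomputed from the
#' reduced `G`), mirroring laser ablation, which removes the cell rather
#' than clamping it silent. Remaining neuron order is preserved.
#'
#' @param model A [circuit_model()].
#' @param names Nonempty subset of the circuit's neurons.
#' @return The reduced [circuit_model()].
#' @export
ablate_neurons <- function(model, names) {
  if (length(names) == 0) stop_input("no neurons named for ablation")
  unknown <- setdiff(names, model$names)
  if (length(unknown) > 0) {
    stop_input("cannot ablate unknown neurons: ",
               paste(unknown, collapse = ", "))
  }
  keep <- setdiff(model$names, names)
  if (length(keep) == 0) {
    stop_input("ablation would leave an empty circuit")
  }
  circuit_model(W = model$W[keep, keep, drop = FALSE],
                G = model$G[keep, keep, drop = FALSE],
                names = keep, tau = model$tau, theta = model$theta,
                k = model$k,
                B = model$B[keep, , drop = FALSE])
}

#' Remove gap junctions from a circuit
#'
#' Zeroes the named symmetric entries of `G` (or all of `G`); chemical
#' synapses are untouched.
#'
#' @param model A [circuit_model()].
#' @param spec An [ablation_spec()], or `NULL` when using the shortcut
#'   arguments.
#' @param pairs List of length-2 name vectors; each names an existing gap
#'   junction.
#' @param all Remove every gap junction.
#' @return The modified [circuit_model()].
#' @export
remove_gap_junctions <- function(model, spec = NULL, pairs = list(),
                                 all = FALSE) {
  if (!is.null(spec)) {
    pairs <- spec$remove_gap_pairs
    all <- spec$remove_gap_all
  }
  G <- model$G
  if (all) {
    G[] <- 0
  }
  for (p in pairs) {
    if (length(p) != 2 || !all(p %in% model$names)) {
      stop_input("gap pair must name two circuit neurons: ",
                 paste(p, collapse = "-"))
    }
    if (model$G[p[1], p[2]] == 0) {
      stop_input("no gap junction exists between ", p[1], " and ", p[2])
    }
    G[p[1], p[2]] <- 0
    G[p[2], p[1]] <- 0
  }
  circuit_model(W = model$W, G = G, names = model$names, tau = model$tau,
                theta = model$theta, k = model$k, B = model$B)
}

apply_ablation_spec <- function(model, spec) {
  out <- model
  if (spec$remove_gap_all || length(spec$remove_gap_pairs) > 0) {
    out <- remove_gap_junctions(out, spec)
  }
  if (length(spec$remove_neurons) > 0) {
    out <- ablate_neurons(out, spec$remove_neurons)
  }
  out
}

## Supra-threshold activation pattern of a state (set of active neurons).
activation_pattern <- function(x, theta) {
  names(x)[x > theta]
}

#' Fixed-point survival screen over perturbation conditions
#'
#' For each condition the perturbed circuit is re-solved with shared solver
#' settings, and each baseline attractor is matched against the perturbed
#' attractors by supra-threshold activation pattern rather than by
#' coordinates: ablation shifts coordinates, but a state's identity is
#' which neurons it keeps active. A baseline attractor whose pattern
#' (restricted to the surviving neurons) is matched by no perturbed
#' attractor — or whose active neurons were all removed — is marked
#' impaired. The quiescent point survives every condition because `x = 0`
#' solves the equilibrium equation up to `sigma(-theta)` leakage.
#'
#' @param model Baseline [circuit_model()].
#' @param conditions Nonempty list of [ablation_spec()]s.
#' @param box,n_starts,seed,solver_tol,dedup_tol Shared
#'   [find_fixed_points()] settings.
#' @return An object of class `ablation_report`: baseline set, per-condition
#'   attractor sets, and the survival matrix (baseline state x condition).
#' @export
ablation_screen <- function(model, conditions, box = c(-3, 3),
                            n_starts = 500, seed = 0, solver_tol = 1e-9,
                            dedup_tol = 1e-3) {
  if (length(conditions) == 0) stop_input("conditions must be nonempty")
  solve_stable <- function(m) {
    stable_points(find_fixed_points(m, box = box, n_starts = n_starts,
                                    seed = seed, solver_tol = solver_tol,
                                    dedup_tol = dedup_tol))
  }
  baseline <- solve_stable(model)
  base_patterns <- lapply(baseline$points, function(p) {
    activation_pattern(p$x, model$theta)
  })
  base_labels <- paste0("S", seq_along(baseline$points))
  results <- list()
  survival <- matrix(NA, nrow = length(base_labels),
                     ncol = length(conditions),
                     dimnames = list(base_labels,
                                     vapply(conditions, function(cd) cd$label,
                                            "")))
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    entry <- tryCatch({
      reduced <- apply_ablation_spec(model, cond)
      fps <- solve_stable(reduced)
      patterns <- lapply(fps$points, function(p) {
        activation_pattern(p$x, reduced$theta)
      })
      for (bi in seq_along(base_patterns)) {
        want_full <- base_patterns[[bi]]
        want <- intersect(want_full, reduced$names)
        lost_all <- length(want_full) > 0 && length(want) == 0
        hit <- any(vapply(patterns, function(p) setequal(p, want), TRUE))
        survival[bi, ci] <- hit && !lost_all
      }
      list(label = cond$label, model = reduced, fixed_points = fps,
           error = NULL)
    }, error = function(e) {
      list(label = cond$label, model = NULL, fixed_points = NULL,
           error = conditionMessage(e))
    })
    results[[ci]] <- entry
  }
  structure(
    list(baseline = baseline, base_labels = base_labels,
         conditions = results, survival = survival, theta = model$theta),
    class = "ablation_report"
  )
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("<ablation_report> %d baseline attractor%s, %d condition%s\n",
              length(x$base_labels),
              if (length(x$base_labels) == 1) "" else "s",
              length(x$conditions),
              if (length(x$conditions) == 1) "" else "s"))
  surv <- ifelse(x$survival, "ok", "impaired")
  print(surv, quote = FALSE)
  invisible(x)
}

#' Tabulate an ablation screen like a fixed-point survival table
#'
#' Produces the neurons x (condition, fixed point) matrix of one-decimal
#' coordinates, with `NA` for impaired states and ablated neurons.
#'
#' @param report An `ablation_report`.
#' @param baseline_model The model the screen was run on (for neuron order).
#' @return A data frame, neurons in rows.
#' @export
ablation_table <- function(report, baseline_model) {
  neurons <- baseline_model$names
  cols <- list(neuron = neurons)
  for (cond in report$conditions) {
    if (!is.null(cond$error)) next
    fps <- cond$fixed_points
    surv_names <- cond$model$names
    for (pi in seq_along(fps$points)) {
      vals <- rep(NA_real_, length(neurons))
      vals[match(surv_names, neurons)] <- round(fps$points[[pi]]$x, 1)
      cols[[paste0(gsub("[^A-Za-z0-9]+", "_", cond$label), "_fp", pi)]] <-
        vals
    }
  }
  as.data.frame(cols)
}

#' Write an ablation screen as TSV
#'
#' @param report An `ablation_report`.
#' @param baseline_model The screened model.
#' @param path Output file.
#' @export
write_ablation_tsv <- function(report, baseline_model, path) {
  utils::write.table(ablation_table(report, baseline_model), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
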