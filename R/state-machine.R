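#' Define a stimulus protocol
#'
#' Protocols perturb the circuit either by resetting initial conditions
#' (`initial-condition` mode: the targeted neurons start at `amplitude`,
#' everything else at the baseline state) or by applying a sustained input
#' through the input matrix `B` for `duration` time units before release
#' (`sustained-input` mode). Activation tables of 0/1 per neuron correspond
#' to the default initial-condition mode with amplitude 1.
#'
#' @param targets Neuron names receiving the stimulus.
#' @param amplitude Stimulus amplitude (model units; default 1).
#' @param mode `"initial-condition"` or `"sustained-input"`.
#' @param duration Stimulus duration (sustained mode only).
#' @param baseline Baseline the untargeted neurons start from: `"zero"`
#'   (activation-table semantics: the stimulus resets the whole circuit, so
#'   its outcome does not depend on the state it interrupts), `"start"` (keep
#'   the current state's values), or a state label present in the fixed-point
#'   set.
#' @param name Optional protocol label.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(targets, amplitude = 1,
                              mode = c("initial-condition", "sustained-input"),
                              duration = NULL, baseline = "zero",
                              name = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(amplitude) || !is.finite(amplitude)) {
    stop_input("amplitude must be finite")
  }
  if (mode == "sustained-input") {
    if (is.null(duration) || duration <= 0) {
      stop_input("sustained-input mode needs a positive duration")
    }
  }
  structure(
    list(targets = targets, amplitude = amplitude, mode = mode,
         duration = duration, baseline = baseline,
         name = name %||% paste0(mode, ":", paste(targets, collapse = "+"))),
    class = "stimulus_protocol"
  )
}

## Labels of the stable points of a set: explicit labels attribute if
## assigned, otherwise S1, S2, ... in set order.
state_labels <- function(fps) {
  st <- stable_points(fps)
  lab <- attr(fps, "state_labels")
  if (is.null(lab)) lab <- paste0("S", seq_along(st$points))
  if (length(lab) != length(st$points)) {
    stop_input("state_labels length does not match number of stable points")
  }
  stats::setNames(st$points, lab)
}

#' Attach state labels to the attractors of a fixed-point set
#'
#' @param fps A `fixed_point_set`.
#' @param labels Character vector, one label per stable point (in set
#'   order).
#' @return The set with a `state_labels` attribute.
#' @export
label_fixed_points <- function(fps, labels) {
  st <- stable_points(fps)
  if (length(labels) != length(st$points)) {
    stop_input("need exactly ", length(st$points), " labels")
  }
  attr(fps, "state_labels") <- labels
  fps
}

match_state <- function(fps, x, radius = 0.05) {
  states <- state_labels(fps)
  for (lab in names(states)) {
    if (max(abs(states[[lab]]$x - x)) < radius) return(lab)
  }
  NA_character_
}

#' Monte-Carlo estimate of attraction domains
#'
#' Samples initial conditions uniformly in a box (seeded), integrates each
#' to equilibrium, and labels it by the stable fixed point its trajectory
#' reaches (within `match_radius` in the infinity norm). Samples whose
#' terminal state matches no attractor are counted as unresolved, never
#' thrown. The labelled fractions plus the unresolved fraction sum to one.
#'
#' @param model A [circuit_model()].
#' @param fps A `fixed_point_set` containing at least one stable point.
#' @param box Sampling box (defaults to the set's search box).
#' @param n_samples Number of initial conditions (>= 1).
#' @param seed RNG seed.
#' @param match_radius Match radius between terminal state and attractor.
#' @param t_end Integration horizon per sample.
#' @return An object of class `basin_estimate`: data frame of samples with
#'   terminal labels, plus `fractions` and `unresolved`.
#' @export
estimate_attraction_domains <- function(model, fps, box = NULL,
                                        n_samples = 200, seed = 0,
                                        match_radius = 0.05, t_end = 100) {
  states <- state_labels(fps)
  if (length(states) < 1) stop_input("fixed-point set has no stable point")
  if (n_samples < 1) stop_input("n_samples must be >= 1")
  n <- n_neurons(model)
  box <- expand_box(box %||% fps$search_box, n)
  samples <- with_seed(seed, {
    matrix(stats::runif(n_samples * n), ncol = n)
  })
  samples <- sweep(sweep(samples, 2, box[2, ] - box[1, ], "*"), 2,
                   box[1, ], "+")
  labels <- character(n_samples)
  for (i in seq_len(n_samples)) {
    traj <- simulate_circuit(model, samples[i, ], t_end = t_end)
    lab <- if (traj$converged) {
      match_state(fps, traj$terminal_state, match_radius)
    } else {
      NA_character_
    }
    labels[i] <- if (is.na(lab)) "unresolved" else lab
  }
  tab <- table(factor(labels, levels = c(names(states), "unresolved")))
  fractions <- as.numeric(tab) / n_samples
  names(fractions) <- names(tab)
  df <- data.frame(samples, label = labels)
  names(df) <- c(model$names, "label")
  structure(
    list(samples = df, fractions = fractions[names(states)],
         unresolved = fractions[["unresolved"]],
         n_samples = n_samples, box = box, seed = seed,
         match_radius = match_radius),
    class = "basin_estimate"
  )
}

#' @export
print.basin_estimate <- function(x, ...) {
  cat(sprintf("<basin_estimate> %d samples\n", x$n_samples))
  for (lab in names(x$fractions)) {
    cat(sprintf("  %-12s %6.1f%%\n", lab, 100 * x$fractions[[lab]]))
  }
  cat(sprintf("  %-12s %6.1f%%\n", "unresolved", 100 * x$unresolved))
  invisible(x)
}

#' Write basin samples to CSV
#'
#' @param basin A `basin_estimate`.
#' @param path Output file (columns: one per neuron, plus terminal label).
#' @export
write_basin_csv <- function(basin, path) {
  utils::write.csv(basin$samples, path, row.names = FALSE)
  invisible(path)
}

#' Run a stimulus protocol and report the reached attractor
#'
#' Applies the protocol from a starting attractor (or the zero state),
#' integrates to equilibrium with no further input, and matches the terminal
#' state to the labelled attractors. `"unresolved"` is returned, with
#' diagnostics attached, when the terminal state matches none.
#'
#' @param model A [circuit_model()].
#' @param protocol A [stimulus_protocol()].
#' @param fps A `fixed_point_set` for the model.
#' @param start Label of the starting attractor; `NULL` uses the protocol's
#'   baseline.
#' @param t_end Integration horizon.
#' @param match_radius Match radius to an attractor.
#' @return The terminal state's label (character), with attributes
#'   `terminal_state` and `converged`.
#' @export
run_protocol <- function(model, protocol, fps, start = NULL, t_end = 200,
                         match_radius = 0.05) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  states <- state_labels(fps)
  bad <- setdiff(protocol$targets, model$names)
  if (length(bad) > 0) {
    stop_input("protocol targets unknown neurons: ",
               paste(bad, collapse = ", "))
  }
  ## Reset-style (initial-condition) protocols define their own initial
  ## state from the protocol baseline, so their outcome is independent of
  ## the current state unless baseline = "start". Sustained stimuli act on
  ## the state the circuit is in.
  base_label <- if (protocol$mode == "initial-condition") {
    if (identical(protocol$baseline, "start")) {
      start %||% stop_input("baseline 'start' needs a start state")
    } else {
      protocol$baseline
    }
  } else {
    start %||% protocol$baseline
  }
  x_base <- if (identical(base_label, "zero")) {
    stats::setNames(rep(0, n_neurons(model)), model$names)
  } else {
    if (!base_label %in% names(states)) {
      stop_input("unknown start state '", base_label, "'")
    }
    states[[base_label]]$x
  }
  if (protocol$mode == "initial-condition") {
    x0 <- x_base
    x0[protocol$targets] <- protocol$amplitude
    traj <- simulate_circuit(model, x0, t_end = t_end)
  } else {
    u_on <- stats::setNames(rep(0, ncol(model$B)), colnames(model$B))
    idx <- match(protocol$targets, model$names)
    u_on[idx] <- protocol$amplitude
    on_traj <- simulate_circuit(model, x_base,
                                input_fn = function(t) u_on,
                                t_end = protocol$duration,
                                stop_at_equilibrium = FALSE)
    traj <- simulate_circuit(model, on_traj$terminal_state, t_end = t_end)
  }
  lab <- if (traj$converged) {
    match_state(fps, traj$terminal_state, match_radius)
  } else {
    NA_character_
  }
  structure(if (is.na(lab)) "unresolved" else lab,
            terminal_state = traj$terminal_state,
            converged = traj$converged)
}

#' Build an attractor-based finite state machine
#'
#' The machine's states are the labelled stable fixed points; its
#' transitions are obtained by running every protocol from every state and
#' recording the attractor reached. The attractors' basins are what make
#' each transition deterministic: a stimulus either leaves the circuit in
#' the current basin or hands it to another one. Unresolved runs are
#' recorded as flagged self-loops.
#'
#' @param model A [circuit_model()].
#' @param fps A `fixed_point_set` with at least one stable point.
#' @param protocols List of [stimulus_protocol()]s (possibly empty).
#' @param ... Passed to [run_protocol()].
#' @return An object of class `state_machine` with `states`, `transitions`
#'   (data frame: state, protocol, target, unresolved flag) and the protocol
#'   registry.
#' @export
build_state_machine <- function(model, fps, protocols = list(), ...) {
  states <- state_labels(fps)
  if (length(states) < 1) stop_input("need at least one stable fixed point")
  rows <- list()
  for (p in protocols) {
    for (s in names(states)) {
      res <- run_protocol(model, p, fps, start = s, ...)
      unresolved <- identical(as.character(res), "unresolved")
      rows[[length(rows) + 1]] <- data.frame(
        state = s, protocol = p$name,
        target = if (unresolved) s else as.character(res),
        unresolved = unresolved
      )
    }
  }
  transitions <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(state = character(), protocol = character(),
               target = character(), unresolved = logical())
  }
  structure(
    list(states = names(states), transitions = transitions,
         protocols = stats::setNames(protocols,
                                     vapply(protocols, function(p) p$name,
                                            ""))),
    class = "state_machine"
  )
}

#' @export
print.state_machine <- function(x, ...) {
  cat(sprintf("<state_machine> states: %s\n", paste(x$states, collapse = ", ")))
  if (nrow(x$transitions) == 0) {
    cat("  (no transitions)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$transitions))) {
    tr <- x$transitions[i, ]
    cat(sprintf("  %s --[%s]--> %s%s\n", tr$state, tr$protocol, tr$target,
                if (tr$unresolved) "  (unresolved)" else ""))
  }
  invisible(x)
}

#' Export a state machine to Graphviz DOT
#'
#' @param machine A `state_machine`.
#' @param path Output file; `NULL` returns the DOT text.
#' @export
write_state_machine_dot <- function(machine, path = NULL) {
  lines <- c("digraph state_machine {",
             paste0("  \"", machine$states, "\";"))
  if (nrow(machine$transitions) > 0) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"%s];",
                              machine$transitions$state,
                              machine$transitions$target,
                              machine$transitions$protocol,
                              ifelse(machine$transitions$unresolved,
                                     " style=dashed", "")))
  }
  lines <- c(lines, "}")
  if (is.null(path)) return(paste(lines, collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}

#' Export a state machine to JSON
#'
#' @param machine A `state_machine`.
#' @param path Output file; `NULL` returns the JSON string.
#' @export
write_state_machine_json <- function(machine, path = NULL) {
  js <- jsonlite::toJSON(list(states = machine$states,
                              transitions = machine$transitions),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
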