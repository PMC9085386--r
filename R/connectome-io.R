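#' Read a connectome from neuron-by-neuron count matrices
#'
#' Reads two square CSV count matrices with identical header-named neuron
#' order: chemical synapses (entry `(i, j)` = number of synapses from neuron
#' `j` onto neuron `i`, the same postsynaptic-row orientation as a circuit's
#' `W`) and gap junctions (symmetric, exact integer equality required).
#' Self-gap entries are dropped with a warning; they are physically inert.
#'
#' @param chem_path CSV of chemical synapse counts.
#' @param gap_path CSV of gap-junction counts.
#' @return A [connectome()].
#' @export
read_adjacency_csv <- function(chem_path, gap_path) {
  chem <- as.matrix(utils::read.csv(chem_path, row.names = 1,
                                    check.names = FALSE))
  gap <- as.matrix(utils::read.csv(gap_path, row.names = 1,
                                   check.names = FALSE))
  if (nrow(chem) != ncol(chem)) stop_input("chemical matrix is not square")
  if (nrow(gap) != ncol(gap)) stop_input("gap matrix is not square")
  if (!identical(rownames(chem), colnames(chem))) {
    stop_input("chemical matrix row/column headers disagree")
  }
  if (!identical(rownames(chem), rownames(gap)) ||
      !identical(colnames(chem), colnames(gap))) {
    stop_input("chemical and gap matrices have different neuron headers")
  }
  if (any(gap != t(gap))) {
    bad <- which(gap != t(gap), arr.ind = TRUE)[1, ]
    stop_input("gap count matrix is asymmetric at pair (",
               rownames(gap)[bad[1]], ", ", colnames(gap)[bad[2]], ")")
  }
  if (any(diag(gap) != 0)) {
    warning("dropping inert self gap junctions", call. = FALSE)
    diag(gap) <- 0
  }
  neurons <- rownames(chem)
  idx <- which(chem != 0, arr.ind = TRUE)
  chem_edges <- data.frame(from = neurons[idx[, 2]], to = neurons[idx[, 1]],
                           count = chem[idx])
  gidx <- which(upper.tri(gap) & gap != 0, arr.ind = TRUE)
  gap_edges <- data.frame(a = neurons[gidx[, 1]], b = neurons[gidx[, 2]],
                          count = gap[gidx])
  connectome(neurons, chem_edges, gap_edges)
}

#' Assign neurons to functional sections and left/right pairs
#'
#' Sections partition the circuit by the behaviour a group promotes (for
#' the command circuit: a forward section AVB+PVC and a backward section
#' AVA+AVD+AVE). Chemical synapses within a section are treated as
#' excitatory, between sections as inhibitory. Pairs record left/right
#' partners; `bistable_pairs` marks the pairs whose neurons show two-level
#' activity and therefore form fixed points.
#'
#' @param sections Named list of neuron-name vectors (a partition).
#' @param pairs List of length-2 name vectors.
#' @param bistable_pairs Subset of `pairs` (as length-2 vectors) that are
#'   state-forming.
#' @return An object of class `group_assignment`.
#' @export
group_assignment <- function(sections, pairs = list(),
                             bistable_pairs = list()) {
  all_neurons <- unlist(sections, use.names = FALSE)
  if (anyDuplicated(all_neurons)) {
    stop_input("sections must be disjoint")
  }
  for (p in c(pairs, bistable_pairs)) {
    if (length(p) != 2) stop_input("pairs must have exactly two members")
  }
  structure(list(sections = sections, pairs = pairs,
                 bistable_pairs = bistable_pairs),
            class = "group_assignment")
}

section_of <- function(groups, neuron) {
  for (s in names(groups$sections)) {
    if (neuron %in% groups$sections[[s]]) return(s)
  }
  NA_character_
}

is_pair <- function(pairs, a, b) {
  any(vapply(pairs, function(p) setequal(p, c(a, b)), TRUE))
}

#' Weight-adjustment rules for building circuits from synapse counts
#'
#' Codifies how raw synapse counts become signed weights: chemical weight
#' magnitudes are monotone in synapse count and capped at `chem_max` /
#' `chem_min` (+1 / -1); connections with at most `weak_count` synapses get
#' the weak weight (~0.1) that keeps them present without driving anything;
#' gap junctions within a left/right pair lie in [1, 2] (monotone in count)
#' to enforce pair synchrony; gap junctions within a section exceed those
#' between sections, whose effective conductance is low regardless of
#' anatomical count (synapse number is a poor proxy for electrical
#' strength). Chemical synapses inside a bistable left/right pair are set to
#' `pair_chem_weight`: two neurons must be strongly reciprocally connected
#' to form a fixed point, and gap junctions between equally active partners
#' carry no current, so the chemical drive has to do the work.
#'
#' @param chem_max,chem_min Caps on chemical weight (+1, -1).
#' @param weak_count Counts up to this get `weak_weight`.
#' @param weak_weight Magnitude for weak connections.
#' @param saturate_count Counts at or above this reach the cap.
#' @param pair_gap_range Gap conductance range for left/right pairs.
#' @param section_gap Gap conductance within a section (non-pair).
#' @param cross_gap Gap conductance between sections.
#' @param pair_chem_weight Chemical weight inside bistable pairs.
#' @return An object of class `adjustment_rules`.
#' @export
adjustment_rules <- function(chem_max = 1, chem_min = -1, weak_count = 2,
                             weak_weight = 0.1, saturate_count = 7,
                             pair_gap_range = c(1, 2), section_gap = 0.5,
                             cross_gap = 0.25, pair_chem_weight = 0.9) {
  stopifnot(chem_max > 0, chem_min < 0, weak_weight > 0,
            saturate_count > weak_count,
            length(pair_gap_range) == 2, pair_gap_range[1] >= 1,
            pair_gap_range[2] <= 2, section_gap > cross_gap)
  structure(list(chem_max = chem_max, chem_min = chem_min,
                 weak_count = weak_count, weak_weight = weak_weight,
                 saturate_count = saturate_count,
                 pair_gap_range = pair_gap_range, section_gap = section_gap,
                 cross_gap = cross_gap,
                 pair_chem_weight = pair_chem_weight),
            class = "adjustment_rules")
}

## Piecewise-linear count -> magnitude map: weak_weight up to weak_count,
## rising linearly to chem_max at saturate_count.
chem_magnitude <- function(count, rules) {
  lo <- rules$weak_count
  hi <- rules$saturate_count
  m <- rules$weak_weight +
    (rules$chem_max - rules$weak_weight) * (count - lo) / (hi - lo)
  pmin(pmax(m, rules$weak_weight), rules$chem_max)
}

pair_gap_magnitude <- function(count, rules) {
  r <- rules$pair_gap_range
  pmin(r[1] + (count - 1) * (r[2] - r[1]) / 26, r[2])
}

#' Build a signed, weighted circuit from a connectome
#'
#' Applies [adjustment_rules()] to a counted [connectome()] and a
#' [group_assignment()]: signs come from section co-membership (within =
#' excitatory, across = inhibitory), chemical magnitudes from the monotone
#' capped count map, gap conductances from the pair/section/cross rules.
#' The construction is sign-safe by design: it never converts a chemical
#' synapse to electrical or vice versa, and an edge's excitatory/inhibitory
#' class is a pure function of the anatomy and the grouping.
#'
#' @param conn A [connectome()].
#' @param groups A [group_assignment()] covering every neuron.
#' @param rules An [adjustment_rules()].
#' @param tau,theta,k Dynamical parameters of the resulting model.
#' @return A [circuit_model()].
#' @export
build_circuit <- function(conn, groups, rules = adjustment_rules(),
                          tau = 1, theta = 0.5, k = 20) {
  neurons <- conn$neurons
  ungrouped <- neurons[vapply(neurons,
                              function(nr) is.na(section_of(groups, nr)),
                              TRUE)]
  if (length(ungrouped) > 0) {
    stop_input("neurons not assigned to a section: ",
               paste(ungrouped, collapse = ", "))
  }
  n <- length(neurons)
  W <- matrix(0, n, n, dimnames = list(neurons, neurons))
  for (i in seq_len(nrow(conn$chem_edges))) {
    e <- conn$chem_edges[i, ]
    same <- identical(section_of(groups, e$from), section_of(groups, e$to))
    mag <- if (same && is_pair(groups$bistable_pairs, e$from, e$to)) {
      rules$pair_chem_weight
    } else {
      chem_magnitude(e$count, rules)
    }
    W[e$to, e$from] <- if (same) mag else -mag
  }
  G <- matrix(0, n, n, dimnames = list(neurons, neurons))
  for (i in seq_len(nrow(conn$gap_edges))) {
    e <- conn$gap_edges[i, ]
    if (e$a == e$b) next
    g <- if (is_pair(groups$pairs, e$a, e$b)) {
      pair_gap_magnitude(e$count, rules)
    } else if (identical(section_of(groups, e$a),
                         section_of(groups, e$b))) {
      rules$section_gap
    } else {
      rules$cross_gap
    }
    G[e$a, e$b] <- g
    G[e$b, e$a] <- g
  }
  circuit_model(W = W, G = G, names = neurons, tau = tau, theta = theta,
                k = k)
}

command_neurons <- c("AVBL", "AVBR", "PVCL", "PVCR", "AVAL", "AVAR",
                     "AVDL", "AVDR", "AVEL", "AVER")

#' Functional grouping of the command interneurons
#'
#' Forward section AVB + PVC, backward section AVA + AVD + AVE, the five
#' left/right pairs, and the three bistable (state-forming) pairs AVB, AVA,
#' AVE.
#'
#' @return A [group_assignment()].
#' @export
command_groups <- function() {
  group_assignment(
    sections = list(
      forward = c("AVBL", "AVBR", "PVCL", "PVCR"),
      backward = c("AVAL", "AVAR", "AVDL", "AVDR", "AVEL", "AVER")
    ),
    pairs = list(c("AVBL", "AVBR"), c("PVCL", "PVCR"), c("AVAL", "AVAR"),
                 c("AVDL", "AVDR"), c("AVEL", "AVER")),
    bistable_pairs = list(c("AVBL", "AVBR"), c("AVAL", "AVAR"),
                          c("AVEL", "AVER"))
  )
}

#' Synthetic synapse-count matrices of the command circuit
#'
#' Reads the packaged count matrices
#' (`extdata/command_chem_synthetic.csv`, `extdata/command_gap_synthetic.csv`).
#' These counts are SYNTHETIC: entries documented in the anatomical
#' literature (the left/right pair statistics of AVA, AVB, AVD, AVE and PVC,
#' the PVCL self-loop, the outsized AVA-PVC gap contact count) are used as
#' printed, and the remaining entries are invented to be qualitatively
#' consistent with the known command-circuit wiring. They exercise the I/O
#' and rule machinery; they are not a connectome release.
#'
#' @return A [connectome()].
#' @export
command_connectome <- function() {
  read_adjacency_csv(
    system.file("extdata", "command_chem_synthetic.csv",
                package = "wormcircuit", mustWork = TRUE),
    system.file("extdata", "command_gap_synthetic.csv",
                package = "wormcircuit", mustWork = TRUE)
  )
}

#' The ten-neuron command-circuit model
#'
#' A packaged model of the forward-backward command circuit (AVBL/R, PVCL/R,
#' AVAL/R, AVDL/R, AVEL/R) with parameters `tau = 1`, `theta = 0.5`,
#' `k = 20`. The weights are this package's own manual adjustment of the
#' synthetic count matrices under the [adjustment_rules()] constraints (the
#' sign and support pattern equals the rule-derived one; magnitudes were
#' tuned by hand, as count-to-strength maps are underdetermined). Its
#' attractors are the three locomotor states:
#' \describe{
#'   \item{forward}{AVBL/R above threshold, every other neuron at or below
#'     zero;}
#'   \item{backward}{AVAL/R and AVEL/R above threshold, AVDL/R mildly
#'     positive, AVBL/R and PVCL/R inhibited;}
#'   \item{quiescent}{all neurons at zero (to one decimal).}
#' }
#'
#' @return A [circuit_model()].
#' @export
command_circuit_fixture <- function() {
  nm <- command_neurons
  W <- matrix(0, 10, 10, dimnames = list(nm, nm))
  set_w <- function(from, to, w) W[to, from] <<- w
  ## forward section, excitatory
  set_w("AVBL", "AVBR", 0.9);  set_w("AVBR", "AVBL", 0.9)
  set_w("PVCL", "PVCR", 0.2);  set_w("PVCR", "PVCL", 0.2)
  set_w("PVCL", "PVCL", 0.1)
  set_w("PVCL", "AVBL", 0.6);  set_w("PVCR", "AVBR", 0.6)
  set_w("PVCL", "AVBR", 0.3);  set_w("PVCR", "AVBL", 0.3)
  ## backward section, excitatory
  set_w("AVAL", "AVAR", 0.35); set_w("AVAR", "AVAL", 0.35)
  set_w("AVER", "AVEL", 0.1)
  set_w("AVEL", "AVAL", 0.6);  set_w("AVEL", "AVAR", 0.6)
  set_w("AVER", "AVAR", 0.6);  set_w("AVER", "AVAL", 0.6)
  set_w("AVAL", "AVEL", 0.6);  set_w("AVAL", "AVER", 0.6)
  set_w("AVAR", "AVER", 0.6);  set_w("AVAR", "AVEL", 0.6)
  set_w("AVDL", "AVAL", 0.8);  set_w("AVDL", "AVAR", 0.4)
  set_w("AVDR", "AVAR", 0.8);  set_w("AVDR", "AVAL", 0.4)
  set_w("AVDL", "AVDR", 0.15); set_w("AVDR", "AVDL", 0.15)
  set_w("AVAL", "AVDL", 0.05); set_w("AVAR", "AVDR", 0.05)
  ## cross-section, inhibitory
  set_w("AVBL", "AVAL", -0.5); set_w("AVBL", "AVAR", -0.5)
  set_w("AVBR", "AVAR", -0.5); set_w("AVBR", "AVAL", -0.5)
  set_w("AVBL", "AVDL", -0.3); set_w("AVBR", "AVDR", -0.3)
  set_w("AVBL", "AVEL", -0.4); set_w("AVBR", "AVER", -0.4)
  set_w("AVAL", "AVBL", -0.5); set_w("AVAR", "AVBR", -0.5)
  set_w("AVEL", "AVBL", -0.4); set_w("AVER", "AVBR", -0.4)
  set_w("AVAL", "PVCL", -0.4); set_w("AVAR", "PVCR", -0.4)
  set_w("AVEL", "PVCL", -0.3); set_w("AVER", "PVCR", -0.3)
  set_w("PVCL", "AVAL", -0.3); set_w("PVCR", "AVAR", -0.3)
  G <- matrix(0, 10, 10, dimnames = list(nm, nm))
  set_g <- function(a, b, g) { G[a, b] <<- g; G[b, a] <<- g }
  set_g("AVBL", "AVBR", 1.5)
  set_g("AVAL", "AVAR", 1.5)
  set_g("AVDL", "AVDR", 1.5)
  set_g("AVEL", "AVER", 1.0)
  set_g("PVCL", "PVCR", 2.0)
  set_g("AVAL", "PVCL", 0.12); set_g("AVAR", "PVCR", 0.12)
  set_g("AVDL", "AVAL", 0.15); set_g("AVDR", "AVAR", 0.15)
  circuit_model(W = W, G = G, names = nm, tau = 1, theta = 0.5, k = 20)
}

#' Label the command-circuit attractors by locomotor state
#'
#' Matches each stable fixed point's supra-threshold activation pattern to
#' the forward (AVB-active), backward (AVA and AVE active) and quiescent
#' (nothing active, near-zero) states and attaches those labels. The
#' numbering convention follows the survival table: state 1 = forward,
#' state 2 = backward, state 3 = quiescent.
#'
#' @param fps A `fixed_point_set` solved from the command circuit (or a
#'   perturbed version of it).
#' @param theta Threshold used for the activation pattern.
#' @return The set with labels among `"forward"`, `"backward"`,
#'   `"quiescent"` (unmatched attractors get `"other<k>"`).
#' @export
command_state_labels <- function(fps, theta = 0.5) {
  st <- stable_points(fps)
  labels <- character(length(st$points))
  for (i in seq_along(st$points)) {
    p <- st$points[[i]]
    act <- activation_pattern(p$x, theta)
    labels[i] <- if (length(act) > 0 && all(grepl("^AVB", act))) {
      "forward"
    } else if (any(grepl("^AVA", act)) && any(grepl("^AVE", act))) {
      "backward"
    } else if (length(act) == 0 && max(abs(p$x)) < 0.01) {
      "quiescent"
    } else {
      paste0("other", i)
    }
  }
  label_fixed_points(fps, labels)
}

#' Deduce structural constraints from functional roles
#'
#' Inverts the structure-to-function logic: given which neuron groups form
#' the bistable states and which support the corresponding attraction
#' domains, emits the connectivity properties the circuit must have for
#' those states to exist. One constraint is emitted per applicable rule
#' instance, deterministically ordered:
#' \itemize{
#'   \item state-forming pairs must be strongly reciprocally connected
#'     (`strong-reciprocal`);
#'   \item pairs without bistability must not strongly activate each other
#'     chemically (`weak-or-gap-only`);
#'   \item groups forming opposite states tend to inhibit each other
#'     (`mutual-inhibition`);
#'   \item basin-forming neurons either excite the state they support or
#'     inhibit the opposite state
#'     (`basin-support-excitation-or-cross-inhibition`);
#'   \item state-forming neurons may inhibit the basin formers of the
#'     opposite state (`state-suppresses-basin-of-opposite`).
#' }
#'
#' @param roles List with `state_groups` (named list of >= 1 neuron-name
#'   vectors, one per state), optional `basin_groups` (named like
#'   `state_groups`; name identifies the state a group supports) and
#'   optional `pairs` (left/right partners inside the groups).
#' @return Data frame of constraints: kind, subject, object, rationale.
#' @export
deduce_structure_constraints <- function(roles) {
  sg <- roles$state_groups
  if (is.null(sg) || length(sg) == 0) {
    stop_input("roles$state_groups must name at least one group")
  }
  bg <- roles$basin_groups %||% list()
  pairs <- roles$pairs %||% list()
  overlap <- intersect(unlist(sg), unlist(bg))
  if (length(overlap) > 0) {
    stop_input("state and basin groups must be disjoint: ",
               paste(overlap, collapse = ", "))
  }
  rows <- list()
  add <- function(kind, subject, object, rationale) {
    rows[[length(rows) + 1]] <<- data.frame(kind = kind, subject = subject,
                                            object = object,
                                            rationale = rationale)
  }
  in_group <- function(p, group) all(p %in% group)
  for (s in names(sg)) {
    for (p in pairs) {
      if (in_group(p, sg[[s]])) {
        add("strong-reciprocal", paste(p, collapse = "-"),
            paste(p, collapse = "-"),
            "two neurons must be strongly connected to form a fixed point")
      }
    }
  }
  for (s in names(bg)) {
    for (p in pairs) {
      if (in_group(p, bg[[s]])) {
        add("weak-or-gap-only", paste(p, collapse = "-"),
            paste(p, collapse = "-"),
            paste("neurons without bistability do not strongly activate",
                  "each other chemically"))
      }
    }
  }
  states <- names(sg)
  if (length(states) >= 2) {
    for (i in seq_along(states)) {
      for (j in seq_along(states)) {
        if (i >= j) next
        add("mutual-inhibition", paste(sg[[states[i]]], collapse = "/"),
            paste(sg[[states[j]]], collapse = "/"),
            "groups forming opposite states tend to inhibit each other")
      }
    }
  }
  for (s in names(bg)) {
    own <- sg[[s]]
    others <- unlist(sg[setdiff(names(sg), s)], use.names = FALSE)
    add("basin-support-excitation-or-cross-inhibition",
        paste(bg[[s]], collapse = "/"),
        paste(c(paste(own, collapse = "/"),
                if (length(others) > 0) paste(others, collapse = "/")),
              collapse = " | "),
        paste("basin formers excite their state formers or inhibit the",
              "opposite state formers"))
    if (length(others) > 0) {
      add("state-suppresses-basin-of-opposite",
          paste(others, collapse = "/"), paste(bg[[s]], collapse = "/"),
          paste("state formers may inhibit the basin formers of the",
                "opposite state"))
    }
  }
  do.call(rbind, rows)
}
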