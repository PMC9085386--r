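# Independent oracles: dense scans, finite differences, exhaustive
# enumeration. These never call the solver paths they check.

# All roots of the 1-neuron equilibrium -x + w*sigma(x - theta) = 0 by a
# dense sign-change scan refined with uniroot.
grid_scan_roots_1d <- function(w, box = c(-1, 3), theta = 0.5, k = 20,
                               step = 1e-3) {
  f <- function(x) -x + w / (1 + exp(-k * (x - theta)))
  xs <- seq(box[1], box[2], by = step)
  fx <- f(xs)
  roots <- c()
  for (i in seq_len(length(xs) - 1)) {
    if (fx[i] == 0) roots <- c(roots, xs[i])
    if (fx[i] * fx[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(f, c(xs[i], xs[i + 1]),
                                       tol = 1e-12)$root)
    }
  }
  sort(unique(roots))
}

# For two neurons coupled only by mutual excitation the equilibria lie on
# the diagonal and solve -x + w*sigma(x - theta) = 0, so the 1-d scan is an
# exact oracle for the 2-d circuit.
grid_scan_roots_symmetric_pair <- function(w, box = c(-1, 3), theta = 0.5,
                                           k = 20) {
  grid_scan_roots_1d(w, box = box, theta = theta, k = k)
}

fd_jacobian <- function(model, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n)
    e[j] <- h
    J[, j] <- (dynamics_rhs(model, x + e) - dynamics_rhs(model, x - e)) /
      (2 * h)
  }
  J
}

# Brute-force motif counts straight off dense count matrices.
brute_motif_counts <- function(chem, gap) {
  n <- nrow(chem)
  self_chem <- sum(diag(chem) > 0)
  self_chem_gap <- sum(diag(chem) > 0 & diag(gap) > 0)
  pair_chem <- 0
  pair_chem_gap <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (chem[i, j] > 0 && chem[j, i] > 0) {
        pair_chem <- pair_chem + 1
        if (gap[i, j] > 0) pair_chem_gap <- pair_chem_gap + 1
      }
    }
  }
  c(self_chem = self_chem, self_chem_gap = self_chem_gap,
    pair_chem = pair_chem, pair_chem_gap = pair_chem_gap)
}

# Exhaustive simple-cycle enumeration over an edge data frame
# (from, to, sign, type) by checking every ordered node subset. Returns a
# sorted character key per cycle (anchored at its smallest node) so two
# enumerations can be compared set-wise. Pure-gap 2-cycles that reuse one
# junction are excluded, matching the package convention.
brute_force_cycles <- function(edges, nodes, max_len) {
  has_edge <- function(a, b) which(edges$from == a & edges$to == b)
  keys <- character(0)
  # length-1 cycles
  for (v in nodes) {
    for (ei in has_edge(v, v)) keys <- c(keys, paste0(v, "#", ei))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (len in 2:max_len) {
    if (len > length(nodes)) break
    subsets <- utils::combn(nodes, len, simplify = FALSE)
    for (sub in subsets) {
      anchor <- sort(sub)[1]
      rest <- setdiff(sub, anchor)
      for (p in perms(rest)) {
        cyc <- c(anchor, p)
        nxt <- c(cyc[-1], cyc[1])
        legs <- lapply(seq_along(cyc),
                       function(i) has_edge(cyc[i], nxt[i]))
        if (any(vapply(legs, length, 0L) == 0)) next
        combos <- expand.grid(legs)
        for (ri in seq_len(nrow(combos))) {
          eis <- as.integer(combos[ri, ])
          if (len == 2 && all(edges$type[eis] == "gap") &&
              edges$from[eis[1]] == edges$to[eis[2]]) {
            next
          }
          keys <- c(keys, paste0(paste(cyc, collapse = ">"), "#",
                                 paste(eis, collapse = ",")))
        }
      }
    }
  }
  sort(unique(keys))
}

# Key for a feedback_loop in the same format (requires the edge data frame
# used to build the loops, with matching row indices).
loop_key <- function(loop, edges) {
  nodes <- loop$nodes
  anchor_pos <- which.min(match(nodes, sort(nodes)))
  rot <- if (anchor_pos == 1) seq_along(nodes) else {
    c(anchor_pos:length(nodes), 1:(anchor_pos - 1))
  }
  cyc <- nodes[rot]
  eis <- integer(length(cyc))
  e <- loop$edges[rot, , drop = FALSE]
  for (i in seq_along(cyc)) {
    eis[i] <- which(edges$from == e$from[i] & edges$to == e$to[i] &
                      edges$type == e$type[i] & edges$sign == e$sign[i])[1]
  }
  if (length(cyc) == 1) return(paste0(cyc, "#", eis))
  paste0(paste(cyc, collapse = ">"), "#", paste(eis, collapse = ","))
}
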