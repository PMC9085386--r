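#' Construct a connectome
#'
#' A light container for anatomical connectivity: directed chemical edges
#' with synapse counts (and optional signs) and undirected gap-junction
#' edges, stored once per unordered pair.
#'
#' @param neurons Character vector of neuron identifiers.
#' @param chem_edges Data frame with columns `from`, `to`, `count` and
#'   optionally `sign` (+1/-1).
#' @param gap_edges Data frame with columns `a`, `b`, `count`.
#' @return An object of class `connectome`.
#' @export
connectome <- function(neurons, chem_edges = NULL, gap_edges = NULL) {
  empty_chem <- data.frame(from = character(), to = character(),
                           count = numeric(), sign = numeric())
  empty_gap <- data.frame(a = character(), b = character(), count = numeric())
  chem_edges <- chem_edges %||% empty_chem
  gap_edges <- gap_edges %||% empty_gap
  if (!all(c("from", "to", "count") %in% names(chem_edges))) {
    stop_input("chem_edges needs columns from, to, count")
  }
  if (!"sign" %in% names(chem_edges)) chem_edges$sign <- NA_real_
  if (!all(c("a", "b", "count") %in% names(gap_edges))) {
    stop_input("gap_edges needs columns a, b, count")
  }
  bad <- setdiff(c(chem_edges$from, chem_edges$to, gap_edges$a, gap_edges$b),
                 neurons)
  if (length(bad) > 0) {
    stop_input("edges reference unknown neurons: ", paste(bad, collapse = ", "))
  }
  if (nrow(chem_edges) > 0 && any(chem_edges$count < 1)) {
    stop_input("chemical synapse counts must be >= 1")
  }
  if (nrow(gap_edges) > 0) {
    if (any(gap_edges$count < 1)) stop_input("gap-junction counts must be >= 1")
    ## canonical order so each unordered pair is stored once
    swap <- gap_edges$a > gap_edges$b
    tmp <- gap_edges$a[swap]
    gap_edges$a[swap] <- gap_edges$b[swap]
    gap_edges$b[swap] <- tmp
    key <- paste(gap_edges$a, gap_edges$b)
    if (anyDuplicated(key)) stop_input("duplicate gap edges for a pair")
  }
  structure(list(neurons = neurons, chem_edges = chem_edges,
                 gap_edges = gap_edges),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d neurons, %d chemical edges, %d gap edges\n",
              length(x$neurons), nrow(x$chem_edges), nrow(x$gap_edges)))
  invisible(x)
}

has_gap <- function(conn, a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  any(conn$gap_edges$a == lo & conn$gap_edges$b == hi)
}

#' Census of bistability-capable motifs
#'
#' Counts the four recurrent motif classes whose positive feedback can
#' support multiple fixed points: neurons with a chemical self-loop
#' (`self_chem`), those whose self-connection is both chemical and
#' electrical (`self_chem_gap`), unordered neuron pairs reciprocally
#' connected by chemical synapses (`pair_chem`), and such pairs that also
#' share a gap junction (`pair_chem_gap`). Classes are nested:
#' `self_chem_gap` hits are a subset of `self_chem`, and `pair_chem_gap` of
#' `pair_chem`; exclusive counts are derivable by subtraction.
#'
#' @param conn A [connectome()].
#' @return An object of class `motif_census` with `counts` and per-class
#'   `hits` (neuron tuples).
#' @export
scan_bistability_motifs <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  ce <- conn$chem_edges
  self_chem <- sort(unique(ce$from[ce$from == ce$to]))
  self_gap <- character(0)  # self gap junctions are inert and not stored
  self_chem_gap <- sort(intersect(
    self_chem,
    conn$gap_edges$a[conn$gap_edges$a == conn$gap_edges$b]
  ))
  dir_key <- unique(paste(ce$from, ce$to, sep = "\r"))
  parts <- strsplit(dir_key, "\r", fixed = TRUE)
  from <- vapply(parts, `[`, "", 1)
  to <- vapply(parts, `[`, "", 2)
  off <- from != to
  from <- from[off]
  to <- to[off]
  fwd <- paste(pmin(from, to), pmax(from, to))
  recip <- names(which(table(fwd) == 2))
  pair_chem <- sort(recip %||% character(0))
  pair_chem_gap <- pair_chem[vapply(strsplit(pair_chem, " "), function(p) {
    has_gap(conn, p[1], p[2])
  }, TRUE)]
  structure(
    list(counts = c(self_chem = length(self_chem),
                    self_chem_gap = length(self_chem_gap),
                    pair_chem = length(pair_chem),
                    pair_chem_gap = length(pair_chem_gap)),
         hits = list(self_chem = self_chem, self_chem_gap = self_chem_gap,
                     pair_chem = pair_chem, pair_chem_gap = pair_chem_gap)),
    class = "motif_census"
  )
}

#' @export
print.motif_census <- function(x, ...) {
  cat("<motif_census>\n")
  cat(sprintf("  chemical self-loops:              %d\n", x$counts["self_chem"]))
  cat(sprintf("    ... also electrical:            %d\n",
              x$counts["self_chem_gap"]))
  cat(sprintf("  reciprocal chemical pairs:        %d\n", x$counts["pair_chem"]))
  cat(sprintf("    ... also sharing a gap junction:%d\n",
              x$counts["pair_chem_gap"]))
  invisible(x)
}

## Signed directed edge list for loop enumeration. Chemical edges keep their
## sign; each gap junction expands to two opposed positive edges.
signed_edge_list <- function(x) {
  if (inherits(x, "circuit_model")) {
    idx <- which(x$W != 0, arr.ind = TRUE)
    chem <- data.frame(from = x$names[idx[, 2]], to = x$names[idx[, 1]],
                       sign = sign(x$W[idx]), type = "chemical")
    gidx <- which(upper.tri(x$G) & x$G != 0, arr.ind = TRUE)
    gap <- if (nrow(gidx) > 0) {
      a <- x$names[gidx[, 1]]
      b <- x$names[gidx[, 2]]
      data.frame(from = c(a, b), to = c(b, a), sign = 1, type = "gap")
    } else {
      data.frame(from = character(), to = character(), sign = numeric(),
                 type = character())
    }
    list(nodes = x$names, edges = rbind(chem, gap))
  } else if (inherits(x, "connectome")) {
    ce <- x$chem_edges
    if (nrow(ce) > 0 && any(is.na(ce$sign))) {
      bad <- ce[is.na(ce$sign), , drop = FALSE][1, ]
      stop_input("chemical edge ", bad$from, " -> ", bad$to,
                 " carries no sign; loop enumeration needs signed edges")
    }
    chem <- data.frame(from = ce$from, to = ce$to, sign = ce$sign,
                       type = "chemical")
    ge <- x$gap_edges
    gap <- data.frame(from = c(ge$a, ge$b), to = c(ge$b, ge$a),
                      sign = rep(1, 2 * nrow(ge)),
                      type = rep("gap", 2 * nrow(ge)))
    list(nodes = x$neurons, edges = rbind(chem, gap))
  } else {
    stop_input("expected a circuit_model or a signed connectome")
  }
}

#' Enumerate feedback loops of a signed circuit
#'
#' Enumerates simple directed cycles up to `max_len` over the signed edge
#' set (gap junctions contribute two opposed positive directed edges). Each
#' loop records its node cycle, edge types and signs, the product of
#' chemical-edge signs, and whether every chemical edge in it is excitatory.
#' Parallel chemical/electrical edges between the same neurons are treated
#' as distinct, so a pair coupled both ways yields both loop variants.
#'
#' @param x A [circuit_model()] or a signed [connectome()].
#' @param max_len Maximum cycle length (>= 1).
#' @return List of `feedback_loop` objects, deterministically ordered.
#' @export
enumerate_feedback_loops <- function(x, max_len = 3) {
  if (max_len < 1) stop_input("max_len must be >= 1")
  g <- signed_edge_list(x)
  nodes <- g$nodes
  edges <- g$edges
  if (nrow(edges) == 0) return(list())
  loops <- list()
  edge_idx_by_from <- split(seq_len(nrow(edges)), edges$from)
  ## DFS over simple paths anchored at the smallest node of each cycle
  rank <- stats::setNames(seq_along(nodes), nodes)
  dfs <- function(anchor, node, path_nodes, path_edges) {
    for (ei in edge_idx_by_from[[node]] %||% integer(0)) {
      nxt <- edges$to[ei]
      if (nxt == anchor) {
        loops[[length(loops) + 1]] <<- c(path_edges, ei)
      } else if (!(nxt %in% path_nodes) && rank[nxt] > rank[anchor] &&
                 length(path_nodes) < max_len) {
        dfs(anchor, nxt, c(path_nodes, nxt), c(path_edges, ei))
      }
    }
  }
  for (a in nodes) {
    if (is.null(edge_idx_by_from[[a]])) next
    dfs(a, a, a, integer(0))
  }
  ## drop degenerate 2-cycles that reuse one gap junction in both directions
  keep <- vapply(loops, function(eis) {
    if (length(eis) != 2) return(TRUE)
    e1 <- edges[eis[1], ]
    e2 <- edges[eis[2], ]
    !(e1$type == "gap" && e2$type == "gap" &&
        e1$from == e2$to && e1$to == e2$from)
  }, TRUE)
  loops <- loops[keep]
  out <- lapply(loops, function(eis) {
    e <- edges[eis, , drop = FALSE]
    chem_signs <- e$sign[e$type == "chemical"]
    structure(
      list(nodes = e$from, edges = e,
           length = nrow(e),
           sign_product = prod(c(1, chem_signs)),
           excitatory_only = length(chem_signs) > 0 && all(chem_signs > 0)),
      class = "feedback_loop"
    )
  })
  ## deterministic order: by length then node sequence
  key <- vapply(out, function(l) sprintf("%03d|%s", l$length,
                                         paste(l$nodes, collapse = ">")), "")
  out[order(key)]
}

#' @export
print.feedback_loop <- function(x, ...) {
  cat(sprintf("<feedback_loop> %s (len %d, sign %+d, %s)\n",
              paste(c(x$nodes, x$nodes[1]), collapse = " -> "), x$length,
              x$sign_product,
              if (x$excitatory_only) "all-excitatory chemical"
              else "mixed composition"))
  invisible(x)
}

#' Check the positive-feedback sufficiency condition for multistability
#'
#' A motif can support multiple fixed points if (i) it contains at least one
#' positive feedback loop dominated by excitatory chemical synapses and (ii)
#' its weights can be adjusted without changing any synapse's
#' chemical/electrical or excitatory/inhibitory character. This predicate
#' checks condition (i); condition (ii) concerns weight adjustability and is
#' reported as a note rather than verified numerically.
#'
#' Under the default strict reading, "dominated by excitatory chemical
#' synapses" requires a loop whose chemical edges are all excitatory (every
#' worked example of the condition — self-loops, the AVA pair — is of this
#' form). With `strict = FALSE`, any loop with positive sign product
#' qualifies, which admits mutual inhibition; the two readings are both
#' available because the boundary case is genuinely ambiguous.
#'
#' @param x A [circuit_model()] or signed [connectome()].
#' @param max_len Maximum loop length searched (defaults to circuit size).
#' @param strict Require all chemical edges in the witness loop excitatory.
#' @return List with `satisfied`, `witness` (shortest qualifying loop or
#'   `NULL`) and `note`.
#' @export
check_sufficiency <- function(x, max_len = NULL, strict = TRUE) {
  n <- if (inherits(x, "circuit_model")) n_neurons(x) else length(x$neurons)
  max_len <- max_len %||% n
  loops <- enumerate_feedback_loops(x, max_len = max_len)
  ok <- vapply(loops, function(l) {
    has_chem <- any(l$edges$type == "chemical")
    if (strict) {
      has_chem && l$sign_product > 0 && l$excitatory_only
    } else {
      has_chem && l$sign_product > 0
    }
  }, TRUE)
  witness <- if (any(ok)) loops[ok][[which.min(vapply(loops[ok],
                                                      function(l) l$length,
                                                      0))]] else NULL
  list(
    satisfied = any(ok),
    witness = witness,
    note = paste("condition (ii) (weights adjustable without changing",
                 "synapse character) is assumed, not checked numerically")
  )
}
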