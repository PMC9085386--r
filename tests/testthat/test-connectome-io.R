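write_count_csvs <- function(chem, gap, nms) {
  dimnames(chem) <- dimnames(gap) <- list(nms, nms)
  tmp_c <- withr::local_tempfile(fileext = ".csv",
                                 .local_envir = parent.frame())
  tmp_g <- withr::local_tempfile(fileext = ".csv",
                                 .local_envir = parent.frame())
  write.csv(chem, tmp_c)
  write.csv(gap, tmp_g)
  c(tmp_c, tmp_g)
}

test_that("adjacency CSVs are read with postsynaptic-row orientation", {
  chem <- matrix(c(0, 1, 3, 0), 2, 2)  # entry (i, j) = count j -> i
  gap <- matrix(c(0, 8, 8, 0), 2, 2)
  paths <- write_count_csvs(chem, gap, c("A", "B"))
  conn <- read_adjacency_csv(paths[1], paths[2])
  e <- conn$chem_edges[order(conn$chem_edges$from), ]
  expect_equal(e$from, c("A", "B"))
  expect_equal(e$to, c("B", "A"))
  expect_equal(e$count[e$from == "B"], 3)  # chem[1, 2] = 3 means B -> A
  expect_equal(nrow(conn$gap_edges), 1)
  expect_equal(conn$gap_edges$count, 8)
})

test_that("malformed adjacency input is rejected with precise errors", {
  nms <- c("A", "B")
  paths <- write_count_csvs(matrix(0, 2, 2),
                            matrix(c(0, 2, 1, 0), 2, 2), nms)
  expect_error(read_adjacency_csv(paths[1], paths[2]), "asymmetric")
  # header mismatch between the two files
  tmp_c <- withr::local_tempfile(fileext = ".csv")
  tmp_g <- withr::local_tempfile(fileext = ".csv")
  cm <- matrix(0, 2, 2, dimnames = list(nms, nms))
  gm <- matrix(0, 2, 2, dimnames = list(c("A", "C"), c("A", "C")))
  write.csv(cm, tmp_c)
  write.csv(gm, tmp_g)
  expect_error(read_adjacency_csv(tmp_c, tmp_g), "headers")
  # nonsquare input
  tmp_n <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(A = c(0, 1), B = c(1, 0), C = c(0, 0),
                       row.names = nms), tmp_n)
  expect_error(read_adjacency_csv(tmp_n, tmp_c), "square")
})

test_that("build_circuit applies the sign and magnitude rules", {
  nms <- c("AVAL", "AVAR", "PVCL")
  chem <- matrix(0, 3, 3, dimnames = list(nms, nms))
  chem["AVAR", "AVAL"] <- 9   # same section, saturating count
  chem["AVAL", "PVCL"] <- 4   # cross section
  chem["PVCL", "AVAL"] <- 1   # cross section, weak
  gap <- matrix(0, 3, 3, dimnames = list(nms, nms))
  gap["AVAL", "AVAR"] <- gap["AVAR", "AVAL"] <- 8
  gap["AVAL", "PVCL"] <- gap["PVCL", "AVAL"] <- 15
  conn <- connectome(
    nms,
    chem_edges = data.frame(from = c("AVAL", "PVCL", "AVAL"),
                            to = c("AVAR", "AVAL", "PVCL"),
                            count = c(9, 4, 1)),
    gap_edges = data.frame(a = c("AVAL", "AVAL"), b = c("AVAR", "PVCL"),
                           count = c(8, 15))
  )
  groups <- group_assignment(
    sections = list(backward = c("AVAL", "AVAR"), forward = "PVCL"),
    pairs = list(c("AVAL", "AVAR"))
  )
  m <- build_circuit(conn, groups)
  expect_equal(m$W["AVAR", "AVAL"], 1)       # count 9 saturates at the cap
  expect_lt(m$W["AVAL", "PVCL"], 0)          # cross-section is inhibitory
  expect_equal(m$W["PVCL", "AVAL"], -0.1)    # 1 synapse -> weak weight
  expect_gte(m$G["AVAL", "AVAR"], 1)         # pair gap in [1, 2]
  expect_lte(m$G["AVAL", "AVAR"], 2)
  expect_equal(m$G["AVAL", "PVCL"],
               adjustment_rules()$cross_gap)  # weak despite 15 contacts
  # bistable pairs get the strong reciprocal chemical weight
  groups_b <- group_assignment(
    sections = list(backward = c("AVAL", "AVAR"), forward = "PVCL"),
    pairs = list(c("AVAL", "AVAR")),
    bistable_pairs = list(c("AVAL", "AVAR"))
  )
  mb <- build_circuit(conn, groups_b)
  expect_equal(mb$W["AVAR", "AVAL"], adjustment_rules()$pair_chem_weight)
  expect_error(build_circuit(conn, group_assignment(
    sections = list(backward = c("AVAL", "AVAR"))
  )), "PVCL")
})

test_that("rule application is sign-safe on random connectomes", {
  set.seed(21)
  for (rep in 1:5) {
    nms <- paste0("x", 1:6)
    secs <- list(one = nms[1:3], two = nms[4:6])
    edges <- expand.grid(from = nms, to = nms, stringsAsFactors = FALSE)
    edges <- edges[stats::runif(nrow(edges)) < 0.3, ]
    edges$count <- sample(1:10, nrow(edges), replace = TRUE)
    conn <- connectome(nms, chem_edges = edges)
    groups <- group_assignment(sections = secs)
    m <- build_circuit(conn, groups)
    for (i in seq_len(nrow(edges))) {
      same <- (edges$from[i] %in% secs$one) == (edges$to[i] %in% secs$one)
      w <- m$W[edges$to[i], edges$from[i]]
      expect_true(if (same) w > 0 else w < 0)
      expect_lte(abs(w), 1)
    }
  }
})

test_that("the command fixture matches the rule-derived sign pattern", {
  m <- command_circuit_fixture()
  built <- build_circuit(command_connectome(), command_groups())
  expect_identical(sign(m$W), sign(built$W))
  expect_identical(m$G != 0, built$G != 0)
  # gap conductance ordering: pair > intra-section > cross-section
  expect_gt(min(m$G["AVBL", "AVBR"], m$G["AVAL", "AVAR"]),
            m$G["AVDL", "AVAL"])
  expect_gt(m$G["AVDL", "AVAL"], m$G["AVAL", "PVCL"])
  expect_equal(m$tau, 1)
  expect_equal(m$theta, 0.5)
  expect_equal(m$k, 20)
})

test_that("structure deduction emits the expected constraint instances", {
  roles <- list(
    state_groups = list(forward = c("AVBL", "AVBR"),
                        backward = c("AVAL", "AVAR", "AVEL", "AVER")),
    basin_groups = list(forward = c("PVCL", "PVCR"),
                        backward = c("AVDL", "AVDR")),
    pairs = list(c("AVBL", "AVBR"), c("AVAL", "AVAR"), c("AVEL", "AVER"),
                 c("PVCL", "PVCR"), c("AVDL", "AVDR"))
  )
  cons <- deduce_structure_constraints(roles)
  expect_true(any(cons$kind == "strong-reciprocal" &
                    cons$subject == "AVBL-AVBR"))
  expect_true(any(cons$kind == "weak-or-gap-only" &
                    cons$subject == "PVCL-PVCR"))
  expect_true(any(cons$kind == "mutual-inhibition"))
  expect_true(any(cons$kind == "state-suppresses-basin-of-opposite" &
                    cons$object == "PVCL/PVCR"))
  # deterministic ordering
  expect_identical(cons, deduce_structure_constraints(roles))
  # amphid interneuron roles: AIB/AIY state formers, AIA/AIZ basin formers
  amphid <- list(
    state_groups = list(avoid = c("AIBL", "AIBR"),
                        approach = c("AIYL", "AIYR")),
    basin_groups = list(approach = c("AIAL", "AIAR"),
                        avoid = c("AIZL", "AIZR")),
    pairs = list(c("AIBL", "AIBR"), c("AIYL", "AIYR"), c("AIAL", "AIAR"),
                 c("AIZL", "AIZR"))
  )
  acons <- deduce_structure_constraints(amphid)
  mi <- acons[acons$kind == "mutual-inhibition", ]
  expect_true(any(grepl("AIB", mi$subject) & grepl("AIY", mi$object)))
  # no basin formers: only state-former rules are emitted
  bare <- deduce_structure_constraints(list(
    state_groups = list(up = c("AVBL", "AVBR")),
    pairs = list(c("AVBL", "AVBR"))
  ))
  expect_setequal(unique(bare$kind), "strong-reciprocal")
  expect_error(deduce_structure_constraints(list(
    state_groups = list(a = "X"), basin_groups = list(a = "X")
  )), "disjoint")
})

test_that("deduced command-circuit constraints hold in the fixture", {
  m <- command_circuit_fixture()
  W <- m$W
  G <- m$G
  strong <- 0.3
  # strong-reciprocal for the bistable pairs: chemical or electrical
  for (p in list(c("AVBL", "AVBR"), c("AVAL", "AVAR"), c("AVEL", "AVER"))) {
    coupled <- (W[p[1], p[2]] > 0 || W[p[2], p[1]] > 0) && G[p[1], p[2]] >= 1
    expect_true(coupled)
  }
  # weak-or-gap-only for PVC and AVD pairs
  for (p in list(c("PVCL", "PVCR"), c("AVDL", "AVDR"))) {
    expect_lt(max(W[p[1], p[2]], W[p[2], p[1]]), strong)
  }
  # mutual inhibition between opposite state formers
  expect_lt(W["AVAL", "AVBL"], 0)
  expect_lt(W["AVBL", "AVAL"], 0)
  expect_lt(W["AVEL", "AVBL"], 0)
  # basin support: PVC excites AVB; AVD excites AVA
  expect_gt(W["AVBL", "PVCL"], 0)
  expect_gt(W["AVAL", "AVDL"], 0)
  # state formers suppress opposite basin formers: AVA/AVE inhibit PVC,
  # AVB inhibits AVD
  expect_lt(W["PVCL", "AVAL"], 0)
  expect_lt(W["PVCL", "AVEL"], 0)
  expect_lt(W["AVDL", "AVBL"], 0)
})
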