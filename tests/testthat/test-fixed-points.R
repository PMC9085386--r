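test_that("self-loop root sets match the dense grid-scan oracle", {
  for (w in c(2, 0.4, -2, 1.2, 2.8)) {
    m <- self_loop_model(w)
    fps <- find_fixed_points(m, box = c(-3, 3), n_starts = 50)
    found <- sort(vapply(fps$points, function(p) unname(p$x), 0))
    oracle <- grid_scan_roots_1d(w, box = c(-3, 3))
    expect_length(found, length(oracle))
    expect_equal(found, oracle, tolerance = 1e-4)
  }
})

test_that("strong self-excitation yields the three known fixed points", {
  m <- self_loop_model(2)
  fps <- find_fixed_points(m, box = c(-1, 3), n_starts = 50)
  xs <- sort(vapply(fps$points, function(p) unname(p$x), 0))
  expect_length(xs, 3)
  oracle <- grid_scan_roots_1d(2, box = c(-1, 3))
  expect_true(all(abs(xs - oracle) < 1e-6))
  # quiescent root sits at the sigmoid leak level ~9.1e-5; the upper state
  # saturates just below the loop weight
  expect_lt(xs[1], 1e-4)
  expect_gt(xs[1], 0)
  expect_true(xs[2] > 0.4 && xs[2] < 0.45)
  expect_equal(xs[3], 2, tolerance = 1e-3)
  stab <- vapply(fps$points, function(p) p$stability, "")
  ord <- order(vapply(fps$points, function(p) unname(p$x), 0))
  expect_equal(stab[ord], c("stable", "unstable", "stable"))
})

test_that("weak or inhibitory self-loops leave a single quiescent root", {
  fps_weak <- find_fixed_points(self_loop_model(0.4), box = c(-1, 3),
                                n_starts = 50)
  expect_length(fps_weak$points, 1)
  expect_lt(abs(fps_weak$points[[1]]$x), 0.01)
  # -x + w*sigma is strictly decreasing for w < 0: unique root
  fps_inh <- find_fixed_points(self_loop_model(-2), box = c(-3, 3),
                               n_starts = 50)
  expect_length(fps_inh$points, 1)
})

test_that("mutual excitation keeps every fixed point on the diagonal", {
  for (w in c(1.5, 2, 2.5)) {
    m <- mutual_excitation_model(w)
    fps <- find_fixed_points(m, box = c(-1, 3), n_starts = 100)
    oracle <- grid_scan_roots_symmetric_pair(w)
    expect_length(fps$points, length(oracle))
    for (p in fps$points) {
      expect_equal(unname(p$x[1]), unname(p$x[2]), tolerance = 1e-6)
    }
    found <- sort(vapply(fps$points, function(p) unname(p$x[1]), 0))
    expect_equal(found, oracle, tolerance = 1e-4)
  }
  # stability at w = 2: extremes stable, middle a saddle
  fps <- find_fixed_points(mutual_excitation_model(2), box = c(-1, 3),
                           n_starts = 100)
  ord <- order(vapply(fps$points, function(p) unname(p$x[1]), 0))
  stab <- vapply(fps$points, function(p) p$stability, "")[ord]
  expect_equal(stab, c("stable", "saddle", "stable"))
})

test_that("a quiescent fixed point exists whenever the threshold is high", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    W <- matrix(stats::runif(n * n, -1, 1), n, n)
    W <- W * (3 / max(rowSums(abs(W))))  # ||W||_inf = 3
    m <- circuit_model(W, theta = 0.5, k = 20)
    fps <- find_fixed_points(m, box = c(-3, 3), n_starts = 150, seed = rep)
    norms <- vapply(fps$points, function(p) max(abs(p$x)), 0)
    expect_true(any(norms < 0.01))
  }
})

test_that("fixed-point sets are deterministic and deduplicated", {
  m <- command_circuit_fixture()
  a <- find_fixed_points(m, n_starts = 120, seed = 3)
  b <- find_fixed_points(m, n_starts = 120, seed = 3)
  expect_identical(
    lapply(a$points, function(p) p$x),
    lapply(b$points, function(p) p$x)
  )
  xs <- lapply(a$points, function(p) p$x)
  if (length(xs) > 1) {
    for (i in seq_along(xs)) {
      for (j in seq_along(xs)) {
        if (i < j) expect_gte(max(abs(xs[[i]] - xs[[j]])), a$dedup_tol)
      }
    }
  }
  for (p in a$points) expect_lt(p$residual, a$solver_tol)
})

test_that("stability labels agree with perturbed simulations", {
  m <- self_loop_model(2)
  fps <- find_fixed_points(m, box = c(-1, 3), n_starts = 50)
  for (p in fps$points) {
    if (p$stability == "stable") {
      traj <- simulate_circuit(m, p$x + 1e-3, t_end = 100)
      expect_lt(max(abs(traj$terminal_state - p$x)), 1e-4)
    } else {
      # depart along the unstable direction
      traj <- simulate_circuit(m, p$x + 1e-3, t_end = 100)
      expect_gt(max(abs(traj$terminal_state - p$x)), 0.1)
    }
  }
  expect_equal(as.character(classify_stability(m, fps$points[[1]])),
               fps$points[[1]]$stability)
})

test_that("bifurcation sweep locates the one-to-three transition", {
  tr <- bifurcation_sweep(function(w) self_loop_model(w),
                          values = seq(0, 3, by = 0.25),
                          box = c(-1, 3), n_starts = 40)
  expect_equal(tr$n_roots[tr$value == 0], 1)
  expect_equal(tr$n_roots[tr$value == 3], 3)
  expect_true(all(diff(tr$n_roots) >= 0))
  jump <- tr$value[which(diff(tr$n_roots) > 0) + 1]
  expect_gt(jump[1], 0)
  expect_lt(jump[1], 3)
  # the same fold happens for the mutually excitatory pair
  tr2 <- bifurcation_sweep(function(w) mutual_excitation_model(w),
                           values = c(0.5, 1, 1.5, 2, 2.5, 3),
                           box = c(-1, 3), n_starts = 60)
  expect_equal(tr2$n_roots[tr2$value == 0.5], 1)
  expect_equal(tr2$n_roots[tr2$value == 3], 3)
  # degenerate sweep: no connections anywhere
  tr3 <- bifurcation_sweep(function(w) self_loop_model(0),
                           values = c(0, 1), box = c(-1, 3), n_starts = 20)
  expect_equal(tr3$n_roots, c(1, 1))
  expect_error(bifurcation_sweep(function(w) self_loop_model(w), values = 1),
               "two grid values")
  # builder failures are recorded, not fatal
  tr4 <- bifurcation_sweep(function(w) {
    if (w > 1) stop("boom") else self_loop_model(w)
  }, values = c(0.5, 2), box = c(-1, 3), n_starts = 20)
  expect_equal(tr4$n_roots, c(1, NA))
  expect_match(tr4$error[2], "boom")
})

test_that("fixed-point tables round to the reporting precision", {
  res <- cached_command_fps()
  df <- as.data.frame(res$fps)
  expect_equal(nrow(df), 10)
  expect_equal(df$neuron, res$model$names)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixed_points_tsv(res$fps, path)
  lines <- readLines(path)
  expect_match(lines[1], "^neuron\tfp1")
  expect_match(lines[length(lines)], "^stability\t")
})
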