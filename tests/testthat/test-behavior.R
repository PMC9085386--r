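paper_config <- function(duration = 10000, frame_rate = 10) {
  behavior_config(duration = duration, frame_rate = frame_rate)
}

test_that("behavior configs are validated", {
  expect_error(behavior_config(occupancy = c(0.5, 0.4)), "sum to 1")
  expect_error(behavior_config(mean_dwell = c(0, 2)), "positive")
  expect_error(behavior_config(sd_speed = c(-1, 1)), "nonnegative")
  expect_error(behavior_config(duration = 0), "positive")
})

test_that("a single-state generator reproduces its mean (CLT check)", {
  cfg <- behavior_config(states = "forward", mean_speed = 259.8,
                        sd_speed = 77.79164, occupancy = 1,
                        mean_dwell = 30, duration = 2000, frame_rate = 10)
  trace <- synthesize_speed_trace(cfg, seed = 11)
  n <- length(trace$speeds)
  se <- 77.79164 / sqrt(n)
  expect_lt(abs(mean(trace$speeds) - 259.8), 3 * se)
})

test_that("two-state occupancy hits its target at large n", {
  cfg <- paper_config()  # 1e5 frames at 10 Hz
  trace <- synthesize_speed_trace(cfg, seed = 1)
  expect_length(trace$speeds, 1e5)
  frac_fwd <- mean(trace$state == "forward")
  expect_lt(abs(frac_fwd - 0.9336), 0.01)
})

test_that("zero-noise traces are piecewise constant at the state means", {
  cfg <- behavior_config(sd_speed = c(0, 0), duration = 200)
  trace <- synthesize_speed_trace(cfg, seed = 3)
  expect_setequal(unique(trace$speeds), c(259.8, -308.03))
})

test_that("traces are reproducible per seed and round-trip through CSV", {
  cfg <- behavior_config(duration = 50)
  a <- synthesize_speed_trace(cfg, seed = 5)
  b <- synthesize_speed_trace(cfg, seed = 5)
  expect_identical(a$speeds, b$speeds)
  path <- withr::local_tempfile(fileext = ".csv")
  write_speed_csv(a, path)
  back <- read_speed_csv(path)
  expect_equal(back$speeds, a$speeds)
  expect_equal(back$frame_rate, a$frame_rate)
})

test_that("segmentation classifies frames by sign and merges runs", {
  trace <- structure(list(times = 0:3, speeds = c(100, 120, -200, -180),
                          frame_rate = 1, state = NULL),
                     class = "speed_trace")
  ev <- segment_locomotion(trace, dead_band = 10)
  expect_equal(nrow(ev$segments), 2)
  expect_equal(ev$segments$state, c("forward", "backward"))
  expect_equal(ev$segments$duration, c(2, 2))
  zero <- structure(list(times = 0:4, speeds = rep(0, 5), frame_rate = 1,
                         state = NULL), class = "speed_trace")
  evz <- segment_locomotion(zero, dead_band = 10)
  expect_equal(evz$segments$state, "pause")
  expect_equal(nrow(evz$segments), 1)
  expect_error(segment_locomotion(structure(
    list(times = numeric(0), speeds = numeric(0), frame_rate = 1),
    class = "speed_trace")), "empty")
})

test_that("segments tile the trace and alternate states", {
  trace <- synthesize_speed_trace(behavior_config(duration = 500), seed = 9)
  ev <- segment_locomotion(trace)
  seg <- ev$segments
  expect_equal(sum(seg$duration), length(trace$speeds) / trace$frame_rate)
  expect_equal(seg$start[-1], seg$end[-nrow(seg)] + 1)
  expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
})

test_that("generator-to-segmenter round trip recovers the occupancy", {
  trace <- synthesize_speed_trace(paper_config(), seed = 2)
  ev <- segment_locomotion(trace, dead_band = 0)
  summ <- locomotion_summary(ev)
  fwd <- summ$states[summ$states$state == "forward", ]
  expect_lt(abs(fwd$time_fraction - 0.9336), 0.01)
})

test_that("the sign-split fit recovers the generating mixture", {
  set.seed(13)
  n <- 1e5
  comp <- stats::rbinom(n, 1, 0.0664)
  speeds <- ifelse(comp == 1, stats::rnorm(n, -308.03, 62.79239),
                   stats::rnorm(n, 259.8, 77.79164))
  fit <- fit_speed_distribution(speeds)
  expect_lt(abs(fit$mu_forward - 259.8), 10)
  expect_lt(abs(fit$mu_backward - (-308.03)), 10)
  expect_lt(abs(fit$weights[["backward"]] - 0.0664), 0.01)
  # symmetric mixture: recovered centres are mirror images
  sym <- c(stats::rnorm(5000, 200, 40), stats::rnorm(5000, -200, 40))
  fsym <- fit_speed_distribution(sym)
  expect_lt(abs(fsym$mu_forward + fsym$mu_backward), 5)
})

test_that("one-signed samples fall back to a single Gaussian", {
  set.seed(14)
  speeds <- abs(stats::rnorm(500, 200, 30)) + 1
  expect_warning(fit <- fit_speed_distribution(speeds), "one-signed")
  expect_true(fit$single_component)
  expect_true(is.na(fit$mu_backward))
  expect_lt(abs(fit$mu_forward - mean(speeds)), 1e-9)
  expect_error(fit_speed_distribution(stats::rnorm(50)), "100")
})

test_that("parameter recovery is unbiased across seeded replicates", {
  mus <- vapply(1:20, function(s) {
    trace <- synthesize_speed_trace(behavior_config(duration = 2000),
                                    seed = s)
    fit_speed_distribution(trace$speeds)$mu_forward
  }, 0)
  expect_lt(abs(mean(mus) - 259.8), 2)
  # spread consistent with delta / sqrt(n * weight) within a factor of 2
  n_eff <- 2000 * 10 * 0.9336
  expect_lt(stats::sd(mus), 2 * 77.79164 / sqrt(n_eff) * 2)
})

test_that("event statistics show the forward bias in duration, not speed", {
  trace <- synthesize_speed_trace(paper_config(duration = 5000), seed = 8)
  ev <- segment_locomotion(trace)
  summ <- locomotion_summary(ev)
  st <- summ$states
  fwd <- st[st$state == "forward", ]
  bwd <- st[st$state == "backward", ]
  expect_gt(fwd$mean_duration, 3 * bwd$mean_duration)
  # mean absolute speeds of the two states are comparable (within 20%)
  expect_lt(abs(fwd$mean_abs_speed - bwd$mean_abs_speed) /
              fwd$mean_abs_speed, 0.2)
  # two equal segments split time evenly
  toy <- structure(list(times = 0:9, speeds = c(rep(100, 5), rep(-100, 5)),
                        frame_rate = 1, state = NULL),
                   class = "speed_trace")
  tsum <- locomotion_summary(segment_locomotion(toy))
  expect_equal(tsum$states$time_fraction, c(0.5, 0.5))
})

test_that("the EM mixture mode agrees with the sign-split fit", {
  set.seed(15)
  speeds <- c(stats::rnorm(7000, 259.8, 77.79164),
              stats::rnorm(3000, -308.03, 62.79239))
  em <- fit_speed_distribution(speeds, method = "em")
  ss <- fit_speed_distribution(speeds, method = "sign-split")
  expect_lt(abs(em$mu_forward - ss$mu_forward), 15)
  expect_lt(abs(em$mu_backward - ss$mu_backward), 15)
})
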