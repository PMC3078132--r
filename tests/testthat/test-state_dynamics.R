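test_that("hysteresis labelling follows the two-threshold rule", {
  expect_equal(unique(classify_states(rep(50, 10))), "extended")
  expect_equal(unique(classify_states(rep(10, 10))), "bent")
  # undecided until the first crossing
  lbl <- classify_states(c(30, 31, 36, 30, 27, 30))
  expect_equal(lbl, c("undecided", "undecided", "extended", "extended",
                      "bent", "bent"))
  expect_error(classify_states(rep(30, 5), theta_up = 20, theta_down = 30),
               class = "configuration_error")
})

test_that("a monotone ramp produces exactly one transition at the crossing", {
  theta <- seq(50, 10, length.out = 81)  # crosses 28 going down
  times <- seq(0, 8000, length.out = 81)
  seg <- segment_states(theta, times, min_dwell_ps = 100)
  expect_equal(nrow(seg$transitions), 1L)
  first_cross <- which(theta <= 28)[1]
  expect_equal(seg$transitions$time_ps, times[first_cross])
  expect_equal(seg$transitions$from, "extended")
  expect_equal(seg$transitions$to, "bent")
})

test_that("oscillation inside the dead band causes no transitions", {
  theta <- c(40, 29 + 5 * sin(seq(0, 20, by = 0.1)))  # stays in (24, 34)
  theta[theta <= 28] <- 28.5
  theta[theta >= 35] <- 34.5
  theta[1] <- 40
  seg <- segment_states(theta, seq_along(theta) * 10, min_dwell_ps = 10)
  expect_equal(nrow(seg$transitions), 0L)
  expect_equal(unique(seg$labels), "extended")
})

test_that("short blips are merged away by the dwell filter", {
  times <- seq(0, by = 10, length.out = 4000)  # 40 ns at 10 ps
  theta <- rep(50, 4000)
  theta[2000:2010] <- 10  # 100 ps blip
  seg <- segment_states(theta, times, min_dwell_ps = 1000)
  expect_equal(nrow(seg$transitions), 0L)
  expect_equal(unique(seg$labels), "extended")
})

test_that("dwell times plus undecided span account for the full duration", {
  theta <- c(30, 30, 50, 50, 10, 10, 50, 50)
  times <- (0:7) * 100
  seg <- segment_states(theta, times, min_dwell_ps = 50)
  total <- sum(unlist(seg$dwell_times))
  undecided_span <- times[3] - times[1]
  expect_equal(total + undecided_span, times[8] - times[1])
  expect_equal(nrow(seg$transitions), 2L)
})

test_that("relabelling symmetry: mirrored thresholds mirror the segmentation", {
  set.seed(21)
  theta <- 31.5 + cumsum(rnorm(500, sd = 2))
  theta <- pmin(pmax(theta, 5), 60)
  up <- 35; down <- 28
  lbl <- classify_states(theta, up, down)
  mirrored <- classify_states((up + down) - theta, up, down)
  swap <- c(extended = "bent", bent = "extended", undecided = "undecided")
  expect_identical(unname(swap[lbl]), mirrored)
})

test_that("widening the hysteresis band never increases the transition count", {
  set.seed(22)
  theta <- 31.5 + cumsum(rnorm(2000, sd = 1.5))
  theta <- pmin(pmax(theta, 2), 70)
  times <- seq_along(theta) * 10
  n_trans <- function(up, down)
    nrow(segment_states(theta, times, up, down, min_dwell_ps = 10)$transitions)
  narrow <- n_trans(32, 31)
  mid <- n_trans(35, 28)
  wide <- n_trans(45, 18)
  expect_gte(narrow, mid)
  expect_gte(mid, wide)
})

test_that("occupancy fractions over decided frames sum to one", {
  theta <- c(rep(50, 70), rep(10, 30))
  seg <- segment_states(theta, seq_along(theta) * 10, min_dwell_ps = 10)
  occ <- occupancy(seg)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["extended"]), 0.7)
  expect_equal(unname(occ["bent"]), 0.3)
  # alternating equal dwells: a half each within one frame's weight
  alt <- rep(c(rep(50, 50), rep(10, 50)), 4)
  occ2 <- occupancy(segment_states(alt, seq_along(alt), min_dwell_ps = 5))
  expect_equal(unname(occ2["extended"]), 0.5, tolerance = 0.02)
  seg_und <- detect_transitions(rep("undecided", 5), 1:5)
  expect_error(occupancy(seg_und), class = "insufficient_data_error")
})

test_that("planted 70/30 two-state path is recovered within binomial error", {
  set.seed(23)
  # construct a state path with stationary occupancy 0.7 extended
  path <- pentadyn:::simulate_state_path(20000, 10, c(extended_to_bent = 0.3,
                                                      bent_to_extended = 0.7),
                                         "extended")
  theta <- ifelse(path$states == 1L, 50, 10)
  seg <- segment_states(theta, (0:19999) * 10, min_dwell_ps = 10)
  occ <- occupancy(seg)
  expect_equal(unname(occ["extended"]), 0.7, tolerance = 0.08)
})

test_that("empirical dwell means match the planted switching rates", {
  set.seed(24)
  k <- 2  # per ns, both directions
  dwells <- c()
  for (r in 1:6) {
    path <- pentadyn:::simulate_state_path(50000, 10,
                                           c(extended_to_bent = k,
                                             bent_to_extended = k),
                                           "extended")
    ev <- path$transition_times_ps
    dwells <- c(dwells, diff(c(0, ev)) / 1000)  # ns
  }
  expect_gt(length(dwells), 500)
  se <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 1 / k), 2 * se + 0.02)
})

test_that("transition times are exact on noise-free threshold crossings", {
  theta <- c(rep(50, 10), rep(20, 10), rep(50, 10))
  times <- (0:29) * 1000
  seg <- segment_states(theta, times, min_dwell_ps = 500)
  expect_equal(seg$transitions$time_ps, c(10000, 20000))
})
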