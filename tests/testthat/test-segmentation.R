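test_that("toe-off is recovered at injected plantarflexion minima", {
  # two-cycle ankle trace with known sharp troughs
  fs <- 100
  u <- seq(0, 2.5, by = 1 / 110)  # 2.5 cycle phases at ~110 samples/cycle
  bump <- function(u, c, w) exp(-0.5 * (((u - c + 0.5) %% 1 - 0.5) / w)^2)
  ankle <- 6 * bump(u, 0, 0.03) + 8 * bump(u, 0.42, 0.10) -
    22 * bump(u, 0.6, 0.035) + 2 * cos(2 * pi * u)
  ev <- detect_events(ankle, fs)
  to <- ev$sample_index[ev$kind == "toe_off"]
  truth <- sapply(c(0.6, 1.6), function(ph) which.min(abs(u - ph)))
  expect_length(to, 2L)
  expect_true(all(abs(to - truth) <= 2))
  # events alternate strictly
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
})

test_that("flat or too-short traces yield a no-events error", {
  expect_error(detect_events(rep(5, 300)), "constant")
  expect_error(detect_events(rep(5, 4)), "constant|short")
})

test_that("generator ground truth is recovered within two samples", {
  co <- default_cohort()
  truth <- attr(co, "truth")
  for (sid in names(co$trials)[c(1, 25, 50, 70)]) {
    tr <- co$trials[[sid]]
    ev <- detect_events(tr$angles$ankle, tr$sampling_rate)
    hs <- ev$sample_index[ev$kind == "heel_strike"]
    to <- ev$sample_index[ev$kind == "toe_off"]
    expect_equal(length(hs), truth[[sid]]$n_cycles + 1L)
    expect_true(all(abs(hs - truth[[sid]]$heel_strikes) <= 2))
    expect_true(all(abs(to - truth[[sid]]$toe_offs) <= 2))
  }
})

test_that("cycles are cut between heel strikes with one toe-off each", {
  co <- default_cohort()
  tr <- co$trials$S001
  cycles <- segment_cycles(tr)
  expect_equal(length(cycles), attr(co, "truth")$S001$n_cycles)
  for (cy in cycles) {
    expect_true(cy$start_index < cy$toe_off_index && cy$toe_off_index < cy$end_index)
    expect_gt(cy$stance_fraction, 0)
    expect_lt(cy$stance_fraction, 1)
    expect_length(cy$hip, 101L)
    expect_length(cy$knee, 101L)
    expect_length(cy$ankle, 101L)
    expect_true(all(is.finite(c(cy$hip, cy$knee, cy$ankle))))
  }
  # explicit event table: 5 heel strikes with interleaved toe-offs -> 4 cycles
  ev <- data.frame(kind = rep(c("heel_strike", "toe_off"), 5)[1:9],
                   sample_index = c(100, 172, 220, 290, 340, 410, 460, 530, 580))
  cyc <- segment_cycles(tr, events = ev[ev$sample_index <= nrow(tr$angles), ])
  expect_equal(length(cyc), sum(ev$kind == "heel_strike") - 1L)
  expect_equal(cyc[[1]]$stance_fraction, (172 - 100) / (220 - 100))
})

test_that("a cycle without a toe-off is skipped with a warning", {
  co <- default_cohort()
  tr <- co$trials$S002
  ev <- detect_events(tr$angles$ankle, tr$sampling_rate)
  drop_to <- which(ev$kind == "toe_off")[2]
  expect_warning(cyc <- segment_cycles(tr, events = ev[-drop_to, ]), "skipped")
  expect_equal(length(cyc), sum(ev$kind == "heel_strike") - 2L)
})

test_that("cycle selection is seeded, complete when few, and uniform", {
  cycles <- replicate(8, make_test_cycle(), simplify = FALSE)
  s1 <- select_cycles(cycles, 3, 5, rng_seed = 9)
  s2 <- select_cycles(cycles, 3, 5, rng_seed = 9)
  expect_identical(s1, s2)
  expect_length(s1, 5L)
  expect_identical(select_cycles(cycles[1:4], 3, 5, rng_seed = 1), cycles[1:4])
  expect_error(select_cycles(cycles[1:2], 3, 5, rng_seed = 1, subject_id = "S9"), "S9")

  for (i in seq_along(cycles)) cycles[[i]]$id <- i
  hits <- integer(8)
  n_draws <- 1000
  for (s in seq_len(n_draws)) {
    picked <- vapply(select_cycles(cycles, 3, 5, rng_seed = s), `[[`, integer(1), "id")
    hits[picked] <- hits[picked] + 1L
  }
  p <- 5 / 8  # each of 8 cycles selected into a 5-subset
  se <- sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(hits / n_draws - p) <= 3 * se))
})

test_that("detected stance fractions sit near the 60% stance convention", {
  co <- default_cohort()
  sf <- unlist(lapply(names(co$trials)[1:20], function(sid) {
    vapply(segment_cycles(co$trials[[sid]]), `[[`, numeric(1), "stance_fraction")
  }))
  expect_true(all(sf > 0.5 & sf < 0.7))
  expect_lt(abs(mean(sf) - 0.60), 0.03)
})
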