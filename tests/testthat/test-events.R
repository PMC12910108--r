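test_that("colocalization event rules follow the frame thresholds", {
  # a single run above threshold becomes one event with frame-quantized
  # duration
  x <- rep(0, 30); x[10:20] <- 100
  ev <- call_colocalization(as_traj(x), threshold = 50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 10L)
  expect_equal(ev$end_frame, 20L)
  expect_equal(ev$duration_s, 11 * 0.2)
  # a single-frame spike is not an event
  y <- rep(0, 30); y[15] <- 200
  expect_equal(nrow(call_colocalization(as_traj(y), threshold = 50)), 0)
  # runs separated by a 2-frame gap merge into one event
  z <- rep(0, 20); z[1:5] <- 100; z[8:12] <- 100
  evz <- call_colocalization(as_traj(z), threshold = 50)
  expect_equal(nrow(evz), 1)
  expect_equal(c(evz$start_frame, evz$end_frame), c(1L, 12L))
  # a 3-frame gap separates two events
  w <- rep(0, 20); w[1:5] <- 100; w[9:13] <- 100
  expect_equal(nrow(call_colocalization(as_traj(w), threshold = 50)), 2)
  expect_error(call_colocalization(as_traj(w), threshold = 0),
               class = "smkinetics_invalid")
})

test_that("production caller matches the naive scanner on random traces", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(20:120, 1)
    # random bursty traces with occasional threshold-straddling noise
    x <- rpois(n, 10) + rbinom(n, 1, runif(1, 0.05, 0.6)) * rpois(n, 90)
    ev <- call_colocalization(as_traj(x), threshold = 50)
    ref <- oracle_coloc_events(x, threshold = 50)
    expect_equal(nrow(ev), nrow(ref))
    expect_equal(ev$start_frame, ref$start)
    expect_equal(ev$end_frame, ref$end)
  }
})

test_that("FRET caller matches the naive scanner on random traces", {
  set.seed(321)
  for (i in 1:300) {
    n <- sample(30:150, 1)
    e <- runif(n, -0.1, 1.0)
    # random smooth-ish segments make realistic windows
    e[sample(n, n %/% 3)] <- runif(n %/% 3, 0.3, 0.8)
    valid <- runif(n) > 0.05
    ev <- call_fret_events(as_trace(e, valid), delta_e_method = "endpoint",
                           events_per_molecule = "all")
    ref <- oracle_fret_events(e, valid)
    expect_equal(nrow(ev), nrow(ref))
    if (nrow(ev) > 0) {
      expect_equal(ev$start_frame, ref$start)
      expect_equal(ev$end_frame, ref$end)
      expect_equal(ev$slope, ref$slope, tolerance = 1e-9)
      expect_equal(ev$delta_e, ref$delta_e, tolerance = 1e-9)
    }
  }
})

test_that("noiseless events match ground-truth intervals frame for frame", {
  sc <- kinetic_scenario(k_bind = 0.005, bound_fraction = 1, tau_dwell = 5,
                         movie_length = 180, photon_budget = 200,
                         bleach_tau_donor = 1e6, bleach_tau_acceptor = 1e6,
                         n_molecules = 40L, seed = 33L)
  sim <- simulate_colocalization(sc, noise = FALSE)
  ev <- call_colocalization(sim$trajectories, threshold = 50)
  tru <- sim$truth[sim$truth$kind == "binding", ]
  # expected events from the ground truth alone: a frame is above 50
  # photons when bound occupancy exceeds 50/200 of the exposure; the
  # naive scanner then applies the frame rules
  n_frames <- floor(sc$movie_length / 0.2)
  for (m in unique(tru$molecule_id)) {
    iv <- tru[tru$molecule_id == m, ]
    occ <- rep(0, n_frames)
    fr_all <- seq_len(n_frames)
    for (j in seq_len(nrow(iv))) {
      ov <- pmin(iv$t_end_s[j], fr_all * 0.2) -
        pmax(iv$t_start_s[j], (fr_all - 1) * 0.2)
      occ <- occ + pmax(ov, 0)
    }
    ref <- oracle_coloc_events(occ * 200 / 0.2, threshold = 50)
    sel <- ev$molecule_id == m
    expect_equal(ev$start_frame[sel], ref$start)
    expect_equal(ev$end_frame[sel], ref$end)
  }
})

test_that("events are ordered, non-overlapping and idempotent", {
  set.seed(55)
  x <- rpois(300, 10) + rbinom(300, 1, 0.3) * rpois(300, 150)
  ev <- call_colocalization(as_traj(x), threshold = 50)
  expect_true(all(diff(ev$start_frame) > 0))
  expect_true(all(ev$start_frame[-1] > ev$end_frame[-nrow(ev)]))
  # recalling on an event's own frames reproduces that event
  for (i in seq_len(min(nrow(ev), 5))) {
    seg <- x[ev$start_frame[i]:ev$end_frame[i]]
    ev2 <- call_colocalization(as_traj(seg), threshold = 50)
    expect_equal(nrow(ev2), 1)
    expect_equal(ev2$n_frames, ev$n_frames[i])
  }
})

test_that("first binding times censor molecules without events", {
  ev <- tibble::tibble(molecule_id = c(1L, 1L, 3L),
                       start_s = c(12.4, 30, 2.0))
  ft <- first_binding_times(ev, molecule_ids = 1:3, observation_window = 180)
  expect_equal(ft$time_s, c(12.4, 180, 2.0))
  expect_equal(ft$censored, c(FALSE, TRUE, FALSE))
})

test_that("FRET event filters implement the window/duration/slope rules", {
  # linear ramp 0.6 -> 0.2 over 10 frames: truncated at the last frame
  # with E >= 0.3, slope negative, retained
  e <- seq(0.6, 0.2, length.out = 10)
  ev <- call_fret_events(as_trace(e), delta_e_method = "endpoint")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end_frame, max(which(e >= 0.3)))
  expect_lt(ev$slope, 0)
  expect_gt(ev$delta_e, 0)
  # constant E: slope zero, rejected
  expect_equal(nrow(call_fret_events(as_trace(rep(0.6, 10)))), 0)
  # a 25 s event is rejected as an outlier
  long_e <- seq(0.79, 0.31, length.out = 125)
  expect_equal(nrow(call_fret_events(as_trace(long_e))), 0)
  # four frames in window: below the five-frame minimum
  short_e <- c(0.1, seq(0.6, 0.45, length.out = 4), 0.1)
  expect_equal(nrow(call_fret_events(as_trace(short_e))), 0)
  # invalid frames cannot carry an event
  expect_equal(nrow(call_fret_events(as_trace(seq(0.6, 0.3, length.out = 10),
                                              valid = FALSE))), 0)
})

test_that("plateau method measures the decrease past the window floor", {
  # staircase 0.6 -> 0.2; the 0.2 terminal level sits below the window,
  # reachable only through the post-run plateau
  e <- c(rep(0.6, 5), rep(0.5, 5), rep(0.4, 5), rep(0.3, 5), rep(0.2, 8),
         rep(0.02, 5))
  ev <- call_fret_events(as_trace(e))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$delta_e, 0.4, tolerance = 1e-9)
  # endpoint reading stops at the window floor
  ev2 <- call_fret_events(as_trace(e), delta_e_method = "endpoint")
  expect_equal(ev2$delta_e, 0.3, tolerance = 1e-9)
  # with no sub-window plateau (staircase ends at 0.4) both methods agree
  e2 <- c(rep(0.6, 5), rep(0.5, 5), rep(0.4, 12), rep(0.02, 5))
  expect_equal(call_fret_events(as_trace(e2))$delta_e, 0.2, tolerance = 1e-9)
})
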