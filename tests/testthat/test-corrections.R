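test_that("zero factors reduce E to the proximity ratio", {
  tr <- as_traj(f_aa = rep(20, 10), f_dd = 40, f_da = 60)
  out <- compute_efret(tr, correction_factors(0, 0, 1), bleach = FALSE)
  expect_equal(out$E, rep(60 / (60 + 40), 10))
  # zero acceptor signal gives E = 0
  tr0 <- as_traj(f_aa = rep(0, 5), f_dd = 40, f_da = 0)
  expect_equal(compute_efret(tr0, correction_factors(0, 0, 1),
                             bleach = FALSE)$E,
               rep(0, 5))
})

test_that("the correction formula matches hand evaluation", {
  # F_DA = 65 contains 0.1*40 = 4 leakage and 0.05*20 = 1 direct
  # excitation on top of 60 true FRET photons
  tr <- as_traj(f_aa = rep(20, 4), f_dd = 40, f_da = 65)
  out <- compute_efret(tr, correction_factors(0.1, 0.05, 1), bleach = FALSE)
  expect_equal(out$E, rep(0.6, 4))
  # gamma reweights the donor in the denominator
  outg <- compute_efret(tr, correction_factors(0.1, 0.05, 1.5), bleach = FALSE)
  expect_equal(outg$E, rep(60 / (60 + 1.5 * 40), 4))
  # non-positive denominator marks the frame invalid, no exception
  trb <- as_traj(f_aa = rep(0, 3), f_dd = 10, f_da = 0)
  outb <- compute_efret(trb, correction_factors(0.9, 0, 0.001), bleach = FALSE)
  expect_true(all(!outb$valid | is.finite(outb$E)))
})

test_that("E is strictly decreasing in donor signal at fixed acceptor", {
  f <- correction_factors(0.1, 0.05, 1.2)
  dd <- seq(10, 500, by = 10)
  tr <- as_traj(f_aa = rep(100, length(dd)), f_dd = dd, f_da = 300)
  e <- compute_efret(tr, f, bleach = FALSE)$E
  expect_true(all(diff(e) < 0))
})

test_that("calibration recovers the simulated distortion factors", {
  sc <- kinetic_scenario(n_molecules = 40L, movie_length = 60,
                         bleach_tau_donor = 30, bleach_tau_acceptor = 30,
                         n_nucleotides = 0L, bound_fraction = 1, k_bind = 1,
                         tau_dwell = 60, photon_budget = 500, seed = 5L)
  don <- simulate_donor_only(sc)
  acc <- simulate_acceptor_only(sc)
  fr <- simulate_fret(sc)$trajectories
  f <- estimate_factors(don, acc, fret = fr, background = 10)
  expect_lt(abs(f$leakage - 0.1), 0.01)
  expect_lt(abs(f$direct_excitation - 0.05), 0.01)
  expect_lt(abs(f$gamma - 1.2), 0.1)
  # zero-distortion data give l = d = 0 and gamma = 1 within noise
  sc0 <- kinetic_scenario(leakage = 0, direct_excitation = 0, gamma = 1,
                          n_molecules = 30L, movie_length = 40,
                          bleach_tau_donor = 20, bleach_tau_acceptor = 20,
                          n_nucleotides = 0L, bound_fraction = 1, k_bind = 1,
                          tau_dwell = 40, photon_budget = 500, seed = 6L)
  f0 <- estimate_factors(simulate_donor_only(sc0), simulate_acceptor_only(sc0),
                         fret = simulate_fret(sc0)$trajectories,
                         background = 10)
  expect_lt(abs(f0$leakage), 0.01)
  expect_lt(abs(f0$direct_excitation), 0.01)
  expect_lt(abs(f0$gamma - 1), 0.1)
  expect_error(estimate_factors(don[0, ], acc), class = "smkinetics_invalid")
  # no usable bleach transitions: gamma falls back to 1 with a warning
  expect_warning(estimate_factors(don, acc, fret = NULL, background = 10),
                 "gamma fallback")
})

test_that("correcting with the true factors inverts the distortion", {
  sc <- kinetic_scenario(bound_fraction = 1, k_bind = 0.5, tau_dwell = 10,
                         n_nucleotides = 4L, t_incorporation = 6,
                         movie_length = 40, photon_budget = 500,
                         bleach_tau_donor = 1e5, bleach_tau_acceptor = 1e5,
                         n_molecules = 30L, seed = 17L)
  f <- correction_factors(sc$leakage, sc$direct_excitation, sc$gamma)
  # noiseless: recovery is exact on frames fully inside constant-E segments
  sim0 <- simulate_fret(sc, noise = FALSE)
  tr0 <- compute_efret(sim0$trajectories, f, background = 0, bleach = FALSE)
  for (m in unique(tr0$molecule_id)) {
    ref <- truth_e_frames(sim0$truth, sc, m)
    e <- tr0$E[tr0$molecule_id == m]
    sel <- ref$full & ref$e > 0
    expect_equal(e[ref$frame[sel]], ref$e[sel], tolerance = 1e-10)
  }
  # shot noise at a 500-photon budget: mean absolute error below 0.02
  sim <- simulate_fret(sc)
  tr <- compute_efret(sim$trajectories, f, background = sc$background,
                      bleach = FALSE)
  errs <- c()
  for (m in unique(tr$molecule_id)) {
    ref <- truth_e_frames(sim$truth, sc, m)
    e <- tr$E[tr$molecule_id == m]
    sel <- ref$full & ref$e > 0
    errs <- c(errs, abs(e[ref$frame[sel]] - ref$e[sel]))
  }
  expect_gt(length(errs), 1000)
  expect_lt(mean(errs, na.rm = TRUE), 0.02)
})

test_that("photobleaching steps are found and flagged downstream", {
  # exact step 500 -> 10 at frame 40
  x <- c(rep(500, 39), rep(10, 41))
  expect_equal(smkinetics:::detect_bleach_channel(x, background = 10), 40L)
  # constant trace: no step
  expect_true(is.na(smkinetics:::detect_bleach_channel(rep(500, 60), 10)))
  # noisy flat background: no spurious step
  set.seed(2)
  expect_true(is.na(smkinetics:::detect_bleach_channel(rpois(200, 10), 10)))
  # frames after the bleach are invalid in the corrected trace
  tr <- as_traj(f_aa = c(rep(500, 39), rep(10, 41)), f_dd = 200, f_da = 300)
  out <- compute_efret(tr, correction_factors(0, 0, 1), background = 10)
  expect_true(all(out$valid[1:39]))
  expect_true(all(!out$valid[40:80]))
})

test_that("detected bleach times reproduce the simulated lifetime (KS)", {
  sc <- kinetic_scenario(n_molecules = 500L, movie_length = 120,
                         bleach_tau_donor = 25, photon_budget = 500, seed = 19L)
  don <- simulate_donor_only(sc)
  bl <- detect_bleach(don, background = 10)
  frames <- bl$donor_bleach_frame[!is.na(bl$donor_bleach_frame)]
  # dequantize: the true bleach instant is uniform within the frame
  set.seed(41)
  times <- (frames - 1 + stats::runif(length(frames))) * 0.2
  expect_gt(length(times), 300)
  # censored at the movie end: compare against the truncated exponential
  pexp_trunc <- function(q) stats::pexp(q, 1 / 25) / stats::pexp(120, 1 / 25)
  expect_gt(stats::ks.test(times, pexp_trunc)$p.value, 0.01)
})
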