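test_that("binding-curve fit recovers a deterministic censored sample", {
  # inverse-CDF construction: 700 binders on the exact Exponential(0.02)
  # quantile grid, 300 never-binders censored at 400 s
  k <- 0.02; a <- 0.7; n <- 1000
  u <- (seq_len(700) - 0.5) / 700
  times <- stats::qexp(u, k)
  ft <- tibble::tibble(
    time_s = c(pmin(times, 400), rep(400, 300)),
    censored = c(times > 400, rep(TRUE, 300)))
  fit <- fit_binding_cdf(ft, n_boot = 0)
  est <- tidy(fit)
  expect_lt(abs(est$estimate[est$term == "bound_fraction"] - a) / a, 0.01)
  expect_lt(abs(est$estimate[est$term == "k_obs"] - k) / k, 0.01)
  # the least-squares curve mode agrees on the same input
  expect_lt(abs(fit$extra$ls["k_obs"] - k) / k, 0.05)
  expect_lt(abs(fit$extra$ls["bound_fraction"] - a) / a, 0.05)
})

test_that("saturated binding hits the optimizer bound with a warning", {
  ft <- tibble::tibble(time_s = rep(0.2, 50), censored = FALSE)
  expect_warning(fit <- fit_binding_cdf(ft, method = "ls", n_boot = 0),
                 "saturated")
  est <- tidy(fit)
  expect_gt(est$estimate[est$term == "bound_fraction"], 0.95)
  ft0 <- tibble::tibble(time_s = rep(180, 10), censored = TRUE)
  expect_error(fit_binding_cdf(ft0), "no events")
})

test_that("dwell exponential MLE handles truncation and scale", {
  suppressWarnings({
    f <- fit_dwell_exponential(c(1, 2, 3))
    expect_equal(tidy(f)$estimate, 2)
  })
  # deterministic Exponential(2.7) quantile sample
  d <- stats::qexp((seq_len(1000) - 0.5) / 1000, 1 / 2.7)
  f2 <- fit_dwell_exponential(d, n_boot = 0)
  expect_lt(abs(tidy(f2)$estimate - 2.7), 0.01)
  # left truncation: shifting by the cutoff leaves tau unchanged
  f3 <- fit_dwell_exponential(d + 0.4, cutoff = 0.4, n_boot = 0)
  expect_equal(tidy(f3)$estimate, tidy(f2)$estimate, tolerance = 1e-9)
  # scale equivariance
  f4 <- fit_dwell_exponential(3 * d, n_boot = 0)
  expect_equal(tidy(f4)$estimate, 3 * tidy(f2)$estimate, tolerance = 1e-9)
  # the two modes agree on large samples
  expect_lt(abs(f2$extra$tau_hist - f2$extra$tau_mle) / f2$extra$tau_mle, 0.1)
  expect_error(fit_dwell_exponential(numeric(0)), "no durations")
})

test_that("Gaussian magnitude fit recovers a deterministic sample", {
  v <- stats::qnorm((seq_len(200) - 0.5) / 200, 0.38, 0.05)
  f <- fit_delta_e_gaussian(v, n_boot = 0)
  est <- tidy(f)
  expect_lt(abs(est$estimate[est$term == "mu"] - 0.38), 0.005)
  expect_lt(abs(est$estimate[est$term == "sigma"] - 0.05), 0.005)
  # all-equal values: mu reported, sigma degenerate with a warning
  expect_warning(f0 <- fit_delta_e_gaussian(rep(0.4, 30), n_boot = 0),
                 "sigma is undefined")
  est0 <- tidy(f0)
  expect_equal(est0$estimate[est0$term == "mu"], 0.4)
  expect_equal(est0$estimate[est0$term == "sigma"], 0)
})

test_that("FRET-change magnitude converts to nucleotide counts", {
  expect_equal(nucleotides_from_delta_e(0.38), 3.8)
  expect_equal(nucleotides_from_delta_e(0.4), 4.0)
  expect_equal(nucleotides_from_delta_e(0), 0)
  expect_error(nucleotides_from_delta_e(-0.1), class = "smkinetics_invalid")
  expect_error(nucleotides_from_delta_e(0.4, step = 0), class = "smkinetics_invalid")
})

test_that("fit objects expose broom-style and plot methods", {
  d <- stats::qexp((seq_len(100) - 0.5) / 100, 1 / 2)
  f <- fit_dwell_exponential(d, n_boot = 50, seed = 3L)
  expect_s3_class(tidy(f), "tbl_df")
  g <- glance(f)
  expect_equal(g$n_obs, 100)
  expect_true(is.finite(g$logLik))
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  expect_output(print(f), "dwell-exp")
})

test_that("simulated kinetics are recovered across the parameter grid", {
  # colocalization grid: binding rate x dwell, full simulate -> call -> fit
  rel_err <- c()
  k_in <- c(); k_out <- c()
  for (k in c(0.005, 0.01, 0.03)) {
    for (tau in c(1.5, 2.7)) {
      sc <- kinetic_scenario(k_bind = k, bound_fraction = 0.7,
                             tau_dwell = tau, photon_budget = 200,
                             n_molecules = 500L, seed = 91L)
      sim <- simulate_colocalization(sc)
      ev <- call_colocalization(sim$trajectories)
      ft <- first_binding_times(ev, unique(sim$trajectories$molecule_id),
                                sc$movie_length)
      est <- tidy(fit_binding_cdf(ft, n_boot = 0))
      k_hat <- est$estimate[est$term == "k_obs"]
      a_hat <- est$estimate[est$term == "bound_fraction"]
      suppressWarnings(
        tau_hat <- tidy(fit_dwell_exponential(ev$duration_s, cutoff = 0.4,
                                              n_boot = 0))$estimate)
      rel_err <- c(rel_err, abs(k_hat - k) / k, abs(a_hat - 0.7) / 0.7,
                   abs(tau_hat - tau) / tau)
      k_in <- c(k_in, k); k_out <- c(k_out, k_hat)
    }
  }
  expect_lt(stats::median(rel_err), 0.15)
  # fitted rate increases with the simulated rate
  expect_true(all(diff(tapply(k_out, k_in, mean)) > 0))

  # incorporation-dwell grid through the full FRET pipeline
  for (t_inc in c(2.4, 4.7)) {
    sc <- kinetic_scenario(t_incorporation = t_inc, n_nucleotides = 4L,
                           k_bind = 0.03, bound_fraction = 0.7,
                           tau_dwell = 2.7, photon_budget = 500,
                           n_molecules = 300L, seed = 92L)
    sim <- simulate_fret(sc)
    tr <- compute_efret(sim$trajectories,
                        correction_factors(sc$leakage, sc$direct_excitation,
                                           sc$gamma),
                        background = sc$background)
    ev <- call_fret_events(tr)
    tau_hat <- tidy(fit_dwell_exponential(ev$duration_s, n_boot = 0))$estimate
    expect_lt(abs(tau_hat - t_inc) / t_inc, 0.15)
  }
})
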