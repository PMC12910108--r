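#' Quantify species fractions from four-box gel densitometry
#'
#' Primer-extension gels are quantified with four boxes per lane: the
#' unextended substrate (0 nt), the 1-5 nt products, the 6-15 nt products,
#' and the whole lane. The fraction of each species is its box intensity
#' divided by the whole-lane intensity; whatever the three species boxes
#' do not account for is reported as the residual fraction.
#'
#' @param lanes Tibble with columns `i_0nt`, `i_1to5`, `i_6to15`,
#'   `i_lane` (and any identifying columns, which are carried through).
#' @return The input tibble with added columns `f_0nt`, `f_1to5`,
#'   `f_6to15`, `f_residual`.
#' @export
#' @examples
#' quantify_lane(tibble::tibble(i_0nt = 25, i_1to5 = 50, i_6to15 = 25,
#'                              i_lane = 100))
quantify_lane <- function(lanes) {
  need <- c("i_0nt", "i_1to5", "i_6to15", "i_lane")
  if (!all(need %in% names(lanes))) {
    stop_invalid(paste0("lanes must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(lanes$i_lane <= 0)) stop_invalid("whole-lane intensity must be > 0")
  if (any(lanes$i_0nt < 0 | lanes$i_1to5 < 0 | lanes$i_6to15 < 0)) {
    stop_invalid("box intensities must be >= 0")
  }
  box_sum <- lanes$i_0nt + lanes$i_1to5 + lanes$i_6to15
  if (any(box_sum > lanes$i_lane * (1 + 1e-9))) {
    stop_invalid("species boxes exceed the whole-lane intensity")
  }
  dplyr::mutate(tibble::as_tibble(lanes),
                f_0nt = .data$i_0nt / .data$i_lane,
                f_1to5 = .data$i_1to5 / .data$i_lane,
                f_6to15 = .data$i_6to15 / .data$i_lane,
                f_residual = 1 - .data$f_0nt - .data$f_1to5 - .data$f_6to15)
}

#' Average nucleotides incorporated over a gel time course
#'
#' Converts per-lane species fractions into a mean number of nucleotides
#' incorporated per time point, using a representative nucleotide count
#' per box (defaults: 0 for the unextended substrate and the bin midpoints
#' 3 and 10.5 for the 1-5 and 6-15 nt products). Replicate lanes at the
#' same time point are averaged, with the SD across replicates reported.
#'
#' @param lanes Tibble with a `time_point` column and the four box
#'   intensity columns of [quantify_lane()].
#' @param nt_values Representative nucleotide counts for the
#'   0 nt / 1-5 nt / 6-15 nt boxes.
#' @return Tibble: `time_point`, `mean_nt`, `sd_nt`, `n_lanes`.
#' @export
extension_time_course <- function(lanes, nt_values = c(0, 3, 10.5)) {
  if (length(nt_values) != 3) stop_invalid("nt_values must have 3 entries")
  if (!"time_point" %in% names(lanes)) stop_invalid("lanes must have time_point")
  fr <- quantify_lane(lanes)
  fr <- dplyr::mutate(fr,
    lane_mean_nt = (nt_values[1] * .data$f_0nt + nt_values[2] * .data$f_1to5 +
                      nt_values[3] * .data$f_6to15) /
      (.data$f_0nt + .data$f_1to5 + .data$f_6to15))
  dplyr::summarise(dplyr::group_by(fr, .data$time_point),
                   mean_nt = mean(.data$lane_mean_nt),
                   sd_nt = stats::sd(.data$lane_mean_nt),
                   n_lanes = dplyr::n(), .groups = "drop")
}

#' Fraction bound under a 1:1 binding model with ligand depletion
#'
#' Solves the quadratic mass-balance for a fixed target concentration `T`
#' titrated with total ligand `L`:
#' \deqn{f_b = \frac{(K_D + L + T) - \sqrt{(K_D + L + T)^2 - 4 L T}}{2T},}
#' evaluated in the numerically stable conjugate form so that the
#' hyperbolic limit \eqn{f_b \to L / (K_D + L)} is recovered exactly as
#' `T -> 0`.
#'
#' @param ligand Total ligand concentrations (molar).
#' @param target Total target concentration (molar).
#' @param kd Dissociation constant (molar).
#' @return Fraction of target bound, in `[0, 1]`.
#' @export
fraction_bound <- function(ligand, target, kd) {
  if (kd < 0 || target < 0) stop_invalid("kd and target must be >= 0")
  s <- kd + ligand + target
  disc <- pmax(s^2 - 4 * ligand * target, 0)
  2 * ligand / (s + sqrt(disc))
}

#' Two-fold serial dilution series
#'
#' @param top Highest concentration (molar).
#' @param n Number of points.
#' @param factor Dilution factor between successive points (default 2).
#' @return Descending concentration vector; the default 19-point series
#'   from 200 uM spans down to ~0.763 nM.
#' @export
dilution_series <- function(top = 200e-6, n = 19, factor = 2) {
  top / factor^(seq_len(n) - 1)
}

#' Simulate a thermophoresis-style titration curve
#'
#' Forward model: the normalized response interpolates linearly between
#' `r_free` and `r_bound` with the depletion-corrected fraction bound
#' ([fraction_bound()]); Gaussian noise with SD `noise` (in response
#' units; binding typically lowers the relative fluorescence, so the
#' default `r_bound < r_free`).
#'
#' @param kd Dissociation constant (molar).
#' @param target Target (labeled species) concentration (molar).
#' @param ligand Ligand concentration series (molar); default the 19-point
#'   2-fold series from 200 uM.
#' @param noise Gaussian response noise SD; default 2% of the response
#'   span.
#' @param r_free,r_bound Response of the free and bound target.
#' @param seed Seed.
#' @return Tibble: `ligand`, `response`, plus the true fraction bound
#'   `fb_true`; `target` carried as an attribute.
#' @export
simulate_titration <- function(kd, target = 50e-9, ligand = dilution_series(),
                               noise = 0.02, r_free = 1, r_bound = 0.8,
                               seed = 1L) {
  if (kd <= 0 || target <= 0) stop_invalid("kd and target must be > 0")
  fb <- fraction_bound(ligand, target, kd)
  withr::with_seed(seed, {
    resp <- r_free + (r_bound - r_free) * fb +
      rnorm(length(ligand), 0, noise * abs(r_bound - r_free))
    out <- tibble::tibble(ligand = ligand, response = resp, fb_true = fb)
    attr(out, "target") <- target
    out
  })
}

#' Fit a binding isotherm to a titration curve
#'
#' Least-squares fit of the 1:1 depletion-corrected binding model
#' `R(L) = r_free + (r_bound - r_free) * fb(L; K_D, T)` to a normalized
#' dose-response series, returning the dissociation constant. The fit is
#' sign-agnostic in the response (binding may raise or lower it) through
#' the free `r_free`/`r_bound` parameters.
#'
#' @param curve Tibble with columns `ligand` (molar) and `response`.
#' @param target Target concentration (molar); taken from the curve
#'   attribute if absent.
#' @param n_boot Bootstrap resamples (residual resampling) for the K_D
#'   standard error; 0 skips.
#' @param seed Seed for the bootstrap.
#' @return A `kin_fit` with terms `kd` (molar), `r_free`, `r_bound`.
#' @export
fit_isotherm <- function(curve, target = NULL, n_boot = 200, seed = 1L) {
  if (is.null(target)) target <- attr(curve, "target")
  if (is.null(target)) stop_invalid("target concentration required")
  if (nrow(curve) < 8) stop_invalid("need at least 8 concentrations")
  conc <- curve$ligand
  if (any(conc <= 0) || anyDuplicated(conc)) {
    stop_invalid("ligand concentrations must be positive and distinct")
  }
  if (diff(range(log10(conc))) < 3) {
    stop_invalid("concentration series must span >= 3 orders of magnitude")
  }
  resp <- curve$response
  ord <- order(conc)
  rs <- resp[ord]
  # monotonicity check beyond noise
  noise_sd <- stats::sd(diff(rs)) / sqrt(2)
  drift <- rs[length(rs)] - rs[1]
  if (abs(drift) < 2 * noise_sd) {
    warn("response is not monotone beyond noise; K_D is unidentifiable")
  }

  fit_once <- function(y) {
    df <- data.frame(L = conc, y = y)
    r_free0 <- rs[1]; r_bound0 <- rs[length(rs)]
    mid <- (r_free0 + r_bound0) / 2
    kd0 <- conc[ord][which.min(abs(rs - mid))]
    kd0 <- min(max(kd0, min(conc)), max(conc))
    lo_kd <- min(conc) / 1e3
    hi_kd <- max(conc) * 1e3
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ rf + (rb - rf) * fraction_bound(L, target, kd),
        data = df,
        start = list(rf = r_free0, rb = r_bound0, kd = kd0),
        lower = c(-Inf, -Inf, lo_kd), upper = c(Inf, Inf, hi_kd),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = coef(fit), rss = sum(resid(fit)^2),
         bounds = c(lo_kd, hi_kd))
  }

  res <- fit_once(resp)
  if (is.null(res)) stop_invalid("isotherm fit failed to converge")
  kd_hat <- unname(res$par["kd"])
  if (kd_hat <= res$bounds[1] * 1.01 || kd_hat >= res$bounds[2] * 0.99) {
    stop_invalid("K_D at parameter bound: fit did not converge")
  }

  kd_se <- NA_real_
  if (n_boot > 0) {
    pred <- res$par["rf"] + (res$par["rb"] - res$par["rf"]) *
      fraction_bound(conc, target, kd_hat)
    r <- resp - pred
    withr::with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(i) {
        y <- pred + sample(r, replace = TRUE)
        out <- fit_once(y)
        if (is.null(out)) NA_real_ else unname(out$par["kd"])
      }, numeric(1))
      kd_se <- stats::sd(reps, na.rm = TRUE)
    })
  }

  new_kin_fit(
    "isotherm",
    tibble::tibble(term = c("kd", "r_free", "r_bound"),
                   estimate = unname(res$par[c("kd", "rf", "rb")]),
                   std.error = c(kd_se, NA_real_, NA_real_)),
    n_obs = nrow(curve),
    goodness = list(rss = res$rss),
    data = tibble::tibble(ligand = conc, response = resp,
                          fitted = res$par["rf"] +
                            (res$par["rb"] - res$par["rf"]) *
                            fraction_bound(conc, target, kd_hat)),
    extra = list(target = target)
  )
}

#' Simulate a primer-extension gel time course
#'
#' Per-molecule nucleotide counts follow a Poisson extension process at
#' `rate` nucleotides per second, capped at `max_nt` (the template
#' length); counts are binned into the 0 / 1-5 / 6-15 nt boxes and scaled
#' to densitometry units with multiplicative log-normal noise per box.
#'
#' @param rate Extension rate (nt/s), >= 0.
#' @param time_points Reaction times (s).
#' @param n_molecules Molecules per lane.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   densitometry noise.
#' @param max_nt Template length cap (default 15).
#' @param scale Densitometry units per molecule.
#' @param seed Seed.
#' @return A lane tibble compatible with [quantify_lane()], one row per
#'   time point, with `lane_label` and `time_point`.
#' @export
simulate_gel_series <- function(rate, time_points, n_molecules = 1e4,
                                noise_cv = 0.05, max_nt = 15, scale = 1,
                                seed = 1L) {
  if (rate < 0) stop_invalid("rate must be >= 0")
  withr::with_seed(seed, {
    rows <- lapply(seq_along(time_points), function(i) {
      tp <- time_points[i]
      nt <- pmin(rpois(n_molecules, rate * tp), max_nt)
      counts <- c(sum(nt == 0), sum(nt >= 1 & nt <= 5), sum(nt >= 6))
      noisy <- counts * scale * exp(rnorm(3, 0, noise_cv))
      tibble::tibble(lane_label = paste0("t", tp), time_point = tp,
                     i_0nt = noisy[1], i_1to5 = noisy[2], i_6to15 = noisy[3],
                     i_lane = sum(noisy))
    })
    dplyr::bind_rows(rows)
  })
}
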