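#' Photophysical correction factors
#'
#' Bundles the three standard ALEX corrections: donor-to-acceptor leakage
#' `l`, direct acceptor excitation `d`, and the gamma detection/quantum
#' yield imbalance.
#'
#' @param leakage Leakage fraction in `[0, 1)`.
#' @param direct_excitation Direct-excitation fraction in `[0, 1)`.
#' @param gamma Gamma factor (> 0).
#' @return An object of class `correction_factors`.
#' @export
correction_factors <- function(leakage = 0, direct_excitation = 0, gamma = 1) {
  if (leakage < 0 || leakage >= 1) stop_invalid("leakage must be in [0, 1)")
  if (direct_excitation < 0 || direct_excitation >= 1) {
    stop_invalid("direct_excitation must be in [0, 1)")
  }
  if (!is.finite(gamma) || gamma <= 0) stop_invalid("gamma must be > 0")
  structure(list(leakage = leakage, direct_excitation = direct_excitation,
                 gamma = gamma),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("<correction_factors> l = %.4f, d = %.4f, gamma = %.4f\n",
              x$leakage, x$direct_excitation, x$gamma))
  invisible(x)
}

#' Estimate correction factors from calibration trajectories
#'
#' Leakage is the mean `F_DA / F_DD` ratio over donor-only molecules;
#' direct excitation is the mean `F_DA / F_AA` ratio over acceptor-only
#' molecules. Gamma is estimated from acceptor photobleaching transitions
#' in FRET trajectories: when the acceptor bleaches mid-binding, the
#' leakage/direct-corrected FRET signal drops by `gamma * E * I` while the
#' donor recovers by `E * I`, so the ratio of the two changes is gamma.
#' With fewer than `min_transitions` usable transitions gamma falls back to
#' 1 with a warning.
#'
#' The camera background must be removed before ratioing; pass the mean
#' background photons per frame (e.g. measured at dark positions) as
#' `background`.
#'
#' @param donor_only Trajectory tibble of donor-only molecules.
#' @param acceptor_only Trajectory tibble of acceptor-only molecules.
#' @param fret Optional trajectory tibble of FRET molecules with acceptor
#'   bleaching events, used for gamma.
#' @param background Mean background photons per frame and channel.
#' @param min_transitions Minimum usable acceptor-bleach transitions before
#'   gamma is estimated rather than defaulted (default 5).
#' @param min_signal Minimum background-subtracted denominator signal for a
#'   frame to enter a calibration ratio (default 20 photons).
#' @return A [correction_factors()] object.
#' @export
estimate_factors <- function(donor_only, acceptor_only, fret = NULL,
                             background = 0, min_transitions = 5,
                             min_signal = 20) {
  if (is.null(donor_only) || nrow(donor_only) == 0) {
    stop_invalid("empty donor-only calibration set")
  }
  if (is.null(acceptor_only) || nrow(acceptor_only) == 0) {
    stop_invalid("empty acceptor-only calibration set")
  }
  dd <- donor_only$F_DD - background
  keep <- dd > min_signal
  if (!any(keep)) stop_invalid("no usable donor-only frames")
  l <- mean((donor_only$F_DA[keep] - background) / dd[keep])

  aa <- acceptor_only$F_AA - background
  keep <- aa > min_signal
  if (!any(keep)) stop_invalid("no usable acceptor-only frames")
  d <- mean((acceptor_only$F_DA[keep] - background) / aa[keep])

  l <- max(0, min(l, 1 - 1e-9))
  d <- max(0, min(d, 1 - 1e-9))

  g <- gamma_from_bleach(fret, l, d, background, min_transitions)
  correction_factors(l, d, g)
}

# gamma from acceptor-bleach transitions: ratio of the corrected FRET-channel
# drop to the donor-channel recovery across the bleach step.
gamma_from_bleach <- function(fret, l, d, background, min_transitions,
                              window = 10) {
  fallback <- function(msg) {
    warn(paste0("gamma fallback to 1.0: ", msg))
    1.0
  }
  if (is.null(fret) || nrow(fret) == 0) {
    return(fallback("no FRET calibration trajectories supplied"))
  }
  ratios <- c()
  for (df in split(fret, fret$molecule_id)) {
    b <- detect_bleach_channel(df$F_AA, background)
    if (is.na(b)) next
    pre <- df[df$frame >= b - window & df$frame < b, , drop = FALSE]
    post <- df[df$frame >= b & df$frame < b + window, , drop = FALSE]
    # both windows must be bound (acceptor present before; donor alive after)
    if (nrow(pre) < 3 || nrow(post) < 3) next
    if (mean(post$F_DD) - background < 2 * sqrt(background + 1)) next
    fda_pre <- mean(pre$F_DA - background - l * (pre$F_DD - background) -
                      d * (pre$F_AA - background))
    fda_post <- mean(post$F_DA - background - l * (post$F_DD - background) -
                       d * (post$F_AA - background))
    ddd <- mean(post$F_DD) - mean(pre$F_DD)
    if (ddd <= 0) next
    ratios <- c(ratios, (fda_pre - fda_post) / ddd)
  }
  ratios <- ratios[is.finite(ratios) & ratios > 0]
  if (length(ratios) < min_transitions) {
    return(fallback(sprintf("only %d usable acceptor-bleach transitions",
                            length(ratios))))
  }
  stats::median(ratios)
}

#' Compute corrected FRET efficiency per frame
#'
#' Applies the standard ALEX correction sequence to a three-channel
#' trajectory: leakage and direct excitation are subtracted from the FRET
#' channel first, then the gamma-weighted donor signal enters the
#' denominator:
#' \deqn{F_{corr} = F_{DA} - l F_{DD} - d F_{AA}, \quad
#'       E = F_{corr} / (F_{corr} + \gamma F_{DD}).}
#' Frames at or after either dye's detected photobleaching step are marked
#' invalid, as are frames whose denominator is non-positive.
#'
#' @param traj Trajectory tibble (one or many molecules).
#' @param factors A [correction_factors()] object.
#' @param background Mean background photons per frame and channel,
#'   subtracted from every channel before correction (default 0).
#' @param bleach Optional precomputed [detect_bleach()] table; computed
#'   from `traj` when `NULL`. Use `bleach = FALSE` to skip bleach
#'   truncation entirely.
#' @return A tibble (`molecule_id`, `frame`, `time_s`, `E`, `valid`,
#'   `F_DD`, `F_DA`, `F_AA`) with the frame interval carried as an
#'   attribute. `E` is left unclipped; values outside `[0, 1]` are
#'   tolerated and simply fall outside downstream event windows.
#' @export
compute_efret <- function(traj, factors, background = 0, bleach = NULL) {
  stopifnot(inherits(factors, "correction_factors"))
  if (!all(is.finite(unlist(factors)))) stop_invalid("non-finite factors")
  if (is.null(bleach)) {
    bleach <- detect_bleach(traj, background = background)
  }
  dd <- traj$F_DD - background
  da <- traj$F_DA - background
  aa <- traj$F_AA - background
  f_corr <- da - factors$leakage * dd - factors$direct_excitation * aa
  denom <- f_corr + factors$gamma * dd
  e <- ifelse(denom > 0, f_corr / denom, NA_real_)
  valid <- denom > 0
  if (!isFALSE(bleach) && nrow(bleach) > 0) {
    first_bleach <- pmin(bleach$donor_bleach_frame, bleach$acceptor_bleach_frame,
                         na.rm = TRUE)
    first_bleach[is.na(bleach$donor_bleach_frame) &
                   is.na(bleach$acceptor_bleach_frame)] <- Inf
    cut <- first_bleach[match(traj$molecule_id, bleach$molecule_id)]
    cut[is.na(cut)] <- Inf
    valid <- valid & traj$frame < cut
  }
  out <- tibble::tibble(
    molecule_id = traj$molecule_id,
    frame = traj$frame,
    time_s = traj$time_s,
    E = e,
    valid = valid,
    F_DD = traj$F_DD, F_DA = traj$F_DA, F_AA = traj$F_AA
  )
  attr(out, "frame_interval") <- frame_dt(traj)
  out
}

#' Detect single-step photobleaching per dye
#'
#' For each molecule and each dye channel (`F_DD` for the donor, `F_AA`
#' for the acceptor) the best two-segment mean shift is located by
#' maximizing the between-segment sum of squares. The changepoint is
#' accepted as a bleach only when the post-step mean falls below
#' `background + 2 * sqrt(background + 1)` (shot-noise band around the
#' camera background) and the step is downward; otherwise the channel is
#' reported unbleached (`NA`).
#'
#' @param traj Trajectory tibble.
#' @param background Mean background photons per frame and channel.
#' @return A tibble with one row per molecule: `molecule_id`,
#'   `donor_bleach_frame`, `acceptor_bleach_frame` (frame index of the
#'   first bleached frame, or `NA`).
#' @export
detect_bleach <- function(traj, background = 0) {
  res <- lapply(split(traj, traj$molecule_id), function(df) {
    tibble::tibble(
      molecule_id = df$molecule_id[1],
      donor_bleach_frame = detect_bleach_channel(df$F_DD, background),
      acceptor_bleach_frame = detect_bleach_channel(df$F_AA, background)
    )
  })
  dplyr::bind_rows(res)
}

# single-channel changepoint: argmax of the two-segment between-group SS
detect_bleach_channel <- function(x, background = 0) {
  n <- length(x)
  if (n < 4) return(NA_integer_)
  cs <- cumsum(x)
  k <- seq_len(n - 1)
  mean_pre <- cs[k] / k
  mean_post <- (cs[n] - cs[k]) / (n - k)
  between_ss <- k * (n - k) / n * (mean_pre - mean_post)^2
  kk <- which.max(between_ss)
  post <- mean_post[kk]
  pre <- mean_pre[kk]
  if (post >= pre) return(NA_integer_)
  if (post > background + 2 * sqrt(background + 1)) return(NA_integer_)
  # the step must stand out of shot noise, or a flat background trace
  # would yield a spurious changepoint
  if (pre - post < 3 * sqrt(pre + 1)) return(NA_integer_)
  as.integer(kk + 1L)
}
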