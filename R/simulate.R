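#' Simulate two-color colocalization trajectories
#'
#' Generates per-molecule, per-frame photon counts in the three
#' alternating-excitation channels for a colocalization experiment: a
#' surface-tethered donor-labeled DNA (constant-bright in `F_DD` until it
#' photobleaches) visited transiently by an acceptor-labeled polymerase
#' (`F_AA` bright while bound). A molecule binds at all with probability
#' `bound_fraction`; its first arrival is exponential with rate `k_bind`,
#' every bound dwell is exponential with mean `tau_dwell`, and gaps between
#' dissociation and rebinding are again exponential with rate `k_bind`.
#' FRET fields of the scenario are ignored (the donor dye sits far from the
#' junction in this geometry); `F_DA` carries only leakage and direct
#' excitation.
#'
#' Counts are occupancy-weighted over each exposure (the camera integrates
#' photons over the full frame), then Poisson-sampled on top of a constant
#' Poisson background when `noise = TRUE`. With `noise = FALSE` the exact
#' expected counts are returned with zero background, which is convenient
#' for closure tests.
#'
#' @param scenario A [kinetic_scenario()].
#' @param noise Logical; Poisson shot noise and background (default `TRUE`).
#' @return A list with elements `trajectories` (tibble: `molecule_id`,
#'   `frame`, `time_s`, `F_DD`, `F_DA`, `F_AA`; attribute `frame_interval`)
#'   and `truth` (tibble of ground-truth events: `molecule_id`, `kind`,
#'   `t_start_s`, `t_end_s`, `nt_index`, `dye`).
#' @export
#' @examples
#' sim <- simulate_colocalization(kinetic_scenario(n_molecules = 5, seed = 2))
#' head(sim$trajectories)
simulate_colocalization <- function(scenario, noise = TRUE) {
  validate_scenario(scenario)
  withr::with_seed(scenario$seed, {
    sim_molecules(scenario, noise = noise, mode = "coloc")
  })
}

#' Simulate FRET nucleotide-incorporation trajectories
#'
#' Generates three-channel trajectories for the FRET geometry: the donor
#' dye sits 11 nucleotides from the primer-template junction, so polymerase
#' binding produces a FRET efficiency of `e_start` that steps down by
#' `delta_e_per_nt` at each incorporated nucleotide. Per-nucleotide waiting
#' times are exponential with mean `t_incorporation / n_nucleotides`; after
#' the last incorporation the polymerase dissociates after an exponential
#' residual dwell of mean `tau_dwell`. Each molecule hosts at most one
#' productive binding (the primer is extended by the event, so a rebinding
#' would not restore the starting FRET state).
#'
#' Ideal channel means while bound are `F_DD = (1 - E) * photon_budget` and
#' `F_DA_ideal = gamma * E * photon_budget`; the recorded FRET channel is
#' distorted as `F_DA = F_DA_ideal + leakage * F_DD + direct_excitation *
#' F_AA` before Poisson sampling. `F_AA` is constant at `photon_budget`
#' while the acceptor is present and unbleached. Single-step photobleaching
#' truncates each dye (acceptor bleach dequenches the donor; donor bleach
#' silences `F_DD` and the FRET pathway).
#'
#' @inheritParams simulate_colocalization
#' @return Same structure as [simulate_colocalization()].
#' @export
simulate_fret <- function(scenario, noise = TRUE) {
  validate_scenario(scenario)
  withr::with_seed(scenario$seed, {
    sim_molecules(scenario, noise = noise, mode = "fret")
  })
}

# Shared trajectory engine. Builds, per molecule, a piecewise-constant
# timeline of ideal channel means, integrates it over exposures, applies
# channel mixing and (optionally) Poisson noise.
sim_molecules <- function(sc, noise, mode) {
  dt <- sc$frame_interval
  n_frames <- as.integer(floor(sc$movie_length / dt))
  if (n_frames < 1) stop_invalid("movie shorter than one frame")
  B <- sc$photon_budget
  bg <- if (noise) sc$background else 0

  truth <- vector("list", sc$n_molecules)
  dd <- da <- aa <- matrix(0, nrow = n_frames, ncol = sc$n_molecules)

  for (m in seq_len(sc$n_molecules)) {
    binder <- runif(1) < sc$bound_fraction
    donor_bleach <- rexp(1, 1 / sc$bleach_tau_donor)
    ev <- list()

    if (mode == "coloc") {
      # alternating gap/dwell renewal process of binding events
      bound_iv <- matrix(numeric(0), ncol = 2)
      if (binder) {
        t <- rexp(1, sc$k_bind)
        while (t < sc$movie_length) {
          d <- rexp(1, 1 / sc$tau_dwell)
          bound_iv <- rbind(bound_iv, c(t, min(t + d, sc$movie_length)))
          t <- t + d + rexp(1, sc$k_bind)
        }
      }
      # acceptor channel: photon_budget while bound
      if (nrow(bound_iv) > 0) {
        breaks <- c(0, as.vector(t(bound_iv)))
        values <- c(0, rep(c(B, 0), nrow(bound_iv)))[seq_along(breaks)]
        aa[, m] <- piecewise_frame_means(breaks, values, n_frames, dt)
        ev <- c(ev, lapply(seq_len(nrow(bound_iv)), function(i) {
          data.frame(molecule_id = m, kind = "binding",
                     t_start_s = bound_iv[i, 1], t_end_s = bound_iv[i, 2],
                     nt_index = NA_integer_, dye = NA_character_)
        }))
      }
      # donor (DNA) channel: constant-bright until bleach
      if (donor_bleach < sc$movie_length) {
        dd[, m] <- piecewise_frame_means(c(0, donor_bleach), c(B, 0), n_frames, dt)
        ev <- c(ev, list(data.frame(molecule_id = m, kind = "bleach",
                                    t_start_s = donor_bleach,
                                    t_end_s = sc$movie_length,
                                    nt_index = NA_integer_, dye = "donor")))
      } else {
        dd[, m] <- B
      }
      da[, m] <- sc$leakage * dd[, m] + sc$direct_excitation * aa[, m]
    } else {
      # FRET mode: single productive binding with an incorporation staircase
      e_breaks <- 0; e_vals <- 0
      a_breaks <- 0; a_vals <- 0
      if (binder) {
        t_arr <- rexp(1, sc$k_bind)
        if (t_arr >= sc$movie_length) binder <- FALSE
      }
      if (binder) {
        waits <- if (sc$n_nucleotides > 0) {
          rexp(sc$n_nucleotides, sc$n_nucleotides / sc$t_incorporation)
        } else {
          numeric(0)
        }
        steps <- t_arr + cumsum(waits)
        t_diss <- (if (length(steps)) steps[length(steps)] else t_arr) +
          rexp(1, 1 / sc$tau_dwell)
        acceptor_bleach <- t_arr + rexp(1, 1 / sc$bleach_tau_acceptor)
        a_end <- min(t_diss, acceptor_bleach, sc$movie_length)

        if (t_arr < sc$movie_length) {
          ev <- c(ev, list(data.frame(molecule_id = m, kind = "binding",
                                      t_start_s = t_arr,
                                      t_end_s = min(t_diss, sc$movie_length),
                                      nt_index = NA_integer_,
                                      dye = NA_character_)))
          prev <- t_arr
          for (j in seq_along(steps)) {
            if (steps[j] >= sc$movie_length) break
            ev <- c(ev, list(data.frame(molecule_id = m,
                                        kind = "incorporation-step",
                                        t_start_s = prev, t_end_s = steps[j],
                                        nt_index = j, dye = NA_character_)))
            prev <- steps[j]
          }
          if (acceptor_bleach < min(t_diss, sc$movie_length)) {
            ev <- c(ev, list(data.frame(molecule_id = m, kind = "bleach",
                                        t_start_s = acceptor_bleach,
                                        t_end_s = sc$movie_length,
                                        nt_index = NA_integer_,
                                        dye = "acceptor")))
          }
        }

        # E(t) and acceptor presence as piecewise levels
        e_breaks <- c(0, t_arr, steps[steps < a_end], a_end)
        n_in <- sum(steps < a_end)
        e_vals <- c(0, sc$e_start - seq(0, n_in) * sc$delta_e_per_nt, 0)
        a_breaks <- c(0, t_arr, a_end)
        a_vals <- c(0, B, 0)
      }
      if (donor_bleach < sc$movie_length) {
        ev <- c(ev, list(data.frame(molecule_id = m, kind = "bleach",
                                    t_start_s = donor_bleach,
                                    t_end_s = sc$movie_length,
                                    nt_index = NA_integer_, dye = "donor")))
      }
      e_frame <- piecewise_frame_means(e_breaks, e_vals, n_frames, dt)
      a_on <- piecewise_frame_means(a_breaks, a_vals, n_frames, dt)
      d_on <- piecewise_frame_means(c(0, min(donor_bleach, sc$movie_length)),
                                    c(1, 0), n_frames, dt)
      if (donor_bleach >= sc$movie_length) d_on <- rep(1, n_frames)
      dd[, m] <- d_on * (1 - e_frame) * B
      da_ideal <- d_on * sc$gamma * e_frame * B
      aa[, m] <- a_on
      da[, m] <- da_ideal + sc$leakage * dd[, m] + sc$direct_excitation * aa[, m]
    }

    truth[[m]] <- if (length(ev)) do.call(rbind, ev) else NULL
  }

  if (noise) {
    n <- length(dd)
    dd[] <- rpois(n, dd + bg)
    da[] <- rpois(n, da + bg)
    aa[] <- rpois(n, aa + bg)
  }

  traj <- tibble::tibble(
    molecule_id = rep(seq_len(sc$n_molecules), each = n_frames),
    frame = rep(seq_len(n_frames), sc$n_molecules),
    time_s = rep((seq_len(n_frames) - 1) * dt, sc$n_molecules),
    F_DD = as.vector(dd),
    F_DA = as.vector(da),
    F_AA = as.vector(aa)
  )
  attr(traj, "frame_interval") <- dt
  attr(traj, "condition_label") <- sc$condition_label

  truth_df <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  truth_tb <- if (is.null(truth_df)) {
    tibble::tibble(molecule_id = integer(), kind = character(),
                   t_start_s = numeric(), t_end_s = numeric(),
                   nt_index = integer(), dye = character())
  } else {
    tibble::as_tibble(truth_df)
  }
  list(trajectories = traj, truth = truth_tb)
}

#' Single-species calibration trajectories
#'
#' `simulate_donor_only()` emulates a field of donor-only molecules (no
#' acceptor present): `F_DD` is bright until donor bleach, `F_DA` carries
#' only leakage, and `F_AA` is background. `simulate_acceptor_only()`
#' emulates acceptor-only molecules: `F_AA` bright until acceptor bleach,
#' `F_DA` carries only direct excitation, `F_DD` is background. These are
#' the standard inputs for estimating leakage and direct-excitation
#' factors with [estimate_factors()].
#'
#' @inheritParams simulate_colocalization
#' @return A trajectory tibble as in [simulate_colocalization()].
#' @export
simulate_donor_only <- function(scenario, noise = TRUE) {
  simulate_single_species(scenario, noise, donor = TRUE)
}

#' @rdname simulate_donor_only
#' @export
simulate_acceptor_only <- function(scenario, noise = TRUE) {
  simulate_single_species(scenario, noise, donor = FALSE)
}

simulate_single_species <- function(sc, noise, donor) {
  validate_scenario(sc)
  withr::with_seed(sc$seed + as.integer(!donor), {
    dt <- sc$frame_interval
    n_frames <- as.integer(floor(sc$movie_length / dt))
    B <- sc$photon_budget
    bg <- if (noise) sc$background else 0
    tau <- if (donor) sc$bleach_tau_donor else sc$bleach_tau_acceptor
    main <- matrix(0, n_frames, sc$n_molecules)
    for (m in seq_len(sc$n_molecules)) {
      tb <- rexp(1, 1 / tau)
      main[, m] <- if (tb < sc$movie_length) {
        piecewise_frame_means(c(0, tb), c(B, 0), n_frames, dt)
      } else {
        rep(B, n_frames)
      }
    }
    dd <- if (donor) main else matrix(0, n_frames, sc$n_molecules)
    aa <- if (donor) matrix(0, n_frames, sc$n_molecules) else main
    da <- sc$leakage * dd + sc$direct_excitation * aa
    if (noise) {
      n <- length(dd)
      dd[] <- rpois(n, dd + bg)
      da[] <- rpois(n, da + bg)
      aa[] <- rpois(n, aa + bg)
    }
    traj <- tibble::tibble(
      molecule_id = rep(seq_len(sc$n_molecules), each = n_frames),
      frame = rep(seq_len(n_frames), sc$n_molecules),
      time_s = rep((seq_len(n_frames) - 1) * dt, sc$n_molecules),
      F_DD = as.vector(dd), F_DA = as.vector(da), F_AA = as.vector(aa)
    )
    attr(traj, "frame_interval") <- dt
    traj
  })
}

#' Read or write trajectory tables
#'
#' Trajectories travel as plain TSV with the header columns
#' `molecule_id`, `frame`, `time_s`, `F_DD`, `F_DA`, `F_AA`.
#'
#' @param traj A trajectory tibble.
#' @param path File path.
#' @param frame_interval Frame interval in seconds to attach on read; if
#'   `NULL` it is inferred from the `time_s` column.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns a trajectory tibble.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.table(traj, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, frame_interval = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("molecule_id", "frame", "time_s", "F_DD", "F_DA", "F_AA")
  if (!all(need %in% names(df))) {
    stop_invalid(paste0("trajectory file must have columns: ",
                        paste(need, collapse = ", ")))
  }
  traj <- tibble::as_tibble(df)
  if (is.null(frame_interval)) {
    ts <- sort(unique(traj$time_s))
    frame_interval <- if (length(ts) > 1) min(diff(ts)) else 0.2
  }
  attr(traj, "frame_interval") <- frame_interval
  traj
}

# frame interval attached to a trajectory/trace tibble, with fallback
frame_dt <- function(x, default = 0.2) {
  attr(x, "frame_interval") %||% default
}
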