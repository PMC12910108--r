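#' Call colocalization events from an acceptor-channel trajectory
#'
#' A colocalization event is a maximal run of frames whose partner-channel
#' intensity exceeds `threshold` photons. Runs separated by fewer than
#' `gap_frames` sub-threshold frames are merged into a single event (the
#' "at least three frames between successive events" rule read as a merge,
#' so that brief single-frame dropouts do not split one dwell in two), and
#' merged runs shorter than `min_frames` frames are discarded (events must
#' last at least two frames).
#'
#' @param traj Trajectory tibble (one or many molecules).
#' @param threshold Intensity threshold in photons (default 50).
#' @param min_frames Minimum event length in frames (default 2).
#' @param gap_frames Minimum number of sub-threshold frames that separates
#'   two events (default 3); shorter gaps are merged.
#' @param channel Column holding the partner intensity (default `"F_AA"`,
#'   the acceptor under direct excitation).
#' @return A tibble of events ordered by molecule and start frame:
#'   `molecule_id`, `start_frame`, `end_frame`, `n_frames`, `start_s`,
#'   `end_s`, `duration_s`, `mean_intensity`.
#' @export
#' @examples
#' sc <- kinetic_scenario(photon_budget = 200, n_molecules = 10, seed = 3)
#' sim <- simulate_colocalization(sc)
#' call_colocalization(sim$trajectories)
call_colocalization <- function(traj, threshold = 50, min_frames = 2,
                                gap_frames = 3, channel = "F_AA") {
  if (threshold <= 0) stop_invalid("threshold must be > 0")
  dt <- frame_dt(traj)
  if (is.null(traj) || nrow(traj) == 0) {
    return(empty_coloc_events())
  }
  res <- lapply(split(traj, traj$molecule_id), function(df) {
    df <- df[order(df$frame), , drop = FALSE]
    x <- df[[channel]]
    runs <- runs_with_gaps(x > threshold, gap_frames)
    runs <- runs[runs$end - runs$start + 1L >= min_frames, , drop = FALSE]
    if (nrow(runs) == 0) return(NULL)
    tibble::tibble(
      molecule_id = df$molecule_id[1],
      start_frame = df$frame[runs$start],
      end_frame = df$frame[runs$end],
      n_frames = runs$end - runs$start + 1L,
      mean_intensity = vapply(seq_len(nrow(runs)), function(i) {
        mean(x[runs$start[i]:runs$end[i]])
      }, numeric(1))
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(empty_coloc_events())
  out <- dplyr::mutate(out,
                       start_s = (.data$start_frame - 1) * dt,
                       end_s = .data$end_frame * dt,
                       duration_s = .data$n_frames * dt)
  out <- dplyr::arrange(out, .data$molecule_id, .data$start_frame)
  dplyr::select(out, "molecule_id", "start_frame", "end_frame", "n_frames",
                "start_s", "end_s", "duration_s", "mean_intensity")
}

empty_coloc_events <- function() {
  tibble::tibble(molecule_id = integer(), start_frame = integer(),
                 end_frame = integer(), n_frames = integer(),
                 start_s = numeric(), end_s = numeric(),
                 duration_s = numeric(), mean_intensity = numeric())
}

#' First binding time per molecule, with right censoring
#'
#' Reduces called colocalization events to the start time of the earliest
#' event on each molecule. Molecules in `molecule_ids` without any event
#' are right-censored at the end of the observation window; they enter the
#' denominator of the cumulative fraction-bound curve but never the
#' numerator.
#'
#' @param events Event tibble from [call_colocalization()].
#' @param molecule_ids Vector of all observed molecule ids (binders and
#'   non-binders alike).
#' @param observation_window Observation window length in seconds.
#' @return A tibble: `molecule_id`, `time_s`, `censored`.
#' @export
first_binding_times <- function(events, molecule_ids, observation_window) {
  firsts <- dplyr::summarise(dplyr::group_by(events, .data$molecule_id),
                             time_s = min(.data$start_s), .groups = "drop")
  out <- tibble::tibble(molecule_id = unique(molecule_ids))
  out <- dplyr::left_join(out, firsts, by = "molecule_id")
  out$censored <- is.na(out$time_s)
  out$time_s[out$censored] <- observation_window
  out
}

#' Call FRET incorporation events from a corrected efficiency trace
#'
#' A candidate event is a maximal run of valid frames whose corrected
#' efficiency lies in the quantitative FRET window `[e_min, e_max]` (the
#' linear range of the dye pair), with interior out-of-window gaps shorter
#' than `gap_frames` frames merged. A candidate is kept when it lasts at
#' least `min_frames` frames (1 s at five 200 ms frames), is shorter than
#' `max_duration_s` (outlier rejection), and its ordinary-least-squares
#' slope of E versus time is strictly negative (incorporation only moves
#' the polymerase away from the donor).
#'
#' The magnitude of the FRET decrease `delta_e` is computed per
#' `delta_e_method`:
#' \describe{
#'   \item{`"plateau"` (default)}{difference between the first-frame E and
#'     the post-event terminal level: the median E of the valid frames
#'     immediately after the run while the trace still shows signal
#'     (E above `plateau_floor`). An incorporation staircase that ends
#'     below `e_min` leaves the window before it reaches its final level,
#'     so the terminal level just outside the window carries the last
#'     nucleotide's contribution; when no such plateau exists (the trace
#'     ends, the dye bleaches, or the polymerase dissociates immediately)
#'     the endpoint difference is used.}
#'   \item{`"endpoint"`}{`E(first frame) - E(last frame)` of the run.}
#'   \item{`"fit"`}{drop of the fitted OLS line across the run.}
#' }
#'
#' @param trace Corrected trace from [compute_efret()] (one or many
#'   molecules).
#' @param e_min,e_max Quantitative FRET window (defaults 0.3 and 0.8).
#' @param min_frames Minimum event length in frames (default 5).
#' @param max_duration_s Maximum event duration in seconds (default 20).
#' @param gap_frames Minimum number of out-of-window frames separating two
#'   events (default 3); shorter interior gaps are merged.
#' @param delta_e_method How to measure the FRET decrease (see Details).
#' @param events_per_molecule `"first"` (default) keeps only the earliest
#'   qualifying event on each molecule: the substrate is single-turnover
#'   (the primer is consumed by the incorporation event), so later
#'   in-window excursions on the same molecule are residual-level
#'   artifacts, not new incorporation events. `"all"` returns every
#'   qualifying run.
#' @param plateau_floor Minimum E for a post-event frame to count as
#'   signal rather than an unbound/dark frame (default 0.1).
#' @param plateau_window Number of post-event frames inspected for the
#'   terminal plateau (default 25).
#' @param plateau_min_frames Minimum plateau length in frames (default 2).
#' @param plateau_margin The plateau must sit at least this far below the
#'   last in-window frame to be used (default 0.05, half a nucleotide
#'   step).
#' @return A tibble of events: `molecule_id`, `start_frame`, `end_frame`,
#'   `n_frames`, `start_s`, `end_s`, `duration_s`, `delta_e`, `slope`,
#'   `e_first`, `e_last`.
#' @export
call_fret_events <- function(trace, e_min = 0.3, e_max = 0.8,
                             min_frames = 5, max_duration_s = 20,
                             gap_frames = 3,
                             delta_e_method = c("plateau", "endpoint", "fit"),
                             events_per_molecule = c("first", "all"),
                             plateau_floor = 0.1, plateau_window = 25,
                             plateau_min_frames = 2, plateau_margin = 0.05) {
  delta_e_method <- match.arg(delta_e_method)
  events_per_molecule <- match.arg(events_per_molecule)
  dt <- frame_dt(trace)
  if (is.null(trace) || nrow(trace) == 0) return(empty_fret_events())

  res <- lapply(split(trace, trace$molecule_id), function(df) {
    df <- df[order(df$frame), , drop = FALSE]
    e <- df$E
    ok <- df$valid & !is.na(e) & e >= e_min & e <= e_max
    runs <- runs_with_gaps(ok, gap_frames)
    if (nrow(runs) == 0) return(NULL)
    evs <- lapply(seq_len(nrow(runs)), function(i) {
      s <- runs$start[i]; en <- runs$end[i]
      nf <- en - s + 1L
      dur <- nf * dt
      if (nf < min_frames || dur >= max_duration_s) return(NULL)
      idx <- s:en
      use <- idx[df$valid[idx] & !is.na(e[idx])]
      if (length(use) < 3) return(NULL)
      tt <- df$time_s[use]
      ee <- e[use]
      slope <- stats::cov(tt, ee) / stats::var(tt)
      if (!is.finite(slope) || slope >= 0) return(NULL)
      e_first <- e[s]
      e_last <- e[en]
      # robust level estimates: the entry and exit frames of a run are
      # partial-occupancy transition frames, so skip them when the run is
      # long enough
      # the top of the staircase is only visible until the first
      # incorporation, possibly for a single frame: take the highest of
      # the first frames rather than an average
      e_start_robust <- max(e[s:min(s + 2, en)])
      e_end_robust <- if (nf >= 4) {
        stats::median(e[max(s, en - 3):(en - 1)])
      } else {
        e_last
      }
      de <- e_first - e_last
      ext <- 0L
      if (delta_e_method == "fit") {
        de <- -slope * (df$time_s[en] - df$time_s[s])
      } else if (delta_e_method == "plateau") {
        # post-run frames while the trace still shows signal: the
        # terminal level of a staircase that ends below the window
        streak <- integer(0)
        p <- en + 1L
        while (p <= min(en + plateau_window, nrow(df))) {
          if (!isTRUE(df$valid[p]) || is.na(e[p]) || e[p] <= plateau_floor) break
          streak <- c(streak, p)
          p <- p + 1L
        }
        if (length(streak) >= plateau_min_frames) {
          terminal <- stats::median(e[utils::tail(streak, 5)])
          de <- e_start_robust - terminal
          if (terminal < e_min - plateau_margin) {
            # the decrease ran out of the window before settling: refine
            # the event end to where the trace reaches the terminal level
            midpoint <- (e_min + terminal) / 2
            flag <- e[streak] >= midpoint
            if (isTRUE(flag[1])) {
              rr <- runs_with_gaps(flag, gap_frames)
              ext <- rr$end[1]
            }
          }
        } else {
          de <- e_start_robust - e_end_robust
        }
      }
      en_ext <- en + ext
      nf_ext <- nf + ext
      dur_ext <- nf_ext * dt
      if (dur_ext >= max_duration_s) return(NULL)
      tibble::tibble(
        molecule_id = df$molecule_id[1],
        start_frame = df$frame[s], end_frame = df$frame[en_ext],
        n_frames = nf_ext,
        start_s = (df$frame[s] - 1) * dt, end_s = df$frame[en_ext] * dt,
        duration_s = dur_ext,
        delta_e = max(0, de), slope = slope,
        e_first = e_first, e_last = e_last
      )
    })
    evs <- dplyr::bind_rows(evs)
    if (events_per_molecule == "first" && nrow(evs) > 1) {
      evs <- evs[which.min(evs$start_frame), , drop = FALSE]
    }
    evs
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(empty_fret_events())
  dplyr::arrange(out, .data$molecule_id, .data$start_frame)
}

empty_fret_events <- function() {
  tibble::tibble(molecule_id = integer(), start_frame = integer(),
                 end_frame = integer(), n_frames = integer(),
                 start_s = numeric(), end_s = numeric(),
                 duration_s = numeric(), delta_e = numeric(),
                 slope = numeric(), e_first = numeric(), e_last = numeric())
}

#' Write called events to CSV
#'
#' @param events Event tibble from [call_colocalization()] or
#'   [call_fret_events()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
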