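# Independent reference implementations used as oracles: index-walking
# scanners, deliberately written differently from the rle-based
# production code.

# naive threshold-run scanner with gap merging
oracle_coloc_events <- function(x, threshold = 50, min_frames = 2,
                                gap_frames = 3) {
  above <- which(x > threshold)
  out <- NULL
  if (length(above) > 0) {
    cur_start <- above[1]
    cur_end <- above[1]
    for (i in above[-1]) {
      gap <- i - cur_end - 1L
      if (gap < gap_frames) {
        cur_end <- i
      } else {
        out <- rbind(out, c(cur_start, cur_end))
        cur_start <- i
        cur_end <- i
      }
    }
    out <- rbind(out, c(cur_start, cur_end))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  out <- as.data.frame(out)
  names(out) <- c("start", "end")
  out[out$end - out$start + 1L >= min_frames, , drop = FALSE]
}

# naive FRET-event scanner: window runs with gap merging, length/duration
# filters, and an lm()-based slope rule (production uses cov/var)
oracle_fret_events <- function(e, valid, dt = 0.2, e_min = 0.3, e_max = 0.8,
                               min_frames = 5, max_duration = 20,
                               gap_frames = 3) {
  ok <- valid & !is.na(e) & e >= e_min & e <= e_max
  runs <- oracle_coloc_events(as.numeric(ok), threshold = 0.5,
                              min_frames = 1, gap_frames = gap_frames)
  keep <- NULL
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; en <- runs$end[i]
    nf <- en - s + 1L
    if (nf < min_frames || nf * dt >= max_duration) next
    idx <- s:en
    use <- idx[valid[idx] & !is.na(e[idx])]
    if (length(use) < 3) next
    fit <- stats::lm(y ~ t, data = data.frame(t = (use - 1) * dt, y = e[use]))
    sl <- unname(coef(fit)[2])
    if (!is.finite(sl) || sl >= 0) next
    keep <- rbind(keep, data.frame(start = s, end = en, slope = sl,
                                   delta_e = max(0, e[s] - e[en])))
  }
  if (is.null(keep)) {
    data.frame(start = integer(), end = integer(), slope = numeric(),
               delta_e = numeric())
  } else {
    keep
  }
}

# wrap a per-frame vector as a one-molecule trajectory tibble
as_traj <- function(f_aa, f_dd = 0, f_da = 0, dt = 0.2, id = 1L) {
  n <- length(f_aa)
  tr <- tibble::tibble(molecule_id = id, frame = seq_len(n),
                       time_s = (seq_len(n) - 1) * dt,
                       F_DD = rep_len(f_dd, n), F_DA = rep_len(f_da, n),
                       F_AA = f_aa)
  attr(tr, "frame_interval") <- dt
  tr
}

# wrap a per-frame efficiency vector as a corrected trace tibble
as_trace <- function(e, valid = TRUE, dt = 0.2, id = 1L) {
  n <- length(e)
  tr <- tibble::tibble(molecule_id = id, frame = seq_len(n),
                       time_s = (seq_len(n) - 1) * dt, E = e,
                       valid = rep_len(valid, n),
                       F_DD = 0, F_DA = 0, F_AA = 0)
  attr(tr, "frame_interval") <- dt
  tr
}

# per-frame ideal E staircase from simulator ground truth, flagging frames
# that lie fully inside one constant-E segment of the bound period
truth_e_frames <- function(truth, sc, molecule) {
  dt <- sc$frame_interval
  n_frames <- floor(sc$movie_length / dt)
  ev <- truth[truth$molecule_id == molecule, , drop = FALSE]
  bind <- ev[ev$kind == "binding", , drop = FALSE]
  out <- data.frame(frame = seq_len(n_frames), e = 0, full = TRUE)
  if (nrow(bind) == 0) return(out)
  steps <- ev[ev$kind == "incorporation-step", , drop = FALSE]
  bleach <- ev[ev$kind == "bleach" & !is.na(ev$dye) & ev$dye == "acceptor", ,
               drop = FALSE]
  a_end <- min(bind$t_end_s[1],
               if (nrow(bleach)) bleach$t_start_s[1] else Inf)
  breaks <- c(0, bind$t_start_s[1], steps$t_end_s[steps$t_end_s < a_end], a_end)
  levels <- c(0, sc$e_start - seq(0, sum(steps$t_end_s < a_end)) *
                sc$delta_e_per_nt, 0)
  t0 <- (out$frame - 1) * dt
  t1 <- out$frame * dt
  seg0 <- findInterval(t0, breaks)
  seg1 <- findInterval(t1 - 1e-12, breaks)
  out$full <- seg0 == seg1
  for (i in seq_len(n_frames)) out$e[i] <- levels[seg0[i]]
  out
}
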