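#' Render trajectories into a synthetic image stack
#'
#' Each molecule is drawn, frame by frame, as a 2-D Gaussian point-spread
#' function integrated to the molecule's photon count for that frame, on
#' top of (optionally Poisson-sampled) camera background. The Gaussian
#' kernel is truncated at +/- 4 sigma and renormalized, so rendered
#' photons are conserved exactly.
#'
#' @param traj Trajectory tibble (one channel is rendered; pick it with
#'   `channel`).
#' @param layout Tibble assigning positions: `molecule_id`, `x`, `y`
#'   (pixels, 1-based, may be fractional). Use [grid_layout()] to build
#'   one. Positions must fall inside the frame.
#' @param dims Image size `c(width, height)` in pixels.
#' @param channel Which intensity column to render (default `"F_AA"`).
#' @param psf_sigma PSF standard deviation in pixels (default 1.3).
#' @param background Mean camera background per pixel (default 0).
#' @param noise Poisson-sample the pixel values (default `FALSE`; the
#'   trajectory counts usually already carry shot noise).
#' @param seed Seed used when `noise = TRUE`.
#' @return An `image_stack`: list with `data` (array width x height x
#'   frames), `frame_interval`, `channel`, `psf_sigma`, `background`.
#' @export
render_movie <- function(traj, layout, dims = c(64, 64), channel = "F_AA",
                         psf_sigma = 1.3, background = 0, noise = FALSE,
                         seed = 1L) {
  frames <- sort(unique(traj$frame))
  n_frames <- length(frames)
  w <- dims[1]; h <- dims[2]
  pad <- ceiling(4 * psf_sigma)
  if (n_frames == 0) {
    stack <- array(background, dim = c(w, h, 1))
  } else {
    if (nrow(layout) > 0) {
      if (any(layout$x < 1 + pad | layout$x > w - pad |
                layout$y < 1 + pad | layout$y > h - pad)) {
        stop_invalid("molecule positions fall outside the usable frame area")
      }
    }
    stack <- array(background, dim = c(w, h, n_frames))
    kern <- function(center, n) {
      g <- stats::dnorm(seq_len(n), mean = center, sd = psf_sigma)
      lo <- max(1, floor(center - pad)); hi <- min(n, ceiling(center + pad))
      g[seq_len(n) < lo | seq_len(n) > hi] <- 0
      g / sum(g)
    }
    traj_split <- split(traj, traj$molecule_id)
    for (mid in names(traj_split)) {
      pos <- layout[layout$molecule_id == as.integer(mid), , drop = FALSE]
      if (nrow(pos) == 0) next
      gx <- kern(pos$x[1], w)
      gy <- kern(pos$y[1], h)
      psf <- outer(gx, gy)
      df <- traj_split[[mid]]
      counts <- df[[channel]][match(frames, df$frame)]
      counts[is.na(counts)] <- 0
      for (f in which(counts > 0)) {
        stack[, , f] <- stack[, , f] + counts[f] * psf
      }
    }
  }
  if (noise) {
    withr::with_seed(seed, {
      stack[] <- rpois(length(stack), stack)
    })
  }
  structure(list(data = stack, frame_interval = frame_dt(traj),
                 channel = channel, psf_sigma = psf_sigma,
                 background = background),
            class = "image_stack")
}

#' Lay molecules out on a regular grid
#'
#' @param n Number of molecules.
#' @param dims Image size `c(width, height)`.
#' @param margin Margin to the frame edge in pixels (default 8).
#' @param spacing Minimum center-to-center spacing in pixels (default 6,
#'   comfortably beyond the PSF width).
#' @return A layout tibble (`molecule_id`, `x`, `y`).
#' @export
grid_layout <- function(n, dims = c(64, 64), margin = 8, spacing = 6) {
  xs <- seq(margin, dims[1] - margin, by = spacing)
  ys <- seq(margin, dims[2] - margin, by = spacing)
  if (length(xs) * length(ys) < n) stop_invalid("grid too small for n molecules")
  g <- expand.grid(x = xs, y = ys)
  tibble::tibble(molecule_id = seq_len(n), x = g$x[seq_len(n)],
                 y = g$y[seq_len(n)])
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' The stack is stored as 16-bit multi-page TIFF; acquisition metadata
#' (frame interval, excitation scheme, channel, intensity scale) goes to
#' `<path>.json`.
#'
#' @param stack An `image_stack` from [render_movie()].
#' @param path Output TIFF path.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` an `image_stack`.
#' @export
write_movie_tiff <- function(stack, path) {
  mx <- max(stack$data, 1)
  pages <- lapply(seq_len(dim(stack$data)[3]), function(f) {
    t(stack$data[, , f]) / mx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(frame_interval = stack$frame_interval,
               excitation = "alternating 532/642 nm, one cycle per frame",
               channel = stack$channel, psf_sigma = stack$psf_sigma,
               background = stack$background, intensity_scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) data[, , f] <- t(pages[[f]]) * meta$intensity_scale
  structure(list(data = data, frame_interval = meta$frame_interval,
                 channel = meta$channel, psf_sigma = meta$psf_sigma,
                 background = meta$background),
            class = "image_stack")
}

#' Detect diffraction-limited spots in a frame
#'
#' Local maxima above an intensity floor are refined to sub-pixel
#' positions by background-subtracted centroiding; candidates are then
#' filtered on the circularity of their half-maximum mask and on the
#' distance to their nearest neighbor (both members of a too-close pair
#' are discarded, since neither intensity can be attributed cleanly).
#'
#' Circularity is `4 * pi * area / perimeter^2` on the thresholded spot
#' mask, with the taxicab perimeter of the pixel mask corrected by the
#' factor `pi / 4` (a pixelated boundary overestimates a smooth perimeter
#' by `4 / pi`), so an ideal round spot scores ~1.
#'
#' @param image Numeric matrix (width x height) or an `image_stack` (all
#'   frames are processed).
#' @param intensity_floor Minimum pixel value for a local maximum.
#' @param min_circularity Minimum mask circularity (default 0.7).
#' @param min_nn_distance Minimum distance to the nearest other spot in
#'   pixels (default 5).
#' @param window Half-width of the centroid window in pixels (default 3).
#' @return Tibble of spots: `frame`, `x`, `y`, `raw_intensity`,
#'   `background`, `corrected_intensity`, `circularity`, `nn_distance`.
#' @export
detect_spots <- function(image, intensity_floor, min_circularity = 0.7,
                         min_nn_distance = 5, window = 3) {
  if (inherits(image, "image_stack")) {
    frames <- lapply(seq_len(dim(image$data)[3]), function(f) image$data[, , f])
  } else {
    frames <- list(image)
  }
  out <- lapply(seq_along(frames), function(f) {
    sp <- detect_spots_frame(frames[[f]], intensity_floor, min_circularity,
                             min_nn_distance, window)
    if (nrow(sp) > 0) sp$frame <- f
    sp
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(frame = integer(), x = numeric(), y = numeric(),
                          raw_intensity = numeric(), background = numeric(),
                          corrected_intensity = numeric(),
                          circularity = numeric(), nn_distance = numeric()))
  }
  dplyr::select(res, "frame", "x", "y", "raw_intensity", "background",
                "corrected_intensity", "circularity", "nn_distance")
}

detect_spots_frame <- function(img, floor, min_circ, min_nn, window) {
  if (!is.matrix(img) || any(dim(img) < 3)) {
    stop_invalid("image must be a matrix of at least 3 x 3 pixels")
  }
  w <- nrow(img); h <- ncol(img)
  empty <- tibble::tibble(x = numeric(), y = numeric(),
                          raw_intensity = numeric(), background = numeric(),
                          corrected_intensity = numeric(),
                          circularity = numeric(), nn_distance = numeric())
  # strict local maxima over the 8-neighborhood, above the floor
  core <- img[2:(w - 1), 2:(h - 1)]
  is_max <- core > floor
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- img[2:(w - 1) + dx, 2:(h - 1) + dy]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(px = idx[, 1] + 1L, py = idx[, 2] + 1L)
  # deduplicate plateaus: keep one representative per connected plateau
  cand <- cand[order(-img[cbind(cand$px, cand$py)]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      d2 <- (cand$px[seq_len(i - 1)] - cand$px[i])^2 +
        (cand$py[seq_len(i - 1)] - cand$py[i])^2
      if (any(keep[seq_len(i - 1)] & d2 <= 2)) keep[i] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  spots <- lapply(seq_len(nrow(cand)), function(i) {
    cx <- cand$px[i]; cy <- cand$py[i]
    x0 <- max(1, cx - window); x1 <- min(w, cx + window)
    y0 <- max(1, cy - window); y1 <- min(h, cy + window)
    sub <- img[x0:x1, y0:y1]
    local_bg <- stats::median(c(sub[1, ], sub[nrow(sub), ],
                                sub[, 1], sub[, ncol(sub)]))
    wgt <- pmax(sub - local_bg, 0)
    if (sum(wgt) <= 0) return(NULL)
    xs <- x0:x1; ys <- y0:y1
    x_hat <- sum(rowSums(wgt) * xs) / sum(wgt)
    y_hat <- sum(colSums(wgt) * ys) / sum(wgt)
    # half-maximum mask circularity
    peak <- img[cx, cy]
    mask <- sub >= local_bg + (peak - local_bg) / 2
    area <- sum(mask)
    per <- mask_perimeter(mask) * pi / 4
    circ <- if (per > 0) min(4 * pi * area / per^2, 1) else 0
    data.frame(x = x_hat, y = y_hat, peak = peak, background = local_bg,
               circularity = circ)
  })
  spots <- do.call(rbind, spots[!vapply(spots, is.null, logical(1))])
  if (is.null(spots) || nrow(spots) == 0) return(empty)
  spots <- spots[spots$circularity >= min_circ, , drop = FALSE]
  if (nrow(spots) == 0) return(empty)
  # nearest-neighbor exclusion: both members of a close pair go
  if (nrow(spots) > 1) {
    dmat <- as.matrix(stats::dist(spots[, c("x", "y")]))
    diag(dmat) <- Inf
    nn <- apply(dmat, 1, min)
  } else {
    nn <- Inf
  }
  spots$nn_distance <- nn
  spots <- spots[nn >= min_nn, , drop = FALSE]
  if (nrow(spots) == 0) return(empty)
  # background-corrected intensity at each retained spot
  ints <- lapply(seq_len(nrow(spots)), function(i) {
    tryCatch(
      extract_intensity_frame(img, spots$x[i], spots$y[i]),
      smkinetics_invalid = function(e) {
        data.frame(raw = NA_real_, background = NA_real_, corrected = NA_real_)
      })
  })
  ints <- do.call(rbind, ints)
  tibble::tibble(x = spots$x, y = spots$y,
                 raw_intensity = ints$raw, background = ints$background,
                 corrected_intensity = ints$corrected,
                 circularity = spots$circularity,
                 nn_distance = spots$nn_distance)
}

# taxicab perimeter: count of 4-neighbor edges between mask and non-mask
# (image border counts as outside)
mask_perimeter <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  p <- 0
  p <- p + sum(m[, -1] & !m[, -ncol(m)]) + sum(m[, -ncol(m)] & !m[, -1])
  p <- p + sum(m[-1, ] & !m[-nrow(m), ]) + sum(m[-nrow(m), ] & !m[-1, ])
  p
}

#' Affine registration of two channels from matched fiducials
#'
#' Least-squares affine map from channel-1 to channel-2 coordinates,
#' estimated from at least three non-collinear matched positions (e.g.
#' multi-color beads imaged in both cameras).
#'
#' @param fiducials Tibble with columns `x`, `y` (channel 1) and `x2`,
#'   `y2` (channel 2).
#' @return A `channel_map`: list with the 2x2 matrix `A`, offset `b`, and
#'   root-mean-square residual `rms`.
#' @export
register_channels <- function(fiducials) {
  need <- c("x", "y", "x2", "y2")
  if (!all(need %in% names(fiducials))) {
    stop_invalid("fiducials must have columns x, y, x2, y2")
  }
  if (nrow(fiducials) < 3) stop_invalid("need at least 3 fiducial pairs")
  X <- cbind(fiducials$x, fiducials$y)
  if (qr(cbind(1, X))$rank < 3) stop_invalid("fiducials are collinear")
  fit <- stats::lm(cbind(x2, y2) ~ x + y, data = fiducials)
  cf <- coef(fit)
  A <- t(cf[c("x", "y"), , drop = FALSE])
  b <- unname(cf["(Intercept)", ])
  rms <- sqrt(mean(resid(fit)^2))
  structure(list(A = unname(A), b = b, rms = rms), class = "channel_map")
}

#' Map positions through a channel registration
#'
#' @param map A `channel_map` from [register_channels()].
#' @param xy Two-column matrix or tibble of positions.
#' @return Matrix of mapped positions.
#' @export
apply_channel_map <- function(map, xy) {
  stopifnot(inherits(map, "channel_map"))
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  t(map$A %*% t(xy) + map$b)
}

#' Per-frame drift by cross-correlation against a reference
#'
#' Each frame is cross-correlated (via FFT, with sub-pixel refinement by
#' parabolic interpolation of the correlation peak) against a reference
#' image; the returned offsets `(dx, dy)` are the shifts that move each
#' frame back onto the reference. The default reference is the pixelwise
#' temporal median of the first ten frames.
#'
#' @param stack An `image_stack` or 3-D array.
#' @param reference Reference image matrix; default median projection of
#'   the first 10 frames.
#' @return Tibble: `frame`, `dx`, `dy`.
#' @export
correct_drift <- function(stack, reference = NULL) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  n_frames <- dim(data)[3]
  if (is.null(reference)) {
    k <- min(10, n_frames)
    reference <- apply(data[, , seq_len(k), drop = FALSE], c(1, 2),
                       stats::median)
  }
  if (stats::sd(reference) == 0) {
    warn("featureless reference frame: reporting zero drift")
    return(tibble::tibble(frame = seq_len(n_frames), dx = 0, dy = 0))
  }
  fr <- stats::fft(reference - mean(reference))
  offs <- vapply(seq_len(n_frames), function(f) {
    img <- data[, , f]
    if (stats::sd(img) == 0) return(c(0, 0))
    cc <- Re(stats::fft(stats::fft(img - mean(img)) * Conj(fr),
                        inverse = TRUE))
    peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    sub <- function(mat, i, j) {
      ni <- nrow(mat); nj <- ncol(mat)
      mat[(i - 1) %% ni + 1, (j - 1) %% nj + 1]
    }
    refine <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (den == 0) 0 else 0.5 * (cm - cp) / den
    }
    di <- refine(sub(cc, peak[1] - 1, peak[2]), cc[peak[1], peak[2]],
                 sub(cc, peak[1] + 1, peak[2]))
    dj <- refine(sub(cc, peak[1], peak[2] - 1), cc[peak[1], peak[2]],
                 sub(cc, peak[1], peak[2] + 1))
    sh <- c(peak[1] - 1 + di, peak[2] - 1 + dj)
    n <- dim(img)
    sh <- ifelse(sh > n / 2, sh - n, sh)
    sh
  }, numeric(2))
  tibble::tibble(frame = seq_len(n_frames), dx = offs[1, ], dy = offs[2, ])
}

#' Apply drift offsets to spot positions
#'
#' @param spots Spot tibble with `frame`, `x`, `y`.
#' @param drift Offsets from [correct_drift()].
#' @return The spot tibble with re-centered positions.
#' @export
apply_drift <- function(spots, drift) {
  j <- match(spots$frame, drift$frame)
  dplyr::mutate(spots, x = .data$x - drift$dx[j], y = .data$y - drift$dy[j])
}

#' Local background-corrected intensity time series
#'
#' Per frame, the photon count is the sum over an integration disc around
#' the position minus the median level of a surrounding annulus times the
#' disc area; the median makes the background estimate robust to a
#' neighboring spot leaking into the annulus.
#'
#' @param stack An `image_stack` or 3-D array.
#' @param x,y Spot position in pixels.
#' @param disc_radius Integration disc radius in pixels (default 3).
#' @param annulus Inner and outer background annulus radii (default
#'   `c(5, 7)`).
#' @return Tibble: `frame`, `raw`, `background` (per-pixel level),
#'   `corrected`.
#' @export
extract_intensity <- function(stack, x, y, disc_radius = 3,
                              annulus = c(5, 7)) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  if (length(dim(data)) == 2) data <- array(data, dim = c(dim(data), 1))
  res <- lapply(seq_len(dim(data)[3]), function(f) {
    df <- extract_intensity_frame(data[, , f], x, y, disc_radius, annulus)
    df$frame <- f
    df
  })
  out <- tibble::as_tibble(do.call(rbind, res))
  dplyr::select(out, "frame", "raw", "background", "corrected")
}

extract_intensity_frame <- function(img, x, y, disc_radius = 3,
                                    annulus = c(5, 7)) {
  if (annulus[1] <= disc_radius || annulus[2] <= annulus[1]) {
    stop_invalid("annulus must lie strictly outside the integration disc")
  }
  w <- nrow(img); h <- ncol(img)
  r_out <- annulus[2]
  if (x - r_out < 1 || x + r_out > w || y - r_out < 1 || y + r_out > h) {
    stop_invalid("background annulus extends outside the frame")
  }
  xs <- floor(x - r_out):ceiling(x + r_out)
  ys <- floor(y - r_out):ceiling(y + r_out)
  d2 <- outer((xs - x)^2, (ys - y)^2, "+")
  sub <- img[xs, ys]
  disc <- d2 <= disc_radius^2
  ann <- d2 >= annulus[1]^2 & d2 <= annulus[2]^2
  raw <- sum(sub[disc])
  bg <- stats::median(sub[ann])
  data.frame(raw = raw, background = bg, corrected = raw - bg * sum(disc))
}

#' Two-color colocalization of DNA spots with a partner channel
#'
#' Each DNA-channel spot position is mapped into the partner channel with
#' the registration transform; the pair is flagged colocalized when a
#' partner spot lies within `distance_threshold` pixels of the mapped
#' position. The partner-channel intensity at the mapped position is read
#' out when a stack is supplied.
#'
#' @param dna_spots Spot tibble (DNA channel).
#' @param partner_spots Spot tibble (partner channel).
#' @param map A `channel_map` from [register_channels()]; use
#'   `identity_map()` for pre-registered data. Required: colocalizing
#'   unregistered channels is an error.
#' @param distance_threshold Maximum separation in pixels (default 2,
#'   about one PSF sigma).
#' @param partner_stack Optional `image_stack` for intensity readout.
#' @return `dna_spots` with added columns `partner_x`, `partner_y`,
#'   `separation`, `colocalized`, and `partner_intensity` (NA without a
#'   stack).
#' @export
colocalize <- function(dna_spots, partner_spots, map,
                       distance_threshold = 2, partner_stack = NULL) {
  if (missing(map) || !inherits(map, "channel_map")) {
    stop_invalid("channels are not registered: supply a channel_map")
  }
  mapped <- apply_channel_map(map, dna_spots[, c("x", "y")])
  sep <- rep(Inf, nrow(dna_spots))
  px <- py <- rep(NA_real_, nrow(dna_spots))
  if (nrow(partner_spots) > 0) {
    for (i in seq_len(nrow(dna_spots))) {
      d <- sqrt((partner_spots$x - mapped[i, 1])^2 +
                  (partner_spots$y - mapped[i, 2])^2)
      j <- which.min(d)
      sep[i] <- d[j]
      px[i] <- partner_spots$x[j]
      py[i] <- partner_spots$y[j]
    }
  }
  out <- dplyr::mutate(dna_spots,
                       partner_x = px, partner_y = py, separation = sep,
                       colocalized = sep <= distance_threshold)
  if (!is.null(partner_stack)) {
    out$partner_intensity <- vapply(seq_len(nrow(out)), function(i) {
      tryCatch(
        extract_intensity_frame(
          partner_stack$data[, , min(out$frame[i], dim(partner_stack$data)[3])],
          mapped[i, 1], mapped[i, 2])$corrected,
        smkinetics_invalid = function(e) NA_real_)
    }, numeric(1))
  } else {
    out$partner_intensity <- NA_real_
  }
  out
}

#' Identity channel map
#'
#' @param rms Residual to record (default 0).
#' @return A `channel_map` representing already-registered channels.
#' @export
identity_map <- function(rms = 0) {
  structure(list(A = diag(2), b = c(0, 0), rms = rms), class = "channel_map")
}
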