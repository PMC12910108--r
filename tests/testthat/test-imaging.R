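render_single_spot <- function(x, y, photons = 1000, dims = c(64, 64),
                               psf_sigma = 1.0, frames = 1) {
  traj <- as_traj(rep(photons, frames))
  lay <- tibble::tibble(molecule_id = 1L, x = x, y = y)
  render_movie(traj, lay, dims = dims, psf_sigma = psf_sigma)
}

test_that("rendering conserves photons and detection recovers the position", {
  st <- render_single_spot(20.0, 30.0)
  expect_equal(sum(st$data[, , 1]), 1000, tolerance = 1e-9)
  sp <- detect_spots(st$data[, , 1], intensity_floor = 5)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x - 20.0), 0.5)
  expect_lt(abs(sp$y - 30.0), 0.5)
  expect_gt(sp$circularity, 0.7)
  # blank frame: nothing detected
  expect_equal(nrow(detect_spots(matrix(0, 32, 32), intensity_floor = 5)), 0)
  # degenerate image errors
  expect_error(detect_spots(matrix(0, 2, 2), 5), class = "smkinetics_invalid")
})

test_that("detection is equivariant under integer translation", {
  st <- render_single_spot(20.4, 30.7)
  img <- st$data[, , 1]
  shifted <- img * 0
  shifted[6:64, 4:64] <- img[1:59, 1:61]
  a <- detect_spots(img, intensity_floor = 5)
  b <- detect_spots(shifted, intensity_floor = 5)
  expect_equal(b$x - a$x, 5, tolerance = 1e-6)
  expect_equal(b$y - a$y, 3, tolerance = 1e-6)
})

test_that("too-close spot pairs are discarded entirely", {
  traj <- dplyr::bind_rows(as_traj(800, id = 1L), as_traj(800, id = 2L))
  lay <- tibble::tibble(molecule_id = 1:2, x = c(30, 34), y = c(30, 30))
  st <- render_movie(traj, lay, psf_sigma = 0.8)
  sp <- detect_spots(st$data[, , 1], intensity_floor = 5, min_nn_distance = 5)
  expect_equal(nrow(sp), 0)
  # the same pair survives with a permissive NN rule (their centroids
  # pull toward each other, so the measured separation is below 3 px)
  sp2 <- detect_spots(st$data[, , 1], intensity_floor = 5, min_nn_distance = 2)
  expect_equal(nrow(sp2), 2)
})

test_that("channel registration recovers exact affine maps", {
  set.seed(31)
  xy <- cbind(runif(12, 5, 60), runif(12, 5, 60))
  fid0 <- tibble::tibble(x = xy[, 1], y = xy[, 2], x2 = xy[, 1], y2 = xy[, 2])
  m0 <- register_channels(fid0)
  expect_equal(m0$A, diag(2), tolerance = 1e-10)
  expect_equal(m0$b, c(0, 0), tolerance = 1e-10)
  expect_equal(m0$rms, 0, tolerance = 1e-10)

  fid1 <- dplyr::mutate(fid0, x2 = x + 3, y2 = y - 2)
  m1 <- register_channels(fid1)
  expect_equal(m1$A, diag(2), tolerance = 1e-9)
  expect_equal(m1$b, c(3, -2), tolerance = 1e-9)

  th <- 0.5 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m2xy <- t(rot %*% t(xy)) + matrix(c(1.5, -0.7), 12, 2, byrow = TRUE)
  m2 <- register_channels(tibble::tibble(x = xy[, 1], y = xy[, 2],
                                         x2 = m2xy[, 1], y2 = m2xy[, 2]))
  expect_lt(max(abs(m2$A - rot)), 1e-6)
  expect_lt(max(abs(m2$b - c(1.5, -0.7))), 1e-6)

  expect_error(register_channels(fid0[1:2, ]), class = "smkinetics_invalid")
  col <- tibble::tibble(x = 1:5, y = 2 * (1:5), x2 = 1:5, y2 = 2 * (1:5))
  expect_error(register_channels(col), class = "smkinetics_invalid")
})

test_that("drift correction recovers injected linear drift", {
  base <- render_single_spot(25.0, 25.0, photons = 2000)$data[, , 1]
  shift_img <- function(img, dx) {
    out <- img * 0
    out[(1 + dx):nrow(img), ] <- img[1:(nrow(img) - dx), ]
    out
  }
  n <- 10
  stack <- array(0, dim = c(64, 64, n))
  for (i in seq_len(n)) stack[, , i] <- shift_img(base, i - 1)  # 1 px / frame
  dr <- correct_drift(stack, reference = base)
  slope <- coef(stats::lm(dx ~ frame, data = dr))[2]
  expect_lt(abs(slope - 1) / 1, 0.1)
  # stationary movie: all offsets zero
  still <- array(rep(base, 5), dim = c(64, 64, 5))
  dr0 <- correct_drift(still)
  expect_equal(dr0$dx, rep(0, 5), tolerance = 1e-9)
  expect_equal(dr0$dy, rep(0, 5), tolerance = 1e-9)
  # reversed frame order: offsets against the final frame are the
  # negated mirror of the forward offsets
  rev_stack <- stack[, , n:1]
  dr_rev <- correct_drift(rev_stack, reference = stack[, , n])
  expect_equal(dr_rev$dx, rev(dr$dx) - dr$dx[n], tolerance = 1e-6)
  expect_lt(coef(stats::lm(dx ~ frame, data = dr_rev))[2], 0)
  # featureless movie: zero offsets with a warning
  expect_warning(correct_drift(array(1, dim = c(16, 16, 3))), "featureless")
})

test_that("background-corrected extraction closes the render loop", {
  # uniform background only: corrected intensity is unbiased near zero
  st <- structure(list(data = array(10, dim = c(64, 64, 100)),
                       frame_interval = 0.2),
                  class = "image_stack")
  ei <- extract_intensity(st, 32, 32)
  expect_lt(abs(mean(ei$corrected)), 1)
  # rendered 1000-photon spot on a uniform background
  spot <- render_single_spot(32, 32)$data[, , 1] + 10
  ei2 <- extract_intensity(spot, 32, 32)
  expect_lt(abs(ei2$corrected - 1000) / 1000, 0.02)
  # annulus clipped by the frame edge is an error
  expect_error(extract_intensity(spot, 3, 32), class = "smkinetics_invalid")
  expect_error(extract_intensity(spot, 32, 32, disc_radius = 5,
                                 annulus = c(4, 7)),
               class = "smkinetics_invalid")
})

test_that("colocalization counts constructed pairs exactly", {
  lay <- grid_layout(25, dims = c(96, 96), margin = 12, spacing = 12)
  dna <- tibble::tibble(frame = 1L, x = lay$x, y = lay$y)
  partner <- dna[1:12, ]
  pairs <- colocalize(dna, partner, identity_map(), distance_threshold = 2)
  expect_equal(sum(pairs$colocalized), 12)
  # a partner spot at 3x the threshold does not colocalize
  far <- tibble::tibble(frame = 1L, x = lay$x[1] + 6, y = lay$y[1])
  p2 <- colocalize(dna[1, ], far, identity_map(), distance_threshold = 2)
  expect_false(p2$colocalized)
  expect_error(colocalize(dna, partner, map = NULL),
               class = "smkinetics_invalid")
})

test_that("dark positions colocalize below 1% under pure background", {
  set.seed(77)
  bgstack <- structure(list(data = array(rpois(96 * 96, 10), c(96, 96, 1)),
                            frame_interval = 0.2),
                      class = "image_stack")
  partner <- detect_spots(bgstack$data[, , 1], intensity_floor = 35)
  lay <- grid_layout(40, dims = c(96, 96), margin = 12, spacing = 12)
  dark <- tibble::tibble(frame = 1L, x = lay$x, y = lay$y)
  pairs <- colocalize(dark, partner, identity_map(), distance_threshold = 2)
  expect_lt(mean(pairs$colocalized), 0.01)
})

test_that("movies round trip through 16-bit TIFF with sidecar metadata", {
  st <- render_single_spot(20, 20, photons = 900, frames = 3)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(st, path)
  expect_true(file.exists(paste0(path, ".json")))
  st2 <- read_movie_tiff(path)
  expect_equal(dim(st2$data), dim(st$data))
  expect_equal(st2$frame_interval, st$frame_interval)
  # 16-bit quantization keeps intensities within 0.1%
  expect_lt(max(abs(st2$data - st$data)) / max(st$data), 1e-3)
})

test_that("render -> detect -> extract reproduces trajectory counts", {
  sc <- kinetic_scenario(bound_fraction = 1, k_bind = 1, tau_dwell = 100,
                         movie_length = 4, photon_budget = 800,
                         n_molecules = 4L, seed = 14L)
  sim <- simulate_colocalization(sc, noise = FALSE)
  lay <- grid_layout(4, dims = c(64, 64), margin = 16, spacing = 16)
  st <- render_movie(sim$trajectories, lay, psf_sigma = 1.0)
  for (m in 1:4) {
    ei <- extract_intensity(st, lay$x[m], lay$y[m])
    ref <- sim$trajectories$F_AA[sim$trajectories$molecule_id == m]
    on <- ref > 100
    expect_true(any(on))
    expect_lt(max(abs(ei$corrected[on] - ref[on]) / ref[on]), 0.02)
  }
})
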