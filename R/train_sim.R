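#' Ground-truth-labelled frame simulation
#'
#' Emitters are placed uniformly inside segmented cells, rendered from the
#' spline PSF, overlaid on structured background sampled from the
#' background model, and passed through the sCMOS camera model.  Per-pixel
#' target maps (detection probability, sub-pixel offsets, scaled depth and
#' photon count) are produced for network training.
#'
#' Scalings: z is mapped affinely from `z_range` onto [-1, 1]; photons are
#' divided by `max_photons`; offsets are in pixels within [-0.5, 0.5].
#'
#' @name train_sim
NULL

#' Sample ground-truth emitters inside cells
#'
#' Per cell, Poisson(`density_per_cell`) emitters at uniform-random
#' positions inside the cell mask; photon counts uniform in `photon_range`;
#' depths uniform in `z_range`.
#'
#' @param masks a [cell_mask_set()]
#' @param density_per_cell mean number of emitters per cell
#' @param photon_range photon count range, default c(750, 3000)
#' @param z_range depth range (nm), default c(-700, 300)
#' @param seed optional RNG seed
#' @return data.frame: cell_id, x_nm, y_nm, z_nm, photons, pixel_row,
#'   pixel_col (1-based), dx_px, dy_px (sub-pixel offsets in [-0.5, 0.5])
#' @export
sample_emitters <- function(masks, density_per_cell = 1.5,
                            photon_range = c(750, 3000),
                            z_range = c(-700, 300), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(density_per_cell > 0)
  if (length(masks$cell_ids) == 0) stop("empty mask set")
  px <- masks$pixel_size
  rows <- NULL
  for (k in masks$cell_ids) {
    n <- rpois(1, density_per_cell)
    if (n == 0) next
    idx <- which(masks$labels == k, arr.ind = TRUE)
    pick <- idx[sample.int(nrow(idx), n, replace = TRUE), , drop = FALSE]
    # uniform position within the chosen pixel
    x <- (pick[, 2] - 1 + runif(n)) * px
    y <- (pick[, 1] - 1 + runif(n)) * px
    rows <- rbind(rows, data.frame(cell_id = k, x_nm = x, y_nm = y,
                                   z_nm = runif(n, z_range[1], z_range[2]),
                                   photons = runif(n, photon_range[1],
                                                   photon_range[2])))
  }
  if (is.null(rows))
    rows <- data.frame(cell_id = integer(0), x_nm = numeric(0),
                       y_nm = numeric(0), z_nm = numeric(0),
                       photons = numeric(0))
  emitter_pixels(rows, px)
}

# annotate emitters with owning pixel and sub-pixel offsets
emitter_pixels <- function(em, pixel_size) {
  if (nrow(em) == 0) {
    em$pixel_row <- integer(0); em$pixel_col <- integer(0)
    em$dx_px <- numeric(0); em$dy_px <- numeric(0)
    return(em)
  }
  gx <- em$x_nm / pixel_size  # continuous pixel coordinate (0-based edges)
  gy <- em$y_nm / pixel_size
  em$pixel_col <- floor(gx) + 1L
  em$pixel_row <- floor(gy) + 1L
  em$dx_px <- gx - (em$pixel_col - 1) - 0.5
  em$dy_px <- gy - (em$pixel_row - 1) - 0.5
  em
}

#' Build per-pixel training target maps
#'
#' The probability map is 1 at each emitter's nearest pixel center; the
#' offset maps hold the sub-pixel offsets there; the z and photon maps hold
#' affinely scaled values.  When two emitters fall in the same pixel the
#' dimmer one is dropped with a warning (targets are single-valued per
#' pixel).
#'
#' @param emitters data.frame as from [sample_emitters()]
#' @param shape c(rows, cols) of the frame
#' @param z_range depth range mapped onto [-1, 1]
#' @param max_photons photon scaling divisor
#' @return list of matrices `p`, `dx`, `dy`, `z`, `I`, plus `emitters`
#'   (the survivors)
#' @export
make_targets <- function(emitters, shape, z_range = c(-700, 300),
                         max_photons = 3000) {
  p <- matrix(0, shape[1], shape[2])
  dx <- dy <- zz <- ii <- matrix(0, shape[1], shape[2])
  if (nrow(emitters) > 0) {
    if (any(emitters$pixel_row < 1 | emitters$pixel_row > shape[1] |
            emitters$pixel_col < 1 | emitters$pixel_col > shape[2]))
      stop("emitter outside the frame")
    key <- (emitters$pixel_row - 1) + shape[1] * (emitters$pixel_col - 1)
    if (anyDuplicated(key)) {
      ord <- order(key, -emitters$photons)
      emitters <- emitters[ord, ][!duplicated(sort(key)), ]
      warning("emitters colliding in one pixel: dropped the dimmer one")
    }
    zc <- mean(z_range); zh <- diff(z_range) / 2
    ind <- cbind(emitters$pixel_row, emitters$pixel_col)
    p[ind] <- 1
    dx[ind] <- emitters$dx_px
    dy[ind] <- emitters$dy_px
    zz[ind] <- (emitters$z_nm - zc) / zh
    ii[ind] <- emitters$photons / max_photons
  }
  list(p = p, dx = dx, dy = dy, z = zz, I = ii, emitters = emitters)
}

#' Decode target maps back into an emitter table
#'
#' Inverse of [make_targets()]; used for round-trip validation and shared
#' by the inference decoder.
#'
#' @param targets list as returned by [make_targets()]
#' @param pixel_size nm per pixel
#' @inheritParams make_targets
#' @return data.frame with x_nm, y_nm, z_nm, photons
#' @export
decode_targets <- function(targets, pixel_size, z_range = c(-700, 300),
                           max_photons = 3000) {
  idx <- which(targets$p == 1, arr.ind = TRUE)
  zc <- mean(z_range); zh <- diff(z_range) / 2
  data.frame(
    x_nm = (idx[, 2] - 1 + 0.5 + targets$dx[idx]) * pixel_size,
    y_nm = (idx[, 1] - 1 + 0.5 + targets$dy[idx]) * pixel_size,
    z_nm = targets$z[idx] * zh + zc,
    photons = targets$I[idx] * max_photons
  )
}

#' Render a simulated frame
#'
#' Sums spline-PSF renderings of all emitters into a noise-free photon
#' image, adds sampled structured background, and applies the camera model.
#' Emitters whose ROI extends past the frame are rendered clipped and kept
#' in the truth table (flagged `near_edge`).
#'
#' @param emitters data.frame from [sample_emitters()]
#' @param psf a `spline_psf`
#' @param bg a `background_model`, or NULL for no background
#' @param cam a [camera_model()], or NULL to return photons
#' @param masks a [cell_mask_set()] supplying geometry for the background
#' @param roi PSF rendering ROI (pixels, odd)
#' @param exposure camera exposure (s)
#' @param seed optional RNG seed
#' @param edt optional precomputed EDT map for background sampling
#' @param targets build full-frame target maps (skip in tight loops that
#'   construct their own tile-local targets)
#' @return list: `gray` (camera image or photon image when `cam` is NULL),
#'   `clean` (noise-free emitter-only photons), `photons` (clean +
#'   background), `truth` (emitter table with `near_edge` flag), `targets`
#' @export
render_frame <- function(emitters, psf, bg, cam, masks, roi = 15,
                         exposure = 0.15, seed = NULL, edt = NULL,
                         targets = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  shape <- dim(masks$labels)
  px <- masks$pixel_size
  clean <- matrix(0, shape[1], shape[2])
  half <- (roi - 1) / 2
  n_em <- nrow(emitters)
  near_edge <- logical(n_em)
  e_dx <- emitters$dx_px; e_dy <- emitters$dy_px
  e_z <- emitters$z_nm; e_ph <- emitters$photons
  e_r <- emitters$pixel_row; e_c <- emitters$pixel_col
  for (i in seq_len(n_em)) {
    # ROI centered on the emitter's pixel; render with the emitter's
    # sub-pixel offset from that pixel center
    img <- render_psf(psf, x_off = e_dx[i] * px, y_off = e_dy[i] * px,
                      z = e_z[i], photons = e_ph[i], roi = roi)
    r0 <- e_r[i] - half; c0 <- e_c[i] - half
    rr <- r0:(r0 + roi - 1); cc <- c0:(c0 + roi - 1)
    vr <- rr >= 1 & rr <= shape[1]; vc <- cc >= 1 & cc <= shape[2]
    near_edge[i] <- !all(vr & vc)
    clean[rr[vr], cc[vc]] <- clean[rr[vr], cc[vc]] + img[vr, vc]
  }
  photons <- clean
  if (!is.null(bg))
    photons <- photons + sample_background(bg, masks$labels, edt = edt)
  gray <- if (!is.null(cam)) apply_camera(photons, cam, exposure) else photons
  truth <- emitters
  truth$near_edge <- near_edge
  tg <- if (targets) make_targets(emitters, shape) else NULL
  list(gray = gray, clean = clean, photons = photons, truth = truth,
       targets = tg)
}

#' Measure signal-to-background ratio on a rendered frame
#'
#' SBR is measured per emitter as the mean signal in an in-spot disk
#' covering the PSF extent
#' over the local background level (median photon level in a surrounding
#' annulus), averaged over emitters.
#'
#' @param frame output of [render_frame()]
#' @param pixel_size nm per pixel
#' @param masks optional [cell_mask_set()]: restrict the background annulus
#'   to pixels of the emitter's own cell
#' @param r_in in-spot radius (pixels)
#' @param r_out annulus outer radius (pixels)
#' @return mean SBR across emitters
#' @export
measure_sbr <- function(frame, pixel_size, masks = NULL, r_in = 5,
                        r_out = 10) {
  tr <- frame$truth
  img <- frame$photons
  vals <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    r <- tr$pixel_row[i]; c <- tr$pixel_col[i]
    rr <- pmax(1, r - r_out):pmin(nrow(img), r + r_out)
    cc <- pmax(1, c - r_out):pmin(ncol(img), c + r_out)
    dd <- sqrt(outer((rr - r)^2, (cc - c)^2, `+`))
    sub <- img[rr, cc]
    spot <- sub[dd <= r_in]
    in_ann <- dd > r_in + 1 & dd <= r_out
    if (!is.null(masks)) {
      # local background from pixels of the same cell only
      same <- masks$labels[rr, cc] == tr$cell_id[i]
      if (sum(in_ann & same) >= 5) in_ann <- in_ann & same
    }
    ann <- sub[in_ann]
    if (length(spot) == 0 || length(ann) == 0) next
    vals <- c(vals, mean(spot) / median(ann))
  }
  mean(vals)
}
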