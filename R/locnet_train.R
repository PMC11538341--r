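#' Training the localizer
#'
#' Batches of simulated tiles with ground truth are generated on the fly,
#' pushed through the network, scored with the compound loss, and the
#' analytic loss gradients are back-propagated through the output
#' activations and the convolutional trunk.  Optimization is AdamW with a
#' step learning-rate schedule.
#'
#' @name locnet_train
NULL

# loss (and gradient w.r.t. the raw 10-channel output) for one batch.
# targets: list per sample with elements p (matrix), truth (data.frame
# x_nm, y_nm, z_nm, photons; tile-local), clean (photon image).
batch_loss <- function(model, raw, targets, need_grad = TRUE) {
  cfg <- model$cfg
  B <- dim(raw)[4]
  acts <- activate_outputs(raw, cfg)
  w <- cfg$loss_weights
  px <- cfg$pixel_size
  n <- dim(raw)[1]
  colc <- matrix((seq_len(n) - 0.5) * px, n, n, byrow = TRUE)
  rowc <- matrix((seq_len(n) - 0.5) * px, n, n)
  zc <- mean(cfg$z_range); zh <- diff(cfg$z_range) / 2
  draw <- if (need_grad) raw * 0 else NULL
  parts <- c(count = 0, ce = 0, loc = 0, mol = 0)
  for (b in seq_len(B)) {
    tg <- targets[[b]]
    p <- acts$p[, , b]
    mu <- list(x = colc + acts$dx[, , b] * px,
               y = rowc + acts$dy[, , b] * px,
               z = zc + zh * acts$z[, , b],
               I = cfg$max_photons * acts$I[, , b])
    sg <- list(x = acts$sx[, , b], y = acts$sy[, , b],
               z = acts$sz[, , b], I = acts$sI[, , b])
    clean_s <- tg$clean / cfg$max_photons
    lc <- loss_count_grad(p, nrow(tg$truth))
    le <- loss_ce_grad(p, tg$p)
    ll <- loss_loc_grad(p, mu, sg, tg$truth)
    lm <- loss_psf_grad(acts$psf[, , b], clean_s)
    parts <- parts + c(lc$value, le$value, ll$value, lm$value) / B
    if (!need_grad) next
    dp <- (w[1] * lc$dp + w[2] * le$dp + w[3] * ll$dp) / B
    draw[, , 1, b] <- dp * p * (1 - p)
    tx <- 2 * acts$dx[, , b]  # tanh values
    draw[, , 2, b] <- w[3] / B * ll$dmu$x * px * 0.5 * (1 - tx^2)
    ty <- 2 * acts$dy[, , b]
    draw[, , 3, b] <- w[3] / B * ll$dmu$y * px * 0.5 * (1 - ty^2)
    tz <- acts$z[, , b]
    draw[, , 4, b] <- w[3] / B * ll$dmu$z * zh * (1 - tz^2)
    si <- acts$I[, , b]
    draw[, , 5, b] <- w[3] / B * ll$dmu$I * cfg$max_photons * si * (1 - si)
    sxs <- (sg$x - cfg$sigma_floor) / cfg$sigma_max_xy
    draw[, , 6, b] <- w[3] / B * ll$dsigma$x * cfg$sigma_max_xy * sxs * (1 - sxs)
    sys_ <- (sg$y - cfg$sigma_floor) / cfg$sigma_max_xy
    draw[, , 7, b] <- w[3] / B * ll$dsigma$y * cfg$sigma_max_xy * sys_ * (1 - sys_)
    szs <- (sg$z - cfg$sigma_floor) / cfg$sigma_max_z
    draw[, , 8, b] <- w[3] / B * ll$dsigma$z * cfg$sigma_max_z * szs * (1 - szs)
    sis <- (sg$I - 10) / cfg$max_photons
    draw[, , 9, b] <- w[3] / B * ll$dsigma$I * cfg$max_photons * sis * (1 - sis)
    pv <- acts$psf[, , b]
    draw[, , 10, b] <- w[4] / B * lm$dI * pv * (1 - pv)
  }
  list(value = total_loss(parts, w), parts = parts, draw = draw)
}

#' Train the localizer network
#'
#' AdamW with the configured schedule: the learning rate starts at
#' `lr_initial` and is reduced by 90% every `lr_decay_every` iterations.
#' Training aborts with a diagnostic dump if the loss turns non-finite.
#'
#' @param model a `locnet_model` from [build_network()]
#' @param simulator function(batch_size) returning a training batch:
#'   list(x = array(tile, tile, 3, B), targets = list of per-sample target
#'   lists with `p`, `truth`, `clean`); see [make_tile_simulator()]
#' @param iterations,batch_size override the configured values (useful for
#'   smoke tests)
#' @param checkpoint_every write `history` attribute entries at this period
#' @param verbose print progress
#' @return the trained model; `$history` holds the per-iteration losses
#' @export
train <- function(model, simulator, iterations = NULL, batch_size = NULL,
                  checkpoint_every = 500, verbose = FALSE) {
  cfg <- model$cfg
  if (is.null(iterations)) iterations <- cfg$iterations
  if (is.null(batch_size)) batch_size <- cfg$batch_size
  set.seed(cfg$seed + 1L)
  params <- model$params
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- matrix(NA_real_, iterations, 6,
                 dimnames = list(NULL, c("iter", "lr", "count", "ce", "loc",
                                         "mol")))
  for (it in seq_len(iterations)) {
    lr <- cfg$lr_initial * cfg$lr_decay_factor^(floor((it - 1) / cfg$lr_decay_every))
    batch <- simulator(batch_size)
    fw <- net_fwd(model, batch$x)
    bl <- batch_loss(model, fw$raw, batch$targets)
    if (!is.finite(bl$value)) {
      diag_path <- file.path(tempdir(), sprintf("locnet_nan_iter%d.rds", it))
      saveRDS(list(batch = batch, raw = fw$raw, parts = bl$parts), diag_path)
      stop(sprintf("non-finite loss at iteration %d; batch dumped to %s",
                   it, diag_path))
    }
    grads <- net_bwd(model, fw$cache, bl$draw)
    for (nm in names(params)) {
      g <- grads[[nm]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
      mh <- m[[nm]] / (1 - b1^it)
      vh <- v[[nm]] / (1 - b2^it)
      params[[nm]] <- params[[nm]] -
        lr * (mh / (sqrt(vh) + eps) + cfg$weight_decay * params[[nm]])
    }
    model$params <- params
    hist[it, ] <- c(it, lr, bl$parts)
    if (verbose && it %% checkpoint_every == 0)
      message(sprintf("iter %6d lr %.2e count %.3f ce %.3f loc %.3f mol %.5f",
                      it, lr, bl$parts[1], bl$parts[2], bl$parts[3],
                      bl$parts[4]))
  }
  model$history <- as.data.frame(hist)
  model
}

#' On-the-fly training-tile simulator
#'
#' Builds a closure that renders random training tiles: a random crop of a
#' bank of synthetic cell-mask scenes, emitters sampled inside cells,
#' spline-PSF rendering on structured background through the camera model.
#' Targets hold tile-local truth for emitters whose center pixel falls
#' inside the crop.
#'
#' @param psf a `spline_psf`
#' @param bg a `background_model` (or NULL for constant background `bg0`)
#' @param cam a [camera_model()] whose maps cover the scene size (or NULL
#'   to train directly in the photon domain)
#' @param masks a [cell_mask_set()] scene to crop tiles from
#' @param cfg the [locnet_config()] used for scaling
#' @param density_per_cell mean emitters per cell and frame during
#'   training (training density is a free training-distribution choice;
#'   higher density gives more positive supervision per tile)
#' @param photon_range,z_range emitter sampling ranges
#' @param bg0 constant background level (photons/pixel) when `bg` is NULL
#' @param crop_bias fraction of crops centered (with jitter) on an emitter
#' @param pool_size if > 0, pre-simulate this many tiles once and resample
#'   them (with 180-degree rotation augmentation) instead of rendering
#'   every batch from scratch
#' @param fov nominal camera field size for CoordConv normalization
#' @return function(batch_size) producing training batches
#' @export
make_tile_simulator <- function(psf, bg, cam, masks, cfg,
                                density_per_cell = 4,
                                photon_range = c(750, 3000),
                                z_range = c(-700, 300), bg0 = 5.8,
                                crop_bias = 0.7, fov = 512,
                                pool_size = 0) {
  tile <- cfg$tile
  shape <- dim(masks$labels)
  stopifnot(all(shape >= tile))
  edt <- compute_edt(masks$labels)
  draw_tiles <- function(batch_size) {
    x <- array(0, c(tile, tile, 3, batch_size))
    targets <- vector("list", batch_size)
    for (b in seq_len(batch_size)) {
      em <- sample_emitters(masks, density_per_cell, photon_range, z_range)
      fr <- render_frame(em, psf, bg, cam = NULL, masks, edt = edt,
                         targets = FALSE)
      lam <- fr$photons + (if (is.null(bg)) bg0 else 0)
      phot <- if (!is.null(cam)) {
        to_photons(apply_camera(lam, cam), cam)
      } else {
        matrix(rpois(length(lam), lam), nrow(lam))
      }
      # crops are biased toward emitters (with jitter) so each batch
      # carries positive supervision; the rest are random cell-containing
      # crops providing negatives
      r0 <- NA
      if (nrow(em) > 0 && runif(1) < crop_bias) {
        e <- em[sample.int(nrow(em), 1), ]
        r0 <- e$pixel_row - sample.int(tile - 4, 1) - 1
        c0 <- e$pixel_col - sample.int(tile - 4, 1) - 1
        r0 <- min(max(r0, 1), shape[1] - tile + 1)
        c0 <- min(max(c0, 1), shape[2] - tile + 1)
      } else {
        for (try in 1:10) {
          r0 <- sample.int(shape[1] - tile + 1, 1)
          c0 <- sample.int(shape[2] - tile + 1, 1)
          if (sum(masks$labels[r0:(r0 + tile - 1), c0:(c0 + tile - 1)] > 0) >
              0.1 * tile^2) break
        }
      }
      x[, , 1, b] <- phot[r0:(r0 + tile - 1), c0:(c0 + tile - 1)] / cfg$input_scale
      x[, , 2:3, b] <- coord_fields(tile, origin = c(r0, c0), fov = fov)
      inside <- em$pixel_row >= r0 & em$pixel_row <= r0 + tile - 1 &
        em$pixel_col >= c0 & em$pixel_col <= c0 + tile - 1
      emt <- em[inside, , drop = FALSE]
      px <- masks$pixel_size
      emt$x_nm <- emt$x_nm - (c0 - 1) * px
      emt$y_nm <- emt$y_nm - (r0 - 1) * px
      emt$pixel_col <- emt$pixel_col - (c0 - 1L)
      emt$pixel_row <- emt$pixel_row - (r0 - 1L)
      tg <- suppressWarnings(
        make_targets(emt, c(tile, tile), cfg$z_range, cfg$max_photons))
      targets[[b]] <- list(p = tg$p, truth = tg$emitters,
                           clean = fr$clean[r0:(r0 + tile - 1),
                                            c0:(c0 + tile - 1)])
    }
    list(x = x, targets = targets)
  }
  if (pool_size <= 0) return(draw_tiles)
  # pre-simulated tile pool: tiles are drawn once and re-sampled (with
  # 180-degree rotation, which preserves the astigmatic orientation) so
  # per-iteration cost is dominated by the optimizer, not the renderer
  pool <- draw_tiles(pool_size)
  rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  px <- masks$pixel_size
  function(batch_size) {
    x <- array(0, c(tile, tile, 3, batch_size))
    targets <- vector("list", batch_size)
    pick <- sample.int(pool_size, batch_size, replace = TRUE)
    for (b in seq_len(batch_size)) {
      i <- pick[b]
      tg <- pool$targets[[i]]
      if (runif(1) < 0.5) {
        x[, , , b] <- pool$x[, , , i]
        targets[[b]] <- tg
      } else {
        x[, , 1, b] <- rot180(pool$x[, , 1, i])
        # coordinate fields are kept as stored: inference always presents
        # monotone fields, so they must not be mirrored with the image
        x[, , 2:3, b] <- pool$x[, , 2:3, i]
        tr <- tg$truth
        if (nrow(tr) > 0) {
          tr$x_nm <- tile * px - tr$x_nm
          tr$y_nm <- tile * px - tr$y_nm
          tr <- emitter_pixels(tr[, c("cell_id", "x_nm", "y_nm", "z_nm",
                                      "photons")], px)
        }
        t2 <- suppressWarnings(
          make_targets(tr, c(tile, tile), cfg$z_range, cfg$max_photons))
        targets[[b]] <- list(p = t2$p, truth = t2$emitters,
                             clean = rot180(tg$clean))
      }
    }
    list(x = x, targets = targets)
  }
}

#' Save / load a trained model
#'
#' Weights and configuration are stored as a binary archive with a JSON
#' sidecar describing the configuration.
#'
#' @param model a `locnet_model`
#' @param path output path (`.rds`)
#' @return `path` (save) / the model (load)
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  jsonlite::write_json(model$cfg[!vapply(model$cfg, is.function, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  m$cfg <- structure(m$cfg, class = "locnet_config")
  structure(m, class = "locnet_model")
}
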