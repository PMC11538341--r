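#' Inference: tiling, decoding and evaluation
#'
#' Full frames are partitioned into overlapping tiles; each tile is pushed
#' through the network; the probability channel is non-max-suppressed and
#' thresholded (p > 0.8); surviving pixels are decoded into a localization
#' table in nanometers from the image origin (top-left corner).  Detection
#' performance against ground truth uses optimal one-to-one matching within
#' a distance gate (Hungarian algorithm) and the Jaccard / RMSE /
#' efficiency metrics of the SMLM challenge.
#'
#' @name inference
NULL

#' Partition a frame into overlapping tiles
#'
#' Tiles of side `tile` with `overlap` pixels of context on each side;
#' every frame pixel is owned by exactly one tile's ownership window.
#' Border tiles are reflect-padded to full size.
#'
#' @param frame image matrix
#' @param tile tile side (pixels)
#' @param overlap context overlap (pixels, >= PSF radius)
#' @return list of tiles: each has `img`, `origin` (row, col of the tile's
#'   top-left pixel in frame coordinates; can be < 1 for padded tiles) and
#'   `own` (rows/cols of the ownership window in frame coordinates)
#' @export
tile_frame <- function(frame, tile = 128, overlap = 16) {
  if (overlap < 0) stop("overlap must be non-negative")
  nr <- nrow(frame); nc <- ncol(frame)
  core <- tile - 2 * overlap
  if (core <= 0) stop("overlap too large for the tile size")
  reflect_idx <- function(i, n) {
    # reflect without repeating the edge pixel; handles any distance
    j <- (i - 1) %% (2 * n - 2)
    ifelse(j < n, j + 1, 2 * n - j - 1)
  }
  starts <- function(n) {
    if (n <= core) return(1L)
    seq(1L, n, by = core)
  }
  out <- list()
  for (r0 in starts(nr)) {
    for (c0 in starts(nc)) {
      own_r <- r0:min(r0 + core - 1, nr)
      own_c <- c0:min(c0 + core - 1, nc)
      orig <- c(r0 - overlap, c0 - overlap)
      rows <- reflect_idx(orig[1]:(orig[1] + tile - 1), nr)
      cols <- reflect_idx(orig[2]:(orig[2] + tile - 1), nc)
      out[[length(out) + 1]] <- list(img = frame[rows, cols],
                                     origin = orig,
                                     own = list(rows = own_r, cols = own_c))
    }
  }
  out
}

#' Decode network outputs into localizations
#'
#' The per-pixel probabilities are first aggregated over each pixel\'s 3x3
#' neighborhood (the network may split one emitter\'s detection probability
#' over the pixels of its spot); local maxima of the aggregated map within
#' a (2r+1)^2 neighborhood that exceed `p_threshold` (strict) and fall
#' inside the ownership window become emitters.  Offsets, depth, photons
#' and uncertainties are read out as probability-weighted averages over the
#' winning neighborhood and converted to physical units.
#'
#' @param outputs activated output maps from [locnet_predict()]
#' @param origin tile origin (row, col) in frame coordinates
#' @param own ownership window (list with `rows`, `cols` in frame
#'   coordinates), or NULL for the whole tile
#' @param cfg the model's [locnet_config()]
#' @param p_threshold detection threshold (default 0.8)
#' @param nms_radius suppression radius r (pixels)
#' @param frame frame index to record
#' @return data.frame: frame, x_nm, y_nm, z_nm, photons, p, sigma_x,
#'   sigma_y, sigma_z, sigma_I
#' @export
decode <- function(outputs, origin = c(1, 1), own = NULL, cfg,
                   p_threshold = 0.8, nms_radius = 2, frame = 1L) {
  p <- outputs$p
  # the network may distribute detection probability over the pixels of one
  # spot; aggregate it in a 3x3 neighborhood before thresholding
  ps <- box3_sum(p)
  keep <- nms_local_maxima(ps, nms_radius) & ps > p_threshold
  idx <- which(keep, arr.ind = TRUE)
  px <- cfg$pixel_size
  zc <- mean(cfg$z_range); zh <- diff(cfg$z_range) / 2
  res <- data.frame(
    frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
    z_nm = numeric(0), photons = numeric(0), p = numeric(0),
    sigma_x = numeric(0), sigma_y = numeric(0), sigma_z = numeric(0),
    sigma_I = numeric(0))
  if (nrow(idx) == 0) return(res)
  # frame coordinates of the winning pixels (1-based)
  fr_r <- idx[, 1] + origin[1] - 1
  fr_c <- idx[, 2] + origin[2] - 1
  if (!is.null(own)) {
    sel <- fr_r %in% own$rows & fr_c %in% own$cols
    idx <- idx[sel, , drop = FALSE]
    fr_r <- fr_r[sel]; fr_c <- fr_c[sel]
    if (nrow(idx) == 0) return(res)
  }
  # probability-weighted readout over each winning 3x3 neighborhood
  n1 <- nrow(p); n2 <- ncol(p)
  out <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rr <- max(1, r - 1):min(n1, r + 1)
    cc <- max(1, c - 1):min(n2, c + 1)
    w <- p[rr, cc, drop = FALSE]
    W <- sum(w)
    colg <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    rowg <- matrix(rr, length(rr), length(cc))
    xs <- (colg - 1 + 0.5 + outputs$dx[rr, cc]) * px
    ys <- (rowg - 1 + 0.5 + outputs$dy[rr, cc]) * px
    wm <- function(v) sum(w * v) / W
    out[[i]] <- data.frame(
      frame = frame,
      x_nm = wm(xs) + (origin[2] - 1) * px,
      y_nm = wm(ys) + (origin[1] - 1) * px,
      z_nm = zc + zh * wm(outputs$z[rr, cc]),
      photons = cfg$max_photons * wm(outputs$I[rr, cc]),
      p = min(W, 1),
      sigma_x = wm(outputs$sx[rr, cc]), sigma_y = wm(outputs$sy[rr, cc]),
      sigma_z = wm(outputs$sz[rr, cc]), sigma_I = wm(outputs$sI[rr, cc]))
  }
  do.call(rbind, out)
}

# sum of each pixel's 3x3 neighborhood (zero beyond borders)
box3_sum <- function(p) {
  n1 <- nrow(p); n2 <- ncol(p)
  out <- matrix(0, n1, n2)
  for (dr in -1:1) for (dc in -1:1) {
    sr <- (1:n1) + dr; sc <- (1:n2) + dc
    vr <- sr >= 1 & sr <= n1; vc <- sc >= 1 & sc <= n2
    out[vr, vc] <- out[vr, vc] + p[sr[vr], sc[vc]]
  }
  out
}

# TRUE at pixels that are the strict-or-first maximum of their
# (2r+1)x(2r+1) neighborhood (ties broken toward the smaller linear index,
# matching a greedy brute-force suppression).
nms_local_maxima <- function(p, r = 2) {
  n1 <- nrow(p); n2 <- ncol(p)
  out <- matrix(TRUE, n1, n2)
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr == 0 && dc == 0) next
      sr <- (1:n1) + dr; sc <- (1:n2) + dc
      vr <- sr >= 1 & sr <= n1; vc <- sc >= 1 & sc <= n2
      shifted <- matrix(-Inf, n1, n2)
      shifted[vr, vc] <- p[sr[vr], sc[vc]]
      prefer_other <- shifted > p |
        (shifted == p & (dr < 0 | (dr == 0 & dc < 0)))
      out <- out & !prefer_other
    }
  }
  out
}

#' Localize a stack of frames
#'
#' Tiles each frame, runs the network, decodes within ownership windows and
#' concatenates the results.  Deterministic given the model and frames.
#'
#' @param frames list of photon-domain images (or a single matrix)
#' @param model a trained `locnet_model`
#' @param p_threshold detection threshold
#' @param overlap tile overlap (pixels)
#' @param fov camera field size for CoordConv normalization
#' @return localization data.frame (see [decode()])
#' @export
localize_stack <- function(frames, model, p_threshold = 0.8, overlap = NULL,
                           fov = 512) {
  if (is.matrix(frames)) frames <- list(frames)
  cfg <- model$cfg
  if (is.null(overlap)) overlap <- cfg$tile %/% 4
  out <- list()
  for (f in seq_along(frames)) {
    tiles <- tile_frame(frames[[f]], tile = cfg$tile, overlap = overlap)
    for (tl in tiles) {
      pred <- locnet_predict(model, tl$img, origin = tl$origin, fov = fov)
      out[[length(out) + 1]] <- decode(pred, tl$origin, tl$own, cfg,
                                       p_threshold = p_threshold, frame = f)
    }
  }
  do.call(rbind, out)
}

#' Match detections to ground truth and score them
#'
#' Optimal one-to-one matching (Hungarian algorithm on the Euclidean
#' distance matrix, gated at `lateral_tol` in xy and `axial_tol` in z) per
#' frame.  Jaccard = TP / (TP + FP + FN); RMSE per axis over matches;
#' efficiency combines Jaccard and RMSE as in the SMLM challenge:
#' \eqn{100 - \sqrt{(100 - 100J)^2 + \alpha^2 RMSE^2}} with alpha = 1 /nm
#' (lateral) and 0.5 /nm (axial).
#'
#' @param pred data.frame with frame, x_nm, y_nm, z_nm
#' @param truth data.frame with frame, x_nm, y_nm, z_nm
#' @param lateral_tol lateral gate (nm)
#' @param axial_tol axial gate (nm)
#' @return list: jaccard, rmse (named x, y, z, lateral, vol),
#'   efficiency (lateral, axial, overall), n_tp, n_fp, n_fn, matches
#'   (data.frame of matched indices)
#' @export
evaluate_detections <- function(pred, truth, lateral_tol = 250,
                                axial_tol = 500) {
  empty <- data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), z_nm = numeric(0))
  if (is.null(pred) || nrow(pred) == 0) pred <- empty
  if (is.null(truth) || nrow(truth) == 0) truth <- empty
  tp <- 0; fp <- 0; fn <- 0
  dx2 <- dy2 <- dz2 <- numeric(0)
  match_rows <- list()
  for (f in unique(c(pred$frame, truth$frame))) {
    P <- pred[pred$frame == f, , drop = FALSE]
    Tr <- truth[truth$frame == f, , drop = FALSE]
    if (nrow(P) == 0 || nrow(Tr) == 0) {
      fp <- fp + nrow(P); fn <- fn + nrow(Tr)
      next
    }
    dlat <- sqrt(outer(P$x_nm, Tr$x_nm, `-`)^2 + outer(P$y_nm, Tr$y_nm, `-`)^2)
    dax <- abs(outer(P$z_nm, Tr$z_nm, `-`))
    gate <- dlat <= lateral_tol & dax <= axial_tol
    cost <- sqrt(dlat^2 + dax^2)
    BIG <- 1e9
    cost[!gate] <- BIG
    flip <- nrow(P) > nrow(Tr)
    cm <- if (flip) t(cost) else cost
    asg <- hungarian_assign(cm)
    tp_f <- 0
    for (i in seq_along(asg)) {
      j <- asg[i]
      if (is.na(j)) next
      pi_ <- if (flip) j else i
      ti_ <- if (flip) i else j
      if (!gate[pi_, ti_]) next
      tp_f <- tp_f + 1
      dx2 <- c(dx2, (P$x_nm[pi_] - Tr$x_nm[ti_])^2)
      dy2 <- c(dy2, (P$y_nm[pi_] - Tr$y_nm[ti_])^2)
      dz2 <- c(dz2, (P$z_nm[pi_] - Tr$z_nm[ti_])^2)
      match_rows[[length(match_rows) + 1]] <-
        data.frame(frame = f, pred_row = pi_, truth_row = ti_,
                   dist = cost[pi_, ti_])
    }
    tp <- tp + tp_f
    fp <- fp + nrow(P) - tp_f
    fn <- fn + nrow(Tr) - tp_f
  }
  jac <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  rmse <- c(x = sqrt(mean(dx2)), y = sqrt(mean(dy2)), z = sqrt(mean(dz2)),
            lateral = sqrt(mean(dx2 + dy2)),
            vol = sqrt(mean(dx2 + dy2 + dz2)))
  eff_lat <- 100 - sqrt((100 - 100 * jac)^2 + (1 * rmse["lateral"])^2)
  eff_ax <- 100 - sqrt((100 - 100 * jac)^2 + (0.5 * rmse["z"])^2)
  list(jaccard = jac, rmse = rmse,
       efficiency = c(lateral = unname(eff_lat), axial = unname(eff_ax),
                      overall = unname((eff_lat + eff_ax) / 2)),
       n_tp = tp, n_fp = fp, n_fn = fn,
       matches = if (length(match_rows)) do.call(rbind, match_rows) else NULL)
}

#' Write / read a localization table
#'
#' CSV with the package's column convention; `dialect = "challenge"` writes
#' the reduced (frame, x, y, z, photons) form.
#'
#' @param locs localization data.frame
#' @param path CSV path
#' @param dialect "full" or "challenge"
#' @return `path` (write) / data.frame (read)
#' @export
write_localizations <- function(locs, path, dialect = c("full", "challenge")) {
  dialect <- match.arg(dialect)
  if (dialect == "challenge")
    locs <- locs[, c("frame", "x_nm", "y_nm", "z_nm", "photons")]
  write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) read.csv(path)
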