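#' Localizer network
#'
#' A fully convolutional localizer built from stacked small U-nets ("two
#' U-nets connected in series"): the first consumes the camera tile plus
#' two CoordConv pixel-coordinate fields and produces a feature map; the
#' second consumes those features together with the raw input and feeds a
#' linear 3x3 head that emits 10 channels per pixel: detection probability
#' logit, sub-pixel x/y offsets, scaled depth, scaled photon count, four
#' uncertainty channels and a background-free PSF image.  Forward and
#' backward passes are implemented over compiled convolution primitives;
#' optimization uses AdamW.
#'
#' @name locnet
NULL

#' Network / training configuration
#'
#' @param tile tile side (pixels); must be divisible by 2^depth
#' @param base base number of filters
#' @param depth number of pooling levels per U-net
#' @param n_stages number of U-nets in series
#' @param pixel_size nm per pixel
#' @param z_range depth range (nm) mapped onto the tanh output
#' @param max_photons photon scaling divisor
#' @param sigma_max_xy,sigma_max_z,sigma_floor uncertainty-channel scaling
#'   (nm); sigma outputs are sigmoid * max + floor
#' @param iterations,batch_size,lr_initial,lr_decay_factor,lr_decay_every,
#'   weight_decay AdamW training schedule (defaults: batch 64, initial
#'   learning rate 6e-4 decayed by 90% every 5000 iterations, weight decay
#'   0.1); scale `iterations` and `batch_size` to the compute available
#' @param input_scale divisor applied to photon images before the network
#' @param loss_weights weights (w_count, w_ce, w_loc, w_mol), default
#'   c(0.2, 0.25, 1, 8000)
#' @param seed RNG seed for initialization and training
#' @return a `locnet_config` list
#' @export
locnet_config <- function(tile = 16, base = 8, depth = 2, n_stages = 2,
                          pixel_size = 110, z_range = c(-700, 300),
                          max_photons = 3000, sigma_max_xy = 300,
                          sigma_max_z = 600, sigma_floor = 1,
                          iterations = 20000, batch_size = 64,
                          lr_initial = 6e-4, lr_decay_factor = 0.1,
                          lr_decay_every = 5000, weight_decay = 0.1,
                          loss_weights = c(0.2, 0.25, 1, 8000),
                          input_scale = 100, seed = 1) {
  if (tile %% (2^depth) != 0)
    stop("tile must be divisible by 2^depth")
  structure(as.list(environment()), class = "locnet_config")
}

ch_of <- function(cfg, lv) cfg$base * 2^lv

#' Build (initialize) a localizer network
#'
#' He-initialized weights for the configured architecture.  The returned
#' model holds the parameter list and its configuration.
#'
#' @param cfg a [locnet_config()]
#' @return a `locnet_model`
#' @export
build_network <- function(cfg = locnet_config()) {
  set.seed(cfg$seed)
  params <- list()
  mk <- function(cin, cout) {
    list(w = array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                   c(3, 3, cin, cout)),
         b = rep(0, cout))
  }
  add <- function(name, cin, cout) {
    p <- mk(cin, cout)
    params[[paste0(name, "_w")]] <<- p$w
    params[[paste0(name, "_b")]] <<- p$b
  }
  for (s in seq_len(cfg$n_stages)) {
    cin <- if (s == 1) 3 else cfg$base + 3
    for (lv in 0:cfg$depth) {
      c_in1 <- if (lv == 0) cin else ch_of(cfg, lv - 1)
      add(sprintf("s%d_e%d_c1", s, lv), c_in1, ch_of(cfg, lv))
      add(sprintf("s%d_e%d_c2", s, lv), ch_of(cfg, lv), ch_of(cfg, lv))
    }
    for (lv in (cfg$depth - 1):0) {
      add(sprintf("s%d_d%d_c1", s, lv), ch_of(cfg, lv) + ch_of(cfg, lv + 1),
          ch_of(cfg, lv))
      add(sprintf("s%d_d%d_c2", s, lv), ch_of(cfg, lv), ch_of(cfg, lv))
    }
  }
  add("head", cfg$base, 10)
  structure(list(params = params, cfg = cfg), class = "locnet_model")
}

cat_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

# forward through one stage U-net; cache is an environment
stage_fwd <- function(x, s, cfg, params, cache) {
  fwd <- function(x, lv) {
    e1 <- sprintf("s%d_e%d_c1", s, lv); e2 <- sprintf("s%d_e%d_c2", s, lv)
    cache[[paste0(e1, "_x")]] <- x
    p1 <- conv3_fwd(x, params[[paste0(e1, "_w")]], params[[paste0(e1, "_b")]])
    cache[[paste0(e1, "_pre")]] <- p1
    h1 <- pmax(p1, 0)
    cache[[paste0(e2, "_x")]] <- h1
    p2 <- conv3_fwd(h1, params[[paste0(e2, "_w")]], params[[paste0(e2, "_b")]])
    cache[[paste0(e2, "_pre")]] <- p2
    h2 <- pmax(p2, 0)
    if (lv == cfg$depth) return(h2)
    pl <- avgpool2_fwd(h2)
    dn <- fwd(pl, lv + 1)
    up <- upsample2_fwd(dn)
    ct <- cat_ch(h2, up)
    d1 <- sprintf("s%d_d%d_c1", s, lv); d2 <- sprintf("s%d_d%d_c2", s, lv)
    cache[[paste0(d1, "_x")]] <- ct
    q1 <- conv3_fwd(ct, params[[paste0(d1, "_w")]], params[[paste0(d1, "_b")]])
    cache[[paste0(d1, "_pre")]] <- q1
    g1 <- pmax(q1, 0)
    cache[[paste0(d2, "_x")]] <- g1
    q2 <- conv3_fwd(g1, params[[paste0(d2, "_w")]], params[[paste0(d2, "_b")]])
    cache[[paste0(d2, "_pre")]] <- q2
    pmax(q2, 0)
  }
  fwd(x, 0)
}

stage_bwd <- function(dout, s, cfg, params, cache, grads) {
  bwd <- function(dout, lv) {
    e1 <- sprintf("s%d_e%d_c1", s, lv); e2 <- sprintf("s%d_e%d_c2", s, lv)
    if (lv < cfg$depth) {
      d1 <- sprintf("s%d_d%d_c1", s, lv); d2 <- sprintf("s%d_d%d_c2", s, lv)
      dq2 <- dout * (cache[[paste0(d2, "_pre")]] > 0)
      r2 <- conv3_bwd(cache[[paste0(d2, "_x")]], params[[paste0(d2, "_w")]], dq2)
      grads[[paste0(d2, "_w")]] <- grads[[paste0(d2, "_w")]] + r2$dw
      grads[[paste0(d2, "_b")]] <- grads[[paste0(d2, "_b")]] + r2$db
      dq1 <- r2$dx * (cache[[paste0(d1, "_pre")]] > 0)
      r1 <- conv3_bwd(cache[[paste0(d1, "_x")]], params[[paste0(d1, "_w")]], dq1)
      grads[[paste0(d1, "_w")]] <- grads[[paste0(d1, "_w")]] + r1$dw
      grads[[paste0(d1, "_b")]] <- grads[[paste0(d1, "_b")]] + r1$db
      nch <- ch_of(cfg, lv)
      dct <- r1$dx
      dh2_cat <- dct[, , seq_len(nch), , drop = FALSE]
      dup <- dct[, , nch + seq_len(dim(dct)[3] - nch), , drop = FALSE]
      ddn <- upsample2_bwd(dup)
      dpl <- bwd(ddn, lv + 1)
      h2dim <- dim(cache[[paste0(e2, "_pre")]])
      dh2 <- dh2_cat + avgpool2_bwd(dpl, h2dim[1], h2dim[2])
    } else {
      dh2 <- dout
    }
    dp2 <- dh2 * (cache[[paste0(e2, "_pre")]] > 0)
    r2 <- conv3_bwd(cache[[paste0(e2, "_x")]], params[[paste0(e2, "_w")]], dp2)
    grads[[paste0(e2, "_w")]] <- grads[[paste0(e2, "_w")]] + r2$dw
    grads[[paste0(e2, "_b")]] <- grads[[paste0(e2, "_b")]] + r2$db
    dp1 <- r2$dx * (cache[[paste0(e1, "_pre")]] > 0)
    need_dx <- !(s == 1 && lv == 0)
    r1 <- conv3_bwd(cache[[paste0(e1, "_x")]], params[[paste0(e1, "_w")]],
                    dp1, need_dx = need_dx)
    grads[[paste0(e1, "_w")]] <- grads[[paste0(e1, "_w")]] + r1$dw
    grads[[paste0(e1, "_b")]] <- grads[[paste0(e1, "_b")]] + r1$db
    if (need_dx) r1$dx else NULL
  }
  bwd(dout, 0)
}

# full network forward: x is (H, W, 3, B) = image + 2 coord fields.
# Returns raw (pre-activation) 10-channel output and the cache.
net_fwd <- function(model, x) {
  cfg <- model$cfg
  cache <- new.env(parent = emptyenv())
  cache$x0 <- x
  feat <- stage_fwd(x, 1, cfg, model$params, cache)
  if (cfg$n_stages > 1) {
    for (s in 2:cfg$n_stages) {
      xin <- cat_ch(feat, x)
      feat <- stage_fwd(xin, s, cfg, model$params, cache)
    }
  }
  cache$head_x <- feat
  raw <- conv3_fwd(feat, model$params$head_w, model$params$head_b)
  list(raw = raw, cache = cache)
}

net_bwd <- function(model, cache, draw) {
  cfg <- model$cfg
  grads <- new.env(parent = emptyenv())
  for (nm in names(model$params)) grads[[nm]] <- model$params[[nm]] * 0
  rh <- conv3_bwd(cache$head_x, model$params$head_w, draw)
  grads$head_w <- grads$head_w + rh$dw
  grads$head_b <- grads$head_b + rh$db
  dfeat <- rh$dx
  if (cfg$n_stages > 1) {
    for (s in cfg$n_stages:2) {
      dxin <- stage_bwd(dfeat, s, cfg, model$params, cache, grads)
      dfeat <- dxin[, , seq_len(cfg$base), , drop = FALSE]
    }
  }
  stage_bwd(dfeat, 1, cfg, model$params, cache, grads)
  as.list(grads)
}

# drop-dimension-safe channel slice helper
chan <- function(a, i) {
  d <- dim(a)
  out <- a[, , i, , drop = FALSE]
  dim(out) <- c(d[1], d[2], length(i), d[4])
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' CoordConv pixel-coordinate fields for a tile
#'
#' Two channels holding the normalized global camera coordinates of each
#' tile pixel (column and row, mapped onto \[-1, 1\] over the camera field).
#'
#' @param tile tile side (pixels)
#' @param origin c(row, col) of the tile's top-left pixel in the camera
#'   frame (1-based)
#' @param fov camera field size (pixels)
#' @return array tile x tile x 2
#' @export
coord_fields <- function(tile, origin = c(1, 1), fov = 512) {
  cols <- (origin[2] - 1 + seq_len(tile) - 0.5) / fov * 2 - 1
  rows <- (origin[1] - 1 + seq_len(tile) - 0.5) / fov * 2 - 1
  array(c(matrix(cols, tile, tile, byrow = TRUE),
          matrix(rows, tile, tile)), c(tile, tile, 2))
}

# Activate the 10 raw channels into physical-scale outputs.
# Returns list of (H, W, B) arrays.
activate_outputs <- function(raw, cfg) {
  squeeze <- function(a) {
    d <- dim(a); dim(a) <- c(d[1], d[2], d[4]); a
  }
  p <- pmin(pmax(sigmoid(chan(raw, 1)), 1e-7), 1 - 1e-7)
  list(
    p = squeeze(p),
    dx = squeeze(0.5 * tanh(chan(raw, 2))),
    dy = squeeze(0.5 * tanh(chan(raw, 3))),
    z = squeeze(tanh(chan(raw, 4))),
    I = squeeze(sigmoid(chan(raw, 5))),
    sx = squeeze(cfg$sigma_floor + cfg$sigma_max_xy * sigmoid(chan(raw, 6))),
    sy = squeeze(cfg$sigma_floor + cfg$sigma_max_xy * sigmoid(chan(raw, 7))),
    sz = squeeze(cfg$sigma_floor + cfg$sigma_max_z * sigmoid(chan(raw, 8))),
    sI = squeeze(10 + cfg$max_photons * sigmoid(chan(raw, 9))),
    psf = squeeze(sigmoid(chan(raw, 10)))
  )
}

#' Run the network on a single tile
#'
#' @param model a trained `locnet_model`
#' @param tile photon-domain image tile (matrix)
#' @param origin tile origin in the camera frame (row, col)
#' @param fov camera field size used for coordinate normalization
#' @return list of activated output maps (each a matrix): `p`, `dx`, `dy`,
#'   `z`, `I`, `sx`, `sy`, `sz`, `sI`, `psf`
#' @export
locnet_predict <- function(model, tile, origin = c(1, 1), fov = 512) {
  cfg <- model$cfg
  n <- nrow(tile)
  x <- array(0, c(n, ncol(tile), 3, 1))
  x[, , 1, 1] <- tile / cfg$input_scale
  x[, , 2:3, 1] <- coord_fields(n, origin, fov)
  out <- net_fwd(model, x)
  acts <- activate_outputs(out$raw, cfg)
  lapply(acts, function(a) a[, , 1])
}
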