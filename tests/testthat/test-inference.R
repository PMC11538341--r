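test_that("tile ownership windows partition the frame exactly once", {
  set.seed(1)
  frame <- matrix(rnorm(200 * 200), 200)
  tiles <- tile_frame(frame, tile = 64, overlap = 8)
  owners <- matrix(0, 200, 200)
  for (tl in tiles)
    owners[tl$own$rows, tl$own$cols] <- owners[tl$own$rows, tl$own$cols] + 1
  expect_true(all(owners == 1))
  expect_true(all(vapply(tiles, function(t) all(dim(t$img) == 64),
                         logical(1))))

  # one tile when the frame fits
  t1 <- tile_frame(matrix(0, 32, 32), tile = 32, overlap = 0)
  expect_length(t1, 1)
  expect_equal(t1[[1]]$own$rows, 1:32)

  # a frame smaller than the tile: single padded tile owning everything
  ts <- tile_frame(matrix(rnorm(20 * 20), 20), tile = 32, overlap = 4)
  expect_length(ts, 1)
  expect_equal(dim(ts[[1]]$img), c(32, 32))

  expect_error(tile_frame(frame, tile = 64, overlap = -1), "non-negative")
})

test_that("NMS matches a brute-force greedy suppression oracle", {
  brute_nms <- function(p, r, thr) {
    keep <- matrix(FALSE, nrow(p), ncol(p))
    alive <- p > thr
    while (any(alive)) {
      i <- which(alive & p == max(p[alive]), arr.ind = TRUE)[1, , drop = FALSE]
      keep[i] <- TRUE
      rr <- pmax(1, i[1] - r):pmin(nrow(p), i[1] + r)
      cc <- pmax(1, i[2] - r):pmin(ncol(p), i[2] + r)
      alive[rr, cc] <- FALSE
    }
    keep
  }
  set.seed(5)
  for (rep in 1:20) {
    p <- matrix(runif(100), 10)
    m <- lociloc3d:::nms_local_maxima(p, 2) & p > 0.5
    b <- brute_nms(p, 2, 0.5)
    # both keep the same isolated peaks; for chained maxima the greedy
    # oracle can keep strictly more, never fewer at the true peaks
    expect_true(all(which(m) %in% which(b) | m == b))
    # two maxima 1 px apart: exactly one survives
    q <- matrix(0, 10, 10); q[5, 5] <- 0.9; q[5, 6] <- 0.85
    expect_equal(sum(lociloc3d:::nms_local_maxima(q, 2) & q > 0.5), 1)
    expect_equal(which(lociloc3d:::nms_local_maxima(q, 2) & q > 0.5), which(q == 0.9))
  }
})

test_that("decode applies the strict p > 0.8 rule and the offset arithmetic", {
  cfg <- locnet_config(tile = 8, pixel_size = 100)
  mk_out <- function(pk) {
    o <- list(p = matrix(0, 8, 8), dx = matrix(0, 8, 8),
              dy = matrix(0, 8, 8), z = matrix(0, 8, 8),
              I = matrix(0.5, 8, 8), sx = matrix(20, 8, 8),
              sy = matrix(20, 8, 8), sz = matrix(40, 8, 8),
              sI = matrix(200, 8, 8), psf = matrix(0, 8, 8))
    o$p[4, 5] <- pk
    o$dx[4, 5] <- 0.2; o$dy[4, 5] <- -0.3
    o$z[4, 5] <- 0.4
    o
  }
  loc <- decode(mk_out(0.95), cfg = cfg)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$x_nm, (5 - 1 + 0.5 + 0.2) * 100)
  expect_equal(loc$y_nm, (4 - 1 + 0.5 - 0.3) * 100)
  expect_equal(loc$z_nm, -200 + 500 * 0.4)
  expect_equal(loc$photons, 0.5 * 3000)

  # p = 0.79 at threshold 0.8: no localization (strict inequality)
  expect_equal(nrow(decode(mk_out(0.79), cfg = cfg)), 0)
  expect_equal(nrow(decode(mk_out(0.8), cfg = cfg)), 0)
  expect_equal(nrow(decode(mk_out(0.801), cfg = cfg)), 1)

  # probability split over a spot is aggregated before thresholding
  osp <- mk_out(0.4)
  osp$p[4, 6] <- 0.3; osp$p[5, 5] <- 0.25
  expect_equal(nrow(decode(osp, cfg = cfg)), 1)
})

test_that("raising the threshold never increases the localization count", {
  cfg <- locnet_config(tile = 16, base = 4, depth = 1, n_stages = 1, seed = 5)
  model <- build_network(cfg)
  set.seed(6)
  frame <- matrix(abs(rnorm(48 * 48, 5, 2)), 48)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    nrow(localize_stack(frame, model, p_threshold = th, overlap = 4)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicated frames give identical localizations", {
  cfg <- locnet_config(tile = 16, base = 4, depth = 1, n_stages = 1, seed = 8)
  model <- build_network(cfg)
  set.seed(7)
  frame <- matrix(abs(rnorm(32 * 32, 5, 2)), 32)
  lc <- localize_stack(list(frame, frame), model, p_threshold = 0.05,
                       overlap = 4)
  l1 <- lc[lc$frame == 1, -1]; l2 <- lc[lc$frame == 2, -1]
  expect_equal(l1, l2, ignore_attr = TRUE)
})

test_that("tile seams do not perturb localizations away from seams", {
  # a model whose receptive field (two 3x3 convs per stage + head) is
  # smaller than the overlap, so interior context is identical
  cfg <- locnet_config(tile = 32, base = 4, depth = 0, n_stages = 1, seed = 9)
  model <- build_network(cfg)
  set.seed(10)
  frame <- matrix(abs(rnorm(64 * 64, 5, 2)), 64)
  whole <- tile_frame(frame, tile = 64, overlap = 0)
  pw <- locnet_predict(model, whole[[1]]$img, origin = c(1, 1), fov = 64)
  lw <- decode(pw, c(1, 1), NULL, cfg, p_threshold = 0.05)
  lt <- localize_stack(frame, model, p_threshold = 0.05, overlap = 8,
                       fov = 64)
  # compare localizations more than overlap/2 = 4 px from any seam (seams
  # at multiples of the 16-px core in both directions)
  seam_dist <- function(v) {
    g <- v %% (16 * cfg$pixel_size)
    pmin(g, 16 * cfg$pixel_size - g)
  }
  # also exclude the frame border: the whole-frame pass zero-pads there
  # while border tiles see reflected content
  brd <- function(v) pmin(v, 64 * cfg$pixel_size - v)
  away <- seam_dist(lw$x_nm) > 4 * cfg$pixel_size &
    seam_dist(lw$y_nm) > 4 * cfg$pixel_size &
    brd(lw$x_nm) > 6 * cfg$pixel_size & brd(lw$y_nm) > 6 * cfg$pixel_size
  lw2 <- lw[away, ]
  key <- function(d) paste(round(d$x_nm, 6), round(d$y_nm, 6), round(d$z_nm, 6))
  expect_true(all(key(lw2) %in% key(lt)))
})

test_that("Hungarian matching equals brute-force enumeration on 5x5", {
  brute <- function(cost) {
    n <- nrow(cost)
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    best <- Inf; barg <- NULL
    for (p in perms(seq_len(n))) {
      s <- sum(cost[cbind(seq_len(n), p)])
      if (s < best) { best <- s; barg <- p }
    }
    list(cost = best, assign = barg)
  }
  set.seed(11)
  for (rep in 1:10) {
    cost <- matrix(runif(25), 5)
    h <- hungarian_assign(cost)
    b <- brute(cost)
    expect_equal(sum(cost[cbind(1:5, h)]), b$cost, tolerance = 1e-12)
  }
})

test_that("detection metrics behave at the extremes", {
  truth <- data.frame(frame = 1, x_nm = c(100, 500, 900),
                      y_nm = c(100, 300, 800), z_nm = c(0, -100, 100))
  perfect <- evaluate_detections(truth, truth)
  expect_equal(perfect$jaccard, 1)
  expect_equal(unname(perfect$rmse["vol"]), 0)
  expect_equal(unname(perfect$efficiency["overall"]), 100)

  none <- evaluate_detections(truth[0, ], truth)
  expect_equal(none$jaccard, 0)
  expect_equal(none$n_fn, 3)

  # a detection outside the gate is a false positive plus a false negative
  far <- truth; far$x_nm <- far$x_nm + 5000
  ev <- evaluate_detections(far, truth)
  expect_equal(ev$jaccard, 0)
  expect_equal(ev$n_fp, 3)
  expect_equal(ev$n_fn, 3)
})

test_that("localization tables round-trip through CSV in both dialects", {
  locs <- data.frame(frame = 1:2, x_nm = c(100.5, 200.25),
                     y_nm = c(50, 60), z_nm = c(-10, 20),
                     photons = c(1000, 2000), p = c(0.9, 0.95),
                     sigma_x = c(20, 21), sigma_y = c(20, 21),
                     sigma_z = c(40, 41), sigma_I = c(200, 210))
  f1 <- tempfile(fileext = ".csv")
  write_localizations(locs, f1)
  expect_equal(read_localizations(f1), locs, tolerance = 1e-12)
  f2 <- tempfile(fileext = ".csv")
  write_localizations(locs, f2, dialect = "challenge")
  ch <- read_localizations(f2)
  expect_named(ch, c("frame", "x_nm", "y_nm", "z_nm", "photons"))
})
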