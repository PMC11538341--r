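test_that("homography fitting recovers a known projective transform", {
  H <- rbind(c(1.02, 0.05, 30), c(-0.04, 0.98, -12), c(1e-5, -2e-5, 1))
  set.seed(2)
  src <- cbind(runif(8, 0, 1000), runif(8, 0, 1000))
  q <- cbind(src, 1) %*% t(H)
  dst <- q[, 1:2] / q[, 3]
  tr <- fit_channel_transform(src, dst)
  expect_lt(max(abs(tr$H / tr$H[3, 3] - H / H[3, 3])) / max(abs(H)), 1e-9)
  expect_lt(max(tr$residuals), 1e-6)

  # exact with only 4 correspondences
  tr4 <- fit_channel_transform(src[1:4, ], dst[1:4, ])
  expect_lt(max(abs(apply_transform(tr4, src[5:8, ]) - dst[5:8, ])), 1e-6)

  # identity on identical point sets
  ti <- fit_channel_transform(src, src)
  expect_equal(ti$H, diag(3), tolerance = 1e-9)

  # inverse composes to the identity
  inv <- invert_transform(tr)
  expect_lt(max(abs(apply_transform(inv, dst) - src)), 1e-6)

  expect_error(fit_channel_transform(src[1:3, ], dst[1:3, ]), "at least 4")
  coll <- cbind(1:6, 2 * (1:6))
  expect_error(fit_channel_transform(coll, coll + 1), "degenerate|collinear")
})

test_that("the fitted transform preserves cross-ratios", {
  H <- rbind(c(0.9, 0.1, 5), c(0.02, 1.1, -8), c(3e-5, 1e-5, 1))
  tr <- structure(list(H = H), class = "channel_transform")
  # four collinear points: the cross-ratio is a projective invariant
  t0 <- c(0, 1, 3, 7)
  pts <- cbind(100 + 50 * t0, 200 + 30 * t0)
  mapped <- apply_transform(tr, pts)
  cross_ratio <- function(p) {
    d <- function(i, j) sqrt(sum((p[i, ] - p[j, ])^2))
    (d(1, 3) * d(2, 4)) / (d(2, 3) * d(1, 4))
  }
  expect_equal(cross_ratio(mapped), cross_ratio(pts), tolerance = 1e-9)
})

test_that("localizations are assigned to the containing cell", {
  masks <- fx_masks()
  px <- masks$pixel_size
  # cell centroids map to their own cell
  cents <- t(vapply(masks$cell_ids, function(k) {
    idx <- which(masks$labels == k, arr.ind = TRUE)
    c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5) * px
  }, numeric(2)))
  locs <- data.frame(x_nm = cents[, 1], y_nm = cents[, 2])
  ann <- assign_to_cells(locs, masks)
  expect_equal(ann$cell_id, masks$cell_ids)
  expect_equal(unname(ann$cell_area_um2),
               unname(masks$areas_um2[as.character(masks$cell_ids)]))

  # chip background and out-of-frame points are unassigned
  chip <- data.frame(x_nm = c(0.6 * px, -500), y_nm = c(0.6 * px, -500))
  expect_true(all(is.na(assign_to_cells(chip, masks)$cell_id)))
})

test_that("backbones of straight and bent cells are recovered", {
  straight <- synth_cell_masks(n_cells = 1, length_range = c(3200, 3200),
                               bend_range = c(0, 0), seed = 31)
  g <- fit_backbone(straight, 1)
  # quadratic coefficient ~ 0 for a straight rod
  expect_lt(abs(g$coef[3]) * g$length_nm, 0.2)  # curvature deflection < 0.2 nm

  bent <- synth_cell_masks(n_cells = 1, length_range = c(3600, 3600),
                           bend_range = c(2.5e-5, 2.5e-5), seed = 32)
  gb <- fit_backbone(bent, 1, new_pole = bent$geometry[[1]]$poles["new", ])
  # recovered centerline within 0.5 px RMS of the generating curve
  truthfun <- bent$geometry[[1]]$backbone
  u <- seq(-1500, 1500, by = 50)
  tpts <- truthfun(u)
  rel <- sweep(tpts, 2, gb$origin)
  uu <- rel %*% cbind(gb$uhat)
  vv <- rel %*% cbind(gb$nhat)
  resid <- vv - (gb$coef[1] + gb$coef[2] * uu + gb$coef[3] * uu^2)
  expect_lt(sqrt(mean(resid^2)), 0.5 * bent$pixel_size)

  # a disk has no long axis
  disk <- matrix(0L, 40, 40)
  for (r in 1:40) for (c in 1:40)
    if ((r - 20.5)^2 + (c - 20.5)^2 < 144) disk[r, c] <- 1L
  expect_error(fit_backbone(cell_mask_set(disk, 110), 1), "not elongated")
})

test_that("internal coordinates are exact on straight cells", {
  straight <- synth_cell_masks(n_cells = 1, length_range = c(3300, 3300),
                               bend_range = c(0, 0), seed = 33)
  tg <- straight$geometry[[1]]
  g <- fit_backbone(straight, 1, new_pole = tg$poles["new", ])
  # a point on the true centerline has small |s| (fitted backbone tracks
  # the true centerline to well under a pixel)
  ctr <- tg$backbone(0)
  on_bb <- data.frame(x_nm = ctr[1], y_nm = ctr[2], z_nm = 0)
  ic <- internal_coords(on_bb, g)
  expect_lt(abs(ic$s_nm), 0.5 * straight$pixel_size)
  expect_equal(ic$rel_l, 0.5, tolerance = 0.02)

  # a horizontal cell: axis-aligned offsets map to (delta l, delta s)
  off <- data.frame(x_nm = ctr[1] + 230, y_nm = ctr[2] + 140, z_nm = -60)
  ic2 <- internal_coords(off, g)
  expect_equal(abs(ic2$s_nm - ic$s_nm), 140, tolerance = 4)
  expect_equal(abs(ic2$l_nm - ic$l_nm), 230, tolerance = 4)
  expect_equal(ic2$r_nm, sqrt(ic2$s_nm^2 + 60^2), tolerance = 1e-9)
  expect_equal(ic2$phi_rad, atan2(-60, ic2$s_nm), tolerance = 1e-9)

  # a point exactly on the fitted backbone has s = 0 exactly
  pt <- internal_to_image(g, g$length_nm / 2, 0)
  ic3 <- internal_coords(data.frame(x_nm = pt[1], y_nm = pt[2], z_nm = 0), g)
  expect_lt(abs(ic3$s_nm), 1e-6)
  expect_equal(ic3$l_nm, g$length_nm / 2, tolerance = 1e-6)
})

test_that("nearest-point search matches dense brute force on bent cells", {
  bent <- synth_cell_masks(n_cells = 1, length_range = c(3600, 3600),
                           bend_range = c(3e-5, 3e-5), seed = 34)
  g <- fit_backbone(bent, 1, new_pole = bent$geometry[[1]]$poles["new", ])
  set.seed(35)
  pts <- data.frame(
    x_nm = g$origin[1] + runif(20, 300, g$length_nm * 0.8) * g$uhat[1],
    y_nm = g$origin[2] + runif(20, -300, 300), z_nm = 0)
  ic <- internal_coords(pts, g)
  # dense sampling oracle (1e4 points along the backbone)
  us <- seq(g$u_range[1], g$u_range[2], length.out = 1e4)
  curve <- cbind(us, g$coef[1] + g$coef[2] * us + g$coef[3] * us^2)
  arc <- c(0, cumsum(sqrt(diff(curve[, 1])^2 + diff(curve[, 2])^2)))
  for (i in seq_len(nrow(pts))) {
    p <- c(pts$x_nm[i], pts$y_nm[i]) - g$origin
    uv <- c(sum(p * g$uhat), sum(p * g$nhat))
    d <- sqrt((curve[, 1] - uv[1])^2 + (curve[, 2] - uv[2])^2)
    j <- which.min(d)
    expect_lt(abs(abs(ic$s_nm[i]) - d[j]), 1)
    expect_lt(abs(ic$l_nm[i] - arc[j]), 1)
  }
})

test_that("internal coordinates round-trip through image space", {
  bent <- synth_cell_masks(n_cells = 1, length_range = c(3400, 3400),
                           bend_range = c(2e-5, 2e-5), seed = 36)
  g <- fit_backbone(bent, 1)
  set.seed(37)
  l <- runif(15, 200, g$length_nm - 200)
  s <- runif(15, -350, 350)
  img <- internal_to_image(g, l, s)
  ic <- internal_coords(data.frame(x_nm = img[, 1], y_nm = img[, 2],
                                   z_nm = 0), g)
  expect_lt(max(abs(ic$l_nm - l)), 1e-6)
  expect_lt(max(abs(ic$s_nm - s)), 1e-6)
})

test_that("tilt-plane correction removes an injected tilt and is idempotent", {
  set.seed(38)
  n <- 800
  locs <- data.frame(x_nm = runif(n, 0, 7e4), y_nm = runif(n, 0, 7e4))
  b <- 5e-4; c_ <- -3e-4
  locs$z_nm <- rnorm(n, 0, 40) + 12 + b * locs$x_nm + c_ * locs$y_nm
  corr <- tilt_correct(locs)
  pl <- attr(corr, "tilt_plane")
  expect_lt(abs(pl[2] - b), 2e-5)
  expect_lt(abs(pl[3] - c_), 2e-5)
  # residual mean z per bin ~ 0
  bx <- cut(corr$x_nm, 8, labels = FALSE)
  by <- cut(corr$y_nm, 8, labels = FALSE)
  bins <- tapply(corr$z_nm, interaction(bx, by, drop = TRUE), mean)
  expect_lt(max(abs(bins)), 30)  # within sampling error of the 40 nm noise
  # second pass changes (almost) nothing
  corr2 <- tilt_correct(corr)
  expect_lt(max(abs(corr2$z_nm - corr$z_nm)), 1)

  # zero tilt: correction ~ 0
  flat <- locs; flat$z_nm <- rnorm(n, 0, 5)
  cf <- attr(tilt_correct(flat), "tilt_plane")
  expect_lt(abs(cf[2]), 3e-5); expect_lt(abs(cf[3]), 3e-5)

  # collinear localizations: warning, no correction
  line <- data.frame(x_nm = seq(0, 1e4, length.out = 20),
                     y_nm = rep(100, 20), z_nm = rnorm(20))
  expect_warning(tilt_correct(line), "rank-deficient|collinear")
  expect_error(tilt_correct(locs[1:5, ]), "at least 10")
})
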