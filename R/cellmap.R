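#' Mapping localizations into internal cell coordinates
#'
#' Localizations from the fluorescence channel are registered onto the
#' phase-contrast/segmentation frame with a projective (homography)
#' transform, assigned to cells via the label mask, and converted to
#' internal coordinates: arc-length position `l` along a quadratic backbone
#' from the new pole, signed perpendicular distance `s` to the backbone,
#' tilt-corrected depth `z_c`, radial distance `r = sqrt(s^2 + z_c^2)` and
#' angle `phi = atan2(z_c, s)`.  Depth is never remapped into the cell
#' frame (there is no common z reference across cells); only the
#' imaging-plane tilt is removed.
#'
#' @name cellmap
NULL

#' Fit a projective transform between channels
#'
#' Normalized direct linear transform (DLT) homography minimizing the
#' algebraic transfer error of point correspondences, with transfer
#' residuals reported.
#'
#' @param points_src n x 2 matrix of source points
#' @param points_dst n x 2 matrix of destination points
#' @return a `channel_transform`: 3x3 matrix `H`, `residuals` (per-point
#'   transfer error), and the inverse transform available via [invert_transform()]
#' @export
fit_channel_transform <- function(points_src, points_dst) {
  points_src <- as.matrix(points_src); points_dst <- as.matrix(points_dst)
  n <- nrow(points_src)
  if (n < 4) stop("need at least 4 point pairs for a projective transform")
  if (nrow(points_dst) != n) stop("point sets differ in size")
  normalize <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    if (mean(d) < .Machine$double.eps) stop("degenerate (coincident) points")
    s <- sqrt(2) / mean(d)
    Tm <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(T = Tm, p = cbind(p, 1) %*% t(Tm))
  }
  ns <- normalize(points_src); nd <- normalize(points_dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- ns$p[i, ]; x <- nd$p[i, 1]; y <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, x * X)
    A[2 * i, ] <- c(0, 0, 0, -X, y * X)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-12)
    stop("degenerate configuration (collinear points): homography not unique")
  h <- sv$v[, 9]
  H <- solve(nd$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% ns$T
  H <- H / H[3, 3]
  tr <- structure(list(H = H), class = "channel_transform")
  tr$residuals <- sqrt(rowSums((apply_transform(tr, points_src) - points_dst)^2))
  tr
}

#' Apply / invert a channel transform
#'
#' @param transform a `channel_transform`
#' @param points n x 2 matrix
#' @return transformed n x 2 matrix ([apply_transform()]) or the inverse
#'   transform ([invert_transform()])
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(points, ncol = 2)
  q <- cbind(points, 1) %*% t(transform$H)
  q[, 1:2, drop = FALSE] / q[, 3]
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  structure(list(H = solve(transform$H), residuals = transform$residuals),
            class = "channel_transform")
}

#' Assign localizations to segmented cells
#'
#' Each localization is mapped through the channel transform (if given) and
#' annotated with the label of the pixel containing it (0 becomes NA:
#' unassigned chip background).
#'
#' @param locs localization data.frame with x_nm, y_nm
#' @param masks a [cell_mask_set()]
#' @param transform optional `channel_transform` from the localization
#'   frame to the mask frame (nm units)
#' @return `locs` with columns cell_id, cell_area_um2 added
#' @export
assign_to_cells <- function(locs, masks, transform = NULL) {
  pts <- cbind(locs$x_nm, locs$y_nm)
  if (!is.null(transform)) pts <- apply_transform(transform, pts)
  px <- masks$pixel_size
  col <- floor(pts[, 1] / px) + 1
  row <- floor(pts[, 2] / px) + 1
  inb <- row >= 1 & row <= nrow(masks$labels) &
    col >= 1 & col <= ncol(masks$labels)
  id <- rep(NA_integer_, nrow(locs))
  id[inb] <- masks$labels[cbind(row[inb], col[inb])]
  id[!is.na(id) & id == 0] <- NA_integer_
  locs$cell_id <- id
  locs$cell_area_um2 <- unname(masks$areas_um2[as.character(id)])
  locs
}

# arc length of v = a1*u + a2*u^2 (plus constant) from u0 to u1
quad_arclen <- function(coef, u0, u1) {
  a1 <- coef[2]; a2 <- coef[3]
  if (abs(a2) < 1e-12) return((u1 - u0) * sqrt(1 + a1^2))
  F <- function(u) {
    t <- a1 + 2 * a2 * u
    (t * sqrt(1 + t^2) + asinh(t)) / (4 * a2)
  }
  F(u1) - F(u0)
}

#' Fit a cell backbone
#'
#' The cell poles are the farthest pair of boundary pixels; mask pixels are
#' rotated into the pole-aligned frame and a second-degree polynomial is
#' least-squares fitted through them, giving the backbone curve.
#'
#' @param masks a [cell_mask_set()]
#' @param cell_id which cell to fit
#' @param new_pole optional c(x, y) nm hint: the pole closer to this point
#'   is designated the new pole (long-axis origin); defaults to the first
#'   pole found
#' @return a `cell_geometry`: poles (nm), rotation frame, polynomial
#'   coefficients (in the pole-aligned frame), arc `length_nm`, area
#' @export
fit_backbone <- function(masks, cell_id, new_pole = NULL) {
  lab <- masks$labels
  px <- masks$pixel_size
  idx <- which(lab == cell_id, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no such cell")
  # boundary pixels: any 4-neighbor outside the cell
  is_in <- function(r, c) r >= 1 & r <= nrow(lab) & c >= 1 & c <= ncol(lab)
  bnd <- rep(FALSE, nrow(idx))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    r2 <- idx[, 1] + d[1]; c2 <- idx[, 2] + d[2]
    ok <- is_in(r2, c2)
    nb <- rep(0L, nrow(idx))
    nb[ok] <- lab[cbind(r2[ok], c2[ok])]
    bnd <- bnd | nb != cell_id
  }
  bpts <- cbind(x = (idx[bnd, 2] - 0.5) * px, y = (idx[bnd, 1] - 0.5) * px)
  D <- as.matrix(dist(bpts))
  far <- which(D == max(D), arr.ind = TRUE)[1, ]
  p1 <- bpts[far[1], ]; p2 <- bpts[far[2], ]
  axis_len <- sqrt(sum((p2 - p1)^2))
  allpts <- cbind(x = (idx[, 2] - 0.5) * px, y = (idx[, 1] - 0.5) * px)
  # elongation check: a disk has pole distance = 2 * equivalent radius
  if (axis_len < 2.4 * sqrt(nrow(idx) * px^2 / pi))
    stop("cell is not elongated: cannot define a backbone")
  if (!is.null(new_pole)) {
    if (sum((p2 - new_pole)^2) < sum((p1 - new_pole)^2)) {
      tmp <- p1; p1 <- p2; p2 <- tmp
    }
  }
  # frame: origin at the new pole p1, u axis toward p2
  uhat <- (p2 - p1) / axis_len
  nhat <- c(-uhat[2], uhat[1])  # left normal
  rel <- sweep(allpts, 2, p1)
  u <- rel %*% uhat
  v <- rel %*% nhat
  fit <- lm(v ~ u + I(u^2))
  coefs <- unname(coef(fit))
  coefs[is.na(coefs)] <- 0
  u_new <- 0; u_old <- axis_len
  structure(list(
    cell_id = cell_id,
    pole_new = p1, pole_old = p2,
    origin = p1, uhat = uhat, nhat = nhat,
    coef = coefs, u_range = c(u_new, u_old),
    length_nm = quad_arclen(coefs, u_new, u_old),
    area_um2 = nrow(idx) * (px / 1000)^2
  ), class = "cell_geometry")
}

# backbone curve value and derivative in the pole frame
bb_v <- function(g, u) g$coef[1] + g$coef[2] * u + g$coef[3] * u^2
bb_dv <- function(g, u) g$coef[2] + 2 * g$coef[3] * u

#' Convert a localization to internal cell coordinates
#'
#' Finds the nearest point on the backbone (exact: the stationarity
#' condition is a cubic, solved by `polyroot`), measures arc length from
#' the new pole (`l`), signed perpendicular distance (`s`, positive on the
#' backbone's left side looking from new to old pole), and derives `r`,
#' `phi` from `s` and the tilt-corrected depth.
#'
#' @param locs data.frame with x_nm, y_nm, z_nm (tilt-corrected)
#' @param geom a `cell_geometry`
#' @return data.frame: l_nm, s_nm, zc_nm, r_nm, phi_rad, rel_l, off_cell
#'   (TRUE when the foot point falls far outside the pole range)
#' @export
internal_coords <- function(locs, geom) {
  out <- data.frame(l_nm = numeric(nrow(locs)), s_nm = NA_real_,
                    zc_nm = locs$z_nm, r_nm = NA_real_, phi_rad = NA_real_,
                    rel_l = NA_real_, off_cell = FALSE)
  a0 <- geom$coef[1]; a1 <- geom$coef[2]; a2 <- geom$coef[3]
  for (i in seq_len(nrow(locs))) {
    p <- c(locs$x_nm[i], locs$y_nm[i]) - geom$origin
    u0 <- sum(p * geom$uhat); v0 <- sum(p * geom$nhat)
    a0p <- a0 - v0
    cc <- c(a0p * a1 - u0,
            2 * a0p * a2 + a1^2 + 1,
            3 * a1 * a2,
            2 * a2^2)
    us <- if (abs(cc[4]) < 1e-16 && abs(cc[3]) < 1e-16) {
      -cc[1] / cc[2]
    } else {
      deg <- max(which(abs(cc) > 0))
      rt <- polyroot(cc[seq_len(deg)])
      Re(rt[abs(Im(rt)) < 1e-6 * (1 + abs(Re(rt)))])
    }
    if (length(us) == 0) us <- u0
    d2 <- (us - u0)^2 + (bb_v(geom, us) - v0)^2
    ustar <- us[which.min(d2)]
    l <- quad_arclen(geom$coef, 0, ustar)
    dv <- bb_dv(geom, ustar)
    tau <- c(1, dv) / sqrt(1 + dv^2)
    nrm <- c(-tau[2], tau[1])
    s <- sum((c(u0, v0) - c(ustar, bb_v(geom, ustar))) * nrm)
    out$l_nm[i] <- l
    out$s_nm[i] <- s
    margin <- 0.25 * geom$length_nm
    out$off_cell[i] <- ustar < geom$u_range[1] - margin ||
      ustar > geom$u_range[2] + margin
  }
  out$r_nm <- sqrt(out$s_nm^2 + out$zc_nm^2)
  out$phi_rad <- atan2(out$zc_nm, out$s_nm)
  out$rel_l <- out$l_nm / geom$length_nm
  out
}

#' Map internal coordinates back to image space
#'
#' Inverse of the (l, s) part of [internal_coords()]; used for round-trip
#' validation.
#'
#' @param geom a `cell_geometry`
#' @param l_nm arc length from the new pole
#' @param s_nm signed perpendicular distance
#' @return matrix with columns x_nm, y_nm
#' @export
internal_to_image <- function(geom, l_nm, s_nm) {
  out <- matrix(0, length(l_nm), 2, dimnames = list(NULL, c("x_nm", "y_nm")))
  for (i in seq_along(l_nm)) {
    f <- function(u) quad_arclen(geom$coef, 0, u) - l_nm[i]
    lo <- geom$u_range[1] - 0.5 * geom$length_nm
    hi <- geom$u_range[2] + 0.5 * geom$length_nm
    ustar <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    dv <- bb_dv(geom, ustar)
    tau <- c(1, dv) / sqrt(1 + dv^2)
    nrm <- c(-tau[2], tau[1])
    fr <- c(ustar, bb_v(geom, ustar)) + s_nm[i] * nrm
    out[i, ] <- geom$origin + fr[1] * geom$uhat + fr[2] * geom$nhat
  }
  out
}

#' Imaging-plane tilt correction
#'
#' The mean depth of localizations varies across the field when the imaging
#' plane is tilted.  Localizations are binned on (x, y); a least-squares
#' plane z = a + b x + c y is fitted to the bin averages and subtracted
#' from every localization.  Idempotent up to numerical precision.
#'
#' @param locs data.frame with x_nm, y_nm, z_nm (one field of view)
#' @param nbins spatial bins per axis
#' @return `locs` with z_nm replaced by the tilt-corrected depth; the plane
#'   coefficients are attached as attribute `tilt_plane`
#' @export
tilt_correct <- function(locs, nbins = 8) {
  if (nrow(locs) < 10) stop("need at least 10 localizations to fit a plane")
  bx <- cut(locs$x_nm, nbins, labels = FALSE)
  by <- cut(locs$y_nm, nbins, labels = FALSE)
  key <- interaction(bx, by, drop = TRUE)
  agg <- data.frame(
    x = tapply(locs$x_nm, key, mean),
    y = tapply(locs$y_nm, key, mean),
    z = tapply(locs$z_nm, key, mean))
  if (nrow(agg) < 3 || qr(cbind(1, agg$x, agg$y))$rank < 3) {
    warning("rank-deficient tilt fit (collinear localizations): no correction")
    attr(locs, "tilt_plane") <- c(0, 0, 0)
    return(locs)
  }
  fit <- lm(z ~ x + y, data = agg)
  cf <- unname(coef(fit))
  locs$z_nm <- locs$z_nm - (cf[1] + cf[2] * locs$x_nm + cf[3] * locs$y_nm)
  attr(locs, "tilt_plane") <- cf
  locs
}
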