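#' Cubic-spline PSF calibration
#'
#' An experimentally measured astigmatic PSF is turned into a piecewise
#' cubic-spline model: bead z-stacks are aligned by 3D cross-correlation and
#' averaged, the mean stack is normalized by the maximum of the mean of the
#' three central planes, and a C2-continuous tensor-product cubic spline
#' (64 polynomial coefficients per voxel, not-a-knot end conditions) is
#' fitted to the normalized stack.  The spline supports rendering of PSF
#' slices at arbitrary sub-voxel emitter positions and analytic derivatives
#' for Cramer-Rao bound computations.
#'
#' Coordinate conventions: image origin at the top-left corner; pixel
#' centers at (index - 0.5) * pixel size for 1-based indices; x runs along
#' columns, y along rows; z = 0 at the calibrated focal plane.
#'
#' @name psf_spline
NULL

# Fourier shift of a 3D array by (possibly fractional) voxels.
fourier_shift3 <- function(a, shift) {
  d <- dim(a)
  ks <- lapply(seq_len(3), function(i) {
    n <- d[i]
    k <- c(0:floor(n / 2), seq_len(n - floor(n / 2) - 1) - (n - floor(n / 2)))
    k / n
  })
  ph <- array(ks[[1]] * shift[1], d) +
    array(rep(ks[[2]] * shift[2], each = d[1]), d) +
    array(rep(ks[[3]] * shift[3], each = d[1] * d[2]), d)
  Re(fft(fft(a) * exp(-2i * pi * ph), inverse = TRUE)) / prod(d)
}

# Cross-correlation peak of two same-size 3D arrays, refined to sub-voxel
# precision by a 3-point quadratic fit per axis.  Returns the displacement
# s such that shifting `mov` by s aligns it with `ref`.
xcorr_shift3 <- function(ref, mov) {
  d <- dim(ref)
  cc <- Re(fft(fft(ref) * Conj(fft(mov)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  shift <- numeric(3)
  for (i in 1:3) {
    n <- d[i]
    idx0 <- pk[i]
    ring <- function(j) ((j - 1) %% n) + 1
    sel <- function(j) {
      p <- pk; p[i] <- ring(j)
      cc[matrix(p, 1)]
    }
    ym <- sel(idx0 - 1); y0 <- sel(idx0); yp <- sel(idx0 + 1)
    denom <- ym - 2 * y0 + yp
    frac <- if (abs(denom) > .Machine$double.eps) 0.5 * (ym - yp) / denom else 0
    frac <- max(-0.5, min(0.5, frac))
    s <- (idx0 - 1) + frac
    if (s > n / 2) s <- s - n
    shift[i] <- s
  }
  # round to the 0.1-voxel precision of the quadratic refinement
  round(shift * 10) / 10
}

#' Average and normalize bead stacks
#'
#' Aligns each stack onto the first by 3D cross-correlation (sub-voxel
#' refinement by a local quadratic fit of the correlation peak, 0.1-voxel
#' precision, Fourier-domain shifting), averages, and normalizes by the
#' maximum intensity of the mean of the three planes centered on the focal
#' plane, so that value is 1 at that maximum.
#'
#' @param stacks list of [bead_stack()] objects with identical shapes and
#'   voxel sizes
#' @return a normalized [bead_stack()]; attribute `normalization` records
#'   the divisor used
#' @export
average_bead_stacks <- function(stacks) {
  if (length(stacks) == 0) stop("need at least one bead stack")
  ref <- stacks[[1]]
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    if (!identical(dim(s$voxels), dim(ref$voxels)))
      stop(sprintf("stack %d has mismatched shape", i))
    if (s$dx != ref$dx || s$dy != ref$dy || s$dz != ref$dz)
      stop(sprintf("stack %d has mismatched voxel sizes", i))
  }
  acc <- ref$voxels
  if (length(stacks) > 1) {
    for (i in 2:length(stacks)) {
      sh <- xcorr_shift3(ref$voxels, stacks[[i]]$voxels)
      aligned <- if (all(sh == 0)) stacks[[i]]$voxels else
        fourier_shift3(stacks[[i]]$voxels, sh)
      acc <- acc + aligned
    }
  }
  m <- acc / length(stacks)
  z0 <- ref$z0_index
  zi <- max(1, z0 - 1):min(dim(m)[3], z0 + 1)
  central <- apply(m[, , zi, drop = FALSE], c(1, 2), mean)
  norm <- max(central)
  if (norm <= 0) stop("degenerate stack: central planes are non-positive")
  m <- pmax(m / norm, 0)
  out <- bead_stack(m, ref$dx, ref$dy, ref$dz, z0)
  attr(out, "normalization") <- norm
  out
}

#' Fit a tensor-product cubic spline to a bead stack
#'
#' Computes the 64 per-voxel polynomial coefficients of the C2-continuous
#' tricubic interpolant of the stack (not-a-knot boundary conditions).  The
#' spline reproduces the stack exactly at the knots and has continuous
#' first and second derivatives across voxel faces.
#'
#' @param stack a [bead_stack()] (at least 4 knots per dimension)
#' @return a `spline_psf` object
#' @export
fit_cspline <- function(stack) {
  v <- stack$voxels
  if (any(!is.finite(v))) stop("NaN or non-finite values in the stack")
  d <- dim(v)
  if (any(d < 4)) stop("need at least 4 knots in every dimension")
  coef <- cspline_build(v)
  z0 <- stack$z0_index
  structure(list(
    coef = coef,
    n_row = d[1], n_col = d[2], n_plane = d[3],
    dx = stack$dx, dy = stack$dy, dz = stack$dz,
    z0_index = z0,
    center_row = (d[1] + 1) / 2, center_col = (d[2] + 1) / 2,
    z_range = c((1 - z0) * stack$dz, (d[3] - z0) * stack$dz),
    normalization = attr(stack, "normalization")
  ), class = "spline_psf")
}

#' @export
print.spline_psf <- function(x, ...) {
  cat(sprintf("spline_psf: %d x %d x %d knots, dx=%g dy=%g dz=%g nm, z range [%g, %g] nm\n",
              x$n_row, x$n_col, x$n_plane, x$dx, x$dy, x$dz,
              x$z_range[1], x$z_range[2]))
  invisible(x)
}

# Evaluate the spline PSF (optionally with derivatives) at ROI pixel
# centers for an emitter at lateral offset (x_off, y_off) nm from the ROI
# center and depth z nm.  Returns a matrix with columns f, df/dx_off,
# df/dy_off, df/dz (nm^-1) when deriv = TRUE.
psf_eval_roi <- function(psf, x_off, y_off, z, roi, deriv = FALSE) {
  half <- (roi - 1) / 2
  opix <- seq_len(roi) - 1 - half
  gc <- (psf$center_col - 1) + rep(opix, each = roi) - x_off / psf$dx
  gr <- (psf$center_row - 1) + rep(opix, times = roi) - y_off / psf$dy
  gz <- (psf$z0_index - 1) + z / psf$dz
  pts <- cbind(gr, gc, gz)
  res <- cspline_eval(psf$coef, pts, deriv = deriv)
  if (!deriv) return(res)
  # chain rule: d(grid)/d(x_off) = -1/dx etc.; z enters with +1/dz
  cbind(f = res[, 1],
        dfdx = -res[, 3] / psf$dx,
        dfdy = -res[, 2] / psf$dy,
        dfdz = res[, 4] / psf$dz)
}

#' Render a PSF image at a sub-voxel emitter position
#'
#' Evaluates the spline at depth `z`, laterally shifted by (`x_off`,
#' `y_off`) from the ROI center, clips negative overshoot at zero,
#' normalizes the slice to sum to 1 and multiplies by `photons`.
#'
#' @param psf a `spline_psf` from [fit_cspline()]
#' @param x_off,y_off lateral emitter offsets from the ROI center (nm)
#' @param z emitter depth (nm); must lie within `psf$z_range`
#' @param photons total photon count of the rendered spot
#' @param roi ROI side length (pixels, odd)
#' @return `roi` x `roi` matrix (rows = y, cols = x) in photons/pixel
#' @export
render_psf <- function(psf, x_off = 0, y_off = 0, z = 0, photons = 1000,
                       roi = 15) {
  if (z < psf$z_range[1] || z > psf$z_range[2])
    stop(sprintf("z = %g nm outside the calibrated range [%g, %g]",
                 z, psf$z_range[1], psf$z_range[2]))
  if (photons <= 0) stop("photons must be positive")
  if (roi %% 2 != 1) stop("roi must be odd")
  half_nm <- roi / 2 * psf$dx
  if (abs(x_off) > half_nm || abs(y_off) > half_nm)
    stop("lateral offset outside half the ROI")
  f <- psf_eval_roi(psf, x_off, y_off, z, roi)[, 1]
  f <- pmax(f, 0)
  s <- sum(f)
  if (s <= 0) stop("rendered slice is all zero")
  matrix(f / s * photons, roi, roi)
}

#' Cramer-Rao lower bound of localization precision
#'
#' For the Poisson imaging model \eqn{\mu_k = N g_k(x, y, z) + bg}, where
#' \eqn{g} is the per-slice-normalized spline PSF, computes the square roots
#' of the diagonal of the inverse Fisher information for the parameters
#' (x, y, z, N), with derivatives of the spline taken analytically from the
#' polynomial coefficients.
#'
#' @param psf a `spline_psf`
#' @param z emitter depth (nm), within `psf$z_range`
#' @param photons expected photons N
#' @param bg background photons per pixel (known, not estimated)
#' @param roi ROI side (pixels, odd)
#' @return named vector (sigma_x, sigma_y, sigma_z) in nm; `Inf` entries
#'   signal an (effectively) singular Fisher matrix, i.e. unbounded
#'   precision along that axis
#' @export
crlb <- function(psf, z, photons, bg = 0, roi = 15) {
  if (z < psf$z_range[1] || z > psf$z_range[2])
    stop("z outside the calibrated range")
  stopifnot(photons > 0, bg >= 0)
  ev <- psf_eval_roi(psf, 0, 0, z, roi, deriv = TRUE)
  f <- ev[, 1]
  pos <- f > 0
  fpos <- pmax(f, 0)
  D <- ev[, 2:4]
  D[!pos, ] <- 0
  S <- sum(fpos)
  dS <- colSums(D)
  g <- fpos / S
  dg <- D / S - outer(g, dS / S)
  mu <- photons * g + bg
  J <- cbind(photons * dg, g)  # d mu / d(x, y, z, N)
  keep <- mu > 1e-12
  Fim <- crossprod(J[keep, , drop = FALSE] / sqrt(mu[keep]))
  sv <- svd(Fim)
  tol <- max(sv$d) * 1e-10
  if (any(sv$d < tol)) {
    inv_d <- ifelse(sv$d < tol, Inf, 1 / sv$d)
    # unbounded precision along near-null directions
    sig2 <- vapply(1:3, function(i) {
      w <- sv$v[i, ]^2
      sum(ifelse(w < 1e-14, 0, w * inv_d))
    }, numeric(1))
    warning("Fisher information is singular; reporting unbounded precision")
    return(setNames(sqrt(sig2), c("sigma_x", "sigma_y", "sigma_z")))
  }
  cov <- solve(Fim)
  setNames(sqrt(diag(cov)[1:3]), c("sigma_x", "sigma_y", "sigma_z"))
}

#' Save / load a spline PSF
#'
#' The model is persisted as a binary archive of the coefficient array and
#' grid metadata, with a JSON header alongside describing the grid.
#'
#' @param psf a `spline_psf`
#' @param path output path (an `.rds` archive; a `.json` header is written
#'   next to it)
#' @return `path`, invisibly
#' @export
save_psf <- function(psf, path) {
  saveRDS(unclass(psf), path)
  hdr <- psf[c("n_row", "n_col", "n_plane", "dx", "dy", "dz",
               "z0_index", "z_range")]
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_psf
#' @export
load_psf <- function(path) {
  structure(readRDS(path), class = "spline_psf")
}
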