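#' Synthetic input generators
#'
#' Seeded generators for every experimental input consumed by the pipeline:
#' astigmatic bead z-stacks, spherocylindrical cell label masks, fractional
#' Brownian motion (fBm) and Ornstein-Uhlenbeck (OU) trajectories.  Each
#' generator returns its ground truth alongside the data, so downstream
#' estimators can be validated as parameter-recovery problems.
#'
#' @name fixtures
NULL

#' Astigmatic PSF width parameters
#'
#' Standard Gaussian-beam defocus model for an astigmatic PSF: the two
#' principal widths are \eqn{\sigma_{a,b}(z) = \sigma_0 \sqrt{1 + ((z \mp
#' \gamma)/z_R)^2}}, with the principal axes rotated by `theta` relative to
#' the image axes.  A 45 degree rotation (the default) mimics a cylindrical
#' lens rotated so that the PSF elongation does not align with the cell's
#' long axis.
#'
#' @param sigma0 focal spot width (nm)
#' @param z_r depth scale of defocus (nm)
#' @param gamma astigmatism offset: the two focal planes sit at +/- gamma (nm)
#' @param theta rotation of the principal axes (radians)
#' @return an `astig_params` object
#' @export
astig_params <- function(sigma0 = 140, z_r = 400, gamma = 250, theta = pi / 4) {
  stopifnot(sigma0 > 0, z_r > 0)
  structure(list(sigma0 = sigma0, z_r = z_r, gamma = gamma, theta = theta),
            class = "astig_params")
}

astig_widths <- function(params, z) {
  sa <- params$sigma0 * sqrt(1 + ((z - params$gamma) / params$z_r)^2)
  sb <- params$sigma0 * sqrt(1 + ((z + params$gamma) / params$z_r)^2)
  cbind(sa = sa, sb = sb)
}

#' Construct a bead z-stack container
#'
#' @param voxels 3D array (rows x cols x planes) of non-negative intensities
#' @param dx,dy lateral pixel size (nm)
#' @param dz axial step (nm)
#' @param z0_index index (1-based) of the focal plane
#' @return a `bead_stack` object
#' @export
bead_stack <- function(voxels, dx, dy, dz, z0_index) {
  stopifnot(length(dim(voxels)) == 3, dx > 0, dy > 0, dz > 0)
  if (z0_index < 1 || z0_index > dim(voxels)[3])
    stop("z0_index outside the stack")
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("stack intensities must be finite and non-negative")
  structure(list(voxels = voxels, dx = dx, dy = dy, dz = dz,
                 z0_index = as.integer(z0_index)),
            class = "bead_stack")
}

#' Simulate an astigmatic bead z-stack
#'
#' Renders a rotated elliptical Gaussian with z-dependent principal widths
#' on a pixel grid, integrating over pixels by 4x4 midpoint supersampling.
#' Each plane is normalized to sum to `photons` (before optional Poisson
#' noise), mimicking a bright bead whose full signal is captured per frame.
#'
#' @param params [astig_params()]
#' @param n_xy lateral grid size (pixels; stack is n_xy x n_xy)
#' @param n_z number of planes
#' @param dx lateral pixel size (nm)
#' @param dz axial step (nm)
#' @param photons photons per plane
#' @param center lateral bead position in pixels from the stack center,
#'   length 2 (row, col); default c(0, 0)
#' @param noise if TRUE, apply Poisson noise (requires a prior seed)
#' @return a [bead_stack()]; the focal plane is the central plane
#' @export
synth_bead_stack <- function(params = astig_params(), n_xy = 25, n_z = 41,
                             dx = 110, dz = 50, photons = 5e4,
                             center = c(0, 0), noise = FALSE) {
  z0 <- (n_z + 1) %/% 2
  zs <- ((1:n_z) - z0) * dz
  cx <- (n_xy + 1) / 2 + center[2]  # column (x) center in pixel units
  cy <- (n_xy + 1) / 2 + center[1]
  # 4x4 supersample offsets within a pixel (pixel centers at integer indices)
  ss <- (seq_len(4) - 2.5) / 4
  off <- expand.grid(oy = ss, ox = ss)
  vox <- array(0, dim = c(n_xy, n_xy, n_z))
  ct <- cos(params$theta); st <- sin(params$theta)
  for (k in seq_len(n_z)) {
    w <- astig_widths(params, zs[k])
    sa <- w[1] / dx; sb <- w[2] / dx  # widths in pixels
    img <- matrix(0, n_xy, n_xy)
    for (i in seq_len(nrow(off))) {
      xr <- outer(rep(1, n_xy), (1:n_xy) + off$ox[i] - cx)  # x (col) offsets
      yr <- outer((1:n_xy) + off$oy[i] - cy, rep(1, n_xy))  # y (row) offsets
      u <- ct * xr + st * yr
      v <- -st * xr + ct * yr
      img <- img + exp(-0.5 * (u / sa)^2 - 0.5 * (v / sb)^2)
    }
    img <- img / sum(img) * photons
    vox[, , k] <- img
  }
  if (noise) vox[] <- rpois(length(vox), vox)
  bead_stack(vox, dx = dx, dy = dx, dz = dz, z0_index = z0)
}

#' Simulate spherocylindrical cell masks
#'
#' Rasterizes rod-shaped cells (optionally bent along a quadratic
#' centerline) into an integer label image, the way a segmentation network
#' would produce them.  Cells are laid out on a grid so masks never overlap.
#' The true backbone (quadratic centerline in image coordinates) and pole
#' positions are returned per cell.
#'
#' @param n_cells number of cells
#' @param length_range cell length range (nm), uniform
#' @param width cell width/diameter (nm)
#' @param bend_range range of quadratic bend coefficient (1/nm); 0 = straight
#' @param pixel_size nm per pixel
#' @param seed RNG seed
#' @param margin spacing between cell bounding boxes (pixels)
#' @return list with `labels` (integer matrix), `pixel_size`,
#'   `areas_um2` (per cell), and `geometry` (list of per-cell truth:
#'   centerline function, poles, bend)
#' @export
synth_cell_masks <- function(n_cells = 6, length_range = c(2500, 4000),
                             width = 900, bend_range = c(0, 0),
                             pixel_size = 110, seed = 1, margin = 4) {
  set.seed(seed)
  lens <- runif(n_cells, length_range[1], length_range[2])
  bends <- runif(n_cells, bend_range[1], bend_range[2])
  wpx <- width / pixel_size
  # grid layout: cells in a column, horizontal orientation
  cell_h <- ceiling(wpx + 2 * abs(max(bends)) * (max(lens) / 2)^2 / pixel_size) + 2 * margin
  cell_w <- ceiling(max(lens) / pixel_size + wpx) + 2 * margin
  nrow_img <- n_cells * cell_h + margin
  ncol_img <- cell_w + margin
  labels <- matrix(0L, nrow_img, ncol_img)
  geometry <- vector("list", n_cells)
  areas <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    L <- lens[i]; b <- bends[i]
    r0 <- (i - 1) * cell_h + cell_h / 2 + margin / 2  # center row (pixels)
    c0 <- ncol_img / 2                                # center col
    # centerline: u in [-L/2, L/2] nm along x; v = b*u^2 (nm) along rows
    us <- seq(-L / 2, L / 2, length.out = 400)
    vs <- b * us^2
    cl_col <- c0 + us / pixel_size
    cl_row <- r0 + vs / pixel_size
    # rasterize: pixel inside if distance to centerline <= width/2
    rr <- floor(r0 - wpx - abs(b) * (L / 2)^2 / pixel_size - 2):ceiling(r0 + wpx + abs(b) * (L / 2)^2 / pixel_size + 2)
    cc <- floor(c0 - L / (2 * pixel_size) - wpx - 2):ceiling(c0 + L / (2 * pixel_size) + wpx + 2)
    rr <- rr[rr >= 1 & rr <= nrow_img]; cc <- cc[cc >= 1 & cc <= ncol_img]
    pts <- expand.grid(r = rr, c = cc)
    d2 <- matrix(Inf, nrow(pts), 1)
    for (j in seq_along(us)) {
      dj <- (pts$r - cl_row[j])^2 + (pts$c - cl_col[j])^2
      d2 <- pmin(d2, dj)
    }
    inside <- sqrt(d2) * pixel_size <= width / 2
    idx <- cbind(pts$r[inside], pts$c[inside])
    labels[idx] <- i
    areas[i] <- sum(inside) * (pixel_size / 1000)^2  # um^2
    geometry[[i]] <- list(
      cell_id = i,
      center_row = r0, center_col = c0,
      length_nm = L, width_nm = width, bend = b,
      # backbone in nm image coordinates (origin at image top-left corner,
      # pixel centers at (index - 0.5) * pixel_size)
      backbone = local({
        r0l <- r0; c0l <- c0; bl <- b; Ll <- L; ps <- pixel_size
        function(u) {
          cbind(x = (c0l - 0.5) * ps + u, y = (r0l - 0.5) * ps + bl * u^2)
        }
      }),
      poles = rbind(new = c((c0 - 0.5) * pixel_size - L / 2,
                            (r0 - 0.5) * pixel_size + b * (L / 2)^2),
                    old = c((c0 - 0.5) * pixel_size + L / 2,
                            (r0 - 0.5) * pixel_size + b * (L / 2)^2))
    )
  }
  cell_mask_set(labels, pixel_size, geometry = geometry)
}

#' Construct a cell mask set
#'
#' @param labels integer label matrix (0 = outside, k > 0 = cell k)
#' @param pixel_size nm per pixel
#' @param geometry optional list of per-cell ground-truth geometry
#' @return a `cell_mask_set` object with per-cell areas in um^2
#' @export
cell_mask_set <- function(labels, pixel_size, geometry = NULL) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  if (any(labels < 0)) stop("labels must be non-negative")
  ids <- sort(unique(labels[labels > 0]))
  areas <- vapply(ids, function(k) sum(labels == k) * (pixel_size / 1000)^2,
                  numeric(1))
  structure(list(labels = labels, pixel_size = pixel_size,
                 cell_ids = as.integer(ids),
                 areas_um2 = setNames(areas, ids),
                 geometry = geometry),
            class = "cell_mask_set")
}

# fGn covariance: autocovariance of unit-variance-per-step fractional
# Gaussian noise at lag k for Hurst exponent H.
fgn_cov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

#' Simulate fractional Brownian motion trajectories
#'
#' Exact simulation via Cholesky factorization of the fractional Gaussian
#' noise covariance.  The generated paths satisfy
#' \eqn{MSD(\tau) = 2 D \tau^{2H}} exactly in expectation.
#'
#' @param H Hurst exponent in (0, 1); H < 0.5 gives subdiffusion
#' @param n_steps number of increments per trajectory
#' @param n_traj number of trajectories
#' @param D generalized diffusion coefficient (nm^2 / s^(2H))
#' @param dt time step (s)
#' @param seed RNG seed
#' @return matrix (n_steps + 1) x n_traj of positions (nm), starting at 0;
#'   attributes `t` (times), `H`, `D`
#' @export
synth_fbm <- function(H, n_steps, n_traj, D = 400, dt = 1, seed = 1) {
  stopifnot(H > 0, H < 1, n_steps >= 1, n_traj >= 1)
  set.seed(seed)
  sig2 <- 2 * D * dt^(2 * H)  # variance of one increment
  C <- sig2 * outer(0:(n_steps - 1), 0:(n_steps - 1),
                    function(i, j) fgn_cov(i - j, H))
  L <- t(chol(C))
  incr <- L %*% matrix(rnorm(n_steps * n_traj), n_steps, n_traj)
  x <- rbind(0, apply(incr, 2, cumsum))
  if (n_steps == 1) x <- rbind(0, incr)
  attr(x, "t") <- (0:n_steps) * dt
  attr(x, "H") <- H
  attr(x, "D") <- D
  x
}

#' Simulate confined (Ornstein-Uhlenbeck) trajectories
#'
#' Stationary OU process with relaxation rate `theta_r` and stationary
#' variance `v`; its MSD is \eqn{2 v (1 - e^{-\theta_r \tau})}, saturating
#' at a plateau of \eqn{2 v}.
#'
#' @param theta_r relaxation rate (1/s)
#' @param v stationary variance (nm^2)
#' @param n_steps steps per trajectory
#' @param n_traj number of trajectories
#' @param dt time step (s)
#' @param seed RNG seed
#' @return matrix (n_steps + 1) x n_traj of positions (nm); attributes
#'   `t`, `v`, `theta_r`
#' @export
synth_confined <- function(theta_r, v, n_steps, n_traj, dt = 1, seed = 1) {
  stopifnot(theta_r > 0, v > 0)
  set.seed(seed)
  a <- exp(-theta_r * dt)
  s_innov <- sqrt(v * (1 - a^2))
  x <- matrix(0, n_steps + 1, n_traj)
  x[1, ] <- rnorm(n_traj, 0, sqrt(v))
  for (k in seq_len(n_steps))
    x[k + 1, ] <- a * x[k, ] + rnorm(n_traj, 0, s_innov)
  attr(x, "t") <- (0:n_steps) * dt
  attr(x, "v") <- v
  attr(x, "theta_r") <- theta_r
  x
}
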