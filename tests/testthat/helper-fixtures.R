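# Shared fixtures, built once per test run.  Everything is generated in
# code; sizes are kept small so the whole suite stays fast.

fx <- new.env()

fx_psf <- function() {
  if (is.null(fx$psf)) fx$psf <- ref_psf()
  fx$psf
}

fx_masks <- function() {
  if (is.null(fx$masks)) fx$masks <- ref_masks(seed = 11)
  fx$masks
}

fx_camera <- function() {
  if (is.null(fx$cam)) fx$cam <- ref_camera(dim(fx_masks()$labels))
  fx$cam
}

# analytic (non-astigmatic) 3D Gaussian sampled on a grid, used as a
# closed-form oracle for the spline interpolant
gauss3_stack <- function(n = 21, sx = 3, sy = 2.6, sz = 3.3) {
  g <- seq(-(n - 1) / 2, (n - 1) / 2)
  v <- array(0, c(n, n, n))
  for (k in seq_len(n))
    v[, , k] <- outer(exp(-g^2 / (2 * sy^2)), exp(-g^2 / (2 * sx^2))) *
      exp(-g[k]^2 / (2 * sz^2))
  list(stack = bead_stack(v, 100, 100, 50, (n + 1) %/% 2),
       f = function(r, c, p) {
         m <- (n - 1) / 2
         exp(-(r - m)^2 / (2 * sy^2)) * exp(-(c - m)^2 / (2 * sx^2)) *
           exp(-(p - m)^2 / (2 * sz^2))
       })
}

# trajectories in the package's internal-coordinate table layout
as_traj <- function(x, i, dt = 1, s = 0, z = 0, r = 300, phi = 0) {
  n <- length(x)
  data.frame(traj_id = i, cell_id = 1L, frame = seq_len(n) - 1L,
             t_s = (seq_len(n) - 1) * dt, l_nm = x,
             s_nm = rep_len(s, n), zc_nm = rep_len(z, n),
             r_nm = rep_len(r, n), phi_rad = rep_len(phi, n))
}

mat_cols <- function(m) lapply(seq_len(ncol(m)), function(j) m[, j])
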