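#' Locus tracking and anomalous-diffusion analysis
#'
#' Localizations mapped to internal cell coordinates are linked into
#' single-locus trajectories under quality gates (>= 5 consecutive frames,
#' cell area >= 1.6 um^2, the cell half closest to the new pole), and
#' ensemble mean-squared displacement (MSD) curves are computed along the
#' long, short, depth, radial and angular axes.  Power-law fits MSD(tau) =
#' 2 D tau^alpha (log-log regression) and 2 D tau^alpha + epsilon
#' (nonlinear, offset accounts for localization error) quantify
#' subdiffusion; the MSD intercept at zero lag gives the localization
#' precision, and the plateau of the radial MSD gives the confinement
#' width.
#'
#' @name tracking
NULL

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbor frame-to-frame linking with a displacement gate,
#' applied per cell after the selection gates.  Runs of at least `min_len`
#' consecutive frames are kept.  When two locus copies are present in the
#' selected region, proximity (seeded by pole distance via the long-axis
#' coordinate) separates the trajectories.
#'
#' @param locs data.frame with frame, cell_id, cell_area_um2, l_nm, s_nm,
#'   zc_nm, r_nm, phi_rad, rel_l and optionally t_s
#' @param min_len minimum trajectory length (consecutive frames)
#' @param area_min minimum cell area (um^2)
#' @param pole_half "new" (rel_l < 0.5), "old", or "both"
#' @param gate_nm maximum frame-to-frame displacement (nm)
#' @param dt frame interval (s), used when `t_s` is absent
#' @return list of trajectory data.frames (traj_id, cell_id, frame, t_s,
#'   l_nm, s_nm, zc_nm, r_nm, phi_rad); attribute `n_skipped` counts
#'   localizations without cell annotation
#' @export
link_trajectories <- function(locs, min_len = 5, area_min = 1.6,
                              pole_half = c("new", "old", "both"),
                              gate_nm = 500, dt = 120) {
  pole_half <- match.arg(pole_half)
  n_skipped <- sum(is.na(locs$cell_id))
  locs <- locs[!is.na(locs$cell_id), , drop = FALSE]
  locs <- locs[!is.na(locs$cell_area_um2) & locs$cell_area_um2 >= area_min, ,
               drop = FALSE]
  if (pole_half == "new") locs <- locs[locs$rel_l < 0.5, , drop = FALSE]
  if (pole_half == "old") locs <- locs[locs$rel_l >= 0.5, , drop = FALSE]
  if (!"t_s" %in% names(locs)) locs$t_s <- locs$frame * dt
  trajs <- list()
  for (cid in unique(locs$cell_id)) {
    cl <- locs[locs$cell_id == cid, , drop = FALSE]
    cl <- cl[order(cl$frame), , drop = FALSE]
    active <- list()  # each: data.frame of rows
    for (f in sort(unique(cl$frame))) {
      cand <- cl[cl$frame == f, , drop = FALSE]
      taken <- rep(FALSE, nrow(cand))
      # close stale tracks
      live <- vapply(active, function(tr) tr$frame[nrow(tr)] == f - 1,
                     logical(1))
      for (ti in which(live)) {
        tr <- active[[ti]]
        last <- tr[nrow(tr), ]
        d <- sqrt((cand$l_nm - last$l_nm)^2 + (cand$s_nm - last$s_nm)^2 +
                    (cand$zc_nm - last$zc_nm)^2)
        d[taken] <- Inf
        if (length(d) && min(d) <= gate_nm) {
          j <- which.min(d)
          active[[ti]] <- rbind(tr, cand[j, ])
          taken[j] <- TRUE
          live[ti] <- FALSE  # mark as extended
        }
      }
      # tracks not extended are finished; harvest below at the end
      for (j in which(!taken)) active[[length(active) + 1]] <- cand[j, ]
    }
    trajs <- c(trajs, active)
  }
  keep <- Filter(function(tr) nrow(tr) >= min_len, trajs)
  out <- lapply(seq_along(keep), function(i) {
    tr <- keep[[i]]
    data.frame(traj_id = i, cell_id = tr$cell_id, frame = tr$frame,
               t_s = tr$t_s, l_nm = tr$l_nm, s_nm = tr$s_nm,
               zc_nm = tr$zc_nm, r_nm = tr$r_nm, phi_rad = tr$phi_rad)
  })
  attr(out, "n_skipped") <- n_skipped
  out
}

unwrap_angle <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  phi[1] + c(0, cumsum(d))
}

#' Ensemble mean-squared displacement
#'
#' Squared displacements are time-averaged within each trajectory per lag,
#' then averaged (unweighted) across trajectories; the SEM is across
#' trajectories.  Axes: `long` (l), `short` (s), `depth` (z_c), `radial`
#' (scalar r(t), or the 2D yz vector MSD with `yz_vector = TRUE`), and
#' `angular` (unwrapped angle times the trajectory's mean radius = arc
#' length).  With `subtract_growth` (long axis), trajectories are re-zeroed
#' at their first point and the ensemble-mean displacement at each elapsed
#' time is subtracted before differencing, removing the net drift due to
#' cell growth.
#'
#' @param trajs list of trajectory data.frames from [link_trajectories()]
#' @param axis which coordinate to analyse
#' @param subtract_growth remove ensemble-mean drift (long axis)
#' @param yz_vector for `axis = "radial"`: use the 2D (s, z) vector MSD
#'   instead of the scalar radius
#' @param r_floor exclude angular points with radius below this (nm)
#' @return data.frame (`msd_curve`): lag_s, msd, sem, n_pairs, n_traj;
#'   attribute `n_excluded` counts angular points under the radius floor
#' @export
msd <- function(trajs, axis = c("long", "short", "depth", "radial",
                                "angular"),
                subtract_growth = FALSE, yz_vector = FALSE, r_floor = 20) {
  axis <- match.arg(axis)
  trajs <- Filter(function(tr) nrow(tr) > 1, trajs)
  if (length(trajs) == 0) stop("need at least one trajectory of length > 1")
  dt <- median(unlist(lapply(trajs, function(tr) diff(tr$t_s))))
  n_excluded <- 0
  series <- lapply(trajs, function(tr) {
    switch(axis,
      long = tr$l_nm,
      short = tr$s_nm,
      depth = tr$zc_nm,
      radial = if (yz_vector) cbind(tr$s_nm, tr$zc_nm) else tr$r_nm,
      angular = {
        ok <- tr$r_nm >= r_floor
        n_excluded <<- n_excluded + sum(!ok)
        if (sum(ok) < 2) return(NULL)
        unwrap_angle(tr$phi_rad[ok]) * mean(tr$r_nm[ok])
      })
  })
  keep <- !vapply(series, is.null, logical(1))
  series <- series[keep]
  if (axis == "long" && subtract_growth) {
    series <- lapply(series, function(x) x - x[1])
    maxlen <- max(lengths(series))
    drift <- vapply(seq_len(maxlen), function(k) {
      vals <- unlist(lapply(series, function(x) if (length(x) >= k) x[k] else NULL))
      mean(vals)
    }, numeric(1))
    series <- lapply(series, function(x) x - drift[seq_along(x)])
  }
  nlag <- max(vapply(series, NROW, numeric(1))) - 1
  per_traj <- matrix(NA_real_, length(series), nlag)
  pairs <- matrix(0, length(series), nlag)
  for (i in seq_along(series)) {
    x <- series[[i]]
    n <- NROW(x)
    for (k in seq_len(n - 1)) {
      if (is.matrix(x)) {
        d2 <- rowSums((x[(1 + k):n, , drop = FALSE] -
                         x[1:(n - k), , drop = FALSE])^2)
      } else {
        d2 <- (x[(1 + k):n] - x[1:(n - k)])^2
      }
      per_traj[i, k] <- mean(d2)
      pairs[i, k] <- length(d2)
    }
  }
  m <- apply(per_traj, 2, mean, na.rm = TRUE)
  ntr <- colSums(!is.na(per_traj))
  sem <- apply(per_traj, 2, sd, na.rm = TRUE) / sqrt(pmax(ntr, 1))
  out <- data.frame(lag_s = seq_len(nlag) * dt, msd = m, sem = sem,
                    n_pairs = colSums(pairs), n_traj = ntr)
  out <- out[out$n_traj > 0, , drop = FALSE]
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit a power law (optionally with offset) to an MSD curve
#'
#' Without offset: ordinary least squares of log(msd) on log(lag); the
#' slope is the anomalous exponent alpha and the intercept gives 2D.  With
#' offset: nonlinear least squares of 2 D tau^alpha + epsilon (epsilon >=
#' 0), initialized from the log-log fit; epsilon absorbs the localization
#' error (MSD intercept at zero lag = 2 sigma^2).
#'
#' @param curve an `msd_curve` (or data.frame with lag_s, msd)
#' @param with_offset fit the offset model
#' @return an `msd_fit`: list(alpha, D, epsilon, ci95 (matrix), model)
#' @export
fit_msd_powerlaw <- function(curve, with_offset = FALSE) {
  stopifnot(nrow(curve) >= 3)
  if (!with_offset) {
    if (any(curve$msd <= 0)) stop("log-log fit requires positive MSD values")
    fit <- lm(log(msd) ~ log(lag_s), data = curve)
    cf <- coef(fit)
    ci <- suppressMessages(confint(fit))
    out <- list(alpha = unname(cf[2]), D = unname(exp(cf[1]) / 2),
                epsilon = NULL,
                ci95 = rbind(alpha = ci[2, ], log2D = ci[1, ]),
                model = "loglog-linear", fit = fit)
  } else {
    start_fit <- fit_msd_powerlaw(curve, with_offset = FALSE)
    st <- list(D = max(start_fit$D, 1e-6), alpha = min(max(start_fit$alpha,
                                                           0.05), 1.95),
               eps = max(min(curve$msd) * 0.1, 1e-9))
    fit <- tryCatch(
      minpack.lm::nlsLM(msd ~ 2 * D * lag_s^alpha + eps, data = curve,
                        start = st,
                        lower = c(D = 1e-12, alpha = 0.01, eps = 0),
                        upper = c(D = Inf, alpha = 3, eps = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) stop("offset power-law fit did not converge: ",
                               conditionMessage(e)))
    cf <- coef(fit)
    ci <- tryCatch(suppressMessages(confint(fit)),
                   error = function(e) {
                     se <- summary(fit)$coefficients[, 2]
                     cbind(cf - 1.96 * se, cf + 1.96 * se)
                   })
    out <- list(alpha = unname(cf["alpha"]), D = unname(cf["D"]),
                epsilon = unname(cf["eps"]), ci95 = ci,
                model = "powerlaw-offset", fit = fit)
  }
  class(out) <- "msd_fit"
  out
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("msd_fit (%s): alpha = %.4f, D = %.4g nm^2/s^alpha",
              x$model, x$alpha, x$D))
  if (!is.null(x$epsilon)) cat(sprintf(", epsilon = %.4g nm^2", x$epsilon))
  cat("\n")
  invisible(x)
}

#' Localization precision from the MSD intercept
#'
#' The MSD extrapolated to zero lag equals twice the squared localization
#' error, so sigma = sqrt(epsilon / 2).
#'
#' @param fit an `msd_fit` with the offset model
#' @return precision sigma (nm)
#' @export
precision_from_intercept <- function(fit) {
  if (fit$model != "powerlaw-offset" || is.null(fit$epsilon))
    stop("precision requires the offset model fit")
  sqrt(fit$epsilon / 2)
}

#' Confinement plateau of an MSD curve
#'
#' Mean of the MSD values at the `n_last` longest time lags.
#'
#' @param curve an `msd_curve`
#' @param n_last number of trailing lags to average
#' @return plateau (nm^2)
#' @export
plateau <- function(curve, n_last = 5) {
  if (nrow(curve) < n_last) stop("curve has fewer lags than n_last")
  mean(tail(curve$msd, n_last))
}

#' Sister-locus angle correlations
#'
#' Pearson correlation between the unwrapped yz-plane angle series of two
#' locus copies from the same cell, over their overlapping frames.
#'
#' @param pairs list of trajectory pairs (each a list of two trajectory
#'   data.frames with `frame` and `phi_rad`)
#' @param min_overlap minimum overlapping frames
#' @return numeric vector of Pearson r (one per usable pair)
#' @export
angle_correlation <- function(pairs, min_overlap = 3) {
  out <- numeric(0)
  for (pr in pairs) {
    f <- intersect(pr[[1]]$frame, pr[[2]]$frame)
    if (length(f) < min_overlap) next
    a1 <- unwrap_angle(pr[[1]]$phi_rad[match(f, pr[[1]]$frame)])
    a2 <- unwrap_angle(pr[[2]]$phi_rad[match(f, pr[[2]]$frame)])
    if (sd(a1) == 0 || sd(a2) == 0) next
    out <- c(out, cor(a1, a2))
  }
  out
}

#' Symmetric bimodal normal fit of a spatial histogram
#'
#' Least-squares fit of A [N(x; mu, sigma) + N(x; -mu, sigma)] (equal
#' widths and weights, centers mirrored about zero) to binned counts.  A
#' fit whose mixture has a single mode (mu <= sigma) is reported as
#' effectively unimodal.
#'
#' @param mids bin centers
#' @param counts bin counts
#' @return list(mu, sigma, amplitude, unimodal, fit)
#' @export
bimodal_fit <- function(mids, counts) {
  if (length(mids) < 7) stop("need at least 7 bins")
  tot <- sum(counts)
  binw <- mean(diff(mids))
  m2 <- sum(counts * mids^2) / tot
  mu0 <- sqrt(max(m2 / 2, 1e-6))
  st <- list(A = tot * binw, mu = mu0, sig = mu0)
  fit <- minpack.lm::nlsLM(
    counts ~ A * (dnorm(mids, mu, sig) + dnorm(mids, -mu, sig)),
    start = st, lower = c(A = 0, mu = 0, sig = binw / 10),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  # a mirrored equal-weight Gaussian pair has a single mode iff mu <= sigma
  list(mu = unname(cf["mu"]), sigma = unname(cf["sig"]),
       amplitude = unname(cf["A"]),
       unimodal = unname(cf["mu"] <= cf["sig"]), fit = fit)
}

#' Write trajectories to CSV
#'
#' @param trajs list of trajectory data.frames
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_trajectories <- function(trajs, path) {
  write.csv(do.call(rbind, trajs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  d <- read.csv(path)
  split(d, d$traj_id)
}
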