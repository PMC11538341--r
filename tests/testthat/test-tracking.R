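test_that("linking gates work: length, area, pole half, displacement", {
  # a noiseless drifting emitter over 20 frames in one cell
  drift <- data.frame(frame = 1:20, cell_id = 1L, cell_area_um2 = 2.0,
                      l_nm = 100 + 10 * (1:20), s_nm = 50, zc_nm = -20,
                      r_nm = sqrt(50^2 + 20^2),
                      phi_rad = atan2(-20, 50), rel_l = 0.2)
  trs <- link_trajectories(drift, dt = 120)
  expect_length(trs, 1)
  expect_equal(trs[[1]]$l_nm, drift$l_nm)
  expect_equal(nrow(trs[[1]]), 20)

  # a 4-frame track is rejected by the >= 5 consecutive frames gate
  short <- drift[1:4, ]
  expect_length(link_trajectories(short, dt = 120), 0)

  # a small cell is excluded by the area gate
  small <- drift; small$cell_area_um2 <- 1.0
  expect_length(link_trajectories(small, dt = 120), 0)

  # the old-pole half is excluded when tracking the new half
  old_half <- drift; old_half$rel_l <- 0.8
  expect_length(link_trajectories(old_half, dt = 120), 0)
  expect_length(link_trajectories(old_half, pole_half = "old", dt = 120), 1)

  # a displacement beyond the gate splits the track
  jump <- drift
  jump$l_nm[11:20] <- jump$l_nm[11:20] + 5000
  trs2 <- link_trajectories(jump, dt = 120)
  expect_length(trs2, 2)

  # two locus copies in the same half stay separate trajectories
  two <- rbind(transform(drift, l_nm = 200), transform(drift, l_nm = 1400))
  trs3 <- link_trajectories(two, dt = 120)
  expect_length(trs3, 2)
  expect_true(all(vapply(trs3, function(t) sd(t$l_nm) == 0, logical(1))))
})

test_that("MSD of static points with iid noise is flat at 2 sigma^2", {
  set.seed(41)
  sg <- 35
  trajs <- lapply(1:500, function(i)
    as_traj(rnorm(30, 0, sg), i))
  curve <- msd(trajs, "long")
  expect_lt(max(abs(curve$msd[1:10] - 2 * sg^2)) / (2 * sg^2), 0.05)
})

test_that("Brownian and fBm trajectories give the right log-log slopes", {
  bm <- synth_fbm(0.5, 40, 300, D = 300, dt = 1, seed = 42)
  trajs <- lapply(seq_len(ncol(bm)), function(i) as_traj(bm[, i], i))
  fit <- fit_msd_powerlaw(msd(trajs, "long")[1:12, ])
  expect_lt(abs(fit$alpha - 1), 0.05)
  expect_true(is.matrix(fit$ci95))

  fb <- synth_fbm(0.25, 40, 300, D = 300, dt = 1, seed = 43)
  trajs2 <- lapply(seq_len(ncol(fb)), function(i) as_traj(fb[, i], i))
  fit2 <- fit_msd_powerlaw(msd(trajs2, "long")[1:12, ])
  expect_lt(abs(fit2$alpha - 0.5), 0.05)
})

test_that("MSD is invariant under translation and rotation about the axis", {
  set.seed(44)
  base <- synth_fbm(0.4, 25, 40, D = 200, dt = 1, seed = 44)
  t1 <- lapply(1:40, function(i) as_traj(base[, i], i))
  t2 <- lapply(1:40, function(i) as_traj(base[, i] + 5000, i))
  expect_equal(msd(t1, "long")$msd, msd(t2, "long")$msd, tolerance = 1e-9)

  # radial/angular MSD invariant under rotation about the cell axis
  set.seed(45)
  phi <- matrix(cumsum(rnorm(26 * 30, 0, 0.15)), 26)
  r <- matrix(280 + rnorm(26 * 30, 0, 15), 26)
  mk <- function(rot) lapply(1:30, function(i)
    as_traj(rep(0, 26), i, s = r[, i] * cos(phi[, i] + rot),
            z = r[, i] * sin(phi[, i] + rot), r = r[, i],
            phi = ((phi[, i] + rot + pi) %% (2 * pi)) - pi))
  m0 <- msd(mk(0), "radial"); m1 <- msd(mk(1.1), "radial")
  expect_equal(m0$msd, m1$msd, tolerance = 1e-9)
  a0 <- msd(mk(0), "angular"); a1 <- msd(mk(1.1), "angular")
  expect_equal(a0$msd, a1$msd, tolerance = 1e-6)
})

test_that("pooling two trajectory sets combines their MSD curves", {
  set.seed(46)
  x <- synth_fbm(0.35, 20, 60, D = 250, dt = 1, seed = 46)
  A <- lapply(1:25, function(i) as_traj(x[, i], i))
  B <- lapply(26:60, function(i) as_traj(x[, i], i))
  mA <- msd(A, "long"); mB <- msd(B, "long")
  mU <- msd(c(A, B), "long")
  comb <- (mA$msd * mA$n_traj + mB$msd * mB$n_traj) / (mA$n_traj + mB$n_traj)
  expect_equal(mU$msd, comb, tolerance = 1e-9)
})

test_that("growth subtraction removes a common drift from the long axis", {
  set.seed(47)
  drift_rate <- 25  # nm per frame, cell growth
  trajs <- lapply(1:120, function(i) {
    noise <- rnorm(30, 0, 20)
    as_traj(500 + drift_rate * (0:29) + noise, i)
  })
  raw <- msd(trajs, "long", subtract_growth = FALSE)
  cor_ <- msd(trajs, "long", subtract_growth = TRUE)
  # uncorrected MSD grows ~ (drift * lag)^2; corrected stays near 2 sigma^2
  expect_gt(raw$msd[10], 0.5 * (drift_rate * 10)^2)
  expect_lt(cor_$msd[10], 4 * 2 * 20^2)
})

test_that("power-law fits invert noiseless curves exactly", {
  tau <- 1:20
  cv <- data.frame(lag_s = tau, msd = 2 * 400 * tau^0.4)
  f <- fit_msd_powerlaw(cv)
  expect_equal(f$alpha, 0.4, tolerance = 1e-6)
  expect_equal(f$D, 400, tolerance = 1e-6)

  cvo <- data.frame(lag_s = tau, msd = 2 * 400 * tau^0.53 + 2 * 45^2)
  fo <- fit_msd_powerlaw(cvo, with_offset = TRUE)
  expect_equal(fo$alpha, 0.53, tolerance = 1e-6)
  expect_equal(fo$D, 400, tolerance = 1e-6)
  expect_equal(fo$epsilon, 4050, tolerance = 1e-6)
  expect_equal(precision_from_intercept(fo), 45, tolerance = 1e-6)

  expect_error(fit_msd_powerlaw(cv[1:2, ]), "nrow")
  expect_error(precision_from_intercept(f), "offset")
})

test_that("localization precision is recovered from the MSD intercept", {
  set.seed(48)
  sg0 <- 50
  fb <- synth_fbm(0.3, 40, 400, D = 150, dt = 1, seed = 48)
  noisy <- fb + rnorm(length(fb), 0, sg0)
  trajs <- lapply(seq_len(ncol(noisy)), function(i) as_traj(noisy[, i], i))
  fit <- fit_msd_powerlaw(msd(trajs, "long")[1:15, ], with_offset = TRUE)
  expect_lt(abs(precision_from_intercept(fit) - sg0) / sg0, 0.05)
})

test_that("the radial plateau of confined motion equals twice the variance", {
  v <- 3600; thr <- 0.35
  x <- synth_confined(thr, v, n_steps = 40, n_traj = 400, dt = 1, seed = 49)
  trajs <- lapply(seq_len(ncol(x)), function(i)
    as_traj(rep(0, 41), i, s = x[, i], z = 0, r = abs(x[, i]), phi = 0))
  curve <- msd(lapply(seq_len(ncol(x)), function(i) as_traj(x[, i], i)),
               "long")
  expect_lt(abs(plateau(curve, 5) - 2 * v) / (2 * v), 0.10)
  expect_equal(plateau(data.frame(lag_s = 1:8, msd = rep(7, 8),
                                  sem = 0, n_pairs = 1, n_traj = 1), 5), 7)
  expect_error(plateau(curve[1:3, ], 5), "fewer")
})

test_that("sister-locus angle correlations behave as expected", {
  t1 <- as_traj(rep(0, 20), 1, phi = seq(0.1, 2, length.out = 20))
  t2 <- t1; t2$traj_id <- 2
  expect_equal(angle_correlation(list(list(t1, t2))), 1)
  t3 <- t1; t3$phi_rad <- -t1$phi_rad
  expect_equal(angle_correlation(list(list(t1, t3))), -1)

  # independent random-walk angles: mean correlation ~ 0
  set.seed(50)
  pairs <- lapply(1:200, function(i) {
    a <- as_traj(rep(0, 25), 1, phi = cumsum(rnorm(25, 0, 0.3)))
    b <- as_traj(rep(0, 25), 2, phi = cumsum(rnorm(25, 0, 0.3)))
    list(a, b)
  })
  rs <- angle_correlation(pairs)
  expect_length(rs, 200)
  expect_lt(abs(mean(rs)), 0.1)

  # insufficient overlap yields no estimate
  t4 <- as_traj(rep(0, 20), 4, phi = rnorm(20))
  t4$frame <- t4$frame + 18
  expect_length(angle_correlation(list(list(t1, t4))), 0)
})

test_that("bimodal histogram fits recover the generating parameters", {
  set.seed(51)
  mu0 <- 220; sg0 <- 130
  x <- c(rnorm(5e4, mu0, sg0), rnorm(5e4, -mu0, sg0))
  h <- hist(x, breaks = seq(-900, 900, by = 40), plot = FALSE)
  fit <- bimodal_fit(h$mids, h$counts)
  expect_lt(abs(fit$mu - mu0) / mu0, 0.03)
  expect_lt(abs(fit$sigma - sg0) / sg0, 0.03)
  expect_false(fit$unimodal)

  # amplitude scales linearly with the sample count
  h2 <- h; h2$counts <- h$counts * 3
  fit3 <- bimodal_fit(h2$mids, h2$counts)
  expect_equal(fit3$amplitude / fit$amplitude, 3, tolerance = 0.01)

  # a central unimodal distribution collapses to mu ~ 0
  xc <- rnorm(5e4, 0, 150)
  hc <- hist(xc, breaks = seq(-900, 900, by = 40), plot = FALSE)
  fitc <- bimodal_fit(hc$mids, hc$counts)
  expect_true(fitc$unimodal)

  expect_error(bimodal_fit(1:5, rep(1, 5)), "7 bins")
})

test_that("trajectory CSV round-trips", {
  trajs <- lapply(1:3, function(i) as_traj(rnorm(8), i))
  f <- tempfile(fileext = ".csv")
  write_trajectories(trajs, f)
  back <- read_trajectories(f)
  expect_length(back, 3)
  expect_equal(back[[2]]$l_nm, trajs[[2]]$l_nm, tolerance = 1e-12)
})
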