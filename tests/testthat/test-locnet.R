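test_that("count loss matches the Gaussian NLL oracle", {
  p <- matrix(0.5, 10, 10)
  # mu = 50, var = 25: oracle from dnorm
  expect_equal(loss_count(p, 50), -log(dnorm(50, 50, 5)), tolerance = 1e-5)
  # minimum over E at E = mu
  expect_lt(loss_count(p, 50), loss_count(p, 49))
  expect_lt(loss_count(p, 50), loss_count(p, 51))
  # strictly increasing in |E - mu|
  expect_lt(loss_count(p, 52), loss_count(p, 55))
})

test_that("cross-entropy loss has its closed-form values", {
  K <- 12
  p_hat <- matrix(0.5, K, K)
  expect_equal(loss_ce(p_hat, matrix(0, K, K)), K^2 * log(2),
               tolerance = 1e-12)
  tgt <- matrix(0, K, K); tgt[3, 7] <- 1
  expect_equal(loss_ce(p_hat, tgt), K^2 * log(2), tolerance = 1e-12)
  # perfect prediction: loss -> 0
  expect_lt(loss_ce(tgt, tgt), 1e-4)
  set.seed(1)
  expect_gte(loss_ce(matrix(runif(K^2), K), matrix(rbinom(K^2, 1, 0.1), K)), 0)
})

test_that("localization loss equals the Gaussian mode value when exact", {
  K <- 8
  truth <- data.frame(x_nm = 345, y_nm = 412, z_nm = -137, photons = 1800)
  p <- matrix(1e-7, K, K); p[4, 4] <- 1 - 1e-7
  mu <- list(x = matrix(truth$x_nm, K, K), y = matrix(truth$y_nm, K, K),
             z = matrix(truth$z_nm, K, K), I = matrix(truth$photons, K, K))
  s <- c(50, 60, 110, 250)
  sg <- list(x = matrix(s[1], K, K), y = matrix(s[2], K, K),
             z = matrix(s[3], K, K), I = matrix(s[4], K, K))
  expect_equal(loss_loc(p, mu, sg, truth), 0.5 * sum(log(2 * pi * s^2)),
               tolerance = 1e-5)
  # moving the mean away increases the loss monotonically
  l0 <- loss_loc(p, mu, sg, truth)
  mu2 <- mu; mu2$x <- mu$x + 40
  mu3 <- mu; mu3$x <- mu$x + 90
  expect_lt(l0, loss_loc(p, mu2, sg, truth))
  expect_lt(loss_loc(p, mu2, sg, truth), loss_loc(p, mu3, sg, truth))
  # zero-probability pixels do not contribute
  expect_equal(loss_loc(p, mu, sg, truth),
               loss_loc(p[1:4, , drop = FALSE],
                        lapply(mu, function(m) m[1:4, , drop = FALSE]),
                        lapply(sg, function(m) m[1:4, , drop = FALSE]),
                        truth),
               tolerance = 1e-6)
  # no emitters: defined as zero
  expect_equal(loss_loc(p, mu, sg, truth[0, ]), 0)
})

test_that("PSF image loss is a sum of squares", {
  a <- matrix(rnorm(36), 6)
  expect_equal(loss_psf(a, a), 0)
  b <- a; b[2, 5] <- a[2, 5] + 3
  expect_equal(loss_psf(b, a), 9, tolerance = 1e-12)
  # additive over disjoint regions
  c1 <- a; c1[1, 1] <- a[1, 1] + 1
  c2 <- a; c2[6, 6] <- a[6, 6] + 2
  c12 <- a; c12[1, 1] <- a[1, 1] + 1; c12[6, 6] <- a[6, 6] + 2
  expect_equal(loss_psf(c12, a), loss_psf(c1, a) + loss_psf(c2, a),
               tolerance = 1e-12)
})

test_that("total loss is the stated weighted sum and linear in each part", {
  w <- c(0.2, 0.25, 1, 8000)
  expect_equal(total_loss(c(1, 1, 1, 1)), sum(w))
  expect_equal(total_loss(c(0, 0, 0, 0)), 0)
  expect_equal(total_loss(c(2, 0, 0, 0)), 2 * total_loss(c(1, 0, 0, 0)))
  expect_equal(total_loss(c(0, 0, 0, 3)), 3 * total_loss(c(0, 0, 0, 1)))
})

test_that("all loss gradients match central finite differences", {
  set.seed(42)
  K <- 5
  p <- matrix(runif(K^2, 0.05, 0.95), K)
  rel_err <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-12)
  fd_grad <- function(f, m, h = 1e-6) {
    g <- m * 0
    for (i in seq_along(m)) {
      e <- m; e[i] <- e[i] + h; f2 <- f(e)
      e[i] <- e[i] - 2 * h; f1 <- f(e)
      g[i] <- (f2 - f1) / (2 * h)
    }
    g
  }
  expect_lt(rel_err(lociloc3d:::loss_count_grad(p, 3)$dp,
                    fd_grad(function(q) loss_count(q, 3), p)), 1e-4)
  tgt <- matrix(0, K, K); tgt[2, 4] <- 1
  expect_lt(rel_err(lociloc3d:::loss_ce_grad(p, tgt)$dp,
                    fd_grad(function(q) loss_ce(q, tgt), p)), 1e-4)

  px <- 100
  mu <- list(x = matrix(runif(K^2, 0, K * px), K),
             y = matrix(runif(K^2, 0, K * px), K),
             z = matrix(runif(K^2, -500, 300), K),
             I = matrix(runif(K^2, 800, 2800), K))
  sg <- list(x = matrix(runif(K^2, 30, 200), K),
             y = matrix(runif(K^2, 30, 200), K),
             z = matrix(runif(K^2, 50, 400), K),
             I = matrix(runif(K^2, 150, 900), K))
  truth <- data.frame(x_nm = c(150, 420), y_nm = c(300, 90),
                      z_nm = c(-120, 80), photons = c(1200, 2100))
  g <- lociloc3d:::loss_loc_grad(p, mu, sg, truth)
  expect_lt(rel_err(g$dp, fd_grad(function(q) loss_loc(q, mu, sg, truth), p)),
            1e-4)
  for (ax in c("x", "y", "z", "I")) {
    h <- if (ax == "I") 1e-3 else 1e-4
    expect_lt(rel_err(g$dmu[[ax]],
                      fd_grad(function(m) {
                        mm <- mu; mm[[ax]] <- m; loss_loc(p, mm, sg, truth)
                      }, mu[[ax]], h = h * max(abs(mu[[ax]])))), 1e-4)
    expect_lt(rel_err(g$dsigma[[ax]],
                      fd_grad(function(m) {
                        ss <- sg; ss[[ax]] <- m; loss_loc(p, mu, ss, truth)
                      }, sg[[ax]], h = h * max(abs(sg[[ax]])))), 1e-4)
  }
  a <- matrix(rnorm(K^2), K)
  b <- matrix(rnorm(K^2), K)
  expect_lt(rel_err(lociloc3d:::loss_psf_grad(a, b)$dI,
                    fd_grad(function(m) loss_psf(m, b), a)), 1e-4)
})

test_that("network output respects the channel contracts", {
  cfg <- locnet_config(tile = 8, base = 4, depth = 1, n_stages = 2, seed = 2)
  model <- build_network(cfg)
  set.seed(3)
  t1 <- matrix(abs(rnorm(64, 5, 2)), 8)
  t2 <- matrix(abs(rnorm(64, 5, 2)), 8)
  o1 <- locnet_predict(model, t1, fov = 64)
  o2 <- locnet_predict(model, t2, fov = 64)
  expect_length(o1, 10)
  expect_true(all(vapply(o1, function(m) all(dim(m) == c(8, 8)), logical(1))))
  expect_true(all(o1$p > 0 & o1$p < 1))
  expect_true(all(abs(o1$dx) <= 0.5 & abs(o1$dy) <= 0.5))
  expect_true(all(o1$z >= -1 & o1$z <= 1))
  expect_true(all(o1$I > 0 & o1$I < 1))
  expect_true(all(o1$sx > 0 & o1$sy > 0 & o1$sz > 0 & o1$sI > 0))
  # different inputs give different outputs
  expect_gt(max(abs(o1$p - o2$p)), 0)
  # tile must be divisible by 2^depth
  expect_error(locnet_config(tile = 18, depth = 2), "divisible")
})

test_that("backpropagation through the network matches finite differences", {
  cfg <- locnet_config(tile = 8, base = 3, depth = 1, n_stages = 2, seed = 3)
  model <- build_network(cfg)
  set.seed(9)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  wts <- array(rnorm(8 * 8 * 10 * 2), c(8, 8, 10, 2))
  f <- function(m) sum(lociloc3d:::net_fwd(m, x)$raw * wts)
  g <- lociloc3d:::net_bwd(model, lociloc3d:::net_fwd(model, x)$cache, wts)
  for (nm in names(model$params)) {
    p0 <- model$params[[nm]]
    idx <- sample(length(p0), min(3, length(p0)))
    for (i in idx) {
      m2 <- model
      m2$params[[nm]][i] <- p0[i] + 1e-5
      f2 <- f(m2)
      m2$params[[nm]][i] <- p0[i] - 1e-5
      f1 <- f(m2)
      fd <- (f2 - f1) / 2e-5
      expect_lt(abs(fd - g[[nm]][i]), 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("the learning-rate schedule reduces by 90% every 5000 iterations", {
  cfg <- locnet_config()
  lr_at <- function(it)
    cfg$lr_initial * cfg$lr_decay_factor^(floor((it - 1) / cfg$lr_decay_every))
  expect_equal(lr_at(1), 6e-4)
  expect_equal(lr_at(5000), 6e-4)
  expect_equal(lr_at(5001), 6e-5)
  expect_equal(lr_at(10001), 6e-6)
})

test_that("short training descends and is seed-reproducible", {
  cfg <- locnet_config(tile = 16, base = 4, depth = 1, n_stages = 1,
                       batch_size = 2, seed = 7)
  setup <- ref_setup(cfg)
  model <- build_network(cfg)
  m1 <- train(model, setup$simulator, iterations = 300)
  h <- m1$history
  first <- mean(total_loss(colMeans(h[1:30, 3:6]), cfg$loss_weights))
  last <- mean(total_loss(colMeans(h[271:300, 3:6]), cfg$loss_weights))
  expect_lt(last, first)
  # identical seeds give identical loss curves
  m2 <- train(build_network(cfg), setup$simulator, iterations = 25)
  m3 <- train(build_network(cfg), setup$simulator, iterations = 25)
  expect_equal(m2$history$loc, m3$history$loc, tolerance = 1e-12)
})

test_that("model persistence round-trips", {
  cfg <- locnet_config(tile = 8, base = 3, depth = 1, n_stages = 1, seed = 4)
  model <- build_network(cfg)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  m2 <- load_model(path)
  set.seed(1)
  tile <- matrix(abs(rnorm(64, 5)), 8)
  expect_identical(locnet_predict(m2, tile), locnet_predict(model, tile))
})
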