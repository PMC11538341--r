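#' Training losses
#'
#' The compound training loss is a weighted sum of four parts: a Gaussian
#' approximation to the emitter-count likelihood, a pixel-wise binary
#' cross-entropy on the detection map, a probability-weighted 4D Gaussian
#' mixture likelihood of the true emitter parameters (x, y, z, photons)
#' under the predicted per-pixel means and uncertainties, and a squared
#' error between the predicted and true background-free emitter images.
#' Default weights are (0.2, 0.25, 1, 8000).
#'
#' @name locnet_loss
NULL

#' Emitter-count loss
#'
#' Negative Gaussian log-likelihood of the true emitter count `E` under the
#' Gaussian approximation of the predicted Bernoulli field: mean
#' \eqn{\mu = \sum_k \hat p_k}, variance \eqn{\sigma^2 = \sum_k \hat p_k (1
#' - \hat p_k)} (plus a small floor so the likelihood stays defined when
#' all probabilities saturate).
#'
#' @param p_hat predicted probability map, values in (0, 1)
#' @param E true emitter count
#' @param var_floor variance floor
#' @return scalar loss (can be negative, as any continuous NLL)
#' @export
loss_count <- function(p_hat, E, var_floor = 1e-6) {
  loss_count_grad(p_hat, E, var_floor)$value
}

loss_count_grad <- function(p_hat, E, var_floor = 1e-6) {
  mu <- sum(p_hat)
  v <- sum(p_hat * (1 - p_hat)) + var_floor
  value <- 0.5 * log(2 * pi * v) + (E - mu)^2 / (2 * v)
  gp <- (0.5 / v - (E - mu)^2 / (2 * v^2)) * (1 - 2 * p_hat) + (mu - E) / v
  list(value = value, dp = gp)
}

#' Pixel-wise binary cross-entropy
#'
#' @param p_hat predicted probability map
#' @param p binary ground-truth map (1 at emitter pixels)
#' @param clamp probabilities are clamped to `[clamp, 1 - clamp]`
#' @return scalar loss (>= 0)
#' @export
loss_ce <- function(p_hat, p, clamp = 1e-7) {
  loss_ce_grad(p_hat, p, clamp)$value
}

loss_ce_grad <- function(p_hat, p, clamp = 1e-7) {
  q <- pmin(pmax(p_hat, clamp), 1 - clamp)
  value <- -sum(p * log(q) + (1 - p) * log(1 - q))
  dq <- -p / q + (1 - p) / (1 - q)
  dq[p_hat < clamp | p_hat > 1 - clamp] <- 0
  list(value = value, dp = dq)
}

#' Localization (4D Gaussian mixture) loss
#'
#' For each true emitter \eqn{u_e = (x_e, y_e, z_e, I_e)} the network's
#' per-pixel predictions define a diagonal 4D Gaussian \eqn{N(u; \mu_k,
#' \Sigma_k)} with \eqn{\mu_k} = pixel center + predicted offsets (nm),
#' predicted depth (nm) and photons, weighted by the normalized detection
#' probability \eqn{\hat p_k / \sum_j \hat p_j}.  The loss is the mean over
#' emitters of the negative log mixture density, evaluated in log space.
#' With no emitters the contribution is zero.
#'
#' @param p_hat probability map
#' @param mu list of maps `x`, `y`, `z`, `I` (means, physical units: nm and
#'   photons)
#' @param sigma list of maps `x`, `y`, `z`, `I` (standard deviations, > 0)
#' @param truth data.frame with columns x_nm, y_nm, z_nm, photons
#' @return scalar loss
#' @export
loss_loc <- function(p_hat, mu, sigma, truth) {
  loss_loc_grad(p_hat, mu, sigma, truth)$value
}

loss_loc_grad <- function(p_hat, mu, sigma, truth) {
  E <- nrow(truth)
  zero <- lapply(list(x = 0, y = 0, z = 0, I = 0), function(.) p_hat * 0)
  if (E == 0)
    return(list(value = 0, dp = p_hat * 0, dmu = zero, dsigma = zero))
  P <- sum(p_hat)
  logq <- log(p_hat) - log(P)
  ax <- c("x", "y", "z", "I")
  u <- rbind(truth$x_nm, truth$y_nm, truth$z_nm, truth$photons)
  # log density terms common over emitters
  logdet <- 0.5 * Reduce(`+`, lapply(sigma, function(s) log(2 * pi * s^2)))
  W <- p_hat * 0          # sum over emitters of responsibilities
  Wd <- lapply(zero, identity)  # per-axis accumulators for dmu
  Ws <- lapply(zero, identity)  # per-axis accumulators for dsigma
  value <- 0
  for (e in seq_len(E)) {
    quad <- p_hat * 0
    for (i in 1:4)
      quad <- quad + (u[i, e] - mu[[ax[i]]])^2 / sigma[[ax[i]]]^2
    a <- logq - logdet - 0.5 * quad
    amax <- max(a)
    lse <- amax + log(sum(exp(a - amax)))
    value <- value - lse / E
    w <- exp(a - lse)
    W <- W + w
    for (i in 1:4) {
      s <- sigma[[ax[i]]]
      d <- u[i, e] - mu[[ax[i]]]
      Wd[[ax[i]]] <- Wd[[ax[i]]] + w * d / s^2
      Ws[[ax[i]]] <- Ws[[ax[i]]] + w * (d^2 / s^3 - 1 / s)
    }
  }
  dp <- 1 / P - W / (E * p_hat)
  dmu <- lapply(Wd, function(g) -g / E)
  dsigma <- lapply(Ws, function(g) -g / E)
  list(value = value, dp = dp, dmu = dmu, dsigma = dsigma)
}

#' Background-free PSF image loss
#'
#' Sum of squared differences between the predicted and the true noise-free
#' emitter image (both on the same intensity scale).
#'
#' @param I_hat predicted emitter image
#' @param I true noise-free emitter image
#' @return scalar loss (>= 0)
#' @export
loss_psf <- function(I_hat, I) sum((I_hat - I)^2)

loss_psf_grad <- function(I_hat, I) {
  list(value = sum((I_hat - I)^2), dI = 2 * (I_hat - I))
}

#' Weighted total loss
#'
#' @param parts numeric vector or list of the four components (count, ce,
#'   loc, mol)
#' @param weights loss weights, default c(0.2, 0.25, 1, 8000)
#' @return scalar weighted sum
#' @export
total_loss <- function(parts, weights = c(0.2, 0.25, 1, 8000)) {
  sum(unlist(parts) * weights)
}
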