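#' Structured cell-background model
#'
#' In-cell fluorescence background (e.g. from unbound fluorescent fusion
#' protein) is heterogeneous and varies with the distance to the cell
#' boundary.  This module models the background in the photon domain as a
#' family of gamma distributions conditioned on the integer Euclidean
#' distance transform (EDT) of the cell mask, plus a separate distribution
#' for outside-cell ("chip") pixels, and samples synthetic backgrounds
#' from the fitted model.
#'
#' @name background_model
NULL

#' Integer Euclidean distance transform
#'
#' Per-pixel Euclidean distance (in pixels) to the nearest outside-cell
#' (label 0) pixel, rounded to the nearest integer.  Outside-cell pixels
#' get 0; boundary cell pixels get 1.
#'
#' @param labels integer label matrix (0 = outside)
#' @return integer matrix of the same shape
#' @export
compute_edt <- function(labels) {
  if (length(labels) == 0) stop("empty label image")
  if (all(labels == 0)) return(matrix(0L, nrow(labels), ncol(labels)))
  d <- EBImage::distmap(labels > 0, metric = "euclidean")
  matrix(as.integer(round(d)), nrow(labels))
}

# Gamma MLE with method-of-moments initialization (Newton on the shape
# equation log k - digamma(k) = log(mean) - mean(log x)).
gamma_mle <- function(x) {
  m <- mean(x); v <- var(x)
  k <- m^2 / v  # moment start
  s <- log(m) - mean(log(x))
  for (i in 1:50) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    knew <- k - f / fp
    if (!is.finite(knew) || knew <= 0) knew <- k / 2
    if (abs(knew - k) < 1e-10 * k) { k <- knew; break }
    k <- knew
  }
  list(shape = k, scale = m / k)
}

# Gamma MLE with right-censored observations: the locus-exclusion rule
# drops the brightest pixels, which would bias a naive fit; the dropped
# pixels are instead entered as censored at the per-cell cutoff, making
# parameter recovery consistent.
gamma_mle_censored <- function(x, cens = numeric(0)) {
  start <- gamma_mle(x)
  if (length(cens) == 0) return(start)
  nll <- function(par) {
    k <- exp(par[1]); th <- exp(par[2])
    -(sum(dgamma(x, shape = k, scale = th, log = TRUE)) +
        sum(pgamma(cens, shape = k, scale = th, lower.tail = FALSE,
                   log.p = TRUE)))
  }
  opt <- optim(log(c(start$shape, start$scale)), nll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  list(shape = exp(opt$par[1]), scale = exp(opt$par[2]))
}

#' Fit the boundary-distance-conditioned background model
#'
#' For each cell the brightest 25% of its pixels (ceil(0.25 n) per cell per
#' frame) are discarded to avoid contamination by the locus signal.  The
#' remaining pixels are pooled across cells and frames by their integer EDT
#' value and a gamma distribution is fitted per shell by maximum likelihood
#' (moment-matching start).  Shells with fewer than `min_pixels_per_shell`
#' pixels are merged into the nearest deeper shell (or the nearest
#' shallower one for the deepest shell).  Outside-cell pixels are fitted as
#' the chip distribution.
#'
#' @param frames list of fluorescence images in photons (use [to_photons()]
#'   on raw gray-level frames first)
#' @param masks list of [cell_mask_set()] objects aligned with `frames`
#'   (recycled if length 1)
#' @param min_pixels_per_shell minimum pixels required to fit a shell
#' @return a `background_model`: list with `shells` (per-distance
#'   `list(shape, scale, degenerate, mean)`), `chip`, and bookkeeping
#' @export
fit_background <- function(frames, masks, min_pixels_per_shell = 200) {
  if (length(masks) == 1) masks <- rep(masks, length(frames))
  stopifnot(length(frames) == length(masks))
  shell_pix <- list()
  shell_cens <- list()
  chip_pix <- numeric(0)
  n_cells <- 0
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    ms <- masks[[i]]
    if (!identical(dim(fr), dim(ms$labels)))
      stop(sprintf("frame %d and mask %d have different shapes", i, i))
    edt <- compute_edt(ms$labels)
    chip_pix <- c(chip_pix, fr[ms$labels == 0])
    for (k in ms$cell_ids) {
      sel <- ms$labels == k
      vals <- fr[sel]
      n_cells <- n_cells + 1
      keep_n <- length(vals) - ceiling(0.25 * length(vals))
      ord <- order(vals)
      keep_idx <- ord[seq_len(keep_n)]
      drop_idx <- ord[-seq_len(keep_n)]
      cutoff <- vals[ord[keep_n]]
      dshell <- edt[sel]
      for (d in unique(dshell)) {
        key <- as.character(d)
        shell_pix[[key]] <- c(shell_pix[[key]],
                              vals[keep_idx][dshell[keep_idx] == d])
        ncd <- sum(dshell[drop_idx] == d)
        if (ncd > 0)
          shell_cens[[key]] <- c(shell_cens[[key]], rep(cutoff, ncd))
      }
    }
  }
  if (n_cells == 0) stop("no cells in the mask set")
  ds <- sort(as.integer(names(shell_pix)))
  # merge small shells into the nearest deeper shell
  groups <- list()
  pending <- numeric(0); pending_cens <- numeric(0)
  pending_ds <- integer(0)
  for (d in ds) {
    pending <- c(pending, shell_pix[[as.character(d)]])
    pending_cens <- c(pending_cens, shell_cens[[as.character(d)]])
    pending_ds <- c(pending_ds, d)
    if (length(pending) >= min_pixels_per_shell) {
      groups[[length(groups) + 1]] <- list(ds = pending_ds, pix = pending,
                                           cens = pending_cens)
      pending <- numeric(0); pending_cens <- numeric(0)
      pending_ds <- integer(0)
    }
  }
  if (length(pending) > 0) {
    if (length(groups) == 0) {
      groups[[1]] <- list(ds = pending_ds, pix = pending, cens = pending_cens)
    } else {
      g <- groups[[length(groups)]]
      groups[[length(groups)]] <- list(ds = c(g$ds, pending_ds),
                                       pix = c(g$pix, pending),
                                       cens = c(g$cens, pending_cens))
    }
  }
  fit_one <- function(x, cens = numeric(0)) {
    if (length(x) < 2 || var(x) == 0 || sum(x > 0) < 2) {
      warning("degenerate background shell fitted as a point mass")
      return(list(shape = NA_real_, scale = NA_real_, degenerate = TRUE,
                  mean = mean(x)))
    }
    keep <- x > 0
    fit <- gamma_mle_censored(x[keep], cens)
    list(shape = fit$shape, scale = fit$scale, degenerate = FALSE,
         mean = fit$shape * fit$scale)
  }
  shells <- list()
  for (g in groups) {
    fit <- fit_one(g$pix, g$cens)
    fit$n_pixels <- length(g$pix)
    fit$group <- min(g$ds)  # shells merged into one fit share this id
    for (d in g$ds) shells[[as.character(d)]] <- fit
  }
  chip <- fit_one(chip_pix)
  structure(list(shells = shells, chip = chip,
                 max_d = max(ds),
                 min_pixels_per_shell = min_pixels_per_shell),
            class = "background_model")
}

#' Sample a synthetic background image from the model
#'
#' Each pixel is drawn independently from the gamma distribution of its
#' integer EDT shell (deepest fitted shell reused beyond the fitted range)
#' or from the chip distribution outside cells.
#'
#' @param model a `background_model` from [fit_background()]
#' @param labels integer label matrix defining the cell geometry
#' @param seed optional RNG seed
#' @param edt optional precomputed [compute_edt()] map (saves recomputation
#'   in tight simulation loops)
#' @return background image in photons/pixel
#' @export
sample_background <- function(model, labels, seed = NULL, edt = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(edt)) edt <- compute_edt(labels)
  out <- matrix(0, nrow(labels), ncol(labels))
  draw <- function(fit, n) {
    if (isTRUE(fit$degenerate)) rep(fit$mean, n)
    else rgamma(n, shape = fit$shape, scale = fit$scale)
  }
  chip_sel <- labels == 0
  out[chip_sel] <- draw(model$chip, sum(chip_sel))
  dvals <- unique(edt[!chip_sel])
  for (d in dvals) {
    key <- as.character(min(d, model$max_d))
    fit <- model$shells[[key]]
    if (is.null(fit)) fit <- model$shells[[as.character(model$max_d)]]
    sel <- edt == d & !chip_sel
    out[sel] <- draw(fit, sum(sel))
  }
  out
}

#' Save / load a background model as JSON
#'
#' @param model a `background_model`
#' @param path JSON file path
#' @return `path` (save) or the model (load)
#' @export
save_background <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_background
#' @export
load_background <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$shells <- lapply(m$shells, as.list)
  m$chip <- as.list(m$chip)
  structure(m, class = "background_model")
}
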