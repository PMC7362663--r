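#' Diffusion tensor scalar metrics from eigenvalue maps
#'
#' Computes the six scalar summaries of the diffusion tensor used throughout
#' the pipeline from its sorted eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge
#' \lambda_3 \ge 0}:
#' \describe{
#'   \item{MD}{mean diffusivity \eqn{(\lambda_1+\lambda_2+\lambda_3)/3}}
#'   \item{AD}{axial diffusivity \eqn{\lambda_1}}
#'   \item{RD}{radial diffusivity \eqn{(\lambda_2+\lambda_3)/2}}
#'   \item{q}{pure anisotropy, the deviatoric magnitude
#'     \eqn{\sqrt{\sum_i (\lambda_i - MD)^2}}}
#'   \item{L}{total diffusion magnitude \eqn{\sqrt{\sum_i \lambda_i^2}}}
#'   \item{FA}{fractional anisotropy \eqn{\sqrt{3/2}\, q / L}, in `[0, 1]`}
#' }
#' Voxels outside the brain mask are set to `NA`. An all-zero tensor
#' (\eqn{L = 0}) gets FA defined as 0 and is counted in `qc$n_zero_tensor`.
#'
#' @param eigen list with 3-D arrays `lam1`, `lam2`, `lam3` (diffusivity,
#'   mm^2/s, dims `rows x cols x slices`) and a logical array `brain_mask`
#'   of the same dimensions. Eigenvalues are re-sorted descending on ingest.
#' @return Object of class `metric_maps`: list of the six metric arrays,
#'   plus `brain_mask` and a `qc` list.
#' @export
compute_dti_metrics <- function(eigen) {
  stopifnot(all(c("lam1", "lam2", "lam3", "brain_mask") %in% names(eigen)))
  dm <- dim(eigen$lam1)
  mask <- eigen$brain_mask
  stopifnot(identical(dim(eigen$lam2), dm), identical(dim(eigen$lam3), dm),
            identical(dim(mask), dm))
  lam <- cbind(as.vector(eigen$lam1), as.vector(eigen$lam2),
               as.vector(eigen$lam3))
  if (any(lam[as.vector(mask), ] < 0, na.rm = TRUE))
    stop("negative eigenvalues inside brain mask")
  # enforce lambda1 >= lambda2 >= lambda3 regardless of input order
  srt <- t(apply(lam, 1L, sort, decreasing = TRUE))
  unsorted <- any(srt != lam, na.rm = TRUE)
  lam <- srt

  md <- rowMeans(lam)
  ad <- lam[, 1L]
  rd <- (lam[, 2L] + lam[, 3L]) / 2
  q <- sqrt((lam[, 1L] - md)^2 + (lam[, 2L] - md)^2 + (lam[, 3L] - md)^2)
  L <- sqrt(lam[, 1L]^2 + lam[, 2L]^2 + lam[, 3L]^2)
  fa <- numeric(length(L))
  pos <- L > 0
  fa[pos] <- sqrt(1.5) * q[pos] / L[pos]
  n_zero <- sum(!pos & as.vector(mask))

  shape <- function(v) {
    v[!as.vector(mask)] <- NA_real_
    array(v, dm)
  }
  structure(list(
    MD = shape(md), AD = shape(ad), RD = shape(rd),
    FA = shape(fa), q = shape(q), L = shape(L),
    brain_mask = mask,
    qc = list(n_zero_tensor = n_zero, resorted = unsorted)
  ), class = "metric_maps")
}

#' Mask-aware Gaussian smoothing of a map stack
#'
#' Within-slice 2-D convolution with a normalized Gaussian kernel. Kernel
#' weights falling on out-of-mask voxels are dropped and the remaining
#' weights renormalized, so masked-out neighbours contribute nothing (the
#' "weighted mean intensity" form of smoothing). Out-of-mask voxels stay
#' `NA`.
#'
#' @param map 3-D numeric array (`rows x cols x slices`) or 2-D matrix.
#' @param mask logical array of the same shape; `NULL` means all-in.
#' @param sigma_vox kernel standard deviation in voxels (> 0). The kernel is
#'   truncated at `truncate * sigma_vox`.
#' @param truncate truncation radius in sigmas (default 2).
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(map, mask = NULL, sigma_vox = 1, truncate = 2) {
  if (!is.numeric(sigma_vox) || length(sigma_vox) != 1L || sigma_vox <= 0)
    stop("sigma_vox must be a single positive number")
  two_d <- length(dim(map)) == 2L || is.null(dim(map))
  if (two_d) map <- array(map, c(dim(as.matrix(map)), 1L))
  dm <- dim(map)
  if (is.null(mask)) mask <- array(TRUE, dm)
  if (two_d && length(dim(mask)) == 2L) mask <- array(mask, dm)
  stopifnot(identical(dim(mask), dm))
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  off <- -r:r
  k <- exp(-off^2 / (2 * sigma_vox^2))
  kern <- outer(k, k)
  kern <- kern / sum(kern)

  out <- array(NA_real_, dm)
  nr <- dm[1L]; nc <- dm[2L]
  for (s in seq_len(dm[3L])) {
    sl <- map[, , s]
    msl <- mask[, , s]
    sl[!msl] <- 0
    num <- matrix(0, nr, nc)
    den <- matrix(0, nr, nc)
    w <- msl * 1
    for (i in seq_along(off)) {
      valid_r <- seq_len(nr) + off[i] >= 1L & seq_len(nr) + off[i] <= nr
      for (j in seq_along(off)) {
        cj <- seq_len(nc) + off[j]
        valid_c <- cj >= 1L & cj <= nc
        if (!any(valid_r) || !any(valid_c)) next
        kw <- kern[i, j]
        rs <- which(valid_r); cs <- which(valid_c)
        num[rs, cs] <- num[rs, cs] + kw * sl[rs + off[i], cs + off[j]]
        den[rs, cs] <- den[rs, cs] + kw * w[rs + off[i], cs + off[j]]
      }
    }
    res <- matrix(NA_real_, nr, nc)
    ok <- msl & den > 0
    res[ok] <- num[ok] / den[ok]
    out[, , s] <- res
  }
  if (two_d) out <- out[, , 1L]
  out
}

#' Linear rescaling of a map to [0, 1]
#'
#' `(x - min) / (max - min)` over in-mask voxels, the normalization used to
#' put maps from different animals on a common display scale. The original
#' bounds are kept for provenance.
#'
#' @param map numeric array.
#' @param mask logical array, same shape (`NULL` = all finite voxels).
#' @return list with the rescaled `map` (out-of-mask voxels `NA`) and
#'   `bounds = c(min, max)`.
#' @export
normalize01 <- function(map, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(map) else mask <- mask & !is.na(map)
  v <- map[mask]
  if (length(v) < 2L) stop("normalize01: fewer than two in-mask voxels")
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("normalize01: map is constant over the mask")
  out <- array(NA_real_, dim(map) %||% length(map))
  out[mask] <- (map[mask] - lo) / (hi - lo)
  list(map = out, bounds = c(min = lo, max = hi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Smooth and normalize every metric in a metric_maps object
#'
#' Convenience wrapper applying [gaussian_smooth()] (if `sigma_vox > 0`) and
#' [normalize01()] to each of the six DTI metrics. With `sigma_vox = 0` the
#' raw maps are passed through unsmoothed.
#'
#' @param metrics a `metric_maps` object.
#' @param sigma_vox smoothing SD in voxels; 0 disables smoothing.
#' @return `metric_maps` with elements `smoothed` (list of 6 arrays) and
#'   `normalized` (list of 6 arrays) and `normalization_bounds` added.
#' @export
process_metric_maps <- function(metrics, sigma_vox = 1) {
  stopifnot(inherits(metrics, "metric_maps"))
  mask <- metrics$brain_mask
  nms <- c("MD", "AD", "RD", "FA", "q", "L")
  sm <- lapply(nms, function(n) {
    if (sigma_vox > 0) gaussian_smooth(metrics[[n]], mask, sigma_vox)
    else metrics[[n]]
  })
  names(sm) <- nms
  nrm <- lapply(sm, function(m) normalize01(m, mask))
  metrics$smoothed <- sm
  metrics$normalized <- lapply(nrm, `[[`, "map")
  metrics$normalization_bounds <- lapply(nrm, `[[`, "bounds")
  metrics
}
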