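METRIC_NAMES <- c("rMD", "rAD", "rRD", "rFA", "rL", "rq")

#' Feature extraction configuration
#'
#' @param coronal_window odd in-plane window width for histogram features
#'   (default 7, i.e. 7x7 = 49 samples).
#' @param axial_window odd window width in the reconstructed axial plane
#'   (default 3).
#' @param n_bins histogram bins (default 11).
#' @param bin_range value range of the bins on the relative metrics
#'   (default `c(-1, 1)`; relative reductions are bounded below by -1).
#'   Values outside are clipped into the end bins.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(coronal_window = 7L, axial_window = 3L,
                           n_bins = 11L, bin_range = c(-1, 1)) {
  stopifnot(coronal_window %% 2L == 1L, axial_window %% 2L == 1L,
            n_bins >= 2L, bin_range[2L] > bin_range[1L])
  structure(list(coronal_window = as.integer(coronal_window),
                 axial_window = as.integer(axial_window),
                 n_bins = as.integer(n_bins), bin_range = bin_range),
            class = "feature_config")
}

#' Names of the 110 feature columns, by block
#'
#' The fixed column schema of the feature matrix: 18 relative-DTI features
#' (6 metrics at the voxel's slice, the slice below, the slice above), 90
#' windowed-histogram features (per metric: 11 normalized coronal bin
#' counts + coronal skewness/kurtosis + axial skewness/kurtosis), and 2
#' Mahalanobis distances to the infarct-core feature distribution (6-dim
#' same-slice and 18-dim variants).
#'
#' @param cfg a [feature_config()].
#' @return list with character vectors `dti` (18), `hist` (90),
#'   `mahal` (2) and `all` (110).
#' @export
feature_columns <- function(cfg = feature_config()) {
  dti <- c(paste0("dti_", METRIC_NAMES, "_s0"),
           paste0("dti_", METRIC_NAMES, "_sm1"),
           paste0("dti_", METRIC_NAMES, "_sp1"))
  hist <- unlist(lapply(METRIC_NAMES, function(m) {
    c(sprintf("hist_%s_cor_bin%02d", m, seq_len(cfg$n_bins)),
      paste0("hist_", m, "_cor_skew"), paste0("hist_", m, "_cor_kurt"),
      paste0("hist_", m, "_ax_skew"), paste0("hist_", m, "_ax_kurt"))
  }))
  mahal <- c("mahal_d6", "mahal_d18")
  list(dti = dti, hist = hist, mahal = mahal, all = c(dti, hist, mahal))
}

#' Relative DTI metric maps against the contralateral homologue
#'
#' For each smoothed metric map X, computes the voxel-wise relative change
#' `rX = (X - X_mirror) / X_mirror` where the mirror value is the
#' homologous voxel obtained by reflecting the column index about the
#' midline. Voxels whose mirror value is not positive (or out of mask) get
#' 0 with a QC count; a perfectly symmetric map yields all-zero rX.
#'
#' @param metric_list named list of the six metric arrays (`MD`, `AD`,
#'   `RD`, `FA`, `q`, `L`), typically the `smoothed` element of
#'   [process_metric_maps()].
#' @param mask brain mask array.
#' @param eps positive lower bound on the mirror value (default 1e-12).
#' @return list with arrays `rMD`, `rAD`, `rRD`, `rFA`, `rL`, `rq`
#'   (0 outside mask) and `qc_zero_mirror` count.
#' @export
relative_metric_maps <- function(metric_list, mask, eps = 1e-12) {
  src <- c(rMD = "MD", rAD = "AD", rRD = "RD", rFA = "FA", rL = "L", rq = "q")
  qc <- 0L
  out <- lapply(src, function(nm) {
    x <- metric_list[[nm]]
    mir <- x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
    r <- array(0, dim(x))
    ok <- mask & !is.na(x) & !is.na(mir) & mir > eps
    qc <<- qc + sum(mask & !is.na(x) & (is.na(mir) | mir <= eps))
    r[ok] <- (x[ok] - mir[ok]) / mir[ok]
    r
  })
  names(out) <- names(src)
  out$qc_zero_mirror <- qc
  out
}

# Gather rel[[m]] values over a window of (dim_a, dim_b) offsets around each
# voxel with clamped (edge-replicated) indices. plane = "coronal" windows
# over (row, col) at fixed slice; "axial" windows over (slice, col) at
# fixed row (the axial projection reconstructed from the coronal stack).
window_values <- function(arr, r, c, s, half_a, half_b, plane) {
  dm <- dim(arr)
  offs_a <- -half_a:half_a
  offs_b <- -half_b:half_b
  n <- length(r)
  m <- matrix(0, n, length(offs_a) * length(offs_b))
  k <- 0L
  for (da in offs_a) for (db in offs_b) {
    k <- k + 1L
    if (plane == "coronal") {
      m[, k] <- arr[cbind(clamp_idx(r + da, 1L, dm[1L]),
                          clamp_idx(c + db, 1L, dm[2L]), s)]
    } else {
      m[, k] <- arr[cbind(r, clamp_idx(c + db, 1L, dm[2L]),
                          clamp_idx(s + da, 1L, dm[3L]))]
    }
  }
  m
}

normalized_hist_counts <- function(vals, cfg) {
  lo <- cfg$bin_range[1L]; hi <- cfg$bin_range[2L]; nb <- cfg$n_bins
  v <- pmin(pmax(vals, lo), hi)
  bi <- pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb)
  n <- nrow(vals)
  cnt <- matrix(0, n, nb)
  for (b in seq_len(nb)) cnt[, b] <- rowSums(bi == b)
  cnt / ncol(vals)
}

#' Per-voxel feature matrix for one animal
#'
#' Builds the 110-column feature rows for every ipsilateral, in-mask,
#' non-ventricle voxel of one rat: the 18 relative-DTI features (own slice,
#' slice below, slice above, with nearest-slice replication at the stack
#' edges), the 90 histogram features (7x7 coronal window: 11 normalized bin
#' counts + skewness + kurtosis; 3x3 axial window: skewness + kurtosis; per
#' metric), and the 2 Mahalanobis columns filled with a sentinel 0 (they
#' are populated against a trained core distribution at classification
#' time). Windows are centered with edge replication; zero-variance windows
#' get skewness = kurtosis = 0.
#'
#' @param rel output of [relative_metric_maps()].
#' @param labels a `label_map` supplying the supervision labels.
#' @param mask,ventricle_mask geometry arrays.
#' @param side ipsilateral hemisphere.
#' @param rat_id identifier stored with each row.
#' @param cfg a [feature_config()].
#' @return data.frame: `rat_id`, `slice`, `row`, `col`, `label`
#'   (IC/IP/NT), then the 110 feature columns in [feature_columns()] order.
#' @export
rat_feature_matrix <- function(rel, labels, mask, ventricle_mask, side,
                               rat_id, cfg = feature_config()) {
  dm <- dim(mask)
  elig <- array(FALSE, dm)
  elig[, hemisphere_cols(dm[2L], side), ] <- TRUE
  elig <- elig & mask & !ventricle_mask
  idx <- which(elig, arr.ind = TRUE)
  r <- idx[, 1L]; cc <- idx[, 2L]; s <- idx[, 3L]
  n <- nrow(idx)
  cols <- feature_columns(cfg)
  X <- matrix(0, n, length(cols$all), dimnames = list(NULL, cols$all))

  ns <- dm[3L]
  for (m in seq_along(METRIC_NAMES)) {
    a <- rel[[METRIC_NAMES[m]]]
    X[, cols$dti[m]] <- a[cbind(r, cc, s)]
    X[, cols$dti[m + 6L]] <- a[cbind(r, cc, clamp_idx(s - 1L, 1L, ns))]
    X[, cols$dti[m + 12L]] <- a[cbind(r, cc, clamp_idx(s + 1L, 1L, ns))]

    hc <- (cfg$coronal_window - 1L) %/% 2L
    w_cor <- window_values(a, r, cc, s, hc, hc, "coronal")
    cnt <- normalized_hist_counts(w_cor, cfg)
    mo <- row_moments(w_cor)
    base <- (m - 1L) * (cfg$n_bins + 4L)
    X[, cols$hist[base + seq_len(cfg$n_bins)]] <- cnt
    X[, cols$hist[base + cfg$n_bins + 1L]] <- mo$skewness
    X[, cols$hist[base + cfg$n_bins + 2L]] <- mo$kurtosis

    ha <- (cfg$axial_window - 1L) %/% 2L
    w_ax <- window_values(a, r, cc, s, ha, ha, "axial")
    mo_ax <- row_moments(w_ax)
    X[, cols$hist[base + cfg$n_bins + 3L]] <- mo_ax$skewness
    X[, cols$hist[base + cfg$n_bins + 4L]] <- mo_ax$kurtosis
  }
  lab_code <- labels$label[cbind(r, cc, s)]
  lab <- names(LBL)[match(lab_code, LBL)]
  if (any(!is.finite(X))) stop("non-finite feature values emitted")
  data.frame(rat_id = rat_id, slice = s, row = r, col = cc, label = lab,
             X, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Fit the infarct-core feature distribution
#'
#' Sample mean and covariance of the core voxels' relative-DTI feature
#' vectors, with a ridge term (`1e-6` times the mean covariance diagonal)
#' added so the covariance is positive-definite even for degenerate clouds.
#' Both the 6-dim same-slice variant and the 18-dim full-block variant are
#' fitted; they are frozen into the trained model so test animals are
#' scored against the training distribution only.
#'
#' @param dti_block numeric matrix of the 18 relative-DTI feature columns,
#'   IC rows only.
#' @param ridge_factor ridge scale relative to the mean diagonal.
#' @return list of class `ic_distribution` with elements `d6` and `d18`,
#'   each `list(mean, cov)`.
#' @export
fit_ic_distribution <- function(dti_block, ridge_factor = 1e-6) {
  stopifnot(ncol(dti_block) == 18L)
  fit_one <- function(X) {
    if (nrow(X) < ncol(X) + 1L)
      stop("too few IC voxels (", nrow(X), ") to fit a ", ncol(X),
           "-dim core distribution; enlarge the training set")
    S <- stats::cov(X)
    ridge <- max(ridge_factor * mean(diag(S)), .Machine$double.eps)
    list(mean = colMeans(X), cov = S + diag(ridge, ncol(X)))
  }
  structure(list(d6 = fit_one(dti_block[, 1:6, drop = FALSE]),
                 d18 = fit_one(dti_block)),
            class = "ic_distribution")
}

#' Mahalanobis distances to the core distribution
#'
#' \eqn{d(x) = \sqrt{(x-\mu)^T \Sigma^{-1} (x-\mu)}} of each row against
#' the fitted core distribution, in the 6-dim same-slice space and the
#' 18-dim full space.
#'
#' @param dti_block matrix of 18 relative-DTI feature columns.
#' @param dist an [fit_ic_distribution()] result.
#' @return matrix with columns `mahal_d6`, `mahal_d18`.
#' @export
mahalanobis_block <- function(dti_block, dist) {
  stopifnot(inherits(dist, "ic_distribution"), ncol(dti_block) == 18L)
  d6 <- sqrt(stats::mahalanobis(dti_block[, 1:6, drop = FALSE],
                                dist$d6$mean, dist$d6$cov))
  d18 <- sqrt(stats::mahalanobis(dti_block, dist$d18$mean, dist$d18$cov))
  cbind(mahal_d6 = d6, mahal_d18 = d18)
}

#' Feature matrix for a whole cohort
#'
#' Convenience wrapper running [relative_metric_maps()] and
#' [rat_feature_matrix()] over per-rat processed maps and stacking the
#' rows. The Mahalanobis columns hold the level-1 sentinel 0; they are
#' recomputed against the frozen training core distribution inside
#' [train_two_level()] / [predict_two_level()].
#'
#' @param rats list of per-rat lists, each with `smoothed` (list of six
#'   metric arrays), `labels` (`label_map`), `brain_mask`,
#'   `ventricle_mask`, `side`, `rat_id`.
#' @param cfg a [feature_config()].
#' @return stacked data.frame, one row per eligible voxel.
#' @export
assemble_feature_matrix <- function(rats, cfg = feature_config()) {
  do.call(rbind, lapply(rats, function(rt) {
    rel <- relative_metric_maps(rt$smoothed, rt$brain_mask)
    rat_feature_matrix(rel, rt$labels, rt$brain_mask, rt$ventricle_mask,
                       rt$side, rt$rat_id, cfg)
  }))
}
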