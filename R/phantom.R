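#' Specification of a synthetic rat stroke cohort
#'
#' Defines the study conditions the phantom generator emulates: a cohort of
#' rats with one lesioned hemisphere containing an ellipsoidal infarct core
#' (IC, ~40% diffusivity reduction), a thin penumbral rim (IP, ~10%
#' reduction) and graded CBF deficits, imaged as multi-slice coronal
#' eigenvalue maps and a 300-point DSC signal series (TR 1 s, TE 20 ms).
#'
#' The CBF drop fractions must be realizable under the 46% viability
#' threshold used for labeling: `ic_cbf_drop > ip_cbf_drop > 0.46` and
#' `nt_cbf_drop < 0.46`.
#'
#' @param n_rats number of animals (default 14).
#' @param n_slices coronal slices per animal (default 5).
#' @param grid `(rows, cols)` voxel counts; columns must be even (default
#'   `c(128, 128)`, the zero-filled acquisition matrix).
#' @param voxel_size_mm in-plane voxel size (default 0.16).
#' @param slice_thickness_mm through-plane size (default 1).
#' @param ic_diffusivity_drop fractional eigenvalue reduction in the core
#'   (default 0.40).
#' @param ip_diffusivity_drop fractional reduction in the rim (default 0.10).
#' @param ic_cbf_drop,ip_cbf_drop,nt_cbf_drop fractional CBF reduction of
#'   core / rim / ipsilateral normal tissue vs the contralateral side
#'   (defaults 0.80, 0.60, 0.10).
#' @param noise_sd_eigen additive Gaussian SD on each eigenvalue, mm^2/s
#'   (default 9e-6, i.e. 1% of normal-tissue MD).
#' @param noise_sd_signal additive Gaussian SD on the DSC signal, in units
#'   of the baseline plateau 100 (default 1).
#' @param gamma_params named vector `(K, alpha, beta, t0)` of the underlying
#'   bolus concentration model (defaults `K = 0.3`, `alpha = 3`, `beta = 4`
#'   s, `t0 = 30` s — injection ~30 s after acquisition start).
#' @param n_timepoints DSC repetitions (default 300); `tr_s`, `te_s` as
#'   acquired.
#' @param rim_thickness_range in-plane IP rim thickness range in voxels,
#'   sampled per rat (default `c(1, 3)`).
#' @param kspace_zerofill if `TRUE`, eigenvalue maps are generated at half
#'   resolution and zero-filled in the spatial-frequency domain to the full
#'   grid, emulating the acquisition's interpolation (default `FALSE`; the
#'   zero-filling affects smoothness only).
#' @param seed integer seed; all generator output is a pure function of the
#'   spec including this seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_rats = 14L, n_slices = 5L, grid = c(128L, 128L),
                         voxel_size_mm = 0.16, slice_thickness_mm = 1,
                         ic_diffusivity_drop = 0.40,
                         ip_diffusivity_drop = 0.10,
                         ic_cbf_drop = 0.80, ip_cbf_drop = 0.60,
                         nt_cbf_drop = 0.10,
                         noise_sd_eigen = 9e-6, noise_sd_signal = 1,
                         gamma_params = c(K = 0.3, alpha = 3, beta = 4, t0 = 30),
                         n_timepoints = 300L, tr_s = 1.0, te_s = 0.020,
                         rim_thickness_range = c(1, 3),
                         kspace_zerofill = FALSE, seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  drops <- c(ic_diffusivity_drop = spec$ic_diffusivity_drop,
             ip_diffusivity_drop = spec$ip_diffusivity_drop,
             ic_cbf_drop = spec$ic_cbf_drop, ip_cbf_drop = spec$ip_cbf_drop,
             nt_cbf_drop = spec$nt_cbf_drop)
  bad <- names(drops)[drops < 0 | drops >= 1]
  if (length(bad))
    stop("phantom_spec: drop fraction out of [0,1): ", paste(bad, collapse = ", "))
  if (!(spec$ic_cbf_drop > spec$ip_cbf_drop && spec$ip_cbf_drop > spec$nt_cbf_drop))
    stop("phantom_spec: need ic_cbf_drop > ip_cbf_drop > nt_cbf_drop")
  if (spec$ip_cbf_drop <= 0.46)
    stop("phantom_spec: ip_cbf_drop must exceed 0.46 so the rim is a true perfusion deficit")
  if (spec$nt_cbf_drop >= 0.46)
    stop("phantom_spec: nt_cbf_drop must be below 0.46 so normal tissue is not a deficit")
  if (spec$grid[2L] %% 2L != 0L)
    stop("phantom_spec: grid columns must be even (midline between hemispheres)")
  if (spec$n_rats < 1L || spec$n_slices < 1L) stop("phantom_spec: empty cohort")
  invisible(spec)
}

# Symmetric elliptical brain mask plus two small periventricular regions,
# identical across slices; symmetric about the midline by construction so
# mirror-based relative metrics vanish in healthy tissue.
phantom_geometry <- function(spec) {
  nr <- spec$grid[1L]; nc <- spec$grid[2L]; ns <- spec$n_slices
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  ar <- 0.40 * nr; ac <- 0.42 * nc
  r <- matrix(seq_len(nr), nr, nc)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  brain2d <- ((r - rc) / ar)^2 + ((cl - cc) / ac)^2 <= 1
  vrad <- max(1.5, 0.035 * nc)
  voff <- 0.15 * nc
  vent2d <- (((r - rc) / vrad)^2 + ((cl - (cc - voff)) / vrad)^2 <= 1) |
            (((r - rc) / vrad)^2 + ((cl - (cc + voff)) / vrad)^2 <= 1)
  vent2d <- vent2d & brain2d
  list(brain = array(brain2d, c(nr, nc, ns)),
       vent = array(vent2d, c(nr, nc, ns)))
}

# Per-rat random lesion: 3-D ellipsoid core with an in-plane rim, placed in
# one hemisphere, clipped to brain and away from ventricles/midline.
sample_lesion <- function(spec, geom) {
  nr <- spec$grid[1L]; nc <- spec$grid[2L]; ns <- spec$n_slices
  mid <- (nc + 1) / 2
  side <- sample(c("left", "right"), 1L)
  thick <- if (diff(range(spec$rim_thickness_range)) == 0)
    spec$rim_thickness_range[1L] else
    sample(seq(spec$rim_thickness_range[1L], spec$rim_thickness_range[2L]), 1L)
  ar <- stats::runif(1, 0.10, 0.17) * nr
  ac <- stats::runif(1, 0.09, 0.14) * nc
  rc <- stats::runif(1, 0.40, 0.60) * nr
  # keep the outer rim off the midline and inside the lateral brain edge
  sgn <- if (side == "right") 1 else -1
  inner <- ac + thick + 2
  outer <- 0.40 * nc
  cc <- mid + sgn * stats::runif(1, min(inner, outer - 1), outer)
  sc <- stats::runif(1, 1.2, ns - 0.2)
  as_ <- stats::runif(1, 1.3, max(1.31, 0.7 * ns))

  r <- array(rep(seq_len(nr), nc * ns), c(nr, nc, ns))
  cl <- array(rep(rep(seq_len(nc), each = nr), ns), c(nr, nc, ns))
  sl <- array(rep(seq_len(ns), each = nr * nc), c(nr, nc, ns))
  d_ic <- ((r - rc) / ar)^2 + ((cl - cc) / ac)^2 + ((sl - sc) / as_)^2
  d_ip <- ((r - rc) / (ar + thick))^2 + ((cl - cc) / (ac + thick))^2 +
    ((sl - sc) / as_)^2
  hemi <- array(FALSE, c(nr, nc, ns))
  hemi[, hemisphere_cols(nc, side), ] <- TRUE
  ok <- geom$brain & !geom$vent & hemi
  ic <- d_ic <= 1 & ok
  ip <- d_ip <= 1 & !ic & ok
  list(side = side, ic = ic, ip = ip, thickness = thick)
}

# NT eigenvalue field: baseline (1.2, 0.9, 0.6)e-3 mm^2/s with a smooth,
# midline-symmetric white-matter anisotropy modulation that keeps MD
# constant (lambda2 fixed, lambda1/lambda3 traded against each other).
baseline_eigen <- function(spec) {
  nr <- spec$grid[1L]; nc <- spec$grid[2L]; ns <- spec$n_slices
  mid <- (nc + 1) / 2
  r <- matrix(seq_len(nr), nr, nc)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  w <- 0.5 * (1 + sin(6 * r / nr) * cos(5 * abs(cl - mid) / nc))
  delta <- (w - 0.5) * 0.2e-3
  l1 <- array(1.2e-3 + delta, c(nr, nc, ns))
  l2 <- array(0.9e-3, c(nr, nc, ns))
  l3 <- array(0.6e-3 - delta, c(nr, nc, ns))
  list(l1 = l1, l2 = l2, l3 = l3)
}

# Zero-fill interpolation: downsample a slice in k-space to half resolution
# and pad back, reproducing the sinc-like smoothness of the acquisition.
kspace_zerofill_slice <- function(sl) {
  nr <- nrow(sl); nc <- ncol(sl)
  f <- stats::fft(sl)
  fs <- f
  keep_r <- c(seq_len(nr / 4), (nr - nr / 4 + 1):nr)
  keep_c <- c(seq_len(nc / 4), (nc - nc / 4 + 1):nc)
  fs[-keep_r, ] <- 0
  fs[, -keep_c] <- 0
  Re(stats::fft(fs, inverse = TRUE)) / (nr * nc)
}

#' Generate a seeded synthetic cohort
#'
#' Produces `spec$n_rats` independent rat phantoms: eigenvalue maps with
#' lesion-scaled diffusivity, a DSC signal series with CBF-scaled bolus
#' passage, geometric ground-truth labels, and brain/ventricle masks.
#' Lesion side, position and size vary across rats under the seeded RNG;
#' the contralateral hemisphere is always lesion-free. The ground-truth
#' label geometry is iterated to a fixed point of the contiguity-correction
#' rule so that it is stable under the labeling stage's cleanup pass.
#'
#' @param spec a [phantom_spec()].
#' @return list of `rat_phantom` objects, each with `rat_id`, `eigen`
#'   (lam1/lam2/lam3 + brain_mask), `dsc` (signal 4-D array, tr_s, te_s,
#'   baseline_window), `truth_labels` (a `label_map`), `ventricle_mask`,
#'   `side`, `cbf_drop` (the per-voxel drop field used), and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  lapply(seq_len(spec$n_rats), function(i) generate_rat(spec, i))
}

generate_rat <- function(spec, rat_idx) {
  geom <- phantom_geometry(spec)
  les <- sample_lesion(spec, geom)
  dm <- c(spec$grid, spec$n_slices)

  factor <- array(1, dm)
  factor[les$ic] <- 1 - spec$ic_diffusivity_drop
  factor[les$ip] <- 1 - spec$ip_diffusivity_drop
  factor[geom$vent] <- 2.5
  base <- baseline_eigen(spec)
  l1 <- base$l1 * factor; l2 <- base$l2 * factor; l3 <- base$l3 * factor
  if (isTRUE(spec$kspace_zerofill)) {
    for (s in seq_len(dm[3L])) {
      l1[, , s] <- kspace_zerofill_slice(l1[, , s])
      l2[, , s] <- kspace_zerofill_slice(l2[, , s])
      l3[, , s] <- kspace_zerofill_slice(l3[, , s])
    }
  }
  if (spec$noise_sd_eigen > 0) {
    n <- prod(dm)
    l1 <- l1 + stats::rnorm(n, 0, spec$noise_sd_eigen)
    l2 <- l2 + stats::rnorm(n, 0, spec$noise_sd_eigen)
    l3 <- l3 + stats::rnorm(n, 0, spec$noise_sd_eigen)
  }
  lam <- pmax(cbind(as.vector(l1), as.vector(l2), as.vector(l3)), 0)
  lam <- t(apply(lam, 1L, sort, decreasing = TRUE))
  eigen <- list(lam1 = array(lam[, 1L], dm), lam2 = array(lam[, 2L], dm),
                lam3 = array(lam[, 3L], dm), brain_mask = geom$brain)

  cbf_drop <- array(0, dm)
  hemi <- array(FALSE, dm)
  hemi[, hemisphere_cols(dm[2L], les$side), ] <- TRUE
  cbf_drop[hemi & geom$brain] <- spec$nt_cbf_drop
  cbf_drop[les$ip] <- spec$ip_cbf_drop
  cbf_drop[les$ic] <- spec$ic_cbf_drop
  dsc <- make_dsc_series(spec, cbf_drop, geom$brain)

  lab <- array(LBL[["EXCLUDED"]], dm)
  elig <- hemi & geom$brain & !geom$vent
  lab[elig] <- LBL[["NT"]]
  lab[les$ip] <- LBL[["IP"]]
  lab[les$ic] <- LBL[["IC"]]
  truth <- structure(list(label = lab, side = les$side, qc = list()),
                     class = "label_map")
  truth <- contiguity_correction(truth, labeling_config(), passes = Inf)

  structure(list(rat_id = sprintf("rat%02d", rat_idx), eigen = eigen,
                 dsc = dsc, truth_labels = truth,
                 ventricle_mask = geom$vent, brain_mask = geom$brain,
                 side = les$side, cbf_drop = cbf_drop, spec = spec),
            class = "rat_phantom")
}

#' Simulate a DSC-MRI signal series from a CBF deficit field
#'
#' Forward model matched to the perfusion module's inversion: each in-brain
#' voxel carries a gamma-variate concentration curve
#' \eqn{C(t) = (1 - drop) K (t-t_0)^\alpha e^{-(t-t_0)/\beta}} whose
#' amplitude is scaled by the local CBF fraction, converted to signal as
#' \eqn{S(t) = S_0 e^{-TE\,C(t)}} around a baseline plateau of 100, plus
#' seeded Gaussian noise. Out-of-brain voxels get a weak flat signal with
#' no bolus.
#'
#' @param spec a [phantom_spec()] (uses `gamma_params`, `n_timepoints`,
#'   `tr_s`, `te_s`, `noise_sd_signal`).
#' @param cbf_drop_map per-voxel drop fraction in `[0, 1)`.
#' @param brain_mask logical array; defaults to all voxels in-brain.
#' @return list: 4-D `signal` array, `tr_s`, `te_s`, `baseline_window`.
#' @export
make_dsc_series <- function(spec, cbf_drop_map, brain_mask = NULL) {
  if (any(cbf_drop_map < 0 | cbf_drop_map >= 1))
    stop("cbf_drop_map values must lie in [0, 1)")
  dm <- dim(cbf_drop_map)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dm)
  gp <- spec$gamma_params
  t <- (seq_len(spec$n_timepoints) - 1) * spec$tr_s
  curve <- gamma_variate(t, gp[["K"]], gp[["alpha"]], gp[["beta"]], gp[["t0"]])
  s0 <- 100
  nvox <- prod(dm)
  amp <- as.vector(1 - cbf_drop_map)
  amp[!as.vector(brain_mask)] <- 0
  sig <- s0 * exp(-spec$te_s * outer(amp, curve))
  sig[!as.vector(brain_mask), ] <- s0 / 10
  if (spec$noise_sd_signal > 0)
    sig <- sig + stats::rnorm(length(sig), 0, spec$noise_sd_signal)
  bw_end <- max(5L, floor((gp[["t0"]] - 5) / spec$tr_s))
  list(signal = array(sig, c(dm, spec$n_timepoints)),
       tr_s = spec$tr_s, te_s = spec$te_s,
       baseline_window = seq_len(bw_end))
}
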