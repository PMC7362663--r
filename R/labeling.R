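#' Labeling configuration
#'
#' Thresholds and contiguity settings for perfusion-diffusion-mismatch
#' labeling. The infarct core is defined by a 30% mean-diffusivity reduction
#' against the contralateral hemisphere and the perfusion deficit by a 46%
#' CBF reduction, the viability threshold for rodent cortex.
#'
#' @param md_reduction_threshold fraction of contralateral-hemisphere mean
#'   MD below which a voxel is core (default 0.30).
#' @param cbf_reduction_threshold fraction of contralateral-hemisphere mean
#'   rCBF below which a voxel is hypoperfused (default 0.46).
#' @param contiguity_min_neighbors minimum count (of 8 in-slice neighbours)
#'   of a single different class that triggers reassignment (default 6).
#' @param contiguity_passes number of correction sweeps (default 1).
#' @return list of class `labeling_config`.
#' @export
labeling_config <- function(md_reduction_threshold = 0.30,
                            cbf_reduction_threshold = 0.46,
                            contiguity_min_neighbors = 6L,
                            contiguity_passes = 1L) {
  stopifnot(md_reduction_threshold > 0, md_reduction_threshold < 1,
            cbf_reduction_threshold > 0, cbf_reduction_threshold < 1,
            contiguity_min_neighbors >= 1, contiguity_min_neighbors <= 8)
  structure(list(md_reduction_threshold = md_reduction_threshold,
                 cbf_reduction_threshold = cbf_reduction_threshold,
                 contiguity_min_neighbors = as.integer(contiguity_min_neighbors),
                 contiguity_passes = as.integer(contiguity_passes)),
            class = "labeling_config")
}

# Integer label codes used in label arrays and NIfTI export.
LBL <- c(EXCLUDED = 0L, IC = 1L, IP = 2L, NT = 3L)

#' Contralateral reference values for a map
#'
#' Two distinct references are used downstream: the scalar in-mask mean of
#' the contralateral hemisphere (for reduction thresholds, which the
#' labeling rules state against "the contralateral hemisphere") and the
#' per-voxel mirror value obtained by reflecting the column index about the
#' midline (for relative metrics against "homologous tissue").
#'
#' @param map numeric 3-D array (`rows x cols x slices`).
#' @param mask logical array of in-brain voxels.
#' @param side ipsilateral (lesioned) side, `"left"` or `"right"`.
#' @return list: `mean` (contralateral in-mask mean) and `mirror` (array of
#'   per-voxel mirror values).
#' @export
contralateral_reference <- function(map, mask, side) {
  dm <- dim(map)
  side <- match.arg(side, c("left", "right"))
  contra <- setdiff(c("left", "right"), side)
  ccols <- hemisphere_cols(dm[2L], contra)
  cm <- mask[, ccols, , drop = FALSE]
  if (!any(cm)) stop("empty contralateral mask")
  cmean <- mean(map[, ccols, , drop = FALSE][cm], na.rm = TRUE)
  mirror <- map[, rev(seq_len(dm[2L])), , drop = FALSE]
  list(mean = cmean, mirror = mirror)
}

#' Infarct-core candidate mask from mean diffusivity
#'
#' A voxel is core iff it is ipsilateral, in-mask, not ventricle, and its MD
#' lies strictly below `(1 - threshold)` times the contralateral-hemisphere
#' mean MD. Ventricles (free water, high MD) are excluded explicitly.
#'
#' @param md MD array (smoothed or raw, consistent with the rCBF map used).
#' @param mask brain mask.
#' @param ventricle_mask logical array of ventricle voxels.
#' @param side ipsilateral side.
#' @param cfg a [labeling_config()].
#' @return logical array of IC candidates.
#' @export
threshold_ic <- function(md, mask, ventricle_mask, side, cfg = labeling_config()) {
  ref <- contralateral_reference(md, mask & !ventricle_mask, side)
  thr <- (1 - cfg$md_reduction_threshold) * ref$mean
  ipsi <- array(FALSE, dim(md))
  ipsi[, hemisphere_cols(dim(md)[2L], side), ] <- TRUE
  out <- ipsi & mask & !ventricle_mask & !is.na(md) & md < thr
  out[is.na(out)] <- FALSE
  out
}

#' Perfusion-deficit mask from relative CBF
#'
#' Deficit iff ipsilateral, in-mask, and rCBF strictly below
#' `(1 - threshold)` times the contralateral-hemisphere mean rCBF.
#'
#' @inheritParams threshold_ic
#' @param rcbf rCBF array.
#' @return logical array of hypoperfused voxels.
#' @export
threshold_perfusion <- function(rcbf, mask, side, cfg = labeling_config()) {
  ref <- contralateral_reference(rcbf, mask & !is.na(rcbf), side)
  thr <- (1 - cfg$cbf_reduction_threshold) * ref$mean
  ipsi <- array(FALSE, dim(rcbf))
  ipsi[, hemisphere_cols(dim(rcbf)[2L], side), ] <- TRUE
  out <- ipsi & mask & !is.na(rcbf) & rcbf < thr
  out[is.na(out)] <- FALSE
  out
}

#' Perfusion-diffusion-mismatch label map
#'
#' Combines the diffusion lesion and the perfusion deficit: IC is the MD
#' lesion; IP is the mismatch (deficit but not IC); NT is the remaining
#' ipsilateral tissue without CBF deficit. IC voxels outside the deficit are
#' retained as IC (the diffusion lesion takes precedence) and counted in
#' `qc$n_ic_outside_deficit`. A contiguity correction pass then removes
#' isolated mislabeled voxels. Everything else (background, ventricles,
#' contralateral hemisphere) is EXCLUDED.
#'
#' @param ic_mask,deficit_mask logical arrays from [threshold_ic()] and
#'   [threshold_perfusion()].
#' @param mask brain mask; @param ventricle_mask ventricle voxels.
#' @param side ipsilateral side; @param cfg a [labeling_config()].
#' @return list of class `label_map`: integer array `label` (0 EXCLUDED,
#'   1 IC, 2 IP, 3 NT), `side`, and `qc`.
#' @export
derive_pdm_labels <- function(ic_mask, deficit_mask, mask, ventricle_mask,
                              side, cfg = labeling_config()) {
  stopifnot(identical(dim(ic_mask), dim(deficit_mask)))
  dm <- dim(ic_mask)
  ipsi <- array(FALSE, dm)
  ipsi[, hemisphere_cols(dm[2L], side), ] <- TRUE
  eligible <- ipsi & mask & !ventricle_mask
  lab <- array(LBL[["EXCLUDED"]], dm)
  lab[eligible] <- LBL[["NT"]]
  lab[eligible & deficit_mask] <- LBL[["IP"]]
  lab[eligible & ic_mask] <- LBL[["IC"]]
  n_out <- sum(eligible & ic_mask & !deficit_mask)
  out <- structure(list(label = lab, side = side,
                        qc = list(n_ic_outside_deficit = n_out)),
                   class = "label_map")
  contiguity_correction(out, cfg)
}

neighbor_class_counts <- function(lab_slice, code) {
  nr <- nrow(lab_slice); nc <- ncol(lab_slice)
  cnt <- matrix(0L, nr, nc)
  is_code <- (lab_slice == code) * 1L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    vr <- rs >= 1L & rs <= nr; vc <- cs >= 1L & cs <= nc
    cnt[vr, vc] <- cnt[vr, vc] + is_code[rs[vr], cs[vc]]
  }
  cnt
}

#' Contiguity correction of a label map
#'
#' Any labeled (IC/IP/NT) voxel whose within-slice 8-neighbourhood contains
#' at least `contiguity_min_neighbors` voxels of one *different* labeled
#' class is reassigned to that class. EXCLUDED voxels are never reassigned
#' and never counted as neighbours. All reassignments within a pass are
#' computed from the pre-pass map, then applied simultaneously.
#'
#' @param labels a `label_map`.
#' @param cfg a [labeling_config()]; `contiguity_passes` sweeps are run.
#' @param passes override for the number of sweeps (`Inf` = to fixed point).
#' @return corrected `label_map` with `qc$n_reassigned` added.
#' @export
contiguity_correction <- function(labels, cfg = labeling_config(),
                                  passes = cfg$contiguity_passes) {
  lab <- labels$label
  dm <- dim(lab)
  total <- 0L
  p <- 0
  repeat {
    if (p >= passes) break
    p <- p + 1
    changed <- 0L
    new <- lab
    for (s in seq_len(dm[3L])) {
      sl <- lab[, , s]
      cnts <- lapply(c(IC = LBL[["IC"]], IP = LBL[["IP"]], NT = LBL[["NT"]]),
                     function(cd) neighbor_class_counts(sl, cd))
      for (cd in c(LBL[["IC"]], LBL[["IP"]], LBL[["NT"]])) {
        here <- sl == cd
        if (!any(here)) next
        for (other in setdiff(c(LBL[["IC"]], LBL[["IP"]], LBL[["NT"]]), cd)) {
          oc <- cnts[[which(c(LBL[["IC"]], LBL[["IP"]], LBL[["NT"]]) == other)]]
          hit <- here & oc >= cfg$contiguity_min_neighbors
          if (any(hit)) {
            tmp <- new[, , s]
            tmp[hit] <- other
            new[, , s] <- tmp
            changed <- changed + sum(hit)
          }
        }
      }
    }
    total <- total + changed
    lab <- new
    if (changed == 0L) break
  }
  labels$label <- lab
  labels$qc$n_reassigned <- total
  labels
}
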