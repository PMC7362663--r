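#' Write a rat phantom to NIfTI volumes
#'
#' Exchange format for per-rat data: eigenvalue maps as one 4-D volume
#' (4th dim = eigenvalue index), the DSC series as a 4-D time series,
#' masks and truth labels as 3-D integer volumes, and a JSON sidecar with
#' the generating spec. Voxel sizes are carried in the NIfTI headers.
#'
#' @param rat a `rat_phantom`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_phantom_nifti <- function(rat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- rat$spec
  pix <- c(sp$voxel_size_mm, sp$voxel_size_mm, sp$slice_thickness_mm)
  dm <- dim(rat$brain_mask)
  eig <- array(c(rat$eigen$lam1, rat$eigen$lam2, rat$eigen$lam3), c(dm, 3L))
  paths <- c(
    eigen = file.path(dir, paste0(rat$rat_id, "_eigen.nii.gz")),
    dsc = file.path(dir, paste0(rat$rat_id, "_dsc.nii.gz")),
    brain_mask = file.path(dir, paste0(rat$rat_id, "_brainmask.nii.gz")),
    ventricle_mask = file.path(dir, paste0(rat$rat_id, "_ventmask.nii.gz")),
    truth = file.path(dir, paste0(rat$rat_id, "_truth.nii.gz")),
    sidecar = file.path(dir, paste0(rat$rat_id, "_spec.json")))
  as_img <- function(x) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- pix
    img
  }
  RNifti::writeNifti(as_img(eig), paths[["eigen"]])
  RNifti::writeNifti(as_img(rat$dsc$signal), paths[["dsc"]])
  RNifti::writeNifti(as_img(rat$brain_mask * 1L), paths[["brain_mask"]],
                     datatype = "uint8")
  RNifti::writeNifti(as_img(rat$ventricle_mask * 1L),
                     paths[["ventricle_mask"]], datatype = "uint8")
  RNifti::writeNifti(as_img(rat$truth_labels$label), paths[["truth"]],
                     datatype = "int16")
  side <- list(rat_id = rat$rat_id, side = rat$side,
               spec = sp[setdiff(names(sp), "gamma_params")],
               gamma_params = as.list(sp$gamma_params))
  jsonlite::write_json(side, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a rat phantom back from NIfTI volumes
#'
#' Inverse of [write_phantom_nifti()].
#'
#' @param dir directory holding the files.
#' @param rat_id animal identifier (file prefix).
#' @return a `rat_phantom` equivalent to the one written (truth label QC
#'   metadata is not round-tripped).
#' @export
read_phantom_nifti <- function(dir, rat_id) {
  pth <- function(suf) file.path(dir, paste0(rat_id, suf))
  side <- jsonlite::read_json(pth("_spec.json"), simplifyVector = TRUE)
  spec <- do.call(phantom_spec, c(
    side$spec[setdiff(names(side$spec), c("grid"))],
    list(grid = as.integer(side$spec$grid),
         gamma_params = unlist(side$gamma_params))))
  eig <- RNifti::readNifti(pth("_eigen.nii.gz"))
  dm <- dim(eig)[1:3]
  eig <- array(as.vector(eig), c(dm, 3L))
  brain <- array(RNifti::readNifti(pth("_brainmask.nii.gz")) > 0, dm)
  vent <- array(RNifti::readNifti(pth("_ventmask.nii.gz")) > 0, dm)
  truth <- array(as.integer(RNifti::readNifti(pth("_truth.nii.gz"))), dm)
  sig <- RNifti::readNifti(pth("_dsc.nii.gz"))
  gp <- spec$gamma_params
  bw_end <- max(5L, floor((gp[["t0"]] - 5) / spec$tr_s))
  structure(list(
    rat_id = rat_id,
    eigen = list(lam1 = eig[, , , 1L], lam2 = eig[, , , 2L],
                 lam3 = eig[, , , 3L], brain_mask = brain),
    dsc = list(signal = array(sig, dim(sig)), tr_s = spec$tr_s,
               te_s = spec$te_s, baseline_window = seq_len(bw_end)),
    truth_labels = structure(list(label = truth, side = side$side,
                                  qc = list()), class = "label_map"),
    ventricle_mask = vent, brain_mask = brain, side = side$side,
    spec = spec), class = "rat_phantom")
}

#' Write a label map as an integer NIfTI volume
#'
#' Codes: 0 EXCLUDED, 1 IC, 2 IP, 3 NT.
#'
#' @param labels a `label_map`.
#' @param path output file (`.nii` / `.nii.gz`).
#' @param pixdim voxel sizes (mm).
#' @return invisibly, `path`.
#' @export
write_label_nifti <- function(labels, path, pixdim = c(0.16, 0.16, 1)) {
  img <- RNifti::asNifti(labels$label)
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
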