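#' Leave-one-out folds over animals
#'
#' @param rat_ids character vector of unique subject identifiers.
#' @return list of folds, each `list(test, train)` of rat ids; one fold per
#'   animal, training on all the others.
#' @export
loocv_split <- function(rat_ids) {
  if (anyDuplicated(rat_ids)) stop("duplicate rat ids")
  if (length(rat_ids) < 2L) stop("need at least 2 rats for LOOCV")
  lapply(rat_ids, function(r) list(test = r, train = setdiff(rat_ids, r)))
}

#' Seeded stratified k-fold split of rows
#'
#' Partitions row indices into `k` near-equal folds, stratified by class so
#' per-fold class proportions match the pool within one row. Classes with
#' fewer than `k` members trigger an unstratified fallback with a warning.
#'
#' @param labels class label per row.
#' @param k folds (default 5).
#' @param seed RNG seed for the shuffle.
#' @return integer vector of fold assignments (1..k) per row.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop("fewer rows than folds")
  set.seed(seed)
  fold <- integer(n)
  if (any(table(labels) < k)) {
    warning("class with fewer than k members; falling back to unstratified folds")
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    for (ix in split(seq_len(n), labels))
      fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Binary confusion-matrix summaries
#'
#' @param pred,truth aligned vectors (any type comparable with `==`).
#' @param positive the positive class value.
#' @return list: `accuracy` (fraction), `sensitivity`, `specificity`, and
#'   the 2x2 counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(pred, truth, positive) {
  if (length(pred) == 0L || length(pred) != length(truth))
    stop("pred and truth must be non-empty and aligned")
  pp <- pred == positive; tp_ <- truth == positive
  tp <- sum(pp & tp_); fp <- sum(pp & !tp_)
  fn <- sum(!pp & tp_); tn <- sum(!pp & !tp_)
  list(accuracy = (tp + tn) / length(pred),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve by the rank statistic
#'
#' AUC as the probability that a random positive outscores a random
#' negative, with ties counted one half (the Mann-Whitney form computed
#' from midranks).
#'
#' @param scores numeric scores, larger favouring the positive class.
#' @param truth logical (or coercible) positive-class indicator.
#' @return AUC in `[0, 1]`; `NA` if only one class is present.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-slice volume correspondence between two labelings
#'
#' For each slice of each rat, counts IC/IP/NT voxels under the estimated
#' and reference labelings, converts counts to volumes, and correlates the
#' two volume series per tissue across all slices (Pearson).
#'
#' @param df data.frame with columns `rat_id`, `slice`, `pred`, `ref`
#'   (IC/IP/NT per voxel).
#' @param voxel_volume_mm3 volume of one voxel (in-plane area x slice
#'   thickness).
#' @return list: `table` (rat, slice, tissue, est_mm3, ref_mm3) and `r`
#'   (named Pearson correlations; `NA` where a series is constant).
#' @export
slice_volume_correspondence <- function(df, voxel_volume_mm3) {
  tissues <- c("IC", "IP", "NT")
  key <- interaction(df$rat_id, df$slice, drop = TRUE)
  rows <- lapply(levels(key), function(kk) {
    sub <- df[key == kk, ]
    data.frame(rat_id = sub$rat_id[1L], slice = sub$slice[1L],
               tissue = tissues,
               est_mm3 = sapply(tissues, function(tt) sum(sub$pred == tt)) *
                 voxel_volume_mm3,
               ref_mm3 = sapply(tissues, function(tt) sum(sub$ref == tt)) *
                 voxel_volume_mm3,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  r <- sapply(tissues, function(tt) {
    sub <- tab[tab$tissue == tt, ]
    if (stats::sd(sub$est_mm3) == 0 || stats::sd(sub$ref_mm3) == 0)
      return(NA_real_)
    stats::cor(sub$est_mm3, sub$ref_mm3)
  })
  list(table = tab, r = r)
}

#' Per-rat volume comparison by Mann-Whitney test
#'
#' Two-sided rank-sum test per tissue comparing the per-animal total
#' estimated volumes with the reference volumes (exact null for small
#' samples without ties, normal approximation with tie correction
#' otherwise, as implemented by [stats::wilcox.test()]).
#'
#' @param est,ref data.frames with columns `rat_id`, `IC`, `IP`, `NT`
#'   (total volume per rat).
#' @return named vector of p-values for IC, IP, NT.
#' @export
volume_comparison_test <- function(est, ref) {
  sapply(c("IC", "IP", "NT"), function(tt) {
    x <- est[[tt]]; y <- ref[[tt]]
    if (length(x) < 2L || length(y) < 2L) stop("need >= 2 rats per group")
    suppressWarnings(stats::wilcox.test(x, y, exact = NULL)$p.value)
  })
}

#' Leave-one-out evaluation of the two-level classifier
#'
#' Runs the full validation design over a cohort feature matrix: one fold
#' per animal, training both classifier levels and the core distribution on
#' the remaining animals only (no leakage), predicting every voxel of the
#' held-out animal, and summarizing per-fold and pooled accuracy together
#' with pooled AUCs.
#'
#' Accuracy conventions: `acc_ic` is the binary IC-vs-nonIC voxel accuracy;
#' `acc_ip_nt` is computed over voxels that are non-IC under both truth and
#' prediction; `acc_3class` is the full three-class hemisphere accuracy.
#'
#' @param features cohort feature data.frame (with `label`).
#' @param backend classifier backend.
#' @param seed base seed; fold f uses `seed + f`.
#' @param max_train_voxels training-row cap per fold.
#' @return list of class `loocv_report`: `folds` (per-fold data.frame),
#'   `pooled` (named list), `predictions` (features rows + `pred`, scores,
#'   `fold`), `meta`.
#' @export
evaluate_loocv <- function(features, backend = "svm", seed = 1L,
                           max_train_voxels = 4000L) {
  folds <- loocv_split(unique(features$rat_id))
  preds <- vector("list", length(folds))
  fold_rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fo <- folds[[f]]
    tr <- features[features$rat_id %in% fo$train, , drop = FALSE]
    te <- features[features$rat_id == fo$test, , drop = FALSE]
    model <- train_two_level(tr, backend, seed + f, max_train_voxels)
    stopifnot(!(fo$test %in% model$training_meta$rat_ids))
    p <- predict_two_level(model, te)
    p$fold <- f
    preds[[f]] <- cbind(te[, c("rat_id", "slice", "row", "col", "label")], p)
    cm_ic <- confusion_metrics(p$pred == "IC", te$label == "IC", TRUE)
    both_non <- p$pred != "IC" & te$label != "IC"
    fold_rows[[f]] <- data.frame(
      fold = f, test_rat = fo$test, n_vox = nrow(te),
      acc_ic = cm_ic$accuracy,
      sens_ic = cm_ic$sensitivity, spec_ic = cm_ic$specificity,
      acc_ip_nt = if (any(both_non))
        mean(p$pred[both_non] == te$label[both_non]) else NA_real_,
      acc_3class = mean(p$pred == te$label),
      sens_ip = {
        cm <- confusion_metrics(p$pred, te$label, "IP")
        cm$sensitivity
      },
      stringsAsFactors = FALSE)
  }
  pr <- do.call(rbind, preds)
  fold_df <- do.call(rbind, fold_rows)
  pooled <- list(
    acc_ic = mean((pr$pred == "IC") == (pr$label == "IC")),
    acc_3class = mean(pr$pred == pr$label),
    acc_ip_nt = {
      b <- pr$pred != "IC" & pr$label != "IC"
      mean(pr$pred[b] == pr$label[b])
    },
    sens_ip = confusion_metrics(pr$pred, pr$label, "IP")$sensitivity,
    auc_ic = roc_auc(pr$score_ic, pr$label == "IC"),
    auc_ip = {
      b <- !is.na(pr$score_ip)
      roc_auc(pr$score_ip[b], pr$label[b] == "IP")
    })
  structure(list(folds = fold_df, pooled = pooled, predictions = pr,
                 meta = list(backend = backend, seed = seed,
                             max_train_voxels = max_train_voxels,
                             fold_train = lapply(folds, `[[`, "train"),
                             fold_test = vapply(folds, `[[`, "", "test"))),
            class = "loocv_report")
}

#' Leave-one-out IP sensitivity of the single-level baseline
#'
#' Same fold design as [evaluate_loocv()] for the 18-feature three-class
#' baseline; reports pooled per-class sensitivities and accuracy.
#'
#' @inheritParams evaluate_loocv
#' @return list: `pooled` (accuracy and per-class sensitivities),
#'   `predictions`.
#' @export
evaluate_loocv_single <- function(features, backend = "svm", seed = 1L,
                                  max_train_voxels = 4000L) {
  folds <- loocv_split(unique(features$rat_id))
  preds <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fo <- folds[[f]]
    tr <- features[features$rat_id %in% fo$train, , drop = FALSE]
    te <- features[features$rat_id == fo$test, , drop = FALSE]
    model <- train_single_level(tr, backend, seed + f, max_train_voxels)
    preds[[f]] <- data.frame(
      te[, c("rat_id", "slice", "row", "col", "label")],
      pred = predict_single_level(model, te), fold = f,
      stringsAsFactors = FALSE)
  }
  pr <- do.call(rbind, preds)
  structure(list(
    pooled = list(
      acc_3class = mean(pr$pred == pr$label),
      sens_ic = confusion_metrics(pr$pred, pr$label, "IC")$sensitivity,
      sens_ip = confusion_metrics(pr$pred, pr$label, "IP")$sensitivity,
      sens_nt = confusion_metrics(pr$pred, pr$label, "NT")$sensitivity),
    predictions = pr), class = "single_level_report")
}

#' Per-rat tissue volumes from a voxel table
#'
#' @param df data.frame with `rat_id` and a label column.
#' @param col name of the label column (`"pred"` or `"label"`).
#' @param voxel_volume_mm3 volume per voxel.
#' @return data.frame: `rat_id`, `IC`, `IP`, `NT` total volumes (mm^3).
#' @export
per_rat_volumes <- function(df, col, voxel_volume_mm3) {
  ids <- unique(df$rat_id)
  out <- data.frame(rat_id = ids, stringsAsFactors = FALSE)
  for (tt in c("IC", "IP", "NT"))
    out[[tt]] <- sapply(ids, function(r)
      sum(df$rat_id == r & df[[col]] == tt)) * voxel_volume_mm3
  out
}
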