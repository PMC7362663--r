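# Backend abstraction: each backend exposes fit(x, y, seed) and
# predict(model, x) -> list(class, score) where score is oriented so larger
# means the positive (first factor level) class.
fit_backend <- function(backend, x, y, seed, knn_k = 5L) {
  set.seed(seed)
  y <- factor(y)
  switch(backend,
    svm = {
      gam <- median_heuristic_gamma(x)
      list(backend = "svm",
           fit = e1071::svm(x, y, kernel = "radial", cost = 1, gamma = gam,
                            scale = FALSE))
    },
    knn = list(backend = "knn", train_x = x, train_y = y, k = knn_k),
    tree = {
      df <- data.frame(.y = y, x, check.names = TRUE)
      list(backend = "tree",
           fit = rpart::rpart(.y ~ ., data = df, method = "class"))
    },
    stop("unknown backend: ", backend))
}

predict_backend <- function(model, x) {
  positive <- function(lv) lv[1L]
  switch(model$backend,
    svm = {
      pr <- stats::predict(model$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      pos <- positive(levels(model$fit$fitted))
      # orient decision values so larger favours the positive class
      sgn <- if (startsWith(colnames(dv)[1L], pos)) 1 else -1
      list(class = as.character(pr), score = sgn * dv[, 1L])
    },
    knn = {
      pr <- class::knn(model$train_x, x, model$train_y, k = model$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      pos <- positive(levels(model$train_y))
      score <- ifelse(as.character(pr) == pos, p, 1 - p)
      list(class = as.character(pr), score = score)
    },
    tree = {
      df <- data.frame(x, check.names = TRUE)
      p <- stats::predict(model$fit, df, type = "prob")
      pos <- positive(colnames(p))
      cl <- colnames(p)[max.col(p, ties.method = "first")]
      list(class = cl, score = p[, pos])
    })
}

median_heuristic_gamma <- function(x, max_rows = 400L) {
  n <- nrow(x)
  if (n > max_rows) x <- x[seq(1L, n, length.out = max_rows), , drop = FALSE]
  med <- stats::median(stats::dist(x))
  if (!is.finite(med) || med <= 0) return(1 / ncol(x))
  1 / (2 * med^2)
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mean = mu, sd = sd)
}
apply_standardizer <- function(x, st) sweep(sweep(x, 2L, st$mean), 2L, st$sd, "/")

# Stratified seeded row subsample capping the training size.
subsample_rows <- function(labels, max_n, seed) {
  n <- length(labels)
  if (n <= max_n) return(seq_len(n))
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(n), labels), function(ix) {
    take <- max(1L, round(length(ix) / n * max_n))
    if (length(ix) <= take) ix else sample(ix, take)
  }))
  sort(keep)
}

#' Train the two-level hierarchical tissue classifier
#'
#' Level 1 is a binary classifier (IC vs non-IC) on the 18 relative-DTI
#' features only. The infarct-core feature distribution is then fitted on
#' the training IC voxels, the two Mahalanobis features are computed for
#' the non-IC training rows against it, and level 2 (IP vs NT) is fitted on
#' all 110 features. Features are standardized with training-set mean/SD
#' before SVM and KNN fits. Training is deterministic given `seed`.
#'
#' @param train feature data.frame from [assemble_feature_matrix()]
#'   including a `label` column with all three classes.
#' @param backend `"svm"` (radial kernel, cost 1, median-heuristic gamma),
#'   `"knn"` (k = 5) or `"tree"` (rpart defaults).
#' @param seed integer controlling subsampling and any backend randomness.
#' @param max_train_voxels stratified cap on training rows per level
#'   (default 4000) keeping kernel fits tractable.
#' @param cfg a [feature_config()].
#' @return list of class `two_level_model`.
#' @export
train_two_level <- function(train, backend = "svm", seed = 1L,
                            max_train_voxels = 4000L,
                            cfg = feature_config()) {
  cols <- feature_columns(cfg)
  if (!all(c("IC", "IP", "NT") %in% train$label))
    stop("training data must contain IC, IP and NT voxels")
  keep <- subsample_rows(train$label, max_train_voxels, seed)
  tr <- train[keep, , drop = FALSE]

  x1 <- as.matrix(tr[, cols$dti, drop = FALSE])
  y1 <- factor(ifelse(tr$label == "IC", "IC", "nonIC"), c("IC", "nonIC"))
  st1 <- standardizer(x1)
  m1 <- fit_backend(backend, apply_standardizer(x1, st1), y1, seed)

  ic_dist <- fit_ic_distribution(
    as.matrix(tr[tr$label == "IC", cols$dti, drop = FALSE]))

  l2 <- tr[tr$label != "IC", , drop = FALSE]
  x2 <- as.matrix(l2[, cols$all, drop = FALSE])
  x2[, cols$mahal] <- mahalanobis_block(
    as.matrix(l2[, cols$dti, drop = FALSE]), ic_dist)
  y2 <- factor(ifelse(l2$label == "IP", "IP", "NT"), c("IP", "NT"))
  st2 <- standardizer(x2)
  m2 <- fit_backend(backend, apply_standardizer(x2, st2), y2, seed + 1L)

  structure(list(level1 = m1, level2 = m2, ic_distribution = ic_dist,
                 std1 = st1, std2 = st2, backend = backend, cfg = cfg,
                 training_meta = list(rat_ids = unique(train$rat_id),
                                      seed = seed,
                                      n_train_rows = nrow(tr),
                                      max_train_voxels = max_train_voxels)),
            class = "two_level_model")
}

#' Apply the two-level classifier to new voxels
#'
#' Level 1 assigns IC or non-IC to every row; rows predicted non-IC get
#' Mahalanobis features against the model's frozen training core
#' distribution and are split into IP vs NT by level 2. Voxels predicted IC
#' never receive a level-2 score.
#'
#' @param model a [train_two_level()] result.
#' @param test feature data.frame with the same schema as training.
#' @return data.frame: `pred` (IC/IP/NT), `score_ic` (level-1 score,
#'   larger = more core-like), `score_ip` (level-2 score, `NA` for
#'   predicted-IC rows).
#' @export
predict_two_level <- function(model, test) {
  cols <- feature_columns(model$cfg)
  miss <- setdiff(cols$all, names(test))
  if (length(miss)) stop("test schema missing columns: ", miss[1L], " ...")
  x1 <- apply_standardizer(as.matrix(test[, cols$dti, drop = FALSE]),
                           model$std1)
  p1 <- predict_backend(model$level1, x1)
  pred <- ifelse(p1$class == "IC", "IC", NA_character_)
  score_ip <- rep(NA_real_, nrow(test))
  non_ic <- which(p1$class != "IC")
  if (length(non_ic)) {
    x2 <- as.matrix(test[non_ic, cols$all, drop = FALSE])
    x2[, cols$mahal] <- mahalanobis_block(
      as.matrix(test[non_ic, cols$dti, drop = FALSE]), model$ic_distribution)
    p2 <- predict_backend(model$level2, apply_standardizer(x2, model$std2))
    pred[non_ic] <- p2$class
    score_ip[non_ic] <- p2$score
  }
  data.frame(pred = pred, score_ic = as.numeric(p1$score),
             score_ip = score_ip, stringsAsFactors = FALSE)
}

#' Train the single-level three-class baseline
#'
#' One multiclass model on the 18 relative-DTI features only, the
#' comparison arm against the hierarchical classifier.
#'
#' @inheritParams train_two_level
#' @return list of class `single_level_model`.
#' @export
train_single_level <- function(train, backend = "svm", seed = 1L,
                               max_train_voxels = 4000L,
                               cfg = feature_config()) {
  cols <- feature_columns(cfg)
  if (!all(c("IC", "IP", "NT") %in% train$label))
    stop("training data must contain IC, IP and NT voxels")
  keep <- subsample_rows(train$label, max_train_voxels, seed)
  tr <- train[keep, , drop = FALSE]
  x <- as.matrix(tr[, cols$dti, drop = FALSE])
  st <- standardizer(x)
  y <- factor(tr$label, c("IC", "IP", "NT"))
  set.seed(seed)
  fit <- switch(backend,
    svm = e1071::svm(apply_standardizer(x, st), y, kernel = "radial",
                     cost = 1, gamma = median_heuristic_gamma(apply_standardizer(x, st)),
                     scale = FALSE),
    knn = list(train_x = apply_standardizer(x, st), train_y = y, k = 5L),
    tree = rpart::rpart(.y ~ ., data = data.frame(.y = y, apply_standardizer(x, st),
                                                  check.names = TRUE),
                        method = "class"),
    stop("unknown backend: ", backend))
  structure(list(fit = fit, std = st, backend = backend, cfg = cfg,
                 training_meta = list(rat_ids = unique(train$rat_id),
                                      seed = seed)),
            class = "single_level_model")
}

#' Predict with the single-level baseline
#'
#' @param model a [train_single_level()] result.
#' @param test feature data.frame.
#' @return character vector of predicted classes; a function of the 18
#'   relative-DTI columns only.
#' @export
predict_single_level <- function(model, test) {
  cols <- feature_columns(model$cfg)
  x <- apply_standardizer(as.matrix(test[, cols$dti, drop = FALSE]), model$std)
  switch(model$backend,
    svm = as.character(stats::predict(model$fit, x)),
    knn = as.character(class::knn(model$fit$train_x, x, model$fit$train_y,
                                  k = model$fit$k)),
    tree = {
      p <- stats::predict(model$fit, data.frame(x, check.names = TRUE),
                          type = "class")
      as.character(p)
    })
}
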