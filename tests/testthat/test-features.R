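test_that("relative metrics vanish on symmetric maps and match direct mirroring", {
  dm <- c(6L, 8L, 2L)
  mask <- array(TRUE, dm)
  sym <- array(0, dm)
  for (cc in 1:8) sym[, cc, ] <- min(cc, 9 - cc)
  ml <- list(MD = sym, AD = sym, RD = sym, FA = sym, q = sym, L = sym)
  rel <- relative_metric_maps(ml, mask)
  expect_equal(max(abs(rel$rMD)), 0)

  # ipsilateral at 0.6 x mirror: rMD = -0.4 (the core effect size)
  asym <- sym
  asym[, 1:4, ] <- 0.6 * sym[, rev(1:8), ][, 1:4, ]
  rel2 <- relative_metric_maps(list(MD = asym, AD = sym, RD = sym, FA = sym,
                                    q = sym, L = sym), mask)
  expect_true(all(abs(rel2$rMD[, 1:4, ] + 0.4) < 1e-10))

  # random asymmetric map vs explicit index arithmetic
  set.seed(8)
  x <- array(stats::runif(prod(dm), 0.5, 2), dm)
  rel3 <- relative_metric_maps(list(MD = x, AD = x, RD = x, FA = x, q = x,
                                    L = x), mask)
  for (k in 1:20) {
    r <- sample(6, 1); cc <- sample(8, 1); s <- sample(2, 1)
    mirror <- x[r, 9L - cc, s]
    expect_equal(rel3$rMD[r, cc, s], (x[r, cc, s] - mirror) / mirror)
  }

  # non-positive mirror values produce 0 with a QC count
  bad <- x; bad[2, 7, 1] <- 0
  rel4 <- relative_metric_maps(list(MD = bad, AD = x, RD = x, FA = x, q = x,
                                    L = x), mask)
  expect_equal(rel4$rMD[2, 2, 1], 0)
  expect_gte(rel4$qc_zero_mirror, 1)
})

test_that("feature matrix has 110 columns in 18/90/2 blocks with stable order", {
  cols <- feature_columns()
  expect_length(cols$all, 110L)
  expect_length(cols$dti, 18L)
  expect_length(cols$hist, 90L)
  expect_length(cols$mahal, 2L)
  expect_identical(cols$all, c(cols$dti, cols$hist, cols$mahal))
  # own slice, slice below, slice above, six metrics each
  expect_identical(cols$dti[1:6], paste0("dti_", c("rMD", "rAD", "rRD",
                                                   "rFA", "rL", "rq"), "_s0"))
  expect_identical(cols$dti[7], "dti_rMD_sm1")
  expect_identical(cols$dti[13], "dti_rMD_sp1")

  rat <- generate_cohort(tiny_spec(n_rats = 1L))[[1]]
  pr <- process_rat(rat, smooth_sigma = 0)
  rel <- relative_metric_maps(pr$smoothed, pr$brain_mask)
  fm <- rat_feature_matrix(rel, pr$labels, pr$brain_mask, pr$ventricle_mask,
                           pr$side, "ratA")
  expect_identical(names(fm)[-(1:5)], cols$all)
  expect_false(any(!is.finite(as.matrix(fm[, cols$all]))))
  # row count = eligible voxel count
  elig <- pr$brain_mask & !pr$ventricle_mask
  elig[, hemisphere_cols(32L, setdiff(c("left", "right"), pr$side)), ] <- FALSE
  expect_equal(nrow(fm), sum(elig))
  # histogram rows sum to one for every metric
  for (m in c("rMD", "rq")) {
    bins <- fm[, sprintf("hist_%s_cor_bin%02d", m, 1:11)]
    expect_equal(unname(rowSums(bins)), rep(1, nrow(fm)))
  }
})

test_that("adjacent-slice features use nearest-slice replication at stack edges", {
  rat <- generate_cohort(tiny_spec(n_rats = 1L))[[1]]
  pr <- process_rat(rat, smooth_sigma = 0)
  rel <- relative_metric_maps(pr$smoothed, pr$brain_mask)
  fm <- rat_feature_matrix(rel, pr$labels, pr$brain_mask, pr$ventricle_mask,
                           pr$side, "ratA")
  first <- fm[fm$slice == 1, ]
  expect_equal(first$dti_rMD_sm1, first$dti_rMD_s0)
  last <- fm[fm$slice == max(fm$slice), ]
  expect_equal(last$dti_rMD_sp1, last$dti_rMD_s0)
  mid <- fm[fm$slice == 2, ][1, ]
  expect_equal(mid$dti_rMD_sm1,
               rel$rMD[mid$row, mid$col, 1])
  expect_equal(mid$dti_rMD_sp1,
               rel$rMD[mid$row, mid$col, 3])
})

test_that("histogram bin counts and moments match brute force on a hand window", {
  dm <- c(9L, 18L, 1L)
  mask <- array(TRUE, dm)
  set.seed(9)
  a <- array(stats::runif(prod(dm), -1.4, 1.4), dm)
  ml <- list(MD = a, AD = a, RD = a, FA = a, q = a, L = a)
  # make the map asymmetric so rel values are nontrivial but known
  rel <- relative_metric_maps(ml, mask)
  lab <- structure(list(label = array(3L, dm), side = "left", qc = list()),
                   class = "label_map")
  fm <- rat_feature_matrix(rel, lab, mask, array(FALSE, dm), "left", "r")
  vox <- fm[fm$row == 5 & fm$col == 5 & fm$slice == 1, ]
  win <- as.vector(rel$rMD[2:8, 2:8, 1])
  expect_length(win, 49L)
  # brute-force equal-width bins on [-1, 1] with end-bin clipping
  wcl <- pmin(pmax(win, -1), 1)
  cnts <- sapply(1:11, function(b) {
    lo <- -1 + (b - 1) * 2 / 11; hi <- -1 + b * 2 / 11
    if (b < 11) sum(wcl >= lo & wcl < hi) else sum(wcl >= lo)
  })
  got <- as.numeric(vox[, sprintf("hist_rMD_cor_bin%02d", 1:11)])
  expect_equal(got, cnts / 49, tolerance = 1e-12)
  m2 <- mean((win - mean(win))^2)
  sk <- mean((win - mean(win))^3) / m2^1.5
  ku <- mean((win - mean(win))^4) / m2^2
  expect_equal(vox$hist_rMD_cor_skew, sk, tolerance = 1e-12)
  expect_equal(vox$hist_rMD_cor_kurt, ku, tolerance = 1e-12)
  # cross-check against the standard moment estimators
  expect_equal(sk, e1071::skewness(win, type = 1), tolerance = 1e-12)
  expect_equal(ku, e1071::kurtosis(win, type = 1) + 3, tolerance = 1e-12)

  # constant window: single full bin, zero moments by convention
  flat <- array(0, dm)
  relf <- list(rMD = flat, rAD = flat, rRD = flat, rFA = flat, rL = flat,
               rq = flat, qc_zero_mirror = 0)
  fmf <- rat_feature_matrix(relf, lab, mask, array(FALSE, dm), "left", "r")
  v <- fmf[1, ]
  expect_equal(v$hist_rMD_cor_bin06, 1)
  expect_equal(sum(as.numeric(v[sprintf("hist_rMD_cor_bin%02d", c(1:5, 7:11))])), 0)
  expect_equal(v$hist_rMD_cor_skew, 0)
  expect_equal(v$hist_rMD_cor_kurt, 0)
})

test_that("Mahalanobis features match the explicit-inverse computation", {
  set.seed(10)
  n <- 40L
  X <- matrix(stats::rnorm(n * 18), n, 18)
  dist <- fit_ic_distribution(X)
  # covariance equals the sample formula plus the ridge
  S <- stats::cov(X[, 1:6])
  ridge <- 1e-6 * mean(diag(stats::cov(X[, 1:6])))
  expect_equal(dist$d6$cov, S + diag(ridge, 6), tolerance = 1e-12)

  q <- matrix(stats::rnorm(5 * 18), 5, 18)
  got <- mahalanobis_block(q, dist)
  inv6 <- solve(dist$d6$cov)
  inv18 <- solve(dist$d18$cov)
  for (i in 1:5) {
    d6 <- sqrt(drop(t(q[i, 1:6] - dist$d6$mean) %*% inv6 %*%
                      (q[i, 1:6] - dist$d6$mean)))
    d18 <- sqrt(drop(t(q[i, ] - dist$d18$mean) %*% inv18 %*%
                       (q[i, ] - dist$d18$mean)))
    expect_equal(unname(got[i, "mahal_d6"]), d6, tolerance = 1e-10)
    expect_equal(unname(got[i, "mahal_d18"]), d18, tolerance = 1e-10)
  }
  # distance to the mean is zero; identity covariance reduces to Euclidean
  at_mu <- matrix(dist$d18$mean, 1)
  expect_lt(mahalanobis_block(at_mu, dist)[1, "mahal_d18"], 1e-8)
  iso <- list(d6 = list(mean = rep(0, 6), cov = diag(6)),
              d18 = list(mean = rep(0, 18), cov = diag(18)))
  class(iso) <- "ic_distribution"
  z <- matrix(stats::rnorm(18), 1)
  expect_equal(unname(mahalanobis_block(z, iso)[1, "mahal_d18"]),
               sqrt(sum(z^2)))

  # degenerate identical cloud: ridge keeps distances to the point near 0
  Xd <- matrix(1, 30, 18)
  dd <- fit_ic_distribution(Xd)
  expect_lt(mahalanobis_block(matrix(1, 1, 18), dd)[1, "mahal_d18"], 1e-6)
  expect_error(fit_ic_distribution(X[1:10, ]), "too few")
})

test_that("core distribution changes if extra animals leak into its fit", {
  set.seed(11)
  A <- matrix(stats::rnorm(40 * 18, -0.4, 0.05), 40, 18)
  B <- matrix(stats::rnorm(40 * 18, -0.3, 0.05), 40, 18)
  d_train <- fit_ic_distribution(A)
  d_leaky <- fit_ic_distribution(rbind(A, B))
  expect_false(isTRUE(all.equal(d_train$d18$mean, d_leaky$d18$mean)))
})

test_that("features translate with the lesion", {
  dm <- c(12L, 16L, 1L)
  mask <- array(TRUE, dm)
  base <- array(1, dm)
  a1 <- base; a1[5:7, 3:4, 1] <- 0.6
  a2 <- base; a2[5:7, 4:5, 1] <- 0.6   # same blob shifted one column
  mk <- function(a) relative_metric_maps(
    list(MD = a, AD = a, RD = a, FA = a, q = a, L = a), mask)
  lab <- structure(list(label = array(3L, dm), side = "left", qc = list()),
                   class = "label_map")
  f1 <- rat_feature_matrix(mk(a1), lab, mask, array(FALSE, dm), "left", "r")
  f2 <- rat_feature_matrix(mk(a2), lab, mask, array(FALSE, dm), "left", "r")
  v1 <- f1[f1$row == 6 & f1$col == 4, feature_columns()$hist]
  v2 <- f2[f2$row == 6 & f2$col == 5, feature_columns()$hist]
  expect_equal(unname(as.numeric(v1)), unname(as.numeric(v2)))
})
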