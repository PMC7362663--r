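make_eigen <- function(l1, l2, l3) {
  dm <- c(1L, 2L, 1L)
  list(lam1 = array(l1, dm), lam2 = array(l2, dm), lam3 = array(l3, dm),
       brain_mask = array(TRUE, dm))
}

test_that("isotropic and stick tensors give their closed-form metrics", {
  iso <- compute_dti_metrics(make_eigen(1e-3, 1e-3, 1e-3))
  expect_equal(iso$MD[1, 1, 1], 1e-3)
  expect_equal(iso$q[1, 1, 1], 0)
  expect_equal(iso$FA[1, 1, 1], 0)
  expect_equal(iso$L[1, 1, 1], sqrt(3) * 1e-3)

  stick <- compute_dti_metrics(make_eigen(1, 0, 0))
  expect_equal(stick$MD[1, 1, 1], 1 / 3)
  expect_equal(stick$L[1, 1, 1], 1)
  expect_equal(stick$q[1, 1, 1], sqrt(6) / 3)
  expect_equal(stick$FA[1, 1, 1], 1)
  expect_equal(stick$AD[1, 1, 1], 1)
  expect_equal(stick$RD[1, 1, 1], 0)
})

test_that("FA from eigenvalue differences agrees with sqrt(3/2) q / L", {
  set.seed(1)
  lam <- matrix(stats::runif(3000, 0, 3e-3), ncol = 3)
  lam <- t(apply(lam, 1, sort, decreasing = TRUE))
  dm <- c(nrow(lam), 1L, 1L)
  m <- compute_dti_metrics(list(
    lam1 = array(lam[, 1], dm), lam2 = array(lam[, 2], dm),
    lam3 = array(lam[, 3], dm), brain_mask = array(TRUE, dm)))
  # independent closed form on pairwise eigenvalue differences
  fa_ref <- sqrt(((lam[, 1] - lam[, 2])^2 + (lam[, 2] - lam[, 3])^2 +
                    (lam[, 3] - lam[, 1])^2) /
                   (2 * (lam[, 1]^2 + lam[, 2]^2 + lam[, 3]^2)))
  expect_lt(max(abs(as.vector(m$FA) - fa_ref)), 1e-12)
  expect_true(all(m$FA >= 0 & m$FA <= 1 + 1e-12))
  expect_true(all(m$L >= m$MD))
})

test_that("uniform eigenvalue scaling scales sizes and fixes FA", {
  set.seed(2)
  lam <- sort(stats::runif(3, 1e-4, 3e-3), decreasing = TRUE)
  a <- compute_dti_metrics(make_eigen(lam[1], lam[2], lam[3]))
  b <- compute_dti_metrics(make_eigen(2.5 * lam[1], 2.5 * lam[2], 2.5 * lam[3]))
  for (nm in c("MD", "AD", "RD", "q", "L"))
    expect_equal(b[[nm]][1, 1, 1], 2.5 * a[[nm]][1, 1, 1])
  expect_equal(b$FA[1, 1, 1], a$FA[1, 1, 1])
})

test_that("zero tensor yields FA 0 with a QC count, unsorted input is sorted", {
  m <- compute_dti_metrics(make_eigen(0, 0, 0))
  expect_equal(m$FA[1, 1, 1], 0)
  expect_equal(m$qc$n_zero_tensor, 2L)
  ms <- compute_dti_metrics(make_eigen(0.5e-3, 1.2e-3, 0.9e-3))
  expect_equal(ms$AD[1, 1, 1], 1.2e-3)
  expect_true(ms$qc$resorted)
})

test_that("gaussian smoothing preserves constants and matches the kernel on an impulse", {
  const <- matrix(7, 11, 11)
  expect_equal(gaussian_smooth(const, sigma_vox = 1), const)

  imp <- matrix(0, 11, 11)
  imp[6, 6] <- 1
  sm <- gaussian_smooth(imp, sigma_vox = 1)
  off <- -2:2
  k <- exp(-off^2 / 2)
  kern <- outer(k, k); kern <- kern / sum(kern)
  expect_lt(max(abs(sm[4:8, 4:8] - kern)), 1e-10)

  # conservation holds for maps supported away from the boundary, where the
  # kernel weight renormalization is inactive
  set.seed(3)
  interior <- matrix(0, 15, 15)
  interior[5:11, 5:11] <- stats::runif(49)
  expect_equal(sum(gaussian_smooth(interior, sigma_vox = 1)), sum(interior),
               tolerance = 1e-8)
})

test_that("masked neighbours contribute nothing to the smoothed value", {
  m <- matrix(1, 7, 7)
  m[, 5:7] <- 100
  mask <- matrix(TRUE, 7, 7)
  mask[, 5:7] <- FALSE
  sm <- gaussian_smooth(m, mask, sigma_vox = 1)
  expect_equal(sm[, 1:4], matrix(1, 7, 4))
  expect_true(all(is.na(sm[, 5:7])))
  expect_error(gaussian_smooth(m, sigma_vox = 0), "positive")
})

test_that("normalize01 maps linearly onto [0,1] and rejects constants", {
  r <- normalize01(array(c(2, 4, 6), c(3, 1, 1)))
  expect_equal(as.vector(r$map), c(0, 0.5, 1))
  expect_equal(unname(r$bounds), c(2, 6))

  set.seed(4)
  x <- array(stats::rnorm(60), c(5, 4, 3))
  n <- normalize01(x)
  expect_equal(min(n$map), 0)
  expect_equal(max(n$map), 1)
  id <- normalize01(array(c(0, 0.3, 1), c(3, 1, 1)))
  expect_equal(as.vector(id$map), c(0, 0.3, 1))
  expect_error(normalize01(array(5, c(2, 2, 1))), "constant")
})

test_that("smoothed+normalized noiseless MD keeps NT > IP > IC region means", {
  spec <- tiny_spec(n_rats = 1L)
  rat <- generate_cohort(spec)[[1]]
  m <- process_metric_maps(compute_dti_metrics(rat$eigen), sigma_vox = 1)
  lab <- rat$truth_labels$label
  md <- m$normalized$MD
  means <- sapply(1:3, function(cd) mean(md[lab == cd], na.rm = TRUE))
  expect_true(means[3] > means[2] && means[2] > means[1])
})
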