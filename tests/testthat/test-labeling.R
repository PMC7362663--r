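test_that("mirror reflection and hemisphere means behave as stated", {
  expect_equal(mirror_col(11L, 128L) - 1L, 117L)  # 0-based: c' = 127 - c
  expect_equal(mirror_col(1L, 128L), 128L)
  expect_equal(hemisphere_cols(8L, "left"), 1:4)
  expect_equal(hemisphere_cols(8L, "right"), 5:8)
  expect_error(hemisphere_cols(7L, "left"), "even")

  sym <- array(rep(c(1, 2, 3, 3, 2, 1), each = 2), c(2, 6, 1))
  mask <- array(TRUE, c(2, 6, 1))
  ref <- contralateral_reference(sym, mask, "left")
  expect_identical(ref$mirror, sym)

  m7 <- array(7, c(2, 6, 1))
  expect_equal(contralateral_reference(m7, mask, "left")$mean, 7)
  empty <- array(FALSE, c(2, 6, 1))
  expect_error(contralateral_reference(m7, empty, "left"), "contralateral")
})

test_that("IC threshold is strict at 30% reduction and excludes ventricles", {
  dm <- c(2L, 6L, 1L)
  mask <- array(TRUE, dm)
  vent <- array(FALSE, dm)
  md <- array(1, dm)
  md[1, 1, 1] <- 0.69   # below (1 - 0.30) x contralateral mean of 1
  md[2, 1, 1] <- 0.71   # above
  md[1, 2, 1] <- 0.70   # exactly at threshold: strict <, not lesion
  md[2, 2, 1] <- 0.50
  vent[2, 2, 1] <- TRUE # would qualify but is ventricle
  ic <- threshold_ic(md, mask, vent, "left")
  expect_true(ic[1, 1, 1])
  expect_false(ic[2, 1, 1])
  expect_false(ic[1, 2, 1])
  expect_false(ic[2, 2, 1])
  expect_equal(sum(ic[, 4:6, ]), 0)  # contralateral side never labeled
})

test_that("perfusion deficit threshold is strict at 46% reduction", {
  dm <- c(2L, 6L, 1L)
  mask <- array(TRUE, dm)
  rcbf <- array(1, dm)
  rcbf[1, 1, 1] <- 0.50
  rcbf[2, 1, 1] <- 0.60
  rcbf[1, 2, 1] <- 0.54  # exactly at threshold
  def <- threshold_perfusion(rcbf, mask, "left", labeling_config())
  expect_true(def[1, 1, 1])
  expect_false(def[2, 1, 1])
  expect_false(def[1, 2, 1])

  low <- array(1, dm); low[, 1:3, ] <- 0.20
  expect_equal(sum(threshold_perfusion(low, mask, "left")[, 1:3, ]), 6)
})

test_that("monotonicity: raising the MD threshold never grows the core", {
  set.seed(6)
  dm <- c(10L, 10L, 2L)
  md <- array(stats::runif(prod(dm), 0.3, 1.2), dm)
  mask <- array(TRUE, dm)
  vent <- array(FALSE, dm)
  sizes <- sapply(c(0.1, 0.2, 0.3, 0.4, 0.5), function(th)
    sum(threshold_ic(md, mask, vent, "left",
                     labeling_config(md_reduction_threshold = th))))
  expect_true(all(diff(sizes) <= 0))
})

test_that("mismatch set algebra: IP = deficit minus IC, NT the rest", {
  dm <- c(8L, 8L, 1L)
  mask <- array(TRUE, dm)
  vent <- array(FALSE, dm)
  ic <- array(FALSE, dm); ic[3:4, 2:3, 1] <- TRUE
  def <- array(FALSE, dm); def[2:5, 1:4, 1] <- TRUE
  lm <- derive_pdm_labels(ic, def, mask, vent, "left",
                          labeling_config(contiguity_passes = 0L))
  expect_equal(sum(lm$label == 1), sum(ic))
  expect_equal(sum(lm$label == 2), sum(def & !ic))
  expect_gt(sum(lm$label == 2), 0)
  # left hemisphere voxels partition into IC/IP/NT
  expect_equal(sum(lm$label[, 1:4, ] != 0), 8 * 4)
  expect_equal(sum(lm$label[, 5:8, ] != 0), 0)

  # deficit exactly the core: empty penumbra
  lm2 <- derive_pdm_labels(ic, ic, mask, vent, "left",
                           labeling_config(contiguity_passes = 0L))
  expect_equal(sum(lm2$label == 2), 0)

  # diffusion lesion outside the deficit keeps IC precedence, QC-counted
  ic3 <- ic; ic3[7, 1, 1] <- TRUE
  lm3 <- derive_pdm_labels(ic3, def, mask, vent, "left",
                           labeling_config(contiguity_passes = 0L))
  expect_equal(lm3$label[7, 1, 1], 1L)
  expect_equal(lm3$qc$n_ic_outside_deficit, 1L)
})

test_that("contiguity correction relabels isolated voxels and matches a brute-force scan", {
  dm <- c(10L, 10L, 1L)
  lab <- array(3L, dm)
  lab[5, 5, 1] <- 1L            # isolated core voxel in normal tissue
  lab[1:3, 8:10, 1] <- 1L       # solid core block
  lm <- structure(list(label = lab, side = "left", qc = list()),
                  class = "label_map")
  fixed <- contiguity_correction(lm, labeling_config())
  expect_equal(fixed$label[5, 5, 1], 3L)
  expect_equal(fixed$label[2, 9, 1], 1L)  # interior of block untouched

  # seeded salt-and-pepper map vs an independent per-voxel neighbourhood scan
  set.seed(7)
  lab2 <- array(sample(1:3, 14 * 14, TRUE, prob = c(0.05, 0.05, 0.9)),
                c(14L, 14L, 1L))
  lm2 <- structure(list(label = lab2, side = "left", qc = list()),
                   class = "label_map")
  got <- contiguity_correction(lm2, labeling_config())$label
  ref <- lab2
  for (r in 1:14) for (cc in 1:14) {
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= 14 && c2 >= 1 && c2 <= 14)
        nb <- c(nb, lab2[rr, c2, 1])
    }
    for (other in setdiff(1:3, lab2[r, cc, 1]))
      if (sum(nb == other) >= 6) ref[r, cc, 1] <- other
  }
  expect_identical(got, ref)
})

test_that("partition invariant survives labeling plus correction on a phantom", {
  rat <- generate_cohort(tiny_spec(n_rats = 1L, grid = c(48L, 48L)))[[1]]
  pr <- process_rat(rat, smooth_sigma = 0)
  elig <- rat$brain_mask & !rat$ventricle_mask
  ipsi <- array(FALSE, dim(elig))
  ipsi[, hemisphere_cols(48L, rat$side), ] <- TRUE
  expect_equal(sum(pr$labels$label != 0), sum(elig & ipsi))
  expect_equal(sum(pr$labels$label == 1) + sum(pr$labels$label == 2) +
                 sum(pr$labels$label == 3), sum(elig & ipsi))
})
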