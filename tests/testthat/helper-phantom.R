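# Small cohort specs shared across test files. Kept deliberately tiny so
# unit tests run in seconds; the acceptance suite builds its own larger
# cohorts.

tiny_spec <- function(...) {
  args <- list(n_rats = 2L, n_slices = 3L, grid = c(32L, 32L),
               noise_sd_eigen = 0, noise_sd_signal = 0, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# Synthetic separable feature matrix: three tissue clusters separated in
# the relative-DTI block, arbitrary small-noise histogram block. Used for
# classifier unit tests without running the imaging pipeline.
toy_features <- function(n_per_class = 60L, n_rats = 3L, sd = 0.005,
                         seed = 99L) {
  set.seed(seed)
  cols <- feature_columns()
  centers <- c(IC = -0.4, IP = -0.1, NT = 0)
  rows <- lapply(names(centers), function(cl) {
    n <- n_per_class
    X <- matrix(stats::rnorm(n * 110, 0, sd), n, 110,
                dimnames = list(NULL, cols$all))
    X[, cols$dti] <- X[, cols$dti] + centers[[cl]]
    X[, cols$mahal] <- 0
    data.frame(rat_id = rep_len(sprintf("rat%02d", seq_len(n_rats)), n),
               slice = 1L, row = seq_len(n), col = 1L, label = cl, X,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
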