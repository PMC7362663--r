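#' @keywords internal
"_PACKAGE"

# Clamp integer indices into [lo, hi]; used by the edge-replication policy
# of windowed feature extraction and adjacent-slice lookups.
clamp_idx <- function(i, lo, hi) pmin(pmax(i, lo), hi)

#' Column indices of one hemisphere
#'
#' Maps on the phantom grid are stored as `rows x cols x slices` arrays with
#' the inter-hemispheric midline between columns `ncol/2` and `ncol/2 + 1`.
#'
#' @param ncols total (even) column count of the grid.
#' @param side `"left"` or `"right"`.
#' @return Integer vector of column indices belonging to that hemisphere.
#' @export
hemisphere_cols <- function(ncols, side) {
  if (ncols %% 2L != 0L) stop("grid must have an even number of columns")
  side <- match.arg(side, c("left", "right"))
  if (side == "left") seq_len(ncols %/% 2L) else (ncols %/% 2L + 1L):ncols
}

#' Mirror a column index about the image midline
#'
#' The contralateral homologue of column `c` on an `ncols`-column grid is
#' `ncols + 1 - c` (0-based: `c' = ncols - 1 - c`).
#'
#' @param col column index (1-based), possibly a vector.
#' @param ncols total column count.
#' @return Mirrored column indices.
#' @export
mirror_col <- function(col, ncols) ncols + 1L - col

#' Population skewness and kurtosis of matrix rows
#'
#' Rowwise third and fourth standardized central moments without bias
#' correction. Zero-variance rows return 0 for both, the convention used for
#' constant feature windows. Kurtosis is Pearson's \eqn{m_4/m_2^2} (not
#' excess).
#'
#' @param m numeric matrix; moments are taken along rows.
#' @return list with numeric vectors `skewness` and `kurtosis`.
#' @export
row_moments <- function(m) {
  mu <- rowMeans(m)
  d <- m - mu
  m2 <- rowMeans(d^2)
  m3 <- rowMeans(d^3)
  m4 <- rowMeans(d^4)
  ok <- m2 > 0
  sk <- ku <- numeric(nrow(m))
  sk[ok] <- m3[ok] / m2[ok]^1.5
  ku[ok] <- m4[ok] / m2[ok]^2
  list(skewness = sk, kurtosis = ku)
}
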