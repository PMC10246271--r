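#' Number of unique functional connections for an atlas
#'
#' A connectome on `R` regions of interest has one edge per unordered ROI
#' pair, i.e. the strict upper triangle of the correlation matrix. The
#' 379-region surface parcellation used throughout this package's defaults
#' yields 71,631 edges.
#'
#' @param R Integer number of ROIs (>= 2).
#' @return Integer, `R * (R - 1) / 2`.
#' @export
#' @examples
#' edge_count(379)  # 71631
edge_count <- function(R) {
  if (length(R) != 1L || !is.finite(R) || R != as.integer(R) || R < 2)
    stop("invalid atlas: 'R' must be a single integer >= 2", call. = FALSE)
  as.integer(R * (R - 1) / 2)
}

#' Map an ROI pair to its edge index
#'
#' Edges are numbered 0-based over the strict upper triangle in row-major
#' order: (0,1), (0,2), ..., (0,R-1), (1,2), ... This ordering is the
#' package-wide edge identity shared by every module; [edge_roi_pair()] is
#' its inverse.
#'
#' @param i,j 0-based ROI indices with `i < j` (vectorised).
#' @param R Number of ROIs.
#' @return 0-based edge indices in `0 .. edge_count(R) - 1`.
#' @seealso [edge_roi_pair()]
#' @export
edge_index <- function(i, j, R) {
  edge_count(R)
  if (any(i < 0) || any(j <= i) || any(j >= R))
    stop("edge index requires 0 <= i < j < R", call. = FALSE)
  as.integer(i * (2 * R - i - 1) / 2 + (j - i - 1))
}

#' Recover the ROI pair of an edge index
#'
#' @param idx 0-based edge indices (vectorised).
#' @param R Number of ROIs.
#' @return A two-column integer matrix with columns `i`, `j` (0-based, i < j).
#' @export
edge_roi_pair <- function(idx, R) {
  m <- edge_count(R)
  if (any(idx < 0) || any(idx >= m))
    stop("edge index out of range 0..", m - 1, call. = FALSE)
  # offsets[i + 1] = first edge index of row i
  rows <- 0:(R - 2)
  offsets <- as.numeric(rows * (2 * R - rows - 1) / 2)
  i <- findInterval(idx, offsets) - 1L
  j <- as.integer(idx - offsets[i + 1L] + i + 1L)
  cbind(i = i, j = as.integer(j))
}

#' Edge labels of the form `e<i>_<j>`
#' @param R Number of ROIs.
#' @return Character vector of length `edge_count(R)`.
#' @keywords internal
edge_labels <- function(R) {
  p <- edge_roi_pair(seq_len(edge_count(R)) - 1L, R)
  paste0("e", p[, "i"], "_", p[, "j"])
}

# Row-major strict upper triangle of a square matrix, in edge_index order.
upper_tri_vector <- function(M) {
  t(M)[lower.tri(M)]
}
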