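#' Tanimoto distance between two binary fingerprints
#'
#' `1 - |a AND b| / |a OR b|`. By convention two all-zero vectors have
#' distance 0 (they are identical).
#'
#' @param a,b Equal-width 0/1 vectors.
#' @return A real in `[0, 1]`.
#' @examples
#' tanimoto_distance(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1))  # 1 - 2/4
#' @export
tanimoto_distance <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint widths differ")
  a <- as.logical(a); b <- as.logical(b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  1 - sum(a & b) / uni
}

#' Tanimoto distance matrix between two fingerprint sets
#'
#' Computed with dense matrix products: intersections via `tcrossprod`,
#' unions from the row bit counts. All-zero pairs get distance 0.
#'
#' @param A,B 0/1 matrices with the same number of columns (rows are
#'   compounds).
#' @return A `nrow(A) x nrow(B)` matrix of distances.
#' @export
tanimoto_distance_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("fingerprint widths differ")
  A <- matrix(as.numeric(A), nrow(A), ncol(A))
  B <- matrix(as.numeric(B), nrow(B), ncol(B))
  inter <- tcrossprod(A, B)
  uni <- outer(rowSums(A), rowSums(B), "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  d
}
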