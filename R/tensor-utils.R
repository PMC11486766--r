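# Dense 3-way tensor algebra used by the Tucker weighting and CP fitting
# routines. Tensors are plain numeric arrays; unfoldings follow the standard
# (Kolda & Bader) convention: the mode-n unfolding has the mode-n fibers as
# columns, with the remaining indices varying fastest in ascending mode order.

#' Mode-n unfolding of a 3-way array
#' @param x numeric 3-way array
#' @param mode 1, 2 or 3
#' @return matrix of dimension `dim(x)[mode]` x `prod(dim(x)[-mode])`
#' @noRd
unfold <- function(x, mode) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  matrix(aperm(x, perm), nrow = d[mode])
}

#' Inverse of `unfold`
#' @noRd
fold <- function(mat, mode, dims) {
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  inv <- order(perm)
  aperm(array(mat, dim = dims[perm]), inv)
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' Row ordering matches the unfolding convention: `khatri_rao(C, B)` has row
#' index `i_B + (i_C - 1) * nrow(B)`, so `unfold(x, 1) %*% khatri_rao(C, B)`
#' is the mode-1 matricized-tensor-times-Khatri-Rao product.
#' @noRd
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  ia <- rep(seq_len(nrow(A)), each = nrow(B))
  ib <- rep(seq_len(nrow(B)), times = nrow(A))
  A[ia, , drop = FALSE] * B[ib, , drop = FALSE]
}

#' Mode-n product of a 3-way array with a matrix
#' @noRd
ttm <- function(x, m, mode) {
  d <- dim(x)
  out <- m %*% unfold(x, mode)
  d[mode] <- nrow(m)
  fold(out, mode, d)
}

#' Reconstruct a tensor from CP factors
#' @param lambda length-R weights
#' @param A,B,C factor matrices (I x R, J x R, K x R)
#' @noRd
cp_tensor <- function(lambda, A, B, C) {
  Al <- sweep(A, 2, lambda, `*`)
  fold(Al %*% t(khatri_rao(C, B)), 1, c(nrow(A), nrow(B), nrow(C)))
}

#' Frobenius norm
#' @noRd
fnorm <- function(x) sqrt(sum(x * x))

#' Moore-Penrose pseudo-inverse with condition-number report
#' @noRd
pinv_cond <- function(m, tol = 1e-12) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) {
    return(list(pinv = matrix(0, ncol(m), nrow(m)), cond = Inf))
  }
  cond <- max(s$d) / min(s$d[pos])
  pinv <- s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  list(pinv = pinv, cond = cond, full_rank = all(pos))
}
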