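#' Signed incidence (boundary) matrix of order m
#'
#' `B_m` maps m-simplices to their (m-1)-faces. With simplices stored as
#' strictly increasing vertex tuples, the face obtained by deleting the
#' vertex at position `p` (0-based) carries the permutation sign `(-1)^p`,
#' so for an edge `[i, j]` (i < j) the column holds `-1` at row `i` and
#' `+1` at row `j`, and a triangle `[i, j, k]` contributes `+1` to face
#' `[j, k]`, `-1` to `[i, k]`, `+1` to `[i, j]`. Consecutive boundaries
#' compose to zero: `B_m %*% B_{m+1} == 0`.
#'
#' @param K A [clique_complex()] result (or any `simplicial_complex`).
#' @param m Order, `1 <= m <= max_dim`.
#' @return A sparse `dgCMatrix` of shape (#(m-1)-simplices x #m-simplices).
#' @export
incidence_matrix <- function(K, m) {
  stopifnot(inherits(K, "simplicial_complex"))
  m <- as.integer(m)
  if (m < 1L || m > K$max_dim) {
    stop(sprintf("m must be between 1 and max_dim = %d, got %d", K$max_dim, m), call. = FALSE)
  }
  upper <- K$simplices[[m + 1L]]
  lower <- K$simplices[[m]]
  lower_key <- apply(lower, 1L, paste, collapse = ",")
  nnz_per_col <- m + 1L
  ii <- integer(nrow(upper) * nnz_per_col)
  jj <- integer(length(ii))
  xx <- numeric(length(ii))
  pos <- 1L
  for (col in seq_len(nrow(upper))) {
    simp <- upper[col, ]
    for (p in seq_len(m + 1L)) {
      face <- simp[-p]
      ri <- match(paste(face, collapse = ","), lower_key)
      ii[pos] <- ri
      jj[pos] <- col
      xx[pos] <- (-1)^(p - 1L)
      pos <- pos + 1L
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nrow(lower), nrow(upper)))
}

#' Assemble all Hodge Laplacians of a complex
#'
#' The m-th order (Hodge) Laplacian is
#' `L_m = t(B_m) %*% B_m + B_{m+1} %*% t(B_{m+1})`, with the empty-matrix
#' convention at the ends, so `L_0 = B_1 %*% t(B_1)` recovers the ordinary
#' graph Laplacian `K - A` of the 1-skeleton. The total Laplacian is the
#' block-diagonal matrix of all `L_m`, acting on one value per simplex in
#' dimension-major, lexicographic order.
#'
#' @param K A `simplicial_complex`.
#' @return An object of class `hodge_operators` with fields `B` (list of
#'   incidence matrices, `B[[m]]` of order m), `Lm` (list of Laplacians,
#'   `Lm[[m + 1]]` of order m), `Ltotal`, the degree matrix `K` and
#'   adjacency `A` of the 1-skeleton, and `complex`.
#' @export
#' @examples
#' K3 <- clique_complex(smx_graph(data.frame(c(1, 1, 2), c(2, 3, 3))))
#' H <- hodge_laplacians(K3)
#' as.matrix(H$Lm[[1]])   # 2 on the diagonal, -1 off: K - A of a triangle
hodge_laplacians <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  M <- K$max_dim
  counts <- vapply(K$simplices, nrow, 1L)
  B <- if (M >= 1L) lapply(seq_len(M), function(m) incidence_matrix(K, m)) else list()
  Lm <- vector("list", M + 1L)
  for (m in 0:M) {
    n_m <- counts[m + 1L]
    down <- if (m >= 1L) Matrix::crossprod(B[[m]]) else
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n_m, n_m))
    up <- if (m + 1L <= M) Matrix::tcrossprod(B[[m + 1L]]) else
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n_m, n_m))
    Lm[[m + 1L]] <- methods::as(down + up, "generalMatrix")
  }
  Ltotal <- Matrix::bdiag(Lm)
  A <- adjacency_matrix_from_complex(K)
  Kdeg <- Matrix::Diagonal(x = Matrix::rowSums(A))
  structure(
    list(B = B, Lm = Lm, Ltotal = Ltotal, K = Kdeg, A = A, complex = K),
    class = "hodge_operators"
  )
}

adjacency_matrix_from_complex <- function(K) {
  nv <- nrow(K$simplices[[1L]])
  if (length(K$simplices) < 2L || nrow(K$simplices[[2L]]) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(nv, nv)))
  }
  E <- K$simplices[[2L]]
  Matrix::sparseMatrix(
    i = c(E[, 1L], E[, 2L]) + 1L,
    j = c(E[, 2L], E[, 1L]) + 1L,
    x = 1, dims = c(nv, nv)
  )
}

#' @export
print.hodge_operators <- function(x, ...) {
  cat(sprintf("<hodge_operators> max_dim %d, total Laplacian %d x %d\n",
              x$complex$max_dim, nrow(x$Ltotal), ncol(x$Ltotal)))
  invisible(x)
}

#' Betti numbers from Hodge Laplacian kernels
#'
#' The multiplicity of the zero eigenvalue of `L_m` equals the m-th Betti
#' number: `beta_0` counts connected components, `beta_1` independent
#' cycles not bounding filled triangles, and so on. Computed by numerical
#' rank with tolerance `tol` times the largest eigenvalue (exact integer
#' homology is out of scope).
#'
#' @param K A `simplicial_complex`, or a precomputed `hodge_operators`.
#' @param tol Relative eigenvalue tolerance for counting zeros.
#' @return Integer vector `beta_0 .. beta_M`.
#' @export
betti_numbers <- function(K, tol = 1e-8) {
  H <- if (inherits(K, "hodge_operators")) K else hodge_laplacians(K)
  vapply(H$Lm, function(L) {
    ev <- eigen(as.matrix(Matrix::forceSymmetric(L)), symmetric = TRUE, only.values = TRUE)$values
    scale <- max(abs(ev), 1)
    sum(abs(ev) < tol * scale)
  }, 1L)
}
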