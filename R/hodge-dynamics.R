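#' Spectral solution of linear diffusion x' = -L x
#'
#' Diagonalizes the symmetric PSD operator once and evaluates
#' `x(t) = sum_j exp(-t * mu_j) (psi_j' x0) psi_j` on the requested grid.
#' For a connected graph Laplacian this converges to the constant vector
#' holding the mean of the initial state; blocks of a Hodge Laplacian with
#' vanishing Betti number instead decay to zero.
#'
#' @param L Symmetric positive semidefinite matrix (dense or `Matrix`).
#' @param x0 Initial state, length `nrow(L)`.
#' @param times Non-negative, increasing time grid.
#' @param gamma Diffusivity; the generator is `-gamma * L`. Default 1.
#' @return Matrix of states, one column per time.
#' @export
spectral_solution <- function(L, x0, times, gamma = 1) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L) || max(abs(L - t(L))) > 1e-10 * max(abs(L), 1)) {
    stop("L must be a symmetric square matrix", call. = FALSE)
  }
  if (length(x0) != nrow(L)) stop("x0 length must equal dim(L)", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be increasing", call. = FALSE)
  es <- eigen((L + t(L)) / 2, symmetric = TRUE)
  coef <- drop(crossprod(es$vectors, x0))
  out <- vapply(times, function(t) {
    drop(es$vectors %*% (exp(-gamma * t * es$values) * coef))
  }, numeric(length(x0)))
  out <- matrix(out, nrow = length(x0))
  dimnames(out) <- list(names(x0), NULL)
  out
}

#' Diffuse a block state under the total Hodge Laplacian
#'
#' Runs `x' = -L x` with `L` the block-diagonal total Laplacian, one scalar
#' per simplex. Each dimension evolves independently under its own `L_m`;
#' there is no exchange across dimensions, which is precisely the pathology
#' the metaplex model removes.
#'
#' @param H A [hodge_laplacians()] result.
#' @param x0 Initial block state: a numeric vector in block order
#'   (dimension-major, lexicographic), or a data frame with columns
#'   `simplex` (labels as in [simplex_labels()]) and `mass`.
#' @param times Increasing time grid.
#' @param gamma Diffusivity.
#' @return A `hodge_trajectory`: list with `times`, `states`
#'   (simplex x time matrix), `totals` (alias of `states`; each simplex is
#'   a point mass under this model), `labels`, `dims`, and `operators`.
#' @export
simulate_hodge <- function(H, x0, times, gamma = 1) {
  stopifnot(inherits(H, "hodge_operators"))
  labels <- simplex_labels(H$complex)
  if (is.data.frame(x0)) x0 <- block_state_from_table(H$complex, x0)
  if (length(x0) != nrow(H$Ltotal)) {
    stop(sprintf("x0 has length %d; total Laplacian needs %d", length(x0), nrow(H$Ltotal)),
         call. = FALSE)
  }
  states <- spectral_solution(H$Ltotal, x0, times, gamma = gamma)
  rownames(states) <- labels
  cnt <- vapply(H$complex$simplices, nrow, 1L)
  structure(
    list(
      times = times, states = states, totals = states, labels = labels,
      dims = rep(seq_along(cnt) - 1L, cnt), operators = H
    ),
    class = "hodge_trajectory"
  )
}

# per-simplex mass table -> block vector in Ltotal order
block_state_from_table <- function(K, tab) {
  tab <- as.data.frame(tab)
  if (!all(c("simplex", "mass") %in% names(tab))) {
    stop("initial-condition table needs columns `simplex` and `mass`", call. = FALSE)
  }
  labels <- simplex_labels(K)
  x0 <- stats::setNames(numeric(length(labels)), labels)
  idx <- match(tab$simplex, labels)
  if (anyNA(idx)) {
    stop("unknown simplex id: ", tab$simplex[which(is.na(idx))[1L]], call. = FALSE)
  }
  x0[idx] <- tab$mass
  x0
}

#' Deflate the lowest nonzero mode of a PSD operator
#'
#' Returns `L - lambda1 * v1 %*% t(v1)` where `lambda1` is the smallest
#' nonzero eigenvalue and `v1` its (unit) eigenvector, sending that mode to
#' the kernel so it persists instead of decaying.
#'
#' @param L Symmetric PSD matrix.
#' @param tol Relative tolerance separating zero from nonzero eigenvalues.
#' @return Dense deflated matrix with attributes `lambda1` and `v1`.
#' @export
deflated_operator <- function(L, tol = 1e-10) {
  L <- as.matrix(L)
  es <- eigen((L + t(L)) / 2, symmetric = TRUE)
  scale <- max(abs(es$values), 1)
  nz <- which(es$values > tol * scale)
  if (length(nz) == 0L) stop("operator has no nonzero eigenvalue to deflate", call. = FALSE)
  k <- nz[length(nz)]  # eigen() sorts decreasing; last nonzero is the smallest
  lambda1 <- es$values[k]
  v1 <- es$vectors[, k]
  out <- L - lambda1 * tcrossprod(v1)
  attr(out, "lambda1") <- lambda1
  attr(out, "v1") <- v1
  out
}

#' Diagnostics of a Hodge-Laplacian trajectory
#'
#' Summarizes the run: the global minimum and where/when it is attained
#' (negative values flag the loss of positivity), total block mass over
#' time (non-constant: the model is not conservative), per-dimension
#' steady states, and whether all blocks reach one common constant.
#'
#' @param traj A [simulate_hodge()] result.
#' @param tol Tolerance for consensus and steady-state comparisons.
#' @return A list of class `hodge_diagnostics`: `min_value`, `min_simplex`,
#'   `min_time`, `mass` (tibble time/total), `steady_by_dim` (tibble),
#'   `reaches_global_consensus`.
#' @export
hodge_diagnostics <- function(traj, tol = 1e-6) {
  stopifnot(inherits(traj, "hodge_trajectory"))
  st <- traj$states
  amin <- arrayInd(which.min(st), dim(st))
  final <- st[, ncol(st)]
  steady <- tibble::tibble(
    dim = sort(unique(traj$dims)),
    steady_min = vapply(sort(unique(traj$dims)), function(d) min(final[traj$dims == d]), 1),
    steady_max = vapply(sort(unique(traj$dims)), function(d) max(final[traj$dims == d]), 1)
  )
  consensus <- max(final) - min(final) < tol
  structure(
    list(
      min_value = st[amin[1L], amin[2L]],
      min_simplex = traj$labels[amin[1L]],
      min_time = traj$times[amin[2L]],
      mass = tibble::tibble(time = traj$times, total = colSums(st)),
      steady_by_dim = steady,
      reaches_global_consensus = consensus
    ),
    class = "hodge_diagnostics"
  )
}

#' @export
print.hodge_diagnostics <- function(x, ...) {
  cat(sprintf("<hodge_diagnostics> min %.4g at %s (t = %.4g); global consensus: %s\n",
              x$min_value, x$min_simplex, x$min_time, x$reaches_global_consensus))
  drift <- max(x$mass$total) - min(x$mass$total)
  cat(sprintf("  total block mass drifts by %.4g over the run\n", drift))
  invisible(x)
}

#' @method tidy hodge_trajectory
#' @export
tidy.hodge_trajectory <- function(x, ...) {
  df <- as.data.frame(x$states)
  names(df) <- as.character(seq_along(x$times))
  df$simplex <- x$labels
  df$dim <- x$dims
  out <- tidyr::pivot_longer(df, cols = -c("simplex", "dim"),
                             names_to = ".tidx", values_to = "value")
  out$time <- x$times[as.integer(out$.tidx)]
  out$.tidx <- NULL
  tibble::as_tibble(out[, c("simplex", "dim", "time", "value")])
}

#' @method glance hodge_trajectory
#' @export
glance.hodge_trajectory <- function(x, ...) {
  d <- hodge_diagnostics(x)
  tibble::tibble(
    n_simplices = length(x$labels),
    min_value = d$min_value,
    mass_drift = max(d$mass$total) - min(d$mass$total),
    reaches_global_consensus = d$reaches_global_consensus
  )
}

#' @method autoplot hodge_trajectory
#' @export
autoplot.hodge_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   group = .data$simplex,
                                   colour = factor(.data$dim))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time", y = "block state", colour = "dim",
                  title = "Hodge-Laplacian diffusion per simplex") +
    ggplot2::theme_minimal()
}
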