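#' Discretize a reference simplex as a continuous diffusion domain
#'
#' Each simplex of a metaplex carries a continuous domain solved by
#' piecewise-linear (P1) finite elements with a lumped (diagonal) mass
#' matrix:
#' \itemize{
#'   \item dim 0: a single point, zero stiffness, unit mass;
#'   \item dim 1: the unit segment as a path of `n` nodes, tridiagonal P1
#'     stiffness with zero row sums, lumped mass summing to the unit
#'     length;
#'   \item dim 2: the unit equilateral triangle under a uniform structured
#'     triangulation with `n` nodes per side, hence `n * (n + 1) / 2` nodes
#'     in total; every element is equilateral, so the assembled stiffness
#'     has non-positive off-diagonals (an M-matrix, which is what makes the
#'     coupled diffusion positivity-preserving). The lumped mass is
#'     rescaled from the geometric area `sqrt(3) / 4` so the domain has
#'     unit measure, putting every simplex on an equal footing in the
#'     consensus state.
#' }
#' Boundary faces are listed per (dim-1)-face in increasing-corner order:
#' side `"0-1"` runs from local corner 0 to corner 1, and so on; a segment
#' exposes its endpoints as faces `"0"` and `"1"`. With simplices stored as
#' increasing vertex tuples this makes face node lists of neighbouring
#' domains align one-to-one without any extra orientation bookkeeping.
#'
#' @param dim Simplex dimension: 0, 1 or 2. Tetrahedral domains are not
#'   supported (the complex may hold 3-simplices, but they cannot be
#'   discretized).
#' @param nodes_per_edge Number of nodes per side, `n >= 2`.
#' @return An object of class `smx_domain`: `dim`, `n_nodes`, `coords`
#'   (nodes x 2 reference coordinates), `stiffness` (sparse symmetric,
#'   zero row sums), `mass` (positive vector summing to 1), `faces` (named
#'   list of local node index vectors).
#' @export
#' @examples
#' d <- discretize_simplex(2, 20)
#' d$n_nodes            # 210
#' sum(d$mass)          # 1
discretize_simplex <- function(dim, nodes_per_edge = 20L) {
  dim <- as.integer(dim)
  n <- as.integer(nodes_per_edge)
  if (dim == 3L) stop("3-simplex (tetrahedral) domains are not supported", call. = FALSE)
  if (dim < 0L || dim > 2L) stop("dim must be 0, 1 or 2", call. = FALSE)
  if (dim > 0L && n < 2L) stop("nodes_per_edge must be >= 2", call. = FALSE)
  out <- switch(dim + 1L, domain_point(), domain_segment(n), domain_triangle(n))
  structure(out, class = "smx_domain")
}

domain_point <- function() {
  list(
    dim = 0L, n_nodes = 1L,
    coords = matrix(0, 1L, 2L),
    stiffness = Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(1L, 1L)),
    mass = 1,
    faces = list()
  )
}

domain_segment <- function(n) {
  h <- 1 / (n - 1)
  diag_v <- c(1, rep(2, n - 2L), 1) / h
  i <- c(seq_len(n), seq_len(n - 1L), seq_len(n - 1L) + 1L)
  j <- c(seq_len(n), seq_len(n - 1L) + 1L, seq_len(n - 1L))
  x <- c(diag_v, rep(-1 / h, 2L * (n - 1L)))
  list(
    dim = 1L, n_nodes = n,
    coords = cbind(seq(0, 1, length.out = n), 0),
    stiffness = Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n)),
    mass = c(h / 2, rep(h, n - 2L), h / 2),
    faces = list(`0` = 1L, `1` = n)
  )
}

# uniform triangulation of the unit equilateral triangle, n nodes per side;
# rows r = 0..n-1 from the bottom side, row r holding n - r nodes
domain_triangle <- function(n) {
  h <- 1 / (n - 1)
  row_start <- cumsum(c(0L, (n):(1L)))[seq_len(n)]  # 0-based offsets per row
  node_id <- function(r, c) row_start[r + 1L] + c + 1L
  coords <- matrix(0, (n * (n + 1L)) %/% 2L, 2L)
  for (r in 0:(n - 1L)) {
    cs <- 0:(n - 1L - r)
    coords[node_id(r, cs), 1L] <- cs * h + r * h / 2
    coords[node_id(r, cs), 2L] <- r * h * sqrt(3) / 2
  }
  # every element is equilateral: the P1 stiffness depends only on angles
  # (cot 60 / 2 = 1 / (2 sqrt(3)) off-diagonal)
  k_off <- -1 / (2 * sqrt(3))
  tris <- list()
  for (r in 0:(n - 2L)) {
    width <- n - 1L - r
    up <- cbind(node_id(r, 0:(width - 1L)),
                node_id(r, 1:width),
                node_id(r + 1L, 0:(width - 1L)))
    tris[[length(tris) + 1L]] <- up
    if (width >= 2L) {
      down <- cbind(node_id(r, 1:(width - 1L)),
                    node_id(r + 1L, 0:(width - 2L)),
                    node_id(r + 1L, 1:(width - 1L)))
      tris[[length(tris) + 1L]] <- down
    }
  }
  tris <- do.call(rbind, tris)
  pair <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  ii <- c(tris[, pair[, 1L]], tris[, pair[, 2L]])
  jj <- c(tris[, pair[, 2L]], tris[, pair[, 1L]])
  n_nodes <- as.integer(n * (n + 1L) / 2L)
  Kmat <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(k_off, length(ii)),
                               dims = c(n_nodes, n_nodes))
  Matrix::diag(Kmat) <- 0
  Matrix::diag(Kmat) <- -Matrix::rowSums(Kmat)
  # lumped mass: element area / 3 per vertex, then rescale total measure
  # from the geometric area sqrt(3)/4 to 1
  area_el <- sqrt(3) / 4 * h^2
  mass <- numeric(n_nodes)
  cnt <- tabulate(as.vector(tris), nbins = n_nodes)
  mass <- cnt * area_el / 3
  mass <- mass / sum(mass)
  faces <- list(
    `0-1` = node_id(0L, 0:(n - 1L)),
    `0-2` = node_id(0:(n - 1L), 0L),
    `1-2` = vapply(0:(n - 1L), function(r) node_id(r, n - 1L - r), 1L)
  )
  list(dim = 2L, n_nodes = n_nodes, coords = coords,
       stiffness = Kmat, mass = mass, faces = faces)
}

#' @export
print.smx_domain <- function(x, ...) {
  cat(sprintf("<smx_domain> dim %d, %d nodes, measure %.6f\n",
              x$dim, x$n_nodes, sum(x$mass)))
  invisible(x)
}

#' Plot the node layout of a discretized domain
#'
#' @param domain An [discretize_simplex()] result.
#' @param values Optional per-node values to colour by (e.g. a density
#'   snapshot).
#' @return A ggplot object.
#' @export
plot_domain <- function(domain, values = NULL) {
  stopifnot(inherits(domain, "smx_domain"))
  df <- tibble::tibble(x = domain$coords[, 1L], y = domain$coords[, 2L])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (is.null(values)) {
    p <- p + ggplot2::geom_point(size = 1.5)
  } else {
    df$value <- values
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$value)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::scale_colour_viridis_c()
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal()
}
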