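#' Assemble a simplicial metaplex from a face-closed complex
#'
#' Every simplex becomes a continuous domain ([discretize_simplex()]) and
#' every (face, coface) incidence becomes a bidirectional sink-source: the
#' boundary nodes of the higher-dimensional domain are matched one-to-one
#' to the nodes of the face's own domain (triangle side to segment, segment
#' endpoint to point), each matched pair exchanging mass at a conductance.
#' Couplings exist only between simplices whose dimensions differ by one,
#' mirroring the incidence structure of the complex. Domains are ordered
#' dimension-major, lexicographic - the same block order as the total
#' Hodge Laplacian - so the two models are directly comparable.
#'
#' The semi-discrete dynamics are `D * du/dt = -S %*% u` for the density
#' vector `u`, with `D` the concatenated lumped masses and
#' `S = blockdiag(stiffness) + C`, `C` the coupling Laplacian (for a
#' matched pair `(a, b)` with conductance `k`: `+k` on both diagonals,
#' `-k` on both off-diagonal entries). `S` is symmetric with zero column
#' sums, so total mass `sum(D * u)` is conserved exactly, and `-S` is
#' Metzler, so nonnegative states stay nonnegative.
#'
#' @param K A `simplicial_complex` of dimension at most 2 (3-simplices in
#'   `K` raise an error: tetrahedral domains are not supported).
#' @param nodes_per_edge Mesh resolution `n` shared by all domains.
#' @param kappa Conductance scale.
#' @param kappa_mode `"per_pair"`: every matched pair gets conductance
#'   `kappa` (pairs behave as unit-weight graph edges); `"normalized"`:
#'   each sink-source distributes `kappa` across its pairs
#'   (`kappa / n_pairs` each), making the domain-level exchange rate
#'   resolution-independent.
#' @return An object of class `metaplex`; see Details for fields.
#' @export
#' @examples
#' K <- fig4_complex()
#' M <- build_metaplex(K, nodes_per_edge = 5)
#' M$n_dof   # 5 vertices + 6 segments of 5 + 2 triangles of 15
build_metaplex <- function(K, nodes_per_edge = 20L, kappa = 1,
                           kappa_mode = c("per_pair", "normalized")) {
  stopifnot(inherits(K, "simplicial_complex"))
  kappa_mode <- match.arg(kappa_mode)
  if (K$max_dim > 2L) {
    stop("metaplex discretization supports complexes of dimension <= 2 ",
         "(3-simplices cannot be meshed)", call. = FALSE)
  }
  n <- as.integer(nodes_per_edge)
  ref <- lapply(0:K$max_dim, function(d) discretize_simplex(d, n))
  cnt <- vapply(K$simplices, nrow, 1L)
  dims <- rep(seq_along(cnt) - 1L, cnt)
  domains <- lapply(dims, function(d) ref[[d + 1L]])
  labels <- simplex_labels(K)

  # domain index of a simplex tuple, in block order
  base <- cumsum(c(0L, cnt))
  dom_of <- function(tuple) {
    m <- length(tuple) - 1L
    base[m + 1L] + simplex_index(K, tuple)
  }

  sink_sources <- list()
  for (m in seq_len(K$max_dim)) {
    S <- K$simplices[[m + 1L]]
    for (r in seq_len(nrow(S))) {
      simp <- S[r, ]
      hi <- dom_of(simp)
      dom_hi <- domains[[hi]]
      for (fk in names(dom_hi$faces)) {
        face_tuple <- simp[as.integer(strsplit(fk, "-", fixed = TRUE)[[1L]]) + 1L]
        lo <- dom_of(face_tuple)
        pairs <- cbind(dom_hi$faces[[fk]], seq_along(dom_hi$faces[[fk]]))
        sink_sources[[length(sink_sources) + 1L]] <-
          list(i = hi, j = lo, pairs = pairs)
      }
    }
  }
  new_metaplex(domains, sink_sources, labels, dims,
               kappa = kappa, kappa_mode = kappa_mode,
               complex = K, nodes_per_edge = n)
}

# shared constructor: computes offsets, per-pair conductances and the
# assembled (D, S) generator
new_metaplex <- function(domains, sink_sources, labels, dims,
                         kappa = 1, kappa_mode = "per_pair",
                         complex = NULL, nodes_per_edge = NA_integer_) {
  sizes <- vapply(domains, function(d) d$n_nodes, 1L)
  offsets <- cumsum(c(0L, sizes))[seq_along(domains)]
  # simplicial metaplexes inherit the incidence structure: couplings only
  # between dimension-adjacent simplices; free-form metaplexes are exempt
  enforce_gap <- !is.null(complex)
  sink_sources <- lapply(sink_sources, function(ss) {
    npair <- nrow(ss$pairs)
    ss$kappa_pair <- if (kappa_mode == "normalized") kappa / npair else kappa
    if (enforce_gap && abs(domains[[ss$i]]$dim - domains[[ss$j]]$dim) != 1L) {
      stop("sink-source may only join domains whose dimensions differ by one",
           call. = FALSE)
    }
    ss
  })
  M <- structure(
    list(
      domains = domains, sink_sources = sink_sources,
      labels = labels, dims = dims,
      offsets = offsets, n_dof = sum(sizes),
      measure = vapply(domains, function(d) sum(d$mass), 1),
      kappa = kappa, kappa_mode = kappa_mode,
      complex = complex, nodes_per_edge = nodes_per_edge
    ),
    class = "metaplex"
  )
  gen <- assemble_generator(M)
  M$D <- gen$D
  M$S <- gen$S
  M
}

#' Mass vector and flow matrix of the metaplex dynamics
#'
#' Recomputes the pair `(D, S)` defining `D * du/dt = -S %*% u`:
#' `D` concatenates the lumped masses of all domains; `S` is the
#' block-diagonal stiffness plus the sink-source coupling Laplacian.
#'
#' @param M A [build_metaplex()] result (or any `metaplex`).
#' @return List with `D` (numeric vector) and `S` (sparse symmetric
#'   matrix with zero row and column sums).
#' @export
assemble_generator <- function(M) {
  stopifnot(inherits(M, "metaplex") || is.list(M))
  D <- unlist(lapply(M$domains, function(d) d$mass), use.names = FALSE)
  S <- Matrix::bdiag(lapply(M$domains, function(d) d$stiffness))
  if (length(M$sink_sources) > 0L) {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (ss in M$sink_sources) {
      a <- M$offsets[ss$i] + ss$pairs[, 1L]
      b <- M$offsets[ss$j] + ss$pairs[, 2L]
      k <- ss$kappa_pair
      ii <- c(ii, a, b, a, b)
      jj <- c(jj, a, b, b, a)
      xx <- c(xx, rep(k, 2L * length(a)), rep(-k, 2L * length(a)))
    }
    C <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(M$n_dof, M$n_dof))
    S <- S + C
  }
  list(D = D, S = methods::as(S, "generalMatrix"))
}

#' Domain-level transition matrix of a metaplex
#'
#' Collapses the sink-source couplings to a matrix over domains: the
#' off-diagonal `(i, j)` entry is the total conductance flowing from
#' domain `j` into domain `i`, and each diagonal entry is minus the total
#' conductance leaving that domain, so columns sum to zero. Distinct
#' metaplexes can share a transition matrix yet behave differently - the
#' matrix records how much the domains exchange, not where on the domains
#' the exchange happens.
#'
#' @param M A `metaplex`.
#' @return Dense square matrix over domains, dimnames from simplex labels.
#' @export
transition_matrix <- function(M) {
  stopifnot(inherits(M, "metaplex"))
  nd <- length(M$domains)
  Tm <- matrix(0, nd, nd, dimnames = list(M$labels, M$labels))
  for (ss in M$sink_sources) {
    k_tot <- ss$kappa_pair * nrow(ss$pairs)
    Tm[ss$i, ss$j] <- Tm[ss$i, ss$j] + k_tot
    Tm[ss$j, ss$i] <- Tm[ss$j, ss$i] + k_tot
    Tm[ss$i, ss$i] <- Tm[ss$i, ss$i] - k_tot
    Tm[ss$j, ss$j] <- Tm[ss$j, ss$j] - k_tot
  }
  Tm
}

#' @export
print.metaplex <- function(x, ...) {
  tab <- table(x$dims)
  cat(sprintf("<metaplex> %d domains (%s), %d DOFs, %d sink-sources, kappa = %g (%s)\n",
              length(x$domains),
              paste(sprintf("%d of dim %s", as.integer(tab), names(tab)), collapse = ", "),
              x$n_dof, length(x$sink_sources), x$kappa, x$kappa_mode))
  invisible(x)
}

#' @method tidy metaplex
#' @export
tidy.metaplex <- function(x, ...) {
  tibble::tibble(
    simplex = x$labels,
    dim = x$dims,
    n_nodes = vapply(x$domains, function(d) d$n_nodes, 1L),
    measure = x$measure,
    offset = x$offsets
  )
}

#' @method glance metaplex
#' @export
glance.metaplex <- function(x, ...) {
  tibble::tibble(
    n_domains = length(x$domains),
    n_dof = x$n_dof,
    n_sink_sources = length(x$sink_sources),
    total_measure = sum(x$measure),
    kappa = x$kappa,
    kappa_mode = x$kappa_mode
  )
}

#' Export the metaplex generator as plain-text files
#'
#' Writes `S` in MatrixMarket format, plus CSV tables for the mass vector
#' and the domain layout, next to the given stem.
#'
#' @param M A `metaplex`.
#' @param stem Path prefix; files `<stem>_S.mtx`, `<stem>_mass.csv`,
#'   `<stem>_domains.csv` are created.
#' @return The three paths, invisibly.
#' @export
write_metaplex <- function(M, stem) {
  stopifnot(inherits(M, "metaplex"))
  p1 <- paste0(stem, "_S.mtx")
  p2 <- paste0(stem, "_mass.csv")
  p3 <- paste0(stem, "_domains.csv")
  Matrix::writeMM(methods::as(M$S, "CsparseMatrix"), p1)
  utils::write.csv(data.frame(dof = seq_len(M$n_dof), mass = M$D), p2, row.names = FALSE)
  utils::write.csv(as.data.frame(tidy(M)), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
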