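#' Five-vertex reference complex with two filled triangles
#'
#' The small complex used throughout the package's examples and tests:
#' vertices 1..5, edges (1,2), (1,3), (2,3), (3,4), (3,5), (4,5) and the
#' filled triangles (1,2,3) and (3,4,5) - the minimal face-closed complex
#' containing those two triangles. It is connected, has Euler
#' characteristic 1 and Betti numbers (1, 0, 0), which makes it the
#' smallest interesting stage for the Hodge-diffusion pathologies: every
#' edge/triangle mode decays to zero while the vertex block reaches its
#' own consensus.
#'
#' @return A `simplicial_complex`.
#' @export
fig4_complex <- function() {
  g <- smx_graph(data.frame(
    from = c(1, 1, 2, 3, 3, 4),
    to   = c(2, 3, 3, 4, 5, 5)
  ))
  clique_complex(g, max_dim = 2L)
}

#' Seeded random clique complex
#'
#' An Erdos-Renyi G(n, p) graph (igraph's generator under a fixed seed)
#' promoted to its clique complex. Used as a deterministic synthetic
#' stand-in for empirical networks such as cortical connectomes.
#'
#' @param n_vertices Number of vertices.
#' @param p_edge Edge probability in `[0, 1]`.
#' @param seed Integer seed; the same spec always yields the same complex.
#' @param max_dim Passed to [clique_complex()].
#' @return A `simplicial_complex`.
#' @export
random_clique_complex <- function(n_vertices, p_edge, seed = 1L, max_dim = 2L) {
  stopifnot(p_edge >= 0, p_edge <= 1)
  set.seed(seed)
  ig <- igraph::sample_gnp(n_vertices, p_edge)
  el <- igraph::as_edgelist(ig)
  labels <- sprintf("v%03d", seq_len(n_vertices))
  if (nrow(el) == 0L) {
    g <- smx_graph(data.frame(from = character(0), to = character(0)), vertices = labels)
  } else {
    g <- smx_graph(data.frame(from = labels[el[, 1L]], to = labels[el[, 2L]]),
                   vertices = labels)
  }
  clique_complex(g, max_dim = max_dim)
}

#' Two segment domains joined by a single sink-source
#'
#' A minimal metaplex of two unit segments exchanging mass through one
#' matched node pair of unit conductance. Both variants collapse to the
#' same domain-level transition matrix `[[-1, 1], [1, -1]]`, yet their
#' dynamics differ: with `separated = FALSE` the coupling joins the
#' adjoining endpoints (right end of the first segment to left end of the
#' second); with `separated = TRUE` it joins the far endpoints (left end
#' of the first to right end of the second), so mass placed near the right
#' end of the first segment must traverse the whole domain before it can
#' leave. The transition matrix alone therefore does not determine the
#' transient behaviour - the placement of sinks and sources inside the
#' domains matters.
#'
#' @param separated Logical; see Description.
#' @param nodes_per_edge Segment resolution.
#' @param kappa Conductance of the single matched pair.
#' @return A `metaplex` with two dim-1 domains.
#' @export
two_domain_metaplex <- function(separated = FALSE, nodes_per_edge = 21L, kappa = 1) {
  n <- as.integer(nodes_per_edge)
  dom <- discretize_simplex(1L, n)
  pairs <- if (separated) cbind(1L, n) else cbind(n, 1L)
  new_metaplex(
    domains = list(dom, dom),
    sink_sources = list(list(i = 1L, j = 2L, pairs = pairs)),
    labels = c("1:a-b", "1:c-d"),
    dims = c(1L, 1L),
    kappa = kappa, kappa_mode = "per_pair",
    nodes_per_edge = n
  )
}

#' Three filled triangles sharing edges in a chain
#'
#' The clique complex of the [fig4_complex()] graph with the extra edge
#' (2,4): triangles (1,2,3), (2,3,4) and (3,4,5) each share an edge with
#' the next. Because adjacent triangles now couple through the curl term
#' of the edge Laplacian, this is the smallest fixture on which the
#' higher-order diffusion visibly loses positivity: mass seeded on
#' triangle (1,2,3) drives neighbouring components negative.
#'
#' @return A `simplicial_complex` with counts (5, 7, 3).
#' @export
triangle_chain_complex <- function() {
  g <- smx_graph(data.frame(
    from = c(1, 1, 2, 2, 3, 3, 4),
    to   = c(2, 3, 3, 4, 4, 5, 5)
  ))
  clique_complex(g, max_dim = 2L)
}
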