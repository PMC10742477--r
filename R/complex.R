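#' Build the clique complex of a graph
#'
#' The clique complex promotes every (m+1)-clique of the graph to an
#' m-simplex: vertices become 0-simplices, edges 1-simplices, triangles
#' 2-simplices, and 4-cliques tetrahedra when `max_dim >= 3`. The result is
#' closed under faces by construction, and simplices are stored in canonical
#' order: strictly increasing vertex tuples, listed lexicographically within
#' each dimension, so rebuilding from a shuffled edge list yields identical
#' operators.
#'
#' @param g An [smx_graph()].
#' @param max_dim Highest simplex dimension to include (0 to 3).
#' @return An object of class `simplicial_complex` with fields
#'   `max_dim`, `simplices` (list indexed by dimension `m + 1`, each an
#'   integer matrix with `m + 1` columns of 0-based vertex ids, rows in
#'   lexicographic order) and `labels` (vertex labels from the graph).
#' @export
#' @examples
#' g <- smx_graph(data.frame(c("a", "b", "a"), c("b", "c", "c")))
#' K <- clique_complex(g, max_dim = 2)
#' simplex_counts(K)
clique_complex <- function(g, max_dim = 2L) {
  stopifnot(inherits(g, "smx_graph"))
  max_dim <- as.integer(max_dim)
  if (max_dim < 0L) stop("max_dim must be >= 0", call. = FALSE)
  if (max_dim > 3L) stop("max_dim is capped at 3", call. = FALSE)
  nv <- length(g$labels)
  simplices <- list(matrix(seq_len(nv) - 1L, ncol = 1L))
  if (max_dim >= 1L && nrow(g$edges) > 0L) {
    simplices[[2L]] <- g$edges
  }
  if (max_dim >= 2L && nrow(g$edges) > 0L) {
    adj <- adjacency_sets(g)
    for (m in 2:max_dim) {
      lower <- simplices[[m]]
      if (is.null(lower) || nrow(lower) == 0L) break
      ext <- extend_cliques(lower, adj)
      if (nrow(ext) == 0L) break
      simplices[[m + 1L]] <- ext
    }
  }
  simplices <- simplices[!vapply(simplices, is.null, TRUE)]
  structure(
    list(
      max_dim = length(simplices) - 1L,
      simplices = simplices,
      labels = g$labels
    ),
    class = "simplicial_complex"
  )
}

# adjacency as a list of sorted 0-based neighbour vectors
adjacency_sets <- function(g) {
  nv <- length(g$labels)
  adj <- vector("list", nv)
  for (v in seq_len(nv)) adj[[v]] <- integer(0)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1L]; j <- g$edges[r, 2L]
    adj[[i + 1L]] <- c(adj[[i + 1L]], j)
    adj[[j + 1L]] <- c(adj[[j + 1L]], i)
  }
  lapply(adj, sort)
}

# extend each (k+1)-clique by a vertex larger than its maximum that is
# adjacent to every member; keeps lexicographic order of the input
extend_cliques <- function(cliques, adj) {
  out <- vector("list", nrow(cliques))
  for (r in seq_len(nrow(cliques))) {
    cl <- cliques[r, ]
    cand <- adj[[cl[1L] + 1L]]
    for (v in cl[-1L]) cand <- intersect(cand, adj[[v + 1L]])
    cand <- cand[cand > cl[length(cl)]]
    if (length(cand) > 0L) {
      out[[r]] <- cbind(matrix(cl, nrow = length(cand), ncol = length(cl), byrow = TRUE), cand)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(matrix(integer(0), ncol = ncol(cliques) + 1L))
  }
  ext <- do.call(rbind, out)
  ext[do.call(order, as.data.frame(ext)), , drop = FALSE]
}

#' Count simplices per dimension
#'
#' @param K A `simplicial_complex`.
#' @return A tibble with columns `dim` and `count`.
#' @export
simplex_counts <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  tibble::tibble(
    dim = seq_along(K$simplices) - 1L,
    count = vapply(K$simplices, nrow, 1L)
  )
}

#' Canonical labels of all simplices, in total-Laplacian block order
#'
#' Labels have the form `"dim:v0-v1-..."` using original vertex labels;
#' order is dimension-major, lexicographic within dimension, matching the
#' block order of the total Hodge Laplacian and the metaplex DOF layout.
#'
#' @param K A `simplicial_complex`.
#' @return Character vector of simplex labels.
#' @export
simplex_labels <- function(K) {
  stopifnot(inherits(K, "simplicial_complex"))
  unlist(lapply(seq_along(K$simplices), function(mi) {
    S <- K$simplices[[mi]]
    apply(S, 1L, function(row) {
      paste0(mi - 1L, ":", paste(K$labels[row + 1L], collapse = "-"))
    })
  }), use.names = FALSE)
}

#' @export
print.simplicial_complex <- function(x, ...) {
  cnt <- vapply(x$simplices, nrow, 1L)
  cat(sprintf("<simplicial_complex> max_dim %d; %s\n", x$max_dim,
              paste(sprintf("%d %d-simplices", cnt, seq_along(cnt) - 1L), collapse = ", ")))
  invisible(x)
}

# row index of a simplex tuple (0-based vertex ids, strictly increasing)
# within its dimension's canonical list; NA if absent
simplex_index <- function(K, tuple) {
  m <- length(tuple) - 1L
  if (m + 1L > length(K$simplices)) return(NA_integer_)
  S <- K$simplices[[m + 1L]]
  key <- paste(tuple, collapse = ",")
  keys <- apply(S, 1L, paste, collapse = ",")
  match(key, keys)
}

# parse "dim:v0-v1-..." (original labels) into a 0-based tuple
parse_simplex_label <- function(K, label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("malformed simplex label: ", label, call. = FALSE)
  verts <- strsplit(parts[2L], "-", fixed = TRUE)[[1L]]
  ids <- match(verts, K$labels) - 1L
  if (anyNA(ids)) stop("unknown vertex label in simplex id: ", label, call. = FALSE)
  sort(ids)
}

#' Serialize a complex to JSON
#'
#' Writes `{"vertices": [labels], "simplices": {"0": [...], "1": [...]}}`
#' with vertex tuples in 0-based id space; [read_complex_json()] restores an
#' identical object.
#'
#' @param K A `simplicial_complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex_json <- function(K, path) {
  stopifnot(inherits(K, "simplicial_complex"))
  simp <- lapply(K$simplices, function(S) lapply(seq_len(nrow(S)), function(r) unname(S[r, ])))
  names(simp) <- as.character(seq_along(K$simplices) - 1L)
  jsonlite::write_json(
    list(vertices = K$labels, simplices = simp),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_complex_json
#' @export
read_complex_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  labels <- unlist(obj$vertices)
  simplices <- lapply(obj$simplices, function(lst) {
    m <- do.call(rbind, lapply(lst, function(x) as.integer(unlist(x))))
    m[do.call(order, as.data.frame(m)), , drop = FALSE]
  })
  names(simplices) <- NULL
  structure(
    list(max_dim = length(simplices) - 1L, simplices = simplices, labels = labels),
    class = "simplicial_complex"
  )
}

#' @method tidy simplicial_complex
#' @export
tidy.simplicial_complex <- function(x, ...) {
  tibble::tibble(
    simplex = simplex_labels(x),
    dim = rep(seq_along(x$simplices) - 1L, vapply(x$simplices, nrow, 1L))
  )
}

#' @method glance simplicial_complex
#' @export
glance.simplicial_complex <- function(x, ...) {
  cnt <- vapply(x$simplices, nrow, 1L)
  tibble::tibble(
    max_dim = x$max_dim,
    n_simplices = sum(cnt),
    n_vertices = cnt[1L],
    n_edges = if (length(cnt) >= 2L) cnt[2L] else 0L,
    n_triangles = if (length(cnt) >= 3L) cnt[3L] else 0L,
    euler_characteristic = sum(cnt * (-1L)^(seq_along(cnt) - 1L))
  )
}
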