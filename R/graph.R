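#' Construct a simple undirected graph from an edge table
#'
#' Vertices carry contiguous integer ids `0..k`, assigned in sorted order of
#' the original labels; the label mapping is retained so results can be
#' reported in the caller's vocabulary. Duplicate rows and reversed pairs
#' collapse to a single undirected edge.
#'
#' @param edges A two-column data frame (or matrix) of endpoint labels, one
#'   row per edge. Extra columns are ignored.
#' @param vertices Optional vector of vertex labels to include even when
#'   isolated (labels appearing in `edges` are always included).
#'
#' @return An object of class `smx_graph` with fields `labels` (character,
#'   position `i` is the label of vertex id `i - 1`), and `edges` (integer
#'   matrix, two columns, 0-based ids, each row sorted, rows in
#'   lexicographic order).
#' @export
#' @examples
#' g <- smx_graph(data.frame(from = c("a", "b", "a"), to = c("b", "c", "c")))
#' g$labels
#' g$edges
smx_graph <- function(edges, vertices = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("`edges` needs at least two columns", call. = FALSE)
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  loops <- which(a == b)
  if (length(loops) > 0L) {
    stop(sprintf("self-loop in edge row %d: '%s' -- '%s'", loops[1L], a[loops[1L]], b[loops[1L]]),
         call. = FALSE)
  }
  labels <- sort(unique(c(a, b, as.character(vertices))))
  ia <- match(a, labels) - 1L
  ib <- match(b, labels) - 1L
  em <- cbind(pmin(ia, ib), pmax(ia, ib))
  em <- unique(em)
  em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  structure(list(labels = labels, edges = em), class = "smx_graph")
}

#' Read a graph from an edge-list file
#'
#' TSV files hold one edge per line as two (or more) whitespace-separated
#' tokens; lines starting with `#` are comments. GraphML is parsed through
#' igraph. Either way the result is canonicalized by [smx_graph()]: labels
#' sorted, ids 0-based, duplicate and reversed edges collapsed.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"graphml"`.
#' @return An `smx_graph`.
#' @export
read_edge_list <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(ig, names = TRUE)
    if (nrow(el) == 0L) stop("graph has no edges: ", path, call. = FALSE)
    nm <- igraph::vertex_attr(ig, "name")
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(ig)))
    return(smx_graph(as.data.frame(el), vertices = nm))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no edges found in ", path, call. = FALSE)
  toks <- strsplit(lines, "[[:space:]]+")
  short <- which(vapply(toks, length, 1L) < 2L)
  if (length(short) > 0L) {
    stop(sprintf("edge row %d of %s has fewer than two tokens", short[1L], path), call. = FALSE)
  }
  smx_graph(data.frame(
    from = vapply(toks, `[[`, "", 1L),
    to   = vapply(toks, `[[`, "", 2L)
  ))
}

#' @export
print.smx_graph <- function(x, ...) {
  cat(sprintf("<smx_graph> %d vertices, %d edges\n", length(x$labels), nrow(x$edges)))
  invisible(x)
}

#' Vertex degrees of a graph
#'
#' @param g An `smx_graph`.
#' @return Integer vector of degrees, one per vertex id `0..k`.
#' @export
graph_degrees <- function(g) {
  stopifnot(inherits(g, "smx_graph"))
  tabulate(c(g$edges[, 1L], g$edges[, 2L]) + 1L, nbins = length(g$labels))
}
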