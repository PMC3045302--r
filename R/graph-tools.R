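# Graph queries on the gene network implied by the precision matrix: there is
# an edge between genes i and j iff the precision entry (i, j) is non-zero.

#' Gene graph from a zero pattern or fitted precision
#'
#' @param x a `zero_pattern`, `sparse_precision`, or symmetric matrix whose
#'   off-diagonal support defines the edges.
#' @param flagged_de,flagged_dc optional character/integer vectors of genes to
#'   record as differentially expressed / differentially connected node
#'   attributes.
#' @return an [igraph::graph] (undirected, no self-loops) with vertex
#'   attribute `name` and logical attributes `de`, `dc`.
#' @export
gene_graph <- function(x, flagged_de = NULL, flagged_dc = NULL) {
  if (inherits(x, "sparse_precision")) x <- x$pattern
  if (inherits(x, "zero_pattern")) {
    N <- x$N; genes <- x$genes
  } else {
    N <- methods::as(x, "CsparseMatrix")
    genes <- if (!is.null(rownames(N))) rownames(N) else
      paste0("g", seq_len(nrow(N)))
  }
  adj <- (N != 0) * 1
  Matrix::diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(Matrix::drop0(adj),
                                           mode = "undirected")
  igraph::V(g)$name <- genes
  to_names <- function(v) if (is.numeric(v)) genes[v] else v
  igraph::V(g)$de <- genes %in% to_names(flagged_de)
  igraph::V(g)$dc <- genes %in% to_names(flagged_dc)
  g
}

as_gene_graph <- function(x) {
  if (igraph::is_igraph(x)) x else gene_graph(x)
}

#' Maximal cliques of the gene graph
#'
#' Enumerates all maximal cliques (fully connected vertex sets not contained
#' in a larger one) using Bron-Kerbosch with pivoting; isolated genes are
#' singleton cliques. The clique submatrices of the sample covariance being
#' positive definite is exactly the condition for the pattern-constrained
#' MLE to exist.
#'
#' @param x a gene graph, `zero_pattern`, or `sparse_precision`.
#' @return list with `cliques` (list of integer vertex index vectors, each
#'   sorted, with gene names), and `size_table` (table of clique sizes).
#' @export
maximal_cliques <- function(x) {
  g <- as_gene_graph(x)
  cl <- igraph::max_cliques(g)
  cliques <- lapply(cl, function(v) {
    idx <- sort(as.integer(v))
    names(idx) <- igraph::V(g)$name[idx]
    idx
  })
  ord <- order(vapply(cliques, function(v) paste(v, collapse = ","),
                      character(1)))
  cliques <- cliques[ord]
  list(cliques = cliques,
       size_table = table(size = lengths(cliques)))
}

#' r-step neighbourhood of a gene
#'
#' The set of genes reachable from `gene` by traversing at most r edges,
#' returned as the induced subgraph. r = 1 gives the gene plus its
#' conditional-regression neighbours.
#'
#' @param x gene graph (or pattern/precision).
#' @param gene gene name or index.
#' @param r radius, non-negative integer.
#' @return induced subgraph (igraph).
#' @export
neighbourhood <- function(x, gene, r = 1) {
  g <- as_gene_graph(x)
  if (r < 0) stop("r must be >= 0", call. = FALSE)
  ball <- igraph::ego(g, order = r, nodes = gene)[[1]]
  igraph::induced_subgraph(g, ball)
}

#' Clusters of flagged genes
#'
#' Connected components of the subgraph induced by a flagged gene set (e.g.
#' all differentially expressed genes), with the distribution of cluster
#' sizes.
#'
#' @param x gene graph (or pattern/precision).
#' @param flagged gene names or indices.
#' @return list with `membership` (named integer vector over flagged genes),
#'   `clusters` (list of gene-name vectors), `size_table`.
#' @export
flagged_clusters <- function(x, flagged) {
  g <- as_gene_graph(x)
  sub <- igraph::induced_subgraph(g, flagged)
  comp <- igraph::components(sub)
  clusters <- split(igraph::V(sub)$name, comp$membership)
  list(membership = comp$membership, clusters = unname(clusters),
       size_table = table(size = comp$csize))
}

# Deterministic BFS shortest path with lexicographic tie-breaking on gene
# labels: among equally short predecessors the smallest label is taken.
#' Shortest path between two genes
#'
#' Unweighted shortest path; when several shortest paths exist the
#' lexicographically smallest (by gene label, walking from the target back)
#' is returned. `NULL` if the genes are disconnected.
#'
#' @param x gene graph (or pattern/precision).
#' @param from,to gene names or indices.
#' @return character vector of gene names along the path (inclusive), or
#'   `NULL`.
#' @export
shortest_gene_path <- function(x, from, to) {
  g <- as_gene_graph(x)
  d <- igraph::distances(g, v = from)[1, ]
  names(d) <- igraph::V(g)$name
  to_name <- if (is.character(to)) to else igraph::V(g)$name[to]
  if (!is.finite(d[[to_name]])) return(NULL)
  path <- to_name
  cur <- to_name
  while (d[[cur]] > 0) {
    nb <- igraph::neighbors(g, cur)$name
    cand <- sort(nb[d[nb] == d[[cur]] - 1])
    cur <- cand[1]
    path <- c(cur, path)
  }
  path
}

#' Nearest flagged gene
#'
#' The flagged gene at the smallest graph distance from `gene` (distance 0,
#' i.e. `gene` itself, is allowed if flagged); ties are broken by gene label.
#'
#' @param x gene graph (or pattern/precision).
#' @param gene query gene.
#' @param flagged candidate gene set.
#' @return list with `gene` (name, or `NA` if none reachable) and `distance`.
#' @export
nearest_flagged <- function(x, gene, flagged) {
  g <- as_gene_graph(x)
  to_names <- function(v) if (is.numeric(v)) igraph::V(g)$name[v] else v
  flagged <- to_names(flagged)
  d <- igraph::distances(g, v = gene, to = flagged)[1, ]
  names(d) <- flagged
  d <- d[is.finite(d)]
  if (length(d) == 0) return(list(gene = NA_character_, distance = Inf))
  best <- sort(names(d)[d == min(d)])[1]
  list(gene = best, distance = unname(d[best]))
}

#' Export the gene graph
#'
#' Writes GraphML (with `de`/`dc` node attributes preserved) or a two-column
#' edge-list TSV.
#'
#' @param x gene graph (or pattern/precision).
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_gene_graph <- function(x, path, format = c("graphml", "edgelist")) {
  g <- as_gene_graph(x)
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
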