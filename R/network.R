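#' Gene-gene interaction graphs
#'
#' An undirected graph of genetic and/or physical interactions, as exported
#' from BioGRID-style tab files. Self-loops are dropped and edges are
#' deduplicated per label (a pair may carry both a genetic and a physical
#' edge).
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `label`
#'   (values typically `"genetic"` / `"physical"`); or a 2-3 column
#'   data.frame in that order.
#' @return object of class `interaction_graph`: list with `edges` (the
#'   cleaned edge data.frame) and `nodes`.
#' @export
interaction_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    stopifnot(ncol(edges) >= 2L)
    names(edges)[1:2] <- c("gene_a", "gene_b")
  }
  if (!"label" %in% names(edges)) {
    edges$label <- if (ncol(edges) >= 3L) edges[[3L]] else "interaction"
  }
  edges <- edges[c("gene_a", "gene_b", "label")]
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]  # no self-loops
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a
  edges$gene_b <- b
  edges <- edges[!duplicated(edges[c("gene_a", "gene_b", "label")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b)))),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (", paste(unique(x$edges$label), collapse = "/"), ")\n")
  invisible(x)
}

#' Read a BioGRID-style tab-delimited edge list
#'
#' Expects at least two gene columns and optionally an interaction-type
#' column (genetic/physical).
#'
#' @param path TSV path with a header line.
#' @param gene_a_col,gene_b_col,label_col column names or indices.
#' @return an [interaction_graph()].
#' @export
read_interactions <- function(path, gene_a_col = 1L, gene_b_col = 2L,
                              label_col = 3L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lab <- if ((is.numeric(label_col) && ncol(df) >= label_col) ||
             (is.character(label_col) && label_col %in% names(df)))
    df[[label_col]] else "interaction"
  interaction_graph(data.frame(gene_a = df[[gene_a_col]],
                               gene_b = df[[gene_b_col]],
                               label = lab, stringsAsFactors = FALSE))
}

#' Number of interactions internal to a gene set
#'
#' Edges of the graph with both endpoints in the set ("total pairwise
#' connections"); genes absent from the graph contribute no edges.
#'
#' @param genes character vector of genes.
#' @param graph an [interaction_graph()].
#' @param label optional label filter (`"genetic"`, `"physical"`, ...).
#'   When off, multi-label pairs count once per label.
#' @return integer edge count.
#' @export
internal_edges <- function(genes, graph, label = NULL) {
  e <- graph$edges
  if (!is.null(label)) e <- e[e$label %in% label, , drop = FALSE]
  sum(e$gene_a %in% genes & e$gene_b %in% genes)
}

#' Permutation test for interaction enrichment in a gene set
#'
#' Compares the observed number of internal interactions to that of
#' `n_perm` randomly sampled gene sets of the same size, drawn uniformly
#' without replacement from the sampling frame (by default all graph nodes
#' plus any supplied assayed genes, so unannotated genes can be drawn).
#' The empirical p-value is the fraction of trials with an equal or
#' greater number of total pairwise connections than observed; with
#' `add_one` (default) the add-one estimator
#' `(1 + #{null >= obs}) / (n_perm + 1)` is used so p is never zero.
#'
#' @param genes character vector of genes (the called set).
#' @param graph an [interaction_graph()].
#' @param n_perm number of random networks (>= 1).
#' @param seed integer seed for reproducibility.
#' @param frame optional explicit sampling frame; overrides `assayed`.
#' @param assayed optional assayed genes added to the graph nodes to form
#'   the default frame.
#' @param label optional edge-label filter passed to [internal_edges()].
#' @param add_one use the add-one empirical p (raw fraction if `FALSE`).
#' @return list of class `perm_test`: `p`, `observed`, `null_counts`,
#'   `n_perm`, `frame_size`.
#' @export
permutation_enrichment <- function(genes, graph, n_perm = 1000L, seed = 1L,
                                   frame = NULL, assayed = NULL,
                                   label = NULL, add_one = TRUE) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  genes <- unique(as.character(genes))
  if (is.null(frame)) frame <- unique(c(graph$nodes, assayed, genes))
  if (length(genes) > length(frame))
    stop("gene set larger than the sampling frame")
  observed <- internal_edges(genes, graph, label)
  e <- graph$edges
  if (!is.null(label)) e <- e[e$label %in% label, , drop = FALSE]
  set.seed(seed)
  k <- length(genes)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    s <- sample(frame, k)
    sum(e$gene_a %in% s & e$gene_b %in% s)
  }, integer(1))
  hits <- sum(null_counts >= observed)
  p <- if (add_one) (1 + hits) / (n_perm + 1) else hits / n_perm
  structure(list(p = p, observed = observed, null_counts = null_counts,
                 n_perm = n_perm, frame_size = length(frame)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("permutation test: observed", x$observed, "internal edges; p =",
      format(x$p, digits = 4), "(", x$n_perm, "permutations )\n")
  invisible(x)
}
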