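#' Venn region counts across call sets
#'
#' Counts the genes in each of the `2^k - 1` non-empty membership regions
#' of `k` sets (e.g. the strains called after each pretreatment). Regions
#' partition the union.
#'
#' @param callsets named list of `call_set` objects or character vectors.
#' @return data.frame (`region`, one indicator column per set, `count`)
#'   with attribute `union_size`; region `"NaCl&HS"` means in NaCl and HS
#'   but in no other set.
#' @examples
#' overlap_table(list(A = c("x", "y"), B = c("y", "z")))
#' @export
overlap_table <- function(callsets) {
  sets <- lapply(callsets, function(s)
    unique(if (inherits(s, "call_set")) s$called else as.character(s)))
  nm <- names(sets)
  if (is.null(nm) || anyDuplicated(nm))
    stop("callsets must be uniquely named (duplicate pretreatment labels?)")
  k <- length(sets)
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  member <- matrix(member, ncol = k, dimnames = list(all_genes, nm))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(patterns) <- nm
  count <- apply(patterns, 1L, function(p)
    sum(apply(member, 1L, function(row) all(row == p))))
  region <- apply(patterns, 1L, function(p) paste(nm[as.logical(p)],
                                                  collapse = "&"))
  out <- data.frame(region = region, patterns, count = count,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "union_size") <- length(all_genes)
  out
}

#' Gene set collections
#'
#' @param universe character vector: all genes eligible for the test (an
#'   explicit input; typically the assayed strains).
#' @param categories named list of gene sets, each a subset of `universe`.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(universe, categories) {
  universe <- unique(as.character(universe))
  categories <- lapply(categories, function(s) unique(as.character(s)))
  out <- lapply(categories, setdiff, y = universe)
  bad <- names(categories)[lengths(out) > 0L]
  if (length(bad))
    stop("categories not contained in the universe: ",
         paste(bad, collapse = ", "))
  structure(list(universe = universe, categories = categories),
            class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' One tab-separated line per category: name, description, genes...
#'
#' @param path GMT file.
#' @param universe universe genes for [gene_set_collection()]; defaults to
#'   the union of all category members.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  categories <- stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                                vapply(fields, `[[`, "", 1L))
  if (is.null(universe)) universe <- unique(unlist(categories))
  gene_set_collection(universe, categories)
}

#' Hypergeometric functional enrichment
#'
#' For each category, the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing at least `k` category members in `n = |hits|`
#' draws without replacement from a universe of `N` genes containing
#' `K` category members. Bonferroni correction multiplies by the number of
#' categories in the collection (all tested, not only those with overlap);
#' corrected p below `alpha` is significant.
#'
#' @param hits character vector of called genes, a subset of the universe.
#' @param collection a [gene_set_collection()].
#' @param alpha significance threshold on the Bonferroni-corrected p.
#' @param tail `"enrichment"` (upper) or `"depletion"` (lower,
#'   `P(X <= k)`).
#' @return data.frame (`category`, `K`, `k`, `p`, `p_bonferroni`,
#'   `significant`), ordered by p.
#' @export
hypergeom_enrich <- function(hits, collection, alpha = 0.01,
                             tail = c("enrichment", "depletion")) {
  tail <- match.arg(tail)
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, collection$universe)
  if (length(outside))
    stop("hits not in the universe: ", paste(outside, collapse = ", "))
  N <- length(collection$universe)
  n <- length(hits)
  m <- length(collection$categories)
  res <- lapply(names(collection$categories), function(nm) {
    cat_set <- collection$categories[[nm]]
    K <- length(cat_set)
    k <- length(intersect(hits, cat_set))
    p <- if (tail == "enrichment")
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    else stats::phyper(k, K, N - K, n, lower.tail = TRUE)
    data.frame(category = nm, K = K, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$significant <- out$p_bonferroni < alpha
  out[order(out$p), , drop = FALSE]
}

#' Classify expression changes by the 1.5-fold rule
#'
#' A gene is induced (repressed) in a condition if its average expression
#' change (n >= 3 measurements) is more than `fold` times higher (lower)
#' than in unstressed cells.
#'
#' @param log2_ratio named numeric vector of mean log2 expression changes.
#' @param fold fold-change threshold.
#' @return data.frame (`gene`, `status` in induced/repressed/unchanged).
#' @export
classify_expression <- function(log2_ratio, fold = 1.5) {
  th <- log2(fold)
  status <- ifelse(log2_ratio > th, "induced",
                   ifelse(log2_ratio < -th, "repressed", "unchanged"))
  data.frame(gene = names(log2_ratio), status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap of called genes with stress-regulated expression
#'
#' Fraction of hit genes induced (and repressed) during the pretreatment,
#' with hypergeometric enrichment p-values using the induced (repressed)
#' set as the category.
#'
#' @param hits character vector of called genes (non-empty).
#' @param expression data.frame from [classify_expression()] (`gene`,
#'   `status`).
#' @param universe universe genes.
#' @return data.frame with rows `induced` and `repressed`: `n_overlap`,
#'   `fraction` of hits, enrichment `p`.
#' @export
expression_overlap <- function(hits, expression, universe) {
  hits <- unique(as.character(hits))
  if (!length(hits)) stop("hits must be non-empty")
  one <- function(status) {
    set <- intersect(expression$gene[expression$status == status], universe)
    coll <- gene_set_collection(universe,
                                stats::setNames(list(set), status))
    k <- length(intersect(hits, set))
    p <- hypergeom_enrich(hits, coll, alpha = 1)$p[1L]
    data.frame(status = status, n_overlap = k,
               fraction = k / length(hits), p = p,
               stringsAsFactors = FALSE)
  }
  rbind(one("induced"), one("repressed"))
}

#' Uncentered Pearson correlation
#'
#' Cosine-like similarity `sum(xy) / sqrt(sum(x^2) * sum(y^2))` computed
#' without mean-centering, between the rows of `x` and the rows of `y`.
#' Invariant to positive rescaling of either vector and bounded in
#' \[-1, 1\]. Pairs are evaluated over positions non-missing in both rows.
#'
#' @param x numeric matrix (rows = profiles) or vector.
#' @param y optional second matrix/vector (default `x`).
#' @return matrix of correlations, rows of `x` by rows of `y`.
#' @export
uncentered_cor <- function(x, y = x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  if (!anyNA(x) && !anyNA(y)) {
    num <- tcrossprod(x, y)
    den <- sqrt(outer(rowSums(x^2), rowSums(y^2)))
    r <- num / den
    r[den == 0] <- NA_real_
    return(r)
  }
  r <- matrix(NA_real_, nrow(x), nrow(y), dimnames = list(rownames(x),
                                                          rownames(y)))
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y))) {
    ok <- !is.na(x[i, ]) & !is.na(y[j, ])
    if (!any(ok)) next
    den <- sqrt(sum(x[i, ok]^2) * sum(y[j, ok]^2))
    if (den > 0) r[i, j] <- sum(x[i, ok] * y[j, ok]) / den
  }
  r
}

#' Hierarchical clustering of fitness profiles
#'
#' Agglomerative clustering with distance `1 - uncentered Pearson r` and
#' (by default) average linkage; leaf order is deterministic given the
#' input row order. Rows whose profile is all zero (undefined similarity)
#' are dropped with a warning.
#'
#' @param m numeric matrix, rows = strains/genes, columns = comparisons.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list of class `profile_clustering`: `tree` (an `hclust`),
#'   `order` (leaf order as row labels), `dropped` (labels of dropped
#'   rows).
#' @export
cluster_profiles <- function(m, linkage = "average") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  norm <- sqrt(rowSums(m^2, na.rm = TRUE))
  drop <- norm == 0 | !is.finite(norm)
  if (any(drop)) {
    warning("dropping ", sum(drop), " all-zero row(s): similarity undefined")
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least two usable rows to cluster")
  d <- stats::as.dist(1 - uncentered_cor(m))
  tree <- stats::hclust(d, method = linkage)
  structure(list(tree = tree, order = rownames(m)[tree$order],
                 dropped = names(norm)[drop]),
            class = "profile_clustering")
}

#' Write a clustering in CDT/GTR-style TSV files for tree viewers
#'
#' @param clust a `profile_clustering`.
#' @param m the matrix that was clustered.
#' @param basename output path prefix (writes `<basename>.cdt`).
#' @export
write_cdt <- function(clust, m, basename) {
  m <- as.matrix(m)[clust$order, , drop = FALSE]
  df <- data.frame(GID = paste0("GENE", seq_len(nrow(m)), "X"),
                   NAME = rownames(m), GWEIGHT = 1, m, check.names = FALSE)
  utils::write.table(df, paste0(basename, ".cdt"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(basename)
}
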