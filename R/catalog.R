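#' Strain catalogs
#'
#' A strain catalog describes one pooled deletion library: one row per
#' strain with its gene, library class (homozygous non-essential deletions,
#' heterozygous essential deletions, or DAmP hypomorphs), the two unique
#' 20-bp barcode tags ("up" and "down") that flank the deletion cassette,
#' a relative growth rate (doublings per outgrowth generation relative to
#' wild type, 1.0 = neutral) and one surviving-fraction column per stress
#' label used by a [selection_design()] (columns named `survival.<label>`).
#'
#' @name strain_catalog
NULL

DNA_BASES <- c("A", "C", "G", "T")
TAG_LENGTH <- 20L
INDEX_LENGTH <- 6L

#' Construct a strain catalog
#'
#' @param strain_id character vector of unique strain identifiers.
#' @param gene character vector of gene names (one strain per gene per
#'   library; the same gene may appear in several libraries).
#' @param library library class, one of `"homozygous"`, `"heterozygous"`,
#'   `"damp"` (recycled).
#' @param up_tag,down_tag 20-bp DNA tags, unique across the catalog. If
#'   `NULL`, tags are generated with [generate_tags()].
#' @param growth_rate relative growth rate, must be > 0 (recycled).
#' @param survival data.frame / named list of surviving fractions in
#'   \[0, 1\], one column per stress label.
#' @param seed seed used when tags are auto-generated.
#' @return a `data.frame` of class `strain_catalog`.
#' @export
strain_catalog <- function(strain_id, gene = strain_id,
                           library = "homozygous",
                           up_tag = NULL, down_tag = NULL,
                           growth_rate = 1, survival = NULL,
                           seed = 1L) {
  n <- length(strain_id)
  if (n == 0L) stop("catalog must contain at least one strain")
  if (anyDuplicated(strain_id)) stop("strain_id values must be unique")
  library <- match.arg(rep_len(as.character(library), n),
                       c("homozygous", "heterozygous", "damp"),
                       several.ok = TRUE)
  if (is.null(up_tag) || is.null(down_tag)) {
    tags <- generate_tags(2L * n, seed = seed)
    up_tag <- tags[seq_len(n)]
    down_tag <- tags[n + seq_len(n)]
  }
  stopifnot(all(nchar(up_tag) == TAG_LENGTH),
            all(nchar(down_tag) == TAG_LENGTH))
  if (anyDuplicated(c(up_tag, down_tag)))
    stop("barcode tags must be unique across the catalog")
  growth_rate <- rep_len(growth_rate, n)
  if (any(growth_rate <= 0)) stop("growth_rate must be > 0")
  cat_df <- data.frame(strain_id = as.character(strain_id),
                       gene = as.character(gene),
                       library = library,
                       up_tag = up_tag, down_tag = down_tag,
                       growth_rate = growth_rate,
                       stringsAsFactors = FALSE)
  if (!is.null(survival)) {
    survival <- as.data.frame(survival)
    bad <- vapply(survival, function(x) any(x < 0 | x > 1), logical(1))
    if (any(bad))
      stop("survival fractions must lie in [0, 1]: ",
           paste(names(survival)[bad], collapse = ", "))
    names(survival) <- paste0("survival.", names(survival))
    cat_df <- cbind(cat_df, survival)
  }
  class(cat_df) <- c("strain_catalog", "data.frame")
  cat_df
}

#' Stress labels for which a catalog carries survival fractions
#' @param catalog a [strain_catalog()].
#' @return character vector of stress labels.
#' @export
catalog_stresses <- function(catalog) {
  sub("^survival\\.", "", grep("^survival\\.", names(catalog), value = TRUE))
}

#' Surviving fractions for one stress label
#' @param catalog a [strain_catalog()].
#' @param stress a stress label known to the catalog.
#' @return numeric vector named by strain.
#' @export
catalog_survival <- function(catalog, stress) {
  col <- paste0("survival.", stress)
  if (!col %in% names(catalog))
    stop("unknown stress label in design: '", stress,
         "' (catalog knows: ", paste(catalog_stresses(catalog), collapse = ", "), ")")
  stats::setNames(catalog[[col]], catalog$strain_id)
}

#' Generate random barcode tags at pairwise Hamming distance >= 5
#'
#' Tags separated by at least 5 substitutions keep <=2-mismatch mapping
#' unambiguous by construction. Random 20-mers almost always satisfy this;
#' rare violators are detected with a chunked pigeonhole scan (two tags
#' within distance 4 must agree on at least one of five 4-bp chunks) and
#' redrawn.
#'
#' @param n number of tags.
#' @param length tag length in bp.
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @return character vector of `n` DNA tags.
#' @export
generate_tags <- function(n, length = TAG_LENGTH, min_dist = 5L, seed = 1L) {
  set.seed(seed)
  draw <- function(k) {
    m <- matrix(sample(DNA_BASES, k * length, replace = TRUE), nrow = k)
    apply(m, 1L, paste0, collapse = "")
  }
  tags <- draw(n)
  for (iter in 1:50) {
    bad <- close_tag_pairs(tags, min_dist)
    if (length(bad) == 0L) break
    tags[bad] <- draw(length(bad))
  }
  if (length(close_tag_pairs(tags, min_dist)) > 0L)
    stop("could not generate a tag set at the requested minimum distance")
  tags
}

# indices of tags involved in a pair closer than min_dist (pigeonhole scan)
close_tag_pairs <- function(tags, min_dist) {
  n <- length(tags)
  if (n < 2L) return(integer())
  L <- nchar(tags[1L])
  n_chunks <- min_dist  # distance <= min_dist-1 forces an identical chunk
  bounds <- floor(seq(0L, L, length.out = n_chunks + 1L))
  enc <- tag_matrix(tags)
  offenders <- logical(n)
  for (ci in seq_len(n_chunks)) {
    rows <- (bounds[ci] + 1L):bounds[ci + 1L]
    key <- apply(enc[rows, , drop = FALSE], 2L, paste0, collapse = "")
    for (grp in split(seq_len(n), key)) {
      if (length(grp) < 2L) next
      for (i in seq_len(length(grp) - 1L)) for (j in (i + 1L):length(grp)) {
        a <- grp[i]; b <- grp[j]
        if (sum(enc[, a] != enc[, b]) < min_dist) offenders[b] <- TRUE
      }
    }
  }
  which(offenders)
}

# tags as an integer-code matrix, one column per tag
tag_matrix <- function(tags) {
  vapply(tags, function(t) utf8ToInt(t), integer(nchar(tags[1L])),
         USE.NAMES = FALSE)
}

#' Hamming distance between equal-length strings
#' @param a,b character scalars or vectors of equal-length strings.
#' @return integer vector of distances.
#' @export
hamming <- function(a, b) {
  if (any(nchar(a) != nchar(b))) stop("strings must have equal length")
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)), a, b,
         USE.NAMES = FALSE)
}

#' Full-scale pooled deletion-library catalog
#'
#' A catalog mirroring the composition of the pooled screens: ~4,800
#' homozygous non-essential deletions, ~1,300 heterozygous essential
#' deletions and 1,140 DAmP hypomorphs of essential genes. DAmP strains
#' share their gene space with the heterozygous collection, so gene-level
#' reconciliation across libraries ([reconcile_genes()],
#' [call_single_replicate()]) can be exercised. All strains are
#' wild-type-like; add `survival.<label>` columns (or use
#' [synth_catalog()]) to plant phenotypes.
#'
#' @param sizes named integer vector of library sizes.
#' @param seed integer seed for tag generation.
#' @return a [strain_catalog()].
#' @export
full_pool_catalog <- function(sizes = c(homozygous = 4800L,
                                        heterozygous = 1300L,
                                        damp = 1140L), seed = 1L) {
  stopifnot(all(names(sizes) %in% c("homozygous", "heterozygous", "damp")))
  ess <- sprintf("ESS%04d", seq_len(max(sizes["heterozygous"],
                                        sizes["damp"], na.rm = TRUE)))
  ids <- c(sprintf("hom%04d", seq_len(sizes["homozygous"])),
           sprintf("het%04d", seq_len(sizes["heterozygous"])),
           sprintf("damp%04d", seq_len(sizes["damp"])))
  genes <- c(sprintf("NON%04d", seq_len(sizes["homozygous"])),
             ess[seq_len(sizes["heterozygous"])],
             ess[seq_len(sizes["damp"])])
  libs <- rep(c("homozygous", "heterozygous", "damp"), sizes)
  strain_catalog(ids, gene = genes, library = libs, seed = seed)
}

#' Read / write a strain catalog as TSV
#'
#' Columns: strain_id, gene, library, up_tag, down_tag, growth_rate and one
#' `survival.<label>` column per stress.
#'
#' @param path file path.
#' @param catalog a [strain_catalog()].
#' @return `read_catalog` returns a `strain_catalog`.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  surv_cols <- grep("^survival\\.", names(df), value = TRUE)
  surv <- if (length(surv_cols)) {
    s <- df[surv_cols]
    names(s) <- sub("^survival\\.", "", surv_cols)
    s
  } else NULL
  strain_catalog(df$strain_id, df$gene, df$library, df$up_tag, df$down_tag,
                 df$growth_rate, survival = surv)
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
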