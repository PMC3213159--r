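#' Mismatch-tolerant sample demultiplexing
#'
#' Assigns each read to the unique sample whose 6-bp multiplex index lies
#' within Hamming distance 1 of the read's index region. Reads whose index
#' matches no catalog index within 1 mismatch, or ties two indexes at the
#' minimum qualifying distance, are returned as `"UNASSIGNED"`; reads
#' shorter than the layout are `"MALFORMED"` (counted, never fatal).
#'
#' @param reads character vector of reads (index at the start of the read).
#' @param indexes named character vector: index sequence -> sample label
#'   (names are the 6-bp indexes, values the sample labels).
#' @param max_mismatch maximum index mismatches (protocol: 1).
#' @return character vector of sample labels, `"UNASSIGNED"` or
#'   `"MALFORMED"`.
#' @export
demultiplex <- function(reads, indexes, max_mismatch = 1L) {
  idx_seqs <- names(indexes)
  if (is.null(idx_seqs) || any(nchar(idx_seqs) != INDEX_LENGTH))
    stop("indexes must be a named vector keyed by ", INDEX_LENGTH, "-bp sequences")
  out <- rep("UNASSIGNED", length(reads))
  short <- nchar(reads) < INDEX_LENGTH
  out[short] <- "MALFORMED"
  obs <- substr(reads[!short], 1L, INDEX_LENGTH)
  if (length(obs)) {
    d <- string_dist_matrix(obs, idx_seqs)
    dmin <- do.call(pmin, as.data.frame(d))
    nmin <- rowSums(d == dmin)
    ok <- dmin <= max_mismatch & nmin == 1L
    hit <- max.col(-d, ties.method = "first")
    assigned <- rep("UNASSIGNED", length(obs))
    assigned[ok] <- unname(indexes[hit[ok]])
    out[!short] <- assigned
  }
  out
}

#' Mismatch-tolerant tag mapping
#'
#' Maps observed 20-bp tags to the unique catalog tag within Hamming
#' distance `max_mismatch` (protocol: 2). Tags with two or more catalog
#' tags within range are `"AMBIGUOUS"` (mismatches that do not map uniquely
#' are discarded); tags matching none are `"UNMAPPED"`; wrong-length tags
#' are `"MALFORMED"`. With catalog tags at pairwise distance >= 5 ambiguity
#' cannot arise at `max_mismatch = 2`, but the rule is enforced regardless.
#'
#' @param observed_tags character vector of observed tag sequences.
#' @param catalog a [strain_catalog()].
#' @param tag_class `"up"` or `"down"`.
#' @param max_mismatch maximum tag mismatches.
#' @return character vector of strain ids or the reserved codes
#'   `"UNMAPPED"`, `"AMBIGUOUS"`, `"MALFORMED"`.
#' @export
map_tag <- function(observed_tags, catalog, tag_class = c("up", "down"),
                    max_mismatch = 2L) {
  tag_class <- match.arg(tag_class)
  cat_tags <- catalog[[paste0(tag_class, "_tag")]]
  out <- rep("UNMAPPED", length(observed_tags))
  bad <- nchar(observed_tags) != TAG_LENGTH
  out[bad] <- "MALFORMED"
  # fast path: exact match
  exact <- match(observed_tags, cat_tags)
  hitx <- !bad & !is.na(exact)
  out[hitx] <- catalog$strain_id[exact[hitx]]
  rest <- which(!bad & is.na(exact))
  if (length(rest)) {
    d <- string_dist_matrix(observed_tags[rest], cat_tags)
    dmin <- do.call(pmin, as.data.frame(d))
    within <- d <= max_mismatch
    nhit <- rowSums(within)
    res <- rep("UNMAPPED", length(rest))
    res[nhit >= 2L] <- "AMBIGUOUS"
    one <- nhit == 1L
    res[one] <- catalog$strain_id[max.col(within + 0, ties.method = "first")[one]]
    out[rest] <- res
  }
  out
}

# Hamming distances between each of `obs` (rows) and each of `refs`
# (columns); strings must share the refs' common length.
string_dist_matrix <- function(obs, refs) {
  L <- nchar(refs[1L])
  ref_m <- tag_matrix(refs)              # L x n_ref
  n <- length(obs)
  d <- matrix(0L, n, length(refs))
  # process in chunks to bound memory at ~L * chunk integers
  chunk <- max(1L, floor(2e6 / L))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    obs_i <- matrix(utf8ToInt(paste0(obs[idx], collapse = "")), nrow = L)
    for (j in seq_along(refs)) {
      d[idx, j] <- as.integer(colSums(obs_i != ref_m[, j]))
    }
  }
  d
}

#' Count barcode tags per sample
#'
#' Applies [demultiplex()] then [map_tag()] to every read and tabulates
#' per-sample per-strain counts, with an audit of discarded reads. The
#' counters satisfy `n_assigned + n_discarded_index + n_discarded_unmapped
#' + n_discarded_ambiguous + n_malformed == total reads`.
#'
#' @param reads character vector of reads (possibly multiple samples
#'   multiplexed together), or a FASTQ path.
#' @param catalog a [strain_catalog()].
#' @param indexes named character vector index -> sample label.
#' @param tag_class `"up"` or `"down"`.
#' @return object of class `tag_counts`: list with `counts` (strain x
#'   sample integer matrix), `tag_class`, and `stats` (the counters).
#' @export
count_tags <- function(reads, catalog, indexes, tag_class = c("up", "down")) {
  tag_class <- match.arg(tag_class)
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  layout <- read_layout(tag_class)
  samples <- unname(indexes)
  counts <- matrix(0L, nrow(catalog), length(samples),
                   dimnames = list(catalog$strain_id, samples))
  stats <- c(n_assigned = 0L, n_discarded_index = 0L,
             n_discarded_unmapped = 0L, n_discarded_ambiguous = 0L,
             n_malformed = 0L)
  if (length(reads)) {
    malformed <- nchar(reads) < layout$length
    stats["n_malformed"] <- sum(malformed)
    reads <- reads[!malformed]
    smp <- demultiplex(reads, indexes)
    stats["n_discarded_index"] <- sum(smp == "UNASSIGNED")
    keep <- smp != "UNASSIGNED"
    tags <- substr(reads[keep], layout$tag_at[1L],
                   layout$tag_at[TAG_LENGTH])
    hit <- map_tag(tags, catalog, tag_class)
    stats["n_discarded_unmapped"] <- sum(hit == "UNMAPPED")
    stats["n_discarded_ambiguous"] <- sum(hit == "AMBIGUOUS")
    ok <- !hit %in% c("UNMAPPED", "AMBIGUOUS", "MALFORMED")
    stats["n_assigned"] <- sum(ok)
    if (any(ok)) {
      tab <- table(factor(hit[ok], levels = catalog$strain_id),
                   factor(smp[keep][ok], levels = samples))
      counts <- counts + unclass(tab)
    }
  }
  structure(list(counts = counts, tag_class = tag_class, stats = stats),
            class = "tag_counts")
}

#' Summarise array features per tag
#'
#' Averages the feature replicates of each tag after excluding clear
#' outliers: features with `|x - median| > outlier_k * MAD` among the
#' replicates of that tag are dropped. Tags retaining fewer than
#' `min_features` features are flagged low-quality; tags with no surviving
#' feature are reported missing (`NA`), never as an error.
#'
#' @param array an `array_table` from [generate_array()] or a data.frame
#'   with columns `tag_id`, `strain_id`, `tag_class`, `intensity`.
#' @param min_features minimum surviving features for a high-quality call.
#' @param outlier_k MAD multiplier of the exclusion rule.
#' @return data.frame (`tag_id`, `strain_id`, `tag_class`, `mean_intensity`,
#'   `n_used`, `low_quality`).
#' @export
summarize_features <- function(array, min_features = 3L, outlier_k = 5) {
  stopifnot(all(c("tag_id", "strain_id", "tag_class", "intensity") %in%
                  names(array)))
  by_tag <- split(seq_len(nrow(array)), array$tag_id)
  res <- lapply(by_tag, function(i) {
    x <- array$intensity[i]
    med <- stats::median(x, na.rm = TRUE)
    keep <- abs(x - med) <= outlier_k * stats::mad(x, center = med, na.rm = TRUE)
    keep[is.na(keep)] <- FALSE
    data.frame(tag_id = array$tag_id[i[1L]],
               strain_id = array$strain_id[i[1L]],
               tag_class = array$tag_class[i[1L]],
               mean_intensity = if (any(keep)) mean(x[keep]) else NA_real_,
               n_used = sum(keep),
               low_quality = sum(keep) < min_features,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Quantile normalisation across arrays
#'
#' Forces every column (array) to the identical sorted value vector: the
#' row-wise mean of the per-column sorted values, preserving within-column
#' rank order. Ties are resolved by average rank. Missing cells are imputed
#' with the column median for the transformation and restored to missing
#' afterwards. A single-column matrix is returned unchanged. Up and down
#' tag intensities are normalised as separate batches by the caller.
#'
#' @param m numeric matrix, rows = tags, columns = arrays.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) <= 1L) return(m)
  na_mask <- is.na(m)
  if (any(na_mask)) {
    for (j in seq_len(ncol(m))) {
      mj <- m[, j]
      mj[is.na(mj)] <- stats::median(mj, na.rm = TRUE)
      m[, j] <- mj
    }
  }
  sorted <- apply(m, 2L, sort)
  target <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    out[, j] <- (lo + hi) / 2
  }
  out[na_mask] <- NA
  out
}

#' Invert the saturating array response
#'
#' The array response is modelled as the hyperbola
#' `I = imax * s / (s + K)`; `desaturate` recovers the unsaturated signal
#' `s = K * I / (imax - I)`, monotone increasing in `I`. Intensities at or
#' above `imax` are clipped to `ceiling` with a warning.
#'
#' @param intensity numeric vector of (normalised) intensities.
#' @param imax maximal intensity of the response.
#' @param K half-saturation constant; `Inf` means the array is linear and
#'   intensities are returned unchanged.
#' @param ceiling clip value for saturated intensities.
#' @return corrected signal vector.
#' @seealso [saturate()] for the forward response.
#' @export
desaturate <- function(intensity, imax, K, ceiling = 0.999 * imax) {
  if (!is.finite(K)) return(intensity)
  over <- !is.na(intensity) & intensity >= imax
  if (any(over)) {
    warning(sum(over), " intensities at or above imax clipped to ceiling")
    intensity[over] <- ceiling
  }
  K * intensity / (imax - intensity)
}

#' @rdname desaturate
#' @param s unsaturated signal.
#' @export
saturate <- function(s, imax, K) {
  if (!is.finite(K)) return(s)
  imax * s / (s + K)
}

#' Relative strain abundances from counts or intensities
#'
#' Per tag class, abundance = value / column total; the combined strain
#' abundance is the mean of the up- and down-class abundances where both
#' are usable, otherwise the usable one.
#'
#' @param up,down strain x sample numeric matrices (counts or corrected
#'   intensities) for the two tag classes; either may be `NULL`. A
#'   `tag_counts` object may be passed as `up` (its class is used).
#' @return object of class `abundance_table`: list with per-class
#'   abundance matrices (`up`, `down`) and `combined`.
#' @export
to_abundance <- function(up = NULL, down = NULL) {
  if (inherits(up, "tag_counts")) {
    tc <- up
    up <- if (tc$tag_class == "up") tc$counts else NULL
    if (is.null(down) && tc$tag_class == "down") down <- tc$counts
  }
  if (inherits(down, "tag_counts")) down <- down$counts
  norm_cols <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    tot <- colSums(m, na.rm = TRUE)
    if (any(tot <= 0)) stop("zero column total in sample(s): ",
                            paste(colnames(m)[tot <= 0], collapse = ", "))
    sweep(m, 2L, tot, "/")
  }
  up_ab <- norm_cols(up)
  down_ab <- norm_cols(down)
  combined <- if (is.null(up_ab)) down_ab else if (is.null(down_ab)) up_ab
  else {
    both <- (up_ab + down_ab) / 2
    both[is.na(up_ab)] <- down_ab[is.na(up_ab)]
    both[is.na(down_ab)] <- up_ab[is.na(down_ab)]
    both
  }
  if (is.null(combined)) stop("at least one tag class must be supplied")
  structure(list(up = up_ab, down = down_ab, combined = combined),
            class = "abundance_table")
}
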