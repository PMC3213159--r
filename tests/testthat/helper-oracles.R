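# Independent oracles used across the suite. These deliberately re-derive
# results with plain loops / closed forms, never by calling the package
# functions they check.

# population standard deviation
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# plain full-scan Hamming mapper: distance of each read tag to every
# catalog tag, then the literal uniqueness rule
oracle_map <- function(tags, cat_tags, cat_ids, max_mm = 2L) {
  L <- nchar(cat_tags[1L])
  m <- matrix(unlist(strsplit(tags, ""), use.names = FALSE), nrow = L)
  out <- character(length(tags))
  dists <- matrix(0L, length(tags), length(cat_tags))
  for (j in seq_along(cat_tags)) {
    ref <- strsplit(cat_tags[j], "")[[1L]]
    dists[, j] <- colSums(m != ref)
  }
  for (i in seq_along(tags)) {
    within <- which(dists[i, ] <= max_mm)
    out[i] <- if (length(within) == 0L) "UNMAPPED"
    else if (length(within) > 1L) "AMBIGUOUS"
    else cat_ids[within]
  }
  out
}

# literal re-evaluation of the four calling criteria, one strain at a time
oracle_calls <- function(ft, pretreatment, min_reps = 2L) {
  strains <- rownames(ft$values)
  info <- ft$info
  cons <- function(comp, rep) {
    cols <- which(info$pretreatment == pretreatment &
                    info$comparison == comp & info$replicate == rep)
    v <- ft$values[, cols, drop = FALSE]
    out <- rowMeans(v, na.rm = TRUE)
    out[rowSums(!is.na(v)) == 0L] <- NA
    out
  }
  reps <- sort(unique(info$replicate[info$pretreatment == pretreatment]))
  called <- character()
  zcol <- function(f) (f - mean(f, na.rm = TRUE)) / pop_sd(f)
  for (s in strains) {
    n_pass <- 0L
    for (r in reps) {
      f4 <- cons("S4vS3", r); f3 <- cons("S3vS1", r); f2 <- cons("S2vS1", r)
      ok <- !is.na(f4[s]) && !is.na(f3[s]) && !is.na(f2[s]) &&
        zcol(f4)[s] <= -1 && zcol(f3)[s] > -1 && f2[s] > f4[s]
      if (isTRUE(ok)) n_pass <- n_pass + 1L
    }
    if (n_pass >= min_reps) called <- c(called, s)
  }
  called
}

# naive O(n^3) average-linkage agglomeration on a distance matrix,
# returning the sequence of merged label sets
oracle_average_linkage <- function(d) {
  clusters <- as.list(rownames(d))
  merges <- list()
  dist_between <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        dd <- dist_between(clusters[[i]], clusters[[j]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# assemble a single-platform fitness table from per-comparison replicate
# columns: cols is a named list comparison -> matrix (strains x replicates)
make_test_ft <- function(cols, pre = "NaCl", platform = "Array") {
  strains <- rownames(cols[[1L]])
  values <- do.call(cbind, unname(cols))
  reps <- ncol(cols[[1L]])
  info <- data.frame(
    pretreatment = pre,
    replicate = rep(seq_len(reps), times = length(cols)),
    comparison = rep(names(cols), each = reps),
    platform = platform, stringsAsFactors = FALSE)
  # interleave: do.call(cbind) laid out comparison-major already
  values <- matrix(values, nrow = length(strains),
                   dimnames = list(strains, NULL))
  fitness_table(values, info)
}

# small ready-made catalog with distinct planted survivals
toy_catalog <- function(n = 6L, pre = "NaCl", surv_severe = NULL, seed = 11L) {
  if (is.null(surv_severe)) surv_severe <- seq(0.9, 0.4, length.out = n)
  surv <- data.frame(a = 0.95, b = 0.9, c = surv_severe, d = 0.8,
                     check.names = FALSE)
  names(surv) <- c(pre, "H2O2_0.4mM", paste0("H2O2_1.0mM.", pre),
                   paste0("H2O2_1.2mM.", pre))
  strain_catalog(sprintf("s%02d", seq_len(n)), survival = surv, seed = seed)
}
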