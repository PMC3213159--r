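#' Simulate a pooled selection/outgrowth experiment
#'
#' Propagates relative strain frequencies through a [selection_design()].
#' At a stress edge each strain's frequency is multiplied by its surviving
#' fraction for that stress label and the pool is renormalised (dead cells
#' are removed at the stress step; the subsequent fixed outgrowth then only
#' expresses growth-rate differences, which is equivalent at the frequency
#' level to carrying dead cells and diluting them out). At an outgrowth
#' edge of `g` generations a strain with relative growth rate `r` is
#' multiplied by `2^(g*(r-1))` and the pool renormalised.
#'
#' @param catalog a [strain_catalog()] carrying `survival.<label>` columns
#'   for every stress label used by `design`.
#' @param design a [selection_design()].
#' @param start_freq optional named starting frequencies at the root sample
#'   (default: uniform). Must sum to 1.
#' @param bottleneck optional integer; if given, each post-edge pool is
#'   resampled multinomially with this many cells (population bottleneck).
#' @param seed seed used only when `bottleneck` is set.
#' @return named list: one `pool_state` per design node, each a list with
#'   `sample` and `abundance` (named frequency vector summing to 1).
#' @examples
#' cat3 <- strain_catalog(c("a", "b", "c"),
#'   survival = data.frame(NaCl = 1, H2O2_1.0mM.NaCl = c(1, .25, 1),
#'     H2O2_1.2mM.NaCl = 1, H2O2_0.4mM = 1, check.names = FALSE))
#' st <- simulate_selection(cat3, selection_design("NaCl"))
#' st$S4$abundance  # (4/9, 1/9, 4/9)
#' @export
simulate_selection <- function(catalog, design, start_freq = NULL,
                               bottleneck = NULL, seed = 1L) {
  validate_design(design)
  n <- nrow(catalog)
  if (n == 0L) stop("catalog must be non-empty")
  ids <- catalog$strain_id
  if (is.null(start_freq)) {
    start_freq <- stats::setNames(rep(1 / n, n), ids)
  } else {
    start_freq <- start_freq[ids]
    if (anyNA(start_freq) || abs(sum(start_freq) - 1) > 1e-9)
      stop("start_freq must cover every strain and sum to 1")
  }
  if (!is.null(bottleneck)) set.seed(seed)
  growth <- stats::setNames(catalog$growth_rate, ids)
  states <- list()
  states[[design$root]] <- start_freq
  for (node in topo_order(design)) {
    for (k in which(design$edges$from == node)) {
      edge <- design$edges[k, ]
      f <- states[[edge$from]]
      if (!is.na(edge$stress)) {
        f <- f * catalog_survival(catalog, edge$stress)
        if (sum(f) <= 0) stop("pool went extinct at stress '", edge$stress, "'")
        f <- f / sum(f)
      }
      if (edge$generations > 0) {
        f <- f * 2^(edge$generations * (growth - 1))
        f <- f / sum(f)
      }
      if (!is.null(bottleneck)) {
        cells <- stats::rmultinom(1L, bottleneck, f)[, 1L]
        f <- cells / sum(cells)
      }
      states[[edge$to]] <- f
    }
  }
  lapply(stats::setNames(nm = names(states)), function(s) {
    structure(list(sample = s, abundance = states[[s]]), class = "pool_state")
  })
}

#' Multinomial read-count draw from a pool state
#'
#' The count table that error-free sequencing of `depth` reads would
#' produce. [generate_reads()] at `error_rate = 0` followed by
#' [count_tags()] reproduces this draw exactly (same seed).
#'
#' @param state a `pool_state`.
#' @param depth total reads.
#' @param seed integer seed.
#' @return named integer vector of per-strain counts.
#' @export
sample_counts <- function(state, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  stats::setNames(stats::rmultinom(1L, depth, state$abundance)[, 1L],
                  names(state$abundance))
}

# common flanks between the multiplex index and the barcode tag
READ_FLANKS <- c(up = "GATGTCCACGAGGTCTCT", down = "CGGTGTCGGTCTCGTAG")

#' Barcode read layout
#'
#' Reads are `index (6 bp) + common flank + tag (20 bp)`; the flank differs
#' between "up" and "down" tag libraries (they are amplified separately).
#'
#' @param tag_class `"up"` or `"down"`.
#' @return list with `index_at`, `tag_at` (position vectors) and `length`.
#' @export
read_layout <- function(tag_class = c("up", "down")) {
  tag_class <- match.arg(tag_class)
  flank <- READ_FLANKS[[tag_class]]
  list(index_at = seq_len(INDEX_LENGTH),
       tag_at = INDEX_LENGTH + nchar(flank) + seq_len(TAG_LENGTH),
       flank = flank,
       length = INDEX_LENGTH + nchar(flank) + TAG_LENGTH)
}

#' Simulate barcode sequencing reads
#'
#' Draws `depth` reads multinomially from a pool state, builds each read as
#' multiplex index + common flank + strain tag, and applies i.i.d. base
#' substitution errors.
#'
#' @param state a `pool_state` from [simulate_selection()].
#' @param catalog the [strain_catalog()].
#' @param depth number of reads (> 0).
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param multiplex_index 6-bp sample index embedded in each read.
#' @param tag_class which tag library is being sequenced.
#' @param seed integer seed.
#' @return character vector of reads, with attribute `truth` (the strain
#'   each read was drawn from).
#' @export
generate_reads <- function(state, catalog, depth, error_rate = 0,
                           multiplex_index = "ACGTAC",
                           tag_class = c("up", "down"), seed = 1L) {
  tag_class <- match.arg(tag_class)
  if (depth <= 0) stop("depth must be positive")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (nchar(multiplex_index) != INDEX_LENGTH)
    stop("multiplex_index must be ", INDEX_LENGTH, " bp")
  counts <- sample_counts(state, depth, seed = seed)
  origin <- rep(names(counts), counts)
  # shuffle so errors are not correlated with file order
  origin <- origin[sample.int(length(origin))]
  tags <- catalog[[paste0(tag_class, "_tag")]][match(origin, catalog$strain_id)]
  layout <- read_layout(tag_class)
  reads <- paste0(multiplex_index, layout$flank, tags)
  if (error_rate > 0) {
    m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                nrow = layout$length)
    hit <- which(stats::runif(length(m)) < error_rate)
    if (length(hit)) {
      # substitute with one of the three other bases
      shift <- sample.int(3L, length(hit), replace = TRUE)
      base_idx <- match(m[hit], DNA_BASES)
      m[hit] <- DNA_BASES[((base_idx - 1L + shift) %% 4L) + 1L]
    }
    reads <- apply(m, 2L, paste0, collapse = "")
  }
  structure(reads, truth = origin)
}

#' Write reads to FASTQ / read them back
#'
#' Constant base quality is used (quality simulation is out of scope).
#'
#' @param reads character vector of reads.
#' @param path FASTQ path.
#' @param id_prefix read-name prefix.
#' @return `read_fastq` returns a character vector of read sequences.
#' @export
write_fastq <- function(reads, path, id_prefix = "read") {
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- paste0(id_prefix, seq_along(reads))
  Biostrings::writeXStringSet(seqs, path, format = "fastq")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Simulate a barcode-array intensity table
#'
#' Each up and down tag is represented `features_per_tag` times on the
#' array. The true signal `s = scale * frequency` passes through a
#' saturating hyperbolic response `I = imax * s / (s + K)` (shared with
#' [desaturate()], its inverse), is offset by an additive background, and
#' each feature replicate receives log-normal noise with coefficient of
#' variation `noise_cv`; with probability `outlier_rate` a feature is
#' replaced by a uniform outlier on `[0, imax]` (to exercise outlier
#' exclusion during summarisation).
#'
#' @param state a `pool_state`.
#' @param catalog the [strain_catalog()].
#' @param scale intensity per unit frequency.
#' @param saturation_K half-saturation signal; `Inf` gives a linear array.
#' @param imax maximal (saturated) intensity.
#' @param features_per_tag features per tag (>= 1; the TAG4 design uses 5).
#' @param noise_cv log-normal noise CV per feature.
#' @param outlier_rate per-feature probability of replacement by an outlier.
#' @param background additive background intensity.
#' @param seed integer seed.
#' @return data.frame (`feature_id`, `tag_id`, `strain_id`, `tag_class`,
#'   `replicate`, `intensity`) of class `array_table`, with the response
#'   parameters stored in attributes `imax`, `saturation_K`, `scale` and
#'   `background`.
#' @export
generate_array <- function(state, catalog, scale = 1e4, saturation_K = Inf,
                           imax = 6e4, features_per_tag = 5L, noise_cv = 0,
                           outlier_rate = 0, background = 0, seed = 1L) {
  if (features_per_tag < 1L) stop("features_per_tag must be >= 1")
  set.seed(seed)
  freq <- state$abundance[catalog$strain_id]
  per_class <- function(tag_class) {
    s <- scale * freq
    I <- if (is.finite(saturation_K)) imax * s / (s + saturation_K) else s
    I <- I + background
    n <- length(I) * features_per_tag
    base <- rep(I, each = features_per_tag)
    val <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      base * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else base
    if (outlier_rate > 0) {
      out <- stats::runif(n) < outlier_rate
      val[out] <- stats::runif(sum(out), 0, imax)
    }
    data.frame(
      feature_id = paste0(catalog$strain_id, "_", tag_class, "_",
                          rep(seq_len(features_per_tag), times = length(I))),
      tag_id = rep(paste0(catalog$strain_id, "_", tag_class),
                   each = features_per_tag),
      strain_id = rep(catalog$strain_id, each = features_per_tag),
      tag_class = tag_class,
      replicate = rep(seq_len(features_per_tag), times = length(I)),
      intensity = val,
      stringsAsFactors = FALSE)
  }
  out <- rbind(per_class("up"), per_class("down"))
  structure(out, class = c("array_table", "data.frame"),
            imax = imax, saturation_K = saturation_K, scale = scale,
            background = background)
}
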