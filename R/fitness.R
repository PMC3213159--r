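#' Per-strain log2 fitness scores
#'
#' Fitness after a treatment step is the log2 change in relative strain
#' abundance between a sample and its control in the selection design
#' (S1vS0 slow growth, S2vS1 low-dose H2O2 sensitivity, S3vS1 mild-stress
#' sensitivity, S4vS3 / S4AvS3 defect in acquiring severe-H2O2 tolerance).
#' Negative values signify decreased strain fitness.
#'
#' A `fitness_table` holds the strain x column score matrix plus per-column
#' metadata: pretreatment, replicate, comparison and platform (`Array` for
#' the barcode microarray, `UP` / `DN` for the sequenced up and down tags).
#'
#' @name fitness
NULL

#' Log2 fitness from a pair of abundance vectors
#'
#' `log2((a_num + floor) / (a_den + floor))`; the floor keeps scores finite
#' for strains that drop out of a pool (default: half a count at the given
#' scale, a pseudofrequency). Strains missing (NA) on either side stay
#' missing; the score is antisymmetric under swapping numerator and
#' denominator.
#'
#' @param abund_num,abund_den numeric vectors of relative abundances for
#'   the treated sample and its control (same strains, same platform).
#' @param floor small positive abundance added to both sides.
#' @return numeric vector of log2 ratios.
#' @export
compute_fitness <- function(abund_num, abund_den, floor = 0.5 / 1e6) {
  if (floor <= 0) stop("floor must be positive")
  if (length(abund_num) != length(abund_den))
    stop("abundance vectors must align")
  log2((abund_num + floor) / (abund_den + floor))
}

#' Column z-scores of a fitness table column
#'
#' `z = (f - mean) / sd` over all non-missing strains of one comparison.
#' The criteria of the caller are expressed in these units ("at least 1
#' standard deviation from the mean of all strains"). Population sd
#' (denominator n) is the default; sample sd is available.
#'
#' @param f numeric vector (one fitness column).
#' @param type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return numeric vector of z-scores (NA preserved).
#' @export
standardize <- function(f, type = c("population", "sample")) {
  type <- match.arg(type)
  x <- f[!is.na(f)]
  if (length(x) < 2L) stop("need at least two non-missing values")
  s <- stats::sd(x)
  if (type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (s == 0) stop("degenerate column: zero standard deviation")
  (f - mean(x)) / s
}

#' Consensus fitness across measurement platforms
#'
#' One comparison may be measured on the array and on the sequenced up and
#' down tags; the consensus is the mean of the available platform values,
#' with the number of supporting platforms retained.
#'
#' @param ... numeric vectors (or a single matrix) of per-strain fitness
#'   from each platform; missing values allowed.
#' @return list with `consensus` (mean of available values; NA where all
#'   are missing) and `n_platforms` (per-strain support count).
#' @export
merge_platforms <- function(...) {
  args <- list(...)
  m <- if (length(args) == 1L && is.matrix(args[[1L]])) args[[1L]]
  else do.call(cbind, args)
  n <- rowSums(!is.na(m))
  cons <- rowMeans(m, na.rm = TRUE)
  cons[n == 0L] <- NA_real_
  list(consensus = cons, n_platforms = n)
}

#' Construct a fitness table
#'
#' @param values numeric matrix, rows = strains (rownames required),
#'   columns aligned with `info` rows.
#' @param info data.frame with columns `pretreatment`, `replicate`,
#'   `comparison`, `platform`.
#' @param gene optional named vector strain -> gene.
#' @return object of class `fitness_table`.
#' @export
fitness_table <- function(values, info, gene = NULL) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)),
            nrow(info) == ncol(values),
            all(c("pretreatment", "replicate", "comparison", "platform") %in%
                  names(info)))
  colnames(values) <- paste(paste0(info$pretreatment, info$replicate),
                            info$comparison, info$platform)
  if (is.null(gene)) gene <- stats::setNames(rownames(values), rownames(values))
  structure(list(values = values, info = info, gene = gene),
            class = "fitness_table")
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("fitness_table:", nrow(x$values), "strains x", ncol(x$values),
      "comparisons\n")
  cat("pretreatments:", paste(unique(x$info$pretreatment), collapse = ", "),
      "\n")
  invisible(x)
}

#' Select fitness-table columns
#'
#' @param ft a [fitness_table()].
#' @param pretreatment,comparison,platform,replicate optional filters.
#' @return integer vector of column indices.
#' @export
ft_columns <- function(ft, pretreatment = NULL, comparison = NULL,
                       platform = NULL, replicate = NULL) {
  keep <- rep(TRUE, nrow(ft$info))
  if (!is.null(pretreatment)) keep <- keep & ft$info$pretreatment %in% pretreatment
  if (!is.null(comparison)) keep <- keep & ft$info$comparison %in% comparison
  if (!is.null(platform)) keep <- keep & ft$info$platform %in% platform
  if (!is.null(replicate)) keep <- keep & ft$info$replicate %in% replicate
  which(keep)
}

#' Per-replicate consensus fitness matrix for one comparison
#'
#' Averages the platform columns ([merge_platforms()]) of each replicate of
#' `pretreatment` for the given comparison.
#'
#' @param ft a [fitness_table()].
#' @param pretreatment pretreatment label.
#' @param comparison comparison label (e.g. `"S4vS3"`).
#' @return numeric matrix strains x replicates (columns named by replicate
#'   number); errors if the comparison is absent.
#' @export
consensus_fitness <- function(ft, pretreatment, comparison) {
  cols <- ft_columns(ft, pretreatment, comparison)
  if (!length(cols))
    stop("missing required comparison '", comparison, "' for pretreatment '",
         pretreatment, "'")
  reps <- sort(unique(ft$info$replicate[cols]))
  out <- vapply(reps, function(r) {
    rc <- cols[ft$info$replicate[cols] == r]
    merge_platforms(ft$values[, rc, drop = FALSE])$consensus
  }, numeric(nrow(ft$values)))
  out <- matrix(out, nrow = nrow(ft$values),
                dimnames = list(rownames(ft$values), reps))
  out
}

#' Read / write a fitness table as TSV
#'
#' The layout mirrors a compiled fitness-defect table: rows are strains
#' (columns `strain` and `gene` first), data columns are named
#' `"<pretreatment><replicate> <comparison> <platform>"` (e.g.
#' `"NaCl2 S4vS3 UP"`, where NaCl2 is the second NaCl replicate), missing
#' values written as `NA`.
#'
#' @param ft a [fitness_table()].
#' @param path TSV path.
#' @return `read_fitness_tsv` returns a `fitness_table`.
#' @export
write_fitness_tsv <- function(ft, path) {
  df <- data.frame(strain = rownames(ft$values),
                   gene = unname(ft$gene[rownames(ft$values)]),
                   ft$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fitness_tsv
#' @export
read_fitness_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  data_cols <- setdiff(names(df), c("strain", "gene"))
  parts <- strsplit(data_cols, " ", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed column header(s): ", paste(data_cols[bad], collapse = ", "))
  exp_lab <- vapply(parts, `[[`, "", 1L)
  m <- regmatches(exp_lab, regexec("^(.*?)([0-9]+)$", exp_lab))
  if (any(lengths(m) != 3L))
    stop("experiment labels must end in a replicate number")
  info <- data.frame(
    pretreatment = vapply(m, `[[`, "", 2L),
    replicate = as.integer(vapply(m, `[[`, "", 3L)),
    comparison = vapply(parts, `[[`, "", 2L),
    platform = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  values <- as.matrix(df[data_cols])
  rownames(values) <- df$strain
  gene <- stats::setNames(if (is.null(df$gene)) df$strain else df$gene,
                          df$strain)
  fitness_table(values, info, gene)
}
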