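#' Multi-criterion calling of acquired-stress-resistance defects
#'
#' A strain is called defective in acquiring H2O2 tolerance after a given
#' mild pretreatment if, in at least `min_reps` replicates (on consensus
#' fitness across platforms):
#' \enumerate{
#'   \item its fitness defect after severe H2O2 following the pretreatment
#'     (S4vS3) is at least 1 standard deviation below the mean of all
#'     strains (`z(S4vS3) <= -1`);
#'   \item its fitness defect after the pretreatment alone (S3vS1) is less
#'     than 1 standard deviation below the mean (`z(S3vS1) > -1`);
#'   \item its defect at the low 0.4 mM H2O2 dose (S2vS1) is strictly
#'     smaller than the defect at the severe dose
#'     (`f(S2vS1) > f(S4vS3)`; ties break toward exclusion).
#' }
#' Strains with positive severe-dose fitness are never called.
#'
#' @param ft a [fitness_table()] providing S4vS3, S3vS1 and S2vS1 columns
#'   for the pretreatment in >= `min_reps` replicates.
#' @param pretreatment pretreatment label.
#' @param z_defect criterion-1 threshold on z(S4vS3).
#' @param z_mild criterion-2 threshold on z(S3vS1).
#' @param min_reps minimum replicates in which all criteria must hold.
#' @param severe_comparison comparison used for the severe dose.
#' @return object of class `call_set`: list with `pretreatment`, `called`
#'   (character vector of strain ids) and `audit` (per-strain data.frame
#'   with per-criterion replicate counts, `n_replicates_passing` and
#'   `route`).
#' @export
call_stringent <- function(ft, pretreatment, z_defect = -1, z_mild = -1,
                           min_reps = 2L, severe_comparison = "S4vS3") {
  f4 <- consensus_fitness(ft, pretreatment, severe_comparison)
  f3 <- consensus_fitness(ft, pretreatment, "S3vS1")
  f2 <- consensus_fitness(ft, pretreatment, "S2vS1")
  if (ncol(f4) < min_reps)
    stop("need >= ", min_reps, " replicates for pretreatment '",
         pretreatment, "' (found ", ncol(f4), ")")
  z4 <- apply(f4, 2L, standardize)
  z3 <- apply(f3, 2L, standardize)
  crit1 <- z4 <= z_defect
  crit2 <- z3 > z_mild
  crit3 <- f2 > f4
  pass <- crit1 & crit2 & crit3
  n_pass <- rowSums(pass, na.rm = TRUE)
  called <- rownames(ft$values)[n_pass >= min_reps]
  audit <- data.frame(
    strain = rownames(ft$values),
    crit1_reps = rowSums(crit1, na.rm = TRUE),
    crit2_reps = rowSums(crit2, na.rm = TRUE),
    crit3_reps = rowSums(crit3, na.rm = TRUE),
    n_replicates_passing = n_pass,
    route = ifelse(n_pass >= min_reps, "stringent", ""),
    added_by_correlation = FALSE,
    added_by_two_dose_rule = FALSE,
    stringsAsFactors = FALSE)
  structure(list(pretreatment = pretreatment, called = called, audit = audit,
                 params = list(z_defect = z_defect, z_mild = z_mild,
                               min_reps = min_reps)),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat("call_set (", x$pretreatment, "): ", length(x$called),
      " strains called\n", sep = "")
  invisible(x)
}

#' Expand a call set by fitness-profile correlation
#'
#' The stringent lists are expanded by adding uncalled strains whose
#' fitness phenotype is highly correlated with an identified mutant:
#' uncentered Pearson correlation >= `r_min` between the strain's fitness
#' vector (all comparisons and replicates of this pretreatment, consensus
#' across platforms) and that of any called strain, guarded by criterion 1
#' in at least one replicate (so expansion cannot recruit strains with no
#' severe-dose defect).
#'
#' @param calls a `call_set` from [call_stringent()].
#' @param ft the [fitness_table()].
#' @param r_min correlation threshold in (0, 1].
#' @param z_defect criterion-1 guard threshold.
#' @return the expanded `call_set`; added strains carry
#'   `added_by_correlation = TRUE` and route `"correlation"`.
#' @export
expand_by_correlation <- function(calls, ft, r_min = 0.9, z_defect = -1) {
  if (r_min <= 0 || r_min > 1) stop("r_min must be in (0, 1]")
  if (!length(calls$called)) return(calls)
  comps <- unique(ft$info$comparison[ft$info$pretreatment == calls$pretreatment])
  prof <- do.call(cbind, lapply(comps, function(cc)
    consensus_fitness(ft, calls$pretreatment, cc)))
  f4 <- consensus_fitness(ft, calls$pretreatment, "S4vS3")
  z4 <- apply(f4, 2L, standardize)
  guard <- rowSums(z4 <= z_defect, na.rm = TRUE) >= 1L
  cand <- setdiff(rownames(prof)[guard], calls$called)
  if (!length(cand)) return(calls)
  r <- uncentered_cor(prof[cand, , drop = FALSE],
                      prof[calls$called, , drop = FALSE])
  add <- cand[apply(r, 1L, function(x) any(x >= r_min, na.rm = TRUE))]
  if (length(add)) {
    calls$called <- c(calls$called, add)
    i <- match(add, calls$audit$strain)
    calls$audit$added_by_correlation[i] <- TRUE
    calls$audit$route[i] <- "correlation"
  }
  calls
}

#' Calling for single-replicate libraries
#'
#' Libraries screened once (e.g. the heterozygous essential collection in
#' some selections) cannot use the two-replicate rule. A strain is called
#' if it meets criteria 1-3 at both severe doses (1.0 mM, S4vS3, and
#' 1.2 mM, S4AvS3) within the single replicate, or if mutants of the same
#' gene pass (at the primary dose) in at least two libraries (e.g. the
#' heterozygous deletion and the DAmP allele).
#'
#' @param ft a [fitness_table()] restricted to one replicate of the
#'   pretreatment (an error is raised otherwise).
#' @param pretreatment pretreatment label.
#' @param library named vector strain -> library class, used for the
#'   multi-library route; `NULL` disables that route.
#' @param z_defect,z_mild criterion thresholds as in [call_stringent()].
#' @return a `call_set`; two-dose strains carry
#'   `added_by_two_dose_rule = TRUE`, multi-library calls route
#'   `"multi_library"`.
#' @export
call_single_replicate <- function(ft, pretreatment, library = NULL,
                                  z_defect = -1, z_mild = -1) {
  reps <- unique(ft$info$replicate[ft$info$pretreatment == pretreatment])
  if (length(reps) != 1L)
    stop("call_single_replicate applies to single-replicate libraries; ",
         "found ", length(reps), " replicates")
  pass_at <- function(comp) {
    f_sev <- consensus_fitness(ft, pretreatment, comp)[, 1L]
    f3 <- consensus_fitness(ft, pretreatment, "S3vS1")[, 1L]
    f2 <- consensus_fitness(ft, pretreatment, "S2vS1")[, 1L]
    p <- standardize(f_sev) <= z_defect & standardize(f3) > z_mild & f2 > f_sev
    p & !is.na(p)
  }
  pass10 <- pass_at("S4vS3")
  pass12 <- pass_at("S4AvS3")
  strains <- rownames(ft$values)
  two_dose <- pass10 & pass12
  multi_lib <- rep(FALSE, length(strains))
  if (!is.null(library)) {
    gene <- ft$gene[strains]
    pass_any <- pass10
    lib <- library[strains]
    gene_libs <- tapply(lib[pass_any], gene[pass_any],
                        function(x) length(unique(x)))
    hit_genes <- names(gene_libs)[gene_libs >= 2L]
    multi_lib <- pass_any & gene %in% hit_genes
  }
  called <- strains[two_dose | multi_lib]
  audit <- data.frame(
    strain = strains,
    crit1_reps = as.integer(pass10),
    crit2_reps = NA_integer_,
    crit3_reps = NA_integer_,
    n_replicates_passing = as.integer(pass10),
    route = ifelse(two_dose, "two_dose",
                   ifelse(multi_lib, "multi_library", "")),
    added_by_correlation = FALSE,
    added_by_two_dose_rule = two_dose,
    stringsAsFactors = FALSE)
  structure(list(pretreatment = pretreatment, called = called, audit = audit,
                 params = list(z_defect = z_defect, z_mild = z_mild,
                               min_reps = 1L)),
            class = "call_set")
}

#' Strains sensitive to low-dose H2O2 without pretreatment
#'
#' One-sample test, per strain, that mean S2vS1 fitness across all
#' sequenced replicates (pooled over pretreatment experiments; the low-dose
#' control branch is independent of the pretreatment) is below zero,
#' Benjamini-Hochberg corrected; strains with `q < q_max` and negative mean
#' are returned.
#'
#' @param ft a [fitness_table()] with >= 3 S2vS1 replicate columns in
#'   total.
#' @param q_max FDR threshold.
#' @param method `"t"` (one-sample one-sided t-test) or `"wilcoxon"`
#'   (signed-rank).
#' @return list of class `lowdose_calls`: `called` (strain ids) and
#'   `table` (strain, mean_fitness, p, q).
#' @export
call_lowdose_sensitive <- function(ft, q_max = 0.05,
                                   method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  cols <- ft_columns(ft, comparison = "S2vS1")
  # consensus per experiment (pretreatment x replicate), pooled as replicates
  key <- paste0(ft$info$pretreatment[cols], ft$info$replicate[cols])
  m <- vapply(unique(key), function(k)
    merge_platforms(ft$values[, cols[key == k], drop = FALSE])$consensus,
    numeric(nrow(ft$values)))
  if (ncol(m) < 3L) stop("need >= 3 low-dose replicates, found ", ncol(m))
  res <- apply(m, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L) return(c(NA_real_, NA_real_))
    if (stats::sd(x) == 0) {
      p <- if (mean(x) < 0) 0 else 1  # degenerate: all replicates identical
    } else {
      p <- if (method == "t") stats::t.test(x, alternative = "less")$p.value
      else stats::wilcox.test(x, alternative = "less", exact = FALSE)$p.value
    }
    c(mean(x), p)
  })
  tab <- data.frame(strain = rownames(ft$values),
                    mean_fitness = res[1L, ], p = res[2L, ],
                    stringsAsFactors = FALSE)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  called <- tab$strain[!is.na(tab$q) & tab$q < q_max & tab$mean_fitness < 0]
  structure(list(called = called, table = tab, q_max = q_max),
            class = "lowdose_calls")
}

#' Remove generally-H2O2-sensitive and mild-stress-sensitive strains
#'
#' The screen targets the *acquisition* of resistance, so two classes of
#' called strains are removed from consideration: (a) strains with equal
#' fitness defects at the low and secondary H2O2 doses - implemented as
#' strains in the low-dose-sensitive set whose severe-dose defect does not
#' exceed their low-dose defect by at least `margin_sd` severe-column
#' standard deviations (plus any strain whose two defects are numerically
#' equal); and (b) strains sensitive to the mild pretreatment alone
#' (`z(S3vS1) <= z_mild` in >= `min_reps` replicates). Idempotent.
#'
#' @param calls a `call_set`.
#' @param lowdose a `lowdose_calls` object (or character vector of strain
#'   ids) from [call_lowdose_sensitive()].
#' @param ft the [fitness_table()].
#' @param margin_sd required margin, in units of the mean severe-column sd,
#'   between low-dose and severe-dose defects for low-dose-sensitive
#'   strains.
#' @param z_mild,min_reps mild-stress-sensitivity rule.
#' @param eps numerical-equality tolerance for the defect comparison.
#' @return the filtered `call_set`; removed strains get route
#'   `"excluded_<reason>"` in the audit.
#' @export
apply_exclusions <- function(calls, lowdose, ft, margin_sd = 2,
                             z_mild = -1, min_reps = 2L, eps = 1e-8) {
  lowdose_set <- if (inherits(lowdose, "lowdose_calls")) lowdose$called
  else as.character(lowdose)
  f4 <- consensus_fitness(ft, calls$pretreatment, "S4vS3")
  f3 <- consensus_fitness(ft, calls$pretreatment, "S3vS1")
  f2 <- consensus_fitness(ft, calls$pretreatment, "S2vS1")
  m4 <- rowMeans(f4, na.rm = TRUE)
  m2 <- rowMeans(f2, na.rm = TRUE)
  sd4 <- mean(apply(f4, 2L, stats::sd, na.rm = TRUE))
  z3 <- apply(f3, 2L, standardize)
  equal_defect <- abs(m2 - m4) <= eps
  lowdose_flat <- rownames(f4) %in% lowdose_set &
    (m2 - m4) < margin_sd * sd4
  mild_sensitive <- rowSums(z3 <= z_mild, na.rm = TRUE) >=
    min(min_reps, ncol(f3))
  drop_reason <- ifelse(equal_defect | lowdose_flat, "uniform_sensitive",
                        ifelse(mild_sensitive, "mild_sensitive", ""))
  names(drop_reason) <- rownames(f4)
  removed <- calls$called[drop_reason[calls$called] != ""]
  calls$called <- setdiff(calls$called, removed)
  if (length(removed)) {
    i <- match(removed, calls$audit$strain)
    calls$audit$route[i] <- paste0("excluded_", drop_reason[removed])
  }
  calls
}

#' Gene-level reconciliation across libraries
#'
#' When a gene is assayed in several libraries, one call per gene is
#' reported, preferring homozygous > DAmP > heterozygous evidence.
#'
#' @param calls a `call_set`.
#' @param catalog a [strain_catalog()] (maps strains to genes/libraries).
#' @return data.frame (`gene`, `strain`, `library`, `route`), one row per
#'   called gene.
#' @export
reconcile_genes <- function(calls, catalog) {
  i <- match(calls$called, catalog$strain_id)
  df <- data.frame(gene = catalog$gene[i], strain = calls$called,
                   library = catalog$library[i],
                   route = calls$audit$route[match(calls$called,
                                                   calls$audit$strain)],
                   stringsAsFactors = FALSE)
  pref <- c(homozygous = 1L, damp = 2L, heterozygous = 3L)
  df <- df[order(df$gene, pref[df$library]), ]
  df[!duplicated(df$gene), , drop = FALSE]
}

#' Write a call list as TSV
#'
#' @param calls a `call_set`.
#' @param catalog a [strain_catalog()].
#' @param path TSV path.
#' @export
write_calls_tsv <- function(calls, catalog, path) {
  aud <- calls$audit[match(calls$called, calls$audit$strain), ]
  i <- match(calls$called, catalog$strain_id)
  df <- data.frame(gene = catalog$gene[i], strain = calls$called,
                   library = catalog$library[i],
                   pretreatment = calls$pretreatment,
                   route = aud$route,
                   n_replicates_passing = aud$n_replicates_passing,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
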