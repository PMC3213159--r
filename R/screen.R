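#' Synthetic screen catalog with planted defects
#'
#' Builds a strain catalog emulating the pooled deletion libraries with
#' known planted phenotype classes:
#' \describe{
#'   \item{acquired}{defective in *acquiring* H2O2 tolerance: reduced
#'     survival of the severe doses after every pretreatment, normal
#'     otherwise. These are the strains the caller must recover.}
#'   \item{pretreat_sensitive}{reduced survival of the mild pretreatments
#'     themselves (S3vS1 defect); must never be called.}
#'   \item{uniform_sensitive}{equally reduced survival of the low 0.4 mM
#'     and severe H2O2 doses (generally H2O2-sensitive); must never be
#'     called as acquisition-defective.}
#'   \item{null}{wild-type-like.}
#' }
#'
#' The planted severe-dose deficit is stated in column-standard-deviation
#' units (`effect_sd`). Because planting outliers itself inflates the
#' column sd, the log2 deficit is derived analytically:
#' `delta = effect_sd * sigma_r / sqrt(1 - effect_sd^2 * f * (1 - f))`
#' where `sigma_r` is the per-replicate log2 survival noise and `f` the
#' fraction of strains planted with the deficit in that column.
#'
#' @param n total strains.
#' @param n_acquired,n_pretreat,n_uniform planted class sizes.
#' @param pretreatments mild-stress labels of the screen.
#' @param effect_sd planted effect size in column-sd units.
#' @param rep_noise_sd,strain_noise_sd per-replicate and persistent
#'   per-strain log2 stress-response noise used by [simulate_screen()];
#'   needed here to express `effect_sd` in log2 survival units (the base
#'   column sd is `sqrt(rep_noise_sd^2 + strain_noise_sd^2)`).
#' @param base_survival named baseline surviving fractions for the
#'   wild-type-like pool: `pretreat`, `low`, `severe`, `severe_alt`.
#' @param library library class of all strains.
#' @param seed integer seed (tags).
#' @return a [strain_catalog()] with attribute `truth`: data.frame
#'   (`strain_id`, `class`).
#' @export
synth_catalog <- function(n = 500L, n_acquired = 50L, n_pretreat = 0L,
                          n_uniform = 0L,
                          pretreatments = c("NaCl", "HS", "DTT"),
                          effect_sd = 2.5, rep_noise_sd = 0.2,
                          strain_noise_sd = 0.2,
                          base_survival = c(pretreat = 0.95, low = 0.9,
                                            severe = 0.8, severe_alt = 0.7),
                          library = "homozygous", seed = 1L) {
  stopifnot(n_acquired + n_pretreat + n_uniform <= n)
  ids <- sprintf("strain%04d", seq_len(n))
  cls <- rep("null", n)
  cls[seq_len(n_acquired)] <- "acquired"
  cls[n_acquired + seq_len(n_pretreat)] <- "pretreat_sensitive"
  cls[n_acquired + n_pretreat + seq_len(n_uniform)] <- "uniform_sensitive"
  sigma_base <- sqrt(rep_noise_sd^2 + strain_noise_sd^2)
  delta_for <- function(frac) {
    shrink <- 1 - effect_sd^2 * frac * (1 - frac)
    if (shrink <= 0)
      stop("planted fraction too large for the requested effect size")
    effect_sd * sigma_base / sqrt(shrink)
  }
  delta_severe <- delta_for((n_acquired + n_uniform) / n)
  delta_pre <- if (n_pretreat > 0) delta_for(n_pretreat / n) else 0
  surv <- list()
  for (p in pretreatments) {
    sp <- rep(base_survival[["pretreat"]], n)
    sp[cls == "pretreat_sensitive"] <- sp[cls == "pretreat_sensitive"] *
      2^(-delta_pre)
    surv[[p]] <- sp
    for (dose in c("severe", "severe_alt")) {
      lab <- paste0("H2O2_", if (dose == "severe") "1.0mM." else "1.2mM.", p)
      sv <- rep(base_survival[[dose]], n)
      hit <- cls %in% c("acquired", "uniform_sensitive")
      sv[hit] <- sv[hit] * 2^(-delta_severe)
      surv[[lab]] <- sv
    }
  }
  low <- rep(base_survival[["low"]], n)
  low[cls == "uniform_sensitive"] <- low[cls == "uniform_sensitive"] *
    2^(-delta_severe)  # equal low/severe deficit
  surv[["H2O2_0.4mM"]] <- low
  cat_out <- strain_catalog(ids, gene = toupper(ids), library = library,
                            survival = as.data.frame(surv, check.names = FALSE,
                                                     optional = TRUE),
                            seed = seed)
  attr(cat_out, "truth") <- data.frame(strain_id = ids, class = cls,
                                       stringsAsFactors = FALSE)
  attr(cat_out, "delta_severe") <- delta_severe
  cat_out
}

# comparison -> (numerator sample, denominator sample)
SCREEN_COMPARISONS <- list(S1vS0 = c("S1", "S0"), S2vS1 = c("S2", "S1"),
                           S3vS1 = c("S3", "S1"), S4vS3 = c("S4", "S3"),
                           S4AvS3 = c("S4A", "S3"))

#' Simulate a full selection screen to a fitness table
#'
#' Runs the selection design for every pretreatment and replicate.
#' The catalog's surviving fractions are modulated by two log2-normal
#' stress-response factors per strain and stress label: a persistent one
#' (`sd = strain_noise_sd`, drawn once per screen - the biological
#' diversity of deletion strains' stress fitness) and a per-experiment one
#' (`sd = rep_noise_sd` - dose/handling variation between replicate
#' selections). When the catalog carries planted truth classes
#' ([synth_catalog()]), the persistent factor is applied to the null
#' background only: planted strains are defined by their planted deficit
#' alone (plus replicate noise), so that recovery is measured against an
#' exactly stated truth. The factors model net enrichment through stress plus
#' recovery, so the effective multiplier may exceed 1 even though catalog
#' survivals are proper fractions. The pool is then propagated through the
#' design and the samples are "measured": on the `seq` platform by multinomial tag counting of both
#' tag libraries at the given depth (UP and DN fitness columns); on the
#' `array` platform by simulated feature intensities, outlier-excluding
#' summarisation, quantile normalisation across the experiment's arrays
#' (per tag class), saturation correction and abundance normalisation
#' (Array fitness columns).
#'
#' @param catalog a [strain_catalog()] (e.g. [synth_catalog()]).
#' @param pretreatments pretreatment labels; must have matching survival
#'   columns in the catalog.
#' @param replicates replicate experiments per pretreatment.
#' @param depth sequencing reads per sample and tag class.
#' @param platform `"seq"`, `"array"`, or both.
#' @param rep_noise_sd per-replicate log2 stress-response noise.
#' @param strain_noise_sd persistent per-strain log2 stress-response
#'   noise.
#' @param start_cv coefficient of variation of the (lognormal) starting
#'   pool frequencies ("roughly equally represented").
#' @param array_noise_cv,array_outlier_rate,array_K,array_imax,array_scale
#'   array measurement parameters (see [generate_array()]).
#' @param seed integer seed for the whole screen.
#' @return list of class `screen_sim`: `fitness` (a [fitness_table()]),
#'   `catalog`, `truth` (planted classes or NULL).
#' @export
simulate_screen <- function(catalog, pretreatments = c("NaCl", "HS", "DTT"),
                            replicates = 2L, depth = 1e6,
                            platform = "seq", rep_noise_sd = 0.2,
                            strain_noise_sd = 0.2, start_cv = 0.15,
                            array_noise_cv = 0.1, array_outlier_rate = 0.01,
                            array_K = 5e3, array_imax = 6e4,
                            array_scale = 1e4, seed = 1L) {
  platform <- match.arg(platform, c("seq", "array"), several.ok = TRUE)
  set.seed(seed)
  n <- nrow(catalog)
  ids <- catalog$strain_id
  surv_cols <- grep("^survival\\.", names(catalog), value = TRUE)
  sub_seed <- function() sample.int(2147483646L, 1L)
  start <- if (start_cv > 0) {
    sdlog <- sqrt(log(1 + start_cv^2))
    w <- stats::rlnorm(n, 0, sdlog)
    stats::setNames(w / sum(w), ids)
  } else stats::setNames(rep(1 / n, n), ids)
  cols <- list()
  info <- list()
  floor <- 0.5 / depth
  truth <- attr(catalog, "truth")
  background <- if (is.null(truth)) rep(TRUE, n) else truth$class == "null"
  persistent <- lapply(stats::setNames(nm = surv_cols), function(sc)
    stats::rnorm(n, 0, strain_noise_sd) * background)
  for (p in pretreatments) {
    design <- selection_design(p)
    for (r in seq_len(replicates)) {
      cat_r <- catalog
      for (sc in surv_cols) {
        eps <- stats::rnorm(n, 0, rep_noise_sd)
        cat_r[[sc]] <- cat_r[[sc]] * 2^(persistent[[sc]] + eps)
      }
      states <- simulate_selection(cat_r, design, start_freq = start)
      samples <- names(states)
      if ("seq" %in% platform) {
        cnt <- lapply(c(up = "up", down = "down"), function(cl) {
          m <- vapply(samples, function(s)
            sample_counts(states[[s]], depth, seed = sub_seed()),
            numeric(n))
          rownames(m) <- ids
          m
        })
        ab <- to_abundance(up = cnt$up, down = cnt$down)
        for (comp in names(SCREEN_COMPARISONS)) {
          pair <- SCREEN_COMPARISONS[[comp]]
          for (cl in c("up", "down")) {
            cols[[length(cols) + 1L]] <-
              compute_fitness(ab[[cl]][, pair[1L]], ab[[cl]][, pair[2L]],
                              floor = floor)
            info[[length(info) + 1L]] <-
              data.frame(pretreatment = p, replicate = r, comparison = comp,
                         platform = if (cl == "up") "UP" else "DN",
                         stringsAsFactors = FALSE)
          }
        }
      }
      if ("array" %in% platform) {
        arr <- lapply(samples, function(s)
          generate_array(states[[s]], cat_r, scale = array_scale,
                         saturation_K = array_K, imax = array_imax,
                         noise_cv = array_noise_cv,
                         outlier_rate = array_outlier_rate,
                         seed = sub_seed()))
        summ <- lapply(arr, summarize_features)
        per_class <- function(cl) {
          m <- vapply(summ, function(s)
            s$mean_intensity[s$tag_class == cl][match(ids,
              s$strain_id[s$tag_class == cl])], numeric(n))
          dimnames(m) <- list(ids, samples)
          m <- quantile_normalize(m)
          apply(m, 2L, desaturate, imax = array_imax, K = array_K)
        }
        ab <- to_abundance(up = per_class("up"), down = per_class("down"))
        for (comp in names(SCREEN_COMPARISONS)) {
          pair <- SCREEN_COMPARISONS[[comp]]
          cols[[length(cols) + 1L]] <-
            compute_fitness(ab$combined[, pair[1L]], ab$combined[, pair[2L]],
                            floor = floor)
          info[[length(info) + 1L]] <-
            data.frame(pretreatment = p, replicate = r, comparison = comp,
                       platform = "Array", stringsAsFactors = FALSE)
        }
      }
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- ids
  ft <- fitness_table(values, do.call(rbind, info),
                      gene = stats::setNames(catalog$gene, ids))
  structure(list(fitness = ft, catalog = catalog,
                 truth = attr(catalog, "truth")),
            class = "screen_sim")
}

#' Full calling pipeline for a screen
#'
#' For each pretreatment: stringent four-criterion calling
#' ([call_stringent()]), optional correlation expansion
#' ([expand_by_correlation()]), then exclusion of generally-H2O2-sensitive
#' and mild-stress-sensitive strains ([apply_exclusions()]) using the
#' pooled low-dose-sensitive set ([call_lowdose_sensitive()]).
#'
#' @param ft a [fitness_table()].
#' @param pretreatments pretreatments to call (default: all in `ft`).
#' @param expand run correlation expansion.
#' @param r_min expansion correlation threshold.
#' @param q_max low-dose FDR threshold.
#' @param ... further arguments to [call_stringent()].
#' @return list of class `screen_calls`: `calls` (named list of
#'   `call_set`), `lowdose` (a `lowdose_calls`).
#' @export
screen_calls <- function(ft, pretreatments = NULL, expand = FALSE,
                         r_min = 0.9, q_max = 0.05, ...) {
  if (is.null(pretreatments))
    pretreatments <- unique(ft$info$pretreatment)
  ld_cols <- ft_columns(ft, comparison = "S2vS1")
  n_ld <- length(unique(paste0(ft$info$pretreatment[ld_cols],
                               ft$info$replicate[ld_cols])))
  lowdose <- if (n_ld >= 3L) call_lowdose_sensitive(ft, q_max = q_max)
  else {
    message("fewer than 3 low-dose replicates: low-dose-sensitive set ",
            "left empty; only the equality and mild-stress exclusions apply")
    structure(list(called = character(), table = NULL, q_max = q_max),
              class = "lowdose_calls")
  }
  calls <- lapply(stats::setNames(nm = pretreatments), function(p) {
    cs <- call_stringent(ft, p, ...)
    if (expand) cs <- expand_by_correlation(cs, ft, r_min = r_min)
    apply_exclusions(cs, lowdose, ft)
  })
  structure(list(calls = calls, lowdose = lowdose), class = "screen_calls")
}

#' @export
print.screen_calls <- function(x, ...) {
  for (p in names(x$calls))
    cat(p, ":", length(x$calls[[p]]$called), "strains called\n")
  cat("low-dose sensitive:", length(x$lowdose$called), "strains\n")
  invisible(x)
}
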