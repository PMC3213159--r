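#' Dose-summed survival score
#'
#' The validation assay exposes pretreated and mock-treated cultures to a
#' ladder of severe H2O2 doses and scores viability at each dose; the
#' single summary score is the viable fraction of pretreated cells minus
#' that of mock-treated cells, summed over all doses. For `D` doses the
#' score lies in `[-D, D]` on the fraction scale (multiply by 100 for
#' percent viability; the dose count is always taken from the input).
#'
#' @param pretreated,mock data.frames with columns `dose` and `viability`
#'   (fractions in \[0, 1\], or percents - any common scale), sharing an
#'   identical strictly-increasing dose grid.
#' @return numeric score (sum over doses of pretreated - mock viability).
#' @examples
#' pre <- data.frame(dose = 0:2, viability = c(1, .8, .5))
#' mock <- data.frame(dose = 0:2, viability = c(.9, .3, 0))
#' survival_score(pre, mock)  # 1.1
#' @export
survival_score <- function(pretreated, mock) {
  stopifnot(all(c("dose", "viability") %in% names(pretreated)),
            all(c("dose", "viability") %in% names(mock)))
  if (is.unsorted(pretreated$dose, strictly = TRUE))
    stop("doses must be strictly increasing")
  if (length(pretreated$dose) != length(mock$dose) ||
      any(pretreated$dose != mock$dose))
    stop("pretreated and mock arms must share the dose grid")
  sum(pretreated$viability - mock$viability)
}

#' Competition fitness defect from GFP mixture fractions
#'
#' A mutant is competed against a GFP-marked reference (mixed roughly 1:5
#' GFP:unmarked) through stress and outgrowth; the wild type is competed
#' in parallel as control. The defect is the change in log2 odds of the
#' GFP fraction in the mutant mixture, relative to the same change in the
#' wild-type control mixture:
#' `defect = log2(odds(end_mut)/odds(start)) -
#'  log2(odds(end_wt)/odds(start_wt))`, `odds(p) = p/(1-p)`.
#' Positive defect: the mutant lost ground relative to wild type (the GFP
#' fraction rose more in its mixture). The odds-ratio form makes the score
#' invariant to the initial mixing ratio.
#'
#' @param gfp_start GFP fraction at mixing in the mutant culture.
#' @param gfp_end GFP fraction after outgrowth in the mutant culture.
#' @param gfp_end_wt GFP fraction after outgrowth in the wild-type control.
#' @param gfp_start_wt GFP fraction at mixing in the control (defaults to
#'   `gfp_start`).
#' @return numeric fitness defect (log2 units).
#' @examples
#' competition_fitness(1/6, 1/3, 1/6)  # log2(2.5) ~ 1.322
#' @export
competition_fitness <- function(gfp_start, gfp_end, gfp_end_wt,
                                gfp_start_wt = gfp_start) {
  fr <- c(gfp_start, gfp_end, gfp_end_wt, gfp_start_wt)
  if (any(fr <= 0 | fr >= 1))
    stop("GFP fractions must lie strictly inside (0, 1)")
  odds <- function(p) p / (1 - p)
  log2(odds(gfp_end) / odds(gfp_start)) -
    log2(odds(gfp_end_wt) / odds(gfp_start_wt))
}

#' Read a viability-curve TSV
#'
#' Columns: `strain`, `arm` (pretreated/mock), `replicate`, `dose`,
#' `viability`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_viability_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "arm", "dose", "viability") %in% names(df)))
  df
}
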