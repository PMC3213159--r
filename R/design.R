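#' Selection designs
#'
#' A selection design is the directed acyclic graph of treatment and
#' outgrowth steps applied to one pooled library for one mild-stress
#' pretreatment. Nodes are sample labels; edges carry an optional stress
#' label (a killing step: each strain's frequency is multiplied by its
#' surviving fraction) and an outgrowth generation count (a growth step:
#' frequency multiplied by `2^(g * (growth_rate - 1))`). The canonical
#' design has samples:
#' \describe{
#'   \item{S0}{unstressed pool after >7 generations log-phase growth}
#'   \item{S1}{S0 outgrown 10 generations (slow-grower control)}
#'   \item{S2}{low-dose 0.4 mM H2O2 alone, then 10 generations outgrowth}
#'   \item{S3}{mild pretreatment alone, then 10 generations outgrowth}
#'   \item{S4}{pretreatment then severe 1.0 mM H2O2, then 10 generations}
#'   \item{S4A}{pretreatment then severe 1.2 mM H2O2, then 10 generations}
#' }
#' Severe-dose stress labels are pretreatment-qualified
#' (e.g. `H2O2_1.0mM.NaCl`) so that a catalog can plant defects in acquired
#' resistance that depend on the prior mild stress.
#'
#' @param pretreatment mild-stress label (e.g. `"NaCl"`, `"HS"`, `"DTT"`,
#'   `"tunicamycin"`).
#' @param generations outgrowth generations per outgrowth step (the
#'   experimental protocol fixes this at 10).
#' @param low_dose,severe_dose,severe_dose_alt stress labels for the 0.4 mM
#'   control dose and the two severe doses.
#' @return object of class `selection_design`: a list with `pretreatment`
#'   and an `edges` data.frame (`from`, `to`, `stress`, `generations`).
#' @examples
#' d <- selection_design("NaCl")
#' d$edges
#' @export
selection_design <- function(pretreatment = "NaCl", generations = 10L,
                             low_dose = "H2O2_0.4mM",
                             severe_dose = paste0("H2O2_1.0mM.", pretreatment),
                             severe_dose_alt = paste0("H2O2_1.2mM.", pretreatment)) {
  edges <- rbind(
    data.frame(from = "S0", to = "S1", stress = NA_character_,
               generations = generations),
    data.frame(from = "S0", to = "S2", stress = low_dose,
               generations = generations),
    data.frame(from = "S0", to = "P", stress = pretreatment, generations = 0L),
    data.frame(from = "P", to = "S3", stress = NA_character_,
               generations = generations),
    data.frame(from = "P", to = "S4", stress = severe_dose,
               generations = generations),
    data.frame(from = "P", to = "S4A", stress = severe_dose_alt,
               generations = generations))
  design <- list(pretreatment = pretreatment, edges = edges, root = "S0")
  class(design) <- "selection_design"
  validate_design(design)
  design
}

#' Validate a selection design
#'
#' Checks that the edge list forms a DAG rooted at a single source node and
#' returns the design invisibly; used internally before simulation.
#'
#' @param design a `selection_design`.
#' @export
validate_design <- function(design) {
  e <- design$edges
  stopifnot(is.data.frame(e),
            all(c("from", "to", "stress", "generations") %in% names(e)))
  nodes <- unique(c(e$from, e$to))
  roots <- setdiff(e$from, e$to)
  if (length(roots) != 1L)
    stop("design must have exactly one root sample (found: ",
         paste(roots, collapse = ", "), ")")
  if (any(e$generations < 0)) stop("generations must be >= 0")
  # topological order must exist (DAG)
  topo_order(design)
  invisible(design)
}

# topological order of design nodes; errors on cycles
topo_order <- function(design) {
  e <- design$edges
  nodes <- unique(c(e$from, e$to))
  order <- character()
  remaining <- nodes
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(n)
      !any(e$to == n & e$from %in% remaining), logical(1))]
    if (!length(free)) stop("design contains a cycle")
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  order
}

#' @export
print.selection_design <- function(x, ...) {
  cat("selection_design:", x$pretreatment, "\n")
  print(x$edges)
  invisible(x)
}

#' Read a selection design (or a set of them) from a YAML config
#'
#' The config maps each pretreatment to optional overrides of the canonical
#' design, e.g.:
#' \preformatted{
#' pretreatments: [NaCl, HS, DTT]
#' generations: 10
#' }
#'
#' @param path YAML file.
#' @return named list of `selection_design` objects.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pres <- cfg$pretreatments
  if (is.null(pres)) stop("config must list 'pretreatments'")
  gens <- if (is.null(cfg$generations)) 10L else as.integer(cfg$generations)
  stats::setNames(lapply(pres, selection_design, generations = gens), pres)
}
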