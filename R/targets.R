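#' High-confidence regulatory targets
#'
#' A linked gene is a high-confidence down-stream regulatory target when
#' any perturbation experiment (genetic interference, epigenetic
#' silencing or activation of the LTR class) significantly altered its
#' expression: the intersection of the linked set with the union of the
#' response sets.
#'
#' @param linked character vector of linked gene symbols.
#' @param response_sets list of character vectors, one per perturbation
#'   experiment.
#' @return character vector (sorted) of high-confidence target symbols.
#' @export
high_confidence_targets <- function(linked, response_sets) {
  if (length(response_sets) == 0L) return(character(0L))
  responded <- unique(unlist(response_sets, use.names = FALSE))
  sort(intersect(unique(linked), responded))
}

#' Coverage fraction of a nested gene set
#'
#' `100 * |subset| / |parent|`; `subset` must be contained in `parent`.
#'
#' @param subset,parent character vectors of gene symbols, or integers
#'   giving the set sizes directly.
#' @return percentage (full precision; round for display).
#' @export
coverage_fraction <- function(subset, parent) {
  if (is.numeric(subset) && is.numeric(parent)) {
    if (subset > parent) stop("subset larger than parent")
    if (parent <= 0) stop("parent set empty")
    return(100 * subset / parent)
  }
  subset <- unique(subset)
  parent <- unique(parent)
  if (length(parent) == 0L) stop("parent set empty")
  if (length(setdiff(subset, parent)) > 0L) {
    stop("subset contains genes outside parent set")
  }
  100 * length(subset) / length(parent)
}

#' Partition linked genes by LTR family
#'
#' Splits the union of two families' linked-gene sets into the genes
#' linked by both families, by LTR7 only, and by LTR5_Hs only. The three
#' parts are disjoint and sum to the union.
#'
#' @param ltr7_targets,ltr5_targets character vectors of linked gene
#'   symbols.
#' @return list `both`, `ltr7_only`, `ltr5_only`, `either` (sorted
#'   character vectors).
#' @export
family_partition <- function(ltr7_targets, ltr5_targets) {
  ltr7_targets <- unique(ltr7_targets)
  ltr5_targets <- unique(ltr5_targets)
  list(
    both = sort(intersect(ltr7_targets, ltr5_targets)),
    ltr7_only = sort(setdiff(ltr7_targets, ltr5_targets)),
    ltr5_only = sort(setdiff(ltr5_targets, ltr7_targets)),
    either = sort(union(ltr7_targets, ltr5_targets))
  )
}

#' Build a target catalog for one LTR family
#'
#' Collects, for one family, the linked genes, the per-experiment response
#' sets, and the derived high-confidence target set, mirroring the
#' catalog-table layout of the analysis (loci, linked genes, per-assay
#' response overlaps, combined high-confidence set).
#'
#' @param linked character vector of linked gene symbols.
#' @param response_sets named list of per-experiment response gene sets.
#' @param universe optional universe symbols for validation.
#' @return list of class `target_catalog`: `linked`, `response_sets`,
#'   `per_experiment` (linked-and-responsive per assay),
#'   `high_confidence`, `summary` (counts data.frame).
#' @export
target_catalog <- function(linked, response_sets, universe = NULL) {
  linked <- unique(linked)
  if (!is.null(universe)) {
    if (inherits(universe, "ltr_genes")) universe <- universe$symbol
    bad <- setdiff(linked, universe)
    if (length(bad) > 0L) {
      stop("linked gene(s) outside universe: ",
           paste(bad[seq_len(min(5L, length(bad)))], collapse = ", "))
    }
  }
  per_experiment <- lapply(response_sets,
                           function(s) sort(intersect(linked, s)))
  hc <- high_confidence_targets(linked, response_sets)
  summary <- data.frame(
    category = c("linked genes",
                 if (length(response_sets) > 0L)
                   paste0(names(response_sets), "/linked") else NULL,
                 "high-confidence targets"),
    n = c(length(linked), vapply(per_experiment, length, integer(1L)),
          length(hc)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(linked = sort(linked), response_sets = response_sets,
                 per_experiment = per_experiment, high_confidence = hc,
                 summary = summary),
            class = "target_catalog")
}

#' @export
print.target_catalog <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
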