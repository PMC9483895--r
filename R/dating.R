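#' Estimate the locus acquisition rate from anchor species
#'
#' Under the linear-accumulation model, loci accumulate on the lineage to
#' the reference genome at a constant rate after the anchor split. The
#' rate is the number of loci gained on that lineage since the anchor
#' divergence, per million years:
#' `rate = (reference_count - mean(anchor counts)) / (anchor_time -
#' reference_time)`. The canonical anchors are the Old World Monkey
#' species at a 29 MYA split.
#'
#' @param anchor_counts named numeric vector (or plain vector) of highly
#'   conserved locus counts in the anchor species.
#' @param anchor_time divergence time of the anchors from the reference
#'   lineage, MYA.
#' @param reference_count catalog size in the reference genome.
#' @param reference_time time of the reference genome (default 0 MYA).
#' @return object of class `acquisition_rate`: list with `rate`
#'   (loci/MYA) and `anchors` bookkeeping.
#' @export
acquisition_rate <- function(anchor_counts, anchor_time, reference_count,
                             reference_time = 0) {
  if (length(anchor_counts) < 1L) stop("need at least one anchor count")
  if (anchor_time <= reference_time) {
    stop("anchor_time must exceed reference_time")
  }
  gain <- reference_count - mean(anchor_counts)
  if (gain <= 0) {
    stop("model violation: reference count does not exceed mean anchor ",
         "count (no accumulation to date)")
  }
  rate <- gain / (anchor_time - reference_time)
  structure(list(
    rate = rate,
    anchors = data.frame(
      species = if (is.null(names(anchor_counts)))
        paste0("anchor", seq_along(anchor_counts)) else names(anchor_counts),
      conserved_count = as.numeric(anchor_counts),
      divergence_mya = anchor_time,
      stringsAsFactors = FALSE
    ),
    reference_count = reference_count,
    reference_time = reference_time
  ), class = "acquisition_rate")
}

#' @export
print.acquisition_rate <- function(x, ...) {
  cat(sprintf("Acquisition rate: %.2f loci/MYA (%d anchors at %.1f MYA)\n",
              x$rate, nrow(x$anchors), x$anchors$divergence_mya[1L]))
  invisible(x)
}

#' Date a species' divergence from its conserved-locus deficit
#'
#' The deficit of highly conserved loci relative to the reference catalog,
#' divided by the acquisition rate, dates the species' split from the
#' extinct common ancestor: `t = (reference_count - conserved_count) /
#' rate`. Losses on the non-reference lineage are ignored by the model
#' (they inflate the deficit, biasing estimates upward).
#'
#' @param conserved_count highly conserved locus count(s) in the species
#'   of interest (vector allowed, optionally named).
#' @param rate an [acquisition_rate()] object.
#' @param reference_count catalog size; defaults to the rate's own.
#' @return data.frame `species`, `conserved_count`, `deficit`,
#'   `estimated_divergence_mya`, `rate_used`.
#' @export
estimate_divergence <- function(conserved_count, rate,
                                reference_count = rate$reference_count) {
  stopifnot(inherits(rate, "acquisition_rate"))
  if (any(conserved_count > reference_count)) {
    stop("conserved count exceeds reference count")
  }
  deficit <- reference_count - conserved_count
  data.frame(
    species = if (is.null(names(conserved_count)))
      paste0("species", seq_along(conserved_count)) else
        names(conserved_count),
    conserved_count = as.numeric(conserved_count),
    deficit = as.numeric(deficit),
    estimated_divergence_mya = deficit / rate$rate,
    rate_used = rate$rate,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Date all panel species from a conserved-count matrix
#'
#' Convenience wrapper: estimates the acquisition rate from designated
#' anchor species and dates every other non-reference species.
#'
#' @param matrix a `conserved_counts` object.
#' @param panel a [species_panel()].
#' @param anchor_species species used as anchors (default: all species at
#'   the maximum divergence time in the panel).
#' @param anchor_time anchor split time (default: their panel time).
#' @return list with `rate` and `dating` (the [estimate_divergence()]
#'   table for non-anchor, non-reference species).
#' @export
date_panel <- function(matrix, panel, anchor_species = NULL,
                       anchor_time = NULL) {
  stopifnot(inherits(matrix, "conserved_counts"))
  panel <- validate_panel(panel)
  nonref <- panel[!panel$is_reference, , drop = FALSE]
  if (is.null(anchor_species)) {
    anchor_species <- nonref$species_id[nonref$divergence_mya ==
                                          max(nonref$divergence_mya)]
  }
  if (is.null(anchor_time)) {
    anchor_time <- unique(nonref$divergence_mya[match(anchor_species,
                                                      nonref$species_id)])
    if (length(anchor_time) != 1L) {
      stop("anchor species have differing panel divergence times; ",
           "supply anchor_time explicitly")
    }
  }
  totals <- matrix$counts[, "Total"]
  rate <- acquisition_rate(totals[anchor_species], anchor_time,
                           reference_count = totals[matrix$reference])
  rest <- setdiff(names(totals), c(matrix$reference, anchor_species))
  list(rate = rate, dating = estimate_divergence(totals[rest], rate))
}
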