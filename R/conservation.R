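#' Call per-species conservation status of LTR loci
#'
#' Implements the two-requirement reciprocal-mapping rule. A human locus is
#' `HIGHLY_CONSERVED` in a target genome only if (1) the direct mapping hit
#' a single orthologous locus recovering at least `min_identity` of the
#' query, and (2) the reciprocal mapping of that hit back to the human
#' genome again hit a single locus at `>= min_identity`, landing on the
#' exact queried interval (same chromosome, coordinate slack at most
#' `slop`). A locus with no direct hit is `ABSENT`; every other outcome is
#' `DIVERGED`.
#'
#' @param loci an [ltr_loci] catalog (the reference-genome catalog).
#' @param direct mapping records of reference loci into target genomes
#'   ([validate_mappings()] columns); may cover several target species.
#' @param reciprocal mapping records of the direct hits back into the
#'   reference genome, keyed by the original `locus_id` and the species the
#'   direct hit was found in (`query_species` = target species of the
#'   direct test). Supplying a reciprocal record for a locus x species pair
#'   with no direct hit is a contract error.
#' @param min_identity identity threshold for both tests (default 0.95).
#' @param slop maximum `|dstart| + |dend|` (bp) for the reciprocal interval
#'   to count as the same locus (default 0).
#' @return data.frame with columns `locus_id`, `species`, `status`
#'   (`HIGHLY_CONSERVED` / `DIVERGED` / `ABSENT`), one row per locus x
#'   target species present in `direct`.
#' @export
classify_conservation <- function(loci, direct, reciprocal = NULL,
                                  min_identity = 0.95, slop = 0) {
  loci <- validate_loci(loci)
  direct <- validate_mappings(direct)
  unknown <- setdiff(direct$locus_id, loci$locus_id)
  if (length(unknown) > 0L) {
    stop("direct mappings reference unknown loci: ",
         paste(unknown[seq_len(min(5L, length(unknown)))], collapse = ", "))
  }
  key <- function(id, sp) paste(id, sp, sep = "\r")
  dkey <- key(direct$locus_id, direct$target_species)
  if (anyDuplicated(dkey)) {
    stop("duplicate direct mapping record for a locus x species pair")
  }

  has_direct_hit <- direct$n_hits >= 1L
  if (!is.null(reciprocal) && nrow(reciprocal) > 0L) {
    reciprocal <- validate_mappings(reciprocal)
    rkey <- key(reciprocal$locus_id, reciprocal$query_species)
    if (anyDuplicated(rkey)) {
      stop("duplicate reciprocal record for a locus x species pair")
    }
    orphan <- !(rkey %in% dkey[has_direct_hit])
    if (any(orphan)) {
      stop("reciprocal record without a direct hit for locus: ",
           paste(reciprocal$locus_id[orphan][1:min(5L, sum(orphan))],
                 collapse = ", "))
    }
    ridx <- match(dkey, rkey)
  } else {
    ridx <- rep(NA_integer_, nrow(direct))
  }

  lidx <- match(direct$locus_id, loci$locus_id)
  direct_pass <- direct$n_hits == 1L & !is.na(direct$identity) &
    direct$identity >= min_identity

  if (is.null(reciprocal) || nrow(reciprocal) == 0L || all(is.na(ridx))) {
    recip_pass <- rep(FALSE, nrow(direct))
  } else {
    r_nhits <- reciprocal$n_hits[ridx]
    r_ident <- reciprocal$identity[ridx]
    r_chrom <- reciprocal$chrom[ridx]
    r_start <- reciprocal$start[ridx]
    r_end <- reciprocal$end[ridx]
    recip_pass <- !is.na(ridx) & !is.na(r_nhits) & r_nhits == 1L &
      !is.na(r_ident) & r_ident >= min_identity &
      !is.na(r_chrom) & r_chrom == loci$chrom[lidx] &
      (abs(r_start - loci$start[lidx]) +
         abs(r_end - loci$end[lidx])) <= slop
    recip_pass[is.na(recip_pass)] <- FALSE
  }

  status <- ifelse(!has_direct_hit, "ABSENT",
                   ifelse(direct_pass & recip_pass, "HIGHLY_CONSERVED",
                          "DIVERGED"))
  data.frame(
    locus_id = direct$locus_id,
    species = direct$target_species,
    status = status,
    stringsAsFactors = FALSE
  )
}

#' Classify loci as human-specific against chimpanzee and bonobo
#'
#' A reference locus is human-specific when in *both* Pan genomes no
#' mapping achieves at least `hs_identity_cutoff` of the query (the
#' permissive sub-10% cutoff: any mapping at or above it disqualifies). It
#' is additionally a bona fide human-specific insertion when no alignment
#' chain intersects the locus in either genome.
#'
#' @param loci an [ltr_loci] catalog.
#' @param chimp_records,bonobo_records direct mapping records of the loci
#'   into the chimpanzee and bonobo genomes; loci without a record are
#'   treated as unmapped with no intersecting chain.
#' @param hs_identity_cutoff identity below which a mapping does not count
#'   as evidence of presence (default 0.10).
#' @return data.frame `locus_id`, `human_specific`, `bona_fide`.
#' @export
classify_human_specific <- function(loci, chimp_records, bonobo_records,
                                    hs_identity_cutoff = 0.10) {
  loci <- validate_loci(loci)
  per_species <- function(recs) {
    if (is.null(recs) || nrow(recs) == 0L) {
      return(data.frame(absent = rep(TRUE, nrow(loci)),
                        chain_free = rep(TRUE, nrow(loci))))
    }
    recs <- validate_mappings(recs)
    idx <- match(loci$locus_id, recs$locus_id)
    hit <- !is.na(idx) & recs$n_hits[idx] >= 1L &
      !is.na(recs$identity[idx]) & recs$identity[idx] >= hs_identity_cutoff
    chain <- !is.na(idx) & recs$intersects_chain[idx]
    data.frame(absent = !hit, chain_free = !chain)
  }
  ch <- per_species(chimp_records)
  bo <- per_species(bonobo_records)
  human_specific <- ch$absent & bo$absent
  data.frame(
    locus_id = loci$locus_id,
    human_specific = human_specific,
    bona_fide = human_specific & ch$chain_free & bo$chain_free,
    stringsAsFactors = FALSE
  )
}

#' Matrix of highly conserved locus counts per species and subfamily
#'
#' Rows are species (the reference first), columns the family's
#' subfamilies plus a `Total` column. The reference row equals the catalog
#' counts. Every locus x non-reference-species pair must be covered by a
#' conservation call; gaps are an error.
#'
#' @param calls output of [classify_conservation()] covering all pairs.
#' @param loci the reference catalog.
#' @param panel a [species_panel()]; its non-reference species define the
#'   expected rows.
#' @param family family to tabulate (default `"LTR7"`).
#' @return object of class `conserved_counts`: a list with `counts`
#'   (integer matrix), `pct` (percentages of the reference counts),
#'   `family` and `reference`.
#' @export
conserved_count_matrix <- function(calls, loci, panel, family = "LTR7") {
  loci <- validate_loci(loci)
  panel <- validate_panel(panel)
  loci <- loci[loci$family == family, , drop = FALSE]
  if (nrow(loci) == 0L) stop("no loci of family ", family, " in catalog")
  species <- panel$species_id[!panel$is_reference]
  reference <- panel$species_id[panel$is_reference]

  calls <- calls[calls$locus_id %in% loci$locus_id &
                   calls$species %in% species, , drop = FALSE]
  have <- paste(calls$locus_id, calls$species, sep = "\r")
  want <- paste(rep(loci$locus_id, times = length(species)),
                rep(species, each = nrow(loci)), sep = "\r")
  gaps <- setdiff(want, have)
  if (length(gaps) > 0L) {
    stop("conservation calls missing for ", length(gaps),
         " locus x species pair(s), e.g. ",
         paste(sub("\r", " in ", gaps[seq_len(min(3L, length(gaps)))]),
               collapse = "; "))
  }

  subs <- subfamilies_for(family)
  ref_counts <- subfamily_counts(loci, family)
  hc <- calls[calls$status == "HIGHLY_CONSERVED", , drop = FALSE]
  sub_of <- loci$subfamily[match(hc$locus_id, loci$locus_id)]
  tab <- table(factor(hc$species, levels = species),
               factor(sub_of, levels = subs))
  counts <- rbind(matrix(ref_counts, nrow = 1,
                         dimnames = list(reference, subs)),
                  as.matrix(tab))
  counts <- cbind(counts, Total = rowSums(counts))
  storage.mode(counts) <- "integer"
  denom <- c(ref_counts, sum(ref_counts))
  pct <- sweep(counts, 2L, denom, "/") * 100
  pct[, denom == 0] <- NA_real_
  structure(list(counts = counts, pct = pct, family = family,
                 reference = reference),
            class = "conserved_counts")
}

#' @export
print.conserved_counts <- function(x, ...) {
  cat("Highly conserved", x$family, "loci (reference:", x$reference, ")\n")
  print(x$counts)
  invisible(x)
}

#' Gains and losses of highly conserved loci per species
#'
#' The gain is the number of highly conserved loci found in a species'
#' genome; the loss is the deficit relative to the reference catalog. Gain
#' and loss always sum to the reference total.
#'
#' @param matrix a `conserved_counts` object.
#' @return data.frame `species`, `gain`, `loss`.
#' @export
gains_losses <- function(matrix) {
  stopifnot(inherits(matrix, "conserved_counts"))
  total <- matrix$counts[matrix$reference, "Total"]
  gain <- matrix$counts[, "Total"]
  data.frame(
    species = rownames(matrix$counts),
    gain = as.integer(gain),
    loss = as.integer(total - gain),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
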