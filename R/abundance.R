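#' Subfamily abundance profile of a species
#'
#' The abundance profile of a species is the percentage of its highly
#' conserved loci falling in each subfamily; percentages sum to 100. The
#' reference species' profile is the catalog composition itself.
#'
#' @param matrix a `conserved_counts` object from
#'   [conserved_count_matrix()].
#' @param species species row to profile.
#' @return named numeric vector of subfamily percentages.
#' @export
subfamily_profile <- function(matrix, species) {
  stopifnot(inherits(matrix, "conserved_counts"))
  if (!species %in% rownames(matrix$counts)) {
    stop("species not in matrix: ", species)
  }
  counts <- matrix$counts[species, colnames(matrix$counts) != "Total"]
  total <- sum(counts)
  if (total == 0L) {
    stop("species ", species,
         " has no conserved loci; abundance profile undefined")
  }
  100 * counts / total
}

#' Pearson correlation of two abundance profiles
#'
#' @param pA,pB numeric vectors of equal length (>= 2); zero variance in
#'   either vector is an error (the correlation is undefined).
#' @return Pearson product-moment correlation coefficient.
#' @export
profile_correlation <- function(pA, pB) {
  if (length(pA) != length(pB)) stop("profiles differ in length")
  if (length(pA) < 2L) stop("need at least 2 components")
  if (stats::sd(pA) == 0 || stats::sd(pB) == 0) {
    stop("zero variance: correlation undefined")
  }
  cor(pA, pB, method = "pearson")
}

#' All pairwise profile correlations
#'
#' @param matrix a `conserved_counts` object.
#' @param species species to include (default: all with >= 1 conserved
#'   locus; excluded species are reported in a warning).
#' @return data.frame `species_a`, `species_b`, `r` for each unordered
#'   pair.
#' @export
profile_correlation_table <- function(matrix, species = NULL) {
  stopifnot(inherits(matrix, "conserved_counts"))
  all_sp <- rownames(matrix$counts)
  if (is.null(species)) species <- all_sp
  empty <- species[matrix$counts[species, "Total"] == 0L]
  if (length(empty) > 0L) {
    warning("excluding species with zero conserved loci: ",
            paste(empty, collapse = ", "))
    species <- setdiff(species, empty)
  }
  profiles <- lapply(species, function(s) subfamily_profile(matrix, s))
  names(profiles) <- species
  pairs <- utils::combn(species, 2L)
  data.frame(
    species_a = pairs[1L, ], species_b = pairs[2L, ],
    r = apply(pairs, 2L, function(p) {
      profile_correlation(profiles[[p[1L]]], profiles[[p[2L]]])
    }),
    stringsAsFactors = FALSE
  )
}

#' Association between divergence time and profile resemblance
#'
#' For each non-reference species, correlates its subfamily abundance
#' profile with the reference profile, then correlates these
#' resemblance values with the species' divergence times. When subfamily
#' retention decays with lineage age the association is negative.
#'
#' @param matrix a `conserved_counts` object.
#' @param panel a [species_panel()].
#' @return list with `pairs` (data.frame `species`, `divergence_mya`,
#'   `r_to_reference`) and `r_assoc` (Pearson correlation of the two
#'   columns).
#' @export
resemblance_vs_divergence <- function(matrix, panel) {
  stopifnot(inherits(matrix, "conserved_counts"))
  panel <- validate_panel(panel)
  reference <- matrix$reference
  ref_profile <- subfamily_profile(matrix, reference)
  species <- intersect(panel$species_id[!panel$is_reference],
                       rownames(matrix$counts))
  species <- species[matrix$counts[species, "Total"] > 0L]
  if (length(species) < 2L) {
    stop("need at least 2 non-reference species with conserved loci")
  }
  r_ref <- vapply(species, function(s) {
    profile_correlation(subfamily_profile(matrix, s), ref_profile)
  }, numeric(1L))
  tms <- panel$divergence_mya[match(species, panel$species_id)]
  pairs <- data.frame(species = species, divergence_mya = tms,
                      r_to_reference = unname(r_ref),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(pairs = pairs, r_assoc = profile_correlation(tms, unname(r_ref)))
}
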