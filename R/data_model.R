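#' ltrevo: evolutionary conservation and regulatory target analysis of
#' endogenous retrovirus LTR loci
#'
#' The package models the life cycle of a comparative analysis of fixed,
#' non-polymorphic retroviral LTR insertions in the human genome: reading
#' locus catalogs and cross-species mapping tables, calling per-species
#' conservation status, profiling subfamily abundance, dating species
#' divergence from locus-acquisition deficits, associating loci with genes
#' through basal-plus-extension regulatory domains, and computing the
#' exact-test enrichment statistics used to summarise category membership
#' of locus-linked genes.
#'
#' @importFrom stats cor dhyper phyper rbinom rnorm runif p.adjust setNames
#' @importFrom utils read.table write.table
#' @keywords internal
"_PACKAGE"

#' The eleven monophyletic LTR7 subfamily labels
#'
#' Sequence subtypes of the HERVH promoter LTR7 recognised throughout the
#' package. The LTR5_Hs family has a single subtype carrying the family
#' name.
#'
#' @export
LTR7_SUBFAMILIES <- c(
  "LTR7B", "LTR7C", "LTR7bc", "LTR7o", "LTR7d1", "LTR7d2",
  "LTR7u1", "LTR7u2", "LTR7up1", "LTR7up2", "LTR7Y"
)

#' Valid LTR family labels
#' @export
LTR_FAMILIES <- c("LTR7", "LTR5_Hs")

subfamilies_for <- function(family) {
  if (family == "LTR7") LTR7_SUBFAMILIES else "LTR5_Hs"
}

#' Construct a validated LTR locus catalog
#'
#' A locus catalog is a plain `data.frame` with one row per fixed LTR
#' insertion and columns `locus_id`, `family`, `subfamily`, `chrom`,
#' `start`, `end`, `strand`. Coordinates are 0-based half-open (BED
#' convention).
#'
#' @param locus_id unique locus identifiers.
#' @param family family label, `"LTR7"` or `"LTR5_Hs"` (recycled).
#' @param subfamily subfamily label; must be one of [LTR7_SUBFAMILIES] for
#'   LTR7 and the literal `"LTR5_Hs"` otherwise.
#' @param chrom,start,end,strand genomic interval; `start < end`, strand in
#'   `+`, `-`, `.`.
#' @return a `data.frame` of class `ltr_loci`.
#' @export
ltr_loci <- function(locus_id, family, subfamily, chrom, start, end,
                     strand = ".") {
  df <- data.frame(
    locus_id = as.character(locus_id),
    family = as.character(family),
    subfamily = as.character(subfamily),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  validate_loci(df)
}

validate_loci <- function(df) {
  required <- c("locus_id", "family", "subfamily", "chrom", "start", "end",
                "strand")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("locus catalog lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$locus_id)) {
    stop("duplicate locus_id: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  }
  bad_fam <- !df$family %in% LTR_FAMILIES
  if (any(bad_fam)) {
    stop("unknown family label: ", paste(unique(df$family[bad_fam]),
                                         collapse = ", "))
  }
  ok_sub <- ifelse(df$family == "LTR7",
                   df$subfamily %in% LTR7_SUBFAMILIES,
                   df$subfamily == "LTR5_Hs")
  if (!all(ok_sub)) {
    stop("subfamily inconsistent with family for locus: ",
         paste(df$locus_id[!ok_sub], collapse = ", "))
  }
  bad_coord <- !(df$start < df$end) | df$start < 0L
  if (any(bad_coord)) {
    stop("invalid coordinates (need 0 <= start < end) for locus: ",
         paste(df$locus_id[bad_coord], collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  class(df) <- c("ltr_loci", "data.frame")
  df
}

#' Read an LTR locus catalog from a BED file
#'
#' Expects at least 4 BED columns; the name field encodes
#' `locus_id|subfamily`. Column 5 (score) is ignored, column 6 is the
#' strand when present.
#'
#' @param path path to a BED file.
#' @param family family label applied to every record.
#' @return an `ltr_loci` catalog.
#' @export
read_locus_bed <- function(path, family = "LTR7") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 4L) stop("BED file needs >= 4 columns: ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0L)
  if (length(bad) > 0L) {
    stop("malformed BED coordinates at line ", bad[1L], " of ", path)
  }
  name <- vapply(fields, `[[`, "", 4L)
  parts <- strsplit(name, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("BED name field must be 'locus_id|subfamily' (line ",
         which(lengths(parts) != 2L)[1L], ")")
  }
  strand <- if (ncol_min >= 6L) vapply(fields, `[[`, "", 6L) else "."
  ltr_loci(
    locus_id = vapply(parts, `[[`, "", 1L),
    family = family,
    subfamily = vapply(parts, `[[`, "", 2L),
    chrom = chrom, start = start, end = end, strand = strand
  )
}

#' Write a locus catalog as 6-column BED
#'
#' @param loci an `ltr_loci` catalog.
#' @param path output path.
#' @export
write_locus_bed <- function(loci, path) {
  loci <- validate_loci(loci)
  bed <- data.frame(
    chrom = loci$chrom, start = loci$start, end = loci$end,
    name = paste(loci$locus_id, loci$subfamily, sep = "|"),
    score = 0L, strand = loci$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count loci per subfamily
#'
#' @param loci an `ltr_loci` catalog.
#' @param family restrict to one family (default: all rows).
#' @return named integer vector over the family's subfamilies (zero counts
#'   included), in canonical subfamily order.
#' @export
subfamily_counts <- function(loci, family = NULL) {
  if (!is.null(family)) loci <- loci[loci$family == family, , drop = FALSE]
  levels <- if (is.null(family)) {
    unique(c(LTR7_SUBFAMILIES, "LTR5_Hs")[c(LTR7_SUBFAMILIES, "LTR5_Hs") %in%
                                            loci$subfamily])
  } else {
    subfamilies_for(family)
  }
  tab <- table(factor(loci$subfamily, levels = levels))
  setNames(as.integer(tab), names(tab))
}

mapping_columns <- c("locus_id", "query_species", "target_species", "n_hits",
                     "chrom", "start", "end", "identity", "intersects_chain")

#' Validate a table of cross-species mapping records
#'
#' One row per (locus, query species, target species) mapping attempt,
#' emulating a LiftOver result: `n_hits` counts candidate target loci,
#' `chrom`/`start`/`end` give the mapped interval (NA when `n_hits == 0`),
#' `identity` is the fraction of the query recovered at the mapped locus
#' (NA when `n_hits == 0`), and `intersects_chain` records whether any
#' alignment chain covered the query at all.
#'
#' @param df a data.frame with the columns listed above.
#' @return the validated data.frame (class `ltr_mappings`).
#' @export
validate_mappings <- function(df) {
  missing <- setdiff(mapping_columns, names(df))
  if (length(missing) > 0L) {
    stop("mapping table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$n_hits < 0L)) stop("n_hits must be non-negative")
  hit <- df$n_hits >= 1L
  if (any(hit & (is.na(df$identity) | is.na(df$chrom)))) {
    stop("records with n_hits >= 1 must carry a mapped interval and identity")
  }
  if (any(!hit & (!is.na(df$identity) | !is.na(df$chrom)))) {
    stop("records with n_hits == 0 must not carry an interval or identity")
  }
  idv <- df$identity[hit]
  if (any(idv < 0 | idv > 1)) {
    stop("identity outside [0,1] for locus: ",
         paste(df$locus_id[hit][idv < 0 | idv > 1], collapse = ", "))
  }
  if (any(hit & !df$intersects_chain)) {
    stop("intersects_chain must be TRUE whenever n_hits >= 1")
  }
  class(df) <- c("ltr_mappings", "data.frame")
  df
}

#' Read a mapping table (TSV with header)
#'
#' @param path path to a tab-separated file with the columns of
#'   [validate_mappings()].
#' @return validated `ltr_mappings` data.frame.
#' @export
read_mapping_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", "."))
  df$n_hits <- as.integer(df$n_hits)
  df$intersects_chain <- as.logical(df$intersects_chain)
  validate_mappings(df)
}

#' Write a mapping table as TSV
#' @param mappings validated `ltr_mappings`.
#' @param path output path.
#' @export
write_mapping_table <- function(mappings, path) {
  mappings <- validate_mappings(mappings)
  write.table(mappings[, mapping_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a validated gene universe
#'
#' The gene universe is the fixed set of genes against which all
#' enrichment statistics are computed (the analysis default holds 18,777
#' genes). Genes absent from the annotation are outside the universe;
#' there is no implicit default universe.
#'
#' @param symbol unique gene symbols.
#' @param chrom,tss,strand single-position TSS annotation; strand `+`/`-`.
#' @param categories character vector of `;`-separated category flags per
#'   gene (e.g. `"OS;SYNAPTIC"`), `""` for none.
#' @return a `data.frame` of class `ltr_genes`.
#' @export
ltr_genes <- function(symbol, chrom, tss, strand, categories = "") {
  df <- data.frame(
    symbol = as.character(symbol), chrom = as.character(chrom),
    tss = as.integer(tss), strand = as.character(strand),
    categories = as.character(categories), stringsAsFactors = FALSE
  )
  validate_genes(df)
}

validate_genes <- function(df) {
  required <- c("symbol", "chrom", "tss", "strand", "categories")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("gene annotation lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$symbol)) {
    stop("duplicate gene symbols: ",
         paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(df$tss < 0L)) stop("TSS positions must be non-negative")
  df$categories[is.na(df$categories)] <- ""
  class(df) <- c("ltr_genes", "data.frame")
  df
}

#' Test category membership of genes
#'
#' @param genes an `ltr_genes` annotation.
#' @param flag category flag name (e.g. `"OS"`).
#' @return logical vector along the rows of `genes`.
#' @export
gene_has_category <- function(genes, flag) {
  vapply(strsplit(genes$categories, ";", fixed = TRUE),
         function(x) flag %in% x, logical(1L))
}

#' Gene symbols carrying a category flag
#' @inheritParams gene_has_category
#' @return character vector of symbols.
#' @export
category_genes <- function(genes, flag) {
  genes$symbol[gene_has_category(genes, flag)]
}

#' Read / write a gene annotation TSV
#'
#' Columns: `symbol`, `chrom`, `tss`, `strand`, `categories`
#' (semicolon-separated flags, empty allowed).
#'
#' @param path file path.
#' @return `read_gene_annotation`: validated `ltr_genes`.
#' @export
read_gene_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = "NA",
                   colClasses = c(categories = "character"))
  validate_genes(df)
}

#' @rdname read_gene_annotation
#' @param genes validated `ltr_genes`.
#' @export
write_gene_annotation <- function(genes, path) {
  genes <- validate_genes(genes)
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated species panel
#'
#' Exactly one reference species (the human genome) must carry
#' `divergence_mya = 0`; all other divergence times are positive and give
#' the species' split from the lineage leading to the reference, in
#' million years ago (MYA).
#'
#' @param species_id unique short species names.
#' @param clade free-text clade label.
#' @param divergence_mya non-negative split times in MYA.
#' @param is_reference logical; exactly one TRUE.
#' @return a `data.frame` of class `ltr_panel`.
#' @export
species_panel <- function(species_id, clade, divergence_mya, is_reference) {
  df <- data.frame(
    species_id = as.character(species_id), clade = as.character(clade),
    divergence_mya = as.numeric(divergence_mya),
    is_reference = as.logical(is_reference), stringsAsFactors = FALSE
  )
  validate_panel(df)
}

validate_panel <- function(df) {
  required <- c("species_id", "clade", "divergence_mya", "is_reference")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("species panel lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$species_id)) stop("species_id must be unique")
  if (sum(df$is_reference) != 1L) {
    stop("species panel must contain exactly one reference species")
  }
  if (df$divergence_mya[df$is_reference] != 0) {
    stop("reference species must have divergence_mya = 0")
  }
  if (any(df$divergence_mya[!df$is_reference] <= 0)) {
    stop("non-reference species must have divergence_mya > 0")
  }
  class(df) <- c("ltr_panel", "data.frame")
  df
}

#' Read / write a species panel TSV
#'
#' Columns: `species_id`, `clade`, `divergence_mya`, `is_reference`.
#'
#' @param path file path.
#' @return `read_species_panel`: validated `ltr_panel`.
#' @export
read_species_panel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$is_reference <- as.logical(df$is_reference)
  validate_panel(df)
}

#' @rdname read_species_panel
#' @param panel validated `ltr_panel`.
#' @export
write_species_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
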