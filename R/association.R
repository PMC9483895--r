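#' Build basal-plus-extension regulatory domains
#'
#' Each gene receives a basal domain around its TSS (`basal_up` bp
#' upstream, `basal_down` bp downstream, orientation-aware) and an
#' extended domain reaching from the basal boundary toward the neighboring
#' genes' basal domains, but never further than `max_extension` bp per
#' side. Extension stops at the nearest non-overlapping neighboring basal
#' boundary; chromosome ends clip all domains. Coordinates are 0-based
#' half-open throughout.
#'
#' Defaults are the published basal-plus-extension defaults of the
#' GREAT-style association (5 kb upstream, 1 kb downstream, 1 Mb maximum
#' extension); all three are configurable.
#'
#' @param genes an [ltr_genes] annotation (unique symbols).
#' @param basal_up,basal_down basal domain extent upstream/downstream of
#'   the TSS, in bp.
#' @param max_extension maximum extension per side, in bp.
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   clip domains on the right; unnamed chromosomes are left unclipped.
#' @return data.frame of class `reg_domains`: `symbol`, `chrom`, `strand`,
#'   `tss`, `basal_start`, `basal_end`, `ext_start`, `ext_end`.
#' @export
build_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                          max_extension = 1e6, chrom_sizes = NULL) {
  genes <- validate_genes(genes)
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  basal_start <- pmax(basal_start, 0)
  limit <- if (is.null(chrom_sizes)) rep(Inf, nrow(genes)) else
    ifelse(is.na(chrom_sizes[genes$chrom]), Inf, chrom_sizes[genes$chrom])
  basal_end <- pmin(basal_end, limit)

  ext_start <- numeric(nrow(genes))
  ext_end <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    bs <- basal_start[i]
    be <- basal_end[i]
    # nearest non-overlapping neighbor basal boundaries: a gene's own basal
    # never qualifies (be > bs), so no self-exclusion is needed
    sbe <- sort(be)
    pos_l <- findInterval(bs, sbe)                 # count of be_j <= bs_k
    left_limit <- ifelse(pos_l > 0L, sbe[pmax(pos_l, 1L)], 0)
    sbs <- sort(bs)
    pos_r <- findInterval(be - 0.5, sbs) + 1L      # first bs_j >= be_k
    right_limit <- ifelse(pos_r <= length(sbs),
                          sbs[pmin(pos_r, length(sbs))], limit[i])
    ext_start[i] <- pmax(bs - max_extension, left_limit, 0)
    ext_end[i] <- pmin(be + max_extension, right_limit, limit[i])
  }
  out <- data.frame(
    symbol = genes$symbol, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss,
    basal_start = as.numeric(basal_start), basal_end = as.numeric(basal_end),
    ext_start = ext_start, ext_end = ext_end,
    stringsAsFactors = FALSE
  )
  class(out) <- c("reg_domains", "data.frame")
  out
}

#' Assign LTR loci to genes via regulatory-domain overlap
#'
#' A locus is linked to every gene whose extended regulatory domain it
#' overlaps by at least one bp (`mode = "any_overlap"`); in
#' `mode = "midpoint"` the locus midpoint must fall inside the domain.
#' Loci overlapping no domain are recorded as unlinked.
#'
#' @param loci an [ltr_loci] catalog.
#' @param domains a `reg_domains` table from [build_domains()].
#' @param mode overlap rule, `"any_overlap"` (default) or `"midpoint"`.
#' @return object of class `association_table`: list with `links`
#'   (data.frame `locus_id`, `symbol`), `gene_counts` (named integer
#'   vector of loci per linked gene), `linked_genes`, `unlinked_loci`.
#' @export
assign_loci <- function(loci, domains, mode = c("any_overlap", "midpoint")) {
  mode <- match.arg(mode)
  loci <- validate_loci(loci)
  stopifnot(inherits(domains, "reg_domains"))
  if (mode == "midpoint") {
    mid <- floor((loci$start + loci$end) / 2)
    qstart <- mid
    qend <- mid + 1L
  } else {
    qstart <- loci$start
    qend <- loci$end
  }
  # 0-based half-open -> 1-based closed for IRanges; shared seqlevels so
  # queries and subjects live on one reference
  seqlv <- union(unique(loci$chrom), unique(domains$chrom))
  q <- GenomicRanges::GRanges(factor(loci$chrom, levels = seqlv),
                              IRanges::IRanges(qstart + 1L, qend))
  s <- GenomicRanges::GRanges(factor(domains$chrom, levels = seqlv),
                              IRanges::IRanges(domains$ext_start + 1L,
                                               domains$ext_end))
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
  links <- data.frame(
    locus_id = loci$locus_id[S4Vectors::queryHits(hits)],
    symbol = domains$symbol[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  links <- links[order(links$locus_id, links$symbol), , drop = FALSE]
  rownames(links) <- NULL
  counts_tab <- table(links$symbol)
  gene_counts <- setNames(as.integer(counts_tab), names(counts_tab))
  structure(list(
    links = links,
    gene_counts = gene_counts,
    linked_genes = sort(unique(links$symbol)),
    unlinked_loci = sort(setdiff(loci$locus_id, links$locus_id))
  ), class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Association table: %d links, %d linked genes, %d unlinked loci\n",
              nrow(x$links), length(x$linked_genes), length(x$unlinked_loci)))
  invisible(x)
}

#' Genes linked by at least k loci
#'
#' @param table an `association_table`.
#' @param k minimum locus count (>= 1).
#' @return character vector of gene symbols.
#' @export
genes_with_min_loci <- function(table, k) {
  stopifnot(inherits(table, "association_table"), k >= 1)
  sort(names(table$gene_counts)[table$gene_counts >= k])
}

#' Export regulatory domains as BED (extended domains; basal encoded in
#' the thickStart/thickEnd columns)
#'
#' @param domains a `reg_domains` table.
#' @param path output path.
#' @export
write_domains_bed <- function(domains, path) {
  stopifnot(inherits(domains, "reg_domains"))
  bed <- data.frame(
    domains$chrom, as.integer(domains$ext_start),
    as.integer(domains$ext_end), domains$symbol, 0L, domains$strand,
    as.integer(domains$basal_start), as.integer(domains$basal_end)
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
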