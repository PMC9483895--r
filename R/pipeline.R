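#' Run the full synthetic analysis pipeline
#'
#' Orchestrates every stage on generator output: lineage simulation for
#' both LTR families, conservation calling, conserved-count matrices,
#' gains/losses, abundance profiles and their divergence association,
#' acquisition-rate dating, human-specific classification, gene-universe
#' simulation, regulatory-domain association, category enrichment,
#' perturbation-response simulation and target-catalog algebra. The run
#' is a pure function of (config, seed): identical configs produce
#' identical results and, when `outdir` is given, byte-identical report
#' files.
#'
#' @param config7,config5 [sim_config()]s for the LTR7 and LTR5_Hs
#'   catalogs; they share the gene universe of `config7`.
#' @param outdir optional directory; when given, every table is written
#'   as TSV with a one-line provenance header.
#' @return (invisibly) a list with all intermediate and final objects:
#'   `sim7`, `sim5`, `calls7`, `matrix7`, `gains7`, `profiles`, `dating`,
#'   `human_specific7`, `genes`, `domains`, `assoc7`, `assoc5`,
#'   `enrichment`, `catalog7`, `catalog5`, `partition`, `coverage`, `log`.
#' @export
run_pipeline <- function(config7 = sim_config(seed = 1L, family = "LTR7"),
                         config5 = sim_config(seed = 2L,
                                              family = "LTR5_Hs"),
                         outdir = NULL) {
  stopifnot(inherits(config7, "sim_config"), inherits(config5, "sim_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- sprintf("[%s] %s", stage,
                                        paste0(..., collapse = ""))
  }

  sim7 <- simulate_locus_history(config7)
  sim5 <- simulate_locus_history(config5)
  note("simulate", nrow(sim7$catalog), " LTR7 and ", nrow(sim5$catalog),
       " LTR5_Hs loci, seed ", config7$seed, "/", config5$seed)

  calls7 <- classify_conservation(sim7$catalog, sim7$direct,
                                  sim7$reciprocal)
  matrix7 <- conserved_count_matrix(calls7, sim7$catalog, sim7$panel,
                                    family = "LTR7")
  gains7 <- gains_losses(matrix7)
  note("conserve", sum(calls7$status == "HIGHLY_CONSERVED"),
       " highly conserved calls of ", nrow(calls7))

  profiles <- list(
    pairwise = profile_correlation_table(matrix7),
    resemblance = resemblance_vs_divergence(matrix7, sim7$panel)
  )
  dating <- date_panel(matrix7, sim7$panel)
  note("date", sprintf("rate %.2f loci/MYA", dating$rate$rate))

  pan7 <- split(sim7$direct, sim7$direct$target_species)
  human_specific7 <- classify_human_specific(sim7$catalog,
                                             pan7[["chimpanzee"]],
                                             pan7[["bonobo"]])
  note("human_specific", sum(human_specific7$human_specific),
       " human-specific LTR7 loci (",
       sum(human_specific7$bona_fide), " bona fide)")

  genes <- simulate_gene_universe(config7)
  chrom_sizes <- setNames(rep(config7$chrom_size, config7$n_chrom),
                          paste0("chr", seq_len(config7$n_chrom)))
  domains <- build_domains(genes, chrom_sizes = chrom_sizes)
  assoc7 <- assign_loci(sim7$catalog, domains)
  assoc5 <- assign_loci(sim5$catalog, domains)
  note("associate", length(assoc7$linked_genes), " LTR7-linked and ",
       length(assoc5$linked_genes), " LTR5_Hs-linked genes")

  enr <- list(
    ltr7_os = category_enrichment(assoc7$linked_genes, "OS", genes),
    ltr5_os = category_enrichment(assoc5$linked_genes, "OS", genes),
    ltr7_synaptic = category_enrichment(assoc7$linked_genes, "SYNAPTIC",
                                        genes),
    ltr5_synaptic = category_enrichment(assoc5$linked_genes, "SYNAPTIC",
                                        genes)
  )
  sub_rows <- lapply(subfamilies_for("LTR7"), function(sf) {
    ids <- sim7$catalog$locus_id[sim7$catalog$subfamily == sf]
    linked <- unique(assoc7$links$symbol[assoc7$links$locus_id %in% ids])
    if (length(linked) == 0L) return(NULL)
    ce <- category_enrichment(linked, "OS", genes)
    data.frame(subfamily = sf, loci = length(ids),
               linked = length(linked),
               os_linked = ce$a, observed_pct = ce$observed_pct_r,
               enrichment = ce$enrichment_r, p = ce$p_two_sided,
               stringsAsFactors = FALSE)
  })
  enrichment_by_subfamily <- do.call(rbind, sub_rows)

  resp7 <- simulate_perturbation_response(assoc7$linked_genes, genes,
                                          config7,
                                          experiments = c("CRISPRi",
                                                          "HERVH"))
  resp5 <- simulate_perturbation_response(assoc5$linked_genes, genes,
                                          config5,
                                          experiments = c("CRISPRi",
                                                          "KRABa"))
  catalog7 <- target_catalog(assoc7$linked_genes, resp7, genes)
  catalog5 <- target_catalog(assoc5$linked_genes, resp5, genes)
  partition <- family_partition(assoc7$linked_genes, assoc5$linked_genes)
  hc_either <- high_confidence_targets(partition$either, c(resp7, resp5))
  coverage <- data.frame(
    set = c("ltr7", "ltr5", "either"),
    n = c(length(catalog7$linked), length(catalog5$linked),
          length(partition$either)),
    high_confidence = c(length(catalog7$high_confidence),
                        length(catalog5$high_confidence),
                        length(hc_either)),
    stringsAsFactors = FALSE
  )
  coverage$pct <- round_half_up(100 * coverage$high_confidence /
                                  coverage$n, 2L)
  note("targets", length(hc_either), " of ", length(partition$either),
       " linked genes are high-confidence targets")

  result <- list(sim7 = sim7, sim5 = sim5, calls7 = calls7,
                 matrix7 = matrix7, gains7 = gains7, profiles = profiles,
                 dating = dating, human_specific7 = human_specific7,
                 genes = genes, domains = domains, assoc7 = assoc7,
                 assoc5 = assoc5, enrichment = enr,
                 enrichment_by_subfamily = enrichment_by_subfamily,
                 catalog7 = catalog7, catalog5 = catalog5,
                 partition = partition, coverage = coverage,
                 log = unlist(log))

  if (!is.null(outdir)) {
    write_pipeline_reports(result, outdir)
  }
  invisible(result)
}

write_tsv_report <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ltrevo %s seed=%d",
                     as.character(utils::packageVersion("ltrevo")), seed),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_reports <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- result$sim7$config$seed
  out <- function(name) file.path(outdir, name)
  cm <- data.frame(species = rownames(result$matrix7$counts),
                   result$matrix7$counts, check.names = FALSE)
  write_tsv_report(cm, out("conservation_matrix.tsv"), seed)
  write_tsv_report(result$gains7, out("gains_losses.tsv"), seed)
  write_tsv_report(result$profiles$pairwise,
                   out("profile_correlations.tsv"), seed)
  write_tsv_report(result$profiles$resemblance$pairs,
                   out("resemblance.tsv"), seed)
  write_tsv_report(result$dating$dating, out("dating.tsv"), seed)
  write_tsv_report(result$human_specific7, out("human_specific.tsv"), seed)
  write_tsv_report(result$assoc7$links, out("associations_ltr7.tsv"), seed)
  gc7 <- data.frame(symbol = names(result$assoc7$gene_counts),
                    n_loci = as.integer(result$assoc7$gene_counts))
  write_tsv_report(gc7, out("gene_locus_counts_ltr7.tsv"), seed)
  enr_df <- do.call(rbind, lapply(names(result$enrichment), function(nm) {
    e <- result$enrichment[[nm]]
    data.frame(comparison = nm, a = e$a, b = e$b, c = e$c, d = e$d,
               observed_pct = e$observed_pct_r,
               expected_pct = e$expected_pct_r,
               enrichment = e$enrichment_r, p = e$p_two_sided,
               stringsAsFactors = FALSE)
  }))
  write_tsv_report(enr_df, out("enrichment.tsv"), seed)
  write_tsv_report(result$enrichment_by_subfamily,
                   out("enrichment_by_subfamily.tsv"), seed)
  write_tsv_report(result$catalog7$summary, out("targets_ltr7.tsv"), seed)
  write_tsv_report(result$catalog5$summary, out("targets_ltr5.tsv"), seed)
  part_df <- data.frame(
    set = c("both", "ltr7_only", "ltr5_only", "either"),
    n = vapply(result$partition, length, integer(1L))
  )
  write_tsv_report(part_df, out("family_partition.tsv"), seed)
  write_tsv_report(result$coverage, out("coverage.tsv"), seed)
  writeLines(result$log, out("pipeline_log.txt"))
  invisible(outdir)
}
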