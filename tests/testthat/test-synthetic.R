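small_cfg <- function(seed = 3L, ...) {
  args <- modifyList(
    list(seed = seed,
         birth_epochs = data.frame(older = c(40, 29, 13),
                                   younger = c(29, 13, 0),
                                   n_loci = c(120L, 500L, 40L)),
         universe_size = 1500L),
    list(...))
  do.call(sim_config, args)
}

test_that("identical configurations reproduce identical outputs", {
  a <- simulate_locus_history(small_cfg())
  b <- simulate_locus_history(small_cfg())
  expect_identical(as.data.frame(a$catalog), as.data.frame(b$catalog))
  expect_identical(as.data.frame(a$direct), as.data.frame(b$direct))
  expect_identical(a$truth$present, b$truth$present)
  ga <- simulate_gene_universe(small_cfg())
  gb <- simulate_gene_universe(small_cfg())
  expect_identical(as.data.frame(ga), as.data.frame(gb))
  # a different seed changes the draw
  c <- simulate_locus_history(small_cfg(seed = 4L))
  expect_false(identical(as.data.frame(a$catalog), as.data.frame(c$catalog)))
})

test_that("every emitted table round trips through the package readers", {
  sim <- simulate_locus_history(small_cfg())
  dir <- withr::local_tempdir()
  write_locus_bed(sim$catalog, file.path(dir, "catalog.bed"))
  expect_equal(as.data.frame(read_locus_bed(file.path(dir, "catalog.bed"))),
               as.data.frame(sim$catalog))
  write_mapping_table(sim$direct, file.path(dir, "direct.tsv"))
  back <- read_mapping_table(file.path(dir, "direct.tsv"))
  expect_equal(back$n_hits, sim$direct$n_hits)
  expect_equal(back$identity, sim$direct$identity, tolerance = 1e-12)
  write_species_panel(sim$panel, file.path(dir, "panel.tsv"))
  expect_equal(as.data.frame(read_species_panel(file.path(dir, "panel.tsv"))),
               as.data.frame(sim$panel))
  genes <- simulate_gene_universe(small_cfg())
  write_gene_annotation(genes, file.path(dir, "genes.tsv"))
  expect_equal(as.data.frame(read_gene_annotation(file.path(dir,
                                                            "genes.tsv"))),
               as.data.frame(genes))
})

test_that("ancestral-only insertions give every species the same truth set", {
  cfg <- sim_config(seed = 6L,
                    birth_epochs = data.frame(older = 40, younger = 35,
                                              n_loci = 200L),
                    retention_loss_prob = 0, pan_loss_frac = 0)
  sim <- simulate_locus_history(cfg)
  expect_true(all(sim$truth$present))
})

test_that("the noise-free limit is recovered exactly and monotonically", {
  cfg <- small_cfg(retention_loss_prob = 0, pan_loss_frac = 0,
                   reciprocal_fail_frac = 0, identity_sd = 0,
                   identity_decay = 0)
  sim <- simulate_locus_history(cfg)
  calls <- classify_conservation(sim$catalog, sim$direct, sim$reciprocal)
  hc <- calls$status == "HIGHLY_CONSERVED"
  truth <- sim$truth$present[cbind(match(calls$locus_id,
                                         rownames(sim$truth$present)),
                                   match(calls$species,
                                         colnames(sim$truth$present)))]
  expect_identical(hc, unname(truth))
  # conserved counts rise toward younger splits
  m <- conserved_count_matrix(calls, sim$catalog, sim$panel)
  tms <- sim$panel$divergence_mya[match(rownames(m$counts),
                                        sim$panel$species_id)]
  ord <- order(tms)
  expect_true(all(diff(m$counts[ord, "Total"]) <= 0L |
                    diff(tms[ord]) == 0))
})

test_that("default-condition conservation calls match planted truth at
           99 percent or better", {
  sim <- simulate_locus_history(sim_config(seed = 21L))
  calls <- classify_conservation(sim$catalog, sim$direct, sim$reciprocal)
  hc <- calls$status == "HIGHLY_CONSERVED"
  truth <- sim$truth$present[cbind(match(calls$locus_id,
                                         rownames(sim$truth$present)),
                                   match(calls$species,
                                         colnames(sim$truth$present)))]
  expect_gte(mean(hc == truth), 0.99)
})

test_that("the simulated gene universe honours its category parameters", {
  cfg <- sim_config(seed = 14L)
  genes <- simulate_gene_universe(cfg)
  expect_equal(nrow(genes), 18777L)
  n_os <- sum(gene_has_category(genes, "OS"))
  expect_lt(abs(n_os - 2413), 4 * sqrt(2413 * (1 - 2413 / 18777)))
  expect_equal(sum(gene_has_category(genes, "SYNAPTIC")), 355L)
  expect_equal(sum(gene_has_category(genes, "FETAL_GONAD_MARKER")), 88L)

  tiny <- simulate_gene_universe(small_cfg(universe_size = 100L,
                                           synaptic_count = 10L,
                                           fetal_gonad_count = 5L))
  expect_equal(nrow(tiny), 100L)

  no_os <- simulate_gene_universe(sim_config(seed = 14L, os_fraction = 0,
                                             universe_size = 500L))
  expect_equal(sum(gene_has_category(no_os, "OS")), 0L)
})
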