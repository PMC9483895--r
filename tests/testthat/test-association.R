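test_that("a lone gene gets the textbook basal and extended domain", {
  genes <- ltr_genes("SOLO", "chr1", 100000L, "+")
  d <- build_domains(genes, chrom_sizes = c(chr1 = 2e6))
  expect_equal(d$basal_start, 95000)
  expect_equal(d$basal_end, 101000)
  expect_equal(d$ext_start, 0)
  expect_equal(d$ext_end, 1101000)

  # minus strand mirrors the basal domain around the TSS
  neg <- ltr_genes("NEG", "chr1", 100000L, "-")
  dn <- build_domains(neg, chrom_sizes = c(chr1 = 2e6))
  expect_equal(dn$basal_start, 99000)
  expect_equal(dn$basal_end, 105000)
})

test_that("close neighbors truncate each other's extensions", {
  genes <- ltr_genes(c("A", "B"), "chr1", c(100000L, 110000L), "+")
  d <- build_domains(genes, chrom_sizes = c(chr1 = 2e6))
  o <- oracle_domains(genes, chrom_sizes = c(chr1 = 2e6))
  expect_equal(d$ext_start, o$ext_start)
  expect_equal(d$ext_end, o$ext_end)
  # A's right extension stops at B's basal start, and vice versa
  expect_equal(d$ext_end[1L], d$basal_start[2L])
  expect_equal(d$ext_start[2L], d$basal_end[1L])
})

test_that("locus assignment matches the canonical cases", {
  genes <- ltr_genes("G1", "chr1", 1000000L, "+")
  d <- build_domains(genes, chrom_sizes = c(chr1 = 1e7))
  inside <- ltr_loci("in_basal", "LTR7", "LTR7Y", "chr1", 995500L,
                     995900L)
  far <- ltr_loci("far", "LTR7", "LTR7Y", "chr1", 3000000L, 3000400L)
  a1 <- assign_loci(inside, d)
  expect_equal(a1$links$symbol, "G1")
  a2 <- assign_loci(far, d)
  expect_equal(nrow(a2$links), 0L)
  expect_equal(a2$unlinked_loci, "far")
})

test_that("a toy chromosome reproduces the exhaustive all-pairs check", {
  genes <- ltr_genes(c("A", "B", "C"), "chr1",
                     c(50000L, 300000L, 1500000L), c("+", "-", "+"))
  d <- build_domains(genes, chrom_sizes = c(chr1 = 3e6))
  set.seed(9)
  loci <- random_loci(5L, n_chrom = 1L, chrom_size = 3e6 - 500L)
  got <- assign_loci(loci, d)$links
  want <- oracle_assign(loci, d)
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("growing the extension cap never removes a link", {
  set.seed(13)
  genes <- random_gene_annotation(20L)
  loci <- random_loci(100L)
  exts <- c(1e4, 1e5, 5e5, 1e6)
  tabs <- lapply(exts, function(e) {
    assign_loci(loci, build_domains(genes, max_extension = e))$links
  })
  for (i in seq_len(length(tabs) - 1L)) {
    small <- paste(tabs[[i]]$locus_id, tabs[[i]]$symbol)
    big <- paste(tabs[[i + 1L]]$locus_id, tabs[[i + 1L]]$symbol)
    expect_true(all(small %in% big))
  }
})

test_that("basal overlap always links regardless of neighbors", {
  genes <- ltr_genes(c("L", "R"), "chr1", c(100000L, 103000L), "+")
  d <- build_domains(genes)
  # locus inside L's basal domain, which overlaps R's basal domain area
  locus <- ltr_loci("x", "LTR7", "LTR7Y", "chr1", 99000L, 99400L)
  links <- assign_loci(locus, d)$links
  expect_true("L" %in% links$symbol)
})

test_that("midpoint mode links only the domain containing the midpoint", {
  genes <- ltr_genes("M", "chr1", 500000L, "+")
  d <- build_domains(genes, max_extension = 0)
  # domain is [495000, 501000); locus straddles the right edge
  locus <- ltr_loci("edge", "LTR7", "LTR7Y", "chr1", 500900L, 501300L)
  expect_equal(nrow(assign_loci(locus, d, mode = "any_overlap")$links), 1L)
  expect_equal(nrow(assign_loci(locus, d, mode = "midpoint")$links), 0L)
})

test_that("gene-level locus counts support the min-k filter", {
  genes <- ltr_genes(c("A", "B", "C"), "chr1",
                     c(100000L, 2000000L, 4000000L), "+")
  d <- build_domains(genes, chrom_sizes = c(chr1 = 6e6))
  mk <- function(id, pos) ltr_loci(id, "LTR7", "LTR7Y", "chr1", pos,
                                   pos + 400L)
  loci <- rbind(mk("a1", 99000L),
                mk("b1", 1999000L), mk("b2", 2000500L),
                mk("c1", 3999000L), mk("c2", 4000500L), mk("c3", 4002000L))
  loci <- validate_loci(loci)
  tab <- assign_loci(loci, d)
  expect_equal(unname(tab$gene_counts[c("A", "B", "C")]), c(1L, 2L, 3L))
  expect_equal(genes_with_min_loci(tab, 1L), c("A", "B", "C"))
  expect_equal(genes_with_min_loci(tab, 2L), c("B", "C"))
  # recount oracle from the raw multimap
  recount <- table(tab$links$symbol)
  expect_equal(genes_with_min_loci(tab, 2L),
               sort(names(recount)[recount >= 2L]))
})
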