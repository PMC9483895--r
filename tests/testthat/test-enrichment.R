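test_that("two-sided Fisher handles symmetric, degenerate and hand-checked
           tables", {
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_two_sided(0, 0, 3, 7), 1)   # empty first row
  # enumeration oracle on the (10,10,10,10)-margin class
  expect_equal(fisher_two_sided(1, 9, 9, 1), oracle_fisher(1, 9, 9, 1))
  expect_error(fisher_two_sided(-1, 2, 3, 4), "negative")
  expect_error(fisher_two_sided(0, 0, 0, 0), "undefined")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(1234)
  for (i in 1:60) {
    cells <- rpois(4L, lambda = sample(c(2, 8, 40), 1L))
    if (sum(cells) == 0L) next
    expect_equal(
      fisher_two_sided(cells[1], cells[2], cells[3], cells[4]),
      fisher.test(matrix(cells, 2L))$p.value,
      tolerance = 1e-10
    )
  }
})

test_that("Fisher p is invariant under simultaneous row and column swap", {
  set.seed(55)
  for (i in 1:40) {
    x <- rpois(4L, 6) + c(1L, 0L, 0L, 1L)
    p1 <- fisher_two_sided(x[1], x[2], x[3], x[4])
    p2 <- fisher_two_sided(x[4], x[3], x[2], x[1])
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_true(p1 > 0 && p1 <= 1)
  }
})

test_that("enrichment ratios reproduce the published arithmetic", {
  er <- enrichment_ratio(562, 2957, 2413, 18777)
  expect_equal(er$observed_pct_r, 19.01)
  expect_equal(er$expected_pct_r, 12.85)
  expect_equal(er$enrichment_r, 1.48)

  er2 <- enrichment_ratio(76, 321, 2413, 18777)
  expect_equal(er2$enrichment_r, 1.84)

  er3 <- enrichment_ratio(30, 100, 60, 200)
  expect_equal(er3$enrichment, 1)
  expect_error(enrichment_ratio(1, 0, 2, 10), "denominator")
})

test_that("category enrichment builds both table constructions", {
  genes <- ltr_genes(
    symbol = sprintf("G%02d", 1:20), chrom = "chr1",
    tss = 1:20 * 1000L, strand = "+",
    categories = rep(c("OS", ""), times = c(8L, 12L))
  )
  linked <- sprintf("G%02d", c(1:5, 15:18))  # 5 of 9 linked are OS
  ce <- category_enrichment(linked, "OS", genes, method = "population")
  expect_equal(unname(c(ce$a, ce$b, ce$c, ce$d)), c(5, 4, 3, 8))
  expect_equal(ce$a + ce$b + ce$c + ce$d, 20)
  expect_equal(ce$p_two_sided, fisher_two_sided(5, 4, 3, 8))
  expect_equal(ce$enrichment, (5 / 9) / (8 / 20))
  # enrichment > 1 exactly when the observed exceeds the expected share
  expect_true((ce$enrichment > 1) == (ce$observed_pct > ce$expected_pct))

  ce2 <- category_enrichment(linked, "OS", genes, method = "expected")
  expect_equal(unname(c(ce2$a, ce2$b, ce2$c, ce2$d)),
               c(5, 4, round(9 * 8 / 20), 9 - round(9 * 8 / 20)))

  # category equal to the whole universe: no signal by construction
  all_cat <- category_enrichment(linked, genes$symbol, genes)
  expect_equal(all_cat$enrichment, 1)
  expect_equal(all_cat$p_two_sided, 1)

  expect_error(category_enrichment(c(linked, "NOT_THERE"), "OS", genes),
               "outside the universe")
})

test_that("differential comparisons reproduce published p-values", {
  d1 <- differential_comparison(251, 377, 1319, 2580)
  expect_equal(signif(d1$p_two_sided, 3L), 1.53e-08)
  expect_equal(round(d1$pct_A, 2L), 66.58)

  d2 <- differential_comparison(50, 58, 201, 319)
  expect_equal(signif(d2$p_two_sided, 3L), 4.27e-04)

  d3 <- differential_comparison(10, 20, 10, 20)
  expect_equal(d3$p_two_sided, 1)
  expect_error(differential_comparison(5, 3, 1, 10), "exceed")
})

test_that("hypergeometric overlap equals the direct tail sum", {
  expect_equal(hypergeometric_overlap(10, 10, 0, 100), 1)
  expect_equal(hypergeometric_overlap(50, 50, 50, 50), 1)
  # independent tail summation for (10, 10, 5, 100)
  tail_sum <- sum(vapply(5:10, function(i) {
    choose(10, i) * choose(90, 10 - i) / choose(100, 10)
  }, numeric(1L)))
  expect_equal(hypergeometric_overlap(10, 10, 5, 100), tail_sum)
  expect_equal(signif(tail_sum, 4L), 6.716e-04)   # frozen oracle value
  expect_error(hypergeometric_overlap(10, 10, 11, 100), "inconsistent")
})

test_that("the combined score is the log-p z product", {
  expect_equal(combined_score(1, 5), 0)
  expect_equal(combined_score(0.01, -2), 9.21034, tolerance = 1e-5)
  expect_equal(combined_score(exp(-1), 3), -3)
  expect_error(combined_score(0, 1), "positive")
  expect_error(combined_score(0.5, Inf), "finite")
})
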