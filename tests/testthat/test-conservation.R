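test_that("the two-requirement rule classifies the canonical cases", {
  loci <- toy_catalog(5L)
  direct <- rbind(
    hit_for(loci, 1L, "chimpanzee", 0.97),   # clean hit, reciprocal below
    hit_for(loci, 2L, "chimpanzee", 0.94),   # below threshold
    hit_for(loci, 3L, "chimpanzee", 0.99),   # multi-hit, see next line
    mapping_row(loci$locus_id[4L], "chimpanzee", 0L),  # no direct hit
    hit_for(loci, 5L, "chimpanzee", 0.98)    # reciprocal lands elsewhere
  )
  direct$n_hits[3L] <- 2L
  reciprocal <- rbind(
    recip_for(loci, 1L, "chimpanzee", 0.96),
    recip_for(loci, 3L, "chimpanzee", 0.99),
    recip_for(loci, 5L, "chimpanzee", 0.98, shift = 5000L)
  )
  calls <- classify_conservation(loci, direct, reciprocal)
  expect_equal(calls$status,
               c("HIGHLY_CONSERVED", "DIVERGED", "DIVERGED", "ABSENT",
                 "DIVERGED"))

  # a direct hit without any reciprocal record cannot be highly conserved
  calls2 <- classify_conservation(loci, direct[1L, , drop = FALSE], NULL)
  expect_equal(calls2$status, "DIVERGED")

  # reciprocal slop admits near-exact return intervals
  near <- classify_conservation(loci, direct[1L, , drop = FALSE],
                                recip_for(loci, 1L, "chimpanzee", 0.96,
                                          shift = 3L), slop = 10)
  expect_equal(near$status, "HIGHLY_CONSERVED")
})

test_that("a reciprocal record without a direct hit is a contract error", {
  loci <- toy_catalog(2L)
  direct <- mapping_row(loci$locus_id[1L], "chimpanzee", 0L)
  reciprocal <- recip_for(loci, 1L, "chimpanzee", 0.99)
  expect_error(classify_conservation(loci, direct, reciprocal),
               "without a direct hit")
})

test_that("batch classification agrees with per-record rule re-evaluation", {
  set.seed(421)
  loci <- toy_catalog(60L, subfamily = "LTR7Y")
  species <- c("chimpanzee", "gibbon")
  direct <- do.call(rbind, lapply(species, function(sp) {
    n_hits <- sample(0:2, nrow(loci), replace = TRUE, prob = c(.3, .5, .2))
    out <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      if (n_hits[i] == 0L) mapping_row(loci$locus_id[i], sp, 0L) else {
        r <- hit_for(loci, i, sp, runif(1, 0.85, 1)); r$n_hits <- n_hits[i]; r
      }
    }))
    out
  }))
  hits <- direct[direct$n_hits >= 1L, ]
  keep <- runif(nrow(hits)) < 0.8
  reciprocal <- do.call(rbind, lapply(which(keep), function(j) {
    i <- match(hits$locus_id[j], loci$locus_id)
    recip_for(loci, i, hits$target_species[j], runif(1, 0.85, 1),
              shift = sample(c(0L, 0L, 0L, 100L), 1L))
  }))
  calls <- classify_conservation(loci, direct, reciprocal)
  expect_equal(calls$status,
               oracle_conservation(loci, direct, reciprocal))
})

test_that("lowering the identity threshold never loses conserved calls", {
  set.seed(77)
  loci <- toy_catalog(40L, subfamily = "LTR7B")
  direct <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    hit_for(loci, i, "gorilla", runif(1, 0.8, 1))
  }))
  reciprocal <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    recip_for(loci, i, "gorilla", runif(1, 0.8, 1))
  }))
  hc <- vapply(c(0.99, 0.97, 0.95, 0.9, 0.85, 0.8), function(th) {
    sum(classify_conservation(loci, direct, reciprocal,
                              min_identity = th)$status ==
          "HIGHLY_CONSERVED")
  }, integer(1L))
  expect_true(all(diff(hc) >= 0L))
})

test_that("human-specific calls follow the dual-genome absence rule", {
  loci <- toy_catalog(3L)
  none <- mapping_row(loci$locus_id, "chimpanzee", 0L, chain = FALSE)
  none_b <- mapping_row(loci$locus_id, "bonobo", 0L, chain = FALSE)
  hs <- classify_human_specific(loci, none, none_b)
  expect_true(all(hs$human_specific) && all(hs$bona_fide))

  # one mid-identity chimp hit disqualifies that locus entirely
  chimp <- rbind(hit_for(loci, 1L, "chimpanzee", 0.50),
                 mapping_row(loci$locus_id[2:3], "chimpanzee", 0L,
                             chain = FALSE))
  hs2 <- classify_human_specific(loci, chimp, none_b)
  expect_equal(hs2$human_specific, c(FALSE, TRUE, TRUE))
  expect_equal(hs2$bona_fide, c(FALSE, TRUE, TRUE))

  # chain intersection without a qualifying hit: human-specific, not bona fide
  chained <- mapping_row(loci$locus_id, "chimpanzee", 0L, chain = TRUE)
  hs3 <- classify_human_specific(loci, chained, none_b)
  expect_true(all(hs3$human_specific))
  expect_false(any(hs3$bona_fide))
})

test_that("the conserved-count matrix tabulates and rejects gaps", {
  loci <- toy_catalog(10L, subfamily = rep(c("LTR7Y", "LTR7B"), 5L))
  panel <- species_panel(c("human", "spX"), c("ref", "ape"), c(0, 10),
                         c(TRUE, FALSE))
  direct <- do.call(rbind, lapply(seq_len(10L), function(i) {
    if (i <= 4L) hit_for(loci, i, "spX", 0.99) else
      mapping_row(loci$locus_id[i], "spX", 0L)
  }))
  reciprocal <- do.call(rbind, lapply(1:4, function(i) {
    recip_for(loci, i, "spX", 0.99)
  }))
  calls <- classify_conservation(loci, direct, reciprocal)
  m <- conserved_count_matrix(calls, loci, panel)
  expect_equal(unname(m$counts["spX", "Total"]), 4L)
  expect_equal(unname(m$pct["spX", "Total"]), 40)
  expect_true(all(m$pct["human", c("LTR7Y", "LTR7B", "Total")] == 100))
  expect_true(all(m$counts <= m$counts["human", ][col(m$counts)]))

  gl <- gains_losses(m)
  expect_equal(gl$gain + gl$loss, rep(10L, 2L))
  expect_equal(gl$loss[gl$species == "human"], 0L)

  expect_error(conserved_count_matrix(calls[-1L, ], loci, panel),
               "missing")
})

test_that("synthetic truth bookkeeping matches the matrix exactly when
           mappings are noise-free", {
  cfg <- sim_config(seed = 5L, identity_sd = 0, identity_decay = 0,
                    reciprocal_fail_frac = 0, retention_loss_prob = 0.05,
                    pan_loss_frac = 0.02)
  sim <- simulate_locus_history(cfg)
  calls <- classify_conservation(sim$catalog, sim$direct, sim$reciprocal)
  m <- conserved_count_matrix(calls, sim$catalog, sim$panel)
  truth_totals <- colSums(sim$truth$present)
  expect_equal(m$counts[names(truth_totals), "Total"],
               setNames(as.integer(truth_totals), names(truth_totals)))
})
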