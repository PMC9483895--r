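#' Published summary-table counts
#'
#' The raw counts behind the published enrichment and coverage tables of
#' the LTR7/LTR5_Hs analysis, embedded as inputs so that every printed
#' statistic (percentages, enrichment ratios, two-sided Fisher p-values)
#' can be recomputed from scratch by the package's own operations.
#'
#' @return list of data.frames: `universe` (gene-universe and category
#'   sizes), `os` (family-level OS-gene enrichment), `subfamilies`
#'   (per-subfamily locus/linked/OS counts with printed ratios),
#'   `synaptic` (synaptic-network gene enrichment), `regulated`
#'   (high-confidence coverage rows with printed percentages and paired
#'   differential p-values), `coverage` (virus-response / differentiation
#'   coverage of the high-confidence set).
#' @export
printed_tables <- function() {
  universe <- data.frame(
    quantity = c("universe", "os_genes", "synaptic_genes"),
    n = c(18777L, 2413L, 355L)
  )
  os <- data.frame(
    family = c("LTR7", "LTR5_Hs"),
    linked = c(2957L, 935L),
    os_linked = c(562L, 126L),
    printed_observed_pct = c(19.01, 13.48),
    printed_expected_pct = c(12.85, 12.85),
    printed_enrichment = c(1.48, 1.05),
    printed_p = c(1.131e-10, 0.732),
    stringsAsFactors = FALSE
  )
  subfamilies <- data.frame(
    subfamily = c(LTR7_SUBFAMILIES, "All"),
    loci = c(547L, 412L, 307L, 243L, 215L, 445L, 143L, 195L, 378L, 96L,
             373L, 3354L),
    linked = c(864L, 622L, 486L, 380L, 361L, 685L, 237L, 321L, 575L, 152L,
               454L, 2957L),
    os_linked = c(145L, 115L, 91L, 76L, 70L, 144L, 48L, 76L, 119L, 34L,
                  79L, 562L),
    printed_pct = c(16.78, 18.49, 18.72, 20.00, 19.39, 21.02, 20.25, 23.68,
                    20.70, 22.37, 17.40, 19.01),
    printed_enrichment = c(1.31, 1.44, 1.46, 1.56, 1.51, 1.64, 1.58, 1.84,
                           1.61, 1.74, 1.35, 1.48),
    stringsAsFactors = FALSE
  )
  synaptic <- data.frame(
    family = c("LTR7", "LTR5_Hs"),
    linked = c(2957L, 935L),
    synaptic_linked = c(87L, 19L),
    printed_observed_pct = c(2.94, 2.03),
    printed_expected_pct = c(1.89, 1.89),
    printed_enrichment = c(1.56, 1.07),
    printed_p = c(0.0109, 1),
    stringsAsFactors = FALSE
  )
  regulated <- data.frame(
    row = c("ltr7", "ltr5", "either", "ge2_loci", "both", "ltr7_only",
            "ltr5_only", "ltr7_os", "ltr7_nonos", "ltr5_os", "ltr5_nonos",
            "either_os", "either_nonos", "both_os", "both_nonos",
            "hs_either", "fetal_gonad_hs", "hs_nonfetal"),
    n = c(2957L, 935L, 3515L, 1202L, 377L, 2580L, 558L, 562L, 2395L, 126L,
          809L, 630L, 2885L, 58L, 319L, 391L, 88L, 303L),
    regulated = c(1570L, 486L, 1944L, 664L, 251L, 1319L, 235L, 392L, 1178L,
                  92L, 394L, 432L, 1512L, 50L, 201L, 215L, 64L, 151L),
    printed_pct = c(53.09, 51.98, 55.31, 55.24, 66.58, 51.12, 42.11, 69.75,
                    49.19, 73.02, 48.70, 68.57, 52.41, 86.21, 63.01, 54.99,
                    72.73, 49.83),
    stringsAsFactors = FALSE
  )
  # differential comparisons: each row pairs two rows of `regulated` and
  # carries the printed two-sided Fisher p-value
  differential <- data.frame(
    name = c("both_vs_ge2loci", "both_vs_ltr7only", "both_vs_ltr5only",
             "ltr7_os_vs_nonos", "ltr5_os_vs_nonos", "either_os_vs_nonos",
             "both_os_vs_nonos", "fetal_vs_nonfetal"),
    group_a = c("both", "both", "both", "ltr7_os", "ltr5_os", "either_os",
                "both_os", "fetal_gonad_hs"),
    group_b = c("ge2_loci", "ltr7_only", "ltr5_only", "ltr7_nonos",
                "ltr5_nonos", "either_nonos", "both_nonos", "hs_nonfetal"),
    printed_p = c(9.958e-05, 1.53e-08, 1.70e-13, 5.96e-19, 2.85e-07,
                  8.34e-14, 0.0004271, 0.0001478),
    stringsAsFactors = FALSE
  )
  coverage <- data.frame(
    set = c("ltr_regulated", "sars_cov2_affected", "differentiation"),
    n = c(1944L, 1696L, 1558L),
    printed_pct = c(100.00, 87.24, 80.14),
    stringsAsFactors = FALSE
  )
  list(universe = universe, os = os, subfamilies = subfamilies,
       synaptic = synaptic, regulated = regulated,
       differential = differential, coverage = coverage)
}

#' Recompute every published table statistic from its raw counts
#'
#' Re-derives, with the package's own enrichment and coverage operations,
#' every percentage, enrichment ratio and two-sided Fisher p-value printed
#' in the embedded summary tables, and compares each to the printed value:
#' ratios and percentages must agree exactly after half-up rounding to two
#' decimals; p-values must agree to three significant figures (absorbing
#' the two-sided convention and rounding of the original report).
#'
#' @return data.frame with one row per statistic: `target` (short stable
#'   name), `value` (recomputed, full precision), `printed`, `cmp`
#'   (`"2dp"` or `"3sig"`), `pass`.
#' @export
replay_printed_tables <- function() {
  pt <- printed_tables()
  U <- pt$universe$n[pt$universe$quantity == "universe"]
  K_os <- pt$universe$n[pt$universe$quantity == "os_genes"]
  K_syn <- pt$universe$n[pt$universe$quantity == "synaptic_genes"]
  rows <- list()
  add <- function(target, value, printed, cmp) {
    pass <- if (cmp == "2dp") {
      isTRUE(all.equal(round_half_up(value, 2L), printed, tolerance = 1e-9))
    } else {
      isTRUE(all.equal(signif(value, 3L), signif(printed, 3L),
                       tolerance = 1e-9))
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, value = value, printed = printed, cmp = cmp,
      pass = pass, stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(nrow(pt$os))) {
    r <- pt$os[i, ]
    tag <- if (r$family == "LTR7") "tab1_ltr7_os" else "tab1_ltr5_os"
    ce <- category_enrichment_counts(r$os_linked, r$linked, K_os, U, "expected")
    add(paste0(tag, "_observed_pct"), ce$observed_pct,
        r$printed_observed_pct, "2dp")
    add(paste0(tag, "_expected_pct"), ce$expected_pct,
        r$printed_expected_pct, "2dp")
    add(paste0(tag, "_enrichment"), ce$enrichment, r$printed_enrichment,
        "2dp")
    add(paste0(tag, "_p"), ce$p_two_sided, r$printed_p, "3sig")
  }

  for (i in seq_len(nrow(pt$subfamilies))) {
    r <- pt$subfamilies[i, ]
    tag <- paste0("tab2_", tolower(r$subfamily), "_os")
    er <- enrichment_ratio(r$os_linked, r$linked, K_os, U)
    add(paste0(tag, "_pct"), er$observed_pct, r$printed_pct, "2dp")
    add(paste0(tag, "_enrichment"), er$enrichment, r$printed_enrichment,
        "2dp")
  }

  for (i in seq_len(nrow(pt$synaptic))) {
    r <- pt$synaptic[i, ]
    tag <- if (r$family == "LTR7") "tab4_ltr7_synaptic" else
      "tab4_ltr5_synaptic"
    ce <- category_enrichment_counts(r$synaptic_linked, r$linked, K_syn, U, "expected")
    add(paste0(tag, "_enrichment"), ce$enrichment, r$printed_enrichment,
        "2dp")
    add(paste0(tag, "_p"), ce$p_two_sided, r$printed_p, "3sig")
  }

  reg <- pt$regulated
  for (i in seq_len(nrow(reg))) {
    add(paste0("tab8_", reg$row[i], "_pct"),
        coverage_fraction(reg$regulated[i], reg$n[i]),
        reg$printed_pct[i], "2dp")
  }
  for (i in seq_len(nrow(pt$differential))) {
    d <- pt$differential[i, ]
    ra <- reg[reg$row == d$group_a, ]
    rb <- reg[reg$row == d$group_b, ]
    dc <- differential_comparison(ra$regulated, ra$n, rb$regulated, rb$n)
    add(paste0("tab8_", d$name, "_p"), dc$p_two_sided, d$printed_p, "3sig")
  }

  cov <- pt$coverage
  parent <- cov$n[cov$set == "ltr_regulated"]
  add("tab9_sars_pct", coverage_fraction(
    cov$n[cov$set == "sars_cov2_affected"], parent),
    cov$printed_pct[cov$set == "sars_cov2_affected"], "2dp")
  add("tab9_differentiation_pct", coverage_fraction(
    cov$n[cov$set == "differentiation"], parent),
    cov$printed_pct[cov$set == "differentiation"], "2dp")

  do.call(rbind, rows)
}

#' The twelve headline printed-table statistics
#'
#' A stable subset of [replay_printed_tables()] covering each table once:
#' family-level OS enrichment and p-values, the strongest subfamily
#' enrichment, synaptic-network enrichment, the high-confidence coverage
#' of dual-family targets with its three differential p-values, and the
#' virus-response coverage fraction.
#'
#' @return character vector of twelve target names.
#' @export
headline_targets <- function() {
  c("tab1_ltr7_os_enrichment", "tab1_ltr7_os_p",
    "tab1_ltr5_os_enrichment", "tab1_ltr5_os_p",
    "tab2_ltr7u2_os_enrichment",
    "tab4_ltr7_synaptic_enrichment", "tab4_ltr7_synaptic_p",
    "tab8_both_pct", "tab8_both_vs_ltr7only_p",
    "tab8_both_vs_ltr5only_p", "tab8_both_os_vs_nonos_p",
    "tab9_sars_pct")
}
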