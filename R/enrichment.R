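#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[a, b; c, d]` under the standard
#' "probability at most that of the observed table" rule: conditioning on
#' the margins, the p-value sums the hypergeometric probabilities of all
#' tables whose probability does not exceed the observed one (within the
#' customary relative tolerance of 1e-7 for ties). This is the convention
#' of mainstream exact-test implementations and reproduces
#' `stats::fisher.test`.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise.
#' @return p-value in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  m <- a + c          # column 1 margin
  n <- b + d          # column 2 margin
  k <- a + b          # row 1 margin
  if (m + n == 0) stop("all margins zero: test undefined")
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  d_obs <- dens[support == a]
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Observed/expected percentages and enrichment ratio
#'
#' @param obs_k,obs_n observed successes and group size.
#' @param exp_k,exp_n reference (expected-by-chance) successes and group
#'   size, typically the category prevalence in the gene universe.
#' @return list `observed_pct`, `expected_pct`, `enrichment` (full
#'   precision) plus their 2-decimal half-up roundings `observed_pct_r`,
#'   `expected_pct_r`, `enrichment_r` as printed in summary tables.
#' @export
enrichment_ratio <- function(obs_k, obs_n, exp_k, exp_n) {
  if (obs_n <= 0 || exp_n <= 0) stop("zero denominator")
  observed_pct <- 100 * obs_k / obs_n
  expected_pct <- 100 * exp_k / exp_n
  list(
    observed_pct = observed_pct,
    expected_pct = expected_pct,
    enrichment = observed_pct / expected_pct,
    observed_pct_r = round_half_up(observed_pct, 2L),
    expected_pct_r = round_half_up(expected_pct, 2L),
    enrichment_r = round_half_up(observed_pct / expected_pct, 2L)
  )
}

round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Enrichment of a gene category among locus-linked genes
#'
#' Builds a 2x2 table comparing the category count among linked genes
#' with its chance expectation and returns the enrichment ratio and the
#' two-sided Fisher p-value.
#'
#' Two table constructions are available. `method = "expected"` (the
#' default, matching the summary-table convention of this analysis)
#' compares the observed category count against the *rounded* expected
#' count in a pseudo-group of the same size:
#' `[k, n-k; round(n*K/U), n - round(n*K/U)]`. This test is conservative
#' because the comparison group carries no sampling variance.
#' `method = "population"` is the classical linked-vs-unlinked partition
#' of the whole universe: `[k, n-k; K-k, U-n-(K-k)]`; only under this
#' construction do the four cells sum to the universe size, and only this
#' construction is calibrated (type-I error approximately the nominal
#' level) under random sampling of the linked set.
#'
#' @param linked_genes character vector of linked gene symbols (must lie
#'   within the universe).
#' @param category_gene_set character vector of category member symbols,
#'   or a category flag name if `universe` is an [ltr_genes] annotation.
#' @param universe gene universe: an [ltr_genes] annotation or a character
#'   vector of symbols.
#' @param method table construction, `"expected"` or `"population"`.
#' @return list of class `contingency_result`: cells `a`,`b`,`c`,`d`,
#'   `observed_pct`, `expected_pct`, `enrichment`, `p_two_sided`, the
#'   rounded display values, and `method`.
#' @export
category_enrichment <- function(linked_genes, category_gene_set, universe,
                                method = c("expected", "population")) {
  method <- match.arg(method)
  if (inherits(universe, "ltr_genes") || is.data.frame(universe)) {
    if (is.character(category_gene_set) && length(category_gene_set) == 1L &&
        !category_gene_set %in% universe$symbol) {
      category_gene_set <- category_genes(universe, category_gene_set)
    }
    universe <- universe$symbol
  }
  outside <- setdiff(linked_genes, universe)
  if (length(outside) > 0L) {
    stop("linked gene(s) outside the universe: ",
         paste(outside[seq_len(min(5L, length(outside)))], collapse = ", "))
  }
  category_gene_set <- intersect(category_gene_set, universe)
  U <- length(universe)
  K <- length(category_gene_set)
  n <- length(unique(linked_genes))
  k <- length(intersect(unique(linked_genes), category_gene_set))
  category_enrichment_counts(k, n, K, U, method)
}

#' Category enrichment from counts
#'
#' Count-level core of [category_enrichment()], useful when only the
#' summary counts of an analysis are available (as when recomputing
#' published tables): `k` category members among `n` linked genes, with
#' `K` category members in a universe of `U`.
#'
#' @param k,n observed category count and linked-set size.
#' @param K,U category size and universe size.
#' @inheritParams category_enrichment
#' @return a `contingency_result`, as for [category_enrichment()].
#' @export
category_enrichment_counts <- function(k, n, K, U,
                                       method = c("expected",
                                                  "population")) {
  method <- match.arg(method)
  if (n <= 0 || U <= 0) stop("empty linked set or universe")
  if (method == "expected") {
    e <- round(n * K / U)
    cells <- c(a = k, b = n - k, c = e, d = n - e)
  } else {
    cells <- c(a = k, b = n - k, c = K - k, d = U - n - (K - k))
  }
  er <- enrichment_ratio(k, n, K, U)
  structure(c(
    as.list(cells),
    er,
    list(p_two_sided = fisher_two_sided(cells["a"], cells["b"],
                                        cells["c"], cells["d"]),
         method = method)
  ), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf(
    "Observed %.2f%%  Expected %.2f%%  Enrichment %.2f  p = %.4g (%s)\n",
    x$observed_pct, x$expected_pct, x$enrichment, x$p_two_sided, x$method))
  invisible(x)
}

#' Differential (set-vs-set) comparison of two proportions
#'
#' Two-sided Fisher's exact test on `[k_A, n_A - k_A; k_B, n_B - k_B]`,
#' used to compare the covered fraction between two gene groups (e.g.
#' perturbation-responsive fractions of two linked-gene classes).
#'
#' @param k_A,n_A successes and total in group A.
#' @param k_B,n_B successes and total in group B.
#' @return list of class `differential_comparison`: `pct_A`, `pct_B`,
#'   `table` (2x2 matrix), `p_two_sided`.
#' @export
differential_comparison <- function(k_A, n_A, k_B, n_B) {
  if (k_A > n_A || k_B > n_B) stop("successes exceed group total")
  tab <- matrix(c(k_A, n_A - k_A, k_B, n_B - k_B), nrow = 2L, byrow = TRUE,
                dimnames = list(c("A", "B"), c("in", "out")))
  structure(list(
    pct_A = 100 * k_A / n_A,
    pct_B = 100 * k_B / n_B,
    table = tab,
    p_two_sided = fisher_two_sided(k_A, n_A - k_A, k_B, n_B - k_B)
  ), class = "differential_comparison")
}

#' @export
print.differential_comparison <- function(x, ...) {
  cat(sprintf("A: %.2f%%  B: %.2f%%  p = %.4g\n",
              x$pct_A, x$pct_B, x$p_two_sided))
  invisible(x)
}

#' Hypergeometric overlap test for two gene sets
#'
#' Upper-tail probability of drawing at least `overlap` members of a
#' size-`size_A` set when sampling `size_B` genes without replacement from
#' a universe of `universe_size`.
#'
#' @param size_A,size_B set sizes.
#' @param overlap observed overlap.
#' @param universe_size universe size.
#' @return `P(X >= overlap)`.
#' @export
hypergeometric_overlap <- function(size_A, size_B, overlap, universe_size) {
  if (overlap > min(size_A, size_B) || size_A > universe_size ||
      size_B > universe_size) {
    stop("inconsistent set sizes")
  }
  phyper(overlap - 1, size_A, universe_size - size_A, size_B,
         lower.tail = FALSE)
}

#' Combined enrichment score
#'
#' `c = ln(p) * z`, the product of the log significance and the z-score
#' deviation from the expected rank (the convention of the Enrichr-style
#' combined score; the z-score is taken as an input).
#'
#' @param p Fisher p-value in (0, 1].
#' @param z finite z-score.
#' @return combined score.
#' @export
combined_score <- function(p, z) {
  if (any(p <= 0)) stop("p must be positive")
  if (any(!is.finite(z))) stop("z must be finite")
  log(p) * z
}

#' Benjamini-Hochberg adjustment utility
#'
#' @param p vector of p-values.
#' @return BH-adjusted p-values (`stats::p.adjust(p, "BH")`).
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")
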