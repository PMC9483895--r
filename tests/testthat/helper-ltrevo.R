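# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: the Fisher oracle enumerates the margin class with
# lchoose, the domain oracle applies the basal-plus-extension rule with
# explicit per-gene loops, and the assignment oracle checks every
# gene x locus pair.

toy_catalog <- function(n = 4L, family = "LTR7",
                        subfamily = rep(c("LTR7Y", "LTR7B"), length.out = n),
                        chrom = "chr1") {
  ltr_loci(
    locus_id = sprintf("T%03d", seq_len(n)),
    family = family, subfamily = subfamily,
    chrom = chrom, start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 400L, strand = "+"
  )
}

mapping_row <- function(locus_id, target, n_hits = 1L, chrom = "chr1",
                        start = NA_integer_, end = NA_integer_,
                        identity = NA_real_, chain = n_hits >= 1L,
                        query = "human") {
  data.frame(
    locus_id = locus_id, query_species = query, target_species = target,
    n_hits = as.integer(n_hits),
    chrom = if (n_hits >= 1L) chrom else NA_character_,
    start = start, end = end, identity = identity,
    intersects_chain = chain, stringsAsFactors = FALSE
  )
}

# hit record mapping a catalog locus to the same interval in the target
hit_for <- function(loci, i, target, identity, query = "human") {
  mapping_row(loci$locus_id[i], target, 1L, loci$chrom[i],
              loci$start[i], loci$end[i], identity, TRUE, query)
}

# reciprocal record landing back on the catalog interval (or shifted)
recip_for <- function(loci, i, species, identity, shift = 0L) {
  mapping_row(loci$locus_id[i], "human", 1L, loci$chrom[i],
              loci$start[i] + shift, loci$end[i] + shift, identity, TRUE,
              query = species)
}

# two-sided Fisher oracle: exhaustive enumeration over the margin class,
# probabilities from log-binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  r <- a + b; s <- c + d; k <- a + c; n <- r + s
  lo <- max(0L, k - s); hi <- min(k, r)
  support <- lo:hi
  lp <- lchoose(r, support) + lchoose(s, k - support) - lchoose(n, k)
  prob <- exp(lp)
  p_obs <- prob[support == a]
  min(sum(prob[prob <= p_obs * (1 + 1e-7)]), 1)
}

# basal-plus-extension rule applied literally, one gene at a time
oracle_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                           max_extension = 1e6, chrom_sizes = NULL) {
  n <- nrow(genes)
  bs <- be <- es <- ee <- numeric(n)
  for (g in seq_len(n)) {
    if (genes$strand[g] == "+") {
      bs[g] <- genes$tss[g] - basal_up
      be[g] <- genes$tss[g] + basal_down
    } else {
      bs[g] <- genes$tss[g] - basal_down
      be[g] <- genes$tss[g] + basal_up
    }
    bs[g] <- max(bs[g], 0)
    if (!is.null(chrom_sizes) && !is.na(chrom_sizes[genes$chrom[g]])) {
      be[g] <- min(be[g], chrom_sizes[genes$chrom[g]])
    }
  }
  for (g in seq_len(n)) {
    lim <- if (!is.null(chrom_sizes) &&
               !is.na(chrom_sizes[genes$chrom[g]]))
      chrom_sizes[genes$chrom[g]] else Inf
    left <- 0; right <- lim
    for (h in seq_len(n)) {
      if (h == g || genes$chrom[h] != genes$chrom[g]) next
      if (be[h] <= bs[g]) left <- max(left, be[h])
      if (bs[h] >= be[g]) right <- min(right, bs[h])
    }
    es[g] <- max(bs[g] - max_extension, left, 0)
    ee[g] <- min(be[g] + max_extension, right, lim)
  }
  data.frame(symbol = genes$symbol, chrom = genes$chrom,
             basal_start = bs, basal_end = be,
             ext_start = es, ext_end = ee, stringsAsFactors = FALSE)
}

# all-pairs overlap check in 0-based half-open coordinates
oracle_assign <- function(loci, domains) {
  links <- list()
  for (i in seq_len(nrow(loci))) {
    for (g in seq_len(nrow(domains))) {
      if (loci$chrom[i] != domains$chrom[g]) next
      if (loci$start[i] < domains$ext_end[g] &&
          domains$ext_start[g] < loci$end[i]) {
        links[[length(links) + 1L]] <- data.frame(
          locus_id = loci$locus_id[i], symbol = domains$symbol[g],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(links) == 0L) {
    return(data.frame(locus_id = character(0L), symbol = character(0L)))
  }
  out <- do.call(rbind, links)
  out[order(out$locus_id, out$symbol), , drop = FALSE]
}

# per-record re-evaluation of the conservation rule text
oracle_conservation <- function(loci, direct, reciprocal, min_identity = 0.95,
                                slop = 0) {
  out <- character(nrow(direct))
  for (i in seq_len(nrow(direct))) {
    d <- direct[i, ]
    if (d$n_hits == 0L) { out[i] <- "ABSENT"; next }
    l <- loci[loci$locus_id == d$locus_id, ]
    r <- reciprocal[reciprocal$locus_id == d$locus_id &
                      reciprocal$query_species == d$target_species, ]
    ok <- d$n_hits == 1L && !is.na(d$identity) && d$identity >= min_identity
    if (ok && nrow(r) == 1L && r$n_hits == 1L && !is.na(r$identity) &&
        r$identity >= min_identity && r$chrom == l$chrom &&
        abs(r$start - l$start) + abs(r$end - l$end) <= slop) {
      out[i] <- "HIGHLY_CONSERVED"
    } else {
      out[i] <- "DIVERGED"
    }
  }
  out
}

random_gene_annotation <- function(n_genes, n_chrom = 2L,
                                   chrom_size = 2e6) {
  ltr_genes(
    symbol = sprintf("G%03d", seq_len(n_genes)),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n_genes, replace = TRUE),
    tss = sample.int(chrom_size, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
}

random_loci <- function(n_loci, n_chrom = 2L, chrom_size = 2e6,
                        len = 400L) {
  start <- sample.int(chrom_size - len, n_loci)
  ltr_loci(
    locus_id = sprintf("R%04d", seq_len(n_loci)), family = "LTR7",
    subfamily = sample(LTR7_SUBFAMILIES, n_loci, replace = TRUE),
    chrom = sample(paste0("chr", seq_len(n_chrom)), n_loci, replace = TRUE),
    start = start, end = start + len, strand = "+"
  )
}
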