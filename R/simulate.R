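#' Default primate species panel
#'
#' Human reference plus ten non-human primates with divergence times (MYA)
#' taken from whole-genome dating consensus values: Pan species at 13,
#' gorilla at 15.1, orangutan at 16.0, gibbon at 16.8, and five Old World
#' Monkey species at 29.
#'
#' @return an [species_panel()] data.frame.
#' @export
default_panel <- function() {
  species_panel(
    species_id = c("human", "chimpanzee", "bonobo", "gorilla", "orangutan",
                   "gibbon", "rhesus", "crab_eating_macaque", "baboon",
                   "green_monkey", "snub_nosed_monkey"),
    clade = c("Human", "Great Ape", "Great Ape", "Great Ape", "Great Ape",
              "Gibbon", rep("Old World Monkey", 5L)),
    divergence_mya = c(0, 13, 13, 15.1, 16.0, 16.8, rep(29, 5L)),
    is_reference = c(TRUE, rep(FALSE, 10L))
  )
}

# Epoch-specific subfamily sampling weights: the catalog-wide composition
# follows the reference subfamily counts, tilted so ancient insertions
# favour the old subtypes (LTR7B/C/bc/o) and recent insertions favour the
# young ones (LTR7u*/up*/Y, with LTR7Y the dominant recent source).
ltr7_epoch_weights <- function(n_epochs) {
  base <- c(547, 412, 307, 243, 215, 445, 143, 195, 378, 96, 373) / 3354
  names(base) <- LTR7_SUBFAMILIES
  old_bias <- c(2, 2, 2, 2, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.2)
  young_bias <- c(0.2, 0.2, 0.2, 0.2, 1, 1, 2, 2, 2, 2, 4)
  mix <- function(b) { w <- base * b; w / sum(w) }
  if (n_epochs == 1L) return(list(base))
  # interpolate bias from old to young across epochs (oldest first)
  lapply(seq_len(n_epochs), function(i) {
    a <- (i - 1) / (n_epochs - 1)
    mix(old_bias^(1 - a) * young_bias^a)
  })
}

default_epochs <- function(family) {
  if (family == "LTR7") {
    data.frame(older = c(40, 29, 13), younger = c(29, 13, 0),
               n_loci = c(600L, 2579L, 175L))
  } else {
    data.frame(older = c(40, 29, 16.8, 13), younger = c(29, 16.8, 13, 0),
               n_loci = c(6L, 137L, 287L, 176L))
  }
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode
#' the study conditions the analysis assumes: a catalog of 3354 LTR7 (606
#' LTR5_Hs) loci on the reference lineage, born in three (four) epochs so
#' that roughly 600 LTR7 loci predate the Old World Monkey split at 29 MYA
#' and roughly 175 postdate the Pan split at 13 MYA; per-MYA linear
#' identity decay with Gaussian jitter; a gene universe of 18,777 with
#' 2413/18777 offspring-survival prevalence and 355 synaptic-network
#' genes; and a perturbation-response model responding with probability
#' 0.53 for linked and 0.04 for unlinked genes.
#'
#' @param seed integer RNG seed; identical configs give identical output.
#' @param family `"LTR7"` or `"LTR5_Hs"`.
#' @param panel species panel (default [default_panel()]).
#' @param insertion_rate optional loci/MYA; when supplied, replaces the
#'   epoch table with a single constant-rate epoch over
#'   `[0, origin_mya]` holding `round(insertion_rate * origin_mya)` loci.
#' @param origin_mya age of the oldest insertions (default 40).
#' @param birth_epochs data.frame `older`, `younger`, `n_loci`; default
#'   per-family profile described above.
#' @param identity_decay expected identity loss per MYA of divergence
#'   (default 0.001).
#' @param identity_sd Gaussian jitter of mapped identity (default 0.005).
#' @param retention_loss_prob per-branch probability that an inherited
#'   locus was lost in a non-reference species (default 0.02).
#' @param pan_loss_frac fraction of pre-Pan loci additionally deleted in
#'   both chimpanzee and bonobo, planting the "human-specific yet
#'   OWM-conserved" regime (default 0.03).
#' @param reciprocal_fail_frac fraction of direct hits whose reciprocal
#'   mapping lands off-target, exercising the DIVERGED path (default
#'   0.005).
#' @param chain_intersect_prob probability that a never-inserted locus
#'   still intersects an alignment chain in a target genome (default
#'   0.15).
#' @param universe_size,os_fraction,synaptic_count,fetal_gonad_count gene
#'   universe parameters (defaults 18777, 2413/18777, 355, 88).
#' @param linked_response_prob,unlinked_response_prob perturbation
#'   response probabilities (defaults 0.53, 0.04).
#' @param n_chrom,chrom_size,locus_length synthetic genome geometry
#'   (5 chromosomes of 50 Mb; 450 bp loci).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, family = "LTR7", panel = default_panel(),
                       insertion_rate = NULL, origin_mya = 40,
                       birth_epochs = NULL,
                       identity_decay = 0.001, identity_sd = 0.005,
                       retention_loss_prob = 0.02, pan_loss_frac = 0.03,
                       reciprocal_fail_frac = 0.005,
                       chain_intersect_prob = 0.15,
                       universe_size = 18777L,
                       os_fraction = 2413 / 18777,
                       synaptic_count = 355L, fetal_gonad_count = 88L,
                       linked_response_prob = 0.53,
                       unlinked_response_prob = 0.04,
                       n_chrom = 5L, chrom_size = 5e7,
                       locus_length = 450L) {
  panel <- validate_panel(panel)
  if (!family %in% LTR_FAMILIES) stop("unknown family: ", family)
  if (!is.null(insertion_rate)) {
    if (insertion_rate <= 0) stop("insertion_rate must be positive")
    birth_epochs <- data.frame(older = origin_mya, younger = 0,
                               n_loci = as.integer(round(insertion_rate *
                                                           origin_mya)))
  } else if (is.null(birth_epochs)) {
    birth_epochs <- default_epochs(family)
  }
  stopifnot(all(birth_epochs$older > birth_epochs$younger),
            all(birth_epochs$n_loci >= 0L))
  probs <- c(retention_loss_prob, pan_loss_frac, reciprocal_fail_frac,
             chain_intersect_prob, os_fraction, linked_response_prob,
             unlinked_response_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  structure(list(
    seed = as.integer(seed), family = family, panel = panel,
    origin_mya = origin_mya, birth_epochs = birth_epochs,
    identity_decay = identity_decay, identity_sd = identity_sd,
    retention_loss_prob = retention_loss_prob,
    pan_loss_frac = pan_loss_frac,
    reciprocal_fail_frac = reciprocal_fail_frac,
    chain_intersect_prob = chain_intersect_prob,
    universe_size = as.integer(universe_size), os_fraction = os_fraction,
    synaptic_count = as.integer(synaptic_count),
    fetal_gonad_count = as.integer(fetal_gonad_count),
    linked_response_prob = linked_response_prob,
    unlinked_response_prob = unlinked_response_prob,
    n_chrom = as.integer(n_chrom), chrom_size = chrom_size,
    locus_length = as.integer(locus_length)
  ), class = "sim_config")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a lineage history of LTR insertions with ground truth
#'
#' Loci are born on the lineage to the reference genome inside the
#' configured epochs; a locus is present in species S iff it was born
#' before S's split and not lost on S's branch. Direct mapping records
#' carry identity `clamp(1 - identity_decay * divergence_mya + noise)`;
#' reciprocal records return to the exact human interval except for a
#' configurable fraction of reciprocity failures. A configured fraction
#' of pre-Pan loci is deleted in both chimpanzee and bonobo, so that the
#' human-specific classifier finds loci that are nevertheless highly
#' conserved in more distant species.
#'
#' @param config a [sim_config()].
#' @return list with `catalog` ([ltr_loci]), `truth` (list: `ages`,
#'   `present` locus x species logical matrix, `pan_deleted` ids),
#'   `direct` and `reciprocal` mapping tables, `panel`, `config`.
#' @export
simulate_locus_history <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ep <- config$birth_epochs
  n <- sum(ep$n_loci)
  if (n == 0L) stop("configuration produces zero loci")
  epoch_of <- rep(seq_len(nrow(ep)), times = ep$n_loci)
  ages <- runif(n, min = ep$younger[epoch_of], max = ep$older[epoch_of])

  if (config$family == "LTR7") {
    w <- ltr7_epoch_weights(nrow(ep))
    subfam <- character(n)
    for (e in seq_len(nrow(ep))) {
      idx <- epoch_of == e
      subfam[idx] <- sample(LTR7_SUBFAMILIES, sum(idx), replace = TRUE,
                            prob = w[[e]])
    }
  } else {
    subfam <- rep("LTR5_Hs", n)
  }

  chroms <- paste0("chr", seq_len(config$n_chrom))
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, config$chrom_size - config$locus_length))
  prefix <- if (config$family == "LTR7") "L7" else "L5"
  catalog <- ltr_loci(
    locus_id = sprintf("%s_%05d", prefix, seq_len(n)),
    family = config$family, subfamily = subfam,
    chrom = chrom, start = start, end = start + config$locus_length,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )

  panel <- config$panel
  species <- panel$species_id[!panel$is_reference]
  tms <- panel$divergence_mya[match(species, panel$species_id)]
  reference <- panel$species_id[panel$is_reference]

  pan_species <- intersect(c("chimpanzee", "bonobo"), species)
  pan_time <- if (length(pan_species) > 0L)
    max(tms[match(pan_species, species)]) else Inf
  pre_pan <- which(ages > pan_time)
  pan_deleted <- integer(0L)
  if (length(pre_pan) > 0L && config$pan_loss_frac > 0) {
    pan_deleted <- pre_pan[runif(length(pre_pan)) < config$pan_loss_frac]
  }

  present <- matrix(FALSE, nrow = n, ncol = length(species),
                    dimnames = list(catalog$locus_id, species))
  direct_list <- vector("list", length(species))
  recip_list <- vector("list", length(species))
  for (j in seq_along(species)) {
    sp <- species[j]
    born <- ages > tms[j]
    lost <- runif(n) < config$retention_loss_prob
    if (sp %in% pan_species) lost[pan_deleted] <- TRUE
    pres <- born & !lost
    present[, j] <- pres

    identity <- clamp01(1 - config$identity_decay * tms[j] +
                          rnorm(n, 0, config$identity_sd))
    n_hits <- ifelse(pres, 1L, 0L)
    # chain coverage: present loci and lost-but-born loci lie in alignable
    # regions; never-born loci intersect a chain only by chance
    chain <- pres | (born & lost) |
      (!born & runif(n) < config$chain_intersect_prob)
    direct_list[[j]] <- data.frame(
      locus_id = catalog$locus_id, query_species = reference,
      target_species = sp, n_hits = n_hits,
      chrom = ifelse(pres, catalog$chrom, NA_character_),
      start = ifelse(pres, catalog$start, NA_integer_),
      end = ifelse(pres, catalog$end, NA_integer_),
      identity = ifelse(pres, identity, NA_real_),
      intersects_chain = chain, stringsAsFactors = FALSE
    )

    hit <- which(pres)
    if (length(hit) > 0L) {
      fail <- runif(length(hit)) < config$reciprocal_fail_frac
      r_ident <- clamp01(1 - config$identity_decay * tms[j] +
                           rnorm(length(hit), 0, config$identity_sd))
      shift <- ifelse(fail, 10L * config$locus_length, 0L)
      recip_list[[j]] <- data.frame(
        locus_id = catalog$locus_id[hit], query_species = sp,
        target_species = reference, n_hits = 1L,
        chrom = catalog$chrom[hit],
        start = catalog$start[hit] + shift,
        end = catalog$end[hit] + shift,
        identity = r_ident, intersects_chain = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  direct <- validate_mappings(do.call(rbind, direct_list))
  reciprocal <- validate_mappings(do.call(rbind, recip_list))

  list(
    catalog = catalog,
    truth = list(ages = setNames(ages, catalog$locus_id),
                 present = present,
                 pan_deleted = catalog$locus_id[pan_deleted]),
    direct = direct, reciprocal = reciprocal,
    panel = panel, config = config
  )
}

#' Simulate a gene universe with category flags
#'
#' Places `universe_size` genes uniformly over the synthetic chromosomes;
#' flags OS membership with probability `os_fraction` per gene, and
#' assigns exactly `synaptic_count` SYNAPTIC and `fetal_gonad_count`
#' FETAL_GONAD_MARKER flags (independent of OS).
#'
#' @param config a [sim_config()].
#' @return an [ltr_genes] annotation.
#' @export
simulate_gene_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$universe_size
  chroms <- paste0("chr", seq_len(config$n_chrom))
  os <- runif(n) < config$os_fraction
  synaptic <- seq_len(n) %in% sample.int(n, min(config$synaptic_count, n))
  fetal <- seq_len(n) %in% sample.int(n, min(config$fetal_gonad_count, n))
  cats <- character(n)
  flags <- cbind(OS = os, SYNAPTIC = synaptic, FETAL_GONAD_MARKER = fetal)
  cats <- apply(flags, 1L, function(f) paste(colnames(flags)[f],
                                             collapse = ";"))
  ltr_genes(
    symbol = sprintf("GENE%05d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    tss = floor(runif(n, 0, config$chrom_size)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    categories = cats
  )
}

#' Simulate perturbation-response gene sets
#'
#' Draws a responder pool: each gene responds with
#' `linked_response_prob` if linked, else `unlinked_response_prob`. Every
#' responder is then observed in at least one of the named experiments
#' (membership in each additional experiment is a fair coin), so the union
#' of the returned sets equals the responder pool and the linked coverage
#' recovers the planted probability.
#'
#' @param linked character vector of linked gene symbols.
#' @param universe gene universe ([ltr_genes] or character symbols).
#' @param config a [sim_config()].
#' @param experiments names of the perturbation assays.
#' @return named list of response gene sets (character vectors).
#' @export
simulate_perturbation_response <- function(linked, universe, config,
                                           experiments = c("CRISPRi",
                                                           "SILENCING")) {
  stopifnot(inherits(config, "sim_config"), length(experiments) >= 1L)
  if (inherits(universe, "ltr_genes") || is.data.frame(universe)) {
    universe <- universe$symbol
  }
  set.seed(config$seed + 2L)
  is_linked <- universe %in% linked
  p <- ifelse(is_linked, config$linked_response_prob,
              config$unlinked_response_prob)
  responders <- universe[runif(length(universe)) < p]
  k <- length(experiments)
  out <- setNames(vector("list", k), experiments)
  if (length(responders) == 0L) {
    return(lapply(out, function(x) character(0L)))
  }
  primary <- sample.int(k, length(responders), replace = TRUE)
  member <- matrix(runif(length(responders) * k) < 0.5,
                   ncol = k)
  member[cbind(seq_along(responders), primary)] <- TRUE
  for (e in seq_len(k)) out[[e]] <- sort(responders[member[, e]])
  out
}
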