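#' Plant a synthetic mutation into one individual's pile
#'
#' Converts `y` reference-supporting reads of one individual into a
#' uniformly chosen different base, leaving depth and all other
#' individuals untouched.  If fewer than `y` reference reads are
#' available, the conversion is clamped to the available count (mirroring
#' read scarcity at low depth) and flagged.
#'
#' @param pile 4 x n-individuals base-count matrix ([site_pile()]).
#' @param individual column name or index of the carrier.
#' @param ref reference base at the site.
#' @param y number of reads to convert.
#' @param mut_base optional forced mutant base (default: uniform over the
#'   three non-reference bases).
#' @return list with `pile` (modified copy), `mut_base`, `y_used` and
#'   `clamped`.
#' @export
plant_mutation <- function(pile, individual, ref, y, mut_base = NULL) {
  stopifnot(is.matrix(pile), nrow(pile) == 4)
  rb <- base_to_code(ref)
  avail <- pile[rb, individual]
  clamped <- y > avail
  y_used <- as.integer(min(y, avail))
  mb <- if (is.null(mut_base)) other_base(rb) else base_to_code(mut_base)
  pile[rb, individual] <- pile[rb, individual] - y_used
  pile[mb, individual] <- pile[mb, individual] + y_used
  list(pile = pile, mut_base = code_to_base(mb), y_used = y_used,
       clamped = clamped)
}

#' Estimate callability and the false-negative rate by spike-in
#'
#' Repeats the synthetic-mutation experiment: sample a uniformly random
#' genomic site and focal offspring, draw the number of mutant reads y
#' from the empirical heterozygote distribution at that individual's
#' depth ([sample_alt_count()]), convert y reference reads to a random
#' mutant base, re-call the site and classify it with the six rules
#' applied to the parents, the bait offspring and the *other* focal
#' offspring only (the carrier is exempt, exactly as a real mutation
#' would present).  Each spike is planted into a fresh copy of the site's
#' counts, so spikes are independent.
#'
#' The fraction of spikes landing on callable sites estimates the
#' callable fraction of the genome; the fraction of callable spikes whose
#' carrier is called heterozygous for the planted base estimates the
#' call rate (1 - false-negative rate).
#'
#' Mapping bias needs no special treatment here: because reads carrying
#' any non-reference allele are dropped by the simulator at natural
#' heterozygous sites too, the empirical distributions that y is drawn
#' from already carry the bias, exactly as the observed distributions in
#' the original procedure did.
#'
#' @param piles a `pile_set`.
#' @param hetdist a [tabulate_het_depths()] result.
#' @param pedigree the pedigree.
#' @param n_spikes number of synthetic mutations (default 1000).
#' @param gconfig,fconfig caller and filter configurations.
#' @return object of class `spikein_result`: counts `n_total`,
#'   `n_callable`, `n_called`, the derived `callable_fraction` and
#'   `call_rate`, and the per-spike data frame `spikes`.
#' @export
spikein_evaluate <- function(piles, hetdist, pedigree, n_spikes = 1000L,
                             gconfig = genotyper_config(),
                             fconfig = filter_config()) {
  check(n_spikes >= 1, "n_spikes must be >= 1")
  idx <- role_indices(pedigree)
  focal_names <- pedigree$individuals[idx$focal]
  lens <- vapply(piles$chroms, function(ch) length(ch$ref), numeric(1))
  chrom_draw <- sample(names(piles$chroms), n_spikes, replace = TRUE,
                       prob = lens)
  pos_draw <- vapply(chrom_draw, function(cn)
    sample.int(lens[[cn]], 1L), integer(1))
  ind_draw <- sample(focal_names, n_spikes, replace = TRUE)
  lut <- genotype_lut(gconfig, lut_nmax(piles))

  depth_v <- integer(n_spikes); y_v <- integer(n_spikes)
  yused_v <- integer(n_spikes); clamp_v <- logical(n_spikes)
  base_v <- character(n_spikes)
  callable_v <- logical(n_spikes); called_v <- logical(n_spikes)
  for (j in seq_len(n_spikes)) {
    cn <- chrom_draw[j]; s <- pos_draw[j]; ind <- ind_draw[j]
    ch <- piles$chroms[[cn]]
    ref <- code_to_base(ch$ref[s])
    pile <- site_pile(piles, cn, s)
    d <- sum(pile[, ind])
    y <- if (d >= 1) sample_alt_count(hetdist, d, 1L) else 0L
    pl <- plant_mutation(pile, ind, ref, y)
    depth_v[j] <- d; y_v[j] <- y; yused_v[j] <- pl$y_used
    clamp_v[j] <- pl$clamped; base_v[j] <- pl$mut_base
    if (sum(pl$pile) == 0) next
    res <- eval_site_counts(pl$pile, ch$ref[s], lut, gconfig, fconfig,
                            idx, exempt = match(ind, piles$individuals))
    callable_v[j] <- res$callable
    called_v[j] <- res$callable && res$alt == base_to_code(pl$mut_base) &&
      res$geno[match(ind, piles$individuals)] == 2L
  }
  spikes <- data.frame(chrom = chrom_draw, pos = pos_draw,
                       individual = ind_draw, mut_base = base_v,
                       depth = depth_v, y = y_v, y_used = yused_v,
                       clamped = clamp_v, outcome_callable = callable_v,
                       outcome_called = called_v, stringsAsFactors = FALSE)
  n_callable <- sum(spikes$outcome_callable)
  n_called <- sum(spikes$outcome_called)
  structure(list(n_total = n_spikes, n_callable = n_callable,
                 n_called = n_called,
                 callable_fraction = n_callable / n_spikes,
                 call_rate = if (n_callable > 0) n_called / n_callable else NA_real_,
                 spikes = spikes),
            class = "spikein_result")
}

#' @export
print.spikein_result <- function(x, ...) {
  cat(sprintf(paste0("spike-in calibration: %d synthetic mutations, ",
                     "%d at callable sites (%.1f%%), %d called (%.1f%%)\n"),
              x$n_total, x$n_callable, 100 * x$callable_fraction,
              x$n_called, 100 * x$call_rate))
  invisible(x)
}

#' Estimate the number of callable sites in the genome
#'
#' The fraction of synthetic mutations landing on callable sites
#' estimates the callable fraction of the genome.
#'
#' @param result a [spikein_evaluate()] result (or anything with a
#'   `callable_fraction` element).
#' @param n_sites total number of sites in the genome.
#' @return estimated count of callable sites.
#' @export
callable_sites_estimate <- function(result, n_sites) {
  check(result$n_total >= 1, "spike-in result is empty")
  result$callable_fraction * n_sites
}

#' Outcomes of the truly planted mutations
#'
#' Direct measurement of callability and recall on the simulator's ground
#' truth: for every planted focal-offspring mutation, classifies its site
#' with the carrier exempt (was the mutation detectable?) and checks
#' whether the carrier is called heterozygous for the planted base (was
#' it detected?).  Used to validate the spike-in estimates.
#'
#' @param sim a [generate()] result.
#' @param gconfig,fconfig caller and filter configurations.
#' @return data frame with one row per planted focal mutation and logical
#'   columns `callable` and `called`.
#' @export
planted_mutation_outcomes <- function(sim, gconfig = genotyper_config(),
                                      fconfig = filter_config()) {
  stopifnot(inherits(sim, "pedsim"))
  ped <- sim$pedigree
  focal_names <- names(ped$roles)[ped$roles == "focal"]
  pm <- sim$truth$planted_mutations
  pm <- pm[pm$individual %in% focal_names, , drop = FALSE]
  if (!nrow(pm)) {
    pm$callable <- logical(0); pm$called <- logical(0)
    return(pm)
  }
  callable <- logical(nrow(pm)); called <- logical(nrow(pm))
  for (j in seq_len(nrow(pm))) {
    cn <- pm$chrom[j]; s <- pm$pos[j]; ind <- pm$individual[j]
    ch <- sim$piles$chroms[[cn]]
    pile <- site_pile(sim$piles, cn, s)
    if (sum(pile) == 0) next
    call <- call_site(pile, code_to_base(ch$ref[s]), gconfig,
                      chrom = cn, pos = s)
    cls <- classify_site(call, fconfig, ped, exempt = ind)
    callable[j] <- cls$callable
    called[j] <- callable[j] && !is.na(call$alt) && call$alt == pm$mut[j] &&
      call$geno[ind] == 2L
  }
  pm$callable <- callable
  pm$called <- called
  pm
}
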