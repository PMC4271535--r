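#' Six-rule candidate filter configuration
#'
#' @param min_parent_depth minimum read depth required in each parent
#'   (default 10).
#' @param max_het_focal maximum number of focal offspring that may be
#'   called heterozygous at a callable site (default 2; two carriers are
#'   interpreted as a premeiotic cluster).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_parent_depth = 10L, max_het_focal = 2L) {
  check(min_parent_depth >= 1, "min_parent_depth must be >= 1")
  check(max_het_focal >= 1, "max_het_focal must be >= 1")
  structure(list(min_parent_depth = as.integer(min_parent_depth),
                 max_het_focal = as.integer(max_het_focal)),
            class = "filter_config")
}

#' Classify one site as callable / uncallable under the six rules
#'
#' The rules, applied to a multi-sample genotype call:
#' 1. not flagged LowQual;
#' 2. both parents have depth at least `min_parent_depth`, are called
#'    homozygous reference, and carry no alternate-allele reads;
#' 3. no bait offspring carries an alternate-allele read;
#' 4. the genotypes of all focal offspring are defined;
#' 5. at most `max_het_focal` focal offspring are called heterozygous;
#' 6. no focal offspring outside the heterozygous set carries an
#'    alternate-allele read.
#'
#' "Carries an alternate-allele read" means an allele depth of at least 1
#' for the site's alternate base, regardless of the called genotype.
#' Sites flagged multiallelic by the caller are excluded outright (recorded
#' separately from the rules).  There is no depth filter on offspring.
#'
#' When `exempt` names a focal individual (used by the spike-in
#' calibration), rules 4-6 are evaluated over the remaining focal offspring
#' only and the rule-5 threshold is reduced by one, so that the exempted
#' carrier neither blocks nor is blocked by its own mutation.
#'
#' @param call a [call_site()] result covering all pedigree members.
#' @param config a [filter_config()].
#' @param pedigree the pedigree.
#' @param exempt optional name of one focal individual to exempt.
#' @return object of class `site_classification`: `callable`,
#'   `failed_rules` (integer subset of 1:6), `multiallelic`, and
#'   `candidate_individuals` (focal offspring called het, when callable).
#' @export
classify_site <- function(call, config = filter_config(), pedigree,
                          exempt = NULL) {
  stopifnot(inherits(call, "site_call"))
  check(identical(names(call$geno), pedigree$individuals),
        "call and pedigree cover different individuals")
  roles <- pedigree$roles
  if (!is.null(exempt))
    check(exempt %in% names(roles)[roles == "focal"],
          "exempt must name a focal offspring")

  geno <- call$geno
  k <- call$ad["alt", ]
  dp <- call$dp
  mother <- names(roles)[roles == "mother"]
  father <- names(roles)[roles == "father"]
  focal <- setdiff(names(roles)[roles == "focal"], exempt)
  bait <- names(roles)[roles == "bait"]
  max_het <- config$max_het_focal - if (is.null(exempt)) 0L else 1L

  failed <- integer(0)
  if (call$lowqual) failed <- c(failed, 1L)
  par <- c(mother, father)
  if (any(dp[par] < config$min_parent_depth) || any(geno[par] != 1L) ||
      any(k[par] > 0)) failed <- c(failed, 2L)
  if (any(k[bait] > 0)) failed <- c(failed, 3L)
  if (any(geno[focal] == 0L)) failed <- c(failed, 4L)
  het <- focal[geno[focal] == 2L]
  if (length(het) > max_het) failed <- c(failed, 5L)
  rest <- setdiff(focal, het)
  if (any(k[rest] > 0)) failed <- c(failed, 6L)

  callable <- length(failed) == 0L && !call$multiallelic
  structure(list(callable = callable, failed_rules = failed,
                 multiallelic = call$multiallelic,
                 candidate_individuals = if (callable) het else character(0)),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  if (x$callable) {
    cat("callable site")
    if (length(x$candidate_individuals))
      cat("; candidate de novo heterozygote in:",
          paste(x$candidate_individuals, collapse = ", "))
    cat("\n")
  } else {
    cat("uncallable site; failed rules:",
        paste(x$failed_rules, collapse = ","),
        if (x$multiallelic) "(multiallelic)" else "", "\n")
  }
  invisible(x)
}

decode_mask <- function(mask) {
  rules <- which(bitwAnd(mask, 2L^(0:5)) > 0)
  list(failed_rules = rules, multiallelic = bitwAnd(mask, 64L) > 0)
}

#' Scan a simulated genome for de novo candidate mutations
#'
#' Applies the caller and the six-rule filter to every site, counting
#' callable sites exhaustively and collecting candidate mutations
#' (heterozygous focal offspring at callable sites).  Candidates sharing a
#' site are flagged as a (premeiotic) cluster and counted as separate
#' mutation events.
#'
#' @param piles a `pile_set`.
#' @param gconfig,fconfig caller and filter configurations.
#' @param pedigree the pedigree.
#' @param scan optionally, a precomputed [genotype_scan()] to reuse.
#' @return list of class `mutation_scan`: `candidates` (data frame with
#'   chrom, pos, individual, wild-type and mutant base, mutant/wild-type
#'   read counts, parent depths, offspring depth, cluster flag),
#'   `n_callable_sites`, `n_sites`, and the per-chromosome sweep results
#'   (`scan`).
#' @export
scan_mutations <- function(piles, gconfig = genotyper_config(),
                           fconfig = filter_config(), pedigree,
                           scan = NULL) {
  if (is.null(scan))
    scan <- genotype_scan(piles, gconfig, fconfig, pedigree)
  stopifnot(inherits(scan, "genome_scan"))
  n_tot <- 0; n_call <- 0
  cand <- list()
  for (cn in names(piles$chroms)) {
    sw <- scan$chroms[[cn]]
    n_tot <- n_tot + length(sw$mask)
    n_call <- n_call + sum(sw$mask == 0L)
    if (length(sw$cand_site)) {
      sites <- sw$cand_site
      inds <- piles$individuals[sw$cand_ind]
      rows <- lapply(seq_along(sites), function(j) {
        s <- sites[j]
        pile <- site_pile(piles, cn, s)
        rb <- piles$chroms[[cn]]$ref[s]
        ab <- sw$alt[s]
        mrow <- role_indices(pedigree)
        data.frame(chrom = cn, pos = s, individual = inds[j],
                   wt = code_to_base(rb), mut = code_to_base(ab),
                   mut_reads = pile[ab, inds[j]],
                   wt_reads = pile[rb, inds[j]],
                   depth_mother = sum(pile[, mrow$mother]),
                   depth_father = sum(pile[, mrow$father]),
                   depth_offspring = sum(pile[, inds[j]]),
                   stringsAsFactors = FALSE)
      })
      cand[[cn]] <- do.call(rbind, rows)
    }
  }
  candidates <- bind_or_empty(cand,
    c("chrom", "pos", "individual", "wt", "mut", "mut_reads", "wt_reads",
      "depth_mother", "depth_father", "depth_offspring"))
  if (nrow(candidates)) {
    key <- paste(candidates$chrom, candidates$pos)
    candidates$cluster <- key %in% key[duplicated(key)]
  } else candidates$cluster <- logical(0)
  structure(list(candidates = candidates, n_callable_sites = n_call,
                 n_sites = n_tot, scan = scan),
            class = "mutation_scan")
}

#' @export
print.mutation_scan <- function(x, ...) {
  cat(sprintf("mutation scan: %d sites, %d callable (%.1f%%), %d candidates\n",
              x$n_sites, x$n_callable_sites,
              100 * x$n_callable_sites / max(x$n_sites, 1),
              nrow(x$candidates)))
  invisible(x)
}

#' Number of callable site-individuals
#'
#' The denominator of the mutation rate counts one unit per callable site
#' per focal offspring (each unit contributing two base copies).
#'
#' @param n_callable_sites callable sites in the genome.
#' @param n_focal number of focal offspring.
#' @return `n_callable_sites * n_focal`.
#' @export
site_individuals <- function(n_callable_sites, n_focal) {
  check(n_callable_sites >= 0 && n_focal >= 0, "counts must be non-negative")
  n_callable_sites * n_focal
}

#' Exhaustive mutation-conditional callability of every site
#'
#' The callable fraction that matters for the rate denominator is the
#' probability that a de novo mutation occurring at a random site in a
#' random focal offspring would have passed the filters.  Because a real
#' (or planted) mutation supplies the reads that define the site's
#' alternate allele, this differs from classifying sites as they stand:
#' a lone sequencing-error read elsewhere in the family defines an
#' error-base alternate that blocks the unmutated site, yet would not
#' block a mutation of a different base at the same position.
#'
#' This function enumerates, for every site, the 3 possible mutant bases
#' times the focal carriers and applies the six rules (carrier exempt)
#' deterministically, giving the exact quantity that the spike-in
#' procedure estimates by Monte Carlo.
#'
#' @param piles a `pile_set`.
#' @param gconfig,fconfig caller and filter configurations.
#' @param pedigree the pedigree.
#' @return list with `per_chrom` (per-site callable probabilities),
#'   `mean` (genome-wide callable fraction) and `n_sites`.
#' @export
callable_probability <- function(piles, gconfig = genotyper_config(),
                                 fconfig = filter_config(), pedigree) {
  idx <- role_indices(pedigree)
  nmax <- lut_nmax(piles)
  lut <- genotype_lut(gconfig, nmax)
  per <- lapply(piles$chroms, function(ch)
    callable_prob_sweep(ch$depth, ch$nonref, ch$ref, lut$geno,
                        idx$mother, idx$father, idx$focal, idx$bait,
                        fconfig$min_parent_depth, fconfig$max_het_focal))
  tot <- sum(vapply(per, length, numeric(1)))
  list(per_chrom = per,
       mean = sum(vapply(per, sum, numeric(1))) / tot,
       n_sites = tot)
}
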