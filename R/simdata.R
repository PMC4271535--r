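#' Simulation configuration for a pedigree sequencing experiment
#'
#' Defines the family structure, sequencing depths and noise processes of a
#' simulated two-parent cross with deeply sequenced focal offspring and
#' shallowly sequenced bait offspring.  The defaults emulate the butterfly
#' cross this package is modelled on: 21 chromosomes inherited whole from
#' the mother (no recombination in female Lepidoptera), 13 focal offspring
#' at mean depth 26.3x, 17 bait offspring at 12.7x, and parents at 33x,
#' on a genome down-scaled to 200 kb per chromosome.
#'
#' @param n_chromosomes number of chromosomes (default 21).
#' @param chrom_length sites per chromosome (default 2e5; a down-scaled
#'   stand-in for the ~12.9 Mb of a real chromosome).
#' @param n_focal number of deeply sequenced focal offspring (default 13).
#' @param n_bait number of shallowly sequenced bait offspring (default 17).
#' @param depth_mean_focal,depth_mean_bait,depth_mean_parent mean sequencing
#'   depth per role; per-site depths are Poisson with these means.
#' @param maternal_het_density per-bp probability that the mother is
#'   heterozygous (and the father homozygous reference) at a site.
#' @param mu_true de novo mutation probability per site per gamete.  The
#'   default (5e-7) is scaled up in proportion to the down-scaled genome so
#'   that a simulated family carries a realistic number of mutations.
#' @param error_rate per-base sequencing error probability; an erroneous
#'   read shows a uniformly chosen different base.
#' @param paralog_fraction fraction of each chromosome covered by a region
#'   receiving mismapped reads from an unassembled paralogous locus.
#' @param paralog_alt_rate per-read probability, inside a paralog region,
#'   that the read is replaced by the region's fixed alternate base.  This
#'   affects every individual equally.
#' @param mapping_bias probability that a read carrying a non-reference
#'   allele (an inherited SNP alternate or a de novo mutant) fails to map
#'   and is dropped; non-reference-bearing reads map less often than
#'   reference-bearing reads, which skews heterozygote allele depths below
#'   50% and is the main source of false negatives.
#' @param seed integer seed; the full experiment is reproducible from the
#'   configuration alone.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 21L,
                       chrom_length = 2e5,
                       n_focal = 13L,
                       n_bait = 17L,
                       depth_mean_focal = 26.3,
                       depth_mean_bait = 12.7,
                       depth_mean_parent = 33,
                       maternal_het_density = 0.02,
                       mu_true = 5e-7,
                       error_rate = 1e-3,
                       paralog_fraction = 0.05,
                       paralog_alt_rate = 0.1,
                       mapping_bias = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_focal = as.integer(n_focal),
    n_bait = as.integer(n_bait),
    depth_mean_focal = depth_mean_focal,
    depth_mean_bait = depth_mean_bait,
    depth_mean_parent = depth_mean_parent,
    maternal_het_density = maternal_het_density,
    mu_true = mu_true,
    error_rate = error_rate,
    paralog_fraction = paralog_fraction,
    paralog_alt_rate = paralog_alt_rate,
    mapping_bias = mapping_bias,
    seed = as.integer(seed)
  )
  probs <- c("maternal_het_density", "mu_true", "error_rate",
             "paralog_fraction", "paralog_alt_rate", "mapping_bias")
  for (p in probs)
    check(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  check(cfg$n_chromosomes >= 1 && cfg$chrom_length >= 1, "counts must be positive")
  check(cfg$n_focal >= 1 && cfg$n_bait >= 0, "offspring counts must be positive")
  check(all(c(cfg$depth_mean_focal, cfg$depth_mean_bait,
              cfg$depth_mean_parent) > 0), "depth means must be > 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Pedigree sequencing simulation configuration\n")
  cat(sprintf("  genome: %d chromosomes x %d bp\n", x$n_chromosomes, x$chrom_length))
  cat(sprintf("  family: 2 parents (%.1fx), %d focal (%.1fx), %d bait (%.1fx)\n",
              x$depth_mean_parent, x$n_focal, x$depth_mean_focal,
              x$n_bait, x$depth_mean_bait))
  cat(sprintf("  mu_true = %g /site/gamete, error = %g, mapping bias = %g\n",
              x$mu_true, x$error_rate, x$mapping_bias))
  cat(sprintf("  maternal het density = %g; paralog fraction %g (alt rate %g)\n",
              x$maternal_het_density, x$paralog_fraction, x$paralog_alt_rate))
  invisible(x)
}

## Individuals are always ordered mother, father, focal offspring, bait
## offspring; many internals rely on this ordering.
pedigree_names <- function(n_focal, n_bait) {
  c("mother", "father",
    sprintf("F%02d", seq_len(n_focal)),
    if (n_bait > 0) sprintf("B%02d", seq_len(n_bait)))
}

#' Construct a pedigree with whole-chromosome inheritance labels
#'
#' Offspring of a female without meiotic recombination receive one of the
#' mother's two homologs intact for every chromosome; the label matrix
#' records which.  Paternal chromosomes are labelled the same way (male
#' recombination exists in the real organism but affects none of the
#' statistics computed here, so paternal transmission is whole-chromosome
#' by default as well).
#'
#' @param n_focal,n_bait offspring counts.
#' @param n_chromosomes number of chromosomes.
#' @return object of class `pedigree` with elements `individuals`, `roles`
#'   (named vector with values mother/father/focal/bait), and two
#'   offspring-by-chromosome label matrices `maternal_inh`, `paternal_inh`
#'   with entries 1 or 2.
#' @export
random_pedigree <- function(n_focal = 13L, n_bait = 17L, n_chromosomes = 21L) {
  inds <- pedigree_names(n_focal, n_bait)
  roles <- setNames(c("mother", "father", rep("focal", n_focal),
                      rep("bait", n_bait)), inds)
  off <- inds[-(1:2)]
  draw <- function() matrix(sample(c(1L, 2L), length(off) * n_chromosomes,
                                   replace = TRUE),
                            nrow = length(off), ncol = n_chromosomes,
                            dimnames = list(off, paste0("chr", seq_len(n_chromosomes))))
  structure(list(individuals = inds, roles = roles,
                 maternal_inh = draw(), paternal_inh = draw()),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: 2 parents, %d focal + %d bait offspring, %d chromosomes\n",
              sum(x$roles == "focal"), sum(x$roles == "bait"),
              ncol(x$maternal_inh)))
  invisible(x)
}

role_indices <- function(ped) {
  list(mother = which(ped$roles == "mother"),
       father = which(ped$roles == "father"),
       focal  = which(ped$roles == "focal"),
       bait   = which(ped$roles == "bait"))
}

#' Maternal segregation pattern of a chromosome
#'
#' Because offspring inherit whole chromosomes from the mother, every
#' heterozygous maternal SNP on one chromosome segregates identically; the
#' pattern is simply the vector of maternal homolog labels across the
#' offspring.
#'
#' @param pedigree a [random_pedigree()] object.
#' @param chromosome chromosome name (e.g. `"chr3"`) or index.
#' @return integer vector of labels (1 or 2) named by offspring.
#' @export
segregation_pattern <- function(pedigree, chromosome) {
  m <- pedigree$maternal_inh
  if (is.numeric(chromosome)) {
    check(chromosome >= 1 && chromosome <= ncol(m), "unknown chromosome")
    return(m[, chromosome])
  }
  check(chromosome %in% colnames(m), paste("unknown chromosome:", chromosome))
  m[, chromosome]
}

#' Simulate a complete pedigree sequencing experiment
#'
#' Generates per-site, per-individual read base counts ("piles") for the
#' whole family, together with the ground truth needed to validate the
#' analysis: planted de novo mutations, maternal SNPs, chromosome
#' segregation patterns and paralog-contaminated regions.
#'
#' Reads are represented as base counts rather than sequences: per site and
#' individual, depth is Poisson with the role-specific mean, each read
#' copies one of the individual's two alleles and is mis-read as a
#' uniformly chosen different base with probability `error_rate`.  Inside a
#' paralog region each read is replaced by the region's fixed alternate
#' base with probability `paralog_alt_rate` in every individual.  Reads
#' carrying a non-reference allele are dropped (fail to map) with
#' probability `mapping_bias`, which reduces the realized depth.
#'
#' @param config a [sim_config()] object.
#' @return list of class `pedsim` with elements
#'   `piles` (class `pile_set`), `pedigree` and `truth`.  `truth` contains
#'   `planted_mutations`, `maternal_snps`, `paralog_regions` and
#'   `segregation_patterns` (the maternal label matrix).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nfo <- config$n_focal; nba <- config$n_bait
  M <- 2L + nfo + nba
  L <- config$chrom_length
  ped <- random_pedigree(nfo, nba, config$n_chromosomes)
  lambda <- c(config$depth_mean_parent, config$depth_mean_parent,
              rep(config$depth_mean_focal, nfo), rep(config$depth_mean_bait, nba))

  exp_mut <- config$chrom_length * config$n_chromosomes * config$mu_true *
    2 * (nfo + nba)
  if (exp_mut < 1)
    warning(sprintf(paste("expected number of planted mutations is %.3g (< 1);",
                          "the simulated experiment is likely uninformative"),
                    exp_mut))

  chroms <- vector("list", config$n_chromosomes)
  names(chroms) <- paste0("chr", seq_len(config$n_chromosomes))
  mut_list <- list(); snp_list <- list(); par_list <- list()

  for (ci in seq_len(config$n_chromosomes)) {
    ref <- sample.int(4L, L, replace = TRUE)

    ## one contiguous paralog-contaminated region per chromosome
    plen <- round(config$paralog_fraction * L)
    if (plen > 0) {
      pstart <- sample.int(L - plen + 1L, 1L)
      pend <- pstart + plen - 1L
      pbase <- sample.int(4L, 1L)
    } else {
      pstart <- 0L; pend <- -1L; pbase <- 1L
    }

    ## maternal SNPs: mother heterozygous ref/alt, father homozygous ref;
    ## the alternate allele rides on one of the mother's two homologs
    nsnp <- rbinom(1L, L, config$maternal_het_density)
    spos <- sort(sample.int(L, nsnp))
    salt <- other_base(ref[spos])
    shom <- sample(c(1L, 2L), nsnp, replace = TRUE)

    ## de novo mutations: Bernoulli(mu_true) per site per gamete for every
    ## offspring, realized as a binomial count over 2L trials
    off_idx <- seq.int(3L, M)
    mrows <- list()
    for (o in off_idx) {
      nm <- rbinom(1L, 2L * L, config$mu_true)
      if (nm == 0) next
      mpos <- unique(sample.int(L, nm, replace = TRUE))
      hap <- sample(c(1L, 2L), length(mpos), replace = TRUE)  # 1 maternal, 2 paternal
      mrows[[length(mrows) + 1L]] <-
        data.frame(pos = mpos, ind = o, hap = hap)
    }
    muts <- if (length(mrows)) do.call(rbind, mrows) else
      data.frame(pos = integer(), ind = integer(), hap = integer())

    ## special (non hom-ref) true genotypes as sparse entries for the
    ## count engine: alleles a1 (maternal haplotype), a2 (paternal)
    if (nsnp > 0) {
      inh <- ped$maternal_inh[, ci]                    # offspring labels
      hit <- which(outer(shom, inh, "=="), arr.ind = TRUE)  # SNP j x offspring o
      sp <- data.frame(
        pos = c(spos, spos[hit[, 1L]]),
        ind = c(rep(1L, nsnp), hit[, 2L] + 2L),
        a1  = c(salt, salt[hit[, 1L]]),
        a2  = c(ref[spos], ref[spos[hit[, 1L]]]),
        mut = 0L)
    } else {
      sp <- data.frame(pos = integer(), ind = integer(), a1 = integer(),
                       a2 = integer(), mut = integer())
    }
    ## overlay mutations (possibly on top of an inherited SNP allele)
    if (nrow(muts)) {
      muts$wt <- NA_integer_; muts$mut <- NA_integer_
      key <- function(p, i) as.numeric(p) * (M + 1) + i
      spkey <- key(sp$pos, sp$ind)
      for (j in seq_len(nrow(muts))) {
        p <- muts$pos[j]; o <- muts$ind[j]; h <- muts$hap[j]
        hitrow <- match(key(p, o), spkey)
        if (is.na(hitrow)) {
          sp <- rbind(sp, data.frame(pos = p, ind = o, a1 = ref[p],
                                     a2 = ref[p], mut = 0L))
          spkey <- c(spkey, key(p, o))
          hitrow <- nrow(sp)
        }
        a <- c(sp$a1[hitrow], sp$a2[hitrow])
        wt <- a[h]
        mb <- other_base(wt)
        a[h] <- mb
        sp$a1[hitrow] <- a[1]; sp$a2[hitrow] <- a[2]
        sp$mut[hitrow] <- bitwOr(sp$mut[hitrow], h)
        muts$wt[j] <- wt; muts$mut[j] <- mb
      }
    }
    ## mapping bias applies to any read carrying a non-reference allele
    ## (inherited SNP alternates and de novo mutants alike); the bit mask
    ## marks which of the two alleles are subject to it
    if (nrow(sp))
      sp$mut <- (sp$a1 != ref[sp$pos]) + 2L * (sp$a2 != ref[sp$pos])
    sp <- sp[order(sp$pos, sp$ind), , drop = FALSE]

    sim <- sim_chrom_counts(L, M, lambda, ref,
                            config$error_rate, config$mapping_bias,
                            pstart, pend, pbase, config$paralog_alt_rate,
                            as.integer(sp$pos), as.integer(sp$ind),
                            as.integer(sp$a1), as.integer(sp$a2),
                            as.integer(sp$mut))
    colnames(sim$depth) <- ped$individuals
    ## cumulative row counts per site for O(1) pile extraction
    cum <- c(0L, cumsum(tabulate(sim$nonref[, 1L], nbins = L)))
    chroms[[ci]] <- list(depth = sim$depth, nonref = sim$nonref, ref = ref,
                         cum = cum)

    if (nrow(muts))
      mut_list[[ci]] <- data.frame(
        chrom = names(chroms)[ci], pos = muts$pos,
        individual = ped$individuals[muts$ind],
        wt = code_to_base(muts$wt), mut = code_to_base(muts$mut),
        haplotype = c("maternal", "paternal")[muts$hap],
        stringsAsFactors = FALSE)
    if (nsnp > 0)
      snp_list[[ci]] <- data.frame(
        chrom = names(chroms)[ci], pos = spos,
        ref = code_to_base(ref[spos]), alt = code_to_base(salt),
        alt_homolog = shom, father_gt = "hom-ref", stringsAsFactors = FALSE)
    if (plen > 0)
      par_list[[ci]] <- data.frame(
        chrom = names(chroms)[ci], start = pstart, end = pend,
        base = code_to_base(pbase), stringsAsFactors = FALSE)
  }

  piles <- structure(list(chroms = chroms, individuals = ped$individuals,
                          roles = ped$roles, lambda = lambda, config = config),
                     class = "pile_set")
  truth <- list(
    planted_mutations = bind_or_empty(mut_list,
      c("chrom", "pos", "individual", "wt", "mut", "haplotype")),
    maternal_snps = bind_or_empty(snp_list,
      c("chrom", "pos", "ref", "alt", "alt_homolog", "father_gt")),
    paralog_regions = bind_or_empty(par_list, c("chrom", "start", "end", "base")),
    segregation_patterns = ped$maternal_inh)
  structure(list(piles = piles, pedigree = ped, truth = truth),
            class = "pedsim")
}

## uniformly chosen base different from each element of `code`
other_base <- function(code) {
  off <- sample.int(3L, length(code), replace = TRUE)
  ((code - 1L + off) %% 4L) + 1L
}

bind_or_empty <- function(lst, cols) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst)) return(do.call(rbind, c(lst, make.row.names = FALSE)))
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  df
}

#' @export
print.pedsim <- function(x, ...) {
  cfg <- x$piles$config
  cat(sprintf("Simulated pedigree experiment: %d x %d bp, %d individuals\n",
              cfg$n_chromosomes, cfg$chrom_length, length(x$piles$individuals)))
  cat(sprintf("  planted mutations: %d (focal: %d), maternal SNPs: %d\n",
              nrow(x$truth$planted_mutations),
              sum(x$truth$planted_mutations$individual %in%
                    names(x$pedigree$roles)[x$pedigree$roles == "focal"]),
              nrow(x$truth$maternal_snps)))
  invisible(x)
}

#' Total number of simulated sites in a pile set
#' @param piles a `pile_set`.
#' @export
n_sites <- function(piles) {
  sum(vapply(piles$chroms, function(ch) length(ch$ref), numeric(1)))
}

## rows of the sparse non-reference count table covering one site
nonref_range <- function(ch, pos) {
  if (is.null(ch$cum)) {
    idx <- findInterval(c(pos - 1L, pos), ch$nonref[, 1L])
  } else {
    idx <- ch$cum[c(pos, pos + 1L)]
  }
  if (idx[1] == idx[2]) return(integer(0))
  seq.int(idx[1] + 1L, idx[2])
}

#' Extract the read-count pile of a single site
#'
#' @param piles a `pile_set` from [generate()].
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @return integer matrix with 4 rows (bases A, C, G, T) and one column per
#'   individual; columns sum to the sequencing depth at the site.
#' @export
site_pile <- function(piles, chrom, pos) {
  ch <- piles$chroms[[chrom]]
  check(!is.null(ch), paste("unknown chromosome:", chrom))
  check(pos >= 1 && pos <= length(ch$ref), "position out of range")
  M <- length(piles$individuals)
  cnt <- matrix(0L, 4L, M, dimnames = list(BASES, piles$individuals))
  rows <- nonref_range(ch, pos)
  if (length(rows)) {
    nr <- ch$nonref[rows, , drop = FALSE]
    cnt[cbind(nr[, 3L], nr[, 2L])] <- nr[, 4L]
  }
  rb <- ch$ref[pos]
  cnt[rb, ] <- ch$depth[pos, ] - colSums(cnt)
  cnt
}

#' Write the planted-mutation truth table as TSV
#' @param truth the `truth` element of a [generate()] result.
#' @param path output file.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth$planted_mutations, path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
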