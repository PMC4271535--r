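#' Genotype caller configuration
#'
#' Parameters of the multi-sample biallelic genotype caller that stands in
#' for a GATK-style pipeline on read-count piles.  Genotype likelihoods are
#' binomial in the alternate-read count: P(alt read) is `error_rate` under
#' hom-ref, 0.5 under het and `1 - error_rate` under hom-alt.  The prior is
#' the standard diploid variant prior with heterozygosity parameter
#' `heterozygosity`: P(het) = theta, P(hom-alt) = theta / 2,
#' P(hom-ref) = 1 - 3 theta / 2.
#'
#' @param error_rate per-read error probability used by the likelihood
#'   (need not equal the error rate that generated the data).
#' @param heterozygosity prior probability theta that a site is variant
#'   (default 0.01, the conventional caller setting).
#' @param lowqual_threshold phred-scaled site quality below which a site
#'   with a non-reference genotype call is flagged LowQual (default 30).
#' @return object of class `genotyper_config`.
#' @export
genotyper_config <- function(error_rate = 0.01, heterozygosity = 0.01,
                             lowqual_threshold = 30) {
  check(error_rate > 0 && error_rate < 0.5, "error_rate must be in (0, 0.5)")
  check(heterozygosity > 0 && heterozygosity < 1 / 3,
        "heterozygosity must be in (0, 1/3)")
  structure(list(error_rate = error_rate, heterozygosity = heterozygosity,
                 lowqual_threshold = lowqual_threshold),
            class = "genotyper_config")
}

#' Biallelic genotype likelihoods from allele depths
#'
#' @param ref_count,alt_count reads supporting the reference and alternate
#'   allele (reads showing a third base are not counted).
#' @param error_rate per-read error probability.
#' @return named numeric vector of the three likelihoods
#'   (`hom_ref`, `het`, `hom_alt`).
#' @export
genotype_likelihoods <- function(ref_count, alt_count, error_rate) {
  check(ref_count >= 0 && alt_count >= 0, "counts must be non-negative")
  n <- ref_count + alt_count
  c(hom_ref = dbinom(alt_count, n, error_rate),
    het     = dbinom(alt_count, n, 0.5),
    hom_alt = dbinom(alt_count, n, 1 - error_rate))
}

genotype_log_priors <- function(theta) {
  c(hom_ref = log1p(-1.5 * theta), het = log(theta), hom_alt = log(theta / 2))
}

## Genotype codes used everywhere: 0 undefined, 1 hom-ref, 2 het, 3 hom-alt
GENO_LEVELS <- c("undefined", "hom-ref", "het", "hom-alt")

geno_label <- function(code) GENO_LEVELS[code + 1L]

## Posterior over the three genotypes for one (n, k); ties go to hom-ref.
## Returns list(geno = code, post_hom_ref = probability).
map_genotype <- function(n, k, cfg) {
  lp <- genotype_log_priors(cfg$heterozygosity)
  ll <- c(dbinom(k, n, cfg$error_rate, log = TRUE),
          dbinom(k, n, 0.5, log = TRUE),
          dbinom(k, n, 1 - cfg$error_rate, log = TRUE)) + lp
  post <- exp(ll - max(ll)); post <- post / sum(post)
  g <- 1L
  if (post[2] > post[g]) g <- 2L
  if (post[3] > post[g]) g <- 3L
  list(geno = g, post_hom_ref = post[1])
}

## Lookup tables over (n, k) for the vectorized engine: MAP genotype code
## and the phred-scaled -10 log10 posterior probability of hom-ref.
## Row/column i corresponds to n = i - 1 / k = i - 1.
genotype_lut <- function(cfg, nmax) {
  n <- matrix(0:nmax, nmax + 1L, nmax + 1L)
  k <- matrix(0:nmax, nmax + 1L, nmax + 1L, byrow = TRUE)
  lp <- genotype_log_priors(cfg$heterozygosity)
  lhr <- dbinom(k, n, cfg$error_rate, log = TRUE) + lp[1]
  lhe <- dbinom(k, n, 0.5, log = TRUE) + lp[2]
  lha <- dbinom(k, n, 1 - cfg$error_rate, log = TRUE) + lp[3]
  geno <- matrix(1L, nmax + 1L, nmax + 1L)
  geno[lhe > lhr] <- 2L
  geno[lha > pmax(lhr, lhe)] <- 3L
  mx <- pmax(lhr, lhe, lha)
  lsum <- mx + log(exp(lhr - mx) + exp(lhe - mx) + exp(lha - mx))
  qhr <- -10 * (lhr - lsum) / log(10)
  bad <- k > n          # impossible cells, never indexed
  geno[bad] <- 1L; qhr[bad] <- 0
  list(geno = geno, qhr = qhr)
}

#' Call genotypes at a single site across all individuals
#'
#' Reference R implementation of the caller used by the per-site API and
#' by the spike-in evaluator; the genome-wide scan uses an equivalent
#' compiled sweep.  The alternate allele is the most frequent non-reference
#' base over all individuals (ties to the alphabetically first base);
#' genotypes are maximum-a-posteriori with ties broken toward hom-ref, and
#' individuals with zero depth are undefined.  Site quality is
#' -10 log10 P(no individual carries a non-reference allele | data), and
#' the LowQual flag is set when quality is below the threshold and some
#' non-reference genotype was called.  Sites where two distinct
#' non-reference bases each have at least two reads in a single individual
#' are flagged multiallelic and excluded downstream.
#'
#' @param pile 4 x n-individuals integer matrix of base counts (rows A, C,
#'   G, T), e.g. from [site_pile()].
#' @param ref reference base ("A", "C", "G" or "T").
#' @param config a [genotyper_config()].
#' @param chrom,pos optional coordinates carried through to the result.
#' @return object of class `site_call` with elements `chrom`, `pos`, `ref`,
#'   `alt` (NA if the site is invariant), `geno` (integer codes, see
#'   [geno_label()]), `ad` (2 x n matrix of ref/alt depths), `dp`, `qual`,
#'   `lowqual` and `multiallelic`.
#' @export
call_site <- function(pile, ref, config = genotyper_config(),
                      chrom = NA_character_, pos = NA_integer_) {
  stopifnot(is.matrix(pile), nrow(pile) == 4)
  check(any(pile > 0), "at least one individual must have depth > 0")
  rb <- base_to_code(ref)
  M <- ncol(pile)
  dp <- as.integer(colSums(pile))
  names(dp) <- colnames(pile)
  tot <- rowSums(pile)
  tot[rb] <- -1L
  ab <- if (all(tot <= 0)) 0L else which.max(tot)

  k <- if (ab > 0) pile[ab, ] else rep(0L, M)
  n <- pile[rb, ] + k
  post <- mapply(function(nn, kk) {
    r <- map_genotype(nn, kk, config)
    c(r$geno, r$post_hom_ref)
  }, n, k)
  geno <- as.integer(post[1, ])
  geno[dp == 0] <- 0L
  qual <- -10 * sum(log10(post[2, ]))
  lowqual <- qual < config$lowqual_threshold && any(geno >= 2L)

  supp <- rowSums(pile >= 2) > 0
  supp[rb] <- FALSE
  multiallelic <- sum(supp) >= 2

  structure(list(chrom = chrom, pos = pos, ref = ref,
                 alt = if (ab > 0) code_to_base(ab) else NA_character_,
                 geno = setNames(geno, colnames(pile)),
                 ad = rbind(ref = pile[rb, ], alt = k),
                 dp = dp, qual = qual, lowqual = lowqual,
                 multiallelic = multiallelic),
            class = "site_call")
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf("site_call %s:%s  ref=%s alt=%s qual=%.1f%s%s\n",
              x$chrom, format(x$pos), x$ref,
              ifelse(is.na(x$alt), ".", x$alt), x$qual,
              if (x$lowqual) " LowQual" else "",
              if (x$multiallelic) " multiallelic" else ""))
  tab <- table(factor(geno_label(x$geno), levels = GENO_LEVELS))
  cat("  genotypes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

## Shared maximum n for lookup tables: largest possible ref+alt count.
lut_nmax <- function(piles) {
  mx <- max(vapply(piles$chroms, function(ch) max(ch$depth), numeric(1)))
  as.integer(mx + 1L)
}

#' Genotype and classify every site of a simulated genome
#'
#' Runs the compiled genotyping + filtering sweep over all chromosomes.
#' Mostly used through [scan_mutations()]; exposed for access to per-site
#' qualities, alternate alleles and rule masks.
#'
#' @param piles a `pile_set`.
#' @param gconfig caller configuration.
#' @param fconfig filter configuration ([filter_config()]).
#' @param pedigree the pedigree.
#' @return list of class `genome_scan`: per chromosome the sweep output
#'   (`alt`, `qual`, `mask`, `mother_geno`, `father_geno`, candidate
#'   vectors), plus the configurations used.
#' @export
genotype_scan <- function(piles, gconfig = genotyper_config(),
                          fconfig = filter_config(), pedigree) {
  check(identical(piles$individuals, pedigree$individuals),
        "pedigree and piles cover different individuals")
  idx <- role_indices(pedigree)
  nmax <- lut_nmax(piles)
  lut <- genotype_lut(gconfig, nmax)
  out <- lapply(piles$chroms, function(ch) {
    classify_sweep(ch$depth, ch$nonref, ch$ref, lut$geno, lut$qhr,
                   idx$mother, idx$father, idx$focal, idx$bait,
                   gconfig$lowqual_threshold, fconfig$min_parent_depth,
                   fconfig$max_het_focal)
  })
  structure(list(chroms = out, gconfig = gconfig, fconfig = fconfig),
            class = "genome_scan")
}

## Fast single-site call + six-rule classification on a 4 x M count
## matrix, using the precomputed genotype tables.  Semantically identical
## to call_site() followed by classify_site() (enforced by tests); used on
## hot paths (spike-in evaluation).
eval_site_counts <- function(pile, rb, lut, gconfig, fconfig, idx,
                             exempt = NULL) {
  dp <- colSums(pile)
  tot <- rowSums(pile)
  tot[rb] <- -1L
  ab <- if (all(tot <= 0)) 0L else which.max(tot)
  M <- ncol(pile)
  k <- if (ab > 0) pile[ab, ] else integer(M)
  n <- pile[rb, ] + k
  geno <- lut$geno[cbind(n + 1L, k + 1L)]
  geno[dp == 0L] <- 0L
  qual <- sum(lut$qhr[cbind(n + 1L, k + 1L)])
  lowqual <- qual < gconfig$lowqual_threshold && any(geno >= 2L)
  supp <- rowSums(pile >= 2L) > 0
  supp[rb] <- FALSE
  multi <- sum(supp) >= 2L
  focal <- setdiff(idx$focal, exempt)
  maxhet <- fconfig$max_het_focal - if (is.null(exempt)) 0L else 1L
  par <- c(idx$mother, idx$father)
  ok <- !multi && !lowqual &&
    all(dp[par] >= fconfig$min_parent_depth) &&
    all(geno[par] == 1L) && all(k[par] == 0L) &&
    all(k[idx$bait] == 0L) &&
    all(geno[focal] != 0L)
  if (ok) {
    het <- focal[geno[focal] == 2L]
    ok <- length(het) <= maxhet && all(k[setdiff(focal, het)] == 0L)
  }
  list(callable = ok, geno = geno, alt = ab, qual = qual)
}
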