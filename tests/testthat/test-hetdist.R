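test_that("informative sites recover pattern-based heterozygotes", {
  ## deep baits so that heterozygote calls are essentially never missed
  sim <- tiny_sim(seed = 41, error_rate = 0, mu_true = 0,
                  paralog_fraction = 0, mapping_bias = 0,
                  maternal_het_density = 0.01, depth_mean_bait = 35)
  scan <- genotype_scan(sim$piles, genotyper_config(error_rate = 0.005),
                        filter_config(), sim$pedigree)
  info <- informative_sites(scan, sim$piles,
                            sim$truth$segregation_patterns, sim$pedigree)
  snp <- sim$truth$maternal_snps
  expect_gt(nrow(info$sites) / nrow(snp), 0.99)
  expect_identical(info$n_ambiguous, 0L)
  ## matched pattern is the site's own chromosome and the truth homolog,
  ## and the focal het assignment equals the inheritance truth
  key <- paste(info$sites$chrom, info$sites$pos)
  hit <- match(key, paste(snp$chrom, snp$pos))
  expect_false(anyNA(hit))
  expect_identical(info$sites$pattern_chrom, snp$chrom[hit])
  expect_identical(info$sites$homolog, as.numeric(snp$alt_homolog[hit]))
  n_wrong <- 0L
  for (j in seq_len(nrow(info$sites))) {
    inh <- sim$pedigree$maternal_inh[info$focal_names, snp$chrom[hit[j]]]
    n_wrong <- n_wrong +
      sum(info$focal_het[j, ] != (inh == snp$alt_homolog[hit[j]]))
  }
  ## pattern-based het assignment essentially never disagrees with truth
  expect_lt(n_wrong / (nrow(info$sites) * ncol(info$focal_het)), 0.001)
})

test_that("non-matching sites are excluded", {
  sim <- tiny_sim(seed = 42, error_rate = 0, mu_true = 0,
                  paralog_fraction = 0, mapping_bias = 0,
                  maternal_het_density = 0.005, depth_mean_bait = 35)
  scan <- genotype_scan(sim$piles, genotyper_config(error_rate = 0.005),
                        filter_config(), sim$pedigree)
  snp <- sim$truth$maternal_snps
  cn <- snp$chrom[1]; p <- snp$pos[1]
  ch <- sim$piles$chroms[[cn]]

  ## flip one matching bait to hom-ref by erasing its alternate reads:
  ## the bait vector no longer matches any pattern
  inh <- sim$pedigree$maternal_inh[, cn]
  bait_het <- names(inh)[grepl("^B", names(inh)) & inh == snp$alt_homolog[1]]
  victim <- match(bait_het[1], sim$piles$individuals)
  rows <- which(ch$nonref[, 1] == p & ch$nonref[, 2] == victim)
  expect_gt(length(rows), 0)
  d <- ch$depth[p, victim]
  sim$piles$chroms[[cn]]$nonref[rows, 4] <- 0L
  scan2 <- genotype_scan(sim$piles, genotyper_config(error_rate = 0.005),
                         filter_config(), sim$pedigree)
  info2 <- informative_sites(scan2, sim$piles,
                             sim$truth$segregation_patterns, sim$pedigree)
  expect_false(p %in% info2$sites$pos[info2$sites$chrom == cn])

  ## a mother called homozygous is excluded regardless of the baits
  expect_identical(sum(scan2$chroms[[cn]]$mother_geno[p] == 2L &
                         p %in% info2$sites$pos), 0L)
})

test_that("tabulated distributions are binomial without error or bias", {
  sim <- tiny_sim(seed = 43, n_chromosomes = 3, chrom_length = 3e4,
                  error_rate = 0, mapping_bias = 0, mu_true = 0,
                  paralog_fraction = 0, maternal_het_density = 0.04,
                  depth_mean_focal = 20)
  scan <- genotype_scan(sim$piles, genotyper_config(error_rate = 0.005),
                        filter_config(), sim$pedigree)
  info <- informative_sites(scan, sim$piles,
                            sim$truth$segregation_patterns, sim$pedigree)
  hd <- tabulate_het_depths(info)
  expect_identical(sum(hd$counts), as.integer(sum(hd$site_counts)))
  ## chi-square goodness of fit against Binomial(20, 0.5) at depth 20
  obs <- hd$counts[20, 1:21]
  expect_gt(sum(obs), 400)
  pr <- dbinom(0:20, 20, 0.5)
  keep <- pr * sum(obs) >= 5
  p <- suppressWarnings(chisq.test(
    c(sum(obs[!keep]), obs[keep]),
    p = c(sum(pr[!keep]), pr[keep]))$p.value)
  expect_gt(p, 0.01)
})

test_that("mapping bias shifts heterozygote alternate fractions as expected", {
  beta <- 0.3
  sim <- tiny_sim(seed = 44, n_chromosomes = 3, chrom_length = 3e4,
                  error_rate = 0, mapping_bias = beta, mu_true = 0,
                  paralog_fraction = 0, maternal_het_density = 0.04)
  scan <- genotype_scan(sim$piles, genotyper_config(error_rate = 0.005),
                        filter_config(), sim$pedigree)
  info <- informative_sites(scan, sim$piles,
                            sim$truth$segregation_patterns, sim$pedigree)
  hd <- tabulate_het_depths(info)
  covered <- which(hd$site_counts > 50)
  fracs <- vapply(covered, function(d) het_mean_alt(hd, d) / d, numeric(1))
  ## expected alternate fraction after dropping mutant-bearing reads:
  ## (1 - beta) / (2 - beta), clearly below one half
  expect_true(all(fracs < 0.5))
  expect_lt(abs(weighted.mean(fracs, hd$site_counts[covered]) -
                  (1 - beta) / (2 - beta)), 0.02)
})

test_that("sampling honors the empirical distribution and its fallback", {
  counts <- matrix(0L, 100, 101)
  counts[14, 8] <- 25L    # all mass at y = 7 for depth 14
  dist <- structure(list(counts = counts, depth_cap = 100L,
                         site_counts = rowSums(counts)),
                    class = "het_depth_dist")
  expect_true(all(sample_alt_count(dist, 14, 50) == 7L))
  ## unseen depth falls back to Binomial(depth, 0.5)
  set.seed(7)
  y <- sample_alt_count(dist, 150, 4000)
  expect_lt(abs(mean(y) - 75), 4 * sqrt(150 * 0.25 / 4000))
  ## depth inside the cap but unobserved also falls back
  set.seed(8)
  y2 <- sample_alt_count(dist, 30, 2000)
  expect_lt(abs(mean(y2) - 15), 4 * sqrt(30 * 0.25 / 2000))
  ## same seed, same draws
  set.seed(9); a <- sample_alt_count(dist, 150, 20)
  set.seed(9); b <- sample_alt_count(dist, 150, 20)
  expect_identical(a, b)
  expect_error(sample_alt_count(dist, 0), "depth")
})

test_that("segregation patterns can be inferred back from the data", {
  sim <- tiny_sim(seed = 45, error_rate = 0, mu_true = 0,
                  paralog_fraction = 0, mapping_bias = 0,
                  maternal_het_density = 0.01)
  scan <- genotype_scan(sim$piles, genotyper_config(error_rate = 0.005),
                        filter_config(), sim$pedigree)
  pat <- infer_segregation_patterns(scan, sim$piles, sim$pedigree,
                                    n_patterns = 3, min_support = 3)
  truth <- sim$truth$segregation_patterns
  canon <- function(v) {
    s <- paste(v, collapse = "")
    min(s, paste(3L - v, collapse = ""))
  }
  truth_set <- apply(truth, 2, canon)
  inferred_set <- apply(pat, 2, canon)
  expect_setequal(unname(inferred_set), unname(truth_set))
})
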