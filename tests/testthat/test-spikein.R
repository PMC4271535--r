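ped <- fixed_pedigree()

test_that("planting conserves depth and touches only the carrier", {
  pile <- clean_pile(ped)
  pl <- plant_mutation(pile, "F02", "A", 9)
  expect_identical(sum(pl$pile[, "F02"]), sum(pile[, "F02"]))
  expect_identical(unname(pl$pile["A", "F02"]), 25L - 9L)
  expect_identical(unname(pl$pile[pl$mut_base, "F02"]), 9L)
  expect_false(pl$clamped)
  expect_identical(pl$pile[, setdiff(colnames(pile), "F02")],
                   pile[, setdiff(colnames(pile), "F02")])
  ## y = 0 is the identity
  expect_identical(plant_mutation(pile, "F02", "A", 0)$pile, pile)
  ## demanding more reads than available clamps and flags
  pl2 <- plant_mutation(pile, "B01", "A", 40)
  expect_true(pl2$clamped)
  expect_identical(unname(pl2$pile["A", "B01"]), 0L)
  expect_identical(pl2$y_used, 12L)
})

test_that("a clean deep genome is almost fully callable and called", {
  sim <- tiny_sim(seed = 51, n_chromosomes = 2, chrom_length = 1e4,
                  error_rate = 0, mu_true = 0, paralog_fraction = 0,
                  mapping_bias = 0, maternal_het_density = 0)
  set.seed(5)
  sp <- spikein_evaluate(sim$piles, empty_hetdist(), sim$pedigree,
                         n_spikes = 300,
                         genotyper_config(error_rate = 0.005))
  expect_gt(sp$callable_fraction, 0.99)
  expect_gt(sp$call_rate, 0.99)
  expect_true(all(sp$spikes$outcome_callable[sp$spikes$outcome_called]))
})

test_that("spike-in recovers a genome half-blocked by construction", {
  ## a paralog region covering 50% of each chromosome floods every
  ## individual with its alternate base.  A spike inside the region is
  ## blocked (bait reads or multiallelic exclusion) except where the
  ## region base happens to equal the reference (probability 1/4), where
  ## the contamination is invisible; expected callable fraction is
  ## 1 - 0.5 * 3/4 = 0.625
  sim <- tiny_sim(seed = 52, n_chromosomes = 2, chrom_length = 2e4,
                  error_rate = 0, mu_true = 0, paralog_fraction = 0.5,
                  paralog_alt_rate = 0.3, mapping_bias = 0,
                  maternal_het_density = 0)
  set.seed(6)
  sp <- spikein_evaluate(sim$piles, empty_hetdist(), sim$pedigree,
                         n_spikes = 600, genotyper_config(error_rate = 0.005))
  se <- sqrt(0.625 * 0.375 / 600)
  expect_lt(abs(sp$callable_fraction - 0.625), 4 * se + 0.01)
  ## single spike keeps the result fields consistent
  set.seed(7)
  sp1 <- spikein_evaluate(sim$piles, empty_hetdist(),
                          sim$pedigree, n_spikes = 1,
                          genotyper_config(error_rate = 0.005))
  expect_true(sp1$n_callable %in% c(0L, 1L))
  expect_lte(sp1$n_called, sp1$n_callable)
})

test_that("spike-in call rate tracks the recall of truly planted mutations", {
  sim <- tiny_sim(seed = 53, n_chromosomes = 3, chrom_length = 3e4,
                  error_rate = 0.005, mu_true = 2e-4, mapping_bias = 0.4,
                  depth_mean_focal = 12, maternal_het_density = 0.03)
  gcfg <- genotyper_config(error_rate = 0.005)
  scan <- genotype_scan(sim$piles, gcfg, filter_config(), sim$pedigree)
  info <- informative_sites(scan, sim$piles,
                            sim$truth$segregation_patterns, sim$pedigree)
  hd <- tabulate_het_depths(info)
  set.seed(8)
  sp <- spikein_evaluate(sim$piles, hd, sim$pedigree, n_spikes = 1500, gcfg)
  po <- planted_mutation_outcomes(sim, gcfg)
  recall <- sum(po$called) / sum(po$callable)
  se <- sqrt(sp$call_rate * (1 - sp$call_rate) / sp$n_callable +
               recall * (1 - recall) / max(sum(po$callable), 1))
  expect_lt(abs(sp$call_rate - recall), 2 * se + 0.02)
  ## at this shallow depth and strong bias, false negatives exist
  expect_lt(sp$call_rate, 1)
})

test_that("raising the mapping bias lowers the spike-in call rate", {
  ## shallow focal offspring so that lost mutant reads actually cost het
  ## calls; deep bait offspring so that segregation matching (and hence
  ## the empirical distributions) survives the bias
  rates <- vapply(c(0, 0.3, 0.6), function(beta) {
    sim <- tiny_sim(seed = 54, n_chromosomes = 2, chrom_length = 2e4,
                    error_rate = 0.002, mu_true = 0, mapping_bias = beta,
                    depth_mean_focal = 10, depth_mean_bait = 35,
                    maternal_het_density = 0.04)
    gcfg <- genotyper_config(error_rate = 0.002)
    scan <- genotype_scan(sim$piles, gcfg, filter_config(), sim$pedigree)
    info <- informative_sites(scan, sim$piles,
                              sim$truth$segregation_patterns, sim$pedigree)
    set.seed(9)
    spikein_evaluate(sim$piles, tabulate_het_depths(info), sim$pedigree,
                     n_spikes = 800, gcfg)$call_rate
  }, numeric(1))
  ## decreasing in expectation: allow Monte Carlo jitter between
  ## neighbours but demand a clear overall drop
  expect_lt(rates[2], rates[1] + 0.02)
  expect_lt(rates[3], rates[2] + 0.02)
  expect_lt(rates[3], rates[1] - 0.05)
})

test_that("callable-site extrapolation follows the published arithmetic", {
  res <- list(n_total = 1000, callable_fraction = 456 / 1000)
  expect_equal(signif(callable_sites_estimate(res, 2.70e8), 3), 1.23e8)
  expect_identical(callable_sites_estimate(list(n_total = 10,
                                                callable_fraction = 0), 5e6), 0)
  expect_identical(callable_sites_estimate(list(n_total = 10,
                                                callable_fraction = 1), 5e6), 5e6)
})
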