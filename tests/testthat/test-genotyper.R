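test_that("genotype likelihoods follow the binomial read model", {
  L <- genotype_likelihoods(10, 0, 0.01)
  expect_equal(unname(L["hom_ref"]), 0.99^10)
  expect_gt(L["hom_ref"], max(L["het"], L["hom_alt"]))
  ## balanced counts: the heterozygote likelihood is maximal for any
  ## error rate below one half
  for (k in c(1, 5, 12)) for (e in c(0.001, 0.01, 0.1)) {
    L <- genotype_likelihoods(k, k, e)
    expect_equal(unname(L["het"]), choose(2 * k, k) * 0.5^(2 * k))
    expect_gt(L["het"], max(L["hom_ref"], L["hom_alt"]))
  }
  ## relabelling ref <-> alt swaps hom-ref and hom-alt
  a <- genotype_likelihoods(0, 10, 0.01)
  b <- genotype_likelihoods(10, 0, 0.01)
  expect_equal(unname(a["hom_alt"]), unname(b["hom_ref"]))
})

test_that("call_site assigns MAP genotypes with conservative ties", {
  ped <- fixed_pedigree()
  cfg <- genotyper_config(error_rate = 0.01, heterozygosity = 0.01)

  pile <- make_het(clean_pile(ped), "F01", "A", "G")
  call <- call_site(pile, "A", cfg)
  expect_identical(call$alt, "G")
  expect_identical(unname(call$geno["F01"]), 2L)
  expect_identical(unname(call$geno["F02"]), 1L)

  ## no alternate evidence at all: invariant site, all hom-ref
  call0 <- call_site(clean_pile(ped), "A", cfg)
  expect_true(is.na(call0$alt))
  expect_true(all(call0$geno == 1L))

  ## a single alternate read is called hom-ref but the allele depth keeps
  ## the read on record (this distinction drives the filter rules)
  pile1 <- clean_pile(ped)
  pile1["A", "F03"] <- 29L; pile1["C", "F03"] <- 1L
  call1 <- call_site(pile1, "A", cfg)
  expect_identical(unname(call1$geno["F03"]), 1L)
  expect_identical(unname(call1$ad["alt", "F03"]), 1L)

  ## depth zero is undefined; an individual whose reads all show a third
  ## base (not the site's alt) has n = 0, all-equal likelihoods, and the
  ## tie resolves conservatively to hom-ref
  pile2 <- make_het(clean_pile(ped), "F01", "A", "G")  # alt is G
  pile2[, "B01"] <- 0L
  pile2[, "B02"] <- c(0L, 1L, 0L, 0L)  # a lone C read only
  call2 <- call_site(pile2, "A", cfg)
  expect_identical(call2$alt, "G")
  expect_identical(unname(call2$geno["B01"]), 0L)
  expect_identical(unname(call2$geno["B02"]), 1L)
})

test_that("calls are invariant to individual order", {
  ped <- fixed_pedigree()
  pile <- make_het(clean_pile(ped), "F05", "A", "T")
  pile["C", "B07"] <- 2L
  perm <- sample(ncol(pile))
  c1 <- call_site(pile, "A")
  c2 <- call_site(pile[, perm], "A")
  expect_identical(c1$alt, c2$alt)
  expect_identical(c1$geno[colnames(pile)[perm]], c2$geno)
  expect_equal(c1$qual, c2$qual)
})

test_that("genotype concordance with truth exceeds 99% at depth >= 20", {
  sim <- tiny_sim(seed = 21, error_rate = 0.005, mapping_bias = 0,
                  mu_true = 0, maternal_het_density = 0.03,
                  paralog_fraction = 0)
  gcfg <- genotyper_config(error_rate = 0.005)
  scan <- genotype_scan(sim$piles, gcfg, filter_config(), sim$pedigree)
  n_ok <- 0; n_tot <- 0
  for (cn in names(sim$piles$chroms)) {
    ch <- sim$piles$chroms[[cn]]
    snp <- sim$truth$maternal_snps
    snp_c <- snp[snp$chrom == cn, ]
    inh <- sim$pedigree$maternal_inh[, cn]
    for (j in seq_len(min(nrow(snp_c), 80))) {
      p <- snp_c$pos[j]
      call <- call_site(site_pile(sim$piles, cn, p), snp_c$ref[j], gcfg)
      truth_het <- c("mother",
                     names(inh)[inh == snp_c$alt_homolog[j]])
      truth_geno <- setNames(rep(1L, length(call$geno)), names(call$geno))
      truth_geno[truth_het] <- 2L
      deep <- call$dp >= 20
      n_ok <- n_ok + sum(call$geno[deep] == truth_geno[deep])
      n_tot <- n_tot + sum(deep)
    }
  }
  expect_gt(n_tot, 1000)
  expect_gt(n_ok / n_tot, 0.99)
})

test_that("compiled sweep matches the reference per-site caller", {
  sim <- tiny_sim(seed = 22, error_rate = 0.01, paralog_fraction = 0.1,
                  mu_true = 2e-5, mapping_bias = 0.1)
  gcfg <- genotyper_config(error_rate = 0.008)
  fcfg <- filter_config()
  scan <- genotype_scan(sim$piles, gcfg, fcfg, sim$pedigree)
  set.seed(1)
  for (cn in names(sim$piles$chroms)) {
    ch <- sim$piles$chroms[[cn]]
    sw <- scan$chroms[[cn]]
    ## bias the sample toward sites with non-reference reads
    pos <- unique(c(sample(length(ch$ref), 40),
                    sample(ch$nonref[, 1], 60)))
    for (p in pos) {
      pile <- site_pile(sim$piles, cn, p)
      if (sum(pile) == 0) next
      call <- call_site(pile, BASES[ch$ref[p]], gcfg, chrom = cn, pos = p)
      cls <- classify_site(call, fcfg, sim$pedigree)
      swm <- decode_mask(sw$mask[p])
      expect_identical(cls$callable, sw$mask[p] == 0L)
      expect_identical(sort(cls$failed_rules), sort(swm$failed_rules))
      expect_identical(cls$multiallelic, swm$multiallelic)
      expect_equal(call$qual, sw$qual[p], tolerance = 1e-8)
      exp_alt <- if (is.na(call$alt)) 0L else match(call$alt, BASES)
      expect_identical(exp_alt, sw$alt[p])
      expect_identical(unname(call$geno["mother"]), sw$mother_geno[p])
      expect_identical(unname(call$geno["father"]), sw$father_geno[p])
      ## fast single-site evaluator agrees too
      idx <- pedmutr:::role_indices(sim$pedigree)
      lut <- pedmutr:::genotype_lut(gcfg, pedmutr:::lut_nmax(sim$piles))
      fast <- pedmutr:::eval_site_counts(pile, ch$ref[p], lut, gcfg, fcfg, idx)
      expect_identical(fast$callable, cls$callable)
      expect_identical(unname(fast$geno), unname(call$geno))
    }
  }
})
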