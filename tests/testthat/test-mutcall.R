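ped <- fixed_pedigree()
gcfg <- genotyper_config(error_rate = 0.01)
fcfg <- filter_config()

classify_pile <- function(pile, ref = "A", exempt = NULL) {
  classify_site(call_site(pile, ref, gcfg), fcfg, ped, exempt = exempt)
}

test_that("each filter rule is violable in isolation", {
  ## clean deep site with one clear heterozygous focal: callable candidate
  base <- make_het(clean_pile(ped), "F01", "A", "G")
  cls <- classify_pile(base)
  expect_true(cls$callable)
  expect_identical(cls$candidate_individuals, "F01")

  ## rule 1: a weak non-reference call at a low-quality site
  p1 <- clean_pile(ped, depth_parent = 30, depth_focal = 4, depth_bait = 12)
  p1["A", "F01"] <- 2L; p1["G", "F01"] <- 2L
  c1 <- call_site(p1, "A", gcfg)
  expect_true(c1$lowqual)
  expect_identical(classify_pile(p1)$failed_rules, 1L)

  ## rule 2: a shallow parent (depth 9 < 10)
  p2 <- base
  p2["A", "mother"] <- 9L
  expect_identical(classify_pile(p2)$failed_rules, 2L)

  ## rule 2 also trips on a single parental alternate read
  p2b <- base
  p2b["A", "father"] <- p2b["A", "father"] - 1L
  p2b["G", "father"] <- 1L
  expect_identical(classify_pile(p2b)$failed_rules, 2L)

  ## rule 3: one bait offspring with a single alternate read
  p3 <- base
  p3["G", "B04"] <- 1L
  expect_identical(classify_pile(p3)$failed_rules, 3L)

  ## rule 4: an undefined focal genotype (zero depth)
  p4 <- base
  p4[, "F09"] <- 0L
  expect_identical(classify_pile(p4)$failed_rules, 4L)

  ## rule 5: three heterozygous focal offspring
  p5 <- make_het(make_het(base, "F02", "A", "G"), "F03", "A", "G")
  expect_identical(classify_pile(p5)$failed_rules, 5L)

  ## rule 6: an alternate read in a focal offspring outside the het set
  p6 <- base
  p6["A", "F07"] <- p6["A", "F07"] - 1L
  p6["G", "F07"] <- 1L
  expect_identical(classify_pile(p6)$failed_rules, 6L)
})

test_that("two heterozygous focals remain callable and flag a cluster", {
  p <- make_het(make_het(clean_pile(ped), "F01", "A", "G"), "F02", "A", "G")
  cls <- classify_pile(p)
  expect_true(cls$callable)
  expect_setequal(cls$candidate_individuals, c("F01", "F02"))
})

test_that("the carrier exemption relaxes only the focal-side rules", {
  ## carrier het + one other het: fails rule 5 under exemption (max 1 other)
  p <- make_het(make_het(clean_pile(ped), "F01", "A", "G"), "F02", "A", "G")
  p <- make_het(p, "F03", "A", "G")
  expect_false(classify_pile(p, exempt = "F01")$callable)
  ## carrier plus a single other het passes
  p2 <- make_het(make_het(clean_pile(ped), "F01", "A", "G"), "F02", "A", "G")
  expect_true(classify_pile(p2, exempt = "F01")$callable)
  ## the carrier's own undefined genotype or alt reads do not block
  p3 <- make_het(clean_pile(ped), "F01", "A", "G")
  p3[, "F01"] <- 0L
  expect_true(classify_pile(p3, exempt = "F01")$callable)
  ## but a parental alternate read still blocks
  p4 <- make_het(clean_pile(ped), "F01", "A", "G")
  p4["G", "mother"] <- 1L
  expect_false(classify_pile(p4, exempt = "F01")$callable)
})

test_that("multiallelic sites are excluded outright", {
  p <- make_het(clean_pile(ped), "F01", "A", "G")
  p["A", "F02"] <- p["A", "F02"] - 2L
  p["T", "F02"] <- 2L           # second supported non-reference base
  call <- call_site(p, "A", gcfg)
  expect_true(call$multiallelic)
  cls <- classify_site(call, fcfg, ped)
  expect_false(cls$callable)
})

test_that("pedigree/call sample mismatch is a hard error", {
  other <- fixed_pedigree(n_focal = 5, n_bait = 3, seed = 1)
  call <- call_site(clean_pile(ped), "A", gcfg)
  expect_error(classify_site(call, fcfg, other), "different individuals")
})

test_that("scan finds exactly the planted mutations on a clean genome", {
  sim <- tiny_sim(seed = 31, error_rate = 0, paralog_fraction = 0,
                  mapping_bias = 0, mu_true = 2e-5,
                  maternal_het_density = 0.01)
  scan <- scan_mutations(sim$piles, genotyper_config(error_rate = 0.005),
                         filter_config(), sim$pedigree)
  pm <- sim$truth$planted_mutations
  focal <- names(sim$pedigree$roles)[sim$pedigree$roles == "focal"]
  pm_f <- pm[pm$individual %in% focal, ]
  key <- function(d) paste(d$chrom, d$pos, d$individual)
  ## every candidate is a planted focal mutation with the right base change
  expect_gt(nrow(scan$candidates), 0)
  expect_true(all(key(scan$candidates) %in% key(pm_f)))
  hit <- pm_f[match(key(scan$candidates), key(pm_f)), ]
  expect_identical(scan$candidates$mut, hit$mut)
  expect_identical(scan$candidates$wt, hit$wt)
})

test_that("paralog contamination produces no candidates inside its regions", {
  sim <- tiny_sim(seed = 32, paralog_fraction = 0.3, paralog_alt_rate = 0.3,
                  mu_true = 5e-5)
  scan <- scan_mutations(sim$piles, genotyper_config(error_rate = 0.002),
                         filter_config(), sim$pedigree)
  reg <- sim$truth$paralog_regions
  cand <- scan$candidates
  baits <- names(sim$pedigree$roles)[sim$pedigree$roles == "bait"]
  ## a candidate inside a region is spurious-prone only where the
  ## contamination is visible, i.e. at least one bait offspring shows the
  ## region's alternate base (where the region base equals the reference
  ## the contamination cannot manifest)
  bad <- 0L
  for (j in seq_len(nrow(cand))) {
    hit <- reg[reg$chrom == cand$chrom[j] & reg$start <= cand$pos[j] &
                 reg$end >= cand$pos[j], ]
    if (!nrow(hit)) next
    pile <- site_pile(sim$piles, cand$chrom[j], cand$pos[j])
    ch <- sim$piles$chroms[[cand$chrom[j]]]
    if (hit$base[1] != BASES[ch$ref[cand$pos[j]]] &&
        any(pile[hit$base[1], baits] > 0)) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("extra alternate reads never rescue an uncallable site", {
  sim <- tiny_sim(seed = 33, error_rate = 0.005, mu_true = 2e-5)
  ch <- sim$piles$chroms$chr1
  set.seed(99)
  pos <- sample(length(ch$ref), 120)
  flips <- 0L
  targets <- names(ped$roles)[ped$roles %in% c("bait", "focal")]
  for (p in pos) {
    pile <- site_pile(sim$piles, "chr1", p)
    call <- call_site(pile, BASES[ch$ref[p]], gcfg)
    if (is.na(call$alt)) next
    before <- classify_site(call, fcfg, sim$pedigree)$callable
    tgt <- sample(targets, 1)
    pile2 <- pile
    pile2[call$alt, tgt] <- pile2[call$alt, tgt] + 1L
    after <- classify_site(call_site(pile2, BASES[ch$ref[p]], gcfg),
                           fcfg, sim$pedigree)$callable
    if (!before && after) flips <- flips + 1L
  }
  expect_identical(flips, 0L)
})

test_that("site-individual arithmetic matches the published convention", {
  expect_equal(signif(site_individuals(1.23e8, 13), 3), 1.60e9)
  expect_identical(site_individuals(0, 13), 0)
  expect_identical(site_individuals(100, 1), 100)
})
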