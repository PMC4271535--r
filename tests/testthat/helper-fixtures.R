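## Shared fixtures: small simulated experiments and hand-built site piles.

BASES <- c("A", "C", "G", "T")
decode_mask <- pedmutr:::decode_mask

## A small, fast simulated experiment; override any sim_config() argument.
tiny_sim <- function(seed = 101, ...) {
  args <- list(n_chromosomes = 3L, chrom_length = 2e4, seed = seed,
               mu_true = 1e-5, error_rate = 0.002)
  extra <- list(...)
  args[names(extra)] <- extra
  ## fixtures legitimately use mu_true = 0; silence the low-yield warning
  withCallingHandlers(
    generate(do.call(sim_config, args)),
    warning = function(w) {
      if (grepl("uninformative", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

## Deterministic pedigree for hand-built sites.
fixed_pedigree <- function(n_focal = 13L, n_bait = 17L, n_chrom = 3L,
                           seed = 999) {
  set.seed(seed)
  random_pedigree(n_focal, n_bait, n_chrom)
}

## All-reference pile: every individual hom-ref at the given depths.
clean_pile <- function(ped, ref = "A", depth_parent = 30L, depth_focal = 25L,
                       depth_bait = 12L) {
  M <- length(ped$individuals)
  d <- ifelse(ped$roles == "focal", depth_focal,
              ifelse(ped$roles == "bait", depth_bait, depth_parent))
  pile <- matrix(0L, 4, M, dimnames = list(c("A", "C", "G", "T"),
                                           ped$individuals))
  pile[ref, ] <- d
  pile
}

## Give one individual an even ref/alt split (a clear heterozygote).
make_het <- function(pile, individual, ref = "A", alt = "G") {
  d <- sum(pile[, individual])
  pile[, individual] <- 0L
  pile[ref, individual] <- d %/% 2L
  pile[alt, individual] <- d - d %/% 2L
  pile
}

## A het-depth distribution with no observations: every draw falls back
## to Binomial(depth, 0.5).
empty_hetdist <- function(n_focal = 13L) {
  tabulate_het_depths(structure(
    list(sites = data.frame(), focal_het = matrix(FALSE, 0, n_focal),
         focal_depth = matrix(0L, 0, n_focal),
         focal_y = matrix(0L, 0, n_focal),
         focal_names = character(n_focal), n_ambiguous = 0L),
    class = "informative_sites"))
}

## Per-seed summaries of the full-scale parameter-recovery study under the
## acceptance conditions (21 x 200 kb, 13 focal / 17 bait, mu = 5e-7,
## eps = 0.005, beta = 0.05).  Computed once per session and reused by the
## acceptance tests.
recovery_cache <- local({
  cache <- NULL
  function(n_seeds = 50L, n_oracle = 8L) {
    if (!is.null(cache) && nrow(cache) >= n_seeds) return(cache)
    gcfg <- genotyper_config(error_rate = 0.005)
    fcfg <- filter_config()
    rows <- vector("list", n_seeds)
    for (seed in seq_len(n_seeds)) {
      cfg <- sim_config(seed = seed, mu_true = 5e-7, error_rate = 0.005,
                        mapping_bias = 0.05)
      res <- run_pipeline(cfg, gconfig = gcfg, fconfig = fcfg)
      r <- res$report

      ## candidates inside paralog regions whose contamination reaches a
      ## bait individual (there should never be any)
      cand <- res$scan$candidates
      bad_paralog <- 0L
      if (nrow(cand)) {
        reg <- res$sim$truth$paralog_regions
        for (j in seq_len(nrow(cand))) {
          hit <- reg[reg$chrom == cand$chrom[j] &
                       reg$start <= cand$pos[j] & reg$end >= cand$pos[j], ]
          if (!nrow(hit)) next
          ## contamination is only visible where the region base differs
          ## from the reference
          ch <- res$sim$piles$chroms[[cand$chrom[j]]]
          if (hit$base[1] == c("A", "C", "G", "T")[ch$ref[cand$pos[j]]]) next
          pile <- site_pile(res$sim$piles, cand$chrom[j], cand$pos[j])
          baits <- names(res$sim$pedigree$roles)[res$sim$pedigree$roles == "bait"]
          if (any(pile[hit$base[1], baits] > 0)) bad_paralog <- bad_paralog + 1L
        }
      }

      oracle <- NA_real_
      if (seed <= n_oracle)
        oracle <- callable_probability(res$sim$piles, gcfg, fcfg,
                                       res$sim$pedigree)$mean

      rows[[seed]] <- data.frame(
        seed = seed, m = r$m, n_sites = r$n_sites,
        frac_spike = r$callable_fraction_spike,
        call_rate = r$call_rate,
        mu_corrected = r$mu_corrected,
        oracle_callable = oracle,
        bad_paralog_candidates = bad_paralog)
      rm(res); gc(FALSE)
    }
    cache <<- do.call(rbind, rows)
    cache
  }
})
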