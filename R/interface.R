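#' Write multi-sample genotype calls as a minimal VCF v4.2 file
#'
#' Emits one data line per call with QUAL, a PASS/LowQual FILTER and
#' per-sample GT:AD:DP fields, in deterministic field order so that
#' write/read round trips are byte-stable.
#'
#' @param calls list of [call_site()] objects (with `chrom`/`pos` set),
#'   all covering the same individuals.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- if (length(calls)) names(calls[[1]]$geno) else character(0)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pedmutr",
    "##FILTER=<ID=LowQual,Description=\"Low quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  gt_str <- c("./.", "0/0", "0/1", "1/1")
  for (call in calls) {
    fields <- sprintf("%s:%d,%d:%d", gt_str[call$geno + 1L],
                      call$ad["ref", ], call$ad["alt", ], call$dp)
    line <- paste(c(call$chrom, call$pos, ".", call$ref,
                    ifelse(is.na(call$alt), ".", call$alt),
                    sprintf("%.6g", call$qual),
                    if (call$lowqual) "LowQual" else "PASS",
                    ".", "GT:AD:DP", fields), collapse = "\t")
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a minimal VCF v4.2 file into genotype calls
#'
#' Parses biallelic SNP records with per-sample GT, AD and DP fields into
#' [call_site()]-shaped objects.  A FILTER value of `LowQual` maps to the
#' lowqual flag; `./.` genotypes become undefined; records with more than
#' one ALT allele are flagged multiallelic (and thereby excluded from
#' downstream counting); records without AD or DP in their FORMAT are
#' skipped with a warning.  A file whose first line is not a VCF
#' fileformat declaration is rejected.
#'
#' @param path VCF file (uncompressed).
#' @return list of `site_call` objects.
#' @export
read_vcf <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "##fileformat=VCF"))
    stop("malformed VCF header: missing ##fileformat declaration")
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(v@gt)))
  samples <- colnames(gt)[-1]
  out <- list()
  for (i in seq_len(nrow(fix))) {
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt); ai <- match("AD", fmt); di <- match("DP", fmt)
    if (is.na(ai) || is.na(di)) {
      warning(sprintf("record %s:%s lacks AD/DP; skipped",
                      fix[i, "CHROM"], fix[i, "POS"]))
      next
    }
    parts <- strsplit(gt[i, -1], ":", fixed = TRUE)
    gts <- vapply(parts, `[`, "", gi)
    ads <- vapply(parts, `[`, "", ai)
    dps <- as.integer(vapply(parts, `[`, "", di))
    adm <- vapply(strsplit(ads, ",", fixed = TRUE),
                  function(x) as.integer(x[1:2]), integer(2))
    adm[is.na(adm)] <- 0L
    geno <- rep(0L, length(samples))
    geno[gts %in% c("0/0", "0|0")] <- 1L
    geno[gts %in% c("0/1", "1/0", "0|1", "1|0")] <- 2L
    geno[gts %in% c("1/1", "1|1")] <- 3L
    alt <- fix[i, "ALT"]
    multi <- grepl(",", alt, fixed = TRUE)
    call <- structure(list(
      chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"],
      alt = if (is.na(alt) || alt == ".") NA_character_ else
        strsplit(alt, ",", fixed = TRUE)[[1]][1],
      geno = setNames(geno, samples),
      ad = rbind(ref = adm[1, ], alt = adm[2, ]),
      dp = setNames(dps, samples),
      qual = as.numeric(fix[i, "QUAL"]),
      lowqual = identical(unname(fix[i, "FILTER"]), "LowQual"),
      multiallelic = multi), class = "site_call")
    out[[length(out) + 1L]] <- call
  }
  out
}

#' Run the complete simulation-calibration-estimation pipeline
#'
#' Executes, in order: read-count simulation, genome-wide genotyping and
#' six-rule classification, candidate mutation scan, segregation-pattern
#' identification of natural heterozygotes and tabulation of their
#' allele-depth distributions, synthetic-mutation spike-in calibration,
#' and the rate arithmetic.  Everything is reproducible from the
#' configuration (which carries the seed).
#'
#' @param config a [sim_config()].
#' @param gconfig,fconfig caller and filter configurations; by default the
#'   caller's likelihood error rate matches the simulated error rate.
#' @param n_spikes synthetic mutations for the calibration (default 1000).
#' @param depth_cap deepest tabulated heterozygote depth (default 100).
#' @param pi,d,gen_per_year optional population-genetic scalars passed to
#'   [estimate_report()]-style derivations.
#' @param report_path optional path; when given, the report is written as
#'   JSON.
#' @param verbose log per-stage timings to stderr.
#' @return list of class `pipeline_result`: the simulation (`sim`), scan
#'   (`scan`), het distributions (`hetdist`), spike-in (`spike`), the
#'   `rate_estimate` (`rate`) and a flat `report` list of every count the
#'   pipeline produced.
#' @export
run_pipeline <- function(config = sim_config(),
                         gconfig = genotyper_config(error_rate = config$error_rate),
                         fconfig = filter_config(),
                         n_spikes = 1000L, depth_cap = 100L,
                         pi = NULL, d = NULL, gen_per_year = 4,
                         report_path = NULL, verbose = FALSE) {
  t0 <- proc.time()[3]
  stage <- function(what, expr) {
    t1 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE))
    if (verbose)
      message(sprintf("[pedmutr] %-10s %6.1f s", what, proc.time()[3] - t1))
    res
  }
  sim <- stage("simulate", generate(config))
  scanres <- stage("scan", scan_mutations(sim$piles, gconfig, fconfig,
                                          sim$pedigree))
  info <- stage("hetdist", informative_sites(scanres$scan, sim$piles,
                                             sim$truth$segregation_patterns,
                                             sim$pedigree))
  hd <- tabulate_het_depths(info, depth_cap)
  spike <- stage("spikein", spikein_evaluate(sim$piles, hd, sim$pedigree,
                                             n_spikes, gconfig, fconfig))
  m <- nrow(scanres$candidates)
  S_hat <- site_individuals(
    callable_sites_estimate(spike, scanres$n_sites), config$n_focal)
  rate <- if (S_hat > 0) {
    est <- rate_estimate(m, S_hat)
    if (!is.na(spike$call_rate) && spike$call_rate > 0)
      est <- correct_rate(est, spike$call_rate)
    est
  } else NULL

  report <- list(
    seed = config$seed,
    n_sites = scanres$n_sites,
    n_callable_exhaustive = scanres$n_callable_sites,
    callable_fraction_spike = spike$callable_fraction,
    call_rate = spike$call_rate,
    n_informative_het_sites = nrow(info$sites),
    m = m,
    site_individuals = S_hat,
    mu_uncorrected = if (!is.null(rate)) rate$mu_uncorrected else NA,
    ci_uncorrected = if (!is.null(rate)) rate$ci_uncorrected else NA,
    mu_corrected = if (!is.null(rate)) rate$mu_corrected %||% NA else NA,
    ci_corrected = if (!is.null(rate)) rate$ci_corrected %||% NA else NA)
  if (!is.null(pi) && !is.null(report$mu_corrected) &&
      is.finite(report$mu_corrected) && report$mu_corrected > 0)
    report$Ne <- ne_from_pi(pi, report$mu_corrected)
  if (!is.null(d) && !is.null(report$mu_corrected) &&
      is.finite(report$mu_corrected) && report$mu_corrected > 0)
    report$divergence <- divergence_time(d, report$mu_corrected, gen_per_year)

  out <- structure(list(sim = sim, scan = scanres, hetdist = hd,
                        info = info, spike = spike, rate = rate,
                        report = report),
                   class = "pipeline_result")
  if (!is.null(report_path)) write_report(out, report_path)
  if (verbose)
    message(sprintf("[pedmutr] total      %6.1f s", proc.time()[3] - t0))
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("pipeline run (seed %d): %d sites, callable %.1f%% (spike) / %.1f%% (scan)\n",
              r$seed, r$n_sites, 100 * r$callable_fraction_spike,
              100 * r$n_callable_exhaustive / r$n_sites))
  cat(sprintf("  m = %d candidate mutations; call rate %.1f%%\n",
              r$m, 100 * r$call_rate))
  if (!is.null(x$rate)) print(x$rate)
  invisible(x)
}

#' Write a pipeline report
#'
#' JSON (default) or TSV of the flat report list; the seed and
#' configuration travel with the numbers.
#'
#' @param result a [run_pipeline()] result.
#' @param path output path; format chosen by extension (.json or .tsv).
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  rep <- result$report
  rep$config <- unclass(result$sim$piles$config)
  if (grepl("\\.tsv$", path)) {
    flat <- unlist(rep)
    write.table(data.frame(key = names(flat), value = unname(flat)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a plain-text key = value configuration file
#'
#' Recognized keys are the arguments of [sim_config()], plus
#' `genotyper.error_rate`, `genotyper.heterozygosity`,
#' `genotyper.lowqual_threshold`, `filter.min_parent_depth`,
#' `filter.max_het_focal`, and the pipeline keys `n_spikes`, `depth_cap`,
#' `pi`, `d`, `gen_per_year`.  Lines starting with `#` are comments.
#'
#' @param path configuration file.
#' @return list with elements `sim`, `gconfig`, `fconfig` and `pipeline`
#'   ready to pass to [run_pipeline()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  named <- setNames(as.list(vals), keys)
  pick <- function(prefix, fun) {
    sel <- startsWith(names(named), prefix)
    args <- setNames(named[sel], sub(prefix, "", names(named)[sel], fixed = TRUE))
    do.call(fun, args)
  }
  sim_keys <- names(formals(sim_config))
  sim <- do.call(sim_config, named[names(named) %in% sim_keys])
  gcfg <- pick("genotyper.", genotyper_config)
  fcfg <- pick("filter.", filter_config)
  pipe <- named[names(named) %in% c("n_spikes", "depth_cap", "pi", "d",
                                    "gen_per_year")]
  list(sim = sim, gconfig = gcfg, fconfig = fcfg, pipeline = pipe)
}
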