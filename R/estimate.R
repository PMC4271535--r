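#' Uncorrected per-site per-generation mutation rate
#'
#' The number of de novo mutations divided by twice the number of
#' callable site-individuals (each site-individual contributes two base
#' copies, one per inherited genome).
#'
#' @param m mutation count.
#' @param S callable site-individuals ([site_individuals()]).
#' @return rate per site per generation.
#' @export
rate_uncorrected <- function(m, S) {
  check(m >= 0, "m must be non-negative")
  check(S > 0, "S must be positive")
  m / (2 * S)
}

#' Exact (Garwood) Poisson confidence interval for a count
#'
#' Two-sided exact interval for the mean of a Poisson count k: the lower
#' bound solves P(X >= k | lambda) = (1 - level)/2 (0 when k = 0) and the
#' upper bound solves P(X <= k | lambda) = (1 - level)/2.  The default
#' implementation uses the chi-square/gamma quantile identity; the
#' `"bisect"` method inverts the Poisson tail sums numerically and is
#' retained as an independent cross-check (the two agree to better than
#' 1e-9 relative).
#'
#' @param k observed count.
#' @param level confidence level (default 0.95).
#' @param method `"chisq"` (closed form, default) or `"bisect"`.
#' @return numeric vector `c(lower, upper)` for the Poisson mean.
#' @export
poisson_exact_ci <- function(k, level = 0.95, method = c("chisq", "bisect")) {
  method <- match.arg(method)
  check(k >= 0 && k == round(k), "k must be a non-negative integer")
  check(level > 0 && level < 1, "level must be in (0, 1)")
  a <- (1 - level) / 2
  if (method == "chisq") {
    lo <- if (k == 0) 0 else qgamma(a, k)
    hi <- qgamma(1 - a, k + 1)
  } else {
    ## invert the exact tail sums by bisection
    lo <- if (k == 0) 0 else
      uniroot(function(l) ppois(k - 1, l, lower.tail = FALSE) - a,
              lower = 1e-12, upper = k + 10 * sqrt(k + 1) + 10,
              tol = 1e-13)$root
    hi <- uniroot(function(l) ppois(k, l) - a,
                  lower = max(k, 1e-12), upper = k + 10 * sqrt(k + 1) + 20,
                  tol = 1e-13)$root
  }
  c(lower = lo, upper = hi)
}

#' Assemble a mutation-rate estimate with exact Poisson intervals
#'
#' @param m mutation count.
#' @param S callable site-individuals.
#' @param call_rate estimated probability that a mutation at a callable
#'   site is called (from [spikein_evaluate()]); NULL for no correction.
#' @param level confidence level for the Poisson interval.
#' @return object of class `rate_estimate` with the raw ingredients, the
#'   uncorrected rate and interval, and (when `call_rate` is given) the
#'   corrected rate and interval (point estimate and both bounds divided
#'   by the call rate; no uncertainty in the call rate is propagated).
#' @export
rate_estimate <- function(m, S, call_rate = NULL, level = 0.95) {
  mu <- rate_uncorrected(m, S)
  ci <- poisson_exact_ci(m, level) / (2 * S)
  out <- list(m = m, S = S, level = level,
              mu_uncorrected = mu, ci_uncorrected = unname(ci),
              call_rate = call_rate,
              mu_corrected = NULL, ci_corrected = NULL)
  if (!is.null(call_rate)) {
    check(call_rate > 0 && call_rate <= 1, "call_rate must be in (0, 1]")
    out$mu_corrected <- mu / call_rate
    out$ci_corrected <- unname(ci) / call_rate
  }
  structure(out, class = "rate_estimate")
}

#' Divide a rate estimate by the spike-in call rate
#'
#' @param est a [rate_estimate()].
#' @param call_rate probability in (0, 1].
#' @return the estimate with corrected point estimate and interval filled
#'   in (all three divided by `call_rate`).
#' @export
correct_rate <- function(est, call_rate) {
  stopifnot(inherits(est, "rate_estimate"))
  check(call_rate > 0 && call_rate <= 1, "call_rate must be in (0, 1]")
  est$call_rate <- call_rate
  est$mu_corrected <- est$mu_uncorrected / call_rate
  est$ci_corrected <- est$ci_uncorrected / call_rate
  est
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("mutation rate: %d mutations / (2 x %.4g site-individuals)\n",
              x$m, x$S))
  cat(sprintf("  uncorrected: %s (%.0f%% CI %s - %s)\n",
              format_rate(x$mu_uncorrected), 100 * x$level,
              format_rate(x$ci_uncorrected[1]), format_rate(x$ci_uncorrected[2])))
  if (!is.null(x$mu_corrected))
    cat(sprintf("  corrected for call rate %.3f: %s (%.0f%% CI %s - %s)\n",
                x$call_rate, format_rate(x$mu_corrected), 100 * x$level,
                format_rate(x$ci_corrected[1]), format_rate(x$ci_corrected[2])))
  invisible(x)
}

#' Effective population size from neutral nucleotide diversity
#'
#' Equates diversity at putatively neutral (e.g. 4-fold degenerate) sites
#' to 4 Ne mu.
#'
#' @param pi nucleotide diversity (a fraction, e.g. 0.024 for 2.4%).
#' @param mu per-site per-generation mutation rate.
#' @return effective population size in individuals.
#' @export
ne_from_pi <- function(pi, mu) {
  check(mu > 0, "mu must be positive")
  pi / (4 * mu)
}

#' Divergence time from neutral divergence and the mutation rate
#'
#' Assumes neutral nucleotide divergence d = 2 mu t with t in
#' generations.
#'
#' @param d corrected neutral divergence between the two species
#'   (fraction).
#' @param mu per-site per-generation mutation rate.
#' @param g generations per year.
#' @return list with `generations` (t) and `years` (t / g).
#' @export
divergence_time <- function(d, mu, g) {
  check(mu > 0, "mu must be positive")
  check(g > 0, "g must be positive")
  t <- d / (2 * mu)
  list(generations = t, years = t / g)
}

TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Transition / transversion spectrum of a mutation set
#'
#' @param mutations data frame with wild-type and mutant base columns
#'   `wt` and `mut` (as in a [scan_mutations()] candidate table), or two
#'   character vectors via `wt`/`mut`.
#' @param wt,mut alternative direct interface.
#' @return object of class `spectrum_summary`: `transitions`,
#'   `transversions` and the tally over the 12 ordered base changes.
#' @export
spectrum <- function(mutations = NULL, wt = mutations$wt, mut = mutations$mut) {
  wt <- toupper(wt); mut <- toupper(mut)
  base_to_code(c(wt, mut))           # validates
  check(all(wt != mut), "mutant base equals wild-type base")
  change <- if (length(wt)) paste0(wt, ">", mut) else character(0)
  all12 <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))
  all12 <- all12[substr(all12, 1, 1) != substr(all12, 3, 3)]
  tally <- table(factor(change, levels = sort(all12)))
  n_ts <- sum(tally[names(tally) %in% TRANSITIONS])
  structure(list(transitions = n_ts,
                 transversions = length(change) - n_ts,
                 changes = tally),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("mutation spectrum: %d transitions, %d transversions (ts/tv %s)\n",
              x$transitions, x$transversions,
              ifelse(x$transversions > 0,
                     sprintf("%.2f", x$transitions / x$transversions), "Inf")))
  nz <- x$changes[x$changes > 0]
  if (length(nz)) cat(" ", paste(names(nz), nz, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Full downstream report from experiment-level counts
#'
#' Chains the estimation arithmetic from the counted ingredients of a
#' parent-offspring experiment: mutation count, genome size, spike-in
#' calibration counts, and the population-genetic scalars.  This is the
#' "counts-only mode" of the pipeline: every downstream quantity (callable
#' fraction, site-individuals, rates, intervals, effective population
#' size, divergence date) is recomputed from the inputs.
#'
#' @param m number of de novo mutations.
#' @param n_sites total sites in the genome assembly.
#' @param n_focal number of focal offspring.
#' @param spike_total,spike_callable,spike_called spike-in counts: planted,
#'   landing on callable sites, and called.
#' @param pi neutral nucleotide diversity (fraction), or NULL to skip.
#' @param d neutral divergence to a sister species (fraction), or NULL.
#' @param gen_per_year generations per year for the divergence date.
#' @param level confidence level (default 0.95).
#' @return list of class `experiment_report` with all derived quantities.
#' @export
estimate_report <- function(m, n_sites, n_focal,
                            spike_total, spike_callable, spike_called,
                            pi = NULL, d = NULL, gen_per_year = 4,
                            level = 0.95) {
  check(spike_called <= spike_callable && spike_callable <= spike_total,
        "spike counts must be nested")
  callable_fraction <- spike_callable / spike_total
  call_rate <- spike_called / spike_callable
  n_callable <- callable_fraction * n_sites
  S <- site_individuals(n_callable, n_focal)
  est <- rate_estimate(m, S, call_rate = call_rate, level = level)
  out <- list(m = m, n_sites = n_sites, n_focal = n_focal,
              callable_fraction = callable_fraction,
              n_callable_sites = n_callable,
              site_individuals = S,
              call_rate = call_rate,
              rate = est)
  if (!is.null(pi)) out$Ne <- ne_from_pi(pi, est$mu_corrected)
  if (!is.null(d)) out$divergence <- divergence_time(d, est$mu_corrected,
                                                     gen_per_year)
  structure(out, class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Parent-offspring mutation rate experiment\n")
  cat(sprintf("  %d / %.3g sites callable (%.0f%%); %.3g site-individuals\n",
              round(x$n_callable_sites), x$n_sites,
              100 * x$callable_fraction, x$site_individuals))
  print(x$rate)
  cat(sprintf("  spike-in call rate: %.0f%%\n", 100 * x$call_rate))
  if (!is.null(x$Ne))
    cat(sprintf("  effective population size: %.3g (~%.0f million)\n",
                x$Ne, x$Ne / 1e6))
  if (!is.null(x$divergence))
    cat(sprintf("  divergence: %.3g generations, ~%.1f Ma\n",
                x$divergence$generations, x$divergence$years / 1e6))
  invisible(x)
}
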