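#' Identify natural heterozygous sites via maternal segregation patterns
#'
#' Offspring inherit whole chromosomes from the mother, so every
#' heterozygous maternal SNP on a chromosome segregates identically across
#' the offspring.  A site is informative when the mother is called
#' heterozygous, the father is called homozygous, and the bait offspring's
#' het/hom genotype vector exactly matches the projection of one
#' chromosome's segregation pattern.  Heterozygous focal offspring are then
#' assigned from the matched pattern, without reference to their own
#' sequenced genotypes - which is what makes the resulting allele-depth
#' distributions an unbiased picture of what a true heterozygote looks
#' like in these data.
#'
#' Sites whose bait vector matches more than one (chromosome, homolog)
#' projection are dropped and counted in `n_ambiguous`.
#'
#' @param scan a [genotype_scan()] (or the `scan` element of
#'   [scan_mutations()]).
#' @param piles the `pile_set` the scan was computed from.
#' @param patterns offspring-by-chromosome matrix of maternal homolog
#'   labels (1/2), e.g. `truth$segregation_patterns` of a simulation.
#' @param pedigree the pedigree.
#' @return list of class `informative_sites`: data frame `sites` (chrom,
#'   pos, matched pattern chromosome, homolog), logical matrix `focal_het`
#'   (site x focal individual, by-pattern het status), integer matrices
#'   `focal_depth` and `focal_y` (total depth and non-reference read count
#'   per site and focal individual), and `n_ambiguous`.
#' @export
informative_sites <- function(scan, piles, patterns, pedigree) {
  stopifnot(inherits(scan, "genome_scan"))
  idx <- role_indices(pedigree)
  focal_names <- pedigree$individuals[idx$focal]
  bait_names <- pedigree$individuals[idx$bait]
  check(all(rownames(patterns) %in% rownames(pedigree$maternal_inh)) ||
          nrow(patterns) == length(c(idx$focal, idx$bait)),
        "patterns must cover all offspring")
  check(ncol(patterns) == length(piles$chroms),
        "patterns must cover all chromosomes")
  nmax <- lut_nmax(piles)
  lut <- genotype_lut(scan$gconfig, nmax)
  M <- length(piles$individuals)
  nb <- length(bait_names)

  ## bait/focal het projections of every (chromosome, homolog) pattern
  proj_b <- list(); proj_f <- list(); proj_id <- list()
  for (c2 in seq_len(ncol(patterns))) for (h in 1:2) {
    proj_b[[length(proj_b) + 1L]] <- patterns[bait_names, c2] == h
    proj_f[[length(proj_f) + 1L]] <- patterns[focal_names, c2] == h
    proj_id[[length(proj_id) + 1L]] <- c(c2, h)
  }

  out_sites <- list(); out_het <- list(); out_d <- list(); out_y <- list()
  n_amb <- 0L
  for (cn in names(piles$chroms)) {
    sw <- scan$chroms[[cn]]
    ch <- piles$chroms[[cn]]
    cand <- which(sw$mother_geno == 2L &
                    (sw$father_geno == 1L | sw$father_geno == 3L) &
                    sw$alt > 0L)
    if (!length(cand)) next
    S <- length(cand)

    ## gather per-(site, individual) aggregates at the candidate sites;
    ## rows are sorted by (site, individual), so groups are runs
    r0 <- ch$cum[cand]
    r1 <- ch$cum[cand + 1L]
    len <- r1 - r0
    rows <- sequence(len) + rep(r0, len)
    si <- rep.int(seq_len(S), len)
    D <- ch$depth[cand, , drop = FALSE]
    G <- matrix(1L, S, M); G[D == 0L] <- 0L
    K <- matrix(0L, S, M); TT <- matrix(0L, S, M)
    if (length(rows)) {
      sub_ind <- ch$nonref[rows, 2L]
      sub_base <- ch$nonref[rows, 3L]
      sub_cnt <- ch$nonref[rows, 4L]
      isalt <- sub_base == sw$alt[cand][si]
      key <- (si - 1L) * M + sub_ind
      new <- c(TRUE, key[-1L] != key[-length(key)])
      gid <- cumsum(new)
      tot_e <- rowsum(sub_cnt, gid, reorder = FALSE)
      k_e <- rowsum(sub_cnt * isalt, gid, reorder = FALSE)
      ukey <- key[new]
      u_si <- ((ukey - 1L) %/% M) + 1L
      u_ind <- ((ukey - 1L) %% M) + 1L
      ij <- cbind(u_si, u_ind)
      n_e <- D[ij] - (tot_e[, 1] - k_e[, 1])
      G[ij] <- ifelse(D[ij] == 0L, 0L,
                      lut$geno[cbind(n_e + 1, k_e[, 1] + 1)])
      K[ij] <- k_e[, 1]
      TT[ij] <- tot_e[, 1]
    }

    ## encode each site's bait het vector as an integer; a pattern matches
    ## iff the codes are equal, no bait is undefined, and the non-het
    ## baits are uniformly hom-ref or uniformly hom-alt
    Gb <- G[, idx$bait, drop = FALSE]
    hetm <- Gb == 2L
    bits <- 2^(seq_len(nb) - 1)
    hcode <- as.vector((Gb == 2L) %*% bits)
    n0 <- rowSums(Gb == 0L)
    nhom1 <- rowSums(Gb == 1L)
    nhom3 <- rowSums(Gb == 3L)
    nmatch <- integer(S); last <- integer(S)
    for (p in seq_along(proj_b)) {
      pred <- proj_b[[p]]
      pcode <- sum(bits[pred])
      nh <- sum(!pred)
      ok <- hcode == pcode & n0 == 0L & (nhom1 == nh | nhom3 == nh)
      nmatch <- nmatch + ok
      last[ok] <- p
    }
    n_amb <- n_amb + sum(nmatch > 1L)
    keep <- which(nmatch == 1L)
    if (!length(keep)) next
    fh <- t(vapply(last[keep], function(p) proj_f[[p]], logical(length(focal_names))))
    ids <- t(vapply(last[keep], function(p) proj_id[[p]], numeric(2)))
    out_sites[[cn]] <- data.frame(
      chrom = cn, pos = cand[keep],
      pattern_chrom = colnames(patterns)[ids[, 1]] %||% ids[, 1],
      homolog = ids[, 2], stringsAsFactors = FALSE)
    out_het[[cn]] <- fh
    out_d[[cn]] <- D[keep, idx$focal, drop = FALSE]
    out_y[[cn]] <- TT[keep, idx$focal, drop = FALSE]
  }

  sites <- bind_or_empty(out_sites, c("chrom", "pos", "pattern_chrom", "homolog"))
  stack <- function(lst, ncols) {
    lst <- Filter(Negate(is.null), lst)
    if (length(lst)) do.call(rbind, lst) else matrix(0L, 0, ncols)
  }
  nf <- length(focal_names)
  structure(list(sites = sites,
                 focal_het = stack(out_het, nf),
                 focal_depth = stack(out_d, nf),
                 focal_y = stack(out_y, nf),
                 focal_names = focal_names,
                 n_ambiguous = n_amb),
            class = "informative_sites")
}

#' @export
print.informative_sites <- function(x, ...) {
  cat(sprintf("informative heterozygous sites: %d (%d ambiguous dropped)\n",
              nrow(x$sites), x$n_ambiguous))
  invisible(x)
}

#' Tabulate depth-indexed distributions of non-reference read counts
#'
#' For every focal offspring known (by segregation pattern) to be
#' heterozygous at an informative site, records the number of
#' non-reference reads y at the individual's total read depth.  The
#' resulting depth-indexed frequency distributions capture allelic
#' sampling, sequencing error and any bias against non-reference reads,
#' and drive the synthetic-mutation spike-in.
#'
#' @param info an [informative_sites()] result.
#' @param depth_cap tabulate depths 1..`depth_cap` (default 100); deeper
#'   observations are ignored.
#' @return object of class `het_depth_dist`: `counts`, a `depth_cap` x
#'   `(depth_cap + 1)` matrix whose `[d, y + 1]` cell counts observations
#'   of y non-reference reads at depth d, plus `site_counts` per depth.
#' @export
tabulate_het_depths <- function(info, depth_cap = 100L) {
  stopifnot(inherits(info, "informative_sites"))
  counts <- matrix(0L, depth_cap, depth_cap + 1L,
                   dimnames = list(depth = 1:depth_cap, y = 0:depth_cap))
  if (nrow(info$focal_het)) {
    sel <- info$focal_het & info$focal_depth >= 1L &
      info$focal_depth <= depth_cap
    d <- info$focal_depth[sel]
    y <- pmin(info$focal_y[sel], d)
    tab <- tabulate((d - 1L) * (depth_cap + 1L) + y + 1L,
                    nbins = depth_cap * (depth_cap + 1L))
    counts[] <- matrix(tab, depth_cap, depth_cap + 1L, byrow = TRUE)
  }
  structure(list(counts = counts, depth_cap = as.integer(depth_cap),
                 site_counts = rowSums(counts)),
            class = "het_depth_dist")
}

#' @export
print.het_depth_dist <- function(x, ...) {
  cat(sprintf("het depth distributions: %d observations over depths 1..%d\n",
              sum(x$site_counts), x$depth_cap))
  nz <- which(x$site_counts > 0)
  if (length(nz))
    cat(sprintf("  covered depths: %d..%d (median count %.0f)\n",
                min(nz), max(nz), stats::median(x$site_counts[nz])))
  invisible(x)
}

#' Sample a non-reference read count for a given depth
#'
#' Draws from the empirical distribution of non-reference read counts at
#' heterozygous sites of the given depth.  Depths with no observations
#' (or beyond the tabulated cap) fall back to Binomial(depth, 0.5), the
#' idealized allele-sampling model.
#'
#' @param dist a [tabulate_het_depths()] result.
#' @param depth read depth (>= 1).
#' @param n number of draws.
#' @return integer vector of n sampled counts.
#' @export
sample_alt_count <- function(dist, depth, n = 1L) {
  stopifnot(inherits(dist, "het_depth_dist"))
  check(depth >= 1, "depth must be >= 1")
  if (depth > dist$depth_cap || dist$site_counts[depth] == 0)
    return(rbinom(n, depth, 0.5))
  freq <- dist$counts[depth, 1:(depth + 1L)]
  sample(0:depth, n, replace = TRUE, prob = freq)
}

#' Mean of the tabulated non-reference fraction at a given depth
#' @param dist a `het_depth_dist`.
#' @param depth read depth.
#' @return mean y at that depth (NA if unobserved).
#' @export
het_mean_alt <- function(dist, depth) {
  if (depth > dist$depth_cap || dist$site_counts[depth] == 0) return(NA_real_)
  freq <- dist$counts[depth, 1:(depth + 1L)]
  sum((0:depth) * freq) / sum(freq)
}

#' Infer chromosome segregation patterns from the data
#'
#' Utility for real data where patterns are not known a priori: collects
#' the bait+focal het/hom vectors of mother-het father-hom sites and
#' returns the most frequent distinct vectors (up to complement) as
#' inferred patterns.  Simulated experiments carry their true patterns in
#' `truth$segregation_patterns`, which is what the calibration uses.
#'
#' @param scan a [genotype_scan()].
#' @param piles the `pile_set`.
#' @param pedigree the pedigree.
#' @param n_patterns number of patterns (chromosomes) to return.
#' @param min_support drop candidate vectors seen fewer times than this.
#' @return offspring-by-pattern label matrix (1/2) analogous to
#'   `truth$segregation_patterns`.
#' @export
infer_segregation_patterns <- function(scan, piles, pedigree,
                                       n_patterns = length(piles$chroms),
                                       min_support = 5L) {
  idx <- role_indices(pedigree)
  off_idx <- c(idx$focal, idx$bait)
  off_names <- pedigree$individuals[off_idx]
  vecs <- character(0)
  nmax <- lut_nmax(piles)
  lut <- genotype_lut(scan$gconfig, nmax)
  M <- length(piles$individuals)
  for (cn in names(piles$chroms)) {
    sw <- scan$chroms[[cn]]
    ch <- piles$chroms[[cn]]
    cand <- which(sw$mother_geno == 2L & sw$father_geno == 1L & sw$alt > 0L)
    if (!length(cand)) next
    for (s in cand) {
      rows <- nonref_range(ch, s)
      if (!length(rows)) next
      nr <- ch$nonref[rows, , drop = FALSE]
      k <- setNames(rep(0L, M), piles$individuals)
      tot <- k
      hit <- nr[, 3L] == sw$alt[s]
      k[nr[hit, 2L]] <- nr[hit, 4L]
      tot[nr[, 2L]] <- unname(tapply(nr[, 4L], nr[, 2L], sum))[
        match(unique(nr[, 2L]), sort(unique(nr[, 2L])))]
      d <- ch$depth[s, ]
      n <- d - (tot - k)
      g <- ifelse(d == 0L, 0L, lut$geno[cbind(n + 1L, k + 1L)])
      go <- g[off_idx]
      if (any(go == 0L | go == 3L)) next
      vecs <- c(vecs, paste(as.integer(go == 2L), collapse = ""))
    }
  }
  if (!length(vecs)) stop("no usable mother-het sites found")
  ## fold complements together (which homolog carries the alternate allele
  ## is arbitrary per SNP)
  flip <- function(v) chartr("01", "10", v)
  canon <- pmin(vecs, vapply(vecs, flip, ""))
  tab <- sort(table(canon), decreasing = TRUE)
  tab <- tab[tab >= min_support]
  take <- head(names(tab), n_patterns)
  pat <- vapply(take, function(v) {
    as.integer(strsplit(v, "")[[1]]) + 1L
  }, integer(length(off_names)))
  rownames(pat) <- off_names
  colnames(pat) <- paste0("pattern", seq_len(ncol(pat)))
  pat
}

#' Plot an observed heterozygote depth distribution against Binomial(0.5)
#'
#' Draws the empirical frequency distribution of non-reference read
#' counts at one read depth, with the idealized Binomial(depth, 0.5)
#' overlaid; mapping bias against non-reference reads shows up as a left
#' shift of the observed bars.
#'
#' @param x a [tabulate_het_depths()] result.
#' @param depth read depth to display (default: the best-covered depth).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.het_depth_dist <- function(x, depth = which.max(x$site_counts), ...) {
  check(depth >= 1 && depth <= x$depth_cap, "depth outside tabulated range")
  obs <- x$counts[depth, 1:(depth + 1)]
  check(sum(obs) > 0, "no observations at this depth")
  freq <- obs / sum(obs)
  mids <- graphics::barplot(freq, names.arg = 0:depth, col = "grey70",
                            border = NA,
                            xlab = "non-reference reads",
                            ylab = "frequency",
                            main = sprintf("depth %d (%d sites)", depth,
                                           sum(obs)), ...)
  graphics::lines(mids, dbinom(0:depth, depth, 0.5), lwd = 2,
                  col = "steelblue")
  graphics::points(mids, dbinom(0:depth, depth, 0.5), pch = 16,
                   col = "steelblue")
  invisible(x)
}
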