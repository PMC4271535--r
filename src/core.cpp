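#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Walker alias sampler for Poisson(lambda), truncated at negligible tail
// mass; one uniform and O(1) work per draw.
struct PoisTab {
  std::vector<double> prob;
  std::vector<int> alias;
  int K;
  void build(double lam) {
    std::vector<double> pmf;
    if (lam <= 0) pmf.push_back(1.0);
    else {
      double p = std::exp(-lam), cum = p;
      pmf.push_back(p);
      int k = 1;
      while (cum < 1.0 - 1e-15 && k < 100000) {
        p *= lam / k;
        cum += p;
        pmf.push_back(p);
        ++k;
      }
      double tot = 0.0;
      for (size_t j = 0; j < pmf.size(); ++j) tot += pmf[j];
      for (size_t j = 0; j < pmf.size(); ++j) pmf[j] /= tot;
    }
    K = (int) pmf.size();
    prob.assign(K, 0.0);
    alias.assign(K, 0);
    std::vector<int> small, large;
    std::vector<double> scaled(K);
    for (int j = 0; j < K; ++j) {
      scaled[j] = pmf[j] * K;
      (scaled[j] < 1.0 ? small : large).push_back(j);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int g = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = g;
      scaled[g] = (scaled[g] + scaled[s]) - 1.0;
      (scaled[g] < 1.0 ? small : large).push_back(g);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }
  int maxval() const { return K; }
  inline int draw() const {
    double u = unif_rand() * K;
    int i = (int) u;
    if (i >= K) i = K - 1;
    return (u - i) < prob[i] ? i : alias[i];
  }
  // draw plus an independent U(0,1) recycled from the unused fraction of
  // the uniform (within either alias branch the residual is uniform and
  // independent of the outcome)
  inline int draw_u(double *resid) const {
    double u = unif_rand() * K;
    int i = (int) u;
    if (i >= K) i = K - 1;
    double f = u - i;
    if (f < prob[i]) {
      *resid = prob[i] > 1e-12 ? f / prob[i] : unif_rand();
      return i;
    }
    double w = 1.0 - prob[i];
    *resid = w > 1e-12 ? (f - prob[i]) / w : unif_rand();
    return alias[i];
  }
};

// cdf tables of Binomial(n, p) for n = 0..nmax
static std::vector<std::vector<double>> binom_tables(int nmax, double p) {
  std::vector<std::vector<double>> tab(nmax + 1);
  for (int n = 0; n <= nmax; ++n) {
    tab[n].resize(n + 1);
    double cum = 0.0;
    for (int k = 0; k <= n; ++k) {
      cum += R::dbinom(k, n, p, 0);
      tab[n][k] = cum;
    }
    tab[n][n] = 1.0;
  }
  return tab;
}

static inline int draw_tab(const std::vector<double> &cdf, double u) {
  if (u < cdf[0]) return 0;   // overwhelmingly common for small p
  return (int)(std::upper_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
}

// Distribute e erroneous reads uniformly over the three bases other than
// `avoid` (0-based), accumulating into c4.  e is almost always tiny, so
// per-read uniforms beat a binomial split.
static inline void spread_errors(int e, int avoid, int *c4) {
  static const int others[4][3] = {{1,2,3},{0,2,3},{0,1,3},{0,1,2}};
  for (int j = 0; j < e; ++j) {
    int t = (int)(unif_rand() * 3.0);
    if (t > 2) t = 2;
    ++c4[others[avoid][t]];
  }
}

// Simulate read base counts for one chromosome.  Individuals without an
// entry in the sparse special-genotype table are homozygous reference.
// Returns the dense depth matrix and the sparse non-reference count table
// (site, individual, base, count), 1-based, sorted by (site, individual,
// base).
// [[Rcpp::export]]
List sim_chrom_counts(int L, int M, NumericVector lambda, IntegerVector ref,
                      double eps, double beta,
                      int pstart, int pend, int pbase, double prate,
                      IntegerVector sp_pos, IntegerVector sp_ind,
                      IntegerVector sp_a1, IntegerVector sp_a2,
                      IntegerVector sp_mut) {
  IntegerMatrix depth(L, M);
  int *dp = INTEGER(depth);
  std::vector<int> r_site, r_ind, r_base, r_cnt;
  r_site.reserve((size_t)(L * (double) M * std::min(1.0, eps * 3) + 1024));

  std::vector<PoisTab> tD(M);
  int dmax = 0;
  for (int i = 0; i < M; ++i) {
    tD[i].build(lambda[i]);
    dmax = std::max(dmax, tD[i].maxval());
  }
  dmax += 2;
  std::vector<std::vector<double>> binE = binom_tables(dmax, eps);
  std::vector<std::vector<double>> binP;
  bool haspar = pstart >= 1 && pend >= pstart;
  if (haspar) binP = binom_tables(dmax, prate);

  int nsp = sp_pos.size(), spi = 0;
  int pb = pbase - 1;
  const int *refp = INTEGER(ref);

  for (int s = 1; s <= L; ++s) {
    bool inpar = haspar && s >= pstart && s <= pend;
    int rb = refp[s - 1] - 1;
    for (int ind = 1; ind <= M; ++ind) {
      int i = ind - 1;
      int c4[4] = {0, 0, 0, 0};
      int d;
      if (spi < nsp && sp_pos[spi] == s && sp_ind[spi] == ind) {
        // heterozygous / mutant / non-reference genotype
        int a1 = sp_a1[spi] - 1, a2 = sp_a2[spi] - 1, mut = sp_mut[spi];
        ++spi;
        int d0 = tD[i].draw();
        int c = inpar ? draw_tab(binP[d0], unif_rand()) : 0;
        int n = d0 - c;
        int n1 = (int) R::rbinom(n, 0.5);
        int n2 = n - n1;
        int dropped = 0;
        if ((mut & 1) && n1 > 0) { int dr = (int) R::rbinom(n1, beta); n1 -= dr; dropped += dr; }
        if ((mut & 2) && n2 > 0) { int dr = (int) R::rbinom(n2, beta); n2 -= dr; dropped += dr; }
        int e1 = n1 > 0 ? draw_tab(binE[n1], unif_rand()) : 0;
        int e2 = n2 > 0 ? draw_tab(binE[n2], unif_rand()) : 0;
        c4[a1] += n1 - e1;
        c4[a2] += n2 - e2;
        spread_errors(e1, a1, c4);
        spread_errors(e2, a2, c4);
        c4[pb] += c;
        d = d0 - dropped;
        // remove any accidental accumulation on the reference base: it is
        // implicit (ref count = depth - emitted non-ref)
      } else if (inpar) {
        double u;
        int d0 = tD[i].draw_u(&u);
        int c = draw_tab(binP[d0], u);
        int n = d0 - c;
        int e = n > 0 ? draw_tab(binE[n], unif_rand()) : 0;
        spread_errors(e, rb, c4);
        c4[pb] += c;
        d = d0;
      } else {
        double u;
        d = tD[i].draw_u(&u);
        int e = d > 0 ? draw_tab(binE[d], u) : 0;
        if (e > 0) spread_errors(e, rb, c4);
      }
      dp[(size_t) i * L + (s - 1)] = d;
      for (int b = 0; b < 4; ++b)
        if (b != rb && c4[b] > 0) {
          r_site.push_back(s); r_ind.push_back(ind);
          r_base.push_back(b + 1); r_cnt.push_back(c4[b]);
        }
    }
  }

  int R = (int) r_site.size();
  IntegerMatrix nonref(R, 4);
  for (int j = 0; j < R; ++j) {
    nonref(j, 0) = r_site[j]; nonref(j, 1) = r_ind[j];
    nonref(j, 2) = r_base[j]; nonref(j, 3) = r_cnt[j];
  }
  colnames(nonref) = CharacterVector::create("site", "ind", "base", "count");
  return List::create(_["depth"] = depth, _["nonref"] = nonref);
}

// Genotype + six-rule classification sweep over one chromosome.
// genoLUT / qhrLUT are (nmax+1) x (nmax+1) tables indexed by [n of
// ref+alt reads, alt reads]; genotype codes 0 undefined, 1 hom-ref,
// 2 het, 3 hom-alt.  Rule bits in `mask`: bit 0..5 = rules 1..6 failed,
// bit 6 = multiallelic exclusion.  mother/father/focal/bait are 1-based
// column indices into the depth matrix.
// [[Rcpp::export]]
List classify_sweep(IntegerMatrix depth, IntegerMatrix nonref, IntegerVector ref,
                    IntegerMatrix genoLUT, NumericMatrix qhrLUT,
                    int mother, int father,
                    IntegerVector focal, IntegerVector bait,
                    double lowqual_thr, int min_parent_depth,
                    int max_het_focal) {
  int L = depth.nrow(), M = depth.ncol(), R = nonref.nrow();
  int nmax = genoLUT.nrow() - 1;
  IntegerVector alt(L), mask(L), mgeno(L), fgeno(L);
  NumericVector qual(L);
  std::vector<int> cand_site, cand_ind;

  const int *dp = INTEGER(depth);
  const int *nr_s = INTEGER(nonref), *nr_i = nr_s + R, *nr_b = nr_s + 2 * (size_t) R,
            *nr_c = nr_s + 3 * (size_t) R;
  const int *refp = INTEGER(ref);
  const int *glut = INTEGER(genoLUT);
  const double *qlut = REAL(qhrLUT);
  std::vector<double> qhr0(nmax + 1);
  for (int n = 0; n <= nmax; ++n) qhr0[n] = qlut[n];
  int ncol1 = nmax + 1;

  // role of each column: 0 other, 1 mother, 2 father, 3 focal, 4 bait
  std::vector<int> role(M, 0);
  role[mother - 1] = 1; role[father - 1] = 2;
  for (int t = 0; t < focal.size(); ++t) role[focal[t] - 1] = 3;
  for (int t = 0; t < bait.size(); ++t) role[bait[t] - 1] = 4;

  std::vector<int> kvec(M, 0), gvec(M, 0), touched; touched.reserve(M);

  int row = 0;
  for (int s = 1; s <= L; ++s) {
    int rb = refp[s - 1];
    // depth-driven pass: baseline quality, parent depths, focal depth-0
    double q = 0.0;
    int dm = 0, df = 0;
    bool focal_zero = false;
    for (int i = 0; i < M; ++i) {
      int d = dp[(size_t) i * L + (s - 1)];
      if (d > nmax) d = nmax;
      q += qhr0[d];
      if (role[i] == 1) dm = d;
      else if (role[i] == 2) df = d;
      else if (role[i] == 3 && d == 0) focal_zero = true;
    }

    int r0 = row;
    while (row < R && nr_s[row] == s) ++row;
    int r1 = row;

    int m = 0;
    int nhet = 0;
    bool other_alt = false, anynonref = false;
    int gm = dm == 0 ? 0 : 1, gf = df == 0 ? 0 : 1;
    int km = 0, kf = 0;
    int ab = 0;

    if (r1 > r0) {
      // site totals per base; multiallelic support (a base with >= 2
      // reads in one individual)
      int tot[5] = {0, 0, 0, 0, 0};
      int has2 = 0;
      for (int j = r0; j < r1; ++j) {
        tot[nr_b[j]] += nr_c[j];
        if (nr_c[j] >= 2) has2 |= (1 << nr_b[j]);
      }
      int best = 0;
      for (int b = 1; b <= 4; ++b)
        if (b != rb && tot[b] > best) { best = tot[b]; ab = b; }
      int nsupp = 0;
      for (int b = 1; b <= 4; ++b)
        if (b != rb && (has2 & (1 << b))) ++nsupp;
      if (nsupp >= 2) m |= 64;

      for (size_t t = 0; t < touched.size(); ++t) {
        kvec[touched[t]] = 0; gvec[touched[t]] = 0;
      }
      touched.clear();

      int j = r0;
      while (j < r1) {
        int ind = nr_i[j];
        int tot_e = 0, k_e = 0;
        while (j < r1 && nr_i[j] == ind) {
          tot_e += nr_c[j];
          if (nr_b[j] == ab) k_e = nr_c[j];
          ++j;
        }
        int i = ind - 1;
        int d = dp[(size_t) i * L + (s - 1)];
        int n = d - (tot_e - k_e);
        if (n > nmax) n = nmax;
        if (k_e > n) k_e = n;
        int g = (d == 0) ? 0 : glut[k_e * ncol1 + n];
        kvec[i] = k_e;
        gvec[i] = g;
        touched.push_back(i);
        int dcap = d > nmax ? nmax : d;
        q += qlut[k_e * ncol1 + n] - qhr0[dcap];
        if (g >= 2) anynonref = true;
        switch (role[i]) {
        case 1: gm = g; km = k_e; break;
        case 2: gf = g; kf = k_e; break;
        case 3:
          if (g == 2) ++nhet;
          else if (k_e > 0) other_alt = true;
          break;
        case 4:
          if (k_e > 0) m |= 4;                                    // rule 3
          break;
        }
      }
    }
    qual[s - 1] = q;
    alt[s - 1] = ab;
    mgeno[s - 1] = gm; fgeno[s - 1] = gf;

    if (anynonref && q < lowqual_thr) m |= 1;                     // rule 1
    if (dm < min_parent_depth || df < min_parent_depth ||
        gm != 1 || gf != 1 || km > 0 || kf > 0) m |= 2;           // rule 2
    if (focal_zero) m |= 8;                                       // rule 4
    if (nhet > max_het_focal) m |= 16;                            // rule 5
    if (other_alt) m |= 32;                                       // rule 6
    mask[s - 1] = m;

    if (m == 0 && nhet > 0)
      for (size_t t = 0; t < touched.size(); ++t) {
        int i = touched[t];
        if (role[i] == 3 && gvec[i] == 2) {
          cand_site.push_back(s); cand_ind.push_back(i + 1);
        }
      }
  }
  return List::create(_["alt"] = alt, _["qual"] = qual, _["mask"] = mask,
                      _["mother_geno"] = mgeno, _["father_geno"] = fgeno,
                      _["cand_site"] = wrap(cand_site),
                      _["cand_ind"] = wrap(cand_ind));
}

// Exact mutation-conditional callability enumeration.  For every site,
// considers a de novo mutation of each of the 3 non-reference bases in
// each focal offspring (a planted mutation supplies the reads that define
// the site's alternate allele) and counts the fraction of the
// 3 x n_focal combinations for which the six-rule filter, with the
// carrier exempt, passes.  This is the deterministic limit of the
// spike-in procedure and serves as its oracle.
// [[Rcpp::export]]
NumericVector callable_prob_sweep(IntegerMatrix depth, IntegerMatrix nonref,
                                  IntegerVector ref,
                                  IntegerMatrix genoLUT,
                                  int mother, int father,
                                  IntegerVector focal, IntegerVector bait,
                                  int min_parent_depth, int max_het_focal) {
  int L = depth.nrow(), M = depth.ncol(), R = nonref.nrow();
  int nmax = genoLUT.nrow() - 1;
  int ncol1 = nmax + 1;
  int nf = focal.size();
  NumericVector prob(L);
  const int *dp = INTEGER(depth);
  const int *nr_s = INTEGER(nonref), *nr_i = nr_s + R, *nr_b = nr_s + 2 * (size_t) R,
            *nr_c = nr_s + 3 * (size_t) R;
  const int *glut = INTEGER(genoLUT);
  int row = 0;
  std::vector<int> kb(M), tote(M);
  for (int s = 1; s <= L; ++s) {
    int rb = ref[s - 1];
    int r0 = row;
    while (row < R && nr_s[row] == s) ++row;
    int r1 = row;
    int supp = 0;
    for (int j = r0; j < r1; ++j)
      if (nr_c[j] >= 2) supp |= (1 << nr_b[j]);
    int ncomb = 0;
    for (int b = 1; b <= 4; ++b) {
      if (b == rb) continue;
      // the mutant base joining any other supported base => multiallelic
      if (supp & ~(1 << b) & 0x1E) continue;
      std::fill(kb.begin(), kb.end(), 0);
      std::fill(tote.begin(), tote.end(), 0);
      for (int j = r0; j < r1; ++j) {
        tote[nr_i[j] - 1] += nr_c[j];
        if (nr_b[j] == b) kb[nr_i[j] - 1] = nr_c[j];
      }
      // rule 2: parents deep, hom-ref, no mutant-base reads
      bool ok = true;
      int par[2] = {mother - 1, father - 1};
      for (int t = 0; t < 2; ++t) {
        int i = par[t], d = dp[(size_t) i * L + (s - 1)];
        if (d < min_parent_depth || kb[i] > 0) { ok = false; break; }
        int n = d - (tote[i] - kb[i]);
        if (n > nmax) n = nmax;
        if (glut[0 * ncol1 + n] != 1) { ok = false; break; }
      }
      if (!ok) continue;
      // rule 3: no mutant-base reads in any bait offspring
      for (int t = 0; t < bait.size(); ++t)
        if (kb[bait[t] - 1] > 0) { ok = false; break; }
      if (!ok) continue;
      // focal offspring: offenders (undefined, or mutant-base reads
      // without a het call) must coincide with the carrier; het calls
      // among the others are capped at max_het_focal - 1
      int n_off = 0, n_het = 0;
      for (int t = 0; t < nf && n_off <= 1; ++t) {
        int i = focal[t] - 1, d = dp[(size_t) i * L + (s - 1)];
        if (d == 0) { ++n_off; continue; }
        int n = d - (tote[i] - kb[i]);
        if (n > nmax) n = nmax;
        int k = kb[i] > n ? n : kb[i];
        int g = glut[k * ncol1 + n];
        if (g == 2) ++n_het;
        else if (kb[i] > 0) ++n_off;
      }
      int maxo = max_het_focal - 1;
      if (n_off == 0) {
        if (n_het <= maxo) ncomb += nf;
        else if (n_het == maxo + 1) ncomb += n_het;
      } else if (n_off == 1) {
        if (n_het <= maxo) ncomb += 1;
      }
    }
    prob[s - 1] = ncomb / (3.0 * nf);
  }
  return prob;
}
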