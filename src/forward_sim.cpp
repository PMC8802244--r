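// Individual-based forward simulator with overlapping generations.
//
// Yearly cycle (reproduction precedes survival): every individual may become
// a parent this year, weighted by its age- and sex-specific fecundity; then
// each individual survives to the next age with probability s[age] (s at the
// maximum age is 0). The newborns created equal the deaths, so census size
// is constant by construction. Each newborn inherits one intact haplotype
// from each parent (no within-locus recombination) plus Poisson(mu*L) new
// mutations at uniform sites (finite-sites, allele flip).
//
// Haplotypes are bit-packed (64 sites/word); heterozygosity is the mean over
// individuals of popcount(hapA XOR hapB)/L. All randomness flows through R's
// RNG so set.seed() makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int sample_weighted(const std::vector<double>& cum) {
  // cum is a strictly increasing cumulative-weight vector; total > 0
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] > u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector s_f, NumericVector fec_f,
              NumericVector s_m, NumericVector fec_m,
              int n_total, double mu, int l_sites, int years,
              int record_every) {
  const int omega_f = s_f.size(), omega_m = s_m.size();
  if (n_total < 10) stop("N_total must be at least 10");
  if (l_sites < 1) stop("L_sites must be positive");
  if (s_f[omega_f - 1] != 0 || s_m[omega_m - 1] != 0)
    stop("terminal survival must be 0 for both sexes");
  const int W = (l_sites + 63) / 64;
  const double lam = mu * (double)l_sites;

  std::vector<int> age(n_total), sex(n_total); // sex: 0 female, 1 male
  std::vector<uint64_t> hap((size_t)2 * n_total * W, 0ULL);
  std::vector<char> dies(n_total);

  // initialise ages from the stable age distribution (proportional to l_x)
  {
    std::vector<double> cum_f(omega_f), cum_m(omega_m);
    double lf = 1.0, acc = 0.0;
    for (int x = 0; x < omega_f; ++x) { acc += lf; cum_f[x] = acc; lf *= s_f[x]; }
    double lm = 1.0; acc = 0.0;
    for (int x = 0; x < omega_m; ++x) { acc += lm; cum_m[x] = acc; lm *= s_m[x]; }
    for (int i = 0; i < n_total; ++i) {
      sex[i] = (unif_rand() < 0.5) ? 0 : 1;
      age[i] = 1 + sample_weighted(sex[i] == 0 ? cum_f : cum_m);
    }
  }

  const int n_rec = years / record_every;
  NumericVector traj(n_rec);
  std::vector<double> cumw_f, cumw_m; // per-year cumulative parent weights
  std::vector<int> idx_f, idx_m;
  std::vector<uint64_t> nb_hap;
  std::vector<int> nb_slot, nb_sex;

  for (int yr = 0; yr < years; ++yr) {
    if (yr % 256 == 0) checkUserInterrupt();

    // (1) parent sampling weights from the pre-death population
    cumw_f.clear(); cumw_m.clear(); idx_f.clear(); idx_m.clear();
    double tf = 0.0, tm = 0.0;
    for (int i = 0; i < n_total; ++i) {
      if (sex[i] == 0) {
        double w = fec_f[age[i] - 1];
        if (w > 0) { tf += w; cumw_f.push_back(tf); idx_f.push_back(i); }
      } else {
        double w = fec_m[age[i] - 1];
        if (w > 0) { tm += w; cumw_m.push_back(tm); idx_m.push_back(i); }
      }
    }
    if (tf <= 0 || tm <= 0)
      stop("population cannot reproduce in year %d: no %s with positive "
           "fecundity", yr + 1, tf <= 0 ? "females" : "males");

    // (2) deaths by per-individual Bernoulli on age-specific survival
    int n_dead = 0;
    for (int i = 0; i < n_total; ++i) {
      double s = (sex[i] == 0) ? s_f[age[i] - 1] : s_m[age[i] - 1];
      dies[i] = (s <= 0.0) || (unif_rand() >= s);
      if (dies[i]) ++n_dead;
    }

    // (3) newborns replace the dead; parents drawn from the pre-death pool
    nb_hap.assign((size_t)2 * n_dead * W, 0ULL);
    nb_slot.resize(n_dead); nb_sex.resize(n_dead);
    int k = 0;
    for (int i = 0; i < n_total; ++i) if (dies[i]) nb_slot[k++] = i;
    for (int j = 0; j < n_dead; ++j) {
      int mom = idx_f[sample_weighted(cumw_f)];
      int dad = idx_m[sample_weighted(cumw_m)];
      nb_sex[j] = (unif_rand() < 0.5) ? 0 : 1;
      for (int p = 0; p < 2; ++p) {
        int par = (p == 0) ? mom : dad;
        int which = (unif_rand() < 0.5) ? 0 : 1;
        const uint64_t* src = hap.data() + ((size_t)2 * par + which) * W;
        uint64_t* dst = nb_hap.data() + ((size_t)2 * j + p) * W;
        std::copy(src, src + W, dst);
        int nmut = (int)R::rpois(lam);
        for (int m2 = 0; m2 < nmut; ++m2) {
          int site = (int)(unif_rand() * l_sites);
          if (site >= l_sites) site = l_sites - 1;
          dst[site >> 6] ^= (1ULL << (site & 63));
        }
      }
    }
    for (int j = 0; j < n_dead; ++j) {
      int i = nb_slot[j];
      const uint64_t* src = nb_hap.data() + (size_t)2 * j * W;
      std::copy(src, src + 2 * (size_t)W, hap.data() + (size_t)2 * i * W);
      sex[i] = nb_sex[j];
      age[i] = 0;
    }

    // (4) ageing: survivors advance, newborns enter at age 1
    for (int i = 0; i < n_total; ++i) ++age[i];

    // (5) record mean individual heterozygosity
    if ((yr + 1) % record_every == 0) {
      double tot = 0.0;
      for (int i = 0; i < n_total; ++i) {
        const uint64_t* a = hap.data() + (size_t)2 * i * W;
        const uint64_t* b = a + W;
        long het = 0;
        for (int w = 0; w < W; ++w) {
#if defined(__GNUC__) || defined(__clang__)
          het += __builtin_popcountll(a[w] ^ b[w]);
#else
          uint64_t x = a[w] ^ b[w];
          while (x) { x &= x - 1; ++het; }
#endif
        }
        tot += (double)het;
      }
      traj[(yr + 1) / record_every - 1] = tot / ((double)n_total * l_sites);
    }
  }

  return List::create(_["H"] = traj, _["record_every"] = record_every,
                      _["n_total"] = n_total);
}
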