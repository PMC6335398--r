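#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Structured coalescent over discrete demes, run independently for each
// non-recombining segment ("chunk") and reduced on the fly either to a joint
// SFS (counts indexed by the combination of derived-allele counts across
// sampled populations) or to a per-site genotype table.
//
// Time is measured in generations, increasing into the past. Demographic
// events arrive pre-sorted by time; ties are applied in input order, which the
// R layer uses to express admixed origins (two mass moves at one time).
//
// Event codes: 0 = mass_move (lineages in deme a -> deme b w.p. p)
//              1 = set_size  (deme a diploid size := p)
//              2 = set_mig   (backward migration rate m[a][b] := p)

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

struct Lineage {
  int deme;
  double birth;
  uint64_t mask;
};

// [[Rcpp::export]]
List coalsim_engine(int n_demes,
                    IntegerVector leaf_deme,   // 0-based deme of each leaf
                    NumericVector leaf_time,   // sampling time (generations)
                    IntegerVector leaf_pop,    // 0-based SFS axis of each leaf
                    int n_pops,
                    NumericVector sizes0,      // diploid Ne per deme at t = 0
                    NumericMatrix mig0,        // backward migration rates
                    NumericVector ev_time,
                    IntegerVector ev_type,
                    IntegerVector ev_a,
                    IntegerVector ev_b,
                    NumericVector ev_p,
                    NumericVector chunk_rate,  // expected mutations per generation of branch
                    NumericVector chunk_len,   // segment length in bp (positions)
                    bool want_sites) {
  const int n_leaves = leaf_deme.size();
  if (n_leaves > 64) stop("at most 64 haploid samples are supported");
  const int n_chunks = chunk_rate.size();

  // per-population leaf masks and axis strides (first population fastest,
  // matching R array layout)
  std::vector<uint64_t> pop_mask(n_pops, 0);
  std::vector<int> pop_n(n_pops, 0);
  for (int i = 0; i < n_leaves; ++i) {
    pop_mask[leaf_pop[i]] |= (uint64_t(1) << i);
    pop_n[leaf_pop[i]] += 1;
  }
  std::vector<long long> stride(n_pops);
  long long ncells = 1;
  for (int p = 0; p < n_pops; ++p) { stride[p] = ncells; ncells *= (pop_n[p] + 1); }
  NumericVector sfs(want_sites ? 1 : ncells);

  // leaf entry order by sampling time
  std::vector<int> leaf_order(n_leaves);
  for (int i = 0; i < n_leaves; ++i) leaf_order[i] = i;
  std::stable_sort(leaf_order.begin(), leaf_order.end(),
                   [&](int a, int b) { return leaf_time[a] < leaf_time[b]; });

  std::vector<int> site_chunk;
  std::vector<double> site_pos;
  std::vector<uint64_t> site_mask;
  double total_sites = 0.0;

  const int n_ev = ev_time.size();
  const double INF = R_PosInf;

  for (int ch = 0; ch < n_chunks; ++ch) {
    // reset demography
    std::vector<double> N(sizes0.begin(), sizes0.end());
    std::vector<double> M(n_demes * n_demes);
    for (int a = 0; a < n_demes; ++a)
      for (int b = 0; b < n_demes; ++b) M[a * n_demes + b] = mig0(a, b);

    std::vector<Lineage> lin;
    lin.reserve(2 * n_leaves);
    size_t next_leaf = 0;
    int next_ev = 0;
    double t = 0.0;

    // enter leaves sampled at the start
    while (next_leaf < leaf_order.size() && leaf_time[leaf_order[next_leaf]] <= 0.0) {
      int i = leaf_order[next_leaf++];
      lin.push_back({leaf_deme[i], leaf_time[i], uint64_t(1) << i});
    }

    std::vector<std::pair<double, uint64_t>> branches;  // (length, subtended leaves)
    branches.reserve(2 * n_leaves);
    long long guard = 0;

    while (lin.size() + (leaf_order.size() - next_leaf) > 1) {
      if (++guard > 50000000LL) stop("coalescent failed to complete (no common ancestor reachable)");
      // rates per deme
      std::vector<int> k(n_demes, 0);
      for (const auto &l : lin) k[l.deme] += 1;
      double coal_tot = 0.0, mig_tot = 0.0;
      std::vector<double> coal_rate(n_demes, 0.0), mig_rate(n_demes, 0.0);
      for (int d = 0; d < n_demes; ++d) {
        if (k[d] > 1) coal_rate[d] = 0.5 * k[d] * (k[d] - 1) / (2.0 * N[d]);
        double mrow = 0.0;
        for (int b = 0; b < n_demes; ++b) if (b != d) mrow += M[d * n_demes + b];
        mig_rate[d] = k[d] * mrow;
        coal_tot += coal_rate[d];
        mig_tot += mig_rate[d];
      }
      double total = coal_tot + mig_tot;

      double t_fixed = INF;
      bool fixed_is_leaf = false;
      if (next_ev < n_ev) t_fixed = ev_time[next_ev];
      if (next_leaf < leaf_order.size()) {
        double tl = leaf_time[leaf_order[next_leaf]];
        if (tl < t_fixed) { t_fixed = tl; fixed_is_leaf = true; }
      }

      double dt = (total > 0.0) ? R::rexp(1.0 / total) : INF;
      if (t + dt >= t_fixed) {
        if (!R_finite(t_fixed)) stop("lineages cannot coalesce: no migration and no remaining events");
        t = t_fixed;
        if (fixed_is_leaf) {
          while (next_leaf < leaf_order.size() &&
                 leaf_time[leaf_order[next_leaf]] <= t) {
            int i = leaf_order[next_leaf++];
            lin.push_back({leaf_deme[i], leaf_time[i], uint64_t(1) << i});
          }
        } else {
          int e = next_ev++;
          int a = ev_a[e], b = ev_b[e];
          if (ev_type[e] == 0) {          // mass move
            double p = ev_p[e];
            for (auto &l : lin)
              if (l.deme == a && (p >= 1.0 || R::unif_rand() < p)) l.deme = b;
          } else if (ev_type[e] == 1) {   // size change
            N[a] = ev_p[e];
          } else {                        // migration change
            M[a * n_demes + b] = ev_p[e];
          }
        }
        continue;
      }
      t += dt;
      double u = R::unif_rand() * total;
      if (u < coal_tot) {
        int d = 0;
        while (d < n_demes && u >= coal_rate[d]) { u -= coal_rate[d]; ++d; }
        if (d >= n_demes) d = n_demes - 1;
        // pick an unordered pair in deme d
        int i1 = (int)(R::unif_rand() * k[d]);
        int i2 = (int)(R::unif_rand() * (k[d] - 1));
        if (i2 >= i1) ++i2;
        int a = -1, bidx = -1, seen = 0;
        for (size_t j = 0; j < lin.size(); ++j) {
          if (lin[j].deme == d) {
            if (seen == i1) a = (int)j;
            if (seen == i2) bidx = (int)j;
            ++seen;
          }
        }
        branches.push_back({t - lin[a].birth, lin[a].mask});
        branches.push_back({t - lin[bidx].birth, lin[bidx].mask});
        lin[a].mask |= lin[bidx].mask;
        lin[a].birth = t;
        lin.erase(lin.begin() + bidx);
      } else {
        u -= coal_tot;
        int d = 0;
        while (d < n_demes && u >= mig_rate[d]) { u -= mig_rate[d]; ++d; }
        if (d >= n_demes) d = n_demes - 1;
        int pick = (int)(R::unif_rand() * k[d]);
        int idx = -1, seen = 0;
        for (size_t j = 0; j < lin.size(); ++j)
          if (lin[j].deme == d && seen++ == pick) { idx = (int)j; break; }
        double mrow = mig_rate[d] / k[d];
        double v = R::unif_rand() * mrow;
        int dest = -1;
        for (int b = 0; b < n_demes; ++b) {
          if (b == d) continue;
          if (v < M[d * n_demes + b]) { dest = b; break; }
          v -= M[d * n_demes + b];
        }
        if (dest < 0) dest = (d == n_demes - 1) ? 0 : n_demes - 1;
        lin[idx].deme = dest;
      }
    }

    // drop mutations on recorded branches
    double rate = chunk_rate[ch];
    for (const auto &br : branches) {
      if (br.first <= 0.0 || rate <= 0.0) continue;
      int nm = (int)R::rpois(br.first * rate);
      if (nm <= 0) continue;
      total_sites += nm;
      if (want_sites) {
        for (int m = 0; m < nm; ++m) {
          site_chunk.push_back(ch + 1);
          site_pos.push_back(std::floor(R::unif_rand() * chunk_len[ch]) + 1.0);
          site_mask.push_back(br.second);
        }
      } else {
        long long cell = 0;
        for (int p = 0; p < n_pops; ++p)
          cell += stride[p] * popcount64(br.second & pop_mask[p]);
        sfs[cell] += nm;
      }
    }
  }

  if (want_sites) {
    const int ns = (int)site_mask.size();
    IntegerMatrix geno(ns, n_leaves);
    for (int s = 0; s < ns; ++s)
      for (int i = 0; i < n_leaves; ++i)
        geno(s, i) = (site_mask[s] >> i) & 1;
    return List::create(_["n_sites"] = total_sites,
                        _["chunk"] = wrap(site_chunk),
                        _["pos"] = wrap(site_pos),
                        _["geno"] = geno);
  }
  return List::create(_["sfs"] = sfs, _["n_sites"] = total_sites);
}
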