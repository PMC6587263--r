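// Structured-coalescent window simulator.
//
// Backward-in-time event simulation over a set of demes with
// piecewise-constant diploid sizes, scheduled backward merges ("splits" in
// forward time) and a constant backward migration-rate matrix.  Mutations
// follow the infinite-sites model at a per-site per-generation rate.
// Within-window recombination uses a block-independence approximation: the
// window is cut into `n_blocks` equal non-recombining blocks, each with an
// independent genealogy.
//
// Uses R's RNG throughout so that set.seed() in R makes output reproducible.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Demography {
  int n_demes;
  std::vector<int> sample_sizes;              // haploid lineages per deme
  // epochs flattened: per entry (deme, start time, Ne), sorted by start within deme
  std::vector<int> ep_deme;
  std::vector<double> ep_start, ep_ne;
  // splits sorted by time ascending
  std::vector<double> sp_time;
  std::vector<int> sp_derived, sp_ancestral;
  std::vector<double> mig;                    // row-major n_demes x n_demes
  std::vector<double> fixed_times;            // sorted unique event times > 0
};

struct Tree {
  // nodes 0..n-1 are leaves (time 0), internal nodes appended; root last
  std::vector<int> parent;    // -1 for root
  std::vector<double> time;
  int n_leaves;
  double tmrca;
};

Tree simulate_tree(const Demography &d) {
  const int P = d.n_demes;
  int n = 0;
  for (int i = 0; i < P; ++i) n += d.sample_sizes[i];
  Tree tr;
  tr.n_leaves = n;
  if (n == 0) { tr.tmrca = 0.0; return tr; }
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);
  if (n == 1) { tr.tmrca = 0.0; return tr; }

  // active lineages kept per deme for O(1) event handling
  std::vector<std::vector<int> > lins(P);
  int leaf = 0, n_active = 0;
  for (int p = 0; p < P; ++p)
    for (int i = 0; i < d.sample_sizes[p]; ++i) {
      lins[p].push_back(leaf++);
      ++n_active;
    }

  std::vector<double> cur_ne(P, 1.0);
  std::vector<bool> active(P, true);
  std::vector<size_t> ep_ptr(P, 0);
  // initial sizes: last epoch with start <= 0 per deme
  for (size_t e = 0; e < d.ep_deme.size(); ++e)
    if (d.ep_start[e] <= 0.0) cur_ne[d.ep_deme[e]] = d.ep_ne[e];

  // per-deme outward migration rate per lineage (to active demes only)
  std::vector<double> mig_out(P, 0.0);
  for (int p = 0; p < P; ++p)
    for (int q = 0; q < P; ++q)
      if (q != p && active[q]) mig_out[p] += d.mig[p * P + q];

  double t = 0.0;
  size_t fe = 0;
  int next_node = n;
  std::vector<double> coal_rate(P), mig_rate_from(P);
  long iter = 0;

  while (n_active > 1) {
    if (++iter > 100000000L)
      stop("coalescent simulation failed to complete (disconnected demography?)");
    double total = 0.0;
    for (int p = 0; p < P; ++p) {
      double k = (double)lins[p].size();
      coal_rate[p] = (k > 1) ? k * (k - 1.0) / (4.0 * cur_ne[p]) : 0.0;
      mig_rate_from[p] = k * mig_out[p];
      total += coal_rate[p] + mig_rate_from[p];
    }
    double next_fixed = (fe < d.fixed_times.size()) ? d.fixed_times[fe] : R_PosInf;
    if (total <= 0.0) {
      if (!R_FINITE(next_fixed))
        stop("lineages cannot coalesce: no further events and multiple demes remain");
      t = next_fixed;
    } else {
      double dt = exp_rand() / total;
      if (t + dt >= next_fixed) t = next_fixed; else t += dt;
    }
    if (t == next_fixed && R_FINITE(next_fixed)) {
      // apply all fixed events at this time
      while (fe < d.fixed_times.size() && d.fixed_times[fe] == next_fixed) ++fe;
      for (size_t e = 0; e < d.ep_deme.size(); ++e)
        if (d.ep_start[e] == next_fixed) cur_ne[d.ep_deme[e]] = d.ep_ne[e];
      bool deme_died = false;
      for (size_t s = 0; s < d.sp_time.size(); ++s)
        if (d.sp_time[s] == next_fixed) {
          int from = d.sp_derived[s], to = d.sp_ancestral[s];
          lins[to].insert(lins[to].end(), lins[from].begin(), lins[from].end());
          lins[from].clear();
          active[from] = false;
          deme_died = true;
        }
      if (deme_died) {
        std::fill(mig_out.begin(), mig_out.end(), 0.0);
        for (int p = 0; p < P; ++p)
          for (int q = 0; q < P; ++q)
            if (q != p && active[q]) mig_out[p] += d.mig[p * P + q];
      }
      continue;
    }
    // random event
    double u = unif_rand() * total;
    int ev_deme = -1; bool is_coal = false;
    for (int p = 0; p < P; ++p) {
      if (u < coal_rate[p]) { ev_deme = p; is_coal = true; break; }
      u -= coal_rate[p];
      if (u < mig_rate_from[p]) { ev_deme = p; is_coal = false; break; }
      u -= mig_rate_from[p];
    }
    if (ev_deme < 0) ev_deme = P - 1, is_coal = (coal_rate[P - 1] > 0);
    std::vector<int> &dl = lins[ev_deme];
    if (is_coal) {
      // pick two distinct lineages in ev_deme
      int sz = (int)dl.size();
      int a = (int)(unif_rand() * sz); if (a >= sz) a = sz - 1;
      int b = (int)(unif_rand() * (sz - 1)); if (b >= sz - 1) b = sz - 2;
      if (b >= a) ++b;
      int node = next_node++;
      tr.time[node] = t;
      tr.parent[dl[a]] = node;
      tr.parent[dl[b]] = node;
      dl[a] = node;
      dl[b] = dl.back();
      dl.pop_back();
      --n_active;
    } else {
      // migration: pick lineage in ev_deme, pick destination
      int sz = (int)dl.size();
      int a = (int)(unif_rand() * sz); if (a >= sz) a = sz - 1;
      double v = unif_rand() * mig_out[ev_deme];
      int dest = -1;
      for (int q = 0; q < P; ++q) {
        if (q == ev_deme || !active[q]) continue;
        if (v < d.mig[ev_deme * P + q]) { dest = q; break; }
        v -= d.mig[ev_deme * P + q];
      }
      if (dest < 0) continue;
      lins[dest].push_back(dl[a]);
      dl[a] = dl.back();
      dl.pop_back();
    }
  }
  tr.tmrca = tr.time[next_node - 1];
  // truncate unused node slots (when n==1 handled above)
  tr.parent.resize(next_node);
  tr.time.resize(next_node);
  return tr;
}

// descendant-leaf lists per node
std::vector<std::vector<int> > leaf_sets(const Tree &tr) {
  int m = (int)tr.parent.size();
  std::vector<std::vector<int> > ls(m);
  for (int v = 0; v < tr.n_leaves; ++v) ls[v].push_back(v);
  // nodes are created in increasing time order, so a simple forward pass works
  for (int v = 0; v < m; ++v) {
    int p = tr.parent[v];
    if (p >= 0) ls[p].insert(ls[p].end(), ls[v].begin(), ls[v].end());
  }
  return ls;
}

Demography build_demography(const IntegerVector &sample_sizes,
                            const IntegerVector &epoch_deme,
                            const NumericVector &epoch_start,
                            const NumericVector &epoch_ne,
                            const NumericVector &split_time,
                            const IntegerVector &split_derived,
                            const IntegerVector &split_ancestral,
                            const NumericMatrix &mig) {
  Demography d;
  d.n_demes = sample_sizes.size();
  d.sample_sizes.assign(sample_sizes.begin(), sample_sizes.end());
  d.ep_deme.assign(epoch_deme.begin(), epoch_deme.end());
  d.ep_start.assign(epoch_start.begin(), epoch_start.end());
  d.ep_ne.assign(epoch_ne.begin(), epoch_ne.end());
  d.sp_time.assign(split_time.begin(), split_time.end());
  d.sp_derived.assign(split_derived.begin(), split_derived.end());
  d.sp_ancestral.assign(split_ancestral.begin(), split_ancestral.end());
  d.mig.assign(d.n_demes * d.n_demes, 0.0);
  for (int i = 0; i < d.n_demes; ++i)
    for (int j = 0; j < d.n_demes; ++j)
      d.mig[i * d.n_demes + j] = mig(i, j);
  std::set<double> ft;
  for (size_t e = 0; e < d.ep_start.size(); ++e)
    if (d.ep_start[e] > 0) ft.insert(d.ep_start[e]);
  for (size_t s = 0; s < d.sp_time.size(); ++s) ft.insert(d.sp_time[s]);
  d.fixed_times.assign(ft.begin(), ft.end());
  return d;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sim_windows_cpp")]]
List sim_windows_cpp(IntegerVector sample_sizes,
                     IntegerVector epoch_deme, NumericVector epoch_start,
                     NumericVector epoch_ne,
                     NumericVector split_time, IntegerVector split_derived,
                     IntegerVector split_ancestral,
                     NumericMatrix mig,
                     double mu_site_gen, int window_length, int n_blocks,
                     int n_windows) {
  if (n_blocks < 1) stop("n_blocks must be >= 1");
  if (window_length < 1) stop("window_length must be >= 1");
  Demography d = build_demography(sample_sizes, epoch_deme, epoch_start,
                                  epoch_ne, split_time, split_derived,
                                  split_ancestral, mig);
  int n_hap = 0;
  for (int i = 0; i < d.n_demes; ++i) n_hap += d.sample_sizes[i];

  List out(n_windows);
  for (int w = 0; w < n_windows; ++w) {
    std::vector<int> site_pos, site_block;
    std::vector<std::vector<int> > site_leaves;   // derived-carrying leaves
    NumericVector tmrca(n_blocks);
    std::set<int> used_pos;
    for (int b = 0; b < n_blocks; ++b) {
      long lo = (long)((double)b * window_length / n_blocks);
      long hi = (long)((double)(b + 1) * window_length / n_blocks);
      int Lb = (int)(hi - lo);
      Tree tr = simulate_tree(d);
      tmrca[b] = tr.tmrca;
      if (n_hap < 2 || mu_site_gen <= 0 || Lb == 0) continue;
      std::vector<std::vector<int> > ls = leaf_sets(tr);
      int m = (int)tr.parent.size();
      for (int v = 0; v < m; ++v) {
        int p = tr.parent[v];
        if (p < 0) continue;
        double len = tr.time[p] - tr.time[v];
        if (len <= 0) continue;
        int nm = (int)R::rpois(mu_site_gen * (double)Lb * len);
        for (int j = 0; j < nm; ++j) {
          // unique position within the block (infinite-sites)
          int pos = 0;
          for (int tries = 0; tries < 1000; ++tries) {
            pos = (int)lo + 1 + (int)(unif_rand() * Lb);
            if (pos > (int)hi) pos = (int)hi;
            if (used_pos.find(pos) == used_pos.end()) break;
            pos = 0;
          }
          if (pos == 0) continue;   // block saturated; drop mutation
          used_pos.insert(pos);
          site_pos.push_back(pos);
          site_block.push_back(b + 1);
          site_leaves.push_back(ls[v]);
        }
      }
    }
    // sort sites by position
    int S = (int)site_pos.size();
    std::vector<int> ord(S);
    for (int i = 0; i < S; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return site_pos[a] < site_pos[b]; });
    IntegerMatrix geno(n_hap, S);
    IntegerVector pos(S), blk(S);
    for (int c = 0; c < S; ++c) {
      int i = ord[c];
      pos[c] = site_pos[i];
      blk[c] = site_block[i];
      const std::vector<int> &lv = site_leaves[i];
      for (size_t j = 0; j < lv.size(); ++j) geno(lv[j], c) = 1;
    }
    out[w] = List::create(_["pos"] = pos, _["hap"] = geno,
                          _["block"] = blk, _["tmrca"] = tmrca);
  }
  return out;
}
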