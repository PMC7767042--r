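// Structured-coalescent simulator for the hierarchical island model used
// as the neutral null of the F_ST outlier scan. Demes are arranged in
// groups; a lineage migrates at total rate (M_w + M_b) / 2, choosing a
// uniform destination among the other demes of its own group with
// probability M_w / (M_w + M_b) and a uniform deme of another group
// otherwise (attempts with no valid destination are no-ops, so the
// per-move rates are M_w / 2 within and M_b / 2 between per lineage).
// Within a deme, each lineage pair coalesces at rate 1 (time in units of
// 2N generations per deme). One genealogy is simulated per locus; a single
// mutation is then placed on a branch chosen with probability proportional
// to its length, so every locus is polymorphic in the pooled sample.
//
// The last coalescence dominates the runtime: once two lineages remain,
// their deme configuration is a Markov chain on three states (same deme /
// same group / different groups), so that phase is simulated as the lumped
// jump chain - distributionally exact and orders of magnitude cheaper than
// tracking every migration.
//
// Derived-allele counts per sampled deme and heterozygote counts after
// random pairing into diploids are returned; summary statistics are
// computed in R. Uses R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Lineage {
  int deme;
  double born;
  std::vector<int> counts;  // derived descendants per sampled deme
};

int pick_weighted(const std::vector<double>& w, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

// Lumped two-lineage phase: returns the additional time to coalescence
// given the current state (0 = same deme, 1 = same group different deme,
// 2 = different groups).
double two_lineage_time(int state, double M_w, double M_b,
                        int n_groups, int demes_per_group) {
  const bool has_within = demes_per_group > 1;
  const bool has_between = n_groups > 1;
  const double to_G_from_S = has_within ? M_w : 0.0;
  const double to_O_from_S = has_between ? M_b : 0.0;
  const double to_S_from_G = has_within ? M_w / (demes_per_group - 1) : 0.0;
  const double to_O_from_G = has_between ? M_b : 0.0;
  const double to_S_from_O =
      has_between ? M_b / ((n_groups - 1) * (double)demes_per_group) : 0.0;
  const double to_G_from_O =
      has_between
          ? M_b * (demes_per_group - 1) / ((n_groups - 1) * (double)demes_per_group)
          : 0.0;
  double t = 0.0;
  for (;;) {
    double r_coal = 0.0, r1 = 0.0, r2 = 0.0;  // rates to two other states
    int s1 = 0, s2 = 0;
    if (state == 0) {            // same deme
      r_coal = 1.0; r1 = to_G_from_S; s1 = 1; r2 = to_O_from_S; s2 = 2;
    } else if (state == 1) {     // same group
      r1 = to_S_from_G; s1 = 0; r2 = to_O_from_G; s2 = 2;
    } else {                     // different groups
      r1 = to_S_from_O; s1 = 0; r2 = to_G_from_O; s2 = 1;
    }
    double total = r_coal + r1 + r2;
    t += exp_rand() / total;
    double u = unif_rand() * total;
    if (u < r_coal) return t;
    state = (u < r_coal + r1) ? s1 : s2;
  }
}

}  // namespace

// [[Rcpp::export]]
List hier_island_sim_cpp(int n_sims, int n_groups, int demes_per_group,
                         double M_w, double M_b, IntegerVector sample_deme,
                         IntegerVector sample_size) {
  const int K = sample_deme.size();
  const int D = n_groups * demes_per_group;
  const double within_rate = (demes_per_group > 1) ? M_w / 2.0 : 0.0;
  const double between_rate = (n_groups > 1) ? M_b / 2.0 : 0.0;
  const double move_rate = within_rate + between_rate;
  const double p_within = (move_rate > 0) ? within_rate / move_rate : 0.0;

  int n_total = 0;
  for (int k = 0; k < K; ++k) n_total += sample_size[k];
  const int n_genes = 2 * n_total;

  IntegerMatrix derived(n_sims, K);
  IntegerMatrix hets(n_sims, K);
  NumericVector tmrca(n_sims);
  NumericVector total_len(n_sims);

  RNGScope scope;

  std::vector<int> occ(D, 0);
  std::vector<double> branch_len;
  std::vector<std::vector<int>> branch_counts;
  branch_len.reserve(2 * n_genes);
  branch_counts.reserve(2 * n_genes);

  for (int s = 0; s < n_sims; ++s) {
    std::vector<Lineage> lin;
    lin.reserve(n_genes);
    std::fill(occ.begin(), occ.end(), 0);
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < 2 * sample_size[k]; ++j) {
        Lineage L;
        L.deme = sample_deme[k];
        L.born = 0.0;
        L.counts.assign(K, 0);
        L.counts[k] = 1;
        lin.push_back(L);
      }
      occ[sample_deme[k]] += 2 * sample_size[k];
    }
    branch_len.clear();
    branch_counts.clear();

    double t = 0.0;
    double coal_rate = 0.0;
    for (int k = 0; k < K; ++k) {
      int c = 2 * sample_size[k];
      coal_rate += c * (c - 1) / 2.0;
    }

    while (lin.size() > 2) {
      double mig_rate = lin.size() * move_rate;
      double total = coal_rate + mig_rate;
      t += exp_rand() / total;
      if (unif_rand() * total < coal_rate) {
        // coalescence: pick deme with prob proportional to k(k-1)/2,
        // scanning the (few) occupied demes via the lineage list
        double u = unif_rand() * coal_rate, acc = 0.0;
        int deme = -1;
        for (size_t i = 0; i < lin.size(); ++i) {
          int d = lin[i].deme;
          if (occ[d] < 0) continue;      // visited marker
          acc += occ[d] * (occ[d] - 1) / 2.0;
          occ[d] = -occ[d];              // mark visited
          if (u <= acc) { deme = d; break; }
        }
        for (size_t i = 0; i < lin.size(); ++i)  // unmark
          if (occ[lin[i].deme] < 0) occ[lin[i].deme] = -occ[lin[i].deme];
        if (deme < 0) deme = lin[0].deme;
        std::vector<int> here;
        for (size_t i = 0; i < lin.size(); ++i)
          if (lin[i].deme == deme) here.push_back((int)i);
        int a = (int)(unif_rand() * here.size());
        int b = (int)(unif_rand() * (here.size() - 1));
        if (b >= a) ++b;
        int ia = here[a], ib = here[b];
        branch_len.push_back(t - lin[ia].born);
        branch_counts.push_back(lin[ia].counts);
        branch_len.push_back(t - lin[ib].born);
        branch_counts.push_back(lin[ib].counts);
        for (int k = 0; k < K; ++k) lin[ia].counts[k] += lin[ib].counts[k];
        lin[ia].born = t;
        lin[ib] = lin.back();
        lin.pop_back();
        int c = occ[deme];
        occ[deme] = c - 1;
        coal_rate -= c - 1;
      } else {
        // migration
        int i = (int)(unif_rand() * lin.size());
        int from = lin[i].deme;
        int group = from / demes_per_group;
        int to;
        if (unif_rand() < p_within) {
          int off = (int)(unif_rand() * (demes_per_group - 1));
          int within = group * demes_per_group + off;
          to = (within >= from) ? within + 1 : within;
        } else {
          int og = (int)(unif_rand() * (n_groups - 1));
          if (og >= group) ++og;
          to = og * demes_per_group + (int)(unif_rand() * demes_per_group);
        }
        coal_rate -= occ[from] - 1;
        occ[from] -= 1;
        coal_rate += occ[to];
        occ[to] += 1;
        lin[i].deme = to;
      }
    }

    // lumped two-lineage phase
    {
      int d0 = lin[0].deme, d1 = lin[1].deme;
      int state = (d0 == d1) ? 0
                  : (d0 / demes_per_group == d1 / demes_per_group) ? 1 : 2;
      t += two_lineage_time(state, M_w, M_b, n_groups, demes_per_group);
      branch_len.push_back(t - lin[0].born);
      branch_counts.push_back(lin[0].counts);
      branch_len.push_back(t - lin[1].born);
      branch_counts.push_back(lin[1].counts);
    }

    tmrca[s] = t;
    double Ltot = 0.0;
    for (double bl : branch_len) Ltot += bl;
    total_len[s] = Ltot;
    int mb = pick_weighted(branch_len, Ltot);
    const std::vector<int>& c = branch_counts[mb];
    for (int k = 0; k < K; ++k) derived(s, k) = c[k];
    // random pairing into diploids within each sampled deme
    for (int k = 0; k < K; ++k) {
      int n2 = 2 * sample_size[k];
      std::vector<int> genes(n2, 0);
      for (int j = 0; j < c[k]; ++j) genes[j] = 1;
      for (int j = n2 - 1; j > 0; --j) {
        int m = (int)(unif_rand() * (j + 1));
        std::swap(genes[j], genes[m]);
      }
      int h = 0;
      for (int j = 0; j < n2; j += 2)
        if (genes[j] != genes[j + 1]) ++h;
      hets(s, k) = h;
    }
  }

  return List::create(_["derived"] = derived, _["hets"] = hets,
                      _["tmrca"] = tmrca, _["total_length"] = total_len);
}
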