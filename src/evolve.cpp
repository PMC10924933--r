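#include <Rcpp.h>
#include <vector>

// Forward Wright-Fisher-style simulation of an ERV family.  One individual =
// a bag of elements (competent flag + affinity for the shared mobilization
// machinery).  Offspring: two fitness-proportional parents sampled with
// replacement; each parental element transmitted w.p. 0.5 and additionally
// copied into the gamete w.p. q_ij = r_i * a_ij / sum_j a_ij; mutation then
// hits each offspring element w.p. mu (competent -> defective; affinity +=
// N(0,1) floored at 0 when allowed and positive).  Uses R's RNG so set.seed()
// governs reproducibility.

struct Genome {
  std::vector<unsigned char> competent;
  std::vector<double> affinity;
  size_t size() const { return competent.size(); }
};

// [[Rcpp::export]]
Rcpp::NumericMatrix evolve_cpp(int N, int G, double s, double p_exp,
                               bool no_selection, double mu,
                               bool allow_affinity_mutation, double t_max,
                               double r_max, double scale,
                               double high_affinity_threshold) {
  Rcpp::RNGScope rng;
  std::vector<Genome> pop(N), next(N);

  // seed generation: proportion s carries one competent element, affinity 1
  int n_seed = (int)std::round(s * N);
  for (int i = 0; i < n_seed; ++i) {
    pop[i].competent.push_back(1);
    pop[i].affinity.push_back(1.0);
  }

  Rcpp::NumericMatrix traj(G, 4);
  std::vector<double> fit(N), cum(N);
  int g_done = 0;

  for (int g = 0; g < G; ++g) {
    // record class means of the current generation
    double tot = 0, comp = 0, def_lo = 0, def_hi = 0;
    for (int i = 0; i < N; ++i) {
      const Genome &gm = pop[i];
      tot += gm.size();
      for (size_t j = 0; j < gm.size(); ++j) {
        if (gm.competent[j]) comp += 1;
        else if (gm.affinity[j] > high_affinity_threshold) def_hi += 1;
        else def_lo += 1;
      }
    }
    traj(g, 0) = tot / N;
    traj(g, 1) = comp / N;
    traj(g, 2) = def_lo / N;
    traj(g, 3) = def_hi / N;
    g_done = g + 1;
    if (g == G - 1) break;

    // fitness and cumulative sampling weights
    double fsum = 0;
    for (int i = 0; i < N; ++i) {
      double t_i = (double)pop[i].size();
      double f = no_selection ? 1.0
                              : 1.0 - std::pow(t_i / t_max, p_exp);
      if (t_i >= t_max) f = 0.0;
      if (f < 0) f = 0.0;
      fsum += f;
      fit[i] = f;
      cum[i] = fsum;
    }
    if (fsum <= 0) break;  // extinction: nobody can reproduce

    for (int k = 0; k < N; ++k) {
      Genome &off = next[k];
      off.competent.clear();
      off.affinity.clear();
      for (int par = 0; par < 2; ++par) {
        double u = unif_rand() * fsum;
        int lo = 0, hi = N - 1;
        while (lo < hi) {  // binary search on the cumulative weights
          int mid = (lo + hi) / 2;
          if (cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        const Genome &p = pop[lo];
        size_t n_el = p.size();
        if (n_el == 0) continue;
        int c_i = 0;
        double asum = 0;
        for (size_t j = 0; j < n_el; ++j) {
          c_i += p.competent[j];
          asum += p.affinity[j];
        }
        double r_i = (1.0 - std::exp(-scale * c_i)) * r_max;
        for (size_t j = 0; j < n_el; ++j) {
          if (unif_rand() < 0.5) {  // Mendelian transmission
            off.competent.push_back(p.competent[j]);
            off.affinity.push_back(p.affinity[j]);
          }
          double q = (asum > 0) ? r_i * p.affinity[j] / asum : 0.0;
          if (q > 0 && unif_rand() < q) {  // de novo copy into the gamete
            off.competent.push_back(p.competent[j]);
            off.affinity.push_back(p.affinity[j]);
          }
        }
      }
      if (mu > 0) {
        for (size_t j = 0; j < off.size(); ++j) {
          if (unif_rand() < mu) {
            off.competent[j] = 0;
            if (allow_affinity_mutation && off.affinity[j] > 0) {
              double a = off.affinity[j] + norm_rand();
              off.affinity[j] = a < 0 ? 0.0 : a;
            }
          }
        }
      }
    }
    pop.swap(next);
  }

  if (g_done == G) return traj;
  return traj(Rcpp::Range(0, g_done - 1), Rcpp::Range(0, 3));
}
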