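#include <Rcpp.h>
using namespace Rcpp;

// Expected force for x = 2 over a CSR adjacency.
//
// Clusters are keyed by ordered transmission-event sequences: the first
// event infects a neighbour a of the seed i, the second event is any edge
// from {i, a} to a node outside {i, a}. A node adjacent to both i and a is
// reachable by two distinct edges and therefore yields two clusters.
//
// Cluster degree d = total (out-)strength of the infected set minus every
// directed internal edge occurrence (an undirected edge stored in both CSR
// directions is thereby subtracted twice, as required).
//
// When `weighted`, cluster degrees are weight sums. When additionally
// `use_p`, each cluster carries a formation weight
// p = prod(step edge weight / total eligible weight at that step) and the
// entropy is taken over q ∝ p*d; otherwise q ∝ d (all p equal), the direct
// weighted analogue of the unweighted definition.
// [[Rcpp::export(name = ".exf_x2_cpp")]]
NumericVector exf_x2_cpp(IntegerVector ptr, IntegerVector nbr,
                         NumericVector wt, NumericVector strength,
                         IntegerVector seeds, bool weighted, bool use_p,
                         bool directed) {
  const int n = ptr.size() - 1;
  NumericVector out(seeds.size());
  // scratch weight marks: w(i->v) and w(a->v); 0 where absent
  std::vector<double> wmi(n, 0.0), wma(n, 0.0);
  std::vector<double> pd;

  for (int s = 0; s < seeds.size(); ++s) {
    const int i = seeds[s];
    pd.clear();
    const double si = strength[i];
    if (ptr[i + 1] - ptr[i] == 0 || si <= 0) { out[s] = 0.0; continue; }
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) wmi[nbr[e]] = wt[e];

    for (int e1 = ptr[i]; e1 < ptr[i + 1]; ++e1) {
      const int a = nbr[e1];
      const double w1 = wt[e1];
      const double p1 = (weighted && use_p) ? w1 / si : 1.0;
      double wai = 0.0; // w(a -> i), may be absent in directed graphs
      for (int e = ptr[a]; e < ptr[a + 1]; ++e) {
        wma[nbr[e]] = wt[e];
        if (nbr[e] == i) wai = wt[e];
      }
      // total eligible infected->susceptible weight after i infected a
      const double W2 = (si - w1) + (strength[a] - wai);
      if (W2 > 0) {
        const double sia = si + strength[a];
        // second event from i
        for (int e2 = ptr[i]; e2 < ptr[i + 1]; ++e2) {
          const int b = nbr[e2];
          if (b == a) continue;
          double d = sia + strength[b];
          if (directed) {
            d -= w1 + wai + wmi[b] + wma[b];
            for (int e = ptr[b]; e < ptr[b + 1]; ++e)
              if (nbr[e] == i || nbr[e] == a) d -= wt[e];
          } else {
            d -= 2.0 * (w1 + wmi[b] + wma[b]);
          }
          if (d < 0) d = 0;
          pd.push_back(((weighted && use_p) ? p1 * wt[e2] / W2 : p1) * d);
        }
        // second event from a
        for (int e2 = ptr[a]; e2 < ptr[a + 1]; ++e2) {
          const int b = nbr[e2];
          if (b == i) continue;
          double d = sia + strength[b];
          if (directed) {
            d -= w1 + wai + wmi[b] + wma[b];
            for (int e = ptr[b]; e < ptr[b + 1]; ++e)
              if (nbr[e] == i || nbr[e] == a) d -= wt[e];
          } else {
            d -= 2.0 * (w1 + wmi[b] + wma[b]);
          }
          if (d < 0) d = 0;
          pd.push_back(((weighted && use_p) ? p1 * wt[e2] / W2 : p1) * d);
        }
      }
      for (int e = ptr[a]; e < ptr[a + 1]; ++e) wma[nbr[e]] = 0.0;
    }
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) wmi[nbr[e]] = 0.0;

    double tot = 0.0;
    for (double v : pd) tot += v;
    double h = 0.0;
    if (tot > 0) {
      for (double v : pd)
        if (v > 0) { const double q = v / tot; h -= q * std::log(q); }
    }
    out[s] = h;
  }
  return out;
}
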