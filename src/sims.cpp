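#include <Rcpp.h>
using namespace Rcpp;

// Event-driven (Gillespie) and synchronous-round epidemic simulators over a
// CSR adjacency. Both use R's RNG so that runs are reproducible under
// set.seed(). A run terminates when the cumulative number of ever-infected
// nodes reaches `half_target` (reached_half = 1), on extinction (no infected
// left), on exhaustion of infected-susceptible edges (SI on a too-small
// component), or at `event_cap` transmissions.
//
// Returned matrix, one row per run:
//   reached_half, t_end, max_ever, n_events, is_final, is_recount, max_prev
// max_prev is the peak instantaneous number of infected nodes (prevalence).
// where is_final is the incrementally maintained infected-susceptible edge
// weight at termination and is_recount the same quantity recomputed from
// scratch (they must agree; exposed for bookkeeping tests).

static double recount_is(const IntegerVector &ptr, const IntegerVector &nbr,
                         const NumericVector &wt, const std::vector<int> &status) {
  const int n = ptr.size() - 1;
  double m = 0.0;
  for (int v = 0; v < n; ++v) {
    if (status[v] != 1) continue;
    for (int e = ptr[v]; e < ptr[v + 1]; ++e)
      if (status[nbr[e]] == 0) m += wt[e];
  }
  return m;
}

// model: 0 = SI, 1 = SIS, 2 = SIR; continuous time
// [[Rcpp::export(name = ".epi_ct_cpp")]]
NumericMatrix epi_ct_cpp(IntegerVector ptr, IntegerVector nbr, NumericVector wt,
                         int seed, int model, double beta, int n_runs,
                         int half_target, double event_cap) {
  const int n = ptr.size() - 1;
  NumericMatrix res(n_runs, 7);
  std::vector<int> status(n), inf_list, inf_pos(n);
  std::vector<double> sw(n);  // per infected node: weight to susceptibles
  std::vector<char> ever(n);

  for (int run = 0; run < n_runs; ++run) {
    std::fill(status.begin(), status.end(), 0);
    std::fill(sw.begin(), sw.end(), 0.0);
    std::fill(ever.begin(), ever.end(), 0);
    inf_list.clear();
    double m = 0.0, t = 0.0;
    int cum = 0, n_events = 0, reached = 0, max_prev = 0;

    // infect node v (must be susceptible)
    auto infect = [&](int v) {
      status[v] = 1;
      inf_pos[v] = (int)inf_list.size();
      inf_list.push_back(v);
      if (!ever[v]) { ever[v] = 1; ++cum; }
      double s = 0.0;
      for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
        const int u = nbr[e];
        if (status[u] == 0) s += wt[e];
        else if (status[u] == 1) { sw[u] -= wt[e]; m -= wt[e]; }
      }
      sw[v] = s; m += s;
      if ((int)inf_list.size() > max_prev) max_prev = inf_list.size();
    };
    auto recover = [&](int v) {
      // remove from infected list
      const int pos = inf_pos[v], last = inf_list.back();
      inf_list[pos] = last; inf_pos[last] = pos; inf_list.pop_back();
      m -= sw[v]; sw[v] = 0.0;
      status[v] = (model == 1) ? 0 : 2;
      if (model == 1) {
        for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
          const int u = nbr[e];
          if (status[u] == 1) { sw[u] += wt[e]; m += wt[e]; }
        }
      }
    };

    infect(seed);
    if (cum >= half_target) reached = 1;

    while (!reached && !inf_list.empty()) {
      const double rate_tr = (model == 0 ? 1.0 : beta) * m;
      const double rate_rec = (model == 0) ? 0.0 : (double)inf_list.size();
      const double total = rate_tr + rate_rec;
      if (total <= 0) break;  // SI with exhausted component
      t += R::exp_rand() / total;
      if (unif_rand() * total < rate_tr) {
        // pick infectious node proportional to its IS weight
        double u = unif_rand() * m, acc = 0.0;
        int v = inf_list.back();
        for (int k = 0; k < (int)inf_list.size(); ++k) {
          acc += sw[inf_list[k]];
          if (u <= acc) { v = inf_list[k]; break; }
        }
        // pick susceptible neighbour proportional to edge weight
        double u2 = unif_rand() * sw[v], acc2 = 0.0;
        int tgt = -1;
        for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
          if (status[nbr[e]] != 0) continue;
          acc2 += wt[e];
          if (u2 <= acc2) { tgt = nbr[e]; break; }
        }
        if (tgt < 0) {  // numerical edge case: take last susceptible
          for (int e = ptr[v + 1] - 1; e >= ptr[v]; --e)
            if (status[nbr[e]] == 0) { tgt = nbr[e]; break; }
        }
        if (tgt >= 0) infect(tgt);
        ++n_events;
        if (cum >= half_target) reached = 1;
        if (n_events >= event_cap) break;
      } else {
        recover(inf_list[(int)(unif_rand() * inf_list.size())]);
      }
    }
    res(run, 0) = reached;
    res(run, 1) = t;
    res(run, 2) = cum;
    res(run, 3) = n_events;
    res(run, 4) = m;
    res(run, 5) = recount_is(ptr, nbr, wt, status);
    res(run, 6) = max_prev;
  }
  return res;
}

// Synchronous rounds, infectious period exactly one round.
// model: 1 = SIS, 2 = SIR; per-edge per-round transmission probability is
// 1 - (1 - r)^w (reduces to r for unit weights).
// [[Rcpp::export(name = ".epi_dt_cpp")]]
NumericMatrix epi_dt_cpp(IntegerVector ptr, IntegerVector nbr, NumericVector wt,
                         int seed, int model, double r, int n_runs,
                         int half_target, double round_cap) {
  const int n = ptr.size() - 1;
  NumericMatrix res(n_runs, 7);
  std::vector<int> status(n), cur, nxt;
  std::vector<char> ever(n), newly(n);

  for (int run = 0; run < n_runs; ++run) {
    std::fill(status.begin(), status.end(), 0);
    std::fill(ever.begin(), ever.end(), 0);
    std::fill(newly.begin(), newly.end(), 0);
    cur.clear(); nxt.clear();
    status[seed] = 1; ever[seed] = 1;
    cur.push_back(seed);
    int cum = 1, rounds = 0, reached = (cum >= half_target) ? 1 : 0,
        max_prev = 1;

    while (!reached && !cur.empty() && rounds < round_cap) {
      nxt.clear();
      for (int k = 0; k < (int)cur.size(); ++k) {
        const int v = cur[k];
        for (int e = ptr[v]; e < ptr[v + 1]; ++e) {
          const int u = nbr[e];
          if (status[u] != 0 || newly[u]) continue;
          const double pe = (wt[e] == 1.0) ? r : 1.0 - std::pow(1.0 - r, wt[e]);
          if (unif_rand() < pe) {
            newly[u] = 1; nxt.push_back(u);
            if (!ever[u]) { ever[u] = 1; ++cum; }
          }
        }
      }
      // all nodes infected at round start recover at end of round
      for (int k = 0; k < (int)cur.size(); ++k)
        status[cur[k]] = (model == 1) ? 0 : 2;
      for (int k = 0; k < (int)nxt.size(); ++k) {
        status[nxt[k]] = 1; newly[nxt[k]] = 0;
      }
      cur.swap(nxt);
      if ((int)cur.size() > max_prev) max_prev = cur.size();
      ++rounds;
      if (cum >= half_target) reached = 1;
    }
    res(run, 0) = reached;
    res(run, 1) = rounds;
    res(run, 2) = cum;
    res(run, 3) = rounds;
    res(run, 4) = 0.0;
    res(run, 5) = 0.0;
    res(run, 6) = max_prev;
  }
  return res;
}

// Chung-Lu pair sampler: connect i<j with probability min(1, w_i w_j / denom).
// Returns a 1-based edge matrix.
// [[Rcpp::export(name = ".chung_lu_edges_cpp")]]
IntegerMatrix chung_lu_edges_cpp(NumericVector w, double denom) {
  const int n = w.size();
  std::vector<int> from, to;
  for (int i = 0; i < n - 1; ++i) {
    const double wi = w[i];
    for (int j = i + 1; j < n; ++j) {
      double p = wi * w[j] / denom;
      if (p > 1.0) p = 1.0;
      if (unif_rand() < p) { from.push_back(i + 1); to.push_back(j + 1); }
    }
  }
  IntegerMatrix el(from.size(), 2);
  for (int k = 0; k < (int)from.size(); ++k) { el(k, 0) = from[k]; el(k, 1) = to[k]; }
  return el;
}
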