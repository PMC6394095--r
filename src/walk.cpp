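#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// Closed-form steady-state fitness of the regulator--target unit.
// Operation order deliberately mirrors the vectorized R implementation so
// both routes produce bit-identical doubles.
struct GrnModel {
  double S, a, b, alpha;
  bool kr_prop;       // true: k_r = kr_ratio * k_act; false: k_r = kr_const
  double kr_ratio, kr_const;

  inline double fitness(const double *pv) const {
    const double bas = pv[0], k = pv[1], kd = pv[2],
                 beta = pv[3], Km = pv[4], kdT = pv[5];
    const double kr = kr_prop ? kr_ratio * k : kr_const;
    const double R  = bas * (kr + kd) / (kd * (kr + kd + k * S));
    const double Rs = k * R * S / (kr + kd);
    const double T  = (beta / kdT) * (Rs * Rs) / (Km * Km + Rs * Rs);
    const double B  = a * T / (T + b);
    const double C  = alpha * (T + Rs + R);
    return B - C;
  }
};

struct WalkRecord {
  std::vector<int> genotypes;   // row-major, D per step
  std::vector<double> fitness;
  std::vector<int> mutated;     // NA for step 0

  List as_list(int D) const {
    const int n = (int)fitness.size();
    IntegerMatrix G(n, D);
    for (int i = 0; i < n; ++i)
      for (int p = 0; p < D; ++p) G(i, p) = genotypes[(size_t)i * D + p];
    return List::create(_["genotypes"] = G,
                        _["fitness"] = NumericVector(fitness.begin(), fitness.end()),
                        _["mutated"] = IntegerVector(mutated.begin(), mutated.end()));
  }
};

// Greedy adaptive walk: at each step enumerate all adjacency-respecting
// one-mutant neighbors, collect the strictly beneficial ones, move to one
// chosen uniformly at random (R's RNG), stop when none exists.
template <class FitFun>
List walk_impl(const IntegerVector &start0, const List &adj, int D,
               FitFun &&fit_of, int max_steps) {
  std::vector<const int *> off(D), nbr(D);
  for (int p = 0; p < D; ++p) {
    List ap = adj[p];
    IntegerVector o = ap["offsets"], v = ap["neighbors"];
    off[p] = INTEGER(o);
    nbr[p] = INTEGER(v);
  }

  std::vector<int> cur(start0.begin(), start0.end());
  double fcur = fit_of(cur.data(), -1, 0);

  WalkRecord rec;
  rec.genotypes.assign(cur.begin(), cur.end());
  rec.fitness.push_back(fcur);
  rec.mutated.push_back(NA_INTEGER);

  std::vector<int> bp, bj;
  std::vector<double> bf;
  int steps = 0;
  for (;;) {
    bp.clear(); bj.clear(); bf.clear();
    for (int p = 0; p < D; ++p) {
      for (int e = off[p][cur[p]]; e < off[p][cur[p] + 1]; ++e) {
        const int j = nbr[p][e];
        const double f = fit_of(cur.data(), p, j);
        if (f > fcur) { bp.push_back(p); bj.push_back(j); bf.push_back(f); }
      }
    }
    if (bp.empty()) break;
    int pick = (int)(unif_rand() * (double)bp.size());
    if (pick >= (int)bp.size()) pick = (int)bp.size() - 1;
    cur[bp[pick]] = bj[pick];
    fcur = bf[pick];
    for (int p = 0; p < D; ++p) rec.genotypes.push_back(cur[p]);
    rec.fitness.push_back(fcur);
    rec.mutated.push_back(bp[pick]);
    if (++steps >= max_steps)
      stop("adaptive walk exceeded the step budget (%d); fitness must increase strictly, so this indicates an internal error", max_steps);
  }
  return rec.as_list(D);
}

} // namespace

// [[Rcpp::export]]
List cpp_walk_grn(IntegerVector start0, List adj, NumericMatrix grid,
                  double S, double a, double b, double alpha,
                  bool kr_prop, double kr_ratio, double kr_const,
                  int max_steps) {
  const int D = start0.size();
  if (D != grid.ncol()) stop("genotype and grid dimensions differ");
  GrnModel m{S, a, b, alpha, kr_prop, kr_ratio, kr_const};
  std::vector<double> pv(D);
  auto fit_of = [&](const int *cur, int p_sub, int j_sub) {
    for (int p = 0; p < D; ++p) pv[p] = grid(cur[p], p);
    if (p_sub >= 0) pv[p_sub] = grid(j_sub, p_sub);
    return m.fitness(pv.data());
  };
  return walk_impl(start0, adj, D, fit_of, max_steps);
}

// [[Rcpp::export]]
List cpp_walk_table(IntegerVector start0, List adj, NumericVector fitness,
                    IntegerVector levels, int max_steps) {
  const int D = start0.size();
  if (D != levels.size()) stop("genotype and level dimensions differ");
  std::vector<long long> stride(D);
  long long s = 1;
  for (int p = 0; p < D; ++p) { stride[p] = s; s *= levels[p]; }
  if (s != (long long)fitness.size()) stop("fitness table size does not match levels");
  const double *F = REAL(fitness);
  auto fit_of = [&](const int *cur, int p_sub, int j_sub) {
    long long code = 0;
    for (int p = 0; p < D; ++p) code += (long long)cur[p] * stride[p];
    if (p_sub >= 0) code += (long long)(j_sub - cur[p_sub]) * stride[p_sub];
    return F[code];
  };
  return walk_impl(start0, adj, D, fit_of, max_steps);
}

// Fitness of many genotypes at once (0-based level indices); used for
// cross-checking the C++ route against the R closed form.
// [[Rcpp::export]]
NumericVector cpp_grn_fitness(IntegerMatrix idx0, NumericMatrix grid,
                              double S, double a, double b, double alpha,
                              bool kr_prop, double kr_ratio, double kr_const) {
  const int n = idx0.nrow(), D = idx0.ncol();
  if (D != grid.ncol()) stop("genotype and grid dimensions differ");
  GrnModel m{S, a, b, alpha, kr_prop, kr_ratio, kr_const};
  NumericVector out(n);
  std::vector<double> pv(D);
  for (int i = 0; i < n; ++i) {
    for (int p = 0; p < D; ++p) pv[p] = grid(idx0(i, p), p);
    out[i] = m.fitness(pv.data());
  }
  return out;
}
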