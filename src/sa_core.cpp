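// Metropolis simulated-annealing core for the DFM matrix-alignment search.
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
// Alignment state: 0-based strictly increasing index vectors a (into Fa)
// and b (into Fb); a move inserts or removes exactly one match column.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct PmsParams {
  double sp, sm, lam, x0;
  int relMethod;  // 0 = mean-normalized, 1 = max-normalized
};

inline double relDiff(double a, double b, int method) {
  if (a == 0.0 && b == 0.0) return 0.0;
  const double denom = (method == 0) ? 0.5 * (a + b) : std::max(a, b);
  if (denom <= 0.0) return 0.0;
  return std::fabs(a - b) / denom;
}

inline double pmsVal(double a, double b, const PmsParams& p) {
  const double d = relDiff(a, b, p.relMethod);
  return p.sm + (p.sp - p.sm) / (1.0 + std::exp(p.lam * (d - p.x0)));
}

// SMS of column (x, y) against all columns of (a, b), skipping index `skip`.
double colSMS(const NumericMatrix& Fa, const NumericMatrix& Fb,
              const std::vector<int>& a, const std::vector<int>& b,
              int x, int y, int skip, const PmsParams& p) {
  double s = 0.0;
  const int k = (int)a.size();
  // DFMs are symmetric: read down columns x and y (contiguous memory)
  const double* fx = &Fa(0, x);
  const double* fy = &Fb(0, y);
  for (int j = 0; j < k; ++j) {
    if (j == skip) continue;
    s += pmsVal(fx[a[j]], fy[b[j]], p);
  }
  return s;
}

double fullScore(const NumericMatrix& Fa, const NumericMatrix& Fb,
                 const std::vector<int>& a, const std::vector<int>& b,
                 const PmsParams& p) {
  double s = 0.0;
  const int k = (int)a.size();
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j)
      s += pmsVal(Fa(a[i], a[j]), Fb(b[i], b[j]), p);
  return s;
}

struct Move {
  bool insert;
  int pos;   // removal: column index; insertion: slot where column goes
  int x, y;  // inserted residue indices (0-based), insertion only
  double delta;
  bool feasible;
};

// Sample one neighbour uniformly within the chosen move type. Insertions
// are sampled uniformly over all feasible cells by weighting the k+1
// inter-column segments by their (free-in-A x free-in-B) cell counts.
Move proposeMove(const NumericMatrix& Fa, const NumericMatrix& Fb,
                 const std::vector<int>& a, const std::vector<int>& b,
                 const PmsParams& p) {
  Move mv; mv.feasible = false;
  const int na = Fa.nrow(), nb = Fb.nrow();
  const int k = (int)a.size();

  // per-segment free-cell counts
  std::vector<double> cnt(k + 1);
  double nIns = 0.0;
  for (int s = 0; s <= k; ++s) {
    const int loA = (s == 0) ? -1 : a[s - 1];
    const int hiA = (s == k) ? na : a[s];
    const int loB = (s == 0) ? -1 : b[s - 1];
    const int hiB = (s == k) ? nb : b[s];
    const double gA = hiA - loA - 1, gB = hiB - loB - 1;
    cnt[s] = (gA > 0 && gB > 0) ? gA * gB : 0.0;
    nIns += cnt[s];
  }
  const bool canRemove = k > 0, canInsert = nIns > 0;
  if (!canRemove && !canInsert) return mv;

  bool doInsert;
  if (canRemove && canInsert) doInsert = unif_rand() < 0.5;
  else doInsert = canInsert;

  if (doInsert) {
    double r = unif_rand() * nIns;
    int s = 0;
    while (s < k && r >= cnt[s]) { r -= cnt[s]; ++s; }
    const int loA = (s == 0) ? -1 : a[s - 1];
    const int loB = (s == 0) ? -1 : b[s - 1];
    const int hiB = (s == k) ? nb : b[s];
    const int gB = hiB - loB - 1;
    const int off = (int)r;  // 0 .. cnt[s]-1
    mv.insert = true;
    mv.pos = s;
    mv.x = loA + 1 + off / gB;
    mv.y = loB + 1 + off % gB;
    mv.delta = colSMS(Fa, Fb, a, b, mv.x, mv.y, -1, p);
  } else {
    const int i = std::min(k - 1, (int)(unif_rand() * k));
    mv.insert = false;
    mv.pos = i;
    mv.x = a[i]; mv.y = b[i];
    mv.delta = -colSMS(Fa, Fb, a, b, a[i], b[i], i, p);
  }
  mv.feasible = true;
  return mv;
}

void applyMove(std::vector<int>& a, std::vector<int>& b, const Move& mv) {
  if (mv.insert) {
    a.insert(a.begin() + mv.pos, mv.x);
    b.insert(b.begin() + mv.pos, mv.y);
  } else {
    a.erase(a.begin() + mv.pos);
    b.erase(b.begin() + mv.pos);
  }
}

PmsParams makeParams(double sPlus, double sMinus, double lambda, double x0,
                     int relMethod) {
  PmsParams p;
  p.sp = sPlus; p.sm = sMinus; p.lam = lambda; p.x0 = x0;
  p.relMethod = relMethod;
  return p;
}

}  // namespace

// Pilot random walk: propose and ALWAYS accept nSteps moves, recording the
// score change of each. Used for Johnson-style initial-temperature
// calibration from the mean magnitude of downhill moves.
// [[Rcpp::export]]
NumericVector cpp_pilot_deltas(NumericMatrix Fa, NumericMatrix Fb,
                               IntegerVector a0, IntegerVector b0,
                               int nSteps, double sPlus, double sMinus,
                               double lambda, double x0, int relMethod) {
  PmsParams p = makeParams(sPlus, sMinus, lambda, x0, relMethod);
  std::vector<int> a(a0.begin(), a0.end()), b(b0.begin(), b0.end());
  NumericVector out(nSteps, NA_REAL);
  for (int t = 0; t < nSteps; ++t) {
    Move mv = proposeMove(Fa, Fb, a, b, p);
    if (!mv.feasible) break;
    out[t] = mv.delta;
    applyMove(a, b, mv);
  }
  return out;
}

// One annealing restart. Returns the best-ever alignment (0-based indices)
// with its exactly recomputed score, plus an optional per-plateau trace.
// [[Rcpp::export]]
List cpp_sa_chain(NumericMatrix Fa, NumericMatrix Fb,
                  IntegerVector a0, IntegerVector b0,
                  double sPlus, double sMinus, double lambda, double x0,
                  int relMethod, double T0, int plateauAccepts,
                  double cooling, double stopAcceptance, int stallPlateaus,
                  double maxProposals, bool keepTrace) {
  PmsParams p = makeParams(sPlus, sMinus, lambda, x0, relMethod);
  std::vector<int> a(a0.begin(), a0.end()), b(b0.begin(), b0.end());

  double S = fullScore(Fa, Fb, a, b, p);
  std::vector<int> bestA = a, bestB = b;
  double bestS = S;

  double T = T0;
  long accepted = 0, proposed = 0, totalProposed = 0;
  int plateausSinceImprove = 0;
  const double capRatio = (stopAcceptance > 0.0)
      ? (double)plateauAccepts / stopAcceptance
      : 100.0 * plateauAccepts;
  std::vector<double> trT, trS, trAcc;

  while (totalProposed < (long)maxProposals) {
    Move mv = proposeMove(Fa, Fb, a, b, p);
    if (!mv.feasible) break;  // both proteins exhausted (cannot happen n>=1)
    ++proposed; ++totalProposed;
    bool accept = mv.delta >= 0.0 ||
                  unif_rand() < std::exp(mv.delta / T);
    if (accept) {
      applyMove(a, b, mv);
      S += mv.delta;
      ++accepted;
      if (S > bestS + 1e-12) {
        bestS = S; bestA = a; bestB = b;
        plateausSinceImprove = -1;  // reset at the end of this plateau
      }
    }
    if (accepted >= plateauAccepts || proposed >= (long)capRatio) {
      const double ratio = (double)accepted / (double)proposed;
      if (keepTrace) {
        trT.push_back(T); trS.push_back(S); trAcc.push_back(ratio);
      }
      // terminate on a frozen chain, or when the incumbent has stalled
      // (zero-delta shuffle moves can keep the raw acceptance ratio high
      // at small alignments even though the search is finished)
      if (ratio < stopAcceptance) break;
      if (++plateausSinceImprove >= stallPlateaus) break;
      T *= cooling;
      accepted = 0; proposed = 0;
    }
  }

  const double bestExact = fullScore(Fa, Fb, bestA, bestB, p);
  List out = List::create(
      _["a"] = IntegerVector(bestA.begin(), bestA.end()),
      _["b"] = IntegerVector(bestB.begin(), bestB.end()),
      _["score"] = bestExact,
      _["score_incremental"] = bestS,
      _["n_proposed"] = (double)totalProposed);
  if (keepTrace)
    out["trace"] = DataFrame::create(_["temperature"] = trT,
                                     _["score"] = trS,
                                     _["acceptance"] = trAcc);
  return out;
}
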