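// Dynamic-programming alignment of one sequence to the profile HMM.
//
// State graph per the phase-2 architecture: N flank -> (M_j | D_j) chain
// over the w model columns with insert states I_j between columns
// (I reachable only from M; I->D and D->I are structurally forbidden),
// then C flank.  Every model column is consumed by M or D; flank and
// insert residues emit at background (log-odds 0), flank residues pay the
// fixed flank self-transition log-probability per residue.
//
// The delete chain is split into D0 (no match emitted yet) and Dm (some
// match emitted): a path that deletes the whole model has an ambiguous
// N/C flank split, so its exit is restricted to the canonical
// all-residues-in-N representative; this keeps the path <-> assignment
// map one-to-one so stochastic traceback samples assignments exactly.
//
// temperature == 0: Viterbi with deterministic tie-breaking (prefer M
// over D over I, earliest exit).  temperature > 0: all arc log-scores
// are divided by T (global tempering: samples exactly from
// p_path^{1/T}) and stochastic traceback over the forward log-sums uses
// R's RNG (reproducible under set.seed).
#include <Rcpp.h>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// sample index 0..(k-1) proportional to exp(logw) using R RNG
static int sample_log(const std::vector<double>& logw) {
  double m = R_NegInf;
  for (double v : logw) if (v > m) m = v;
  if (m == R_NegInf) return 0;
  double tot = 0.0;
  std::vector<double> w(logw.size());
  for (size_t i = 0; i < logw.size(); ++i) {
    w[i] = std::exp(logw[i] - m);
    tot += w[i];
  }
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t i = 0; i < logw.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)logw.size() - 1;
}

// res: residue codes 1..20 (NA allowed); elo: 20 x w log(theta/theta0);
// ltr: 7 x (w+1) log transition matrix, rows mm,mi,md,im,ii,dm,dd;
// lflank: log flank self-probability; temperature: 0 = Viterbi.
// [[Rcpp::export(name = ".dp_align_cpp")]]
IntegerVector dp_align_cpp(IntegerVector res, NumericMatrix elo,
                           NumericMatrix ltr, double lflank,
                           double temperature) {
  const int n = res.size();
  const int w = elo.ncol();
  const bool greedy = (temperature <= 0.0);
  const double invT = greedy ? 1.0 : 1.0 / temperature;

  std::vector<double> tmm(w + 1), tmi(w + 1), tmd(w + 1), tim(w + 1),
      tii(w + 1), tdm(w + 1), tdd(w + 1);
  for (int j = 0; j <= w; ++j) {
    tmm[j] = ltr(0, j) * invT; tmi[j] = ltr(1, j) * invT;
    tmd[j] = ltr(2, j) * invT; tim[j] = ltr(3, j) * invT;
    tii[j] = ltr(4, j) * invT; tdm[j] = ltr(5, j) * invT;
    tdd[j] = ltr(6, j) * invT;
  }
  const double fl = lflank * invT;

  auto em = [&](int i, int j) -> double {  // i,j 1-based
    int r = res[i - 1];
    if (r == NA_INTEGER) return 0.0;
    return elo(r - 1, j - 1) * invT;
  };

  const double NEG = R_NegInf;
  std::vector<std::vector<double>> VM(n + 1, std::vector<double>(w + 1, NEG)),
      VI(n + 1, std::vector<double>(w + 1, NEG)),
      VDm(n + 1, std::vector<double>(w + 1, NEG)),
      VD0(n + 1, std::vector<double>(w + 1, NEG));

  auto comb = [&](double a, double b) {
    return greedy ? std::max(a, b) : lse2(a, b);
  };

  for (int i = 0; i <= n; ++i) {
    for (int j = 1; j <= w; ++j) {
      if (j == 1) {
        VD0[i][1] = i * fl + tmd[0];
      } else {
        VD0[i][j] = VD0[i][j - 1] + tdd[j - 1];
        VDm[i][j] = comb(VM[i][j - 1] + tmd[j - 1],
                         VDm[i][j - 1] + tdd[j - 1]);
      }
      if (i >= 1) {
        if (j == 1) {
          VM[i][1] = em(i, 1) + (i - 1) * fl + tmm[0];
        } else {
          double v = comb(VM[i - 1][j - 1] + tmm[j - 1],
                          comb(VDm[i - 1][j - 1] + tdm[j - 1],
                               VD0[i - 1][j - 1] + tdm[j - 1]));
          v = comb(v, VI[i - 1][j - 1] + tim[j - 1]);
          VM[i][j] = em(i, j) + v;
        }
        if (j <= w - 1) {
          VI[i][j] = comb(VM[i - 1][j] + tmi[j], VI[i - 1][j] + tii[j]);
        }
      }
    }
  }

  // end: exit from M_w or Dm_w at any i (rest = C flank); the pure-delete
  // path (D0) exits only with all residues in the N flank (i = n)
  int best_i = 0, best_s = 1;  // s: 0=M, 1=Dm, 3=D0
  if (greedy) {
    double best = NEG;
    for (int i = 0; i <= n; ++i) {
      if (i >= 1 && w >= 1) {
        double vm = VM[i][w] + tmm[w] + (n - i) * fl;
        if (vm > best) { best = vm; best_i = i; best_s = 0; }
      }
      double vd = VDm[i][w] + tdm[w] + (n - i) * fl;
      if (vd > best) { best = vd; best_i = i; best_s = 1; }
    }
    double v0 = VD0[n][w] + tdm[w];
    if (v0 > best) { best = v0; best_i = n; best_s = 3; }
  } else {
    std::vector<double> cand;
    std::vector<std::pair<int, int>> lab;
    for (int i = 0; i <= n; ++i) {
      if (i >= 1 && w >= 1) {
        cand.push_back(VM[i][w] + tmm[w] + (n - i) * fl);
        lab.push_back({i, 0});
      }
      cand.push_back(VDm[i][w] + tdm[w] + (n - i) * fl);
      lab.push_back({i, 1});
    }
    cand.push_back(VD0[n][w] + tdm[w]);
    lab.push_back({n, 3});
    int pick = sample_log(cand);
    best_i = lab[pick].first; best_s = lab[pick].second;
  }

  IntegerVector assign(n, 0);
  if (best_s == 3) return assign;  // pure-delete path: nothing aligned

  int i = best_i, j = w, s = best_s;  // s: 0=M, 1=Dm, 2=I
  while (j >= 1) {
    if (s == 0) {               // at M_j emitting residue i
      assign[i - 1] = j;
      if (j == 1) break;
      double cm = VM[i - 1][j - 1] + tmm[j - 1];
      double cd = VDm[i - 1][j - 1] + tdm[j - 1];
      double c0 = VD0[i - 1][j - 1] + tdm[j - 1];
      double ci = VI[i - 1][j - 1] + tim[j - 1];
      int pick;
      if (greedy) {
        pick = 0; double b = cm;
        if (cd > b) { b = cd; pick = 1; }
        if (c0 > b) { b = c0; pick = 3; }
        if (ci > b) { b = ci; pick = 2; }
      } else {
        pick = sample_log({cm, cd, c0, ci});
        if (pick == 2) pick = 3;       // order in vector: cm, cd, c0, ci
        else if (pick == 3) pick = 2;
      }
      i -= 1; j -= 1;
      if (pick == 3) break;            // rest of model is the pure-D0 chain
      s = pick;
    } else if (s == 1) {        // at Dm_j
      // j == 1 cannot be Dm (no match before column 1)
      double cm = VM[i][j - 1] + tmd[j - 1];
      double cd = VDm[i][j - 1] + tdd[j - 1];
      int pick;
      if (greedy) pick = (cd > cm) ? 1 : 0;
      else pick = sample_log({cm, cd});
      j -= 1; s = pick;
    } else {                    // at I_j emitting residue i
      double cm = VM[i - 1][j] + tmi[j];
      double ci = VI[i - 1][j] + tii[j];
      int pick;
      if (greedy) pick = (ci > cm) ? 1 : 0;
      else pick = sample_log({cm, ci});
      i -= 1;
      s = (pick == 0) ? 0 : 2;
    }
  }
  return assign;
}
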