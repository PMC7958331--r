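#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex minimum-free-energy dynamic program.
//
// mir and tgt are integer-encoded RNA (A=0, C=1, G=2, U=3), both 5'->3'.
// The target is reversed internally so that pairing is antiparallel:
// mir position i pairs reversed-target position j, and paired positions
// are strictly increasing in both indices.  Only intermolecular pairs are
// considered; dangling (unpaired) ends cost nothing.
//
// Energy of a duplex = sum of pair energies + loop penalties between
// consecutive pairs: a gap of (a, b) unpaired bases on the two strands
// scores 0 if a==b==0 (stack), bulge_open + bulge_ext*(len-1) if exactly
// one side is unpaired, and il_open + il_ext*(a+b-2) if both are.
// Gaps longer than max_bulge on either side are disallowed.

static inline double pair_energy(int x, int y, double gc, double au, double gu) {
  // x, y: 0=A 1=C 2=G 3=U
  if ((x == 2 && y == 1) || (x == 1 && y == 2)) return gc;
  if ((x == 0 && y == 3) || (x == 3 && y == 0)) return au;
  if ((x == 2 && y == 3) || (x == 3 && y == 2)) return gu;
  return 1.0; // sentinel: not a pair
}

// [[Rcpp::export]]
List hybrid_dp_cpp(IntegerVector mir, IntegerVector tgt,
                   double e_gc, double e_au, double e_gu,
                   double bulge_open, double bulge_ext,
                   double il_open, double il_ext, int max_bulge) {
  const int m = mir.size();
  const int n = tgt.size();
  // reversed target
  std::vector<int> u(n);
  for (int j = 0; j < n; ++j) u[j] = tgt[n - 1 - j];

  const double INF = 1e18;
  // E[i][j]: best energy of a duplex whose last pair is (i, j), 0-based
  std::vector<std::vector<double> > E(m, std::vector<double>(n, INF));
  std::vector<std::vector<int> > Pi(m, std::vector<int>(n, -1));
  std::vector<std::vector<int> > Pj(m, std::vector<int>(n, -1));

  double best = 0.0; // empty duplex allowed at energy 0
  int bi = -1, bj = -1;

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double pe = pair_energy(mir[i], u[j], e_gc, e_au, e_gu);
      if (pe > 0) continue; // not pairable
      double acc = 0.0; // open a new duplex here
      int pi = -1, pj = -1;
      int amax = std::min(i, max_bulge + 1);
      for (int a = 0; a <= amax - 0 && a <= max_bulge; ++a) {
        int ii = i - 1 - a;
        if (ii < 0) break;
        for (int b = 0; b <= max_bulge; ++b) {
          int jj = j - 1 - b;
          if (jj < 0) break;
          if (E[ii][jj] >= INF) continue;
          double gap;
          if (a == 0 && b == 0) gap = 0.0;
          else if (a == 0) gap = bulge_open + bulge_ext * (b - 1);
          else if (b == 0) gap = bulge_open + bulge_ext * (a - 1);
          else gap = il_open + il_ext * (a + b - 2);
          double cand = E[ii][jj] + gap;
          if (cand < acc) { acc = cand; pi = ii; pj = jj; }
        }
      }
      E[i][j] = pe + acc;
      Pi[i][j] = pi;
      Pj[i][j] = pj;
      if (E[i][j] < best) { best = E[i][j]; bi = i; bj = j; }
    }
  }

  std::vector<int> mir_pos, tgt_pos;
  int ci = bi, cj = bj;
  while (ci >= 0 && cj >= 0) {
    mir_pos.push_back(ci + 1);              // 1-based mir position
    tgt_pos.push_back(n - cj);              // back to forward target coords
    int ni = Pi[ci][cj], nj = Pj[ci][cj];
    ci = ni; cj = nj;
  }
  std::reverse(mir_pos.begin(), mir_pos.end());
  std::reverse(tgt_pos.begin(), tgt_pos.end());

  return List::create(_["mfe"] = best,
                      _["mir_pos"] = wrap(mir_pos),
                      _["target_pos"] = wrap(tgt_pos));
}
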