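#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive CHNOSP formula enumeration for a vector of neutral masses.
// For every combination of N, S, P, O, C within bounds the hydrogen count is
// solved from the mass remainder; a candidate is kept when its theoretical
// mass lies within tol_ppm of the query and it passes the validity screens
// (H/C and O/C windows, integer nonnegative DBE -- which for CHNOSP formulas
// is equivalent to the nitrogen parity rule).
//
// Masses must match the R-side element mass table exactly, so they are
// passed in rather than duplicated here.

// [[Rcpp::export]]
DataFrame enumerate_candidates_cpp(NumericVector masses,
                                   double tol_ppm,
                                   NumericVector element_mass,
                                   IntegerVector lo,
                                   IntegerVector hi,
                                   double hc_min,
                                   double hc_max,
                                   double oc_max) {
  const double mC = element_mass[0], mH = element_mass[1], mN = element_mass[2],
               mO = element_mass[3], mS = element_mass[4], mP = element_mass[5];
  std::vector<int> r_idx, r_c, r_h, r_n, r_o, r_s, r_p;
  std::vector<double> r_ppm;

  for (int i = 0; i < masses.size(); ++i) {
    const double M = masses[i];
    const double tol_da = M * tol_ppm * 1e-6;
    for (int n = lo[2]; n <= hi[2]; ++n) {
      const double bn = n * mN;
      if (bn + lo[0] * mC > M + tol_da) break;
      for (int s = lo[4]; s <= hi[4]; ++s) {
        const double bs = bn + s * mS;
        if (bs + lo[0] * mC > M + tol_da) break;
        for (int p = lo[5]; p <= hi[5]; ++p) {
          const double bp = bs + p * mP;
          if (bp + lo[0] * mC > M + tol_da) break;
          for (int o = lo[3]; o <= hi[3]; ++o) {
            const double bo = bp + o * mO;
            if (bo + lo[0] * mC > M + tol_da) break;
            for (int c = std::max(lo[0], 1); c <= hi[0]; ++c) {
              const double base = bo + c * mC;
              if (base > M + tol_da) break;
              const double rem = M - base;
              const int h = (int)std::lround(rem / mH);
              if (h < lo[1] || h > hi[1]) continue;
              const double theo = base + h * mH;
              const double ppm = (M - theo) / theo * 1e6;
              if (std::fabs(ppm) > tol_ppm) continue;
              const double hc = (double)h / c;
              if (hc < hc_min || hc > hc_max) continue;
              if ((double)o / c > oc_max) continue;
              // integer DBE >= 0 (equivalently the nitrogen rule)
              if ((h + n + p) % 2 != 0) continue;
              const double dbe = 1.0 + c - h / 2.0 + (n + p) / 2.0;
              if (dbe < 0) continue;
              r_idx.push_back(i + 1);
              r_c.push_back(c); r_h.push_back(h); r_n.push_back(n);
              r_o.push_back(o); r_s.push_back(s); r_p.push_back(p);
              r_ppm.push_back(ppm);
            }
          }
        }
      }
    }
  }
  return DataFrame::create(_["idx"] = r_idx,
                           _["c"] = r_c, _["h"] = r_h, _["n"] = r_n,
                           _["o"] = r_o, _["s"] = r_s, _["p"] = r_p,
                           _["ppm"] = r_ppm);
}
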