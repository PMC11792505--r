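#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance for one site pair:
//   0.5 * [ sum_i f_k[i] * min_j D(i in k, j in m)  +  sum_i f_m[i] * min_j D(i in m, j in k) ]
// idx_k / idx_m are 1-based positions (columns of the community matrix) of the
// taxa with positive abundance in each site; f_k / f_m the matching relative
// abundances. lab maps matrix position -> cophenetic row (1-based); the
// identity gives the observed value, a permutation gives one null value.

static double bmntd_one(const NumericMatrix& D,
                        const std::vector<int>& lk, const NumericVector& f_k,
                        const std::vector<int>& lm, const NumericVector& f_m) {
  const int nk = lk.size(), nm = lm.size();
  double s1 = 0.0, s2 = 0.0;
  for (int a = 0; a < nk; ++a) {
    double mn = R_PosInf;
    const int la = lk[a];
    for (int b = 0; b < nm; ++b) {
      const double d = D(la, lm[b]);
      if (d < mn) mn = d;
    }
    s1 += f_k[a] * mn;
  }
  for (int b = 0; b < nm; ++b) {
    double mn = R_PosInf;
    const int lb = lm[b];
    for (int a = 0; a < nk; ++a) {
      const double d = D(lb, lk[a]);
      if (d < mn) mn = d;
    }
    s2 += f_m[b] * mn;
  }
  return 0.5 * (s1 + s2);
}

// [[Rcpp::export]]
double beta_mntd_obs_kernel(const NumericMatrix& D,
                            const IntegerVector& idx_k, const NumericVector& f_k,
                            const IntegerVector& idx_m, const NumericVector& f_m) {
  std::vector<int> lk(idx_k.size()), lm(idx_m.size());
  for (int a = 0; a < idx_k.size(); ++a) lk[a] = idx_k[a] - 1;
  for (int b = 0; b < idx_m.size(); ++b) lm[b] = idx_m[b] - 1;
  return bmntd_one(D, lk, f_k, lm, f_m);
}

// Null distribution under tip-label permutations: perms is n_reps x n_taxa
// (1-based), row r relabelling position t as perms(r, t).
// [[Rcpp::export]]
NumericVector beta_mntd_null_kernel(const NumericMatrix& D, const IntegerMatrix& perms,
                                    const IntegerVector& idx_k, const NumericVector& f_k,
                                    const IntegerVector& idx_m, const NumericVector& f_m) {
  const int R = perms.nrow();
  const int nk = idx_k.size(), nm = idx_m.size();
  NumericVector out(R);
  std::vector<int> lk(nk), lm(nm);
  for (int r = 0; r < R; ++r) {
    for (int a = 0; a < nk; ++a) lk[a] = perms(r, idx_k[a] - 1) - 1;
    for (int b = 0; b < nm; ++b) lm[b] = perms(r, idx_m[b] - 1) - 1;
    out[r] = bmntd_one(D, lk, f_k, lm, f_m);
  }
  return out;
}
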