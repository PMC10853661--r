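// One chain of the conditional-model Gibbs sampler.  The conditional model
// fixes the per-individual log-likelihood tables at the start of the run,
// so each table row can be exponentiated once (relative to its row maximum,
// which keeps everything in [0, 1] regardless of how many loci contribute)
// and the sweep reduces to categorical membership draws from p_k * E[m, k]
// plus Dirichlet proportion draws.  This is the hot loop behind
// run_msgsi()/run_single_gsi().  All randomness comes from R's RNG
// (GetRNGstate/PutRNGstate), so set.seed() upstream makes chains
// reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// likelihood table exp(logL - rowmax), transposed to K x M so that one
// fish's weights are contiguous
static std::vector<double> normalized_table(const NumericMatrix& logL) {
  const int M = logL.nrow(), K = logL.ncol();
  std::vector<double> E((size_t)M * K);
  for (int m = 0; m < M; ++m) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) if (logL(m, k) > mx) mx = logL(m, k);
    for (int k = 0; k < K; ++k) {
      double v = logL(m, k);
      E[(size_t)m * K + k] = (v == R_NegInf) ? 0.0 : std::exp(v - mx);
    }
  }
  return E;
}

// categorical draw with probability proportional to p[k] * e[k]
static inline int draw_member(const double* e, const double* p, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += p[k] * e[k];
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += p[k] * e[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

static inline void dirichlet_draw(const double* shape, int K, double* out) {
  double s = 0.0;
  int kmax = 0;
  for (int k = 0; k < K; ++k) {
    out[k] = R::rgamma(shape[k], 1.0);
    s += out[k];
    if (shape[k] > shape[kmax]) kmax = k;
  }
  if (s <= 0.0) { out[kmax] = 1.0; s = 1.0; }
  for (int k = 0; k < K; ++k) out[k] /= s;
}

// [[Rcpp::export(name = ".gibbs_chain_cond")]]
List gibbs_chain_cond(NumericMatrix logL_broad, List logL_reg, List br_idx,
                      NumericVector alpha, List alpha_reg,
                      int n_iter, int n_burn, int thin, bool record_z) {
  const int M = logL_broad.nrow(), B = logL_broad.ncol();
  const int R_n = logL_reg.size();
  const int n_keep = (n_iter - n_burn) / thin;

  std::vector<double> Eb = normalized_table(logL_broad);
  std::vector<std::vector<double>> Er(R_n);
  std::vector<NumericVector> ar(R_n);
  std::vector<std::vector<bool>> in_region(R_n, std::vector<bool>(B, false));
  std::vector<int> Kr(R_n);
  for (int r = 0; r < R_n; ++r) {
    NumericMatrix L = as<NumericMatrix>(logL_reg[r]);
    Er[r] = normalized_table(L);
    Kr[r] = L.ncol();
    ar[r] = as<NumericVector>(alpha_reg[r]);
    IntegerVector idx = br_idx[r];  // 1-based broad population indices
    for (int i = 0; i < idx.size(); ++i) in_region[r][idx[i] - 1] = true;
  }

  NumericMatrix P(n_keep, B);
  List Preg(R_n);
  for (int r = 0; r < R_n; ++r) Preg[r] = NumericMatrix(n_keep, Kr[r]);
  IntegerMatrix z_hits(M, B);
  IntegerMatrix zrec = record_z ? IntegerMatrix(n_keep, M) : IntegerMatrix(0, 0);

  int Kmax = B;
  for (int r = 0; r < R_n; ++r) Kmax = std::max(Kmax, Kr[r]);
  std::vector<double> w(Kmax), p(B);
  std::vector<std::vector<double>> p_r(R_n);
  std::vector<int> z(M);
  std::vector<std::vector<int>> zr(R_n, std::vector<int>(M, -1));
  std::vector<int> cnt(Kmax);

  GetRNGstate();
  // initial values from the priors
  dirichlet_draw(REAL(alpha), B, p.data());
  for (int r = 0; r < R_n; ++r) {
    p_r[r].resize(Kr[r]);
    dirichlet_draw(REAL(ar[r]), Kr[r], p_r[r].data());
  }

  int keep = 0;
  for (int t = 1; t <= n_iter; ++t) {
    // broad-scale memberships
    for (int m = 0; m < M; ++m) {
      z[m] = draw_member(&Eb[(size_t)m * B], p.data(), B);
    }
    // regional memberships for currently eligible fish
    for (int r = 0; r < R_n; ++r) {
      for (int m = 0; m < M; ++m) {
        zr[r][m] = in_region[r][z[m]]
          ? draw_member(&Er[r][(size_t)m * Kr[r]], p_r[r].data(), Kr[r])
          : -1;
      }
    }
    // proportion updates from their Dirichlet full conditionals
    std::fill(cnt.begin(), cnt.begin() + B, 0);
    for (int m = 0; m < M; ++m) ++cnt[z[m]];
    for (int b = 0; b < B; ++b) w[b] = cnt[b] + alpha[b];
    dirichlet_draw(w.data(), B, p.data());
    for (int r = 0; r < R_n; ++r) {
      std::fill(cnt.begin(), cnt.begin() + Kr[r], 0);
      for (int m = 0; m < M; ++m) if (zr[r][m] >= 0) ++cnt[zr[r][m]];
      for (int k = 0; k < Kr[r]; ++k) w[k] = cnt[k] + ar[r][k];
      dirichlet_draw(w.data(), Kr[r], p_r[r].data());
    }

    if (t > n_burn && (t - n_burn) % thin == 0) {
      for (int b = 0; b < B; ++b) P(keep, b) = p[b];
      for (int r = 0; r < R_n; ++r) {
        NumericMatrix Pr = Preg[r];
        for (int k = 0; k < Kr[r]; ++k) Pr(keep, k) = p_r[r][k];
      }
      for (int m = 0; m < M; ++m) ++z_hits(m, z[m]);
      if (record_z) for (int m = 0; m < M; ++m) zrec(keep, m) = z[m] + 1;
      ++keep;
    }
  }
  PutRNGstate();

  return List::create(_["p"] = P, _["p_reg"] = Preg, _["z_hits"] = z_hits,
                      _["memberships"] = record_z ? (SEXP)zrec : R_NilValue);
}
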