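// Scaled HMM recursions for the Markov-modulated SMC'.
// States are category-major: state = l * t + j (0-based here).
// A_c = Q * diag(em[, c]) is the one-step update for symbol c; the
// run-length path advances whole runs at once via cached binary powers
// of A_c, each power matrix stored normalised with a log scale factor.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::vector<double> vec;

// out = v %*% M with raw pointers, M column-major n x n
inline void vmatmul_off(const double *v, const double *M, double *out, int n) {
  for (int j = 0; j < n; ++j) {
    const double *col = M + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += v[i] * col[i];
    out[j] = s;
  }
}

// v_out = v_in %*% M (row vector times matrix), M column-major n x n
inline void vmatmul(const vec &v, const double *M, vec &out, int n) {
  for (int j = 0; j < n; ++j) {
    const double *col = M + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += v[i] * col[i];
    out[j] = s;
  }
}

// M_out = A %*% B, all column-major n x n
inline void matmul(const double *A, const double *B, double *C, int n) {
  for (int j = 0; j < n; ++j) {
    const double *bcol = B + (size_t)j * n;
    double *ccol = C + (size_t)j * n;
    for (int i = 0; i < n; ++i) ccol[i] = 0.0;
    for (int kk = 0; kk < n; ++kk) {
      double b = bcol[kk];
      if (b == 0.0) continue;
      const double *acol = A + (size_t)kk * n;
      for (int i = 0; i < n; ++i) ccol[i] += acol[i] * b;
    }
  }
}

inline double normalise(vec &v) {
  double s = 0.0;
  for (double x : v) s += x;
  if (s <= 0.0 || !std::isfinite(s)) return -1.0;
  double inv = 1.0 / s;
  for (double &x : v) x *= inv;
  return s;
}

struct SymbolPowers {
  // powers[b] = normalised A^(2^b), logscale[b] its log factor (cumulative
  // for a single application)
  std::vector<std::vector<double>> powers;
  std::vector<double> logscale;
};

// build A_c (column-major) from Q (n x n, column-major from R) and em col c
std::vector<double> build_A(const NumericMatrix &Q, const NumericMatrix &em,
                            int c, int n) {
  std::vector<double> A((size_t)n * n);
  for (int j = 0; j < n; ++j) {
    double e = em(j, c);
    for (int i = 0; i < n; ++i) A[(size_t)j * n + i] = Q(i, j) * e;
  }
  return A;
}

SymbolPowers build_powers(const std::vector<double> &A, int n, int levels) {
  SymbolPowers sp;
  sp.powers.resize(levels + 1);
  sp.logscale.resize(levels + 1);
  sp.powers[0] = A;
  sp.logscale[0] = 0.0;
  std::vector<double> tmp((size_t)n * n);
  for (int b = 1; b <= levels; ++b) {
    matmul(sp.powers[b - 1].data(), sp.powers[b - 1].data(), tmp.data(), n);
    double mx = 0.0;
    for (double x : tmp) if (x > mx) mx = x;
    if (mx <= 0.0) mx = 1.0;
    double inv = 1.0 / mx;
    sp.powers[b] = tmp;
    for (double &x : sp.powers[b]) x *= inv;
    sp.logscale[b] = 2.0 * sp.logscale[b - 1] + std::log(mx);
  }
  return sp;
}

// advance v by A^m using cached powers; returns accumulated log scale or NaN
double advance_power(vec &v, const SymbolPowers &sp, long m, int n) {
  double lg = 0.0;
  vec tmp(n);
  int b = 0;
  while (m > 0) {
    if (m & 1L) {
      vmatmul(v, sp.powers[b].data(), tmp, n);
      v.swap(tmp);
      lg += sp.logscale[b];
      double s = normalise(v);
      if (s < 0.0) return NA_REAL;
      lg += std::log(s);
    }
    m >>= 1;
    ++b;
  }
  return lg;
}

} // namespace

// [[Rcpp::export]]
double rm_forward_cpp(NumericMatrix Q, NumericMatrix em, NumericVector init,
                      IntegerVector codes) {
  int n = Q.nrow();
  int L = codes.size();
  vec f(n), tmp(n);
  std::vector<std::vector<double>> A(3);
  for (int c = 0; c < 3; ++c) A[c] = build_A(Q, em, c, n);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) f[i] = init[i] * em(i, codes[0]);
  double s = normalise(f);
  if (s < 0.0) return R_NegInf;
  ll += std::log(s);
  for (int i = 1; i < L; ++i) {
    vmatmul(f, A[codes[i]].data(), tmp, n);
    f.swap(tmp);
    s = normalise(f);
    if (s < 0.0) return R_NegInf;
    ll += std::log(s);
  }
  return ll;
}

// [[Rcpp::export]]
double rm_forward_runs_cpp(NumericMatrix Q, NumericMatrix em,
                           NumericVector init, IntegerVector run_symbol,
                           IntegerVector run_length,
                           IntegerVector contig_runs) {
  int n = Q.nrow();
  long maxrun = 1;
  for (int r = 0; r < run_length.size(); ++r)
    if (run_length[r] > maxrun) maxrun = run_length[r];
  int levels = 0;
  while ((1L << levels) < maxrun) ++levels;
  std::vector<SymbolPowers> sp(3);
  for (int c = 0; c < 3; ++c)
    sp[c] = build_powers(build_A(Q, em, c, n), n, levels);

  double ll = 0.0;
  int r0 = 0;
  vec f(n);
  for (int ci = 0; ci < contig_runs.size(); ++ci) {
    int nr = contig_runs[ci];
    bool first = true;
    for (int r = r0; r < r0 + nr; ++r) {
      int c = run_symbol[r];
      long m = run_length[r];
      if (first) {
        for (int i = 0; i < n; ++i) f[i] = init[i] * em(i, c);
        double s = normalise(f);
        if (s < 0.0) return R_NegInf;
        ll += std::log(s);
        m -= 1;
        first = false;
      }
      if (m > 0) {
        double lg = advance_power(f, sp[c], m, n);
        if (!std::isfinite(lg)) return R_NegInf;
        ll += lg;
      }
    }
    r0 += nr;
  }
  return ll;
}

// Block-structured posterior decoding.  The modulated transition matrix is
// Q[(l,j),(m,j')] = P_lm * Ql[l][j,j'] with P_lm = a + b*1{l==m},
// a = delta/(k-1), b = (1-delta) - a; forward and backward steps therefore
// cost k*t^2 instead of (k*t)^2.
// Ql is passed as a list of k t x t matrices; em is t x 3 (per interval).
// [[Rcpp::export]]
List rm_posterior_cpp(List Ql, double delta, NumericMatrix em,
                      NumericVector init, IntegerVector codes, int t, int k,
                      bool keep_joint) {
  int n = t * k;
  int L = codes.size();
  const int CHUNK = 1024;
  int nchunk = (L + CHUNK - 1) / CHUNK;
  double a = (k > 1) ? delta / (k - 1) : 0.0;
  double bdiag = (1.0 - delta) - a;
  if (k == 1) { a = 0.0; bdiag = 1.0; }

  // per-category matrices, column-major (Qc) and row-major (Qr, = transpose
  // stored column-major) for the two recursion directions
  std::vector<std::vector<double>> Qc(k), Qr(k);
  for (int l = 0; l < k; ++l) {
    NumericMatrix M = Ql[l];
    Qc[l].resize((size_t)t * t);
    Qr[l].resize((size_t)t * t);
    for (int j = 0; j < t; ++j)
      for (int i = 0; i < t; ++i) {
        Qc[l][(size_t)j * t + i] = M(i, j);
        Qr[l][(size_t)i * t + j] = M(i, j);
      }
  }
  // emission per state column c: e[j + l*t] = em(j, c)
  std::vector<vec> estate(3, vec(n));
  for (int c = 0; c < 3; ++c)
    for (int l = 0; l < k; ++l)
      for (int j = 0; j < t; ++j) estate[c][(size_t)l * t + j] = em(j, c);

  vec G(t), g(n), w(t);
  // forward step: f_out[(m,j')] = e[j'] * sum_l P_lm (f_l Q_l)[j']
  auto fwd_step = [&](const vec &f, vec &out, int c) {
    std::fill(G.begin(), G.end(), 0.0);
    for (int l = 0; l < k; ++l) {
      vmatmul_off(f.data() + (size_t)l * t, Qc[l].data(), g.data() + (size_t)l * t, t);
      for (int j = 0; j < t; ++j) G[j] += g[(size_t)l * t + j];
    }
    const vec &e = estate[c];
    for (int m = 0; m < k; ++m)
      for (int j = 0; j < t; ++j)
        out[(size_t)m * t + j] = e[(size_t)m * t + j] *
          (a * G[j] + bdiag * g[(size_t)m * t + j]);
  };
  // backward step: b_out[(l,j)] = sum_{m,j'} P_lm Ql[l][j,j'] e[j'] b[(m,j')]
  auto bwd_step = [&](const vec &b, vec &out, int c) {
    const vec &e = estate[c];
    std::fill(G.begin(), G.end(), 0.0);
    for (int m = 0; m < k; ++m)
      for (int j = 0; j < t; ++j) {
        g[(size_t)m * t + j] = e[(size_t)m * t + j] * b[(size_t)m * t + j];
        G[j] += g[(size_t)m * t + j];
      }
    for (int l = 0; l < k; ++l) {
      for (int j = 0; j < t; ++j) w[j] = a * G[j] + bdiag * g[(size_t)l * t + j];
      // out_l = Ql[l] %*% w  (row i dot w) via row-major storage
      vmatmul_off(w.data(), Qr[l].data(), out.data() + (size_t)l * t, t);
    }
  };

  // forward pass: store the (normalised) forward vector entering each chunk
  std::vector<vec> enter(nchunk, vec(n));
  vec f(n), tmp(n);
  double ll = 0.0;
  bool bad = false;
  for (int i = 0; i < L; ++i) {
    if (i % CHUNK == 0) enter[i / CHUNK] = f;
    if (i == 0) {
      for (int z = 0; z < n; ++z) f[z] = init[z] * estate[codes[0]][z];
    } else {
      fwd_step(f, tmp, codes[i]);
      f.swap(tmp);
    }
    double s = normalise(f);
    if (s < 0.0) { bad = true; break; }
    ll += std::log(s);
  }
  if (bad) {
    return List::create(Named("loglik") = R_NegInf);
  }

  NumericMatrix cat_marg(L, k);
  IntegerVector map_int(L);
  NumericMatrix cat_at_map(L, k);
  NumericVector map_mass(L);
  NumericMatrix joint;
  if (keep_joint) joint = NumericMatrix(L, n);

  vec b(n, 1.0), post(n);
  std::vector<double> fbuf((size_t)CHUNK * n);
  std::vector<double> im(t), cm(k);
  for (int ch = nchunk - 1; ch >= 0; --ch) {
    int s0 = ch * CHUNK;
    int e0 = std::min(L, s0 + CHUNK);
    // recompute forward vectors within the chunk
    vec fv = enter[ch];
    for (int i = s0; i < e0; ++i) {
      if (i == 0) {
        for (int z = 0; z < n; ++z) fv[z] = init[z] * estate[codes[0]][z];
      } else {
        fwd_step(fv, tmp, codes[i]);
        fv.swap(tmp);
      }
      normalise(fv);
      std::copy(fv.begin(), fv.end(), fbuf.begin() + (size_t)(i - s0) * n);
    }
    // backward within the chunk (b enters holding values for site e0-1)
    for (int i = e0 - 1; i >= s0; --i) {
      const double *fi = fbuf.data() + (size_t)(i - s0) * n;
      double tot = 0.0;
      for (int z = 0; z < n; ++z) { post[z] = fi[z] * b[z]; tot += post[z]; }
      double inv = (tot > 0) ? 1.0 / tot : 0.0;
      for (int z = 0; z < n; ++z) post[z] *= inv;
      // reductions
      std::fill(im.begin(), im.end(), 0.0);
      std::fill(cm.begin(), cm.end(), 0.0);
      for (int l = 0; l < k; ++l) {
        const double *pz = post.data() + (size_t)l * t;
        double s = 0.0;
        for (int j = 0; j < t; ++j) { s += pz[j]; im[j] += pz[j]; }
        cm[l] = s;
      }
      int best = 0;
      for (int j = 1; j < t; ++j) if (im[j] > im[best]) best = j;
      map_int[i] = best + 1;
      map_mass[i] = im[best];
      for (int l = 0; l < k; ++l) {
        cat_marg(i, l) = cm[l];
        cat_at_map(i, l) = (im[best] > 1e-12)
          ? post[(size_t)l * t + best] / im[best] : cm[l];
      }
      if (keep_joint)
        for (int z = 0; z < n; ++z) joint(i, z) = post[z];
      // step b back to site i-1: b_{i-1} = A_{c_i} b_i
      if (i > s0 || ch > 0) {
        bwd_step(b, tmp, codes[i]);
        b.swap(tmp);
        normalise(b);
      }
    }
  }

  List out = List::create(Named("loglik") = ll,
                          Named("cat_marginal") = cat_marg,
                          Named("map_interval") = map_int,
                          Named("cat_at_map") = cat_at_map,
                          Named("map_mass") = map_mass);
  if (keep_joint) out["joint"] = joint;
  return out;
}
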