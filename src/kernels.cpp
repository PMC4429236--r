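#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Feed-forward compressor gain: a peak detector (instant rise, first-order
// release decay) drives the static gain law; the gain itself is smoothed
// first-order with the attack coefficient when reduction deepens and the
// release coefficient when it recovers.
// [[Rcpp::export]]
arma::vec compressor_gain_cpp(const arma::vec& absx, const double a_att,
                              const double a_rel, const double threshold_db,
                              const double ratio) {
  const uword n = absx.n_elem;
  vec gain(n);
  double e = 0.0, g = 1.0;
  const double ln10_20 = std::log(10.0) / 20.0;
  for (uword i = 0; i < n; ++i) {
    e = std::max(absx[i], e * (1.0 - a_rel));
    double gt = 1.0;
    if (e > 1e-12) {
      const double lvl_db = std::log10(e) * 20.0;
      if (lvl_db > threshold_db) {
        const double gt_db =
            threshold_db + (lvl_db - threshold_db) / ratio - lvl_db;
        gt = std::exp(gt_db * ln10_20);
      }
    }
    const double a = (gt < g) ? a_att : a_rel;
    g += a * (gt - g);
    gain[i] = g;
  }
  return gain;
}

// One pass of an IIR filter (direct form II transposed) with initial
// conditions zi (steady-state unit-step response scaled by the caller).
static void lfilter(const vec& b, const vec& a, const vec& x, vec& y,
                    const vec& zi) {
  const uword n = x.n_elem, nf = b.n_elem;
  vec z = zi;
  for (uword i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (uword k = 1; k < nf - 1; ++k) {
      z[k - 1] = b[k] * xi + z[k] - a[k] * yi;
    }
    z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
}

// Steady-state initial conditions for lfilter (unit step input).
static vec lfilter_zi(const vec& b, const vec& a) {
  const uword n = b.n_elem - 1;
  // companion matrix C of a (monic); solve (I - C^T) zi = b[1:] - a[1:] b[0]
  mat C(n, n, fill::zeros);
  for (uword j = 0; j < n; ++j) C(0, j) = -a[j + 1];
  for (uword i = 1; i < n; ++i) C(i, i - 1) = 1.0;
  mat M = eye(n, n) - C.t();
  vec B(n);
  for (uword i = 0; i < n; ++i) B[i] = b[i + 1] - a[i + 1] * b[0];
  return solve(M, B);
}

// Zero-phase IIR filtering of each column of X: odd-reflection padding,
// forward pass, reversed backward pass (scipy filtfilt conventions).
// [[Rcpp::export]]
arma::mat filtfilt_cols(const arma::vec& b, const arma::vec& a,
                        const arma::mat& X, const int pad = -1) {
  if (b.n_elem != a.n_elem) Rcpp::stop("b and a must have equal length");
  const uword T = X.n_rows, V = X.n_cols;
  const uword padlen = std::min<uword>(
      T - 1, pad >= 0 ? (uword)pad : 3 * b.n_elem);
  const uword Text = T + 2 * padlen;
  if (T <= padlen) Rcpp::stop("series too short for filtfilt padding");
  const vec zi = lfilter_zi(b, a);
  mat out(T, V);
  vec ext(Text), y1(Text), y2(Text);
  for (uword v = 0; v < V; ++v) {
    const vec x = X.col(v);
    for (uword i = 0; i < padlen; ++i) ext[i] = 2 * x[0] - x[padlen - i];
    for (uword i = 0; i < T; ++i) ext[padlen + i] = x[i];
    for (uword i = 0; i < padlen; ++i) {
      ext[padlen + T + i] = 2 * x[T - 1] - x[T - 2 - i];
    }
    lfilter(b, a, ext, y1, zi * ext[0]);
    vec y1r = reverse(y1);
    lfilter(b, a, y1r, y2, zi * y1r[0]);
    vec y2r = reverse(y2);
    out.col(v) = y2r.subvec(padlen, padlen + T - 1);
  }
  return out;
}

// Null distribution of leave-one-out ISC by phase randomization.
//
// x: T x V x N cube (time x voxel x subject). Each replicate independently
// randomizes the Fourier phases of every subject's series at every voxel
// (spectrum preserved; DC untouched; an even-length Nyquist component gets
// a random sign) and recomputes R = mean_j corr(x_j, mean of others).
// Correlations are evaluated in the frequency domain via Parseval's
// identity, which is algebraically identical to inverting the FFT and
// correlating in time. Uses a dedicated mt19937_64 stream so results are
// reproducible given `seed` and independent of R's RNG state.
//
// Returns V x n_perm matrix of null R values.
// [[Rcpp::export]]
arma::mat isc_null_kernel(const arma::cube& x, const int n_perm,
                          const double seed) {
  const uword T = x.n_rows, V = x.n_cols, N = x.n_slices;
  if (N < 2) Rcpp::stop("need at least 2 subjects");
  if (T < 4) Rcpp::stop("need at least 4 time points");
  const uword h = (T - 1) / 2;          // strictly positive frequencies
  const bool has_nyq = (T % 2 == 0);

  // FFT of centered series, keep half spectrum (+ Nyquist row if even)
  std::vector<cx_mat> F(N);
  mat Fnyq(has_nyq ? V : 0, N);
  mat var_j(V, N);                       // 2*sum|F|^2 (+ nyq^2), constant
  for (uword s = 0; s < N; ++s) {
    mat Xs = x.slice(s);
    Xs.each_row() -= mean(Xs, 0);
    cx_mat Ff = fft(Xs);
    F[s] = Ff.rows(1, h);
    vec v2 = 2.0 * sum(square(abs(F[s])), 0).t();
    if (has_nyq) {
      vec ny = real(Ff.row(T / 2)).t();
      Fnyq.col(s) = ny;
      v2 += square(ny);
    }
    var_j.col(s) = v2;
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> coin(0, 1);
  // uniform phase as a unit complex number without transcendentals
  // (Marsaglia polar: the squared point on the unit disk has uniform angle)
  auto rand_phase = [&](double& c, double& s) {
    double u, v, q;
    do {
      u = 2.0 * unif(rng) - 1.0;
      v = 2.0 * unif(rng) - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    c = (u * u - v * v) / q;
    s = 2.0 * u * v / q;
  };

  mat out(V, n_perm);
  cx_cube G(h, V, N);
  mat Gnyq(has_nyq ? V : 0, N);
  cx_mat S(h, V);
  mat Snyq(has_nyq ? V : 0, 1);
  vec normS2(V), Rsum(V), Rcnt(V);
  for (int p = 0; p < n_perm; ++p) {
    // phase-randomize every subject at every voxel; accumulate the sum S
    S.zeros();
    if (has_nyq) Snyq.zeros();
    for (uword s = 0; s < N; ++s) {
      const std::complex<double>* fp = F[s].memptr();
      std::complex<double>* gp = G.slice_memptr(s);
      std::complex<double>* sp = S.memptr();
      const uword hV = h * V;
      for (uword i = 0; i < hV; ++i) {
        double c, sn;
        rand_phase(c, sn);
        const double re = fp[i].real(), im = fp[i].imag();
        const std::complex<double> g(re * c - im * sn, re * sn + im * c);
        gp[i] = g;
        sp[i] += g;
      }
      if (has_nyq) {
        for (uword v = 0; v < V; ++v) {
          const double g = (coin(rng) ? 1.0 : -1.0) * Fnyq(v, s);
          Gnyq(v, s) = g;
          Snyq(v, 0) += g;
        }
      }
    }
    {
      const std::complex<double>* sp = S.memptr();
      for (uword v = 0; v < V; ++v) {
        double acc = 0.0;
        for (uword f = 0; f < h; ++f) {
          const std::complex<double>& z = sp[v * h + f];
          acc += z.real() * z.real() + z.imag() * z.imag();
        }
        normS2[v] = 2.0 * acc;
        if (has_nyq) normS2[v] += Snyq(v, 0) * Snyq(v, 0);
      }
    }
    Rsum.zeros();
    Rcnt.zeros();
    for (uword s = 0; s < N; ++s) {
      const std::complex<double>* gp = G.slice_memptr(s);
      const std::complex<double>* sp = S.memptr();
      for (uword v = 0; v < V; ++v) {
        double acc = 0.0;
        for (uword f = 0; f < h; ++f) {
          const std::complex<double>& g = gp[v * h + f];
          const std::complex<double>& z = sp[v * h + f];
          acc += g.real() * z.real() + g.imag() * z.imag();
        }
        double crossS = 2.0 * acc;                 // <g_j, S>
        if (has_nyq) crossS += Gnyq(v, s) * Snyq(v, 0);
        const double vj = var_j(v, s);
        const double cross = crossS - vj;          // <g_j, S - g_j>
        const double varO = normS2[v] - 2.0 * crossS + vj;
        const double denom = vj * varO;
        if (denom > 0) {
          Rsum[v] += cross / std::sqrt(denom);
          Rcnt[v] += 1.0;
        }
      }
    }
    for (uword v = 0; v < V; ++v) {
      out(v, p) = Rsum[v] / std::max(Rcnt[v], 1.0);
    }
  }
  return out;
}
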