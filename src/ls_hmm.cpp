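#include <Rcpp.h>
using namespace Rcpp;

// Diploid Li-Stephens haplotype-copying forward-backward.
//
// Hidden state: ordered pair (k1, k2) of panel haplotypes. Each haploid copy
// switches independently between sites with probability rho (recombination-
// scaled), choosing its new donor uniformly among the K haplotypes (including
// the current one). Emission mixes a per-haplotype miscopy rate theta with the
// site's normalized genotype likelihoods.
//
// The structured transition factorizes, so each pass is O(S * K^2):
// applying the haploid kernel T = (1-rho) I + (rho/K) 11' along one axis of
// the K x K state matrix costs one row/column-sum reduction.

// genotype distribution given copied-pair dosage d and miscopy theta
static void miscopy_table(double theta, double M[3][3]) {
  double a = 1.0 - theta, b = theta;
  M[0][0] = a * a;         M[0][1] = 2 * a * b;       M[0][2] = b * b;
  M[1][0] = a * b;         M[1][1] = a * a + b * b;   M[1][2] = a * b;
  M[2][0] = b * b;         M[2][1] = 2 * a * b;       M[2][2] = a * a;
}

// apply T along rows then columns of mat (K x K), in place
static void apply_transition(std::vector<double> &mat, int K, double rho) {
  if (rho <= 0) return;
  double stay = 1.0 - rho, move = rho / K;
  // axis 1 (rows index k1): new[i,j] = stay*old[i,j] + move*colsum_j
  for (int j = 0; j < K; ++j) {
    double cs = 0;
    for (int i = 0; i < K; ++i) cs += mat[i + K * j];
    cs *= move;
    for (int i = 0; i < K; ++i) mat[i + K * j] = stay * mat[i + K * j] + cs;
  }
  // axis 2 (columns index k2)
  for (int i = 0; i < K; ++i) {
    double rs = 0;
    for (int j = 0; j < K; ++j) rs += mat[i + K * j];
    rs *= move;
    for (int j = 0; j < K; ++j) mat[i + K * j] = stay * mat[i + K * j] + rs;
  }
}

// [[Rcpp::export(name = ".ls_fb_cpp")]]
List ls_fb_cpp(IntegerMatrix alleles, NumericMatrix gl, NumericVector rho,
               double theta) {
  const int K = alleles.nrow(), S = alleles.ncol();
  if (gl.nrow() != S || gl.ncol() != 3) stop("gl must be S x 3");
  if (rho.size() != S) stop("rho must have one entry per site (first unused)");

  double M[3][3];
  miscopy_table(theta, M);

  // per-site emission by dosage class: e[s][d] = sum_g M[d][g] * gl[s][g]
  std::vector<double> em(S * 3);
  for (int s = 0; s < S; ++s)
    for (int d = 0; d < 3; ++d)
      em[s * 3 + d] = M[d][0] * gl(s, 0) + M[d][1] * gl(s, 1) +
                      M[d][2] * gl(s, 2);

  const int KK = K * K;
  std::vector<double> F(static_cast<size_t>(S) * KK), cur(KK), scale_f(S);

  // forward
  double loglik_f = 0;
  for (int s = 0; s < S; ++s) {
    if (s == 0) {
      double init = 1.0 / KK;
      for (int q = 0; q < KK; ++q) cur[q] = init;
    } else {
      apply_transition(cur, K, rho[s]);
    }
    const double *e = &em[s * 3];
    double tot = 0;
    for (int j = 0; j < K; ++j) {
      int aj = alleles(j, s);
      for (int i = 0; i < K; ++i) {
        double v = cur[i + K * j] * e[alleles(i, s) + aj];
        cur[i + K * j] = v;
        tot += v;
      }
    }
    if (tot <= 0) stop("zero forward mass at site %d (degenerate likelihoods)",
                       s + 1);
    double inv = 1.0 / tot;
    for (int q = 0; q < KK; ++q) {
      cur[q] *= inv;
      F[static_cast<size_t>(s) * KK + q] = cur[q];
    }
    scale_f[s] = tot;
    loglik_f += std::log(tot);
  }

  // backward, accumulating genotype posteriors on the fly
  NumericMatrix gp(S, 3);
  std::vector<double> B(KK, 1.0), tmp(KK);
  double loglik_b = NA_REAL;
  for (int s = S - 1; s >= 0; --s) {
    // genotype posterior at s: P(g | obs) ~ sum_state F'(state) B(state)
    // M[dos][g] gl[s][g], where F' excludes the site-s emission (divide the
    // stored forward value by the state's aggregated emission)
    double w[3] = {0, 0, 0};
    const double *Fs = &F[static_cast<size_t>(s) * KK];
    const double *e = &em[s * 3];
    for (int j = 0; j < K; ++j) {
      int aj = alleles(j, s);
      for (int i = 0; i < K; ++i) {
        int d = alleles(i, s) + aj;
        w[d] += Fs[i + K * j] * B[i + K * j] / e[d];
      }
    }
    double tot = 0;
    for (int g = 0; g < 3; ++g) {
      gp(s, g) = (w[0] * M[0][g] + w[1] * M[1][g] + w[2] * M[2][g]) *
                 gl(s, g);
      tot += gp(s, g);
    }
    for (int g = 0; g < 3; ++g) gp(s, g) /= tot;

    // extend B to exclude site s-1's emission: B <- T (E_s * B), rescaled
    for (int j = 0; j < K; ++j) {
      int aj = alleles(j, s);
      for (int i = 0; i < K; ++i)
        tmp[i + K * j] = B[i + K * j] * e[alleles(i, s) + aj];
    }
    if (s > 0) {
      apply_transition(tmp, K, rho[s]);
      double mx = 0;
      for (int q = 0; q < KK; ++q) if (tmp[q] > mx) mx = tmp[q];
      if (mx <= 0) stop("zero backward mass at site %d", s);
      double inv = 1.0 / mx;
      for (int q = 0; q < KK; ++q) B[q] = tmp[q] * inv;
      scale_f[s] = mx; // forward scales already consumed; reuse for backward
    } else {
      // total backward likelihood: sum_q pi_q * (E_0 * B)_q
      double tot0 = 0;
      for (int q = 0; q < KK; ++q) tot0 += tmp[q];
      tot0 /= KK;
      loglik_b = std::log(tot0);
    }
  }
  // add back the backward rescaling factors (stored in scale_f[1..S-1])
  for (int s = 1; s < S; ++s) loglik_b += std::log(scale_f[s]);

  return List::create(_["gp"] = gp,
                      _["loglik_forward"] = loglik_f,
                      _["loglik_backward"] = loglik_b);
}
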