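// Compact 1D convolutional network for AP-shape risk classification:
// conv(2 filters) -> batchnorm -> ReLU -> maxpool | conv -> ReLU -> dropout
// -> maxpool | conv -> ReLU | flatten -> dense(ReLU) -> dense(softmax).
// Forward and backward passes over one minibatch; the Adam loop lives in R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double relu(double x) { return x > 0.0 ? x : 0.0; }

// [[Rcpp::export(name = ".cnn_batch_cpp")]]
List cnn_batch_cpp(NumericMatrix X, NumericMatrix Y, List params, List arch,
                   NumericVector bn_mean, NumericVector bn_var,
                   bool training, NumericVector dropout_mask,
                   bool compute_grads) {
  const int n = X.nrow();
  const int L0 = as<int>(arch["input_len"]);
  const int K1 = as<int>(arch["k1"]), S1 = as<int>(arch["s1"]);
  const int P1 = as<int>(arch["p1"]), PS1 = as<int>(arch["ps1"]);
  const int K2 = as<int>(arch["k2"]), S2 = as<int>(arch["s2"]);
  const int P2 = as<int>(arch["p2"]), PS2 = as<int>(arch["ps2"]);
  const int K3 = as<int>(arch["k3"]), S3 = as<int>(arch["s3"]);
  const int NH = as<int>(arch["hidden"]), NC = as<int>(arch["classes"]);
  const int NF = 2; // filters per conv layer
  const int L1 = (L0 - K1) / S1 + 1;
  const int Q1 = (L1 - P1) / PS1 + 1;
  const int L2 = (Q1 - K2) / S2 + 1;
  const int Q2 = (L2 - P2) / PS2 + 1;
  const int L3 = (Q2 - K3) / S3 + 1;
  const int NFEAT = NF * L3;
  if (X.ncol() != L0) stop("input traces must have %d points, got %d", L0, X.ncol());

  NumericMatrix W1 = params["W1"]; NumericVector b1 = params["b1"];
  NumericVector gamma = params["gamma"], beta = params["beta"];
  NumericVector W2 = params["W2"]; NumericVector b2 = params["b2"];
  NumericVector W3 = params["W3"]; NumericVector b3 = params["b3"];
  NumericMatrix W4 = params["W4"]; NumericVector b4 = params["b4"];
  NumericMatrix W5 = params["W5"]; NumericVector b5 = params["b5"];
  // W2/W3 layout: [out + NF*(in + NF*tap)]

  const double eps = 1e-5;
  const bool use_drop = training && dropout_mask.size() > 0;

  // batch-wide activation storage
  std::vector<double> z1(n * NF * L1), xhat(n * NF * L1), r1(n * NF * L1);
  std::vector<double> p1(n * NF * Q1); std::vector<int> a1arg(n * NF * Q1);
  std::vector<double> z2(n * NF * L2), d2(n * NF * L2);
  std::vector<double> p2(n * NF * Q2); std::vector<int> a2arg(n * NF * Q2);
  std::vector<double> z3(n * NF * L3), f(n * NFEAT), hh(n * NH);
  NumericMatrix probs(n, NC);

  #define Z1(i,c,k) z1[((i) * NF + (c)) * L1 + (k)]
  #define XH(i,c,k) xhat[((i) * NF + (c)) * L1 + (k)]
  #define R1(i,c,k) r1[((i) * NF + (c)) * L1 + (k)]
  #define PP1(i,c,k) p1[((i) * NF + (c)) * Q1 + (k)]
  #define Z2(i,c,k) z2[((i) * NF + (c)) * L2 + (k)]
  #define D2(i,c,k) d2[((i) * NF + (c)) * L2 + (k)]
  #define PP2(i,c,k) p2[((i) * NF + (c)) * Q2 + (k)]
  #define Z3(i,c,k) z3[((i) * NF + (c)) * L3 + (k)]

  // conv1
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < L1; ++k) {
        double s = b1[c];
        const int base = S1 * k;
        for (int t = 0; t < K1; ++t) s += W1(c, t) * X(i, base + t);
        Z1(i, c, k) = s;
      }
  // batchnorm (per channel over batch x positions)
  double mu[2], var[2];
  const double Nbn = (double)n * L1;
  for (int c = 0; c < NF; ++c) {
    if (training) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) for (int k = 0; k < L1; ++k) m += Z1(i, c, k);
      m /= Nbn;
      double v = 0.0;
      for (int i = 0; i < n; ++i) for (int k = 0; k < L1; ++k) {
        const double d = Z1(i, c, k) - m; v += d * d;
      }
      v /= Nbn;
      mu[c] = m; var[c] = v;
    } else {
      mu[c] = bn_mean[c]; var[c] = bn_var[c];
    }
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < L1; ++k) {
        const double xh = (Z1(i, c, k) - mu[c]) * inv;
        XH(i, c, k) = xh;
        R1(i, c, k) = relu(gamma[c] * xh + beta[c]);
      }
  }
  // pool1
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < Q1; ++k) {
        const int base = PS1 * k;
        double best = R1(i, c, base); int barg = base;
        for (int w = 1; w < P1; ++w) {
          const double vv = R1(i, c, base + w);
          if (vv > best) { best = vv; barg = base + w; }
        }
        PP1(i, c, k) = best; a1arg[((i) * NF + c) * Q1 + k] = barg;
      }
  // conv2 + relu + dropout
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < L2; ++k) {
        double s = b2[c];
        const int base = S2 * k;
        for (int ci = 0; ci < NF; ++ci)
          for (int t = 0; t < K2; ++t)
            s += W2[c + NF * (ci + NF * t)] * PP1(i, ci, base + t);
        Z2(i, c, k) = s;
        double r = relu(s);
        if (use_drop) r *= dropout_mask[((i) * NF + c) * L2 + k];
        D2(i, c, k) = r;
      }
  // pool2
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < Q2; ++k) {
        const int base = PS2 * k;
        double best = D2(i, c, base); int barg = base;
        for (int w = 1; w < P2; ++w) {
          const double vv = D2(i, c, base + w);
          if (vv > best) { best = vv; barg = base + w; }
        }
        PP2(i, c, k) = best; a2arg[((i) * NF + c) * Q2 + k] = barg;
      }
  // conv3 + relu, flatten (channel-major)
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < L3; ++k) {
        double s = b3[c];
        const int base = S3 * k;
        for (int ci = 0; ci < NF; ++ci)
          for (int t = 0; t < K3; ++t)
            s += W3[c + NF * (ci + NF * t)] * PP2(i, ci, base + t);
        Z3(i, c, k) = s;
        f[i * NFEAT + c * L3 + k] = relu(s);
      }
  // dense layers + softmax
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int u = 0; u < NH; ++u) {
      double s = b4[u];
      for (int q = 0; q < NFEAT; ++q) s += W4(u, q) * f[i * NFEAT + q];
      hh[i * NH + u] = relu(s);
    }
    double omax = -1e300; double o[16];
    for (int c = 0; c < NC; ++c) {
      double s = b5[c];
      for (int u = 0; u < NH; ++u) s += W5(c, u) * hh[i * NH + u];
      o[c] = s; if (s > omax) omax = s;
    }
    double zsum = 0.0;
    for (int c = 0; c < NC; ++c) { o[c] = std::exp(o[c] - omax); zsum += o[c]; }
    for (int c = 0; c < NC; ++c) {
      const double pc = o[c] / zsum;
      probs(i, c) = pc;
      if (Y.nrow() == n && Y(i, c) > 0.0)
        loss -= Y(i, c) * std::log(pc > 1e-300 ? pc : 1e-300);
    }
  }
  loss /= n;

  List out = List::create(_["loss"] = loss, _["probs"] = probs,
                          _["bn_mean"] = NumericVector::create(mu[0], mu[1]),
                          _["bn_var"] = NumericVector::create(var[0], var[1]));
  if (!compute_grads) return out;

  // ---------------- backward ----------------
  NumericMatrix gW1(NF, K1); NumericVector gb1(NF), ggamma(NF), gbeta(NF);
  NumericVector gW2(NF * NF * K2), gb2(NF), gW3(NF * NF * K3), gb3(NF);
  NumericMatrix gW4(NH, NFEAT); NumericVector gb4(NH);
  NumericMatrix gW5(NC, NH); NumericVector gb5(NC);

  std::vector<double> df(n * NFEAT, 0.0), dp2(n * NF * Q2, 0.0),
      dd2(n * NF * L2, 0.0), dp1(n * NF * Q1, 0.0), dr1(n * NF * L1, 0.0),
      dz1(n * NF * L1, 0.0);

  for (int i = 0; i < n; ++i) {
    double dO[16], dH[16];
    for (int c = 0; c < NC; ++c) dO[c] = (probs(i, c) - Y(i, c)) / n;
    for (int c = 0; c < NC; ++c) {
      gb5[c] += dO[c];
      for (int u = 0; u < NH; ++u) gW5(c, u) += dO[c] * hh[i * NH + u];
    }
    for (int u = 0; u < NH; ++u) {
      double s = 0.0;
      for (int c = 0; c < NC; ++c) s += W5(c, u) * dO[c];
      dH[u] = (hh[i * NH + u] > 0.0) ? s : 0.0;
      gb4[u] += dH[u];
    }
    for (int u = 0; u < NH; ++u) {
      if (dH[u] == 0.0) continue;
      for (int q = 0; q < NFEAT; ++q) {
        gW4(u, q) += dH[u] * f[i * NFEAT + q];
        df[i * NFEAT + q] += W4(u, q) * dH[u];
      }
    }
    // conv3 backward
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < L3; ++k) {
        double g = df[i * NFEAT + c * L3 + k];
        if (Z3(i, c, k) <= 0.0 || g == 0.0) continue;
        gb3[c] += g;
        const int base = S3 * k;
        for (int ci = 0; ci < NF; ++ci)
          for (int t = 0; t < K3; ++t) {
            gW3[c + NF * (ci + NF * t)] += g * PP2(i, ci, base + t);
            dp2[((i) * NF + ci) * Q2 + base + t] += g * W3[c + NF * (ci + NF * t)];
          }
      }
    // pool2 backward
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < Q2; ++k) {
        const double g = dp2[((i) * NF + c) * Q2 + k];
        if (g != 0.0) dd2[((i) * NF + c) * L2 + a2arg[((i) * NF + c) * Q2 + k]] += g;
      }
    // dropout + relu + conv2 backward
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < L2; ++k) {
        double g = dd2[((i) * NF + c) * L2 + k];
        if (g == 0.0) continue;
        if (use_drop) g *= dropout_mask[((i) * NF + c) * L2 + k];
        if (Z2(i, c, k) <= 0.0) continue;
        gb2[c] += g;
        const int base = S2 * k;
        for (int ci = 0; ci < NF; ++ci)
          for (int t = 0; t < K2; ++t) {
            gW2[c + NF * (ci + NF * t)] += g * PP1(i, ci, base + t);
            dp1[((i) * NF + ci) * Q1 + base + t] += g * W2[c + NF * (ci + NF * t)];
          }
      }
    // pool1 backward
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < Q1; ++k) {
        const double g = dp1[((i) * NF + c) * Q1 + k];
        if (g != 0.0) dr1[((i) * NF + c) * L1 + a1arg[((i) * NF + c) * Q1 + k]] += g;
      }
  }
  // batchnorm backward (per channel, over the whole batch)
  for (int c = 0; c < NF; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double sum_dxhat = 0.0, sum_dxhat_xhat = 0.0;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < L1; ++k) {
        double da = dr1[((i) * NF + c) * L1 + k];
        if (gamma[c] * XH(i, c, k) + beta[c] <= 0.0) da = 0.0; // relu gate
        dr1[((i) * NF + c) * L1 + k] = da;
        ggamma[c] += da * XH(i, c, k);
        gbeta[c] += da;
        const double dxh = da * gamma[c];
        sum_dxhat += dxh;
        sum_dxhat_xhat += dxh * XH(i, c, k);
      }
    if (training) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < L1; ++k) {
          const double dxh = dr1[((i) * NF + c) * L1 + k] * gamma[c];
          dz1[((i) * NF + c) * L1 + k] = inv *
              (dxh - sum_dxhat / Nbn - XH(i, c, k) * sum_dxhat_xhat / Nbn);
        }
    } else {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < L1; ++k)
          dz1[((i) * NF + c) * L1 + k] = dr1[((i) * NF + c) * L1 + k] * gamma[c] * inv;
    }
  }
  // conv1 backward
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < NF; ++c)
      for (int k = 0; k < L1; ++k) {
        const double g = dz1[((i) * NF + c) * L1 + k];
        if (g == 0.0) continue;
        gb1[c] += g;
        const int base = S1 * k;
        for (int t = 0; t < K1; ++t) gW1(c, t) += g * X(i, base + t);
      }

  out["grads"] = List::create(
      _["W1"] = gW1, _["b1"] = gb1, _["gamma"] = ggamma, _["beta"] = gbeta,
      _["W2"] = gW2, _["b2"] = gb2, _["W3"] = gW3, _["b3"] = gb3,
      _["W4"] = gW4, _["b4"] = gb4, _["W5"] = gW5, _["b5"] = gb5);
  return out;
}
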