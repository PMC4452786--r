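#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian convolution with replicate (clamp-to-edge) padding.
// Kernel truncated at `trunc` standard deviations. Both passes keep the
// inner loop contiguous in the column-major layout.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(const NumericMatrix& m, double sigma, double trunc = 3.0) {
  const int H = m.nrow(), W = m.ncol();
  const int r = std::max(1, (int)std::ceil(trunc * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(H, W), out(H, W);
  const double* __restrict__ src0 = m.begin();
  double* __restrict__ tmp0 = tmp.begin();
  double* __restrict__ out0 = out.begin();
  std::vector<double> col(H + 2 * r);

  // vertical pass: pad each column once, then accumulate contiguously
  for (int j = 0; j < W; ++j) {
    const double* cj = src0 + (size_t)j * H;
    for (int i = 0; i < r; ++i) col[i] = cj[0];
    std::copy(cj, cj + H, col.data() + r);
    for (int i = 0; i < r; ++i) col[H + r + i] = cj[H - 1];
    double* o = tmp0 + (size_t)j * H;
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      const double* c = &col[i];
      for (int t = 0; t <= 2 * r; ++t) acc += k[t] * c[t];
      o[i] = acc;
    }
  }
  // horizontal pass: for each output column, sum scaled neighbour columns
  for (int j = 0; j < W; ++j) {
    double* __restrict__ o = out0 + (size_t)j * H;
    std::fill(o, o + H, 0.0);
    for (int t = -r; t <= r; ++t) {
      int jj = j + t;
      if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
      const double kt = k[t + r];
      const double* __restrict__ src = tmp0 + (size_t)jj * H;
      for (int i = 0; i < H; ++i) o[i] += kt * src[i];
    }
  }
  return out;
}

// Scale-space non-maximum suppression: returns (row, col, level, response)
// for strict local maxima over the 3x3x3 neighbourhood (image borders and
// missing neighbour levels compare against what exists) above `threshold`.
// [[Rcpp::export]]
DataFrame scale_space_maxima_cpp(const List& resps, double threshold) {
  const int S = resps.size();
  std::vector<NumericMatrix> R(S);
  for (int s = 0; s < S; ++s) R[s] = as<NumericMatrix>(resps[s]);
  const int H = R[0].nrow(), W = R[0].ncol();
  std::vector<int> rr, cc, ss;
  std::vector<double> vv;
  for (int s = 0; s < S; ++s) {
    const NumericMatrix& m = R[s];
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = m(i, j);
        if (v <= threshold) continue;
        bool ok = true;
        for (int t = std::max(0, s - 1); t <= std::min(S - 1, s + 1) && ok; ++t) {
          const NumericMatrix& n = R[t];
          for (int dj = -1; dj <= 1 && ok; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= W) continue;
            for (int di = -1; di <= 1; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= H) continue;
              if (t == s && di == 0 && dj == 0) continue;
              if (n(ii, jj) >= v) { ok = false; break; }
            }
          }
        }
        if (ok) {
          rr.push_back(i + 1); cc.push_back(j + 1); ss.push_back(s + 1);
          vv.push_back(v);
        }
      }
    }
  }
  return DataFrame::create(_["row"] = rr, _["col"] = cc,
                           _["level"] = ss, _["response"] = vv);
}
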