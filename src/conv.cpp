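#include <Rcpp.h>
using namespace Rcpp;

// Fused convolution + thresholded rectifier + max-pool over one strand.
//
// codes: B x N integer matrix, base codes A=1,C=2,G=3,T=4, N-base=0.
// W: filter bank as the flat vector of an R array dim (F, 4, K).
// b: K per-filter rectifier thresholds.
// literal: TRUE -> z = y * (y > b); FALSE -> z = (y - b) * (y > b).
//
// The filter bank is transposed internally to a (K, F*4) layout so the
// inner accumulation runs contiguously over filters and vectorizes.
//
// Returns pooled maxima P (B x nw*K, column (w-1)*K + k), the convolution
// row achieving each maximum (1-based), and whether the rectifier mask was
// open there (needed for the sparse backward pass).
// [[Rcpp::export]]
List conv_pool_forward_cpp(IntegerMatrix codes, NumericVector W,
                           NumericVector b, int F, int K, int pool_window,
                           bool literal) {
  const int B = codes.nrow(), N = codes.ncol();
  const int R = N - F + 1;
  if (R < 1) stop("sequence shorter than filter");
  const int nw = (R + pool_window - 1) / pool_window;
  NumericMatrix P(B, nw * K);
  IntegerMatrix argmax(B, nw * K);
  LogicalMatrix maskmax(B, nw * K);

  // Wt[k + K*(i + F*c)] = W[i + F*c + F*4*k]
  std::vector<double> Wt((size_t)K * F * 4);
  for (int k = 0; k < K; ++k)
    for (int jc = 0; jc < F * 4; ++jc)
      Wt[(size_t)k + (size_t)K * jc] = W[jc + (size_t)F * 4 * k];

  std::vector<double> z(K);
  std::vector<double> best(nw * K);
  std::vector<int> bestr(nw * K);
  std::vector<int> row(N);
  const double NEG = -1e300;

  for (int bi = 0; bi < B; ++bi) {
    for (int p = 0; p < N; ++p) row[p] = codes(bi, p);
    std::fill(best.begin(), best.end(), NEG);
    for (int r = 0; r < R; ++r) {
      std::fill(z.begin(), z.end(), 0.0);
      double* __restrict__ zp = z.data();
      for (int i = 0; i < F; ++i) {
        const int c = row[r + i];
        if (c <= 0) continue;
        const double* __restrict__ wp = &Wt[(size_t)K * (i + F * (c - 1))];
        for (int k = 0; k < K; ++k) zp[k] += wp[k];
      }
      const int w = r / pool_window;
      double* bw = &best[(size_t)w * K];
      int* br = &bestr[(size_t)w * K];
      if (literal) {
        for (int k = 0; k < K; ++k) {
          const double zz = (zp[k] > b[k]) ? zp[k] : 0.0;
          if (zz > bw[k]) { bw[k] = zz; br[k] = r; }
        }
      } else {
        for (int k = 0; k < K; ++k) {
          const double zz = (zp[k] > b[k]) ? zp[k] - b[k] : 0.0;
          if (zz > bw[k]) { bw[k] = zz; br[k] = r; }
        }
      }
    }
    // recover the mask at each argmax (recompute y there cheaply per k)
    for (int w = 0; w < nw; ++w) {
      for (int k = 0; k < K; ++k) {
        const int col = w * K + k;
        P(bi, col) = best[(size_t)w * K + k];
        const int r = bestr[(size_t)w * K + k];
        argmax(bi, col) = r + 1;
        // mask open iff the stored max came from an open rectifier:
        // closed rectifier contributes exactly 0, open contributes
        // y (literal, may be any sign) or y-b > 0 (shifted).
        double y = 0.0;
        for (int i = 0; i < F; ++i) {
          const int c = row[r + i];
          if (c > 0) y += Wt[(size_t)k + (size_t)K * (i + F * (c - 1))];
        }
        maskmax(bi, col) = y > b[k];
        // distinguish "max is 0 from a closed gate" from "open gate with
        // value 0": if the pooled max is exactly 0 and y <= b the mask is
        // closed (consistent), if y > b and z == 0 it is open with y == 0.
      }
    }
  }
  return List::create(_["P"] = P, _["argmax"] = argmax,
                      _["mask"] = maskmax, _["nw"] = nw, _["R"] = R);
}

// Sparse backward of the fused layer: the pooled-gradient dP only reaches
// the argmax convolution rows, so dW gets at most B * nw * K scatter
// updates.  Returns dW (flat, dim (F,4,K)) and db (nonzero only in shifted
// mode, where d z / d b = -1 on the open mask).
// [[Rcpp::export]]
List conv_pool_backward_cpp(IntegerMatrix codes, IntegerMatrix argmax,
                            LogicalMatrix maskmax, NumericMatrix dP,
                            int F, int K, bool literal) {
  const int B = codes.nrow();
  const int nwK = dP.ncol();
  NumericVector dW((size_t)F * 4 * K);
  NumericVector db(K);
  for (int bi = 0; bi < B; ++bi) {
    for (int col = 0; col < nwK; ++col) {
      const double v = dP(bi, col);
      if (v == 0.0 || !maskmax(bi, col)) continue;
      const int k = col % K;
      const int r = argmax(bi, col) - 1;
      double* dWk = &dW[(size_t)k * F * 4];
      for (int i = 0; i < F; ++i) {
        const int c = codes(bi, r + i);
        if (c > 0) dWk[i + F * (c - 1)] += v;
      }
      if (!literal) db[k] -= v;
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}
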