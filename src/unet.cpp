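// Convolutional encoder-decoder for per-pixel tumor-fraction estimation.
//
// Feature maps are stored as (channels x npix) matrices with pixels in
// column-major (row + col*h) order.  3x3 same-padding convolutions are
// computed as GEMMs on im2col matrices; the contracting path halves the
// spatial dimensions with 2x2 average pooling, the expansive path restores
// them with nearest-neighbor upsampling, and skip connections are added
// element-wise.  The final 1x1 convolution is squashed through a logistic
// so every output lies strictly in (0, 1), as required for the binary
// cross-entropy cost to be finite.  Training uses Adam on the aggregate
// BCE cost (per-image sum over pixels, mean over the minibatch); the
// gradient of that cost with respect to the output logit is simply
// (prediction - target), which keeps backpropagation exact regardless of
// the log-clamping used when reporting the cost.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Geometry {
  int depth, base, h0;
  std::vector<int> hh, np;          // per resolution level 0..depth
  std::vector<umat> nb;             // 3x3 neighbor table per level
  std::vector<umat> pool;           // children (4 x np[l]) per level 1..depth
  // layer descriptors, in weight-list order
  std::vector<int> cin, cout, ksz, lev;
  int nLayers;
};

umat neighborTable(int h) {
  const int npx = h * h;
  umat nb(9, npx);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr, ++k)
      for (int c = 0; c < h; ++c)
        for (int r = 0; r < h; ++r) {
          int r2 = r + dr, c2 = c + dc;
          nb(k, r + c * h) =
            (r2 >= 0 && r2 < h && c2 >= 0 && c2 < h) ? uword(r2 + c2 * h)
                                                     : uword(npx);
        }
  return nb;
}

Geometry makeGeometry(int depth, int base, int h0) {
  Geometry g;
  g.depth = depth; g.base = base; g.h0 = h0;
  for (int l = 0; l <= depth; ++l) {
    int h = h0 >> l;
    g.hh.push_back(h);
    g.np.push_back(h * h);
    g.nb.push_back(neighborTable(h));
  }
  g.pool.resize(depth + 1);
  for (int l = 1; l <= depth; ++l) {
    int hc = g.hh[l], hf = g.hh[l - 1];
    umat ch(4, hc * hc);
    for (int c = 0; c < hc; ++c)
      for (int r = 0; r < hc; ++r) {
        int p = r + c * hc, m = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr)
            ch(m++, p) = uword((2 * r + dr) + (2 * c + dc) * hf);
      }
    g.pool[l] = ch;
  }
  auto chan = [&](int l) { return base << (l - 1); };  // channels at level l
  // encoder convs
  for (int l = 1; l <= depth; ++l) {
    g.cin.push_back(l == 1 ? 1 : chan(l - 1));
    g.cout.push_back(chan(l));
    g.ksz.push_back(3); g.lev.push_back(l - 1);
  }
  // bottleneck (two convs at level depth)
  g.cin.push_back(chan(depth));     g.cout.push_back(2 * chan(depth));
  g.ksz.push_back(3);               g.lev.push_back(depth);
  g.cin.push_back(2 * chan(depth)); g.cout.push_back(2 * chan(depth));
  g.ksz.push_back(3);               g.lev.push_back(depth);
  // decoder: for l = depth..1, conv after upsample then conv after skip-add
  for (int l = depth; l >= 1; --l) {
    g.cin.push_back(l == depth ? 2 * chan(depth) : chan(l + 1));
    g.cout.push_back(chan(l));
    g.ksz.push_back(3); g.lev.push_back(l - 1);
    g.cin.push_back(chan(l)); g.cout.push_back(chan(l));
    g.ksz.push_back(3); g.lev.push_back(l - 1);
  }
  // head: 1x1 conv to a single channel
  g.cin.push_back(chan(1)); g.cout.push_back(1);
  g.ksz.push_back(1); g.lev.push_back(0);
  g.nLayers = (int)g.cin.size();
  return g;
}

mat im2col(const mat& F, const umat& nb) {
  const uword C = F.n_rows, P = F.n_cols;
  mat col(9 * C, P);
  for (uword p = 0; p < P; ++p) {
    double* dst = col.colptr(p);
    for (uword k = 0; k < 9; ++k) {
      uword q = nb(k, p);
      if (q < P) std::memcpy(dst + k * C, F.colptr(q), C * sizeof(double));
      else std::memset(dst + k * C, 0, C * sizeof(double));
    }
  }
  return col;
}

void col2imAdd(mat& dF, const mat& dCol, const umat& nb) {
  const uword C = dF.n_rows, P = dF.n_cols;
  for (uword p = 0; p < P; ++p) {
    const double* src = dCol.colptr(p);
    for (uword k = 0; k < 9; ++k) {
      uword q = nb(k, p);
      if (q < P) {
        double* dst = dF.colptr(q);
        for (uword c = 0; c < C; ++c) dst[c] += src[k * C + c];
      }
    }
  }
}

mat poolDown(const mat& F, const umat& ch) {
  mat out(F.n_rows, ch.n_cols);
  for (uword p = 0; p < ch.n_cols; ++p)
    out.col(p) = 0.25 * (F.col(ch(0, p)) + F.col(ch(1, p)) +
                         F.col(ch(2, p)) + F.col(ch(3, p)));
  return out;
}

mat poolBack(const mat& dF, const umat& ch, uword npFine) {
  mat out(dF.n_rows, npFine, fill::zeros);
  for (uword p = 0; p < ch.n_cols; ++p)
    for (int m = 0; m < 4; ++m) out.col(ch(m, p)) += 0.25 * dF.col(p);
  return out;
}

mat upsample(const mat& F, const umat& ch, uword npFine) {
  mat out(F.n_rows, npFine);
  for (uword p = 0; p < ch.n_cols; ++p)
    for (int m = 0; m < 4; ++m) out.col(ch(m, p)) = F.col(p);
  return out;
}

mat upsampleBack(const mat& dFine, const umat& ch) {
  mat out(dFine.n_rows, ch.n_cols);
  for (uword p = 0; p < ch.n_cols; ++p)
    out.col(p) = dFine.col(ch(0, p)) + dFine.col(ch(1, p)) +
                 dFine.col(ch(2, p)) + dFine.col(ch(3, p));
  return out;
}

struct Params {
  std::vector<mat> W;
  std::vector<vec> b;
};

Params unpackWeights(const Rcpp::List& weights, const Geometry& g) {
  if ((int)weights.size() != 2 * g.nLayers)
    Rcpp::stop("weight list has wrong length");
  Params p;
  for (int i = 0; i < g.nLayers; ++i) {
    mat W = Rcpp::as<mat>(weights[2 * i]);
    vec b = Rcpp::as<vec>(weights[2 * i + 1]);
    int exp_cols = g.cin[i] * g.ksz[i] * g.ksz[i];
    if ((int)W.n_rows != g.cout[i] || (int)W.n_cols != exp_cols ||
        (int)b.n_elem != g.cout[i])
      Rcpp::stop("weight matrix %d has wrong shape", i + 1);
    p.W.push_back(W); p.b.push_back(b);
  }
  return p;
}

Rcpp::List packWeights(const Params& p) {
  Rcpp::List out(2 * p.W.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    out[2 * i] = Rcpp::wrap(p.W[i]);
    out[2 * i + 1] = Rcpp::wrap(p.b[i]);
  }
  return out;
}

struct Cache {
  std::vector<mat> col;   // conv input (im2col for k=3, raw input for k=1)
  std::vector<mat> act;   // post-nonlinearity output per layer
};

mat convForward(const Params& p, const Geometry& g, int i, const mat& F,
                Cache* cache) {
  mat in = (g.ksz[i] == 3) ? im2col(F, g.nb[g.lev[i]]) : F;
  mat Z = p.W[i] * in;
  Z.each_col() += p.b[i];
  if (cache) cache->col[i] = std::move(in);
  return Z;
}

// Forward pass for one sample; x is np0-vector.  Returns the output map.
rowvec forwardOne(const Params& p, const Geometry& g, const vec& x,
                  Cache* cache) {
  const int D = g.depth;
  mat F(1, g.np[0]);
  F.row(0) = x.t();
  for (int l = 1; l <= D; ++l) {
    int i = l - 1;
    mat Z = convForward(p, g, i, F, cache);
    F = clamp(Z, 0.0, datum::inf);
    if (cache) cache->act[i] = F;
    F = poolDown(F, g.pool[l]);
  }
  for (int t = 0; t < 2; ++t) {
    int i = D + t;
    mat Z = convForward(p, g, i, F, cache);
    F = clamp(Z, 0.0, datum::inf);
    if (cache) cache->act[i] = F;
  }
  for (int j = 0; j < D; ++j) {
    int l = D - j, levf = l - 1;
    int iA = D + 2 + 2 * j, iB = iA + 1;
    F = upsample(F, g.pool[l], g.np[levf]);
    mat Z = convForward(p, g, iA, F, cache);
    F = clamp(Z, 0.0, datum::inf);
    if (cache) cache->act[iA] = F;
    // element-wise skip addition requires a cached forward pass
    if (!cache) Rcpp::stop("internal: forward without cache unsupported");
    F += cache->act[l - 1];
    Z = convForward(p, g, iB, F, cache);
    F = clamp(Z, 0.0, datum::inf);
    cache->act[iB] = F;
  }
  int iH = 3 * D + 2;
  mat Z = convForward(p, g, iH, F, cache);
  rowvec out = 1.0 / (1.0 + exp(-Z.row(0)));
  cache->act[iH] = out;
  return out;
}

// Backward pass; dOut is d(cost)/d(logit) = (prediction - target)/batchN.
void backwardOne(const Params& p, const Geometry& g, const Cache& cache,
                 const rowvec& dLogit, Params& grad) {
  const int D = g.depth;
  int iH = 3 * D + 2;
  mat dZ(1, g.np[0]);
  dZ.row(0) = dLogit;
  grad.W[iH] += dZ * cache.col[iH].t();
  grad.b[iH] += sum(dZ, 1);
  mat dF = p.W[iH].t() * dZ;
  std::vector<mat> dSkip(D + 1);
  for (int j = D - 1; j >= 0; --j) {  // decoder levels, reverse of forward
    int l = D - j, levf = l - 1;
    int iA = D + 2 + 2 * j, iB = iA + 1;
    mat dZ2 = dF % conv_to<mat>::from(cache.act[iB] > 0);
    grad.W[iB] += dZ2 * cache.col[iB].t();
    grad.b[iB] += sum(dZ2, 1);
    mat dCol = p.W[iB].t() * dZ2;
    mat dIn(g.cout[iA], g.np[levf], fill::zeros);
    col2imAdd(dIn, dCol, g.nb[levf]);
    dSkip[l] = dIn;  // gradient w.r.t. the encoder activation fed by skip
    mat dZ1 = dIn % conv_to<mat>::from(cache.act[iA] > 0);
    grad.W[iA] += dZ1 * cache.col[iA].t();
    grad.b[iA] += sum(dZ1, 1);
    dCol = p.W[iA].t() * dZ1;
    mat dUp(g.cin[iA], g.np[levf], fill::zeros);
    col2imAdd(dUp, dCol, g.nb[levf]);
    dF = upsampleBack(dUp, g.pool[l]);
  }
  for (int t = 1; t >= 0; --t) {
    int i = D + t;
    mat dZb = dF % conv_to<mat>::from(cache.act[i] > 0);
    grad.W[i] += dZb * cache.col[i].t();
    grad.b[i] += sum(dZb, 1);
    mat dCol = p.W[i].t() * dZb;
    dF.zeros(g.cin[i], g.np[D]);
    col2imAdd(dF, dCol, g.nb[D]);
  }
  for (int l = D; l >= 1; --l) {
    int i = l - 1;
    mat dFine = poolBack(dF, g.pool[l], g.np[l - 1]);
    dFine += dSkip[l];
    mat dZe = dFine % conv_to<mat>::from(cache.act[i] > 0);
    grad.W[i] += dZe * cache.col[i].t();
    grad.b[i] += sum(dZe, 1);
    if (l > 1) {
      mat dCol = p.W[i].t() * dZe;
      dF.zeros(g.cin[i], g.np[l - 1]);
      col2imAdd(dF, dCol, g.nb[l - 1]);
    }
  }
}

double bceLoss(const rowvec& pred, const rowvec& y, double eps) {
  rowvec ph = clamp(pred, eps, 1.0 - eps);
  return -accu(y % log(ph) + (1.0 - y) % log(1.0 - ph));
}

Params zeroLike(const Params& p) {
  Params z;
  for (size_t i = 0; i < p.W.size(); ++i) {
    z.W.push_back(mat(p.W[i].n_rows, p.W[i].n_cols, fill::zeros));
    z.b.push_back(vec(p.b[i].n_elem, fill::zeros));
  }
  return z;
}

}  // namespace

// Layer dimensions (cout, cin, kernel) in weight-list order, so the caller
// can initialize the parameter list.
// [[Rcpp::export(name = ".unetLayerDims")]]
Rcpp::IntegerMatrix unetLayerDims(int depth, int base) {
  Geometry g = makeGeometry(depth, base, 1 << depth);
  Rcpp::IntegerMatrix out(g.nLayers, 3);
  for (int i = 0; i < g.nLayers; ++i) {
    out(i, 0) = g.cout[i]; out(i, 1) = g.cin[i]; out(i, 2) = g.ksz[i];
  }
  colnames(out) = Rcpp::CharacterVector::create("cout", "cin", "kernel");
  return out;
}

// Forward pass on a batch: X is (npix x nsamples); returns same shape.
// [[Rcpp::export(name = ".unetForward")]]
arma::mat unetForward(Rcpp::List weights, const arma::mat& X, int inputDim,
                      int depth, int base) {
  Geometry g = makeGeometry(depth, base, inputDim);
  if ((int)X.n_rows != g.np[0]) Rcpp::stop("input size mismatch");
  Params p = unpackWeights(weights, g);
  mat out(X.n_rows, X.n_cols);
  Cache cache;
  cache.col.resize(g.nLayers); cache.act.resize(g.nLayers);
  for (uword s = 0; s < X.n_cols; ++s)
    out.col(s) = forwardOne(p, g, X.col(s), &cache).t();
  return out;
}

// Aggregate BCE cost and its gradient for a batch (mean over samples of the
// per-image pixel sum); used by the finite-difference correctness test.
// [[Rcpp::export(name = ".unetLossGrad")]]
Rcpp::List unetLossGrad(Rcpp::List weights, const arma::mat& X,
                        const arma::mat& Y, int inputDim, int depth,
                        int base, double clampEps) {
  Geometry g = makeGeometry(depth, base, inputDim);
  Params p = unpackWeights(weights, g);
  Params grad = zeroLike(p);
  Cache cache;
  cache.col.resize(g.nLayers); cache.act.resize(g.nLayers);
  double loss = 0;
  const double n = (double)X.n_cols;
  for (uword s = 0; s < X.n_cols; ++s) {
    rowvec pred = forwardOne(p, g, X.col(s), &cache);
    rowvec y = Y.col(s).t();
    loss += bceLoss(pred, y, clampEps) / n;
    backwardOne(p, g, cache, (pred - y) / n, grad);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = packWeights(grad));
}

// Adam training.  order: (nsamples x epochs) matrix of 1-based sample
// indices fixing the shuffling (drawn on the R side for seed control).
// [[Rcpp::export(name = ".unetTrain")]]
Rcpp::List unetTrain(Rcpp::List weights, const arma::mat& X,
                     const arma::mat& Y, int inputDim, int depth, int base,
                     const arma::imat& order, int batchSize, double lr,
                     double clampEps) {
  Geometry g = makeGeometry(depth, base, inputDim);
  Params p = unpackWeights(weights, g);
  Params m = zeroLike(p), v = zeroLike(p);
  const int nSamples = X.n_cols, nEpochs = order.n_cols;
  if ((int)order.n_rows != nSamples) Rcpp::stop("order/sample mismatch");
  const double b1 = 0.9, b2 = 0.999, adamEps = 1e-8;
  double t = 0;
  Cache cache;
  cache.col.resize(g.nLayers); cache.act.resize(g.nLayers);
  std::vector<double> history;
  for (int e = 0; e < nEpochs; ++e) {
    double epochLoss = 0;
    for (int start = 0; start < nSamples; start += batchSize) {
      int stop = std::min(start + batchSize, nSamples) - 1;
      double bn = stop - start + 1;
      Params grad = zeroLike(p);
      for (int k = start; k <= stop; ++k) {
        int s = order(k, e) - 1;
        if (s < 0 || s >= nSamples) Rcpp::stop("order index out of range");
        rowvec pred = forwardOne(p, g, X.col(s), &cache);
        rowvec y = Y.col(s).t();
        epochLoss += bceLoss(pred, y, clampEps);
        backwardOne(p, g, cache, (pred - y) / bn, grad);
      }
      t += 1;
      double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
      for (int i = 0; i < g.nLayers; ++i) {
        m.W[i] = b1 * m.W[i] + (1 - b1) * grad.W[i];
        v.W[i] = b2 * v.W[i] + (1 - b2) * square(grad.W[i]);
        p.W[i] -= lr * (m.W[i] / c1) / (sqrt(v.W[i] / c2) + adamEps);
        m.b[i] = b1 * m.b[i] + (1 - b1) * grad.b[i];
        v.b[i] = b2 * v.b[i] + (1 - b2) * square(grad.b[i]);
        p.b[i] -= lr * (m.b[i] / c1) / (sqrt(v.b[i] / c2) + adamEps);
      }
      if (!std::isfinite(epochLoss))
        Rcpp::stop("non-finite training cost at epoch %d", e + 1);
    }
    history.push_back(epochLoss / nSamples);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = packWeights(p),
                            Rcpp::Named("history") = Rcpp::wrap(history));
}
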