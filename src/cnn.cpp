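// 3D convolutional regression network on cubic voxel grids.
//
// Architecture: four "fire" stages (1x1x1 squeeze convolution + ReLU, then
// 3x3x3 same-padded expand convolution + ReLU), optional 2x2x2 max or average
// pooling after each stage, inverted dropout applied to the input of the last
// stage during training, global average pooling over the final feature maps,
// and a linear scalar head. Channels-first storage: a feature tensor on an
// N^3 grid with C channels is a C x N^3 matrix, voxel index v = x + N*(y + N*z).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3^3 kernel with zero padding 1 on an N^3 grid.
// in: C x N^3 -> out: (C*27) x N^3, row index = c*27 + t, t enumerating the
// 27 neighbor offsets in (dx,dy,dz) lexicographic order, dx fastest.
static arma::mat im2col3(const arma::mat& in, int N) {
  const int C = in.n_rows;
  const arma::uword V = (arma::uword)N * N * N;
  arma::mat out(C * 27, V, arma::fill::zeros);
  for (int z = 0; z < N; ++z)
    for (int y = 0; y < N; ++y)
      for (int x = 0; x < N; ++x) {
        const arma::uword v = x + (arma::uword)N * (y + (arma::uword)N * z);
        int t = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx, ++t) {
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= N || yy >= N || zz >= N)
                continue;
              const arma::uword u = xx + (arma::uword)N * (yy + (arma::uword)N * zz);
              for (int c = 0; c < C; ++c)
                out(c * 27 + t, v) = in(c, u);
            }
      }
  return out;
}

// Adjoint of im2col3: scatter gradient back onto the C x N^3 input.
static arma::mat col2im3(const arma::mat& gcol, int N, int C) {
  const arma::uword V = (arma::uword)N * N * N;
  arma::mat out(C, V, arma::fill::zeros);
  for (int z = 0; z < N; ++z)
    for (int y = 0; y < N; ++y)
      for (int x = 0; x < N; ++x) {
        const arma::uword v = x + (arma::uword)N * (y + (arma::uword)N * z);
        int t = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx, ++t) {
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= N || yy >= N || zz >= N)
                continue;
              const arma::uword u = xx + (arma::uword)N * (yy + (arma::uword)N * zz);
              for (int c = 0; c < C; ++c)
                out(c, u) += gcol(c * 27 + t, v);
            }
      }
  return out;
}

// 2x2x2 pooling (N even). mode 1 = max (records argmax), 2 = average.
static arma::mat pool2(const arma::mat& in, int N, int mode, arma::umat& argmax) {
  const int M = N / 2;
  const int C = in.n_rows;
  const arma::uword Vo = (arma::uword)M * M * M;
  arma::mat out(C, Vo);
  if (mode == 1) argmax.set_size(C, Vo);
  for (int z = 0; z < M; ++z)
    for (int y = 0; y < M; ++y)
      for (int x = 0; x < M; ++x) {
        const arma::uword vo = x + (arma::uword)M * (y + (arma::uword)M * z);
        arma::uword src[8]; int ns = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              src[ns++] = (2*x+dx) + (arma::uword)N * ((2*y+dy) + (arma::uword)N * (2*z+dz));
        for (int c = 0; c < C; ++c) {
          if (mode == 1) {
            double best = in(c, src[0]); arma::uword bi = src[0];
            for (int s = 1; s < 8; ++s)
              if (in(c, src[s]) > best) { best = in(c, src[s]); bi = src[s]; }
            out(c, vo) = best; argmax(c, vo) = bi;
          } else {
            double acc = 0.0;
            for (int s = 0; s < 8; ++s) acc += in(c, src[s]);
            out(c, vo) = acc / 8.0;
          }
        }
      }
  return out;
}

static arma::mat unpool2(const arma::mat& g, int N, int mode, const arma::umat& argmax) {
  const int M = N / 2;
  const int C = g.n_rows;
  arma::mat out(C, (arma::uword)N * N * N, arma::fill::zeros);
  for (int z = 0; z < M; ++z)
    for (int y = 0; y < M; ++y)
      for (int x = 0; x < M; ++x) {
        const arma::uword vo = x + (arma::uword)M * (y + (arma::uword)M * z);
        if (mode == 1) {
          for (int c = 0; c < C; ++c) out(c, argmax(c, vo)) += g(c, vo);
        } else {
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const arma::uword u = (2*x+dx) + (arma::uword)N * ((2*y+dy) + (arma::uword)N * (2*z+dz));
                for (int c = 0; c < C; ++c) out(c, u) += g(c, vo) / 8.0;
              }
        }
      }
  return out;
}

struct StageW {
  arma::mat Wsq; arma::vec bsq;   // squeeze: Sq x Cin, 1^3
  arma::mat Wex; arma::vec bex;   // expand:  Ex x (Sq*27), 3^3
};

static std::vector<StageW> unpack_stages(const List& weights) {
  List stages = weights["stages"];
  std::vector<StageW> out(stages.size());
  for (int s = 0; s < stages.size(); ++s) {
    List st = stages[s];
    out[s].Wsq = as<arma::mat>(st["Wsq"]);
    out[s].bsq = as<arma::vec>(st["bsq"]);
    out[s].Wex = as<arma::mat>(st["Wex"]);
    out[s].bex = as<arma::vec>(st["bex"]);
  }
  return out;
}

// Forward pass for one sample; optionally keeps intermediates for backprop.
struct FwdCache {
  std::vector<arma::mat> Xin, A1, Col, A2pre, A2;  // per stage
  std::vector<arma::umat> argmax;
  std::vector<int> Nin, Nout;
  arma::vec gap;
  arma::mat dropmask;     // empty when not training
  double yhat;
};

static void forward_one(const std::vector<StageW>& W, const IntegerVector& pool,
                        const arma::vec& head_w, double head_b,
                        arma::mat X, int N, int dropout_stage,
                        const arma::mat* dropmask, FwdCache* cache,
                        double* yhat_out) {
  const int S = (int)W.size();
  FwdCache local;
  FwdCache& cc = cache ? *cache : local;
  cc.Xin.resize(S); cc.A1.resize(S); cc.Col.resize(S);
  cc.A2pre.resize(S); cc.A2.resize(S); cc.argmax.resize(S);
  cc.Nin.resize(S); cc.Nout.resize(S);
  for (int s = 0; s < S; ++s) {
    if (s == dropout_stage && dropmask && dropmask->n_elem > 0)
      X %= *dropmask;
    if (cache) cc.Xin[s] = X;
    cc.Nin[s] = N;
    arma::mat Z1 = W[s].Wsq * X;
    Z1.each_col() += W[s].bsq;
    arma::mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
    arma::mat C = im2col3(A1, N);
    arma::mat Z2 = W[s].Wex * C;
    Z2.each_col() += W[s].bex;
    arma::mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);
    if (cache) { cc.A1[s] = A1; cc.Col[s] = std::move(C); cc.A2pre[s] = Z2; }
    if (pool[s] != 0) {
      arma::umat am;
      X = pool2(A2, N, pool[s], am);
      N /= 2;
      if (cache) { cc.A2[s] = std::move(A2); cc.argmax[s] = std::move(am); }
    } else {
      if (cache) cc.A2[s] = A2;
      X = std::move(A2);
    }
    cc.Nout[s] = N;
  }
  arma::vec gap = arma::mean(X, 1);
  double yhat = arma::dot(head_w, gap) + head_b;
  if (cache) { cc.gap = gap; cc.yhat = yhat; }
  *yhat_out = yhat;
}

// Predictions for a batch. X: (Cin*N^3) x nsamp matrix, channels-first per
// column. No dropout at inference.
// [[Rcpp::export]]
NumericVector cpp_cnn_forward(const List& weights, const arma::mat& X,
                              int N, int Cin, const IntegerVector& pool) {
  std::vector<StageW> W = unpack_stages(weights);
  arma::vec head_w = as<arma::vec>(weights["head_w"]);
  double head_b = as<double>(weights["head_b"]);
  const int nsamp = X.n_cols;
  NumericVector out(nsamp);
  for (int i = 0; i < nsamp; ++i) {
    arma::mat Xi(const_cast<double*>(X.colptr(i)), Cin,
                 (arma::uword)N * N * N, false, true);
    double yh;
    forward_one(W, pool, head_w, head_b, Xi, N, -1, nullptr, nullptr, &yh);
    out[i] = yh;
  }
  return out;
}

// Mean-squared-error loss and weight gradients over a mini-batch.
// dropout_p > 0 applies inverted dropout to the input of the last stage,
// with an element mask drawn per sample from a deterministic RNG.
// [[Rcpp::export]]
List cpp_cnn_grad(const List& weights, const arma::mat& X, const arma::vec& y,
                  int N, int Cin, const IntegerVector& pool,
                  double dropout_p, int seed) {
  std::vector<StageW> W = unpack_stages(weights);
  arma::vec head_w = as<arma::vec>(weights["head_w"]);
  double head_b = as<double>(weights["head_b"]);
  const int S = (int)W.size();
  const int nsamp = X.n_cols;
  const int drop_stage = (dropout_p > 0.0) ? S - 1 : -1;

  std::vector<arma::mat> gWsq(S), gWex(S);
  std::vector<arma::vec> gbsq(S), gbex(S);
  for (int s = 0; s < S; ++s) {
    gWsq[s].zeros(W[s].Wsq.n_rows, W[s].Wsq.n_cols);
    gbsq[s].zeros(W[s].bsq.n_elem);
    gWex[s].zeros(W[s].Wex.n_rows, W[s].Wex.n_cols);
    gbex[s].zeros(W[s].bex.n_elem);
  }
  arma::vec ghead_w(head_w.n_elem, arma::fill::zeros);
  double ghead_b = 0.0, loss = 0.0;
  NumericVector preds(nsamp);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  for (int i = 0; i < nsamp; ++i) {
    arma::mat Xi(const_cast<double*>(X.colptr(i)), Cin,
                 (arma::uword)N * N * N, false, true);
    arma::mat dropmask;
    if (drop_stage >= 0) {
      // stage input dims: channels of stage drop_stage, grid after prior pools
      int Nd = N;
      for (int s = 0; s < drop_stage; ++s) if (pool[s] != 0) Nd /= 2;
      const int Cd = W[drop_stage].Wsq.n_cols;
      dropmask.set_size(Cd, (arma::uword)Nd * Nd * Nd);
      const double keep = 1.0 - dropout_p;
      for (arma::uword t = 0; t < dropmask.n_elem; ++t)
        dropmask(t) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    }
    FwdCache cc;
    double yh;
    forward_one(W, pool, head_w, head_b, Xi, N, drop_stage,
                drop_stage >= 0 ? &dropmask : nullptr, &cc, &yh);
    preds[i] = yh;
    const double err = yh - y(i);
    loss += err * err;

    // backward
    const double dy = 2.0 * err / nsamp;
    ghead_w += dy * cc.gap;
    ghead_b += dy;
    const int Slast = S - 1;
    arma::uword Vout = (arma::uword)cc.Nout[Slast] * cc.Nout[Slast] * cc.Nout[Slast];
    arma::mat gX = (dy / (double)Vout) * head_w * arma::ones<arma::rowvec>(Vout);
    for (int s = Slast; s >= 0; --s) {
      if (pool[s] != 0) gX = unpool2(gX, cc.Nin[s], pool[s], cc.argmax[s]);
      arma::mat gZ2 = gX % arma::conv_to<arma::mat>::from(cc.A2pre[s] > 0);
      gWex[s] += gZ2 * cc.Col[s].t();
      gbex[s] += arma::sum(gZ2, 1);
      arma::mat gCol = W[s].Wex.t() * gZ2;
      arma::mat gA1 = col2im3(gCol, cc.Nin[s], cc.A1[s].n_rows);
      arma::mat gZ1 = gA1 % arma::conv_to<arma::mat>::from(cc.A1[s] > 0);
      gWsq[s] += gZ1 * cc.Xin[s].t();
      gbsq[s] += arma::sum(gZ1, 1);
      if (s > 0 || drop_stage == 0) {
        gX = W[s].Wsq.t() * gZ1;
        if (s == drop_stage && dropmask.n_elem > 0) gX %= dropmask;
      }
    }
  }
  // dy already carries the 1/nsamp of the batch-mean loss
  List stages(S);
  for (int s = 0; s < S; ++s)
    stages[s] = List::create(_["Wsq"] = gWsq[s], _["bsq"] = gbsq[s],
                             _["Wex"] = gWex[s], _["bex"] = gbex[s]);
  return List::create(_["loss"] = loss / nsamp,
                      _["preds"] = preds,
                      _["stages"] = stages,
                      _["head_w"] = ghead_w, _["head_b"] = ghead_b);
}
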