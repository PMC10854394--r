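// Compact 3D convolutional network engine for volume-level artifact
// classification: blocks of [conv3d(3x3x3, same padding) + ReLU ->
// maxpool(2, stride 2) -> batch norm], then dense(128) + dropout ->
// dense(128) -> sigmoid(1); binary cross-entropy + Adam.
//
// Activations are float32, channel-major (channels contiguous per voxel) with
// a one-voxel zero halo so the 27-point stencil needs no boundary tests; the
// convolutions run as register-blocked direct stencils templated on channel
// count, which on small channel widths far outperforms im2col + GEMM.
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Shape3 {
  int x, y, z;
  long n() const { return (long)x * y * z; }
  long pn() const { return (long)(x + 2) * (y + 2) * (z + 2); }
};

// flush subnormal floats to zero: tiny backpropagated gradients otherwise
// trigger the hardware denormal penalty and stall the conv kernels.
static void enable_ftz() {
#ifdef __SSE2__
  _mm_setcsr(_mm_getcsr() | 0x8040);
#endif
}

static Shape3 halve(const Shape3& d) { return Shape3{d.x / 2, d.y / 2, d.z / 2}; }

static void offsets27(const Shape3& d, long* off) {
  const long PX = d.x + 2, PY = d.y + 2;
  int j = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++j) off[j] = dx + PX * (dy + PY * (long)dz);
}

static long pvox(const Shape3& d, int x, int y, int z) {
  return (x + 1) + (long)(d.x + 2) * ((y + 1) + (long)(d.y + 2) * (z + 1));
}

// ---------------------------------------------------------------------------
// forward convolution + ReLU; `in` stride cin, `out` stride CS (>= cout, the
// extra channels carry zero weights); both padded channel-major buffers.
template <int CS>
static void conv_relu_fwd_t(const float* __restrict__ in, int cin,
                            const float* __restrict__ w,
                            const float* __restrict__ bias,
                            float* __restrict__ out, const Shape3& d) {
  long off[27];
  offsets27(d, off);
  const int TS = 4;
  for (int z = 0; z < d.z; ++z)
    for (int y = 0; y < d.y; ++y) {
      long srow = pvox(d, 0, y, z);
      for (int x0 = 0; x0 < d.x; x0 += TS) {
        int nt = (d.x - x0) < TS ? (d.x - x0) : TS;
        if (nt == TS) {
          float acc[TS][CS];
          for (int k = 0; k < TS; ++k)
            for (int c = 0; c < CS; ++c) acc[k][c] = bias[c];
          for (int j = 0; j < 27; ++j) {
            const long t0 = (srow + x0 + off[j]) * cin;
            for (int ci = 0; ci < cin; ++ci) {
              const float* wv = w + (size_t)CS * (ci + (size_t)cin * j);
              for (int k = 0; k < TS; ++k) {
                float a = in[t0 + (long)k * cin + ci];
                for (int c = 0; c < CS; ++c) acc[k][c] += wv[c] * a;
              }
            }
          }
          for (int k = 0; k < TS; ++k) {
            float* o = out + (size_t)CS * (srow + x0 + k);
            for (int c = 0; c < CS; ++c) o[c] = acc[k][c] > 0 ? acc[k][c] : 0.0f;
          }
        } else {
          for (int k = 0; k < nt; ++k) {
            float acc[CS];
            for (int c = 0; c < CS; ++c) acc[c] = bias[c];
            for (int j = 0; j < 27; ++j) {
              const long t = (srow + x0 + k + off[j]) * cin;
              for (int ci = 0; ci < cin; ++ci) {
                const float* wv = w + (size_t)CS * (ci + (size_t)cin * j);
                float a = in[t + ci];
                for (int c = 0; c < CS; ++c) acc[c] += wv[c] * a;
              }
            }
            float* o = out + (size_t)CS * (srow + x0 + k);
            for (int c = 0; c < CS; ++c) o[c] = acc[c] > 0 ? acc[c] : 0.0f;
          }
        }
      }
    }
}

static void conv_relu_fwd_g(const float* in, int cin, const float* w,
                            const float* bias, float* out, int cs, const Shape3& d) {
  long off[27];
  offsets27(d, off);
  std::vector<float> acc(cs);
  for (int z = 0; z < d.z; ++z)
    for (int y = 0; y < d.y; ++y)
      for (int x = 0; x < d.x; ++x) {
        long s = pvox(d, x, y, z);
        for (int c = 0; c < cs; ++c) acc[c] = bias[c];
        for (int j = 0; j < 27; ++j) {
          const long t = (s + off[j]) * cin;
          for (int ci = 0; ci < cin; ++ci) {
            const float* wv = w + (size_t)cs * (ci + (size_t)cin * j);
            float a = in[t + ci];
            for (int c = 0; c < cs; ++c) acc[c] += wv[c] * a;
          }
        }
        float* o = out + (size_t)cs * s;
        for (int c = 0; c < cs; ++c) o[c] = acc[c] > 0 ? acc[c] : 0.0f;
      }
}

// gradient wrt weights: dw[co + cs*(ci + cin*j)] += sum_s dout[co,s]*in[ci,s+off_j]
template <int CS>
static void conv_bwd_dw_t(const float* __restrict__ in, int cin,
                          const float* __restrict__ dout, float* __restrict__ dw,
                          const Shape3& d) {
  long off[27];
  offsets27(d, off);
  const int TS = 4;
  for (int z = 0; z < d.z; ++z)
    for (int y = 0; y < d.y; ++y) {
      long srow = pvox(d, 0, y, z);
      for (int x0 = 0; x0 < d.x; x0 += TS) {
        int nt = (d.x - x0) < TS ? (d.x - x0) : TS;
        for (int j = 0; j < 27; ++j) {
          const long t0 = (srow + x0 + off[j]) * cin;
          for (int ci = 0; ci < cin; ++ci) {
            float* __restrict__ dwv = dw + (size_t)CS * (ci + (size_t)cin * j);
            for (int k = 0; k < nt; ++k) {
              float a = in[t0 + (long)k * cin + ci];
              const float* __restrict__ g = dout + (size_t)CS * (srow + x0 + k);
              #pragma GCC ivdep
              for (int c = 0; c < CS; ++c) dwv[c] += g[c] * a;
            }
          }
        }
      }
    }
}

static void conv_bwd_dw_g(const float* in, int cin, const float* dout, float* dw,
                          int cs, const Shape3& d) {
  long off[27];
  offsets27(d, off);
  for (int z = 0; z < d.z; ++z)
    for (int y = 0; y < d.y; ++y)
      for (int x = 0; x < d.x; ++x) {
        long s = pvox(d, x, y, z);
        const float* g = dout + (size_t)cs * s;
        for (int j = 0; j < 27; ++j) {
          const long t = (s + off[j]) * cin;
          for (int ci = 0; ci < cin; ++ci) {
            float a = in[t + ci];
            float* dwv = dw + (size_t)cs * (ci + (size_t)cin * j);
            for (int c = 0; c < cs; ++c) dwv[c] += g[c] * a;
          }
        }
      }
}

// gradient wrt input: din[ci + cin*(s+off_j)] += sum_co wT[ci + cin*(co+cout*j)]*dout[co,s]
// adjacent x voxels are processed in pairs so the scatter-add hits one
// contiguous 2*CIN-float span (keeps the store vectorizable at CIN = 8).
template <int CIN>
static void conv_bwd_din_t(float* __restrict__ din, const float* __restrict__ wT,
                           int cout, int cs, const float* __restrict__ dout,
                           const Shape3& d) {
  long off[27];
  offsets27(d, off);
  for (int z = 0; z < d.z; ++z)
    for (int y = 0; y < d.y; ++y) {
      int x = 0;
      for (; x + 1 < d.x; x += 2) {
        long s = pvox(d, x, y, z);
        const float* __restrict__ g0 = dout + (size_t)cs * s;
        const float* __restrict__ g1 = g0 + cs;
        for (int j = 0; j < 27; ++j) {
          float acc[2 * CIN];
          #pragma GCC ivdep
          for (int c = 0; c < 2 * CIN; ++c) acc[c] = 0.0f;
          const float* __restrict__ wj = wT + (size_t)CIN * (size_t)cout * j;
          for (int co = 0; co < cout; ++co) {
            float ga = g0[co], gb = g1[co];
            const float* __restrict__ wv = wj + (size_t)CIN * co;
            #pragma GCC ivdep
            for (int c = 0; c < CIN; ++c) {
              acc[c] += wv[c] * ga;
              acc[CIN + c] += wv[c] * gb;
            }
          }
          float* __restrict__ dst = din + (s + off[j]) * CIN;
          #pragma GCC ivdep
          for (int c = 0; c < 2 * CIN; ++c) dst[c] += acc[c];
        }
      }
      for (; x < d.x; ++x) {
        long s = pvox(d, x, y, z);
        const float* __restrict__ g = dout + (size_t)cs * s;
        for (int j = 0; j < 27; ++j) {
          float acc[CIN];
          #pragma GCC ivdep
          for (int c = 0; c < CIN; ++c) acc[c] = 0.0f;
          const float* __restrict__ wj = wT + (size_t)CIN * (size_t)cout * j;
          for (int co = 0; co < cout; ++co) {
            float gv = g[co];
            const float* __restrict__ wv = wj + (size_t)CIN * co;
            #pragma GCC ivdep
            for (int c = 0; c < CIN; ++c) acc[c] += wv[c] * gv;
          }
          float* __restrict__ dst = din + (s + off[j]) * CIN;
          #pragma GCC ivdep
          for (int c = 0; c < CIN; ++c) dst[c] += acc[c];
        }
      }
    }
}

static void conv_bwd_din_g(float* din, int cin, const float* wT, int cout, int cs,
                           const float* dout, const Shape3& d) {
  long off[27];
  offsets27(d, off);
  std::vector<float> acc(cin);
  for (int z = 0; z < d.z; ++z)
    for (int y = 0; y < d.y; ++y)
      for (int x = 0; x < d.x; ++x) {
        long s = pvox(d, x, y, z);
        const float* g = dout + (size_t)cs * s;
        for (int j = 0; j < 27; ++j) {
          std::fill(acc.begin(), acc.end(), 0.0f);
          const float* wj = wT + (size_t)cin * (size_t)cout * j;
          for (int co = 0; co < cout; ++co) {
            float gv = g[co];
            const float* wv = wj + (size_t)cin * co;
            for (int c = 0; c < cin; ++c) acc[c] += wv[c] * gv;
          }
          float* dst = din + (s + off[j]) * cin;
          for (int c = 0; c < cin; ++c) dst[c] += acc[c];
        }
      }
}

// ---------------------------------------------------------------------------
struct AdamState {
  arma::fmat m, v;
  void init(arma::uword r, arma::uword c) { m.zeros(r, c); v.zeros(r, c); }
};

struct Block {
  int cin, cout, cs;             // cs: conv buffer channel stride (>= cout)
  int gs, cin_pad;               // grad-buffer stride and padded input width
  Shape3 din, dpool;             // conv (=input) and pooled spatial dims
  // canonical parameters; conv weight rows indexed ci*27 + j
  arma::fmat W;                  // (cin*27) x cout
  arma::frowvec b, gamma, beta, rmean, rvar;
  AdamState aW, ab, agamma, abeta;
  // internal compute layouts
  std::vector<float> wint;       // co + cs*(ci + cin*j), co >= cout zero
  std::vector<float> wT;         // ci + cin*(co + cout*j)
  std::vector<float> bint;       // cs
  // per-batch buffers (padded channel-major)
  std::vector<float> conv;       // B * cs * din.pn()   (post-ReLU)
  std::vector<float> pooled;     // B * cout * dpool.pn() (pre-BN)
  std::vector<float> bnout;      // B * cout * dpool.pn()
  std::vector<float> grad;       // d(bnout), same size
  std::vector<float> dconv;      // B * cs * din.pn()
  std::vector<int>   argmax;     // B * cout * dpool.n(), conv spatial index
  arma::frowvec mu, var;
  // gradients (canonical)
  arma::fmat gW;
  arma::frowvec gb, ggamma, gbeta;
};

struct Dense {
  arma::fmat W;
  arma::frowvec b;
  AdamState aW, ab;
  arma::fmat in, out;
  arma::fmat gW;
  arma::frowvec gb;
};

struct QCNet {
  Shape3 input;
  std::vector<int> filters;
  int dense_units;
  double dropout;
  std::vector<Block> blocks;
  Dense d1, d2, d3;
  long flat;
  std::mt19937 rng;
  long step = 0;
  int seed;
  int cur_B = -1;
  std::vector<float> input_buf;  // B * input.pn()
  static constexpr double bn_eps = 1e-5, bn_mom = 0.1;
};

static void refresh_internal(Block& blk) {
  const int cin = blk.cin, cout = blk.cout, cs = blk.cs, cp = blk.cin_pad;
  std::fill(blk.wT.begin(), blk.wT.end(), 0.0f);
  std::fill(blk.wint.begin(), blk.wint.end(), 0.0f);
  for (int j = 0; j < 27; ++j)
    for (int ci = 0; ci < cin; ++ci)
      for (int co = 0; co < cout; ++co) {
        float w = blk.W(ci * 27 + j, co);
        blk.wint[(size_t)co + (size_t)cs * (ci + (size_t)cin * j)] = w;
        blk.wT[(size_t)ci + (size_t)cp * (co + (size_t)cout * j)] = w;
      }
  for (int c = 0; c < cs; ++c) blk.bint[c] = c < cout ? blk.b[c] : 0.0f;
}

static void he_init(arma::fmat& W, int fan_in, std::mt19937& rng) {
  std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / fan_in));
  for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = nd(rng);
}

// [[Rcpp::export(name = ".qcnet_create")]]
SEXP qcnet_create(IntegerVector input_shape, IntegerVector filters,
                  int dense_units, double dropout, int seed) {
  std::unique_ptr<QCNet> net(new QCNet());
  net->input = Shape3{input_shape[0], input_shape[1], input_shape[2]};
  net->filters = as<std::vector<int>>(filters);
  net->dense_units = dense_units;
  net->dropout = dropout;
  net->seed = seed;
  net->rng.seed((unsigned)seed);

  Shape3 d = net->input;
  int cin = 1;
  const char axname[4] = "xyz";
  for (size_t k = 0; k < net->filters.size(); ++k) {
    int half[3] = {d.x / 2, d.y / 2, d.z / 2};
    for (int a = 0; a < 3; ++a)
      if (half[a] < 1)
        stop("input axis '%s' too small: max pooling in block %d would shrink it below 1 voxel",
             std::string(1, axname[a]).c_str(), (int)k + 1);
    Block blk;
    blk.cin = cin;
    blk.cout = net->filters[k];
    blk.cs = (blk.cout == 8) ? 16 : blk.cout;  // pad 8 channels to a full SIMD lane
    auto pad_up = [](int c) { return c <= 16 ? 16 : (c <= 32 ? 32 : (c <= 64 ? 64 : c)); };
    blk.gs = pad_up(blk.cout);
    blk.cin_pad = pad_up(cin);
    blk.din = d;
    blk.dpool = halve(d);
    blk.W.set_size(cin * 27, blk.cout);
    he_init(blk.W, cin * 27, net->rng);
    blk.b.zeros(blk.cout);
    blk.gamma.ones(blk.cout);
    blk.beta.zeros(blk.cout);
    blk.rmean.zeros(blk.cout);
    blk.rvar.ones(blk.cout);
    blk.aW.init(blk.W.n_rows, blk.W.n_cols);
    blk.ab.init(1, blk.cout);
    blk.agamma.init(1, blk.cout);
    blk.abeta.init(1, blk.cout);
    blk.wint.assign((size_t)blk.cs * cin * 27, 0.0f);
    blk.wT.assign((size_t)blk.cin_pad * blk.cout * 27, 0.0f);
    blk.bint.assign(blk.cs, 0.0f);
    refresh_internal(blk);
    net->blocks.push_back(std::move(blk));
    d = halve(d);
    cin = net->filters[k];
  }
  net->flat = d.n() * cin;
  auto mk = [&](Dense& dl, int nin, int nout) {
    dl.W.set_size(nin, nout);
    he_init(dl.W, nin, net->rng);
    dl.b.zeros(nout);
    dl.aW.init(nin, nout);
    dl.ab.init(1, nout);
  };
  mk(net->d1, net->flat, dense_units);
  mk(net->d2, dense_units, dense_units);
  mk(net->d3, dense_units, 1);
  XPtr<QCNet> ptr(net.release(), true);
  return ptr;
}

static void ensure_buffers(QCNet* net, int B) {
  if (net->cur_B == B) return;
  net->input_buf.assign((size_t)B * net->input.pn(), 0.0f);
  for (auto& blk : net->blocks) {
    blk.conv.assign((size_t)B * blk.cs * blk.din.pn(), 0.0f);
    blk.pooled.assign((size_t)B * blk.cout * blk.dpool.pn(), 0.0f);
    blk.bnout.assign((size_t)B * blk.cout * blk.dpool.pn(), 0.0f);
    blk.grad.assign((size_t)B * blk.gs * blk.dpool.pn(), 0.0f);
    blk.dconv.assign((size_t)B * blk.cs * blk.din.pn(), 0.0f);
    blk.argmax.assign((size_t)B * blk.cout * blk.dpool.n(), 0);
  }
  net->cur_B = B;
}

static void pool_fwd(Block& blk, int B) {
  const Shape3 di = blk.din, dp = blk.dpool;
  const int cs = blk.cs, cout = blk.cout;
  const long PNi = di.pn(), PNp = dp.pn(), Np = dp.n();
  const long PXi = di.x + 2, PYi = di.y + 2;
  for (int b = 0; b < B; ++b) {
    const float* src = blk.conv.data() + (size_t)b * cs * PNi;
    float* out = blk.pooled.data() + (size_t)b * cout * PNp;
    int* am = blk.argmax.data() + (size_t)b * cout * Np;
    long k = 0;
    for (int z = 0; z < dp.z; ++z)
      for (int y = 0; y < dp.y; ++y)
        for (int x = 0; x < dp.x; ++x, ++k) {
          long base = pvox(di, 2 * x, 2 * y, 2 * z);
          long cand[8] = {base, base + 1, base + PXi, base + PXi + 1,
                          base + PXi * PYi, base + PXi * PYi + 1,
                          base + PXi * PYi + PXi, base + PXi * PYi + PXi + 1};
          float* o = out + (size_t)cout * pvox(dp, x, y, z);
          for (int c = 0; c < cout; ++c) {
            float best = src[c + (size_t)cs * cand[0]];
            long bi = cand[0];
            for (int q = 1; q < 8; ++q) {
              float v = src[c + (size_t)cs * cand[q]];
              if (v > best) { best = v; bi = cand[q]; }
            }
            o[c] = best;
            am[(size_t)c * Np + k] = (int)bi;
          }
        }
  }
}

// batch-norm forward over interior voxels; train uses batch statistics.
static void bn_fwd(QCNet* net, Block& blk, int B, bool train) {
  const Shape3 dp = blk.dpool;
  const int cout = blk.cout;
  const long PNp = dp.pn();
  arma::frowvec mu(cout, arma::fill::zeros), m2(cout, arma::fill::zeros);
  const double n = (double)B * dp.n();
  if (train) {
    for (int b = 0; b < B; ++b) {
      const float* src = blk.pooled.data() + (size_t)b * cout * PNp;
      for (int z = 0; z < dp.z; ++z)
        for (int y = 0; y < dp.y; ++y) {
          long row = pvox(dp, 0, y, z);
          for (int x = 0; x < dp.x; ++x) {
            const float* v = src + (size_t)cout * (row + x);
            for (int c = 0; c < cout; ++c) {
              mu[c] += v[c];
              m2[c] += v[c] * v[c];
            }
          }
        }
    }
    mu /= (float)n;
    m2 /= (float)n;
    blk.mu = mu;
    blk.var = arma::max(m2 - arma::square(mu), arma::frowvec(cout, arma::fill::zeros));
    blk.rmean = (float)(1 - QCNet::bn_mom) * blk.rmean + (float)QCNet::bn_mom * blk.mu;
    blk.rvar = (float)(1 - QCNet::bn_mom) * blk.rvar + (float)QCNet::bn_mom * blk.var;
  }
  const arma::frowvec& m = train ? blk.mu : blk.rmean;
  const arma::frowvec& v = train ? blk.var : blk.rvar;
  std::vector<float> scale(cout), shift(cout);
  for (int c = 0; c < cout; ++c) {
    float inv = 1.0f / std::sqrt(v[c] + (float)QCNet::bn_eps);
    scale[c] = blk.gamma[c] * inv;
    shift[c] = blk.beta[c] - m[c] * scale[c];
  }
  for (int b = 0; b < B; ++b) {
    const float* src = blk.pooled.data() + (size_t)b * cout * PNp;
    float* dst = blk.bnout.data() + (size_t)b * cout * PNp;
    for (int z = 0; z < dp.z; ++z)
      for (int y = 0; y < dp.y; ++y) {
        long row = pvox(dp, 0, y, z);
        for (int x = 0; x < dp.x; ++x) {
          const float* pv = src + (size_t)cout * (row + x);
          float* ov = dst + (size_t)cout * (row + x);
          for (int c = 0; c < cout; ++c) ov[c] = pv[c] * scale[c] + shift[c];
        }
      }
  }
}

static void conv_dispatch_fwd(const float* in, Block& blk, float* out) {
  switch (blk.cs) {
    case 16: conv_relu_fwd_t<16>(in, blk.cin, blk.wint.data(), blk.bint.data(), out, blk.din); break;
    case 32: conv_relu_fwd_t<32>(in, blk.cin, blk.wint.data(), blk.bint.data(), out, blk.din); break;
    case 64: conv_relu_fwd_t<64>(in, blk.cin, blk.wint.data(), blk.bint.data(), out, blk.din); break;
    default: conv_relu_fwd_g(in, blk.cin, blk.wint.data(), blk.bint.data(), out, blk.cs, blk.din);
  }
}

static void forward_blocks(QCNet* net, int B, bool train) {
  for (size_t k = 0; k < net->blocks.size(); ++k) {
    Block& blk = net->blocks[k];
    const float* in0 = (k == 0) ? net->input_buf.data() : net->blocks[k - 1].bnout.data();
    const long instride = (long)blk.cin * blk.din.pn();
    for (int b = 0; b < B; ++b)
      conv_dispatch_fwd(in0 + (size_t)b * instride, blk,
                        blk.conv.data() + (size_t)b * blk.cs * blk.din.pn());
    pool_fwd(blk, B);
    bn_fwd(net, blk, B, train);
  }
}

static arma::fmat flatten_last(QCNet* net, int B) {
  Block& blk = net->blocks.back();
  const Shape3 dp = blk.dpool;
  const int cout = blk.cout;
  const long PNp = dp.pn();
  arma::fmat F(net->flat, B);
  for (int b = 0; b < B; ++b) {
    const float* src = blk.bnout.data() + (size_t)b * cout * PNp;
    float* dst = F.colptr(b);
    long i = 0;
    for (int z = 0; z < dp.z; ++z)
      for (int y = 0; y < dp.y; ++y) {
        long row = pvox(dp, 0, y, z);
        for (int x = 0; x < dp.x; ++x) {
          const float* v = src + (size_t)cout * (row + x);
          for (int c = 0; c < cout; ++c) dst[i++] = v[c];
        }
      }
  }
  return F;
}

static void unflatten_last(QCNet* net, const arma::fmat& dF, int B) {
  Block& blk = net->blocks.back();
  const Shape3 dp = blk.dpool;
  const int cout = blk.cout, gs = blk.gs;
  const long PNp = dp.pn();
  std::fill(blk.grad.begin(), blk.grad.end(), 0.0f);
  for (int b = 0; b < B; ++b) {
    const float* src = dF.colptr(b);
    float* dst = blk.grad.data() + (size_t)b * gs * PNp;
    long i = 0;
    for (int z = 0; z < dp.z; ++z)
      for (int y = 0; y < dp.y; ++y) {
        long row = pvox(dp, 0, y, z);
        for (int x = 0; x < dp.x; ++x) {
          float* v = dst + (size_t)gs * (row + x);
          for (int c = 0; c < cout; ++c) v[c] = src[i++];
        }
      }
  }
}

static arma::frowvec head_forward(QCNet* net, const arma::fmat& F, bool train,
                                  arma::fmat& dropmask) {
  net->d1.in = F;
  arma::fmat H1 = net->d1.W.t() * F;
  H1.each_col() += net->d1.b.t();
  H1.transform([](float v) { return v > 0 ? v : 0.0f; });
  if (train && net->dropout > 0) {
    std::uniform_real_distribution<float> ud(0.0f, 1.0f);
    dropmask.set_size(H1.n_rows, H1.n_cols);
    const float keep = 1.0f - (float)net->dropout;
    for (arma::uword i = 0; i < dropmask.n_elem; ++i)
      dropmask[i] = (ud(net->rng) < keep) ? 1.0f / keep : 0.0f;
    H1 %= dropmask;
  }
  net->d1.out = H1;
  net->d2.in = H1;
  arma::fmat H2 = net->d2.W.t() * H1;
  H2.each_col() += net->d2.b.t();
  H2.transform([](float v) { return v > 0 ? v : 0.0f; });
  net->d2.out = H2;
  net->d3.in = H2;
  arma::fmat Z = net->d3.W.t() * H2;
  Z.each_col() += net->d3.b.t();
  return Z.row(0);  // logits
}

static void dense_backward(Dense& d, const arma::fmat& dout, arma::fmat& din,
                           bool relu_out) {
  arma::fmat g = dout;
  if (relu_out)
    for (arma::uword i = 0; i < g.n_elem; ++i)
      if (d.out[i] <= 0) g[i] = 0;
  d.gW = d.in * g.t();
  d.gb = arma::sum(g, 1).t();
  din = d.W * g;
}

// forward + backward on one batch (no parameter update); fills all gradients.
static std::pair<double, int> compute_grads(QCNet* net, int B, const arma::ivec& y) {
  forward_blocks(net, B, true);
  arma::fmat F = flatten_last(net, B);
  arma::fmat dropmask;
  arma::frowvec z = head_forward(net, F, true, dropmask);

  double loss = 0;
  int correct = 0;
  arma::fmat dz(1, B);
  for (int b = 0; b < B; ++b) {
    double zb = z[b], yb = (double)y[b];
    double p = 1.0 / (1.0 + std::exp(-zb));
    loss += std::max(zb, 0.0) - zb * yb + std::log1p(std::exp(-std::fabs(zb)));
    if ((p >= 0.5 ? 1 : 0) == y[b]) ++correct;
    dz(0, b) = (float)((p - yb) / B);
  }
  loss /= B;

  arma::fmat dH2, dH1, dF;
  dense_backward(net->d3, dz, dH2, false);
  dense_backward(net->d2, dH2, dH1, true);
  if (net->dropout > 0 && dropmask.n_elem > 0) dH1 %= dropmask;
  dense_backward(net->d1, dH1, dF, true);
  unflatten_last(net, dF, B);

  for (int k = (int)net->blocks.size() - 1; k >= 0; --k) {
    Block& blk = net->blocks[k];
    const Shape3 dp = blk.dpool, di = blk.din;
    const int cout = blk.cout, cs = blk.cs, gs = blk.gs;
    const long PNp = dp.pn(), Np = dp.n();
    const double n = (double)B * Np;

    // batch-norm backward (in place on blk.grad)
    arma::frowvec sdy(cout, arma::fill::zeros), sdyx(cout, arma::fill::zeros);
    std::vector<float> inv(cout);
    for (int c = 0; c < cout; ++c) inv[c] = 1.0f / std::sqrt(blk.var[c] + (float)QCNet::bn_eps);
    for (int b = 0; b < B; ++b) {
      const float* pv = blk.pooled.data() + (size_t)b * cout * PNp;
      const float* gv = blk.grad.data() + (size_t)b * gs * PNp;
      for (int zz = 0; zz < dp.z; ++zz)
        for (int yy = 0; yy < dp.y; ++yy) {
          long row = pvox(dp, 0, yy, zz);
          for (int xx = 0; xx < dp.x; ++xx) {
            const float* p = pv + (size_t)cout * (row + xx);
            const float* g = gv + (size_t)gs * (row + xx);
            for (int c = 0; c < cout; ++c) {
              sdy[c] += g[c];
              sdyx[c] += g[c] * (p[c] - blk.mu[c]) * inv[c];
            }
          }
        }
    }
    blk.ggamma = sdyx;
    blk.gbeta = sdy;
    for (int b = 0; b < B; ++b) {
      const float* pv = blk.pooled.data() + (size_t)b * cout * PNp;
      float* gv = blk.grad.data() + (size_t)b * gs * PNp;
      for (int zz = 0; zz < dp.z; ++zz)
        for (int yy = 0; yy < dp.y; ++yy) {
          long row = pvox(dp, 0, yy, zz);
          for (int xx = 0; xx < dp.x; ++xx) {
            const float* p = pv + (size_t)cout * (row + xx);
            float* g = gv + (size_t)gs * (row + xx);
            for (int c = 0; c < cout; ++c) {
              float xhat = (p[c] - blk.mu[c]) * inv[c];
              g[c] = (blk.gamma[c] * inv[c] / (float)n) *
                     ((float)n * g[c] - sdy[c] - xhat * sdyx[c]);
            }
          }
        }
    }

    // pool backward + ReLU mask -> dconv
    std::fill(blk.dconv.begin(), blk.dconv.end(), 0.0f);
    for (int b = 0; b < B; ++b) {
      const float* gv = blk.grad.data() + (size_t)b * gs * PNp;
      const float* cv = blk.conv.data() + (size_t)b * cs * blk.din.pn();
      float* dcv = blk.dconv.data() + (size_t)b * cs * blk.din.pn();
      const int* am = blk.argmax.data() + (size_t)b * cout * Np;
      long kk = 0;
      for (int zz = 0; zz < dp.z; ++zz)
        for (int yy = 0; yy < dp.y; ++yy) {
          long row = pvox(dp, 0, yy, zz);
          for (int xx = 0; xx < dp.x; ++xx, ++kk) {
            const float* g = gv + (size_t)gs * (row + xx);
            for (int c = 0; c < cout; ++c) {
              long s = am[(size_t)c * Np + kk];
              if (cv[c + (size_t)cs * s] > 0) dcv[c + (size_t)cs * s] += g[c];
            }
          }
        }
    }

    // conv backward: weights/bias
    const float* in0 = (k == 0) ? net->input_buf.data() : net->blocks[k - 1].bnout.data();
    const long inst = (long)blk.cin * di.pn();
    std::vector<float> dwint((size_t)cs * blk.cin * 27, 0.0f);
    for (int b = 0; b < B; ++b) {
      const float* dcv = blk.dconv.data() + (size_t)b * cs * di.pn();
      const float* in = in0 + (size_t)b * inst;
      switch (cs) {
        case 16: conv_bwd_dw_t<16>(in, blk.cin, dcv, dwint.data(), di); break;
        case 32: conv_bwd_dw_t<32>(in, blk.cin, dcv, dwint.data(), di); break;
        case 64: conv_bwd_dw_t<64>(in, blk.cin, dcv, dwint.data(), di); break;
        default: conv_bwd_dw_g(in, blk.cin, dcv, dwint.data(), cs, di);
      }
    }
    blk.gW.set_size(blk.W.n_rows, blk.W.n_cols);
    for (int j = 0; j < 27; ++j)
      for (int ci = 0; ci < blk.cin; ++ci)
        for (int co = 0; co < cout; ++co)
          blk.gW(ci * 27 + j, co) = dwint[(size_t)co + (size_t)cs * (ci + (size_t)blk.cin * j)];
    blk.gb.zeros(cout);
    for (int b = 0; b < B; ++b) {
      const float* dcv = blk.dconv.data() + (size_t)b * cs * di.pn();
      for (int zz = 0; zz < di.z; ++zz)
        for (int yy = 0; yy < di.y; ++yy) {
          long row = pvox(di, 0, yy, zz);
          for (int xx = 0; xx < di.x; ++xx) {
            const float* g = dcv + (size_t)cs * (row + xx);
            for (int c = 0; c < cout; ++c) blk.gb[c] += g[c];
          }
        }
    }

    // gradient wrt input of this block -> previous block's grad buffer
    if (k > 0) {
      Block& prev = net->blocks[k - 1];
      std::fill(prev.grad.begin(), prev.grad.end(), 0.0f);
      for (int b = 0; b < B; ++b) {
        float* din = prev.grad.data() + (size_t)b * blk.cin_pad * di.pn();
        const float* dcv = blk.dconv.data() + (size_t)b * cs * di.pn();
        switch (blk.cin_pad) {
          case 16: conv_bwd_din_t<16>(din, blk.wT.data(), cout, cs, dcv, di); break;
          case 32: conv_bwd_din_t<32>(din, blk.wT.data(), cout, cs, dcv, di); break;
          case 64: conv_bwd_din_t<64>(din, blk.wT.data(), cout, cs, dcv, di); break;
          default: conv_bwd_din_g(din, blk.cin_pad, blk.wT.data(), cout, cs, dcv, di);
        }
      }
      // stencil spill lands in the halo of prev.grad; downstream consumers
      // (batch-norm and pool backward) only read the interior, so no cleanup.
    }
  }
  return {loss, correct};
}

static double adam_alpha(long step, double lr) {
  const double b1 = 0.9, b2 = 0.999;
  return lr * std::sqrt(1.0 - std::pow(b2, (double)step)) / (1.0 - std::pow(b1, (double)step));
}

static void adam_update(arma::fmat& p, const arma::fmat& g, AdamState& st, double alpha) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  st.m = b1 * st.m + (1 - b1) * g;
  st.v = b2 * st.v + (1 - b2) * arma::square(g);
  p -= (float)alpha * st.m / (arma::sqrt(st.v) + eps);
}

static void adam_update_row(arma::frowvec& p, const arma::frowvec& g, AdamState& st,
                            double alpha) {
  arma::fmat pm(p), gm(g);
  adam_update(pm, gm, st, alpha);
  p = pm.row(0);
}

static void apply_updates(QCNet* net, double lr) {
  net->step += 1;
  double alpha = adam_alpha(net->step, lr);
  for (auto& blk : net->blocks) {
    adam_update(blk.W, blk.gW, blk.aW, alpha);
    adam_update_row(blk.b, blk.gb, blk.ab, alpha);
    adam_update_row(blk.gamma, blk.ggamma, blk.agamma, alpha);
    adam_update_row(blk.beta, blk.gbeta, blk.abeta, alpha);
    refresh_internal(blk);
  }
  auto upd = [&](Dense& d) {
    adam_update(d.W, d.gW, d.aW, alpha);
    adam_update_row(d.b, d.gb, d.ab, alpha);
  };
  upd(net->d1);
  upd(net->d2);
  upd(net->d3);
}

// copy volume i of the R array (double, compact spatial) into the padded
// channel-1 input buffer slot b.
static void load_input(QCNet* net, const double* x, long i, int b) {
  const Shape3 d = net->input;
  float* dst = net->input_buf.data() + (size_t)b * d.pn();
  const double* src = x + (size_t)i * d.n();
  long s = 0;
  for (int z = 0; z < d.z; ++z)
    for (int y = 0; y < d.y; ++y) {
      float* row = dst + pvox(d, 0, y, z);
      for (int x2 = 0; x2 < d.x; ++x2) row[x2] = (float)src[s++];
    }
}

// [[Rcpp::export(name = ".qcnet_train")]]
List qcnet_train(SEXP ptr_, NumericVector x, IntegerVector dims, IntegerVector y,
                 int epochs, int batch_size, double lr0, double decay, int seed) {
  enable_ftz();
  XPtr<QCNet> ptr(ptr_);
  QCNet* net = ptr.get();
  const int nsamp = dims[3];
  if (seed >= 0) net->rng.seed((unsigned)seed);
  const double* xp = REAL(x);
  std::vector<int> order(nsamp);
  for (int i = 0; i < nsamp; ++i) order[i] = i;
  NumericVector loss_hist(epochs), acc_hist(epochs);
  for (int e = 0; e < epochs; ++e) {
    double lr = lr0 * std::pow(decay, e);
    std::shuffle(order.begin(), order.end(), net->rng);
    double tot_loss = 0;
    int tot_correct = 0;
    for (int off = 0; off < nsamp; off += batch_size) {
      int B = std::min(batch_size, nsamp - off);
      ensure_buffers(net, B);
      arma::ivec yb(B);
      for (int b = 0; b < B; ++b) {
        int i = order[off + b];
        load_input(net, xp, i, b);
        yb[b] = y[i];
      }
      auto res = compute_grads(net, B, yb);
      apply_updates(net, lr);
      tot_loss += res.first * B;
      tot_correct += res.second;
      Rcpp::checkUserInterrupt();
    }
    loss_hist[e] = tot_loss / nsamp;
    acc_hist[e] = (double)tot_correct / nsamp;
  }
  return List::create(_["loss"] = loss_hist, _["train_accuracy"] = acc_hist);
}

// [[Rcpp::export(name = ".qcnet_loss_grads")]]
List qcnet_loss_grads(SEXP ptr_, NumericVector x, IntegerVector dims, IntegerVector y) {
  enable_ftz();
  XPtr<QCNet> ptr(ptr_);
  QCNet* net = ptr.get();
  const int B = dims.size() == 4 ? dims[3] : 1;
  ensure_buffers(net, B);
  const double* xp = REAL(x);
  arma::ivec yb(B);
  for (int b = 0; b < B; ++b) {
    load_input(net, xp, b, b);
    yb[b] = y[b];
  }
  auto res = compute_grads(net, B, yb);
  List gblocks(net->blocks.size());
  for (size_t k = 0; k < net->blocks.size(); ++k) {
    Block& blk = net->blocks[k];
    gblocks[k] = List::create(
        _["W"] = wrap(arma::conv_to<arma::mat>::from(blk.gW)),
        _["b"] = wrap(arma::conv_to<arma::rowvec>::from(blk.gb)),
        _["gamma"] = wrap(arma::conv_to<arma::rowvec>::from(blk.ggamma)),
        _["beta"] = wrap(arma::conv_to<arma::rowvec>::from(blk.gbeta)));
  }
  auto dl = [](const Dense& d) {
    return List::create(_["W"] = wrap(arma::conv_to<arma::mat>::from(d.gW)),
                        _["b"] = wrap(arma::conv_to<arma::rowvec>::from(d.gb)));
  };
  return List::create(_["loss"] = res.first, _["blocks"] = gblocks,
                      _["dense1"] = dl(net->d1), _["dense2"] = dl(net->d2),
                      _["dense3"] = dl(net->d3));
}

// [[Rcpp::export(name = ".qcnet_predict")]]
NumericVector qcnet_predict(SEXP ptr_, NumericVector x, IntegerVector dims) {
  enable_ftz();
  XPtr<QCNet> ptr(ptr_);
  QCNet* net = ptr.get();
  const int nsamp = dims.size() == 4 ? dims[3] : 1;
  NumericVector out(nsamp);
  const double* xp = REAL(x);
  ensure_buffers(net, 1);
  arma::fmat dropmask;
  for (int i = 0; i < nsamp; ++i) {
    load_input(net, xp, i, 0);
    forward_blocks(net, 1, false);
    arma::fmat F = flatten_last(net, 1);
    arma::frowvec z = head_forward(net, F, false, dropmask);
    out[i] = 1.0 / (1.0 + std::exp(-(double)z[0]));
    if (i % 16 == 15) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export(name = ".qcnet_describe")]]
List qcnet_describe(SEXP ptr_) {
  XPtr<QCNet> ptr(ptr_);
  QCNet* net = ptr.get();
  int nb = net->blocks.size();
  IntegerMatrix conv_dims(nb, 3), pool_dims(nb, 3);
  IntegerVector filt(nb);
  double npar = 0;
  for (int k = 0; k < nb; ++k) {
    const Block& b = net->blocks[k];
    filt[k] = b.cout;
    conv_dims(k, 0) = b.din.x; conv_dims(k, 1) = b.din.y; conv_dims(k, 2) = b.din.z;
    pool_dims(k, 0) = b.dpool.x; pool_dims(k, 1) = b.dpool.y; pool_dims(k, 2) = b.dpool.z;
    npar += (double)b.W.n_elem + b.b.n_elem + 2.0 * b.gamma.n_elem;
  }
  npar += (double)net->d1.W.n_elem + net->d1.b.n_elem + net->d2.W.n_elem +
          net->d2.b.n_elem + net->d3.W.n_elem + net->d3.b.n_elem;
  return List::create(
      _["input_shape"] = IntegerVector::create(net->input.x, net->input.y, net->input.z),
      _["block_filters"] = filt, _["conv_kernel"] = IntegerVector::create(3, 3, 3),
      _["pool_size"] = 2, _["pool_stride"] = 2, _["batchnorm_per_block"] = true,
      _["conv_input_dims"] = conv_dims, _["pooled_dims"] = pool_dims,
      _["flatten_units"] = (double)net->flat,
      _["dense_units"] = IntegerVector::create(net->dense_units, net->dense_units, 1),
      _["dropout_rate"] = net->dropout, _["n_parameters"] = npar,
      _["seed"] = net->seed);
}

// [[Rcpp::export(name = ".qcnet_weights")]]
List qcnet_weights(SEXP ptr_) {
  XPtr<QCNet> ptr(ptr_);
  QCNet* net = ptr.get();
  List blocks(net->blocks.size());
  for (size_t k = 0; k < net->blocks.size(); ++k) {
    const Block& b = net->blocks[k];
    blocks[k] = List::create(
        _["W"] = wrap(arma::conv_to<arma::mat>::from(b.W)),
        _["b"] = wrap(arma::conv_to<arma::rowvec>::from(b.b)),
        _["gamma"] = wrap(arma::conv_to<arma::rowvec>::from(b.gamma)),
        _["beta"] = wrap(arma::conv_to<arma::rowvec>::from(b.beta)),
        _["running_mean"] = wrap(arma::conv_to<arma::rowvec>::from(b.rmean)),
        _["running_var"] = wrap(arma::conv_to<arma::rowvec>::from(b.rvar)));
  }
  auto dl = [](const Dense& d) {
    return List::create(_["W"] = wrap(arma::conv_to<arma::mat>::from(d.W)),
                        _["b"] = wrap(arma::conv_to<arma::rowvec>::from(d.b)));
  };
  return List::create(_["blocks"] = blocks, _["dense1"] = dl(net->d1),
                      _["dense2"] = dl(net->d2), _["dense3"] = dl(net->d3));
}

// [[Rcpp::export(name = ".qcnet_set_weights")]]
void qcnet_set_weights(SEXP ptr_, List w) {
  XPtr<QCNet> ptr(ptr_);
  QCNet* net = ptr.get();
  List blocks = w["blocks"];
  if ((size_t)blocks.size() != net->blocks.size()) stop("weight/block count mismatch");
  for (size_t k = 0; k < net->blocks.size(); ++k) {
    Block& b = net->blocks[k];
    List bl = blocks[k];
    arma::mat W = as<arma::mat>(bl["W"]);
    if (W.n_rows != b.W.n_rows || W.n_cols != b.W.n_cols)
      stop("conv weight shape mismatch in block %d: stored %dx%d, expected %dx%d",
           (int)k + 1, (int)W.n_rows, (int)W.n_cols, (int)b.W.n_rows, (int)b.W.n_cols);
    b.W = arma::conv_to<arma::fmat>::from(W);
    b.b = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(bl["b"]));
    b.gamma = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(bl["gamma"]));
    b.beta = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(bl["beta"]));
    b.rmean = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(bl["running_mean"]));
    b.rvar = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(bl["running_var"]));
    refresh_internal(b);
  }
  auto setd = [&](Dense& d, List dl, const char* what) {
    arma::mat W = as<arma::mat>(dl["W"]);
    if (W.n_rows != d.W.n_rows || W.n_cols != d.W.n_cols)
      stop("dense weight shape mismatch (%s): stored %dx%d, expected %dx%d", what,
           (int)W.n_rows, (int)W.n_cols, (int)d.W.n_rows, (int)d.W.n_cols);
    d.W = arma::conv_to<arma::fmat>::from(W);
    d.b = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(dl["b"]));
  };
  setd(net->d1, w["dense1"], "dense1");
  setd(net->d2, w["dense2"], "dense2");
  setd(net->d3, w["dense3"], "dense3");
}
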