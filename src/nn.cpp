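// Recurrent-convolutional sequence-labeling network used by the revision
// models: residual 1-D CNN over the raw-signal window, Bi-LSTM over the
// per-event feature window, merged Bi-LSTM trunk, two dense layers, softmax,
// trained with softmax cross-entropy plus a weighted center loss.
//
// The engine is templated on the floating type: the double instantiation is
// used for loss verification and finite-difference gradient checks, the float
// instantiation for training throughput. All heavy lifting is BLAS dgemm /
// sgemm through Armadillo.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <chrono>
#if defined(__x86_64__) || defined(__i386__)
#include <immintrin.h>
#endif
#include <vector>
#include <string>

using namespace arma;

// ----------------------------------------------------------------- config --

struct NetCfg {
  int w = 13, cap = 40, F = 7, C = 8, nres = 3, hf = 16, nfeat = 2,
      ht = 64, ntrunk = 2, d = 64, K = 6;
  int batch = 256, epochs = 50;
  double dropout = 0.2, lambda = 0.2, lr = 0.002, decay = 0.05,
         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
         bn_eps = 1e-5, bn_mom = 0.9, center_alpha = 0.5;
  bool shortcut = true;
  std::string precision = "double";
};

static NetCfg parse_cfg(const Rcpp::List& cf) {
  NetCfg c;
  c.w = cf["window"]; c.cap = cf["signal_cap"]; c.F = cf["feat_dim"];
  c.C = cf["conv_filters"]; c.nres = cf["n_res_blocks"];
  c.hf = cf["feat_lstm_state"]; c.nfeat = cf["n_feat_lstm"];
  c.ht = cf["trunk_lstm_state"]; c.ntrunk = cf["n_trunk_lstm"];
  c.d = cf["dense_units"]; c.K = cf["num_classes"];
  c.batch = cf["batch_size"]; c.epochs = cf["epochs"];
  c.dropout = cf["dropout"]; c.lambda = cf["lambda_center"];
  c.lr = cf["lr"]; c.decay = cf["decay"];
  c.beta1 = cf["beta1"]; c.beta2 = cf["beta2"];
  c.adam_eps = cf["adam_epsilon"]; c.bn_eps = cf["bn_epsilon"];
  c.bn_mom = cf["bn_momentum"]; c.center_alpha = cf["center_alpha"];
  c.shortcut = cf["use_shortcut"];
  c.precision = Rcpp::as<std::string>(cf["precision"]);
  if (c.K != 4 && c.K != 6) Rcpp::stop("num_classes must be 4 or 6");
  if (c.w < 3 || c.w % 2 == 0) Rcpp::stop("window must be an odd integer >= 3");
  if (c.lambda < 0) Rcpp::stop("lambda_center must be >= 0");
  return c;
}

// Parameter layout, single source of truth (mirrored into R by cpp_param_spec).
struct ParamInfo { std::string name; int nr, nc; };

static std::vector<ParamInfo> param_spec(const NetCfg& c) {
  std::vector<ParamInfo> s;
  auto add = [&](const std::string& n, int r, int cc) { s.push_back({n, r, cc}); };
  add("conv0_W", 3, c.C); add("conv0_b", 1, c.C);
  add("bn0_g", 1, c.C);   add("bn0_b", 1, c.C);
  for (int r = 0; r < c.nres; ++r) {
    std::string p = "res" + std::to_string(r + 1) + "_";
    add(p + "convA_W", 3 * c.C, c.C); add(p + "convA_b", 1, c.C);
    add(p + "bnA_g", 1, c.C);         add(p + "bnA_b", 1, c.C);
    add(p + "convB_W", 3 * c.C, c.C); add(p + "convB_b", 1, c.C);
    add(p + "bnB_g", 1, c.C);         add(p + "bnB_b", 1, c.C);
  }
  for (int l = 0; l < c.nfeat; ++l) {
    std::string p = "feat" + std::to_string(l + 1) + "_";
    int in = (l == 0) ? c.F : 2 * c.hf;
    add(p + "Wx", in, 8 * c.hf); add(p + "Whf", c.hf, 4 * c.hf);
    add(p + "Whr", c.hf, 4 * c.hf); add(p + "b", 1, 8 * c.hf);
    add(p + "bn_g", 1, 2 * c.hf); add(p + "bn_b", 1, 2 * c.hf);
  }
  for (int l = 0; l < c.ntrunk; ++l) {
    std::string p = "trunk" + std::to_string(l + 1) + "_";
    int in = (l == 0) ? (c.C + 2 * c.hf) : 2 * c.ht;
    add(p + "Wx", in, 8 * c.ht); add(p + "Whf", c.ht, 4 * c.ht);
    add(p + "Whr", c.ht, 4 * c.ht); add(p + "b", 1, 8 * c.ht);
  }
  add("dense1_W", 2 * c.ht, c.d); add("dense1_b", 1, c.d);
  add("dense2_W", c.d, c.K);      add("dense2_b", 1, c.K);
  return s;
}

// number of batch-norm layers (running-stat slots): bn0 + 2/res block + 1/feat layer
static int n_bn(const NetCfg& c) { return 1 + 2 * c.nres + c.nfeat; }

// ------------------------------------------------------------- fast math ---

// float tanh: clamped rational approximation (well-known 13/6-degree
// minimax coefficients), ~1e-7 absolute error, auto-vectorizable.
static inline float fast_tanh_s(float x) {
  const float mx = 7.90531110763549805f;
  x = x > mx ? mx : (x < -mx ? -mx : x);
  const float a1 = 4.89352455891786e-03f, a3 = 6.37261928875436e-04f,
              a5 = 1.48572235717979e-05f, a7 = 5.12229709037114e-08f,
              a9 = -8.60467152213735e-11f, a11 = 2.00018790482477e-13f,
              a13 = -2.76076847742355e-16f;
  const float b0 = 4.89352518554385e-03f, b2 = 2.26843463243900e-03f,
              b4 = 1.18534705686654e-04f, b6 = 1.19825839466702e-06f;
  float x2 = x * x;
  float p = a13;
  p = p * x2 + a11; p = p * x2 + a9; p = p * x2 + a7;
  p = p * x2 + a5; p = p * x2 + a3; p = p * x2 + a1;
  p = p * x;
  float q = b6;
  q = q * x2 + b4; q = q * x2 + b2; q = q * x2 + b0;
  return p / q;
}

template <typename T> static inline void tanh_ip(Mat<T>& m);
template <> inline void tanh_ip<double>(Mat<double>& m) {
  double* p = m.memptr();
  for (uword i = 0; i < m.n_elem; ++i) p[i] = std::tanh(p[i]);
}
template <> inline void tanh_ip<float>(Mat<float>& m) {
  float* p = m.memptr();
  for (uword i = 0; i < m.n_elem; ++i) p[i] = fast_tanh_s(p[i]);
}

template <typename T> static inline void sigmoid_ip(Mat<T>& m);
template <> inline void sigmoid_ip<double>(Mat<double>& m) {
  double* p = m.memptr();
  for (uword i = 0; i < m.n_elem; ++i) p[i] = 1.0 / (1.0 + std::exp(-p[i]));
}
template <> inline void sigmoid_ip<float>(Mat<float>& m) {
  float* p = m.memptr();
  for (uword i = 0; i < m.n_elem; ++i)
    p[i] = 0.5f * (1.0f + fast_tanh_s(0.5f * p[i]));
}

// raw BLAS gemm on strided views (C := alpha*A*op(B) + beta*C), avoiding
// the temporaries Armadillo creates for subview products in the sequential
// recurrent updates
extern "C" {
void sgemm_(const char*, const char*, const int*, const int*, const int*,
            const float*, const float*, const int*, const float*, const int*,
            const float*, float*, const int*);
void dgemm_(const char*, const char*, const int*, const int*, const int*,
            const double*, const double*, const int*, const double*, const int*,
            const double*, double*, const int*);
}
template <typename T>
static inline void gemm2_raw(char transa, char transb, int m, int n, int k,
                             const T* A, int lda, const T* B, int ldb, T beta,
                             T* C, int ldc);
template <>
inline void gemm2_raw<float>(char transa, char transb, int m, int n, int k,
                             const float* A, int lda, const float* B, int ldb,
                             float beta, float* C, int ldc) {
  const float one = 1.0f;
  sgemm_(&transa, &transb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta, C, &ldc);
}
template <>
inline void gemm2_raw<double>(char transa, char transb, int m, int n, int k,
                              const double* A, int lda, const double* B, int ldb,
                              double beta, double* C, int ldc) {
  const double one = 1.0;
  dgemm_(&transa, &transb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta, C, &ldc);
}

template <typename T>
static inline void gemm_raw(char transb, int m, int n, int k, const T* A,
                            int lda, const T* B, int ldb, T beta, T* C, int ldc);
template <>
inline void gemm_raw<float>(char transb, int m, int n, int k, const float* A,
                            int lda, const float* B, int ldb, float beta,
                            float* C, int ldc) {
  const char na = 'N';
  const float one = 1.0f;
  sgemm_(&na, &transb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta, C, &ldc);
}
template <>
inline void gemm_raw<double>(char transb, int m, int n, int k, const double* A,
                             int lda, const double* B, int ldb, double beta,
                             double* C, int ldc) {
  const char na = 'N';
  const double one = 1.0;
  dgemm_(&na, &transb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta, C, &ldc);
}

// ------------------------------------------------------------ conversions --

template <typename T>
static Mat<T> as_matT(SEXP x) {
  Rcpp::NumericMatrix m(x);
  mat d(m.begin(), m.nrow(), m.ncol(), false);
  return conv_to<Mat<T>>::from(d);
}

template <typename T>
static Rcpp::NumericMatrix to_rmat(const Mat<T>& m) {
  mat d = conv_to<mat>::from(m);
  Rcpp::NumericMatrix out(d.n_rows, d.n_cols);
  std::copy(d.begin(), d.end(), out.begin());
  return out;
}

template <typename T>
static std::vector<Mat<T>> params_in(const Rcpp::List& pl, const NetCfg& cfg) {
  auto spec = param_spec(cfg);
  if ((int)pl.size() != (int)spec.size())
    Rcpp::stop("parameter list has %d entries, expected %d", pl.size(), (int)spec.size());
  std::vector<Mat<T>> out(spec.size());
  for (size_t i = 0; i < spec.size(); ++i) {
    out[i] = as_matT<T>(pl[i]);
    if ((int)out[i].n_rows != spec[i].nr || (int)out[i].n_cols != spec[i].nc)
      Rcpp::stop("parameter '%s' has wrong shape", spec[i].name.c_str());
  }
  return out;
}

template <typename T>
static Rcpp::List params_out(const std::vector<Mat<T>>& ps, const NetCfg& cfg) {
  auto spec = param_spec(cfg);
  Rcpp::List out(ps.size());
  Rcpp::CharacterVector nm(ps.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    out[i] = to_rmat(ps[i]);
    nm[i] = spec[i].name;
  }
  out.attr("names") = nm;
  return out;
}

// bn running stats: list of 2 x channels matrices (row 0 mean, row 1 var)
template <typename T>
static std::vector<Mat<T>> bn_in(const Rcpp::List& bl) {
  std::vector<Mat<T>> out(bl.size());
  for (int i = 0; i < bl.size(); ++i) out[i] = as_matT<T>(bl[i]);
  return out;
}

// --------------------------------------------------------------- layers ----

// zero gradient entries where the stored ReLU output is zero
template <typename T>
static inline void relu_mask_ip(Mat<T>& dY, const Mat<T>& act) {
  T* p = dY.memptr();
  const T* a = act.memptr();
  for (uword i = 0; i < dY.n_elem; ++i) if (a[i] <= 0) p[i] = 0;
}

template <typename T>
static inline void relu_ip(Mat<T>& m) {
  T* p = m.memptr();
  for (uword i = 0; i < m.n_elem; ++i) if (p[i] < 0) p[i] = 0;
}

// Signal-branch activations are stored channel-major (C x B*L, one column
// per flat sample position): the kernel-3 convolution then runs as three
// shifted BLAS products whose large dimension is the sample axis, which is
// where the throughput is. W is (3*Cin x Cout) with the tap blocks stacked.
template <typename T>
static Mat<T> conv3_forward_gen(const Mat<T>& A, const Mat<T>& W, const Mat<T>& b,
                                int B) {
  const int cin = A.n_rows, n = A.n_cols, cout = W.n_cols, ldw = 3 * cin;
  Mat<T> Y(cout, n);
  Col<T> bias = b.row(0).t();
  Y.each_col() = bias;
  // center tap: Y += W1^T * A
  gemm2_raw<T>('T', 'N', cout, n, cin, W.memptr() + cin, ldw,
               A.memptr(), cin, (T)1, Y.memptr(), cout);
  // tap p-1: output cols B.. read input cols 0..
  gemm2_raw<T>('T', 'N', cout, n - B, cin, W.memptr(), ldw,
               A.colptr(0), cin, (T)1, Y.colptr(B), cout);
  // tap p+1: output cols 0.. read input cols B..
  gemm2_raw<T>('T', 'N', cout, n - B, cin, W.memptr() + 2 * cin, ldw,
               A.colptr(B), cin, (T)1, Y.colptr(0), cout);
  return Y;
}

template <typename T>
static Mat<T> conv3_backward_gen(const Mat<T>& dY, const Mat<T>& A, const Mat<T>& W,
                                 int B, Mat<T>& dW, Mat<T>& db) {
  const int cin = A.n_rows, n = A.n_cols, cout = W.n_cols, ldw = 3 * cin;
  dW.set_size(3 * cin, cout);
  // weight gradients: large-k reductions
  gemm2_raw<T>('N', 'T', cin, cout, n - B, A.colptr(0), cin,
               dY.colptr(B), cout, (T)0, dW.memptr(), ldw);
  gemm2_raw<T>('N', 'T', cin, cout, n, A.memptr(), cin,
               dY.memptr(), cout, (T)0, dW.memptr() + cin, ldw);
  gemm2_raw<T>('N', 'T', cin, cout, n - B, A.colptr(B), cin,
               dY.colptr(0), cout, (T)0, dW.memptr() + 2 * cin, ldw);
  db = sum(dY, 1).t();
  Mat<T> dA(cin, n, fill::zeros);
  gemm2_raw<T>('N', 'N', cin, n, cout, W.memptr() + cin, ldw,
               dY.memptr(), cout, (T)1, dA.memptr(), cin);
  gemm2_raw<T>('N', 'N', cin, n - B, cout, W.memptr(), ldw,
               dY.colptr(B), cout, (T)1, dA.colptr(0), cin);
  gemm2_raw<T>('N', 'N', cin, n - B, cout, W.memptr() + 2 * cin, ldw,
               dY.colptr(0), cout, (T)1, dA.colptr(B), cin);
  return dA;
}

#if defined(__x86_64__) || defined(__i386__)
static bool have_avx2_conv();  // defined with the activation kernels below

// 8-filter kernels: one AVX register holds all output (or input) channels of
// a column, so a window column costs 3*cin fused multiply-adds.
__attribute__((target("avx2,fma")))
static void conv3_fwd_avx8(const float* A, int cin, int n, int B,
                           const float* W, const float* bias, float* Y) {
  const int ldw = 3 * cin;
  std::vector<float> wt((size_t)3 * cin * 8);
  for (int r = 0; r < 3 * cin; ++r)
    for (int j = 0; j < 8; ++j) wt[(size_t)r * 8 + j] = W[(size_t)j * ldw + r];
  const __m256 vb = _mm256_loadu_ps(bias);
  for (int p = 0; p < n; ++p) {
    __m256 acc = vb;
    if (p >= B) {
      const float* a = A + (size_t)(p - B) * cin;
      const float* wp = wt.data();
      for (int k = 0; k < cin; ++k)
        acc = _mm256_fmadd_ps(_mm256_broadcast_ss(a + k),
                              _mm256_loadu_ps(wp + (size_t)k * 8), acc);
    }
    {
      const float* a = A + (size_t)p * cin;
      const float* wp = wt.data() + (size_t)cin * 8;
      for (int k = 0; k < cin; ++k)
        acc = _mm256_fmadd_ps(_mm256_broadcast_ss(a + k),
                              _mm256_loadu_ps(wp + (size_t)k * 8), acc);
    }
    if (p + B < n) {
      const float* a = A + (size_t)(p + B) * cin;
      const float* wp = wt.data() + (size_t)2 * cin * 8;
      for (int k = 0; k < cin; ++k)
        acc = _mm256_fmadd_ps(_mm256_broadcast_ss(a + k),
                              _mm256_loadu_ps(wp + (size_t)k * 8), acc);
    }
    _mm256_storeu_ps(Y + (size_t)p * 8, acc);
  }
}

// dA[:,q] = W1 dY[:,q] + W0 dY[:,q+B] + W2 dY[:,q-B]  (cin == 8)
__attribute__((target("avx2,fma")))
static void conv3_bwd_dA_avx8(const float* dY, int cout, int n, int B,
                              const float* W, float* dA) {
  const int cin = 8, ldw = 3 * cin;
  // wt2[tap][j][0..7] = W(tap*cin .. tap*cin+7, j), contiguous per (tap, j)
  std::vector<float> wt((size_t)3 * cout * 8);
  for (int tap = 0; tap < 3; ++tap)
    for (int j = 0; j < cout; ++j)
      for (int k = 0; k < 8; ++k)
        wt[((size_t)tap * cout + j) * 8 + k] = W[(size_t)j * ldw + tap * cin + k];
  for (int q = 0; q < n; ++q) {
    __m256 acc = _mm256_setzero_ps();
    {
      const float* d = dY + (size_t)q * cout;
      const float* wp = wt.data() + (size_t)1 * cout * 8;
      for (int j = 0; j < cout; ++j)
        acc = _mm256_fmadd_ps(_mm256_broadcast_ss(d + j),
                              _mm256_loadu_ps(wp + (size_t)j * 8), acc);
    }
    if (q + B < n) {
      const float* d = dY + (size_t)(q + B) * cout;
      const float* wp = wt.data();
      for (int j = 0; j < cout; ++j)
        acc = _mm256_fmadd_ps(_mm256_broadcast_ss(d + j),
                              _mm256_loadu_ps(wp + (size_t)j * 8), acc);
    }
    if (q >= B) {
      const float* d = dY + (size_t)(q - B) * cout;
      const float* wp = wt.data() + (size_t)2 * cout * 8;
      for (int j = 0; j < cout; ++j)
        acc = _mm256_fmadd_ps(_mm256_broadcast_ss(d + j),
                              _mm256_loadu_ps(wp + (size_t)j * 8), acc);
    }
    _mm256_storeu_ps(dA + (size_t)q * 8, acc);
  }
}

// dW(tap*cin + k, j) = sum_p A[k, p - delta_tap] dY[j, p]  (cout == 8)
__attribute__((target("avx2,fma")))
static void conv3_bwd_dW_avx8(const float* dY, const float* A, int cin, int n,
                              int B, float* dW /* 3cin x 8 col-major */) {
  const int ldw = 3 * cin;
  alignas(32) float acc[3 * 8 * 8];  // cin <= 8
  for (int i = 0; i < 3 * cin * 8; ++i) acc[i] = 0.0f;
  for (int p = 0; p < n; ++p) {
    const __m256 d = _mm256_loadu_ps(dY + (size_t)p * 8);
    if (p >= B) {
      const float* a = A + (size_t)(p - B) * cin;
      for (int k = 0; k < cin; ++k) {
        float* ap = acc + (size_t)k * 8;
        _mm256_store_ps(ap, _mm256_fmadd_ps(_mm256_broadcast_ss(a + k), d,
                                            _mm256_load_ps(ap)));
      }
    }
    {
      const float* a = A + (size_t)p * cin;
      for (int k = 0; k < cin; ++k) {
        float* ap = acc + (size_t)(cin + k) * 8;
        _mm256_store_ps(ap, _mm256_fmadd_ps(_mm256_broadcast_ss(a + k), d,
                                            _mm256_load_ps(ap)));
      }
    }
    if (p + B < n) {
      const float* a = A + (size_t)(p + B) * cin;
      for (int k = 0; k < cin; ++k) {
        float* ap = acc + (size_t)(2 * cin + k) * 8;
        _mm256_store_ps(ap, _mm256_fmadd_ps(_mm256_broadcast_ss(a + k), d,
                                            _mm256_load_ps(ap)));
      }
    }
  }
  for (int r = 0; r < 3 * cin; ++r)
    for (int j = 0; j < 8; ++j) dW[(size_t)j * ldw + r] = acc[(size_t)r * 8 + j];
}
#endif

template <typename T>
static Mat<T> conv3_forward(const Mat<T>& A, const Mat<T>& W, const Mat<T>& b,
                            int B);
template <>
inline Mat<double> conv3_forward<double>(const Mat<double>& A, const Mat<double>& W,
                                         const Mat<double>& b, int B) {
  return conv3_forward_gen(A, W, b, B);
}
template <>
inline Mat<float> conv3_forward<float>(const Mat<float>& A, const Mat<float>& W,
                                       const Mat<float>& b, int B) {
#if defined(__x86_64__) || defined(__i386__)
  if (W.n_cols == 8 && have_avx2_conv()) {
    Mat<float> Y(8, A.n_cols);
    conv3_fwd_avx8(A.memptr(), A.n_rows, A.n_cols, B, W.memptr(),
                   b.memptr(), Y.memptr());
    return Y;
  }
#endif
  return conv3_forward_gen(A, W, b, B);
}

template <typename T>
static Mat<T> conv3_backward(const Mat<T>& dY, const Mat<T>& A, const Mat<T>& W,
                             int B, Mat<T>& dW, Mat<T>& db);
template <>
inline Mat<double> conv3_backward<double>(const Mat<double>& dY, const Mat<double>& A,
                                          const Mat<double>& W, int B,
                                          Mat<double>& dW, Mat<double>& db) {
  return conv3_backward_gen(dY, A, W, B, dW, db);
}
template <>
inline Mat<float> conv3_backward<float>(const Mat<float>& dY, const Mat<float>& A,
                                        const Mat<float>& W, int B,
                                        Mat<float>& dW, Mat<float>& db) {
#if defined(__x86_64__) || defined(__i386__)
  if (W.n_cols == 8 && dY.n_rows == 8 && (int)A.n_rows <= 8 &&
      have_avx2_conv()) {
    const int cin = A.n_rows, n = A.n_cols;
    dW.set_size(3 * cin, 8);
    conv3_bwd_dW_avx8(dY.memptr(), A.memptr(), cin, n, B, dW.memptr());
    db = sum(dY, 1).t();
    if (cin == 8) {
      Mat<float> dA(8, n);
      conv3_bwd_dA_avx8(dY.memptr(), 8, n, B, W.memptr(), dA.memptr());
      return dA;
    }
    // cin != 8 only for the stem conv, whose input gradient is discarded
    return Mat<float>(cin, n, fill::zeros);
  }
#endif
  return conv3_backward_gen(dY, A, W, B, dW, db);
}

// batch norm over the sample axis of a channel-major (C x n) activation
template <typename T>
struct BnCmCache { Mat<T> xhat; Col<T> invstd; };

#if defined(__x86_64__) || defined(__i386__)
__attribute__((target("avx2,fma")))
static void bn_cm_stats_avx8(const float* X, size_t n, double* sum, double* ssq) {
  __m256d s_lo = _mm256_setzero_pd(), s_hi = _mm256_setzero_pd();
  __m256d q_lo = _mm256_setzero_pd(), q_hi = _mm256_setzero_pd();
  for (size_t i = 0; i < n; ++i) {
    const __m256 v = _mm256_loadu_ps(X + i * 8);
    const __m256d lo = _mm256_cvtps_pd(_mm256_castps256_ps128(v));
    const __m256d hi = _mm256_cvtps_pd(_mm256_extractf128_ps(v, 1));
    s_lo = _mm256_add_pd(s_lo, lo); s_hi = _mm256_add_pd(s_hi, hi);
    q_lo = _mm256_fmadd_pd(lo, lo, q_lo); q_hi = _mm256_fmadd_pd(hi, hi, q_hi);
  }
  _mm256_storeu_pd(sum, s_lo); _mm256_storeu_pd(sum + 4, s_hi);
  _mm256_storeu_pd(ssq, q_lo); _mm256_storeu_pd(ssq + 4, q_hi);
}

__attribute__((target("avx2,fma")))
static void bn_cm_norm_avx8(const float* X, size_t n, const float* mu,
                            const float* invstd, const float* g, const float* b,
                            float* xhat, float* Y) {
  const __m256 vm = _mm256_loadu_ps(mu), vi = _mm256_loadu_ps(invstd);
  const __m256 vg = _mm256_loadu_ps(g), vb = _mm256_loadu_ps(b);
  for (size_t i = 0; i < n; ++i) {
    const __m256 xh = _mm256_mul_ps(_mm256_sub_ps(_mm256_loadu_ps(X + i * 8), vm), vi);
    if (xhat) _mm256_storeu_ps(xhat + i * 8, xh);
    _mm256_storeu_ps(Y + i * 8, _mm256_fmadd_ps(vg, xh, vb));
  }
}

__attribute__((target("avx2,fma")))
static void bn_cm_bwd_sums_avx8(const float* dY, const float* xhat, size_t n,
                                double* sdg, double* sdb) {
  __m256d g_lo = _mm256_setzero_pd(), g_hi = _mm256_setzero_pd();
  __m256d b_lo = _mm256_setzero_pd(), b_hi = _mm256_setzero_pd();
  for (size_t i = 0; i < n; ++i) {
    const __m256 d = _mm256_loadu_ps(dY + i * 8);
    const __m256 h = _mm256_loadu_ps(xhat + i * 8);
    const __m256 dh = _mm256_mul_ps(d, h);
    b_lo = _mm256_add_pd(b_lo, _mm256_cvtps_pd(_mm256_castps256_ps128(d)));
    b_hi = _mm256_add_pd(b_hi, _mm256_cvtps_pd(_mm256_extractf128_ps(d, 1)));
    g_lo = _mm256_add_pd(g_lo, _mm256_cvtps_pd(_mm256_castps256_ps128(dh)));
    g_hi = _mm256_add_pd(g_hi, _mm256_cvtps_pd(_mm256_extractf128_ps(dh, 1)));
  }
  _mm256_storeu_pd(sdg, g_lo); _mm256_storeu_pd(sdg + 4, g_hi);
  _mm256_storeu_pd(sdb, b_lo); _mm256_storeu_pd(sdb + 4, b_hi);
}

__attribute__((target("avx2,fma")))
static void bn_cm_bwd_dx_avx8(const float* dY, const float* xhat, size_t n,
                              const float* g, const float* s1, const float* s2,
                              const float* invstd_n, float N, float* dX) {
  const __m256 vg = _mm256_loadu_ps(g), v1 = _mm256_loadu_ps(s1),
               v2 = _mm256_loadu_ps(s2), vi = _mm256_loadu_ps(invstd_n),
               vN = _mm256_set1_ps(N);
  for (size_t i = 0; i < n; ++i) {
    const __m256 dxh = _mm256_mul_ps(_mm256_loadu_ps(dY + i * 8), vg);
    __m256 t = _mm256_sub_ps(_mm256_mul_ps(vN, dxh), v1);
    t = _mm256_fnmadd_ps(_mm256_loadu_ps(xhat + i * 8), v2, t);
    _mm256_storeu_ps(dX + i * 8, _mm256_mul_ps(t, vi));
  }
}
#endif

template <typename T>
static Mat<T> bn_forward_cm(const Mat<T>& X, const Mat<T>& g, const Mat<T>& b,
                            Mat<T>& run, bool training, const NetCfg& cfg,
                            BnCmCache<T>* cache) {
  const int C = X.n_rows;
  const uword n = X.n_cols;
  Col<T> mu(C), var(C);
  if (training) {
    std::vector<double> s(C, 0.0), ss(C, 0.0);
    const T* p = X.memptr();
#if defined(__x86_64__) || defined(__i386__)
    if (C == 8 && std::is_same<T, float>::value && have_avx2_conv()) {
      bn_cm_stats_avx8((const float*)p, n, s.data(), ss.data());
    } else
#endif
    for (uword i = 0; i < n; ++i) {
      for (int k = 0; k < C; ++k) {
        const double v = p[i * C + k];
        s[k] += v; ss[k] += v * v;
      }
    }
    for (int k = 0; k < C; ++k) {
      mu[k] = (T)(s[k] / n);
      var[k] = (T)(ss[k] / n - (s[k] / n) * (s[k] / n));
      if (var[k] < 0) var[k] = 0;
    }
    const T m = (T)cfg.bn_mom;
    run.row(0) = m * run.row(0) + (1 - m) * mu.t();
    run.row(1) = m * run.row(1) + (1 - m) * var.t();
  } else {
    mu = run.row(0).t(); var = run.row(1).t();
  }
  Col<T> invstd = 1.0 / sqrt(var + (T)cfg.bn_eps);
  Mat<T> Y(C, n);
  if (cache) cache->xhat.set_size(C, n);
  std::vector<T> gm(C), bm(C), mm(C), im(C);
  for (int k = 0; k < C; ++k) {
    gm[k] = g(0, k); bm[k] = b(0, k); mm[k] = mu[k]; im[k] = invstd[k];
  }
  const T* px = X.memptr();
  T* py = Y.memptr();
  T* ph = cache ? cache->xhat.memptr() : nullptr;
#if defined(__x86_64__) || defined(__i386__)
  if (C == 8 && std::is_same<T, float>::value && have_avx2_conv()) {
    bn_cm_norm_avx8((const float*)px, n, (const float*)mm.data(),
                    (const float*)im.data(), (const float*)gm.data(),
                    (const float*)bm.data(), (float*)ph, (float*)py);
  } else
#endif
  for (uword i = 0; i < n; ++i) {
    for (int k = 0; k < C; ++k) {
      const T xh = (px[i * C + k] - mm[k]) * im[k];
      if (ph) ph[i * C + k] = xh;
      py[i * C + k] = gm[k] * xh + bm[k];
    }
  }
  if (cache) cache->invstd = std::move(invstd);
  return Y;
}

template <typename T>
static Mat<T> bn_backward_cm(const Mat<T>& dY, const BnCmCache<T>& c,
                             const Mat<T>& g, Mat<T>& dg, Mat<T>& db) {
  const int C = dY.n_rows;
  const uword n = dY.n_cols;
  const T N = (T)n;
  std::vector<double> sdg(C, 0.0), sdb(C, 0.0);
  const T* pd = dY.memptr();
  const T* ph = c.xhat.memptr();
#if defined(__x86_64__) || defined(__i386__)
  if (C == 8 && std::is_same<T, float>::value && have_avx2_conv()) {
    bn_cm_bwd_sums_avx8((const float*)pd, (const float*)ph, n, sdg.data(),
                        sdb.data());
  } else
#endif
  for (uword i = 0; i < n; ++i) {
    for (int k = 0; k < C; ++k) {
      const double d = pd[i * C + k], h = ph[i * C + k];
      sdg[k] += d * h; sdb[k] += d;
    }
  }
  dg.set_size(1, C); db.set_size(1, C);
  std::vector<T> gm(C), s1m(C), s2m(C), im(C);
  for (int k = 0; k < C; ++k) {
    dg(0, k) = (T)sdg[k]; db(0, k) = (T)sdb[k];
    gm[k] = g(0, k);
    s1m[k] = (T)(sdb[k] * g(0, k));        // sum of dxhat
    s2m[k] = (T)(sdg[k] * g(0, k));        // sum of dxhat * xhat
    im[k] = c.invstd[k] / N;
  }
  Mat<T> dX(C, n);
  T* px = dX.memptr();
#if defined(__x86_64__) || defined(__i386__)
  if (C == 8 && std::is_same<T, float>::value && have_avx2_conv()) {
    bn_cm_bwd_dx_avx8((const float*)pd, (const float*)ph, n,
                      (const float*)gm.data(), (const float*)s1m.data(),
                      (const float*)s2m.data(), (const float*)im.data(), N,
                      (float*)px);
    return dX;
  }
#endif
  for (uword i = 0; i < n; ++i) {
    for (int k = 0; k < C; ++k) {
      const T dxhat = pd[i * C + k] * gm[k];
      px[i * C + k] = (N * dxhat - s1m[k] - ph[i * C + k] * s2m[k]) * im[k];
    }
  }
  return dX;
}

template <typename T>
struct BnCache { Mat<T> xhat; Row<T> invstd; };

// batch norm over rows, per column; training uses batch stats and refreshes
// the running (mean, var) slot.
template <typename T>
static Mat<T> bn_forward(const Mat<T>& X, const Mat<T>& g, const Mat<T>& b,
                         Mat<T>& run, bool training, const NetCfg& cfg,
                         BnCache<T>* cache) {
  const uword N = X.n_rows, C = X.n_cols;
  Row<T> mu(C), var(C);
  if (training) {
    mu = mean(X, 0);
    for (uword c = 0; c < C; ++c) {
      const T* p = X.colptr(c);
      const T m = mu[c];
      double s = 0;
      for (uword i = 0; i < N; ++i) { const double d = p[i] - m; s += d * d; }
      var[c] = (T)(s / N);
    }
    const T m = (T)cfg.bn_mom;
    run.row(0) = m * run.row(0) + (1 - m) * mu;
    run.row(1) = m * run.row(1) + (1 - m) * var;
  } else {
    mu = run.row(0); var = run.row(1);
  }
  Row<T> invstd = 1.0 / sqrt(var + (T)cfg.bn_eps);
  Mat<T> Y(N, C);
  if (cache) cache->xhat.set_size(N, C);
  for (uword c = 0; c < C; ++c) {
    const T m = mu[c], is = invstd[c], gc = g(0, c), bc = b(0, c);
    const T* px = X.colptr(c);
    T* py = Y.colptr(c);
    T* ph = cache ? cache->xhat.colptr(c) : nullptr;
    for (uword i = 0; i < N; ++i) {
      const T xh = (px[i] - m) * is;
      if (ph) ph[i] = xh;
      py[i] = gc * xh + bc;
    }
  }
  if (cache) cache->invstd = std::move(invstd);
  return Y;
}

template <typename T>
static Mat<T> bn_backward(const Mat<T>& dY, const BnCache<T>& c, const Mat<T>& g,
                          Mat<T>& dg, Mat<T>& db) {
  const T N = (T)dY.n_rows;
  dg = sum(dY % c.xhat, 0); db = sum(dY, 0);
  Mat<T> dxhat = dY.each_row() % Row<T>(g.row(0));
  Row<T> s1 = sum(dxhat, 0);
  Row<T> s2 = sum(dxhat % c.xhat, 0);
  Mat<T> dX = dxhat * N;
  dX.each_row() -= s1;
  dX -= c.xhat.each_row() % s2;
  dX.each_row() %= (c.invstd / N);
  return dX;
}

template <typename T> static inline T scal_tanh(T x);
template <> inline double scal_tanh<double>(double x) { return std::tanh(x); }
template <> inline float scal_tanh<float>(float x) { return fast_tanh_s(x); }
template <typename T> static inline T scal_sig(T x) {
  return (T)0.5 * ((T)1 + scal_tanh<T>((T)0.5 * x));
}

// contiguous-array activation passes; on x86 with AVX2 a runtime-dispatched
// 8-wide kernel evaluates the same rational polynomial (identical results up
// to float rounding of identical operations, so training stays deterministic
// on a given machine)
#if defined(__x86_64__) || defined(__i386__)
__attribute__((target("avx2,fma")))
static void tanh_arr_avx(float* p, int n, bool half, bool shift) {
  // half/shift turn tanh(x) into sigmoid(x) = 0.5 * (1 + tanh(x / 2))
  const __m256 mx = _mm256_set1_ps(7.90531110763549805f);
  const __m256 mn = _mm256_set1_ps(-7.90531110763549805f);
  const __m256 a1 = _mm256_set1_ps(4.89352455891786e-03f);
  const __m256 a3 = _mm256_set1_ps(6.37261928875436e-04f);
  const __m256 a5 = _mm256_set1_ps(1.48572235717979e-05f);
  const __m256 a7 = _mm256_set1_ps(5.12229709037114e-08f);
  const __m256 a9 = _mm256_set1_ps(-8.60467152213735e-11f);
  const __m256 a11 = _mm256_set1_ps(2.00018790482477e-13f);
  const __m256 a13 = _mm256_set1_ps(-2.76076847742355e-16f);
  const __m256 b0 = _mm256_set1_ps(4.89352518554385e-03f);
  const __m256 b2 = _mm256_set1_ps(2.26843463243900e-03f);
  const __m256 b4 = _mm256_set1_ps(1.18534705686654e-04f);
  const __m256 b6 = _mm256_set1_ps(1.19825839466702e-06f);
  const __m256 haf = _mm256_set1_ps(0.5f);
  const __m256 one = _mm256_set1_ps(1.0f);
  int i = 0;
  for (; i + 8 <= n; i += 8) {
    __m256 x = _mm256_loadu_ps(p + i);
    if (half) x = _mm256_mul_ps(x, haf);
    x = _mm256_min_ps(_mm256_max_ps(x, mn), mx);
    __m256 x2 = _mm256_mul_ps(x, x);
    __m256 pp = a13;
    pp = _mm256_fmadd_ps(pp, x2, a11); pp = _mm256_fmadd_ps(pp, x2, a9);
    pp = _mm256_fmadd_ps(pp, x2, a7);  pp = _mm256_fmadd_ps(pp, x2, a5);
    pp = _mm256_fmadd_ps(pp, x2, a3);  pp = _mm256_fmadd_ps(pp, x2, a1);
    pp = _mm256_mul_ps(pp, x);
    __m256 q = b6;
    q = _mm256_fmadd_ps(q, x2, b4); q = _mm256_fmadd_ps(q, x2, b2);
    q = _mm256_fmadd_ps(q, x2, b0);
    __m256 t = _mm256_div_ps(pp, q);
    if (shift) t = _mm256_mul_ps(haf, _mm256_add_ps(one, t));
    _mm256_storeu_ps(p + i, t);
  }
  for (; i < n; ++i) {
    p[i] = shift ? 0.5f * (1.0f + fast_tanh_s(0.5f * p[i])) : fast_tanh_s(p[i]);
  }
}
static bool have_avx2() {
  static const bool ok = __builtin_cpu_supports("avx2") &&
                         __builtin_cpu_supports("fma") &&
                         std::getenv("NR_NO_AVX2") == nullptr;
  return ok;
}
static bool have_avx2_conv() { return have_avx2(); }

__attribute__((target("avx2,fma")))
static void lstm_bwd_gates_avx(float* pi, float* pf, float* pg, float* po,
                               const float* pt, const float* pdH,
                               const float* pcp, float* pdhc, float* pdcc,
                               int B) {
  const __m256 one = _mm256_set1_ps(1.0f);
  int b = 0;
  for (; b + 8 <= B; b += 8) {
    const __m256 i = _mm256_loadu_ps(pi + b);
    const __m256 f = _mm256_loadu_ps(pf + b);
    const __m256 g = _mm256_loadu_ps(pg + b);
    const __m256 o = _mm256_loadu_ps(po + b);
    const __m256 tc = _mm256_loadu_ps(pt + b);
    const __m256 dh = _mm256_add_ps(_mm256_loadu_ps(pdH + b),
                                    _mm256_loadu_ps(pdhc + b));
    __m256 dc = _mm256_mul_ps(_mm256_mul_ps(dh, o),
                              _mm256_fnmadd_ps(tc, tc, one));
    dc = _mm256_add_ps(dc, _mm256_loadu_ps(pdcc + b));
    const __m256 cp = pcp ? _mm256_loadu_ps(pcp + b) : _mm256_setzero_ps();
    _mm256_storeu_ps(pi + b, _mm256_mul_ps(_mm256_mul_ps(dc, g),
        _mm256_mul_ps(i, _mm256_sub_ps(one, i))));
    _mm256_storeu_ps(pf + b, _mm256_mul_ps(_mm256_mul_ps(dc, cp),
        _mm256_mul_ps(f, _mm256_sub_ps(one, f))));
    _mm256_storeu_ps(pg + b, _mm256_mul_ps(_mm256_mul_ps(dc, i),
        _mm256_fnmadd_ps(g, g, one)));
    _mm256_storeu_ps(po + b, _mm256_mul_ps(_mm256_mul_ps(dh, tc),
        _mm256_mul_ps(o, _mm256_sub_ps(one, o))));
    _mm256_storeu_ps(pdcc + b, _mm256_mul_ps(dc, f));
  }
  for (; b < B; ++b) {
    const float i = pi[b], f = pf[b], g = pg[b], o = po[b], tc = pt[b];
    const float dh = pdH[b] + pdhc[b];
    const float dc = dh * o * (1 - tc * tc) + pdcc[b];
    const float cp = pcp ? pcp[b] : 0.0f;
    pi[b] = dc * g * i * (1 - i);
    pf[b] = dc * cp * f * (1 - f);
    pg[b] = dc * i * (1 - g * g);
    po[b] = dh * tc * o * (1 - o);
    pdcc[b] = dc * f;
  }
}
#else
static bool have_avx2() { return false; }
static void tanh_arr_avx(float*, int, bool, bool) {}
static void lstm_bwd_gates_avx(float*, float*, float*, float*, const float*,
                               const float*, const float*, float*, float*,
                               int) {}
#endif

template <typename T>
static inline void lstm_bwd_gates(T* pi, T* pf, T* pg, T* po, const T* pt,
                                  const T* pdH, const T* pcp, T* pdhc, T* pdcc,
                                  int B) {
  for (int bb = 0; bb < B; ++bb) {
    const T i = pi[bb], f = pf[bb], g = pg[bb], o = po[bb], tc = pt[bb];
    const T dh = pdH[bb] + pdhc[bb];
    const T dc = dh * o * (1 - tc * tc) + pdcc[bb];
    const T cprev = pcp ? pcp[bb] : (T)0;
    pi[bb] = dc * g * i * (1 - i);
    pf[bb] = dc * cprev * f * (1 - f);
    pg[bb] = dc * i * (1 - g * g);
    po[bb] = dh * tc * o * (1 - o);
    pdcc[bb] = dc * f;
  }
}
template <>
inline void lstm_bwd_gates<float>(float* pi, float* pf, float* pg, float* po,
                                  const float* pt, const float* pdH,
                                  const float* pcp, float* pdhc, float* pdcc,
                                  int B) {
  if (have_avx2()) {
    lstm_bwd_gates_avx(pi, pf, pg, po, pt, pdH, pcp, pdhc, pdcc, B);
    return;
  }
  for (int bb = 0; bb < B; ++bb) {
    const float i = pi[bb], f = pf[bb], g = pg[bb], o = po[bb], tc = pt[bb];
    const float dh = pdH[bb] + pdhc[bb];
    const float dc = dh * o * (1 - tc * tc) + pdcc[bb];
    const float cprev = pcp ? pcp[bb] : 0.0f;
    pi[bb] = dc * g * i * (1 - i);
    pf[bb] = dc * cprev * f * (1 - f);
    pg[bb] = dc * i * (1 - g * g);
    po[bb] = dh * tc * o * (1 - o);
    pdcc[bb] = dc * f;
  }
}

template <typename T> static inline void tanh_arr(T* p, int n) {
  for (int i = 0; i < n; ++i) p[i] = scal_tanh<T>(p[i]);
}
template <> inline void tanh_arr<float>(float* p, int n) {
  if (have_avx2()) tanh_arr_avx(p, n, false, false);
  else for (int i = 0; i < n; ++i) p[i] = fast_tanh_s(p[i]);
}
template <typename T> static inline void sig_arr(T* p, int n) {
  for (int i = 0; i < n; ++i) p[i] = scal_sig<T>(p[i]);
}
template <> inline void sig_arr<float>(float* p, int n) {
  if (have_avx2()) tanh_arr_avx(p, n, true, true);
  else for (int i = 0; i < n; ++i)
    p[i] = 0.5f * (1.0f + fast_tanh_s(0.5f * p[i]));
}

// Bi-LSTM over a (B*w x in) position-major input. Gate order [i f g o];
// Wx columns are [forward 4h | reverse 4h]. After the forward pass the gate
// matrix G holds the *activated* gates (consumed again by the backward
// pass, which overwrites them with pre-activation gradients).
template <typename T>
struct LstmCache {
  Mat<T> X, H;          // input, output (BW x 2h)
  Mat<T> G;             // BW x 8h activated gates
  Mat<T> Cf, Tf, Cr, Tr;  // cell states and tanh(cell) per direction
};

// contiguous row-block helper (rows p0..p0+B-1, cols c..c+k-1) as a copy
template <typename T>
static inline Mat<T> cc_rows(const Mat<T>& M, uword p0, int B, int c, int k) {
  return M.submat(p0, c, p0 + B - 1, c + k - 1);
}

template <typename T>
static Mat<T> lstm_bi_forward(const Mat<T>& X, const Mat<T>& Wx, const Mat<T>& Whf,
                              const Mat<T>& Whr, const Mat<T>& b, int B, int w,
                              LstmCache<T>* cache) {
  const int h = Whf.n_rows;
  const uword BW = X.n_rows;
  Mat<T> G = X * Wx;
  G.each_row() += Row<T>(b.row(0));
  Mat<T> H(BW, 2 * h);
  Mat<T> Cf(BW, h), Tf(BW, h), Cr(BW, h), Tr(BW, h);

  auto run_dir = [&](bool fwd) {
    Mat<T>& C_ = fwd ? Cf : Cr;
    Mat<T>& T_ = fwd ? Tf : Tr;
    const Mat<T>& Wh = fwd ? Whf : Whr;
    const int c0 = fwd ? 0 : 4 * h;
    const int hcol = fwd ? 0 : h;
    for (int s = 0; s < w; ++s) {
      const int t = fwd ? s : (w - 1 - s);
      const uword r0 = (uword)t * B, r1 = r0 + B - 1;
      const int tp = fwd ? (t - 1) : (t + 1);
      const uword p0 = (uword)tp * B;
      if (s > 0) {
        // G[t-block] += H[prev-block] * Wh, both strided views
        gemm_raw<T>('N', B, 4 * h, h,
                    H.colptr(hcol) + p0, (int)H.n_rows,
                    Wh.memptr(), h,
                    (T)1, G.colptr(c0) + r0, (int)G.n_rows);
      }
      // gate activations, one vectorizable pass per column
      for (int j = 0; j < 4 * h; ++j) {
        T* p = G.colptr(c0 + j) + r0;
        if (j >= 2 * h && j < 3 * h) tanh_arr(p, B); else sig_arr(p, B);
      }
      // cell state, tanh(cell), hidden output
      for (int j = 0; j < h; ++j) {
        const T* pi = G.colptr(c0 + j) + r0;
        const T* pf = G.colptr(c0 + h + j) + r0;
        const T* pg = G.colptr(c0 + 2 * h + j) + r0;
        T* pc = C_.colptr(j) + r0;
        T* pt = T_.colptr(j) + r0;
        const T* pcp = (s > 0) ? (C_.colptr(j) + p0) : nullptr;
        if (pcp) {
          for (int bb = 0; bb < B; ++bb) pc[bb] = pf[bb] * pcp[bb] + pi[bb] * pg[bb];
        } else {
          for (int bb = 0; bb < B; ++bb) pc[bb] = pi[bb] * pg[bb];
        }
        for (int bb = 0; bb < B; ++bb) pt[bb] = pc[bb];
        tanh_arr(pt, B);
      }
      for (int j = 0; j < h; ++j) {
        const T* po = G.colptr(c0 + 3 * h + j) + r0;
        const T* pt = T_.colptr(j) + r0;
        T* ph = H.colptr(hcol + j) + r0;
        for (int bb = 0; bb < B; ++bb) ph[bb] = po[bb] * pt[bb];
      }
    }
  };
  run_dir(true); run_dir(false);
  if (cache) {
    cache->X = X; cache->H = H; cache->G = std::move(G);
    cache->Cf = std::move(Cf); cache->Tf = std::move(Tf);
    cache->Cr = std::move(Cr); cache->Tr = std::move(Tr);
    return cache->H;
  }
  return H;
}

template <typename T>
static Mat<T> lstm_bi_backward(const Mat<T>& dH, LstmCache<T>& cc,
                               const Mat<T>& Wx, const Mat<T>& Whf, const Mat<T>& Whr,
                               int B, int w,
                               Mat<T>& dWx, Mat<T>& dWhf, Mat<T>& dWhr, Mat<T>& db) {
  const int h = Whf.n_rows;
  Mat<T>& G = cc.G;  // activated gates; overwritten with dG in place
  dWhf.zeros(h, 4 * h); dWhr.zeros(h, 4 * h);

  auto run_dir = [&](bool fwd) {
    const Mat<T>& C_ = fwd ? cc.Cf : cc.Cr;
    const Mat<T>& T_ = fwd ? cc.Tf : cc.Tr;
    const Mat<T>& Wh = fwd ? Whf : Whr;
    Mat<T>& dWh = fwd ? dWhf : dWhr;
    const int c0 = fwd ? 0 : 4 * h;
    const int hcol = fwd ? 0 : h;
    Mat<T> dh_carry(B, h, fill::zeros), dc_carry(B, h, fill::zeros);
    for (int s = w - 1; s >= 0; --s) {
      const int t = fwd ? s : (w - 1 - s);
      const uword r0 = (uword)t * B, r1 = r0 + B - 1;
      const int tp = fwd ? (t - 1) : (t + 1);
      const uword p0 = (s > 0) ? (uword)tp * B : 0;
      for (int j = 0; j < h; ++j) {
        lstm_bwd_gates<T>(G.colptr(c0 + j) + r0, G.colptr(c0 + h + j) + r0,
                          G.colptr(c0 + 2 * h + j) + r0,
                          G.colptr(c0 + 3 * h + j) + r0,
                          T_.colptr(j) + r0, dH.colptr(hcol + j) + r0,
                          (s > 0) ? (C_.colptr(j) + p0) : nullptr,
                          dh_carry.colptr(j), dc_carry.colptr(j), B);
      }
      if (s > 0) {
        // dh_carry = dG[t-block] * Wh^T
        gemm_raw<T>('T', B, h, 4 * h,
                    G.colptr(c0) + r0, (int)G.n_rows,
                    Wh.memptr(), h,
                    (T)0, dh_carry.memptr(), B);
      }
    }
    // dWh = sum_t Hprev_t^T dG_t collapses into one shifted product: the
    // previous-step rows of H are the output rows offset by one time block
    const uword BW = G.n_rows;
    if (fwd) {
      dWh = cc.H.submat(0, hcol, BW - B - 1, hcol + h - 1).t() *
            G.submat(B, c0, BW - 1, c0 + 4 * h - 1);
    } else {
      dWh = cc.H.submat(B, hcol, BW - 1, hcol + h - 1).t() *
            G.submat(0, c0, BW - B - 1, c0 + 4 * h - 1);
    }
  };
  run_dir(true); run_dir(false);
  dWx = cc.X.t() * G;
  db = sum(G, 0);
  return G * Wx.t();
}

// mean-pool each event's cap-sample block: channel-major (C x B*L) in,
// position-major (B*w x C) out (the layout the trunk consumes)
template <typename T>
static Mat<T> pool_forward(const Mat<T>& A, int B, int w, int cap) {
  const int C = A.n_rows;
  const uword BW = (uword)B * w;
  Mat<T> P(BW, C);
  std::vector<T> buf((size_t)B * C);
  const T inv = (T)1 / (T)cap;
  for (int t = 0; t < w; ++t) {
    std::fill(buf.begin(), buf.end(), (T)0);
    for (int i = 0; i < cap; ++i) {
      // consecutive columns are contiguous, so an event block is one flat run
      const T* src = A.colptr(((uword)t * cap + i) * B);
      for (size_t j = 0; j < buf.size(); ++j) buf[j] += src[j];
    }
    for (int b = 0; b < B; ++b)
      for (int ch = 0; ch < C; ++ch)
        P((uword)t * B + b, ch) = buf[(size_t)b * C + ch] * inv;
  }
  return P;
}

template <typename T>
static Mat<T> pool_backward(const Mat<T>& dP, int B, int w, int cap) {
  const int C = dP.n_cols;
  Mat<T> dA(C, (uword)B * w * cap);
  std::vector<T> buf((size_t)B * C);
  const T inv = (T)1 / (T)cap;
  for (int t = 0; t < w; ++t) {
    for (int b = 0; b < B; ++b)
      for (int ch = 0; ch < C; ++ch)
        buf[(size_t)b * C + ch] = dP((uword)t * B + b, ch) * inv;
    for (int i = 0; i < cap; ++i) {
      T* dst = dA.colptr(((uword)t * cap + i) * B);
      std::copy(buf.begin(), buf.end(), dst);
    }
  }
  return dA;
}

// ------------------------------------------------------------ whole net ----

static double prof_conv = 0, prof_feat = 0, prof_trunk = 0, prof_head = 0,
              prof_layout = 0, prof_bhead = 0, prof_btrunk = 0, prof_bfeat = 0,
              prof_bconv = 0;
static inline double prof_now() {
  return std::chrono::duration<double>(
      std::chrono::steady_clock::now().time_since_epoch()).count();
}

template <typename T>
struct NetCache {
  int B = 0;
  // signal branch
  Mat<T> X0;                       // signal input, channel-major (1 x B*L)
  std::vector<BnCmCache<T>> bn_cm; // conv-side batch norms (bn0, bnA/bnB ...)
  std::vector<BnCache<T>> bn;      // feature-branch batch norms
  std::vector<Mat<T>> relu;        // outputs after each relu (mask source)
  // feature branch
  std::vector<LstmCache<T>> feat;
  std::vector<LstmCache<T>> trunk;
  Mat<T> Xtr;                      // trunk input
  Mat<T> Hc, Hd, mask;             // center slice, after dropout, mask
  Mat<T> F1pre, F1, logits, probs;
};

// layout helpers: R gives B x (w*cap) and B x (w*F); the signal branch is
// channel-major over flat sample index p*B + b, the recurrent branches are
// position-major over rows.
template <typename T>
static Mat<T> sig_to_internal(const Mat<T>& S) {
  Mat<T> X(1, S.n_rows * S.n_cols);
  X.row(0) = vectorise(S).t();
  return X;
}

template <typename T>
static Mat<T> feat_to_internal(const Mat<T>& Xf, int w, int F) {
  const uword B = Xf.n_rows;
  Mat<T> X((uword)B * w, F);
  for (int t = 0; t < w; ++t)
    for (int f = 0; f < F; ++f)
      X.submat((uword)t * B, f, (uword)t * B + B - 1, f) = Xf.col((uword)t * F + f);
  return X;
}

template <typename T>
static void forward_net(const std::vector<Mat<T>>& P, std::vector<Mat<T>>& bnrun,
                        const NetCfg& cfg, const Mat<T>& S, const Mat<T>& Xf,
                        bool training, bool use_dropout, std::mt19937* rng,
                        NetCache<T>& cc) {
  const int B = S.n_rows, w = cfg.w, cap = cfg.cap;
  cc.B = B;
  int pi = 0, bni = 0;
  cc.bn.clear(); cc.bn_cm.clear(); cc.relu.clear();
  cc.feat.clear(); cc.trunk.clear();
  const int nbn_cm = 1 + 2 * cfg.nres;
  cc.bn_cm.resize(nbn_cm);
  cc.bn.resize(n_bn(cfg) - nbn_cm);

  double tA = prof_now();
  // --- signal branch
  cc.X0 = sig_to_internal(S);
  Mat<T> A = conv3_forward(cc.X0, P[pi], P[pi + 1], B);
  A = bn_forward_cm(A, P[pi + 2], P[pi + 3], bnrun[bni], training, cfg,
                    &cc.bn_cm[bni]);
  pi += 4; bni += 1;
  relu_ip(A);
  cc.relu.push_back(A);
  for (int r = 0; r < cfg.nres; ++r) {
    Mat<T> a1 = conv3_forward(A, P[pi], P[pi + 1], B);
    a1 = bn_forward_cm(a1, P[pi + 2], P[pi + 3], bnrun[bni], training, cfg,
                       &cc.bn_cm[bni]);
    bni += 1;
    relu_ip(a1);
    cc.relu.push_back(a1);
    Mat<T> a2 = conv3_forward(a1, P[pi + 4], P[pi + 5], B);
    a2 = bn_forward_cm(a2, P[pi + 6], P[pi + 7], bnrun[bni], training, cfg,
                       &cc.bn_cm[bni]);
    bni += 1;
    if (cfg.shortcut) a2 += A;
    relu_ip(a2);
    A = std::move(a2);
    cc.relu.push_back(A);
    pi += 8;
  }
  Mat<T> Psig = pool_forward(A, B, w, cap);
  double tB = prof_now(); prof_conv += tB - tA;

  // --- feature branch
  Mat<T> Xl = feat_to_internal(Xf, w, cfg.F);
  cc.feat.resize(cfg.nfeat);
  for (int l = 0; l < cfg.nfeat; ++l) {
    Mat<T> H = lstm_bi_forward(Xl, P[pi], P[pi + 1], P[pi + 2], P[pi + 3], B, w,
                               &cc.feat[l]);
    H = bn_forward(H, P[pi + 4], P[pi + 5], bnrun[bni], training, cfg,
                   &cc.bn[bni - nbn_cm]);
    bni += 1; pi += 6;
    Xl = std::move(H);
  }

  double tC = prof_now(); prof_feat += tC - tB;
  // --- trunk
  cc.Xtr = join_rows(Psig, Xl);
  Mat<T> Ht = cc.Xtr;
  cc.trunk.resize(cfg.ntrunk);
  for (int l = 0; l < cfg.ntrunk; ++l) {
    Ht = lstm_bi_forward(Ht, P[pi], P[pi + 1], P[pi + 2], P[pi + 3], B, w,
                         &cc.trunk[l]);
    pi += 4;
  }
  double tD = prof_now(); prof_trunk += tD - tC;
  const int tc = (w - 1) / 2;
  cc.Hc = Ht.rows((uword)tc * B, (uword)tc * B + B - 1);
  if (training && use_dropout && cfg.dropout > 0) {
    cc.mask.set_size(cc.Hc.n_rows, cc.Hc.n_cols);
    const T keep = (T)(1.0 - cfg.dropout);
    T* mp = cc.mask.memptr();
    for (uword i = 0; i < cc.mask.n_elem; ++i) {
      double u = ((*rng)() >> 8) * (1.0 / 16777216.0);
      mp[i] = (u >= cfg.dropout) ? (T)1 / keep : (T)0;
    }
    cc.Hd = cc.Hc % cc.mask;
  } else {
    cc.mask.reset();
    cc.Hd = cc.Hc;
  }
  cc.F1pre = cc.Hd * P[pi]; cc.F1pre.each_row() += Row<T>(P[pi + 1].row(0));
  cc.F1 = cc.F1pre;
  cc.F1.transform([](T v) { return v > 0 ? v : (T)0; });
  cc.logits = cc.F1 * P[pi + 2]; cc.logits.each_row() += Row<T>(P[pi + 3].row(0));

  // stable softmax
  Mat<T> z = cc.logits;
  z.each_col() -= max(cc.logits, 1);
  z = exp(z);
  Col<T> rs = sum(z, 1);
  z.each_col() /= rs;
  cc.probs = std::move(z);
  prof_head += prof_now() - tD;
}

// cross-entropy (mean) and center loss (mean, paper's 1/2 factor) on a batch
template <typename T>
static void loss_head(const NetCache<T>& cc, const uvec& y, const Mat<T>& centers,
                      double lambda, double& ls, double& lc) {
  const uword B = cc.probs.n_rows;
  double s = 0;
  for (uword i = 0; i < B; ++i)
    s -= std::log(std::max((double)cc.probs(i, y[i]), 1e-300));
  ls = s / B;
  double c = 0;
  for (uword i = 0; i < B; ++i) {
    Row<T> diff = cc.F1.row(i) - centers.row(y[i]);
    c += 0.5 * (double)dot(diff, diff);
  }
  lc = c / B;
  (void)lambda;
}

// full backward pass; grads aligned with param_spec order
template <typename T>
static std::vector<Mat<T>> backward_net(const std::vector<Mat<T>>& P, const NetCfg& cfg,
                                        NetCache<T>& cc, const uvec& y,
                                        const Mat<T>& centers) {
  auto spec = param_spec(cfg);
  std::vector<Mat<T>> G(spec.size());
  const int B = cc.B, w = cfg.w, cap = cfg.cap;
  int pi = (int)spec.size();
  double tq = prof_now();

  // head
  Mat<T> dlogits = cc.probs;
  for (int i = 0; i < B; ++i) dlogits(i, y[i]) -= (T)1;
  dlogits /= (T)B;
  pi -= 4; // dense1_W dense1_b dense2_W dense2_b
  G[pi + 2] = cc.F1.t() * dlogits;
  G[pi + 3] = sum(dlogits, 0);
  Mat<T> dF1 = dlogits * P[pi + 2].t();
  if (cfg.lambda > 0) {
    Mat<T> cdiff = cc.F1;
    for (int i = 0; i < B; ++i) cdiff.row(i) -= centers.row(y[i]);
    dF1 += ((T)(cfg.lambda / B)) * cdiff;
  }
  relu_mask_ip(dF1, cc.F1);
  G[pi] = cc.Hd.t() * dF1;
  G[pi + 1] = sum(dF1, 0);
  Mat<T> dHd = dF1 * P[pi].t();
  if (!cc.mask.is_empty()) dHd %= cc.mask;

  // scatter into trunk output grad
  const int tc = (w - 1) / 2;
  Mat<T> dHt((uword)B * w, 2 * cfg.ht, fill::zeros);
  dHt.rows((uword)tc * B, (uword)tc * B + B - 1) = dHd;

  prof_bhead += prof_now() - tq; tq = prof_now();
  for (int l = cfg.ntrunk - 1; l >= 0; --l) {
    pi -= 4;
    Mat<T> dWx, dWhf, dWhr, db;
    dHt = lstm_bi_backward(dHt, cc.trunk[l], P[pi], P[pi + 1], P[pi + 2], B, w,
                           dWx, dWhf, dWhr, db);
    G[pi] = std::move(dWx); G[pi + 1] = std::move(dWhf);
    G[pi + 2] = std::move(dWhr); G[pi + 3] = std::move(db);
  }
  prof_btrunk += prof_now() - tq; tq = prof_now();
  Mat<T> dPsig = dHt.cols(0, cfg.C - 1);
  Mat<T> dXl = dHt.cols(cfg.C, cfg.C + 2 * cfg.hf - 1);

  // feature branch (reverse); cc.bn holds only the feature-layer caches
  int bni = cfg.nfeat;
  for (int l = cfg.nfeat - 1; l >= 0; --l) {
    pi -= 6; bni -= 1;
    Mat<T> dg, db2;
    dXl = bn_backward(dXl, cc.bn[bni], P[pi + 4], dg, db2);
    G[pi + 4] = std::move(dg); G[pi + 5] = std::move(db2);
    Mat<T> dWx, dWhf, dWhr, db;
    dXl = lstm_bi_backward(dXl, cc.feat[l], P[pi], P[pi + 1], P[pi + 2], B, w,
                           dWx, dWhf, dWhr, db);
    G[pi] = std::move(dWx); G[pi + 1] = std::move(dWhf);
    G[pi + 2] = std::move(dWhr); G[pi + 3] = std::move(db);
  }

  prof_bfeat += prof_now() - tq; tq = prof_now();
  // signal branch (reverse); relu list is [r0, (a1, out) per block]
  Mat<T> dA = pool_backward(dPsig, B, w, cap);
  int relu_i = (int)cc.relu.size() - 1;
  for (int r = cfg.nres - 1; r >= 0; --r) {
    pi -= 8;
    relu_mask_ip(dA, cc.relu[relu_i]); relu_i--;
    Mat<T> dshort = cfg.shortcut ? dA : Mat<T>(dA.n_rows, dA.n_cols, fill::zeros);
    // bnB then convB (input = a1 = relu[relu_i])
    bni = 1 + 2 * r + 1;
    Mat<T> dg, dbb;
    Mat<T> da2 = bn_backward_cm(dA, cc.bn_cm[bni], P[pi + 6], dg, dbb);
    G[pi + 6] = std::move(dg); G[pi + 7] = std::move(dbb);
    Mat<T> dr1 = conv3_backward(da2, cc.relu[relu_i], P[pi + 4], B,
                                G[pi + 4], G[pi + 5]);
    relu_mask_ip(dr1, cc.relu[relu_i]); relu_i--;
    // bnA then convA (input = previous block output = relu[relu_i])
    bni = 1 + 2 * r;
    Mat<T> da1 = bn_backward_cm(dr1, cc.bn_cm[bni], P[pi + 2], dg, dbb);
    G[pi + 2] = std::move(dg); G[pi + 3] = std::move(dbb);
    dA = conv3_backward(da1, cc.relu[relu_i], P[pi], B, G[pi], G[pi + 1]);
    dA += dshort;
  }
  pi -= 4;
  relu_mask_ip(dA, cc.relu[relu_i]);
  Mat<T> dg0, db0;
  Mat<T> da0 = bn_backward_cm(dA, cc.bn_cm[0], P[pi + 2], dg0, db0);
  G[pi + 2] = std::move(dg0); G[pi + 3] = std::move(db0);
  Mat<T> dX0 = conv3_backward(da0, cc.X0, P[pi], B, G[pi], G[pi + 1]);
  (void)dX0;
  prof_bconv += prof_now() - tq;
  return G;
}

// standard mini-batch center update: c_j <- c_j - alpha * sum(c_j - x_i)/(1+n_j)
template <typename T>
static void update_centers(Mat<T>& centers, const Mat<T>& F1, const uvec& y,
                           double alpha) {
  const int K = centers.n_rows;
  std::vector<int> n(K, 0);
  Mat<T> acc(centers.n_rows, centers.n_cols, fill::zeros);
  for (uword i = 0; i < y.n_elem; ++i) {
    acc.row(y[i]) += centers.row(y[i]) - F1.row(i);
    n[y[i]] += 1;
  }
  for (int j = 0; j < K; ++j)
    if (n[j] > 0) centers.row(j) -= (T)alpha * acc.row(j) / (T)(1 + n[j]);
}

// ------------------------------------------------------------- training ----

template <typename T>
static Rcpp::List train_impl(const Rcpp::List& paramsR, const Rcpp::List& bnR,
                             SEXP centersR, const NetCfg& cfg,
                             SEXP S_R, SEXP X_R, const ivec& yv,
                             unsigned int seed) {
  std::vector<Mat<T>> P = params_in<T>(paramsR, cfg);
  std::vector<Mat<T>> bnrun = bn_in<T>(bnR);
  Mat<T> centers = as_matT<T>(centersR);
  // transposed storage: gathering a mini-batch reads contiguous columns
  Mat<T> S_all = as_matT<T>(S_R).t(), X_all = as_matT<T>(X_R).t();
  const int N = S_all.n_cols;
  if (N < 1) Rcpp::stop("empty training set");
  uvec y(N);
  for (int i = 0; i < N; ++i) {
    if (yv[i] < 0 || yv[i] >= cfg.K) Rcpp::stop("label outside class range");
    y[i] = (uword)yv[i];
  }

  // Adam state
  std::vector<Mat<T>> m(P.size()), v(P.size());
  for (size_t i = 0; i < P.size(); ++i) {
    m[i].zeros(P[i].n_rows, P[i].n_cols);
    v[i].zeros(P[i].n_rows, P[i].n_cols);
  }
  std::mt19937 rng(seed);
  std::vector<uword> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;

  mat history(cfg.epochs, 3, fill::zeros);
  long step = 0;
  double prof_gather = 0, prof_fwd = 0, prof_bwd = 0, prof_adam = 0;
  NetCache<T> cc;
  for (int e = 0; e < cfg.epochs; ++e) {
    // Fisher-Yates with explicit modulo draw for cross-platform determinism
    for (int i = N - 1; i > 0; --i) {
      uword j = rng() % (uword)(i + 1);
      std::swap(perm[i], perm[j]);
    }
    const double lr_e = cfg.lr / (1.0 + cfg.decay * e);
    double etot = 0, els = 0, elc = 0; long seen = 0;
    for (int off = 0; off < N; off += cfg.batch) {
      const int B = std::min(cfg.batch, N - off);
      uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = perm[off + i];
      auto t0 = std::chrono::steady_clock::now();
      Mat<T> S = S_all.cols(idx).t(), X = X_all.cols(idx).t();
      uvec yb(B);
      for (int i = 0; i < B; ++i) yb[i] = y[idx[i]];
      auto t1 = std::chrono::steady_clock::now();

      forward_net(P, bnrun, cfg, S, X, true, true, &rng, cc);
      double ls, lc;
      loss_head(cc, yb, centers, cfg.lambda, ls, lc);
      const double tot = ls + cfg.lambda * lc;
      if (!std::isfinite(tot))
        Rcpp::stop("non-finite loss at epoch %d (Ls=%g, Lc=%g); aborting", e + 1, ls, lc);
      etot += tot * B; els += ls * B; elc += lc * B; seen += B;
      auto t2 = std::chrono::steady_clock::now();

      std::vector<Mat<T>> Gd = backward_net(P, cfg, cc, yb, centers);
      auto t3 = std::chrono::steady_clock::now();
      prof_gather += std::chrono::duration<double>(t1 - t0).count();
      prof_fwd += std::chrono::duration<double>(t2 - t1).count();
      prof_bwd += std::chrono::duration<double>(t3 - t2).count();
      step += 1;
      const double b1t = 1.0 - std::pow(cfg.beta1, (double)step);
      const double b2t = 1.0 - std::pow(cfg.beta2, (double)step);
      const T bb1 = (T)cfg.beta1, bb2 = (T)cfg.beta2;
      const T ib1 = 1 - bb1, ib2 = 1 - bb2;
      const T ilr = (T)lr_e, ieps = (T)cfg.adam_eps;
      const T r1 = (T)(1.0 / b1t), r2 = (T)(1.0 / b2t);
      for (size_t i = 0; i < P.size(); ++i) {
        T* pp = P[i].memptr(); T* pm = m[i].memptr();
        T* pv = v[i].memptr(); const T* pg = Gd[i].memptr();
        const uword n = P[i].n_elem;
        for (uword j = 0; j < n; ++j) {
          const T gj = pg[j];
          pm[j] = bb1 * pm[j] + ib1 * gj;
          pv[j] = bb2 * pv[j] + ib2 * gj * gj;
          pp[j] -= ilr * (pm[j] * r1) / (std::sqrt(pv[j] * r2) + ieps);
        }
      }
      if (cfg.lambda > 0) update_centers(centers, cc.F1, yb, cfg.center_alpha);
      prof_adam += std::chrono::duration<double>(
          std::chrono::steady_clock::now() - t3).count();
    }
    history(e, 0) = etot / seen; history(e, 1) = els / seen; history(e, 2) = elc / seen;
    Rcpp::checkUserInterrupt();
  }

  if (std::getenv("NR_PROFILE") != nullptr) {
    Rcpp::Rcout << "profile: gather " << prof_gather << "s forward " << prof_fwd
                << "s backward " << prof_bwd << "s update " << prof_adam
                << "s | fwd: conv " << prof_conv << " feat " << prof_feat
                << " trunk " << prof_trunk << " head " << prof_head
                << " | bwd: head " << prof_bhead << " trunk " << prof_btrunk
                << " feat " << prof_bfeat << " conv " << prof_bconv << "\n";
  }
  Rcpp::List bnOut(bnrun.size());
  for (size_t i = 0; i < bnrun.size(); ++i) bnOut[i] = to_rmat(bnrun[i]);
  return Rcpp::List::create(
      Rcpp::Named("params") = params_out(P, cfg),
      Rcpp::Named("bn") = bnOut,
      Rcpp::Named("centers") = to_rmat(centers),
      Rcpp::Named("history") = history);
}

template <typename T>
static Rcpp::List predict_impl(const Rcpp::List& paramsR, const Rcpp::List& bnR,
                               const NetCfg& cfg, SEXP S_R, SEXP X_R,
                               bool return_features) {
  std::vector<Mat<T>> P = params_in<T>(paramsR, cfg);
  std::vector<Mat<T>> bnrun = bn_in<T>(bnR);
  Mat<T> S_all = as_matT<T>(S_R), X_all = as_matT<T>(X_R);
  const int N = S_all.n_rows;
  mat probs(N, cfg.K);
  mat feats;
  if (return_features) feats.set_size(N, cfg.d);
  NetCache<T> cc;
  for (int off = 0; off < N; off += cfg.batch) {
    const int B = std::min(cfg.batch, N - off);
    Mat<T> S = S_all.rows(off, off + B - 1), X = X_all.rows(off, off + B - 1);
    forward_net(P, bnrun, cfg, S, X, false, false, nullptr, cc);
    probs.rows(off, off + B - 1) = conv_to<mat>::from(cc.probs);
    if (return_features) feats.rows(off, off + B - 1) = conv_to<mat>::from(cc.F1);
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("features") = feats);
}

// ------------------------------------------------------------ interfaces ---

// [[Rcpp::export]]
Rcpp::List cpp_param_spec(Rcpp::List config) {
  NetCfg cfg = parse_cfg(config);
  auto spec = param_spec(cfg);
  Rcpp::CharacterVector nm(spec.size());
  Rcpp::IntegerMatrix dims(spec.size(), 2);
  for (size_t i = 0; i < spec.size(); ++i) {
    nm[i] = spec[i].name;
    dims(i, 0) = spec[i].nr; dims(i, 1) = spec[i].nc;
  }
  return Rcpp::List::create(Rcpp::Named("names") = nm,
                            Rcpp::Named("dims") = dims,
                            Rcpp::Named("n_bn") = n_bn(cfg));
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_train(Rcpp::List params, Rcpp::List bn, SEXP centers,
                        Rcpp::List config, SEXP S, SEXP X,
                        Rcpp::IntegerVector y, int seed) {
  NetCfg cfg = parse_cfg(config);
  ivec yv(y.size());
  for (int i = 0; i < y.size(); ++i) yv[i] = y[i];
  if (cfg.precision == "single")
    return train_impl<float>(params, bn, centers, cfg, S, X, yv, (unsigned)seed);
  return train_impl<double>(params, bn, centers, cfg, S, X, yv, (unsigned)seed);
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_predict(Rcpp::List params, Rcpp::List bn, Rcpp::List config,
                          SEXP S, SEXP X, bool return_features = false) {
  NetCfg cfg = parse_cfg(config);
  if (cfg.precision == "single")
    return predict_impl<float>(params, bn, cfg, S, X, return_features);
  return predict_impl<double>(params, bn, cfg, S, X, return_features);
}

// Loss (and optionally analytic gradients) on one batch in training mode
// (batch statistics, no dropout); double precision only — used by the
// finite-difference gradient verification and loss-decomposition tests.
// [[Rcpp::export]]
Rcpp::List cpp_nn_loss_grads(Rcpp::List params, Rcpp::List bn, SEXP centers,
                             Rcpp::List config, SEXP S, SEXP X,
                             Rcpp::IntegerVector y, bool gradients = true) {
  NetCfg cfg = parse_cfg(config);
  std::vector<mat> P = params_in<double>(params, cfg);
  std::vector<mat> bnrun = bn_in<double>(bn);
  // copy: loss evaluation must not mutate running stats observable to caller
  mat C = as_matT<double>(centers);
  mat Sm = as_matT<double>(S), Xm = as_matT<double>(X);
  uvec yb(y.size());
  for (int i = 0; i < y.size(); ++i) {
    if (y[i] < 0 || y[i] >= cfg.K) Rcpp::stop("label outside class range");
    yb[i] = (uword)y[i];
  }
  NetCache<double> cc;
  forward_net(P, bnrun, cfg, Sm, Xm, true, false, nullptr, cc);
  double ls, lc;
  loss_head(cc, yb, C, cfg.lambda, ls, lc);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("total") = ls + cfg.lambda * lc,
      Rcpp::Named("ls") = ls, Rcpp::Named("lc") = lc,
      Rcpp::Named("features") = to_rmat(cc.F1),
      Rcpp::Named("probs") = to_rmat(cc.probs));
  if (gradients) {
    std::vector<mat> G = backward_net(P, cfg, cc, yb, C);
    out["grads"] = params_out(G, cfg);
  }
  return out;
}

// softmax cross-entropy from logits; reduce = "mean" or "sum"
// [[Rcpp::export]]
double cpp_softmax_ce(SEXP logits, Rcpp::IntegerVector y, std::string reduce) {
  mat L = as_matT<double>(logits);
  if ((int)L.n_rows != y.size()) Rcpp::stop("logits/labels length mismatch");
  double s = 0;
  for (uword i = 0; i < L.n_rows; ++i) {
    rowvec z = L.row(i) - L.row(i).max();
    double lse = std::log(accu(exp(z)));
    int yi = y[i];
    if (yi < 0 || yi >= (int)L.n_cols) Rcpp::stop("label outside class range");
    s -= z[yi] - lse;
  }
  return reduce == "mean" ? s / L.n_rows : s;
}

// center loss 0.5 * sum_i ||x_i - c_{y_i}||^2; reduce = "mean" or "sum"
// [[Rcpp::export]]
double cpp_center_loss(SEXP features, Rcpp::IntegerVector y, SEXP centers,
                       std::string reduce) {
  mat F = as_matT<double>(features), C = as_matT<double>(centers);
  if ((int)F.n_rows != y.size()) Rcpp::stop("features/labels length mismatch");
  if (F.n_cols != C.n_cols) Rcpp::stop("feature/center dimension mismatch");
  double s = 0;
  for (uword i = 0; i < F.n_rows; ++i) {
    int yi = y[i];
    if (yi < 0 || yi >= (int)C.n_rows) Rcpp::stop("label outside center set");
    rowvec diff = F.row(i) - C.row(yi);
    s += 0.5 * dot(diff, diff);
  }
  return reduce == "mean" ? s / F.n_rows : s;
}
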