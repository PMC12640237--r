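#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place AdamW step over the flat parameter vector.
// Updates m, v and params in place (the caller owns these buffers
// exclusively for the duration of training), applying decoupled weight
// decay only where decay[i] is TRUE. Avoids the ~10 full-length
// temporaries a vectorized R implementation allocates per step.
// [[Rcpp::export(rng = false)]]
void adamw_step_inplace(NumericVector params, NumericVector m,
                        NumericVector v, NumericVector grad,
                        LogicalVector decay, double lr, double beta1,
                        double beta2, double corr1, double corr2,
                        double weight_decay, double eps,
                        double grad_scale) {
  const R_xlen_t n = params.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = grad[i] * grad_scale;
    const double mi = beta1 * m[i] + (1.0 - beta1) * g;
    const double vi = beta2 * v[i] + (1.0 - beta2) * g * g;
    m[i] = mi;
    v[i] = vi;
    double upd = (mi / corr1) / (std::sqrt(vi / corr2) + eps);
    if (decay[i]) upd += weight_decay * params[i];
    params[i] -= lr * upd;
  }
}

// In-place accumulate: dst[offset..offset+len-1] += src. Used to fold
// per-sequence gradients into the flat batch-gradient buffer without
// allocating.
// [[Rcpp::export(rng = false)]]
void axpy_at(NumericVector dst, double offset, NumericVector src) {
  const R_xlen_t o = (R_xlen_t) offset;
  const R_xlen_t n = src.size();
  for (R_xlen_t i = 0; i < n; ++i) dst[o + i] += src[i];
}
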