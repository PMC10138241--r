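#include <Rcpp.h>
using namespace Rcpp;

// Online Auto-CM training loop. Mirrors autocm_forward()/autocm_update()
// exactly: per record, hidden = x * (1 - v/C); net_i = sum_s h_s (1 - w_is/C);
// out = h * (1 - net/C); then v += alpha (x - h)(1 - v/C),
// w_is += alpha (h_i - out_i)(1 - w_is/C) h_s, both clamped to [0, C].
// Convergence: epoch mean |out| < tol.
// [[Rcpp::export]]
List autocm_train_cpp(NumericMatrix x, double C, double alpha, double w0,
                      double tol, int max_epochs, Nullable<IntegerMatrix> orders) {
  const int R = x.nrow(), N = x.ncol();
  NumericVector v(N, w0);
  NumericMatrix w(N, N);
  std::fill(w.begin(), w.end(), w0);
  std::vector<double> h(N), net(N), out(N);
  std::vector<double> trace;
  trace.reserve(max_epochs);
  bool converged = false;
  int epochs_run = 0;

  IntegerMatrix ord;
  bool shuffled = orders.isNotNull();
  if (shuffled) ord = orders.get();

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double abs_out = 0.0;
    for (int r = 0; r < R; ++r) {
      int rec = shuffled ? (ord(r, epoch) - 1) : r;
      // forward
      for (int s = 0; s < N; ++s) h[s] = x(rec, s) * (1.0 - v[s] / C);
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int s = 0; s < N; ++s) acc += h[s] * (1.0 - w(i, s) / C);
        net[i] = acc;
        out[i] = h[i] * (1.0 - acc / C);
        abs_out += std::fabs(out[i]);
      }
      // update (simultaneous, from this record's forward quantities)
      for (int s = 0; s < N; ++s) {
        double vs = v[s] + alpha * (x(rec, s) - h[s]) * (1.0 - v[s] / C);
        v[s] = std::min(std::max(vs, 0.0), C);
      }
      for (int i = 0; i < N; ++i) {
        double g = alpha * (h[i] - out[i]);
        for (int s = 0; s < N; ++s) {
          double ws = w(i, s) + g * (1.0 - w(i, s) / C) * h[s];
          w(i, s) = std::min(std::max(ws, 0.0), C);
        }
      }
    }
    trace.push_back(abs_out / (double)(R * N));
    epochs_run = epoch + 1;
    if (trace.back() < tol) { converged = true; break; }
  }
  return List::create(_["v"] = v, _["w"] = w,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["epochs_run"] = epochs_run,
                      _["converged"] = converged);
}
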