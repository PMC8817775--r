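#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Panel mixed-logit simulated log-likelihood and analytic gradient.
//
// SLL = sum_i log( (1/R) sum_r prod_t P_it(chosen | beta_ir) ),
// beta_ir = mu + sigma (.) z_ir on the random dimensions.
//
// Xt:          P x N matrix, column n = covariates of long-format row n;
//              rows must be grouped respondent-major, task-minor.
// task_start:  0-based row offsets per task (length Ttot + 1).
// chosen_row:  0-based global row index of the chosen alternative per task.
// resp_start:  0-based task offsets per respondent (length n_resp + 1).
// Z:           draws, dim (R, Kr, n_resp), column-major.
// rand_idx:    0-based coefficient indices with nonzero mixing.
//
// The gradient uses the standard simulated-score identity: with
// w_ir = softmax_r(sum_t log P_it), the score of mu is
// sum_i sum_r w_ir sum_t (x_chosen - sum_j p_j x_j) and the score of
// sigma_k multiplies the same task sums by z_irk.
// [[Rcpp::export]]
List mixl_sll(NumericVector mu, NumericVector sigma_full, NumericMatrix Xt,
              IntegerVector task_start, IntegerVector chosen_row,
              IntegerVector resp_start, NumericVector Z,
              IntegerVector rand_idx, int R, bool want_grad) {
  const int P = Xt.nrow();
  const int n_resp = resp_start.size() - 1;
  const int Kr = rand_idx.size();
  const double *X = REAL(Xt);
  const double *z = REAL(Z);

  std::vector<double> beta(P), lp(R), u(64), prob(64);
  std::vector<double> S;  // per-draw score columns, P x R
  if (want_grad) S.assign((size_t)P * R, 0.0);
  std::vector<double> gmu(P, 0.0), gsig(Kr, 0.0);
  double ll = 0.0;

  for (int i = 0; i < n_resp; ++i) {
    if (want_grad) std::fill(S.begin(), S.end(), 0.0);
    for (int r = 0; r < R; ++r) {
      for (int p = 0; p < P; ++p) beta[p] = mu[p];
      for (int k = 0; k < Kr; ++k) {
        int j = rand_idx[k];
        beta[j] += sigma_full[j] * z[r + (size_t)R * (k + (size_t)Kr * i)];
      }
      double lpr = 0.0;
      double *Sc = want_grad ? &S[(size_t)P * r] : (double *)0;
      for (int t = resp_start[i]; t < resp_start[i + 1]; ++t) {
        int r0 = task_start[t], r1 = task_start[t + 1];
        int J = r1 - r0;
        if ((int)u.size() < J) { u.resize(J); prob.resize(J); }
        double umax = -1e300;
        for (int j = 0; j < J; ++j) {
          const double *x = X + (size_t)P * (r0 + j);
          double uj = 0.0;
          for (int p = 0; p < P; ++p) uj += x[p] * beta[p];
          u[j] = uj;
          if (uj > umax) umax = uj;
        }
        double denom = 0.0;
        for (int j = 0; j < J; ++j) { prob[j] = std::exp(u[j] - umax); denom += prob[j]; }
        int ch = chosen_row[t] - r0;
        lpr += u[ch] - umax - std::log(denom);
        if (want_grad) {
          for (int j = 0; j < J; ++j) prob[j] /= denom;
          const double *xc = X + (size_t)P * chosen_row[t];
          for (int p = 0; p < P; ++p) Sc[p] += xc[p];
          for (int j = 0; j < J; ++j) {
            const double *x = X + (size_t)P * (r0 + j);
            double pj = prob[j];
            for (int p = 0; p < P; ++p) Sc[p] -= pj * x[p];
          }
        }
      }
      lp[r] = lpr;
    }
    double m = lp[0];
    for (int r = 1; r < R; ++r) if (lp[r] > m) m = lp[r];
    double sumw = 0.0;
    for (int r = 0; r < R; ++r) { lp[r] = std::exp(lp[r] - m); sumw += lp[r]; }
    ll += m + std::log(sumw / R);
    if (want_grad) {
      for (int r = 0; r < R; ++r) {
        double w = lp[r] / sumw;
        const double *Sc = &S[(size_t)P * r];
        for (int p = 0; p < P; ++p) gmu[p] += w * Sc[p];
        for (int k = 0; k < Kr; ++k) {
          int j = rand_idx[k];
          gsig[k] += w * z[r + (size_t)R * (k + (size_t)Kr * i)] * Sc[j];
        }
      }
    }
  }
  return List::create(_["loglik"] = ll,
                      _["grad_mu"] = NumericVector(gmu.begin(), gmu.end()),
                      _["grad_sigma"] = NumericVector(gsig.begin(), gsig.end()));
}
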