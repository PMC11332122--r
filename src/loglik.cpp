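#include <Rcpp.h>
using namespace Rcpp;

// Natural-scale parameter layout (18 values):
//  0 bias, 1 prior_in, 2 prior_out, 3 w_star, 4 w_target, 5 w_zap,
//  6 lr_zap_in, 7 lr_zap_out, 8 lr_avoid_in, 9 lr_avoid_out,
// 10 at_zap_in, 11 at_zap_out, 12 at_avoid_in, 13 at_avoid_out,
// 14 lr_zap_neutral, 15 lr_avoid_neutral, 16 at_zap_neutral, 17 at_avoid_neutral
//
// Event encoding: type 0 = observation, 1 = decision; pidx is the 0-based
// index of the acting/target player among the K tracked players; rel is
// 0 ingroup, 1 outgroup, 2 neutral; act is 1 zap / 0 avoid (observations) or
// the participant's choice (decisions); sd/td are the scaled distance
// covariates of decision rows; mate is the K x K same-team indicator.

static inline double pick_rate(const double* nat, int base, int rel) {
  // base 6 = lr_zap, 8 = lr_avoid, 10 = at_zap, 12 = at_avoid
  if (rel == 2) return nat[base == 6 ? 14 : base == 8 ? 15 : base == 10 ? 16 : 17];
  return nat[base + rel];
}

static void forward_ll(const double* nat,
                       const IntegerVector& type, const IntegerVector& pidx,
                       const IntegerVector& rel, const IntegerVector& act,
                       const NumericVector& sd, const NumericVector& td,
                       const IntegerMatrix& mate, int K,
                       double* out_ll /* length n_dec */) {
  std::vector<double> belief(K, 0.0);
  int n = type.size();
  int d = 0;
  for (int i = 0; i < n; ++i) {
    int p = pidx[i];
    if (type[i] == 0) {
      double target = act[i] == 1 ? 1.0 : 0.0;
      double lr = pick_rate(nat, act[i] == 1 ? 6 : 8, rel[i]);
      belief[p] += lr * (target - belief[p]);
      double at = pick_rate(nat, act[i] == 1 ? 10 : 12, rel[i]);
      if (at != 0.0) {
        for (int q = 0; q < K; ++q) {
          if (q != p && mate(p, q) == 1) belief[q] += at * (target - belief[q]);
        }
      }
    } else {
      double prior = rel[i] == 0 ? nat[1] : (rel[i] == 1 ? nat[2] : 0.0);
      double eta = nat[0] + prior + nat[3] * sd[i] + nat[4] * td[i] +
                   nat[5] * belief[p];
      double pr = 1.0 / (1.0 + std::exp(-eta));
      if (pr < 1e-12) pr = 1e-12;
      if (pr > 1.0 - 1e-12) pr = 1.0 - 1e-12;
      out_ll[d++] = act[i] == 1 ? std::log(pr) : std::log1p(-pr);
    }
  }
}

// [[Rcpp::export]]
NumericVector sg_loglik_pointwise(NumericVector nat, IntegerVector type,
                                  IntegerVector pidx, IntegerVector rel,
                                  IntegerVector act, NumericVector sd,
                                  NumericVector td, IntegerMatrix mate, int K) {
  int ndec = 0;
  for (int i = 0; i < type.size(); ++i) if (type[i] == 1) ++ndec;
  NumericVector out(ndec);
  forward_ll(REAL(nat), type, pidx, rel, act, sd, td, mate, K, REAL(out));
  return out;
}

// [[Rcpp::export]]
double sg_loglik_sum(NumericVector nat, IntegerVector type, IntegerVector pidx,
                     IntegerVector rel, IntegerVector act, NumericVector sd,
                     NumericVector td, IntegerMatrix mate, int K) {
  int ndec = 0;
  for (int i = 0; i < type.size(); ++i) if (type[i] == 1) ++ndec;
  std::vector<double> ll(ndec);
  forward_ll(REAL(nat), type, pidx, rel, act, sd, td, mate, K, ll.data());
  double s = 0.0;
  for (double v : ll) s += v;
  return s;
}

// [[Rcpp::export]]
NumericMatrix sg_loglik_draws(NumericMatrix natdraws, IntegerVector type,
                              IntegerVector pidx, IntegerVector rel,
                              IntegerVector act, NumericVector sd,
                              NumericVector td, IntegerMatrix mate, int K) {
  int S = natdraws.nrow();
  int ndec = 0;
  for (int i = 0; i < type.size(); ++i) if (type[i] == 1) ++ndec;
  NumericMatrix out(S, ndec);
  std::vector<double> nat(natdraws.ncol());
  std::vector<double> ll(ndec);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < natdraws.ncol(); ++j) nat[j] = natdraws(s, j);
    forward_ll(nat.data(), type, pidx, rel, act, sd, td, mate, K, ll.data());
    for (int d = 0; d < ndec; ++d) out(s, d) = ll[d];
  }
  return out;
}

// ---- sampler support ------------------------------------------------------

struct EncData {
  Rcpp::IntegerVector type, pidx, rel, act;
  Rcpp::NumericVector sd, td;
  Rcpp::IntegerMatrix mate;
  int K;
};

static std::vector<EncData> unpack_encs(const List& encs) {
  std::vector<EncData> out;
  out.reserve(encs.size());
  for (int j = 0; j < encs.size(); ++j) {
    List e = encs[j];
    out.push_back(EncData{e["type"], e["pidx"], e["rel"], e["act"],
                          e["sd"], e["td"], e["mate"],
                          Rcpp::as<int>(e["K"])});
  }
  return out;
}

// sampling-scale active parameters -> 18-value natural vector
static void active_nat(const double* th, const IntegerVector& active,
                       double* nat /* length 18 */) {
  for (int i = 0; i < 18; ++i) nat[i] = 0.0;
  for (int a = 0; a < active.size(); ++a) {
    int idx = active[a] - 1;           // R indices are 1-based
    double v = th[a];
    nat[idx] = idx >= 6 ? 1.0 / (1.0 + std::exp(-v)) : v;
  }
  nat[14] = (nat[6] + nat[7]) / 2.0;
  nat[15] = (nat[8] + nat[9]) / 2.0;
  nat[16] = (nat[10] + nat[11]) / 2.0;
  nat[17] = (nat[12] + nat[13]) / 2.0;
}

static double enc_ll(const EncData& e, const double* nat) {
  int n = e.type.size();
  std::vector<double> belief(e.K, 0.0);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int p = e.pidx[i];
    if (e.type[i] == 0) {
      double target = e.act[i] == 1 ? 1.0 : 0.0;
      double lr = pick_rate(nat, e.act[i] == 1 ? 6 : 8, e.rel[i]);
      belief[p] += lr * (target - belief[p]);
      double at = pick_rate(nat, e.act[i] == 1 ? 10 : 12, e.rel[i]);
      if (at != 0.0) {
        for (int q = 0; q < e.K; ++q) {
          if (q != p && e.mate(p, q) == 1) belief[q] += at * (target - belief[q]);
        }
      }
    } else {
      double prior = e.rel[i] == 0 ? nat[1] : (e.rel[i] == 1 ? nat[2] : 0.0);
      double eta = nat[0] + prior + nat[3] * e.sd[i] + nat[4] * e.td[i] +
                   nat[5] * belief[p];
      double pr = 1.0 / (1.0 + std::exp(-eta));
      if (pr < 1e-12) pr = 1e-12;
      if (pr > 1.0 - 1e-12) pr = 1.0 - 1e-12;
      total += e.act[i] == 1 ? std::log(pr) : std::log1p(-pr);
    }
  }
  return total;
}

// log-likelihood of every participant at their own parameter row
// [[Rcpp::export]]
NumericVector sg_ll_batch(List encs, NumericMatrix theta, IntegerVector active) {
  std::vector<EncData> e = unpack_encs(encs);
  int J = e.size();
  NumericVector out(J);
  std::vector<double> th(theta.ncol());
  double nat[18];
  for (int j = 0; j < J; ++j) {
    for (int k = 0; k < theta.ncol(); ++k) th[k] = theta(j, k);
    active_nat(th.data(), active, nat);
    out[j] = enc_ll(e[j], nat);
  }
  return out;
}

// one componentwise random-walk Metropolis sweep over all participants and
// parameters, using R's RNG; updates theta, ll_cur and (during warmup) the
// proposal scales in place on copies that are returned
// [[Rcpp::export]]
List sg_sweep(List encs, NumericMatrix theta_in, NumericVector ll_in,
              NumericVector mu, NumericVector sig, NumericMatrix prop_in,
              IntegerVector active, bool adapt, double a_t) {
  std::vector<EncData> e = unpack_encs(encs);
  NumericMatrix theta = clone(theta_in);
  NumericVector ll_cur = clone(ll_in);
  NumericMatrix prop = clone(prop_in);
  int J = e.size(), p = theta.ncol();
  std::vector<double> th(p);
  double nat[18];
  for (int j = 0; j < J; ++j) {
    for (int k = 0; k < p; ++k) th[k] = theta(j, k);
    for (int k = 0; k < p; ++k) {
      double old = th[k];
      double cand = old + R::rnorm(0.0, prop(j, k));
      th[k] = cand;
      active_nat(th.data(), active, nat);
      double llp = enc_ll(e[j], nat);
      double d = (llp - ll_cur[j]) +
        R::dnorm(cand, mu[k], sig[k], 1) - R::dnorm(old, mu[k], sig[k], 1);
      bool acc = std::isfinite(d) && std::log(R::runif(0.0, 1.0)) < d;
      if (acc) {
        theta(j, k) = cand;
        ll_cur[j] = llp;
      } else {
        th[k] = old;
      }
      if (adapt) {
        double s = prop(j, k) * std::exp(a_t * ((acc ? 1.0 : 0.0) - 0.44));
        prop(j, k) = std::min(std::max(s, 1e-3), 5.0);
      }
    }
  }
  return List::create(Named("theta") = theta, Named("ll") = ll_cur,
                      Named("prop") = prop);
}
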