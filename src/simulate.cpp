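// Closed-loop trial simulation engine and policy forward pass.
//
// The hot loops live here: per-step forward-model state estimation under a
// feedback delay of tau steps, piecewise-linear control policy evaluation,
// AR(p) decoding noise with optional signal-dependent variance scaling, and
// the first-order smoothing decoder dynamics. All randomness goes through
// R's RNG (norm_rand), so set.seed() in R makes every trial reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Clamped piecewise-linear interpolation: boundary ordinate outside the range.
static double pl_clamped(const arma::vec &kn, const arma::vec &va, double x) {
  const arma::uword K = kn.n_elem;
  if (x <= kn(0)) return va(0);
  if (x >= kn(K - 1)) return va(K - 1);
  arma::uword j = 1;
  while (kn(j) < x) ++j;           // kn(j-1) <= x < kn(j) after loop
  double w = (x - kn(j - 1)) / (kn(j) - kn(j - 1));
  return (1.0 - w) * va(j - 1) + w * va(j);
}

// Linear interpolation that extrapolates the last segment (speed transform).
static double pl_extrap(const arma::vec &kn, const arma::vec &va, double x) {
  const arma::uword K = kn.n_elem;
  if (x <= kn(0)) return va(0);
  arma::uword j = K - 1;
  if (x < kn(K - 1)) {
    j = 1;
    while (kn(j) < x) ++j;
  }
  double slope = (va(j) - va(j - 1)) / (kn(j) - kn(j - 1));
  return va(j - 1) + slope * (x - kn(j - 1));
}

// transform codes: 0 identity, 1 exponent (s^p), 2 piecewise (extrapolating)
static arma::vec apply_transform_cpp(const arma::vec &u, int code, double p,
                                     const arma::vec &bk_in,
                                     const arma::vec &bk_out) {
  if (code == 0) return u;
  double s = arma::norm(u);
  if (s < 1e-12) return u;
  double s_out = (code == 1) ? std::pow(s, p) : pl_extrap(bk_in, bk_out, s);
  return u * (s_out / s);
}

// A, B for one decoder step: v' = a v + (1-a) b u, p' = p + dt v'
static void build_ab(double alpha, double beta, double dt, int d,
                     arma::mat &A, arma::mat &B) {
  A.zeros(2 * d, 2 * d);
  B.zeros(2 * d, d);
  for (int i = 0; i < d; ++i) {
    A(i, i) = 1.0;
    A(i, d + i) = dt * alpha;
    A(d + i, d + i) = alpha;
    B(i, i) = dt * (1.0 - alpha) * beta;
    B(d + i, i) = (1.0 - alpha) * beta;
  }
}

static arma::vec policy_control(const arma::vec &target, const arma::vec &p_hat,
                                const arma::vec &v_hat, const arma::vec &ftk,
                                const arma::vec &ftv, const arma::vec &fvk,
                                const arma::vec &fvv) {
  arma::vec c(target.n_elem, arma::fill::zeros);
  arma::vec dvec = target - p_hat;
  double dn = arma::norm(dvec);
  if (dn >= 1e-9) c += (dvec / dn) * pl_clamped(ftk, ftv, dn);
  double sn = arma::norm(v_hat);
  if (sn >= 1e-9) c += (v_hat / sn) * pl_clamped(fvk, fvv, sn);
  return c;
}

static arma::vec std_normal(int d) {
  arma::vec z(d);
  for (int i = 0; i < d; ++i) z(i) = norm_rand();
  return z;
}

// One AR noise draw given the lag buffer (most recent first).
static arma::vec ar_draw(const arma::mat &Pi, int n_lags,
                         const std::deque<arma::vec> &lagbuf,
                         const arma::mat &cholL, double scale, int d) {
  arma::vec e = std::sqrt(scale) * (cholL * std_normal(d));
  for (int i = 0; i < n_lags; ++i)
    e += Pi.cols(i * d, (i + 1) * d - 1) * lagbuf[i];
  return e;
}

// Core closed-loop trial. Two selection modes:
//  mode 0: radial target — contact iff ||p - target|| <= r_eff
//  mode 1: grid keyboard — "contact" is presence on a single key; dwelling on
//          any key selects it (outcome 2 correct, 1 wrong key, 0 timeout)
// [[Rcpp::export]]
List cpp_simulate_trial(
    const arma::vec &start_pos, const arma::vec &start_vel,
    const arma::vec &target, double r_eff,
    const arma::vec &ftk, const arma::vec &ftv,
    const arma::vec &fvk, const arma::vec &fvv,
    int n_lags, const arma::mat &Pi, const arma::mat &cholL,
    const arma::vec &sdnk, const arma::vec &sdnv, bool sdn_on,
    int tau, double alpha, double beta, double dt,
    int tcode, double texp, const arma::vec &bk_in, const arma::vec &bk_out,
    int max_steps, int dwell_steps, int burnin,
    int mode, double key_origin, double key_w, int n_side,
    bool clamp_ws, double ws_lo, double ws_hi) {
  const int d = target.n_elem;
  arma::mat A, B;
  build_ab(alpha, beta, dt, d, A, B);

  // powers of A and A^i B for the forward model (i = 0..tau-1)
  std::vector<arma::mat> Apow(tau + 1), AiB(std::max(tau, 1));
  Apow[0] = arma::eye(2 * d, 2 * d);
  for (int i = 1; i <= tau; ++i) Apow[i] = A * Apow[i - 1];
  for (int i = 0; i < tau; ++i) AiB[i] = Apow[i] * B;

  arma::mat pos(d, max_steps + 1), vel(d, max_steps + 1);
  arma::mat cmat(d, max_steps), emat(d, max_steps), umat(d, max_steps);
  pos.col(0) = start_pos;
  vel.col(0) = start_vel;
  arma::mat xhist(2 * d, max_steps + 1);     // true states
  xhist.col(0) = arma::join_cols(start_pos, start_vel);
  arma::mat tc(d, max_steps);                 // transformed efference copies

  // AR lag buffer, warm-started toward stationarity with unit variance scale
  std::deque<arma::vec> lagbuf;
  for (int i = 0; i < n_lags; ++i) lagbuf.push_back(arma::vec(d, arma::fill::zeros));
  for (int b = 0; b < burnin && n_lags > 0; ++b) {
    arma::vec e = ar_draw(Pi, n_lags, lagbuf, cholL, 1.0, d);
    lagbuf.push_front(e);
    lagbuf.pop_back();
  }

  auto key_of = [&](const arma::vec &p) {
    long id = 0;
    for (int i = 0; i < d; ++i) {
      double r = (p(i) - key_origin) / key_w;
      long k = (long)std::floor(r);
      if (k < 0) k = 0;
      if (k >= n_side) k = n_side - 1;
      id = id * n_side + k;
    }
    return id;
  };
  long target_key = (mode == 1) ? key_of(target) : -1;

  int run = 0;                 // unbroken-contact steps since first touch
  bool prev_contact = false;
  long prev_key = -1;
  double t_first_contact = NA_REAL, t_acquire = NA_REAL;
  int outcome = 0;             // 0 timeout, 1 success, (mode 1: 2 correct, 1 wrong)
  long selected_key = -1;
  IntegerVector contact(max_steps + 1);

  // initial sample (time 0)
  if (mode == 0) {
    prev_contact = arma::norm(start_pos - target) <= r_eff;
    contact[0] = prev_contact ? 1 : 0;
    if (prev_contact) t_first_contact = 0.0;
  } else {
    prev_key = key_of(start_pos);
    contact[0] = (prev_key == target_key) ? 1 : 0;
  }

  int n_steps = 0;
  for (int t = 0; t < max_steps; ++t) {
    // forward-model internal estimate from delayed feedback + efference copies
    int m = std::min(t, tau);
    arma::vec xhat = Apow[m] * xhist.col(t - m);
    for (int i = 0; i < m; ++i) xhat += AiB[i] * tc.col(t - 1 - i);
    arma::vec p_hat = xhat.head(d), v_hat = xhat.tail(d);

    arma::vec c = policy_control(target, p_hat, v_hat, ftk, ftv, fvk, fvv);
    double scale = sdn_on ? std::max(pl_clamped(sdnk, sdnv, arma::norm(c)), 0.0) : 1.0;
    arma::vec e(d, arma::fill::zeros);
    bool any_noise = (cholL.n_elem > 0 && arma::norm(cholL, "fro") > 0) || n_lags > 0;
    if (any_noise) {
      e = ar_draw(Pi, n_lags, lagbuf, cholL, scale, d);
      if (n_lags > 0) {
        lagbuf.push_front(e);
        lagbuf.pop_back();
      }
    }
    arma::vec u = c + e;
    arma::vec Tu = apply_transform_cpp(u, tcode, texp, bk_in, bk_out);
    arma::vec v_new = alpha * vel.col(t) + (1.0 - alpha) * beta * Tu;
    arma::vec p_new = pos.col(t) + dt * v_new;
    if (clamp_ws) p_new = arma::clamp(p_new, ws_lo, ws_hi);

    cmat.col(t) = c;
    emat.col(t) = e;
    umat.col(t) = u;
    tc.col(t) = apply_transform_cpp(c, tcode, texp, bk_in, bk_out);
    pos.col(t + 1) = p_new;
    vel.col(t + 1) = v_new;
    xhist.col(t + 1) = arma::join_cols(p_new, v_new);
    n_steps = t + 1;
    double now = (t + 1) * dt;

    if (mode == 0) {
      bool in = arma::norm(p_new - target) <= r_eff;
      contact[t + 1] = in ? 1 : 0;
      if (in) {
        if (prev_contact) ++run; else run = 0;
        if (ISNA(t_first_contact)) t_first_contact = now;
        if (run >= dwell_steps) {
          outcome = 1;
          t_acquire = now;
          break;
        }
      } else run = 0;
      prev_contact = in;
    } else {
      long k = key_of(p_new);
      contact[t + 1] = (k == target_key) ? 1 : 0;
      if (k == prev_key) ++run; else run = 0;
      prev_key = k;
      if (run >= dwell_steps) {
        selected_key = k;
        t_acquire = now;
        outcome = (k == target_key) ? 2 : 1;
        break;
      }
    }
  }

  int n = n_steps;
  return List::create(
      _["pos"] = pos.cols(0, n).t(), _["vel"] = vel.cols(0, n).t(),
      _["u"] = umat.cols(0, n - 1).t(), _["c"] = cmat.cols(0, n - 1).t(),
      _["e"] = emat.cols(0, n - 1).t(),
      _["contact"] = contact[Rcpp::Range(0, n)],
      _["outcome"] = outcome, _["t_first_contact"] = t_first_contact,
      _["t_acquire"] = t_acquire, _["n_steps"] = n,
      _["selected_key"] = (int)selected_key, _["target_key"] = (int)target_key);
}

// Forward pass used by the iterative policy fit: internal estimates from
// delayed *observed* states plus efference copies of the *modeled* control,
// then the modeled control at each step. Trial boundaries reset the history
// (delayed index is clamped to the trial start; no efference leaks across).
// [[Rcpp::export]]
List cpp_policy_forward(const arma::mat &pos, const arma::mat &vel,
                        const arma::mat &targ, const arma::ivec &trial_start,
                        int tau, double alpha, double beta, double dt,
                        const arma::vec &ftk, const arma::vec &ftv,
                        const arma::vec &fvk, const arma::vec &fvv) {
  const int T = pos.n_rows, d = pos.n_cols;
  arma::mat A, B;
  build_ab(alpha, beta, dt, d, A, B);
  std::vector<arma::mat> Apow(tau + 1), AiB(std::max(tau, 1));
  Apow[0] = arma::eye(2 * d, 2 * d);
  for (int i = 1; i <= tau; ++i) Apow[i] = A * Apow[i - 1];
  for (int i = 0; i < tau; ++i) AiB[i] = Apow[i] * B;

  arma::mat chat(T, d), phat(T, d), vhat(T, d);
  arma::mat cbuf(d, T);
  for (int t = 0; t < T; ++t) {
    int t0 = trial_start(t);                  // 0-based first index of this trial
    int m = std::min(t - t0, tau);
    arma::vec xdel = arma::join_cols(pos.row(t - m).t(), vel.row(t - m).t());
    arma::vec xhat = Apow[m] * xdel;
    for (int i = 0; i < m; ++i) xhat += AiB[i] * cbuf.col(t - 1 - i);
    arma::vec p_hat = xhat.head(d), v_hat = xhat.tail(d);
    arma::vec c = policy_control(targ.row(t).t(), p_hat, v_hat, ftk, ftv, fvk, fvv);
    cbuf.col(t) = c;
    chat.row(t) = c.t();
    phat.row(t) = p_hat.t();
    vhat.row(t) = v_hat.t();
  }
  return List::create(_["c_hat"] = chat, _["p_hat"] = phat, _["v_hat"] = vhat);
}
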