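// Actor-critic recurrent network model: two LSTM networks (critic and
// actor) trained with the advantage actor-critic algorithm and
// backpropagation through time, plus frozen-weight test runs. The critic
// reads the choice-selective sequence input and the reward; the actor
// reads an efference copy of the previous action, a temporal-context
// one-hot and the dopamine RPE, and emits a 3-way policy
// (left / right / do nothing).
//
// Gate layout in the stacked weight matrices (rows): forget, input,
// output, candidate. Gates use the logistic nonlinearity, the candidate
// uses tanh.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::ivec;

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LSTM {
  mat W, U; vec b;           // (4H x D), (4H x H), (4H)
  int H() const { return U.n_rows / 4; }
  int D() const { return W.n_cols; }
};

static LSTM as_lstm(const List& p, const char* w, const char* u,
                    const char* b) {
  LSTM out;
  out.W = as<mat>(p[w]); out.U = as<mat>(p[u]); out.b = as<vec>(p[b]);
  return out;
}

// per-episode activation storage for BPTT
struct Cache {
  mat X, H, C, Gf, Gi, Go, Gg;
  void init(int D, int Hn, int T) {
    X.zeros(D, T); H.zeros(Hn, T); C.zeros(Hn, T);
    Gf.zeros(Hn, T); Gi.zeros(Hn, T); Go.zeros(Hn, T); Gg.zeros(Hn, T);
  }
};

static void lstm_fwd_step(const LSTM& P, const vec& x, const vec& h_prev,
                          const vec& c_prev, int t, Cache& S) {
  const int H = P.H();
  vec z = P.W * x + P.U * h_prev + P.b;
  vec f = sigm(z.subvec(0, H - 1));
  vec i = sigm(z.subvec(H, 2 * H - 1));
  vec o = sigm(z.subvec(2 * H, 3 * H - 1));
  vec g = arma::tanh(z.subvec(3 * H, 4 * H - 1));
  vec c = f % c_prev + i % g;
  vec h = o % arma::tanh(c);
  S.X.col(t) = x; S.H.col(t) = h; S.C.col(t) = c;
  S.Gf.col(t) = f; S.Gi.col(t) = i; S.Go.col(t) = o; S.Gg.col(t) = g;
}

struct LSTMGrad { mat dW, dU; vec db; };

// backward pass through time given the direct gradient on h at each step
static LSTMGrad lstm_bptt(const LSTM& P, const Cache& S,
                          const mat& dH_direct) {
  const int H = P.H(), T = S.H.n_cols;
  LSTMGrad G;
  G.dW.zeros(P.W.n_rows, P.W.n_cols);
  G.dU.zeros(P.U.n_rows, P.U.n_cols);
  G.db.zeros(P.b.n_elem);
  vec dh_carry(H, arma::fill::zeros), dc_carry(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec dh = dH_direct.col(t) + dh_carry;
    vec c = S.C.col(t), tc = arma::tanh(c);
    vec f = S.Gf.col(t), i = S.Gi.col(t), o = S.Go.col(t),
        g = S.Gg.col(t);
    vec c_prev = (t > 0) ? vec(S.C.col(t - 1))
                         : vec(H, arma::fill::zeros);
    vec h_prev = (t > 0) ? vec(S.H.col(t - 1))
                         : vec(H, arma::fill::zeros);
    vec dc = dh % o % (1.0 - tc % tc) + dc_carry;
    vec do_ = dh % tc;
    vec df = dc % c_prev, di = dc % g, dg = dc % i;
    dc_carry = dc % f;
    vec dz(4 * H);
    dz.subvec(0, H - 1) = df % f % (1.0 - f);
    dz.subvec(H, 2 * H - 1) = di % i % (1.0 - i);
    dz.subvec(2 * H, 3 * H - 1) = do_ % o % (1.0 - o);
    dz.subvec(3 * H, 4 * H - 1) = dg % (1.0 - g % g);
    G.dW += dz * S.X.col(t).t();
    G.dU += dz * h_prev.t();
    G.db += dz;
    dh_carry = P.U.t() * dz;
  }
  return G;
}

// ------------------------------------------------------------------
// exported building blocks

// [[Rcpp::export]]
List cs_lstm_step(const arma::mat& W, const arma::mat& U,
                  const arma::vec& b, const arma::vec& x,
                  const arma::vec& h, const arma::vec& c) {
  LSTM P; P.W = W; P.U = U; P.b = b;
  Cache S; S.init(W.n_cols, P.H(), 1);
  lstm_fwd_step(P, x, h, c, 0, S);
  return List::create(_["h"] = S.H.col(0), _["c"] = S.C.col(0));
}

// critic loss 0.5 * beta_v * sum_t (R_t - V_t)^2 for a fixed episode of
// inputs and fixed target returns, with analytic gradients (used by the
// finite-difference tests and by training)
// [[Rcpp::export]]
List cs_critic_loss_grad(const List params, const arma::mat& X,
                         const arma::vec& returns, double beta_v) {
  LSTM P = as_lstm(params, "Wc", "Uc", "bc");
  vec wv = as<vec>(params["wv"]);
  double bv = as<double>(params["bv"]);
  const int T = X.n_cols, H = P.H();
  Cache S; S.init(P.D(), H, T);
  vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  vec V(T);
  for (int t = 0; t < T; ++t) {
    lstm_fwd_step(P, X.col(t), h, c, t, S);
    h = S.H.col(t); c = S.C.col(t);
    V(t) = arma::dot(wv, h) + bv;
  }
  vec A = returns - V;
  double loss = 0.5 * beta_v * arma::dot(A, A);
  mat dH(H, T);
  vec dwv(H, arma::fill::zeros);
  double dbv = 0.0;
  for (int t = 0; t < T; ++t) {
    double dV = -beta_v * A(t);
    dH.col(t) = wv * dV;
    dwv += S.H.col(t) * dV;
    dbv += dV;
  }
  LSTMGrad G = lstm_bptt(P, S, dH);
  return List::create(_["loss"] = loss, _["V"] = V, _["dWc"] = G.dW,
                      _["dUc"] = G.dU, _["dbc"] = G.db, _["dwv"] = dwv,
                      _["dbv"] = dbv);
}

// actor loss sum_t (-log pi(a_t) * adv_t - beta_e * H_t) for fixed
// inputs, actions and (detached) advantages, with analytic gradients
// [[Rcpp::export]]
List cs_actor_loss_grad(const List params, const arma::mat& X,
                        const arma::ivec& actions, const arma::vec& adv,
                        double beta_e) {
  LSTM P = as_lstm(params, "Wa", "Ua", "ba");
  mat Wpi = as<mat>(params["Wpi"]);
  vec bpi = as<vec>(params["bpi"]);
  const int T = X.n_cols, H = P.H(), A = Wpi.n_rows;
  Cache S; S.init(P.D(), H, T);
  vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  mat dH(H, T, arma::fill::zeros);
  mat dWpi(A, H, arma::fill::zeros);
  vec dbpi(A, arma::fill::zeros);
  double loss = 0.0;
  for (int t = 0; t < T; ++t) {
    lstm_fwd_step(P, X.col(t), h, c, t, S);
    h = S.H.col(t); c = S.C.col(t);
    vec logits = Wpi * h + bpi;
    vec p = arma::exp(logits - logits.max());
    p /= arma::accu(p);
    vec logp = arma::log(p + 1e-12);
    double ent = -arma::dot(p, logp);
    int a = actions(t);
    loss += -logp(a) * adv(t) - beta_e * ent;
    vec e(A, arma::fill::zeros); e(a) = 1.0;
    vec dlog = adv(t) * (p - e) + beta_e * (p % (logp + ent));
    dWpi += dlog * h.t();
    dbpi += dlog;
    dH.col(t) = Wpi.t() * dlog;
  }
  LSTMGrad G = lstm_bptt(P, S, dH);
  return List::create(_["loss"] = loss, _["dWa"] = G.dW,
                      _["dUa"] = G.dU, _["dba"] = G.db,
                      _["dWpi"] = dWpi, _["dbpi"] = dbpi);
}

// ------------------------------------------------------------------
// environment helpers (R RNG throughout, so runs are seed-reproducible)

static double rtnorm0_c(double mean, double sd) {
  double p0 = R::pnorm(0.0, mean, sd, 1, 0);
  double u = R::runif(p0, 1.0);
  return R::qnorm(u, mean, sd, 1, 0);
}

struct SeqGen {
  vec peaks; ivec side; double jitter_sd, amp_sd, selectivity;
  double sd_eff, amp_factor;
  int n() const { return peaks.n_elem; }
  // n x 40 rate matrix for one trial given the chosen side (0/1)
  mat trial(int chosen, int input_mode) const {
    const int N = n(), Tn = 40;
    mat F(N, Tn);
    if (input_mode == 1) {           // persistent choice-selective input
      for (int i = 0; i < N; ++i)
        F.row(i).fill(side(i) == chosen ? 1.0 : 0.0);
      return F;
    }
    for (int i = 0; i < N; ++i) {
      double mu = peaks(i) + R::rnorm(0.0, jitter_sd);
      double a = (amp_sd > 0 ? rtnorm0_c(1.0, amp_sd) : 1.0) *
                 (side(i) == chosen ? 1.0 : selectivity) * amp_factor;
      for (int k = 0; k < Tn; ++k) {
        double t = -2.0 + 0.1 * k;
        double z = (t - mu) / sd_eff;
        F(i, k) = (std::fabs(z) > 6.0) ? 0.0 : a * std::exp(-0.5 * z * z);
      }
    }
    return F;
  }
};

static SeqGen as_seqgen(const List& cfg) {
  SeqGen g;
  g.peaks = as<vec>(cfg["peaks"]);
  g.side = as<ivec>(cfg["side"]);
  g.jitter_sd = as<double>(cfg["jitter_sd"]);
  g.amp_sd = as<double>(cfg["amp_sd"]);
  g.selectivity = as<double>(cfg["selectivity"]);
  g.sd_eff = as<double>(cfg["sd_eff"]);
  g.amp_factor = as<double>(cfg["amp_factor"]);
  return g;
}

// truncated-Gaussian reward input over the 40 sequence steps; r(t) is
// the kernel amplitude itself at each step (the per-step reward signal),
// so a rewarded trial delivers pulses of order 1 against the unit
// wrong-time penalty
static vec reward_profile(double mu_r, double sigma, double dt) {
  (void) dt;
  vec r(40, arma::fill::zeros);
  for (int k = 0; k < 40; ++k) {
    double t = -2.0 + 0.1 * k;
    if (t >= mu_r - 0.2)
      r(k) = R::dnorm(t, mu_r, sigma, 0);
  }
  return r;
}

struct RMSState { mat c; };
static void rms_update(mat& theta, const mat& g, mat& cache, double lr,
                       double rho, double eps) {
  if (cache.n_rows == 0) cache.zeros(g.n_rows, g.n_cols);
  cache = rho * cache + (1.0 - rho) * (g % g);
  theta -= lr * g / (arma::sqrt(cache) + eps);
}

// block-state machinery shared by training and testing
struct BlockState {
  int mode;            // 0 reward_counted, 1 geometric_only, 2 fixed
  int block = 0;       // 0 = left_high, 1 = right_high
  double p_high, p_low, geom_p;
  int rewards_needed, fixed_len;
  int rewards = 0, ext_left = -1, trials_in_block = 0;
  void start() {
    block = (R::unif_rand() < 0.5) ? 0 : 1;
    rewards = 0; trials_in_block = 0;
    ext_left = (mode == 1) ? (int) R::rgeom(geom_p) + 1 :
               (mode == 2) ? fixed_len : -1;
  }
  int draw_outcome(int choice) {      // choice 0/1; returns 0/1
    double p = (choice == block) ? p_high : p_low;
    return (R::unif_rand() < p) ? 1 : 0;
  }
  bool advance(int outcome, bool completed) {
    ++trials_in_block;
    if (mode == 0) {
      if (!completed) return false;
      if (ext_left < 0) {
        rewards += outcome;
        if (rewards >= rewards_needed)
          ext_left = (int) R::rgeom(geom_p) + 1;
        return false;
      }
      if (--ext_left <= 0) {
        block = 1 - block; rewards = 0; ext_left = -1;
        trials_in_block = 0;
        return true;
      }
      return false;
    }
    if (--ext_left <= 0) {
      block = 1 - block; trials_in_block = 0;
      ext_left = (mode == 1) ? (int) R::rgeom(geom_p) + 1 : fixed_len;
      return true;
    }
    return false;
  }
};

static BlockState as_blockstate(const List& cfg, int mode,
                                int fixed_len) {
  BlockState b;
  b.mode = mode;
  b.p_high = as<double>(cfg["p_high"]);
  b.p_low = as<double>(cfg["p_low"]);
  b.geom_p = as<double>(cfg["geom_p"]);
  b.rewards_needed = as<int>(cfg["rewards_to_reversal"]);
  b.fixed_len = fixed_len;
  return b;
}

// ------------------------------------------------------------------
// full A2C training loop

// [[Rcpp::export]]
List cs_a2c_train(List params, List cfg) {
  LSTM Pc = as_lstm(params, "Wc", "Uc", "bc");
  LSTM Pa = as_lstm(params, "Wa", "Ua", "ba");
  vec wv = as<vec>(params["wv"]);
  double bv = as<double>(params["bv"]);
  mat Wpi = as<mat>(params["Wpi"]);
  vec bpi = as<vec>(params["bpi"]);

  const int n_episodes = as<int>(cfg["n_episodes"]);
  const int n_trials = as<int>(cfg["episode_trials"]);
  const int SPT = 42, T = n_trials * SPT;
  const double gamma = as<double>(cfg["gamma"]);
  const double beta_v = as<double>(cfg["beta_v"]);
  const double beta_e = as<double>(cfg["beta_e"]);
  const double lr = as<double>(cfg["lr"]);
  const double rho = as<double>(cfg["rho"]);
  const double eps = as<double>(cfg["eps"]);
  const double penalty = as<double>(cfg["penalty"]);
  const double mu_lo = as<double>(cfg["mu_lo"]);
  const double mu_hi = as<double>(cfg["mu_hi"]);
  const double r_sigma = as<double>(cfg["r_sigma"]);
  const double dt = as<double>(cfg["dt"]);
  const int input_mode = as<int>(cfg["input_mode"]);
  const bool as_printed = as<bool>(cfg["as_printed"]);
  SeqGen gen = as_seqgen(cfg);
  const int N = gen.n(), Hc = Pc.H(), Ha = Pa.H();
  const int Dc = N + 1, Da = 3 + SPT + 1;
  if (Pc.D() != Dc || Pa.D() != Da)
    stop("parameter / config dimension mismatch");

  BlockState blk = as_blockstate(cfg, 1, 0);   // geometric_only training

  mat mWc, mUc, mWa, mUa, mWpi;                // RMSprop caches
  mat mbc, mba, mbpi, mwv, mbv;

  Cache Sc, Sa;
  NumericVector curve(n_episodes), rew_sum(n_episodes);

  for (int ep = 0; ep < n_episodes; ++ep) {
    blk.start();
    Sc.init(Dc, Hc, T); Sa.init(Da, Ha, T);
    vec hc(Hc, arma::fill::zeros), cc(Hc, arma::fill::zeros);
    vec ha(Ha, arma::fill::zeros), ca(Ha, arma::fill::zeros);
    vec V(T), r_env(T, arma::fill::zeros), gam(T);
    ivec act(T);
    mat Pi(3, T);
    int prev_a = 2;
    double V_prev = 0.0;
    int n_rewarded = 0;
    mat Ftrial; vec rvec; int chosen = -1; int outcome = 0;

    for (int j = 0; j < n_trials; ++j) {
      for (int s = 1; s <= SPT; ++s) {
        int t = j * SPT + (s - 1);
        double r_in = (t > 0) ? r_env(t - 1) : 0.0;
        vec xc(Dc, arma::fill::zeros);
        if (s >= 2 && s <= 41 && chosen >= 0)
          xc.subvec(0, N - 1) = Ftrial.col(s - 2);
        xc(Dc - 1) = r_in;
        lstm_fwd_step(Pc, xc, hc, cc, t, Sc);
        hc = Sc.H.col(t); cc = Sc.C.col(t);
        V(t) = arma::dot(wv, hc) + bv;
        double delta = r_in + gamma * V(t) - V_prev;
        V_prev = V(t);

        vec xa(Da, arma::fill::zeros);
        xa(prev_a) = 1.0;
        xa(3 + (s - 1)) = 1.0;
        xa(Da - 1) = delta;
        lstm_fwd_step(Pa, xa, ha, ca, t, Sa);
        ha = Sa.H.col(t); ca = Sa.C.col(t);
        vec logits = Wpi * ha + bpi;
        vec p = arma::exp(logits - logits.max());
        p /= arma::accu(p);
        Pi.col(t) = p;
        double u = R::unif_rand();
        int a = (u < p(0)) ? 0 : (u < p(0) + p(1) ? 1 : 2);
        act(t) = a;

        double r_now = 0.0;
        if (s == 1) {
          if (a == 2) {
            r_now = penalty; chosen = -1; outcome = 0;
          } else {
            chosen = a;
            outcome = blk.draw_outcome(a);
            if (outcome) ++n_rewarded;
            Ftrial = gen.trial(chosen, input_mode);
            rvec = outcome
              ? reward_profile(R::runif(mu_lo, mu_hi), r_sigma, dt)
              : vec(40, arma::fill::zeros);
          }
        } else {
          if (a != 2) r_now = penalty;
          if (chosen >= 0 && s >= 2 && s <= 41) r_now += rvec(s - 2);
        }
        r_env(t) = r_now;
        gam(t) = (s == SPT) ? 0.0 : gamma;
        prev_a = a;
      }
      blk.advance(outcome, chosen >= 0);
      chosen = -1;
    }

    // returns and advantages
    vec Ret(T);
    double carry = 0.0;
    for (int t = T - 1; t >= 0; --t) {
      carry = as_printed ? gam(t) * (r_env(t) + carry)
                         : r_env(t) + gam(t) * carry;
      Ret(t) = carry;
    }
    vec A = Ret - V;

    // readout gradients and direct h-gradients
    mat dHc(Hc, T), dHa(Ha, T);
    vec dwv(Hc, arma::fill::zeros); double dbv = 0.0;
    mat dWpi(3, Ha, arma::fill::zeros);
    vec dbpi(3, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      double dV = -beta_v * A(t);
      dHc.col(t) = wv * dV;
      dwv += Sc.H.col(t) * dV;
      dbv += dV;
      vec p = Pi.col(t);
      vec logp = arma::log(p + 1e-12);
      double ent = -arma::dot(p, logp);
      vec e(3, arma::fill::zeros); e(act(t)) = 1.0;
      vec dlog = A(t) * (p - e) + beta_e * (p % (logp + ent));
      dWpi += dlog * Sa.H.col(t).t();
      dbpi += dlog;
      dHa.col(t) = Wpi.t() * dlog;
    }
    LSTMGrad Gc = lstm_bptt(Pc, Sc, dHc);
    LSTMGrad Ga = lstm_bptt(Pa, Sa, dHa);

    rms_update(Pc.W, Gc.dW, mWc, lr, rho, eps);
    rms_update(Pc.U, Gc.dU, mUc, lr, rho, eps);
    { mat g = Gc.db, th = Pc.b; rms_update(th, g, mbc, lr, rho, eps);
      Pc.b = th; }
    { mat g = dwv, th = wv; rms_update(th, g, mwv, lr, rho, eps);
      wv = th; }
    { mat g(1, 1), th(1, 1); g(0, 0) = dbv; th(0, 0) = bv;
      rms_update(th, g, mbv, lr, rho, eps); bv = th(0, 0); }
    rms_update(Pa.W, Ga.dW, mWa, lr, rho, eps);
    rms_update(Pa.U, Ga.dU, mUa, lr, rho, eps);
    { mat g = Ga.db, th = Pa.b; rms_update(th, g, mba, lr, rho, eps);
      Pa.b = th; }
    rms_update(Wpi, dWpi, mWpi, lr, rho, eps);
    { mat g = dbpi, th = bpi; rms_update(th, g, mbpi, lr, rho, eps);
      bpi = th; }

    curve[ep] = (double) n_rewarded / n_trials;
    rew_sum[ep] = arma::accu(r_env);
    if (!std::isfinite(rew_sum[ep]) || !V.is_finite())
      stop("training diverged (non-finite loss) at episode %d", ep + 1);
  }

  List out_params = List::create(
    _["Wc"] = Pc.W, _["Uc"] = Pc.U, _["bc"] = Pc.b, _["wv"] = wv,
    _["bv"] = bv, _["Wa"] = Pa.W, _["Ua"] = Pa.U, _["ba"] = Pa.b,
    _["Wpi"] = Wpi, _["bpi"] = bpi);
  return List::create(_["params"] = out_params, _["curve"] = curve,
                      _["reward_sum"] = rew_sum);
}

// ------------------------------------------------------------------
// frozen-weight episode

// [[Rcpp::export]]
List cs_a2c_run(List params, List cfg, int n_trials, int block_mode,
                int fixed_len, double stim_frac, double stim_value,
                double stim_neuron_frac, bool record_h) {
  LSTM Pc = as_lstm(params, "Wc", "Uc", "bc");
  LSTM Pa = as_lstm(params, "Wa", "Ua", "ba");
  vec wv = as<vec>(params["wv"]);
  double bv = as<double>(params["bv"]);
  mat Wpi = as<mat>(params["Wpi"]);
  vec bpi = as<vec>(params["bpi"]);
  const int SPT = 42;
  const double gamma = as<double>(cfg["gamma"]);
  const double penalty = as<double>(cfg["penalty"]);
  const double mu_lo = as<double>(cfg["mu_lo"]);
  const double mu_hi = as<double>(cfg["mu_hi"]);
  const double r_sigma = as<double>(cfg["r_sigma"]);
  const double dt = as<double>(cfg["dt"]);
  const int input_mode = as<int>(cfg["input_mode"]);
  SeqGen gen = as_seqgen(cfg);
  const int N = gen.n(), Hc = Pc.H(), Ha = Pa.H();
  const int Dc = N + 1, Da = 3 + SPT + 1;

  BlockState blk = as_blockstate(cfg, block_mode, fixed_len);
  blk.start();

  vec hc(Hc, arma::fill::zeros), cc(Hc, arma::fill::zeros);
  vec ha(Ha, arma::fill::zeros), ca(Ha, arma::fill::zeros);
  Cache Sc, Sa; Sc.init(Dc, Hc, 1); Sa.init(Da, Ha, 1);

  IntegerVector choice(n_trials), outcome_v(n_trials), block_v(n_trials);
  LogicalVector stim_v(n_trials);
  NumericVector rpe02(n_trials);
  mat Hdec;
  if (record_h) Hdec.zeros(Ha, n_trials);

  int prev_a = 2;
  double V_prev = 0.0, r_prev = 0.0;

  for (int j = 0; j < n_trials; ++j) {
    bool stim_trial = stim_frac > 0 && R::unif_rand() < stim_frac;
    arma::uvec stim_sel;
    if (stim_trial) {
      int n_sel = (int) std::lround(stim_neuron_frac * N);
      // Fisher-Yates draw through R's RNG for seed reproducibility
      std::vector<int> idx(N);
      for (int q = 0; q < N; ++q) idx[q] = q;
      for (int q = 0; q < n_sel; ++q) {
        int pick = q + (int) std::floor(R::unif_rand() * (N - q));
        if (pick >= N) pick = N - 1;
        std::swap(idx[q], idx[pick]);
      }
      stim_sel.set_size(n_sel);
      for (int q = 0; q < n_sel; ++q) stim_sel(q) = idx[q];
    }
    mat Ftrial; vec rvec; int chosen = -1; int outcome = 0;
    double rpe_acc = 0.0; int rpe_n = 0;
    for (int s = 1; s <= SPT; ++s) {
      vec xc(Dc, arma::fill::zeros);
      if (s >= 2 && s <= 41) {
        if (chosen >= 0) xc.subvec(0, N - 1) = Ftrial.col(s - 2);
        if (stim_trial)
          for (arma::uword q = 0; q < stim_sel.n_elem; ++q)
            xc(stim_sel(q)) = stim_value;
      }
      xc(Dc - 1) = r_prev;
      lstm_fwd_step(Pc, xc, hc, cc, 0, Sc);
      hc = Sc.H.col(0); cc = Sc.C.col(0);
      double V = arma::dot(wv, hc) + bv;
      double delta = r_prev + gamma * V - V_prev;
      V_prev = V;
      if (s >= 22 && s <= 41) { rpe_acc += delta; ++rpe_n; }

      vec xa(Da, arma::fill::zeros);
      xa(prev_a) = 1.0;
      xa(3 + (s - 1)) = 1.0;
      xa(Da - 1) = delta;
      lstm_fwd_step(Pa, xa, ha, ca, 0, Sa);
      ha = Sa.H.col(0); ca = Sa.C.col(0);
      if (record_h && s == 1) Hdec.col(j) = ha;
      vec logits = Wpi * ha + bpi;
      vec p = arma::exp(logits - logits.max());
      p /= arma::accu(p);
      double u = R::unif_rand();
      int a = (u < p(0)) ? 0 : (u < p(0) + p(1) ? 1 : 2);

      double r_now = 0.0;
      if (s == 1) {
        if (a == 2) { chosen = -1; outcome = 0; r_now = penalty; }
        else {
          chosen = a;
          outcome = blk.draw_outcome(a);
          Ftrial = gen.trial(chosen, input_mode);
          rvec = outcome
            ? reward_profile(R::runif(mu_lo, mu_hi), r_sigma, dt)
            : vec(40, arma::fill::zeros);
        }
      } else {
        if (a != 2) r_now = penalty;
        if (chosen >= 0 && s >= 2 && s <= 41) r_now += rvec(s - 2);
      }
      r_prev = r_now;
      prev_a = a;
    }
    choice[j] = (chosen >= 0) ? chosen : 2;
    outcome_v[j] = outcome;
    block_v[j] = blk.block;
    stim_v[j] = stim_trial;
    rpe02[j] = rpe_acc / std::max(rpe_n, 1);
    blk.advance(outcome, chosen >= 0);
  }

  List out = List::create(_["choice"] = choice, _["outcome"] = outcome_v,
                          _["block"] = block_v, _["stimulated"] = stim_v,
                          _["rpe02"] = rpe02);
  if (record_h) out["h_decision"] = Hdec;
  return out;
}
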