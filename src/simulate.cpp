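// Hot loops of the channel-noise simulators. All random draws go through
// R's RNG (R::rbinom / norm_rand), so set.seed() on the R side makes every
// simulation bit-for-bit reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parametric rate laws (see R/rates.R): 0 constant, 1 linexp,
// 2 exponential, 3 sigmoid.
struct RateLaw {
  int type;
  double a, vh, k;
};

static inline double eval_rate_law(const RateLaw &r, double v) {
  switch (r.type) {
  case 0:
    return r.a;
  case 1: {
    double u = (v - r.vh) / r.k;
    if (std::fabs(u) < 1e-6)
      return r.a * r.k * (1.0 + u / 2.0 + u * u / 12.0);
    return r.a * r.k * u / (1.0 - std::exp(-u));
  }
  case 2:
    return r.a * std::exp((v - r.vh) / r.k);
  case 3:
    return r.a / (1.0 + std::exp(-(v - r.vh) / r.k));
  }
  return NA_REAL;
}

static inline int draw_binom(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return (int)R::rbinom((double)n, p);
}

// One ionic current: subunit-composed scheme plus per-backend state.
struct Current {
  int nsub;
  std::vector<int> counts;           // subunit multiplicities q_j
  std::vector<RateLaw> al, be;       // per-subunit rate laws
  double N;                          // number of channels
  double gmax;                       // mS/cm^2 (= gamma * N / area)
  double erev;                       // mV
  // deterministic gates (det / effective / reduced / fox backends)
  std::vector<double> x;
  // effective backend: exponent grid (terms x nsub), binomial coefficient
  // products, OU values
  std::vector<std::vector<int>> expo;
  std::vector<double> chooseprod;
  std::vector<double> zeta;
  // microscopic backend: occupancy counts over the product state space
  int M, open_idx;
  std::vector<int> occ;
  std::vector<std::vector<int>> kvec; // per state: activation counts
  std::vector<int> stride;
  // scratch
  std::vector<double> a_v, b_v, xinf_v, taux_v;
};

static void build_expo_grid(Current &cur) {
  // exponent vectors k (0 <= k_j <= q_j, k != 0) in odometer order with
  // subunit 1 varying fastest — matches R's expand.grid ordering
  std::vector<int> k(cur.nsub, 0);
  for (;;) {
    int j = 0;
    while (j < cur.nsub && k[j] == cur.counts[j]) {
      k[j] = 0;
      ++j;
    }
    if (j == cur.nsub) break;
    ++k[j];
    double cp = 1.0;
    for (int s = 0; s < cur.nsub; ++s)
      cp *= R::choose((double)cur.counts[s], (double)k[s]);
    cur.expo.push_back(k);
    cur.chooseprod.push_back(cp);
  }
}

static void build_state_space(Current &cur) {
  cur.stride.assign(cur.nsub, 1);
  cur.M = 1;
  for (int j = 0; j < cur.nsub; ++j) {
    cur.stride[j] = cur.M;
    cur.M *= cur.counts[j] + 1;
  }
  cur.kvec.assign(cur.M, std::vector<int>(cur.nsub));
  for (int s = 0; s < cur.M; ++s) {
    int rem = s;
    for (int j = 0; j < cur.nsub; ++j) {
      cur.kvec[s][j] = rem % (cur.counts[j] + 1);
      rem /= cur.counts[j] + 1;
    }
  }
  cur.open_idx = cur.M - 1;
}

static Current parse_current(List li, int backend) {
  Current cur;
  IntegerVector counts = li["counts"];
  NumericMatrix rates = li["rates"]; // nsub x 8
  cur.nsub = counts.size();
  cur.counts.assign(counts.begin(), counts.end());
  for (int j = 0; j < cur.nsub; ++j) {
    RateLaw a = {(int)rates(j, 0), rates(j, 1), rates(j, 2), rates(j, 3)};
    RateLaw b = {(int)rates(j, 4), rates(j, 5), rates(j, 6), rates(j, 7)};
    cur.al.push_back(a);
    cur.be.push_back(b);
  }
  cur.N = as<double>(li["n_channels"]);
  cur.gmax = as<double>(li["g_max"]);
  cur.erev = as<double>(li["e_rev"]);
  NumericVector g0 = li["gates0"];
  cur.x.assign(g0.begin(), g0.end());
  cur.a_v.assign(cur.nsub, 0.0);
  cur.b_v.assign(cur.nsub, 0.0);
  cur.xinf_v.assign(cur.nsub, 0.0);
  cur.taux_v.assign(cur.nsub, 0.0);
  if (backend == 2 || backend == 3) {
    build_expo_grid(cur);
    NumericVector z0 = li["zeta0"];
    cur.zeta.assign(z0.begin(), z0.end());
    int want = (backend == 2) ? (int)cur.expo.size() : 1;
    if ((int)cur.zeta.size() != want)
      stop("zeta0 has wrong length for this backend");
  }
  if (backend == 1) {
    build_state_space(cur);
    IntegerVector c0 = li["counts0"];
    if (c0.size() != cur.M) stop("counts0 has wrong length");
    cur.occ.assign(c0.begin(), c0.end());
  }
  return cur;
}

static inline void refresh_rates(Current &cur, double v) {
  for (int j = 0; j < cur.nsub; ++j) {
    double a = eval_rate_law(cur.al[j], v);
    double b = eval_rate_law(cur.be[j], v);
    cur.a_v[j] = a;
    cur.b_v[j] = b;
    double s = a + b;
    if (s > 0) {
      cur.xinf_v[j] = a / s;
      cur.taux_v[j] = 1.0 / s;
    } else {
      cur.xinf_v[j] = cur.x[j];
      cur.taux_v[j] = R_PosInf;
    }
  }
}

static inline void gates_rush_larsen(Current &cur, double dt) {
  for (int j = 0; j < cur.nsub; ++j) {
    if (R_finite(cur.taux_v[j]))
      cur.x[j] = cur.xinf_v[j] +
                 (cur.x[j] - cur.xinf_v[j]) * std::exp(-dt / cur.taux_v[j]);
  }
}

static inline double gate_product(const Current &cur) {
  double z = 1.0;
  for (int j = 0; j < cur.nsub; ++j)
    z *= std::pow(cur.x[j], (double)cur.counts[j]);
  return z;
}

// multinomial exit from every occupied state (sequential conditional
// binomials); exact channel-count conservation
static void micro_step(Current &cur, double dt, int step_idx) {
  static thread_local std::vector<int> delta;
  delta.assign(cur.M, 0);
  for (int s = 0; s < cur.M; ++s) {
    int n_s = cur.occ[s];
    if (n_s == 0) continue;
    const std::vector<int> &k = cur.kvec[s];
    double ptot = 0.0;
    int rem = n_s;
    double acc = 0.0;
    for (int j = 0; j < cur.nsub && rem > 0; ++j) {
      double up = (cur.counts[j] - k[j]) * cur.a_v[j] * dt;
      double dn = k[j] * cur.b_v[j] * dt;
      ptot += up + dn;
      if (ptot >= 1.0)
        stop("time step too large for microscopic simulation at step %d "
             "(total exit probability >= 1 in state %d)",
             step_idx, s + 1);
      if (up > 0.0) {
        int b = draw_binom(rem, up / (1.0 - acc));
        delta[s + cur.stride[j]] += b;
        delta[s] -= b;
        rem -= b;
        acc += up;
      }
      if (dn > 0.0 && rem > 0) {
        int b = draw_binom(rem, dn / (1.0 - acc));
        delta[s - cur.stride[j]] += b;
        delta[s] -= b;
        rem -= b;
        acc += dn;
      }
    }
  }
  for (int s = 0; s < cur.M; ++s) cur.occ[s] += delta[s];
}

// advance one current by dt at voltage v; returns the open fraction z
static double advance_current(Current &cur, double v, double dt, int backend,
                              bool noise_off, bool clip, int step_idx) {
  refresh_rates(cur, v);
  if (backend == 1 && !noise_off) {
    micro_step(cur, dt, step_idx);
    return (double)cur.occ[cur.open_idx] / cur.N;
  }
  gates_rush_larsen(cur, dt);
  double z = gate_product(cur);
  if (backend == 0 || noise_off) return z;
  if (backend == 4) { // fox: per-gate white noise, gates clipped
    for (int j = 0; j < cur.nsub; ++j) {
      double var = (cur.a_v[j] * (1.0 - cur.x[j]) + cur.b_v[j] * cur.x[j]) /
                   cur.N;
      cur.x[j] += std::sqrt(dt * var) * norm_rand();
      if (cur.x[j] < 0.0) cur.x[j] = 0.0;
      if (cur.x[j] > 1.0) cur.x[j] = 1.0;
    }
    return gate_product(cur);
  }
  // effective / reduced: refresh OU coefficients at the instantaneous
  // gating point, then exact OU update
  int nterm = (int)cur.expo.size();
  double ssum = 0.0, sotau = 0.0, zeta_sum = 0.0;
  for (int t = 0; t < nterm; ++t) {
    double s2 = cur.chooseprod[t];
    double itau = 0.0;
    for (int j = 0; j < cur.nsub; ++j) {
      int kj = cur.expo[t][j];
      double xj = cur.xinf_v[j];
      s2 *= std::pow(xj, 2.0 * (cur.counts[j] - kj)) *
            std::pow(xj * (1.0 - xj), (double)kj);
      itau += kj / cur.taux_v[j];
    }
    s2 /= cur.N;
    double tau = 1.0 / itau;
    if (backend == 2) {
      double e = std::exp(-dt / tau);
      cur.zeta[t] = cur.zeta[t] * e +
                    std::sqrt(s2 * (1.0 - e * e)) * norm_rand();
      zeta_sum += cur.zeta[t];
    } else {
      ssum += s2;
      sotau += s2 / tau;
    }
  }
  if (backend == 3) { // reduced: single OU term, variance-preserving tau
    double tau = (sotau > 0.0) ? ssum / sotau : 1.0;
    double e = std::exp(-dt / tau);
    cur.zeta[0] = cur.zeta[0] * e +
                  std::sqrt(ssum * (1.0 - e * e)) * norm_rand();
    zeta_sum = cur.zeta[0];
  }
  z += zeta_sum;
  if (clip) {
    if (z < 0.0) z = 0.0;
    if (z > 1.0) z = 1.0;
  }
  return z;
}

// [[Rcpp::export]]
List cpp_integrate_membrane(double cm, double gl, double el, List currents,
                            NumericVector stim, double dt, int backend,
                            double v0, bool noise_off, bool clip,
                            int record_every) {
  int nsteps = stim.size();
  int ncur = currents.size();
  std::vector<Current> curs;
  curs.reserve(ncur);
  for (int c = 0; c < ncur; ++c)
    curs.push_back(parse_current(currents[c], noise_off ? 0 : backend));
  int nrec = nsteps / record_every + 1;
  NumericVector vout(nrec);
  NumericMatrix zout(nrec, ncur);
  double v = v0;
  std::vector<double> z(ncur);
  for (int c = 0; c < ncur; ++c) {
    if (backend == 1 && !noise_off)
      z[c] = (double)curs[c].occ[curs[c].open_idx] / curs[c].N;
    else
      z[c] = gate_product(curs[c]);
    if (backend == 2 || backend == 3) {
      if (!noise_off)
        for (double zz : curs[c].zeta) z[c] += zz;
      if (clip) z[c] = std::min(1.0, std::max(0.0, z[c]));
    }
  }
  int irec = 0;
  for (int i = 0; i <= nsteps; ++i) {
    if (i % record_every == 0 && irec < nrec) {
      vout[irec] = v;
      for (int c = 0; c < ncur; ++c) zout(irec, c) = z[c];
      ++irec;
    }
    if (i == nsteps) break;
    double iion = gl * (v - el);
    for (int c = 0; c < ncur; ++c)
      iion += curs[c].gmax * z[c] * (v - curs[c].erev);
    double vnew = v + dt / cm * (stim[i] - iion);
    for (int c = 0; c < ncur; ++c)
      z[c] = advance_current(curs[c], v, dt, backend, noise_off, clip, i);
    v = vnew;
    if (!R_finite(v) || std::fabs(v) > 200.0)
      stop("membrane integration diverged at step %d (V = %g mV)", i, v);
  }
  return List::create(_["v"] = vout, _["z"] = zout);
}

// Voltage clamp of a microscopic population with a fixed rate matrix
// (works for any scheme, not just composed ones). A is in the column
// convention: A(i, j) = rate j -> i.
// [[Rcpp::export]]
NumericVector cpp_vclamp_micro(NumericMatrix A, int open_idx,
                               IntegerVector counts0, int nsteps, double dt,
                               int record_every) {
  int M = A.nrow();
  std::vector<std::vector<std::pair<int, double>>> dest(M);
  for (int s = 0; s < M; ++s)
    for (int d = 0; d < M; ++d)
      if (d != s && A(d, s) > 0.0) dest[s].push_back({d, A(d, s) * dt});
  std::vector<int> occ(counts0.begin(), counts0.end());
  double N = 0;
  for (int s = 0; s < M; ++s) N += occ[s];
  int nrec = nsteps / record_every + 1;
  NumericVector zout(nrec);
  std::vector<int> delta(M);
  int irec = 0;
  for (int i = 0; i <= nsteps; ++i) {
    if (i % record_every == 0 && irec < nrec)
      zout[irec++] = occ[open_idx] / N;
    if (i == nsteps) break;
    std::fill(delta.begin(), delta.end(), 0);
    for (int s = 0; s < M; ++s) {
      int rem = occ[s];
      if (rem == 0) continue;
      double acc = 0.0;
      for (auto &pr : dest[s]) {
        int b = draw_binom(rem, pr.second / (1.0 - acc));
        delta[pr.first] += b;
        delta[s] -= b;
        rem -= b;
        acc += pr.second;
        if (rem == 0) break;
      }
    }
    for (int s = 0; s < M; ++s) occ[s] += delta[s];
  }
  return zout;
}

// Voltage clamp of a single Fox-Lu gate: Rush-Larsen drift plus white-noise
// increment of variance (alpha (1 - x) + beta x) / N per unit time, clipped
// to [0, 1].
// [[Rcpp::export]]
NumericVector cpp_fox_gate_clamp(double alpha, double beta, double N,
                                 double x0, int nsteps, double dt,
                                 int record_every) {
  double xinf = alpha / (alpha + beta);
  double e = std::exp(-dt * (alpha + beta));
  int nrec = nsteps / record_every + 1;
  NumericVector out(nrec);
  double x = x0;
  int irec = 0;
  for (int i = 0; i <= nsteps; ++i) {
    if (i % record_every == 0 && irec < nrec) out[irec++] = x;
    if (i == nsteps) break;
    x = xinf + (x - xinf) * e;
    double var = (alpha * (1.0 - x) + beta * x) / N;
    x += std::sqrt(dt * var) * norm_rand();
    if (x < 0.0) x = 0.0;
    if (x > 1.0) x = 1.0;
  }
  return out;
}
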