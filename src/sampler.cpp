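// Collapsed Gibbs sampler (fixed number of assemblies) and Dirichlet-process
// Metropolis-Hastings sampler (variable number of assemblies) for the
// hierarchical Bernoulli assembly model. All conditionals are evaluated from
// incrementally maintained sufficient statistics; uses R's RNG so set.seed()
// in R makes runs reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Hyper {
  double ap, bp;      // Beta prior on assembly activation p
  double a0, b0;      // Beta prior on lambda(0) (asynchrony)
  double a1, b1;      // Beta prior on lambda(1) (synchrony)
  double an;          // symmetric Dirichlet weight (fixed-A mode)
  double dpa;         // DP concentration (variable-A mode)
};

static inline double lb(double a, double b) { return R::lbeta(a, b); }

class AssemblySampler {
public:
  int N, M, A;
  Hyper h;
  bool dp;
  std::vector<std::vector<int>> frames;   // active frames per neuron
  std::vector<int> rsum;                  // active-frame count per neuron
  std::vector<int> t;                     // neuron -> assembly index (0-based)
  // per-assembly state
  std::vector<int> G;                     // occupancy
  std::vector<std::vector<int>> omega;    // on/off per frame
  std::vector<std::vector<int>> C;        // member-active count per frame
  std::vector<int> m1;                    // number of on frames
  std::vector<long long> S1, Stot;        // sum of C over on frames / all frames
  std::vector<int> ids;                   // stable assembly identifiers
  int next_id;

  AssemblySampler(const IntegerMatrix& s, const IntegerVector& t_init,
                  int A_init, const Hyper& hy, bool dp_mode)
      : N(s.nrow()), M(s.ncol()), h(hy), dp(dp_mode) {
    frames.resize(N); rsum.resize(N);
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < M; ++k) if (s(i, k) == 1) frames[i].push_back(k);
      rsum[i] = (int)frames[i].size();
    }
    // compress labels
    std::vector<int> map(N + 1, -1);
    A = 0;
    t.resize(N);
    for (int i = 0; i < N; ++i) {
      int lab = t_init[i];
      if (map[lab] < 0) map[lab] = A++;
      t[i] = map[lab];
    }
    if (!dp && A_init > A) A = A_init;  // allow initially empty assemblies
    G.assign(A, 0); m1.assign(A, 0);
    S1.assign(A, 0); Stot.assign(A, 0);
    ids.resize(A); next_id = A + 1;   // 1-based stable labels
    for (int mu = 0; mu < A; ++mu) ids[mu] = mu + 1;
    omega.assign(A, std::vector<int>(M, 0));
    C.assign(A, std::vector<int>(M, 0));
    for (int i = 0; i < N; ++i) {
      G[t[i]]++;
      for (int k : frames[i]) C[t[i]][k]++;
    }
    // initialize omega from its prior (p drawn per assembly)
    for (int mu = 0; mu < A; ++mu) {
      double pstar = R::rbeta(h.ap, h.bp);
      for (int k = 0; k < M; ++k) {
        int z = (unif_rand() < pstar) ? 1 : 0;
        omega[mu][k] = z;
        if (z) { m1[mu]++; S1[mu] += C[mu][k]; }
      }
      for (int k = 0; k < M; ++k) Stot[mu] += C[mu][k];
    }
  }

  // a1(i, mu) = #frames with omega[mu]=1 and s[i]=1
  inline long long a1_of(int i, int mu) const {
    long long a = 0;
    const std::vector<int>& om = omega[mu];
    for (int k : frames[i]) a += om[k];
    return a;
  }

  // raw co-occurrence counts of assembly mu
  inline void tab(int mu, long long& T11, long long& T10,
                  long long& T01, long long& T00) const {
    long long g = G[mu];
    T11 = S1[mu];
    T10 = g * (long long)m1[mu] - T11;
    T01 = Stot[mu] - T11;
    T00 = g * (long long)(M - m1[mu]) - T01;
  }

  // one Gibbs update of omega[mu][k]
  void update_omega_site(int mu, int k) {
    int z = omega[mu][k];
    int c = C[mu][k];
    long long g = G[mu];
    int m1p = m1[mu] - z;
    long long S1p = S1[mu] - (long long)z * c;
    long long T11 = S1p;
    long long T10 = g * (long long)m1p - T11;
    long long T01 = (Stot[mu] - c) - T11;
    long long T00 = g * (long long)(M - 1 - m1p) - T01;
    double logR = std::log(m1p + h.ap) - std::log(M - 1 - m1p + h.bp)
      + lb(T11 + c + h.a1, T10 + (g - c) + h.b1) - lb(T11 + h.a1, T10 + h.b1)
      - lb(T01 + c + h.a0, T00 + (g - c) + h.b0) + lb(T01 + h.a0, T00 + h.b0);
    double p1 = 1.0 / (1.0 + std::exp(-logR));
    int znew = (unif_rand() < p1) ? 1 : 0;
    if (znew != z) {
      omega[mu][k] = znew;
      m1[mu] += znew - z;
      S1[mu] += (long long)(znew - z) * c;
    }
  }

  void remove_neuron(int i) {
    int mu = t[i];
    long long a1 = a1_of(i, mu);
    G[mu]--;
    S1[mu] -= a1;
    Stot[mu] -= rsum[i];
    for (int k : frames[i]) C[mu][k]--;
    t[i] = -1;
  }

  void add_neuron(int i, int mu) {
    long long a1 = a1_of(i, mu);
    G[mu]++;
    S1[mu] += a1;
    Stot[mu] += rsum[i];
    for (int k : frames[i]) C[mu][k]++;
    t[i] = mu;
  }

  // log Beta-ratio of adding neuron i (with a1 on-active frames) to the
  // current table of assembly mu
  inline double add_logratio(int i, int mu, long long a1) const {
    long long T11, T10, T01, T00;
    tab(mu, T11, T10, T01, T00);
    long long r = rsum[i];
    long long mm1 = m1[mu];
    return lb(T11 + a1 + h.a1, T10 + (mm1 - a1) + h.b1)
         - lb(T11 + h.a1, T10 + h.b1)
         + lb(T01 + (r - a1) + h.a0, T00 + (M - mm1) - (r - a1) + h.b0)
         - lb(T01 + h.a0, T00 + h.b0);
  }

  void delete_assembly(int mu) {
    int last = A - 1;
    if (mu != last) {
      omega[mu] = std::move(omega[last]);
      C[mu] = std::move(C[last]);
      G[mu] = G[last]; m1[mu] = m1[last];
      S1[mu] = S1[last]; Stot[mu] = Stot[last];
      ids[mu] = ids[last];
      for (int i = 0; i < N; ++i) if (t[i] == last) t[i] = mu;
    }
    omega.pop_back(); C.pop_back();
    G.pop_back(); m1.pop_back(); S1.pop_back(); Stot.pop_back(); ids.pop_back();
    A--;
  }

  // fixed-A Gibbs membership update (Eq-18 style categorical)
  void gibbs_membership(int i) {
    remove_neuron(i);
    std::vector<double> logw(A);
    double mx = -1e300;
    for (int mu = 0; mu < A; ++mu) {
      long long a1 = a1_of(i, mu);
      logw[mu] = std::log(G[mu] + h.an) + add_logratio(i, mu, a1);
      if (logw[mu] > mx) mx = logw[mu];
    }
    double tot = 0;
    for (int mu = 0; mu < A; ++mu) { logw[mu] = std::exp(logw[mu] - mx); tot += logw[mu]; }
    double u = unif_rand() * tot;
    int pick = A - 1;
    double acc = 0;
    for (int mu = 0; mu < A; ++mu) { acc += logw[mu]; if (u <= acc) { pick = mu; break; } }
    add_neuron(i, pick);
  }

  // DP Metropolis-Hastings membership move (proposal from occupancy /
  // concentration weights; acceptance is the collapsed likelihood ratio)
  void dp_membership(int i) {
    int cur = t[i];
    double tot = (double)(N - 1) + h.dpa;
    double u = unif_rand() * tot;
    int prop = -1;             // -1 encodes "new assembly"
    double acc = 0;
    for (int mu = 0; mu < A; ++mu) {
      acc += (double)(G[mu] - (mu == cur ? 1 : 0));
      if (u <= acc) { prop = mu; break; }
    }
    if (prop == cur && prop >= 0) return;   // identical proposal, accepted no-op
    // leave-one-out log-predictive of staying in cur
    long long a1cur = a1_of(i, cur);
    remove_neuron(i);
    double ll_cur = add_logratio(i, cur, a1cur);
    if (prop >= 0) {
      long long a1p = a1_of(i, prop);
      double ll_new = add_logratio(i, prop, a1p);
      if (std::log(unif_rand()) < ll_new - ll_cur) {
        add_neuron(i, prop);
        if (G[cur] == 0) delete_assembly(cur);
      } else add_neuron(i, cur);
    } else {
      // propose a fresh assembly with an omega column drawn from its prior
      double pstar = R::rbeta(h.ap, h.bp);
      std::vector<int> col(M);
      long long m1n = 0, a1n = 0;
      for (int k = 0; k < M; ++k) {
        col[k] = (unif_rand() < pstar) ? 1 : 0;
        m1n += col[k];
      }
      for (int k : frames[i]) a1n += col[k];
      long long r = rsum[i];
      double ll_new = lb(a1n + h.a1, (m1n - a1n) + h.b1) - lb(h.a1, h.b1)
        + lb((r - a1n) + h.a0, (M - m1n) - (r - a1n) + h.b0) - lb(h.a0, h.b0);
      if (std::log(unif_rand()) < ll_new - ll_cur) {
        omega.push_back(std::move(col));
        C.push_back(std::vector<int>(M, 0));
        G.push_back(0); m1.push_back((int)m1n);
        S1.push_back(0); Stot.push_back(0);
        ids.push_back(next_id++);
        A++;
        add_neuron(i, A - 1);
        if (G[cur] == 0) delete_assembly(cur);
      } else add_neuron(i, cur);
    }
  }

  double log_marginal() const {
    double ll = 0;
    if (dp) {
      ll += A * std::log(h.dpa) + R::lgammafn(h.dpa) - R::lgammafn(h.dpa + N);
      for (int mu = 0; mu < A; ++mu) ll += R::lgammafn((double)G[mu]);
    } else {
      double sa = 0, sl = 0;
      for (int mu = 0; mu < A; ++mu) {
        sl += R::lgammafn(G[mu] + h.an) - R::lgammafn(h.an);
        sa += G[mu] + h.an;
      }
      ll += sl + R::lgammafn(A * h.an) - R::lgammafn(sa);
    }
    for (int mu = 0; mu < A; ++mu) {
      ll += lb(m1[mu] + h.ap, M - m1[mu] + h.bp) - lb(h.ap, h.bp);
      long long T11, T10, T01, T00;
      tab(mu, T11, T10, T01, T00);
      ll += lb(T11 + h.a1, T10 + h.b1) - lb(h.a1, h.b1);
      ll += lb(T01 + h.a0, T00 + h.b0) - lb(h.a0, h.b0);
    }
    return ll;
  }

  // recompute all aggregates from scratch and compare (debug integrity check)
  bool stats_consistent(const IntegerMatrix& s) const {
    for (int mu = 0; mu < A; ++mu) {
      int g = 0; long long s1 = 0, stot = 0; int mm = 0;
      std::vector<int> cc(M, 0);
      for (int i = 0; i < N; ++i) if (t[i] == mu) { g++; for (int k : frames[i]) cc[k]++; }
      for (int k = 0; k < M; ++k) {
        if (cc[k] != C[mu][k]) return false;
        mm += omega[mu][k];
        stot += cc[k];
        if (omega[mu][k]) s1 += cc[k];
      }
      if (g != G[mu] || mm != m1[mu] || s1 != S1[mu] || stot != Stot[mu]) return false;
    }
    return true;
  }
};

// [[Rcpp::export(name = ".sampler_run")]]
List sampler_run(IntegerMatrix s, IntegerVector t_init, int A_init,
                 List hyper, int n_iter, int burn_in, int thin,
                 bool dp, bool record_omega, bool record_theta) {
  Hyper h;
  h.ap = hyper["alpha_p"]; h.bp = hyper["beta_p"];
  h.a0 = hyper["alpha_lambda0"]; h.b0 = hyper["beta_lambda0"];
  h.a1 = hyper["alpha_lambda1"]; h.b1 = hyper["beta_lambda1"];
  h.an = hyper["alpha_n"]; h.dpa = hyper["dp_alpha"];

  AssemblySampler S(s, t_init, A_init, h, dp);
  int N = S.N, M = S.M;

  std::vector<double> loglik(n_iter), trans(n_iter);
  std::vector<int> Atrace(n_iter);
  std::vector<std::vector<int>> t_samples;
  List omega_samples, theta_samples;
  std::vector<int> prev_id(N);

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) prev_id[i] = S.ids[S.t[i]];
    for (int mu = 0; mu < S.A; ++mu)
      for (int k = 0; k < M; ++k) S.update_omega_site(mu, k);
    if (dp) { for (int i = 0; i < N; ++i) S.dp_membership(i); }
    else    { for (int i = 0; i < N; ++i) S.gibbs_membership(i); }

    // theta readout draws (Algorithm line 7); stored only at save points
    NumericVector p_draw(S.A), l0_draw(S.A), l1_draw(S.A);
    for (int mu = 0; mu < S.A; ++mu) {
      long long T11, T10, T01, T00;
      S.tab(mu, T11, T10, T01, T00);
      p_draw[mu]  = R::rbeta(S.m1[mu] + h.ap, M - S.m1[mu] + h.bp);
      l1_draw[mu] = R::rbeta(T11 + h.a1, T10 + h.b1);
      l0_draw[mu] = R::rbeta(T01 + h.a0, T00 + h.b0);
    }

    int moved = 0;
    for (int i = 0; i < N; ++i) if (S.ids[S.t[i]] != prev_id[i]) moved++;
    trans[it] = (double)moved / N;
    loglik[it] = S.log_marginal();
    Atrace[it] = S.A;

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      std::vector<int> snap(N);
      for (int i = 0; i < N; ++i) snap[i] = S.ids[S.t[i]];
      t_samples.push_back(snap);
      if (record_omega) {
        IntegerMatrix om(M, S.A);
        IntegerVector cid(S.A);
        for (int mu = 0; mu < S.A; ++mu) {
          cid[mu] = S.ids[mu];
          for (int k = 0; k < M; ++k) om(k, mu) = S.omega[mu][k];
        }
        om.attr("assembly_id") = cid;
        omega_samples.push_back(om);
      }
      if (record_theta) {
        IntegerVector gg(S.A), cid(S.A);
        for (int mu = 0; mu < S.A; ++mu) { gg[mu] = S.G[mu]; cid[mu] = S.ids[mu]; }
        theta_samples.push_back(List::create(
          _["id"] = cid, _["G"] = gg, _["p"] = p_draw,
          _["lambda0"] = l0_draw, _["lambda1"] = l1_draw));
      }
    }
  }

  int nsave = (int)t_samples.size();
  IntegerMatrix ts(nsave, N);
  for (int r = 0; r < nsave; ++r)
    for (int i = 0; i < N; ++i) ts(r, i) = t_samples[r][i];

  IntegerVector t_final(N);
  for (int i = 0; i < N; ++i) t_final[i] = S.ids[S.t[i]];

  return List::create(
    _["t_samples"] = ts,
    _["omega_samples"] = omega_samples,
    _["theta_samples"] = theta_samples,
    _["loglik"] = NumericVector(loglik.begin(), loglik.end()),
    _["trans_rate"] = NumericVector(trans.begin(), trans.end()),
    _["A"] = IntegerVector(Atrace.begin(), Atrace.end()),
    _["t_final"] = t_final,
    _["A_final"] = S.A,
    _["stats_ok"] = S.stats_consistent(s));
}
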