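#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact stochastic simulation of the bulk reaction network with scheduled ion
// injections.  Reactions (propensities per ms):
//   buffer binding   k0 * Nf * (S_tot - Nb)
//   buffer release   km1 * Nb
//   escape           kes * Nf
//   target binding   kT * Nf   per free (not yet released) target
// Injections arrive at pre-sampled times; dest 0 sends the ion to the bulk,
// dest i (1..NT) binds it instantly to target i (if that target has already
// released, the ion joins the bulk instead).  When a target accumulates Tthr
// bound ions it releases: the time is recorded, the Tthr ions return to the
// bulk and the target is retired.

struct SsaState {
  long Nf = 0, Nb = 0, entered = 0, escaped = 0, events = 0, redirected = 0;
  std::vector<int> bound;
  std::vector<bool> released;
  int n_free_targets;
  SsaState(int NT) : bound(NT, 0), released(NT, false), n_free_targets(NT) {}
  long bound_active() const {
    long s = 0;
    for (size_t i = 0; i < bound.size(); ++i)
      if (!released[i]) s += bound[i];
    return s;
  }
};

typedef void (*EventHook)(double t, int type, int index, const SsaState &st,
                          void *ctx);

// type codes for the event log
enum { EV_ARR_BULK = 1, EV_ARR_DIRECT, EV_BUF_BIND, EV_BUF_UNBIND, EV_ESCAPE,
       EV_TGT_BIND, EV_RELEASE };

static void run_one(const double *arr_t, const int *arr_dest, int n_arr,
                    double k0, double km1, double kes, double kT,
                    int S_tot, int Tthr, int NT, double t_max,
                    std::mt19937_64 &rng, SsaState &st,
                    std::vector<double> &rel_t, std::vector<int> &rel_tgt,
                    EventHook hook, void *ctx) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double t = 0.0;
  int next_arr = 0;
  // places one ion on target i, logs the placing event (with the ion already
  // counted among the bound), then handles a threshold crossing
  auto bind_target = [&](int i, double tnow, int ev_type) {
    st.bound[i]++;
    if (hook) hook(tnow, ev_type, i + 1, st, ctx);
    if (st.bound[i] >= Tthr) {
      st.released[i] = true;
      st.n_free_targets--;
      st.Nf += Tthr;
      rel_t.push_back(tnow);
      rel_tgt.push_back(i + 1);
      if (hook) hook(tnow, EV_RELEASE, i + 1, st, ctx);
    }
  };
  while (t < t_max) {
    double a1 = k0 * st.Nf * (S_tot - st.Nb);
    double a2 = km1 * st.Nb;
    double a3 = kes * st.Nf;
    double a4 = kT * st.Nf * st.n_free_targets;
    double atot = a1 + a2 + a3 + a4;
    double t_next;
    if (atot > 0) {
      double u = unif(rng);
      if (u <= 0.0) u = 1e-300;
      t_next = t - std::log(u) / atot;
    } else {
      t_next = R_PosInf;
    }
    if (next_arr < n_arr && arr_t[next_arr] <= t_next) {
      t = arr_t[next_arr];
      if (t > t_max) break;
      int d = arr_dest[next_arr];
      st.entered++;
      st.events++;
      if (d >= 1 && !st.released[d - 1]) {
        bind_target(d - 1, t, EV_ARR_DIRECT);
      } else {
        if (d >= 1) st.redirected++;
        st.Nf++;
        if (hook) hook(t, EV_ARR_BULK, 0, st, ctx);
      }
      next_arr++;
      continue;
    }
    if (!R_finite(t_next)) break;
    t = t_next;
    if (t > t_max) break;
    st.events++;
    double u2 = unif(rng) * atot;
    if (u2 < a1) {
      st.Nf--; st.Nb++;
      if (hook) hook(t, EV_BUF_BIND, 0, st, ctx);
    } else if (u2 < a1 + a2) {
      st.Nb--; st.Nf++;
      if (hook) hook(t, EV_BUF_UNBIND, 0, st, ctx);
    } else if (u2 < a1 + a2 + a3) {
      st.Nf--; st.escaped++;
      if (hook) hook(t, EV_ESCAPE, 0, st, ctx);
    } else {
      int pick = (int)std::floor(unif(rng) * st.n_free_targets);
      if (pick >= st.n_free_targets) pick = st.n_free_targets - 1;
      int i = -1, seen = 0;
      for (int j = 0; j < NT; ++j)
        if (!st.released[j] && seen++ == pick) { i = j; break; }
      st.Nf--;
      bind_target(i, t, EV_TGT_BIND);
    }
    if (st.Nf == 0 && st.Nb == 0 && next_arr >= n_arr) break;
  }
}

// [[Rcpp::export]]
List ssa_batch_cpp(IntegerVector run_of_ion, NumericVector t_arrival,
                   IntegerVector dest, int n_runs,
                   double k0, double km1, double kes, double kT,
                   int S_tot, int Tthr, int NT, double t_max, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<double> rel_t;
  std::vector<int> rel_tgt, rel_run;
  IntegerMatrix ledger(n_runs, 8);
  colnames(ledger) = CharacterVector::create(
      "entered", "escaped", "free", "buffer_bound", "target_bound",
      "released", "events", "redirected");
  int n_ions = run_of_ion.size(), pos = 0;
  for (int run = 0; run < n_runs; ++run) {
    int start = pos;
    while (pos < n_ions && run_of_ion[pos] == run) pos++;
    SsaState st(NT);
    std::vector<double> rt;
    std::vector<int> rg;
    run_one(&t_arrival[start], &dest[start], pos - start, k0, km1, kes, kT,
            S_tot, Tthr, NT, t_max, rng, st, rt, rg, nullptr, nullptr);
    for (size_t i = 0; i < rt.size(); ++i) {
      rel_t.push_back(rt[i]);
      rel_tgt.push_back(rg[i]);
      rel_run.push_back(run + 1);
    }
    ledger(run, 0) = (int)st.entered;
    ledger(run, 1) = (int)st.escaped;
    ledger(run, 2) = (int)st.Nf;
    ledger(run, 3) = (int)st.Nb;
    ledger(run, 4) = (int)st.bound_active();
    ledger(run, 5) = (int)rt.size();
    ledger(run, 6) = (int)st.events;
    ledger(run, 7) = (int)st.redirected;
    if (run % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["release_time"] = wrap(rel_t),
                      _["release_target"] = wrap(rel_tgt),
                      _["release_run"] = wrap(rel_run),
                      _["ledger"] = ledger);
}

struct LogCtx {
  std::vector<double> t;
  std::vector<int> type, index;
  std::vector<long> Nf, Nb, entered, escaped, bound;
};

static void log_hook(double t, int type, int index, const SsaState &st,
                     void *ctx) {
  LogCtx *lc = static_cast<LogCtx *>(ctx);
  lc->t.push_back(t);
  lc->type.push_back(type);
  lc->index.push_back(index);
  lc->Nf.push_back(st.Nf);
  lc->Nb.push_back(st.Nb);
  lc->entered.push_back(st.entered);
  lc->escaped.push_back(st.escaped);
  lc->bound.push_back(st.bound_active());
}

// [[Rcpp::export]]
List ssa_single_cpp(NumericVector t_arrival, IntegerVector dest,
                    double k0, double km1, double kes, double kT,
                    int S_tot, int Tthr, int NT, double t_max, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  SsaState st(NT);
  std::vector<double> rt;
  std::vector<int> rg;
  LogCtx lc;
  run_one(t_arrival.size() ? &t_arrival[0] : nullptr,
          dest.size() ? &dest[0] : nullptr, t_arrival.size(),
          k0, km1, kes, kT, S_tot, Tthr, NT, t_max, rng, st, rt, rg,
          log_hook, &lc);
  IntegerVector bound_end(NT), released_end(NT);
  for (int j = 0; j < NT; ++j) {
    bound_end[j] = st.bound[j];
    released_end[j] = st.released[j] ? 1 : 0;
  }
  return List::create(
      _["log"] = DataFrame::create(
          _["t"] = wrap(lc.t), _["type"] = wrap(lc.type),
          _["index"] = wrap(lc.index), _["N_f"] = wrap(lc.Nf),
          _["N_b"] = wrap(lc.Nb), _["entered"] = wrap(lc.entered),
          _["escaped"] = wrap(lc.escaped), _["target_bound"] = wrap(lc.bound)),
      _["release_time"] = wrap(rt), _["release_target"] = wrap(rg),
      _["bound_end"] = bound_end, _["released_end"] = released_end,
      _["ledger"] = IntegerVector::create(
          _["entered"] = (int)st.entered, _["escaped"] = (int)st.escaped,
          _["free"] = (int)st.Nf, _["buffer_bound"] = (int)st.Nb,
          _["target_bound"] = (int)st.bound_active(),
          _["released"] = (int)rt.size(), _["events"] = (int)st.events,
          _["redirected"] = (int)st.redirected));
}
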