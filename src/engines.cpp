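#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Compartment order used throughout (states x, counts n):
//   0 lc   low-threshold, current nest
//   1 hc   high-threshold, current nest
//   2 lpcom low, committed to poor site
//   3 hpvis high, visiting poor site (never commits)
//   4 lgcom low, committed to good site
//   5 hgcom high, committed to good site
//   6 lprec low, recruiting to poor site
//   7 lgrec low, recruiting to good site
//   8 hgrec high, recruiting to good site

static inline void mean_field_rhs(const double *x, double ap, double ag,
                                  double as, double al, double *dx) {
  double rec_tot = x[6] + x[7] + x[8];
  double grec = x[7] + x[8];
  dx[0] = -rec_tot * x[0] + al * (x[2] + x[6] + x[4] + x[7]);
  dx[1] = -rec_tot * x[1] + al * (x[3] + x[5] + x[8]);
  dx[2] = x[6] * x[0] - ap * x[2] - al * x[2];
  dx[3] = x[6] * x[1] - as * x[3] - al * x[3];
  dx[4] = grec * x[0] - ag * x[4] - al * x[4];
  dx[5] = grec * x[1] + as * x[3] - ag * x[5] - al * x[5];
  dx[6] = ap * x[2] - al * x[6];
  dx[7] = ag * x[4] - al * x[7];
  dx[8] = ag * x[5] - al * x[8];
}

// [[Rcpp::export]]
NumericVector cpp_ode_rhs(NumericVector state, double alpha_p, double alpha_g,
                          double alpha_s, double alpha_leak) {
  NumericVector out(9);
  mean_field_rhs(state.begin(), alpha_p, alpha_g, alpha_s, alpha_leak,
                 out.begin());
  return out;
}

// Forward-Euler integration with decimated storage.  The stored grid keeps
// every `stride`-th step (plus t = 0 and the final step); negativity beyond
// `neg_tol` aborts (signals the step size is too large for positivity).
// [[Rcpp::export]]
List cpp_euler(NumericVector y0, double alpha_p, double alpha_g,
               double alpha_s, double alpha_leak, double dt, double t_max,
               int stride, double neg_tol) {
  int n_steps = (int)std::ceil(t_max / dt - 1e-9);
  int n_keep = n_steps / stride + 2;
  NumericVector times(n_keep);
  NumericMatrix states(n_keep, 9);
  double x[9], dx[9];
  for (int j = 0; j < 9; ++j) x[j] = y0[j];
  int k = 0;
  times[0] = 0.0;
  for (int j = 0; j < 9; ++j) states(0, j) = x[j];
  ++k;
  for (int i = 1; i <= n_steps; ++i) {
    mean_field_rhs(x, alpha_p, alpha_g, alpha_s, alpha_leak, dx);
    for (int j = 0; j < 9; ++j) {
      x[j] += dt * dx[j];
      if (x[j] < -neg_tol)
        stop("state component %d went negative (%.3e) at t=%.4f; "
             "reduce dt", j + 1, x[j], i * dt);
    }
    if (i % stride == 0 || i == n_steps) {
      times[k] = i * dt;
      for (int j = 0; j < 9; ++j) states(k, j) = x[j] < 0.0 ? 0.0 : x[j];
      ++k;
    }
  }
  return List::create(_["times"] = times[Range(0, k - 1)],
                      _["states"] = states(Range(0, k - 1), _));
}

// Full-resolution quorum pass for the deterministic model: integrates without
// storing the trajectory and returns the first step at which either vote
// reaches the quorum fraction.  site: 1 = good, 2 = poor, 0 = never.
// [[Rcpp::export]]
List cpp_ode_quorum(NumericVector y0, double alpha_p, double alpha_g,
                    double alpha_s, double alpha_leak, double dt,
                    double t_max, double quorum) {
  int n_steps = (int)std::ceil(t_max / dt - 1e-9);
  double x[9], dx[9];
  for (int j = 0; j < 9; ++j) x[j] = y0[j];
  for (int i = 1; i <= n_steps; ++i) {
    mean_field_rhs(x, alpha_p, alpha_g, alpha_s, alpha_leak, dx);
    for (int j = 0; j < 9; ++j) x[j] += dt * dx[j];
    double v_good = x[4] + x[5] + x[7] + x[8];
    double v_poor = x[2] + x[6] + x[3];
    if (v_good >= quorum || v_poor >= quorum)
      return List::create(_["time"] = i * dt,
                          _["site"] = v_good >= quorum ? 1 : 2);
  }
  return List::create(_["time"] = R_NilValue, _["site"] = 0);
}

// The 15 Poisson event channels of the finite-population model.
// src/dst give the compartment whose count decreases/increases by one.
static const int EV_SRC[15] = {0, 0, 1, 1, 2, 4, 5, 3, 2, 4, 6, 7, 3, 5, 8};
static const int EV_DST[15] = {2, 4, 3, 5, 6, 7, 8, 5, 0, 0, 0, 0, 1, 1, 1};

static inline void channel_rates(const int *n, double N, double ap, double ag,
                                 double as, double al, double *r) {
  double grec = (n[7] + n[8]) / N;
  r[0] = n[0] * (n[6] / N);   // lc -> lpcom, recruited by poor recruiters
  r[1] = n[0] * grec;         // lc -> lgcom, recruited by good recruiters
  r[2] = n[1] * (n[6] / N);   // hc -> hpvis
  r[3] = n[1] * grec;         // hc -> hgcom
  r[4] = ap * n[2];           // lpcom -> lprec
  r[5] = ag * n[4];           // lgcom -> lgrec
  r[6] = ag * n[5];           // hgcom -> hgrec
  r[7] = as * n[3];           // hpvis -> hgcom (switch to good site)
  r[8]  = al * n[2];          // leakage back to the current nest
  r[9]  = al * n[4];
  r[10] = al * n[6];
  r[11] = al * n[7];
  r[12] = al * n[3];
  r[13] = al * n[5];
  r[14] = al * n[8];
}

// [[Rcpp::export]]
NumericVector cpp_event_rates(IntegerVector counts, double N, double alpha_p,
                              double alpha_g, double alpha_s,
                              double alpha_leak) {
  NumericVector r(15);
  int n[9];
  for (int j = 0; j < 9; ++j) n[j] = counts[j];
  channel_rates(n, N, alpha_p, alpha_g, alpha_s, alpha_leak, r.begin());
  return r;
}

// Exact event-driven (Gillespie) simulation.  quorum_n <= 0 disables the
// quorum stopping rule (used for trajectory recording in the mean-field-limit
// checks).  record_times, if non-empty, receives state snapshots: the counts
// in force at each requested time.  Result codes: 1 good-site quorum, 2
// poor-site quorum, 3 unsuccessful (total rate zero), 4 censored at t_max.
// [[Rcpp::export]]
List cpp_ssa(IntegerVector counts0, double N, double alpha_p, double alpha_g,
             double alpha_s, double alpha_leak, int quorum_n, double t_max,
             NumericVector record_times, bool log_events, int max_log) {
  int n[9];
  for (int j = 0; j < 9; ++j) n[j] = counts0[j];
  double r[15];
  double t = 0.0;
  long n_events = 0;
  int result = 0;
  double t_event = NA_REAL;
  int n_rec = record_times.size();
  int rec_i = 0;
  NumericMatrix snaps(n_rec, 9);
  std::vector<double> logbuf;
  if (log_events) logbuf.reserve(1024);

  for (;;) {
    channel_rates(n, N, alpha_p, alpha_g, alpha_s, alpha_leak, r);
    double total = 0.0;
    for (int c = 0; c < 15; ++c) total += r[c];
    if (total <= 0.0) {  // absorbing: every ant back in the current nest
      result = 3;
      t_event = t;
      break;
    }
    double t_next = t + R::exp_rand() / total;
    while (rec_i < n_rec && record_times[rec_i] < t_next) {
      for (int j = 0; j < 9; ++j) snaps(rec_i, j) = n[j];
      ++rec_i;
    }
    if (t_next > t_max) {
      result = 4;
      t_event = t_max;
      break;
    }
    t = t_next;
    double u = unif_rand() * total;
    int c = 0;
    double acc = r[0];
    while (acc < u && c < 14) acc += r[++c];
    --n[EV_SRC[c]];
    ++n[EV_DST[c]];
    ++n_events;
    if (log_events && (max_log <= 0 || (int)(logbuf.size() / 11) < max_log)) {
      logbuf.push_back(t);
      logbuf.push_back(c + 1);
      for (int j = 0; j < 9; ++j) logbuf.push_back(n[j]);
    }
    if (quorum_n > 0) {
      int v_good = n[4] + n[5] + n[7] + n[8];
      int v_poor = n[2] + n[6] + n[3];
      if (v_good >= quorum_n) { result = 1; t_event = t; break; }
      if (v_poor >= quorum_n) { result = 2; t_event = t; break; }
    }
  }
  while (rec_i < n_rec) {  // remaining snapshot times: frozen final state
    for (int j = 0; j < 9; ++j) snaps(rec_i, j) = n[j];
    ++rec_i;
  }
  IntegerVector final_counts(9);
  for (int j = 0; j < 9; ++j) final_counts[j] = n[j];
  List out = List::create(
      _["result"] = result, _["t_event"] = t_event,
      _["n_events"] = (double)n_events, _["counts"] = final_counts,
      _["snapshots"] = n_rec > 0 ? (SEXP)snaps : R_NilValue);
  if (log_events) {
    int nrow = (int)(logbuf.size() / 11);
    NumericMatrix lg(nrow, 11);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < 11; ++j) lg(i, j) = logbuf[i * 11 + j];
    out["event_log"] = lg;
  }
  return out;
}

// Discrete-time cross-validation engine: per-step Bernoulli transitions with
// probability rate*dt per ant.  Competing exits from one compartment are
// drawn as sequential binomials (an exact multinomial split).  Any per-ant
// per-step probability >= p_max aborts, naming the offending channel.
static inline int draw_bin(int size, double p) {
  if (size <= 0 || p <= 0.0) return 0;
  return (int)R::rbinom((double)size, p);
}

// [[Rcpp::export]]
List cpp_discrete(IntegerVector counts0, double N, double alpha_p,
                  double alpha_g, double alpha_s, double alpha_leak,
                  double dt, int quorum_n, double t_max, double p_max) {
  int n[9];
  for (int j = 0; j < 9; ++j) n[j] = counts0[j];
  long n_steps_max = (long)std::ceil(t_max / dt);
  int result = 0;
  double t_event = NA_REAL;
  long n_moves = 0;
  static const char *chan_names[4] = {
      "recruitment to the poor site", "recruitment to the good site",
      "leakage", "conversion/switch"};
  for (long s = 1; s <= n_steps_max; ++s) {
    bool any = false;
    for (int j = 2; j < 9; ++j) any = any || n[j] > 0;
    if (!any) { result = 3; t_event = (s - 1) * dt; break; }
    double p_poor = n[6] / N * dt;
    double p_good = (n[7] + n[8]) / N * dt;
    double p_ap = alpha_p * dt, p_ag = alpha_g * dt, p_as = alpha_s * dt;
    double p_al = alpha_leak * dt;
    double probs[4] = {p_poor, p_good, p_al,
                       std::max(p_ap, std::max(p_ag, p_as))};
    for (int c = 0; c < 4; ++c)
      if (probs[c] >= p_max)
        stop("per-ant per-step probability %.3f for %s exceeds %.2f; "
             "reduce dt", probs[c], chan_names[c], p_max);
    // draws from start-of-step counts
    int lc_p = draw_bin(n[0], p_poor);
    int lc_g = draw_bin(n[0] - lc_p, p_poor < 1.0 ? p_good / (1.0 - p_poor) : 0.0);
    int hc_p = draw_bin(n[1], p_poor);
    int hc_g = draw_bin(n[1] - hc_p, p_poor < 1.0 ? p_good / (1.0 - p_poor) : 0.0);
    int lpcom_rec = draw_bin(n[2], p_ap);
    int lpcom_leak = draw_bin(n[2] - lpcom_rec, p_ap < 1.0 ? p_al / (1.0 - p_ap) : 0.0);
    int lgcom_rec = draw_bin(n[4], p_ag);
    int lgcom_leak = draw_bin(n[4] - lgcom_rec, p_ag < 1.0 ? p_al / (1.0 - p_ag) : 0.0);
    int hgcom_rec = draw_bin(n[5], p_ag);
    int hgcom_leak = draw_bin(n[5] - hgcom_rec, p_ag < 1.0 ? p_al / (1.0 - p_ag) : 0.0);
    int hpvis_sw = draw_bin(n[3], p_as);
    int hpvis_leak = draw_bin(n[3] - hpvis_sw, p_as < 1.0 ? p_al / (1.0 - p_as) : 0.0);
    int lprec_leak = draw_bin(n[6], p_al);
    int lgrec_leak = draw_bin(n[7], p_al);
    int hgrec_leak = draw_bin(n[8], p_al);

    n[0] += -lc_p - lc_g + lpcom_leak + lgcom_leak + lprec_leak + lgrec_leak;
    n[1] += -hc_p - hc_g + hpvis_leak + hgcom_leak + hgrec_leak;
    n[2] += lc_p - lpcom_rec - lpcom_leak;
    n[3] += hc_p - hpvis_sw - hpvis_leak;
    n[4] += lc_g - lgcom_rec - lgcom_leak;
    n[5] += hc_g + hpvis_sw - hgcom_rec - hgcom_leak;
    n[6] += lpcom_rec - lprec_leak;
    n[7] += lgcom_rec - lgrec_leak;
    n[8] += hgcom_rec - hgrec_leak;
    n_moves += lc_p + lc_g + hc_p + hc_g + lpcom_rec + lgcom_rec + hgcom_rec +
               hpvis_sw + lpcom_leak + lgcom_leak + hgcom_leak + hpvis_leak +
               lprec_leak + lgrec_leak + hgrec_leak;
    if (quorum_n > 0) {
      int v_good = n[4] + n[5] + n[7] + n[8];
      int v_poor = n[2] + n[6] + n[3];
      if (v_good >= quorum_n || v_poor >= quorum_n) {
        result = v_good >= quorum_n ? 1 : 2;
        t_event = s * dt;
        break;
      }
    }
  }
  if (result == 0) { result = 4; t_event = t_max; }
  IntegerVector final_counts(9);
  for (int j = 0; j < 9; ++j) final_counts[j] = n[j];
  return List::create(_["result"] = result, _["t_event"] = t_event,
                      _["n_events"] = (double)n_moves,
                      _["counts"] = final_counts);
}

// Multi-nest emigration engine (all sites equally good: single low threshold,
// no switching).  State: n_c plus (committed_i, recruiter_i) per site.
// Stops when the total new-site occupancy reaches finish_n (result 1), at
// extinction (3), or t_max (4).
// [[Rcpp::export]]
List cpp_cohesion(int n_c0, IntegerVector com0, IntegerVector rec0, double N,
                  double alpha, double alpha_leak, int finish_n,
                  double t_max) {
  int k = com0.size();
  std::vector<int> com(k), rec(k);
  int n_c = n_c0;
  for (int i = 0; i < k; ++i) { com[i] = com0[i]; rec[i] = rec0[i]; }
  std::vector<double> r(3 * k);  // per site: recruit, convert, leak(com)+leak(rec) folded below
  double t = 0.0;
  long n_events = 0;
  int result = 0;
  double t_event = NA_REAL;
  // channel layout: for site i: [4i] recruit c->com_i, [4i+1] com_i->rec_i,
  // [4i+2] com_i->c, [4i+3] rec_i->c
  std::vector<double> rate(4 * k);
  for (;;) {
    double total = 0.0;
    for (int i = 0; i < k; ++i) {
      rate[4 * i] = n_c * (rec[i] / N);
      rate[4 * i + 1] = alpha * com[i];
      rate[4 * i + 2] = alpha_leak * com[i];
      rate[4 * i + 3] = alpha_leak * rec[i];
      total += rate[4 * i] + rate[4 * i + 1] + rate[4 * i + 2] +
               rate[4 * i + 3];
    }
    if (total <= 0.0) { result = 3; t_event = t; break; }
    double t_next = t + R::exp_rand() / total;
    if (t_next > t_max) { result = 4; t_event = t_max; break; }
    t = t_next;
    double u = unif_rand() * total;
    int c = 0;
    double acc = rate[0];
    while (acc < u && c < 4 * k - 1) acc += rate[++c];
    int site = c / 4, kind = c % 4;
    if (kind == 0) { --n_c; ++com[site]; }
    else if (kind == 1) { --com[site]; ++rec[site]; }
    else if (kind == 2) { --com[site]; ++n_c; }
    else { --rec[site]; ++n_c; }
    ++n_events;
    if ((int)N - n_c >= finish_n) { result = 1; t_event = t; break; }
  }
  IntegerVector occ(k);
  for (int i = 0; i < k; ++i) occ[i] = com[i] + rec[i];
  return List::create(_["result"] = result, _["t_event"] = t_event,
                      _["n_events"] = (double)n_events,
                      _["site_counts"] = occ, _["n_current"] = n_c);
}
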