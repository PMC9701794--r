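#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Draw-order contract (shared with the pure-R backend and the naive oracle;
// all draws come from R's global RNG stream, so a shared seed reproduces the
// run bit-for-bit across backends):
//   init (uniform_random scheme): per individual, one uniform per allele slot
//     (slot 1 then slot 2), label = floor(u * A).
//   per attack: (1) target draw j = floor(u * n_alive) into the alive list,
//     (2) kill draw, killed iff u < 1 - escape[target]. Learning updates
//     consume no draws.
//   per birth: parent position draw(s) (asexual: one; sexual: first-parent
//     position j1 = floor(u * n_surv), then second-parent position
//     j2 = floor(u * (n_surv - 1)), shifted past j1 to force a distinct
//     pair), then allele-pick draw(s) (haploid sexual: one, < 0.5 takes the
//     first parent's allele; diploid: one per parent, < 0.5 takes that
//     parent's first slot). Newborns are not drawable as parents within
//     their birth step.
// Alive-list semantics: creation order; a predation kill swap-removes (last
// element moves into the freed slot); age-cap mortality is a stable filter;
// newborns are appended in birth order.

static inline int draw_index(int n) {
  int j = (int)(unif_rand() * n);
  if (j >= n) j = n - 1; // unreachable for R's RNG, defensive only
  return j;
}

static inline double learn(double p, int mode, double rate, double cap) {
  double q = (mode == 0) ? p * (1.0 + rate) : p + rate * (cap - p);
  return q > cap ? cap : q;
}

// learning_mode: 0 accelerating, 1 decelerating
// learning_timing: 0 step_end, 1 immediate
// reproduction_mode: 0 haploid_asexual, 1 haploid_sexual, 2 diploid_sexual
// max_age: negative means unbounded
// [[Rcpp::export]]
List sim_run_cpp(int population_size, int n_initial_alleles, int n_steps,
                 int n_removed, double initial_escape, double escape_cap,
                 bool learning_enabled, int learning_mode, int learning_timing,
                 double learning_rate, int reproduction_mode, int max_age,
                 bool balanced_init, bool log_events) {
  const int N = population_size, A = n_initial_alleles;
  const bool diploid = (reproduction_mode == 2);
  const bool sexual = (reproduction_mode != 0);
  const bool immediate = (learning_timing == 1);

  // individual table (grows over the run; ids are 1-based row numbers)
  std::vector<int> birth, death, cause, a1, a2, off_n, age;
  std::vector<double> off_sum, escape;
  std::vector<char> flag;
  size_t reserve = (size_t)N + (size_t)n_steps * ((size_t)n_removed + 8) + 64;
  birth.reserve(reserve); death.reserve(reserve); cause.reserve(reserve);
  a1.reserve(reserve); a2.reserve(reserve); off_n.reserve(reserve);
  off_sum.reserve(reserve); escape.reserve(reserve); age.reserve(reserve);
  flag.reserve(reserve);

  std::vector<int> alive; alive.reserve(N + 8);

  for (int i = 0; i < N; i++) {
    int l1, l2 = NA_INTEGER;
    if (balanced_init) {
      l1 = i / (N / A);
      if (diploid) l2 = l1;
    } else {
      l1 = draw_index(A);
      if (diploid) l2 = draw_index(A);
    }
    birth.push_back(0); death.push_back(NA_INTEGER); cause.push_back(0);
    a1.push_back(l1); a2.push_back(l2); off_n.push_back(0);
    off_sum.push_back(0.0); escape.push_back(initial_escape);
    age.push_back(0); flag.push_back(0);
    alive.push_back(i);
  }

  // per-step trajectory records
  IntegerVector tr_alleles(n_steps), tr_dpred(n_steps), tr_dage(n_steps),
      tr_attacks(n_steps);
  NumericVector tr_mean_escape(n_steps);
  IntegerMatrix age_hist(n_steps, n_steps + 1);
  IntegerMatrix spectrum(n_steps, A);

  // optional event log (intended for small validation runs)
  std::vector<int> ev_step, ev_target, ev_escaped;
  std::vector<int> bv_step, bv_child, bv_p1, bv_p2;

  for (int t = 1; t <= n_steps; t++) {
    // (1) age-cap mortality: stable filter, deaths outside the quota
    int d_age = 0;
    if (max_age >= 0) {
      size_t w = 0;
      for (size_t k = 0; k < alive.size(); k++) {
        int id = alive[k];
        if (age[id] > max_age) {
          death[id] = t; cause[id] = 2; d_age++;
        } else {
          alive[w++] = id;
        }
      }
      alive.resize(w);
    }

    int need = sexual ? 2 : 1;
    if ((int)alive.size() - n_removed < need)
      stop("step %d: %d alive before predation; quota %d leaves fewer than the %d survivor(s) reproduction requires",
           t, (int)alive.size(), n_removed, need);

    // (2) predation to quota
    int killed = 0, attacks = 0;
    while (killed < n_removed) {
      attacks++;
      int j = draw_index((int)alive.size());
      int id = alive[j];
      double u = unif_rand();
      bool dead = (u < 1.0 - escape[id]);
      if (log_events) {
        ev_step.push_back(t); ev_target.push_back(id + 1);
        ev_escaped.push_back(dead ? 0 : 1);
      }
      if (dead) {
        death[id] = t; cause[id] = 1;
        alive[j] = alive.back(); alive.pop_back();
        killed++;
      } else if (learning_enabled) {
        if (immediate)
          escape[id] = learn(escape[id], learning_mode, learning_rate, escape_cap);
        else
          flag[id] = 1;
      }
    }

    // (3) step-end learning: one update per flagged survivor, however many
    // attacks it escaped this step
    if (learning_enabled && !immediate) {
      for (size_t k = 0; k < alive.size(); k++) {
        int id = alive[k];
        if (flag[id]) {
          escape[id] = learn(escape[id], learning_mode, learning_rate, escape_cap);
          flag[id] = 0;
        }
      }
    }

    // (4) reproduction restores the population to its original size;
    // newborn escape probability resets to the initial value (learning is
    // not heritable)
    const int n_surv = (int)alive.size();
    const int n_births = N - n_surv;
    for (int b = 0; b < n_births; b++) {
      int c1, c2 = NA_INTEGER, p1, p2 = -1;
      if (!sexual) {
        p1 = alive[draw_index(n_surv)];
        c1 = a1[p1];
        if (diploid) c2 = a2[p1]; // not reachable: diploid implies sexual
      } else {
        int j1 = draw_index(n_surv);
        int j2 = draw_index(n_surv - 1);
        if (j2 >= j1) j2++;
        p1 = alive[j1]; p2 = alive[j2];
        if (!diploid) {
          c1 = (unif_rand() < 0.5) ? a1[p1] : a1[p2];
        } else {
          c1 = (unif_rand() < 0.5) ? a1[p1] : a2[p1];
          c2 = (unif_rand() < 0.5) ? a1[p2] : a2[p2];
        }
      }
      int child = (int)birth.size();
      birth.push_back(t); death.push_back(NA_INTEGER); cause.push_back(0);
      a1.push_back(c1); a2.push_back(c2); off_n.push_back(0);
      off_sum.push_back(0.0); escape.push_back(initial_escape);
      age.push_back(0); flag.push_back(0);
      alive.push_back(child);
      off_n[p1]++; off_sum[p1] += t - birth[p1];
      if (p2 >= 0) { off_n[p2]++; off_sum[p2] += t - birth[p2]; }
      if (log_events) {
        bv_step.push_back(t); bv_child.push_back(child + 1);
        bv_p1.push_back(p1 + 1); bv_p2.push_back(p2 >= 0 ? p2 + 1 : NA_INTEGER);
      }
    }

    // (5) record metrics (after reproduction, before the age increment)
    {
      std::vector<int> spec(A, 0);
      double esc_sum = 0.0;
      for (size_t k = 0; k < alive.size(); k++) {
        int id = alive[k];
        spec[a1[id]]++;
        if (diploid) spec[a2[id]]++;
        esc_sum += escape[id];
        age_hist(t - 1, age[id])++;
      }
      int distinct = 0;
      for (int l = 0; l < A; l++) {
        spectrum(t - 1, l) = spec[l];
        if (spec[l] > 0) distinct++;
      }
      tr_alleles[t - 1] = distinct;
      tr_dpred[t - 1] = killed;
      tr_dage[t - 1] = d_age;
      tr_attacks[t - 1] = attacks;
      tr_mean_escape[t - 1] = esc_sum / alive.size();
    }

    // (6) ages advance by one completed step; newborns stay at 0
    for (size_t k = 0; k < alive.size(); k++) {
      int id = alive[k];
      if (birth[id] < t) age[id]++;
    }
  }

  int M = (int)birth.size();
  IntegerVector r_id(M), r_birth(M), r_death(M), r_cause(M), r_a1(M), r_a2(M),
      r_offn(M), r_age(M);
  NumericVector r_offsum(M), r_escape(M);
  for (int i = 0; i < M; i++) {
    r_id[i] = i + 1; r_birth[i] = birth[i]; r_death[i] = death[i];
    r_cause[i] = cause[i]; r_a1[i] = a1[i]; r_a2[i] = a2[i];
    r_offn[i] = off_n[i]; r_offsum[i] = off_sum[i];
    r_escape[i] = escape[i]; r_age[i] = age[i];
  }

  List out = List::create(
      _["n_alleles"] = tr_alleles, _["deaths_predation"] = tr_dpred,
      _["deaths_agecap"] = tr_dage, _["n_attacks"] = tr_attacks,
      _["mean_escape"] = tr_mean_escape, _["age_hist"] = age_hist,
      _["spectrum"] = spectrum,
      _["individuals"] = DataFrame::create(
          _["id"] = r_id, _["birth_step"] = r_birth, _["death_step"] = r_death,
          _["cause"] = r_cause, _["allele1"] = r_a1, _["allele2"] = r_a2,
          _["n_offspring"] = r_offn, _["offspring_age_sum"] = r_offsum,
          _["escape_prob"] = r_escape, _["age"] = r_age));
  if (log_events) {
    out["attacks"] = DataFrame::create(
        _["step"] = wrap(ev_step), _["target_id"] = wrap(ev_target),
        _["escaped"] = wrap(ev_escaped));
    out["births"] = DataFrame::create(
        _["step"] = wrap(bv_step), _["child_id"] = wrap(bv_child),
        _["parent1_id"] = wrap(bv_p1), _["parent2_id"] = wrap(bv_p2));
  }
  return out;
}
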