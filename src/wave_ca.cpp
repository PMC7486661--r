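#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Bucket-grid neighbour search: for each row of `a`, the (1-based) indices of
// rows of `b` within `radius`. With exclude_self = true, entry i of `a` never
// lists entry i of `b` (used when a and b are the same point set).
// [[Rcpp::export]]
List radius_pairs(NumericMatrix a, NumericMatrix b, double radius,
                  bool exclude_self = false) {
  const int na = a.nrow(), nb = b.nrow();
  const double r2 = radius * radius;
  const double cell = radius > 0 ? radius : 1.0;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(nb * 2);
  auto key = [&](double x, double y) -> long long {
    long long ix = (long long)std::floor(x / cell);
    long long iy = (long long)std::floor(y / cell);
    return ix * 2000003LL + iy;
  };
  for (int j = 0; j < nb; ++j) grid[key(b(j, 0), b(j, 1))].push_back(j);

  List out(na);
  std::vector<int> hits;
  for (int i = 0; i < na; ++i) {
    hits.clear();
    const double x = a(i, 0), y = a(i, 1);
    long long ix = (long long)std::floor(x / cell);
    long long iy = (long long)std::floor(y / cell);
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        auto it = grid.find((ix + dx) * 2000003LL + (iy + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (exclude_self && j == i) continue;
          double ddx = b(j, 0) - x, ddy = b(j, 1) - y;
          if (ddx * ddx + ddy * ddy <= r2) hits.push_back(j + 1);
        }
      }
    }
    out[i] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}

static inline std::vector<std::vector<int> > as_adj(List l) {
  std::vector<std::vector<int> > adj(l.size());
  for (int i = 0; i < l.size(); ++i) {
    IntegerVector v = l[i];
    adj[i].assign(v.begin(), v.end());
    for (size_t k = 0; k < adj[i].size(); ++k) adj[i][k] -= 1;  // 0-based
  }
  return adj;
}

// Cellular-automaton retinal wave on an extended mosaic.
//
// States: ON  0 waiting, 1 active, 2 inactive
//         AC  0 waiting, 1 active
//         OFF 0 waiting, 1 inhibited, 2 active, 3 inactive (Stage III)
//             0 waiting, 2 active, 3 inactive             (Stage II)
// All transitions are synchronous; input at time t determines states at t+1.
// Uses R's RNG (seed with set.seed() on the R side).
// [[Rcpp::export]]
List ca_simulate_cpp(NumericMatrix on_pos,
                     List on_on, List on_ac, List ac_off, List on_off,
                     int n_ac, int n_off,
                     double theta_on, double theta_ac, double theta_off,
                     double delta_c, double waiting_fraction,
                     double r_init, NumericVector init_center,
                     int t_steps, int max_steps, int stage,
                     bool record_states = false) {
  const int n_on = on_pos.nrow();
  std::vector<std::vector<int> > nb_on = as_adj(on_on);
  std::vector<std::vector<int> > nb_ac = as_adj(on_ac);
  std::vector<std::vector<int> > nb_off3 = as_adj(ac_off);
  std::vector<std::vector<int> > nb_off2 = as_adj(on_off);

  std::vector<int> s_on(n_on, 2), t_on(n_on, 0);
  std::vector<int> s_ac(n_ac, 0);
  std::vector<int> s_off(n_off, 3), t_off(n_off, 0);
  std::vector<double> eta(n_on);
  for (int i = 0; i < n_on; ++i) eta[i] = 1.0 + delta_c * R::norm_rand();

  // exact 80/20 split by permutation (Fisher-Yates with R RNG)
  {
    std::vector<int> perm(n_on);
    for (int i = 0; i < n_on; ++i) perm[i] = i;
    for (int i = n_on - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    int n_wait = (int)std::lround(waiting_fraction * n_on);
    for (int i = 0; i < n_wait; ++i) s_on[perm[i]] = 0;
  }
  if (stage == 2) {
    std::vector<int> perm(n_off);
    for (int i = 0; i < n_off; ++i) perm[i] = i;
    for (int i = n_off - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    int n_wait = (int)std::lround(waiting_fraction * n_off);
    for (int i = 0; i < n_wait; ++i) s_off[perm[i]] = 0;
  } else {
    std::fill(s_off.begin(), s_off.end(), 0);
  }

  int n_waiting_on = 0;
  for (int i = 0; i < n_on; ++i) if (s_on[i] == 0) ++n_waiting_on;

  // ignition: waiting ON cells inside the R_init disc become active at t = 0
  const double ri2 = r_init * r_init;
  int n_ignited = 0;
  for (int i = 0; i < n_on; ++i) {
    if (s_on[i] != 0) continue;
    double dx = on_pos(i, 0) - init_center[0], dy = on_pos(i, 1) - init_center[1];
    if (dx * dx + dy * dy <= ri2) { s_on[i] = 1; t_on[i] = t_steps; ++n_ignited; }
  }

  std::vector<double> in_on(n_on), in_ac(n_ac), in_off(n_off);
  List rec_on, rec_off, st_on, st_off, st_ac;
  std::vector<int> tmp;
  bool truncated = false;
  int t = 0;
  while (true) {
    // record states at time t
    tmp.clear();
    for (int i = 0; i < n_on; ++i) if (s_on[i] == 1) tmp.push_back(i + 1);
    rec_on.push_back(IntegerVector(tmp.begin(), tmp.end()));
    tmp.clear();
    for (int j = 0; j < n_off; ++j) if (s_off[j] == 2) tmp.push_back(j + 1);
    rec_off.push_back(IntegerVector(tmp.begin(), tmp.end()));
    if (record_states) {
      st_on.push_back(IntegerVector(s_on.begin(), s_on.end()));
      st_off.push_back(IntegerVector(s_off.begin(), s_off.end()));
      st_ac.push_back(IntegerVector(s_ac.begin(), s_ac.end()));
    }

    bool alive = false;
    for (int i = 0; i < n_on && !alive; ++i) alive = s_on[i] == 1;
    if (!alive) for (int j = 0; j < n_off && !alive; ++j)
      alive = s_off[j] == 2 || (stage == 3 && s_off[j] == 1);
    if (!alive && stage == 3) for (int k = 0; k < n_ac && !alive; ++k) alive = s_ac[k] == 1;
    if (!alive) break;
    if (t >= max_steps) { truncated = true; break; }

    // inputs from states at time t
    std::fill(in_on.begin(), in_on.end(), 0.0);
    std::fill(in_ac.begin(), in_ac.end(), 0.0);
    std::fill(in_off.begin(), in_off.end(), 0.0);
    for (int i = 0; i < n_on; ++i) {
      if (s_on[i] != 1) continue;
      for (int j : nb_on[i]) in_on[j] += eta[i];
      if (stage == 3) { for (int k : nb_ac[i]) in_ac[k] += eta[i]; }
      else           { for (int j : nb_off2[i]) in_off[j] += eta[i]; }
    }
    if (stage == 3) {
      for (int k = 0; k < n_ac; ++k) {
        if (s_ac[k] != 1) continue;
        for (int j : nb_off3[k]) in_off[j] -= 1.0;
      }
    }

    // transitions to t+1
    for (int i = 0; i < n_on; ++i) {
      if (s_on[i] == 1) {
        if (--t_on[i] == 0) s_on[i] = 2;
      } else if (s_on[i] == 0 && in_on[i] > theta_on) {
        s_on[i] = 1; t_on[i] = t_steps;
      }
    }
    if (stage == 3) {
      for (int k = 0; k < n_ac; ++k) s_ac[k] = in_ac[k] > theta_ac ? 1 : 0;
      for (int j = 0; j < n_off; ++j) {
        if (s_off[j] == 2) {
          if (--t_off[j] == 0) s_off[j] = 3;
        } else if (s_off[j] == 0) {
          if (in_off[j] < theta_off) s_off[j] = 1;
        } else if (s_off[j] == 1) {
          if (in_off[j] >= theta_off) { s_off[j] = 2; t_off[j] = t_steps; }
        }
      }
    } else {
      for (int j = 0; j < n_off; ++j) {
        if (s_off[j] == 2) {
          if (--t_off[j] == 0) s_off[j] = 3;
        } else if (s_off[j] == 0 && in_off[j] > theta_on) {
          s_off[j] = 2; t_off[j] = t_steps;
        }
      }
    }
    ++t;
  }

  List out = List::create(
    _["on_active"] = rec_on, _["off_active"] = rec_off,
    _["n_steps"] = (int)rec_on.size(), _["truncated"] = truncated,
    _["n_waiting_on"] = n_waiting_on, _["n_ignited"] = n_ignited);
  if (record_states) {
    out["states_on"] = st_on; out["states_off"] = st_off; out["states_ac"] = st_ac;
  }
  return out;
}
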