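#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Yates shuffle using R's RNG so runs are reproducible under set.seed()
static void shuffle_order(std::vector<int> &ord) {
  const int n = static_cast<int>(ord.size());
  for (int k = n - 1; k > 0; --k) {
    int j = static_cast<int>(unif_rand() * (k + 1));
    if (j > k) j = k; // unif_rand() can in principle return 1.0
    std::swap(ord[k], ord[j]);
  }
}

// Core ABM loop. Agents perform activity-gated correlated random walks on a
// bounded square arena and form directed pairwise interactions.
//
// initiation_rule: 0 = by_activity, 1 = random_half
// direction_rule:  0 = active_outgoing, 1 = random, 2 = relative_activity,
//                  3 = to_active
// boundary_rule:   0 = truncate (the step stops where the path meets the
//                  boundary; an agent pressed against the wall with an
//                  outward heading does not move), 1 = clamp (each
//                  coordinate of the full step is clamped independently,
//                  so agents slide along the wall), 2 = reflect (the step
//                  bounces off the wall and the heading is mirrored)
//
// Returns a list with integer vectors t, signaller, receiver (agent ids are
// 0-based) and, if record_positions, (n_steps+1) x n position matrices whose
// first row is the initial placement.
// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int n_agents, int n_steps, double grid_size, double step_length,
              double radius, NumericVector activity, NumericVector turning,
              int initiation_rule, int direction_rule, int boundary_rule,
              bool record_positions) {
  RNGScope scope;

  std::vector<double> x(n_agents), y(n_agents), heading(n_agents);
  for (int i = 0; i < n_agents; ++i) {
    x[i] = unif_rand() * grid_size;
    y[i] = unif_rand() * grid_size;
    heading[i] = unif_rand() * 360.0;
  }

  NumericMatrix pos_x, pos_y;
  if (record_positions) {
    pos_x = NumericMatrix(n_steps + 1, n_agents);
    pos_y = NumericMatrix(n_steps + 1, n_agents);
    for (int i = 0; i < n_agents; ++i) {
      pos_x(0, i) = x[i];
      pos_y(0, i) = y[i];
    }
  }

  std::vector<int> ev_t, ev_s, ev_r;
  ev_t.reserve(4096); ev_s.reserve(4096); ev_r.reserve(4096);

  std::vector<bool> active(n_agents, false);
  std::vector<int> order(n_agents);
  for (int i = 0; i < n_agents; ++i) order[i] = i;
  std::vector<int> nb;
  nb.reserve(n_agents);

  const double r2 = radius * radius;
  const double deg2rad = M_PI / 180.0;

  for (int t = 1; t <= n_steps; ++t) {
    // one activation draw per agent per step, shared by both phases
    for (int i = 0; i < n_agents; ++i) active[i] = exp_rand() < activity[i];

    // movement phase, fresh random order
    shuffle_order(order);
    for (int k = 0; k < n_agents; ++k) {
      const int i = order[k];
      if (!active[i]) continue;
      double h = heading[i] + norm_rand() * turning[i];
      h -= 360.0 * std::floor(h / 360.0); // wrap to [0, 360)
      heading[i] = h;
      const double dx = step_length * std::cos(h * deg2rad);
      const double dy = step_length * std::sin(h * deg2rad);
      double nx = x[i] + dx, ny = y[i] + dy;
      if (boundary_rule == 2) {
        if (nx < 0)              { nx = -nx; h = 180.0 - h; }
        else if (nx > grid_size) { nx = 2 * grid_size - nx; h = 180.0 - h; }
        if (ny < 0)              { ny = -ny; h = -h; }
        else if (ny > grid_size) { ny = 2 * grid_size - ny; h = -h; }
        h -= 360.0 * std::floor(h / 360.0);
        heading[i] = h;
      } else if (boundary_rule == 0) {
        // truncate: advance along the heading only as far as the first
        // boundary crossing; heading unchanged
        double f = 1.0;
        if (nx < 0)               f = std::min(f, (0 - x[i]) / dx);
        else if (nx > grid_size)  f = std::min(f, (grid_size - x[i]) / dx);
        if (ny < 0)               f = std::min(f, (0 - y[i]) / dy);
        else if (ny > grid_size)  f = std::min(f, (grid_size - y[i]) / dy);
        nx = x[i] + f * dx;
        ny = y[i] + f * dy;
      }
      // guard against rounding; under boundary_rule 1 this IS the rule
      // (independent per-axis clamp, so agents slide along the wall)
      if (nx < 0) nx = 0; else if (nx > grid_size) nx = grid_size;
      if (ny < 0) ny = 0; else if (ny > grid_size) ny = grid_size;
      x[i] = nx;
      y[i] = ny;
    }

    if (record_positions) {
      for (int i = 0; i < n_agents; ++i) {
        pos_x(t, i) = x[i];
        pos_y(t, i) = y[i];
      }
    }

    // interaction phase, fresh random order; positions fixed within the phase
    shuffle_order(order);
    for (int k = 0; k < n_agents; ++k) {
      const int i = order[k];
      if (initiation_rule == 0 && !active[i]) continue;

      nb.clear();
      for (int j = 0; j < n_agents; ++j) {
        if (j == i) continue;
        const double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx * dx + dy * dy <= r2) nb.push_back(j);
      }
      if (nb.empty()) continue;
      if (initiation_rule == 1 && unif_rand() >= 0.5) continue;

      int pick = static_cast<int>(unif_rand() * nb.size());
      if (pick >= static_cast<int>(nb.size())) pick = static_cast<int>(nb.size()) - 1;
      const int j = nb[pick];

      int s = i, r = j;
      switch (direction_rule) {
      case 0: break;                                   // active_outgoing
      case 1:                                          // fair coin
        if (unif_rand() < 0.5) { s = j; r = i; }
        break;
      case 2: {                                        // relative_activity
        const double p = activity[i] / (activity[i] + activity[j]);
        if (unif_rand() >= p) { s = j; r = i; }
        break;
      }
      case 3: s = j; r = i; break;                     // to_active
      }
      ev_t.push_back(t);
      ev_s.push_back(s);
      ev_r.push_back(r);
    }
  }

  List out = List::create(_["t"] = wrap(ev_t),
                          _["signaller"] = wrap(ev_s),
                          _["receiver"] = wrap(ev_r));
  if (record_positions) {
    out["pos_x"] = pos_x;
    out["pos_y"] = pos_y;
  }
  return out;
}

// Time-ordered susceptible-informed diffusion over an event log.
// Events must be sorted by time (and, within a step, in logged order).
// The signaller of the first event is the seed; a naive receiver becomes
// informed the moment it receives from an informed signaller and can relay
// later in the same step. Agent ids are 0-based.
//
// Returns the 0-based seed id, the informed count after each event and a
// flag per event marking whether its signaller was informed at event time.
// [[Rcpp::export(name = ".diffusion_core")]]
List diffusion_core(IntegerVector signaller, IntegerVector receiver, int n_agents) {
  const int m = signaller.size();
  if (m == 0) stop("empty event log");
  std::vector<bool> informed(n_agents, false);
  IntegerVector count_after(m);
  LogicalVector signaller_informed(m);

  const int seed = signaller[0];
  informed[seed] = true;
  int n_informed = 1;

  for (int e = 0; e < m; ++e) {
    const int s = signaller[e], r = receiver[e];
    signaller_informed[e] = informed[s];
    if (informed[s] && !informed[r]) {
      informed[r] = true;
      ++n_informed;
    }
    count_after[e] = n_informed;
  }
  return List::create(_["seed_agent"] = seed,
                      _["count_after"] = count_after,
                      _["signaller_informed"] = signaller_informed);
}
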