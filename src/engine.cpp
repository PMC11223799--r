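// Monte Carlo engine for the coarse-grained RNA model.
//
// The R side compiles a simulation context (bond topology, excluded-volume
// parameters, candidate canonical pairs with their target distances,
// stacking neighbours, slope/well restraints, exclusion marks, reactivity
// profile, frozen mask) into flat vectors; everything here works on a
// beads x 3 coordinate matrix whose rows are residue-major in slot order
// P, C4', Ngly, C2, C46.  All randomness comes from R's RNG so that
// set.seed() fully determines a run.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int N_TERMS = 8; // bond ev pairing stacking slope well excl probing

struct Ctx {
  int nres, nbeads;
  IntegerVector res_chain;
  IntegerVector bond_a, bond_b;
  NumericVector bond_d0, bond_k;
  double ev_radius, ev_k;
  IntegerVector cand_i, cand_j;
  NumericMatrix cand_t;
  double pair_w, pair_scale, guide_w, guide_scale, coop_w, detect_tol;
  IntegerVector stack_i;
  double stack_d, stack_w, stack_scale;
  IntegerVector slope_a, slope_b;
  NumericVector slope_lo, slope_hi, slope_w;
  IntegerVector well_a, well_b;
  NumericVector well_lo, well_hi, well_w;
  LogicalVector excluded;
  double excl_penalty;
  NumericVector react;
  double probe_w;
  LogicalVector frozen;
};

static Ctx unpack(const List& ctx) {
  Ctx c;
  c.nres = as<int>(ctx["nres"]);
  c.nbeads = 5 * c.nres;
  c.res_chain = ctx["res_chain"];
  c.bond_a = ctx["bond_a"]; c.bond_b = ctx["bond_b"];
  c.bond_d0 = ctx["bond_d0"]; c.bond_k = ctx["bond_k"];
  c.ev_radius = as<double>(ctx["ev_radius"]);
  c.ev_k = as<double>(ctx["ev_k"]);
  c.cand_i = ctx["cand_i"]; c.cand_j = ctx["cand_j"];
  c.cand_t = as<NumericMatrix>(ctx["cand_t"]);
  c.pair_w = as<double>(ctx["pair_w"]);
  c.pair_scale = as<double>(ctx["pair_scale"]);
  c.guide_w = as<double>(ctx["guide_w"]);
  c.guide_scale = as<double>(ctx["guide_scale"]);
  c.coop_w = as<double>(ctx["coop_w"]);
  c.detect_tol = as<double>(ctx["detect_tol"]);
  c.stack_i = ctx["stack_i"];
  c.stack_d = as<double>(ctx["stack_d"]);
  c.stack_w = as<double>(ctx["stack_w"]);
  c.stack_scale = as<double>(ctx["stack_scale"]);
  c.slope_a = ctx["slope_a"]; c.slope_b = ctx["slope_b"];
  c.slope_lo = ctx["slope_lo"]; c.slope_hi = ctx["slope_hi"];
  c.slope_w = ctx["slope_w"];
  c.well_a = ctx["well_a"]; c.well_b = ctx["well_b"];
  c.well_lo = ctx["well_lo"]; c.well_hi = ctx["well_hi"];
  c.well_w = ctx["well_w"];
  c.excluded = ctx["excluded"];
  c.excl_penalty = as<double>(ctx["excl_penalty"]);
  c.react = ctx["react"];
  c.probe_w = as<double>(ctx["probe_w"]);
  c.frozen = ctx["frozen"];
  return c;
}

static inline double dist(const double* X, int a, int b, int n) {
  double dx = X[a] - X[b], dy = X[a + n] - X[b + n],
         dz = X[a + 2 * n] - X[b + 2 * n];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

struct Formed { double dev; int i, j, cand; };

// candidate pairs whose three base-bead distances all fall within tol of
// the family targets, then greedy one-partner-per-residue matching by
// total deviation (ties: lower (i, j) first)
static void detect_pairs(const Ctx& c, const double* X,
                         std::vector<int>& match_i, std::vector<int>& match_j,
                         std::vector<int>& flags) {
  int n = c.nbeads;
  std::vector<Formed> formed;
  for (int k = 0; k < c.cand_i.size(); ++k) {
    int ri = c.cand_i[k], rj = c.cand_j[k];
    double dev = 0.0;
    bool ok = true;
    for (int m = 0; m < 3 && ok; ++m) {
      double d = dist(X, 5 * ri + 2 + m, 5 * rj + 2 + m, n);
      double dd = std::fabs(d - c.cand_t(k, m));
      if (dd > c.detect_tol) ok = false;
      dev += dd;
    }
    if (ok) formed.push_back({dev, ri, rj, k});
  }
  std::sort(formed.begin(), formed.end(), [](const Formed& a, const Formed& b) {
    if (a.dev != b.dev) return a.dev < b.dev;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  std::vector<char> used(c.nres, 0);
  flags.assign(c.nres, 1);
  match_i.clear(); match_j.clear();
  for (const Formed& f : formed) {
    if (used[f.i] || used[f.j]) continue;
    used[f.i] = used[f.j] = 1;
    flags[f.i] = flags[f.j] = 0;
    match_i.push_back(f.i);
    match_j.push_back(f.j);
  }
}


// soft quadratic repulsion below ev_radius, skipping beads of the same or
// sequence-adjacent residue
static inline double ev_one(const Ctx& c, const double* X, int a, int b, int n) {
  int ra = a / 5, rb = b / 5;
  if (ra == rb) return 0.0;
  int lo = ra < rb ? ra : rb, hi = ra < rb ? rb : ra;
  if (c.res_chain[lo] == c.res_chain[hi] && hi - lo == 1) return 0.0;
  double r0 = c.ev_radius;
  double dx = X[a] - X[b];
  if (dx > r0 || dx < -r0) return 0.0;
  double dy = X[a + n] - X[b + n];
  if (dy > r0 || dy < -r0) return 0.0;
  double dz = X[a + 2 * n] - X[b + 2 * n];
  if (dz > r0 || dz < -r0) return 0.0;
  double d2 = dx * dx + dy * dy + dz * dz;
  if (d2 >= r0 * r0) return 0.0;
  double d = r0 - std::sqrt(d2);
  return c.ev_k * d * d;
}

static double ev_full(const Ctx& c, const double* X) {
  int n = c.nbeads;
  double e = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      e += ev_one(c, X, a, b, n);
  return e;
}

// excluded-volume energy of all pairs touching the bead range [b_lo, b_hi]
static double ev_partial(const Ctx& c, const double* X, int b_lo, int b_hi) {
  int n = c.nbeads;
  double e = 0.0;
  for (int a = b_lo; a <= b_hi; ++a) {
    for (int b = 0; b < b_lo; ++b) e += ev_one(c, X, a, b, n);
    for (int b = b_hi + 1; b < n; ++b) e += ev_one(c, X, a, b, n);
    for (int b = a + 1; b <= b_hi; ++b) e += ev_one(c, X, a, b, n);
  }
  return e;
}

static void energy_terms_no_ev(const Ctx& c, const double* X, double* terms);

static void energy_terms(const Ctx& c, const double* X, double* terms) {
  energy_terms_no_ev(c, X, terms);
  terms[1] = ev_full(c, X);
}

static void energy_terms_no_ev(const Ctx& c, const double* X, double* terms) {
  int n = c.nbeads;
  for (int t = 0; t < N_TERMS; ++t) terms[t] = 0.0;
  // bonds
  for (int k = 0; k < c.bond_a.size(); ++k) {
    double d = dist(X, c.bond_a[k], c.bond_b[k], n) - c.bond_d0[k];
    terms[0] += c.bond_k[k] * d * d;
  }
  // pairing attraction: a sharp Gaussian well at the canonical cWW
  // geometry (on the summed deviation of the three base-bead distances),
  // scored over a greedy one-partner-per-residue matching so that a residue
  // cannot collect pairing energy from several partners at once, plus a
  // weak long-range guidance pull between complementary bases
  {
    static std::vector<Formed> cands;
    cands.clear();
    cands.reserve(c.cand_i.size());
    for (int k = 0; k < c.cand_i.size(); ++k) {
      int ri = c.cand_i[k], rj = c.cand_j[k];
      double dev = 0.0;
      for (int m = 0; m < 3; ++m)
        dev += std::fabs(dist(X, 5 * ri + 2 + m, 5 * rj + 2 + m, n) - c.cand_t(k, m));
      cands.push_back({dev, ri, rj, k});
      if (c.guide_w > 0) {
        double g = dist(X, 5 * ri + 2, 5 * rj + 2, n) / c.guide_scale;
        terms[2] += -c.guide_w / (1.0 + g * g);
      }
    }
    std::sort(cands.begin(), cands.end(), [](const Formed& a, const Formed& b) {
      if (a.dev != b.dev) return a.dev < b.dev;
      if (a.i != b.i) return a.i < b.i;
      return a.j < b.j;
    });
    static std::vector<char> used;
    static std::vector<int> partner;
    used.assign(c.nres, 0);
    partner.assign(c.nres, -1);
    for (const Formed& f : cands) {
      if (used[f.i] || used[f.j]) continue;
      double r = f.dev / c.pair_scale;
      double e = -c.pair_w * std::exp(-r * r);
      if (e < -1e-8) { // negligible wells do not block better partners
        used[f.i] = used[f.j] = 1;
        partner[f.i] = f.j; partner[f.j] = f.i;
        terms[2] += e;
      }
    }
    // helix cooperativity: bonus when adjacent rungs (i,j) and (i+1,j-1)
    // are both matched (the zipper term that favours contiguous stems)
    if (c.coop_w > 0) {
      for (int i = 0; i + 1 < c.nres; ++i) {
        int j = partner[i];
        if (j > i + 1 && partner[i + 1] == j - 1 &&
            c.res_chain[i] == c.res_chain[i + 1] &&
            c.res_chain[j - 1] == c.res_chain[j])
          terms[2] += -c.coop_w;
      }
    }
  }
  // stacking: attraction between consecutive glycosidic beads
  for (int k = 0; k < c.stack_i.size(); ++k) {
    int ri = c.stack_i[k];
    double d = dist(X, 5 * ri + 2, 5 * (ri + 1) + 2, n);
    double r = (d - c.stack_d) / c.stack_scale;
    terms[3] += -c.stack_w / (1.0 + r * r);
  }
  // slope restraints
  for (int k = 0; k < c.slope_a.size(); ++k) {
    double d = dist(X, c.slope_a[k], c.slope_b[k], n);
    if (d > c.slope_hi[k]) terms[4] += c.slope_w[k] * (d - c.slope_hi[k]);
    else if (d < c.slope_lo[k]) terms[4] += c.slope_w[k] * (c.slope_lo[k] - d);
  }
  // well restraints
  for (int k = 0; k < c.well_a.size(); ++k) {
    double d = dist(X, c.well_a[k], c.well_b[k], n);
    if (d >= c.well_lo[k] && d <= c.well_hi[k]) terms[5] += -c.well_w[k];
  }
  // exclusion penalties and probing score need the matched pairing state
  bool need_excl = false;
  if (c.excl_penalty != 0.0)
    for (int r = 0; r < c.nres; ++r) if (c.excluded[r]) { need_excl = true; break; }
  bool need_probe = c.probe_w != 0.0 && c.react.size() == c.nres;
  if (need_excl || need_probe) {
    std::vector<int> mi, mj, flags;
    detect_pairs(c, X, mi, mj, flags);
    if (need_excl) {
      for (size_t k = 0; k < mi.size(); ++k)
        if (c.excluded[mi[k]] || c.excluded[mj[k]])
          terms[6] += c.excl_penalty;
    }
    if (need_probe) {
      double s = 0.0;
      for (int r = 0; r < c.nres; ++r) {
        double v = c.react[r];
        if (!ISNAN(v)) {
          double e = flags[r] - v;
          s += e * e;
        }
      }
      terms[7] = c.probe_w * s;
    }
  }
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix coords, List ctx) {
  Ctx c = unpack(ctx);
  std::vector<double> terms(N_TERMS);
  energy_terms(c, REAL(coords), terms.data());
  double total = 0.0;
  for (double t : terms) total += t;
  NumericVector tv(terms.begin(), terms.end());
  tv.names() = CharacterVector::create("bond", "ev", "pairing", "stacking",
                                       "slope", "well", "exclusion", "probing");
  return List::create(_["total"] = total, _["terms"] = tv);
}

// [[Rcpp::export]]
List cpp_detect(NumericMatrix coords, List ctx) {
  Ctx c = unpack(ctx);
  std::vector<int> mi, mj, flags;
  detect_pairs(c, REAL(coords), mi, mj, flags);
  return List::create(_["i"] = wrap(mi), _["j"] = wrap(mj),
                      _["flags"] = wrap(flags));
}

// --- moves -----------------------------------------------------------------

// move record: kind (0 jitter, 1 shift, 2 pivot), ok flag, and the
// parameters needed to apply or invert the move
struct Move {
  int kind = 0;
  bool ok = false;
  int bead = -1, res = -1, pivot_bead = -1, lo = 0, hi = -1;
  double disp[3] = {0, 0, 0}, axis[3] = {1, 0, 0}, angle = 0;
};

static Move draw_move(const Ctx& c, const double* weights, const double* sigmas) {
  Move mv;
  int n_unfrozen = 0;
  for (int r = 0; r < c.nres; ++r) if (!c.frozen[r]) ++n_unfrozen;
  if (n_unfrozen == 0) stop("all residues are frozen");
  auto pick_unfrozen = [&]() {
    int t = (int)(unif_rand() * n_unfrozen) % n_unfrozen;
    for (int r = 0; r < c.nres; ++r)
      if (!c.frozen[r] && t-- == 0) return r;
    return c.nres - 1;
  };
  double wtot = weights[0] + weights[1] + weights[2];
  double u = unif_rand() * wtot;
  mv.kind = u < weights[0] ? 0 : (u < weights[0] + weights[1] ? 1 : 2);
  if (mv.kind == 0) {
    mv.res = pick_unfrozen();
    mv.bead = 5 * mv.res + (int)(unif_rand() * 5) % 5;
    for (int d = 0; d < 3; ++d) mv.disp[d] = norm_rand() * sigmas[0];
    mv.ok = true;
    return mv;
  }
  if (mv.kind == 1) {
    mv.res = pick_unfrozen();
    for (int d = 0; d < 3; ++d) mv.disp[d] = norm_rand() * sigmas[1];
    mv.ok = true;
    return mv;
  }
  // pivot: rotate the chain segment on one side of a backbone bead; since
  // the energy is invariant to rigid motion, rotating the shorter side is
  // equivalent to rotating the longer one and much cheaper to evaluate
  mv.res = (int)(unif_rand() * c.nres) % c.nres;
  mv.pivot_bead = 5 * mv.res + ((unif_rand() < 0.5) ? 0 : 1); // P or C4'
  double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
  double an = std::sqrt(ax * ax + ay * ay + az * az);
  if (an < 1e-12) { ax = 1; ay = 0; az = 0; an = 1; }
  mv.axis[0] = ax / an; mv.axis[1] = ay / an; mv.axis[2] = az / an;
  mv.angle = norm_rand() * sigmas[2];
  int chain = c.res_chain[mv.res];
  int up_hi = mv.res, dn_lo = mv.res;
  while (up_hi + 1 < c.nres && c.res_chain[up_hi + 1] == chain) ++up_hi;
  while (dn_lo - 1 >= 0 && c.res_chain[dn_lo - 1] == chain) --dn_lo;
  if (up_hi - mv.res <= mv.res - dn_lo) {
    mv.lo = mv.res + 1; mv.hi = up_hi;
  } else {
    mv.lo = dn_lo; mv.hi = mv.res - 1;
  }
  mv.ok = mv.lo <= mv.hi;
  if (mv.ok)
    for (int q = mv.lo; q <= mv.hi; ++q)
      if (c.frozen[q]) { mv.ok = false; break; }
  return mv;
}

static void apply_move(double* X, int n, const Move& mv, bool inverse) {
  if (!mv.ok) return;
  if (mv.kind == 0 || mv.kind == 1) {
    double s = inverse ? -1.0 : 1.0;
    int b0 = mv.kind == 0 ? mv.bead : 5 * mv.res;
    int b1 = mv.kind == 0 ? mv.bead : 5 * mv.res + 4;
    for (int b = b0; b <= b1; ++b) {
      X[b] += s * mv.disp[0];
      X[b + n] += s * mv.disp[1];
      X[b + 2 * n] += s * mv.disp[2];
    }
    return;
  }
  double angle = inverse ? -mv.angle : mv.angle;
  int pb = mv.pivot_bead;
  double px = X[pb], py = X[pb + n], pz = X[pb + 2 * n];
  double ca = std::cos(angle), sa = std::sin(angle);
  double ux = mv.axis[0], uy = mv.axis[1], uz = mv.axis[2];
  for (int q = mv.lo; q <= mv.hi; ++q) {
    for (int b = 5 * q; b < 5 * q + 5; ++b) {
      double x = X[b] - px, y = X[b + n] - py, z = X[b + 2 * n] - pz;
      double dot = ux * x + uy * y + uz * z;
      double cx = uy * z - uz * y, cy = uz * x - ux * z, cz = ux * y - uy * x;
      X[b] = px + x * ca + cx * sa + ux * dot * (1 - ca);
      X[b + n] = py + y * ca + cy * sa + uy * dot * (1 - ca);
      X[b + 2 * n] = pz + z * ca + cz * sa + uz * dot * (1 - ca);
    }
  }
}

static List move_to_list(const Move& mv) {
  return List::create(_["kind"] = mv.kind, _["ok"] = mv.ok,
                      _["bead"] = mv.bead, _["res"] = mv.res,
                      _["pivot_bead"] = mv.pivot_bead,
                      _["res_lo"] = mv.lo, _["res_hi"] = mv.hi,
                      _["disp"] = NumericVector::create(mv.disp[0], mv.disp[1], mv.disp[2]),
                      _["axis"] = NumericVector::create(mv.axis[0], mv.axis[1], mv.axis[2]),
                      _["angle"] = mv.angle);
}

static Move move_from_list(const List& rec) {
  Move mv;
  mv.kind = as<int>(rec["kind"]);
  mv.ok = as<bool>(rec["ok"]);
  mv.bead = as<int>(rec["bead"]);
  mv.res = as<int>(rec["res"]);
  mv.pivot_bead = as<int>(rec["pivot_bead"]);
  mv.lo = as<int>(rec["res_lo"]);
  mv.hi = as<int>(rec["res_hi"]);
  NumericVector disp = rec["disp"], axis = rec["axis"];
  for (int d = 0; d < 3; ++d) { mv.disp[d] = disp[d]; mv.axis[d] = axis[d]; }
  mv.angle = as<double>(rec["angle"]);
  return mv;
}

// [[Rcpp::export]]
List cpp_draw_move(List ctx, NumericVector weights, NumericVector sigmas,
                   NumericMatrix coords) {
  Ctx c = unpack(ctx);
  RNGScope scope;
  return move_to_list(draw_move(c, REAL(weights), REAL(sigmas)));
}

// [[Rcpp::export]]
NumericMatrix cpp_apply_move(NumericMatrix coords, List rec, bool inverse) {
  NumericMatrix out = clone(coords);
  apply_move(REAL(out), out.nrow(), move_from_list(rec), inverse);
  return out;
}

// --- Monte Carlo loop ------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix coords, List ctx, List cfg) {
  Ctx c = unpack(ctx);
  int n = c.nbeads;
  if (coords.nrow() != n) stop("coordinate rows do not match the context");
  int n_steps = as<int>(cfg["n_steps"]);
  int frame_every = as<int>(cfg["frame_every"]);
  NumericVector tvec = cfg["tvec"];
  NumericVector weights = cfg["move_weights"];
  NumericVector sigmas = cfg["move_sigmas"];
  bool record_initial = as<bool>(cfg["record_initial"]);
  int step0 = as<int>(cfg["step_offset"]); // for chunked (replica) runs
  if (tvec.size() != n_steps) stop("temperature vector length != n_steps");

  NumericMatrix X = clone(coords);
  double* px = REAL(X);
  std::vector<double> terms(N_TERMS), new_terms(N_TERMS);
  energy_terms(c, px, terms.data());
  double e_cur = 0.0;
  for (double t : terms) e_cur += t;

  int n_frames = n_steps / frame_every + (record_initial ? 1 : 0);
  NumericMatrix fr_xyz(n_frames, 3 * n);
  NumericMatrix fr_terms(n_frames, N_TERMS);
  IntegerVector fr_step(n_frames);
  NumericVector fr_temp(n_frames);
  int fi = 0;
  std::vector<double> saved; // coordinate backup of the affected bead range

  RNGScope scope;
  auto record = [&](int step, double temp) {
    for (int b = 0; b < n; ++b) {
      fr_xyz(fi, 3 * b) = px[b];
      fr_xyz(fi, 3 * b + 1) = px[b + n];
      fr_xyz(fi, 3 * b + 2) = px[b + 2 * n];
    }
    for (int t = 0; t < N_TERMS; ++t) fr_terms(fi, t) = terms[t];
    fr_step[fi] = step;
    fr_temp[fi] = temp;
    ++fi;
  };
  if (record_initial) record(step0, tvec.size() ? tvec[0] : 1.0);

  long accepted = 0;
  for (int step = 1; step <= n_steps; ++step) {
    double T = tvec[step - 1];
    Move rec = draw_move(c, REAL(weights), REAL(sigmas));
    if (rec.ok) {
      // back up affected beads, apply, evaluate, accept/reject
      int b_lo, b_hi;
      if (rec.kind == 0) { b_lo = b_hi = rec.bead; }
      else if (rec.kind == 1) { b_lo = 5 * rec.res; b_hi = 5 * rec.res + 4; }
      else { b_lo = 5 * rec.lo; b_hi = 5 * rec.hi + 4; }
      int span = b_hi - b_lo + 1;
      saved.resize(3 * span);
      for (int b = 0; b < span; ++b) {
        saved[3 * b] = px[b_lo + b];
        saved[3 * b + 1] = px[b_lo + b + n];
        saved[3 * b + 2] = px[b_lo + b + 2 * n];
      }
      double ev_before = ev_partial(c, px, b_lo, b_hi);
      apply_move(px, n, rec, false);
      // delta update for the O(n^2) excluded-volume term; everything else
      // is cheap and recomputed in full
      energy_terms_no_ev(c, px, new_terms.data());
      new_terms[1] = terms[1] + ev_partial(c, px, b_lo, b_hi) - ev_before;
      double e_new = 0.0;
      for (double t : new_terms) e_new += t;
      double dE = e_new - e_cur;
      bool acc = dE <= 0.0 || unif_rand() < std::exp(-dE / T);
      if (acc) {
        e_cur = e_new;
        terms = new_terms;
        ++accepted;
      } else {
        for (int b = 0; b < span; ++b) {
          px[b_lo + b] = saved[3 * b];
          px[b_lo + b + n] = saved[3 * b + 1];
          px[b_lo + b + 2 * n] = saved[3 * b + 2];
        }
      }
    }
    if (!std::isfinite(e_cur))
      stop("energy overflow at step %d", step0 + step);
    if (step % frame_every == 0) {
      energy_terms(c, px, terms.data()); // resync the delta-tracked EV term
      e_cur = 0.0;
      for (double t : terms) e_cur += t;
      record(step0 + step, T);
    }
  }
  NumericVector final_terms(terms.begin(), terms.end());
  final_terms.names() = CharacterVector::create(
    "bond", "ev", "pairing", "stacking", "slope", "well", "exclusion", "probing");
  return List::create(_["frames"] = fr_xyz, _["terms"] = fr_terms,
                      _["steps"] = fr_step, _["temps"] = fr_temp,
                      _["accepted"] = (double)accepted,
                      _["attempted"] = (double)n_steps,
                      _["coords"] = X, _["energy"] = e_cur,
                      _["final_terms"] = final_terms);
}
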