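// Core lattice + event engine for enzymatic cellulose hydrolysis.
//
// The substrate is a 2-D grid of glucose units (n_chains x dp).  Chains run
// left (nonreducing end, column 0) to right (reducing end, column dp-1),
// the cellulose I-beta orientation.  Intra-chain glycosidic bonds are indexed
// by their left unit; inter-chain hydrogen bonds by (chain pair, column),
// one effective bond per vertically adjacent unit pair.
//
// Enzyme particles are explicit agents.  Endo-cellulases adsorb onto a
// 9-column footprint, sequentially break the hydrogen bonds between their
// covered core units, hydrolyze the central glycosidic bond and desorb.
// Exo-cellulases bind free chain ends and run a processive cleave-and-slide
// cycle releasing cellobiose.  All waiting times are exponential (Gillespie
// direct method); every draw comes from R's RNG so a set.seed() on the R side
// makes a run fully reproducible.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <cstdint>
#include <climits>
#include <algorithm>

using namespace Rcpp;

static const double NA_CONST = 6.02214076e23;  // Avogadro, mol^-1

enum Kind { K_ENDO = 0, K_EXOR = 1, K_EXON = 2 };
enum Stage { S_FREE = 0, S_BREAKING, S_READY, S_POSTCLEAVE, S_FASTDESORB, S_CYCLING };
enum Act { A_NONE = 0, A_BREAK_HB, A_CLEAVE, A_DESORB, A_DESORB_FAST, A_STEP, A_RECYCLE };

static const int PSEUDO_OWNER = 1000000;  // fixture marks, not a real agent

struct Species {
  int kind;
  double kon, koff, kofffast, kgly, khb;  // rates, s^-1 except kon (s M)^-1
  double tmove, tstay, thb, alpha;        // exo cycle parameters
  double mw;
  int count;
};

struct Agent {
  int sp = 0;
  bool bound = false;
  int chain = -1;
  int core = -1;     // endo: first column of the 4-unit catalytic core
  int endcol = -1;   // exo: current processed-end column
  int stage = S_FREE;
  std::vector<int> covered, locked;  // flat unit indices
  double ev_time = R_PosInf;
  int ev_act = A_NONE;
};

struct Anchor {
  int chain, col, core;
  bool truncated;
};

struct Counters {
  long long adsorb = 0, desorb = 0, fastdesorb = 0, cleave = 0,
            ready_desorb = 0, hb_breaks = 0, steps = 0, waits = 0,
            alpha_desorb = 0, spatial_desorb = 0, events = 0;
};

// exponential waiting time with given rate
static double rexp_rate(double rate) {
  double u = unif_rand();
  while (u <= 0.0) u = unif_rand();
  return -std::log(u) / rate;
}

static int runif_int(int n) {  // uniform on 0..n-1
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

class Sim {
public:
  int nc = 0, dp = 0;
  std::vector<uint8_t> soluble;   // nc*dp
  std::vector<uint8_t> end2;      // 0 none, 1 NE, 2 RE
  std::vector<int> covered_by;    // agent id or -1
  std::vector<int> locked_by;
  std::vector<uint8_t> gly;       // nc*(dp-1), 1 = intact
  std::vector<uint8_t> hb;        // (nc-1)*dp, 1 = intact
  long long n_soluble = 0;
  long long g1 = 0, g2 = 0, g3 = 0;

  std::vector<Species> sp;
  std::vector<Agent> agents;
  std::vector<double> ads_time;           // per species
  std::vector<long> site_count;           // cached
  std::vector<std::vector<Anchor> > site_list;  // cached
  std::vector<int> n_free;
  int dirty_since = 0;
  bool dirty = true;
  bool hooked = false;     // species attached
  double t = 0.0;
  double d_m = 1e-6, ag2 = 5.512e-19;
  double vol_L = 0.0;
  Counters ctr;
  std::vector<double> fp;  // first-passage times to k% conversion, k = 0..100
  std::vector<int> last_released;  // oligomer lengths from the last applied event

  // ---- indexing -------------------------------------------------------
  inline int iu(int c, int j) const { return c * dp + j; }
  inline int ig(int c, int b) const { return c * (dp - 1) + b; }
  inline int ih(int p, int j) const { return p * dp + j; }
  inline bool blocked(int c, int j) const {
    int u = iu(c, j);
    return covered_by[u] >= 0 || locked_by[u] >= 0;
  }

  long long n_units() const { return (long long)nc * dp; }
  double conversion() const { return (double)n_soluble / (double)n_units(); }

  void touch_fp() {
    int k = (int)std::floor(conversion() * 100.0 + 1e-12);
    if (k > 100) k = 100;
    for (int i = 0; i <= k; ++i)
      if (!R_FINITE(fp[i])) fp[i] = t;
  }

  // ---- construction ---------------------------------------------------
  void init(int nchains, int dpoly) {
    nc = nchains; dp = dpoly;
    soluble.assign((size_t)nc * dp, 0);
    end2.assign((size_t)nc * dp, 0);
    covered_by.assign((size_t)nc * dp, -1);
    locked_by.assign((size_t)nc * dp, -1);
    gly.assign((size_t)nc * (dp > 1 ? dp - 1 : 0), 1);
    hb.assign((size_t)(nc > 1 ? nc - 1 : 0) * dp, 1);
    for (int c = 0; c < nc; ++c) {
      end2[iu(c, 0)] = 1;
      end2[iu(c, dp - 1)] = 2;
    }
    if (dp == 1) for (int c = 0; c < nc; ++c) end2[iu(c, 0)] = 2;
    fp.assign(101, R_NaReal);
    fp[0] = 0.0;
  }

  // pre-cleave a deterministic number of bonds, then apply the
  // short-fragment solubilization rule once over the whole sheet
  void precleave(double fraction) {
    long long nb = (long long)(nc) * (dp - 1);
    long long ncut = (long long)std::floor(fraction * nb + 0.5);
    if (ncut <= 0) return;
    std::vector<long long> ids(nb);
    for (long long i = 0; i < nb; ++i) ids[i] = i;
    for (long long i = 0; i < ncut; ++i) {  // partial Fisher-Yates
      long long j = i + (long long)std::floor(unif_rand() * (nb - i));
      if (j >= nb) j = nb - 1;
      std::swap(ids[i], ids[j]);
      int c = (int)(ids[i] / (dp - 1)), b = (int)(ids[i] % (dp - 1));
      gly[ig(c, b)] = 0;
      end2[iu(c, b)] = 2;
      end2[iu(c, b + 1)] = 1;
    }
    for (int c = 0; c < nc; ++c) {  // dissolve fragments shorter than 4
      int j = 0;
      while (j < dp) {
        int a = j;
        while (j + 1 < dp && gly[ig(c, j)]) ++j;
        int len = j - a + 1;
        if (len < 4) dissolve_run(c, a, j);
        ++j;
      }
    }
    dirty = true;
  }

  // ---- substrate mutation ---------------------------------------------
  void notify_strip(int u) {
    int id = covered_by[u];
    if (id >= 0 && id < (int)agents.size()) {
      Agent &a = agents[id];
      a.covered.erase(std::remove(a.covered.begin(), a.covered.end(), u), a.covered.end());
    }
    covered_by[u] = -1;
    id = locked_by[u];
    if (id >= 0 && id < (int)agents.size()) {
      Agent &a = agents[id];
      a.locked.erase(std::remove(a.locked.begin(), a.locked.end(), u), a.locked.end());
    }
    locked_by[u] = -1;
  }

  void dissolve_run(int c, int a, int b) {  // inclusive columns, length < 4
    int len = b - a + 1;
    for (int j = a; j <= b; ++j) {
      int u = iu(c, j);
      soluble[u] = 1;
      end2[u] = 0;
      notify_strip(u);
      if (c > 0) hb[ih(c - 1, j)] = 0;
      if (c < nc - 1) hb[ih(c, j)] = 0;
    }
    for (int j = a; j < b; ++j) gly[ig(c, j)] = 0;
    n_soluble += len;
    if (len == 1) ++g1; else if (len == 2) ++g2; else ++g3;
    last_released.push_back(len);
    dirty = true;
  }

  // cleave an intact bond; apply the fragment rule on both sides
  void cleave_bond(int c, int b) {
    gly[ig(c, b)] = 0;
    end2[iu(c, b)] = 2;
    end2[iu(c, b + 1)] = 1;
    // left side: walk from column b toward the NE
    int lo = b;
    int n = 1;
    while (lo > 0 && gly[ig(c, lo - 1)] && n < 4) { --lo; ++n; }
    if (n < 4) dissolve_run(c, lo, b);
    // right side
    int hi = b + 1;
    n = 1;
    while (hi < dp - 1 && gly[ig(c, hi)] && n < 4) { ++hi; ++n; }
    if (n < 4) dissolve_run(c, b + 1, hi);
    dirty = true;
  }

  // ---- site enumeration -----------------------------------------------
  inline int blk3(int c, int j) const {
    int s = blocked(c, j) ? 1 : 0;
    if (c > 0 && blocked(c - 1, j)) ++s;
    if (c < nc - 1 && blocked(c + 1, j)) ++s;
    return s;
  }

  long count_endo(std::vector<Anchor> *out) const {
    long n = 0;
    for (int c = 0; c < nc; ++c) {
      if (dp >= 9) {
        int winSol = 0, coreBlk = 0;
        for (int j = 0; j < 9; ++j) winSol += soluble[iu(c, j)];
        for (int j = 3; j < 7; ++j) coreBlk += blk3(c, j);
        for (int j = 0;; ++j) {
          if (winSol == 0 && coreBlk == 0) {
            ++n;
            if (out) out->push_back(Anchor{c, j, j + 3, false});
          }
          if (j == dp - 9) break;
          winSol += soluble[iu(c, j + 9)] - soluble[iu(c, j)];
          coreBlk += blk3(c, j + 7) - blk3(c, j + 3);
        }
      }
      // truncated anchors: connected fragments of length 4..8
      int j = 0;
      while (j < dp) {
        if (soluble[iu(c, j)]) { ++j; continue; }
        int a = j;
        while (j + 1 < dp && gly[ig(c, j)] && !soluble[iu(c, j + 1)]) ++j;
        int len = j - a + 1;
        if (len >= 4 && len <= 8) {
          int core = a + (len - 4) / 2;
          bool ok = true;
          for (int m = core; m < core + 4 && ok; ++m)
            if (blk3(c, m) > 0) ok = false;
          if (ok) {
            ++n;
            if (out) out->push_back(Anchor{c, a, core, true});
          }
        }
        ++j;
      }
    }
    return n;
  }

  bool endo_anchor_valid(const Anchor &an) const {
    int c = an.chain;
    if (c < 0 || c >= nc) return false;
    if (!an.truncated) {
      int j = an.col;
      if (j < 0 || j > dp - 9) return false;
      for (int m = j; m < j + 9; ++m)
        if (soluble[iu(c, m)]) return false;
      for (int m = j + 3; m < j + 7; ++m)
        if (blk3(c, m) > 0) return false;
      return true;
    }
    int a = an.col;
    if (a < 0 || a >= dp || soluble[iu(c, a)]) return false;
    if (a > 0 && gly[ig(c, a - 1)] && !soluble[iu(c, a - 1)]) return false;  // not a fragment start
    int b = a;
    while (b + 1 < dp && gly[ig(c, b)] && !soluble[iu(c, b + 1)] && b - a < 9) ++b;
    int len = b - a + 1;
    if (len < 4 || len > 8) return false;
    int core = a + (len - 4) / 2;
    for (int m = core; m < core + 4; ++m)
      if (blk3(c, m) > 0) return false;
    return true;
  }

  long count_exo(int kind, std::vector<Anchor> *out) const {
    long n = 0;
    int want = (kind == K_EXOR) ? 2 : 1;
    for (int c = 0; c < nc; ++c)
      for (int e = 0; e < dp; ++e) {
        int u = iu(c, e);
        if (soluble[u] || end2[u] != want) continue;
        Anchor an{c, e, 0, false};
        if (exo_anchor_valid(an, kind)) {
          ++n;
          if (out) out->push_back(an);
        }
      }
    return n;
  }

  bool exo_anchor_valid(const Anchor &an, int kind) const {
    int c = an.chain, e = an.col;
    int want = (kind == K_EXOR) ? 2 : 1;
    int dir = (kind == K_EXOR) ? -1 : +1;
    if (c < 0 || c >= nc || e < 0 || e >= dp) return false;
    int u = iu(c, e);
    if (soluble[u] || end2[u] != want) return false;
    int inner = e + 8 * dir;     // far end of the 9-unit window
    if (inner < 0 || inner >= dp) return false;
    int lo = std::min(e, inner), hi = std::max(e, inner);
    for (int m = lo; m <= hi; ++m)
      if (soluble[iu(c, m)]) return false;
    for (int b = lo; b < hi; ++b)
      if (!gly[ig(c, b)]) return false;
    for (int m = lo; m <= hi; ++m)
      if (blk3(c, m) > 0) return false;
    return true;
  }

  // ---- species / agents ----------------------------------------------
  void attach(const std::vector<Species> &species, double d, double a_g2) {
    sp = species;
    d_m = d; ag2 = a_g2;
    vol_L = ((double)n_units() / 2.0) * ag2 * d_m * 1000.0;
    agents.clear();
    for (size_t s = 0; s < sp.size(); ++s)
      for (int i = 0; i < sp[s].count; ++i) {
        Agent a; a.sp = (int)s; agents.push_back(a);
      }
    n_free.assign(sp.size(), 0);
    for (size_t s = 0; s < sp.size(); ++s) n_free[s] = sp[s].count;
    ads_time.assign(sp.size(), R_PosInf);
    site_count.assign(sp.size(), 0);
    site_list.assign(sp.size(), std::vector<Anchor>());
    dirty = true;
    hooked = true;
    refresh_sites();
    reschedule_ads();
  }

  void refresh_sites() {
    for (size_t s = 0; s < sp.size(); ++s) {
      site_list[s].clear();
      if (sp[s].kind == K_ENDO) site_count[s] = count_endo(&site_list[s]);
      else site_count[s] = count_exo(sp[s].kind, &site_list[s]);
    }
    dirty = false;
    dirty_since = 0;
  }

  void maybe_refresh() {
    if (!dirty) return;
    ++dirty_since;
    if (agents.empty()) { refresh_sites(); return; }
    long mn = LONG_MAX;
    for (size_t s = 0; s < sp.size(); ++s)
      if (sp[s].count > 0) mn = std::min(mn, site_count[s]);
    int thr = (mn < 256) ? 8 : 64;
    if (dirty_since >= thr) refresh_sites();
  }

  double propensity(int s) const {
    if (n_free[s] <= 0 || site_count[s] <= 0 || vol_L <= 0) return 0.0;
    return sp[s].kon * (double)n_free[s] * (double)site_count[s] / (NA_CONST * vol_L);
  }

  void reschedule_ads() {
    for (size_t s = 0; s < sp.size(); ++s) {
      double a = propensity((int)s);
      ads_time[s] = (a > 0.0) ? t + rexp_rate(a) : R_PosInf;
    }
  }

  int find_free(int s) const {
    for (size_t i = 0; i < agents.size(); ++i)
      if (agents[i].sp == s && !agents[i].bound) return (int)i;
    return -1;
  }

  // ---- endo behaviour --------------------------------------------------
  void collect_core_hbs(const Agent &a, std::vector<std::pair<int,int> > &out) const {
    out.clear();
    int c = a.chain;
    int id = (int)(&a - &agents[0]);
    for (int m = a.core; m < a.core + 4; ++m) {
      if (c > 0 && hb[ih(c - 1, m)] &&
          covered_by[iu(c - 1, m)] == id && covered_by[iu(c, m)] == id)
        out.push_back(std::make_pair(c - 1, m));
      if (c < nc - 1 && hb[ih(c, m)] &&
          covered_by[iu(c, m)] == id && covered_by[iu(c + 1, m)] == id)
        out.push_back(std::make_pair(c, m));
    }
  }

  bool cat_bond_intact(const Agent &a) const {
    int b = a.core + 1;
    if (b < 0 || b >= dp - 1) return false;
    return gly[ig(a.chain, b)] &&
           !soluble[iu(a.chain, b)] && !soluble[iu(a.chain, b + 1)];
  }

  void schedule_race(Agent &a, double r_act, int act) {
    const Species &s = sp[a.sp];
    double tot = r_act + s.koff;
    double dt = rexp_rate(tot);
    int chosen = (unif_rand() < r_act / tot) ? act : A_DESORB;
    a.ev_time = t + dt;
    a.ev_act = chosen;
  }

  void endo_adsorb(int id, const Anchor &an) {
    Agent &a = agents[id];
    a.bound = true;
    a.chain = an.chain;
    a.core = an.core;
    a.endcol = -1;
    a.covered.clear(); a.locked.clear();
    for (int cc = std::max(0, an.chain - 1); cc <= std::min(nc - 1, an.chain + 1); ++cc)
      for (int m = an.core; m < an.core + 4; ++m) {
        int u = iu(cc, m);
        if (!soluble[u] && covered_by[u] < 0) {
          covered_by[u] = id;
          a.covered.push_back(u);
        }
      }
    --n_free[a.sp];
    ++ctr.adsorb;
    dirty = true;
    std::vector<std::pair<int,int> > hbs;
    if (!cat_bond_intact(a)) {
      a.stage = S_FASTDESORB;
      a.ev_time = t + rexp_rate(sp[a.sp].kofffast);
      a.ev_act = A_DESORB_FAST;
      return;
    }
    collect_core_hbs(a, hbs);
    if (!hbs.empty()) {
      a.stage = S_BREAKING;
      schedule_race(a, sp[a.sp].khb, A_BREAK_HB);
    } else {
      a.stage = S_READY;
      schedule_race(a, sp[a.sp].kgly, A_CLEAVE);
    }
  }

  void fire_endo(int id) {
    Agent &a = agents[id];
    const Species &s = sp[a.sp];
    std::vector<std::pair<int,int> > hbs;
    switch (a.ev_act) {
    case A_BREAK_HB:
      if (!cat_bond_intact(a)) {  // substrate dissolved under the footprint
        a.stage = S_FASTDESORB;
        a.ev_time = t + rexp_rate(s.kofffast);
        a.ev_act = A_DESORB_FAST;
        return;
      }
      collect_core_hbs(a, hbs);
      if (!hbs.empty()) {
        std::pair<int,int> pick = hbs[runif_int((int)hbs.size())];
        hb[ih(pick.first, pick.second)] = 0;
        ++ctr.hb_breaks;
        hbs.clear();
        collect_core_hbs(a, hbs);
      }
      if (hbs.empty()) {
        a.stage = S_READY;
        schedule_race(a, s.kgly, A_CLEAVE);
      } else {
        schedule_race(a, s.khb, A_BREAK_HB);
      }
      return;
    case A_CLEAVE:
      if (!cat_bond_intact(a)) {
        a.stage = S_FASTDESORB;
        a.ev_time = t + rexp_rate(s.kofffast);
        a.ev_act = A_DESORB_FAST;
        return;
      }
      cleave_bond(a.chain, a.core + 1);
      ++ctr.cleave;
      a.stage = S_POSTCLEAVE;
      a.ev_time = t + rexp_rate(s.koff);
      a.ev_act = A_DESORB;
      return;
    case A_DESORB:
      if (a.stage == S_READY) ++ctr.ready_desorb;
      release(id);
      ++ctr.desorb;
      return;
    case A_DESORB_FAST:
      release(id);
      ++ctr.fastdesorb;
      return;
    }
  }

  // ---- exo behaviour ---------------------------------------------------
  // covered middle-chain interval of a bound exo; returns false if empty
  bool exo_mid(const Agent &a, int &lo, int &hi) const {
    lo = dp; hi = -1;
    for (size_t k = 0; k < a.covered.size(); ++k) {
      int u = a.covered[k];
      if (u / dp == a.chain) {
        int j = u % dp;
        if (j < lo) lo = j;
        if (j > hi) hi = j;
      }
    }
    return hi >= 0;
  }

  void exo_cover_window(int id) {
    Agent &a = agents[id];
    int dir = (sp[a.sp].kind == K_EXOR) ? -1 : +1;
    int e = a.endcol;
    int inner = e + 8 * dir;
    int lo = std::max(0, std::min(e, inner)), hi = std::min(dp - 1, std::max(e, inner));
    for (int cc = std::max(0, a.chain - 1); cc <= std::min(nc - 1, a.chain + 1); ++cc)
      for (int m = lo; m <= hi; ++m) {
        int u = iu(cc, m);
        if (!soluble[u] && covered_by[u] < 0) {
          covered_by[u] = id;
          a.covered.push_back(u);
        }
      }
    // hydrogen bonds under the enzyme break instantly
    for (int m = lo; m <= hi; ++m) {
      if (a.chain > 0 && hb[ih(a.chain - 1, m)] &&
          covered_by[iu(a.chain - 1, m)] == id && covered_by[iu(a.chain, m)] == id)
        hb[ih(a.chain - 1, m)] = 0;
      if (a.chain < nc - 1 && hb[ih(a.chain, m)] &&
          covered_by[iu(a.chain, m)] == id && covered_by[iu(a.chain + 1, m)] == id)
        hb[ih(a.chain, m)] = 0;
    }
  }

  void exo_adsorb(int id, const Anchor &an) {
    Agent &a = agents[id];
    a.bound = true;
    a.chain = an.chain;
    a.endcol = an.col;
    a.core = -1;
    a.covered.clear(); a.locked.clear();
    a.stage = S_CYCLING;
    exo_cover_window(id);
    --n_free[a.sp];
    ++ctr.adsorb;
    dirty = true;
    exo_decide(id);
  }

  void exo_decide(int id) {
    Agent &a = agents[id];
    const Species &s = sp[a.sp];
    int dir = (s.kind == K_EXOR) ? -1 : +1;
    int lo, hi;
    bool any = exo_mid(a, lo, hi);
    int nmid = any ? hi - lo + 1 : 0;
    // 1. continuity of the chain inside the tunnel
    bool broken = !any;
    if (any) {
      if (nmid != (int)std::count_if(a.covered.begin(), a.covered.end(),
            [&](int u) { return u / dp == a.chain; })) broken = true;
      for (int m = lo; m < hi && !broken; ++m)
        if (!gly[ig(a.chain, m)]) broken = true;
    }
    if (broken || nmid < 3) {
      if (broken && any) {
        a.ev_time = t + rexp_rate(s.kofffast);
        a.ev_act = A_DESORB_FAST;
      } else {
        // chain consumed or too short to hold an active-site bond
        ++ctr.spatial_desorb;
        a.ev_time = t + rexp_rate(s.koff);
        a.ev_act = A_DESORB;
      }
      return;
    }
    a.endcol = (dir < 0) ? hi : lo;
    // 2. voluntary desorption
    if (unif_rand() < s.alpha) {
      ++ctr.alpha_desorb;
      a.ev_time = t + rexp_rate(s.koff);
      a.ev_act = A_DESORB;
      return;
    }
    // 3. spatial conditions ahead of the tunnel
    int lead = (dir < 0) ? lo : hi;
    int a1 = lead + dir, a2 = lead + 2 * dir;
    bool a1in = a1 >= 0 && a1 < dp, a2in = a2 >= 0 && a2 < dp;
    if (a1in && !soluble[iu(a.chain, a1)]) {
      // units ahead on the middle chain: lock and step, or wait if blocked
      std::vector<int> ahead;
      int cols[2] = {a1, a2};
      for (int k = 0; k < 2; ++k) {
        int m = cols[k];
        if (m < 0 || m >= dp) continue;
        for (int cc = std::max(0, a.chain - 1); cc <= std::min(nc - 1, a.chain + 1); ++cc) {
          int u = iu(cc, m);
          if (!soluble[u]) ahead.push_back(u);
        }
      }
      for (size_t k = 0; k < ahead.size(); ++k) {
        int u = ahead[k];
        if ((covered_by[u] >= 0 && covered_by[u] != id) ||
            (locked_by[u] >= 0 && locked_by[u] != id)) {
          ++ctr.waits;
          a.ev_time = t + s.tstay;
          a.ev_act = A_RECYCLE;
          return;
        }
      }
      for (size_t k = 0; k < ahead.size(); ++k) {
        int u = ahead[k];
        if (locked_by[u] < 0) { locked_by[u] = id; a.locked.push_back(u); }
      }
      // intact hydrogen bonds incident to the locked units, each counted once
      // (a bond between two locked units is attributed to its lower unit)
      int nrhb = 0;
      for (size_t k = 0; k < ahead.size(); ++k) {
        int u = ahead[k], cc = u / dp, m = u % dp;
        if (cc > 0 && hb[ih(cc - 1, m)] && locked_by[iu(cc - 1, m)] != id)
          ++nrhb;
        if (cc < nc - 1 && hb[ih(cc, m)])
          ++nrhb;
      }
      dirty = true;
      a.ev_time = t + s.tmove + s.thb * nrhb;
      a.ev_act = A_STEP;
      return;
    }
    if (a1in && soluble[iu(a.chain, a1)] && a2in && !soluble[iu(a.chain, a2)]) {
      // single-column hole ahead: cannot thread the chain
      ++ctr.spatial_desorb;
      a.ev_time = t + rexp_rate(s.koff);
      a.ev_act = A_DESORB;
      return;
    }
    // terminal tail: process the remaining units inside the tunnel
    a.ev_time = t + s.tmove;
    a.ev_act = A_STEP;
  }

  void exo_step(int id) {
    Agent &a = agents[id];
    const Species &s = sp[a.sp];
    int dir = (s.kind == K_EXOR) ? -1 : +1;
    int lo, hi;
    if (!exo_mid(a, lo, hi) || hi - lo + 1 < 3) { exo_decide(id); return; }
    int e = (dir < 0) ? hi : lo;
    int bact = (dir < 0) ? e - 2 : e + 1;  // bond between units 2 and 3 from the end
    if (bact < 0 || bact >= dp - 1 || !gly[ig(a.chain, bact)]) { exo_decide(id); return; }
    cleave_bond(a.chain, bact);  // releases the terminal cellobiose and any short remnant
    ++ctr.steps;
    // slide: uncover everything, unlock, re-cover the advanced window
    for (size_t k = 0; k < a.covered.size(); ++k) covered_by[a.covered[k]] = -1;
    a.covered.clear();
    for (size_t k = 0; k < a.locked.size(); ++k) locked_by[a.locked[k]] = -1;
    a.locked.clear();
    int enew = e + 2 * dir;
    if (enew >= 0 && enew < dp && !soluble[iu(a.chain, enew)]) {
      a.endcol = enew;
      exo_cover_window(id);
    }
    dirty = true;
    exo_decide(id);
  }

  void fire_exo(int id) {
    Agent &a = agents[id];
    switch (a.ev_act) {
    case A_STEP:    exo_step(id); return;
    case A_RECYCLE: exo_decide(id); return;
    case A_DESORB:
      release(id); ++ctr.desorb; return;
    case A_DESORB_FAST:
      release(id); ++ctr.fastdesorb; return;
    }
  }

  // ---- shared ----------------------------------------------------------
  void release(int id) {
    Agent &a = agents[id];
    for (size_t k = 0; k < a.covered.size(); ++k) covered_by[a.covered[k]] = -1;
    for (size_t k = 0; k < a.locked.size(); ++k) locked_by[a.locked[k]] = -1;
    a.covered.clear(); a.locked.clear();
    a.bound = false;
    a.stage = S_FREE;
    a.ev_time = R_PosInf;
    a.ev_act = A_NONE;
    a.chain = a.core = a.endcol = -1;
    ++n_free[a.sp];
    dirty = true;
  }

  // pick one available site of species s uniformly, with rejection of
  // anchors that have gone stale since the cached list was built
  bool pick_site(int s, Anchor &out) {
    for (int attempt = 0; attempt < 2; ++attempt) {
      std::vector<Anchor> &lst = site_list[s];
      int tries = 0;
      while (!lst.empty() && tries < 60) {
        const Anchor &an = lst[runif_int((int)lst.size())];
        bool ok = (sp[s].kind == K_ENDO) ? endo_anchor_valid(an)
                                         : exo_anchor_valid(an, sp[s].kind);
        if (ok) { out = an; return true; }
        ++tries;
      }
      refresh_sites();
      if (site_list[s].empty()) return false;
    }
    return false;
  }

  void fire_adsorption(int s) {
    int id = find_free(s);
    Anchor an;
    if (id < 0 || !pick_site(s, an)) return;  // stale; clocks are redrawn below
    if (sp[s].kind == K_ENDO) endo_adsorb(id, an);
    else exo_adsorb(id, an);
  }

  // apply the earliest pending event; returns false when none is pending
  bool step_once(int &ev_kind, int &ev_who, int &ev_act_out) {
    last_released.clear();
    double tmin = R_PosInf;
    int what = -1, who = -1;
    for (size_t s = 0; s < sp.size(); ++s)
      if (ads_time[s] < tmin) { tmin = ads_time[s]; what = 0; who = (int)s; }
    for (size_t i = 0; i < agents.size(); ++i)
      if (agents[i].bound && agents[i].ev_time < tmin) {
        tmin = agents[i].ev_time; what = 1; who = (int)i;
        // deterministic tie-break by agent id: strictly-less keeps first
      }
    if (what < 0) {
      // nothing pending: make sure this is not a stale zero-site cache
      if (dirty) {
        refresh_sites();
        reschedule_ads();
        return step_once(ev_kind, ev_who, ev_act_out);
      }
      return false;
    }
    t = tmin;
    ev_kind = what; ev_who = who;
    if (what == 0) {
      ev_act_out = A_NONE;
      fire_adsorption(who);
      refresh_maybe_and_reschedule(true);
    } else {
      ev_act_out = agents[who].ev_act;
      if (sp[agents[who].sp].kind == K_ENDO) fire_endo(who);
      else fire_exo(who);
      refresh_maybe_and_reschedule(dirty);
    }
    ++ctr.events;
    touch_fp();
    return true;
  }

  // dirty stays set until a real refresh happens; between refreshes the
  // cached site counts (and hence the adsorption propensities) may lag by a
  // bounded number of events, which the rejection step at adsorption time
  // corrects for site identity
  void refresh_maybe_and_reschedule(bool force_resched) {
    if (dirty) maybe_refresh();
    if (dirty || force_resched) reschedule_ads();
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

typedef XPtr<Sim> SimPtr;

// [[Rcpp::export(name = ".sheet_new")]]
SEXP sheet_new(int n_chains, int dp, double broken_fraction) {
  Sim *s = new Sim();
  s->init(n_chains, dp);
  if (broken_fraction > 0) s->precleave(broken_fraction);
  s->touch_fp();
  return SimPtr(s, true);
}

// [[Rcpp::export(name = ".sheet_dims")]]
IntegerVector sheet_dims(SEXP xp) {
  SimPtr s(xp);
  return IntegerVector::create(s->nc, s->dp);
}

// [[Rcpp::export(name = ".sheet_counts")]]
List sheet_counts(SEXP xp) {
  SimPtr s(xp);
  long long ngly = 0, nhb = 0;
  for (size_t i = 0; i < s->gly.size(); ++i) ngly += s->gly[i];
  for (size_t i = 0; i < s->hb.size(); ++i) nhb += s->hb[i];
  return List::create(
    _["n_units"] = (double)s->n_units(),
    _["soluble"] = (double)s->n_soluble,
    _["intact_glycosidic"] = (double)ngly,
    _["intact_hbonds"] = (double)nhb,
    _["g1"] = (double)s->g1, _["g2"] = (double)s->g2, _["g3"] = (double)s->g3);
}

// [[Rcpp::export(name = ".sheet_state")]]
List sheet_state(SEXP xp) {
  SimPtr s(xp);
  int nc = s->nc, dp = s->dp;
  IntegerMatrix P1(nc, dp), P2(nc, dp), cov(nc, dp), lock(nc, dp);
  for (int c = 0; c < nc; ++c)
    for (int j = 0; j < dp; ++j) {
      int u = s->iu(c, j);
      P1(c, j) = s->soluble[u];
      P2(c, j) = s->end2[u];
      cov(c, j) = s->covered_by[u] >= 0 ?
        (s->covered_by[u] >= (int)s->agents.size() ? 99 :
         s->sp[s->agents[s->covered_by[u]].sp].kind + 1) : 0;
      lock(c, j) = s->locked_by[u] >= 0 ?
        (s->locked_by[u] >= (int)s->agents.size() ? 99 :
         s->sp[s->agents[s->locked_by[u]].sp].kind) : 0;
    }
  IntegerMatrix G(nc, std::max(0, dp - 1));
  for (int c = 0; c < nc; ++c)
    for (int b = 0; b < dp - 1; ++b) G(c, b) = s->gly[s->ig(c, b)];
  IntegerMatrix H(std::max(0, nc - 1), dp);
  for (int p = 0; p < nc - 1; ++p)
    for (int j = 0; j < dp; ++j) H(p, j) = s->hb[s->ih(p, j)];
  return List::create(_["soluble"] = P1, _["ends"] = P2, _["covered"] = cov,
                      _["locked"] = lock, _["glycosidic"] = G, _["hbonds"] = H);
}

// [[Rcpp::export(name = ".sheet_cleave")]]
IntegerVector sheet_cleave(SEXP xp, int chain, int bond) {
  SimPtr s(xp);
  if (chain < 0 || chain >= s->nc || bond < 0 || bond >= s->dp - 1)
    stop("bond index out of range");
  if (!s->gly[s->ig(chain, bond)])
    stop("bond is already cleaved");
  if (s->soluble[s->iu(chain, bond)] || s->soluble[s->iu(chain, bond + 1)])
    stop("bond is incident to a soluble unit");
  s->last_released.clear();
  s->cleave_bond(chain, bond);
  s->touch_fp();
  return wrap(s->last_released);
}

// [[Rcpp::export(name = ".sheet_break_hb")]]
bool sheet_break_hb(SEXP xp, int pair, int column) {
  SimPtr s(xp);
  if (pair < 0 || pair >= s->nc - 1 || column < 0 || column >= s->dp)
    stop("hydrogen-bond index out of range");
  if (!s->hb[s->ih(pair, column)]) return false;
  s->hb[s->ih(pair, column)] = 0;
  return true;
}

// [[Rcpp::export(name = ".sheet_endo_sites")]]
IntegerMatrix sheet_endo_sites(SEXP xp) {
  SimPtr s(xp);
  std::vector<Anchor> v;
  s->count_endo(&v);
  IntegerMatrix m((int)v.size(), 4);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i, 0) = v[i].chain; m(i, 1) = v[i].col;
    m(i, 2) = v[i].core;  m(i, 3) = v[i].truncated ? 1 : 0;
  }
  return m;
}

// [[Rcpp::export(name = ".sheet_exo_sites")]]
IntegerMatrix sheet_exo_sites(SEXP xp, int kind) {
  SimPtr s(xp);
  std::vector<Anchor> v;
  s->count_exo(kind, &v);
  IntegerMatrix m((int)v.size(), 2);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i, 0) = v[i].chain; m(i, 1) = v[i].col;
  }
  return m;
}

// [[Rcpp::export(name = ".sheet_mark")]]
void sheet_mark(SEXP xp, int chain, int column, std::string what) {
  SimPtr s(xp);
  if (chain < 0 || chain >= s->nc || column < 0 || column >= s->dp)
    stop("unit index out of range");
  int u = s->iu(chain, column);
  if (what == "lock") s->locked_by[u] = PSEUDO_OWNER;
  else if (what == "cover") s->covered_by[u] = PSEUDO_OWNER;
  else if (what == "clear") { s->locked_by[u] = -1; s->covered_by[u] = -1; }
  else stop("unknown mark");
  s->dirty = true;
}

// [[Rcpp::export(name = ".sheet_restore")]]
SEXP sheet_restore(int n_chains, int dp,
                   IntegerMatrix cleaved, IntegerMatrix broken_hb,
                   IntegerMatrix soluble_units, IntegerMatrix re_units,
                   IntegerMatrix ne_units, double g1, double g2, double g3) {
  Sim *s = new Sim();
  s->init(n_chains, dp);
  for (int i = 0; i < cleaved.nrow(); ++i)
    s->gly[s->ig(cleaved(i, 0), cleaved(i, 1))] = 0;
  for (int i = 0; i < broken_hb.nrow(); ++i)
    s->hb[s->ih(broken_hb(i, 0), broken_hb(i, 1))] = 0;
  for (int c = 0; c < n_chains; ++c)
    for (int j = 0; j < dp; ++j) s->end2[s->iu(c, j)] = 0;
  for (int i = 0; i < soluble_units.nrow(); ++i) {
    int u = s->iu(soluble_units(i, 0), soluble_units(i, 1));
    s->soluble[u] = 1;
  }
  for (int i = 0; i < ne_units.nrow(); ++i)
    s->end2[s->iu(ne_units(i, 0), ne_units(i, 1))] = 1;
  for (int i = 0; i < re_units.nrow(); ++i)
    s->end2[s->iu(re_units(i, 0), re_units(i, 1))] = 2;
  s->n_soluble = 0;
  for (size_t i = 0; i < s->soluble.size(); ++i) s->n_soluble += s->soluble[i];
  s->g1 = (long long)g1; s->g2 = (long long)g2; s->g3 = (long long)g3;
  s->touch_fp();
  return SimPtr(s, true);
}

// [[Rcpp::export(name = ".sim_attach")]]
SEXP sim_attach(SEXP xp, List species, double d_m, double a_g2) {
  SimPtr src(xp);
  Sim *s = new Sim(*src);  // substrate snapshot; the source sheet is untouched
  std::vector<Species> v;
  int n = ((IntegerVector)species["kind"]).size();
  for (int i = 0; i < n; ++i) {
    Species e;
    e.kind = ((IntegerVector)species["kind"])[i];
    e.kon = ((NumericVector)species["kon"])[i];
    e.koff = ((NumericVector)species["koff"])[i];
    e.kofffast = ((NumericVector)species["kofffast"])[i];
    e.kgly = ((NumericVector)species["kgly"])[i];
    e.khb = ((NumericVector)species["khbbreak"])[i];
    e.tmove = ((NumericVector)species["tmove"])[i];
    e.tstay = ((NumericVector)species["tstay"])[i];
    e.thb = ((NumericVector)species["thbbreak"])[i];
    e.alpha = ((NumericVector)species["alpha"])[i];
    e.mw = ((NumericVector)species["mw"])[i];
    e.count = ((IntegerVector)species["count"])[i];
    v.push_back(e);
  }
  s->attach(v, d_m, a_g2);
  return SimPtr(s, true);
}

// [[Rcpp::export(name = ".sim_info")]]
List sim_info(SEXP xp) {
  SimPtr s(xp);
  int ns = (int)s->sp.size();
  NumericVector prop(ns), adst(ns);
  IntegerVector nfree(ns), nbound(ns), sites(ns), kind(ns);
  if (s->dirty) s->refresh_sites();
  for (int i = 0; i < ns; ++i) {
    prop[i] = s->propensity(i);
    adst[i] = s->ads_time[i];
    nfree[i] = s->n_free[i];
    nbound[i] = s->sp[i].count - s->n_free[i];
    sites[i] = (int)s->site_count[i];
    kind[i] = s->sp[i].kind;
  }
  return List::create(_["time"] = s->t, _["volume_L"] = s->vol_L,
                      _["kind"] = kind, _["propensity"] = prop,
                      _["ads_time"] = adst, _["free"] = nfree,
                      _["bound"] = nbound, _["sites"] = sites,
                      _["conversion"] = s->conversion());
}

// [[Rcpp::export(name = ".sim_counters")]]
List sim_counters(SEXP xp) {
  SimPtr s(xp);
  const Counters &c = s->ctr;
  return List::create(_["events"] = (double)c.events, _["adsorb"] = (double)c.adsorb,
    _["desorb"] = (double)c.desorb, _["fastdesorb"] = (double)c.fastdesorb,
    _["cleave"] = (double)c.cleave, _["ready_desorb"] = (double)c.ready_desorb,
    _["hb_breaks"] = (double)c.hb_breaks, _["steps"] = (double)c.steps,
    _["waits"] = (double)c.waits, _["alpha_desorb"] = (double)c.alpha_desorb,
    _["spatial_desorb"] = (double)c.spatial_desorb);
}

// [[Rcpp::export(name = ".sim_agent_state")]]
List sim_agent_state(SEXP xp, int id) {
  SimPtr s(xp);
  if (id < 0 || id >= (int)s->agents.size()) stop("no such agent");
  const Agent &a = s->agents[id];
  const char *stages[] = {"free", "breaking_hbonds", "ready_to_cleave",
                          "post_cleave_desorbing", "fast_desorbing", "cycling"};
  IntegerMatrix cov((int)a.covered.size(), 2), lock((int)a.locked.size(), 2);
  for (size_t k = 0; k < a.covered.size(); ++k) {
    cov(k, 0) = a.covered[k] / s->dp; cov(k, 1) = a.covered[k] % s->dp;
  }
  for (size_t k = 0; k < a.locked.size(); ++k) {
    lock(k, 0) = a.locked[k] / s->dp; lock(k, 1) = a.locked[k] % s->dp;
  }
  return List::create(_["species"] = a.sp, _["bound"] = a.bound,
                      _["chain"] = a.chain, _["core"] = a.core,
                      _["endColumn"] = a.endcol,
                      _["stage"] = std::string(stages[a.stage]),
                      _["covered"] = cov, _["locked"] = lock,
                      _["eventTime"] = a.ev_time, _["eventAction"] = a.ev_act);
}

// [[Rcpp::export(name = ".sim_adsorb")]]
void sim_adsorb(SEXP xp, int id, int chain, int column, bool truncated) {
  SimPtr s(xp);
  if (id < 0 || id >= (int)s->agents.size()) stop("no such agent");
  Agent &a = s->agents[id];
  if (a.bound) stop("agent is already bound");
  int kind = s->sp[a.sp].kind;
  if (kind == K_ENDO) {
    Anchor an{chain, column, 0, truncated};
    if (!truncated) an.core = column + 3;
    else {
      int b = column;
      while (b + 1 < s->dp && s->gly[s->ig(chain, b)] &&
             !s->soluble[s->iu(chain, b + 1)] && b - column < 9) ++b;
      an.core = column + ((b - column + 1) - 4) / 2;
    }
    if (!s->endo_anchor_valid(an)) stop("site is not available");
    s->endo_adsorb(id, an);
  } else {
    Anchor an{chain, column, 0, false};
    if (!s->exo_anchor_valid(an, kind)) stop("site is not available");
    s->exo_adsorb(id, an);
  }
  s->maybe_refresh();
  s->reschedule_ads();
}

// fire the pending event of one specific agent (stepwise inspection API);
// simulation time jumps to that event's time
// [[Rcpp::export(name = ".sim_agent_fire")]]
List sim_agent_fire(SEXP xp, int id) {
  SimPtr s(xp);
  if (id < 0 || id >= (int)s->agents.size()) stop("no such agent");
  Agent &a = s->agents[id];
  if (!a.bound) stop("agent is not bound");
  s->last_released.clear();
  double t0 = s->t;
  double delay = a.ev_time - s->t;
  int act = a.ev_act;
  s->t = a.ev_time;
  if (s->sp[a.sp].kind == K_ENDO) s->fire_endo(id);
  else s->fire_exo(id);
  s->touch_fp();
  if (s->dirty) { s->maybe_refresh(); s->reschedule_ads(); }
  const char *acts[] = {"none", "break_one_hbond", "cleave", "desorb",
                        "desorb_fast", "process_step", "recycle"};
  return List::create(_["time"] = s->t, _["delay"] = delay,
                      _["action"] = std::string(acts[act]),
                      _["released"] = wrap(s->last_released),
                      _["timeBefore"] = t0);
}

// [[Rcpp::export(name = ".sim_release")]]
void sim_release(SEXP xp, int id) {
  SimPtr s(xp);
  if (id < 0 || id >= (int)s->agents.size()) stop("no such agent");
  if (!s->agents[id].bound) stop("agent is not bound");
  s->release(id);
  s->maybe_refresh();
  s->reschedule_ads();
}

// [[Rcpp::export(name = ".sim_step")]]
List sim_step(SEXP xp) {
  SimPtr s(xp);
  int kind = -1, who = -1, act = A_NONE;
  bool any = s->step_once(kind, who, act);
  const char *acts[] = {"none", "break_one_hbond", "cleave", "desorb",
                        "desorb_fast", "process_step", "recycle"};
  return List::create(_["fired"] = any, _["time"] = s->t,
    _["kind"] = kind == 0 ? "adsorption" : (kind == 1 ? "agent" : "none"),
    _["who"] = who, _["action"] = std::string(acts[act]),
    _["released"] = wrap(s->last_released),
    _["conversion"] = s->conversion());
}

// [[Rcpp::export(name = ".sim_run")]]
List sim_run(SEXP xp, double threshold, double t_max, double sample_dt) {
  SimPtr s(xp);
  int ns = (int)s->sp.size();
  std::vector<double> rows;
  int ncol = 5 + 3 * ns;
  double next_sample = s->t;
  std::string term = "exhausted";

  // a trajectory row reflects the state that held at `when`
  auto push_row = [&](double when) {
    if (s->dirty) s->refresh_sites();
    rows.push_back(when);
    rows.push_back(s->conversion());
    rows.push_back((double)s->g1);
    rows.push_back((double)s->g2);
    rows.push_back((double)s->g3);
    for (int i = 0; i < ns; ++i) {
      rows.push_back((double)(s->sp[i].count - s->n_free[i]));
      rows.push_back((double)s->n_free[i]);
      rows.push_back((double)s->site_count[i]);
    }
  };

  if (s->conversion() >= threshold) {
    term = "threshold";
    push_row(s->t);
  } else {
    for (;;) {
      // locate next event time without applying, to emit grid samples first
      double tmin = R_PosInf;
      for (int i = 0; i < ns; ++i) tmin = std::min(tmin, s->ads_time[i]);
      for (size_t i = 0; i < s->agents.size(); ++i)
        if (s->agents[i].bound) tmin = std::min(tmin, s->agents[i].ev_time);
      if (!R_FINITE(tmin)) {
        if (s->dirty) {  // a stale zero site count must not end the run
          s->refresh_sites();
          s->reschedule_ads();
          continue;
        }
        term = "exhausted";
        break;
      }
      double horizon = std::min(tmin, t_max);
      const size_t max_rows = 200000;  // keep pathological waits bounded
      while (next_sample < horizon) {
        if (rows.size() / ncol >= max_rows) {
          double k = std::ceil((horizon - next_sample) / sample_dt);
          next_sample += k * sample_dt;
          break;
        }
        push_row(next_sample);
        next_sample += sample_dt;
      }
      if (tmin > t_max) { term = "t_max"; s->t = t_max; break; }
      int kind, who, act;
      if (!s->step_once(kind, who, act)) { term = "exhausted"; break; }
      if (s->conversion() >= threshold) { term = "threshold"; break; }
      if (s->ctr.events % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    push_row(s->t);
  }

  int nrow = (int)rows.size() / ncol;
  NumericMatrix traj(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c2 = 0; c2 < ncol; ++c2) traj(r, c2) = rows[(size_t)r * ncol + c2];
  return List::create(_["trajectory"] = traj,
                      _["termination"] = term,
                      _["finalTime"] = s->t,
                      _["conversion"] = s->conversion(),
                      _["tally"] = NumericVector::create((double)s->g1, (double)s->g2, (double)s->g3),
                      _["firstPassage"] = wrap(s->fp),
                      _["counters"] = sim_counters(xp));
}

// [[Rcpp::export(name = ".sim_first_passage")]]
NumericVector sim_first_passage(SEXP xp) {
  SimPtr s(xp);
  return wrap(s->fp);
}
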