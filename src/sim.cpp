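// Core annual-cycle engine. The R-level module functions document and test
// the individual rules; this file runs them over 10^3-10^4 years at C speed.
// All randomness goes through R's RNG so set.seed() governs every draw.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

enum Stage { PRE = 1, ADULT = 2 };            // juveniles exist only within a year
enum Status { NONE = 0, FAILED = 1, SUCC = 2 };
enum Strategy { UNINFORMED = 0, PERSONAL = 1, PERSONAL_PUBLIC = 2 };
enum Process { INACCURATE = 0, ACCURATE = 1, DETERMINISTIC = 2 };

static inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

// uniform integer on 0..n-1 (unif_rand() is in [0,1))
static inline int unif_index(int n) {
  if (n <= 1) return 0;
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Params {
  int n_patches;
  double K0, Off_max, S_J, S_I, S_A, sigma, autocorr, Rmean, mu, mut_sd, M, accuracy;
  int strategy, process;
  double fE, fEsucc, fEfail, fbsucc, fasucc, fbfail, fafail;
  int fNp;
  bool evE, evEsucc, evEfail, evbsucc, evasucc, evbfail, evafail, evNp;
  int init_adults;
  int settle_rule;   // 0 breeding adults, 1 any individual, 2 all patches
  int recruit_lead;  // years between settlement and first breeding (0 or 1)
  int recruit_surv;  // survival prob in the settlement year: 0 = S_I, 1 = S_A
};

// structure-of-arrays roster; fixed loci are stored at their scenario constant
struct Pop {
  std::vector<int> stage, age, rec_age, status, patch, np;
  std::vector<double> E, Esucc, Efail, bsucc, asucc, bfail, afail;

  size_t size() const { return stage.size(); }

  void reserve(size_t n) {
    stage.reserve(n); age.reserve(n); rec_age.reserve(n); status.reserve(n);
    patch.reserve(n); np.reserve(n); E.reserve(n); Esucc.reserve(n);
    Efail.reserve(n); bsucc.reserve(n); asucc.reserve(n); bfail.reserve(n);
    afail.reserve(n);
  }

  void push(int st, int a, int ra, int bs, int p, int npv,
            double e, double es, double ef, double Bs, double As, double Bf, double Af) {
    stage.push_back(st); age.push_back(a); rec_age.push_back(ra); status.push_back(bs);
    patch.push_back(p); np.push_back(npv); E.push_back(e); Esucc.push_back(es);
    Efail.push_back(ef); bsucc.push_back(Bs); asucc.push_back(As);
    bfail.push_back(Bf); afail.push_back(Af);
  }

  // drop individuals flagged dead, preserving order
  void compact(const std::vector<char>& dead) {
    size_t w = 0;
    for (size_t i = 0; i < size(); ++i) {
      if (dead[i]) continue;
      if (w != i) {
        stage[w] = stage[i]; age[w] = age[i]; rec_age[w] = rec_age[i];
        status[w] = status[i]; patch[w] = patch[i]; np[w] = np[i];
        E[w] = E[i]; Esucc[w] = Esucc[i]; Efail[w] = Efail[i];
        bsucc[w] = bsucc[i]; asucc[w] = asucc[i]; bfail[w] = bfail[i];
        afail[w] = afail[i];
      }
      ++w;
    }
    stage.resize(w); age.resize(w); rec_age.resize(w); status.resize(w);
    patch.resize(w); np.resize(w); E.resize(w); Esucc.resize(w); Efail.resize(w);
    bsucc.resize(w); asucc.resize(w); bfail.resize(w); afail.resize(w);
  }
};

static int draw_rec_age(double Rmean) {
  int ra = (int) R::rpois(Rmean);
  return ra < 2 ? 2 : ra;            // >=1 full year as juvenile and as pre-breeder
}

static inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// maternal inheritance with per-locus mutation; only evolving loci mutate.
// Mutated continuous alleles are truncated to their initialization interval
// ([0,1] for probabilities/intercepts, [-1,0] for slopes), which keeps the
// allele distributions stationary at mutation-selection balance
static void inherit(const Params& P, const Pop& pop, size_t m, Pop& kids, int patch_id) {
  double e = pop.E[m], es = pop.Esucc[m], ef = pop.Efail[m];
  double Bs = pop.bsucc[m], As = pop.asucc[m], Bf = pop.bfail[m], Af = pop.afail[m];
  int npv = pop.np[m];
  if (P.evE && unif_rand() < P.mu) e = clamp(e + R::norm_rand() * P.mut_sd, 0, 1);
  if (P.evEsucc && unif_rand() < P.mu) es = clamp(es + R::norm_rand() * P.mut_sd, 0, 1);
  if (P.evEfail && unif_rand() < P.mu) ef = clamp(ef + R::norm_rand() * P.mut_sd, 0, 1);
  if (P.evbsucc && unif_rand() < P.mu) Bs = clamp(Bs + R::norm_rand() * P.mut_sd, 0, 1);
  if (P.evasucc && unif_rand() < P.mu) As = clamp(As + R::norm_rand() * P.mut_sd, -1, 0);
  if (P.evbfail && unif_rand() < P.mu) Bf = clamp(Bf + R::norm_rand() * P.mut_sd, 0, 1);
  if (P.evafail && unif_rand() < P.mu) Af = clamp(Af + R::norm_rand() * P.mut_sd, -1, 0);
  if (P.evNp && unif_rand() < P.mu) {
    npv += (unif_rand() < 0.5) ? -1 : 1;
    if (npv < 0) npv = 0;
    if (npv > P.n_patches - 1) npv = P.n_patches - 1;
  }
  kids.push(PRE, 0, draw_rec_age(P.Rmean), NONE, patch_id, npv, e, es, ef, Bs, As, Bf, Af);
}

// emigration probability: status-conditional rules, clamped at use;
// recruits (status NONE) use the failed-breeder rule
static double emig_prob(const Params& P, const Pop& pop, size_t i, int st, double lbs) {
  double e;
  switch (P.strategy) {
  case UNINFORMED:       e = pop.E[i]; break;
  case PERSONAL:         e = (st == SUCC) ? pop.Esucc[i] : pop.Efail[i]; break;
  default:               e = (st == SUCC) ? pop.bsucc[i] + pop.asucc[i] * lbs
                                          : pop.bfail[i] + pop.afail[i] * lbs;
  }
  return clamp01(e);
}

// sample destination among prospected patches given the process
static int choose_patch(const std::vector<int>& pros, int k,
                        const std::vector<double>& LBS, int process, double accuracy) {
  if (process == DETERMINISTIC) {
    double best = -1.0; int nties = 0;
    for (int j = 0; j < k; ++j) {
      double l = LBS[pros[j]];
      if (l > best) { best = l; nties = 1; }
      else if (l == best) ++nties;
    }
    int pick = unif_index(nties);
    for (int j = 0; j < k; ++j) {
      if (LBS[pros[j]] == best && pick-- == 0) return pros[j];
    }
    return pros[k - 1];              // unreachable
  }
  std::vector<double> w(k);
  double sum = 0.0;
  if (process == INACCURATE) {
    for (int j = 0; j < k; ++j) { w[j] = LBS[pros[j]]; sum += w[j]; }
    if (sum <= 0.0) return pros[unif_index(k)];   // all-zero LBS: uniform completion
  } else {                                        // ACCURATE: softmax on LBS
    double maxl = LBS[pros[0]];
    for (int j = 1; j < k; ++j) if (LBS[pros[j]] > maxl) maxl = LBS[pros[j]];
    for (int j = 0; j < k; ++j) { w[j] = std::exp(accuracy * (LBS[pros[j]] - maxl)); sum += w[j]; }
  }
  double u = unif_rand() * sum, c = 0.0;
  for (int j = 0; j < k; ++j) { c += w[j]; if (u < c) return pros[j]; }
  return pros[k - 1];
}

// exported for cross-checking the R-level settlement rule against the engine's
// [[Rcpp::export(name = ".settlement_choose_cpp")]]
int settlement_choose_cpp(IntegerVector prospected, NumericVector lbs_all,
                          int process, double accuracy) {
  std::vector<int> pros(prospected.begin(), prospected.end());
  std::vector<double> LBS(lbs_all.begin(), lbs_all.end());
  return choose_patch(pros, (int) pros.size(), LBS, process, accuracy);
}

static Params read_params(List cfg) {
  Params P;
  P.n_patches = as<int>(cfg["n_patches"]);
  P.K0 = as<double>(cfg["K0"]);
  P.Off_max = as<double>(cfg["Off_max"]);
  P.S_J = as<double>(cfg["S_J"]);
  P.S_I = as<double>(cfg["S_I"]);
  P.S_A = as<double>(cfg["S_A"]);
  P.sigma = as<double>(cfg["sigma"]);
  P.autocorr = as<double>(cfg["autocorr"]);
  P.Rmean = as<double>(cfg["R"]);
  P.mu = as<double>(cfg["mu"]);
  P.mut_sd = as<double>(cfg["mut_sd"]);
  P.M = as<double>(cfg["M"]);
  P.accuracy = as<double>(cfg["accuracy"]);
  P.strategy = as<int>(cfg["strategy_code"]);
  P.process = as<int>(cfg["process_code"]);
  P.fE = as<double>(cfg["E"]);
  P.fEsucc = as<double>(cfg["E_succ"]);
  P.fEfail = as<double>(cfg["E_fail"]);
  P.fbsucc = as<double>(cfg["beta_succ"]);
  P.fasucc = as<double>(cfg["alpha_succ"]);
  P.fbfail = as<double>(cfg["beta_fail"]);
  P.fafail = as<double>(cfg["alpha_fail"]);
  P.fNp = as<int>(cfg["Np_fixed"]);
  LogicalVector ev = cfg["evolving_flags"];   // E, E_succ, E_fail, beta_succ, alpha_succ, beta_fail, alpha_fail, Np
  P.evE = ev[0]; P.evEsucc = ev[1]; P.evEfail = ev[2]; P.evbsucc = ev[3];
  P.evasucc = ev[4]; P.evbfail = ev[5]; P.evafail = ev[6]; P.evNp = ev[7];
  P.init_adults = as<int>(cfg["init_adults"]);
  P.settle_rule = as<int>(cfg["settle_rule_code"]);
  P.recruit_lead = as<int>(cfg["recruit_lead"]);
  P.recruit_surv = as<int>(cfg["recruit_surv"]);
  return P;
}

static double runif_range(double lo, double hi) { return lo + unif_rand() * (hi - lo); }

// one replicate: full run of `years` annual cycles from the standard
// initialization (each patch holds init_adults adults of age 2..10 with
// random alleles at evolving loci)
// [[Rcpp::export(name = ".sim_replicate_cpp")]]
List sim_replicate_cpp(List cfg, int years, int summary_every, bool record_patches) {
  RNGScope scope;
  Params P = read_params(cfg);
  const int NP = P.n_patches;

  std::vector<double> Q(NP, 0.0), K(NP, 0.0), LBS(NP, 0.0), muoff(NP, 0.0);
  std::vector<int> N(NP, 0), nsucc(NP, 0);
  std::vector<char> occ(NP, 0), settleable(NP, 0);

  Pop pop, kids;
  pop.reserve((size_t) NP * P.init_adults * 4 + 64);

  for (int p = 0; p < NP; ++p) {
    for (int j = 0; j < P.init_adults; ++j) {
      double e  = P.evE     ? runif_range(0, 1)  : P.fE;
      double es = P.evEsucc ? runif_range(0, 1)  : P.fEsucc;
      double ef = P.evEfail ? runif_range(0, 1)  : P.fEfail;
      double Bs = P.evbsucc ? runif_range(0, 1)  : P.fbsucc;
      double As = P.evasucc ? runif_range(-1, 0) : P.fasucc;
      double Bf = P.evbfail ? runif_range(0, 1)  : P.fbfail;
      double Af = P.evafail ? runif_range(-1, 0) : P.fafail;
      int npv   = P.evNp    ? unif_index(NP)     : P.fNp;
      pop.push(ADULT, 2 + unif_index(9), 2, NONE, p, npv, e, es, ef, Bs, As, Bf, Af);
    }
  }

  // yearly summary accumulators
  std::vector<int> s_year, s_adults, s_pre, s_births, s_djuv, s_dpre, s_dad, s_dpro,
                   s_recruits, s_nocc;
  std::vector<double> s_mE, s_mEs, s_mEf, s_mBs, s_mAs, s_mBf, s_mAf, s_mNp;
  std::vector<int> p_year, p_patch, p_N;
  std::vector<double> p_Q, p_K, p_LBS;

  std::vector<int> cand(NP), pros(NP);
  const double sq = std::sqrt(1.0 - P.autocorr * P.autocorr);

  for (int year = 1; year <= years; ++year) {
    // (1) environment: init at year 1, AR(1) step after
    if (year == 1) {
      for (int p = 0; p < NP; ++p) Q[p] = R::norm_rand() * P.sigma;
    } else {
      for (int p = 0; p < NP; ++p)
        Q[p] = P.autocorr * Q[p] + R::norm_rand() * P.sigma * sq;
    }
    for (int p = 0; p < NP; ++p) K[p] = std::max(0.0, P.K0 + P.K0 * Q[p]);

    // adult counts at breeding
    std::fill(N.begin(), N.end(), 0);
    for (size_t i = 0; i < pop.size(); ++i)
      if (pop.stage[i] == ADULT) ++N[pop.patch[i]];
    for (int p = 0; p < NP; ++p)
      muoff[p] = (K[p] > 0.0 && N[p] > 0)
        ? P.Off_max / (1.0 + (P.Off_max - 1.0) * N[p] / K[p]) : 0.0;

    // (2) reproduction + breeding status
    std::fill(nsucc.begin(), nsucc.end(), 0);
    kids.stage.clear(); kids.age.clear(); kids.rec_age.clear(); kids.status.clear();
    kids.patch.clear(); kids.np.clear(); kids.E.clear(); kids.Esucc.clear();
    kids.Efail.clear(); kids.bsucc.clear(); kids.asucc.clear(); kids.bfail.clear();
    kids.afail.clear();
    int births = 0;
    const size_t n0 = pop.size();
    for (size_t i = 0; i < n0; ++i) {
      if (pop.stage[i] != ADULT) continue;
      int p = pop.patch[i];
      int noff = muoff[p] > 0.0 ? (int) R::rpois(muoff[p]) : 0;
      pop.status[i] = noff >= 1 ? SUCC : FAILED;
      if (noff >= 1) ++nsucc[p];
      for (int o = 0; o < noff; ++o) inherit(P, pop, i, kids, p);
      births += noff;
    }

    // (3) pre-dispersal snapshot: occupancy, settlement candidacy and
    // local breeding success (LBS of a patch without breeders reads as 0)
    int nocc = 0;
    for (int p = 0; p < NP; ++p) {
      occ[p] = N[p] > 0;
      LBS[p] = occ[p] ? (double) nsucc[p] / N[p] : 0.0;
      if (occ[p]) ++nocc;
    }
    if (P.settle_rule == 0) {
      for (int p = 0; p < NP; ++p) settleable[p] = occ[p];
    } else if (P.settle_rule == 1) {
      std::fill(settleable.begin(), settleable.end(), 0);
      for (size_t i = 0; i < pop.size(); ++i) settleable[pop.patch[i]] = 1;
      for (size_t j = 0; j < kids.size(); ++j) settleable[kids.patch[j]] = 1;
    } else {
      std::fill(settleable.begin(), settleable.end(), 1);
    }

    // (4) dispersal: adults, then this year's recruits; all read the snapshot
    std::vector<char> dead(n0, 0), recruited(n0, 0);
    int dpro = 0, recruits = 0;
    for (int pass = 0; pass < 2; ++pass) {
      for (size_t i = 0; i < n0; ++i) {
        int st;
        if (pass == 0) {
          if (pop.stage[i] != ADULT) continue;
          st = pop.status[i];
        } else {
          // with recruit_lead = 1, settlement happens the year before the
          // first breeding attempt, so first breeding falls at the drawn age
          if (pop.stage[i] != PRE ||
              pop.age[i] + P.recruit_lead != pop.rec_age[i]) continue;
          pop.stage[i] = ADULT; pop.status[i] = NONE; ++recruits;
          recruited[i] = 1;
          st = NONE;
        }
        int here = pop.patch[i];
        double lbs_here = occ[here] ? LBS[here] : 0.0;
        if (unif_rand() >= emig_prob(P, pop, i, st, lbs_here)) continue;
        // candidates: settleable patches other than the current one
        int ncand = 0;
        for (int p = 0; p < NP; ++p)
          if (settleable[p] && p != here) cand[ncand++] = p;
        if (ncand == 0) continue;                 // no eligible destination: stay
        int npv = pop.np[i];
        if (npv <= 0) {                           // no prospecting: random settlement
          pop.patch[i] = cand[unif_index(ncand)];
          continue;
        }
        int k = npv < ncand ? npv : ncand;
        for (int j = 0; j < k; ++j) {             // partial Fisher-Yates draw
          int r = j + unif_index(ncand - j);
          int tmp = cand[j]; cand[j] = cand[r]; cand[r] = tmp;
          pros[j] = cand[j];
        }
        if (P.M > 0.0 && unif_rand() < P.M * k) { // prospecting mortality
          dead[i] = 1; ++dpro;
          continue;
        }
        pop.patch[i] = choose_patch(pros, k, LBS, P.process, P.accuracy);
      }
    }

    // (5) survival: adults S_A, remaining pre-breeders S_I, then juveniles S_J
    int djuv = 0, dpre = 0, dad = 0;
    for (size_t i = 0; i < n0; ++i) {
      if (dead[i]) continue;
      double s = pop.stage[i] == ADULT
        ? ((recruited[i] && P.recruit_surv == 0) ? P.S_I : P.S_A)
        : P.S_I;
      if (unif_rand() >= s) {
        dead[i] = 1;
        if (pop.stage[i] == ADULT) ++dad; else ++dpre;
      }
    }
    pop.compact(dead);
    for (size_t j = 0; j < kids.size(); ++j) {
      if (unif_rand() < P.S_J) {
        pop.push(PRE, 0, kids.rec_age[j], NONE, kids.patch[j], kids.np[j],
                 kids.E[j], kids.Esucc[j], kids.Efail[j], kids.bsucc[j],
                 kids.asucc[j], kids.bfail[j], kids.afail[j]);
      } else ++djuv;
    }

    // (6) ageing
    for (size_t i = 0; i < pop.size(); ++i) ++pop.age[i];

    if (year % summary_every == 0 || year == years) {
      int nad = 0, npre = 0;
      double mE = 0, mEs = 0, mEf = 0, mBs = 0, mAs = 0, mBf = 0, mAf = 0, mNp = 0;
      for (size_t i = 0; i < pop.size(); ++i) {
        if (pop.stage[i] == ADULT) {
          ++nad;
          mE += pop.E[i]; mEs += pop.Esucc[i]; mEf += pop.Efail[i];
          mBs += pop.bsucc[i]; mAs += pop.asucc[i]; mBf += pop.bfail[i];
          mAf += pop.afail[i]; mNp += pop.np[i];
        } else ++npre;
      }
      s_year.push_back(year); s_adults.push_back(nad); s_pre.push_back(npre);
      s_births.push_back(births); s_djuv.push_back(djuv); s_dpre.push_back(dpre);
      s_dad.push_back(dad); s_dpro.push_back(dpro); s_recruits.push_back(recruits);
      s_nocc.push_back(nocc);
      double d = nad > 0 ? (double) nad : NA_REAL;
      s_mE.push_back(mE / d); s_mEs.push_back(mEs / d); s_mEf.push_back(mEf / d);
      s_mBs.push_back(mBs / d); s_mAs.push_back(mAs / d); s_mBf.push_back(mBf / d);
      s_mAf.push_back(mAf / d); s_mNp.push_back(mNp / d);
      if (record_patches) {
        for (int p = 0; p < NP; ++p) {
          p_year.push_back(year); p_patch.push_back(p + 1);
          p_Q.push_back(Q[p]); p_K.push_back(K[p]); p_N.push_back(N[p]);
          p_LBS.push_back(occ[p] ? LBS[p] : NA_REAL);
        }
      }
    }
  }

  // final-year individual snapshot (end-of-year roster, with the breeding
  // snapshot's LBS of each individual's current patch)
  const size_t n = pop.size();
  IntegerVector f_stage(n), f_age(n), f_rec(n), f_status(n), f_patch(n), f_np(n);
  NumericVector f_E(n), f_Es(n), f_Ef(n), f_Bs(n), f_As(n), f_Bf(n), f_Af(n), f_lbs(n);
  for (size_t i = 0; i < n; ++i) {
    f_stage[i] = pop.stage[i]; f_age[i] = pop.age[i]; f_rec[i] = pop.rec_age[i];
    f_status[i] = pop.status[i]; f_patch[i] = pop.patch[i] + 1; f_np[i] = pop.np[i];
    f_E[i] = pop.E[i]; f_Es[i] = pop.Esucc[i]; f_Ef[i] = pop.Efail[i];
    f_Bs[i] = pop.bsucc[i]; f_As[i] = pop.asucc[i]; f_Bf[i] = pop.bfail[i];
    f_Af[i] = pop.afail[i];
    f_lbs[i] = occ[pop.patch[i]] ? LBS[pop.patch[i]] : NA_REAL;
  }

  return List::create(
    _["summary"] = List::create(
      _["year"] = s_year, _["n_adults"] = s_adults, _["n_prebreeders"] = s_pre,
      _["births"] = s_births, _["deaths_juvenile"] = s_djuv,
      _["deaths_prebreeder"] = s_dpre, _["deaths_adult"] = s_dad,
      _["deaths_prospecting"] = s_dpro, _["recruits"] = s_recruits,
      _["n_occupied"] = s_nocc,
      _["mean_E"] = s_mE, _["mean_E_succ"] = s_mEs, _["mean_E_fail"] = s_mEf,
      _["mean_beta_succ"] = s_mBs, _["mean_alpha_succ"] = s_mAs,
      _["mean_beta_fail"] = s_mBf, _["mean_alpha_fail"] = s_mAf,
      _["mean_Np"] = s_mNp),
    _["patches"] = List::create(
      _["year"] = p_year, _["patch"] = p_patch, _["Q"] = p_Q, _["K"] = p_K,
      _["N"] = p_N, _["LBS"] = p_LBS),
    _["snapshot"] = List::create(
      _["stage"] = f_stage, _["age"] = f_age, _["recruitment_age"] = f_rec,
      _["status"] = f_status, _["patch"] = f_patch, _["lbs_patch"] = f_lbs,
      _["E"] = f_E, _["E_succ"] = f_Es, _["E_fail"] = f_Ef,
      _["beta_succ"] = f_Bs, _["alpha_succ"] = f_As,
      _["beta_fail"] = f_Bf, _["alpha_fail"] = f_Af, _["Np"] = f_np));
}
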