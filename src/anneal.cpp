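#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Metropolis Monte Carlo kernel for one temperature level of the
// bead-spring ligand on affinity grids. Bead positions are 0-based node
// indices here (the R wrapper converts). The AIE bead (index 2) is fixed.
//
// Energy arithmetic mirrors the R-level springEnergy/hardCoreOk/gridEnergy
// exactly: distances are computed from node-index differences times the
// per-axis spacing, the hard core applies to the six non-bonded pairs with
// |i-j| >= 2, and grid terms are direct node lookups (GCP beads on the GCP
// grid, Lys beads on the Lys grid; no AIE term).

static const int NB_I[6] = {0, 0, 0, 1, 1, 2};
static const int NB_J[6] = {2, 3, 4, 3, 4, 4};

struct System {
  const double *gcp;
  const double *lys;
  const int *forb;
  int n1, n2, n3;
  double sp[3];
  double leq[4], k[4], a2;
};

static inline double totalEnergyC(const System &sys, const int *b) {
  const double inf = std::numeric_limits<double>::infinity();
  // hard core on non-bonded pairs
  for (int p = 0; p < 6; ++p) {
    const int *u = b + 3 * NB_I[p];
    const int *v = b + 3 * NB_J[p];
    double dx = (u[0] - v[0]) * sys.sp[0];
    double dy = (u[1] - v[1]) * sys.sp[1];
    double dz = (u[2] - v[2]) * sys.sp[2];
    if (dx * dx + dy * dy + dz * dz < sys.a2) return inf;
  }
  // grid terms for beads 0, 1, 3, 4
  double grid = 0.0;
  static const int gb[4] = {0, 1, 3, 4};
  for (int t = 0; t < 4; ++t) {
    const int *u = b + 3 * gb[t];
    if (u[0] < 0 || u[0] >= sys.n1 || u[1] < 0 || u[1] >= sys.n2 ||
        u[2] < 0 || u[2] >= sys.n3)
      return inf;
    R_xlen_t lin = u[0] + (R_xlen_t)u[1] * sys.n1 +
                   (R_xlen_t)u[2] * sys.n1 * sys.n2;
    if (sys.forb[lin]) return inf;
    grid += (gb[t] == 0 || gb[t] == 4) ? sys.gcp[lin] : sys.lys[lin];
  }
  // springs
  double spring = 0.0;
  for (int s = 0; s < 4; ++s) {
    const int *u = b + 3 * s;
    const int *v = b + 3 * (s + 1);
    double dx = (u[0] - v[0]) * sys.sp[0];
    double dy = (u[1] - v[1]) * sys.sp[1];
    double dz = (u[2] - v[2]) * sys.sp[2];
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dl = l - sys.leq[s];
    spring += 0.5 * sys.k[s] * dl * dl;
  }
  return spring + grid;
}

// [[Rcpp::export(name = ".run_level_cpp")]]
List run_level_cpp(IntegerMatrix conf0, NumericVector gcp, NumericVector lys,
                   LogicalVector forb, IntegerVector shape,
                   NumericVector spacing, NumericVector leq, NumericVector k,
                   double hardCore, double temperature, double kB,
                   int maxMoves, int maxAccepted, int maxDisp,
                   int recordEvery) {
  if (temperature <= 0) stop("temperature must be > 0");
  System sys;
  sys.gcp = REAL(gcp);
  sys.lys = REAL(lys);
  sys.forb = LOGICAL(forb);
  sys.n1 = shape[0]; sys.n2 = shape[1]; sys.n3 = shape[2];
  for (int d = 0; d < 3; ++d) sys.sp[d] = spacing[d];
  for (int s = 0; s < 4; ++s) { sys.leq[s] = leq[s]; sys.k[s] = k[s]; }
  sys.a2 = hardCore * hardCore;

  int b[15];
  for (int i = 0; i < 5; ++i)
    for (int d = 0; d < 3; ++d) b[3 * i + d] = conf0(i, d);

  double energy = totalEnergyC(sys, b);
  if (!R_finite(energy)) stop("current state has infinite energy");
  double best = energy;
  const double kT = kB * temperature;
  static const int mobile[4] = {0, 1, 3, 4};
  const int span = 2 * maxDisp + 1;

  int nRec = 0;
  IntegerMatrix traj;
  if (recordEvery > 0) {
    nRec = maxMoves / recordEvery + 1;
    traj = IntegerMatrix(nRec, 12);
  }
  int recRow = 0;

  int proposals = 0, acceptances = 0;
  int cand[15];
  while (proposals < maxMoves && acceptances < maxAccepted) {
    for (int i = 0; i < 15; ++i) cand[i] = b[i];
    int which = (int)(unif_rand() * 4.0);
    if (which > 3) which = 3;
    int bead = mobile[which];
    for (int d = 0; d < 3; ++d) {
      int step = (int)(unif_rand() * span);
      if (step >= span) step = span - 1;
      cand[3 * bead + d] += step - maxDisp;
    }
    double eNew = totalEnergyC(sys, cand);
    double dE = eNew - energy;
    bool accept;
    if (dE <= 0) {
      accept = true;
    } else if (!R_finite(dE)) {
      accept = false;
    } else {
      accept = unif_rand() < std::exp(-dE / kT);
    }
    if (accept) {
      for (int i = 0; i < 15; ++i) b[i] = cand[i];
      energy = eNew;
      if (energy < best) best = energy;
      ++acceptances;
    }
    ++proposals;
    if (recordEvery > 0 && proposals % recordEvery == 0 && recRow < nRec) {
      for (int t = 0; t < 4; ++t)
        for (int d = 0; d < 3; ++d)
          traj(recRow, 3 * t + d) = b[3 * mobile[t] + d];
      ++recRow;
    }
  }

  IntegerMatrix confOut(5, 3);
  for (int i = 0; i < 5; ++i)
    for (int d = 0; d < 3; ++d) confOut(i, d) = b[3 * i + d];

  List out = List::create(
      _["conf"] = confOut, _["energy"] = energy, _["bestEnergy"] = best,
      _["proposals"] = proposals, _["acceptances"] = acceptances);
  if (recordEvery > 0) {
    out["trajectory"] =
        traj(Range(0, recRow > 0 ? recRow - 1 : 0), Range(0, 11));
  }
  return out;
}
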