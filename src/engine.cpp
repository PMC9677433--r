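// Energy kernels and the NPT Metropolis Monte Carlo loop for a fixed ion in
// rigid four-site water with sharp molecule-based truncation.
//
// Layout of the flat force-field vector (see .ffPack in R/forcefield.R):
//   [0] sigmaO  [1] epsO  [2..13] site offsets row-major (O,H1,H2,M) x (x,y,z)
//   [14..17] site charges (O,H1,H2,M)
//
// The ion is pinned at the origin; oxygen positions are kept wrapped into
// [-L/2, L/2).  The image shift of a molecule pair is decided once from the
// oxygens, so truncation is all-or-nothing per pair of molecules.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KC = 332.06;          // kcal A / (mol e^2)
static const double KB = 1.9872041e-3;    // kcal / (mol K)
static const double ATM = 1.4584e-5;      // kcal / (mol A^3) per atm

struct FF {
  double sigO, epsO;
  double off[4][3];
  double chg[4];
  explicit FF(const NumericVector& p) {
    sigO = p[0]; epsO = p[1];
    for (int s = 0; s < 4; ++s)
      for (int d = 0; d < 3; ++d) off[s][d] = p[2 + 3 * s + d];
    for (int s = 0; s < 4; ++s) chg[s] = p[14 + s];
  }
};

static inline void quatToMat(const double* q, double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

// global site coordinates of water i: sites[4][3]
static inline void buildSites(const double* pos, const double* quat,
                              const FF& ff, double sites[4][3]) {
  double R[3][3];
  quatToMat(quat, R);
  for (int s = 0; s < 4; ++s)
    for (int d = 0; d < 3; ++d)
      sites[s][d] = pos[d] + R[d][0] * ff.off[s][0] + R[d][1] * ff.off[s][1] +
                    R[d][2] * ff.off[s][2];
}

static inline double ljE(double sig, double eps, double r2) {
  if (eps == 0.0 || sig == 0.0) return 0.0;
  double sr2 = sig * sig / r2;
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * sr6 * (sr6 - 1.0);
}

static inline double mimg(double x, double L) { return x - L * std::round(x / L); }

// water-water pair energy with molecule-based minimum image and truncation
static double pairWW(const double* pi, const double* pj,
                     const double si[4][3], const double sj[4][3],
                     double L, double rww2, const FF& ff) {
  double d[3], dm[3], shift[3], r2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    d[k] = pj[k] - pi[k];
    dm[k] = mimg(d[k], L);
    shift[k] = dm[k] - d[k];
    r2 += dm[k] * dm[k];
  }
  if (r2 >= rww2) return 0.0;
  double e = ljE(ff.sigO, ff.epsO, r2);
  for (int a = 1; a < 4; ++a) {
    for (int b = 1; b < 4; ++b) {
      double rr = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dd = sj[b][k] + shift[k] - si[a][k];
        rr += dd * dd;
      }
      e += KC * ff.chg[a] * ff.chg[b] / std::sqrt(rr);
    }
  }
  return e;
}

// ion (origin) - water i energy at coupling (lLJ, lQ)
static double ionWater(const double* pi, const double si[4][3], double L,
                       double riw2, const FF& ff, double qIon, double sigI,
                       double epsI, double lLJ, double lQ) {
  double dm[3], shift[3], r2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    dm[k] = mimg(pi[k], L);
    shift[k] = dm[k] - pi[k];
    r2 += dm[k] * dm[k];
  }
  if (r2 >= riw2) return 0.0;
  double sig = std::sqrt(lLJ * sigI * ff.sigO);
  double eps = std::sqrt(lLJ * epsI * ff.epsO);
  double e = ljE(sig, eps, r2);
  if (lQ != 0.0) {
    double qe = lQ * qIon;
    for (int a = 1; a < 4; ++a) {
      double rr = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dd = si[a][k] + shift[k];
        rr += dd * dd;
      }
      e += KC * qe * ff.chg[a] / std::sqrt(rr);
    }
  }
  return e;
}

struct System {
  int N;
  double L;
  std::vector<double> pos;            // 3N, wrapped
  std::vector<double> quat;           // 4N
  std::vector<double> sites;          // 12N
  FF ff;
  double riw, rww;
  double qIon, sigI, epsI, lLJ, lQ;

  System(const NumericMatrix& p, const NumericMatrix& q, double L_,
         const NumericVector& ffv, double riw_, double rww_, double qIon_,
         double sigI_, double epsI_, double lLJ_, double lQ_)
      : N(p.nrow()), L(L_), pos(3 * N), quat(4 * N), sites(12 * N), ff(ffv),
        riw(riw_), rww(rww_), qIon(qIon_), sigI(sigI_), epsI(epsI_),
        lLJ(lLJ_), lQ(lQ_) {
    for (int i = 0; i < N; ++i) {
      for (int d = 0; d < 3; ++d) pos[3 * i + d] = mimg(p(i, d), L);
      for (int d = 0; d < 4; ++d) quat[4 * i + d] = q(i, d);
      rebuild(i);
    }
  }

  void rebuild(int i) {
    double s[4][3];
    buildSites(&pos[3 * i], &quat[4 * i], ff, s);
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) sites[12 * i + 3 * a + d] = s[a][d];
  }

  typedef const double (*SitePtr)[3];
  SitePtr site(int i) const {
    return reinterpret_cast<SitePtr>(&sites[12 * i]);
  }

  double ionEnergyOne(int i, double lLJ_, double lQ_) const {
    return ionWater(&pos[3 * i], site(i), L, riw * riw, ff, qIon, sigI, epsI,
                    lLJ_, lQ_);
  }

  double ionEnergy(double lLJ_, double lQ_) const {
    double e = 0.0;
    for (int i = 0; i < N; ++i) e += ionEnergyOne(i, lLJ_, lQ_);
    return e;
  }

  double waterEnergy() const {
    double e = 0.0, rww2 = rww * rww;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j)
        e += pairWW(&pos[3 * i], &pos[3 * j], site(i), site(j), L, rww2, ff);
    return e;
  }

  double total() const { return waterEnergy() + ionEnergy(lLJ, lQ); }

  // interaction of molecule i with everything else (ion + other waters)
  double molEnergy(int i) const {
    double e = ionEnergyOne(i, lLJ, lQ), rww2 = rww * rww;
    for (int j = 0; j < N; ++j)
      if (j != i)
        e += pairWW(&pos[3 * i], &pos[3 * j], site(i), site(j), L, rww2, ff);
    return e;
  }
};

// [[Rcpp::export]]
double cppWaterWaterEnergy(NumericMatrix pos, NumericMatrix quat, double L,
                           NumericVector ff, double rww) {
  System s(pos, quat, L, ff, rww, rww, 0, 1, 1, 0, 0);
  return s.waterEnergy();
}

// [[Rcpp::export]]
double cppIonWaterEnergy(NumericMatrix pos, NumericMatrix quat, double L,
                         NumericVector ff, double riw, double qIon,
                         double sigI, double epsI, double lLJ, double lQ) {
  System s(pos, quat, L, ff, riw, riw, qIon, sigI, epsI, lLJ, lQ);
  return s.ionEnergy(lLJ, lQ);
}

static inline void randRotation(double maxRot, double* dq) {
  // random axis (Gaussian trick), uniform angle in [-maxRot, maxRot]
  double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
  double n = std::sqrt(ax * ax + ay * ay + az * az);
  if (n < 1e-12) { ax = 1; ay = 0; az = 0; n = 1; }
  double ang = (2.0 * unif_rand() - 1.0) * maxRot;
  double s = std::sin(ang / 2.0) / n;
  dq[0] = std::cos(ang / 2.0);
  dq[1] = ax * s; dq[2] = ay * s; dq[3] = az * s;
}

static inline void quatMul(const double* a, const double* b, double* out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// Metropolis NPT run.  perturb: nPert x 2 matrix of (lambdaLJ', lambdaQ')
// couplings at which ion-water perturbation energies are collected every
// `stride` trials (relative to the reference coupling).
// [[Rcpp::export]]
List cppRunMC(NumericMatrix pos, NumericMatrix quat, double L,
              NumericVector ff, double riw, double rww, double qIon,
              double sigI, double epsI, double lLJ, double lQ, double tempK,
              double pAtm, int nTrials, double maxTrans, double maxRot,
              double maxVol, double pVolMove, NumericMatrix perturb,
              int stride, int sampleStride, int checkInterval,
              double driftTol) {
  System s(pos, quat, L, ff, riw, rww, qIon, sigI, epsI, lLJ, lQ);
  const int N = s.N;
  const double beta = 1.0 / (KB * tempK);
  double U = s.total();
  double Uref0 = U;
  double maxDrift = 0.0;

  long accT = 0, nT = 0, accV = 0, nV = 0;
  const int nPert = perturb.nrow();
  std::vector<double> dE;
  std::vector<double> eTrace, vTrace;

  std::vector<double> oldPos(3), oldQuat(4), oldSites(12);

  for (int t = 1; t <= nTrials; ++t) {
    if (N > 0 && unif_rand() >= pVolMove) {
      // combined translation + rotation of one random water
      int i = (int)(unif_rand() * N); if (i == N) i = N - 1;
      ++nT;
      double eOld = s.molEnergy(i);
      std::copy(&s.pos[3 * i], &s.pos[3 * i + 3], oldPos.begin());
      std::copy(&s.quat[4 * i], &s.quat[4 * i + 4], oldQuat.begin());
      std::copy(&s.sites[12 * i], &s.sites[12 * i + 12], oldSites.begin());
      for (int d = 0; d < 3; ++d)
        s.pos[3 * i + d] =
            mimg(s.pos[3 * i + d] + (2.0 * unif_rand() - 1.0) * maxTrans, s.L);
      double dq[4], qn[4];
      randRotation(maxRot, dq);
      quatMul(dq, &s.quat[4 * i], qn);
      double nrm = std::sqrt(qn[0] * qn[0] + qn[1] * qn[1] + qn[2] * qn[2] +
                             qn[3] * qn[3]);
      for (int d = 0; d < 4; ++d) s.quat[4 * i + d] = qn[d] / nrm;
      s.rebuild(i);
      double dU = s.molEnergy(i) - eOld;
      if (dU <= 0.0 || unif_rand() < std::exp(-beta * dU)) {
        U += dU;
        ++accT;
      } else {
        std::copy(oldPos.begin(), oldPos.end(), &s.pos[3 * i]);
        std::copy(oldQuat.begin(), oldQuat.end(), &s.quat[4 * i]);
        std::copy(oldSites.begin(), oldSites.end(), &s.sites[12 * i]);
      }
    } else {
      // volume move, linear in V; molecule centers scale, geometry rigid
      ++nV;
      double V = s.L * s.L * s.L;
      double Vn = V + (2.0 * unif_rand() - 1.0) * maxVol;
      if (Vn > 0.0) {
        double sc = std::cbrt(Vn / V), Ln = s.L * sc;
        bool ok = (s.riw <= Ln / 2.0 && s.rww <= Ln / 2.0) || N == 0;
        if (ok) {
          double Lold = s.L;
          std::vector<double> posOld(s.pos);
          for (int k = 0; k < 3 * N; ++k) s.pos[k] *= sc;
          s.L = Ln;
          for (int i = 0; i < N; ++i) s.rebuild(i);
          double Un = s.total();
          double w = (Un - U) + pAtm * ATM * (Vn - V) -
                     N * KB * tempK * std::log(Vn / V);
          if (w <= 0.0 || unif_rand() < std::exp(-beta * w)) {
            U = Un;
            ++accV;
          } else {
            s.pos = posOld;
            s.L = Lold;
            for (int i = 0; i < N; ++i) s.rebuild(i);
          }
        }
      }
    }

    if (stride > 0 && nPert > 0 && t % stride == 0) {
      double eRef = s.ionEnergy(lLJ, lQ);
      for (int p = 0; p < nPert; ++p)
        dE.push_back(s.ionEnergy(perturb(p, 0), perturb(p, 1)) - eRef);
    }
    if (sampleStride > 0 && t % sampleStride == 0) {
      eTrace.push_back(U);
      vTrace.push_back(s.L * s.L * s.L);
    }
    if (checkInterval > 0 && t % checkInterval == 0) {
      double Ufull = s.total();
      double drift = std::fabs(Ufull - U);
      if (drift > maxDrift) maxDrift = drift;
      if (drift > driftTol)
        stop("energy bookkeeping drift %g kcal/mol exceeds tolerance %g "
             "after %d trials", drift, driftTol, t);
    }
  }

  NumericMatrix posOut(N, 3), quatOut(N, 4);
  for (int i = 0; i < N; ++i) {
    for (int d = 0; d < 3; ++d) posOut(i, d) = s.pos[3 * i + d];
    for (int d = 0; d < 4; ++d) quatOut(i, d) = s.quat[4 * i + d];
  }
  NumericMatrix dEout(nPert > 0 && stride > 0 ? dE.size() / nPert : 0, nPert);
  for (int r = 0; r < dEout.nrow(); ++r)
    for (int p = 0; p < nPert; ++p) dEout(r, p) = dE[r * nPert + p];

  return List::create(
      _["positions"] = posOut, _["quaternions"] = quatOut, _["L"] = s.L,
      _["energy"] = U, _["initialEnergy"] = Uref0,
      _["accTrans"] = (double)accT, _["nTrans"] = (double)nT,
      _["accVol"] = (double)accV, _["nVol"] = (double)nV,
      _["energyTrace"] = wrap(eTrace), _["volumeTrace"] = wrap(vTrace),
      _["dE"] = dEout, _["maxDrift"] = maxDrift);
}
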