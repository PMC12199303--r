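// Geometry kernels: NeRF chain construction, dihedrals, Kabsch superposition,
// the Salpha window sum, clash detection, and the pivot Monte-Carlo refiner.
// All coordinates here are in Angstrom; the R layer owns the nm conversion.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Place atom D given positions A, B, C, the C-D bond length, the B-C-D
// angle (degrees) and the A-B-C-D dihedral (degrees).
static arma::rowvec nerf_place(const arma::rowvec& A, const arma::rowvec& B,
                               const arma::rowvec& C, double bond,
                               double angle_deg, double dihedral_deg) {
  arma::rowvec bc = C - B, ab = B - A;
  arma::rowvec bch = bc / arma::norm(bc);
  arma::rowvec n = arma::cross(ab, bch);
  double nn = arma::norm(n);
  if (nn < 1e-12) { // collinear reference: pick any perpendicular
    arma::rowvec tmp = {1.0, 0.0, 0.0};
    if (std::abs(arma::dot(tmp, bch)) > 0.9) tmp = {0.0, 1.0, 0.0};
    n = arma::cross(tmp, bch);
    nn = arma::norm(n);
  }
  n /= nn;
  arma::rowvec m = arma::cross(n, bch);
  double th = angle_deg * DEG, chi = dihedral_deg * DEG;
  // sign of the out-of-plane component chosen so that the measured
  // A-B-C-D dihedral (IUPAC convention) equals the requested one
  arma::rowvec d2 = {-bond * std::cos(th),
                     bond * std::sin(th) * std::cos(chi),
                     -bond * std::sin(th) * std::sin(chi)};
  return C + d2(0) * bch + d2(1) * m + d2(2) * n;
}

// [[Rcpp::export(name = ".cpp_nerf_place")]]
NumericVector cpp_nerf_place(NumericVector A, NumericVector B, NumericVector C,
                             double bond, double angle_deg, double dihedral_deg) {
  arma::rowvec a(A.begin(), 3), b(B.begin(), 3), c(C.begin(), 3);
  arma::rowvec d = nerf_place(a, b, c, bond, angle_deg, dihedral_deg);
  return NumericVector::create(d(0), d(1), d(2));
}

// Ideal backbone covalent geometry (Angstrom / degrees).
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329,
                    B_C_O = 1.231, B_N_H = 1.010;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7,
                    A_CA_C_O = 120.8, A_C_N_H = 119.0;

// Backbone with atoms N, H, CA, C, O per residue (5 atoms each), built from
// phi/psi (degrees) with omega fixed at 180. phi[0] and psi[n-1] only affect
// terminal H/O placement.
static arma::mat build_backbone(const arma::vec& phi, const arma::vec& psi) {
  int n = phi.n_elem;
  arma::mat X(5 * n, 3, arma::fill::zeros);
  // indices within residue i: N=5i, H=5i+1, CA=5i+2, C=5i+3, O=5i+4
  arma::rowvec N0 = {0.0, 0.0, 0.0};
  arma::rowvec CA0 = {B_N_CA, 0.0, 0.0};
  double th = (180.0 - A_N_CA_C) * DEG;
  arma::rowvec C0 = CA0 + arma::rowvec({B_CA_C * std::cos(th), B_CA_C * std::sin(th), 0.0});
  X.row(0) = N0; X.row(2) = CA0; X.row(3) = C0;
  for (int i = 1; i < n; ++i) {
    arma::rowvec Np = X.row(5 * (i - 1));
    arma::rowvec CAp = X.row(5 * (i - 1) + 2);
    arma::rowvec Cp = X.row(5 * (i - 1) + 3);
    arma::rowvec Ni = nerf_place(Np, CAp, Cp, B_C_N, A_CA_C_N, psi(i - 1));
    arma::rowvec CAi = nerf_place(CAp, Cp, Ni, B_N_CA, A_C_N_CA, 180.0);
    arma::rowvec Ci = nerf_place(Cp, Ni, CAi, B_CA_C, A_N_CA_C, phi(i));
    X.row(5 * i) = Ni; X.row(5 * i + 2) = CAi; X.row(5 * i + 3) = Ci;
    // amide hydrogen: anti to CA(i) across the C(i-1)-N(i) bond
    X.row(5 * i + 1) = nerf_place(CAp, Cp, Ni, B_N_H, A_C_N_H, 0.0);
  }
  // carbonyl O: dihedral N-CA-C-O = psi + 180
  for (int i = 0; i < n; ++i) {
    arma::rowvec Ni = X.row(5 * i), CAi = X.row(5 * i + 2), Ci = X.row(5 * i + 3);
    X.row(5 * i + 4) = nerf_place(Ni, CAi, Ci, B_C_O, A_CA_C_O, psi(i) + 180.0);
  }
  // first-residue H: placed from C(0), CA(0), N(0)
  X.row(1) = nerf_place(X.row(3), X.row(2), X.row(0), B_N_H, A_C_N_H, 180.0);
  return X;
}

// [[Rcpp::export(name = ".cpp_build_backbone")]]
NumericMatrix cpp_build_backbone(NumericVector phi, NumericVector psi) {
  arma::vec p(phi.begin(), phi.size()), s(psi.begin(), psi.size());
  return wrap(build_backbone(p, s));
}

static double dihedral(const arma::rowvec& p1, const arma::rowvec& p2,
                       const arma::rowvec& p3, const arma::rowvec& p4) {
  arma::rowvec b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  arma::rowvec n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
  arma::rowvec m1 = arma::cross(n1, b2 / arma::norm(b2));
  double x = arma::dot(n1, n2), y = arma::dot(m1, n2);
  return std::atan2(y, x) / DEG;
}

// [[Rcpp::export(name = ".cpp_dihedral")]]
double cpp_dihedral(NumericVector p1, NumericVector p2, NumericVector p3,
                    NumericVector p4) {
  arma::rowvec a(p1.begin(), 3), b(p2.begin(), 3), c(p3.begin(), 3), d(p4.begin(), 3);
  return dihedral(a, b, c, d);
}

// phi/psi (degrees) from a 5-atoms-per-residue backbone block.
// phi undefined for residue 1, psi undefined for residue n (NA).
static arma::mat backbone_phipsi(const arma::mat& X, int n) {
  arma::mat out(n, 2);
  out.fill(arma::datum::nan);
  for (int i = 1; i < n; ++i)
    out(i, 0) = dihedral(X.row(5 * (i - 1) + 3), X.row(5 * i),
                         X.row(5 * i + 2), X.row(5 * i + 3));
  for (int i = 0; i + 1 < n; ++i)
    out(i, 1) = dihedral(X.row(5 * i), X.row(5 * i + 2), X.row(5 * i + 3),
                         X.row(5 * (i + 1)));
  return out;
}

// [[Rcpp::export(name = ".cpp_backbone_phipsi")]]
NumericMatrix cpp_backbone_phipsi(NumericMatrix X, int n_res) {
  arma::mat x(X.begin(), X.nrow(), 3, false);
  return wrap(backbone_phipsi(x, n_res));
}

// Minimal RMSD after optimal superposition (Kabsch, proper rotations only).
static double kabsch_rmsd(const arma::mat& A, const arma::mat& B) {
  arma::mat Ac = A.each_row() - arma::mean(A, 0);
  arma::mat Bc = B.each_row() - arma::mean(B, 0);
  arma::mat H = Ac.t() * Bc;
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::vec corr = {1.0, 1.0, d >= 0 ? 1.0 : -1.0};
  arma::mat R = V * arma::diagmat(corr) * U.t();
  arma::mat Ar = Ac * R.t();
  return std::sqrt(arma::accu(arma::square(Ar - Bc)) / A.n_rows);
}

// [[Rcpp::export(name = ".cpp_kabsch_rmsd")]]
double cpp_kabsch_rmsd(NumericMatrix A, NumericMatrix B) {
  arma::mat a(A.begin(), A.nrow(), 3, false), b(B.begin(), B.nrow(), 3, false);
  return kabsch_rmsd(a, b);
}

// All-to-all RMSD over frames: coords is (n_frames x (3*m)) with xyz triplets
// per selected atom, row-frame layout.
// [[Rcpp::export(name = ".cpp_rmsd_matrix")]]
NumericMatrix cpp_rmsd_matrix(NumericMatrix coords) {
  int nf = coords.nrow(), m = coords.ncol() / 3;
  arma::mat C(coords.begin(), nf, coords.ncol(), false);
  NumericMatrix D(nf, nf);
  std::vector<arma::mat> frames(nf);
  for (int i = 0; i < nf; ++i) {
    arma::mat F(m, 3);
    for (int a = 0; a < m; ++a)
      for (int k = 0; k < 3; ++k) F(a, k) = C(i, 3 * a + k);
    frames[i] = F;
  }
  for (int i = 0; i < nf; ++i)
    for (int j = i + 1; j < nf; ++j) {
      double r = kabsch_rmsd(frames[i], frames[j]);
      D(i, j) = r; D(j, i) = r;
    }
  return D;
}

static double salpha_term_c(double rmsd, double r0) {
  double x = rmsd / r0;
  if (std::abs(x - 1.0) < 1e-9) return 2.0 / 3.0;
  double x4 = x * x * x * x, x8 = x4 * x4;
  return (1.0 - x8) / (1.0 - x8 * x4);
}

// Salpha over all 7-residue CA windows; ca is (n_res x 3), tmpl is (7 x 3),
// both in Angstrom.
// [[Rcpp::export(name = ".cpp_salpha")]]
double cpp_salpha(NumericMatrix ca, NumericMatrix tmpl, double r0) {
  arma::mat C(ca.begin(), ca.nrow(), 3, false);
  arma::mat T(tmpl.begin(), 7, 3, false);
  int n = C.n_rows;
  double s = 0.0;
  for (int i = 0; i + 6 < n; ++i)
    s += salpha_term_c(kabsch_rmsd(C.rows(i, i + 6), T), r0);
  return s;
}

static double rg_of(const arma::mat& X, const arma::vec& mass) {
  arma::rowvec com = (mass.t() * X) / arma::accu(mass);
  arma::mat d = X.each_row() - com;
  return std::sqrt(arma::dot(mass, arma::sum(arma::square(d), 1)) / arma::accu(mass));
}

// [[Rcpp::export(name = ".cpp_rg")]]
double cpp_rg(NumericMatrix X, NumericVector mass) {
  arma::mat x(X.begin(), X.nrow(), 3, false);
  arma::vec m(mass.begin(), mass.size(), false);
  return rg_of(x, m);
}

// Count of non-bonded heavy-atom pairs below `floor_d`; atoms with residue
// separation <= 1 are excluded as bonded neighbourhood.
static int clash_count(const arma::mat& X, const arma::ivec& res, double floor_d) {
  int n = X.n_rows, c = 0;
  double f2 = floor_d * floor_d;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (std::abs(res(i) - res(j)) <= 1) continue;
      double dx = X(i,0)-X(j,0), dy = X(i,1)-X(j,1), dz = X(i,2)-X(j,2);
      if (dx*dx + dy*dy + dz*dz < f2) ++c;
    }
  return c;
}

// [[Rcpp::export(name = ".cpp_clash_count")]]
int cpp_clash_count(NumericMatrix X, IntegerVector resindex, double floor_d) {
  arma::mat x(X.begin(), X.nrow(), 3, false);
  arma::ivec r(resindex.size());
  for (int i = 0; i < resindex.size(); ++i) r(i) = resindex[i];
  return clash_count(x, r, floor_d);
}

static void draw_residue(int helix, double* phi, double* psi) {
  if (helix) {
    *phi = -57.0 + 5.0 * R::rnorm(0.0, 1.0);
    *psi = -47.0 + 5.0 * R::rnorm(0.0, 1.0);
  } else {
    *phi = R::runif(-180.0, -30.0);
    if (R::runif(0.0, 1.0) < 120.0 / 150.0) *psi = R::runif(60.0, 180.0);
    else *psi = R::runif(-180.0, -150.0);
  }
}

// Pivot Monte-Carlo refinement of one frame. Heavy atoms (N, CA, C, O) enter
// the clash test and the Rg restraint; kT = 1. Phase 1 removes steric clashes
// by greedy resampling; phase 2 runs Metropolis sweeps on the harmonic Rg
// restraint with a hard steric core. Uses R's RNG, so set.seed() governs.
// [[Rcpp::export(name = ".cpp_mc_frame")]]
List cpp_mc_frame(NumericVector phi0, NumericVector psi0, IntegerVector state,
                  double rg_target, double k_rg, double clash_floor,
                  int sweeps, int max_clash_tries) {
  int n = phi0.size();
  arma::vec phi(phi0.begin(), n), psi(psi0.begin(), n);
  arma::ivec st(n);
  for (int i = 0; i < n; ++i) st(i) = state[i];
  // heavy atom rows within the 5-per-residue block: N(0), CA(2), C(3), O(4)
  arma::uvec hv(4 * n); arma::ivec hres(4 * n); arma::vec hmass(4 * n);
  const int off[4] = {0, 2, 3, 4};
  const double ms[4] = {14.007, 12.011, 12.011, 15.999};
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 4; ++k) {
      hv(4 * i + k) = 5 * i + off[k];
      hres(4 * i + k) = i;
      hmass(4 * i + k) = ms[k];
    }
  arma::mat X = build_backbone(phi, psi);
  arma::mat H = X.rows(hv);
  int cl = clash_count(H, hres, clash_floor);
  int tries = 0;
  while (cl > 0 && tries < max_clash_tries) {
    ++tries;
    int j = (int)std::floor(R::runif(0.0, (double)n));
    if (j >= n) j = n - 1;
    double np, ns;
    draw_residue(st(j), &np, &ns);
    double op = phi(j), os = psi(j);
    phi(j) = np; psi(j) = ns;
    arma::mat Xn = build_backbone(phi, psi);
    arma::mat Hn = Xn.rows(hv);
    int cln = clash_count(Hn, hres, clash_floor);
    if (cln <= cl) { X = Xn; H = Hn; cl = cln; }
    else { phi(j) = op; psi(j) = os; }
  }
  bool resolved = (cl == 0);
  double rg = rg_of(H, hmass);
  if (resolved && k_rg > 0.0 && sweeps > 0) {
    // rg_target/k_rg arrive in nm / kT nm^-2; geometry is in Angstrom
    double e = k_rg * std::pow(rg / 10.0 - rg_target, 2.0);
    for (int sw = 0; sw < sweeps; ++sw)
      for (int t = 0; t < n; ++t) {
        int j = (int)std::floor(R::runif(0.0, (double)n));
        if (j >= n) j = n - 1;
        double np, ns;
        draw_residue(st(j), &np, &ns);
        double op = phi(j), os = psi(j);
        phi(j) = np; psi(j) = ns;
        arma::mat Xn = build_backbone(phi, psi);
        arma::mat Hn = Xn.rows(hv);
        if (clash_count(Hn, hres, clash_floor) > 0) { phi(j) = op; psi(j) = os; continue; }
        double rgn = rg_of(Hn, hmass);
        double en = k_rg * std::pow(rgn / 10.0 - rg_target, 2.0);
        if (en <= e || R::runif(0.0, 1.0) < std::exp(e - en)) {
          X = Xn; H = Hn; rg = rgn; e = en;
        } else { phi(j) = op; psi(j) = os; }
      }
  }
  return List::create(_["coords"] = wrap(X), _["phi"] = wrap(phi),
                      _["psi"] = wrap(psi), _["clashes"] = cl,
                      _["resolved"] = resolved, _["rg"] = rg);
}
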