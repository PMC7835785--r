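// Grid-based ELF/basin machinery: GTO evaluation, steepest-ascent basin
// assignment, basin integrals (n, T, domain overlap matrices), and coarse
// 6D quadrature for inter-basin Coulomb/exchange terms.
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Basis {
  int nsh = 0, nbf = 0;
  std::vector<int> l, pstart, nprim, off;
  std::vector<double> cx, cy, cz; // shell centers
  std::vector<double> pexp, pcoef;
  std::vector<double> rcut2;
  // component tables per l
  static const int compx[3][6], compy[3][6], compz[3][6];
  static const double compf[3][6];
  static int ncomp(int l) { return l == 0 ? 1 : (l == 1 ? 3 : 6); }
};

const int Basis::compx[3][6] = {{0,0,0,0,0,0},{1,0,0,0,0,0},{2,0,0,1,1,0}};
const int Basis::compy[3][6] = {{0,0,0,0,0,0},{0,1,0,0,0,0},{0,2,0,1,0,1}};
const int Basis::compz[3][6] = {{0,0,0,0,0,0},{0,0,1,0,0,0},{0,0,2,0,1,1}};
// sqrt((2l-1)!! / prod (2li-1)!!)
const double Basis::compf[3][6] = {
  {1,0,0,0,0,0}, {1,1,1,0,0,0},
  {1,1,1,1.7320508075688772,1.7320508075688772,1.7320508075688772}};

Basis make_basis(const List& sh) {
  Basis b;
  IntegerVector l = sh["l"], pstart = sh["pstart"], nprim = sh["nprim"];
  NumericMatrix cen = sh["center"];
  NumericVector pe = sh["pexp"], pc = sh["pcoef"];
  b.nsh = l.size();
  b.l.assign(l.begin(), l.end());
  b.pstart.assign(pstart.begin(), pstart.end());
  b.nprim.assign(nprim.begin(), nprim.end());
  b.pexp.assign(pe.begin(), pe.end());
  b.pcoef.assign(pc.begin(), pc.end());
  b.off.resize(b.nsh);
  int n = 0;
  for (int s = 0; s < b.nsh; ++s) { b.off[s] = n; n += Basis::ncomp(b.l[s]); }
  b.nbf = n;
  b.cx.resize(b.nsh); b.cy.resize(b.nsh); b.cz.resize(b.nsh);
  b.rcut2.resize(b.nsh);
  for (int s = 0; s < b.nsh; ++s) {
    b.cx[s] = cen(s, 0); b.cy[s] = cen(s, 1); b.cz[s] = cen(s, 2);
    double amin = 1e30, cmax = 0.0;
    for (int p = 0; p < b.nprim[s]; ++p) {
      amin = std::min(amin, b.pexp[b.pstart[s] + p]);
      cmax = std::max(cmax, std::fabs(b.pcoef[b.pstart[s] + p]));
    }
    // |c| r^l exp(-a r^2) < 1e-14 bound (crude, generous)
    b.rcut2[s] = (std::log(std::max(cmax, 1.0)) + 34.5) / amin;
  }
  return b;
}

// Evaluate basis values (and first derivatives if dchi != nullptr) at one
// batch of points. chi: np x nbf (column-major as arma).
void eval_chunk(const Basis& b, const arma::mat& pts, arma::mat& chi,
                arma::mat* dchix, arma::mat* dchiy, arma::mat* dchiz) {
  const int np = pts.n_rows;
  chi.zeros(np, b.nbf);
  if (dchix) { dchix->zeros(np, b.nbf); dchiy->zeros(np, b.nbf); dchiz->zeros(np, b.nbf); }
  for (int s = 0; s < b.nsh; ++s) {
    const int l = b.l[s], nc = Basis::ncomp(l);
    for (int p = 0; p < np; ++p) {
      const double dx = pts(p, 0) - b.cx[s];
      const double dy = pts(p, 1) - b.cy[s];
      const double dz = pts(p, 2) - b.cz[s];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > b.rcut2[s]) continue;
      double g0 = 0.0, g1 = 0.0;
      for (int ip = 0; ip < b.nprim[s]; ++ip) {
        const double a = b.pexp[b.pstart[s] + ip];
        const double e = b.pcoef[b.pstart[s] + ip] * std::exp(-a * r2);
        g0 += e;
        g1 += -2.0 * a * e;
      }
      const double pw[3][3] = {{1, dx, dx * dx}, {1, dy, dy * dy}, {1, dz, dz * dz}};
      for (int m = 0; m < nc; ++m) {
        const int i = Basis::compx[l][m], j = Basis::compy[l][m], k = Basis::compz[l][m];
        const double px = pw[0][i], py = pw[1][j], pz = pw[2][k];
        const double poly = px * py * pz;
        const double f = Basis::compf[l][m];
        const int idx = b.off[s] + m;
        chi(p, idx) = f * poly * g0;
        if (dchix) {
          const double dpx = i > 0 ? i * pw[0][i - 1] : 0.0;
          const double dpy = j > 0 ? j * pw[1][j - 1] : 0.0;
          const double dpz = k > 0 ? k * pw[2][k - 1] : 0.0;
          (*dchix)(p, idx) = f * (dpx * py * pz * g0 + poly * g1 * dx);
          (*dchiy)(p, idx) = f * (px * dpy * pz * g0 + poly * g1 * dy);
          (*dchiz)(p, idx) = f * (px * py * dpz * g0 + poly * g1 * dz);
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_eval_fields(List shells, const arma::mat& C, const arma::vec& occ,
                     const arma::mat& pts, bool want_mo) {
  Basis b = make_basis(shells);
  const int np = pts.n_rows, nocc = C.n_cols;
  arma::vec rho(np), tau(np);
  arma::mat grad(np, 3);
  arma::mat mo;
  if (want_mo) mo.set_size(np, nocc);
  const int chunk = 20000;
  arma::mat chi, dx_, dy_, dz_;
  for (int s0 = 0; s0 < np; s0 += chunk) {
    const int s1 = std::min(np, s0 + chunk);
    arma::mat sub = pts.rows(s0, s1 - 1);
    eval_chunk(b, sub, chi, &dx_, &dy_, &dz_);
    arma::mat m = chi * C;           // (m x nocc)
    arma::mat mx = dx_ * C, my = dy_ * C, mz = dz_ * C;
    arma::vec r = (arma::square(m) * occ);
    arma::vec t = 0.5 * (arma::square(mx) + arma::square(my) + arma::square(mz)) * occ;
    rho.subvec(s0, s1 - 1) = r;
    tau.subvec(s0, s1 - 1) = t;
    grad.submat(s0, 0, s1 - 1, 0) = 2.0 * ((m % mx) * occ);
    grad.submat(s0, 1, s1 - 1, 1) = 2.0 * ((m % my) * occ);
    grad.submat(s0, 2, s1 - 1, 2) = 2.0 * ((m % mz) * occ);
    if (want_mo) mo.rows(s0, s1 - 1) = m;
  }
  List out = List::create(_["rho"] = rho, _["grad_rho"] = grad, _["tau"] = tau);
  if (want_mo) out["mo_values"] = mo;
  return out;
}

static inline void grid_point(const arma::vec& o, const arma::vec& h,
                              const IntegerVector& dims, int ix, int iy, int iz,
                              double* xyz) {
  xyz[0] = o[0] + ix * h[0];
  xyz[1] = o[1] + iy * h[1];
  xyz[2] = o[2] + iz * h[2];
}

// rho, |grad rho|^2, tau on a regular grid (x fastest). Streams in slabs.
// [[Rcpp::export]]
List cpp_grid_fields(List shells, const arma::mat& C, const arma::vec& occ,
                     const arma::vec& origin, const arma::vec& spacing,
                     const IntegerVector& dims) {
  Basis b = make_basis(shells);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long ntot = (long)nx * ny * nz;
  NumericVector rho(ntot), gradsq(ntot), tau(ntot);
  arma::mat chi, dx_, dy_, dz_;
  arma::mat pts(nx * ny, 3);
  for (int iz = 0; iz < nz; ++iz) {
    long base = (long)iz * nx * ny;
    int q = 0;
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++q) {
        double xyz[3];
        grid_point(origin, spacing, dims, ix, iy, iz, xyz);
        pts(q, 0) = xyz[0]; pts(q, 1) = xyz[1]; pts(q, 2) = xyz[2];
      }
    eval_chunk(b, pts, chi, &dx_, &dy_, &dz_);
    arma::mat m = chi * C;
    arma::mat mx = dx_ * C, my = dy_ * C, mz = dz_ * C;
    arma::vec r = arma::square(m) * occ;
    arma::vec t = 0.5 * (arma::square(mx) + arma::square(my) + arma::square(mz)) * occ;
    arma::vec gx = 2.0 * ((m % mx) * occ), gy = 2.0 * ((m % my) * occ),
              gz = 2.0 * ((m % mz) * occ);
    for (int q2 = 0; q2 < nx * ny; ++q2) {
      rho[base + q2] = r[q2];
      gradsq[base + q2] = gx[q2] * gx[q2] + gy[q2] * gy[q2] + gz[q2] * gz[q2];
      tau[base + q2] = t[q2];
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["rho"] = rho, _["gradsq"] = gradsq, _["tau"] = tau);
}

// Discrete steepest ascent over the 26-neighbour stencil with path
// compression. Returns for each voxel the linear index (1-based) of its
// attractor voxel, or 0 for masked (vacuum) voxels.
// [[Rcpp::export]]
IntegerVector cpp_basin_ascent(const NumericVector& field,
                               const IntegerVector& dims,
                               const LogicalVector& vacuum,
                               double plateau_tol) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long ntot = (long)nx * ny * nz;
  std::vector<long> up(ntot, -2); // -2 unset, -1 vacuum, self => attractor
  for (long i = 0; i < ntot; ++i) if (vacuum[i]) up[i] = -1;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const long i = (long)iz * nx * ny + (long)iy * nx + ix;
        if (up[i] == -1) continue;
        // steepest positive slope (value difference over neighbour
        // distance); slope ties broken by lowest linear index. If no strict
        // uphill neighbour exists, exactly-equal-valued neighbours with a
        // lower linear index absorb the voxel (collapses exact plateaus);
        // otherwise it is an attractor. Every move strictly increases
        // (value, -index) lexicographically, so paths terminate.
        const double f0 = field[i];
        double bestslope = 0.0;
        long bestj = -1;
        long eqj = -1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dxx = -1; dxx <= 1; ++dxx) {
              if (dxx == 0 && dy == 0 && dz == 0) continue;
              const int jx = ix + dxx, jy = iy + dy, jz = iz + dz;
              if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
                continue;
              const long j = (long)jz * nx * ny + (long)jy * nx + jx;
              if (up[j] == -1) continue;
              const double df = field[j] - f0;
              if (df > 0.0) {
                const double s = df / std::sqrt((double)(dxx * dxx + dy * dy
                                                         + dz * dz));
                if (s > bestslope * (1.0 + 1e-12)) {
                  bestslope = s;
                  bestj = j;
                } else if (s >= bestslope * (1.0 - 1e-12) && j < bestj) {
                  bestj = j;
                }
              } else if (df == 0.0 && j < i && (eqj < 0 || j < eqj)) {
                eqj = j;
              }
            }
        up[i] = bestj >= 0 ? bestj : (eqj >= 0 ? eqj : i);
      }
  // path compression
  IntegerVector lab(ntot);
  std::vector<long> stack;
  for (long i = 0; i < ntot; ++i) {
    if (up[i] == -1) { lab[i] = 0; continue; }
    long j = i;
    stack.clear();
    while (up[j] != j) {
      stack.push_back(j);
      j = up[j];
      if ((long)stack.size() > ntot)
        stop("ascent path failed to terminate (degenerate field)");
    }
    for (long s : stack) up[s] = j;
    lab[i] = (int)(j + 1);
  }
  return lab;
}

// Counts of face/edge/corner adjacency between differently-labelled voxels.
// labels: 1..K (0 = vacuum). Returns K x K contact-count matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_basin_adjacency(const IntegerVector& labels,
                                  const IntegerVector& dims, int K) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerMatrix adj(K, K);
  const int sten[13][3] = {{1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},
                           {1,0,-1},{0,1,1},{0,1,-1},{1,1,1},{1,1,-1},
                           {1,-1,1},{1,-1,-1}};
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const long i = (long)iz * nx * ny + (long)iy * nx + ix;
        const int li = labels[i];
        if (li == 0) continue;
        for (int s = 0; s < 13; ++s) {
          const int jx = ix + sten[s][0], jy = iy + sten[s][1], jz = iz + sten[s][2];
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
            continue;
          const long j = (long)jz * nx * ny + (long)jy * nx + jx;
          const int lj = labels[j];
          if (lj == 0 || lj == li) continue;
          adj(li - 1, lj - 1)++;
          adj(lj - 1, li - 1)++;
        }
      }
  return adj;
}

// Basin populations, positive-definite kinetic energies and domain overlap
// matrices by Riemann voxel sums. labels: 1..K, 0 skipped.
// [[Rcpp::export]]
List cpp_integrate_basins(List shells, const arma::mat& C, const arma::vec& occ,
                          const arma::vec& origin, const arma::vec& spacing,
                          const IntegerVector& dims, const IntegerVector& labels,
                          int K) {
  Basis b = make_basis(shells);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nocc = C.n_cols;
  const double dV = spacing[0] * spacing[1] * spacing[2];
  arma::vec n(K, arma::fill::zeros), T(K, arma::fill::zeros);
  arma::cube S(nocc, nocc, K, arma::fill::zeros);
  arma::mat chi, dx_, dy_, dz_;
  arma::mat pts(nx, 3);
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      const long base = (long)iz * nx * ny + (long)iy * nx;
      bool any = false;
      for (int ix = 0; ix < nx; ++ix) if (labels[base + ix] > 0) { any = true; break; }
      if (!any) continue;
      for (int ix = 0; ix < nx; ++ix) {
        double xyz[3];
        grid_point(origin, spacing, dims, ix, iy, iz, xyz);
        pts(ix, 0) = xyz[0]; pts(ix, 1) = xyz[1]; pts(ix, 2) = xyz[2];
      }
      eval_chunk(b, pts, chi, &dx_, &dy_, &dz_);
      arma::mat m = chi * C;
      arma::mat mx = dx_ * C, my = dy_ * C, mz = dz_ * C;
      for (int ix = 0; ix < nx; ++ix) {
        const int lb = labels[base + ix];
        if (lb == 0) continue;
        const int k = lb - 1;
        double r = 0.0, t = 0.0;
        for (int o = 0; o < nocc; ++o) {
          r += occ[o] * m(ix, o) * m(ix, o);
          t += 0.5 * occ[o] * (mx(ix, o) * mx(ix, o) + my(ix, o) * my(ix, o)
                               + mz(ix, o) * mz(ix, o));
        }
        n[k] += r;
        T[k] += t;
        for (int o1 = 0; o1 < nocc; ++o1) {
          const double v1 = m(ix, o1);
          for (int o2 = 0; o2 <= o1; ++o2) S(o1, o2, k) += v1 * m(ix, o2);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  n *= dV;
  T *= dV;
  S *= dV;
  for (int k = 0; k < K; ++k)
    for (int o1 = 0; o1 < nocc; ++o1)
      for (int o2 = 0; o2 < o1; ++o2) S(o2, o1, k) = S(o1, o2, k);
  return List::create(_["n"] = n, _["T"] = T, _["S"] = S);
}

// Coarse-cell reduction of one basin: groups voxels of `basin` into cubic
// cells of `factor`^3 voxels; returns per-cell charge (electrons), centroid
// (charge-weighted), and orbital-pair products P_ij = int_cell phi_i phi_j.
// [[Rcpp::export]]
List cpp_cell_products(List shells, const arma::mat& C, const arma::vec& occ,
                       const arma::vec& origin, const arma::vec& spacing,
                       const IntegerVector& dims, const IntegerVector& labels,
                       int basin, int factor) {
  Basis b = make_basis(shells);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nocc = C.n_cols;
  const int npair = nocc * (nocc + 1) / 2;
  const double dV = spacing[0] * spacing[1] * spacing[2];
  const int cnx = (nx + factor - 1) / factor, cny = (ny + factor - 1) / factor,
            cnz = (nz + factor - 1) / factor;
  std::map<long, int> cellmap;
  std::vector<double> q, wx, wy, wz;
  std::vector<std::vector<double>> P;
  arma::mat chi, dx_, dy_, dz_;
  arma::mat pts(nx, 3);
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      const long base = (long)iz * nx * ny + (long)iy * nx;
      bool any = false;
      for (int ix = 0; ix < nx; ++ix) if (labels[base + ix] == basin) { any = true; break; }
      if (!any) continue;
      for (int ix = 0; ix < nx; ++ix) {
        double xyz[3];
        grid_point(origin, spacing, dims, ix, iy, iz, xyz);
        pts(ix, 0) = xyz[0]; pts(ix, 1) = xyz[1]; pts(ix, 2) = xyz[2];
      }
      eval_chunk(b, pts, chi, nullptr, nullptr, nullptr);
      arma::mat m = chi * C;
      for (int ix = 0; ix < nx; ++ix) {
        if (labels[base + ix] != basin) continue;
        const long ci = (long)(iz / factor) * cnx * cny
                        + (long)(iy / factor) * cnx + (ix / factor);
        auto it = cellmap.find(ci);
        int id;
        if (it == cellmap.end()) {
          id = (int)q.size();
          cellmap[ci] = id;
          q.push_back(0.0); wx.push_back(0.0); wy.push_back(0.0); wz.push_back(0.0);
          P.emplace_back(npair, 0.0);
        } else id = it->second;
        double r = 0.0;
        for (int o = 0; o < nocc; ++o) r += occ[o] * m(ix, o) * m(ix, o);
        const double qv = r * dV;
        q[id] += qv;
        wx[id] += qv * pts(ix, 0);
        wy[id] += qv * pts(ix, 1);
        wz[id] += qv * pts(ix, 2);
        int pp = 0;
        for (int o1 = 0; o1 < nocc; ++o1)
          for (int o2 = 0; o2 <= o1; ++o2, ++pp)
            P[id][pp] += m(ix, o1) * m(ix, o2) * dV;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  const int ncell = (int)q.size();
  NumericMatrix cells(ncell, 4);
  NumericMatrix Pm(ncell, npair);
  for (int i = 0; i < ncell; ++i) {
    const double qq = q[i];
    cells(i, 0) = qq > 0 ? wx[i] / qq : 0.0;
    cells(i, 1) = qq > 0 ? wy[i] / qq : 0.0;
    cells(i, 2) = qq > 0 ? wz[i] / qq : 0.0;
    cells(i, 3) = qq;
    for (int pp = 0; pp < npair; ++pp) Pm(i, pp) = P[i][pp];
  }
  return List::create(_["cells"] = cells, _["P"] = Pm);
}

// Coulomb and exchange interaction between two coarse-cell sets.
// Vcoul = sum qA qB / r ; Vx = -2 sum_ij sum_ab PA_ij(a) PB_ij(b) / r_ab
// (the ij sum runs over the symmetric pair packing with off-diagonal x2).
// [[Rcpp::export]]
List cpp_pair_interaction(const NumericMatrix& cellsA, const arma::mat& PA,
                          const NumericMatrix& cellsB, const arma::mat& PB,
                          int nocc, bool same) {
  const int na = cellsA.nrow(), nb = cellsB.nrow();
  const int npair = nocc * (nocc + 1) / 2;
  // pair weights: 1 for diagonal ij, 2 for off-diagonal
  arma::vec wpair(npair);
  {
    int pp = 0;
    for (int o1 = 0; o1 < nocc; ++o1)
      for (int o2 = 0; o2 <= o1; ++o2, ++pp) wpair[pp] = (o1 == o2) ? 1.0 : 2.0;
  }
  double vc = 0.0, vx = 0.0;
  for (int a = 0; a < na; ++a) {
    const double ax = cellsA(a, 0), ay = cellsA(a, 1), az = cellsA(a, 2),
                 aq = cellsA(a, 3);
    const int b0 = same ? a + 1 : 0;
    arma::rowvec pa = PA.row(a);
    for (int bb = b0; bb < nb; ++bb) {
      const double dx = ax - cellsB(bb, 0), dy = ay - cellsB(bb, 1),
                   dz = az - cellsB(bb, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-8) continue; // coincident coarse cells: self-term excluded
      const double inv = 1.0 / r;
      vc += aq * cellsB(bb, 3) * inv;
      double s = 0.0;
      const double* pav = pa.memptr();
      for (int pp = 0; pp < npair; ++pp) s += wpair[pp] * pav[pp] * PB(bb, pp);
      vx += s * inv;
    }
  }
  // closed-shell exchange of the pseudo one-determinant state
  vx *= -2.0;
  if (same) { vc *= 1.0; } // pairs counted once already
  return List::create(_["Vcoul"] = vc, _["Vx"] = vx);
}

// Electron-nuclear attraction of a coarse-cell set with one nucleus.
// [[Rcpp::export]]
double cpp_cells_nuclear(const NumericMatrix& cells, const arma::vec& nuc,
                         double Z) {
  double v = 0.0;
  for (int a = 0; a < cells.nrow(); ++a) {
    const double dx = cells(a, 0) - nuc[0], dy = cells(a, 1) - nuc[1],
                 dz = cells(a, 2) - nuc[2];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-8) continue;
    v -= Z * cells(a, 3) / r;
  }
  return v;
}

namespace {
// 1D Hermite E(i,j,0) overlap coefficient via recursion (s,p,d: i,j <= 2)
void fill_E0(double E[5][5][11], int la, int lb, double a, double bb, double AB) {
  const double p = a + bb, mu = a * bb / p;
  const double XPA = -bb / p * AB, XPB = a / p * AB;
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j)
      for (int t = 0; t < 11; ++t) E[i][j][t] = 0.0;
  E[0][0][0] = std::exp(-mu * AB * AB);
  for (int i = 0; i <= la; ++i)
    for (int j = 0; j <= lb; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double v = 0.0;
        if (j == 0) {
          v = XPA * E[i - 1][j][t];
          if (t > 0) v += E[i - 1][j][t - 1] / (2 * p);
          if (t + 1 <= i + j - 1) v += (t + 1) * E[i - 1][j][t + 1];
        } else {
          v = XPB * E[i][j - 1][t];
          if (t > 0) v += E[i][j - 1][t - 1] / (2 * p);
          if (t + 1 <= i + j - 1) v += (t + 1) * E[i][j - 1][t + 1];
        }
        E[i][j][t] = v;
      }
    }
}
} // namespace

// Analytic basis overlap matrix (Cartesian s/p/d shells).
// [[Rcpp::export]]
arma::mat cpp_overlap(List shells) {
  Basis b = make_basis(shells);
  arma::mat S(b.nbf, b.nbf, arma::fill::zeros);
  double Ex[5][5][11], Ey[5][5][11], Ez[5][5][11];
  for (int si = 0; si < b.nsh; ++si)
    for (int sj = 0; sj <= si; ++sj) {
      const int la = b.l[si], lb = b.l[sj];
      const int nca = Basis::ncomp(la), ncb = Basis::ncomp(lb);
      arma::mat blk(nca, ncb, arma::fill::zeros);
      for (int ip = 0; ip < b.nprim[si]; ++ip) {
        const double a = b.pexp[b.pstart[si] + ip];
        const double ca = b.pcoef[b.pstart[si] + ip];
        for (int jp = 0; jp < b.nprim[sj]; ++jp) {
          const double bb = b.pexp[b.pstart[sj] + jp];
          const double cb = b.pcoef[b.pstart[sj] + jp];
          const double p = a + bb, sp = std::sqrt(M_PI / p);
          fill_E0(Ex, la, lb, a, bb, b.cx[si] - b.cx[sj]);
          fill_E0(Ey, la, lb, a, bb, b.cy[si] - b.cy[sj]);
          fill_E0(Ez, la, lb, a, bb, b.cz[si] - b.cz[sj]);
          for (int ma = 0; ma < nca; ++ma) {
            const int ia = Basis::compx[la][ma], ja = Basis::compy[la][ma],
                      ka = Basis::compz[la][ma];
            for (int mb = 0; mb < ncb; ++mb) {
              const int ib = Basis::compx[lb][mb], jb = Basis::compy[lb][mb],
                        kb = Basis::compz[lb][mb];
              blk(ma, mb) += ca * cb * Basis::compf[la][ma] * Basis::compf[lb][mb]
                             * Ex[ia][ib][0] * Ey[ja][jb][0] * Ez[ka][kb][0]
                             * sp * sp * sp;
            }
          }
        }
      }
      for (int ma = 0; ma < nca; ++ma)
        for (int mb = 0; mb < ncb; ++mb) {
          S(b.off[si] + ma, b.off[sj] + mb) = blk(ma, mb);
          S(b.off[sj] + mb, b.off[si] + ma) = blk(ma, mb);
        }
    }
  return S;
}

// Max over boundary voxel pairs of min(field_i, field_j): the saddle height
// between adjacent basins. Entries stay -1 for non-adjacent pairs.
// [[Rcpp::export]]
NumericMatrix cpp_boundary_saddle(const IntegerVector& labels,
                                  const IntegerVector& dims,
                                  const NumericVector& field, int K) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix sad(K, K);
  std::fill(sad.begin(), sad.end(), -1.0);
  const int sten[13][3] = {{1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},
                           {1,0,-1},{0,1,1},{0,1,-1},{1,1,1},{1,1,-1},
                           {1,-1,1},{1,-1,-1}};
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        const long i = (long)iz * nx * ny + (long)iy * nx + ix;
        const int li = labels[i];
        if (li == 0) continue;
        for (int s = 0; s < 13; ++s) {
          const int jx = ix + sten[s][0], jy = iy + sten[s][1], jz = iz + sten[s][2];
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
            continue;
          const long j = (long)jz * nx * ny + (long)jy * nx + jx;
          const int lj = labels[j];
          if (lj == 0 || lj == li) continue;
          const double h = std::min(field[i], field[j]);
          if (h > sad(li - 1, lj - 1)) {
            sad(li - 1, lj - 1) = h;
            sad(lj - 1, li - 1) = h;
          }
        }
      }
  return sad;
}

namespace {
// trilinear interpolation of a grid field at a point (grid coords u in
// [0, n-1]); clamped at the box
double trilin(const NumericVector& f, const int nx, const int ny, const int nz,
              double ux, double uy, double uz) {
  ux = std::min(std::max(ux, 0.0), nx - 1.000001);
  uy = std::min(std::max(uy, 0.0), ny - 1.000001);
  uz = std::min(std::max(uz, 0.0), nz - 1.000001);
  const int i = (int)ux, j = (int)uy, k = (int)uz;
  const double fx = ux - i, fy = uy - j, fz = uz - k;
  double v = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy)
                         * (dz ? fz : 1 - fz);
        v += w * f[(long)(k + dz) * nx * ny + (long)(j + dy) * nx + (i + dx)];
      }
  return v;
}
} // namespace

// Basin integration with boundary-voxel subdivision: voxels whose 6-face
// neighbourhood is single-labelled are integrated at their centre; voxels on
// an inter-basin boundary are subdivided refine^3-fold and every sub-point is
// assigned by trilinear-gradient ascent of the field until it enters the
// interior of a basin.
// [[Rcpp::export]]
List cpp_integrate_basins_refined(List shells, const arma::mat& C,
                                  const arma::vec& occ, const arma::vec& origin,
                                  const arma::vec& spacing,
                                  const IntegerVector& dims,
                                  const IntegerVector& labels,
                                  const NumericVector& field, int K,
                                  int refine, const arma::mat& heavy_nuc,
                                  double refine_radius, double rho_skip) {
  Basis b = make_basis(shells);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nocc = C.n_cols;
  const double dV = spacing[0] * spacing[1] * spacing[2];
  arma::vec n(K, arma::fill::zeros), T(K, arma::fill::zeros);
  arma::cube S(nocc, nocc, K, arma::fill::zeros);
  // interior test: all 6 face neighbours share the label (vacuum ignored)
  auto lab_at = [&](int ix, int iy, int iz) -> int {
    return labels[(long)iz * nx * ny + (long)iy * nx + ix];
  };
  auto interior = [&](int ix, int iy, int iz) -> bool {
    const int l0 = lab_at(ix, iy, iz);
    if (l0 == 0) return true;
    const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int s = 0; s < 6; ++s) {
      const int jx = ix + d[s][0], jy = iy + d[s][1], jz = iz + d[s][2];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
        continue;
      const int lj = lab_at(jx, jy, jz);
      if (lj != 0 && lj != l0) return false;
    }
    return true;
  };
  // assign a sub-point (grid coords) by short trilinear ascent
  auto assign = [&](double ux, double uy, double uz) -> int {
    for (int it = 0; it < 80; ++it) {
      const int ix = (int)std::min(std::max(ux + 0.5, 0.0), (double)(nx - 1));
      const int iy = (int)std::min(std::max(uy + 0.5, 0.0), (double)(ny - 1));
      const int iz = (int)std::min(std::max(uz + 0.5, 0.0), (double)(nz - 1));
      if (interior(ix, iy, iz)) return lab_at(ix, iy, iz);
      const double h = 0.25;
      const double gx = (trilin(field, nx, ny, nz, ux + h, uy, uz)
                         - trilin(field, nx, ny, nz, ux - h, uy, uz));
      const double gy = (trilin(field, nx, ny, nz, ux, uy + h, uz)
                         - trilin(field, nx, ny, nz, ux, uy - h, uz));
      const double gz = (trilin(field, nx, ny, nz, ux, uy, uz + h)
                         - trilin(field, nx, ny, nz, ux, uy, uz - h));
      const double g2 = gx * gx + gy * gy + gz * gz;
      if (g2 < 1e-12) return lab_at(ix, iy, iz);
      const double step = 0.7 / std::sqrt(g2);
      ux += gx * step;
      uy += gy * step;
      uz += gz * step;
    }
    const int ix = (int)std::min(std::max(ux + 0.5, 0.0), (double)(nx - 1));
    const int iy = (int)std::min(std::max(uy + 0.5, 0.0), (double)(ny - 1));
    const int iz = (int)std::min(std::max(uz + 0.5, 0.0), (double)(nz - 1));
    return lab_at(ix, iy, iz);
  };
  arma::mat chi, dx_, dy_, dz_;
  arma::mat pts(nx, 3);
  const int r3 = refine * refine * refine;
  arma::mat spts(r3, 3);
  arma::ivec slab(r3);
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      const long base = (long)iz * nx * ny + (long)iy * nx;
      bool any = false;
      for (int ix = 0; ix < nx; ++ix) if (labels[base + ix] > 0) { any = true; break; }
      if (!any) continue;
      for (int ix = 0; ix < nx; ++ix) {
        double xyz[3];
        grid_point(origin, spacing, dims, ix, iy, iz, xyz);
        pts(ix, 0) = xyz[0]; pts(ix, 1) = xyz[1]; pts(ix, 2) = xyz[2];
      }
      eval_chunk(b, pts, chi, &dx_, &dy_, &dz_);
      arma::mat m = chi * C;
      arma::mat mx = dx_ * C, my = dy_ * C, mz = dz_ * C;
      for (int ix = 0; ix < nx; ++ix) {
        const int lb = labels[base + ix];
        if (lb == 0) continue;
        bool is_interior = interior(ix, iy, iz);
        bool near_core = false;
        if (!is_interior) {
          // skip refinement where the density is negligible
          double r0 = 0.0;
          for (int o = 0; o < nocc; ++o) r0 += occ[o] * m(ix, o) * m(ix, o);
          if (r0 < rho_skip) is_interior = true;
        }
        if (refine > 1 && is_interior && heavy_nuc.n_rows > 0) {
          for (arma::uword a = 0; a < heavy_nuc.n_rows; ++a) {
            const double ddx = pts(ix, 0) - heavy_nuc(a, 0);
            const double ddy = pts(ix, 1) - heavy_nuc(a, 1);
            const double ddz = pts(ix, 2) - heavy_nuc(a, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz
                < refine_radius * refine_radius) { near_core = true; break; }
          }
        }
        if (refine <= 1 || (is_interior && !near_core)) {
          const int k = lb - 1;
          double r = 0.0, t = 0.0;
          for (int o = 0; o < nocc; ++o) {
            r += occ[o] * m(ix, o) * m(ix, o);
            t += 0.5 * occ[o] * (mx(ix, o) * mx(ix, o) + my(ix, o) * my(ix, o)
                                 + mz(ix, o) * mz(ix, o));
          }
          n[k] += r * dV;
          T[k] += t * dV;
          for (int o1 = 0; o1 < nocc; ++o1) {
            const double v1 = m(ix, o1);
            for (int o2 = 0; o2 <= o1; ++o2)
              S(o1, o2, k) += v1 * m(ix, o2) * dV;
          }
        } else {
          // subdivide
          int q = 0;
          for (int a = 0; a < refine; ++a)
            for (int bq = 0; bq < refine; ++bq)
              for (int c = 0; c < refine; ++c, ++q) {
                const double ux = ix + (a + 0.5) / refine - 0.5;
                const double uy = iy + (bq + 0.5) / refine - 0.5;
                const double uz = iz + (c + 0.5) / refine - 0.5;
                spts(q, 0) = origin[0] + ux * spacing[0];
                spts(q, 1) = origin[1] + uy * spacing[1];
                spts(q, 2) = origin[2] + uz * spacing[2];
                slab[q] = is_interior ? lb : assign(ux, uy, uz);
              }
          arma::mat schi, sdx, sdy, sdz;
          eval_chunk(b, spts, schi, &sdx, &sdy, &sdz);
          arma::mat sm = schi * C;
          arma::mat smx = sdx * C, smy = sdy * C, smz = sdz * C;
          const double sdV = dV / r3;
          for (int q2 = 0; q2 < r3; ++q2) {
            const int lq = slab[q2];
            if (lq == 0) continue;
            const int k = lq - 1;
            double r = 0.0, t = 0.0;
            for (int o = 0; o < nocc; ++o) {
              r += occ[o] * sm(q2, o) * sm(q2, o);
              t += 0.5 * occ[o] * (smx(q2, o) * smx(q2, o)
                                   + smy(q2, o) * smy(q2, o)
                                   + smz(q2, o) * smz(q2, o));
            }
            n[k] += r * sdV;
            T[k] += t * sdV;
            for (int o1 = 0; o1 < nocc; ++o1) {
              const double v1 = sm(q2, o1);
              for (int o2 = 0; o2 <= o1; ++o2)
                S(o1, o2, k) += v1 * sm(q2, o2) * sdV;
            }
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < K; ++k)
    for (int o1 = 0; o1 < nocc; ++o1)
      for (int o2 = 0; o2 < o1; ++o2) S(o2, o1, k) = S(o1, o2, k);
  return List::create(_["n"] = n, _["T"] = T, _["S"] = S);
}
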