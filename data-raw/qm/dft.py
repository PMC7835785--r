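"""Becke-type molecular quadrature grid + B3LYP (VWN3 correlation) XC.

Closed-shell only. Functional derivatives (vrho, vsigma) are generated
symbolically with sympy once and cached as numba-jitted lambdas.
"""
import numpy as np
from numba import njit
import sympy as sp

BOHR = 0.529177210903

# Bragg-Slater radii (Angstrom) for Becke size adjustment
BRAGG = {"H": 0.35, "C": 0.70, "N": 0.65, "O": 0.60}


# ---------------- functionals (closed shell, total rho/sigma) -------------
def _build_b3lyp():
    rho, sigma = sp.symbols("rho sigma", positive=True)
    # Slater exchange, closed shell
    Cx = sp.Rational(3, 4) * (3 / sp.pi) ** sp.Rational(1, 3)
    # spin-resolved Dirac: -2^{1/3} Cx sum_s rho_s^{4/3} -> closed shell -Cx rho^{4/3}
    ex_lda = -Cx * rho ** sp.Rational(4, 3)
    # Becke 88 gradient correction (per spin, summed; rho_s = rho/2)
    beta = sp.Float("0.0042")
    rs_ = rho / 2
    gs = sp.sqrt(sigma) / 2  # |grad rho_s|
    x = gs / rs_ ** sp.Rational(4, 3)
    ex_b88 = 2 * (-beta * rs_ ** sp.Rational(4, 3) * x ** 2 / (1 + 6 * beta * x * sp.asinh(x)))
    # VWN3 (functional III) paramagnetic
    A = sp.Float("0.0310907")
    x0 = sp.Float("-0.409286")
    b = sp.Float("13.0720")
    c = sp.Float("42.7198")
    rs = (3 / (4 * sp.pi * rho)) ** sp.Rational(1, 3)
    xv = sp.sqrt(rs)
    X = lambda t: t ** 2 + b * t + c
    Q = sp.sqrt(4 * c - b ** 2)
    ec_vwn = A * (sp.log(xv ** 2 / X(xv)) + 2 * b / Q * sp.atan(Q / (2 * xv + b))
                  - b * x0 / X(x0) * (sp.log((xv - x0) ** 2 / X(xv))
                                      + 2 * (b + 2 * x0) / Q * sp.atan(Q / (2 * xv + b))))
    e_vwn = rho * ec_vwn
    # LYP, closed shell (Miehlich et al. reformulation with rho_a=rho_b=rho/2)
    a_ = sp.Float("0.04918")
    b_ = sp.Float("0.132")
    c_ = sp.Float("0.2533")
    d_ = sp.Float("0.349")
    CF = sp.Rational(3, 10) * (3 * sp.pi ** 2) ** sp.Rational(2, 3)
    ra = rho / 2
    rb = rho / 2
    saa = sigma / 4
    sbb = sigma / 4
    st = sigma
    rm13 = rho ** sp.Rational(-1, 3)
    om = sp.exp(-c_ * rm13) / (1 + d_ * rm13) * rho ** sp.Rational(-11, 3)
    de = c_ * rm13 + d_ * rm13 / (1 + d_ * rm13)
    e_lyp = (-4 * a_ * ra * rb / (rho * (1 + d_ * rm13))
             - a_ * b_ * om * (
                 ra * rb * (2 ** sp.Rational(11, 3) * CF * (ra ** sp.Rational(8, 3) + rb ** sp.Rational(8, 3))
                            + (sp.Rational(47, 18) - 7 * de / 18) * st
                            - (sp.Rational(5, 2) - de / 18) * (saa + sbb)
                            - (de - 11) / 9 * (ra * saa + rb * sbb) / rho)
                 - sp.Rational(2, 3) * rho ** 2 * st
                 + (sp.Rational(2, 3) * rho ** 2 - ra ** 2) * sbb
                 + (sp.Rational(2, 3) * rho ** 2 - rb ** 2) * saa))
    # B3LYP blend (Gaussian convention; the 0.2 HF part handled elsewhere)
    e = (sp.Float("0.80") * ex_lda + sp.Float("0.72") * ex_b88
         + sp.Float("0.19") * e_vwn + sp.Float("0.81") * e_lyp)
    vr = sp.diff(e, rho)
    vs = sp.diff(e, sigma)
    mods = ["numpy"]
    f_e = sp.lambdify((rho, sigma), e, modules=mods, cse=True)
    f_vr = sp.lambdify((rho, sigma), vr, modules=mods, cse=True)
    f_vs = sp.lambdify((rho, sigma), vs, modules=mods, cse=True)
    return f_e, f_vr, f_vs


_F_E, _F_VR, _F_VS = _build_b3lyp()
RHO_FLOOR = 1e-11


def xc_eval(rho, sigma):
    """Return (e, vrho, vsigma) arrays; floor applied."""
    r = np.maximum(rho, RHO_FLOOR)
    s = np.maximum(sigma, 1e-24)
    e = _F_E(r, s)
    vr = _F_VR(r, s)
    vs = _F_VS(r, s)
    dead = rho < RHO_FLOOR
    e = np.where(dead, 0.0, e)
    vr = np.where(dead, 0.0, vr)
    vs = np.where(dead, 0.0, vs)
    return e, vr, vs


# ---------------- molecular grid ----------------
def _radial_mk(n, alpha):
    i = np.arange(1, n + 1)
    x = i / (n + 1.0)
    r = -alpha * np.log1p(-x ** 3)
    dr = alpha * 3 * x ** 2 / (1 - x ** 3) / (n + 1.0)
    return r, dr


def _angular(ntheta):
    nphi = 2 * ntheta
    xt, wt = np.polynomial.legendre.leggauss(ntheta)
    phi = (np.arange(nphi) + 0.5) * 2 * np.pi / nphi
    ct = xt
    st_ = np.sqrt(1 - ct ** 2)
    pts = []
    wts = []
    for k in range(ntheta):
        for ph in phi:
            pts.append((st_[k] * np.cos(ph), st_[k] * np.sin(ph), ct[k]))
            wts.append(wt[k] * 2 * np.pi / nphi)
    return np.array(pts), np.array(wts)


@njit(cache=True)
def _becke_w(points, centers, radii, iat, out):
    nat = centers.shape[0]
    npt = points.shape[0]
    for ip in range(npt):
        x, y, z = points[ip, 0], points[ip, 1], points[ip, 2]
        Ptot = 0.0
        Pme = 0.0
        for i in range(nat):
            cell = 1.0
            dxi = x - centers[i, 0]
            dyi = y - centers[i, 1]
            dzi = z - centers[i, 2]
            ri = np.sqrt(dxi * dxi + dyi * dyi + dzi * dzi)
            for j in range(nat):
                if j == i:
                    continue
                dxj = x - centers[j, 0]
                dyj = y - centers[j, 1]
                dzj = z - centers[j, 2]
                rj = np.sqrt(dxj * dxj + dyj * dyj + dzj * dzj)
                dx = centers[i, 0] - centers[j, 0]
                dy = centers[i, 1] - centers[j, 1]
                dz = centers[i, 2] - centers[j, 2]
                Rij = np.sqrt(dx * dx + dy * dy + dz * dz)
                mu = (ri - rj) / Rij
                chi = radii[i] / radii[j]
                uu = (chi - 1.0) / (chi + 1.0)
                aij = uu / (uu * uu - 1.0)
                if aij > 0.5:
                    aij = 0.5
                if aij < -0.5:
                    aij = -0.5
                nu = mu + aij * (1.0 - mu * mu)
                f = nu
                for _ in range(3):
                    f = 1.5 * f - 0.5 * f * f * f
                cell *= 0.5 * (1.0 - f)
            Ptot += cell
            if i == iat:
                Pme = cell
        out[ip] = Pme / Ptot if Ptot > 0 else 0.0


def molecular_grid(symbols, coords, nrad=60, ntheta=16):
    """Becke-weighted product grid. Returns points (n,3), weights (n,)."""
    apts, awts = _angular(ntheta)
    radii = np.array([BRAGG[s] / BOHR for s in symbols])
    allp = []
    allw = []
    for ia, sym in enumerate(symbols):
        alpha = 5.0
        r, dr = _radial_mk(nrad, alpha)
        # outer product
        pts = (coords[ia][None, None, :]
               + r[:, None, None] * apts[None, :, :]).reshape(-1, 3)
        w = (r ** 2 * dr)[:, None] * awts[None, :]
        w = w.reshape(-1)
        bw = np.empty(len(pts))
        _becke_w(pts, coords, radii, ia, bw)
        w = w * bw
        keep = w > 1e-14
        allp.append(pts[keep])
        allw.append(w[keep])
    return np.vstack(allp), np.concatenate(allw)


# ---------------- basis evaluation on points ----------------
@njit(cache=True)
def eval_basis(points, shell_l, shell_center, shell_off, pstart, nprim,
               pexp, pcoef, cx, cy, cz, cf, nbf, order, chi, dchi, d2chi):
    """chi (npts,nbf); dchi (npts,3,nbf) if order>=1;
    d2chi (npts,6,nbf) xx,yy,zz,xy,xz,yz if order>=2."""
    npt = points.shape[0]
    nsh = shell_l.shape[0]
    for p in range(npt):
        x, y, z = points[p, 0], points[p, 1], points[p, 2]
        for s in range(nsh):
            l = shell_l[s]
            dx = x - shell_center[s, 0]
            dy = y - shell_center[s, 1]
            dz = z - shell_center[s, 2]
            r2 = dx * dx + dy * dy + dz * dz
            # radial part: g = sum c_p exp(-a r2); also -2a weighted sums
            g0 = 0.0
            g1 = 0.0
            g2 = 0.0
            for ipr in range(nprim[s]):
                a = pexp[pstart[s] + ipr]
                e = pcoef[pstart[s] + ipr] * np.exp(-a * r2)
                g0 += e
                g1 += -2.0 * a * e
                g2 += 4.0 * a * a * e
            nc = 1 if l == 0 else (3 if l == 1 else 6)
            for m in range(nc):
                i, j, k = cx[s, m], cy[s, m], cz[s, m]
                px = dx ** i
                py = dy ** j
                pz = dz ** k
                poly = px * py * pz
                idx = shell_off[s] + m
                f = cf[s, m]
                chi[p, idx] = f * poly * g0
                if order >= 1:
                    # d/dx = (i*x^{i-1}) y^j z^k g + x^i y^j z^k g1 x
                    dpx = i * dx ** (i - 1) if i > 0 else 0.0
                    dpy = j * dy ** (j - 1) if j > 0 else 0.0
                    dpz = k * dz ** (k - 1) if k > 0 else 0.0
                    dchi[p, 0, idx] = f * (dpx * py * pz * g0 + poly * g1 * dx)
                    dchi[p, 1, idx] = f * (px * dpy * pz * g0 + poly * g1 * dy)
                    dchi[p, 2, idx] = f * (px * py * dpz * g0 + poly * g1 * dz)
                if order >= 2:
                    d2px = i * (i - 1) * dx ** (i - 2) if i > 1 else 0.0
                    d2py = j * (j - 1) * dy ** (j - 2) if j > 1 else 0.0
                    d2pz = k * (k - 1) * dz ** (k - 2) if k > 1 else 0.0
                    dpx = i * dx ** (i - 1) if i > 0 else 0.0
                    dpy = j * dy ** (j - 1) if j > 0 else 0.0
                    dpz = k * dz ** (k - 1) if k > 0 else 0.0
                    # xx
                    d2chi[p, 0, idx] = f * (d2px * py * pz * g0
                                            + 2 * dpx * py * pz * g1 * dx
                                            + poly * (g1 + g2 * dx * dx))
                    d2chi[p, 1, idx] = f * (px * d2py * pz * g0
                                            + 2 * px * dpy * pz * g1 * dy
                                            + poly * (g1 + g2 * dy * dy))
                    d2chi[p, 2, idx] = f * (px * py * d2pz * g0
                                            + 2 * px * py * dpz * g1 * dz
                                            + poly * (g1 + g2 * dz * dz))
                    # xy
                    d2chi[p, 3, idx] = f * (dpx * dpy * pz * g0
                                            + dpx * py * pz * g1 * dy
                                            + px * dpy * pz * g1 * dx
                                            + poly * g2 * dx * dy)
                    d2chi[p, 4, idx] = f * (dpx * py * dpz * g0
                                            + dpx * py * pz * g1 * dz
                                            + px * py * dpz * g1 * dx
                                            + poly * g2 * dx * dz)
                    d2chi[p, 5, idx] = f * (px * dpy * dpz * g0
                                            + px * dpy * pz * g1 * dz
                                            + px * py * dpz * g1 * dy
                                            + poly * g2 * dy * dz)


def basis_on_points(bs, points, order=1, chunk=20000):
    """Convenience wrapper returning full arrays (may be large)."""
    npt = len(points)
    chi = np.zeros((npt, bs.nbf))
    dchi = np.zeros((npt, 3, bs.nbf)) if order >= 1 else np.zeros((1, 3, 1))
    d2chi = np.zeros((npt, 6, bs.nbf)) if order >= 2 else np.zeros((1, 6, 1))
    eval_basis(points, bs.shell_l, bs.shell_center, bs.shell_off, bs.pstart,
               bs.nprim, bs.pexp, bs.pcoef, bs.cx, bs.cy, bs.cz, bs.cf,
               bs.nbf, order, chi, dchi, d2chi)
    return chi, dchi, d2chi
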