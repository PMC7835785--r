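"""McMurchie-Davidson Gaussian integrals (s,p,d + first derivatives), numba.

Cartesian components, per-component normalized. Packed ERI storage with
8-fold symmetry. Single-threaded (target machine has one core).
"""
import numpy as np
from numba import njit

# ---- component tables ----
# l=0: (000); l=1: x,y,z; l=2: xx,yy,zz,xy,xz,yz  (Molden cart order)
COMP = {
    0: [(0, 0, 0)],
    1: [(1, 0, 0), (0, 1, 0), (0, 0, 1)],
    2: [(2, 0, 0), (0, 2, 0), (0, 0, 2), (1, 1, 0), (1, 0, 1), (0, 1, 1)],
}
NCOMP = {0: 1, 1: 3, 2: 6}


def dfact(n):
    r = 1.0
    while n > 1:
        r *= n
        n -= 2
    return r


def comp_factor(i, j, k):
    L = i + j + k
    return np.sqrt(dfact(2 * L - 1) / (dfact(2 * i - 1) * dfact(2 * j - 1) * dfact(2 * k - 1)))


class BasisSet:
    """Flattened shell arrays for numba kernels."""

    def __init__(self, atoms, coords, basis_dict, zmap):
        # atoms: element symbols; coords: (nat,3) bohr
        self.symbols = list(atoms)
        self.coords = np.asarray(coords, float)
        self.charges = np.array([zmap[s] for s in atoms], float)
        sl, sc, sat = [], [], []
        pexp, pcoef = [], []
        pstart, nprim = [], []
        for ia, sym in enumerate(atoms):
            for (l, exps, coefs) in basis_dict[sym]:
                sl.append(l)
                sat.append(ia)
                sc.append(self.coords[ia])
                pstart.append(len(pexp))
                nprim.append(len(exps))
                for a, c in zip(exps, coefs):
                    # fold (l00) primitive norm into coefficient
                    nrm = (2 * a / np.pi) ** 0.75 * (4 * a) ** (l / 2.0) / np.sqrt(dfact(2 * l - 1))
                    pexp.append(a)
                    pcoef.append(c * nrm)
        self.shell_l = np.array(sl, np.int64)
        self.shell_atom = np.array(sat, np.int64)
        self.shell_center = np.array(sc, float)
        self.pstart = np.array(pstart, np.int64)
        self.nprim = np.array(nprim, np.int64)
        self.pexp = np.array(pexp, float)
        self.pcoef = np.array(pcoef, float)
        self.nshell = len(sl)
        off = []
        n = 0
        for l in sl:
            off.append(n)
            n += NCOMP[l]
        self.shell_off = np.array(off, np.int64)
        self.nbf = n
        # per-component angular factors and exponent triples, padded to 6
        cx = np.zeros((self.nshell, 6), np.int64)
        cy = np.zeros((self.nshell, 6), np.int64)
        cz = np.zeros((self.nshell, 6), np.int64)
        cf = np.zeros((self.nshell, 6), float)
        for s, l in enumerate(sl):
            for m, (i, j, k) in enumerate(COMP[l]):
                cx[s, m], cy[s, m], cz[s, m] = i, j, k
                cf[s, m] = comp_factor(i, j, k)
        self.cx, self.cy, self.cz, self.cf = cx, cy, cz, cf

    def unnormalized_contraction_norms(self):
        """Self-overlap of each contracted (l00) function (typo check: ~1)."""
        S = overlap(self)
        return np.diag(S)


# ---------- low-level numba helpers ----------
@njit(cache=True)
def _fill_E(E, la, lb, a, b, AB):
    # E[i,j,t]; includes K_ab = exp(-mu*AB^2)
    p = a + b
    mu = a * b / p
    XPA = -b / p * AB
    XPB = a / p * AB
    E[:, :, :] = 0.0
    E[0, 0, 0] = np.exp(-mu * AB * AB)
    for i in range(la + 1):
        for j in range(lb + 1):
            if i == 0 and j == 0:
                continue
            if j == 0:
                for t in range(i + j + 1):
                    v = XPA * E[i - 1, j, t]
                    if t > 0:
                        v += E[i - 1, j, t - 1] / (2 * p)
                    if t + 1 <= i + j - 1:
                        v += (t + 1) * E[i - 1, j, t + 1]
                    E[i, j, t] = v
            else:
                for t in range(i + j + 1):
                    v = XPB * E[i, j - 1, t]
                    if t > 0:
                        v += E[i, j - 1, t - 1] / (2 * p)
                    if t + 1 <= i + j - 1:
                        v += (t + 1) * E[i, j - 1, t + 1]
                    E[i, j, t] = v


@njit(cache=True)
def _boys(m_max, T, F):
    # fills F[0..m_max]
    if T < 1e-13:
        for m in range(m_max + 1):
            F[m] = 1.0 / (2 * m + 1)
        return
    if T > 35.0:
        F[0] = 0.5 * np.sqrt(np.pi / T)
        eT = 0.0
        for m in range(m_max):
            F[m + 1] = ((2 * m + 1) * F[m] - eT) / (2 * T)
        return
    # series for highest m, downward recursion
    eT = np.exp(-T)
    s = 0.0
    term = 1.0 / (2 * m_max + 1)
    k = 0
    while True:
        s += term
        k += 1
        term *= 2 * T / (2 * m_max + 2 * k + 1)
        if term < 1e-17 * s or k > 200:
            break
    F[m_max] = s * eT
    for m in range(m_max - 1, -1, -1):
        F[m] = (2 * T * F[m + 1] + eT) / (2 * m + 1)


@njit(cache=True)
def _fill_R(L, p, PC, R):
    # Hermite Coulomb integrals R[t,u,v] for t+u+v<=L
    F = np.zeros(L + 1)
    T = p * (PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2])
    _boys(L, T, F)
    # Rn[n, t, u, v]
    Rn = np.zeros((L + 1, L + 1, L + 1, L + 1))
    for n in range(L + 1):
        Rn[n, 0, 0, 0] = (-2.0 * p) ** n * F[n]
    for total in range(1, L + 1):
        for t in range(total + 1):
            for u in range(total - t + 1):
                v = total - t - u
                for n in range(L - total + 1):
                    val = 0.0
                    if t > 0:
                        if t > 1:
                            val += (t - 1) * Rn[n + 1, t - 2, u, v]
                        val += PC[0] * Rn[n + 1, t - 1, u, v]
                    elif u > 0:
                        if u > 1:
                            val += (u - 1) * Rn[n + 1, t, u - 2, v]
                        val += PC[1] * Rn[n + 1, t, u - 1, v]
                    else:
                        if v > 1:
                            val += (v - 1) * Rn[n + 1, t, u, v - 2]
                        val += PC[2] * Rn[n + 1, t, u, v - 1]
                    Rn[n, t, u, v] = val
    for t in range(L + 1):
        for u in range(L + 1 - t):
            for v in range(L + 1 - t - u):
                R[t, u, v] = Rn[0, t, u, v]


# ---------- one-electron integrals ----------
@njit(cache=True)
def _ov_kin_block(la, lb, A, B, pexp, pcoef, pa0, na, pb0, nb,
                  cxa, cya, cza, cfa, cxb, cyb, czb, cfb, Sblk, Tblk):
    LE = la + lb + 3
    Ex = np.zeros((LE, LE, 2 * LE))
    Ey = np.zeros((LE, LE, 2 * LE))
    Ez = np.zeros((LE, LE, 2 * LE))
    for ip in range(na):
        a = pexp[pa0 + ip]
        ca = pcoef[pa0 + ip]
        for jp in range(nb):
            b = pexp[pb0 + jp]
            cb = pcoef[pb0 + jp]
            p = a + b
            pref = ca * cb
            _fill_E(Ex, la + 2, lb + 2, a, b, A[0] - B[0])
            _fill_E(Ey, la + 2, lb + 2, a, b, A[1] - B[1])
            _fill_E(Ez, la + 2, lb + 2, a, b, A[2] - B[2])
            sp = np.sqrt(np.pi / p)
            for ma in range(6):
                ia, ja, ka = cxa[ma], cya[ma], cza[ma]
                if ia + ja + ka != la and ma > 0:
                    continue
                if ma >= 1 and la == 0:
                    break
                if ma >= 3 and la == 1:
                    break
                for mb in range(6):
                    if mb >= 1 and lb == 0:
                        break
                    if mb >= 3 and lb == 1:
                        break
                    ib, jb, kb = cxb[mb], cyb[mb], czb[mb]
                    sx = Ex[ia, ib, 0] * sp
                    sy = Ey[ja, jb, 0] * sp
                    sz = Ez[ka, kb, 0] * sp
                    # 1d kinetic: t_ij = -2b^2 S(i,j+2)+b(2j+1)S(i,j)-0.5 j(j-1)S(i,j-2)
                    tx = -2 * b * b * Ex[ia, ib + 2, 0] * sp + b * (2 * ib + 1) * sx
                    if ib >= 2:
                        tx -= 0.5 * ib * (ib - 1) * Ex[ia, ib - 2, 0] * sp
                    ty = -2 * b * b * Ey[ja, jb + 2, 0] * sp + b * (2 * jb + 1) * sy
                    if jb >= 2:
                        ty -= 0.5 * jb * (jb - 1) * Ey[ja, jb - 2, 0] * sp
                    tz = -2 * b * b * Ez[ka, kb + 2, 0] * sp + b * (2 * kb + 1) * sz
                    if kb >= 2:
                        tz -= 0.5 * kb * (kb - 1) * Ez[ka, kb - 2, 0] * sp
                    f = pref * cfa[ma] * cfb[mb]
                    Sblk[ma, mb] += f * sx * sy * sz
                    Tblk[ma, mb] += f * (tx * sy * sz + sx * ty * sz + sx * sy * tz)


@njit(cache=True)
def _nuc_block(la, lb, A, B, pexp, pcoef, pa0, na, pb0, nb,
               cxa, cya, cza, cfa, cxb, cyb, czb, cfb,
               nuc_xyz, nuc_q, Vblk):
    LE = la + lb + 1
    Ex = np.zeros((LE, LE, 2 * LE))
    Ey = np.zeros((LE, LE, 2 * LE))
    Ez = np.zeros((LE, LE, 2 * LE))
    L = la + lb
    R = np.zeros((L + 1, L + 1, L + 1))
    PC = np.zeros(3)
    nnuc = nuc_q.shape[0]
    for ip in range(na):
        a = pexp[pa0 + ip]
        ca = pcoef[pa0 + ip]
        for jp in range(nb):
            b = pexp[pb0 + jp]
            cb = pcoef[pb0 + jp]
            p = a + b
            Px = (a * A[0] + b * B[0]) / p
            Py = (a * A[1] + b * B[1]) / p
            Pz = (a * A[2] + b * B[2]) / p
            _fill_E(Ex, la, lb, a, b, A[0] - B[0])
            _fill_E(Ey, la, lb, a, b, A[1] - B[1])
            _fill_E(Ez, la, lb, a, b, A[2] - B[2])
            pref = ca * cb * 2.0 * np.pi / p
            for inuc in range(nnuc):
                PC[0] = Px - nuc_xyz[inuc, 0]
                PC[1] = Py - nuc_xyz[inuc, 1]
                PC[2] = Pz - nuc_xyz[inuc, 2]
                _fill_R(L, p, PC, R)
                q = nuc_q[inuc]
                for ma in range(6):
                    if ma >= 1 and la == 0:
                        break
                    if ma >= 3 and la == 1:
                        break
                    ia, ja, ka = cxa[ma], cya[ma], cza[ma]
                    for mb in range(6):
                        if mb >= 1 and lb == 0:
                            break
                        if mb >= 3 and lb == 1:
                            break
                        ib, jb, kb = cxb[mb], cyb[mb], czb[mb]
                        v = 0.0
                        for t in range(ia + ib + 1):
                            for u in range(ja + jb + 1):
                                for w in range(ka + kb + 1):
                                    v += (Ex[ia, ib, t] * Ey[ja, jb, u]
                                          * Ez[ka, kb, w] * R[t, u, w])
                        Vblk[ma, mb] -= q * pref * v * cfa[ma] * cfb[mb]


def _shell_pairs(bs):
    pairs = []
    for i in range(bs.nshell):
        for j in range(i + 1):
            pairs.append((i, j))
    return pairs


def overlap_kinetic(bs):
    n = bs.nbf
    S = np.zeros((n, n))
    T = np.zeros((n, n))
    for (i, j) in _shell_pairs(bs):
        la, lb = bs.shell_l[i], bs.shell_l[j]
        Sb = np.zeros((6, 6))
        Tb = np.zeros((6, 6))
        _ov_kin_block(la, lb, bs.shell_center[i], bs.shell_center[j],
                      bs.pexp, bs.pcoef, bs.pstart[i], bs.nprim[i],
                      bs.pstart[j], bs.nprim[j],
                      bs.cx[i], bs.cy[i], bs.cz[i], bs.cf[i],
                      bs.cx[j], bs.cy[j], bs.cz[j], bs.cf[j], Sb, Tb)
        oi, oj = bs.shell_off[i], bs.shell_off[j]
        for ma in range(NCOMP[la]):
            for mb in range(NCOMP[lb]):
                S[oi + ma, oj + mb] = Sb[ma, mb]
                S[oj + mb, oi + ma] = Sb[ma, mb]
                T[oi + ma, oj + mb] = Tb[ma, mb]
                T[oj + mb, oi + ma] = Tb[ma, mb]
    return S, T


def overlap(bs):
    return overlap_kinetic(bs)[0]


def nuclear(bs):
    n = bs.nbf
    V = np.zeros((n, n))
    for (i, j) in _shell_pairs(bs):
        la, lb = bs.shell_l[i], bs.shell_l[j]
        Vb = np.zeros((6, 6))
        _nuc_block(la, lb, bs.shell_center[i], bs.shell_center[j],
                   bs.pexp, bs.pcoef, bs.pstart[i], bs.nprim[i],
                   bs.pstart[j], bs.nprim[j],
                   bs.cx[i], bs.cy[i], bs.cz[i], bs.cf[i],
                   bs.cx[j], bs.cy[j], bs.cz[j], bs.cf[j],
                   bs.coords, bs.charges, Vb)
        oi, oj = bs.shell_off[i], bs.shell_off[j]
        for ma in range(NCOMP[la]):
            for mb in range(NCOMP[lb]):
                V[oi + ma, oj + mb] = Vb[ma, mb]
                V[oj + mb, oi + ma] = Vb[ma, mb]
    return V


# ---------- ERI ----------
@njit(cache=True)
def _eri_quartet(la, lb, lc, ld, A, B, C, D,
                 pexp, pcoef, pa0, na, pb0, nb, pc0, nc, pd0, nd,
                 cxa, cya, cza, cfa, cxb, cyb, czb, cfb,
                 cxc, cyc, czc, cfc, cxd, cyd, czd, cfd, out):
    # out: (6,6,6,6) accumulated contracted integrals
    nca = 1 if la == 0 else (3 if la == 1 else 6)
    ncb = 1 if lb == 0 else (3 if lb == 1 else 6)
    ncc = 1 if lc == 0 else (3 if lc == 1 else 6)
    ncd = 1 if ld == 0 else (3 if ld == 1 else 6)
    Lb = la + lb
    Lk = lc + ld
    L = Lb + Lk
    E1x = np.zeros((la + 1, lb + 1, Lb + 1))
    E1y = np.zeros((la + 1, lb + 1, Lb + 1))
    E1z = np.zeros((la + 1, lb + 1, Lb + 1))
    E2x = np.zeros((lc + 1, ld + 1, Lk + 1))
    E2y = np.zeros((lc + 1, ld + 1, Lk + 1))
    E2z = np.zeros((lc + 1, ld + 1, Lk + 1))
    R = np.zeros((L + 1, L + 1, L + 1))
    Th = np.zeros((ncc * ncd, Lb + 1, Lb + 1, Lb + 1))
    PQ = np.zeros(3)
    out[:, :, :, :] = 0.0
    for ip in range(na):
        a = pexp[pa0 + ip]
        ca = pcoef[pa0 + ip]
        for jp in range(nb):
            b = pexp[pb0 + jp]
            cab = ca * pcoef[pb0 + jp]
            p = a + b
            Px = (a * A[0] + b * B[0]) / p
            Py = (a * A[1] + b * B[1]) / p
            Pz = (a * A[2] + b * B[2]) / p
            _fill_E(E1x, la, lb, a, b, A[0] - B[0])
            _fill_E(E1y, la, lb, a, b, A[1] - B[1])
            _fill_E(E1z, la, lb, a, b, A[2] - B[2])
            for kp in range(nc):
                c = pexp[pc0 + kp]
                cc = pcoef[pc0 + kp]
                for lp in range(nd):
                    d = pexp[pd0 + lp]
                    ccd = cc * pcoef[pd0 + lp]
                    q = c + d
                    Qx = (c * C[0] + d * D[0]) / q
                    Qy = (c * C[1] + d * D[1]) / q
                    Qz = (c * C[2] + d * D[2]) / q
                    _fill_E(E2x, lc, ld, c, d, C[0] - D[0])
                    _fill_E(E2y, lc, ld, c, d, C[1] - D[1])
                    _fill_E(E2z, lc, ld, c, d, C[2] - D[2])
                    alpha = p * q / (p + q)
                    PQ[0] = Px - Qx
                    PQ[1] = Py - Qy
                    PQ[2] = Pz - Qz
                    _fill_R(L, alpha, PQ, R)
                    pref = cab * ccd * 2.0 * np.pi ** 2.5 / (p * q * np.sqrt(p + q))
                    # ket contraction
                    for mc in range(ncc):
                        ic, jc, kc = cxc[mc], cyc[mc], czc[mc]
                        for md in range(ncd):
                            idx, jd, kd = cxd[md], cyd[md], czd[md]
                            mm = mc * ncd + md
                            for t in range(Lb + 1):
                                for u in range(Lb + 1 - t):
                                    for v in range(Lb + 1 - t - u):
                                        s = 0.0
                                        for tt in range(ic + idx + 1):
                                            for uu in range(jc + jd + 1):
                                                for vv in range(kc + kd + 1):
                                                    sgn = 1.0 if ((tt + uu + vv) % 2 == 0) else -1.0
                                                    s += (sgn * E2x[ic, idx, tt]
                                                          * E2y[jc, jd, uu]
                                                          * E2z[kc, kd, vv]
                                                          * R[t + tt, u + uu, v + vv])
                                        Th[mm, t, u, v] = s
                    # bra contraction
                    for ma in range(nca):
                        ia, ja, ka = cxa[ma], cya[ma], cza[ma]
                        for mb in range(ncb):
                            ib, jb, kb = cxb[mb], cyb[mb], czb[mb]
                            for mc in range(ncc):
                                for md in range(ncd):
                                    mm = mc * ncd + md
                                    s = 0.0
                                    for t in range(ia + ib + 1):
                                        for u in range(ja + jb + 1):
                                            for v in range(ka + kb + 1):
                                                s += (E1x[ia, ib, t] * E1y[ja, jb, u]
                                                      * E1z[ka, kb, v] * Th[mm, t, u, v])
                                    out[ma, mb, mc, md] += pref * s
    for ma in range(nca):
        for mb in range(ncb):
            for mc in range(ncc):
                for md in range(ncd):
                    out[ma, mb, mc, md] *= cfa[ma] * cfb[mb] * cfc[mc] * cfd[md]


@njit(cache=True)
def _eri_all(shell_l, shell_center, shell_off, pstart, nprim, pexp, pcoef,
             cx, cy, cz, cf, nbf, qsh, eri):
    # packed eri[ij>=kl]; ij = i*(i+1)/2+j (i>=j); eri index ij*(ij+1)/2+kl
    nsh = shell_l.shape[0]
    out = np.zeros((6, 6, 6, 6))
    for I in range(nsh):
        for J in range(I + 1):
            qIJ = qsh[I, J]
            for K in range(I + 1):
                Lmax = K if K < I else J
                for Lsh in range(K + 1):
                    if K == I and Lsh > J:
                        continue
                    if qIJ * qsh[K, Lsh] < 1e-12:
                        continue
                    _eri_quartet(shell_l[I], shell_l[J], shell_l[K], shell_l[Lsh],
                                 shell_center[I], shell_center[J],
                                 shell_center[K], shell_center[Lsh],
                                 pexp, pcoef, pstart[I], nprim[I], pstart[J], nprim[J],
                                 pstart[K], nprim[K], pstart[Lsh], nprim[Lsh],
                                 cx[I], cy[I], cz[I], cf[I],
                                 cx[J], cy[J], cz[J], cf[J],
                                 cx[K], cy[K], cz[K], cf[K],
                                 cx[Lsh], cy[Lsh], cz[Lsh], cf[Lsh], out)
                    nca = 1 if shell_l[I] == 0 else (3 if shell_l[I] == 1 else 6)
                    ncb = 1 if shell_l[J] == 0 else (3 if shell_l[J] == 1 else 6)
                    ncc = 1 if shell_l[K] == 0 else (3 if shell_l[K] == 1 else 6)
                    ncd = 1 if shell_l[Lsh] == 0 else (3 if shell_l[Lsh] == 1 else 6)
                    oi, oj = shell_off[I], shell_off[J]
                    ok, ol = shell_off[K], shell_off[Lsh]
                    for ma in range(nca):
                        mu = oi + ma
                        for mb in range(ncb):
                            nu = oj + mb
                            if nu > mu:
                                continue
                            ij = mu * (mu + 1) // 2 + nu
                            for mc in range(ncc):
                                lam = ok + mc
                                for md in range(ncd):
                                    sig = ol + md
                                    if sig > lam:
                                        continue
                                    kl = lam * (lam + 1) // 2 + sig
                                    if kl > ij:
                                        # same value by bra-ket symmetry
                                        eri[kl * (kl + 1) // 2 + ij] = out[ma, mb, mc, md]
                                    else:
                                        eri[ij * (ij + 1) // 2 + kl] = out[ma, mb, mc, md]


def schwarz(bs):
    nsh = bs.nshell
    q = np.zeros((nsh, nsh))
    out = np.zeros((6, 6, 6, 6))
    for i in range(nsh):
        for j in range(i + 1):
            _eri_quartet(bs.shell_l[i], bs.shell_l[j], bs.shell_l[i], bs.shell_l[j],
                         bs.shell_center[i], bs.shell_center[j],
                         bs.shell_center[i], bs.shell_center[j],
                         bs.pexp, bs.pcoef,
                         bs.pstart[i], bs.nprim[i], bs.pstart[j], bs.nprim[j],
                         bs.pstart[i], bs.nprim[i], bs.pstart[j], bs.nprim[j],
                         bs.cx[i], bs.cy[i], bs.cz[i], bs.cf[i],
                         bs.cx[j], bs.cy[j], bs.cz[j], bs.cf[j],
                         bs.cx[i], bs.cy[i], bs.cz[i], bs.cf[i],
                         bs.cx[j], bs.cy[j], bs.cz[j], bs.cf[j], out)
        # max over components of |(ab|ab)|
            m = 0.0
            nca = NCOMP[bs.shell_l[i]]
            ncb = NCOMP[bs.shell_l[j]]
            for ma in range(nca):
                for mb in range(ncb):
                    v = abs(out[ma, mb, ma, mb])
                    if v > m:
                        m = v
            q[i, j] = q[j, i] = np.sqrt(m)
    return q


def eri_packed(bs):
    npair = bs.nbf * (bs.nbf + 1) // 2
    eri = np.zeros(npair * (npair + 1) // 2)
    qsh = schwarz(bs)
    _eri_all(bs.shell_l, bs.shell_center, bs.shell_off, bs.pstart, bs.nprim,
             bs.pexp, bs.pcoef, bs.cx, bs.cy, bs.cz, bs.cf, bs.nbf, qsh, eri)
    return eri


@njit(cache=True)
def build_JK(eri, P, nbf):
    J = np.zeros((nbf, nbf))
    K = np.zeros((nbf, nbf))
    idx = 0
    for mu in range(nbf):
        for nu in range(mu + 1):
            ij = mu * (mu + 1) // 2 + nu
            for lam in range(mu + 1):
                smax = lam if lam < mu else nu
                for sig in range(lam + 1):
                    if lam == mu and sig > nu:
                        continue
                    kl = lam * (lam + 1) // 2 + sig
                    v = eri[ij * (ij + 1) // 2 + kl]
                    if v == 0.0:
                        continue
                    # degeneracy handling
                    dij = 1.0 if mu == nu else 2.0
                    dkl = 1.0 if lam == sig else 2.0
                    same = (ij == kl)
                    # J
                    J[mu, nu] += v * dkl * P[lam, sig] if True else 0.0
                    if not same:
                        J[lam, sig] += v * dij * P[mu, nu]
                    # K: loop the distinct index orderings explicitly
                    # contributions (mu nu | lam sig) to K[mu,lam] etc.
                    K[mu, lam] += v * P[nu, sig]
                    if nu != mu:
                        K[nu, lam] += v * P[mu, sig]
                    if sig != lam:
                        K[mu, sig] += v * P[nu, lam]
                    if nu != mu and sig != lam:
                        K[nu, sig] += v * P[mu, lam]
                    if not same:
                        K[lam, mu] += v * P[sig, nu]
                        if sig != lam:
                            K[sig, mu] += v * P[lam, nu]
                        if nu != mu:
                            K[lam, nu] += v * P[sig, mu]
                        if sig != lam and nu != mu:
                            K[sig, nu] += v * P[lam, mu]
    # symmetrize
    for mu in range(nbf):
        for nu in range(mu):
            J[nu, mu] = J[mu, nu]
    K2 = 0.5 * (K + K.T)
    return J, K2
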