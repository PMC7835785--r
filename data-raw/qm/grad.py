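"""Analytic nuclear gradients for RKS B3LYP (Becke-weight derivatives omitted;
the quadrature grid is converged well past the resulting error)."""
import numpy as np
from numba import njit
import mdint
import dft
from mdint import _fill_E, _fill_R


@njit(cache=True, inline='always')
def _nc(l):
    if l == 0:
        return 1
    if l == 1:
        return 3
    return 6


@njit(cache=True)
def _dE(E, ia, ib, t, a, upper):
    # d/dAx of E[ia,ib,t] = 2a E[ia+1,ib,t] - ia E[ia-1,ib,t]
    v = 2.0 * a * E[ia + 1, ib, t]
    if ia > 0:
        v -= ia * E[ia - 1, ib, t]
    return v


@njit(cache=True)
def _dEb(E, ia, ib, t, b):
    v = 2.0 * b * E[ia, ib + 1, t]
    if ib > 0:
        v -= ib * E[ia, ib - 1, t]
    return v


@njit(cache=True)
def _grad_1e_pairs(shell_l, shell_atom, shell_center, shell_off, pstart, nprim,
                   pexp, pcoef, cx, cy, cz, cf, nuc_xyz, nuc_q,
                   PW, W, grad):
    """Accumulate d/dX [ sum P*(T+V) - sum W*S ] into grad (nat,3).
    PW = density matrix P; W = energy-weighted density."""
    nsh = shell_l.shape[0]
    for I in range(nsh):
        la = shell_l[I]
        A = shell_center[I]
        atA = shell_atom[I]
        for J in range(nsh):
            lb = shell_l[J]
            B = shell_center[J]
            atB = shell_atom[J]
            # E arrays up to la+1 (bra deriv), lb+2 (kinetic)
            LE1 = la + 2
            LE2 = lb + 3
            Ex = np.zeros((LE1 + 1, LE2 + 1, LE1 + LE2 + 2))
            Ey = np.zeros((LE1 + 1, LE2 + 1, LE1 + LE2 + 2))
            Ez = np.zeros((LE1 + 1, LE2 + 1, LE1 + LE2 + 2))
            L = la + lb + 1
            R = np.zeros((L + 1, L + 1, L + 1))
            PC = np.zeros(3)
            nca = _nc(la)
            ncb = _nc(lb)
            oi = shell_off[I]
            oj = shell_off[J]
            for ip in range(nprim[I]):
                a = pexp[pstart[I] + ip]
                ca = pcoef[pstart[I] + ip]
                for jp in range(nprim[J]):
                    b = pexp[pstart[J] + jp]
                    cb = pcoef[pstart[J] + jp]
                    p = a + b
                    _fill_E(Ex, la + 1, lb + 2, a, b, A[0] - B[0])
                    _fill_E(Ey, la + 1, lb + 2, a, b, A[1] - B[1])
                    _fill_E(Ez, la + 1, lb + 2, a, b, A[2] - B[2])
                    sp_ = np.sqrt(np.pi / p)
                    pref = ca * cb
                    # ---- overlap & kinetic derivative wrt A ----
                    for ma in range(nca):
                        ia, ja, ka = cx[I, ma], cy[I, ma], cz[I, ma]
                        for mb in range(ncb):
                            ib, jb, kb = cx[J, mb], cy[J, mb], cz[J, mb]
                            f = pref * cf[I, ma] * cf[J, mb]
                            pw = PW[oi + ma, oj + mb]
                            ww = W[oi + ma, oj + mb]
                            sx = Ex[ia, ib, 0] * sp_
                            sy = Ey[ja, jb, 0] * sp_
                            sz = Ez[ka, kb, 0] * sp_
                            dsx = _dE(Ex, ia, ib, 0, a, 0) * sp_
                            dsy = _dE(Ey, ja, jb, 0, a, 0) * sp_
                            dsz = _dE(Ez, ka, kb, 0, a, 0) * sp_
                            # kinetic 1d pieces
                            def0 = 0.0  # placeholder to appease numba scoping
                            tx = -2 * b * b * Ex[ia, ib + 2, 0] * sp_ + b * (2 * ib + 1) * sx
                            if ib >= 2:
                                tx -= 0.5 * ib * (ib - 1) * Ex[ia, ib - 2, 0] * sp_
                            ty = -2 * b * b * Ey[ja, jb + 2, 0] * sp_ + b * (2 * jb + 1) * sy
                            if jb >= 2:
                                ty -= 0.5 * jb * (jb - 1) * Ey[ja, jb - 2, 0] * sp_
                            tz = -2 * b * b * Ez[ka, kb + 2, 0] * sp_ + b * (2 * kb + 1) * sz
                            if kb >= 2:
                                tz -= 0.5 * kb * (kb - 1) * Ez[ka, kb - 2, 0] * sp_
                            dtx = -2 * b * b * _dE(Ex, ia, ib + 2, 0, a, 0) * sp_ + b * (2 * ib + 1) * dsx
                            if ib >= 2:
                                dtx -= 0.5 * ib * (ib - 1) * _dE(Ex, ia, ib - 2, 0, a, 0) * sp_
                            dty = -2 * b * b * _dE(Ey, ja, jb + 2, 0, a, 0) * sp_ + b * (2 * jb + 1) * dsy
                            if jb >= 2:
                                dty -= 0.5 * jb * (jb - 1) * _dE(Ey, ja, jb - 2, 0, a, 0) * sp_
                            dtz = -2 * b * b * _dE(Ez, ka, kb + 2, 0, a, 0) * sp_ + b * (2 * kb + 1) * dsz
                            if kb >= 2:
                                dtz -= 0.5 * kb * (kb - 1) * _dE(Ez, ka, kb - 2, 0, a, 0) * sp_
                            # d/dA of S and T
                            dS0 = f * dsx * sy * sz
                            dS1 = f * sx * dsy * sz
                            dS2 = f * sx * sy * dsz
                            dT0 = f * (dtx * sy * sz + dsx * ty * sz + dsx * sy * tz)
                            dT1 = f * (tx * dsy * sz + sx * dty * sz + sx * dsy * tz)
                            dT2 = f * (tx * sy * dsz + sx * ty * dsz + sx * sy * dtz)
                            # P*dT - W*dS ; B-center derivative = -(A) for S,T
                            grad[atA, 0] += pw * dT0 - ww * dS0
                            grad[atA, 1] += pw * dT1 - ww * dS1
                            grad[atA, 2] += pw * dT2 - ww * dS2
                            grad[atB, 0] -= pw * dT0 - ww * dS0
                            grad[atB, 1] -= pw * dT1 - ww * dS1
                            grad[atB, 2] -= pw * dT2 - ww * dS2
                    # ---- nuclear attraction derivatives ----
                    Px = (a * A[0] + b * B[0]) / p
                    Py = (a * A[1] + b * B[1]) / p
                    Pz = (a * A[2] + b * B[2]) / p
                    pref_v = pref * 2.0 * np.pi / p
                    for inuc in range(nuc_q.shape[0]):
                        PC[0] = Px - nuc_xyz[inuc, 0]
                        PC[1] = Py - nuc_xyz[inuc, 1]
                        PC[2] = Pz - nuc_xyz[inuc, 2]
                        _fill_R(L, p, PC, R)
                        q = nuc_q[inuc]
                        for ma in range(nca):
                            ia, ja, ka = cx[I, ma], cy[I, ma], cz[I, ma]
                            for mb in range(ncb):
                                ib, jb, kb = cx[J, mb], cy[J, mb], cz[J, mb]
                                f = -q * pref_v * cf[I, ma] * cf[J, mb]
                                pw = PW[oi + ma, oj + mb]
                                if abs(pw) < 1e-14:
                                    continue
                                dA0 = 0.0
                                dA1 = 0.0
                                dA2 = 0.0
                                dB0 = 0.0
                                dB1 = 0.0
                                dB2 = 0.0
                                for t in range(ia + ib + 2):
                                    for u in range(ja + jb + 2):
                                        for w_ in range(ka + kb + 2):
                                            r = R[t, u, w_]
                                            if r == 0.0:
                                                continue
                                            ex = Ex[ia, ib, t] if t <= ia + ib else 0.0
                                            ey = Ey[ja, jb, u] if u <= ja + jb else 0.0
                                            ez = Ez[ka, kb, w_] if w_ <= ka + kb else 0.0
                                            if u <= ja + jb and w_ <= ka + kb:
                                                dA0 += _dE(Ex, ia, ib, t, a, 0) * ey * ez * r
                                                dB0 += _dEb(Ex, ia, ib, t, b) * ey * ez * r
                                            if t <= ia + ib and w_ <= ka + kb:
                                                dA1 += ex * _dE(Ey, ja, jb, u, a, 0) * ez * r
                                                dB1 += ex * _dEb(Ey, ja, jb, u, b) * ez * r
                                            if t <= ia + ib and u <= ja + jb:
                                                dA2 += ex * ey * _dE(Ez, ka, kb, w_, a, 0) * r
                                                dB2 += ex * ey * _dEb(Ez, ka, kb, w_, b) * r
                                grad[atA, 0] += pw * f * dA0
                                grad[atA, 1] += pw * f * dA1
                                grad[atA, 2] += pw * f * dA2
                                grad[atB, 0] += pw * f * dB0
                                grad[atB, 1] += pw * f * dB1
                                grad[atB, 2] += pw * f * dB2
                                grad[inuc, 0] -= pw * f * (dA0 + dB0)
                                grad[inuc, 1] -= pw * f * (dA1 + dB1)
                                grad[inuc, 2] -= pw * f * (dA2 + dB2)


@njit(cache=True)
def _eri_grad_quartet(la, lb, lc, ld, A, B, C, D,
                      pexp, pcoef, pa0, na, pb0, nb, pc0, nc, pd0, nd,
                      cxa, cya, cza, cfa, cxb, cyb, czb, cfb,
                      cxc, cyc, czc, cfc, cxd, cyd, czd, cfd, og):
    """og: (9,6,6,6,6) derivatives dAx,dAy,dAz,dBx,dBy,dBz,dCx,dCy,dCz."""
    nca = _nc(la)
    ncb = _nc(lb)
    ncc = _nc(lc)
    ncd = _nc(ld)
    Lb = la + lb + 1
    Lk = lc + ld + 1
    L = Lb + Lk
    E1x = np.zeros((la + 2, lb + 2, Lb + 2))
    E1y = np.zeros((la + 2, lb + 2, Lb + 2))
    E1z = np.zeros((la + 2, lb + 2, Lb + 2))
    E2x = np.zeros((lc + 2, ld + 2, Lk + 2))
    E2y = np.zeros((lc + 2, ld + 2, Lk + 2))
    E2z = np.zeros((lc + 2, ld + 2, Lk + 2))
    R = np.zeros((L + 1, L + 1, L + 1))
    nk = ncc * ncd
    Thb = np.zeros((nk, Lb + 1, Lb + 1, Lb + 1))   # base ket
    Thc = np.zeros((3, nk, Lb, Lb, Lb))            # ket with dC in one dim
    PQ = np.zeros(3)
    og[:, :, :, :, :] = 0.0
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
            _fill_E(E1x, la + 1, lb + 1, a, b, A[0] - B[0])
            _fill_E(E1y, la + 1, lb + 1, a, b, A[1] - B[1])
            _fill_E(E1z, la + 1, lb + 1, a, b, A[2] - B[2])
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
                    _fill_E(E2x, lc + 1, ld + 1, c, d, C[0] - D[0])
                    _fill_E(E2y, lc + 1, ld + 1, c, d, C[1] - D[1])
                    _fill_E(E2z, lc + 1, ld + 1, c, d, C[2] - D[2])
                    alpha = p * q / (p + q)
                    PQ[0] = Px - Qx
                    PQ[1] = Py - Qy
                    PQ[2] = Pz - Qz
                    _fill_R(L, alpha, PQ, R)
                    pref = cab * ccd * 2.0 * np.pi ** 2.5 / (p * q * np.sqrt(p + q))
                    # ket contractions
                    for mc in range(ncc):
                        ic, jc, kc = cxc[mc], cyc[mc], czc[mc]
                        for md in range(ncd):
                            idx, jd, kd = cxd[md], cyd[md], czd[md]
                            mm = mc * ncd + md
                            # base: ranges to Lb (bra deriv needs t up to ia+ib+1 <= Lb)
                            for t in range(Lb + 1):
                                for u in range(Lb + 1 - t):
                                    for v in range(Lb + 1 - t - u):
                                        s = 0.0
                                        for tt in range(ic + idx + 1):
                                            for uu in range(jc + jd + 1):
                                                for vv in range(kc + kd + 1):
                                                    sgn = 1.0 if ((tt + uu + vv) % 2 == 0) else -1.0
                                                    s += (sgn * E2x[ic, idx, tt] * E2y[jc, jd, uu]
                                                          * E2z[kc, kd, vv] * R[t + tt, u + uu, v + vv])
                                        Thb[mm, t, u, v] = s
                            # dC variants (bra ranges to Lb-1 = la+lb)
                            for t in range(Lb):
                                for u in range(Lb - t):
                                    for v in range(Lb - t - u):
                                        s0 = 0.0
                                        s1 = 0.0
                                        s2 = 0.0
                                        for tt in range(ic + idx + 2):
                                            for uu in range(jc + jd + 2):
                                                for vv in range(kc + kd + 2):
                                                    r = R[t + tt, u + uu, v + vv]
                                                    if r == 0.0:
                                                        continue
                                                    sgn = 1.0 if ((tt + uu + vv) % 2 == 0) else -1.0
                                                    e2y = E2y[jc, jd, uu] if uu <= jc + jd else 0.0
                                                    e2z = E2z[kc, kd, vv] if vv <= kc + kd else 0.0
                                                    e2x = E2x[ic, idx, tt] if tt <= ic + idx else 0.0
                                                    if uu <= jc + jd and vv <= kc + kd:
                                                        s0 += sgn * _dE(E2x, ic, idx, tt, c, 0) * e2y * e2z * r
                                                    if tt <= ic + idx and vv <= kc + kd:
                                                        s1 += sgn * e2x * _dE(E2y, jc, jd, uu, c, 0) * e2z * r
                                                    if tt <= ic + idx and uu <= jc + jd:
                                                        s2 += sgn * e2x * e2y * _dE(E2z, kc, kd, vv, c, 0) * r
                                        Thc[0, mm, t, u, v] = s0
                                        Thc[1, mm, t, u, v] = s1
                                        Thc[2, mm, t, u, v] = s2
                    # bra assembly
                    for ma in range(nca):
                        ia, ja, ka = cxa[ma], cya[ma], cza[ma]
                        for mb in range(ncb):
                            ib, jb, kb = cxb[mb], cyb[mb], czb[mb]
                            for mc in range(ncc):
                                for md in range(ncd):
                                    mm = mc * ncd + md
                                    gax = 0.0
                                    gay = 0.0
                                    gaz = 0.0
                                    gbx = 0.0
                                    gby = 0.0
                                    gbz = 0.0
                                    gcx = 0.0
                                    gcy = 0.0
                                    gcz = 0.0
                                    for t in range(ia + ib + 2):
                                        for u in range(ja + jb + 2):
                                            for v in range(ka + kb + 2):
                                                th = Thb[mm, t, u, v]
                                                if th == 0.0:
                                                    continue
                                                e1x = E1x[ia, ib, t] if t <= ia + ib else 0.0
                                                e1y = E1y[ja, jb, u] if u <= ja + jb else 0.0
                                                e1z = E1z[ka, kb, v] if v <= ka + kb else 0.0
                                                if u <= ja + jb and v <= ka + kb:
                                                    gax += _dE(E1x, ia, ib, t, a, 0) * e1y * e1z * th
                                                    gbx += _dEb(E1x, ia, ib, t, b) * e1y * e1z * th
                                                if t <= ia + ib and v <= ka + kb:
                                                    gay += e1x * _dE(E1y, ja, jb, u, a, 0) * e1z * th
                                                    gby += e1x * _dEb(E1y, ja, jb, u, b) * e1z * th
                                                if t <= ia + ib and u <= ja + jb:
                                                    gaz += e1x * e1y * _dE(E1z, ka, kb, v, a, 0) * th
                                                    gbz += e1x * e1y * _dEb(E1z, ka, kb, v, b) * th
                                    for t in range(ia + ib + 1):
                                        for u in range(ja + jb + 1):
                                            for v in range(ka + kb + 1):
                                                e = E1x[ia, ib, t] * E1y[ja, jb, u] * E1z[ka, kb, v]
                                                if e == 0.0:
                                                    continue
                                                gcx += e * Thc[0, mm, t, u, v]
                                                gcy += e * Thc[1, mm, t, u, v]
                                                gcz += e * Thc[2, mm, t, u, v]
                                    og[0, ma, mb, mc, md] += pref * gax
                                    og[1, ma, mb, mc, md] += pref * gay
                                    og[2, ma, mb, mc, md] += pref * gaz
                                    og[3, ma, mb, mc, md] += pref * gbx
                                    og[4, ma, mb, mc, md] += pref * gby
                                    og[5, ma, mb, mc, md] += pref * gbz
                                    og[6, ma, mb, mc, md] += pref * gcx
                                    og[7, ma, mb, mc, md] += pref * gcy
                                    og[8, ma, mb, mc, md] += pref * gcz
    for ma in range(nca):
        for mb in range(ncb):
            for mc in range(ncc):
                for md in range(ncd):
                    f = cfa[ma] * cfb[mb] * cfc[mc] * cfd[md]
                    for k in range(9):
                        og[k, ma, mb, mc, md] *= f


@njit(cache=True)
def _eri_grad_all(shell_l, shell_atom, shell_center, shell_off, pstart, nprim,
                  pexp, pcoef, cx, cy, cz, cf, qsh, P, hfx, grad):
    nsh = shell_l.shape[0]
    og = np.zeros((9, 6, 6, 6, 6))
    pmax = np.max(np.abs(P))
    for I in range(nsh):
        for J in range(I + 1):
            qIJ = qsh[I, J]
            for K in range(I + 1):
                for Lsh in range(K + 1):
                    if K == I and Lsh > J:
                        continue
                    if qIJ * qsh[K, Lsh] * pmax * pmax < 1e-11:
                        continue
                    nca = _nc(shell_l[I])
                    ncb = _nc(shell_l[J])
                    ncc = _nc(shell_l[K])
                    ncd = _nc(shell_l[Lsh])
                    oi, oj = shell_off[I], shell_off[J]
                    ok, ol = shell_off[K], shell_off[Lsh]
                    _eri_grad_quartet(shell_l[I], shell_l[J], shell_l[K], shell_l[Lsh],
                                      shell_center[I], shell_center[J],
                                      shell_center[K], shell_center[Lsh],
                                      pexp, pcoef, pstart[I], nprim[I], pstart[J], nprim[J],
                                      pstart[K], nprim[K], pstart[Lsh], nprim[Lsh],
                                      cx[I], cy[I], cz[I], cf[I],
                                      cx[J], cy[J], cz[J], cf[J],
                                      cx[K], cy[K], cz[K], cf[K],
                                      cx[Lsh], cy[Lsh], cz[Lsh], cf[Lsh], og)
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
                                    if I == K and J == Lsh and kl > ij:
                                        # same shell pair on both sides: the
                                        # (kl,ij) ordering re-enumerates this
                                        # quartet
                                        continue
                                    # permutation-summed two-particle density
                                    Wq = 0.0
                                    # perm 1: (mu nu|lam sig)
                                    Wq += (0.5 * P[mu, nu] * P[lam, sig]
                                           - 0.25 * hfx * P[mu, lam] * P[nu, sig])
                                    if nu != mu:
                                        Wq += (0.5 * P[nu, mu] * P[lam, sig]
                                               - 0.25 * hfx * P[nu, lam] * P[mu, sig])
                                    if sig != lam:
                                        Wq += (0.5 * P[mu, nu] * P[sig, lam]
                                               - 0.25 * hfx * P[mu, sig] * P[nu, lam])
                                    if nu != mu and sig != lam:
                                        Wq += (0.5 * P[nu, mu] * P[sig, lam]
                                               - 0.25 * hfx * P[nu, sig] * P[mu, lam])
                                    if ij != kl:
                                        Wq += (0.5 * P[lam, sig] * P[mu, nu]
                                               - 0.25 * hfx * P[lam, mu] * P[sig, nu])
                                        if sig != lam:
                                            Wq += (0.5 * P[sig, lam] * P[mu, nu]
                                                   - 0.25 * hfx * P[sig, mu] * P[lam, nu])
                                        if nu != mu:
                                            Wq += (0.5 * P[lam, sig] * P[nu, mu]
                                                   - 0.25 * hfx * P[lam, nu] * P[sig, mu])
                                        if nu != mu and sig != lam:
                                            Wq += (0.5 * P[sig, lam] * P[nu, mu]
                                                   - 0.25 * hfx * P[sig, nu] * P[lam, mu])
                                    if Wq == 0.0:
                                        continue
                                    for kxyz in range(3):
                                        ga = og[kxyz, ma, mb, mc, md]
                                        gb = og[3 + kxyz, ma, mb, mc, md]
                                        gc = og[6 + kxyz, ma, mb, mc, md]
                                        grad[shell_atom[I], kxyz] += Wq * ga
                                        grad[shell_atom[J], kxyz] += Wq * gb
                                        grad[shell_atom[K], kxyz] += Wq * gc
                                        grad[shell_atom[Lsh], kxyz] -= Wq * (ga + gb + gc)


def xc_gradient(mf, P):
    """Grid XC gradient (no weight derivatives)."""
    bs = mf.bs
    nat = len(mf.symbols)
    grad = np.zeros((nat, 3))
    atom_of = np.zeros(bs.nbf, np.int64)
    for s in range(bs.nshell):
        for m in range(_nc(bs.shell_l[s])):
            atom_of[bs.shell_off[s] + m] = bs.shell_atom[s]
    masks = [atom_of == ia for ia in range(nat)]
    npts = len(mf.gpts)
    chunk = 10000
    # second derivative component pairs for d(grad rho)
    hij = {(0, 0): 0, (1, 1): 1, (2, 2): 2, (0, 1): 3, (1, 0): 3,
           (0, 2): 4, (2, 0): 4, (1, 2): 5, (2, 1): 5}
    for s0 in range(0, npts, chunk):
        s1 = min(s0 + chunk, npts)
        pts = mf.gpts[s0:s1]
        w = mf.gwts[s0:s1]
        chi, dchi, d2chi = dft.basis_on_points(bs, pts, order=2)
        PC = chi @ P
        PD = [dchi[:, k, :] @ P for k in range(3)]
        rho = np.einsum("pi,pi->p", PC, chi)
        g = [2 * np.einsum("pi,pi->p", PC, dchi[:, k, :]) for k in range(3)]
        sigma = g[0] ** 2 + g[1] ** 2 + g[2] ** 2
        _, vr, vs = dft.xc_eval(rho, sigma)
        for ia in range(nat):
            mk = masks[ia]
            for x in range(3):
                # d rho / dXa
                t1 = -2 * np.einsum("pi,pi->p", PC[:, mk], dchi[:, x, mk])
                acc = np.dot(w * vr, t1)
                for k in range(3):
                    h = d2chi[:, hij[(x, k)], :]
                    t2 = -2 * (np.einsum("pi,pi->p", PC[:, mk], h[:, mk])
                               + np.einsum("pi,pi->p", PD[k][:, mk], dchi[:, x, mk]))
                    acc += np.dot(2 * w * vs * g[k], t2)
                grad[ia, x] += acc
    return grad


def gradient(mf):
    """Total RKS nuclear gradient (hartree/bohr), analytic."""
    bs = mf.bs
    nat = len(mf.symbols)
    P = mf.P
    # energy-weighted density
    Co = mf.C[:, :mf.nocc]
    eo = mf.mo_energy[:mf.nocc]
    Wmat = 2 * (Co * eo) @ Co.T
    grad = np.zeros((nat, 3))
    _grad_1e_pairs(bs.shell_l, bs.shell_atom, bs.shell_center, bs.shell_off,
                   bs.pstart, bs.nprim, bs.pexp, bs.pcoef,
                   bs.cx, bs.cy, bs.cz, bs.cf, bs.coords, bs.charges,
                   P, Wmat, grad)
    qsh = mdint.schwarz(bs)
    _eri_grad_all(bs.shell_l, bs.shell_atom, bs.shell_center, bs.shell_off,
                  bs.pstart, bs.nprim, bs.pexp, bs.pcoef,
                  bs.cx, bs.cy, bs.cz, bs.cf, qsh, P, mf.hfx, grad)
    if mf.xc is not None:
        grad += xc_gradient(mf, P)
    # nuclear-nuclear
    for i in range(nat):
        for j in range(nat):
            if i == j:
                continue
            rij = bs.coords[i] - bs.coords[j]
            grad[i] -= bs.charges[i] * bs.charges[j] * rij / np.linalg.norm(rij) ** 3
    return grad
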