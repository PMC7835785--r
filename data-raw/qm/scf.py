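"""Restricted Kohn-Sham B3LYP/6-31G(d) SCF with DIIS."""
import numpy as np
import mdint
import dft
from basis631gd import BASIS, Z

HF_X = 0.20


def nuclear_repulsion(coords, charges):
    e = 0.0
    for i in range(len(charges)):
        for j in range(i):
            e += charges[i] * charges[j] / np.linalg.norm(coords[i] - coords[j])
    return e


class RKS:
    def __init__(self, symbols, coords_bohr, charge=0, nrad=60, ntheta=16,
                 xc="b3lyp"):
        self.symbols = symbols
        self.coords = np.asarray(coords_bohr, float)
        self.charge = charge
        self.xc = xc
        self.hfx = 1.0 if xc is None else HF_X
        self.bs = mdint.BasisSet(symbols, self.coords, BASIS, Z)
        self.nelec = int(sum(Z[s] for s in symbols) - charge)
        assert self.nelec % 2 == 0
        self.nocc = self.nelec // 2
        self.nrad, self.ntheta = nrad, ntheta
        self._setup()

    def _setup(self):
        bs = self.bs
        self.S, self.T = mdint.overlap_kinetic(bs)
        self.V = mdint.nuclear(bs)
        self.H = self.T + self.V
        self.Enuc = nuclear_repulsion(self.coords, bs.charges)
        w, U = np.linalg.eigh(self.S)
        self.X = U @ np.diag(w ** -0.5) @ U.T
        self.gpts, self.gwts = dft.molecular_grid(self.symbols, self.coords,
                                                  self.nrad, self.ntheta)
        self.eri = None

    def _xc(self, P):
        """XC energy and matrix on the molecular grid, chunked."""
        bs = self.bs
        n = bs.nbf
        Vxc = np.zeros((n, n))
        Exc = 0.0
        npts = len(self.gpts)
        chunk = 20000
        for s0 in range(0, npts, chunk):
            s1 = min(s0 + chunk, npts)
            pts = self.gpts[s0:s1]
            w = self.gwts[s0:s1]
            chi, dchi, _ = dft.basis_on_points(bs, pts, order=1)
            PC = chi @ P                      # (m, n)
            rho = np.einsum("pi,pi->p", PC, chi)
            gx = 2 * np.einsum("pi,pi->p", PC, dchi[:, 0, :])
            gy = 2 * np.einsum("pi,pi->p", PC, dchi[:, 1, :])
            gz = 2 * np.einsum("pi,pi->p", PC, dchi[:, 2, :])
            sigma = gx ** 2 + gy ** 2 + gz ** 2
            e, vr, vs = dft.xc_eval(rho, sigma)
            Exc += np.dot(w, e)
            # V contribution: vr*chi_mu chi_nu + 2 vs grad rho . (chi_mu grad chi_nu + ...)
            a = (w * vr)[:, None] * chi
            a += (2 * w * vs * gx)[:, None] * dchi[:, 0, :]
            a += (2 * w * vs * gy)[:, None] * dchi[:, 1, :]
            a += (2 * w * vs * gz)[:, None] * dchi[:, 2, :]
            Vxc += chi.T @ a
        Vxc = 0.5 * (Vxc + Vxc.T)
        return Exc, Vxc

    def energy(self, P, J, K, Exc):
        return (np.sum(P * self.H) + 0.5 * np.sum(P * J)
                - 0.25 * self.hfx * np.sum(P * K) + Exc + self.Enuc)

    def run(self, P0=None, conv=1e-8, maxiter=60, verbose=True):
        bs = self.bs
        n = bs.nbf
        if self.eri is None:
            self.eri = mdint.eri_packed(bs)
        if P0 is None:
            # core guess
            Fp = self.X.T @ self.H @ self.X
            e, Cp = np.linalg.eigh(Fp)
            C = self.X @ Cp
            P = 2 * C[:, :self.nocc] @ C[:, :self.nocc].T
        else:
            P = P0
        Eold = 0.0
        diis_F, diis_E = [], []
        for it in range(maxiter):
            J, K = mdint.build_JK(self.eri, P, n)
            if self.xc is None:
                Exc, Vxc = 0.0, np.zeros_like(self.H)
            else:
                Exc, Vxc = self._xc(P)
            F = self.H + J - 0.5 * self.hfx * K + Vxc
            E = self.energy(P, J, K, Exc)
            err = F @ P @ self.S - self.S @ P @ F
            err = self.X.T @ err @ self.X
            enorm = np.max(np.abs(err))
            if verbose:
                print(f"  iter {it:2d}  E = {E:.9f}  dE = {E - Eold:+.2e}  |err| = {enorm:.2e}",
                      flush=True)
            if abs(E - Eold) < conv and enorm < 5e-5:
                self.E, self.P, self.F = E, P, F
                Fp = self.X.T @ F @ self.X
                eo, Cp = np.linalg.eigh(Fp)
                self.C = self.X @ Cp
                self.mo_energy = eo
                self.Exc = Exc
                return E
            Eold = E
            diis_F.append(F.copy())
            diis_E.append(err.copy())
            if len(diis_F) > 10:
                diis_F.pop(0)
                diis_E.pop(0)
            if len(diis_F) >= 2:
                m = len(diis_F)
                B = -np.ones((m + 1, m + 1))
                B[m, m] = 0.0
                for i in range(m):
                    for j in range(m):
                        B[i, j] = np.sum(diis_E[i] * diis_E[j])
                rhs = np.zeros(m + 1)
                rhs[m] = -1.0
                try:
                    c = np.linalg.solve(B, rhs)
                    F = sum(c[i] * diis_F[i] for i in range(m))
                except np.linalg.LinAlgError:
                    pass
            Fp = self.X.T @ F @ self.X
            if it < 4 and len(diis_F) < 2:
                # mild level shift early on
                pass
            eo, Cp = np.linalg.eigh(Fp)
            C = self.X @ Cp
            Pnew = 2 * C[:, :self.nocc] @ C[:, :self.nocc].T
            if it < 3:
                P = 0.3 * Pnew + 0.7 * P
            else:
                P = Pnew
        raise RuntimeError("SCF not converged")
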