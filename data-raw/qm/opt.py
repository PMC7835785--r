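"""Geometry optimization driver (Cartesian BFGS, analytic gradients)."""
import sys
import time
import json
import numpy as np
import scf
import grad
import molden

BOHR = 0.529177210903


def read_xyz(path):
    with open(path) as fh:
        n = int(fh.readline())
        fh.readline()
        syms, xyz = [], []
        for _ in range(n):
            parts = fh.readline().split()
            syms.append(parts[0])
            xyz.append([float(x) for x in parts[1:4]])
    return syms, np.array(xyz) / BOHR  # to bohr


def optimize(symbols, coords, charge, name, gtol=7e-4, maxstep=30,
             nrad=60, ntheta=16, nrad_final=80, ntheta_final=22):
    x = coords.copy().reshape(-1)
    nat = len(symbols)
    Hinv = np.eye(3 * nat) * 1.0  # bohr^2/hartree-ish initial inverse Hessian
    P0 = None
    E_prev = None
    g_prev = None
    x_prev = None
    for step in range(maxstep):
        t0 = time.time()
        mf = scf.RKS(symbols, x.reshape(-1, 3), charge=charge,
                     nrad=nrad, ntheta=ntheta)
        E = mf.run(P0=P0, verbose=False)
        P0 = mf.P
        g = grad.gradient(mf).reshape(-1)
        gmax = np.max(np.abs(g))
        grms = np.sqrt(np.mean(g ** 2))
        print(f"[{name}] step {step:2d} E={E:.8f} gmax={gmax:.2e} grms={grms:.2e} "
              f"({time.time()-t0:.0f}s)", flush=True)
        np.save(f"/root/pkg/scratch/{name}_geom.npy", x.reshape(-1, 3))
        if gmax < gtol:
            print(f"[{name}] converged at step {step}", flush=True)
            break
        if g_prev is not None:
            s = x - x_prev
            yv = g - g_prev
            sy = s @ yv
            if sy > 1e-10:
                I = np.eye(len(x))
                rho_ = 1.0 / sy
                V = I - rho_ * np.outer(s, yv)
                Hinv = V @ Hinv @ V.T + rho_ * np.outer(s, s)
        dx = -Hinv @ g
        # trust radius 0.3 bohr max atomic displacement
        mx = np.max(np.abs(dx))
        if mx > 0.3:
            dx *= 0.3 / mx
        x_prev = x.copy()
        g_prev = g.copy()
        x = x + dx
    # final tight SCF on finer grid at converged geometry
    mf = scf.RKS(symbols, x.reshape(-1, 3), charge=charge,
                 nrad=nrad_final, ntheta=ntheta_final)
    E = mf.run(P0=P0, verbose=False, conv=1e-9)
    print(f"[{name}] final E = {E:.8f}", flush=True)
    molden.write_molden(f"/root/pkg/scratch/{name}.molden", symbols,
                        x.reshape(-1, 3), mf.C[:, :mf.nocc],
                        mf.mo_energy[:mf.nocc])
    with open(f"/root/pkg/scratch/{name}_info.json", "w") as fh:
        json.dump({"E": E, "charge": charge, "symbols": symbols,
                   "coords_bohr": x.reshape(-1, 3).tolist()}, fh)
    return x.reshape(-1, 3), E


if __name__ == "__main__":
    import os
    name = sys.argv[1]
    charge = int(sys.argv[2])
    syms, coords = read_xyz(f"/root/pkg/scratch/{name}_start.xyz")
    saved = f"/root/pkg/scratch/{name}_geom.npy"
    if os.path.exists(saved):
        coords = np.load(saved)
        print(f"[{name}] resuming from saved geometry", flush=True)
    optimize(syms, coords, charge, name)
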