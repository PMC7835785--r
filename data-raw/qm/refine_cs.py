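"""Cs-symmetrize a monosubstituted ring: mirror plane through C1 and C4,
perpendicular to the ring plane (keeps pyramidal/rotor substituents),
then re-optimize briefly."""
import sys
import numpy as np
import opt


def cs_symmetrize(symbols, c):
    nat = len(symbols)
    d = lambda i, j: np.linalg.norm(c[i] - c[j])
    cs_idx = [i for i, s in enumerate(symbols) if s == "C"]
    # ring carbons: those with >= 2 C/N/O neighbours at aromatic distance
    ring = []
    for i in cs_idx:
        nb = [j for j in cs_idx if j != i and d(i, j) < 2.9]  # bohr? no: input bohr
        ring.append((i, len(nb)))
    # work in bohr: aromatic CC ~ 2.64 bohr
    ring = [i for i in cs_idx
            if sum(1 for j in cs_idx if j != i and d(i, j) < 2.9) >= 2]
    if len(ring) != 6:
        raise RuntimeError(f"ring detection found {len(ring)} carbons")
    heavy = [i for i, s in enumerate(symbols) if s not in ("H",) and i not in ring]
    # C1: ring carbon bonded to the substituent heavy atom (or to the methyl C)
    c1 = None
    for i in ring:
        for j in heavy:
            if d(i, j) < 3.2:
                c1 = i
                break
        if c1 is not None:
            break
    if c1 is None:
        raise RuntimeError("no substituted ring carbon found")
    # C4 = ring carbon farthest from C1
    c4 = max(ring, key=lambda i: d(i, c1))
    # ring plane normal
    rc = c[ring] - c[ring].mean(axis=0)
    _, _, vt = np.linalg.svd(rc)
    nr = vt[2]
    a = c[c4] - c[c1]
    a /= np.linalg.norm(a)
    m = np.cross(nr, a)
    m /= np.linalg.norm(m)
    origin = c[c1]
    refl = c - 2.0 * np.outer((c - origin) @ m, m)
    # pair atoms with their mirror images
    used = [False] * nat
    out = c.copy()
    for i in range(nat):
        if used[i]:
            continue
        jbest, db = -1, 1e9
        for j in range(nat):
            if used[j] or symbols[j] != symbols[i]:
                continue
            dd = np.linalg.norm(refl[i] - c[j])
            if dd < db:
                db, jbest = dd, j
        j = jbest
        if j == i:
            # on-plane atom: project onto the plane
            out[i] = c[i] - ((c[i] - origin) @ m) * m
            used[i] = True
        else:
            avg = 0.5 * (c[i] + refl[j])
            out[i] = avg
            out[j] = refl[i] * 0 + (avg - 2.0 * ((avg - origin) @ m) * m)
            used[i] = used[j] = True
    return out


if __name__ == "__main__":
    name = sys.argv[1]
    charge = int(sys.argv[2])
    syms, _ = opt.read_xyz(f"/root/pkg/scratch/{name}_start.xyz")
    c = np.load(f"/root/pkg/scratch/{name}_geom.npy")
    c2 = cs_symmetrize(syms, c)
    print(f"[{name}] Cs symmetrization max move:",
          float(np.abs(c2 - c).max()), flush=True)
    np.save(f"/root/pkg/scratch/{name}_geom.npy", c2)
    opt.optimize(syms, c2, charge, name, gtol=4e-4, maxstep=8,
                 nrad=70, ntheta=18)
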