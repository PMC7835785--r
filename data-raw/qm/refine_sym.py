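"""Symmetrize a near-C2v monosubstituted ring to exact Cs/C2v and re-optimize
with tighter settings (reduces mirror-pair population asymmetry)."""
import sys
import numpy as np
import opt
import scf

BOHR = 0.529177210903


def symmetrize_c2v(symbols, coords):
    """Project onto the mirror plane defined by the substituent axis.

    Works for planar C2v rings (phenolate, nitrobenzene): puts the molecule
    in the xy-plane, the C2 axis on x, and averages y-mirror pairs.
    """
    c = coords - coords.mean(axis=0)
    # plane normal via SVD: smallest singular vector
    _, _, vt = np.linalg.svd(c)
    R = vt  # rows: new axes; third row = normal
    c = c @ R.T
    c[:, 2] = 0.0  # planarize
    # C2 axis: direction from ring centroid to the unique (substituent) atom
    # -> already roughly x after SVD if the molecule is longer than wide
    # pair atoms by symbol and (x, |y|)
    used = [False] * len(symbols)
    for i in range(len(symbols)):
        if used[i]:
            continue
        best, bd = -1, 1e9
        for j in range(len(symbols)):
            if j == i or used[j] or symbols[j] != symbols[i]:
                continue
            d = abs(c[i, 0] - c[j, 0]) + abs(c[i, 1] + c[j, 1])
            if d < bd:
                bd, best = d, j
        if best >= 0 and bd < 0.4 and abs(c[i, 1]) > 0.2:
            j = best
            x = 0.5 * (c[i, 0] + c[j, 0])
            y = 0.5 * (abs(c[i, 1]) + abs(c[j, 1]))
            si = 1.0 if c[i, 1] > 0 else -1.0
            c[i] = [x, si * y, 0.0]
            c[j] = [x, -si * y, 0.0]
            used[i] = used[j] = True
        else:
            c[i, 1] = c[i, 1] if abs(c[i, 1]) > 0.2 else 0.0
            used[i] = True
    return c


if __name__ == "__main__":
    name = sys.argv[1]
    charge = int(sys.argv[2])
    geom = np.load(f"/root/pkg/scratch/{name}_geom.npy")
    syms, _ = opt.read_xyz(f"/root/pkg/scratch/{name}_start.xyz")
    c = symmetrize_c2v(syms, geom)
    np.save(f"/root/pkg/scratch/{name}_geom.npy", c)
    opt.optimize(syms, c, charge, name, gtol=4e-4, maxstep=10,
                 nrad=70, ntheta=18)
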