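"""Molden writer: occupied MOs only, Cartesian 6d, atomic units."""
from basis631gd import BASIS, Z


def write_molden(path, symbols, coords_bohr, C_occ, mo_energy_occ, prec="%.9e"):
    lines = ["[Molden Format]", "[Title]", " generated fixture", "[Atoms] AU"]
    for i, (s, xyz) in enumerate(zip(symbols, coords_bohr)):
        lines.append(f" {s:2s} {i+1:3d} {Z[s]:3d} {xyz[0]:.8f} {xyz[1]:.8f} {xyz[2]:.8f}")
    lines.append("[GTO]")
    lab = {0: "s", 1: "p", 2: "d"}
    for i, s in enumerate(symbols):
        lines.append(f" {i+1} 0")
        for (l, exps, coefs) in BASIS[s]:
            lines.append(f" {lab[l]} {len(exps)} 1.00")
            for a, c in zip(exps, coefs):
                lines.append(f"  {a:.10e} {c:.10e}")
        lines.append("")
    lines.append("[MO]")
    nocc = C_occ.shape[1]
    for k in range(nocc):
        lines.append(" Sym= A")
        lines.append(f" Ene= {mo_energy_occ[k]:.6f}")
        lines.append(" Spin= Alpha")
        lines.append(" Occup= 2.0")
        for mu in range(C_occ.shape[0]):
            lines.append(f" {mu+1:4d} {prec % C_occ[mu, k]}")
    with open(path, "w") as fh:
        fh.write("\n".join(lines) + "\n")
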