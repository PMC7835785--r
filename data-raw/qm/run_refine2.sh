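#!/bin/bash
cd /root/pkg/data-raw/qm
while [ ! -f /root/pkg/scratch/CHAIN_DONE ]; do sleep 120; done
python - <<'PY' >> /root/pkg/scratch/aniline.log 2>&1
import numpy as np, opt
syms, _ = opt.read_xyz("/root/pkg/scratch/aniline_start.xyz")
c = np.load("/root/pkg/scratch/aniline_geom.npy")
opt.optimize(syms, c, 0, "aniline", gtol=3.5e-4, maxstep=12, nrad=70, ntheta=18)
PY
python - <<'PY' >> /root/pkg/scratch/anilinium.log 2>&1
import numpy as np, opt
syms, _ = opt.read_xyz("/root/pkg/scratch/anilinium_start.xyz")
c = np.load("/root/pkg/scratch/anilinium_geom.npy")
opt.optimize(syms, c, 1, "anilinium", gtol=3.5e-4, maxstep=10, nrad=70, ntheta=18)
PY
echo REFINE2_DONE > /root/pkg/scratch/REFINE2_DONE
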