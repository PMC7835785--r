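#!/bin/bash
cd /root/pkg/data-raw/qm
while [ ! -f /root/pkg/scratch/REFINE2_DONE ]; do sleep 120; done
python - <<'PY' >> /root/pkg/scratch/toluene.log 2>&1
import numpy as np, opt
syms, _ = opt.read_xyz("/root/pkg/scratch/toluene_start.xyz")
c = np.load("/root/pkg/scratch/toluene_geom.npy")
opt.optimize(syms, c, 0, "toluene", gtol=3.5e-4, maxstep=12, nrad=70, ntheta=18)
PY
echo REFINE3_DONE > /root/pkg/scratch/REFINE3_DONE
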