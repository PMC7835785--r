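#!/bin/bash
cd /root/pkg/data-raw/qm
while [ ! -f /root/pkg/scratch/REFINE3_DONE ]; do sleep 120; done
python refine_cs.py aniline 0    >> /root/pkg/scratch/aniline.log 2>&1
python refine_cs.py anilinium 1  >> /root/pkg/scratch/anilinium.log 2>&1
python refine_cs.py toluene 0    >> /root/pkg/scratch/toluene.log 2>&1
echo REFINE4_DONE > /root/pkg/scratch/REFINE4_DONE
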