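#!/bin/bash
cd /root/pkg/data-raw/qm
set -x
python opt.py benzene 0      > /root/pkg/scratch/benzene.log 2>&1
python opt.py phenolate -1   > /root/pkg/scratch/phenolate.log 2>&1
python opt.py anilinium 1    > /root/pkg/scratch/anilinium.log 2>&1
python opt.py aniline 0      > /root/pkg/scratch/aniline.log 2>&1
python opt.py nitrobenzene 0 > /root/pkg/scratch/nitrobenzene.log 2>&1
python opt.py toluene 0      > /root/pkg/scratch/toluene.log 2>&1
echo ALL_DONE
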