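"""6-31G(d) basis set data (Cartesian 6d), H/C/N/O, Gaussian convention.

Exponents/coefficients are the standard published Pople values.
Shells are given as (angmom, [exponents], [contraction coeffs]);
SP shells are split into separate s and p entries sharing exponents.
"""

BASIS = {
    "H": [
        (0, [18.73113696, 2.825394365, 0.6401216923],
            [0.03349460434, 0.2347269535, 0.8137573261]),
        (0, [0.1612777588], [1.0]),
    ],
    "C": [
        (0, [3047.52488, 457.369518, 103.948685, 29.2101553, 9.28666296, 3.16392696],
            [0.0018347, 0.0140373, 0.0688426, 0.2321844, 0.4679413, 0.3623120]),
        (0, [7.86827235, 1.88128854, 0.544249258],
            [-0.1193324, -0.1608542, 1.1434564]),
        (1, [7.86827235, 1.88128854, 0.544249258],
            [0.0689991, 0.3164240, 0.7443083]),
        (0, [0.1687144782], [1.0]),
        (1, [0.1687144782], [1.0]),
        (2, [0.8], [1.0]),
    ],
    "N": [
        (0, [4173.51146, 627.457911, 142.902093, 40.2343293, 12.8202129, 4.39043701],
            [0.00183477216, 0.013994627, 0.068586551, 0.232240873, 0.469069948, 0.360455199]),
        (0, [11.6263619, 2.71627981, 0.772218397],
            [-0.114961182, -0.169117478, 1.14585195]),
        (1, [11.6263619, 2.71627981, 0.772218397],
            [0.0675797980, 0.323907297, 0.740895400]),
        (0, [0.212031498], [1.0]),
        (1, [0.212031498], [1.0]),
        (2, [0.8], [1.0]),
    ],
    "O": [
        (0, [5484.67166, 825.234946, 188.046958, 52.9645000, 16.8975704, 5.79963534],
            [0.00183107443, 0.0139501722, 0.0684450781, 0.232714336, 0.470192898, 0.358520853]),
        (0, [15.5396162, 3.59993359, 1.01376175],
            [-0.110777549, -0.148026262, 1.13076701]),
        (1, [15.5396162, 3.59993359, 1.01376175],
            [0.0708742682, 0.339752839, 0.727158577]),
        (0, [0.270005823], [1.0]),
        (1, [0.270005823], [1.0]),
        (2, [0.8], [1.0]),
    ],
}

Z = {"H": 1, "C": 6, "N": 7, "O": 8}
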