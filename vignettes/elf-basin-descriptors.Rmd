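---
title: "Electron-pair basins and substituent-effect descriptors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-pair basins and substituent-effect descriptors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`elfiqa` analyses a closed-shell single-determinant wavefunction (Kohn-Sham
or Hartree-Fock) through the topology of the electron localization function
(ELF). The chain is:

1. evaluate the electron density $\rho$, its gradient, and the
   positive-definite kinetic-energy density
   $\tau = \tfrac12 \sum_i n_i |\nabla\varphi_i|^2$ on a uniform grid;
2. map them through the ELF kernel
   $\chi = D/D_0$, with $D = \tau - |\nabla\rho|^2/(8\rho)$ (the Pauli
   excess kinetic energy density) and
   $D_0 = \tfrac{3}{10}(3\pi^2)^{2/3}\rho^{5/3}$ (its homogeneous-gas
   value), and the Lorentzian $\eta = 1/(1+\chi^2) \in [0,1]$;
3. partition space into basins of attraction of the maxima of $\eta$
   (cores, bonds, lone pairs), classify each basin by the atomic cores it
   touches (synapticity), and label the six ring-bond basins
   $b_{12}\dots b_{61}$ of a monosubstituted benzene, with $C_1$ the
   substituted carbon;
4. integrate per-basin populations $n_\Omega$, kinetic energies $T_\Omega$
   and the domain overlap matrices
   $S^\Omega_{ij} = \int_\Omega \varphi_i\varphi_j$;
5. derive delocalization indices
   $\delta(A,B) = 4\sum_{ij} S^A_{ij}S^B_{ij}$ and localization indices
   $\lambda(A) = 2\sum_{ij}(S^A_{ij})^2$ (closed-shell single-determinant
   reduction; $\delta(A,B)$ equals $-2\,\mathrm{cov}(n_A,n_B)$, the
   population-fluctuation measure), and the *vicinal* indices DI(i/o/m/p)
   between adjacent ring-bond basins sharing the ipso/ortho/meta/para
   carbon;
6. optionally compute interacting-quantum-atoms (IQA) style inter-basin
   energies: the classical Coulomb term (electron-electron plus the nuclear
   terms a basin owns) and the exchange part of $V_{xc}$,
   $V_x^{AB} = -2\sum_{ij}\int_A\int_B
   \varphi_i\varphi_j(1)\,\varphi_i\varphi_j(2)/r_{12}$,
   at deliberately coarse resolution;
7. assemble substituent-effect descriptors: symmetry-averaged ring
   populations $(n_{12}, n_{23}, n_{34})$, kinetic energy per electron
   $t_{ij}/n_{ij}$, their changes against a benzene reference computed at
   identical settings, the inductive-vs-mesomeric pattern label, the
   orientation prediction from the signs of $\Delta$DI(o/m/p), and the
   Hammett correlation of $\sigma_m-\sigma_p$ with DI(m)$-$DI(p).

The ELF kernel convention is the closed-shell total-density form above.
The literature also writes a spin-resolved kernel $\chi_\sigma$; for the
closed-shell determinants this package accepts, the two conventions produce
the same $\eta$ field, so nothing is lost by fixing the total-density form.

Assumptions: the state is a closed-shell single determinant with integer
occupations ("pseudo one-determinant"); open-shell input is rejected at
parse time. Basis functions are contracted Cartesian Gaussians up to d.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_points` | 150 | per axis | grid resolution of the analysis protocol |
| `margin` | 5 | bohr | box padding beyond the outermost nucleus |
| `floor` | 1e-10 | e/bohr^3 | density below which a voxel is vacuum ($\eta := 0$) |
| `merge_dist` | 0.2 | bohr | attractors closer than this (and within `merge_eta`) coalesce |
| `merge_eta` | 1e-3 | -- | ELF tolerance for attractor merging and shallow-saddle merging |
| `refine` | 3 | -- | subdivision factor for boundary/near-core voxels |
| `refine_radius` | 1.2 | bohr | radius around Z>2 nuclei with forced subdivision |
| `refine_rho_min` | 1e-5 | e/bohr^3 | boundary voxels below this density are not subdivided |
| `resolution` (IQA) | 24 | cells/axis | coarse-cell resolution of the 6D quadrature |
| `eps_pop` | 0.01 | e | tie tolerance of the decay/oscillation pattern rule |
| `eps_di` | 0.005 | -- | sign tolerance of the orientation rule |

The 150-point grid and the energetic analysis protocol follow standard
practice for ELF basin integration of single-ring aromatics; the margin is
chosen so that valence basins of neutral and singly charged rings decay
well inside the box. Basins whose population falls below 0.05 e are
flagged `spurious` in the observables table and reported as such -- they are
never merged silently. Such basins arise from a genuine artifact of the ELF
formula: in far low-density tails a single orbital dominates, so
$D \to 0$ and $\eta$ rises again, producing shallow far-field attractors
that carry a few thousandths of an electron.

# Numerical choices

**Basin assignment.** Discrete steepest ascent over the 26-neighbour
stencil, moving to the neighbour with the largest *slope* (value difference
divided by neighbour distance -- using raw differences instead biases the
walk toward diagonal moves and visibly breaks the D6h degeneracy of
benzene). Slope ties break to the lowest linear voxel index; exactly flat
neighbourhoods drain to the lowest-index equal-valued voxel, which makes
every move strictly increase (value, -index) lexicographically and
guarantees termination. Paths are compressed union-find style.

**Attractor merging.** Two rules, both with ELF tolerance `merge_eta`:
attractors within `merge_dist` of each other (grid noise splitting one
maximum), and adjacent basins whose separating saddle lies within
`merge_eta` of the lower attractor (ring-shaped maxima, e.g. around the
O axis in phenolate, and exactly degenerate plateaus such as the
one-orbital toy whose ELF is identically 1).

**Boundary-refined integration.** Basin integrals are Riemann voxel sums,
but voxels on an inter-basin boundary, and voxels within `refine_radius` of
a heavy nucleus, are subdivided `refine`^3-fold; boundary sub-points are
assigned by trilinear-interpolated gradient ascent of $\eta$. Plain
centre-point sums at the protocol grid leave two visible artifacts: the
electron count comes out ~0.05 e short (the 1s density peak is
under-sampled) and the core/valence dividing surface -- across which $\tau$
varies steeply -- is quantized to whole voxels, which biases the aromatic
bond kinetic energy per electron downward by about 0.05 au. With
refinement, benzene's six V(C,C) populations agree within 0.007 e, the
total electron count is recovered to better than 0.01 e, and t/n is
converged to ~0.01 au at the protocol grid. The residual difference of the
benzene t/n from the reference value it is compared against in the
acceptance suite (~0.02 au low) is dominated by the integration-box
convention: a tighter box clips diffuse low-$\tau$ tails and raises t/n,
but discards real electron density (box-size studies are easy to repeat by
passing `margin`). We keep the complete-space convention and document the
deviation rather than tuning the box to the target.

**Degenerate inputs.** All-vacuum fields raise "no attractors"; empty
basins raise an undefined-ratio error in `kinetic_per_electron()`;
geometry mismatches between a partition and a wavefunction (nuclei moved
beyond 1e-6 bohr) are refused; open-shell or fractionally occupied files
are rejected loudly.

**Reduced-precision coefficient files.** The shipped Molden fixtures store
occupied-MO coefficients at reduced precision to stay compact. On parsing,
if the occupied-MO overlap residual is above 1e-8 but small, the occupied
block is Loewdin-orthonormalised against the analytic basis overlap; this
restores orthonormality to machine precision without biasing the density.
Residuals above 1e-3 are treated as corrupt input.

**IQA accuracy class.** The inter-basin Coulomb and exchange terms use
direct double sums over coarse cells (charge, centroid, and orbital-pair
products per cell) with coincident-cell self-terms excluded. This is a
descriptor-grade quadrature: on toys it reproduces the point-charge limit
to 1%, the Gaussian self-energy to a few percent, and the exchange of a
half-split bond to machine precision at voxel-level cells. It is *not*
chemical-accuracy IQA; its purpose is ranks and signs (|V_x| tracking
delta across ring pairs), and the output carries `resolution` and
`error_class` fields to say so.

# What the toy generator emulates

`make_toy_wavefunction()` builds three analytic closed-shell systems:

- `one_orbital_bond`: one doubly occupied sigma-type MO over two s
  Gaussians. For any single-orbital closed shell,
  $\tau = |\nabla\rho|^2/(8\rho)$ pointwise, so $D = 0$ and ELF is
  identically 1 -- the sharpest available oracle for the kernel, and the
  midplane split gives the closed forms $n = 1$ per half and
  $\delta(A,B) = 4s(1-s)$ with $s = S^A_{11}$.
- `two_orbital_model`: four electrons in the orthogonal symmetric and
  antisymmetric combinations; used for MO-rotation invariance and sum
  rules.
- `atomlike`: a tight core plus diffuse valence s orbital on one centre,
  giving the simplest core + shell ELF topology.

These toys exercise every numerical path (evaluation, kernel, ascent,
merging, integration, DIs, IQA) with closed-form or brute-force oracles,
but they do not probe d-function bonding, ring topology detection, or
near-degenerate attractor merging on realistic fields -- that is what the
shipped single-ring wavefunctions cover. Passing toy tests therefore
validates the machinery, not the chemistry; the chemistry checks are the
benzene census, the D6h degeneracies, and the substituted-ring descriptor
patterns in the acceptance suite.

# Wavefunction fixtures

The package ships optimized wavefunctions for benzene, phenolate,
anilinium, aniline, nitrobenzene and toluene as Molden files (occupied
orbitals only, Cartesian 6d). They were produced with a restricted
Kohn-Sham B3LYP implementation using the VWN3 (RPA-parametrised) local
correlation in the Gaussian-style blend, the 6-31G(d) basis, Becke-grid
quadrature, and analytic-gradient geometry optimization (maximum force
below 7e-4 hartree/bohr; benzene optimizes to r(CC) = 1.399 A,
r(CH) = 1.087 A). The generation scripts live in `data-raw/qm/` and are
validated against closed-form integrals, finite-difference gradients, and
the Hartree-Fock water energy at its textbook geometry. An external QM
driver can substitute its own Molden files anywhere a fixture is used.

# Known limitations

- Closed-shell determinants only; no spin-polarized ELF, no correlated
  pair densities.
- Basis support stops at Cartesian d shells; Molden files with spherical
  d ([5D]) or f functions are rejected.
- The bifurcation-tree (f-localization) analysis of ELF is out of scope.
- Inter-basin V_xc is exchange-only and coarse by design; absolute values
  should not be quoted, only ranks/signs.
- The full DI matrix is cheap, but `assemble_iqa()` cost grows with the
  square of the number of coarse cells per basin; request only the pairs
  of interest.
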