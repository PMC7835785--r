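# elfiqa

Electron-pair basin analysis of substituent effects in electrophilic
aromatic substitution (EAS), for computational chemists who want
bond-centric — rather than atom-centric — descriptors of ring
activation and orientation.

## What it computes

From a closed-shell single-determinant wavefunction (Molden, AIM
`.wfn`/`.wfx`), `elfiqa`:

1. evaluates the density ρ, its gradient, and the positive-definite
   kinetic-energy density τ = ½ Σᵢ nᵢ |∇φᵢ|² on a uniform grid;
2. computes the electron localization function through the kernel
   χ = D/D₀ with D = τ − |∇ρ|²/(8ρ) and D₀ = (3/10)(3π²)^{2/3} ρ^{5/3},
   mapped by the Lorentzian η = 1/(1 + χ²) ∈ [0, 1];
3. partitions space into basins of the maxima of η (cores C(X), bonds
   V(X,Y), lone pairs V(X)) by steepest ascent, and labels the six
   aromatic ring-bond basins b12…b61 with C1 the substituted carbon;
4. integrates basin populations n_Ω, kinetic energies T_Ω, and domain
   overlap matrices S^Ω over the occupied orbitals;
5. derives delocalization indices δ(A,B) = 4 Σᵢⱼ S^A_ij S^B_ij
   (= −2·cov(n_A, n_B), the shared electron-pair count) and the vicinal
   indices DI(i/o/m/p) between adjacent ring-bond basins;
6. computes inter-basin IQA-style Coulomb and exchange energies at
   coarse (descriptor-grade) resolution;
7. assembles EAS descriptors: n₁₂/n₂₃/n₃₄ decay (inductive) vs
   oscillation (mesomeric), kinetic energy per electron t/n, Δ values
   against a benzene reference, orientation prediction from the signs of
   ΔDI(o/m/p), and the Hammett regression of σ_m − σ_p on DI(m) − DI(p).

Optimized B3LYP(VWN3)/6-31G(d) wavefunctions for benzene and several
monosubstituted benzenes ship with the package; see
`elfiqa_example()` and the methods vignette
(`vignettes/elf-basin-descriptors.Rmd`).

## Worked example

```r
library(elfiqa)
benzene <- analyze_molecule(elfiqa_example("benzene"), n_points = 150)
print(benzene)
#> <elf_analysis> 12 atoms, 24 basins
#>   ring n_ij: b12 2.798 b23 2.798 b34 2.793 b45 2.798 b56 2.798 b61 2.793
#>   DI(a): i 0.556 o 0.557 m 0.557 p 0.556

rep <- build_report(benzene, benzene)   # benzene against itself: all deltas 0
print(rep)
#> <ring_descriptors>
#>   n:      q12 2.795  q23 2.798  q34 2.795  (mean ring 2.796)
#>   t/n:    q12 1.1506  q23 1.1423  q34 1.1506 au
#>   dn:     +0.000 +0.000 +0.000   d(t/n): +0.0000 +0.0000 +0.0000
#>   DI(i/o/m/p): 0.556 0.557 0.557 0.556   dDI: +0.000 +0.000 +0.000 +0.000
#>   pattern: mixed   orientation: indeterminate
```

Reading the output: each aromatic C–C bond basin holds ≈ 2.80 electrons
and its electrons carry ≈ 1.15 hartree of kinetic energy per electron;
the four vicinal delocalization indices are degenerate (D6h), so benzene
shows no decay pattern ("mixed") and no orientation preference. For a
substituted ring, analyze the molecule the same way and pass the benzene
analysis as `reference`: monotonically decaying populations
(n12 > n23 > n34) mark inductively dominated substituents (e.g. toluene),
an interior maximum at n23 marks mesomeric ones (e.g. aniline), and a
(+, −, +) sign pattern of ΔDI(o/m/p) predicts ortho/para orientation.

A command-line interface wrapping the same functions is installed at
`inst/cli/elfiqa.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "elfiqa.R", package="elfiqa"))') \
    analyze aniline.molden --ref benzene.molden --grid 150 --out results/
```

Subcommands: `analyze`, `elf-cube`, `basins`, `di`, `iqa`, `hammett`,
`fixtures`.

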