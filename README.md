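# patchyfold

Monte Carlo design and folding of patchy heteropolymers: a simulator and
analysis toolkit for asking when a polymer architecture — a chain of
beads with an alphabet of isotropic "chemical" interactions plus
directional surface patches — is *designable*, i.e. admits at least one
sequence that reliably refolds into a unique compact target structure,
the way protein sequences do.

It is aimed at researchers in coarse-grained molecular modelling and
colloidal self-assembly who want to probe the interplay of alphabet size
*q*, patch number and chain stiffness in sequence design, without
cluster-scale infrastructure: everything runs from R, with the Monte
Carlo inner loops compiled via Rcpp.

## The model

Each monomer is a hard bead of radius *R*<sub>bead</sub> (the unit of
length; energies are in units of *k*<sub>B</sub>*T*<sub>Ref</sub>).
Two chain models are supported: the **FRC** (freely rotating chain),
whose harmonic spring bonds bead centers, and the **FJC** (freely
jointed chain), whose spring connects anchoring points on the bead
surfaces, coupling orientation to the chain.

Non-bonded beads of types *A*, *B* interact isotropically through a
square-well-like sigmoid,

> *E*<sub>AB</sub>(r) = ε<sub>AB</sub> [1 − 1/(1 + e^{2.5(r_max − r)})],  r_max = 6,

infinite below the hard-core contact (*r* &lt; 2) and equal to
ε<sub>AB</sub>/2 exactly at the cutoff *r*<sub>max</sub>. The q(q+1)/2
prefactors ε<sub>AB</sub> are Gaussian with zero mean and standard
deviation 0.33 — the heteropolymer's random chemistry. Patches fixed on
the bead surface (poles, equatorial triangle, tetrahedron, octahedron,
10-point spherical code) add the directional term

> *E*<sub>p</sub> = s ε<sub>p</sub> (cos θ₁ cos θ₂)^ν [5(σ/R)¹² − 6(σ/R)¹⁰],

with s = 4, ε<sub>p</sub> = 3.1, ν = 2, σ = *R*<sub>bead</sub>: a 10–12
well of depth −s ε<sub>p</sub> = −12.4 *k*<sub>B</sub>*T* reached when
two patches face each other at patch separation σ (bead centers 3 radii
apart — the origin of the directional peak in g(r) at r ≈ 3).

The **SDF protocol** decides designability in three Monte Carlo stages,
each replica-exchanged over a 16-temperature ladder and repeated over
independent runs until the free-energy profiles agree within their
statistical errors:

1. **SEEK** — joint sampling of conformations *and* sequences; the
   target structure is extracted from the global minimum basin of the
   cold free-energy landscape.
2. **DESIGN** — sequence-only sampling with the structure frozen;
   returns the minimum-energy sequence subject to a composition-entropy
   (heterogeneity) constraint.
3. **FOLD** — conformational sampling from a stretched chain with the
   designed sequence; the free energy *F*(DRMSD) per temperature decides
   whether the chain refolds (global minimum below the molten-globule
   band of the matched 0-patch baseline) or collapses into a disordered
   globule.

Order parameters are the DRMSD (root-mean-square deviation of all
inter-bead distances, zero only at the target's distance set) and the
Kabsch-superposition RMSD, both with a 1/N prefactor.

## Worked example

A desk-scale designability fingerprint: a 20-mer FRC chain with 4
patches and the full q = 20 alphabet, on a reduced 6-temperature ladder,
2 independent runs per stage.

```r
library(patchyfold)

p <- model_params("FRC")
isotropic_pair_energy(6, -1, p)      # [1] -0.5  (half depth at r_max)
directional_pair_energy(c(0,0,0), c(1,0,0),
                        c(1,0,0), c(-1,0,0), p)   # [1] -12.4

cfg <- run_config(n = 20, q = 20, n_patches = 4, seed = 101, n_runs = 2,
                  sweeps = 6000, burnin = 2000, stride = 5,
                  temperature_ladder = c(3, 2, 1.4, 1, 0.7, 0.4))
target   <- sdf_seek(cfg)
designed <- sdf_design(target, cfg)
folded   <- sdf_fold(designed, target, cfg)
print(folded)
#> <fold_result> 6 temperatures; global-minimum DRMSD per T:
#>   temperature min_drmsd
#> 1         3       1.38
#> 2         2       1.18
#> 3         1.4     1.02
#> 4         1       0.975
#> 5         0.7     1.12
#> 6         0.4     0.975

gr <- radial_distribution(fold_ensemble(folded), bin_width = 0.1)
peak_area_ratio(gr)
#> <peak_report> random / directional = 0.2696 / 1.362 = 0.1979
#>   r_left r_max r_right height prominence  area
#> 1   2.25  2.85    3.35   2.07       1.95  1.36
```

The analysis detects a distinct peak at r ≈ 2.85–2.95 — the directional
patch-bonding peak — whose area dominates the random-packing peak at
bead contact (ratio ≈ 0.2). Re-running the identical protocol with
`n_patches = 0` yields a featureless curve in the directional window
(ratio ≈ 0.95, no detected peak): the fingerprint that separates
designable patchy architectures from bare heteropolymers. At this desk
scale the folding minima sit near the molten-globule band; resolving a
sharp folded minimum at DRMSD &lt; 0.6 for 50-mers requires
cluster-scale sweep counts.

`autoplot(gr)`, `autoplot(folded)` and `plot_designability_diagram()`
give quick-look figures; `tidy()`/`glance()` return tibbles for further
dplyr work.

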