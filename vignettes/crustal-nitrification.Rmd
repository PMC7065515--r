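---
title: "Inferring nitrification in oxic subseafloor crust: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nitrification in oxic subseafloor crust: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrocrust)
```

Cold, oxygenated seawater circulates for millennia through the basaltic
crust of sediment-covered ridge flanks. If ammonia-oxidizing archaea (AOA)
live there, three independent lines of evidence should agree: nitrification
must be thermodynamically worthwhile, the basement nitrate budget must show
a source that advection and diffusion alone cannot supply, and the rocks
must host AOA at densities above what passive seeding from seawater would
leave behind. `nitrocrust` implements the quantitative chain behind each
line, plus the diversity and community statistics used to describe the
organisms. This vignette explains the models, the defaults, and what the
package does and does not claim.

## 1. Energetics of complete nitrification

The balanced overall reaction is

$$\mathrm{NH_4^+ + 2\,O_2 \rightarrow NO_3^- + 2\,H^+ + H_2O},$$

the sum of ammonia oxidation (1.5 mol O2) and nitrite oxidation (0.5 mol
O2). Its free-energy yield under in situ conditions is

$$\Delta G = \Delta G^\circ(T) + RT \ln Q, \qquad
Q = \frac{a_{\mathrm{NO_3^-}}\, a_{\mathrm{H^+}}^2\, a_{\mathrm{H_2O}}}
         {a_{\mathrm{NH_4^+}}\, a_{\mathrm{O_2}}^2}.$$

Design choices, each visible in the stored metadata:

* **Standard-state data.** The package ships a small versioned table of
  25 °C formation free energies and enthalpies (Amend & Shock 2001 values)
  for the five species of the reaction; `thermo_constants()` can read any
  table in the same format, so the provenance of every number is a text
  file, not code.
* **Temperature correction.** $\Delta G^\circ(T)$ uses the constant-
  $\Delta H^\circ$ van't Hoff form
  $\Delta G^\circ(T) = \Delta H^\circ_{298} - T(\Delta H^\circ_{298} -
  \Delta G^\circ_{298})/298.15$. Between 25 °C and the 1.5 °C aquifer this
  moves the standard energy by under 3 kJ mol⁻¹ — three decades smaller
  than the favorability margin — so neglecting $\Delta C_p$ is harmless.
* **Pressure.** Carried in `reaction_conditions()` for documentation
  (default 450 bar, ~4.5 km water depth) but off in the energy by default;
  a constant-$\Delta V$ term can be switched on
  (`pressure_correction = TRUE`). For aqueous reactions with
  $|\Delta V| \lesssim 50$ cm³ mol⁻¹ the correction is ~2 kJ mol⁻¹ —
  again negligible against a −300 kJ mol⁻¹ signal.
* **Activities.** Equal to molar concentrations (ideal dilute solution),
  water activity 1. Seawater ionic strength would shift individual activity
  coefficients by tens of percent, i.e. $RT\ln(\gamma)$ terms of order
  1 kJ mol⁻¹; no speciation or Debye–Hückel modelling is attempted
  (a stated non-goal).
* **pH.** The aquifer pH is not measured; 7.9 (deep Atlantic bottom-water
  like) is the default and is recorded in every grid's metadata. Because
  H⁺ enters squared, a full unit of pH moves $\Delta G$ by
  $2RT\ln 10 \approx 10.5$ kJ mol⁻¹ — material for marginal systems,
  irrelevant at a −330 kJ mol⁻¹ yield.

```{r thermo}
tc <- thermo_constants()
rc <- reaction_conditions(activity_nh4 = 1e-8, activity_o2 = 2.1e-4,
                          activity_no3 = 2.11e-5)
gibbs_free_energy(tc, rc)
```

Even at the lowest measured crustal ammonium (0.01 µM) the yield is
hundreds of kJ mol⁻¹ past the −10 kJ mol⁻¹ minimal energy quantum that
`favorability_mask()` uses as its default threshold. The exact contour
values of an energy surface depend on the constants table and the activity
conventions above; the robust, reproducible claim is the favorability
classification, not any individual contour.

## 2. The two-borehole box model

`fick_flux()` estimates the diffusive nitrate flux across the
sediment–basement interface from the basal porewater gradient:
$F_d = \phi D_s\, dC/dz$, with the gradient from an OLS line through a
caller-chosen number of deepest samples (default 3; the fitting window is
an honest free parameter, so it is an argument, not a constant). With
depth in m and concentrations in µM, $\phi D_s$ in m² yr⁻¹ gives $F_d$
directly in mmol m⁻² yr⁻¹. Positive flux means transport downward into the
basement.

The box model treats the basement flow path between two boreholes (length
$X$, cross-section 1 cm × 1 cm, flow rate $Q_{sw}$ in m³ yr⁻¹ per cm of
width) as a single stirred box with advective throughput and diffusive
input $I$ from the sediment above:

* conservative prediction:
  $[\mathrm{NO_3^-}]_{end}^{cons} = [\mathrm{NO_3^-}]_{start} + I/Q_{sw}$;
* net reaction rate:
  $R = ([\mathrm{NO_3^-}]_{end}^{obs} Q_{sw} -
  [\mathrm{NO_3^-}]_{start} Q_{sw} - I)/X$, in µmol yr⁻¹ per cm of path
  length (the per-cm denominator is read as path length, one of two
  defensible readings, and documented here).

Two deliberate modelling decisions:

* **Sign of the diffusive term.** $I$ is *subtracted* in $R$: diffusive
  input is supply, not in-basement production. The acid test is built into
  the suite — a conservative solute whose observed endpoint equals the
  conservative prediction must return exactly $R = 0$ — and an
  along-path discretization (100 segments, each receiving $I/100$)
  reproduces the closed form to 10⁻⁹ relative.
* **The flux–volume coupling.** A per-area flux must be multiplied by an
  exchange area to enter a volumetric budget. The literal geometry
  ($A_{eff} = X \times 1\,\mathrm{cm} = 39$ m² for a 3.9 km path) yields a
  diffusive enrichment of ~41 µM at $Q_{sw} = 0.01$ m³ yr⁻¹ — an order of
  magnitude more than published endpoint bands for comparable settings —
  so the effective area evidently is not the literal one, and the original
  coupling rule is not recoverable from the printed equations.
  `flow_path_model()` therefore exposes `effective_exchange_area` as an
  explicit parameter defaulting to the literal geometry, and every sweep
  reports the `implied_exchange_area_m2` that would match a target
  endpoint (~0.48 m² for a 0.5 µM enrichment at the low-flow end). The
  discrepancy is surfaced, not tuned away; consequently the package treats
  endpoint bands and O2-share curves as *structure* to verify (monotone in
  $Q_{sw}$, conservative round trip, exact stoichiometric ratio) rather
  than numbers to reproduce.

Uncertainty propagates by interval arithmetic on the start/end
concentrations at the stated 2% relative measurement uncertainty — the
same gray-band construction used in flow-sweep figures. The
nitrification share of oxygen consumption is $2R$ (2 mol O2 per mol NH4⁺)
over an externally supplied O2 consumption rate; with rate 3 and
consumption 100 the share is exactly 0.06.

```{r transport}
m <- flow_path_model(path_length = 3900, flow_rate = 0.01,
                     start_concentration = 23.5,
                     end_concentration_observed = 28.2,
                     flux_start = 0.010, flux_end = 0.011,
                     effective_exchange_area = 0.476)
reaction_rate(m)
```

## 3. qPCR and cell densities

The standard curve is an OLS fit of Cq on log10(copies µl⁻¹);
amplification efficiency is $E = 10^{-1/\mathrm{slope}} - 1$ (slope
−3.3219 at 100% efficiency). `quantify()` inverts the curve, scales by
elution/template volume and sample mass, and flags — never censors —
results under the detection limit (default 150 copies g⁻¹, typical of
low-biomass rock assays): a non-detect is information, not a zero.
Elution volume (100 µl) and sample mass (0.5 g) default to a standard
spin-kit extraction; the template volume has no default because no
universal convention exists.

Cell densities follow from single-copy marker arithmetic:
cells cm⁻³ of pore space = copies g⁻¹ × grain density / porosity
(defaults 3 g cm⁻³ and 4%, representative of altered basalt). For
seawater, `seawater_taxon_density()` multiplies a total cell count by an
ordered chain of fractions (e.g. archaeal fraction, then clade fraction)
with 1 mL ≡ 1 cm³ explicit. Published clade-level seawater densities are
often built from intermediate fractions that are not printed; the function
supports arbitrary chains and deliberately hard-codes none of them.

## 4. Clone-library diversity

Distances are uncorrected p-distances with pairwise deletion: columns with
a gap or N in either sequence are dropped per pair (computed via
`ape::dist.dna`; a pair with no comparable columns is an error naming the
pair). No evolutionary correction is applied — at the 3–5% divergences
where OTUs are called, correction models differ by far less than the
cutoff granularity.

OTU clustering is furthest-neighbor (complete-linkage) agglomeration:
merges in ascending linkage order while the merged cluster's maximum
pairwise distance stays within the cutoff (0.03 for the 16S 97%
convention, 0.05 for the *amoA* 95% convention). The implementation rides
on `stats::hclust`/`cutree`, which is deterministic for a fixed input
order; the suite checks it against a naive independently coded
agglomerator on hundreds of random small alignments.

Richness and coverage use the small-library estimators:

* **Chao1, bias-corrected:** $S_{chao1} = S_{obs} + n_1(n_1-1)/(2(n_2+1))$.
  The bias-corrected form is the only defensible choice here: real clone
  libraries of a few dozen clones routinely have $n_2 = 0$, where the
  classic $n_1^2/(2n_2)$ form is undefined — and the corrected form
  reproduces the worked library examples (36 clones/8 OTUs/4 singletons →
  14; 33/6/2 → 7) exactly.
* **Coverage:** $C = (1 - n_1/N) \times 100$ with $n_1$ counting
  *singleton OTUs* (not singleton reads — the two conventions coexist in
  the literature; the OTU reading is adopted and stated).
* **Shannon** uses the natural log; **Simpson** is reported both as
  $D = \sum p_i^2$ and $1 - D$.
* **Rarefaction** is the analytic hypergeometric expectation
  $E[S_k] = \sum_i [1 - \binom{N-N_i}{k}/\binom{N}{k}]$, evaluated through
  log-binomials for stability, cross-checked in the tests against both
  `vegan::rarefy` and 10⁴-draw Monte Carlo subsampling.

Integer presentation uses round-half-away-from-zero (`round_half_up()`),
the convention of printed diversity tables; machine output always keeps
the exact value.

## 5. Community tables

`community_table()` couples a samples × OTU count matrix to habitat/depth
metadata (seawater, sediment, basalt) and an OTU → (family, clade)
taxonomy. Clade labels are *inputs*: phylogenetic placement is upstream,
out of scope. `relative_abundance()` computes percent ratios between
arbitrary taxon selectors with zero-denominator samples flagged and
excluded from summaries; `habitat_summary()` reports mean ± sample SD
(n−1; SD 0 for singletons groups); `clade_profile()` and `heatmap_table()`
produce the depth-ordered within-family composition and OTU-level percent
matrices behind profile and heatmap figures, with family-absent samples as
blanks (NA), not zeros. Percent denominators are always computed from the
supplied count matrix; published table percentages that use unstated
denominators are not reproduced as exact values by design.

## 6. The synthetic-data generators

Every input has a seeded generator (`make_*`), a pure function of its
arguments drawing from a locally seeded Mersenne-Twister stream that
leaves the caller's RNG untouched:

* **Porewater profiles:** linear gradient + i.i.d. Gaussian noise. Real
  profiles have curvature from reaction within the sediment column; the
  generator only emulates the basal quasi-linear zone that the flux fit
  actually uses.
* **Clone libraries:** explicit abundance vectors verbatim (the worked
  examples), or symmetric-Dirichlet proportions + multinomial draw.
* **Sequence families:** a random root, clade ancestors mutated at
  (between-divergence)/2 per site, leaves at (within-divergence)/2.
  Realized mean divergences land within ±20% of target for alignments of a
  few hundred nt (verified at the 592-nt functional-gene width). No
  indels, chimeras, or rate heterogeneity — this is a clustering test
  harness, not a sequence evolution model.
* **Community tables:** Dirichlet-multinomial counts around per-habitat
  clade designs, with a per-habitat family fraction (defaults 1.15%
  seawater, 10% sediment, 0.5% basalt — the magnitudes typical of the
  three habitats) and a residual "other" compartment.
  `overdispersion = 0` gives plain multinomial sampling.
* **qPCR series:** Cq from the log-linear amplification model over a 10×
  series from 1.5×10⁵ down to 1.5 copies µl⁻¹, plus Gaussian Cq noise.

Because generated data satisfy the model assumptions by construction,
passing tests demonstrate *correct implementation and estimator
consistency* — flux recovery, efficiency recovery, planted-clade
resolution, design-proportion recovery — not robustness to the ways real
profiles, chromatograms, and amplicon libraries violate those assumptions.

## 7. Numerical choices and test scale

* All box-model arithmetic is SI internally (mol, m³, yr) with unit
  conversion at the constructor boundary; supplying concentrations in
  mol m⁻³ instead of µM yields bit-identical results.
* Rarefaction uses `lchoose` differences to avoid overflow at any library
  size.
* Clustering ties (exactly equal distances) follow `hclust`'s
  deterministic input-order behavior; for continuous distances ties have
  probability zero, and the test oracle compares partitions up to
  relabeling.
* The suite runs at desk scale by design: 10³ random box models for the
  conservation round trip, 200 random ≤6-sequence alignments against the
  brute-force clustering oracle, 10⁴ Monte Carlo draws for rarefaction,
  10³ random libraries for the Chao1 bound — a few seconds each, chosen as
  the smallest sizes at which the property, not the sample noise,
  dominates.

## 8. Known limitations

* One box, two endpoints: no vertical structure in the basement, no
  along-path nitrate profile, so R is an average, not a local rate.
* The effective exchange area is honest but unresolved (§2); absolute
  endpoint predictions inherit its uncertainty wholesale.
* Thermodynamics is endmember-level: no activity coefficients, no
  speciation, no competing metabolisms.
* Diversity statistics assume the OTU table is correct; chimera removal,
  alignment, and denoising are upstream of this package.
* The seawater taxon-density chain reproduces published clade densities
  only when the full fraction chain is supplied; partial chains printed in
  the literature are not guessed at.
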