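---
title: "Groundwater energetics and microbial community structure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groundwater energetics and microbial community structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mahomet)
```

This vignette is the package's own account of the science it implements:
the thermodynamic model of microbial available energy in aquifer
groundwater, the sulfate-based zonation of wells, the community statistics
used to relate 16S rRNA clone libraries to groundwater chemistry, and the
synthetic data generators that make every stage testable without field
samples. It also records the numerical and design choices that were
genuinely open, and what the tests do and do not demonstrate.

## The system

The Mahomet aquifer (east-central Illinois) is an anoxic glacial-drift
aquifer with distinct geochemical zones: some wells carry several mM of
sulfate while others hold negligible sulfate but up to ~1.2 mM of
biogenic methane. Wells are classified from their sulfate concentration
into high sulfate (HS, > 0.2 mM), low sulfate (LS, 0.03–0.2 mM) and
negligible sulfate (NS, < 0.03 mM) zones. The printed class intervals
leave the two boundary values ambiguous; `classify_sulfate()` assigns
0.03 mM to NS and 0.2 mM to LS, which reproduces the reported zone
membership of the wells that sit exactly on the NS/LS boundary. One well
(Ver94C, 0.23 mM) was reported in the low-sulfate group although it
exceeds 0.2 mM; the classifier applies the thresholds strictly and the
pipeline accepts an explicit per-well override
(`sulfate_classes(..., override = c(Ver94C = "LS"))`) so the historical
grouping is reproducible as recorded data rather than a softened rule.

Analytes in the chemistry schema may be censored (`"< limit"`) or missing
(`"n/a"`). Censored values default to the detection limit in arithmetic
(`censor_policy = "limit"`), a deliberately conservative choice that is
configurable to half-limit or exclusion; missing analytes are never
imputed — a well lacking a required measurement is excluded from range
summaries and flagged in the energy report.

## Available energy

For a respiratory reaction with stoichiometric coefficients $v_i$, the
in situ reaction free energy is

$$\Delta G_r = \Delta G^\circ_T + RT \ln \prod_i (\gamma_i m_i)^{v_i},$$

and the *available energy* is $\Delta G_A = -\Delta G_r$: the energy the
organisms catalysing that reaction can harvest under ambient conditions.
A reaction is considered able to support life when
$\Delta G_A \ge \Delta G_{\min}$, with $\Delta G_{\min} = 10$ kJ/mol by
default (configurable), the commonly assumed minimum for energy
conservation.

The modelled metabolisms (`reaction_catalog()`) are written with aqueous
species and one mole of terminal acceptor (or of CH~4~), i.e. 8-electron
forms, so the magnitudes are directly comparable with values quoted per
mole of sulfate or methane:

* sulfate reduction: SO~4~^2−^ + 4 H~2(aq)~ + H^+^ → HS^−^ + 4 H~2~O
* hydrogenotrophic methanogenesis: HCO~3~^−^ + 4 H~2(aq)~ + H^+^ →
  CH~4(aq)~ + 3 H~2~O
* anaerobic oxidation of methane (AOM) as the exact reversal of
  methanogenesis (producing H~2~)
* direct sulfate-coupled AOM: CH~4(aq)~ + SO~4~^2−^ → HCO~3~^−^ + HS^−^ +
  H~2~O (the Hess sum of the previous two)
* ferrihydrite reduction: 2 Fe(OH)~3(s)~ + H~2(aq)~ + 4 H^+^ → 2 Fe^2+^ +
  6 H~2~O (flagged assumption-dependent: neither ferrous iron nor the
  ferrihydrite activity is measured)

Every catalog entry is element- and charge-balanced by construction and
the balance is re-checked in tests.

**Thermodynamic constants.** $\Delta G^\circ_{298}$ and
$\Delta H^\circ_{298}$ of formation are embedded for the nine
participating species, taken from the CODATA key values and
SUPCRT-consistent compilations. Temperature correction to the in situ
12–16 °C uses the integrated Gibbs–Helmholtz relation with constant
reaction enthalpy,
$\Delta G^\circ_T = \Delta G^\circ_{298}\,(T/298.15) +
\Delta H^\circ\,(1 - T/298.15)$, an excellent approximation over a ±13 K
span. Registry values can be overridden per species
(`thermo_registry(overrides = ...)`).

**Activities.** Activity coefficients come from the extended
Debye–Hückel equation,
$\log_{10}\gamma_i = -A(T) z_i^2 \sqrt I / (1 + B(T) \mathring a_i \sqrt I)$,
with $A$, $B$ interpolated from an embedded 0–50 °C table
($A = 0.5092$, $B = 0.3283$ at 25 °C) and Kielland ion-size parameters.
Neutral aqueous species take $\gamma = 1$; water and minerals have unit
activity. Because the chemistry table reports no full major-ion
analysis, ionic strength is estimated from specific conductance with the
standard proxy $I = 1.6\times10^{-5}\,\mathrm{mol\,kg^{-1}}$ per µS/cm
(configurable, or supply $I$ directly). The H^+^ activity is taken
directly from pH.

**Declared assumptions.** Two participating species are not measured:
dissolved sulfide defaults to $10^{-5}$ mol/kg and ferrous iron to
$10^{-5}$ mol/kg, both configurable. DIC is treated entirely as
bicarbonate, which dominates over the 7.1–7.9 pH window. Because an
assumed molality enters $\ln Q$ logarithmically, its leverage is exactly
$RT\ln 10 \approx 5.5$ kJ/mol per decade at 14 °C;
`assumption_sensitivity()` exposes this sweep so the effect of the
sulfide assumption on any reported range can be bounded explicitly.

With these inputs, the bundled 25-well table yields across-well
$\Delta G_A$ of roughly 34–83 kJ/mol for H~2~-driven sulfate reduction
and 13–55 kJ/mol for methanogenesis (21 and 20 computable wells; the
analysis scripts print the exact values). Published estimates for the
same wells, computed with a commercial geochemistry package and its LLNL
thermodynamic database plus unpublished assumed activities, are 43–102
and 17–56 kJ/mol. The upper methanogenesis endpoints agree to ~2%; the
remaining offsets (8–19 kJ/mol) are consistent with 1.5–3.5 decades of
difference in the assumed sulfide/H~2~ activities combined with
database-level differences in formation energies, and we prefer keeping
the declared, documented assumptions over reverse-engineering
undocumented ones.

**AOM threshold.** Since AOM (reverse methanogenesis) produces 4 H~2~
per CH~4~, its $\Delta G_A$ falls with rising H~2~ and crosses zero at a
threshold concentration found by bisection on $\log_{10}[\mathrm{H_2}]$
(tolerance $10^{-9}$ kJ/mol) and verified against the closed form
$\ln a_{\mathrm{H_2}} = (-\Delta G^\circ_T/RT - \ln Q_{\mathrm{rest}})/4$;
the two agree to better than six significant digits on every computable
well. Thresholds in LS wells are sub-nanomolar (0.4–0.9 nM here,
published value "roughly 0.2 nM", same orders of magnitude below the
3–240 nM bulk H~2~ — the threshold inherits the exponentiated
$\Delta G^\circ/4RT$, so a few-percent database difference moves it
several-fold). The qualitative conclusions are database-independent: AOM
via reverse methanogenesis is endergonic at bulk H~2~ in every well,
direct sulfate-coupled AOM is exergonic in every well, and AOM becomes
feasible only where a hydrogen-consuming partner maintains sub-nM H~2~.

## Clone libraries and OTUs

Sequences are read from FASTA with the sample identity parsed from a
configurable header pattern. Dissimilarities are computed either on
pre-aligned sequences (mismatch fraction over columns, ignoring gap–gap
columns and counting gap–base columns as differences — a stated
convention, since the original workflow aligned against a 16S reference
database that is out of scope here) or by global Needleman–Wunsch
alignment (match 1, mismatch −1, gap −2) of raw sequences.

OTUs are formed at 97% similarity (cutoff 0.03) by average-neighbour
(UPGMA) agglomeration: repeatedly merge the pair of clusters with the
smallest average member-to-member distance while that distance does not
exceed the cutoff. Ties are broken deterministically toward the pair
containing the lexicographically smallest sequence id, and each OTU's
representative is its smallest member id, so clustering is reproducible
to the byte. The implementation maintains cluster distances by the
Lance–Williams update; tests verify it against a brute-force oracle that
recomputes every cluster pair average from the original matrix, and
against `hclust(..., "average")`.

Collector's curves, without-replacement subsampling
(`subsample_table()`, mirroring the normalization of unequal library
depths by drawing a random subset), and the hypergeometric rarefaction
expectation
$E[S_d] = \sum_j \bigl(1 - \binom{N-n_j}{d}/\binom{N}{d}\bigr)$
(computed on the log scale) support the richness accounting;
`shared_richness()` reports, for two disjoint sample groups, the OTUs
detected in both and the share of each group's sequences they contain.

## Community comparison statistics

These are implemented from their definitions rather than wrapped, with
established implementations used as independent cross-checks in the test
suite only.

* **Bray–Curtis**: $d(x,y) = 1 - 2\sum_k \min(x_k,y_k) / \sum_k (x_k +
  y_k)$, optionally on per-sample relative abundances (recommended for
  clone libraries of unequal size).
* **ANOSIM**: mid-ranks of all pairwise dissimilarities;
  $R = (\bar r_B - \bar r_W)/(M/2)$ with $M = n(n-1)/2$. Inference
  permutes group labels; when the number of distinct labellings is within
  the permutation budget the null is enumerated exhaustively (exact p),
  otherwise p carries the +1 correction
  $(1 + \#\{R^* \ge R\})/(1 + n_\mathrm{perms})$, making the reportable
  floor explicit. Interpretation bands follow common practice:
  $R > 0.75$ distinct, 0.25–0.75 overlapping, $< 0.25$ indistinct.
* **SIMPER**: for each cross-group pair the Bray–Curtis dissimilarity
  decomposes exactly into per-OTU terms
  $|x_{ik} - x_{jk}| / \sum_m (x_{im} + x_{jm})$; terms are averaged over
  pairs and ranked. The conservation identity (terms sum to the pair's
  dissimilarity) is asserted to $10^{-12}$.
* **NMDS**: Kruskal stress-1 minimized by alternating isotonic
  regression of configuration distances on the dissimilarity order
  (primary, "weak" tie treatment via `isoreg`) with Guttman-transform
  updates. An update that would increase stress terminates the run, so
  the stress trace is monotone non-increasing by construction; the best
  of 20 seeded starts (one classical-scaling start plus random starts) is
  reported, with the stress printed alongside the coordinates.

The pipeline evaluates the three class contrasts (HS–LS, HS–NS, LS–NS)
within each fraction plus the overall ATT–SUS contrast; a contrast whose
group has fewer than two samples is reported as an explicit
"not testable: group too small" row rather than omitted, mirroring how
designs with a single suspended NS well must be presented.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, seeded, pure functions of their
arguments, and their defaults encode the emulated study design:

* `gen_chemistry()`: 9/8/8 wells per HS/LS/NS class; sulfate inside each
  class interval; methane inversely tied to class (NS wells ≥ 100 µM, HS
  wells ≤ 20 µM, giving the negative CH~4~–SO~4~ rank correlation);
  H~2~ log-uniform over 3–240 nM; temperature 12–16 °C, pH 7.1–7.9, DIC
  5–9 mM.
* `gen_otu_table()`: one 192-clone library per well × fraction (the
  emulated minimum per-sample depth), 300 OTUs, Dirichlet-multinomial
  counts. The base composition decays geometrically (a few dominant,
  many rare OTUs). Planted effects multiply the Dirichlet weights of
  disjoint OTU blocks for chosen fraction/class combinations; after an
  effect is applied the concentration vector is rescaled to a fixed
  total so effects shift the expected composition without also changing
  the overdispersion (otherwise a strong enrichment would silently make
  the affected group tighter, confounding location and spread). The
  default blocks mimic the headline contrasts — an iron-reducer-like
  block enriched when attached, a sulfate-reducer-like block enriched in
  attached HS samples, a methanogen-like block enriched in NS wells — at
  ×15, the order of the reported fold-contrasts, and with the default
  total concentration of 150 they reproduce the reported ANOSIM regime
  (fraction contrast R ≈ 0.5, NS-versus-HS contrasts R ≳ 0.9). A
  "strong" effect in the tests boosts a block that is *rare* in the base
  composition, the regime that actually drives R toward 1 (boosting
  already-dominant OTUs barely moves relative composition).
* `gen_sequences()`: one random ancestor per cluster, members mutated so
  that the expected *pairwise* within-cluster divergence equals
  `within_divergence`; independent ancestors differ at ~75% of sites, so
  any between-divergence up to 0.7 is feasible. Truth labels ride along
  for partition-recovery tests.

The Dirichlet-multinomial is a testability choice, not a biological
claim: it expresses overdispersed compositional counts with plantable
group effects in the simplest form. Real clone libraries add
phylogenetic correlation between OTUs, chimeras, primer and cloning
biases, and abundance structure the geometric base only caricatures;
passing tests therefore demonstrate that the statistics recover known
structure from data satisfying their assumptions, not that they would
assign the same p-values to the original libraries.

## Numerical choices and degenerate inputs

* Censored values: detection limit by default; configurable.
* Zero activities in $\ln Q$ raise an error directing the caller to a
  floor value or exclusion, rather than silently returning ±Inf.
* Bisection brackets H~2~ in $[10^{-15}, 10^{-3}]$ mol/kg and refuses to
  proceed without a sign change.
* Clustering and ANOSIM tie-breaks are deterministic (lexicographic ids;
  mid-ranks).
* SIMPER on two identical groups is flagged degenerate (percent
  contributions undefined) instead of dividing by zero.
* All stochastic stages consume explicit seeds; pipeline reruns with the
  same config are byte-identical, and the config snapshot written next
  to the outputs suffices to reproduce them.

## Problem sizes used by the test suite

The suite favours small, closed-form-checkable instances: exhaustive
ANOSIM on six samples (20 labellings), brute-force UPGMA on ≤ 12
sequences, rarefaction against the hypergeometric closed form with a few
hundred seeded draws, and band-recovery sweeps of 100 seeded synthetic
communities of 24 libraries each. These sizes keep the default run to
well under a minute while exercising every code path; the analysis
scripts run the full 25-well × 2-fraction design.

## Known limitations

* The thermodynamic registry is a nine-species excerpt, not a general
  speciation engine: no carbonate system beyond bicarbonate, no mineral
  saturation, no Pitzer/b-dot activity models, no kinetics.
* $\Delta G_A$ endpoint values inherit the documented assumptions for
  sulfide and ferrous iron and the conductivity proxy for ionic
  strength; sensitivity to each is quantifiable (and quantified) but the
  field-true values are unknown.
* The OTU distance on pre-aligned input treats gap–base columns as
  differences; other conventions exist and would shift distances near
  the cutoff.
* NMDS is a local optimizer; restarts mitigate but cannot guarantee the
  global minimum for pathological inputs.
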