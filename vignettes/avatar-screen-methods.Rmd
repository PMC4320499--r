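---
title: "AvatarScreen methods: from aberration calls to ranked regimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AvatarScreen methods: from aberration calls to ranked regimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AvatarScreen)
```

AvatarScreen turns a patient's genomic aberration calls into a *simulation
avatar*: a set of quantitative perturbations applied to a curated signed
signaling network, whose ordinary-differential-equation steady state stands
in for the patient's malignant cell. Drugs and drug pairs are then screened
*in silico* and ranked by how far they push that steady state back toward
the healthy control. This vignette documents every modelling convention,
including the invented defaults, so results can be audited.

## 1. From aberrations to perturbations

Aberration calls arrive as a TSV with columns `kind`, `scope_type`,
`chrom`, `start`, `end`, `band_from`, `band_to`, `gene`, `zygosity`.
Supported kinds: `copy_gain`, `copy_loss`, `monosomy`, `trisomy`,
`translocation_amplification`, `mutation_gof`, `mutation_lof`. Scopes may
be a single `gene`, a genomic `interval`, a `cytoband_range`, a
`whole_chromosome`, or karyotype notation such as `del(7)(q22q36)` which is
expanded to a band range. Intervals are 1-based inclusive and resolved
against the bundled gene annotation by any-overlap; cytobands resolve
through a bundled band-order table.

Each resolved gene becomes one perturbation: a multiplicative factor on the
node's maximal attainable activity. The **magnitude policy** (an invented,
documented default; `magnitudePolicy()`):

| event                                            | factor |
|--------------------------------------------------|--------|
| heterozygous / unspecified loss                  | 0.5    |
| homozygous loss, loss-of-function mutation       | 0.05   |
| trisomy, heterozygous gain                       | 1.5    |
| translocation amplification, homozygous gain, gain-of-function mutation | 2.5 |

Conflicting calls for the same gene raise an error by default
(`tiePolicy = "error"`); with `tiePolicy = "drop"` the most severe
magnitude is kept. Genes not present in the network are reported, not
silently dropped: `coverageReport(avatar)` plus the perturbation table
always account for every resolved gene.

## 2. Network model and dynamics

The network is a signed directed graph. Nodes carry a basal activation
`basal`, a ceiling `x_max`, and Hill parameters `(n, k)`; edges are
`activating`, `inhibiting`, or `degrading` with a mandatory cofactor node
(e.g. ubiquitin-ligase substrates degraded only when the proteasome is
active).

Dynamics follow a normalized-Hill formalism. Each node's functional output
is squashed by

$$\phi(x; n, k) = \frac{x^n (k^n + 1)}{x^n + k^n}, \qquad \phi \in [0, 1],$$

normalized so that $\phi(1) = 1$. The state equation is

$$\frac{dx_i}{dt} = \frac{u_i \, D_i \, \hat{x}_i - x_i}{\tau},$$

where $\hat{x}_i$ is `x_max` times the avatar's multiplicative factor
(clipped to 1), the activation term combines activators by independent OR,

$$u_i = 1 - \prod_{j \in \mathrm{act}(i)} \bigl(1 - w_j \phi(\mathrm{out}_j)\bigr),$$

and the inhibition term multiplies the surviving fractions,

$$D_i = \prod_{k \in \mathrm{inh}(i)} \bigl(1 - w_k \phi(\mathrm{out}_k)\, c_k\bigr),$$

with $c_k = \phi$ of the cofactor for degradation edges and $c_k = 1$
otherwise. A node with no activators holds its basal drive $u_i = b_i$;
once a node has activators, its basal value only sets the initial condition
$x_i(0) = b_i \hat{x}_i$. Integration uses `deSolve::lsoda` with a
pre-trigger equilibration (control), then a continuation with the avatar
applied (disease) and optionally drugs (treatment); convergence requires
$\max_i |dx_i/dt| < 10^{-6}$.

Drugs act on **functional output**, not expression: an inhibitor at dose
$d$ multiplies the target's outgoing signal by $1 - \mathrm{FI}(d)$ with
$\mathrm{FI}(d) = d^h / (d^h + \mathrm{EC}_{50}^h)$. The node's own level is
unchanged, which matters for readouts of the target itself.

When several inhibitors hit the *same* node they combine by Loewe dose
additivity: normalized doses $z_j = d_j/\mathrm{EC}_{50,j}$ add, the
effective Hill coefficient is their dose-weighted mean
$\bar h = \sum_j z_j h_j / \sum_j z_j$, and the joint fractional
inhibition is $\bar z^{\bar h} / (\bar z^{\bar h} + 1)$ with
$\bar z = \sum_j z_j$. This reduces exactly to the single-drug curve for
one inhibitor and makes a drug combined with a copy of itself behave like
a doubled dose — never a "synergy". Activating actions multiply their
$(1 + f)$ boosts, capped at the node ceiling.

## 3. Phenotype: the relative growth index

Marker nodes are grouped (`defaultMarkerConfig()`): proliferation
{CCND1–CDK4/6 complex, E2F}, survival {BCL2, MCL1, BIRC3}, apoptosis
{CASP3, CASP9, BBC3, cleaved PARP1}, with equal weights within each group.
From group means $P$, $S$, $A$ of functional outputs,

$$\mathrm{rgi} = \bigl(\alpha P + (1 - \alpha) S\bigr)(1 - A), \qquad
\alpha = 0.5,$$

and treatment efficacy is the percent rgi reduction versus the untreated
disease state, $100 (1 - \mathrm{rgi}_{\mathrm{treated}} /
\mathrm{rgi}_{\mathrm{disease}})$. The weights and $\alpha$ are invented,
documented defaults and are deliberately *not* tuned per patient.

## 4. Pharmacology and screening conventions

* **Default screening dose** — small molecules are screened at the dose
  giving 55% target manipulation (mid-range, within the 50–60% band);
  biologics at 95% (near-saturating). Both are inverted exactly from the
  Hill equation.
* **ICxx** — the dose reducing rgi by xx% versus disease, found by bracket
  doubling then bisection, self-consistent to 0.5 percentage points. An
  unreachable ICxx is reported (`reachable = FALSE`), and such drugs are
  skipped (and logged) by the combination screen.
* **Single-agent shortlist** — efficacy above 30% at the default screening
  dose. The pipeline labels agents sensitive (> 30), resistant (< 10), or
  intermediate.
* **Combinations** — every pair is dosed at each agent's own IC20 (default).
  With fractional effects $E_a$, $E_b$, $E_{ab}$: Bliss excess
  $E_{ab} - (E_a + E_b - E_a E_b)$, HSA excess $E_{ab} - \max(E_a, E_b)$.
  A pair is *dominated* when HSA excess $< \delta = 0.05$, *synergistic*
  when Bliss excess $> 0$ and not dominated, and *shortlisted* when
  synergistic with $E_{ab} > 0.5$.
* **Subclones** — when an avatar carries clone-specific aberration sets,
  every efficacy is the worst case across clones: a regimen is only as good
  as its effect on the least sensitive subclone.

## 5. The curated myeloma fixture

`mmCoreNetwork()` encodes a ~46-node core signaling map of the malignant
plasma cell (PI3K/AKT/mTOR, RAS/MAPK, JAK/STAT, NF-κB, Wnt, Notch, Hedgehog
inputs; TP53/RB/E2F cell-cycle control; SCF–proteasome degradation arm; and
the intrinsic apoptosis pathway). Two curation choices deserve emphasis:

* **Apoptotic switch.** CASP9 receives a constitutive apoptosome drive
  (APAF1) and a CASP3→CASP9 positive feedback, while BCL2 and MCL1 act as
  independent degradation clamps on CASP9. This textbook motif makes
  apoptotic commitment switch-like: releasing *both* clamps (e.g. a BCL2
  antagonist plus a PI3K/mTOR inhibitor that starves MCL1) fires a
  self-sustaining caspase cascade, while either clamp alone holds it off.
  This is what lets two IC20-dosed agents jointly exceed 50% efficacy —
  the supra-Bliss synergy the screen is designed to surface.
* **Trametinib targets MEK** (its physiological target), feeding the
  ERK→AP-1→cyclin-D axis.

Edge weights and Hill parameters of this fixture are invented and were
calibrated numerically (simulated annealing against the case-study
acceptance suite); the shipped JSON (`inst/extdata/mm_core_network.json`)
is the frozen result and is asserted byte-stable by the test suite.

## 6. Synthetic benchmarks

`plantedDriverScenario()` generates random connected signed networks with
all three marker groups, plants a dominant hyperactivated driver
(magnitude 2.5) among mild distractor knockdowns, and pairs each hub with
an inhibitor. The driver's inhibitor should rank first in the single-agent
screen — the package's self-benchmark, verified across ≥ 50 seeds.

## 7. Limitations

* The network is a coarse, cell-autonomous core map: no microenvironment,
  immune compartment, or pharmacokinetics; doses are in EC50 units, not
  plasma concentrations.
* Magnitude policy and marker weights are invented defaults, not fitted to
  expression data.
* Steady-state readouts ignore transient dynamics; bistable motifs make
  outcomes dependent on the equilibration protocol, which is why the
  control→disease→treatment continuation order is fixed and documented.
* Synergy is evaluated at ICxx dose pairs only, not over full dose
  response surfaces.
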