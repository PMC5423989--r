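---
title: "Tiered grouping of nanomaterials: the decision model behind df4nano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered grouping of nanomaterials: the decision model behind df4nano}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(df4nano)
```

## The framework

df4nano implements the ECETOC decision-making framework for the grouping and
testing of nanomaterials (DF4nanoGrouping; Arts et al. 2015, 2016), a
three-tier scheme that assigns a nanomaterial to one of four hazard-relevant
main groups:

* **MG1 — soluble nanomaterials.** Toxicity is dominated by the released
  ions; further assessment reads across to the dissolved species.
* **MG2 — biopersistent high-aspect-ratio (HAR) nanomaterials.** Fiber-shaped
  and not dissolving in biological media; assessed along the fiber-toxicity
  track.
* **MG3 — passive nanomaterials.** No material-specific activity; effects in
  the rat occur only under pulmonary overload. The general occupational dust
  limit is considered sufficient.
* **MG4 — active nanomaterials.** Any demonstrated (or non-excludable)
  concern: surface reactivity, cytotoxicity, high dispersibility/mobility or
  hazardous components. These merit in-depth investigation and may need
  specific occupational exposure limits.

Tier 1 consults intrinsic properties (water solubility, particle morphology,
composition); Tier 2 consults system-dependent properties and in vitro
effects (dissolution in biological fluids, surface reactivity, dispersibility,
lung epithelial cytotoxicity and the NR8383 alveolar-macrophage assay);
Tier 3 confirms or corrects the non-animal assignment with rat short-term
inhalation study (STIS) results. Use, release and exposure route act as
*qualifiers*: a material that cannot be released from its product matrix in
any way is waived from testing and carries no main group.

Classification stops at the earliest terminal tier (the framework's
data-economy principle): a Tier 1 solubility assignment is never re-litigated
in Tier 2, and a biopersistent fiber is MG2 without consulting the remaining
Tier 2 criteria. Every comparison actually performed is recorded as one
trace entry — criterion, tier, input, threshold, printed comparison
direction, outcome — so an assignment is auditable end to end, and the
effective threshold configuration is echoed into every report.

## Thresholds and comparison directions

The defaults in `df4_thresholds()` are the framework's published cut-offs.
The comparison direction is part of the criterion, not a tunable: solubility
and dissolution trigger strictly above 100 mg/L, the hazardous-component rule
is inclusive at 0.1 %, the aspect-ratio rule strictly above 3, dispersibility
strictly below an AAN of 3 (or an agglomerate diameter strictly below
100 nm), epithelial cytotoxicity inclusive at 10 µg/cm², a macrophage assay
parameter counts as altered strictly below the 6000 mm²/mL non-overload
surface-area dose, Range IV starts inclusively at a NOAEC of 10 mg/m³, and
biopersistence is low strictly below a 40-day half-life. A dedicated boundary
test pins each operator so a flipped direction fails the suite.

Two documented variants are selectable in `df4_config()`:

* `strict_who_fiber`: the fiber rule by default omits the WHO length
  criterion (length > 5 µm), because biopersistent HAR materials are assigned
  to MG2 even when their length misses the WHO bound; the strict variant
  re-instates it.
* `range_i_variant`: the published materials disagree on the Range I NOAEC
  bound — the criteria table says < 0.5 mg/m³ (with no regression of
  effects), the case-study table legend says < 0.1 mg/m³. Both are shipped;
  the criteria-table value is the default. The choice can move a material
  between subgroups I and II but never across the MG3/MG4 boundary, which is
  decided at 10 mg/m³ alone.

## Missing data: direction of precaution

Missingness is handled by the direction of the concern a criterion raises,
not uniformly:

* Missing water solubility is **not** precautionary — MG1 lowers
  particle-specific concern, so the record simply continues to the Tier 2
  dissolution criterion.
* Missing dissolution on a fiber-indicated material **is** precautionary: a
  biopersistent fiber is assumed (MG2).
* Missing surface reactivity **is** precautionary (MG4): reactivity cannot be
  excluded. This is the graphite-nanoplatelets precedent, where reactivity
  was not determinable for technical reasons and concern was assumed.
* Missing dispersibility is **not** precautionary: agglomeration is assumed,
  matching the behaviour of unfunctionalized suspensions.
* The in vitro battery needs one assessable cellular assay. A missing
  epithelial assay is covered by an assessable macrophage call (and vice
  versa); when neither exists, both are precautionary-missing and the record
  is provisionally MG4. A *partially* reported macrophage assay that has not
  established activity is treated as precautionary-missing, because activity
  cannot be excluded from an incomplete parameter set.
* A record with no data at all is therefore reported as provisional MG4 with
  a data-poor warning — never silently MG3.

The macrophage call itself is resolved as: **active** as soon as two of the
four parameters (LDH, glucuronidase, TNF-α, ROS) are altered below the
non-overload bound — established positives cannot be undone by the missing
parameters — and **passive** only when all four were assessed and at most one
is altered. This is the only reading under which replacing a single measured
value by "missing" can never relax an assignment, the package's global
precaution-monotonicity property. Note that the property is stated for
non-triggering values: deleting an established *trigger* (say, the low AAN
that made a material MG4) lawfully removes that indication, because the
framework's own missing-data rules for dispersibility and the cellular
battery are not precautionary in those configurations.

Two Tier 2 resolutions are fixed by case-study precedent where the published
wording is open: dispersibility assigns MG4 for non-fiber materials (for
fibers it only feeds the MG2 context), and either cellular assay triggering
suffices for a provisional MG4 (OR logic). Both choices are flagged in the
trace notes. A Tier 2 MG1 (dissolution) coinciding with a Tier 1
hazardous-component indication yields MG1 with an explicit warning rather
than a silent resolution; likewise an MG2 fiber with a Range IV NOAEC stays
MG2 — fiber hazard is not NOAEC-driven — with a trace warning.

## Tier 3 resolution and subgrouping

With usable STIS data (and an inhalation route), the NOAEC is banded:
Range IV (≥ 10 mg/m³) finalizes MG3, confirming a provisional MG3 or
*correcting* a provisional MG4 (the resolved over-prediction); Ranges I–III
finalize MG4, confirming a provisional MG4 or correcting a provisional MG3
upward (never observed in the case studies but logically required). Censored
"at least X" NOAECs band at their lower bound; X ≥ 10 is a definitive
Range IV. A NOAEC below the Range I bound falls in Range I when effects did
not regress post-exposure, in Range II when they did, and — a deliberate
precautionary choice — in Range I when the course is unknown. Final MG4
materials are subgrouped by NOAEC range, by reversibility (regression →
reversible; progression or persistent effects → progressive) and by
biodistribution: beyond the mononuclear phagocyte system (MPS), inside the
MPS, or confined to the portal-of-entry organ, using 1 mass percent of the
total dose as the bound for each step outward. A half-life below 40 days
upgrades an MG1 assignment from "assigned" to "confirmed". For routes
without an STIS analogue the engine still groups on Tiers 1–2 and marks
Tier 3 as not covering the route instead of demanding data.

The occupational annotation follows the final group: MG3 materials carry
"general dust limit sufficient", MG4 materials "specific OEL needed"
(applied to provisional MG3/MG4 as the current best assignment, flagged by
the `indicated` status), and MG1/MG2/waived materials "not applicable".

## The case-study dataset

`load_case_studies()` ships 25 materials: four carbonaceous materials
(a multi-walled carbon nanotube, graphene, graphite nanoplatelets,
low-surface carbon black), metal oxides (two ZnO, TiO₂, two CeO₂, four
surface-functionalized ZrO₂, nano-CuO), BaSO₄, six amorphous silicas
(an unfunctionalized suspension, acrylate/phosphate/PEG/amino
functionalizations, and a precipitated silica), three organic pigments
(nanosized Pigment blue 15:1 and a nano/non-nano diketopyrrolopyrrole orange
pair) and a non-nanosized quartz dust benchmark. Twenty-two are already
final after the non-animal tiers; exactly three — SiO₂.phosphate (dispersible,
low AAN), Pigment blue 15:1 (macrophage-assay active) and graphite
nanoplatelets (reactivity not determinable) — carry a Tier 2 concern that a
Range IV STIS NOAEC corrects to MG3.

Where the published record is qualitative ("high dissolution",
"dispersible", "Range II"), the encoded value is a representative number on
the stated side of the threshold, marked as representative in the entry's
source note. This is faithful by construction: the engine consumes threshold
comparisons, not raw measurements, so any compliant value reproduces the
assignment. The dataset encodes assignment-level information only and makes
no attempt to recover the raw measurements of the underlying inhalation
studies.

```{r casestudies}
v <- verify_case_studies()
v$n_concordant
v$corrected
```

## The synthetic generator

`generate_cohort()` draws materials with known intended groups for
property-based and recovery testing. Each grouping-relevant quantity is drawn
uniformly from an interval lying entirely on the group-consistent side of its
threshold (e.g. intended-MG1 solubility on 150–5000 mg/L against the
100 mg/L cut-off; intended-MG3 reactivity on 0.001–0.08 of the Mn₂O₃
reference against the 0.10 bound; intended-MG2 aspect ratios on 10–500),
which trivially satisfies the requirement that at least 95 % of the mass lie
on the correct side. Intended MG4 records realize exactly one concern
channel (reactivity, epithelial, macrophage, dispersibility or composition),
so channel isolation can be asserted from the trace. Half of the intended
MG3/MG4 records (by default) carry an STIS result on the group-consistent
side of the 10 mg/m³ bound, so Tier 3 runs on part of every cohort.
Optional missingness blanks only precaution-neutral supplementary fields
(zeta potential, surface area, primary particle size, hydrophobicity,
medium labels), keeping the intended group well-defined; at zero missingness
recovery is 100 % by construction, which the acceptance suite verifies on a
400-record cohort.

What the generator deliberately does **not** emulate: correlated properties
(real coatings shift dispersibility, charge and dissolution together),
measurement noise and inter-laboratory variability, discordant duplicate
measurements, censored in vitro ranges, or materials near the thresholds.
Passing the recovery tests therefore demonstrates the engine's rule logic,
not classification performance on borderline real-world materials, whose
measured values may legitimately straddle thresholds across media and
protocols.

```{r cohort}
cohort <- generate_cohort(synthetic_spec(
  c(MG1 = 5, MG2 = 5, MG3 = 5, MG4 = 5), seed = 1))
batch <- classify_batch(cohort$records)
recovery_report(cohort, batch$assignments)$accuracy
```

## Numerical and testing choices

Threshold comparisons are exact floating-point comparisons with the printed
operators; ties are never broken randomly, and an equality case (a
dissolution of exactly 100 mg/L) simply fails both strict directions and
flows on. The classifier is deterministic and idempotent: repeated calls on
the same record and configuration serialize bit-for-bit identically.

The test suite cross-checks `classify()` against an independently written
flat decision table over an exhaustive discretized grid of all tier inputs
(three to six levels per criterion including "missing", about 1.2 × 10⁴
combinations), verifies precaution monotonicity under single-field deletion
on a seeded 1000-record cohort, the Tier 3 override (NOAEC ≥ 10 mg/m³ →
MG3 for any non-fiber), and boundary semantics for every printed operator.
These problem sizes keep the default suite comfortably inside a couple of
minutes on one core while exercising every rule path.

## Limitations

The engine encodes the inhalation-focused framework: route qualifiers other
than inhalation are carried and reported but no route-specific thresholds
exist. Genotoxicity is outside the framework (no thresholds or benchmarks
were established for it), as are deposition/clearance kinetics modelling,
overload-volume computation, and the numeric derivation of DNELs or OELs —
the dust-limit annotation is a pointer for the risk assessor, not a limit
value. How an average agglomeration number is computed from raw size
distributions is likewise out of scope; the AAN is consumed as a measured
input. Threshold adequacy for substances dissolving into non-toxic
components (the published caveat on the 100 mg/L rules) is supported only as
a configurable threshold, not as an automatic rule.
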