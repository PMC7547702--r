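---
title: "Models and methods: screening and 13C label propagation for the reductive glycine pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rglypath)
```

## The scientific problem

The reductive glycine (rGly) pathway fixes CO2 in anaerobes such as
*Desulfovibrio desulfuricans*: CO2 is reduced to formate, activated onto
tetrahydrofolate (formate–THF ligase, ATP-consuming), reduced to
methylene-THF, and condensed with a second CO2 and ammonia into glycine by
the glycine cleavage system running in the reductive direction. Glycine is
then assimilated either by **glycine reductase** (GR: glycine + Pi + 2e⁻ →
acetyl-phosphate + NH3, then acetyl-CoA and a PFOR carboxylation to
pyruvate) or by the **serine route** (serine hydroxymethyltransferase plus
serine deaminase, straight to pyruvate). Two questions follow naturally and
are what this package computes:

1. *Which organisms encode the pathway?* — a comparative-genomics screen
   over translated-homology hits with operon co-occurrence rules.
2. *Which route is actually running?* — the two routes leave different
   ¹³C mass-isotopomer (MID) signatures in amino acids when cells grow on a
   ¹³C-formate tracer with unlabelled CO2, so an atom-mapping label
   propagation model can predict both signatures and classify observed MIDs.

A third, smaller computation supports the second: correcting measured MIDs
for natural ¹³C abundance.

## The pathway model

The model is a single editable YAML file
(`system.file("extdata", "rgly_pathway.yaml", package = "rglypath")`)
declaring compounds (with per-carbon "roles"), reactions (signed
stoichiometry, net ATP-equivalents, reducing-equivalent pairs and a
per-carbon atom transition map), pathway variants and label-propagation
networks. Other pathways can be declared without code changes.

Fixed conventions, documented in the model file:

* glycine C1 = carboxyl (from CO2 via GCS), C2 = alpha (from formate via
  methylene-THF); serine C3 = hydroxymethyl (from formate); pyruvate C1 =
  carboxyl, C2 = carbonyl, C3 = methyl.
* Every reaction's transitions must form a **bijection** over its carbon
  multiset — each product carbon (including released CO2) has exactly one
  source and each substrate carbon is used exactly once.
  `validate_atom_maps()` enforces this; the loader refuses inconsistent
  files.
* ATP accounting: ATP→ADP counts 1 equivalent consumed; AMP+PPi-forming
  activations (acetyl-CoA synthetase) count 2 assuming pyrophosphatase
  activity, switchable to 1 via `acs_equivalents` because the pathway's
  1–2 ATP-per-pyruvate range reflects the activation variant, not this
  bookkeeping convention.
* Reducing equivalents are undifferentiated electron pairs; carrier
  identity and electron bifurcation are deliberately not modelled —
  bifurcation can only make the ATP balance *more* favourable, so the
  accounted costs are conservative.

```{r energetics}
model <- load_pathway_model()
vapply(names(model$variants), function(v) atp_cost(v, model), numeric(1))
```

The GR route yields pyruvate for 1 ATP (direct acetyl-P → acetyl-CoA via
PTA) or 2 ATP (via acetate: ACK recovers one ATP, AMP-forming ACS spends
two); acetate itself costs net 0 ATP (FTL's 1 ATP is recovered by ACK).
Zero-ATP acetate is sometimes attributed to the PTA branch, but PTA yields
acetyl-CoA and recovers no ATP; net zero is only reachable through the
ATP-forming acetate kinase step, so the shipped `rGly-GR-acetate` variant
uses GR + ACK. The reductive acetyl-CoA
reference variant (methyl branch + CODH/ACS + PFOR) costs 1 ATP per
pyruvate.

A note on gene/complex naming in the ruleset: the GR complex is modelled as
its seven protein components (A, B-alpha/beta, C-alpha/beta, thioredoxin,
thioredoxin reductase) to match the five-of-seven presence rule; the
six-gene FDH operon list likewise includes the accessory/cofactor loci its
four-of-six rule presumes.

## Label propagation

`propagate()` computes, per compound, the joint probability distribution
over binary carbon-labelling patterns:

* Tracer substrates are labelled **independently per position** with their
  configured enrichment (default: formate 0.99 — the tracer purity — and
  CO2 at natural abundance 0.0107).
* Each product carbon inherits the distribution of its mapped source
  carbon; condensation products take the product of their substrates'
  (marginal) joints — substrate pools are assumed infinite, well mixed and
  independent. Substrate channelling, discussed for this organism, would
  correlate pools and is intentionally not modelled.
* Compounds named in the tracer are fixed source pools: released CO2 never
  re-enters the labelled pool, justified by the large unlabelled headspace
  CO2 excess. The compound graph must otherwise be acyclic with a unique
  producer per compound (errors name the cycle or the orphan compound).
* Steady-state end points only; no kinetics are modelled (the time-course
  spike experiment is represented by its end-point comparison).

Because tracer positions are independent Bernoulli draws and transitions
are bijections, each carbon traces to a single tracer position; the tests
exploit this with an independent back-tracing enumeration oracle that must
agree with the joint-propagation path to 1e-12.

Biosynthetic extensions (alanine, valine, leucine, threonine via
oxaloacetate from pyruvate carboxylase, proline via oxoglutarate from
citrate synthase + isocitrate dehydrogenase, PEP/3-PG/aspartate proxies)
use textbook atom maps — e.g. the valine skeleton takes C2/C3 of one
pyruvate and loses the second pyruvate's carboxyl, and the oxoglutarate
synthesis releases the oxaloacetate C1 carboxyl. They are fixtures for MID
prediction, not pathway-energetics claims.

`classify_route()` scores observed MIDs against both routes' predictions by
summed squared L2 distance with equal metabolite weights — simple,
symmetric, and adequate because the two predictions are several units apart
across the discriminating metabolites. The ambiguity margin defaults to
1e-3 on the score difference; at least one metabolite whose predictions
differ (pyruvate family, Ser/Thr/Pro) must be present.

## Natural-abundance correction

`build_correction_matrix(n, p13)` is the carbon-only convolution matrix,
entry `[i, j] = Binomial(n − j, p13)` at `i − j`: the probability that a
molecule with `j` tracer-labelled carbons is measured at shift `i` because
`i − j` of its remaining carbons carry natural ¹³C. `correct_mid()` inverts
it by non-negativity-constrained least squares (never negative fractions,
robust to noise) and renormalizes. Carbon-only correction is exactly the
portion needed for ¹³C signatures; N/H/O/S isotopes and
resolution-dependent peak merging are out of scope.

## The genome screen

The screen consumes 12-column tabular translated-homology hits (or runs its
own desk-scale `six_frame_search()` on fixture genomes) and applies, per
genome:

1. **Filtering** — identity ≥ 25% and e-value ≤ 1e-4, both inclusive (a
   bare "25% homology" criterion does not state strictness; inclusivity is
   the documented, configurable choice). No query-coverage filter by default;
   one is available.
2. **Co-occurrence chaining** — single-linkage chaining of hit intervals at
   inter-interval gap ≤ 20,000 bp — reading co-occurrence of genes within
   20,000 bp of each other as a chainable pairwise relation;
   overlap counts as gap 0. A start-to-start anchor is available as an
   option. Chaining is strand-agnostic (translated searches report either
   orientation) and, for each complex, considers only that complex's hits,
   so unrelated hits cannot bridge two distant operon fragments.
3. **Complex rules** — a complex is present when one cluster covers at
   least `min_detected` *distinct* genes: GCS 3-of-4, GR 5-of-7, FDH
   complexes 4-of-6 (EC 1.17.2.3), 4-of-5 (EC 1.17.1.9), 5-of-8
   (EC 1.17.1.11), 3-of-3 (EC 1.17.5.3); EC 1.17.1.10 is excluded from the
   any-of FDH clause. Repeated hits to one gene count once.
4. **Route logic** — pathway present = FDH (any of four; skipped in
   `fdh_optional` mode) AND GCS AND formate–THF ligase AND methenyl-THF
   cyclohydrolase AND (route A: GR + PTA or ACK | route B: SHMT + SDA).

Multi-contig assemblies are aggregated through an optional
`subject_id → genome` mapping; without one, each subject sequence is its
own genome. Reproducing database-wide genome counts is a
non-goal: such counts depend on the NCBI NT snapshot; the screen's correctness is
instead validated against planted synthetic truth.

`six_frame_search()` performs affine-gap local alignment (BLOSUM62, gap
open 11 / extend 1, a gap of length L costing open + L·ext) of each query
against all six translated frames, reporting frame-correct nucleotide
coordinates. Its e-values use the standard gapped Karlin–Altschul
approximation (λ = 0.267, K = 0.041) and are meant for threshold filtering
of desk-scale fixtures, not as reproductions of NCBI e-values.

## The synthetic-data generators

`make_genomes()` emulates: planted operons as random-codon
back-translations of random ~120–250-residue proteins, intra-operon gaps
uniform on 50–500 bp, blocks separated by more than the window, decoys as
shuffled queries verified at generation to fall below 25% global identity
to every query, clean hits at exact planted coordinates, and spurious hits
that carry real rule-gene names but fail exactly one threshold. Operon
degradation scenarios: below-minimum gene subsets, same-contig splits with
a gap of exactly *window + 1* bp (probing the boundary), and splits across
two contigs. It does **not** emulate real phylogenetic divergence,
partial-homology gradients, or read-level sequencing artefacts — passing
the screen on these fixtures validates the rule pipeline (parsing,
filtering, chaining, counting, route logic), not remote-homology
sensitivity of any particular aligner.

`make_mid_dataset()` perturbs route predictions with Gaussian noise per MID
entry (sd 0.02 by default), truncates at zero and renormalizes — keeping
every observation a valid MID, at the cost of slightly non-Gaussian
effective noise. It does not emulate metabolite-specific measurement bias
or correlated errors within a spectrum; classification power measured on it
is an upper bound for real instruments.

Both generators are deterministic given their seed (identical outputs,
byte for byte).

## Numerical choices and problem sizes

* Joint label distributions are dense vectors over 2ⁿ patterns; the largest
  shipped compound has 6 carbons (64 patterns), so exact enumeration is
  both the implementation and the test oracle's regime.
* Intermediate-cancellation and carbon-conservation checks use exact
  integer arithmetic with a 1e-9 guard for flux sums.
* MID validity tolerances: sums within 1e-9; correction round-trip asserted
  at 1e-9 over 1,000 random MIDs; propagation vs oracle at 1e-12.
* Analysis scale: 50 synthetic genomes for the screen validation (all
  route × intactness combinations) and 100 noisy datasets per route for
  classification power — sizes at which every result in `analysis/` and the
  test suite recomputes in seconds to a couple of minutes on one core.

## Known limitations

* End-point labelling only; no flux fitting (EMU/cumomer), compartments, or
  ¹⁵N/²H tracing.
* The classifier assumes the tracer configuration is known; misspecified
  tracer purity biases both scores, though symmetrically.
* The screen cannot call genes the hit table does not contain; its
  per-complex gene lists for the non-native FDH operons name reference loci
  whose operative content is the min-detected threshold.
* Thermodynamics and enzyme kinetics are cited facts about the pathway, not
  computations of this package.
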