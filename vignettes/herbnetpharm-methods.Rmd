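---
title: "Methods: screening, diffusion and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, diffusion and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnetpharm)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the synthetic study conditions it is tested under,
and the choices made where the design was genuinely open.

## 1. The ADMET screen

Every compound enters with signed class probabilities from binary ADMET
classifiers. The sign is the predicted class, the magnitude the class
probability in (0, 1]; both the ASCII hyphen and the Unicode minus are
accepted on input, as published admetSAR-style tables use either.

**Absorption gate.** A compound is retained iff both the human intestinal
absorption (HIA) and Caco-2 permeability calls are positive. No probability
threshold beyond the class sign is applied: the upstream classifiers
already encode their decision boundary in the sign, and any extra cutoff
would double-count their uncertainty. The gate is idempotent and order
preserving; magnitudes pass through untouched for reporting.

**Metabolism score.** Retained compounds are ranked by

$$\mathrm{score} = \sum_{k \in \mathrm{CYP}} \mathrm{result}_k \, Q_k$$

over the five major CYP450 isoforms (1A2, 2C9, 2D6, 2C19, 3A4), where
$\mathrm{result}_k$ is the class-signed inhibition probability and $Q_k$
the isoform model's overall predictive accuracy. The defaults are the
published accuracies of the admetSAR inhibition models:

| isoform | $Q$ |
|---|---|
| CYP1A2 | 0.8147 |
| CYP2C9 | 0.8018 |
| CYP2D6 | 0.8551 |
| CYP2C19 | 0.8054 |
| CYP3A4 | 0.6450 |

The sign convention — inhibitor positive — means the score *rewards*
predicted CYP inhibition. That is intentional: in this screening tradition
the metabolism criterion favours compounds that inhibit the major
drug-metabolising isoforms (higher expected metabolic stability of the
lead), and this convention is the one that makes the published worked
examples reproducible to eight decimal places. Consequences worth knowing:
$|\mathrm{score}| \le \sum_k Q_k = 3.9220$, with equality only for unit
probabilities all of one class, and flipping a single call changes the
score by exactly $2\,p\,Q_k$.

Ties in the ranking are broken by compound id ascending. This is our rule,
stated because published tables present tied compounds in an order they do
not explain; any deterministic tie-break would do, and the lexicographic one
is reproducible across platforms. Truncation to the `top_n` leads happens
after the full ranking, so ranks are stable under truncation.

## 2. Target diffusion on the substructure–drug–target network

Query compounds are new chemical entities: they are never nodes of the
training network and inject mass only through the substructure keys they
share with known drugs. Prediction is a three-hop, degree-normalised
resource-allocation process — the parameterless base case of the
network-based-inference family:

1. unit mass is split equally over the query's substructures present in
   the network (absent keys are dropped with a warning);
2. each substructure splits its mass equally over the drugs carrying it;
3. each drug splits its mass equally over its known targets.

Mass reaching a drug with no targets is reported as `leaked_mass` and
**never renormalised**: renormalisation would silently inflate the scores
of reached targets and hide how much of the query's evidence fell off the
network. Resource plus leakage sums to 1 to machine precision on every
query; the test suite holds this at 1e-12 and checks the whole kernel
against an independent path-enumeration oracle (sum over
substructure→drug→target paths of products of inverse out-degrees) on a
dense randomized sweep of small instances — all class-size combinations up
to 6 nodes per class crossed with several edge densities and seeds —
because literal exhaustion over all small edge sets is combinatorially
impossible.

The published method family does not fix its propagation equations in
print, so the kernel here is the family's canonical base case, and the one
tunable we expose is a neighbour-degree exponent `alpha` on the final hop
(mass to target $t$ proportional to $\deg(t)^\alpha$): `alpha = 0` (the
default used everywhere in the package) recovers the equal split, negative
values damp hub targets. Any `alpha` conserves mass.

Per-compound predictions keep the top `k = 20` targets (descending
resource, ties by target id ascending); a batch's compound–target edges
are the union of per-compound top-20 lists, which is the reading consistent
with storing "top 20 per compound" before network construction.

**Cross-validation protocol.** `cross_validate()` partitions the known
drug–target edges into folds (10-fold default, or leave-one-out), rebuilds
the network without the held-out edges, and scores each held-out drug as a
query through its own substructure profile. Each held-out positive is
compared against 10 non-edges of that drug sampled uniformly under the run
seed (targets never linked to the drug in the *full* network; unreached
targets score 0); the per-positive AUC counts wins with ties as ½, and
fold AUCs average over positives. Two properties of this protocol matter
for interpretation: (i) positives arising from background noise edges have
no recoverable signal and dilute the AUC toward 0.5 in proportion to the
noise rate; (ii) a label-permutation null preserves target degree, and
degree-normalised diffusion favours high-degree targets, so the null AUC
sits slightly above 0.5 (≈ 0.55 under the default synthetic conditions)
rather than at it — the acceptance check therefore brackets the null in
[0.4, 0.6] averaged over seeds.

## 3. Tissue classification

Expression tables are ordinal (`not_detected < low < medium < high`), one
row per target, one column per tissue. A target counts as expressed in a
tissue iff its level is at or above `detected_threshold`; the default
`"low"` treats any detection as expression, because antibody-based
expression atlases already fold reliability into the detected/not-detected
call and no published cutoff exists for this screen. The five classes
(`both`, `keratinocyte_only`, `melanocyte_only`, `neither`, `unmapped`)
always partition the input, and raising the threshold can only shrink the
retained (skin-relevant) set — both are tested properties.

## 4. Over-representation analysis

Enrichment of a target set in a gene-set collection is the upper
hypergeometric tail $P(X \ge k)$ with population $N$ (the universe), $K$
successes (the set), $n$ draws (the query), adjusted across the collection
by Benjamini–Hochberg. The universe defaults to whatever the caller
supplies — in the pipeline, the targets of the DTI network — since an
enrichment p-value is only meaningful relative to a stated universe.
One-sided over-representation only; no EASE-style score modification is
applied. Exactness is tested against brute-force combinatorial summation
($\sum_j \binom{K}{j}\binom{N-K}{n-j}/\binom{N}{n}$) for all $N \le 30$.

## 5. The synthetic study conditions

The generators in `synth_config()` define the study conditions every test
and the acceptance script run under; they are fixed defaults, not tuning
knobs.

* **Compound library**: 48 compounds in classes 18 steroids / 13 terpenes /
  11 flavonoids / 3 fatty acids / 3 others, mirroring the printed tally of
  the motivating screen. Fixture SMILES are simple valid aliphatic strings;
  realistic chemistry is deliberately out of scope, so structural classes
  are decoration and fingerprints in fixtures are random binary profiles,
  not chemical truth.
* **ADMET table**: exactly 37 of 48 compounds double-positive on
  HIA/Caco-2 (the screen's printed pass count); magnitudes uniform on
  (0.5, 1]; CYP calls with random sign. The ground-truth pass list is
  emitted alongside so tests never re-derive truth from generator
  internals.
* **DTI network with planted signal**: 100 drugs, 20 targets, 30
  substructure keys of which 15 are planted in a one-to-one map to the
  first 15 targets; a drug carrying planted key $i$ gains target $i$ with
  probability `strength = 0.95`; background edges occur at rate 0.005.
  Profiles are sparse (each key carried with probability 0.08, ~2.4 keys
  per drug), so each drug's target set is driven by one or two planted
  keys — the statistical structure the diffusion method assumes of its
  training data (substructure sharing predicts target sharing). Earlier,
  denser designs in which every drug mixed three or more planted signals
  and >10% of edges were noise made held-out edges intrinsically ambiguous
  and are not what "planted signal" should mean. Queries carry one planted
  key each (cycling through the 15) plus noise keys only, with the
  expected target recorded in a truth sidecar.
* **Expression table**: detection rates 0.8 (keratinocyte) and 0.75
  (melanocyte), levels uniform over low/medium/high among detected —
  roughly the detected fraction a skin-expressed target list shows in
  antibody atlases.
* **Gene sets**: ten background sets of 20 drawn uniformly from a
  100-id universe, plus one planted set drawing 90% of its members from a
  designated 25-id query set.

All generators are pure functions of the configuration: same seed, byte
identical files. What passing tests on these conditions shows is that the
implementation recovers signal that is present by construction; it says
nothing about the biological correctness of any real screen, about real
fingerprint chemistry, or about atlas-version-dependent tissue counts.

## 6. Numerical and design choices

* Ties break lexicographically by id at every ranking surface (compounds,
  targets, enrichment sets at equal p).
* Mass bookkeeping is exact to 1e-12; no tolerance is hidden in the
  diffusion itself.
* All stochastic steps (fold assignment, negative sampling, every
  generator) take explicit seeds; child seeds are derived additively and
  kept below 2^31.
* Degenerate inputs have defined behaviour rather than errors where the
  pipeline can proceed: empty library files load as empty tibbles,
  queries with no in-network substructure return leakage 1, unparseable
  SMILES are flagged and carried, unmapped targets form their own class.
* Problem sizes in the test suite and acceptance script — 1000
  mass-conservation queries, 5-seed cross-validation batches, 20-seed
  enrichment recovery, ~200 small instances for the oracle sweep — were
  chosen to make the stochastic contracts sharp at interactive runtimes.
* Replicated qRT-PCR wells are summarised by condition-mean ΔCt before
  ΔΔCt (the common convention when none is stated); per-replicate fold
  changes are attached for dispersion reporting.

## 7. Known limitations

* The diffusion kernel is the family's base case; the published variant's
  exact propagation weights are not public, so absolute resource values
  (not ranks) should be compared across implementations with care.
* Without a chemistry backend the package trusts supplied fingerprint
  matrices; SMARTS dictionaries are matched via OpenBabel when available,
  and molecules the toolkit cannot round-trip (e.g. single heavy atoms)
  fingerprint as all-zero rather than erroring.
* The tissue filter is a two-column detection rule, not an antibody
  reliability model; published only-expressed-in counts are atlas-version
  dependent and are not reproduced here.
* Enrichment replaces a DAVID workflow; p/q ranks are comparable,
  DAVID's clustered reports are not.
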