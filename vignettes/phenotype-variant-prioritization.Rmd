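---
title: "Phenotype-driven variant prioritization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven variant prioritization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoprio)
```

`phenoprio` ranks the variants of a single patient VCF by the probability
that each is causative for the patient's phenotypes. This vignette explains
the three models the package composes — a cross-species phenotype ontology,
a semantic-similarity engine, and a random-forest classifier — together with
the synthetic benchmark that exercises them, the tunable parameters, and
the numerical and design choices a maintainer should know about.

## The phene pattern and the restricted reasoner

Phenotype vocabularies from different species cannot be compared directly,
but most of their classes decompose into an affected **entity** (an
anatomical structure or physiological process) bearing a **quality**. The
package normalizes every phenotype class to

```
P  EquivalentTo:  has-part some (E and has-quality some Q)
```

by applying rewriting rules to raw entity–quality conjuncts, starting from
`E = Q = owl:Thing`: `inheres-in X` sets the entity, `inheres-in-part-of X`
sets it wrapped in `part-of`, `modifier X` attaches to the quality, and
`towards`, `exists-during`, `part-of`, `has-central-participant`,
`results-from` and `occurs-in` attach to the entity as qualifier conjuncts.
`has-part X1 and ... and has-part Xn` is treated as an intersection: each
conjunct is rewritten recursively and the phenotype is subsumed by each
conjunct's class.

Three readings here were genuinely open and are the package's own choices:

* **Primary quality.** In flattened conjunct lists the phene pattern's
  primary quality arrives as a `has-quality` conjunct, while the same
  relation can also qualify the entity. The first `has-quality` conjunct
  therefore sets `Q`; subsequent ones attach to `E` as opaque qualifiers.
* **Rule order and composition.** Conjuncts are processed left-to-right in
  input order; repeated attachment rules compose by conjunction (two
  `towards` fillers both attach). `inheres-in` replaces the entity class
  but preserves previously attached qualifiers.
* **Qualifier semantics.** Modifier and qualifier conjuncts are inert
  except during subsumption, where a parent's conjunct must be matched by a
  child conjunct of the same relation whose filler the parent's filler
  subsumes; a conjunct absent from the parent never blocks. In particular
  an *unmodified* quality subsumes a modified one — severity modifiers
  specialize. `part-of` qualifiers are compared under the combined
  is-a + part-of closure, all others under is-a alone.

Subsumption between two phene-pattern classes is then decidable without a
general-purpose description-logic reasoner: `P1 = (E1, Q1)` is below
`P2 = (E2, Q2)` iff the entity test passes (against the is-a closure for
plain parents, the is-a + part-of closure for `part-of`-wrapped parents,
which includes every abstract S-class), the quality test passes under the
quality is-a closure, and all qualifier conjuncts are compatible. One
abstract class `S(E) ≡ has-part some (part-of some E)` is minted per
distinct entity so that parthood in the anatomy becomes subsumption in the
phenotype hierarchy; generated class IDs are deterministic hashes of the
normalized definition, so rebuilds are bit-identical. Classes that subsume
each other (e.g. a zebrafish-style class precomposed from the same `E` and
`Q` as an existing class) are kept as distinct nodes whose *relation*
records the equivalence; the serialized edge list canonicalizes each
equivalence group under a representative so it remains a DAG.

The reasoner is deliberately restricted to the fragment the rewriting rules
produce. Its contract is enforced by a brute-force oracle: an independent
O(n²) pairwise decision procedure (igraph reachability, direct fixed-point
transitive closure) must agree exactly with `infer_hierarchy()` on dozens
of random ontologies of up to 200 classes per run.

## Information content and profile similarity

Given a corpus of gene → phenotype-class annotations (tagged `human`,
`mouse` or `zebrafish`), annotations propagate to all ancestors and each
class receives `IC(c) = −ln(n_c / N)` nats, where `n_c` counts genes
reaching `c` and `N` is the corpus gene count. The natural logarithm is a
convention only — the per-profile normalization removes the scale. Classes
reached by no gene receive the corpus minimum frequency `1/N` instead of
infinite IC, so pairwise similarity is always finite.

Pairwise similarity is Resnik's measure (IC of the most informative common
ancestor); profile-to-gene similarity is the symmetric best-matching
average

```
BMA(p, g) = ( mean_x max_y res(x, y)  +  mean_y max_x res(x, y) ) / 2 .
```

Per patient profile, gene scores are divided by their maximum, so the
best-matching gene always scores 1; an all-zero profile maps to all zeros
rather than dividing by zero. Restricting the corpus to `human`, to
`{mouse, zebrafish}`, or to all three reproduces the three standard source
configurations (known-disease-gene mode, novel-gene mode, and both);
normalization is applied *after* source filtering, and a gene's annotations
surviving the filter are pooled into a single set.

## The 60-feature representation and the classifier

Each (variant, profile) pair is represented by exactly 60 features, in a
fixed documented order: three pathogenicity scores (possibly missing),
zygosity (het = 1, hom = 2), the mode of inheritance of the presented
disease as a single four-valued categorical (Dominant/Recessive/X-linked/
Other — the single-categorical reading is what makes the total come out at
60 rather than 63 with one-hot coding), 54 binary flags marking which
high-level panel classes subsume any profile class, and the normalized
gene similarity. For generated worlds the 54-class panel is derived from
the hierarchy by breadth-first order from the root, padded by repeating the
root when the hierarchy is shallow (a constant flag, harmless to a tree
ensemble); for real vocabularies it would be the curated upper-level
classes and is plain configuration.

Training sets are built from a ClinVar-like labeled table. Pathogenic
variants are expanded into candidate genotypes by the disease's mode of
inheritance — recessive diseases yield a single homozygote, everything else
a heterozygote and a homozygote — and paired with their own disease's
profile as positives. Negatives come in two flavors: *pathogenic
non-causative* (the same genotypes presented with a uniformly sampled
different disease's profile and MOI — the genotype physically present, the
phenotypic context swapped) and *benign non-causative* (benign variants
expanded under a randomly assigned disease). The three model modes use one
pool, the other, or a 50/50 blend obtained by subsampling the larger pool
to the smaller one's size. Diseases without phenotype annotations cannot
supply a profile and are excluded with a message. The forest itself is a
standard implementation configured to 100 trees, unlimited depth and 6
candidate features per split; all stochastic steps (disease mismatching,
subsampling, fold assignment, tree growing) are seeded, and two runs with
equal seeds are bit-identical.

Missing values (unscored indels, absent MAF entries) are never grounds for
dropping a variant. A transparent imputer stands in for decision-tree
fractional-instance imputation: at training time missing numerics take the
label-conditional median and missing categoricals the label-conditional
mode; the model stores pooled statistics and applies those at prediction
time, when labels are unknown. The stored table travels with the
serialized model, together with the feature signature that `read_model()`
verifies.

## Filtering and ranking

Before scoring, three filters run in a fixed order, each variant counted
against the first rule that removes it: uncalled genotypes (missing calls,
half-calls, and multi-allelic calls that are neither simply het against the
reference nor hom for a single alternate); heterozygotes when the disease
is recessive; and variants whose known minor allele frequency exceeds the
cutoff (default 1%). A missing MAF is treated as rare and retained — novel
variants are precisely the method's target. X-linked inheritance adds no
extra zygosity filter. Kept variants are ranked by forest probability;
ties break deterministically by higher mean of the available pathogenicity
scores, then chromosome, then position. Gene assignment uses containment
in half-open intervals (ties to the smaller start) and otherwise the
nearest contained coordinate (`start − pos` upstream, `pos − (end − 1)`
downstream), so top-k metrics are reproducible to the byte.

## The synthetic benchmark

`generate_toy_world()` fabricates the complete input universe: a layered
random entity DAG with is-a and part-of edges under a fixed
quality/modifier vocabulary, phenotype classes produced by the actual
rewriting rules (including inheres-in-part-of, modifier, towards and
zebrafish-style classes), a gene–phenotype corpus, a disease table with
sampled modes of inheritance, and non-overlapping gene intervals on two
chromosomes. Each gene carries *private* phenotype classes (grounded in
entities no other gene uses) plus draws from a *shared* pool; each
disease's profile is a prefix of its causal gene's annotation set, which
makes the causal gene the profile's unique best match — an invariant the
tests assert per world.

`spike_in_case()` emulates the spike-in benchmark: background variants are
placed uniformly over genic and intergenic space (fraction exonic
configurable; 1.0 emulates an exome run) with benign-model scores and a
mixture of rare, common and missing MAFs, a few percent uncalled genotypes
to exercise the filters, and exactly one causative variant inserted into
the causal gene — homozygous if the disease is recessive — with
pathogenic-model scores and no MAF entry. Scores follow truncated normals
centred at 0.3 (benign) and 0.8 (pathogenic): the *separable* signal clamps
the two supports apart (σ = 0.05, benign ≤ 0.55, pathogenic ≥ 0.65) so the
clean benchmark has a recoverable answer by construction, while the *noisy*
signal overlaps them with a configurable σ. Training variants occupy the
first half of each gene interval and spiked variants the second half, so
the evaluation cohort never contains a trained-on variant while sharing the
ontology and annotations, mirroring a holdout design. Truth records
(which variant was spiked) are returned separately and never written into
any pipeline-visible file.

Profile perturbations model imperfect phenotyping: *comorbid* unions in a
second disease's phenotypes; *dropout* removes each class independently
with probability p (default 1/3) and resamples rather than emptying a
profile — at degenerate p ≈ 1 a single random class is retained;
*two-variant* selects the most phenotypically similar other disease (by
BMA between disease profiles) whose causative variant is spiked in
alongside.

What the generator does **not** emulate: realistic allele-frequency
spectra, linkage structure, overlapping genes and transcripts, read-level
error, multi-gene (oligogenic) causation, and the sheer scale of a real
exome (tens of thousands of variants, thousands of genes). Passing tests
therefore demonstrate that the machinery is correct and that the method
recovers signal under stated noise models — not that a particular recovery
percentage transfers to clinical data.

## Problem sizes and experiment designs

The default study conditions are: worlds of 24 genes and 12 diseases
(4 phenotypes per disease), training tables of 2–3 pathogenic variants per
disease plus 40–60 benign variants, spike-in cases of 200–500 background
variants, clean-recovery cohorts of 200 cases, noise cohorts of 60 paired
cases, two-variant cohorts of 100 cases, and stratified 10-fold
cross-validation. These sizes were chosen so each experiment comfortably
estimates the quantity it reports while the whole suite runs on one CPU.

The phenotyping-depth experiment (the Spearman correlation between summed
profile IC and causative rank) uses its own world: 6 phenotypes per
disease split 3 private / 3 shared and the noisy score signal (σ = 0.3)
over 150 cases with dropout probability growing linearly with case index
to 0.85, paired with the pathogenic-negative model. The reasoning: the
correlation measures whether *richer phenotyping yields better ranks*, so
the profile axis must have room to vary (deep profiles), degraded profiles
must actually become ambiguous (shared low-IC annotations left after
dropout match many genes), and ranks must be able to respond (overlapping
scores, a model that leans on phenotype similarity). With fully private
annotations or fully separable scores the rank saturates at 1 and the
correlation degenerates.

## Numerical choices and degenerate inputs

* Oracle-equivalence tests compare boolean subsumption matrices exactly;
  similarity oracles use a 1e-9 absolute tolerance.
* Zero-max normalization returns zeros; empty profiles, empty corpora,
  single-label training sets, unstratifiable folds, and profiles with
  unknown classes are errors naming the offender; an empty ranked result
  is a warning, not an error.
* The recovery summary excludes unranked causative variants from
  percentage denominators while reporting them in `n_total`, and uses the
  lower median for even case counts.
* ROC AUC is the rank-based Mann–Whitney estimator with ties counted ½,
  identical to the brute-force pairwise comparison.
* Multi-allelic genotype calls such as `1/2` are split into per-alternate
  records, each marked uncalled unless it is simply het or hom for that
  alternate.
* The seven source mode-of-inheritance labels collapse to four
  (Multifactorial/Others/Sporadic/Y-linked → Other).
* Rare variants are *kept* by the MAF filter (remove-common reading):
  the filter removes variants with known MAF above the cutoff.

## Known limitations

The reasoner handles only the phene-pattern fragment — arbitrary OWL
axioms, role chains beyond is-a/part-of, and consistency checking are out
of scope, as is parsing real OWL/RDF serializations (the OBO-style flat
dialect is the interface). The imputer is a deliberate simplification of
fractional-instance imputation. Compound-heterozygote logic, pedigree
analysis and structural variants are not modelled. The information content
used in the depth experiment is corpus IC only; measures mixing ontology
depth with disease frequency would need a separate definition.
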