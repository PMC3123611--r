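---
title: "Building and validating biomedical WSD benchmarks from MeSH indexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating biomedical WSD benchmarks from MeSH indexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsdbench)
```

## The problem

A term like *cold* can denote a temperature, an infection, a sensation or a
lung disease; which concept is meant depends on context. Supervised word
sense disambiguation (WSD) needs sense-annotated examples, and manual
annotation is the bottleneck: hand-curated biomedical collections are small
and skewed. This package implements an automatic construction of such a
benchmark that reuses two existing, independently maintained resources:

* the **UMLS Metathesaurus**, where ambiguity is visible structurally — a
  surface string associated with two or more Concept Unique Identifiers
  (CUIs); and
* the **manual MeSH indexing of MEDLINE**, where human indexers have
  already recorded, citation by citation, which Medical Subject Heading a
  paper is about.

When an ambiguous string's candidate CUIs are each anchored to a distinct
MeSH main heading, a citation that (a) contains the string in its title or
abstract and (b) is indexed with exactly one of those headings is an
instance of that sense, annotated for free. The package turns this idea
into a reproducible pipeline and implements the disambiguation methods used
to validate the result.

## Pipeline

### 1. Ambiguous term identification

`read_mrconso()` materializes English atoms from a release-style MRCONSO
table; `build_concept_store()` indexes them under case-normalized term keys
(lowercase, internal whitespace collapsed; punctuation kept — only case and
spacing variants merge). `find_ambiguous_terms()` returns keys with two or
more CUIs, and `restrict_to_mesh_headings()` keeps a candidate only if at
least two of its CUIs carry an `MSH`/`MH` atom. Suppressible atoms are kept
by default (`keep_suppressed = TRUE`) since release-level ambiguity counts
conventionally include them; the switch exists because the choice is
genuinely open.

`ambiguity_statistics()` reports, per semantic group, the distinct and
ambiguous term-key counts, percent ambiguous and an inter-group
shared-term matrix. Group membership of a key is through *any* of its
CUIs' semantic types, the natural term-level reading; percentages are
rounded half up to two decimals (`round_half_up()`), the convention under
which the shipped reference counts reproduce their published percentages
(e.g. 445/1835 → 24.25). The `mesh_linked` column counts ambiguous keys
with at least two main-heading senses, i.e. benchmark candidates — the
counting rule is stated here because reference tables of this kind leave
it implicit.

### 2. Citation retrieval

For each sense, `build_query()` renders a PubMed-compatible boolean query:

```
"<term>"[TIAB] AND "<heading>"[MH:noexp] NOT "<other>"[MH:noexp] ...
```

with one `NOT` clause per competing sense. No-explosion (`MH:noexp`)
matching keeps descendant headings out; the `NOT` clauses guarantee that a
citation indexed with two candidate headings is retrieved for *no* sense,
which is what makes the per-sense sets disjoint by construction.
`evaluate_query_local()` evaluates the same contract against a local
MEDLINE-format corpus: term presence is a case-insensitive token-boundary
match of the exact surface string (`term_in_tiab()`, offsets reported
0-based half-open), and heading comparison is exact and case-sensitive on
the descriptor part. PubMed's automatic term mapping and lexical-variant
expansion are deliberately not emulated; an entry-term variant of the
surface string does not satisfy the TIAB constraint here.

### 3. Quality assurance

Three filters run in order (`run_filter_chain()`), each survivor set a
subset of its input:

1. **Minimum evidence** — every sense needs at least
   `min_citations_per_sense` (default 10) retrieved citations.
2. **Separability** — senses that cannot be told apart in text (e.g. a
   hypernym split across two concepts) are detected by training a linear
   maximum-margin classifier (libsvm C-classification, linear kernel, cost
   `svm_cost = 1`) on raw token counts under seeded stratified
   `cv_folds`-fold cross-validation; a term is discarded when any sense's
   recall falls strictly below `recall_threshold` (default 0.8 — a recall
   of exactly 0.8 passes). Recall, not F-measure, is the criterion: a
   sense that silently absorbs the other's instances shows up as the other
   sense's recall collapsing. Recall is computed on pooled out-of-fold
   predictions rather than averaged per fold, which avoids undefined
   per-fold recalls when a fold happens to contain few instances of a
   sense.
3. **Length** — term keys shorter than `min_term_length` (default 2)
   characters, whitespace ignored, are noise (one-letter "terms") and are
   removed; two-character chemical symbols survive.

### 4. Assembly

`assign_sense_labels()` names senses `M1..Mk` in ascending CUI order — an
arbitrary but deterministic rule; the emitted label→CUI→heading mapping
makes downstream comparisons independent of it. `balance_and_sample()`
draws, per sense, a seeded uniform sample without replacement of up to
`max_instances_per_sense` (default 100) citations; instance text is title
plus abstract, with no sentence windowing. `write_arff()` serializes each
term as an ARFF file (pmid string, text string, nominal sense label;
double quotes, backslash escapes) whose relation line carries the sense
mapping, and `read_arff()` inverts it exactly. Provenance (seed,
configuration hash, corpus id) is stamped in comments, never timestamps,
so identical runs are byte-identical.

## Disambiguation methods

All methods share one text normalization (`normalize_tokens()`): lowercase,
split on non-alphanumerics, drop stopwords (shipped general-English list)
and tokens under two characters, Porter-stem. The stemmer is implemented
in the package (with the two standard departures of the reference
implementation) because no stemming dependency is available; it is tested
against canonical word/stem pairs.

* **NB** — supervised multinomial Naive Bayes with add-one smoothing over
  the training vocabulary; tokens unseen in training are ignored at
  scoring, so an all-unknown instance scores the priors. Evaluated by
  seeded stratified 10-fold cross-validation (`nb_crossval()`), since a
  benchmark provides no external training data.
* **MRD** — a concept profile per sense: tokens pooled from the concept's
  definitions, its synonym strings, and the definitions and preferred
  strings of related concepts *excluding siblings* (siblings describe
  neighbors, not the concept). Weights are tf × ln(N/cf), where N is the
  number of profiles in the sense collection and cf the number containing
  the token — the log form zeroes tokens common to every sense, which is
  the point of inverting the concept frequency. Instances are scored by
  cosine between their term-frequency vector and each profile; cosine with
  a zero vector is 0.
* **2-MRD** — second-order variant: a symmetric within-window co-occurrence
  matrix (radius `cooccurrence_window = 2`, diagonal excluded) is built
  over the run's corpus; an instance is represented by the centroid of its
  tokens' matrix rows. Concept centroids average the rows of the profile
  tokens weighted by their tf·icf weights; this keeps ubiquitous pool
  tokens inert and has a useful degeneracy: with an identity co-occurrence
  matrix over a shared vocabulary, 2-MRD reproduces MRD's predictions
  exactly, which the tests assert.
* **AEC** — an automatically extracted training corpus: for each sense,
  `monosemous_relatives()` collects synonym and related-concept strings
  that map to exactly one CUI, and citations matching a relative as an
  exact phrase (or, if a phrase retrieves nothing, all of its words
  anywhere in title/abstract — the broadened form) are labeled with that
  sense. Citations claimed by relatives of two senses are dropped rather
  than double-labeled. Up to `aec_max_train_per_sense = 100` documents per
  sense (seeded sample) train a Naive Bayes model that then scores the
  instances. A sense with no training document after the fallback makes
  the term unscorable by AEC; other methods are unaffected. Training
  retrieval is taken over the whole local corpus with no test-instance
  exclusion — the construction mirrors harvesting from an independent
  literature corpus, and in the synthetic fixtures relative-bearing
  citations never contain the ambiguous term, so overlap cannot occur.

`combine_scores()` implements two ensembles: *sum* (each method's scores
shifted nonnegative, normalized to sum one, then added) and *vote*
(majority of argmaxes; ties resolved by the sum-mode score, then by the
lower label). Ties everywhere break to the lowest sense label —
deterministic by design.

## Evaluation

`accuracy_report()` computes per-term accuracy and category accuracies over
the abbreviation/term/mixed sets, both macro (unweighted over terms) and
micro (instance-weighted); both are printed because either convention is
defensible and they differ exactly when per-term instance counts differ.
`quartile_breakdown()` sorts terms by corpus frequency (descending, ties
by term key), splits them into four contiguous groups with remainders to
the earlier groups, and reports macro accuracy with frequency ranges.
`group_pair_breakdown()` assigns each term to every unordered pair of its
senses' semantic groups (a three-sense term with groups A, B, B feeds
(A,B) and (B,B); a group-less CUI appears as `UNK`).

`randomization_test()` compares two methods by the absolute difference of
overall macro accuracies: each iteration swaps the two methods'
predictions per instance with probability 1/2, and the p-value is
`(#{statistic ≥ observed} + 1) / (iterations + 1)` (10,000 iterations by
default, two-sided via the absolute difference, add-one correction so the
p-value is never zero). The test is exact under instance-level
exchangeability and conservative under heavy ties in the discrete
statistic — with few terms and uniform instance weights the rejection rate
at α = 0.05 sits slightly below 0.05, which the calibration test makes
visible.

## The synthetic fixture generator

`generate_fixture()` emits an internally consistent miniature of the whole
input universe: release tables in which every ambiguous term has k CUIs,
each with a main-heading atom, a monosemous synonym, a definition, two
non-sibling relatives (with definitions drawn from the same sense
vocabulary) and one sibling (with a shared-vocabulary definition, so tests
can prove sibling exclusion); and a MEDLINE corpus in which each citation's
content tokens come from a mixture λ·(sense vocabulary) + (1−λ)·(shared
vocabulary). λ is the *separability* of the senses: at λ = 1 sense
vocabularies are disjoint and any consistent classifier can reach recall
1; at λ = 0 the senses are statistically identical and every method must
sit at chance. Citations carry their sense's heading plus distractor
headings from a pool disjoint from all sense headings, so cross-sense
leakage can only come from the dedicated dual-indexed plant. Planted
failures realize each QA filter's removal condition literally (a sense
with 9 citations under a threshold of 10; a λ = 0 term; the term `q`).
Vocabulary words are random alphabetic strings whose Porter stems are
unique and stable under restemming — stability keeps token identity
well-defined across repeated normalization, which real English words do
not always guarantee and nothing in the pipeline should depend on. All
randomness flows from the single spec seed; identical specs produce
byte-identical files.

What the generator does **not** emulate: Zipfian token frequencies,
document length correlations, entry-term variation of the ambiguous
surface string, or realistic MeSH co-assignment patterns. Passing tests on
fixtures therefore demonstrate the pipeline's logic — filters remove what
they should, retrieval is sound and disjoint, methods order as expected as
separability varies — not performance on real MEDLINE text. In particular,
fixture definitions are drawn from the same vocabularies that generate the
citations, which makes the knowledge-based methods unrealistically
well-informed: at very low λ, MRD can even edge out cross-validated NB
because its profiles are built from noise-free sense vocabulary. Real
Metathesaurus definitions are far weaker signals.

## Problem sizes and numerical choices

The test and acceptance workloads use 2-term fixtures with 2 senses, 15–30
citations per sense, 20–40-token abstracts, shared vocabulary 60–150 and
sense vocabularies 20–40 — sizes chosen so that the statistical
assertions (recall 1.0 at λ = 1, chance bands at λ = 0, NB ≥
knowledge-based at λ = 0.6 over 10 seeds) are stable under their fixed
seeds while the whole suite stays quick. The randomization calibration
uses 200 null pairs of 100 instances at 999 iterations. Other fixed
choices: percentages round half up; cosine of any zero vector is 0; NB
works in log space with a max-shift before exponentiation; fold assignment
is stratified round-robin after a seeded shuffle; per-term sampling seeds
are derived by hashing the master seed with the term key, so adding a term
never perturbs another term's sample.

## Limitations

* The remote retrieval path (live E-utilities queries) is out of the
  tested surface; the local corpus evaluator is the normative
  implementation of the query contract.
* Entity classes (abbreviation / term / both) are editorial annotations
  supplied by the user, not detected.
* The semantic-type categorization method that requires externally trained
  journal-descriptor vectors is not implemented; its training resources
  are not reconstructible from release tables.
* Survivor counts and accuracies of a full-release run depend on licensed
  UMLS and complete MEDLINE data and are outside what the synthetic
  fixtures can certify.
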