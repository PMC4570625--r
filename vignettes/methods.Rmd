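---
title: "Scoring, fusing and evaluating GO-term predictions with gofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, fusing and evaluating GO-term predictions with gofuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofuse)
```

## The problem

Automated function prediction assigns Gene Ontology (GO) terms to a protein
from its sequence alone, usually by transferring annotations from homologs
found in a database search. gofuse implements this workflow as a library
over plain hit tables and prediction tables, so no live database search is
needed: two homology-based scorers (a PFP-style E-value/co-annotation
scorer and a two-level ESG-style scorer), two ensemble methods that fuse
per-method prediction tables (CONS and FPM), and a CAFA-style F-max
evaluation protocol over the GO directed acyclic graph.

## The ontology layer

GO terms form a DAG with three namespace roots (biological process,
molecular function, cellular component). `parse_obo()` keeps `is_a` edges
only: the minimal CAFA-style reading of "parental terms". `part_of` and
other relationships cross subontology boundaries and change the semantics
of propagation, so they are deliberately out of scope. Obsolete terms are
dropped at parse time; inputs referencing them are discarded with a warning
rather than an error, because archived annotation sets routinely contain
retired accessions.

`go_propagate()` extends a score map with all ancestors, giving each term
the **maximum** over its scored descendants. The max rule was a genuinely
open choice: summing scores up the DAG would break the [0, 1] confidence
contract and make propagation non-idempotent, whereas the max preserves the
interpretation of a confidence as a threshold cut (an ancestor is true
whenever any descendant is) and makes `propagate(propagate(x)) ==
propagate(x)`, which the test suite asserts. Truth sets are propagated with
the same operation at score 1.0. Propagation stays within a namespace
automatically because every term's ancestor chain ends at its own namespace
root; the evaluator can additionally filter to chosen namespaces
(`eval_config(namespaces = ...)`), covering both the per-ontology and the
pooled three-ontology evaluation styles.

## PFP scoring

For a target with homology hits $i = 1 \dots N$ (E-values $E_i$) whose
subjects carry direct annotations $f_j$, the raw score of a term
$f_\alpha$ is

$$ s(f_\alpha) = \sum_i \sum_j \big( (-\log_{10} E_i + b)\, P(f_\alpha \mid f_j) \big), $$

summed over all $f_\alpha$ with $P(f_\alpha \mid f_j)$ at or above the FAM
cutoff. The constant $b = 2 = \log_{10} 100$ keeps hit weights positive up
to the E-value-100 search bound, which also fixes the log base.
$P(f_\alpha \mid f_j)$ is the functional association matrix (FAM): the
fraction of database proteins directly annotated with $f_j$ that also
carry $f_\alpha$ (`build_fam()`). FAM counting is on directly assigned
terms without DAG closure — parental transfer is a separate step, and
counting closed sets here would double-count the hierarchy — and a protein
carries a term once no matter how many resources assigned it.

Tunable parameters (`pfp_config()`): `b` (default 2, dimensionless),
`fam_cutoff` (default 0.9, the best-performing of the published
0.25–0.9 range; lower values pull in weakly associated terms),
`evalue_ceiling` (default 100; hits above it are ignored at scoring time,
not parse time, so the benchmark homolog filter still sees them) and
`evalue_floor` (default 1e-180, substituted for literal E-value 0 before
the log; search programs print 0.0 for extreme hits and $-\log 0$ is
undefined). The floor is configurable because it is a numerical guard, not
a modelling choice. We use every hit within the ceiling rather than
capping the hit count, since nothing in the score depends on rank.

Parental transfer (`pfp_parent_transfer()`) then adds, for each directly
scored term $f$ and each ancestor $p$,
$s(f) \cdot \mathrm{count}(f)/\mathrm{count}(p)$, where counts are
ancestor-closed annotation counts, so $\mathrm{count}(p) \ge
\mathrm{count}(f)$ and the ratio is a proper fraction. Transfer runs once,
from directly scored terms only; re-transferring transferred mass would
compound geometrically. An ancestor with zero annotations contributes 0
with a warning. Confidences are finally obtained by dividing by the
maximum raw score (`pfp_confidence()`); the published material shows
confidences in [0, 1] without giving a formula, and max-normalization is
the simplest map consistent with them and with the downstream per-target
normalization used by the ensembles.

## ESG scoring

ESG explores similarity space in exactly two levels: a search from the
target, then one search from each level-1 hit. Within a search, each
retained hit's weight is its share of $-\log_{10} E$ over all retained
hits of that search (`esg_level_weights()`); hits with $E \ge 1$ have
non-positive logs — meaningless as proportions — and are excluded. A
level-1 hit contributes its weight to its terms; a level-2 hit contributes
the **product** of its seed's level-1 weight and its own within-search
share. The combination rule across levels is stated only as "the total
weight from the two levels"; the product respects the probabilistic
reading (a walk to a level-2 neighbour through its seed), keeps scores
at most 1 in the common case, and a final clamp to [0, 1] guards
pathological overlaps where both levels hit the same annotated proteins.
This choice is validated by its stated range property (scores in [0, 1],
exact 1.0 under unanimous annotation), not by an external reference.

## CONS

The consensus score of a term is the accuracy-weighted sum of its
per-method confidences (0 where a method lacks the term), normalized by
the maximum weighted sum over the target's own predicted terms:

$$ \mathrm{CONS}(GO^i) = \frac{\sum_m w_m\, \mathrm{conf}_m(GO^i)}{\max_k \sum_m w_m\, \mathrm{conf}_m(GO^k)}. $$

Normalization is per target — the denominator's $N$ is "the total number
of unique GO terms for the target", which pins the per-target reading.
The weights $w_m$ are prior accuracies; `loo_accuracy()` computes them as
each method's mean F-max over the benchmark with the current target held
out, so a target never contributes to its own weights.

## FPM

FPM mines GO-term sets supported by heavily weighted method subsets. A
method's weight is its mean predicted confidence times its accuracy; a
set's weight is the summed weight of the methods predicting **all** of its
members over the summed weight of all methods. Mining is apriori-style:
surviving singletons form the ordered list L, and each iteration extends
every surviving set with each L member lexicographically greater than its
last member, keeping sets at or above the weight cutoff (default 0.7, the
published operating point). Set weights are anti-monotone under extension
(the supporting method set can only shrink), which is what makes the
lexicographic candidate generation complete; the suite checks completeness
against brute-force subset enumeration.

Decisions the published description leaves open, fixed here for
determinism: lexicographic order is plain string order of accessions
(equivalent to numeric order for zero-padded GO ids); selection ties are
broken by higher weight, then by lexicographically smallest tuple; and the
final prediction is the selected set only, with the set's weight attached
to every member as a uniform confidence so the result can be evaluated on
the common F-max footing. `maxLen` selects the largest mined set,
`maxScoreLen` the largest among the top-weight sets.

## F-max evaluation

At a threshold $t$, the predicted set is every term with confidence
$\ge t$ (the inclusive cut makes $t = 1$ meaningful for max-normalized
scores). Per target, precision $= TP/(TP+FP)$ and recall $= TP/(TP+FN)$
against the (optionally propagated) truth set; precision is undefined when
nothing is predicted at $t$. Averages are taken across targets — precision
over targets with a defined value, recall over all targets — and F-max is
the maximum harmonic mean over the grid. Excluding empty-prediction
targets from the precision average follows CAFA1 practice and avoids an
arbitrary 0/0; `eval_config(count_empty_precision = TRUE)` switches to
counting them as precision 0. The default grid is the 0.01-step lattice
`0:100 / 100`, computed by division so two-decimal confidences land
exactly on grid points; F is piecewise constant between distinct
confidence values, so a 0.01 grid loses at most the pieces narrower than
one step, and the suite verifies exact agreement with an
enumerate-all-confidences oracle on lattice instances. Targets with empty
truth sets are a hard error: they must be excluded upstream, exactly as
unannotated proteins are excluded from benchmarks.

Prior augmentation (`augment_with_prior()`) first normalizes a prediction
to maximum 1, then merges in the `top_n` (default 1000) most frequent
vocabulary terms at their max-normalized database frequency, keeping the
larger score on collision; the same terms are added for every target.
`win_counts()` reports, per method, the fraction of targets on which it
attains the largest F-max, crediting all tied methods, so fractions can
sum to more than 1.

## Synthetic data

The fixture generators exist so every stage is testable offline.
`synth_dag()` grows a single-namespace DAG (root first, one or two parents
per later term); `synth_db()` assigns each protein 1–4 direct terms with
mixed experimental/electronic evidence (IEA-weighted, mimicking the
preponderance of electronic annotation in real databases); `synth_hits()`
draws E-values log-uniformly over $[10^{-40}, 1]$; `synth_bundle()` plants
a truth set of 3–6 terms per target and has each method report each true
term with probability `agreement` at a confidence uniform on
`conf_model = c(0.5, 1)`, plus spurious terms at binomial rate `noise` per
true term. Default study conditions: 3 methods, agreement 0.8, noise 0.1,
accuracy 0.8 per method — a moderately concordant ensemble of the kind the
fusion methods target. All generators run under an isolated seed (the
caller's RNG stream is untouched) and the same seed reproduces fixtures
byte-for-byte.

What the generator does **not** emulate: realistic GO DAG shape (tens of
thousands of terms, multiple namespaces, heavy-tailed branching),
correlated errors between methods that share a sequence-search backend,
E-value calibration of a real search program, and annotation bias toward
well-studied proteins. Passing the recovery tests therefore shows the
fusion and evaluation machinery is correct under known ground truth, not
that any particular F-max level will be attained on real proteomes; the
full-database benchmark figures reported for methods of this family
require era-matched database builds and thousands of PSI-BLAST searches
and are out of scope here.

## Problem sizes and numerical choices

The shipped tests run at desk scale, chosen so the whole suite completes
in well under a minute while still exercising every code path: DAGs of
20–50 terms, databases of 15–40 proteins, bundles of 3–4 methods over 4–7
terms for the mining oracles (brute-force enumeration is exponential in
the surviving-singleton count, so oracle comparisons cap it at 6–7), 200
random instances for the F-max oracle, and 5 seeded replicates for the
noisy-ensemble dominance check. Worked-example values are compared at
2-decimal rounding, matching the precision at which they are printed.
Ties in FAM probabilities, FPM selection and win counting are all broken
deterministically (documented above) so results are reproducible across
platforms; the only true floating-point comparison, the `maxScoreLen`
top-weight group, uses a 1e-12 slack.

## Known limitations

- `is_a`-only traversal understates ancestor sets for terms whose
  canonical path to the root uses `part_of`.
- The ESG cross-level combination rule is a documented interpretation of
  an underspecified description; alternatives (renormalizing across
  levels) would change absolute scores but not the [0, 1] contract.
- FPM's uniform per-member confidence discards within-set ranking, which
  makes its `maxScoreLen` variant conservative in threshold sweeps.
- The evaluator's precision-averaging convention for empty predictions is
  one of two defensible CAFA readings; both are available via
  configuration, and comparisons should state which was used.
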