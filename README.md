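# gofuse

Homology-based GO-term prediction, ensemble fusion and F-max evaluation
for protein function prediction, in plain R over plain tables.

## The problem

Most proteins are annotated by transferring Gene Ontology (GO) terms from
homologs found by a sequence database search. gofuse implements, at the
library level, the pieces of that pipeline that come **after** the search:

- **PFP scoring** — score a GO term for a target by summing, over all
  homology hits *i* and all terms *f<sub>j</sub>* annotated to each hit,

  *s(f<sub>α</sub>) = Σ<sub>i</sub> Σ<sub>j</sub> (−log₁₀ E<sub>i</sub> + b) · P(f<sub>α</sub> | f<sub>j</sub>)*

  with *b* = 2 and *P(f<sub>α</sub> | f<sub>j</sub>)* the co-annotation
  probability from a functional association matrix, followed by parental
  score transfer up the GO DAG in proportion to annotation-count ratios,
  and max-normalization to confidences.
- **ESG scoring** — a two-level search expansion: level-1 hits weighted by
  their share of −log₁₀ E, level-2 hits by the product of the seed's
  weight and their own share; scores stay in [0, 1].
- **CONS** — an accuracy-weighted consensus of several methods'
  confidences, max-normalized per target.
- **FPM** — apriori-style mining of GO-term sets whose supporting methods
  carry enough weight (method weight = mean confidence × accuracy; set
  weight = supporting weight / total weight), then selection of the
  largest (`maxLen`) or highest-scoring largest (`maxScoreLen`) set.
- **F-max evaluation** — CAFA-style: at each threshold *t*, average
  precision over targets that predict something and recall over all
  targets, and report the maximum harmonic mean over a 0.01 threshold
  grid, optionally after propagating predictions and truth to GO
  ancestors, with optional background-frequency prior augmentation.
- **Synthetic fixtures** — seeded generators for DAGs, annotation
  databases, hit tables and multi-method prediction bundles, so the whole
  pipeline is testable offline and byte-reproducible.

See `vignettes/methods.Rmd` for the full model, parameter defaults and
the numerical conventions.

## Worked example

The package ships the small three-method FPM bundle used throughout the
tests (`toy_fpm_bundle()`): MethodA (accuracy 0.6) predicts GO1 0.5,
GO2 0.6, GO3 0.4; MethodB (0.7) predicts GO2 0.7, GO3 0.8, GO4 0.4,
GO5 0.6; MethodC (0.5) predicts GO2 0.8, GO3 0.9, GO5 0.6.

```r
library(gofuse)
b <- toy_fpm_bundle()

sapply(b$methods, fpm_method_weight)
#> MethodA MethodB MethodC
#>    0.30    0.44    0.38      (mean confidence x accuracy, 2 dp)

round(sapply(c("GO1", "GO2", "GO3", "GO4", "GO5"),
             fpm_set_weight, bundle = b), 2)
#>  GO1  GO2  GO3  GO4  GO5
#> 0.27 1.00 1.00 0.39 0.73

fpm_set_weight(c("GO2", "GO5"), b)
#> 0.7321429                    (only B and C predict both)

g <- fpm_mine(b, weight_cutoff = 0.5)
# iteration 1: {GO2} {GO3} {GO5}    (GO1 and GO4 fall below 0.5)
# iteration 2: {GO2,GO3} {GO2,GO5} {GO3,GO5}
# iteration 3: {GO2,GO3,GO5}

fpm_select(g, "maxLen")$members        # "GO2" "GO3" "GO5"  (weight 0.73)
fpm_select(g, "maxScoreLen")$members   # "GO2" "GO3"        (weight 1.00)
```

Evaluating a prediction against a truth set:

```r
targets <- list(list(truth = c("GO2", "GO3", "GO5"),
                     pred = c(GO2 = 1.0, GO3 = 1.0, GO5 = 0.73, GO4 = 0.39)))
fmax(targets, eval_config(propagate = FALSE))$fmax
#> 1  (at threshold 0.73)
```

## Layout

| Path | Contents |
| --- | --- |
| `R/ontology.R` | OBO parsing, ancestor closure, max-rule propagation |
| `R/annodb.R` | annotation DB, functional association matrix, term frequencies |
| `R/homology.R` | hit tables, tabular-search parsing, close-homolog removal |
| `R/pfp.R`, `R/esg.R` | the two homology scorers |
| `R/ensemble.R` | CONS, FPM mining/selection, leave-one-out accuracies |
| `R/evaluate.R` | precision/recall, F-max, prior augmentation, win counts |
| `R/fixtures.R` | seeded synthetic DAG/DB/hits/bundle generators |
| `R/io.R` | TSV/GAF/OBO readers and writers |
| `inst/extdata/` | small text fixtures (diamond DAG, the toy bundle) |
| `tests/testthat/` | unit, property and oracle tests; `helper-oracles.R` holds the independent reimplementations |
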