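# mtgo

Module detection in protein–protein interaction (PPI) networks that uses
Gene Ontology (GO) annotation *during* module assembly, not just for
post-hoc enrichment. The algorithm iteratively re-partitions the network so
that topological modules align with GO-term protein sets, jointly tracking
Newman modularity

    Q(C) = Σ_h [ e_h / W − (d_h / 2W)² ]

and a GO-agreement functional

    QGO(C) = Σ_h |δ_B,h ∩ c_h| / N_GO ,

where `δ_B,h` is the protein set of the GO term that best describes module
`c_h` (the term minimizing the count of nodes outside `c_h ∩ δ`) and `N_GO`
is the number of GO-covered nodes. The result is a full-coverage partition
in which every module carries the single GO term that best explains it —
and, through those terms, an overlapping functional view of the network.
This joint optimization is particularly effective at recovering functional
modules that are **small** (2–3 proteins) or **sparsely connected**, which
purely topological community detection tends to miss.

The package is for computational biologists who want to decompose an
interactome (or any annotated network) into interpretable, GO-labeled
modules, and for methodologists who need the standard complex-prediction
benchmark stack: overlap/affinity score ω = |A∩B|²/(|A||B|),
Recall/Precision/F, clustering-wise Sn/PPV/Accuracy, Maximum Matching Ratio,
Composite Score, small/sparse target-set derivation, and Fisher's exact
significance of assigned labels with Bonferroni correction. A
planted-partition generator with controllable annotation degradation makes
everything testable without downloads.

## Worked example

The package ships a small synthetic benchmark (a planted network of four
modules, annotations at 90% coverage plus decoy terms, and the true module
catalog):

```r
library(mtgo)

net   <- read_network(system.file("extdata", "synthetic_network.txt",   package = "mtgo"))
ann   <- read_annotations(system.file("extdata", "synthetic_annotations.tsv", package = "mtgo"))
terms <- build_term_set(ann, net)          # filter to network, sizes 2..100
terms
#> GO term set: 7 terms covering 23 nodes (sizes 3-7)

res <- run_mtgo(net, terms, mtgo_params(seed = 7))
res
#> MTGO result: 5 modules (5 labeled), QGO = 1.0000, Q = 0.4621
#>   3 iteration(s), converged, solution from iteration 2
res$final_assignment
#>   module      term_id term_name size term_size overlap
#> 1      1  GO:TRUE0004      <NA>    3         3       3
#> 2      2  GO:TRUE0001      <NA>    8         7       7
#> 3      3 GO:DECOY0002      <NA>    1         3       1
#> 4      4  GO:TRUE0003      <NA>    5         5       5
#> 5      5  GO:TRUE0002      <NA>    8         7       7
```

QGO = 1 says every GO-covered node ended up inside the intersection of its
module with the module's selected term; the `overlap` column shows how much
of each module its term explains. Scoring the predicted modules against the
true complexes:

```r
targets <- read_complexes(system.file("extdata", "synthetic_complexes.txt", package = "mtgo"))
pred    <- predicted_complexes(res)        # modules of size >= 2
round(c(recall_precision_f(pred, targets),
        sn_ppv_accuracy(pred, targets),
        mmr = mmr(pred, targets),
        composite = composite_score(pred, targets)), 3)
#>    recall precision         f        sn       ppv  accuracy       mmr composite
#>     1.000     1.000     1.000     0.960     1.000     0.980     0.958     2.938
```

All four planted modules are recovered (Recall 1), and the Composite Score
(Recall + Accuracy + MMR, maximum 3) is 2.94. Fisher's exact tests of the
assigned labels over the GO-covered background give
`label_significance(res, terms, net)$significant_fraction` = 0.6 of labeled
modules significant at Bonferroni-corrected 1e-3 on this tiny example.

A command-line wrapper with `run`, `evaluate` and `simulate` subcommands is
installed at `system.file("cli", "mtgo.R", package = "mtgo")`; see the
methods vignette (`vignettes/mtgo-methods.Rmd`) for the model, parameter
semantics and design choices.

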