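# fcalink

Bipartite link prediction with FCA-based negative sample selection.

## The problem

Association networks — chemical–disease, user–item, author–paper — are
bipartite, and in most of them an unlinked pair does not mean "no
association", only "not observed yet". Matrix-factorization link
prediction needs negative training samples, and treating every unlinked
pair as a reliable zero biases the model toward predicting nothing.

`fcalink` implements **negative sample selection (NSS)**: before training,
it enumerates the maximal bi-cliques of the observed network as formal
concepts (formal concept analysis, FCA), finds pairs of non-trivially
overlapping bi-cliques, and marks the node pairs in their *structural
holes* — pairs that the cluster structure itself suggests should be links —
as unsafe negatives. Negative samples are then drawn uniformly from the
unmarked unobserved pairs only, and a biased SGD matrix factorization is
trained on present links (1) plus those negatives (0).

For comparable concepts `(A_l, B_l) ⪯ (A_u, B_u)` with component sizes at
least `α` and overlap rates

    σ1 = min(|A_l|,|A_u|)/max(|A_l|,|A_u|),  σ2 = min(|B_l|,|B_u|)/max(|B_l|,|B_u|)

at least `ρ`, the structural hole is `(A_l − A_u) × (B_u − B_l)`. The
confidence score of pair `(i, j)` is `μ + b_i + b_j + p_i·q_j`, trained by
SGD on the regularized squared error. The package also ships the usual
unsupervised comparators (common neighbours, Jaccard, Adamic–Adar,
preferential attachment, random walk with restart), rank-based AUC and
average-precision AUPR evaluation, a planted-bi-clique synthetic network
generator, and a CLI. See `vignettes/negative-sample-selection.Rmd` for the
full method description.

## Worked example

Simulate a 60×80 network with six overlapping planted bi-cliques, hide the
links the structure implies, and compare MF with FCA-based negative
selection against raw MF (every unobserved pair treated as a zero):

```r
library(fcalink)

sim <- generate_planted(planted_config(seed = 7))
sim
#> planted_sim: 60 x 80, 6 blocks, 1095 target present (447 hidden)

nss <- nss_params(alpha = 3, rho = 0.3, sample_rate = 1.0, seed = 7)
res <- run_prediction(sim$input, "mf-nss", nss = nss, mf = mf_params(seed = 7))
str(res$info)
#> List of 4
#>  $ method     : chr "mf-nss"
#>  $ n_marked   : int 582
#>  $ pool_size  : int 3570
#>  $ n_negatives: int 3570

evaluate_scores(sim$truth, res$scores)
#> eval_result: AUC 0.9347, AUPR 0.8265 (447 pos / 1111 neg, universe 1558)

raw <- run_prediction(sim$input, "mf", mf = mf_params(seed = 7))
evaluate_scores(sim$truth, raw$scores)
#> eval_result: AUC 0.9081, AUPR 0.7705 (447 pos / 1111 neg, universe 1558)

head(res$scores[order(-res$scores$score), ], 3)
#>  left right     score
#>  u011  v016 0.7469829
#>  u016  v015 0.7434632
#>  u042  v038 0.7317009
```

Reading the numbers: 582 unobserved pairs sit in structural holes of
overlapping bi-cliques and are excluded from the negative pool of 3570;
trained on that pool, the model ranks the 447 hidden true links against
1111 labeled absents with AUC 0.935 / AUPR 0.827, versus 0.908 / 0.771 for
raw MF on the same split. The top-scored pairs are hole pairs of planted
blocks — exactly the links the generator hid. The sample rate is an
operating parameter: sweep it with `benchmark_planted()` /
`cmd_benchmark()` (the package's acceptance suite asserts the orderings
over five seeds at the best rate, echoing how the method is meant to be
run).

## Command line

```sh
Rscript inst/cli/fcalink simulate --out-prefix work/sim --seed 7
Rscript inst/cli/fcalink predict  --input work/sim_input.tsv --out work/pred.tsv \
        --method mf-nss --alpha 3 --rho 0.3 --sample-rate 1.0 --seed 7
Rscript inst/cli/fcalink evaluate --predictions work/pred.tsv \
        --input work/sim_input.tsv --target work/sim_target.tsv \
        --out work/metrics.json
```

Subcommands: `simulate`, `enumerate`, `select-negatives`, `predict`,
`evaluate`, `benchmark`. Edge-list TSV (2 or 3 columns), Burmeister CXT and
dense 0/1 CSV bi-adjacency formats are read and written; exit codes are 0
(ok), 2 (usage), 3 (data error), 4 (numeric failure).

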