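# sigcrf — signal peptide prediction with a grammar-constrained CRF

Signal peptides (SPs) are short N-terminal sequences that target proteins
for secretion or membrane translocation and are removed by a signal
peptidase. Five SP classes exist, defined by translocation pathway and
cleaving peptidase: Sec/SPI, Sec/SPII (lipoproteins), Sec/SPIII
(prepilins), Tat/SPI and Tat/SPII. Within an SP, three subregions underlie
function: a positively charged **n-region**, a hydrophobic **h-region**
and a polar **c-region**; Tat substrates additionally carry a conserved
twin-arginine (RR) motif and SPII substrates end in a lipobox before a
lipidated cysteine.

`sigcrf` is an R package for biologists and method developers that
predicts, for a protein sequence, (i) its SP class, (ii) the cleavage site
(CS) and (iii) the per-residue region structure — using a linear-chain
conditional random field (CRF) whose transition matrix is constrained to a
biological region grammar, on top of a small trainable sequence encoder.
The whole method — weak-supervision labeling, training, homology-aware
evaluation — runs at desk scale on one CPU with no downloads.

## The model

Per-residue hidden states `h_t` from the encoder are projected to CRF
emissions `ψ(h_t) = W_ψ h_t + b_ψ`, and the CRF models

```
P(y | h) = (1/Z(h)) · Π_t exp(ψ(h_t)[y_t]) · Π_t exp(φ[y_t, y_t+1])
```

over 41 states: per class, its region states (e.g. `N → H → C` for
Sec/SPI, `N1 → R1 R2 → N2 → H → …` for Tat, a lipobox `L1 L2 L3` for SPII,
one undifferentiated `P` state for SPIII) plus class-private mature states
`O/M/I`. Transitions violating the region order are masked to −∞, so any
decoded path is grammatical by construction. Inference uses Viterbi
decoding for the path and CS (position of the last SP state), and
forward–backward marginals for class probabilities: `p(G) = (1/T) Σ_t
Σ_{c∈G} p(y_t = c | x)`.

Training minimizes the **multitag** negative log likelihood — region
labels are rule-generated and deliberately ambiguous (`{n,h}` / `{h,c}`
at region borders), and the likelihood marginalizes over all paths
consistent with the admissible tag sets — plus a **composition
regularizer**: cosine similarities between soft per-region amino acid
score vectors (built from the marginals), pushing n/h/c towards distinct
compositions. Runs that collapse to the degenerate uniform 2-residue
n-region after one epoch are detected and aborted.

Evaluation follows the field's conventions: per-type detection MCC with
negatives either excluding (MCC1) or including (MCC2) other SP types,
class-conditional CS precision/recall with 0–3 residue tolerance windows,
Gorodkin's multiclass MCC, and performance stratified by Needleman–Wunsch
identity to the training set. Datasets are split by homology partitioning:
single-linkage clusters at 30% global identity, balanced across organism
groups, with iterative removal of cross-partition violators.

## Worked example

```r
library(sigcrf)

train <- generate_dataset(generator_config(seed = 1001))   # 600 records
res   <- sp_train(train, train_config(seed = 1))           # ~1.5 min, 1 CPU
res$status
#> [1] "ok"

q <- "MKAKSGKAKNLFLVILLASASKALPYSILPKSDIDGFKDLLYETSHQCFTIILCSEF"
p <- sp_predict(q, "GRAM_POS", res$model)
round(p$class_probs, 3)
#>     NO_SP   SEC_SPI  SEC_SPII SEC_SPIII   TAT_SPI  TAT_SPII
#>     0.000     0.938     0.061     0.000     0.001     0.000
p$predicted_class; p$cs; round(p$cs_prob, 3)
#> [1] "SEC_SPI"
#> [1] 20
#> [1] 0.892

summarize_regions(p, q, "GRAM_POS", res$model$space)
#>   region start end length hydrophobicity net_charge
#> 1      N     1   9      9     -1.2555556          4
#> 2      H    10  17      8      2.9000000          0
#> 3      C    18  20      3      0.9333333          0
```

The class probabilities are the length-normalized marginal mass of each
class's states (they sum to 1); `cs = 20` says cleavage falls between
residues 20 and 21, with `cs_prob` the marginal probability of the
CS-defining state there. The region table shows the decoded n/h/c runs
with mean Kyte–Doolittle hydrophobicity and net charge at pH 7 (the
n-region is basic, the h-region hydrophobic, as expected; this sequence
was generated as a Gram-positive Sec/SPI SP with true CS 20).

A command-line interface covers the full pipeline
(`generate | label | partition | train | crossval | predict | regions |
evaluate`), e.g.:

```sh
Rscript -e 'sigcrf::sp_cli()' generate --out train.fasta --seed 7
Rscript -e 'sigcrf::sp_cli()' train --data train.fasta --model m.json --seed 1
Rscript -e 'sigcrf::sp_cli()' predict --fasta query.fa --model m.json \
    --out pred.tsv            # no --organism flag -> UNKNOWN group token
```

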