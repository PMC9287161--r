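---
title: "Methods: grammar-constrained CRF signal peptide prediction at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grammar-constrained CRF signal peptide prediction at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sigcrf)
```

# The problem and the model

Signal peptides (SPs) come in five classes (Sec/SPI, Sec/SPII, Sec/SPIII,
Tat/SPI, Tat/SPII) that share a coarse architecture — a positively charged
n-region, a hydrophobic h-region and, for SPase-I-cleaved SPs, a polar
c-region — decorated with class-specific motifs (the Tat twin-arginine
dimer, the SPII lipobox). `sigcrf` casts joint class, cleavage-site (CS)
and region prediction as sequence labeling with a linear-chain conditional
random field (CRF) over a *region grammar*.

## State space and grammar

Each class owns its region states and a private copy of the mature states
`O` (extracellular/lumenal), `M` (membrane) and `I` (cytosolic): 41 states
in total. Private mature copies make every state map to exactly one global
class, so summing marginals over a class's states yields a proper class
probability; whether the original architecture shares mature states across
classes is not derivable from its description, and duplication is the
interpretation that keeps the global-probability computation exact.

Transitions are masked (score −∞) unless they follow the region order:

* Sec/SPI: `N → H → C`, self-loops on all three;
* Sec/SPII: `N → H → L1 → L2 → L3` — the lipobox states are fixed length,
  each with a single outgoing edge;
* Sec/SPIII: one undifferentiated `P` state;
* Tat: `N1 → R1 → R2 → N2 → H → …` with the two motif states fixed length,
  continuing as SPI (Tat/SPI) or with a lipobox (Tat/SPII);
* the last SP state exits into the class's own `O`; mature topology is
  `O ↔ M ↔ I` with `O → M`, `M → I/O`, `I → M` (a minimal secretory
  topology; `O` and `I` never touch directly).

SP classes must start in their first SP state; `NO_SP` starts in `I`, `M`
or `O`. *End states:* the grammar's source description fixes starts but
not ends; all states are allowed to end a sequence so that sequences of
every length (including length 1) are decodable for at least one class.
A decoded path is grammatical by construction; this is checked
property-style over thousands of random emission matrices.

## Inference

All lattice computations run in log space with per-step scalar shifts (and
a global shift of the transition matrix), so arbitrary finite scores are
handled without overflow; marginals of mask-unreachable states come out
exactly 0 because −∞ propagates, not a rounded small number. Viterbi ties
break towards the lowest state id at the latest differing position, making
decoding deterministic. Class probabilities are the *arithmetic mean* over
positions of the class's marginal mass — the formulation consistent with a
probability vector summing to 1 (a product over positions, which one
printed formula suggests, is not normalized and is not used). The CS is
the position of the last SP state on the Viterbi path; its reported
confidence is the marginal probability of that state at that position
(an artifact choice — the source does not define a CS confidence).

## Weak-supervision labels

There is no agreed ground truth for region borders, so training targets
are *multitag*: at each position a set of admissible states. The rules:
n-region minimum 2 residues, c-region minimum 3; the center of the
maximum-sum 7-residue Kyte–Doolittle window (ties leftmost, admissible
centers keeping n ≥ 2 and c ≥ 3 satisfiable) is h; positions between the
six fixed ones carry `{n,h}` or `{h,c}`. Tat SPs place `n` before the
leftmost admissible RR dimer (first R at position ≥ 3), two dedicated
motif states, then a single `n` position; SPII SPs have no c-region — the
last three SP positions are the lipobox and positions from the h-center to
the lipobox are `h` only (the n-rules still govern the N-terminal part;
reading "everything before the lipobox is h" literally would erase the
n-region and contradict its stated minimum length). SPIII SPs get one
undifferentiated label. Interpretations made where the rules are silent:
positions between the post-motif `n` and the h-center are filled with the
generic `{n,h}` ambiguity; for SPs of length 6 (the 7-window does not fit)
the single most hydrophobic admissible residue serves as h-center; for Tat
SPs the h-center search is restricted to start after the post-motif n
position, otherwise the layout would be unsatisfiable.

The multitag likelihood is the marginal probability of the set of paths
consistent with the tag sets (a forward pass on the lattice restricted to
`M_t`), i.e. `NLL = log Z − log Z_constrained`. The printed one-line
variant (summing emissions over true labels inside a single `exp`) is
ill-defined for transitions when `|M_t| > 1`; the constrained-lattice
marginal likelihood reduces to it exactly for singleton sets and is
validated against brute-force path enumeration.

# Encoder

The original system uses a 30-layer pretrained protein language model;
that is out of scope here and replaced by a pluggable desk-scale encoder:
learned residue embeddings (20 aa + UNK + a boundary token standing in for
start/end markers), an organism-group embedding (4 groups + UNKNOWN for
the no-organism-information mode) and a position embedding (positions
beyond 50 shared — SPs are N-terminal), concatenated over a ±3-residue
window and passed through one linear layer with tanh, D = 64. Non-standard
residues (B, Z, X, U, O, J) map to UNK and never fail. The contract —
deterministic, residue-aligned T×D output whose row t depends only on
input tokens — permits wrapping a real language model instead.

# Training

Loss = multitag NLL + α · (mean cos(score_n, score_h) + mean cos(score_h,
score_c)), where the per-region score vectors accumulate marginal region
mass by amino acid (regions pooled across classes — the rules speak of
regions, not class-specific regions), and each mean runs over the
sequences whose true class has both regions (no c-term for SPII classes;
nothing for SPIII and NO_SP; zero-norm vectors skip themselves). Cosine
similarity is scale-invariant, so normalizing the score vectors changes
nothing numerically. α defaults to 0.5 (the source treats it as a
tunable; 0 disables the term and the training log then shows exactly 0).
Because the regularizer is a function of the marginals, its gradient needs
reverse-mode differentiation *through* forward–backward; the package
implements the exact adjoint of the log-space recursions (validated
against finite differences to ~1e−9).

Optimization: Adamax, 15 epochs, batch size 32, dropout 0.1 on encoder
hidden states, slanted triangular learning rate with 10% warmup. Peak
learning rate is 1e−2 with floor 1e−4: the schedule's *shape* follows the
original recipe, but its constants were never published; finetuning-scale
peaks (1e−3) demonstrably underfit a from-scratch encoder of this size
within 15 epochs, while 1e−2 reaches the parameter-recovery targets with
margin on every seed tried. Seeded runs are bit-reproducible.

**Degeneracy guard.** With the regularizer active, training can collapse
to predicting a 2-residue n-region in every SP — compositionally cheap,
biologically implausible (2 is the minimum, not the mean). After epoch 1 a
validation slice is decoded; if the mean predicted n-region length is
≤ 2 + 0.05 (tolerance configurable; the threshold is not stated at the
source and 0.05 distinguishes "pinned at the floor" from "short but
data-driven"), the run aborts with status `"degenerate"` and must be
restarted with a new seed. The slice defaults to a prefix of the training
set — the check measures collapse, not generalization.

**Nested cross-validation.** Outer threefold over homology partitions;
for each outer test partition the two remaining partitions are train/check
and swapped (twofold inner), giving 3 × 2 models. Test sequences are
predicted only by the two models that never saw their partition. How the
models are combined is unspecified at the source; the package averages
class probabilities and marginals and re-decodes the path from the
averaged marginals under the transition mask — simple and deterministic.

# Homology partitioning

Pairwise global Needleman–Wunsch identities (BLOSUM62, gap open 11,
extend 1 — the algorithm is named but not the scoring, these are standard
protein defaults, all configurable; identity = identical aligned positions
/ alignment length including gap columns), single-linkage clustering at
the 30% threshold, greedy assignment of size-sorted clusters to 3
partitions minimizing partition size plus 0.5 × organism-group imbalance
(the balance tolerance is unquantified at the source and exposed as a
parameter), run separately per class and concatenated; then iterative
removal of the sequence with the most cross-partition violations (ties to
the smaller id — greedy-minimal data loss) until an exhaustive scan finds
no cross-partition pair above the threshold. Alignment is delegated to
`Biostrings::pairwiseAlignment`; tests validate it against an independent
hand-written Gotoh DP. On unrelated random pairs many co-optimal
alignments exist and "identity" is defined only up to the traceback's
choice among them (scores agree exactly, match counts can differ by a few
percent) — oracle identity comparisons therefore use mutated-copy pairs,
the regime the threshold actually operates in.

# Synthetic data

The generator states a world in which the method is checkable: Sec n-regions
are K/R-rich (Tat n-regions use K only, so the RR dimer is unambiguous),
h-regions are L/A/V/I/F-rich, c-regions small-polar ending in an A-x-A
motif, lipoboxes are `L[ASTV][GA]` followed by a mature-initial cysteine,
SPIII SPs are short and undifferentiated; negatives are soluble proteins
or transmembrane proteins with an internal hydrophobic stretch. Default
region lengths: n 2–10 (Tat: 2–5 + RR + 1–3), h 7–15, c 3–7, mature
20–45; 600 training and 200 test records over four organism groups
(eukaryotes receive only Sec/SPI and negatives). Composition tables are
inventions tuned so a small encoder can learn the classes — configuration,
not claims about real SP statistics. Every generated record is consistent
with the labeling rules by construction (tested at 100% over 1,000 SPs).
What a green parameter-recovery test establishes: the training machinery
can recover class structure this compositional signal encodes. What it
does not: performance on real proteomes, whose signal is weaker, longer
range and confounded (real Sec/SPI n-regions may legitimately contain RR
dimers, a deliberate residual ambiguity of the generator too).

# Numerical choices and degenerate inputs

* Lattice computations: log space, per-step scalar shifts; no allowed
  path raises an error naming the first infeasible position (for tag sets).
* Viterbi tie-break: lowest state id at the latest differing position.
* Multitag NLL clamped at 0 against last-ulp negatives.
* Histidine charge at pH 7 is 0 by default (configurable to a fractional
  charge); hydrophobicity is the *mean* Kyte–Doolittle value so regions of
  different lengths are comparable (the aggregation is unspecified at the
  source).
* The N-terminal amino-group charge (+1) applies to n-terminal regions in
  Eukarya/Archaea only — bacterial initiator methionine is formylated.
  `UNKNOWN` group is treated as formylated (no bonus charge).
* Degenerate confusion matrices (zero margin) yield MCC 0 with a warning;
  empty identity bins are absent from reports, not 0.

# Known limitations

* The encoder is a stand-in: no evolutionary context, so no claim of
  reaching language-model performance on real data.
* Identity computation is O(N²) alignments — desk scale by design.
* `predicted_class` (argmax of class probabilities) and the Viterbi path
  may rarely disagree near class boundaries; the CS always follows the
  path.
* The CS confidence and the cross-validation ensemble rule are artifact
  decisions, not reproductions.
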