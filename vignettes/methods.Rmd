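---
title: "Methods: GRU SMILES modelling, screening and contact analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GRU SMILES modelling, screening and contact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the modelling choices behind `molgru`: the
language model and its training schedule, the strict SMILES validity
policy, the tokenization scheme, the screening metric suite, the
chemical-space and contact analyses, and the problem sizes the package
is designed for.

```{r setup}
library(molgru)
```

## The generative model

The generator is an autoregressive language model over SMILES tokens:
a learned 128-dimensional token embedding feeds three stacked GRU
layers of 512 hidden units each, followed by a linear layer and
softmax over the vocabulary. Training is teacher-forced next-token
prediction under mean negative log likelihood, optimized with Adam at
an initial learning rate of 0.001, decayed multiplicatively by a
factor of 0.95 every 300 steps, with batches of 128 sequences and
global gradient-norm clipping at 5. By default each batch is a random
contiguous window over the length-sorted corpus, so sequences of
similar length are batched together and little compute is spent on
padding; `train_config(bucket = FALSE)` recovers plain uniform
sampling with replacement.

```{r}
lr_at_step(c(0, 300, 600))
```

The numerical core is implemented in C++ (RcppArmadillo) with full
backpropagation through time and float32 arithmetic. The GRU gate
layout is `[reset, update, candidate]` with the candidate computed as
`tanh(A_n + r * (H_prev %*% Wh_n))` — the convention used by the major
deep-learning frameworks, which matters when comparing checkpoints.
Correctness was established by finite-difference gradient checking and
memorization tests; all stochastic paths (batch selection, sampling)
take explicit integer seeds, so training and sampling are bit-exactly
reproducible.

Sampling is ancestral: starting from BOS, tokens are drawn from the
softmax until EOS or a length cap. Each batch reports its
`valid_fraction` — the proportion of sampled strings accepted by the
strict parser — which is the standard sanity metric for SMILES
generators.

### Transfer learning

`fine_tune_lm()` continues optimization of *all* weights on a small
focused corpus. The learning-rate schedule restarts at the initial
rate (the usual warm-start convention; the step counter for the decay
is reset) while Adam's moment estimates are retained. History rows are
tagged by phase so pretraining and fine-tuning losses can be
separated. The intended effect — shifting sampled property
distributions toward the focused set while retaining validity — is
verified end-to-end in the acceptance tests.

## SMILES validity: why the parser is strict

Generated strings must be judged by a checker that *rejects* broken
output. General-purpose toolkits often repair what they read —
OpenBabel, for instance, silently accepts `"C("` (drops the dangling
branch) and even pentavalent carbon — which would inflate
`valid_fraction` and hide model failures. `smiles_parse()` therefore
implements validity in-package:

- tokenization and syntactic checks (balanced branches, paired ring
  closures, no dangling bonds or misplaced dots);
- aromaticity: aromatic atoms must lie in aromatic rings, every
  aromatic component must admit a Kekulé structure (perfect matching,
  found by backtracking) and satisfy the Hückel 4n+2 electron count;
- valence: charge-adjusted allowed valences per element, with
  implicit-hydrogen filling; bracket atoms take their explicit H
  count and charge.

Two deliberate strictness choices go beyond some mainstream parsers:
`c1ccc1` (a four-membered "aromatic" ring — antiaromatic) and
`N(=O)=O` (pentavalent neutral nitrogen, accepted by RDKit for legacy
nitro-group notation) are both **rejected**. Nitro groups are
expressible in the charge-separated form `[N+](=O)[O-]`. For the
corpora this package generates and curates, the two conventions never
disagree.

Canonicalization, by contrast, is delegated to OpenBabel (via
ChemmineOB): it runs only on strings that already passed the strict
parser, its output is re-validated, and idempotence
(`canon(canon(s)) == canon(s)`) is tested. Validity and canonical
identity are thus decided by different engines, each used where it is
trustworthy.

## Tokenization

`smiles_tokenize()` splits on grammar-level units: bracket atoms
(`[C@H]`, `[NH3+]`) are single tokens, as are `Cl`, `Br` and
two-digit ring closures `%nn`; all other characters (organic-subset
atoms, aromatic atoms, bonds, branches, ring digits, the dot) stand
alone. Concatenating the tokens reproduces the input exactly, which
gives the encode/decode round trip:

```{r}
v <- smiles_vocabulary(c("CCO", "c1ccc(Cl)cc1", "C[C@H](N)[O-]"))
s <- "c1ccc(Cl)cc1"
identical(smiles_decode(smiles_encode(s, v), v), s)
```

The vocabulary places `<pad>`, `<bos>`, `<eos>` at indices 1–3;
they are outside the SMILES alphabet, so the tokenizer can never emit
them from text.

## Screening

`compute_descriptors()` evaluates a fixed registry of 200 graph-based
descriptors (frozen in `inst/extdata/descriptor_manifest.csv`):
whole-molecule counts, element counts, degree and hydrogen
environments, ring environments, bond-type × element-pair counts,
functional-group fragment counts, topological indices (Wiener,
Zagreb, Randić, Balaban-J, kappa shape indices, …) and topological
distance-pair counts. All are pure functions of the molecular graph,
so descriptor rows are invariant to the SMILES form of a molecule.

Five classifiers run behind one interface with fixed, conventional
hyperparameters: RBF-kernel SVM (cost 1, gamma 1/p), KNN (k = 5 on
z-scored features), Gaussian naive Bayes, random forest, and
L1-penalized logistic regression. The metric suite reports accuracy,
specificity, sensitivity, MCC, AUC, and **random accuracy** — the
expected accuracy of a chance predictor matching the observed class
and prediction marginals, i.e. the expected-agreement term of Cohen's
kappa:

```{r}
unlist(metrics_from_cm(confusion_matrix(tp = 102, fp = 49,
                                        fn = 42, tn = 451)))
```

Undefined metrics (zero denominators) are reported as `NA`, never
silently as 0. The evaluation protocol is a stratified 6:4
train/validation split repeated 10 times (`repeat_classifiers()`),
plus k-fold cross-validation. `retrospective_recall()` measures the
fraction of held-out actives rediscovered among generated strings by
canonical identity, optionally gated by a classifier's positive
predictions; it is non-decreasing in the generated set.

## Chemical space

Each molecule is summarized by seven properties (H-bond acceptors and
donors, rotatable bonds, aromatic and aliphatic ring counts,
heteroatoms, molecular weight), z-scored over the pooled sets and
embedded in 2-D with an exact t-SNE implemented in the package (the
frozen environment provides no t-SNE library): per-point precisions
calibrated to the target perplexity by binary search, early
exaggeration, momentum gradient descent with adaptive gains, seeded
initialization. Because t-SNE layouts are not metric, the
**overlap number** is computed in standardized property space: the
fraction of generated molecules whose k nearest neighbours include at
least one known molecule. The embedding is for the eye; the statistic
is independent of it.

## Contacts

A residue is "in contact" with a ligand pose when any of its heavy
atoms lies within the cutoff (inclusive, default 5 Å) of any ligand
heavy atom; hydrogens are excluded by default because docked poses
rarely have consistent protonation (an `include_h` flag exists).
`contact_frequencies()` reports, per residue, the fraction of poses in
contact; `hotspot_filter()` keeps residues with frequency strictly
above a threshold (default 50%), sorted descending. Two distance
engines — naive all-pairs and a cell-list grid — are required by the
test suite to agree exactly on random pose sets. Profile similarity
between two ligand sets is reported as a Pearson correlation over the
union of residues, as a number rather than a verdict.

## Problem sizes and scaling

The package targets desk-scale experiments on one CPU core:

- toy corpora of 10^3–10^4 molecules with 10–16 heavy atoms
  (~24 tokens per sequence); the full-size model (3×512 GRU) then
  trains at roughly 1–2 s per batch-128 step (batches are drawn as
  random windows over a length-sorted corpus by default, which keeps
  padding waste low; set `bucket = FALSE` in `train_config()` for
  pure uniform sampling), so several hundred steps — enough to exceed
  90% sampled validity on such corpora — fit in minutes;
- descriptor screening of 10^2–10^4 molecules;
- t-SNE up to a few thousand points (dense, quadratic memory);
- contact profiles of hundreds of poses against ordinary proteins
  (the grid engine is linear in atoms at fixed density).

Full-scale corpus pretraining (millions of molecules) is out of scope:
the architecture and procedures are the same, but the published
validity/recall levels attained at that scale are not claimed here.

## Limitations

- The parser is intentionally stricter than some toolkits
  (antiaromatic rings, hypervalent neutral N); corpora containing
  legacy nitro notation must be rewritten in charge-separated form.
- Pose input formats are SDF (V2000, multi-pose) and PDB; MOL2 is not
  parsed.
- t-SNE is exact, not Barnes-Hut: beyond ~5,000 points it becomes
  slow.
- Fine-tuning updates all weights; layer freezing is not implemented.
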