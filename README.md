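# molgru

An R toolkit for de novo molecular design with a GRU-based SMILES
language model, transfer learning toward a focused library, and
ligand-based screening of the generated molecules.

The package covers the full pipeline:

1. **Corpus curation** — strict SMILES validity checking,
   canonicalization, heavy-atom/length filters, blocklist exclusion,
   deduplication, tokenization, and vocabulary/encoding utilities.
2. **Language model** — a 128-dim embedding feeding 3×512 stacked GRU
   layers with a softmax head (implemented in Rcpp/RcppArmadillo with
   full backpropagation through time), Adam at lr 0.001 decayed ×0.95
   every 300 steps, batch 128; pretraining, fine-tuning on a focused
   set, and seeded ancestral sampling with validity reporting.
3. **Screening** — 200 graph-derived fragmental/topological
   descriptors, five classical classifiers (SVM, KNN, Gaussian naive
   Bayes, random forest, L1 logistic regression) behind one interface,
   the full metric suite (Acc/Spe/Sen/MCC/AUC and chance-level "random
   accuracy"), stratified 6:4 splits with repeats, k-fold CV, and
   retrospective recall of held-out actives.
4. **Chemical space** — a seven-property vector (HBA, HBD, rotatable
   bonds, aromatic/aliphatic rings, heteroatoms, molecular weight),
   an exact t-SNE embedding implemented in-package, and a quantitative
   overlap report between generated and known sets.
5. **Contacts** — per-residue occurrence frequencies of protein–ligand
   heavy-atom contacts across docked poses at an inclusive 5 Å cutoff,
   with naive and grid-accelerated engines that agree exactly,
   hotspot filtering (frequency > 50%), and profile comparison.
6. **Synthetic data** — seeded generators for a valid-SMILES toy
   corpus (graph assembly, controllable grammar features), a
   property-biased focused set, a two-class descriptor dataset with
   controllable separability, and toy protein/ligand complexes with
   known ground-truth contacts. They make every stage testable offline.

## Quick start

```r
library(molgru)

# 1. a reproducible toy corpus, curated
recs  <- gen_corpus(corpus_spec(n = 5000, seed = 1))
corp  <- filter_corpus(recs)
vocab <- smiles_vocabulary(corp$canonical)

# 2. pretrain the language model, then bias it by transfer learning
model <- gru_lm(vocab, gru_config(vocab_size = length(vocab$tokens)))
model <- train_lm(model, corp$canonical, train_config(max_steps = 300))
focus <- gen_focused(corpus_spec(n = 50, seed = 2), bias = "aromatic_rings")
model <- fine_tune_lm(model, focus$canonical, train_config(max_steps = 150))
batch <- sample_lm(model, n = 1000, seed = 7)
batch$valid_fraction

# 3. screen with descriptors + classifiers
lab <- gen_labeled(labeled_spec(n_pos = 200, n_neg = 300,
                                effect_size = 2, n_informative = 20,
                                seed = 3))
rep <- repeat_classifiers(lab$descriptors, lab$labels, n_repeats = 10)
rep$summary

# 4. chemical space overlap
emb <- chemspace_embed(c(batch$strings[smiles_is_valid(batch$strings)][1:100],
                         corp$canonical[1:200]),
                       c(rep("generated", 100), rep("known_train", 200)),
                       seed = 1)
overlap_report(emb)$overlap_fraction

# 5. contact frequencies on a toy complex
ps   <- gen_complex(8, data.frame(residue = c(2, 2, 6),
                                  distance = c(3, 4.5, 3)), seed = 4)
prof <- contact_frequencies(ps, cutoff = 5)
hotspot_filter(prof, 0.5)
```

## Command-line interface

`inst/cli/molgru.R` is a thin dispatcher over the exported functions:

```sh
Rscript inst/cli/molgru.R curate   --in raw.smi --out corpus.smi
Rscript inst/cli/molgru.R train    --corpus corpus.smi --steps 300 --out model.rds
Rscript inst/cli/molgru.R finetune --ckpt model.rds --focused focus.smi --out ft.rds
Rscript inst/cli/molgru.R sample   --ckpt ft.rds -n 10000 --seed 7 --out gen.smi
Rscript inst/cli/molgru.R screen-fit --data labeled.csv --repeats 10
Rscript inst/cli/molgru.R contacts --protein prot.pdb --poses poses.sdf --cutoff 5.0
Rscript inst/cli/molgru.R synth corpus --seed 1 -n 5000 --out toy.smi
```

## Testing and acceptance

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "molgru",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

`tests/testthat/test-acceptance.R` contains one block per acceptance
criterion (metric-suite worked example, tokenizer round trip on a
5,000-string corpus, desk-scale LM validity, transfer-learning shift,
classifier null/power contract, recall monotonicity, contact-engine
oracle equivalence, and the learning-rate schedule). The acceptance
script writes the headline quantities as a flat JSON object.

See `vignettes/methods.Rmd` for the modelling choices, parser
strictness policy, and scaling decisions.
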