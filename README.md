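# spliceppi

Quantitative machinery for studying NAD⁺-responsive neuronal alternative
splicing and the protein interactions behind it, at desk scale. The
package pairs two analysis tracks that normally require separate tool
chains:

1. **Protein–protein-interaction (PPI) screening** with a prompt-guided
   multi-task protein encoder. The encoder is pretrained under three
   weighted objectives, each steered by its own learned prompt token:
   masked-residue modelling
   (L<sub>MLM</sub> = Σ<sub>y∈Y</sub> −log q(y|h<sub>p</sub>), softmax
   over the 20-residue vocabulary), Cα-coordinate prediction
   (L<sub>CRD</sub> = MSE(Z, Kabsch(κ(h<sub>p</sub>))), mean squared
   error after optimal rigid superposition), and pair-interaction
   prediction from an attention-based pair representation
   (Attn = σ((H<sub>m</sub>W)(H<sub>n</sub>W)ᵀ/d), binary
   cross-entropy). A linear prompt-tuning module combines the task
   prompts for downstream screening; networks are split by BFS/DFS
   traversal or at random, compared by F1, and candidate interactors are
   tag-filtered and ranked with a top-k cap and a minimax consensus
   across query isoforms.
2. **Splicing and assay statistics**: percent-spliced-in (PSI/IncLevel)
   estimation from length-normalized junction reads, five-type
   alternative-splicing-event classification (ES, MES, IR, A5SS, A3SS)
   from transcript models, a binomial likelihood-ratio test with
   Benjamini–Hochberg adjustment and the |ΔPSI| > 0.1, adjusted
   p < 0.05 reporting filter, UpSet-style condition-set intersection
   with a rule language, and the three bespoke assay statistics:
   reporter splicing index (GFP/mCherry), chemotaxis index
   ((#IA − #T)/(#IA + #T + #S)) and Manders colocalization coefficients
   with ROI percentage summaries.

Seeded synthetic-data generators (planted interaction motifs, binomial
junction reads, designed channel overlap) produce every input the
pipeline consumes, so the whole analysis is reproducible and testable
without any external download. See `vignettes/spliceppi-methods.Rmd`
for the models, conventions and limitations.

## Worked example

```r
library(spliceppi)

# a planted-signal corpus: 200 proteins, 4 shared motifs
cfg <- sim_config(seed = 1, n_proteins = 200)
proteins <- gen_structures(gen_proteins(cfg), noise_sd = 0.5, config = cfg)
network <- gen_ppi_network(proteins, cfg)

split <- split_network(network, "random", test_fraction = 0.2, seed = 1)
train <- structure(list(proteins = network$proteins, pairs = split$train),
                   class = "InteractionNetwork")

model <- pretrain(list(proteins = proteins, network = train), seed = 1)
predictor <- finetune(model, train, seed = 1)
screen_f1(predictor, split$test)
#> precision 0.8888, recall 0.8567, F1 0.8725 (TP 879, FP 110, FN 147)
```

Held-out F1 of 0.87 against a positive rate of ~0.26 says the encoder
recovered the planted motif-sharing rule from sequence alone; the same
pipeline on label-shuffled edges stays near the ~0.4 all-positive
baseline.

```r
# differential inclusion between two conditions
counts <- gen_junction_reads(sprintf("e%03d", 1:200),
                             c(vehicle = 0.74, treated = 0.34),
                             depth = 500, n_reps = 3, seed = 1)
res <- run_delta_psi(counts, "vehicle", "treated")
head(filter_significant(res), 3)
#>   event psi_a psi_b  delta         p testable      padj
#> 1  e001 0.735 0.361 -0.374  1.63e-78     TRUE  1.73e-78
#> 2  e002 0.722 0.348 -0.374  4.00e-82     TRUE  4.73e-82
#> 3  e003 0.762 0.328 -0.433 2.29e-112     TRUE 6.54e-111
```

Each retained event passed both reporting thresholds
(|ΔIncLevel| > 0.1, adjusted p < 0.05); `psi_a`/`psi_b` are the pooled
per-group inclusion levels.

```r
chemotaxis_index(list(IA = 30, T = 10, S = 10))   # 0.4
manders_coefficients(gen_coloc_images(256, coloc_fraction = 0.6, seed = 1))
#>        M1        M2
#> 0.6027750 0.6011629
```

A command-line front end for the simulation, PSI and assay stages is
installed at `system.file("cli", "spliceppi-cli", package = "spliceppi")`;
every stage is byte-identical when rerun with the same seed.

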