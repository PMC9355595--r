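# mirnet

Integrated miRNA–mRNA regulatory network analysis for bud dormancy
transcriptomics.

Deciduous fruit trees arrest their floral buds each winter and release
them only after enough chilling has accumulated. Understanding which
miRNAs steer that release means combining several analyses that usually
live in separate tools: expression screening of genes and miRNAs across
dormancy stages, plant-style miRNA target prediction, degradome (PARE)
validation of predicted cleavage sites, weighted co-expression network
analysis against the bud break rate, term enrichment, and assembly of the
resulting miRNA → transcription-factor network. `mirnet` implements that
whole chain as one tested R package, aimed at analysts working on bud
dormancy or any comparable staged bulk expression design with small-RNA
and degradome support.

## What it computes

* **Small-RNA processing** — tag quality filtering (18–30 nt window,
  quality/adapter/polyA defect flags) and miRNA family assignment
  (≤ 1 mismatch or ≥ 16 nt exact overlap with a known mature miRNA).
* **Quantification and screening** — `TPM = count/total × 10⁶`;
  negative-binomial Wald screen with moderated dispersions; gene calls at
  |log2FC| > 1.5 with adjusted *P* < 0.05, miRNA calls at log2FC ≥ 1 with
  FDR < 0.05.
* **Target prediction** — duplex alignment of each miRNA (5'→3') against
  transcript windows (3'→5') with G:U wobbles scored as half a mismatch,
  screened by six conjunctive criteria: energy ratio ≥ 74%, score ≤ 4,
  ≤ 2 adjacent-mismatch pairs, no adjacent mismatches in positions 2–12,
  no mismatch at positions 10–11, weighted mismatches in 2–12 ≤ 2.5.
* **Degradome validation** — per-transcript 5'-end profiles; cleavage
  sites classified into categories 0–4 (unique maximum … single read);
  categories 0–2 kept as true targets.
* **Co-expression networks** — unsigned adjacency `|r|^β` (β = 9 genes,
  8 miRNAs), topological overlap, average-linkage modules (minimum size
  50, merge similarity 0.8), eigengenes, module–trait correlation, and
  top-0.1%-kME hub selection.
* **Enrichment** — upper-tail hypergeometric test
  `P = 1 − Σ_{i<m} C(M,i)C(N−M,n−i)/C(N,n)` with Benjamini–Hochberg FDR.
* **Network assembly** — validated DE-miRNA → TF edges inside
  trait-associated modules plus co-expression neighborhoods, exported as
  SIF / GraphML / attribute tables for Cytoscape.
* **Phenology** — chilling hours in the (0, 7.2] °C band, bud break rate,
  endodormancy release date (first observation ≥ 50%), and 2^−ΔΔCt
  relative qPCR expression.

A synthetic-data generator (`simulate_bundle()`) emulates the full study
design — 4 stages × 3 replicates, planted co-expression modules with a
trait-associated module and hubs, planted target sites with controlled
mismatch/G:U patterns, planted degradome peaks — so the entire pipeline is
testable without external data. See the methods vignette
(`vignettes/mirnet-methods.Rmd`) for the models, parameter choices, and
limitations.

## Worked example

```r
library(mirnet)
set.seed(160)

mir <- c(mir160 = "UGCCUGGCUCCCUGUAUGCCA")
# a random 1.5-kb transcript carrying one planted site: the reverse
# complement of the miRNA with a single G:U wobble opposite position 15
bg   <- paste(sample(c("A", "C", "G", "U"), 1500, replace = TRUE),
              collapse = "")
site <- strsplit(rev_comp_rna(mir), "")[[1]]
site[21 + 1 - 15] <- "U"                       # G:U wobble at position 15
tx <- c(ARF17 = paste0(substr(bg, 1, 1352), paste(site, collapse = ""),
                       substr(bg, 1374, 1500)))

preds <- predict_targets(mir, tx)
preds[, c("transcript_id", "start", "score", "mfe_ratio", "cleave_site")]
#>   transcript_id start score mfe_ratio cleave_site
#> 1         ARF17  1353   0.5  98.18182        1364
```

A score of 0.5 means the duplex carries a single G:U wobble and nothing
else; `cleave_site` is the transcript coordinate paired with miRNA
position 10, where a degradome peak is expected if the site is really
cleaved. Validating against a degradome profile and classifying the site:

```r
tags <- data.frame(transcript_id = "ARF17",
                   position = c(1364, 77, 410, 1120),
                   count = c(48, 2, 1, 3))
prof  <- build_profile(tags, "ARF17", nchar(tx[["ARF17"]]))
calls <- validate_targets(preds, list(ARF17 = prof))
calls[, c("mirna_id", "cleave_site", "score", "category", "kept")]
#>   mirna_id cleave_site score category kept
#> 1   mir160        1364   0.5        0 TRUE
```

Category 0 (the transcript-wide unique maximum of degradome signal at the
predicted position) with score ≤ 4 and clean positions 10–11 keeps the
pair as a validated target.

The whole pipeline on a synthetic bundle:

```r
res <- run_pipeline(default_config(seed = 1), "all", outdir = "run1")
res$network
#> regulatory network: 83 nodes (10 miRNA, 10 TF, 63 gene), 109 edges (10 targeting)
```

The same run is available from a shell via the launcher:

```sh
Rscript inst/cli/mirnet.R all --seed 1 --outdir run1
```

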