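# gw2drug

Genomics-driven drug repurposing from GWAS associations, as an offline,
fully testable R pipeline.

## The problem

Genome-wide association studies (GWAS) report disease-associated variants,
but turning a list of lead SNPs into actionable drug candidates requires a
chain of annotation and network steps that is usually performed by hand
against half a dozen web databases. `gw2drug` implements that chain as a
deterministic five-stage pipeline over flat-file snapshots, built around
the analysis that identified repurposing candidates for multiple myeloma
(MM), a plasma-cell malignancy:

1. **select** — keep associations at genome-wide significance
   (p < 10⁻⁸, strict boundary) and deduplicate lead SNPs per rsID
   (minimum p across studies);
2. **expand-ld** — widen each lead to its linkage-disequilibrium proxies
   (r² > 0.80, 1000 Genomes Phase 1 Asian panel by default) and collect
   the genes the proxies fall in;
3. **score** — award each gene one point per criterion met, out of six
   binary criteria: missense proxy variant, significant whole-blood
   cis-eQTL, membership in an enriched Gene Ontology biological-process /
   cellular-component / molecular-function term (upper-tail
   hypergeometric test, p < 0.05 against a 20,000-gene background), and
   primary-immunodeficiency (PID) list membership. Genes with a total
   score ≥ 2 are called *biological risk genes*;
4. **expand-ppi** — widen the risk genes one hop through a STRING-style
   protein–protein interaction edge list (combined score ≥ 400);
5. **map-drugs** — overlap the expanded gene set with a drug–target
   table and triage every candidate drug as **approved** for the disease,
   **in trial** (with its NCT registry identifiers as evidence), or
   **novel**, with precedence approved > in-trial > novel.

The enrichment statistic is the upper-tail hypergeometric probability
P(X ≥ k) for X ~ Hypergeometric(N, K, n) — drawing n query genes from a
background of N of which K carry the annotation — accumulated in
log-space so it is exact to well below 1e-12.

Because the public databases behind such analyses change continuously,
the package replaces every live query with a file adapter and ships a
synthetic-data generator (`generate_bundle()`) that emits complete,
internally consistent input bundles with *planted ground truth*, so the
entire pipeline is verifiable end-to-end without network access.

## Worked example

The published MM scoring matrix (14 genes × 6 criteria) and drug
evidence ship as fixtures:

```r
library(gw2drug)

scores <- score_genes(table1_fixture())
head(scores[, c("gencode_id", "gene_symbol", "total", "is_risk")], 4)
#>        gencode_id gene_symbol total is_risk
#> 1 ENSG00000168411       RFWD3     5    TRUE
#> 2 ENSG00000100281      HMGXB4     3    TRUE
#> 3 ENSG00000164649      CDCA7L     3    TRUE
#> 4 ENSG00000204536      CCHCR1     3    TRUE
```

All 14 genes reach the risk threshold of 2; the top four (score ≥ 3) are
RFWD3, HMGXB4, CDCA7L and CCHCR1, and only RFWD3 reaches 5. Triage of the
nine named candidate drugs against the two most promising target genes,
CAMLG and HDAC2:

```r
fx <- paper_drug_fixture()
cand <- classify_drug_status(map_drugs(c("CAMLG", "HDAC2"), fx$drug_targets),
                             fx$approvals, fx$trials)
partition_candidates(cand)$counts
#> approved_for_disease             in_trial                novel
#>                    1                    4                    4

cand[cand$status == "in_trial", c("drug_name", "targets", "evidence")]
#>      drug_name targets    evidence
#> 2   belinostat   HDAC2 NCT00131261
#> 3 cyclosporine   CAMLG NCT04813653
#> 6   romidepsin   HDAC2 NCT00765102
#> 9   vorinostat   HDAC2 NCT01502085
```

Panobinostat is the one drug already approved for MM; the four in-trial
drugs carry their registry identifiers as evidence; the remaining drugs
(theophylline, aminophylline, oxtriphylline, tixocortol) are novel
repurposing candidates.

A full synthetic run from a single configuration:

```r
bundle <- generate_bundle(generator_config(seed = 5))
paths <- write_bundle(bundle, "fixtures")
cfg <- pipeline_config(inputs = paths[names(paths) != "manifest"],
                       out_dir = "run")
report <- run_pipeline(cfg)
report$counts$n_risk_genes   # 14, matching bundle$manifest$risk_genes
```

A command-line front end with per-stage subcommands (`run`, `select`,
`expand-ld`, `score`, `expand-ppi`, `map-drugs`, `make-fixtures`) is
installed at `inst/cli/gw2drug.R`.

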