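---
title: "Methods: from GWAS associations to triaged repurposing candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GWAS associations to triaged repurposing candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gw2drug)
```

## The procedure and its assumptions

`gw2drug` operationalizes a gene-prioritization and drug-repurposing
analysis for a disease — multiple myeloma in the shipped fixtures — as a
deterministic pipeline over flat-file database snapshots. The procedure
rests on three assumptions worth making explicit.

First, that *association signal localizes to genes through linkage
disequilibrium*: a lead SNP at genome-wide significance tags a haplotype,
and any gene carrying a proxy variant in strong LD (r² > 0.80) with the
lead is a candidate causal gene. No fine-mapping, colocalization or
distance window is applied; the LD table is taken as given and never
derived from genotypes.

Second, that *functional plausibility can be scored additively*: six
binary criteria (missense proxy, whole-blood cis-eQTL, enrichment-backed
membership in GO biological-process, cellular-component and
molecular-function terms, and presence on the IUIS primary-immunodeficiency
list) each contribute one point, and a total of two or more marks a
*biological risk gene*. The criteria are deliberately heterogeneous —
coding impact, regulatory impact, pathway context, immunological prior —
and the additive score makes no attempt to weight them.

Third, that *druggability propagates one interaction hop*: risk genes are
widened through direct protein–protein interaction partners above a
confidence cutoff before overlapping with a drug–target table, because
risk genes themselves are rarely druggable.

The enrichment statistic is the upper-tail hypergeometric probability

$$P(X \ge k) = \sum_{i \ge k} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

the chance of drawing at least $k$ term members when sampling the $n$
candidate genes from a background of $N$ genes of which $K$ belong to the
term. `hypergeometric_tail()` accumulates the mass in log-space via
`lchoose()` and sums term-wise, which keeps the tail exact to well below
1e-12 across the whole small-parameter range (the test suite checks every
combination with N ≤ 60 against direct enumeration, and random larger
cases against `stats::phyper()`).

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `p_threshold` | 1e-8 | Genome-wide significance; the boundary is a strict `<`, so p = 1e-8 exactly is excluded. A `strict = FALSE` flag exposes `<=` for sensitivity runs. |
| `r2_threshold` | 0.80 | LD proxy inclusion, strict `>`; proxies at exactly 0.80 are excluded. |
| `population` | `"ASN"` | Reference-panel label matched exactly against the LD table; the default is the 1000 Genomes Phase 1 Asian panel label used by HaploReg v4.1. |
| `alpha` | 0.05 | Raw enrichment significance for the three GO criteria. No multiple-testing correction is applied by default; a Benjamini–Hochberg option (`enrich_terms(correction = "BH")`) adjusts within each category. |
| `background_n` | 20000 | Enrichment background, approximately the protein-coding gene count. Term sizes in the background come from the membership table's `term_size` column, so small shipped membership files can still represent realistically sized terms. |
| `risk_threshold` | 2 | Minimum total score for the risk call. |
| `ppi_min_score` | 400 | STRING "medium confidence" combined-score cutoff (scores live in [0, 1000]); edges at or above it count. |
| `condition` | `"multiple myeloma"` | Case-insensitive substring matched against approval and registry condition fields. |

## Design choices where the design was open

**Gene identity.** All gene-keyed joins use the Ensembl/GENCODE stable id
as the canonical key; symbol-only tables (PID list, PPI edges, drug
targets) are matched case-insensitively, with a bundle-supplied
symbol-to-id map bridging the PPI stage. Strand and coordinates play no
role: every join is on rsID or gene identifier.

**Lead-SNP deduplication.** When several studies report the same rsID,
the record with the minimum p-value is kept — the strongest evidence per
locus. Filtering and deduplication commute at a fixed threshold, which
the suite checks as a property.

**GO criterion semantics.** A gene is flagged for a category iff it
belongs to at least one term of that category enriched at raw p < `alpha`
over the candidate set. This mirrors how a DAVID-style chart report is
read (per-term enrichment over the submitted list), without reimplementing
any particular tool's modified statistic; term membership is taken as
given, with no is-a propagation over the ontology graph.

**eQTL significance.** The eQTL table carries a pre-thresholded 0/1
`significant` column; when only a numeric `fdr` column is present,
significance is derived at FDR < 0.05. The criterion is restricted to
whole-blood tissue.

**Ranking rule.** Scores are ranked by descending total, ties broken by
ascending GENCODE id, then symbol. This is the ordering of the published
scoring matrix (within each total, rows ascend by ENSG id), and it is
fully deterministic. A flag-priority tie-break was considered and
rejected: it cannot reproduce the published row order for genes with
identical flag patterns.

**Drug triage.** Status precedence is approved-for-disease > in-trial >
novel; an approval row always wins, and removing it can only demote a
drug down the chain. Name matching normalizes case and whitespace and
strips trailing salt/formulation words ("sodium", "hydrochloride", ...),
since registries routinely list salts. The trial registry table is the
sole in-trial oracle — literature-based preclinical triage is out of
scope. Drug–target links without known pharmacological action are kept
and annotated (`pharm_action_any`) rather than filtered;
`map_drugs(pharm_action_only = TRUE)` provides the strict mode.

**Self-proxies.** Every lead SNP is carried as its own proxy at r² = 1,
so a lead absent from the LD table (or with no qualifying partner) still
reaches the gene-collection stage; synthesized self-proxies have unknown
gene annotation and contribute no gene, and a warning names them.

## What the synthetic generator emulates — and what it does not

`generate_bundle()` plants a complete ground truth and then emits input
files consistent with it: significant lead p-values log-uniform on
(1e-30, 1e-9) and non-significant ones uniform on (1e-7, 1), leaving a
clean margin around the 1e-8 boundary (boundary-exact behaviour is
exercised by dedicated unit tests instead); LD blocks of high-r² proxies
around each lead plus below-threshold and wrong-panel decoy rows; planted
flag totals ≥ `risk_threshold` for risk genes and < `risk_threshold` for
all others, with per-criterion prevalences defaulting to the published
counts (11/19/4/11/5/2 of 63); one genuinely enriched term per GO
category (its members are exactly the flagged genes) plus large decoy
terms (background size N/4) that cannot reach significance; planted
interaction partners for every risk gene plus noise edges that either
fall below the score cutoff or avoid risk genes; and drugs whose
approval/registry records realize a chosen status mix, plus decoy drugs
targeting genes outside the expanded set. The generator verifies that its
planted GO flags are recoverable by the package's own enrichment before
returning, redrawing deterministically from the seed in the rare
infeasible case.

The defaults describe the study conditions of the shipped analysis
(72 significant leads out of 120 rows, 63 candidate genes, 14 risk genes,
LD blocks averaging 35 proxies, a 1/4/5 approved/in-trial/novel drug
mix). The replay and property tests use smaller configurations
(30–60 SNPs, 8–16 genes, block mean 4) so that dozens of full end-to-end
replays stay cheap; the planted-truth guarantee is size-independent.

What the generator does **not** emulate: realistic LD structure (blocks
are abstract, with no recombination or allele-frequency model), overlap
of LD blocks across loci, multi-gene proxy annotations, GO term overlap
structure, or noisy identifier mappings. Passing the planted-truth suite
therefore demonstrates that the pipeline's logic is faithful to its
contracts, not that the thresholds are well calibrated for any particular
real dataset — the published counts (2,555 proxies, 63 genes, 336 PPI
pairs) depend on database snapshots that cannot be reproduced offline.

## Numerical and degenerate-input behaviour

Strict boundaries are used exactly where stated (`p <`, `r² >`) and
inclusive ones where stated (`combined_score >=`). The hypergeometric
tail clamps to [0, 1] and returns 1 for k at or below the support's lower
end and 0 beyond `min(K, n)`. Empty inputs flow through every stage: an
association file from which nothing passes significance completes the
pipeline with all-zero counts and a warning rather than an error, an
empty risk set warns and expands to nothing, and an empty candidate table
partitions to (0, 0, 0). Readers reject malformed records fatally in
strict mode (naming the row) and count rejections in permissive mode;
row-rejection plus acceptance always reconciles with the input row count.
Reports contain no timestamps, so identical inputs and configuration
produce byte-identical output trees.

## Known limitations

- The six criteria are unweighted and the risk threshold is a blunt
  instrument; a gene with one strong coding variant scores the same as a
  gene with one marginal eQTL.
- Enrichment treats term membership as flat sets; ontology structure,
  term overlap and gene-length bias are ignored.
- One-hop PPI expansion with a global score cutoff can pull in
  promiscuous hub proteins; no centrality correction is applied.
- Drug-name matching is lexical; brand names, combination products and
  biologics with divergent naming will not match without a curated
  synonym table.
- The pipeline is only as current as its input snapshots; it performs no
  live queries by design.
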