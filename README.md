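# veriset

Self-verifying functional annotation of gene sets.

Large language models are increasingly used to name the biological process
shared by a set of genes — the narrative step after gene-set enrichment
analysis — but their raw output can assert gene functions that no curated
database supports. `veriset` implements an agent-style pipeline that makes
such claims checkable: it generates a candidate process name and an
analytical narrative, extracts every affirmative claim the output makes,
verifies each claim against expert-curated knowledge sources, and revises
the output in light of the evidence. Every external dependency — the text
backend, the text encoder, the knowledge sources — is a pluggable contract
with a deterministic offline substitute, so the whole system runs, and is
fully testable, with no network access.

It is aimed at computational biologists who want LLM-assisted gene-set
interpretation with an audit trail, and at method developers who need a
reproducible harness for studying claim verification.

## The pipeline

For a gene set `D = {g_1, ..., g_N}` with optional curated name `G`, four
stages run in fixed order:

1. **Generation** — the backend proposes an initial process name `P_ini`
   and narrative `A_ini` from the comma-separated gene list.
2. **Self-verification of `P_ini`** — a claim of the form
   "`g_1, ..., g_N` is involved in `P_ini`" is checked against enrichment
   sources (a g:GOSt-style multi-database interface and an Enrichr-style
   per-database interface, top-5 terms each). A judging backend reads the
   evidence and each claim receives a decision: *supported*, *partially
   supported*, *refuted*, *unknown* (no explicit decision in the judge's
   text), or *unverified* (no gene symbols to query with). The result is
   the report `R_P`.
3. **Modification** — `P_ini` is retained when every decision is
   supported, otherwise revised using `R_P`; the narrative follows. The
   revised narrative `A_mod` is then itself verified: one claim per
   gene–function pair mined from its sentences, checked against
   gene-centric sources (gene summaries, literature, disease / domain /
   PPI / complex interfaces, top-10 records each), yielding `R_A` — so
   the process name is verified twice.
4. **Summarization** — the final `(P, A)` are consolidated from
   `(P_mod, A_mod, R_A)`.

A masking rule prevents any database from verifying gene sets drawn from
itself (the g:GOSt-style source is removed for GO-derived sets; the
`MSigDB_Hallmark_2020` database is masked for MSigDB-derived sets). The
full trace — both reports and every backend and transport call — is kept
in the `pipeline_result`.

## The evaluation suite

Generated names are scored against ground truths with:

- **ROUGE-N** (N = 1, 2): clipped n-gram matches over reference n-grams,
  `ROUGE-N = Σ count_match(g_N) / Σ count(g_N)`;
- **ROUGE-L**: token-level longest common subsequence with
  `R = LCS/m`, `P = LCS/n`, `F_β = (1+β²)RP / (R+β²P)` (β = 1 default);
- **semantic similarity**: cosine of text embeddings under any encoder
  satisfying the contract (a deterministic hashed bag-of-words encoder
  ships for offline use);
- **background percentile**: where the name–truth similarity ranks among
  similarities to all candidate background terms;
- **hierarchical comparison**: whether the name is closer to an ontology
  ancestor of the ground truth (within 3 hops over *is_a*, *part_of* and
  the three *regulates* relations of an OBO graph) than to the truth
  itself;
- **exact-match testing** of summarized enrichment terms against
  GSEA-significant terms (p ≤ 0.05), by normalized word-multiset equality;
- **Wilson score intervals** for agreement proportions and **batch-sampled
  aggregation** (mean ± s.d. across sampled batches) for score vectors.

## Worked example

Everything below runs offline: `generate_world()` builds a synthetic
ontology, gene sets with planted process names, fixture knowledge bases
and a scripted backend transcript, all determined by the seed.

```r
library(veriset)

world  <- generate_world(seed = 1, n_terms = 30, n_genes = 120,
                         n_sets = 3, n_negative = 1)
config <- pipeline_config(scripted_backend(world$transcript),
                          fixture_registry(world$kb))
res <- run_pipeline(world$gene_sets[[1]], config)
res
#> <pipeline_result SET01>
#>   initial : ribosome remodeling dynamics
#>   modified: ribosome remodeling
#>   final   : ribosome remodeling
#>   report_p: refuted=1
#>   report_a: supported=8
```

The generation stage proposed a spurious name (`ribosome remodeling
dynamics`); verification refuted it because the enrichment sources list
`ribosome remodeling` (the planted truth) for these genes; modification
adopted the evidence; the narrative's eight per-gene claims then all
verified as supported, and the final name matches the planted truth:

```r
gt <- world$gene_sets[[1]]$ground_truth
round(rouge_scores(res$p_final$text, gt), 3)
#> rouge1 rouge2 rougeL
#>      1      1      1
pc <- background_percentile(res$p_final$text, gt,
                            background_set(world$background))
round(pc$percentile, 1)
#> [1] 96.7
round(100 * wilson_interval(124, 132), 1)  # agreement 124/132 claims
#> lower upper
#>  88.5  96.9
```

A command-line surface wraps the same functions
(`inst/cli/veriset annotate | evaluate | ontology | fixtures`); see
`veriset --help`.

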