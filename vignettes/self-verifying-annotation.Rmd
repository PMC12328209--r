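---
title: "Self-verifying gene-set annotation: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-verifying gene-set annotation: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veriset)
```

## The problem and the model

Gene-set enrichment analysis ends with a ranked list of curated terms; the
interpretive step — naming the single biological process a gene set most
plausibly acts in, and explaining each gene's role — is increasingly
delegated to large language models. Those models produce fluent but
occasionally unsupported assertions. The procedure implemented here treats
the model's output not as an answer but as a bundle of *claims*, each of
which must survive contact with expert-curated databases before it is
allowed to stand.

Formally, for a gene set $D = \{g_i\}_{i=1}^N$ the pipeline computes

$$\text{generate}(D) = (P_{\mathrm{ini}}, A_{\mathrm{ini}})
  \;\rightarrow\; \mathcal{R}_P
  \;\rightarrow\; (P_{\mathrm{mod}}, A_{\mathrm{mod}})
  \;\rightarrow\; \mathcal{R}_A
  \;\rightarrow\; (P, A),$$

where $P$ is a process name, $A$ an analytical narrative, and
$\mathcal{R}_P$, $\mathcal{R}_A$ are verification reports. Each report
entry couples one claim with the evidence retrieved for it and exactly one
categorical decision. Because $\mathcal{R}_A$ re-examines the revised
narrative, which discusses the revised process name, the process name is
effectively verified twice.

The key assumption is that a claim whose function phrase appears among the
top-ranked curated terms for its genes is trustworthy, and that a claim
contradicted or unmatched by every queried source should be revised. This
is a precision-oriented stance: it will wrongly refute genuinely novel
names whose function is absent from the databases (the cost of verifying
against curation), and it can wrongly endorse a name when an unrelated
database happens to match it.

## Claims: grammar, extraction, decisions

Claim generation is deterministic code, not a model call. One claim ties
the full gene list to the process name ("$g_1, \dots, g_N$ is involved in
$P$"); the narrative contributes one claim per gene–function pair mined
from its sentences. Sentence mining uses case-insensitive token matching
against the input set's own symbols (no alias service: symbols are taken
as given, stored verbatim, compared case-folded so human `TP53` and mouse
`Trp53` conventions coexist) and takes the function phrase as the text
trailing the first linking phrase ("is involved in", "related to", "plays
a role in", ...). A sentence naming no known symbol yields a claim with no
genes, which is marked `unverified` and triggers no query — the one
decision category reserved for structurally unverifiable claims.

The judge's free text is parsed by scanning for "partially supported",
then "refuted", then "supported", first match wins; text with none of
these parses to `unknown`. The precedence resolves the substring
ambiguity — "supported" occurs inside "partially supported" — in favour of
the more specific phrase.

## Knowledge sources, dispatch and masking

Multi-gene claims consult the enrichment sources (a pooled multi-database
g:GOSt-style interface and an Enrichr-style interface, five top terms
each); single-gene claims consult the gene-centric sources (gene summary,
literature, and disease / domain / PPI / complex interfaces, ten records
each). This arity-based dispatch is an interpretation: the procedure being
modelled says only that the appropriate interfaces are invoked, and
matching query arity to source arity is the natural reading. Each queried
source contributes at most one evidence item, truncated at its rank limit.

Masking keeps any database from verifying gene sets drawn from itself:
sets tagged `GO` lose the g:GOSt-style source entirely, sets tagged
`MSigDB` lose the `MSigDB_Hallmark_2020` database inside the Enrichr-style
source, and sets tagged `NeST` or `custom` are untouched (no rule is
defined for them). Masking soundness — no masked pair ever appears in any
evidence item — is asserted property-style over randomized configurations
in the test suite.

Live HTTP transports are deliberately not shipped: a source descriptor
carries a `fetch` function, and the packaged implementation answers from
local JSON knowledge bases. A user with network access and credentials can
supply live fetchers through the same contract; everything downstream
(masking, caching, rank truncation, logging) is transport-agnostic.
Queries are memoized within a registry, keyed by source, database and the
canonical (sorted, case-folded) gene list, so repeated claims cost one
transport call.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `temperature` | 0 | backend sampling temperature; 0 makes runs deterministic and the pipeline seed-free |
| enrichment rank limit | 5 terms | top enrichment terms retained per source |
| gene-centric rank limit | 10 records | top records per gene-centric source |
| `alpha` | 0.05 | p-value threshold defining significant enrichment terms |
| `evidence_budget` | 4000 characters | evidence digest handed to the judge/revision prompts, truncated at whole-line boundaries |
| `regenerate_narrative` | `"on_change"` | regenerate the narrative only when the process name is revised (`"always"` available) |
| ROUGE-L `beta` | 1 | recall weight in the F-measure |
| ancestor hop bound `k` | 3 | BFS depth for hierarchical comparison |
| `batch_size`, `n_batches` | 200 or 20, 9 | batch-sampled aggregation (200 suits a ~1,000-set collection, 20 a ~50-set one) |

The revision-scope default follows the narrower reading of the modelled
procedure (the narrative "is also instructed to be modified accordingly"
when the name is revised); the `"always"` option covers the broader
reading. The evidence budget exists because prompt-size limits of live
backends are unspecified; truncation respects whole lines so no term is
cut mid-way. Summarization always calls the backend (its prompt carries a
content digest of the narrative report, pinning what it saw); an empty
response falls back to the modified values, mirroring the modification
stage's degradation rule.

## Metrics: numerical choices

**Tokenizer.** One policy — lower-case, strip punctuation, split on
whitespace — is shared by ROUGE and exact-match so the metrics are
comparable; case-sensitivity conventions are otherwise unstated in the
modelled procedure, and a single explicit policy is the reproducible
choice.

**ROUGE.** ROUGE-N is recall over reference n-grams with clipped match
counts; a reference shorter than $n$ tokens makes the score undefined and
it is reported as missing, never as 0. ROUGE-L uses token-level LCS via
dynamic programming, cross-checked in tests against an exhaustive
subsequence-enumeration oracle.

**Percentile.** The background percentile uses strict greater-than-count
semantics: $100 \cdot |\{q : \mathrm{sim}(P,q) < \mathrm{sim}(P,G)\}| /
|\mathcal{Q}|$. "Position in the ranking" is ambiguous under ties;
counting ties as not-below is the conservative resolution, and ties are
reported alongside the value. The background is assembled by concatenation
without deduplication so pool sizes add exactly; a ground truth absent
from the pool is appended and flagged.

**Exact match.** A tested term matches when its normalized word multiset
equals that of some significant term — "all the words" read as word-level
equality, invariant to word order. An ordered-sequence mode is provided
for the stricter reading.

**Wilson interval.** Computed from the closed form with the two-sided
normal quantile; tests cross-check against `prop.test(correct = FALSE)`,
which implements the same interval independently.

**Ontology.** All five relation types (*is_a*, *part_of*, *regulates*,
*negatively_regulates*, *positively_regulates*) are traversed uniformly —
one hop is one edge of any type, and mixed-relation paths count — because
the modelled analysis pools term pairs across the five relationships
without weighting. Ancestors follow child-to-parent edges as encoded in
OBO. Obsolete terms load but are never traversed; cycles are rejected at
load. Ground-truth names resolve to term ids by exact case-insensitive
name match; unresolvable names are skipped and flagged rather than
guessed.

## The synthetic world

`generate_world(seed, ...)` builds every external dependency from one
seed: a toy ontology (random DAG over the five relation types), disjoint
synthetic gene sets, knowledge bases in which each set's planted process
name is the rank-1 enrichment hit (fixture p-values are rank/1000, so
significance filtering is predictable), per-gene summary entries, and a
scripted transcript recorded from a rule-based backend that derives every
response from its prompt alone: generation proposes the planted name plus
a spurious token, judgments compare the claimed phrase against the
evidence lines, revision adopts the report's top evidence term.

Negative controls are sets whose only annotating database is one the
masking rules remove, so their evidence is withheld at verification time.
The headline offline property — planted names recovered for 100% of
positive sets and 0% of controls — therefore exercises the entire
evidence path, not a lookup: a positive set recovers its name only because
verification refutes the perturbed name and revision follows the evidence.

What the world does *not* emulate: real gene symbols or term names beyond
format, correlated annotations across databases, noisy or partially
relevant evidence, judge errors, and the semantics of a trained text
encoder (the toy encoder is a hashed bag-of-words and measures lexical
overlap only). Passing the offline suite shows the machinery is correct
and deterministic; it says nothing about the biological quality of any
live backend's output, and aggregate scores obtained with the toy encoder
are not comparable to those from a trained encoder.

Test problem sizes are deliberately desk-scale: worlds of 20–40 terms,
2–10 sets, property loops of 100–120 random cases, DAGs of up to 50 nodes
— chosen so the whole suite completes in well under a minute while still
covering every code path; the generators scale up by argument if heavier
randomized testing is wanted.

## Limitations

- Verification inherits the coverage of its sources: processes absent
  from every configured database cannot be supported, biasing revision
  toward well-annotated biology.
- The claim grammar is one plausible reading of "claims generated from the
  output"; narratives phrased without linking phrases yield no narrative
  claims (they are then simply not re-verified).
- No gene-identifier mapping: misspelled or aliased symbols silently fail
  to match and reduce a claim to `unverified`.
- The shipped encoder is lexical; percentile and similarity analyses meant
  for publication should plug in a trained biomedical encoder through the
  encoder contract.
- Batch-sampled standard deviations depend on the sampler's seed; the seed
  is an explicit argument so aggregates are reproducible.
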