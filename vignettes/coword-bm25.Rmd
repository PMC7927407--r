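---
title: "Co-word augmented BM25 ranking and its Cuckoo Search tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-word augmented BM25 ranking and its Cuckoo Search tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobm25)
```

## The retrieval problem

Precision-medicine literature search starts from a structured case
description — a disease, a gene (possibly with a variant), and patient
demographics — and must rank millions of MEDLINE abstracts so that
articles discussing treatment evidence for *that disease-gene
combination* come first. Plain BM25 over abstract text underuses two
signals that such records carry: the curated term fields (chemical
substances, MeSH headings, author keywords), and the fact that an
article mentioning both the disease *and* the gene is far more likely to
be relevant than one mentioning either alone.

`cobm25` scores a document $d$ for an expanded query $Q$ with a
three-part composite,

$$\mathrm{Score}(Q,d) \;=\; \mathrm{Score}_{\mathrm{abstract}}(Q,d)
 \;+\; \mathrm{Score}_{\mathrm{word}}(Q,d)
 \;+\; \alpha\,\mathrm{Score}_{\mathrm{co\text{-}word}}(Q,d),$$

and tunes the five free parameters of this function by Cuckoo Search
against an $\mathrm{Avg}_{P@10} + \mathrm{Avg}_{nDCG}$ objective.

## The three component scores

**Abstract score.** Classic BM25 over the stop-word-filtered abstract
tokens. For each query morpheme $q_i$ (duplicates collapsed, so the
query-side frequency factor is identically 1):

$$\mathrm{Score}_{\mathrm{abstract}} = \sum_i
 \log\frac{D}{df(q_i)}\cdot
 \frac{f_i\,(k_1+1)}{f_i + k_1\left(1-b_1+b_1\,\frac{dl}{avgdl}\right)}$$

with $D$ the corpus size, $df$ the abstract document frequency, $f_i$
the within-abstract term frequency, $dl$ the abstract length and
$avgdl$ its corpus mean.

**Expanded-word score.** Each document's chemical, MeSH and keyword
terms are concatenated into a *word list* of length
$dwl = dcl + dml + dkl$. Query expansion (below) produces a set of
expanded terms; the matched-term weight of a document is the sum of
smoothed IDFs of the expanded terms present in its word list,

$$tf_{\mathrm{word}} = \sum_{q_i \in \mathrm{wordlist}(d)}
 \log\frac{N_{wl} - n(q_i) + 0.5}{n(q_i) + 0.5},$$

where $N_{wl}$ counts documents with a non-empty word list. Note that
this weight is a sum of IDFs, not an occurrence count: each matching
term contributes once regardless of repetition. The weight is then
saturated with the BM25 transfer function using its own parameters
$k_3$, $b_2$ and the word-list lengths $dwl$, $avgdwl$ (the mean over
documents that have a word list).

**Co-word score.** A gene $g_i$ of the query *co-occurs* with the
disease in document $d$ when both are detected across the four fields
(abstract, chemical list, MeSH headings, keywords). Two modes exist:
`cross` (default) accepts the disease in any field and the gene in any,
possibly different, field; `within` requires both inside the same
field, so within-matches are a strict subset of cross-matches. The
score sums a smoothed gene IDF over the matched genes, computed against
all $D$ documents (a flag switches to the $N_{wl}$ reading).

Matching is contiguous token-subsequence matching on normalized terms:
a multi-word disease name must appear as consecutive tokens, and a gene
symbol must be a whole token — `ras` never matches `kras`. Substring
matching inside tokens is deliberately not performed.

## Parameters

| parameter | role | default | search bounds |
|---|---|---|---|
| $k_1$ | abstract tf saturation | 1.2 | (0, 100) |
| $k_2$ | query-frequency factor | 1 (fixed, inert) | — |
| $k_3$ | word-list saturation | 1.2 | (0, 100) |
| $b_1$ | abstract length normalization | 0.75 | (0, 1) |
| $b_2$ | word-list length normalization | 0.75 | (0, 1) |
| $\alpha$ | co-word weight | 1 | (0, 5) |

Two presets ship with the package: `"normal"`, the conventional
empirical setting above, and `"cs"` — $k_1 = 3.59$, $k_3 = 1.3$,
$b_1 = 0.84$, $b_2 = 1$, $\alpha = 4$ — a Cuckoo-Search-optimized
setting that shifts weight onto the expanded word list and the co-word
signal. All parameters are dimensionless.

## Query expansion

A topic supplies a disease, a gene field, a demographic string and an
optional extra condition. Expansion produces four term sets:

* **abstract terms** — disease tokens, gene symbols, variant/qualifier
  tokens (V600E, Amplification, ...) and, by default, the extra
  condition; duplicates collapsed. The extra condition can be excluded
  with `include_other = FALSE` since its role in scoring is a judgment
  call rather than something the method prescribes.
* **word-list terms** — static-lexicon expansions of the disease and
  gene field, the age-band terms, the sex, and the constant `Human`.
  The lexicon is a plain two-column TSV mapping a term to MeSH-style
  expansions; a packaged example covers the classic liposarcoma /
  CDK4-amplification topic. Using a static file keeps builds hermetic —
  no web service is consulted.
* **disease terms** (disease plus its lexicon synonyms) and **gene
  terms** (symbols only) — the co-word keys. Variant tokens are
  intentionally *not* co-word keys: co-occurrence is a gene-level
  notion, and requiring the exact variant would discard most of the
  signal.

Ages map to demographic check tags through half-open bands (Newborn up
to one month, Infant to < 24 months, Preschool 2-<6, Child 6-<13,
Adolescent 13-<19, Young 19-<35, Middle age 35-<60, Aged 60-<80, Aged
80 at 80+). The Adult band (≥ 18) overlaps the finer bands on purpose,
so 38 expands to *Middle age* and *Adult*, and 18 to *Adolescent* and
*Adult*. All matching bands are returned.

## Numerical choices

* All IDF variants use the natural logarithm (one named constant). The
  base only rescales scores, and nDCG is base-invariant.
* The abstract IDF floors $df$ at 1, so out-of-corpus terms get
  $\log D$ instead of a division by zero.
* The smoothed IDFs can go negative when a term occurs in more than
  half the documents; values are kept as defined. `floor_zero = TRUE`
  gives the common clamped behavior.
* Documents without an abstract ($dl = 0$) or without a word list
  ($dwl = 0$) score 0 on the corresponding component and are otherwise
  ranked normally.
* Ties in ranking break by ascending document id; run files print
  scores at fixed 6-decimal precision, so identical runs are
  byte-identical.
* The composite decomposition
  `composite == abstract + word + alpha * coword` is an exact identity,
  not a tolerance statement.
* `rank_corpus()` and the optimizer share one code path: a per-topic
  *profile* caches everything that does not depend on the parameters
  (term-frequency matrix, IDFs, matched-term weights, co-word scores),
  so re-ranking at new parameters is vectorized arithmetic. The
  profile evaluation is tested to equal the per-document scoring
  functions to 1e-12.

## Evaluation

Per topic: P@10 (denominator fixed at 10 even for short result lists),
nDCG at the run depth with linear gains $g(\vartheta)=\vartheta$ (an
exponential-gain flag exists), R-precision, and precision / recall / F1
at the run cutoff. The ideal DCG ranks *all* judged documents of the
topic, truncated at the same depth. Averages run over the topics of the
qrels; topics missing from a run contribute 0. The co-word *coverage
rate* is the per-topic fraction of relevant documents that are co-word
documents, averaged over topics with at least one relevant document.

## Cuckoo Search

Positions are the parameter vectors $(k_1, k_3, b_1, b_2, \alpha)$;
$k_2$ is fixed at 1 and excluded. The position update is
$X^{(t+1)} = X^{(t)} + T \otimes \mathrm{Levy}(\lambda)$ with the
Mantegna construction: stable index $\beta = \lambda - 1$, giving step
lengths with tail $p(s) \sim |s|^{-\lambda}$ over the admissible range
$\lambda \in (1,3]$ (default 1.5). The displacement is modulated
per-component by $0.05\,(X - X_{best})$, as in the origin method's
reference implementation: steps shrink automatically as a nest
approaches the incumbent best, which is what enables fine convergence.
Out-of-bounds proposals are clamped to the violated boundary
(reflection was considered and rejected as needlessly complex).

Selection is elitist throughout: an egg replaces its host nest only
when fitter, and an abandonment draw (fresh uniform position, each
non-best nest with probability $P_a = 0.25$) is accepted only when
fitter. This choice was made after reference experiments on a 5-D
sphere objective (25 nests, 300 generations, 20 seeds): the
alternative — dropping eggs into random nests and replacing abandoned
nests unconditionally — keeps churning a quarter of the population and
stalls around $10^{-1}$–$10^0$ from the optimum, while the elitist
variant reaches $10^{-4}$ or better on every seed. Elitism also makes
the best-so-far trace monotone by construction, which every run
asserts.

Defaults follow the published tuning setup (40 nests, $T = 1$, 500
generations, the bounds of the table above); $P_a$ and $\lambda$ are
the standard settings of the origin method. Objective evaluations are
cached by parameter vector quantized at 1e-9 — the retrieval objective
is deterministic, so re-evaluating a visited point is wasted work.

## The synthetic collection generator

Testing a retrieval pipeline hermetically needs corpora whose relevance
structure is known. `synth_config()` / `write_collection()` generate:

* documents with Poisson field lengths around means 77.5 (abstract),
  3.8 (chemical), 10.5 (MeSH), 4.1 (keywords) and field-presence rates
  0.49 / 0.92 / 0.15 — the shape of large MEDLINE-scale
  precision-medicine corpora; vocabulary is Zipf-distributed (exponent
  1.1) over synthetic symbols;
* a planted subset (`coword_fraction`, default 0.15) carrying a
  disease-gene pair, placed inside one field or across two fields with
  probability `same_field_prob`, so cross and within detection modes
  are distinguishable;
* a further `partial_fraction` (default 0.25) of documents mentioning
  only one side of a pair, emulating the many articles that discuss a
  disease without the queried gene — without them every preset ranks
  identically because only fully planted documents match anything;
* topics naming the planted pairs with sampled age and sex, and graded
  qrels in which $P(\text{relevant}) = $ `base_relevance` (0.02) plus
  `coword_boost` (0.35) when the document actually contains both the
  topic's disease and gene; relevant documents draw grade 2 with
  probability 0.4, else 1.

The generator does **not** imitate real biomedical language: tokens are
synthetic symbols, list terms are random 1-2 token strings, there is no
MeSH hierarchy, no titles, and no correlation between abstract content
and list fields beyond the plants. Passing tests therefore demonstrate
that the *mechanics* — parsing, statistics, scoring algebra, metric
arithmetic, optimizer behavior — are correct, and that the method
recovers planted co-word structure; they say nothing about retrieval
quality on real MEDLINE text.

## Problem sizes used by the test suite

The suite checks the scoring algebra against an independent
straight-line transcription on fifty random corpora of up to 200
documents; metric implementations against an independent evaluator on
fifty random run/qrels fixtures; optimizer convergence on a 5-D sphere
across ten seeds (25 nests, 300 generations); and co-word parameter
recovery on 500-document, 10-topic collections across five seeds with a
reduced search (15 nests, 50 generations). The acceptance script uses a
1000-document, 10-topic collection. These sizes keep a full run
comfortably on one core while leaving every property statistically
meaningful.

## Known limitations

* The word-list match is exact term equality after normalization; a
  lexicon expansion that differs from the indexed heading by one word
  ("middle age" vs "middle aged") only matches if both forms are
  provided. Shipping both in the lexicon is the intended usage.
* The matched-term weight is a sum of IDFs, as the method defines it;
  occurrence counts in the word list never enter. A `tf`-weighted
  variant was considered and left out to keep the scoring function as
  specified.
* Coverage, like any per-topic average, is unstable for topics with
  very few relevant documents; such topics are excluded (with a
  warning) only when they have none.
* The optimizer offers no stopping rule beyond the generation cap; the
  trace lets users judge convergence.

## A minimal session

```{r example, eval = FALSE}
dir <- tempfile()
write_collection(synth_config(n_docs = 300, n_topics = 5), seed = 42, dir)

index   <- build_index(parse_medline_xml(file.path(dir, "corpus.xml")))
topics  <- read_topics(file.path(dir, "topics.xml"))
qrels   <- read_qrels(file.path(dir, "qrels.txt"))
queries <- lapply(topics, build_expanded_query)

run <- do.call(rbind, lapply(queries, rank_corpus, index = index,
                             params = params_preset("cs"), top_k = 300))
evaluate_run(run, qrels, z = 300)

tuned <- optimize_params(index, queries, qrels,
                         cs_config(n = 15, max_generation = 30, seed = 1),
                         top_k = 300)
tuned$params$alpha
```
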