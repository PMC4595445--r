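---
title: "Passage-based bibliographic coupling: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passage-based bibliographic coupling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbcouple)
```

## The problem

Given a full-text scientific article $r$ (the *target*), rank a pool of
candidate articles so that the ones *highly related* to $r$ — sharing its
research goal, methods and findings, in the way articles curated for the
same gene–disease association do — come out on top. Plain bibliographic
coupling (BC) scores a candidate by the overlap of cited works,

$$\mathrm{BC}(d_1, d_2) = \frac{|O_{d_1} \cap O_{d_2}|}{|O_{d_1} \cup O_{d_2}|},$$

where $O_d$ is the set of works $d$ cites. Its weakness is that two highly
related articles may cite *different* works that are all about the same
issue, leaving $O_{d_1} \cap O_{d_2}$ empty. The passage-based measure
(PBC) implemented here repairs this by comparing not the cited works
themselves but the *text the citing authors wrote about them*.

## The model

**Context passages.** For a reference $c$ in article $d$, the context
passage is the set union of $d$'s title tokens with, for every place $p$
where $c$ is cited, the $\alpha$ tokens immediately preceding $p$:

$$\mathrm{CP}(c, d) = \{\text{title tokens of } d\} \cup
  \bigcup_{p} \{\alpha \text{ tokens before } p\}.$$

Everything is computed on the stopword-removed token stream; the window may
cross sentence and section boundaries and truncates at the document start.
A reference that is listed but never cited in the body gets a title-only
passage (the formulas must be total; this is the empty-union case).

**Reference-pair similarity.** Two references score

$$\mathrm{LinkSim}(c_1, d_1, c_2, d_2) =
  \begin{cases} 1 & \text{if } c_1 = c_2\\
  \dfrac{|\mathrm{CP}_1 \cap \mathrm{CP}_2|}{|\mathrm{CP}_1 \cup \mathrm{CP}_2|} & \text{otherwise,}
  \end{cases}$$

so an identity match is a perfect link and everything else falls back to
passage overlap. Identity is resolved as PMID, else DOI, else a lowercase
alphanumeric normalization of the citation string; unresolved identities
never compare equal. The score is weighted by citation importance,

$$\mathrm{LinkSimIMP} = \mathrm{LinkSim} \times
  \frac{\mathrm{IMP}(c_1, d_1) + \mathrm{IMP}(c_2, d_2)}{2},$$

with three interchangeable importance strategies: *frequency* (2 if the
reference is cited at least twice, else 1 — the canonical choice),
*position* ($1 + \max_p p / \mathrm{Length}(d)$, so a document-final
citation scores 2), and *section* (2 if any mention falls in or after the
first section whose title contains "result", case-insensitively).

**Article-level score.** Each reference is matched with its best-scoring
counterpart in the other article, in both directions:

$$\mathrm{PBC}(d_1, d_2) = \frac{\sum_{c_1 \in O_1} \max_{c_2 \in O_2} \mathrm{LinkSimIMP}
 + \sum_{c_2 \in O_2} \max_{c_1 \in O_1} \mathrm{LinkSimIMP}}{|O_1| + |O_2|} \in [0, 2].$$

If either article cites nothing, the score is 0, the same convention BC
uses for two empty reference sets. The two ablation variants keep this
aggregation and the importance weighting but restrict the pair score:
*link-only* uses just the identity branch (with uniform importance it
collapses, provably, to the Dice coefficient of the reference-identity
sets — a closed-form limit the tests assert), and *text-only* always uses
the passage Jaccard. For identical citations the text-only variant returns
the Jaccard term literally rather than 1; that is the plain reading of
"use only the lower branch", and it keeps the variant a pure ablation.

**Baselines.** Besides BC, the package implements a BM25-based similarity
("OK"): the sum over shared terms of the product of the two BM25
saturation factors and $\log_2(N/n)$, with $k_1 = 8$ and $b = 1$, in a
title+abstract and a whole-article field view sharing one code path. A
further published hybrid baseline whose formula is defined in other work is
deliberately *not* reimplemented; recorded scores for it can be evaluated
through the recorded-similarity loader or the `external` measure plug-in.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 10 tokens | context-window length before each mention; about one commenting sentence. 10–20 works; the section-based variant prefers 15 (`alpha_section`). |
| `k1` | 8 | BM25 term-frequency saturation. |
| `b` | 1.0 | BM25 length normalization (full normalization). |
| `gerund_min_stem_length` | 3 chars | guard so "ring"/"king" are not treated as gerunds. |
| `ties` | `"rank"` | AP tie handling; `"pessimistic"` charges a relevant item for every score-tied competitor. |

Collection statistics for the OK measures ($N$, $n$, $avgdl$) are computed
over the evaluation corpus itself (all targets and candidates). A global
background collection would be equally defensible; corpus-local statistics
make runs self-contained and reproducible, and the choice is isolated in
`build_corpus_stats()`.

## Preprocessing

Tokenization splits on non-alphanumeric boundaries (unigrams only, no
phrases). Each word is normalized by stripping a trailing possessive
*'s*, lowercasing, stripping *-ing* when at least three stem characters
remain, and stripping one trailing *-s* unless the word ends in *-ss*. The
suffix rules are iterated to a fixpoint so stacked suffixes resolve in one
call ("meetings" → "meet") and normalization is idempotent — a single pass
would not be. A word is discarded as a stopword if either its surface form
or its normalized form is on the list; the surface check matters because
inflected function words ("has") normalize off the list. The shipped list
is a standard closed-class English function-word list
(`inst/extdata/stopwords_en.txt`); ranking quality is mildly sensitive to
the stopword list, so exact reproduction of any run requires holding the
shipped file fixed, and the list is a config parameter rather than a
constant.

## Reading JATS full text

In-text citations are recognized from typed cross-reference elements; the
marker text (the bibliography number) never enters the token stream, and a
mention's position is the number of body tokens preceding the marker —
equivalently, the index of the first token after it, which may equal the
body length for a document-final citation. Grouped markers like "[3,4]"
give both references the same position, since both share the same
commenting text. Markers inside tables, figures and captions are not
counted as mentions: such mentions have no running-text context, and
float placement is layout-dependent, so only body paragraphs count. The
α-window deliberately does not skip tokens of an immediately preceding
citation cluster; those tokens are part of the discourse the authors
placed before the citation, and skipping them would require sentence
segmentation the model otherwise avoids.

## Evaluation harness

Per topic, average precision is $\frac{1}{k}\sum_{j=1}^{k} j/\mathrm{Arc}(j)$
with $\mathrm{Arc}(j)$ the rank of the $j$-th relevant item after
deterministic tie-breaking (descending score, then ascending id — so runs
are byte-reproducible). Relevant articles a system never scored are
appended after all scored candidates in ascending id order, i.e. ranked
lowest. MAP averages AP over topics; average P@X and the fraction of
topics with P@X > 0 are reported for X ∈ {1, 3, 5}. System pairs are
compared with two-sided paired t-tests at the 95% level on the per-topic
vectors; an all-zero difference vector reports $p = 1$ (no evidence of a
difference), and a constant non-zero difference — zero variance, where the
t statistic is undefined — reports $p = 0$ with a `degenerate` flag rather
than an error, so whole-benchmark sweeps never abort on a pathological
pair.

## The synthetic benchmark

`generate_corpus()` plants the structure the measures are meant to
recover: each topic is a cluster (one target plus three highly related
candidates, about what expert curation yields per gene–disease pair)
padded with 30 near-miss candidates. Each cluster owns a disjoint content
vocabulary split into two halves playing the roles of the gene and disease
terms; cluster members draw titles and context windows from the whole
vocabulary, near-miss articles from one half only (they "mention g or d
but not both") plus a shared common block. `p_shared_reference` controls
how often a member's reference comes from the cluster's reference pool
(hence can coincide with another member's), and `passage_overlap` controls
the fraction of window tokens drawn from cluster vocabulary rather than
article-private filler. Candidate ids are assigned by a seeded permutation
so lexicographic tie-breaking cannot correlate with relevance. All
randomness flows from the single config seed through a local RNG that is
restored afterwards; generation is a pure function of the config.

Two regimes reproduce the motivating scenarios as statistical properties:
with `p_shared_reference = 0` and high `passage_overlap`, BC is blind
(every pair scores 0) while PBC still separates clusters, so
MAP(PBC) > MAP(BC); with the regime reversed, the integrated measure is at
least as good as its text-only component.

What the generator does **not** emulate: real scientific prose (tokens are
synthetic symbols, so no polysemy, no term burstiness, no section-specific
style), realistic reference-count and citation-frequency distributions
(every article cites 10 works here, versus ~44 on average in real PMC
corpora), abstracts that summarize the body, or the expert curation
process behind real relevance labels. Passing the synthetic benchmarks
therefore shows the machinery is correct and the measures behave as
designed under controlled overlap, not that the measured MAP values
transfer to real literature; real-corpus quality also depends on the
stopword list and on JATS citation-markup quality. Benchmark sizes in the
tests and the acceptance script (20 topics, 34 articles per topic, 10
references per article) are the package's chosen desk-scale study
conditions; they keep a full multi-measure evaluation under a minute while
leaving enough topics for paired significance tests to be meaningful.

## Numerical conventions and degenerate inputs

* All token indices are 0-based; spans are half-open. Mention positions lie
  in $[0, L]$ inclusive (a position is "tokens before the marker").
* $0/0$ cases are pinned: Jaccard of two empty passages is 0, BC of two
  empty reference sets is 0, PBC with an empty reference list on either
  side is 0.
* Pairwise PBC scores and per-article reference profiles are memoized in an
  explicit cache keyed by unordered article pair, α and variant; repeated
  queries return identical values and the cache is semantically invisible.
* Ranking ties always break by ascending candidate id; every output file
  is byte-stable under reruns.

## Known limitations

* Only backward context windows are modeled; commenting text after a
  citation is ignored by design.
* Citation recognition requires numbered/typed cross-references (JATS);
  plain-text or PDF citation recognition is out of scope.
* The frequency importance is a coarse two-level weight; truly important
  references cited once are underweighted.
* `load_s1_run()` expects its documented tabular layout and fails loudly on
  anything else; extracting a supplementary archive into that layout is an
  external step.
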