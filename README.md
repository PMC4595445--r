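# pbcouple

Passage-based bibliographic coupling for biomedical full-text articles.

Given a target article *r*, the package ranks candidate articles by how
*highly related* they are to *r* — sharing its research goal, methods and
findings, the way articles that experts select to curate the same
gene–disease association are related to each other. Plain bibliographic
coupling,

    BC(d1, d2) = |O_d1 ∩ O_d2| / |O_d1 ∪ O_d2|,

with `O_d` the set of works `d` cites, fails exactly when two highly
related articles cite *different* works about the same issue. The
passage-based measure (PBC) implemented here integrates the citation link
with the **context passage** of each reference `c` in `d` — the title of
`d` plus the α tokens immediately before every place `c` is cited:

    CP(c, d)     = {title of d} ∪ ⋃_p {α tokens before p}
    LinkSim      = 1 if c1 = c2, else |CP1 ∩ CP2| / |CP1 ∪ CP2|
    LinkSimIMP   = LinkSim × (IMP(c1,d1) + IMP(c2,d2)) / 2
    PBC(d1, d2)  = [Σ_{c1∈O1} max_{c2} LinkSimIMP + Σ_{c2∈O2} max_{c1} LinkSimIMP]
                   / (|O1| + |O2|)        ∈ [0, 2]

where the importance weight `IMP` is 2 for references cited at least twice
and 1 otherwise (position- and section-based alternatives are included, as
are the link-only and text-only ablations). Baselines: BC and a BM25-based
similarity ("OK", k1 = 8, b = 1) over title+abstract or whole-article
fields. The evaluation harness computes average precision, MAP, average
P@X, the fraction of topics with P@X > 0, and pairwise two-sided paired
t-tests.

The package also ships

* a JATS/NXML reader (typed `xref` bibliography markers, PMID/DOI identity
  resolution, abstract and section spans),
* a documented JSON corpus dialect and TSV qrels/run formats,
* a loader for recorded-similarity tables (eight measures per candidate,
  the layout used for archived study runs),
* a synthetic citation-corpus generator with planted related-article
  structure, so the whole pipeline is testable without any download,
* a command-line interface (`inst/cli/pbcouple.R`) with subcommands
  `synth`, `ingest`, `rank`, `eval`, `s1-eval`.

## Worked example

Generate a 6-topic synthetic benchmark (each topic: one target, 3 highly
related articles built on the topic vocabulary, 20 near-miss articles that
use only half of it), rank with three measures, and evaluate:

```r
library(pbcouple)

cfg <- synth_config(n_topics = 6, n_near_miss = 20, seed = 42)
gen <- generate_corpus(cfg)
gen$corpus
#> <pbc_corpus> 144 articles

runs <- rank_all_topics(gen$corpus, gen$qrels,
                        measures = c("PBC", "BC", "OK-WholeArticle"))
head(runs$PBC[[1]]$ranking, 4)
#>   candidate_id     score rank
#> 1     T01-c001 0.5266835    1
#> 2     T01-c005 0.4521548    2
#> 3     T01-c017 0.4369905    3
#> 4     T01-c003 0.2818027    4

report <- evaluate_runs(unlist(unname(runs), recursive = FALSE), gen$qrels)
report
#> Ranked-retrieval evaluation over 6 topics
#>
#>          measure    map avg_p_at_1 hit_at_1 avg_p_at_3 hit_at_3 avg_p_at_5 hit_at_5
#>              PBC 0.8880     1.0000   1.0000     0.8333        1     0.5333        1
#>               BC 0.6551     1.0000   1.0000     0.5556        1     0.3333        1
#>  OK-WholeArticle 0.9042     0.8333   0.8333     0.8889        1     0.5667        1
#>
#> Significant paired differences (p < 0.05): 4 of 12 tests
```

The three top-ranked PBC candidates for topic 1 are exactly the three
planted highly related articles (`gen$qrels$topics$topic01$highly_related_ids`
is `T01-c017, T01-c005, T01-c001`). The `map` column is the mean over
topics of average precision; `avg_p_at_X` is precision in the top X
averaged over topics; `hit_at_X` is the fraction of topics with at least
one relevant article in the top X. Here PBC beats BC on MAP (0.888
vs 0.655) because many related pairs share commenting vocabulary but not
references; the paired t-test on per-topic AP puts that difference at
p ≈ 0.014.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/pbcouple.R synth --seed 42 --n-topics 6 \
    --out-corpus corpus.json --out-qrels qrels.tsv
Rscript inst/cli/pbcouple.R rank --corpus corpus.json --qrels qrels.tsv \
    --measure PBC --alpha 10 --out run-pbc.tsv
Rscript inst/cli/pbcouple.R eval --run run-pbc.tsv --qrels qrels.tsv \
    --x 1,3,5 --out report.json
```

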