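# collabflow

Institution-level network analysis of bibliographic corpora, for
scientometric studies of collaborative research — the motivating use case
is mapping how academic and industrial institutions collaborate and how
knowledge flows between them during drug discovery (e.g. the literature
around a drug target such as PCSK9 and its inhibitors).

Given a corpus of papers — each with a publication year, a deduplicated
set of institutional affiliations, author ids, referenced paper ids and
topic tags — the package builds two institution-level networks:

- **Collaboration network** (undirected): nodes are institutions; the
  weight `w_ij` of edge `{i, j}` counts the papers on which institutions
  `i` and `j` co-appear (one increment per paper per unordered pair).
- **Knowledge-flow network** (directed): an edge `u -> v` counts the
  citation cases in which a paper affiliated with `v` cites a paper
  affiliated with `u` — knowledge moves from the cited toward the citing
  institution. Self-loops `u -> u` measure within-institution flow.

On top of these it computes the standard summary indices of such
networks:

- weighted degree `s_i = Σ_j w_ij`;
- **industrial participation**
  `Σ_{i or j ∈ Corporates} w_ij / Σ_{i,j} w_ij`, the share of link weight
  on edges touching at least one corporate institution (each edge counted
  once);
- **weighted average clustering**, the mean over all nodes of the
  geometric-average triangle statistic
  `C_i = (1 / k_i(k_i−1)) Σ_{j,k} (ŵ_ij ŵ_ik ŵ_jk)^{1/3}` with weights
  normalized by the graph maximum;
- **weighted-degree assortativity**, the Pearson correlation of `(s_i,
  s_j)` across the two ends of every edge (symmetrized);
- **top-share concentration**, the minimal fraction of institutions,
  ranked by weighted degree, whose degrees cumulate to ≥ 90 % of the
  total;
- **internal-dissemination fractions** of the flow network: overall and
  per-institution shares of citation flow that stay inside an
  institution;
- the fraction of papers with inter-institutional collaboration, and
  annual publication/citation series with optional self-citation
  exclusion (shared-institution or shared-author definition).

A synthetic-corpus generator (`generate_corpus()`) with Zipf-like
institutional activity, planted industrial shares and preferential
citation attachment makes the whole pipeline testable without access to
any bibliographic database, and `fig1_corpus()` provides the classic
three-paper worked example.

## Worked example

Paper I (institutions *a*, *b*) cites paper II (*c*, *d*, *e*) and
paper III (*c*, *d*):

```r
library(collabflow)
corp <- fig1_corpus()

g <- build_collaboration(corp)
g$edges
#>   a b weight
#> 1 a b      1
#> 2 c d      2
#> 3 c e      1
#> 4 d e      1

f <- build_flow(corp, collect_citations(corp, c("II", "III")))
f$edges
#>   from to weight
#> 1    c  a      2
#> 2    c  b      2
#> 3    d  a      2
#> 4    d  b      2
#> 5    e  a      1
#> 6    e  b      1
```

Institutions *c* and *d* co-appear on two papers, hence `w{c,d} = 2`;
every other pair co-appears once. Both citations flow out of *c* and *d*
(weight 2 toward each of the citing institutions *a* and *b*) and one
out of *e* (weight 1). The one-row index report for this corpus:

```r
smap <- sector_map(c(a = "academic", b = "academic", c = "industrial",
                     d = "academic", e = "academic"))
compile_index_report(corp, corpus_ids(corp), s = smap)
#>  n_papers n_authors n_institutions frac_inter_institutional frac_industrial
#>         3         7              5                        1             0.6
#>  avg_clustering assortativity frac_top_90
#>       0.3779763     0.6363636         0.8
```

All three papers are multi-institutional (`frac_inter_institutional =
1`); the two edges touching the one industrial institution *c* carry 3
of the 5 weight units (`frac_industrial = 0.6`); the triangle *c–d–e*
gives the three central nodes clustering `(1·0.5·0.5)^{1/3} ≈ 0.63` and
the five-node average 0.378; and 4 of the 5 institutions are needed to
cover 90 % of the total weighted degree (`frac_top_90 = 0.8`).

`run_pipeline()` chains all of the above — tag selection, citation
collection, both projections, annual series with and without
self-citation exclusion, index report, flow fractions, ranked edge
tables — and writes plain-text artifacts plus a JSON manifest.

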