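---
title: "Methods: institutional collaboration and knowledge-flow networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: institutional collaboration and knowledge-flow networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collabflow)
```

## The model

collabflow analyses a tagged bibliographic corpus at the level of
institutions. The unit of observation is the paper: an id, a publication
year, and the deduplicated sets of institutional affiliations, author
ids, referenced paper ids and normalized topic tags. Everything the
package computes is a deterministic function of these per-paper sets.

Two projections are derived from a selected (core) set of papers.

**Collaboration network.** For every paper, every unordered pair of
distinct institutions in its institution set increments the weight of
that pair's edge by exactly one — one increment per paper per pair, no
matter how many author pairs span the two institutions. A paper with
$k$ institutions therefore adds exactly $\binom{k}{2}$ units of edge
weight, and the network's total weight is
$\sum_p \binom{|I_p|}{2}$ — an invariant asserted in the test suite.
Single-institution papers contribute an (isolated) node; papers with no
recorded affiliation contribute nothing to the network but are retained
in the corpus and counted, since silently dropping them would bias the
paper-level statistics (their number is logged on the corpus).

**Knowledge-flow network.** Citations whose cited end lies in the core
set are collected over the whole corpus. For each citation pair, each
(cited-institution, citing-institution) combination increments the
directed edge cited → citing by one, so total flow equals
$\sum_{\text{pairs}} |I_{cited}|\,|I_{citing}|$ (the second conservation
invariant). The direction encodes knowledge moving from the cited
institution toward the one that cites it. Self-loops are retained: they
are the signal behind the within-institution flow fractions. The
collaboration network, in contrast, forbids self-loops — co-membership
of one institution on one paper is not an edge.

## Indices

All indices operate on the whole weighted collaboration network,
including isolated institutions.

- **Weighted degree** $s_i = \sum_j w_{ij}$.
- **Industrial participation**: the share of total link weight on edges
  with at least one corporate endpoint,
  $\sum_{i\,\text{or}\,j \in \text{Corporates}} w_{ij} / \sum_{i,j} w_{ij}$.
  The numerator counts each qualifying edge once, also when both
  endpoints are corporate — an inclusive-or read that keeps the
  fraction in $[0,1]$ and makes it monotone under relabeling an
  academic institution as industrial (a tested property).
- **Weighted average clustering**: the geometric-average-of-edge-weights
  form. With $\hat w = w / \max_{edges} w$,
  $$C_i = \frac{1}{k_i(k_i-1)} \sum_{j,k}
    (\hat w_{ij}\,\hat w_{ik}\,\hat w_{jk})^{1/3},$$
  where $k_i$ is the number of neighbours and the sum runs over ordered
  neighbour pairs. Nodes with $k_i < 2$ have $C_i = 0$ and are included
  in the unweighted mean over all nodes, so one number summarizes the
  whole network. Normalizing by the global maximum makes the statistic
  invariant under uniform rescaling of all weights (tested to 1e-12).
- **Weighted-degree assortativity**: each edge contributes the two
  symmetric ordered pairs $(s_i, s_j)$ and $(s_j, s_i)$, and the index
  is the plain Pearson correlation over that pair list. Edges are not
  weight-weighted: the definition correlates weighted degrees across
  linked nodes, nothing more. When all endpoint degrees are equal the
  correlation is undefined and the package reports `NA` — an explicit
  not-applicable marker, never 0, since 0 would assert "no mixing
  preference" that the data cannot support.
- **Top-share concentration**: institutions ranked by weighted degree
  (descending, ties broken lexicographically by id so runs are
  deterministic); the index is $m/N$ with $m$ the smallest prefix whose
  cumulative degree reaches the share threshold (default 0.9) of
  $\sum_i s_i$ and $N$ the total node count including isolated nodes.
  The comparison uses a relative tolerance of $10^{-9}$ of the total so
  that an exact hit (e.g. uniform degrees, where the closed form is
  $\lceil 0.9N \rceil / N$) is not missed to floating-point rounding of
  `0.9 * total`.
- **Flow fractions**: overall internal flow is self-loop flow over
  total flow; an institution's internal-dissemination fraction is its
  self-loop flow over its total out-flow (all citations of its papers).
  The out-flow denominator makes the per-institution number answer "of
  the citations my papers receive, how many did I generate myself?";
  the overall fraction is then exactly the out-flow-weighted mean of
  the per-institution fractions. Institutions with no out-flow are
  omitted rather than reported as 0/0.
- **Inter-institutional collaboration fraction**: the share of selected
  papers whose institution set has size ≥ 2, with empty-affiliation
  papers in the denominator. This is a paper-level definition; an
  author-pair-level alternative would need author–affiliation links
  that the data model deliberately does not carry.

## Self-citations and time series

Annual publication counts use the core papers' years; annual citation
counts attribute each citation pair to the year of the *citing* paper,
since a citation accrues when it is made. "Self-citation" has no single
accepted definition at the institution level, so both are implemented
and exposed as a flag: shared-institution (default, consistent with
institution-level networks) and shared-author. Exclusion removes the
flagged pairs before counting; by construction every excluded-count is
dominated by the unexcluded one, and the difference equals the number
of excluded pairs — both tested. Citation pairs whose citing paper has
no affiliations still count in the time series although they add no
flow edge: trajectories and networks answer different questions.

## The synthetic generator

The generator exists so that every stage of the pipeline can be
exercised, and its parameter effects recovered, without any database
access. It emulates four features of real bibliometric data:

- **Heavy-tailed institutional activity**: institution $r$ (by rank) is
  drawn with probability $\propto r^{-\alpha}$
  (`institution_activity_exponent`). At $\alpha = 0$ activity is
  uniform; growing $\alpha$ concentrates collaboration weight on few
  institutions, which the top-share index must detect (median top-share
  strictly decreasing over $\alpha \in \{0, 0.8, 1.6\}$ across 10
  seeds — a tested recovery property).
- **A planted industrial share**: each institution is labeled
  industrial with probability `industrial_share`; the measured
  industrial participation must increase with the planted share
  (second recovery property, over $\{0.1, 0.3, 0.5\}$).
- **Multi-institution papers with nested authors**: per-paper
  institution and author counts follow bounded skewed integer
  distributions (`dist_spec(min, max, skew)`, mass
  $\propto (v-\min+1)^{-skew}$); authors are drawn from per-institution
  pools, so author ids are nested within institutions.
- **Preferential, time-ordered citation**: references go to strictly
  earlier-year papers with probability $\propto (1+c)^\beta$ where $c$
  is the target's citations so far (`citation_attachment_exponent`).
  $\beta = 0$ is exactly uniform (verified by a chi-square
  goodness-of-fit on ~10,000 draws); $\beta > 0$ concentrates citations
  on early/highly cited papers. Papers that request more references
  than there are earlier papers are truncated and logged, never an
  error. The strict time ordering keeps annual citation series
  well-defined and the citation graph acyclic.

Defaults describe a mid-sized single-target literature: 500
institutions, 5,000 papers over 20 years (1998–2017), 1–5 affiliations
and 1–8 authors per paper skewed toward small counts, up to 10
within-corpus references per paper, activity exponent 1 (a Zipf law),
attachment exponent 1 (linear preferential attachment), 20 % industrial
institutions. The recovery and acceptance checks run at exactly these
sizes (10 seeds per planted value).

What the generator does *not* emulate: real affiliation noise and
disambiguation errors, author name ambiguity, topic drift, citations
arriving from outside the corpus, or any fitted resemblance to a real
database. Passing tests therefore demonstrate that the *operations* are
correct and that planted structure is recovered monotonically — not
that any real literature has these parameter values.

The generator uses one private RNG stream per corpus, seeded from its
configuration, and restores the caller's RNG state; the analysis
pipeline itself contains no randomness, so re-running it on unchanged
inputs reproduces every artifact byte for byte.

## Degenerate inputs and numerical choices

- Indices that are mathematically undefined on an input (edgeless graph
  for industrial participation or assortativity, zero total degree for
  top-share, zero flow for flow fractions, empty selection for the
  inter-institutional fraction) raise a classed undefined-result
  condition; the report assembler converts it to `NA`, which exports as
  an empty CSV cell.
- An edgeless but non-empty graph has average clustering 0 (every node
  has fewer than two neighbours), not an error.
- Tags are normalized (lowercase, trimmed, internal whitespace
  collapsed) and matched by exact string equality — the intended use is
  curated alias lists (a focal target plus its synonyms), not free-text
  search.
- Self-references are rejected at parse time; duplicate entries within
  any per-paper set are silently deduplicated; reference lists have set
  semantics, so a repeated mention is one citation.
- All set orderings, rankings and exports use explicit deterministic
  tie-breaks (lexicographic ids, radix sort), so identical inputs give
  byte-identical outputs across runs and platforms.

## Worked example

```{r}
corp <- fig1_corpus()
build_collaboration(corp)$edges
f <- build_flow(corp, collect_citations(corp, c("II", "III")))
f$edges
flow_fractions(f)$overall_internal
```

The two papers co-authored by institutions *c* and *d* give their edge
weight 2; both citations originate outside the citing institutions, so
no self-loop exists and the internal flow fraction is 0.

## Known limitations

- Counts of "authors" are unique author *ids*; no disambiguation is
  attempted, and the author count of a summary row covers the selected
  papers only (a separate helper pools any other id set, since summary
  tables in the literature are ambiguous on this point).
- The per-paper definition of inter-institutional collaboration is one
  of several possible readings of "a collaboration"; it is labeled as
  paper-level and not asserted equivalent to author-pair readings.
- Whether published assortativity values in the scientometrics
  literature use the weighted-degree Pearson form or a library default
  varies; this package follows the weighted-degree definition literally
  and cross-checks it against an independent implementation in the test
  suite.
- The pipeline counts only citation pairs present in the supplied
  corpus; citations from papers outside it are invisible by
  construction.
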