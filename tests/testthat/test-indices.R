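fig1_graph <- function() build_collaboration(fig1_corpus())

test_that("weighted degree sums incident edge weights", {
  g <- fig1_graph()
  expect_equal(weighted_degree(g, "c"), 3)   # edges to d (2) and e (1)
  expect_equal(weighted_degree(g, "a"), 1)
  expect_error(weighted_degree(g, "nope"), class = "collabflow_domain_error")

  iso <- collab_graph(g$edges, nodes = c(g$nodes, "lonely"))
  expect_equal(weighted_degree(iso, "lonely"), 0)

  for (seed in 1:10) {
    rg <- random_collab_graph(n = 9L, seed = seed)
    s <- weighted_degree(rg)
    brute <- sapply(rg$nodes, function(i) {
      sum(rg$edges$weight[rg$edges$a == i]) + sum(rg$edges$weight[rg$edges$b == i])
    })
    expect_equal(s, brute)
  }
})

test_that("industrial fraction counts each corporate-touching edge once", {
  g <- fig1_graph()
  all_acad <- sector_map(stats::setNames(rep("academic", 5), g$nodes))
  all_ind <- sector_map(stats::setNames(rep("industrial", 5), g$nodes))
  expect_equal(industrial_fraction(g, all_acad), 0)
  expect_equal(industrial_fraction(g, all_ind), 1)

  mixed <- sector_map(c(c = "industrial", a = "academic", b = "academic",
                        d = "academic", e = "academic"))
  expect_equal(industrial_fraction(g, mixed), 3 / 5)  # edges {c,d}=2, {c,e}=1

  # monotone under relabeling academic -> industrial
  set.seed(5)
  for (k in 1:20) {
    rg <- random_collab_graph(n = 8L, seed = k)
    labs <- sample(c("industrial", "academic"), length(rg$nodes), replace = TRUE)
    s1 <- sector_map(stats::setNames(labs, rg$nodes))
    flip <- which(labs == "academic")
    if (length(flip) == 0L) next
    labs2 <- labs
    labs2[sample(flip, 1L)] <- "industrial"
    s2 <- sector_map(stats::setNames(labs2, rg$nodes))
    expect_gte(industrial_fraction(rg, s2), industrial_fraction(rg, s1))
  }

  empty <- collab_graph(NULL, nodes = c("x", "y"))
  expect_error(industrial_fraction(empty, all_acad),
               class = "collabflow_undefined_error")
})

test_that("weighted clustering reproduces closed forms", {
  tri_eq <- collab_graph(data.frame(a = c("x", "x", "y"), b = c("y", "z", "z"),
                                    weight = c(3, 3, 3)))
  expect_equal(average_clustering(tri_eq), 1)

  path_g <- collab_graph(data.frame(a = c("a", "b"), b = c("b", "c"), weight = 1))
  expect_equal(average_clustering(path_g), 0)

  tri_124 <- collab_graph(data.frame(a = c("x", "x", "y"), b = c("y", "z", "z"),
                                     weight = c(1, 2, 4)))
  expect_equal(average_clustering(tri_124), 0.5)  # (0.25 * 0.5 * 1)^(1/3) per node
})

test_that("weighted clustering is scale invariant and matches the triple-loop oracle", {
  for (seed in 1:25) {
    rg <- random_collab_graph(n = sample(3:12, 1L), seed = seed)
    expect_equal(average_clustering(rg), oracle_clustering(rg),
                 tolerance = 1e-12)
    scaled <- collab_graph(transform(rg$edges, weight = weight * 7.3),
                           nodes = rg$nodes)
    expect_equal(average_clustering(scaled), average_clustering(rg),
                 tolerance = 1e-12)
  }
})

test_that("assortativity is the symmetrized endpoint-degree Pearson correlation", {
  star <- collab_graph(data.frame(a = rep("hub", 3),
                                  b = c("l1", "l2", "l3"), weight = 1))
  expect_equal(weighted_assortativity(star), -1)

  ring <- collab_graph(data.frame(a = c("a", "b", "c", "d"),
                                  b = c("b", "c", "d", "a"), weight = 1))
  expect_true(is.na(weighted_assortativity(ring)))  # zero variance: undefined

  for (seed in 1:25) {
    rg <- random_collab_graph(n = sample(4:12, 1L), seed = seed + 100L)
    got <- weighted_assortativity(rg)
    want <- oracle_assortativity(rg)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("assortativity agrees with igraph on strength-valued mixing", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    rg <- random_collab_graph(n = 10L, seed = seed)
    ig <- igraph::graph_from_data_frame(rg$edges, directed = FALSE,
                                        vertices = rg$nodes)
    s <- igraph::strength(ig, weights = igraph::E(ig)$weight)
    want <- suppressWarnings(
      igraph::assortativity(ig, values = s, directed = FALSE))
    got <- weighted_assortativity(rg)
    if (is.nan(want) || is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("top-share fraction finds the minimal dominating prefix", {
  # hand cumulative-sum evaluation: hub-and-9-leaves star, unit weights.
  # degrees hub 9, leaves 1 each; total 18, target 16.2; the prefix first
  # reaches it at the hub plus 8 leaves -> 9/10
  star9 <- collab_graph(data.frame(a = rep("hub", 9),
                                   b = sprintf("leaf%d", 1:9), weight = 1))
  expect_equal(top_share_fraction(star9), 9 / 10)

  # uniform degrees: closed form ceil(0.9 N) / N
  for (N in c(4L, 5L, 10L, 12L)) {
    ring <- collab_graph(data.frame(
      a = sprintf("n%02d", seq_len(N)),
      b = sprintf("n%02d", c(seq_len(N)[-1L], 1L)),
      weight = 1))
    expect_equal(top_share_fraction(ring), ceiling(0.9 * N) / N)
  }

  # share = 1 needs exactly the nodes with nonzero degree
  for (seed in 1:10) {
    rg <- random_collab_graph(n = 9L, seed = seed)
    withiso <- collab_graph(rg$edges, nodes = c(rg$nodes, "iso1", "iso2"))
    nz <- sum(weighted_degree(withiso) > 0)
    expect_equal(top_share_fraction(withiso, share = 1),
                 nz / length(withiso$nodes))
    expect_equal(top_share_fraction(rg), oracle_top_share(rg))
  }

  empty <- collab_graph(NULL, nodes = "x")
  expect_error(top_share_fraction(empty), class = "collabflow_undefined_error")
})

test_that("flow fractions split internal and external dissemination", {
  corp <- fig1_corpus()
  f <- build_flow(corp, collect_citations(corp, c("II", "III")))
  ff <- flow_fractions(f)
  expect_equal(ff$overall_internal, 0)  # no u->u edge in the worked example

  solo <- flow_graph(data.frame(from = "x", to = "x", weight = 4))
  ffs <- flow_fractions(solo)
  expect_equal(ffs$overall_internal, 1)
  expect_equal(ffs$per_institution_internal, c(x = 1))

  mixed <- flow_graph(data.frame(from = c("u", "u", "v"),
                                 to = c("u", "v", "w"),
                                 weight = c(2, 6, 4)))
  ffm <- flow_fractions(mixed)
  expect_equal(ffm$overall_internal, 2 / 12)
  expect_equal(ffm$per_institution_internal, c(u = 2 / 8, v = 0))
  # overall equals the out-flow-weighted mean of per-institution fractions
  out_flow <- c(u = 8, v = 4)
  expect_equal(ffm$overall_internal,
               sum(out_flow * ffm$per_institution_internal) / sum(out_flow))
})

test_that("inter-institutional fraction is a per-paper count", {
  corp <- fig1_corpus()
  expect_equal(inter_institutional_fraction(corp, corpus_ids(corp)), 1)

  solos <- bib_corpus(list(paper_record("A", 2001, institutions = "x"),
                           paper_record("B", 2002, institutions = "y"),
                           paper_record("C", 2003)))
  expect_equal(inter_institutional_fraction(solos, corpus_ids(solos)), 0)
  expect_error(inter_institutional_fraction(corp, character(0)),
               class = "collabflow_undefined_error")

  for (seed in 1:5) {
    rc <- random_corpus(n_papers = 40L, seed = seed)
    brute <- mean(vapply(rc$papers,
                         function(p) length(p$institutions) >= 2L, logical(1)))
    expect_equal(inter_institutional_fraction(rc, corpus_ids(rc)), brute)
  }
})

test_that("index report assembles all fields and marks undefined indices", {
  corp <- fig1_corpus()
  smap <- sector_map(c(a = "academic", b = "academic", c = "industrial",
                       d = "academic", e = "academic"))
  rep1 <- compile_index_report(corp, corpus_ids(corp), s = smap)
  expect_equal(rep1$n_papers, 3L)
  expect_equal(rep1$n_authors, 7L)
  expect_equal(rep1$n_institutions, 5L)
  expect_equal(rep1$frac_inter_institutional, 1)
  expect_equal(rep1$frac_industrial, 3 / 5)
  expect_equal(rep1$frac_top_90, 0.8)

  # edgeless corpus: edge-dependent indices carry the undefined marker
  solos <- bib_corpus(list(paper_record("A", 2001, institutions = "x")))
  rep2 <- compile_index_report(solos, "A", s = smap)
  expect_true(is.na(rep2$frac_industrial))
  expect_true(is.na(rep2$assortativity))
  expect_true(is.na(rep2$frac_top_90))
  expect_equal(rep2$avg_clustering, 0)

  # every field equals its independently recomputed value
  rc <- random_corpus(n_papers = 80L, seed = 9L)
  g <- build_collaboration(rc)
  labs <- sector_map(stats::setNames(
    rep(c("industrial", "academic"), length.out = length(g$nodes)), g$nodes))
  rep3 <- compile_index_report(rc, corpus_ids(rc), s = labs)
  expect_equal(rep3$avg_clustering, oracle_clustering(g), tolerance = 1e-12)
  expect_equal(rep3$frac_top_90, oracle_top_share(g))
  expect_equal(rep3$frac_industrial, industrial_fraction(g, labs))
  expect_equal(rep3$n_authors,
               length(unique(unlist(lapply(rc$papers, `[[`, "authors")))))
})

test_that("index report CSV uses the documented columns and empty cells for NA", {
  solos <- bib_corpus(list(paper_record("A", 2001, institutions = "x")))
  rep <- compile_index_report(solos, "A")
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_report(rep, path)
  lines <- readLines(path)
  expect_identical(lines[1],
    "papers,authors,institutions,frac_inter_institutional,frac_industrial,avg_clustering,assortativity,frac_top_90")
  expect_match(lines[2], ",,$")  # trailing undefined cells are empty
})
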