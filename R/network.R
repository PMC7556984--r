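#' Construct a collaboration graph from an edge table
#'
#' The collaboration network is undirected: nodes are institutions and the
#' weight of edge \{i, j\} counts the co-publication cases, i.e. the number
#' of papers on which both institutions appear. Pairs are stored once in
#' canonical (lexicographic) order; self-loops are forbidden.
#'
#' @param edges data frame with columns `a`, `b` (institution ids) and
#'   `weight` (positive integers). Unordered duplicates of the same pair
#'   are summed.
#' @param nodes optional character vector of nodes; institutions appearing
#'   in `edges` are always included, extra entries become isolated nodes.
#' @return an object of class `collab_graph` with elements `nodes`
#'   (character) and `edges` (data frame `a`, `b`, `weight`, with `a < b`).
#' @export
collab_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(a = character(0), b = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("a", "b", "weight") %in% names(edges)))
    a <- as.character(edges$a); b <- as.character(edges$b)
    if (any(a == b)) cf_schema_error("collaboration graph forbids self-loops")
    if (any(edges$weight <= 0)) cf_schema_error("edge weights must be positive")
    lo <- pmin(a, b); hi <- pmax(a, b)
    w <- rowsum(as.numeric(edges$weight), group = paste(lo, hi, sep = "\r"))
    key <- strsplit(rownames(w), "\r", fixed = TRUE)
    edges <- data.frame(
      a = vapply(key, `[`, character(1), 1L),
      b = vapply(key, `[`, character(1), 2L),
      weight = as.numeric(w[, 1L]),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$a, edges$b, method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- canon_set(c(nodes, edges$a, edges$b))
  structure(list(nodes = nodes, edges = edges), class = "collab_graph")
}

#' @export
print.collab_graph <- function(x, ...) {
  cat(sprintf("<collab_graph> %d institutions, %d edges, total weight %g\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Construct a knowledge-flow graph from an edge table
#'
#' The knowledge-flow network is directed: an edge u -> v counts the
#' citation cases in which a paper affiliated with v cites a paper
#' affiliated with u (knowledge moves from the cited toward the citing
#' institution). Self-loops u -> u are meaningful; they measure
#' within-institution flow.
#'
#' @param edges data frame with columns `from`, `to`, `weight`; duplicated
#'   ordered pairs are summed.
#' @param nodes optional extra nodes (isolated unless they carry flow).
#' @return an object of class `flow_graph` with elements `nodes` and
#'   `edges` (data frame `from`, `to`, `weight`).
#' @export
flow_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("from", "to", "weight") %in% names(edges)))
    if (any(edges$weight <= 0)) cf_schema_error("edge weights must be positive")
    w <- rowsum(as.numeric(edges$weight),
                group = paste(edges$from, edges$to, sep = "\r"))
    key <- strsplit(rownames(w), "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(key, `[`, character(1), 1L),
      to = vapply(key, `[`, character(1), 2L),
      weight = as.numeric(w[, 1L]),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- canon_set(c(nodes, edges$from, edges$to))
  structure(list(nodes = nodes, edges = edges), class = "flow_graph")
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf("<flow_graph> %d institutions, %d directed edges, total flow %g\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Project papers onto the institutional collaboration network
#'
#' For every selected paper, every unordered pair of distinct institutions
#' in its deduplicated institution set increments that pair's edge weight
#' by exactly one -- one increment per paper per pair, regardless of how
#' many authors span the two institutions. Single-institution papers
#' contribute a node but no edge; papers without institutions contribute
#' nothing. The total edge weight therefore equals
#' \eqn{\sum_p \binom{|I_p|}{2}} over the selected papers.
#'
#' @param corpus a [bib_corpus()].
#' @param paper_ids papers to project; default all papers in the corpus.
#' @return a [collab_graph()].
#' @export
#' @examples
#' g <- build_collaboration(fig1_corpus())
#' g$edges  # weight of {c, d} is 2, all other edges 1
build_collaboration <- function(corpus, paper_ids = corpus_ids(corpus)) {
  stopifnot(inherits(corpus, "bib_corpus"))
  paper_ids <- canon_set(paper_ids)
  absent <- setdiff(paper_ids, corpus_ids(corpus))
  if (length(absent)) {
    cf_precondition_error(sprintf("unknown paper id(s): %s",
                                  paste(absent, collapse = ", ")))
  }
  papers <- corpus$papers[paper_ids]
  nodes <- canon_set(unlist(lapply(papers, `[[`, "institutions"),
                            use.names = FALSE))
  pair_mats <- lapply(papers, function(p) {
    inst <- p$institutions  # already sorted: pairs come out in canonical order
    if (length(inst) < 2L) return(NULL)
    t(utils::combn(inst, 2L))
  })
  m <- do.call(rbind, pair_mats)
  if (is.null(m) || nrow(m) == 0L) return(collab_graph(NULL, nodes = nodes))
  collab_graph(
    data.frame(a = m[, 1L], b = m[, 2L], weight = 1L, stringsAsFactors = FALSE),
    nodes = nodes
  )
}

#' Project citation pairs onto the knowledge-flow network
#'
#' For each citation pair, every (cited-institution, citing-institution)
#' combination increments the directed edge cited -> citing by one, so the
#' total flow equals \eqn{\sum_{pairs} |I_{cited}| \times |I_{citing}|}.
#' Pairs whose citing paper has no institutions add no flow (they still
#' count in annual citation series, which answer a different question).
#'
#' @param corpus a [bib_corpus()].
#' @param citation_pairs data frame with columns `citing`, `cited`, as
#'   returned by [collect_citations()]; both ends must be corpus papers.
#' @return a [flow_graph()].
#' @export
#' @examples
#' corp <- fig1_corpus()
#' build_flow(corp, collect_citations(corp, c("II", "III")))$edges
build_flow <- function(corpus, citation_pairs) {
  stopifnot(inherits(corpus, "bib_corpus"),
            is.data.frame(citation_pairs),
            all(c("citing", "cited") %in% names(citation_pairs)))
  involved <- unique(c(citation_pairs$citing, citation_pairs$cited))
  absent <- setdiff(involved, corpus_ids(corpus))
  if (length(absent)) {
    cf_precondition_error(sprintf("citation pair references unknown paper(s): %s",
                                  paste(absent, collapse = ", ")))
  }
  nodes <- canon_set(unlist(lapply(corpus$papers[involved], `[[`, "institutions"),
                            use.names = FALSE))
  if (nrow(citation_pairs) == 0L) return(flow_graph(NULL, nodes = nodes))
  pieces <- vector("list", nrow(citation_pairs))
  for (k in seq_len(nrow(citation_pairs))) {
    src <- corpus$papers[[citation_pairs$cited[k]]]$institutions
    dst <- corpus$papers[[citation_pairs$citing[k]]]$institutions
    if (length(src) == 0L || length(dst) == 0L) next
    pieces[[k]] <- expand.grid(from = src, to = dst,
                               KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, pieces)
  if (is.null(m) || nrow(m) == 0L) return(flow_graph(NULL, nodes = nodes))
  m$weight <- 1L
  flow_graph(m, nodes = nodes)
}

#' Is a citation a self-citation?
#'
#' Self-citation is not uniquely defined in the literature; two variants are
#' supported. Under `shared_institution` (the default, consistent with
#' institution-level networks) a citation is a self-citation when the citing
#' and cited papers share at least one institution; under `shared_author`,
#' when they share at least one author id.
#'
#' @param citing,cited [paper_record()] objects.
#' @param mode `"shared_institution"` or `"shared_author"`.
#' @return logical scalar.
#' @export
is_self_citation <- function(citing, cited,
                             mode = c("shared_institution", "shared_author")) {
  mode <- match.arg(mode)
  field <- if (mode == "shared_institution") "institutions" else "authors"
  length(intersect(citing[[field]], cited[[field]])) > 0L
}

#' Annual publication and citation series
#'
#' Publication counts are the number of core papers published each year.
#' Citation counts attribute each citation pair to the year of its CITING
#' paper (citations accrue when made). With `exclude_self = TRUE`,
#' self-citations under the chosen mode are removed before counting.
#' The series covers the contiguous year range spanned by the observed
#' events; years with no events report zero.
#'
#' @param corpus a [bib_corpus()].
#' @param core_ids core paper ids (publication side of the series).
#' @param citation_pairs data frame from [collect_citations()].
#' @param exclude_self drop self-citations before counting?
#' @param mode self-citation mode, see [is_self_citation()].
#' @return data frame of class `annual_series` with columns `year`,
#'   `publications`, `citations`.
#' @export
annual_series <- function(corpus, core_ids, citation_pairs = NULL,
                          exclude_self = FALSE,
                          mode = c("shared_institution", "shared_author")) {
  stopifnot(inherits(corpus, "bib_corpus"))
  mode <- match.arg(mode)
  core_ids <- canon_set(core_ids)
  absent <- setdiff(core_ids, corpus_ids(corpus))
  if (length(absent)) {
    cf_precondition_error(sprintf("core id(s) not in corpus: %s",
                                  paste(absent, collapse = ", ")))
  }
  pub_years <- vapply(corpus$papers[core_ids], `[[`, integer(1), "year")
  cit_years <- integer(0)
  if (!is.null(citation_pairs) && nrow(citation_pairs) > 0L) {
    keep <- rep(TRUE, nrow(citation_pairs))
    if (exclude_self) {
      keep <- !mapply(function(ci, cd) {
        is_self_citation(corpus$papers[[ci]], corpus$papers[[cd]], mode = mode)
      }, citation_pairs$citing, citation_pairs$cited, USE.NAMES = FALSE)
    }
    cit_years <- vapply(corpus$papers[citation_pairs$citing[keep]],
                        `[[`, integer(1), "year")
  }
  all_years <- c(pub_years, cit_years)
  if (length(all_years) == 0L) {
    out <- data.frame(year = integer(0), publications = integer(0),
                      citations = integer(0))
    class(out) <- c("annual_series", "data.frame")
    return(out)
  }
  span <- seq.int(min(all_years), max(all_years))
  out <- data.frame(
    year = span,
    publications = as.integer(tabulate(pub_years - min(span) + 1L,
                                       nbins = length(span))),
    citations = as.integer(tabulate(cit_years - min(span) + 1L,
                                    nbins = length(span)))
  )
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Export a collaboration graph as a TSV edge list
#'
#' Columns `inst_a`, `inst_b`, `weight`; each unordered pair appears once
#' in lexicographic order; rows sorted by weight descending, then pair.
#'
#' @param g a [collab_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collab_edges <- function(g, path) {
  stopifnot(inherits(g, "collab_graph"))
  e <- g$edges
  e <- e[order(-e$weight, e$a, e$b, method = "radix"), , drop = FALSE]
  names(e) <- c("inst_a", "inst_b", "weight")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a knowledge-flow graph as a TSV edge list
#'
#' Columns `from`, `to`, `weight`; rows sorted by weight descending, then
#' ordered pair.
#'
#' @param f a [flow_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flow_edges <- function(f, path) {
  stopifnot(inherits(f, "flow_graph"))
  e <- f$edges
  e <- e[order(-e$weight, e$from, e$to, method = "radix"), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an annual series as CSV
#' @param s an [annual_series()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annual_series <- function(s, path) {
  utils::write.csv(as.data.frame(s), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
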