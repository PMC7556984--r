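#' Weighted degree of institutions
#'
#' The weighted degree (strength) of institution i is
#' \eqn{s_i = \sum_j w_{ij}}, the sum of collaboration edge weights
#' incident to it; isolated nodes have degree 0.
#'
#' @param g a [collab_graph()].
#' @param i optional single institution id; if omitted, the full named
#'   vector of weighted degrees over all nodes is returned.
#' @return numeric scalar (if `i` given) or named numeric vector.
#' @export
weighted_degree <- function(g, i = NULL) {
  stopifnot(inherits(g, "collab_graph"))
  s <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    for (col in c("a", "b")) {
      agg <- rowsum(g$edges$weight, group = g$edges[[col]])
      s[rownames(agg)] <- s[rownames(agg)] + agg[, 1L]
    }
  }
  if (is.null(i)) return(s)
  if (length(i) != 1L || !(i %in% g$nodes)) {
    cf_domain_error(sprintf("unknown institution: %s", paste(i, collapse = ", ")))
  }
  unname(s[[i]])
}

#' Fraction of industrial participation
#'
#' The share of total collaboration link weight carried by edges with at
#' least one corporate endpoint:
#' \deqn{\sum_{i \mathrm{\ or\ } j \in \mathrm{Corporates}} w_{ij} \Big/ \sum_{i,j} w_{ij}}
#' Each qualifying edge is counted once even when both endpoints are
#' industrial, so the fraction stays in \[0, 1\].
#'
#' @param g a [collab_graph()] with at least one edge.
#' @param s a `sector_map` (see [load_sector_map()]).
#' @return fraction in \[0, 1\].
#' @export
industrial_fraction <- function(g, s) {
  stopifnot(inherits(g, "collab_graph"))
  if (nrow(g$edges) == 0L) {
    cf_undefined_error("industrial fraction undefined on an edgeless graph")
  }
  ind <- sector_of(s, g$edges$a) == "industrial" |
         sector_of(s, g$edges$b) == "industrial"
  sum(g$edges$weight[ind]) / sum(g$edges$weight)
}

#' Weighted average clustering coefficient
#'
#' Per-node clustering uses the geometric average of subgraph edge weights:
#' with weights rescaled by the graph-wide maximum,
#' \eqn{\hat w = w / \max w}, the coefficient of node i is
#' \deqn{C_i = \frac{1}{k_i (k_i - 1)} \sum_{j,k}
#'   (\hat w_{ij} \hat w_{ik} \hat w_{jk})^{1/3}}
#' where \eqn{k_i} is the (unweighted) number of neighbours and the sum runs
#' over ordered neighbour pairs. Nodes with fewer than two neighbours have
#' \eqn{C_i = 0} and are included in the unweighted mean over ALL nodes.
#' The statistic is invariant under uniform rescaling of all edge weights.
#'
#' @param g a non-empty [collab_graph()].
#' @return average clustering in \[0, 1\].
#' @export
average_clustering <- function(g) {
  stopifnot(inherits(g, "collab_graph"))
  n <- length(g$nodes)
  if (n == 0L) cf_undefined_error("average clustering undefined on an empty graph")
  if (nrow(g$edges) == 0L) return(0)
  a_idx <- match(g$edges$a, g$nodes)
  b_idx <- match(g$edges$b, g$nodes)
  w_hat <- g$edges$weight / max(g$edges$weight)
  A <- matrix(0, n, n)
  A[cbind(a_idx, b_idx)] <- w_hat^(1 / 3)
  A[cbind(b_idx, a_idx)] <- w_hat^(1 / 3)
  k <- rowSums(A > 0)
  # diag(A^3)[i] accumulates (w_ij w_jk w_ki)^{1/3} over ordered pairs (j, k)
  closed <- diag(A %*% A %*% A)
  C <- ifelse(k < 2, 0, closed / (k * (k - 1)))
  mean(C)
}

#' Weighted-degree assortativity
#'
#' The Pearson correlation of weighted degrees \eqn{s_i} found at the two
#' ends of the same link: each edge contributes the two symmetric ordered
#' pairs \eqn{(s_i, s_j)} and \eqn{(s_j, s_i)}, and the correlation is
#' taken over that pair list. Edges are not weight-weighted. Negative
#' values mean that highly connected institutions tend to collaborate with
#' weakly connected ones.
#'
#' @param g a [collab_graph()] with at least one edge.
#' @return correlation in \[-1, 1\], or `NA_real_` when endpoint degrees
#'   have zero variance (the statistic is then undefined, not zero).
#' @export
weighted_assortativity <- function(g) {
  stopifnot(inherits(g, "collab_graph"))
  if (nrow(g$edges) == 0L) {
    cf_undefined_error("assortativity undefined on an edgeless graph")
  }
  s <- weighted_degree(g)
  x <- c(s[g$edges$a], s[g$edges$b])
  y <- c(s[g$edges$b], s[g$edges$a])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  unname(stats::cor(x, y))
}

#' Fraction of top institutions holding a share of total degree
#'
#' Institutions are ranked by weighted degree (descending; ties broken by
#' institution id for determinism). The statistic is m / N, where m is the
#' smallest number of top-ranked institutions whose cumulative weighted
#' degree reaches `share` of the total \eqn{\sum_i s_i}, and N is the total
#' node count including isolated institutions. Small values mean that a few
#' institutions dominate the network's collaborations.
#'
#' @param g a [collab_graph()] with positive total degree.
#' @param share target cumulative share, default 0.9.
#' @return fraction in (0, 1\].
#' @export
top_share_fraction <- function(g, share = 0.9) {
  stopifnot(inherits(g, "collab_graph"), share > 0, share <= 1)
  s <- weighted_degree(g)
  total <- sum(s)
  if (total <= 0) {
    cf_undefined_error("top-share fraction undefined when total degree is 0")
  }
  ord <- order(-s, names(s), method = "radix")
  cum <- cumsum(s[ord])
  # tolerance guards against e.g. 0.9 * total overshooting an exact hit
  m <- unname(which(cum >= share * total - 1e-9 * total)[1L])
  m / length(s)
}

#' Within-institution knowledge-flow fractions
#'
#' `overall_internal` is the share of total citation flow on self-loops:
#' citation cases where the citing and cited papers share the institution.
#' `per_institution_internal[u]` is the internal-dissemination fraction of
#' institution u: the share of all citations of u's papers (u's out-flow,
#' flow u -> anything) generated by u itself (flow u -> u). Institutions
#' with zero out-flow are omitted from the map. The overall fraction equals
#' the out-flow-weighted mean of the per-institution fractions.
#'
#' @param f a [flow_graph()] with positive total flow.
#' @return object of class `flow_fractions`: list with `overall_internal`
#'   (scalar) and `per_institution_internal` (named numeric vector).
#' @export
flow_fractions <- function(f) {
  stopifnot(inherits(f, "flow_graph"))
  total <- sum(f$edges$weight)
  if (nrow(f$edges) == 0L || total <= 0) {
    cf_undefined_error("flow fractions undefined when total flow is 0")
  }
  self <- f$edges$from == f$edges$to
  out_flow <- rowsum(f$edges$weight, group = f$edges$from)
  internal <- stats::setNames(numeric(nrow(out_flow)), rownames(out_flow))
  if (any(self)) {
    sl <- rowsum(f$edges$weight[self], group = f$edges$from[self])
    internal[rownames(sl)] <- sl[, 1L]
  }
  per <- internal / out_flow[, 1L]
  per <- per[order(names(per), method = "radix")]
  structure(
    list(overall_internal = sum(f$edges$weight[self]) / total,
         per_institution_internal = per),
    class = "flow_fractions"
  )
}

#' @export
print.flow_fractions <- function(x, ...) {
  cat(sprintf("<flow_fractions> overall internal flow: %.1f%% (%d institutions with out-flow)\n",
              100 * x$overall_internal, length(x$per_institution_internal)))
  invisible(x)
}

#' Fraction of papers with inter-institutional collaboration
#'
#' The share of selected papers whose institution set has size >= 2.
#' Papers with an empty institution set count in the denominator: they are
#' observed papers that display no inter-institutional collaboration.
#'
#' @param corpus a [bib_corpus()].
#' @param paper_ids non-empty set of paper ids.
#' @return fraction in \[0, 1\].
#' @export
inter_institutional_fraction <- function(corpus, paper_ids) {
  stopifnot(inherits(corpus, "bib_corpus"))
  paper_ids <- canon_set(paper_ids)
  if (length(paper_ids) == 0L) {
    cf_undefined_error("inter-institutional fraction undefined on an empty selection")
  }
  absent <- setdiff(paper_ids, corpus_ids(corpus))
  if (length(absent)) {
    cf_precondition_error(sprintf("unknown paper id(s): %s",
                                  paste(absent, collapse = ", ")))
  }
  multi <- vapply(corpus$papers[paper_ids],
                  function(p) length(p$institutions) >= 2L, logical(1))
  mean(multi)
}

#' Count distinct authors over a paper selection
#'
#' Exposed separately because summary tables may count authors of the core
#' papers only, or of core plus citing papers; pass whichever id set the
#' table intends.
#'
#' @param corpus a [bib_corpus()].
#' @param paper_ids paper ids to pool authors over.
#' @return integer count of unique author ids.
#' @export
author_count <- function(corpus, paper_ids) {
  stopifnot(inherits(corpus, "bib_corpus"))
  paper_ids <- canon_set(paper_ids)
  length(unique(unlist(lapply(corpus$papers[paper_ids], `[[`, "authors"),
                       use.names = FALSE)))
}

#' Compile the network-index report for one corpus selection
#'
#' Assembles one summary row: paper, author and institution counts plus the
#' five network indices (inter-institutional fraction, industrial
#' participation, weighted average clustering, weighted-degree
#' assortativity, top-share concentration). Indices that are undefined for
#' the given network (e.g. on an edgeless graph) are reported as `NA`.
#'
#' @param corpus a [bib_corpus()].
#' @param paper_ids the selected (core) papers.
#' @param g optional prebuilt [collab_graph()]; built from `paper_ids`
#'   when omitted.
#' @param s a `sector_map`; when omitted the industrial fraction is `NA`.
#' @param share top-share threshold, default 0.9.
#' @return one-row data frame of class `index_report` with columns
#'   `n_papers`, `n_authors`, `n_institutions`, `frac_inter_institutional`,
#'   `frac_industrial`, `avg_clustering`, `assortativity`, `frac_top_90`.
#' @export
compile_index_report <- function(corpus, paper_ids, g = NULL, s = NULL,
                                 share = 0.9) {
  stopifnot(inherits(corpus, "bib_corpus"))
  paper_ids <- canon_set(paper_ids)
  if (is.null(g)) g <- build_collaboration(corpus, paper_ids)
  na_if_undefined <- function(expr) {
    tryCatch(expr, collabflow_undefined_error = function(e) NA_real_)
  }
  out <- data.frame(
    n_papers = length(paper_ids),
    n_authors = author_count(corpus, paper_ids),
    n_institutions = length(g$nodes),
    frac_inter_institutional =
      na_if_undefined(inter_institutional_fraction(corpus, paper_ids)),
    frac_industrial = if (is.null(s)) NA_real_ else
      na_if_undefined(industrial_fraction(g, s)),
    avg_clustering = na_if_undefined(average_clustering(g)),
    assortativity = na_if_undefined(weighted_assortativity(g)),
    frac_top_90 = na_if_undefined(top_share_fraction(g, share = share))
  )
  class(out) <- c("index_report", "data.frame")
  out
}

#' Export index reports as CSV
#'
#' Columns exactly: `papers`, `authors`, `institutions`,
#' `frac_inter_institutional`, `frac_industrial`, `avg_clustering`,
#' `assortativity`, `frac_top_90`. Undefined indices become empty cells.
#'
#' @param reports one `index_report` or a list of them (one row each).
#' @param path output path.
#' @param names optional row labels, written as a leading `corpus` column.
#' @return `path`, invisibly.
#' @export
write_index_report <- function(reports, path, names = NULL) {
  if (inherits(reports, "index_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  colnames(df) <- c("papers", "authors", "institutions",
                    "frac_inter_institutional", "frac_industrial",
                    "avg_clustering", "assortativity", "frac_top_90")
  if (!is.null(names)) df <- cbind(corpus = names, df)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Export flow fractions as CSV
#'
#' Per-institution internal-dissemination fractions, one row per
#' institution, preceded by a comment line with the overall internal share.
#'
#' @param ff a [flow_fractions()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flow_fractions <- function(ff, path) {
  stopifnot(inherits(ff, "flow_fractions"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# overall_internal,%.12g", ff$overall_internal), con)
  writeLines("institution,internal_fraction", con)
  writeLines(sprintf("%s,%.12g",
                     names(ff$per_institution_internal),
                     ff$per_institution_internal), con)
  invisible(path)
}
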