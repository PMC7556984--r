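# Independent brute-force reference implementations and random fixtures.
# These deliberately share no code with the package internals: explicit
# loops over materialized structures, so they can serve as oracles.

random_corpus <- function(n_papers = 30L, n_inst_pool = 10L, seed = 1L,
                          p_empty_inst = 0.1, max_inst = 4L,
                          tag_pool = c("alpha", "beta", "gamma")) {
  set.seed(seed)
  pool <- sprintf("inst%02d", seq_len(n_inst_pool))
  ids <- sprintf("R%03d", seq_len(n_papers))
  records <- lapply(seq_len(n_papers), function(k) {
    ni <- if (stats::runif(1) < p_empty_inst) 0L else sample.int(max_inst, 1L)
    others <- setdiff(ids, ids[k])
    nr <- sample(0:4, 1L)
    paper_record(
      ids[k],
      year = sample(2000:2010, 1L),
      institutions = sample(pool, ni),
      authors = sprintf("auth%02d", sample.int(25L, sample.int(5L, 1L))),
      references = sample(others, min(nr, length(others))),
      tags = sample(tag_pool, sample(0:2, 1L))
    )
  })
  bib_corpus(records)
}

random_collab_graph <- function(n = 8L, seed = 1L, max_w = 10L,
                                p_edge = 0.45) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 2L)] <- TRUE
  collab_graph(
    data.frame(a = pairs[keep, 1L], b = pairs[keep, 2L],
               weight = sample.int(max_w, sum(keep), replace = TRUE),
               stringsAsFactors = FALSE),
    nodes = nodes
  )
}

# explicit per-paper pair enumeration, environment-backed counter
oracle_collab_weights <- function(corpus, ids) {
  cnt <- list()
  for (pid in ids) {
    inst <- sort(corpus$papers[[pid]]$institutions)
    if (length(inst) < 2L) next
    for (i in seq_along(inst)) for (j in seq_along(inst)) if (i < j) {
      key <- paste(inst[i], inst[j], sep = "|")
      cnt[[key]] <- if (is.null(cnt[[key]])) 1L else cnt[[key]] + 1L
    }
  }
  cnt
}

# explicit double loop over papers x references
oracle_citation_pairs <- function(corpus, core_ids) {
  out <- character(0)
  for (pid in names(corpus$papers)) {
    for (ref in corpus$papers[[pid]]$references) {
      if (ref %in% core_ids && ref %in% names(corpus$papers)) {
        out <- c(out, paste(pid, ref, sep = "->"))
      }
    }
  }
  sort(out)
}

# triple loop over nodes and their neighbour pairs
oracle_clustering <- function(g) {
  n <- length(g$nodes)
  if (n == 0L) stop("empty graph")
  if (nrow(g$edges) == 0L) return(0)
  W <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (r in seq_len(nrow(g$edges))) {
    W[g$edges$a[r], g$edges$b[r]] <- g$edges$weight[r]
    W[g$edges$b[r], g$edges$a[r]] <- g$edges$weight[r]
  }
  Wh <- W / max(W)
  cs <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    acc <- 0
    for (j in nb) for (l in nb) if (j != l) {
      acc <- acc + (Wh[i, j] * Wh[i, l] * Wh[j, l])^(1 / 3)
    }
    cs[i] <- acc / (k * (k - 1))
  }
  mean(cs)
}

# materialized symmetric endpoint-degree pair list, then plain Pearson
oracle_assortativity <- function(g) {
  deg <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  for (r in seq_len(nrow(g$edges))) {
    deg[g$edges$a[r]] <- deg[g$edges$a[r]] + g$edges$weight[r]
    deg[g$edges$b[r]] <- deg[g$edges$b[r]] + g$edges$weight[r]
  }
  xs <- ys <- numeric(0)
  for (r in seq_len(nrow(g$edges))) {
    xs <- c(xs, deg[g$edges$a[r]], deg[g$edges$b[r]])
    ys <- c(ys, deg[g$edges$b[r]], deg[g$edges$a[r]])
  }
  if (stats::sd(xs) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

# scan every prefix of the sorted degree list
oracle_top_share <- function(g, share = 0.9) {
  deg <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  for (r in seq_len(nrow(g$edges))) {
    deg[g$edges$a[r]] <- deg[g$edges$a[r]] + g$edges$weight[r]
    deg[g$edges$b[r]] <- deg[g$edges$b[r]] + g$edges$weight[r]
  }
  sorted <- deg[order(-deg, names(deg))]
  total <- sum(sorted)
  for (m in seq_along(sorted)) {
    if (sum(sorted[seq_len(m)]) >= share * total - 1e-9 * total) {
      return(m / length(sorted))
    }
  }
  1
}
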