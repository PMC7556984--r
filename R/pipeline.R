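#' Configuration for an end-to-end pipeline run
#'
#' @param corpus_path JSON Lines corpus file (see [read_corpus()]).
#' @param alias_path tag alias list (see [read_tag_query()]).
#' @param sector_path optional sector-map CSV (see [load_sector_map()]);
#'   without it the industrial fraction is reported as undefined.
#' @param output_dir directory for the written artifacts (created if needed).
#' @param self_citation_mode mode used for the self-citation-excluded
#'   series, see [is_self_citation()].
#' @param exclude_self also write the self-citation-excluded annual series?
#' @param top_k number of edges / institutions in the ranked reports.
#' @param share_threshold top-share concentration threshold in (0, 1].
#' @return object of class `run_config`.
#' @export
run_config <- function(corpus_path, alias_path, sector_path = NULL,
                       output_dir,
                       self_citation_mode = c("shared_institution",
                                              "shared_author"),
                       exclude_self = TRUE,
                       top_k = 20L,
                       share_threshold = 0.9) {
  self_citation_mode <- match.arg(self_citation_mode)
  stopifnot(top_k >= 1L, share_threshold > 0, share_threshold <= 1)
  structure(
    list(corpus_path = corpus_path, alias_path = alias_path,
         sector_path = sector_path, output_dir = output_dir,
         self_citation_mode = self_citation_mode,
         exclude_self = isTRUE(exclude_self),
         top_k = as.integer(top_k),
         share_threshold = share_threshold),
    class = "run_config"
  )
}

#' Highest-weight edges of a graph
#'
#' Edges sorted by weight descending, ties broken by the (lexicographic)
#' node pair; the first `k` are returned, or all edges when fewer exist.
#'
#' @param g a [collab_graph()] or [flow_graph()].
#' @param k number of edges requested, `k >= 1`.
#' @return data frame of at most `k` edge rows in rank order.
#' @export
top_k_edges <- function(g, k) {
  stopifnot(inherits(g, "collab_graph") || inherits(g, "flow_graph"),
            k >= 1L)
  e <- g$edges
  u <- e[[1L]]; v <- e[[2L]]
  e <- e[order(-e$weight, u, v, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  utils::head(e, k)
}

#' Top institutions by weighted degree and by paper count
#'
#' The primary ranking is weighted degree in the collaboration network;
#' the paper count over the selection is reported alongside as an
#' alternative ranking key.
#'
#' @param corpus a [bib_corpus()].
#' @param paper_ids the selected papers.
#' @param g the collaboration graph built from the selection.
#' @param k number of institutions to report.
#' @param by ranking key, `"weighted_degree"` (default) or `"papers"`.
#' @return data frame with columns `institution`, `weighted_degree`,
#'   `papers`, in rank order.
#' @export
top_institutions <- function(corpus, paper_ids, g, k = 20L,
                             by = c("weighted_degree", "papers")) {
  by <- match.arg(by)
  s <- weighted_degree(g)
  inst_per_paper <- lapply(corpus$papers[canon_set(paper_ids)],
                           `[[`, "institutions")
  cnt <- table(unlist(inst_per_paper, use.names = FALSE))
  papers <- stats::setNames(integer(length(s)), names(s))
  papers[names(cnt)] <- as.integer(cnt)
  df <- data.frame(institution = names(s),
                   weighted_degree = unname(s),
                   papers = unname(papers),
                   stringsAsFactors = FALSE)
  key <- if (by == "weighted_degree") df$weighted_degree else df$papers
  df <- df[order(-key, df$institution, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}

#' Run the full corpus-to-report pipeline
#'
#' Orchestrates: read corpus, tag selection, citation collection, both
#' network projections, annual series (with and without self-citation
#' exclusion), index report, flow fractions, ranked edge reports, and a
#' machine-readable JSON manifest. The pipeline contains no randomness;
#' re-running on unchanged inputs reproduces every artifact byte for byte.
#'
#' Artifacts written to `output_dir`: `collaboration_edges.tsv`,
#' `flow_edges.tsv`, `annual_series_all.csv`,
#' `annual_series_excl_self.csv` (when `exclude_self`),
#' `index_report.csv`, `flow_fractions.csv`,
#' `top_edges_collaboration.tsv`, `top_institutions.csv`, `manifest.json`.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly (also written as JSON). On failure the
#'   manifest names the failing stage before the error is re-signalled.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "collabflow",
    version = as.character(utils::packageVersion("collabflow")),
    inputs = list(corpus = cfg$corpus_path, aliases = cfg$alias_path,
                  sectors = cfg$sector_path),
    parameters = list(self_citation_mode = cfg$self_citation_mode,
                      exclude_self = cfg$exclude_self,
                      top_k = cfg$top_k,
                      share_threshold = cfg$share_threshold),
    warnings = character(0)
  )
  stage <- "init"
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  tryCatch({
    stage <- "read_inputs"
    corpus <- read_corpus(cfg$corpus_path)
    query <- read_tag_query(cfg$alias_path)
    sectors <- if (!is.null(cfg$sector_path)) load_sector_map(cfg$sector_path)

    stage <- "select"
    core <- select_tagged(corpus, query)
    if (length(core) == 0L) {
      cf_precondition_error(sprintf(
        "no papers match tag query '%s'", query$canonical_name))
    }
    pairs <- collect_citations(corpus, core)

    stage <- "networks"
    g <- build_collaboration(corpus, core)
    f <- build_flow(corpus, pairs)

    stage <- "series"
    s_all <- annual_series(corpus, core, pairs, exclude_self = FALSE)
    s_excl <- if (cfg$exclude_self) {
      annual_series(corpus, core, pairs, exclude_self = TRUE,
                    mode = cfg$self_citation_mode)
    }

    stage <- "indices"
    report <- compile_index_report(corpus, core, g = g, s = sectors,
                                   share = cfg$share_threshold)
    ff <- tryCatch(flow_fractions(f),
                   collabflow_undefined_error = function(e) NULL)
    if (is.null(ff)) {
      manifest$warnings <- c(manifest$warnings,
                             "zero citation flow: flow fractions not written")
    }

    stage <- "write"
    paths <- c(
      write_collab_edges(g, file.path(cfg$output_dir, "collaboration_edges.tsv")),
      write_flow_edges(f, file.path(cfg$output_dir, "flow_edges.tsv")),
      write_annual_series(s_all, file.path(cfg$output_dir, "annual_series_all.csv")),
      if (!is.null(s_excl))
        write_annual_series(s_excl,
                            file.path(cfg$output_dir, "annual_series_excl_self.csv")),
      write_index_report(report, file.path(cfg$output_dir, "index_report.csv")),
      if (!is.null(ff))
        write_flow_fractions(ff, file.path(cfg$output_dir, "flow_fractions.csv"))
    )
    tke <- top_k_edges(g, cfg$top_k)
    names(tke) <- c("inst_a", "inst_b", "weight")
    utils::write.table(tke,
                       file.path(cfg$output_dir, "top_edges_collaboration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ti <- top_institutions(corpus, core, g, k = cfg$top_k)
    utils::write.csv(ti, file.path(cfg$output_dir, "top_institutions.csv"),
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, file.path(cfg$output_dir, "top_edges_collaboration.tsv"),
               file.path(cfg$output_dir, "top_institutions.csv"))

    stage <- "manifest"
    n_no_inst <- attr(corpus, "n_no_institution")
    manifest$counts <- list(
      corpus_papers = length(corpus$papers),
      dangling_refs = length(corpus$dangling_refs),
      core_papers = length(core),
      citation_pairs = nrow(pairs),
      citation_pairs_core_to_core = sum(pairs$both_core),
      citing_papers = length(unique(pairs$citing)),
      institutions = length(g$nodes),
      collaboration_edges = nrow(g$edges),
      collaboration_total_weight = sum(g$edges$weight),
      flow_edges = nrow(f$edges),
      flow_total_weight = sum(f$edges$weight),
      papers_without_institutions = n_no_inst
    )
    if (n_no_inst > 0L) {
      manifest$warnings <- c(manifest$warnings, sprintf(
        "%d paper(s) without institutions contribute no network edges", n_no_inst))
    }
    manifest$outputs <- as.list(stats::setNames(
      unname(tools::md5sum(paths)), basename(paths)))
    manifest$status <- "ok"
    write_manifest()
    invisible(manifest)
  }, error = function(e) {
    manifest$status <<- "error"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop(e)
  })
}
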