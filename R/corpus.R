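#' Construct a single paper record
#'
#' A paper record is the unit of a bibliographic corpus: an identifier,
#' a publication year, and the deduplicated sets of institution affiliations,
#' author identifiers, referenced paper identifiers and normalized topic tags.
#' A paper listing an author with several affiliations contributes all of
#' those institutions; the institution set is deduplicated per paper.
#'
#' @param paper_id non-empty string, unique within a corpus.
#' @param year integer calendar year, inside `year_window`.
#' @param institutions,authors,references character vectors; duplicates are
#'   silently removed (set semantics).
#' @param tags character vector of topic tags; normalized with
#'   [normalize_tag()] and deduplicated.
#' @param year_window length-2 integer vector of admissible years.
#' @return an object of class `paper_record`.
#' @export
#' @examples
#' paper_record("P1", 2005, institutions = c("a", "b"), references = "P2")
paper_record <- function(paper_id, year,
                         institutions = character(),
                         authors = character(),
                         references = character(),
                         tags = character(),
                         year_window = c(1900L, 2100L)) {
  paper_id <- as.character(paper_id)
  if (length(paper_id) != 1L || is.na(paper_id) || !nzchar(paper_id)) {
    cf_schema_error("paper_id must be a single non-empty string")
  }
  if (length(year) != 1L || is.na(suppressWarnings(as.numeric(year)))) {
    cf_schema_error(sprintf("paper %s: year must be a single number", paper_id))
  }
  year <- as.integer(year)
  if (year < year_window[1L] || year > year_window[2L]) {
    cf_schema_error(sprintf(
      "paper %s: year %d outside validity window [%d, %d]",
      paper_id, year, year_window[1L], year_window[2L]))
  }
  references <- canon_set(references)
  if (paper_id %in% references) {
    cf_parse_error(sprintf("paper %s references itself", paper_id))
  }
  structure(
    list(
      paper_id     = paper_id,
      year         = year,
      institutions = canon_set(institutions),
      authors      = canon_set(authors),
      references   = references,
      tags         = canon_set(normalize_tag(tags))
    ),
    class = "paper_record"
  )
}

#' Assemble a corpus from paper records
#'
#' A corpus keys its records by `paper_id` and keeps track of dangling
#' references: identifiers cited by some record but absent from the corpus.
#' Records with an empty institution set are retained (they contribute to
#' counts and time series but never to network edges); their number is
#' available as `attr(corpus, "n_no_institution")`.
#'
#' @param records list of [paper_record()] objects.
#' @return an object of class `bib_corpus` with elements `papers` (named
#'   list, sorted by id) and `dangling_refs` (character vector).
#' @export
bib_corpus <- function(records) {
  if (length(records) == 0L) {
    return(structure(list(papers = structure(list(), names = character(0)),
                          dangling_refs = character(0)),
                     class = "bib_corpus",
                     n_no_institution = 0L))
  }
  ids <- vapply(records, function(r) r$paper_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    cf_integrity_error(sprintf("duplicate paper_id: %s",
                               paste(unique(dup), collapse = ", ")))
  }
  names(records) <- ids
  records <- records[order(ids, method = "radix")]
  all_refs <- unique(unlist(lapply(records, `[[`, "references"),
                            use.names = FALSE))
  dangling <- canon_set(setdiff(all_refs, ids))
  structure(
    list(papers = records, dangling_refs = dangling),
    class = "bib_corpus",
    n_no_institution = sum(vapply(records,
                                  function(r) length(r$institutions) == 0L,
                                  logical(1)))
  )
}

#' @export
print.bib_corpus <- function(x, ...) {
  cat(sprintf("<bib_corpus> %d papers, %d dangling references\n",
              length(x$papers), length(x$dangling_refs)))
  yrs <- vapply(x$papers, `[[`, integer(1), "year")
  if (length(yrs)) cat(sprintf("  years %d-%d\n", min(yrs), max(yrs)))
  invisible(x)
}

#' Paper identifiers of a corpus
#' @param corpus a [bib_corpus()].
#' @return character vector of paper ids, sorted.
#' @export
corpus_ids <- function(corpus) names(corpus$papers)

#' Read a corpus from a JSON Lines file
#'
#' One JSON object per line with keys `id` (string), `year` (integer),
#' `institutions`, `authors`, `references`, `tags` (arrays of strings).
#' Duplicate entries within a record's arrays are silently deduplicated;
#' dangling references are collected on the corpus. Blank lines are ignored.
#'
#' @param path path to a JSON Lines corpus file.
#' @param year_window admissible year range, default 1900-2100.
#' @return a [bib_corpus()].
#' @export
read_corpus <- function(path, year_window = c(1900L, 2100L)) {
  if (!file.exists(path)) cf_precondition_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  required <- c("id", "year", "institutions", "authors", "references", "tags")
  records <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    obj <- tryCatch(
      jsonlite::fromJSON(lines[ln], simplifyVector = TRUE),
      error = function(e) cf_parse_error(
        sprintf("line %d: malformed JSON (%s)", ln, conditionMessage(e)))
    )
    missing <- setdiff(required, names(obj))
    if (length(missing)) {
      cf_schema_error(sprintf("line %d: missing required field(s): %s",
                              ln, paste(missing, collapse = ", ")))
    }
    records[[k]] <- paper_record(
      paper_id     = obj$id,
      year         = obj$year,
      institutions = unlist(obj$institutions, use.names = FALSE),
      authors      = unlist(obj$authors, use.names = FALSE),
      references   = unlist(obj$references, use.names = FALSE),
      tags         = unlist(obj$tags, use.names = FALSE),
      year_window  = year_window
    )
  }
  bib_corpus(records)
}

#' Write a corpus to a JSON Lines file
#'
#' Inverse of [read_corpus()]: records are written one JSON object per line,
#' in paper-id order with sorted arrays, so that writing and re-reading
#' yields a field-by-field identical corpus and identical inputs produce
#' byte-identical files.
#'
#' @param corpus a [bib_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus$papers, function(p) {
    jsonlite::toJSON(
      list(id = jsonlite::unbox(p$paper_id),
           year = jsonlite::unbox(p$year),
           institutions = p$institutions,
           authors = p$authors,
           references = p$references,
           tags = p$tags),
      auto_unbox = FALSE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Load an institution sector map
#'
#' Reads a two-column CSV with header `institution,sector` labeling each
#' institution `industrial`, `academic` or `unknown`. Institutions absent
#' from the map are treated as `unknown` at lookup time ([sector_of()]).
#'
#' @param path path to the CSV file.
#' @return a named character vector of class `sector_map`.
#' @export
load_sector_map <- function(path) {
  if (!file.exists(path)) cf_precondition_error(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (!identical(names(df), c("institution", "sector"))) {
    cf_schema_error("sector map must have header: institution,sector")
  }
  allowed <- c("industrial", "academic", "unknown")
  bad <- setdiff(unique(df$sector), allowed)
  if (length(bad)) {
    cf_schema_error(sprintf("unknown sector label(s): %s (allowed: %s)",
                            paste(bad, collapse = ", "),
                            paste(allowed, collapse = ", ")))
  }
  df <- unique(df)
  if (anyDuplicated(df$institution)) {
    dups <- unique(df$institution[duplicated(df$institution)])
    cf_integrity_error(sprintf("conflicting sector labels for: %s",
                               paste(dups, collapse = ", ")))
  }
  structure(stats::setNames(df$sector, df$institution), class = "sector_map")
}

#' Build a sector map in code
#' @param sectors named character vector, institution id -> label in
#'   `industrial`, `academic`, `unknown`.
#' @return a `sector_map`.
#' @export
sector_map <- function(sectors) {
  allowed <- c("industrial", "academic", "unknown")
  bad <- setdiff(unique(unname(sectors)), allowed)
  if (length(bad)) cf_schema_error(sprintf("unknown sector label(s): %s",
                                           paste(bad, collapse = ", ")))
  if (is.null(names(sectors)) || anyDuplicated(names(sectors))) {
    cf_integrity_error("sectors must be uniquely named by institution id")
  }
  structure(sectors, class = "sector_map")
}

#' Look up institution sectors
#' @param s a `sector_map`.
#' @param ids character vector of institution ids.
#' @return character vector of labels; unmapped ids return `"unknown"`.
#' @export
sector_of <- function(s, ids) {
  out <- unname(unclass(s)[ids])
  out[is.na(out)] <- "unknown"
  out
}

#' Construct a tag query
#'
#' A tag query names a focal topic (for the analyses here, a drug target
#' such as PCSK9) through a canonical name and a set of aliases. All
#' strings are normalized; the canonical name is always a member of the
#' alias set.
#'
#' @param canonical_name the canonical tag.
#' @param aliases further aliases (e.g. gene synonyms).
#' @return an object of class `tag_query`.
#' @export
#' @examples
#' tag_query("PCSK9", c("NARC-1", "FH3", "HCHOLA3"))
tag_query <- function(canonical_name, aliases = character()) {
  canonical_name <- normalize_tag(canonical_name)
  if (length(canonical_name) != 1L || !nzchar(canonical_name)) {
    cf_schema_error("canonical_name must be a single non-empty string")
  }
  structure(
    list(canonical_name = canonical_name,
         aliases = canon_set(c(canonical_name, normalize_tag(aliases)))),
    class = "tag_query"
  )
}

#' Read a tag query from an alias list file
#'
#' Plain text, one alias per line; `#` starts a comment; blank lines are
#' ignored. The first alias is taken as the canonical name.
#'
#' @param path path to the alias file.
#' @return a [tag_query()].
#' @export
read_tag_query <- function(path) {
  if (!file.exists(path)) cf_precondition_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) cf_schema_error("empty tag query: no aliases in file")
  tag_query(lines[1L], lines[-1L])
}

#' Select papers matching a tag query
#'
#' Returns the ids of papers whose (normalized) tag set intersects the
#' query's alias set. Matching is exact string equality on normalized tags.
#'
#' @param corpus a [bib_corpus()].
#' @param query a [tag_query()].
#' @return sorted character vector of matching paper ids (possibly empty).
#' @export
select_tagged <- function(corpus, query) {
  stopifnot(inherits(corpus, "bib_corpus"), inherits(query, "tag_query"))
  hit <- vapply(corpus$papers,
                function(p) any(p$tags %in% query$aliases),
                logical(1))
  canon_set(names(corpus$papers)[hit])
}

#' Collect citation pairs into a core paper set
#'
#' Scans the whole corpus for citations whose cited end lies in `core_ids`:
#' every (citing, cited) pair with `cited` in the core set, `citing` any
#' corpus paper whose reference list contains it. Pairs internal to the core
#' set are flagged in the `both_core` column. Reference lists have set
#' semantics, so a repeated mention counts once.
#'
#' @param corpus a [bib_corpus()].
#' @param core_ids character vector of paper ids, all present in the corpus.
#' @return data frame with columns `citing`, `cited` (character) and
#'   `both_core` (logical), sorted by citing then cited id.
#' @export
collect_citations <- function(corpus, core_ids) {
  stopifnot(inherits(corpus, "bib_corpus"))
  core_ids <- canon_set(core_ids)
  absent <- setdiff(core_ids, corpus_ids(corpus))
  if (length(absent)) {
    cf_precondition_error(sprintf("core id(s) not in corpus: %s",
                                  paste(absent, collapse = ", ")))
  }
  pieces <- lapply(corpus$papers, function(p) {
    hits <- p$references[p$references %in% core_ids]
    if (length(hits) == 0L) return(NULL)
    data.frame(citing = p$paper_id, cited = hits, stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  out <- if (length(pieces)) {
    do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  } else {
    data.frame(citing = character(0), cited = character(0),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$citing, out$cited, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out$both_core <- out$citing %in% core_ids
  out
}
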