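#' Integer distribution specification
#'
#' Bounded integer distribution used for per-paper counts. Values are drawn
#' from `min:max` with probability proportional to
#' \eqn{(v - min + 1)^{-skew}}: `skew = 0` is uniform, larger values favour
#' the small counts typical of affiliation and reference lists.
#'
#' @param min,max inclusive integer bounds, `0 <= min <= max`.
#' @param skew non-negative concentration toward `min`.
#' @return object of class `dist_spec`.
#' @export
dist_spec <- function(min, max, skew = 0) {
  min <- as.integer(min); max <- as.integer(max)
  stopifnot(min >= 0L, max >= min, skew >= 0)
  structure(list(min = min, max = max, skew = skew), class = "dist_spec")
}

draw_dist <- function(spec, n) {
  vals <- spec$min:spec$max
  if (length(vals) == 1L) return(rep.int(vals, n))
  p <- (seq_along(vals))^(-spec$skew)
  sample(vals, n, replace = TRUE, prob = p)
}

#' Generator configuration for synthetic corpora
#'
#' Describes a corpus with the statistical structure the network analyses
#' assume: heavy-tailed institutional activity (a Zipf-like law over
#' institutions, so a small fraction of institutions carries most of the
#' collaboration weight), a configurable industrial share of institutions,
#' multi-institution papers with authors nested inside institutions, and
#' references attaching preferentially to already-cited earlier papers.
#'
#' @param n_institutions number of institutions in the pool.
#' @param industrial_share probability that an institution is industrial.
#' @param n_papers number of papers to generate.
#' @param year_range length-2 integer vector of publication years.
#' @param institutions_per_paper [dist_spec()] for affiliations per paper.
#' @param authors_per_paper [dist_spec()] for authors per paper.
#' @param institution_activity_exponent Zipf exponent of institutional
#'   activity; 0 gives uniform participation, larger values concentrate
#'   papers on the top institutions.
#' @param citation_attachment_exponent preference exponent for reference
#'   targets: an earlier paper is drawn with probability proportional to
#'   `(1 + citations received so far) ^ exponent`; 0 is uniform.
#' @param refs_per_paper [dist_spec()] for references per paper.
#' @param tag_fraction fraction of papers carrying the focal tag.
#' @param focal_tag the focal tag string.
#' @param seed integer seed; the generator uses a single private random
#'   stream and never touches the caller's RNG state.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_institutions = 500L,
                             industrial_share = 0.2,
                             n_papers = 5000L,
                             year_range = c(1998L, 2017L),
                             institutions_per_paper = dist_spec(1, 5, 1.2),
                             authors_per_paper = dist_spec(1, 8, 0.8),
                             institution_activity_exponent = 1.0,
                             citation_attachment_exponent = 1.0,
                             refs_per_paper = dist_spec(0, 10, 0.5),
                             tag_fraction = 1.0,
                             focal_tag = "focal",
                             seed = 1L) {
  stopifnot(n_institutions >= 1L, n_papers >= 1L,
            industrial_share >= 0, industrial_share <= 1,
            tag_fraction >= 0, tag_fraction <= 1,
            institution_activity_exponent >= 0,
            citation_attachment_exponent >= 0,
            length(year_range) == 2L, year_range[1L] <= year_range[2L],
            inherits(institutions_per_paper, "dist_spec"),
            inherits(authors_per_paper, "dist_spec"),
            inherits(refs_per_paper, "dist_spec"))
  structure(
    list(n_institutions = as.integer(n_institutions),
         industrial_share = industrial_share,
         n_papers = as.integer(n_papers),
         year_range = as.integer(year_range),
         institutions_per_paper = institutions_per_paper,
         authors_per_paper = authors_per_paper,
         institution_activity_exponent = institution_activity_exponent,
         citation_attachment_exponent = citation_attachment_exponent,
         refs_per_paper = refs_per_paper,
         tag_fraction = tag_fraction,
         focal_tag = focal_tag,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Run expr under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_private_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' The three-paper worked-example corpus
#'
#' The textbook fixture for both network projections: paper II (year 2003,
#' institutions c, d, e) and paper III (2004, institutions c, d) are both
#' cited by paper I (2005, institutions a, b). Projecting it gives a
#' collaboration edge \{c, d\} of weight 2 with all other edges weight 1,
#' and knowledge flow of weight 2 from each of c and d to each of a and b,
#' and weight 1 from e to a and b. Author ids are distinct per institution
#' and per paper, so the corpus contains no self-citations under either
#' definition.
#'
#' @return a [bib_corpus()] with papers `I`, `II`, `III`.
#' @export
#' @examples
#' build_collaboration(fig1_corpus())$edges
fig1_corpus <- function() {
  bib_corpus(list(
    paper_record("I", 2005L, institutions = c("a", "b"),
                 authors = c("a.1", "b.1"),
                 references = c("II", "III"),
                 tags = "cholesterol"),
    paper_record("II", 2003L, institutions = c("c", "d", "e"),
                 authors = c("c.1", "d.1", "e.1"),
                 tags = "pcsk9"),
    paper_record("III", 2004L, institutions = c("c", "d"),
                 authors = c("c.2", "d.2"),
                 tags = "ldl")
  ))
}

#' Generate a synthetic corpus
#'
#' Papers receive uniform years over the configured range; each paper draws
#' its institutions without replacement with probability proportional to
#' the Zipf-like activity weight \eqn{r^{-\alpha}} of institution rank r;
#' authors are drawn from per-institution pools (nesting authors within
#' institutions); references go to strictly earlier-year papers with
#' probability proportional to \eqn{(1 + c)^{\beta}} where c is the number
#' of citations the target has accrued so far. When a paper requests more
#' references than there are earlier papers, the list is truncated (never
#' an error); the truncation count is recorded in the generator log.
#'
#' The result carries two attributes: `sector_map` (the planted industrial
#' / academic labels, see [synthetic_sector_map()]) and `generator_log`
#' (a list with `truncated_refs` and `n_no_institution`).
#'
#' @param cfg a [generator_config()].
#' @return a [bib_corpus()]; identical configurations yield byte-identical
#'   corpora when written with [write_corpus()].
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_private_seed(cfg$seed, {
    n_inst <- cfg$n_institutions
    inst_ids <- sprintf("INST%05d", seq_len(n_inst))
    activity <- seq_len(n_inst)^(-cfg$institution_activity_exponent)
    sectors <- ifelse(stats::runif(n_inst) < cfg$industrial_share,
                      "industrial", "academic")
    smap <- sector_map(stats::setNames(sectors, inst_ids))

    n <- cfg$n_papers
    yrs <- cfg$year_range[1L]:cfg$year_range[2L]
    years <- sort(yrs[sample.int(length(yrs), n, replace = TRUE)])
    ids <- sprintf("P%06d", seq_len(n))
    n_inst_per <- draw_dist(cfg$institutions_per_paper, n)
    n_auth_per <- draw_dist(cfg$authors_per_paper, n)
    n_refs_per <- draw_dist(cfg$refs_per_paper, n)
    tagged <- logical(n)
    n_tagged <- round(cfg$tag_fraction * n)
    if (n_tagged > 0L) tagged[sample.int(n, n_tagged)] <- TRUE

    # strictly-earlier eligibility: papers are in year order, so paper k may
    # cite papers 1..(first index of its year - 1)
    first_of_year <- match(years, years)
    cites <- integer(n)
    beta <- cfg$citation_attachment_exponent
    truncated <- 0L

    records <- vector("list", n)
    for (k in seq_len(n)) {
      ki <- min(n_inst_per[k], n_inst)
      inst_k <- if (ki > 0L) {
        inst_ids[sample.int(n_inst, ki, prob = activity)]
      } else character(0)
      na <- n_auth_per[k]
      auth_k <- if (na > 0L && length(inst_k) > 0L) {
        host <- inst_k[sample.int(length(inst_k), na, replace = TRUE)]
        sprintf("%s.a%02d", host, sample.int(30L, na, replace = TRUE))
      } else character(0)
      n_elig <- first_of_year[k] - 1L
      r <- min(n_refs_per[k], n_elig)
      if (r < n_refs_per[k]) truncated <- truncated + 1L
      refs_k <- if (r > 0L) {
        idx <- if (beta == 0) {
          sample.int(n_elig, r)
        } else {
          sample.int(n_elig, r, prob = (1 + cites[seq_len(n_elig)])^beta)
        }
        cites[idx] <- cites[idx] + 1L
        ids[idx]
      } else character(0)
      records[[k]] <- paper_record(
        ids[k], years[k],
        institutions = inst_k,
        authors = unique(auth_k),
        references = refs_k,
        tags = if (tagged[k]) cfg$focal_tag else character(0)
      )
    }
    corpus <- bib_corpus(records)
    attr(corpus, "sector_map") <- smap
    attr(corpus, "generator_log") <- list(
      truncated_refs = truncated,
      n_no_institution = attr(corpus, "n_no_institution")
    )
    corpus
  })
}

#' Planted sector map of a synthetic corpus
#' @param corpus a corpus produced by [generate_corpus()].
#' @return the `sector_map` planted by the generator.
#' @export
synthetic_sector_map <- function(corpus) {
  s <- attr(corpus, "sector_map")
  if (is.null(s)) cf_precondition_error("corpus carries no planted sector map")
  s
}
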