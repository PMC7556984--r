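# Classed conditions so callers can distinguish parse, schema, integrity,
# precondition and undefined-result failures programmatically.

cf_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "collabflow_error", "error")))
}

cf_parse_error        <- function(msg) cf_stop(msg, "collabflow_parse_error")
cf_schema_error       <- function(msg) cf_stop(msg, "collabflow_schema_error")
cf_integrity_error    <- function(msg) cf_stop(msg, "collabflow_integrity_error")
cf_precondition_error <- function(msg) cf_stop(msg, "collabflow_precondition_error")
cf_domain_error       <- function(msg) cf_stop(msg, "collabflow_domain_error")
cf_undefined_error    <- function(msg) cf_stop(msg, "collabflow_undefined_error")

#' Normalize a tag or alias string
#'
#' Lowercases, trims leading/trailing whitespace, and collapses internal
#' whitespace runs to a single space. All tag matching in the package is
#' exact string equality on normalized tags; no substring matching.
#'
#' @param x character vector of raw tags.
#' @return character vector of normalized tags.
#' @export
#' @examples
#' normalize_tag(c("  PCSK9 ", "Narc  1"))
normalize_tag <- function(x) {
  gsub("[[:space:]]+", " ", trimws(tolower(as.character(x))))
}

# Deterministic set canonicalization: unique + sorted (C locale).
canon_set <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- as.character(x)
  sort(unique(x[!is.na(x) & nzchar(x)]), method = "radix")
}
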