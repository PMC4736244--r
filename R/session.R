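# ---- analysis session ------------------------------------------------------

SESSION_SCHEMA <- "phenodiff-session/1"

#' Create an analysis session
#'
#' A session bundles the complete analysis state: the phenotype query, the
#' variant (or gene-list) input, every active filter and curation exclusion,
#' and the method/aggregation settings.  Sessions round-trip through
#' [save_session()] / [load_session()] unchanged.
#'
#' @param query_terms character vector of ontology term ids (the query Q).
#' @param variants data frame of variant records (see [read_vcf()]), or `NULL`.
#' @param method similarity metric: `"resnik"` (default), `"ato"`,
#'   `"ato_ic"` or `"ato_tic"`.
#' @param aggregation transitive aggregation function F: `"max"` (default),
#'   `"mean"` or `"sum"`.
#' @param inheritance genetic-model constraint: `"none"` (default),
#'   `"dominant"` or `"recessive"`.
#' @param required_terms term ids every retained disease must present
#'   (ancestrally matched).
#' @param excluded_diseases disease ids curated out of the differential.
#' @param require_morbidmap keep only diseases with gene links.
#' @param require_exome keep only diseases linked to genes variant in the
#'   session.
#' @param m_neighbors neighbors for the global-map query projection
#'   (default 5).
#' @param top_n number of top diseases used for local views and phenotype
#'   suggestion (default 500).
#' @param free_text opaque clinical narrative (stored, never parsed).
#' @param viz_settings,discovery_settings opaque named lists.
#' @param extra named list of unknown keys preserved for forward
#'   compatibility.
#' @return an object of class `pd_session`.
#' @export
new_session <- function(query_terms, variants = NULL,
                        method = "resnik", aggregation = "max",
                        inheritance = "none",
                        required_terms = character(),
                        excluded_diseases = character(),
                        require_morbidmap = FALSE, require_exome = FALSE,
                        m_neighbors = 5L, top_n = 500L, free_text = "",
                        viz_settings = list(), discovery_settings = list(),
                        extra = list()) {
  method <- match.arg(method, c("resnik", "ato", "ato_ic", "ato_tic"))
  aggregation <- match.arg(aggregation, c("max", "mean", "sum"))
  inheritance <- match.arg(inheritance, c("none", "dominant", "recessive"))
  if (length(query_terms) == 0L) stop("query must contain at least one term")
  structure(list(schema = SESSION_SCHEMA,
                 query_terms = as.character(query_terms),
                 variants = variants,
                 method = method, aggregation = aggregation,
                 inheritance = inheritance,
                 required_terms = as.character(required_terms),
                 excluded_diseases = as.character(excluded_diseases),
                 require_morbidmap = isTRUE(require_morbidmap),
                 require_exome = isTRUE(require_exome),
                 m_neighbors = as.integer(m_neighbors),
                 top_n = as.integer(top_n),
                 free_text = as.character(free_text),
                 viz_settings = viz_settings,
                 discovery_settings = discovery_settings,
                 extra = extra),
            class = "pd_session")
}

#' @export
print.pd_session <- function(x, ...) {
  cat("<pd_session> ", length(x$query_terms), " query terms; ",
      if (is.null(x$variants)) 0L else nrow(x$variants), " variants; method ",
      x$method, "/", x$aggregation, "; model ", x$inheritance, "; ",
      length(x$excluded_diseases), " exclusions\n", sep = "")
  invisible(x)
}

#' Save a session to JSON
#'
#' @param session a `pd_session`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "pd_session"))
  obj <- unclass(session)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns", pretty = TRUE)
  invisible(path)
}

.as_settings <- function(x) {
  x <- as.list(x)
  if (length(x) == 0L) list() else x
}

#' Load a session from JSON
#'
#' Unknown top-level keys are preserved in `$extra` and survive a
#' save/load round-trip.
#'
#' @param path JSON session file.
#' @return a `pd_session`.
#' @export
load_session <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse session file ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(obj$schema) || !identical(obj$schema, SESSION_SCHEMA))
    stop("session schema mismatch: file has ",
         if (is.null(obj$schema)) "<none>" else obj$schema,
         ", this package reads ", SESSION_SCHEMA)
  known <- c("schema", "query_terms", "variants", "method", "aggregation",
             "inheritance", "required_terms", "excluded_diseases",
             "require_morbidmap", "require_exome", "m_neighbors", "top_n",
             "free_text", "viz_settings", "discovery_settings", "extra")
  extra <- obj[setdiff(names(obj), known)]
  if (length(obj$extra) > 0L) extra <- c(obj$extra, extra)
  if (length(extra) == 0L) extra <- list()
  variants <- obj$variants
  if (!is.null(variants) && length(variants) > 0L) {
    variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  } else variants <- NULL
  new_session(query_terms = obj$query_terms, variants = variants,
              method = obj$method, aggregation = obj$aggregation,
              inheritance = obj$inheritance,
              required_terms = as.character(unlist(obj$required_terms)),
              excluded_diseases = as.character(unlist(obj$excluded_diseases)),
              require_morbidmap = obj$require_morbidmap,
              require_exome = obj$require_exome,
              m_neighbors = obj$m_neighbors, top_n = obj$top_n,
              free_text = obj$free_text,
              viz_settings = .as_settings(obj$viz_settings),
              discovery_settings = .as_settings(obj$discovery_settings),
              extra = .as_settings(extra))
}
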