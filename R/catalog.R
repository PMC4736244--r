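# ---- disease catalog -------------------------------------------------------

#' Construct a disease catalog
#'
#' @param diseases named list; each element a list with fields `id`, `name`,
#'   `terms` (character vector of ontology term ids), `inheritance`
#'   (character subset of `c("dominant","recessive","other")`), `genes`
#'   (character vector of gene symbols).
#' @return object of class `disease_catalog` with `diseases`, `N` (number of
#'   annotated diseases), `term_index` (term id -> disease ids annotated with
#'   that exact term) and `gene_index` (gene symbol -> disease ids).
#' @export
disease_catalog <- function(diseases) {
  stopifnot(is.list(diseases), length(diseases) > 0L)
  ids <- vapply(diseases, `[[`, "", "id")
  names(diseases) <- ids
  for (i in seq_along(diseases)) {
    d <- diseases[[i]]
    if (is.null(d$name)) d$name <- d$id
    if (is.null(d$inheritance)) d$inheritance <- character(0)
    if (is.null(d$genes)) d$genes <- character(0)
    d$terms <- unique(as.character(d$terms))
    diseases[[i]] <- d
  }
  annotated <- vapply(diseases, function(d) length(d$terms) > 0L, logical(1))
  term_index <- list()
  for (d in diseases[annotated])
    for (t in d$terms)
      term_index[[t]] <- c(term_index[[t]], d$id)
  gene_index <- list()
  for (d in diseases)
    for (g in d$genes)
      gene_index[[g]] <- unique(c(gene_index[[g]], d$id))
  structure(list(diseases = diseases, N = sum(annotated),
                 term_index = term_index, gene_index = gene_index),
            class = "disease_catalog")
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat("<disease_catalog> ", length(x$diseases), " diseases (", x$N,
      " annotated), ", length(x$gene_index), " linked genes\n", sep = "")
  invisible(x)
}

#' Load disease-phenotype annotations
#'
#' Reads a tab-separated annotation file with (at least) three columns:
#' disease id, disease name, phenotype term id.  Lines starting with `#` are
#' comments.  Term ids are remapped through the ontology's alternate-id
#' index; rows whose term cannot be resolved are dropped with a logged
#' count.  Rows sharing a disease id are merged (union of terms).
#'
#' @param path annotation TSV path.
#' @param dag an [ontology_dag].
#' @return a [disease_catalog] (gene links empty until [load_gene_map()]).
#' @export
load_annotations <- function(path, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, comment.char = "#",
                      colClasses = "character", quote = ""),
    error = function(e) stop("cannot read annotation file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop("annotation file is empty: ", path)
  if (ncol(df) < 3L) {
    warning("annotation file has fewer than 3 columns; malformed rows skipped")
    stop("no parseable annotation rows in ", path)
  }
  ok <- nzchar(df[[1]]) & nzchar(df[[3]])
  if (any(!ok)) warning(sum(!ok), " malformed annotation row(s) skipped")
  df <- df[ok, , drop = FALSE]

  term <- as.character(df[[3]])
  # resolve: primary ids pass, alt ids remap, others drop
  resolved <- term
  miss <- !(resolved %in% dag$ids)
  remap <- dag$alt_ids[resolved[miss]]
  resolved[miss] <- ifelse(is.na(remap), NA_character_, remap)
  resolved[resolved %in% dag$obsolete] <- NA_character_
  dropped <- sum(is.na(resolved))
  if (dropped > 0L)
    message(dropped, " annotation row(s) with unresolvable terms dropped")
  keep <- !is.na(resolved)
  did <- as.character(df[[1]])[keep]
  dname <- as.character(df[[2]])[keep]
  term <- resolved[keep]
  if (length(did) == 0L) stop("no resolvable annotation rows in ", path)

  split_terms <- split(term, did)
  first_name <- tapply(dname, did, `[`, 1L)
  diseases <- lapply(names(split_terms), function(id)
    list(id = id, name = unname(first_name[[id]]),
         terms = unique(split_terms[[id]]),
         inheritance = character(0), genes = character(0)))
  disease_catalog(diseases)
}

#' Load disease-gene links (Morbidmap-like)
#'
#' Reads a tab-separated file whose first column is a disease phenotype
#' label containing the disease id (either the catalog id itself, or a
#' 6-digit MIM-style number, with an optional trailing mapping-key
#' \dQuote{(n)}), second column a comma-separated gene symbol list, and an
#' optional third column with an inheritance annotation (`AD`, `AR`,
#' anything else -> other/unknown).  Rows whose disease id cannot be matched
#' to the catalog are skipped with a warning.
#'
#' @param path gene-map TSV path.
#' @param catalog a [disease_catalog].
#' @param alias optional named character vector remapping gene symbols
#'   (alias -> canonical), e.g. from [read_alias_table()].
#' @return the catalog with `genes`, `inheritance` and `gene_index` filled.
#' @export
load_gene_map <- function(path, catalog, alias = NULL) {
  stopifnot(inherits(catalog, "disease_catalog"))
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("gene map file needs at least 2 columns: ", path)
  known <- names(catalog$diseases)
  skipped <- 0L
  for (i in seq_len(nrow(df))) {
    label <- trimws(df[i, 1])
    id <- .resolve_disease_label(label, known)
    if (is.na(id)) { skipped <- skipped + 1L; next }
    genes <- trimws(strsplit(df[i, 2], ",")[[1]])
    genes <- genes[nzchar(genes)]
    if (!is.null(alias)) {
      hit <- genes %in% names(alias)
      genes[hit] <- unname(alias[genes[hit]])
    }
    inh <- if (ncol(df) >= 3L) trimws(df[i, 3]) else ""
    mode <- switch(toupper(inh), AD = "dominant", AR = "recessive",
                   if (nzchar(inh)) "other" else NULL)
    d <- catalog$diseases[[id]]
    d$genes <- unique(c(d$genes, genes))
    if (!is.null(mode)) d$inheritance <- unique(c(d$inheritance, mode))
    catalog$diseases[[id]] <- d
  }
  if (skipped > 0L)
    warning(skipped, " gene map row(s) with unparsable disease ids skipped")
  disease_catalog(catalog$diseases)
}

# Match a Morbidmap-style phenotype label to a catalog disease id.
.resolve_disease_label <- function(label, known_ids) {
  stripped <- trimws(sub("\\s*\\([0-9]\\)\\s*$", "", label))
  if (stripped %in% known_ids) return(stripped)
  num <- regmatches(stripped, regexpr("[0-9]{6}", stripped))
  if (length(num) == 1L) {
    for (cand in c(num, paste0("OMIM:", num)))
      if (cand %in% known_ids) return(cand)
  }
  # last comma-separated token, e.g. "Toy syndrome, D4"
  tok <- trimws(utils::tail(strsplit(stripped, ",")[[1]], 1))
  if (tok %in% known_ids) return(tok)
  NA_character_
}

#' Diseases annotated at or below a term
#'
#' Union of the exact-term disease index over the reflexive-transitive
#' descendant closure of `t` - the count `||d{C{t}}||` that feeds the
#' information content.
#'
#' @param catalog a [disease_catalog].
#' @param dag an [ontology_dag].
#' @param t a single term id.
#' @return character vector of disease ids.
#' @export
diseases_at_or_below <- function(catalog, dag, t) {
  stopifnot(inherits(catalog, "disease_catalog"))
  ds <- descendants(dag, t)
  unique(unlist(catalog$term_index[ds], use.names = FALSE))
}

#' Catalog-based information content
#'
#' For every term with at least one disease annotated at or below it,
#' `ic[t] = -log(||d{C{t}}|| / N)` (natural log), where N is the number of
#' annotated diseases.  Rare terms are informative; the root (below which
#' everything is annotated) has IC 0.  Terms with zero annotations are
#' excluded: they carry no IC and are dropped from catalog-weighted
#' similarity.
#'
#' @param catalog a [disease_catalog].
#' @param dag an [ontology_dag].
#' @return object of class `catalog_ic`: list with `ic` (named numeric, on
#'   annotated terms only), `annotated` (their ids) and `N`.
#' @export
catalog_information_content <- function(catalog, dag) {
  stopifnot(inherits(catalog, "disease_catalog"), inherits(dag, "ontology_dag"))
  if (catalog$N == 0L) stop("catalog has no annotated diseases")
  counts <- vapply(dag$ids, function(t)
    length(unique(unlist(catalog$term_index[dag$des[[t]]], use.names = FALSE))),
    integer(1))
  annotated <- dag$ids[counts > 0L]
  ic <- -log(counts[annotated] / catalog$N)
  structure(list(ic = ic, annotated = annotated, N = catalog$N),
            class = "catalog_ic")
}

#' @export
print.catalog_ic <- function(x, ...) {
  cat("<catalog_ic> ", length(x$annotated), " annotated terms, N = ",
      x$N, "\n", sep = "")
  invisible(x)
}
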