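# ---- semantic similarity metrics -------------------------------------------

# Best common-ancestor IC for one term against a set of terms: for each
# t2 in `others`, the MICA IC is the max IC over A{t1} n A{t2}; return the
# max over t2 (the best match for t1).
.best_match_ic <- function(dag, ic_vec, t1, others) {
  a1 <- dag$anc[[t1]]
  best <- 0
  for (t2 in others) {
    common <- a1[a1 %in% dag$anc[[t2]]]
    vals <- ic_vec[common]
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0L) best <- max(best, max(vals))
  }
  best
}

# Drop terms without catalog IC (the exclusion rule for catalog-weighted
# metrics); error if nothing remains.
.keep_annotated <- function(terms, ic, what) {
  kept <- terms[terms %in% ic$annotated]
  if (length(kept) < length(terms))
    message(length(terms) - length(kept), " ", what,
            " term(s) without catalog annotation dropped")
  if (length(kept) == 0L)
    stop("all ", what, " terms lack catalog annotations; ",
         "use the ato or ato_tic metric instead")
  kept
}

#' Symmetrized Resnik similarity
#'
#' Best-match-average similarity between two phenotype term sets.  For each
#' term of one set, the best match in the other set is the maximum
#' information content over their common ancestors (the MICA); the two
#' directional best-match averages are themselves averaged.  Terms without
#' catalog annotations carry no IC and are dropped before scoring.
#'
#' @param q_terms character vector of query term ids (Q).
#' @param d_terms character vector of disease term ids (D).
#' @param ic a [catalog_information_content()] result.
#' @param dag an [ontology_dag].
#' @return similarity in nats (>= 0).
#' @export
resnik_similarity <- function(q_terms, d_terms, ic, dag) {
  stopifnot(inherits(ic, "catalog_ic"), inherits(dag, "ontology_dag"))
  q <- .keep_annotated(resolve_term(dag, unique(q_terms), "query"), ic, "query")
  d <- .keep_annotated(resolve_term(dag, unique(d_terms), "disease"), ic, "disease")
  fwd <- mean(vapply(d, .best_match_ic, 0, dag = dag, ic_vec = ic$ic, others = q))
  rev <- mean(vapply(q, .best_match_ic, 0, dag = dag, ic_vec = ic$ic, others = d))
  0.5 * fwd + 0.5 * rev
}

#' Ancestral term overlap (ATO)
#'
#' The number of ontology nodes shared between the ancestral closures of the
#' two term sets: each shared node counts once, regardless of how many term
#' pairs recruit it.
#'
#' @inheritParams resnik_similarity
#' @return integer count.
#' @export
ato_similarity <- function(q_terms, d_terms, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  length(intersect(ancestral_closure(dag, q_terms),
                   ancestral_closure(dag, d_terms)))
}

#' Weighted ancestral term overlap
#'
#' Like [ato_similarity()], but each shared closure node contributes its
#' weight instead of 1.  With catalog IC weights (`catalog_ic`),
#' unannotated terms are excluded; with topological weights
#' (`topo_weights`), every term has a weight (TIC).
#'
#' @inheritParams resnik_similarity
#' @param weights a `catalog_ic` or `topo_weights` object.
#' @return weighted overlap (>= 0).
#' @export
weighted_ato_similarity <- function(q_terms, d_terms, dag, weights) {
  stopifnot(inherits(dag, "ontology_dag"))
  shared <- intersect(ancestral_closure(dag, q_terms),
                      ancestral_closure(dag, d_terms))
  if (inherits(weights, "catalog_ic")) {
    shared <- shared[shared %in% weights$annotated]
    sum(weights$ic[shared])
  } else if (inherits(weights, "topo_weights")) {
    sum(weights$tic[shared])
  } else if (is.numeric(weights)) {            # named weight vector
    sum(weights[shared], na.rm = TRUE)
  } else stop("unsupported weights object")
}

# Internal dispatcher: score one disease term set against prepared query data.
.score_one <- function(method, q, d_terms, dag, ic, tw) {
  switch(method,
    resnik = {
      d <- d_terms[d_terms %in% ic$annotated]
      if (length(d) == 0L) return(0)
      fwd <- mean(vapply(d, .best_match_ic, 0, dag = dag, ic_vec = ic$ic, others = q))
      rev <- mean(vapply(q, .best_match_ic, 0, dag = dag, ic_vec = ic$ic, others = d))
      0.5 * fwd + 0.5 * rev
    },
    ato = length(intersect(q, unique(unlist(dag$anc[d_terms], use.names = FALSE)))),
    ato_ic = {
      shared <- intersect(q, unique(unlist(dag$anc[d_terms], use.names = FALSE)))
      shared <- shared[shared %in% ic$annotated]
      sum(ic$ic[shared])
    },
    ato_tic = {
      shared <- intersect(q, unique(unlist(dag$anc[d_terms], use.names = FALSE)))
      sum(tw$tic[shared])
    },
    stop("unknown method: ", method))
}

#' Score a phenotype query against every annotated disease
#'
#' Computes one similarity score per annotated catalog disease and returns
#' the ranked list (descending score).  Ties receive the minimum
#' (competition) rank; within a tie, diseases are ordered by id for
#' determinism.
#'
#' @param q_terms character vector of query term ids.
#' @param catalog a [disease_catalog].
#' @param dag an [ontology_dag].
#' @param method one of `"resnik"`, `"ato"`, `"ato_ic"`, `"ato_tic"`.
#' @param ic optional precomputed [catalog_information_content()]; computed
#'   on the fly when needed.
#' @param topo optional precomputed [topological_weights()].
#' @return data frame with columns `rank`, `disease_id`, `name`, `score`,
#'   `method`.
#' @export
score_all_diseases <- function(q_terms, catalog, dag,
                               method = c("resnik", "ato", "ato_ic", "ato_tic"),
                               ic = NULL, topo = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(catalog, "disease_catalog"))
  if (catalog$N == 0L) stop("catalog has no annotated diseases")
  if (method %in% c("resnik", "ato_ic") && is.null(ic))
    ic <- catalog_information_content(catalog, dag)
  if (method == "ato_tic" && is.null(topo)) topo <- topological_weights(dag)

  qt <- resolve_term(dag, unique(q_terms), "query")
  if (method %in% c("resnik", "ato_ic"))
    qt <- .keep_annotated(qt, ic, "query")
  q_prepared <- if (method == "resnik") qt else ancestral_closure(dag, qt)

  ann <- Filter(function(d) length(d$terms) > 0L, catalog$diseases)
  scores <- vapply(ann, function(d)
    .score_one(method, q_prepared, d$terms, dag, ic, topo), 0)
  out <- data.frame(disease_id = vapply(ann, `[[`, "", "id"),
                    name = vapply(ann, `[[`, "", "name"),
                    score = unname(scores),
                    method = method,
                    stringsAsFactors = FALSE, row.names = NULL)
  rerank_diseases(out)
}

#' Recompute competition ranks on a scored disease table
#'
#' Sorts descending by score (ties by disease id ascending) and assigns
#' minimum-rank ("competition") ranks.
#'
#' @param scored data frame with at least `disease_id` and `score`.
#' @return the same data frame, sorted, with a `rank` column.
#' @export
rerank_diseases <- function(scored) {
  scored <- scored[order(-scored$score, scored$disease_id), , drop = FALSE]
  scored$rank <- rank(-scored$score, ties.method = "min")
  rownames(scored) <- NULL
  scored[, c("rank", setdiff(names(scored), "rank")), drop = FALSE]
}

#' Pairwise disease similarity matrix
#'
#' Symmetric matrix of similarities between all annotated diseases (each
#' disease's term set treated as a query), used for class signal-to-noise
#' analysis and map layouts.
#'
#' @inheritParams score_all_diseases
#' @param disease_ids optional subset of disease ids (default: all annotated).
#' @return numeric matrix with disease ids as dimnames.
#' @export
similarity_matrix <- function(catalog, dag,
                              method = c("resnik", "ato", "ato_ic", "ato_tic"),
                              ic = NULL, topo = NULL, disease_ids = NULL) {
  method <- match.arg(method)
  if (method %in% c("resnik", "ato_ic") && is.null(ic))
    ic <- catalog_information_content(catalog, dag)
  if (method == "ato_tic" && is.null(topo)) topo <- topological_weights(dag)
  ann <- Filter(function(d) length(d$terms) > 0L, catalog$diseases)
  if (!is.null(disease_ids)) {
    miss <- setdiff(disease_ids, names(ann))
    if (length(miss) > 0L) stop("unknown/unannotated disease id(s): ",
                                paste(miss, collapse = ", "))
    ann <- ann[disease_ids]
  }
  ids <- names(ann)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  prepared <- lapply(ann, function(d) {
    terms <- d$terms
    if (method %in% c("resnik", "ato_ic"))
      terms <- terms[terms %in% ic$annotated]
    if (method == "resnik") terms
    else unique(unlist(dag$anc[terms], use.names = FALSE))
  })
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <-
        .score_one(method, prepared[[i]], ann[[j]]$terms, dag, ic, topo)
    }
  }
  m
}

#' Within- versus between-class signal-to-noise of a similarity metric
#'
#' For predefined classes of related diseases, computes the mean pairwise
#' similarity inside each class (unordered member pairs, self-pairs
#' excluded), the mean similarity of members to all non-members, and their
#' quotient (SNR).  Classes with fewer than 2 resolvable members are skipped
#' with a warning; a between-class mean of 0 makes the SNR undefined (NA
#' with a warning).
#'
#' @inheritParams score_all_diseases
#' @param classes named list: class id -> character vector of disease ids.
#' @param min_size minimum class size to analyze (default 2; the class-level
#'   catalog analysis conventionally uses 6).
#' @return data frame with `class_id`, `n_members`, `within_mean`,
#'   `between_mean`, `snr`.
#' @export
class_signal_to_noise <- function(catalog, dag, classes,
                                  method = c("resnik", "ato", "ato_ic", "ato_tic"),
                                  ic = NULL, topo = NULL, min_size = 2L) {
  method <- match.arg(method)
  sim <- similarity_matrix(catalog, dag, method, ic = ic, topo = topo)
  all_ids <- rownames(sim)
  rows <- list()
  for (cl in names(classes)) {
    members <- intersect(classes[[cl]], all_ids)
    if (length(members) < max(2L, min_size)) {
      warning("class ", cl, " skipped: fewer than ", max(2L, min_size),
              " resolvable members")
      next
    }
    others <- setdiff(all_ids, members)
    wm <- sim[members, members, drop = FALSE]
    within <- mean(wm[upper.tri(wm)])
    between <- if (length(others) > 0L)
      mean(sim[members, others, drop = FALSE]) else NA_real_
    snr <- if (!is.na(between) && between > 0) within / between else {
      warning("class ", cl, ": between-class mean is 0 or undefined; SNR NA")
      NA_real_
    }
    rows[[cl]] <- data.frame(class_id = cl, n_members = length(members),
                             within_mean = within, between_mean = between,
                             snr = snr, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no analyzable classes")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
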