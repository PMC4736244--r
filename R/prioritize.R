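# ---- transitive prioritization of genes and variants -----------------------

#' Inheritance-model check for one gene's variants
#'
#' Decides whether the variants observed in a gene are compatible with a
#' genetic-model constraint.  Under no constraint everything passes; a
#' dominant model needs a single variant; a recessive model needs a
#' homozygous variant or at least two distinct variants in the gene
#' (compound heterozygosity being possible - phase is unknown, so
#' possibility suffices).  When a disease with known inheritance modes is
#' supplied, a constraint that is absent from those modes also fails;
#' diseases with unknown/other modes are unaffected.
#'
#' @param gene gene symbol (for messages only).
#' @param variants data frame of variant records restricted to this gene,
#'   with a `zygosity` column (`"het"`/`"hom"`).
#' @param disease optional disease (list with `inheritance`), as stored in a
#'   [disease_catalog].
#' @param constraint `"none"`, `"dominant"` or `"recessive"`.
#' @return logical scalar.
#' @export
check_inheritance <- function(gene, variants, disease = NULL,
                              constraint = c("none", "dominant", "recessive")) {
  constraint <- match.arg(constraint)
  if (constraint == "none") return(TRUE)
  if (!is.null(disease)) {
    modes <- setdiff(disease$inheritance, "other")
    if (length(modes) > 0L && !(constraint %in% modes)) return(FALSE)
  }
  n <- if (is.null(variants)) 0L else nrow(variants)
  if (constraint == "dominant") return(n >= 1L)
  n >= 2L || (n >= 1L && any(variants$zygosity == "hom"))
}

#' Apply restriction and curation filters to a ranked disease list
#'
#' Filters the exhaustively scored disease list down to the active
#' differential, in order: (1) gene-link (Morbidmap) restriction; (2)
#' exome-link restriction (disease genes intersect the session's variant
#' genes); (3) inheritance-model restriction via [check_inheritance()];
#' (4) required-phenotype restriction: a disease survives iff its ancestral
#' closure contains every required term (approximate/ancestral matching; set
#' `exact_required = TRUE` in the session's `viz_settings` for exact-only);
#' (5) curation: excluded diseases removed.  Every step is a subset
#' operation, so relative score order is unchanged; ranks are recomputed.
#'
#' @param session a [new_session()].
#' @param scored data frame from [score_all_diseases()].
#' @param catalog a [disease_catalog].
#' @param dag an [ontology_dag].
#' @return filtered, re-ranked data frame.
#' @export
qualify_diseases <- function(session, scored, catalog, dag) {
  stopifnot(inherits(session, "pd_session"))
  keep <- scored$disease_id
  dis <- catalog$diseases
  variant_genes <- session_variant_genes(session)

  if (session$require_morbidmap)
    keep <- keep[vapply(dis[keep], function(d) length(d$genes) > 0L, logical(1))]
  if (session$require_exome)
    keep <- keep[vapply(dis[keep], function(d)
      length(intersect(d$genes, variant_genes)) > 0L, logical(1))]
  if (session$inheritance != "none") {
    has_variants <- length(variant_genes) > 0L
    if (has_variants) .check_variants_usable(session)
    keep <- keep[vapply(dis[keep], function(d) {
      modes <- setdiff(d$inheritance, "other")
      if (length(modes) > 0L && !(session$inheritance %in% modes))
        return(FALSE)                    # known modes exclude the constraint
      if (!has_variants) return(TRUE)    # disease-only workflow: mode check only
      genes_with_variants <- intersect(d$genes, variant_genes)
      any(vapply(genes_with_variants, function(g)
        check_inheritance(g, .gene_variants(session, g), NULL,
                          session$inheritance), logical(1)))
    }, logical(1))]
  }
  if (length(session$required_terms) > 0L) {
    req <- resolve_term(dag, session$required_terms, "required")
    exact <- isTRUE(session$viz_settings$exact_required)
    keep <- keep[vapply(dis[keep], function(d) {
      pool <- if (exact) d$terms else ancestral_closure(dag, d$terms)
      all(req %in% pool)
    }, logical(1))]
  }
  keep <- setdiff(keep, session$excluded_diseases)
  rerank_diseases(scored[scored$disease_id %in% keep,
                         setdiff(names(scored), "rank"), drop = FALSE])
}

# gene symbols carried by the session's variant input
session_variant_genes <- function(session) {
  if (is.null(session$variants) || nrow(session$variants) == 0L)
    return(character(0))
  unique(session$variants$gene)
}

.gene_variants <- function(session, gene) {
  v <- session$variants
  v[v$gene == gene, , drop = FALSE]
}

.check_variants_usable <- function(session) {
  v <- session$variants
  if (!is.null(v) && nrow(v) > 0L && "source" %in% names(v) &&
      all(v$source == "gene_list"))
    stop("inheritance constraints need zygosity information; ",
         "a bare gene list provides none (use constraint \"none\")")
  invisible(TRUE)
}

#' Transitive gene score
#'
#' Aggregates the scores of the qualified diseases cataloged to result from
#' variants in a gene - the transitive diagnostic relevance of the gene to
#' the query.  Excluded (curated-out) diseases are absent from `qualified`
#' and therefore never contribute.
#'
#' @param gene gene symbol.
#' @param qualified qualified scored-disease data frame
#'   (from [qualify_diseases()]).
#' @param catalog a [disease_catalog].
#' @param aggregation `"max"` (default), `"mean"` or `"sum"`.
#' @return a list of class `gene_score` (`gene`, `score`, `aggregation`,
#'   `supporting` data frame), or `NULL` when the gene has no qualified
#'   supporting disease (unscored).
#' @export
transitive_gene_score <- function(gene, qualified, catalog,
                                  aggregation = c("max", "mean", "sum")) {
  aggregation <- match.arg(aggregation)
  linked <- catalog$gene_index[[gene]]
  sup <- qualified[qualified$disease_id %in% linked, , drop = FALSE]
  if (nrow(sup) == 0L) return(NULL)
  f <- switch(aggregation, max = max, mean = mean, sum = sum)
  structure(list(gene = gene, score = f(sup$score), aggregation = aggregation,
                 supporting = sup[, c("disease_id", "score", "rank")]),
            class = "gene_score")
}

#' Rank variants transitively against the phenotype query
#'
#' Full pipeline: score every disease, apply the session's filters, score
#' each variant gene by aggregating its qualified supporting diseases, and
#' let variants inherit their gene's score.  Genes are ordered by score
#' descending with competition ranks; within a gene, variants are ordered by
#' pathogenicity descending, then MAF ascending (missing last), then
#' position.  Genes with no qualified catalog link are unscored and their
#' variants are reported separately.
#'
#' @param session a [new_session()] with variants.
#' @param catalog a [disease_catalog].
#' @param dag an [ontology_dag].
#' @param ic,topo optional precomputed weights.
#' @return list of class `pd_ranking`: `variants` (ranked data frame),
#'   `genes` (gene-level data frame), `gene_scores` (list of `gene_score`),
#'   `unscored_genes`, `unscored_variants`, `qualified` (the filtered
#'   disease differential).
#' @export
rank_variants <- function(session, catalog, dag, ic = NULL, topo = NULL) {
  stopifnot(inherits(session, "pd_session"))
  if (is.null(session$variants) || nrow(session$variants) == 0L)
    stop("session has no variants")
  scored <- score_all_diseases(session$query_terms, catalog, dag,
                               session$method, ic = ic, topo = topo)
  qualified <- qualify_diseases(session, scored, catalog, dag)
  genes <- unique(session$variants$gene)
  gs <- lapply(genes, transitive_gene_score, qualified = qualified,
               catalog = catalog, aggregation = session$aggregation)
  names(gs) <- genes
  scored_genes <- genes[!vapply(gs, is.null, logical(1))]
  if (length(scored_genes) == 0L) {
    warning("no variant gene maps to any qualified catalog disease")
    return(structure(list(variants = NULL, genes = NULL, gene_scores = gs,
                          unscored_genes = genes,
                          unscored_variants = session$variants,
                          qualified = qualified), class = "pd_ranking"))
  }
  gtab <- data.frame(
    gene = scored_genes,
    score = vapply(gs[scored_genes], `[[`, 0, "score"),
    aggregation = session$aggregation,
    top_supporting_disease = vapply(gs[scored_genes], function(x)
      x$supporting$disease_id[which.max(x$supporting$score)], ""),
    disease_rank = vapply(gs[scored_genes], function(x)
      as.integer(min(x$supporting$rank)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  gtab <- gtab[order(-gtab$score, gtab$gene), , drop = FALSE]
  gtab$rank <- rank(-gtab$score, ties.method = "min")
  rownames(gtab) <- NULL

  v <- session$variants
  ranked <- v[v$gene %in% scored_genes, , drop = FALSE]
  ranked$score <- gtab$score[match(ranked$gene, gtab$gene)]
  ranked$rank <- gtab$rank[match(ranked$gene, gtab$gene)]
  # within-gene order: pathogenicity desc (NA last), MAF asc (NA last), pos
  path_key <- ifelse(is.na(ranked$pathogenicity), -Inf, ranked$pathogenicity)
  maf_key <- ifelse(is.na(ranked$maf), Inf, ranked$maf)
  ranked <- ranked[order(ranked$rank, ranked$gene, -path_key, maf_key,
                         ranked$pos), , drop = FALSE]
  rownames(ranked) <- NULL
  unscored <- setdiff(genes, scored_genes)
  structure(list(variants = ranked,
                 genes = gtab[, c("rank", "gene", "score", "aggregation",
                                  "top_supporting_disease", "disease_rank")],
                 gene_scores = gs,
                 unscored_genes = unscored,
                 unscored_variants = v[v$gene %in% unscored, , drop = FALSE],
                 qualified = qualified),
            class = "pd_ranking")
}

#' @export
print.pd_ranking <- function(x, ...) {
  cat("<pd_ranking> ",
      if (is.null(x$genes)) 0L else nrow(x$genes), " scored genes, ",
      length(x$unscored_genes), " unscored; differential of ",
      nrow(x$qualified), " diseases\n", sep = "")
  if (!is.null(x$genes)) print(utils::head(x$genes, 10L))
  invisible(x)
}

#' Phenotype-collapsed comparator gene score
#'
#' Scores a gene by the symmetrized Resnik similarity of the query to the
#' union of phenotype terms over every disease the gene is cataloged to
#' cause, treated as one pseudo-disease (the phenotype-collapsing strategy
#' used by direct gene-rank tools).
#'
#' @param gene gene symbol.
#' @param q_terms query term ids.
#' @param catalog a [disease_catalog].
#' @param dag an [ontology_dag].
#' @param ic a [catalog_information_content()] result.
#' @return Resnik score, or `NA` if the gene has no annotated linked disease.
#' @export
gene_score_collapsed <- function(gene, q_terms, catalog, dag, ic) {
  linked <- catalog$gene_index[[gene]]
  if (is.null(linked)) return(NA_real_)
  terms <- unique(unlist(lapply(catalog$diseases[linked], `[[`, "terms"),
                         use.names = FALSE))
  if (length(terms) == 0L) return(NA_real_)
  resnik_similarity(q_terms, terms, ic, dag)
}

#' Direct term-to-gene comparator gene score
#'
#' Scores a gene by the symmetrized Resnik similarity of the query to the
#' gene's own term annotations from a term-to-gene table.
#'
#' @param gene gene symbol.
#' @param q_terms query term ids.
#' @param gene_term_map named list: gene symbol -> character vector of term
#'   ids.
#' @param dag an [ontology_dag].
#' @param ic a [catalog_information_content()] result.
#' @return Resnik score, or `NA` if the gene is absent from the table.
#' @export
gene_score_direct <- function(gene, q_terms, gene_term_map, dag, ic) {
  terms <- gene_term_map[[gene]]
  if (is.null(terms) || length(terms) == 0L) return(NA_real_)
  resnik_similarity(q_terms, terms, ic, dag)
}

#' Suggest informative phenotypes to extend the query
#'
#' Collects the phenotype terms annotated to the `top_n` highest-scoring
#' diseases, removes the query terms and all their ancestors, and returns
#' the `k` rarest (highest catalog IC) remaining terms, ties broken by term
#' id.  These are the observations most likely to discriminate among the
#' current top candidates.
#'
#' @param q_terms query term ids.
#' @param scored scored-disease data frame (ranked).
#' @param catalog a [disease_catalog].
#' @param dag an [ontology_dag].
#' @param ic a [catalog_information_content()] result.
#' @param top_n number of top diseases to harvest terms from.
#' @param k maximum number of suggestions.
#' @return character vector of term ids (possibly shorter than `k`).
#' @export
suggest_phenotypes <- function(q_terms, scored, catalog, dag, ic,
                               top_n = 10L, k = 5L) {
  stopifnot(k >= 1L, nrow(scored) > 0L)
  top <- utils::head(scored$disease_id, top_n)
  cand <- unique(unlist(lapply(catalog$diseases[top], `[[`, "terms"),
                        use.names = FALSE))
  cand <- setdiff(cand, ancestral_closure(dag, resolve_term(dag, q_terms)))
  cand <- cand[cand %in% ic$annotated]
  if (length(cand) == 0L) return(character(0))
  cand <- cand[order(-ic$ic[cand], cand)]
  utils::head(cand, k)
}

#' Shared versus disease-only phenotypes (approximate matching)
#'
#' Splits a disease's annotated terms into those shared with the query -
#' where sharing incorporates ontological ancestry: a disease term counts as
#' shared when its ancestor set meets the query's ancestral closure anywhere
#' above the root - and the remaining disease-only (hallmark) terms.
#'
#' @param disease_terms character vector of the disease's term ids.
#' @param q_terms query term ids.
#' @param dag an [ontology_dag].
#' @return list with `shared` and `disease_only` character vectors.
#' @export
shared_phenotypes <- function(disease_terms, q_terms, dag) {
  qc <- setdiff(ancestral_closure(dag, q_terms), dag$root)
  dt <- resolve_term(dag, unique(disease_terms), "disease")
  shared <- vapply(dt, function(t)
    length(intersect(setdiff(dag$anc[[t]], dag$root), qc)) > 0L, logical(1))
  list(shared = dt[shared], disease_only = dt[!shared])
}

#' Relative information-content weights of the query terms
#'
#' Weight of each query term relative to the most informative one
#' (`ic / max(ic)`), as used to size terms in a query wordcloud.  If every
#' term has IC 0 the weights degenerate to 1.
#'
#' @param q_terms query term ids.
#' @param ic a [catalog_information_content()] result.
#' @return named numeric vector in (0, 1].
#' @export
query_term_weights <- function(q_terms, ic) {
  q <- unique(as.character(q_terms))
  miss <- setdiff(q, ic$annotated)
  if (length(miss) > 0L)
    stop("query term(s) without catalog IC: ", paste(miss, collapse = ", "))
  vals <- ic$ic[q]
  top <- max(vals)
  if (top == 0) return(stats::setNames(rep(1, length(q)), q))
  stats::setNames(as.numeric(vals / top), q)
}
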