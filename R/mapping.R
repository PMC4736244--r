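# ---- global map (classical MDS) and radar layout ---------------------------

#' Similarity to dissimilarity
#'
#' Subtracts every similarity from the maximum observed score, so the most
#' similar pair is at dissimilarity 0; the diagonal is then forced to 0
#' (self-dissimilarity is 0 by definition even when a metric's self-score is
#' not the global maximum).
#'
#' @param scores symmetric numeric similarity matrix (dimnames = ids).
#' @param tol asymmetry tolerance (default 1e-9).
#' @return object of class `dissimilarity_matrix`: list with `ids`, `values`.
#' @export
to_dissimilarity <- function(scores, tol = 1e-9) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  if (!all(is.finite(scores))) stop("similarity matrix has non-finite entries")
  if (max(abs(scores - t(scores))) > tol)
    stop("similarity matrix is not symmetric within tolerance ", tol)
  d <- max(scores) - scores
  diag(d) <- 0
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(scores)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, values = d), class = "dissimilarity_matrix")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a dissimilarity matrix into `k` dimensions (k in 1..3) by double
#' centering and eigendecomposition (via [stats::cmdscale()]).  Coordinates
#' are scaled eigenvectors, column-centered; if fewer than `k` positive
#' eigenvalues exist, the missing columns are zero-filled with a warning.
#' Each coordinate column is sign-canonicalized (first nonzero entry
#' positive) so repeated runs are deterministic.
#'
#' @param d a [to_dissimilarity()] result or a symmetric matrix.
#' @param k target dimension, 1..3.
#' @return object of class `map_layout`: list with `ids`, `coords`
#'   (n x k matrix) and `eigenvalues` (the k leading values).
#' @export
classical_mds <- function(d, k = 2L) {
  if (inherits(d, "dissimilarity_matrix")) { ids <- d$ids; dm <- d$values }
  else { dm <- as.matrix(d); ids <- rownames(dm)
         if (is.null(ids)) ids <- as.character(seq_len(nrow(dm))) }
  n <- nrow(dm)
  stopifnot(n >= 2L, k >= 1L, k <= 3L)
  fit <- suppressWarnings(stats::cmdscale(dm, k = min(k, n - 1L), eig = TRUE))
  pts <- fit$points
  eig <- fit$eig[seq_len(k)]
  coords <- matrix(0, n, k, dimnames = list(ids, paste0("dim", seq_len(k))))
  got <- min(ncol(pts), k)
  if (got > 0L) coords[, seq_len(got)] <- pts[, seq_len(got)]
  # an eigenvalue that is negative, or negligible against the leading one,
  # carries no usable coordinate information
  thresh <- max(eig[1], 0) * 1e-9
  bad <- which(!is.na(eig[seq_len(k)]) & eig[seq_len(k)] <= thresh)
  if (length(bad) > 0L || got < k) {
    coords[, union(bad, setdiff(seq_len(k), seq_len(got)))] <- 0
    warning("fewer than ", k, " positive eigenvalues; ",
            "affected coordinate column(s) set to 0")
  }
  # canonical sign: first nonzero entry of each column positive
  for (j in seq_len(k)) {
    col <- coords[, j]
    nz <- which(abs(col) > 1e-12)
    if (length(nz) > 0L && col[nz[1]] < 0) coords[, j] <- -col
  }
  eig[is.na(eig)] <- 0
  structure(list(ids = ids, coords = coords, eigenvalues = eig),
            class = "map_layout")
}

#' @export
print.map_layout <- function(x, ...) {
  cat("<map_layout> ", length(x$ids), " points in ", ncol(x$coords),
      "-D; leading eigenvalues ",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project a query into the global disease map
#'
#' Places the query at the convex combination of the coordinates of its `m`
#' most similar diseases, weighted by similarity (weights = score / sum of
#' the m scores), so the projected point always lies within the neighbors'
#' convex hull.
#'
#' @param layout a [classical_mds()] result over the disease catalog.
#' @param top scored-disease data frame (ranked, descending).
#' @param m number of nearest semantic neighbors (default 5).
#' @return numeric coordinate vector of length `ncol(layout$coords)`.
#' @export
project_query <- function(layout, top, m = 5L) {
  stopifnot(inherits(layout, "map_layout"))
  top <- top[top$disease_id %in% layout$ids, , drop = FALSE]
  if (nrow(top) < m) stop("need at least m = ", m,
                          " scored diseases present in the layout")
  nb <- utils::head(top, m)
  if (any(nb$score < 0)) stop("negative similarity scores cannot be weights")
  s <- sum(nb$score)
  if (s == 0) stop("all m nearest neighbors have similarity 0; ",
                   "try another metric or a richer query")
  w <- nb$score / s
  drop(t(w) %*% layout$coords[nb$disease_id, , drop = FALSE])
}

#' Radar (polar) layout of the top differential diseases
#'
#' Radial coordinate: `r = (S(Q,Q) - S(Q,D)) / S(Q,Q)`, so a disease scoring
#' the query's self-similarity sits at the center and a score of 0 sits on
#' the unit circle.  Angular coordinate: the 1-D MDS coordinate of the
#' diseases, linearly rescaled onto `[0, 360*(n-1)/n)` degrees so the two
#' extremes do not coincide.  Variant encodings: for each disease, the most
#' pathogenic variant in any linked gene supplies `size_value =
#' -log10(max(maf, 1e-6))` (missing MAF renders at maximum size, i.e.
#' rarest) and `color_value` = that variant's pathogenicity; diseases with
#' no linked variant get `NA` sentinels.
#'
#' @param top scored-disease data frame of the `n` diseases to display.
#' @param self_score the metric's self-similarity `S(Q,Q)` (must be > 0),
#'   e.g. from [query_self_score()].
#' @param one_d a `map_layout` with `k = 1` over the same diseases; if
#'   `NULL`, all angles are 0.
#' @param catalog optional [disease_catalog] for gene links.
#' @param variants optional variant data frame (columns `gene`, `maf`,
#'   `pathogenicity`).
#' @param excluded character vector of curated-out disease ids (flagged,
#'   not removed).
#' @return data frame with `disease_id`, `r`, `theta`, `size_value`,
#'   `color_value`, `excluded`.
#' @export
radar_layout <- function(top, self_score, one_d = NULL, catalog = NULL,
                         variants = NULL, excluded = character()) {
  if (self_score <= 0) stop("self-similarity must be positive")
  n <- nrow(top)
  stopifnot(n >= 1L)
  r <- (self_score - top$score) / self_score
  theta <- rep(0, n)
  if (n >= 2L && !is.null(one_d)) {
    x <- one_d$coords[match(top$disease_id, one_d$ids), 1]
    span <- max(x) - min(x)
    theta <- if (span > 0) 360 * (n - 1) / n * (x - min(x)) / span
             else rep(0, n)
  }
  size_value <- rep(NA_real_, n)
  color_value <- rep(NA_real_, n)
  if (!is.null(catalog) && !is.null(variants) && nrow(variants) > 0L) {
    for (i in seq_len(n)) {
      genes <- catalog$diseases[[top$disease_id[i]]]$genes
      vv <- variants[variants$gene %in% genes, , drop = FALSE]
      if (nrow(vv) == 0L) next
      pk <- ifelse(is.na(vv$pathogenicity), -Inf, vv$pathogenicity)
      best <- which.max(pk)
      maf <- vv$maf[best]
      size_value[i] <- -log10(max(if (is.na(maf)) 1e-6 else maf, 1e-6))
      color_value[i] <- vv$pathogenicity[best]
    }
  }
  data.frame(disease_id = top$disease_id, r = r, theta = theta,
             size_value = size_value, color_value = color_value,
             excluded = top$disease_id %in% excluded,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Self-similarity of a query under a metric
#'
#' `S(Q,Q)`, the score of the query against itself, used to normalize radar
#' radii.
#'
#' @inheritParams score_all_diseases
#' @export
query_self_score <- function(q_terms, catalog, dag,
                             method = c("resnik", "ato", "ato_ic", "ato_tic"),
                             ic = NULL, topo = NULL) {
  method <- match.arg(method)
  if (method %in% c("resnik", "ato_ic") && is.null(ic))
    ic <- catalog_information_content(catalog, dag)
  if (method == "ato_tic" && is.null(topo)) topo <- topological_weights(dag)
  switch(method,
    resnik = resnik_similarity(q_terms, q_terms, ic, dag),
    ato = ato_similarity(q_terms, q_terms, dag),
    ato_ic = weighted_ato_similarity(q_terms, q_terms, dag, ic),
    ato_tic = weighted_ato_similarity(q_terms, q_terms, dag, topo))
}
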