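# ---- PPI-network disease gene discovery ------------------------------------

#' Build a PPI network from an edge table
#'
#' @param edges two-column data frame (or matrix) of gene symbol pairs.
#' @param alias optional named character vector (alias -> canonical) applied
#'   to symbols before the graph is built.
#' @return an undirected, simplified `igraph` graph (no self-edges or
#'   multi-edges).
#' @export
ppi_network <- function(edges, alias = NULL) {
  e <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(e) <- "character"
  if (!is.null(alias)) {
    hit <- e %in% names(alias)
    e[hit] <- unname(alias[e[hit]])
  }
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a PPI network file
#'
#' Accepts either a plain two-column TSV of gene symbols or a PSI-MITAB
#' file (detected by column count >= 15), from which columns 1-2 are parsed
#' (text after the last `:` in each identifier).
#'
#' @param path file path.
#' @param alias optional alias table (named character vector).
#' @return an `igraph` graph.
#' @export
read_ppi <- function(path, alias = NULL) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", quote = "")
  if (ncol(df) >= 15L) {
    a <- sub("^.*:", "", df[[1]])
    b <- sub("^.*:", "", df[[2]])
    df <- data.frame(a, b, stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2L) stop("PPI file needs at least two columns: ", path)
  ppi_network(df[, 1:2], alias = alias)
}

#' Training genes from the semantic neighborhood of the query
#'
#' Walks the ranked disease list and takes the union of gene symbols over
#' the `top_m` highest-scoring diseases that have gene links; unlinked
#' diseases are skipped and do not consume slots.
#'
#' @param scored ranked scored-disease data frame.
#' @param catalog a [disease_catalog].
#' @param top_m number of linked diseases to use.
#' @return character vector of training gene symbols.
#' @export
training_genes <- function(scored, catalog, top_m = 10L) {
  stopifnot(top_m >= 1L)
  genes <- character(0)
  used <- 0L
  for (id in scored$disease_id) {
    g <- catalog$diseases[[id]]$genes
    if (length(g) == 0L) next
    genes <- union(genes, g)
    used <- used + 1L
    if (used >= top_m) break
  }
  if (used == 0L) stop("no gene-linked disease among the scored set")
  genes
}

#' Discover candidate disease genes in the PPI network
#'
#' For each patient variant gene that is not itself a training gene,
#' counts its direct PPI neighbors that are training genes
#' (`n_training_links`) and the fraction of its total degree they represent
#' (`fraction_training`).  Candidates with fewer than `min_links` training
#' neighbors are dropped; survivors are ordered by fraction descending,
#' then count descending, then symbol.
#'
#' @param variant_genes character vector of genes variant in the patient.
#' @param training character vector of training genes.
#' @param ppi an `igraph` PPI network.
#' @param min_links minimum training links (1 by default; 2 when the
#'   two-training-interactor constraint is enabled).
#' @return data frame with `gene`, `n_training_links`, `degree`,
#'   `fraction_training`, `training_neighbors`.
#' @export
discover_candidates <- function(variant_genes, training, ppi, min_links = 1L) {
  stopifnot(length(training) > 0L, min_links >= 1L)
  nodes <- igraph::V(ppi)$name
  cands <- setdiff(unique(variant_genes), training)
  absent <- setdiff(cands, nodes)
  if (length(absent) > 0L)
    message(length(absent), " variant gene(s) absent from the PPI network: ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "")
  cands <- intersect(cands, nodes)
  rows <- lapply(cands, function(g) {
    nb <- igraph::V(ppi)$name[igraph::neighbors(ppi, g)]
    tn <- intersect(nb, training)
    data.frame(gene = g, n_training_links = length(tn), degree = length(nb),
               fraction_training = if (length(nb) > 0L)
                 length(tn) / length(nb) else 0,
               training_neighbors = paste(sort(tn), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(gene = character(0), n_training_links = integer(0),
               degree = integer(0), fraction_training = numeric(0),
               training_neighbors = character(0), stringsAsFactors = FALSE)
  out <- out[out$n_training_links >= min_links, , drop = FALSE]
  out <- out[order(-out$fraction_training, -out$n_training_links, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate semantic neighborhoods against PPI distances
#'
#' For every gene-linked disease, finds its nearest semantic neighbor
#' disease (highest similarity, self excluded) and records the unweighted
#' shortest-path PPI distances between the neighbor's genes and the
#' disease's own genes.  A background sample records the same distances for
#' randomly paired diseases.  Unreachable pairs are assigned graph diameter
#' + 1.  The two samples are compared with a two-sample Kolmogorov-Smirnov
#' statistic: the larger it is, the more semantic neighborhood concentrates
#' in PPI space.
#'
#' @param catalog a [disease_catalog] with gene links.
#' @param dag an [ontology_dag].
#' @param ppi an `igraph` PPI network.
#' @param method similarity metric for the disease-disease matrix.
#' @param n_pairs number of random background disease pairs (default 200).
#' @param seed RNG seed for the background pairing.
#' @param ic,topo optional precomputed weights.
#' @return list with `ks_statistic`, `neighbor_distances`,
#'   `background_distances`.
#' @export
neighbor_distance_validation <- function(catalog, dag, ppi,
                                         method = "resnik", n_pairs = 200L,
                                         seed = 1L, ic = NULL, topo = NULL) {
  linked <- names(Filter(function(d)
    length(d$genes) > 0L && length(d$terms) > 0L, catalog$diseases))
  if (length(linked) < 2L) stop("need at least 2 gene-linked diseases")
  sim <- similarity_matrix(catalog, dag, method, ic = ic, topo = topo,
                           disease_ids = linked)
  nodes <- igraph::V(ppi)$name
  diam <- igraph::diameter(ppi, unconnected = TRUE)
  pair_dist <- function(d1, d2) {
    g1 <- intersect(catalog$diseases[[d1]]$genes, nodes)
    g2 <- intersect(catalog$diseases[[d2]]$genes, nodes)
    if (length(g1) == 0L || length(g2) == 0L) return(numeric(0))
    dd <- igraph::distances(ppi, v = g1, to = g2)
    dd[!is.finite(dd)] <- diam + 1
    as.numeric(dd)
  }
  neighbor <- unlist(lapply(linked, function(d) {
    s <- sim[d, ]
    s <- s[names(s) != d]
    nn <- names(s)[order(-s, names(s))][1]
    pair_dist(d, nn)
  }), use.names = FALSE)
  background <- withr_seed(seed, {
    unlist(lapply(seq_len(n_pairs), function(i) {
      pr <- sample(linked, 2L)
      pair_dist(pr[1], pr[2])
    }), use.names = FALSE)
  })
  if (length(neighbor) == 0L || length(background) == 0L)
    stop("no PPI-resolvable gene pairs; check the network's gene symbols")
  ks <- suppressWarnings(
    stats::ks.test(neighbor, background)$statistic)
  list(ks_statistic = unname(ks), neighbor_distances = neighbor,
       background_distances = background)
}

# Evaluate an expression under a local, restorable RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
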