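# ---- ontology construction -------------------------------------------------

#' Construct a rooted phenotype ontology DAG
#'
#' Builds the in-memory DAG used by every downstream computation: reflexive-
#' transitive ancestor and descendant closures, an alternate-id index, and a
#' topological order.  Obsolete terms are recorded but excluded from the graph
#' and from all closures.
#'
#' @param ids character vector of primary term ids.
#' @param names character vector of term labels (same length as `ids`).
#' @param parents named list mapping each id to a character vector of parent
#'   ids (`is_a` targets); the root has `character(0)`.
#' @param alt_ids named character vector mapping alternate ids to primary ids.
#' @param obsolete character vector of obsolete term ids (these must not
#'   appear in `ids`).
#' @param add_root if `TRUE` and more than one parentless term exists, a
#'   synthetic super-root (`"SUPER:ROOT"`) is inserted above them; if `FALSE`
#'   (default), multiple roots are an error.
#' @return an object of class `ontology_dag` with elements `ids`, `labels`,
#'   `parents`, `children`, `root`, `alt_ids`, `obsolete`, `topo` (parents
#'   before children), `anc` and `des` (named lists of reflexive-transitive
#'   closures).
#' @export
ontology_dag <- function(ids, names = ids, parents,
                         alt_ids = character(), obsolete = character(),
                         add_root = FALSE) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("ontology has no terms")
  if (anyDuplicated(ids)) stop("duplicate term ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("empty term id")
  labels <- stats::setNames(as.character(names), ids)
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) unique(as.character(p)))

  unknown <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unknown) > 0L)
    stop("unknown parent id(s): ", paste(unknown, collapse = ", "))
  if (any(vapply(ids, function(t) t %in% parents[[t]], logical(1))))
    stop("self-loop detected in is_a edges")

  roots <- ids[vapply(parents, length, integer(1)) == 0L]
  if (length(roots) == 0L) stop("no root term (every term has a parent)")
  if (length(roots) > 1L) {
    if (!add_root)
      stop("multiple parentless terms (", paste(roots, collapse = ", "),
           "); pass add_root = TRUE to insert a synthetic super-root")
    super <- "SUPER:ROOT"
    ids <- c(super, ids)
    labels <- c(stats::setNames("synthetic super-root", super), labels)
    for (r in roots) parents[[r]] <- super
    parents[[super]] <- character(0)
    parents <- parents[ids]
    roots <- super
  }

  # edges parent -> child; topological order gives parents before children
  edge_child <- rep(ids, vapply(parents, length, integer(1)))
  edge_parent <- unlist(parents, use.names = FALSE)
  g <- igraph::make_empty_graph(n = length(ids), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(edge_parent) > 0L)
    g <- igraph::add_edges(g, rbind(edge_parent, edge_child))
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    stop("cycle detected in ontology; offending edge: ",
         ends[2], " is_a ", ends[1])
  }
  topo <- igraph::topo_sort(g, mode = "out")$name

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) children[[t]] <- character(0)
  for (i in seq_along(edge_child))
    children[[edge_parent[i]]] <- c(children[[edge_parent[i]]], edge_child[i])

  anc <- stats::setNames(vector("list", length(ids)), ids)
  for (t in topo)
    anc[[t]] <- unique(c(t, unlist(anc[parents[[t]]], use.names = FALSE)))
  des <- stats::setNames(vector("list", length(ids)), ids)
  for (t in rev(topo))
    des[[t]] <- unique(c(t, unlist(des[children[[t]]], use.names = FALSE)))

  alt_ids <- alt_ids[!names(alt_ids) %in% ids]  # primary wins on clash
  structure(list(ids = ids, labels = labels, parents = parents,
                 children = children, root = roots, alt_ids = alt_ids,
                 obsolete = unique(as.character(obsolete)), topo = topo,
                 anc = anc, des = des),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("<ontology_dag> ", length(x$ids), " terms, root ", x$root,
      ", ", length(x$alt_ids), " alt ids, ",
      length(x$obsolete), " obsolete\n", sep = "")
  invisible(x)
}

# Resolve a user-supplied id to a primary id (alt_id remap), or error.
resolve_term <- function(dag, t, context = "term") {
  t <- as.character(t)
  out <- t
  miss <- !(out %in% dag$ids)
  if (any(miss)) {
    remap <- dag$alt_ids[out[miss]]
    ok <- !is.na(remap)
    if (any(ok)) {
      message("remapped alt id(s): ",
              paste(out[miss][ok], "->", remap[ok], collapse = ", "))
      out[miss][ok] <- remap[ok]
    }
  }
  if (any(out %in% dag$obsolete))
    stop("obsolete ", context, " id(s): ",
         paste(out[out %in% dag$obsolete], collapse = ", "))
  bad <- setdiff(out, dag$ids)
  if (length(bad) > 0L)
    stop("unknown ", context, " id(s): ", paste(bad, collapse = ", "))
  out
}

# ---- OBO parsing -----------------------------------------------------------

#' Load an ontology from an OBO flat file
#'
#' Reads `[Term]` stanzas from an OBO 1.2/1.4 file.  Only `id`, `name`,
#' `is_a`, `alt_id` and `is_obsolete` tags are interpreted; only `is_a`
#' edges are used.  Obsolete terms are excluded from the graph (and carry no
#' parents); their ids and any `alt_id` values are indexed so that queries
#' using them can be remapped or rejected with a clear message.
#'
#' @param path path to the OBO file.
#' @param add_root insert a synthetic super-root when the file contains more
#'   than one parentless term (default `FALSE`: refuse).
#' @return an [ontology_dag].
#' @export
load_ontology <- function(path, add_root = FALSE) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) stop("no stanzas found in OBO file: ", path)
  stops <- c(starts[-1] - 1L, length(lines))
  ids <- character(); labels <- character()
  parents <- list(); alt <- character(); obsolete <- character()
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    body <- lines[(starts[k] + 1L):stops[k]]
    body <- body[nzchar(body)]
    tagval <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    tags <- vapply(tagval, function(m) if (length(m) == 3L) m[2] else "", "")
    vals <- vapply(tagval, function(m) if (length(m) == 3L) m[3] else "", "")
    id <- vals[tags == "id"][1]
    if (is.na(id) || !nzchar(id)) stop("[Term] stanza without id in ", path)
    nm <- vals[tags == "name"][1]
    if (is.na(nm)) nm <- id
    obs <- any(tags == "is_obsolete" & grepl("^true", vals))
    isa <- vals[tags == "is_a"]
    isa <- sub("\\s*!.*$", "", isa)            # strip trailing "! label"
    isa <- trimws(isa)
    alts <- trimws(vals[tags == "alt_id"])
    if (obs) {
      obsolete <- c(obsolete, id)
      next                                      # obsolete terms carry no parents
    }
    ids <- c(ids, id)
    labels <- c(labels, nm)
    parents[[id]] <- isa
    if (length(alts) > 0L)
      alt <- c(alt, stats::setNames(rep(id, length(alts)), alts))
  }
  if (length(ids) == 0L) stop("OBO file contains no non-obsolete terms: ", path)
  ontology_dag(ids, labels, parents, alt_ids = alt, obsolete = obsolete,
               add_root = add_root)
}

# ---- closures --------------------------------------------------------------

#' Ancestors of a term (reflexive-transitive)
#'
#' Returns the term itself plus every term reachable by following `is_a`
#' parent edges to the root.
#'
#' @param dag an [ontology_dag].
#' @param t a single term id (alt ids are remapped).
#' @return character vector of term ids.
#' @export
ancestors <- function(dag, t) {
  stopifnot(inherits(dag, "ontology_dag"), length(t) == 1L)
  dag$anc[[resolve_term(dag, t)]]
}

#' Descendants of a term (reflexive-transitive)
#'
#' Returns the term itself plus every term from which it is reachable via
#' parent edges, i.e. the full subtree at or below the term.  This closure is
#' what makes annotation counts "at or below" a term well defined.
#'
#' @inheritParams ancestors
#' @return character vector of term ids.
#' @export
descendants <- function(dag, t) {
  stopifnot(inherits(dag, "ontology_dag"), length(t) == 1L)
  dag$des[[resolve_term(dag, t)]]
}

#' Ancestral closure of a term set
#'
#' Union of [ancestors()] over a set of terms; the empty set maps to the
#' empty set.
#'
#' @param dag an [ontology_dag].
#' @param ts character vector of term ids.
#' @return character vector of term ids.
#' @export
ancestral_closure <- function(dag, ts) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (length(ts) == 0L) return(character(0))
  ts <- resolve_term(dag, ts)
  unique(unlist(dag$anc[ts], use.names = FALSE))
}

# ---- topological weights ---------------------------------------------------

# Terms whose topological position characteristic underflows to numeric zero
# get this topological information content instead of -log(0) = Inf.
TIC_CLAMP <- 2.225074e-308

#' Topological term weights (reachability-based)
#'
#' Computes, for every term, a topological position characteristic (TPC) and
#' the derived topological information content (TIC), using only the graph
#' structure (no catalog annotations).  The root has TPC 1 (TIC 0); for a
#' non-root term the TPC is the product over its parents p of
#' `tpc(p) / |children(p)|`, evaluated in topological order, so terms that
#' are harder to reach carry more information.  A TPC that underflows to
#' numeric 0 would give an infinite TIC; such terms are clamped to the
#' machine-minimum constant `2.225074e-308`.
#'
#' @param dag an [ontology_dag].
#' @return an object of class `topo_weights`: list with named numeric
#'   vectors `tpc` and `tic`, and `clamped`, the ids of clamped terms.
#' @export
topological_weights <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  nchild <- vapply(dag$children, length, integer(1))
  tpc <- stats::setNames(rep(NA_real_, length(dag$ids)), dag$ids)
  tpc[dag$root] <- 1
  for (t in dag$topo) {
    if (t == dag$root) next
    ps <- dag$parents[[t]]
    tpc[t] <- prod(tpc[ps] / nchild[ps])
  }
  tic <- -log(tpc)
  clamped <- names(tpc)[tpc == 0]
  tic[clamped] <- TIC_CLAMP
  structure(list(tpc = tpc, tic = tic, clamped = clamped),
            class = "topo_weights")
}

#' @export
print.topo_weights <- function(x, ...) {
  cat("<topo_weights> ", length(x$tpc), " terms, ",
      length(x$clamped), " clamped to TIC ", format(TIC_CLAMP), "\n", sep = "")
  invisible(x)
}
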