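# Naive reference implementations, independent of the package internals:
# closures by plain recursion over a parent list, metrics by double loops.

oracle_ancestors <- function(parents, t) {
  out <- t
  for (p in parents[[t]])
    out <- union(out, oracle_ancestors(parents, p))
  out
}

oracle_descendants <- function(parents, t) {
  ids <- names(parents)
  ids[vapply(ids, function(s) t %in% oracle_ancestors(parents, s), logical(1))]
}

oracle_closure <- function(parents, ts) {
  out <- character(0)
  for (t in ts) out <- union(out, oracle_ancestors(parents, t))
  out
}

# IC per term from annotation lists (disease -> exact terms)
oracle_ic <- function(parents, annot) {
  N <- length(annot)
  ids <- names(parents)
  counts <- vapply(ids, function(t) {
    below <- oracle_descendants(parents, t)
    sum(vapply(annot, function(ts) any(ts %in% below), logical(1)))
  }, integer(1))
  ic <- -log(counts / N)
  ic[counts == 0] <- NA_real_
  ic
}

oracle_mica_ic <- function(parents, ic, t1, t2) {
  common <- intersect(oracle_ancestors(parents, t1),
                      oracle_ancestors(parents, t2))
  vals <- ic[common]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) 0 else max(vals)
}

oracle_resnik <- function(parents, ic, q, d) {
  q <- q[!is.na(ic[q])]
  d <- d[!is.na(ic[d])]
  best <- function(t, others)
    max(vapply(others, function(o) oracle_mica_ic(parents, ic, t, o), 0))
  fwd <- mean(vapply(d, best, 0, others = q))
  bwd <- mean(vapply(q, best, 0, others = d))
  (fwd + bwd) / 2
}

oracle_ato <- function(parents, q, d)
  length(intersect(oracle_closure(parents, q), oracle_closure(parents, d)))

oracle_wato <- function(parents, q, d, w) {
  shared <- intersect(oracle_closure(parents, q), oracle_closure(parents, d))
  sum(w[shared], na.rm = TRUE)
}

# random DAG + annotations used by the oracle-equivalence suites;
# this generator is deliberately separate from the package's own.
random_oracle_fixture <- function(seed, n_terms = 30, n_diseases = 10) {
  set.seed(seed)
  n <- sample(5:n_terms, 1)
  ids <- paste0("R", seq_len(n))
  parents <- setNames(vector("list", n), ids)
  parents[[ids[1]]] <- character(0)
  for (i in 2:n) {
    np <- sample(1:min(2, i - 1), 1)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], np)
  }
  k <- sample(2:n_diseases, 1)
  annot <- lapply(seq_len(k), function(j)
    sample(ids, sample(1:min(4, n), 1)))
  names(annot) <- paste0("dis", seq_len(k))
  q <- sample(ids, sample(1:3, 1))
  list(ids = ids, parents = parents, annot = annot, query = q)
}

# build package objects from an oracle fixture
pkg_objects_from <- function(fx) {
  dag <- ontology_dag(fx$ids, parents = fx$parents)
  diseases <- lapply(names(fx$annot), function(id)
    list(id = id, name = id, terms = fx$annot[[id]],
         inheritance = character(0), genes = character(0)))
  catalog <- disease_catalog(diseases)
  list(dag = dag, catalog = catalog,
       ic = catalog_information_content(catalog, dag))
}
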