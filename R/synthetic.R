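# ---- seeded synthetic generators -------------------------------------------

#' Canonical 6-term worked-example fixture
#'
#' A tiny rooted DAG (T0 root; T1, T2 under T0; T3, T4 under T1; T5 under
#' T2), four diseases (D1 \{T3\}, D2 \{T4\}, D3 \{T5\}, D4 \{T3, T5\}) and
#' two linked genes (GZ -> \{D1, D2\}, GX -> \{D4\}).  All hand-checkable
#' similarity values in the documentation and tests are computed on this
#' fixture.
#'
#' @return list with `dag` ([ontology_dag]), `catalog` ([disease_catalog])
#'   and `gene_map` (named list gene -> disease ids).
#' @export
make_fixture_t6 <- function() {
  dag <- ontology_dag(
    ids = paste0("T", 0:5),
    names = paste("toy term", 0:5),
    parents = list(T0 = character(0), T1 = "T0", T2 = "T0",
                   T3 = "T1", T4 = "T1", T5 = "T2"))
  diseases <- list(
    list(id = "D1", name = "toy disease 1", terms = "T3",
         inheritance = character(0), genes = "GZ"),
    list(id = "D2", name = "toy disease 2", terms = "T4",
         inheritance = character(0), genes = "GZ"),
    list(id = "D3", name = "toy disease 3", terms = "T5",
         inheritance = character(0), genes = character(0)),
    list(id = "D4", name = "toy disease 4", terms = c("T3", "T5"),
         inheritance = character(0), genes = "GX"))
  list(dag = dag, catalog = disease_catalog(diseases),
       gene_map = list(GZ = c("D1", "D2"), GX = "D4"))
}

#' Simulation configuration
#'
#' Fixes every knob of [simulate_case()]; the seed fixes every downstream
#' draw.
#'
#' @param seed integer RNG seed.
#' @param n_terms ontology size (including root and branch heads).
#' @param ontology_depth maximum term depth below the root.
#' @param branching_factor number of disjoint top-level branches.
#' @param n_diseases catalog size.
#' @param terms_per_disease length-2 integer range.
#' @param n_classes number of coherent disease classes (0 = none).
#' @param class_coherence number of class-specific terms shared by all
#'   classmates.
#' @param n_decoy_genes decoy variant genes drawn from the catalog.
#' @param planted_causal plant a causal disease/gene and build the query
#'   from its term set.
#' @param compound_het give the causal gene two het variants instead of one
#'   hom variant.
#' @param query_noise_terms extra query terms drawn from branches disjoint
#'   from the planted disease.
#' @param n_novel_genes variant genes absent from the catalog (discovery
#'   decoys), in addition to the planted candidate.
#' @param planted_candidate_links training-gene links wired to the planted
#'   discovery candidate.
#' @param discovery_top_m linked diseases defining the training set.
#' @param ppi_class_cliques wire each class's genes as a PPI clique with
#'   classes >= 3 hops apart (needs `n_classes > 0`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_terms = 120L, ontology_depth = 4L,
                       branching_factor = 3L, n_diseases = 40L,
                       terms_per_disease = c(3L, 6L), n_classes = 0L,
                       class_coherence = 0L, n_decoy_genes = 20L,
                       planted_causal = TRUE, compound_het = FALSE,
                       query_noise_terms = 0L, n_novel_genes = 6L,
                       planted_candidate_links = 3L, discovery_top_m = 10L,
                       ppi_class_cliques = FALSE) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              ontology_depth = as.integer(ontology_depth),
              branching_factor = as.integer(branching_factor),
              n_diseases = as.integer(n_diseases),
              terms_per_disease = as.integer(terms_per_disease),
              n_classes = as.integer(n_classes),
              class_coherence = as.integer(class_coherence),
              n_decoy_genes = as.integer(n_decoy_genes),
              planted_causal = isTRUE(planted_causal),
              compound_het = isTRUE(compound_het),
              query_noise_terms = as.integer(query_noise_terms),
              n_novel_genes = as.integer(n_novel_genes),
              planted_candidate_links = as.integer(planted_candidate_links),
              discovery_top_m = as.integer(discovery_top_m),
              ppi_class_cliques = isTRUE(ppi_class_cliques))
  stopifnot(cfg$n_terms > cfg$branching_factor + 1L,
            cfg$ontology_depth >= 2L, cfg$branching_factor >= 2L,
            cfg$n_diseases >= 2L, length(cfg$terms_per_disease) == 2L,
            cfg$terms_per_disease[1] >= 1L,
            cfg$terms_per_disease[2] >= cfg$terms_per_disease[1])
  if (cfg$terms_per_disease[2] + cfg$class_coherence > cfg$n_terms)
    stop("terms_per_disease exceeds ontology size")
  if (cfg$ppi_class_cliques && cfg$n_classes < 2L)
    stop("ppi_class_cliques needs n_classes >= 2")
  structure(cfg, class = "sim_config")
}

#' Simulate a complete synthetic case
#'
#' Generates, under one seed, every input the pipeline consumes: a rooted
#' ontology DAG with `branching_factor` ancestrally disjoint top-level
#' branches (random top-down attachment below them), a disease catalog with
#' optional coherent classes, a gene map with inheritance modes, a variant
#' set with a planted causal gene, a PPI network with a planted discovery
#' candidate, the phenotype query (the planted disease's term set plus
#' optional noise from disjoint branches), and a truth record naming every
#' planted entity.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_case`: `cfg`, `dag`, `catalog`, `classes`
#'   (named list or NULL), `variants`, `query_terms`, `ppi` (igraph),
#'   `truth` (list: `causal_gene`, `causal_disease`, `candidate_gene`,
#'   `training_genes`).
#' @export
simulate_case <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr_seed(cfg$seed, .simulate_case_impl(cfg))
}

.simulate_case_impl <- function(cfg) {
  # ---- ontology: branch heads, then random top-down attachment -------------
  ids <- sprintf("HP:%07d", seq_len(cfg$n_terms))
  root <- ids[1]
  heads <- ids[1 + seq_len(cfg$branching_factor)]
  parents <- stats::setNames(vector("list", cfg$n_terms), ids)
  parents[[root]] <- character(0)
  branch <- stats::setNames(rep(NA_integer_, cfg$n_terms), ids)
  depth <- stats::setNames(rep(0L, cfg$n_terms), ids)
  for (b in seq_along(heads)) {
    parents[[heads[b]]] <- root
    branch[heads[b]] <- b
    depth[heads[b]] <- 1L
  }
  for (i in (cfg$branching_factor + 2L):cfg$n_terms) {
    t <- ids[i]
    pool <- ids[2:(i - 1L)]
    pool <- pool[depth[pool] < cfg$ontology_depth]
    if (length(pool) == 0L) pool <- heads
    p1 <- sample(pool, 1L)
    ps <- p1
    # occasional second parent within the same branch keeps branches disjoint
    same <- pool[branch[pool] == branch[p1] & pool != p1 &
                   depth[pool] <= depth[p1]]
    if (length(same) > 0L && stats::runif(1) < 0.1)
      ps <- c(ps, sample(same, 1L))
    parents[[t]] <- ps
    branch[t] <- branch[p1]
    depth[t] <- max(depth[ps]) + 1L
  }
  dag <- ontology_dag(ids, sprintf("synthetic term %d", seq_len(cfg$n_terms)),
                      parents)
  by_branch <- split(ids[-1], branch[ids[-1]])

  # ---- diseases ------------------------------------------------------------
  n <- cfg$n_diseases
  class_of <- if (cfg$n_classes > 0L)
    rep(seq_len(cfg$n_classes), length.out = n) else rep(0L, n)
  class_terms <- list()
  if (cfg$n_classes > 0L && cfg$class_coherence > 0L) {
    for (cl in seq_len(cfg$n_classes)) {
      home <- by_branch[[1L + (cl - 1L) %% length(by_branch)]]
      class_terms[[cl]] <- sample(home, min(cfg$class_coherence, length(home)))
    }
  }
  planted_idx <- if (cfg$planted_causal) 1L else 0L
  planted_branch <- 1L
  diseases <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(cfg$terms_per_disease[1]:cfg$terms_per_disease[2], 1L)
    shared <- if (class_of[i] > 0L && cfg$class_coherence > 0L)
      class_terms[[class_of[i]]] else character(0)
    pool <- if (i == planted_idx) {
      by_branch[[planted_branch]]
    } else if (cfg$planted_causal) {
      # decoys draw from branches disjoint from the planted disease
      unlist(by_branch[-planted_branch], use.names = FALSE)
    } else unlist(by_branch, use.names = FALSE)
    avail <- setdiff(pool, shared)
    extra <- sample(avail, min(max(0L, k - length(shared)), length(avail)))
    inh <- sample(c("dominant", "recessive", ""), 1L,
                  prob = c(0.35, 0.35, 0.3))
    diseases[[i]] <- list(
      id = sprintf("OMIM:%06d", 100000L + i),
      name = sprintf("synthetic disease %d", i),
      terms = unique(c(shared, extra)),
      inheritance = if (nzchar(inh)) inh else character(0),
      genes = sprintf("G%03d", i))
  }
  # some genes are cataloged to cause more than one disease (not under the
  # clique construction, whose validation needs per-class gene adjacency)
  for (i in seq_len(n)) {
    if (cfg$ppi_class_cliques) break
    if (n > 1L && stats::runif(1) < 0.3) {
      j <- sample(setdiff(seq_len(n), i), 1L)
      diseases[[i]]$genes <- unique(c(diseases[[i]]$genes,
                                      diseases[[j]]$genes[1]))
    }
  }
  catalog <- disease_catalog(diseases)
  classes <- if (cfg$n_classes > 0L)
    split(vapply(diseases, `[[`, "", "id"), class_of) else NULL
  disease_ids <- names(catalog$diseases)
  gene_of <- stats::setNames(vapply(diseases, function(d) d$genes[1], ""),
                             disease_ids)

  # ---- query ---------------------------------------------------------------
  if (cfg$planted_causal) {
    causal_disease <- disease_ids[planted_idx]
    causal_gene <- unname(gene_of[causal_disease])
    query <- catalog$diseases[[causal_disease]]$terms
    if (cfg$query_noise_terms > 0L) {
      noise_pool <- unlist(by_branch[-planted_branch], use.names = FALSE)
      query <- c(query, sample(noise_pool, cfg$query_noise_terms))
    }
  } else {
    causal_disease <- NA_character_; causal_gene <- NA_character_
    query <- sample(ids[-1], mean(cfg$terms_per_disease))
  }

  # ---- variants ------------------------------------------------------------
  decoy_pool <- setdiff(unname(gene_of), causal_gene)
  decoys <- sample(decoy_pool, min(cfg$n_decoy_genes, length(decoy_pool)))
  novel <- if (cfg$n_novel_genes > 0L)
    sprintf("NOVEL%02d", seq_len(cfg$n_novel_genes)) else character(0)
  candidate <- "CAND01"
  vgenes <- c(if (cfg$planted_causal) causal_gene, decoys, novel, candidate)
  rows <- list()
  vi <- 0L
  add_variant <- function(gene, zyg) {
    vi <<- vi + 1L
    data.frame(chrom = sprintf("chr%d", 1L + (vi - 1L) %% 22L),
               pos = 1000L * vi, ref = "A",
               alt = sample(c("C", "G", "T"), 1L),
               zygosity = zyg, gene = gene,
               maf = 10^stats::runif(1, -6, -2),
               pathogenicity = round(stats::runif(1), 4),
               consequence = "missense_variant", source = "vcf",
               stringsAsFactors = FALSE)
  }
  for (g in vgenes) {
    if (cfg$planted_causal && g == causal_gene) {
      if (cfg$compound_het) {
        rows[[length(rows) + 1L]] <- add_variant(g, "het")
        rows[[length(rows) + 1L]] <- add_variant(g, "het")
      } else rows[[length(rows) + 1L]] <- add_variant(g, "hom")
    } else rows[[length(rows) + 1L]] <- add_variant(g, "het")
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL

  # ---- PPI -----------------------------------------------------------------
  training <- tryCatch({
    scored <- score_all_diseases(query, catalog, dag, "resnik")
    training_genes(scored, catalog, cfg$discovery_top_m)
  }, error = function(e) unname(gene_of[seq_len(min(cfg$discovery_top_m, n))]))
  edges <- list()
  link <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
  if (cfg$ppi_class_cliques) {
    hub <- "HUB00"
    for (cl in seq_along(classes)) {
      members <- unname(gene_of[classes[[cl]]])
      if (length(members) >= 2L)
        for (a in seq_len(length(members) - 1L))
          for (b in (a + 1L):length(members)) link(members[a], members[b])
      port <- sprintf("PORT%02d", cl)
      for (m in members) link(m, port)
      link(port, hub)
    }
  } else {
    # sparse random background among catalog genes
    gs <- unname(gene_of)
    for (i in seq_len(2L * length(gs))) {
      pr <- sample(gs, 2L)
      link(pr[1], pr[2])
    }
  }
  k <- min(cfg$planted_candidate_links, length(training))
  for (g in sample(training, k)) link(candidate, g)
  bg <- sprintf("BGND%02d", seq_len(4L))
  for (i in seq_along(novel)) {
    if (i %% 2L == 1L) link(novel[i], sample(training, 1L))  # one training link
    link(novel[i], bg[1L + (i - 1L) %% length(bg)])
    link(novel[i], bg[1L + i %% length(bg)])
  }
  ppi <- ppi_network(do.call(rbind, edges))

  structure(list(cfg = cfg, dag = dag, catalog = catalog, classes = classes,
                 variants = variants, query_terms = query, ppi = ppi,
                 truth = list(causal_gene = causal_gene,
                              causal_disease = causal_disease,
                              candidate_gene = candidate,
                              training_genes = training)),
            class = "sim_case")
}

#' @export
print.sim_case <- function(x, ...) {
  cat("<sim_case> seed ", x$cfg$seed, ": ", length(x$dag$ids), " terms, ",
      length(x$catalog$diseases), " diseases, ", nrow(x$variants),
      " variants; causal gene ", x$truth$causal_gene, "\n", sep = "")
  invisible(x)
}

# ---- file writers ----------------------------------------------------------

#' Write a simulated case to disk in the standard input formats
#'
#' Emits `ontology.obo`, `annotations.tsv`, `morbidmap.tsv`,
#' `variants.vcf`, `genes.txt`, `ppi.tsv`, `pathogenicity.tsv` and
#' `query.txt` into `dir`.  Every file parses back through the package's
#' readers to objects equal to the in-memory ones; identical configurations
#' give byte-identical files.
#'
#' @param sim a [simulate_case()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_obo(sim$dag, file.path(dir, "ontology.obo"))
  write_annotations(sim$catalog, file.path(dir, "annotations.tsv"))
  write_morbidmap(sim$catalog, file.path(dir, "morbidmap.tsv"))
  write_vcf(sim$variants, file.path(dir, "variants.vcf"))
  writeLines(unique(sim$variants$gene), file.path(dir, "genes.txt"))
  utils::write.table(igraph::as_edgelist(sim$ppi), file.path(dir, "ppi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  pt <- data.frame(key = variant_key(sim$variants$chrom, sim$variants$pos,
                                     sim$variants$ref, sim$variants$alt),
                   pathogenicity = sim$variants$pathogenicity)
  utils::write.table(pt, file.path(dir, "pathogenicity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(sim$query_terms, file.path(dir, "query.txt"))
  invisible(dir)
}

#' Write an ontology DAG as an OBO flat file
#'
#' @param dag an [ontology_dag].
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$ids) {
    alts <- names(dag$alt_ids)[dag$alt_ids == t]
    ps <- dag$parents[[t]]
    writeLines(c("[Term]", paste0("id: ", t),
                 paste0("name: ", dag$labels[[t]]),
                 if (length(ps) > 0L) paste0("is_a: ", ps),
                 if (length(alts) > 0L) paste0("alt_id: ", alts),
                 ""), con)
  }
  invisible(path)
}

#' Write catalog annotations as HPOA-like TSV
#'
#' @param catalog a [disease_catalog].
#' @param path output path.
#' @export
write_annotations <- function(catalog, path) {
  rows <- list()
  for (d in catalog$diseases)
    for (t in d$terms)
      rows[[length(rows) + 1L]] <- c(d$id, d$name, t)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write disease-gene links as a Morbidmap-like TSV
#'
#' @param catalog a [disease_catalog].
#' @param path output path.
#' @export
write_morbidmap <- function(catalog, path) {
  rows <- list()
  for (d in catalog$diseases) {
    if (length(d$genes) == 0L) next
    inh <- if ("dominant" %in% d$inheritance) "AD"
           else if ("recessive" %in% d$inheritance) "AR" else ""
    rows[[length(rows) + 1L]] <-
      c(paste0(d$name, ", ", d$id, " (3)"), paste(d$genes, collapse = ", "),
        inh)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write variant records as a minimal VCF 4.2 file
#'
#' Genotypes go to a single sample; gene and consequence are carried in an
#' `ANN` INFO field (gene in pipe-field 4) and the allele frequency in
#' `AF`.  Pathogenicity is not a VCF concept and is written separately by
#' [write_case()] as a sidecar.
#'
#' @param variants variant data frame (see [read_vcf()]).
#' @param path output path.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
               "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotation\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE"),
             con)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- sprintf("AF=%.8g;ANN=%s|%s|MODIFIER|%s|x|x",
                    v$maf, v$alt, v$consequence, v$gene)
    gt <- if (v$zygosity == "hom") "1/1" else "0/1"
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                       v$chrom, v$pos, v$ref, v$alt, info, gt), con)
  }
  invisible(path)
}
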