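scored_t6 <- score_all_diseases("T3", t6$catalog, t6$dag, "resnik")

test_that("inheritance truth table matches the genetic models", {
  het1 <- data.frame(zygosity = "het")
  hom1 <- data.frame(zygosity = "hom")
  het2 <- data.frame(zygosity = c("het", "het"))
  for (v in list(het1, hom1, het2))
    expect_true(check_inheritance("G", v, NULL, "none"))
  expect_true(check_inheritance("G", het1, NULL, "dominant"))
  expect_true(check_inheritance("G", hom1, NULL, "dominant"))
  expect_true(check_inheritance("G", het2, NULL, "dominant"))
  expect_false(check_inheritance("G", het1, NULL, "recessive"))
  expect_true(check_inheritance("G", hom1, NULL, "recessive"))
  expect_true(check_inheritance("G", het2, NULL, "recessive"))  # compound het
  # known disease modes excluding the constraint fail; unknown modes pass
  dom_dis <- list(inheritance = "dominant")
  unk_dis <- list(inheritance = character(0))
  expect_false(check_inheritance("G", hom1, dom_dis, "recessive"))
  expect_true(check_inheritance("G", hom1, unk_dis, "recessive"))
})

test_that("qualification filters apply in order and only shrink the list", {
  s <- t6_session(require_exome = TRUE)
  s$variants <- s$variants[s$variants$gene == "GZ", , drop = FALSE]
  q <- qualify_diseases(s, scored_t6, t6$catalog, t6$dag)
  expect_setequal(q$disease_id, c("D1", "D2"))

  s2 <- t6_session(required_terms = "T1")
  q2 <- qualify_diseases(s2, scored_t6, t6$catalog, t6$dag)
  expect_setequal(q2$disease_id, c("D1", "D2", "D4"))

  s3 <- t6_session(excluded_diseases = "D1")
  q3 <- qualify_diseases(s3, scored_t6, t6$catalog, t6$dag)
  expect_false("D1" %in% q3$disease_id)
  expect_identical(q3$rank, seq_len(nrow(q3)))

  # relative order preserved, ranks recomputed
  expect_identical(q3$disease_id,
                   scored_t6$disease_id[scored_t6$disease_id != "D1"])
  expect_error(qualify_diseases(t6_session(required_terms = "T99"),
                                scored_t6, t6$catalog, t6$dag), "unknown")
})

test_that("transitive gene scores aggregate supporting diseases", {
  gs <- transitive_gene_score("GZ", scored_t6, t6$catalog, "max")
  expect_equal(gs$score, 0.69315, tolerance = 1e-5)
  expect_equal(transitive_gene_score("GZ", scored_t6, t6$catalog, "mean")$score,
               0.49041, tolerance = 1e-5)
  expect_equal(transitive_gene_score("GZ", scored_t6, t6$catalog, "sum")$score,
               0.98083, tolerance = 1e-5)
  expect_setequal(gs$supporting$disease_id, c("D1", "D2"))
  # curation exclusion propagates into the gene score
  s <- t6_session(excluded_diseases = "D1")
  q <- qualify_diseases(s, scored_t6, t6$catalog, t6$dag)
  expect_equal(transitive_gene_score("GZ", q, t6$catalog, "max")$score,
               0.28768, tolerance = 1e-5)
  # unlinked gene is unscored
  expect_null(transitive_gene_score("NOPE", scored_t6, t6$catalog, "max"))
})

test_that("variant ranking runs the full pipeline on the toy case", {
  rk <- rank_variants(t6_session(), t6$catalog, t6$dag)
  expect_identical(rk$genes$gene, c("GZ", "GX"))
  expect_equal(rk$genes$score, c(0.69315, 0.51986), tolerance = 1e-5)
  expect_identical(rk$genes$rank, c(1L, 2L))
  expect_identical(rk$variants$gene, c("GZ", "GX"))
  expect_identical(rk$variants$rank, c(1L, 2L))
  # tie -> both rank 1, next rank 3 (competition)
  cat3 <- disease_catalog(list(
    list(id = "E1", name = "e1", terms = "T3", genes = "GA"),
    list(id = "E2", name = "e2", terms = "T3", genes = "GB"),
    list(id = "E3", name = "e3", terms = "T4", genes = "GC")))
  v <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L), ref = "A", alt = "T",
                  zygosity = "het", gene = c("GA", "GB", "GC"),
                  maf = NA_real_, pathogenicity = NA_real_,
                  consequence = "", source = "vcf")
  rk3 <- rank_variants(new_session("T3", variants = v), cat3, t6$dag)
  expect_identical(rk3$genes$rank, c(1L, 1L, 3L))
  # a variant in a gene with no catalog link is reported unscored
  v$gene[3] <- "UNKNOWN"
  rk4 <- rank_variants(new_session("T3", variants = v), cat3, t6$dag)
  expect_identical(rk4$unscored_genes, "UNKNOWN")
  expect_identical(nrow(rk4$unscored_variants), 1L)
})

test_that("variants within a gene share the gene score and sort by pathogenicity", {
  v <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A",
                  alt = "T", zygosity = "het", gene = "GZ",
                  maf = c(NA, 1e-4, 1e-5),
                  pathogenicity = c(0.2, 0.9, NA),
                  consequence = "", source = "vcf")
  rk <- rank_variants(new_session("T3", variants = v), t6$catalog, t6$dag)
  expect_identical(unique(rk$variants$score), rk$genes$score[1])
  expect_identical(rk$variants$pos, c(20L, 10L, 30L))  # patho desc, NA last
})

test_that("comparator gene scores match the worked examples", {
  expect_equal(gene_score_collapsed("GZ", "T3", t6$catalog, t6$dag, t6_ic),
               0.59178, tolerance = 1e-5)
  # union of one disease equals the plain disease score
  expect_equal(gene_score_collapsed("GX", "T3", t6$catalog, t6$dag, t6_ic),
               resnik_similarity("T3", c("T3", "T5"), t6_ic, t6$dag))
  expect_true(is.na(gene_score_collapsed("NOPE", "T3", t6$catalog,
                                         t6$dag, t6_ic)))
  gmap <- list(GD = "T3")
  expect_equal(gene_score_direct("GD", "T3", gmap, t6$dag, t6_ic),
               0.69315, tolerance = 1e-5)
  expect_true(is.na(gene_score_direct("GE", "T3", gmap, t6$dag, t6_ic)))
  # a direct table equal to the collapsed union gives identical scores
  gmap2 <- list(GZ = c("T3", "T4"))
  expect_equal(gene_score_direct("GZ", "T3", gmap2, t6$dag, t6_ic),
               gene_score_collapsed("GZ", "T3", t6$catalog, t6$dag, t6_ic))
})

test_that("phenotype suggestion returns rare non-query terms", {
  sug <- suggest_phenotypes("T3", scored_t6, t6$catalog, t6$dag, t6_ic,
                            top_n = 2, k = 5)
  expect_identical(sug, "T5")
  # top diseases annotating only query terms -> empty
  sug2 <- suggest_phenotypes("T3", scored_t6, t6$catalog, t6$dag, t6_ic,
                             top_n = 1, k = 5)
  expect_length(sug2, 0L)
  # k = 1 picks the rarest candidate
  sug3 <- suggest_phenotypes("T1", scored_t6, t6$catalog, t6$dag, t6_ic,
                             top_n = 4, k = 1)
  expect_identical(sug3, "T4")  # ic 1.386 beats T5/T3 at 0.693
})

test_that("shared phenotypes use ancestral matching above the root", {
  sp <- shared_phenotypes(c("T3", "T5"), "T3", t6$dag)
  expect_identical(sp$shared, "T3")
  expect_identical(sp$disease_only, "T5")
  sp2 <- shared_phenotypes("T5", "T3", t6$dag)   # root-only overlap
  expect_length(sp2$shared, 0L)
  expect_identical(sp2$disease_only, "T5")
  sp3 <- shared_phenotypes(c("T3", "T5"), c("T3", "T5"), t6$dag)
  expect_setequal(sp3$shared, c("T3", "T5"))
})

test_that("query term weights are relative information content", {
  w <- query_term_weights(c("T3", "T4"), t6_ic)
  expect_equal(unname(w["T4"]), 1)
  expect_equal(unname(w["T3"]), 0.5, tolerance = 1e-12)
  expect_identical(unname(query_term_weights("T3", t6_ic)), 1)
  expect_identical(unname(query_term_weights("T0", t6_ic)), 1)  # degenerate
})

test_that("curation monotonicity: excluding the argmax disease never raises a max score", {
  for (seed in 1:20) {
    sim <- simulate_case(sim_config(seed = seed, n_diseases = 15,
                                    n_decoy_genes = 8, query_noise_terms = 2))
    s <- new_session(sim$query_terms, variants = sim$variants,
                     aggregation = "max")
    rk <- rank_variants(s, sim$catalog, sim$dag)
    g <- rk$genes$gene[1]
    argmax <- rk$gene_scores[[g]]$supporting$disease_id[
      which.max(rk$gene_scores[[g]]$supporting$score)]
    s2 <- s; s2$excluded_diseases <- argmax
    rk2 <- rank_variants(s2, sim$catalog, sim$dag)
    old <- rk$genes$score[rk$genes$gene == g]
    if (g %in% rk2$genes$gene)
      expect_lte(rk2$genes$score[rk2$genes$gene == g], old + 1e-12)
    # every affected gene score shrinks or ties; ranks can only demote
    both <- intersect(rk$genes$gene, rk2$genes$gene)
    expect_true(all(rk2$genes$score[match(both, rk2$genes$gene)] <=
                      rk$genes$score[match(both, rk$genes$gene)] + 1e-12))
  }
})

test_that("gene lists refuse inheritance constraints", {
  gl <- read_gene_list(write_tmp(c("GZ", "GX")))
  s <- new_session("T3", variants = gl, inheritance = "recessive")
  expect_error(rank_variants(s, t6$catalog, t6$dag), "zygosity")
})
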