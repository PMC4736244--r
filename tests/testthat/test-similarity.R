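test_that("Resnik similarity reproduces the worked examples", {
  expect_equal(resnik_similarity("T3", "T4", t6_ic, t6$dag),
               0.28768, tolerance = 1e-5)
  expect_equal(resnik_similarity("T3", c("T3", "T5"), t6_ic, t6$dag),
               0.51986, tolerance = 1e-5)
  expect_equal(resnik_similarity("T3", "T5", t6_ic, t6$dag), 0)
  # symmetry
  expect_equal(resnik_similarity(c("T3", "T5"), "T3", t6_ic, t6$dag),
               resnik_similarity("T3", c("T3", "T5"), t6_ic, t6$dag))
})

test_that("ATO and weighted ATO reproduce the worked examples", {
  expect_identical(ato_similarity("T3", c("T3", "T5"), t6$dag), 3L)
  expect_identical(ato_similarity("T3", "T5", t6$dag), 1L)
  expect_identical(ato_similarity("T3", "T3", t6$dag),
                   length(ancestors(t6$dag, "T3")))
  expect_equal(weighted_ato_similarity("T3", c("T3", "T5"), t6$dag, t6_ic),
               0.98083, tolerance = 1e-5)
  expect_equal(weighted_ato_similarity("T3", "T5", t6$dag, t6_ic), 0)
  # uniform weights of 1 degenerate to plain ATO
  u <- setNames(rep(1, 6), paste0("T", 0:5))
  expect_equal(weighted_ato_similarity("T3", c("T3", "T5"), t6$dag, u), 3)
})

test_that("exhaustive scoring ranks the toy catalog correctly", {
  s <- score_all_diseases("T3", t6$catalog, t6$dag, "resnik")
  expect_identical(s$disease_id, c("D1", "D4", "D2", "D3"))
  expect_equal(s$score, c(0.69315, 0.51986, 0.28768, 0), tolerance = 1e-5)
  expect_identical(s$rank, 1:4)

  a <- score_all_diseases("T3", t6$catalog, t6$dag, "ato")
  expect_identical(a$disease_id[1:2], c("D1", "D4"))  # tie at 3, id order
  expect_identical(a$rank[1:2], c(1L, 1L))            # competition ranks
  expect_identical(a$rank[3:4], c(3L, 4L))
  expect_equal(a$score, c(3, 3, 2, 1))

  one <- disease_catalog(list(list(id = "X", name = "x", terms = "T5")))
  expect_identical(score_all_diseases("T3", one, t6$dag, "ato")$rank, 1L)
})

test_that("all four metrics agree with naive oracles on random fixtures", {
  for (seed in 1:25) {
    fx <- random_oracle_fixture(seed)
    obj <- pkg_objects_from(fx)
    oic <- oracle_ic(fx$parents, fx$annot)
    tw <- topological_weights(obj$dag)
    q <- fx$query
    suppressMessages(for (d in names(fx$annot)) {
      dt <- fx$annot[[d]]
      expect_identical(ato_similarity(q, dt, obj$dag),
                       oracle_ato(fx$parents, q, dt))
      expect_equal(weighted_ato_similarity(q, dt, obj$dag, obj$ic),
                   oracle_wato(fx$parents, q, dt, oic), tolerance = 1e-10)
      expect_equal(weighted_ato_similarity(q, dt, obj$dag, tw),
                   oracle_wato(fx$parents, q, dt, tw$tic), tolerance = 1e-10)
      if (any(!is.na(oic[q])))
        expect_equal(resnik_similarity(q, dt, obj$ic, obj$dag),
                     oracle_resnik(fx$parents, oic, q, dt),
                     tolerance = 1e-10)
    })
  }
})

test_that("similarity invariants hold on random fixtures", {
  for (seed in 1:8) {
    fx <- random_oracle_fixture(seed)
    obj <- pkg_objects_from(fx)
    q <- fx$query
    self_ato <- ato_similarity(q, q, obj$dag)
    for (d in fx$annot) {
      # ATO self-maximality
      expect_lte(ato_similarity(q, d, obj$dag), self_ato)
      # adding an ancestor of an existing disease term never changes ATO
      anc_pool <- setdiff(ancestral_closure(obj$dag, d), d)
      if (length(anc_pool) > 0) {
        d2 <- c(d, anc_pool[1])
        expect_identical(ato_similarity(q, d2, obj$dag),
                         ato_similarity(q, d, obj$dag))
      }
      # Resnik bound: each best match <= the anchor term's own IC
      qa <- q[q %in% obj$ic$annotated]; da <- d[d %in% obj$ic$annotated]
      if (length(qa) > 0 && length(da) > 0) {
        suppressMessages(
          expect_lte(resnik_similarity(q, d, obj$ic, obj$dag),
                     0.5 * (mean(obj$ic$ic[qa]) + mean(obj$ic$ic[da])) + 1e-12))
      }
    }
  }
})

test_that("unannotated query terms are dropped for catalog-weighted metrics only", {
  # T2 is annotated in t6 (D3, D4 below); craft a catalog where it is not
  cat2 <- disease_catalog(list(
    list(id = "A", name = "a", terms = "T3"),
    list(id = "B", name = "b", terms = "T4")))
  ic2 <- catalog_information_content(cat2, t6$dag)
  expect_false("T5" %in% ic2$annotated)
  expect_message(
    val <- resnik_similarity(c("T3", "T5"), "T4", ic2, t6$dag), "dropped")
  expect_equal(val, resnik_similarity("T3", "T4", ic2, t6$dag))
  expect_error(resnik_similarity("T5", "T4", ic2, t6$dag), "ato")
  # plain ATO keeps all resolvable terms
  expect_identical(ato_similarity(c("T3", "T5"), "T4", t6$dag), 2L)
})

test_that("class signal-to-noise separates coherent classes", {
  # class A diseases share 3 specific terms; others are spread out
  dagA <- ontology_dag(
    ids = c("Z0", paste0("Z", 1:8)),
    parents = c(list(Z0 = character(0)),
                setNames(as.list(rep("Z0", 8)), paste0("Z", 1:8))))
  mk <- function(id, ts) list(id = id, name = id, terms = ts)
  catA <- disease_catalog(list(
    mk("A1", c("Z1", "Z2", "Z3")), mk("A2", c("Z1", "Z2", "Z3")),
    mk("A3", c("Z1", "Z2", "Z3", "Z4")),
    mk("B1", c("Z4", "Z5")), mk("B2", c("Z4", "Z6")),
    mk("B3", c("Z4", "Z7")), mk("B4", c("Z1", "Z8"))))
  snr <- class_signal_to_noise(catA, dagA, list(A = c("A1", "A2", "A3")),
                               method = "resnik")
  expect_gt(snr$snr[1], 1)

  # identical term sets everywhere -> every pairwise score equal -> snr 1
  catU <- disease_catalog(lapply(1:6, function(i)
    mk(paste0("U", i), c("Z1", "Z2"))))
  snrU <- class_signal_to_noise(catU, dagA,
                                list(c1 = c("U1", "U2", "U3")), "ato")
  expect_equal(snrU$snr[1], 1, tolerance = 1e-12)

  # zero between-class similarity -> flagged undefined
  catZ <- disease_catalog(list(mk("P1", "Z1"), mk("P2", "Z1"),
                               mk("Q1", "Z5"), mk("Q2", "Z6")))
  expect_warning(
    snrZ <- class_signal_to_noise(catZ, dagA, list(P = c("P1", "P2")),
                                  method = "ato_ic"),
    "SNR NA")
  expect_true(is.na(snrZ$snr[1]))
  # too-small classes are skipped
  expect_warning(expect_error(
    class_signal_to_noise(catZ, dagA, list(P = "P1"), "resnik"),
    "no analyzable"), "skipped")
})
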