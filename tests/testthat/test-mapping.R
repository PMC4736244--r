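test_that("similarity converts to dissimilarity by max-subtraction", {
  s <- matrix(c(9, 5, 3,
                5, 9, 1,
                3, 1, 9), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d <- to_dissimilarity(s)
  expect_equal(unname(d$values["a", "b"]), 4)
  expect_equal(unname(d$values["b", "c"]), 8)
  expect_identical(unname(diag(d$values)), c(0, 0, 0))
  # constant matrix -> all zero
  expect_true(all(to_dissimilarity(matrix(2, 2, 2))$values == 0))
  ns <- s; ns[1, 2] <- 99
  expect_error(to_dissimilarity(ns), "symmetric")
  # entrywise check against the formula on a real toy score matrix
  sm <- similarity_matrix(t6$catalog, t6$dag, "resnik")
  dd <- to_dissimilarity(sm)
  off <- upper.tri(sm)
  expect_equal(dd$values[off], (max(sm) - sm)[off])
})

test_that("classical MDS reconstructs Euclidean-embeddable distances", {
  # 3-4-5 right triangle
  dm <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3)
  lay <- classical_mds(dm, k = 2)
  rec <- as.matrix(stats::dist(lay$coords))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-9)
  # random planar point sets reproduce their own distances
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:10, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    dm2 <- as.matrix(stats::dist(pts))
    lay2 <- classical_mds(dm2, k = 2)
    rec2 <- as.matrix(stats::dist(lay2$coords))
    expect_lt(max(abs(rec2 - dm2)) / max(dm2), 1e-6)
  }
  # identical points are coincident
  lay3 <- suppressWarnings(classical_mds(matrix(0, 2, 2), k = 1))
  expect_equal(lay3$coords[1, ], lay3$coords[2, ])
  # deterministic sign canonicalization
  a <- classical_mds(dm, k = 2)
  b <- classical_mds(dm, k = 2)
  expect_identical(a$coords, b$coords)
  expect_true(all(diff(a$eigenvalues) <= 1e-9))
})

test_that("MDS zero-pads dimensions beyond the positive eigenvalues", {
  # 3 collinear points have one positive eigenvalue
  dm <- matrix(c(0, 1, 2,
                 1, 0, 1,
                 2, 1, 0), 3, 3)
  expect_warning(lay <- classical_mds(dm, k = 2), "positive eigenvalues")
  expect_true(all(lay$coords[, 2] == 0))
})

test_that("query projection is a convex combination of m neighbors", {
  lay <- structure(list(ids = c("A", "B"),
                        coords = matrix(c(0, 1, 0, 0), 2, 2,
                                        dimnames = list(c("A", "B"), NULL)),
                        eigenvalues = c(1, 0)), class = "map_layout")
  top <- data.frame(disease_id = c("B", "A"), score = c(3, 1))
  p <- project_query(lay, top, m = 2)
  expect_equal(unname(p), c(0.75, 0))
  expect_equal(unname(project_query(lay, top, m = 1)),
               unname(lay$coords["B", ]))
  expect_error(project_query(lay, data.frame(disease_id = c("A", "B"),
                                             score = c(0, 0)), m = 2),
               "similarity 0")
  # default m = 5 on a real layout; projection inside the hull per axis
  sim <- similarity_matrix(t6$catalog, t6$dag, "resnik")
  lay4 <- classical_mds(to_dissimilarity(sim), k = 2)
  scored <- score_all_diseases("T3", t6$catalog, t6$dag, "resnik")
  expect_error(project_query(lay4, scored), "at least m = 5")
  p4 <- project_query(lay4, scored, m = 4)
  for (j in 1:2) {
    expect_gte(p4[j], min(lay4$coords[, j]) - 1e-12)
    expect_lte(p4[j], max(lay4$coords[, j]) + 1e-12)
  }
})

test_that("radar radii follow the self-normalized dissimilarity formula", {
  scored <- score_all_diseases("T3", t6$catalog, t6$dag, "resnik")
  self <- query_self_score("T3", t6$catalog, t6$dag, "resnik")
  expect_equal(self, 0.69315, tolerance = 1e-5)
  sim <- similarity_matrix(t6$catalog, t6$dag, "resnik")
  oneD <- classical_mds(to_dissimilarity(sim), k = 1)
  rp <- radar_layout(scored, self, oneD)
  expect_equal(rp$r[rp$disease_id == "D1"], 0, tolerance = 1e-9)
  expect_equal(rp$r[rp$disease_id == "D2"], 0.58496, tolerance = 1e-5)
  expect_equal(rp$r[rp$disease_id == "D3"], 1, tolerance = 1e-9)
  # r ordering is the reverse of the score ordering
  expect_identical(order(rp$r), order(-scored$score))
  # angles span [0, 360*(n-1)/n]
  expect_gte(min(rp$theta), 0)
  expect_lte(max(rp$theta), 360 * 3 / 4 + 1e-9)
  expect_error(radar_layout(scored, 0, oneD), "positive")
  # single point gets theta 0
  rp1 <- radar_layout(scored[1, ], self, NULL)
  expect_identical(rp1$theta, 0)
})

test_that("radar encodings use the most pathogenic linked variant", {
  scored <- score_all_diseases("T3", t6$catalog, t6$dag, "resnik")
  self <- query_self_score("T3", t6$catalog, t6$dag, "resnik")
  v <- data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "T",
                  zygosity = "het", gene = c("GZ", "GZ"),
                  maf = c(1e-3, NA), pathogenicity = c(0.4, 0.8),
                  consequence = "", source = "vcf")
  rp <- radar_layout(scored, self, NULL, t6$catalog, v,
                     excluded = "D2")
  d1 <- rp[rp$disease_id == "D1", ]
  expect_equal(d1$color_value, 0.8)             # most pathogenic wins
  expect_equal(d1$size_value, -log10(1e-6))     # its missing MAF -> max size
  expect_true(rp$excluded[rp$disease_id == "D2"])
  expect_true(is.na(rp$size_value[rp$disease_id == "D3"]))  # no linked variant
  # frameshift rule upstream: missing pathogenicity becomes 1 at VCF load
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
           "chr1\t5\t.\tA\tAT\t.\tPASS\tANN=AT|frameshift_variant|HIGH|GZ|x|x\tGT\t0/1")
  vv <- read_vcf(write_tmp(vcf, ".vcf"))
  expect_identical(vv$pathogenicity, 1)
  rp2 <- radar_layout(scored, self, NULL, t6$catalog, vv)
  expect_equal(rp2$color_value[rp2$disease_id == "D1"], 1)
})
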