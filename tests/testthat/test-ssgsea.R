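test_that("rank transform gives average ranks and monotone invariance", {
  m <- ExpressionMatrix(matrix(c(1, 2, 3,
                                 5, 5, 1), 3, 2,
                               dimnames = list(c("A", "B", "C"),
                                               c("s1", "s2"))))
  R <- rankTransform(m)
  expect_equal(unname(R[, "s1"]), c(1, 2, 3))
  expect_equal(unname(R[, "s2"]), c(2.5, 2.5, 1))
  expect_equal(unname(colSums(R)), rep(3 * 4 / 2, 2))

  big <- randomExpression(40, 5, seed = 2)
  logged <- ExpressionMatrix(log2(exprValues(big) + 1))
  expect_equal(rankTransform(big), rankTransform(logged))

  flat <- ExpressionMatrix(matrix(c(1, 1, 2, 3), 2, 2,
                                  dimnames = list(c("A", "B"),
                                                  c("s1", "s2"))))
  expect_error(rankTransform(flat), "identical values")
})

test_that("single-set ES matches direct summation of the running sum", {
  ranks <- setNames(c(5, 4, 3, 2, 1), c("g1", "g2", "g3", "g4", "g5"))
  es <- singleSetES(ranks, "g1", alpha = 0.25)
  expect_equal(es, oracleES(ranks, "g1", alpha = 0.25), tolerance = 1e-12)
  # top-ranked singleton: P_in is 1 at every position, P_out accumulates
  expect_equal(es, 5 - (0 + 1/4 + 2/4 + 3/4 + 4/4), tolerance = 1e-12)

  expect_error(singleSetES(ranks, "absent"), "no genes")
  expect_error(singleSetES(ranks, names(ranks)), "whole gene universe")
})

test_that("matrix scorer agrees with the single-set path and the oracle", {
  m <- randomExpression(30, 4, seed = 5)
  sets <- randomSets(geneIds(m), 4, seed = 6)
  e <- ssgseaScore(m, sets, ssgseaParams(minSetOverlap = 0.5))
  R <- rankTransform(m)
  for (sig in names(sets)) for (j in sampleIds(m)) {
    expect_equal(enrichES(e)[sig, j],
                 singleSetES(R[, j], geneSets(sets)[[sig]]),
                 tolerance = 1e-12)
    expect_equal(enrichES(e)[sig, j],
                 oracleES(R[, j], geneSets(sets)[[sig]]),
                 tolerance = 1e-9)
  }
})

test_that("scores are deterministic and invariant to gene row order", {
  m <- randomExpression(50, 6, seed = 9)
  sets <- randomSets(geneIds(m), 5, seed = 10)
  e1 <- ssgseaScore(m, sets)
  e2 <- ssgseaScore(m, sets)
  expect_identical(enrichES(e1), enrichES(e2))

  perm <- sample(nrow(exprValues(m)))
  mPerm <- ExpressionMatrix(exprValues(m)[perm, ])
  expect_equal(enrichES(ssgseaScore(mPerm, sets)), enrichES(e1))

  # identical samples get identical scores
  v <- exprValues(m); v[, 2] <- v[, 1]
  eDup <- ssgseaScore(ExpressionMatrix(v), sets)
  expect_identical(enrichES(eDup)[, 1], setNames(enrichES(eDup)[, 2],
                                                 rownames(enrichES(eDup))))
})

test_that("ES is invariant under strictly monotone per-sample transforms", {
  m <- randomExpression(40, 5, seed = 12)
  sets <- randomSets(geneIds(m), 3, seed = 13)
  mono <- ExpressionMatrix(exp(exprValues(m) / 10))
  expect_equal(enrichES(ssgseaScore(mono, sets)),
               enrichES(ssgseaScore(m, sets)), tolerance = 1e-12)
})

test_that("tied expression values are scored with the documented tie order", {
  v <- matrix(c(2, 2, 2, 1, 5), 5, 1,
              dimnames = list(c("g1", "g2", "g3", "g4", "g5"), "s1"))
  m <- ExpressionMatrix(v)
  sets <- GeneSetCollection(list(a = c("g2", "g5"), b = c("g1", "g4")))
  e <- ssgseaScore(m, sets, ssgseaParams())
  R <- rankTransform(m)
  for (sig in c("a", "b"))
    expect_equal(enrichES(e)[sig, 1],
                 oracleES(R[, 1], geneSets(sets)[[sig]]), tolerance = 1e-12)
})

test_that("signatures failing the overlap filter are dropped with a warning", {
  m <- randomExpression(20, 3, seed = 3)
  sets <- GeneSetCollection(list(
    ok = geneIds(m)[1:5],
    thin = c(geneIds(m)[1], paste0("zz", 1:9))))  # 10% present
  expect_warning(e <- ssgseaScore(m, sets), "thin")
  expect_equal(rownames(enrichES(e)), "ok")

  allThin <- GeneSetCollection(list(thin = paste0("zz", 1:5)))
  expect_error(suppressWarnings(ssgseaScore(m, allThin)), "all signatures")
})

test_that("NES normalization follows its two documented modes", {
  es <- matrix(c(0, 2, 4, 1, 3, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  e <- new("EnrichmentMatrix", es = es, nes = matrix(numeric(0), 0, 0),
           params = ssgseaParams())
  n1 <- normalizeNES(e)
  expect_equal(unname(enrichNES(n1)["a", ]), c(0, 0.5, 1))  # range 4

  # positive scaling leaves range-normalized NES unchanged
  e2 <- new("EnrichmentMatrix", es = es * 7, nes = matrix(numeric(0), 0, 0),
            params = ssgseaParams())
  expect_equal(enrichNES(normalizeNES(e2)), enrichNES(n1))

  ez <- new("EnrichmentMatrix", es = es, nes = matrix(numeric(0), 0, 0),
            params = ssgseaParams(normalization = "zscore"))
  nz <- enrichNES(normalizeNES(ez))
  expect_equal(unname(rowMeans(nz)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(nz, 1, sd)), c(1, 1), tolerance = 1e-12)

  const <- new("EnrichmentMatrix",
               es = matrix(1, 2, 2, dimnames = list(c("a", "b"),
                                                    c("s1", "s2"))),
               nes = matrix(numeric(0), 0, 0), params = ssgseaParams())
  expect_error(normalizeNES(const), "degenerate")
  expect_error(enrichNES(e), "normalizeNES")
})

test_that("adding a gene outside every set shifts ES only via the complement ECDF", {
  m <- randomExpression(30, 3, seed = 21)
  sets <- randomSets(geneIds(m), 3, seed = 22)
  vPlus <- rbind(exprValues(m),
                 extra001 = rexp(3, 0.2))
  mPlus <- ExpressionMatrix(vPlus)
  ePlus <- ssgseaScore(mPlus, sets)
  RPlus <- rankTransform(mPlus)
  for (sig in names(sets)) for (j in 1:3)
    expect_equal(enrichES(ePlus)[sig, j],
                 oracleES(RPlus[, j], geneSets(sets)[[sig]]),
                 tolerance = 1e-9)
})
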