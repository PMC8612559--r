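test_that("synthetic morphologies are seeded, bounded, and degrade to a ball", {
  spec <- SyntheticMorphologySpec()
  m1 <- generateSyntheticMorphology(spec)
  m2 <- generateSyntheticMorphology(spec)
  f1 <- tempfile(); f2 <- tempfile()
  writeSWC(m1, f1); writeSWC(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s <- m1@sections
  # one primary dendrite per stem attached to the soma
  expect_equal(sum(s$parent == "soma"), 56)
  perdend <- tapply(s$nseg[-1], sub("_.*", "", s$name[-1]), sum)
  expect_true(all(perdend >= 2 & perdend <= 193))
  m0 <- generateSyntheticMorphology(SyntheticMorphologySpec(nDendrites = 0))
  expect_equal(nrow(m0@sections), 1)
  expect_equal(m0@sections$kind, "sphere")
})

test_that("random patterns are seeded and partition the dendrites", {
  m <- small_synth_model()
  p1 <- drawPattern(m, nAmpa = 20, nGaba = 10, seed = 3)
  p2 <- drawPattern(m, nAmpa = 20, nGaba = 10, seed = 3)
  expect_identical(p1@sites, p2@sites)
  expect_true(all(p1@sites$onset >= 0 & p1@sites$onset <= 2000))
  dend <- egabathr:::.dendrite_table(m)
  med <- stats::median(rep(dend$pathlen, times = pmax(1L, round(dend$area /
           min(dend$area)))))
  prox <- dend$pathlen <= med
  expect_true(any(prox) && any(!prox))
  pp <- drawPattern(m, nAmpa = 200, seed = 5, ampaPlacement = "proximal")
  pd <- drawPattern(m, nAmpa = 200, seed = 5, ampaPlacement = "distal")
  key <- function(p) paste(p@sites$section, round(p@sites$pos, 6))
  dkey <- paste(dend$section, round(dend$pos, 6))
  expect_true(all(key(pp) %in% dkey[prox]))
  expect_true(all(key(pd) %in% dkey[!prox]))
})

test_that("synapse placement is uniform per unit dendritic length", {
  m <- small_synth_model()
  n <- 20000
  pat <- drawPattern(m, nAmpa = n, seed = 11)
  dend <- egabathr:::.dendrite_table(m)
  dkey <- paste(dend$section, round(dend$pos, 6))
  counts <- table(factor(paste(pat@sites$section, round(pat@sites$pos, 6)),
                         levels = dkey))
  expected <- n * dend$area / sum(dend$area)
  chi2 <- sum((as.numeric(counts) - expected)^2 / expected)
  df <- nrow(dend) - 1
  expect_lt(chi2, qchisq(0.999, df))
})

test_that("spike probability is zero without drive and seeded exactly", {
  m <- small_synth_model()
  r0 <- estimatePAP(m, nAmpa = 10, gAmpa = 0, nSweeps = 5, seed = 2)
  expect_equal(r0$pap, 0)
  r1 <- estimatePAP(m, nAmpa = 10, gAmpa = 1.5, nSweeps = 8, seed = 2)
  r2 <- estimatePAP(m, nAmpa = 10, gAmpa = 1.5, nSweeps = 8, seed = 2)
  expect_identical(r1$apSweeps, r2$apSweeps)
  expect_equal(r1$se, sqrt(r1$pap * (1 - r1$pap) / 8))
})

test_that("the half-maximum conductance interpolates the p_AP curve", {
  cur <- new("PAPCurve", grid = c(0.1, 0.2, 0.3), pap = c(0.1, 0.5, 0.9),
             nSweeps = rep(99, 3), se = rep(0.05, 3), meta = list())
  expect_equal(gAmpa50(cur)$gAmpa50, 0.2)
  cur2 <- new("PAPCurve", grid = c(0.1, 0.3), pap = c(0.2, 0.8),
              nSweeps = rep(99, 2), se = rep(0.05, 2), meta = list())
  expect_equal(gAmpa50(cur2)$gAmpa50, 0.2)
  cur3 <- new("PAPCurve", grid = c(0.1, 0.3), pap = c(0.6, 0.9),
              nSweeps = rep(99, 2), se = rep(0.05, 2), meta = list())
  expect_error(gAmpa50(cur3), "bracket")
})
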