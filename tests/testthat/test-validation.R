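test_that("confusion_matrix cross-tabulates classification rows against reference columns", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                         classes = c("a", "b"))
  expect_equal(unclass(cm)[, ], matrix(c(1, 0, 1, 1), 2, 2,
               dimnames = list(classification = c("a", "b"),
                               reference = c("a", "b"))))
  ident <- confusion_matrix(letters[1:4], letters[1:4])
  expect_true(all(unclass(ident)[upper.tri(ident) | lower.tri(ident)] == 0))
  single <- confusion_matrix("HC", "FC", classes = c("FC", "HC"))
  expect_equal(unclass(single)["HC", "FC"], 1)
  expect_equal(sum(single), 1)
  expect_error(confusion_matrix("a", c("a", "b")), "equal length")
  expect_error(confusion_matrix("z", "a", classes = "a"), "outside")
})

test_that("overall accuracy is the diagonal share, with guarded degenerate cases", {
  cm <- confusion_matrix(c("a", "a", "b", "c"), c("a", "b", "b", "c"))
  expect_equal(overall_accuracy(cm), 75)
  perfect <- confusion_matrix(letters[1:5], letters[1:5])
  expect_equal(overall_accuracy(perfect), 100)
  none <- confusion_matrix(c("a", "b"), c("b", "a"))
  expect_equal(overall_accuracy(none), 0)
  expect_error(overall_accuracy(matrix(0, 2, 2)), "empty")
  expect_error(overall_accuracy(matrix(1, 2, 3)), "square")
})

test_that("user and producer accuracies follow row and column marginals", {
  m <- matrix(c(9, 0, 1, 10), 2, 2,
              dimnames = list(classification = c("x", "y"),
                              reference = c("x", "y")))
  ua <- user_producer_accuracies(m)
  expect_equal(ua$user_pct[ua$class == "x"], 90)
  expect_equal(ua$producer_pct[ua$class == "x"], 100)
  # zero marginal flagged as NA, not an error
  m0 <- matrix(c(5, 0, 0, 0), 2, 2,
               dimnames = list(classification = c("x", "y"),
                               reference = c("x", "y")))
  ua0 <- user_producer_accuracies(m0)
  expect_true(is.na(ua0$user_pct[ua0$class == "y"]))
  expect_true(is.na(ua0$producer_pct[ua0$class == "y"]))
})

test_that("kappa has its analytic fixed points and symmetry properties", {
  perfect <- confusion_matrix(rep(letters[1:4], 5), rep(letters[1:4], 5))
  expect_equal(cohens_kappa(perfect), 1)
  # rank-1 expected table (independent marginals) -> kappa = 0
  m <- outer(c(2, 3, 5), c(4, 1, 5))
  dimnames(m) <- list(classification = letters[1:3], reference = letters[1:3])
  expect_equal(cohens_kappa(m), 0, tolerance = 1e-12)
  # invariance under simultaneous row/column permutation
  cmm <- unclass(acp_reference_confusion())
  p <- sample(nrow(cmm))
  expect_equal(cohens_kappa(cmm[p, p]), cohens_kappa(cmm))
  expect_true(cohens_kappa(cmm) >= -1 && cohens_kappa(cmm) <= 1)
  # all mass in one agreeing cell: expected agreement 1, kappa undefined
  one <- matrix(c(7, 0, 0, 0), 2, 2)
  expect_warning(k <- cohens_kappa(one), "undefined")
  expect_true(is.na(k))
})

test_that("accuracies track labels, not positions, under class reordering", {
  cmm <- acp_reference_confusion()
  p <- rev(seq_len(nrow(cmm)))
  a <- user_producer_accuracies(cmm)
  b <- user_producer_accuracies(unclass(cmm)[p, p])
  b <- b[match(a$class, b$class), ]
  expect_equal(a$user_pct, b$user_pct)
  expect_equal(a$producer_pct, b$producer_pct)
})

test_that("misclassification composition summarizes the off-diagonal reference column", {
  cmm <- matrix(c(5, 1, 3, 0, 4, 0, 0, 0, 6), 3, 3,
                dimnames = list(classification = c("a", "b", "c"),
                                reference = c("a", "b", "c")))
  comp <- misclassification_composition(cmm, "a")
  expect_equal(unname(comp[c("c", "b")]), c(75, 25))
  expect_length(misclassification_composition(cmm, "b"), 0)  # clean column
  single <- matrix(c(1, 2, 0, 5), 2, 2,
                   dimnames = list(classification = c("a", "b"),
                                   reference = c("a", "b")))
  expect_equal(unname(misclassification_composition(single, "a")), 100)
  expect_error(misclassification_composition(cmm, "zz"), "unknown")
})

test_that("stratified sampling from rasters is exact, reproducible and guarded", {
  set.seed(2)
  labels <- matrix(sample(1:4, 400, replace = TRUE), 20, 20)
  strata <- matrix(rep(c("A", "B"), each = 200), 20, 20)
  s <- stratified_sample(labels, strata, c(A = 30, B = 10), seed = 5)
  expect_equal(as.vector(table(s$stratum)), c(30, 10))
  expect_false(any(duplicated(s[, c("row", "col")])))
  expect_equal(s$label, labels[cbind(s$row, s$col)])
  expect_identical(s, stratified_sample(labels, strata, c(A = 30, B = 10),
                                        seed = 5))
  expect_error(stratified_sample(labels, strata, c(A = 300)), "candidate")
})

test_that("end-to-end accuracy equals independent pixel-count agreement", {
  m <- default_mosaic()
  sc <- render_scene(m, seed = 3)
  map <- classify_scene(sc)
  sites <- generate_reference_sites(m, seed = 4)
  got <- map$labels[cbind(sites$row, sites$col)]
  truth <- m$labels[cbind(sites$row, sites$col)]
  cm <- confusion_matrix(tundramorph:::landform_name(got),
                         tundramorph:::landform_name(truth))
  # oracle: direct agreement fraction over the same sites
  expect_equal(overall_accuracy(cm), 100 * mean(got == truth),
               tolerance = 1e-9)
  expect_gte(overall_accuracy(cm), 90)
})

test_that("the confusion-matrix CSV loader refuses ambiguous orientation", {
  p <- tempfile(fileext = ".csv")
  cm <- confusion_matrix(c("a", "b", "b"), c("a", "b", "a"))
  write_confusion_csv(cm, p)
  back <- read_confusion_csv(p)
  expect_equal(unclass(back)[, ], unclass(cm)[, ])
  bad <- tempfile(fileext = ".csv")
  writeLines(c("foo,a,b", "a,1,0", "b,0,1"), bad)
  expect_error(read_confusion_csv(bad), "orientation")
})
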