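# Longitudinal panel statistics: Kruskal-Wallis + Dunn comparisons, Fisher
# discriminant projection, and trajectory summaries.

seriesFrom <- function(counts, days, cytokine = "FGF-2") {
  # counts: list of per-day replicate vectors
  rows <- do.call(rbind, lapply(seq_along(days), function(i)
    data.frame(day = days[i], cytokine = cytokine, chip = 1L,
               image = seq_along(counts[[i]]), count = counts[[i]])))
  PatientSeries("p", rows)
}

test_that("Dunn pairwise z statistics match the tie-corrected formula", {
  x <- c(1, 2, 3, 2, 3, 4, 5, 10, 11, 12)
  g <- rep(c("a", "b", "c"), c(3, 4, 3))
  d <- dunnTest(x, g, adjust = "bonferroni")
  # frozen from an independent step-by-step evaluation (joint ranks, tie
  # term T = sum(t^3 - t) / (12 (N-1)))
  expect_equal(d$z, c(-1.015222, -2.577629, -1.740380), tolerance = 1e-5)
  expect_equal(d$p, c(0.310000, 0.009948, 0.081792), tolerance = 1e-5)
  expect_equal(d$p.adj, pmin(1, d$p * 3), tolerance = 1e-12)
  dh <- dunnTest(x, g, adjust = "holm")
  expect_equal(dh$p.adj, p.adjust(d$p, "holm"), tolerance = 1e-12)
})

test_that("two-group Dunn z squares to the Kruskal-Wallis statistic", {
  set.seed(2)
  x <- c(rnorm(12), rnorm(15, 0.5))
  x[3] <- x[5]  # introduce a tie to exercise the correction
  g <- rep(c("g1", "g2"), c(12, 15))
  expect_equal(dunnTest(x, g)$z^2,
               unname(kruskal.test(x, factor(g))$statistic),
               tolerance = 1e-9)
})

test_that("identical groups give a degenerate omnibus p of one", {
  # identical group contents: H = 0, p = 1
  s <- seriesFrom(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)), c(0, 21, 42))
  out <- compareTimepoints(s, "FGF-2")
  expect_equal(out$p.value, 1, tolerance = 1e-12)
  expect_equal(out$H, 0, tolerance = 1e-12)
  # fully constant data additionally warn as degenerate
  sc <- seriesFrom(list(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5)), c(0, 21, 42))
  expect_warning(outc <- compareTimepoints(sc, "FGF-2"), "degenerate")
  expect_identical(outc$p.value, 1)
})

test_that("timepoint comparison detects a shifted final timepoint", {
  set.seed(5)
  s <- seriesFrom(list(rnorm(9, 20, 3), rnorm(9, 20, 3), rnorm(9, 29, 3)),
                  c(7, 21, 42))
  out <- compareTimepoints(s, "FGF-2")
  expect_lt(out$p.value, 0.05)
  pw <- out$pairwise
  d42 <- pw[pw$group2 == "42" | pw$group1 == "42", ]
  expect_true(all(d42$p.adj < 0.05))
  expect_error(compareTimepoints(s, "nope"), "no observations")
})

test_that("null Kruskal-Wallis p-values are approximately uniform", {
  set.seed(77)
  ps <- replicate(400, {
    x <- rnorm(27)
    kruskal.test(x, factor(rep(1:3, each = 9)))$p.value
  })
  # type-I error close to nominal at the 0.05 level
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("the first discriminant recovers a planted separation axis", {
  set.seed(8)
  v <- c(3, 1, -2, 0.5); v <- v / sqrt(sum(v^2))
  x <- matrix(rnorm(200 * 4, sd = 0.2), 200, 4)
  cl <- rep(c("A", "B"), each = 100)
  x[cl == "B", ] <- x[cl == "B", ] + matrix(4 * v, 100, 4, byrow = TRUE)
  res <- ldaFitProject(x, cl, nPermutations = 100, seed = 1)
  w <- res@scaling[, 1]
  cosSim <- abs(sum(w * v)) / sqrt(sum(w^2))
  expect_gt(cosSim, 0.99)
  expect_true(res@separable)
  expect_lt(res@pvalue, 0.05)
})

test_that("LDA direction agrees with the classical reference fit", {
  set.seed(9)
  x <- matrix(rnorm(90 * 3), 90, 3)
  cl <- rep(c("A", "B", "C"), each = 30)
  x[cl == "B", 1] <- x[cl == "B", 1] + 2
  x[cl == "C", 2] <- x[cl == "C", 2] + 3
  ours <- ldaFitProject(x, cl, ridge = 0, nPermutations = 0)
  ref <- MASS::lda(x, grouping = cl)
  for (k in 1:2) {
    w1 <- ours@scaling[, k] / sqrt(sum(ours@scaling[, k]^2))
    w2 <- ref$scaling[, k] / sqrt(sum(ref$scaling[, k]^2))
    expect_gt(abs(sum(w1 * w2)), 0.999)
  }
})

test_that("classes with identical distributions are not separable", {
  set.seed(10)
  x <- matrix(rnorm(36 * 4), 36, 4)
  cl <- rep(c("d0", "d21", "d42"), each = 12)
  res <- ldaFitProject(x, cl, seed = 2)
  expect_false(res@separable)
  expect_gt(res@pvalue, 0.05)
})

test_that("LDA scores are affine-invariant without regularisation", {
  set.seed(11)
  x <- matrix(rnorm(40 * 3), 40, 3)
  cl <- rep(c("A", "B"), each = 20)
  x[cl == "B", ] <- x[cl == "B", ] + 1.5
  a <- ldaFitProject(x, cl, ridge = 0, nPermutations = 0)
  scale <- diag(c(10, 0.1, 3))
  b <- ldaFitProject(x %*% scale, cl, ridge = 0, nPermutations = 0)
  # scores identical up to per-discriminant sign and scale
  for (k in seq_len(ncol(a@scores))) {
    r <- cor(a@scores[, k], b@scores[, k])
    expect_gt(abs(r), 1 - 1e-9)
  }
  expect_equal(a@separation, b@separation, tolerance = 1e-6)
})

test_that("separation grows monotonically with class mean shift", {
  set.seed(12)
  x0 <- matrix(rnorm(40 * 2), 40, 2)
  cl <- rep(c("A", "B"), each = 20)
  seps <- sapply(c(0, 1, 2, 4), function(s) {
    x <- x0
    x[cl == "B", 1] <- x[cl == "B", 1] + s
    ldaFitProject(x, cl, nPermutations = 0)@separation
  })
  expect_true(all(diff(seps) > 0))
})

test_that("degenerate class sizes are reported by name", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(ldaFitProject(x, c("A", "A", "B", "B", "lone")),
               "lone")
})

test_that("trajectory report applies the interpolated quartile convention", {
  s <- seriesFrom(list(c(63.5, 72, 76.75), c(63.5, 72, 76.75)), c(0, 21))
  rep <- trajectoryReport(s)
  # median (IQR) printed as 72 (63.5-76.75) under type-6 interpolation
  expect_equal(rep$median[1], 72)
  expect_equal(rep$q1[1], 63.5)
  expect_equal(rep$q3[1], 76.75)
  # a constant series raises no flags
  sc <- seriesFrom(list(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5)), c(0, 21, 42))
  expect_false(any(suppressWarnings(trajectoryReport(sc))$elevated))
  # an escalating series flags its final timepoint
  set.seed(13)
  se <- seriesFrom(list(rnorm(9, 15, 2), rnorm(9, 16, 2), rnorm(9, 40, 4)),
                   c(0, 21, 42))
  repE <- trajectoryReport(se)
  expect_true(repE$elevated[repE$day == 42])
  expect_false(repE$elevated[repE$day == 0])
})
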