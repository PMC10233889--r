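toy_counts <- function(m, classes = NULL) {
  if (is.null(classes)) classes <- rep("Endogenous", nrow(m))
  mir_counts(m, classes)
}

test_that("normalization factors follow the geometric-mean definition", {
  m <- matrix(c(8L, 16L, 100L, 12L, 30L, 7L,
                8L, 16L, 100L, 12L, 30L, 7L), ncol = 2,
              dimnames = list(sprintf("m%d", 1:6), c("A", "B")))
  # identical samples: unit factors, identical log matrices
  expect_warning(nr <- normalize_counts(toy_counts(m), "top100"),
                 "endogenous")
  expect_equal(unname(nr$f), c(1, 1))
  expect_equal(nr$log2[, 1], nr$log2[, 2])

  # exact doubling: factor ratio 1/2, normalized matrices equal
  m2 <- cbind(A = c(8L, 16L, 100L, 12L, 30L, 7L),
              B = 2L * c(8L, 16L, 100L, 12L, 30L, 7L))
  rownames(m2) <- sprintf("m%d", 1:6)
  nr2 <- suppressWarnings(normalize_counts(toy_counts(m2), "top100"))
  # geometric means use count + 1, so the ratio is approximate at small counts
  expect_equal(unname(nr2$f["B"] / nr2$f["A"]), 0.5, tolerance = 0.05)

  # hand-computed oracle on a 6 x 3 matrix, spike-in scheme
  m3 <- matrix(c(5L, 9L, 14L, 200L, 100L, 50L,
                 10L, 18L, 28L, 400L, 200L, 100L,
                 2L, 4L, 7L, 100L, 50L, 25L), ncol = 3,
               dimnames = list(c("e1", "e2", "e3", "s1", "s2", "s3"),
                               c("A", "B", "C")))
  cls <- c("Endogenous", "Endogenous", "Endogenous",
           "SpikeIn", "SpikeIn", "SpikeIn")
  nr3 <- normalize_counts(toy_counts(m3, cls), "spikein")
  g_hand <- apply(m3[4:6, ] + 1, 2, function(v) exp(mean(log(v))))
  f_hand <- mean(g_hand) / g_hand
  expect_equal(nr3$g, g_hand, tolerance = 1e-12)
  expect_equal(nr3$f, f_hand, tolerance = 1e-12)
  expect_equal(nr3$normalized, sweep(m3, 2, f_hand, `*`), tolerance = 1e-12)
})

test_that("post-normalization reference geometric means are equal across samples", {
  set.seed(31)
  for (rep in 1:10) {
    nf <- 120L; ns <- sample(3:8, 1)
    m <- matrix(rnbinom(nf * ns, mu = 150, size = 5), nf, ns,
                dimnames = list(sprintf("f%03d", 1:nf),
                                sprintf("S%d", 1:ns)))
    cls <- c(rep("Endogenous", nf - 5L), rep("SpikeIn", 5L))
    for (scheme in c("top100", "spikein")) {
      nr <- normalize_counts(mir_counts(m, cls), scheme)
      ref <- m[nr$ref_features, , drop = FALSE]
      post_g <- exp(colMeans(log(sweep(ref + 1, 2, nr$f, `*`))))
      expect_lt(max(post_g) - min(post_g), 1e-9)
    }
  }
})

test_that("per-sample scaling of raw counts is removed (approximately)", {
  set.seed(7)
  # exactly 100 endogenous features so the reference set cannot shift
  m <- matrix(rnbinom(500, mu = 4000, size = 10), 100, 5,
              dimnames = list(sprintf("f%03d", 1:100), sprintf("S%d", 1:5)))
  scl <- c(1, 2, 0.5, 3, 1.5)
  m2 <- round(sweep(m, 2, scl, `*`))
  storage.mode(m2) <- "integer"
  n1 <- normalize_counts(mir_counts(m, rep("Endogenous", 100)), "top100")
  n2 <- normalize_counts(mir_counts(m2, rep("Endogenous", 100)), "top100")
  # per-sample scaling cancels up to the global reference value r (and the
  # pseudocount, negligible at counts >> 1)
  expect_equal(n1$normalized / n1$r, n2$normalized / n2$r, tolerance = 1e-2)
})

test_that("t statistics match the textbook oracle and handle degeneracy", {
  set.seed(12)
  sim <- simulate_counts(null_config(55))
  nr <- normalize_counts(sim$counts, "top100")
  de <- differential_mirnas(nr, sim$samples, "Y537S_vs_WT")
  y <- nr$log2[nr$code_class == "Endogenous", ]
  g1 <- sim$samples$sample_id[sim$samples$genotype == "Y537S"]
  g2 <- sim$samples$sample_id[sim$samples$genotype == "WT"]
  oracle <- tt_oracle_unpaired(y[, g1, drop = FALSE], y[, g2, drop = FALSE])
  expect_equal(de$t, unname(oracle[, "t"]), tolerance = 1e-10)
  expect_equal(de$p, unname(oracle[, "p"]), tolerance = 1e-10)
  expect_equal(de$log2fc, unname(rowMeans(y[, g1]) - rowMeans(y[, g2])),
               tolerance = 1e-12)

  # identical groups: log2FC 0, p 1, not significant
  norm0 <- structure(list(
    scheme = "top100", code_class = rep("Endogenous", 2),
    log2 = matrix(c(1, 2, 1, 2, 1, 2, 1, 2), 2,
                  dimnames = list(c("mA", "mB"), c("a1", "a2", "b1", "b2")))),
    class = "mir_norm")
  sheet0 <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                       genotype = c("Y537S", "Y537S", "WT", "WT"),
                       clone = "c1", treatment = "DMSO",
                       pair_id = NA_character_)
  de0 <- differential_mirnas(norm0, sheet0, "Y537S_vs_WT")
  expect_equal(de0$log2fc, c(0, 0))
  expect_equal(de0$p, c(1, 1))
  expect_false(any(de0$significant))

  # paired design, every pair shifted by exactly +1: infinite t, flagged
  ymat <- rbind(mA = c(2, 3, 4, 1, 2, 3))
  colnames(ymat) <- c("k1", "k2", "k3", "n1", "n2", "n3")
  normp <- structure(list(scheme = "top100",
                          code_class = "Endogenous", log2 = ymat),
                     class = "mir_norm")
  sheetp <- data.frame(sample_id = colnames(ymat),
                       genotype = "Y537S", clone = "c1",
                       treatment = rep(c("siESR1", "siNT"), each = 3),
                       pair_id = rep(c("p1", "p2", "p3"), 2))
  dep <- differential_mirnas(normp, sheetp, "siESR1_vs_siNT", paired = TRUE)
  expect_equal(dep$t, Inf)
  expect_equal(dep$p, 0)
  expect_equal(dep$direction, "up")
  expect_true(dep$degenerate)
  expect_equal(dep$log2fc, 1)
})

test_that("scheme union keeps either-scheme calls and drops conflicts", {
  base <- data.frame(mirna = c("m1", "m2", "m3", "m4"),
                     contrast = "Y537S_vs_WT", scheme = "top100",
                     mean_1 = 0, mean_2 = 0,
                     log2fc = c(1, 1, 1, -1), t = 2, df = 10,
                     p = c(0.01, 0.2, 0.03, 0.01), q = NA,
                     direction = c("up", "up", "up", "down"),
                     significant = c(TRUE, FALSE, TRUE, TRUE),
                     paired = FALSE, degenerate = FALSE)
  other <- base
  other$scheme <- "spikein"
  other$p <- c(0.2, 0.04, 0.001, 0.04)
  other$log2fc <- c(1, 1, 1, 1)
  other$direction <- c("up", "up", "up", "up")
  other$significant <- c(FALSE, TRUE, TRUE, TRUE)
  u <- union_de_calls(list(base, other))
  # m1 from top100 only, m2 from spikein only, m3 from the smaller p scheme
  expect_setequal(u$mirna, c("m1", "m2", "m3"))
  expect_equal(u$scheme[u$mirna == "m1"], "top100")
  expect_equal(u$scheme[u$mirna == "m2"], "spikein")
  expect_equal(u$scheme[u$mirna == "m3"], "spikein")
  # m4 significant in both directions: dropped and logged
  expect_equal(attr(u, "conflicts"), "m4")

  # union call set contains each single-scheme set minus conflicts
  for (tab in list(base, other)) {
    single <- tab$mirna[tab$significant]
    expect_true(all(setdiff(single, attr(u, "conflicts")) %in% u$mirna))
  }
})

test_that("expected-direction fractions count sign reversals", {
  mut <- data.frame(mirna = c("m1", "m2"), log2fc = c(2, -2),
                    significant = TRUE)
  kd0 <- data.frame(mirna = c("m1", "m2"), log2fc = c(0, 0),
                    significant = FALSE)
  expect_equal(expected_direction_fraction(mut, kd0)$lenient, 0)
  kd_flip <- data.frame(mirna = c("m1", "m2"), log2fc = c(-2, 2),
                        significant = c(TRUE, FALSE))
  fr <- expected_direction_fraction(mut, kd_flip)
  expect_equal(fr$lenient, 1)
  expect_equal(fr$strict, 0.5)
  # missing miRNAs leave the denominator
  fr2 <- expected_direction_fraction(mut,
                                     data.frame(mirna = "m1", log2fc = -1,
                                                significant = FALSE))
  expect_equal(fr2$n, 1)
  expect_equal(fr2$missing, "m2")

  # null Monte Carlo: with symmetric random perturbation signs the lenient
  # fraction sits at one half
  set.seed(202)
  fracs <- replicate(200, {
    kd <- data.frame(mirna = c("m1", "m2"),
                     log2fc = sample(c(-1, 1), 2, replace = TRUE),
                     significant = FALSE)
    expected_direction_fraction(mut, kd)$lenient
  })
  expect_lt(abs(mean(fracs) - 0.5), 4 * sqrt(0.25 / (2 * 200)) + 0.02)
})
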