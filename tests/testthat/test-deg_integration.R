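make_mutant <- function(genes_up, genes_down, genotype = "Y537S",
                        flags = NULL) {
  n_up <- length(genes_up); n_dn <- length(genes_down)
  deg_table(data.frame(
    gene = c(genes_up, genes_down),
    log2FC = c(rep(1, n_up), rep(-1, n_dn)),
    padj = 0.001,
    direction = c(rep("up", n_up), rep("down", n_dn)),
    label = "mutant_specific", genotype = genotype,
    mechanism_flags = flags %||% "."))
}

make_perturb <- function(genes_up, genes_down, mirna = "miR-t",
                         label = "mimic", genotype = "Y537S") {
  n_up <- length(genes_up); n_dn <- length(genes_down)
  deg_table(data.frame(
    gene = c(genes_up, genes_down),
    log2FC = c(rep(1, n_up), rep(-1, n_dn)),
    padj = 0.001,
    direction = c(rep("up", n_up), rep("down", n_dn)),
    label = label, genotype = genotype,
    mechanism_flags = ".", mirna = mirna))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("overlap report partitions the intersection by direction pair", {
  uni <- sprintf("G%02d", 1:40)
  mut <- make_mutant(uni[1:10], uni[11:20])
  # perturbation is the sign-flipped mutant table: concordant overlaps are
  # empty and opposed overlaps complete
  per <- make_perturb(uni[11:20], uni[1:10])
  rep <- overlap_perturbation_vs_mutant(per, mut, uni)
  expect_equal(rep$genes[["up_vs_down"]], sort(uni[11:20]))
  expect_equal(rep$genes[["down_vs_up"]], sort(uni[1:10]))
  expect_length(rep$genes[["up_vs_up"]], 0)
  expect_length(rep$genes[["down_vs_down"]], 0)

  # the four overlaps are disjoint and their union is the full intersection
  all_ov <- unlist(rep$genes)
  expect_equal(anyDuplicated(all_ov), 0)
  expect_setequal(all_ov, intersect(per$gene, mut$gene))

  # disjoint gene sets: all four overlaps empty with p = 1
  per2 <- make_perturb(uni[21:25], uni[26:30])
  rep2 <- overlap_perturbation_vs_mutant(per2, mut, uni)
  expect_true(all(rep2$tests$k == 0))
  expect_true(all(rep2$tests$p == 1))
})

# the direction pair expected to carry signal for a perturbation type
opposed_pair_of <- function(rep) {
  if (rep$perturbation == "mimic") "down_vs_up" else "up_vs_down"
}

test_that("planted perturbations give opposed, not concordant, enrichment", {
  for (s in 1:8) {
    cfg <- quick_config(7700 + s, target_response_frac = 1, offtarget_frac = 0,
                        coupling_odds = 25)
    net <- simulate_target_network(cfg, simulate_counts(cfg)$truth)
    per <- simulate_perturbation_degs(cfg, net$truth)
    keys <- unique(per$perturb_degs[, c("mirna", "genotype")])
    for (i in seq_len(nrow(keys))) {
      sub <- per$perturb_degs[per$perturb_degs$mirna == keys$mirna[i] &
                                per$perturb_degs$genotype == keys$genotype[i], ]
      rep <- overlap_perturbation_vs_mutant(sub, net$mutant_degs, net$universe)
      opp <- opposed_pair_of(rep)
      conc <- c("up_vs_up", "down_vs_down")
      p_opp <- rep$tests$p[rep$tests$direction_pair == opp]
      p_conc <- rep$tests$p[rep$tests$direction_pair %in% conc]
      expect_lt(p_opp, 1e-6)
      expect_true(all(p_opp < p_conc))
    }
  }
})

test_that("direct-target fractions follow the arithmetic oracle", {
  uni <- sprintf("G%04d", 1:1000)
  predicted <- list(`miR-t` = uni[1:100])
  shared <- c(uni[1:23], uni[101:127])  # 50 shared genes, 23 predicted
  rep <- structure(list(mirna = "miR-t", perturbation = "mimic",
                        genotype = "Y537S",
                        genes = list(down_vs_up = shared)),
                   class = "overlap_report")
  dtf <- direct_target_fraction(rep, predicted, uni)
  expect_equal(dtf$fraction, 0.46)
  expect_equal(dtf$p, hypergeom_upper_tail(1000, 100, 50, 23))
  expect_equal(dtf$p, stats::phyper(22, 100, 900, 50, lower.tail = FALSE))

  # predicted superset: fraction 1; disjoint: fraction 0 and p = 1
  rep_all <- rep; rep_all$genes$down_vs_up <- uni[1:10]
  expect_equal(direct_target_fraction(rep_all, predicted, uni)$fraction, 1)
  rep_none <- rep; rep_none$genes$down_vs_up <- uni[900:950]
  r0 <- direct_target_fraction(rep_none, predicted, uni)
  expect_equal(r0$fraction, 0)
  expect_equal(r0$p, 1)

  # empty shared set: fraction undefined, n = 0
  rep_empty <- rep; rep_empty$genes$down_vs_up <- character(0)
  re <- direct_target_fraction(rep_empty, predicted, uni)
  expect_equal(re$n_shared, 0)
  expect_true(is.na(re$fraction))
})

test_that("attribution counts unexplained coverage exactly and monotonically", {
  uni <- sprintf("G%02d", 1:60)
  # 10 unexplained up-regulated genes + 10 constitutive down-regulated
  mut <- make_mutant(uni[1:10], uni[11:20],
                     flags = c(rep("unexplained", 10),
                               rep("constitutive", 10)))
  mk_rep <- function(genes) structure(
    list(mirna = "miR-t", perturbation = "mimic", genotype = "Y537S",
         genes = list(down_vs_up = genes)), class = "overlap_report")

  # covers 3 of 10 unexplained (plus 5 explained genes): E = 0.30
  rep1 <- mk_rep(c(uni[1:3], uni[11:15]))
  att <- attribute_unexplained(mut, list(rep1))
  expect_equal(att$explained_fraction, 0.30)
  expect_equal(att$n_unexplained, 10)
  expect_equal(att$n_constitutive, 10)

  # no reports: E = 0; full coverage: E = 1
  expect_equal(attribute_unexplained(mut, list())$explained_fraction, 0)
  expect_equal(attribute_unexplained(mut,
                                     list(mk_rep(uni[1:10])))$explained_fraction, 1)

  # pooling never decreases E and matches a brute-force union count
  rep2 <- mk_rep(c(uni[3:6]))
  e_single <- vapply(list(rep1, rep2), function(r)
    attribute_unexplained(mut, list(r))$explained_fraction, numeric(1))
  e_pooled <- attribute_unexplained(mut, list(rep1, rep2))$explained_fraction
  expect_gte(e_pooled, max(e_single))
  brute <- length(intersect(union(rep1$genes$down_vs_up,
                                  rep2$genes$down_vs_up), uni[1:10])) / 10
  expect_equal(e_pooled, brute)

  # no unexplained genes: E reported missing, not 0/0
  mut2 <- make_mutant(uni[1:5], character(0), flags = rep("constitutive", 5))
  expect_true(is.na(attribute_unexplained(mut2,
                                          list(rep1))$explained_fraction))
})
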