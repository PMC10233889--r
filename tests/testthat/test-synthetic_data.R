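test_that("count simulation is deterministic and respects the null", {
  a <- simulate_counts(quick_config(42))
  b <- simulate_counts(quick_config(42))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$planted, b$truth$planted)

  n <- simulate_counts(null_config(42))
  expect_equal(nrow(n$truth$planted), 0)
  expect_length(n$truth$coupled, 0)
})

test_that("NB counts match their configured means (moment oracle)", {
  # near-zero dispersion, unit size factors, 1000 draws per feature
  cfg <- null_config(9, n_mirna = 25L, n_spikein = 2L,
                     clones_per_genotype = 2L, reps_per_clone = 250L,
                     nb_dispersion = 1e-6, size_factor_sdlog = 0)
  sim <- simulate_counts(cfg)
  wt <- sim$samples$sample_id[sim$samples$genotype == "WT"]
  cts <- sim$counts$counts[names(sim$truth$base_mu), wt]
  m <- rowMeans(cts)
  se <- apply(cts, 1, stats::sd) / sqrt(length(wt))
  expect_true(all(abs(m - sim$truth$base_mu) <= 3 * se + 1e-9))
})

test_that("coupled target sampling achieves the configured odds", {
  # Monte-Carlo oracle on a scaled-down network: the empirical odds of a
  # coupled miRNA's target landing in its direction-opposed DEG set should
  # match coupling_odds
  hits <- tot <- 0
  base <- NULL
  for (s in 1:300) {
    cfg <- simulation_config(seed = 5000 + s, n_mirna = 10L, n_genes = 1500L,
                             genotypes = "Y537S",
                             n_planted_de_mirna = 2L,
                             planted_split = c(both = 0L, Y537S = 2L),
                             n_coupled_mirna = 1L,
                             coupled_split = c(both = 0L, Y537S = 1L),
                             coupling_odds = 5, deg_per_direction = 150L,
                             targets_per_mirna = c(30L, 30L),
                             knockdown = FALSE)
    net <- simulate_target_network(cfg, simulate_counts(cfg)$truth)
    m <- net$truth$coupled
    opp <- net$truth$opposed_sets[[m]]
    k <- length(intersect(net$truth$targets[[m]], opp))
    hits <- hits + k
    tot <- tot + length(net$truth$targets[[m]])
    base <- length(opp) / cfg$n_genes
  }
  p <- hits / tot
  odds_ratio <- (p / (1 - p)) / (base / (1 - base))
  expect_lt(abs(odds_ratio - 5) / 5, 0.1)

  # saturation: infinite odds draws targets only from the opposed set
  cfg_inf <- simulation_config(seed = 77, n_mirna = 10L, n_genes = 1500L,
                               genotypes = "Y537S",
                               n_planted_de_mirna = 2L,
                               planted_split = c(both = 0L, Y537S = 2L),
                               n_coupled_mirna = 1L,
                               coupled_split = c(both = 0L, Y537S = 1L),
                               coupling_odds = Inf, deg_per_direction = 150L,
                               targets_per_mirna = c(30L, 30L),
                               knockdown = FALSE)
  net <- simulate_target_network(cfg_inf, simulate_counts(cfg_inf)$truth)
  m <- net$truth$coupled
  expect_true(all(net$truth$targets[[m]] %in% net$truth$opposed_sets[[m]]))
})

test_that("perturbation DEGs follow the sign convention and response rate", {
  cfg <- quick_config(21, target_response_frac = 1, offtarget_frac = 0)
  net <- simulate_target_network(cfg, simulate_counts(cfg)$truth)
  per <- simulate_perturbation_degs(cfg, net$truth)
  planted <- net$truth$planted
  for (m in net$truth$coupled) {
    sub <- per$perturb_degs[per$perturb_degs$mirna == m, ]
    lfc <- planted$log2fc[planted$mirna == m][1]
    if (lfc < 0) {
      # mimic of a mutant-down miRNA: all responsive targets go down
      expect_true(all(sub$label == "mimic"))
      expect_true(all(sub$direction == "down"))
    } else {
      # inhibitor of a mutant-up miRNA: responsive targets appear up
      expect_true(all(sub$label == "inhibitor"))
      expect_true(all(sub$direction == "up"))
    }
    expect_setequal(unique(sub$gene), unique(net$truth$targets[[m]]))
  }

  # binomial oracle on the response fraction
  hits <- tot <- 0
  for (s in 1:60) {
    cfg <- quick_config(6000 + s, target_response_frac = 0.5,
                        offtarget_frac = 0)
    net <- simulate_target_network(cfg, simulate_counts(cfg)$truth)
    per <- simulate_perturbation_degs(cfg, net$truth)
    for (m in net$truth$coupled) {
      tg <- unique(net$truth$targets[[m]])
      deg <- unique(per$perturb_degs$gene[per$perturb_degs$mirna == m])
      hits <- hits + length(intersect(deg, tg))
      tot <- tot + length(tg)
    }
  }
  se <- sqrt(0.25 / tot)
  expect_lt(abs(hits / tot - 0.5), 4 * se + 0.01)
})

test_that("genome context placement matches its ground truth by brute force", {
  cfg <- quick_config(8)
  net <- simulate_target_network(cfg, simulate_counts(cfg)$truth)
  ctx <- simulate_genome_context(cfg, net$truth)
  tr <- ctx$truth$context
  bf10 <- brute_window_count(tr$chrom, tr$tss, as.data.frame(ctx$erbs), 1e4)
  bf100 <- brute_window_count(tr$chrom, tr$tss, as.data.frame(ctx$erbs), 1e5)
  expect_equal(bf10$count >= 1, tr$erbs_within_10kb)
  expect_equal(bf100$count >= 1, tr$erbs_within_100kb)

  # no placement probability, no in-window sites
  cfg0 <- quick_config(8, erbs_prob_10kb = 0, erbs_prob_100kb_only = 0,
                       erbs_diff_prob = 0)
  ctx0 <- simulate_genome_context(cfg0, net$truth)
  tr0 <- ctx0$truth$context
  bf0 <- brute_window_count(tr0$chrom, tr0$tss, as.data.frame(ctx0$erbs), 1e5)
  expect_true(all(bf0$count == 0))

  # no intronic fraction, no host assignments
  cfg_noh <- quick_config(8, intronic_host_fraction = 0,
                          host_concordant_fraction = 0,
                          intronic_opposite_frac = 0)
  ctx_noh <- simulate_genome_context(cfg_noh, net$truth)
  expect_true(all(is.na(ctx_noh$truth$context$host_gene)))
})

test_that("growth curves obey the closed form and recover the rate", {
  g <- make_growth(c(A = 1 / 24), sd = 0)
  norm <- normalize_confluence(g)
  expect_equal(norm$log2_rel[norm$time_h == 48], rep(2, 4))
  flat <- make_growth(c(A = 0), sd = 0)
  expect_true(all(abs(normalize_confluence(flat)$log2_rel) < 1e-12))

  # estimator-recovery: mean fitted slope across seeds within 2 SE of truth
  r <- 0.03
  slopes <- vapply(1:300, function(s) {
    set.seed(9000 + s)
    g <- make_growth(c(A = r, B = r), sd = 0.05)
    compare_slopes(normalize_confluence(g), c("A", "B"))$fits$slope[1]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - r), 2 * stats::sd(slopes) / sqrt(length(slopes)))
})

test_that("whole simulations are deterministic and internally consistent", {
  a <- simulate_all(quick_config(13))
  b <- simulate_all(quick_config(13))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$targets, b$truth$targets)
  expect_equal(as.data.frame(a$growth), as.data.frame(b$growth))

  # coupled subset of planted; every coupled miRNA has direction-opposed
  # targets among mutant-specific genes
  expect_true(all(a$truth$coupled %in% a$truth$planted$mirna))
  for (m in a$truth$coupled)
    expect_gt(length(intersect(a$truth$targets[[m]],
                               a$truth$opposed_sets[[m]])), 0)

  # predicted sets are subsets of validated sets
  expect_true(all(vapply(names(a$predicted), function(m)
    all(a$predicted[[m]] %in% a$validated[[m]]), logical(1))))
})
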