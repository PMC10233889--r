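# Synthetic-data generator: every pipeline input with planted ground truth.
#
# Counts are negative binomial with lognormal per-sample size factors, so
# both normalization schemes are consequential; spike-ins share one mean
# across samples before size-factor scaling, so spike-in normalization
# removes size factors in expectation. Differential miRNAs are planted as
# group-mean shifts; a coupled subset gets target sets preferentially drawn
# from direction-opposed mutant-specific genes; mimic/inhibitor
# perturbations re-regulate a fraction of those targets; a synthetic genome
# places ER-binding sites and host genes around planted miRNA TSSs; growth
# curves are exponential with planted rates.
#
# Each simulate_* stage draws from its own seeded stream (config seed plus a
# fixed stage offset) so stages are individually reproducible and
# order-independent.

#' Build a simulation configuration
#'
#' Defaults describe the study-shaped scenario: ~800 panel miRNAs with 5
#' spike-ins, 84 planted differential miRNAs (|log2FC| = 2) split across two
#' ER-mutant genotypes (12 in both, 44 Y537S-only, 28 D538G-only), 15 of
#' them coupled to mutant-specific genes (2/8/5 both/Y537S/D538G), 500
#' mutant-specific genes per genotype and direction in a 15000-gene
#' universe, and IncuCyte-style growth at 2-h intervals over 48 h.
#'
#' @param seed integer RNG seed.
#' @param n_mirna,n_spikein panel composition.
#' @param n_genes gene universe size.
#' @param genotypes mutant genotypes simulated against WT.
#' @param clones_per_genotype,reps_per_clone baseline arm design (2 x 3 = 6
#'   samples per genotype).
#' @param nb_mean_log2_range range of log2 baseline NB means (uniform).
#' @param nb_dispersion NB dispersion (1/size), > 0.
#' @param size_factor_sdlog lognormal sdlog of per-sample size factors.
#' @param spikein_mean_log2_range log2 mean range of spike-in features.
#' @param n_planted_de_mirna number of planted differential miRNAs.
#' @param planted_split named counts (both, plus one per genotype) summing
#'   to `n_planted_de_mirna`.
#' @param planted_log2fc absolute planted effect size (sign random per
#'   miRNA).
#' @param n_coupled_mirna coupled subset size.
#' @param coupled_split named counts like `planted_split`, summing to
#'   `n_coupled_mirna`, each component at most its planted counterpart.
#' @param coupling_odds odds favoring direction-opposed mutant-specific
#'   genes when drawing a coupled miRNA's targets (>= 1; Inf draws targets
#'   exclusively from the opposed set).
#' @param targets_per_mirna integer range of target-set sizes.
#' @param predicted_overlap_frac fraction of each validated set kept in the
#'   predicted collection.
#' @param deg_per_direction mutant-specific genes per genotype and
#'   direction.
#' @param mechanism_props named proportions over mechanism flags
#'   (constitutive, er_binding, accessibility, unexplained); must sum to 1.
#' @param target_response_frac fraction of a perturbed miRNA's targets that
#'   respond to mimic/inhibitor treatment.
#' @param offtarget_frac off-target perturbation DEGs as a fraction of the
#'   responsive-target count.
#' @param knockdown simulate the paired ER knock-down arm.
#' @param n_pairs_knockdown complete (siNT, siESR1) pairs per mutant
#'   genotype.
#' @param knockdown_reversal_prob probability a planted miRNA reverts toward
#'   WT upon ER knock-down.
#' @param knockdown_reversal_frac fractional reversal of the planted log2FC
#'   in reverting miRNAs.
#' @param pair_sdlog lognormal sdlog of pair-level (clonal) offsets in the
#'   knock-down arm.
#' @param erbs_prob_10kb probability a planted miRNA has an ER-binding site
#'   within 10 kb of its pri-miRNA TSS.
#' @param erbs_prob_100kb_only probability of a site within 100 kb only.
#' @param erbs_diff_prob probability an in-window site is differential
#'   (gained/lost), given any site within 100 kb.
#' @param atac_diff_prob probability of a differential accessible-chromatin
#'   peak within 100 kb.
#' @param intronic_host_fraction fraction of planted miRNAs placed inside a
#'   host-gene intron.
#' @param intronic_opposite_frac fraction of intronic placements on the
#'   strand opposite their host.
#' @param host_concordant_fraction fraction of same-strand intronic miRNAs
#'   whose host is differentially expressed concordantly.
#' @param growth_rates named vector of growth rates (doublings per hour) per
#'   condition.
#' @param growth_noise_sd sd of multiplicative log-normal confluence noise.
#' @param growth_wells wells per condition.
#' @param growth_t_max,growth_dt time course (h) and sampling interval (h).
#' @param growth_c0 initial confluence percent.
#' @param growth_ceiling confluence ceiling percent.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_mirna = 800L,
                              n_spikein = 5L,
                              n_genes = 15000L,
                              genotypes = c("Y537S", "D538G"),
                              clones_per_genotype = 2L,
                              reps_per_clone = 3L,
                              nb_mean_log2_range = c(3, 11),
                              nb_dispersion = 0.1,
                              size_factor_sdlog = 0.2,
                              spikein_mean_log2_range = c(9, 11),
                              n_planted_de_mirna = 84L,
                              planted_split = c(both = 12L, Y537S = 44L,
                                                D538G = 28L),
                              planted_log2fc = 2,
                              n_coupled_mirna = 15L,
                              coupled_split = c(both = 2L, Y537S = 8L,
                                                D538G = 5L),
                              coupling_odds = 5,
                              targets_per_mirna = c(60L, 150L),
                              predicted_overlap_frac = 0.6,
                              deg_per_direction = 500L,
                              mechanism_props = c(constitutive = 0.45,
                                                  er_binding = 0.15,
                                                  accessibility = 0.1,
                                                  unexplained = 0.3),
                              target_response_frac = 0.6,
                              offtarget_frac = 0.5,
                              knockdown = TRUE,
                              n_pairs_knockdown = 4L,
                              knockdown_reversal_prob = 0.5,
                              knockdown_reversal_frac = 0.6,
                              pair_sdlog = 0.4,
                              erbs_prob_10kb = 12 / 15,
                              erbs_prob_100kb_only = 1 / 15,
                              erbs_diff_prob = 4 / 13,
                              atac_diff_prob = 6 / 15,
                              intronic_host_fraction = 30 / 84,
                              intronic_opposite_frac = 0.1,
                              host_concordant_fraction = 4 / 30,
                              growth_rates = c(WT_negctrl = 0.021,
                                               WT_mimic = 0.019,
                                               Y537S_negctrl = 0.033,
                                               Y537S_mimic = 0.004,
                                               D538G_negctrl = 0.030,
                                               D538G_mimic = 0.005),
                              growth_noise_sd = 0.05,
                              growth_wells = 4L,
                              growth_t_max = 48,
                              growth_dt = 2,
                              growth_c0 = 15,
                              growth_ceiling = 100) {
  cfg <- as.list(environment())
  probs <- c(cfg$predicted_overlap_frac, cfg$target_response_frac,
             cfg$knockdown_reversal_prob, cfg$erbs_prob_10kb,
             cfg$erbs_prob_100kb_only, cfg$erbs_diff_prob,
             cfg$atac_diff_prob, cfg$intronic_host_fraction,
             cfg$intronic_opposite_frac, cfg$host_concordant_fraction,
             cfg$mechanism_props)
  if (any(probs < 0 | probs > 1)) stopf("all probabilities must lie in [0, 1]")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (cfg$coupling_odds < 1) stopf("coupling_odds must be >= 1")
  if (abs(sum(cfg$mechanism_props) - 1) > 1e-9)
    stopf("mechanism_props must sum to 1")
  if (sum(cfg$planted_split) != cfg$n_planted_de_mirna)
    stopf("planted_split must sum to n_planted_de_mirna")
  if (sum(cfg$coupled_split) != cfg$n_coupled_mirna)
    stopf("coupled_split must sum to n_coupled_mirna")
  if (!all(names(cfg$coupled_split) %in% names(cfg$planted_split)) ||
      any(cfg$coupled_split > cfg$planted_split[names(cfg$coupled_split)]))
    stopf("coupled_split components must not exceed planted_split")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# stage seed offsets: counts 0, network 1, perturbation 2, genome 3, growth 4
stage_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% .Machine$integer.max)
}

mirna_ids <- function(n) sprintf("miR-%04d", seq_len(n))
gene_ids <- function(n) sprintf("GENE%05d", seq_len(n))

#' Simulate panel miRNA counts with planted differential expression
#'
#' @param config a [simulation_config()].
#' @return list with `counts` ([mir_counts()]), `samples` (sample sheet) and
#'   `truth` (planted table, coupled set, knock-down reverting set, size
#'   factors, seed, warnings).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, 0L)
  n_m <- config$n_mirna; n_s <- config$n_spikein
  mirnas <- mirna_ids(n_m)
  spikes <- sprintf("SPIKE-%d", seq_len(n_s))
  warnings <- character(0)

  # planted assignment: which miRNAs shift, in which genotype(s), which sign
  planted_idx <- sort(sample.int(n_m, config$n_planted_de_mirna))
  groups <- rep(names(config$planted_split), config$planted_split)
  groups <- sample(groups)
  signs <- sample(c(-1, 1), config$n_planted_de_mirna, replace = TRUE)
  lfc <- matrix(0, nrow = n_m, ncol = length(config$genotypes),
                dimnames = list(mirnas, config$genotypes))
  planted_rows <- list()
  for (j in seq_along(planted_idx)) {
    gts <- if (groups[j] == "both") config$genotypes else groups[j]
    for (gt in gts) {
      lfc[planted_idx[j], gt] <- signs[j] * config$planted_log2fc
      planted_rows[[length(planted_rows) + 1L]] <- data.frame(
        mirna = mirnas[planted_idx[j]], genotype = gt,
        log2fc = signs[j] * config$planted_log2fc, group = groups[j],
        stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted_rows)) do.call(rbind, planted_rows) else
    data.frame(mirna = character(), genotype = character(),
               log2fc = numeric(), group = character(),
               stringsAsFactors = FALSE)

  # coupled subset, respecting the both/Y537S-only/D538G-only split
  coupled <- character(0)
  for (g in names(config$coupled_split)) {
    pool <- mirnas[planted_idx][groups == g]
    coupled <- c(coupled, sample(pool, config$coupled_split[[g]]))
  }
  coupled <- sort(coupled)

  # baseline arm sample sheet
  sheet <- do.call(rbind, lapply(c("WT", config$genotypes), function(gt) {
    do.call(rbind, lapply(seq_len(config$clones_per_genotype), function(cl) {
      data.frame(
        sample_id = sprintf("%s_c%d_r%d", gt, cl,
                            seq_len(config$reps_per_clone)),
        genotype = gt, clone = sprintf("c%d", cl), treatment = "DMSO",
        pair_id = NA_character_, cohort = "cell_line",
        stringsAsFactors = FALSE)
    }))
  }))
  n_per_group <- config$clones_per_genotype * config$reps_per_clone
  if (n_per_group < 2)
    warnings <- c(warnings,
                  "fewer than 2 samples per group; differential tests will fail")

  # knock-down arm: paired siNT/siESR1 in mutant genotypes
  reverting <- character(0)
  if (config$knockdown) {
    kd <- do.call(rbind, lapply(config$genotypes, function(gt) {
      do.call(rbind, lapply(seq_len(config$n_pairs_knockdown), function(i) {
        data.frame(
          sample_id = sprintf("%s_p%d_%s", gt, i, c("siNT", "siESR1")),
          genotype = gt,
          clone = sprintf("c%d", (i - 1L) %% config$clones_per_genotype + 1L),
          treatment = c("siNT", "siESR1"),
          pair_id = sprintf("%s_p%d", gt, i), cohort = "cell_line",
          stringsAsFactors = FALSE)
      }))
    }))
    sheet <- rbind(sheet, kd)
    pl_mirnas <- unique(planted$mirna)
    reverting <- sort(pl_mirnas[runif(length(pl_mirnas)) <
                                  config$knockdown_reversal_prob])
  }

  base_mu <- 2^runif(n_m, config$nb_mean_log2_range[1],
                     config$nb_mean_log2_range[2])
  spike_mu <- 2^runif(n_s, config$spikein_mean_log2_range[1],
                      config$spikein_mean_log2_range[2])
  sf <- exp(rnorm(nrow(sheet), 0, config$size_factor_sdlog))
  names(sf) <- sheet$sample_id

  # pair-level lognormal offsets model clonal variability in the
  # knock-down arm (the motivation for the paired t test)
  pair_ids <- unique(sheet$pair_id[!is.na(sheet$pair_id)])
  pair_off <- lapply(setNames(pair_ids, pair_ids), function(p)
    exp(rnorm(n_m, 0, config$pair_sdlog)))

  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = n_m + n_s, ncol = nrow(sheet),
                   dimnames = list(c(mirnas, spikes), sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    gt <- sheet$genotype[j]
    mu <- base_mu
    if (gt %in% colnames(lfc)) mu <- mu * 2^lfc[, gt]
    if (!is.na(sheet$pair_id[j])) {
      mu <- mu * pair_off[[sheet$pair_id[j]]]
      if (sheet$treatment[j] == "siESR1" && length(reverting)) {
        rv <- match(reverting, mirnas)
        mu[rv] <- mu[rv] *
          2^(-config$knockdown_reversal_frac * lfc[rv, gt])
      }
    }
    counts[, j] <- c(rnbinom(n_m, mu = sf[j] * mu, size = size),
                     rnbinom(n_s, mu = sf[j] * spike_mu, size = size))
  }
  list(counts = mir_counts(counts,
                           c(rep("Endogenous", n_m), rep("SpikeIn", n_s))),
       samples = sheet,
       truth = list(planted = planted, coupled = coupled,
                    reverting = reverting, size_factors = sf,
                    base_mu = setNames(base_mu, mirnas),
                    seed = config$seed, warnings = warnings))
}

#' Simulate the miRNA-target network and mutant-specific DEG table
#'
#' Uncoupled miRNAs draw targets uniformly from the gene universe; coupled
#' miRNAs draw them with odds `coupling_odds` in favor of mutant-specific
#' genes regulated opposite to the miRNA. The predicted collection is a
#' subset of the validated one.
#'
#' @param config a [simulation_config()].
#' @param truth truth list from [simulate_counts()].
#' @return list with `validated`, `predicted` (gene-set collections),
#'   `mutant_degs` (a `deg_table`), `universe`, and updated `truth` (adds
#'   `targets` and `opposed_sets`).
#' @export
simulate_target_network <- function(config, truth) {
  stage_seed(config, 1L)
  genes <- gene_ids(config$n_genes)
  mirnas <- mirna_ids(config$n_mirna)

  deg_rows <- list()
  deg_sets <- list()
  for (gt in config$genotypes) {
    picked <- sample(genes, 2L * config$deg_per_direction)
    up <- picked[seq_len(config$deg_per_direction)]
    down <- picked[config$deg_per_direction + seq_len(config$deg_per_direction)]
    deg_sets[[gt]] <- list(up = up, down = down)
    for (dir in c("up", "down")) {
      gset <- deg_sets[[gt]][[dir]]
      n <- length(gset)
      mech <- sample(names(config$mechanism_props), n, replace = TRUE,
                     prob = config$mechanism_props)
      deg_rows[[length(deg_rows) + 1L]] <- data.frame(
        gene = gset,
        log2FC = (if (dir == "up") 1 else -1) * (0.25 + abs(rnorm(n, 1, 0.6))),
        padj = 10^runif(n, -8, log10(0.049)),
        direction = dir, label = "mutant_specific", genotype = gt,
        mechanism_flags = mech, mirna = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  mutant_degs <- deg_table(do.call(rbind, deg_rows))

  planted_by_mirna <- split(truth$planted, truth$planted$mirna)
  opposed_sets <- list()
  targets <- list()
  for (m in mirnas) {
    n_t <- sample(seq(config$targets_per_mirna[1],
                      config$targets_per_mirna[2]), 1L)
    if (m %in% truth$coupled) {
      pl <- planted_by_mirna[[m]]
      opposed <- unique(unlist(lapply(seq_len(nrow(pl)), function(i) {
        dir <- if (pl$log2fc[i] > 0) "down" else "up"
        deg_sets[[pl$genotype[i]]][[dir]]
      })))
      opposed_sets[[m]] <- opposed
      if (is.infinite(config$coupling_odds)) {
        if (n_t > length(opposed))
          stopf("coupling_odds = Inf demands %d targets but only %d direction-opposed genes exist",
                n_t, length(opposed))
        targets[[m]] <- sample(opposed, n_t)
      } else {
        w <- rep(1, config$n_genes)
        w[match(opposed, genes)] <- config$coupling_odds
        targets[[m]] <- sample(genes, n_t, prob = w)
      }
    } else {
      targets[[m]] <- sample(genes, n_t)
    }
  }
  predicted <- lapply(targets, function(tg)
    sample(tg, max(1L, round(config$predicted_overlap_frac * length(tg)))))
  attr(targets, "provenance") <- "validated"
  attr(predicted, "provenance") <- "predicted"
  truth$targets <- targets
  truth$opposed_sets <- opposed_sets
  truth$deg_sets <- deg_sets
  list(validated = targets, predicted = predicted,
       mutant_degs = mutant_degs, universe = genes, truth = truth)
}

#' Simulate mimic/inhibitor perturbation DEG tables
#'
#' Each coupled miRNA is perturbed toward WT: a mimic for mutant-down
#' miRNAs (responsive targets go down), an inhibitor for mutant-up miRNAs
#' (responsive targets go up), plus off-target DEGs with random directions.
#'
#' @param config a [simulation_config()].
#' @param truth truth list from [simulate_target_network()].
#' @return list with `perturb_degs` (one `deg_table` covering all
#'   perturbations; split by `mirna` x `genotype` for analysis) and updated
#'   `truth` (adds `responsive` per miRNA).
#' @export
simulate_perturbation_degs <- function(config, truth) {
  stage_seed(config, 2L)
  genes <- gene_ids(config$n_genes)
  rows <- list()
  responsive <- list()
  planted_by_mirna <- split(truth$planted, truth$planted$mirna)
  for (m in truth$coupled) {
    tg <- unique(truth$targets[[m]])
    n_resp <- round(config$target_response_frac * length(tg))
    resp <- if (n_resp > 0) sample(tg, n_resp) else character(0)
    responsive[[m]] <- resp
    pl <- planted_by_mirna[[m]]
    for (i in seq_len(nrow(pl))) {
      gt <- pl$genotype[i]
      type <- if (pl$log2fc[i] < 0) "mimic" else "inhibitor"
      dir <- if (type == "mimic") "down" else "up"
      n_off <- round(config$offtarget_frac * length(resp))
      off <- sample(setdiff(genes, resp), n_off)
      off_dir <- sample(c("up", "down"), n_off, replace = TRUE)
      g_all <- c(resp, off)
      d_all <- c(rep(dir, length(resp)), off_dir)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g_all,
        log2FC = ifelse(d_all == "up", 1, -1) *
          (0.25 + abs(rnorm(length(g_all), 1, 0.5))),
        padj = 10^runif(length(g_all), -10, log10(0.049)),
        direction = d_all, label = type, genotype = gt,
        mechanism_flags = ".", mirna = m, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) deg_table(do.call(rbind, rows)) else
    deg_table(data.frame(gene = character(), log2FC = numeric(),
                         padj = numeric(), direction = character(),
                         label = character(), genotype = character(),
                         mechanism_flags = character(),
                         mirna = character(), stringsAsFactors = FALSE))
  truth$responsive <- responsive
  list(perturb_degs = tab, truth = truth)
}

#' Simulate the genomic context: ERBS, ATAC peaks, TSSs, loci, host genes
#'
#' Planted miRNAs are spaced 1 Mb apart on one synthetic chromosome. Sites
#' are placed inside or outside the 10 kb / 100 kb TSS windows according to
#' the configured probabilities; an `intronic_host_fraction` of miRNAs is
#' placed wholly inside a host-gene intron, with a configured fraction of
#' same-strand hosts concordantly differentially expressed.
#'
#' @param config a [simulation_config()].
#' @param truth truth list from [simulate_target_network()].
#' @return list with `erbs`, `atac`, `mirna_tss`, `mirna_loci`
#'   (interval sets), `genes` (a [gene_models()] object) and updated `truth`
#'   (adds a per-miRNA `context` data.frame).
#' @export
simulate_genome_context <- function(config, truth) {
  stage_seed(config, 3L)
  mirnas <- sort(unique(truth$planted$mirna))
  n <- length(mirnas)
  empty_iv <- interval_set(data.frame(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = numeric(), strand = character(),
    status = character(), stringsAsFactors = FALSE))
  if (n == 0) {
    truth$context <- data.frame(
      mirna = character(), chrom = character(), tss = integer(),
      strand = character(), erbs_within_10kb = logical(),
      erbs_within_100kb = logical(), differential_erbs_100kb = logical(),
      atac_diff_100kb = logical(), host_gene = character(),
      host_same_strand = logical(), host_concordant = logical(),
      stringsAsFactors = FALSE)
    dummy <- gene_models(data.frame(
      gene_id = "DUMMY", chrom = "chrS1", start = c(0L, 2000L),
      end = c(1000L, 3000L), strand = "+", stringsAsFactors = FALSE))
    return(list(erbs = empty_iv, atac = empty_iv, mirna_tss = empty_iv,
                mirna_loci = empty_iv, genes = dummy, truth = truth))
  }
  chrom <- "chrS1"
  chrom_vec <- rep(chrom, n)
  tss <- 1000000L * seq_len(n)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  within10 <- runif(n) < config$erbs_prob_10kb
  within100 <- within10 | (runif(n) < config$erbs_prob_100kb_only /
                             max(1e-12, 1 - config$erbs_prob_10kb))
  diff_erbs <- within100 & (runif(n) < config$erbs_diff_prob)
  atac_diff <- runif(n) < config$atac_diff_prob

  erbs_rows <- list(); atac_rows <- list()
  add_site <- function(rows, pos, name, status) {
    pos <- as.integer(pos)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = pos, end = pos + 400L, name = name, score = 0,
      strand = ".", status = status, stringsAsFactors = FALSE)
    rows
  }
  for (i in seq_len(n)) {
    side <- sample(c(-1, 1), 3, replace = TRUE)
    if (within10[i]) {
      d <- sample(1000:9000, 1)
      st <- if (diff_erbs[i]) sample(c("gained", "lost"), 1) else "shared"
      erbs_rows <- add_site(erbs_rows, tss[i] + side[1] * d,
                            sprintf("ERBS_%s_a", mirnas[i]), st)
      # often a second, distal site so 100 kb counts exceed 10 kb counts
      if (runif(1) < 0.5)
        erbs_rows <- add_site(erbs_rows, tss[i] + side[2] * sample(20000:90000, 1),
                              sprintf("ERBS_%s_b", mirnas[i]), "shared")
    } else if (within100[i]) {
      st <- if (diff_erbs[i]) sample(c("gained", "lost"), 1) else "shared"
      erbs_rows <- add_site(erbs_rows, tss[i] + side[1] * sample(15000:90000, 1),
                            sprintf("ERBS_%s_a", mirnas[i]), st)
    }
    # decoy far outside every window (spacing is 1 Mb, windows are 100 kb)
    if (runif(1) < 0.5)
      erbs_rows <- add_site(erbs_rows, tss[i] + sample(250000:400000, 1),
                            sprintf("ERBS_%s_x", mirnas[i]), NA_character_)
    if (atac_diff[i])
      atac_rows <- add_site(atac_rows, tss[i] + side[3] * sample(1000:90000, 1),
                            sprintf("ATAC_%s_a", mirnas[i]),
                            sample(c("gained", "lost"), 1))
    if (runif(1) < 0.5)
      atac_rows <- add_site(atac_rows, tss[i] + sample(250000:400000, 1),
                            sprintf("ATAC_%s_x", mirnas[i]), "shared")
  }
  empty_iv <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), name = character(),
                         score = numeric(), strand = character(),
                         status = character(), stringsAsFactors = FALSE)
  erbs <- interval_set(if (length(erbs_rows))
    do.call(rbind, erbs_rows) else empty_iv)
  atac <- interval_set(if (length(atac_rows))
    do.call(rbind, atac_rows) else empty_iv)

  mirna_tss <- interval_set(data.frame(
    chrom = chrom_vec, start = tss, end = tss + 1L, name = mirnas, score = 0,
    strand = strand, status = NA_character_, stringsAsFactors = FALSE))
  mirna_loci <- interval_set(data.frame(
    chrom = chrom_vec, start = tss + 200L, end = tss + 280L, name = mirnas,
    score = 0, strand = strand, status = NA_character_,
    stringsAsFactors = FALSE))

  # intronic host genes
  n_intronic <- round(config$intronic_host_fraction * n)
  intronic_idx <- sort(sample.int(n, n_intronic))
  n_opp <- round(config$intronic_opposite_frac * n_intronic)
  opp_idx <- if (n_opp > 0) sample(intronic_idx, n_opp) else integer(0)
  same_idx <- setdiff(intronic_idx, opp_idx)
  n_conc <- round(config$host_concordant_fraction * n_intronic)
  n_conc <- min(n_conc, length(same_idx))
  conc_idx <- if (n_conc > 0) sample(same_idx, n_conc) else integer(0)

  planted_by_mirna <- split(truth$planted, truth$planted$mirna)
  deg_genes_all <- unique(unlist(truth$deg_sets, use.names = FALSE))
  neutral_pool <- setdiff(gene_ids(config$n_genes), deg_genes_all)
  used_hosts <- character(0)
  host_gene <- rep(NA_character_, n)
  host_same <- rep(NA, n)
  host_conc <- rep(FALSE, n)
  exon_rows <- list()
  for (i in intronic_idx) {
    m <- mirnas[i]
    if (i %in% conc_idx) {
      pl <- planted_by_mirna[[m]][1, ]
      dir <- if (pl$log2fc > 0) "up" else "down"
      pool <- setdiff(truth$deg_sets[[pl$genotype]][[dir]], used_hosts)
      host <- pool[1]
    } else {
      pool <- setdiff(neutral_pool, used_hosts)
      host <- pool[1]
    }
    used_hosts <- c(used_hosts, host)
    h_strand <- if (i %in% opp_idx)
      setdiff(c("+", "-"), strand[i]) else strand[i]
    host_gene[i] <- host
    host_same[i] <- !(i %in% opp_idx)
    host_conc[i] <- i %in% conc_idx
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      gene_id = host, chrom = chrom,
      start = c(tss[i] - 5000L, tss[i] + 1000L),
      end = c(tss[i] - 4000L, tss[i] + 2000L),
      strand = h_strand, stringsAsFactors = FALSE)
  }
  genes <- gene_models(if (length(exon_rows)) do.call(rbind, exon_rows) else
    data.frame(gene_id = "DUMMY", chrom = chrom, start = c(0, 2000),
               end = c(1000, 3000), strand = "+", stringsAsFactors = FALSE))

  truth$context <- data.frame(
    mirna = mirnas, chrom = chrom_vec, tss = tss, strand = strand,
    erbs_within_10kb = within10, erbs_within_100kb = within100,
    differential_erbs_100kb = diff_erbs, atac_diff_100kb = atac_diff,
    host_gene = host_gene, host_same_strand = host_same,
    host_concordant = host_conc, stringsAsFactors = FALSE)
  list(erbs = erbs, atac = atac, mirna_tss = mirna_tss,
       mirna_loci = mirna_loci, genes = genes, truth = truth)
}

#' Simulate exponential confluence time courses
#'
#' `confluence(t) = C0 * 2^(r t) * exp(eps)`, `eps ~ N(0, sd^2)`, clipped at
#' the ceiling, sampled on a regular grid per well.
#'
#' @param config a [simulation_config()].
#' @return list with `growth` (a `growth_table`) and `truth_rates` (the
#'   planted rates, doublings/h).
#' @export
simulate_growth <- function(config) {
  stage_seed(config, 4L)
  t <- seq(0, config$growth_t_max, by = config$growth_dt)
  rows <- list()
  for (cond in names(config$growth_rates)) {
    r <- config$growth_rates[[cond]]
    for (w in seq_len(config$growth_wells)) {
      eps <- rnorm(length(t), 0, config$growth_noise_sd)
      conf <- pmin(config$growth_ceiling,
                   config$growth_c0 * 2^(r * t) * exp(eps))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, well = sprintf("w%d", w), time_h = t,
        confluence_pct = conf, stringsAsFactors = FALSE)
    }
  }
  list(growth = growth_table(do.call(rbind, rows)),
       truth_rates = config$growth_rates)
}

#' Run every simulation stage
#'
#' @param config a [simulation_config()].
#' @return list with all pipeline inputs (`counts`, `samples`, `validated`,
#'   `predicted`, `mutant_degs`, `perturb_degs`, `universe`, `erbs`, `atac`,
#'   `mirna_tss`, `mirna_loci`, `genes`, `growth`) plus the merged `truth`.
#' @export
simulate_all <- function(config) {
  cts <- simulate_counts(config)
  net <- simulate_target_network(config, cts$truth)
  per <- simulate_perturbation_degs(config, net$truth)
  ctx <- simulate_genome_context(config, per$truth)
  gro <- simulate_growth(config)
  truth <- ctx$truth
  truth$growth_rates <- gro$truth_rates
  list(counts = cts$counts, samples = cts$samples,
       validated = net$validated, predicted = net$predicted,
       mutant_degs = net$mutant_degs, universe = net$universe,
       perturb_degs = per$perturb_degs,
       erbs = ctx$erbs, atac = ctx$atac, mirna_tss = ctx$mirna_tss,
       mirna_loci = ctx$mirna_loci, genes = ctx$genes,
       growth = gro$growth, truth = truth, config = config)
}

#' Write a simulation to disk as pipeline input files
#'
#' Emits counts.tsv, samples.tsv, validated.gmt, predicted.gmt,
#' mutant_specific.tsv, perturbation_degs.tsv, erbs.bed, atac.bed,
#' mirna_tss.bed, mirna_loci.bed, genes.gff3, growth.tsv and truth.json.
#'
#' @param sim output of [simulate_all()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_count_matrix(sim$counts, fp("counts.tsv"))
  write_sample_sheet(sim$samples, fp("samples.tsv"))
  write_gmt(sim$validated, fp("validated.gmt"))
  write_gmt(sim$predicted, fp("predicted.gmt"))
  write_deg_table(sim$mutant_degs, fp("mutant_specific.tsv"))
  write_deg_table(sim$perturb_degs, fp("perturbation_degs.tsv"))
  writeLines(sim$universe, fp("universe.txt"))
  write_bed6(sim$erbs, fp("erbs.bed"), status = TRUE)
  write_bed6(sim$atac, fp("atac.bed"), status = TRUE)
  write_bed6(sim$mirna_tss, fp("mirna_tss.bed"), status = FALSE)
  write_bed6(sim$mirna_loci, fp("mirna_loci.bed"), status = FALSE)
  write_gff3(sim$genes, fp("genes.gff3"))
  write_growth_table(sim$growth, fp("growth.tsv"))
  tr <- sim$truth
  tr$size_factors <- as.list(tr$size_factors)
  tr$base_mu <- NULL
  tr$deg_sets <- NULL
  write_json_report(tr, fp("truth.json"))
  invisible(dir)
}
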