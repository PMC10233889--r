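# End-to-end orchestration: simulate (or load) inputs, normalize and call
# differential miRNAs under both schemes, union the calls, run
# direction-aware target enrichment and candidate selection, integrate
# perturbation DEGs with the attribution summary, annotate regulatory
# context, compare growth slopes, and emit a consolidated report.

#' Build a pipeline run configuration
#'
#' @param sim a [simulation_config()] describing the synthetic inputs
#'   (simulation-backed runs; file-backed runs can instead pass a ready-made
#'   input list to [run_pipeline()]).
#' @param alpha significance threshold for miRNA DE calls and enrichment.
#' @param padj_cutoff DEG significance threshold.
#' @param windows context half-window widths (bp).
#' @param schemes normalization schemes to union over.
#' @param growth_comparisons list of condition pairs to compare.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(),
                       alpha = 0.05,
                       padj_cutoff = 0.05,
                       windows = c(10e3, 100e3),
                       schemes = c("top100", "spikein"),
                       growth_comparisons = list(
                         c("Y537S_mimic", "Y537S_negctrl"),
                         c("D538G_mimic", "D538G_negctrl"),
                         c("WT_mimic", "WT_negctrl"))) {
  structure(list(sim = sim, alpha = alpha, padj_cutoff = padj_cutoff,
                 windows = windows, schemes = schemes,
                 growth_comparisons = growth_comparisons),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `sim` block
#' mirrors [simulation_config()].
#'
#' @param path path to a YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  for (nm in c("planted_split", "coupled_split", "mechanism_props",
               "growth_rates"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  if (!is.null(sim_args$targets_per_mirna))
    sim_args$targets_per_mirna <- unlist(sim_args$targets_per_mirna)
  sim <- do.call(simulation_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  if (!is.null(args$growth_comparisons))
    args$growth_comparisons <- lapply(args$growth_comparisons, unlist)
  do.call(run_config, c(list(sim = sim), args))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order; every stage consumes only validated
#' objects and the run is deterministic given the configuration seed.
#'
#' @param config a [run_config()].
#' @param inputs optional pre-built input list with the elements produced by
#'   [simulate_all()]; when NULL the configured simulation is run.
#' @return list of class `run_report` with per-stage tables and a `summary`
#'   list mirroring the JSON report.
#' @export
run_pipeline <- function(config = run_config(), inputs = NULL) {
  sim <- inputs %||% simulate_all(config$sim)
  genotypes <- config$sim$genotypes
  alpha <- config$alpha

  # --- normalization + differential miRNAs, union over schemes ---
  norms <- lapply(setNames(config$schemes, config$schemes), function(s)
    normalize_counts(sim$counts, scheme = s))
  de_union <- list()
  de_by_scheme <- list()
  for (gt in genotypes) {
    contrast <- paste0(gt, "_vs_WT")
    per_scheme <- lapply(norms, differential_mirnas, samples = sim$samples,
                         contrast = contrast, alpha = alpha,
                         filter = list(treatment = "DMSO"))
    de_by_scheme[[gt]] <- per_scheme
    u <- union_de_calls(per_scheme)
    u$genotype <- if (nrow(u)) gt else character(0)
    de_union[[gt]] <- u
  }
  de_all <- do.call(rbind, lapply(de_union, as.data.frame))
  rownames(de_all) <- NULL

  # --- ER knock-down reversal accounting (paired t test) ---
  kd_fractions <- NULL
  if (any(sim$samples$treatment == "siESR1")) {
    kd_fractions <- do.call(rbind, lapply(genotypes, function(gt) {
      kd <- differential_mirnas(norms[[1]], sim$samples, "siESR1_vs_siNT",
                                paired = TRUE, alpha = alpha,
                                filter = list(genotype = gt))
      fr <- expected_direction_fraction(de_union[[gt]], kd)
      data.frame(genotype = gt, n = fr$n, lenient = fr$lenient,
                 strict = fr$strict, stringsAsFactors = FALSE)
    }))
  }

  # --- direction-aware target enrichment + candidate funnel ---
  enrich <- direction_aware_enrichment(de_all, sim$validated,
                                       sim$mutant_degs, sim$universe,
                                       alpha = alpha,
                                       padj_cutoff = config$padj_cutoff)
  candidates <- select_candidates(enrich, alpha = alpha)

  # --- perturbation integration + attribution ---
  perturb_keys <- unique(sim$perturb_degs[, c("mirna", "genotype")])
  reports <- list()
  direct_fracs <- list()
  for (i in seq_len(nrow(perturb_keys))) {
    sub <- sim$perturb_degs[
      sim$perturb_degs$mirna == perturb_keys$mirna[i] &
        sim$perturb_degs$genotype == perturb_keys$genotype[i], , drop = FALSE]
    rep <- overlap_perturbation_vs_mutant(sub, sim$mutant_degs,
                                          sim$universe,
                                          padj_cutoff = config$padj_cutoff)
    reports[[i]] <- rep
    direct_fracs[[i]] <- direct_target_fraction(rep, sim$predicted,
                                                sim$universe)
  }
  direct_fracs <- if (length(direct_fracs)) do.call(rbind, direct_fracs)
  else NULL
  attribution <- attribute_unexplained(sim$mutant_degs, reports,
                                       padj_cutoff = config$padj_cutoff)

  # --- regulatory context ---
  context <- annotate_differential_context(sim$mirna_tss, sim$erbs,
                                           sim$atac,
                                           windows = config$windows)
  hosts <- host_gene_concordance(sim$mirna_loci, sim$genes,
                                 de_all[, c("mirna", "genotype", "direction")],
                                 sim$mutant_degs,
                                 padj_cutoff = config$padj_cutoff)

  # --- growth kinetics ---
  growth_tbl <- normalize_confluence(sim$growth)
  slopes <- do.call(rbind, lapply(config$growth_comparisons, function(pair)
    compare_slopes(growth_tbl, pair)$comparison))

  de_counts <- lapply(de_union, nrow)
  shared <- if (length(genotypes) >= 2)
    length(Reduce(intersect, lapply(de_union, function(u) u$mirna)))
  else 0L
  de_set <- sort(unique(de_all$mirna))
  intronic <- hosts[hosts$host_relationship != "none" &
                      hosts$mirna %in% de_set, , drop = FALSE]
  summary <- list(
    seed = config$sim$seed,
    alpha = alpha,
    padj_cutoff = config$padj_cutoff,
    universe_size = length(sim$universe),
    n_de_mirnas_total = length(de_set),
    n_de_mirnas_by_genotype = de_counts,
    n_de_shared = shared,
    n_candidates = nrow(candidates),
    candidate_genotype_split = as.list(table(candidates$genotypes)),
    n_context_ge1_erbs_10kb = sum(context$n_erbs_10kb >= 1),
    n_context_ge1_erbs_100kb = sum(context$n_erbs_100kb >= 1),
    n_context_ge2_erbs_10kb = sum(context$n_erbs_10kb >= 2),
    n_context_ge2_erbs_100kb = sum(context$n_erbs_100kb >= 2),
    n_differential_erbs_100kb = sum(context$any_differential_erbs_100kb),
    n_intronic = nrow(intronic),
    n_host_concordant = sum(intronic$host_concordant),
    explained_fraction = setNames(as.list(attribution$explained_fraction),
                                  attribution$genotype),
    knockdown_expected_direction = if (!is.null(kd_fractions))
      setNames(as.list(kd_fractions$lenient), kd_fractions$genotype)
    else NULL,
    slope_comparisons = lapply(seq_len(nrow(slopes)), function(i)
      as.list(slopes[i, ]))
  )
  structure(list(de_by_scheme = de_by_scheme, de_union = de_union,
                 de_all = de_all, kd_fractions = kd_fractions,
                 enrichment = enrich, candidates = candidates,
                 overlap_reports = reports, direct_fractions = direct_fracs,
                 attribution = attribution, context = context,
                 hosts = hosts, slopes = slopes, summary = summary,
                 config = config, truth = sim$truth),
            class = "run_report")
}

#' Write a run report to disk
#'
#' Emits one TSV per stage plus `report.json`; every number in the JSON
#' summary is recomputable from the stage TSVs.
#'
#' @param run a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  stopifnot(inherits(run, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_tsv(run$de_all, fp("de_mirna.tsv"))
  if (!is.null(run$kd_fractions))
    write_tsv(run$kd_fractions, fp("knockdown_fractions.tsv"))
  write_tsv(run$enrichment, fp("enrichment.tsv"))
  write_tsv(run$candidates, fp("candidates.tsv"))
  if (!is.null(run$direct_fractions))
    write_tsv(run$direct_fractions, fp("direct_target_fractions.tsv"))
  write_tsv(run$attribution, fp("attribution.tsv"))
  write_tsv(run$context, fp("context.tsv"))
  write_tsv(run$hosts, fp("host_concordance.tsv"))
  if (!is.null(run$slopes)) write_tsv(run$slopes, fp("slopes.tsv"))
  write_json_report(run$summary, fp("report.json"))
  invisible(dir)
}
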