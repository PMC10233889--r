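# Integration of mimic/inhibitor perturbation transcriptomes with
# mutant-specific genes.
#
# Reverting a miRNA toward WT levels (mimic of a mutant-down miRNA,
# inhibitor of a mutant-up miRNA) should move its responsive genes in the
# direction opposite to their mutant-specific change. The direction-opposed
# overlaps are the "miRNA-altered mutant-specific genes"; concordant
# overlaps act as negative controls.

DIRECTION_PAIRS <- c("up_vs_down", "down_vs_up", "up_vs_up", "down_vs_down")

#' Overlap a perturbation DEG table with mutant-specific genes
#'
#' Partitions the intersection of the two significant gene sets by direction
#' combination and tests each of the four combinations with a hypergeometric
#' overlap test. Pair labels read `perturbationdir_vs_mutantdir`.
#'
#' @param perturb_degs `deg_table` rows for one miRNA perturbation (one
#'   miRNA, one genotype; label `mimic` or `inhibitor`).
#' @param mutant_degs `deg_table` of mutant-specific genes.
#' @param universe gene universe: genes tested in both experiments.
#' @param padj_cutoff significance threshold applied to both tables.
#' @return object of class `overlap_report`: list with `mirna`,
#'   `perturbation`, `genotype`, `tests` (4-row data.frame with N, K, n, k,
#'   p per direction pair) and `genes` (named list of overlap gene vectors).
#' @export
overlap_perturbation_vs_mutant <- function(perturb_degs, mutant_degs,
                                           universe, padj_cutoff = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  mirna <- unique(perturb_degs$mirna[!is.na(perturb_degs$mirna)])
  if (length(mirna) != 1)
    stopf("perturbation table must name exactly one miRNA")
  label <- unique(perturb_degs$label)
  if (length(label) != 1 || !label %in% c("mimic", "inhibitor"))
    stopf("perturbation table must carry a single mimic/inhibitor label")
  gt <- unique(perturb_degs$genotype)
  if (length(gt) != 1) stopf("perturbation table must be single-genotype")
  per <- deg_direction_sets(perturb_degs, gt, padj_cutoff)
  mut <- deg_direction_sets(mutant_degs, gt, padj_cutoff)
  per <- lapply(per, intersect, universe)
  mut <- lapply(mut, intersect, universe)
  tests <- list(); genes <- list()
  for (pair in DIRECTION_PAIRS) {
    d <- strsplit(pair, "_vs_", fixed = TRUE)[[1]]
    ov <- sort(intersect(per[[d[1]]], mut[[d[2]]]))
    genes[[pair]] <- ov
    tst <- set_overlap_test(per[[d[1]]], mut[[d[2]]], universe,
                            query_id = paste(mirna, label, d[1], sep = "_"),
                            reference_id = paste(gt, "mutant", d[2], sep = "_"))
    tst$direction_pair <- pair
    tests[[pair]] <- tst
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  structure(list(mirna = mirna, perturbation = label, genotype = gt,
                 tests = tests, genes = genes),
            class = "overlap_report")
}

# the direction pair carrying the expected (reverting) signal for a
# perturbation type: a mimic re-represses its targets (perturbation-down x
# mutant-up); an inhibitor de-represses them (perturbation-up x mutant-down)
expected_pair <- function(perturbation) {
  switch(perturbation,
         mimic = "down_vs_up",
         inhibitor = "up_vs_down",
         stopf("unknown perturbation type '%s'", perturbation))
}

#' Fraction of shared genes that are predicted direct targets
#'
#' Takes the direction-opposed shared gene set of an overlap report (the
#' combination expected for the perturbation type) and asks which fraction
#' are predicted direct targets of the miRNA, with a hypergeometric
#' enrichment p against the universe.
#'
#' @param report an `overlap_report`.
#' @param predicted named list of predicted target sets.
#' @param universe gene universe.
#' @return one-row data.frame: mirna, perturbation, genotype,
#'   direction_pair, n_shared, n_predicted_in_shared, fraction (NA when the
#'   shared set is empty), p.
#' @export
direct_target_fraction <- function(report, predicted, universe) {
  stopifnot(inherits(report, "overlap_report"))
  universe <- unique(universe)
  pair <- expected_pair(report$perturbation)
  shared <- intersect(report$genes[[pair]], universe)
  pred <- intersect(unique(predicted[[report$mirna]]), universe)
  n <- length(shared)
  k <- length(intersect(shared, pred))
  data.frame(mirna = report$mirna, perturbation = report$perturbation,
             genotype = report$genotype, direction_pair = pair,
             n_shared = n, n_predicted_in_shared = k,
             fraction = if (n > 0) k / n else NA_real_,
             p = if (n > 0)
               hypergeom_upper_tail(length(universe), length(pred), n, k)
             else NA_real_,
             stringsAsFactors = FALSE)
}

#' Attribute unexplained mutant-specific genes to miRNA perturbation effects
#'
#' Pools, per genotype, the direction-opposed shared genes across overlap
#' reports ("miRNA-altered mutant-specific genes") and computes the explained
#' fraction E = |unexplained genes covered by the pool| / |unexplained
#' genes|, where "unexplained" is the mechanism flag for mutant-specific
#' genes not accounted for by constitutive ER activity, altered ER binding,
#' or chromatin accessibility. Also cross-tabulates the pooled genes across
#' all mechanism categories.
#'
#' @param mutant_degs `deg_table` of mutant-specific genes with mechanism
#'   flags.
#' @param overlap_reports list of `overlap_report` objects; each contributes
#'   its expected direction-opposed gene set to the pool of its genotype.
#' @param padj_cutoff significance threshold on the mutant table.
#' @return data.frame of class `attribution_summary`, one row per genotype:
#'   genotype, n_mutant_specific, n_constitutive, n_er_binding,
#'   n_accessibility, n_unexplained, n_pooled, n_pooled_unexplained,
#'   explained_fraction (NA when no gene is flagged unexplained); attributes
#'   `pooled` (per-genotype pooled gene lists) and `per_mirna` (per-report
#'   explained fractions).
#' @export
attribute_unexplained <- function(mutant_degs, overlap_reports,
                                  padj_cutoff = 0.05) {
  mut <- mutant_degs[mutant_degs$padj < padj_cutoff, , drop = FALSE]
  flags <- split_flags(mut$mechanism_flags)
  gts <- unique(mut$genotype)
  pooled <- setNames(vector("list", length(gts)), gts)
  per_mirna <- list()
  for (rep in overlap_reports) {
    g <- rep$genes[[expected_pair(rep$perturbation)]]
    gt <- rep$genotype
    if (!gt %in% gts) next
    pooled[[gt]] <- union(pooled[[gt]], g)
    unex_gt <- unique(mut$gene[mut$genotype == gt &
                                 vapply(flags, function(f)
                                   "unexplained" %in% f, logical(1))])
    per_mirna[[length(per_mirna) + 1L]] <- data.frame(
      mirna = rep$mirna, genotype = gt, n_altered = length(g),
      explained_fraction = if (length(unex_gt))
        length(intersect(g, unex_gt)) / length(unex_gt) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(gts, function(gt) {
    rows <- mut$genotype == gt
    gf <- flags[rows]
    genes_gt <- mut$gene[rows]
    has <- function(flag) unique(genes_gt[vapply(gf, function(f)
      flag %in% f, logical(1))])
    unex <- has("unexplained")
    pool <- pooled[[gt]] %||% character(0)
    data.frame(genotype = gt,
               n_mutant_specific = length(unique(genes_gt)),
               n_constitutive = length(has("constitutive")),
               n_er_binding = length(has("er_binding")),
               n_accessibility = length(has("accessibility")),
               n_unexplained = length(unex),
               n_pooled = length(pool),
               n_pooled_unexplained = length(intersect(pool, unex)),
               explained_fraction = if (length(unex))
                 length(intersect(pool, unex)) / length(unex) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("attribution_summary", "data.frame")
  attr(out, "pooled") <- pooled
  attr(out, "per_mirna") <- if (length(per_mirna))
    do.call(rbind, per_mirna) else NULL
  out
}
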