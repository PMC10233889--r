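# Direction-aware hypergeometric enrichment of miRNA target sets.
#
# Because miRNAs repress their targets, an up-regulated miRNA is tested
# against the down-regulated gene set and vice versa; concordant pairings are
# available as negative controls. All set sizes are computed after
# intersecting with the gene universe.

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of drawing at least `k` reference-set members in a sample of
#' `n` from a universe of `N` containing `K` reference members. Delegates to
#' [stats::phyper()] (which works in log space); the over-representation
#' convention includes `k` itself.
#'
#' @param N universe size.
#' @param K reference-set size.
#' @param n query-set size.
#' @param k observed overlap.
#' @return the p value; exactly 1 when `k == 0`.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      stopf("hypergeometric parameters must be single non-negative integers")
  }
  if (K > N || n > N) stopf("K and n must not exceed N")
  if (k > min(n, K)) stopf("k must not exceed min(n, K)")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric overlap test between two gene sets
#'
#' @param set_a query gene set.
#' @param set_b reference gene set.
#' @param universe gene universe; both sets are intersected with it first.
#' @param query_id,reference_id labels carried into the result.
#' @return one-row data.frame: query_set_id, reference_set_id, N, K, n, k, p.
#' @export
set_overlap_test <- function(set_a, set_b, universe,
                             query_id = "A", reference_id = "B") {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  a <- intersect(unique(set_a), universe)
  b <- intersect(unique(set_b), universe)
  k <- length(intersect(a, b))
  data.frame(query_set_id = query_id, reference_set_id = reference_id,
             N = length(universe), K = length(b), n = length(a), k = k,
             p = hypergeom_upper_tail(length(universe), length(b),
                                      length(a), k),
             stringsAsFactors = FALSE)
}

# direction-split significant gene sets from a DEG table
deg_direction_sets <- function(degs, genotype, padj_cutoff = 0.05) {
  rows <- degs[degs$genotype == genotype & degs$padj < padj_cutoff, ,
               drop = FALSE]
  list(up = unique(rows$gene[rows$direction == "up"]),
       down = unique(rows$gene[rows$direction == "down"]))
}

#' Direction-aware enrichment of miRNA targets in mutant-specific genes
#'
#' For every differentially expressed miRNA and each genotype it is called
#' in, tests its target set against the direction-opposed mutant-specific
#' gene set (up-miRNA vs down-genes, down-miRNA vs up-genes) with an
#' upper-tail hypergeometric test. Concordant pairings are added when
#' `include_concordant = TRUE` (negative-control analysis).
#'
#' @param de_mirnas data.frame with columns `mirna`, `genotype`, `direction`
#'   (a union call set annotated with its genotype).
#' @param targets named list of target gene sets (e.g. from [read_gmt()]).
#' @param degs a `deg_table` of mutant-specific genes.
#' @param universe gene universe (all genes tested in the DEG analysis,
#'   intersected with the target database's gene space upstream if desired).
#' @param alpha significance threshold on the raw hypergeometric p.
#' @param padj_cutoff DEG significance threshold (default 0.05).
#' @param include_concordant also compute direction-concordant tests.
#' @return data.frame of class `enrichment_result`: mirna, genotype,
#'   mirna_direction, direction_pair, N, K, n, k, p, q, significant; with
#'   attribute `skipped` (miRNAs without a target set).
#' @export
direction_aware_enrichment <- function(de_mirnas, targets, degs, universe,
                                       alpha = 0.05, padj_cutoff = 0.05,
                                       include_concordant = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  skipped <- character(0)
  rows <- list()
  for (gt in unique(de_mirnas$genotype)) {
    sets <- deg_direction_sets(degs, gt, padj_cutoff)
    sets$up <- intersect(sets$up, universe)
    sets$down <- intersect(sets$down, universe)
    sub <- de_mirnas[de_mirnas$genotype == gt, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      m <- sub$mirna[i]
      if (is.null(targets[[m]])) {
        skipped <- c(skipped, m)
        next
      }
      tg <- intersect(unique(targets[[m]]), universe)
      dirs <- if (include_concordant) c("up", "down")
              else if (sub$direction[i] == "up") "down" else "up"
      for (ref_dir in dirs) {
        ref <- sets[[ref_dir]]
        k <- length(intersect(tg, ref))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, genotype = gt, mirna_direction = sub$direction[i],
          direction_pair = paste0(sub$direction[i], "_vs_", ref_dir),
          N = length(universe), K = length(ref), n = length(tg), k = k,
          p = hypergeom_upper_tail(length(universe), length(ref),
                                   length(tg), k),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), genotype = character(),
               mirna_direction = character(), direction_pair = character(),
               N = integer(), K = integer(), n = integer(), k = integer(),
               p = numeric(), stringsAsFactors = FALSE)
  opposed <- out$direction_pair %in% c("up_vs_down", "down_vs_up")
  out$q <- NA_real_
  out$q[opposed] <- p.adjust(out$p[opposed], method = "BH")
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "skipped") <- unique(skipped)
  out
}

#' Select candidate miRNAs from direction-opposed enrichments
#'
#' A miRNA is a candidate when its direction-opposed enrichment is
#' significant in at least one genotype. The `genotypes` annotation is
#' `"both"` when significant in both mutant genotypes tested, otherwise the
#' genotype name.
#'
#' @param enrichments an `enrichment_result` data.frame.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: mirna, genotypes, n_genotypes, min_p; sorted by mirna
#'   so the result is invariant to input ordering.
#' @export
select_candidates <- function(enrichments, alpha = 0.05) {
  opp <- enrichments[enrichments$direction_pair %in%
                       c("up_vs_down", "down_vs_up"), , drop = FALSE]
  sig <- opp[opp$p < alpha, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(mirna = character(), genotypes = character(),
                      n_genotypes = integer(), min_p = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(sig, sig$mirna), function(s) {
    gts <- sort(unique(s$genotype))
    lab <- if (length(gts) >= 2) "both" else gts
    data.frame(mirna = s$mirna[1], genotypes = lab,
               n_genotypes = length(gts), min_p = min(s$p),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
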