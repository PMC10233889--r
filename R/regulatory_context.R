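# Regulatory context around differentially expressed miRNAs: ER-binding
# sites and differential chromatin accessibility near the pri-miRNA TSS, and
# intronic host-gene concordance.
#
# Windows are anchored at the pri-miRNA TSS point, symmetric +/- d and
# half-open [tss - d, tss + d); any overlap of a site interval with the
# window counts. Interval queries go through GenomicRanges (coordinates
# converted from the internal 0-based half-open convention at the call).

# point TSS (0-based position) as a width-1 GRanges
tss_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
}

#' Count interval-set members within a window of each TSS
#'
#' @param tss data.frame with columns `chrom` and `pos` (0-based TSS
#'   positions), one row per anchor.
#' @param sites an `interval_set` data.frame.
#' @param d half-window width in bp (> 0); the window is
#'   `[tss - d, tss + d)`.
#' @return data.frame with columns `count` and `nearest` (0 when a site
#'   covers the TSS, otherwise the minimal gap — the number of bases
#'   strictly between the TSS and the site; NA when the chromosome holds no
#'   site).
#' @export
count_sites_in_window <- function(tss, sites, d) {
  stopifnot(d > 0)
  if (!nrow(sites)) {
    return(data.frame(count = rep(0L, nrow(tss)),
                      nearest = rep(NA_real_, nrow(tss))))
  }
  win <- GenomicRanges::GRanges(
    tss$chrom,
    IRanges::IRanges(start = tss$pos - d + 1L, end = tss$pos + d))
  s_gr <- as_granges(sites)
  count <- GenomicRanges::countOverlaps(win, s_gr, ignore.strand = TRUE)
  pt <- tss_granges(tss$chrom, tss$pos)
  dist <- suppressWarnings(
    GenomicRanges::distanceToNearest(pt, s_gr, ignore.strand = TRUE))
  nearest <- rep(NA_real_, nrow(tss))
  nearest[S4Vectors::queryHits(dist)] <- S4Vectors::mcols(dist)$distance
  data.frame(count = as.integer(count), nearest = nearest)
}

#' Annotate miRNA TSSs with ER-binding and accessibility context
#'
#' For each pri-miRNA TSS, counts ER-binding sites (ERBS) within each window,
#' flags whether any in-window site shows differential binding
#' (status `gained` or `lost`), and counts differential accessible-chromatin
#' (ATAC) peaks within the large window.
#'
#' @param mirna_tss `interval_set` of pri-miRNA TSSs (the TSS is the interval
#'   start; the name column holds the miRNA).
#' @param erbs `interval_set` of ER-binding sites with optional status.
#' @param atac `interval_set` of accessible-chromatin peaks with optional
#'   status.
#' @param windows half-window widths in bp, small then large
#'   (default 10 kb and 100 kb).
#' @return data.frame of class `context_annotation`: mirna, chrom, tss,
#'   strand, n_erbs_10kb, n_erbs_100kb, nearest_erbs,
#'   any_differential_erbs_100kb, n_atac_diff_100kb.
#' @export
annotate_differential_context <- function(mirna_tss, erbs, atac,
                                          windows = c(10e3, 100e3)) {
  stopifnot(length(windows) == 2, windows[1] < windows[2])
  tss <- data.frame(chrom = mirna_tss$chrom, pos = mirna_tss$start)
  w_small <- count_sites_in_window(tss, erbs, windows[1])
  w_large <- count_sites_in_window(tss, erbs, windows[2])
  diff_erbs <- erbs[!is.na(erbs$status) & erbs$status %in% c("gained", "lost"), ,
                    drop = FALSE]
  any_diff <- count_sites_in_window(tss, diff_erbs, windows[2])$count > 0
  diff_atac <- atac[!is.na(atac$status) & atac$status %in% c("gained", "lost"), ,
                    drop = FALSE]
  n_atac <- count_sites_in_window(tss, diff_atac, windows[2])$count
  out <- data.frame(mirna = mirna_tss$name, chrom = mirna_tss$chrom,
                    tss = mirna_tss$start, strand = mirna_tss$strand,
                    n_erbs_10kb = w_small$count,
                    n_erbs_100kb = w_large$count,
                    nearest_erbs = w_small$nearest,
                    any_differential_erbs_100kb = any_diff,
                    n_atac_diff_100kb = n_atac,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("context_annotation", "data.frame")
  out
}

#' Intronic host-gene relationship and expression concordance
#'
#' A miRNA is intronic when its locus lies wholly inside a single intron of
#' a gene (strict containment; touching an exon boundary disqualifies).
#' Same-strand containment supports co-transcription from the host promoter;
#' opposite-strand containment is reported but excluded from concordance by
#' default. A host/miRNA pair is concordant when both are significantly
#' differentially expressed in the same genotype with the same sign.
#'
#' @param mirna_loci `interval_set` of miRNA loci (name = miRNA).
#' @param genes a [gene_models()] object.
#' @param mirna_de data.frame with columns mirna, genotype, direction for
#'   significantly DE miRNAs (union call set annotated with genotype).
#' @param host_degs `deg_table` with host gene expression calls.
#' @param same_strand_only require strand match for concordance evaluation
#'   (default TRUE).
#' @param padj_cutoff significance threshold on the host table.
#' @return data.frame: mirna, host_gene, host_relationship
#'   (`intronic_same_strand` / `intronic_opposite_strand` / `none`),
#'   host_concordant, ambiguous (multiple candidate hosts). miRNAs inside
#'   introns of several genes get one row per host, flagged ambiguous.
#' @export
host_gene_concordance <- function(mirna_loci, genes, mirna_de, host_degs,
                                  same_strand_only = TRUE,
                                  padj_cutoff = 0.05) {
  stopifnot(inherits(genes, "gene_models"))
  introns <- gene_introns(genes)
  rows <- list()
  for (i in seq_len(nrow(mirna_loci))) {
    m <- mirna_loci[i, ]
    hit <- introns[introns$chrom == m$chrom &
                     introns$start <= m$start & introns$end >= m$end, ,
                   drop = FALSE]
    # strict containment: overlapping an exon boundary is never intronic;
    # half-open coordinates make [start, end] containment exact here
    if (!nrow(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m$name, host_gene = NA_character_,
        host_relationship = "none", host_concordant = FALSE,
        ambiguous = FALSE, stringsAsFactors = FALSE)
      next
    }
    hosts <- unique(hit$gene_id)
    for (h in hosts) {
      strand_match <- hit$strand[hit$gene_id == h][1] == m$strand
      rel <- if (strand_match) "intronic_same_strand"
             else "intronic_opposite_strand"
      conc <- FALSE
      if (strand_match || !same_strand_only) {
        mde <- mirna_de[mirna_de$mirna == m$name, , drop = FALSE]
        hde <- host_degs[host_degs$gene == h &
                           host_degs$padj < padj_cutoff, , drop = FALSE]
        conc <- any(vapply(seq_len(nrow(mde)), function(j)
          any(hde$genotype == mde$genotype[j] &
                hde$direction == mde$direction[j]), logical(1)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m$name, host_gene = h, host_relationship = rel,
        host_concordant = conc, ambiguous = length(hosts) > 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), host_gene = character(),
               host_relationship = character(), host_concordant = logical(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
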