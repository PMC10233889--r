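# Panel miRNA normalization and differential expression.
#
# Two normalization schemes, both geometric-mean based:
#   top100  - reference set is the 100 endogenous features with the highest
#             mean raw count across all samples (one global set);
#   spikein - reference set is the spike-in controls.
# Per-sample factor f_j = r / g_j where g_j is the geometric mean of
# (count + pseudocount) over the reference set in sample j and r is the mean
# of the g_j, so the overall count magnitude is preserved. A +1 pseudocount
# keeps zero counts finite both inside the geometric means and before log2.

#' Normalize a count matrix by a geometric-mean reference scheme
#'
#' @param x a [mir_counts()] object.
#' @param scheme `"top100"` (highest-expressed endogenous miRNAs) or
#'   `"spikein"` (spike-in controls).
#' @param pseudocount added to counts inside geometric means and before log2
#'   (default 1).
#' @param n_ref size of the top-expressed reference set (default 100). If
#'   fewer endogenous features exist, all are used with a warning.
#' @return object of class `mir_norm`: list with `scheme`, `ref_features`,
#'   `g` (per-sample geometric means), `f` (per-sample factors), `r`
#'   (reference value, mean of `g`), `normalized` (counts * f), `log2`
#'   (log2(normalized + pseudocount)), `pseudocount`, `code_class`.
#' @export
normalize_counts <- function(x, scheme = c("top100", "spikein"),
                             pseudocount = 1, n_ref = 100L) {
  stopifnot(inherits(x, "mir_counts"))
  scheme <- match.arg(scheme)
  cts <- x$counts
  if (scheme == "top100") {
    endo <- which(x$code_class == "Endogenous")
    if (!length(endo)) stopf("no Endogenous features")
    if (length(endo) < n_ref) {
      warnf("only %d endogenous features; using all as the reference set",
            length(endo))
      ref <- endo
    } else {
      mu <- rowMeans(cts[endo, , drop = FALSE])
      ref <- endo[order(mu, decreasing = TRUE)[seq_len(n_ref)]]
    }
  } else {
    ref <- which(x$code_class == "SpikeIn")
    if (!length(ref)) stopf("spike-in normalization requires >=1 SpikeIn feature")
  }
  zero_samples <- colSums(cts) == 0
  if (any(zero_samples))
    warnf("sample '%s' has all-zero counts; factor computed from pseudocounts",
          colnames(cts)[zero_samples][1])
  g <- exp(colMeans(log(cts[ref, , drop = FALSE] + pseudocount)))
  r <- mean(g)
  f <- r / g
  normalized <- sweep(cts, 2L, f, `*`)
  structure(list(scheme = scheme,
                 ref_features = rownames(cts)[ref],
                 g = g, f = f, r = r,
                 normalized = normalized,
                 log2 = log2(normalized + pseudocount),
                 pseudocount = pseudocount,
                 code_class = x$code_class),
            class = "mir_norm")
}

# row-wise two-sample t statistics on a log-expression matrix.
# var_equal = TRUE gives the classical Student test (pooled variance);
# FALSE gives Welch. Zero-variance rows follow the degenerate convention:
# identical groups -> t = 0, p = 1; zero variance with a nonzero difference
# -> t = +/-Inf, p = 0, flagged.
row_t_unpaired <- function(y1, y2, var_equal = TRUE) {
  n1 <- ncol(y1); n2 <- ncol(y2)
  m1 <- rowMeans(y1); m2 <- rowMeans(y2)
  v1 <- rowSums((y1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((y2 - m2)^2) / (n2 - 1)
  d <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[se == 0] <- n1 + n2 - 2
  }
  finish_t(d, se, df, m1, m2)
}

row_t_paired <- function(d_mat) {
  n <- ncol(d_mat)
  d <- rowMeans(d_mat)
  v <- rowSums((d_mat - d)^2) / (n - 1)
  se <- sqrt(v / n)
  finish_t(d, se, rep(n - 1, length(d)), d, rep(0, length(d)))
}

finish_t <- function(d, se, df, m1, m2) {
  t <- d / se
  degenerate <- se == 0
  t[degenerate & d == 0] <- 0
  t[degenerate & d > 0] <- Inf
  t[degenerate & d < 0] <- -Inf
  p <- 2 * pt(-abs(t), df)
  p[degenerate & d == 0] <- 1
  p[degenerate & d != 0] <- 0
  data.frame(mean_1 = m1, mean_2 = m2, log2fc = d, t = t, df = df, p = p,
             degenerate = degenerate & d != 0)
}

#' Call differentially expressed miRNAs for one contrast
#'
#' Performs a per-miRNA two-sided t test on log2-normalized values between
#' the two groups of a contrast. Groups are matched against the `genotype`
#' column of the sample sheet, or against `treatment` when the contrast
#' levels are treatments (e.g. `"siESR1_vs_siNT"`). A paired test uses
#' within-pair differences (pairs linked by `pair_id`), motivated by clonal
#' variability between clones of the same genotype.
#'
#' @param norm a `mir_norm` object from [normalize_counts()].
#' @param samples harmonized sample sheet.
#' @param contrast string `"GROUP1_vs_GROUP2"`; log2FC is mean(GROUP1) -
#'   mean(GROUP2).
#' @param paired use a paired t test over `pair_id`-linked samples.
#' @param alpha significance threshold on the raw p value (default 0.05; no
#'   multiple-testing correction at the calling stage, BH q values are
#'   reported alongside).
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @param filter optional named list; only samples whose sheet columns equal
#'   the given values are used (e.g. `list(treatment = "DMSO")`).
#' @return data.frame of class `mir_de` with one row per endogenous miRNA:
#'   mirna, contrast, scheme, mean_1, mean_2, log2fc, t, df, p, q,
#'   direction, significant, paired, degenerate.
#' @export
differential_mirnas <- function(norm, samples, contrast, paired = FALSE,
                                alpha = 0.05, var_equal = TRUE,
                                filter = NULL) {
  stopifnot(inherits(norm, "mir_norm"))
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2) stopf("contrast must be of the form 'A_vs_B'")
  sheet <- samples
  for (nm in names(filter)) sheet <- sheet[sheet[[nm]] %in% filter[[nm]], ]
  by <- if (all(parts %in% sheet$genotype)) "genotype"
        else if (all(parts %in% sheet$treatment)) "treatment"
        else stopf("contrast levels '%s'/'%s' not found in genotype or treatment",
                   parts[1], parts[2])
  y <- norm$log2[norm$code_class == "Endogenous", , drop = FALSE]
  s1 <- sheet$sample_id[sheet[[by]] == parts[1]]
  s2 <- sheet$sample_id[sheet[[by]] == parts[2]]
  if (paired) {
    p1 <- sheet$pair_id[match(s1, sheet$sample_id)]
    p2 <- sheet$pair_id[match(s2, sheet$sample_id)]
    if (anyNA(p1) || anyNA(p2)) stopf("paired test requires pair_id on all samples")
    common <- intersect(p1, p2)
    if (length(common) < 2) stopf("paired test requires >=2 complete pairs")
    d_mat <- y[, s1[match(common, p1)], drop = FALSE] -
             y[, s2[match(common, p2)], drop = FALSE]
    res <- row_t_paired(d_mat)
    # report the per-group means of y, not the difference components
    res$mean_1 <- rowMeans(y[, s1[match(common, p1)], drop = FALSE])
    res$mean_2 <- rowMeans(y[, s2[match(common, p2)], drop = FALSE])
  } else {
    if (length(s1) < 2 || length(s2) < 2)
      stopf("unpaired test requires >=2 samples per group (got %d vs %d)",
            length(s1), length(s2))
    res <- row_t_unpaired(y[, s1, drop = FALSE], y[, s2, drop = FALSE],
                          var_equal = var_equal)
  }
  out <- data.frame(mirna = rownames(y), contrast = contrast,
                    scheme = norm$scheme, res,
                    stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out$significant <- out$p < alpha
  out$paired <- paired
  rownames(out) <- NULL
  class(out) <- c("mir_de", "data.frame")
  out
}

#' Union differential calls across normalization schemes
#'
#' A miRNA is differentially expressed if it is significant under either
#' scheme. A miRNA significant under both schemes but with conflicting
#' directions is dropped (recorded in the `conflicts` attribute). The
#' reported statistics come from the significant scheme with the smaller p.
#'
#' @param results list of `mir_de` data.frames for the same contrast, one per
#'   scheme.
#' @return `mir_de` data.frame containing only the union call set, with
#'   attribute `conflicts` (dropped miRNA names).
#' @export
union_de_calls <- function(results) {
  all <- do.call(rbind, lapply(results, as.data.frame))
  if (length(unique(all$contrast)) != 1)
    stopf("union_de_calls requires results from a single contrast")
  sig <- all[all$significant, , drop = FALSE]
  conflicts <- character(0)
  keep <- list()
  for (m in unique(sig$mirna)) {
    rows <- sig[sig$mirna == m, , drop = FALSE]
    if (length(unique(rows$direction)) > 1) {
      conflicts <- c(conflicts, m)
      next
    }
    keep[[m]] <- rows[which.min(rows$p), , drop = FALSE]
  }
  out <- if (length(keep)) do.call(rbind, keep) else
    all[0, , drop = FALSE]
  out <- out[order(out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mir_de", "data.frame")
  attr(out, "conflicts") <- sort(conflicts)
  out
}

#' Fraction of mutant-DE miRNAs reverting direction upon perturbation
#'
#' For each miRNA called differentially expressed in the mutant-vs-WT
#' contrast, asks whether its log2FC in a perturbation contrast (e.g. ER
#' knock-down vs control in the same genotype) has the opposite sign — the
#' direction expected if mutant ER drives the miRNA change. Reports the
#' lenient fraction (sign flip regardless of significance) and the strict
#' fraction (sign flip and significant in the perturbation).
#'
#' @param mutant_de `mir_de` rows for the mutant-vs-WT DE set (the union
#'   call set).
#' @param perturbation_de `mir_de` data.frame for the perturbation contrast
#'   covering all miRNAs (not only significant ones).
#' @return list with `n` (denominator), `lenient`, `strict`, and `missing`
#'   (miRNAs absent from the perturbation results, excluded from the
#'   denominator).
#' @export
expected_direction_fraction <- function(mutant_de, perturbation_de) {
  idx <- match(mutant_de$mirna, perturbation_de$mirna)
  missing <- mutant_de$mirna[is.na(idx)]
  ok <- !is.na(idx)
  mut <- mutant_de[ok, , drop = FALSE]
  per <- perturbation_de[idx[ok], , drop = FALSE]
  opposite <- sign(per$log2fc) == -sign(mut$log2fc) & per$log2fc != 0
  list(n = nrow(mut),
       lenient = if (nrow(mut)) mean(opposite) else NA_real_,
       strict = if (nrow(mut)) mean(opposite & per$significant) else NA_real_,
       missing = missing)
}
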