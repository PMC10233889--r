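# Readers and writers for every external artifact of the pipeline.
#
# All tabular formats are tab-delimited UTF-8 TSV with "." for missing values,
# so outputs diff cleanly. Genomic coordinates are 0-based half-open
# internally; GFF3 (1-based closed) is converted at the boundary.

#' Construct a validated panel miRNA count matrix
#'
#' Container for raw panel counts: an integer feature-by-sample matrix plus a
#' per-feature code class separating endogenous miRNAs from spike-in controls.
#' Raw counts are never overwritten by normalization; normalized values live
#' in the object returned by [normalize_counts()].
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). All values must be
#'   non-negative integers.
#' @param code_class character vector, one of `"Endogenous"` or `"SpikeIn"`
#'   per feature row.
#' @return An object of class `mir_counts` with elements `counts` and
#'   `code_class`.
#' @export
mir_counts <- function(counts, code_class) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate feature_id: %s",
          rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample_id: %s",
          colnames(counts)[duplicated(colnames(counts))][1])
  bad <- which(!is_count(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stopf("count at feature '%s', sample '%s' is not a non-negative integer",
          rownames(counts)[i[1]], colnames(counts)[i[2]])
  }
  code_class <- as.character(code_class)
  if (length(code_class) != nrow(counts))
    stopf("code_class length (%d) != number of features (%d)",
          length(code_class), nrow(counts))
  if (!all(code_class %in% c("Endogenous", "SpikeIn")))
    stopf("code_class must be 'Endogenous' or 'SpikeIn'")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, code_class = code_class),
            class = "mir_counts")
}

#' @export
print.mir_counts <- function(x, ...) {
  cat(sprintf("mir_counts: %d features (%d endogenous, %d spike-in) x %d samples\n",
              nrow(x$counts), sum(x$code_class == "Endogenous"),
              sum(x$code_class == "SpikeIn"), ncol(x$counts)))
  invisible(x)
}

#' Validate a sample sheet against a set of sample ids
#'
#' @param sheet data.frame with columns `sample_id`, `genotype`, `clone`,
#'   `treatment` and optionally `pair_id` and `cohort`.
#' @param sample_ids character vector of sample ids the sheet must cover
#'   exactly once each.
#' @return The sheet, row-reordered to `sample_ids`.
#' @export
validate_sample_sheet <- function(sheet, sample_ids) {
  need <- c("sample_id", "genotype", "clone", "treatment")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stopf("sample sheet lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stopf("duplicate sample_id in sample sheet: %s",
          sheet$sample_id[duplicated(sheet$sample_id)][1])
  absent <- setdiff(sample_ids, sheet$sample_id)
  if (length(absent))
    stopf("sample '%s' present in counts but missing from sample sheet",
          absent[1])
  bad_gt <- setdiff(unique(sheet$genotype), GENOTYPE_LEVELS)
  if (length(bad_gt)) stopf("unknown genotype '%s'", bad_gt[1])
  if (!is.null(sheet$cohort)) {
    bad_co <- setdiff(unique(sheet$cohort), c("cell_line", "PDX"))
    if (length(bad_co)) stopf("unknown cohort '%s'", bad_co[1])
  }
  if (is.null(sheet$pair_id)) sheet$pair_id <- NA_character_
  sheet$pair_id <- as.character(sheet$pair_id)
  sheet <- sheet[match(sample_ids, sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  sheet
}

#' Read a wide count TSV together with its sample sheet
#'
#' The count file has columns `feature_id`, `code_class`, then one column per
#' sample. The sample sheet must describe every sample column; its rows are
#' reordered to the column order of the count matrix.
#'
#' @param path path to the wide count TSV.
#' @param samplesheet_path path to the sample-sheet TSV.
#' @return list with elements `counts` (a [mir_counts()] object) and
#'   `samples` (the harmonized sample sheet).
#' @export
read_count_matrix <- function(path, samplesheet_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "code_class") %in% names(tab)))
    stopf("count file must start with feature_id and code_class columns")
  samp_cols <- setdiff(names(tab), c("feature_id", "code_class"))
  if (!length(samp_cols)) stopf("count file has no sample columns")
  m <- as.matrix(tab[, samp_cols, drop = FALSE])
  rownames(m) <- tab$feature_id
  counts <- mir_counts(m, tab$code_class)
  sheet <- read.delim(samplesheet_path, check.names = FALSE,
                      stringsAsFactors = FALSE, na.strings = c("NA", "."))
  sheet <- validate_sample_sheet(sheet, colnames(counts$counts))
  list(counts = counts, samples = sheet)
}

#' Write a count matrix to wide TSV
#' @param x a [mir_counts()] object.
#' @param path output path.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "mir_counts"))
  out <- data.frame(feature_id = rownames(x$counts),
                    code_class = x$code_class,
                    x$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(path)
}

#' Write a sample sheet TSV
#' @param sheet sample-sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv(sheet, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) || is.factor(df[[j]])) {
      v <- as.character(df[[j]]); v[is.na(v)] <- "."
      df[[j]] <- v
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".", fileEncoding = "UTF-8")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `set_id<TAB>description<TAB>gene1...`.
#' Duplicate genes within a line are dropped with a warning; empty sets and
#' lines with fewer than three fields are errors.
#'
#' @param path path to the GMT file.
#' @param provenance `"validated"` or `"predicted"`, recorded as an attribute.
#' @return named list of unique gene vectors with attribute `provenance`.
#' @export
read_gmt <- function(path, provenance = c("validated", "predicted")) {
  provenance <- match.arg(provenance)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("GMT line %d has fewer than 3 fields", i)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warnf("GMT line %d ('%s'): %d duplicate gene(s) dropped",
            i, f[1], sum(duplicated(genes)))
      genes <- unique(genes)
    }
    if (!length(genes)) stopf("GMT line %d ('%s') defines an empty set", i, f[1])
    if (f[1] %in% names(sets)) stopf("duplicate set id '%s' in GMT", f[1])
    sets[[f[1]]] <- genes
  }
  attr(sets, "provenance") <- provenance
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, attr(sets, "provenance") %||% "na", sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a BED6 interval file with an optional differential-status column
#'
#' Coordinates are 0-based half-open, kept as such internally. A 7th column,
#' when present, carries a per-interval differential status
#' (`gained`/`lost`/`shared`, `.` for not assessed).
#'
#' @param path path to the BED file.
#' @return data.frame with columns chrom, start, end, name, score, strand,
#'   status (class `interval_set`).
#' @export
read_bed6 <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (!ncol(tab) %in% c(6, 7)) stopf("BED file must have 6 or 7 columns")
  names(tab)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  tab$status <- if (ncol(tab) >= 7) as.character(tab[[7]]) else NA_character_
  tab <- tab[, c("chrom", "start", "end", "name", "score", "strand", "status")]
  interval_set(tab)
}

#' Construct/validate an interval set (0-based half-open)
#' @param df data.frame with columns chrom, start, end, name, score, strand
#'   and optionally status.
#' @return validated data.frame of class `interval_set`.
#' @export
interval_set <- function(df) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("interval set lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(df$status)) df$status <- NA_character_
  df$status[df$status %in% c(".", "")] <- NA_character_
  if (any(!is.na(df$status) & !df$status %in% STATUS_LEVELS))
    stopf("unknown status token '%s'",
          df$status[!is.na(df$status) & !df$status %in% STATUS_LEVELS][1])
  if (any(!nzchar(df$chrom))) stopf("empty chrom field")
  bad <- which(df$start >= df$end)
  if (length(bad)) stopf("interval %d has start >= end (%d >= %d)",
                         bad[1], df$start[bad[1]], df$end[bad[1]])
  if (any(!df$strand %in% c("+", "-", ".")))
    stopf("malformed strand '%s'",
          df$strand[!df$strand %in% c("+", "-", ".")][1])
  df <- df[, c("chrom", "start", "end", "name", "score", "strand", "status")]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Write an interval set as BED6(+status)
#' @param x interval set data.frame.
#' @param path output path.
#' @param status write the 7th status column (default: only when any status
#'   is set).
#' @export
write_bed6 <- function(x, path, status = any(!is.na(x$status))) {
  cols <- x[, c("chrom", "start", "end", "name", "score", "strand")]
  if (status) cols$status <- ifelse(is.na(x$status), ".", x$status)
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# interval_set (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand))
  if (!is.null(x$name)) gr$name <- x$name
  if (!is.null(x$status)) gr$status <- x$status
  gr
}

#' Construct a validated gene model set
#'
#' Gene models are held as an exon table (0-based half-open); introns are the
#' gaps between consecutive exons of a gene, and the TSS is the 5'-most exon
#' boundary on the gene's strand.
#'
#' @param exons data.frame with columns gene_id, chrom, start, end, strand.
#' @return object of class `gene_models`: list with `exons` (sorted, validated)
#'   and `genes` (one row per gene: gene_id, chrom, strand, tss).
#' @export
gene_models <- function(exons) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stopf("exon table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(exons$start >= exons$end)) stopf("exon with start >= end")
  if (any(!exons$strand %in% c("+", "-"))) stopf("gene strand must be + or -")
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  by_gene <- split(exons, exons$gene_id)
  genes <- do.call(rbind, lapply(by_gene, function(e) {
    if (length(unique(e$chrom)) != 1 || length(unique(e$strand)) != 1)
      stopf("gene '%s' spans multiple chromosomes or strands", e$gene_id[1])
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stopf("gene '%s' has overlapping exons", e$gene_id[1])
    tss <- if (e$strand[1] == "+") min(e$start) else max(e$end) - 1L
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               strand = e$strand[1], tss = tss, stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(exons = exons, genes = genes), class = "gene_models")
}

#' Derive introns from a gene model set
#' @param gm a [gene_models()] object.
#' @return data.frame gene_id, chrom, start, end, strand of introns
#'   (0-based half-open); zero rows for single-exon genes.
#' @export
gene_introns <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  by_gene <- split(gm$exons, gm$exons$gene_id)
  out <- lapply(by_gene, function(e) {
    if (nrow(e) < 2) return(NULL)
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = e$end[-nrow(e)], end = e$start[-1],
               strand = e$strand[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read gene models from GFF3
#'
#' Reads `exon` features (grouped by their `Parent` attribute) via
#' rtracklayer and converts coordinates from 1-based closed to the internal
#' 0-based half-open convention.
#'
#' @param path path to a GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stopf("GFF3 file contains no exon features")
  parent <- vapply(as.list(ex$Parent), function(p) {
    if (!length(p)) NA_character_ else sub("^gene:", "", p[1])
  }, character(1))
  if (anyNA(parent)) stopf("GFF3 exon without a Parent attribute")
  gene_models(data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE))
}

#' Write gene models to GFF3
#' @param gm a [gene_models()] object.
#' @param path output path.
#' @export
write_gff3 <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  ex <- gm$exons
  spans <- gm$genes
  span_rng <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e)
    data.frame(gene_id = e$gene_id[1], start = min(e$start),
               end = max(e$end), stringsAsFactors = FALSE)))
  spans <- merge(spans, span_rng, by = "gene_id", sort = TRUE)
  g_gr <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end),
    strand = spans$strand, type = "gene", ID = spans$gene_id,
    Parent = IRanges::CharacterList(vector("list", nrow(spans))))
  e_gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
    strand = ex$strand, type = "exon", ID = NA_character_,
    Parent = IRanges::CharacterList(as.list(ex$gene_id)))
  rtracklayer::export(c(g_gr, e_gr), path, format = "gff3")
  invisible(path)
}

#' Read a DEG (differentially expressed gene) table
#'
#' TSV with columns gene, log2FC, padj, direction, label, genotype,
#' mechanism_flags (semicolon-joined, `.` for none) and, for perturbation
#' tables, an optional `mirna` column naming the perturbed miRNA.
#'
#' @param path path to the TSV.
#' @return validated data.frame of class `deg_table`.
#' @export
read_deg_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA"))
  if (!is.null(tab$mirna)) tab$mirna[tab$mirna == "."] <- NA_character_
  deg_table(tab)
}

#' Construct/validate a DEG table
#' @param tab data.frame; see [read_deg_table()] for columns.
#' @return validated data.frame of class `deg_table`.
#' @export
deg_table <- function(tab) {
  need <- c("gene", "log2FC", "padj", "direction", "label", "genotype")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("DEG table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(tab$mechanism_flags)) tab$mechanism_flags <- "."
  if (is.null(tab$mirna)) tab$mirna <- NA_character_
  if (any(is.na(tab$padj) | tab$padj < 0 | tab$padj > 1))
    stopf("padj must lie in [0, 1]")
  if (any(!tab$direction %in% c("up", "down")))
    stopf("direction must be 'up' or 'down'")
  if (any(!tab$label %in% c("mutant_specific", "mimic", "inhibitor")))
    stopf("unknown DEG label '%s'",
          tab$label[!tab$label %in% c("mutant_specific", "mimic", "inhibitor")][1])
  bad_dir <- (tab$direction == "up") != (tab$log2FC > 0)
  if (any(bad_dir))
    stopf("direction inconsistent with sign(log2FC) for gene '%s'",
          tab$gene[bad_dir][1])
  flags <- split_flags(tab$mechanism_flags)
  bad_flag <- vapply(flags, function(f) any(!f %in% MECHANISM_FLAGS), logical(1))
  if (any(bad_flag)) stopf("unknown mechanism flag on gene '%s'",
                           tab$gene[bad_flag][1])
  has_flag <- lengths(flags) > 0
  if (any(has_flag & tab$label != "mutant_specific"))
    stopf("mechanism flags are only allowed on mutant_specific rows")
  excl <- vapply(flags, function(f)
    "unexplained" %in% f && length(f) > 1, logical(1))
  if (any(excl)) stopf("'unexplained' excludes all other mechanism flags")
  tab <- tab[, c("gene", "log2FC", "padj", "direction", "label",
                 "genotype", "mechanism_flags", "mirna")]
  rownames(tab) <- NULL
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Write a DEG table TSV
#' @param tab a `deg_table`.
#' @param path output path.
#' @export
write_deg_table <- function(tab, path) {
  write_tsv(tab, path)
  invisible(path)
}

#' Read a confluence time-course table
#'
#' Long TSV with columns condition, well, time_h, confluence_pct. Each
#' (condition, well) series must have at least three strictly increasing
#' time points, and confluence must lie in (0, 100].
#'
#' @param path path to the TSV.
#' @return validated data.frame of class `growth_table`.
#' @export
read_growth_table <- function(path) {
  growth_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Construct/validate a growth table
#' @param tab data.frame; see [read_growth_table()].
#' @return validated data.frame of class `growth_table`.
#' @export
growth_table <- function(tab) {
  need <- c("condition", "well", "time_h", "confluence_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("growth table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(tab$time_h < 0)) stopf("negative time_h")
  if (any(tab$confluence_pct <= 0 | tab$confluence_pct > 100))
    stopf("confluence_pct must lie in (0, 100] (well '%s')",
          tab$well[tab$confluence_pct <= 0 | tab$confluence_pct > 100][1])
  key <- paste(tab$condition, tab$well, sep = "\r")
  for (s in split(tab, key)) {
    if (nrow(s) < 3)
      stopf("well '%s' (%s) has fewer than 3 time points", s$well[1],
            s$condition[1])
    if (any(diff(s$time_h) <= 0))
      stopf("time not strictly increasing in well '%s' (%s)", s$well[1],
            s$condition[1])
  }
  tab <- tab[, need]
  rownames(tab) <- NULL
  class(tab) <- c("growth_table", "data.frame")
  tab
}

#' Write a growth table TSV
#' @param tab a `growth_table`.
#' @param path output path.
#' @export
write_growth_table <- function(tab, path) {
  write_tsv(tab, path)
  invisible(path)
}

#' Write a machine-readable JSON report
#'
#' Scalars are unboxed and numbers written at full precision so identical
#' runs produce byte-identical files.
#'
#' @param x list to serialize.
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
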