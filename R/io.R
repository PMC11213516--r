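#' Write methylation counts as Bismark-style coverage files
#'
#' One file per sample with the six Bismark coverage columns: chrom,
#' 1-based start, 1-based end, methylation percentage, count methylated,
#' count unmethylated. Sites with zero coverage in a sample are omitted from
#' that sample's file.
#'
#' @param table a `cpg_counts`.
#' @param dir output directory (created if needed).
#' @return invisibly, a sample sheet data.frame (sample_id, group, file).
#' @export
write_bismark <- function(table, dir) {
  stopifnot(inherits(table, "cpg_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(ncol(table$meth))
  for (j in seq_len(ncol(table$meth))) {
    keep <- table$total[, j] > 0
    m <- table$meth[keep, j]; n <- table$total[keep, j]
    df <- data.frame(chrom = table$sites$chrom[keep],
                     start = table$sites$pos[keep] + 1,
                     end = table$sites$pos[keep] + 1,
                     pct = round(100 * m / n, 6),
                     count_m = m, count_u = n - m)
    files[j] <- file.path(dir, paste0(table$sample_ids[j], ".cov"))
    write.table(df, files[j], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  sheet <- data.frame(sample_id = table$sample_ids,
                      group = as.character(table$groups), file = files)
  write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sheet)
}

#' Read Bismark-style coverage files into a count table
#'
#' Takes a sample sheet (columns sample_id, group, file). Sites form the
#' union over samples; a site unobserved in a sample gets total 0 there
#' (remove with [filter_coverage()]). Coordinates are converted from the
#' 1-based file format to the 0-based internal convention; strand is
#' recorded as `"+"` (coverage files are strand-collapsed).
#'
#' @param sheet data.frame or path to a TSV sample sheet.
#' @return a `cpg_counts`.
#' @export
read_bismark <- function(sheet) {
  if (is.character(sheet))
    sheet <- read.table(sheet, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group", "file") %in% names(sheet)))
  per <- lapply(sheet$file, function(f) {
    d <- read.table(f, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "pct", "count_m", "count_u"))
    d$pos <- d$start - 1
    d
  })
  key <- unique(do.call(rbind, lapply(per, function(d) d[c("chrom", "pos")])))
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  kid <- paste(key$chrom, key$pos)
  meth <- total <- matrix(0L, nrow(key), nrow(sheet))
  for (j in seq_along(per)) {
    i <- match(paste(per[[j]]$chrom, per[[j]]$pos), kid)
    meth[i, j] <- per[[j]]$count_m
    total[i, j] <- per[[j]]$count_m + per[[j]]$count_u
  }
  cpg_count_table(data.frame(chrom = key$chrom, pos = key$pos, strand = "+"),
                  meth, total, sheet$group, sheet$sample_id)
}

#' Write / read a gene x sample expression table as TSV
#'
#' The TSV has a `gene_id` column followed by one column per sample; the
#' sample sheet (sample_id, group) is written alongside.
#'
#' @param table an `expr_counts`.
#' @param file output TSV path.
#' @return invisibly, `file`.
#' @export
write_expression_tsv <- function(table, file) {
  stopifnot(inherits(table, "expr_counts"))
  df <- data.frame(gene_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = table$sample_ids,
                      group = as.character(table$groups))
  write.table(sheet, paste0(file, ".samples"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_expression_tsv
#' @param sheet data.frame (sample_id, group) or path; default
#'   `paste0(file, ".samples")`.
#' @export
read_expression_tsv <- function(file, sheet = paste0(file, ".samples")) {
  if (is.character(sheet))
    sheet <- read.table(sheet, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, sheet$sample_id, drop = FALSE])
  rownames(counts) <- df$gene_id
  expression_count_table(counts, sheet$group, sheet$sample_id)
}

#' Write an annotation as BED6 (TSS as single-bp features) and minimal GTF
#'
#' @param genome a `genome_model`.
#' @param bed,gtf output paths (either may be NULL to skip).
#' @return invisibly NULL.
#' @export
write_annotation <- function(genome, bed = NULL, gtf = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  g <- genome$genes
  if (!is.null(bed)) {
    df <- data.frame(g$chrom, g$tss, g$tss + 1, g$gene_id, 0, g$strand)
    write.table(df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(gtf)) {
    attrs <- sprintf('gene_id "%s";', g$gene_id)
    df <- data.frame(g$chrom, "methlink", "gene", g$tss + 1, g$tss + 1,
                     ".", g$strand, ".", attrs)
    write.table(df, gtf, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

#' Read a BED6 annotation of TSS positions into a genome model
#'
#' Chromosome lengths are taken from `chrom_lengths` if given, otherwise set
#' to the maximum feature end per chromosome (sufficient for window logic on
#' the low side only; supply real lengths for correct right clipping).
#'
#' @param bed path to a BED6 file (single-bp TSS features, name = gene id).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return a `genome_model`.
#' @export
read_annotation_bed <- function(bed, chrom_lengths = NULL) {
  d <- read.table(bed, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "name", "score", "strand"))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(d$end, d$chrom, max)
  }
  chroms <- data.frame(name = names(chrom_lengths),
                       length = as.numeric(chrom_lengths))
  genome_model(chroms, data.frame(gene_id = d$name, chrom = d$chrom,
                                  tss = d$start, strand = d$strand))
}

#' Write / read a boundary polygon as two-column CSV
#'
#' @param polygon a [boundary_polygon()].
#' @param file CSV path.
#' @return invisibly `file`; the reader returns a `boundary_polygon`.
#' @export
write_polygon_csv <- function(polygon, file) {
  write.table(data.frame(x = polygon$x, y = polygon$y), file, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_polygon_csv
#' @param spacing physical units per coordinate unit.
#' @export
read_polygon_csv <- function(file, spacing = 1) {
  d <- read.table(file, header = TRUE, sep = ",")
  boundary_polygon(d$x, d$y, spacing = spacing)
}

#' Write a complete synthetic study to disk
#'
#' Emits every input format the pipeline reads: Bismark coverage files plus
#' sample sheet, expression TSV, BED6 + GTF annotation, per-slice polygon
#' CSVs, metabolite/nucleotide panels and the ground-truth tables.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param dir output directory.
#' @return invisibly `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bismark(study$meth$table, file.path(dir, "methylation"))
  write_expression_tsv(study$expr$table, file.path(dir, "expression.tsv"))
  write_annotation(study$genome, bed = file.path(dir, "annotation.bed"),
                   gtf = file.path(dir, "annotation.gtf"))
  pd <- file.path(dir, "boundaries")
  dir.create(pd, showWarnings = FALSE)
  for (grp in names(study$boundaries))
    for (p in study$boundaries[[grp]])
      write_polygon_csv(p, file.path(pd, paste0(attr(p, "id"), ".csv")))
  mt <- data.frame(metabolite = rownames(study$panels$metabolites),
                   study$panels$metabolites, check.names = FALSE)
  write.table(mt, file.path(dir, "metabolites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$panels$nucleotides, file.path(dir, "nucleotides.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$meth$truth, file.path(dir, "truth_methylation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$expr$truth, file.path(dir, "truth_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
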