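#' Genome model: chromosome lengths and gene TSS records
#'
#' Minimal annotation container anchoring all interval logic: chromosome
#' lengths plus one record per gene giving its transcriptional start site
#' (TSS, 0-based) and strand.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (0-based bp),
#'   `strand` (`"+"` or `"-"`). May have zero rows.
#' @return An object of class `genome_model` (a list with elements
#'   `chromosomes` and `genes`, the latter sorted by (chrom, tss)).
#' @export
genome_model <- function(chromosomes, genes) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)),
            is.data.frame(genes), all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
  if (nrow(genes)) {
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    len <- chromosomes$length[match(genes$chrom, chromosomes$name)]
    if (anyNA(len)) stop("gene on unknown chromosome")
    if (any(genes$tss < 0 | genes$tss >= len)) stop("TSS outside chromosome bounds")
    genes <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(chromosomes = chromosomes, genes = genes), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosome(s),", nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Per-CpG methylation count table
#'
#' The methylome's raw observable: for every CpG site, per-sample methylated
#' and total read counts, with a sample-to-group map.
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `strand`.
#' @param meth,total integer matrices, sites x samples, `0 <= meth <= total`.
#' @param groups factor or character of length `ncol(meth)`; two levels,
#'   the first level is the reference (e.g. WT).
#' @param sample_ids optional character vector of sample names.
#' @return An object of class `cpg_counts`.
#' @export
cpg_count_table <- function(sites, meth, total, groups,
                            sample_ids = colnames(meth)) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  stopifnot(is.data.frame(sites), all(c("chrom", "pos", "strand") %in% names(sites)),
            nrow(sites) == nrow(meth), identical(dim(meth), dim(total)),
            length(groups) == ncol(meth))
  if (any(meth < 0) || any(meth > total)) stop("need 0 <= methylated <= total")
  if (!all(sites$strand %in% c("+", "-", "*"))) stop("malformed strand values")
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]; rownames(sites) <- NULL
  meth <- meth[o, , drop = FALSE]; total <- total[o, , drop = FALSE]
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(meth)))
  dimnames(meth) <- dimnames(total) <- list(NULL, sample_ids)
  structure(list(sites = sites, meth = meth, total = total,
                 groups = groups, sample_ids = sample_ids),
            class = "cpg_counts")
}

#' @export
print.cpg_counts <- function(x, ...) {
  cat("cpg_counts:", nrow(x$sites), "sites x", ncol(x$meth), "samples (",
      paste(levels(x$groups), tabulate(x$groups), sep = ":", collapse = ", "), ")\n")
  invisible(x)
}

#' @export
dim.cpg_counts <- function(x) dim(x$meth)

#' Gene x sample expression count table
#'
#' @param counts nonnegative integer matrix, genes x samples, with rownames
#'   as gene ids.
#' @param groups two-level factor/character per sample (first level = reference).
#' @param sample_ids optional sample names.
#' @return An object of class `expr_counts` with library sizes (column sums).
#' @export
expression_count_table <- function(counts, groups, sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (any(counts < 0) || any(counts != round(counts))) stop("counts must be nonnegative integers")
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (length(groups) != ncol(counts)) stop("groups/sample mismatch")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(counts)))
  colnames(counts) <- sample_ids
  structure(list(counts = counts, groups = groups, sample_ids = sample_ids,
                 lib_sizes = colSums(counts)),
            class = "expr_counts")
}

#' @export
print.expr_counts <- function(x, ...) {
  cat("expr_counts:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' @export
dim.expr_counts <- function(x) dim(x$counts)

#' Closed boundary polygon in physical units
#'
#' Ordered vertex list of a traced tissue boundary; closure is implicit
#' (first vertex is not repeated).
#'
#' @param x,y numeric vertex coordinates (same length, >= 3).
#' @param spacing physical units per coordinate unit (e.g. micrometres per
#'   pixel); stored as an attribute and applied multiplicatively.
#' @param id optional source identifier (slice/animal).
#' @return An object of class `boundary_polygon` (a data.frame of vertices).
#' @export
boundary_polygon <- function(x, y, spacing = 1, id = NA_character_) {
  stopifnot(length(x) == length(y), length(x) >= 3, spacing > 0)
  if (isTRUE(all.equal(c(x[1], y[1]), c(x[length(x)], y[length(y)])))) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (length(x) < 3) stop("polygon needs at least 3 distinct vertices")
  structure(data.frame(x = x * spacing, y = y * spacing),
            spacing = spacing, id = id,
            class = c("boundary_polygon", "data.frame"))
}
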