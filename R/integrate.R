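#' TSS windows
#'
#' Symmetric regulatory windows `[tss - half_width, tss + half_width)`
#' (0-based half-open), clipped at chromosome bounds, for every gene.
#'
#' @param genome a `genome_model`.
#' @param half_width window half-width in bp (default 2000).
#' @return data.frame: gene_id, chrom, start, end, tss, strand.
#' @export
derive_tss_windows <- function(genome, half_width = 2000) {
  stopifnot(inherits(genome, "genome_model"), half_width > 0)
  g <- genome$genes
  len <- genome$chromosomes$length[match(g$chrom, genome$chromosomes$name)]
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = pmax(g$tss - half_width, 0),
             end = pmin(g$tss + half_width, len),
             tss = g$tss, strand = g$strand)
}

#' Link DMCs to genes by TSS-window containment
#'
#' Every (site, window) containment is reported; a site inside two
#' overlapping windows yields two links. Windows are half-open, so a site at
#' `end` is not linked. Distance to the TSS is signed on the gene strand
#' (negative = upstream).
#'
#' @param dmcs data.frame of called DMCs ([call_dmcs()]): needs chrom, pos,
#'   and is carried through (q, mean_ref, mean_alt, meth_diff, direction).
#' @param windows data.frame from [derive_tss_windows()].
#' @return data.frame of links: gene_id, chrom, pos, distance, plus the
#'   carried DMC columns.
#' @export
link_dmcs_to_genes <- function(dmcs, windows) {
  stopifnot(is.data.frame(dmcs), is.data.frame(windows))
  empty <- data.frame(gene_id = character(), chrom = character(),
                      pos = numeric(), distance = numeric())
  if (!nrow(dmcs) || !nrow(windows)) return(empty)
  out <- list()
  for (ch in intersect(unique(dmcs$chrom), unique(windows$chrom))) {
    d <- dmcs[dmcs$chrom == ch, , drop = FALSE]
    w <- windows[windows$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(IRanges::IRanges(d$pos + 1, d$pos + 1),
                                  IRanges::IRanges(w$start + 1, w$end))
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    carried <- d[qi, setdiff(names(d), c("chrom", "pos", "strand")), drop = FALSE]
    link <- data.frame(gene_id = w$gene_id[si], chrom = ch, pos = d$pos[qi],
                       distance = (d$pos[qi] - w$tss[si]) *
                         ifelse(w$strand[si] == "-", -1, 1))
    out[[length(out) + 1]] <- cbind(link, carried)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap of DEGs with DMC-linked genes
#'
#' @param deg_genes character vector of DEG gene ids.
#' @param linked data.frame from [link_dmcs_to_genes()].
#' @return list with `overlap` (sorted gene ids), `n_deg`, `n_linked_genes`,
#'   `n_overlap` (the Venn margins and intersection).
#' @export
overlap_deg_dmc <- function(deg_genes, linked) {
  linked_genes <- unique(linked$gene_id)
  overlap <- sort(intersect(unique(deg_genes), linked_genes))
  list(overlap = overlap, n_deg = length(unique(deg_genes)),
       n_linked_genes = length(linked_genes), n_overlap = length(overlap))
}

# per-gene per-group mean CPM (TMM-effective library sizes)
group_mean_cpm <- function(table, norm_factors = tmm_factors(table)) {
  cpm <- sweep(table$counts, 2, table$lib_sizes * norm_factors, `/`) * 1e6
  ref <- table$groups == levels(table$groups)[1]
  data.frame(gene_id = rownames(cpm),
             cpm_ref = rowMeans(cpm[, ref, drop = FALSE]),
             cpm_alt = rowMeans(cpm[, !ref, drop = FALSE]))
}

#' Methylation-expression anticorrelation filter
#'
#' For each overlap gene, the lower-expression group is the group with the
#' smaller mean CPM for that gene. The gene passes if at least one linked
#' DMC is more highly methylated in the lower-expression group by at least
#' `threshold` -- by default an absolute difference of 0.25 on the
#' methylation-proportion scale (inclusive); `relative = TRUE` instead
#' requires a (1 + threshold)-fold ratio.
#'
#' @param overlap character vector of overlap gene ids.
#' @param linked data.frame from [link_dmcs_to_genes()] (needs `mean_ref`,
#'   `mean_alt`).
#' @param expr an `expr_counts` aligned with the DMC groups (same level
#'   order: level 1 = reference group).
#' @param threshold methylation difference required (default 0.25).
#' @param relative use the ratio reading instead of the absolute difference.
#' @return data.frame per overlap gene: gene_id, lower_group, best_diff
#'   (methylation in lower-expression group minus higher, best linked DMC),
#'   pass. Genes with no linked DMC are dropped with a note attribute.
#' @export
anticorrelation_filter <- function(overlap, linked, expr, threshold = 0.25,
                                   relative = FALSE) {
  stopifnot(inherits(expr, "expr_counts"))
  cpm <- group_mean_cpm(expr)
  no_dmc <- setdiff(overlap, unique(linked$gene_id))
  genes <- setdiff(overlap, no_dmc)
  rows <- lapply(genes, function(g) {
    l <- linked[linked$gene_id == g, , drop = FALSE]
    e <- cpm[cpm$gene_id == g, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    lower_ref <- e$cpm_ref[1] <= e$cpm_alt[1]
    lo <- if (lower_ref) l$mean_ref else l$mean_alt
    hi <- if (lower_ref) l$mean_alt else l$mean_ref
    diff <- lo - hi
    crit <- if (relative) lo / pmax(hi, 1e-12) - 1 else diff
    data.frame(gene_id = g,
               lower_group = ifelse(lower_ref, levels(expr$groups)[1],
                                    levels(expr$groups)[2]),
               best_diff = max(diff),
               pass = any(crit >= threshold))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), lower_group = character(),
                      best_diff = numeric(), pass = logical())
  rownames(out) <- NULL
  attr(out, "no_linked_dmc") <- no_dmc
  out
}

#' Direction class of an overlap gene
#'
#' Cross-classifies the expression change (second group vs first) with the
#' methylation change of the strongest linked DMC into `down_hyper`,
#' `up_hypo`, `down_hypo`, `up_hyper`. A zero methylation difference is
#' tie-broken to hypo with a warning.
#'
#' @param log2fc gene log2 fold change (alt vs ref).
#' @param meth_diff methylation difference (alt - ref) of the strongest
#'   linked DMC.
#' @return character class (vectorized).
#' @export
classify_direction <- function(log2fc, meth_diff) {
  if (any(meth_diff == 0)) warning("zero methylation difference tie-broken to hypo")
  paste0(ifelse(log2fc < 0, "down", "up"), "_",
         ifelse(meth_diff > 0, "hyper", "hypo"))
}

# k-means++ initial centers
kmpp_init <- function(z, k) {
  n <- nrow(z)
  centers <- matrix(NA_real_, k, ncol(z))
  idx <- sample.int(n, 1)
  centers[1, ] <- z[idx, ]
  if (k > 1) {
    d2 <- rowSums((z - matrix(centers[1, ], n, ncol(z), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- z[idx, ]
      d2 <- pmin(d2, rowSums((z - matrix(centers[j, ], n, ncol(z), byrow = TRUE))^2))
    }
  }
  centers
}

#' K-means clustering of z-scored expression
#'
#' Genes are z-scored across samples (constant genes set to 0), then
#' clustered with Lloyd's algorithm from k-means++ starts; the best of
#' `restarts` runs (smallest total within-cluster sum of squares) is
#' returned. Deterministic given `seed`.
#'
#' @param mat numeric gene x sample matrix.
#' @param k number of clusters (default 2).
#' @param seed integer seed.
#' @param restarts number of restarts (default 10).
#' @return list with `labels` (named by gene), `inertia`, `centers`.
#' @export
zscore_kmeans <- function(mat, k = 2, seed = 1, restarts = 10) {
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("k exceeds number of genes")
  sds <- apply(mat, 1, sd)
  z <- (mat - rowMeans(mat)) / ifelse(sds > 0, sds, 1)
  if (k == 1) {
    ctr <- colMeans(z)
    return(list(labels = setNames(rep(1L, nrow(z)), rownames(z)),
                inertia = sum(sweep(z, 2, ctr)^2),
                centers = matrix(ctr, 1)))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- tryCatch(
      suppressWarnings(kmeans(z, kmpp_init(z, k), iter.max = 100,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed for all restarts")
  list(labels = setNames(best$cluster, rownames(z)),
       inertia = best$tot.withinss, centers = best$centers)
}

#' Assemble the methylation-expression integration report
#'
#' Runs the full linkage stage downstream of the DMC and DEG fits: TSS
#' windows, DMC linkage, DEG/DMC overlap (Venn counts), the
#' anticorrelation filter, direction classification of the survivors, and
#' k-means clustering of their z-scored log-CPM. The report is a pure
#' function of its inputs and the seed.
#'
#' @param dmc_fits data.frame from [dmc_fit()].
#' @param deg_fits data.frame from [deg_test()].
#' @param genome a `genome_model`.
#' @param expr the `expr_counts` used for `deg_fits`.
#' @param fdr q threshold for both DMCs and DEGs (default 0.05).
#' @param tss_half_width TSS window half-width in bp (default 2000).
#' @param meth_threshold anticorrelation filter threshold (default 0.25).
#' @param relative relative (ratio) reading of the filter (default FALSE).
#' @param k,seed k-means settings.
#' @return list of class `integration_report`: counts (n_dmc,
#'   n_tss_proximal_dmc, n_deg, n_overlap, n_survivors), tables (linked,
#'   overlap genes, survivors with direction class), class tallies, cluster
#'   labels.
#' @export
integration_report <- function(dmc_fits, deg_fits, genome, expr,
                               fdr = 0.05, tss_half_width = 2000,
                               meth_threshold = 0.25, relative = FALSE,
                               k = 2, seed = 1) {
  stopifnot(inherits(expr, "expr_counts"))
  dmcs <- call_dmcs(dmc_fits, fdr)
  degs <- call_degs(deg_fits, fdr)
  if (nrow(degs) && !any(degs$gene_id %in% genome$genes$gene_id))
    stop("gene namespace mismatch between DEG table and annotation")
  windows <- derive_tss_windows(genome, tss_half_width)
  linked <- link_dmcs_to_genes(dmcs, windows)
  ov <- overlap_deg_dmc(degs$gene_id, linked)
  filt <- anticorrelation_filter(ov$overlap, linked, expr,
                                 threshold = meth_threshold, relative = relative)
  survivors <- filt[filt$pass, , drop = FALSE]
  if (nrow(survivors)) {
    lfc <- degs$log2fc[match(survivors$gene_id, degs$gene_id)]
    md <- vapply(survivors$gene_id, function(g) {
      l <- linked[linked$gene_id == g, , drop = FALSE]
      l$meth_diff[which.max(abs(l$meth_diff))]
    }, numeric(1))
    survivors$log2fc <- lfc
    survivors$meth_diff <- md
    survivors$class <- suppressWarnings(classify_direction(lfc, md))
  } else {
    survivors$log2fc <- survivors$meth_diff <- numeric(0)
    survivors$class <- character(0)
  }
  tallies <- table(factor(survivors$class,
                          levels = c("down_hyper", "up_hypo", "down_hypo", "up_hyper")))
  clusters <- NULL
  if (nrow(survivors) >= k && k >= 1) {
    cpm <- sweep(expr$counts, 2, expr$lib_sizes, `/`) * 1e6
    sub <- log2(cpm[survivors$gene_id, , drop = FALSE] + 0.25)
    clusters <- zscore_kmeans(sub, k = k, seed = seed)$labels
  }
  counts <- c(n_dmc = nrow(dmcs),
              n_tss_proximal_dmc = length(unique(paste(linked$chrom, linked$pos))),
              n_deg = nrow(degs), n_overlap = ov$n_overlap,
              n_survivors = nrow(survivors))
  stopifnot(counts["n_survivors"] <= counts["n_overlap"])
  structure(list(counts = counts, venn = ov[c("n_deg", "n_linked_genes", "n_overlap")],
                 linked = linked, overlap_genes = ov$overlap,
                 filter = filt, survivors = survivors,
                 class_tallies = tallies, clusters = clusters,
                 parameters = list(fdr = fdr, tss_half_width = tss_half_width,
                                   meth_threshold = meth_threshold,
                                   relative = relative, k = k, seed = seed)),
            class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  cat("integration_report\n")
  cat(sprintf("  DMCs (q <= %.3g):            %d\n", x$parameters$fdr, x$counts["n_dmc"]))
  cat(sprintf("  TSS-proximal DMCs (+/-%d bp): %d\n",
              x$parameters$tss_half_width, x$counts["n_tss_proximal_dmc"]))
  cat(sprintf("  DEGs:                        %d\n", x$counts["n_deg"]))
  cat(sprintf("  DEG/DMC overlap genes:       %d\n", x$counts["n_overlap"]))
  cat(sprintf("  filter survivors (>= %.2f):  %d\n",
              x$parameters$meth_threshold, x$counts["n_survivors"]))
  if (sum(x$class_tallies) > 0) {
    cat("  direction classes: ",
        paste(names(x$class_tallies), as.integer(x$class_tallies),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Deterministic text serialization of an integration report
#'
#' Fixed-format rendering used for byte-identity checks across runs and for
#' writing plain-text reports.
#'
#' @param x an `integration_report`.
#' @param ... unused.
#' @return character vector of lines.
#' @export
format.integration_report <- function(x, ...) {
  fm <- function(v) formatC(v, digits = 10, format = "g")
  lines <- c("integration_report",
             paste0("counts: ", paste(names(x$counts), x$counts, sep = "=", collapse = " ")),
             paste0("venn: ", paste(names(x$venn), unlist(x$venn), sep = "=", collapse = " ")),
             paste0("classes: ", paste(names(x$class_tallies),
                                       as.integer(x$class_tallies), sep = "=", collapse = " ")))
  if (nrow(x$survivors)) {
    lines <- c(lines, "survivors:",
               paste(x$survivors$gene_id, x$survivors$class,
                     fm(x$survivors$log2fc), fm(x$survivors$meth_diff), sep = "\t"))
  }
  if (!is.null(x$clusters)) {
    lines <- c(lines, "clusters:",
               paste(names(x$clusters), x$clusters, sep = "\t"))
  }
  lines
}
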