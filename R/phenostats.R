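#' Adenylate energy charge
#'
#' ([ATP] + 0.5 [ADP]) / ([ATP] + [ADP] + [AMP]): the fraction of the
#' adenine nucleotide pool carrying high-energy phosphoanhydride bonds,
#' on [0, 1]. Scale-invariant in the three concentrations.
#'
#' @param atp,adp,amp concentrations in a common unit (vectors recycled).
#' @return value(s) in `[0, 1]`.
#' @export
energy_charge <- function(atp, adp, amp) {
  if (any(atp < 0 | adp < 0 | amp < 0)) stop("concentrations must be >= 0")
  tot <- atp + adp + amp
  if (any(tot == 0)) stop("all-zero nucleotide panel")
  (atp + 0.5 * adp) / tot
}

#' Total adenine nucleotide pool
#'
#' @inheritParams energy_charge
#' @return ATP + ADP + AMP.
#' @export
total_adenine <- function(atp, adp, amp) atp + adp + amp

#' Median-scale a metabolite panel
#'
#' Divides each metabolite (row) by its cross-sample median so every scaled
#' metabolite has median 1 -- the usual display convention for scaled
#' intensities. Zero-median metabolites are left unscaled and flagged.
#'
#' @param panel numeric matrix, metabolites x samples, positive values.
#' @return scaled matrix; attribute `flagged` lists zero-median metabolites.
#' @export
median_scale <- function(panel) {
  panel <- as.matrix(panel)
  med <- apply(panel, 1, median)
  flagged <- rownames(panel)[med == 0]
  med[med == 0] <- 1
  out <- panel / med
  attr(out, "flagged") <- flagged
  out
}

#' Methylation-potential metabolite ratios
#'
#' Per-sample ratios indexing the balance between DNA methylation and
#' demethylation substrates: 2-HG/a-KG, succinate/a-KG and fumarate/a-KG
#' (competitive inhibitors of a-ketoglutarate-dependent demethylases over
#' their co-substrate) and SAM/SAH (methyl-donor potential). Computed on raw
#' abundances, never on median-scaled values.
#'
#' @param panel numeric matrix, metabolites x samples; rownames must include
#'   `"2HG"`, `"aKG"`, `"succinate"`, `"fumarate"`, `"SAM"`, `"SAH"`.
#' @return matrix 4 ratios x samples with rownames
#'   `"2HG/aKG"`, `"succinate/aKG"`, `"fumarate/aKG"`, `"SAM/SAH"`.
#' @export
methylation_ratio_panel <- function(panel) {
  panel <- as.matrix(panel)
  need <- c("2HG", "aKG", "succinate", "fumarate", "SAM", "SAH")
  missing <- setdiff(need, rownames(panel))
  if (length(missing))
    stop("missing metabolite(s): ", paste(missing, collapse = ", "))
  if (any(panel[c("aKG", "SAH"), ] == 0)) stop("zero denominator metabolite")
  out <- rbind(`2HG/aKG` = panel["2HG", ] / panel["aKG", ],
               `succinate/aKG` = panel["succinate", ] / panel["aKG", ],
               `fumarate/aKG` = panel["fumarate", ] / panel["aKG", ],
               `SAM/SAH` = panel["SAM", ] / panel["SAH", ])
  colnames(out) <- colnames(panel)
  out
}

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-sided p
#' value. Implemented in closed form so the zero-variance contract is
#' explicit: if both groups have zero variance, p = 1 when the means are
#' equal and 0 (with a warning) otherwise.
#'
#' @param a,b numeric vectors, each with >= 2 values.
#' @return list with `t`, `df`, `p.value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  va <- var(a) / length(a); vb <- var(b) / length(b)
  if (va + vb == 0) {
    equal <- mean(a) == mean(b)
    if (!equal) warning("zero variance in both groups with unequal means")
    return(list(t = if (equal) 0 else Inf, df = NA_real_,
                p.value = if (equal) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Group comparison of the methylation-potential ratios
#'
#' Computes the four ratios per sample, then a Welch t test per ratio
#' between the two groups; also reports the ratios normalized to the
#' reference-group mean.
#'
#' @param panel metabolite x sample matrix (see [methylation_ratio_panel()]).
#' @param groups two-level factor per sample (level 1 = reference).
#' @return list with `ratios` (raw), `ratios_ref_normalized` and `tests`
#'   (data.frame ratio, mean_ref, mean_alt, fold, t, df, p).
#' @export
ratio_group_tests <- function(panel, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  r <- methylation_ratio_panel(panel)
  ref <- groups == levels(groups)[1]
  tests <- do.call(rbind, lapply(rownames(r), function(nm) {
    w <- welch_t(r[nm, !ref], r[nm, ref])   # alt vs ref
    data.frame(ratio = nm, mean_ref = mean(r[nm, ref]),
               mean_alt = mean(r[nm, !ref]),
               fold = mean(r[nm, !ref]) / mean(r[nm, ref]),
               t = w$t, df = w$df, p = w$p.value)
  }))
  list(ratios = r,
       ratios_ref_normalized = r / rowMeans(r[, ref, drop = FALSE]),
       tests = tests)
}

#' Whole-organ count extrapolation from an aliquot
#'
#' @param counted cells counted in the aliquot.
#' @param aliquot_fraction fraction of the whole digest in the aliquot,
#'   in (0, 1].
#' @return whole-organ estimate, rounded to the nearest integer.
#' @export
extrapolate_count <- function(counted, aliquot_fraction) {
  if (any(aliquot_fraction <= 0 | aliquot_fraction > 1))
    stop("aliquot fraction must lie in (0, 1]")
  if (any(counted < 0)) stop("counted cells must be >= 0")
  round(counted / aliquot_fraction)
}

#' Nucleation distribution of a cardiomyocyte census
#'
#' Percentages of mono-, bi- and polynucleated cells (summing to 100) and
#' the implied total nuclei count: 1 per mononucleated + 2 per binucleated +
#' `poly_multiplicity` per polynucleated cell.
#'
#' @param mono,bi,poly cell counts (>= 0, positive total).
#' @param poly_multiplicity assumed nuclei per polynucleated cell
#'   (default 3).
#' @return list with `percent` (named, sums to 100) and `nuclei`.
#' @export
nucleation_distribution <- function(mono, bi, poly, poly_multiplicity = 3) {
  if (any(c(mono, bi, poly) < 0)) stop("counts must be >= 0")
  total <- mono + bi + poly
  if (total == 0) stop("zero total cell count")
  list(percent = c(mono = 100 * mono / total, bi = 100 * bi / total,
                   poly = 100 * poly / total),
       nuclei = mono + 2 * bi + poly_multiplicity * poly)
}
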