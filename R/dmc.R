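#' Collapse symmetric CpG dyads onto the plus strand
#'
#' A CpG on the minus strand at position i+1 reports the same dyad as the
#' plus-strand CpG at position i; their counts are summed onto the
#' plus-strand position. Minus-strand sites without a plus partner are
#' passed through unchanged.
#'
#' @param table a `cpg_counts`.
#' @return a `cpg_counts` with dyads merged.
#' @export
collapse_strands <- function(table) {
  stopifnot(inherits(table, "cpg_counts"))
  s <- table$sites
  if (!all(s$strand %in% c("+", "-"))) stop("malformed strand values")
  minus <- which(s$strand == "-")
  if (!length(minus))
    return(table)
  plus_idx <- which(s$strand == "+")
  partner <- plus_idx[match(paste(s$chrom[minus], s$pos[minus] - 1),
                            paste(s$chrom[plus_idx], s$pos[plus_idx]))]
  has <- !is.na(partner)
  meth <- table$meth; total <- table$total
  if (any(has)) {
    for (k in which(has)) {
      i <- minus[k]; j <- partner[k]
      meth[j, ] <- meth[j, ] + meth[i, ]
      total[j, ] <- total[j, ] + total[i, ]
    }
    drop <- minus[has]
    s <- s[-drop, , drop = FALSE]
    meth <- meth[-drop, , drop = FALSE]
    total <- total[-drop, , drop = FALSE]
  }
  cpg_count_table(s, meth, total, table$groups, table$sample_ids)
}

#' Filter CpG sites on per-sample coverage
#'
#' Retains sites where every sample has at least `min_total` reads.
#'
#' @param table a `cpg_counts`.
#' @param min_total minimum total count required in every sample (>= 1).
#' @return filtered `cpg_counts`; the number of removed sites is attached as
#'   attribute `n_removed`.
#' @export
filter_coverage <- function(table, min_total = 5) {
  stopifnot(inherits(table, "cpg_counts"), min_total >= 1)
  keep <- rowSums(table$total >= min_total) == ncol(table$total)
  out <- cpg_count_table(table$sites[keep, , drop = FALSE],
                         table$meth[keep, , drop = FALSE],
                         table$total[keep, , drop = FALSE],
                         table$groups, table$sample_ids)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Arcsine variance-stabilizing transform of a methylation proportion
#'
#' y = arcsin(2 p~ - 1) with the continuity-corrected proportion
#' p~ = (m + 1/2) / (n + 1). For a binomial proportion the delta method gives
#' Var(y) ~ 1/n independent of p, and under beta-binomial overdispersion
#' Var(y) ~ (1 + (n - 1) phi) / n -- the weights used by [fit_site_gls()].
#'
#' @param methylated,total count vectors (recycled); `total >= 1`.
#' @return values in `[-pi/2, pi/2]`.
#' @export
arcsine_transform <- function(methylated, total) {
  if (any(total < 1)) stop("total must be >= 1")
  if (any(methylated < 0 | methylated > total)) stop("need 0 <= methylated <= total")
  asin(2 * (methylated + 0.5) / (total + 1) - 1)
}

# per-site moment sums for the dispersion estimator.
# E[(p_ij - p_g)^2] = p(1-p)(1 + (n_ij - 1) phi)/n_ij; num/den estimates phi.
dispersion_moments <- function(meth, total, groups) {
  num <- 0; den <- 0
  for (g in levels(groups)) {
    j <- groups == g
    m <- sum(j)
    p <- meth[, j, drop = FALSE] / total[, j, drop = FALSE]
    pbar <- rowMeans(p)
    ss <- rowSums((p - pbar)^2) * m / (m - 1)
    v <- pbar * (1 - pbar)
    num <- num + ss - v * rowSums(1 / total[, j, drop = FALSE])
    den <- den + v * rowSums((total[, j, drop = FALSE] - 1) / total[, j, drop = FALSE])
  }
  list(num = num, den = den)
}

# vectorized per-site method-of-moments dispersion
site_dispersion_mom <- function(meth, total, groups) {
  mo <- dispersion_moments(meth, total, groups)
  phi <- ifelse(mo$den > 0, mo$num / mo$den, 0)
  pmin(pmax(phi, 0), 0.99)
}

# genome-wide dispersion: ratio of pooled moment sums (near-unbiased, unlike
# the median of floored per-site estimates)
pooled_dispersion <- function(meth, total, groups, use = NULL) {
  mo <- dispersion_moments(meth, total, groups)
  if (!is.null(use)) { mo$num <- mo$num[use]; mo$den <- mo$den[use] }
  d <- sum(mo$den)
  if (d <= 0) return(0)
  min(max(sum(mo$num) / d, 0), 0.99)
}

#' Per-site beta-binomial dispersion (method of moments)
#'
#' Pooled across the two groups on the proportion scale, floored at 0 and
#' capped at 0.99. Degenerate sites (identical proportions everywhere)
#' return 0. Shrinkage toward the genome-wide median is applied by
#' [dmc_fit()], not here.
#'
#' @param methylated,total per-sample count vectors for one site.
#' @param groups two-level factor.
#' @return scalar dispersion estimate phi-hat.
#' @export
estimate_site_dispersion <- function(methylated, total, groups) {
  groups <- factor(groups)
  if (any(tabulate(groups) < 2)) stop("need >= 2 samples per group")
  site_dispersion_mom(matrix(methylated, 1), matrix(total, 1), groups)[1]
}

#' Generalized least-squares fit of one CpG site on the arcsine scale
#'
#' Design: intercept + group indicator. Observation variances are the
#' delta-method values (1 + (n_ij - 1) phi) / n_ij, so the GLS group
#' coefficient is the difference of precision-weighted group means of the
#' transformed values, its standard error comes from the known weights, and
#' the Wald z statistic is referred to a standard normal.
#'
#' @param y arcsine-transformed values per sample.
#' @param totals per-sample total counts (define the weights).
#' @param groups two-level factor; the effect is level 2 minus level 1.
#' @param phi dispersion used in the weights.
#' @return list with `beta`, `se`, `z`, `p`, `status`.
#' @export
fit_site_gls <- function(y, totals, groups, phi) {
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(tabulate(groups) == 0))
    stop("singular design: need both groups present")
  w <- totals / (1 + (totals - 1) * phi)
  if (all(w == 0)) return(list(beta = NA_real_, se = NA_real_, z = NA_real_,
                               p = NA_real_, status = "degenerate"))
  g2 <- groups == levels(groups)[2]
  sw1 <- sum(w[!g2]); sw2 <- sum(w[g2])
  beta <- sum(w[g2] * y[g2]) / sw2 - sum(w[!g2] * y[!g2]) / sw1
  se <- sqrt(1 / sw1 + 1 / sw2)
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)), status = "ok")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (wraps
#' [stats::p.adjust()] after validating the inputs).
#'
#' @param p p values in `[0, 1]`.
#' @return q values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fit the beta-binomial arcsine-GLS model at every site
#'
#' The full differential-methylation caller: optional strand collapsing,
#' per-sample coverage filtering, flagging of degenerate sites (methylation
#' identically 0 or 1 in every sample of both groups), moment-based
#' dispersion estimation (genome-wide pooled when groups have fewer than 6
#' samples, per-site otherwise), GLS/Wald testing on the arcsine scale, and
#' BH adjustment over the testable sites.
#'
#' @param table a `cpg_counts`.
#' @param min_coverage per-sample minimum total count (default 5).
#' @param collapse merge symmetric CpG dyads first (default TRUE).
#' @return data.frame with one row per retained site: chrom, pos, strand,
#'   mean_ref, mean_alt (mean per-sample methylation proportion per group),
#'   meth_diff (alt - ref), phi, beta, se, z, p, q, status.
#' @export
dmc_fit <- function(table, min_coverage = 5, collapse = TRUE) {
  stopifnot(inherits(table, "cpg_counts"))
  if (any(tabulate(table$groups) < 2)) stop("need >= 2 samples per group")
  if (collapse) table <- collapse_strands(table)
  table <- filter_coverage(table, min_coverage)
  meth <- table$meth; total <- table$total; groups <- table$groups
  n_sites <- nrow(meth)
  res <- data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
                    strand = table$sites$strand)
  if (n_sites == 0) {
    res$mean_ref <- res$mean_alt <- res$meth_diff <- res$phi <- numeric(0)
    res$beta <- res$se <- res$z <- res$p <- res$q <- numeric(0)
    res$status <- character(0)
    return(res)
  }
  p_mat <- meth / total
  ref <- groups == levels(groups)[1]
  res$mean_ref <- rowMeans(p_mat[, ref, drop = FALSE])
  res$mean_alt <- rowMeans(p_mat[, !ref, drop = FALSE])
  res$meth_diff <- res$mean_alt - res$mean_ref

  degenerate <- rowSums(meth == 0) == ncol(meth) | rowSums(meth == total) == ncol(meth)

  # per-site MoM dispersion is essentially unidentifiable at n = 4 per group:
  # below 6 samples per group the genome-wide pooled estimate is used for all
  # sites; with larger groups the per-site estimate stands on its own.
  phi <- if (min(tabulate(groups)) < 6) {
    rep(pooled_dispersion(meth, total, groups, use = !degenerate), n_sites)
  } else {
    site_dispersion_mom(meth, total, groups)
  }
  res$phi <- phi

  y <- asin(2 * (meth + 0.5) / (total + 1) - 1)
  w <- total / (1 + (total - 1) * phi)
  g2 <- !ref
  sw1 <- rowSums(w[, ref, drop = FALSE]); sw2 <- rowSums(w[, g2, drop = FALSE])
  beta <- rowSums((w * y)[, g2, drop = FALSE]) / sw2 -
    rowSums((w * y)[, ref, drop = FALSE]) / sw1
  se <- sqrt(1 / sw1 + 1 / sw2)
  z <- beta / se
  res$beta <- beta; res$se <- se; res$z <- z
  res$p <- 2 * pnorm(-abs(z))
  res$status <- ifelse(degenerate, "degenerate", "ok")
  res$p[degenerate] <- NA_real_
  res$z[degenerate] <- NA_real_
  res$q <- NA_real_
  ok <- res$status == "ok"
  res$q[ok] <- adjust_bh(res$p[ok])
  res
}

#' Call differentially methylated CpGs at an FDR threshold
#'
#' @param fits data.frame from [dmc_fit()].
#' @param q_threshold inclusive q-value cutoff (default 0.05).
#' @return data.frame of significant sites with a `direction` column
#'   (`"hyper"`/`"hypo"`, methylation in the second group relative to the
#'   first); attribute `q_threshold` records the cutoff.
#' @export
call_dmcs <- function(fits, q_threshold = 0.05) {
  stopifnot(is.data.frame(fits), "q" %in% names(fits))
  keep <- !is.na(fits$q) & fits$q <= q_threshold & fits$status == "ok"
  out <- fits[keep, , drop = FALSE]
  out$direction <- ifelse(out$meth_diff >= 0, "hyper", "hypo")
  rownames(out) <- NULL
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Genome-wide methylation shift test
#'
#' Two-sample Kolmogorov-Smirnov test comparing the distributions of
#' per-site group-mean methylation proportions between the two groups.
#'
#' @param table a `cpg_counts`.
#' @return list with `statistic` (D) and `p.value`.
#' @export
global_methylation_shift <- function(table) {
  stopifnot(inherits(table, "cpg_counts"))
  if (nrow(table$sites) < 2) stop("need at least 2 sites")
  p_mat <- table$meth / table$total
  ref <- table$groups == levels(table$groups)[1]
  m1 <- rowMeans(p_mat[, ref, drop = FALSE])
  m2 <- rowMeans(p_mat[, !ref, drop = FALSE])
  kt <- suppressWarnings(ks.test(m2, m1))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

# beta-binomial log-likelihood; rho ~ 0 falls back to binomial
bb_loglik <- function(m, n, p, rho) {
  if (rho < 1e-8) return(sum(stats::dbinom(m, n, p, log = TRUE)))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  sum(lchoose(n, m) + lbeta(m + a, n - m + b) - lbeta(a, b))
}

#' Reference beta-binomial likelihood-ratio test (numerical ML)
#'
#' Independent check of the Wald test: fits the beta-binomial on the
#' proportion scale by numerical maximum likelihood under the null (shared
#' mean) and the alternative (group-specific means, shared dispersion), and
#' refers twice the log-likelihood ratio to chi-square with 1 df. This path
#' shares no code with the arcsine-GLS fit.
#'
#' @param methylated,total per-sample counts for one site.
#' @param groups two-level factor.
#' @return list with `lr`, `p.value`, and the ML estimates.
#' @export
bb_lrt_pvalue <- function(methylated, total, groups) {
  groups <- factor(groups)
  g2 <- groups == levels(groups)[2]
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  p_all <- clamp(sum(methylated) / sum(total), 1e-4, 1 - 1e-4)
  p1 <- clamp(sum(methylated[!g2]) / sum(total[!g2]), 1e-4, 1 - 1e-4)
  p2 <- clamp(sum(methylated[g2]) / sum(total[g2]), 1e-4, 1 - 1e-4)
  lo <- c(1e-4, 1e-8); hi <- c(1 - 1e-4, 0.95)
  nll0 <- function(par) -bb_loglik(methylated, total, par[1], par[2])
  nll1 <- function(par) {
    -(bb_loglik(methylated[!g2], total[!g2], par[1], par[3]) +
        bb_loglik(methylated[g2], total[g2], par[2], par[3]))
  }
  best <- function(fn, starts, lo, hi) {
    fits <- lapply(starts, function(s)
      tryCatch(optim(s, fn, method = "L-BFGS-B", lower = lo, upper = hi),
               error = function(e) list(value = Inf)))
    fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  }
  f0 <- best(nll0, list(c(p_all, 0.01), c(p_all, 0.2)), lo, hi)
  f1 <- best(nll1, list(c(p1, p2, 0.01), c(p1, p2, 0.2)),
             c(lo[1], lo[1], lo[2]), c(hi[1], hi[1], hi[2]))
  lr <- max(0, 2 * (f0$value - f1$value))
  list(lr = lr, p.value = pchisq(lr, df = 1, lower.tail = FALSE),
       null = f0$par, alt = f1$par)
}
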