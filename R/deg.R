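#' TMM normalization factors
#'
#' Trimmed mean of M-values against a reference sample (the sample whose
#' upper-quartile count fraction is closest to the mean upper quartile).
#' Per sample, genes positive in both sample and reference are doubly
#' trimmed -- 30% on each tail of the log ratios M and 5% on each tail of
#' the average log abundance A -- and the factor is 2^mean(M) over the kept
#' genes, rescaled so the factors have geometric mean 1.
#'
#' @param table an `expr_counts` (or a counts matrix).
#' @return named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(table) {
  counts <- if (inherits(table, "expr_counts")) table$counts else as.matrix(table)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample")
  frac <- sweep(counts, 2, lib, `/`)
  uq <- apply(frac, 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    ok <- counts[, s] > 0 & counts[, ref] > 0
    if (!any(ok)) return(1)
    M <- log2(frac[ok, s] / frac[ok, ref])
    A <- 0.5 * log2(frac[ok, s] * frac[ok, ref])
    keepM <- M >= quantile(M, 0.3) & M <= quantile(M, 0.7)
    keepA <- A >= quantile(A, 0.05) & A <= quantile(A, 0.95)
    keep <- keepM & keepA
    if (!any(keep)) keep <- keepM
    if (!any(keep)) keep <- rep(TRUE, length(M))
    2^mean(M[keep])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Filter genes on counts-per-million
#'
#' Keeps genes with CPM >= `min_cpm` (raw library sizes) in at least
#' `min_samples` samples.
#'
#' @param table an `expr_counts`.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples meeting it; default half
#'   the samples (rounded up).
#' @return filtered `expr_counts`.
#' @export
cpm_filter <- function(table, min_cpm = 1,
                       min_samples = ceiling(ncol(table$counts) / 2)) {
  stopifnot(inherits(table, "expr_counts"))
  if (min_samples > ncol(table$counts)) stop("min_samples exceeds sample count")
  cpm <- sweep(table$counts, 2, table$lib_sizes, `/`) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  expression_count_table(table$counts[keep, , drop = FALSE],
                         table$groups, table$sample_ids)
}

# per-gene dispersion by the Pearson estimating equation: find phi such that
# sum (y - mu)^2 / (mu + phi mu^2) equals the residual df (n - 2 for the
# saturated two-group fit), which corrects the df lost to the fitted means.
pearson_gene_dispersion <- function(y, groups, scaled_lib) {
  mg <- tapply(y / scaled_lib, groups, mean)
  mu <- as.numeric(mg[groups]) * scaled_lib
  pos <- mu > 0
  if (!any(pos)) return(0)
  df <- length(y) - 2
  f <- function(phi) sum((y[pos] - mu[pos])^2 / (mu[pos] + phi * mu[pos]^2)) - df
  if (f(0) <= 0) return(0)
  if (f(20) > 0) return(20)
  stats::uniroot(f, c(0, 20), tol = 1e-8)$root
}

#' Per-gene NB dispersion with trend shrinkage
#'
#' Per-gene dispersion solves the df-corrected Pearson estimating equation
#' (Pearson chi-square equal to residual df under the saturated two-group
#' fit), then a locally weighted (lowess) mean-dispersion trend is fitted
#' and each gene is shrunk 70% toward the trend -- except in small designs
#' (per-gene residual df < 10), where the per-gene values are too noisy to
#' carry weight and the trend is used as is. With fewer than 20 genes the
#' trend is replaced by the global median.
#'
#' @param table an `expr_counts`.
#' @param norm_factors TMM factors (default computed by [tmm_factors()]).
#' @return data.frame with `gene_id`, `mean_norm` (mean normalized count),
#'   `raw` (per-gene Pearson estimate) and `dispersion` (shrunken, used for
#'   fitting).
#' @export
estimate_dispersion <- function(table, norm_factors = tmm_factors(table)) {
  stopifnot(inherits(table, "expr_counts"))
  counts <- table$counts; groups <- table$groups
  eff <- table$lib_sizes * norm_factors
  s <- eff / mean(eff)
  raw <- vapply(seq_len(nrow(counts)), function(i)
    pearson_gene_dispersion(counts[i, ], groups, s), numeric(1))
  mean_norm <- rowMeans(sweep(counts, 2, s, `/`))
  if (nrow(counts) >= 20) {
    o <- order(mean_norm)
    # iter = 0: the local mean is the unbiased target for the skewed
    # per-gene estimates; robustness iterations would chase their median
    lw <- lowess(log(mean_norm[o] + 1e-8), raw[o], f = 0.5, iter = 0)
    trend <- approx(lw$x, lw$y, xout = log(mean_norm + 1e-8), rule = 2)$y
    trend <- pmax(trend, 0)
  } else {
    trend <- rep(max(0, median(raw)), nrow(counts))
  }
  w_raw <- if (ncol(counts) - 2 < 10) 0 else 0.3
  data.frame(gene_id = rownames(counts), mean_norm = mean_norm, raw = raw,
             dispersion = pmax(w_raw * raw + (1 - w_raw) * trend, 0))
}

# NB log-likelihood at fitted means (Poisson when dispersion ~ 0)
nb_loglik <- function(y, mu, dispersion) {
  if (dispersion < 1e-10) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / dispersion, mu = mu, log = TRUE))
}

#' Fit a negative binomial log-linear model for one gene
#'
#' Iteratively reweighted least squares with log link and offsets
#' (log effective library sizes). Design is intercept + group indicator;
#' pass `group = NULL` for the intercept-only reduced model.
#'
#' @param y counts for one gene.
#' @param group two-level factor (or NULL for the reduced model).
#' @param offsets log effective library sizes.
#' @param dispersion NB dispersion (0 = Poisson).
#' @param max_iter,tol IRLS controls.
#' @return list with `coef` (natural log), `log2fc` (NA for reduced model),
#'   `mu`, `loglik`, `converged`.
#' @export
fit_nb_glm <- function(y, group, offsets, dispersion, max_iter = 100, tol = 1e-8) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  X <- if (is.null(group)) matrix(1, length(y), 1) else {
    group <- factor(group)
    cbind(1, as.numeric(group == levels(group)[2]))
  }
  rate <- pmax(y, 0.125) / exp(offsets)
  beta <- qr.solve(X, log(rate))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offsets
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + dispersion * mu)
    zv <- (eta - offsets) + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X, XtW %*% zv)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + offsets
  mu <- pmax(exp(eta), 1e-10)
  list(coef = drop(beta),
       log2fc = if (ncol(X) == 2) drop(beta)[2] / log(2) else NA_real_,
       mu = mu, loglik = nb_loglik(y, mu, dispersion), converged = converged)
}

#' Likelihood-ratio test between nested NB fits
#'
#' 2 * (logLik full - logLik reduced) against chi-square with 1 df; small
#' negative statistics (numerical) are clamped to 0 with a warning.
#'
#' @param full,reduced fits from [fit_nb_glm()] on the same gene.
#' @return list with `lr` and `p.value`.
#' @export
lrt_test <- function(full, reduced) {
  lr <- 2 * (full$loglik - reduced$loglik)
  if (lr < 0) {
    if (lr < -1e-6) warning("negative LR statistic clamped to 0")
    lr <- 0
  }
  list(lr = lr, p.value = pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Two-group differential expression (NB GLM + likelihood-ratio test)
#'
#' The full stage: TMM normalization, CPM filtering, moment/trend dispersion
#' estimation, per-gene NB GLM fits (full vs intercept-only), LRT, and BH
#' adjustment. All-zero or non-converged genes are flagged and excluded from
#' testing.
#'
#' @param table an `expr_counts`.
#' @param min_cpm,min_samples CPM filter settings (see [cpm_filter()]).
#' @return data.frame per retained gene: gene_id, log2fc (second group vs
#'   first), avg_logcpm, dispersion, lr, p, q, status.
#' @export
deg_test <- function(table, min_cpm = 1,
                     min_samples = ceiling(ncol(table$counts) / 2)) {
  stopifnot(inherits(table, "expr_counts"))
  if (any(tabulate(table$groups) < 2)) stop("need >= 2 samples per group")
  nf <- tmm_factors(table)
  table <- cpm_filter(table, min_cpm, min_samples)
  counts <- table$counts; groups <- table$groups
  disp <- estimate_dispersion(table, nf)
  offsets <- log(table$lib_sizes * nf)
  cpm <- sweep(counts, 2, table$lib_sizes, `/`) * 1e6
  n <- nrow(counts)
  log2fc <- lr <- p <- rep(NA_real_, n)
  status <- rep("ok", n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) { status[i] <- "all_zero"; next }
    full <- fit_nb_glm(y, groups, offsets, disp$dispersion[i])
    red <- fit_nb_glm(y, NULL, offsets, disp$dispersion[i])
    if (!full$converged || !red$converged) { status[i] <- "not_converged"; next }
    log2fc[i] <- full$log2fc
    t <- lrt_test(full, red)
    lr[i] <- t$lr; p[i] <- t$p.value
  }
  q <- rep(NA_real_, n)
  ok <- status == "ok"
  q[ok] <- adjust_bh(p[ok])
  data.frame(gene_id = rownames(counts), log2fc = log2fc,
             avg_logcpm = log2(rowMeans(cpm) + 0.25),
             dispersion = disp$dispersion, lr = lr, p = p, q = q,
             status = status)
}

#' Call differentially expressed genes at an FDR threshold
#'
#' @param fits data.frame from [deg_test()].
#' @param q_threshold inclusive q cutoff (default 0.05).
#' @return subset of `fits` with `q <= q_threshold`.
#' @export
call_degs <- function(fits, q_threshold = 0.05) {
  stopifnot(is.data.frame(fits), "q" %in% names(fits))
  out <- fits[!is.na(fits$q) & fits$q <= q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "q_threshold") <- q_threshold
  out
}
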