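# shared fixtures, built in code

wtko <- function(m) factor(rep(c("WT", "KO"), each = m), levels = c("WT", "KO"))

# tiny hand-built count table (3 sites x 4 samples)
toy_cpg_table <- function() {
  cpg_count_table(
    sites = data.frame(chrom = "chr1", pos = c(100, 200, 300), strand = "+"),
    meth = matrix(c(3, 5, 0, 2, 6, 1, 4, 5, 0, 3, 7, 2), 3),
    total = matrix(10, 3, 4),
    groups = wtko(2))
}

# NB expression table with optional planted fold changes
toy_expr_table <- function(n_genes, m, mean0 = 200, disp = 0.05,
                           lfc = 0, lfc_frac = 0, seed = 1, sf = NULL) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(mean0), 1)
  planted <- seq_len(n_genes) <= round(lfc_frac * n_genes)
  l <- ifelse(planted, lfc, 0)
  if (is.null(sf)) sf <- runif(2 * m, 0.8, 1.2)
  mu <- outer(base, rep(1, 2 * m))
  mu[, (m + 1):(2 * m)] <- mu[, (m + 1):(2 * m)] * 2^l
  mu <- sweep(mu, 2, sf, `*`)
  cnt <- if (disp > 0)
    matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / disp), n_genes)
  else matrix(rpois(length(mu), as.vector(mu)), n_genes)
  rownames(cnt) <- sprintf("g%05d", seq_len(n_genes))
  list(table = expression_count_table(cnt, wtko(m)), planted = planted)
}

# independent quadratic oracle: all (site, window) containments, half-open
brute_force_links <- function(pos, starts, ends) {
  hits <- list()
  for (i in seq_along(pos))
    for (j in seq_along(starts))
      if (pos[i] >= starts[j] && pos[i] < ends[j])
        hits[[length(hits) + 1]] <- c(site = i, window = j)
  if (!length(hits)) return(matrix(numeric(0), 0, 2))
  do.call(rbind, hits)
}

# independent sup-difference of empirical CDFs
brute_force_ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
}
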