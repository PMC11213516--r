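test_that("strand collapsing merges symmetric dyads and conserves counts", {
  tb <- cpg_count_table(
    sites = data.frame(chrom = "chr1", pos = c(100, 101, 300), strand = c("+", "-", "+")),
    meth = matrix(c(3, 2, 1, 1, 1, 0, 2, 2, 5, 0, 1, 1), 3),
    total = matrix(c(10, 8, 5, 6, 4, 3, 7, 9, 8, 2, 3, 4), 3),
    groups = wtko(2))
  out <- collapse_strands(tb)
  expect_identical(nrow(out$sites), 2L)
  expect_identical(out$sites$pos, c(100, 300))
  expect_equal(unname(out$meth[1, ]), c(3 + 2, 1 + 1, 2 + 2, 0 + 1))
  expect_equal(unname(out$total[1, ]), c(10 + 8, 6 + 4, 7 + 9, 2 + 3))

  # plus-only table is unchanged
  tb2 <- toy_cpg_table()
  expect_identical(collapse_strands(tb2), tb2)

  # conservation over random tables
  set.seed(4)
  for (rep in 1:5) {
    n <- 20
    total <- matrix(rpois(n * 4, 15) + 1, n)
    meth <- matrix(rbinom(n * 4, as.vector(total), 0.4), n)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tbr <- cpg_count_table(data.frame(chrom = "chr1",
                                      pos = sort(sample.int(500, n)) * 2 +
                                        (strand == "-"),
                                      strand = strand),
                           meth, total, wtko(2))
    outr <- collapse_strands(tbr)
    expect_identical(sum(outr$meth), sum(tbr$meth))
    expect_identical(sum(outr$total), sum(tbr$total))
  }
})

test_that("coverage filter keeps exactly the sites covered in every sample", {
  tb <- toy_cpg_table()
  expect_identical(filter_coverage(tb, 1)$sites, tb$sites)

  tb$total[2, 3] <- 0; tb$meth[2, 3] <- 0
  out <- filter_coverage(tb, 5)
  expect_identical(out$sites$pos, c(100, 300))
  expect_identical(attr(out, "n_removed"), 1L)

  set.seed(9)
  total <- matrix(rpois(50 * 6, 6), 50)
  meth <- matrix(rbinom(50 * 6, as.vector(total), 0.5), 50)
  tbr <- cpg_count_table(data.frame(chrom = "chr1", pos = 1:50, strand = "+"),
                         meth, total, wtko(3))
  # independent row-scan oracle
  expect_identical(nrow(filter_coverage(tbr, 5)$sites),
                   sum(apply(tbr$total, 1, function(r) all(r >= 5))))
})

test_that("arcsine transform matches its closed form and is monotone", {
  expect_equal(arcsine_transform(5, 10), 0)
  expect_equal(arcsine_transform(0, 10), asin(-10 / 11))
  y <- arcsine_transform(0:20, 20)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= -pi / 2 & y <= pi / 2))
  expect_error(arcsine_transform(0, 0), "total")
})

test_that("dispersion estimation recovers planted values and nulls", {
  # binomial null: median estimate near zero
  s0 <- simulate_null_sites(10000, 50, 4, 0, seed = 41)
  phis <- methlink:::site_dispersion_mom(s0$table$meth, s0$table$total,
                                         s0$table$groups)
  expect_lte(median(phis), 0.01)

  # planted phi = 0.2 at coverage 50, n = 8
  s2 <- simulate_null_sites(10000, 50, 8, 0.2, seed = 42)
  phis2 <- methlink:::site_dispersion_mom(s2$table$meth, s2$table$total,
                                          s2$table$groups)
  expect_gte(median(phis2), 0.15)
  expect_lte(median(phis2), 0.25)

  # identical proportions everywhere -> 0
  expect_identical(estimate_site_dispersion(rep(5, 8), rep(10, 8), wtko(4)), 0)
  expect_error(estimate_site_dispersion(c(1, 2), c(5, 5), factor(c("WT", "KO"))),
               "2 samples")
})

test_that("the GLS site fit has the stated closed-form limits", {
  # identical counts in every sample: beta = 0, p = 1
  y <- arcsine_transform(rep(4, 8), rep(10, 8))
  f <- fit_site_gls(y, rep(10, 8), wtko(4), 0.1)
  expect_equal(f$beta, 0)
  expect_equal(f$p, 1)

  # equal totals, phi = 0: beta is the difference of group means of y
  set.seed(5)
  yv <- arcsine_transform(rbinom(8, 20, 0.4), rep(20, 8))
  f2 <- fit_site_gls(yv, rep(20, 8), wtko(4), 0)
  expect_equal(f2$beta, mean(yv[5:8]) - mean(yv[1:4]))

  # permutation of sample order never changes the fit
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  f3 <- fit_site_gls(yv[perm], rep(20, 8), wtko(4)[perm], 0)
  expect_equal(f3$beta, f2$beta)
  expect_equal(f3$p, f2$p)

  expect_error(fit_site_gls(yv, rep(20, 8), factor(rep("WT", 8), levels = c("WT", "KO")), 0),
               "singular")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.4, 0.01, 0.2, 0.03, 0.9)
  o <- sample(5)
  expect_equal(adjust_bh(p)[o], adjust_bh(p[o]))
  expect_true(all(adjust_bh(p) >= p))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DMC calling respects the q threshold and direction signs", {
  f0 <- dmc_fit(toy_cpg_table())
  expect_identical(nrow(call_dmcs(f0[0, ])), 0L)

  s <- simulate_null_sites(800, 30, 4, 0.01, seed = 43,
                           delta = 0.3, planted_fraction = 0.2)
  fits <- dmc_fit(s$table)
  d <- call_dmcs(fits, 0.05)
  expect_true(all(d$q <= 0.05))
  expect_true(all(d$direction[d$meth_diff > 0] == "hyper"))
  expect_true(all(d$direction[d$meth_diff < 0] == "hypo"))
  # members are exactly the q-passing ok fits
  expect_identical(nrow(d), sum(fits$q <= 0.05 & fits$status == "ok", na.rm = TRUE))
})

test_that("sample order never changes the site fits", {
  s <- simulate_null_sites(200, 30, 4, 0.05, seed = 44)
  tb <- s$table
  perm <- c(6, 2, 8, 4, 1, 7, 3, 5)
  tbp <- cpg_count_table(tb$sites, tb$meth[, perm], tb$total[, perm],
                         tb$groups[perm], tb$sample_ids[perm])
  f1 <- dmc_fit(tb); f2 <- dmc_fit(tbp)
  expect_equal(f1$p, f2$p)
  expect_equal(f1$beta, f2$beta)
})

test_that("global methylation shift detects constructed shifts and nulls", {
  s <- simulate_null_sites(500, 60, 4, 0, seed = 45)
  tb <- s$table
  # identical groups: duplicate WT columns as KO
  tb0 <- cpg_count_table(tb$sites, tb$meth[, c(1:4, 1:4)], tb$total[, c(1:4, 1:4)],
                         wtko(4))
  r0 <- global_methylation_shift(tb0)
  expect_equal(r0$statistic, 0)

  # +0.2 shift on the KO mean methylation
  s1 <- simulate_null_sites(1000, 200, 4, 0, seed = 46, delta = 0.2,
                            planted_fraction = 1, p0_range = c(0.2, 0.6))
  r1 <- global_methylation_shift(s1$table)
  expect_gte(r1$statistic, 0.2 - 0.05)
  expect_lt(r1$p.value, 1e-6)

  # D equals the brute-force sup-difference of empirical CDFs
  p_mat <- s1$table$meth / s1$table$total
  ko <- s1$table$groups == "KO"
  D <- brute_force_ks_d(rowMeans(p_mat[, ko]), rowMeans(p_mat[, !ko]))
  expect_equal(r1$statistic, D, tolerance = 1e-12)

  expect_error(global_methylation_shift(
    cpg_count_table(data.frame(chrom = "chr1", pos = 1, strand = "+"),
                    matrix(1, 1, 4), matrix(2, 1, 4), wtko(2))), "2 sites")
})

test_that("degenerate sites are flagged and excluded from testing", {
  tb <- cpg_count_table(
    sites = data.frame(chrom = "chr1", pos = c(10, 20), strand = "+"),
    meth = rbind(rep(0, 8), c(3, 4, 2, 5, 6, 7, 8, 5)),
    total = matrix(10, 2, 8),
    groups = wtko(4))
  f <- dmc_fit(tb)
  expect_identical(f$status, c("degenerate", "ok"))
  expect_true(is.na(f$p[1]) && is.na(f$q[1]))
  expect_false(is.na(f$p[2]))
})
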