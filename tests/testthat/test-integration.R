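toy_genome <- function() {
  genome_model(data.frame(name = "chr1", length = 100000),
               data.frame(gene_id = c("ga", "gb", "gc"), chrom = "chr1",
                          tss = c(5000, 8000, 50000), strand = c("+", "-", "+")))
}

test_that("TSS windows are symmetric, half-open and clipped", {
  g <- toy_genome()
  w <- derive_tss_windows(g, 2000)
  expect_equal(w$start[w$gene_id == "ga"], 3000)
  expect_equal(w$end[w$gene_id == "ga"], 7000)

  gnear <- genome_model(data.frame(name = "chr1", length = 100000),
                        data.frame(gene_id = "g1", chrom = "chr1",
                                   tss = 1000, strand = "+"))
  wn <- derive_tss_windows(gnear, 2000)
  expect_equal(wn$start, 0)
  expect_equal(wn$end, 3000)

  # windows of random genes contain their own TSS
  gr <- simulate_annotation(100, 1e7, 2e4, seed = 15)
  wr <- derive_tss_windows(gr)
  expect_true(all(wr$tss >= wr$start & wr$tss < wr$end))
})

test_that("DMC-to-gene linkage matches the quadratic containment oracle", {
  g <- toy_genome()
  w <- derive_tss_windows(g, 2000)
  mk_dmcs <- function(pos) data.frame(chrom = rep("chr1", length(pos)), pos = pos,
                                      q = rep(0.01, length(pos)),
                                      mean_ref = rep(0.2, length(pos)),
                                      mean_alt = rep(0.6, length(pos)),
                                      meth_diff = rep(0.4, length(pos)))
  # half-open convention at both edges
  l1 <- link_dmcs_to_genes(mk_dmcs(c(3000, 6999, 7000)), w)
  expect_setequal(l1$pos[l1$gene_id == "ga"], c(3000, 6999))

  expect_identical(nrow(link_dmcs_to_genes(mk_dmcs(numeric(0)), w)), 0L)

  # 5-site toy instance vs brute force (gb overlaps ga)
  pos <- c(4000, 6500, 9500, 49999, 52001)
  l <- link_dmcs_to_genes(mk_dmcs(pos), w)
  oracle <- brute_force_links(pos, w$start, w$end)
  expect_identical(nrow(l), nrow(oracle))
  expect_setequal(paste(l$gene_id, l$pos),
                  paste(w$gene_id[oracle[, "window"]], pos[oracle[, "site"]]))
  # signed distance on the gene strand, within the window half-width
  expect_true(all(abs(l$distance) <= 2000))
  expect_equal(l$distance[l$gene_id == "gb" & l$pos == 6500], 8000 - 6500)
})

test_that("DEG/DMC overlap is plain set intersection with Venn margins", {
  linked <- data.frame(gene_id = c("b", "c", "c", "d"))
  ov <- overlap_deg_dmc(c("a", "b", "c"), linked)
  expect_identical(ov$overlap, c("b", "c"))
  expect_identical(ov$n_deg, 3L)
  expect_identical(ov$n_linked_genes, 3L)
  expect_identical(ov$n_overlap, 2L)
  expect_identical(overlap_deg_dmc(c("x", "y"), linked)$n_overlap, 0L)

  set.seed(16)
  for (rep in 1:5) {
    a <- sample(letters, 10)
    b <- sample(letters, 12)
    ov2 <- overlap_deg_dmc(a, data.frame(gene_id = b))
    expect_setequal(ov2$overlap, intersect(a, b))
  }
})

test_that("the anticorrelation filter applies the 25% rule inclusively", {
  cnt <- rbind(gx = c(400, 360, 440, 100, 90, 110),
               gy = c(100, 110, 90, 100, 110, 90))
  expr <- expression_count_table(cnt, wtko(3))
  mk <- function(gene, ref, alt)
    data.frame(gene_id = gene, chrom = "chr1", pos = 1, distance = 0,
               q = 0.01, mean_ref = ref, mean_alt = alt,
               meth_diff = alt - ref)
  # gx down in KO, KO methylation 0.8 vs 0.4 -> passes
  f1 <- anticorrelation_filter("gx", mk("gx", 0.4, 0.8), expr)
  expect_true(f1$pass)
  expect_identical(f1$lower_group, "KO")
  expect_equal(f1$best_diff, 0.4)

  # boundary: difference exactly 0.25 passes (inclusive)
  f2 <- anticorrelation_filter("gx", mk("gx", 0.40, 0.65), expr)
  expect_true(f2$pass)
  f3 <- anticorrelation_filter("gx", mk("gx", 0.40, 0.6499), expr)
  expect_false(f3$pass)

  # wrong direction (hypermethylated in the higher-expression group) fails
  f4 <- anticorrelation_filter("gx", mk("gx", 0.8, 0.4), expr)
  expect_false(f4$pass)

  # genes without a linked DMC are dropped with a note
  f5 <- anticorrelation_filter(c("gx", "gy"), mk("gx", 0.4, 0.8), expr)
  expect_identical(attr(f5, "no_linked_dmc"), "gy")

  # relative reading: 0.3 -> 0.4 is a 1.33-fold rise, passes at 25% relative
  f6 <- anticorrelation_filter("gx", mk("gx", 0.3, 0.4), expr, relative = TRUE)
  expect_true(f6$pass)
  expect_false(anticorrelation_filter("gx", mk("gx", 0.3, 0.4), expr)$pass)
})

test_that("direction classes partition the overlap genes", {
  expect_identical(classify_direction(-2, 0.3), "down_hyper")
  expect_identical(classify_direction(2, -0.3), "up_hypo")
  expect_identical(classify_direction(-2, -0.3), "down_hypo")
  expect_identical(classify_direction(2, 0.3), "up_hyper")
  expect_warning(cl <- classify_direction(1, 0), "tie-broken")
  expect_identical(cl, "up_hypo")
  cls <- classify_direction(c(-1, 1, -1, 1), c(0.2, -0.2, -0.2, 0.2))
  expect_identical(sum(table(cls)), 4L)
})

test_that("k-means recovers planted blocks and is seed-deterministic", {
  set.seed(17)
  blockA <- matrix(rnorm(40 * 6, 0), 40, 6); blockA[, 1:3] <- blockA[, 1:3] + 4
  blockB <- matrix(rnorm(40 * 6, 0), 40, 6); blockB[, 4:6] <- blockB[, 4:6] + 4
  mat <- rbind(blockA, blockB)
  rownames(mat) <- paste0("g", 1:80)
  km <- zscore_kmeans(mat, k = 2, seed = 3, restarts = 10)
  lab <- km$labels
  agree <- max(mean(lab == c(rep(1, 40), rep(2, 40))),
               mean(lab == c(rep(2, 40), rep(1, 40))))
  expect_equal(agree, 1)

  km2 <- zscore_kmeans(mat, k = 2, seed = 3, restarts = 10)
  expect_identical(km$labels, km2$labels)

  # k = 1: single label, inertia equals total sum of squares of z-scores
  k1 <- zscore_kmeans(mat, k = 1)
  expect_true(all(k1$labels == 1))
  z <- t(scale(t(mat)))
  expect_equal(k1$inertia, sum(sweep(z, 2, colMeans(z))^2))

  expect_error(zscore_kmeans(mat[1:3, ], k = 5), "k exceeds")
})

test_that("the integration report assembles counts consistently", {
  # empty inputs: all-zero report
  fits0 <- dmc_fit(toy_cpg_table())
  fits0$q[] <- 1
  deg0 <- data.frame(gene_id = "ga", log2fc = 0, avg_logcpm = 1,
                     dispersion = 0.1, lr = 0, p = 1, q = 1, status = "ok")
  expr0 <- expression_count_table(
    matrix(5, 1, 4, dimnames = list("ga", NULL)), wtko(2))
  r0 <- integration_report(fits0, deg0, toy_genome(), expr0)
  expect_true(all(r0$counts == 0))

  # synthetic run: survivor count equals brute-force reapplication
  study <- simulate_study(sim_config(n_genes = 300, seed = 55))
  dmc_fits <- dmc_fit(study$meth$table)
  deg_fits <- deg_test(study$expr$table)
  rep1 <- integration_report(dmc_fits, deg_fits, study$genome, study$expr$table)
  rep2 <- integration_report(dmc_fits, deg_fits, study$genome, study$expr$table)
  expect_identical(format(rep1), format(rep2))

  dmcs <- call_dmcs(dmc_fits, 0.05)
  degs <- call_degs(deg_fits, 0.05)
  linked <- link_dmcs_to_genes(dmcs, derive_tss_windows(study$genome))
  ovg <- intersect(degs$gene_id, linked$gene_id)
  nf <- tmm_factors(study$expr$table)
  cpm <- sweep(study$expr$table$counts, 2,
               study$expr$table$lib_sizes * nf, `/`) * 1e6
  ko <- study$expr$table$groups == "KO"
  n_surv <- sum(vapply(ovg, function(g) {
    l <- linked[linked$gene_id == g, ]
    lower_ko <- mean(cpm[g, ko]) <= mean(cpm[g, !ko])
    lo <- if (lower_ko) l$mean_alt else l$mean_ref
    hi <- if (lower_ko) l$mean_ref else l$mean_alt
    any(lo - hi >= 0.25)
  }, logical(1)))
  expect_identical(unname(rep1$counts["n_survivors"]), n_surv)
  expect_lte(rep1$counts["n_survivors"], rep1$counts["n_overlap"])
  expect_identical(unname(rep1$counts["n_overlap"]), length(ovg))
  expect_identical(sum(rep1$class_tallies), as.integer(rep1$counts["n_survivors"]))
})

test_that("raising the methylation threshold never grows the survivor set", {
  study <- simulate_study(sim_config(n_genes = 300, seed = 56))
  dmc_fits <- dmc_fit(study$meth$table)
  deg_fits <- deg_test(study$expr$table)
  prev <- NULL
  for (thr in c(0.1, 0.2, 0.25, 0.3, 0.4)) {
    r <- integration_report(dmc_fits, deg_fits, study$genome,
                            study$expr$table, meth_threshold = thr)
    cur <- r$survivors$gene_id
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})
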