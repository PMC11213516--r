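#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. Defaults reproduce
#' the study conditions the pipeline is designed for: two groups (WT vs KO),
#' n = 4 animals per group, mean sequencing coverage 30x, planted
#' differentially methylated CpGs with an effect of +/-0.30 on the
#' methylation-proportion scale, planted differentially expressed genes at
#' |log2 fold change| = 2 with negative binomial dispersion 0.05, and a
#' fraction of "coupled" genes whose promoter hypermethylation accompanies
#' downregulation.
#'
#' @param samples_per_group samples (animals) per group.
#' @param n_genes number of genes on the simulated chromosome.
#' @param chrom_length chromosome length in bp.
#' @param min_spacing minimum TSS-to-TSS distance in bp.
#' @param sites_per_tss CpG sites placed inside each TSS +/- 2 kb window.
#' @param tss_site_fraction fraction of all CpG sites that fall in TSS
#'   windows (the rest are background); default 0.6.
#' @param coverage_mean,coverage_shape negative binomial read-depth model
#'   (mean and shape); depth is floored at 1 read.
#' @param dmc_fraction fraction of CpG sites carrying a planted group effect.
#' @param dmc_delta planted methylation difference (KO - WT, proportion scale).
#' @param hyper_fraction fraction of planted DMCs that are hypermethylated in
#'   KO (the global shift in the system is upward).
#' @param phi beta-binomial biological dispersion of methylation proportions.
#' @param deg_fraction fraction of genes planted as differentially expressed.
#' @param deg_log2fc planted |log2 fold change| for DEGs.
#' @param nb_dispersion negative binomial dispersion of expression counts.
#' @param mean_log_expression,sd_log_expression lognormal model of baseline
#'   gene mean counts.
#' @param coupling_fraction fraction of planted DEGs that are methylation-
#'   coupled (promoter hypermethylation + downregulation).
#' @param coupled_sites_min planted promoter DMCs per coupled gene.
#' @param metabolite_cv lognormal coefficient of variation of panel
#'   abundances (0 gives noise-free group means).
#' @param seed master seed; mandatory. All sub-generators derive their own
#'   seeds from it deterministically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(samples_per_group = 4,
                       n_genes = 200,
                       chrom_length = 2e7,
                       min_spacing = 2e4,
                       sites_per_tss = 6,
                       tss_site_fraction = 0.6,
                       coverage_mean = 30,
                       coverage_shape = 5,
                       dmc_fraction = 0.05,
                       dmc_delta = 0.3,
                       hyper_fraction = 0.8,
                       phi = 0.01,
                       deg_fraction = 0.1,
                       deg_log2fc = 2,
                       nb_dispersion = 0.05,
                       mean_log_expression = log(150),
                       sd_log_expression = 1.2,
                       coupling_fraction = 0.2,
                       coupled_sites_min = 3,
                       metabolite_cv = 0.3,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  fr <- c(tss_site_fraction = tss_site_fraction, dmc_fraction = dmc_fraction,
          hyper_fraction = hyper_fraction, deg_fraction = deg_fraction,
          coupling_fraction = coupling_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (samples_per_group < 1 || n_genes < 0) stop("invalid sizes")
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  if (nb_dispersion < 0) stop("dispersion must be >= 0")
  if (metabolite_cv < 0) stop("metabolite_cv must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a gene annotation
#'
#' Places `n_genes` TSSs on a single chromosome with a guaranteed minimum
#' spacing, random strands, and returns a valid [genome_model()].
#'
#' @param n_genes number of genes (0 allowed).
#' @param chrom_length chromosome length in bp.
#' @param min_spacing minimum pairwise TSS distance in bp.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return A `genome_model`.
#' @export
simulate_annotation <- function(n_genes, chrom_length, min_spacing, seed) {
  if (n_genes * min_spacing > chrom_length)
    stop("cannot place genes: n_genes * min_spacing exceeds chromosome length")
  chroms <- data.frame(name = "chr1", length = chrom_length)
  if (n_genes == 0)
    return(genome_model(chroms, data.frame(gene_id = character(), chrom = character(),
                                           tss = numeric(), strand = character())))
  set.seed(seed)
  # draw gaps uniformly, then re-insert the guaranteed spacing
  slack <- chrom_length - n_genes * min_spacing
  u <- sort(runif(n_genes, 0, slack))
  tss <- floor(u + (seq_len(n_genes) - 1) * min_spacing + min_spacing / 2)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                      chrom = "chr1", tss = tss, strand = strand)
  genome_model(chroms, genes)
}

# beta-binomial sampler: mean p, dispersion phi; phi = 0 degenerates to binomial
rbetabinom <- function(n, size, p, phi) {
  p <- rep_len(p, n); phi <- rep_len(phi, n); size <- rep_len(size, n)
  pr <- p
  idx <- phi > 0 & p > 0 & p < 1
  if (any(idx)) {
    a <- p[idx] * (1 - phi[idx]) / phi[idx]
    b <- (1 - p[idx]) * (1 - phi[idx]) / phi[idx]
    pr[idx] <- rbeta(sum(idx), a, b)
  }
  rbinom(n, size, pr)
}

#' Simulate per-CpG methylation counts with planted DMCs
#'
#' Emulates reduced-representation bisulfite sequencing counts: CpG sites are
#' placed both inside TSS +/- 2 kb windows and in background regions; read
#' depth is negative binomial (floored at 1); methylated counts are
#' beta-binomial around a group mean proportion. A `dmc_fraction` of sites
#' carries a planted KO - WT difference `dmc_delta`; a subset of genes is
#' pre-selected as methylation-coupled and receives planted hypermethylated
#' promoter CpGs (their ids are recorded for [simulate_expression_counts()]).
#'
#' Baseline methylation is bimodal as in real methylomes: promoter-window
#' sites are drawn hypomethylated (Beta(1.5, 6)), background sites
#' hypermethylated (Beta(6, 1.5)); planted sites get baselines that keep
#' `p0 + delta` inside [0, 1].
#'
#' @param genome a `genome_model`.
#' @param config a [sim_config()].
#' @return list with elements `table` (a `cpg_counts`) and `truth`
#'   (data.frame: chrom, pos, p0, delta, phi, is_planted_dmc, gene_id of the
#'   covering TSS window or NA, is_coupled_site), plus attribute
#'   `coupled_genes` on `truth`.
#' @export
simulate_methylation_counts <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  if (config$coverage_mean <= 0) stop("coverage mean must be positive")
  seeds <- split_seed(config$seed, 4)

  set.seed(seeds[1])
  genes <- genome$genes
  L <- genome$chromosomes$length[1]
  hw <- 2000L
  n_tss_sites <- nrow(genes) * config$sites_per_tss
  pos_tss <- integer(0); site_gene <- character(0)
  if (n_tss_sites > 0) {
    pos_tss <- unlist(lapply(seq_len(nrow(genes)), function(i) {
      p <- floor(runif(config$sites_per_tss, genes$tss[i] - hw, genes$tss[i] + hw))
      pmin(pmax(p, 0), L - 1)
    }))
    site_gene <- rep(genes$gene_id, each = config$sites_per_tss)
  }
  f <- config$tss_site_fraction
  n_bg <- if (f > 0) round(n_tss_sites * (1 - f) / f) else 0L
  pos_bg <- floor(runif(n_bg, 0, L))
  pos <- c(pos_tss, pos_bg)
  gene_of <- c(site_gene, rep(NA_character_, n_bg))
  keep <- !duplicated(pos)
  pos <- pos[keep]; gene_of <- gene_of[keep]
  o <- order(pos); pos <- pos[o]; gene_of <- gene_of[o]
  n_sites <- length(pos)
  in_window <- !is.na(gene_of)

  # baselines: promoters hypomethylated, background hypermethylated
  p0 <- numeric(n_sites)
  p0[in_window] <- rbeta(sum(in_window), 1.5, 6)
  p0[!in_window] <- rbeta(sum(!in_window), 6, 1.5)
  delta <- numeric(n_sites)
  planted <- logical(n_sites)
  coupled_site <- logical(n_sites)

  # coupled genes: planted hypermethylated promoter CpGs
  n_deg <- round(config$deg_fraction * nrow(genes))
  n_coupled <- round(config$coupling_fraction * n_deg)
  coupled_genes <- character(0)
  if (n_coupled > 0) {
    hyper_hi <- max(0.05, min(0.45, 1 - config$dmc_delta - 0.05))
    hyper_lo <- min(0.15, hyper_hi)
    cand <- unique(gene_of[in_window])
    coupled_genes <- cand[sample.int(length(cand), min(n_coupled, length(cand)))]
    for (g in coupled_genes) {
      idx <- which(gene_of == g)
      take <- idx[seq_len(min(config$coupled_sites_min, length(idx)))]
      planted[take] <- TRUE
      coupled_site[take] <- TRUE
      delta[take] <- config$dmc_delta
      p0[take] <- runif(length(take), hyper_lo, hyper_hi)
    }
  }

  # remaining planted DMCs scattered over unplanted sites
  n_dmc <- round(config$dmc_fraction * n_sites)
  n_more <- max(0L, n_dmc - sum(planted))
  free <- which(!planted)
  if (n_more > 0 && length(free) > 0) {
    hyper_hi <- max(0.05, min(0.45, 1 - config$dmc_delta - 0.05))
    hyper_lo <- min(0.15, hyper_hi)
    hypo_lo <- min(0.95, max(0.55, config$dmc_delta + 0.05))
    hypo_hi <- max(0.85, hypo_lo)
    take <- free[sample.int(length(free), min(n_more, length(free)))]
    planted[take] <- TRUE
    hyper <- runif(length(take)) < config$hyper_fraction
    delta[take] <- ifelse(hyper, config$dmc_delta, -config$dmc_delta)
    p0[take[hyper]] <- runif(sum(hyper), hyper_lo, hyper_hi)
    p0[take[!hyper]] <- runif(sum(!hyper), hypo_lo, hypo_hi)
  }

  m <- config$samples_per_group
  n_samp <- 2L * m
  groups <- factor(rep(c("WT", "KO"), each = m), levels = c("WT", "KO"))
  sample_ids <- paste0(rep(c("WT", "KO"), each = m), rep(seq_len(m), 2))

  set.seed(seeds[2])
  total <- matrix(pmax(1L, rnbinom(n_sites * n_samp, mu = config$coverage_mean,
                                   size = config$coverage_shape)),
                  nrow = n_sites)
  set.seed(seeds[3])
  p_group <- matrix(p0, n_sites, n_samp)
  ko <- groups == "KO"
  p_group[, ko] <- pmin(pmax(p_group[, ko] + delta, 0), 1)
  meth <- matrix(rbetabinom(n_sites * n_samp, as.vector(total),
                            as.vector(p_group), config$phi),
                 nrow = n_sites)

  sites <- data.frame(chrom = "chr1", pos = pos, strand = "+")
  table <- cpg_count_table(sites, meth, total, groups, sample_ids)
  truth <- data.frame(chrom = "chr1", pos = pos, p0 = p0, delta = delta,
                      phi = config$phi, is_planted_dmc = planted,
                      gene_id = gene_of, is_coupled_site = coupled_site)
  attr(truth, "coupled_genes") <- sort(coupled_genes)
  list(table = table, truth = truth)
}

#' Simulate expression counts with planted DEGs, partially coupled to
#' promoter methylation
#'
#' Negative binomial gene x sample counts. Genes recorded as coupled in the
#' methylation truth (promoter hypermethylation planted) are downregulated in
#' KO (log2FC = -`deg_log2fc`); additional uncoupled DEGs are planted with
#' random sign among genes whose TSS window carries no planted DMC, so that
#' coupling is unambiguous in the truth tables.
#'
#' @param genome a `genome_model`.
#' @param config a [sim_config()].
#' @param meth_truth truth table from [simulate_methylation_counts()].
#' @return list with `table` (an `expr_counts`) and `truth` (data.frame:
#'   gene_id, base_mean, log2fc, dispersion, is_planted_deg, is_coupled).
#' @export
simulate_expression_counts <- function(genome, config, meth_truth) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  if (config$nb_dispersion < 0) stop("dispersion must be >= 0")
  seeds <- split_seed(config$seed + 17, 2)
  genes <- genome$genes
  n_genes <- nrow(genes)

  coupled_genes <- attr(meth_truth, "coupled_genes")
  if (is.null(coupled_genes))
    coupled_genes <- sort(unique(meth_truth$gene_id[meth_truth$is_coupled_site &
                                                      !is.na(meth_truth$gene_id)]))
  genes_with_dmc <- unique(meth_truth$gene_id[meth_truth$is_planted_dmc &
                                                !is.na(meth_truth$gene_id)])

  set.seed(seeds[1])
  base_mean <- rlnorm(n_genes, config$mean_log_expression, config$sd_log_expression)
  log2fc <- numeric(n_genes)
  is_deg <- logical(n_genes)
  is_coupled <- genes$gene_id %in% coupled_genes
  log2fc[is_coupled] <- -config$deg_log2fc
  is_deg[is_coupled] <- TRUE

  n_deg <- round(config$deg_fraction * n_genes)
  n_more <- max(0L, n_deg - sum(is_coupled))
  free <- which(!is_deg & !(genes$gene_id %in% genes_with_dmc))
  if (n_more > 0 && length(free) > 0) {
    take <- free[sample.int(length(free), min(n_more, length(free)))]
    is_deg[take] <- TRUE
    log2fc[take] <- sample(c(-1, 1), length(take), replace = TRUE) * config$deg_log2fc
  }

  m <- config$samples_per_group
  groups <- factor(rep(c("WT", "KO"), each = m), levels = c("WT", "KO"))
  sample_ids <- paste0(rep(c("WT", "KO"), each = m), rep(seq_len(m), 2))
  sf <- runif(2 * m, 0.8, 1.2)
  mu <- outer(base_mean, rep(1, 2 * m))
  mu[, groups == "KO"] <- mu[, groups == "KO"] * 2^log2fc
  mu <- sweep(mu, 2, sf, `*`)

  set.seed(seeds[2])
  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$nb_dispersion),
           nrow = n_genes)
  } else {
    matrix(rpois(length(mu), as.vector(mu)), nrow = n_genes)
  }
  rownames(counts) <- genes$gene_id
  table <- expression_count_table(counts, groups, sample_ids)
  truth <- data.frame(gene_id = genes$gene_id, base_mean = base_mean,
                      log2fc = log2fc, dispersion = config$nb_dispersion,
                      is_planted_deg = is_deg, is_coupled = is_coupled)
  list(table = table, truth = truth)
}

#' Simulate a closed boundary of controllable roughness
#'
#' Samples the star-shaped curve r(theta) = R (1 + eps sin(k theta)) at
#' `n_vertices` equally spaced angles, optionally with seeded multiplicative
#' radial jitter. With `amplitude = 0` this is a regular n-gon approximating
#' a circle; increasing `amplitude` adds `lobes` finger-like projections.
#'
#' @param radius base radius R (physical units).
#' @param amplitude lobe amplitude eps in [0, 1).
#' @param lobes integer number of lobes k.
#' @param n_vertices number of vertices (>= 16).
#' @param seed seed for the jitter (unused when `jitter_sd = 0`).
#' @param jitter_sd sd of lognormal radial jitter (0 = none).
#' @return A [boundary_polygon()].
#' @export
simulate_boundary <- function(radius, amplitude, lobes, n_vertices,
                              seed = 1, jitter_sd = 0) {
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must lie in [0, 1)")
  if (n_vertices < 16) stop("need at least 16 vertices")
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  r <- radius * (1 + amplitude * sin(lobes * theta))
  if (jitter_sd > 0) {
    set.seed(seed)
    r <- r * exp(rnorm(n_vertices, 0, jitter_sd))
  }
  boundary_polygon(r * cos(theta), r * sin(theta))
}

#' Simulate metabolite and adenine-nucleotide panels
#'
#' Lognormal abundances around group means with coefficient of variation
#' `metabolite_cv`. Planted KO/WT fold changes emulate the metabolic shift of
#' complex III loss: 2-HG doubled, succinate and fumarate up 1.5-fold,
#' alpha-ketoglutarate down to 0.7, SAM up 1.3, SAH down to 0.9 -- so all
#' four methylation-potential ratios rise in KO. Nucleotides (ATP, ADP, AMP)
#' are scaled jointly by 0.7 in KO: concentrations fall but the adenylate
#' energy charge is preserved.
#'
#' @param config a [sim_config()].
#' @return list with `metabolites` (matrix metabolite x sample), `nucleotides`
#'   (data.frame sample, group, ATP, ADP, AMP), `groups`, and `truth`
#'   (planted KO/WT fold change per analyte).
#' @export
simulate_panels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(config$seed + 31, 2)
  m <- config$samples_per_group
  groups <- factor(rep(c("WT", "KO"), each = m), levels = c("WT", "KO"))
  sample_ids <- paste0(rep(c("WT", "KO"), each = m), rep(seq_len(m), 2))

  met_names <- c("2HG", "aKG", "succinate", "fumarate", "SAM", "SAH",
                 "lactate", "glutamate", "malate", "citrate")
  ko_fold <- c(`2HG` = 2, aKG = 0.7, succinate = 1.5, fumarate = 1.5,
               SAM = 1.3, SAH = 0.9, lactate = 1.2, glutamate = 1,
               malate = 1, citrate = 1)
  cv <- config$metabolite_cv
  sdlog <- sqrt(log(1 + cv^2))

  draw <- function(mean_mat, seed) {
    if (cv == 0) return(mean_mat)
    set.seed(seed)
    meanlog <- log(mean_mat) - sdlog^2 / 2
    matrix(rlnorm(length(mean_mat), as.vector(meanlog), sdlog),
           nrow = nrow(mean_mat), dimnames = dimnames(mean_mat))
  }

  mm <- matrix(1, length(met_names), 2 * m, dimnames = list(met_names, sample_ids))
  mm[, groups == "KO"] <- ko_fold[met_names]
  metabolites <- draw(mm, seeds[1])

  nuc_base <- c(ATP = 5, ADP = 1, AMP = 0.2)   # nmol/mg tissue
  nm <- matrix(nuc_base, 3, 2 * m, dimnames = list(names(nuc_base), sample_ids))
  nm[, groups == "KO"] <- nm[, groups == "KO"] * 0.7
  nuc <- draw(nm, seeds[2])
  nucleotides <- data.frame(sample = sample_ids, group = groups,
                            ATP = nuc["ATP", ], ADP = nuc["ADP", ],
                            AMP = nuc["AMP", ], row.names = NULL)

  truth <- data.frame(analyte = c(met_names, names(nuc_base)),
                      ko_fold = c(unname(ko_fold[met_names]), rep(0.7, 3)))
  list(metabolites = metabolites, nucleotides = nucleotides,
       groups = groups, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs every generator with sub-seeds derived from the master seed:
#' annotation, methylation counts with planted DMCs, expression counts with
#' planted (partially coupled) DEGs, metabolite/nucleotide panels, and
#' per-animal infarct-boundary tracings (4 animals x 6 slices per group;
#' control boundaries nearly smooth, KO boundaries with 12 lobes of
#' amplitude 0.25 emulating finger-like projections).
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_study` with elements `genome`, `meth`,
#'   `expr`, `panels`, `boundaries`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_annotation(config$n_genes, config$chrom_length,
                                config$min_spacing, seed = config$seed + 7)
  meth <- simulate_methylation_counts(genome, config)
  expr <- simulate_expression_counts(genome, config, meth$truth)
  panels <- simulate_panels(config)
  bseeds <- split_seed(config$seed + 59, 48)
  mk <- function(amp, label, off) {
    out <- list()
    for (a in 1:4) for (s in 1:6) {
      p <- simulate_boundary(1000, amp, 12, 400,
                             seed = bseeds[off + (a - 1) * 6 + s], jitter_sd = 0.002)
      attr(p, "id") <- sprintf("%s_m%d_s%d", label, a, s)
      attr(p, "animal") <- sprintf("%s_m%d", label, a)
      out[[length(out) + 1]] <- p
    }
    out
  }
  boundaries <- list(WT = mk(0.05, "WT", 0), KO = mk(0.25, "KO", 24))
  structure(list(genome = genome, meth = meth, expr = expr, panels = panels,
                 boundaries = boundaries, config = config),
            class = "synthetic_study")
}

#' Simulate null or constant-effect CpG sites for calibration designs
#'
#' A flat design for operating-characteristic checks: baseline methylation
#' drawn uniformly over the informative range (default [0.1, 0.9], avoiding
#' the boundary regimes that the caller flags as degenerate), negative
#' binomial coverage floored at one read, beta-binomial counts with common
#' dispersion, and an optional constant planted effect `delta` (KO - WT) on
#' a leading fraction of sites.
#'
#' @param n_sites number of CpG sites.
#' @param coverage mean read depth (NB with shape 5, floored at 1).
#' @param samples_per_group samples per group.
#' @param phi beta-binomial dispersion.
#' @param seed integer seed.
#' @param delta planted effect for the first `round(planted_fraction *
#'   n_sites)` sites (default 0 = pure null).
#' @param planted_fraction fraction of sites carrying `delta`.
#' @param p0_range range of the uniform baseline.
#' @return list with `table` (a `cpg_counts`, groups WT/KO) and `truth`
#'   (data.frame: pos, p0, delta, is_planted).
#' @export
simulate_null_sites <- function(n_sites, coverage, samples_per_group, phi,
                                seed, delta = 0, planted_fraction = 0,
                                p0_range = c(0.1, 0.9)) {
  if (coverage <= 0) stop("coverage must be positive")
  if (phi < 0 || phi >= 1) stop("phi must lie in [0, 1)")
  set.seed(seed)
  m <- samples_per_group
  planted <- seq_len(n_sites) <= round(planted_fraction * n_sites)
  p0 <- runif(n_sites, p0_range[1], p0_range[2])
  # keep planted baselines clear of the boundary on the shifted side
  if (delta > 0) p0[planted] <- runif(sum(planted), 0.15, min(0.95 - delta, 0.45))
  if (delta < 0) p0[planted] <- runif(sum(planted), max(0.05 - delta, 0.55), 0.85)
  d <- ifelse(planted, delta, 0)
  total <- matrix(pmax(1L, rnbinom(n_sites * 2 * m, mu = coverage, size = 5)),
                  n_sites)
  pg <- matrix(p0, n_sites, 2 * m)
  ko <- rep(c(FALSE, TRUE), each = m)
  pg[, ko] <- pmin(pmax(pg[, ko] + d, 0), 1)
  meth <- matrix(rbetabinom(n_sites * 2 * m, as.vector(total), as.vector(pg), phi),
                 n_sites)
  groups <- factor(rep(c("WT", "KO"), each = m), levels = c("WT", "KO"))
  table <- cpg_count_table(data.frame(chrom = "chr1",
                                      pos = seq_len(n_sites) * 50, strand = "+"),
                           meth, total, groups,
                           paste0(rep(c("WT", "KO"), each = m), rep(seq_len(m), 2)))
  list(table = table,
       truth = data.frame(pos = seq_len(n_sites) * 50, p0 = p0, delta = d,
                          is_planted = planted))
}
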