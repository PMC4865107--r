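test_that("consecutive distances summarize adjacent-site spacing", {
  cd <- consecutive_distances(c(100, 200, 400))
  expect_equal(cd$distances, c(100, 200))
  expect_equal(cd$mean, 150)
  expect_equal(consecutive_distances(c(5000))$distances, numeric(0))
  # uniform sites: mean spacing near region/(n-1) within 2 SE
  g <- small_genome(1000000, 0, 500000)
  s <- random_sites(100, g, seed = 9)
  cd2 <- consecutive_distances(s$center, 0, 1e6)
  se <- sd(cd2$distances) / sqrt(length(cd2$distances))
  expect_lt(abs(cd2$mean - 1e6 / 100), 2.5 * se + 1e4 / sqrt(100))
})

test_that("site density histograms count every site once", {
  g <- small_genome(200000, 0, 100000)
  expect_equal(sum(site_density(numeric(0), g)$count), 0)
  one_bin <- site_density(c(60001, 60002, 74000), g)
  expect_equal(sum(one_bin$count > 0), 1)
  s <- random_sites(500, g, seed = 2)
  h <- site_density(s, g, bin = 50000)
  expect_equal(sum(h$count), 500)
  expect_equal(nrow(h), 4)
})

test_that("gene localization classifies and orients sites", {
  genes <- tibble::tibble(start = c(100, 1000), end = c(500, 1400),
                          strand = c("+", "-"))
  gl <- gene_localization(c(150, 1100, 700), genes)
  expect_equal(gl$frac_in_genes, 2 / 3)
  expect_equal(gl$frac_intergenic, 1 / 3)
  expect_equal(gl$frac_in_genes + gl$frac_intergenic, 1)
  expect_true(all(gl$normalized_positions >= 0 &
                    gl$normalized_positions <= 1))
  # minus-strand gene: a site at the gene start maps to 1 (3' end)
  gl2 <- gene_localization(1000, genes)
  expect_equal(gl2$normalized_positions, 1.0)
  # random sites fall in genes at the genome's gene coverage
  g <- small_genome(200000, 0, 100000)
  ann <- make_annotation(g, n_genes = 150, n_tu_highly_expressed = 10,
                         seed = 5)
  s <- random_sites(800, g, seed = 6)
  gl3 <- gene_localization(s, ann$genes)
  f <- 1 - intergenic_fraction(ann)
  se <- sqrt(f * (1 - f) / 800)
  expect_lt(abs(gl3$frac_in_genes - f), 3 * se)
})

test_that("TU proximity distances and ANOVA behave as constructed", {
  g <- small_genome(500000, 0, 250000)
  tus <- tibble::tibble(start = seq(20000, 470000, by = 50000),
                        end = seq(20000, 470000, by = 50000) + 5000,
                        expression = rep(c(1000, 10), 5))
  hot <- tus[tus$expression >= 500, ]
  # a site inside a hot TU has distance 0
  tp0 <- tu_proximity(hot$start + 100, tus, g, seed = 1)
  expect_equal(tp0$distances, rep(0, nrow(hot)))
  # sites planted exactly 1 kb from hot TU ends beat the uniform control
  near <- rep(hot$end + 999, 20)
  tp <- tu_proximity(near, tus, g, seed = 3)
  expect_equal(unique(tp$distances), 1000)
  expect_gt(tp$control_median, tp$median)
  expect_lt(tp$p_value, 0.05)
  expect_equal(tp$frac_within_cut, 1)
  expect_error(tu_proximity(c(1, 2), tus, g, expr_threshold = 1e9),
               "threshold")
})

test_that("the TU-proximity p-value is well calibrated under the null", {
  g <- small_genome(200000, 0, 100000)
  ann <- make_annotation(g, n_genes = 80, n_tu_highly_expressed = 12,
                         seed = 7)
  pvals <- vapply(1:200, function(s) {
    sites <- random_sites(40, g, seed = 10000 + s)
    tu_proximity(sites, ann$tus, g, seed = 20000 + s)$p_value
  }, numeric(1))
  # super-uniform at alpha = 0.05 (allowing binomial slack at 200 draws)
  expect_lte(mean(pvals < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("Fisher overlap matches brute-force hypergeometric enumeration", {
  # the published-style 2x2 gene-level test on a small universe
  g <- small_genome(50000, 0, 25000)
  genes <- tibble::tibble(start = seq(0, 49000, by = 1000) + 100,
                          end = seq(0, 49000, by = 1000) + 900)
  genes <- genes[1:20, ]
  sites <- genes$start[1:10] + 10          # sites in genes 1..10
  features <- tibble::tibble(start = genes$start[c(1:8, 11, 12)],
                             end = genes$end[c(1:8, 11, 12)])
  res <- overlap_fisher(sites, features, genes)
  expect_equal(res$n_common_genes, 8)
  expect_equal(res$n_feature_genes, 10)
  a <- res$n_common_genes
  b <- res$n_site_genes - a
  c_ <- res$n_feature_genes - a
  d <- res$n_genes - a - b - c_
  expect_equal(res$p_value, fisher_enumerate(a, b, c_, d),
               tolerance = 1e-10)
  # the fixed [[8,2],[2,8]] table on 20 genes
  expect_equal(fisher_enumerate(8, 2, 2, 8),
               fisher.test(matrix(c(8, 2, 2, 8), 2),
                           alternative = "greater")$p.value,
    tolerance = 1e-10)
  # extreme enrichment
  sites2 <- genes$start[1:6] + 10
  feat2 <- tibble::tibble(start = genes$start[1:6], end = genes$end[1:6])
  expect_lt(overlap_fisher(sites2, feat2, genes)$p_value, 1e-3)
  expect_error(overlap_fisher(sites, features, genes[0, ]), "empty")
})

test_that("Fisher p-values are uniform under independent random labels", {
  g <- small_genome(60000, 0, 30000)
  genes <- tibble::tibble(start = seq(0, 59000, by = 1000) + 100,
                          end = seq(0, 59000, by = 1000) + 900)
  pvals <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      site_genes <- sample.int(60, 15)
      feat_genes <- sample.int(60, 20)
      overlap_fisher(genes$start[site_genes] + 5,
                     tibble::tibble(start = genes$start[feat_genes],
                                    end = genes$end[feat_genes]),
                     genes)$p_value
    })
  }, numeric(1))
  # exact-test p-values are discrete and therefore super-uniform: the
  # rejection rate must not exceed alpha (plus binomial slack) at any level
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= alpha),
               alpha + 2 * sqrt(alpha * (1 - alpha) / 200))
  }
  # ...but the p-values are not degenerate either
  expect_gt(mean(pvals <= 0.5), 0.2)
})

test_that("dinucleotide profiles recover engineered and random content", {
  # strict alternation: GC at even offsets only
  gcrep <- genome_spec(1000, 0, 500,
                       sequence = paste(rep("GC", 500), collapse = ""))
  prof <- dinucleotide_profile(gcrep, c(100, 500), window = 20)
  even <- prof$offset %% 2 == 0
  expect_equal(prof$frequency[even], rep(1, sum(even)))
  expect_equal(prof$frequency[!even], rep(0, sum(!even)))
  # random sequence: flat near p(G) * p(C)
  g <- make_genome(200000, oriC = 0, dif = 100000, gc_fraction = 0.5,
                   seed = 11)
  s <- random_sites(300, g, seed = 12)
  prof2 <- dinucleotide_profile(g, s, window = 100)
  expect_lt(abs(mean(prof2$frequency) - 0.0625), 0.01)
  # engineered GC-rich 20 bp cores produce a central bump
  core <- strrep("GC", 10)
  seq3 <- strsplit(make_genome(50000, oriC = 0, dif = 25000,
                               gc_fraction = 0.4, seed = 13)$sequence, "")[[1]]
  centers3 <- seq(5000, 45000, by = 5000)
  for (c0 in centers3) {
    seq3[(c0 - 10 + 1):(c0 + 10)] <- strsplit(core, "")[[1]]
  }
  g3 <- genome_spec(50000, 0, 25000, sequence = paste(seq3, collapse = ""))
  prof3 <- dinucleotide_profile(g3, centers3, window = 200)
  central <- abs(prof3$offset) < 10
  expect_gt(mean(prof3$frequency[central]),
            5 * mean(prof3$frequency[!central]))
})

test_that("GATC spacing profiles match engineered and random expectations", {
  # exact 256 bp lattice
  unit <- paste0("GATC", strrep("A", 252))
  gl <- genome_spec(256 * 100, 0, 12800,
                    sequence = strrep(unit, 100))
  gs <- gatc_spacing(gl, c(6400, 12800, 19200), k = 5)
  expect_equal(gs$profile$mean_spacing, rep(256, 11))
  # random sequence: expected spacing 1/p = 4^4 = 256
  g <- make_genome(400000, oriC = 0, dif = 200000, gc_fraction = 0.5,
                   seed = 14)
  s <- random_sites(150, g, seed = 15)
  gs2 <- gatc_spacing(g, s, k = 10, seed = 16)
  flank <- gs2$profile$rank != 0
  expect_lt(abs(mean(gs2$profile$mean_spacing[flank]) - 256), 26)
  expect_lt(abs(mean(gs2$profile$control_spacing[flank]) - 256), 26)
  # the rank-0 gap is the one containing a uniformly drawn point, hence
  # length-biased: E = E[X^2]/E[X] ~ 2/p - 1 = 511 for geometric gaps
  expect_gt(gs2$profile$mean_spacing[!flank], 350)
  expect_lt(gs2$profile$mean_spacing[!flank], 700)
  # sites centered in engineered 800 bp GATC-free windows: central rank
  # spacing ~ 800, flanks much closer
  seqv <- strsplit(strrep(paste0("GATC", strrep("T", 60)), 800), "")[[1]]
  centers <- seq(5000, 45000, by = 5000)
  for (c0 in centers) {
    win <- (c0 - 400 + 1):(c0 + 400)
    seqv[win] <- "T"
  }
  ge <- genome_spec(length(seqv), 0, 25000,
                    sequence = paste(seqv, collapse = ""))
  gs3 <- gatc_spacing(ge, centers, k = 3)
  central <- gs3$profile$rank == 0
  expect_gte(min(gs3$profile$mean_spacing[central]), 800)
  expect_lt(max(gs3$profile$mean_spacing[!central]), 200)
})

test_that("random control sites are uniform and respect exclusions", {
  g <- small_genome(100000, 0, 50000)
  expect_equal(nrow(random_sites(0, g)), 0)
  # exclusions leaving a single 1 kb window
  ex <- tibble::tibble(start = c(0, 21000), end = c(20000, 100000))
  s <- random_sites(50, g, seed = 4, exclusions = ex)
  expect_true(all(s$center >= 20000 & s$center < 21000))
  # determinism
  expect_identical(random_sites(20, g, seed = 5), random_sites(20, g, seed = 5))
  # chi-square goodness of fit on 10 bins at alpha = 0.01
  s2 <- random_sites(10000, g, seed = 6)
  counts <- tabulate(s2$center %/% 10000 + 1, 10)
  chi <- sum((counts - 1000)^2 / 1000)
  expect_lt(chi, qchisq(0.99, df = 9))
})
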