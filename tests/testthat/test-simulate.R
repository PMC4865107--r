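test_that("noise-free NorflIP rates reproduce the canonical geometry exactly", {
  exp <- canonical_experiment()
  shp <- measure_shape(exp$ip, 50000)
  expect_equal(shp$fwd_span, 170)
  expect_equal(shp$rev_span, 170)
  expect_equal(shp$gap, 130)
  expect_equal(shp$read_depletion, 100)
  # combined IP/input ratio equals fold on the blocks
  ratio <- combine_strands(exp$ip) / combine_strands(exp$input)
  expect_equal(max(ratio), 10)
  # null experiment: IP indistinguishable from input
  g <- small_genome()
  null <- plant_norflip_experiment(g, depth = 5, noise = FALSE)
  expect_equal(combine_strands(null$ip), combine_strands(null$input))
})

test_that("a non-default shape round-trips through measure_shape", {
  g <- small_genome()
  shape <- shape_params(fwd_span = 300, rev_span = 220, gap = 150,
                        read_depletion = 120)
  exp <- plant_norflip_experiment(g, planted_sites(40000, fold = 8),
                                  shape = shape, depth = 5, noise = FALSE)
  m <- measure_shape(exp$ip, 40000)
  expect_equal(m$fwd_span, 300)
  expect_equal(m$rev_span, 220)
  expect_equal(m$gap, 150)
  expect_equal(m$read_depletion, 120)
  expect_error(shape_params(gap = 50, read_depletion = 100), "gap")
  # flat profile: shape undefined
  flat <- plant_norflip_experiment(g, depth = 5, noise = FALSE)
  expect_error(measure_shape(flat$ip, 40000), "background")
})

test_that("Poisson sampling matches its rates and is seed-deterministic", {
  g <- small_genome(50000, 0, 25000)
  e1 <- plant_norflip_experiment(g, depth = 5, seed = 9)
  e2 <- plant_norflip_experiment(g, depth = 5, seed = 9)
  expect_identical(e1$ip$fwd, e2$ip$fwd)
  expect_identical(e1$input$rev, e2$input$rev)
  e3 <- plant_norflip_experiment(g, depth = 5, seed = 10)
  expect_false(identical(e1$ip$fwd, e3$ip$fwd))
  # empirical background mean within 3*sqrt(rate/N)
  n <- length(e1$ip$fwd)
  expect_lt(abs(mean(e1$ip$fwd + e1$ip$rev) - 5), 3 * sqrt(5 / n))
  # smoothed IP/input maximum lands on the planted site
  site <- plant_norflip_experiment(g, planted_sites(20000, fold = 30),
                                   depth = 5, seed = 3)
  ip_s <- smooth_circular(combine_strands(rpm_normalize(site$ip)), 200)
  in_s <- smooth_circular(combine_strands(rpm_normalize(site$input)), 200)
  peak <- which.max(ip_s / in_s) - 1
  expect_lt(abs(peak - 20000), 300)
})

test_that("close planted sites trigger a spacing warning", {
  g <- small_genome()
  expect_warning(
    plant_norflip_experiment(g, planted_sites(c(30000, 30500), fold = 5),
                             noise = FALSE),
    "closer")
})

test_that("ChIP planting is symmetric with ratio equal to fold on the span", {
  g <- small_genome()
  exp <- plant_chip_experiment(g, planted_sites(50000, fold = 10,
                                                kind = "binding"),
                               depth = 10, noise = FALSE)
  ratio <- combine_strands(exp$ip) / combine_strands(exp$input)
  on_span <- (49900:50099) + 1
  expect_equal(ratio[on_span], rep(10, 200))
  expect_equal(ratio[-on_span], rep(1, length(ratio) - 200))
  expect_equal(exp$ip$fwd, exp$ip$rev)
  # empty site list: flat ratio
  null <- plant_chip_experiment(g, depth = 10, noise = FALSE)
  expect_equal(combine_strands(null$ip) / combine_strands(null$input),
               rep(1, g$length))
})

test_that("artifacts multiply IP and mock but not input", {
  g <- small_genome()
  exp <- plant_chip_experiment(g, depth = 10, noise = FALSE)
  exp2 <- add_artifacts(exp, artifact_regions(20000, 23000, fold = 20))
  reg <- 20001:23000
  expect_equal(combine_strands(exp2$mock)[reg] /
                 combine_strands(exp2$input)[reg], rep(20, 3000))
  expect_equal(combine_strands(exp2$ip)[reg][1], 200)
  expect_equal(exp2$input$fwd, exp$input$fwd)
  expect_identical(exp2$truth, exp$truth)
  # empty region list is the identity
  expect_equal(add_artifacts(exp, artifact_regions(integer(0), integer(0)))$ip$fwd,
               exp$ip$fwd)
})

test_that("dosage tracks follow the replication state", {
  g <- small_genome()
  flat1 <- make_dosage_track(g, list(type = "sync", forks = c(g$oriC, g$oriC)))
  expect_equal(flat1, rep(1, g$length))
  ter <- (g$oriC + g$length / 2) %% g$length
  flat2 <- make_dosage_track(g, list(type = "sync", forks = c(ter, ter)))
  expect_equal(flat2, rep(2, g$length))
  # partial: values in {1,2}, transitions at the fork positions
  forks <- c((g$oriC + 20000) %% g$length, (g$oriC - 25000) %% g$length)
  d <- make_dosage_track(g, list(type = "sync", forks = forks))
  expect_setequal(unique(d), c(1, 2))
  expect_equal(sum(d == 2), 20000 + 25000)
  # async closed form: ori:ter ratio 2^(C/T)
  da <- make_dosage_track(g, list(type = "async", C = 40, T = 40))
  expect_equal(max(da) / min(da), 2, tolerance = 1e-6)
  expect_equal(da[g$oriC + 1], max(da))
  db <- make_dosage_track(g, list(type = "async", C = 40, T = 60))
  expect_equal(max(db) / min(db), 2^(40 / 60), tolerance = 1e-6)
})

test_that("synthetic annotations pack genes without overlap, reproducibly", {
  g <- small_genome(200000, 10000, 150000)
  ann <- make_annotation(g, n_genes = 120, n_tu_highly_expressed = 15,
                         seed = 3)
  genes <- ann$genes[order(ann$genes$start), ]
  expect_true(all(genes$start[-1] >= genes$end[-nrow(genes)]))
  expect_true(all(genes$end <= g$length))
  expect_gte(sum(ann$tus$expression >= 500), 15)
  expect_equal(intergenic_fraction(ann),
               1 - sum(genes$end - genes$start) / g$length)
  ann2 <- make_annotation(g, n_genes = 120, n_tu_highly_expressed = 15,
                          seed = 3)
  expect_identical(ann$genes, ann2$genes)
  expect_identical(ann$tus$expression, ann2$tus$expression)
  # no genes: intergenic fraction 1
  empty <- make_annotation(g, n_genes = 0, n_tu_highly_expressed = 0,
                           n_fis = 0, n_hns_regions = 0, seed = 1)
  expect_equal(intergenic_fraction(empty), 1)
  # infeasible packing is an error
  expect_error(make_annotation(g, n_genes = 300, mean_gene_len = 5000,
                               seed = 1), "fit")
})
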