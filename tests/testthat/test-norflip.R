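test_that("differential track is smooth(fwd) - smooth(rev)", {
  g <- small_genome(10000, 0, 5000)
  set.seed(8)
  p <- stranded_profile(rpois(10000, 4), rpois(10000, 4), g)
  d <- differential_track(p, window = 200)
  pn <- rpm_normalize(p)
  expect_equal(d, smooth_circular(pn$fwd, 200) - smooth_circular(pn$rev, 200))
  same <- stranded_profile(rep(2, 10000), rep(2, 10000), g)
  expect_equal(differential_track(same), rep(0, 10000))
  # canonical site: positive then negative lobe, zero crossing at center
  exp <- canonical_experiment()
  dc <- differential_track(exp$ip)
  expect_gt(dc[49800], 0)
  expect_lt(dc[50200], 0)
  expect_lt(abs(dc[50001]), 1e-9 * max(abs(dc)))
})

test_that("cleavage templates average site windows and self-match at r = 1", {
  g <- small_genome()
  exp <- plant_norflip_experiment(
    g, planted_sites(c(25000, 50000, 75000), fold = 10),
    depth = 5, noise = FALSE)
  d <- differential_track(exp$ip)
  t1 <- cleavage_template(d, 25000, window = 600)
  t2 <- cleavage_template(d, c(25000, 50000), window = 600)
  expect_equal(t1, t2)  # identical planted sites -> identical windows
  expect_error(cleavage_template(d, c(25000, 25200), window = 600), "overlap")
  # the averaged template correlates perfectly with the third site
  sc <- window_scan_corr <- scan_cleavage(d, t2)
  expect_true(any(abs(sc$center - 75000) <= 100 & sc$r > 0.999))
  # canonical synthetic template also self-matches planted sites
  tc <- canonical_cleavage_template()
  scc <- scan_cleavage(d, tc)
  expect_equal(nrow(scc), 3)
  expect_true(all(nearest_truth(scc$center, c(25000, 50000, 75000),
                                g$length) <= 100))
})

test_that("mirrored (reverse-lobe-first) shapes are never called", {
  g <- small_genome()
  exp <- plant_norflip_experiment(g, planted_sites(50000, fold = 10),
                                  depth = 5, noise = FALSE)
  # swap strands: the mirrored signature correlates at r <= -0.72
  flipped <- stranded_profile(exp$ip$rev, exp$ip$fwd, g)
  d <- differential_track(flipped)
  cand <- scan_cleavage(d, canonical_cleavage_template())
  expect_equal(nrow(cand), 0)
  # antisymmetry: the same sites reappear when the template is also flipped
  cand2 <- scan_cleavage(-d, canonical_cleavage_template())
  expect_true(any(abs(cand2$center - 50000) <= 100))
})

test_that("fold validation keeps true sites and drops weak or masked ones", {
  g <- small_genome()
  exp <- plant_norflip_experiment(g, planted_sites(50000, fold = 30),
                                  depth = 5, noise = FALSE)
  ip_s <- smooth_circular(combine_strands(rpm_normalize(exp$ip)), 200)
  in_s <- smooth_circular(combine_strands(rpm_normalize(exp$input)), 200)
  rt <- ratio_track(ip_s, in_s, g)
  cand <- tibble::tibble(center = c(50000, 20000), r = c(0.99, 0.8))
  v <- validate_sites(cand, rt)
  expect_equal(v$center, 50000)
  # smoothing over the 170 bp block attenuates the planted 30-fold
  expect_gt(v$fold, 0.8 * 30 * 170 / 200)
  expect_lte(v$fold, 30)
  # candidate inside a masked artifact is dropped
  rt$mask <- rep(FALSE, g$length)
  rt$mask[(49000:51000) + 1] <- TRUE
  expect_equal(nrow(validate_sites(cand, rt)), 0)
  # fold below threshold is dropped
  weak <- plant_norflip_experiment(g, planted_sites(50000, fold = 1.5),
                                   depth = 5, noise = FALSE)
  wt <- ratio_track(
    smooth_circular(combine_strands(rpm_normalize(weak$ip)), 200),
    in_s, g)
  expect_equal(nrow(validate_sites(cand, wt)), 0)
})

test_that("cleavage-point estimation is exact on noiseless canonical input", {
  exp <- canonical_experiment()
  est <- estimate_cleavage_point(exp$ip, 50000)
  expect_equal(est$center_est, 50000)
  expect_equal(est$offset, 150)
  expect_equal(est$method, "gap")
  # both estimators agree: gap center and fwd_center + (fwd_span + gap)/2
  expect_equal(est$fwd_peak_center + 150, est$center_est)
  # a symmetric binding peak has no strand offset -> flagged fallback
  g <- small_genome()
  sym <- plant_chip_experiment(g, planted_sites(50000, fold = 10,
                                                kind = "binding"),
                               depth = 10, noise = FALSE)
  est2 <- estimate_cleavage_point(sym$ip, 50000)
  expect_equal(est2$method, "zero-crossing")
})

test_that("cleavage-point error stays small under Poisson noise", {
  g <- small_genome(200000, 10000, 150000)
  errs <- vapply(1:20, function(s) {
    exp <- plant_norflip_experiment(g, planted_sites(100000, fold = 8),
                                    depth = 5, seed = s)
    est <- estimate_cleavage_point(exp$ip, 100000, raw_smooth = 40)
    abs(est$center_est - 100000)
  }, numeric(1))
  expect_lte(median(errs), 50)
})

test_that("calls are invariant to a constant background on both strands", {
  g <- small_genome(400000, 10000, 200000)
  centers <- c(100000, 250000, 330000)
  exp <- plant_norflip_experiment(g, planted_sites(centers, fold = 10),
                                  depth = 5, seed = 21)
  s1 <- call_cleavage_sites(exp$ip, exp$input)
  lifted <- stranded_profile(exp$ip$fwd + 3, exp$ip$rev + 3, g)
  d1 <- differential_track(exp$ip)
  d2 <- differential_track(lifted)
  # the differential signal is unchanged up to the RPM rescaling
  expect_equal(cor(d1, d2), 1, tolerance = 1e-6)
  cand <- scan_cleavage(d2, canonical_cleavage_template())
  expect_true(all(nearest_truth(centers, cand$center, g$length) <= 150))
})

test_that("the full caller recovers noisy planted sites with no extras", {
  fx <- noisy_norflip()
  sites <- call_cleavage_sites(fx$exp$ip, fx$exp$input, fx$exp$mock)
  d <- nearest_truth(sites$center, fx$centers, fx$genome$length)
  expect_equal(sum(d <= 250), length(fx$centers))
  expect_equal(nrow(sites), length(fx$centers))
  expect_true(all(sites$template_r >= 0.72))
  expect_true(all(sites$fold >= 2))
  # background-only genomes yield no validated calls
  g0 <- small_genome(500000, 10000, 250000)
  exp0 <- plant_norflip_experiment(g0, depth = 5, seed = 33)
  expect_equal(nrow(call_cleavage_sites(exp0$ip, exp0$input, exp0$mock)), 0)
  # an artifact region shared with mock is masked out of the calls
  expa <- plant_norflip_experiment(g0, planted_sites(250000, fold = 10),
                                   depth = 5, seed = 34)
  expa <- add_artifacts(expa, artifact_regions(100000, 103000, fold = 25))
  sa <- call_cleavage_sites(expa$ip, expa$input, expa$mock)
  expect_true(all(circ_dist(sa$center, 250000, g0$length) <= 250))
})

test_that("the data-template mode bootstraps from the strongest sites", {
  g <- small_genome(500000, 10000, 250000)
  centers <- c(100000, 250000, 400000)
  exp <- plant_norflip_experiment(g, planted_sites(centers,
                                                   fold = c(30, 20, 8)),
                                  depth = 5, seed = 12)
  sites <- call_cleavage_sites(exp$ip, exp$input, template = "data")
  expect_equal(sum(nearest_truth(sites$center, centers, g$length) <= 250), 3)
})

test_that("cross-experiment overlap counts shared and unique sites", {
  a <- c(1000, 5000, 9000)
  ov <- cross_experiment_overlap(list(a, a), tolerance = 250)
  expect_equal(ov$common_all, 3)
  expect_equal(ov$n_union, 3)
  disj <- cross_experiment_overlap(list(a, a + 2000), tolerance = 250)
  expect_equal(disj$common_all, 0)
  expect_equal(disj$n_union, 6)
  # partial sharing with three experiments
  ov3 <- cross_experiment_overlap(
    list(c(1000, 5000, 9000), c(1100, 5050, 20000), c(980, 30000)),
    tolerance = 250)
  expect_equal(ov3$common_all, 1)          # only the 1000 site is in all
  expect_equal(ov3$n_union, 5)
  expect_equal(sort(ov3$pair_counts$common), c(1, 1, 2))
  expect_error(cross_experiment_overlap(list(a)), "two")
})
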