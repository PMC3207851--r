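test_that("distortion bands have the 2.33 sigma half-width", {
  calls <- matrix(rep(c("A", "H"), each = 750), ncol = 1)
  pop <- toy_population(calls, positions = 1e6)
  prof <- distortion_profile(pop)
  expect_equal(prof$half_width, 2.33 / sqrt(4 * 1500))
  expect_equal(prof$half_width, 0.03008, tolerance = 1e-4)
  expect_false(prof$flagged)  # exactly 0.5 is inside the band
})

test_that("null flag rate matches the exact binomial exceedance of the band", {
  # independent markers drawn at the 1:1 backcross ratio; the two-sided
  # exceedance of the 2.33 s band is ~2% (computed exactly below)
  n <- 400L
  hw <- 2.33 / sqrt(4 * n)
  k_lo <- floor(n * (0.5 - hw))
  k_hi <- ceiling(n * (0.5 + hw))
  p_exact <- pbinom(k_lo, n, 0.5) + pbinom(k_hi - 1, n, 0.5,
                                           lower.tail = FALSE)
  expect_gt(p_exact, 0.01)  # the band is one-sided-1%, two-sided ~2%
  set.seed(33)
  n_markers <- 3000L
  calls <- matrix(ifelse(runif(n * n_markers) < 0.5, "A", "H"), nrow = n)
  pop <- toy_population(calls, positions = seq_len(n_markers) * 1e3)
  prof <- distortion_profile(pop)
  expect_lt(abs(sum(prof$flagged) - n_markers * p_exact),
            3 * sqrt(n_markers * p_exact * (1 - p_exact)))
})

test_that("a selected locus is flagged with the allele-ratio frequency", {
  sp <- toy_spec(L = 1.0, n_markers = 21)
  sel <- selection_model("c1", sp$marker_positions[11],
                         sp$marker_positions[21], s1 = 0.37, s2 = 1,
                         unfavored1 = "H")
  pop <- simulate_backcross(sp, 4000, gamma_model(3), selection = sel,
                            seed = 44)
  prof <- distortion_profile(pop)
  expect_true(prof$flagged[11])
  expect_equal(prof$freq[11], 1 / 1.37, tolerance = 0.02)
  fit <- estimate_single_locus_fitness(prof, prof$marker[11])
  expect_equal(fit$s, 0.37, tolerance = 0.05)
  expect_identical(fit$unfavored, "H")
})

test_that("single-locus fitness is the minor/major count ratio", {
  prof <- data.frame(chrom = "c1", marker = c("m1", "m2", "m3"),
                     pos = 1:3, N_C = c(600, 1490, 500),
                     N_L = c(1620, 1000, 500))
  expect_equal(estimate_single_locus_fitness(prof, "m1")$s, 600 / 1620)
  expect_lt(abs(estimate_single_locus_fitness(prof, "m1")$s - 0.370), 5e-3)
  expect_lt(abs(estimate_single_locus_fitness(prof, "m2")$s - 0.671), 5e-3)
  expect_identical(estimate_single_locus_fitness(prof, "m3")$s, 1)
})

test_that("16-class frequencies follow the Haldane product rule", {
  p0 <- predict_16_genotype_freqs(0.1, 0.02, 0.15)
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0["AAAA"]), 0.5 * 0.9 * 0.98 * 0.85)
  expect_equal(unname(p0["AHHA"]), 0.5 * 0.1 * 0.98 * 0.15)
  # r23 = 0: the middle markers always agree, 8 classes vanish
  pz <- predict_16_genotype_freqs(0.2, 0, 0.3)
  mid_differ <- grepl("^.AH.|^.HA.", names(pz))
  expect_true(all(pz[mid_differ] == 0))
  expect_identical(sum(pz == 0), 8L)
  # full linkage with selection: only the parental classes survive
  sel <- selection_model("c1", 1, 2, s1 = 0.67, s2 = 0.37)
  ps <- predict_16_genotype_freqs(0, 0, 0, sel)
  expect_equal(unname(ps["AAAA"]), 0.67 / 1.04)
  expect_equal(unname(ps["HHHH"]), 0.37 / 1.04)
  expect_identical(sum(ps > 0), 2L)
})

test_that("class frequencies are a simplex for random admissible parameters", {
  set.seed(55)
  for (i in 1:25) {
    r <- runif(3, 0, 0.499)
    sel <- selection_model("c1", 1, 2, s1 = runif(1, 0.05, 1),
                           s2 = runif(1, 0.05, 1),
                           unfavored1 = sample(c("A", "H"), 1),
                           unfavored2 = sample(c("A", "H"), 1))
    p <- predict_16_genotype_freqs(r[1], r[2], r[3], sel)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1)
  }
})

test_that("interval-rate fitting recovers generating rates from exact counts", {
  n <- 1e5
  counts <- n * predict_16_genotype_freqs(0.1, 0.02, 0.15)
  fit <- fit_interval_rates(counts)
  expect_lt(max(abs(fit$rates - c(0.1, 0.02, 0.15))), 1e-3)
  sel <- selection_model("c1", 1, 2, s1 = 0.67, s2 = 0.37)
  counts2 <- n * predict_16_genotype_freqs(0.2, 0.05, 0.1, sel)
  fit2 <- fit_interval_rates(counts2, sel)
  expect_lt(max(abs(fit2$rates - c(0.2, 0.05, 0.1))), 1e-3)
  expect_lt(fit2$chi2, 1e-2)  # numerically zero at the optimizer tolerance
  # perturbed counts: positive chi2, rates still near truth
  set.seed(66)
  counts3 <- rmultinom(1, 1500, predict_16_genotype_freqs(0.2, 0.05, 0.1,
                                                          sel))[, 1]
  names(counts3) <- names(counts2)
  fit3 <- fit_interval_rates(counts3, sel)
  expect_gt(fit3$chi2, 0)
  expect_lt(max(abs(fit3$rates - c(0.2, 0.05, 0.1))), 0.05)
})

test_that("joint selection fit recovers the generating coefficients", {
  sp <- toy_spec(L = 1.4, n_markers = 12, P = 28e6)
  sel <- selection_model("c1", sp$marker_positions[2],
                         sp$marker_positions[11], s1 = 0.67, s2 = 0.37,
                         unfavored1 = "A", unfavored2 = "H")
  pop <- simulate_backcross(sp, 1500, gamma_model(1), selection = sel,
                            seed = 77)
  fit <- fit_selection_coefficients(pop, "c1", sp$marker_positions[2],
                                    sp$marker_positions[11],
                                    grid_step = 0.1)
  expect_identical(fit$unfavored, c("A", "H"))
  expect_lt(abs(fit$s1 - 0.67), 0.15)
  expect_lt(abs(fit$s2 - 0.37), 0.15)
  # marginal single-locus ratios agree with the joint fit to first order
  expect_lt(abs(fit$marginal["s1"] - fit$s1), 0.25)
  expect_lt(abs(fit$marginal["s2"] - fit$s2), 0.25)
})

test_that("correction is exactly the identity without selection", {
  sp <- toy_spec(L = 0.9, n_markers = 10)
  pop <- simulate_backcross(sp, 600, gamma_model(2), seed = 88)
  fit <- fit_selection_coefficients(pop, "c1", sp$marker_positions[3],
                                    sp$marker_positions[8],
                                    grid_step = 0.25, unfavored = c("A", "H"))
  # truth is s = (1, 1); fitted coefficients drift to the no-selection corner
  expect_gt(fit$s1, 0.8)
  expect_gt(fit$s2, 0.8)
  corr <- corrected_map_length(pop, "c1", fit)
  expect_lt(abs(corr$corrected_L_G - corr$naive_L_G) / corr$naive_L_G, 0.05)
  # intervals outside (L1, L2) keep byte-identical naive estimates
  out <- corr$table$left_bp < sp$marker_positions[3] |
    corr$table$left_bp >= sp$marker_positions[8]
  expect_identical(corr$table$r_corrected[out], corr$table$r[out])
})

test_that("two-locus correction removes the inter-locus length inflation", {
  # under opposite-parent selection the naive inter-locus genetic length is
  # inflated (analytically ~ +2.4% for this geometry); the corrected
  # estimate should track the truth more closely on average
  sp <- toy_spec(L = 1.4, n_markers = 10, P = 28e6)
  sel <- selection_model("c1", sp$marker_positions[2],
                         sp$marker_positions[9], s1 = 0.67, s2 = 0.37,
                         unfavored1 = "A", unfavored2 = "H")
  true_between <- 1.4 * 7 / 9  # genetic span between the selected loci
  err_naive <- err_fixed <- numeric(6)
  for (s in 1:6) {
    pop <- simulate_backcross(sp, 2500, gamma_model(1), selection = sel,
                              seed = 900 + s)
    fit <- fit_selection_coefficients(pop, "c1", sp$marker_positions[2],
                                      sp$marker_positions[9],
                                      grid_step = 0.25)
    corr <- corrected_map_length(pop, "c1", fit)
    between <- corr$table$left_bp >= sp$marker_positions[2] &
      corr$table$right_bp <= sp$marker_positions[9]
    err_naive[s] <- sum(corr$table$d_M[between]) - true_between
    err_fixed[s] <- sum(corr$table$d_M_corrected[between]) - true_between
  }
  expect_lt(mean(abs(err_fixed)), mean(abs(err_naive)))
  expect_gt(mean(err_naive), 0)  # the naive inflation is real
})
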