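test_that("recombination fractions count informative plants only", {
  # 100 informative plants, 10 recombinant; one plant missing on the right
  calls <- cbind(rep("A", 101),
                 c(rep("H", 10), rep("A", 90), "H"))
  calls[101, 2] <- NA
  pop <- toy_population(calls)
  est <- interval_recomb_fraction(pop, "c1", 1)
  expect_identical(est$N, 100L)
  expect_identical(est$N_r, 10L)
  expect_equal(est$r, 0.1)
  expect_equal(est$r_hi - est$r, 1.96 * sqrt(0.1 * 0.9 / 100))
  expect_equal(est$r_hi - est$r, 0.0588, tolerance = 1e-3)
  # zero recombinants: lower bound clamped at 0
  pop0 <- toy_population(cbind(rep("A", 50), rep("A", 50)))
  est0 <- interval_recomb_fraction(pop0, "c1", 1)
  expect_identical(est0$r, 0)
  expect_identical(est0$r_lo, 0)
})

test_that("Haldane map function matches its closed form", {
  expect_identical(haldane_distance(0), 0)
  expect_lt(abs(haldane_distance(0.0906346) - 0.1), 1e-6)
  expect_lt(abs(haldane_distance(0.01) - 0.0101014), 1e-6)
  expect_error(haldane_distance(0.5), "0.5")
})

test_that("interval-sum length matches closed form and recovers the truth", {
  # single interval with r = 0.1
  calls <- cbind(rep("A", 100), c(rep("H", 10), rep("A", 90)))
  pop <- toy_population(calls)
  L <- chromosome_length_interval_sum(pop, "c1")
  expect_equal(L$L_G, -0.5 * log(0.8))
  expect_lt(abs(L$L_G - 0.111572), 1e-6)
  # unbiased at nu = 1 (Haldane's double-CO adjustment is then exact, up
  # to the O(L/n) convexity term); under interference the adjustment
  # overshoots by at most its own magnitude, ~ sum of r_i^2
  sp <- toy_spec(L = 0.8, n_markers = 41)
  allow <- c("1" = 0.8 / 250, "3" = 0.8 / 250 + 40 * (0.8 / 40)^2)
  for (nu in c(1, 3)) {
    ests <- vapply(1:40, function(s) {
      p <- simulate_backcross(sp, 250, gamma_model(nu), seed = 7000 + s)
      chromosome_length_interval_sum(p, "c1")$L_G
    }, 0)
    expect_lt(abs(mean(ests) - 0.8),
              2 * sd(ests) / sqrt(40) + allow[[as.character(nu)]])
  }
})

test_that("switch counting is transparent to missing data", {
  pop <- toy_population(rbind(c("A", "A", NA, "H", "H")))
  expect_equal(chromosome_length_switch_count(pop, "c1")$L_G, 1)
  # every plant exactly one switch: length 1 Morgan, variance 0
  pop2 <- toy_population(matrix(c("A", "A", "H", "H", "H"), 20, 5,
                                byrow = TRUE))
  L2 <- chromosome_length_switch_count(pop2, "c1")
  expect_identical(L2$L_G, 1)
  expect_identical(L2$variance, 0)
  # a CO bracketing a missing call is seen by switch counting but falls in
  # no informative interval of the interval-sum estimator
  calls <- matrix("A", 10, 3)
  calls[1, ] <- c("A", NA, "H")
  pop3 <- toy_population(calls)
  expect_equal(chromosome_length_switch_count(pop3, "c1")$L_G, 0.1)
  expect_identical(chromosome_length_interval_sum(pop3, "c1")$L_G, 0)
})

test_that("the two length estimators agree to within the Haldane correction", {
  sp <- toy_spec(L = 0.9, n_markers = 45)
  for (s in 1:10) {
    pop <- simulate_backcross(sp, 300, gamma_model(3), missing_rate = 0.02,
                              seed = 100 + s)
    tab <- interval_table(pop, "c1")
    sw <- chromosome_length_switch_count(pop, "c1")$L_G
    is <- chromosome_length_interval_sum(pop, "c1")$L_G
    # Haldane inflation is at most sum of r^2-order terms
    bound <- sum(-0.5 * log(1 - 2 * tab$r) - tab$r) + 0.02 * is
    expect_lt(abs(sw - is), bound + 0.02)
  }
})

test_that("male/female ratio confidence intervals follow the relative-variance sum", {
  Lm <- list(L_G = 2, variance = 0.1^2)
  Lf <- list(L_G = 1, variance = 0.1^2)
  r <- mf_ratio_ci(Lm, Lf)
  expect_equal(r$f, 2)
  expect_equal(r$ci95, 2 + c(-1, 1) * 1.96 * 2 * sqrt(0.0025 + 0.01),
               tolerance = 1e-10)
  expect_equal(r$ci95, c(1.56, 2.44), tolerance = 0.01)
  ident <- mf_ratio_ci(Lm, Lm)
  expect_equal(ident$f, 1)
  expect_equal(mean(ident$ci95), 1)
})

test_that("truncation removes end intervals and shortens the map accordingly", {
  sp <- toy_spec(L = 1.0, n_markers = 51)
  pop <- simulate_backcross(sp, 800, gamma_model(1), seed = 21)
  t0 <- truncate_chromosome(pop, "c1", 0)
  expect_identical(t0$pop$geno, pop$geno)
  tr <- truncate_chromosome(pop, "c1", 0.30)
  expect_identical(tr$removed_markers, 16L)   # 8 markers per 15% end
  L_tr <- chromosome_length_switch_count(tr$pop, "c1")
  expect_lt(abs(L_tr$L_G - 0.7), 4 * sqrt(L_tr$variance))
})

test_that("truncating an end-loaded male map shrinks the M/F ratio", {
  P <- 20e6
  # male map holds 35% of its genetic length in each terminal 15%
  male_map <- cbind(c(1, 0.15 * P, 0.85 * P, P), c(0, 0.42, 0.78, 1.2))
  sp_m <- toy_spec(L = 1.2, n_markers = 51, genetic_map = male_map)
  sp_f <- toy_spec(L = 0.7, n_markers = 51)
  wins <- 0L
  for (s in 1:8) {
    pm <- simulate_backcross(sp_m, 400, gamma_model(3), seed = 300 + s)
    pf <- simulate_backcross(sp_f, 400, gamma_model(3), seed = 400 + s)
    full <- chromosome_length_switch_count(pm, "c1")$L_G /
      chromosome_length_switch_count(pf, "c1")$L_G
    tm <- truncate_chromosome(pm, "c1", 0.30)$pop
    tf <- truncate_chromosome(pf, "c1", 0.30)$pop
    trunc <- chromosome_length_switch_count(tm, "c1")$L_G /
      chromosome_length_switch_count(tf, "c1")$L_G
    if (trunc < full) wins <- wins + 1L
  }
  expect_gte(wins, 7L)  # one-sided sign test, p < 0.04
})

test_that("truncation losses are class-independent without interference", {
  sp <- toy_spec(L = 1.0, n_markers = 51)
  pop <- simulate_backcross(sp, 4000, gamma_model(1), seed = 23)
  lt <- truncation_loss_table(pop, "c1", 0.30)
  expect_identical(lt$class, c("1", "2+"))
  expect_lt(max(abs(lt$observed_loss - lt$expected_loss)), 0.05)
  # no truncation: zero losses
  lt0 <- truncation_loss_table(pop, "c1", 0)
  expect_equal(lt0$observed_loss, c(0, 0))
})

test_that("interference makes multi-CO plants lose more under truncation", {
  sp <- toy_spec(L = 1.0, n_markers = 51)
  wins <- 0L
  for (s in 1:10) {
    pop <- simulate_backcross(sp, 1200, gamma_model(3), seed = 500 + s)
    lt <- truncation_loss_table(pop, "c1", 0.30)
    d <- lt$observed_loss - lt$expected_loss
    if (d[lt$class == "2+"] > d[lt$class == "1"]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("length equality test behaves like Welch's t-test", {
  x <- c(0, 1, 1, 2, 0, 1)
  expect_equal(compare_lengths_ttest(x, x), 1)
  y <- c(1, 2, 0, 1, 1, 1)
  expect_equal(compare_lengths_ttest(x, y), compare_lengths_ttest(y, x))
  # map lengths 142 cM vs 81 cM at n = 1500: overwhelming evidence
  sp_m <- toy_spec(L = 1.42, n_markers = 41)
  sp_f <- toy_spec(L = 0.81, n_markers = 41)
  pm <- simulate_backcross(sp_m, 1500, gamma_model(3), seed = 61)
  pf <- simulate_backcross(sp_f, 1500, gamma_model(3), seed = 62)
  p <- compare_lengths_ttest(chromosome_length_switch_count(pm, "c1")$counts,
                             chromosome_length_switch_count(pf, "c1")$counts)
  expect_lt(p, 1e-8)
})

test_that("CO-count classes partition the plants", {
  pop <- toy_population(rbind(
    c("A", "A", "A", "A"),
    c("A", "H", "A", "A"),   # 2 switches
    c("A", "H", "H", "H"),   # 1
    c("H", "A", "H", "A"),   # 3
    c("A", "A", "H", "H")))  # 1
  cls <- co_count_distribution(pop, "c1")
  expect_identical(cls, c("0" = 1L, "1" = 2L, "2" = 1L, "3+" = 1L))
  expect_identical(sum(cls), 5L)
  # all-parental matrix: everything in class 0
  pop0 <- toy_population(matrix("A", 7, 4))
  expect_identical(co_count_distribution(pop0, "c1")[["0"]], 7L)
})
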