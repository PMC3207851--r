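test_that("model constructors validate their invariants", {
  expect_error(gamma_model(nu = -1), "positive")
  expect_error(gamma_model(nu = 2, bivalent_rate = 3), "fixed")
  expect_error(gamma_model(nu = 2, thinning_p = 0.3), "fixed")
  expect_error(chromosome_spec("c1", -1, 1e6, c(1, 10)), "positive")
  expect_error(toy_spec(n_markers = 3, P = 1e6,
                        genetic_map = cbind(c(1, 2), c(0.2, 0.1))),
               "monotone")
  expect_error(selection_model("c1", 10, 5, 0.5, 0.5), "locus1")
  expect_error(selection_model("c1", 5, 10, 0, 0.5), "\\(0, 1\\]")
})

test_that("bivalent CO counts are stationary with mean 2 per Morgan", {
  set.seed(41)
  for (nu in c(1, 2.6)) {
    L <- 1.4236
    biv <- simulate_bivalent_crossovers(L, gamma_model(nu), n = 40000)
    k <- lengths(biv)
    # expected count 2 L by stationarity, any nu
    expect_lt(abs(mean(k) - 2 * L), 3 * sd(k) / sqrt(length(k)))
    # stationarity on a sub-segment too
    sub <- vapply(biv, function(x) sum(x > 0.3 & x <= 0.9), 0L)
    expect_lt(abs(mean(sub) - 2 * 0.6), 3 * sd(sub) / sqrt(length(sub)))
  }
})

test_that("nu = 1 reduces to a Poisson process and larger nu shrinks variance", {
  set.seed(42)
  biv1 <- simulate_bivalent_crossovers(1.0, gamma_model(1), n = 50000)
  k1 <- lengths(biv1)
  # chi-squared GOF of counts against Poisson(2)
  classes <- pmin(k1, 6L)
  p <- c(dpois(0:5, 2), ppois(5, 2, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(tabulate(classes + 1L, 7L), p = p))
  expect_gt(gof$p.value, 0.001)
  k5 <- lengths(simulate_bivalent_crossovers(1.0, gamma_model(5), n = 50000))
  expect_lt(var(k5), var(k1))
})

test_that("thinning retains each CO with probability 1/2 preserving order", {
  expect_identical(thin_to_gamete(numeric(0)), numeric(0))
  set.seed(7)
  kept <- thin_to_gamete(replicate(20000, sort(runif(8)), simplify = FALSE))
  expect_true(all(vapply(kept, function(x) !is.unsorted(x), TRUE)))
  n_kept <- lengths(kept)
  # retained count ~ Binomial(8, 1/2): chi-squared GOF
  p <- dbinom(0:8, 8, 0.5)
  gof <- suppressWarnings(chisq.test(tabulate(n_kept + 1L, 9L), p = p))
  expect_gt(gof$p.value, 0.001)
  # mean gamete CO count equals genetic length in Morgans
  set.seed(8)
  gam <- thin_to_gamete(simulate_bivalent_crossovers(1.0, gamma_model(2),
                                                     n = 40000))
  m <- lengths(gam)
  expect_lt(abs(mean(m) - 1.0), 3 * sd(m) / sqrt(length(m)))
})

test_that("gamete genotyping flips alleles exactly at crossovers", {
  sp <- toy_spec(L = 1, n_markers = 10)
  g <- sp$genetic_map(sp$marker_positions)
  expect_identical(genotype_gamete(numeric(0), sp, "A"), rep("A", 10))
  expect_identical(genotype_gamete(numeric(0), sp, "H"), rep("H", 10))
  # one CO between markers 3 and 4
  co <- mean(g[3:4])
  calls <- genotype_gamete(co, sp, "A")
  expect_identical(calls, c(rep("A", 3), rep("H", 7)))
  # two COs inside the same interval: even parity, invisible
  co2 <- g[5] + diff(g[5:6]) * c(0.3, 0.6)
  expect_identical(genotype_gamete(co2, sp, "A"), rep("A", 10))
  expect_error(genotype_gamete(1.5, sp, "A"), "outside")
})

test_that("gametic selection filters by haplotype weight and is the identity at s = 1", {
  sp <- toy_spec(L = 0.6, n_markers = 11)
  pop <- simulate_backcross(sp, 300, gamma_model(2), seed = 5)
  sel1 <- selection_model("c1", pop$markers$pos[2], pop$markers$pos[9], 1, 1)
  expect_identical(apply_gametic_selection(pop, sel1, seed = 1)$geno, pop$geno)

  # single-locus selection at s = 0.37: surviving allele ratio 2.70 : 1
  pop2 <- simulate_backcross(sp, 40000, gamma_model(2), seed = 6)
  sel2 <- selection_model("c1", pop2$markers$pos[6], pop2$markers$pos[11],
                          s1 = 0.37, s2 = 1, unfavored1 = "H")
  kept <- apply_gametic_selection(pop2, sel2, seed = 2)
  a <- kept$geno[, 6]
  ratio <- sum(a == "A") / sum(a == "H")
  se <- 2.70 * sqrt(1 / sum(a == "A") + 1 / sum(a == "H"))
  expect_lt(abs(ratio - 2.70), 3 * se)
})

test_that("single-locus selection leaves recombination fractions unbiased", {
  # the two-marker argument: selection rescales recombinants and
  # non-recombinants by the same factor (1 + s) / 2
  sp <- toy_spec(L = 0.4, n_markers = 5)
  pop <- simulate_backcross(sp, 1e5, gamma_model(1),
                            selection = selection_model(
                              "c1", sp$marker_positions[3],
                              sp$marker_positions[5], s1 = 0.3, s2 = 1,
                              unfavored1 = "A"),
                            seed = 9)
  tab <- interval_table(pop, "c1")
  r_true <- 0.5 * (1 - exp(-2 * 0.1))  # Haldane for a 0.1 M interval
  for (i in seq_len(4))
    expect_lt(abs(tab$r[i] - r_true), 3 * tab$se[i])
})

test_that("missing/error injection degrades at the stated rates", {
  g <- matrix(sample(c("A", "H"), 4e5, replace = TRUE), 1000)
  expect_identical(inject_missing_and_errors(g, 0, 0), g)
  set.seed(3)
  d <- inject_missing_and_errors(g, missing_rate = 0.02, error_rate = 0)
  p_hat <- mean(is.na(d))
  expect_lt(abs(p_hat - 0.02), 3 * sqrt(0.02 * 0.98 / length(g)))
  d2 <- inject_missing_and_errors(g, 0, error_rate = 0.01)
  flip <- mean(d2 != g)
  expect_lt(abs(flip - 0.01), 3 * sqrt(0.01 * 0.99 / length(g)))
})

test_that("selection with s1 = s2 = 1 commutes with population simulation", {
  sp <- toy_spec(L = 0.8, n_markers = 21)
  sel <- selection_model("c1", sp$marker_positions[5],
                         sp$marker_positions[15], 1, 1)
  p0 <- simulate_backcross(sp, 120, gamma_model(3), seed = 31)
  p1 <- simulate_backcross(sp, 120, gamma_model(3), selection = sel,
                           seed = 31)
  expect_identical(p0$geno, p1$geno)
})

test_that("feature tracks carry the built-in arm gradients", {
  sp <- toy_spec(L = 1, n_markers = 61, cen = c(9e6, 11e6))
  tr <- generate_feature_tracks(sp, seed = 12)
  f <- tr$features
  for (arm in list(f$midpoint < 9e6, f$midpoint > 11e6)) {
    d <- abs(f$midpoint[arm] - 10e6)
    expect_gt(cor(f$gc[arm], d), 0)
    expect_gt(cor(f$gene[arm], d), 0)
    expect_lt(cor(f$te[arm], d), 0)
  }
  # centromeric 2 kb windows have low euchromatin presence
  w <- tr$windows
  in_cen <- (w$start + w$end) / 2 >= 9e6 & (w$start + w$end) / 2 <= 11e6
  expect_lt(mean(w$presence[in_cen]), 0.2)
  # CpG has no positional trend: association rarely significant
  set.seed(13)
  n_sig <- 0L
  for (s in 1:30) {
    tr_s <- generate_feature_tracks(sp, seed = 1000 + s)
    f_s <- tr_s$features
    arm <- f_s$midpoint > 11e6
    ct <- cor.test(f_s$cpg[arm], abs(f_s$midpoint[arm] - 11e6))
    if (ct$p.value < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 3L)  # >= 90% of seeds non-significant
})
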