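#' Poisson expectations for gametic crossover counts
#'
#' Under no interference, gametic CO counts on a chromosome of genetic length
#' `lambda` Morgans are Poisson(`lambda`).  Returns the class probabilities
#' for 0, 1, 2, 3+ COs, the expected plant counts, and the probability of
#' more than one CO, `P(>=2) = 1 - exp(-lambda) (1 + lambda)`.
#'
#' @param lambda Mean gametic CO count (the genetic length in Morgans).
#' @param n_plants Number of plants (scales the expected counts).
#' @return List: `probs` (named, classes `0`,`1`,`2`,`3+`), `expected`,
#'   `p_ge2`.
#' @export
poisson_expectation <- function(lambda, n_plants = 1) {
  if (lambda < 0) stop("'lambda' must be non-negative")
  p <- c("0" = stats::dpois(0, lambda), "1" = stats::dpois(1, lambda),
         "2" = stats::dpois(2, lambda))
  p <- c(p, "3+" = max(0, 1 - sum(p)))
  list(probs = p, expected = n_plants * p,
       p_ge2 = 1 - exp(-lambda) * (1 + lambda))
}

#' Chi-squared goodness-of-fit test against a Poisson CO-count law
#'
#' Pearson chi-squared of observed CO-count class frequencies (0, 1, 2, 3+)
#' against Poisson(`lambda`) expectations, with `lambda` estimated from the
#' data (one parameter), so the degrees of freedom are `classes - 2`.  Tail
#' classes are pooled until every expected count is at least 5.
#'
#' @param observed Named class counts as from [co_count_distribution()].
#' @param lambda Poisson mean (the measured mean CO count).
#' @return List of class `poisson_gof`: `chi2`, `df`, `p_value`, the pooled
#'   `observed` and `expected` vectors.
#' @export
poisson_gof_test <- function(observed, lambda) {
  n <- sum(observed)
  exp_p <- poisson_expectation(lambda, n)$expected
  obs <- as.numeric(observed)
  expd <- as.numeric(exp_p)
  labs <- names(exp_p)
  while (length(expd) > 2L && expd[length(expd)] < 5) {
    k <- length(expd)
    expd[k - 1L] <- expd[k - 1L] + expd[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    labs[k - 1L] <- paste0(sub("\\+$", "", labs[k - 1L]), "+")
    expd <- expd[-k]; obs <- obs[-k]; labs <- labs[-k]
  }
  chi2 <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 2L
  p <- if (df >= 1L) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  structure(list(chi2 = chi2, df = df, p_value = p,
                 observed = stats::setNames(obs, labs),
                 expected = stats::setNames(expd, labs), lambda = lambda),
            class = "poisson_gof")
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf("Poisson GOF: chi2 = %.3g on %d df, p = %.3g (lambda = %.3f)\n",
              x$chi2, x$df, x$p_value, x$lambda))
  invisible(x)
}

#' Marker positions in genetic coordinates
#'
#' Cumulative Haldane distances along the chromosome's adjacent-marker
#' intervals, starting at 0 for the first marker.  This is the coordinate
#' system in which the gamma interference model is fitted.
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @return Numeric vector of marker positions in Morgans (named by marker).
#' @export
marker_genetic_positions <- function(pop, chrom) {
  tab <- interval_table(pop, chrom)
  if (any(is.na(tab$d_M))) stop("undefined interval distance on ", chrom)
  mk <- pop$markers[pop$markers$chrom == chrom, ]
  stats::setNames(c(0, cumsum(tab$d_M)), mk$name)
}

#' Localize gametic crossovers from genotype switches
#'
#' Each A/H switch along a plant's non-missing call sequence is one CO,
#' placed within its bracketing non-missing marker pair in genetic
#' coordinates: at the interval midpoint (`placement = "midpoint"`) or
#' uniformly at random within the interval (`placement = "uniform"`, the
#' default; uniform placement is the exact conditional law of a single CO
#' under no interference and removes the artificial gap floor that midpoints
#' impose on nearby COs).  A switch across a run of missing calls gets the
#' flanking informative markers as its bracket.  Plants with fewer than two
#' non-missing calls are dropped.
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @param genetic_positions Optional marker positions in Morgans (defaults to
#'   [marker_genetic_positions()]).
#' @param placement `"uniform"` (stochastic, seeded by the caller) or
#'   `"midpoint"`.
#' @return List: `co_lists` (per plant, sorted CO positions in Morgans),
#'   `L` (map length in Morgans), `genetic_positions`, `mean_spacing`.
#' @export
infer_gamete_co_positions <- function(pop, chrom, genetic_positions = NULL,
                                      placement = c("uniform", "midpoint")) {
  placement <- match.arg(placement)
  if (is.null(genetic_positions))
    genetic_positions <- marker_genetic_positions(pop, chrom)
  mk <- pop$markers[pop$markers$chrom == chrom, ]
  g <- pop$geno[, mk$name, drop = FALSE]
  gp <- as.numeric(genetic_positions)
  co_lists <- apply(g, 1L, function(v) {
    idx <- which(!is.na(v))
    if (length(idx) < 2L) return(NULL)
    a <- v[idx]
    sw <- which(a[-1L] != a[-length(a)])
    lo <- gp[idx[sw]]
    hi <- gp[idx[sw + 1L]]
    if (placement == "midpoint") (lo + hi) / 2
    else sort(stats::runif(length(sw), lo, hi))
  }, simplify = FALSE)
  co_lists <- co_lists[!vapply(co_lists, is.null, TRUE)]
  list(co_lists = co_lists, L = gp[length(gp)] - gp[1L],
       genetic_positions = genetic_positions,
       mean_spacing = (gp[length(gp)] - gp[1L]) / (length(gp) - 1L))
}

## ---- thinned stationary gamma renewal likelihood --------------------------

# geometric mixture weights for the retained-gap distribution: a retained
# gap spans j >= 1 bivalent gaps with probability p (1-p)^(j-1); terms are
# kept until the geometric tail falls below 1e-12 (J = 40 at p = 0.5)
.thin_weights <- function(p = 0.5, tol = 1e-12) {
  J <- ceiling(log(tol) / log(1 - p))
  p * (1 - p)^(seq_len(J) - 1)
}

# density of the retained (gametic) inter-CO distance:
# g(x) = sum_j w_j Gamma(x; j nu, 2 nu); mean 1 Morgan at p = 0.5
.g_dens <- function(x, nu, w) {
  b <- 2 * nu
  m <- vapply(seq_along(w), function(j)
    stats::dgamma(x, shape = j * nu, rate = b), numeric(length(x)))
  as.numeric(matrix(m, ncol = length(w)) %*% w)
}

# survival of the retained gap
.g_surv <- function(x, nu, w) {
  b <- 2 * nu
  m <- vapply(seq_along(w), function(j)
    stats::pgamma(x, shape = j * nu, rate = b, lower.tail = FALSE),
    numeric(length(x)))
  as.numeric(matrix(m, ncol = length(w)) %*% w)
}

# CDF of the retained gap
.g_cdf <- function(x, nu, w) {
  b <- 2 * nu
  m <- vapply(seq_along(w), function(j)
    stats::pgamma(x, shape = j * nu, rate = b), numeric(length(x)))
  as.numeric(matrix(m, ncol = length(w)) %*% w)
}

# int_0^L S(t) dt for a w-weighted mixture of Gamma(j nu, 2 nu); closed form
# int_0^L S_Gamma(t; a, b) dt = L S(L; a, b) + (a/b) F(L; a+1, b)
.mix_surv_integral <- function(L, nu, w) {
  b <- 2 * nu
  terms <- vapply(seq_along(w), function(j) {
    a <- j * nu
    L * stats::pgamma(L, shape = a, rate = b, lower.tail = FALSE) +
      (a / b) * stats::pgamma(L, shape = a + 1, rate = b)
  }, numeric(length(L)))
  as.numeric(matrix(terms, ncol = length(w)) %*% w)
}

.g_surv_integral <- function(L, nu, w) .mix_surv_integral(L, nu, w)

# weights of the two-gap convolution g*g: mixture of Gamma(m nu, 2 nu),
# m = 2 .. 2J, with coefficients sum_{j+k=m} w_j w_k
.gg_weights <- function(w) {
  c(0, stats::convolve(w, rev(w), type = "open"))
}

.gg_dens <- function(x, nu, w2) {
  b <- 2 * nu
  m <- vapply(seq_along(w2), function(j)
    stats::dgamma(x, shape = j * nu, rate = b), numeric(length(x)))
  as.numeric(matrix(m, ncol = length(w2)) %*% w2)
}

.gg_cdf <- function(x, nu, w2) {
  b <- 2 * nu
  m <- vapply(seq_along(w2), function(j)
    stats::pgamma(x, shape = j * nu, rate = b), numeric(length(x)))
  as.numeric(matrix(m, ncol = length(w2)) %*% w2)
}

#' Log-likelihood of gametic crossover positions under the thinned gamma model
#'
#' The bivalent CO process is a stationary gamma renewal process with gaps
#' Gamma(`nu`, `2 nu`); thinning each CO with probability 1/2 makes the
#' gametic process a stationary renewal process whose gap density is the
#' geometric mixture `g(x) = sum_j (1/2)^j Gamma(x; j nu, 2 nu)` with mean 1
#' Morgan.  For a gamete with ordered COs `x_1 < ... < x_k` on `[0, L]` the
#' likelihood is `h(x_1) prod g(gaps) S_g(L - x_k)`, where
#' `h(x) = S_g(x) / 1` is the stationary first-event density and `S_g` the
#' gap survival; a gamete without COs contributes the equilibrium survival
#' `1 - int_0^L S_g(t) dt` (closed form in regularized incomplete gamma
#' functions).  The mixture is truncated when the geometric tail drops below
#' 1e-12 (40 terms).
#'
#' When CO positions come from marker data, a pair of COs falling in the
#' same marker interval is invisible (the genotype parity does not change).
#' With `censor_spacing` set to the marker spacing in Morgans, the
#' likelihood includes the first-order correction for these hidden pairs:
#' each gamete's likelihood gains the summed probability of one unobserved
#' tight CO pair anywhere along the chromosome, integrated in closed form
#' over the pair's location (interior gaps use the two-gap convolution
#' `g*g`, the flanking and zero-CO segments the matching survival
#' integrals).  The correction vanishes as interference strengthens or
#' markers densify, and restores near-unbiasedness of the MLE at weak
#' interference where tight pairs are non-negligible.
#'
#' @param co_lists List of per-gamete CO position vectors (Morgans, sorted,
#'   within `[0, L]`); empty vectors are zero-CO gametes.
#' @param L Chromosome genetic length in Morgans.
#' @param nu Gamma shape parameter, > 0.
#' @param censor_spacing Marker spacing in Morgans for the hidden-pair
#'   censoring correction; `NULL` (default) for exactly observed positions.
#' @return The total log-likelihood (sum over gametes).
#' @export
thinned_gamma_loglik <- function(co_lists, L, nu, censor_spacing = NULL) {
  if (!is.numeric(nu) || nu <= 0) stop("'nu' must be positive")
  if (!is.numeric(L) || L <= 0) stop("'L' must be positive")
  lens <- lengths(co_lists)
  allpos <- unlist(co_lists, use.names = FALSE)
  if (length(allpos) && (min(allpos) < -1e-9 || max(allpos) > L + 1e-9))
    stop("CO positions must lie within [0, L]")
  w <- .thin_weights()
  correct <- !is.null(censor_spacing) && censor_spacing > 0
  if (correct) {
    w2 <- .gg_weights(w)
    # mean probability that the partner of a CO falls in the same marker
    # interval: (1/D) int_0^D F_g(s) ds = 1 - I_g(D)/D
    D <- censor_spacing
    pbar <- 1 - .mix_surv_integral(D, nu, w) / D
  }
  ll <- 0
  n0 <- sum(lens == 0L)
  if (n0 > 0) {
    I_L <- .mix_surv_integral(L, nu, w)
    s_eq <- max(1 - I_L, 1e-300)
    ll <- ll + n0 * log(s_eq)
    if (correct) {
      # int_0^L S_g(t) S_g(L - t) dt = 2 I_g(L) - I_gg(L)
      J2 <- 2 * I_L - .mix_surv_integral(L, nu, w2)
      ll <- ll + n0 * log1p(pbar * J2 / s_eq)
    }
  }
  has <- which(lens > 0L)
  if (length(has)) {
    firsts <- vapply(co_lists[has], function(x) x[1L], 0)
    lasts <- vapply(co_lists[has], function(x) x[length(x)], 0)
    gaps <- unlist(lapply(co_lists[has], function(x)
      if (length(x) > 1L) diff(x) else numeric(0)), use.names = FALSE)
    s_first <- pmax(.g_surv(firsts, nu, w), 1e-300)
    s_last <- pmax(.g_surv(L - lasts, nu, w), 1e-300)
    g_gaps <- pmax(.g_dens(gaps, nu, w), 1e-300)
    ll <- ll + sum(log(s_first)) + sum(log(s_last)) + sum(log(g_gaps))
    if (correct) {
      # per-gamete summed likelihood ratio of one hidden pair:
      # flanks: int_0^x S_g(t) g(x-t) dt = F_g(x) - F_gg(x), over S_g(x);
      # interior gaps: (g*g)(G) over g(G)
      r_first <- (.g_cdf(firsts, nu, w) - .gg_cdf(firsts, nu, w2)) / s_first
      r_last <- (.g_cdf(L - lasts, nu, w) - .gg_cdf(L - lasts, nu, w2)) /
        s_last
      r_gaps <- .gg_dens(gaps, nu, w2) / g_gaps
      gam_of_gap <- rep.int(seq_along(has), pmax(lens[has] - 1L, 0L))
      r_tot <- r_first + r_last
      if (length(gaps))
        r_tot <- r_tot + as.numeric(
          tapply(r_gaps, factor(gam_of_gap, levels = seq_along(has)), sum,
                 default = 0))
      ll <- ll + sum(log1p(pbar * r_tot))
    }
  }
  ll
}

#' Maximum-likelihood estimate of the interference parameter nu
#'
#' Maximizes [thinned_gamma_loglik()] over `nu` in `[0.05, 50]` (1-D bounded
#' search on `log nu`) and builds a 95% profile-likelihood confidence
#' interval, `{nu : loglik(nu) >= max - 1.92}` (the chi-squared(1) cutoff).
#' `nu = 1` is the no-interference (Poisson) null; the counting-model
#' equivalent is `m = nu - 1`.
#'
#' @param co_lists Per-gamete CO position lists (see
#'   [infer_gamete_co_positions()]).
#' @param L Chromosome genetic length in Morgans.
#' @param censor_spacing Marker spacing in Morgans enabling the hidden-pair
#'   censoring correction of [thinned_gamma_loglik()]; `NULL` for exactly
#'   observed positions.
#' @return Object of class `interference_fit`: `nu`, `ci95`, `loglik`,
#'   `m_equivalent`, `n_gametes`, `n_cos`, `L`.
#' @param ci Compute the profile-likelihood interval (default `TRUE`).
#' @export
fit_nu <- function(co_lists, L, censor_spacing = NULL, ci = TRUE) {
  n_cos <- sum(lengths(co_lists))
  if (n_cos < 2L)
    stop("fewer than 2 COs in the data; interference is not estimable")
  lo <- 0.05; hi <- 50
  f <- function(lnu) thinned_gamma_loglik(co_lists, L, exp(lnu),
                                          censor_spacing)
  opt <- stats::optimize(f, c(log(lo), log(hi)), maximum = TRUE,
                         tol = 1e-6)
  nu_hat <- exp(opt$maximum)
  ll_max <- opt$objective
  ci_lo <- ci_hi <- NA_real_
  if (ci) {
    cut <- ll_max - stats::qchisq(0.95, 1) / 2
    g <- function(nu) thinned_gamma_loglik(co_lists, L, nu, censor_spacing) -
      cut
    ci_lo <- if (g(lo) < 0)
      stats::uniroot(g, c(lo, nu_hat), tol = 1e-5)$root else lo
    ci_hi <- if (g(hi) < 0)
      stats::uniroot(g, c(nu_hat, hi), tol = 1e-5)$root else hi
  }
  structure(list(nu = nu_hat, ci95 = c(ci_lo, ci_hi), loglik = ll_max,
                 m_equivalent = nu_hat - 1,
                 n_gametes = length(co_lists), n_cos = n_cos, L = L),
            class = "interference_fit")
}

#' @rdname fit_nu
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @param censoring Apply the hidden-pair correction at the chromosome's
#'   mean marker spacing (default `TRUE`).
#' @export
fit_nu_chromosome <- function(pop, chrom, censoring = TRUE) {
  inf <- infer_gamete_co_positions(pop, chrom)
  n_mark <- sum(pop$markers$chrom == chrom)
  spacing <- if (censoring) inf$L / (n_mark - 1L) else NULL
  fit <- fit_nu(inf$co_lists, inf$L, censor_spacing = spacing)
  fit$chrom <- chrom
  fit
}

#' @export
print.interference_fit <- function(x, ...) {
  cat(sprintf(
    "Gamma interference fit%s: nu = %.2f [%.2f-%.2f] (m = %.2f)\n",
    if (!is.null(x$chrom)) paste0(" on ", x$chrom) else "",
    x$nu, x$ci95[1], x$ci95[2], x$m_equivalent))
  cat(sprintf("  loglik = %.2f, %d gametes, %d COs, L = %.3f M\n",
              x$loglik, x$n_gametes, x$n_cos, x$L))
  invisible(x)
}

#' @export
logLik.interference_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n_gametes,
            class = "logLik")
}

#' @export
coef.interference_fit <- function(object, ...) c(nu = object$nu)

#' @export
confint.interference_fit <- function(object, parm = "nu", level = 0.95, ...) {
  if (level != 0.95)
    stop("only the 95% profile interval is computed")
  matrix(object$ci95, nrow = 1,
         dimnames = list("nu", c("2.5 %", "97.5 %")))
}
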