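#' Linear fit of crossover number against chromosome size
#'
#' Ordinary least squares of per-bivalent CO counts (twice the genetic
#' length in Morgans) on chromosome size, in Mb or in micrometers of
#' synaptonemal complex.
#'
#' @param sizes Chromosome sizes.
#' @param co_counts Mean CO counts per bivalent.
#' @return List: `slope`, `intercept`, `r_squared`.
#' @export
fit_linear <- function(sizes, co_counts) {
  if (length(sizes) != length(co_counts) || length(sizes) < 2L)
    stop("need matching vectors of at least two chromosomes")
  fit <- stats::lm(co_counts ~ sizes)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}

# weighted chi-squared of residuals; weights are inverse variances of the
# genetic-length estimates (per-plant CO-count variance / n_plants)
.wchi2 <- function(obs, pred, variances) sum((obs - pred)^2 / variances)

#' Obligate-crossover threshold model fit
#'
#' Fits `L_G = 0.5 + a (L_Mb - L_thr)` by weighted least squares: genetic
#' length (Morgans) rises linearly with physical size above a threshold size
#' `L_thr` at which only the obligate CO (`L_G = 0.5` Morgan) remains.  The
#' model is linear in `(intercept, a)`, so the weighted normal equations
#' give the optimum and `L_thr = (0.5 - intercept) / a`.  Goodness of fit is
#' the weighted chi-squared at the optimum with `n - 2` degrees of freedom.
#'
#' @param L_G Genetic lengths in Morgans, one per chromosome.
#' @param L_Mb Physical sizes in Mb.
#' @param variances Variances of the `L_G` estimates (per-plant CO-count
#'   variance divided by the number of plants).
#' @return Object of class `scaling_fit`: `a`, `L_thr`, `chi2`, `dof`,
#'   `p_value`, `weights`, fitted values.
#' @export
fit_threshold_model <- function(L_G, L_Mb, variances) {
  n <- length(L_G)
  stopifnot(length(L_Mb) == n, length(variances) == n)
  if (n < 3L) stop("need at least 3 chromosomes for the free-threshold fit")
  w <- 1 / variances
  fit <- stats::lm(L_G ~ L_Mb, weights = w)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  pred <- b + a * L_Mb
  chi2 <- .wchi2(L_G, pred, variances)
  dof <- n - 2L
  structure(list(a = a, L_thr = (0.5 - b) / a, intercept = b,
                 chi2 = chi2, dof = dof,
                 p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
                 weights = w, fitted = pred, L_G = L_G, L_Mb = L_Mb,
                 model = "threshold"),
            class = "scaling_fit")
}

#' Test of the zero-threshold (Li-Freudenberg) scaling model
#'
#' The special case `L_thr = 0`: `L_G = 0.5 + a L_Mb`, a single free
#' parameter.  `a` solves the weighted normal equation
#' `a = sum(w x (y - 0.5)) / sum(w x^2)`; the model is tested by the
#' weighted chi-squared at the fit with `n - 1` degrees of freedom.  The
#' constrained chi-squared is never below the free-threshold one (nesting).
#'
#' @inheritParams fit_threshold_model
#' @return Object of class `scaling_fit` with `L_thr = 0`.
#' @export
test_li_freudenberg <- function(L_G, L_Mb, variances) {
  n <- length(L_G)
  stopifnot(length(L_Mb) == n, length(variances) == n)
  if (n < 2L) stop("test undefined with fewer than 2 chromosomes")
  w <- 1 / variances
  a <- sum(w * L_Mb * (L_G - 0.5)) / sum(w * L_Mb^2)
  pred <- 0.5 + a * L_Mb
  chi2 <- .wchi2(L_G, pred, variances)
  dof <- n - 1L
  structure(list(a = a, L_thr = 0, intercept = 0.5,
                 chi2 = chi2, dof = dof,
                 p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
                 weights = w, fitted = pred, L_G = L_G, L_Mb = L_Mb,
                 model = "li-freudenberg"),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "%s scaling fit: a = %.4f M/Mb, L_thr = %.2f Mb; chi2 = %.3g on %d df (p = %.3g)\n",
    x$model, x$a, x$L_thr, x$chi2, x$dof, x$p_value))
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...)
  c(a = object$a, L_thr = object$L_thr)
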