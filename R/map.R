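#' Haldane map function
#'
#' Converts a recombination fraction into genetic distance under the Haldane
#' (no-interference) map function, `d = -log(1 - 2 r) / 2` Morgans.  At the
#' small fractions typical of dense maps `d` is essentially `r` itself.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5`.
#' @return Genetic distance(s) in Morgans.
#' @export
haldane_distance <- function(r) {
  if (any(!is.finite(r) | r < 0 | r >= 0.5))
    stop("recombination fractions must lie in [0, 0.5)")
  -0.5 * log(1 - 2 * r)
}

#' Per-interval recombination fractions
#'
#' For every pair of adjacent markers, counts the plants with data at both
#' markers (`N`) and the recombinants among them (`N_r`), and estimates the
#' recombination fraction `r = N_r / N` with standard error
#' `sqrt(r (1 - r) / N)` and normal 95% confidence bounds.  Genetic distance
#' uses [haldane_distance()]; the rate per Mb uses the bp span of the
#' half-open interval `[left_bp, right_bp)`.
#'
#' @param pop A `backcross_population`.
#' @param chrom Optional chromosome label to restrict to.
#' @return data.frame, one row per interval: `chrom`, `left`, `right`,
#'   `left_bp`, `right_bp`, `span_bp`, `N`, `N_r`, `r`, `se`, `r_lo`, `r_hi`,
#'   `d_M` (Morgans), `cM`, `cM_per_Mb`, `rate_lo`, `rate_hi` (cM/Mb bounds).
#' @export
interval_table <- function(pop, chrom = NULL) {
  markers <- pop$markers
  if (!is.null(chrom)) markers <- markers[markers$chrom %in% chrom, ]
  rows <- list()
  for (ch in unique(markers$chrom)) {
    mk <- markers[markers$chrom == ch, ]
    if (nrow(mk) < 2L) next
    g <- pop$geno[, mk$name, drop = FALSE]
    left <- g[, -ncol(g), drop = FALSE]
    right <- g[, -1L, drop = FALSE]
    ok <- !is.na(left) & !is.na(right)
    N <- as.integer(colSums(ok))
    N_r <- as.integer(colSums(ok & left != right, na.rm = TRUE))
    r <- ifelse(N > 0, N_r / N, NA_real_)
    se <- ifelse(N > 0, sqrt(r * (1 - r) / N), NA_real_)
    span <- diff(mk$pos)
    d <- ifelse(!is.na(r) & r < 0.5, -0.5 * log(1 - 2 * r), NA_real_)
    rate <- 100 * r / (span / 1e6)
    rate_se <- 100 * se / (span / 1e6)
    rows[[ch]] <- data.frame(
      chrom = ch,
      left = mk$name[-nrow(mk)], right = mk$name[-1L],
      left_bp = mk$pos[-nrow(mk)], right_bp = mk$pos[-1L],
      span_bp = span, N = N, N_r = N_r, r = r, se = se,
      r_lo = pmax(0, r - 1.96 * se), r_hi = pmin(1, r + 1.96 * se),
      d_M = d, cM = 100 * d, cM_per_Mb = rate,
      rate_lo = pmax(0, rate - 1.96 * rate_se),
      rate_hi = rate + 1.96 * rate_se,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname interval_table
#' @param index Interval index on `chrom` (between markers `index` and
#'   `index + 1`).
#' @export
interval_recomb_fraction <- function(pop, chrom, index) {
  tab <- interval_table(pop, chrom)
  if (index < 1L || index > nrow(tab)) stop("no such interval")
  as.list(tab[index, ])
}

#' Chromosome genetic length by interval summation
#'
#' Estimator (1): add the Haldane lengths of all adjacent-marker intervals.
#' The variance follows by the delta method, `var(d) = se(r)^2 / (1 - 2 r)^2`
#' per interval, summed (intervals are independent given the plants).
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @return An object of class `chromosome_length` with fields `L_G` (Morgans),
#'   `variance`, `n_plants`, `method`.
#' @export
chromosome_length_interval_sum <- function(pop, chrom) {
  tab <- interval_table(pop, chrom)
  if (any(is.na(tab$r))) stop("interval with no informative plants on ", chrom)
  L <- sum(tab$d_M)
  v <- sum(tab$se^2 / (1 - 2 * tab$r)^2)
  structure(list(L_G = L, variance = v, n_plants = nrow(pop$geno),
                 chrom = chrom, method = "interval-sum"),
            class = "chromosome_length")
}

# per-plant CO (switch) counts on one chromosome; missing calls are
# transparent: each A<->H transition of the non-missing sequence is one CO.
# Plants with < 2 non-missing calls give NA.  'region' optionally restricts
# to markers with bp inside [region[1], region[2]].
switch_counts <- function(pop, chrom, region = NULL) {
  mk <- pop$markers[pop$markers$chrom == chrom, ]
  if (!is.null(region))
    mk <- mk[mk$pos >= region[1] & mk$pos <= region[2], ]
  if (nrow(mk) < 2L) stop("fewer than two markers on ", chrom)
  g <- pop$geno[, mk$name, drop = FALSE]
  apply(g, 1L, function(v) {
    a <- v[!is.na(v)]
    if (length(a) < 2L) return(NA_integer_)
    sum(a[-1L] != a[-length(a)])
  })
}

#' Chromosome genetic length by crossover counting
#'
#' Estimator (2): count each plant's observable COs -- every genotype switch
#' along the non-missing call sequence -- and average; with at most one CO per
#' interval the mean CO count per gamete is the genetic length in Morgans.
#' Unlike interval summation this uses more than two loci at a time, so a CO
#' bracketing a missing call is still detected.  The estimator variance is
#' the per-plant CO-count sample variance divided by the number of plants.
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @param region Optional bp interval restricting the markers used.
#' @return An object of class `chromosome_length`; also carries the per-plant
#'   `counts`.
#' @export
chromosome_length_switch_count <- function(pop, chrom, region = NULL) {
  counts <- switch_counts(pop, chrom, region)
  counts <- counts[!is.na(counts)]
  structure(list(L_G = mean(counts),
                 variance = stats::var(counts) / length(counts),
                 n_plants = length(counts), chrom = chrom,
                 method = "switch-count", counts = counts),
            class = "chromosome_length")
}

#' @export
print.chromosome_length <- function(x, ...) {
  cat(sprintf("%s genetic length (%s): %.2f cM (se %.2f cM, n = %d)\n",
              x$chrom, x$method, 100 * x$L_G, 100 * sqrt(x$variance),
              x$n_plants))
  invisible(x)
}

#' Male/female genetic length ratio with confidence interval
#'
#' `f = L_G(male) / L_G(female)`.  Both lengths being well estimated, the
#' relative variance of the ratio is the sum of the two relative variances
#' and `f` is approximately Gaussian, giving
#' `ci95 = f (1 +/- 1.96 sqrt(relvar_m + relvar_f))`.
#'
#' @param Lm,Lf `chromosome_length` objects (male, female), or plain lists
#'   with fields `L_G` and `variance`.
#' @return Object of class `ratio_estimate` with `f` and `ci95`.
#' @export
mf_ratio_ci <- function(Lm, Lf) {
  f <- Lm$L_G / Lf$L_G
  relvar <- Lm$variance / Lm$L_G^2 + Lf$variance / Lf$L_G^2
  hw <- 1.96 * f * sqrt(relvar)
  structure(list(f = f, ci95 = c(f - hw, f + hw), relvar = relvar),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("M/F ratio %.2f (%.2f-%.2f)\n", x$f, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Truncate a chromosome to its physical center
#'
#' Removes a fraction `end_fraction` of the physical length, half from each
#' end; markers outside the central region are dropped, so every genetic
#' interval overlapping a truncated region is entirely removed.  Map lengths
#' on the truncated chromosome are then computed by crossover counting on the
#' surviving markers.
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @param end_fraction Total physical fraction removed, in `[0, 1)`
#'   (0.30 removes 15% from each end).
#' @return List: `pop` (restricted population), `region` (kept bp interval),
#'   `removed_markers`, `removed_intervals`.
#' @export
truncate_chromosome <- function(pop, chrom, end_fraction) {
  if (end_fraction < 0 || end_fraction >= 1)
    stop("'end_fraction' must lie in [0, 1)")
  sp <- pop$chromosomes[[chrom]]
  P <- if (!is.null(sp)) sp$physical_length else
    max(pop$markers$pos[pop$markers$chrom == chrom])
  lo <- end_fraction / 2 * P
  hi <- (1 - end_fraction / 2) * P
  on_ch <- pop$markers$chrom == chrom
  drop <- on_ch & (pop$markers$pos < lo | pop$markers$pos > hi)
  n_mark_before <- sum(on_ch)
  out <- pop
  out$markers <- pop$markers[!drop, , drop = FALSE]
  out$geno <- pop$geno[, !drop, drop = FALSE]
  list(pop = out, region = c(lo, hi),
       removed_markers = sum(drop),
       removed_intervals = (n_mark_before - 1L) - (sum(on_ch & !drop) - 1L))
}

#' Crossover losses under truncation, by per-plant CO class
#'
#' Classifies plants by their full-chromosome CO count (1 CO vs 2 or more)
#' and compares, per class, the observed fraction of COs lost after
#' truncation with the expectation under position-independent loss, namely
#' the genetic fraction removed.  Under interference-free (Poisson) CO
#' placement losses are class-independent; positive interference pushes the
#' COs of multi-CO plants towards the chromosome ends, so the 2+ class loses
#' more than expected.
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @param end_fraction Total physical fraction removed (see
#'   [truncate_chromosome()]).
#' @return data.frame, one row per class: `class`, `n_plants`, `cos_full`,
#'   `cos_kept`, `observed_loss`, `expected_loss`.
#' @export
truncation_loss_table <- function(pop, chrom, end_fraction) {
  full <- switch_counts(pop, chrom)
  tr <- truncate_chromosome(pop, chrom, end_fraction)
  kept <- switch_counts(tr$pop, chrom)
  ok <- !is.na(full) & !is.na(kept)
  full <- full[ok]; kept <- kept[ok]
  L_full <- mean(full)
  L_kept <- mean(kept)
  expected <- if (L_full > 0) 1 - L_kept / L_full else 0
  cls <- ifelse(full >= 2, "2+", as.character(full))
  out <- do.call(rbind, lapply(c("1", "2+"), function(cl) {
    sel <- cls == cl
    cf <- sum(full[sel]); ck <- sum(kept[sel])
    data.frame(class = cl, n_plants = sum(sel), cos_full = cf, cos_kept = ck,
               observed_loss = if (cf > 0) 1 - ck / cf else NA_real_,
               expected_loss = expected, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Test equality of male and female genetic lengths
#'
#' Welch two-sample t-test on the per-plant CO counts of the two populations
#' (each plant's count estimates the genetic length in Morgans).
#'
#' @param counts_male,counts_female Per-plant CO counts (see
#'   [chromosome_length_switch_count()]).
#' @return The p-value.
#' @export
compare_lengths_ttest <- function(counts_male, counts_female) {
  stats::t.test(counts_male, counts_female)$p.value
}

#' Distribution of plants over CO-count classes
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @return Named integer vector of plant counts in classes `0`, `1`, `2`,
#'   `3+` (plants with usable data only).
#' @export
co_count_distribution <- function(pop, chrom) {
  counts <- switch_counts(pop, chrom)
  counts <- counts[!is.na(counts)]
  c("0" = sum(counts == 0L), "1" = sum(counts == 1L),
    "2" = sum(counts == 2L), "3+" = sum(counts >= 3L))
}
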