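#' Segregation distortion profile
#'
#' Per marker, counts the plants carrying each parental allele
#' (`N_C` recurrent-parent homozygotes "A", `N_L` heterozygotes "H") and
#' tests the no-distortion hypothesis (allele fraction 0.5).  The rejection
#' band is centered on 0.5 with half-width `2.33 s`,
#' `s^2 = 1 / (4 (N_C + N_L))`; a marker is flagged when its observed
#' frequency falls outside.  Bands vary marker-to-marker with the number of
#' valid calls.
#'
#' @param pop A `backcross_population`.
#' @param chrom Optional chromosome restriction.
#' @return data.frame of class `distortion_profile`: `chrom`, `marker`,
#'   `pos`, `N_C`, `N_L`, `freq` (frequency of the "A"/recurrent allele),
#'   `s`, `half_width`, `flagged`.
#' @export
distortion_profile <- function(pop, chrom = NULL) {
  mk <- pop$markers
  if (!is.null(chrom)) mk <- mk[mk$chrom %in% chrom, ]
  g <- pop$geno[, mk$name, drop = FALSE]
  N_C <- colSums(g == "A", na.rm = TRUE)
  N_L <- colSums(g == "H", na.rm = TRUE)
  n <- N_C + N_L
  freq <- ifelse(n > 0, N_C / n, NA_real_)
  s <- ifelse(n > 0, sqrt(1 / (4 * n)), NA_real_)
  hw <- 2.33 * s
  out <- data.frame(chrom = mk$chrom, marker = mk$name, pos = mk$pos,
                    N_C = N_C, N_L = N_L, freq = freq, s = s,
                    half_width = hw,
                    flagged = !is.na(freq) & abs(freq - 0.5) > hw,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("distortion_profile", "data.frame")
  out
}

#' @export
print.distortion_profile <- function(x, ...) {
  cat(sprintf("Segregation distortion profile: %d markers, %d flagged at the 2.33 s band\n",
              nrow(x), sum(x$flagged)))
  fl <- x[x$flagged, c("chrom", "marker", "pos", "freq")]
  if (nrow(fl)) print.data.frame(utils::head(fl, 10))
  invisible(x)
}

#' Single-locus relative fitness from allele counts
#'
#' Under single-locus gametic selection the surviving allele ratio is
#' `1 : s`, so the retention probability of the unfavored allele is simply
#' the minor/major allele-count ratio at the locus.
#'
#' @param profile A [distortion_profile()].
#' @param marker Marker name, or bp position on `chrom`.
#' @param chrom Chromosome label (needed when `marker` is a position).
#' @return List: `s`, `unfavored` (allele code), `N_C`, `N_L`.
#' @export
estimate_single_locus_fitness <- function(profile, marker, chrom = NULL) {
  i <- if (is.character(marker)) which(profile$marker == marker)
       else which(profile$pos == marker &
                  (is.null(chrom) | profile$chrom == chrom))
  if (length(i) != 1L) stop("marker not found (or ambiguous) in the profile")
  nc <- profile$N_C[i]; nl <- profile$N_L[i]
  if (nc == nl) return(list(s = 1, unfavored = NA_character_,
                            N_C = nc, N_L = nl))
  list(s = min(nc, nl) / max(nc, nl),
       unfavored = if (nc < nl) "A" else "H",
       N_C = nc, N_L = nl)
}

## ---- multi-locus genotype-class model -------------------------------------

# Post-selection class frequencies for k ordered loci with k-1 recombination
# rates.  Classes enumerate alleles ("A"/"H") at each locus, first locus most
# significant; pre-selection frequency is 1/2 times r or (1-r) per interval
# (standard Haldane model, independent intervals); selection multiplies by
# s1/s2 when the alleles at the selected loci are unfavored, then
# re-normalizes.
.class_freqs <- function(rates, selpos = NULL, s = c(1, 1),
                         unfavored = c("A", "H")) {
  if (any(rates < 0 | rates >= 0.5)) stop("rates must lie in [0, 0.5)")
  k <- length(rates) + 1L
  classes <- as.matrix(expand.grid(rep(list(c("A", "H")), k),
                                   KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE))[, k:1, drop = FALSE]
  p <- rep(0.5, 2^k)
  for (j in seq_len(k - 1L)) {
    differ <- classes[, j] != classes[, j + 1L]
    p <- p * ifelse(differ, rates[j], 1 - rates[j])
  }
  if (!is.null(selpos)) {
    w <- ifelse(classes[, selpos[1]] == unfavored[1], s[1], 1) *
      ifelse(classes[, selpos[2]] == unfavored[2], s[2], 1)
    p <- p * w
    p <- p / sum(p)
  }
  names(p) <- apply(classes, 1L, paste0, collapse = "")
  p
}

#' Predicted 16-genotype frequencies under two-locus selection
#'
#' Four ordered loci `L1 < M_i < M_{i+1} < L2` define three consecutive
#' intervals with recombination rates `r12`, `r23`, `r34`.  Under the Haldane
#' model the pre-selection frequency of each of the 16 four-locus gamete
#' classes is `1/2` times the product over intervals of `r` (switch) or
#' `1 - r` (no switch); gametic selection at the flanking loci multiplies by
#' the haplotype weight (`s1` and/or `s2` for unfavored alleles) and the
#' frequencies are re-normalized.
#'
#' @param r12,r23,r34 Recombination rates of the three intervals, in
#'   `[0, 0.5)`.
#' @param sel Optional [selection_model()] acting at `L1` and `L2` (only its
#'   `s1`, `s2`, `unfavored1`, `unfavored2` are used); `NULL` means no
#'   selection.
#' @return Named numeric vector of 16 class frequencies (names are the
#'   allele codes at `L1, M_i, M_{i+1}, L2`), summing to 1.
#' @export
predict_16_genotype_freqs <- function(r12, r23, r34, sel = NULL) {
  rates <- c(r12, r23, r34)
  if (is.null(sel)) return(.class_freqs(rates))
  .class_freqs(rates, selpos = c(1L, 4L), s = c(sel$s1, sel$s2),
               unfavored = c(sel$unfavored1, sel$unfavored2))
}

# observed class counts for the loci (marker column indices, ordered);
# plants missing at any locus are excluded
.class_counts <- function(geno, cols) {
  sub <- geno[, cols, drop = FALSE]
  ok <- rowSums(is.na(sub)) == 0L
  sub <- sub[ok, , drop = FALSE]
  k <- length(cols)
  template <- names(.class_freqs(rep(0.1, k - 1L)))
  obs <- table(factor(apply(sub, 1L, paste0, collapse = ""),
                      levels = template))
  cnt <- as.integer(obs)
  names(cnt) <- template
  cnt
}

# Pearson chi-squared between observed class counts and model frequencies;
# classes with zero expected and zero observed contribute nothing, zero
# expected with observed > 0 rejects the parameter point
.class_chi2 <- function(counts, p) {
  n <- sum(counts)
  e <- n * p
  pos <- e > 0
  if (any(counts[!pos] > 0)) return(1e12)
  sum((counts[pos] - e[pos])^2 / e[pos])
}

# fit the k-1 interval rates for fixed selection parameters, by
# box-constrained minimization of the Pearson chi-squared from naive starts
.fit_class_rates <- function(counts, selpos, s, unfavored, start = NULL) {
  k <- as.integer(log2(length(counts)))
  n <- sum(counts)
  classes <- do.call(rbind, strsplit(names(counts), ""))
  if (is.null(start)) {
    start <- vapply(seq_len(k - 1L), function(j)
      sum(counts[classes[, j] != classes[, j + 1L]]) / max(n, 1L), 0)
  }
  start <- pmin(pmax(start, 1e-4), 0.49)
  obj <- function(r) .class_chi2(counts,
    .class_freqs(r, selpos = selpos, s = s, unfavored = unfavored))
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = rep(1e-6, k - 1L), upper = rep(0.4999, k - 1L))
  list(rates = opt$par, chi2 = opt$value, convergence = opt$convergence)
}

#' Fit interval recombination rates from 16-class counts
#'
#' Given the observed counts of the 16 four-locus genotype classes and fixed
#' selection coefficients, recovers `(r12, r23, r34)` by minimizing the
#' Pearson chi-squared between observed and predicted class counts
#' (box-constrained local optimization started at the naive pairwise
#' recombination fractions).
#'
#' @param counts Named 16-vector of class counts as produced by the
#'   population (same class order as [predict_16_genotype_freqs()]).
#' @param sel A [selection_model()] or `NULL` (no selection).
#' @return Object of class `sixteen_class_fit`: `rates` (`r12, r23, r34`),
#'   `chi2` at the optimum, `counts`, `convergence`.
#' @export
fit_interval_rates <- function(counts, sel = NULL) {
  if (length(counts) != 16L) stop("'counts' must have 16 classes")
  if (sum(counts) == 0L) stop("no informative plants")
  if (max(counts) == sum(counts))
    warning("all mass in one genotype class; boundary fit")
  s <- if (is.null(sel)) c(1, 1) else c(sel$s1, sel$s2)
  unf <- if (is.null(sel)) c("A", "H") else c(sel$unfavored1, sel$unfavored2)
  fit <- .fit_class_rates(counts, selpos = c(1L, 4L), s = s, unfavored = unf)
  structure(list(rates = stats::setNames(fit$rates, c("r12", "r23", "r34")),
                 chi2 = fit$chi2, counts = counts,
                 convergence = fit$convergence, sel = sel),
            class = "sixteen_class_fit")
}

#' @export
print.sixteen_class_fit <- function(x, ...) {
  cat(sprintf("16-class fit: r12 = %.4f, r23 = %.4f, r34 = %.4f (chi2 = %.3g)\n",
              x$rates[1], x$rates[2], x$rates[3], x$chi2))
  invisible(x)
}

# interval-level machinery for the two-locus correction: for each adjacent
# marker pair between the selected loci, the distinct ordered loci
# {L1, M_j, M_j+1, L2} (the four collapse to three or two when a marker
# coincides with a selected locus) and the observed class counts
.correction_intervals <- function(pop, chrom, i1, i2) {
  mk <- pop$markers[pop$markers$chrom == chrom, ]
  lapply(i1:(i2 - 1L), function(j) {
    loci <- sort(unique(c(i1, j, j + 1L, i2)))
    counts <- .class_counts(pop$geno, mk$name[loci])
    list(j = j, loci = loci,
         selpos = c(match(i1, loci), match(i2, loci)),
         rate_idx = match(j, loci),  # rate between loci j and j+1
         counts = counts)
  })
}

#' Fit two-locus selection coefficients and correct interval rates
#'
#' Joint estimation of the gametic selection coefficients `(s1, s2)` acting
#' at two distorted loci `L1 < L2` on one chromosome.  For each adjacent
#' marker interval between the loci, the observed multi-locus genotype-class
#' counts are fitted (for given `s1, s2`) by minimizing a Pearson
#' chi-squared over the interval recombination rates
#' ([fit_interval_rates()]); the per-interval chi-squares are summed into a
#' total chi-squared which is minimized over `(s1, s2)` on a 0.05-step grid
#' refined by box-constrained local optimization.  All interval rates are
#' then re-fitted at the optimum `(s1*, s2*)`.
#'
#' Unfavored alleles default to the minor allele at each locus as seen in
#' the distortion profile.
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome carrying the loci.
#' @param locus1_bp,locus2_bp Marker bp positions of the selected loci
#'   (`locus1_bp < locus2_bp`); both should be flagged by
#'   [distortion_profile()].
#' @param grid_step Grid step of the outer `(s1, s2)` search (default 0.05).
#' @param unfavored Length-2 allele codes of the unfavored alleles at
#'   (`L1`, `L2`), or `NULL` to infer from the data.
#' @return Object of class `selection_fit`: `s1`, `s2`, `unfavored`,
#'   `total_chi2`, `marginal` (single-locus ratio estimates), `intervals`
#'   (per-interval corrected rates), `sel` (the fitted [selection_model()]).
#' @export
fit_selection_coefficients <- function(pop, chrom, locus1_bp, locus2_bp,
                                       grid_step = 0.05, unfavored = NULL) {
  mk <- pop$markers[pop$markers$chrom == chrom, ]
  i1 <- which(mk$pos == locus1_bp)
  i2 <- which(mk$pos == locus2_bp)
  if (length(i1) != 1L || length(i2) != 1L || i1 >= i2)
    stop("selected loci must be distinct markers of ", chrom,
         " with locus1 < locus2")
  prof <- distortion_profile(pop, chrom)
  if (is.null(unfavored)) {
    unfavored <- c(
      if (prof$freq[i1] < 0.5) "A" else "H",
      if (prof$freq[i2] < 0.5) "A" else "H")
  }
  marginal <- c(s1 = estimate_single_locus_fitness(prof, mk$name[i1])$s,
                s2 = estimate_single_locus_fitness(prof, mk$name[i2])$s)

  ivs <- .correction_intervals(pop, chrom, i1, i2)
  warm <- vector("list", length(ivs))
  total_chi2 <- function(s1, s2) {
    tot <- 0
    for (q in seq_along(ivs)) {
      iv <- ivs[[q]]
      fit <- .fit_class_rates(iv$counts, iv$selpos, c(s1, s2), unfavored,
                              start = warm[[q]])
      warm[[q]] <<- fit$rates
      tot <- tot + fit$chi2
    }
    tot
  }
  grid <- seq(grid_step, 1, by = grid_step)
  gval <- matrix(NA_real_, length(grid), length(grid),
                 dimnames = list(s1 = grid, s2 = grid))
  for (a in seq_along(grid)) for (b in seq_along(grid))
    gval[a, b] <- total_chi2(grid[a], grid[b])
  best <- which(gval == min(gval), arr.ind = TRUE)[1L, ]
  # Nelder-Mead with clamping: the inner fits use L-BFGS-B, which is not
  # reentrant, so the outer search must not
  clamp <- function(s) pmin(pmax(s, 0.01), 1)
  opt <- stats::optim(c(grid[best[1]], grid[best[2]]),
                      function(s) { s <- clamp(s); total_chi2(s[1], s[2]) },
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-6))
  s_star <- clamp(opt$par)
  # re-fit every interval at the optimum
  intervals <- lapply(ivs, function(iv) {
    fit <- .fit_class_rates(iv$counts, iv$selpos, s_star, unfavored)
    list(j = iv$j,
         left = mk$name[iv$j], right = mk$name[iv$j + 1L],
         left_bp = mk$pos[iv$j], right_bp = mk$pos[iv$j + 1L],
         r_corrected = fit$rates[iv$rate_idx], chi2 = fit$chi2)
  })
  sel <- selection_model(chrom, locus1_bp, locus2_bp,
                         s1 = s_star[1], s2 = s_star[2],
                         unfavored1 = unfavored[1], unfavored2 = unfavored[2])
  structure(list(s1 = s_star[1], s2 = s_star[2], unfavored = unfavored,
                 total_chi2 = opt$value, marginal = marginal,
                 intervals = intervals, sel = sel, grid = gval,
                 convergence = opt$convergence, chrom = chrom,
                 loci_bp = c(locus1_bp, locus2_bp)),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf(
    "Two-locus selection fit on %s:\n  s1* = %.3f ('%s' at %d), s2* = %.3f ('%s' at %d)\n",
    x$chrom, x$s1, x$unfavored[1], as.integer(x$loci_bp[1]),
    x$s2, x$unfavored[2], as.integer(x$loci_bp[2])))
  cat(sprintf("  total chi2 = %.3g over %d intervals; marginal ratio estimates s1 = %.3f, s2 = %.3f\n",
              x$total_chi2, length(x$intervals),
              x$marginal[1], x$marginal[2]))
  invisible(x)
}

#' @export
coef.selection_fit <- function(object, ...)
  c(s1 = object$s1, s2 = object$s2)

#' Selection-corrected chromosome genetic length
#'
#' Rebuilds the interval map of a chromosome with the recombination rates of
#' the intervals between the two selected loci replaced by the corrected
#' rates from a [fit_selection_coefficients()] fit; intervals outside
#' `(L1, L2)` keep their naive estimates (single-locus selection leaves them
#' unbiased).  Lengths are interval sums of Haldane distances.
#'
#' @param pop A `backcross_population`.
#' @param chrom Chromosome label.
#' @param fit A `selection_fit` for that chromosome.
#' @return List: `naive_L_G`, `corrected_L_G` (Morgans), `table` (interval
#'   table with `r_corrected` and `d_M_corrected` columns).
#' @export
corrected_map_length <- function(pop, chrom, fit) {
  stopifnot(inherits(fit, "selection_fit"), identical(fit$chrom, chrom))
  tab <- interval_table(pop, chrom)
  tab$r_corrected <- tab$r
  for (iv in fit$intervals) {
    i <- which(tab$left == iv$left & tab$right == iv$right)
    tab$r_corrected[i] <- iv$r_corrected
  }
  tab$d_M_corrected <- haldane_distance(pmin(tab$r_corrected, 0.499999))
  list(naive_L_G = sum(tab$d_M),
       corrected_L_G = sum(tab$d_M_corrected),
       table = tab)
}
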