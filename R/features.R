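#' Infer heterochromatic intervals from epigenetic-mark windows
#'
#' Euchromatin presence (either of the H3K4me3 / H3K27me3 marks) is averaged
#' in 2 kb windows; a marker interval is called heterochromatic when the
#' overlap-weighted mean presence over the interval is strictly below the
#' 0.2 threshold (a mean of exactly 0.2 is euchromatic).
#'
#' @param windows BED-style data.frame: `chrom`, `start`, `end` (0-based,
#'   half-open), `presence` in `[0, 1]`.
#' @param intervals Interval data.frame with `chrom`, `left_bp`, `right_bp`
#'   (1-based marker positions; the interval is `[left_bp, right_bp)`).
#' @param threshold Presence threshold (default 0.2).
#' @return `intervals` with columns `mean_presence` and `heterochromatic`.
#' @export
infer_heterochromatin <- function(windows, intervals, threshold = 0.2) {
  mp <- het <- numeric(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    w <- windows[windows$chrom == intervals$chrom[i], ]
    # convert the 1-based marker interval to 0-based half-open
    lo <- intervals$left_bp[i] - 1
    hi <- intervals$right_bp[i] - 1
    ov <- pmin(w$end, hi) - pmax(w$start, lo)
    sel <- ov > 0
    mp[i] <- if (any(sel)) sum(w$presence[sel] * ov[sel]) / sum(ov[sel])
             else NA_real_
  }
  intervals$mean_presence <- mp
  intervals$heterochromatic <- !is.na(mp) & mp < threshold
  intervals
}

#' Merge heterochromatic intervals into BED regions
#'
#' @param intervals Output of [infer_heterochromatin()].
#' @return BED-style data.frame (`chrom`, `start`, `end`, 0-based half-open)
#'   of maximal runs of heterochromatic intervals.
#' @export
heterochromatin_regions <- function(intervals) {
  out <- list()
  for (ch in unique(intervals$chrom)) {
    sub <- intervals[intervals$chrom == ch, ]
    runs <- rle(sub$heterochromatic)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = sub$left_bp[starts[k]] - 1,
        end = sub$right_bp[ends[k]] - 1, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0)))
  do.call(rbind, out)
}

#' Arm mean recombination rates
#'
#' Weighted mean CO rate (cM/Mb) per chromosome arm, each interval weighted
#' by its bp span; heterochromatic intervals are excluded.  Intervals are
#' assigned to the arm containing their midpoint (intervals whose midpoint
#' falls inside the centromere span belong to no arm and are excluded).
#'
#' @param tab Interval table ([interval_table()]) with a `heterochromatic`
#'   column (see [infer_heterochromatin()]).
#' @param centromere_spans Named list of length-2 bp intervals, one per
#'   chromosome.
#' @return data.frame: `chrom`, `arm` (`"L"`/`"R"`), `mean_rate` (cM/Mb),
#'   `weight_bp`.
#' @export
arm_mean_rates <- function(tab, centromere_spans) {
  tab$arm <- .assign_arm(tab, centromere_spans)
  ok <- !is.na(tab$arm) & !tab$heterochromatic & !is.na(tab$cM_per_Mb)
  agg <- stats::aggregate(
    cbind(wsum = tab$span_bp[ok] * tab$cM_per_Mb[ok], w = tab$span_bp[ok]),
    by = list(chrom = tab$chrom[ok], arm = tab$arm[ok]), FUN = sum)
  data.frame(chrom = agg$chrom, arm = agg$arm,
             mean_rate = agg$wsum / agg$w, weight_bp = agg$w,
             stringsAsFactors = FALSE)
}

.assign_arm <- function(tab, centromere_spans) {
  mid <- (tab$left_bp + tab$right_bp) / 2
  arm <- rep(NA_character_, nrow(tab))
  for (ch in unique(tab$chrom)) {
    cen <- centromere_spans[[ch]]
    if (is.null(cen)) stop("no centromere span for ", ch)
    sel <- tab$chrom == ch
    arm[sel & mid < cen[1]] <- "L"
    arm[sel & mid > cen[2]] <- "R"
  }
  arm
}

#' Hot and cold interval classification
#'
#' An interval is "hot" ("cold") when the 95% confidence interval of its CO
#' rate lies entirely above (below) the weighted mean rate of its chromosome
#' arm.  Heterochromatic intervals and intervals inside the centromere span
#' are left unclassified.
#'
#' @param tab Interval table with `heterochromatic`, `cM_per_Mb`, `rate_lo`,
#'   `rate_hi` columns.
#' @param centromere_spans Named list of centromere bp intervals.
#' @return `tab` with columns `arm`, `arm_mean`, `hot`, `cold`.
#' @export
classify_hot_cold <- function(tab, centromere_spans) {
  arms <- arm_mean_rates(tab, centromere_spans)
  tab$arm <- .assign_arm(tab, centromere_spans)
  key <- paste(tab$chrom, tab$arm)
  tab$arm_mean <- arms$mean_rate[match(key, paste(arms$chrom, arms$arm))]
  usable <- !is.na(tab$arm) & !tab$heterochromatic & !is.na(tab$arm_mean)
  tab$hot <- usable & !is.na(tab$rate_lo) & tab$rate_lo > tab$arm_mean
  tab$cold <- usable & !is.na(tab$rate_hi) & tab$rate_hi < tab$arm_mean
  tab
}

#' Compare male and female recombination rates per interval
#'
#' For each interval shared between the male and female tables, tests
#' equality of the two recombination fractions.  The default is the
#' two-proportion normal test
#' `z = (r_m - r_f) / sqrt(se_m^2 + se_f^2)`; `method = "fisher"` uses
#' Fisher's exact test on the 2x2 recombinant table.  P-values are corrected
#' genome-wide by Benjamini-Hochberg and flagged at `q`.
#'
#' @param tab_m,tab_f Interval tables ([interval_table()]) for the male and
#'   female populations (matched on `chrom`, `left`, `right`).
#' @param q FDR level (default 0.05).
#' @param method `"z"` (default) or `"fisher"`.
#' @return data.frame: interval keys, `r_m`, `r_f`, `p_value`, `p_adj`,
#'   `significant`.
#' @export
compare_intervals_mf <- function(tab_m, tab_f, q = 0.05,
                                 method = c("z", "fisher")) {
  method <- match.arg(method)
  key_m <- paste(tab_m$chrom, tab_m$left, tab_m$right)
  key_f <- paste(tab_f$chrom, tab_f$left, tab_f$right)
  shared <- intersect(key_m, key_f)
  m <- tab_m[match(shared, key_m), ]
  f <- tab_f[match(shared, key_f), ]
  if (method == "z") {
    z <- (m$r - f$r) / sqrt(m$se^2 + f$se^2)
    p <- 2 * stats::pnorm(-abs(z))
    p[m$se == 0 & f$se == 0 & m$r == f$r] <- 1
  } else {
    p <- mapply(function(nr1, n1, nr2, n2)
      stats::fisher.test(matrix(c(nr1, n1 - nr1, nr2, n2 - nr2), 2))$p.value,
      m$N_r, m$N, f$N_r, f$N)
  }
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(chrom = m$chrom, left = m$left, right = m$right,
             left_bp = m$left_bp, right_bp = m$right_bp,
             r_m = m$r, r_f = f$r, p_value = p, p_adj = padj,
             significant = !is.na(padj) & padj <= q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Linear association between CO rate and a genomic feature
#'
#' Ordinary least squares of the interval CO rate on a feature density,
#' heterochromatic intervals excluded beforehand by the caller; reports the
#' slope, R-squared and the F-test p-value for no association (identical to
#' the slope t-test in simple regression).
#'
#' @param rates Interval CO rates (cM/Mb).
#' @param feature Feature densities for the same intervals.
#' @return List: `slope`, `r_squared`, `p_value`, `n`.
#' @export
associate_rate_feature <- function(rates, feature) {
  ok <- is.finite(rates) & is.finite(feature)
  if (sum(ok) < 3L) stop("need at least 3 intervals")
  fit <- stats::lm(rates[ok] ~ feature[ok])
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = sm$r.squared,
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       n = sum(ok))
}

#' Positional gradient of a feature along chromosome arms
#'
#' Pearson correlation (and its test) between a feature and the distance
#' from the centromere, per arm.  Intervals whose midpoint falls inside the
#' centromere span are excluded.
#'
#' @param values Feature values per interval.
#' @param midpoints Interval midpoints in bp.
#' @param centromere_span Length-2 bp interval.
#' @return data.frame: `arm`, `cor`, `p_value`, `n`.
#' @export
positional_gradient <- function(values, midpoints, centromere_span) {
  cen <- centromere_span
  arm <- ifelse(midpoints < cen[1], "L", ifelse(midpoints > cen[2], "R", NA))
  out <- lapply(c("L", "R"), function(a) {
    sel <- !is.na(arm) & arm == a & is.finite(values)
    if (sum(sel) < 3L)
      return(data.frame(arm = a, cor = NA_real_, p_value = NA_real_,
                        n = sum(sel)))
    d <- abs(midpoints[sel] - ifelse(a == "L", cen[1], cen[2]))
    ct <- stats::cor.test(values[sel], d)
    data.frame(arm = a, cor = unname(ct$estimate), p_value = ct$p.value,
               n = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
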