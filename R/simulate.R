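#' Gamma interference model for crossover placement
#'
#' Describes crossover (CO) formation on the bivalent as a stationary gamma
#' renewal process in genetic coordinates: successive inter-CO distances are
#' i.i.d. Gamma(shape = `nu`, rate = `2 * nu`) Morgans, so the mean spacing is
#' 0.5 Morgan and the CO intensity on the bivalent is 2 per Morgan.  A gamete
#' inherits each bivalent CO independently with probability 1/2 ("thinning"),
#' giving a gametic intensity of 1 CO per Morgan -- i.e. genetic length in,
#' genetic length out.  `nu = 1` is the interference-free (Poisson) case;
#' larger `nu` means stronger positive interference.  For integer `nu` the
#' model coincides with the counting model with `m = nu - 1`.
#'
#' @param nu Gamma shape parameter, > 0.
#' @param bivalent_rate CO intensity on the bivalent, COs per Morgan. Fixed at
#'   2 by the definition of genetic length; values other than 2 are rejected.
#' @param thinning_p Probability a gamete retains a given bivalent CO. Fixed
#'   at 0.5 (two of four chromatids are involved in each CO).
#' @return An object of class `gamma_model`.
#' @examples
#' m <- gamma_model(nu = 2.6)
#' @export
gamma_model <- function(nu = 1, bivalent_rate = 2, thinning_p = 0.5) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 1e-6)
    stop("'nu' must be a single positive number")
  if (bivalent_rate != 2)
    stop("'bivalent_rate' is fixed at 2 COs per Morgan on the bivalent")
  if (thinning_p != 0.5)
    stop("'thinning_p' is fixed at 0.5 (one of two chromatid pairs)")
  structure(list(nu = nu, bivalent_rate = 2, thinning_p = 0.5),
            class = "gamma_model")
}

#' @export
print.gamma_model <- function(x, ...) {
  cat(sprintf(
    "Gamma interference model: nu = %g (m = %g), 2 COs/Morgan on bivalent, thinning p = 0.5\n",
    x$nu, x$nu - 1))
  invisible(x)
}

#' Chromosome specification for simulation
#'
#' @param name Chromosome label, e.g. `"chr1"`.
#' @param genetic_length Genetic length of the gametic map in Morgans (> 0).
#' @param physical_length Physical length in bp.
#' @param marker_positions Strictly increasing marker bp positions
#'   (1-based, within `[1, physical_length]`).
#' @param centromere_span Length-2 bp interval covered by the (peri)centromere.
#' @param genetic_map Optional monotone map from bp to Morgans: either a
#'   function, or a two-column matrix/data.frame of (bp, Morgan) anchor points
#'   interpolated linearly.  The default is a uniform (linear) cM/Mb profile.
#' @return An object of class `chromosome_spec`.
#' @export
chromosome_spec <- function(name, genetic_length, physical_length,
                            marker_positions, centromere_span = NULL,
                            genetic_map = NULL) {
  if (!is.numeric(genetic_length) || genetic_length <= 0)
    stop("'genetic_length' must be positive (Morgans)")
  if (!is.numeric(physical_length) || physical_length <= 0)
    stop("'physical_length' must be positive (bp)")
  marker_positions <- as.numeric(marker_positions)
  if (any(diff(marker_positions) <= 0))
    stop("'marker_positions' must be strictly increasing")
  if (any(marker_positions < 1 | marker_positions > physical_length))
    stop("markers must lie within [1, physical_length]")
  if (is.null(centromere_span))
    centromere_span <- round(physical_length * c(0.45, 0.55))
  if (length(centromere_span) != 2L || centromere_span[1] >= centromere_span[2])
    stop("'centromere_span' must be an increasing length-2 bp interval")
  map_fun <- .make_genetic_map(genetic_map, genetic_length, physical_length)
  structure(list(name = as.character(name),
                 genetic_length = genetic_length,
                 physical_length = physical_length,
                 marker_positions = marker_positions,
                 centromere_span = as.numeric(centromere_span),
                 genetic_map = map_fun),
            class = "chromosome_spec")
}

# bp -> Morgan map; linear unless anchors or a function are supplied
.make_genetic_map <- function(genetic_map, L, P) {
  if (is.null(genetic_map)) {
    force(L); force(P)
    return(function(bp) L * bp / P)
  }
  if (is.function(genetic_map)) return(genetic_map)
  anchors <- as.matrix(genetic_map)
  if (ncol(anchors) != 2L) stop("'genetic_map' anchors need columns (bp, Morgan)")
  if (any(diff(anchors[, 1]) <= 0) || any(diff(anchors[, 2]) < 0))
    stop("'genetic_map' anchors must be monotone")
  function(bp) stats::approx(anchors[, 1], anchors[, 2], xout = bp,
                             rule = 2)$y
}

#' @export
print.chromosome_spec <- function(x, ...) {
  cat(sprintf("Chromosome %s: %.1f Mb, %.1f cM, %d markers\n",
              x$name, x$physical_length / 1e6, 100 * x$genetic_length,
              length(x$marker_positions)))
  invisible(x)
}

#' Two-locus gametic selection model
#'
#' Gametic selection acting at two loci: a gamete carrying the unfavored
#' allele at locus 1 (2) survives with probability `s1` (`s2`), and with
#' probability `s1 * s2` when it carries both (no epistasis).  Gametes with
#' both favored alleles always survive.
#'
#' @param chrom Chromosome label carrying the two loci.
#' @param locus1_bp,locus2_bp bp positions of the selected loci
#'   (`locus1_bp < locus2_bp`); each must coincide with a genotyped marker.
#' @param s1,s2 Retention probabilities in (0, 1] for the unfavored allele.
#' @param unfavored1,unfavored2 Genotype code (`"A"` or `"H"`) of the
#'   unfavored allele at each locus.  `"A"` is the recurrent-parent
#'   homozygote (a recurrent-parent gamete), `"H"` the heterozygote (a
#'   donor-parent gamete).
#' @return An object of class `selection_model`.
#' @export
selection_model <- function(chrom, locus1_bp, locus2_bp, s1, s2,
                            unfavored1 = "A", unfavored2 = "H") {
  if (locus1_bp >= locus2_bp) stop("'locus1_bp' must be < 'locus2_bp'")
  for (s in c(s1, s2))
    if (!is.numeric(s) || s <= 0 || s > 1)
      stop("selection coefficients must lie in (0, 1]")
  if (!unfavored1 %in% c("A", "H") || !unfavored2 %in% c("A", "H"))
    stop("unfavored alleles must be coded 'A' or 'H'")
  structure(list(chrom = as.character(chrom),
                 locus1_bp = locus1_bp, locus2_bp = locus2_bp,
                 s1 = s1, s2 = s2,
                 unfavored1 = unfavored1, unfavored2 = unfavored2),
            class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat(sprintf(
    "Gametic selection on %s: s1 = %.3g against '%s' at %d; s2 = %.3g against '%s' at %d\n",
    x$chrom, x$s1, x$unfavored1, as.integer(x$locus1_bp),
    x$s2, x$unfavored2, as.integer(x$locus2_bp)))
  invisible(x)
}

## ---- stationary gamma renewal sampling ------------------------------------

# CDF of the equilibrium (forward-recurrence) distribution of a
# Gamma(nu, rate = 2 nu) gap: F_e(x) = (1/mu) int_0^x S(t) dt with mu = 0.5,
# which closes to 2 x S(x; nu) + F(x; nu + 1).
.peq_gap <- function(x, nu) {
  b <- 2 * nu
  2 * x * pgamma(x, shape = nu, rate = b, lower.tail = FALSE) +
    pgamma(x, shape = nu + 1, rate = b)
}

.eq_grid_cache <- new.env(parent = emptyenv())

# inverse-CDF sampler for the equilibrium first-gap distribution,
# grid inversion with a cached 8193-point grid per nu
.req_gap <- function(n, nu) {
  key <- format(nu, digits = 15)
  g <- .eq_grid_cache[[key]]
  if (is.null(g)) {
    hi <- qgamma(1 - 1e-13, shape = nu + 1, rate = 2 * nu)
    while (.peq_gap(hi, nu) < 1 - 1e-11) hi <- hi * 2
    xs <- seq(0, hi, length.out = 8193L)
    Fe <- .peq_gap(xs, nu)
    g <- list(xs = xs, Fe = Fe)
    .eq_grid_cache[[key]] <- g
  }
  u <- stats::runif(n)
  stats::approx(g$Fe, g$xs, xout = pmin(u, max(g$Fe)), ties = "ordered")$y
}

#' Simulate crossover positions on bivalents
#'
#' Draws CO positions on `[0, L]` Morgans from the stationary gamma renewal
#' process: the first CO distance follows the equilibrium (forward-recurrence)
#' distribution of the Gamma(`nu`, `2 nu`) gap, subsequent gaps are i.i.d.
#' Gamma(`nu`, `2 nu`).  Stationarity makes the expected CO count on any
#' sub-segment of length `l` equal to `2 l`, so simulated genetic length
#' equals nominal genetic length exactly.
#'
#' @param spec A [chromosome_spec()], or a plain genetic length in Morgans.
#' @param model A [gamma_model()].
#' @param n Number of bivalents to simulate.
#' @param seed Optional integer seed.
#' @return For `n = 1` a sorted numeric vector of positions (Morgans);
#'   otherwise a list of `n` such vectors.
#' @export
simulate_bivalent_crossovers <- function(spec, model = gamma_model(), n = 1L,
                                         seed = NULL) {
  L <- if (inherits(spec, "chromosome_spec")) spec$genetic_length else spec
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("genetic length must be a single positive number (Morgans)")
  if (!inherits(model, "gamma_model")) stop("'model' must be a gamma_model")
  if (!is.null(seed)) set.seed(seed)
  out <- .sim_bivalents(L, model$nu, n)
  if (n == 1L) out[[1L]] else out
}

# vectorized renewal simulation: equilibrium first gap, then a block of
# i.i.d. gamma gaps cumulated column-wise; columns are bivalents
.sim_bivalents <- function(L, nu, n) {
  n <- as.integer(n)
  first <- .req_gap(n, nu)
  k_extra <- max(4L, ceiling(2 * L + 6 * sqrt(2 * L + 1) + 8))
  pos <- matrix(0, nrow = k_extra + 1L, ncol = n)
  pos[1L, ] <- first
  if (k_extra > 0L) {
    gaps <- matrix(stats::rgamma(k_extra * n, shape = nu, rate = 2 * nu),
                   nrow = k_extra, ncol = n)
    for (i in seq_len(k_extra)) pos[i + 1L, ] <- pos[i, ] + gaps[i, ]
  }
  # extend the rare columns whose running sum has not yet left [0, L]
  need <- which(pos[nrow(pos), ] <= L)
  while (length(need)) {
    add <- matrix(stats::rgamma(8L * length(need), shape = nu, rate = 2 * nu),
                  nrow = 8L)
    tail_row <- pos[nrow(pos), need, drop = FALSE]
    add <- apply(add, 2L, cumsum) + rep(tail_row, each = 8L)
    pos <- rbind(pos, matrix(Inf, nrow = 8L, ncol = ncol(pos)))
    pos[(nrow(pos) - 7L):nrow(pos), need] <- add
    need <- which(pos[nrow(pos), ] <= L)
  }
  lapply(seq_len(n), function(j) {
    v <- pos[, j]
    v[v <= L]
  })
}

#' Thin bivalent crossovers to a gamete
#'
#' Each bivalent CO is transmitted to a given gamete independently with
#' probability 0.5 (each CO involves two of the four chromatids).  Order is
#' preserved.
#'
#' @param positions Sorted CO positions on the bivalent (Morgans), or a list
#'   of such vectors.
#' @param model A [gamma_model()] (supplies the thinning probability).
#' @param seed Optional integer seed.
#' @return Retained positions, same shape as the input.
#' @export
thin_to_gamete <- function(positions, model = gamma_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- model$thinning_p
  thin1 <- function(x) {
    if (length(x) == 0L) return(x)
    if (is.unsorted(x)) stop("bivalent positions must be sorted")
    x[stats::runif(length(x)) < p]
  }
  if (is.list(positions)) lapply(positions, thin1) else thin1(positions)
}

#' Genotype a gamete at the marker positions
#'
#' Converts a gamete's CO positions into the per-marker allele vector a
#' backcross progeny would show: the allele flips at every CO, and each marker
#' carries the allele of the segment containing it.  `"A"` codes the
#' recurrent-parent homozygote, `"H"` the heterozygote.
#'
#' @param gamete_positions CO positions in Morgans (sorted).
#' @param spec A [chromosome_spec()]; its `genetic_map` converts marker bp to
#'   Morgans (linear by default).
#' @param start_allele Allele carried at position 0, `"A"` or `"H"`.
#' @return Character vector of calls, one per marker.
#' @export
genotype_gamete <- function(gamete_positions, spec, start_allele = "A") {
  stopifnot(inherits(spec, "chromosome_spec"))
  if (!start_allele %in% c("A", "H")) stop("'start_allele' must be 'A' or 'H'")
  if (length(gamete_positions) &&
      (min(gamete_positions) < 0 ||
       max(gamete_positions) > spec$genetic_length + 1e-9))
    stop("CO position outside the chromosome span")
  g <- spec$genetic_map(spec$marker_positions)
  n_co_before <- findInterval(g, sort(gamete_positions))
  flip <- n_co_before %% 2L == 1L
  other <- if (start_allele == "A") "H" else "A"
  ifelse(flip, other, start_allele)
}

#' Filter a population by two-locus gametic selection
#'
#' Applies the [selection_model()] retention probabilities to each plant of a
#' backcross population: survival probability is the product of `s1` and/or
#' `s2` over the unfavored alleles the plant's gamete carries.  Survivors are
#' returned unchanged.
#'
#' @param pop A `backcross_population` (see [simulate_backcross()]).
#' @param sel A [selection_model()]; both loci must coincide with markers.
#' @param seed Optional integer seed.
#' @return The filtered population (fewer plants, same markers).
#' @export
apply_gametic_selection <- function(pop, sel, seed = NULL) {
  stopifnot(inherits(pop, "backcross_population"),
            inherits(sel, "selection_model"))
  if (!is.null(seed)) set.seed(seed)
  w <- .selection_weights(pop$geno, pop$markers, sel)
  keep <- stats::runif(nrow(pop$geno)) < w
  .subset_population(pop, keep)
}

# per-plant survival weight; calls at the selected loci must be non-missing
.selection_weights <- function(geno, markers, sel) {
  i1 <- which(markers$chrom == sel$chrom & markers$pos == sel$locus1_bp)
  i2 <- which(markers$chrom == sel$chrom & markers$pos == sel$locus2_bp)
  if (length(i1) != 1L || length(i2) != 1L)
    stop("selected loci must coincide with genotyped markers")
  a1 <- geno[, i1]
  a2 <- geno[, i2]
  if (anyNA(a1) || anyNA(a2))
    stop("missing genotype calls at a selected locus; apply selection before degrading data")
  ifelse(a1 == sel$unfavored1, sel$s1, 1) *
    ifelse(a2 == sel$unfavored2, sel$s2, 1)
}

.subset_population <- function(pop, keep) {
  pop$geno <- pop$geno[keep, , drop = FALSE]
  if (!is.null(pop$truth)) {
    pop$truth$co_positions <- lapply(pop$truth$co_positions,
                                     function(l) l[keep])
    pop$truth$start_allele <- lapply(pop$truth$start_allele,
                                     function(v) v[keep])
  }
  pop
}

#' Degrade genotype calls with missing data and genotyping errors
#'
#' Independently flips each call (`A` to `H` and vice versa) with probability
#' `error_rate`, then masks each call as missing with probability
#' `missing_rate`.
#'
#' @param geno Character genotype matrix (`"A"`/`"H"`, `NA` allowed).
#' @param missing_rate,error_rate Per-call probabilities in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The degraded matrix.
#' @export
inject_missing_and_errors <- function(geno, missing_rate = 0,
                                      error_rate = 0, seed = NULL) {
  for (rt in c(missing_rate, error_rate))
    if (!is.numeric(rt) || rt < 0 || rt >= 1)
      stop("rates must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(geno)
  if (error_rate > 0) {
    flip <- stats::runif(n) < error_rate & !is.na(geno)
    geno[flip] <- ifelse(geno[flip] == "A", "H", "A")
  }
  if (missing_rate > 0) geno[stats::runif(n) < missing_rate] <- NA_character_
  geno
}

#' Simulate a backcross population
#'
#' Full generative model for a backcross genotyping experiment: per plant and
#' chromosome, COs are placed on the bivalent by the stationary gamma renewal
#' process, thinned to the transmitted gamete, and scored at the marker
#' positions; optional two-locus gametic selection is applied by
#' accept-reject resampling (keeping the population size fixed at
#' `n_plants`); finally genotyping errors and missing data are injected.
#' Chromosomes are simulated independently.
#'
#' All randomness derives from `seed`; per-chromosome substreams are seeded
#' deterministically so populations are reproducible.
#'
#' @param chromosomes A [chromosome_spec()] or list of them.
#' @param n_plants Number of plants genotyped.
#' @param model A [gamma_model()], or a list of one per chromosome.
#' @param selection Optional [selection_model()] (one chromosome only).
#' @param missing_rate,error_rate Per-call degradation probabilities.
#' @param seed Integer master seed.
#' @return An object of class `backcross_population`: a list with `markers`
#'   (data.frame `chrom`, `pos`, `name`), `geno` (plants x markers character
#'   matrix), `chromosomes` (the specs, named), and `truth` (gamete CO
#'   positions in Morgans and starting alleles per chromosome -- kept so
#'   estimators can be validated against the generating process).
#' @export
simulate_backcross <- function(chromosomes, n_plants,
                               model = gamma_model(),
                               selection = NULL,
                               missing_rate = 0, error_rate = 0,
                               seed = 1L) {
  if (inherits(chromosomes, "chromosome_spec")) chromosomes <- list(chromosomes)
  stopifnot(all(vapply(chromosomes, inherits, TRUE, "chromosome_spec")))
  names(chromosomes) <- vapply(chromosomes, `[[`, "", "name")
  if (inherits(model, "gamma_model"))
    model <- rep(list(model), length(chromosomes))
  stopifnot(length(model) == length(chromosomes))

  markers <- do.call(rbind, lapply(chromosomes, function(sp)
    data.frame(chrom = sp$name, pos = sp$marker_positions,
               name = sprintf("%s_%09d", sp$name, as.integer(sp$marker_positions)),
               stringsAsFactors = FALSE)))
  rownames(markers) <- NULL

  geno <- matrix(NA_character_, nrow = n_plants, ncol = nrow(markers),
                 dimnames = list(sprintf("plant_%05d", seq_len(n_plants)),
                                 markers$name))
  truth_pos <- vector("list", length(chromosomes))
  truth_start <- vector("list", length(chromosomes))
  names(truth_pos) <- names(truth_start) <- names(chromosomes)

  for (ci in seq_along(chromosomes)) {
    sp <- chromosomes[[ci]]
    set.seed((seed %% 1000003L) * 1009L + ci)
    sel_here <- if (!is.null(selection) && selection$chrom == sp$name)
      selection else NULL
    res <- .sim_chromosome(sp, model[[ci]]$nu, n_plants, sel_here)
    cols <- which(markers$chrom == sp$name)
    geno[, cols] <- res$calls
    truth_pos[[ci]] <- res$pos
    truth_start[[ci]] <- res$start
  }

  set.seed((seed %% 1000003L) * 1009L + length(chromosomes) + 1L)
  geno <- inject_missing_and_errors(geno, missing_rate, error_rate)

  structure(list(markers = markers, geno = geno, chromosomes = chromosomes,
                 truth = list(co_positions = truth_pos,
                              start_allele = truth_start,
                              seed = seed)),
            class = "backcross_population")
}

# simulate one chromosome for n plants, with optional gametic selection by
# accept-reject (same conditional law as filtering a larger population)
.sim_chromosome <- function(sp, nu, n_plants, sel) {
  g_mark <- sp$genetic_map(sp$marker_positions)
  m <- length(g_mark)
  if (!is.null(sel)) {
    i1 <- which(sp$marker_positions == sel$locus1_bp)
    i2 <- which(sp$marker_positions == sel$locus2_bp)
    if (length(i1) != 1L || length(i2) != 1L)
      stop("selected loci must coincide with markers of their chromosome")
  }
  calls <- matrix(NA_character_, n_plants, m)
  pos_out <- vector("list", n_plants)
  start_out <- character(n_plants)
  filled <- 0L
  while (filled < n_plants) {
    batch <- max(64L, ceiling((n_plants - filled) * 1.6))
    biv <- .sim_bivalents(sp$genetic_length, nu, batch)
    gam <- lapply(biv, function(x) x[stats::runif(length(x)) < 0.5])
    start <- ifelse(stats::runif(batch) < 0.5, "A", "H")
    cm <- matrix("A", batch, m)
    for (j in seq_len(batch)) {
      n_before <- findInterval(g_mark, gam[[j]])
      flip <- n_before %% 2L == 1L
      other <- if (start[j] == "A") "H" else "A"
      cm[j, ] <- ifelse(flip, other, start[j])
    }
    if (!is.null(sel)) {
      w <- ifelse(cm[, i1] == sel$unfavored1, sel$s1, 1) *
        ifelse(cm[, i2] == sel$unfavored2, sel$s2, 1)
      keep <- which(stats::runif(batch) < w)
    } else keep <- seq_len(batch)
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), n_plants - filled))]
      idx <- filled + seq_along(take)
      calls[idx, ] <- cm[take, , drop = FALSE]
      pos_out[idx] <- gam[take]
      start_out[idx] <- start[take]
      filled <- filled + length(take)
    }
  }
  list(calls = calls, pos = pos_out, start = start_out)
}

#' @export
print.backcross_population <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf(
    "Backcross population: %d plants x %d markers on %d chromosome(s), %.1f%% missing\n",
    nrow(x$geno), ncol(x$geno), length(x$chromosomes), 100 * miss))
  invisible(x)
}

#' Synthetic genomic feature tracks and epigenetic windows
#'
#' Generates per-interval feature densities with the positional structure the
#' association analysis probes: GC content and gene density increase, TE
#' density decreases from centromere to telomere along each arm, while the
#' CpG ratio has no positional trend.  Also tiles the chromosome into 2 kb
#' windows carrying the average presence of euchromatic histone marks
#' (H3K4me3/H3K27me3-like), low inside the pericentromeric span -- the input
#' for heterochromatin inference.
#'
#' @param spec A [chromosome_spec()]; intervals are the marker intervals.
#' @param gradients Named list overriding defaults; each element is
#'   `c(base, slope, sd)` for features `gc`, `gene`, `te`, `cpg` (slope is the
#'   change from centromere to telomere along an arm).
#' @param window_bp Epigenetic window size in bp (default 2000).
#' @param seed Optional integer seed.
#' @return List with `features` (data.frame: `chrom`, `left_bp`, `right_bp`,
#'   `midpoint`, `gc`, `cpg`, `gene`, `te`) and `windows` (BED-style
#'   data.frame: `chrom`, `start`, `end` 0-based half-open, `presence`).
#' @export
generate_feature_tracks <- function(spec, gradients = NULL,
                                    window_bp = 2000, seed = NULL) {
  stopifnot(inherits(spec, "chromosome_spec"))
  if (!is.null(seed)) set.seed(seed)
  defaults <- list(gc   = c(base = 0.33, slope = 0.07,  sd = 0.010),
                   gene = c(base = 0.40, slope = 0.25,  sd = 0.030),
                   te   = c(base = 0.45, slope = -0.38, sd = 0.030),
                   cpg  = c(base = 0.035, slope = 0,    sd = 0.004))
  if (!is.null(gradients)) defaults[names(gradients)] <- gradients
  mp <- spec$marker_positions
  left <- mp[-length(mp)]
  right <- mp[-1L]
  mid <- (left + right) / 2
  cen <- spec$centromere_span
  # normalized distance from the centromere edge to the telomere, per arm
  d <- ifelse(mid < cen[1], (cen[1] - mid) / max(cen[1] - 1, 1),
       ifelse(mid > cen[2],
              (mid - cen[2]) / max(spec$physical_length - cen[2], 1), 0))
  feat <- function(p) pmin(0.99, pmax(0.001,
    p["base"] + p["slope"] * d + stats::rnorm(length(d), 0, p["sd"])))
  features <- data.frame(chrom = spec$name, left_bp = left, right_bp = right,
                         midpoint = mid,
                         gc = feat(defaults$gc), cpg = feat(defaults$cpg),
                         gene = feat(defaults$gene), te = feat(defaults$te),
                         stringsAsFactors = FALSE)
  starts <- seq(0, spec$physical_length - 1, by = window_bp)
  ends <- pmin(starts + window_bp, spec$physical_length)
  wmid <- (starts + ends) / 2
  in_cen <- wmid >= cen[1] & wmid <= cen[2]
  presence <- ifelse(in_cen,
                     stats::plogis(stats::rnorm(length(wmid), stats::qlogis(0.05), 0.5)),
                     stats::plogis(stats::rnorm(length(wmid), stats::qlogis(0.75), 0.7)))
  windows <- data.frame(chrom = spec$name, start = starts, end = ends,
                        presence = presence, stringsAsFactors = FALSE)
  list(features = features, windows = windows)
}
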