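#' Study-scale default chromosome parameters
#'
#' Five chromosomes emulating the *Arabidopsis thaliana* backcross design:
#' physical sizes 18.6-30.4 Mb, pericentromeric spans, ~380 markers split
#' proportionally to physical length, and sex-specific genetic lengths and
#' interference strengths at the values measured for the male and female
#' maps (e.g. chromosome 1: 142.4 cM male, 81.3 cM female; nu 2.6 male,
#' 2.7 female).
#'
#' @return data.frame, one row per chromosome: `name`, `physical_Mb`,
#'   `cen_lo_Mb`, `cen_hi_Mb`, `n_markers`, `L_male`, `L_female` (Morgans),
#'   `nu_male`, `nu_female`.
#' @export
study_chromosome_table <- function() {
  data.frame(
    name = paste0("chr", 1:5),
    physical_Mb = c(30.4, 19.7, 23.5, 18.6, 27.0),
    cen_lo_Mb = c(13.7, 2.5, 12.5, 2.8, 11.0),
    cen_hi_Mb = c(15.9, 3.8, 14.8, 4.1, 13.3),
    n_markers = c(97L, 63L, 75L, 59L, 86L),
    L_male = c(1.4236, 0.945, 1.0678, 0.855, 1.2895),
    L_female = c(0.8129, 0.595, 0.6430, 0.550, 0.7190),
    nu_male = c(2.6, 2.5, 2.5, 3.5, 3.0),
    nu_female = c(2.7, 2.8, 2.6, 4.1, 3.5),
    stringsAsFactors = FALSE)
}

# build chromosome_spec / gamma_model lists for one sex from the table
.specs_for_sex <- function(tab, sex) {
  L <- if (sex == "male") tab$L_male else tab$L_female
  nu <- if (sex == "male") tab$nu_male else tab$nu_female
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    P <- tab$physical_Mb[i] * 1e6
    chromosome_spec(tab$name[i], genetic_length = L[i], physical_length = P,
                    marker_positions = round(seq(1, P,
                                                 length.out = tab$n_markers[i])),
                    centromere_span = c(tab$cen_lo_Mb[i], tab$cen_hi_Mb[i]) * 1e6)
  })
  models <- lapply(nu, gamma_model)
  list(specs = specs, models = models)
}

#' Pipeline run configuration
#'
#' Bundles the simulation and analysis parameters of a full pipeline run.
#' Analysis thresholds default to the standard choices: distortion band
#' half-width 2.33 sigma, heterochromatin presence threshold 0.2,
#' Benjamini-Hochberg level 0.05, truncation fractions 0.30 and 0.50.
#'
#' @param chromosomes Chromosome parameter table (default
#'   [study_chromosome_table()]).
#' @param n_plants_male,n_plants_female Population sizes (defaults 1505,
#'   1507).
#' @param missing_rate,error_rate Genotyping degradation rates.
#' @param selection Optional list `(chrom, locus1_bp, locus2_bp, s1, s2,
#'   unfavored1, unfavored2)` describing male-side gametic selection; loci
#'   snap to the nearest marker.  `NULL` disables selection and the
#'   distortion correction.
#' @param bh_q,het_threshold,truncations,correction_grid_step Analysis
#'   thresholds.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(chromosomes = study_chromosome_table(),
                       n_plants_male = 1505L, n_plants_female = 1507L,
                       missing_rate = 0.02, error_rate = 0.001,
                       selection = NULL,
                       bh_q = 0.05, het_threshold = 0.2,
                       truncations = c(0.30, 0.50),
                       correction_grid_step = 0.1,
                       seed = 1L) {
  structure(list(chromosomes = chromosomes,
                 n_plants_male = n_plants_male,
                 n_plants_female = n_plants_female,
                 missing_rate = missing_rate, error_rate = error_rate,
                 selection = selection, bh_q = bh_q,
                 het_threshold = het_threshold, truncations = truncations,
                 correction_grid_step = correction_grid_step,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full crossover-landscape pipeline
#'
#' Simulate male and female backcross populations, then run every analysis
#' stage: QC (singleton flagging), per-interval maps and chromosome lengths
#' by both estimators, male/female ratios with confidence intervals,
#' segregation-distortion profile (with the two-locus correction when
#' selection is configured), Poisson goodness-of-fit and gamma-interference
#' fits per chromosome and sex, heterochromatin inference, hot/cold
#' classification, male/female interval comparison, rate-feature
#' associations, and the chromosome-size scaling fits.  The run is
#' deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   interval tables and the feature/epigenetic tracks there.
#' @param verbose Log stage progress to stderr.
#' @return The report, a nested list.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  tab <- config$chromosomes
  report <- list(schema = "1.0", seed = config$seed,
                 params = config[setdiff(names(config), "chromosomes")])
  pops <- list(); itabs <- list(); lengths_sw <- list()
  sexes <- c("male", "female")

  for (sex in sexes) {
    say("stage simulate [%s]", sex)
    sm <- .specs_for_sex(tab, sex)
    sel <- NULL
    if (!is.null(config$selection) && sex == "male") {
      s <- config$selection
      sp <- sm$specs[[which(tab$name == s$chrom)]]
      snap <- function(bp) sp$marker_positions[which.min(abs(sp$marker_positions - bp))]
      sel <- selection_model(s$chrom, snap(s$locus1_bp), snap(s$locus2_bp),
                             s$s1, s$s2,
                             unfavored1 = if (is.null(s$unfavored1)) "A" else s$unfavored1,
                             unfavored2 = if (is.null(s$unfavored2)) "H" else s$unfavored2)
    }
    n <- if (sex == "male") config$n_plants_male else config$n_plants_female
    pop <- simulate_backcross(sm$specs, n, model = sm$models, selection = sel,
                              missing_rate = config$missing_rate,
                              error_rate = config$error_rate,
                              seed = config$seed + match(sex, sexes))
    pops[[sex]] <- pop

    say("stage qc/map [%s]", sex)
    itab <- interval_table(pop)
    itabs[[sex]] <- itab
    qc <- flag_singletons(pop)
    chrom_out <- list()
    for (ch in tab$name) {
      Ls <- chromosome_length_interval_sum(pop, ch)
      Lc <- chromosome_length_switch_count(pop, ch)
      lengths_sw[[sex]][[ch]] <- Lc
      cls <- co_count_distribution(pop, ch)
      gof <- poisson_gof_test(cls, Lc$L_G)
      say("stage interference [%s %s]", sex, ch)
      nu_fit <- fit_nu_chromosome(pop, ch)
      chrom_out[[ch]] <- list(
        L_interval_sum_cM = 100 * Ls$L_G,
        L_switch_count_cM = 100 * Lc$L_G,
        L_variance = Lc$variance,
        co_classes = as.list(cls),
        poisson_p = gof$p_value,
        nu = nu_fit$nu, nu_ci95 = nu_fit$ci95, loglik = nu_fit$loglik)
    }
    prof <- distortion_profile(pop)
    dist_out <- list(n_flagged = sum(prof$flagged))
    if (!is.null(sel)) {
      say("stage distortion correction [%s]", sex)
      fitS <- fit_selection_coefficients(pop, sel$chrom, sel$locus1_bp,
                                         sel$locus2_bp,
                                         grid_step = config$correction_grid_step)
      corr <- corrected_map_length(pop, sel$chrom, fitS)
      dist_out$correction <- list(
        chrom = sel$chrom, s1_star = fitS$s1, s2_star = fitS$s2,
        marginal_s = as.list(fitS$marginal),
        naive_cM = 100 * corr$naive_L_G,
        corrected_cM = 100 * corr$corrected_L_G)
    } else dist_out$correction <- "skipped (no selection configured)"

    report[[sex]] <- list(n_plants = nrow(pop$geno),
                          n_markers = ncol(pop$geno),
                          singletons_flagged = qc$n,
                          chromosomes = chrom_out,
                          distortion = dist_out)
  }

  say("stage ratios")
  cen_spans <- stats::setNames(lapply(seq_len(nrow(tab)), function(i)
    c(tab$cen_lo_Mb[i], tab$cen_hi_Mb[i]) * 1e6), tab$name)
  ratios <- lapply(tab$name, function(ch) {
    r <- mf_ratio_ci(lengths_sw$male[[ch]], lengths_sw$female[[ch]])
    tt <- compare_lengths_ttest(lengths_sw$male[[ch]]$counts,
                                lengths_sw$female[[ch]]$counts)
    list(chrom = ch, f = r$f, ci95 = r$ci95, t_test_p = tt)
  })
  genome_m <- list(L_G = sum(vapply(lengths_sw$male, `[[`, 0, "L_G")),
                   variance = sum(vapply(lengths_sw$male, `[[`, 0, "variance")))
  genome_f <- list(L_G = sum(vapply(lengths_sw$female, `[[`, 0, "L_G")),
                   variance = sum(vapply(lengths_sw$female, `[[`, 0, "variance")))
  gr <- mf_ratio_ci(genome_m, genome_f)
  report$ratios <- list(per_chromosome = ratios,
                        genome = list(f = gr$f, ci95 = gr$ci95,
                                      male_cM = 100 * genome_m$L_G,
                                      female_cM = 100 * genome_f$L_G))

  say("stage features")
  feat_report <- list()
  tracks <- list()
  for (sex in sexes) {
    sm <- .specs_for_sex(tab, sex)
    tr <- lapply(sm$specs, generate_feature_tracks,
                 seed = config$seed + 97L)
    names(tr) <- tab$name
    tracks[[sex]] <- tr
    features <- do.call(rbind, lapply(tr, `[[`, "features"))
    windows <- do.call(rbind, lapply(tr, `[[`, "windows"))
    itab <- itabs[[sex]]
    itab <- infer_heterochromatin(windows, itab,
                                  threshold = config$het_threshold)
    itab <- classify_hot_cold(itab, cen_spans)
    itabs[[sex]] <- itab
    eu <- !itab$heterochromatic
    assoc <- lapply(c("gc", "cpg", "gene", "te"), function(fn) {
      by_chr <- lapply(tab$name, function(ch) {
        sel <- eu & itab$chrom == ch
        a <- associate_rate_feature(itab$cM_per_Mb[sel], features[[fn]][sel])
        list(chrom = ch, slope = a$slope, r_squared = a$r_squared,
             p_value = a$p_value)
      })
      list(feature = fn, per_chromosome = by_chr)
    })
    feat_report[[sex]] <- list(hot = sum(itab$hot), cold = sum(itab$cold),
                               associations = assoc)
  }
  mf_cmp <- compare_intervals_mf(itabs$male, itabs$female, q = config$bh_q)
  report$features <- feat_report
  report$features$mf_significant_intervals <- sum(mf_cmp$significant)

  say("stage scaling")
  scaling <- lapply(sexes, function(sex) {
    L_G <- vapply(lengths_sw[[sex]], `[[`, 0, "L_G")
    v <- vapply(lengths_sw[[sex]], `[[`, 0, "variance")
    lf <- test_li_freudenberg(L_G, tab$physical_Mb, v)
    lin <- fit_linear(tab$physical_Mb, 2 * L_G)
    thr <- if (nrow(tab) >= 3L) {
      f <- fit_threshold_model(L_G, tab$physical_Mb, v)
      list(a = f$a, L_thr = f$L_thr, chi2 = f$chi2, p_value = f$p_value)
    } else "skipped (fewer than 3 chromosomes)"
    list(sex = sex,
         linear = lin,
         threshold = thr,
         li_freudenberg = list(a = lf$a, chi2 = lf$chi2,
                               p_value = lf$p_value))
  })
  names(scaling) <- sexes
  report$scaling <- scaling

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (sex in sexes) {
      write_interval_table(itabs[[sex]],
                           file.path(out_dir, paste0("intervals_", sex, ".tsv")))
      write_genotype_matrix(pops[[sex]],
                            file.path(out_dir, paste0("genotypes_", sex, ".tsv")))
      write_marker_map(pops[[sex]]$markers,
                       file.path(out_dir, paste0("markers_", sex, ".tsv")))
      wins <- do.call(rbind, lapply(tracks[[sex]], `[[`, "windows"))
      write_bed(wins, file.path(out_dir, paste0("epigenetic_", sex, ".bed")))
    }
  }
  invisible(report)
}
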