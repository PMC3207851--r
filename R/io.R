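#' Read a marker map
#'
#' Tab-separated file with columns `chrom`, `pos` (1-based bp), `name`.
#' Positions must be strictly increasing within a chromosome and names
#' unique; violations are rejected, never coerced.
#'
#' @param path File path.
#' @return data.frame with columns `chrom`, `pos`, `name`.
#' @export
read_marker_map <- function(path) {
  mm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "character"))
  if (!identical(names(mm), c("chrom", "pos", "name")))
    stop("marker map must have columns chrom, pos, name")
  if (anyDuplicated(mm$name))
    stop("duplicate marker name: ", mm$name[anyDuplicated(mm$name)])
  for (ch in unique(mm$chrom))
    if (is.unsorted(mm$pos[mm$chrom == ch], strictly = TRUE))
      stop("marker positions not strictly increasing on ", ch)
  mm
}

#' @rdname read_marker_map
#' @param markers data.frame as returned by [read_marker_map()].
#' @export
write_marker_map <- function(markers, path) {
  utils::write.table(markers[c("chrom", "pos", "name")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a backcross genotype matrix
#'
#' Tab-separated file: header `plant` followed by marker names, one row per
#' plant.  Calls are `A` (recurrent-parent homozygote), `H` (heterozygote);
#' missing data is `-` or `NA`.  Any other code, and any marker absent from
#' the map, is rejected with the offending cell named.
#'
#' @param path File path.
#' @param marker_map Marker map data.frame (`chrom`, `pos`, `name`).
#' @return A `backcross_population` (without simulation truth).
#' @export
read_genotype_matrix <- function(path, marker_map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1] != "plant") stop("first column must be 'plant'")
  mk <- names(tab)[-1]
  unknown <- setdiff(mk, marker_map$name)
  if (length(unknown))
    stop("markers absent from the map: ", paste(unknown, collapse = ", "))
  geno <- as.matrix(tab[, -1, drop = FALSE])
  rownames(geno) <- tab$plant
  geno[geno %in% c("-", "NA")] <- NA_character_
  bad <- which(!is.na(geno) & !geno %in% c("A", "H"), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid genotype code '%s' at plant '%s', marker '%s'",
                 geno[bad[1, 1], bad[1, 2]], rownames(geno)[bad[1, 1]],
                 colnames(geno)[bad[1, 2]]))
  # order columns by the map
  keep <- marker_map$name %in% mk
  geno <- geno[, marker_map$name[keep], drop = FALSE]
  structure(list(markers = marker_map[keep, , drop = FALSE],
                 geno = geno, chromosomes = NULL, truth = NULL),
            class = "backcross_population")
}

#' @rdname read_genotype_matrix
#' @param pop A `backcross_population`.
#' @export
write_genotype_matrix <- function(pop, path) {
  geno <- pop$geno
  geno[is.na(geno)] <- "-"
  tab <- data.frame(plant = rownames(geno), geno, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag singleton genotype calls
#'
#' A singleton is an isolated call that differs from both its nearest
#' non-missing neighbors on the same chromosome while those two neighbors
#' agree with each other -- the signature of a genotyping error (a real CO
#' pair tight enough to look like this is rare at typical marker spacing).
#' Chromosome-terminal calls cannot be singletons.
#'
#' @param pop A `backcross_population`.
#' @return List with `flags` (data.frame `plant`, `marker`, `chrom`) and
#'   `n` (total flagged calls).
#' @export
flag_singletons <- function(pop) {
  geno <- pop$geno
  markers <- pop$markers
  out_p <- character(0); out_m <- character(0); out_c <- character(0)
  for (ch in unique(markers$chrom)) {
    cols <- which(markers$chrom == ch)
    sub <- geno[, cols, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      idx <- which(!is.na(sub[i, ]))
      k <- length(idx)
      if (k < 3L) next
      a <- sub[i, idx]
      mid <- 2:(k - 1)
      sing <- a[mid] != a[mid - 1] & a[mid] != a[mid + 1] &
        a[mid - 1] == a[mid + 1]
      if (any(sing)) {
        j <- idx[mid[sing]]
        out_p <- c(out_p, rep(rownames(geno)[i], length(j)))
        out_m <- c(out_m, colnames(sub)[j])
        out_c <- c(out_c, rep(ch, length(j)))
      }
    }
  }
  flags <- data.frame(plant = out_p, marker = out_m, chrom = out_c,
                      stringsAsFactors = FALSE)
  list(flags = flags, n = nrow(flags))
}

#' Drop plants and markers with excessive missing data
#'
#' @param pop A `backcross_population`.
#' @param max_missing_frac Maximum tolerated missing fraction per plant and
#'   per marker (default 0.1).
#' @return The filtered population.
#' @export
filter_missing <- function(pop, max_missing_frac = 0.1) {
  keep_m <- colMeans(is.na(pop$geno)) <= max_missing_frac
  pop$geno <- pop$geno[, keep_m, drop = FALSE]
  pop$markers <- pop$markers[keep_m, , drop = FALSE]
  keep_p <- rowMeans(is.na(pop$geno)) <= max_missing_frac
  .subset_population(pop, keep_p)
}

#' Write / read an interval table
#'
#' One row per adjacent-marker interval; all numeric columns are written with
#' 6 significant digits and `NA` for undefined values (e.g. confidence bounds
#' at `N = 0`).  `write` then `read` is the identity up to that precision.
#'
#' @param table Interval data.frame (see [interval_table()]).
#' @param path File path.
#' @export
write_interval_table <- function(table, path) {
  tab <- table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, digits = 6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_interval_table
#' @export
read_interval_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Write BED intervals (0-based, half-open)
#'
#' @param bed data.frame whose first three columns are `chrom`, `start`,
#'   `end`; extra columns become BED score/name fields.
#' @param path File path.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
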