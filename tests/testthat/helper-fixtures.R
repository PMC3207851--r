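# shared fixtures, built in code

# small uniform chromosome: length in Morgans, physical 20 Mb
toy_spec <- function(L = 1.0, n_markers = 41, P = 20e6, name = "c1",
                     cen = NULL, genetic_map = NULL) {
  chromosome_spec(name, genetic_length = L, physical_length = P,
                  marker_positions = round(seq(1, P, length.out = n_markers)),
                  centromere_span = cen, genetic_map = genetic_map)
}

# hand-built population from a character matrix (rows plants, cols markers)
toy_population <- function(calls, chrom = "c1", positions = NULL) {
  m <- ncol(calls)
  if (is.null(positions)) positions <- seq(1e6, m * 1e6, by = 1e6)
  markers <- data.frame(chrom = chrom, pos = positions,
                        name = sprintf("%s_%02d", chrom, seq_len(m)),
                        stringsAsFactors = FALSE)
  colnames(calls) <- markers$name
  rownames(calls) <- sprintf("p%03d", seq_len(nrow(calls)))
  structure(list(markers = markers, geno = calls, chromosomes = NULL,
                 truth = NULL),
            class = "backcross_population")
}

# brute-force Benjamini-Hochberg step-up: reject the smallest k p-values
# where k is the largest index with p_(k) <= k q / m
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- max(c(0L, which(ps <= seq_len(m) * q / m)))
  rej <- logical(m)
  if (k > 0L) rej[o[seq_len(k)]] <- TRUE
  rej
}
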