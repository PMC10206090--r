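#' Fixed-width genomic binning
#'
#' Tiles each chromosome with half-open, 0-based windows of `bin_size` base
#' pairs (the last window of a chromosome may be shorter). Bins are indexed
#' globally in file/argument order, chromosome by chromosome.
#'
#' @param chrom_names character vector of chromosome identifiers (unique).
#' @param chrom_lengths integer vector of chromosome lengths in base pairs.
#' @param bin_size window width in base pairs.
#' @return An object of class `genome_binning` with elements `chrom_names`,
#'   `chrom_lengths`, `bin_size`, `n_bins`, and per-bin vectors `bin_chrom`
#'   (1-based chromosome index), `bin_start`, `bin_end` (0-based half-open),
#'   plus `r` (relative arm position, `NA` until
#'   [compute_relative_positions()] is called) and `centromere_pos`.
#' @export
genome_binning <- function(chrom_names, chrom_lengths, bin_size) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) == 0L) stop("no chromosomes supplied")
  if (anyDuplicated(chrom_names)) stop("duplicate chromosome name")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be positive")

  nb <- as.integer(ceiling(chrom_lengths / bin_size))
  bin_chrom <- rep.int(seq_along(chrom_names), nb)
  ord <- unlist(lapply(nb, function(k) seq_len(k) - 1L), use.names = FALSE)
  bin_start <- ord * bin_size
  bin_end <- pmin(bin_start + bin_size, chrom_lengths[bin_chrom])

  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = chrom_lengths,
      bin_size = bin_size,
      n_bins = sum(nb),
      bins_per_chrom = nb,
      bin_chrom = bin_chrom,
      bin_start = bin_start,
      bin_end = bin_end,
      centromere_pos = rep(NA_real_, length(chrom_names)),
      r = rep(NA_real_, sum(nb))
    ),
    class = "genome_binning"
  )
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf(
    "genome_binning: %d chromosomes, %d bins of %g bp%s\n",
    length(x$chrom_names), x$n_bins, x$bin_size,
    if (all(is.na(x$r))) " (relative positions unset)" else ""
  ))
  invisible(x)
}

#' Read a UCSC-style chrom.sizes file and build a binning
#'
#' @param path two whitespace-delimited columns: chromosome name, length (bp).
#' @param bin_size window width in base pairs.
#' @return A [genome_binning()] object (relative positions unset).
#' @export
load_chrom_sizes <- function(path, bin_size) {
  dt <- tryCatch(
    suppressWarnings(data.table::fread(path, header = FALSE, select = 1:2,
                                       colClasses = list(character = 1))),
    error = function(e) stop("cannot read chrom.sizes file: ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) stop("empty chrom.sizes file: ", path)
  len <- suppressWarnings(as.numeric(dt[[2]]))
  if (any(is.na(len))) stop("non-numeric chromosome length in ", path)
  genome_binning(dt[[1]], len, bin_size)
}

#' Read a centromere coordinates file
#'
#' @param path two whitespace-delimited columns: chromosome name, centromere
#'   position (bp).
#' @return named numeric vector of positions.
#' @export
load_centromeres <- function(path) {
  dt <- data.table::fread(path, header = FALSE, select = 1:2,
                          colClasses = list(character = 1))
  stats::setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' Compute per-bin relative arm positions
#'
#' Assigns each bin its relative position `r` along the chromosome arm,
#' running from -0.5 at the centromere to +0.5 at the telomere. For a bin
#' whose midpoint lies at arm-distance `d` from the centromere on an arm of
#' length `A`, `r = d/A - 0.5`. Chromosomes without a supplied centromere are
#' treated as acrocentric with the centromere at coordinate 0, so `r`
#' reduces to `midpoint/length - 0.5`.
#'
#' @param binning a [genome_binning()] object.
#' @param centromeres optional named numeric vector of centromere positions
#'   (bp), names matching chromosome names. Positions must lie within the
#'   chromosome.
#' @return the binning with `r` filled in and `centromere_pos` recorded.
#' @export
compute_relative_positions <- function(binning, centromeres = NULL) {
  stopifnot(inherits(binning, "genome_binning"))
  cen <- rep(0, length(binning$chrom_names))
  if (!is.null(centromeres)) {
    idx <- match(names(centromeres), binning$chrom_names)
    known <- !is.na(idx)
    if (any(centromeres[known] < 0 |
            centromeres[known] > binning$chrom_lengths[idx[known]]))
      stop("centromere position outside chromosome")
    cen[idx[known]] <- as.numeric(centromeres[known])
  }
  mid <- (binning$bin_start + binning$bin_end) / 2
  cpos <- cen[binning$bin_chrom]
  clen <- binning$chrom_lengths[binning$bin_chrom]
  arm_len <- ifelse(mid >= cpos, clen - cpos, cpos)
  d <- abs(mid - cpos)
  r <- d / arm_len - 0.5
  # degenerate arm (centromere at a chromosome end): the other arm spans all
  r[!is.finite(r)] <- -0.5
  binning$r <- pmin(pmax(r, -0.5), 0.5)
  binning$centromere_pos <- cen
  binning
}

#' Map genomic coordinates to global bin indices
#'
#' @param binning a [genome_binning()] object.
#' @param chrom chromosome names (character vector).
#' @param pos 0-based positions.
#' @return 1-based global bin indices; `NA` for unknown chromosomes.
#' @export
bin_index <- function(binning, chrom, pos) {
  ci <- match(chrom, binning$chrom_names)
  off <- c(0L, cumsum(binning$bins_per_chrom))
  bad <- !is.na(ci) & (pos < 0 | pos >= binning$chrom_lengths[ci])
  if (any(bad))
    stop("position outside chromosome (assembly mismatch?): e.g. ",
         chrom[which(bad)[1]], ":", pos[which(bad)[1]])
  out <- off[ci] + as.integer(floor(pos / binning$bin_size)) + 1L
  out[is.na(ci)] <- NA_integer_
  out
}
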