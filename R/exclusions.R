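#' Excluded bins and region groups
#'
#' Holds the two exclusion mechanisms of the model: individually blacklisted
#' bins (assembly artifacts; their score rows are fixed at zero) and
#' "region groups" (e.g. partners of a genomic translocation, whose
#' within-group trans contacts behave like cis contacts and are dropped from
#' the likelihood).
#'
#' @param blacklist integer vector of global bin indices (1-based).
#' @param groups list of integer vectors of global bin indices; a bin may
#'   belong to at most one group.
#' @return an object of class `exclusion_set`.
#' @export
exclusion_set <- function(blacklist = integer(0), groups = list()) {
  blacklist <- sort(unique(as.integer(blacklist)))
  groups <- lapply(groups, function(g) sort(unique(as.integer(g))))
  all_grp <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_grp))
    stop("a bin appears in more than one region group")
  structure(list(blacklist = blacklist, groups = groups),
            class = "exclusion_set")
}

#' @export
print.exclusion_set <- function(x, ...) {
  cat(sprintf("exclusion_set: %d blacklisted bins, %d region groups\n",
              length(x$blacklist), length(x$groups)))
  invisible(x)
}

bins_overlapping_intervals <- function(binning, chrom, start, end) {
  # BED-style 0-based half-open intervals -> overlapped global bin indices
  ci <- match(chrom, binning$chrom_names)
  off <- c(0L, cumsum(binning$bins_per_chrom))
  out <- vector("list", length(chrom))
  for (q in seq_along(chrom)) {
    if (is.na(ci[q])) next
    s <- max(0, start[q])
    e <- min(binning$chrom_lengths[ci[q]], end[q])
    if (e <= s) next
    b0 <- floor(s / binning$bin_size)
    b1 <- floor((e - 1) / binning$bin_size)
    out[[q]] <- off[ci[q]] + seq.int(b0, b1) + 1L
  }
  out
}

#' Read a BED blacklist into bin indices
#'
#' Every bin overlapping a blacklist interval is excluded.
#'
#' @param path BED file (>= 3 columns, 0-based half-open).
#' @param binning a [genome_binning()] object.
#' @return integer vector of global bin indices.
#' @export
load_blacklist <- function(path, binning) {
  dt <- data.table::fread(path, header = FALSE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("blacklist BED needs at least 3 columns")
  sort(unique(unlist(
    bins_overlapping_intervals(binning, dt[[1]],
                               as.numeric(dt[[2]]), as.numeric(dt[[3]])),
    use.names = FALSE
  )))
}

#' Read region groups from a BED file
#'
#' Intervals sharing the same name-column value form one region group; all
#' trans contacts between bins of the same group are excluded from the
#' likelihood.
#'
#' @param path BED file with the group identifier in column 4.
#' @param binning a [genome_binning()] object.
#' @return list of integer vectors of global bin indices, one per group.
#' @export
load_region_groups <- function(path, binning) {
  dt <- data.table::fread(path, header = FALSE,
                          colClasses = list(character = c(1, 4)))
  if (ncol(dt) < 4L) stop("region-group BED needs a name column (column 4)")
  hits <- bins_overlapping_intervals(binning, dt[[1]],
                                     as.numeric(dt[[2]]), as.numeric(dt[[3]]))
  split_bins <- split(hits, dt[[4]])
  lapply(split_bins, function(x) sort(unique(unlist(x, use.names = FALSE))))
}

# per-bin group id (0-based for the C++ core; -1L = no group)
group_id_vector <- function(binning, exclusions) {
  g <- rep(-1L, binning$n_bins)
  if (!is.null(exclusions)) {
    for (q in seq_along(exclusions$groups))
      g[exclusions$groups[[q]]] <- q - 1L
  }
  g
}

blacklist_vector <- function(binning, exclusions) {
  b <- rep(FALSE, binning$n_bins)
  if (!is.null(exclusions)) b[exclusions$blacklist] <- TRUE
  b
}
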