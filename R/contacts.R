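#' Sparse trans-only contact table
#'
#' Stores aggregated inter-chromosomal (trans) Hi-C contact counts per bin
#' pair. Only pairs with `i < j` on different chromosomes are kept; access is
#' symmetric by construction.
#'
#' @param i,j 1-based global bin indices (any order within each pair).
#' @param count nonnegative integer counts per pair.
#' @param binning a [genome_binning()] object.
#' @return an object of class `contact_table` with integer vectors `i`, `j`
#'   (i < j), numeric `count`, the `binning`, and `total_trans`.
#' @export
contact_table <- function(i, j, count, binning) {
  stopifnot(inherits(binning, "genome_binning"))
  i <- as.integer(i); j <- as.integer(j); count <- as.numeric(count)
  stopifnot(length(i) == length(j), length(i) == length(count))
  if (any(count < 0)) stop("negative contact count")
  keep <- count > 0
  i <- i[keep]; j <- j[keep]; count <- count[keep]
  if (any(i < 1 | i > binning$n_bins | j < 1 | j > binning$n_bins))
    stop("bin index out of range")
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  if (any(binning$bin_chrom[i] == binning$bin_chrom[j]))
    stop("contact_table accepts only inter-chromosomal pairs")
  if (length(i)) {
    dt <- data.table::data.table(i = i, j = j, n = count)
    dt <- dt[, list(n = sum(n)), by = c("i", "j")]
    data.table::setorderv(dt, c("i", "j"))
    i <- dt$i; j <- dt$j; count <- dt$n
  }
  structure(
    list(i = i, j = j, count = count, binning = binning,
         total_trans = sum(count)),
    class = "contact_table"
  )
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("contact_table: %d trans bin pairs, %g read pairs (%d bins)\n",
              length(x$i), x$total_trans, x$binning$n_bins))
  invisible(x)
}

#' Per-bin total trans read count
#'
#' @param table a [contact_table()].
#' @return numeric vector of length `n_bins`: read ends per bin.
#' @export
bin_totals <- function(table) {
  n <- table$binning$n_bins
  tot <- numeric(n)
  if (length(table$i)) {
    a <- tapply(table$count, table$i, sum)
    b <- tapply(table$count, table$j, sum)
    tot[as.integer(names(a))] <- tot[as.integer(names(a))] + a
    tot[as.integer(names(b))] <- tot[as.integer(names(b))] + b
  }
  tot
}

# drop pairs touching blacklisted bins or inside one region group;
# returns the filtered table with a `filter_counts` attribute
apply_exclusions <- function(table, exclusions) {
  if (is.null(exclusions)) return(table)
  bl <- blacklist_vector(table$binning, exclusions)
  gid <- group_id_vector(table$binning, exclusions)
  in_bl <- bl[table$i] | bl[table$j]
  in_grp <- !in_bl & gid[table$i] >= 0L & gid[table$i] == gid[table$j]
  keep <- !(in_bl | in_grp)
  out <- contact_table(table$i[keep], table$j[keep], table$count[keep],
                       table$binning)
  attr(out, "filter_counts") <- c(
    blacklisted = sum(table$count[in_bl]),
    grouped = sum(table$count[in_grp])
  )
  out
}

#' Read Hi-C read pairs into a binned trans contact table
#'
#' Accepts 4DN-style `.pairs` text (header lines starting with `#`; columns
#' readID, chrom1, pos1, chrom2, pos2, optionally strands) or a headerless
#' 4-column dialect (chrom1, pos1, chrom2, pos2). Positions are 1-based in
#' the file and mapped to 0-based half-open bins. Cis pairs, pairs touching
#' blacklisted bins, and pairs with both ends in the same region group are
#' discarded; pairs on chromosomes absent from the binning are skipped with
#' a warning.
#'
#' @param path pairs file.
#' @param binning a [genome_binning()] object.
#' @param exclusions optional [exclusion_set()].
#' @return a [contact_table()]; attribute `filter_counts` reports how many
#'   read pairs were dropped as cis / blacklisted / grouped / unknown
#'   chromosome, so that input reads are exactly accounted for.
#' @export
load_pairs <- function(path, binning, exclusions = NULL) {
  # header lines start with '#' and sit at the top of the file
  n_header <- 0L
  repeat {
    chunk <- readLines(path, n = n_header + 512L)
    if (length(chunk) <= n_header) break  # file exhausted: all headers
    fresh <- chunk[(n_header + 1L):length(chunk)]
    first_data <- which(!startsWith(fresh, "#"))
    if (length(first_data)) { n_header <- n_header + first_data[1] - 1L; break }
    n_header <- length(chunk)
  }
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, skip = n_header, fill = TRUE,
                      colClasses = list(character = 1)),
    error = function(e) {
      if (grepl("empty|rows", conditionMessage(e)))
        data.table::data.table()
      else stop(e)
    })
  if (nrow(dt) == 0L) {
    empty <- contact_table(integer(0), integer(0), numeric(0), binning)
    attr(empty, "filter_counts") <-
      c(cis = 0, blacklisted = 0, grouped = 0, unknown_chrom = 0)
    return(empty)
  }
  if (ncol(dt) >= 5L) {
    # 4DN layout: readID chrom1 pos1 chrom2 pos2 [strand1 strand2 ...]
    c1 <- as.character(dt[[2]]); p1 <- suppressWarnings(as.numeric(dt[[3]]))
    c2 <- as.character(dt[[4]]); p2 <- suppressWarnings(as.numeric(dt[[5]]))
  } else if (ncol(dt) == 4L) {
    # headerless dialect: chrom1 pos1 chrom2 pos2
    c1 <- as.character(dt[[1]]); p1 <- suppressWarnings(as.numeric(dt[[2]]))
    c2 <- as.character(dt[[3]]); p2 <- suppressWarnings(as.numeric(dt[[4]]))
  } else {
    stop("unrecognized pairs format: need >= 4 columns")
  }
  bad <- is.na(p1) | is.na(p2)
  if (any(bad)) stop("malformed pairs line (non-numeric position), e.g. data line ",
                     which(bad)[1])

  known <- c1 %in% binning$chrom_names & c2 %in% binning$chrom_names
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    warning(n_unknown, " pairs on chromosomes absent from the binning were skipped")
  c1 <- c1[known]; p1 <- p1[known]; c2 <- c2[known]; p2 <- p2[known]

  # 1-based file positions -> 0-based coordinates
  bi <- bin_index(binning, c1, p1 - 1)
  bj <- bin_index(binning, c2, p2 - 1)
  cis <- binning$bin_chrom[bi] == binning$bin_chrom[bj]
  n_cis <- sum(cis)
  bi <- bi[!cis]; bj <- bj[!cis]

  tab <- contact_table(bi, bj, rep(1, length(bi)), binning)
  tab <- apply_exclusions(tab, exclusions)
  fc <- attr(tab, "filter_counts")
  attr(tab, "filter_counts") <- c(
    cis = n_cis,
    blacklisted = if (is.null(fc)) 0 else unname(fc["blacklisted"]),
    grouped = if (is.null(fc)) 0 else unname(fc["grouped"]),
    unknown_chrom = n_unknown
  )
  tab
}

#' Write a contact table as a `.pairs` text file
#'
#' Emits one synthetic read pair per count, placed at the bin midpoints
#' (1-based positions), with a 4DN-style header. Round-trips through
#' [load_pairs()] at the same binning.
#'
#' @param table a [contact_table()].
#' @param path output file.
#' @export
write_pairs <- function(table, path) {
  b <- table$binning
  writeLines(c("## pairs format v1.0",
               "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2"),
             path)
  if (length(table$i)) {
    reps <- as.integer(round(table$count))
    i <- rep.int(table$i, reps); j <- rep.int(table$j, reps)
    mid <- function(idx) floor((b$bin_start[idx] + b$bin_end[idx]) / 2) + 1
    dt <- data.table::data.table(
      readID = sprintf("read%d", seq_along(i)),
      chrom1 = b$chrom_names[b$bin_chrom[i]], pos1 = mid(i),
      chrom2 = b$chrom_names[b$bin_chrom[j]], pos2 = mid(j),
      strand1 = "+", strand2 = "-"
    )
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  }
  invisible(path)
}
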