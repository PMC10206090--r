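#' Forward-simulate a trans contact table
#'
#' Draws, for every eligible trans bin pair, an observed count
#' `N_ij ~ Poisson(depth_scale * R_ij * sum_k C_ik C_jk)` and keeps the
#' nonzero draws. Blacklisted bins are zeroed out of the truth; pairs inside
#' one region group are not generated. Deterministic given `seed`.
#'
#' @param binning a [genome_binning()] with relative arm positions.
#' @param C nonnegative truth score matrix (n x M).
#' @param alpha,beta Rabl coefficients of the generative model.
#' @param depth_scale multiplier on all expected counts (> 0).
#' @param seed integer seed.
#' @param exclusions optional [exclusion_set()].
#' @return a [contact_table()].
#' @export
simulate_contacts <- function(binning, C, alpha = 0, beta = 0,
                              depth_scale = 1, seed, exclusions = NULL) {
  stopifnot(inherits(binning, "genome_binning"), depth_scale > 0)
  if (missing(seed)) stop("a seed is required")
  if (all(is.na(binning$r)))
    stop("relative arm positions unset: call compute_relative_positions() first")
  C <- as.matrix(C)
  if (any(C < 0)) stop("truth scores must be nonnegative")
  if (nrow(C) != binning$n_bins) stop("truth matrix rows do not match binning")
  if (cpp_min_rabl(alpha, beta) <= 0)
    stop("Rabl coefficients give a non-positive factor on [-0.5, 0.5]^2")
  C[blacklist_vector(binning, exclusions), ] <- 0
  gid <- group_id_vector(binning, exclusions)

  set.seed(seed)
  nc <- length(binning$chrom_names)
  acc_i <- list(); acc_j <- list(); acc_n <- list(); q <- 0L
  bins_of <- split(seq_len(binning$n_bins), binning$bin_chrom)
  for (a in seq_len(nc - 1L)) {
    ia <- bins_of[[a]]
    ra <- binning$r[ia]
    for (b in seq.int(a + 1L, nc)) {
      ib <- bins_of[[b]]
      rb <- binning$r[ib]
      Rblk <- 1 + alpha * outer(ra, rb) +
        beta * outer(ra, rb, function(x, y) (x + y) * x * y)
      Fblk <- depth_scale * Rblk * (C[ia, , drop = FALSE] %*%
                                      t(C[ib, , drop = FALSE]))
      if (any(gid[ia] >= 0L)) {
        same <- outer(gid[ia], gid[ib],
                      function(x, y) x >= 0L & x == y)
        Fblk[same] <- 0
      }
      N <- stats::rpois(length(Fblk), Fblk)
      nz <- which(N > 0)
      if (length(nz)) {
        q <- q + 1L
        acc_i[[q]] <- ia[(nz - 1L) %% length(ia) + 1L]
        acc_j[[q]] <- ib[(nz - 1L) %/% length(ia) + 1L]
        acc_n[[q]] <- N[nz]
      }
    }
  }
  contact_table(unlist(acc_i), unlist(acc_j), unlist(acc_n), binning)
}

#' Expected total contacts of a generative model
#'
#' Closed-form `sum_ij depth_scale * R_ij * (C_i . C_j)` over eligible trans
#' pairs; used to calibrate `depth_scale` to a target sequencing depth.
#'
#' @inheritParams simulate_contacts
#' @return expected total read pairs.
#' @export
expected_total_contacts <- function(binning, C, alpha = 0, beta = 0,
                                    depth_scale = 1, exclusions = NULL) {
  C <- as.matrix(C)
  C[blacklist_vector(binning, exclusions), ] <- 0
  a <- list(r = binning$r, chrom = chrom0(binning),
            group = group_id_vector(binning, exclusions),
            n_chrom = length(binning$chrom_names),
            n_group = if (is.null(exclusions)) 0L else length(exclusions$groups))
  # -loglik of an all-zero-count table is exactly the total expected rate
  -cpp_loglik(integer(0), integer(0), numeric(0), C, a$r, a$chrom, a$group,
              a$n_chrom, a$n_group, alpha, beta) * depth_scale
}

#' Down-sample a contact table
#'
#' Keeps each read pair independently with probability `fraction` (binomial
#' thinning per bin pair), the exact distributional equivalent of sequencing
#' fewer reads. `fraction = 1` returns the table unchanged.
#'
#' @param table a [contact_table()].
#' @param fraction retention probability in (0, 1].
#' @param seed integer seed.
#' @return a [contact_table()].
#' @export
downsample_contacts <- function(table, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(table)
  set.seed(seed)
  kept <- stats::rbinom(length(table$count), size = as.integer(table$count),
                        prob = fraction)
  contact_table(table$i, table$j, kept, table$binning)
}

#' Mix two contact tables into one population-mixture dataset
#'
#' The deeper table is first down-sampled to the shallower one's total depth,
#' then counts are summed per bin pair — emulating an equal-weight mixture of
#' two cell populations sequenced to the same depth.
#'
#' @param table_a,table_b [contact_table()]s on the identical binning.
#' @param seed integer seed (for the depth-matching thinning).
#' @return a [contact_table()].
#' @export
mix_contacts <- function(table_a, table_b, seed) {
  if (!identical(table_a$binning[c("chrom_names", "chrom_lengths", "bin_size")],
                 table_b$binning[c("chrom_names", "chrom_lengths", "bin_size")]))
    stop("contact tables are on different binnings")
  ta <- table_a$total_trans; tb <- table_b$total_trans
  thin_to <- function(tab, target, seed) {
    if (target == 0)
      return(contact_table(integer(0), integer(0), numeric(0), tab$binning))
    downsample_contacts(tab, target / tab$total_trans, seed)
  }
  if (ta > tb) table_a <- thin_to(table_a, tb, seed)
  else if (tb > ta) table_b <- thin_to(table_b, ta, seed)
  contact_table(c(table_a$i, table_b$i), c(table_a$j, table_b$j),
                c(table_a$count, table_b$count), table_a$binning)
}

#' Randomized truth scores from a compartment annotation
#'
#' For each bin, the annotated sub-compartment receives a score drawn from
#' `U(1 - NL, 1)` and every other sub-compartment from `U(0, NL)`; rows are
#' then normalized to sum to 1. `NL` (noise level) in (0, 0.5] controls how
#' distinguishable the annotated compartment remains.
#'
#' @param labels character/factor vector of per-bin compartment labels
#'   (e.g. Rao-style A1, A2, B1, B2, B3, B4); `NA` rows are all-zero.
#' @param NL noise level in (0, 0.5].
#' @param seed integer seed.
#' @param levels optional explicit label set (column order); defaults to the
#'   sorted unique labels.
#' @return truth score matrix (rows sum to 1) with column names `levels`.
#' @export
randomize_from_annotation <- function(labels, NL, seed, levels = NULL) {
  stopifnot(NL > 0, NL <= 0.5)
  if (missing(seed)) stop("a seed is required")
  labels <- as.character(labels)
  if (is.null(levels)) levels <- sort(unique(labels[!is.na(labels)]))
  if (any(!is.na(labels) & !(labels %in% levels)))
    stop("unknown annotation label: ",
         stats::na.omit(setdiff(labels, levels))[1])
  n <- length(labels); M <- length(levels)
  set.seed(seed)
  P <- matrix(stats::runif(n * M, 0, NL), n, M)
  hit <- cbind(seq_len(n), match(labels, levels))
  hit <- hit[!is.na(hit[, 2]), , drop = FALSE]
  P[hit] <- stats::runif(nrow(hit), 1 - NL, 1)
  P[is.na(labels), ] <- 0
  rs <- rowSums(P)
  P <- P / ifelse(rs > 0, rs, 1)
  colnames(P) <- levels
  P
}

#' Synthetic genome layout with block-structured truth scores
#'
#' Builds a test genome of `n_chroms` equal chromosomes binned at `bin_size`
#' and a ground-truth score matrix that mimics compartmentalized Hi-C:
#' contiguous runs of bins share a dominant sub-compartment (domain lengths
#' uniform on `block_len` bins), each row is a Dirichlet draw concentrated on
#' the dominant compartment, and rows are scaled by a log-normal bias factor.
#' Relative arm positions use the acrocentric convention (centromere at
#' coordinate 0).
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param bin_size bin width (bp).
#' @param M number of sub-compartments.
#' @param seed integer seed.
#' @param block_len length-2 range of domain lengths in bins.
#' @param conc_dominant,conc_other Dirichlet concentrations of the dominant
#'   and remaining compartments (defaults give a mean dominant probability of
#'   0.8, typical of well-localized sub-compartment calls).
#' @param bias_meanlog,bias_sdlog log-normal bias parameters (defaults give
#'   ~25% coverage variation between bins).
#' @return list with `binning` (a [genome_binning()] with `r` set) and
#'   `C` (truth matrix, `B_i * P_ik`).
#' @export
make_synthetic_genome <- function(n_chroms, chrom_length, bin_size, M, seed,
                                  block_len = c(5, 20),
                                  conc_dominant = 12, conc_other = 0.75,
                                  bias_meanlog = 0, bias_sdlog = 0.25) {
  stopifnot(n_chroms >= 1, chrom_length > 0, bin_size > 0, M >= 1)
  if (missing(seed)) stop("a seed is required")
  binning <- genome_binning(sprintf("chrS%d", seq_len(n_chroms)),
                            rep(chrom_length, n_chroms), bin_size)
  binning <- compute_relative_positions(binning)
  n <- binning$n_bins
  set.seed(seed)

  # contiguous dominant-compartment domains
  dominant <- integer(n)
  pos <- 1L
  while (pos <= n) {
    len <- sample(seq.int(block_len[1], block_len[2]), 1L)
    end <- min(pos + len - 1L, n)
    # domains do not straddle chromosomes
    end <- min(end, max(which(binning$bin_chrom == binning$bin_chrom[pos])))
    dominant[pos:end] <- sample.int(M, 1L)
    pos <- end + 1L
  }

  conc <- matrix(conc_other, n, M)
  conc[cbind(seq_len(n), dominant)] <- conc_dominant
  g <- matrix(stats::rgamma(n * M, shape = conc), n, M)
  P <- g / rowSums(g)
  B <- stats::rlnorm(n, bias_meanlog, bias_sdlog)
  list(binning = binning, C = B * P, P = P, B = B, dominant = dominant)
}
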