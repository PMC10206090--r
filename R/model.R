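#' Rabl configuration factor for a bin pair
#'
#' The inter-chromosomal clustering of centromeres with centromeres and
#' telomeres with telomeres (the Rabl configuration) multiplies the expected
#' contact rate of a trans bin pair by
#' \deqn{R_{ij} = 1 + \alpha r_i r_j + \beta (r_i + r_j) r_i r_j,}
#' where `r` is the relative arm position (-0.5 at the centromere, +0.5 at
#' the telomere), `alpha` scales the strength of the effect and `beta` its
#' skew towards the centromeric or telomeric side. With `alpha = beta = 0`
#' the factor is identically 1. Vectorized and symmetric in `(r_i, r_j)`.
#'
#' @param r_i,r_j relative arm positions in `[-0.5, 0.5]`.
#' @param alpha,beta Rabl coefficients.
#' @return numeric vector of factors (must be positive for a valid model; a
#'   warning is raised otherwise).
#' @export
rabl_term <- function(r_i, r_j, alpha, beta) {
  out <- 1 + alpha * r_i * r_j + beta * (r_i + r_j) * r_i * r_j
  if (any(out <= 0))
    warning("non-positive Rabl factor: (alpha, beta) invalid for these positions")
  out
}

#' Expected trans contacts for one bin pair
#'
#' The Poisson rate of the observed count: `F_ij = R_ij * sum_k C_ik C_jk`.
#' Two bins with disjoint compartment support never interact.
#'
#' @param C_i,C_j nonnegative score rows of length M.
#' @param R_ij Rabl factor (positive scalar).
#' @return nonnegative rate.
#' @export
expected_contacts <- function(C_i, C_j, R_ij) {
  R_ij * sum(C_i * C_j)
}

#' Compartment score model
#'
#' Container for the fitted (or ground-truth) model: the nonnegative n x M
#' score matrix `C` with `C[i,k] = B_i * P_ik` (bias times sub-compartment
#' probability, in units of the square root of expected read counts), and the
#' Rabl coefficients.
#'
#' @param C nonnegative numeric matrix, one row per bin.
#' @param alpha,beta Rabl coefficients.
#' @param binning the [genome_binning()] the rows refer to (optional but
#'   required for likelihood evaluation).
#' @param loglik,trace,n_nonempty,seed optional fit metadata.
#' @return object of class `compartment_model`.
#' @export
compartment_model <- function(C, alpha = 0, beta = 0, binning = NULL,
                              loglik = NA_real_, trace = NULL,
                              n_nonempty = NA_integer_, seed = NA_integer_) {
  C <- as.matrix(C)
  if (any(C < 0)) stop("compartment scores must be nonnegative")
  if (!is.null(binning) && nrow(C) != binning$n_bins)
    stop("score matrix rows do not match the binning")
  structure(
    list(C = C, alpha = alpha, beta = beta, M = ncol(C), binning = binning,
         loglik = loglik, trace = trace, n_nonempty = n_nonempty, seed = seed),
    class = "compartment_model"
  )
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf(
    "compartment_model: %d bins x %d sub-compartments; alpha=%.4g beta=%.4g; logL=%.6g\n",
    nrow(x$C), x$M, x$alpha, x$beta, x$loglik))
  invisible(x)
}

#' Split scores into bias and sub-compartment probabilities
#'
#' `B_i = sum_k C_ik` is the per-bin bias factor (mappability, accessibility,
#' ligation/PCR efficiency) and `P_ik = C_ik / B_i` the probability that bin
#' `i` resides in sub-compartment `k`; rows of `P` sum to 1 wherever
#' `B_i > 0`. Bins with `B_i = 0` (blacklisted or without trans reads) get an
#' all-zero `P` row and are flagged missing.
#'
#' @param model a [compartment_model()] or a nonnegative matrix.
#' @return list with `B` (numeric vector), `P` (matrix), and logical
#'   `missing` (TRUE where `B_i = 0`).
#' @export
decompose <- function(model) {
  C <- if (inherits(model, "compartment_model")) model$C else as.matrix(model)
  B <- rowSums(C)
  P <- C / ifelse(B > 0, B, 1)
  P[B == 0, ] <- 0
  list(B = B, P = P, missing = B == 0)
}

# 0-based chromosome index per bin for the C++ core
chrom0 <- function(binning) binning$bin_chrom - 1L

# shared argument marshalling for the C++ routines
core_args <- function(contacts, exclusions) {
  b <- contacts$binning
  if (all(is.na(b$r)))
    stop("relative arm positions unset: call compute_relative_positions() first")
  list(
    ii = contacts$i - 1L, jj = contacts$j - 1L, nn = contacts$count,
    r = b$r, chrom = chrom0(b),
    group = group_id_vector(b, exclusions),
    blacklist = blacklist_vector(b, exclusions),
    n_chrom = length(b$chrom_names),
    n_group = if (is.null(exclusions)) 0L else length(exclusions$groups)
  )
}

#' Poisson log-likelihood of a contact table under a model
#'
#' Computes \eqn{\sum_{ij} [N_{ij} \ln F_{ij} - F_{ij}]} over all eligible
#' trans bin pairs (constants in \eqn{N_{ij}} omitted). Pairs with
#' \eqn{N_{ij} = 0} contribute only \eqn{-F_{ij}}, evaluated in closed form
#' through per-chromosome column moment sums rather than by enumerating all
#' pairs. A pair with \eqn{N_{ij} > 0} but \eqn{F_{ij} = 0} yields `-Inf`.
#' Pairs inside one region group and pairs touching blacklisted bins are
#' excluded.
#'
#' @param contacts a [contact_table()].
#' @param model a [compartment_model()] with matching dimensions.
#' @param exclusions optional [exclusion_set()].
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(contacts, model, exclusions = NULL) {
  if (nrow(model$C) != contacts$binning$n_bins)
    stop("model dimensions do not match the binning")
  tab <- apply_exclusions(contacts, exclusions)
  a <- core_args(tab, exclusions)
  C <- model$C
  if (!is.null(exclusions)) C[exclusions$blacklist, ] <- 0
  cpp_loglik(a$ii, a$jj, a$nn, C, a$r, a$chrom, a$group,
             a$n_chrom, a$n_group, model$alpha, model$beta)
}
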