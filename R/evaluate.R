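#' Akaike information criterion of a fitted model
#'
#' `AIC = 2k - 2 ln L` with `k = n*M + 2`, where `n` is the number of
#' non-empty genomic windows (bins with at least one trans read, not
#' blacklisted) and `M` the number of sub-compartments; the `+ 2` counts the
#' Rabl coefficients and is applied regardless of whether the Rabl term was
#' enabled. Set `k_formula = "nM"` to drop the two Rabl parameters.
#'
#' @param model a [compartment_model()] with `n_nonempty` and `loglik` set,
#'   or `NULL` if both are supplied explicitly.
#' @param loglik optional override of the maximized log-likelihood.
#' @param n_nonempty optional override of the non-empty window count.
#' @param M optional override of the compartment number.
#' @param k_formula `"nM+2"` (default) or `"nM"`.
#' @return the AIC value.
#' @export
aic <- function(model = NULL, loglik = NULL, n_nonempty = NULL, M = NULL,
                k_formula = c("nM+2", "nM")) {
  k_formula <- match.arg(k_formula)
  if (!is.null(model)) {
    if (is.null(loglik)) loglik <- model$loglik
    if (is.null(n_nonempty)) n_nonempty <- model$n_nonempty
    if (is.null(M)) M <- model$M
  }
  k <- n_nonempty * M + if (k_formula == "nM+2") 2 else 0
  2 * k - 2 * loglik
}

#' Fit a range of compartment numbers and compare by AIC
#'
#' Runs [fit_compartments()] for each `M` in `M_list` with the same restart
#' budget and seed policy, and tabulates log-likelihood and AIC. The selected
#' model size is the AIC argmin.
#'
#' @param contacts a [contact_table()].
#' @param M_list integer vector of compartment numbers to try.
#' @param config a [fit_config()]; its `M` is overridden by each entry of
#'   `M_list` (the seed is offset per M so restarts differ across models
#'   while remaining reproducible).
#' @param exclusions optional [exclusion_set()].
#' @return data.frame with columns `M`, `loglik`, `aic`, `converged`;
#'   attribute `selected_M` holds the argmin-AIC entry, and attribute
#'   `models` the fitted models (named by M).
#' @export
aic_sweep <- function(contacts, M_list, config, exclusions = NULL) {
  M_list <- as.integer(M_list)
  fits <- vector("list", length(M_list))
  for (q in seq_along(M_list)) {
    cfg <- config
    cfg$M <- M_list[q]
    cfg$seed <- config$seed + M_list[q]
    fits[[q]] <- fit_compartments(contacts, cfg, exclusions)
  }
  out <- data.frame(
    M = M_list,
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1))
  )
  attr(out, "selected_M") <- M_list[which.min(out$aic)]
  names(fits) <- M_list
  attr(out, "models") <- fits
  out
}

#' Per-bin information content of sub-compartment probabilities
#'
#' `IC_i = sum_k p_ik log2(p_ik * M)` in bits, with `0*log2(0) = 0`: 0 for a
#' uniform row (maximal population heterogeneity), `log2(M)` for a one-hot
#' row (deterministic localization). The uniform baseline `1/M` generalizes
#' the five-compartment case (baseline 0.2).
#'
#' @param P probability matrix (rows sum to 1) or a single row.
#' @param M number of sub-compartments (defaults to `ncol(P)`).
#' @return numeric vector of IC values; `NA` for all-zero (missing) rows.
#' @export
information_content <- function(P, M = NULL) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  if (is.null(M)) M <- ncol(P)
  if (any(P < 0)) stop("negative probability entries")
  rs <- rowSums(P)
  ok <- abs(rs - 1) <= 1e-6
  if (any(rs > 0 & !ok))
    stop("probability rows must sum to 1 (tolerance 1e-6)")
  terms <- P * log2(pmax(P, .Machine$double.xmin) * M)
  terms[P == 0] <- 0
  ic <- rowSums(terms)
  ic[rs == 0] <- NA_real_
  ic
}

#' Hard sub-compartment assignment
#'
#' Assigns each bin the sub-compartment with the highest probability; exact
#' ties go to the lowest compartment index, and all-zero (missing) rows get
#' `NA`.
#'
#' @param P probability (or score) matrix.
#' @return integer vector of 1-based compartment labels with `NA` for
#'   missing bins.
#' @export
assign_compartments <- function(P) {
  P <- as.matrix(P)
  lab <- max.col(P, ties.method = "first")
  lab[rowSums(P) == 0] <- NA_integer_
  lab
}

# Hungarian algorithm (O(n^3) Jonker-style shortest augmenting path) for the
# square min-cost assignment problem; no assignment solver ships with the
# installed stack. Returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j+1] = row assigned to column j
  way <- integer(n + 1)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match(seq_len(n), p[-1])  # column per row
}

#' Match inferred to reference score columns and correlate
#'
#' Compartment labels are arbitrary, so inferred columns are matched to
#' reference columns by the permutation maximizing the summed Pearson
#' correlation (exhaustive search for `M <= 6`, Hungarian assignment above).
#' When the inferred matrix has more columns than the reference, the best
#' subset of inferred columns is matched and the rest are reported as
#' unmatched. Rows that are missing (all-zero or `NA`) in either matrix are
#' dropped before correlating.
#'
#' @param P_inferred matrix of inferred scores (n x M_inf).
#' @param P_truth matrix of reference scores (n x M_ref, `M_ref <= M_inf`).
#' @return list with `permutation` (for each reference column, the matched
#'   inferred column), `r` (per-matched-column Pearson correlation), and
#'   `total` (their sum).
#' @export
matched_correlation <- function(P_inferred, P_truth) {
  P_inferred <- as.matrix(P_inferred); P_truth <- as.matrix(P_truth)
  stopifnot(nrow(P_inferred) == nrow(P_truth),
            ncol(P_inferred) >= ncol(P_truth))
  ok <- stats::complete.cases(P_inferred) & stats::complete.cases(P_truth) &
    rowSums(P_inferred) > 0 & rowSums(P_truth) > 0
  if (sum(ok) < 3L) stop("fewer than 3 common non-missing bins")
  A <- P_inferred[ok, , drop = FALSE]; B <- P_truth[ok, , drop = FALSE]
  Mi <- ncol(A); Mr <- ncol(B)
  cors <- suppressWarnings(stats::cor(B, A))  # Mr x Mi
  cors[!is.finite(cors)] <- 0

  if (Mi <= 6L && Mi == Mr) {
    perms <- all_permutations(Mi)
    sums <- vapply(seq_len(nrow(perms)), function(q)
      sum(cors[cbind(seq_len(Mr), perms[q, ])]), numeric(1))
    perm <- perms[which.max(sums), ]
  } else {
    # pad to square with zero-gain dummy reference rows, minimize -r
    pad <- rbind(cors, matrix(0, Mi - Mr, Mi))
    perm <- solve_assignment(-pad)[seq_len(Mr)]
  }
  r <- cors[cbind(seq_len(Mr), perm)]
  list(permutation = perm, r = r, total = sum(r))
}

all_permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, 0, m)
  for (k in seq_len(m)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  out
}
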