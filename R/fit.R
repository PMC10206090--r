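#' Fit configuration
#'
#' @param M number of sub-compartments (>= 1).
#' @param seed integer seed; mandatory, recorded in the run summary so every
#'   fit is reproducible.
#' @param n_restarts number of random restarts; the restart with the highest
#'   final likelihood wins, ties broken by lowest restart index.
#' @param max_outer_iters cap on outer coordinate-ascent iterations.
#' @param rel_tol relative log-likelihood improvement threshold for outer
#'   convergence.
#' @param inner_tol KKT tolerance of the per-locus subproblem.
#' @param rabl_enabled if `FALSE`, `alpha` and `beta` are fixed at 0
#'   (no Rabl correction).
#' @param max_inner cap on Newton iterations per locus subproblem.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(M, seed, n_restarts = 5L, max_outer_iters = 400L,
                       rel_tol = 1e-6, inner_tol = 1e-6,
                       rabl_enabled = TRUE, max_inner = 50L) {
  stopifnot(M >= 1, n_restarts >= 1, max_outer_iters >= 1,
            rel_tol > 0, inner_tol > 0)
  if (missing(seed) || is.na(seed)) stop("a seed is required")
  structure(list(M = as.integer(M), seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 max_outer_iters = as.integer(max_outer_iters),
                 rel_tol = rel_tol, inner_tol = inner_tol,
                 rabl_enabled = isTRUE(rabl_enabled),
                 max_inner = as.integer(max_inner)),
            class = "fit_config")
}

# number of eligible trans bin pairs (for the initialization's mean rate)
n_eligible_pairs <- function(binning, exclusions = NULL) {
  nb <- binning$bins_per_chrom
  bl <- blacklist_vector(binning, exclusions)
  nb_ok <- tapply(!bl, binning$bin_chrom, sum)
  n_ok <- sum(nb_ok)
  total <- (n_ok^2 - sum(nb_ok^2)) / 2
  if (!is.null(exclusions)) {
    for (g in exclusions$groups) {
      g <- g[!bl[g]]
      cg <- table(binning$bin_chrom[g])
      total <- total - (length(g)^2 - sum(cg^2)) / 2
    }
  }
  total
}

# Random initialization. Row magnitudes are scaled to the observed per-bin
# totals (sqrt(T_i / (M * mean rate per eligible pair))), so initial Poisson
# rates have the right order of magnitude. Row *shapes* are sparse random
# mixtures: a Dirichlet draw with one dominant compartment per bin (random,
# or taken from `clusters` when supplied). Near-uniform rows put the ascent
# at a compartment-symmetric configuration it escapes only slowly at low
# depth; sharp rows break that symmetry and restarts then reliably reach
# high-likelihood optima.
init_scores <- function(contacts, M, exclusions = NULL, clusters = NULL) {
  Ti <- bin_totals(contacts)
  npairs <- max(n_eligible_pairs(contacts$binning, exclusions), 1)
  mean_rate <- max(contacts$total_trans / npairs, .Machine$double.eps)
  base <- sqrt(Ti / (M * mean_rate))
  n <- contacts$binning$n_bins
  if (is.null(clusters)) clusters <- sample.int(M, n, replace = TRUE)
  g <- matrix(stats::rgamma(n * M, shape = 0.3), n, M)
  g[cbind(seq_len(n), clusters)] <- stats::rgamma(n, shape = 8)
  C0 <- base * sqrt(M) * (g / rowSums(g))
  C0[blacklist_vector(contacts$binning, exclusions), ] <- 0
  C0
}

# Spectral seeding for the first restart: k-means on the leading
# eigenvectors of the symmetrically normalized trans-contact matrix groups
# bins with similar contact profiles, which places the ascent in a basin
# consistent with the data's compartment structure. Dense spectral
# decomposition is only attempted up to `max_bins`; NULL (random seeding)
# is returned otherwise or when the decomposition is degenerate.
spectral_clusters <- function(contacts, M, max_bins = 6000L) {
  n <- contacts$binning$n_bins
  if (M < 2L || n > max_bins || length(contacts$i) < n) return(NULL)
  out <- tryCatch({
    A <- matrix(0, n, n)
    A[cbind(contacts$i, contacts$j)] <- contacts$count
    A <- A + t(A)
    s <- sqrt(pmax(rowSums(A), 1))
    eg <- eigen(A / tcrossprod(s), symmetric = TRUE)
    V <- eg$vectors[, seq_len(min(M + 1L, n)), drop = FALSE]
    V <- V / sqrt(rowSums(V^2) + 1e-12)
    stats::kmeans(V, centers = M, nstart = 10, iter.max = 50)$cluster
  }, error = function(e) NULL)
  out
}

#' Maximum-likelihood fit of compartment scores
#'
#' Maximizes the trans-contact Poisson likelihood by block coordinate ascent:
#' all loci of one chromosome are updated from the same snapshot of the other
#' chromosomes' scores (they are conditionally independent because cis pairs
#' are not modeled), chromosomes are swept in input order, and each outer
#' iteration ends with one damped Newton update of the Rabl coefficients.
#' Each per-locus subproblem is convex and solved to its KKT conditions under
#' the nonnegativity constraint. The likelihood trace is non-decreasing
#' within every restart; the restart with the highest final likelihood is
#' returned.
#'
#' @param contacts a [contact_table()] whose binning has relative arm
#'   positions (see [compute_relative_positions()]).
#' @param config a [fit_config()].
#' @param exclusions optional [exclusion_set()]; blacklisted bins keep
#'   all-zero score rows, within-group pairs are excluded from the
#'   likelihood.
#' @return a [compartment_model()] with fit metadata: `loglik`, `trace`
#'   (per-outer-iteration log-likelihood of the winning restart), `aic`,
#'   `n_nonempty`, `kkt_max`, `converged`, `restart_logliks`, `seed`.
#' @export
fit_compartments <- function(contacts, config, exclusions = NULL) {
  stopifnot(inherits(contacts, "contact_table"), inherits(config, "fit_config"))
  if (length(contacts$i) == 0L) stop("empty contact table")
  tab <- apply_exclusions(contacts, exclusions)
  a <- core_args(tab, exclusions)

  best <- NULL
  restart_logliks <- numeric(config$n_restarts)
  set.seed(config$seed)
  spectral <- spectral_clusters(tab, config$M)
  for (s in seq_len(config$n_restarts)) {
    C0 <- init_scores(tab, config$M, exclusions,
                      clusters = if (s == 1L) spectral)
    res <- cpp_fit(a$ii, a$jj, a$nn, C0, a$r, a$chrom, a$group, a$blacklist,
                   a$n_chrom, a$n_group, 0, 0, config$rabl_enabled,
                   config$max_outer_iters, config$rel_tol, config$inner_tol,
                   config$max_inner)
    restart_logliks[s] <- res$loglik
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }

  bl <- a$blacklist
  nonempty <- bin_totals(tab) > 0 & !bl
  model <- compartment_model(best$C, best$alpha, best$beta,
                             binning = contacts$binning,
                             loglik = best$loglik, trace = best$trace,
                             n_nonempty = sum(nonempty), seed = config$seed)
  model$aic <- aic(model)
  model$kkt_max <- best$kkt_max
  model$converged <- best$converged
  model$n_outer <- best$n_outer
  model$restart_logliks <- restart_logliks
  model$config <- config
  model
}

# all eligible trans pairs of a small binning (dense; test-scale oracle route)
eligible_pairs <- function(binning, exclusions = NULL) {
  n <- binning$n_bins
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  keep <- binning$bin_chrom[i] != binning$bin_chrom[j]
  if (!is.null(exclusions)) {
    bl <- blacklist_vector(binning, exclusions)
    gid <- group_id_vector(binning, exclusions)
    keep <- keep & !bl[i] & !bl[j] & !(gid[i] >= 0L & gid[i] == gid[j])
  }
  cbind(i = i[keep], j = j[keep])
}

#' Gradient and Hessian of the per-locus likelihood
#'
#' For locus `i` with all other score rows and the Rabl coefficients fixed:
#' `G_k = sum_j N_ij C_jk / (C_i . C_j) - sum_j R_ij C_jk` and
#' `H_kl = -sum_j N_ij C_jk C_jl / (C_i . C_j)^2`; `-H` is positive
#' semidefinite, so the subproblem is convex. The unobserved-pair term is
#' evaluated by direct summation over all eligible partners (intended for
#' small instances and cross-checks; the fitter uses an equivalent
#' closed-form route).
#'
#' @param i 1-based bin index.
#' @param contacts a [contact_table()].
#' @param model a [compartment_model()].
#' @param exclusions optional [exclusion_set()].
#' @return list with `G` (length-M) and `H` (M x M).
#' @export
locus_gradient_hessian <- function(i, contacts, model, exclusions = NULL) {
  b <- contacts$binning
  C <- model$C
  M <- ncol(C)
  bl <- blacklist_vector(b, exclusions)
  gid <- group_id_vector(b, exclusions)
  elig <- which(b$bin_chrom != b$bin_chrom[i] & !bl &
                  !(gid >= 0L & gid == gid[i]))
  R <- rabl_term(b$r[i], b$r[elig], model$alpha, model$beta)
  w <- colSums(R * C[elig, , drop = FALSE])

  sel <- which(contacts$i == i | contacts$j == i)
  jn <- ifelse(contacts$i[sel] == i, contacts$j[sel], contacts$i[sel])
  ok <- !bl[jn] & !bl[i] & !(gid[jn] >= 0L & gid[jn] == gid[i])
  jn <- jn[ok]; Nn <- contacts$count[sel][ok]

  G <- -w
  H <- matrix(0, M, M)
  if (length(jn)) {
    Cn <- C[jn, , drop = FALSE]
    dots <- as.numeric(Cn %*% C[i, ])
    if (any(dots <= 0))
      stop("infeasible iterate: observed pair with zero expected rate")
    G <- G + colSums(Nn / dots * Cn)
    H <- -crossprod(Cn * sqrt(Nn) / dots)
  }
  list(G = G, H = H)
}

#' Solve one per-locus subproblem to its KKT conditions
#'
#' Maximizes the locus likelihood over `C_i >= 0` with everything else fixed
#' (projected Newton on the convex subproblem). Never decreases the locus
#' likelihood relative to the input row.
#'
#' @inheritParams locus_gradient_hessian
#' @param inner_tol KKT tolerance.
#' @param max_inner iteration cap.
#' @return list with the updated `row` and the final `kkt` residual.
#' @export
solve_locus <- function(i, contacts, model, exclusions = NULL,
                        inner_tol = 1e-6, max_inner = 50L) {
  tab <- apply_exclusions(contacts, exclusions)
  a <- core_args(tab, exclusions)
  C <- model$C
  if (!is.null(exclusions)) C[exclusions$blacklist, ] <- 0
  cpp_solve_locus(i - 1L, a$ii, a$jj, a$nn, C, a$r, a$chrom, a$group,
                  a$n_chrom, a$n_group, model$alpha, model$beta,
                  inner_tol, max_inner)
}

#' Gradient and Hessian of the likelihood in the Rabl coefficients
#'
#' With all score rows fixed, the log-likelihood is concave in
#' `(alpha, beta)`. Direct summation over eligible pairs (test-scale route).
#'
#' @param contacts a [contact_table()].
#' @param model a [compartment_model()].
#' @param exclusions optional [exclusion_set()].
#' @return list with `G` (length-2: alpha, beta) and `H` (2 x 2).
#' @export
rabl_gradient_hessian <- function(contacts, model, exclusions = NULL) {
  b <- contacts$binning
  C <- model$C
  ep <- eligible_pairs(b, exclusions)
  x_all <- b$r[ep[, 1]] * b$r[ep[, 2]]
  y_all <- x_all * (b$r[ep[, 1]] + b$r[ep[, 2]])
  dots_all <- rowSums(C[ep[, 1], , drop = FALSE] * C[ep[, 2], , drop = FALSE])

  tab <- apply_exclusions(contacts, exclusions)
  x <- b$r[tab$i] * b$r[tab$j]
  y <- x * (b$r[tab$i] + b$r[tab$j])
  R <- 1 + model$alpha * x + model$beta * y
  if (any(R <= 0)) stop("non-positive Rabl factor at an observed pair")
  N <- tab$count

  G <- c(alpha = sum(N * x / R) - sum(x_all * dots_all),
         beta = sum(N * y / R) - sum(y_all * dots_all))
  H <- -matrix(c(sum(N * x^2 / R^2), sum(N * x * y / R^2),
                 sum(N * x * y / R^2), sum(N * y^2 / R^2)), 2, 2)
  list(G = G, H = H)
}

#' One damped Newton update of the Rabl coefficients
#'
#' Performs a single Newton step on `(alpha, beta)` with all score rows
#' fixed, halving the step until the likelihood does not decrease and the
#' Rabl factor stays positive over the whole `[-0.5, 0.5]^2` square.
#'
#' @inheritParams rabl_gradient_hessian
#' @return list with updated `alpha`, `beta`, and the pre-step gradient.
#' @export
rabl_step <- function(contacts, model, exclusions = NULL) {
  tab <- apply_exclusions(contacts, exclusions)
  a <- core_args(tab, exclusions)
  C <- model$C
  if (!is.null(exclusions)) C[exclusions$blacklist, ] <- 0
  cpp_rabl_step(a$ii, a$jj, a$nn, C, a$r, a$chrom, a$group,
                a$n_chrom, a$n_group, model$alpha, model$beta)
}
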