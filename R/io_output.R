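#' Write fitted scores, bedGraphs and a run summary
#'
#' Writes, under `prefix`:
#' \itemize{
#'   \item `<prefix>_scores.tsv` — chrom, start, end (0-based half-open),
#'     `P_1..P_M` (sub-compartment probabilities), `B` (bias), `missing`
#'     flag (1 for blacklisted/empty bins, whose rows are all zero);
#'   \item `<prefix>_comp<k>.bedGraph` — one track per sub-compartment;
#'   \item `<prefix>_summary.json` — alpha, beta, final log-likelihood, AIC,
#'     iteration count, convergence flag, seed, restart likelihoods and the
#'     outer-iteration likelihood trace.
#' }
#'
#' @param model a fitted [compartment_model()].
#' @param binning the [genome_binning()] (defaults to the model's).
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_scores <- function(model, binning = model$binning, prefix) {
  stopifnot(inherits(model, "compartment_model"),
            inherits(binning, "genome_binning"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  d <- decompose(model)
  M <- model$M
  tsv <- file.path(paste0(prefix, "_scores.tsv"))
  dt <- data.table::data.table(
    chrom = binning$chrom_names[binning$bin_chrom],
    start = as.integer(binning$bin_start),
    end = as.integer(binning$bin_end)
  )
  for (k in seq_len(M)) dt[[paste0("P_", k)]] <- round(d$P[, k], 6)
  dt$B <- round(d$B, 6)
  dt$missing <- as.integer(d$missing)
  data.table::fwrite(dt, tsv, sep = "\t")

  bg_paths <- character(M)
  for (k in seq_len(M)) {
    bg_paths[k] <- paste0(prefix, "_comp", k, ".bedGraph")
    bg <- dt[, 1:3]
    bg$value <- round(d$P[, k], 6)
    writeLines(sprintf("track type=bedGraph name=subcompartment_%d", k),
               bg_paths[k])
    data.table::fwrite(bg, bg_paths[k], sep = "\t", col.names = FALSE,
                       append = TRUE)
  }

  js <- paste0(prefix, "_summary.json")
  summary <- list(
    alpha = model$alpha, beta = model$beta,
    loglik = model$loglik, aic = model$aic,
    M = M, n_bins = nrow(model$C), n_nonempty = model$n_nonempty,
    n_outer = model$n_outer, converged = model$converged,
    kkt_max = model$kkt_max, seed = model$seed,
    restart_logliks = model$restart_logliks, trace = model$trace
  )
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(scores = tsv, stats::setNames(bg_paths, paste0("bedgraph", seq_len(M))),
              summary = js))
}

#' Read a score table written by [write_scores()]
#'
#' @param path the `<prefix>_scores.tsv` file.
#' @return list with `P` (probability matrix), `B`, `missing`, and the
#'   interval columns as a data.frame.
#' @export
read_scores <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  pcols <- grep("^P_", names(dt), value = TRUE)
  P <- as.matrix(dt[, pcols, with = FALSE])
  list(P = P, B = dt$B, missing = dt$missing == 1L,
       intervals = as.data.frame(dt[, 1:3]))
}

#' Write a hard compartment assignment as BED
#'
#' @param labels integer labels from [assign_compartments()] (`NA` skipped).
#' @param binning the [genome_binning()].
#' @param path output BED path; the label goes in the name column.
#' @export
write_assignment_bed <- function(labels, binning, path) {
  keep <- !is.na(labels)
  dt <- data.table::data.table(
    chrom = binning$chrom_names[binning$bin_chrom][keep],
    start = as.integer(binning$bin_start[keep]),
    end = as.integer(binning$bin_end[keep]),
    name = paste0("C", labels[keep])
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
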