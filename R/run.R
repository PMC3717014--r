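#' Run the full analysis and write report files
#'
#' Reads a Cq table and an efficiency table, fits [ref_stability()], and
#' writes the standard report set to `out_dir`:
#' `stability_report.csv` (gene, M, CV, gates), `ranking_trace.csv`
#' (per-step M-values), `v_series.csv`, `qc_log.csv`, and a human-readable
#' `summary.md` (validated genes, recommended pair, recommended n).
#'
#' @param cq_file path to a delimited Cq table (see [read_cq_table()]).
#' @param eff_file path to a `gene,efficiency` table.
#' @param out_dir output directory, created if needed.
#' @param policy a [cutoff_policy()].
#' @param v_threshold,max_cq,max_replicate_spread see [ref_stability()].
#' @return The `ref_stability` fit, invisibly.
#' @export
run_analyze <- function(cq_file, eff_file, out_dir,
                        policy = cutoff_policy(), v_threshold = 0.15,
                        max_cq = 30, max_replicate_spread = 0.5) {
  if (!file.exists(cq_file)) stop("Cq table not found: ", cq_file)
  if (!file.exists(eff_file)) stop("efficiency file not found: ", eff_file)
  fit <- ref_stability(read_cq_table(cq_file), read_efficiencies(eff_file),
                       policy = policy, v_threshold = v_threshold,
                       max_cq = max_cq,
                       max_replicate_spread = max_replicate_spread)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, digits = 6, trim = TRUE, scientific = FALSE)

  s <- fit$stability
  s$m_value <- fmt(s$m_value); s$cv <- fmt(s$cv)
  con <- file(file.path(out_dir, "stability_report.csv"), "w")
  writeLines(sprintf("# panel=%s m_cutoff=%g cv_cutoff=%g",
                     fit$policy$panel, fit$policy$m_cutoff,
                     fit$policy$cv_cutoff), con)
  utils::write.csv(as.data.frame(s), con, row.names = FALSE, quote = FALSE)
  close(con)

  if (!is.null(fit$ranking)) {
    tr <- as.data.frame(fit$ranking)
    num <- vapply(tr, is.numeric, TRUE)
    tr[num] <- lapply(tr[num], function(c) ifelse(is.na(c), "", fmt(c)))
    utils::write.csv(tr, file.path(out_dir, "ranking_trace.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(fit$v_series)) {
    con <- file(file.path(out_dir, "v_series.csv"), "w")
    writeLines(sprintf("# threshold=%g recommended_n=%d", fit$v_threshold,
                       attr(fit$v_series, "recommended_n")), con)
    v <- data.frame(fit$v_series)
    v$v <- fmt(v$v)
    utils::write.csv(v, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  if (!is.null(fit$qc_log))
    utils::write.csv(fit$qc_log, file.path(out_dir, "qc_log.csv"),
                     row.names = FALSE, quote = FALSE)

  sm <- summary(fit)
  lines <- c("# Reference-gene validation summary", "",
             sprintf("- genes: %d, samples: %d", sm$n_genes, sm$n_samples),
             sprintf("- QC removals: %d", sm$n_qc_removals),
             sprintf("- validated genes: %s",
                     if (length(sm$validated))
                       paste(sm$validated, collapse = ", ") else "(none)"),
             sprintf("- rejected genes: %s",
                     if (length(sm$rejected))
                       paste(sm$rejected, collapse = ", ") else "(none)"))
  if (!is.null(sm$best_pair))
    lines <- c(lines, sprintf("- most stable pair (tied): %s, %s",
                              sm$best_pair[1L], sm$best_pair[2L]))
  if (!is.null(sm$recommended_n))
    lines <- c(lines,
               sprintf("- recommended number of reference genes: %d",
                       sm$recommended_n))
  if (!is.null(sm$worst_pair))
    lines <- c(lines,
               sprintf("- worst validated pair V = %s (threshold %g): %s",
                       fmt(sm$worst_pair$max_pair_v), fit$v_threshold,
                       if (sm$worst_pair$all_below) "below" else "ABOVE"))
  writeLines(lines, file.path(out_dir, "summary.md"))
  invisible(fit)
}

#' Simulate a dataset and write it as the pipeline's input files
#'
#' Writes `cq_table.csv` (long format), `efficiencies.csv`, and
#' `truth.csv` (`gene,is_stable,max_effect_cycles`) to `out_dir`.
#'
#' @param out_dir output directory, created if needed.
#' @param config a [sim_config()].
#' @param seed integer seed for reproducibility.
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(out_dir, config = sim_config(), seed = 1L) {
  sim <- simulate_cq(config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("cq_table.csv", "efficiencies.csv",
                                "truth.csv"))
  cq <- as.data.frame(sim$cq)
  cq$cq <- format(cq$cq, digits = 10, trim = TRUE, scientific = FALSE)
  utils::write.csv(cq, paths[1L], row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(sim$efficiencies)[c("gene", "efficiency")],
                   paths[2L], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth, paths[3L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
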