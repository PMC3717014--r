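#' Validate and rank candidate reference genes
#'
#' The main fitting function: runs the full reference-gene validation
#' pipeline on a table of Cq values and per-gene amplification
#' efficiencies. Steps, in order:
#' \enumerate{
#'   \item quality filtering ([qc_filter()]): Cq cap and replicate-spread
#'     outlier removal;
#'   \item efficiency-corrected conversion to relative quantities with
#'     replicate averaging ([relative_quantities()]);
#'   \item per-gene geNorm M-values and coefficients of variation,
#'     classified against the cut-off policy ([m_values()], [cv_values()],
#'     [classify_stability()]);
#'   \item stepwise-elimination stability ranking ([rank_genes()]);
#'   \item pairwise-variation series V(n, n+1) and the recommended number
#'     of reference genes ([pairwise_variation_series()]), plus the
#'     worst-validated-pair sensitivity check ([worst_pair_check()]).
#' }
#' All samples are pooled into one panel; condition labels are carried as
#' metadata only.
#'
#' @param cq a [cq_table()] (or path to one, read via [read_cq_table()]).
#' @param efficiencies an [efficiency_table()] (or path, read via
#'   [read_efficiencies()]).
#' @param policy a [cutoff_policy()]; default heterogeneous (M < 1,
#'   CV < 50%).
#' @param v_threshold pairwise-variation acceptance threshold (default
#'   0.15).
#' @param max_cq,max_replicate_spread QC parameters, see [qc_filter()].
#' @param qc set `FALSE` to skip quality filtering (input already clean).
#' @return An object of class `ref_stability` with components `rq`,
#'   `stability` (the per-gene report), `ranking`, `v_series`,
#'   `worst_pair`, `qc_log`, `policy`, `v_threshold`. Methods: `print`,
#'   `summary`, `coef` (per-gene M and CV), `predict` (per-sample
#'   normalization factors), `plot`.
#' @examples
#' sim <- simulate_cq(sim_config(), seed = 42)
#' fit <- ref_stability(sim$cq, sim$efficiencies)
#' summary(fit)
#' @export
ref_stability <- function(cq, efficiencies, policy = cutoff_policy(),
                          v_threshold = 0.15, max_cq = 30,
                          max_replicate_spread = 0.5, qc = TRUE) {
  if (is.character(cq)) cq <- read_cq_table(cq)
  if (is.character(efficiencies))
    efficiencies <- read_efficiencies(efficiencies)
  stopifnot(inherits(cq, "cq_table"),
            inherits(efficiencies, "efficiency_table"),
            inherits(policy, "cutoff_policy"))
  qc_log <- NULL
  if (qc) {
    res <- qc_filter(cq, max_cq = max_cq,
                     max_replicate_spread = max_replicate_spread)
    cq <- res$table
    qc_log <- res$log
  }
  rq <- relative_quantities(cq, efficiencies)
  m <- m_values(rq)
  cv <- cv_values(rq)
  stability <- classify_stability(m, cv, policy)
  ranking <- if (nrow(rq) >= 3L) rank_genes(rq) else NULL
  vs <- if (nrow(rq) >= 3L)
    pairwise_variation_series(rq, ranking, threshold = v_threshold)
  else NULL
  validated <- stability$gene[stability$validated]
  wp <- if (length(validated) >= 2L)
    worst_pair_check(rq, validated, ranking = ranking,
                     threshold = v_threshold)
  else NULL
  structure(list(rq = rq, stability = stability, ranking = ranking,
                 v_series = vs, worst_pair = wp, qc_log = qc_log,
                 policy = policy, v_threshold = v_threshold,
                 call = match.call()),
            class = "ref_stability")
}

#' @export
print.ref_stability <- function(x, digits = 3L, ...) {
  cat("Reference-gene stability analysis\n")
  cat(sprintf("  %d gene(s) x %d sample(s); %s panel (M < %g, CV < %g%%)\n",
              nrow(x$rq), ncol(x$rq), x$policy$panel, x$policy$m_cutoff,
              100 * x$policy$cv_cutoff))
  tab <- x$stability[order(x$stability$m_value), ]
  tab$m_value <- round(tab$m_value, digits)
  tab$cv <- round(tab$cv, digits)
  print(as.data.frame(tab), row.names = FALSE, ...)
  if (!is.null(x$ranking))
    cat(sprintf("  most stable pair: %s, %s (tied)\n",
                x$ranking$final_pair[1L], x$ranking$final_pair[2L]))
  if (!is.null(x$v_series))
    cat(sprintf("  recommended number of reference genes: %d (V threshold %g)\n",
                attr(x$v_series, "recommended_n"), x$v_threshold))
  invisible(x)
}

#' @export
summary.ref_stability <- function(object, ...) {
  s <- object$stability
  out <- list(
    n_genes = nrow(object$rq),
    n_samples = ncol(object$rq),
    validated = s$gene[s$validated],
    rejected = s$gene[!s$validated],
    best_pair = if (!is.null(object$ranking)) object$ranking$final_pair,
    stability_order = if (!is.null(object$ranking))
      object$ranking$full_order,
    recommended_n = if (!is.null(object$v_series))
      attr(object$v_series, "recommended_n"),
    v_series = object$v_series,
    worst_pair = object$worst_pair,
    n_qc_removals = if (is.null(object$qc_log)) 0L else nrow(object$qc_log),
    stability = s,
    policy = object$policy)
  class(out) <- "summary.ref_stability"
  out
}

#' @export
print.summary.ref_stability <- function(x, ...) {
  cat(sprintf("Reference-gene validation: %d gene(s), %d sample(s)\n",
              x$n_genes, x$n_samples))
  cat(sprintf("  QC removals: %d well(s)\n", x$n_qc_removals))
  cat("  validated:", if (length(x$validated))
        paste(x$validated, collapse = ", ") else "(none)", "\n")
  if (length(x$rejected))
    cat("  rejected: ", paste(x$rejected, collapse = ", "), "\n")
  if (!is.null(x$best_pair))
    cat(sprintf("  most stable pair (tied): %s, %s\n",
                x$best_pair[1L], x$best_pair[2L]))
  if (!is.null(x$recommended_n))
    cat(sprintf("  recommended number of reference genes: %d\n",
                x$recommended_n))
  if (!is.null(x$worst_pair))
    cat(sprintf("  worst validated pair V = %.4f (%s threshold)\n",
                x$worst_pair$max_pair_v,
                if (x$worst_pair$all_below) "below" else "ABOVE"))
  invisible(x)
}

#' @describeIn ref_stability per-gene M-values and CVs as a two-column
#'   matrix.
#' @param object,x a `ref_stability` fit.
#' @param ... passed on or ignored.
#' @export
coef.ref_stability <- function(object, ...) {
  cbind(m_value = stats::setNames(object$stability$m_value,
                                  object$stability$gene),
        cv = object$stability$cv)
}

#' @describeIn ref_stability per-sample normalization factors from the
#'   `n_genes` most stable genes (default: the recommended number).
#' @param n_genes how many of the most stable genes to combine.
#' @export
predict.ref_stability <- function(object, n_genes = NULL, ...) {
  order <- if (!is.null(object$ranking)) object$ranking$full_order
           else object$stability$gene[order(object$stability$m_value)]
  if (is.null(n_genes))
    n_genes <- if (!is.null(object$v_series))
      attr(object$v_series, "recommended_n") else 2L
  stopifnot(n_genes >= 1L, n_genes <= length(order))
  normalization_factor(object$rq, order[seq_len(n_genes)])
}

#' @describeIn ref_stability three-panel base-graphics display: per-gene
#'   M-values and CVs (sorted, with cut-offs) and the V(n, n+1) series.
#' @export
plot.ref_stability <- function(x, ...) {
  old <- graphics::par(mfrow = c(1L, if (is.null(x$v_series)) 2L else 3L),
                       mar = c(6, 4, 3, 1))
  on.exit(graphics::par(old))
  s <- x$stability[order(x$stability$m_value), ]
  graphics::barplot(stats::setNames(s$m_value, s$gene), las = 2,
                    main = "Stability (M)", ylab = "M-value",
                    ylim = c(0, max(1.05 * x$policy$m_cutoff, s$m_value)))
  graphics::abline(h = x$policy$m_cutoff, lty = 2)
  graphics::barplot(stats::setNames(100 * s$cv, s$gene), las = 2,
                    main = "Coefficient of variation", ylab = "CV (%)",
                    ylim = c(0, max(105 * x$policy$cv_cutoff, 100 * s$cv)))
  graphics::abline(h = 100 * x$policy$cv_cutoff, lty = 2)
  if (!is.null(x$v_series)) {
    v <- x$v_series
    graphics::barplot(stats::setNames(v$v, sprintf("V%d/%d", v$n, v$n + 1)),
                      las = 2, main = "Pairwise variation",
                      ylab = "V(n, n+1)",
                      ylim = c(0, max(0.2, v$v)))
    graphics::abline(h = x$v_threshold, lty = 2)
  }
  invisible(x)
}
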