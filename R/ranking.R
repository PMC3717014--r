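#' Stepwise-elimination stability ranking
#'
#' Iteratively recomputes M-values on the remaining gene set and removes the
#' gene with the highest M (the least stable), until two genes remain. The
#' final pair cannot be discriminated further — the M-value of either gene
#' in a two-gene panel is, by construction, the same pairwise variation —
#' so it is reported as tied. Ties in the maximum M during elimination are
#' broken deterministically by removing the lexicographically last gene
#' label, and the tie is recorded in the trace.
#'
#' @inheritParams pairwise_variation_matrix
#' @return An object of class `ranking_trace`: a list with
#'   \describe{
#'     \item{steps}{list of per-step records `eliminated`, `m_values`
#'       (M on the gene set before elimination), `tie` (logical).}
#'     \item{final_pair}{the two undiscriminated most stable genes.}
#'     \item{full_order}{all genes from most to least stable: the tied final
#'       pair first, then the eliminated genes in reverse elimination order.
#'       This is the inclusion order used for normalization factors.}
#'   }
#' @examples
#' rq <- rbind(A = c(1, 2), B = c(1, 2), C = c(1, 8))
#' rank_genes(rq)
#' @export
rank_genes <- function(rq, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  rq <- as_rq(rq)
  if (nrow(rq) < 3L) stop("ranking needs at least 3 genes")
  remaining <- rownames(rq)
  steps <- list()
  while (length(remaining) > 2L) {
    m <- m_values(rq[remaining, , drop = FALSE], sd_type = sd_type)
    worst <- names(m)[m == max(m)]
    tie <- length(worst) > 1L
    eliminated <- max(worst)  # lexicographically last on a tie
    steps[[length(steps) + 1L]] <-
      list(eliminated = eliminated, m_values = m, tie = tie)
    remaining <- setdiff(remaining, eliminated)
  }
  final_m <- m_values(rq[remaining, , drop = FALSE], sd_type = sd_type)
  out <- list(steps = steps,
              final_pair = sort(remaining),
              final_m = final_m,
              full_order = c(sort(remaining),
                             rev(vapply(steps, `[[`, "", "eliminated"))))
  class(out) <- "ranking_trace"
  out
}

#' @export
print.ranking_trace <- function(x, ...) {
  cat("Stepwise stability ranking (most to least stable):\n  ")
  ord <- x$full_order
  cat(paste0(ord[1L], " = ", ord[2L], " (tied)"),
      if (length(ord) > 2L) paste(ord[-(1:2)], collapse = " > "),
      sep = " > ")
  cat("\n")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  step %d: eliminated %s (M = %.4f%s)\n", i, s$eliminated,
                max(s$m_values), if (s$tie) ", tie broken" else ""))
  }
  invisible(x)
}

#' Tabulate a ranking trace
#'
#' One row per elimination step; one column per gene holding its M-value at
#' that step (NA once eliminated).
#'
#' @param x a `ranking_trace` from [rank_genes()].
#' @param ... unused.
#' @return A data frame with columns `step`, `eliminated`, then one per gene.
#' @export
as.data.frame.ranking_trace <- function(x, ...) {
  genes <- x$full_order
  rows <- lapply(seq_along(x$steps), function(i) {
    s <- x$steps[[i]]
    m <- stats::setNames(rep(NA_real_, length(genes)), genes)
    m[names(s$m_values)] <- s$m_values
    cbind(data.frame(step = i, eliminated = s$eliminated,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m), check.names = FALSE))
  })
  do.call(rbind, rows)
}
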