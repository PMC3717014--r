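#' Quality-filter a Cq table
#'
#' Applies the two well-level quality gates used before quantification:
#' (1) wells with Cq above `max_cq` cycles are discarded (late amplification
#' is unreliable and may reflect primer dimers or contamination);
#' (2) within each (sample, gene) technical-replicate group whose Cq range
#' exceeds `max_replicate_spread`, the replicate farthest from the group
#' median is removed, iteratively, until the range is within tolerance or a
#' single replicate remains. The rule is deterministic and order-independent.
#'
#' @param table a [cq_table()].
#' @param max_cq maximum acceptable Cq in cycles (default 30).
#' @param max_replicate_spread maximum tolerated within-group Cq range in
#'   cycles (default 0.5).
#' @return A list of class `qc_result` with elements `table` (the filtered
#'   [cq_table()]) and `log` (data frame `sample,gene,replicate,cq,reason`
#'   recording every removal).
#' @details If the Cq gate empties a (sample, gene) group entirely, the
#'   function errors naming the group: downstream statistics need at least
#'   one retained well per measured pair. Filtering is idempotent.
#' @examples
#' tab <- cq_table(data.frame(sample = "s1", gene = "Actb",
#'                            replicate = 1:3, cq = c(20.1, 20.2, 22)))
#' qc_filter(tab)$log
#' @export
qc_filter <- function(table, max_cq = 30, max_replicate_spread = 0.5) {
  stopifnot(inherits(table, "cq_table"))
  if (!is.numeric(max_cq) || max_cq <= 0) stop("max_cq must be > 0")
  if (!is.numeric(max_replicate_spread) || max_replicate_spread <= 0)
    stop("max_replicate_spread must be > 0")
  df <- as.data.frame(table)
  log <- df[0, c("sample", "gene", "replicate", "cq")]
  log$reason <- character(0)

  drop <- df$cq > max_cq
  if (any(drop)) {
    gone <- df[drop, c("sample", "gene", "replicate", "cq")]
    keep <- df[!drop, , drop = FALSE]
    emptied <- setdiff(unique(paste(df$sample, df$gene, sep = " / ")),
                       unique(paste(keep$sample, keep$gene, sep = " / ")))
    if (length(emptied))
      stop("Cq filter removed every replicate of: ",
           paste(emptied, collapse = "; "))
    gone$reason <- sprintf("cq %.6g above max_cq %.6g", gone$cq, max_cq)
    log <- rbind(log, gone)
    df <- keep
  }

  key <- paste(df$sample, df$gene, sep = "\r")
  kept <- lapply(split(df, key), function(grp) {
    while (nrow(grp) > 1L &&
           diff(range(grp$cq)) > max_replicate_spread) {
      dev <- abs(grp$cq - stats::median(grp$cq))
      # deterministic tie-break: largest deviation, then largest cq,
      # then highest replicate index
      ord <- order(-dev, -grp$cq, -grp$replicate)
      out <- grp[ord[1L], c("sample", "gene", "replicate", "cq")]
      out$reason <- sprintf(
        "replicate outlier: |cq - median| = %.6g, group range %.6g > %.6g",
        dev[ord[1L]], diff(range(grp$cq)), max_replicate_spread)
      log <<- rbind(log, out)
      grp <- grp[-ord[1L], , drop = FALSE]
    }
    grp
  })
  df <- do.call(rbind, kept)
  rownames(df) <- NULL
  rownames(log) <- NULL
  out <- list(table = cq_table(df, metadata = attr(table, "metadata")),
              log = log)
  class(out) <- "qc_result"
  out
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: %d well(s) retained, %d removed\n",
              nrow(x$table), nrow(x$log)))
  if (nrow(x$log)) print(x$log, ...)
  invisible(x)
}
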