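#' Convert Cq values to efficiency-corrected relative quantities
#'
#' For each gene g the anchor A_g is the minimum Cq observed over all its
#' wells (the highest-expressing well acts as internal control). Each well's
#' relative quantity is then
#' \deqn{RQ = (1 + E_g)^{A_g - Cq},}
#' where E_g is the gene's fractional amplification efficiency, and the
#' per-(sample, gene) value is the arithmetic mean of its replicate RQs.
#' The anchor cancels from every downstream ratio statistic (M, V, CV), so
#' its choice only affects reported RQ magnitudes.
#'
#' @param table a quality-filtered [cq_table()].
#' @param eff an [efficiency_table()] covering every gene in `table`.
#' @param average `"rq"` (default): convert each well to RQ, then average
#'   replicates arithmetically; `"cq"`: average replicate Cq first, which
#'   yields geometric-mean behaviour on the linear scale.
#' @param on_incomplete what to do with samples that lack one or more genes
#'   after QC: `"drop"` them with a warning (default) or `"error"`.
#'   Pairwise statistics require a complete gene-by-sample matrix.
#' @return A numeric matrix of class `rq_matrix` (genes in rows, samples in
#'   columns, all entries > 0) with attributes `anchors` (per-gene anchor
#'   Cq), `efficiencies`, and `conditions` (per-sample condition label).
#' @examples
#' tab <- cq_table(data.frame(sample = rep(c("s1", "s2"), each = 2),
#'                            gene = "Actb", replicate = rep(1:2, 2),
#'                            cq = c(20, 20, 22, 22)))
#' relative_quantities(tab, efficiency_table("Actb", 1))
#' @export
relative_quantities <- function(table, eff, average = c("rq", "cq"),
                                on_incomplete = c("drop", "error")) {
  stopifnot(inherits(table, "cq_table"))
  average <- match.arg(average)
  on_incomplete <- match.arg(on_incomplete)
  df <- as.data.frame(table)
  genes <- unique(df$gene)
  missing_eff <- setdiff(genes, eff$gene)
  if (length(missing_eff))
    stop("no efficiency provided for gene(s): ",
         paste(missing_eff, collapse = ", "))
  E <- stats::setNames(eff$efficiency, eff$gene)[genes]

  # complete-case requirement
  samples <- unique(df$sample)
  have <- table(df$sample, df$gene) > 0
  complete <- rownames(have)[rowSums(have[, genes, drop = FALSE]) ==
                               length(genes)]
  incomplete <- setdiff(samples, complete)
  if (length(incomplete)) {
    msg <- paste("sample(s) missing one or more genes:",
                 paste(incomplete, collapse = ", "))
    if (on_incomplete == "error") stop(msg)
    warning(msg, "; dropped from the relative-quantity matrix")
    df <- df[df$sample %in% complete, , drop = FALSE]
    samples <- samples[samples %in% complete]
  }
  if (!length(samples)) stop("no complete samples remain")

  anchors <- vapply(split(df$cq, df$gene)[genes], min, numeric(1))
  rq <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  for (g in genes) {
    sub <- df[df$gene == g, , drop = FALSE]
    if (average == "rq") {
      well_rq <- (1 + E[[g]])^(anchors[[g]] - sub$cq)
      m <- tapply(well_rq, sub$sample, mean)
    } else {
      mcq <- tapply(sub$cq, sub$sample, mean)
      m <- (1 + E[[g]])^(anchors[[g]] - mcq)
    }
    rq[g, names(m)] <- m
  }
  cond <- df$condition[match(samples, df$sample)]
  structure(rq,
            anchors = anchors, efficiencies = E,
            conditions = stats::setNames(cond, samples),
            class = c("rq_matrix", class(rq)))
}

#' Estimate amplification efficiency from a serial-dilution series
#'
#' Fits ordinary least squares of Cq against log10 relative template amount
#' (amount = 1 / dilution factor) and inverts the slope:
#' \deqn{E = 10^{-1/\mathrm{slope}} - 1.}
#' A slope of -3.32 cycles per decade corresponds to perfect doubling
#' (E = 1).
#'
#' @param series a [dilution_series()] with >= 3 distinct dilution factors.
#' @return A list with `efficiency` (fraction), `slope` (cycles per
#'   log10 dilution, negative), and `r_squared` of the fit.
#' @examples
#' s <- dilution_series("Actb", c(1, 10, 100, 1000),
#'                      20 + log2(c(1, 10, 100, 1000)))
#' estimate_efficiency(s)$efficiency   # 1: perfect doubling
#' @export
estimate_efficiency <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  if (length(unique(series$dilution_factor)) < 3L)
    stop("insufficient data: need >= 3 distinct dilution factors")
  log_amount <- -log10(series$dilution_factor)
  fit <- stats::lm(cq ~ log_amount, data = data.frame(
    cq = series$cq, log_amount = log_amount))
  slope <- unname(stats::coef(fit)[["log_amount"]])
  if (!is.finite(slope) || slope >= 0)
    stop("nonnegative slope: Cq must increase with dilution")
  ss_tot <- sum((series$cq - mean(series$cq))^2)
  list(efficiency = 10^(-1 / slope) - 1,
       slope = slope,
       r_squared = 1 - sum(stats::residuals(fit)^2) / ss_tot)
}
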