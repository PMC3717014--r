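#' Normalization factor from a set of reference genes
#'
#' The per-sample normalization factor is the geometric mean of the chosen
#' genes' relative quantities — the geNorm construction. The geometric mean
#' damps the influence of any single gene and is scale-consistent: scaling
#' one gene by d scales the factor by d^(1/n).
#'
#' @param rq positive gene-by-sample matrix.
#' @param genes nonempty character vector of row labels to combine.
#' @return Named numeric vector of per-sample factors (all > 0).
#' @examples
#' rq <- rbind(A = c(1, 4), B = c(4, 1))
#' normalization_factor(rq, c("A", "B"))   # 2 2
#' @export
normalization_factor <- function(rq, genes) {
  rq <- as_rq(rq)
  if (!length(genes)) stop("gene subset must be nonempty")
  missing <- setdiff(genes, rownames(rq))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  exp(colMeans(log(rq[genes, , drop = FALSE])))
}

#' Pairwise-variation series V(n, n+1) for the number of reference genes
#'
#' Starting from the two most stable genes of a stepwise ranking, genes are
#' added one at a time in decreasing stability. V(n, n+1) is the sample
#' standard deviation across samples of log2(NF_n / NF_{n+1}), where NF_n is
#' the normalization factor built from the n most stable genes. A small V
#' means the added gene barely changes normalization; once V drops below the
#' threshold (0.15 by convention), no further gene is needed.
#'
#' @param rq positive gene-by-sample matrix.
#' @param ranking a `ranking_trace` from [rank_genes()] covering the
#'   matrix's genes, or a character vector of genes from most to least
#'   stable.
#' @param threshold acceptance threshold on V (default 0.15).
#' @return An object of class `v_series`: data frame with columns `n`, `v`,
#'   `below_threshold`, plus attributes `gene_order`, `threshold` and
#'   `recommended_n` (smallest n with V < threshold; the total gene count
#'   if no V passes).
#' @export
pairwise_variation_series <- function(rq, ranking, threshold = 0.15) {
  rq <- as_rq(rq)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  order <- if (inherits(ranking, "ranking_trace")) ranking$full_order
           else as.character(ranking)
  if (!setequal(order, rownames(rq)))
    stop("ranking must cover exactly the matrix's genes")
  G <- length(order)
  if (G < 3L) stop("need at least 3 genes")
  ns <- 2:(G - 1L)
  v <- vapply(ns, function(n) {
    nf_n <- normalization_factor(rq, order[seq_len(n)])
    nf_n1 <- normalization_factor(rq, order[seq_len(n + 1L)])
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1))
  out <- data.frame(n = ns, v = v, below_threshold = v < threshold)
  rec <- if (any(out$below_threshold)) min(out$n[out$below_threshold]) else G
  attr(out, "gene_order") <- order
  attr(out, "threshold") <- threshold
  attr(out, "recommended_n") <- rec
  class(out) <- c("v_series", "data.frame")
  out
}

#' @export
print.v_series <- function(x, ...) {
  cat(sprintf("Pairwise variation V(n, n+1), threshold %.3g:\n",
              attr(x, "threshold")))
  print(data.frame(x), row.names = FALSE, ...)
  cat(sprintf("recommended number of reference genes: %d\n",
              attr(x, "recommended_n")))
  invisible(x)
}

#' Pairwise variation of the least stable validated genes
#'
#' Sensitivity check on the recommendation that two reference genes
#' suffice: build the normalization factor from the two *least* stable
#' validated genes and measure the V-style standard deviation of log2 NF
#' ratios when the next least stable validated gene is added. If even the
#' worst validated pair stays below the threshold, any validated pair is an
#' acceptable normalizer. With exactly two validated genes there is no
#' third to add; the pairwise variation between the two genes themselves is
#' reported instead.
#'
#' @param rq positive gene-by-sample matrix.
#' @param validated_genes character vector of genes that passed both
#'   stability gates (>= 2).
#' @param ranking optional `ranking_trace` or most-to-least-stable gene
#'   vector used to identify the least stable validated genes; defaults to
#'   ordering by M-value.
#' @param threshold acceptance threshold on V (default 0.15).
#' @return List with `max_pair_v` (the V of the worst validated pair) and
#'   `all_below` (logical, `max_pair_v < threshold`).
#' @export
worst_pair_check <- function(rq, validated_genes, ranking = NULL,
                             threshold = 0.15) {
  rq <- as_rq(rq)
  validated_genes <- as.character(validated_genes)
  if (length(validated_genes) < 2L)
    stop("need at least 2 validated genes")
  missing <- setdiff(validated_genes, rownames(rq))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  order <- if (is.null(ranking)) {
    m <- m_values(rq[validated_genes, , drop = FALSE])
    names(sort(m))
  } else {
    full <- if (inherits(ranking, "ranking_trace")) ranking$full_order
            else as.character(ranking)
    intersect(full, validated_genes)
  }
  worst <- rev(order)  # least stable first
  if (length(worst) >= 3L) {
    nf2 <- normalization_factor(rq, worst[1:2])
    nf3 <- normalization_factor(rq, worst[1:3])
    v <- stats::sd(log2(nf2 / nf3))
  } else {
    v <- pairwise_variation_matrix(rq[worst, , drop = FALSE])[1L, 2L]
  }
  list(max_pair_v = v, all_below = v < threshold)
}
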