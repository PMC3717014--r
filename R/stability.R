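as_rq <- function(rq) {
  if (!is.matrix(rq) || !is.numeric(rq))
    stop("rq must be a numeric gene-by-sample matrix")
  if (is.null(rownames(rq)))
    rownames(rq) <- paste0("g", seq_len(nrow(rq)))
  if (any(!is.finite(rq) | rq <= 0))
    stop("relative quantities must be finite and > 0")
  rq
}

#' Pairwise-variation matrix of log-ratio standard deviations
#'
#' For genes j and k, entry (j, k) is the sample standard deviation (n - 1
#' denominator) across samples of log2(rq_j / rq_k) — the geNorm pairwise
#' variation. The ratio of two ideal reference genes is constant across
#' samples regardless of expression changes, so this SD measures how far a
#' pair departs from joint stability. Per-sample scaling (e.g. input-amount
#' differences) cancels in the ratio.
#'
#' @param rq positive gene-by-sample matrix (see [relative_quantities()]).
#' @param sd_type `"sample"` (n - 1, geNorm convention, default) or
#'   `"population"` (n) standard deviation.
#' @return Symmetric gene-by-gene matrix with a zero diagonal.
#' @export
pairwise_variation_matrix <- function(rq, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  rq <- as_rq(rq)
  if (nrow(rq) < 2L) stop("need at least 2 genes")
  if (ncol(rq) < 2L) stop("need at least 2 samples")
  L <- log2(rq)
  # sd(x - y)^2 = var(x) + var(y) - 2 cov(x, y)
  C <- stats::cov(t(L))
  if (sd_type == "population") C <- C * (ncol(rq) - 1) / ncol(rq)
  v2 <- outer(diag(C), diag(C), `+`) - 2 * C
  v2[v2 < 0] <- 0  # guard tiny negative round-off
  V <- sqrt(v2)
  diag(V) <- 0
  dimnames(V) <- list(rownames(rq), rownames(rq))
  V
}

#' geNorm expression-stability values (M)
#'
#' The M-value of gene j is the mean over all other candidate genes k of
#' the pairwise variation V(j, k) (see [pairwise_variation_matrix()]).
#' Lower M means more stable expression relative to the panel; for a
#' heterogeneous sample panel, M below 1 marks a reliable reference gene.
#'
#' @inheritParams pairwise_variation_matrix
#' @return Named numeric vector of per-gene M-values.
#' @examples
#' rq <- rbind(A = c(1, 2), B = c(1, 2), C = c(1, 8))
#' m_values(rq)
#' @export
m_values <- function(rq, sd_type = c("sample", "population")) {
  V <- pairwise_variation_matrix(rq, sd_type = sd_type)
  rowSums(V) / (nrow(V) - 1)
}

#' Coefficient of variation of relative quantities
#'
#' Per gene, the sample standard deviation (n - 1) of its relative
#' quantities across samples divided by their mean (CV = sigma / mu). Unlike
#' M, the CV is sensitive to sample-wide content shifts, so the two gates
#' carry different information. Computed on raw relative quantities.
#'
#' @inheritParams pairwise_variation_matrix
#' @return Named numeric vector of per-gene CVs (fractions).
#' @export
cv_values <- function(rq) {
  rq <- as_rq(rq)
  if (ncol(rq) < 2L) stop("need at least 2 samples")
  apply(rq, 1L, stats::sd) / rowMeans(rq)
}

#' Stability cut-off policy
#'
#' Heterogeneous panels (distinct experimental conditions pooled, as in a
#' time-course after nerve injury) use M < 1.0 and CV < 50%; homogeneous
#' panels use the stricter M < 0.5 and CV < 25%. Comparisons are strict.
#'
#' @param panel `"heterogeneous"` (default) or `"homogeneous"`.
#' @param m_cutoff,cv_cutoff optional overrides of the panel defaults.
#' @return A list of class `cutoff_policy`.
#' @export
cutoff_policy <- function(panel = c("heterogeneous", "homogeneous"),
                          m_cutoff = NULL, cv_cutoff = NULL) {
  panel <- match.arg(panel)
  defaults <- switch(panel,
                     heterogeneous = c(m = 1.0, cv = 0.50),
                     homogeneous   = c(m = 0.5, cv = 0.25))
  out <- list(panel = panel,
              m_cutoff = if (is.null(m_cutoff)) defaults[["m"]] else m_cutoff,
              cv_cutoff = if (is.null(cv_cutoff)) defaults[["cv"]] else cv_cutoff)
  stopifnot(out$m_cutoff > 0, out$cv_cutoff > 0)
  class(out) <- "cutoff_policy"
  out
}

#' Classify candidate reference genes against stability cut-offs
#'
#' A gene passes the M gate if its M-value is strictly below the cut-off and
#' the CV gate if its CV is strictly below the CV cut-off; it is validated
#' only when both gates pass. A gene can have an acceptable M yet fail on
#' CV (high gene-specific dispersion), so both are always checked.
#'
#' @param m named per-gene M-values, as from [m_values()].
#' @param cv named per-gene CVs, as from [cv_values()]; names must match `m`.
#' @param policy a [cutoff_policy()].
#' @return Data frame of class `stability_report` with columns `gene`,
#'   `m_value`, `cv`, `passes_m`, `passes_cv`, `validated`.
#' @export
classify_stability <- function(m, cv, policy = cutoff_policy()) {
  stopifnot(inherits(policy, "cutoff_policy"),
            setequal(names(m), names(cv)))
  cv <- cv[names(m)]
  out <- data.frame(gene = names(m),
                    m_value = unname(m),
                    cv = unname(cv),
                    passes_m = unname(m < policy$m_cutoff),
                    passes_cv = unname(cv < policy$cv_cutoff),
                    stringsAsFactors = FALSE)
  out$validated <- out$passes_m & out$passes_cv
  attr(out, "policy") <- policy
  class(out) <- c("stability_report", "data.frame")
  out
}
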