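#' Construct a validated Cq table
#'
#' A Cq table holds well-level quantification-cycle (Cq) observations from an
#' RT-qPCR experiment: one row per well, labelled with sample, gene and
#' technical-replicate index, plus an optional condition (group/timepoint)
#' label. All pipeline stages consume this structure.
#'
#' @param data data frame with columns `sample`, `gene`, `cq` and optionally
#'   `replicate` (defaults to within-group sequence) and `condition`.
#' @param metadata named list of free-form metadata (instrument, notes, ...).
#' @return An object of class `cq_table`: a data frame with columns
#'   `sample`, `gene`, `replicate`, `cq`, `condition` and a `metadata`
#'   attribute.
#' @examples
#' cq_table(data.frame(sample = "s1", gene = c("Actb", "GAPDH"),
#'                     cq = c(19.2, 21.4)))
#' @export
cq_table <- function(data, metadata = list()) {
  stopifnot(is.data.frame(data))
  need <- c("sample", "gene", "cq")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    sample = as.character(data$sample),
    gene = as.character(data$gene),
    replicate = if ("replicate" %in% names(data)) as.integer(data$replicate)
                else stats::ave(seq_len(nrow(data)), data$sample, data$gene,
                                FUN = seq_along),
    cq = as.numeric(data$cq),
    condition = if ("condition" %in% names(data)) as.character(data$condition)
                else NA_character_,
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(out$cq) | out$cq <= 0)
  if (length(bad))
    stop("cq must be finite and > 0; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (any(!is.finite(out$replicate) | out$replicate < 1L))
    stop("replicate indices must be positive integers")
  key <- paste(out$sample, out$gene, out$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- out[which(dup)[1L], ]
    stop(sprintf("duplicate (sample, gene, replicate) = (%s, %s, %d)",
                 d$sample, d$gene, d$replicate))
  }
  attr(out, "metadata") <- metadata
  class(out) <- c("cq_table", "data.frame")
  out
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("Cq table: %d wells, %d sample(s), %d gene(s)\n",
              nrow(x), length(unique(x$sample)), length(unique(x$gene))))
  print(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Construct a per-gene amplification-efficiency table
#'
#' Amplification efficiency E is the per-cycle fractional gain of PCR
#' product: E = 1 means perfect doubling each cycle. Stored as a fraction;
#' values slightly above 1 (up to 1.1) are tolerated because serial-dilution
#' regressions can overshoot, but anything outside (0, 1.1] is rejected.
#'
#' @param gene character vector of gene labels.
#' @param efficiency numeric vector of fractional efficiencies in (0, 1.1].
#' @param source `"provided"` or `"estimated"` (recycled).
#' @return data frame of class `efficiency_table` with columns `gene`,
#'   `efficiency`, `source`.
#' @examples
#' efficiency_table(c("GAPDH", "18S"), c(0.89, 0.78))
#' @export
efficiency_table <- function(gene, efficiency,
                             source = c("provided", "estimated")) {
  source <- match.arg(source)
  gene <- as.character(gene)
  efficiency <- as.numeric(efficiency)
  stopifnot(length(gene) == length(efficiency))
  if (anyDuplicated(gene))
    stop("duplicate gene label(s) in efficiency table")
  bad <- !is.finite(efficiency) | efficiency <= 0 | efficiency > 1.1
  if (any(bad))
    stop("efficiency out of range (0, 1.1] for gene(s): ",
         paste(gene[bad], collapse = ", "))
  out <- data.frame(gene = gene, efficiency = efficiency, source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("efficiency_table", "data.frame")
  out
}

#' Construct a serial-dilution series for one primer pair
#'
#' @param gene gene label.
#' @param dilution_factor positive dilution factors (e.g. 1, 10, 100, 1000
#'   for a ten-fold series); larger means more dilute.
#' @param cq measured Cq at each dilution.
#' @return data frame of class `dilution_series`.
#' @seealso [estimate_efficiency()]
#' @export
dilution_series <- function(gene, dilution_factor, cq) {
  dilution_factor <- as.numeric(dilution_factor)
  cq <- as.numeric(cq)
  stopifnot(length(dilution_factor) == length(cq))
  if (any(!is.finite(dilution_factor) | dilution_factor <= 0))
    stop("dilution factors must be strictly positive")
  if (length(unique(dilution_factor)) < 3L)
    stop("a dilution series needs >= 3 distinct dilution factors")
  out <- data.frame(gene = as.character(gene)[1L],
                    dilution_factor = dilution_factor, cq = cq,
                    stringsAsFactors = FALSE)
  class(out) <- c("dilution_series", "data.frame")
  out
}

sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a Cq table from delimited text
#'
#' Accepts either long format (columns `sample,gene,replicate,cq,condition`;
#' `replicate` and `condition` optional) or wide format (leading columns
#' `sample[,replicate][,condition]`, then one column per gene). The delimiter
#' (comma or tab) is sniffed from the header line.
#'
#' @param path path to a UTF-8 delimited text file with a header.
#' @param format `"auto"` (default), `"long"`, or `"wide"`. Auto detection
#'   treats any file with a `cq` column as long.
#' @return A validated [cq_table()].
#' @export
read_cq_table <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (format == "auto")
    format <- if ("cq" %in% names(raw)) "long" else "wide"
  if (format == "long") {
    miss <- setdiff(c("sample", "gene", "cq"), names(raw))
    if (length(miss))
      stop("long format requires column(s): ", paste(miss, collapse = ", "))
    cqnum <- suppressWarnings(as.numeric(raw$cq))
    bad <- which(is.na(cqnum) & !is.na(raw$cq))
    if (length(bad))
      stop("non-numeric cq in data row(s): ", paste(bad, collapse = ", "))
    raw$cq <- cqnum
    cq_table(raw)
  } else {
    idcols <- intersect(c("sample", "replicate", "condition"), names(raw))
    if (!"sample" %in% idcols)
      stop("wide format requires a 'sample' column")
    genes <- setdiff(names(raw), idcols)
    if (!length(genes)) stop("wide format has no gene columns")
    long <- do.call(rbind, lapply(genes, function(g) {
      cqnum <- suppressWarnings(as.numeric(raw[[g]]))
      bad <- which(is.na(cqnum) & !is.na(raw[[g]]))
      if (length(bad))
        stop(sprintf("non-numeric cq for gene %s in data row(s): %s",
                     g, paste(bad, collapse = ", ")))
      d <- raw[idcols]
      d$gene <- g
      d$cq <- cqnum
      d
    }))
    cq_table(long)
  }
}

#' Write a Cq table as long-format delimited text
#'
#' @param x a [cq_table()].
#' @param path output path; comma-separated with header.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(x, path) {
  stopifnot(inherits(x, "cq_table"))
  utils::write.csv(as.data.frame(x)[c("sample", "gene", "replicate",
                                      "cq", "condition")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-gene efficiency table
#'
#' @param path two-column delimited file with header `gene,efficiency`.
#' @param scale `"auto"` (default), `"fraction"`, or `"percent"`. Auto mode
#'   treats values above 1.5 as percentages: no plausible fractional
#'   efficiency exceeds 1.1 and no plausible percentage is below 50.
#' @return An [efficiency_table()] with fractional efficiencies.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("gene,efficiency", "GAPDH,89", "18S,78"), tf)
#' read_efficiencies(tf)
#' @export
read_efficiencies <- function(path, scale = c("auto", "fraction", "percent")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "efficiency"), names(raw))
  if (length(miss))
    stop("efficiency file requires column(s): ", paste(miss, collapse = ", "))
  e <- as.numeric(raw$efficiency)
  if (any(!is.finite(e))) stop("non-numeric efficiency values")
  pct <- switch(scale,
                percent = rep(TRUE, length(e)),
                fraction = rep(FALSE, length(e)),
                auto = e > 1.5)
  if (any(e[pct] > 110) || any(e[!pct] > 1.1) || any(e <= 0))
    stop("efficiency out of range: must be in (0, 1.1] fraction or ",
         "(0, 110] percent")
  efficiency_table(raw$gene, ifelse(pct, e / 100, e))
}
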