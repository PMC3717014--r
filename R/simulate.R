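with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reference-gene panel used in the nerve-injury study design
#'
#' Seven candidate reference genes commonly used in nervous-system RT-qPCR,
#' with dorsal-horn amplification efficiencies and plausible baseline Cq
#' levels (18S, an rRNA, is far more abundant than the mRNAs, hence its
#' much lower baseline).
#'
#' @return Data frame with columns `gene`, `baseline_cq`, `efficiency`,
#'   `biological_noise_sd` (cycles).
#' @export
sni_gene_panel <- function() {
  data.frame(
    gene = c("18S", "RPL29", "RPL13a", "Actb", "HPRT1", "HMBS", "GAPDH"),
    baseline_cq = c(10, 17, 18, 17.5, 24, 25, 16),
    efficiency = c(0.78, 0.81, 0.88, 0.85, 0.70, 0.78, 0.89),
    biological_noise_sd = 0.2,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a nerve-injury-shaped Cq experiment
#'
#' Encodes the study design being emulated: 7 candidate genes measured in
#' naive animals and at 6 post-surgery timepoints (days 2, 4, 7, 10, 14,
#' 21), 3 biological replicates (rats) per group, triplicate wells. Noise
#' is additive on the Cq (log-expression) scale, the standard qPCR error
#' model: a per-animal sample-content shift common to all genes (RNA
#' input/RT yield), per-gene biological noise, and per-well technical
#' noise. Condition effects are deterministic per-condition Cq shifts
#' (fixed-effect timepoint design); a gene is "unstable" iff any of its
#' condition effects is nonzero.
#'
#' @param genes data frame like [sni_gene_panel()]: columns `gene`,
#'   `baseline_cq`, `efficiency`, `biological_noise_sd`.
#' @param conditions character vector of condition labels.
#' @param n_subjects biological replicates per condition (default 3).
#' @param technical_replicates wells per (sample, gene) (default 3).
#' @param technical_noise_sd per-well Cq noise SD in cycles (default 0.1,
#'   consistent with triplicates passing a 0.5-cycle spread filter).
#' @param sample_content_sd SD in cycles of the per-animal content shift
#'   common to all genes (default 0.15).
#' @param condition_effects numeric matrix (genes x conditions) of Cq
#'   shifts in cycles; default all zero (every gene stable).
#' @return List of class `sim_config`.
#' @seealso [simulate_cq()], [unstable_gene_effects()]
#' @export
sim_config <- function(genes = sni_gene_panel(),
                       conditions = c("naive", "d2", "d4", "d7",
                                      "d10", "d14", "d21"),
                       n_subjects = 3L,
                       technical_replicates = 3L,
                       technical_noise_sd = 0.1,
                       sample_content_sd = 0.15,
                       condition_effects = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "baseline_cq", "efficiency",
                  "biological_noise_sd") %in% names(genes)))
  if (any(genes$efficiency <= 0 | genes$efficiency > 1.1))
    stop("efficiencies must be in (0, 1.1]")
  if (any(genes$biological_noise_sd < 0) || technical_noise_sd < 0 ||
      sample_content_sd < 0)
    stop("noise SDs must be >= 0")
  if (n_subjects < 1L || technical_replicates < 1L)
    stop("n_subjects and technical_replicates must be >= 1")
  if (is.null(condition_effects))
    condition_effects <- matrix(0, nrow(genes), length(conditions))
  stopifnot(nrow(condition_effects) == nrow(genes),
            ncol(condition_effects) == length(conditions))
  dimnames(condition_effects) <- list(genes$gene, conditions)
  structure(list(genes = genes, conditions = conditions,
                 n_subjects = as.integer(n_subjects),
                 technical_replicates = as.integer(technical_replicates),
                 technical_noise_sd = technical_noise_sd,
                 sample_content_sd = sample_content_sd,
                 condition_effects = condition_effects),
            class = "sim_config")
}

#' Condition-effect matrix with one destabilised gene
#'
#' Builds a condition-effects matrix in which a single gene's Cq shifts
#' ramp linearly from 0 in the first (control) condition up to `max_effect`
#' cycles in the last, emulating a gene regulated progressively after
#' injury; all other genes stay flat.
#'
#' @param config a [sim_config()] (used for gene and condition labels).
#' @param gene label of the gene to destabilise.
#' @param max_effect peak Cq shift in cycles (default 1.5).
#' @return Numeric genes-by-conditions matrix of Cq shifts.
#' @export
unstable_gene_effects <- function(config, gene, max_effect = 1.5) {
  stopifnot(inherits(config, "sim_config"),
            gene %in% config$genes$gene)
  eff <- config$condition_effects * 0
  nc <- length(config$conditions)
  eff[gene, ] <- seq(0, max_effect, length.out = nc)
  eff
}

#' Simulate a Cq dataset with controlled stability structure
#'
#' Draws, for each animal j in condition c, a sample-content shift
#' S_j ~ N(0, sample_content_sd); each gene g's true sample Cq is
#' baseline_g + S_j + effect_g(c) + N(0, biological_noise_sd_g), and each
#' technical replicate adds N(0, technical_noise_sd). Identical seeds give
#' identical output. A warning is issued if any simulated Cq exceeds 30
#' cycles, since such wells would be removed by the default QC gate.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return List with `cq` (a [cq_table()]), `efficiencies` (an
#'   [efficiency_table()]), and `truth` (data frame `gene`, `is_stable`,
#'   `max_effect_cycles`).
#' @examples
#' sim <- simulate_cq(sim_config(), seed = 1)
#' nrow(sim$cq)   # 7 genes x 21 samples x 3 wells = 441
#' @export
simulate_cq <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    g <- config$genes
    rows <- vector("list", 0L)
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[[ci]]
      for (j in seq_len(config$n_subjects)) {
        sid <- sprintf("%s_r%d", cond, j)
        shift <- stats::rnorm(1L, 0, config$sample_content_sd)
        true_cq <- g$baseline_cq + shift +
          config$condition_effects[, ci] +
          stats::rnorm(nrow(g), 0, g$biological_noise_sd)
        for (r in seq_len(config$technical_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sid, gene = g$gene, replicate = r,
            cq = true_cq + stats::rnorm(nrow(g), 0,
                                        config$technical_noise_sd),
            condition = cond, stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    if (any(df$cq > 30))
      warning("simulated Cq value(s) above 30 cycles; ",
              "the default QC gate would remove them")
    max_eff <- apply(abs(config$condition_effects), 1L, max)
    list(cq = cq_table(df, metadata = list(origin = "simulate_cq")),
         efficiencies = efficiency_table(g$gene, g$efficiency),
         truth = data.frame(gene = g$gene,
                            is_stable = max_eff == 0,
                            max_effect_cycles = unname(max_eff),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a serial-dilution series for a known efficiency
#'
#' Cq at dilution factor d is
#' anchor_cq + log(d) / log(1 + efficiency) + N(0, noise_sd):
#' each (1 + E)-fold loss of template costs one cycle.
#'
#' @param efficiency fractional amplification efficiency in (0, 1.1].
#' @param anchor_cq Cq of the undiluted point, in cycles.
#' @param dilutions positive dilution factors (default 1, 10, 100, 1000).
#' @param noise_sd Cq noise SD in cycles (default 0).
#' @param gene gene label for the series.
#' @param seed integer seed.
#' @return A [dilution_series()].
#' @export
simulate_dilution_series <- function(efficiency, anchor_cq = 18,
                                     dilutions = c(1, 10, 100, 1000),
                                     noise_sd = 0, gene = "sim",
                                     seed = NULL) {
  if (efficiency <= 0 || efficiency > 1.1)
    stop("efficiency must be in (0, 1.1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(seed, {
    cq <- anchor_cq + log(dilutions) / log(1 + efficiency) +
      stats::rnorm(length(dilutions), 0, noise_sd)
    dilution_series(gene, dilutions, cq)
  })
}
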