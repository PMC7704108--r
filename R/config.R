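#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators in one validated
#' object, so that a single seed reproduces a whole simulated study
#' bit-for-bit.
#'
#' The defaults encode the study conditions the generators emulate: a
#' sustained TNF-alpha stimulation driving TET-dependent demethylation at
#' p65-bound kappaB sites. `demethylation_scale` (delta) is the maximal
#' per-CpG methylation loss at the motif center; `decay_length` (lambda) is
#' the exponential length scale of the loss away from the motif;
#' `occupancy_decay` (beta) converts total methylation (methylated-CpG
#' equivalents) into fold-loss of p65 occupancy, with the default ln 2
#' meaning one methylated-CpG equivalent halves occupancy.
#'
#' Genotype multipliers scale the demethylation: WT 1.0, TET2_KO 0.3,
#' TET3_KO 0.7, TET1_KO 0.95, RELA_KO 0.05, TET_TKO 0.05 — chosen so that
#' demethylation depends mainly on TET2, partly on TET3, barely on TET1,
#' and requires p65; they are simulator knobs, not estimates.
#'
#' @param seed Integer seed; identical configs give bit-identical outputs.
#' @param n_genes,n_peaks Feature counts for the toy genome.
#' @param genome_length Toy chromosome length in bp.
#' @param conversion_efficiency Probability that an unmethylated (non-CpG)
#'   C is bisulfite-converted to T.
#' @param sequencing_error_rate Per-base probability of a random
#'   substitution in a sequenced clone.
#' @param genotype One of `"WT"`, `"RELA_KO"`, `"TET1_KO"`, `"TET2_KO"`,
#'   `"TET3_KO"`, `"TET_TKO"`.
#' @param demethylation_scale Maximal per-CpG methylation loss (fraction).
#' @param decay_length Exponential decay length of demethylation from the
#'   motif center, bp.
#' @param occupancy_decay Occupancy loss per methylated-CpG equivalent
#'   (natural-log scale).
#' @param coverage Simulated read coverage per CpG for methylation counts.
#' @param noise_sd Lognormal noise, log2 units, for expression and
#'   occupancy.
#' @param n_replicates Replicates per expression condition.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, genotype = "TET2_KO")
#' cfg$demethylation_scale
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 30L,
                       n_peaks = 20L,
                       genome_length = 1e6,
                       conversion_efficiency = 0.99,
                       sequencing_error_rate = 0.001,
                       genotype = c("WT", "RELA_KO", "TET1_KO", "TET2_KO",
                                    "TET3_KO", "TET_TKO"),
                       demethylation_scale = 0.6,
                       decay_length = 300,
                       occupancy_decay = log(2),
                       coverage = 30L,
                       noise_sd = 0.1,
                       n_replicates = 2L) {
  genotype <- match.arg(genotype)
  stopifnot(length(seed) == 1, is.finite(seed))
  for (p in c(conversion_efficiency, sequencing_error_rate,
              demethylation_scale)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      abort("probabilities and fractions must lie in [0, 1]")
    }
  }
  for (ct in list(n_genes = n_genes, n_peaks = n_peaks,
                  genome_length = genome_length, coverage = coverage,
                  n_replicates = n_replicates)) {
    if (!is.numeric(ct) || ct <= 0) abort("counts must be > 0")
  }
  if (decay_length <= 0) abort("decay_length must be > 0 bp")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(
    list(seed = as.integer(seed),
         n_genes = as.integer(n_genes),
         n_peaks = as.integer(n_peaks),
         genome_length = as.integer(genome_length),
         conversion_efficiency = conversion_efficiency,
         sequencing_error_rate = sequencing_error_rate,
         genotype = genotype,
         demethylation_scale = demethylation_scale,
         decay_length = decay_length,
         occupancy_decay = occupancy_decay,
         coverage = coverage,
         noise_sd = noise_sd,
         n_replicates = as.integer(n_replicates)),
    class = "sim_config")
}

#' Genotype multiplier for simulated demethylation
#'
#' @param genotype Genotype label as in [sim_config()].
#' @return Scalar multiplier applied to the demethylation amplitude.
#' @export
genotype_multiplier <- function(genotype) {
  g <- c(WT = 1.0, TET2_KO = 0.3, TET3_KO = 0.7, TET1_KO = 0.95,
         RELA_KO = 0.05, TET_TKO = 0.05)
  if (!genotype %in% names(g)) abort(paste0("unknown genotype: ", genotype))
  unname(g[[genotype]])
}

#' Read or write a simulation/run configuration as YAML
#'
#' Flat key-value YAML; round-trips read -> write -> read unchanged.
#'
#' @param path File path.
#' @return `read_run_config()` returns a named list; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  yaml::read_yaml(path)
}

#' @param config Named list (or `sim_config`) to serialize.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# kB consensus used when planting motifs: the classic NF-kB site.
KB_CONSENSUS <- "GGGACTTTCC"

#' Default kappaB position weight matrix
#'
#' A near-consensus probability PWM for the canonical NF-kB binding site
#' GGGACTTTCC, with weight `1 - 3 * eps` on the consensus base and `eps`
#' elsewhere. Columns (positions) sum to 1.
#'
#' @param eps Off-consensus base probability.
#' @return A 4 x 10 numeric matrix, rows named A, C, G, T.
#' @export
kb_pwm <- function(eps = 0.04) {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(KB_CONSENSUS, "")[[1]]
  m <- matrix(eps, nrow = 4, ncol = length(cons), dimnames = list(bases))
  for (j in seq_along(cons)) m[cons[j], j] <- 1 - 3 * eps
  m
}
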