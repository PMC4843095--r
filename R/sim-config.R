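#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults mirror the design of the heat-stress root
#' experiment the pipeline targets: two root fractions (root hairs `RH`
#' and stripped roots `STR`), a 25 vs 40 degree C contrast at 0/3/6/12/24 h,
#' two biological replicates, plate-level batching, and 8-plex iTRAQ
#' proteomics with two pooled-reference channels and three replicates per
#' temperature.
#'
#' @param n_genes number of genes in the simulated count matrix.
#' @param n_tf number of transcription factors for module simulation.
#' @param tissues character vector of tissue labels.
#' @param timepoints numeric vector of treatment times in hours.
#' @param n_replicates biological replicates per tissue x time x treatment.
#' @param n_plates number of plates per tissue x time (batch factor).
#' @param libsize_range length-2 positive range from which per-sample
#'   library sizes are drawn uniformly.
#' @param de_fraction proportion of genes (or proteins) with a planted
#'   treatment effect.
#' @param effect_log_fc natural-log treatment effect for true DE genes;
#'   the default `log(2)` is a two-fold change. The planted protein shift
#'   is the same effect expressed in log2 units.
#' @param sigma_rep,sigma_plate SDs of the per-gene replicate and plate
#'   random intercepts (natural-log scale).
#' @param n_modules number of planted regulatory modules.
#' @param tree_depth depth of planted regulator trees.
#' @param leaf_sep separation between adjacent leaf mean expression
#'   regimes (log2 fold-change units).
#' @param noise_sd residual SD around leaf means (module simulation) and
#'   around channel means (iTRAQ simulation, log2 units).
#' @param n_proteins number of proteins in the simulated spectrum report.
#' @param peptides_per_protein length-2 integer range of peptides drawn
#'   per protein.
#' @param n_channels iTRAQ plex width; fixed at 8.
#' @param ref_channels two distinct channel indices in 1..8 carrying the
#'   pooled reference.
#' @param missing_rate completely-at-random missingness rate applied to
#'   scan-level reporter intensities.
#' @param seed master RNG seed; all generators are deterministic given it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 42)
#' cfg$de_fraction
sim_config <- function(n_genes = 2000, n_tf = 5,
                       tissues = c("RH", "STR"),
                       timepoints = c(0, 3, 6, 12, 24),
                       n_replicates = 2, n_plates = 2,
                       libsize_range = c(8e5, 1.2e6),
                       de_fraction = 0.10, effect_log_fc = log(2),
                       sigma_rep = 0.1, sigma_plate = 0.1,
                       n_modules = 10, tree_depth = 2, leaf_sep = 4,
                       noise_sd = 0.1,
                       n_proteins = 500, peptides_per_protein = c(2L, 5L),
                       n_channels = 8L, ref_channels = c(4L, 8L),
                       missing_rate = 0.05, seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_tf = n_tf, tissues = as.character(tissues),
    timepoints = as.numeric(timepoints), n_replicates = n_replicates,
    n_plates = n_plates, libsize_range = as.numeric(libsize_range),
    de_fraction = de_fraction, effect_log_fc = effect_log_fc,
    sigma_rep = sigma_rep, sigma_plate = sigma_plate,
    n_modules = n_modules, tree_depth = tree_depth, leaf_sep = leaf_sep,
    noise_sd = noise_sd, n_proteins = n_proteins,
    peptides_per_protein = as.integer(peptides_per_protein),
    n_channels = as.integer(n_channels),
    ref_channels = as.integer(ref_channels),
    missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(is_count(cfg$n_genes), "n_genes must be a count >= 1")
  assert_that(is_count(cfg$n_tf), "n_tf must be a count >= 1")
  assert_that(length(cfg$tissues) >= 1, "at least one tissue required")
  assert_that(length(cfg$timepoints) >= 1, "at least one timepoint required")
  assert_that(is_count(cfg$n_replicates), "n_replicates must be >= 1")
  assert_that(is_count(cfg$n_plates), "n_plates must be >= 1")
  assert_that(length(cfg$libsize_range) == 2 && all(cfg$libsize_range > 0) &&
                cfg$libsize_range[1] <= cfg$libsize_range[2],
              "libsize_range must be an increasing positive pair")
  assert_that(is_prop(cfg$de_fraction), "de_fraction must be in [0,1]")
  assert_that(is.finite(cfg$effect_log_fc), "effect_log_fc must be finite")
  assert_that(cfg$sigma_rep >= 0 && cfg$sigma_plate >= 0,
              "random-effect SDs must be nonnegative")
  assert_that(is_count(cfg$n_modules), "n_modules must be >= 1")
  assert_that(is_count(cfg$tree_depth, min = 0L), "tree_depth must be >= 0")
  assert_that(cfg$noise_sd > 0, "noise_sd must be positive")
  assert_that(is_count(cfg$n_proteins), "n_proteins must be >= 1")
  assert_that(length(cfg$peptides_per_protein) == 2 &&
                all(cfg$peptides_per_protein >= 1) &&
                cfg$peptides_per_protein[1] <= cfg$peptides_per_protein[2],
              "peptides_per_protein must be a nonempty count range")
  assert_that(cfg$n_channels == 8L, "n_channels is fixed at 8 (8-plex iTRAQ)")
  assert_that(length(cfg$ref_channels) == 2 &&
                cfg$ref_channels[1] != cfg$ref_channels[2] &&
                all(cfg$ref_channels %in% 1:8),
              "ref_channels must be two distinct channels in 1..8")
  assert_that(is_prop(cfg$missing_rate), "missing_rate must be in [0,1]")
  assert_that(is_count(cfg$seed, min = 0L), "seed must be a nonneg integer")
  invisible(cfg)
}
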