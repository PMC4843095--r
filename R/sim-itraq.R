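#' Simulate an 8-plex iTRAQ spectrum report with planted protein shifts
#'
#' Emits scan-level peptide-spectrum records for `n_proteins` proteins.
#' Each plex covers one tissue x time block: the six non-reference
#' channels carry three 25 degree C and three 40 degree C replicates, and
#' the two `ref_channels` carry the pooled reference (the mean of the six
#' sample signals). Per peptide and channel, the true log2 abundance is
#' `protein baseline + peptide ionization offset + planted heat shift
#' (affected proteins, heat channels) + N(0, noise_sd^2)`.
#' Scan-level reporter intensities are the linear-scale abundances times
#' a lognormal per-scan scale factor, so the base peak (their sum) makes
#' [channel_intensities_from_scan()] exactly invertible. Reporter values
#' are zeroed completely at random at `missing_rate`.
#'
#' A fraction `de_fraction` of proteins receives a heat shift of
#' `effect_log_fc / log(2)` log2 units (a two-fold change by default).
#'
#' @param config a [sim_config()] object; plexes are generated for each
#'   tissue and each positive timepoint.
#' @return list with `spectra` (tibble: scan, peptide, protein, plex,
#'   fraction, base_peak, ch1..ch8), `channel_design` (tibble: plex,
#'   channel, sample_id, tissue, treatment, time_h, replicate, is_ref)
#'   and `truth` (list with `protein_effects`: tibble of protein_id,
#'   tissue, time_h, log2_shift for affected proteins).
#' @export
gen_itraq_peptides <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 3L), {
    times <- config$timepoints[config$timepoints > 0]
    assert_that(length(times) >= 1, "need at least one positive timepoint")
    blocks <- expand.grid(time_h = times, tissue = config$tissues,
                          stringsAsFactors = FALSE)
    design <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b)
      plex_design(sprintf("plex%02d", b), blocks$tissue[b],
                  blocks$time_h[b], config$ref_channels)))
    design <- tibble::as_tibble(design)

    prot_ids <- sprintf("prot%04d", seq_len(config$n_proteins))
    n_de <- round(config$de_fraction * config$n_proteins)
    de_idx <- if (n_de > 0) sort(sample.int(config$n_proteins, n_de))
              else integer(0)
    shift <- numeric(config$n_proteins)
    shift[de_idx] <- config$effect_log_fc / log(2)

    base <- runif(config$n_proteins, 14, 20)
    plexes <- unique(design$plex)
    rows <- vector("list", 2000)
    nr <- 0L
    scan_no <- 0L
    for (pr in seq_len(config$n_proteins)) {
      n_pep <- sample(seq(config$peptides_per_protein[1],
                          config$peptides_per_protein[2]), 1)
      pep_off <- rnorm(n_pep, 0, 1.5)
      for (pe in seq_len(n_pep)) {
        pep_id <- sprintf("%s_pep%d", prot_ids[pr], pe)
        for (px in plexes) {
          dch <- design[design$plex == px, ]
          heat <- as.numeric(dch$treatment == "heat_40C" & !dch$is_ref)
          v <- base[pr] + pep_off[pe] + shift[pr] * heat
          v[dch$is_ref] <- base[pr] + pep_off[pe] +
            mean(shift[pr] * (dch$treatment[!dch$is_ref] == "heat_40C"))
          v <- v + rnorm(8, 0, config$noise_sd)
          n_scans <- sample(1:3, 1)
          # missing channels are absent from every scan of the peptide,
          # so consolidation yields a missing value rather than a
          # systematically low sum
          miss <- runif(8) < config$missing_rate
          for (s in seq_len(n_scans)) {
            scale <- rlnorm(1, 0, 0.3)
            rep_int <- 2^v * scale
            rep_int[miss] <- 0
            if (all(rep_int == 0)) next
            scan_no <- scan_no + 1L
            nr <- nr + 1L
            if (nr > length(rows)) rows <- c(rows, vector("list", nr))
            rows[[nr]] <- data.frame(
              scan = sprintf("scan%06d", scan_no), peptide = pep_id,
              protein = prot_ids[pr], plex = px,
              fraction = sprintf("f%02d", sample.int(12, 1)),
              base_peak = sum(rep_int), t(setNames(rep_int, paste0("ch", 1:8))))
          }
        }
      }
    }
    spectra <- tibble::as_tibble(do.call(rbind, rows[seq_len(nr)]))

    effects <- expand.grid(protein_id = prot_ids[de_idx],
                           tissue = config$tissues, time_h = times,
                           stringsAsFactors = FALSE)
    effects$log2_shift <- rep(shift[de_idx],
                              length(config$tissues) * length(times))
    list(spectra = spectra, channel_design = design,
         truth = list(protein_effects = tibble::as_tibble(effects)))
  })
}

# channel layout of one plex: non-reference channels split into a 25C
# half and a 40C half, three replicates each with the default 8-plex
plex_design <- function(plex, tissue, time_h, ref_channels) {
  ch <- 1:8
  is_ref <- ch %in% ref_channels
  samp <- ch[!is_ref]
  n_half <- length(samp) %/% 2
  treatment <- rep(NA_character_, 8)
  replicate <- rep(NA_integer_, 8)
  treatment[samp[seq_len(n_half)]] <- "control_25C"
  treatment[samp[n_half + seq_len(length(samp) - n_half)]] <- "heat_40C"
  replicate[samp] <- c(seq_len(n_half), seq_len(length(samp) - n_half))
  data.frame(
    plex = plex, channel = ch,
    sample_id = ifelse(is_ref, paste0(plex, "_ref", cumsum(is_ref)[ch]),
                       sprintf("%s_%s_t%g_%s_r%d", plex, tissue, time_h,
                               ifelse(treatment == "heat_40C", "heat",
                                      "ctrl"), replicate)),
    tissue = tissue, treatment = treatment, time_h = time_h,
    replicate = replicate, is_ref = is_ref)
}
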