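# iTRAQ reporter-ion quantification: scan-level channel intensities,
# peptide consolidation, pooled-reference + central-tendency
# normalization, Rrollup peptide-to-protein aggregation, and
# per-time-point ANOVA differential testing.

#' Channel intensities of one MS/MS scan
#'
#' Distributes the scan's base-peak intensity over the eight reporter
#' channels proportionally to the reporter-ion fractions:
#' `intensity_c = base_peak * reporter_c / sum(reporter)`. The
#' intensities therefore always sum to the base peak.
#'
#' @param reporter numeric vector of 8 nonnegative reporter-ion
#'   intensities.
#' @param base_peak positive base-peak intensity of the scan.
#' @return numeric vector of 8 channel intensities, or `NULL` (with a
#'   warning) when every reporter is zero.
#' @export
#' @examples
#' channel_intensities_from_scan(c(3, 1, 0, 0, 0, 0, 0, 0), 100)
channel_intensities_from_scan <- function(reporter, base_peak) {
  assert_that(length(reporter) == 8 && all(reporter >= 0),
              "reporter must be 8 nonnegative intensities")
  assert_that(base_peak > 0, "base_peak must be positive")
  tot <- sum(reporter)
  if (tot == 0) {
    warning("scan with all-zero reporters skipped")
    return(NULL)
  }
  base_peak * reporter / tot
}

#' Consolidate scans into peptide-level log2 abundances
#'
#' Converts each scan to channel intensities, sums multiple scans of the
#' same peptide within a plex channel-wise, and log2-transforms the
#' sums. Channels that are zero after summation become missing values
#' (`NA`), never `-Inf`.
#'
#' @param spectra spectrum report: data frame with columns `scan`,
#'   `peptide`, `protein`, `plex`, `base_peak`, `ch1`..`ch8`.
#' @return tibble with one row per peptide x plex: `protein`, `peptide`,
#'   `plex`, `ch1`..`ch8` (log2 intensities, NA where absent).
#' @export
consolidate_peptides <- function(spectra) {
  chcols <- paste0("ch", 1:8)
  assert_that(all(c("peptide", "protein", "plex", "base_peak", chcols)
                  %in% names(spectra)),
              "spectrum report is missing required columns")
  rep_mat <- as.matrix(spectra[, chcols])
  tot <- rowSums(rep_mat)
  keep <- tot > 0
  if (any(!keep))
    warning(sum(!keep), " scan(s) with all-zero reporters skipped")
  ints <- rep_mat[keep, , drop = FALSE] *
    (spectra$base_peak[keep] / tot[keep])
  key <- interaction(spectra$protein[keep], spectra$peptide[keep],
                     spectra$plex[keep], drop = TRUE)
  summed <- rowsum(ints, key)
  # rowsum orders rows by the key's levels; align metadata the same way
  first <- match(rownames(summed), as.character(key))
  meta <- spectra[keep, c("protein", "peptide", "plex")][first, ]
  lg <- log2(summed)
  lg[!is.finite(lg)] <- NA_real_
  out <- tibble::as_tibble(cbind(meta, as.data.frame(lg)))
  out[order(out$protein, out$peptide, out$plex), ]
}

#' Pooled-reference and central-tendency normalization
#'
#' Two-step normalization of peptide log2 abundances. Step 1 subtracts
#' from each peptide row the mean of its two pooled-reference channels,
#' bridging plexes onto a common scale; peptides whose reference
#' channels are both missing are dropped (with a message). Step 2
#' removes channel bias by shifting every plex x channel column so its
#' median equals the global median of all (post-step-1) values.
#'
#' @param peptides peptide table from [consolidate_peptides()].
#' @param ref_channels integer pair of pooled-reference channels.
#' @return normalized peptide table (same shape, possibly fewer rows).
#' @export
normalize_peptides <- function(peptides, ref_channels = c(4L, 8L)) {
  chcols <- paste0("ch", 1:8)
  assert_that(length(ref_channels) == 2 && all(ref_channels %in% 1:8) &&
                ref_channels[1] != ref_channels[2],
              "ref_channels must be two distinct channels in 1..8")
  vals <- as.matrix(peptides[, chcols])
  refs <- vals[, paste0("ch", ref_channels), drop = FALSE]
  ref_mean <- rowMeans(refs, na.rm = TRUE)
  drop <- !is.finite(ref_mean)
  if (any(drop))
    message(sum(drop), " peptide row(s) dropped: reference channels missing")
  peptides <- peptides[!drop, ]
  vals <- vals[!drop, , drop = FALSE] - ref_mean[!drop]

  global_med <- median(vals, na.rm = TRUE)
  for (px in unique(peptides$plex)) {
    sel <- peptides$plex == px
    for (ch in chcols) {
      col_med <- median(vals[sel, ch], na.rm = TRUE)
      if (is.finite(col_med))
        vals[sel, ch] <- vals[sel, ch] + (global_med - col_med)
    }
  }
  peptides[, chcols] <- as.data.frame(vals)
  peptides
}

#' Rrollup: aggregate peptide abundances to one protein profile
#'
#' Chooses the reference peptide with the most presence (fewest missing
#' values), breaking ties by highest median abundance and then by input
#' order; scales every other peptide onto it by adding the median
#' difference `reference - peptide` over their shared samples; and
#' returns the per-sample median of the scaled peptides. Peptides
#' sharing no samples with the reference are excluded (with a message).
#'
#' @param pep_mat numeric matrix, peptides x samples, log2 scale, `NA`
#'   for missing.
#' @return numeric vector of per-sample protein abundances.
#' @export
rrollup_protein <- function(pep_mat) {
  pep_mat <- as.matrix(pep_mat)
  assert_that(nrow(pep_mat) >= 1, "at least one peptide required")
  if (nrow(pep_mat) == 1) return(pep_mat[1, ])
  n_miss <- rowSums(is.na(pep_mat))
  meds <- apply(pep_mat, 1, median, na.rm = TRUE)
  ref <- order(n_miss, -meds)[1]

  scaled <- pep_mat
  keep <- rep(TRUE, nrow(pep_mat))
  for (i in seq_len(nrow(pep_mat))) {
    if (i == ref) next
    shared <- !is.na(pep_mat[ref, ]) & !is.na(pep_mat[i, ])
    if (!any(shared)) {
      keep[i] <- FALSE
      next
    }
    scaled[i, ] <- pep_mat[i, ] +
      median(pep_mat[ref, shared] - pep_mat[i, shared])
  }
  if (any(!keep))
    message(sum(!keep), " peptide(s) share no samples with the reference;",
            " excluded")
  apply(scaled[keep, , drop = FALSE], 2, median, na.rm = TRUE)
}

#' Per-time-point protein differential testing
#'
#' One-way ANOVA between the 25 and 40 degree C groups of each protein
#' at each time point, Benjamini-Hochberg correction across proteins
#' within the time point, and a log2 fold change defined as
#' `mean(40C) - mean(25C)` in log2 abundance. A protein is called when
#' its adjusted p-value is below `p_threshold` and `|log2_fc| >=
#' log2(min_fold)`; proteins with fewer than two values in either group
#' are marked untestable (`NA` p-values, never called).
#'
#' @param abundance numeric matrix, proteins x samples (log2 scale).
#' @param sample_design data frame with `sample_id`, `treatment`,
#'   `time_h` describing the abundance columns.
#' @param p_threshold adjusted-p cutoff (default 0.05).
#' @param min_fold minimum linear fold change (default 2).
#' @param global_correction apply BH across all time points jointly
#'   instead of within each time point.
#' @return tibble: protein_id, time_h, f_stat, p_value, p_adjusted,
#'   log2_fc, testable, called.
#' @export
protein_de_test <- function(abundance, sample_design, p_threshold = 0.05,
                            min_fold = 2, global_correction = FALSE) {
  abundance <- as.matrix(abundance)
  assert_that(all(colnames(abundance) %in% sample_design$sample_id),
              "every abundance column needs a design row")
  sample_design <-
    sample_design[match(colnames(abundance), sample_design$sample_id), ]
  out <- list()
  for (t in sort(unique(sample_design$time_h))) {
    sel_c <- sample_design$time_h == t &
      sample_design$treatment == "control_25C"
    sel_h <- sample_design$time_h == t &
      sample_design$treatment == "heat_40C"
    p <- l2fc <- fs <- rep(NA_real_, nrow(abundance))
    testable <- logical(nrow(abundance))
    for (i in seq_len(nrow(abundance))) {
      x <- abundance[i, sel_c]
      yv <- abundance[i, sel_h]
      x <- x[!is.na(x)]
      yv <- yv[!is.na(yv)]
      if (length(x) < 2 || length(yv) < 2) next
      testable[i] <- TRUE
      l2fc[i] <- mean(yv) - mean(x)
      ft <- anova_two_group(x, yv)
      p[i] <- ft$p
      fs[i] <- ft$f
    }
    out[[length(out) + 1]] <- tibble::tibble(
      protein_id = rownames(abundance), time_h = t, f_stat = fs,
      p_value = p, log2_fc = l2fc, testable = testable)
  }
  res <- do.call(rbind, out)
  if (global_correction) {
    res$p_adjusted <- NA_real_
    res$p_adjusted[res$testable] <- p.adjust(res$p_value[res$testable],
                                             method = "BH")
  } else {
    res$p_adjusted <- NA_real_
    for (t in unique(res$time_h)) {
      sel <- res$time_h == t & res$testable
      res$p_adjusted[sel] <- p.adjust(res$p_value[sel], method = "BH")
    }
  }
  res$called <- !is.na(res$p_adjusted) & res$p_adjusted < p_threshold &
    abs(res$log2_fc) >= log2(min_fold)
  res[, c("protein_id", "time_h", "f_stat", "p_value", "p_adjusted",
          "log2_fc", "testable", "called")]
}

# two-group one-way ANOVA with graceful degenerate handling
anova_two_group <- function(x, y) {
  if (var(c(x, y)) == 0) return(list(f = 0, p = 1))  # identical groups
  ft <- try(oneway.test(v ~ g,
                        data = data.frame(v = c(x, y),
                                          g = rep(c("a", "b"),
                                                  c(length(x), length(y)))),
                        var.equal = TRUE), silent = TRUE)
  if (inherits(ft, "try-error") || !is.finite(ft$p.value)) {
    # zero within-group variance with distinct means
    return(list(f = Inf, p = 0))
  }
  list(f = unname(ft$statistic), p = ft$p.value)
}

#' Run the full iTRAQ protein quantification chain
#'
#' [consolidate_peptides()] on the spectrum report, pooled-reference and
#' central-tendency normalization, [rrollup_protein()] per protein over
#' the non-reference sample channels, and [protein_de_test()] per time
#' point.
#'
#' @param spectra spectrum report (see [consolidate_peptides()]).
#' @param channel_design plex x channel design with columns `plex`,
#'   `channel`, `sample_id`, `treatment`, `time_h`, `is_ref`.
#' @param ref_channels pooled-reference channels (default 4 and 8).
#' @inheritParams protein_de_test
#' @return list with `abundance` (protein x sample matrix) and `results`
#'   (tibble from [protein_de_test()]).
#' @export
run_proteome <- function(spectra, channel_design, ref_channels = c(4L, 8L),
                         p_threshold = 0.05, min_fold = 2,
                         global_correction = FALSE) {
  peptides <- consolidate_peptides(spectra)
  peptides <- normalize_peptides(peptides, ref_channels = ref_channels)

  samp <- channel_design[!channel_design$is_ref, ]
  proteins <- unique(peptides$protein)
  abundance <- matrix(NA_real_, length(proteins), nrow(samp),
                      dimnames = list(proteins, samp$sample_id))
  for (pr in proteins) {
    sub <- peptides[peptides$protein == pr, ]
    pep_mat <- matrix(NA_real_, length(unique(sub$peptide)), nrow(samp),
                      dimnames = list(unique(sub$peptide), samp$sample_id))
    for (r in seq_len(nrow(sub))) {
      sel <- samp$plex == sub$plex[r]
      pep_mat[sub$peptide[r], samp$sample_id[sel]] <-
        as.numeric(sub[r, paste0("ch", samp$channel[sel])])
    }
    abundance[pr, ] <- rrollup_protein(pep_mat)
  }
  results <- protein_de_test(abundance, samp, p_threshold = p_threshold,
                             min_fold = min_fold,
                             global_correction = global_correction)
  list(abundance = abundance, results = results)
}
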