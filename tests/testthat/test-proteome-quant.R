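# iTRAQ quantification: channel intensities, consolidation,
# normalization and Rrollup against hand-computed fixtures, and the
# per-time-point ANOVA stage.

test_that("channel intensities distribute the base peak by reporter fraction", {
  expect_equal(channel_intensities_from_scan(rep(1, 8), 800), rep(100, 8))
  expect_equal(channel_intensities_from_scan(c(3, 1, rep(0, 6)), 100),
               c(75, 25, rep(0, 6)))
  set.seed(5)
  for (i in 1:20) {
    rep_int <- runif(8, 0, 1e4)
    bp <- runif(1, 1, 1e6)
    expect_equal(sum(channel_intensities_from_scan(rep_int, bp)), bp)
  }
  expect_warning(out <- channel_intensities_from_scan(rep(0, 8), 10),
                 "all-zero")
  expect_null(out)
})

test_that("scan consolidation sums intensities and log2-transforms", {
  base <- tibble::tibble(
    scan = c("s1", "s2"), peptide = "pep1", protein = "P1", plex = "plex01",
    fraction = "f01", base_peak = c(800, 800))
  ints <- matrix(c(400, 200, 100, 50, 25, 15, 7, 3), 2, 8, byrow = TRUE)
  ints[2, ] <- ints[1, ]  # identical second scan
  colnames(ints) <- paste0("ch", 1:8)
  spectra <- cbind(base, tibble::as_tibble(ints))
  spectra$base_peak <- rowSums(ints)
  pep <- consolidate_peptides(spectra)
  expect_equal(nrow(pep), 1)
  # doubling a scan adds exactly +1 in log2
  single <- consolidate_peptides(spectra[1, ])
  expect_equal(as.numeric(pep[1, paste0("ch", 1:8)]),
               as.numeric(single[1, paste0("ch", 1:8)]) + 1)
  expect_equal(as.numeric(single[1, "ch1"]), log2(400))
  # zero after summation is missing, never -Inf
  spectra$ch8 <- 0
  spectra$base_peak <- spectra$base_peak - 3
  pep0 <- consolidate_peptides(spectra)
  expect_true(is.na(pep0$ch8))
  expect_false(any(is.infinite(as.matrix(pep0[, paste0("ch", 1:8)]))))
})

test_that("normalization removes peptide reference level and channel bias", {
  chcols <- paste0("ch", 1:8)
  tab <- tibble::tibble(
    protein = c("P1", "P2"), peptide = c("pep1", "pep2"),
    plex = "plex01")
  tab[, chcols] <- NA_real_
  tab[1, chcols] <- as.list(c(1, 2, 3, 2, 4, 5, 6, 4))
  tab[2, chcols] <- as.list(rep(5, 8))
  norm <- normalize_peptides(tab, ref_channels = c(4, 8))
  # hand-computed: step 1 subtracts ref means (3 and 5), step 2 shifts
  # each channel median to the global median 0
  expect_equal(as.numeric(norm[1, chcols]),
               c(-1, -0.5, 0, -0.5, 0.5, 1, 1.5, 0.5))
  expect_equal(as.numeric(norm[2, chcols]),
               c(1, 0.5, 0, 0.5, -0.5, -1, -1.5, -0.5))

  # a peptide equal to its references everywhere collapses to a constant
  # after step 1 (bridging across plexes)
  tab2 <- tibble::tibble(protein = "P1", peptide = "pep1",
                         plex = c("plex01", "plex02"))
  tab2[, chcols] <- NA_real_
  tab2[1, chcols] <- as.list(rep(7, 8))    # plex 1 overall level 7
  tab2[2, chcols] <- as.list(rep(12, 8))   # plex 2 overall level 12
  norm2 <- normalize_peptides(tab2)
  expect_equal(as.numeric(unlist(norm2[, chcols])), rep(0, 16))

  # peptides with both reference channels missing are dropped
  tab$ch4 <- NA_real_
  tab$ch8 <- NA_real_
  expect_message(norm3 <- normalize_peptides(tab), "dropped")
  expect_equal(nrow(norm3), 0)
})

test_that("Rrollup scales peptides to the most present, most abundant one", {
  # single peptide passes through untouched
  m1 <- matrix(c(1, 2, NA, 4), 1, dimnames = list("pep1", paste0("s", 1:4)))
  expect_equal(rrollup_protein(m1), m1[1, ])

  # parallel peptides collapse onto the reference exactly; the higher-
  # abundance peptide wins the reference tie, fixing the overall level
  sig <- c(0, 1, 2, 3)
  m2 <- rbind(pep1 = sig, pep2 = sig + 3)
  colnames(m2) <- paste0("s", 1:4)
  expect_equal(rrollup_protein(m2), setNames(sig + 3, colnames(m2)))

  # hand-computed: planted signal + offsets + one outlier sample;
  # the per-sample median rejects the outlier
  m3 <- rbind(pep1 = sig,
              pep2 = c(3, NA, 5, 6),
              pep3 = c(-2, -1, 10, 1))
  colnames(m3) <- paste0("s", 1:4)
  expect_equal(rrollup_protein(m3), setNames(c(0, 1, 2, 3), colnames(m3)))

  # shift invariance: adding a constant to one non-reference peptide row
  # leaves the protein estimate unchanged
  m4 <- m3
  m4["pep2", ] <- m4["pep2", ] + 57
  expect_equal(rrollup_protein(m4), rrollup_protein(m3))

  # peptides sharing no samples with the reference are excluded
  m5 <- rbind(pep1 = c(1, 2, NA), pep2 = c(NA, NA, 9))
  colnames(m5) <- paste0("s", 1:3)
  expect_message(out <- rrollup_protein(m5), "no samples")
  expect_equal(unname(out[1:2]), c(1, 2))
})

test_that("protein ANOVA reproduces hand-computed sums of squares", {
  ab <- matrix(c(1, 2, 3, 4, 5, 6), 1,
               dimnames = list("P1", paste0("s", 1:6)))
  des <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    treatment = rep(c("control_25C", "heat_40C"), each = 3),
    time_h = 3)
  res <- protein_de_test(ab, des)
  expect_equal(res$f_stat, 13.5)          # SSB 13.5 / MSW 1, df (1, 4)
  expect_equal(res$log2_fc, 3)
  expect_equal(res$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_true(res$called)                  # adj p < 0.05 and |fc| >= 1

  # identical groups: F = 0, p = 1, fc = 0
  ab0 <- matrix(rep(2, 6), 1, dimnames = list("P1", paste0("s", 1:6)))
  res0 <- protein_de_test(ab0, des)
  expect_equal(res0$f_stat, 0)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$log2_fc, 0)
  expect_false(res0$called)

  # fewer than two values per group is untestable, never called
  ab_na <- ab
  ab_na[1, 1:2] <- NA
  res_na <- protein_de_test(ab_na, des)
  expect_false(res_na$testable)
  expect_false(res_na$called)
  expect_true(is.na(res_na$p_value))
})

test_that("BH correction is applied within each time point", {
  set.seed(31)
  ab <- matrix(rnorm(8 * 12), 8,
               dimnames = list(paste0("P", 1:8), paste0("s", 1:12)))
  des <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    treatment = rep(rep(c("control_25C", "heat_40C"), each = 3), 2),
    time_h = rep(c(3, 6), each = 6))
  res <- protein_de_test(ab, des)
  for (t in c(3, 6)) {
    sel <- res$time_h == t
    expect_equal(res$p_adjusted[sel],
                 p.adjust(res$p_value[sel], method = "BH"))
  }
  resg <- protein_de_test(ab, des, global_correction = TRUE)
  expect_equal(resg$p_adjusted, p.adjust(res$p_value, method = "BH"))
})

test_that("full chain recovers planted protein shifts", {
  cfg <- sim_config(n_proteins = 200, de_fraction = 0.1,
                    effect_log_fc = log(2), noise_sd = 0.05,
                    missing_rate = 0.05, tissues = "RH", timepoints = 3,
                    peptides_per_protein = c(3, 3), seed = 42)
  sim <- gen_itraq_peptides(cfg)
  out <- suppressMessages(run_proteome(sim$spectra, sim$channel_design))
  m <- merge(out$results, sim$truth$protein_effects,
             by = c("protein_id", "time_h"))
  expect_gte(mean(abs(m$log2_fc - m$log2_shift) <= 0.1), 0.95)
  # null proteins stay near zero
  nulls <- out$results[!out$results$protein_id %in% m$protein_id, ]
  expect_lt(max(abs(nulls$log2_fc), na.rm = TRUE), 1)
})
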