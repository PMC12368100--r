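test_that("k-mer levels are deterministic, in range, and T/U-equivalent", {
  lm <- level_model(seed = 7)
  km <- c("ACGUACGUA", "ACGTACGTA", "GGGGGGGGG")
  lv <- kmer_level(lm, km)
  expect_identical(lv, kmer_level(lm, km))
  expect_true(all(lv >= 60 & lv <= 120))
  expect_equal(lv[1], lv[2])  # U reads as T
  expect_false(isTRUE(all.equal(lv, kmer_level(level_model(seed = 8), km))))
})

test_that("simulate_read is bit-identical under a fixed seed", {
  ref <- tiny_ref()
  eff <- effect_profiles("bio-default", ref_length = nchar(ref$sequence))
  tr <- list(isodecoder = "Gly-GCC", charged = TRUE, aa = "W")
  r1 <- simulate_read(ref, tr, level_model(), eff, seed = 99, signal = "samples")
  r2 <- simulate_read(ref, tr, level_model(), eff, seed = 99, signal = "samples")
  expect_identical(r1, r2)
  expect_error(
    simulate_read(ref, list(isodecoder = "x", charged = TRUE, aa = "Z"),
                  level_model(), eff, seed = 1),
    "unknown amino-acid")
})

test_that("sample counts and durations obey the conservation contract", {
  ref <- tiny_ref()
  reads <- sim_reads(ref, 10, signal = "samples", seed = 3)
  lm <- level_model()
  for (r in reads) {
    expect_equal(r$n_samples,
                 pmax(1L, as.integer(round(r$dwell * lm$sample_rate))))
    expect_equal(vapply(r$samples, length, 0L), r$n_samples)
    expect_equal(r$total_duration, sum(r$dwell))
  }
})

test_that("uncharged reads recover the baseline level at the anchor", {
  ref <- tiny_ref()
  lm <- level_model()
  reads <- sim_reads(ref, 150, charged = FALSE, signal = "samples", seed = 5)
  at_anchor <- unlist(lapply(reads, function(r) r$samples[[r$anchor + 1L]]))
  expected <- position_levels(lm, ref$sequence)[ref$anchor + 1L]
  se <- lm$noise_sd / sqrt(length(at_anchor))
  expect_lt(abs(mean(at_anchor) - expected), 3 * se)
})

test_that("Monte-Carlo recovery of the configured Trp current shift", {
  ref <- tiny_ref()
  eff <- effect_profiles("bio-default", ref_length = nchar(ref$sequence))
  rc <- sim_reads(ref, 300, charged = TRUE, aa = "W", signal = "samples",
                  seed = 6, effects = eff)
  ru <- sim_reads(ref, 300, charged = FALSE, signal = "samples",
                  seed = 7, effects = eff)
  anchor_mean <- function(reads) {
    s <- unlist(lapply(reads, function(r) r$samples[[r$anchor + 1L]]))
    c(mean(s), stats::var(s), length(s))
  }
  a <- anchor_mean(rc); b <- anchor_mean(ru)
  diff_se <- sqrt(a[2] / a[3] + b[2] / b[3])
  configured <- eff[["W"]]$current_shift[eff[["W"]]$shift_offsets == 0]
  expect_lt(abs((a[1] - b[1]) - configured), 3 * diff_se)
})

test_that("library sampling honors weights and charged fractions", {
  spec <- library_spec(isodecoders = synthetic_isodecoders()[c("G", "W")],
                       charged_fraction = 0.5, n_reads = 1000, seed = 21)
  lib <- simulate_library(spec, signal = "none")
  expect_equal(nrow(lib$truth), 1000)
  expect_lt(abs(mean(lib$truth$charged) - 0.5), 4 * sqrt(0.25 / 1000))

  spec0 <- library_spec(isodecoders = synthetic_isodecoders()["G"],
                        charged_fraction = 0, n_reads = 200, seed = 22)
  lib0 <- simulate_library(spec0, signal = "none")
  expect_false(any(lib0$truth$charged))
  expect_error(library_spec(isodecoders = list()), "no isodecoders")
  expect_error(library_spec(n_reads = 10, time_budget = 10), "exactly one")
})

test_that("time-budget sampling under-represents slow charged reads", {
  # budget ~ 2 mean read durations: two uncharged reads fit, two charged do
  # not, so the crossing read is disproportionately charged and discarded
  spec <- library_spec(time_budget = 2.2, n_channels = 400, n_reads = NULL,
                       charged_fraction = 0.5, seed = 23)
  lib <- simulate_library(spec, signal = "none")
  expect_lt(mean(lib$truth$charged), 0.48)
})

test_that("unblocking truncates a contiguous 3'-terminal block", {
  ref <- tiny_ref()
  read <- sim_reads(ref, 1, seed = 8)[[1]]
  expect_identical(apply_unblocking(read, prob = 0, seed = 1), read)
  for (i in 1:5) {
    tr <- apply_unblocking(read, prob = 1, seed = i)
    expect_true(tr$truncated)
    expect_gte(tr$covered_from, 1L)
    expect_lt(tr$covered_from, ref$n5)
    expect_true(all(is.na(tr$dwell[seq_len(tr$covered_from)])))
    expect_true(all(!is.na(tr$dwell[(tr$covered_from + 1L):tr$L])))
    expect_equal(tr$total_duration, sum(tr$dwell, na.rm = TRUE))
  }
})

test_that("basecall emulation honors its error model", {
  ref <- tiny_ref()
  read <- sim_reads(ref, 1, seed = 9, signal = "none")[[1]]
  expect_equal(emulate_basecalls(read, ref, error_rate = 0), ref$sequence)

  bc <- emulate_basecalls(read, ref, error_rate = 1, seed = 4,
                          type_probs = c(sub = 1, ins = 0, del = 0))
  orig <- strsplit(ref$sequence, "")[[1]]
  out <- strsplit(bc, "")[[1]]
  expect_equal(length(out), length(orig))
  expect_false(any(out == orig))
})

test_that("charged reads accrue more basecall errors near the anchor", {
  ref <- tiny_ref()
  eff <- effect_profiles("bio-default", ref_length = nchar(ref$sequence))
  rc <- sim_reads(ref, 60, charged = TRUE, aa = "K", seed = 11,
                  signal = "none", effects = eff)
  ru <- sim_reads(ref, 60, charged = FALSE, seed = 12,
                  signal = "none", effects = eff)
  mean_dist <- function(reads, seed0) {
    mean(vapply(seq_along(reads), function(i) {
      bc <- emulate_basecalls(reads[[i]], ref, error_rate = 0.05,
                              charged_error_boost = 5, window = 3,
                              seed = derive_seed(seed0, i))
      as.numeric(utils::adist(bc, ref$sequence))
    }, 0))
  }
  expect_gt(mean_dist(rc, 31), mean_dist(ru, 32))
})

test_that("bio-default preset recovers the 1.2x translocation-time ratio", {
  spec <- library_spec(charged_fraction = 0.5, n_reads = 2000, seed = 33)
  lib <- simulate_library(spec, signal = "none")
  db <- dwell_bias_diagnostic(lib$truth$duration, lib$truth$charged)
  expect_lt(abs(db$ratio - 1.2), 0.03)
})

test_that("monotone calibration of the default effect profiles", {
  aa <- aa_properties()
  ord_v <- order(aa$volume_A3, aa$hydrophobicity_ph7)
  ord_h <- order(aa$hydrophobicity_ph7, aa$volume_A3)
  for (preset in c("bio-default", "flexizyme-panel")) {
    eff <- effect_profiles(preset)
    shift0 <- vapply(aa$code, function(cd)
      eff[[cd]]$current_shift[eff[[cd]]$shift_offsets == 0], 0)
    mult9 <- vapply(aa$code, function(cd)
      eff[[cd]]$dwell_multiplier[eff[[cd]]$dwell_offsets == 9], 0)
    expect_true(all(diff(abs(shift0)[ord_v]) > 0))
    expect_true(all(diff(mult9[ord_h]) > 0))
    for (cd in aa$code) {
      expect_true(all(eff[[cd]]$current_shift <= 0))
      expect_true(all(eff[[cd]]$dwell_multiplier >= 1))
      s <- abs(eff[[cd]]$current_shift)
      expect_equal(which.max(s), which(eff[[cd]]$shift_offsets == 0))
    }
  }
  # flexizyme-panel: exactly the 9 most hydrophobic amino acids exceed a
  # 1 s expected dwell at +9 (multiplier / mean_speed > 1 s)
  eff <- effect_profiles("flexizyme-panel")
  mean_dwell9 <- vapply(aa$code, function(cd)
    eff[[cd]]$dwell_multiplier[eff[[cd]]$dwell_offsets == 9], 0) / 130
  expect_equal(sum(mean_dwell9 > 1), 9)
  top9 <- aa$code[order(-aa$hydrophobicity_ph7, -aa$volume_A3)][1:9]
  expect_setequal(names(mean_dwell9)[mean_dwell9 > 1], top9)
})

test_that("legacy 5' adapter elevates Asn/Cys unblocking only", {
  leg <- effect_profiles("bio-default", adapter_mode = "legacy_rna_5p")
  hyb <- effect_profiles("bio-default", adapter_mode = "hybrid_5p")
  expect_equal(leg[["N"]]$unblock_prob, 0.410)
  expect_equal(leg[["C"]]$unblock_prob, 0.276)
  expect_equal(leg[["G"]]$unblock_prob, 0.02)
  expect_true(all(vapply(aa_properties()$code,
                         function(cd) hyb[[cd]]$unblock_prob, 0) == 0.02))
})
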