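test_that("tabulation produces exact counts and exclusions", {
  calls <- data.frame(read_id = sprintf("r%02d", 1:10),
                      charged = rep(c(TRUE, FALSE), c(4, 6)))
  asn <- data.frame(read_id = calls$read_id, isodecoder = "Gly-GCC")
  tab <- tabulate_isodecoders(calls, asn)
  expect_equal(tab$frac_charged, 0.4)
  expect_equal(attr(tab, "excluded"), 0)

  asn2 <- data.frame(read_id = calls$read_id,
                     isodecoder = rep(c("A-x", "B-y"), c(3, 7)))
  tab2 <- tabulate_isodecoders(calls, asn2)
  expect_equal(tab2$abundance_frac[order(tab2$isodecoder)], c(0.3, 0.7))
  expect_equal(sum(tab2$abundance_frac), 1)
  expect_equal(sum(tab2$n_total) + attr(tab2, "excluded"), nrow(calls))

  asn3 <- data.frame(read_id = calls$read_id, isodecoder = "Gly-GCC",
                     excluded = TRUE)
  tab3 <- tabulate_isodecoders(calls, asn3)
  expect_equal(nrow(tab3), 0)
  expect_equal(attr(tab3, "excluded"), 10)

  expect_error(tabulate_isodecoders(calls, asn2[1:5, ]), "no isodecoder assignment")
})

test_that("two-proportion z agrees with the closed-form oracle", {
  eq <- two_proportion_ztest(5, 10, 50, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  zt <- two_proportion_ztest(30, 100, 10, 100)
  # oracle: p_hat = 0.2, z = 0.2 / sqrt(0.16 * 0.02)
  expect_equal(zt$z, 0.2 / sqrt(0.16 * 0.02), tolerance = 1e-12)
  expect_equal(zt$z, 3.5355, tolerance = 1e-4)
  expect_equal(zt$p, 4.07e-4, tolerance = 1e-2)

  sw <- two_proportion_ztest(10, 100, 30, 100)
  expect_equal(sw$z, -zt$z)
  expect_equal(sw$p, zt$p)

  expect_error(two_proportion_ztest(1, 0, 1, 10), "positive")
  expect_error(two_proportion_ztest(11, 10, 1, 10), "0 <= x <= n")
  expect_equal(two_proportion_ztest(0, 10, 0, 20)$z, 0)
  expect_equal(two_proportion_ztest(10, 10, 20, 20)$p, 1)

  set.seed(4)
  for (i in 1:50) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    res <- two_proportion_ztest(x1, n1, x2, n2)
    pp <- (x1 + x2) / (n1 + n2)
    if (pp %in% c(0, 1)) next
    z_or <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(res$z, z_or, tolerance = 1e-10)
    expect_equal(res$p, 2 * pnorm(-abs(z_or)), tolerance = 1e-10)
  }
})

test_that("BH adjustment agrees with an independent step-up implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  p <- c(0.04, NA, 0.01)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(p[c(1, 3)], "BH"))
})

test_that("differential analysis is null on identical tables and scale-consistent", {
  tab <- function(n, x, s = "s") {
    tabulate_isodecoders(
      data.frame(read_id = sprintf("%s%04d", s, 1:n),
                 charged = rep(c(TRUE, FALSE), c(x, n - x))),
      data.frame(read_id = sprintf("%s%04d", s, 1:n),
                 isodecoder = rep(c("Gly-GCC", "Trp-CCA"), length.out = n)),
      sample = s)
  }
  a <- tab(400, 100, "a")
  d0 <- differential(a, a)
  expect_true(all(d0$log2fc_charging == 0))
  expect_true(all(d0$log2fc_abundance == 0))
  expect_true(all(d0$q_charging == 1))

  b <- tab(400, 200, "b")
  d1 <- differential(a, b)
  a2 <- tab(800, 200, "c"); b2 <- tab(800, 400, "d")
  d2 <- differential(a2, b2)
  expect_equal(d2$log2fc_charging, d1$log2fc_charging)
  expect_true(all(d2$p_charging < d1$p_charging))

  # missing isodecoder flagged and excluded from testing
  b3 <- b
  b3 <- b3[b3$isodecoder != "Trp-CCA", ]
  d3 <- differential(a, b3)
  expect_true(d3$missing[d3$isodecoder == "Trp-CCA"])
  expect_true(is.na(d3$p_charging[d3$isodecoder == "Trp-CCA"]))
})

test_that("a synthetic starvation scenario recovers exactly the perturbed isodecoders", {
  iso <- synthetic_isodecoders()
  panel <- iso[c("G", "W", "D", "K", "V", "M", "S", "T")]
  # four leucyl isodecoders with distinct anticodon labels
  leu <- lapply(c("CAA", "AAG", "UAA", "GAG"), function(ac) {
    trna_isodecoder(paste0("Leu-", ac), iso[["L"]]$body)
  })
  names(leu) <- paste0("L", 1:4)
  isodec <- c(panel, leu)
  cf_ctrl <- c(rep(0.7, 8), rep(0.8, 4))
  cf_starv <- c(rep(0.7, 8), rep(0.2, 4))
  run <- function(cf, seed, cond) {
    spec <- library_spec(isodecoders = isodec, charged_fraction = cf,
                         n_reads = 20000, seed = seed, condition = cond)
    lib <- simulate_library(spec, signal = "none", unblocking = FALSE)
    tabulate_isodecoders(
      data.frame(read_id = lib$truth$read_id, charged = lib$truth$charged),
      data.frame(read_id = lib$truth$read_id,
                 isodecoder = lib$truth$isodecoder),
      sample = cond)
  }
  d <- differential(run(cf_ctrl, 71, "ctrl"), run(cf_starv, 72, "starved"))
  hits <- d$isodecoder[!is.na(d$q_charging) & d$q_charging < 0.05 &
                         d$log2fc_charging < 0]
  expect_setequal(hits, c("Leu-CAA", "Leu-AAG", "Leu-UAA", "Leu-GAG"))
  null_q <- d$q_charging[!grepl("^Leu", d$isodecoder)]
  expect_true(all(null_q >= 0.05, na.rm = TRUE))
})

test_that("charging concordance reports identity-line residuals", {
  seq_tab <- data.frame(isodecoder = c("a", "b", "c", "d"),
                        frac_charged = c(0.2, 0.4, 0.6, 0.8))
  ext_same <- seq_tab
  cc <- charging_concordance(seq_tab, ext_same)
  expect_equal(cc$r, 1)
  expect_equal(unname(cc$residuals), rep(0, 4))

  ext_off <- transform(seq_tab, frac_charged = frac_charged + 0.1)
  cc2 <- charging_concordance(seq_tab, ext_off)
  expect_equal(cc2$r, 1)
  expect_equal(cc2$mean_residual, -0.1)
  expect_error(charging_concordance(seq_tab[1:2, ], ext_same), "at least 3")
})
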