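# Per-isodecoder aggregation and differential charging / abundance
# statistics: pooled two-proportion Z-tests with Benjamini-Hochberg
# correction, as used for volcano-style analyses of condition pairs.

#' Tabulate per-isodecoder charging and abundance
#'
#' Aggregates per-read charging calls into per-isodecoder counts. Reads
#' flagged as not covering the anchor (`excluded`) are removed from the
#' table and counted separately (attribute `excluded`).
#'
#' @param calls `data.frame` with `read_id` and logical `charged`.
#' @param assignments `data.frame` with `read_id`, `isodecoder` and
#'   optionally logical `excluded`. Every call must have an assignment.
#' @param sample Sample label.
#' @return `data.frame` of class `isodecoder_table` with columns `sample`,
#'   `isodecoder`, `n_total`, `n_charged`, `frac_charged`, `abundance_frac`;
#'   attribute `excluded` holds the excluded-read count.
#' @export
tabulate_isodecoders <- function(calls, assignments, sample = "sample") {
  m <- match(calls$read_id, assignments$read_id)
  if (anyNA(m)) {
    stopf("%d read(s) have no isodecoder assignment", sum(is.na(m)))
  }
  iso <- assignments$isodecoder[m]
  if (anyNA(iso) || any(iso == "")) stopf("unknown isodecoder label")
  excl <- if ("excluded" %in% names(assignments)) {
    isTRUE_v <- assignments$excluded[m]
    !is.na(isTRUE_v) & isTRUE_v
  } else rep(FALSE, nrow(calls))
  keep <- !excl
  iso_k <- iso[keep]
  ch_k <- calls$charged[keep]
  if (length(iso_k) == 0) {
    out <- data.frame(sample = character(0), isodecoder = character(0),
                      n_total = integer(0), n_charged = integer(0),
                      frac_charged = numeric(0), abundance_frac = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    lev <- sort(unique(iso_k))
    n_total <- as.integer(table(factor(iso_k, levels = lev)))
    n_charged <- as.integer(tapply(ch_k, factor(iso_k, levels = lev), sum))
    out <- data.frame(sample = sample, isodecoder = lev,
                      n_total = n_total, n_charged = n_charged,
                      frac_charged = n_charged / n_total,
                      abundance_frac = n_total / sum(n_total),
                      stringsAsFactors = FALSE)
  }
  attr(out, "excluded") <- sum(excl)
  class(out) <- c("isodecoder_table", "data.frame")
  out
}

#' Pooled two-proportion Z-test
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2) / (n1 + n2)`; two-sided p-value `2 * pnorm(-|z|)`. When
#' both proportions are jointly 0 or jointly 1 the statistic is defined as
#' z = 0 (p = 1).
#'
#' @param x1,n1 Successes and trials in sample 1.
#' @param x2,n2 Successes and trials in sample 2.
#' @return List with `z`, `p`, `p1`, `p2`, `p_pooled`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stopf("both sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stopf("counts must satisfy 0 <= x <= n")
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    return(list(z = 0, p = 1, p1 = p1, p2 = p2, p_pooled = pp))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2, p_pooled = pp)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment `q(i) = min_{k >= i} p(k) * m / k` on the
#' sorted p-values, returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0,1\] (NA passed through).
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0,1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  }
  q
}

pool_tables <- function(tables) {
  if (inherits(tables, "isodecoder_table")) tables <- list(tables)
  all_iso <- sort(unique(unlist(lapply(tables, `[[`, "isodecoder"))))
  per_rep <- lapply(tables, function(tb) {
    m <- match(all_iso, tb$isodecoder)
    data.frame(isodecoder = all_iso,
               n_total = ifelse(is.na(m), 0L, tb$n_total[m]),
               n_charged = ifelse(is.na(m), 0L, tb$n_charged[m]),
               frac_charged = tb$frac_charged[m],
               abundance_frac = ifelse(is.na(m), 0, tb$abundance_frac[m]))
  })
  list(iso = all_iso,
       n_total = Reduce(`+`, lapply(per_rep, `[[`, "n_total")),
       n_charged = Reduce(`+`, lapply(per_rep, `[[`, "n_charged")),
       grand_total = sum(vapply(tables, function(tb) sum(tb$n_total), 0)),
       per_rep = per_rep)
}

#' Differential charging and abundance between two conditions
#'
#' Per isodecoder: log2 fold changes of abundance fraction and charged
#' fraction (condition B over A), pooled two-proportion Z-tests (charging:
#' charged vs total; abundance: isodecoder reads vs the rest of the
#' sample), and Benjamini-Hochberg q-values computed separately within the
#' abundance and charging families. Replicates are pooled for the test
#' statistics; per-replicate log2 fold changes are summarized as mean and
#' SD. A pseudocount (default 0.5) is added to zero cells for fold changes
#' only, never for tests. Isodecoders absent from one condition are flagged
#' `missing` and excluded from testing.
#'
#' @param tables_a,tables_b An `isodecoder_table` or list of replicate
#'   tables per condition.
#' @param pseudocount Added to zero counts for fold-change computation.
#' @return `data.frame` of class `differential_result`.
#' @export
differential <- function(tables_a, tables_b, pseudocount = 0.5) {
  a <- pool_tables(tables_a)
  b <- pool_tables(tables_b)
  iso <- sort(union(a$iso, b$iso))
  ia <- match(iso, a$iso); ib <- match(iso, b$iso)
  nA <- ifelse(is.na(ia), 0L, a$n_total[ia])
  nB <- ifelse(is.na(ib), 0L, b$n_total[ib])
  xA <- ifelse(is.na(ia), 0L, a$n_charged[ia])
  xB <- ifelse(is.na(ib), 0L, b$n_charged[ib])
  missing <- nA == 0L | nB == 0L
  pc <- function(x) ifelse(x == 0, pseudocount, x)

  ab_A <- pc(nA) / a$grand_total
  ab_B <- pc(nB) / b$grand_total
  log2fc_ab <- log2(ab_B / ab_A)
  fc_A <- pc(xA) / pmax(nA, 1)
  fc_B <- pc(xB) / pmax(nB, 1)
  log2fc_ch <- log2(fc_B / fc_A)

  z_ab <- p_ab <- z_ch <- p_ch <- rep(NA_real_, length(iso))
  for (i in seq_along(iso)) {
    if (missing[i]) next
    tab <- two_proportion_ztest(nA[i], a$grand_total, nB[i], b$grand_total)
    z_ab[i] <- tab$z; p_ab[i] <- tab$p
    tch <- two_proportion_ztest(xB[i], nB[i], xA[i], nA[i])
    z_ch[i] <- tch$z; p_ch[i] <- tch$p
  }
  rep_l2 <- function(per_rep, field) {
    vals <- vapply(per_rep, function(d) {
      d[[field]][match(iso, d$isodecoder)]
    }, numeric(length(iso)))
    matrix(vals, nrow = length(iso))
  }
  l2_ch_reps_A <- rep_l2(a$per_rep, "frac_charged")
  l2_ch_reps_B <- rep_l2(b$per_rep, "frac_charged")
  # per-replicate-pair fold changes (all A-rep x B-rep combinations)
  l2_mat <- function(mA, mB) {
    out_mean <- out_sd <- rep(NA_real_, length(iso))
    for (i in seq_along(iso)) {
      va <- mA[i, ]; vb <- mB[i, ]
      va <- va[!is.na(va) & va > 0]; vb <- vb[!is.na(vb) & vb > 0]
      if (length(va) && length(vb)) {
        l2 <- as.vector(outer(vb, va, function(x, y) log2(x / y)))
        out_mean[i] <- mean(l2)
        out_sd[i] <- if (length(l2) > 1) stats::sd(l2) else NA_real_
      }
    }
    list(mean = out_mean, sd = out_sd)
  }
  ch_reps <- l2_mat(l2_ch_reps_A, l2_ch_reps_B)

  out <- data.frame(
    isodecoder = iso,
    n_total_a = nA, n_total_b = nB,
    n_charged_a = xA, n_charged_b = xB,
    frac_charged_a = ifelse(nA > 0, xA / nA, NA_real_),
    frac_charged_b = ifelse(nB > 0, xB / nB, NA_real_),
    log2fc_abundance = ifelse(missing & (nA == 0 & nB == 0), NA_real_, log2fc_ab),
    log2fc_charging = ifelse(missing, NA_real_, log2fc_ch),
    log2fc_charging_rep_mean = ch_reps$mean,
    log2fc_charging_rep_sd = ch_reps$sd,
    z_abundance = z_ab, p_abundance = p_ab,
    z_charging = z_ch, p_charging = p_ch,
    missing = missing,
    stringsAsFactors = FALSE)
  out$q_abundance <- bh_adjust(out$p_abundance)
  out$q_charging <- bh_adjust(out$p_charging)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Concordance between sequencing-based and external charging estimates
#'
#' Pearson correlation of paired percent-charging values plus residuals
#' from the identity line (sequencing minus external), which expose any
#' systematic under- or over-estimation.
#'
#' @param seq_table `isodecoder_table` (or data.frame with `isodecoder`,
#'   `frac_charged`).
#' @param external `data.frame` with `isodecoder` and `frac_charged` from
#'   the orthogonal assay.
#' @return List with `r`, `p`, `n`, `residuals` (named), `mean_residual`
#'   and the paired `data`.
#' @export
charging_concordance <- function(seq_table, external) {
  iso <- intersect(seq_table$isodecoder, external$isodecoder)
  if (length(iso) < 3) stopf("at least 3 shared isodecoders are required")
  x <- seq_table$frac_charged[match(iso, seq_table$isodecoder)]
  y <- external$frac_charged[match(iso, external$isodecoder)]
  res <- x - y
  ct <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    list(r = NA_real_, p = NA_real_)
  } else {
    pc <- property_correlation(x, y)
    list(r = pc$r, p = pc$p)
  }
  list(r = ct$r, p = ct$p, n = length(iso),
       residuals = stats::setNames(res, iso),
       mean_residual = mean(res),
       data = data.frame(isodecoder = iso, seq = x, external = y))
}
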