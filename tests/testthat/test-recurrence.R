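# Random cohort matrix builder used across these tests.
random_cohort <- function(n_samples = 50, n_loci = 200, seed = 1,
                          p_event = 0.05) {
  set.seed(seed)
  loci <- data.table::data.table(
    locus_id = sprintf("c1:%d-%d:A", seq_len(n_loci) * 50,
                       seq_len(n_loci) * 50 + 10),
    region = sample(c("coding", "utr5", "utr3", "intronic", "intergenic"),
                    n_loci, replace = TRUE),
    gene = sprintf("G%03d", seq_len(n_loci)))
  meta <- data.table::data.table(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    tumour_type = sample(c("COAD", "STAD", "UCEC"), n_samples, replace = TRUE),
    msi_label = sample(c("MSI-H", "MSI-L", "MSS"), n_samples, replace = TRUE,
                       prob = c(0.3, 0.2, 0.5)))
  ev <- matrix(rbinom(n_samples * n_loci, 1, p_event), n_samples, n_loci,
               dimnames = list(meta$sample_id, loci$locus_id))
  fs <- ev * matrix(rbinom(n_samples * n_loci, 1, 0.5), n_samples, n_loci)
  structure(list(samples = meta, loci = loci, events = ev,
                 frameshift_events = fs), class = "cohort_calls")
}

test_that("recurrence_rank counts, fractions and order match a recount", {
  cm <- random_cohort(50, 200, seed = 3)
  rk <- recurrence_rank(cm, group_by = "tumour_type")
  # brute-force recount
  for (g in unique(cm$samples$tumour_type)) {
    sel <- cm$samples$tumour_type == g
    want <- colSums(cm$events[sel, , drop = FALSE])
    got <- rk[[paste0("n_", g)]][match(colnames(cm$events), rk$locus_id)]
    expect_equal(got, unname(as.integer(want)))
    expect_equal(rk[[paste0("frac_", g)]][match(colnames(cm$events),
                                                rk$locus_id)],
                 unname(want) / sum(sel))
  }
  expect_true(all(diff(rk$total) <= 0))
  ties <- rk[, .N, by = total][N > 1, total]
  for (t in ties) {
    expect_equal(rk[total == t, locus_id], sort(rk[total == t, locus_id]))
  }
  expect_true(all(rk$total == rowSums(rk[, .(total)])))  # fractions in [0,1]
  frac_cols <- grep("^frac_", names(rk), value = TRUE)
  for (fc in frac_cols) expect_true(all(rk[[fc]] >= 0 & rk[[fc]] <= 1))
})

test_that("an all-zero matrix ranks stably by locus id", {
  cm <- random_cohort(10, 30, seed = 4, p_event = 0)
  rk <- recurrence_rank(cm)
  expect_true(all(rk$total == 0))
  expect_equal(rk$locus_id, sort(cm$loci$locus_id))
})

test_that("type_enrichment reproduces the hypergeometric tail on the
           COAD-vs-rest frameshift split", {
  # 26/45 events in the focal type vs 4/75 elsewhere
  cm <- random_cohort(120, 5, seed = 5, p_event = 0)
  cm$samples$tumour_type <- rep(c("COAD", "UCEC"), c(45, 75))
  lid <- cm$loci$locus_id[1]
  cm$events[1:26, 1] <- 1L          # 26 of the 45 COAD
  cm$events[46:49, 1] <- 1L         # 4 of the 75 UCEC
  r <- type_enrichment(cm, lid, "COAD")
  expect_equal(r$a, 26); expect_equal(r$b, 19)
  expect_equal(r$c, 4); expect_equal(r$d, 71)
  expect_equal(r$p, oracle_fisher_greater(26, 19, 4, 71), tolerance = 1e-10)
  expect_lt(r$p, 0.05)
  # equal event rates in both groups (20% each): no enrichment signal
  cm$events[, 2] <- 0L
  cm$events[c(1:9, 46:60), 2] <- 1L
  r2 <- type_enrichment(cm, cm$loci$locus_id[2], "COAD")
  expect_gte(r2$p, 0.5)
  # zero events anywhere
  r3 <- type_enrichment(cm, cm$loci$locus_id[3], "COAD")
  expect_equal(r3$p, 1)
  expect_error(type_enrichment(cm, "nope", "COAD"), "not in catalogue")
  expect_error(type_enrichment(cm, lid, "BRCA"), "unknown tumour type")
})

test_that("small focal groups warn in type_enrichment", {
  cm <- random_cohort(30, 3, seed = 6)
  cm$samples$tumour_type <- c(rep("COAD", 27), rep("RARE", 3))
  expect_warning(type_enrichment(cm, cm$loci$locus_id[1], "RARE"),
                 "fewer than 5")
})

test_that("msih_specificity_rank puts planted loci first", {
  set.seed(8)
  cm <- random_cohort(100, 50, seed = 8, p_event = 0.02)
  cm$samples$msi_label <- rep(c("MSI-H", "MSS"), c(30, 70))
  planted <- cm$loci$locus_id[7]
  cm$events[, 7] <- 0L
  cm$events[1:27, 7] <- 1L                       # 90% of MSI-H
  cm$events[31, 7] <- 1L                         # 1 of 70 MSS
  rk <- msih_specificity_rank(cm)
  expect_equal(rk$locus_id[1], planted)
  expect_equal(rk$p[1], oracle_fisher_greater(27, 3, 1, 69), tolerance = 1e-10)
  # a flat locus ranks below the planted one with p >= 0.5
  flat <- cm$loci$locus_id[9]
  cm$events[, 9] <- 0L
  cm$events[c(1:3, 31:37), 9] <- 1L              # 10% both classes
  rk2 <- msih_specificity_rank(cm)
  expect_gte(rk2[locus_id == flat, p], 0.5)
  expect_gt(which(rk2$locus_id == flat), which(rk2$locus_id == planted))
  # invariant to sample order permutation
  perm <- sample(nrow(cm$samples))
  cmp <- cm
  cmp$samples <- cmp$samples[perm]
  cmp$events <- cmp$events[perm, ]
  cmp$frameshift_events <- cmp$frameshift_events[perm, ]
  rk3 <- msih_specificity_rank(cmp)
  expect_equal(rk3$locus_id, rk2$locus_id)
  expect_equal(rk3$p, rk2$p)
  # single-class cohorts are rejected
  cm1 <- cm; cm1$samples$msi_label <- "MSI-H"
  expect_error(msih_specificity_rank(cm1), "MSI-H and non-MSI-H")
})

test_that("region_bias_test flags planted composition skews", {
  comp <- c(coding = 500L, utr5 = 100L, utr3 = 120L, intronic = 280L)
  # calls proportional to composition: neutral everywhere
  calls <- data.table::data.table(
    locus_id = sprintf("L%03d", 1:100),
    region = rep(c("coding", "utr5", "utr3", "intronic"), c(50, 10, 12, 28)),
    significant = TRUE)
  rb <- region_bias_test(calls, comp)
  expect_true(all(rb$verdict == "neutral"))
  # 100 of 120 calls in utr3 when utr3 is ~12% of the catalogue
  calls2 <- data.table::data.table(
    locus_id = sprintf("L%03d", 1:120),
    region = rep(c("utr3", "coding"), c(100, 20)),
    significant = TRUE)
  rb2 <- region_bias_test(calls2, comp)
  expect_equal(rb2[region == "utr3", verdict], "enriched")
  expect_equal(rb2[region == "utr3", p_enrich],
               oracle_fisher_greater(100, 20, 20, 860), tolerance = 1e-10)
  expect_lt(rb2[region == "utr3", p_enrich], 0.05)
  expect_equal(rb2[region == "coding", verdict], "depleted")
  # zero calls: warning, all neutral
  calls0 <- calls[significant == FALSE]
  expect_warning(rb0 <- region_bias_test(calls0, comp), "no significant")
  expect_true(all(rb0$verdict == "neutral"))
})

test_that("chromatin_enrichment recovers a planted state and rejects bad input", {
  set.seed(12)
  n_loci <- 300
  catalogue <- data.table::data.table(
    chrom = "c1", start = seq_len(n_loci) * 100L,
    end = seq_len(n_loci) * 100L + 20L,
    locus_id = sprintf("c1:%d-%d:A", seq_len(n_loci) * 100L,
                       seq_len(n_loci) * 100L + 20L),
    unit = "A", unit_len = 1L, length = 20L,
    region = "intergenic", gene = NA_character_)
  # states tile the contig in 3 kb blocks cycling over three labels
  blocks <- seq(0L, max(catalogue$end), by = 3000L)
  state_map <- data.table::data.table(
    chrom = "c1", start = blocks, end = blocks + 3000L,
    state = rep(c("Tss", "Quies", "Enh"), length.out = length(blocks)))
  in_tss <- msisweep:::assign_state(catalogue, state_map) == "Tss"
  calls <- data.table::data.table(locus_id = catalogue$locus_id,
                                  significant = in_tss)
  res <- chromatin_enrichment(calls, catalogue, state_map)
  expect_equal(res[state == "Tss", verdict], "enriched")
  expect_true(all(res[state != "Tss", verdict] %in% c("depleted", "neutral")))
  # agreement with the two-tailed oracle
  for (i in seq_len(nrow(res))) {
    a <- res$n_called[i]; b <- sum(calls$significant) - a
    c_ <- res$n_background[i]; d <- n_loci - c_
    expect_equal(res$p[i], oracle_fisher_two(a, b, c_, d), tolerance = 1e-10)
  }
  expect_error(chromatin_enrichment(calls, catalogue, state_map[0]),
               "empty chromatin state map")
  m2 <- data.table::copy(state_map)
  data.table::setattr(m2, "assembly", "hg38")
  expect_error(chromatin_enrichment(calls, catalogue, m2, assembly = "hg19"),
               "assembly mismatch")
})

test_that("uniform calls leave chromatin states unflagged at the alpha rate", {
  set.seed(33)
  n_loci <- 400
  catalogue <- data.table::data.table(
    chrom = "c1", start = seq_len(n_loci) * 100L,
    end = seq_len(n_loci) * 100L + 20L,
    locus_id = sprintf("L%04d", seq_len(n_loci)),
    unit = "A", unit_len = 1L, length = 20L,
    region = "intergenic", gene = NA_character_)
  blocks <- seq(0L, max(catalogue$end), by = 2000L)
  state_map <- data.table::data.table(
    chrom = "c1", start = blocks, end = blocks + 2000L,
    state = rep(sprintf("S%d", 1:5), length.out = length(blocks)))
  flagged <- 0L; total <- 0L
  for (r in 1:20) {
    calls <- data.table::data.table(
      locus_id = sample(catalogue$locus_id, 60),
      significant = TRUE)
    res <- chromatin_enrichment(calls, catalogue, state_map)
    flagged <- flagged + sum(res$verdict != "neutral")
    total <- total + nrow(res)
  }
  # null behaviour: flags at most around the alpha false-positive rate
  expect_lt(flagged / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("label permutation destroys planted MSI-H specificity", {
  set.seed(21)
  cm <- random_cohort(80, 150, seed = 21, p_event = 0.05)
  cm$samples$msi_label <- rep(c("MSI-H", "MSS"), c(25, 55))
  # permuting labels: fraction of p < 0.05 stays near the nominal rate
  perm <- sample(nrow(cm$samples))
  cm$samples$msi_label <- cm$samples$msi_label[perm]
  rk <- msih_specificity_rank(cm)
  frac <- mean(rk$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(rk))
  expect_lt(frac, 0.05 + 2 * se)
})

test_that("build_cohort_matrix ties events to frameshift events and metadata", {
  ref <- simulate_reference(n_loci = 80, seed = 61)
  model <- slippage_model()
  set.seed(9)
  calls_list <- list()
  for (s in c("SA", "SB")) {
    unstable <- sample(ref$catalogue$locus_id, 10)
    sh <- -ref$catalogue$unit_len[match(unstable, ref$catalogue$locus_id)]
    tl <- msisweep::simulate_pair_tallies(ref$catalogue, unstable, sh, model)
    calls_list[[s]] <- call_sample(tl[role == "tumor",
                                      .(locus_id, length, count)],
                                   tl[role == "normal",
                                      .(locus_id, length, count)],
                                   ref$catalogue)
  }
  meta <- data.table::data.table(sample_id = c("SA", "SB"),
                                 tumour_type = "COAD",
                                 msi_label = c("MSI-H", "MSS"))
  cm <- build_cohort_matrix(calls_list, meta, ref$catalogue)
  expect_true(all(cm$frameshift_events <= cm$events))
  expect_equal(dim(cm$events), c(2L, 80L))
  expect_equal(sum(cm$events["SA", ]),
               sum(calls_list$SA$significant))
  expect_error(build_cohort_matrix(calls_list,
                                   meta[sample_id == "SA"], ref$catalogue),
               "absent from metadata")
})
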