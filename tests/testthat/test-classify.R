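test_that("encode_features builds gene indicators plus a total count", {
  loci <- data.table::data.table(
    locus_id = c("L1", "L2", "L3", "L4"),
    region = c("coding", "coding", "utr3", "intergenic"),
    gene = c("GA", "GB", "GB", NA))
  meta <- data.table::data.table(sample_id = c("S1", "S2"),
                                 tumour_type = "COAD",
                                 msi_label = c("MSI-H", "MSS"))
  ev <- matrix(c(1L, 0L, 0L, 1L,
                 0L, 0L, 0L, 0L), 2, 4, byrow = TRUE,
               dimnames = list(meta$sample_id, loci$locus_id))
  cm <- structure(list(samples = meta, loci = loci, events = ev,
                       frameshift_events = ev * 0L),
                  class = "cohort_calls")
  x <- encode_features(cm)
  # GB never hit (L2, L3 eventless): no column; geneless L4 counts in total
  expect_equal(colnames(x), c("GA", "TOTAL_MSI"))
  expect_equal(x["S1", ], c(GA = 1, TOTAL_MSI = 2))
  expect_equal(x["S2", ], c(GA = 0, TOTAL_MSI = 0))
})

test_that("encoding a simulated cohort round-trips against its truth", {
  spec <- cohort_spec(n_samples = 16, n_loci = 120,
                      unstable_loci_per_msih = 30, seed = 9)
  coh <- simulate_cohort(spec, output = "calls")
  cm <- build_cohort_matrix(coh$calls, coh$metadata, coh$catalogue)
  x <- encode_features(cm)
  expect_equal(unname(x[, "TOTAL_MSI"]), unname(rowSums(cm$events)))
  # every gene feature corresponds to >= 1 called event in that gene
  for (g in setdiff(colnames(x), "TOTAL_MSI")) {
    lids <- cm$loci$locus_id[cm$loci$gene %in% g]
    expect_equal(unname(x[, g]),
                 unname(as.numeric(rowSums(
                   cm$events[, lids, drop = FALSE]) > 0)))
  }
})

test_that("nzv_filter drops constant and extreme-ratio features", {
  set.seed(1)
  x <- cbind(const = rep(1, 400),
             rare = c(1, rep(0, 399)),            # ratio 399 > 19
             balanced = rep(c(0, 1), 200),
             total = rnorm(400))
  out <- nzv_filter(x)
  expect_equal(sort(out$removed), c("const", "rare"))
  expect_equal(sort(out$kept), c("balanced", "total"))
  # agreement with the caret reference implementation
  if (requireNamespace("caret", quietly = TRUE)) {
    ref <- caret::nearZeroVar(as.data.frame(x))
    expect_equal(sort(colnames(x)[ref]), sort(out$removed))
  }
  expect_error(nzv_filter(x[, "const", drop = FALSE]), "all features")
})

test_that("standardize centres, scales and honours a stored record", {
  x <- cbind(a = c(0, 0, 1, 1), b = c(1, 2, 3, 4))
  z <- standardize(x)
  expect_equal(unname(colMeans(z$x)), c(0, 0))
  expect_equal(unname(apply(z$x, 2, sd)), c(1, 1))
  expect_equal(unname(z$x[, "a"]),
               (c(0, 0, 1, 1) - 0.5) / sd(c(0, 0, 1, 1)), tolerance = 1e-12)
  # re-applying the stored record reproduces the transform exactly
  z2 <- standardize(x, center = z$center, scale = z$scale)
  expect_identical(z$x, z2$x)
  # a held-out sample uses the training parameters, not its own
  held <- cbind(a = c(10, 20), b = c(100, 200))
  zh <- standardize(held, center = z$center, scale = z$scale)
  expect_equal(unname(zh$x[, "a"]), (c(10, 20) - 0.5) / sd(c(0, 0, 1, 1)))
  expect_error(standardize(cbind(a = rep(1, 4))), "zero-variance")
})

test_that("fit_forest is deterministic and separates a clean cohort", {
  toy <- toy_cohort_features(n = 80, seed = 2)
  z <- standardize(nzv_filter(toy$x)$x)$x
  f1 <- fit_forest(z, toy$labels, mtry = 8, seed = 5)
  f2 <- fit_forest(z, toy$labels, mtry = 8, seed = 5)
  v1 <- msisweep:::forest_votes(f1$model, z)
  expect_identical(v1, msisweep:::forest_votes(f2$model, z))
  # training votes strongly favour the true class on separable data
  truth <- factor(toy$labels, levels = c("MSI-H", "MSS"))
  own <- v1[cbind(seq_len(nrow(v1)), as.integer(truth))]
  expect_gt(mean(own >= 0.9), 0.95)
  expect_error(fit_forest(z, rep("MSS", nrow(z)), mtry = 2, seed = 1),
               "single class")
})

test_that("mtry tuning scans the grid and label permutation is at chance", {
  toy <- toy_cohort_features(n = 60, n_genes = 40, seed = 3)
  z <- standardize(nzv_filter(toy$x)$x)$x
  f <- fit_forest(z, toy$labels, seed = 4, cv_folds = 5)
  expect_false(is.null(f$tuning))
  expect_true(f$mtry %in% f$tuning$mtry)
  expect_gt(max(f$tuning$balanced_accuracy), 0.9)
  # permuted labels: balanced accuracy within noise of 0.5
  set.seed(6)
  perm <- sample(toy$labels)
  fp <- fit_forest(z, perm, seed = 4, cv_folds = 5)
  n_h <- sum(perm == "MSI-H")
  se <- sqrt(0.25 / n_h + 0.25 / (length(perm) - n_h)) / 2
  expect_lt(abs(max(fp$tuning$balanced_accuracy) - 0.5), 3 * se + 0.15)
})

test_that("calibrate_mondrian sorts label-conditional vote lists", {
  votes <- rbind(c(0.2, 0.8), c(0.9, 0.1), c(0.6, 0.4), c(0.3, 0.7))
  colnames(votes) <- c("MSI-H", "MSS")
  labels <- c("MSI-H", "MSI-H", "MSI-H", "MSS")
  cal <- calibrate_mondrian(votes, labels)
  expect_equal(cal$lists[["MSI-H"]], c(0.2, 0.6, 0.9))
  expect_equal(cal$lists[["MSS"]], 0.7)      # singleton class still works
  expect_error(calibrate_mondrian(rbind(votes, c(NA, 0.5)),
                                  c(labels, "MSS")),
               "missing out-of-fold vote")
  # prediction is defined with a singleton list
  p <- conformal_predict(rbind(c(0.5, 0.5)), cal, epsilon = 0.1)
  expect_true(p$p_MSS %in% c(1 / 2, 2 / 2))
})

test_that("conformal p-values follow the counting definitions", {
  cal <- calibrate_mondrian(
    rbind(c(0.1, 0.9), c(0.3, 0.7), c(0.5, 0.5), c(0.7, 0.3), c(0.9, 0.1),
          c(0.2, 0.8), c(0.4, 0.6)),
    c(rep("MSI-H", 5), rep("MSS", 2)))
  L <- cal$lists[["MSI-H"]]
  expect_equal(L, c(0.1, 0.3, 0.5, 0.7, 0.9))
  # v above every calibration score: maximally conforming
  p_top <- conformal_predict(rbind(c(0.95, 0.05)), cal, epsilon = 0.1)
  expect_equal(p_top$p_MSIH, 1)
  # v at the median of an odd-length list: (k + 1)/(n + 1) by counting
  p_med <- conformal_predict(rbind(c(0.5, 0.5)), cal, epsilon = 0.1)
  expect_equal(p_med$p_MSIH, oracle_conformal_p(L, 0.5))
  expect_equal(p_med$p_MSIH, (3 + 1) / (5 + 1))
  # epsilon = 0 includes both classes always
  p0 <- conformal_predict(rbind(c(0.01, 0.99)), cal, epsilon = 0)
  expect_equal(p0$verdict, "both")
  # literal convention counts calibration votes above the test vote
  pl <- conformal_predict(rbind(c(0.5, 0.5)), cal, epsilon = 0.1,
                          convention = "literal")
  expect_equal(pl$p_MSIH, sum(L > 0.5) / length(L))
  expect_error(conformal_predict(rbind(c(0.5, 0.5)), cal, epsilon = 1),
               "epsilon")
})

test_that("prediction sets shrink monotonically in epsilon", {
  set.seed(10)
  cal <- calibrate_mondrian(
    cbind(`MSI-H` = runif(40), MSS = runif(40)),
    rep(c("MSI-H", "MSS"), each = 20))
  votes <- cbind(`MSI-H` = runif(25), MSS = runif(25))
  eps_grid <- c(0, 0.05, 0.1, 0.25, 0.5, 0.9)
  sets <- lapply(eps_grid, function(e) {
    p <- conformal_predict(votes, cal, epsilon = e)
    cbind(p$in_set_MSIH, p$in_set_MSS)
  })
  for (i in seq_along(eps_grid)[-1]) {
    expect_true(all(sets[[i]] <= sets[[i - 1]]))
  }
  # both/none verdicts never decrease as confidence rises
  unsure <- vapply(seq_along(eps_grid), function(i) {
    sum(rowSums(sets[[i]]) != 1L & rowSums(sets[[i]]) == 2L)
  }, integer(1))
  expect_true(all(diff(unsure) <= 0))  # "both" shrinks as epsilon grows
})

test_that("train/predict pipeline keeps preprocessing leak-free", {
  toy <- toy_cohort_features(n = 100, seed = 12)
  m <- train_msi_model(toy$x, toy$labels, seed = 3, cv_folds = 5)
  # training transform is reproduced bit-for-bit from the stored record
  z1 <- standardize(toy$x[, m$preprocess$kept],
                    center = m$preprocess$center,
                    scale = m$preprocess$scale)$x
  z2 <- standardize(toy$x[, m$preprocess$kept])$x
  expect_identical(z1, z2)
  # a deliberately shifted held-out sample is scaled by training parameters
  held <- toy$x[1:2, , drop = FALSE] + 1000
  pred <- predict(m, held, epsilon = 0.2)
  expect_equal(nrow(pred), 2L)
  expect_true(all(pred$p_MSIH >= 0 & pred$p_MSIH <= 1))
  # calibration lists are sorted and sized by class
  expect_equal(length(m$calibration$lists[["MSI-H"]]),
               sum(m$labels == "MSI-H"))
  expect_false(is.unsorted(m$calibration$lists[["MSS"]]))
})

test_that("cross_validate covers every sample once and scores a clean cohort", {
  toy <- toy_cohort_features(n = 120, seed = 15)
  cv <- cross_validate(toy$x, toy$labels, k = 5, seed = 8, mtry = 8,
                       calib_folds = 5)
  expect_equal(sort(cv$predictions$sample_id), sort(rownames(toy$x)))
  expect_equal(nrow(cv$predictions), 120L)
  expect_true(all(table(cv$predictions$fold) > 0))
  expect_gt(cv$sensitivity, 0.85)
  expect_gt(cv$specificity, 0.9)
  expect_true(all(cv$conformal$error_msih <= cv$conformal$epsilon + 0.25))
  # MSI-L merges into MSS for training
  lab2 <- toy$labels
  lab2[lab2 == "MSS"][1:5] <- "MSI-L"
  cv2 <- cross_validate(toy$x, lab2, k = 5, seed = 8, mtry = 8,
                        calib_folds = 5)
  expect_equal(sort(unique(cv2$predictions$truth)), c("MSI-H", "MSS"))
})
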