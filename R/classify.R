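# MSI status prediction: gene-level feature encoding, near-zero-variance
# filtering, z-scaling, a 100-tree random forest, and Mondrian (label-
# conditional) conformal prediction with per-class p-values.

#' Encode a cohort of MSI calls as a feature matrix
#'
#' Each sample is encoded by binary presence/absence of MSI events per gene
#' (restricted to genes with at least one event anywhere in the cohort) plus
#' one integer total-event-count feature. Loci that map to no gene are
#' excluded from the gene features but still counted in the total. Column
#' order is deterministic: gene ids ascending, the total (`TOTAL_MSI`) last.
#'
#' @param matrix A `cohort_calls` object ([build_cohort_matrix()]).
#' @return Numeric matrix, samples x features.
#' @export
encode_features <- function(matrix) {
  ev <- matrix$events
  if (nrow(ev) == 0) stop("empty cohort")
  genes <- matrix$loci$gene
  total <- rowSums(ev)
  has_gene <- !is.na(genes)
  gene_ids <- sort(unique(genes[has_gene]))
  gm <- vapply(gene_ids, function(g) {
    cols <- which(has_gene & genes == g)
    as.numeric(rowSums(ev[, cols, drop = FALSE]) > 0)
  }, numeric(nrow(ev)))
  if (length(gene_ids) == 1L) gm <- base::matrix(gm, ncol = 1L)
  colnames(gm) <- gene_ids
  keep <- colSums(gm) > 0
  gm <- gm[, keep, drop = FALSE]
  out <- cbind(gm, TOTAL_MSI = total)
  rownames(out) <- rownames(ev)
  out
}

#' Remove near-zero-variance features
#'
#' Drops constant columns and columns whose most-common to second-most-
#' common value frequency ratio exceeds `freq_cut` while the fraction of
#' unique values is below `unique_cut` (the conventional defaults of the
#' caret near-zero-variance filter).
#'
#' @param x Feature matrix.
#' @param freq_cut Frequency-ratio threshold (default 95/5 = 19).
#' @param unique_cut Unique-value-fraction threshold (default 0.10).
#' @return List with `x` (reduced matrix), `kept` and `removed` column
#'   names.
#' @export
nzv_filter <- function(x, freq_cut = 95 / 5, unique_cut = 0.10) {
  nzv <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    tb <- sort(table(v), decreasing = TRUE)
    if (length(tb) == 1L) return(TRUE)               # constant
    freq_ratio <- tb[1L] / tb[2L]
    unique_frac <- length(tb) / length(v)
    freq_ratio > freq_cut && unique_frac < unique_cut
  }, logical(1))
  if (all(nzv)) stop("all features removed by the near-zero-variance filter")
  list(x = x[, !nzv, drop = FALSE],
       kept = colnames(x)[!nzv], removed = colnames(x)[nzv])
}

#' Z-score a feature matrix
#'
#' Mean-centres each column to zero and scales to unit variance. When
#' `center`/`scale` are supplied (a stored preprocessing record), they are
#' applied instead of being re-estimated, so held-out samples are
#' transformed with the training parameters.
#'
#' @param x Feature matrix (post-filter).
#' @param center,scale Optional stored per-feature means and standard
#'   deviations.
#' @return List with `x` (z-scored), `center`, `scale`.
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
  } else {
    stopifnot(identical(names(center), colnames(x)),
              identical(names(scale), colnames(x)))
  }
  if (any(scale == 0 | is.na(scale))) {
    stop("zero-variance feature after filtering: ",
         paste(colnames(x)[scale == 0 | is.na(scale)], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  list(x = z, center = stats::setNames(center, colnames(x)),
       scale = stats::setNames(scale, colnames(x)))
}

msi_levels <- c("MSI-H", "MSS")

as_msi_factor <- function(labels, merge_msil = TRUE) {
  lab <- as.character(labels)
  if (merge_msil) lab[lab == "MSI-L"] <- "MSS"
  if (!all(lab %in% msi_levels)) {
    stop("labels must be MSI-H, MSS (or MSI-L when merge_msil = TRUE)")
  }
  factor(lab, levels = msi_levels)
}

# Stratified fold assignment, deterministic under the current RNG state.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit the MSI random forest
#'
#' A 100-tree random forest on z-scored features with binary MSI-H/MSS
#' labels. When `mtry` is `NULL` it is selected over the grid
#' {sqrt(d), d/10, d/4, d/2} (capped at d) by stratified 10-fold
#' cross-validated balanced accuracy, then the final model is refit on all
#' training data.
#'
#' @param x Z-scored feature matrix.
#' @param y Labels (factor MSI-H/MSS, or character).
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; `NULL` tunes by CV.
#' @param seed Random seed controlling fold assignment and forest
#'   randomness.
#' @param cv_folds Folds for mtry tuning (default 10).
#' @return List with `model` (randomForest), `mtry`, `n_trees`, `seed`,
#'   and `tuning` (grid results or NULL).
#' @export
fit_forest <- function(x, y, n_trees = 100L, mtry = NULL, seed = 1L,
                       cv_folds = 10L) {
  y <- as_msi_factor(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  d <- ncol(x)
  tuning <- NULL
  if (is.null(mtry)) {
    grid <- sort(unique(pmin(d, pmax(1L, floor(c(sqrt(d), d / 10, d / 4, d / 2))))))
    set.seed(seed)
    fold <- stratified_folds(y, cv_folds)
    bacc <- numeric(length(grid))
    for (gi in seq_along(grid)) {
      pred <- factor(rep(NA_character_, length(y)), levels = msi_levels)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        set.seed(seed + 1000L * gi + f)
        m <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                        ntree = n_trees, mtry = grid[gi])
        pred[!tr] <- stats::predict(m, x[!tr, , drop = FALSE])
      }
      sens <- mean(pred[y == "MSI-H"] == "MSI-H")
      spec <- mean(pred[y == "MSS"] == "MSS")
      bacc[gi] <- (sens + spec) / 2
    }
    mtry <- grid[which.max(bacc)]
    tuning <- data.table::data.table(mtry = grid, balanced_accuracy = bacc)
  }
  set.seed(seed)
  model <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry)
  list(model = model, mtry = mtry, n_trees = n_trees, seed = seed,
       tuning = tuning)
}

# Vote fraction for each class on new samples: fraction of trees voting.
forest_votes <- function(model, newx) {
  v <- stats::predict(model, newx, type = "vote", norm.votes = TRUE)
  v[, msi_levels, drop = FALSE]
}

# Coerce a vote input to a samples x 2 matrix with MSI-H/MSS columns.
as_vote_matrix <- function(votes) {
  v <- as.matrix(votes)
  if (is.null(colnames(v))) {
    if (ncol(v) != 2L) stop("vote matrix must have two columns")
    colnames(v) <- msi_levels
  }
  v[, msi_levels, drop = FALSE]
}

#' Out-of-fold vote fractions by cross-validation
#'
#' Fits the forest on k-1 folds and records, for each held-out sample, the
#' fraction of trees voting for each class. These out-of-fold votes are the
#' inputs to the Mondrian calibration lists.
#'
#' @param x Z-scored feature matrix.
#' @param y Labels.
#' @param mtry Features tried per split.
#' @param k Number of folds (default 10).
#' @param seed Seed controlling fold assignment and forests.
#' @param n_trees Number of trees (default 100).
#' @return List with `votes` (samples x 2 matrix) and `fold` (assignment).
#' @export
cv_votes <- function(x, y, mtry, k = 10L, seed = 1L, n_trees = 100L) {
  y <- as_msi_factor(y)
  set.seed(seed)
  fold <- stratified_folds(y, k)
  votes <- base::matrix(NA_real_, nrow = nrow(x), ncol = 2L,
                        dimnames = list(rownames(x), msi_levels))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) stop("fold ", f, " leaves a single class")
    set.seed(seed + f)
    m <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                    ntree = n_trees, mtry = mtry)
    votes[!tr, ] <- forest_votes(m, x[!tr, , drop = FALSE])
  }
  list(votes = votes, fold = fold)
}

# Leak-free out-of-fold votes on RAW features: the near-zero-variance
# filter and z-scaling are refit inside each calibration fold, and the
# held-out samples are transformed with that fold's training record, so the
# calibration votes are exchangeable with votes on genuinely new samples.
nested_cv_votes <- function(x_raw, y, mtry, k = 10L, seed = 1L,
                            n_trees = 100L) {
  y <- as_msi_factor(y)
  set.seed(seed)
  fold <- stratified_folds(y, k)
  votes <- base::matrix(NA_real_, nrow = nrow(x_raw), ncol = 2L,
                        dimnames = list(rownames(x_raw), msi_levels))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) stop("fold ", f, " leaves a single class")
    flt <- nzv_filter(x_raw[tr, , drop = FALSE])
    std <- standardize(flt$x)
    set.seed(seed + f)
    m <- randomForest::randomForest(std$x, y[tr], ntree = n_trees,
                                    mtry = min(mtry, ncol(std$x)))
    xte <- base::matrix(0, nrow = sum(!tr), ncol = length(flt$kept),
                        dimnames = list(rownames(x_raw)[!tr], flt$kept))
    shared <- intersect(colnames(x_raw), flt$kept)
    xte[, shared] <- x_raw[!tr, shared, drop = FALSE]
    zte <- standardize(xte, center = std$center, scale = std$scale)$x
    votes[!tr, ] <- forest_votes(m, zte)
  }
  list(votes = votes, fold = fold)
}

#' Build Mondrian calibration lists
#'
#' For each class c, the calibration list is the increasingly sorted vector
#' of out-of-fold vote fractions for c over the training samples whose true
#' label is c (label-conditional calibration, the defining property of the
#' Mondrian scheme).
#'
#' @param votes Out-of-fold vote matrix from [cv_votes()].
#' @param labels True labels.
#' @param fold Optional fold-assignment record to store.
#' @return Object of class `mondrian_calibration`: per-class sorted lists,
#'   class counts, fold record.
#' @export
calibrate_mondrian <- function(votes, labels, fold = NULL) {
  labels <- as_msi_factor(labels)
  votes <- as_vote_matrix(votes)
  if (any(is.na(votes))) stop("missing out-of-fold vote")
  lists <- lapply(msi_levels, function(cl) {
    unname(sort(votes[labels == cl, cl]))
  })
  names(lists) <- msi_levels
  structure(list(lists = lists,
                 class_counts = table(labels),
                 fold = fold),
            class = "mondrian_calibration")
}

#' Conformal prediction of MSI status
#'
#' For each class c with calibration list L_c and test vote fraction v_c,
#' the standard convention computes the smoothed conformal p-value
#' p_c = (#\{a in L_c : a <= v_c\} + 1) / (|L_c| + 1) (conformity = own-class
#' vote fraction); the class is included in the prediction set when
#' p_c > epsilon. The literal convention instead computes
#' p_c = #\{a in L_c : a > v_c\} / |L_c|, the reading in which calibration
#' votes *above* the test vote count towards inclusion; it is provided for
#' comparison and recorded in the output. The verdict is MSI-H or MSS for a
#' singleton prediction set, "both" when both classes are included and
#' "none" when neither is.
#'
#' @param votes Test vote matrix (samples x 2, columns MSI-H, MSS) from
#'   [forest_votes()], or a fitted forest list plus `newx`.
#' @param calibration A `mondrian_calibration`.
#' @param epsilon Significance level in [0, 1).
#' @param convention `"standard"` (default) or `"literal"`.
#' @return `data.table`: sample_id, vote and p per class, epsilon,
#'   convention, prediction-set membership and verdict.
#' @export
conformal_predict <- function(votes, calibration, epsilon,
                              convention = c("standard", "literal")) {
  convention <- match.arg(convention)
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must lie in [0, 1)")
  if (is.list(votes) && !is.null(votes$model)) {
    stop("pass a vote matrix from forest_votes(model, newx)")
  }
  votes <- as_vote_matrix(votes)
  pm <- vapply(msi_levels, function(cl) {
    L <- calibration$lists[[cl]]
    v <- votes[, cl]
    if (convention == "standard") {
      (vapply(v, function(vi) sum(L <= vi), numeric(1)) + 1) / (length(L) + 1)
    } else {
      vapply(v, function(vi) sum(L > vi), numeric(1)) / length(L)
    }
  }, numeric(nrow(votes)))
  if (nrow(votes) == 1L) pm <- base::matrix(pm, nrow = 1L,
                                            dimnames = list(rownames(votes),
                                                            msi_levels))
  inc <- pm > epsilon
  verdict <- ifelse(inc[, "MSI-H"] & inc[, "MSS"], "both",
                    ifelse(inc[, "MSI-H"], "MSI-H",
                           ifelse(inc[, "MSS"], "MSS", "none")))
  data.table::data.table(
    sample_id = if (is.null(rownames(votes))) as.character(seq_len(nrow(votes)))
                else rownames(votes),
    vote_MSIH = votes[, "MSI-H"], vote_MSS = votes[, "MSS"],
    p_MSIH = pm[, "MSI-H"], p_MSS = pm[, "MSS"],
    epsilon = epsilon, convention = convention,
    in_set_MSIH = inc[, "MSI-H"], in_set_MSS = inc[, "MSS"],
    verdict = verdict)
}

#' Train the full MSI prediction pipeline
#'
#' Applies the near-zero-variance filter and z-scaling, tunes and fits the
#' forest, computes out-of-fold votes and builds the Mondrian calibration
#' lists. The returned bundle carries everything needed to predict new
#' samples with the training preprocessing record.
#'
#' @param x_raw Raw feature matrix ([encode_features()]).
#' @param labels Training labels (MSI-L merged into MSS by default).
#' @param seed Pipeline seed (fold assignment and forest randomness).
#' @param n_trees,mtry,cv_folds Passed to [fit_forest()] / [cv_votes()].
#' @param merge_msil Treat MSI-L samples as MSS (default TRUE).
#' @return Object of class `msi_model`.
#' @export
train_msi_model <- function(x_raw, labels, seed = 1L, n_trees = 100L,
                            mtry = NULL, cv_folds = 10L, merge_msil = TRUE) {
  y <- as_msi_factor(labels, merge_msil = merge_msil)
  flt <- nzv_filter(x_raw)
  std <- standardize(flt$x)
  fit <- fit_forest(std$x, y, n_trees = n_trees, mtry = mtry, seed = seed,
                    cv_folds = cv_folds)
  cv <- nested_cv_votes(x_raw, y, mtry = fit$mtry, k = cv_folds, seed = seed,
                        n_trees = n_trees)
  cal <- calibrate_mondrian(cv$votes, y, fold = cv$fold)
  structure(list(fit = fit, calibration = cal,
                 preprocess = list(kept = flt$kept, removed = flt$removed,
                                   center = std$center, scale = std$scale),
                 labels = y, seed = seed),
            class = "msi_model")
}

#' Predict MSI status for new samples
#'
#' @param object An `msi_model`.
#' @param x_raw Raw feature matrix for new samples; columns are matched to
#'   the training features (missing features are zero-filled before
#'   z-scaling with the stored training parameters).
#' @param epsilon Significance level (confidence = 1 - epsilon).
#' @param convention Conformal p-value convention (see
#'   [conformal_predict()]).
#' @param ... Unused.
#' @return Predictions `data.table` from [conformal_predict()].
#' @export
predict.msi_model <- function(object, x_raw, epsilon = 0.25,
                              convention = c("standard", "literal"), ...) {
  kept <- object$preprocess$kept
  x <- base::matrix(0, nrow = nrow(x_raw), ncol = length(kept),
                    dimnames = list(rownames(x_raw), kept))
  shared <- intersect(colnames(x_raw), kept)
  x[, shared] <- x_raw[, shared]
  z <- standardize(x, center = object$preprocess$center,
                   scale = object$preprocess$scale)$x
  v <- forest_votes(object$fit$model, z)
  conformal_predict(v, object$calibration, epsilon = epsilon,
                    convention = match.arg(convention))
}

#' Cross-validated performance of the MSI pipeline
#'
#' Stratified k-fold cross-validation with no leakage: the near-zero-
#' variance filter, z-scaling parameters, mtry tuning and Mondrian
#' calibration are all recomputed inside each training fold. Reports
#' sensitivity (MSI-H recall) and specificity (MSS recall) of forced
#' single-class predictions (argmax vote), plus conformal verdict counts
#' and class-conditional exclusion errors at each requested epsilon.
#'
#' @param x_raw Raw feature matrix.
#' @param labels Labels (MSI-L merged into MSS by default).
#' @param k Outer folds (default 10).
#' @param epsilons Significance levels evaluated (default 0.05, 0.1, 0.25).
#' @param seed Pipeline seed.
#' @param n_trees,mtry Forest parameters; `mtry = NULL` tunes inside each
#'   training fold.
#' @param calib_folds Folds of the inner calibration CV (default 10).
#' @param merge_msil Treat MSI-L as MSS.
#' @return List with `sensitivity`, `specificity`, `confusion`,
#'   `conformal` (per-epsilon verdict counts and class-conditional error
#'   rates) and the per-sample prediction table.
#' @export
cross_validate <- function(x_raw, labels, k = 10L,
                           epsilons = c(0.05, 0.1, 0.25), seed = 1L,
                           n_trees = 100L, mtry = NULL, calib_folds = 10L,
                           merge_msil = TRUE) {
  y <- as_msi_factor(labels, merge_msil = merge_msil)
  if (min(table(y)) < k) stop("not enough samples per class for ", k, " folds")
  set.seed(seed)
  fold <- stratified_folds(y, k)
  votes <- base::matrix(NA_real_, nrow = nrow(x_raw), ncol = 2L,
                        dimnames = list(rownames(x_raw), msi_levels))
  pvals <- list()
  for (f in seq_len(k)) {
    tr <- fold != f
    flt <- nzv_filter(x_raw[tr, , drop = FALSE])
    std <- standardize(flt$x)
    fit <- fit_forest(std$x, y[tr], n_trees = n_trees, mtry = mtry,
                      seed = seed + 100L * f, cv_folds = calib_folds)
    cvv <- nested_cv_votes(x_raw[tr, , drop = FALSE], y[tr],
                           mtry = fit$mtry, k = calib_folds,
                           seed = seed + 100L * f, n_trees = n_trees)
    cal <- calibrate_mondrian(cvv$votes, y[tr])
    # held-out fold transformed with the training fold's record
    xte <- base::matrix(0, nrow = sum(!tr), ncol = length(flt$kept),
                        dimnames = list(rownames(x_raw)[!tr], flt$kept))
    shared <- intersect(colnames(x_raw), flt$kept)
    xte[, shared] <- x_raw[!tr, shared, drop = FALSE]
    zte <- standardize(xte, center = std$center, scale = std$scale)$x
    vte <- forest_votes(fit$model, zte)
    votes[!tr, ] <- vte
    pvals[[f]] <- conformal_predict(vte, cal, epsilon = 0)[,
      .(sample_id, p_MSIH, p_MSS)]
  }
  pv <- data.table::rbindlist(pvals)
  pv <- pv[match(rownames(x_raw), sample_id)]
  forced <- factor(ifelse(votes[, "MSI-H"] >= votes[, "MSS"], "MSI-H", "MSS"),
                   levels = msi_levels)
  sens <- mean(forced[y == "MSI-H"] == "MSI-H")
  spec <- mean(forced[y == "MSS"] == "MSS")
  conf <- table(truth = y, forced = forced)
  conformal <- data.table::rbindlist(lapply(epsilons, function(eps) {
    inc_h <- pv$p_MSIH > eps
    inc_s <- pv$p_MSS > eps
    verdict <- ifelse(inc_h & inc_s, "both",
                      ifelse(inc_h, "MSI-H", ifelse(inc_s, "MSS", "none")))
    err_h <- mean(!inc_h[y == "MSI-H"])   # true class excluded
    err_s <- mean(!inc_s[y == "MSS"])
    data.table::data.table(epsilon = eps,
                           n_msih = sum(verdict == "MSI-H"),
                           n_mss = sum(verdict == "MSS"),
                           n_both = sum(verdict == "both"),
                           n_none = sum(verdict == "none"),
                           error_msih = err_h, error_mss = err_s)
  }))
  list(sensitivity = sens, specificity = spec, confusion = conf,
       conformal = conformal,
       predictions = data.table::data.table(
         sample_id = rownames(x_raw), truth = as.character(y),
         fold = fold, vote_MSIH = votes[, "MSI-H"],
         vote_MSS = votes[, "MSS"], forced = as.character(forced),
         p_MSIH = pv$p_MSIH, p_MSS = pv$p_MSS))
}
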