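# Independent brute-force oracles used to validate the package's
# statistical and scanning cores. These deliberately share no code with the
# implementation: plain loops and first-principles formulas only.

# Enumerate every maximal perfect tandem tract by trying every (position,
# unit size) pair and extending maximally, then filtering like the scanner
# definition: minimal period, length window, optional score floor, no N.
oracle_find_repeats <- function(seq, min_len = 6L, max_len = 60L,
                                max_unit = 4L, min_score = NULL) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  found <- list()
  for (k in seq_len(max_unit)) {
    i <- 1L
    while (i + k <= n) {
      # i must start a maximal run for period k
      if (i > 1L && !is.na(chars[i - 1L]) &&
          chars[i - 1L] != "N" && chars[i - 1L] == chars[i + k - 1L]) {
        # left-extendable; skip (handled at the true start)
      }
      j <- i
      while (j + k <= n && chars[j] != "N" && chars[j + k] != "N" &&
             chars[j] == chars[j + k]) {
        j <- j + 1L
      }
      if (j > i) {                      # run of matches [i, j-1]
        len <- (j - i) + k
        st <- i
        ok <- TRUE
        if (any(chars[st:(st + len - 1L)] == "N")) ok <- FALSE
        if (ok && len > max_len) ok <- FALSE
        if (ok) {
          if (is.null(min_score)) { if (len < min_len) ok <- FALSE }
          else if (len - k < min_score) ok <- FALSE
        }
        if (ok && k >= 2L && len < 2L * k) ok <- FALSE
        if (ok && k > 1L) {
          for (p in seq_len(k - 1L)) {
            idx <- st:(st + len - 1L - p)
            if (all(chars[idx] == chars[idx + p])) { ok <- FALSE; break }
          }
        }
        if (ok) {
          found[[length(found) + 1L]] <-
            data.frame(start = st - 1L, end = st - 1L + len, unit_len = k,
                       unit = paste(chars[st:(st + k - 1L)], collapse = ""))
        }
        i <- j                           # next possible start for this k
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      unit_len = integer(), unit = character()))
  }
  out <- do.call(rbind, found)
  out <- out[!duplicated(out[, c("start", "end", "unit_len")]), ]
  out[order(out$start, out$unit_len), , drop = FALSE]
}

# KS D by evaluating both step ECDFs on the merged support.
oracle_ks_D <- function(x, y) {
  support <- sort(unique(c(x, y)))
  dx <- vapply(support, function(t) mean(x <= t), numeric(1))
  dy <- vapply(support, function(t) mean(y <= t), numeric(1))
  max(abs(dx - dy))
}

# BH step-up: q_(i) = min over j >= i of p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# One-tailed (enrichment) Fisher p by hypergeometric tail summation over
# all tables at least as extreme as observed. Table: a of (a+b) focal
# samples with events, c of (c+d) others.
oracle_fisher_greater <- function(a, b, c, d) {
  K <- a + b          # focal group size
  N <- a + b + c + d
  n1 <- a + c         # total events
  amax <- min(K, n1)
  tot <- 0
  for (x in a:amax) {
    tot <- tot + exp(lchoose(K, x) + lchoose(N - K, n1 - x) - lchoose(N, n1))
  }
  min(1, tot)
}

oracle_fisher_less <- function(a, b, c, d) {
  K <- a + b; N <- a + b + c + d; n1 <- a + c
  amin <- max(0, n1 - (N - K))
  tot <- 0
  for (x in amin:a) {
    tot <- tot + exp(lchoose(K, x) + lchoose(N - K, n1 - x) - lchoose(N, n1))
  }
  min(1, tot)
}

# Two-tailed Fisher p: sum of all table probabilities not exceeding the
# observed one (with the customary relative tolerance).
oracle_fisher_two <- function(a, b, c, d) {
  K <- a + b; N <- a + b + c + d; n1 <- a + c
  amin <- max(0, n1 - (N - K)); amax <- min(K, n1)
  probs <- vapply(amin:amax, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n1 - x) - lchoose(N, n1))
  }, numeric(1))
  p_obs <- probs[a - amin + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Smoothed conformal p by explicit counting.
oracle_conformal_p <- function(calibration_list, v) {
  k <- 0L
  for (a in calibration_list) if (a <= v) k <- k + 1L
  (k + 1) / (length(calibration_list) + 1)
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Small deterministic cohort for classifier tests (cheaper than the full
# simulator): MSI-H samples carry many gene events, MSS few.
toy_cohort_features <- function(n = 120, n_genes = 60, msih_frac = 0.25,
                                seed = 1) {
  set.seed(seed)
  n_h <- round(n * msih_frac)
  labels <- c(rep("MSI-H", n_h), rep("MSS", n - n_h))
  x <- matrix(0, n, n_genes,
              dimnames = list(sprintf("S%03d", 1:n),
                              sprintf("GENE%03d", 1:n_genes)))
  for (i in seq_len(n)) {
    k <- if (labels[i] == "MSI-H") rpois(1, 18) else rpois(1, 1)
    k <- min(k, n_genes)
    if (k > 0) x[i, sample(n_genes, k)] <- 1
  }
  x <- cbind(x, TOTAL_MSI = rowSums(x))
  list(x = x, labels = labels)
}
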