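# Cohort-level aggregation of per-sample MSI calls: recurrence ranking,
# tumour-type and MSI-H enrichment, region bias, chromatin-state enrichment.

#' Build a cohort call matrix from per-sample calls
#'
#' @param calls_list Named list of per-sample calls tables (names are sample
#'   ids; see [call_sample()]).
#' @param metadata `data.frame` with columns `sample_id`, `tumour_type`,
#'   `msi_label` (MSI-H, MSI-L, MSS or unknown).
#' @param catalogue Reference catalogue; its loci define the matrix columns.
#' @return An object of class `cohort_calls`: list with `samples` (metadata),
#'   `loci` (locus_id, region, gene), `events` and `frameshift_events`
#'   (binary sample x locus matrices).
#' @export
build_cohort_matrix <- function(calls_list, metadata, catalogue) {
  meta <- data.table::as.data.table(metadata)
  stopifnot(all(c("sample_id", "tumour_type", "msi_label") %in% names(meta)))
  if (!all(names(calls_list) %in% meta$sample_id)) {
    stop("calls_list contains sample ids absent from metadata")
  }
  meta <- meta[sample_id %in% names(calls_list)]
  loci <- catalogue[, .(locus_id, region, gene)]
  ev <- matrix(0L, nrow = nrow(meta), ncol = nrow(loci),
               dimnames = list(meta$sample_id, loci$locus_id))
  fs <- ev
  for (sid in meta$sample_id) {
    calls <- calls_list[[sid]]
    sig <- calls$locus_id[calls$significant %in% TRUE]
    sig <- intersect(sig, loci$locus_id)
    ev[sid, sig] <- 1L
    fsl <- calls$locus_id[calls$significant %in% TRUE &
                            calls$event_class %in% "frameshift"]
    fs[sid, intersect(fsl, loci$locus_id)] <- 1L
  }
  structure(list(samples = meta, loci = loci,
                 events = ev, frameshift_events = fs),
            class = "cohort_calls")
}

#' @export
print.cohort_calls <- function(x, ...) {
  cat(sprintf("cohort_calls: %d samples x %d loci; %d events (%d frameshift)\n",
              nrow(x$samples), nrow(x$loci),
              sum(x$events), sum(x$frameshift_events)))
  invisible(x)
}

event_matrix <- function(matrix, event_kind = c("all", "frameshift")) {
  event_kind <- match.arg(event_kind)
  if (event_kind == "all") matrix$events else matrix$frameshift_events
}

#' Rank loci by cohort recurrence of MSI events
#'
#' Per locus and sample group, reports the number and fraction of samples
#' harbouring an event, ranked by total event count descending with ties
#' broken by locus_id ascending.
#'
#' @param matrix A `cohort_calls` object.
#' @param group_by Metadata column defining groups (`"tumour_type"` or
#'   `"msi_label"`).
#' @param event_kind `"all"` events or `"frameshift"` only.
#' @return `data.table` with locus_id, region, gene, per-group `n_<group>`
#'   and `frac_<group>` columns, `total`, and `rank`.
#' @export
recurrence_rank <- function(matrix, group_by = c("tumour_type", "msi_label"),
                            event_kind = c("all", "frameshift")) {
  group_by <- match.arg(group_by)
  ev <- event_matrix(matrix, event_kind)
  if (nrow(ev) == 0) stop("empty cohort matrix")
  groups <- matrix$samples[[group_by]]
  out <- data.table::as.data.table(as.list(matrix$loci))
  for (g in sort(unique(groups))) {
    sel <- groups == g
    cnt <- colSums(ev[sel, , drop = FALSE])
    data.table::set(out, j = paste0("n_", g), value = as.integer(cnt))
    data.table::set(out, j = paste0("frac_", g), value = cnt / sum(sel))
  }
  data.table::set(out, j = "total", value = as.integer(colSums(ev)))
  data.table::setorder(out, -total, locus_id)
  data.table::set(out, j = "rank", value = seq_len(nrow(out)))
  out[]
}

# One-tailed (enrichment-direction) Fisher p for the 2x2 table
#   [a b; c d] = (focal, other) x (event, no event).
fisher_greater <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                     alternative = "greater")$p.value
}
fisher_less <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                     alternative = "less")$p.value
}
fisher_two <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Tumour-type enrichment of events at one locus
#'
#' One-tailed Fisher's exact test of the 2x2 table (focal type vs all other
#' samples) x (event vs no event), in the enrichment direction.
#'
#' @param matrix A `cohort_calls` object.
#' @param locus A locus_id present in the matrix.
#' @param focal_type Tumour type tested for enrichment.
#' @param event_kind `"all"` or `"frameshift"`.
#' @return List with the table cells `a`, `b`, `c`, `d` and the one-tailed
#'   `p`.
#' @export
type_enrichment <- function(matrix, locus, focal_type,
                            event_kind = c("all", "frameshift")) {
  ev <- event_matrix(matrix, event_kind)
  j <- match(locus, matrix$loci$locus_id)
  if (is.na(j)) stop("locus not in catalogue: ", locus)
  types <- matrix$samples$tumour_type
  if (!focal_type %in% types) stop("unknown tumour type: ", focal_type)
  if (sum(types == focal_type) < 5L) {
    warning("focal tumour type has fewer than 5 samples: ", focal_type)
  }
  focal <- types == focal_type
  a <- sum(ev[focal, j]); b <- sum(focal) - a
  c_ <- sum(ev[!focal, j]); d <- sum(!focal) - c_
  list(a = a, b = b, c = c_, d = d, p = fisher_greater(a, b, c_, d))
}

#' Rank loci by specificity for MSI-H tumours
#'
#' For each locus, a one-tailed Fisher test of enrichment in MSI-H samples
#' versus the rest (MSI-L and MSS); loci are ranked by raw p ascending, ties
#' broken by higher MSI-H event fraction and then locus_id. BH-adjusted q
#' values are reported alongside but the ranking uses raw p.
#'
#' @param matrix A `cohort_calls` object with at least one MSI-H and one
#'   non-MSI-H sample.
#' @param event_kind `"all"` or `"frameshift"`.
#' @return Ranked `data.table` with per-class counts, fractions, p, q, rank.
#' @export
msih_specificity_rank <- function(matrix, event_kind = c("all", "frameshift")) {
  ev <- event_matrix(matrix, event_kind)
  lab <- matrix$samples$msi_label
  if (!any(lab == "MSI-H") || all(lab == "MSI-H")) {
    stop("cohort must contain MSI-H and non-MSI-H samples")
  }
  h <- lab == "MSI-H"
  nh <- sum(h); nr <- sum(!h)
  a <- colSums(ev[h, , drop = FALSE])
  c_ <- colSums(ev[!h, , drop = FALSE])
  p <- vapply(seq_along(a), function(j) {
    fisher_greater(a[j], nh - a[j], c_[j], nr - c_[j])
  }, numeric(1))
  out <- data.table::copy(matrix$loci)
  out[, `:=`(n_msih = as.integer(a),
             n_msil = as.integer(colSums(ev[lab == "MSI-L", , drop = FALSE])),
             n_mss = as.integer(colSums(ev[lab == "MSS", , drop = FALSE])),
             frac_msih = a / nh, frac_rest = c_ / nr,
             p = p, q = bh_fdr(p))]
  data.table::setorder(out, p, -frac_msih, locus_id)
  out[, rank := .I]
  out[]
}

#' Per-sample region bias of MSI calls
#'
#' Tests, for each region among coding, utr5 and utr3, whether the sample's
#' significant calls are enriched or depleted in that region relative to the
#' composition of the testable catalogue, with separate one-tailed Fisher
#' tests in each direction.
#'
#' @param sample_calls Calls table for one sample ([call_sample()]).
#' @param catalogue_composition Named integer vector of testable locus
#'   counts per region (the background; typically the loci tested in this
#'   sample, else the full catalogue).
#' @param alpha Significance level for the verdict (default 0.05).
#' @return `data.table` with region, called/background counts, enrichment
#'   and depletion p-values and a verdict in {enriched, depleted, neutral}.
#' @export
region_bias_test <- function(sample_calls, catalogue_composition,
                             alpha = 0.05) {
  regions <- c("coding", "utr5", "utr3")
  comp <- catalogue_composition
  called <- sample_calls[sample_calls$significant %in% TRUE, ]
  n_called_total <- nrow(called)
  total_bg <- sum(comp)
  out <- data.table::data.table(region = regions, n_called = 0L,
                                n_background = 0L,
                                p_enrich = NA_real_, p_deplete = NA_real_,
                                verdict = "neutral")
  if (n_called_total == 0) {
    warning("no significant calls; all regions neutral")
    return(out[])
  }
  for (i in seq_along(regions)) {
    rg <- regions[i]
    nr_bg <- if (rg %in% names(comp)) comp[[rg]] else 0L
    a <- sum(called$region == rg)            # called, in region
    b <- n_called_total - a                  # called, elsewhere
    c_ <- nr_bg - a                          # not called, in region
    d <- (total_bg - nr_bg) - b              # not called, elsewhere
    if (nr_bg == 0) next
    pe <- fisher_greater(a, b, c_, d)
    pd <- fisher_less(a, b, c_, d)
    out[i, `:=`(n_called = a, n_background = as.integer(nr_bg),
                p_enrich = pe, p_deplete = pd,
                verdict = if (pe < alpha) "enriched"
                          else if (pd < alpha) "depleted" else "neutral")]
  }
  out[]
}

#' Chromatin-state enrichment of MSI calls
#'
#' Assigns each called locus and each background catalogue locus to the
#' chromatin state overlapping its start coordinate (loci are at most 60 bp,
#' so boundary straddles are rare and a single unambiguous assignment is
#' used), then tests each state's 2x2 table (in state vs not) x (called vs
#' background) with a two-tailed Fisher test. When several epigenome state
#' maps are supplied, the per-state overlap percentages are averaged across
#' maps before testing.
#'
#' @param sample_calls Calls table (significant calls are used).
#' @param catalogue Reference catalogue (the background locus set).
#' @param state_map A state map `data.frame` with columns `chrom`, `start`,
#'   `end`, `state` (0-based half-open, non-overlapping), optionally with an
#'   `assembly` attribute, or a list of such maps.
#' @param alpha Significance level (default 0.05).
#' @param assembly Optional assembly tag; when both this and the map's
#'   `assembly` attribute are set they must agree.
#' @return `data.table` with state, counts, odds ratio, two-tailed p and a
#'   verdict in {enriched, depleted, neutral}.
#' @export
chromatin_enrichment <- function(sample_calls, catalogue, state_map,
                                 alpha = 0.05, assembly = NULL) {
  maps <- if (is.data.frame(state_map)) list(state_map) else state_map
  if (length(maps) == 0 || any(vapply(maps, nrow, integer(1)) == 0)) {
    stop("empty chromatin state map")
  }
  for (m in maps) {
    tag <- attr(m, "assembly")
    if (!is.null(assembly) && !is.null(tag) && !identical(tag, assembly)) {
      stop("assembly mismatch: catalogue ", assembly, " vs state map ", tag)
    }
  }
  called_ids <- sample_calls$locus_id[sample_calls$significant %in% TRUE]
  called <- catalogue[catalogue$locus_id %in% called_ids, ]
  n_called <- nrow(called); n_bg <- nrow(catalogue)
  if (n_called == 0) stop("no significant calls to test")
  states <- sort(unique(unlist(lapply(maps, function(m) unique(m$state)))))
  # per-map fraction of called / background loci whose start falls in state
  frac_called <- matrix(0, length(states), length(maps),
                        dimnames = list(states, NULL))
  frac_bg <- frac_called
  for (mi in seq_along(maps)) {
    m <- data.table::as.data.table(maps[[mi]])
    asg_c <- assign_state(called, m)
    asg_b <- assign_state(catalogue, m)
    tc <- table(factor(asg_c, levels = states))
    tb <- table(factor(asg_b, levels = states))
    frac_called[, mi] <- as.numeric(tc) / n_called
    frac_bg[, mi] <- as.numeric(tb) / n_bg
  }
  fc <- rowMeans(frac_called); fb <- rowMeans(frac_bg)
  a <- as.integer(round(fc * n_called))
  c_ <- as.integer(round(fb * n_bg))
  b <- n_called - a
  d <- n_bg - c_
  p <- vapply(seq_along(states), function(i) fisher_two(a[i], b[i], c_[i], d[i]),
              numeric(1))
  or <- (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
  data.table::data.table(
    state = states, n_called = a, n_background = c_,
    odds_ratio = or, p = p,
    verdict = ifelse(p < alpha & or > 1, "enriched",
                     ifelse(p < alpha & or < 1, "depleted", "neutral")))[]
}

# State label overlapping each locus start; NA when uncovered.
assign_state <- function(loci, state_dt) {
  lv <- unique(c(loci$chrom, state_dt$chrom))
  pts <- GenomicRanges::GRanges(factor(loci$chrom, lv),
                                IRanges::IRanges(loci$start + 1L,
                                                 loci$start + 1L))
  iv <- GenomicRanges::GRanges(factor(state_dt$chrom, lv),
                               IRanges::IRanges(state_dt$start + 1L,
                                                state_dt$end))
  hits <- GenomicRanges::findOverlaps(pts, iv, select = "first")
  ifelse(is.na(hits), NA_character_, state_dt$state[hits])
}
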