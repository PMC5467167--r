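# Per-locus MSI event calling from tumour/normal allele-length tallies:
# spanning-read extraction, KS testing, FDR control, frameshift rule.

#' Construct an allele-length tally
#'
#' A tally is the per-locus multiset of observed intra-read repeat lengths,
#' stored as a `data.table` with columns `length` (bp, integer >= 5) and
#' `count` (reads).
#'
#' @param lengths Integer vector of observed tract lengths (one per read),
#'   or the unique lengths when `counts` is given.
#' @param counts Optional read counts parallel to `lengths`.
#' @return A tally `data.table` sorted by length.
#' @export
tally <- function(lengths, counts = NULL) {
  if (is.null(counts)) {
    tb <- table(lengths)
    dt <- data.table::data.table(length = as.integer(names(tb)),
                                 count = as.integer(tb))
  } else {
    dt <- data.table::data.table(length = as.integer(lengths),
                                 count = as.integer(counts))
    dt <- dt[, .(count = sum(count)), by = length]
  }
  dt <- dt[count > 0]
  if (nrow(dt) > 0 && any(dt$length < 5L)) {
    stop("tally lengths must be >= 5 bp (intra-read detection floor)")
  }
  data.table::setorder(dt, length)
  dt[]
}

n_reads <- function(tally) sum(tally$count)

#' Extract the spanning repeat length from one read
#'
#' Re-detects microsatellite tracts inside the read sequence (minimum
#' intra-read tract size 5 bp) and returns the length of the tract whose
#' canonical unit matches the locus and whose 2 bp flanking sequences on
#' both sides are identical to the reference flanks. Reads in which the
#' tract is truncated, contracted below 5 bp, or flank-mismatched are
#' discounted (`NA`).
#'
#' @param read_seq Read sequence (character scalar).
#' @param unit Canonical repeat unit of the locus.
#' @param flank5,flank3 Reference 2 bp flanks immediately 5' and 3' of the
#'   locus tract.
#' @param expected_offset Optional expected 0-based offset of the tract
#'   start within the read; when several tracts match unit and flanks the
#'   one nearest this offset is used (ties: the first).
#' @param max_unit Maximum unit size for the intra-read scan.
#' @return Integer tract length in bp, or `NA_integer_`.
#' @export
extract_spanning_length <- function(read_seq, unit, flank5, flank3,
                                    expected_offset = NULL, max_unit = 4L) {
  stopifnot(nchar(flank5) == 2L, nchar(flank3) == 2L)
  cu <- canonical_unit(toupper(unit))
  hits <- find_repeats(read_seq, min_len = 5L, max_len = nchar(read_seq),
                       max_unit = max_unit)
  if (nrow(hits) == 0) return(NA_integer_)
  hits <- hits[unit == cu]
  if (nrow(hits) == 0) return(NA_integer_)
  s <- toupper(read_seq)
  ok <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    st <- hits$start[i]; en <- hits$end[i]          # 0-based half-open
    if (st < 2L || en + 2L > nchar(s)) next          # truncated at read edge
    ok[i] <- substr(s, st - 1L, st) == toupper(flank5) &&
      substr(s, en + 1L, en + 2L) == toupper(flank3)
  }
  hits <- hits[ok]
  if (nrow(hits) == 0) return(NA_integer_)
  if (nrow(hits) > 1L && !is.null(expected_offset)) {
    hits <- hits[order(abs(start - expected_offset))]
  }
  as.integer(hits$length[1L])
}

# Read alignments from a SAM/BAM file into a data.table of
# (qname, rname, pos, mapq, seq). SAM text is converted on the fly.
read_alignments <- function(path) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "mapq", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.table::data.table(qname = x$qname,
                         rname = as.character(x$rname),
                         pos = x$pos,           # 1-based leftmost
                         mapq = x$mapq,
                         seq = as.character(x$seq))
}

#' Tally intra-read repeat lengths per catalogue locus for one sample
#'
#' Collects, for every catalogue locus, the intra-read tract lengths of all
#' reads spanning the locus with matching 2 bp reference flanks, after
#' removing reads below the mapping-quality floor.
#'
#' @param alignments Path to a SAM/BAM file, or a `data.frame` with columns
#'   `rname`, `pos` (1-based leftmost), `mapq`, `seq`.
#' @param catalogue Reference catalogue (see [build_reference()]).
#' @param reference Named character vector of contig sequences (or FASTA
#'   path) supplying the 2 bp flanks.
#' @param mapq_min Mapping-quality floor (default 20).
#' @return A `data.table` with columns `locus_id`, `length`, `count`
#'   containing one tally per locus with at least one spanning read.
#' @export
tally_sample <- function(alignments, catalogue, reference, mapq_min = 20L) {
  reads <- if (is.character(alignments)) read_alignments(alignments)
           else data.table::as.data.table(alignments)
  seqs <- read_fasta_seqs(reference)
  cat_contigs <- unique(catalogue$chrom)
  read_contigs <- unique(reads$rname)
  if (length(read_contigs) > 0 && !any(read_contigs %in% cat_contigs)) {
    stop("no alignment contig matches the catalogue; offending contigs: ",
         paste(read_contigs, collapse = ", "))
  }
  stray <- setdiff(read_contigs, cat_contigs)
  if (length(stray) > 0) {
    warning("ignoring reads on contigs absent from the catalogue: ",
            paste(stray, collapse = ", "))
    reads <- reads[rname %in% cat_contigs]
  }
  if (!is.null(reads$mapq)) reads <- reads[is.na(mapq) | mapq >= mapq_min]
  out <- vector("list", nrow(catalogue))
  for (i in seq_len(nrow(catalogue))) {
    cm <- catalogue$chrom[i]
    st <- catalogue$start[i]; en <- catalogue$end[i]
    refseq <- seqs[[cm]]
    if (is.null(refseq)) next
    if (st < 2L || en + 2L > nchar(refseq)) next   # no 2 bp flanks available
    flank5 <- substr(refseq, st - 1L, st)          # ref[start-2, start)
    flank3 <- substr(refseq, en + 1L, en + 2L)     # ref[end, end+2)
    cand <- reads[rname == cm &
                    pos <= st - 1L &               # read starts at/before flank5
                    pos + nchar(seq) - 1L >= en + 2L]
    if (nrow(cand) == 0) next
    lens <- vapply(seq_len(nrow(cand)), function(j) {
      off <- st - (cand$pos[j] - 1L)               # expected 0-based offset
      extract_spanning_length(cand$seq[j], catalogue$unit[i], flank5, flank3,
                              expected_offset = off)
    }, integer(1))
    lens <- lens[!is.na(lens)]
    if (length(lens) == 0) next
    tl <- tally(lens)
    tl[, locus_id := catalogue$locus_id[i]]
    out[[i]] <- tl
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0) {
    return(data.table::data.table(locus_id = character(),
                                  length = integer(), count = integer()))
  }
  data.table::setcolorder(res, c("locus_id", "length", "count"))
  res[]
}

#' Two-sample Kolmogorov-Smirnov test on allele-length tallies
#'
#' Computes the KS statistic D as the supremum over the merged integer
#' support of the absolute difference of the two empirical CDFs, and an
#' asymptotic p-value from the Kolmogorov distribution with effective sample
#' size nm/(n+m). Integer read lengths make ties ubiquitous; the asymptotic
#' p-value is used as-is (its anticonservative behaviour is absorbed by the
#' FDR step). An exact p-value computed by the permutation distribution of D
#' (conditioning on ties) is available for small samples.
#'
#' @param tumor,normal Tally `data.table`s (see [tally()]).
#' @param exact Use the exact conditional (tie-respecting permutation)
#'   distribution of D instead of the asymptotic formula.
#' @return List with elements `D` and `p`.
#' @export
ks_two_sample <- function(tumor, normal, exact = FALSE) {
  if (nrow(tumor) == 0 || nrow(normal) == 0) {
    stop("both tallies must be non-empty")
  }
  n <- n_reads(tumor); m <- n_reads(normal)
  support <- sort(unique(c(tumor$length, normal$length)))
  ct <- numeric(length(support)); cn <- numeric(length(support))
  ct[match(tumor$length, support)] <- tumor$count
  cn[match(normal$length, support)] <- normal$count
  D <- max(abs(cumsum(ct) / n - cumsum(cn) / m))
  p <- if (exact) ks_p_exact(D, ct, cn) else ks_p_asymptotic(D, n, m)
  list(D = D, p = p)
}

# Exact conditional two-sided p-value of D given the pooled tie pattern
# (counts per support point ct, cn for the two samples).
ks_p_exact <- function(D, ct, cn) {
  n <- sum(ct); m <- sum(cn)
  z <- rep.int(seq_along(ct), ct + cn)
  stats::psmirnov(D - 1e-9, sizes = c(n, m), z = z,
                  two.sided = TRUE, lower.tail = FALSE, exact = TRUE)
}

# Asymptotic two-sided two-sample KS p-value: Kolmogorov series at
# lambda = sqrt(nm/(n+m)) * D.
ks_p_asymptotic <- function(D, n, m) {
  if (D <= 0) return(1)
  lambda <- sqrt(n * m / (n + m)) * D
  j <- seq_len(101L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

#' Benjamini-Hochberg adjusted FDR values
#'
#' Step-up adjusted values, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Mode of a tally with deterministic tie-breaking: among equally frequent
# lengths, the one closest to the reference tract length wins; remaining
# ties go to the shorter length.
tally_mode <- function(tl, ref_length) {
  mx <- max(tl$count)
  cand <- tl$length[tl$count == mx]
  cand[order(abs(cand - ref_length), cand)][1L]
}

#' Classify a significant coding MSI event as frameshift or in-frame
#'
#' Candidate tumour alleles are the mode of the tumour tally plus the
#' second-most-frequent tumour length when it is supported by at least 20%
#' of the tumour reads. Shifts are the candidate lengths minus the mode of
#' the normal tally. The event is a frameshift when any candidate shift is
#' non-zero and not a multiple of three, otherwise in-frame. A candidate
#' shift of 0 contributes no class on its own.
#'
#' @param tumor,normal Tally `data.table`s.
#' @param ref_length Reference tract length of the locus (used only to
#'   break mode ties deterministically).
#' @param second_allele_frac Support threshold for the second tumour allele
#'   (default 0.20).
#' @return List with `event_class` ("frameshift" or "inframe") and integer
#'   `shifts`.
#' @export
classify_event <- function(tumor, normal, ref_length,
                           second_allele_frac = 0.20) {
  if (nrow(tumor) == 0 || nrow(normal) == 0) {
    stop("both tallies must be non-empty")
  }
  m <- tally_mode(normal, ref_length)
  t_mode <- tally_mode(tumor, ref_length)
  cand <- t_mode
  rest <- tumor[length != t_mode]
  if (nrow(rest) > 0) {
    second <- tally_mode(rest, ref_length)
    if (rest[length == second, count] >= second_allele_frac * n_reads(tumor)) {
      cand <- c(cand, second)
    }
  }
  shifts <- as.integer(cand - m)
  frameshift <- any(shifts != 0L & shifts %% 3L != 0L)
  list(event_class = if (frameshift) "frameshift" else "inframe",
       shifts = shifts)
}

#' Call somatic MSI events for one tumour/normal pair
#'
#' Tests every catalogue locus with at least `min_reads` spanning reads in
#' both the tumour and the matched normal, comparing the two allele-length
#' distributions with the two-sample KS test, adjusting p-values by
#' Benjamini-Hochberg across the tested loci of the sample, and marking loci
#' with q below `fdr_threshold` as significant MSI events. Significant
#' events at coding loci are classified as frameshift or in-frame; events
#' elsewhere are labelled noncoding.
#'
#' @param tumor_tallies,normal_tallies `data.table`s with columns
#'   `locus_id`, `length`, `count` (see [tally_sample()]).
#' @param catalogue Reference catalogue.
#' @param min_reads Minimum tumour and normal read counts (default 5).
#' @param fdr_threshold FDR significance threshold (default 0.05).
#' @param fdr_scope `"sample"` adjusts across the tested loci of this sample
#'   (default); `"none"` reports raw p in `q` (used when a caller performs a
#'   cohort-wide adjustment itself).
#' @param p_method KS p-value computation: `"hybrid"` (default; exact
#'   conditional p where the asymptotic screen is below 0.2 — with integer
#'   read lengths the tie-heavy asymptotic p is conservative and costs
#'   sensitivity), `"asymptotic"`, or `"exact"` everywhere.
#' @return Calls `data.table`: chrom, start, end, locus_id, region, gene,
#'   n_normal, n_tumor, ks_D, p, q, significant, event_class, shifts
#'   (comma-joined).
#' @export
call_sample <- function(tumor_tallies, normal_tallies, catalogue,
                        min_reads = 5L, fdr_threshold = 0.05,
                        fdr_scope = c("sample", "none"),
                        p_method = c("hybrid", "asymptotic", "exact")) {
  fdr_scope <- match.arg(fdr_scope)
  p_method <- match.arg(p_method)
  tt <- data.table::as.data.table(tumor_tallies)
  nt <- data.table::as.data.table(normal_tallies)
  nt_tot <- nt[, .(n_normal = sum(count)), by = locus_id]
  tt_tot <- tt[, .(n_tumor = sum(count)), by = locus_id]
  tested <- merge(nt_tot, tt_tot, by = "locus_id")
  tested <- tested[n_normal >= min_reads & n_tumor >= min_reads]
  if (nrow(tested) == 0) {
    warning("no locus with >= ", min_reads, " tumour and normal reads")
    return(empty_calls())
  }
  tt <- tt[locus_id %in% tested$locus_id]
  nt <- nt[locus_id %in% tested$locus_id]
  ks <- ks_batch(tt, nt, p_method = p_method)
  res <- merge(tested, ks, by = "locus_id")
  res[, q := if (fdr_scope == "sample") bh_fdr(p) else p]
  res[, significant := q < fdr_threshold]
  res <- merge(res,
               catalogue[, .(locus_id, chrom, start, end, region, gene,
                             ref_length = length)],
               by = "locus_id")
  res[, event_class := NA_character_]
  res[, shifts := NA_character_]
  sig_idx <- which(res$significant)
  for (i in sig_idx) {
    if (identical(res$region[i], "coding")) {
      cl <- classify_event(tt[locus_id == res$locus_id[i], .(length, count)],
                           nt[locus_id == res$locus_id[i], .(length, count)],
                           ref_length = res$ref_length[i])
      res$event_class[i] <- cl$event_class
      res$shifts[i] <- paste(cl$shifts, collapse = ",")
    } else {
      res$event_class[i] <- "noncoding"
    }
  }
  data.table::setcolorder(res, c("chrom", "start", "end", "locus_id",
                                 "region", "gene", "n_normal", "n_tumor",
                                 "ks_D", "p", "q", "significant",
                                 "event_class", "shifts"))
  res[, ref_length := NULL]
  data.table::setorder(res, chrom, start)
  res[]
}

empty_calls <- function() {
  data.table::data.table(chrom = character(), start = integer(),
                         end = integer(), locus_id = character(),
                         region = character(), gene = character(),
                         n_normal = integer(), n_tumor = integer(),
                         ks_D = numeric(), p = numeric(), q = numeric(),
                         significant = logical(),
                         event_class = character(), shifts = character())
}

# Vectorised KS over many loci: both inputs keyed by locus_id.
# p_method "hybrid" screens with the asymptotic p and recomputes the exact
# conditional p where the screen falls below `exact_below`; because the
# exact p is only substituted when the (conservative) screen is already
# small, the reported values remain valid p-values.
ks_batch <- function(tumor, normal, p_method = c("hybrid", "asymptotic",
                                                 "exact"),
                     exact_below = 0.2) {
  p_method <- match.arg(p_method)
  tt <- data.table::copy(tumor)[, role := "t"]
  nt <- data.table::copy(normal)[, role := "n"]
  both <- data.table::rbindlist(list(tt, nt), use.names = TRUE)
  both[, `:=`(nt_tot = sum(count[role == "t"]),
              nn_tot = sum(count[role == "n"])), by = locus_id]
  res <- both[, {
    sup <- sort(unique(length))
    ct <- numeric(base::length(sup)); cn <- numeric(base::length(sup))
    it <- role == "t"
    ct[match(length[it], sup)] <- count[it]
    cn[match(length[!it], sup)] <- count[!it]
    D <- max(abs(cumsum(ct) / nt_tot[1L] - cumsum(cn) / nn_tot[1L]))
    p_asym <- ks_p_asymptotic(D, nt_tot[1L], nn_tot[1L])
    p <- if (p_method == "asymptotic") p_asym
         else if (p_method == "exact" ||
                  (p_method == "hybrid" && p_asym < exact_below))
           ks_p_exact(D, ct, cn)
         else p_asym
    .(ks_D = D, p = p)
  }, by = locus_id]
  res
}

#' Write / read tally TSVs
#'
#' Columns: locus_id, sample_role (tumor|normal), length_bp, read_count.
#'
#' @param tumor_tallies,normal_tallies Tally tables keyed by `locus_id`.
#' @param path File path.
#' @rdname tally_io
#' @export
write_tally_tsv <- function(tumor_tallies, normal_tallies, path) {
  tt <- data.table::copy(data.table::as.data.table(tumor_tallies))
  nt <- data.table::copy(data.table::as.data.table(normal_tallies))
  tt[, sample_role := "tumor"]; nt[, sample_role := "normal"]
  both <- data.table::rbindlist(list(tt, nt))
  data.table::setnames(both, c("length", "count"), c("length_bp", "read_count"))
  data.table::setcolorder(both, c("locus_id", "sample_role", "length_bp",
                                  "read_count"))
  data.table::fwrite(both, path, sep = "\t")
  invisible(path)
}

#' @rdname tally_io
#' @export
read_tally_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read tally file: ", path)
  dt <- data.table::fread(path, sep = "\t")
  data.table::setnames(dt, c("length_bp", "read_count"), c("length", "count"))
  list(tumor = dt[sample_role == "tumor",
                  .(locus_id, length = as.integer(length),
                    count = as.integer(count))],
       normal = dt[sample_role == "normal",
                   .(locus_id, length = as.integer(length),
                     count = as.integer(count))])
}

#' Write calls TSV
#'
#' @param calls Calls table from [call_sample()].
#' @param path File path.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- data.table::copy(calls)
  out[, significant := as.integer(significant)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
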