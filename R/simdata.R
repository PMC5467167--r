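# Synthetic slippage data: planted-repeat references, stutter-model allele
# tallies, aligned reads (SAM) and labelled MSI-H/MSS cohorts with ground
# truth.

#' Slippage model parameters
#'
#' The generative model for observed intra-read repeat lengths. Each read
#' first draws its template allele: in a tumour read at an unstable locus
#' the somatically shifted allele with probability purity x
#' somatic_fraction, otherwise the germline allele. PCR/sequencing stutter
#' then perturbs the observed length with probability `stutter_rate`; the
#' deviation is a whole number of repeat units, unit_len x (1 + G) bp with
#' G geometric(`stutter_step`), and is a contraction with probability
#' `contraction_bias`. Observed lengths are floored at 5 bp (the intra-read
#' detection limit).
#'
#' @param stutter_rate Probability a read's length deviates from its
#'   template (default 0.05).
#' @param stutter_step Geometric success parameter for the deviation
#'   magnitude in units (default 0.5).
#' @param contraction_bias Probability a stutter deviation is a contraction
#'   (default 0.7; polymerase slippage favours contractions).
#' @param somatic_fraction Fraction of tumour cells carrying the shifted
#'   allele (default 0.5).
#' @param purity Tumour-cell fraction of the tumour sample (default 1).
#' @param depth Mean reads per locus, Poisson (default 40).
#' @return List of class `slippage_model`.
#' @export
slippage_model <- function(stutter_rate = 0.05, stutter_step = 0.5,
                           contraction_bias = 0.7, somatic_fraction = 0.5,
                           purity = 1.0, depth = 40) {
  stopifnot(stutter_rate >= 0, stutter_rate <= 1,
            stutter_step > 0, stutter_step <= 1,
            contraction_bias >= 0, contraction_bias <= 1,
            somatic_fraction >= 0, somatic_fraction <= 1,
            purity >= 0, purity <= 1, depth > 0)
  structure(list(stutter_rate = stutter_rate, stutter_step = stutter_step,
                 contraction_bias = contraction_bias,
                 somatic_fraction = somatic_fraction,
                 purity = purity, depth = depth),
            class = "slippage_model")
}

# Floor observed lengths at the intra-read detection limit (5 bp, and at
# least two full units for unit sizes 2-4) while keeping whole-unit
# slippage steps: a contraction that would fall below the limit stops at
# the smallest detectable length reachable in unit-sized steps.
floor_at_detection <- function(len, unit_len) {
  lim <- pmax(5L, 2L * unit_len)
  below <- len < lim
  if (any(below)) {
    len[below] <- len[below] + unit_len[below] *
      as.integer(ceiling((lim[below] - len[below]) / unit_len[below]))
  }
  len
}

# Observed lengths for n reads from a template allele, with stutter.
stutter_lengths <- function(n, template_len, unit_len, model) {
  if (n == 0L) return(integer(0))
  len <- rep.int(as.integer(template_len), n)
  hit <- stats::runif(n) < model$stutter_rate
  k <- sum(hit)
  if (k > 0) {
    mag <- unit_len * (1L + stats::rgeom(k, model$stutter_step))
    sgn <- ifelse(stats::runif(k) < model$contraction_bias, -1L, 1L)
    len[hit] <- len[hit] + sgn * mag
  }
  floor_at_detection(len, rep.int(as.integer(unit_len), n))
}

#' Simulate an allele-length tally for one locus
#'
#' Draws a Poisson read count at the model depth and applies the template
#' and stutter process of [slippage_model()].
#'
#' @param germline_length Germline tract length(s) in bp (6..60). A single
#'   value gives a homozygous germline; two values give a heterozygous
#'   germline whose alleles each template half the reads (this mode
#'   stresses the mode-based frameshift rule with bimodal normals).
#' @param unit_len Repeat-unit size (1..4).
#' @param model A `slippage_model`.
#' @param role `"tumor"` or `"normal"`.
#' @param somatic_shift Signed shift (bp) of the unstable allele; 0 for a
#'   stable locus. In the heterozygous mode the shift applies to the first
#'   allele.
#' @param seed Optional seed.
#' @return Tally `data.table` (possibly empty when the Poisson draw is 0).
#' @export
simulate_tallies <- function(germline_length, unit_len, model,
                             role = c("normal", "tumor"), somatic_shift = 0L,
                             seed = NULL) {
  role <- match.arg(role)
  stopifnot(length(germline_length) %in% c(1L, 2L),
            all(germline_length >= 6), all(germline_length <= 60))
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, model$depth)
  if (n == 0L) return(tally(integer(0)))
  # template allele per read: heterozygous germlines split reads evenly
  tmpl <- if (length(germline_length) == 2L) {
    germline_length[1L + (stats::runif(n) < 0.5)]
  } else rep.int(germline_length, n)
  if (role == "tumor" && somatic_shift != 0L) {
    p_shift <- model$purity * model$somatic_fraction
    shifted <- stats::runif(n) < p_shift
    tmpl[shifted] <- germline_length[1] + somatic_shift
  }
  lens <- unlist(lapply(unique(tmpl), function(tm) {
    stutter_lengths(sum(tmpl == tm), tm, unit_len, model)
  }))
  tally(lens)
}

random_spacer_pool <- c("A", "C", "G", "T")

# A spacer that contains no microsatellite tract detectable at the 5 bp
# intra-read floor, so planted tracts are the only repeats in the contig.
clean_spacer <- function(len, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    sp <- paste(sample(random_spacer_pool, len, replace = TRUE), collapse = "")
    if (nrow(find_repeats(sp, min_len = 5L)) == 0) return(sp)
  }
  stop("could not generate a repeat-free spacer of length ", len,
       " after ", max_tries, " attempts")
}

#' Simulate a reference contig with planted microsatellites
#'
#' Builds one contig with `n_loci` perfect repeats separated by random
#' spacers that contain no repeat detectable at the 5 bp floor, and returns
#' the FASTA sequence together with a truth catalogue in the reference-
#' catalogue schema. Running [find_repeats()] on the sequence recovers the
#' truth rows exactly.
#'
#' @param n_loci Number of planted loci.
#' @param unit_mix Named probabilities for unit sizes mono/di/tri/tetra
#'   (default 40/20/20/20).
#' @param tract_len_range Range of planted tract lengths in repeat units
#'   beyond the score floor; lengths are unit_len + 6 .. unit_len + 6 +
#'   `tract_len_range` bp (default 0..14).
#' @param spacer_len Range of spacer lengths in bp (default 30..60).
#' @param region_mix Named probabilities over region labels for the truth
#'   catalogue (default coding 0.4, utr3 0.25, utr5 0.1, intronic 0.15,
#'   intergenic 0.1).
#' @param chrom Contig name.
#' @param seed Seed (required for reproducibility).
#' @return List with `fasta` (named character vector) and `catalogue`
#'   (truth `data.table` with region, gene and `germline_length`).
#' @export
simulate_reference <- function(n_loci = 100L,
                               unit_mix = c(mono = 0.4, di = 0.2,
                                            tri = 0.2, tetra = 0.2),
                               tract_len_range = c(0L, 14L),
                               spacer_len = c(30L, 60L),
                               region_mix = c(coding = 0.40, utr3 = 0.25,
                                              utr5 = 0.10, intronic = 0.15,
                                              intergenic = 0.10),
                               chrom = "sim1", seed = 1L) {
  stopifnot(spacer_len[1] >= 10L)
  set.seed(seed)
  unit_sizes <- sample(1:4, n_loci, replace = TRUE,
                       prob = unit_mix / sum(unit_mix))
  regions <- sample(names(region_mix), n_loci, replace = TRUE,
                    prob = region_mix / sum(region_mix))
  pieces <- character(2L * n_loci + 1L)
  rows <- vector("list", n_loci)
  pos <- 0L
  for (i in seq_len(n_loci)) {
    k <- unit_sizes[i]
    # primitive unit, rejection-sampled
    repeat {
      unit <- paste(sample(random_spacer_pool, k, replace = TRUE),
                    collapse = "")
      if (is_primitive_unit(unit)) break
    }
    unit <- canonical_unit(unit)
    extra <- sample(tract_len_range[1]:tract_len_range[2], 1L)
    len <- k + 6L + extra                       # >= score floor of 6
    tract <- substr(strrep(unit, ceiling(len / k) + 1L), 1L, len)
    prev_tract <- if (i > 1L) pieces[2L * (i - 1L)] else ""
    prev_len <- nchar(prev_tract)
    repeat {
      sp <- clean_spacer(sample(spacer_len[1]:spacer_len[2], 1L))
      # validate both junctions: the previous tract must not extend into
      # this spacer, the new tract must not extend into it either, and no
      # new repeat may arise across either junction
      block <- paste0(prev_tract, sp, tract)
      hits <- find_repeats(block, min_len = 5L)
      expected_starts <- c(if (prev_len > 0L) 0L, prev_len + nchar(sp))
      expected_lens <- c(if (prev_len > 0L) prev_len, len)
      ok <- nrow(hits) == length(expected_starts) &&
        identical(hits$start, as.integer(expected_starts)) &&
        identical(hits$length, as.integer(expected_lens))
      if (ok) break
    }
    pieces[2L * i - 1L] <- sp
    pieces[2L * i] <- tract
    pos <- pos + nchar(sp)
    rows[[i]] <- list(chrom = chrom, start = pos, end = pos + len,
                      unit = unit, unit_len = k, length = len,
                      region = regions[i],
                      gene = if (regions[i] %in% c("coding", "utr5", "utr3"))
                               sprintf("GENE%04d", i) else NA_character_)
    pos <- pos + len
  }
  repeat {
    tail_sp <- clean_spacer(sample(spacer_len[1]:spacer_len[2], 1L))
    last_tract <- pieces[2L * n_loci]
    hits <- find_repeats(paste0(last_tract, tail_sp), min_len = 5L)
    if (nrow(hits) == 1L && hits$start[1] == 0L &&
        hits$length[1] == nchar(last_tract)) break
  }
  pieces[2L * n_loci + 1L] <- tail_sp
  contig <- paste(pieces, collapse = "")
  truth <- data.table::rbindlist(rows)
  truth[, locus_id := locus_id(chrom, start, end, unit)]
  data.table::setcolorder(truth, c("chrom", "start", "end", "locus_id",
                                   "unit", "unit_len", "length", "region",
                                   "gene"))
  # verify: the scan sees exactly the planted tracts (junction effects can
  # in principle merge or extend tracts; regenerate-on-failure keeps this
  # deterministic given the seed)
  seen <- find_repeats(contig, min_len = 5L, chrom = chrom)
  if (!identical(seen[, .(start, end, unit)],
                 truth[, .(start, end, unit)])) {
    stop("planted-repeat validation failed; adjust spacer constraints")
  }
  fasta <- stats::setNames(contig, chrom)
  list(fasta = fasta, catalogue = truth[])
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Simulate aligned reads realising a set of tallies
#'
#' Emits single-end, perfectly aligned 100 bp reads whose sequences contain
#' each locus tract at the tallied length with the correct 2 bp reference
#' flanks, as a SAM file. [tally_sample()] on the output reproduces the
#' input tallies exactly.
#'
#' @param tallies `data.table` with columns `locus_id`, `length`, `count`.
#' @param reference Named character vector of contig sequences (or FASTA
#'   path).
#' @param catalogue Reference catalogue describing the loci.
#' @param out Output SAM path.
#' @param read_length Read length in bp (default 100).
#' @param seed Seed for read placement.
#' @param sample_name Read-name prefix.
#' @return The SAM path, invisibly.
#' @export
simulate_reads <- function(tallies, reference, catalogue, out,
                           read_length = 100L, seed = 1L,
                           sample_name = "sim") {
  seqs <- read_fasta_seqs(reference)
  set.seed(seed)
  tl <- data.table::as.data.table(tallies)
  cat_idx <- match(tl$locus_id, catalogue$locus_id)
  if (any(is.na(cat_idx))) {
    stop("tally loci absent from catalogue: ",
         paste(tl$locus_id[is.na(cat_idx)], collapse = ", "))
  }
  bad <- tl$length + 4L > read_length
  if (any(bad)) {
    stop("tract plus flanks exceeds the read length at ",
         paste(unique(tl$locus_id[bad]), collapse = ", "))
  }
  # Per-locus read context: the locus's own flanking spacers from the
  # reference, extended outwards with repeat-free filler so that a read
  # window never carries a neighbouring locus's tract (each read must tally
  # at exactly one locus for the round-trip identity to hold).
  ctx <- vector("list", nrow(catalogue))
  ctx_for <- function(ci) {
    if (!is.null(ctx[[ci]])) return(ctx[[ci]])
    cm <- catalogue$chrom[ci]
    st <- catalogue$start[ci]; en <- catalogue$end[ci]
    refseq <- seqs[[cm]]
    same <- which(catalogue$chrom == cm)
    prev_end <- max(c(0L, catalogue$end[same][catalogue$end[same] <= st]))
    next_start <- min(c(nchar(refseq),
                        catalogue$start[same][catalogue$start[same] >= en]))
    ref_left <- substr(refseq, prev_end + 1L, st)       # clean spacer + flank5
    ref_right <- substr(refseq, en + 1L, next_start)    # flank3 + clean spacer
    ref_tract <- substr(refseq, st + 1L, en)
    pad_l <- max(0L, read_length - nchar(ref_left))
    pad_r <- max(0L, read_length - nchar(ref_right))
    repeat {
      fill_l <- if (pad_l > 0L) clean_spacer(pad_l) else ""
      fill_r <- if (pad_r > 0L) clean_spacer(pad_r) else ""
      left_ctx <- paste0(fill_l, ref_left)
      right_ctx <- paste0(ref_right, fill_r)
      probe <- paste0(left_ctx, ref_tract, right_ctx)
      hits <- find_repeats(probe, min_len = 5L)
      if (nrow(hits) == 1L && hits$start[1] == nchar(left_ctx) &&
          hits$length[1] == nchar(ref_tract)) break
    }
    ctx[[ci]] <<- list(left = left_ctx, right = right_ctx)
    ctx[[ci]]
  }
  recs <- character(sum(tl$count))
  rid <- 0L
  for (i in seq_len(nrow(tl))) {
    ci <- cat_idx[i]
    cm <- catalogue$chrom[ci]
    st <- catalogue$start[ci]; en <- catalogue$end[ci]
    unit <- catalogue$unit[ci]
    ref_len <- en - st
    L <- tl$length[i]
    cx <- ctx_for(ci)
    # observed tract keeps the reference phase of the unit
    ref_tract_start_unit <- substr(seqs[[cm]], st + 1L, st + nchar(unit))
    tract <- substr(strrep(ref_tract_start_unit, ceiling(L / nchar(unit)) + 1L),
                    1L, L)
    # read start offset: 2 bp flank5 must be in-read, the reference span
    # [st-2, en+2) must be covered, and 2 bp flank3 must fit after the tract
    left_max <- min(read_length - 2L - ref_len,
                    read_length - 2L - L,
                    nchar(cx$left))
    for (r in seq_len(tl$count[i])) {
      left <- if (left_max > 2L) sample(2L:left_max, 1L) else 2L
      a <- max(0L, st - left)                          # 0-based read start
      left_part <- substr(cx$left, nchar(cx$left) - left + 1L, nchar(cx$left))
      right_needed <- read_length - left - L
      right_part <- substr(cx$right, 1L, right_needed)
      readseq <- paste0(left_part, tract, right_part)
      rid <- rid + 1L
      recs[rid] <- paste(
        sprintf("%s_r%06d", sample_name, rid), 0L, cm, a + 1L, 60L,
        paste0(nchar(readseq), "M"), "*", 0L, 0L, readseq,
        strrep("I", nchar(readseq)), sep = "\t")
    }
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              vapply(names(seqs), function(cm) {
                sprintf("@SQ\tSN:%s\tLN:%d", cm, nchar(seqs[[cm]]))
              }, character(1)))
  # coordinate-sort the records
  if (length(recs) > 0) {
    fields <- data.table::tstrsplit(recs, "\t", fixed = TRUE)
    ord <- order(unlist(fields[[3]]), as.integer(unlist(fields[[4]])))
    recs <- recs[ord]
  }
  writeLines(c(header, recs), out)
  invisible(out)
}

#' Cohort specification for the synthetic MSI study
#'
#' @param n_samples Number of tumour/normal pairs (default 800).
#' @param msih_fraction Fraction of MSI-H samples (default 0.25); label
#'   counts are deterministic (rounded).
#' @param n_loci Catalogue size (default 600).
#' @param unstable_loci_per_msih Mean planted unstable loci per MSI-H
#'   sample, Poisson (default 120).
#' @param unstable_loci_per_mss Mean per MSS sample (default 2).
#' @param tumour_types Tumour-type labels cycled over samples.
#' @param seed Master seed; per-sample seeds are derived deterministically.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 800L, msih_fraction = 0.25,
                        n_loci = 600L, unstable_loci_per_msih = 120,
                        unstable_loci_per_mss = 2,
                        tumour_types = c("COAD", "STAD", "UCEC"),
                        seed = 1L) {
  stopifnot(msih_fraction >= 0, msih_fraction <= 1,
            unstable_loci_per_msih <= n_loci)
  structure(list(n_samples = as.integer(n_samples),
                 msih_fraction = msih_fraction, n_loci = as.integer(n_loci),
                 unstable_loci_per_msih = unstable_loci_per_msih,
                 unstable_loci_per_mss = unstable_loci_per_mss,
                 tumour_types = tumour_types, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate tumour and normal tallies for every locus of one sample
#'
#' Vectorised tally simulation across a whole catalogue: Poisson read
#' counts at the model depth, somatic-template assignment at the unstable
#' loci, and whole-unit stutter, for both the tumour and the matched
#' normal of one sample.
#'
#' @param catalogue Reference catalogue; its `length` column supplies the
#'   germline allele lengths.
#' @param unstable_ids Locus ids carrying a somatic shift in this sample.
#' @param shifts Signed bp shifts parallel to `unstable_ids`.
#' @param model A `slippage_model`.
#' @return `data.table` with columns `locus_id`, `length`, `count`,
#'   `role` (`"tumor"`/`"normal"`).
#' @export
simulate_pair_tallies <- function(catalogue, unstable_ids, shifts, model) {
  n_loci <- nrow(catalogue)
  out <- list()
  for (role in c("normal", "tumor")) {
    n <- stats::rpois(n_loci, model$depth)
    shift_vec <- integer(n_loci)
    if (role == "tumor" && length(unstable_ids) > 0) {
      idx <- match(unstable_ids, catalogue$locus_id)
      shift_vec[idx] <- shifts
    }
    n_shifted <- integer(n_loci)
    has_shift <- shift_vec != 0L & n > 0L
    n_shifted[has_shift] <- stats::rbinom(sum(has_shift), n[has_shift],
                                          model$purity * model$somatic_fraction)
    # template lengths per read, expanded
    tmpl_g <- rep.int(catalogue$length, n - n_shifted)
    tmpl_s <- rep.int(catalogue$length + shift_vec, n_shifted)
    ulen_g <- rep.int(catalogue$unit_len, n - n_shifted)
    ulen_s <- rep.int(catalogue$unit_len, n_shifted)
    lid_g <- rep.int(catalogue$locus_id, n - n_shifted)
    lid_s <- rep.int(catalogue$locus_id, n_shifted)
    tmpl <- c(tmpl_g, tmpl_s); ulen <- c(ulen_g, ulen_s)
    lid <- c(lid_g, lid_s)
    m <- length(tmpl)
    obs <- tmpl
    hit <- stats::runif(m) < model$stutter_rate
    kk <- sum(hit)
    if (kk > 0) {
      mag <- ulen[hit] * (1L + stats::rgeom(kk, model$stutter_step))
      sgn <- ifelse(stats::runif(kk) < model$contraction_bias, -1L, 1L)
      obs[hit] <- obs[hit] + sgn * mag
    }
    obs <- floor_at_detection(obs, ulen)
    dt <- data.table::data.table(locus_id = lid, length = obs)
    dt <- dt[, .(count = .N), by = .(locus_id, length)]
    dt[, role := role]
    out[[role]] <- dt
  }
  data.table::rbindlist(out)
}

#' Simulate a labelled MSI cohort with known ground truth
#'
#' Assigns each sample an MSI label (deterministic rounded counts) and a
#' planted set of unstable loci (Poisson means per label), simulates
#' tumour/normal allele-length tallies per locus under the slippage model,
#' and optionally runs the caller to emit per-sample calls. Per-sample
#' seeds are derived deterministically from the master seed.
#'
#' @param spec A `cohort_spec`.
#' @param model A `slippage_model` (defaults used when `NULL`).
#' @param reference Optional list from [simulate_reference()]; generated
#'   with `spec$n_loci` planted loci when `NULL`.
#' @param output `"tallies"` (default) or `"calls"` (runs [call_sample()]
#'   per sample).
#' @param somatic_shift_units Magnitude of the planted shift in repeat
#'   units (default 1; the shift is a contraction of
#'   `somatic_shift_units * unit_len` bp, which is a frameshift for
#'   mono/di/tetra units at 1 unit).
#' @return List with `catalogue`, `metadata`, `truth` (sample_id, locus_id,
#'   shift), and `tallies` (long `data.table`) or `calls` (named list).
#' @export
simulate_cohort <- function(spec, model = NULL, reference = NULL,
                            output = c("tallies", "calls"),
                            somatic_shift_units = 1L) {
  output <- match.arg(output)
  if (is.null(model)) model <- slippage_model()
  if (is.null(reference)) {
    reference <- simulate_reference(n_loci = spec$n_loci, seed = spec$seed)
  }
  catalogue <- reference$catalogue
  n <- spec$n_samples
  n_msih <- round(spec$msih_fraction * n)
  labels <- c(rep("MSI-H", n_msih), rep("MSS", n - n_msih))
  meta <- data.table::data.table(
    sample_id = sprintf("S%04d", seq_len(n)),
    tumour_type = rep_len(spec$tumour_types, n),
    msi_label = labels)
  set.seed(spec$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  tallies <- vector("list", n)
  truth <- vector("list", n)
  calls <- if (output == "calls") vector("list", n) else NULL
  for (i in seq_len(n)) {
    set.seed(sample_seeds[i])
    mu <- if (labels[i] == "MSI-H") spec$unstable_loci_per_msih
          else spec$unstable_loci_per_mss
    k <- min(stats::rpois(1L, mu), spec$n_loci)
    unstable <- if (k > 0) sample(catalogue$locus_id, k) else character(0)
    shifts <- -somatic_shift_units *
      catalogue$unit_len[match(unstable, catalogue$locus_id)]
    tl <- simulate_pair_tallies(catalogue, unstable, shifts, model)
    truth[[i]] <- data.table::data.table(sample_id = meta$sample_id[i],
                                         locus_id = unstable,
                                         shift = as.integer(shifts))
    if (output == "calls") {
      calls[[i]] <- call_sample(tl[role == "tumor",
                                   .(locus_id, length, count)],
                                tl[role == "normal",
                                   .(locus_id, length, count)],
                                catalogue)
    } else {
      tl[, sample_id := meta$sample_id[i]]
      tallies[[i]] <- tl
    }
  }
  res <- list(catalogue = catalogue, metadata = meta,
              truth = data.table::rbindlist(truth),
              reference = reference$fasta)
  if (output == "calls") {
    names(calls) <- meta$sample_id
    res$calls <- calls
  } else {
    res$tallies <- data.table::rbindlist(tallies)
  }
  res
}
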