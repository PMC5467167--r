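# Reference microsatellite cataloguing: perfect tandem-repeat detection,
# region annotation and catalogue construction.

#' Canonical form of a repeat unit
#'
#' The canonical unit is the lexicographically smallest rotation of the
#' observed unit on the forward strand. Strand is not tracked: repeat content
#' is strand-symmetric for the purposes of slippage calling.
#'
#' @param unit Character vector of repeat units (1-4 nt each).
#' @return Character vector of canonical units.
#' @examples
#' canonical_unit(c("CA", "GAT"))  # "AC", "ATG"
#' @export
canonical_unit <- function(unit) {
  vapply(unit, function(u) {
    k <- nchar(u)
    if (k == 1L) return(u)
    rots <- vapply(seq_len(k), function(i) {
      paste0(substr(u, i, k), substr(u, 1, i - 1L))
    }, character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

# A unit is primitive when it is not itself a repetition of a shorter unit.
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L && unit == strrep(substr(unit, 1, p), k / p)) return(FALSE)
  }
  TRUE
}

locus_id <- function(chrom, start, end, unit) {
  paste0(chrom, ":", start, "-", end, ":", unit)
}

#' Find maximal perfect microsatellite tracts in a DNA sequence
#'
#' Scans a sequence for maximal perfect tandem repeats of primitive units of
#' 1 to `max_unit` nucleotides. A tract is reported exactly once, at its
#' minimal period, so a run of A's is a mononucleotide tract and never a
#' dinucleotide one. Tracts containing N are never reported, and tracts
#' longer than `max_len` are excluded entirely rather than truncated.
#'
#' Two reporting modes are available:
#' * the plain length floor (default): tract length must be at least
#'   `min_len` bp (and at least two full units for unit sizes 2-4);
#' * the score floor (`min_score` set): the tract must contain at least
#'   `min_score` positions matching the position one unit earlier, i.e.
#'   tract length >= unit length + `min_score`. On perfect tracts this is
#'   the Sputnik match score, and `min_score = 6` is the calibration used
#'   for the reference catalogues (see the methods vignette).
#'
#' @param sequence A single DNA string over A, C, G, T, N (case-insensitive).
#' @param min_len Minimum tract length in bp (default 6; the intra-read scan
#'   used during allele extraction lowers this to 5).
#' @param max_len Maximum tract length in bp (default 60).
#' @param max_unit Maximum repeat-unit size in nt (default 4).
#' @param min_score Optional minimum number of matched positions beyond the
#'   first unit. When non-`NULL` it replaces the `min_len` floor.
#' @param chrom Sequence name used for coordinates and locus ids.
#' @return A `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `locus_id`, `unit` (canonical), `unit_len`, `length`,
#'   `region` (`NA`), `gene` (`NA`), sorted by `start`.
#' @examples
#' find_repeats("GGAAAAAAGG")          # one A tract, start 2, end 8
#' find_repeats("TTACACACACTT")        # one AC tract of 8 bp
#' @export
find_repeats <- function(sequence, min_len = 6L, max_len = 60L, max_unit = 4L,
                         min_score = NULL, chrom = "seq") {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (min_len < 5L) stop("min_len must be >= 5")
  if (max_unit < 1L || max_unit > 4L) stop("max_unit must be in 1..4")
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bad <- !chars %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    stop("non-DNA characters in sequence: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  isN <- chars == "N"
  out <- vector("list", 64L)
  n_out <- 0L
  for (k in seq_len(max_unit)) {
    if (n < k + 1L) break
    m <- chars[seq_len(n - k)] == chars[(k + 1L):n]
    # positions involving N never match
    if (any(isN)) {
      m[isN[seq_len(n - k)] | isN[(k + 1L):n]] <- FALSE
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      st <- starts[j]                      # 1-based tract start
      len <- r$lengths[j] + k              # tract length in bp
      if (len > max_len) next
      if (is.null(min_score)) {
        if (len < min_len) next
      } else {
        if (len - k < min_score) next
      }
      if (k >= 2L && len < 2L * k) next
      # minimal period must be k (also implies the unit is primitive)
      if (k > 1L) {
        minper <- k
        for (p in seq_len(k - 1L)) {
          idx <- st:(st + len - 1L - p)
          if (all(chars[idx] == chars[idx + p])) { minper <- p; break }
        }
        if (minper < k) next
      }
      unit <- paste(chars[st:(st + k - 1L)], collapse = "")
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- list(start = st - 1L, end = st + len - 1L,
                           unit = unit, unit_len = k, length = len)
    }
  }
  if (n_out == 0L) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      locus_id = character(), unit = character(), unit_len = integer(),
      length = integer(), region = character(), gene = character()))
  }
  dt <- data.table::rbindlist(out[seq_len(n_out)])
  dt[, `:=`(chrom = chrom, unit = canonical_unit(unit),
            region = NA_character_, gene = NA_character_)]
  dt[, locus_id := locus_id(chrom, start, end, unit)]
  data.table::setcolorder(dt, c("chrom", "start", "end", "locus_id", "unit",
                                "unit_len", "length", "region", "gene"))
  data.table::setorder(dt, start, unit_len)
  dt[]
}

#' Annotate repeat loci with genomic region classes
#'
#' Assigns each locus exactly one region label with precedence
#' coding > utr5 > utr3 > intronic > intergenic when it overlaps several
#' annotation intervals, attaches a gene id where the locus overlaps a gene
#' (ties broken by the lexicographically first gene id), and removes any
#' locus straddling an internal exon boundary (splice site), because such
#' loci have undetermined genomic coordinates across isoforms.
#'
#' @param loci Catalogue `data.table` from [find_repeats()].
#' @param annotation `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open, same assembly as `loci`), `region` (one of coding,
#'   utr5, utr3, intronic, intergenic) and `gene`.
#' @param exon_boundaries Optional `data.frame` with columns `chrom`, `pos`
#'   giving internal exon boundary coordinates; a locus with
#'   `start < pos < end` is removed.
#' @return Annotated catalogue; loci overlapping no annotation get
#'   `region = "intergenic"`.
#' @export
annotate_regions <- function(loci, annotation, exon_boundaries = NULL) {
  loci <- data.table::as.data.table(loci)
  ann <- data.table::as.data.table(annotation)
  if (nrow(ann) > 0 && any(ann$end <= ann$start)) {
    stop("annotation intervals must satisfy start < end (0-based half-open)")
  }
  region_rank <- c(coding = 1L, utr5 = 2L, utr3 = 3L,
                   intronic = 4L, intergenic = 5L)
  if (nrow(ann) > 0 && !all(ann$region %in% names(region_rank))) {
    stop("unknown region label(s): ",
         paste(setdiff(unique(ann$region), names(region_rank)), collapse = ", "))
  }
  loci[, region := "intergenic"]
  loci[, gene := NA_character_]
  if (nrow(ann) > 0 && nrow(loci) > 0 &&
      length(intersect(unique(loci$chrom), unique(ann$chrom))) > 0) {
    lv <- unique(c(loci$chrom, ann$chrom))
    lr <- GenomicRanges::GRanges(factor(loci$chrom, lv),
                                 IRanges::IRanges(loci$start + 1L, loci$end))
    ar <- GenomicRanges::GRanges(factor(ann$chrom, lv),
                                 IRanges::IRanges(ann$start + 1L, ann$end))
    hits <- GenomicRanges::findOverlaps(lr, ar)
    if (length(hits) > 0) {
      h <- data.table::data.table(
        i = S4Vectors::queryHits(hits),
        region = ann$region[S4Vectors::subjectHits(hits)],
        gene = ann$gene[S4Vectors::subjectHits(hits)])
      h[, rank := region_rank[region]]
      data.table::setorder(h, i, rank, gene, na.last = TRUE)
      best <- h[, .(region = region[1L], gene = gene[1L]), by = i]
      loci[best$i, `:=`(region = best$region, gene = best$gene)]
    }
  }
  if (!is.null(exon_boundaries) && nrow(loci) > 0) {
    eb <- data.table::as.data.table(exon_boundaries)
    if (nrow(eb) > 0) {
      drop <- logical(nrow(loci))
      for (cm in unique(eb$chrom)) {
        pos <- eb$pos[eb$chrom == cm]
        sel <- which(loci$chrom == cm)
        if (length(sel) == 0) next
        drop[sel] <- vapply(sel, function(i) {
          any(pos > loci$start[i] & pos < loci$end[i])
        }, logical(1))
      }
      loci <- loci[!drop]
    }
  }
  loci[]
}

# Resolve overlapping tracts so that no two catalogue rows overlap:
# keep the longer tract; ties broken by smaller start, then unit.
resolve_overlaps <- function(loci) {
  if (nrow(loci) <= 1L) return(loci)
  dt <- data.table::copy(loci)
  data.table::setorder(dt, chrom, -length, start, unit)
  keep <- rep(TRUE, nrow(dt))
  by_chrom <- split(seq_len(nrow(dt)), dt$chrom)
  for (idx in by_chrom) {
    taken_start <- integer(0); taken_end <- integer(0)
    for (i in idx) {
      s <- dt$start[i]; e <- dt$end[i]
      if (length(taken_start) && any(s < taken_end & e > taken_start)) {
        keep[i] <- FALSE
      } else {
        taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
      }
    }
  }
  dt <- dt[keep]
  data.table::setorder(dt, chrom, start)
  dt
}

is_mito_contig <- function(chrom) {
  grepl("^(chr)?M(T)?$", chrom, ignore.case = TRUE) |
    grepl("mitochondrion|^NC_001807", chrom, ignore.case = TRUE)
}

#' Build a reference microsatellite catalogue from sequence
#'
#' Scans every contig of a FASTA file (or a named character vector of
#' sequences) for microsatellite tracts, annotates regions, removes
#' splice-site-straddling loci, collapses duplicates discovered on
#' overlapping isoforms, resolves overlapping tracts and writes a sorted
#' BED-like TSV catalogue.
#'
#' The default `min_score = 6` is the score floor calibrated on the human
#' mitochondrial catalogue (31 loci: 10 mono-, 2 di-, 11 tri- and 8
#' tetranucleotides); pass `min_score = NULL` to use the plain `min_len`
#' floor instead.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param annotation Optional annotation table (see [annotate_regions()]) or
#'   path to a 5-column TSV (chrom, start, end, region, gene). When absent,
#'   loci are labelled `intergenic`, or `mito` on mitochondrial contigs.
#' @param exon_boundaries Optional splice-site table (see
#'   [annotate_regions()]).
#' @param out Optional output TSV path.
#' @inheritParams find_repeats
#' @return The catalogue `data.table` (invisibly when `out` is given), with
#'   a `summary` attribute holding counts by unit length and region.
#' @export
build_reference <- function(fasta, annotation = NULL, exon_boundaries = NULL,
                            out = NULL, min_len = 6L, max_len = 60L,
                            max_unit = 4L, min_score = 6L) {
  seqs <- read_fasta_seqs(fasta)
  if (is.character(annotation) && length(annotation) == 1L) {
    if (!file.exists(annotation)) stop("cannot read annotation file: ", annotation)
    annotation <- data.table::fread(annotation, header = TRUE)
  }
  loci <- data.table::rbindlist(lapply(names(seqs), function(cm) {
    find_repeats(seqs[[cm]], min_len = min_len, max_len = max_len,
                 max_unit = max_unit, min_score = min_score, chrom = cm)
  }))
  if (nrow(loci) > 0) {
    if (!is.null(annotation)) {
      loci <- annotate_regions(loci, annotation, exon_boundaries)
    } else {
      loci[, region := "intergenic"]
    }
    loci[is_mito_contig(chrom), region := "mito"]
    loci <- unique(loci, by = "locus_id")
    loci <- resolve_overlaps(loci)
    data.table::setorder(loci, chrom, start)
  }
  summ <- list(by_unit = table(factor(loci$unit_len, levels = 1:4)),
               by_region = table(loci$region))
  data.table::setattr(loci, "summary", summ)
  if (!is.null(out)) {
    write_catalogue(loci, out)
    message(sprintf("catalogue: %d loci (%s by unit length; %s)",
                    nrow(loci),
                    paste(summ$by_unit, collapse = "/"),
                    paste(names(summ$by_region), summ$by_region,
                          sep = "=", collapse = ", ")))
    return(invisible(loci))
  }
  loci
}

read_fasta_seqs <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    x <- Biostrings::readDNAStringSet(fasta)
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    return(seqs)
  }
  if (is.character(fasta) && !is.null(names(fasta))) return(fasta)
  stop("fasta must be a readable FASTA path or a named character vector; got: ",
       if (is.character(fasta)) fasta[1] else class(fasta)[1])
}

#' Write / read a catalogue TSV
#'
#' The catalogue is tab-separated with one `#`-prefixed header line and
#' columns chrom, start, end, locus_id, unit, unit_len, length, region,
#' gene, sorted by (chrom, start).
#'
#' @param catalogue Catalogue `data.table`.
#' @param path Output/input file path.
#' @rdname catalogue_io
#' @export
write_catalogue <- function(catalogue, path) {
  cols <- c("chrom", "start", "end", "locus_id", "unit", "unit_len",
            "length", "region", "gene")
  header <- paste0("#", paste(cols, collapse = "\t"))
  lines <- do.call(paste, c(lapply(cols, function(cn) {
    v <- catalogue[[cn]]
    ifelse(is.na(v), ".", as.character(v))
  }), sep = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname catalogue_io
#' @export
read_catalogue <- function(path) {
  if (!file.exists(path)) stop("cannot read catalogue file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, skip = 1L,
                          col.names = c("chrom", "start", "end", "locus_id",
                                        "unit", "unit_len", "length",
                                        "region", "gene"),
                          na.strings = ".")
  dt[, `:=`(start = as.integer(start), end = as.integer(end),
            unit_len = as.integer(unit_len), length = as.integer(length))]
  if (nrow(dt) > 0 && any(dt$end <= dt$start)) {
    stop("mis-sorted or malformed catalogue (end <= start): ", path)
  }
  dt
}

#' The hg19 mitochondrial reference sequence
#'
#' Reads the human mitochondrial genome NC_001807.4 (the sequence used as
#' chrM in the hg19 assembly, 16,571 bp) from the copy distributed with the
#' seqinr package.
#'
#' @return A single upper-case DNA string named `chrM`.
#' @export
hg19_chrM <- function() {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stop("the seqinr package is required for hg19_chrM()")
  }
  f <- system.file("sequences/humanMito.fasta", package = "seqinr")
  fa <- seqinr::read.fasta(f, seqtype = "DNA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  s <- toupper(fa[[1]])
  if (nchar(s) != 16571L) stop("unexpected mitochondrial sequence length")
  c(chrM = s)
}
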