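#' Genomic interval tables
#'
#' All located features in the package are plain data frames carrying at least
#' `chrom`, `start`, `end` (and optionally `strand`).  Coordinates are 0-based
#' half-open throughout: a feature occupies bases `start .. end - 1`, so
#' `end - start` is its length.  RepeatMasker `.out` input (1-based inclusive)
#' is converted on read; BED passes through unchanged.
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors, `0 <= start < end`
#' @param strand one of `"+"`, `"-"`, `"."` per feature
#' @return a data frame with columns `chrom`, `start`, `end`, `strand`
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) || any(start >= end))
    stop("invalid interval: require 0 <= start < end")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(strand, length(chrom)),
             stringsAsFactors = FALSE)
}

# Convert an interval data frame (0-based half-open) to GRanges (1-based closed).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Pairwise interval overlap
#'
#' Two intervals overlap iff they share at least one base: same chromosome and
#' `max(start) < min(end)` under the half-open convention.  Vectorised over
#' rows; the shorter argument is recycled.
#'
#' @param a,b interval data frames (`chrom`, `start`, `end`)
#' @return logical vector
#' @export
interval_overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ia] == b$chrom[ib] &
    pmax(a$start[ia], b$start[ib]) < pmin(a$end[ia], b$end[ib])
}

#' Construct peak records with fixed-width analysis windows
#'
#' Each peak gets a `window_size` bp window centered on the geometric midpoint
#' of its interval: `mid = floor((start + end) / 2)`, window
#' `[mid - window_size/2, mid + window_size/2)`.  Windows running past a
#' chromosome end (when `genome` is supplied) are clipped and flagged via the
#' `clipped` column; flagged peaks are excluded from sequence-scanning stages
#' but kept for interval arithmetic.
#'
#' @param intervals interval data frame
#' @param id peak identifiers; auto-assigned `peak_0001`, ... when `NULL`
#' @param window_size analysis window width in bp (default 200)
#' @param genome optional [genome_model()] used to clip windows
#' @return data frame with columns `id`, `chrom`, `start`, `end`,
#'   `win_start`, `win_end`, `clipped`
#' @export
make_peaks <- function(intervals, id = NULL, window_size = 200L, genome = NULL) {
  n <- nrow(intervals)
  if (is.null(id)) id <- sprintf("peak_%04d", seq_len(n))
  half <- window_size %/% 2L
  mid <- (intervals$start + intervals$end) %/% 2L
  ws <- mid - half
  we <- ws + as.integer(window_size)
  clipped <- rep(FALSE, n)
  cs <- pmax(ws, 0L)
  ce <- we
  if (!is.null(genome)) {
    len <- unname(genome$chrom_lengths[intervals$chrom])
    if (anyNA(len)) stop("peak chromosome absent from genome model")
    ce <- pmin(we, len)
  }
  clipped <- cs != ws | ce != we
  data.frame(id = as.character(id), chrom = intervals$chrom,
             start = intervals$start, end = intervals$end,
             win_start = cs, win_end = ce, clipped = clipped,
             stringsAsFactors = FALSE)
}

peak_windows <- function(peaks) {
  data.frame(chrom = peaks$chrom, start = peaks$win_start,
             end = peaks$win_end, stringsAsFactors = FALSE)
}

#' Read a ChIP-seq peak table
#'
#' Accepts BED (no header, optional `track`/`#` lines) or TSV exports with a
#' header naming at least `chrom`, `start`, `end`.  Rows with malformed
#' coordinates (`start >= end` or non-numeric) are rejected and counted in the
#' parse report attached as `attr(x, "report")`.
#'
#' @param path input file
#' @param dialect `"bed"` or `"tsv"`
#' @inheritParams make_peaks
#' @return peak data frame as from [make_peaks()]
#' @export
read_peaks <- function(path, dialect = c("bed", "tsv"), window_size = 200L,
                       genome = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (dialect == "tsv") {
    if (length(lines) < 1L) stop("empty peak file: ", path)
    hdr <- tolower(strsplit(lines[1L], "\t")[[1L]])
    ci <- match(c("chrom", "start", "end"), hdr)
    if (anyNA(ci)) stop("tsv dialect requires a header naming chrom/start/end")
    lines <- lines[-1L]
    fields <- strsplit(lines, "\t")
  } else {
    ci <- 1:3
    fields <- strsplit(lines, "[ \t]+")
  }
  if (length(fields) == 0L) stop("empty peak file: ", path)
  n_skipped <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    s <- suppressWarnings(as.integer(f[ci[2L]]))
    e <- suppressWarnings(as.integer(f[ci[3L]]))
    if (is.na(s) || is.na(e) || s < 0L || s >= e) {
      n_skipped <- n_skipped + 1L
      next
    }
    id <- if (dialect == "bed" && length(f) >= 4L) f[4L] else NA_character_
    rows[[i]] <- data.frame(chrom = f[ci[1L]], start = s, end = e, id = id,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no valid peak rows in ", path)
  df <- do.call(rbind, rows)
  ids <- if (all(is.na(df$id))) NULL else df$id
  pk <- make_peaks(df[c("chrom", "start", "end")], id = ids,
                   window_size = window_size, genome = genome)
  attr(pk, "report") <- list(rows_read = length(fields), rows_kept = nrow(pk),
                             rows_skipped = n_skipped)
  pk
}

#' Read a repeat annotation
#'
#' `rm_out` parses the standard RepeatMasker `.out` layout (3 header lines,
#' whitespace-separated; query begin/end in columns 6-7, repeat name in 10,
#' class/family in 11) and converts 1-based inclusive coordinates to the
#' internal 0-based half-open convention.  `bed_name_class` expects
#' chrom/start/end/name/class (optionally strand) already 0-based.
#'
#' @param path input file
#' @param dialect `"rm_out"` or `"bed_name_class"`
#' @return data frame with columns `instance_id`, `chrom`, `start`, `end`,
#'   `strand`, `name`, `te_class`
#' @export
read_repeatmasker <- function(path, dialect = c("rm_out", "bed_name_class")) {
  dialect <- match.arg(dialect)
  if (dialect == "rm_out") {
    lines <- readLines(path)
    if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no repeat rows in ", path)
    fields <- strsplit(trimws(lines), "[ \t]+")
    chrom <- vapply(fields, `[`, "", 5L)
    begin <- as.integer(vapply(fields, `[`, "", 6L))
    end <- as.integer(vapply(fields, `[`, "", 7L))
    strand <- vapply(fields, `[`, "", 9L)
    strand <- ifelse(strand == "C", "-", "+")
    name <- vapply(fields, `[`, "", 10L)
    te_class <- vapply(fields, `[`, "", 11L)
    start <- begin - 1L # 1-based inclusive -> 0-based half-open
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 5L) stop("bed_name_class dialect requires 5 columns (class column missing?)")
    chrom <- df[[1L]]; start <- as.integer(df[[2L]]); end <- as.integer(df[[3L]])
    name <- df[[4L]]; te_class <- df[[5L]]
    strand <- if (ncol(df) >= 6L) df[[6L]] else "."
  }
  if (any(!nzchar(name)) || any(!nzchar(te_class)))
    stop("repeat name and class must be non-empty")
  data.frame(instance_id = sprintf("te_%06d", seq_along(chrom)),
             chrom = chrom, start = start, end = end,
             strand = rep_len(strand, length(chrom)),
             name = name, te_class = te_class, stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' BED3 plus optional name (and class as column 5 when `te_class` is present),
#' preserving the 0-based half-open coordinates unchanged.
#' @param df interval data frame; optional `id`/`name`/`te_class` columns
#' @param path output file
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  nm <- if (!is.null(df$name)) df$name else df$id
  if (!is.null(nm)) cols <- c(cols, list(nm))
  if (!is.null(df$te_class)) cols <- c(cols, list(df$te_class))
  out <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED3/BED5 as plain intervals
#' @export
#' @rdname write_bed
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(chrom = df[[1L]], start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- df[[4L]]
  if (ncol(df) >= 5L) out$te_class <- df[[5L]]
  out
}

#' Partition two peak sets by window overlap
#'
#' A peak of A belongs to the intersection iff its analysis window overlaps at
#' least one window of B (and symmetrically for B).  Because one window can
#' overlap several on the other side, the two intersection counts need not
#' coincide; both are reported.
#'
#' @param a,b peak data frames from [make_peaks()]
#' @return list with subsets `a_in_b`, `a_only`, `b_in_a`, `b_only` and a
#'   `counts` summary
#' @export
partition_peaksets <- function(a, b) {
  gra <- as_granges0(peak_windows(a))
  grb <- as_granges0(peak_windows(b))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  ia <- unique(S4Vectors::queryHits(hits))
  ib <- unique(S4Vectors::subjectHits(hits))
  in_a <- seq_len(nrow(a)) %in% ia
  in_b <- seq_len(nrow(b)) %in% ib
  list(
    a_in_b = a[in_a, , drop = FALSE],
    a_only = a[!in_a, , drop = FALSE],
    b_in_a = b[in_b, , drop = FALSE],
    b_only = b[!in_b, , drop = FALSE],
    counts = c(n_a = nrow(a), n_b = nrow(b),
               a_and_b_from_a = sum(in_a), a_and_b_from_b = sum(in_b),
               a_only = sum(!in_a), b_only = sum(!in_b))
  )
}

#' Genome model
#'
#' Chromosome lengths, optional sequences, and a background nucleotide
#' distribution.  The background is the empirical composition of the supplied
#' sequences, symmetrised across strands (A with T, C with G averaged), which
#' is what both PWM scoring and threshold calibration use.
#'
#' @param chrom_lengths named integer vector of chromosome sizes (bp)
#' @param sequences optional named character vector of chromosome sequences
#' @param background optional length-4 named vector (A,C,G,T) summing to 1;
#'   computed from `sequences` when present, uniform otherwise
#' @return an object of class `genome_model`
#' @export
genome_model <- function(chrom_lengths, sequences = NULL, background = NULL) {
  chrom_lengths <- vapply(chrom_lengths, as.integer, 1L)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be named")
  if (!is.null(sequences)) {
    if (!all(names(chrom_lengths) %in% names(sequences)))
      stop("sequences missing for some chromosomes")
    if (!all(nchar(sequences[names(chrom_lengths)]) == chrom_lengths))
      stop("sequence lengths disagree with chrom_lengths")
  }
  if (is.null(background)) {
    if (!is.null(sequences)) {
      codes <- encode_dna(paste(sequences, collapse = ""))
      cnt <- tabulate(codes, nbins = 4L)
      at <- (cnt[1L] + cnt[4L]) / 2
      cg <- (cnt[2L] + cnt[3L]) / 2
      background <- c(A = at, C = cg, G = cg, T = at) / (2 * at + 2 * cg)
    } else {
      background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    }
  }
  background <- background[DNA_BASES]
  if (any(background < 0) || abs(sum(background) - 1) > 1e-9)
    stop("background must be nonnegative and sum to 1")
  structure(list(chrom_lengths = chrom_lengths, sequences = sequences,
                 background = background),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), "bp,",
      if (is.null(x$sequences)) "lengths only" else "with sequence", "\n")
  cat("  background:", paste(sprintf("%s=%.3f", names(x$background),
                                     x$background), collapse = " "), "\n")
  invisible(x)
}

# Extract sequence [start, end) from a genome with sequences.
genome_seq <- function(genome, chrom, start, end) {
  s <- genome$sequences[[chrom]]
  if (is.null(s)) stop("genome model has no sequence for ", chrom)
  substr(s, start + 1L, end)
}
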