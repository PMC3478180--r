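#' Position weight matrices
#'
#' A PWM holds per-position base probabilities obtained from a count matrix by
#' adding a pseudocount (default 0.25 per base) and normalising each position.
#' Scores are log2 likelihood ratios against a background composition; an `N`
#' in the scanned word contributes 0.  The score threshold used for scanning
#' is unset until [calibrate_threshold()] fixes it.
#'
#' @param id matrix identifier
#' @param counts 4 x width numeric matrix (rows A, C, G, T) of counts or
#'   probabilities
#' @param pseudocount added to every cell before normalisation
#' @param background length-4 base composition used for scoring (may be reset
#'   at calibration time)
#' @return an object of class `pwm`
#' @export
new_pwm <- function(id, counts, pseudocount = 0.25,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PWM counts must have 4 rows (A,C,G,T)")
  rownames(counts) <- DNA_BASES
  tot <- colSums(counts) + 4 * pseudocount
  if (any(colSums(counts) < 0) || any(tot <= 0))
    stop(sprintf("matrix '%s': position %d does not sum to a positive total",
                 id, which(tot <= 0)[1L]))
  probs <- sweep(counts + pseudocount, 2L, tot, "/")
  structure(list(id = id, width = ncol(probs), probs = probs,
                 background = background[DNA_BASES], pseudocount = pseudocount,
                 threshold = NA_real_, calibration = NULL),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, threshold %s\n", x$id, x$width,
              if (is.na(x$threshold)) "uncalibrated"
              else sprintf("%.3f (hit rate %.4f)", x$threshold,
                           x$calibration$achieved_rate)))
  invisible(x)
}

# log2-odds matrix with a 5th row of zeros for N.
pwm_logodds <- function(pwm) {
  lo <- log2(pwm$probs / pwm$background)
  rbind(lo, N = 0)
}

# Reverse-complement of a PWM: reversed positions, complemented bases.
pwm_revcomp <- function(pwm) {
  p <- pwm
  p$probs <- pwm$probs[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(p$probs) <- DNA_BASES
  p$background <- pwm$background[4:1]
  names(p$background) <- DNA_BASES
  p
}

#' Highest-probability word of a PWM
#' @param pwm a [new_pwm()] object
#' @return character scalar of length `pwm$width`
#' @export
max_prob_word <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2L, which.max)], collapse = "")
}

#' Score one word against a PWM
#'
#' Sum over positions of `log2(P_pwm(base) / P_bg(base))`; `N` contributes 0.
#' `strand = "-"` scores the reverse complement of `word`.
#'
#' @param pwm a [new_pwm()] object
#' @param word string of length `pwm$width` over A,C,G,T,N
#' @param strand `"+"` or `"-"`
#' @return numeric log-odds score
#' @export
score_word <- function(pwm, word, strand = "+") {
  if (nchar(word) != pwm$width) stop("word length must equal PWM width")
  if (strand == "-") word <- revcomp(word)
  lo <- pwm_logodds(pwm)
  codes <- encode_dna(word)
  sum(lo[cbind(codes, seq_len(pwm$width))])
}

# Score every start position of every row of an integer code matrix (n x L)
# on the forward strand.  Returns an n x (L - width + 1) score matrix.
scan_code_matrix <- function(codes, pwm) {
  lo <- pwm_logodds(pwm)
  n <- nrow(codes); L <- ncol(codes); w <- pwm$width
  P <- L - w + 1L
  if (P < 1L) return(matrix(numeric(0), nrow = n, ncol = 0L))
  scores <- matrix(0, n, P)
  for (j in seq_len(w)) {
    idx <- codes[, j:(j + P - 1L), drop = FALSE]
    scores <- scores + matrix(lo[cbind(as.vector(idx), j)], n, P)
  }
  scores
}

# Per-sequence maximum score over both strands for a batch of sequences
# given as a code matrix.
max_scores_both_strands <- function(codes, pwm) {
  fw <- scan_code_matrix(codes, pwm)
  rv <- scan_code_matrix(codes, pwm_revcomp(pwm))
  if (ncol(fw) == 0L) return(rep(-Inf, nrow(codes)))
  pmax(apply(fw, 1L, max), apply(rv, 1L, max))
}

#' Scan a window for motif hits
#'
#' All start positions on both strands with score at or above the PWM's
#' calibrated threshold.  A reverse-strand hit at position `p` means the
#' reverse complement of the window bases `[p, p + width)` matches; positions
#' are 0-based and window-relative.  Results are sorted by position, then
#' strand.
#'
#' @param sequence window sequence (e.g. 200 bp)
#' @param pwm calibrated [new_pwm()]
#' @param threshold override for the PWM threshold
#' @return data frame `pwm_id`, `pos`, `strand`, `score`
#' @export
scan_window <- function(sequence, pwm, threshold = pwm$threshold) {
  if (is.na(threshold)) stop("PWM '", pwm$id, "' has no calibrated threshold")
  hits <- scan_windows(sequence, pwm, threshold)
  hits$window <- NULL
  hits
}

# Vectorised scan of many equal-length windows; returns window index + hits.
scan_windows <- function(sequences, pwm, threshold = pwm$threshold) {
  if (is.na(threshold)) stop("PWM '", pwm$id, "' has no calibrated threshold")
  empty <- data.frame(window = integer(0), pwm_id = character(0),
                      pos = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(sequences) == 0L) return(empty)
  if (nchar(sequences[1L]) < pwm$width) return(empty)
  codes <- encode_dna_matrix(sequences)
  out <- list()
  for (s in c("+", "-")) {
    m <- if (s == "+") pwm else pwm_revcomp(pwm)
    sc <- scan_code_matrix(codes, m)
    keep <- which(sc >= threshold, arr.ind = TRUE)
    if (nrow(keep)) {
      out[[s]] <- data.frame(window = keep[, 1L], pwm_id = pwm$id,
                             pos = keep[, 2L] - 1L, strand = s,
                             score = sc[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$window, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Calibrate a PWM score threshold to a target random-sequence hit rate
#'
#' Monte Carlo calibration: draw `n_mc` i.i.d. background sequences of
#' `window` bp, record each sequence's maximum score over both strands, and
#' set the threshold between order statistics so that the fraction of random
#' sequences containing at least one hit equals `target_rate` (up to score
#' ties).  The achieved rate, sample size and seed are attached to the
#' returned PWM as its calibration report.
#'
#' @param pwm a [new_pwm()] object
#' @param background length-4 composition to calibrate (and subsequently
#'   score) against; defaults to the PWM's stored background
#' @param target_rate desired per-window hit probability (default 0.01)
#' @param window scanned window width in bp (default 200)
#' @param n_mc number of random sequences (>= 1000)
#' @param seed RNG seed for the calibration draw
#' @return the PWM with `threshold`, scoring `background`, and `calibration`
#'   set
#' @export
calibrate_threshold <- function(pwm, background = pwm$background,
                                target_rate = 0.01, window = 200L,
                                n_mc = 10000L, seed = NULL) {
  stopifnot(target_rate > 0, target_rate < 1, n_mc >= 1000L)
  background <- background[DNA_BASES]
  pwm$background <- background
  codes <- with_seed(seed, matrix(
    sample.int(4L, n_mc * window, replace = TRUE, prob = background),
    nrow = n_mc, ncol = window))
  mx <- max_scores_both_strands(codes, pwm)
  if (!any(is.finite(mx)))
    stop("matrix '", pwm$id, "': no finite scores at this window size")
  # hit rates are only achievable at the distinct levels of the per-sequence
  # maximum (a whole tie cluster enters or leaves the hit set together);
  # pick the level whose achieved rate is closest to the target
  lev <- sort(unique(mx), decreasing = TRUE)
  rate_at <- cumsum(tabulate(match(mx, lev), nbins = length(lev))) / n_mc
  best <- which.min(abs(rate_at - target_rate))
  thr <- lev[best]
  achieved <- rate_at[best]
  if (achieved >= 1 || achieved <= 0)
    stop("matrix '", pwm$id, "': degenerate score distribution, ",
         "target rate not achievable")
  pwm$threshold <- thr
  pwm$calibration <- list(target_rate = target_rate, achieved_rate = achieved,
                          n_mc = n_mc, window = window, seed = seed)
  pwm
}

#' Empirical hit rate of a calibrated PWM on fresh random sequences
#'
#' Fraction of `n` independent background sequences of `window` bp containing
#' at least one hit on either strand — the validation counterpart of
#' [calibrate_threshold()].
#'
#' @inheritParams calibrate_threshold
#' @param n number of validation sequences
#' @return fraction in \[0, 1\]
#' @export
random_hit_rate <- function(pwm, n = 10000L, window = 200L, seed = NULL,
                            background = pwm$background) {
  codes <- with_seed(seed, matrix(
    sample.int(4L, n * window, replace = TRUE, prob = background[DNA_BASES]),
    nrow = n, ncol = window))
  mx <- max_scores_both_strands(codes, pwm)
  mean(mx >= pwm$threshold)
}

#' Read PWMs from JASPAR or TRANSFAC flat text
#'
#' JASPAR: `>ID name` followed by four rows `A [ 1 2 3 ]` (brackets optional).
#' TRANSFAC: blocks delimited by `//` with `ID`/`NA` lines, a `P0  A C G T`
#' header and numbered count rows.  Counts are converted to probabilities with
#' the pseudocount at construction time.
#'
#' @param path matrix file
#' @param format `"jaspar"` or `"transfac"`
#' @inheritParams new_pwm
#' @return named list of [new_pwm()] objects
#' @export
read_pwms <- function(path, format = c("jaspar", "transfac"),
                      pseudocount = 0.25,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  format <- match.arg(format)
  lines <- readLines(path)
  pwms <- list()
  if (format == "jaspar") {
    starts <- grep("^>", lines)
    bounds <- c(starts, length(lines) + 1L)
    for (k in seq_along(starts)) {
      hdr <- sub("^>\\s*", "", lines[starts[k]])
      id <- strsplit(trimws(hdr), "[ \t]+")[[1L]][1L]
      block <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
      block <- block[nzchar(trimws(block))]
      rows <- lapply(c("A", "C", "G", "T"), function(b) {
        ln <- grep(paste0("^\\s*", b, "\\b"), block, value = TRUE)
        if (length(ln) != 1L)
          stop("matrix '", id, "': expected one row for base ", b)
        nums <- gsub("[][]", " ", sub("^\\s*[ACGT]\\s*", "", ln))
        as.numeric(strsplit(trimws(nums), "\\s+")[[1L]])
      })
      counts <- do.call(rbind, rows)
      pwms[[id]] <- new_pwm(id, counts, pseudocount, background)
    }
  } else {
    blocks <- split(lines, cumsum(grepl("^//", lines)))
    for (block in blocks) {
      block <- block[!grepl("^//", block)]
      idln <- grep("^(ID|NA)\\b", block, value = TRUE)
      if (length(idln) == 0L) next
      id <- strsplit(trimws(idln[1L]), "\\s+")[[1L]][2L]
      p0 <- grep("^P0\\b", block)
      if (length(p0) == 0L) next
      order4 <- strsplit(trimws(sub("^P0", "", block[p0[1L]])), "\\s+")[[1L]][1:4]
      cnt <- list()
      for (ln in block[grepl("^\\d+\\s", block)]) {
        f <- strsplit(trimws(ln), "\\s+")[[1L]]
        cnt[[length(cnt) + 1L]] <- as.numeric(f[2:5])
      }
      if (length(cnt) == 0L) next
      counts <- t(do.call(rbind, cnt))
      rownames(counts) <- order4
      counts <- counts[DNA_BASES, , drop = FALSE]
      pwms[[id]] <- new_pwm(id, counts, pseudocount, background)
    }
  }
  if (length(pwms) == 0L) stop("no matrices parsed from ", path)
  pwms
}
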