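#' Count TE instances overlapping peak windows
#'
#' The count for a family is the number of *distinct* instances of that
#' family whose span shares at least one base with at least one peak window:
#' an instance overlapping two windows counts once, while a window overlapping
#' two instances increments both.  Class counts aggregate family counts by
#' `te_class`, so a class count always equals the sum of its member family
#' counts.
#'
#' @param peaks peak table from [make_peaks()]
#' @param tes TE instance table
#' @return list with named integer vectors `family` and `class` (all families
#'   and classes present in `tes`, zeros included) and the index vector
#'   `overlapped` of hit instances
#' @export
count_te_overlaps <- function(peaks, tes) {
  fam_levels <- unique(tes$name)
  cls_levels <- unique(tes$te_class)
  if (nrow(peaks) == 0L || nrow(tes) == 0L) {
    return(list(family = stats::setNames(integer(length(fam_levels)), fam_levels),
                class = stats::setNames(integer(length(cls_levels)), cls_levels),
                overlapped = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(peak_windows(peaks)),
                                      as_granges0(tes))
  idx <- unique(S4Vectors::subjectHits(hits))
  fam <- table(factor(tes$name[idx], levels = fam_levels))
  cls <- table(factor(tes$te_class[idx], levels = cls_levels))
  list(family = stats::setNames(as.integer(fam), names(fam)),
       class = stats::setNames(as.integer(cls), names(cls)),
       overlapped = idx)
}

#' Draw a locally matched random peak set
#'
#' Each chromosome is divided into fixed 1 Mb windows anchored at position 0;
#' for every real peak, one random peak of the same width is placed with a
#' flat distribution inside the 1 Mb window containing the real peak's
#' midpoint (the last, partial window of a chromosome is used as-is).  A
#' window too short to host a peak falls back to whole-chromosome uniform
#' placement.
#'
#' @param peaks peak table
#' @param genome a [genome_model()] covering the peaks
#' @param window_size_mb width of the matching window in Mb (default 1)
#' @param seed RNG seed
#' @return peak table of the same size; all windows `win_end - win_start ==`
#'   the peak window width
#' @export
sample_random_peakset <- function(peaks, genome, window_size_mb = 1, seed = NULL) {
  W <- as.integer(window_size_mb * 1e6)
  wlen <- peaks$win_end - peaks$win_start
  clen <- genome$chrom_lengths[peaks$chrom]
  if (anyNA(clen)) stop("peak chromosome absent from genome model")
  mid <- (peaks$start + peaks$end) %/% 2L
  wi <- mid %/% W
  lo <- wi * W
  hi <- pmin(lo + W, clen)
  short <- (hi - lo) < wlen
  lo[short] <- 0L
  hi[short] <- clen[short]
  n_max <- hi - wlen - lo + 1L
  if (any(n_max < 1L)) stop("chromosome shorter than the peak window")
  start <- with_seed(seed, lo + floor(stats::runif(nrow(peaks)) * n_max))
  start <- pmin(as.integer(start), hi - wlen)  # guard the runif upper edge
  iv <- data.frame(chrom = peaks$chrom, start = start, end = start + wlen,
                   stringsAsFactors = FALSE)
  make_peaks(iv, id = sprintf("rand_%04d", seq_len(nrow(peaks))),
             window_size = wlen[1L], genome = genome)
}

#' TE-family and class enrichment z-scores by Monte Carlo resampling
#'
#' The core enrichment statistic: the observed overlap count `x` of every TE
#' family (and class) is compared with its distribution over `n_random`
#' locally matched random peak sets, giving `z = (x - mu) / sqrt(s)` with
#' `mu` and `s` the sample mean and (unbiased) variance of the random counts.
#' One child seed per replicate is derived from `seed` and recorded, so any
#' replicate can be re-drawn exactly.
#'
#' @param peaks peak table
#' @param tes TE instance table
#' @param genome a [genome_model()]
#' @param n_random number of random peak sets (default 1000)
#' @param seed master RNG seed
#' @param window_size_mb matching-window width for [sample_random_peakset()]
#' @param keep_replicates retain the per-replicate count matrices as an
#'   attribute for audit
#' @return data frame `unit`, `level`, `x`, `mu`, `var`, `z`, `degenerate`,
#'   `n_random`; units never observed in the real or any random set are
#'   omitted.  `degenerate` flags zero-variance units, whose `z` is 0 when
#'   `x == mu` and signed `Inf` otherwise.
#' @export
enrichment_zscores <- function(peaks, tes, genome, n_random = 1000L,
                               seed = NULL, window_size_mb = 1,
                               keep_replicates = FALSE) {
  stopifnot(n_random >= 2L)
  obs <- count_te_overlaps(peaks, tes)
  seeds <- spawn_seeds(seed, n_random)
  fam_mat <- matrix(0L, n_random, length(obs$family),
                    dimnames = list(NULL, names(obs$family)))
  cls_mat <- matrix(0L, n_random, length(obs$class),
                    dimnames = list(NULL, names(obs$class)))
  for (r in seq_len(n_random)) {
    rp <- sample_random_peakset(peaks, genome, window_size_mb, seed = seeds[r])
    cnt <- count_te_overlaps(rp, tes)
    fam_mat[r, ] <- cnt$family
    cls_mat[r, ] <- cnt$class
  }
  build <- function(x, mat, level) {
    mu <- colMeans(mat)
    v <- apply(mat, 2L, stats::var)
    degenerate <- v == 0
    z <- ifelse(degenerate, ifelse(x == mu, 0, sign(x - mu) * Inf),
                (x - mu) / sqrt(v))
    keep <- x > 0 | colSums(mat) > 0
    data.frame(unit = names(x), level = level, x = as.integer(x), mu = mu,
               var = v, z = z, degenerate = degenerate,
               n_random = as.integer(n_random),
               stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  res <- rbind(build(obs$family, fam_mat, "family"),
               build(obs$class, cls_mat, "class"))
  rownames(res) <- NULL
  attr(res, "replicate_seeds") <- seeds
  if (keep_replicates)
    attr(res, "replicates") <- list(family = fam_mat, class = cls_mat)
  res
}

#' Retain significantly enriched units
#'
#' Strict threshold, as in "only values z > 3": a unit at exactly `z_min` is
#' dropped.  Family- and class-level results are returned separately, each
#' sorted by decreasing z.
#'
#' @param results output of [enrichment_zscores()]
#' @param z_min z-score cutoff (default 3)
#' @return list with data frames `family` and `class`
#' @export
filter_enriched <- function(results, z_min = 3) {
  keep <- results[!is.na(results$z) & results$z > z_min, , drop = FALSE]
  keep <- keep[order(-keep$z), , drop = FALSE]
  list(family = keep[keep$level == "family", , drop = FALSE],
       class = keep[keep$level == "class", , drop = FALSE])
}
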