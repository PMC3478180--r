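#' Scan all peak windows of a dataset with a set of PWMs
#'
#' Extracts the (unclipped) 200 bp window sequences, scans each with every
#' calibrated PWM on both strands, and reports hits with window-relative and
#' genome-absolute coordinates.  Clipped windows are excluded from scanning.
#'
#' @param peaks peak table
#' @param genome a [genome_model()] with sequences
#' @param pwms list of calibrated [new_pwm()] objects
#' @return data frame `peak_id`, `pwm_id`, `pos` (0-based, window-relative),
#'   `gstart`/`gend` (genome-absolute span of the match), `strand`, `score`
#' @export
scan_peak_windows <- function(peaks, genome, pwms) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  use <- !peaks$clipped
  pk <- peaks[use, , drop = FALSE]
  if (nrow(pk) == 0L)
    return(data.frame(peak_id = character(0), pwm_id = character(0),
                      pos = integer(0), gstart = integer(0), gend = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  seqs <- vapply(seq_len(nrow(pk)), function(i) {
    genome_seq(genome, pk$chrom[i], pk$win_start[i], pk$win_end[i])
  }, character(1))
  out <- lapply(pwms, function(p) {
    h <- scan_windows(seqs, p)
    if (nrow(h) == 0L) return(NULL)
    data.frame(peak_id = pk$id[h$window], pwm_id = h$pwm_id, pos = h$pos,
               gstart = pk$win_start[h$window] + h$pos,
               gend = pk$win_start[h$window] + h$pos + p$width,
               chrom = pk$chrom[h$window],
               strand = h$strand, score = h$score, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(peak_id = character(0), pwm_id = character(0),
                      pos = integer(0), gstart = integer(0), gend = integer(0),
                      chrom = character(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Transposon Affinity Score
#'
#' For each TE family, the TAS of a transcription factor is the fraction of
#' the family's peak-overlapping instances that carry at least one hit of the
#' factor's PWM: the denominator is the instance set counted by
#' [count_te_overlaps()], and an instance "carries" the factor when a hit in
#' an overlapping peak window has its matched bases intersecting the
#' instance's span (`carry_mode = "span"`, the default) or merely lies
#' anywhere in such a window (`carry_mode = "window"`).
#'
#' @param peaks peak table
#' @param tes TE instance table
#' @param genome a [genome_model()] with sequences
#' @param pwms list of calibrated [new_pwm()] objects
#' @param carry_mode `"span"` or `"window"`
#' @param hits optional precomputed [scan_peak_windows()] table
#' @return data frame `te_name`, `tf_id`, `n_instances`, `n_carrying`, `tas`;
#'   families with no peak-overlapping instances are omitted
#' @export
compute_tas <- function(peaks, tes, genome, pwms,
                        carry_mode = c("span", "window"), hits = NULL) {
  carry_mode <- match.arg(carry_mode)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  cnt <- count_te_overlaps(peaks, tes)
  inst <- tes[cnt$overlapped, , drop = FALSE]
  fams <- names(cnt$family)[cnt$family > 0]
  if (is.null(hits)) hits <- scan_peak_windows(peaks, genome, pwms)
  pwm_ids <- vapply(pwms, `[[`, "", "id")
  out <- list()
  inst_gr <- as_granges0(inst)
  for (tf in pwm_ids) {
    h <- hits[hits$pwm_id == tf, , drop = FALSE]
    carrying <- rep(FALSE, nrow(inst))
    if (nrow(h) > 0L) {
      if (carry_mode == "span") {
        hg <- as_granges0(data.frame(chrom = h$chrom, start = h$gstart,
                                     end = h$gend))
      } else {
        pk <- peaks[match(h$peak_id, peaks$id), , drop = FALSE]
        hg <- as_granges0(data.frame(chrom = pk$chrom, start = pk$win_start,
                                     end = pk$win_end))
      }
      ov <- GenomicRanges::findOverlaps(hg, inst_gr)
      carrying[unique(S4Vectors::subjectHits(ov))] <- TRUE
    }
    n_carry <- tapply(carrying, factor(inst$name, levels = fams), sum)
    out[[tf]] <- data.frame(te_name = fams, tf_id = tf,
                            n_instances = as.integer(cnt$family[fams]),
                            n_carrying = as.integer(n_carry),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$tas <- res$n_carrying / res$n_instances
  rownames(res) <- NULL
  res
}

#' TE-by-TF affinity matrix with interactor calls and clustering
#'
#' Spreads TAS records into a dense family x factor matrix (absent
#' combinations are 0), lists the factors reaching `tas_min` in at least one
#' family as putative interactors (the threshold is inclusive), and attaches
#' row and column leaf orders from average-linkage hierarchical clustering of
#' Euclidean distances, as used for affinity heat maps.
#'
#' @param records output of [compute_tas()]
#' @param tas_min interactor cutoff on TAS (default 0.10, inclusive)
#' @return list: `matrix`, `interactors` (character vector), `row_order`,
#'   `col_order`
#' @export
tas_matrix <- function(records, tas_min = 0.10) {
  stopifnot(nrow(records) >= 1L)
  fams <- sort(unique(records$te_name))
  tfs <- sort(unique(records$tf_id))
  m <- matrix(0, length(fams), length(tfs), dimnames = list(fams, tfs))
  m[cbind(match(records$te_name, fams), match(records$tf_id, tfs))] <-
    records$tas
  interactors <- tfs[apply(m >= tas_min, 2L, any)]
  cluster_order <- function(x) {
    if (nrow(x) < 3L) return(seq_len(nrow(x)))
    hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                        method = "average")
    hc$order
  }
  list(matrix = m, interactors = interactors,
       row_order = cluster_order(m), col_order = cluster_order(t(m)))
}
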