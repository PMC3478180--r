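#' Project an interval through a syntenic block
#'
#' Linear interpolation of the endpoints of an interval in genome A into the
#' block's genome-B coordinates.  Inverted blocks reverse the endpoint order:
#' the projected start is `b_end - (a_end' - a_start_block)` where `a_end'`
#' is the query end.  Output respects the 0-based half-open convention.
#'
#' @param block one-row block table (`a_chrom`, `a_start`, `a_end`,
#'   `b_chrom`, `b_start`, `b_end`, `orientation`)
#' @param interval one-row interval data frame in genome A
#' @return one-row interval data frame in genome B
#' @export
project_interval <- function(block, interval) {
  stopifnot(nrow(block) == 1L, nrow(interval) == 1L)
  if (interval$chrom != block$a_chrom ||
      interval$start < block$a_start || interval$end > block$a_end)
    stop("interval not in block ", block$block_id %||% "")
  scale <- (block$b_end - block$b_start) / (block$a_end - block$a_start)
  off_s <- round((interval$start - block$a_start) * scale)
  off_e <- round((interval$end - block$a_start) * scale)
  if (identical(block$orientation, "inverted")) {
    s <- block$b_end - off_e
    e <- block$b_end - off_s
  } else {
    s <- block$b_start + off_s
    e <- block$b_start + off_e
  }
  data.frame(chrom = block$b_chrom, start = as.integer(s), end = as.integer(e),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Inverse projection (genome B -> genome A) through the same block.
project_interval_back <- function(block, interval) {
  stopifnot(nrow(block) == 1L, nrow(interval) == 1L)
  if (interval$chrom != block$b_chrom ||
      interval$start < block$b_start || interval$end > block$b_end)
    stop("interval not in block ", block$block_id %||% "")
  scale <- (block$a_end - block$a_start) / (block$b_end - block$b_start)
  if (identical(block$orientation, "inverted")) {
    off_s <- round((block$b_end - interval$end) * scale)
    off_e <- round((block$b_end - interval$start) * scale)
  } else {
    off_s <- round((interval$start - block$b_start) * scale)
    off_e <- round((interval$end - block$b_start) * scale)
  }
  data.frame(chrom = block$a_chrom, start = as.integer(block$a_start + off_s),
             end = as.integer(block$a_start + off_e), stringsAsFactors = FALSE)
}

#' Identify TE instances conserved between two genomes
#'
#' For every TE in genome A lying inside a syntenic block, its span is
#' projected into genome B and compared with same-family TE annotations
#' there.  A candidate match must reach the reciprocal-overlap threshold
#' `min(|proj intersect te_b| / |proj|, |proj intersect te_b| / |te_b|) >=
#' min_reciprocal_overlap`; the best match per A instance is kept (largest
#' overlap, ties toward the smaller B start coordinate).  TEs spanning a
#' block boundary are projected per block and matched on their largest
#' in-block fragment.
#'
#' @param tes_a,tes_b TE instance tables for genomes A and B
#' @param blocks block table as produced by [generate_synteny()] or read from
#'   TSV (`block_id`, `a_chrom`, `a_start`, `a_end`, `b_chrom`, `b_start`,
#'   `b_end`, `orientation`)
#' @param min_reciprocal_overlap matching threshold in (0, 1\] (default 0.5)
#' @param match_level `"name"` (same family required, default) or `"class"`
#' @return data frame `te_a`, `te_b`, `name`, `block_id`,
#'   `reciprocal_overlap`
#' @export
find_conserved_te_pairs <- function(tes_a, tes_b, blocks,
                                    min_reciprocal_overlap = 0.5,
                                    match_level = c("name", "class")) {
  match_level <- match.arg(match_level)
  key_a <- if (match_level == "name") tes_a$name else tes_a$te_class
  key_b <- if (match_level == "name") tes_b$name else tes_b$te_class
  out <- list()
  for (i in seq_len(nrow(tes_a))) {
    bl <- blocks[blocks$a_chrom == tes_a$chrom[i] &
                   blocks$a_start < tes_a$end[i] &
                   blocks$a_end > tes_a$start[i], , drop = FALSE]
    if (nrow(bl) == 0L) next
    # largest in-block fragment
    frag_len <- pmin(bl$a_end, tes_a$end[i]) - pmax(bl$a_start, tes_a$start[i])
    bl <- bl[which.max(frag_len), , drop = FALSE]
    frag <- data.frame(chrom = tes_a$chrom[i],
                       start = max(bl$a_start, tes_a$start[i]),
                       end = min(bl$a_end, tes_a$end[i]),
                       stringsAsFactors = FALSE)
    proj <- project_interval(bl, frag)
    cand <- which(key_b == key_a[i] & tes_b$chrom == proj$chrom &
                    tes_b$start < proj$end & tes_b$end > proj$start)
    if (length(cand) == 0L) next
    inter <- pmin(tes_b$end[cand], proj$end) - pmax(tes_b$start[cand], proj$start)
    ro <- pmin(inter / (proj$end - proj$start),
               inter / (tes_b$end[cand] - tes_b$start[cand]))
    ok <- ro >= min_reciprocal_overlap
    if (!any(ok)) next
    cand <- cand[ok]; ro <- ro[ok]
    best <- order(-ro, tes_b$start[cand])[1L]
    out[[length(out) + 1L]] <- data.frame(
      te_a = tes_a$instance_id[i], te_b = tes_b$instance_id[cand[best]],
      name = key_a[i], block_id = bl$block_id,
      reciprocal_overlap = ro[best], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(te_a = character(0), te_b = character(0),
                      name = character(0), block_id = character(0),
                      reciprocal_overlap = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write syntenic block tables
#'
#' TSV with columns block_id, a_chrom, a_start, a_end, b_chrom, b_start,
#' b_end, orientation, header prefixed with `#`.
#' @param blocks block table
#' @param path file path
#' @export
write_synteny_blocks <- function(blocks, path) {
  write_tsv_hash(blocks, path)
}

#' @export
#' @rdname write_synteny_blocks
read_synteny_blocks <- function(path) {
  df <- read_tsv_hash(path)
  need <- c("block_id", "a_chrom", "a_start", "a_end", "b_chrom", "b_start",
            "b_end", "orientation")
  if (!all(need %in% names(df))) stop("block table missing required columns")
  df[need]
}
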