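#' Signed start-to-start distance histogram for a TFBS pair
#'
#' Counts, over a set of scanned windows, how often a hit of `tf_b` occurs at
#' each signed distance `d = start(b) - start(a)` from a hit of `tf_a`,
#' start-to-start on the forward strand.  Every hit pair within a window
#' contributes one count; when `tf_a == tf_b`, a hit is never paired with
#' itself (same position and strand), but distinct same-factor hits are
#' counted in both orders, which makes the histogram symmetric.
#'
#' @param hits hit table from [scan_peak_windows()] (needs `peak_id`,
#'   `pwm_id`, `pos`, `strand`)
#' @param tf_a,tf_b PWM ids
#' @param te_name label recorded on the histogram (default `"all"`)
#' @param window_len scanned window width, used for the permutation null
#' @param widths named widths of the two PWMs (taken from the hit table
#'   context by the caller); required by [detect_spacing_peak()]'s null
#' @return object of class `spacing_histogram`: counts per distance, the
#'   per-window hit positions, and bookkeeping
#' @export
pair_distance_counts <- function(hits, tf_a, tf_b, te_name = "all",
                                 window_len = 200L,
                                 widths = c(a = NA_integer_, b = NA_integer_)) {
  ha <- hits[hits$pwm_id == tf_a, , drop = FALSE]
  hb <- hits[hits$pwm_id == tf_b, , drop = FALSE]
  windows <- unique(c(ha$peak_id, hb$peak_id))
  per_window <- list()
  counts <- integer(0)
  for (w in windows) {
    a <- ha[ha$peak_id == w, , drop = FALSE]
    b <- hb[hb$peak_id == w, , drop = FALSE]
    per_window[[w]] <- list(n_a = nrow(a), n_b = nrow(b))
    if (nrow(a) == 0L || nrow(b) == 0L) next
    d <- as.vector(outer(b$pos, a$pos, "-"))
    if (tf_a == tf_b) {
      self <- as.vector(outer(seq_len(nrow(b)), seq_len(nrow(a)), function(i, j)
        b$pos[i] == a$pos[j] & b$strand[i] == a$strand[j]))
      d <- d[!self]
    }
    for (di in d) {
      key <- as.character(di)
      counts[key] <- if (key %in% names(counts)) counts[[key]] + 1L else 1L
    }
  }
  dd <- as.integer(names(counts))
  ord <- order(dd)
  structure(list(tf_a = tf_a, tf_b = tf_b, te_name = te_name,
                 counts = data.frame(d = dd[ord],
                                     count = as.integer(counts)[ord]),
                 n_windows = length(windows), per_window = per_window,
                 window_len = as.integer(window_len),
                 widths = widths),
            class = "spacing_histogram")
}

#' @export
print.spacing_histogram <- function(x, ...) {
  cat(sprintf("spacing_histogram %s~%s [%s]: %d windows, %d pair counts\n",
              x$tf_a, x$tf_b, x$te_name, x$n_windows, sum(x$counts$count)))
  invisible(x)
}

#' Detect a fixed-distance spacing peak with a permutation null
#'
#' The modal distance `d_star` is the argmax of the histogram (ties broken
#' toward the smallest `|d|`, then the smaller `d`).  Significance comes from
#' a permutation null that redraws every hit position uniformly within its
#' window (preserving per-window hit counts and motif widths) and records the
#' maximum histogram count of each permuted set; the empirical p-value is
#' `(1 + #\{null max >= observed\}) / (n_permutations + 1)`.
#'
#' @param hist a `spacing_histogram`
#' @param n_permutations number of null redraws (default 1000)
#' @param seed RNG seed
#' @return list of class `spacing_peak`: `d_star`, `count_at_peak`,
#'   `background_mean` (expected count per admissible distance bin),
#'   `enrichment_ratio`, `empirical_p`
#' @export
detect_spacing_peak <- function(hist, n_permutations = 1000L, seed = NULL) {
  cts <- hist$counts
  stopifnot(sum(cts$count) >= 1L)
  best <- which(cts$count == max(cts$count))
  best <- best[order(abs(cts$d[best]), cts$d[best])][1L]
  d_star <- cts$d[best]
  observed <- cts$count[best]
  wa <- hist$widths[["a"]]; wb <- hist$widths[["b"]]
  if (is.na(wa)) wa <- 1L
  if (is.na(wb)) wb <- 1L
  L <- hist$window_len
  n_bins <- (L - wa) + (L - wb) + 1L
  background_mean <- sum(cts$count) / n_bins
  same <- hist$tf_a == hist$tf_b
  null_max <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      tab <- integer(2L * L + 1L)  # offset-coded distance counts
      for (w in hist$per_window) {
        na <- w$n_a; nb <- w$n_b
        if (same) {
          if (na < 2L) next
          pos <- sample.int(L - wa + 1L, na, replace = TRUE) - 1L
          d <- as.vector(outer(pos, pos, "-"))
          d <- d[as.vector(!diag(na))]
        } else {
          if (na == 0L || nb == 0L) next
          pa <- sample.int(L - wa + 1L, na, replace = TRUE) - 1L
          pb <- sample.int(L - wb + 1L, nb, replace = TRUE) - 1L
          d <- as.vector(outer(pb, pa, "-"))
        }
        for (di in d) tab[di + L + 1L] <- tab[di + L + 1L] + 1L
      }
      max(tab)
    }, 1L)
  })
  structure(list(tf_a = hist$tf_a, tf_b = hist$tf_b, te_name = hist$te_name,
                 d_star = d_star, count_at_peak = observed,
                 background_mean = background_mean,
                 enrichment_ratio = observed / background_mean,
                 empirical_p = (1 + sum(null_max >= observed)) /
                   (n_permutations + 1),
                 n_permutations = as.integer(n_permutations)),
            class = "spacing_peak")
}

#' @export
print.spacing_peak <- function(x, ...) {
  cat(sprintf("spacing_peak %s~%s [%s]: d* = %d (count %d, %.1fx background), p = %.4g\n",
              x$tf_a, x$tf_b, x$te_name, x$d_star, x$count_at_peak,
              x$enrichment_ratio, x$empirical_p))
  invisible(x)
}

#' Align TE instances to a conserved core and annotate motif content
#'
#' Each instance is globally aligned to the core consensus (Needleman-Wunsch
#' via Biostrings, match +1 / mismatch -1 / linear gap -2 by default).  The
#' report gives, per core position, the fraction of instances matching the
#' core base (gaps count as mismatches), plus the calibrated-PWM hits found
#' on the core itself.  Substitutions that create a hit in an instance where
#' the core has none overlapping the same core positions are flagged as
#' site-creating mutations, with the core position(s) at which the instance
#' differs.
#'
#' @param instance_seqs named character vector of instance sequences
#' @param core core consensus sequence (e.g. the conserved ~70 bp MIR core)
#' @param pwms optional list of calibrated [new_pwm()] objects for motif
#'   annotation
#' @param match,mismatch,gap alignment scores
#' @return list: `positions` (per-core-position identity and motif labels),
#'   `alignments` (aligned instance/core strings), `site_creating`
#'   (instance, pwm, core positions, offending substitution positions),
#'   `skipped` (instances shorter than half the core)
#' @export
core_alignment_report <- function(instance_seqs, core, pwms = NULL,
                                  match = 1, mismatch = -1, gap = -2) {
  stopifnot(nchar(core) >= 1L)
  if (!is.null(pwms) && inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(instance_seqs)))
    names(instance_seqs) <- sprintf("inst_%03d", seq_along(instance_seqs))
  keep <- nchar(instance_seqs) >= nchar(core) / 2
  skipped <- names(instance_seqs)[!keep]
  instance_seqs <- instance_seqs[keep]
  nc <- nchar(core)
  core_chars <- strsplit(core, "")[[1L]]
  sm <- matrix(mismatch, 5L, 5L, dimnames = list(c(DNA_BASES, "N"),
                                                 c(DNA_BASES, "N")))
  diag(sm) <- match
  match_count <- integer(nc)
  covered <- integer(nc)
  alignments <- list()
  inst_core_maps <- list()
  for (nm in names(instance_seqs)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(instance_seqs[[nm]]),
      Biostrings::DNAString(core),
      type = "global", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = abs(gap))
    al_i <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    al_c <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    cpos <- cumsum(al_c != "-")          # core position at each column
    ipos <- cumsum(al_i != "-")          # instance position at each column
    core_cols <- which(al_c != "-")
    cp <- cpos[core_cols]
    covered[cp] <- covered[cp] + 1L
    match_count[cp] <- match_count[cp] + (al_i[core_cols] == al_c[core_cols])
    alignments[[nm]] <- list(instance = paste(al_i, collapse = ""),
                             core = paste(al_c, collapse = ""))
    # instance position -> core position map (NA where instance is inserted)
    map <- rep(NA_integer_, nchar(instance_seqs[[nm]]))
    inst_cols <- which(al_i != "-" & al_c != "-")
    map[ipos[inst_cols]] <- cpos[inst_cols]
    inst_core_maps[[nm]] <- map
  }
  positions <- data.frame(pos = seq_len(nc), core_base = core_chars,
                          identity = ifelse(covered > 0,
                                            match_count / pmax(covered, 1L), NA),
                          n_covered = covered,
                          pwm_ids = "", stringsAsFactors = FALSE)
  site_creating <- data.frame(instance = character(0), pwm_id = character(0),
                              core_start = integer(0), core_end = integer(0),
                              mutated_core_pos = character(0),
                              stringsAsFactors = FALSE)
  if (!is.null(pwms)) {
    core_hits <- lapply(pwms, function(p) scan_window(core, p))
    for (k in seq_along(pwms)) {
      p <- pwms[[k]]
      ch <- core_hits[[k]]
      if (nrow(ch) > 0L) {
        for (r in seq_len(nrow(ch))) {
          span <- (ch$pos[r] + 1L):(ch$pos[r] + p$width)
          positions$pwm_ids[span] <- trimws(paste(positions$pwm_ids[span],
                                                  p$id))
        }
      }
      core_cov <- rep(FALSE, nc)
      if (nrow(ch) > 0L)
        for (r in seq_len(nrow(ch)))
          core_cov[(ch$pos[r] + 1L):(ch$pos[r] + p$width)] <- TRUE
      for (nm in names(instance_seqs)) {
        ih <- scan_window(instance_seqs[[nm]], p)
        if (nrow(ih) == 0L) next
        map <- inst_core_maps[[nm]]
        for (r in seq_len(nrow(ih))) {
          ispan <- (ih$pos[r] + 1L):(ih$pos[r] + p$width)
          cspan <- map[ispan[ispan <= length(map)]]
          cspan <- cspan[!is.na(cspan)]
          if (length(cspan) == 0L || any(core_cov[cspan])) next
          inst_chars <- strsplit(instance_seqs[[nm]], "")[[1L]]
          diff_pos <- cspan[inst_chars[ispan[match(cspan, map[ispan])]] !=
                              core_chars[cspan]]
          site_creating <- rbind(site_creating, data.frame(
            instance = nm, pwm_id = p$id,
            core_start = min(cspan), core_end = max(cspan),
            mutated_core_pos = paste(diff_pos, collapse = ","),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(positions = positions, alignments = alignments,
       site_creating = site_creating, skipped = skipped)
}
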