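#' Generate a random genome
#'
#' I.i.d. nucleotides at the requested GC content on each chromosome.  The
#' returned [genome_model()] carries the empirical (strand-symmetrised)
#' composition as its background, which is what downstream scoring and
#' calibration use.
#'
#' @param chrom_lengths named integer vector of chromosome sizes
#' @param gc_content fraction of G+C bases (default 0.5)
#' @param seed RNG seed
#' @param with_sequence generate sequences (`TRUE`) or a lengths-only model
#'   for interval-level simulations (`FALSE`)
#' @return a [genome_model()]
#' @export
generate_genome <- function(chrom_lengths, gc_content = 0.5, seed = NULL,
                            with_sequence = TRUE) {
  stopifnot(gc_content >= 0, gc_content <= 1, length(chrom_lengths) >= 1L)
  if (!with_sequence) {
    at <- (1 - gc_content) / 2; cg <- gc_content / 2
    return(genome_model(chrom_lengths,
                        background = c(A = at, C = cg, G = cg, T = at)))
  }
  prob <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
            (1 - gc_content) / 2)
  seqs <- with_seed(seed, {
    vapply(chrom_lengths, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
  names(seqs) <- names(chrom_lengths)
  genome_model(chrom_lengths, sequences = seqs)
}

#' Random consensus sequence for a simulated TE family
#' @param length consensus length in bp
#' @param gc_content fraction of G+C
#' @param seed RNG seed
#' @return character scalar
#' @export
random_consensus <- function(length, gc_content = 0.5, seed = NULL) {
  prob <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
            (1 - gc_content) / 2)
  with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE, prob = prob),
                        collapse = ""))
}

#' Plant high-scoring motif sites into a consensus
#'
#' Replaces the bases at `offset_a` with PWM A's maximum-probability word and,
#' when `pwm_b` is given, the bases at `offset_a + distance` with PWM B's,
#' so the two site starts differ by exactly `distance` (start-to-start).
#'
#' @param consensus consensus sequence to modify
#' @param pwm_a,pwm_b [new_pwm()] objects (`pwm_b` optional)
#' @param offset_a 0-based start of the A site in the consensus
#' @param distance start-to-start spacing `start(B) - start(A)` in bp
#' @param allow_overlap permit the two sites to overlap (`distance <
#'   width(A)`); otherwise an error
#' @return the modified consensus
#' @export
plant_motif_combination <- function(consensus, pwm_a, pwm_b = NULL,
                                    offset_a = 0L, distance = NULL,
                                    allow_overlap = FALSE) {
  n <- nchar(consensus)
  stopifnot(offset_a >= 0L, offset_a + pwm_a$width <= n)
  word_a <- max_prob_word(pwm_a)
  substr(consensus, offset_a + 1L, offset_a + pwm_a$width) <- word_a
  if (!is.null(pwm_b)) {
    stopifnot(!is.null(distance), distance >= 0L)
    if (distance < pwm_a$width && !allow_overlap)
      stop("planted sites would overlap (distance < width of A); ",
           "set allow_overlap = TRUE to permit")
    off_b <- offset_a + distance
    if (off_b + pwm_b$width > n)
      stop("second site extends past the consensus end")
    substr(consensus, off_b + 1L, off_b + pwm_b$width) <- max_prob_word(pwm_b)
  }
  consensus
}

#' Plant decayed copies of a TE family into a genome
#'
#' Places `n_copies` of the consensus uniformly at random, without overlap
#' among planted TEs (an `occupied` interval table threads occupancy across
#' successive families).  Each copy is the consensus with i.i.d. substitutions
#' at the per-base `divergence` rate, emulating the sequence decay of ancient
#' repeats.
#'
#' @param genome a [genome_model()] (sequences optional)
#' @param name,te_class family name (e.g. `"MIRb"`) and class path
#'   (e.g. `"SINE/MIR"`)
#' @param consensus family consensus sequence
#' @param n_copies number of instances to plant
#' @param divergence per-base substitution probability in `[0, 1)`
#' @param seed RNG seed
#' @param occupied interval data frame of already-occupied spans
#' @param max_tries placement retries before giving up
#' @return list with the updated `genome`, the new `tes` table, and the
#'   combined `occupied` table
#' @export
plant_te_family <- function(genome, name, te_class, consensus, n_copies,
                            divergence = 0, seed = NULL, occupied = NULL,
                            max_tries = 1000L) {
  len <- nchar(consensus)
  if (len > min(genome$chrom_lengths))
    stop("consensus longer than the shortest chromosome")
  if (n_copies == 0L) {
    tes <- data.frame(instance_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), name = character(0),
                      te_class = character(0), stringsAsFactors = FALSE)
    return(list(genome = genome, tes = tes, occupied = occupied))
  }
  chroms <- names(genome$chrom_lengths)
  clens <- genome$chrom_lengths
  out <- with_seed(seed, {
    occ <- occupied
    rows <- vector("list", n_copies)
    cons_codes <- encode_dna(consensus)
    for (i in seq_len(n_copies)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ch <- sample(chroms, 1L, prob = as.numeric(clens))
        st <- sample.int(clens[[ch]] - len + 1L, 1L) - 1L
        cand <- data.frame(chrom = ch, start = st, end = st + len,
                           stringsAsFactors = FALSE)
        if (is.null(occ) || nrow(occ) == 0L ||
            !any(occ$chrom == ch & pmax(occ$start, st) < pmin(occ$end, st + len))) {
          occ <- rbind(occ, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place TE copy without overlap after ", max_tries,
             " tries")
      codes <- cons_codes
      if (divergence > 0) {
        mut <- which(stats::runif(len) < divergence)
        if (length(mut)) {
          # substitute to one of the three other bases, uniformly
          shift <- sample.int(3L, length(mut), replace = TRUE)
          codes[mut] <- ((codes[mut] - 1L + shift) %% 4L) + 1L
        }
      }
      rows[[i]] <- list(chrom = ch, start = st, end = st + len,
                        seq = decode_dna(codes))
    }
    list(rows = rows, occupied = occ)
  })
  tes <- data.frame(
    instance_id = sprintf("%s_%04d", name, seq_len(n_copies)),
    chrom = vapply(out$rows, `[[`, "", "chrom"),
    start = vapply(out$rows, `[[`, 1L, "start"),
    end = vapply(out$rows, `[[`, 1L, "end"),
    strand = "+", name = name, te_class = te_class,
    stringsAsFactors = FALSE)
  if (!is.null(genome$sequences)) {
    for (i in seq_len(n_copies)) {
      r <- out$rows[[i]]
      substr(genome$sequences[[r$chrom]], r$start + 1L, r$end) <- r$seq
    }
    genome <- genome_model(genome$chrom_lengths, genome$sequences)
  }
  list(genome = genome, tes = tes, occupied = out$occupied)
}

#' Generate a peak set with controlled TE-family enrichment
#'
#' For a family with multiplier `k`, the expected fraction of the `n_peaks`
#' 200 bp windows overlapping one of its instances is `min(1, k * b)`, where
#' `b` is the background probability that a uniformly placed window overlaps
#' the family (computed from the family's genomic footprint).  This is
#' achieved by routing each peak, with probability `(k - 1) * b`, to a
#' uniformly chosen instance of the family (window start uniform over all
#' starts sharing >= 1 bp with the instance) and placing the remainder
#' uniformly over the genome, which contributes the background rate on its
#' own.  Multiplier 1 therefore reduces to fully uniform placement.
#'
#' @param genome a [genome_model()]
#' @param tes TE instance table
#' @param multipliers named numeric vector, family -> k (families absent
#'   default to 1)
#' @param n_peaks number of peaks
#' @param window_size peak/window width (default 200)
#' @param seed RNG seed
#' @return peak data frame (as [make_peaks()]) with a `truth` attribute:
#'   per-peak planted family (`NA` for background peaks) and the per-family
#'   background rates `b` and target fractions
#' @export
generate_peaks <- function(genome, tes, multipliers = numeric(0),
                           n_peaks, window_size = 200L, seed = NULL) {
  stopifnot(n_peaks > 0)
  chroms <- names(genome$chrom_lengths)
  clens <- as.numeric(genome$chrom_lengths)
  gsize <- sum(clens)
  fams <- names(multipliers)
  b <- vapply(fams, function(f) {
    ft <- tes[tes$name == f, , drop = FALSE]
    # windows with >=1 bp overlap: len + window - 1 valid starts per instance
    sum(ft$end - ft$start + window_size - 1) / gsize
  }, 1)
  target <- stats::setNames(pmin(1, multipliers * b), fams)
  q <- pmax(0, (multipliers - 1) * b)
  if (sum(q) > 1) {
    warning("requested overlap fractions exceed 1; rescaling")
    q <- q / sum(q)
  }
  out <- with_seed(seed, {
    assignment <- sample(c(fams, NA), n_peaks, replace = TRUE,
                         prob = c(q, 1 - sum(q)))
    chrom <- character(n_peaks); start <- integer(n_peaks)
    for (i in seq_len(n_peaks)) {
      f <- assignment[i]
      if (!is.na(f)) {
        ft <- tes[tes$name == f, , drop = FALSE]
        j <- sample.int(nrow(ft), 1L)
        lo <- max(0L, ft$start[j] - window_size + 1L)
        hi <- min(genome$chrom_lengths[[ft$chrom[j]]] - window_size,
                  ft$end[j] - 1L)
        chrom[i] <- ft$chrom[j]
        start[i] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      } else {
        ch <- sample(chroms, 1L, prob = clens)
        chrom[i] <- ch
        start[i] <- sample.int(genome$chrom_lengths[[ch]] - window_size + 1L,
                               1L) - 1L
      }
    }
    list(chrom = chrom, start = start, assignment = assignment)
  })
  iv <- data.frame(chrom = out$chrom, start = out$start,
                   end = out$start + as.integer(window_size),
                   stringsAsFactors = FALSE)
  pk <- make_peaks(iv, window_size = window_size, genome = genome)
  attr(pk, "truth") <- list(planted_family = out$assignment,
                            background_rate = b, target_fraction = target,
                            multipliers = multipliers)
  pk
}

#' Generate gene TSS annotations, optionally clustered near TEs
#'
#' A fraction `tss_near_te_fraction` of TSSs is placed within +/- 2 kb of the
#' midpoint of a uniformly chosen TE instance; the rest are uniform over the
#' genome.  Strands are random.
#'
#' @param genome a [genome_model()]
#' @param tes TE instance table
#' @param n_genes number of genes
#' @param tss_near_te_fraction fraction in `[0, 1]`
#' @param near_bp half-width of the near-TE placement window (default 2000)
#' @param seed RNG seed
#' @return data frame `gene_id`, `chrom`, `tss`, `strand` with a `truth`
#'   attribute flagging near-TE genes and their source instance
#' @export
generate_genes <- function(genome, tes, n_genes, tss_near_te_fraction = 0,
                           near_bp = 2000L, seed = NULL) {
  stopifnot(n_genes > 0, tss_near_te_fraction >= 0, tss_near_te_fraction <= 1)
  chroms <- names(genome$chrom_lengths)
  clens <- as.numeric(genome$chrom_lengths)
  with_seed(seed, {
    near <- stats::runif(n_genes) < tss_near_te_fraction
    chrom <- character(n_genes); tss <- integer(n_genes)
    src <- rep(NA_character_, n_genes)
    for (i in seq_len(n_genes)) {
      if (near[i] && nrow(tes) > 0L) {
        j <- sample.int(nrow(tes), 1L)
        mid <- (tes$start[j] + tes$end[j]) %/% 2L
        chrom[i] <- tes$chrom[j]
        lo <- max(0L, mid - near_bp)
        hi <- min(genome$chrom_lengths[[chrom[i]]] - 1L, mid + near_bp)
        tss[i] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        src[i] <- tes$instance_id[j]
      } else {
        near[i] <- FALSE
        ch <- sample(chroms, 1L, prob = clens)
        chrom[i] <- ch
        tss[i] <- sample.int(genome$chrom_lengths[[ch]], 1L) - 1L
      }
    }
    genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
                        chrom = chrom, tss = tss,
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    attr(genes, "truth") <- data.frame(gene_id = genes$gene_id, near_te = near,
                                       source_te = src,
                                       stringsAsFactors = FALSE)
    genes
  })
}

#' Derive a syntenic second genome
#'
#' Cuts each chromosome of genome A into contiguous blocks (`n_blocks` in
#' total, allocated by chromosome length), shuffles their order, reverse
#' complements a fraction of them, and concatenates the result into a
#' single-chromosome genome B.  Each TE instance fully contained in a block
#' is carried over (projected through the block) with probability
#' `conserved_te_fraction`; non-conserved instances have their B-side
#' sequence overwritten with random background bases and per-family decoy
#' annotations are planted at unrelated B positions so that matching has a
#' realistic negative set.
#'
#' @param genome a [genome_model()] with or without sequences
#' @param tes TE instance table on genome A
#' @param n_blocks number of syntenic blocks (>= 1)
#' @param inversion_fraction fraction of blocks placed in inverted
#'   orientation
#' @param conserved_te_fraction probability an in-block TE is conserved
#' @param seed RNG seed
#' @return list: `genome_b`, `tes_b`, `blocks` (block table usable by
#'   [project_interval()]), and `pairs_truth` (conserved A/B instance id
#'   pairs)
#' @export
generate_synteny <- function(genome, tes, n_blocks = 10L,
                             inversion_fraction = 0, conserved_te_fraction = 1,
                             seed = NULL) {
  stopifnot(n_blocks >= 1L)
  chroms <- names(genome$chrom_lengths)
  clens <- as.numeric(genome$chrom_lengths)
  # allocate blocks to chromosomes proportionally, at least one each
  alloc <- pmax(1L, round(n_blocks * clens / sum(clens)))
  while (sum(alloc) > n_blocks) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_blocks) alloc[which.max(clens / alloc)] <- alloc[which.max(clens / alloc)] + 1L
  with_seed(seed, {
    blocks_a <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      k <- alloc[ci]; L <- genome$chrom_lengths[[ci]]
      cuts <- if (k > 1L) sort(sample.int(L - 1L, k - 1L)) else integer(0)
      bnd <- c(0L, cuts, L)
      data.frame(a_chrom = chroms[ci], a_start = bnd[-length(bnd)],
                 a_end = bnd[-1L], stringsAsFactors = FALSE)
    }))
    ord <- sample.int(nrow(blocks_a))
    blocks_a <- blocks_a[ord, , drop = FALSE]
    inv <- stats::runif(nrow(blocks_a)) < inversion_fraction
    blen <- blocks_a$a_end - blocks_a$a_start
    b_end <- cumsum(blen)
    blocks <- data.frame(block_id = sprintf("block_%03d", seq_len(nrow(blocks_a))),
                         a_chrom = blocks_a$a_chrom,
                         a_start = blocks_a$a_start, a_end = blocks_a$a_end,
                         b_chrom = "chrB1", b_start = b_end - blen,
                         b_end = b_end,
                         orientation = ifelse(inv, "inverted", "same"),
                         stringsAsFactors = FALSE)
    seq_b <- NULL
    if (!is.null(genome$sequences)) {
      pieces <- vapply(seq_len(nrow(blocks)), function(i) {
        s <- genome_seq(genome, blocks$a_chrom[i], blocks$a_start[i],
                        blocks$a_end[i])
        if (blocks$orientation[i] == "inverted") revcomp(s) else s
      }, character(1))
      seq_b <- paste(pieces, collapse = "")
    }
    # conserved / dropped TEs
    tes_b_rows <- list(); pairs <- list()
    occupied_b <- NULL
    scramble <- list()
    for (i in seq_len(nrow(tes))) {
      bi <- which(blocks$a_chrom == tes$chrom[i] &
                    blocks$a_start <= tes$start[i] &
                    blocks$a_end >= tes$end[i])
      if (length(bi) == 0L) next  # spans a breakpoint: not carried over
      bi <- bi[1L]
      proj <- project_interval(blocks[bi, ],
                               data.frame(chrom = tes$chrom[i],
                                          start = tes$start[i],
                                          end = tes$end[i]))
      if (stats::runif(1) < conserved_te_fraction) {
        bid <- sprintf("b_%s", tes$instance_id[i])
        tes_b_rows[[length(tes_b_rows) + 1L]] <- data.frame(
          instance_id = bid, chrom = proj$chrom, start = proj$start,
          end = proj$end, strand = tes$strand[i], name = tes$name[i],
          te_class = tes$te_class[i], stringsAsFactors = FALSE)
        pairs[[length(pairs) + 1L]] <- data.frame(
          te_a = tes$instance_id[i], te_b = bid,
          block_id = blocks$block_id[bi], stringsAsFactors = FALSE)
        occupied_b <- rbind(occupied_b,
                            data.frame(chrom = proj$chrom, start = proj$start,
                                       end = proj$end, stringsAsFactors = FALSE))
      } else {
        scramble[[length(scramble) + 1L]] <- proj
        occupied_b <- rbind(occupied_b,
                            data.frame(chrom = proj$chrom, start = proj$start,
                                       end = proj$end, stringsAsFactors = FALSE))
      }
    }
    if (!is.null(seq_b) && length(scramble)) {
      bg <- genome$background
      for (pr in scramble) {
        len <- pr$end - pr$start
        substr(seq_b, pr$start + 1L, pr$end) <-
          paste(sample(DNA_BASES, len, replace = TRUE, prob = bg),
                collapse = "")
      }
    }
    # decoy annotations: same families, random unoccupied B positions
    fams <- unique(tes$name)
    Lb <- sum(blen)
    decoys <- list()
    for (f in fams) {
      flen <- tes$end[tes$name == f][1L] - tes$start[tes$name == f][1L]
      n_dec <- max(1L, sum(tes$name == f) %/% 4L)
      for (d in seq_len(n_dec)) {
        for (try in 1:200) {
          st <- sample.int(Lb - flen + 1L, 1L) - 1L
          if (is.null(occupied_b) ||
              !any(pmax(occupied_b$start, st) < pmin(occupied_b$end, st + flen))) {
            decoys[[length(decoys) + 1L]] <- data.frame(
              instance_id = sprintf("decoy_%s_%03d", f, d), chrom = "chrB1",
              start = st, end = st + flen, strand = "+", name = f,
              te_class = tes$te_class[tes$name == f][1L],
              stringsAsFactors = FALSE)
            occupied_b <- rbind(occupied_b,
                                data.frame(chrom = "chrB1", start = st,
                                           end = st + flen,
                                           stringsAsFactors = FALSE))
            break
          }
        }
      }
    }
    tes_b <- do.call(rbind, c(tes_b_rows, decoys))
    if (is.null(tes_b)) tes_b <- tes[0, , drop = FALSE]
    pairs_truth <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(te_a = character(0), te_b = character(0),
                 block_id = character(0), stringsAsFactors = FALSE)
    genome_b <- genome_model(c(chrB1 = sum(blen)),
                             sequences = if (!is.null(seq_b)) c(chrB1 = seq_b))
    list(genome_b = genome_b, tes_b = tes_b, blocks = blocks,
         pairs_truth = pairs_truth)
  })
}

#' Write a genome's sequences as FASTA
#' @param genome a [genome_model()] with sequences
#' @param path output file
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequences)) stop("genome model has no sequences")
  ss <- Biostrings::DNAStringSet(unlist(genome$sequences))
  names(ss) <- names(genome$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTA genome into a genome model
#' @export
#' @rdname write_genome_fasta
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  genome_model(stats::setNames(Biostrings::width(ss), names(ss)),
               sequences = seqs)
}
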