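#' Assign peaks to genes through TSS windows
#'
#' A gene and a peak are linked iff the peak's midpoint lies within
#' `half_window` bp of the gene's TSS (point containment in the
#' +/- 20 kb window by default; set `mode = "overlap"` to link on any
#' peak-window overlap with the TSS window instead).  A peak may link to
#' many genes and vice versa.  Distances are signed relative to the gene's
#' strand: negative upstream.
#'
#' @param peaks peak table
#' @param genes gene table (`gene_id`, `chrom`, `tss`, `strand`)
#' @param half_window half-width of the TSS window in bp (default 20000)
#' @param mode `"midpoint"` or `"overlap"`
#' @param tes optional TE table; when given, each link lists the TE families
#'   overlapping the peak's window
#' @return data frame `gene_id`, `peak_id`, `distance`, `te_families`
#' @export
assign_peaks_to_genes <- function(peaks, genes, half_window = 20000L,
                                  mode = c("midpoint", "overlap"),
                                  tes = NULL) {
  mode <- match.arg(mode)
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0L, genes$tss - as.integer(half_window)),
                    end = genes$tss + as.integer(half_window) + 1L,
                    stringsAsFactors = FALSE)
  mid <- (peaks$start + peaks$end) %/% 2L
  if (mode == "midpoint") {
    qry <- data.frame(chrom = peaks$chrom, start = mid, end = mid + 1L,
                      stringsAsFactors = FALSE)
  } else {
    qry <- peak_windows(peaks)
  }
  ov <- GenomicRanges::findOverlaps(as_granges0(qry), as_granges0(win))
  pi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  raw <- mid[pi] - genes$tss[gi]
  dist <- ifelse(genes$strand[gi] == "-", -raw, raw)
  fam_by_peak <- NULL
  if (!is.null(tes)) {
    po <- GenomicRanges::findOverlaps(as_granges0(peak_windows(peaks)),
                                      as_granges0(tes))
    fam_by_peak <- tapply(tes$name[S4Vectors::subjectHits(po)],
                          S4Vectors::queryHits(po),
                          function(x) paste(sort(unique(x)), collapse = ","))
  }
  links <- data.frame(gene_id = genes$gene_id[gi], peak_id = peaks$id[pi],
                      distance = as.integer(dist), stringsAsFactors = FALSE)
  links$te_families <- if (!is.null(fam_by_peak) && nrow(links) > 0) {
    v <- fam_by_peak[as.character(pi)]
    ifelse(is.na(v), "", unname(v))
  } else rep("", nrow(links))
  links[order(links$gene_id, links$peak_id), , drop = FALSE]
}

#' Histogram of TE-to-nearest-TSS signed distances
#'
#' For every TE instance, the nearest TSS on the same chromosome by absolute
#' genomic distance (ties broken toward the smaller TSS coordinate); the
#' distance from that TSS to the TE midpoint is signed relative to the gene's
#' strand (upstream negative) and binned into half-open bins of `bin_width`
#' bp aligned on 0.  TEs on chromosomes without genes are excluded and
#' counted in the report.
#'
#' @param tes TE instance table (typically the peak-overlapping subset)
#' @param genes gene table
#' @param bin_width histogram bin width in bp (default 1000)
#' @return list: `hist` (bin_start, bin_end, count), `distances` per TE,
#'   `n_excluded`
#' @export
te_tss_distance_hist <- function(tes, genes, bin_width = 1000L) {
  dists <- rep(NA_integer_, nrow(tes))
  gene_idx <- rep(NA_integer_, nrow(tes))
  for (i in seq_len(nrow(tes))) {
    g <- which(genes$chrom == tes$chrom[i])
    if (length(g) == 0L) next
    mid <- (tes$start[i] + tes$end[i]) %/% 2L
    ad <- abs(genes$tss[g] - mid)
    cand <- g[ad == min(ad)]
    j <- cand[which.min(genes$tss[cand])]
    raw <- mid - genes$tss[j]
    dists[i] <- if (genes$strand[j] == "-") -raw else raw
    gene_idx[i] <- j
  }
  ok <- !is.na(dists)
  d <- dists[ok]
  bin <- floor(d / bin_width)
  tb <- table(bin)
  bs <- as.integer(names(tb)) * as.integer(bin_width)
  list(hist = data.frame(bin_start = bs, bin_end = bs + as.integer(bin_width),
                         count = as.integer(tb)),
       distances = data.frame(instance_id = tes$instance_id[ok],
                              gene_id = genes$gene_id[gene_idx[ok]],
                              distance = d, stringsAsFactors = FALSE),
       n_excluded = sum(!ok))
}

#' Hypergeometric functional-category enrichment
#'
#' A generic category-enrichment test over a user-supplied gene-to-category
#' table: for each category, the one-sided hypergeometric upper-tail
#' probability of drawing `k` or more category genes when sampling `n` linked
#' genes from a background of `N` genes of which `K` are in the category,
#' with Benjamini-Hochberg correction across the categories of one gene set.
#' Categories with no background gene are skipped.
#'
#' @param genes character vector of tested (e.g. TE-linked) gene ids
#' @param categories data frame `gene_id`, `category`
#' @param background character vector of background gene ids; must contain
#'   every tested gene
#' @return data frame `category`, `k`, `K`, `n`, `N`, `p`, `q`
#' @export
functional_enrichment <- function(genes, categories, background) {
  genes <- unique(genes)
  background <- unique(background)
  if (!all(genes %in% background))
    stop("background must contain every tested gene")
  categories <- categories[categories$gene_id %in% background, , drop = FALSE]
  cats <- sort(unique(categories$category))
  N <- length(background)
  n <- length(genes)
  out <- lapply(cats, function(ct) {
    members <- unique(categories$gene_id[categories$category == ct])
    K <- length(members)
    k <- sum(genes %in% members)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = ct, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
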