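# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive n reproducible child seeds (< 2^31) from a master seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

DNA_BASES <- c("A", "C", "G", "T")

# Map a nucleotide string to integer codes A=1 C=2 G=3 T=4, anything else 5 (N).
# Vector-valued over the characters of one string.
encode_dna <- function(x) {
  lut <- rep.int(5L, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(x)]
}

decode_dna <- function(codes) {
  paste(c(DNA_BASES, "N")[codes], collapse = "")
}

# Encode equal-length strings into an n x L integer matrix (one row per sequence).
encode_dna_matrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == L))
  matrix(encode_dna(paste(seqs, collapse = "")), nrow = n, ncol = L, byrow = TRUE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Tab-separated writer with "#"-prefixed header line, matching the pipeline's
# plain-text output convention.
write_tsv_hash <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (line in comment) writeLines(paste0("# ", line), con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv_hash <- function(path, col_names) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  header <- if (length(hdr)) sub("^#", "", lines[hdr[length(hdr)]]) else NULL
  body <- if (length(hdr)) lines[-hdr] else lines
  if (length(body) == 0) {
    cols <- if (!is.null(header)) strsplit(header, "\t")[[1]] else col_names
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(header)) names(df) <- strsplit(header, "\t")[[1]]
  if (!missing(col_names)) names(df) <- col_names
  df
}
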