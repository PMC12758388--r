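# Shared fixtures and independent oracles, all built in code.

# A plus- or minus-strand toy gene with n equal exons (len 100) separated by
# introns (len 200), starting at genomic position `origin`.
toy_transcripts <- function(n_exons, strand = "+", gene_id = "G1",
                            origin = 1000L, exon_len = 100L,
                            intron_len = 200L, transcript_id = "T1") {
  starts <- origin + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  data.frame(gene_id = gene_id, transcript_id = transcript_id,
             chrom = "chrT", strand = strand,
             start = starts, end = starts + exon_len,
             stringsAsFactors = FALSE)
}

toy_model <- function(n_exons, strand = "+", ...) {
  build_gene_model(toy_transcripts(n_exons, strand, ...))
}

# Significant-record table for one gene from ladder indices and dPSI values.
toy_significant <- function(idx, dpsi, gene_id = "G1") {
  data.frame(gene_id = gene_id, exon_index = idx, delta_psi = dpsi,
             probability = 0.95, stringsAsFactors = FALSE)
}

# Independent brute-force oracle for block calling: enumerate every
# contiguous window of significant ladder exons, keep the valid ones
# (consecutive indices; chain-wise tolerance; optional shared sign), and
# retain those not contained in a larger valid window.
oracle_block_runs <- function(idx, dpsi, tol = 0.02, same_sign = TRUE) {
  ord <- order(idx)
  idx <- idx[ord]; dpsi <- dpsi[ord]
  n <- length(idx)
  valid <- function(i, j) {
    if (j > i && any(diff(idx[i:j]) != 1L)) return(FALSE)
    d <- dpsi[i:j]
    if (j > i && same_sign && length(unique(sign(d))) > 1L) return(FALSE)
    all(abs(diff(d)) <= tol)
  }
  wins <- list()
  for (i in seq_len(n)) for (j in i:n)
    if (valid(i, j)) wins[[length(wins) + 1L]] <- c(i, j)
  maximal <- Filter(function(r) {
    !any(vapply(wins, function(s)
      s[1L] <= r[1L] && s[2L] >= r[2L] && (s[2L] - s[1L] > r[2L] - r[1L]),
      logical(1)))
  }, wins)
  runs <- lapply(maximal, function(r) idx[r[1L]:r[2L]])
  runs[order(vapply(runs, `[`, numeric(1), 1L))]
}

run_key <- function(runs) vapply(runs, paste, character(1), collapse = ",")

# Random CIGAR built from a random op walk (always starts/ends aligned).
random_cigar <- function(max_ops = 12L) {
  n <- sample(1:max_ops, 1L)
  ops <- character(0)
  prev <- ""
  for (i in seq_len(n)) {
    pool <- c("M", "N", "D", "I", "S", "=", "X")
    if (i == 1L || i == n) pool <- c("M", "=", "X")
    op <- sample(pool, 1L)
    ops <- c(ops, op)
  }
  lens <- sample(1:300, length(ops), replace = TRUE)
  paste0(lens, ops, collapse = "")
}

# Reference span consumed by a CIGAR, straight from the op definitions.
cigar_ref_span <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub(".$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(len[op %in% c("M", "=", "X", "D", "N")])
}

# aligned_read built directly from segment spec, bypassing the CIGAR path
# (for tests that need exact geometry without parsing).
manual_read <- function(blocks, gaps, chrom = "chrT", read_id = "r") {
  structure(list(read_id = read_id, chrom = chrom,
                 start = min(blocks$start),
                 end = max(blocks$end),
                 blocks = blocks, gaps = gaps),
            class = "aligned_read")
}

# SAM-field data.frame row
sam_row <- function(read_id, pos, cigar, chrom = "chr1", flag = 0L) {
  data.frame(read_id = read_id, flag = flag, chrom = chrom, pos = pos,
             cigar = cigar, stringsAsFactors = FALSE)
}

# Reads encoding a chosen splicing efficiency for one intron: n_spliced
# junction reads and the rest boundary-crossing reads.
spi_reads <- function(intron_start, intron_end, n, n_spliced,
                      chrom = "chr1") {
  ilen <- intron_end - intron_start
  rows <- list()
  for (r in seq_len(n_spliced))
    rows[[length(rows) + 1L]] <- sam_row(sprintf("s%d", r),
                                         intron_start - 30L,
                                         sprintf("30M%dN30M", ilen), chrom)
  for (r in seq_len(n - n_spliced))
    rows[[length(rows) + 1L]] <- sam_row(sprintf("u%d", r),
                                         intron_start - 30L, "60M", chrom)
  reconstruct_geometries(do.call(rbind, rows))
}

# Write a synthetic MaxEnt-format table directory (real file layout, random
# probability values) and return its path plus the raw vectors for oracle
# recomputation.
synthetic_maxent_dir <- function(seed = 42L) {
  dir <- file.path(tempdir(), sprintf("maxent_%d", seed))
  dir.create(dir, showWarnings = FALSE)
  set.seed(seed)
  acc_lens <- c(7L, 7L, 7L, 7L, 7L, 3L, 4L, 3L, 4L)
  me2x5 <- stats::runif(4^7, 0.01, 100)
  writeLines(format(me2x5, digits = 12), file.path(dir, "me2x5"))
  acc <- lapply(acc_lens, function(l) stats::runif(4^l, 0.01, 100))
  for (i in seq_len(9L))
    writeLines(format(acc[[i]], digits = 12),
               file.path(dir, sprintf("me2x3acc%d", i)))
  list(dir = dir, me2x5 = me2x5, acc = acc)
}

random_mer <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
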