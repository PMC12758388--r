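#' Tokenize a CIGAR string
#'
#' @param cigar CIGAR string.
#' @return list with integer `len` and character `op` vectors.
#' @export
parse_cigar <- function(cigar) {
  if (!valid_cigar(cigar)) stop("invalid CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

#' Reconstruct reference-space alignment geometry from POS and CIGAR
#'
#' Walks the reference-consuming CIGAR operations left to right from the
#' 0-based alignment start. M/=/X consume reference and read (aligned);
#' D and N consume reference only (gap); I/S consume read only; H/P consume
#' neither. Adjacent D/N runs merge into one gap, and gaps shorter than
#' `min_gap` are reclassified as aligned-internal (indels, not splice gaps)
#' and absorbed into the surrounding aligned block.
#'
#' @param pos 0-based reference start.
#' @param cigar CIGAR string.
#' @param chrom reference name carried through (optional).
#' @param read_id read name carried through (optional).
#' @param min_gap minimum reference-gap length treated as a splice gap
#'   (default 20 nt; the smallest human introns are about 30 nt).
#' @return object of class `aligned_read`: list with `read_id`, `chrom`,
#'   `start`, `end` (reference span, 0-based half-open), `blocks` and `gaps`
#'   (data.frames with `start`,`end`), which alternate and tile
#'   `[start, end)` exactly.
#' @export
reconstruct_geometry <- function(pos, cigar, chrom = NA_character_,
                                 read_id = NA_character_, min_gap = 20L) {
  ops <- parse_cigar(cigar)
  consume_ref <- ops$op %in% c("M", "=", "X", "D", "N")
  is_gap <- ops$op %in% c("D", "N")
  len <- ops$len[consume_ref]
  gap <- is_gap[consume_ref]
  if (!length(len)) stop("CIGAR consumes no reference: ", cigar)

  # run-length merge of aligned/gap segments, then absorb short gaps
  repeat {
    r <- rle(gap)
    seg_len <- vapply(seq_along(r$lengths), function(i) {
      sum(len[sum(r$lengths[seq_len(i - 1L)]) + seq_len(r$lengths[i])])
    }, integer(1))
    seg_gap <- r$values
    short <- seg_gap & seg_len < min_gap
    # terminal gaps (D/N at the alignment edge) are degenerate; treat as
    # aligned so that blocks and gaps alternate starting/ending aligned
    short <- short | (seg_gap & (seq_along(seg_gap) %in%
                                   c(1L, length(seg_gap))))
    if (!any(short)) {
      len <- seg_len; gap <- seg_gap
      break
    }
    len <- seg_len
    gap <- seg_gap
    gap[short] <- FALSE
  }

  ends <- pos + cumsum(len)
  starts <- c(pos, ends[-length(ends)])
  blocks <- data.frame(start = starts[!gap], end = ends[!gap])
  gaps <- data.frame(start = starts[gap], end = ends[gap])
  structure(list(read_id = read_id, chrom = chrom, start = pos,
                 end = pos + sum(len), blocks = blocks, gaps = gaps),
            class = "aligned_read")
}

#' Reconstruct geometry for a table of alignments
#'
#' @param alignments data.frame from [read_alignments()].
#' @param min_gap see [reconstruct_geometry()].
#' @return list of `aligned_read` objects.
#' @export
reconstruct_geometries <- function(alignments, min_gap = 20L) {
  lapply(seq_len(nrow(alignments)), function(i)
    reconstruct_geometry(alignments$pos[i], alignments$cigar[i],
                         alignments$chrom[i], alignments$read_id[i],
                         min_gap = min_gap))
}

overlaps_any <- function(blocks, start, end) {
  any(blocks$start < end & blocks$end > start)
}

#' Classify reads of a locus as block-skipping or block-including
#'
#' A read is a SKIP read when one of its splice gaps matches the block's
#' skip junction within `tolerance_nt` at both ends. A read is an INCLUSION
#' read when it has an aligned segment overlapping at least one member exon
#' and aligned segments overlapping both flanking exons. All other reads are
#' uninformative and excluded from the denominator.
#'
#' @param reads list of `aligned_read` objects (same chromosome as the
#'   block's gene).
#' @param block one-row block data.frame with `first_index`, `last_index`,
#'   `skip_start`, `skip_end`.
#' @param model the gene's `gene_model`.
#' @param tolerance_nt allowed wobble of gap ends relative to the skip
#'   junction (default 8 nt, for long-read alignment imprecision).
#' @return list of class `block_skip_call` with `block_id`, `n_skip`,
#'   `n_inclusion`, `n_uninformative`, `percent_skip` (fraction; NA when no
#'   informative reads) and per-read `labels`.
#' @export
call_block_skip <- function(reads, block, model, tolerance_nt = 8L) {
  if (is.na(block$skip_start) || is.na(block$skip_end))
    stop("terminal block: no skip junction to test")
  members <- model$exons[seq(block$first_index, block$last_index), ,
                         drop = FALSE]
  up <- model$exons[block$first_index - 1L, ]
  down <- model$exons[block$last_index + 1L, ]

  labels <- vapply(reads, function(r) {
    if (!is.na(r$chrom) && !is.na(model$chrom) && r$chrom != model$chrom)
      return("uninformative")
    skip <- nrow(r$gaps) > 0L &&
      any(abs(r$gaps$start - block$skip_start) <= tolerance_nt &
            abs(r$gaps$end - block$skip_end) <= tolerance_nt)
    if (skip) return("skip")
    member_hit <- any(vapply(seq_len(nrow(members)), function(i)
      overlaps_any(r$blocks, members$start[i], members$end[i]), logical(1)))
    flank_hit <- overlaps_any(r$blocks, up$start, up$end) &&
      overlaps_any(r$blocks, down$start, down$end)
    if (member_hit && flank_hit) "inclusion" else "uninformative"
  }, character(1))

  n_skip <- sum(labels == "skip")
  n_incl <- sum(labels == "inclusion")
  structure(list(
    block_id = block$block_id,
    n_skip = n_skip, n_inclusion = n_incl,
    n_uninformative = sum(labels == "uninformative"),
    percent_skip = if (n_skip + n_incl > 0) n_skip / (n_skip + n_incl)
      else NA_real_,
    labels = labels
  ), class = "block_skip_call")
}

#' Count reads supporting a set of junctions
#'
#' From an SJ-tab table an exact coordinate match is required (short reads
#' are splice-aware aligned); from reconstructed reads a gap matching the
#' junction within `tolerance_nt` at both ends counts.
#'
#' @param junctions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open gap interval).
#' @param sj optional SJ table from [read_sj_tab()].
#' @param reads optional list of `aligned_read` objects.
#' @param tolerance_nt gap-end tolerance for read-based counting (default 0).
#' @return the `junctions` data.frame with an added `count` column.
#' @export
count_junction_reads <- function(junctions, sj = NULL, reads = NULL,
                                 tolerance_nt = 0L) {
  if (is.null(sj) == is.null(reads))
    stop("provide exactly one of 'sj' or 'reads'")
  counts <- integer(nrow(junctions))
  if (!is.null(sj)) {
    key <- paste(sj$chrom, sj$start, sj$end)
    jkey <- paste(junctions$chrom, junctions$start, junctions$end)
    hit <- match(jkey, key)
    counts <- ifelse(is.na(hit), 0L, sj$count[hit])
  } else {
    for (i in seq_len(nrow(junctions))) {
      counts[i] <- sum(vapply(reads, function(r) {
        (is.na(r$chrom) || r$chrom == junctions$chrom[i]) &&
          nrow(r$gaps) > 0L &&
          any(abs(r$gaps$start - junctions$start[i]) <= tolerance_nt &
                abs(r$gaps$end - junctions$end[i]) <= tolerance_nt)
      }, logical(1)))
    }
  }
  junctions$count <- as.integer(counts)
  junctions
}

#' Reads-per-million normalization
#'
#' @param count junction read count.
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return count x 1e6 / total_mapped.
#' @export
rpm <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count * 1e6 / total_mapped
}

#' Detection summary over junction counts per condition
#'
#' A junction is detected in a condition when its count reaches `min_reads`
#' in at least one sample of that condition.
#'
#' @param counts data.frame with one row per junction x sample: `junction_id`,
#'   `condition`, `sample`, `count`, `total_mapped`.
#' @param min_reads minimum read count for detection (default 1).
#' @return list with `fraction_detected` (named per condition),
#'   `fraction_detected_any`, and `rpm` (the input with an `rpm` column).
#' @export
detection_summary <- function(counts, min_reads = 1L) {
  counts$rpm <- rpm(counts$count, counts$total_mapped)
  detected_by <- function(sub) {
    hits <- tapply(sub$count >= min_reads, sub$junction_id, any)
    mean(hits)
  }
  by_cond <- vapply(split(counts, counts$condition), detected_by, numeric(1))
  any_cond <- detected_by(counts)
  list(fraction_detected = by_cond,
       fraction_detected_any = any_cond,
       rpm = counts)
}
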