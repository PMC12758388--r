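#' Read exon annotation from a GTF file
#'
#' Imports `exon` features and returns the exon table consumed by
#' [build_gene_models()]. GTF coordinates (1-based inclusive) are converted
#' to the package's internal 0-based half-open convention.
#'
#' @param path GTF file. `gene_id` and `transcript_id` attributes are
#'   required on every exon feature.
#' @return data.frame with `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("gene_id and transcript_id attributes are required on exon features")
  data.frame(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write an exon table to GTF
#'
#' @param transcripts exon data.frame (see [read_annotation_gtf()] for the
#'   schema; 0-based half-open coordinates).
#' @param path output GTF path.
#' @export
write_annotation_gtf <- function(transcripts, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start + 1L,
                              end = transcripts$end),
    strand = transcripts$strand
  )
  gr$type <- "exon"
  gr$source <- "exonblocks"
  gr$gene_id <- transcripts$gene_id
  gr$transcript_id <- transcripts$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# ---- differential PSI tables -------------------------------------------------

parse_rep_field <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), as.numeric)
}

#' Read an exon-level differential PSI table
#'
#' Two dialects are supported. `native` is this package's own round-trippable
#' schema with per-replicate PSI values as comma-separated lists and all PSI
#' quantities as fractions. `whippet_diff` is a Whippet-style `.diff` layout
#' (`Gene`, `Node`, `Coord`, `Strand`, `Psi_A`, `Psi_B`, `DeltaPsi`,
#' `Probability`) in which `DeltaPsi` is percent-scaled and `Coord` is
#' 1-based inclusive; values are converted on read. The sign convention is
#' normalized to treatment minus control in both dialects.
#'
#' @param path TSV file with a header.
#' @param dialect "native" or "whippet_diff".
#' @param treatment_first for `whippet_diff`: `Psi_A` is the treatment group
#'   (default TRUE); set FALSE to flip the stored DeltaPsi sign.
#' @return data.frame with `gene_id`, `exon_index`, `chrom`, `start`, `end`,
#'   `strand`, list-columns `psi_ctrl` and `psi_treat` (replicate fractions),
#'   `delta_psi` (fraction, treatment - control), `probability`, and
#'   `constitutive` (NA when the dialect does not carry it).
#' @export
read_diff_table <- function(path, dialect = c("native", "whippet_diff"),
                            treatment_first = TRUE) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "native") {
    req <- c("gene_id", "exon_index", "chrom", "start", "end", "strand",
             "psi_ctrl", "psi_treat", "delta_psi", "probability",
             "constitutive")
    miss <- setdiff(req, names(tab))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    out <- data.frame(
      gene_id = tab$gene_id, exon_index = as.integer(tab$exon_index),
      chrom = tab$chrom, start = as.integer(tab$start),
      end = as.integer(tab$end), strand = tab$strand,
      delta_psi = as.numeric(tab$delta_psi),
      probability = as.numeric(tab$probability),
      constitutive = as.logical(tab$constitutive),
      stringsAsFactors = FALSE
    )
    out$psi_ctrl <- parse_rep_field(tab$psi_ctrl)
    out$psi_treat <- parse_rep_field(tab$psi_treat)
  } else {
    req <- c("Gene", "Node", "Coord", "Strand", "Psi_A", "Psi_B", "DeltaPsi",
             "Probability")
    miss <- setdiff(req, names(tab))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    coord <- regmatches(tab$Coord,
                        regexec("^([^:]+):(\\d+)-(\\d+)$", tab$Coord))
    if (any(lengths(coord) != 4L)) stop("malformed Coord field")
    coord <- do.call(rbind, coord)
    dpsi <- as.numeric(tab$DeltaPsi) / 100   # dialect is percent-scaled
    if (!treatment_first) dpsi <- -dpsi
    out <- data.frame(
      gene_id = tab$Gene, exon_index = as.integer(tab$Node),
      chrom = coord[, 2L], start = as.integer(coord[, 3L]) - 1L,
      end = as.integer(coord[, 4L]), strand = tab$Strand,
      delta_psi = dpsi, probability = as.numeric(tab$Probability),
      constitutive = NA, stringsAsFactors = FALSE
    )
    ctrl <- if (treatment_first) tab$Psi_B else tab$Psi_A
    trt <- if (treatment_first) tab$Psi_A else tab$Psi_B
    out$psi_ctrl <- parse_rep_field(ctrl)
    out$psi_treat <- parse_rep_field(trt)
  }
  psi_all <- unlist(c(out$psi_ctrl, out$psi_treat))
  if (anyNA(psi_all) || any(psi_all < 0 | psi_all > 1)) {
    bad <- which(vapply(seq_len(nrow(out)), function(i) {
      v <- c(out$psi_ctrl[[i]], out$psi_treat[[i]])
      anyNA(v) || any(v < 0 | v > 1)
    }, logical(1)))
    stop("PSI outside [0,1] in row(s): ", paste(bad, collapse = ", "))
  }
  bad_p <- which(is.na(out$probability) | out$probability < 0 |
                   out$probability > 1)
  if (length(bad_p))
    stop("probability outside [0,1] in row(s): ", paste(bad_p, collapse = ", "))
  if (any(abs(out$delta_psi) > 1 + 1e-9))
    stop("|delta_psi| > 1: is the input percent-scaled in the wrong dialect?")
  out
}

#' Write a differential PSI table in the native dialect
#'
#' Inverse of `read_diff_table(dialect = "native")`; the round trip is the
#' identity on all fields.
#'
#' @param records diff table as returned by [read_diff_table()].
#' @param path output TSV path.
#' @export
write_diff_table <- function(records, path) {
  fmt_rep <- function(col) vapply(col, function(v)
    paste(format(v, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = ","), character(1))
  out <- data.frame(
    gene_id = records$gene_id, exon_index = records$exon_index,
    chrom = records$chrom, start = records$start, end = records$end,
    strand = records$strand,
    psi_ctrl = fmt_rep(records$psi_ctrl),
    psi_treat = fmt_rep(records$psi_treat),
    delta_psi = format(records$delta_psi, digits = 15, scientific = FALSE,
                       trim = TRUE),
    probability = format(records$probability, digits = 15,
                         scientific = FALSE, trim = TRUE),
    constitutive = records$constitutive,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- STAR SJ.out.tab ---------------------------------------------------------

#' Read a STAR-style SJ.out.tab junction count file
#'
#' The SJ.out.tab dialect stores the intron's first and last base 1-based
#' inclusive; these are converted to 0-based half-open gap intervals. Strand
#' codes 0/1/2 decode to NA/"+"/"-". Duplicate junction lines (e.g. merged
#' lanes) have their counts summed, with a warning.
#'
#' @param path 9-column tab-separated file without a header.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `count`
#'   (unique-read count, column 7) and `multi` (column 8).
#' @export
read_sj_tab <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "first", "last", "strand",
                                         "motif", "annotated", "unique",
                                         "multi", "overhang"))
  for (col in c("first", "last", "strand", "unique", "multi"))
    if (!is.numeric(tab[[col]]))
      stop("non-integer value in SJ.out.tab column '", col, "'")
  out <- data.frame(
    chrom = tab$chrom,
    start = as.integer(tab$first) - 1L,
    end = as.integer(tab$last),
    strand = c(NA, "+", "-")[tab$strand + 1L],
    count = as.integer(tab$unique),
    multi = as.integer(tab$multi),
    stringsAsFactors = FALSE
  )
  key <- paste(out$chrom, out$start, out$end)
  if (anyDuplicated(key)) {
    warning("duplicate junction lines in ", path, "; counts summed")
    out <- do.call(rbind, lapply(split(out, key), function(g) {
      g$count[1L] <- sum(g$count); g$multi[1L] <- sum(g$multi); g[1L, ]
    }))
    out <- out[order(out$chrom, out$start, out$end), ]
    rownames(out) <- NULL
  }
  out
}

#' Write junction counts in the STAR SJ.out.tab dialect
#'
#' @param sj data.frame as returned by [read_sj_tab()] (0-based half-open).
#' @param path output path.
#' @export
write_sj_tab <- function(sj, path) {
  strand_code <- ifelse(is.na(sj$strand), 0L, ifelse(sj$strand == "+", 1L, 2L))
  multi <- if (is.null(sj$multi)) 0L else sj$multi
  out <- data.frame(sj$chrom, sj$start + 1L, sj$end, strand_code,
                    0L, 0L, sj$count, multi, 0L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- SAM text ----------------------------------------------------------------

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

valid_cigar <- function(cigar) {
  !is.na(cigar) & cigar != "*" &
    grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
}

#' Read spliced alignments from a SAM text file
#'
#' Parses the alignment fields needed for gap geometry (QNAME, FLAG, RNAME,
#' POS, CIGAR) from headerful or headerless SAM text. Unmapped records
#' (FLAG 0x4) are skipped; secondary (0x100) and supplementary (0x800)
#' alignments are excluded by default. Records with an invalid CIGAR are
#' dropped with a warning. POS is converted to 0-based.
#'
#' @param path SAM text file.
#' @param keep_secondary keep secondary/supplementary alignments.
#' @return data.frame with `read_id`, `flag`, `chrom`, `pos` (0-based),
#'   `cigar`.
#' @export
read_alignments <- function(path, keep_secondary = FALSE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(read_id = character(0), flag = integer(0),
                      chrom = character(0), pos = integer(0),
                      cigar = character(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) stop("truncated SAM record in ", path)
  out <- data.frame(
    read_id = vapply(fields, `[[`, character(1), 1L),
    flag = as.integer(vapply(fields, `[[`, character(1), 2L)),
    chrom = vapply(fields, `[[`, character(1), 3L),
    pos = as.integer(vapply(fields, `[[`, character(1), 4L)) - 1L,
    cigar = vapply(fields, `[[`, character(1), 6L),
    stringsAsFactors = FALSE
  )
  out <- out[bitwAnd(out$flag, 0x4L) == 0L, ]
  if (!keep_secondary)
    out <- out[bitwAnd(out$flag, 0x100L) == 0L &
                 bitwAnd(out$flag, 0x800L) == 0L, ]
  bad <- !valid_cigar(out$cigar)
  if (any(bad)) {
    warning(sum(bad), " record(s) with invalid CIGAR dropped")
    out <- out[!bad, ]
  }
  rownames(out) <- NULL
  out
}

#' Write minimal SAM text
#'
#' Emits a headerful SAM file with `*` sequence/quality placeholders —
#' sufficient for gap-geometry analysis, which only uses POS and CIGAR.
#'
#' @param reads data.frame with `read_id`, `flag`, `chrom`, `pos` (0-based),
#'   `cigar`.
#' @param seqinfo data.frame with `name` and `length` for `@SQ` header lines.
#' @param path output path.
#' @export
write_sam <- function(reads, seqinfo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", seqinfo$name, seqinfo$length), con)
  if (nrow(reads))
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                       reads$read_id, reads$flag, reads$chrom,
                       reads$pos + 1L, reads$cigar), con)
  invisible(path)
}

# ---- BED ---------------------------------------------------------------------

#' Write an exon ladder as BED6
#'
#' @param model `gene_model`.
#' @param path output path; scores are 0 and names are `gene:index`.
#' @export
write_ladder_bed6 <- function(model, path) {
  ex <- model$exons
  lines <- sprintf("%s\t%d\t%d\t%s:%d\t0\t%s",
                   model$chrom, ex$start, ex$end, model$gene_id,
                   seq_len(nrow(ex)), model$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write called blocks as BED12
#'
#' One BED12 line per block spanning its member exons, with the members as
#' sub-blocks.
#'
#' @param blocks block data.frame from [call_blocks_all()].
#' @param models named list of `gene_model` objects.
#' @param path output path.
#' @export
write_blocks_bed12 <- function(blocks, models, path) {
  lines <- vapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    m <- models[[b$gene_id]]
    ex <- m$exons[seq(b$first_index, b$last_index), , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    span_start <- min(ex$start); span_end <- max(ex$end)
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            m$chrom, span_start, span_end, b$block_id,
            round(1000 * min(1, abs(b$mean_delta_psi))), m$strand,
            span_start, span_end, nrow(ex),
            paste(ex$end - ex$start, collapse = ","),
            paste(ex$start - span_start, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
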