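#' Build a collapsed, strand-aware gene model from annotated transcripts
#'
#' Collapses the exons of all transcripts of one gene into a single exon
#' "ladder" ordered transcriptionally (index 1 = 5'-most exon of the gene),
#' and derives the introns between consecutive ladder exons. Exons are
#' de-duplicated by exact coordinates; overlapping-but-unequal exon variants
#' are both retained as separate ladder entries.
#'
#' All coordinates are 0-based half-open genomic intervals.
#'
#' @param transcripts data.frame of exon rows with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand` ("+"/"-"), `start`, `end`
#'   (0-based half-open). All rows must belong to one gene on one
#'   chromosome and strand.
#' @return An object of class `gene_model`: a list with `gene_id`, `chrom`,
#'   `strand`, `exons` (data.frame `start`,`end` in transcriptional order),
#'   `introns` (data.frame `start`,`end`, one fewer row than exons; a row is
#'   NA when consecutive ladder exons overlap so no intron exists),
#'   `constitutive` (logical per exon) and `n_transcripts`.
#' @export
build_gene_model <- function(transcripts) {
  stopifnot(is.data.frame(transcripts), nrow(transcripts) >= 1L)
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(req, names(transcripts))
  if (length(missing_cols))
    stop("transcripts is missing columns: ", paste(missing_cols, collapse = ", "))
  if (length(unique(transcripts$gene_id)) != 1L)
    stop("all exon rows must share one gene_id")
  if (length(unique(transcripts$chrom)) != 1L)
    stop("all exons of a gene must be on one chromosome")
  if (length(unique(transcripts$strand)) != 1L)
    stop("mixed strands within one gene are not supported")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(transcripts$start < 0L) || any(transcripts$start >= transcripts$end))
    stop("exon intervals must satisfy 0 <= start < end")
  tx_sizes <- table(transcripts$transcript_id)
  if (any(tx_sizes == 0L)) stop("empty transcript")
  # within-transcript exons must not overlap
  by_tx <- split(transcripts[, c("start", "end")], transcripts$transcript_id)
  for (tx in by_tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) > 1L && any(tx$start[-1L] < tx$end[-nrow(tx)]))
      stop("overlapping exons within a transcript")
  }

  strand <- transcripts$strand[1L]
  ex <- unique(transcripts[, c("start", "end")])
  ex <- ex[order(ex$start, ex$end), , drop = FALSE]
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  rownames(ex) <- NULL

  n <- nrow(ex)
  if (n > 1L) {
    a <- ex[-n, , drop = FALSE]  # upstream exon (transcriptional)
    b <- ex[-1L, , drop = FALSE]
    if (strand == "+") {
      istart <- a$end; iend <- b$start
    } else {
      istart <- b$end; iend <- a$start
    }
    bad <- istart >= iend          # overlapping ladder variants: no intron
    istart[bad] <- NA_integer_
    iend[bad] <- NA_integer_
    introns <- data.frame(start = istart, end = iend)
  } else {
    introns <- data.frame(start = integer(0), end = integer(0))
  }

  structure(list(
    gene_id = transcripts$gene_id[1L],
    chrom = transcripts$chrom[1L],
    strand = strand,
    exons = ex,
    introns = introns,
    constitutive = rep(NA, n),
    n_transcripts = length(by_tx)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d exons, %d introns, %d transcripts\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), nrow(x$introns),
              x$n_transcripts))
  invisible(x)
}

#' Flag constitutive exons on a gene model
#'
#' An exon is constitutive when an exon with exactly its coordinates is
#' present in every annotated transcript of the gene.
#'
#' @param model `gene_model` built from the same transcripts.
#' @param transcripts the exon data.frame the model was built from.
#' @return The model with its `constitutive` logical vector filled in.
#' @export
classify_constitutive <- function(model, transcripts) {
  stopifnot(inherits(model, "gene_model"))
  tx_ids <- unique(transcripts$transcript_id)
  keys_by_tx <- lapply(tx_ids, function(id) {
    tx <- transcripts[transcripts$transcript_id == id, ]
    paste(tx$start, tx$end)
  })
  exon_keys <- paste(model$exons$start, model$exons$end)
  model$constitutive <- vapply(exon_keys, function(k) {
    all(vapply(keys_by_tx, function(ks) k %in% ks, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  model
}

#' Build gene models for a whole annotation
#'
#' @param transcripts exon data.frame covering any number of genes.
#' @param constitutive also classify constitutive exons (default TRUE).
#' @return Named list of `gene_model` objects, one per gene_id.
#' @export
build_gene_models <- function(transcripts, constitutive = TRUE) {
  lapply(split(transcripts, transcripts$gene_id), function(tx) {
    m <- build_gene_model(tx)
    if (constitutive) m <- classify_constitutive(m, tx) else m
    m
  })
}

#' Assign each ladder exon of a gene to an analysis category
#'
#' Block members are labelled by their position within the block
#' (`first_block`, `internal_block`, `last_block`; a two-exon block has a
#' first and a last member and no internal one). Significant exons that are
#' in no block are `single_regulated`; everything else is `non_regulated`.
#'
#' @param blocks data.frame of blocks for this gene (columns `first_index`,
#'   `last_index`), as produced by [call_blocks()]. Blocks must be disjoint.
#' @param significant_indices integer ladder indices of significant exons.
#' @param model `gene_model`.
#' @return data.frame with `exon_index` and `category`.
#' @export
categorize_exons <- function(blocks, significant_indices, model) {
  n <- nrow(model$exons)
  category <- rep("non_regulated", n)
  if (!is.null(blocks) && nrow(blocks)) {
    covered <- unlist(lapply(seq_len(nrow(blocks)), function(i)
      seq(blocks$first_index[i], blocks$last_index[i])))
    if (anyDuplicated(covered))
      stop("blocks are not disjoint: an exon is assigned to two blocks")
    for (i in seq_len(nrow(blocks))) {
      idx <- seq(blocks$first_index[i], blocks$last_index[i])
      category[idx] <- "internal_block"
      category[idx[1L]] <- "first_block"
      category[idx[length(idx)]] <- "last_block"
    }
  } else {
    covered <- integer(0)
  }
  singles <- setdiff(significant_indices, covered)
  category[singles] <- "single_regulated"
  data.frame(exon_index = seq_len(n), category = category,
             stringsAsFactors = FALSE)
}

# exon length helper (0-based half-open)
exon_lengths <- function(model) model$exons$end - model$exons$start
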