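#' Significance thresholds for differential exon inclusion
#'
#' Defaults follow the analysis convention for Whippet-style cassette-exon
#' calls: event probability at least 0.9 and a mean |dPSI| of at least 10%,
#' with neighboring exons considered coordinately affected when their dPSI
#' values differ by at most 0.02.
#'
#' @param min_probability minimum event probability (fraction).
#' @param min_abs_delta_psi minimum |dPSI| (fraction).
#' @param pair_tolerance maximal |dPSI difference| between coordinated
#'   neighbors (fraction).
#' @return list of class `significance_thresholds`.
#' @export
significance_thresholds <- function(min_probability = 0.9,
                                    min_abs_delta_psi = 0.10,
                                    pair_tolerance = 0.02) {
  stopifnot(min_probability >= 0, min_probability <= 1,
            min_abs_delta_psi >= 0, min_abs_delta_psi <= 1,
            pair_tolerance >= 0, pair_tolerance <= 1)
  structure(list(min_probability = min_probability,
                 min_abs_delta_psi = min_abs_delta_psi,
                 pair_tolerance = pair_tolerance),
            class = "significance_thresholds")
}

#' Filter a differential PSI table to significant exons
#'
#' Keeps records with `probability >= min_probability` and
#' `|delta_psi| >= min_abs_delta_psi` (both boundaries inclusive) and records
#' the direction of change: negative dPSI under treatment - control means the
#' exon is more skipped upon treatment.
#'
#' @param records diff table (see [read_diff_table()]).
#' @param thresholds [significance_thresholds()].
#' @return The significant subset with an added `direction` column
#'   ("more_skipped"/"more_included").
#' @export
filter_significant <- function(records, thresholds = significance_thresholds()) {
  keep <- records$probability >= thresholds$min_probability &
    abs(records$delta_psi) >= thresholds$min_abs_delta_psi
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$delta_psi < 0, "more_skipped", "more_included")
  rownames(out) <- NULL
  out
}

#' Enumerate within-gene pairs of significant exons
#'
#' Emits every unordered pair of significant exons of each gene, flagging
#' pairs on consecutive ladder indices as `adjacent` and pairs whose dPSI
#' values differ by at most `pair_tolerance` as `similar`.
#'
#' @param significant significant diff records (one gene or many).
#' @param thresholds [significance_thresholds()].
#' @return data.frame with `gene_id`, `exon_a`, `exon_b` (`exon_a < exon_b`),
#'   `dpsi_a`, `dpsi_b`, `adjacent`, `similar`.
#' @export
pair_exons <- function(significant, thresholds = significance_thresholds()) {
  empty <- data.frame(gene_id = character(0), exon_a = integer(0),
                      exon_b = integer(0), dpsi_a = numeric(0),
                      dpsi_b = numeric(0), adjacent = logical(0),
                      similar = logical(0), stringsAsFactors = FALSE)
  pieces <- lapply(split(significant, significant$gene_id), function(g) {
    if (nrow(g) < 2L) return(NULL)
    g <- g[order(g$exon_index), ]
    cmb <- utils::combn(nrow(g), 2L)
    data.frame(
      gene_id = g$gene_id[1L],
      exon_a = g$exon_index[cmb[1L, ]],
      exon_b = g$exon_index[cmb[2L, ]],
      dpsi_a = g$delta_psi[cmb[1L, ]],
      dpsi_b = g$delta_psi[cmb[2L, ]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(list(empty[, 1:5]), pieces))
  out$adjacent <- out$exon_b - out$exon_a == 1L
  out$similar <- abs(out$dpsi_a - out$dpsi_b) <= thresholds$pair_tolerance
  rownames(out) <- NULL
  out
}

#' Fraction of adjacent pairs among similarly affected pairs
#'
#' @param pairs output of [pair_exons()].
#' @return list with `n_similar`, `n_adjacent_similar`, `fraction_adjacent`.
#' @export
summarize_pairs <- function(pairs) {
  sim <- pairs[pairs$similar, , drop = FALSE]
  list(n_similar = nrow(sim),
       n_adjacent_similar = sum(sim$adjacent),
       fraction_adjacent = if (nrow(sim)) mean(sim$adjacent) else NA_real_)
}

# Chain validity of a candidate run of significant exons (already sorted by
# ladder index, consecutive indices assumed checked by the caller).
run_is_valid <- function(dpsi, tolerance, same_sign, all_pairs) {
  if (length(dpsi) < 2L) return(TRUE)
  if (same_sign && length(unique(sign(dpsi))) != 1L) return(FALSE)
  if (all_pairs) {
    max(dpsi) - min(dpsi) <= tolerance
  } else {
    all(abs(diff(dpsi)) <= tolerance)
  }
}

#' Call coordinated exon blocks within one gene
#'
#' A block is a maximal run of consecutive significant ladder exons in which
#' every consecutive pair shares the dPSI sign and differs in dPSI by at most
#' `pair_tolerance` (chain-wise rule; an all-pairs variant is available).
#' Runs of length one are returned separately as single regulated exons.
#'
#' @param significant significant diff records of one gene.
#' @param model the gene's `gene_model`.
#' @param thresholds [significance_thresholds()].
#' @param same_sign require a shared dPSI sign within a block (default TRUE).
#' @param all_pairs require the tolerance over all member pairs rather than
#'   consecutive pairs only (default FALSE).
#' @return list with `blocks` (data.frame: `gene_id`, `block_id`,
#'   `first_index`, `last_index`, `n_members`, `mean_delta_psi`,
#'   `frame_preserving`, `chrom`, `strand`, `skip_start`, `skip_end`) and
#'   `singles` (data.frame: `gene_id`, `exon_index`, `delta_psi`).
#' @export
call_blocks <- function(significant, model,
                        thresholds = significance_thresholds(),
                        same_sign = TRUE, all_pairs = FALSE) {
  stopifnot(inherits(model, "gene_model"))
  g <- significant[order(significant$exon_index), , drop = FALSE]
  tol <- thresholds$pair_tolerance

  runs <- list()
  if (nrow(g)) {
    cur <- 1L
    for (i in seq_len(nrow(g))[-1L]) {
      ok <- g$exon_index[i] == g$exon_index[i - 1L] + 1L &&
        run_is_valid(g$delta_psi[cur:i], tol, same_sign, all_pairs)
      if (!ok) {
        runs[[length(runs) + 1L]] <- cur:(i - 1L)
        cur <- i
      }
    }
    runs[[length(runs) + 1L]] <- cur:nrow(g)
  }

  sizes <- lengths(runs)
  singles <- do.call(rbind, lapply(runs[sizes == 1L], function(r)
    data.frame(gene_id = g$gene_id[r], exon_index = g$exon_index[r],
               delta_psi = g$delta_psi[r], stringsAsFactors = FALSE)))
  if (is.null(singles))
    singles <- data.frame(gene_id = character(0), exon_index = integer(0),
                          delta_psi = numeric(0), stringsAsFactors = FALSE)

  blocks <- do.call(rbind, lapply(runs[sizes >= 2L], function(r) {
    first <- g$exon_index[r[1L]]
    last <- g$exon_index[r[length(r)]]
    sj <- derive_skip_junction(first, last, model)
    lens <- exon_lengths(model)[first:last]
    data.frame(
      gene_id = g$gene_id[1L],
      block_id = sprintf("%s:%d-%d", g$gene_id[1L], first, last),
      first_index = first, last_index = last, n_members = length(r),
      mean_delta_psi = mean(g$delta_psi[r]),
      frame_preserving = sum(lens) %% 3L == 0L,
      chrom = model$chrom, strand = model$strand,
      skip_start = sj[1L], skip_end = sj[2L],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(blocks))
    blocks <- data.frame(gene_id = character(0), block_id = character(0),
                         first_index = integer(0), last_index = integer(0),
                         n_members = integer(0), mean_delta_psi = numeric(0),
                         frame_preserving = logical(0), chrom = character(0),
                         strand = character(0), skip_start = integer(0),
                         skip_end = integer(0), stringsAsFactors = FALSE)
  rownames(blocks) <- rownames(singles) <- NULL
  list(blocks = blocks, singles = singles)
}

#' Call blocks across a whole cohort of genes
#'
#' @param significant significant diff records (any number of genes).
#' @param models named list of `gene_model` objects.
#' @inheritParams call_blocks
#' @return list with combined `blocks` and `singles` data.frames.
#' @export
call_blocks_all <- function(significant, models,
                            thresholds = significance_thresholds(),
                            same_sign = TRUE, all_pairs = FALSE) {
  per_gene <- lapply(split(significant, significant$gene_id), function(g) {
    m <- models[[g$gene_id[1L]]]
    if (is.null(m)) stop("no gene model for ", g$gene_id[1L])
    call_blocks(g, m, thresholds, same_sign, all_pairs)
  })
  list(blocks = do.call(rbind, c(lapply(per_gene, `[[`, "blocks"),
                                 make.row.names = FALSE)),
       singles = do.call(rbind, c(lapply(per_gene, `[[`, "singles"),
                                  make.row.names = FALSE)))
}

#' Genomic interval of a block-skipping junction
#'
#' The block-skipping junction is the exon-exon junction formed when the
#' exons immediately upstream of and downstream from the block are spliced
#' together. Returned as the 0-based half-open genomic interval of the
#' excised region (identical for plus- and minus-strand genes with the same
#' genomic layout). Absent (NA) when the block touches the first or last
#' ladder exon, since no flanking exon exists on that side.
#'
#' @param first_index,last_index ladder indices of the block's first and
#'   last member (transcriptional order).
#' @param model `gene_model`.
#' @return integer vector `c(start, end)`, NA when absent.
#' @export
derive_skip_junction <- function(first_index, last_index, model) {
  n <- nrow(model$exons)
  if (first_index <= 1L || last_index >= n)
    return(c(NA_integer_, NA_integer_))
  up <- model$exons[first_index - 1L, ]    # transcriptional upstream flank
  down <- model$exons[last_index + 1L, ]
  if (model$strand == "+") {
    c(up$end, down$start)
  } else {
    c(down$end, up$start)
  }
}

#' Is a block frame-preserving?
#'
#' TRUE when the summed lengths of the member exons are divisible by three,
#' so that skipping the whole block preserves the reading frame.
#'
#' @param first_index,last_index member range (ladder indices).
#' @param model `gene_model`.
#' @export
frame_preserving <- function(first_index, last_index, model) {
  sum(exon_lengths(model)[first_index:last_index]) %% 3L == 0L
}

#' Summary statistics over a set of called blocks
#'
#' @param blocks combined block data.frame.
#' @param singles combined singles data.frame (optional, for the
#'   constitutive-fraction comparison).
#' @param models named list of gene models (needed for constitutive flags).
#' @return list with `n_blocks`, `n_genes`, `n_member_exons`,
#'   `fraction_two_exon`, `median_size_larger`, `mean_size_larger`,
#'   `mean_abs_delta_psi`, `fraction_frame_preserving`,
#'   `constitutive_fraction_blocks`, `constitutive_fraction_singles`.
#' @export
summarize_blocks <- function(blocks, singles = NULL, models = NULL) {
  if (is.null(blocks) || !nrow(blocks)) return(list(n_blocks = 0L))
  larger <- blocks$n_members[blocks$n_members > 2L]
  const_frac <- function(df, index_cols) {
    if (is.null(models) || is.null(df) || !nrow(df)) return(NA_real_)
    flags <- unlist(lapply(seq_len(nrow(df)), function(i) {
      m <- models[[df$gene_id[i]]]
      m$constitutive[seq(df[[index_cols[1L]]][i], df[[index_cols[2L]]][i])]
    }))
    mean(flags, na.rm = TRUE)
  }
  list(
    n_blocks = nrow(blocks),
    n_genes = length(unique(blocks$gene_id)),
    n_member_exons = sum(blocks$n_members),
    fraction_two_exon = mean(blocks$n_members == 2L),
    median_size_larger = if (length(larger)) stats::median(larger) else NA_real_,
    mean_size_larger = if (length(larger)) mean(larger) else NA_real_,
    mean_abs_delta_psi = mean(abs(blocks$mean_delta_psi)),
    fraction_frame_preserving = mean(blocks$frame_preserving),
    constitutive_fraction_blocks =
      const_frac(blocks, c("first_index", "last_index")),
    constitutive_fraction_singles = if (!is.null(singles) && nrow(singles))
      const_frac(cbind(singles, first_index = singles$exon_index,
                       last_index = singles$exon_index),
                 c("first_index", "last_index")) else NA_real_
  )
}

#' Write blocks and their properties as TSV
#'
#' @param blocks block data.frame.
#' @param path output path.
#' @export
write_blocks_tsv <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
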