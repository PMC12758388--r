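# Splice-site strength scoring: MaxEnt-table lookup when the canonical
# table files are supplied, otherwise a log-odds PWM trained on the
# annotation's own splice sites.

DONOR_LEN <- 9L      # 3 exonic + 6 intronic
ACCEPTOR_LEN <- 23L  # 20 intronic + 3 exonic

BASES <- c("A", "C", "G", "T")

seq_to_rows <- function(seqs) {
  do.call(rbind, strsplit(toupper(seqs), ""))
}

base4_index <- function(seqs) {
  # lexicographic (A<C<G<T) base-4 index of each sequence, 0-based
  rows <- seq_to_rows(seqs)
  codes <- matrix(match(rows, BASES) - 1L, nrow = nrow(rows))
  if (anyNA(codes)) stop("non-ACGT character in splice-site sequence")
  L <- ncol(codes)
  as.integer(codes %*% (4 ^ ((L - 1L):0)))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Train a position weight matrix splice model on observed sites
#'
#' Builds a log2-odds PWM per side (donor 9-mers: 3 exonic + 6 intronic nt;
#' acceptor 23-mers: 20 intronic + 3 exonic nt) with pseudocounts and a
#' uniform background. Training-site scores are stored so that percentile
#' thresholds (e.g. for the recursive-donor scan) can be derived.
#'
#' @param donor_seqs character vector of 9-mers (5'->3').
#' @param acceptor_seqs character vector of 23-mers (5'->3').
#' @param pseudocount added per base per position (default 1).
#' @param background per-base background probabilities (default uniform).
#' @return object of class `splice_model` with `kind = "pwm"`.
#' @export
train_pwm_model <- function(donor_seqs, acceptor_seqs, pseudocount = 1,
                            background = rep(0.25, 4)) {
  train_one <- function(seqs, len) {
    stopifnot(all(nchar(seqs) == len))
    rows <- seq_to_rows(seqs)
    pwm <- vapply(seq_len(len), function(j) {
      counts <- table(factor(rows[, j], levels = BASES))
      as.numeric(counts + pseudocount) /
        (length(seqs) + 4 * pseudocount)
    }, numeric(4))
    rownames(pwm) <- BASES
    pwm
  }
  names(background) <- BASES
  model <- structure(list(
    kind = "pwm",
    donor_pwm = train_one(donor_seqs, DONOR_LEN),
    acceptor_pwm = train_one(acceptor_seqs, ACCEPTOR_LEN),
    background = background
  ), class = "splice_model")
  model$donor_training_scores <-
    vapply(donor_seqs, score_site, numeric(1), side = "donor",
           model = model, USE.NAMES = FALSE)
  model$acceptor_training_scores <-
    vapply(acceptor_seqs, score_site, numeric(1), side = "acceptor",
           model = model, USE.NAMES = FALSE)
  model
}

#' Load MaxEnt splice-site score tables
#'
#' Reads the canonical maximum-entropy model files: `me2x5` (donor; one
#' probability ratio per line, indexed by the base-4 rank of the 9-mer with
#' the two consensus positions removed) and `me2x3acc1` .. `me2x3acc9`
#' (acceptor sub-models over fragments of the 23-mer with the two consensus
#' positions removed). Scoring with these tables reproduces the reference
#' implementation's scores exactly.
#'
#' @param dir directory containing `me2x5` and `me2x3acc1`..`me2x3acc9`.
#' @return object of class `splice_model` with `kind = "maxent_tables"`.
#' @export
load_maxent_tables <- function(dir) {
  read_tab <- function(name, expected) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("missing MaxEnt table file: ", p)
    v <- as.numeric(readLines(p))
    if (length(v) != expected)
      stop(name, ": expected ", expected, " values, got ", length(v))
    v
  }
  acc_lens <- c(7L, 7L, 7L, 7L, 7L, 3L, 4L, 3L, 4L)
  structure(list(
    kind = "maxent_tables",
    me2x5 = read_tab("me2x5", 4^7),
    me2x3acc = lapply(seq_len(9L), function(i)
      read_tab(paste0("me2x3acc", i), 4^acc_lens[i])),
    acc_frag_len = acc_lens
  ), class = "splice_model")
}

# consensus/background constants of the canonical donor and acceptor models
ME_BGD <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
ME5_CONS1 <- c(A = 0.0040, C = 0.0032, G = 0.9896, T = 0.0022)  # position 4
ME5_CONS2 <- c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884)  # position 5
ME3_CONS1 <- c(A = 0.9903, C = 0.0032, G = 0.0034, T = 0.0030)  # position 19
ME3_CONS2 <- c(A = 0.0027, C = 0.0037, G = 0.9905, T = 0.0030)  # position 20

maxent_score5 <- function(seq, model) {
  s <- strsplit(toupper(seq), "")[[1L]]
  cons <- (ME5_CONS1[s[4L]] * ME5_CONS2[s[5L]]) /
    (ME_BGD[s[4L]] * ME_BGD[s[5L]])
  rest <- paste(s[-c(4L, 5L)], collapse = "")
  log2(cons * model$me2x5[base4_index(rest) + 1L])
}

maxent_score3 <- function(seq, model) {
  s <- strsplit(toupper(seq), "")[[1L]]
  cons <- (ME3_CONS1[s[19L]] * ME3_CONS2[s[20L]]) /
    (ME_BGD[s[19L]] * ME_BGD[s[20L]])
  rest <- s[-c(19L, 20L)]                  # 21-mer
  frag <- function(from, len) paste(rest[from:(from + len - 1L)],
                                    collapse = "")
  fragments <- c(frag(1L, 7L), frag(8L, 7L), frag(15L, 7L),
                 frag(5L, 7L), frag(12L, 7L),
                 frag(5L, 3L), frag(8L, 4L), frag(12L, 3L), frag(15L, 4L))
  sc <- vapply(seq_len(9L), function(i)
    model$me2x3acc[[i]][base4_index(fragments[i]) + 1L], numeric(1))
  log2(cons * prod(sc[1:5]) / prod(sc[6:9]))
}

#' Score one splice-site sequence
#'
#' @param seq 9-mer (donor) or 23-mer (acceptor), 5'->3'.
#' @param side "donor" or "acceptor".
#' @param model `splice_model` from [train_pwm_model()] or
#'   [load_maxent_tables()].
#' @return numeric score (log2-odds-like units). NA with a warning when the
#'   sequence contains N.
#' @export
score_site <- function(seq, side = c("donor", "acceptor"), model) {
  side <- match.arg(side)
  len <- if (side == "donor") DONOR_LEN else ACCEPTOR_LEN
  if (nchar(seq) != len)
    stop("expected a ", len, "-mer for side '", side, "', got ",
         nchar(seq), " nt")
  seq <- toupper(seq)
  if (grepl("N", seq, fixed = TRUE)) {
    warning("sequence contains N; score undefined")
    return(NA_real_)
  }
  if (grepl("[^ACGT]", seq)) stop("non-ACGTN character in sequence")
  if (model$kind == "pwm") {
    pwm <- if (side == "donor") model$donor_pwm else model$acceptor_pwm
    s <- match(strsplit(seq, "")[[1L]], BASES)
    sum(log2(pwm[cbind(s, seq_along(s))] / model$background[s]))
  } else if (side == "donor") {
    unname(maxent_score5(seq, model))
  } else {
    unname(maxent_score3(seq, model))
  }
}

#' Extract donor/acceptor site sequences for every applicable ladder exon
#'
#' Donor 9-mer: last 3 exonic nt + first 6 intronic nt downstream (no donor
#' for the last ladder exon). Acceptor 23-mer: last 20 intronic nt + first 3
#' exonic nt (no acceptor for the first ladder exon). Minus-strand sequences
#' are reverse-complemented so motifs read 5'->3'.
#'
#' @param model `gene_model`.
#' @param genome named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param side "donor" or "acceptor".
#' @return data.frame `exon_index`, `seq`; exons at contig edges or without
#'   the required intron are skipped.
#' @export
extract_site_sequences <- function(model, genome, side = c("donor",
                                                           "acceptor")) {
  side <- match.arg(side)
  chrom_seq <- as.character(genome[[model$chrom]])
  chrom_len <- nchar(chrom_seq)
  n <- nrow(model$exons)
  plus <- model$strand == "+"
  rows <- lapply(seq_len(n), function(i) {
    has_down <- i < n && !is.na(model$introns$start[i])
    has_up <- i > 1L && !is.na(model$introns$start[i - 1L])
    if (side == "donor" && !has_down) return(NULL)
    if (side == "acceptor" && !has_up) return(NULL)
    ex <- model$exons[i, ]
    if (side == "donor") {
      # junction at the exon's transcriptional 3' end
      if (plus) { from <- ex$end - 3L; to <- ex$end + 6L; rc <- FALSE }
      else { from <- ex$start - 6L; to <- ex$start + 3L; rc <- TRUE }
    } else {
      # junction at the exon's transcriptional 5' end
      if (plus) { from <- ex$start - 20L; to <- ex$start + 3L; rc <- FALSE }
      else { from <- ex$end - 3L; to <- ex$end + 20L; rc <- TRUE }
    }
    if (from < 0L || to > chrom_len) {
      message("exon ", i, " of ", model$gene_id,
              " at contig edge; site skipped")
      return(NULL)
    }
    s <- substr(chrom_seq, from + 1L, to)
    if (rc) s <- revcomp(s)
    data.frame(exon_index = i, seq = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(exon_index = integer(0), seq = character(0))
  out
}

#' Scan an exon for a recursive 5' splice site
#'
#' After the upstream intron is spliced, the junction of the upstream exon's
#' last 3 nt with the candidate exon's first 6 nt reconstitutes a potential
#' donor 9-mer; a strong score there marks the exon as a candidate for
#' recursive splicing (resplicing that removes the exon). With MaxEnt tables
#' the conventional threshold is 5.52, which captures 90% of human canonical
#' 5' splice sites; with the PWM fallback the threshold is instead the 10th
#' percentile of the model's training donor scores (the equivalent
#' 90%-sensitivity point), labelled as such.
#'
#' @param exon_index candidate exon ladder index (> 1).
#' @param model `gene_model`.
#' @param genome named `DNAStringSet` / character chromosome sequences.
#' @param splice_model `splice_model`.
#' @param threshold MaxEnt-units threshold (default 5.52); ignored for PWM
#'   models unless `threshold_kind = "absolute"`.
#' @param threshold_kind "auto" (5.52 for MaxEnt, training percentile for
#'   PWM) or "absolute" (use `threshold` as given).
#' @return list of class `recursive_scan`: `exon_index`, `recursive_9mer`,
#'   `score`, `threshold`, `threshold_kind`, `above_threshold`.
#' @export
scan_recursive_5ss <- function(exon_index, model, genome, splice_model,
                               threshold = 5.52,
                               threshold_kind = c("auto", "absolute")) {
  threshold_kind <- match.arg(threshold_kind)
  if (exon_index <= 1L) stop("first ladder exon has no upstream neighbor")
  chrom_seq <- as.character(genome[[model$chrom]])
  up <- model$exons[exon_index - 1L, ]
  ex <- model$exons[exon_index, ]
  take <- function(from, to) substr(chrom_seq, from + 1L, to)
  if (model$strand == "+") {
    nine <- paste0(take(up$end - 3L, up$end), take(ex$start, ex$start + 6L))
  } else {
    nine <- paste0(revcomp(take(up$start, up$start + 3L)),
                   revcomp(take(ex$end - 6L, ex$end)))
  }
  score <- score_site(nine, "donor", splice_model)
  if (threshold_kind == "auto" && splice_model$kind == "pwm") {
    threshold <- stats::quantile(splice_model$donor_training_scores, 0.10,
                                 names = FALSE)
    kind_label <- "pwm_training_10th_percentile"
  } else {
    kind_label <- if (splice_model$kind == "maxent_tables" ||
                        threshold_kind == "absolute") "absolute"
      else "absolute"
  }
  structure(list(exon_index = exon_index, recursive_9mer = nine,
                 score = score, threshold = threshold,
                 threshold_kind = kind_label,
                 above_threshold = is.finite(score) && score > threshold),
            class = "recursive_scan")
}

#' Extract the EJC-footprint window of an exon
#'
#' The exon junction complex is deposited about 24 nt upstream of the
#' exon-exon junction; this returns the 10 nt (default) window centered on
#' the position `offset_nt` upstream of the exon's transcriptional 3' end,
#' as transcript-oriented sequence (reverse-complemented on minus strands).
#'
#' @param exon_index ladder index.
#' @param model `gene_model`.
#' @param genome named `DNAStringSet` / character chromosome sequences.
#' @param window_nt window width (default 10).
#' @param offset_nt distance of the window center from the 3' end
#'   (default 24).
#' @return the window sequence, or NA when the exon is too short (logged).
#' @export
extract_ejc_window <- function(exon_index, model, genome, window_nt = 10L,
                               offset_nt = 24L) {
  ex <- model$exons[exon_index, ]
  len <- ex$end - ex$start
  half_lo <- window_nt %/% 2L
  if (len < offset_nt + half_lo + 1L) {
    message("exon ", exon_index, " of ", model$gene_id,
            " too short for EJC window")
    return(NA_character_)
  }
  # transcript-relative 1-based center at len - offset_nt; window covers
  # 1-based positions [center - floor(w/2), center + ceiling(w/2) - 1]
  center <- len - offset_nt
  w_from <- center - half_lo - 1L     # 0-based inclusive
  w_to <- w_from + window_nt          # 0-based exclusive
  chrom_seq <- as.character(genome[[model$chrom]])
  if (model$strand == "+") {
    substr(chrom_seq, ex$start + w_from + 1L, ex$start + w_to)
  } else {
    revcomp(substr(chrom_seq, ex$end - w_to + 1L, ex$end - w_from))
  }
}

#' Compare a quantity between exon categories
#'
#' Runs a two-sided Mann-Whitney U test of every category against a
#' reference category and reports medians. No multiple-testing correction by
#' default; Benjamini-Hochberg available.
#'
#' @param values numeric vector (site scores, lengths, ...).
#' @param category character category per value.
#' @param reference reference category name (default "non_regulated").
#' @param adjust "none" (default) or "BH".
#' @return data.frame with `category`, `n`, `median`, `reference_median`,
#'   `p_value`; categories with fewer than 2 values are excluded (logged).
#' @export
compare_categories <- function(values, category,
                               reference = "non_regulated",
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  groups <- split(values, category)
  if (!reference %in% names(groups))
    stop("reference category '", reference, "' not present")
  ref <- groups[[reference]]
  others <- groups[setdiff(names(groups), reference)]
  keep <- vapply(others, length, integer(1)) >= 2L
  if (any(!keep))
    message("excluded category with < 2 values: ",
            paste(names(others)[!keep], collapse = ", "))
  others <- others[keep]
  if (!length(others)) stop("need at least 2 non-empty categories")
  out <- data.frame(
    category = names(others),
    n = vapply(others, length, integer(1)),
    median = vapply(others, stats::median, numeric(1)),
    reference_median = stats::median(ref),
    p_value = vapply(others, function(v)
      stats::wilcox.test(v, ref, exact = FALSE)$p.value, numeric(1)),
    stringsAsFactors = FALSE
  )
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

#' Train a PWM splice model from an annotation and genome
#'
#' Convenience wrapper: extracts every annotated donor and acceptor site
#' sequence across the gene models and trains the PWM fallback on them.
#'
#' @param models named list of `gene_model` objects.
#' @param genome named `DNAStringSet` / character chromosome sequences.
#' @inheritParams train_pwm_model
#' @return `splice_model` of kind "pwm".
#' @export
train_pwm_from_annotation <- function(models, genome, pseudocount = 1) {
  donors <- unlist(lapply(models, function(m)
    extract_site_sequences(m, genome, "donor")$seq))
  acceptors <- unlist(lapply(models, function(m)
    extract_site_sequences(m, genome, "acceptor")$seq))
  donors <- donors[!grepl("[^ACGT]", donors)]
  acceptors <- acceptors[!grepl("[^ACGT]", acceptors)]
  if (!length(donors) || !length(acceptors))
    stop("no usable splice-site sequences in the annotation")
  train_pwm_model(donors, acceptors, pseudocount = pseudocount)
}
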