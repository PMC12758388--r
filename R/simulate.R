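# Synthetic data generator with planted ground truth. Emulates the genomic
# structure the block analysis assumes: multi-exon genes on both strands,
# planted coordinated exon blocks flanked by long introns and weakened
# splice sites (block-internal introns short with consensus-strength sites),
# two-condition replicate PSI tables, isoform mixtures of block-inclusion
# vs block-skipping long reads, and nascent-style short reads encoding
# per-intron splicing efficiencies and pairwise intron order.

DONOR_CONSENSUS <- "CAGGTAAGT"                    # 3 exonic + 6 intronic
ACCEPTOR_CONSENSUS <- "TTTTTTTTTTTTTTTTTCAGGTC"   # 20 intronic + 3 exonic

#' Configuration of the synthetic-data generator
#'
#' Defaults define the package's reference simulation: 20 genes on both
#' strands, 8 planted two-to-three-exon blocks whose members shift by a mean
#' dPSI of -0.198 with tiny within-block spread, block-flanking introns long
#' with weakened splice sites, block-internal introns short with
#' consensus-strength sites and high splicing efficiency, and a 50%
#' block-skipping isoform fraction in the treatment long reads.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range of exons per gene.
#' @param exon_len integer range of exon lengths (nt).
#' @param intron_len_internal,intron_len_other,intron_len_flanking integer
#'   length ranges per intron class; flanking introns are the longest,
#'   block-internal the shortest.
#' @param n_blocks number of genes carrying one planted block each.
#' @param block_size integer range of planted block sizes (members).
#' @param block_size_probs sampling weights over the block-size range
#'   (default favors two-exon blocks 3:1, the dominant size class in
#'   cohort-scale block calls).
#' @param block_spec optional explicit data.frame (`gene`, `first_index`,
#'   `size`) overriding the random placement.
#' @param dpsi_block planted mean dPSI magnitude of block members (sign is
#'   negative: skipping upon treatment).
#' @param dpsi_gene_sd between-gene Gaussian spread of the block effect
#'   (magnitude kept above the significance threshold); gives within-gene
#'   exon pairs their shared, gene-specific effect size.
#' @param dpsi_noise_sd per-member Gaussian spread around the gene's block
#'   effect.
#' @param dpsi_block_spread maximal within-block range of planted member
#'   dPSI values (redrawn when exceeded); kept below the 0.02 coordination
#'   tolerance so planted blocks are coordinated by construction.
#' @param decoy_single_fraction probability that an eligible non-block exon
#'   is planted as a significant single-regulated decoy.
#' @param site_consensus_internal,site_consensus_other,site_consensus_flanking
#'   per-position probability of the consensus base at splice sites of each
#'   intron class (flanking sites are degenerate, i.e. weak).
#' @param spi_internal,spi_flanking,spi_other true splicing efficiency per
#'   intron class.
#' @param order_prob_default P(upstream intron spliced first) for exons with
#'   no class-determined order.
#' @param skip_fraction_ctrl,skip_fraction_treat fraction of long reads from
#'   the block-skipping isoform per condition.
#' @param n_long_reads long reads per gene per condition.
#' @param reads_per_intron nascent reads informative for each intron's SPI.
#' @param order_reads_per_exon order-informative nascent reads per exon.
#' @param skip_sj_reads_treat nascent block-skip junction reads planted in
#'   the treatment condition (0 in control).
#' @param n_replicates replicates per condition in the PSI table.
#' @param psi_rep_sd Gaussian replicate noise on PSI (truncated to the unit interval).
#' @param wobble maximal +/- jitter (nt) applied to long-read gap ends.
#' @param seed master RNG seed; every generator stage derives its stream
#'   from it, so identical configs give byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20L,
                       exons_per_gene = c(6L, 10L),
                       exon_len = c(80L, 200L),
                       intron_len_internal = c(80L, 160L),
                       intron_len_other = c(150L, 400L),
                       intron_len_flanking = c(800L, 2000L),
                       n_blocks = 8L,
                       block_size = c(2L, 3L),
                       block_size_probs = c(0.75, 0.25),
                       block_spec = NULL,
                       dpsi_block = 0.198,
                       dpsi_gene_sd = 0.05,
                       dpsi_noise_sd = 0.005,
                       dpsi_block_spread = 0.016,
                       decoy_single_fraction = 0.05,
                       site_consensus_internal = 0.95,
                       site_consensus_other = 0.85,
                       site_consensus_flanking = 0.55,
                       spi_internal = 0.9,
                       spi_flanking = 0.35,
                       spi_other = 0.7,
                       order_prob_default = 0.5,
                       skip_fraction_ctrl = 0,
                       skip_fraction_treat = 0.5,
                       n_long_reads = 200L,
                       reads_per_intron = 100L,
                       order_reads_per_exon = 60L,
                       skip_sj_reads_treat = 15L,
                       n_replicates = 3L,
                       psi_rep_sd = 0.003,
                       wobble = 0L,
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$dpsi_block, cfg$decoy_single_fraction,
             cfg$site_consensus_internal, cfg$site_consensus_other,
             cfg$site_consensus_flanking, cfg$spi_internal,
             cfg$spi_flanking, cfg$spi_other, cfg$order_prob_default,
             cfg$skip_fraction_ctrl, cfg$skip_fraction_treat)
  stopifnot(all(fracs >= 0 & fracs <= 1), cfg$n_blocks <= cfg$n_genes)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

sample_consensus <- function(consensus, frac) {
  s <- strsplit(consensus, "")[[1L]]
  mutate <- stats::runif(length(s)) >= frac
  s[mutate] <- vapply(which(mutate), function(i)
    sample(setdiff(BASES, s[i]), 1L), character(1))
  paste(s, collapse = "")
}

rint <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

# size-safe sampling (sample() on a length-1 numeric means 1:x)
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

#' Generate annotation, genome and truth manifest
#'
#' Builds the synthetic gene models described by the config, writes
#' consensus-strength splice-site sequences into the genome for
#' block-internal and other introns and degenerate (weak) variants for
#' block-flanking introns, and records the complete planted truth.
#'
#' @param config [sim_config()].
#' @return list of class `sim_annotation` with `config`, `transcripts`
#'   (exon data.frame), `genome` (`DNAStringSet`, one chromosome), `models`
#'   (gene models with constitutive flags) and `manifest` (list of
#'   data.frames: `blocks` with planted members and skip junctions,
#'   `introns` with class/length/efficiency, `exons` with category and
#'   order probability).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_ex <- rint(config$exons_per_gene, config$n_genes)
  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))

  # one planted block per gene for the first n_blocks genes (never touching
  # the first or last ladder exon so that a skip junction exists)
  if (is.null(config$block_spec)) {
    sizes_pool <- seq(config$block_size[1L], config$block_size[2L])
    block_spec <- do.call(rbind, lapply(seq_len(config$n_blocks), function(g) {
      size <- sizes_pool[sample.int(length(sizes_pool), 1L,
                                    prob = config$block_size_probs)]
      size <- min(size, n_ex[g] - 2L)
      first <- resample(seq(2L, n_ex[g] - size), 1L)
      data.frame(gene = gene_ids[g], first_index = first, size = size,
                 stringsAsFactors = FALSE)
    }))
  } else {
    block_spec <- config$block_spec
  }
  if (is.null(block_spec))
    block_spec <- data.frame(gene = character(0), first_index = integer(0),
                             size = integer(0), stringsAsFactors = FALSE)

  chrom <- "chr1"
  cursor <- 0L
  chrom_parts <- character(0)
  tx_rows <- list()
  intron_rows <- list()
  exon_rows <- list()

  cons_frac <- c(block_internal = config$site_consensus_internal,
                 other = config$site_consensus_other,
                 block_flanking = config$site_consensus_flanking)
  spi_truth <- c(block_internal = config$spi_internal,
                 other = config$spi_other,
                 block_flanking = config$spi_flanking)

  for (g in seq_len(config$n_genes)) {
    gid <- gene_ids[g]
    n <- n_ex[g]
    strand <- if (g %% 2L == 1L) "+" else "-"
    bs <- block_spec[block_spec$gene == gid, ]
    members <- if (nrow(bs)) seq(bs$first_index, bs$first_index + bs$size - 1L)
      else integer(0)

    icls <- rep("other", n - 1L)
    if (length(members)) {
      if (length(members) > 1L)
        icls[members[-length(members)]] <- "block_internal"
      icls[members[1L] - 1L] <- "block_flanking"
      icls[members[length(members)]] <- "block_flanking"
    }
    ilen <- integer(n - 1L)
    for (i in seq_len(n - 1L)) {
      rng <- switch(icls[i], block_internal = config$intron_len_internal,
                    block_flanking = config$intron_len_flanking,
                    config$intron_len_other)
      ilen[i] <- rint(rng)
    }
    elen <- rint(config$exon_len, n)

    ex_seq <- vapply(elen, random_dna, character(1))
    in_seq <- vapply(ilen, random_dna, character(1))
    for (i in seq_len(n - 1L)) {
      fr <- cons_frac[[icls[i]]]
      donor <- sample_consensus(DONOR_CONSENSUS, fr)
      acceptor <- sample_consensus(ACCEPTOR_CONSENSUS, fr)
      substr(ex_seq[i], elen[i] - 2L, elen[i]) <- substr(donor, 1L, 3L)
      substr(in_seq[i], 1L, 6L) <- substr(donor, 4L, 9L)
      substr(in_seq[i], ilen[i] - 19L, ilen[i]) <- substr(acceptor, 1L, 20L)
      substr(ex_seq[i + 1L], 1L, 3L) <- substr(acceptor, 21L, 23L)
    }

    # transcript-oriented offsets
    parts_len <- as.vector(rbind(elen, c(ilen, NA)))
    parts_len <- parts_len[!is.na(parts_len)]
    offsets <- cumsum(c(0L, parts_len[-length(parts_len)]))
    ex_off <- offsets[seq(1L, by = 2L, length.out = n)]
    in_off <- if (n > 1L) offsets[seq(2L, by = 2L, length.out = n - 1L)]
      else integer(0)
    L <- sum(parts_len)

    gene_seq <- paste(as.vector(rbind(ex_seq, c(in_seq, ""))), collapse = "")
    gap <- rint(c(500L, 1500L))
    gene_start <- cursor + gap
    chrom_parts <- c(chrom_parts, random_dna(gap),
                     if (strand == "+") gene_seq else revcomp(gene_seq))
    cursor <- gene_start + L

    to_genomic <- function(off, len) {
      if (strand == "+") gene_start + off
      else gene_start + (L - off - len)
    }
    ex_gstart <- to_genomic(ex_off, elen)
    in_gstart <- to_genomic(in_off, ilen)

    # transcripts: T1 all exons; T2 lacking one non-block internal exon
    t1 <- data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                     chrom = chrom, strand = strand,
                     start = ex_gstart, end = ex_gstart + elen,
                     stringsAsFactors = FALSE)
    droppable <- setdiff(seq(2L, n - 1L), members)
    tx_rows[[length(tx_rows) + 1L]] <- t1
    if (length(droppable)) {
      drop <- resample(droppable, 1L)
      t2 <- t1[-drop, ]
      t2$transcript_id <- paste0(gid, ".t2")
      tx_rows[[length(tx_rows) + 1L]] <- t2
    }

    if (n > 1L)
      intron_rows[[length(intron_rows) + 1L]] <- data.frame(
        gene_id = gid, intron_index = seq_len(n - 1L), chrom = chrom,
        strand = strand, start = in_gstart, end = in_gstart + ilen,
        length = ilen, class = icls,
        efficiency = unname(spi_truth[icls]),
        site_consensus = unname(cons_frac[icls]),
        stringsAsFactors = FALSE)

    category <- rep("non_regulated", n)
    if (length(members)) {
      category[members] <- "internal_block"
      category[members[1L]] <- "first_block"
      category[members[length(members)]] <- "last_block"
    }
    order_prob <- rep(NA_real_, n)
    for (e in seq(2L, n - 1L)) {
      u <- icls[e - 1L]; d <- icls[e]
      order_prob[e] <-
        if (u == "block_flanking" && d == "block_internal") 0
        else if (u == "block_internal" && d == "block_flanking") 1
        else config$order_prob_default
    }
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      gene_id = gid, exon_index = seq_len(n), chrom = chrom,
      strand = strand, start = ex_gstart, end = ex_gstart + elen,
      length = elen, category = category, order_prob = order_prob,
      stringsAsFactors = FALSE)
  }

  transcripts <- do.call(rbind, tx_rows)
  genome_seq <- paste(chrom_parts, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, chrom))
  models <- build_gene_models(transcripts)

  blocks <- if (!nrow(block_spec)) NULL
    else do.call(rbind, lapply(seq_len(nrow(block_spec)), function(i) {
    b <- block_spec[i, ]
    m <- models[[b$gene]]
    sj <- derive_skip_junction(b$first_index, b$first_index + b$size - 1L, m)
    data.frame(gene_id = b$gene, first_index = b$first_index,
               last_index = b$first_index + b$size - 1L, size = b$size,
               chrom = m$chrom, strand = m$strand,
               skip_start = sj[1L], skip_end = sj[2L],
               stringsAsFactors = FALSE)
  }))

  structure(list(config = config, transcripts = transcripts,
                 genome = genome, models = models,
                 manifest = list(blocks = blocks,
                                 introns = do.call(rbind, intron_rows),
                                 exons = do.call(rbind, exon_rows))),
            class = "sim_annotation")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Generate the two-condition differential PSI table
#'
#' Block members receive dPSI near `-dpsi_block` with within-block spread
#' set by `dpsi_noise_sd` and probability >= 0.9; a configured fraction of
#' eligible non-block exons become significant single-regulated decoys
#' (never adjacent to a block or to another decoy); all remaining exons get
#' near-zero dPSI with sub-threshold probability. Replicate PSI values are
#' consistent with the planted means, and the stored `delta_psi` is the
#' replicate-mean difference (treatment - control).
#'
#' @param config [sim_config()].
#' @param ann [generate_annotation()] output.
#' @return list with `table` (native diff-table data.frame, see
#'   [read_diff_table()]) and `truth` (per-exon planted status:
#'   "block", "decoy_single" or "background").
#' @export
generate_diff_table <- function(config, ann) {
  set.seed(config$seed + 101L)
  ex <- ann$manifest$exons
  n_rep <- config$n_replicates

  planted <- ifelse(ex$category %in% c("first_block", "internal_block",
                                       "last_block"), "block", "background")
  # decoy singles: eligible exons are non-block, not adjacent to a block
  for (gid in unique(ex$gene_id)) {
    idx <- which(ex$gene_id == gid)
    block_pos <- which(planted[idx] == "block")
    eligible <- setdiff(seq_along(idx),
                        unique(c(block_pos, block_pos - 1L, block_pos + 1L)))
    prev_decoy <- -2L
    for (e in eligible) {
      if (e - prev_decoy <= 1L) next
      if (stats::runif(1L) < config$decoy_single_fraction) {
        planted[idx[e]] <- "decoy_single"
        prev_decoy <- e
      }
    }
  }

  # gene-specific block effect magnitude, kept above the |dPSI| threshold
  gene_effect <- vapply(unique(ex$gene_id), function(g) {
    min(0.9, max(0.12, config$dpsi_block +
                   stats::rnorm(1L, 0, config$dpsi_gene_sd)))
  }, numeric(1))
  names(gene_effect) <- unique(ex$gene_id)

  n <- nrow(ex)
  dpsi <- numeric(n)
  prob <- numeric(n)
  # block members drawn jointly per block, with the within-block range
  # bounded so planted blocks are coordinated by construction
  if (!is.null(ann$manifest$blocks)) {
    for (bi in seq_len(nrow(ann$manifest$blocks))) {
      b <- ann$manifest$blocks[bi, ]
      rows <- which(ex$gene_id == b$gene_id &
                      ex$exon_index %in% seq(b$first_index, b$last_index))
      for (try in 1:100) {
        noise <- stats::rnorm(length(rows), 0, config$dpsi_noise_sd)
        if (max(noise) - min(noise) <= config$dpsi_block_spread) break
      }
      dpsi[rows] <- -gene_effect[[b$gene_id]] + noise
      prob[rows] <- stats::runif(length(rows), 0.905, 0.999)
    }
  }
  for (i in seq_len(n)) {
    if (planted[i] == "block") {
      # drawn above
    } else if (planted[i] == "decoy_single") {
      dpsi[i] <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.12, 0.35)
      prob[i] <- stats::runif(1L, 0.905, 0.999)
    } else {
      dpsi[i] <- stats::rnorm(1L, 0, 0.02)
      prob[i] <- stats::runif(1L, 0, 0.85)
    }
  }
  psi_ctrl_mean <- vapply(dpsi, function(d)
    stats::runif(1L, max(0.05, 0.02 - d), min(0.95, 0.98 - d)), numeric(1))
  psi_treat_mean <- clamp01(psi_ctrl_mean + dpsi)

  rep_draw <- function(mean) clamp01(stats::rnorm(n_rep, mean,
                                                  config$psi_rep_sd))
  psi_ctrl <- lapply(psi_ctrl_mean, rep_draw)
  psi_treat <- lapply(psi_treat_mean, rep_draw)
  delta <- vapply(seq_len(n), function(i)
    mean(psi_treat[[i]]) - mean(psi_ctrl[[i]]), numeric(1))

  const <- vapply(seq_len(n), function(i)
    ann$models[[ex$gene_id[i]]]$constitutive[ex$exon_index[i]], logical(1))

  tab <- data.frame(gene_id = ex$gene_id, exon_index = ex$exon_index,
                    chrom = ex$chrom, start = ex$start, end = ex$end,
                    strand = ex$strand, delta_psi = delta,
                    probability = prob, constitutive = const,
                    stringsAsFactors = FALSE)
  tab$psi_ctrl <- psi_ctrl
  tab$psi_treat <- psi_treat
  list(table = tab,
       truth = data.frame(gene_id = ex$gene_id, exon_index = ex$exon_index,
                          planted = planted, stringsAsFactors = FALSE))
}

make_cigar <- function(len, op) {
  keep <- len > 0L
  paste0(len[keep], op[keep], collapse = "")
}

# collapse consecutive identical ops, then render
segments_to_cigar <- function(len, op) {
  stopifnot(length(len) == length(op))
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (!length(len)) stop("empty alignment")
  r <- rle(op)
  out_len <- integer(length(r$lengths))
  pos <- 1L
  for (i in seq_along(r$lengths)) {
    out_len[i] <- sum(len[pos:(pos + r$lengths[i] - 1L)])
    pos <- pos + r$lengths[i]
  }
  make_cigar(out_len, r$values)
}

#' Simulate long reads from inclusion and block-skipping isoforms
#'
#' For each gene carrying a planted block, emits full-length reads drawn
#' from the block-inclusion isoform (all ladder exons) or the block-skipping
#' isoform (members excised; one large gap spanning flank-to-flank) at the
#' per-condition skip fraction. CIGARs are composed of M and N operations
#' matching the template geometry, with optional +/- `wobble` jitter on gap
#' ends to stress tolerance logic.
#'
#' @param config [sim_config()].
#' @param ann [generate_annotation()] output.
#' @return list with `reads` (SAM-field data.frame accepted by
#'   [write_sam()]; conditions "ctrl" and "treat" mixed, encoded in
#'   `condition`) and `truth` (per-read isoform label).
#' @export
simulate_long_reads <- function(config, ann) {
  set.seed(config$seed + 202L)
  out <- list(); truth <- list()
  n_blocks <- if (is.null(ann$manifest$blocks)) 0L
    else nrow(ann$manifest$blocks)
  for (bi in seq_len(n_blocks)) {
    b <- ann$manifest$blocks[bi, ]
    m <- ann$models[[b$gene_id]]
    ex <- m$exons[order(m$exons$start), , drop = FALSE]   # genomic order
    member_idx <- seq(b$first_index, b$last_index)
    member_rows <- m$exons[member_idx, , drop = FALSE]
    is_member <- paste(ex$start, ex$end) %in%
      paste(member_rows$start, member_rows$end)

    template <- function(keep) {
      exk <- ex[keep, , drop = FALSE]
      n <- nrow(exk)
      len <- integer(0); op <- character(0)
      for (i in seq_len(n)) {
        len <- c(len, exk$end[i] - exk$start[i]); op <- c(op, "M")
        if (i < n) {
          len <- c(len, exk$start[i + 1L] - exk$end[i]); op <- c(op, "N")
        }
      }
      list(pos = exk$start[1L], len = len, op = op)
    }
    incl <- template(rep(TRUE, nrow(ex)))
    skip <- template(!is_member)

    for (cond in c("ctrl", "treat")) {
      frac <- if (cond == "treat") config$skip_fraction_treat
        else config$skip_fraction_ctrl
      isoform <- ifelse(stats::runif(config$n_long_reads) < frac,
                        "skip", "inclusion")
      for (r in seq_len(config$n_long_reads)) {
        tpl <- if (isoform[r] == "skip") skip else incl
        len <- tpl$len; pos <- tpl$pos
        if (config$wobble > 0L) {
          gap_idx <- which(tpl$op == "N")
          for (gi in gap_idx) {
            d1 <- sample(-config$wobble:config$wobble, 1L)
            d2 <- sample(-config$wobble:config$wobble, 1L)
            len[gi - 1L] <- len[gi - 1L] + d1
            len[gi] <- len[gi] - d1 + d2
            len[gi + 1L] <- len[gi + 1L] - d2
          }
        }
        rid <- sprintf("%s_%s_r%04d", b$gene_id, cond, r)
        out[[length(out) + 1L]] <- data.frame(
          read_id = rid, flag = if (m$strand == "+") 0L else 16L,
          chrom = m$chrom, pos = pos,
          cigar = segments_to_cigar(len, tpl$op),
          condition = cond, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          read_id = rid, gene_id = b$gene_id, condition = cond,
          isoform = isoform[r], stringsAsFactors = FALSE)
      }
    }
  }
  list(reads = do.call(rbind, out), truth = do.call(rbind, truth))
}

#' Simulate nascent-RNA style short reads and junction counts
#'
#' Per intron, emits junction-spanning (spliced) and exon-intron
#' boundary-spanning (unspliced) reads at the intron's true efficiency; per
#' internal exon, emits order-informative reads spanning both flanking
#' introns with the upstream intron spliced first at the exon's true order
#' probability; in the treatment condition additionally plants
#' block-skipping junction reads. Also aggregates all splice gaps into an
#' SJ-tab style junction count table.
#'
#' @param config [sim_config()].
#' @param ann [generate_annotation()] output.
#' @param condition "ctrl" or "treat".
#' @param efficiency_override optional function(intron_row) -> efficiency,
#'   replacing the manifest truth (used for differential-SPI simulations).
#' @param order_prob_override optional function(exon_row) -> order
#'   probability.
#' @return list with `reads` (SAM-field data.frame), `sj` (junction count
#'   data.frame with `chrom`, `start`, `end`, `strand`, `count`),
#'   `total_mapped`, and `truth` (per-intron efficiency and per-exon order
#'   probability actually used).
#' @export
simulate_nascent_reads <- function(config, ann,
                                   condition = c("ctrl", "treat"),
                                   efficiency_override = NULL,
                                   order_prob_override = NULL) {
  condition <- match.arg(condition)
  set.seed(config$seed + 303L + (condition == "treat") * 1000L)
  anchor <- 30L
  reads <- list()
  add_read <- function(gid, what, i, pos, len, op, strand) {
    rid <- sprintf("%s_%s_%s_%04d", gid, condition, what, i)
    reads[[length(reads) + 1L]] <<- data.frame(
      read_id = rid, flag = if (strand == "+") 0L else 16L,
      chrom = "chr1", pos = pos, cigar = segments_to_cigar(len, op),
      stringsAsFactors = FALSE)
  }

  introns <- ann$manifest$introns
  eff_used <- numeric(nrow(introns))
  for (i in seq_len(nrow(introns))) {
    intr <- introns[i, ]
    eff <- if (is.null(efficiency_override)) intr$efficiency
      else efficiency_override(intr)
    eff_used[i] <- eff
    n <- config$reads_per_intron
    n_spliced <- stats::rbinom(1L, n, eff)
    ilen <- intr$end - intr$start
    for (r in seq_len(n_spliced))
      add_read(intr$gene_id, sprintf("spi%d_spl", intr$intron_index), r,
               intr$start - anchor, c(anchor, ilen, anchor),
               c("M", "N", "M"), intr$strand)
    for (r in seq_len(n - n_spliced))
      add_read(intr$gene_id, sprintf("spi%d_uns", intr$intron_index), r,
               intr$start - anchor, 2L * anchor, "M", intr$strand)
  }

  exons <- ann$manifest$exons
  order_used <- rep(NA_real_, nrow(exons))
  for (e in seq_len(nrow(exons))) {
    exr <- exons[e, ]
    if (is.na(exr$order_prob)) next
    p <- if (is.null(order_prob_override)) exr$order_prob
      else order_prob_override(exr)
    order_used[e] <- p
    gi <- introns[introns$gene_id == exr$gene_id, ]
    # transcriptional upstream/downstream flanking introns
    up <- gi[gi$intron_index == exr$exon_index - 1L, ]
    down <- gi[gi$intron_index == exr$exon_index, ]
    left <- if (up$start < down$start) up else down
    right <- if (up$start < down$start) down else up
    build <- function(left_spliced, right_spliced) {
      # segments: 20M, left intron, mid exon, right intron, 20M
      mid <- right$start - left$end
      len <- c(20L, left$end - left$start, mid,
               right$end - right$start, 20L)
      op <- c("M", if (left_spliced) "N" else "M", "M",
              if (right_spliced) "N" else "M", "M")
      list(pos = left$start - 20L, len = len, op = op)
    }
    n_inf <- config$order_reads_per_exon
    up_first <- stats::rbinom(n_inf, 1L, p) == 1L
    for (r in seq_len(n_inf)) {
      # "upstream spliced first": upstream intron spliced, downstream not
      us <- up_first[r]; ds <- !up_first[r]
      left_s <- if (identical(left$intron_index, up$intron_index)) us else ds
      right_s <- if (identical(right$intron_index, up$intron_index)) us else ds
      tpl <- build(left_s, right_s)
      add_read(exr$gene_id, sprintf("ord%d", exr$exon_index), r,
               tpl$pos, tpl$len, tpl$op, exr$strand)
    }
    # a few both-spliced reads: real data contains them; order-uninformative
    n_unf <- ceiling(0.1 * n_inf)
    for (r in seq_len(n_unf)) {
      tpl <- build(TRUE, TRUE)
      add_read(exr$gene_id, sprintf("ordu%d", exr$exon_index), r,
               tpl$pos, tpl$len, tpl$op, exr$strand)
    }
  }

  if (condition == "treat" && config$skip_sj_reads_treat > 0L &&
        !is.null(ann$manifest$blocks)) {
    for (bi in seq_len(nrow(ann$manifest$blocks))) {
      b <- ann$manifest$blocks[bi, ]
      if (is.na(b$skip_start)) next
      for (r in seq_len(config$skip_sj_reads_treat))
        add_read(b$gene_id, "skipj", r, b$skip_start - anchor,
                 c(anchor, b$skip_end - b$skip_start, anchor),
                 c("M", "N", "M"), b$strand)
    }
  }

  reads <- do.call(rbind, reads)
  # SJ tab: aggregate splice gaps over all emitted reads
  geoms <- reconstruct_geometries(reads)
  gaps <- do.call(rbind, lapply(geoms, function(g)
    if (nrow(g$gaps)) cbind(g$gaps, chrom = g$chrom) else NULL))
  sj <- if (!is.null(gaps)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(gaps))),
                            by = list(chrom = gaps$chrom, start = gaps$start,
                                      end = gaps$end), FUN = sum)
    agg$strand <- NA_character_
    agg[order(agg$start), c("chrom", "start", "end", "strand", "count")]
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), count = integer(0))
  }
  rownames(sj) <- NULL
  list(reads = reads, sj = sj, total_mapped = nrow(reads),
       truth = list(intron_efficiency = cbind(introns, used = eff_used),
                    exon_order_prob = cbind(exons, used = order_used)))
}

#' Run the full generator and write every artifact to a directory
#'
#' Writes GTF, FASTA, the native diff table, long-read and nascent SAM
#' files, SJ tabs per condition and a JSON truth manifest. Outputs are
#' byte-identical across runs with the same config.
#'
#' @param config [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with the in-memory objects: `ann`, `diff`,
#'   `long_reads`, `nascent` (per condition).
#' @export
simulate_all <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  diff <- generate_diff_table(config, ann)
  lr <- simulate_long_reads(config, ann)
  nasc <- lapply(c(ctrl = "ctrl", treat = "treat"), function(cond)
    simulate_nascent_reads(config, ann, cond))

  write_annotation_gtf(ann$transcripts, file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(ann$genome, file.path(dir, "genome.fa"))
  write_diff_table(diff$table, file.path(dir, "diff_table.tsv"))
  seqinfo <- data.frame(name = names(ann$genome),
                        length = Biostrings::width(ann$genome))
  write_sam(lr$reads, seqinfo, file.path(dir, "long_reads.sam"))
  for (cond in names(nasc)) {
    write_sam(nasc[[cond]]$reads, seqinfo,
              file.path(dir, sprintf("nascent_%s.sam", cond)))
    write_sj_tab(nasc[[cond]]$sj, file.path(dir, sprintf("sj_%s.tab", cond)))
  }
  jsonlite::write_json(
    list(seed = config$seed,
         blocks = ann$manifest$blocks,
         introns = ann$manifest$introns,
         exons = ann$manifest$exons,
         diff_truth = diff$truth),
    file.path(dir, "truth_manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(list(ann = ann, diff = diff, long_reads = lr, nascent = nasc))
}
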