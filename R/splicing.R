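#' Per-intron splicing efficiency (SPI)
#'
#' SPI = spliced / (spliced + unspliced). A read is *spliced* for an intron
#' when one of its splice gaps matches the intron coordinates exactly; it is
#' *unspliced* when an aligned segment crosses the 5' or 3' exon-intron
#' boundary contiguously with at least `min_overhang` nucleotides on both
#' sides of the boundary. SPI is reported only when the total informative
#' count reaches `min_cov`; otherwise the record is flagged low-coverage.
#'
#' @param intron list/row with `chrom`, `start`, `end` (0-based half-open).
#' @param reads list of `aligned_read` objects.
#' @param min_cov minimum spliced+unspliced count (default 10).
#' @param min_overhang minimum contiguous overhang on each side of a crossed
#'   boundary (default 3 nt).
#' @return list of class `spi_record`: `chrom`, `start`, `end`, `spliced`,
#'   `unspliced`, `spi` (NA when low coverage), `low_coverage`.
#' @export
compute_spi <- function(intron, reads, min_cov = 10L, min_overhang = 3L) {
  st <- intron$start; en <- intron$end
  spliced <- 0L; unspliced <- 0L
  for (r in reads) {
    if (!is.na(r$chrom) && !is.na(intron$chrom) && r$chrom != intron$chrom)
      next
    if (nrow(r$gaps) && any(r$gaps$start == st & r$gaps$end == en)) {
      spliced <- spliced + 1L
      next
    }
    crosses <- function(b) any(r$blocks$start <= b - min_overhang &
                                 r$blocks$end >= b + min_overhang)
    if (crosses(st) || crosses(en)) unspliced <- unspliced + 1L
  }
  total <- spliced + unspliced
  structure(list(chrom = intron$chrom, start = st, end = en,
                 spliced = spliced, unspliced = unspliced,
                 spi = if (total >= min_cov) spliced / total else NA_real_,
                 low_coverage = total < min_cov),
            class = "spi_record")
}

#' SPI for every intron of a gene model
#'
#' @param model `gene_model`.
#' @param reads list of `aligned_read` objects.
#' @inheritParams compute_spi
#' @return data.frame with one row per intron: `intron_index`, `chrom`,
#'   `start`, `end`, `spliced`, `unspliced`, `spi`, `low_coverage`.
#' @export
compute_spi_gene <- function(model, reads, min_cov = 10L, min_overhang = 3L) {
  n <- nrow(model$introns)
  rows <- lapply(seq_len(n), function(i) {
    intr <- list(chrom = model$chrom, start = model$introns$start[i],
                 end = model$introns$end[i])
    if (is.na(intr$start)) return(NULL)
    s <- compute_spi(intr, reads, min_cov, min_overhang)
    data.frame(intron_index = i, chrom = s$chrom, start = s$start,
               end = s$end, spliced = s$spliced, unspliced = s$unspliced,
               spi = s$spi, low_coverage = s$low_coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(intron_index = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      spliced = integer(0), unspliced = integer(0),
                      spi = numeric(0), low_coverage = logical(0))
  out
}

#' Differential splicing efficiency between two conditions
#'
#' Replicate SPI tables are pooled per condition into a 2x2 spliced/unspliced
#' count table; the p-value comes from a chi-square test with continuity
#' correction, or Fisher's exact test when any cell is below 5. dSPI is the
#' difference of replicate-mean SPI values (treatment - control). An intron
#' is significant at `p <= max_p` and `|dSPI| >= min_abs_delta`.
#'
#' @param ctrl,treat data.frames of per-replicate SPI rows for one intron
#'   (columns `spliced`, `unspliced`, `spi`, `low_coverage`).
#' @param max_p significance threshold on the raw p-value (default 0.01).
#' @param min_abs_delta minimum |dSPI| (default 0.10).
#' @return list of class `diff_spi`: `spi_ctrl`, `spi_treat`, `delta_spi`,
#'   `p_value`, `significant`, or NULL when either condition is entirely
#'   low-coverage.
#' @export
differential_spi <- function(ctrl, treat, max_p = 0.01,
                             min_abs_delta = 0.10) {
  ctrl_ok <- ctrl[!ctrl$low_coverage, , drop = FALSE]
  treat_ok <- treat[!treat$low_coverage, , drop = FALSE]
  if (!nrow(ctrl_ok) || !nrow(treat_ok)) {
    message("intron low-coverage in one condition; excluded")
    return(NULL)
  }
  tab <- matrix(c(sum(ctrl_ok$spliced), sum(ctrl_ok$unspliced),
                  sum(treat_ok$spliced), sum(treat_ok$unspliced)),
                nrow = 2L, byrow = TRUE)
  p <- if (any(tab < 5)) {
    stats::fisher.test(tab)$p.value
  } else {
    stats::chisq.test(tab, correct = TRUE)$p.value
  }
  spi_c <- mean(ctrl_ok$spi)
  spi_t <- mean(treat_ok$spi)
  delta <- spi_t - spi_c
  structure(list(spi_ctrl = spi_c, spi_treat = spi_t, delta_spi = delta,
                 p_value = p,
                 significant = p <= max_p & abs(delta) >= min_abs_delta),
            class = "diff_spi")
}

#' Categorize introns relative to called blocks
#'
#' Introns between block members are `block_internal`; the immediate
#' upstream and downstream introns of a block are `block_flanking`; all
#' remaining introns are `other`. An intron that is internal to one block
#' and flanking another is labelled internal (logged).
#'
#' @param blocks block data.frame for one gene (possibly empty).
#' @param model `gene_model`.
#' @return data.frame `intron_index`, `category`.
#' @export
categorize_introns <- function(blocks, model) {
  n <- nrow(model$introns)
  cat <- rep("other", n)
  flanking <- integer(0)
  internal <- integer(0)
  if (!is.null(blocks) && nrow(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      f <- blocks$first_index[i]; l <- blocks$last_index[i]
      internal <- c(internal, seq(f, l - 1L))       # introns f..l-1
      if (f - 1L >= 1L) flanking <- c(flanking, f - 1L)
      if (l <= n) flanking <- c(flanking, l)
    }
  }
  flanking <- unique(flanking)
  if (length(intersect(internal, flanking)))
    message("intron both internal and flanking; internal wins")
  flanking <- setdiff(flanking, internal)
  cat[flanking] <- "block_flanking"
  cat[unique(internal)] <- "block_internal"
  data.frame(intron_index = seq_len(n), category = cat,
             stringsAsFactors = FALSE)
}

#' Normalized SPI frequency histograms per intron category
#'
#' @param spi numeric SPI values.
#' @param category character category per value.
#' @param binwidth histogram bin width on the unit interval (default 0.05).
#' @return named list of histograms; each a data.frame `mid`, `frequency`
#'   summing to 1 (all-zero when the category is empty).
#' @export
spi_histograms <- function(spi, category, binwidth = 0.05) {
  breaks <- seq(0, 1, by = binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  lapply(split(spi, category), function(v) {
    v <- v[!is.na(v)]
    counts <- if (length(v))
      tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
               nbins = length(mids))
    else rep(0L, length(mids))
    freq <- if (sum(counts)) counts / sum(counts) else rep(0, length(mids))
    data.frame(mid = mids, frequency = freq)
  })
}

# spliced/unspliced/ambiguous status of one intron in one read
intron_status <- function(r, st, en, min_overhang = 3L) {
  if (nrow(r$gaps) && any(r$gaps$start == st & r$gaps$end == en))
    return("spliced")
  crosses <- function(b) any(r$blocks$start <= b - min_overhang &
                               r$blocks$end >= b + min_overhang)
  if (crosses(st) || crosses(en)) return("unspliced")
  "ambiguous"
}

#' Fraction of upstream intron spliced first (F_UPFI) for one exon
#'
#' Considers reads that span both flanking introns of the exon with an
#' unambiguous spliced/unspliced status for each (a gap exactly matching the
#' intron = spliced; contiguous coverage across an exon-intron boundary =
#' unspliced). Reads with the upstream intron spliced and the downstream one
#' unspliced count toward `n_up_first`; the reverse counts toward
#' `n_down_first`; both-spliced and both-unspliced reads carry no order
#' information.
#'
#' @param exon_index ladder index (transcriptional order); must have an
#'   upstream and a downstream intron.
#' @param reads list of `aligned_read` objects.
#' @param model `gene_model`.
#' @param min_informative minimum informative reads for a defined F_UPFI
#'   (default 5).
#' @param min_overhang boundary overhang for unspliced status (default 3).
#' @return list of class `fupfi_record`: `exon_index`, `n_up_first`,
#'   `n_down_first`, `f_upfi` (NA below `min_informative`).
#' @export
compute_fupfi <- function(exon_index, reads, model, min_informative = 5L,
                          min_overhang = 3L) {
  n_ex <- nrow(model$exons)
  if (exon_index <= 1L || exon_index >= n_ex)
    stop("no flanking intron pair for first/last ladder exon")
  up <- model$introns[exon_index - 1L, ]    # transcriptional upstream intron
  down <- model$introns[exon_index, ]
  if (anyNA(c(up$start, down$start)))
    stop("flanking intron undefined (overlapping exon variants)")
  n_up_first <- 0L; n_down_first <- 0L
  for (r in reads) {
    if (!is.na(r$chrom) && r$chrom != model$chrom) next
    su <- intron_status(r, up$start, up$end, min_overhang)
    sd <- intron_status(r, down$start, down$end, min_overhang)
    if (su == "ambiguous" || sd == "ambiguous") next
    if (su == "spliced" && sd == "unspliced") n_up_first <- n_up_first + 1L
    else if (su == "unspliced" && sd == "spliced")
      n_down_first <- n_down_first + 1L
    # both spliced / both unspliced: uninformative for order
  }
  tot <- n_up_first + n_down_first
  structure(list(exon_index = exon_index, n_up_first = n_up_first,
                 n_down_first = n_down_first,
                 f_upfi = if (tot >= min_informative) n_up_first / tot
                   else NA_real_),
            class = "fupfi_record")
}
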