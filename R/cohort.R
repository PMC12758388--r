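#' Permutation test for per-gene enrichment of splicing events
#'
#' Drops the observed number of events uniformly at random (with
#' replacement across events, i.e. multinomially) onto the quantified genes
#' and counts genes receiving at least `k` events. The one-sided p-value
#' uses the add-one estimator `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param event_gene_ids gene id per observed event (defines both the number
#'   of events and the observed statistic).
#' @param quantified_gene_ids ids of all quantified genes the events could
#'   have fallen on.
#' @param k minimum events per gene counted as "multi-event" (default 2).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (recorded in the result).
#' @param weights optional per-gene placement weights (e.g. quantified exon
#'   counts); uniform when NULL.
#' @return list of class `permutation_result`: `observed`,
#'   `null_distribution`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_gene_enrichment <- function(event_gene_ids, quantified_gene_ids,
                                        k = 2L, n_perm = 1000L, seed = 1L,
                                        weights = NULL) {
  stopifnot(length(event_gene_ids) >= 1L, length(quantified_gene_ids) >= 2L)
  n_events <- length(event_gene_ids)
  n_genes <- length(quantified_gene_ids)
  observed <- sum(table(event_gene_ids) >= k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    hits <- sample.int(n_genes, n_events, replace = TRUE, prob = weights)
    sum(tabulate(hits, nbins = n_genes) >= k)
  }, integer(1))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(observed = observed, null_distribution = null,
                 p_value = (1 + sum(null >= observed)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' Pearson correlation of dPSI over within-gene exon pairs
#'
#' Each unordered pair contributes once, oriented with the lower ladder
#' index first (the orientation [pair_exons()] already produces).
#'
#' @param pairs data.frame from [pair_exons()] (columns `dpsi_a`, `dpsi_b`).
#' @return Pearson r; NA with a warning when either margin has zero
#'   variance.
#' @export
paired_dpsi_correlation <- function(pairs) {
  ok <- is.finite(pairs$dpsi_a) & is.finite(pairs$dpsi_b)
  a <- pairs$dpsi_a[ok]; b <- pairs$dpsi_b[ok]
  if (length(a) < 2L) stop("need at least 2 pairs with finite dPSI")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Random-pairing control for the paired-dPSI correlation
#'
#' Draws pairs uniformly at random from the pooled significant-exon dPSI
#' values, ignoring gene membership (no exon is used twice within one pair),
#' and returns their Pearson correlation.
#'
#' @param dpsi_pool numeric dPSI values of all significant exons.
#' @param n_pairs number of random pairs to draw.
#' @param seed RNG seed.
#' @return Pearson r; NA with a warning on zero variance.
#' @export
random_pairing_control <- function(dpsi_pool, n_pairs, seed = 1L) {
  stopifnot(length(dpsi_pool) >= 2L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  idx <- replicate(n_pairs, sample.int(length(dpsi_pool), 2L))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  pairs <- data.frame(dpsi_a = dpsi_pool[idx[1L, ]],
                      dpsi_b = dpsi_pool[idx[2L, ]])
  if (stats::sd(pairs$dpsi_a) == 0 || stats::sd(pairs$dpsi_b) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(pairs$dpsi_a, pairs$dpsi_b)
}

#' Relative enrichment of block events across RBP knockdowns
#'
#' For each RNA-binding-protein knockdown, the fraction of its regulated
#' alternative-splicing events that are exon blocks is divided by the median
#' fraction over all qualifying RBPs (those with at least one regulated
#' block event); the median RBP therefore maps to a relative enrichment of
#' exactly 1.
#'
#' @param tables data.frame with `rbp`, `cell_type`, `n_block_events` and
#'   `n_total_events` (total regulated events of all types).
#' @return data.frame with `rbp`, `cell_type`, `fraction_block`,
#'   `relative_enrichment` and `qualifying`; non-qualifying rows (zero block
#'   events) keep their fraction but get NA enrichment, and rows with zero
#'   total events are dropped (logged).
#' @export
rbp_block_enrichment <- function(tables) {
  if (any(tables$n_block_events > tables$n_total_events))
    stop("n_block_events exceeds n_total_events")
  zero_tot <- tables$n_total_events == 0L
  if (any(zero_tot)) {
    message("excluded RBP(s) with zero total events: ",
            paste(tables$rbp[zero_tot], collapse = ", "))
    tables <- tables[!zero_tot, , drop = FALSE]
  }
  if (!nrow(tables)) stop("no usable RBP tables")
  frac <- tables$n_block_events / tables$n_total_events
  qualifying <- tables$n_block_events >= 1L
  if (!any(qualifying)) stop("no RBP with at least one block event")
  med <- stats::median(frac[qualifying])
  data.frame(
    rbp = tables$rbp, cell_type = tables$cell_type,
    fraction_block = frac,
    relative_enrichment = ifelse(qualifying, frac / med, NA_real_),
    qualifying = qualifying,
    stringsAsFactors = FALSE
  )
}

#' Overlap bookkeeping between two identifier sets
#'
#' @param set_a,set_b character vectors of comparable ids (duplicates are
#'   collapsed).
#' @return list with `n_a`, `n_b`, `n_overlap`, `fraction_of_a`.
#' @export
overlap_report <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  ov <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_overlap = ov,
       fraction_of_a = if (length(a)) ov / length(a) else NA_real_)
}

#' Read a per-RBP event-count table
#'
#' @param path TSV with columns `rbp`, `cell_type`, `n_block_events`, and
#'   one or more `n_<event_type>` columns whose sum is the total event
#'   count (or a single `n_total_events` column).
#' @return data.frame suitable for [rbp_block_enrichment()].
#' @export
read_rbp_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("rbp", "cell_type", "n_block_events")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!"n_total_events" %in% names(tab)) {
    type_cols <- setdiff(grep("^n_", names(tab), value = TRUE),
                         "n_block_events")
    if (!length(type_cols)) stop("no event-type count columns found")
    tab$n_total_events <- rowSums(tab[, type_cols, drop = FALSE])
  }
  if (any(tab$n_block_events > tab$n_total_events))
    stop("n_block_events exceeds the summed event-type counts")
  tab
}
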