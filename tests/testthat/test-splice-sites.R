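test_that("PWM scoring behaves as a log-odds model", {
  set.seed(61)
  donors <- random_mer(30, 9)
  acceptors <- random_mer(30, 23)
  model <- train_pwm_model(donors, acceptors)
  # a PWM trained on a single sequence scores it maximally
  single <- train_pwm_model(rep("CAGGTAAGT", 2), acceptors)
  s_own <- score_site("CAGGTAAGT", "donor", single)
  for (other in random_mer(20, 9))
    expect_lte(score_site(other, "donor", single), s_own)
  # uniform matrix scores zero everywhere
  uniform <- model
  uniform$donor_pwm[] <- 0.25
  expect_equal(score_site("ACGTACGTA", "donor", uniform), 0)
  # contract errors
  expect_error(score_site("ACGT", "donor", model), "9-mer")
  expect_error(score_site("ACGTACGTB", "donor", model), "non-ACGTN")
  expect_warning(s <- score_site("ACGTNCGTA", "donor", model), "N")
  expect_true(is.na(s))
})

test_that("MaxEnt table scoring equals direct table recomputation", {
  syn <- synthetic_maxent_dir(71)
  model <- load_maxent_tables(syn$dir)
  bgd <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
  c5a <- c(A = 0.0040, C = 0.0032, G = 0.9896, T = 0.0022)
  c5b <- c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884)
  c3a <- c(A = 0.9903, C = 0.0032, G = 0.0034, T = 0.0030)
  c3b <- c(A = 0.0027, C = 0.0037, G = 0.9905, T = 0.0030)
  idx <- function(s) {   # base-4 rank, recomputed independently
    v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
    sum(v * 4 ^ rev(seq_along(v) - 1L)) + 1L
  }
  set.seed(72)
  for (s in random_mer(25, 9)) {
    ch <- strsplit(s, "")[[1]]
    expected <- log2(c5a[ch[4]] * c5b[ch[5]] / (bgd[ch[4]] * bgd[ch[5]]) *
                       syn$me2x5[idx(paste(ch[-c(4, 5)], collapse = ""))])
    expect_equal(score_site(s, "donor", model), unname(expected))
  }
  for (s in random_mer(25, 23)) {
    ch <- strsplit(s, "")[[1]]
    rest <- ch[-c(19, 20)]
    sub <- function(from, len) paste(rest[from:(from + len - 1)],
                                     collapse = "")
    num <- syn$acc[[1]][idx(sub(1, 7))] * syn$acc[[2]][idx(sub(8, 7))] *
      syn$acc[[3]][idx(sub(15, 7))] * syn$acc[[4]][idx(sub(5, 7))] *
      syn$acc[[5]][idx(sub(12, 7))]
    den <- syn$acc[[6]][idx(sub(5, 3))] * syn$acc[[7]][idx(sub(8, 4))] *
      syn$acc[[8]][idx(sub(12, 3))] * syn$acc[[9]][idx(sub(15, 4))]
    expected <- log2(c3a[ch[19]] * c3b[ch[20]] /
                       (bgd[ch[19]] * bgd[ch[20]]) * num / den)
    expect_equal(score_site(s, "acceptor", model), unname(expected))
  }
})

test_that("site sequence extraction follows the junction geometry on both strands", {
  cfg <- sim_config(n_genes = 4L, n_blocks = 2L, seed = 7L)
  ann <- generate_annotation(cfg)
  chrom <- as.character(ann$genome[["chr1"]])
  for (gid in names(ann$models)) {
    m <- ann$models[[gid]]
    donors <- extract_site_sequences(m, ann$genome, "donor")
    acceptors <- extract_site_sequences(m, ann$genome, "acceptor")
    expect_equal(donors$exon_index, seq_len(nrow(m$exons) - 1L))
    expect_equal(acceptors$exon_index, seq(2L, nrow(m$exons)))
    for (k in seq_len(nrow(donors))) {
      i <- donors$exon_index[k]
      ex <- m$exons[i, ]
      expected <- if (m$strand == "+")
        substr(chrom, ex$end - 2L, ex$end + 6L)
      else as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(chrom, ex$start - 5L, ex$start + 3L))))
      expect_equal(donors$seq[k], expected)
    }
  }
})

test_that("annotation-planted donor sites carry the GT consensus signal", {
  cfg <- sim_config(n_genes = 6L, n_blocks = 3L, seed = 13L)
  ann <- generate_annotation(cfg)
  donors <- unlist(lapply(ann$models, function(m)
    extract_site_sequences(m, ann$genome, "donor")$seq))
  acceptors <- unlist(lapply(ann$models, function(m)
    extract_site_sequences(m, ann$genome, "acceptor")$seq))
  # consensus GT at intron positions +1/+2 dominates across classes
  expect_gt(mean(substr(donors, 4, 5) == "GT"), 0.6)
  expect_gt(mean(substr(acceptors, 19, 20) == "AG"), 0.6)
})

test_that("strand flip leaves every site score unchanged", {
  cfg <- sim_config(n_genes = 2L, n_blocks = 1L, seed = 19L)
  ann <- generate_annotation(cfg)
  sm <- train_pwm_from_annotation(ann$models, ann$genome)
  L <- Biostrings::width(ann$genome)[1]
  flipped_genome <- Biostrings::reverseComplement(ann$genome)
  names(flipped_genome) <- names(ann$genome)
  tx <- ann$transcripts
  new_start <- L - tx$end
  tx$end <- L - tx$start
  tx$start <- new_start
  tx$strand <- ifelse(tx$strand == "+", "-", "+")
  flipped_models <- build_gene_models(tx)
  for (gid in names(ann$models)) {
    for (side in c("donor", "acceptor")) {
      a <- extract_site_sequences(ann$models[[gid]], ann$genome, side)
      b <- extract_site_sequences(flipped_models[[gid]], flipped_genome, side)
      expect_equal(a$seq, b$seq)   # identical sequences => identical scores
    }
  }
})

test_that("recursive donor scan reconstructs the post-splicing 9-mer", {
  # genome engineered so the exon2 junction forms the trained consensus
  chrom <- paste0(strrep("A", 97), "CAG",           # exon1 (1..100) ends CAG
                  strrep("C", 200),                 # intron
                  "GTAAGT", strrep("A", 94),        # exon2 (301..400)
                  strrep("C", 200), strrep("A", 100))
  genome <- Biostrings::DNAStringSet(c(chrT = chrom))
  tx <- data.frame(gene_id = "G1", transcript_id = "T1", chrom = "chrT",
                   strand = "+", start = c(0L, 300L, 600L),
                   end = c(100L, 400L, 700L))
  m <- build_gene_model(tx)
  set.seed(91)
  # realistic training set: consensus donors with mild degeneracy
  variant <- function() {
    s <- strsplit("CAGGTAAGT", "")[[1]]
    mut <- runif(9) < 0.1
    s[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }
  sm <- train_pwm_model(replicate(100, variant()), random_mer(50, 23))
  r <- scan_recursive_5ss(2L, m, genome, sm)
  expect_equal(r$recursive_9mer, "CAGGTAAGT")
  expect_equal(r$threshold_kind, "pwm_training_10th_percentile")
  expect_true(r$above_threshold)   # consensus scores above the 10th pctile
  # a poly-A 9-mer under a GT-trained model stays below threshold
  tx_a <- tx  # same layout, but junction forms a poly-A 9-mer
  chrom_a <- paste0(strrep("A", 100), strrep("C", 200),
                    strrep("A", 100), strrep("C", 200), strrep("A", 100))
  genome_a <- Biostrings::DNAStringSet(c(chrT = chrom_a))
  r_a <- scan_recursive_5ss(2L, build_gene_model(tx_a), genome_a, sm)
  expect_false(r_a$above_threshold)
  # +Inf threshold can never be exceeded
  r_inf <- scan_recursive_5ss(2L, m, genome, sm, threshold = Inf,
                              threshold_kind = "absolute")
  expect_false(r_inf$above_threshold)
  expect_error(scan_recursive_5ss(1L, m, genome, sm), "upstream")
})

test_that("EJC window sits 24 nt upstream of the 3' end, strand-aware", {
  # exon of 100 nt with a marked decamer at positions 71-80
  marked <- paste0(strrep("A", 70), "GGGGGCCCCC", strrep("A", 20))
  chrom <- paste0(strrep("T", 50), marked, strrep("T", 50))
  genome <- Biostrings::DNAStringSet(c(chrT = chrom))
  tx <- data.frame(gene_id = "G1", transcript_id = "T1", chrom = "chrT",
                   strand = "+", start = 50L, end = 150L)
  m <- build_gene_model(tx)
  expect_equal(extract_ejc_window(1L, m, genome), "GGGGGCCCCC")
  # literal string-slice oracle
  expect_equal(extract_ejc_window(1L, m, genome), substr(marked, 71, 80))
  # minus strand: same transcript-relative window, reverse-complemented
  tx_m <- tx; tx_m$strand <- "-"
  rc_chrom <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
  genome_rc <- Biostrings::DNAStringSet(c(chrT = rc_chrom))
  tx_rc <- tx_m
  tx_rc$start <- nchar(chrom) - 150L
  tx_rc$end <- nchar(chrom) - 50L
  expect_equal(extract_ejc_window(1L, build_gene_model(tx_rc), genome_rc),
               "GGGGGCCCCC")
  # too-short exon
  tx_s <- tx; tx_s$end <- 70L
  expect_message(w <- extract_ejc_window(1L, build_gene_model(tx_s), genome),
                 "too short")
  expect_true(is.na(w))
})

test_that("category comparison reports Mann-Whitney p-values with exact U", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(10.1, 12.3, 9.8, 11.0, 13.3)
  # enumeration oracle for the U statistic
  u_oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  w <- wilcox.test(x, y, exact = FALSE)
  expect_equal(unname(w$statistic), u_oracle)
  res <- compare_categories(c(x, y), rep(c("a", "non_regulated"), each = 5))
  expect_equal(res$p_value, w$p.value)
  # identical distributions: p near 1, equal medians
  set.seed(101)
  v <- rnorm(100)
  res_same <- compare_categories(c(v, v), rep(c("a", "non_regulated"),
                                              each = 100))
  expect_gt(res_same$p_value, 0.9)
  expect_equal(res_same$median, res_same$reference_median)
  # large shift at n = 100 is overwhelming
  res_shift <- compare_categories(c(v + 10, v), rep(c("a", "non_regulated"),
                                                    each = 100))
  expect_lt(res_shift$p_value, 1e-3)
  # under-filled categories are excluded
  expect_message(
    res_ex <- compare_categories(c(v, v, 1), c(rep(c("a", "non_regulated"),
                                                   each = 100), "tiny")),
    "excluded")
  expect_false("tiny" %in% res_ex$category)
})
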