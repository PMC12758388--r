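test_that("SPI counts spliced and boundary-crossing reads correctly", {
  intr <- list(chrom = "chr1", start = 1000L, end = 1500L)
  reads <- spi_reads(1000L, 1500L, 100L, 90L)
  s <- compute_spi(intr, reads)
  expect_equal(s$spi, 0.9)
  expect_equal(s$spliced, 90L)

  s0 <- compute_spi(intr, spi_reads(1000L, 1500L, 50L, 0L))
  expect_equal(s0$spi, 0)

  low <- compute_spi(intr, spi_reads(1000L, 1500L, 7L, 4L))
  expect_true(low$low_coverage)
  expect_true(is.na(low$spi))

  # a gap at slightly different coordinates is not this intron's junction
  off <- reconstruct_geometries(sam_row("x", 969L, "30M501N30M"))
  expect_equal(compute_spi(intr, off, min_cov = 1L)$spliced, 0L)
  # an aligned block with < min_overhang beyond the boundary is not unspliced
  graze <- reconstruct_geometries(sam_row("g", 998L, "4M"))
  expect_equal(compute_spi(intr, graze, min_cov = 0L)$unspliced, 0L)
})

test_that("SPI recovers a planted efficiency within binomial error", {
  set.seed(41)
  hits <- 0L; trials <- 60L
  for (t in seq_len(trials)) {
    e <- sample(c(0.1, 0.5, 0.9), 1)
    n <- 100L
    k <- rbinom(1, n, e)
    s <- compute_spi(list(chrom = "chr1", start = 5000L, end = 5400L),
                     spi_reads(5000L, 5400L, n, k))
    if (abs(s$spi - e) <= 3 * sqrt(e * (1 - e) / n)) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.95)
})

test_that("differential SPI pools replicates and applies both thresholds", {
  mk <- function(spliced, unspliced) {
    data.frame(spliced = spliced, unspliced = unspliced,
               spi = spliced / (spliced + unspliced), low_coverage = FALSE)
  }
  # strong shift: ctrl 50/50 vs treat 90/10
  d <- differential_spi(mk(50L, 50L), mk(90L, 10L))
  expect_equal(d$delta_spi, 0.4)
  expect_true(d$significant)
  # identical counts: Fisher-style p of 1 when cells are small
  d2 <- differential_spi(mk(3L, 3L), mk(3L, 3L))
  expect_equal(d2$delta_spi, 0)
  expect_equal(d2$p_value, 1)
  expect_false(d2$significant)
  # small-cell path must equal the exact Fisher oracle
  d3 <- differential_spi(mk(3L, 20L), mk(12L, 8L))
  expect_equal(d3$p_value,
               fisher.test(matrix(c(3, 20, 12, 8), 2, byrow = TRUE))$p.value)
  # large shift in p but |dSPI| < 0.10 is not significant
  d4 <- differential_spi(mk(500L, 500L), mk(580L, 420L))
  expect_lt(d4$p_value, 0.01)
  expect_false(d4$significant)
  # low coverage in one condition excluded
  lc <- mk(2L, 1L); lc$low_coverage <- TRUE
  expect_message(out <- differential_spi(lc, mk(50L, 50L)), "low-coverage")
  expect_null(out)
})

test_that("intron categories partition the ladder with internal precedence", {
  m <- toy_model(7)
  blocks <- data.frame(first_index = 3L, last_index = 5L)
  cats <- categorize_introns(blocks, m)
  expect_equal(cats$category,
               c("other", "block_flanking", "block_internal",
                 "block_internal", "block_flanking", "other"))
  # no blocks: all other
  expect_true(all(categorize_introns(NULL, m)$category == "other"))
  # adjacent blocks sharing an intron: shared intron flanking once
  two <- data.frame(first_index = c(2L, 4L), last_index = c(3L, 5L))
  cats2 <- categorize_introns(two, m)
  expect_equal(sum(cats2$category == "block_flanking"), 3L)
  expect_equal(cats2$category[3L], "block_flanking")  # shared intron
  # every intron gets exactly one label
  expect_equal(nrow(cats2), nrow(m$introns))
})

test_that("SPI histograms are normalized per category", {
  h <- spi_histograms(c(0.9), c("a"))
  expect_equal(sum(h$a$frequency), 1)
  expect_equal(h$a$frequency[h$a$mid == 0.925], 1)  # 0.9 is a bin boundary
  h2 <- spi_histograms(c(0, 1, NA), c("b", "b", "b"))
  expect_equal(sort(h2$b$frequency[h2$b$frequency > 0]), c(0.5, 0.5))
  h3 <- spi_histograms(numeric(0), character(0))
  expect_length(h3, 0L)
})

test_that("F_UPFI counts order-informative reads and matches planted order", {
  m <- toy_model(5)      # exon len 100, intron len 200
  up <- m$introns[1, ]; down <- m$introns[2, ]
  mk_order_read <- function(id, up_spliced, down_spliced) {
    ops <- c("M", if (up_spliced) "N" else "M", "M",
             if (down_spliced) "N" else "M", "M")
    lens <- c(20L, 200L, 100L, 200L, 20L)
    sam_row(id, up$start - 20L,
            paste0(lens, ops, collapse = ""), chrom = "chrT")
  }
  reads <- reconstruct_geometries(rbind(
    do.call(rbind, lapply(1:8, function(i) mk_order_read(paste0("a", i),
                                                         TRUE, FALSE))),
    do.call(rbind, lapply(1:2, function(i) mk_order_read(paste0("b", i),
                                                         FALSE, TRUE))),
    mk_order_read("c", TRUE, TRUE)))      # uninformative for order
  f <- compute_fupfi(2L, reads, m)
  expect_equal(f$n_up_first, 8L)
  expect_equal(f$n_down_first, 2L)
  expect_equal(f$f_upfi, 0.8)
  # extremes
  all_up <- reconstruct_geometries(do.call(rbind, lapply(1:10, function(i)
    mk_order_read(paste0("u", i), TRUE, FALSE))))
  expect_equal(compute_fupfi(2L, all_up, m)$f_upfi, 1)
  all_down <- reconstruct_geometries(do.call(rbind, lapply(1:10, function(i)
    mk_order_read(paste0("d", i), FALSE, TRUE))))
  expect_equal(compute_fupfi(2L, all_down, m)$f_upfi, 0)
  # below min_informative the estimate is withheld
  few <- reconstruct_geometries(do.call(rbind, lapply(1:3, function(i)
    mk_order_read(paste0("f", i), TRUE, FALSE))))
  expect_true(is.na(compute_fupfi(2L, few, m)$f_upfi))
  expect_error(compute_fupfi(1L, reads, m), "flanking intron")
})

test_that("F_UPFI recovers an intermediate order probability (binomial oracle)", {
  set.seed(53)
  cfg <- sim_config(n_genes = 2L, n_blocks = 2L, reads_per_intron = 0L,
                    order_reads_per_exon = 500L, seed = 53L)
  ann <- generate_annotation(cfg)
  nas <- simulate_nascent_reads(cfg, ann, "ctrl",
                                order_prob_override = function(ex) 0.7)
  for (gid in names(ann$models)) {
    m <- ann$models[[gid]]
    reads <- reconstruct_geometries(
      nas$reads[grepl(paste0("^", gid, "_"), nas$reads$read_id), ])
    for (e in 2:(nrow(m$exons) - 1L)) {
      f <- compute_fupfi(e, reads, m)
      n <- f$n_up_first + f$n_down_first
      expect_gte(n, 500L * 0.9)
      expect_lt(abs(f$f_upfi - 0.7), 3 * sqrt(0.7 * 0.3 / n))
    }
  }
})
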