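test_that("geometry reconstruction handles N, D, and sub-threshold gaps", {
  r <- reconstruct_geometry(100L, "50M700N50M")
  expect_equal(r$blocks, data.frame(start = c(100L, 850L),
                                    end = c(150L, 900L)))
  expect_equal(r$gaps, data.frame(start = 150L, end = 850L))

  # D is a gap like N when long enough
  r <- reconstruct_geometry(100L, "50M300D50M")
  expect_equal(r$gaps, data.frame(start = 150L, end = 450L))

  # short deletions are indels, not splice gaps
  r <- reconstruct_geometry(100L, "50M5D50M")
  expect_equal(nrow(r$gaps), 0L)
  expect_equal(r$blocks, data.frame(start = 100L, end = 205L))

  # adjacent D/N runs merge into one gap
  r <- reconstruct_geometry(100L, "10M15D30N10M")
  expect_equal(r$gaps, data.frame(start = 110L, end = 155L))

  # X and = are aligned ops
  r <- reconstruct_geometry(100L, "10M5X10=")
  expect_equal(r$blocks, data.frame(start = 100L, end = 125L))
  expect_error(reconstruct_geometry(100L, "10M5Q"), "invalid CIGAR")
})

test_that("geometry conservation holds on random CIGARs and matches an independent parser", {
  set.seed(17)
  for (i in 1:300) {
    cg <- random_cigar()
    r <- reconstruct_geometry(50L, cg, min_gap = 20L)
    span <- cigar_ref_span(cg)
    expect_equal(r$end - r$start, span)
    expect_equal(sum(r$blocks$end - r$blocks$start) +
                   sum(r$gaps$end - r$gaps$start), span)
    # blocks and gaps alternate and tile the span
    seg <- rbind(r$blocks, r$gaps)
    seg <- seg[order(seg$start), ]
    expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  }
  # cross-check splice gaps against GenomicAlignments on M/N-only CIGARs
  for (i in 1:50) {
    n_introns <- sample(1:4, 1)
    lens <- sample(25:500, 2 * n_introns + 1, replace = TRUE)
    ops <- rep(c("M", "N"), length.out = 2 * n_introns + 1)
    cg <- paste0(lens, ops, collapse = "")
    r <- reconstruct_geometry(1000L, cg)
    ref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cg, ops = "N", pos = 1001L)[[1]]
    expect_equal(r$gaps$start, IRanges::start(ref) - 1L)
    expect_equal(r$gaps$end, IRanges::end(ref))
  }
})

test_that("block-skip calls follow the junction-match and flank-coverage rules", {
  tx <- data.frame(gene_id = "G1", transcript_id = "T1", chrom = "chrT",
                   strand = "+", start = c(100L, 300L, 600L, 900L),
                   end = c(200L, 400L, 700L, 1000L))
  m <- build_gene_model(tx)
  block <- data.frame(block_id = "G1:2-3", first_index = 2L, last_index = 3L,
                      skip_start = 200L, skip_end = 900L)
  # exact skip gap
  skip_read <- reconstruct_geometry(100L, "100M700N100M", "chrT", "s")
  # full inclusion read with gaps only at annotated introns
  incl_read <- reconstruct_geometry(
    100L, "100M100N100M200N100M200N100M", "chrT", "i")
  # wobbled skip gap (3 nt both ends) still within tolerance 8
  wob <- reconstruct_geometry(100L, "103M694N100M", "chrT", "w")
  # read not touching the flanks
  uninf <- reconstruct_geometry(300L, "100M", "chrT", "u")
  call <- call_block_skip(list(skip_read, incl_read, wob, uninf), block, m)
  expect_equal(unname(call$labels),
               c("skip", "inclusion", "skip", "uninformative"))
  expect_equal(call$percent_skip, 2 / 3)

  term <- data.frame(block_id = "t", first_index = 1L, last_index = 2L,
                     skip_start = NA_integer_, skip_end = NA_integer_)
  expect_error(call_block_skip(list(skip_read), term, m), "terminal")
})

test_that("junction counting is exact for SJ tables, tolerant for reads", {
  j <- data.frame(chrom = "chr1", start = 200L, end = 900L)
  sj <- data.frame(chrom = "chr1", start = c(200L, 200L),
                   end = c(900L, 899L), count = c(12L, 99L))
  expect_equal(count_junction_reads(j, sj = sj)$count, 12L)
  expect_equal(count_junction_reads(
    data.frame(chrom = "chr1", start = 200L, end = 899L), sj = sj)$count, 99L)
  expect_equal(count_junction_reads(
    data.frame(chrom = "chr1", start = 1L, end = 50L), sj = sj)$count, 0L)

  reads <- list(reconstruct_geometry(100L, "100M703N100M", "chr1", "a"),
                reconstruct_geometry(100L, "100M700N100M", "chr1", "b"))
  expect_equal(count_junction_reads(j, reads = reads)$count, 1L)
  expect_equal(count_junction_reads(j, reads = reads,
                                    tolerance_nt = 8L)$count, 2L)
})

test_that("RPM scales counts per million and is conserved over junctions", {
  expect_equal(rpm(12, 1e6), 12)
  expect_equal(rpm(0, 5e6), 0)
  expect_equal(rpm(25, 5e6), 5)
  expect_error(rpm(1, 0), "total_mapped")
  set.seed(5)
  counts <- sample(0:50, 20, TRUE)
  total <- 3.7e6
  expect_equal(sum(rpm(counts, total)), 1e6 * sum(counts) / total)
})

test_that("detection summary applies the min-read rule per condition", {
  counts <- data.frame(
    junction_id = rep(c("j1", "j2", "j3", "j4"), each = 2),
    condition = rep(c("ctrl", "treat"), 4),
    sample = "s1",
    count = c(0L, 1L, 0L, 2L, 0L, 3L, 0L, 0L),
    total_mapped = 1e6)
  s <- detection_summary(counts)
  expect_equal(unname(s$fraction_detected["treat"]), 0.75)
  expect_equal(unname(s$fraction_detected["ctrl"]), 0)
  s2 <- detection_summary(counts, min_reads = 2L)
  expect_equal(unname(s2$fraction_detected["treat"]), 0.5)
  zero <- counts; zero$count <- 0L
  expect_equal(unname(detection_summary(zero)$fraction_detected["treat"]), 0)
})
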