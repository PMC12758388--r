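cfg_small <- sim_config(n_genes = 4L, n_blocks = 2L, seed = 5L)

test_that("generated annotation matches the config and its own manifest", {
  ann <- generate_annotation(cfg_small)
  expect_length(ann$models, 4L)
  expect_setequal(unique(ann$transcripts$strand), c("+", "-"))
  expect_equal(nrow(ann$manifest$blocks), 2L)
  for (i in seq_len(nrow(ann$manifest$blocks))) {
    b <- ann$manifest$blocks[i, ]
    m <- ann$models[[b$gene_id]]
    # planted skip junction equals the model-derived one
    expect_equal(unname(derive_skip_junction(b$first_index, b$last_index, m)),
                 c(b$skip_start, b$skip_end))
  }
  # intron genomic intervals in the manifest equal the collapsed models
  for (gid in names(ann$models)) {
    mi <- ann$manifest$introns[ann$manifest$introns$gene_id == gid, ]
    m <- ann$models[[gid]]
    expect_equal(mi$start[order(mi$intron_index)], m$introns$start)
    expect_equal(mi$end[order(mi$intron_index)], m$introns$end)
  }
})

test_that("flanking introns are longer and weaker-sited than others by construction", {
  cfg <- sim_config(n_genes = 12L, n_blocks = 8L, seed = 21L)
  ann <- generate_annotation(cfg)
  introns <- ann$manifest$introns
  med <- tapply(introns$length, introns$class, median)
  expect_gt(med["block_flanking"], med["other"])
  expect_gt(med["other"], med["block_internal"])
})

test_that("identical configs give byte-identical simulation outputs", {
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  simulate_all(cfg_small, d1)
  simulate_all(cfg_small, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8L)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("diff table plants recoverable blocks and decoys stay single", {
  cfg <- sim_config(seed = 2L, decoy_single_fraction = 0.15,
                    dpsi_gene_sd = 0)    # sharp effect-scale check below
  ann <- generate_annotation(cfg)
  d <- generate_diff_table(cfg, ann)
  sig <- filter_significant(d$table)
  res <- call_blocks_all(sig, ann$models)
  key <- function(x, a, b) paste(x$gene_id, x[[a]], x[[b]])
  expect_setequal(key(res$blocks, "first_index", "last_index"),
                  key(ann$manifest$blocks, "first_index", "last_index"))
  # every decoy is recovered as single-regulated, never inside a block
  decoys <- d$truth[d$truth$planted == "decoy_single", ]
  expect_gt(nrow(decoys), 0L)
  expect_true(all(paste(decoys$gene_id, decoys$exon_index) %in%
                    paste(res$singles$gene_id, res$singles$exon_index)))
  # zero-noise table reproduces the planted mean |dPSI| scale
  s <- summarize_blocks(res$blocks, res$singles, ann$models)
  expect_lt(abs(s$mean_abs_delta_psi - cfg$dpsi_block), 0.01)
})

test_that("decoy-only tables yield no blocks", {
  cfg <- sim_config(n_genes = 6L, n_blocks = 0L, decoy_single_fraction = 0.3,
                    seed = 8L)
  ann <- generate_annotation(cfg)
  # no planted blocks: manifest empty, caller finds only singles
  expect_null(ann$manifest$blocks)
  d <- generate_diff_table(cfg, ann)
  sig <- filter_significant(d$table)
  res <- call_blocks_all(sig, ann$models)
  expect_true(is.null(res$blocks) || nrow(res$blocks) == 0L)
  expect_gt(nrow(res$singles), 0L)
})

test_that("long reads follow the configured skip fractions with exact CIGAR geometry", {
  cfg <- sim_config(n_genes = 4L, n_blocks = 2L, n_long_reads = 150L,
                    skip_fraction_treat = 0.5, seed = 31L)
  ann <- generate_annotation(cfg)
  lr <- simulate_long_reads(cfg, ann)
  expect_equal(nrow(lr$reads), 2L * 2L * 150L)
  # control has no skip reads at skip_fraction_ctrl = 0
  tr <- lr$truth
  expect_true(all(tr$isoform[tr$condition == "ctrl"] == "inclusion"))
  frac_treat <- mean(tr$isoform[tr$condition == "treat"] == "skip")
  expect_lt(abs(frac_treat - 0.5), 3 * sqrt(0.25 / 300))
  # a skip read's gap equals the planted junction exactly at wobble 0
  b <- ann$manifest$blocks[1, ]
  skip_ids <- tr$read_id[tr$gene_id == b$gene_id & tr$isoform == "skip"]
  one <- lr$reads[lr$reads$read_id == skip_ids[1], ]
  g <- reconstruct_geometry(one$pos, one$cigar, one$chrom, one$read_id)
  expect_true(any(g$gaps$start == b$skip_start & g$gaps$end == b$skip_end))
})

test_that("nascent SPI reads reproduce efficiency 1 exactly", {
  cfg <- sim_config(n_genes = 2L, n_blocks = 1L, reads_per_intron = 30L,
                    order_reads_per_exon = 0L, spi_internal = 1,
                    spi_flanking = 1, spi_other = 1, seed = 43L)
  ann <- generate_annotation(cfg)
  nas <- simulate_nascent_reads(cfg, ann, "ctrl")
  for (gid in names(ann$models)) {
    m <- ann$models[[gid]]
    reads <- reconstruct_geometries(
      nas$reads[grepl(paste0("^", gid, "_"), nas$reads$read_id), ])
    spi <- compute_spi_gene(m, reads)
    expect_true(all(spi$spi == 1))
  }
  # treatment-only skip-junction reads appear in the SJ table
  nas_t <- simulate_nascent_reads(cfg, ann, "treat")
  b <- ann$manifest$blocks[1, ]
  j <- data.frame(chrom = b$chrom, start = b$skip_start, end = b$skip_end)
  expect_equal(count_junction_reads(j, sj = nas$sj)$count, 0L)
  expect_equal(count_junction_reads(j, sj = nas_t$sj)$count,
               cfg$skip_sj_reads_treat)
})

test_that("planted intron-first order gives F_UPFI extremes at block edges", {
  cfg <- sim_config(n_genes = 2L, n_blocks = 1L, reads_per_intron = 0L,
                    order_reads_per_exon = 40L, seed = 43L)
  ann <- generate_annotation(cfg)
  nas <- simulate_nascent_reads(cfg, ann, "ctrl")
  b <- ann$manifest$blocks[1, ]
  m <- ann$models[[b$gene_id]]
  reads <- reconstruct_geometries(
    nas$reads[grepl(paste0("^", b$gene_id, "_"), nas$reads$read_id), ])
  expect_equal(compute_fupfi(b$first_index, reads, m)$f_upfi, 0)
  expect_equal(compute_fupfi(b$last_index, reads, m)$f_upfi, 1)
})
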