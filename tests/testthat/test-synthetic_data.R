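small_cfg <- function(seed = 17) {
  simulation_config(
    seed = seed, n_chromosomes = 1L, chrom_length_bp = 800000L,
    n_genes = 40L, n_fg_promoters = 20L, n_bg_promoters = 60L,
    de_group_sizes = c(up_10 = 4L, down_10 = 4L, up_30 = 4L, down_30 = 4L,
                       up_60 = 4L, down_60 = 4L),
    peak_counts = c(promoter = 25L, five_utr = 5L, exon = 20L, intron = 20L,
                    three_utr = 5L, intergenic = 25L))
}

test_that("one seed fixes every emitted file byte-for-byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_study(small_cfg(), dir = d1)
  s2 <- simulate_study(small_cfg(), dir = d2)
  for (f in c("genome.fa", "genes.gff3", "de_table.tsv", "peaks.bed")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  different <- simulate_study(small_cfg(seed = 18), dir = withr::local_tempdir())
  expect_false(identical(tools::md5sum(s1$fasta_path)[[1]],
                         tools::md5sum(different$fasta_path)[[1]]))
})

test_that("emitted annotations validate and round-trip through read_gff3", {
  dir <- withr::local_tempdir()
  s <- simulate_study(small_cfg(), dir = dir)
  back <- suppressWarnings(read_gff3(s$gff3_path))
  expect_equal(back$genes$gene_id, s$annotation$genes$gene_id)
  expect_equal(back$genes$start, s$annotation$genes$start)
  expect_equal(back$genes$strand, s$annotation$genes$strand)
  key <- function(f) f[order(f$gene_id, f$type, f$start),
                       c("gene_id", "type", "start", "end")]
  expect_equal(unname(as.list(key(back$features))),
               unname(as.list(key(s$annotation$features))))
})

test_that("mean emitted transcript length is within 5% of the target", {
  gen <- simulate_genome(simulation_config(seed = 91))
  tx <- gen$annotation$genes$tx_end - gen$annotation$genes$tx_start
  expect_equal(length(tx), 200L)
  expect_lt(abs(mean(tx) - 4500) / 4500, 0.05)
})

test_that("infeasible packing is rejected with guidance", {
  expect_error(simulate_genome(simulation_config(
    seed = 1, n_genes = 500L, chrom_length_bp = 100000L)),
    "infeasible")
})

test_that("plant_motifs at extreme rates gives clean presence flags", {
  cfg <- simulation_config(seed = 3, n_fg_promoters = 30L,
                           n_bg_promoters = 30L, promoter_bp = 150L)
  ps <- simulate_promoter_sets(cfg)
  motif <- "TTACGCGTAA"
  fg <- plant_motifs(ps$foreground, motif, 1, seed = 4)
  bg <- plant_motifs(ps$background, motif, 0, seed = 5)
  ms_fg <- scan_promoters(motif, fg$promoters)
  expect_true(all(ms_fg$presence))
  expect_equal(nrow(bg$ground_truth), 0L)
  # lengths unchanged: motifs overwrite, never insert
  expect_equal(nchar(fg$promoters$entries$sequence),
               nchar(ps$foreground$entries$sequence))
  # recorded positions point at a true occurrence
  for (i in seq_len(nrow(fg$ground_truth))) {
    gt <- fg$ground_truth[i, ]
    s <- fg$promoters$entries$sequence[
      fg$promoters$entries$gene_id == gt$gene_id]
    planted <- substr(s, gt$position + 1, gt$position + nchar(motif))
    expect_equal(planted,
                 if (gt$strand == "+") gt$instance else
                   oracle_revcomp(gt$instance))
  }
})

test_that("planted counts fall in the central 99% binomial interval", {
  cfg <- simulation_config(seed = 101)
  ps <- simulate_promoter_sets(cfg)
  fg <- plant_motifs(ps$foreground, "ACGTACGT", 0.9, seed = 102)
  n <- nrow(fg$ground_truth)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.9)
  expect_gte(n, bounds[1])
  expect_lte(n, bounds[2])
})

test_that("minus-strand plantings are invisible to single-strand scans", {
  withr::local_seed(2024)
  p <- promoter_set(stats::setNames(
    vapply(1:3, function(i) helper_rand_dna(60), character(1)),
    sprintf("g%02d", 1:3)))
  motif <- "TTAACGCGGT"  # not its own reverse complement
  # force minus-strand planting by retrying seeds until all strands are '-'
  seed <- 1L
  repeat {
    pl <- plant_motifs(p, motif, 1, seed = seed)
    if (all(pl$ground_truth$strand == "-")) break
    seed <- seed + 1L
  }
  single <- scan_promoters(motif, pl$promoters, both_strands = FALSE)
  both <- scan_promoters(motif, pl$promoters, both_strands = TRUE)
  expect_false(any(single$presence[pl$ground_truth$gene_id]))
  expect_true(all(both$presence[pl$ground_truth$gene_id]))
})

test_that("DE simulation plants recoverable groups with matching signs", {
  gen <- simulate_genome(small_cfg())
  sizes <- c(up_10 = 5L, down_10 = 5L, up_30 = 5L, down_30 = 5L,
             up_60 = 5L, down_60 = 5L)
  sim <- simulate_de_table(gen$annotation, sizes, seed = 77)
  groups <- gene_groups_from_de(sim$de, q_cutoff = 0.1)
  for (lb in names(groups)) {
    want <- sim$ground_truth$gene_id[
      paste(sim$ground_truth$direction, sim$ground_truth$timepoint,
            sep = "_") == lb]
    expect_setequal(groups[[lb]]$gene_ids, want)
  }
  # direction always matches the sign of the fold-change
  gt <- sim$ground_truth
  for (i in seq_len(nrow(gt))) {
    row <- sim$de[sim$de$gene_id == gt$gene_id[i] &
                    sim$de$timepoint == gt$timepoint[i], ]
    expect_equal(row$log2fc > 0, gt$direction[i] == "up")
  }
  # all-zero sizes -> nothing significant
  empty <- simulate_de_table(gen$annotation, c(up_10 = 0L), seed = 78)
  expect_false(any(empty$de$q_value < 0.1))
})

test_that("oversubscribed DE groups are rejected", {
  gen <- simulate_genome(small_cfg())
  expect_error(simulate_de_table(gen$annotation, c(up_10 = 1000L), seed = 1),
               "exceed")
})

test_that("requested peak categories are honoured by construction", {
  gen <- simulate_genome(small_cfg())
  lens <- stats::setNames(nchar(gen$genome), names(gen$genome))
  pk <- simulate_peaks(gen$annotation, c(intron = 10L), lens, seed = 11)
  expect_equal(nrow(pk$peaks), 10L)
  ann <- annotate_peaks(pk$peaks, gen$annotation)
  expect_true(all(ann$category == "intron"))
  pk2 <- simulate_peaks(gen$annotation, c(intron = 10L), lens, seed = 11)
  expect_identical(pk$peaks, pk2$peaks)
  expect_error(simulate_peaks(gen$annotation, c(bogus = 5L), lens, seed = 1),
               "unknown")
})
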