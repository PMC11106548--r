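peak_row <- function(seq_name, start, end, id = "pk") {
  data.frame(seq_name = seq_name, start = start, end = end, peak_id = id,
             summit_offset = NA_integer_, stringsAsFactors = FALSE)
}

test_that("category assignment follows the documented priority", {
  an <- toy_annotation()
  # 2,000 bp upstream of geneA's 5'UTR start (anchor 18000) -> promoter
  pr <- assign_category(peak_row("chrT", 17950, 18050), an)
  expect_equal(pr$category, "promoter")
  expect_equal(pr$nearest_gene, "geneA")
  expect_true(pr$signed_tss_distance < 0 && pr$signed_tss_distance >= -5000)

  # inside geneA's first intron (anchor 22500)
  intr <- assign_category(peak_row("chrT", 22450, 22550), an)
  expect_equal(intr$category, "intron")
  expect_equal(intr$signed_tss_distance, 2500L)

  # inside geneA's 5'UTR, which also lies in an exon: UTR outranks exon
  utr <- assign_category(peak_row("chrT", 20050, 20150), an)
  expect_equal(utr$category, "five_utr")

  # >= 5 kb from every gene: intergenic, nearest gene still reported
  far <- assign_category(peak_row("chrT", 1000, 1200), an)
  expect_equal(far$category, "intergenic")
  expect_equal(far$nearest_gene, "geneA")

  # minus-strand promoter: geneB's 5'UTR anchor is at 43999, window
  # (43999, 49000]; anchor 45000 -> promoter of geneB
  prB <- assign_category(peak_row("chrT", 44900, 45100), an)
  expect_equal(prB$category, "promoter")
  expect_equal(prB$nearest_gene, "geneB")
  expect_equal(prB$signed_tss_distance, 43999L - 45000L)

  expect_error(assign_category(peak_row("chrX", 10, 20), an), "unknown")
})

test_that("summits override midpoints as peak anchors", {
  an <- toy_annotation()
  pk <- peak_row("chrT", 22900, 23300)  # midpoint 23100: in second exon
  expect_equal(assign_category(pk, an)$category, "exon")
  pk$summit_offset <- 50L               # anchor 22950: first intron
  expect_equal(assign_category(pk, an)$category, "intron")
})

test_that("category assignment matches the brute-force oracle on synthetic peaks", {
  cfg <- simulation_config(seed = 23, n_genes = 30L, n_chromosomes = 1L,
                           chrom_length_bp = 600000L)
  gen <- simulate_genome(cfg)
  counts <- c(promoter = 30L, five_utr = 10L, exon = 30L, intron = 30L,
              three_utr = 10L, intergenic = 30L)
  pk <- simulate_peaks(gen$annotation, counts,
                       stats::setNames(nchar(gen$genome), names(gen$genome)),
                       seed = 29)
  ann <- annotate_peaks(pk$peaks, gen$annotation)
  oracle <- vapply(seq_len(nrow(ann)), function(i)
    oracle_anchor_category(ann$anchor[i], ann$seq_name[i], gen$annotation),
    character(1))
  expect_identical(ann$category, oracle)
  gt <- pk$ground_truth[match(ann$peak_id, pk$ground_truth$peak_id), ]
  expect_identical(ann$category, gt$category)
})

test_that("feature_distribution recovers planted proportions exactly", {
  cfg <- simulation_config(seed = 31)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks(gen$annotation, cfg$peak_counts,
                       stats::setNames(nchar(gen$genome), names(gen$genome)),
                       seed = 37)
  ann <- annotate_peaks(pk$peaks, gen$annotation)
  fd <- feature_distribution(ann)
  expect_equal(sum(fd$fraction), 1)
  expect_equal(stats::setNames(fd$count, fd$category),
               cfg$peak_counts[fd$category])
  expect_error(feature_distribution(ann[0, ]), "no annotated peaks")
  one_cat <- feature_distribution(ann[ann$category == "intergenic", ])
  expect_equal(one_cat$fraction[one_cat$category == "intergenic"], 1)
})

test_that("tss_profile puts TSS peaks in the zero bin and marks the TTS", {
  an <- toy_annotation()
  # anchors exactly at both genes' TSS (geneA: 20000; geneB: 43999)
  pk <- rbind(peak_row("chrT", 19950, 20050, "a"),
              peak_row("chrT", 43949, 44049, "b"))
  ann <- annotate_peaks(pk, an)
  expect_equal(ann$signed_tss_distance, c(0L, 0L))
  prof <- tss_profile(ann, an, bins = 20, flank_bp = 1000)
  zero_bin <- findInterval(0, prof$breaks, rightmost.closed = TRUE)
  expect_equal(sum(prof$counts), 2L)
  expect_equal(prof$counts[zero_bin], 2L)
  # toy transcripts are 6000 and 4000 bp: the TTS mark is their mean
  expect_equal(prof$mean_transcript_length, 5000)
})

test_that("tss_profile is invariant under translating all coordinates", {
  an <- toy_annotation()
  shift <- 1234L
  an2 <- an
  an2$genes[c("start", "end", "tx_start", "tx_end")] <-
    an$genes[c("start", "end", "tx_start", "tx_end")] + shift
  an2$features[c("start", "end")] <- an$features[c("start", "end")] + shift
  pk <- rbind(peak_row("chrT", 18000, 18200, "a"),
              peak_row("chrT", 22450, 22550, "b"),
              peak_row("chrT", 41000, 41400, "c"))
  pk2 <- pk
  pk2$start <- pk$start + shift
  pk2$end <- pk$end + shift
  p1 <- tss_profile(annotate_peaks(pk, an), an)
  p2 <- tss_profile(annotate_peaks(pk2, an2), an2)
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$breaks, p2$breaks)
})

test_that("crosstab counts single-path example and deduplicates genes", {
  an <- toy_annotation()
  de <- data.frame(gene_id = "geneA", log2fc = 2.1, q_value = 0.05,
                   timepoint = 10L, genotype = "WT",
                   stringsAsFactors = FALSE)
  one <- crosstab_targets(annotate_peaks(peak_row("chrT", 17950, 18050), an),
                          de)
  expect_equal(one$n_genes[one$binding == "promoter" & one$direction == "up" &
                             one$timepoint == 10], 1L)
  expect_true(all(one$n_genes[!(one$binding == "promoter" &
                                  one$direction == "up")] == 0L))

  # two promoter peaks + one intron peak on the same gene: the gene counts
  # once per cell, and appears in both binding classes
  pk <- rbind(peak_row("chrT", 17950, 18050, "p1"),
              peak_row("chrT", 16000, 16200, "p2"),
              peak_row("chrT", 22450, 22550, "p3"))
  both <- crosstab_targets(annotate_peaks(pk, an), de)
  expect_equal(both$n_genes[both$direction == "up" & both$timepoint == 10],
               c(1L, 1L))

  # no DE genes -> all cells zero
  de0 <- de; de0$q_value <- 0.5
  expect_true(all(crosstab_targets(annotate_peaks(pk, an), de0)$n_genes == 0L))
})

test_that("strict gene body excludes UTR-only bound genes", {
  an <- toy_annotation()
  de <- data.frame(gene_id = "geneA", log2fc = 2.1, q_value = 0.05,
                   timepoint = 10L, genotype = "WT",
                   stringsAsFactors = FALSE)
  utr_peak <- annotate_peaks(peak_row("chrT", 20050, 20150), an)
  loose <- crosstab_targets(utr_peak, de)
  strict <- crosstab_targets(utr_peak, de, strict_gene_body = TRUE)
  cell <- function(x) x$n_genes[x$binding == "gene_body" &
                                  x$direction == "up" & x$timepoint == 10]
  expect_equal(cell(loose), 1L)
  expect_equal(cell(strict), 0L)
})
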