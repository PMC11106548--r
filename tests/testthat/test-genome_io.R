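test_that("read_fasta normalises case, joins lines and keeps record order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt", "ACGT", ">chr2 some description", "NNTTAA"),
             fa)
  x <- read_fasta(fa)
  expect_identical(x, c(chr1 = "ACGTACGT", chr2 = "NNTTAA"))
})

test_that("read_fasta error contracts: duplicate header, empty record", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", ">a", "ACGT"), fa)
  expect_error(read_fasta(fa), "duplicate")
  writeLines(c(">a", "", ">b", "ACGT"), fa)
  expect_error(read_fasta(fa), "empty")
})

test_that("FASTA round-trips byte-identically after normalisation", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgtn", "ACGT", ">s2", paste(rep("ACGTT", 40),
                                                    collapse = "")), fa)
  x <- read_fasta(fa)
  out1 <- withr::local_tempfile(fileext = ".fa")
  out2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(x, out1)
  write_fasta(read_fasta(out1), out2)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  expect_identical(read_fasta(out1), x)
})

make_toy_gff3 <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("read_gff3 converts coordinates and derives introns", {
  gff <- make_toy_gff3(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tsrc\texon\t1\t30\t.\t+\t.\tParent=g1.1",
    "chr1\tsrc\texon\t51\t100\t.\t+\t.\tParent=g1.1"))
  an <- read_gff3(gff)
  expect_equal(an$genes$start, 0L)
  expect_equal(an$genes$end, 100L)
  ex <- an$features[an$features$type == "exon", ]
  expect_equal(ex$start, c(0L, 50L))
  expect_equal(ex$end, c(30L, 100L))
  intr <- an$features[an$features$type == "intron", ]
  expect_equal(intr$start, 30L)
  expect_equal(intr$end, 50L)
})

test_that("read_gff3 keeps the first mRNA per gene and skips mRNA-less genes", {
  gff <- make_toy_gff3(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t80\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g1.2;Parent=g1",
    "chr1\tsrc\texon\t1\t80\t.\t+\t.\tParent=g1.1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=g1.2",
    "chr1\tsrc\tgene\t200\t300\t.\t-\t.\tID=g2"))
  expect_warning(an <- read_gff3(gff), "no mRNA")
  expect_equal(an$genes$gene_id, "g1")
  expect_equal(an$genes$tx_end, 80L)          # first mRNA child, by file order
  expect_equal(nrow(an$features), 1L)         # second transcript's exon dropped
})

test_that("exon outside its gene span is an error", {
  expect_error(
    genome_annotation(
      data.frame(gene_id = "g", seq_name = "c", strand = "+", start = 10,
                 end = 50, tx_start = 10, tx_end = 50),
      data.frame(gene_id = "g", type = "exon", start = 5, end = 50)),
    "outside gene span")
})

test_that("extract_promoters obeys window arithmetic and clipping", {
  genome <- c(chrP = paste(rep("A", 6000), collapse = ""))
  an <- genome_annotation(
    data.frame(gene_id = c("gA", "gB"), seq_name = "chrP",
               strand = "+", start = c(5000L, 300L), end = c(5500L, 400L),
               tx_start = c(5000L, 300L), tx_end = c(5500L, 400L)),
    data.frame(gene_id = character(), type = character(),
               start = integer(), end = integer()))
  pr <- extract_promoters(genome, an, 1000L)
  eA <- pr$entries[pr$entries$gene_id == "gA", ]
  expect_equal(c(eA$start, eA$end), c(4000L, 5000L))
  expect_equal(nchar(eA$sequence), 1000L)
  expect_false(eA$truncated)
  eB <- pr$entries[pr$entries$gene_id == "gB", ]
  expect_equal(c(eB$start, eB$end), c(0L, 300L))
  expect_true(eB$truncated)
})

test_that("minus-strand promoters are reverse-complemented downstream flank", {
  # TSS base at position 9 (0-based); genomic flank [10, 14) reads AAAC
  genome <- c(chrM = paste0("GGGGGGGGGG", "AAAC", "GGGG"))
  an <- genome_annotation(
    data.frame(gene_id = "gM", seq_name = "chrM", strand = "-",
               start = 2L, end = 10L, tx_start = 2L, tx_end = 10L),
    data.frame(gene_id = character(), type = character(),
               start = integer(), end = integer()))
  pr <- extract_promoters(genome, an, 4L)
  expect_equal(pr$entries$sequence, "GTTT")
  expect_error(extract_promoters(c(other = "ACGT"), an, 4L), "unknown")
})

test_that("promoter extraction matches a naive per-base oracle", {
  withr::local_seed(421)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:100) {
    clen <- sample(200:400, 1)
    genome <- stats::setNames(helper_rand_dna(clen), "c")
    strand <- sample(c("+", "-"), 1)
    s <- sample(50:(clen - 50), 1)
    e <- s + sample(20:40, 1)
    w <- sample(10:120, 1)
    an <- genome_annotation(
      data.frame(gene_id = "g", seq_name = "c", strand = strand,
                 start = s, end = e, tx_start = s, tx_end = e),
      data.frame(gene_id = character(), type = character(),
                 start = integer(), end = integer()))
    got <- extract_promoters(genome, an, w)$entries$sequence
    ch <- strsplit(genome[["c"]], "")[[1]]
    want <- if (strand == "+") {
      lo <- max(0, s - w)
      if (lo >= s) "" else paste(ch[(lo + 1):s], collapse = "")
    } else {
      tss <- e - 1
      hi <- min(clen, tss + 1 + w)
      if (tss + 1 >= hi) "" else
        paste(rev(unname(comp[ch[(tss + 2):hi]])), collapse = "")
    }
    expect_identical(got, want)
  }
})

test_that("generated gene models satisfy exon+intron = transcript span", {
  cfg <- simulation_config(seed = 5, n_genes = 20L, n_chromosomes = 1L,
                           chrom_length_bp = 400000L)
  an <- simulate_genome(cfg)$annotation
  f <- an$features
  for (gid in an$genes$gene_id) {
    ei <- f[f$gene_id == gid & f$type %in% c("exon", "intron"), ]
    g <- an$genes[an$genes$gene_id == gid, ]
    expect_equal(sum(ei$end - ei$start), g$tx_end - g$tx_start)
  }
})

test_that("read_bed parses, sorts and validates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t100\t200\tpk2", "chr1\t10\t20\tpk1"), bed)
  pk <- read_bed(bed)
  expect_equal(pk$seq_name, c("chr1", "chr2"))
  expect_equal(pk$start, c(10L, 100L))
  expect_equal(pk$peak_id, c("pk1", "pk2"))
  writeLines("chr1\t20\t10", bed)
  expect_error(read_bed(bed), "line 1")
})

test_that("BED round-trips through write_bed/read_bed", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\ta", "chr1\t30\t40\tb"), bed)
  pk <- read_bed(bed)
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk, out)
  pk2 <- read_bed(out)
  expect_identical(pk[c("seq_name", "start", "end", "peak_id")],
                   pk2[c("seq_name", "start", "end", "peak_id")])
})

test_that("read_de_table validates columns, q range and timepoints", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tq_value\ttimepoint\tgenotype",
               "g1\t1.5\t0.01\t10\tWT"), tsv)
  de <- read_de_table(tsv)
  expect_equal(de$gene_id, "g1")
  writeLines(c("gene_id\tlog2fc\tq_value\ttimepoint\tgenotype",
               "g1\t1.5\t1.2\t10\tWT"), tsv)
  expect_error(read_de_table(tsv), "q_value")
  writeLines(c("gene_id\tlog2fc\tq_value\ttimepoint",
               "g1\t1.5\t0.2\t10"), tsv)
  expect_error(read_de_table(tsv), "genotype")
})
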