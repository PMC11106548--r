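# Toy promoter sets engineered so the hypergeometric counts are known:
# all 4 foreground promoters carry the planted 7-mer ACGTACG; background
# promoter 1 carries the 6-mer prefix ACGTAC but not the 7-mer.
toy_fg <- c(f1 = "AAACGTACGAAAAA", f2 = "TTACGTACGTTTTT",
            f3 = "CCACGTACGAAACC", f4 = "GAACGTACGTTTAG")
toy_bg <- c(b1 = "AAACGTACTTAAAA", b2 = "TTTTGGGGAAAACC",
            b3 = "GGGGAAAATTTTCC", b4 = "CCAATTGGCCAATT",
            b5 = "GGTTAACCGGTTAA", b6 = "AACCGGTTAACCGG")

test_that("seed_kmers enumerates all 4096 candidates with exact p-values", {
  seeds <- seed_kmers(toy_fg, toy_bg)
  expect_equal(nrow(seeds), 4096L)
  expect_equal(attr(seeds, "fg_total"), 4L)
  expect_equal(attr(seeds, "bg_total"), 6L)
  # ACGTAC: present in all 4 fg and 1 bg -> N=10, m=5, n=4, k=4 -> 5/210
  row <- seeds[seeds$kmer == "ACGTAC", ]
  expect_equal(row$fg_with, 4L)
  expect_equal(row$bg_with, 1L)
  expect_equal(row$p_value, 5 / 210)
  expect_equal(row$p_value, oracle_hyper_upper(10, 5, 4, 4))
  # an absent k-mer scores p = 1
  expect_equal(seeds$p_value[seeds$kmer == "AAAAAA"],
               hypergeom_upper_tail(10, sum(grepl("AAAAAA", c(toy_fg, toy_bg)) |
                                              grepl("TTTTTT", c(toy_fg, toy_bg))),
                                    4, sum(grepl("AAAAAA", toy_fg) |
                                             grepl("TTTTTT", toy_fg))))
  expect_error(seed_kmers(character(), toy_bg), "empty foreground")
  expect_error(seed_kmers(c(x = "ACGTACGT"), c(x = "ACGTACGT")), "share")
})

test_that("grow keeps strictly improving extensions only", {
  seeds <- seed_kmers(toy_fg, toy_bg)
  node <- seeds[seeds$kmer == "ACGTAC", ]
  kept <- grow(node, toy_fg, toy_bg)
  # the planted 7-mer drops the one background carrier: 5/210 -> 1/210
  ch <- kept[kept$kmer == "ACGTACG" & kept$length == 7, ]
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$p_value, 1 / 210)
  expect_equal(ch$parent, "ACGTAC")
  # every kept node strictly improves on its recorded parent
  expect_true(all(kept$p_value < kept$parent_p))
  # a child with p equal to its parent is never kept
  expect_false(any(kept$p_value >= kept$parent_p))
  # nodes at max_len generate no candidates
  long_node <- list(kmer = paste(rep("A", 12), collapse = ""), p_value = 0.5)
  expect_equal(nrow(grow(long_node, toy_fg, toy_bg, max_len = 12L)), 0L)
})

test_that("level-wise driver reproduces the recursive reference kept set", {
  seeds <- seed_kmers(toy_fg, toy_bg)
  ref <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i)
    grow(seeds[i, ], toy_fg, toy_bg)))
  forest <- discover_kmers(toy_fg, toy_bg)
  drv <- forest$nodes[forest$nodes$length > 6, ]
  expect_gt(nrow(drv), 0)
  expect_setequal(unique(ref$kmer), unique(drv$kmer))
  # p-values agree k-mer by k-mer
  ref_p <- tapply(ref$p_value, ref$kmer, min)
  expect_equal(as.numeric(ref_p[drv$kmer]), drv$p_value)
})

test_that("reported counts equal a naive double-strand presence scan", {
  forest <- discover_kmers(toy_fg, toy_bg)
  rep_nodes <- forest$report[seq_len(min(8, nrow(forest$report))), ]
  for (i in seq_len(nrow(rep_nodes))) {
    km <- rep_nodes$kmer[i]
    rc <- oracle_revcomp(km)
    naive <- function(seqs) sum(grepl(km, seqs, fixed = TRUE) |
                                  grepl(rc, seqs, fixed = TRUE))
    expect_equal(rep_nodes$fg_with[i], naive(toy_fg))
    expect_equal(rep_nodes$bg_with[i], naive(toy_bg))
  }
})

test_that("growth is deterministic and p-values strictly decrease along paths", {
  d <- discovery_data(404, planted = TRUE)
  # scale down for a unit test: 40 fg / 120 bg promoters of 300 bp
  fg <- substr(d$fg$entries$sequence[1:40], 1, 300)
  bg <- substr(d$bg$entries$sequence[1:120], 1, 300)
  f1 <- discover_kmers(fg, bg)
  f2 <- discover_kmers(fg, bg)
  expect_identical(f1$nodes, f2$nodes)
  expect_identical(f1$report, f2$report)
  deeper <- f1$nodes[f1$nodes$length > 6, ]
  expect_true(all(deeper$p_value < deeper$parent_p))
})

test_that("report collapses reverse-complement duplicates canonically", {
  forest <- discover_kmers(toy_fg, toy_bg)
  rep <- forest$report
  expect_false(any(duplicated(rep$canonical)))
  expect_true(all(rep$canonical ==
                    pmin(rep$kmer, vapply(rep$kmer, oracle_revcomp,
                                          character(1), USE.NAMES = FALSE))))
  expect_true(all(rep$length >= 6 & rep$length <= 12))
  expect_true(all(rep$q_value >= rep$p_value - 1e-15))
  # both orientations of the planted 7-mer resolve to one canonical entry
  expect_equal(sum(rep$canonical ==
                     pmin("ACGTACG", oracle_revcomp("ACGTACG"))), 1L)
})

test_that("an all-identical no-signal design yields no significant k-mers", {
  same <- paste(rep("ACGT", 25), collapse = "")
  fg <- stats::setNames(rep(same, 4), paste0("f", 1:4))
  bg <- stats::setNames(rep(same, 8), paste0("b", 1:8))
  forest <- discover_kmers(fg, bg)
  expect_false(any(forest$report$significant))
  # presence is proportional, so every evaluated seed has p >= n-choose level
  expect_true(all(forest$report$p_value > 0.05 |
                    !forest$report$significant))
})
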