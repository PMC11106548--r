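# Independent brute-force / enumeration oracles and fixture builders.
# These deliberately avoid the package's own code paths.

# IUPAC symbol table, written out independently of touchcre::IUPAC_CLASSES
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(x) {
  s <- strsplit(x, "")[[1]]
  paste(rev(unname(ORACLE_COMP[s])), collapse = "")
}

# naive O(nm) single-strand scan; subject N matches nothing
oracle_scan_one_strand <- function(consensus, sequence) {
  cs <- strsplit(consensus, "")[[1]]
  ss <- strsplit(sequence, "")[[1]]
  w <- length(cs); n <- length(ss)
  hits <- integer(0)
  if (n < w) return(hits)
  for (p in 0:(n - w)) {
    ok <- TRUE
    for (i in seq_len(w)) {
      if (!(ss[p + i] %in% ORACLE_IUPAC[[cs[i]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# both-strand scan with palindromic-site dedup by start position
oracle_scan_both <- function(consensus, sequence) {
  fwd <- oracle_scan_one_strand(consensus, sequence)
  rev <- oracle_scan_one_strand(oracle_revcomp(consensus), sequence)
  list(fwd = fwd, rev = setdiff(rev, fwd),
       starts = sort(union(fwd, rev)))
}

# exact hypergeometric upper tail by term enumeration (choose() is exact
# for these small integers)
oracle_hyper_upper <- function(N, m, n, k) {
  hi <- min(n, m)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i)
    choose(m, i) * choose(N - m, n - i), numeric(1))) / choose(N, n)
}

# exact two-sided Fisher p by table enumeration with exact integer
# numerator comparison (all tables share the denominator choose(N, c1))
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  nums <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x), numeric(1))
  obs <- nums[a - lo + 1]
  sum(nums[nums <= obs]) / choose(N, c1)
}

# manual BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

helper_rand_dna <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

helper_rand_iupac <- function(len) {
  syms <- names(ORACLE_IUPAC)
  # favour concrete bases so random motifs still hit occasionally
  w <- c(rep(6, 4), rep(1, 11))
  paste(sample(syms, len, replace = TRUE, prob = w), collapse = "")
}

# longest run of contiguous shared bases between a k-mer and a planted
# motif, considering both orientations of both
shared_contiguous <- function(kmer, planted) {
  best <- 0L
  for (x in unique(c(kmer, oracle_revcomp(kmer))))
    for (y in unique(c(planted, oracle_revcomp(planted))))
      for (w in seq(min(nchar(x), nchar(y)), 1)) {
        if (w <= best) break
        for (i in seq_len(nchar(x) - w + 1)) {
          if (grepl(substr(x, i, i + w - 1), y, fixed = TRUE)) {
            best <- max(best, w)
            break
          }
        }
      }
  best
}

# a small hand-laid-out annotation on one 60 kb chromosome:
# geneA (+): span [20000, 26000), 5'UTR [20000,20200), exons
#   [20000,22000)+[23000,26000), intron [22000,23000), 3'UTR [25800,26000)
# geneB (-): span [40000, 44000), structure mirrored
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB"), seq_name = "chrT",
    strand = c("+", "-"),
    start = c(20000L, 40000L), end = c(26000L, 44000L),
    tx_start = c(20000L, 40000L), tx_end = c(26000L, 44000L),
    stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = c("geneA", "geneA", "geneA", "geneA", "geneA",
                "geneB", "geneB", "geneB", "geneB", "geneB"),
    type = c("five_utr", "exon", "intron", "exon", "three_utr",
             "three_utr", "exon", "intron", "exon", "five_utr"),
    start = c(20000L, 20000L, 22000L, 23000L, 25800L,
              40000L, 40000L, 41500L, 42000L, 43800L),
    end = c(20200L, 22000L, 23000L, 26000L, 26000L,
            40200L, 41500L, 42000L, 44000L, 44000L),
    stringsAsFactors = FALSE)
  genome_annotation(genes, features)
}

# brute-force category of an anchor point under the documented priority,
# written as plain loops over every feature and promoter window
oracle_anchor_category <- function(anchor, seq_name, annot,
                                   promoter_bp = 5000L) {
  g <- annot$genes
  f <- annot$features
  for (type in c("five_utr", "three_utr", "exon", "intron")) {
    ff <- f[f$type == type, , drop = FALSE]
    for (i in seq_len(nrow(ff))) {
      gsq <- g$seq_name[g$gene_id == ff$gene_id[i]]
      if (gsq == seq_name && anchor >= ff$start[i] && anchor < ff$end[i])
        return(type)
    }
  }
  for (i in seq_len(nrow(g))) {
    if (g$seq_name[i] != seq_name) next
    utr <- f[f$gene_id == g$gene_id[i] & f$type == "five_utr", , drop = FALSE]
    a <- if (g$strand[i] == "+") {
      if (nrow(utr)) min(utr$start) else g$tx_start[i]
    } else {
      if (nrow(utr)) max(utr$end) - 1L else g$tx_end[i] - 1L
    }
    inside <- if (g$strand[i] == "+")
      anchor >= a - promoter_bp && anchor < a
    else anchor > a && anchor <= a + promoter_bp
    if (inside) return("promoter")
  }
  "intergenic"
}

# discovery study design at the package's default scale, with or without
# the planted motif
discovery_data <- function(seed, planted = TRUE, motif = "ACGTACGT",
                           fg_rate = 0.9, bg_rate = 0.05) {
  cfg <- simulation_config(seed = seed)
  ps <- simulate_promoter_sets(cfg)
  if (!planted) return(list(fg = ps$foreground, bg = ps$background))
  list(fg = plant_motifs(ps$foreground, motif, fg_rate,
                         seed = seed + 10001L)$promoters,
       bg = plant_motifs(ps$background, motif, bg_rate,
                         seed = seed + 20002L)$promoters)
}
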