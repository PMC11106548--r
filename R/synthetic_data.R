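# --- seeded synthetic-data generator ---------------------------------------
#
# Produces toy genomes with gene models, promoter sets with motifs planted
# at controlled foreground/background rates, DE tables with six planted
# direction-by-timepoint groups, and peak sets placed unambiguously inside
# intended feature categories -- each with a ground-truth record, so every
# downstream stage is testable with no external data. Everything is
# reproducible from the seed.

#' Default simulation configuration
#'
#' Defaults mirror the study design the package emulates: 1000 bp promoter
#' scans with 200 foreground and 1000 background promoters, one 8-mer
#' planted at 90% foreground / 5% background occurrence, a mean primary
#' transcript length of 4500 bp, six DE groups (up/down at 10, 30, 60 min),
#' and 1000 peaks split 25/25/21/21/8 percent across promoter, intergenic,
#' exon, intron and UTR categories (UTR mass split equally between the
#' 5' and 3' UTR).
#'
#' @param seed integer seed driving every random draw.
#' @param ... overrides for any config field (see Details in the package
#'   vignette).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 2L,
    chrom_length_bp = 2000000L,
    n_genes = 200L,
    mean_transcript_bp = 4500L,
    exons_per_gene = 5L,
    utr_bp = 200L,
    intergenic_min_bp = 11000L,
    n_fg_promoters = 200L,
    n_bg_promoters = 1000L,
    promoter_bp = 1000L,
    planted_motifs = list(list(motif = "ACGTACGT", fg_rate = 0.9,
                               bg_rate = 0.05)),
    base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    de_group_sizes = c(up_10 = 25L, down_10 = 25L, up_30 = 25L,
                       down_30 = 25L, up_60 = 25L, down_60 = 25L),
    peak_counts = c(promoter = 250L, five_utr = 40L, exon = 210L,
                    intron = 210L, three_utr = 40L, intergenic = 250L))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config field: %s", unknown[1])
  cfg[names(dots)] <- dots
  if (abs(sum(cfg$base_composition) - 1) > 1e-9)
    stopf("base_composition must sum to 1")
  for (pm in cfg$planted_motifs)
    if (any(c(pm$fg_rate, pm$bg_rate) < 0 | c(pm$fg_rate, pm$bg_rate) > 1))
      stopf("planted motif rates must lie in [0, 1]")
  structure(cfg, class = "simulation_config")
}

# n random sequences of equal length from the base composition
rand_dna <- function(n, len, base_composition = rep(0.25, 4)) {
  if (n == 0) return(character())
  s <- paste(sample(c("A", "C", "G", "T"), n * len, replace = TRUE,
                    prob = base_composition), collapse = "")
  substring(s, seq(1L, n * len, by = len), seq(len, n * len, by = len))
}

# split `total` into n parts, each >= minima[i], randomly
random_partition <- function(total, minima) {
  n <- length(minima)
  slack <- total - sum(minima)
  if (slack < 0) stopf("partition infeasible")
  if (n == 1) return(total)
  cuts <- sort(sample.int(slack + n - 1L, n - 1L))
  parts <- diff(c(0L, cuts, slack + n)) - 1L
  minima + parts
}

#' Simulate a toy genome with gene models
#'
#' Chromosome sequences are i.i.d. draws from the base composition. Genes
#' are placed on a regular grid with random jitter such that consecutive
#' genes are at least `intergenic_min_bp` apart (so 5 kb promoter windows
#' never collide); about half are on the minus strand. Each gene has
#' `exons_per_gene` exons with random intron gaps, and terminal UTRs of
#' `utr_bp` nested in the terminal exons. Transcript lengths are uniform on
#' 0.7-1.3 times `mean_transcript_bp`.
#'
#' @param config a [simulation_config()].
#' @param dir if non-NULL, write `genome.fa` and `genes.gff3` there.
#' @return list with `genome` (named character vector), `annotation`
#'   (a [genome_annotation()]) and, when `dir` is given, `fasta_path` and
#'   `gff3_path`.
#' @export
simulate_genome <- function(config = simulation_config(), dir = NULL) {
  withr::with_seed(config$seed, {
    n_chr <- config$n_chromosomes
    genes_per_chr <- ceiling(config$n_genes / n_chr)
    slot <- config$chrom_length_bp %/% genes_per_chr
    max_len <- ceiling(1.3 * config$mean_transcript_bp)
    pad <- config$intergenic_min_bp %/% 2L + 500L
    if (slot < max_len + 2L * pad)
      stopf(paste0("infeasible gene packing: %d genes of up to %d bp plus ",
                   "%d bp spacing do not fit in %d bp chromosomes; increase ",
                   "chrom_length_bp or reduce n_genes"),
            config$n_genes, max_len, config$intergenic_min_bp,
            config$chrom_length_bp)

    genome <- stats::setNames(
      rand_dna(n_chr, config$chrom_length_bp, config$base_composition),
      sprintf("chr%d", seq_len(n_chr)))

    genes <- list(); feats <- list()
    gid <- 0L
    for (ci in seq_len(n_chr)) {
      n_here <- min(genes_per_chr, config$n_genes - (ci - 1L) * genes_per_chr)
      for (si in seq_len(n_here)) {
        gid <- gid + 1L
        L <- as.integer(round(runif(1, 0.7, 1.3) * config$mean_transcript_bp))
        lo <- (si - 1L) * slot + pad
        hi <- si * slot - pad - L
        s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        strand <- sample(c("+", "-"), 1L)
        id <- sprintf("gene%04d", gid)

        n_ex <- config$exons_per_gene
        nseg <- 2L * n_ex - 1L
        minima <- rep(c(80L, 150L), length.out = nseg)     # exon, intron, ...
        minima[c(1L, nseg)] <- config$utr_bp + 100L        # terminal exons
        seg <- random_partition(L, minima)
        bounds <- cumsum(c(0L, seg))
        ex_idx <- seq(1L, nseg, by = 2L)
        exons <- data.frame(start = s + bounds[ex_idx],
                            end = s + bounds[ex_idx + 1L])
        introns <- if (n_ex > 1) {
          in_idx <- seq(2L, nseg - 1L, by = 2L)
          data.frame(start = s + bounds[in_idx], end = s + bounds[in_idx + 1L])
        } else NULL

        utr5 <- if (strand == "+") c(s, s + config$utr_bp) else
          c(s + L - config$utr_bp, s + L)
        utr3 <- if (strand == "+") c(s + L - config$utr_bp, s + L) else
          c(s, s + config$utr_bp)

        genes[[gid]] <- data.frame(
          gene_id = id, seq_name = names(genome)[ci], strand = strand,
          start = s, end = s + L, tx_start = s, tx_end = s + L,
          stringsAsFactors = FALSE)
        feats[[gid]] <- rbind(
          data.frame(gene_id = id, type = "exon", start = exons$start,
                     end = exons$end, stringsAsFactors = FALSE),
          if (!is.null(introns))
            data.frame(gene_id = id, type = "intron", start = introns$start,
                       end = introns$end, stringsAsFactors = FALSE),
          data.frame(gene_id = id, type = c("five_utr", "three_utr"),
                     start = c(utr5[1], utr3[1]), end = c(utr5[2], utr3[2]),
                     stringsAsFactors = FALSE))
      }
    }
    annot <- genome_annotation(do.call(rbind, genes), do.call(rbind, feats))
    out <- list(genome = genome, annotation = annot)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$fasta_path <- write_fasta(genome, file.path(dir, "genome.fa"))
      out$gff3_path <- write_gff3(annot, file.path(dir, "genes.gff3"))
    }
    out
  })
}

#' Write a genome annotation as GFF3
#'
#' Emits gene, mRNA (one primary transcript per gene), exon and UTR
#' features with 1-based inclusive coordinates and LF line endings.
#' Derived introns are not written; [read_gff3()] re-derives them.
#'
#' @param annot a [genome_annotation()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff3 <- function(annot, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  g <- annot$genes
  type_gff <- c(exon = "exon", five_utr = "five_prime_UTR",
                three_utr = "three_prime_UTR")
  for (i in order(g$seq_name, g$start, method = "radix")) {
    id <- g$gene_id[i]
    tx <- paste0(id, ".1")
    row <- function(type, s, e, attrs)
      paste(g$seq_name[i], "touchcre_sim", type, s + 1L, e, ".",
            g$strand[i], ".", attrs, sep = "\t")
    lines <- c(row("gene", g$start[i], g$end[i], paste0("ID=", id)),
               row("mRNA", g$tx_start[i], g$tx_end[i],
                   paste0("ID=", tx, ";Parent=", id)))
    ff <- annot$features[annot$features$gene_id == id &
                           annot$features$type != "intron", , drop = FALSE]
    ff <- ff[order(ff$start, ff$type, method = "radix"), , drop = FALSE]
    lines <- c(lines, vapply(seq_len(nrow(ff)), function(j)
      row(type_gff[[ff$type[j]]], ff$start[j], ff$end[j],
          paste0("Parent=", tx)), character(1)))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Simulate bare foreground/background promoter sets
#'
#' Random sequences from the base composition, named `fg_0001`... and
#' `bg_0001`..., as the substrate for [plant_motifs()].
#'
#' @param config a [simulation_config()].
#' @return list with `foreground` and `background` `promoter_set` objects.
#' @export
simulate_promoter_sets <- function(config = simulation_config()) {
  withr::with_seed(config$seed, {
    fg <- rand_dna(config$n_fg_promoters, config$promoter_bp,
                   config$base_composition)
    bg <- rand_dna(config$n_bg_promoters, config$promoter_bp,
                   config$base_composition)
    list(
      foreground = promoter_set(
        stats::setNames(fg, sprintf("fg_%04d", seq_along(fg))),
        config$promoter_bp),
      background = promoter_set(
        stats::setNames(bg, sprintf("bg_%04d", seq_along(bg))),
        config$promoter_bp))
  })
}

#' Plant motif occurrences into a promoter set
#'
#' Each promoter independently receives one occurrence of each motif with
#' the motif's rate, at a uniform random position on a uniform random
#' strand, overwriting the background sequence (promoter lengths are
#' unchanged). Degenerate IUPAC symbols are instantiated with a uniform
#' draw from the allowed bases per planting. Positions are recorded as
#' ground truth.
#'
#' @param promoters a `promoter_set`.
#' @param motifs character vector of motif sequences (IUPAC allowed).
#' @param rates per-motif planting probability, recycled to
#'   `length(motifs)`.
#' @param seed integer seed.
#' @return list with `promoters` (modified set) and `ground_truth`
#'   (data frame `gene_id`, `motif`, `instance`, `position` (0-based),
#'   `strand`).
#' @export
plant_motifs <- function(promoters, motifs, rates, seed) {
  if (missing(seed) || !is_count(seed)) stopf("a single integer seed is required")
  rates <- rep_len(rates, length(motifs))
  entries <- promoters$entries
  gt <- list()
  withr::with_seed(as.integer(seed), {
    for (mi in seq_along(motifs)) {
      sym <- check_iupac(motifs[mi])
      w <- length(sym)
      if (any(nchar(entries$sequence) < w))
        stopf("motif '%s' is longer than the shortest promoter", motifs[mi])
      hit <- which(runif(nrow(entries)) < rates[mi])
      if (!length(hit)) next
      pos <- vapply(hit, function(i)
        sample.int(nchar(entries$sequence[i]) - w + 1L, 1L), integer(1))
      strand <- sample(c("+", "-"), length(hit), replace = TRUE)
      inst <- vapply(seq_along(hit), function(j)
        paste(vapply(sym, function(s) {
          b <- IUPAC_CLASSES[[s]]
          if (length(b) == 1) b else sample(b, 1L)
        }, character(1)), collapse = ""), character(1))
      planted <- ifelse(strand == "+", inst, vapply(inst, function(x)
        reverse_complement(x), character(1), USE.NAMES = FALSE))
      entries$sequence[hit] <- paste0(
        substr(entries$sequence[hit], 1L, pos - 1L), planted,
        substr(entries$sequence[hit], pos + w, nchar(entries$sequence[hit])))
      gt[[mi]] <- data.frame(gene_id = entries$gene_id[hit],
                             motif = motifs[mi], instance = inst,
                             position = as.integer(pos - 1L), strand = strand,
                             stringsAsFactors = FALSE)
    }
  })
  promoters$entries <- entries
  ground_truth <- if (length(gt)) do.call(rbind, gt) else
    data.frame(gene_id = character(), motif = character(),
               instance = character(), position = integer(),
               strand = character(), stringsAsFactors = FALSE)
  rownames(ground_truth) <- NULL
  list(promoters = promoters, ground_truth = ground_truth)
}

#' Simulate a differential-expression table with planted groups
#'
#' Assigns disjoint random gene sets to the six direction-by-timepoint
#' groups. Group members get `q < 0.1` and a log2 fold-change whose sign
#' matches their direction at their timepoint; all other (gene, timepoint)
#' rows get `q >= 0.1` and small noise fold-changes.
#'
#' @param annot a [genome_annotation()] supplying the gene universe.
#' @param group_sizes named integer vector over
#'   `up_10, down_10, ..., down_60` (a subset is fine; missing groups are
#'   size 0).
#' @param seed integer seed.
#' @param genotype genotype label for the table (default `"WT"`).
#' @return list with `de` (data frame as read by [read_de_table()]) and
#'   `ground_truth` (data frame `gene_id`, `direction`, `timepoint`).
#' @export
simulate_de_table <- function(annot, group_sizes, seed, genotype = "WT") {
  if (missing(seed) || !is_count(seed)) stopf("a single integer seed is required")
  gene_ids <- annot$genes$gene_id
  all_labels <- c("up_10", "down_10", "up_30", "down_30", "up_60", "down_60")
  sizes <- stats::setNames(rep(0L, 6L), all_labels)
  if (!all(names(group_sizes) %in% all_labels))
    stopf("unknown group label: %s",
          setdiff(names(group_sizes), all_labels)[1])
  sizes[names(group_sizes)] <- as.integer(group_sizes)
  if (sum(sizes) > length(gene_ids))
    stopf("group sizes (%d) exceed the number of genes (%d)",
          sum(sizes), length(gene_ids))
  withr::with_seed(as.integer(seed), {
    shuffled <- sample(gene_ids)
    assign <- list(); at <- 0L
    for (lb in all_labels) {
      assign[[lb]] <- if (sizes[lb] > 0) shuffled[at + seq_len(sizes[lb])]
      else character()
      at <- at + sizes[lb]
    }
    gt <- do.call(rbind, lapply(all_labels, function(lb) {
      if (!length(assign[[lb]])) return(NULL)
      parts <- strsplit(lb, "_", fixed = TRUE)[[1]]
      data.frame(gene_id = assign[[lb]], direction = parts[1],
                 timepoint = as.integer(parts[2]), stringsAsFactors = FALSE)
    }))
    if (is.null(gt))
      gt <- data.frame(gene_id = character(), direction = character(),
                       timepoint = integer(), stringsAsFactors = FALSE)
    de <- do.call(rbind, lapply(c(10L, 30L, 60L), function(tp) {
      member <- gt[gt$timepoint == tp, , drop = FALSE]
      is_m <- gene_ids %in% member$gene_id
      dir <- member$direction[match(gene_ids, member$gene_id)]
      lfc <- ifelse(is_m,
                    ifelse(dir == "up", 1, -1) * runif(length(gene_ids), 1, 4),
                    rnorm(length(gene_ids), 0, 0.2))
      q <- ifelse(is_m, runif(length(gene_ids), 0, 0.0999),
                  runif(length(gene_ids), 0.1001, 1))
      data.frame(gene_id = gene_ids, log2fc = lfc, q_value = q,
                 timepoint = tp, genotype = genotype,
                 stringsAsFactors = FALSE)
    }))
    rownames(de) <- NULL
    list(de = de, ground_truth = gt)
  })
}

# 1-based IRanges category partition of one chromosome under the peak
# category priority (five_utr > three_utr > exon > intron > promoter >
# intergenic)
category_partition <- function(annot, seq_name, seq_len, promoter_bp = 5000L) {
  g <- annot$genes[annot$genes$seq_name == seq_name, , drop = FALSE]
  f <- annot$features[annot$features$gene_id %in% g$gene_id, , drop = FALSE]
  ir <- function(df) IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
  parts <- list()
  claimed <- IRanges::IRanges()
  for (type in c("five_utr", "three_utr", "exon", "intron")) {
    x <- ir(f[f$type == type, , drop = FALSE])
    parts[[type]] <- BiocGenerics::setdiff(x, claimed)
    claimed <- IRanges::reduce(c(claimed, x))
  }
  pw <- promoter_windows(annot, promoter_bp)
  pw <- pw[pw$seq_name == seq_name & pw$end > pw$start, , drop = FALSE]
  prom <- IRanges::reduce(IRanges::IRanges(pw$start + 1L, pw$end))
  parts$promoter <- BiocGenerics::setdiff(prom, claimed)
  claimed <- IRanges::reduce(c(claimed, prom))
  parts$intergenic <- BiocGenerics::setdiff(IRanges::IRanges(1L, seq_len),
                                            claimed)
  parts
}

#' Simulate peaks planted in known feature categories
#'
#' For each requested category, anchors are drawn uniformly from the
#' category's genomic intervals shrunk by `margin` bp on each side (so the
#' anchor is unambiguously inside the category), then expanded to peaks of
#' 100-400 bp centred on the anchor. The intended category and gene are
#' recorded as ground truth.
#'
#' @param annot a [genome_annotation()].
#' @param category_counts named integer vector over `promoter`, `five_utr`,
#'   `exon`, `intron`, `three_utr`, `intergenic`.
#' @param seq_lengths named integer vector of chromosome lengths.
#' @param seed integer seed.
#' @param promoter_bp promoter width used for the promoter category
#'   (default 5000).
#' @param margin minimum distance of an anchor from its category border
#'   (default 10).
#' @return list with `peaks` (data frame as from [read_bed()], sorted, ids
#'   `peak_00001`...) and `ground_truth` (data frame `peak_id`, `category`,
#'   `gene_id`; NA gene for intergenic peaks).
#' @export
simulate_peaks <- function(annot, category_counts, seq_lengths, seed,
                           promoter_bp = 5000L, margin = 10L) {
  if (missing(seed) || !is_count(seed)) stopf("a single integer seed is required")
  bad <- setdiff(names(category_counts), PEAK_CATEGORIES)
  if (length(bad)) stopf("unknown peak category: %s", bad[1])
  withr::with_seed(as.integer(seed), {
    # gather per-chromosome shrunken category intervals
    pools <- list()
    for (sq in names(seq_lengths)) {
      parts <- category_partition(annot, sq, seq_lengths[[sq]], promoter_bp)
      for (ct in names(parts)) {
        x <- parts[[ct]]
        x <- IRanges::restrict(x, start = 251L,
                               end = as.integer(seq_lengths[[sq]]) - 250L)
        x <- x[IRanges::width(x) > 2L * margin]
        if (!length(x)) next
        pools[[ct]] <- rbind(pools[[ct]], data.frame(
          seq_name = sq, start = IRanges::start(x) + margin,
          end = IRanges::end(x) - margin, stringsAsFactors = FALSE))
      }
    }
    rows <- list()
    for (ct in names(category_counts)) {
      cnt <- category_counts[[ct]]
      if (cnt == 0) next
      pool <- pools[[ct]]
      if (is.null(pool) || !nrow(pool))
        stopf("category '%s' is not realisable in this annotation", ct)
      widths <- pool$end - pool$start + 1L
      iv <- sample.int(nrow(pool), cnt, replace = TRUE, prob = widths)
      pos1 <- pool$start[iv] + floor(runif(cnt) * widths[iv])  # 1-based
      anchor <- as.integer(pos1) - 1L                          # 0-based
      len <- sample(100:400, cnt, replace = TRUE)
      rows[[ct]] <- data.frame(seq_name = pool$seq_name[iv],
                               start = anchor - len %/% 2L,
                               end = anchor - len %/% 2L + len,
                               category = ct, stringsAsFactors = FALSE)
    }
    pk <- do.call(rbind, rows)
    pk <- pk[order(pk$seq_name, pk$start, pk$end, method = "radix"), ,
             drop = FALSE]
    pk$peak_id <- sprintf("peak_%05d", seq_len(nrow(pk)))

    # intended gene: the gene whose span (genic categories) or promoter
    # window (promoter category) contains the anchor
    anchor <- (pk$start + pk$end) %/% 2L
    gene <- rep(NA_character_, nrow(pk))
    g <- annot$genes
    pw <- promoter_windows(annot, promoter_bp)
    for (sq in unique(pk$seq_name)) {
      pi <- which(pk$seq_name == sq)
      a <- anchor[pi]
      gg <- g[g$seq_name == sq, , drop = FALSE]
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(a + 1L, a + 1L),
        IRanges::IRanges(gg$start + 1L, gg$end), select = "first")
      genic <- pk$category[pi] %in% GENIC_CATEGORIES
      gene[pi[genic]] <- gg$gene_id[hit[genic]]
      ww <- pw[pw$seq_name == sq & pw$end > pw$start, , drop = FALSE]
      hitp <- IRanges::findOverlaps(
        IRanges::IRanges(a + 1L, a + 1L),
        IRanges::IRanges(ww$start + 1L, ww$end), select = "first")
      isp <- pk$category[pi] == "promoter"
      gene[pi[isp]] <- ww$gene_id[hitp[isp]]
    }
    gt <- data.frame(peak_id = pk$peak_id, category = pk$category,
                     gene_id = gene, stringsAsFactors = FALSE)
    peaks <- data.frame(seq_name = pk$seq_name, start = pk$start,
                        end = pk$end, peak_id = pk$peak_id,
                        summit_offset = NA_integer_, stringsAsFactors = FALSE)
    rownames(peaks) <- NULL; rownames(gt) <- NULL
    list(peaks = peaks, ground_truth = gt)
  })
}

#' Simulate a complete study and write its files
#'
#' Generates the genome and annotation, a DE table with the six planted
#' groups, and a peak set with planted categories; writes `genome.fa`,
#' `genes.gff3`, `de_table.tsv`, `peaks.bed` and a `ground_truth.json`
#' manifest (seed and config echoed) under `dir`. Sub-generator seeds are
#' derived from `config$seed` so one seed fixes every emitted file.
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return list with the in-memory objects (`genome`, `annotation`, `de`,
#'   `peaks`), the ground-truth records, and the file paths.
#' @export
simulate_study <- function(config = simulation_config(), dir) {
  if (missing(dir)) stopf("an output directory is required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config, dir = dir)
  de <- simulate_de_table(gen$annotation, config$de_group_sizes,
                          seed = config$seed + 1L)
  pk <- simulate_peaks(gen$annotation, config$peak_counts,
                       stats::setNames(nchar(gen$genome), names(gen$genome)),
                       seed = config$seed + 2L)
  de_path <- file.path(dir, "de_table.tsv")
  write_tsv_commented(de$de, de_path)
  bed_path <- write_bed(pk$peaks, file.path(dir, "peaks.bed"))
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = config$seed,
         config = unclass(config),
         de_groups = de$ground_truth,
         peak_categories = pk$ground_truth),
    gt_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(genome = gen$genome, annotation = gen$annotation,
       de = de$de, de_ground_truth = de$ground_truth,
       peaks = pk$peaks, peak_ground_truth = pk$ground_truth,
       fasta_path = gen$fasta_path, gff3_path = gen$gff3_path,
       de_path = de_path, bed_path = bed_path,
       ground_truth_path = gt_path)
}
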