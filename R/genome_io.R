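#' Read a FASTA file into a named sequence vector
#'
#' Sequences are upper-cased and multi-line records are joined. Record order
#' is preserved. Only the first whitespace-delimited token of each header is
#' used as the sequence name.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences over A,C,G,T,N.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt", "ACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  dss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stopf("duplicate FASTA header: %s", dup[1])
  seqs <- toupper(as.character(dss))
  names(seqs) <- nm
  empty <- nm[nchar(seqs) == 0L]
  if (length(empty))
    stopf("empty FASTA record: %s", empty[1])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopf("sequence '%s' contains characters outside A,C,G,T,N", nm[bad][1])
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stopf("all sequences must be named")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Construct a genome annotation object
#'
#' Internal coordinates are 0-based half-open throughout the package; GFF3
#' input (1-based inclusive) is converted at the boundary by [read_gff3()].
#' One primary transcript is kept per gene.
#'
#' @param genes data frame with columns `gene_id`, `seq_name`, `strand`
#'   (`+`/`-`), `start`, `end` (gene span), `tx_start`, `tx_end` (primary
#'   transcript span).
#' @param features data frame with columns `gene_id`, `type` (one of
#'   `five_utr`, `three_utr`, `exon`, `intron`), `start`, `end`.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, features) {
  need_g <- c("gene_id", "seq_name", "strand", "start", "end",
              "tx_start", "tx_end")
  if (!all(need_g %in% names(genes)))
    stopf("genes is missing columns: %s",
          paste(setdiff(need_g, names(genes)), collapse = ", "))
  need_f <- c("gene_id", "type", "start", "end")
  if (!all(need_f %in% names(features)))
    stopf("features is missing columns: %s",
          paste(setdiff(need_f, names(features)), collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene_id: %s", genes$gene_id[duplicated(genes$gene_id)][1])
  if (!all(genes$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  bad_types <- setdiff(unique(features$type),
                       c("five_utr", "three_utr", "exon", "intron"))
  if (length(bad_types))
    stopf("unknown feature type: %s", bad_types[1])
  gs <- genes$start[match(features$gene_id, genes$gene_id)]
  ge <- genes$end[match(features$gene_id, genes$gene_id)]
  out_of_span <- features$start < gs | features$end > ge
  if (any(out_of_span))
    stopf("feature outside gene span for gene %s",
          features$gene_id[out_of_span][1])
  genes <- as.data.frame(genes)
  features <- as.data.frame(features)
  for (cl in c("start", "end", "tx_start", "tx_end"))
    genes[[cl]] <- as.integer(genes[[cl]])
  for (cl in c("start", "end"))
    features[[cl]] <- as.integer(features[[cl]])
  structure(list(genes = genes, features = features),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d sequence(s), %d features\n",
              nrow(x$genes), length(unique(x$genes$seq_name)),
              nrow(x$features)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/five_prime_UTR/three_prime_UTR features. The first
#' mRNA child of each gene, in file order, is taken as the primary
#' transcript; further transcripts are ignored. Introns are derived as the
#' gaps between consecutive exons of the primary transcript. GFF3 1-based
#' inclusive coordinates are converted to the package's 0-based half-open
#' convention. Genes with no mRNA child are skipped with a warning; an exon
#' outside its gene's span is an error.
#'
#' @param path path to a GFF3 file.
#' @return a [genome_annotation()] object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1]] else NA_character_, character(1))

  gi <- which(type == "gene")
  if (!length(gi)) stopf("no gene features in %s", path)
  gid <- as.character(gr$ID[gi])
  if (any(is.na(gid) | gid == "")) stopf("gene feature without an ID attribute")
  genes <- data.frame(
    gene_id = gid,
    seq_name = as.character(GenomeInfoDb::seqnames(gr)[gi]),
    strand = as.character(BiocGenerics::strand(gr)[gi]),
    start = BiocGenerics::start(gr)[gi] - 1L,
    end = BiocGenerics::end(gr)[gi],
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene ID in GFF3: %s",
          genes$gene_id[duplicated(genes$gene_id)][1])
  if (!all(genes$strand %in% c("+", "-")))
    stopf("gene %s has no strand", genes$gene_id[!genes$strand %in% c("+", "-")][1])

  mi <- which(type == "mRNA")
  m_parent <- first_parent(gr$Parent[mi])
  primary <- mi[!duplicated(m_parent)]
  primary_gene <- m_parent[!duplicated(m_parent)]
  primary_id <- as.character(gr$ID[primary])
  keep <- genes$gene_id %in% primary_gene
  if (any(!keep))
    warnf("skipping %d gene(s) with no mRNA child: %s",
          sum(!keep), paste(utils::head(genes$gene_id[!keep], 3), collapse = ", "))
  genes <- genes[keep, , drop = FALSE]
  ord <- match(genes$gene_id, primary_gene)
  genes$tx_start <- BiocGenerics::start(gr)[primary][ord] - 1L
  genes$tx_end <- BiocGenerics::end(gr)[primary][ord]
  tx2gene <- stats::setNames(primary_gene, primary_id)

  fmap <- c(exon = "exon", five_prime_UTR = "five_utr",
            three_prime_UTR = "three_utr")
  fi <- which(type %in% names(fmap))
  f_parent <- first_parent(gr$Parent[fi])
  fi <- fi[f_parent %in% primary_id]
  f_parent <- f_parent[f_parent %in% primary_id]
  feats <- data.frame(
    gene_id = unname(tx2gene[f_parent]),
    type = unname(fmap[type[fi]]),
    start = BiocGenerics::start(gr)[fi] - 1L,
    end = BiocGenerics::end(gr)[fi],
    stringsAsFactors = FALSE)
  feats <- feats[feats$gene_id %in% genes$gene_id, , drop = FALSE]

  # derive introns from exon gaps, per gene
  introns <- do.call(rbind, lapply(split(feats[feats$type == "exon", ],
                                         feats$gene_id[feats$type == "exon"]),
    function(ex) {
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
        stopf("overlapping exons for gene %s", ex$gene_id[1])
      if (nrow(ex) < 2) return(NULL)
      data.frame(gene_id = ex$gene_id[1], type = "intron",
                 start = ex$end[-nrow(ex)], end = ex$start[-1],
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(introns) && nrow(introns)) {
    introns <- introns[introns$end > introns$start, , drop = FALSE]
    feats <- rbind(feats, introns)
  }
  rownames(feats) <- NULL
  feats <- feats[order(feats$gene_id, feats$start, feats$type), , drop = FALSE]
  rownames(feats) <- NULL
  genome_annotation(genes, feats)
}

#' Transcription start site of each gene
#'
#' 0-based position of the 5'-most base of the primary transcript
#' (strand-aware).
#'
#' @param annot a [genome_annotation()] object.
#' @return named integer vector of TSS positions.
#' @export
gene_tss <- function(annot) {
  g <- annot$genes
  stats::setNames(ifelse(g$strand == "+", g$tx_start, g$tx_end - 1L),
                  g$gene_id)
}

# 0-based position of the 5'-most annotated 5'UTR base per gene, falling
# back to the TSS when no 5'UTR is annotated.
five_utr_anchor <- function(annot) {
  tss <- gene_tss(annot)
  utr <- annot$features[annot$features$type == "five_utr", , drop = FALSE]
  if (nrow(utr)) {
    g <- annot$genes
    for (gid in unique(utr$gene_id)) {
      u <- utr[utr$gene_id == gid, , drop = FALSE]
      tss[gid] <- if (g$strand[g$gene_id == gid] == "+")
        min(u$start) else max(u$end) - 1L
    }
  }
  tss
}

#' Extract strand-aware promoter sequences
#'
#' For a `+` strand gene with anchor base at position `a` (0-based), the
#' promoter window is the genomic interval `[a - window_bp, a)`; for a `-`
#' strand gene it is `[a + 1, a + 1 + window_bp)`, reverse-complemented so
#' that position 0 of the returned sequence is farthest from the anchor,
#' reading toward it. Windows are clipped at chromosome ends and flagged
#' `truncated`.
#'
#' @param genome named character vector from [read_fasta()].
#' @param annot a [genome_annotation()] object.
#' @param window_bp positive window width in bp (1000 for enrichment scans,
#'   5000 for peak-style promoter definitions).
#' @param anchor `"tss"` (5'-most base of the primary transcript) or
#'   `"five_utr_start"` (5'-most annotated 5'UTR base, falling back to the
#'   TSS when no 5'UTR is annotated).
#' @return an object of class `promoter_set`: list with `window_bp`,
#'   `anchor`, and `entries` (data frame with `gene_id`, `seq_name`,
#'   `start`, `end`, `strand`, `truncated`, `sequence`).
#' @export
extract_promoters <- function(genome, annot, window_bp = 1000L,
                              anchor = c("tss", "five_utr_start")) {
  anchor <- match.arg(anchor)
  if (!is_count(window_bp) || window_bp < 1) stopf("window_bp must be >= 1")
  window_bp <- as.integer(window_bp)
  g <- annot$genes
  unknown <- setdiff(unique(g$seq_name), names(genome))
  if (length(unknown))
    stopf("gene on unknown sequence: %s", unknown[1])
  a <- if (anchor == "tss") gene_tss(annot) else five_utr_anchor(annot)
  a <- unname(a[g$gene_id])
  clen <- nchar(genome)[g$seq_name]

  plus <- g$strand == "+"
  start <- ifelse(plus, pmax(0L, a - window_bp), a + 1L)
  end <- ifelse(plus, a, pmin(clen, a + 1L + window_bp))
  start <- pmin(start, end)  # guard degenerate windows at sequence edges
  truncated <- (end - start) < window_bp
  seqs <- substring(genome[g$seq_name], start + 1L, end)
  seqs[!plus] <- revcomp_dna(seqs[!plus])

  structure(list(
    window_bp = window_bp, anchor = anchor,
    entries = data.frame(gene_id = g$gene_id, seq_name = g$seq_name,
                         start = as.integer(start), end = as.integer(end),
                         strand = g$strand, truncated = truncated,
                         sequence = unname(seqs), stringsAsFactors = FALSE)),
    class = "promoter_set")
}

#' Construct a promoter set from bare sequences
#'
#' Used by the synthetic-data generator and anywhere promoters exist without
#' genomic provenance.
#'
#' @param sequences named character vector (names are gene ids).
#' @param window_bp nominal window width.
#' @param anchor anchor label to record.
#' @return a `promoter_set` object.
#' @export
promoter_set <- function(sequences, window_bp = max(nchar(sequences)),
                         anchor = "tss") {
  if (is.null(names(sequences))) stopf("sequences must be named by gene id")
  structure(list(
    window_bp = as.integer(window_bp), anchor = anchor,
    entries = data.frame(gene_id = names(sequences), seq_name = NA_character_,
                         start = NA_integer_, end = NA_integer_,
                         strand = "+", truncated = FALSE,
                         sequence = unname(sequences),
                         stringsAsFactors = FALSE)),
    class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters, window %d bp, anchor %s\n",
              nrow(x$entries), x$window_bp, x$anchor))
  invisible(x)
}

#' Read peak intervals from BED
#'
#' Standard BED (0-based half-open), at least three columns. Column 4, when
#' present, is used as the peak id; otherwise ids are generated after
#' sorting. Peaks are returned sorted by (seq_name, start).
#'
#' @param path path to a BED file.
#' @return data frame with columns `seq_name`, `start`, `end`, `peak_id`,
#'   `summit_offset` (NA; BED carries no summit).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(fields)) stopf("no intervals in %s", path)
  nf <- lengths(fields)
  if (any(nf < 3))
    stopf("line %d: fewer than 3 BED columns", lineno[nf < 3][1])
  seq_name <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end))
    stopf("line %d: non-integer BED coordinates",
          lineno[is.na(start) | is.na(end)][1])
  bad <- start >= end
  if (any(bad)) stopf("line %d: start >= end", lineno[bad][1])
  peak_id <- ifelse(nf >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[[4]] else NA_character_, character(1)),
    NA_character_)
  o <- order(seq_name, start, end, method = "radix")
  df <- data.frame(seq_name = seq_name[o], start = start[o], end = end[o],
                   peak_id = peak_id[o], summit_offset = NA_integer_,
                   stringsAsFactors = FALSE)
  miss <- is.na(df$peak_id) | df$peak_id == "" | df$peak_id == "."
  if (any(miss))
    df$peak_id[miss] <- sprintf("peak_%05d", which(miss))
  rownames(df) <- NULL
  df
}

#' Write peaks to BED6
#'
#' @param peaks data frame as from [read_bed()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(peaks$seq_name, peaks$start, peaks$end, peaks$peak_id,
                   0L, ".", sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with a header; required columns: `gene_id`, `log2fc`,
#' `q_value`, `timepoint` (minutes, one of 0/10/30/60), `genotype`.
#'
#' @param path path to the TSV.
#' @return validated data frame.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("DE table not found: %s", path)
  de <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "q_value", "timepoint", "genotype")
  if (!all(need %in% names(de)))
    stopf("DE table is missing columns: %s",
          paste(setdiff(need, names(de)), collapse = ", "))
  if (any(is.na(de$q_value) | de$q_value < 0 | de$q_value > 1))
    stopf("q_value outside [0,1] at row %d",
          which(is.na(de$q_value) | de$q_value < 0 | de$q_value > 1)[1])
  if (!all(de$timepoint %in% c(0L, 10L, 30L, 60L)))
    stopf("timepoint must be one of 0, 10, 30, 60 (row %d)",
          which(!de$timepoint %in% c(0L, 10L, 30L, 60L))[1])
  de
}
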