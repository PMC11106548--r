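# --- DAP-seq-style peak annotation -----------------------------------------
#
# Each peak is reduced to an anchor point (summit when present, else the
# interval midpoint) and assigned exactly one feature category in priority
# order five_utr > three_utr > exon > intron > promoter > intergenic. UTRs
# outrank the exons that contain them; the promoter (promoter_bp upstream
# of the 5'UTR start, falling back to the TSS) ranks below all genic
# categories so a peak inside one gene is never called promoter of a
# neighbour. Coordinates are 0-based half-open throughout.

GENIC_CATEGORIES <- c("five_utr", "three_utr", "exon", "intron")
PEAK_CATEGORIES <- c("promoter", "five_utr", "exon", "intron", "three_utr",
                     "intergenic")

# promoter windows, strand-aware, anchored on the 5'UTR start (TSS
# fallback): [a - promoter_bp, a) for '+', [a + 1, a + 1 + promoter_bp)
# for '-'
promoter_windows <- function(annot, promoter_bp = 5000L) {
  g <- annot$genes
  a <- unname(five_utr_anchor(annot)[g$gene_id])
  plus <- g$strand == "+"
  data.frame(gene_id = g$gene_id, seq_name = g$seq_name,
             start = ifelse(plus, pmax(0L, a - promoter_bp), a + 1L),
             end = ifelse(plus, a, a + 1L + promoter_bp),
             stringsAsFactors = FALSE)
}

#' Annotate peaks with feature category, nearest gene and TSS distance
#'
#' @param peaks data frame as from [read_bed()] (`seq_name`, `start`,
#'   `end`, `peak_id`, optional `summit_offset`).
#' @param annot a [genome_annotation()] object.
#' @param promoter_bp promoter width upstream of the 5'UTR start used for
#'   the `promoter` category (default 5000).
#' @return data frame with columns `peak_id`, `seq_name`, `anchor`,
#'   `category`, `nearest_gene`, `signed_tss_distance` (negative = upstream
#'   of the nearest gene's TSS, strand-aware), `in_gene_body`.
#' @export
annotate_peaks <- function(peaks, annot, promoter_bp = 5000L) {
  unknown <- setdiff(unique(peaks$seq_name), unique(annot$genes$seq_name))
  if (length(unknown))
    stopf("peak on unknown sequence: %s", unknown[1])
  anchor <- as.integer(ifelse(!is.na(peaks$summit_offset),
                              peaks$start + peaks$summit_offset,
                              (peaks$start + peaks$end) %/% 2L))
  g <- annot$genes
  f <- annot$features
  f$seq_name <- g$seq_name[match(f$gene_id, g$gene_id)]
  pw <- promoter_windows(annot, promoter_bp)
  tss <- gene_tss(annot)

  category <- rep("intergenic", nrow(peaks))
  nearest <- character(nrow(peaks))
  tssd <- integer(nrow(peaks))
  for (sq in unique(peaks$seq_name)) {
    pi <- which(peaks$seq_name == sq)
    a <- anchor[pi]
    anch_ir <- IRanges::IRanges(a + 1L, a + 1L)
    cat_sq <- rep(NA_character_, length(pi))
    for (type in GENIC_CATEGORIES) {
      ff <- f[f$seq_name == sq & f$type == type, , drop = FALSE]
      if (!nrow(ff)) next
      hit <- IRanges::overlapsAny(anch_ir,
                                  IRanges::IRanges(ff$start + 1L, ff$end))
      cat_sq[is.na(cat_sq) & hit] <- type
    }
    pp <- pw[pw$seq_name == sq & pw$end > pw$start, , drop = FALSE]
    if (nrow(pp)) {
      hit <- IRanges::overlapsAny(anch_ir,
                                  IRanges::IRanges(pp$start + 1L, pp$end))
      cat_sq[is.na(cat_sq) & hit] <- "promoter"
    }
    cat_sq[is.na(cat_sq)] <- "intergenic"
    category[pi] <- cat_sq

    gg <- g[g$seq_name == sq, , drop = FALSE]
    gg <- gg[order(gg$start, gg$gene_id, method = "radix"), , drop = FALSE]
    # distance from anchor to gene span; ties go to the smaller gene start
    # then lexicographic gene_id (the sort order above)
    dmat <- vapply(seq_len(nrow(gg)), function(j) {
      gs <- gg$start[j]; ge <- gg$end[j]
      ifelse(a < gs, gs - a, ifelse(a >= ge, a - ge + 1L, 0L))
    }, integer(length(pi)))
    dmat <- matrix(dmat, nrow = length(pi))
    ng <- apply(dmat, 1, which.min)
    nearest[pi] <- gg$gene_id[ng]
    gtss <- unname(tss[gg$gene_id[ng]])
    plus <- gg$strand[ng] == "+"
    tssd[pi] <- ifelse(plus, a - gtss, gtss - a)
  }
  data.frame(peak_id = peaks$peak_id, seq_name = peaks$seq_name,
             anchor = anchor, category = category, nearest_gene = nearest,
             signed_tss_distance = tssd,
             in_gene_body = category %in% GENIC_CATEGORIES,
             stringsAsFactors = FALSE)
}

#' Assign the feature category of a single peak
#'
#' Convenience wrapper around [annotate_peaks()] for one peak.
#'
#' @param peak single-row data frame or list with `seq_name`, `start`,
#'   `end`, optional `summit_offset` and `peak_id`.
#' @param annot a [genome_annotation()] object.
#' @param promoter_bp promoter width (default 5000).
#' @return single-row annotation data frame (see [annotate_peaks()]).
#' @export
assign_category <- function(peak, annot, promoter_bp = 5000L) {
  df <- data.frame(seq_name = peak$seq_name, start = peak$start,
                   end = peak$end,
                   peak_id = if (!is.null(peak$peak_id)) peak$peak_id else "peak",
                   summit_offset = if (!is.null(peak$summit_offset))
                     peak$summit_offset else NA_integer_,
                   stringsAsFactors = FALSE)
  annotate_peaks(df, annot, promoter_bp)
}

#' Distribution of peaks across feature categories
#'
#' @param annotations data frame from [annotate_peaks()].
#' @return data frame with one row per category (`promoter`, `five_utr`,
#'   `exon`, `intron`, `three_utr`, `intergenic`): `count` and `fraction`
#'   (fractions sum to 1).
#' @export
feature_distribution <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0)
    stopf("no annotated peaks")
  counts <- table(factor(annotations$category, levels = PEAK_CATEGORIES))
  data.frame(category = PEAK_CATEGORIES, count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(annotations),
             stringsAsFactors = FALSE)
}

#' TSS-anchored peak density profile
#'
#' Histograms the strand-aware signed distances from peak anchors to their
#' nearest gene's TSS over `[-flank_bp, mean_transcript_length + flank_bp]`
#' so the mean transcript length marks the expected TTS position on the
#' axis. Distances outside the range are dropped (and counted).
#'
#' @param annotations data frame from [annotate_peaks()].
#' @param annot the [genome_annotation()] used to compute the mean primary
#'   transcript length.
#' @param bins number of bins (>= 10; default 100).
#' @param flank_bp flank on each side of the gene span (default 2000).
#' @return list with `breaks`, `mid` (bin midpoints), `counts`, `density`
#'   (per-bp, sums to 1 over in-range peaks), `mean_transcript_length`
#'   (the TTS mark), `n_in_range`, `n_dropped`.
#' @export
tss_profile <- function(annotations, annot, bins = 100L, flank_bp = 2000L) {
  if (!is_count(bins) || bins < 10) stopf("bins must be >= 10")
  mean_tx <- mean(annot$genes$tx_end - annot$genes$tx_start)
  lo <- -flank_bp
  hi <- mean_tx + flank_bp
  d <- annotations$signed_tss_distance
  inr <- d >= lo & d <= hi
  breaks <- seq(lo, hi, length.out = bins + 1)
  counts <- as.integer(table(cut(d[inr], breaks, include.lowest = TRUE)))
  width <- diff(breaks)[1]
  list(breaks = breaks, mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts,
       density = if (sum(counts)) counts / sum(counts) / width else
         rep(0, bins),
       mean_transcript_length = mean_tx,
       n_in_range = sum(inr), n_dropped = sum(!inr))
}

#' Cross-tabulate binding location against DE direction
#'
#' A gene is promoter-bound if any of its peaks is in the `promoter`
#' category and gene-body-bound if any peak is in a genic category (UTRs,
#' exons, introns; set `strict_gene_body` to restrict the gene body to
#' exons and introns, i.e. between the translational start and stop). A
#' gene can be both. Within each (binding, direction, timepoint) cell genes
#' are counted once; genes absent from the DE table are treated as not
#' differentially expressed.
#'
#' @param annotations data frame from [annotate_peaks()].
#' @param de_records data frame from [read_de_table()].
#' @param q_cutoff DE significance cutoff on the q-value (default 0.1).
#' @param strict_gene_body exclude UTR-bound genes from the gene body class
#'   (default FALSE).
#' @return data frame with columns `binding` (`promoter`/`gene_body`),
#'   `direction` (`up`/`down`), `timepoint`, `n_genes`.
#' @export
crosstab_targets <- function(annotations, de_records, q_cutoff = 0.1,
                             strict_gene_body = FALSE) {
  body_cats <- if (strict_gene_body) c("exon", "intron") else GENIC_CATEGORIES
  bound <- list(
    promoter = unique(annotations$nearest_gene[
      annotations$category == "promoter"]),
    gene_body = unique(annotations$nearest_gene[
      annotations$category %in% body_cats]))
  tps <- sort(unique(de_records$timepoint))
  rows <- list()
  for (b in names(bound)) for (dir in c("up", "down")) for (tp in tps) {
    sel <- de_records$timepoint == tp & de_records$q_value < q_cutoff &
      (if (dir == "up") de_records$log2fc > 0 else de_records$log2fc < 0)
    de_genes <- unique(de_records$gene_id[sel])
    rows[[length(rows) + 1L]] <- data.frame(
      binding = b, direction = dir, timepoint = tp,
      n_genes = length(intersect(bound[[b]], de_genes)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
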