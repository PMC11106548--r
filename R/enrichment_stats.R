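#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, m, n)`: the probability of
#' observing at least `k` marked genes in a draw of `n` from a universe of
#' `N` genes of which `m` are marked. This is the enrichment p-value used
#' throughout the package (enrichment, not depletion; set
#' `lower = TRUE` for the depletion tail `P(X <= k)`).
#'
#' @param N universe size.
#' @param m number of marked genes in the universe.
#' @param n draw (foreground group) size.
#' @param k observed number of marked genes in the draw.
#' @param lower if TRUE return the depletion tail `P(X <= k)` instead.
#' @return upper-tail probability; vectorised over `m`, `n`, `k`.
#' @export
#' @examples
#' hypergeom_upper_tail(10, 4, 4, 3)  # 25/210
hypergeom_upper_tail <- function(N, m, n, k, lower = FALSE) {
  if (any(N < 0 | m < 0 | n < 0 | m > N | n > N))
    stopf("need 0 <= m, n <= N")
  lo <- pmax(0, n + m - N)
  hi <- pmin(n, m)
  if (any(k < lo | k > hi))
    stopf("k outside its feasible range [max(0, n + m - N), min(n, m)]")
  if (lower) phyper(k, m, N - m, n, lower.tail = TRUE)
  else phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value is the sum of probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table. Degenerate margins (an all-zero row or column) are an error; use
#' [family_enrichment()] for the gene-family wrapper that treats the
#' no-contrast case as p = 1.
#'
#' @param table 2x2 matrix (or vector `c(a, b, c, d)` filled by row) of
#'   non-negative integer counts.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_two_sided(matrix(c(3, 1, 1, 5), 2, byrow = TRUE))  # 40/210
fisher_exact_two_sided <- function(table) {
  if (is.vector(table) && length(table) == 4)
    table <- matrix(table, 2, 2, byrow = TRUE)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stopf("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stopf("table entries must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("degenerate margin: a row or column of the table is zero")
  min(1, stats::fisher.test(table)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min_{j : rank(j) >= rank(i)}
#' p_(j) * m / j`, capped at 1; the input order is preserved.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p_values) {
  if (any(is.na(p_values) | p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Construct a labelled gene group
#'
#' @param direction `"up"` or `"down"`.
#' @param timepoint minutes (10, 30 or 60).
#' @param gene_ids character vector of member gene ids.
#' @return an object of class `gene_group` with a `label` field like
#'   `"up_30"`.
#' @export
gene_group <- function(direction = c("up", "down"), timepoint, gene_ids) {
  direction <- match.arg(direction)
  if (!timepoint %in% c(10, 30, 60))
    stopf("timepoint must be 10, 30 or 60 minutes")
  structure(list(direction = direction, timepoint = as.integer(timepoint),
                 label = sprintf("%s_%d", direction, timepoint),
                 gene_ids = unique(as.character(gene_ids))),
            class = "gene_group")
}

#' Build the six direction-by-timepoint gene groups from a DE table
#'
#' Touch-responsive genes are divided into six groups: up- or down-regulated
#' at each of the 10, 30 and 60 minute timepoints, using the sign of the
#' log2 fold-change among genes passing the q-value cutoff.
#'
#' @param de data frame from [read_de_table()].
#' @param q_cutoff significance cutoff on the adjusted p-value (default
#'   0.1).
#' @param genotype restrict to one genotype label (default: first in the
#'   table).
#' @return named list of six [gene_group()] objects
#'   (`up_10`, `down_10`, ..., `down_60`).
#' @export
gene_groups_from_de <- function(de, q_cutoff = 0.1, genotype = NULL) {
  if (is.null(genotype)) genotype <- de$genotype[1]
  de <- de[de$genotype == genotype, , drop = FALSE]
  groups <- list()
  for (tp in c(10L, 30L, 60L)) {
    sel <- de$timepoint == tp & de$q_value < q_cutoff
    for (dir in c("up", "down")) {
      ids <- de$gene_id[sel & (if (dir == "up") de$log2fc > 0 else de$log2fc < 0)]
      g <- gene_group(dir, tp, ids)
      groups[[g$label]] <- g
    }
  }
  groups
}

#' Hypergeometric enrichment of one motif across gene groups
#'
#' For each group: `N` = background size, `m` = background genes whose
#' promoter contains the motif, `n` = group size, `k` = group genes with
#' the motif; the p-value is the hypergeometric upper tail. q-values are
#' BH-adjusted within this call; when scanning several motifs use
#' [enrich_motifs()] so that the BH family spans all motif-by-group tests
#' of the run.
#'
#' @param matchset a `match_set` from [scan_promoters()] covering the
#'   background.
#' @param groups list of [gene_group()] objects; each must be a subset of
#'   the background.
#' @param background character vector of background gene ids (the universe).
#' @param adjust compute q-values within this call (default TRUE).
#' @return data frame with columns `motif`, `group`, `fg_with`, `fg_total`,
#'   `bg_with`, `bg_total`, `p_value` and (if `adjust`) `q_value`.
#' @export
enrich_motif_in_groups <- function(matchset, groups, background,
                                   adjust = TRUE) {
  background <- unique(as.character(background))
  if (!all(background %in% names(matchset$presence)))
    stopf("matchset does not cover the background universe")
  pres <- matchset$presence[background]
  N <- length(background)
  m <- sum(pres)
  rows <- lapply(groups, function(g) {
    extra <- setdiff(g$gene_ids, background)
    if (length(extra))
      stopf("group %s contains genes outside the background: %s",
            g$label, extra[1])
    n <- length(g$gene_ids)
    if (n == 0) {
      warnf("group %s is empty; p = 1", g$label)
      p <- 1
      k <- 0L
    } else {
      k <- sum(pres[g$gene_ids])
      p <- hypergeom_upper_tail(N, m, n, k)
    }
    data.frame(motif = matchset$motif, group = g$label,
               fg_with = k, fg_total = n, bg_with = m, bg_total = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$q_value <- bh_adjust(out$p_value)
  out
}

#' Enrichment of a set of motifs across gene groups
#'
#' Runs [enrich_motif_in_groups()] for every match set and BH-adjusts over
#' the whole motif-by-group family of the run, flagging results significant
#' at `q_threshold`.
#'
#' @param matchsets list of `match_set` objects.
#' @param groups list of [gene_group()] objects.
#' @param background character vector of background gene ids.
#' @param q_threshold FDR threshold for the `significant` flag (default
#'   0.05).
#' @return data frame as in [enrich_motif_in_groups()] plus `q_value` and
#'   `significant`.
#' @export
enrich_motifs <- function(matchsets, groups, background, q_threshold = 0.05) {
  out <- do.call(rbind, lapply(matchsets, enrich_motif_in_groups,
                               groups = groups, background = background,
                               adjust = FALSE))
  rownames(out) <- NULL
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < q_threshold
  out
}

#' Export a -log10(p) motif-by-group matrix
#'
#' @param enrichment data frame from [enrich_motifs()].
#' @return numeric matrix, motifs in rows and groups in columns, of
#'   `-log10(p)` values.
#' @export
enrichment_neglog10_matrix <- function(enrichment) {
  motifs <- unique(enrichment$motif)
  groups <- unique(enrichment$group)
  m <- matrix(NA_real_, length(motifs), length(groups),
              dimnames = list(motifs, groups))
  m[cbind(match(enrichment$motif, motifs), match(enrichment$group, groups))] <-
    -log10(pmax(enrichment$p_value, .Machine$double.xmin))
  m
}

#' Gene-family enrichment among differentially expressed genes
#'
#' Builds the 2x2 table `[[|family & de|, |family \ de|], [|de \ family|,
#' |universe \ (family | de)|]]` and tests it with the two-sided Fisher
#' exact test. A table with a zero margin carries no contrast and returns
#' p = 1.
#'
#' @param family_ids gene ids of the family.
#' @param de_ids differentially expressed gene ids.
#' @param universe all measured gene ids; both sets must be subsets.
#' @return list with `table` (2x2 matrix) and `p_value`.
#' @export
family_enrichment <- function(family_ids, de_ids, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stopf("empty universe")
  family_ids <- unique(as.character(family_ids))
  de_ids <- unique(as.character(de_ids))
  if (!all(family_ids %in% universe)) stopf("family_ids must be a subset of the universe")
  if (!all(de_ids %in% universe)) stopf("de_ids must be a subset of the universe")
  a <- length(intersect(family_ids, de_ids))
  b <- length(setdiff(family_ids, de_ids))
  cc <- length(setdiff(de_ids, family_ids))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("family", "not_family"),
                                c("de", "not_de")))
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
  else fisher_exact_two_sided(tab)
  list(table = tab, p_value = p)
}
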