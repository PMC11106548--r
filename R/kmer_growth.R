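# --- de novo CRE discovery: exhaustive 6-mer seeding + greedy growth -------
#
# All possible 6-mers are evaluated for gene-level presence enrichment
# (hypergeometric upper tail, foreground vs background promoters). Each
# k-mer is then extended by one base on either end (8 candidates); an
# extension is kept only when its p-value is strictly lower than its
# parent's, and kept children are grown further, up to 12-mers. Reported
# "maximal" k-mers are kept nodes with no kept extension, collapsed to the
# lexicographically smaller of k-mer / reverse complement, and BH-adjusted.
#
# Internally k-mers are 2-bit integer codes; presence counting is compiled
# (see src/kmer_presence.cpp) and counts gene-level presence on either
# strand, identical by contract to a naive per-promoter scan.

promoter_seqs <- function(x) {
  if (inherits(x, "promoter_set")) {
    stats::setNames(x$entries$sequence, x$entries$gene_id)
  } else if (is.character(x)) x
  else stopf("expected a promoter_set or a character vector of sequences")
}

hyper_p_counts <- function(counts, n_fg, n_bg) {
  N <- n_fg + n_bg
  m <- counts[, 1] + counts[, 2]
  phyper(counts[, 1] - 1, m, N - m, n_fg, lower.tail = FALSE)
}

#' Evaluate all 6-mer seeds
#'
#' Enumerates all 4^6 = 4096 candidate 6-mers, counts gene-level presence
#' (either strand) in the foreground and background promoter sets once, and
#' assigns each seed its hypergeometric upper-tail enrichment p-value. All
#' seeds enter growth regardless of seed significance; significance is
#' assessed once, at reporting, over maximal nodes.
#'
#' @param promoters_fg foreground `promoter_set` (or character vector of
#'   sequences, optionally named by gene id).
#' @param promoters_bg background `promoter_set` or character vector;
#'   disjoint from the foreground on gene id.
#' @param k seed length (default 6; capped at 8 since seeds are exhaustive).
#' @return data frame of 4^k seed nodes: `kmer`, `length`, `parent` (NA),
#'   `parent_p` (NA), `fg_with`, `bg_with`, `p_value`, sorted
#'   lexicographically; foreground/background sizes in attributes
#'   `fg_total`, `bg_total`.
#' @export
seed_kmers <- function(promoters_fg, promoters_bg, k = 6L) {
  fg <- promoter_seqs(promoters_fg)
  bg <- promoter_seqs(promoters_bg)
  if (length(fg) == 0) stopf("empty foreground promoter set")
  if (!is.null(names(fg)) && !is.null(names(bg))) {
    shared <- intersect(names(fg), names(bg))
    if (length(shared))
      stopf("foreground and background share gene ids (e.g. %s)", shared[1])
  }
  if (!is_count(k) || k < 4 || k > 8)
    stopf("seed length must be between 4 and 8")
  k <- as.integer(k)
  codes <- 0:(4L^k - 1L)
  cnt <- kmer_presence_counts_codes_cpp(fg, bg, codes, k)
  data.frame(kmer = decode_kmers_cpp(codes, k), length = k,
             parent = NA_character_, parent_p = NA_real_,
             fg_with = cnt[, 1], bg_with = cnt[, 2],
             p_value = hyper_p_counts(cnt, length(fg), length(bg)),
             stringsAsFactors = FALSE) -> nodes
  attr(nodes, "fg_total") <- length(fg)
  attr(nodes, "bg_total") <- length(bg)
  nodes
}

#' Grow one k-mer node (reference implementation)
#'
#' Candidate children are the 8 single-base extensions `{b+kmer, kmer+b}`
#' for b in A, C, G, T. A child is kept iff its enrichment p-value is
#' strictly lower than the node's; kept children are grown recursively
#' until length `max_len` or no child improves. [discover_kmers()] computes
#' the identical kept-node set level-wise and is the driver to use at
#' scale.
#'
#' @param node list or single-row data frame with `kmer` and `p_value`.
#' @param promoters_fg,promoters_bg promoter sets as in [seed_kmers()].
#' @param max_len maximum k-mer length (default 12).
#' @return data frame of kept descendant nodes (possibly empty) with the
#'   same columns as [seed_kmers()].
#' @export
grow <- function(node, promoters_fg, promoters_bg, max_len = 12L) {
  fg <- promoter_seqs(promoters_fg)
  bg <- promoter_seqs(promoters_bg)
  empty <- data.frame(kmer = character(), length = integer(),
                      parent = character(), parent_p = numeric(),
                      fg_with = integer(), bg_with = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  recurse <- function(kmer, p) {
    if (nchar(kmer) >= max_len) return(empty)
    bases <- c("A", "C", "G", "T")
    cand <- unique(c(paste0(bases, kmer), paste0(kmer, bases)))
    cnt <- kmer_presence_counts_cpp(fg, bg, cand)
    cp <- hyper_p_counts(cnt, length(fg), length(bg))
    keep <- which(cp < p)
    if (!length(keep)) return(empty)
    kept <- data.frame(kmer = cand[keep], length = nchar(kmer) + 1L,
                       parent = kmer, parent_p = p,
                       fg_with = cnt[keep, 1], bg_with = cnt[keep, 2],
                       p_value = cp[keep], stringsAsFactors = FALSE)
    deeper <- lapply(keep, function(i) recurse(cand[i], cp[i]))
    rbind(kept, do.call(rbind, deeper))
  }
  out <- recurse(node$kmer, node$p_value)
  rownames(out) <- NULL
  out
}

#' De novo k-mer discovery by seeded growth
#'
#' Runs the full seed-and-grow search level-wise: all `4^kmin` seeds, then
#' for each level the 8 single-base extensions of every kept node, keeping
#' a child iff its p-value is strictly below its parent's, up to `kmax`.
#' A child string reachable from several parents is evaluated once; its
#' recorded parent is the lexicographically smallest qualifying parent.
#' The algorithm is deterministic.
#'
#' @param promoters_fg,promoters_bg promoter sets as in [seed_kmers()].
#' @param kmin seed length (default 6).
#' @param kmax maximum k-mer length (default 12).
#' @param q_threshold FDR threshold passed to [growth_report()].
#' @return an object of class `growth_forest`: list with `nodes` (all kept
#'   nodes with a `maximal` flag), `fg_total`, `bg_total`, `kmin`, `kmax`,
#'   and `report` (the [growth_report()] of the forest).
#' @export
discover_kmers <- function(promoters_fg, promoters_bg, kmin = 6L,
                           kmax = 12L, q_threshold = 0.05) {
  fg <- promoter_seqs(promoters_fg)
  bg <- promoter_seqs(promoters_bg)
  if (length(fg) == 0) stopf("empty foreground promoter set")
  if (!is_count(kmin) || !is_count(kmax) || kmin > kmax)
    stopf("need kmin <= kmax")
  if (kmin < 4 || kmin > 8) stopf("seed length must be between 4 and 8")
  if (kmax > 15) stopf("kmax must be <= 15")
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  n_fg <- length(fg); n_bg <- length(bg)

  k <- kmin
  codes <- 0:(4L^kmin - 1L)
  cnt <- kmer_presence_counts_codes_cpp(fg, bg, codes, k)
  levels <- list(list(k = k, codes = codes, p = hyper_p_counts(cnt, n_fg, n_bg),
                      fg = cnt[, 1], bg = cnt[, 2],
                      parent = rep(NA_integer_, length(codes)),
                      parent_p = rep(NA_real_, length(codes))))
  kept_parents <- list()

  while (k < kmax) {
    lev <- levels[[length(levels)]]
    m <- length(lev$codes)
    if (m == 0) break
    four_k <- as.integer(4^k)
    child <- c(rep(lev$codes, times = 4) + rep(0:3, each = m) * four_k,
               rep(lev$codes, times = 4) * 4L + rep(0:3, each = m))
    par_idx <- rep(seq_len(m), 8)
    uch <- sort(unique(child))
    cnt <- kmer_presence_counts_codes_cpp(fg, bg, uch, k + 1L)
    cp <- hyper_p_counts(cnt, n_fg, n_bg)
    ci <- match(child, uch)
    keep <- cp[ci] < lev$p[par_idx]
    kept_parents[[length(kept_parents) + 1L]] <-
      unique(lev$codes[par_idx[keep]])
    child <- child[keep]; par_idx <- par_idx[keep]
    if (!length(child)) break
    o <- order(child, lev$codes[par_idx], method = "radix")
    child <- child[o]; par_idx <- par_idx[o]
    first <- !duplicated(child)
    child <- child[first]; par_idx <- par_idx[first]
    ci <- match(child, uch)
    k <- k + 1L
    levels[[length(levels) + 1L]] <-
      list(k = k, codes = child, p = cp[ci],
           fg = cnt[ci, 1], bg = cnt[ci, 2],
           parent = lev$codes[par_idx], parent_p = lev$p[par_idx])
  }

  nodes <- do.call(rbind, lapply(seq_along(levels), function(i) {
    lev <- levels[[i]]
    kp <- if (i <= length(kept_parents)) kept_parents[[i]] else integer(0)
    parent <- if (all(is.na(lev$parent))) rep(NA_character_, length(lev$codes))
    else decode_kmers_cpp(lev$parent, lev$k - 1L)
    data.frame(kmer = decode_kmers_cpp(lev$codes, lev$k), length = lev$k,
               parent = parent, parent_p = lev$parent_p,
               fg_with = lev$fg, bg_with = lev$bg, p_value = lev$p,
               maximal = !(lev$codes %in% kp),
               canonical = decode_kmers_cpp(
                 pmin(lev$codes, revcomp_codes_cpp(lev$codes, lev$k)), lev$k),
               stringsAsFactors = FALSE)
  }))
  rownames(nodes) <- NULL
  forest <- structure(list(nodes = nodes, fg_total = n_fg, bg_total = n_bg,
                           kmin = kmin, kmax = kmax),
                      class = "growth_forest")
  forest$report <- growth_report(forest, q_threshold = q_threshold)
  forest
}

#' @export
print.growth_forest <- function(x, ...) {
  cat(sprintf(paste0("growth_forest: %d kept nodes (lengths %d-%d), ",
                     "%d/%d fg/bg promoters; %d maximal after collapse, ",
                     "%d significant\n"),
              nrow(x$nodes), min(x$nodes$length), max(x$nodes$length),
              x$fg_total, x$bg_total, nrow(x$report),
              sum(x$report$significant)))
  invisible(x)
}

#' Report maximal k-mers of a growth forest
#'
#' Collects maximal nodes (kept nodes with no kept extension), collapses
#' each to its canonical form -- the lexicographic minimum of the k-mer and
#' its reverse complement, merging exact duplicates and keeping the smaller
#' p-value -- and BH-adjusts p-values across the surviving nodes.
#'
#' @param forest a `growth_forest` from [discover_kmers()].
#' @param q_threshold FDR threshold for the `significant` flag (default
#'   0.05).
#' @return data frame with columns `kmer` (canonical form), `length`,
#'   `parent`, `fg_with`, `fg_total`, `bg_with`, `bg_total`, `p_value`,
#'   `q_value`, `canonical`, `maximal`, `significant`, ordered by p-value.
#' @export
growth_report <- function(forest, q_threshold = 0.05) {
  nodes <- forest$nodes[forest$nodes$maximal, , drop = FALSE]
  o <- order(nodes$canonical, nodes$p_value, nodes$kmer, method = "radix")
  nodes <- nodes[o, , drop = FALSE]
  nodes <- nodes[!duplicated(nodes$canonical), , drop = FALSE]
  out <- data.frame(kmer = nodes$kmer, length = nodes$length,
                    parent = nodes$parent,
                    fg_with = nodes$fg_with, fg_total = forest$fg_total,
                    bg_with = nodes$bg_with, bg_total = forest$bg_total,
                    p_value = nodes$p_value,
                    q_value = bh_adjust(nodes$p_value),
                    canonical = nodes$canonical, maximal = TRUE,
                    stringsAsFactors = FALSE)
  out$significant <- out$q_value < q_threshold
  out <- out[order(out$p_value, out$canonical, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
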