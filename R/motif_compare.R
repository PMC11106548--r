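# --- matching discovered k-mers against a known-motif library --------------
#
# Ungapped column alignment of probability matrices. The per-offset score is
# the mean, over query columns, of the Pearson correlation between the
# query column and its aligned target column; query columns hanging off the
# target are compared against the uniform background (0.25 each), whose
# zero variance makes their contribution 0 under the degenerate-column
# guard. Significance comes from an empirical null that permutes the query
# columns, with BH control across the library per query.

# standardise PFM probability columns for Pearson correlation:
# (x - mean) / sd, zero for degenerate (constant) columns; with these,
# cor(x, y) = crossprod(xs, ys) / 3.
standardize_cols <- function(prob) {
  ctr <- sweep(prob, 2, colMeans(prob), "-")
  sdv <- sqrt(colSums(ctr^2) / 3)
  ok <- sdv > 1e-12
  ctr[, ok] <- sweep(ctr[, ok, drop = FALSE], 2, sdv[ok], "/")
  ctr[, !ok] <- 0
  ctr
}

#' Alignment score between two PFMs at a fixed offset
#'
#' Query column `i` is paired with target column `i + offset`; columns
#' falling outside the target are paired with the uniform background and
#' contribute 0 (degenerate-column guard). The score is the mean Pearson
#' correlation over all query columns. At least 4 query columns must
#' overlap the target.
#'
#' @param query,target [pfm()] objects.
#' @param offset integer offset of query column 1 relative to target
#'   column 1 (0 = left-aligned).
#' @param orientation `"+"` to compare against the target as given, `"-"`
#'   against its reverse complement.
#' @return alignment score in `[-1, 1]`.
#' @export
align_score <- function(query, target, offset = 0L,
                        orientation = c("+", "-")) {
  orientation <- match.arg(orientation)
  if (orientation == "-") target <- revcomp_pfm(target)
  q <- pfm_prob(query)
  t_ <- pfm_prob(target)
  wq <- ncol(q); wt <- ncol(t_)
  idx <- seq_len(wq) + offset
  overlap <- sum(idx >= 1 & idx <= wt)
  if (overlap < 4)
    stopf("offset %d leaves %d overlapping column(s); need at least 4",
          offset, overlap)
  qs <- standardize_cols(q)
  ts <- standardize_cols(t_)
  contrib <- numeric(wq)
  inside <- idx >= 1 & idx <= wt
  contrib[inside] <- colSums(qs[, inside, drop = FALSE] *
                               ts[, idx[inside], drop = FALSE]) / 3
  mean(contrib)
}

# per-column correlation matrix between two PFMs (wq x wt); band sums over
# its diagonals give all offset scores at once.
column_cor_matrix <- function(query_prob, target_prob) {
  crossprod(standardize_cols(query_prob), standardize_cols(target_prob)) / 3
}

# scores for every admissible offset given a (possibly row-permuted)
# correlation matrix; returns named vector indexed by offset.
offset_scores <- function(cormat, perm = NULL) {
  wq <- nrow(cormat); wt <- ncol(cormat)
  if (!is.null(perm)) cormat <- cormat[perm, , drop = FALSE]
  offs <- (4L - wq):(wt - 4L)
  vapply(offs, function(o) {
    i <- seq_len(wq)
    j <- i + o
    ok <- j >= 1 & j <= wt
    sum(cormat[cbind(i[ok], j[ok])]) / wq
  }, numeric(1)) -> sc
  names(sc) <- offs
  sc
}

#' Best library match for a query motif with an empirical shuffle null
#'
#' For every library member the score is maximised over all offsets with at
#' least 4 overlapping columns and both orientations. The empirical
#' p-value compares the observed best score against the best scores of
#' `n_shuffles` column-permuted copies of the query (the same permutations
#' for every target), with +1 smoothing:
#' `p = (1 + #\{shuffled >= observed\}) / (1 + n_shuffles)`. q-values are
#' BH-adjusted across the library; a match is reported at `q < match_fdr`.
#'
#' @param query a [pfm()] with at least 4 columns.
#' @param library list of [pfm()] objects.
#' @param n_shuffles number of column permutations (>= 99; default 999).
#' @param seed integer seed for the permutation generator (required).
#' @param match_fdr FDR cutoff for the `matched` flag (default 0.01).
#' @return data frame with one row per library member: `query`, `target`,
#'   `offset`, `orientation`, `score`, `empirical_p`, `q_value`, `matched`,
#'   ordered by q then score.
#' @export
best_match <- function(query, library, n_shuffles = 999L, seed,
                       match_fdr = 0.01) {
  if (missing(seed) || !is_count(seed)) stopf("a single integer seed is required")
  if (!is_count(n_shuffles) || n_shuffles < 99)
    stopf("n_shuffles must be at least 99")
  if (ncol(query$counts) < 4)
    stopf("query '%s' has %d column(s); minimum informative width is 4",
          query$name, ncol(query$counts))
  empty <- data.frame(query = character(), target = character(),
                      offset = integer(), orientation = character(),
                      score = numeric(), empirical_p = numeric(),
                      q_value = numeric(), matched = logical(),
                      stringsAsFactors = FALSE)
  if (!length(library)) return(empty)
  qp <- pfm_prob(query)
  wq <- ncol(qp)
  perms <- withr::with_seed(as.integer(seed), {
    replicate(as.integer(n_shuffles), sample.int(wq), simplify = FALSE)
  })
  rows <- lapply(library, function(target) {
    tp <- pfm_prob(target)
    if (ncol(tp) < 4)
      stopf("library member '%s' is narrower than 4 columns", target$name)
    best <- list(score = -Inf, offset = NA_integer_, orientation = NA_character_)
    cors <- list(`+` = column_cor_matrix(qp, tp),
                 `-` = column_cor_matrix(qp, pfm_prob(revcomp_pfm(target))))
    for (ori in c("+", "-")) {
      sc <- offset_scores(cors[[ori]])
      i <- which.max(sc)
      if (sc[i] > best$score)
        best <- list(score = unname(sc[i]),
                     offset = as.integer(names(sc)[i]), orientation = ori)
    }
    shuf_best <- vapply(perms, function(p)
      max(max(offset_scores(cors[["+"]], p)),
          max(offset_scores(cors[["-"]], p))), numeric(1))
    p_emp <- (1 + sum(shuf_best >= best$score)) / (1 + length(perms))
    data.frame(query = query$name, target = target$name,
               offset = best$offset, orientation = best$orientation,
               score = best$score, empirical_p = p_emp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- bh_adjust(out$empirical_p)
  out$matched <- out$q_value < match_fdr
  out[order(out$q_value, -out$score, out$target, method = "radix"), ,
      drop = FALSE]
}

#' Match a set of discovered k-mers against a motif library
#'
#' Converts each k-mer (and each library consensus, if given as IUPAC) to a
#' PFM via [kmer_to_pfm()] and runs [best_match()] per query.
#'
#' @param kmers character vector of discovered k-mers.
#' @param library named list of [pfm()] or [iupac_motif()] objects.
#' @param n_shuffles,seed,match_fdr passed to [best_match()].
#' @param pseudocount smoothing used when converting consensi to PFMs
#'   (default 0.1).
#' @return data frame of per-(query, target) results as in [best_match()].
#' @export
compare_kmers_to_library <- function(kmers, library, n_shuffles = 999L,
                                     seed, match_fdr = 0.01,
                                     pseudocount = 0.1) {
  lib <- lapply(library, function(m)
    if (inherits(m, "pfm")) m else kmer_to_pfm(m, pseudocount))
  out <- lapply(kmers, function(km)
    best_match(kmer_to_pfm(km, pseudocount), lib, n_shuffles = n_shuffles,
               seed = seed, match_fdr = match_fdr))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
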