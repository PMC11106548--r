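#' IUPAC nucleotide ambiguity classes
#'
#' Named list mapping each of the 15 IUPAC symbols to its set of concrete
#' bases (e.g. `R` = A/G, `W` = A/T, `N` = any).
#'
#' @export
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' @noRd
check_iupac <- function(consensus) {
  if (length(consensus) != 1L || !is.character(consensus) || is.na(consensus))
    stopf("consensus must be a single string")
  sym <- strsplit(consensus, "", fixed = TRUE)[[1]]
  bad <- !(sym %in% names(IUPAC_CLASSES))
  if (any(bad))
    stopf("invalid IUPAC symbol '%s' at offset %d in '%s'",
          sym[bad][1], which(bad)[1] - 1L, consensus)
  invisible(sym)
}

#' Construct a named IUPAC consensus motif
#'
#' @param name motif name.
#' @param consensus string over the 15-letter IUPAC alphabet, length >= 4.
#' @return an object of class `iupac_motif`.
#' @export
iupac_motif <- function(name, consensus) {
  check_iupac(consensus)
  if (nchar(consensus) < 4) stopf("consensus '%s' is shorter than 4", consensus)
  structure(list(name = name, consensus = consensus), class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat(sprintf("iupac_motif %s: %s\n", x$name, x$consensus))
  invisible(x)
}

#' Reverse complement of an IUPAC consensus
#'
#' Complement maps A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W and N are
#' self-complementary. The result is reversed. An involution on all 15
#' symbols.
#'
#' @param consensus IUPAC consensus string.
#' @return reverse-complemented consensus.
#' @export
#' @examples
#' reverse_complement("MCAGCTGK")  # palindromic under IUPAC: "MCAGCTGK"
reverse_complement <- function(consensus) {
  check_iupac(consensus)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", consensus)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# translate a consensus into a regex of concrete-base character classes;
# N in the *subject* can never match because classes contain only A/C/G/T.
iupac_to_regex <- function(consensus) {
  sym <- check_iupac(consensus)
  paste(vapply(sym, function(s) {
    b <- IUPAC_CLASSES[[s]]
    if (length(b) == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Match an IUPAC consensus against one strand of a sequence
#'
#' Position `p` (0-based) is reported iff, for every consensus symbol, the
#' symbol's allowed base set contains the subject base at `p + i`. `N` in
#' the subject matches nothing. Matches may overlap.
#'
#' @param consensus IUPAC consensus string.
#' @param sequence subject sequence over A,C,G,T,N.
#' @return integer vector of 0-based match start positions.
#' @export
#' @examples
#' iupac_match("MCAGCTGK", "ACAGCTGT")  # 0
iupac_match <- function(consensus, sequence) {
  if (length(sequence) != 1L || is.na(sequence))
    stopf("sequence must be a single string")
  if (grepl("[^ACGTN]", sequence))
    stopf("sequence contains characters outside A,C,G,T,N")
  rx <- iupac_to_regex(consensus)
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a promoter set for a motif
#'
#' Scans every promoter sequence for the consensus, on the forward strand
#' and (by default) the reverse strand via the reverse-complemented
#' consensus. A site matching both strands at the same start (a palindromic
#' site) is counted once. The per-gene presence flag -- not the occurrence
#' count -- is what feeds the hypergeometric enrichment test, which models
#' draws of genes, not sites.
#'
#' @param motif an [iupac_motif()] or a bare consensus string.
#' @param promoters a `promoter_set`.
#' @param both_strands scan both strands (default TRUE).
#' @return an object of class `match_set`: list with `motif` (name),
#'   `consensus`, `matches` (data frame `gene_id`, `position`, `strand`) and
#'   `presence` (named logical over all promoters).
#' @export
scan_promoters <- function(motif, promoters, both_strands = TRUE) {
  if (is.character(motif)) motif <- iupac_motif(motif, motif)
  if (!inherits(promoters, "promoter_set") || nrow(promoters$entries) == 0)
    stopf("promoters must be a non-empty promoter_set")
  cons <- motif$consensus
  rc <- reverse_complement(cons)
  entries <- promoters$entries
  res <- lapply(seq_len(nrow(entries)), function(i) {
    s <- entries$sequence[i]
    fwd <- iupac_match(cons, s)
    if (!both_strands)
      return(data.frame(gene_id = rep(entries$gene_id[i], length(fwd)),
                        position = fwd, strand = rep("+", length(fwd)),
                        stringsAsFactors = FALSE))
    rev <- iupac_match(rc, s)
    rev <- setdiff(rev, fwd)  # same start + same length: palindromic site, once
    data.frame(gene_id = rep(entries$gene_id[i], length(fwd) + length(rev)),
               position = c(fwd, rev),
               strand = c(rep("+", length(fwd)), rep("-", length(rev))),
               stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, res)
  presence <- stats::setNames(entries$gene_id %in% matches$gene_id,
                              entries$gene_id)
  structure(list(motif = motif$name, consensus = cons,
                 matches = matches, presence = presence),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("match_set %s (%s): %d matches in %d/%d promoters\n",
              x$motif, x$consensus, nrow(x$matches), sum(x$presence),
              length(x$presence)))
  invisible(x)
}

#' Construct a position frequency matrix
#'
#' @param name motif name.
#' @param counts 4 x width numeric matrix of non-negative counts, rows
#'   A,C,G,T. Every column sum must be positive.
#' @return an object of class `pfm`.
#' @export
pfm <- function(name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stopf("a PFM needs 4 rows (A,C,G,T)")
  dimnames(counts) <- list(c("A", "C", "G", "T"), NULL)
  if (any(counts < 0)) stopf("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) stopf("every PFM column sum must be > 0")
  structure(list(name = name, counts = counts), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm %s (%d columns)\n", x$name, ncol(x$counts)))
  print(round(pfm_prob(x), 3))
  invisible(x)
}

#' Column-normalised probability form of a PFM
#'
#' @param x a [pfm()].
#' @return 4 x width matrix of column probabilities (each column sums to 1).
#' @export
pfm_prob <- function(x) {
  sweep(x$counts, 2, colSums(x$counts), "/")
}

#' Convert a k-mer or IUPAC consensus to a PFM
#'
#' Each column distributes unit mass equally over the symbol's allowed
#' bases; `pseudocount` is then added to all four cells of every column.
#'
#' @param x a k-mer/consensus string or an [iupac_motif()].
#' @param pseudocount non-negative smoothing count added to every cell
#'   (default 0).
#' @param name optional motif name (defaults to the consensus).
#' @return a [pfm()].
#' @export
#' @examples
#' kmer_to_pfm("R")$counts[, 1]  # A and G get 0.5 each
kmer_to_pfm <- function(x, pseudocount = 0, name = NULL) {
  if (inherits(x, "iupac_motif")) {
    if (is.null(name)) name <- x$name
    x <- x$consensus
  }
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  sym <- check_iupac(x)
  counts <- vapply(sym, function(s) {
    col <- rep(pseudocount, 4)
    names(col) <- c("A", "C", "G", "T")
    b <- IUPAC_CLASSES[[s]]
    col[b] <- col[b] + 1 / length(b)
    col
  }, numeric(4))
  pfm(if (is.null(name)) x else name, counts)
}

#' Reverse complement a PFM
#'
#' Reverses column order and swaps A<->T and C<->G within each column.
#'
#' @param x a [pfm()].
#' @return a [pfm()].
#' @export
revcomp_pfm <- function(x) {
  m <- x$counts[c("T", "G", "C", "A"), rev(seq_len(ncol(x$counts))),
                drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pfm(x$name, m)
}

#' Read a motif library file
#'
#' One motif per line, `name<TAB>IUPAC`; lines starting with `#` are
#' comments.
#'
#' @param path path to the library file.
#' @return named list of [iupac_motif()] objects.
#' @export
read_motif_library <- function(path) {
  if (!file.exists(path)) stopf("motif library not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2
  if (any(bad)) stopf("malformed motif library line: %s", lines[bad][1])
  motifs <- lapply(fields, function(f) iupac_motif(f[[1]], f[[2]]))
  stats::setNames(motifs, vapply(motifs, `[[`, character(1), "name"))
}

#' The bundled known-CRE library
#'
#' Cis-regulatory consensi with published sequences relevant to plant touch
#' and cell-wall transcriptional responses: the GCC boxes, the E-box/G-box
#' CACGTG, the site II element, the TCP site II element, the AC element and
#' two E-box variants bound by a wall-associated bZIP. Elements whose
#' consensus is not published as a concrete sequence (RSRE, CM2, AP2-like,
#' P-box, GRF, FAR1, VNS, CGCG-box, GATA-like, homeobox) are listed as
#' commented placeholders in the file for the user to fill; they are not
#' invented here.
#'
#' @return named list of [iupac_motif()] objects.
#' @export
known_cre_library <- function() {
  read_motif_library(system.file("extdata", "known_cres.tsv",
                                 package = "touchcre", mustWork = TRUE))
}

#' Write PFMs in MEME minimal format
#'
#' @param pfms list of [pfm()] objects.
#' @param path output path.
#' @param background background base frequencies (default uniform).
#' @return invisibly, `path`.
#' @export
write_meme_pfm <- function(pfms, path, background = rep(0.25, 4)) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con, sep = "\n")
  for (p in pfms) {
    pr <- pfm_prob(p)
    nsites <- max(1, round(sum(p$counts) / ncol(p$counts)))
    writeLines(c(sprintf("MOTIF %s", p$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         ncol(pr), nsites)), con, sep = "\n")
    writeLines(apply(pr, 2, function(col)
      sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])),
      con, sep = "\n")
    writeLines("", con, sep = "\n")
  }
  invisible(path)
}

#' Read PFMs from MEME minimal format
#'
#' @param path path to a MEME minimal file.
#' @return named list of [pfm()] objects.
#' @export
read_meme_pfm <- function(path) {
  if (!file.exists(path)) stopf("MEME file not found: %s", path)
  lines <- readLines(path)
  mi <- grep("^MOTIF\\s", lines)
  if (!length(mi)) stopf("no MOTIF entries in %s", path)
  out <- lapply(mi, function(i) {
    name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i + 1
    while (j <= length(lines) && !grepl("^letter-probability", lines[j])) j <- j + 1
    if (j > length(lines)) stopf("motif %s has no probability matrix", name)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1):(j + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    pfm(name, t(m))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}
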