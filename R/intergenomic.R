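# VIRIDIC-style intergenomic similarity.
#
# The statistic is fixed as
#     sim(A, B) = 100 * (I_A / len(A) + I_B / len(B)) / 2
# where I_A (resp. I_B) is the number of positions of A (B) covered by an
# identical aligned position after merging alignment blocks, each genome
# position credited at most once. Blocks come from exact k-mer seeding on
# both strands followed by ungapped extension along the seeded diagonal;
# a block is broken wherever the running score (+1 match, -mismatch_penalty)
# would drop by more than `xdrop`, i.e. at any mismatch run of length
# >= ceiling(xdrop / mismatch_penalty), and trimmed to its first/last match.
# `N` mismatches everything, including another `N`.

default_align_params <- function() {
  list(k = 15L, min_block = 100L, xdrop = 20L, mismatch_penalty = 2L,
       max_occ = 8L, pad = 200L)
}

# k-mer -> positions index for one sequence; k-mers containing N or occurring
# more than max_occ times are dropped.
kmer_index <- function(s, k, max_occ) {
  n <- nchar(s)
  if (n < k) return(list())
  km <- substring(s, 1:(n - k + 1L), k:n)
  keep <- !grepl("N", km, fixed = TRUE)
  pos <- which(keep)
  idx <- split(pos, km[keep])
  idx[lengths(idx) <= max_occ]
}

# ungapped blocks between a and one strand of b along seeded diagonals
diagonal_blocks <- function(ra, rb, idx_a, kb, strand, p) {
  na <- length(ra); nb <- length(rb)
  if (length(kb) == 0L || length(idx_a) == 0L) return(NULL)
  hit <- match(kb, names(idx_a))
  bpos <- which(!is.na(hit))
  if (length(bpos) == 0L) return(NULL)
  apos_list <- idx_a[hit[bpos]]
  bpos <- rep.int(bpos, lengths(apos_list))
  apos <- unlist(apos_list, use.names = FALSE)
  diag <- apos - bpos
  max_gap <- as.integer(ceiling(p$xdrop / p$mismatch_penalty))
  blocks <- list(); nb_out <- 0L
  nraw <- charToRaw("N")
  for (d in sort(unique(diag))) {
    bp <- bpos[diag == d]
    lo <- max(1L, min(bp) - p$pad, 1L - d)
    hi <- min(nb, max(bp) + p$k - 1L + p$pad, na - d)
    if (hi < lo) next
    seg_b <- rb[lo:hi]
    seg_a <- ra[(lo + d):(hi + d)]
    m <- (seg_a == seg_b) & (seg_a != nraw)
    r <- rle(m)
    cut <- !r$values & r$lengths >= max_gap
    grp <- cumsum(cut)  # segment id; changes at each breaking mismatch run
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (g in unique(grp)) {
      sel <- which(grp == g & r$values)  # match runs in this segment
      if (length(sel) == 0L) next
      s0 <- starts[sel[1L]]
      e0 <- ends[sel[length(sel)]]
      len <- e0 - s0 + 1L
      if (len < p$min_block) next
      nmatch <- sum(r$lengths[sel])
      nb_out <- nb_out + 1L
      blocks[[nb_out]] <- c(a_start = lo + d + s0 - 1L, a_end = lo + d + e0 - 1L,
                            b_start = lo + s0 - 1L, b_end = lo + e0 - 1L,
                            matches = nmatch, aln_len = len)
    }
  }
  if (nb_out == 0L) return(NULL)
  out <- as.data.frame(do.call(rbind, blocks))
  out$strand <- strand
  out
}

#' Seed-and-extend nucleotide alignment blocks between two genomes
#'
#' Finds exact `k`-mer seeds on both strands of `b`, extends each seeded
#' diagonal ungapped until the score drops (see package vignette), and
#' reports blocks of length at least `min_block` with their identical-position
#' counts. Deterministic for fixed inputs and parameters. `b`-coordinates of
#' minus-strand blocks refer to the reverse-complement strand of `b`.
#'
#' @param a,b DNA strings.
#' @param k Seed length (default 15, must be >= 8).
#' @param min_block Minimum reported block length in bp (default 100).
#' @param xdrop Score drop that terminates extension (default 20).
#' @param mismatch_penalty Per-mismatch score penalty (default 2; match = +1).
#' @param max_occ Seeds occurring more often than this in `a` are skipped.
#' @param pad Extension allowance beyond the outermost seeds of a diagonal.
#' @return `data.frame` with columns `a_start`, `a_end`, `b_start`, `b_end`,
#'   `matches`, `aln_len`, `strand`; zero rows if no block was found.
#' @export
seed_extend_align <- function(a, b, k = 15L, min_block = 100L, xdrop = 20L,
                              mismatch_penalty = 2L, max_occ = 8L,
                              pad = 200L) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L, k >= 8L)
  p <- list(k = as.integer(k), min_block = as.integer(min_block),
            xdrop = xdrop, mismatch_penalty = mismatch_penalty,
            max_occ = max_occ, pad = as.integer(pad))
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      matches = integer(), aln_len = integer(),
                      strand = character())
  if (nchar(a) < k || nchar(b) < k) return(empty)
  idx_a <- kmer_index(a, p$k, p$max_occ)
  ra <- charToRaw(a)
  res <- list()
  for (strand in c("+", "-")) {
    bs <- if (strand == "+") b else revcomp(b)
    rb <- charToRaw(bs)
    kb <- substring(bs, 1:(nchar(bs) - p$k + 1L), p$k:nchar(bs))
    res[[strand]] <- diagonal_blocks(ra, rb, idx_a, kb, strand, p)
  }
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(-out$matches, out$a_start, out$b_start), , drop = FALSE]
}

#' Merge alignment blocks on one genome and total the identical positions
#'
#' Overlaps are resolved greedily by descending match count (ties by
#' `a_start`, then `b_start`); each genome position is counted at most once.
#' A lower-priority block overlapping already-covered positions is credited
#' pro-rata: `matches * uncovered_length / block_length`.
#'
#' @param blocks Blocks from [seed_extend_align()] for one genome pair.
#' @param genome `"A"` or `"B"`: which genome's coordinates to merge on.
#' @param len Length of that genome in bp (needed to map minus-strand
#'   `B` coordinates back to the forward strand).
#' @return `list(intervals = data.frame(start, end), matches = total credited
#'   identical positions)`.
#' @export
merge_blocks <- function(blocks, genome = c("A", "B"), len) {
  genome <- match.arg(genome)
  if (nrow(blocks) == 0L)
    return(list(intervals = data.frame(start = integer(), end = integer()),
                matches = 0))
  if (genome == "A") {
    s <- blocks$a_start; e <- blocks$a_end
  } else {
    s <- blocks$b_start; e <- blocks$b_end
    neg <- blocks$strand == "-"
    s2 <- ifelse(neg, len - blocks$b_end + 1L, s)
    e2 <- ifelse(neg, len - blocks$b_start + 1L, e)
    s <- s2; e <- e2
  }
  ord <- order(-blocks$matches, blocks$a_start, blocks$b_start)
  covered <- logical(len)
  total <- 0
  for (i in ord) {
    span <- s[i]:e[i]
    uncov <- !covered[span]
    n_unc <- sum(uncov)
    if (n_unc == 0L) next
    total <- total + as.numeric(blocks$matches[i]) * n_unc / length(span)
    covered[span] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  list(intervals = data.frame(start = starts[r$values], end = ends[r$values]),
       matches = total)
}

# core pair statistic, optionally with a prebuilt index for `a`
pair_similarity <- function(a, b, params, idx_a = NULL) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L || lb == 0L) stop("zero-length genome")
  blocks <- if (is.null(idx_a)) {
    do.call(seed_extend_align, c(list(a = a, b = b), params))
  } else {
    p <- utils::modifyList(default_align_params(), params)
    ra <- charToRaw(a)
    res <- list()
    for (strand in c("+", "-")) {
      bs <- if (strand == "+") b else revcomp(b)
      kb <- substring(bs, 1:(nchar(bs) - p$k + 1L), p$k:nchar(bs))
      res[[strand]] <- diagonal_blocks(ra, charToRaw(bs), idx_a, kb, strand, p)
    }
    res <- res[!vapply(res, is.null, logical(1L))]
    if (length(res) == 0L) {
      data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
                 b_end = integer(), matches = integer(), aln_len = integer(),
                 strand = character())
    } else do.call(rbind, res)
  }
  ia <- merge_blocks(blocks, "A", la)$matches
  ib <- merge_blocks(blocks, "B", lb)$matches
  min(100, 100 * (ia / la + ib / lb) / 2)
}

#' Intergenomic nucleotide similarity between two genomes (percent)
#'
#' `100 * (I_A/len(A) + I_B/len(B)) / 2` with `I_A`, `I_B` the merged
#' identical-position totals credited to each genome (the VIRIDIC statistic).
#' Identical genomes give exactly 100.
#'
#' @param a,b DNA strings.
#' @param ... Alignment parameters passed to [seed_extend_align()].
#' @return Percent similarity in `[0, 100]`.
#' @export
intergenomic_similarity <- function(a, b, ...) {
  pair_similarity(a, b, list(...))
}

#' Pairwise intergenomic similarity matrix
#'
#' @param genomes Named character vector of genome sequences
#'   (e.g. from [read_genome_fasta()]).
#' @param ... Alignment parameters passed to [seed_extend_align()].
#' @return Symmetric percent matrix with a diagonal of 100 and genome ids as
#'   dimnames.
#' @export
similarity_matrix <- function(genomes, ...) {
  n <- length(genomes)
  stopifnot(n >= 2L)
  ids <- names(genomes)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("genomes must carry unique non-empty names")
  params <- list(...)
  p <- utils::modifyList(default_align_params(), params)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    idx_a <- kmer_index(genomes[[i]], p$k, p$max_occ)
    for (j in (i + 1L):n) {
      s <- pair_similarity(genomes[[i]], genomes[[j]], p, idx_a = idx_a)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}
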