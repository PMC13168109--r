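#' Read phage genome sequences from a FASTA file
#'
#' Reads a (multi-record) nucleotide FASTA file into a named character vector
#' of uppercase genome sequences. The header token up to the first whitespace
#' becomes the genome identifier. Only the characters `A`, `C`, `G`, `T`, `N`
#' are accepted.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return Named character vector of genome sequences (class `genome_set`).
#'   `names()` are the genome identifiers; record order is preserved.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "acgt", "ACGT"), f)
#' g <- read_genome_fasta(f)
#' nchar(g)  # g1 = 8
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("empty genome identifier in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate identifier: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L)
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   substr(seqs[[i]], bad, bad), ids[[i]], bad))
    if (nchar(seqs[[i]]) == 0L)
      stop("empty sequence for record '", ids[[i]], "'")
  }
  structure(seqs, class = c("genome_set", "character"))
}

#' Write genome sequences to FASTA
#'
#' @param genomes Named character vector of sequences.
#' @param path Output file path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genomes)) {
    writeLines(paste0(">", id), con)
    s <- genomes[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read per-genome protein complements from a tagged protein FASTA
#'
#' Headers follow the `genomeID|geneID` dialect so that every protein carries
#' an unambiguous join key for the presence/absence matrix. Anything after the
#' first whitespace is kept as an optional annotation label.
#'
#' @param path Path to a protein FASTA file.
#' @return A `data.frame` with columns `genome_id`, `gene_id`, `aa`,
#'   `label` (annotation string or `NA`).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no records in ", path)
  hdr <- names(x)
  tok <- sub("\\s.*$", "", hdr)
  label <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
  if (any(!grepl("\\|", tok)))
    stop("protein header lacks 'genomeID|geneID' tag: ",
         tok[!grepl("\\|", tok)][1L])
  genome_id <- sub("\\|.*$", "", tok)
  gene_id <- sub("^[^|]*\\|", "", tok)
  aa <- toupper(as.character(x))
  key <- paste(genome_id, gene_id, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate protein identifier: ", key[duplicated(key)][1L])
  if (any(grepl("\\*", sub("\\*$", "", aa))))
    stop("internal stop character in protein: ",
         key[grepl("\\*", sub("\\*$", "", aa))][1L])
  aa <- sub("\\*$", "", aa)
  if (any(nchar(aa) == 0L)) stop("empty protein sequence: ",
                                 key[nchar(aa) == 0L][1L])
  data.frame(genome_id = genome_id, gene_id = gene_id, aa = aa,
             label = label, stringsAsFactors = FALSE)
}

#' Write proteins to a tagged FASTA (`genomeID|geneID` headers)
#'
#' @param proteins Protein table as returned by [read_protein_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    hdr <- paste0(">", proteins$genome_id[i], "|", proteins$gene_id[i])
    if (!is.null(proteins$label) && !is.na(proteins$label[i]))
      hdr <- paste(hdr, proteins$label[i])
    writeLines(c(hdr, proteins$aa[i]), con)
  }
  invisible(path)
}

#' Read a genome metadata table
#'
#' Tab-separated with a header row; must contain a `genome_id` column and may
#' carry `year`, `tissue`, `cultivar` and `clade` columns.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`, one row per genome.
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"genome_id" %in% names(md)) stop("metadata lacks a 'genome_id' column")
  if (anyDuplicated(md$genome_id))
    stop("duplicate genome_id in metadata: ",
         md$genome_id[duplicated(md$genome_id)][1L])
  if ("year" %in% names(md)) {
    ok <- is.na(md$year) | (md$year >= 1000 & md$year <= 9999)
    if (!all(ok)) stop("year is not a 4-digit integer for genome ",
                       md$genome_id[!ok][1L])
  }
  md
}

#' Write a labeled numeric matrix as TSV
#'
#' Values are serialized at fixed 4-decimal precision so that
#' `read_matrix_tsv(write_matrix_tsv(M))` is an identity at that precision.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.4f", m[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' @param path Path to a TSV written by [write_matrix_tsv()] (header row of
#'   column labels, first column row labels).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_exp <- length(parts[[1L]])
  cn <- parts[[1L]][-1L]
  n <- length(lines) - 1L
  m <- matrix(NA_real_, n, length(cn))
  rn <- character(n)
  for (i in seq_len(n)) {
    p <- parts[[i + 1L]]
    if (length(p) != ncol_exp)
      stop(sprintf("ragged row at line %d: expected %d fields, got %d",
                   i + 1L, ncol_exp, length(p)))
    rn[i] <- p[1L]
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell at line %d, column '%s' (value '%s')",
                   i + 1L, cn[which(is.na(v))[1L]], p[-1L][which(is.na(v))[1L]]))
    m[i, ] <- v
  }
  dimnames(m) <- list(rn, cn)
  m
}
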