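# GenBank flat-file CDS extraction. Coordinates are 1-based inclusive
# throughout (GenBank convention). Only the feature subset needed to recover
# protein complements is parsed: CDS locations (join/complement supported)
# plus /translation, /locus_tag, /protein_id and /product qualifiers.

#' Translate a CDS nucleotide sequence with genetic code table 11
#'
#' The annotated first codon is treated as an initiator, so alternative starts
#' (GTG/TTG) are rendered as `M`. A trailing stop is removed; fuzzy codons
#' containing `N` translate to `X`.
#'
#' @param cds CDS nucleotide string (already on the coding strand).
#' @return Amino-acid string. Internal stops, if present in the conceptual
#'   translation, are kept as `*` so callers can flag them.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  cds <- toupper(substr(cds, 1L, 3L * (nchar(cds) %/% 3L)))
  tab <- genetic_code_11()
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- tab$code[codons]
  aa[is.na(aa)] <- "X"  # fuzzy codons (N etc.)
  if (codons[1L] %in% tab$alt_init) aa[1L] <- "M"
  sub("\\*$", "", paste(aa, collapse = ""))
}

# table-11 codon lookup, built once from the Biostrings genetic-code table
genetic_code_11 <- function() {
  if (is.null(.gb_env$gc11)) {
    gc <- Biostrings::getGeneticCode("11")
    .gb_env$gc11 <- list(code = gc,
                         alt_init = attr(gc, "alt_init_codons"))
  }
  .gb_env$gc11
}
.gb_env <- new.env(parent = emptyenv())

#' Reverse complement of a DNA string
#'
#' @param s DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Parse a GenBank location string into a list:
#   list(strand = "+"|"-", spans = matrix[n, 2])
# Supports "a..b", "join(...)", "complement(...)", "complement(join(...))".
# Partial-end markers (< >) are tolerated and stripped.
parse_gb_location <- function(loc) {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  spans <- t(vapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      v <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else {
      v <- rep(as.integer(p), 2L)  # single-base location
    }
    if (anyNA(v) || v[2L] < v[1L]) stop("cannot parse location: ", p)
    v
  }, integer(2L)))
  dimnames(spans) <- NULL
  list(strand = strand, spans = spans)
}

#' Extract protein-coding records from a GenBank flat file
#'
#' One record per CDS feature. When a `/translation` qualifier is present it
#' is used verbatim; otherwise the CDS is translated with table 11 (trailing
#' stop removed). CDS whose conceptual translation contains an internal stop
#' are kept but flagged (`flagged = TRUE`) with a warning, so that downstream
#' clustering can exclude them.
#'
#' @param path Path to a GenBank flat file (may hold multiple LOCUS entries).
#' @return A `data.frame` with columns `genome_id`, `gene_id`, `aa`, `start`,
#'   `end`, `strand`, `label`, `flagged`.
#' @export
read_genbank_cds <- function(path) {
  lines <- readLines(path)
  ends <- grep("^//", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (e in seq_along(ends)) {
    rec <- lines[starts[e]:ends[e]]
    out[[e]] <- parse_gb_record(rec)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res) || nrow(res) == 0L) stop("no CDS features in ", path)
  rownames(res) <- NULL
  res
}

parse_gb_record <- function(rec) {
  locus_line <- grep("^LOCUS", rec, value = TRUE)
  if (length(locus_line) == 0L) return(NULL)
  genome_id <- strsplit(trimws(sub("^LOCUS", "", locus_line[1L])),
                        "\\s+")[[1L]][1L]
  ori <- grep("^ORIGIN", rec)
  if (length(ori) == 0L) stop("no ORIGIN section for ", genome_id)
  seq_lines <- rec[(ori[1L] + 1L):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat <- grep("^FEATURES", rec)
  if (length(feat) == 0L) return(NULL)
  body <- rec[(feat[1L] + 1L):(ori[1L] - 1L)]

  # split the feature table into features (key at column 6)
  key_idx <- grep("^ {5}\\S", body)
  if (length(key_idx) == 0L) return(NULL)
  feat_end <- c(key_idx[-1L] - 1L, length(body))
  cds <- list()
  n_cds <- 0L
  for (f in seq_along(key_idx)) {
    block <- body[key_idx[f]:feat_end[f]]
    key <- strsplit(trimws(block[1L]), "\\s+")[[1L]][1L]
    if (key != "CDS") next
    n_cds <- n_cds + 1L
    # location may continue over lines until the first qualifier
    qual_start <- grep("^ {21}/", block)
    loc_end <- if (length(qual_start)) qual_start[1L] - 1L else length(block)
    loc <- paste(trimws(sub("^ {5}CDS", "", block[1L])),
                 paste(trimws(block[seq_len(loc_end)[-1L]]), collapse = ""),
                 sep = "")
    loc <- gsub("\\s", "", loc)
    pl <- parse_gb_location(loc)
    if (any(pl$spans > nchar(genome)) || any(pl$spans < 1L))
      stop(sprintf("CDS coordinates outside sequence in %s: %s",
                   genome_id, loc))
    quals <- parse_gb_qualifiers(block[seq_len(length(block))[-seq_len(loc_end)]])
    gene_id <- quals[["locus_tag"]] %||% quals[["protein_id"]] %||%
      sprintf("CDS_%04d", n_cds)
    parts <- substring(genome, pl$spans[, 1L], pl$spans[, 2L])
    nt <- paste(parts, collapse = "")
    if (pl$strand == "-") nt <- revcomp(nt)
    if (!is.null(quals[["translation"]])) {
      aa <- quals[["translation"]]
    } else {
      aa <- translate_cds(nt)
    }
    flagged <- grepl("\\*", aa)
    if (flagged)
      warning(sprintf("internal stop in conceptual translation of %s|%s; record flagged",
                      genome_id, gene_id))
    cds[[n_cds]] <- data.frame(
      genome_id = genome_id, gene_id = gene_id, aa = aa,
      start = min(pl$spans), end = max(pl$spans), strand = pl$strand,
      label = quals[["product"]] %||% NA_character_,
      flagged = flagged, stringsAsFactors = FALSE)
  }
  if (length(cds) == 0L) return(NULL)
  do.call(rbind, cds)
}

parse_gb_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  txt <- trimws(lines)
  starts <- grep("^/", txt)
  quals <- list()
  for (i in seq_along(starts)) {
    end <- if (i < length(starts)) starts[i + 1L] - 1L else length(txt)
    piece <- txt[starts[i]:end]
    first <- piece[1L]
    name <- sub("^/([A-Za-z_]+).*$", "\\1", first)
    if (!grepl("=", first)) { quals[[name]] <- TRUE; next }
    val <- sub("^/[A-Za-z_]+=", "", first)
    sep <- if (name == "translation") "" else " "
    if (length(piece) > 1L) val <- paste(c(val, piece[-1L]), collapse = sep)
    quals[[name]] <- gsub("\"", "", val)
  }
  quals
}

`%||%` <- function(a, b) if (is.null(a)) b else a
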