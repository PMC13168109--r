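# Synthetic phage-community generator. Emits genomes (ordered genes +
# intergenic spacers), consistent protein complements, metadata and a truth
# record, with known clade structure and gene-family repertoires.
#
# Mutation model: i.i.d. per-site substitution to a uniformly chosen
# different base. Under this model the probability that two lineages with
# per-lineage substitution probabilities a and b differ at a site is
#     a (+) b = a + b - (4/3) a b
# (the 4/3 term accounts for coincident substitutions). The configured
# within/between_clade_sub_rate are EXPECTED PAIRWISE divergences; the
# generator inverts (+) to derive per-lineage rates, so the configured
# numbers are directly observable between emitted genome pairs.

compose_rate <- function(a, b) a + b - (4 / 3) * a * b
decompose_rate <- function(target, existing) {
  (target - existing) / (1 - (4 / 3) * existing)
}
half_rate <- function(target) (3 / 4) * (1 - sqrt(1 - (4 / 3) * target))

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

#' Configuration for a synthetic phage community
#'
#' Defaults emulate a two-clade community of ~45 kb genomes: 9 recent and 6
#' older isolates, 63 core gene families, 4 signature clusters for the older
#' clade and 3 for the newer (realized as 3 shared divergent loci plus one
#' short clade-exclusive family), sporadic short accessory families, 0.5%
#' expected within-clade and 4% between-clade pairwise nucleotide divergence.
#'
#' @param n_clades Number of clades.
#' @param genomes_per_clade Integer vector of clade sizes.
#' @param n_core_families Gene families present in every genome.
#' @param n_signature_families Per-clade counts of clade-signature protein
#'   clusters. The minimum across clades is realized as shared divergent loci
#'   (one allele per clade, amino-acid identity pushed below the clustering
#'   threshold); any excess as short clade-exclusive families.
#' @param n_accessory_families Size of the accessory family pool.
#' @param accessory_rate Probability a genome carries an accessory family.
#' @param gene_length_aa `(min, max)` uniform range for core protein lengths.
#' @param small_gene_length_aa `(min, max)` range for signature, exclusive
#'   and accessory protein lengths (short, homing-endonuclease-like).
#' @param intergenic_bp `(min, max)` uniform range for spacer lengths.
#' @param within_clade_sub_rate Expected pairwise nucleotide divergence
#'   between genomes of the same clade.
#' @param between_clade_sub_rate Expected pairwise divergence between
#'   genomes of different clades (must be >= the within rate).
#' @param divergence_codon_frac Fraction of interior codons substituted (at
#'   codon position 2, hence always amino-acid-changing) between the clade
#'   alleles of a divergent signature locus.
#' @param paralog_rate Per-genome probability that a core gene is duplicated.
#' @param indel_rate Per-site indel probability in intergenic spacers
#'   (geometric lengths, mean 3 bp); default 0 keeps divergence arithmetic
#'   exact.
#' @param discordant_marker If `TRUE`, the first core family simulates a
#'   horizontal transfer: half of the last clade's genomes carry the first
#'   clade's allele, making its marker tree discordant with the core tree.
#' @param max_genome_bp Upper bound on the worst-case genome length; an
#'   impossible configuration errors before any output is produced.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return Validated list of class `community_config`.
#' @export
community_config <- function(n_clades = 2L,
                             genomes_per_clade = c(9L, 6L),
                             n_core_families = 63L,
                             n_signature_families = c(3L, 4L),
                             n_accessory_families = 3L,
                             accessory_rate = 0.12,
                             gene_length_aa = c(150L, 280L),
                             small_gene_length_aa = c(90L, 160L),
                             intergenic_bp = c(10L, 60L),
                             within_clade_sub_rate = 0.005,
                             between_clade_sub_rate = 0.04,
                             divergence_codon_frac = 0.45,
                             paralog_rate = 0,
                             indel_rate = 0,
                             discordant_marker = FALSE,
                             max_genome_bp = 2e5,
                             seed = 1L) {
  cfg <- list(n_clades = as.integer(n_clades),
              genomes_per_clade = as.integer(genomes_per_clade),
              n_core_families = as.integer(n_core_families),
              n_signature_families = as.integer(n_signature_families),
              n_accessory_families = as.integer(n_accessory_families),
              accessory_rate = accessory_rate,
              gene_length_aa = as.integer(gene_length_aa),
              small_gene_length_aa = as.integer(small_gene_length_aa),
              intergenic_bp = as.integer(intergenic_bp),
              within_clade_sub_rate = within_clade_sub_rate,
              between_clade_sub_rate = between_clade_sub_rate,
              divergence_codon_frac = divergence_codon_frac,
              paralog_rate = paralog_rate,
              indel_rate = indel_rate,
              discordant_marker = isTRUE(discordant_marker),
              max_genome_bp = max_genome_bp,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_clades >= 1L,
              length(genomes_per_clade) == n_clades,
              all(genomes_per_clade >= 1L),
              n_core_families >= 1L,
              length(n_signature_families) == n_clades,
              all(n_signature_families >= 0L),
              n_accessory_families >= 0L,
              accessory_rate >= 0, accessory_rate < 1,
              within_clade_sub_rate >= 0, within_clade_sub_rate < 1,
              between_clade_sub_rate >= within_clade_sub_rate,
              between_clade_sub_rate < 1,
              divergence_codon_frac >= 0, divergence_codon_frac < 1,
              paralog_rate >= 0, paralog_rate < 1,
              indel_rate >= 0, indel_rate < 1,
              gene_length_aa[1L] >= 30L,
              gene_length_aa[1L] <= gene_length_aa[2L],
              small_gene_length_aa[1L] >= 10L,
              small_gene_length_aa[1L] <= small_gene_length_aa[2L],
              intergenic_bp[1L] >= 0L,
              intergenic_bp[1L] <= intergenic_bp[2L])
  })
  n_genes_max <- cfg$n_core_families + max(cfg$n_signature_families) +
    cfg$n_accessory_families
  worst <- n_genes_max * (3L * max(cfg$gene_length_aa) + 3L +
                            cfg$intergenic_bp[2L]) * 2L
  if (worst > cfg$max_genome_bp)
    stop("impossible configuration: worst-case genome length ", worst,
         " bp exceeds max_genome_bp = ", cfg$max_genome_bp)
  structure(cfg, class = "community_config")
}

# --- mutation primitives (operate on single-character vectors) ----------

substitute_chars <- function(ch, rate) {
  hits <- which(stats::runif(length(ch)) < rate)
  if (length(hits) == 0L) return(ch)
  idx <- match(ch[hits], BASES)
  ok <- !is.na(idx)
  hits <- hits[ok]; idx <- idx[ok]
  if (length(hits) == 0L) return(ch)
  altm <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                c("A", "C", "T"), c("A", "C", "G"))
  ch[hits] <- altm[cbind(idx, sample.int(3L, length(hits), replace = TRUE))]
  ch
}

#' Substitute bases of a DNA string at an i.i.d. per-site rate
#'
#' Every substituted site changes to a uniformly chosen different base, so
#' the expected fraction of differing positions equals `rate`. Length is
#' preserved. Uses the current RNG state; set a seed for reproducibility.
#'
#' @param s DNA string.
#' @param rate Per-site substitution probability in `[0, 1)`.
#' @return Mutated DNA string.
#' @export
mutate_sequence <- function(s, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(s)
  paste(substitute_chars(strsplit(s, "", fixed = TRUE)[[1L]], rate),
        collapse = "")
}

# gene-aware substitution: first and last codon protected, substitutions
# never create an in-frame stop codon (so emitted proteins stay stop-free
# and every selected site still changes, keeping divergence = rate exact
# over the mutable interior)
mutate_gene_chars <- function(ch, rate) {
  n <- length(ch)
  if (n < 9L || rate == 0) return(ch)
  interior <- 4:(n - 3L)
  hits <- interior[stats::runif(length(interior)) < rate]
  for (i in hits) {
    ci <- (i - 1L) %/% 3L          # 0-based codon index
    cpos <- i - 3L * ci            # position within codon (1..3)
    codon <- ch[(3L * ci + 1L):(3L * ci + 3L)]
    alts <- setdiff(BASES, ch[i])
    ok <- vapply(alts, function(b) {
      cd <- codon; cd[cpos] <- b
      !(paste(cd, collapse = "") %in% STOPS)
    }, logical(1L))
    alts <- alts[ok]
    if (length(alts) == 0L) next   # cannot happen for sense codons
    ch[i] <- alts[sample.int(length(alts), 1L)]
  }
  ch
}

# clade-allele diversification of a signature locus: substitute position 2
# of a fixed number of interior codons (always amino-acid-changing),
# avoiding stops
diversify_allele_chars <- function(ch, codon_frac) {
  n_codon <- length(ch) %/% 3L
  cand <- 2:(n_codon - 1L)         # all codons except start and stop
  m <- round(codon_frac * length(cand))
  if (m == 0L) return(ch)
  pick <- sort(sample(cand, m))
  for (ci in pick) {
    i <- 3L * (ci - 1L) + 2L       # codon position 2
    codon <- ch[(3L * ci - 2L):(3L * ci)]
    alts <- setdiff(BASES, ch[i])
    ok <- vapply(alts, function(b) {
      cd <- codon; cd[2L] <- b
      !(paste(cd, collapse = "") %in% STOPS)
    }, logical(1L))
    alts <- alts[ok]
    ch[i] <- alts[sample.int(length(alts), 1L)]
  }
  ch
}

random_gene_chars <- function(len_aa) {
  sense <- apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = "")
  sense <- setdiff(sense, STOPS)
  codons <- c("ATG", sample(sense, len_aa - 1L, replace = TRUE),
              sample(STOPS, 1L))
  strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1L]]
}

spacer_indels <- function(ch, rate) {
  if (rate == 0) return(ch)
  events <- which(stats::runif(length(ch)) < rate)
  for (i in rev(events)) {
    len <- stats::rgeom(1L, 1 / 3) + 1L
    if (stats::runif(1L) < 0.5) {        # insertion after i
      ins <- sample(BASES, len, replace = TRUE)
      ch <- append(ch, ins, after = i)
    } else {                             # deletion from i
      drop <- i:min(length(ch), i + len - 1L)
      ch <- ch[-drop]
    }
  }
  ch
}

# --- community generation ------------------------------------------------

#' Generate a synthetic phage community with known truth
#'
#' See [community_config()] for the model. The emitted protein sequences are
#' exactly the table-11 translations of their CDS in the emitted genomes.
#'
#' @param config A `community_config` (default configuration if omitted).
#' @return List of class `phage_community`: `genomes` (named character
#'   vector), `proteins` (data.frame `genome_id`, `gene_id`, `aa`, `label`),
#'   `metadata` (data.frame), `truth` (list: clade assignment, family table,
#'   per-genome gene coordinates, expected signature sets, expected pairwise
#'   divergence), `config`.
#' @export
generate_community <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  k <- config$n_clades
  q_w <- half_rate(config$within_clade_sub_rate)
  q_b <- half_rate(config$between_clade_sub_rate)
  r_c <- decompose_rate(q_b, q_w)  # clade-ancestor branch rate

  n_allelic <- min(config$n_signature_families)
  n_excl <- config$n_signature_families - n_allelic

  fam <- list()
  add_fam <- function(id, type, clade, len_aa) {
    fam[[length(fam) + 1L]] <<- list(family = id, type = type, clade = clade,
                                     len_aa = len_aa)
  }
  runif_int <- function(lo, hi)
    as.integer(lo + floor(stats::runif(1L) * (hi - lo + 1L)))
  for (i in seq_len(config$n_core_families))
    add_fam(sprintf("core_%03d", i), "core", NA,
            runif_int(config$gene_length_aa[1L], config$gene_length_aa[2L]))
  for (i in seq_len(n_allelic))
    add_fam(sprintf("sig_%02d", i), "signature_allelic", NA,
            runif_int(config$small_gene_length_aa[1L],
                      config$small_gene_length_aa[2L]))
  for (cl in seq_len(k)) {
    for (i in seq_len(n_excl[cl]))
      add_fam(sprintf("excl_c%d_%02d", cl, i), "signature_exclusive", cl,
              runif_int(config$small_gene_length_aa[1L],
                        config$small_gene_length_aa[2L]))
  }
  for (i in seq_len(config$n_accessory_families))
    add_fam(sprintf("acc_%02d", i), "accessory", NA,
            runif_int(config$small_gene_length_aa[1L],
                      config$small_gene_length_aa[2L]))

  # ancestral (root) sequences per family, plus per-family spacers
  root_gene <- lapply(fam, function(f) random_gene_chars(f$len_aa))
  root_spacer <- lapply(fam, function(f) {
    sample(BASES, runif_int(config$intergenic_bp[1L],
                            config$intergenic_bp[2L]), replace = TRUE)
  })
  names(root_gene) <- names(root_spacer) <- vapply(fam, `[[`, "", "family")
  ftype <- setNames(vapply(fam, `[[`, "", "type"), names(root_gene))
  fclade <- setNames(vapply(fam, function(f)
    if (is.na(f$clade[1L])) NA_integer_ else as.integer(f$clade),
    integer(1L)), names(root_gene))

  # clade ancestors
  clade_gene <- clade_spacer <- vector("list", k)
  for (cl in seq_len(k)) {
    clade_gene[[cl]] <- lapply(names(root_gene), function(fid) {
      if (ftype[[fid]] == "signature_allelic") {
        if (cl == 1L) root_gene[[fid]]
        else diversify_allele_chars(root_gene[[fid]],
                                    config$divergence_codon_frac)
      } else {
        mutate_gene_chars(root_gene[[fid]], r_c)
      }
    })
    names(clade_gene[[cl]]) <- names(root_gene)
    clade_spacer[[cl]] <- lapply(root_spacer, substitute_chars, rate = r_c)
  }

  genome_ids <- unlist(lapply(seq_len(k), function(cl)
    sprintf("c%d_g%02d", cl, seq_len(config$genomes_per_clade[cl]))))
  clade_of <- setNames(rep(seq_len(k), config$genomes_per_clade), genome_ids)

  # accessory presence (Bernoulli per genome per family)
  acc_ids <- names(root_gene)[ftype == "accessory"]
  acc_present <- matrix(stats::runif(length(acc_ids) * length(genome_ids)) <
                          config$accessory_rate,
                        length(acc_ids), length(genome_ids),
                        dimnames = list(acc_ids, genome_ids))

  # which genomes carry the transferred (clade-1) allele of core_001
  disc_genomes <- character(0)
  if (config$discordant_marker && k >= 2L) {
    last <- genome_ids[clade_of == k]
    disc_genomes <- last[seq_len(ceiling(length(last) / 2))]
  }

  genomes <- character(length(genome_ids))
  names(genomes) <- genome_ids
  prot <- list(); genes <- list()
  for (g in genome_ids) {
    cl <- clade_of[[g]]
    fams_here <- names(root_gene)[
      ftype %in% c("core", "signature_allelic") |
        (ftype == "signature_exclusive" & fclade == cl) |
        (names(root_gene) %in% acc_ids &
           acc_present[match(names(root_gene), acc_ids), g] %in% TRUE)]
    pieces <- character(0)
    pos <- 0L
    gi <- 0L
    for (fid in fams_here) {
      src_cl <- if (fid == "core_001" && g %in% disc_genomes) 1L else cl
      sp <- substitute_chars(clade_spacer[[src_cl]][[fid]], q_w)
      sp <- spacer_indels(sp, config$indel_rate)
      gene <- mutate_gene_chars(clade_gene[[src_cl]][[fid]], q_w)
      copies <- 1L
      if (ftype[[fid]] == "core" && config$paralog_rate > 0 &&
          stats::runif(1L) < config$paralog_rate) copies <- 2L
      pieces <- c(pieces, paste(sp, collapse = ""))
      pos <- pos + length(sp)
      for (cp in seq_len(copies)) {
        gi <- gi + 1L
        gid <- sprintf("g%03d", gi)
        gene_str <- paste(gene, collapse = "")
        pieces <- c(pieces, gene_str)
        genes[[length(genes) + 1L]] <- data.frame(
          genome_id = g, gene_id = gid, family = fid,
          start = pos + 1L, end = pos + length(gene), strand = "+",
          stringsAsFactors = FALSE)
        prot[[length(prot) + 1L]] <- data.frame(
          genome_id = g, gene_id = gid,
          aa = translate_cds(gene_str), label = NA_character_,
          stringsAsFactors = FALSE)
        pos <- pos + length(gene)
      }
    }
    genomes[[g]] <- paste(pieces, collapse = "")
  }
  proteins <- do.call(rbind, prot)
  genes <- do.call(rbind, genes)

  # metadata: clade 1 = recent isolates, later clades = older
  year_pool <- list(c(2021L, 2022L), c(1987L, 2012L, 2013L),
                    c(1998L, 1999L), c(2005L, 2006L))
  metadata <- data.frame(
    genome_id = genome_ids,
    year = vapply(genome_ids, function(g) {
      pool <- year_pool[[min(clade_of[[g]], length(year_pool))]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1L)),
    tissue = sample(c("Leaf", "Stem"), length(genome_ids), replace = TRUE),
    cultivar = sample(c("OHenry", "Norman", "Winblo", "Contender", "Parade"),
                      length(genome_ids), replace = TRUE),
    clade = paste0("clade_", clade_of),
    stringsAsFactors = FALSE)

  truth <- list(
    clades = setNames(paste0("clade_", clade_of), genome_ids),
    families = data.frame(
      family = names(root_gene), type = unname(ftype),
      clade = unname(fclade), len_aa = vapply(fam, `[[`, 0L, "len_aa"),
      stringsAsFactors = FALSE),
    genes = genes,
    accessory_present = acc_present,
    signature_families = lapply(seq_len(k), function(cl) {
      c(names(root_gene)[ftype == "signature_allelic"],
        names(root_gene)[ftype == "signature_exclusive" & fclade == cl])
    }),
    discordant_genomes = disc_genomes,
    expected_divergence = expected_divergence_matrix(
      genome_ids, clade_of, fam, ftype, acc_present, acc_ids, config),
    rates = list(q_within = q_w, q_between = q_b, r_clade = r_c),
    seed = config$seed)
  names(truth$signature_families) <- paste0("clade_", seq_len(k))

  structure(list(genomes = structure(genomes,
                                     class = c("genome_set", "character")),
                 proteins = proteins, metadata = metadata, truth = truth,
                 config = config),
            class = "phage_community")
}

# expected pairwise divergence over the mutable interiors of shared genes
expected_divergence_matrix <- function(genome_ids, clade_of, fam, ftype,
                                       acc_present, acc_ids, config) {
  q_w <- half_rate(config$within_clade_sub_rate)
  q_b <- half_rate(config$between_clade_sub_rate)
  n <- length(genome_ids)
  m <- matrix(0, n, n, dimnames = list(genome_ids, genome_ids))
  fids <- vapply(fam, `[[`, "", "family")
  len_int <- vapply(fam, function(f) 3L * f$len_aa - 3L, integer(1L))
  names(len_int) <- fids
  d_within <- compose_rate(q_w, q_w)
  d_between <- config$between_clade_sub_rate
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      gi <- genome_ids[i]; gj <- genome_ids[j]
      same <- clade_of[[gi]] == clade_of[[gj]]
      tot <- 0; exp_mm <- 0
      for (f in seq_along(fids)) {
        fid <- fids[f]
        shared <- switch(ftype[[fid]],
          core = TRUE,
          signature_allelic = TRUE,
          signature_exclusive = same && fam[[f]]$clade == clade_of[[gi]],
          accessory = acc_present[fid, gi] && acc_present[fid, gj])
        if (!isTRUE(shared)) next
        d <- if (same) d_within
             else if (ftype[[fid]] == "signature_allelic") {
               ncand <- fam[[f]]$len_aa - 1L
               d0 <- round(config$divergence_codon_frac * ncand) / len_int[fid]
               compose_rate(d0, d_within)
             } else d_between
        tot <- tot + len_int[fid]
        exp_mm <- exp_mm + len_int[fid] * d
      }
      m[i, j] <- m[j, i] <- exp_mm / tot
    }
  }
  m
}

#' Write a synthetic community to disk
#'
#' Emits `genomes.fasta`, `proteins.faa` (tagged `genomeID|geneID` headers),
#' `metadata.tsv` and `truth.json` under `dir`.
#'
#' @param community A `phage_community` from [generate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "phage_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(community$genomes, file.path(dir, "genomes.fasta"))
  write_protein_fasta(community$proteins, file.path(dir, "proteins.faa"))
  utils::write.table(community$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- community$truth
  tr$accessory_present <- apply(tr$accessory_present, 1L, function(r)
    colnames(tr$accessory_present)[r], simplify = FALSE)
  tr$expected_divergence <- as.data.frame(tr$expected_divergence)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @export
print.phage_community <- function(x, ...) {
  cat(sprintf(
    "phage_community: %d genomes in %d clade(s), %d-%d bp, %d proteins\n",
    length(x$genomes), x$config$n_clades, min(nchar(x$genomes)),
    max(nchar(x$genomes)), nrow(x$proteins)))
  invisible(x)
}
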