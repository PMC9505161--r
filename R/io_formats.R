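# Readers/writers for every external representation the pipeline touches:
# FASTA references, GFF3 gene models, the bespoke matched DNA/RNA pileup TSV,
# Newick species trees and the flat site table.

PILEUP_COLS <- c(
  "chrom", "pos", "ref",
  paste0("dna_", BASES),
  paste0("rna_fwd_clean_", BASES),
  paste0("rna_rev_clean_", BASES),
  paste0("rna_fwd_all_", BASES),
  paste0("rna_rev_all_", BASES)
)

SITE_COLS <- c(
  "chrom", "pos", "strand", "type", "efficiency", "dna_depth", "rna_depth",
  "p_value", "rescued", "region", "gene_id", "site_label", "codon_pos",
  "ref_codon", "edit_codon", "aa_ref", "aa_edit", "synonymous", "hydropathy",
  "context",
  # evidence/extension columns kept after the documented core order
  "ref_sense", "edit_sense", "edited_reads", "gta_supported", "ambiguous",
  "antisense_candidate", "start_gain"
)

#' Read a plastome reference from FASTA
#'
#' Parses one or more nucleotide records. Sequences are restricted to
#' A/C/G/T; `N` is tolerated but flagged so downstream consumers can avoid
#' ambiguous positions.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param circular Logical, mark records as circular plastomes (positions are
#'   linearised on the deposited sequence).
#' @return A list of `genome_record` objects with fields `id`, `sequence`,
#'   `circular`, `length` and `has_n`.
#' @export
read_genome <- function(path, circular = TRUE) {
  # BString keeps invalid letters so the alphabet check below can name them
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  lapply(seq_along(ss), function(i) {
    seq <- as.character(ss[[i]])
    bad <- setdiff(unique(strsplit(seq, "")[[1]]), c(BASES, "N"))
    if (length(bad) > 0L) {
      stop("non-nucleotide character '", bad[[1]], "' in record ", names(ss)[i])
    }
    genome_record(id = sub("\\s.*$", "", names(ss)[i]), sequence = seq,
                  circular = circular)
  })
}

#' Construct a genome record
#'
#' @param id Sequence identifier.
#' @param sequence Character string over A/C/G/T (N allowed, flagged).
#' @param circular Logical.
#' @return A `genome_record` list.
#' @export
genome_record <- function(id, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  structure(
    list(id = id, sequence = sequence, circular = circular,
         length = nchar(sequence), has_n = grepl("N", sequence, fixed = TRUE)),
    class = "genome_record"
  )
}

#' Write genome records to FASTA
#' @param genomes A `genome_record` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(ss) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a gene model
#'
#' Exons are 1-based closed genomic intervals, stored in ascending coordinate
#' order regardless of strand; transcription order is derived downstream. A
#' CDS whose spliced length (after discounting `codon_start - 1` leading
#' bases) is not divisible by 3 is flagged partial.
#'
#' @param gene_id Gene identifier.
#' @param biotype One of `"CDS"`, `"tRNA"`, `"rRNA"`.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of 1-based closed intervals.
#' @param codon_start 1, 2 or 3; first base of the first complete codon.
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene_id, biotype, strand, exons, codon_start = 1L) {
  stopifnot(biotype %in% c("CDS", "tRNA", "rRNA"), strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1] <= exons[-nrow(exons), 2])) {
    stop("overlapping exons in gene ", gene_id)
  }
  spliced_len <- sum(exons[, 2] - exons[, 1] + 1L)
  partial <- biotype == "CDS" &&
    ((spliced_len - (codon_start - 1L)) %% 3L != 0L)
  structure(
    list(gene_id = gene_id, biotype = biotype, strand = strand,
         exons = exons, codon_start = as.integer(codon_start),
         spliced_length = spliced_len, partial = partial,
         span = c(min(exons[, 1]), max(exons[, 2]))),
    class = "gene_model"
  )
}

#' Read gene models from GFF3
#'
#' Features of type CDS, tRNA or rRNA are grouped into genes by their `ID`
#' (or `Parent`, or `gene_id`) attribute; multi-row groups become multi-exon
#' models. The phase of the transcription-first segment sets `codon_start`.
#' Features of other biotypes are skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of [gene_model()] objects.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("CDS", "tRNA", "rRNA")
  skip_types <- setdiff(unique(type), c("CDS", "tRNA", "rRNA", "gene", "exon",
                                        "region"))
  if (length(skip_types) > 0L) {
    warning("skipping features of unknown biotype: ",
            paste(skip_types, collapse = ", "))
  }
  gr <- gr[keep]
  type <- type[keep]
  md <- as.data.frame(gr)
  ids <- md$ID
  if (is.null(ids)) ids <- rep(NA_character_, nrow(md))
  if (!is.null(md$Parent)) {
    parent <- vapply(md$Parent, function(p)
      if (length(p) > 0) as.character(p[[1]]) else NA_character_, "")
    ids <- ifelse(is.na(ids) | ids == "", parent, ids)
  }
  if (!is.null(md$gene_id)) {
    ids <- ifelse(is.na(ids) | ids == "", md$gene_id, ids)
  }
  if (anyNA(ids)) stop("GFF3 feature without ID/Parent/gene_id attribute")
  ids <- sub("\\.exon\\d+$", "", ids)  # ID=rpl20.exon1 style
  out <- lapply(split(seq_len(nrow(md)), ids), function(i) {
    strand <- as.character(md$strand[i[1]])
    if (!strand %in% c("+", "-")) stop("unstranded feature for gene ", ids[i[1]])
    ex <- cbind(md$start[i], md$end[i])
    phase <- suppressWarnings(as.integer(as.character(md$phase[i])))
    phase[is.na(phase)] <- 0L
    # codon_start comes from the transcription-first exon's phase
    first <- if (strand == "+") which.min(ex[, 1]) else which.max(ex[, 2])
    gene_model(gene_id = ids[i[1]], biotype = type[i[1]], strand = strand,
               exons = ex, codon_start = phase[first] + 1L)
  })
  out[order(vapply(out, function(g) g$span[1], 1))]
}

#' Write gene models to GFF3
#' @param genes List of [gene_model()] objects.
#' @param chrom Reference sequence name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, chrom, path) {
  rows <- lapply(genes, function(g) {
    n <- nrow(g$exons)
    # phase of each CDS segment in transcription order
    phase <- rep(".", n)
    if (g$biotype == "CDS") {
      ord <- if (g$strand == "+") seq_len(n) else rev(seq_len(n))
      lens <- g$exons[ord, 2] - g$exons[ord, 1] + 1L
      ph <- integer(n)
      ph[1] <- g$codon_start - 1L
      if (n > 1L) for (k in 2:n) {
        ph[k] <- (3L - (sum(lens[1:(k - 1)]) - ph[1]) %% 3L) %% 3L
      }
      phase[ord] <- ph
    }
    data.frame(seqid = chrom, source = "plastedit", type = g$biotype,
               start = g$exons[, 1], end = g$exons[, 2], score = ".",
               strand = g$strand, phase = phase,
               attributes = paste0("ID=", g$gene_id, ";gene_id=", g$gene_id),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a matched DNA/RNA base-count pileup
#'
#' The pileup TSV starts with a `#indel_window=<w>` header line, then a
#' column-name row, then one row per genomic position: reference base, DNA
#' base counts, and strand-specific RNA base counts in two pools — `clean`
#' (reads without a nearby indel) and `all` (including reads with an indel
#' within `w` bp, projected gap-aware upstream). `fwd`/`rev` refer to
#' transcript orientation relative to the reference plus strand.
#'
#' @param path Path to a pileup TSV.
#' @return A data frame with columns [`PILEUP_COLS`] and attribute
#'   `indel_window`.
#' @export
read_pileup <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#indel_window=\\d+", first)) {
    stop("pileup file must start with '#indel_window=<w>': ", path)
  }
  w <- as.integer(sub("^#indel_window=(\\d+).*", "\\1", first))
  df <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PILEUP_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("pileup missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[PILEUP_COLS]
  validate_pileup(df)
  attr(df, "indel_window") <- w
  df
}

validate_pileup <- function(df) {
  counts <- df[, setdiff(PILEUP_COLS, c("chrom", "pos", "ref"))]
  if (any(counts < 0)) stop("negative counts in pileup")
  for (orient in c("fwd", "rev")) {
    cl <- as.matrix(df[paste0("rna_", orient, "_clean_", BASES)])
    al <- as.matrix(df[paste0("rna_", orient, "_all_", BASES)])
    bad <- which(cl > al, arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("clean count exceeds all count at row ", bad[1, 1],
           " (", orient, " ", BASES[bad[1, 2]], ")")
    }
  }
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0L)) {
      stop("positions not strictly increasing on ", ch, " at line ",
           which(df$chrom == ch)[which(diff(p) <= 0L)[1] + 1L])
    }
  }
  invisible(df)
}

#' Write a pileup TSV
#' @param df Pileup data frame (columns [`PILEUP_COLS`]).
#' @param path Output path.
#' @param indel_window Indel window `w` in bp recorded in the header
#'   (defaults to the data frame's `indel_window` attribute, else 5).
#' @return `path`, invisibly.
#' @export
write_pileup <- function(df, path, indel_window = NULL) {
  if (is.null(indel_window)) {
    indel_window <- attr(df, "indel_window")
    if (is.null(indel_window)) indel_window <- 5L
  }
  validate_pileup(df[PILEUP_COLS])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#indel_window=", indel_window), con)
  write.table(df[PILEUP_COLS], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a rooted species tree from Newick
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object, checked to be rooted with
#'   unique tip labels; zero-length branches are permitted and flagged via
#'   the `zero_length_branches` attribute.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  }
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted (trifurcating root); root it on an outgroup ",
         "before use")
  }
  if (!is.null(tree$edge.length)) {
    nz <- sum(tree$edge.length == 0)
    if (nz > 0L) {
      warning(nz, " zero-length branch(es) in tree")
      attr(tree, "zero_length_branches") <- nz
    }
  }
  tree
}

empty_site_table <- function(n = 0L) {
  df <- data.frame(
    chrom = character(n), pos = integer(n), strand = character(n),
    type = character(n), efficiency = numeric(n), dna_depth = integer(n),
    rna_depth = integer(n), p_value = numeric(n), rescued = logical(n),
    region = character(n), gene_id = character(n), site_label = character(n),
    codon_pos = integer(n), ref_codon = character(n),
    edit_codon = character(n), aa_ref = character(n), aa_edit = character(n),
    synonymous = logical(n), hydropathy = character(n), context = character(n),
    ref_sense = character(n), edit_sense = character(n),
    edited_reads = integer(n), gta_supported = logical(n),
    ambiguous = logical(n), antisense_candidate = logical(n),
    start_gain = logical(n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) df else df
}

#' Write a site table to TSV
#'
#' Columns are written in the documented fixed order (chrom, pos, strand,
#' type, efficiency, dna_depth, rna_depth, p_value, rescued, region, gene_id,
#' site_label, codon_pos, ref_codon, edit_codon, aa_ref, aa_edit, synonymous,
#' hydropathy, context) followed by evidence columns; the table round-trips
#' losslessly through [read_site_table()].
#'
#' @param sites Site data frame as produced by [call_editing_sites()] /
#'   [annotate_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  for (col in setdiff(SITE_COLS, names(sites))) sites[[col]] <- NA
  write.table(sites[SITE_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#' @param path Path to a site-table TSV.
#' @return Site data frame.
#' @export
read_site_table <- function(path) {
  # read everything as character first: bare bases like "T" must not be
  # type-converted to logicals
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("rescued", "synonymous", "gta_supported", "ambiguous",
                "antisense_candidate", "start_gain")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  for (col in c("efficiency", "p_value")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("pos", "codon_pos", "dna_depth", "rna_depth",
                "edited_reads")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  df
}
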