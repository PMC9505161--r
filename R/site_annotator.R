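# Genomic-context and coding-consequence annotation of called editing
# sites: region, gene-relative site label, codon position, amino-acid
# change under the plastid genetic code (NCBI table 11), hydropathy
# transition, and sense-strand flanking context.

#' Hydropathy partition of the amino acids
#'
#' The default places P and G with the hydrophobic residues, so that
#' Ser-to-Leu edits read hydrophilic-to-hydrophobic and Pro-to-Leu edits
#' maintain hydrophobicity — the behaviour expected of chloroplast C-to-U
#' editing. The stop codon is its own category.
#'
#' @param hydrophobic Character vector of one-letter hydrophobic residues.
#' @return A `hydropathy_scheme` list with `hydrophobic` and `hydrophilic`
#'   members.
#' @export
hydropathy_scheme <- function(hydrophobic = c("A", "C", "F", "G", "I", "L",
                                              "M", "P", "V", "W")) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  stopifnot(all(hydrophobic %in% aa20))
  structure(list(hydrophobic = hydrophobic,
                 hydrophilic = setdiff(aa20, hydrophobic)),
            class = "hydropathy_scheme")
}

plastid_code <- function() {
  gc <- Biostrings::getGeneticCode("11")
  gc  # named by DNA codons, stop = "*"
}

#' Classify a hydropathy transition
#'
#' @param aa_ref,aa_edit One-letter amino acids or `"*"` for stop.
#' @param scheme A [hydropathy_scheme()].
#' @return One of `"phil->phob"`, `"phob->phil"`, `"maintained"`,
#'   `"stop-gain"`, `"stop-loss"`.
#' @export
hydropathy_change <- function(aa_ref, aa_edit,
                              scheme = hydropathy_scheme()) {
  classify_one <- function(r, e) {
    if (is.na(r) || is.na(e)) return(NA_character_)
    if (e == "*" && r != "*") return("stop-gain")
    if (r == "*" && e != "*") return("stop-loss")
    if (r == "*" && e == "*") return("maintained")
    known <- c(scheme$hydrophobic, scheme$hydrophilic)
    if (!r %in% known || !e %in% known) {
      stop("unknown amino acid symbol: ", if (!r %in% known) r else e)
    }
    cr <- r %in% scheme$hydrophobic
    ce <- e %in% scheme$hydrophobic
    if (cr == ce) "maintained" else if (ce) "phil->phob" else "phob->phil"
  }
  mapply(classify_one, aa_ref, aa_edit, USE.NAMES = FALSE)
}

# spliced sense-strand sequence of a gene
spliced_gene_seq <- function(gene, genome) {
  pieces <- vapply(seq_len(nrow(gene$exons)), function(e)
    substr(genome$sequence, gene$exons[e, 1], gene$exons[e, 2]), "")
  plus <- paste(pieces, collapse = "")
  if (gene$strand == "+") plus else revcomp(plus)
}

#' Locate a site relative to the gene models
#'
#' Region precedence when features overlap: CDS > tRNA > rRNA > intron >
#' intergenic. A position inside a gene's span but outside its exons is an
#' intron. Exonic sites get the label `<gene>-<spliced position>` using the
#' 1-based position within the spliced sense-strand gene sequence.
#'
#' @param pos Genomic position (1-based).
#' @param genes List of [gene_model()] objects.
#' @return List with `region`, `gene_id`, `site_label`, `spliced_pos`,
#'   `gene` (the model or NULL).
#' @export
locate_site <- function(pos, genes) {
  prec <- c(CDS = 4L, tRNA = 3L, rRNA = 2L, intron = 1L)
  best <- list(region = "intergenic", gene_id = NA_character_,
               site_label = NA_character_, spliced_pos = NA_integer_,
               gene = NULL, level = 0L)
  for (g in genes) {
    if (pos < g$span[1] || pos > g$span[2]) next
    exonic <- any(pos >= g$exons[, 1] & pos <= g$exons[, 2])
    region <- if (exonic) g$biotype else "intron"
    lvl <- prec[[region]]
    if (lvl <= best$level) next
    sp <- NA_integer_
    label <- NA_character_
    if (exonic) {
      off <- spliced_offsets(g)
      sp <- off$offset[off$pos == pos]
      label <- paste0(g$gene_id, "-", sp)
    }
    best <- list(region = region, gene_id = g$gene_id, site_label = label,
                 spliced_pos = sp, gene = g, level = lvl)
  }
  best$level <- NULL
  best
}

#' Coding consequence of an edit
#'
#' Computes codon position, reference and edited codons, amino acids under
#' NCBI translation table 11, synonymy, and a start-gain flag (edit creates
#' an ATG).
#'
#' @param gene A CDS [gene_model()], not partial.
#' @param genome The [genome_record()].
#' @param spliced_pos 1-based position within the spliced sense sequence.
#' @param edit_sense Edited base on the sense strand (DNA alphabet).
#' @return List with `codon_pos`, `ref_codon`, `edit_codon`, `aa_ref`,
#'   `aa_edit`, `synonymous`, `start_gain`.
#' @export
codon_effect <- function(gene, genome, spliced_pos, edit_sense) {
  stopifnot(gene$biotype == "CDS")
  if (gene$partial) stop("cannot annotate codons on a partial CDS model: ",
                         gene$gene_id)
  seq <- spliced_gene_seq(gene, genome)
  if (spliced_pos > nchar(seq)) {
    stop("edit position ", spliced_pos, " beyond spliced length of ",
         gene$gene_id)
  }
  idx <- spliced_pos - (gene$codon_start - 1L)
  none <- list(codon_pos = NA_integer_, ref_codon = NA_character_,
               edit_codon = NA_character_, aa_ref = NA_character_,
               aa_edit = NA_character_, synonymous = NA, start_gain = NA)
  if (idx < 1L) return(none)  # upstream of the first complete codon
  codon_pos <- ((idx - 1L) %% 3L) + 1L
  cstart <- gene$codon_start + 3L * ((idx - 1L) %/% 3L)
  if (cstart + 2L > nchar(seq)) return(none)  # trailing incomplete codon
  ref_codon <- substr(seq, cstart, cstart + 2L)
  edit_codon <- ref_codon
  substr(edit_codon, codon_pos, codon_pos) <- edit_sense
  code <- plastid_code()
  aa_ref <- unname(code[ref_codon])
  aa_edit <- unname(code[edit_codon])
  list(codon_pos = codon_pos, ref_codon = ref_codon,
       edit_codon = edit_codon, aa_ref = aa_ref, aa_edit = aa_edit,
       synonymous = aa_ref == aa_edit,
       start_gain = edit_codon == "ATG" && ref_codon != "ATG")
}

#' Sense-strand context around a site
#'
#' Returns the 2k+1 window centred on the site, reverse-complemented for
#' minus-strand sites, with circular wrap-around on circular genomes. On
#' linear genomes a window exceeding the sequence bounds is truncated and
#' flagged via the `truncated` attribute.
#'
#' @param pos Genomic position.
#' @param strand Transcribed strand, `"+"` or `"-"`.
#' @param genome A [genome_record()].
#' @param k Flank size in bp (>= 1).
#' @return Character string of length up to 2k+1.
#' @export
site_context <- function(pos, strand, genome, k = 5L) {
  stopifnot(k >= 1L)
  L <- genome$length
  want <- (pos - k):(pos + k)
  truncated <- FALSE
  if (genome$circular) {
    want <- ((want - 1L) %% L) + 1L
  } else {
    ok <- want >= 1L & want <= L
    truncated <- !all(ok)
    want <- want[ok]
  }
  chars <- strsplit(genome$sequence, "")[[1]][want]
  out <- paste(chars, collapse = "")
  if (strand == "-") out <- revcomp(out)
  attr(out, "truncated") <- truncated
  out
}

#' Position frequency matrix of site contexts
#'
#' Aggregates sense-strand contexts of a site list into a 4 x (2k+1) base
#' frequency matrix; column `"-1"` is the base immediately upstream of the
#' edited position on the sense strand.
#'
#' @param sites Site data frame with `pos` and `strand`.
#' @param genome A [genome_record()].
#' @param k Flank size in bp.
#' @return Numeric matrix, rows A/C/G/T, columns -k..k, columns summing
#'   to 1.
#' @export
context_pfm <- function(sites, genome, k = 5L) {
  stopifnot(genome$circular)  # fixed-width windows need wrap-around
  counts <- matrix(0, 4, 2L * k + 1L,
                   dimnames = list(BASES, as.character(-k:k)))
  for (i in seq_len(nrow(sites))) {
    ctx <- strsplit(site_context(sites$pos[i], sites$strand[i], genome,
                                 k)[[1]], "")[[1]]
    for (j in seq_along(ctx)) {
      if (ctx[j] %in% BASES) counts[ctx[j], j] <- counts[ctx[j], j] + 1
    }
  }
  sweep(counts, 2, pmax(colSums(counts), 1), "/")
}

#' Annotate called sites with genomic context and coding consequences
#'
#' Fills `region`, `gene_id`, `site_label`, codon fields, synonymy,
#' hydropathy transition and flanking context for every site. Consequences
#' are computed in the frame of the overlapping gene; for sites flagged as
#' antisense candidates the edited base is complemented into the gene sense
#' first.
#'
#' @param sites Site data frame from [call_editing_sites()].
#' @param genes List of [gene_model()] objects.
#' @param genome A [genome_record()].
#' @param scheme A [hydropathy_scheme()].
#' @param context_k Flank size of the stored context string.
#' @return Annotated site data frame.
#' @export
annotate_sites <- function(sites, genes, genome,
                           scheme = hydropathy_scheme(), context_k = 5L) {
  if (nrow(sites) == 0L) return(sites)
  for (i in seq_len(nrow(sites))) {
    loc <- locate_site(sites$pos[i], genes)
    sites$region[i] <- loc$region
    sites$gene_id[i] <- loc$gene_id
    sites$site_label[i] <- loc$site_label
    if (loc$region == "CDS" && !loc$gene$partial) {
      edit_gene_sense <- if (loc$gene$strand == sites$strand[i]) {
        sites$edit_sense[i]
      } else {
        unname(COMPLEMENT[sites$edit_sense[i]])
      }
      ce <- codon_effect(loc$gene, genome, loc$spliced_pos, edit_gene_sense)
      sites$codon_pos[i] <- ce$codon_pos
      sites$ref_codon[i] <- ce$ref_codon
      sites$edit_codon[i] <- ce$edit_codon
      sites$aa_ref[i] <- ce$aa_ref
      sites$aa_edit[i] <- ce$aa_edit
      sites$synonymous[i] <- ce$synonymous
      sites$start_gain[i] <- ce$start_gain
      if (!is.na(ce$aa_ref)) {
        sites$hydropathy[i] <- hydropathy_change(ce$aa_ref, ce$aa_edit,
                                                 scheme)
      }
    }
    sites$context[i] <- as.character(site_context(sites$pos[i],
                                                  sites$strand[i], genome,
                                                  context_k))
  }
  sites
}
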