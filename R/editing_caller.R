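# RNA editing site caller on matched DNA / strand-specific RNA base counts.
#
# A site is called per transcript orientation when the DNA evidence excludes
# genomic polymorphism (depth, reference-major consensus) and the RNA
# evidence supports an edited base (depth, supporting reads, binomial test
# against the sequencing-error rate, minimum efficiency, strand purity).
# Sites masked because indel-bearing reads were excluded from the clean
# count pool are rescued by re-applying the same rules on the all-reads
# pool.

#' Caller thresholds
#'
#' @param min_dna_depth Minimum DNA read depth.
#' @param min_rna_depth Minimum RNA read depth on the calling orientation.
#' @param min_edited_reads Minimum reads carrying the edited base.
#' @param dna_major_allele_min_fraction Minimum fraction of DNA reads on the
#'   major allele; the major allele must equal the reference base (rejects
#'   heterozygous/polymorphic positions).
#' @param error_rate Per-base sequencing error rate used in the binomial
#'   test.
#' @param alpha One-sided binomial p-value threshold: P(X >= k | n,
#'   error_rate) must not exceed `alpha`.
#' @param min_efficiency Minimum editing efficiency (edited / total RNA
#'   reads on the calling orientation).
#' @param strand_purity Minimum fraction of the edited-base reads that lie
#'   on the calling orientation; below it the site is flagged ambiguous and
#'   suppressed.
#' @param indel_rescue Logical; re-evaluate indel-masked positions on the
#'   all-counts pool.
#' @param gta_window Distance (bp, inclusive) within which a same-strand
#'   C-to-U site supports a G-to-A call.
#' @return A `caller_params` list.
#' @export
caller_params <- function(min_dna_depth = 10L,
                          min_rna_depth = 10L,
                          min_edited_reads = 3L,
                          dna_major_allele_min_fraction = 0.95,
                          error_rate = 0.001,
                          alpha = 1e-3,
                          min_efficiency = 0.05,
                          strand_purity = 0.90,
                          indel_rescue = TRUE,
                          gta_window = 150L) {
  p <- as.list(environment())
  stopifnot(p$min_dna_depth > 0, p$min_rna_depth > 0, p$min_edited_reads > 0,
            p$dna_major_allele_min_fraction >= 0,
            p$dna_major_allele_min_fraction <= 1,
            p$error_rate >= 0, p$error_rate <= 1,
            p$alpha > 0, p$min_efficiency >= 0, p$min_efficiency <= 1,
            p$strand_purity >= 0, p$strand_purity <= 1, p$gta_window >= 0)
  structure(p, class = "caller_params")
}

# Vectorised evaluation of the calling rules for one orientation and count
# pool. Returns per-row criteria so that callers and the rescue path share
# one rule set.
evaluate_rules <- function(pileup, params, orient = c("fwd", "rev"),
                           pool = c("clean", "all")) {
  orient <- match.arg(orient)
  pool <- match.arg(pool)
  other <- if (orient == "fwd") "rev" else "fwd"
  n_row <- nrow(pileup)
  i <- seq_len(n_row)
  dna <- as.matrix(pileup[paste0("dna_", BASES)])
  rna <- as.matrix(pileup[paste0("rna_", orient, "_", pool, "_", BASES)])
  rna_other <- as.matrix(pileup[paste0("rna_", other, "_", pool, "_", BASES)])
  ref_i <- match(pileup$ref, BASES)

  dna_depth <- rowSums(dna)
  major_i <- max.col(dna, ties.method = "first")
  major_frac <- ifelse(dna_depth > 0, dna[cbind(i, major_i)] / dna_depth, 0)
  dna_depth_ok <- dna_depth >= params$min_dna_depth
  major_is_ref <- major_i == ref_i
  dna_ok <- dna_depth_ok & major_is_ref &
    major_frac >= params$dna_major_allele_min_fraction
  assembly_suspect <- dna_depth_ok & !major_is_ref &
    major_frac >= params$dna_major_allele_min_fraction

  rna_n <- rowSums(rna)
  masked <- rna
  masked[cbind(i, ref_i)] <- -1L
  k <- apply(masked, 1, max)
  k[k < 0] <- 0L
  edit_i <- max.col(masked, ties.method = "first")
  k_other <- rna_other[cbind(i, edit_i)]
  purity <- ifelse(k + k_other > 0, k / (k + k_other), 0)
  p_value <- pbinom(k - 1, rna_n, params$error_rate, lower.tail = FALSE)
  efficiency <- ifelse(rna_n > 0, k / rna_n, 0)

  rna_depth_ok <- rna_n >= params$min_rna_depth
  k_ok <- k >= params$min_edited_reads
  p_ok <- p_value <= params$alpha
  eff_ok <- efficiency >= params$min_efficiency
  purity_ok <- purity >= params$strand_purity

  data.frame(
    row = i, chrom = pileup$chrom, pos = pileup$pos,
    strand = if (orient == "fwd") "+" else "-",
    ref_plus = pileup$ref, edit_plus = BASES[edit_i],
    dna_depth = dna_depth, rna_depth = rna_n, edited_reads = k,
    efficiency = efficiency, p_value = p_value, purity = purity,
    dna_ok = dna_ok, assembly_suspect = assembly_suspect,
    rna_depth_ok = rna_depth_ok, k_ok = k_ok, p_ok = p_ok,
    eff_ok = eff_ok, purity_ok = purity_ok,
    call = dna_ok & rna_depth_ok & k_ok & p_ok & eff_ok & purity_ok,
    ambiguous = dna_ok & rna_depth_ok & k_ok & p_ok & eff_ok & !purity_ok,
    stringsAsFactors = FALSE
  )
}

candidate_to_site <- function(cand, rescued = FALSE) {
  n <- nrow(cand)
  sites <- empty_site_table(n)
  sites$chrom <- cand$chrom
  sites$pos <- cand$pos
  sites$strand <- cand$strand
  sites$efficiency <- cand$efficiency
  sites$dna_depth <- as.integer(cand$dna_depth)
  sites$rna_depth <- as.integer(cand$rna_depth)
  sites$edited_reads <- as.integer(cand$edited_reads)
  sites$p_value <- cand$p_value
  sites$rescued <- rep(rescued, n)
  ref_sense <- ifelse(cand$strand == "+", cand$ref_plus,
                      unname(COMPLEMENT[cand$ref_plus]))
  edit_sense <- ifelse(cand$strand == "+", cand$edit_plus,
                       unname(COMPLEMENT[cand$edit_plus]))
  sites$ref_sense <- as.character(ref_sense)
  sites$edit_sense <- as.character(edit_sense)
  sites$type <- if (n > 0) edit_type_label(ref_sense, edit_sense) else
    character(0)
  sites$ambiguous <- rep(FALSE, n)
  sites$gta_supported <- rep(NA, n)
  sites$antisense_candidate <- rep(FALSE, n)
  for (col in c("region", "gene_id", "site_label", "ref_codon", "edit_codon",
                "aa_ref", "aa_edit", "hydropathy", "context")) {
    sites[[col]] <- rep(NA_character_, n)
  }
  sites$codon_pos <- rep(NA_integer_, n)
  sites$synonymous <- rep(NA, n)
  sites$start_gain <- rep(NA, n)
  sites
}

#' Call editing sites from clean count pools
#'
#' Applies the full rule set (see [caller_params()]) independently on each
#' transcript orientation of every position. Positions whose DNA consensus
#' differs from the reference base are skipped with an assembly-error
#' warning; sites failing only strand purity are suppressed as ambiguous.
#'
#' @param pileup Pileup data frame (see [read_pileup()]).
#' @param params A [caller_params()].
#' @return Site data frame, ordered by position then strand.
#' @export
call_sites <- function(pileup, params = caller_params()) {
  cands <- rbind(evaluate_rules(pileup, params, "fwd", "clean"),
                 evaluate_rules(pileup, params, "rev", "clean"))
  n_bad <- length(unique(cands$pos[cands$assembly_suspect &
                                     cands$rna_depth_ok & cands$k_ok]))
  if (n_bad > 0L) {
    warning(n_bad, " position(s) with DNA consensus differing from the ",
            "reference skipped (possible assembly error)")
  }
  sites <- candidate_to_site(cands[cands$call, , drop = FALSE])
  sites <- sites[order(sites$pos, sites$strand), ]
  rownames(sites) <- NULL
  sites
}

#' Rescue sites masked by indel-bearing reads
#'
#' Positions that pass every DNA-level criterion but fail the RNA depth or
#' edited-read criterion on the clean pool (the signature of reads excluded
#' for a nearby indel) are re-evaluated on the all-counts pool; positions
#' passing the full rule set there are emitted with `rescued = TRUE`. The
#' rescue never overrides a DNA-level rejection and never duplicates a site
#' already called on clean counts.
#'
#' @param pileup Pileup data frame.
#' @param preliminary_sites Output of [call_sites()] on the same pileup.
#' @param params A [caller_params()].
#' @return Site data frame of rescued sites only.
#' @export
rescue_indel_adjacent <- function(pileup, preliminary_sites,
                                  params = caller_params()) {
  out <- empty_site_table(0L)
  for (orient in c("fwd", "rev")) {
    clean <- evaluate_rules(pileup, params, orient, "clean")
    eligible <- clean$dna_ok & !clean$call &
      (!clean$rna_depth_ok | !clean$k_ok)
    if (!any(eligible)) next
    all_eval <- evaluate_rules(pileup[eligible, , drop = FALSE], params,
                               orient, "all")
    hit <- all_eval[all_eval$call, , drop = FALSE]
    if (nrow(hit) == 0L) next
    key <- paste(hit$chrom, hit$pos, hit$strand)
    called <- paste(preliminary_sites$chrom, preliminary_sites$pos,
                    preliminary_sites$strand)
    hit <- hit[!key %in% called, , drop = FALSE]
    out <- rbind(out, candidate_to_site(hit, rescued = TRUE))
  }
  out <- out[order(out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

# gene overlapping a position, highest-precedence biotype first
find_gene <- function(pos, genes) {
  prec <- c(CDS = 3L, tRNA = 2L, rRNA = 1L)
  best <- NULL
  for (g in genes) {
    if (pos >= g$span[1] && pos <= g$span[2]) {
      if (is.null(best) || prec[[g$biotype]] > prec[[best$biotype]]) best <- g
    }
  }
  best
}

#' Classify editing type on the transcribed strand
#'
#' The edited change is expressed on the transcribed (sense) strand: a
#' genomic G-to-A change inside a minus-strand gene is a C-to-U event. The
#' read-derived strand is authoritative; if it contradicts the annotation
#' strand of an overlapping gene, the site is flagged as an
#' antisense-transcript candidate and the read-derived strand kept.
#'
#' @param sites Site data frame from [call_sites()] /
#'   [rescue_indel_adjacent()].
#' @param genes List of [gene_model()] objects.
#' @return Sites with `type`, `ref_sense`, `edit_sense` and
#'   `antisense_candidate` set.
#' @export
classify_type <- function(sites, genes) {
  if (nrow(sites) == 0L) return(sites)
  for (i in seq_len(nrow(sites))) {
    g <- find_gene(sites$pos[i], genes)
    sites$antisense_candidate[i] <- !is.null(g) && g$strand != sites$strand[i]
  }
  sites$type <- edit_type_label(sites$ref_sense, sites$edit_sense)
  sites
}

#' Flag G-to-A sites supported by nearby C-to-U sites
#'
#' A G-to-A site is corroborated when at least one called C-to-U site lies
#' within `gta_window` bp (inclusive) on the same transcribed strand.
#'
#' @param sites Classified site data frame.
#' @param params A [caller_params()].
#' @return Sites with `gta_supported` set (`NA` for non-G-to-A sites).
#' @export
flag_gta_support <- function(sites, params = caller_params()) {
  if (nrow(sites) == 0L) return(sites)
  sites$gta_supported <- NA
  gta <- which(sites$type == "G-to-A")
  ctu <- which(sites$type == "C-to-U")
  for (i in gta) {
    near <- ctu[sites$chrom[ctu] == sites$chrom[i] &
                  sites$strand[ctu] == sites$strand[i] &
                  abs(sites$pos[ctu] - sites$pos[i]) <= params$gta_window]
    sites$gta_supported[i] <- length(near) > 0L
  }
  sites
}

#' Full calling pipeline
#'
#' [call_sites()] on clean counts, optional [rescue_indel_adjacent()],
#' [classify_type()] against the gene models and [flag_gta_support()].
#'
#' @param pileup Pileup data frame.
#' @param genes List of [gene_model()] objects (may be empty).
#' @param params A [caller_params()].
#' @return Site data frame.
#' @export
call_editing_sites <- function(pileup, genes = list(),
                               params = caller_params()) {
  sites <- call_sites(pileup, params)
  if (isTRUE(params$indel_rescue)) {
    sites <- rbind(sites, rescue_indel_adjacent(pileup, sites, params))
  }
  sites <- classify_type(sites, genes)
  sites <- flag_gta_support(sites, params)
  sites <- sites[order(sites$pos, sites$strand), ]
  rownames(sites) <- NULL
  sites
}
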