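# Synthetic plastome, gene-model, planted-site and pileup generator.
#
# The generator reproduces the statistical structure of gymnosperm chloroplast
# editing data: high-efficiency C-to-U sites vs low-efficiency G-to-A sites,
# a pyrimidine bias at the -1 position of C-to-U sites and an A bias for
# G-to-A, a codon-position skew of coding C-to-U sites toward positions 1-2,
# DNA-polymorphism decoys that a naive caller would miscall as editing, and
# indel-adjacent sites whose clean read counts are suppressed so that only
# the rescue path can recover them. Counts are simulated directly (the
# pipeline consumes base counts, not reads).

#' Simulation configuration
#'
#' Defaults describe a realistic mid-size gymnosperm plastome experiment:
#' a 120 kb genome at 37% GC carrying 40 protein-coding, 10 tRNA and 4 rRNA
#' genes; 150 C-to-U and 6 G-to-A editing sites (79% / 32% of them coding);
#' Beta(8,2) / Beta(2,8) editing efficiencies; 50x DNA and RNA depths with a
#' 0.1% per-base error rate; 40 DNA-polymorphism decoys; and 8 indel-adjacent
#' sites whose clean RNA counts keep only 10% of reads.
#'
#' @param genome_length Plastome length in bp.
#' @param gc_content Fraction of G+C in the simulated background sequence.
#' @param n_genes Named integer vector: genes per biotype (CDS, tRNA, rRNA).
#' @param intron_fraction Fraction of CDS genes given a single intron.
#' @param n_ctu_sites,n_gta_sites Planted C-to-U and G-to-A site counts.
#' @param ctu_eff_shape,gta_eff_shape Beta shape pairs for per-site editing
#'   efficiency.
#' @param ctu_cds_fraction,gta_cds_fraction Fraction of each type planted in
#'   coding sequence.
#' @param ctu_codon_weights Codon-position weights (1,2,3) for coding C-to-U
#'   sites.
#' @param ctu_pyrimidine_bias Probability that the -1 (sense) base of a
#'   C-to-U site is a pyrimidine.
#' @param gta_a_bias Probability that the -1 (sense) base of a G-to-A site
#'   is an A.
#' @param dna_depth,rna_depth Mean Poisson sequencing depths.
#' @param error_rate Per-base miscall probability (spread over the 3
#'   alternative bases).
#' @param intergenic_expression Relative RNA depth over intergenic positions.
#' @param antisense_leakage Relative RNA depth on the non-template strand of
#'   genes.
#' @param polymorphism_decoy_count Number of heterozygous DNA decoys.
#' @param decoy_allele_fraction DNA alternative-allele fraction at decoys.
#' @param indel_adjacent_count Number of planted C-to-U sites flagged
#'   indel-adjacent.
#' @param clean_suppression Fraction of RNA reads diverted from the clean to
#'   the all-counts pool at indel-adjacent sites.
#' @param indel_window Indel window `w` (bp) recorded in the pileup header.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 120000L,
                       gc_content = 0.37,
                       n_genes = c(CDS = 40L, tRNA = 10L, rRNA = 4L),
                       intron_fraction = 0.2,
                       n_ctu_sites = 150L,
                       n_gta_sites = 6L,
                       ctu_eff_shape = c(8, 2),
                       gta_eff_shape = c(2, 8),
                       ctu_cds_fraction = 0.79,
                       gta_cds_fraction = 0.32,
                       ctu_codon_weights = c(0.45, 0.45, 0.10),
                       ctu_pyrimidine_bias = 0.65,
                       gta_a_bias = 0.55,
                       dna_depth = 50,
                       rna_depth = 50,
                       error_rate = 0.001,
                       intergenic_expression = 0.3,
                       antisense_leakage = 0.02,
                       polymorphism_decoy_count = 40L,
                       decoy_allele_fraction = 0.5,
                       indel_adjacent_count = 8L,
                       clean_suppression = 0.9,
                       indel_window = 5L,
                       seed = 17L) {
  cfg <- as.list(environment())
  probs <- c(cfg$gc_content, cfg$ctu_cds_fraction, cfg$gta_cds_fraction,
             cfg$ctu_pyrimidine_bias, cfg$gta_a_bias, cfg$error_rate,
             cfg$intergenic_expression, cfg$antisense_leakage,
             cfg$decoy_allele_fraction, cfg$clean_suppression,
             cfg$intron_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(cfg$ctu_codon_weights) - 1) < 1e-8,
            all(c("CDS", "tRNA", "rRNA") %in% names(cfg$n_genes)))
  structure(cfg, class = "sim_config")
}

# codon pools for CDS sequence construction
.STOP_CODONS <- c("TAA", "TAG", "TGA")

random_nonstop_codons <- function(n) {
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste0,
                      collapse = "")
  pool <- setdiff(all_codons, .STOP_CODONS)
  sample(pool, n, replace = TRUE)
}

#' Simulate a plastome-like reference with gene models
#'
#' Places non-overlapping genes on both strands with intergenic gaps. CDS
#' genes carry a valid start codon, no internal stops, a terminal stop, and a
#' spliced length divisible by 3; a configurable fraction receives one
#' intron.
#'
#' @param config A [sim_config()].
#' @return `list(genome = genome_record, genes = list of gene_model)`.
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- sample(BASES, L, replace = TRUE, prob = base_probs)

  specs <- list()
  for (bt in c("CDS", "tRNA", "rRNA")) {
    n <- config$n_genes[[bt]]
    if (n == 0L) next
    len <- switch(bt,
      CDS = 3L * sample(100:400, n, replace = TRUE),
      tRNA = sample(70:90, n, replace = TRUE),
      rRNA = sample(1500:2900, n, replace = TRUE))
    intron <- rep(0L, n)
    if (bt == "CDS") {
      has_intron <- runif(n) < config$intron_fraction
      intron[has_intron] <- sample(80:300, sum(has_intron), replace = TRUE)
    }
    specs <- c(specs, lapply(seq_len(n), function(i) {
      list(id = paste0(tolower(bt), sprintf("%02d", i)), biotype = bt,
           spliced = len[i], intron = intron[i])
    }))
  }
  specs <- specs[sample(length(specs))]
  footprints <- vapply(specs, function(s) s$spliced + s$intron, 1L)
  min_gap <- 20L
  slack <- L - sum(footprints) - min_gap * (length(specs) + 1L)
  if (slack < 0L) {
    stop("gene footprint ", sum(footprints), " bp does not fit in ",
         L, " bp; increase genome_length")
  }
  # random intergenic gaps: min_gap plus a random split of the slack
  cuts <- sort(sample.int(slack + 1L, length(specs) + 1L, replace = TRUE)) - 1L
  extra <- diff(c(0L, cuts))
  extra <- c(extra, slack - sum(extra))[seq_len(length(specs) + 1L)]
  gaps <- min_gap + extra

  genes <- vector("list", length(specs))
  cursor <- 1L + gaps[1]
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    strand <- sample(c("+", "-"), 1L)
    if (s$biotype == "CDS") {
      n_cod <- s$spliced %/% 3L
      sense <- paste0("ATG",
                      paste(random_nonstop_codons(n_cod - 2L), collapse = ""),
                      sample(.STOP_CODONS, 1L))
    } else {
      sense <- paste(sample(BASES, s$spliced, replace = TRUE,
                            prob = base_probs), collapse = "")
    }
    if (s$intron > 0L) {
      split_at <- 3L * sample.int(s$spliced %/% 3L - 1L, 1L)
      ex1_len <- split_at
      exons <- rbind(c(cursor, cursor + ex1_len - 1L),
                     c(cursor + ex1_len + s$intron,
                       cursor + s$spliced + s$intron - 1L))
    } else {
      exons <- rbind(c(cursor, cursor + s$spliced - 1L))
    }
    genomic <- if (strand == "+") sense else revcomp(sense)
    # write the spliced sequence into its exons (transcription order)
    offs <- 0L
    ord <- seq_len(nrow(exons))
    for (e in ord) {
      elen <- exons[e, 2] - exons[e, 1] + 1L
      piece <- substr(genomic, offs + 1L, offs + elen)
      seq[exons[e, 1]:exons[e, 2]] <- strsplit(piece, "")[[1]]
      offs <- offs + elen
    }
    genes[[i]] <- gene_model(s$id, s$biotype, strand, exons, codon_start = 1L)
    cursor <- cursor + s$spliced + s$intron + gaps[i + 1L]
  }
  genome <- genome_record("plastome_sim", paste(seq, collapse = ""),
                          circular = TRUE)
  list(genome = genome, genes = genes)
}

# per-position annotation used by the planter: region, gene, strand,
# codon position (sense), spliced offset
position_index <- function(genome, genes) {
  L <- genome$length
  region <- rep("intergenic", L)
  gene_id <- rep(NA_character_, L)
  strand <- rep(NA_character_, L)
  codon_pos <- rep(NA_integer_, L)
  prec <- c(CDS = 3L, tRNA = 2L, rRNA = 1L)
  level <- rep(0L, L)
  for (g in genes) {
    span <- g$span[1]:g$span[2]
    in_exon <- rep(FALSE, length(span))
    for (e in seq_len(nrow(g$exons))) {
      in_exon[span >= g$exons[e, 1] & span <= g$exons[e, 2]] <- TRUE
    }
    lvl <- prec[[g$biotype]]
    upd_exon <- span[in_exon][level[span[in_exon]] < lvl]
    region[upd_exon] <- g$biotype
    gene_id[upd_exon] <- g$gene_id
    strand[upd_exon] <- g$strand
    level[upd_exon] <- lvl
    upd_intr <- span[!in_exon][level[span[!in_exon]] < 1L]
    region[upd_intr] <- "intron"
    gene_id[upd_intr] <- g$gene_id
    strand[upd_intr] <- g$strand
    if (g$biotype == "CDS" && !g$partial) {
      sp <- spliced_offsets(g)
      cp <- ((sp$offset - g$codon_start) %% 3L) + 1L
      sel <- sp$pos %in% upd_exon
      codon_pos[sp$pos[sel]] <- cp[sel]
    }
  }
  data.frame(pos = seq_len(L), region = region, gene_id = gene_id,
             strand = strand, codon_pos = codon_pos,
             stringsAsFactors = FALSE)
}

# genomic position -> 1-based spliced (sense) offset for every exonic base
spliced_offsets <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$exons)), function(e)
    gene$exons[e, 1]:gene$exons[e, 2]))
  plus_off <- seq_along(pos)
  off <- if (gene$strand == "+") plus_off else rev(plus_off)
  data.frame(pos = pos, offset = off)
}

#' Plant editing sites and decoys on a simulated reference
#'
#' C-to-U sites are planted on sense-strand C positions (genomic G on
#' minus-strand genes), G-to-A sites on sense-strand G. Editing efficiencies
#' are drawn from the configured Beta distributions; the -1 sense context
#' follows the configured pyrimidine (C-to-U) or A (G-to-A) bias; coding
#' C-to-U sites follow the codon-position weights. DNA-polymorphism decoys
#' are planted at untouched positions and are never editing sites.
#'
#' @param genome,genes Output of [simulate_reference()].
#' @param config The [sim_config()].
#' @return A `SimTruth` data frame: chrom, pos, strand, type, efficiency,
#'   is_indel_adjacent, is_decoy, ref_plus, edit_plus.
#' @export
plant_sites <- function(genome, genes, config) {
  set.seed(config$seed + 1L)
  idx <- position_index(genome, genes)
  base <- strsplit(genome$sequence, "")[[1]]
  L <- genome$length
  # intergenic positions transcribe on a random but fixed strand
  idx$strand[is.na(idx$strand)] <- sample(c("+", "-"),
                                          sum(is.na(idx$strand)),
                                          replace = TRUE)
  sense_base <- ifelse(idx$strand == "+", base, COMPLEMENT[base])
  prev_pos <- ifelse(idx$strand == "+",
                     ifelse(idx$pos == 1L, L, idx$pos - 1L),
                     ifelse(idx$pos == L, 1L, idx$pos + 1L))
  minus1 <- ifelse(idx$strand == "+", base[prev_pos],
                   COMPLEMENT[base[prev_pos]])

  used <- rep(FALSE, L)
  pick_sites <- function(type, n_total) {
    if (n_total == 0L) return(integer(0))
    want_base <- if (type == "C-to-U") "C" else "G"
    cds_frac <- if (type == "C-to-U") config$ctu_cds_fraction else
      config$gta_cds_fraction
    bias_set <- if (type == "C-to-U") c("C", "T") else "A"
    bias_p <- if (type == "C-to-U") config$ctu_pyrimidine_bias else
      config$gta_a_bias
    elig <- which(sense_base == want_base & !used)
    n_cds <- round(n_total * cds_frac)
    chosen <- integer(0)
    for (grp in c("cds", "noncds")) {
      n_grp <- if (grp == "cds") n_cds else n_total - n_cds
      if (n_grp == 0L) next
      pool <- if (grp == "cds") {
        elig[idx$region[elig] == "CDS" & !is.na(idx$codon_pos[elig])]
      } else {
        elig[idx$region[elig] != "CDS"]
      }
      pool <- setdiff(pool, chosen)
      if (grp == "cds" && type == "C-to-U") {
        target_cp <- sample(1:3, n_grp, replace = TRUE,
                            prob = config$ctu_codon_weights)
      } else target_cp <- rep(NA_integer_, n_grp)
      want_bias <- runif(n_grp) < bias_p
      for (i in seq_len(n_grp)) {
        sub <- pool
        if (!is.na(target_cp[i])) sub <- sub[idx$codon_pos[sub] == target_cp[i]]
        sub2 <- if (want_bias[i]) sub[minus1[sub] %in% bias_set] else
          sub[!minus1[sub] %in% bias_set]
        if (length(sub2) > 0L) sub <- sub2
        if (length(sub) == 0L) {
          stop("insufficient eligible positions for ", type, ": needed ",
               n_grp - i + 1L, " more")
        }
        p <- if (length(sub) == 1L) sub else sample(sub, 1L)
        chosen <- c(chosen, p)
        pool <- setdiff(pool, p)
      }
    }
    used[chosen] <<- TRUE
    chosen
  }

  ctu <- pick_sites("C-to-U", config$n_ctu_sites)
  gta <- pick_sites("G-to-A", config$n_gta_sites)

  mk <- function(pos, type, shape) {
    if (length(pos) == 0L) return(NULL)
    strand <- idx$strand[pos]
    ref_plus <- base[pos]
    from <- if (type == "C-to-U") "C" else "G"
    to <- if (type == "C-to-U") "T" else "A"
    edit_sense <- to
    edit_plus <- ifelse(strand == "+", edit_sense, COMPLEMENT[edit_sense])
    data.frame(chrom = genome$id, pos = pos, strand = strand, type = type,
               efficiency = rbeta(length(pos), shape[1], shape[2]),
               is_indel_adjacent = FALSE, is_decoy = FALSE,
               ref_plus = ref_plus, edit_plus = unname(edit_plus),
               stringsAsFactors = FALSE)
  }
  truth <- rbind(mk(ctu, "C-to-U", config$ctu_eff_shape),
                 mk(gta, "G-to-A", config$gta_eff_shape))

  if (!is.null(truth) && config$indel_adjacent_count > 0L &&
      nrow(truth) > 0L) {
    n_ia <- min(config$indel_adjacent_count, sum(truth$type == "C-to-U"))
    ia <- sample(which(truth$type == "C-to-U"), n_ia)
    truth$is_indel_adjacent[ia] <- TRUE
  }

  if (config$polymorphism_decoy_count > 0L) {
    pool <- which(!used)
    dec <- sample(pool, config$polymorphism_decoy_count)
    alt <- vapply(base[dec], function(b) sample(setdiff(BASES, b), 1L), "")
    truth <- rbind(truth, data.frame(
      chrom = genome$id, pos = dec, strand = idx$strand[dec],
      type = NA_character_, efficiency = NA_real_,
      is_indel_adjacent = FALSE, is_decoy = TRUE,
      ref_plus = base[dec], edit_plus = unname(alt),
      stringsAsFactors = FALSE))
  }
  if (is.null(truth)) {
    truth <- data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), type = character(0),
                        efficiency = numeric(0), is_indel_adjacent = logical(0),
                        is_decoy = logical(0), ref_plus = character(0),
                        edit_plus = character(0), stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$pos), ]
  rownames(truth) <- NULL
  stopifnot(!anyDuplicated(truth$pos))
  truth
}

# multinomial scatter of error reads over the 3 non-reference bases
scatter_errors <- function(counts, err, ref_idx) {
  rows <- which(err > 0L)
  if (length(rows) == 0L) return(counts)
  reps <- rep(rows, err[rows])
  pick <- sample.int(3L, length(reps), replace = TRUE)
  # map 1:3 onto the non-ref base indices
  alt_idx <- (ref_idx[reps] + pick - 1L) %% 4L + 1L
  tab <- table(factor(reps, levels = rows),
               factor(alt_idx, levels = 1:4))
  counts[rows, ] <- counts[rows, , drop = FALSE] +
    matrix(as.integer(tab), nrow = length(rows))
  counts
}

#' Simulate matched DNA and strand-specific RNA pileups
#'
#' DNA counts are Poisson around the reference base with error-rate
#' misincorporations; decoy positions carry two DNA (and RNA) alleles; RNA
#' counts at planted sites mix edited and unedited bases at the true
#' efficiency on the transcribed orientation; indel-adjacent sites have
#' their clean counts thinned by the configured suppression, mimicking reads
#' excluded because an insertion/deletion lies at or near the site.
#'
#' @param genome,genes Output of [simulate_reference()].
#' @param truth Output of [plant_sites()].
#' @param config The [sim_config()].
#' @return A pileup data frame (see [read_pileup()]) with attribute
#'   `indel_window`.
#' @export
simulate_pileups <- function(genome, truth, genes, config) {
  set.seed(config$seed + 2L)
  L <- genome$length
  e <- config$error_rate
  base <- strsplit(genome$sequence, "")[[1]]
  ref_idx <- match(base, BASES)

  # DNA
  dna_n <- rpois(L, config$dna_depth)
  dna <- matrix(0L, L, 4)
  is_decoy <- rep(FALSE, L)
  if (nrow(truth) > 0L) is_decoy[truth$pos[truth$is_decoy]] <- TRUE
  alt_reads <- rep(0L, L)
  alt_idx_vec <- ref_idx
  if (any(is_decoy)) {
    dpos <- truth$pos[truth$is_decoy]
    alt_reads[dpos] <- rbinom(length(dpos), dna_n[dpos],
                              config$decoy_allele_fraction)
    alt_idx_vec[dpos] <- match(truth$edit_plus[truth$is_decoy], BASES)
  }
  ref_reads <- dna_n - alt_reads
  err <- rbinom(L, ref_reads, e)
  dna[cbind(seq_len(L), ref_idx)] <- ref_reads - err
  dna[cbind(seq_len(L), alt_idx_vec)] <- dna[cbind(seq_len(L), alt_idx_vec)] +
    alt_reads
  dna <- scatter_errors(dna, err, ref_idx)

  # expected RNA coverage per strand
  cov <- matrix(config$rna_depth * config$intergenic_expression, L, 2,
                dimnames = list(NULL, c("+", "-")))
  for (g in genes) {
    span <- g$span[1]:g$span[2]
    cov[span, g$strand] <- config$rna_depth
    cov[span, setdiff(c("+", "-"), g$strand)] <-
      config$rna_depth * config$antisense_leakage
  }

  eff <- rep(0, L)
  edit_idx <- ref_idx
  site_strand <- rep(NA_character_, L)
  if (nrow(truth) > 0L) {
    real <- truth[!truth$is_decoy, ]
    eff[real$pos] <- real$efficiency
    edit_idx[real$pos] <- match(real$edit_plus, BASES)
    site_strand[real$pos] <- real$strand
    dpos <- truth$pos[truth$is_decoy]
    # decoy RNA expresses both DNA alleles at the DNA allele fraction
    eff[dpos] <- config$decoy_allele_fraction
    edit_idx[dpos] <- match(truth$edit_plus[truth$is_decoy], BASES)
    site_strand[dpos] <- NA  # decoys edited on neither; both strands show alt
  }

  rna <- list()
  for (orient in c("+", "-")) {
    n <- rpois(L, cov[, orient])
    # edited (or decoy-alt) reads on this orientation
    on_strand <- !is.na(site_strand) & site_strand == orient
    carries_alt <- on_strand | is_decoy
    k <- integer(L)
    k[carries_alt] <- rbinom(sum(carries_alt), n[carries_alt],
                             eff[carries_alt])
    ref_n <- n - k
    err <- rbinom(L, ref_n, e)
    m <- matrix(0L, L, 4)
    m[cbind(seq_len(L), ref_idx)] <- ref_n - err
    m[cbind(seq_len(L), edit_idx)] <- m[cbind(seq_len(L), edit_idx)] + k
    m <- scatter_errors(m, err, ref_idx)
    rna[[orient]] <- m
  }

  # clean pools: thin indel-adjacent positions
  clean <- rna
  if (nrow(truth) > 0L && any(truth$is_indel_adjacent)) {
    ia <- truth$pos[truth$is_indel_adjacent]
    for (orient in c("+", "-")) {
      sub <- rna[[orient]][ia, , drop = FALSE]
      kept <- matrix(rbinom(length(sub), as.integer(sub),
                            1 - config$clean_suppression), nrow(sub))
      clean[[orient]][ia, ] <- kept
    }
  }

  df <- data.frame(chrom = genome$id, pos = seq_len(L), ref = base,
                   stringsAsFactors = FALSE)
  df[paste0("dna_", BASES)] <- dna
  df[paste0("rna_fwd_clean_", BASES)] <- clean[["+"]]
  df[paste0("rna_rev_clean_", BASES)] <- clean[["-"]]
  df[paste0("rna_fwd_all_", BASES)] <- rna[["+"]]
  df[paste0("rna_rev_all_", BASES)] <- rna[["-"]]
  attr(df, "indel_window") <- config$indel_window
  df
}

#' Simulate a complete dataset
#'
#' @param config A [sim_config()].
#' @return `list(genome, genes, truth, pileup, config)`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  truth <- plant_sites(ref$genome, ref$genes, config)
  pileup <- simulate_pileups(ref$genome, truth, ref$genes, config)
  list(genome = ref$genome, genes = ref$genes, truth = truth,
       pileup = pileup, config = config)
}

#' Simulate a presence/absence site matrix on a tree
#'
#' Each site evolves independently under the two-state gain/loss Markov
#' chain, starting from a stationary root draw.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param gain,loss Gain (0 to 1) and loss (1 to 0) rates per unit branch
#'   length; both > 0.
#' @param n_sites Number of independent sites.
#' @param seed Integer seed.
#' @return Integer matrix (tips x sites) of 0/1 states.
#' @export
simulate_site_matrix <- function(tree, gain, loss, n_sites, seed = 17L) {
  stopifnot(gain > 0, loss > 0, n_sites >= 1)
  set.seed(seed)
  r <- gain + loss
  pi1 <- gain / r
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, n_sites)
  root <- n_tip + 1L
  states[root, ] <- as.integer(runif(n_sites) < pi1)
  # preorder edge traversal: parents before children
  ord <- rev(ape::postorder(tree))
  for (ei in ord) {
    par <- tree$edge[ei, 1]; chi <- tree$edge[ei, 2]
    t <- tree$edge.length[ei]
    p_change <- ifelse(states[par, ] == 0L,
                       pi1 * (1 - exp(-r * t)),
                       (1 - pi1) * (1 - exp(-r * t)))
    flip <- runif(n_sites) < p_change
    states[chi, ] <- ifelse(flip, 1L - states[par, ], states[par, ])
  }
  m <- states[seq_len(n_tip), , drop = FALSE]
  rownames(m) <- tree$tip.label
  colnames(m) <- paste0("site", seq_len(n_sites))
  m
}
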