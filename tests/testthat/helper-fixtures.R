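# Fixture builders and independent oracles shared across tests.

# one pileup row from named base-count vectors; all-pools default to clean
pileup_rows <- function(..., chrom = "chr") {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    cnt <- function(x) {
      v <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
      if (!is.null(x)) v[names(x)] <- as.integer(x)
      v
    }
    fwd_clean <- cnt(r$fwd_clean)
    rev_clean <- cnt(r$rev_clean)
    fwd_all <- if (is.null(r$fwd_all)) fwd_clean else cnt(r$fwd_all)
    rev_all <- if (is.null(r$rev_all)) rev_clean else cnt(r$rev_all)
    out <- data.frame(chrom = chrom,
                      pos = if (is.null(r$pos)) i else r$pos,
                      ref = r$ref, stringsAsFactors = FALSE)
    out[paste0("dna_", c("A", "C", "G", "T"))] <- as.list(cnt(r$dna))
    out[paste0("rna_fwd_clean_", c("A", "C", "G", "T"))] <- as.list(fwd_clean)
    out[paste0("rna_rev_clean_", c("A", "C", "G", "T"))] <- as.list(rev_clean)
    out[paste0("rna_fwd_all_", c("A", "C", "G", "T"))] <- as.list(fwd_all)
    out[paste0("rna_rev_all_", c("A", "C", "G", "T"))] <- as.list(rev_all)
    out
  }))
  attr(df, "indel_window") <- 5L
  df
}

# Independent scalar re-implementation of the calling rule set (clean pool,
# no rescue); deliberately written as per-row loops, not shared with the
# package internals.
brute_force_calls <- function(pileup, params) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  for (i in seq_len(nrow(pileup))) {
    dna <- as.numeric(pileup[i, paste0("dna_", bases)])
    ref <- pileup$ref[i]
    dna_depth <- sum(dna)
    if (dna_depth < params$min_dna_depth) next
    major <- bases[which.max(dna)]
    if (major != ref) next
    if (max(dna) / dna_depth < params$dna_major_allele_min_fraction) next
    for (orient in c("fwd", "rev")) {
      rna <- as.numeric(pileup[i, paste0("rna_", orient, "_clean_", bases)])
      other <- as.numeric(pileup[i, paste0("rna_",
                                           if (orient == "fwd") "rev" else
                                             "fwd", "_clean_", bases)])
      n <- sum(rna)
      if (n < params$min_rna_depth) next
      alt <- setdiff(bases, ref)
      k <- -1; eb <- NA
      for (b in alt) {
        if (rna[match(b, bases)] > k) {
          k <- rna[match(b, bases)]; eb <- b
        }
      }
      if (k < params$min_edited_reads) next
      p <- sum(dbinom(k:n, n, params$error_rate))
      if (p > params$alpha) next
      if (k / n < params$min_efficiency) next
      k_other <- other[match(eb, bases)]
      if (k / (k + k_other) < params$strand_purity) next
      strand <- if (orient == "fwd") "+" else "-"
      ref_sense <- if (strand == "+") ref else comp[[ref]]
      edit_sense <- if (strand == "+") eb else comp[[eb]]
      hits[[length(hits) + 1]] <- data.frame(
        pos = pileup$pos[i], strand = strand,
        ref_sense = ref_sense, edit_sense = edit_sense,
        efficiency = k / n, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(pos = integer(0), strand = character(0),
                      ref_sense = character(0), edit_sense = character(0),
                      efficiency = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$pos, out$strand), ]
}

# exhaustive two-state likelihood: sum over all assignments of internal
# (and missing-tip) states of prior x product of edge transition probs
enum_likelihood <- function(states, tree, gain, loss,
                            prior = c(loss, gain) / (gain + loss)) {
  r <- gain + loss
  pmat <- function(t) {
    pi1 <- gain / r; pi0 <- 1 - pi1; e <- exp(-r * t)
    matrix(c(pi0 + pi1 * e, pi0 * (1 - e), pi1 * (1 - e), pi1 + pi0 * e),
           2, 2)
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  free <- c(which(is.na(states)), (n_tip + 1):n_node)
  fixed <- setdiff(seq_len(n_tip), free)
  total <- 0
  grid <- expand.grid(rep(list(0:1), length(free)))
  for (g in seq_len(nrow(grid))) {
    s <- integer(n_node)
    s[fixed] <- states[fixed]
    s[free] <- as.integer(grid[g, ])
    p <- prior[s[n_tip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      P <- pmat(tree$edge.length[e])
      p <- p * P[s[tree$edge[e, 1]] + 1, s[tree$edge[e, 2]] + 1]
    }
    total <- total + p
  }
  total
}

# exhaustive Fitch: minimum changes over all internal-state assignments
enum_min_changes <- function(states, tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  free <- c(which(is.na(states)), (n_tip + 1):n_node)
  fixed <- setdiff(seq_len(n_tip), free)
  best <- Inf
  grid <- expand.grid(rep(list(0:1), length(free)))
  for (g in seq_len(nrow(grid))) {
    s <- integer(n_node)
    s[fixed] <- states[fixed]
    s[free] <- as.integer(grid[g, ])
    ch <- sum(s[tree$edge[, 1]] != s[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# brute-force UpSet counting over the power set of lineages
enum_intersections <- function(m, lineages) {
  lin_levels <- sort(unique(unname(lineages[rownames(m)])))
  counts <- list()
  for (j in seq_len(ncol(m))) {
    present <- character(0)
    for (l in lin_levels) {
      rows <- rownames(m)[lineages[rownames(m)] == l]
      if (any(m[rows, j] == 1, na.rm = TRUE)) present <- c(present, l)
    }
    if (length(present) == 0) next
    key <- paste(sort(present), collapse = "&")
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  counts
}

# tiny genome + single-gene fixture for annotation tests
toy_gene_genome <- function(sense_cds, strand = "+", pad = 10L,
                            gene_id = "geneA") {
  left <- strrep("A", pad)
  right <- strrep("A", pad)
  genomic <- if (strand == "+") sense_cds else
    as.character(plastedit_revcomp(sense_cds))
  seq <- paste0(left, genomic, right)
  genome <- genome_record("toy", seq, circular = TRUE)
  gene <- gene_model(gene_id, "CDS", strand,
                     rbind(c(pad + 1L, pad + nchar(sense_cds))))
  list(genome = genome, gene = gene)
}

# local reverse complement so the helper stays independent of pkg internals
plastedit_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
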