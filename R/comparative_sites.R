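# Cross-species homology of editing sites: projection of per-species
# spliced gene positions onto alignment columns, UpSet-style intersection
# counts over lineages, and per-gene editing-site density.

#' Project per-species sites onto alignment columns
#'
#' Each site's 1-based position in its species' spliced gene sequence is
#' projected to the column that position occupies in the per-gene multiple
#' alignment. Homologous sites across species therefore share a column key
#' `<gene>:<column>`.
#'
#' @param alignments Named list (by gene) of named character vectors
#'   (by species) of equal-length aligned sequences (gaps `-`).
#' @param sites Data frame with columns `species`, `gene_id`,
#'   `spliced_pos`.
#' @param gene_seqs Optional named list (gene -> species -> ungapped spliced
#'   sequence); when given, each species' ungapped alignment row must equal
#'   it, otherwise an error names the species and gene.
#' @return Integer matrix: rows = species, columns = homologous sites
#'   bearing at least one presence; entries 1 (present), 0 (absent, species
#'   has the gene), `NA` (species lacks the gene). Sites in genes without an
#'   alignment are listed in the `unmapped` attribute.
#' @export
map_to_columns <- function(alignments, sites, gene_seqs = NULL) {
  species <- sort(unique(c(unlist(lapply(alignments, names)),
                           sites$species)))
  col_keys <- character(0)
  presence <- list()
  unmapped <- sites[0, , drop = FALSE]

  colmap <- list()  # gene -> species -> ungapped-position -> column
  for (gene in names(alignments)) {
    aln <- alignments[[gene]]
    lens <- unique(nchar(aln))
    if (length(lens) != 1L) stop("ragged alignment for gene ", gene)
    colmap[[gene]] <- lapply(aln, function(s) which(strsplit(s, "")[[1]] != "-"))
    if (!is.null(gene_seqs) && gene %in% names(gene_seqs)) {
      for (sp in intersect(names(aln), names(gene_seqs[[gene]]))) {
        if (gsub("-", "", aln[[sp]], fixed = TRUE) !=
            gene_seqs[[gene]][[sp]]) {
          stop("ungapped alignment row differs from the annotated gene ",
               "sequence for species ", sp, ", gene ", gene)
        }
      }
    }
  }

  hit <- data.frame(species = character(0), key = character(0))
  for (i in seq_len(nrow(sites))) {
    gene <- sites$gene_id[i]; sp <- sites$species[i]
    if (!gene %in% names(alignments) ||
        !sp %in% names(alignments[[gene]])) {
      unmapped <- rbind(unmapped, sites[i, , drop = FALSE])
      next
    }
    cm <- colmap[[gene]][[sp]]
    p <- sites$spliced_pos[i]
    if (p > length(cm)) {
      stop("site position ", p, " beyond ungapped length of ", gene,
           " in ", sp)
    }
    hit <- rbind(hit, data.frame(species = sp,
                                 key = paste0(gene, ":", cm[p])))
  }

  keys <- sort(unique(hit$key))
  m <- matrix(NA_integer_, length(species), length(keys),
              dimnames = list(species, keys))
  for (key in keys) {
    gene <- sub(":.*$", "", key)
    has_gene <- intersect(species, names(alignments[[gene]]))
    m[has_gene, key] <- 0L
  }
  if (nrow(hit) > 0L) m[cbind(hit$species, hit$key)] <- 1L
  attr(m, "unmapped") <- unmapped
  m
}

#' UpSet-style intersection counts over lineages
#'
#' A column (homologous site) belongs to a lineage when at least one member
#' species carries a 1. Lineages whose members are all missing (`NA`) for a
#' column do not enter that column's combination key. Output covers every
#' non-empty lineage combination plus pairwise shared counts.
#'
#' @param matrix Output of [map_to_columns()] (or any 0/1/NA species-site
#'   matrix).
#' @param lineages Named character vector mapping every row species to a
#'   lineage.
#' @return List with `combinations` (data frame: combo, degree, count),
#'   `lineage_specific` (named vector of singleton counts), `pairwise`
#'   (symmetric matrix of shared-column counts) and `n_columns` (columns
#'   with at least one presence).
#' @export
site_intersections <- function(matrix, lineages) {
  stopifnot(ncol(matrix) > 0L, all(rownames(matrix) %in% names(lineages)))
  lin <- lineages[rownames(matrix)]
  lin_levels <- sort(unique(unname(lin)))
  present <- sapply(lin_levels, function(l) {
    sub <- matrix[lin == l, , drop = FALSE]
    apply(sub, 2, function(col) any(col == 1L, na.rm = TRUE))
  })
  if (is.null(dim(present))) present <- matrix(present, nrow = 1)
  # present: columns(sites) x lineages
  keys <- apply(present, 1, function(row) {
    paste(lin_levels[row], collapse = "&")
  })
  nonempty <- keys != ""
  tab <- table(keys[nonempty])
  combos <- data.frame(combo = names(tab),
                       degree = lengths(strsplit(names(tab), "&",
                                                 fixed = TRUE)),
                       count = as.integer(tab), stringsAsFactors = FALSE)
  combos <- combos[order(combos$degree, combos$combo), ]
  rownames(combos) <- NULL
  specific <- setNames(integer(length(lin_levels)), lin_levels)
  single <- combos[combos$degree == 1L, ]
  specific[single$combo] <- single$count
  pairwise <- crossprod(present * 1L)
  list(combinations = combos, lineage_specific = specific,
       pairwise = pairwise, n_columns = sum(nonempty))
}

#' Editing-site density per gene
#'
#' Density is the number of sites per 1000 bp of spliced gene length.
#'
#' @param sites Annotated site data frame (uses `gene_id`).
#' @param genes List of [gene_model()] objects.
#' @return Data frame: gene_id, n_sites, spliced_length, density.
#' @export
editing_density <- function(sites, genes) {
  out <- do.call(rbind, lapply(genes, function(g) {
    if (g$spliced_length <= 0L) stop("zero-length gene ", g$gene_id)
    n <- sum(!is.na(sites$gene_id) & sites$gene_id == g$gene_id)
    data.frame(gene_id = g$gene_id, n_sites = n,
               spliced_length = g$spliced_length,
               density = 1000 * n / g$spliced_length,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise global alignment (Needleman-Wunsch)
#'
#' Minimal scoring aligner (match 1, mismatch -1, gap -2) for self-contained
#' tests of column projection; production alignments are expected as inputs
#' from a dedicated aligner.
#'
#' @param a,b Sequences to align.
#' @param match,mismatch,gap Scoring parameters.
#' @return Character vector of the two aligned sequences.
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (x[i] == y[j]) match else mismatch,
      S[i, j + 1] + gap,
      S[i + 1, j] + gap)
  }
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (x[i] == y[j]) match else mismatch)) {
      ai <- c(x[i], ai); bi <- c(y[j], bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ai <- c(x[i], ai); bi <- c("-", bi); i <- i - 1
    } else {
      ai <- c("-", ai); bi <- c(y[j], bi); j <- j - 1
    }
  }
  c(paste(ai, collapse = ""), paste(bi, collapse = ""))
}

#' Simple progressive multiple alignment
#'
#' Aligns sequences in input order by aligning each new sequence to the
#' column-majority consensus of the growing alignment and propagating the
#' induced gaps. Test-support quality only.
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams nw_align
#' @return Named character vector of aligned sequences.
#' @export
progressive_align <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  stopifnot(length(seqs) >= 1L)
  aln <- seqs[1]
  if (length(seqs) == 1L) return(aln)
  consensus <- function(rows) {
    mat <- do.call(rbind, strsplit(rows, ""))
    apply(mat, 2, function(col) {
      col <- col[col != "-"]
      if (length(col) == 0) "-" else names(sort(table(col),
                                                decreasing = TRUE))[1]
    })
  }
  for (s in seq(2, length(seqs))) {
    # the consensus has one gap-free character per alignment column, so the
    # pairwise alignment of consensus vs new sequence dictates, column by
    # column, whether to copy the next old column or insert a gap column
    cons <- paste(consensus(aln), collapse = "")
    pa <- nw_align(cons, seqs[[s]], match, mismatch, gap)
    aligned_cons <- strsplit(pa[1], "")[[1]]
    old <- do.call(rbind, strsplit(aln, ""))
    new_mat <- matrix("-", nrow(old) + 1L, length(aligned_cons))
    ci <- 0L
    for (j in seq_along(aligned_cons)) {
      if (aligned_cons[j] != "-") {
        ci <- ci + 1L
        new_mat[seq_len(nrow(old)), j] <- old[, ci]
      }
    }
    new_mat[nrow(old) + 1L, ] <- strsplit(pa[2], "")[[1]]
    aln <- setNames(apply(new_mat, 1, paste, collapse = ""),
                    c(names(aln), names(seqs)[s]))
  }
  aln
}
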