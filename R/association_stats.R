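# Cohort-level summaries of annotated editing sites (per-species counts by
# type, codon position, synonymy and region) and Pearson correlations
# between editing-site abundance and plastome features.

SUMMARY_COLS <- c("species", "type", "n_sites", "codon1", "codon2", "codon3",
                  "silent", "nonsynonymous", "tRNA", "rRNA", "intron",
                  "intergenic")

#' Summarise annotated sites per species and editing type
#'
#' Produces the per-species count table: total sites, coding sites by codon
#' position and by synonymy, and non-coding sites by region, plus a Total
#' row per type. The marginal identities (coding = 1st + 2nd + 3rd codon =
#' silent + nonsynonymous; total = coding + tRNA + rRNA + intron +
#' intergenic) are enforced and an internal consistency error is raised if
#' they fail.
#'
#' @param sites Annotated site data frame with a `species` column.
#' @return Summary data frame with columns [`SUMMARY_COLS`].
#' @export
summarize_cohort <- function(sites) {
  if (nrow(sites) == 0L || !"species" %in% names(sites)) {
    out <- data.frame(species = "Total", type = c("C-to-U", "G-to-A"),
                      n_sites = 0L, codon1 = 0L, codon2 = 0L, codon3 = 0L,
                      silent = 0L, nonsynonymous = 0L, tRNA = 0L, rRNA = 0L,
                      intron = 0L, intergenic = 0L, stringsAsFactors = FALSE)
    return(out)
  }
  groups <- unique(sites[c("species", "type")])
  groups <- groups[order(groups$species, groups$type), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    s <- sites[sites$species == groups$species[i] &
                 sites$type == groups$type[i], ]
    coding <- s$region == "CDS"
    data.frame(
      species = groups$species[i], type = groups$type[i],
      n_sites = nrow(s),
      codon1 = sum(coding & s$codon_pos == 1L, na.rm = TRUE),
      codon2 = sum(coding & s$codon_pos == 2L, na.rm = TRUE),
      codon3 = sum(coding & s$codon_pos == 3L, na.rm = TRUE),
      silent = sum(coding & s$synonymous, na.rm = TRUE),
      nonsynonymous = sum(coding & !s$synonymous, na.rm = TRUE),
      tRNA = sum(s$region == "tRNA"), rRNA = sum(s$region == "rRNA"),
      intron = sum(s$region == "intron"),
      intergenic = sum(s$region == "intergenic"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  check_summary_identities(out)
  rbind(out, aggregate_summary(out))
}

check_summary_identities <- function(tbl) {
  coding_by_codon <- tbl$codon1 + tbl$codon2 + tbl$codon3
  coding_by_syn <- tbl$silent + tbl$nonsynonymous
  total <- coding_by_codon + tbl$tRNA + tbl$rRNA + tbl$intron + tbl$intergenic
  if (any(coding_by_codon != coding_by_syn) || any(total != tbl$n_sites)) {
    bad <- which(coding_by_codon != coding_by_syn | total != tbl$n_sites)[1]
    stop("summary identity violated for ", tbl$species[bad], " / ",
         tbl$type[bad])
  }
  invisible(tbl)
}

#' Aggregate a per-species summary into Total rows
#'
#' Column sums per editing type over the per-species rows; identities are
#' checked on both input and output.
#'
#' @param tbl Summary data frame (per-species rows, no Total rows).
#' @return Data frame of one Total row per type.
#' @export
aggregate_summary <- function(tbl) {
  tbl <- tbl[tbl$species != "Total", ]
  check_summary_identities(tbl)
  counts <- setdiff(SUMMARY_COLS, c("species", "type"))
  rows <- lapply(sort(unique(tbl$type)), function(ty) {
    sub <- tbl[tbl$type == ty, ]
    out <- data.frame(species = "Total", type = ty, stringsAsFactors = FALSE)
    out[counts] <- lapply(sub[counts], sum)
    out
  })
  out <- do.call(rbind, rows)
  check_summary_identities(out)
  out
}

#' Packaged per-species summary of gymnosperm chloroplast editing sites
#'
#' Loads the packaged 19-species summary table of chloroplast C-to-U and
#' G-to-A editing-site counts (per species: totals, coding counts by codon
#' position and synonymy, and non-coding counts by region), with the
#' lineage of each species.
#'
#' @return Data frame with a `lineage` column plus [`SUMMARY_COLS`].
#' @export
gymnosperm_summary <- function() {
  path <- system.file("extdata", "gymnosperm_editing_summary.tsv",
                      package = "plastedit", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_summary_identities(df)
  df
}

#' Packaged gymnosperm species-to-lineage map
#' @return Named character vector: species -> lineage.
#' @export
gymnosperm_lineages <- function() {
  df <- gymnosperm_summary()
  m <- unique(df[c("species", "lineage")])
  setNames(m$lineage, m$species)
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation; two-sided p-value from
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-constant.
#' @return A `correlation_result` list: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = n),
            class = "correlation_result")
}

#' Correlate editing-site abundance with plastome features
#'
#' One Pearson correlation of `n_editing_sites` against each available
#' factor among plastome size, GC content, C content, dN, dS, RN and RS.
#' Incomplete rows are dropped pairwise; constant factors are skipped with
#' a warning.
#'
#' @param features Data frame with `n_editing_sites` and any of
#'   `plastome_size`, `gc_content`, `c_content`, `dN`, `dS`, `RN`, `RS`.
#' @return Data frame: factor, r, p_value, n.
#' @export
correlate_features <- function(features) {
  stopifnot("n_editing_sites" %in% names(features))
  fr <- c("plastome_size", "gc_content", "c_content", "dN", "dS", "RN", "RS")
  factors <- intersect(fr, names(features))
  frac_cols <- intersect(c("gc_content", "c_content"), factors)
  for (col in frac_cols) {
    v <- features[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop(col, " must lie in [0, 1]")
  }
  rate_cols <- intersect(c("dN", "dS", "RN", "RS"), factors)
  for (col in rate_cols) {
    if (any(!is.na(features[[col]]) & features[[col]] < 0)) {
      stop(col, " must be non-negative")
    }
  }
  rows <- lapply(factors, function(f) {
    res <- tryCatch(pearson_cor(features[[f]], features$n_editing_sites),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping factor ", f, ": ", conditionMessage(res))
      return(NULL)
    }
    data.frame(factor = f, r = res$r, p_value = res$p_value, n = res$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(factor = character(0), r = numeric(0),
                                      p_value = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}
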