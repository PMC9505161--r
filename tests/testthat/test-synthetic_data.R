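# Synthetic-data generator: determinism, planted structure, count models.

small_cfg <- function(...) {
  defaults <- list(genome_length = 20000L,
                   n_genes = c(CDS = 8L, tRNA = 2L, rRNA = 1L),
                   n_ctu_sites = 40L, n_gta_sites = 4L,
                   polymorphism_decoy_count = 10L,
                   indel_adjacent_count = 3L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("simulated references satisfy the gene-model invariants", {
  ref <- simulate_reference(small_cfg())
  expect_s3_class(ref$genome, "genome_record")
  spans <- t(vapply(ref$genes, function(g) g$span, numeric(2)))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))  # non-overlapping
  expect_true(any(spans[-1, 1] - spans[-nrow(spans), 2] > 1))  # gaps exist
  for (g in ref$genes) {
    if (g$biotype != "CDS") next
    expect_false(g$partial)
    seq <- plastedit:::spliced_gene_seq(g, ref$genome)
    expect_equal(substr(seq, 1, 3), "ATG")
    expect_true(substr(seq, nchar(seq) - 2, nchar(seq)) %in%
                  c("TAA", "TAG", "TGA"))
  }
  # infeasible packing is refused with advice
  expect_error(simulate_reference(sim_config(genome_length = 5000L)),
               "genome_length")
})

test_that("generation is deterministic in the seed", {
  a <- simulate_dataset(small_cfg(seed = 99L))
  b <- simulate_dataset(small_cfg(seed = 99L))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth, b$truth)
  expect_identical(a$pileup, b$pileup)
  c <- simulate_dataset(small_cfg(seed = 100L))
  expect_false(identical(a$pileup, c$pileup))
})

test_that("zero genes and zero sites degenerate cleanly", {
  cfg <- sim_config(genome_length = 5000L,
                    n_genes = c(CDS = 0L, tRNA = 0L, rRNA = 0L),
                    n_ctu_sites = 0L, n_gta_sites = 0L,
                    polymorphism_decoy_count = 0L, indel_adjacent_count = 0L)
  d <- simulate_dataset(cfg)
  expect_length(d$genes, 0)
  expect_equal(nrow(d$truth), 0L)
})

test_that("with no planted sites and no errors the caller is silent", {
  cfg <- sim_config(genome_length = 10000L,
                    n_genes = c(CDS = 4L, tRNA = 0L, rRNA = 0L),
                    n_ctu_sites = 0L, n_gta_sites = 0L,
                    polymorphism_decoy_count = 0L, indel_adjacent_count = 0L,
                    error_rate = 0)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(call_editing_sites(d$pileup, d$genes)), 0L)
})

test_that("planted sites respect strand and -1 context bias", {
  cfg <- sim_config(n_ctu_sites = 100L, n_gta_sites = 0L,
                    polymorphism_decoy_count = 0L,
                    indel_adjacent_count = 0L, seed = 5L)
  ref <- simulate_reference(cfg)
  truth <- plant_sites(ref$genome, ref$genes, cfg)
  base <- strsplit(ref$genome$sequence, "")[[1]]
  # sense C means genomic C on plus, genomic G on minus
  expect_true(all(base[truth$pos[truth$strand == "+"]] == "C"))
  expect_true(all(base[truth$pos[truth$strand == "-"]] == "G"))
  # -1 pyrimidine fraction within binomial noise of the configured 0.65
  m1 <- vapply(seq_len(nrow(truth)), function(i) {
    p <- truth$pos[i]
    if (truth$strand[i] == "+") base[p - 1L] else
      c(A = "T", C = "G", G = "C", T = "A")[[base[p + 1L]]]
  }, "")
  frac <- mean(m1 %in% c("C", "T"))
  tol <- 3 * sqrt(0.65 * 0.35 / nrow(truth))
  expect_lt(abs(frac - 0.65), tol)
})

test_that("pileup counts follow the planted efficiencies", {
  cfg <- small_cfg(error_rate = 0, rna_depth = 1000, seed = 3L,
                   indel_adjacent_count = 0L,
                   polymorphism_decoy_count = 0L)
  ref <- simulate_reference(cfg)
  truth <- plant_sites(ref$genome, ref$genes, cfg)
  # force one site to full efficiency
  truth$efficiency[1] <- 1.0
  pile <- simulate_pileups(ref$genome, truth, ref$genes, cfg)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(truth))) {
    row <- pile[pile$pos == truth$pos[i], ]
    orient <- if (truth$strand[i] == "+") "fwd" else "rev"
    cnt <- as.numeric(row[paste0("rna_", orient, "_clean_", bases)])
    n <- sum(cnt)
    k <- cnt[match(truth$edit_plus[i], bases)]
    if (i == 1) {
      expect_equal(k, n)  # efficiency 1, no error: everything edited
    } else if (n > 0) {
      se <- sqrt(truth$efficiency[i] * (1 - truth$efficiency[i]) / n)
      expect_lt(abs(k / n - truth$efficiency[i]), 3 * se + 1e-9)
    }
  }
})

test_that("indel-adjacent sites have clean counts suppressed as configured", {
  cfg <- small_cfg(indel_adjacent_count = 3L, clean_suppression = 0.9,
                   rna_depth = 200, seed = 11L)
  d <- simulate_dataset(cfg)
  ia <- d$truth[d$truth$is_indel_adjacent, ]
  expect_equal(nrow(ia), 3L)
  rows <- d$pileup[match(ia$pos, d$pileup$pos), ]
  clean <- rowSums(rows[grep("rna_(fwd|rev)_clean_", names(rows))])
  all_ <- rowSums(rows[grep("rna_(fwd|rev)_all_", names(rows))])
  # expected keep fraction 0.1; pooled binomial check
  expect_lt(abs(sum(clean) / sum(all_) - 0.1),
            3 * sqrt(0.1 * 0.9 / sum(all_)))
  # non-indel positions have identical pools
  other <- d$pileup[!d$pileup$pos %in% ia$pos, ]
  expect_equal(other$rna_fwd_clean_T, other$rna_fwd_all_T)
})

test_that("site-matrix simulation matches the two-state chain", {
  tree <- gymnosperm_tree()
  m1 <- simulate_site_matrix(tree, 1, 1, 50, seed = 4L)
  m2 <- simulate_site_matrix(tree, 1, 1, 50, seed = 4L)
  expect_identical(m1, m2)
  # overwhelming loss drives tips to absence
  m <- simulate_site_matrix(tree, 0.01, 100, 200, seed = 4L)
  expect_lt(mean(m), 0.01)
  # g = l on long branches: stationary tip frequency ~ 0.5
  long <- tree
  long$edge.length <- long$edge.length * 100
  m <- simulate_site_matrix(long, 1, 1, 2000, seed = 4L)
  expect_lt(abs(mean(m) - 0.5), 3 * sqrt(0.25 / length(m)) + 0.01)
})
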