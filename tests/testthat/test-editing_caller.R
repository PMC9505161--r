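# Calling rules, indel rescue, type classification, G-to-A corroboration.

test_that("a clear C-to-U signal is called with exact binomial p-value", {
  df <- pileup_rows(list(ref = "C", dna = c(C = 30),
                         fwd_clean = c(T = 24, C = 6)))
  sites <- call_sites(df)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$type, "C-to-U")
  expect_equal(sites$strand, "+")
  expect_equal(sites$efficiency, 0.8)
  # independent tail computation
  p_oracle <- sum(dbinom(24:30, 30, 0.001))
  expect_equal(sites$p_value, p_oracle)
  expect_lt(sites$p_value, 1e-3)
})

test_that("DNA polymorphism and reference-matching RNA are not called", {
  # heterozygous DNA: major fraction 20/30 < 0.95
  df <- pileup_rows(list(ref = "C", dna = c(C = 20, T = 10),
                         fwd_clean = c(T = 24, C = 6)))
  expect_equal(nrow(call_sites(df)), 0L)
  # RNA identical to DNA reference everywhere
  df <- pileup_rows(list(ref = "C", dna = c(C = 30), fwd_clean = c(C = 40)),
                    list(ref = "G", dna = c(G = 30), rev_clean = c(G = 35)))
  expect_equal(nrow(call_sites(df)), 0L)
})

test_that("DNA consensus differing from the reference warns and skips", {
  df <- pileup_rows(list(ref = "C", dna = c(T = 30),
                         fwd_clean = c(T = 40)))
  expect_warning(sites <- call_sites(df), "assembly")
  expect_equal(nrow(sites), 0L)
})

test_that("strand purity suppresses ambiguous sites", {
  # edited T reads split 12/10 across orientations: purity 0.55 < 0.90
  df <- pileup_rows(list(ref = "C", dna = c(C = 30),
                         fwd_clean = c(T = 12, C = 8),
                         rev_clean = c(T = 10, C = 10)))
  expect_equal(nrow(call_sites(df)), 0L)
})

test_that("indel rescue recovers masked sites on the all-counts pool", {
  df <- pileup_rows(list(ref = "C", dna = c(C = 30),
                         fwd_clean = c(T = 2),
                         fwd_all = c(T = 15, C = 5)))
  clean <- call_sites(df)
  expect_equal(nrow(clean), 0L)
  rescued <- rescue_indel_adjacent(df, clean)
  expect_equal(nrow(rescued), 1L)
  expect_true(rescued$rescued)
  expect_equal(rescued$efficiency, 0.75)

  # a site passing on clean counts is not duplicated by rescue
  df2 <- pileup_rows(list(ref = "C", dna = c(C = 30),
                          fwd_clean = c(T = 24, C = 6),
                          fwd_all = c(T = 30, C = 8)))
  clean2 <- call_sites(df2)
  expect_equal(nrow(clean2), 1L)
  expect_equal(nrow(rescue_indel_adjacent(df2, clean2)), 0L)
  all_sites <- call_editing_sites(df2)
  expect_equal(nrow(all_sites), 1L)
  expect_false(all_sites$rescued)

  # rescue never overrides a DNA-level rejection
  df3 <- pileup_rows(list(ref = "C", dna = c(C = 15, T = 15),
                          fwd_clean = c(T = 2),
                          fwd_all = c(T = 20, C = 5)))
  expect_equal(nrow(rescue_indel_adjacent(df3, call_sites(df3))), 0L)
})

test_that("types are classified on the transcribed strand", {
  genes <- list(gene_model("plusG", "CDS", "+", rbind(c(1, 30))),
                gene_model("minusG", "CDS", "-", rbind(c(101, 130))))
  df <- pileup_rows(
    # plus-strand gene, genomic C->T on fwd reads
    list(pos = 10, ref = "C", dna = c(C = 30), fwd_clean = c(T = 20, C = 5)),
    # minus-strand gene, genomic G->A seen on rev reads: sense C-to-U
    list(pos = 110, ref = "G", dna = c(G = 30), rev_clean = c(A = 20, G = 5)),
    # plus-strand gene, genomic G->A on fwd reads: a true G-to-A event
    list(pos = 20, ref = "G", dna = c(G = 30), fwd_clean = c(A = 18, G = 6))
  )
  sites <- call_editing_sites(df, genes)
  expect_equal(sites$type[sites$pos == 10], "C-to-U")
  expect_equal(sites$type[sites$pos == 110], "C-to-U")
  expect_equal(sites$strand[sites$pos == 110], "-")
  expect_equal(sites$type[sites$pos == 20], "G-to-A")
  expect_false(any(sites$antisense_candidate))

  # read strand contradicting the annotation strand is flagged, kept
  df2 <- pileup_rows(list(pos = 110, ref = "C", dna = c(C = 30),
                          fwd_clean = c(T = 20, C = 5)))
  s2 <- call_editing_sites(df2, genes)
  expect_true(s2$antisense_candidate)
  expect_equal(s2$strand, "+")
})

test_that("G-to-A support window is same-strand and inclusive at 150 bp", {
  mk <- function(ctu_pos, ctu_orient = "fwd") {
    # a sense C-to-U is genomic C->T on fwd reads, genomic G->A on rev reads
    ctu <- if (ctu_orient == "fwd") {
      list(pos = ctu_pos, ref = "C", dna = c(C = 30),
           fwd_clean = c(T = 20, C = 5))
    } else {
      list(pos = ctu_pos, ref = "G", dna = c(G = 30),
           rev_clean = c(A = 20, G = 5))
    }
    pileup_rows(
      list(pos = 1000, ref = "G", dna = c(G = 30),
           fwd_clean = c(A = 15, G = 15)),
      ctu)
  }
  s <- flag_gta_support(call_editing_sites(mk(1100)))
  expect_true(s$gta_supported[s$type == "G-to-A"])
  s <- flag_gta_support(call_editing_sites(mk(1150)))
  expect_true(s$gta_supported[s$type == "G-to-A"])   # boundary inclusive
  s <- flag_gta_support(call_editing_sites(mk(1151)))
  expect_false(s$gta_supported[s$type == "G-to-A"])
  s <- flag_gta_support(call_editing_sites(mk(1100, "rev")))
  expect_false(s$gta_supported[s$type == "G-to-A"])  # opposite strand
  expect_true(all(is.na(s$gta_supported[s$type == "C-to-U"])))
})

test_that("efficiency is exactly k/n and raising thresholds is monotone", {
  cfg <- sim_config(genome_length = 15000L,
                    n_genes = c(CDS = 6L, tRNA = 1L, rRNA = 1L),
                    n_ctu_sites = 30L, n_gta_sites = 3L,
                    polymorphism_decoy_count = 5L,
                    indel_adjacent_count = 2L, seed = 21L)
  d <- simulate_dataset(cfg)
  base <- caller_params()
  sites <- call_sites(d$pileup, base)
  expect_true(all(sites$efficiency ==
                    sites$edited_reads / sites$rna_depth))
  expect_true(all(sites$efficiency >= 0 & sites$efficiency <= 1))
  n0 <- nrow(sites)
  for (p in list(caller_params(min_dna_depth = 20L),
                 caller_params(min_rna_depth = 25L),
                 caller_params(min_edited_reads = 8L),
                 caller_params(dna_major_allele_min_fraction = 0.99),
                 caller_params(alpha = 1e-8),
                 caller_params(min_efficiency = 0.5),
                 caller_params(strand_purity = 0.99))) {
    expect_lte(nrow(call_sites(d$pileup, p)), n0)
  }
})

test_that("caller output equals brute-force rule application", {
  cfg <- sim_config(genome_length = 12000L,
                    n_genes = c(CDS = 5L, tRNA = 1L, rRNA = 1L),
                    n_ctu_sites = 25L, n_gta_sites = 3L,
                    polymorphism_decoy_count = 6L, indel_adjacent_count = 0L,
                    seed = 8L)
  d <- simulate_dataset(cfg)
  # a 200-position window enriched for planted sites
  centre <- d$truth$pos[10]
  window <- d$pileup[d$pileup$pos >= centre - 100 &
                       d$pileup$pos < centre + 100, ]
  params <- caller_params()
  mine <- call_sites(window, params)
  oracle <- brute_force_calls(window, params)
  expect_equal(nrow(mine), nrow(oracle))
  expect_equal(mine$pos, oracle$pos)
  expect_equal(mine$strand, oracle$strand)
  expect_equal(mine$ref_sense, oracle$ref_sense)
  expect_equal(mine$edit_sense, oracle$edit_sense)
  expect_equal(mine$efficiency, oracle$efficiency)

  # and on the full (small) pileup in aggregate
  mine_all <- call_sites(d$pileup, params)
  oracle_all <- brute_force_calls(d$pileup, params)
  expect_equal(paste(mine_all$pos, mine_all$strand),
               paste(oracle_all$pos, oracle_all$strand))
})
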