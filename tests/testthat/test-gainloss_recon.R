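# Two-state gain/loss machinery: pruning likelihood, rate fitting,
# expected event counts, Fitch parsimony.

two_tip_tree <- function(t1 = 0.1, t2 = 0.1) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", t1, t2))
}

quartet_tree <- function(b = 0.3) {
  ape::read.tree(text = sprintf(
    "((A:%g,B:%g):%g,(C:%g,D:%g):%g);", b, b, b, b, b, b))
}

pattern_matrix <- function(states, tips) {
  matrix(states, length(tips), 1, dimnames = list(tips, "s1"))
}

test_that("the two-taxon likelihood matches the closed form", {
  tree <- two_tip_tree()
  m <- pattern_matrix(c(1L, 0L), c("A", "B"))
  model <- gainloss_model(1, 1)
  ll <- gainloss_likelihood(m, tree, model)
  # pi = (1/2,1/2); L = sum_a pi_a P_a1(.1) P_a0(.1) = (1 - e^{-0.4})/4
  expect_equal(as.numeric(ll), log((1 - exp(-0.4)) / 4))
  expect_equal(as.numeric(exp(ll)), 0.0824, tolerance = 1e-3)
})

test_that("zero branch lengths collapse to the root prior", {
  tree <- two_tip_tree(0, 0)
  model <- gainloss_model(2, 3)
  m1 <- pattern_matrix(c(1L, 1L), c("A", "B"))
  m0 <- pattern_matrix(c(0L, 0L), c("A", "B"))
  expect_equal(as.numeric(exp(gainloss_likelihood(m1, tree, model))),
               model$root_prior[2])
  expect_equal(as.numeric(exp(gainloss_likelihood(m0, tree, model))),
               model$root_prior[1])
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(7)
  for (rep in 1:8) {
    n_tip <- sample(3:5, 1)
    tree <- ape::rtree(n_tip, br = function(n) runif(n, 0.05, 1))
    g <- runif(1, 0.2, 2); l <- runif(1, 0.2, 2)
    states <- sample(c(0L, 1L, NA), n_tip, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    m <- pattern_matrix(states, tree$tip.label)
    ll <- gainloss_likelihood(m, tree, gainloss_model(g, l))
    expect_equal(as.numeric(exp(ll)), enum_likelihood(states, tree, g, l),
                 tolerance = 1e-12)
  }
})

test_that("time/rate rescaling leaves the likelihood unchanged", {
  tree <- quartet_tree()
  m <- pattern_matrix(c(1L, 1L, 0L, 1L), tree$tip.label)
  ll1 <- gainloss_likelihood(m, tree, gainloss_model(0.8, 1.6))
  tree2 <- tree
  tree2$edge.length <- tree2$edge.length * 2
  ll2 <- gainloss_likelihood(m, tree2, gainloss_model(0.4, 0.8))
  expect_equal(as.numeric(ll1), as.numeric(ll2))
})

test_that("replacing an observed state by missing never lowers site likelihood", {
  set.seed(11)
  tree <- ape::rtree(5, br = function(n) runif(n, 0.1, 0.8))
  model <- gainloss_model(0.7, 1.2)
  for (rep in 1:5) {
    states <- sample(0:1, 5, replace = TRUE)
    m <- pattern_matrix(states, tree$tip.label)
    base <- exp(as.numeric(gainloss_likelihood(m, tree, model)))
    for (i in 1:5) {
      m2 <- m
      m2[i, 1] <- NA
      relaxed <- exp(as.numeric(gainloss_likelihood(m2, tree, model)))
      expect_gte(relaxed + 1e-12, base)
    }
  }
})

test_that("degenerate matrices push a rate to its bound with a warning", {
  tree <- quartet_tree()
  m <- matrix(1L, 4, 5, dimnames = list(tree$tip.label, paste0("s", 1:5)))
  expect_warning(fit <- fit_gainloss(m, tree), "degenerate")
  expect_lt(fit$loss, 1e-4)
})

test_that("expected events behave in limits and dominate parsimony", {
  tree <- quartet_tree()
  m <- pattern_matrix(c(0L, 0L, 0L, 0L), tree$tip.label)
  res <- expected_events(m, tree, gainloss_model(1e-6, 1))
  expect_lt(res$total_gains, 1e-4)
  expect_lt(res$total_losses, 1e-4)

  # (1,1,0,0) on ((A,B),(C,D)): one dominant event where Fitch puts it
  m <- pattern_matrix(c(1L, 1L, 0L, 0L), tree$tip.label)
  model <- gainloss_model(0.5, 0.5)
  res <- expected_events(m, tree, model)
  fp <- fitch_parsimony(m, tree)
  expect_equal(fp$total, 1L)
  top <- which.max(res$branches$expected_gains +
                     res$branches$expected_losses)
  expect_equal(res$branches$child[top],
               res$tree$edge[which(fp$branch_changes == 1L), 2])
  # expectation dominates the parsimony minimum
  expect_gte(res$total_gains + res$total_losses, fp$total)
})

test_that("analytic expected counts agree with stochastic mapping", {
  tree <- quartet_tree(0.4)
  m <- cbind(pattern_matrix(c(1L, 1L, 0L, 0L), tree$tip.label),
             s2 = c(1L, 0L, 1L, 0L), s3 = c(1L, 1L, 1L, 0L))
  model <- gainloss_model(0.8, 1.1)
  res <- expected_events(m, tree, model, mapping_samples = 2000L, seed = 2L)
  for (ei in seq_len(nrow(res$branches))) {
    tol <- 4 * res$mapping$gains_se[ei] + 1e-3
    expect_lt(abs(res$branches$expected_gains[ei] -
                    res$mapping$gains_mean[ei]), tol)
    tol <- 4 * res$mapping$losses_se[ei] + 1e-3
    expect_lt(abs(res$branches$expected_losses[ei] -
                    res$mapping$losses_mean[ei]), tol)
  }
})

test_that("Fitch parsimony matches exhaustive minimisation", {
  tree <- quartet_tree()
  expect_equal(fitch_parsimony(
    pattern_matrix(c(1L, 1L, 1L, 1L), tree$tip.label), tree)$total, 0L)
  expect_equal(fitch_parsimony(
    pattern_matrix(c(1L, 1L, 0L, 0L), tree$tip.label), tree)$total, 1L)
  expect_equal(fitch_parsimony(
    pattern_matrix(c(1L, 0L, 1L, 0L), tree$tip.label), tree)$total, 2L)

  set.seed(19)
  for (rep in 1:10) {
    tr <- ape::rtree(5)
    states <- sample(c(0L, 1L, NA), 5, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    m <- pattern_matrix(states, tr$tip.label)
    fp <- fitch_parsimony(m, tr)
    expect_equal(fp$per_site[[1]], enum_min_changes(states, tr))
    expect_equal(sum(fp$branch_changes), fp$total)
  }
})

test_that("rates are recovered from simulated matrices", {
  tree <- gymnosperm_tree()
  m <- simulate_site_matrix(tree, 0.5, 1.0, 800, seed = 31L)
  fit <- fit_gainloss(m, tree)
  expect_lt(abs(fit$gain - 0.5) / 0.5, 0.25)
  expect_lt(abs(fit$loss - 1.0) / 1.0, 0.25)
})
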