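# Gain/loss reconstruction of presence/absence characters on a rooted
# phylogeny under a two-state Markov model: pruning likelihood, rate
# fitting, analytic expected per-branch gain and loss counts (with a
# stochastic-mapping sampler as cross-check), and Fitch parsimony.

#' Packaged 19-species gymnosperm reference tree
#'
#' Rooted binary topology following the five gymnosperm lineages
#' (Cycadales + Ginkgoaceae sister to the conifer/gnetophyte clade, with
#' Gnetales sister to Pinaceae); branch lengths are synthetic, chosen in the
#' informative regime for presence/absence characters.
#'
#' @return An [ape::read.tree()] `phylo` object with 19 tips.
#' @export
gymnosperm_tree <- function() {
  read_tree(system.file("extdata", "gymnosperm_tree.nwk",
                        package = "plastedit", mustWork = TRUE))
}

#' Two-state gain/loss model
#'
#' States are 0 (site absent) and 1 (site present); `gain` is the 0->1 rate
#' and `loss` the 1->0 rate per unit branch length. Optional discrete rate
#' categories scale both rates by `rate_multipliers` with `weights`. The
#' root prior defaults to the stationary distribution
#' (pi1 = gain / (gain + loss)).
#'
#' @param gain,loss Positive rates.
#' @param rate_multipliers Numeric vector of per-category multipliers.
#' @param weights Category weights summing to 1.
#' @param root_prior Length-2 vector (state 0, state 1) or NULL for
#'   stationary.
#' @return A `gainloss_model` list.
#' @export
gainloss_model <- function(gain, loss, rate_multipliers = 1,
                           weights = 1, root_prior = NULL) {
  stopifnot(gain > 0, loss > 0,
            length(rate_multipliers) == length(weights),
            abs(sum(weights) - 1) < 1e-8, all(rate_multipliers > 0))
  if (is.null(root_prior)) {
    root_prior <- c(loss, gain) / (gain + loss)
  }
  stopifnot(length(root_prior) == 2, abs(sum(root_prior) - 1) < 1e-8)
  structure(list(gain = gain, loss = loss,
                 rate_multipliers = rate_multipliers, weights = weights,
                 root_prior = root_prior),
            class = "gainloss_model")
}

# 2x2 transition probability matrix, rows = from-state (0,1)
gl_pmatrix <- function(gain, loss, t) {
  r <- gain + loss
  pi1 <- gain / r
  pi0 <- 1 - pi1
  e <- exp(-r * t)
  matrix(c(pi0 + pi1 * e, pi0 * (1 - e),
           pi1 * (1 - e), pi1 + pi0 * e),
         2, 2, dimnames = list(c("0", "1"), c("0", "1")))
}

# checks/normalises the inputs shared by the likelihood machinery
gl_prepare <- function(matrix, tree) {
  stopifnot(!is.null(rownames(matrix)))
  if (!all(rownames(matrix) %in% tree$tip.label)) {
    stop("matrix rows not in tree: ",
         paste(setdiff(rownames(matrix), tree$tip.label), collapse = ", "))
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  n_sites <- ncol(matrix)
  # tip partials: observed state or (1,1) for missing / absent species
  tip_part <- lapply(seq_len(n_tip), function(i) {
    sp <- tree$tip.label[i]
    out <- matrix(1, n_sites, 2)
    if (sp %in% rownames(matrix)) {
      s <- matrix[sp, ]
      out[!is.na(s) & s == 0L, 2] <- 0
      out[!is.na(s) & s == 1L, 1] <- 0
    }
    out
  })
  list(tree = tree, n_tip = n_tip, n_sites = n_sites, tip_part = tip_part,
       postorder = ape::postorder(tree))
}

# pruning pass for one rate category; returns partials for every node and
# per-site likelihoods
gl_prune <- function(prep, gain, loss, prior) {
  tree <- prep$tree
  n_node <- prep$n_tip + tree$Nnode
  partial <- vector("list", n_node)
  partial[seq_len(prep$n_tip)] <- prep$tip_part
  S_edge <- vector("list", nrow(tree$edge))  # S_v(a) per edge
  for (ei in prep$postorder) {
    par <- tree$edge[ei, 1]; chi <- tree$edge[ei, 2]
    P <- gl_pmatrix(gain, loss, tree$edge.length[ei])
    S <- partial[[chi]] %*% t(P)
    S_edge[[ei]] <- S
    if (is.null(partial[[par]])) {
      partial[[par]] <- S
    } else {
      partial[[par]] <- partial[[par]] * S
    }
  }
  root <- prep$n_tip + 1L
  site_lik <- as.vector(partial[[root]] %*% prior)
  list(partial = partial, S_edge = S_edge, site_lik = site_lik)
}

#' Pruning log-likelihood of a presence/absence matrix
#'
#' Missing entries (`NA`, gene absent in a species) contribute a partial
#' likelihood of 1 for both states; tree tips without a matrix row are
#' treated the same way. With rate categories the per-site likelihood is
#' the weighted sum over categories.
#'
#' @param matrix 0/1/NA matrix, rows named by species.
#' @param tree Rooted `phylo` with branch lengths (tips >= matrix rows).
#' @param model A [gainloss_model()].
#' @return Log-likelihood (scalar) with per-site likelihoods in the
#'   `site_lik` attribute.
#' @export
gainloss_likelihood <- function(matrix, tree, model) {
  prep <- gl_prepare(matrix, tree)
  site_lik <- rep(0, prep$n_sites)
  for (c in seq_along(model$rate_multipliers)) {
    m <- model$rate_multipliers[c]
    pr <- gl_prune(prep, model$gain * m, model$loss * m, model$root_prior)
    site_lik <- site_lik + model$weights[c] * pr$site_lik
  }
  ll <- sum(log(site_lik))
  attr(ll, "site_lik") <- site_lik
  ll
}

#' Fit gain and loss rates by maximum likelihood
#'
#' Bounded quasi-Newton optimisation on log rates from the fixed starting
#' point g = l = 1, hence deterministic. With `K` > 1 the model uses K
#' equal-weight discrete rate categories whose multipliers are fixed at
#' K evenly spaced quantile midpoints of an exponential(1) (mean-one)
#' distribution.
#'
#' @param matrix 0/1/NA matrix, rows named by species.
#' @param tree Rooted `phylo` with branch lengths.
#' @param K Number of rate categories.
#' @return Fitted [gainloss_model()] with `loglik` and `convergence`
#'   attributes.
#' @export
fit_gainloss <- function(matrix, tree, K = 1L) {
  stopifnot(ncol(matrix) >= 2L)
  vals <- matrix[!is.na(matrix)]
  if (all(vals == 0L) || all(vals == 1L)) {
    warning("degenerate matrix (all-absent or all-present): a rate is ",
            "reported at its bound")
  }
  if (K > 1L) {
    q <- (seq_len(K) - 0.5) / K
    mult <- stats::qexp(q)
    mult <- mult / mean(mult)
    weights <- rep(1 / K, K)
  } else {
    mult <- 1; weights <- 1
  }
  prep <- gl_prepare(matrix, tree)
  nll <- function(par) {
    g <- exp(par[1]); l <- exp(par[2])
    site_lik <- rep(0, prep$n_sites)
    prior <- c(l, g) / (g + l)
    for (c in seq_along(mult)) {
      pr <- gl_prune(prep, g * mult[c], l * mult[c], prior)
      site_lik <- site_lik + weights[c] * pr$site_lik
    }
    -sum(log(pmax(site_lik, 1e-300)))
  }
  fit <- optim(c(0, 0), nll, method = "L-BFGS-B",
               lower = c(-12, -12), upper = c(8, 8))
  model <- gainloss_model(exp(fit$par[1]), exp(fit$par[2]),
                          rate_multipliers = mult, weights = weights)
  attr(model, "loglik") <- -fit$value
  attr(model, "convergence") <- fit$convergence
  model
}

# closed-form E[N_{01} * 1(X_t = b) | X_0 = a] (and 1->0 analogue) for the
# two-state chain: the transition kernel is a constant plus one exponential,
# so the path integral has an explicit form.
gl_expected_transitions <- function(gain, loss, t) {
  r <- gain + loss
  pi1 <- gain / r
  pi0 <- 1 - pi1
  e <- exp(-r * t)
  P <- gl_pmatrix(gain, loss, t)
  J <- function(rate, from_absorb, to_emit) {
    # rate * int_0^t P_{a,from}(s) P_{to,b}(t-s) ds for all (a,b)
    out <- matrix(0, 2, 2)
    for (a in 0:1) for (b in 0:1) {
      pi_from <- if (from_absorb == 0) pi0 else pi1
      A <- (if (a == from_absorb) 1 else 0) - pi_from
      pi_b <- if (b == 1) pi1 else pi0
      B <- (if (to_emit == b) 1 else 0) - pi_b
      out[a + 1, b + 1] <- rate *
        (pi_from * pi_b * t +
           pi_from * B * (1 - e) / r +
           A * pi_b * (1 - e) / r +
           A * B * t * e)
    }
    out
  }
  list(gain = J(gain, 0, 1) / pmax(P, 1e-300),
       loss = J(loss, 1, 0) / pmax(P, 1e-300))
}

# joint endpoint posteriors and expected counts for one category;
# returns per-edge gains/losses (summed over sites) and node posteriors
gl_updown <- function(prep, gain, loss, prior, site_weight) {
  tree <- prep$tree
  n_sites <- prep$n_sites
  n_node <- prep$n_tip + tree$Nnode
  pr <- gl_prune(prep, gain, loss, prior)
  root <- prep$n_tip + 1L
  lik <- pr$site_lik

  out_part <- vector("list", n_node)  # Out_v(a): data outside subtree of v
  out_part[[root]] <- matrix(rep(prior, each = n_sites), n_sites, 2)
  n_edge <- nrow(tree$edge)
  gains <- numeric(n_edge); losses <- numeric(n_edge)
  node_post <- vector("list", n_node)
  node_post[[root]] <- out_part[[root]] * pr$partial[[root]] / lik

  children <- split(seq_len(n_edge), tree$edge[, 1])
  preorder <- rev(prep$postorder)
  for (ei in preorder) {
    par <- tree$edge[ei, 1]; chi <- tree$edge[ei, 2]
    t <- tree$edge.length[ei]
    P <- gl_pmatrix(gain, loss, t)
    sib <- setdiff(children[[as.character(par)]], ei)
    pre <- out_part[[par]]
    for (si in sib) pre <- pre * pr$S_edge[[si]]
    # joint posterior over (parent a, child b), per site
    EN <- gl_expected_transitions(gain, loss, t)
    eg <- numeric(n_sites); el <- numeric(n_sites)
    out_chi <- matrix(0, n_sites, 2)
    for (a in 1:2) {
      for (b in 1:2) {
        joint <- pre[, a] * P[a, b] * pr$partial[[chi]][, b] / lik
        eg <- eg + joint * EN$gain[a, b]
        el <- el + joint * EN$loss[a, b]
      }
      out_chi <- out_chi + pre[, a] * matrix(P[a, ], n_sites, 2,
                                             byrow = TRUE)
    }
    out_part[[chi]] <- out_chi
    node_post[[chi]] <- out_chi * pr$partial[[chi]] / lik
    gains[ei] <- sum(site_weight * eg)
    losses[ei] <- sum(site_weight * el)
  }
  list(gains = gains, losses = losses, node_post = node_post, lik = lik)
}

#' Expected gain and loss events per branch
#'
#' Computes, for every branch, the posterior expected number of 0->1 (gain)
#' and 1->0 (loss) transitions summed over sites, using the analytic
#' expected Markov transition counts conditioned on branch-endpoint joint
#' posteriors. With `mapping_samples > 0` a seeded stochastic-mapping
#' sampler is run alongside as an independent Monte-Carlo estimate.
#'
#' @param matrix 0/1/NA matrix, rows named by species.
#' @param tree Rooted `phylo` with branch lengths.
#' @param model A [gainloss_model()] (fitted or supplied).
#' @param mapping_samples Number of stochastic-mapping samples (0 = off).
#' @param seed Seed for the sampler.
#' @return A `gainloss_result` list: `branches` (data frame with parent,
#'   child, length, expected_gains, expected_losses), `total_gains`,
#'   `total_losses`, `node_posterior` (nodes x 2 matrix of mean presence
#'   posteriors), `loglik`, and optionally `mapping` (sampled per-branch
#'   means).
#' @export
expected_events <- function(matrix, tree, model, mapping_samples = 0L,
                            seed = 17L) {
  prep <- gl_prepare(matrix, tree)
  tree <- prep$tree
  n_edge <- nrow(tree$edge)
  n_cat <- length(model$rate_multipliers)

  # category posterior per site
  cat_lik <- matrix(0, prep$n_sites, n_cat)
  for (c in seq_len(n_cat)) {
    m <- model$rate_multipliers[c]
    cat_lik[, c] <- model$weights[c] *
      gl_prune(prep, model$gain * m, model$loss * m, model$root_prior)$site_lik
  }
  tot_lik <- rowSums(cat_lik)
  cat_post <- cat_lik / tot_lik

  gains <- numeric(n_edge); losses <- numeric(n_edge)
  node_mean <- NULL
  for (c in seq_len(n_cat)) {
    m <- model$rate_multipliers[c]
    ud <- gl_updown(prep, model$gain * m, model$loss * m, model$root_prior,
                    site_weight = cat_post[, c])
    gains <- gains + ud$gains
    losses <- losses + ud$losses
    post_c <- t(vapply(ud$node_post, function(np) colMeans(np * cat_post[, c]),
                       numeric(2)))
    node_mean <- if (is.null(node_mean)) post_c else node_mean + post_c
  }

  branches <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2],
                         length = tree$edge.length,
                         expected_gains = gains, expected_losses = losses)
  res <- list(model = model, branches = branches,
              total_gains = sum(gains), total_losses = sum(losses),
              node_posterior = node_mean,
              loglik = sum(log(tot_lik)), tree = tree)
  if (mapping_samples > 0L) {
    res$mapping <- gl_stochastic_map(prep, model, mapping_samples, seed)
  }
  class(res) <- "gainloss_result"
  res
}

# stochastic mapping: sample node states from the joint posterior, then
# branch paths conditioned on endpoints (rejection sampling), and average
# realised transition counts
gl_stochastic_map <- function(prep, model, n_samples, seed) {
  set.seed(seed)
  tree <- prep$tree
  n_edge <- nrow(tree$edge)
  n_sites <- prep$n_sites
  root <- prep$n_tip + 1L
  n_cat <- length(model$rate_multipliers)

  runs <- vector("list", n_cat)
  cat_lik <- matrix(0, n_sites, n_cat)
  for (c in seq_len(n_cat)) {
    m <- model$rate_multipliers[c]
    runs[[c]] <- gl_prune(prep, model$gain * m, model$loss * m,
                          model$root_prior)
    cat_lik[, c] <- model$weights[c] * runs[[c]]$site_lik
  }
  cat_post <- cat_lik / rowSums(cat_lik)

  sim_path <- function(a, b, g, l, t) {
    # CTMC path from state a over time t conditioned on ending in b;
    # returns c(gains, losses)
    repeat {
      s <- a; tt <- 0; ng <- 0L; nl <- 0L
      repeat {
        rate <- if (s == 0L) g else l
        tt <- tt + rexp(1, rate)
        if (tt > t) break
        if (s == 0L) { ng <- ng + 1L; s <- 1L } else { nl <- nl + 1L; s <- 0L }
      }
      if (s == b) return(c(ng, nl))
    }
  }

  gains <- matrix(0, n_samples, n_edge)
  losses <- matrix(0, n_samples, n_edge)
  preorder <- rev(prep$postorder)
  for (it in seq_len(n_samples)) {
    for (site in seq_len(n_sites)) {
      c <- sample.int(n_cat, 1L, prob = cat_post[site, ])
      m <- model$rate_multipliers[c]
      g <- model$gain * m; l <- model$loss * m
      pr <- runs[[c]]
      node_state <- integer(prep$n_tip + tree$Nnode)
      w <- model$root_prior * pr$partial[[root]][site, ]
      node_state[root] <- sample(0:1, 1L, prob = w)
      for (ei in preorder) {
        par <- tree$edge[ei, 1]; chi <- tree$edge[ei, 2]
        t <- tree$edge.length[ei]
        P <- gl_pmatrix(g, l, t)
        a <- node_state[par]
        w <- P[a + 1L, ] * pr$partial[[chi]][site, ]
        b <- sample(0:1, 1L, prob = w)
        node_state[chi] <- b
        nn <- sim_path(a, b, g, l, t)
        gains[it, ei] <- gains[it, ei] + nn[1]
        losses[it, ei] <- losses[it, ei] + nn[2]
      }
    }
  }
  list(gains_mean = colMeans(gains), losses_mean = colMeans(losses),
       gains_se = apply(gains, 2, stats::sd) / sqrt(n_samples),
       losses_se = apply(losses, 2, stats::sd) / sqrt(n_samples))
}

#' Fitch parsimony on a presence/absence matrix
#'
#' Minimal state changes per site with missing entries unconstrained, plus
#' one optimal assignment used to tally changes per branch.
#'
#' @param matrix 0/1/NA matrix, rows named by species.
#' @param tree Rooted binary `phylo`.
#' @return List with `per_site` (minimal changes per site), `total`
#'   (their sum) and `branch_changes` (per-edge change counts under one
#'   optimal assignment).
#' @export
fitch_parsimony <- function(matrix, tree) {
  prep <- gl_prepare(matrix, tree)
  tree <- prep$tree
  n_sites <- prep$n_sites
  n_node <- prep$n_tip + tree$Nnode
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  sets <- matrix(0L, n_node, n_sites)
  for (i in seq_len(prep$n_tip)) {
    part <- prep$tip_part[[i]]
    sets[i, ] <- ifelse(part[, 1] == 1 & part[, 2] == 1, 3L,
                        ifelse(part[, 2] == 1, 2L, 1L))
  }
  changes <- matrix(0L, 1, n_sites)[1, ]
  for (ei in prep$postorder) {
    par <- tree$edge[ei, 1]; chi <- tree$edge[ei, 2]
    if (all(sets[par, ] == 0L)) {
      sets[par, ] <- sets[chi, ]
    } else {
      inter <- bitwAnd(sets[par, ], sets[chi, ])
      un <- bitwOr(sets[par, ], sets[chi, ])
      empty <- inter == 0L
      changes <- changes + empty
      sets[par, ] <- ifelse(empty, un, inter)
    }
  }
  # one optimal assignment, top-down; prefer absence on ties
  assign <- matrix(NA_integer_, n_node, n_sites)
  root <- prep$n_tip + 1L
  assign[root, ] <- ifelse(sets[root, ] == 2L, 1L, 0L)
  branch_changes <- integer(nrow(tree$edge))
  for (ei in rev(prep$postorder)) {
    par <- tree$edge[ei, 1]; chi <- tree$edge[ei, 2]
    par_state <- assign[par, ]
    par_bit <- ifelse(par_state == 0L, 1L, 2L)
    keep <- bitwAnd(sets[chi, ], par_bit) != 0L
    assign[chi, ] <- ifelse(keep, par_state,
                            ifelse(sets[chi, ] == 2L, 1L, 0L))
    branch_changes[ei] <- sum(assign[chi, ] != par_state)
  }
  list(per_site = changes, total = sum(changes),
       branch_changes = branch_changes)
}
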