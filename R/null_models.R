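#' Degree-preserving rewiring (Markov edge switching)
#'
#' Generates a randomized surrogate network in which every node keeps its
#' exact in-degree and out-degree while the global topology is destroyed.
#' The classic Maslov-Sneppen switching walk for directed graphs: repeatedly
#' draw two edges `a -> b` and `c -> d` and replace them with `a -> d` and
#' `c -> b`. A proposed swap is rejected (and still counts against the
#' attempt budget) if it would create a self-loop or a duplicate edge.
#'
#' @param net A `directed_network` with at least 2 edges.
#' @param n_attempts Number of attempted swaps; default `10 * n_edges(net)`,
#'   a standard burn-in for switching randomization.
#' @param seed Integer seed; the result is a deterministic function of
#'   `(net, n_attempts, seed)`. `NULL` uses (and advances) the session RNG.
#' @return A `directed_network` with identical per-node degree sequences.
#'   The realized swap count is attached as attribute `n_swaps`; a warning
#'   is issued if no swap succeeded on a non-degenerate network.
#' @examples
#' net <- generate_background(20, 0.2, seed = 1)
#' surr <- rewire_degree_preserving(net, seed = 42)
#' all.equal(node_degrees(net), node_degrees(surr))
#' @export
rewire_degree_preserving <- function(net, n_attempts = NULL, seed = NULL) {
  stopifnot(inherits(net, "directed_network"))
  m <- n_edges(net)
  if (m < 2) abort("Rewiring needs a network with at least 2 edges.")
  if (is.null(n_attempts)) n_attempts <- 10L * m
  if (!is.null(seed)) withr::local_seed(seed)

  adj <- net$adjacency
  idx <- which(adj == 1L, arr.ind = TRUE)
  from <- idx[, 1]
  to <- idx[, 2]
  n_swaps <- 0L
  picks <- matrix(sample.int(m, 2L * n_attempts, replace = TRUE), ncol = 2)
  for (s in seq_len(n_attempts)) {
    e1 <- picks[s, 1]; e2 <- picks[s, 2]
    if (e1 == e2) next
    a <- from[e1]; b <- to[e1]; c <- from[e2]; d <- to[e2]
    # proposed: a->d, c->b
    if (a == d || c == b) next                       # self-loop
    if (adj[a, d] == 1L || adj[c, b] == 1L) next     # duplicate edge
    adj[a, b] <- 0L; adj[c, d] <- 0L
    adj[a, d] <- 1L; adj[c, b] <- 1L
    to[e1] <- d; to[e2] <- b
    n_swaps <- n_swaps + 1L
  }
  if (n_swaps == 0L) {
    warn("No legal swap found within the attempt budget; returning best effort.")
  }
  out <- directed_network(adj, labels = net$labels)
  attr(out, "n_swaps") <- n_swaps
  out
}

#' Reverse a fraction of unidirectional projections
#'
#' The directionality null model: a uniformly random subset of exactly
#' `round(fraction * U)` of the network's `U` unidirectional edges is
#' replaced by the opposite-direction edge. Reciprocal (bidirectional) pairs
#' are untouched, so the edge count, the number of reciprocal pairs, and the
#' number of unidirectional edges are all preserved. `fraction = 1` is an
#' involution: applying it twice restores the original network.
#'
#' @param net A `directed_network`.
#' @param fraction Real in `[0, 1]`. The study design uses
#'   `0.2, 0.4, 0.6, 0.8, 1.0`; arbitrary fractions are allowed.
#' @param seed Integer seed (the subset draw is the only randomness;
#'   irrelevant at fractions 0 and 1). `NULL` uses the session RNG.
#' @return A `directed_network`.
#' @examples
#' chain <- walkthrough_fixture()$network
#' reverse_fraction(chain, 1)  # both one-way pathways flipped
#' @export
reverse_fraction <- function(net, fraction, seed = NULL) {
  stopifnot(inherits(net, "directed_network"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction > 1) {
    abort("`fraction` must be a single number in [0, 1].")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  a <- net$adjacency
  uni <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  u_count <- nrow(uni)
  n_flip <- round_half_up(fraction * u_count)
  if (n_flip > 0) {
    sel <- if (n_flip == u_count) seq_len(u_count) else
      sample.int(u_count, n_flip, replace = FALSE)
    a[uni[sel, , drop = FALSE]] <- 0L
    a[uni[sel, c(2, 1), drop = FALSE]] <- 1L
  }
  directed_network(a, labels = net$labels)
}

# round() in R rounds half to even; the subset size uses half-up
round_half_up <- function(x) floor(x + 0.5)

#' Generate an ensemble of surrogate networks
#'
#' Repeatedly applies one null model with seeds derived deterministically
#' from `seed`, rejecting (and redrawing, up to `max_retries` extra seeds
#' per slot) surrogates containing a node with out-degree 0, which the
#' traffic simulation cannot route from. Whether surrogate ensembles should
#' enforce connectedness is an open design choice; this retry policy is
#' recorded in the returned attributes.
#'
#' @param net A `directed_network`.
#' @param n Number of surrogates.
#' @param kind `"rewired"` (degree-preserving switching) or `"reversed"`
#'   (directional reversal).
#' @param fraction Reversal fraction, `kind = "reversed"` only.
#' @param n_attempts Swap attempt budget, `kind = "rewired"` only.
#' @param seed Integer seed for the whole ensemble.
#' @param max_retries Extra seeds tried per slot before giving up.
#' @return A list of `directed_network`s with attributes `seeds` (the seed
#'   actually used per surrogate) and `kind`.
#' @export
surrogate_ensemble <- function(net, n, kind = c("rewired", "reversed"),
                               fraction = 1, n_attempts = NULL, seed = 1L,
                               max_retries = 20L) {
  kind <- match.arg(kind)
  out <- vector("list", n)
  seeds <- integer(n)
  for (i in seq_len(n)) {
    made <- FALSE
    for (try in 0:max_retries) {
      s <- derive_seed(seed, paste0(kind, "_", i, "_", try))
      cand <- if (kind == "rewired") {
        rewire_degree_preserving(net, n_attempts = n_attempts, seed = s)
      } else {
        reverse_fraction(net, fraction, seed = s)
      }
      if (all(rowSums(cand$adjacency) >= 1L)) {
        out[[i]] <- cand; seeds[i] <- s; made <- TRUE
        break
      }
    }
    if (!made) {
      abort(sprintf(
        "Could not generate surrogate %d with out-degree >= 1 everywhere after %d retries.",
        i, max_retries))
    }
  }
  attr(out, "seeds") <- seeds
  attr(out, "kind") <- kind
  out
}

# deterministic 31-bit seed derived from a base seed and a stage name
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(paste0(stage, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}
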