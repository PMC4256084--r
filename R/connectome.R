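#' Synthetic macaque-like connectome stand-in
#'
#' A synthetic 242-node, 4090-edge directed network reproducing the
#' structural facts reported for the CoCoMac-derived macaque matrix, for
#' use when the real supplementary dataset is not at hand. It is a
#' stand-in, not the anatomical network: only the features listed below are
#' matched, everything else is random.
#'
#' Construction, fully determined by `seed`:
#' * 242 uniquely labelled nodes including `CA1`, the parahippocampal
#'   relays `TFM` and `TFL`, and prosubiculum `PROS`;
#' * `TFM` has in-degree 34 and out-degree 1 (its sole efferent is `CA1`);
#'   `TFL` has in-degree 41 and out-degree 2 (efferents `CA1` and `PROS`) —
#'   the degree imbalance that funnels traffic into CA1;
#' * a rich club of `n_hubs` hub areas whose attachment propensity is
#'   `hub_weight`-fold the background, giving hub degrees in the 60-90
#'   range typical of collated macaque matrices, and leaving CA1 itself
#'   with unremarkable degree;
#' * every node has out-degree >= 1; the total edge count is exactly 4090.
#'
#' @param seed Integer seed.
#' @param n_hubs Number of rich-club hub nodes (labelled `HUB01`, ...).
#' @param hub_weight Attachment propensity multiplier for hubs.
#' @return A `directed_network` with attribute `roles` (a tibble of the
#'   special node labels).
#' @export
synthetic_connectome <- function(seed = 1L, n_hubs = 8L, hub_weight = 5) {
  N <- 242L
  E_target <- 4090L
  hubs <- sprintf("HUB%02d", seq_len(n_hubs))
  labels <- c("CA1", "TFM", "TFL", "PROS", hubs,
              sprintf("R%03d", seq_len(N - 4L - n_hubs)))
  build <- function() {
    adj <- matrix(0L, N, N, dimnames = list(labels, labels))
    relays <- c("TFM", "TFL")
    rel_idx <- match(relays, labels)
    ca1 <- match("CA1", labels)
    pros <- match("PROS", labels)
    hub_idx <- match(hubs, labels)

    # relay efferents: the funnel
    adj["TFM", "CA1"] <- 1L
    adj["TFL", "CA1"] <- 1L
    adj["TFL", "PROS"] <- 1L

    # relay afferents from distinct non-relay, non-CA1 areas
    pool <- setdiff(seq_len(N), c(rel_idx, ca1))
    adj[sample_from(pool, 34L), "TFM"] <- 1L
    adj[sample_from(pool, 41L), "TFL"] <- 1L

    # every remaining node gets one out-edge so the network is routable
    others <- setdiff(seq_len(N), rel_idx)
    w <- rep(1, N)
    w[hub_idx] <- hub_weight
    for (u in others) {
      cand <- setdiff(seq_len(N), c(u, rel_idx))
      v <- cand[sample.int(length(cand), 1L, prob = w[cand])]
      adj[u, v] <- 1L
    }

    # fill to the exact edge count with weighted attachment (rich club):
    # both endpoints hub-weighted, relays excluded so their degrees stay put
    while (sum(adj) < E_target) {
      need <- E_target - sum(adj)
      us <- others[sample.int(length(others), 2L * need, replace = TRUE,
                              prob = w[others])]
      vs <- others[sample.int(length(others), 2L * need, replace = TRUE,
                              prob = w[others])]
      ok <- us != vs
      adj[cbind(us[ok], vs[ok])] <- 1L
      if (sum(adj) > E_target) {
        # drop surplus among the newest candidates deterministically:
        # remove random non-relay edges that are not funnel edges
        excess <- sum(adj) - E_target
        cand <- which(adj == 1L, arr.ind = TRUE)
        keep_safe <- !(cand[, 1] %in% rel_idx) & !(cand[, 2] %in% rel_idx)
        # never orphan a node's last out-edge
        kout <- rowSums(adj)
        removable <- which(keep_safe & kout[cand[, 1]] > 1L)
        drop <- sample_from(removable, excess)
        adj[cand[drop, , drop = FALSE]] <- 0L
      }
    }
    adj
  }
  adj <- withr::with_seed(seed, build())
  out <- directed_network(adj, labels = labels)
  attr(out, "roles") <- tibble::tibble(
    node = c("CA1", "TFM", "TFL", "PROS", hubs),
    role = c("target", "relay", "relay", "relay_secondary",
             rep("hub", n_hubs)))
  attr(out, "synthetic") <- TRUE
  out
}
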