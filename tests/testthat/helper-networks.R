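# Shared fixtures and independent brute-force oracles. The oracles work
# directly on edge lists / degree vectors, never through the package's
# matrix representation, so measure tests are genuine dual-route checks.

# One woman, two men; m1<->w1 mutual, m2 -> w1.
net_a <- function() {
  nodes <- data.frame(user_id = c("w1", "m1", "m2"),
                      gender = c("F", "M", "M"))
  edges <- data.frame(sender_id = c("m1", "m2", "w1"),
                      receiver_id = c("w1", "w1", "m1"))
  swipe_network(edges, nodes)
}

# Two women, two men; ties m1->w1, m2->w1, w1->m1, w2->m1.
net_b <- function() {
  nodes <- data.frame(user_id = c("w1", "w2", "m1", "m2"),
                      gender = c("F", "F", "M", "M"))
  edges <- data.frame(sender_id = c("m1", "m2", "w1", "w2"),
                      receiver_id = c("w1", "w1", "m1", "m1"))
  swipe_network(edges, nodes)
}

# Random bipartite network built through the public constructor from a
# Bernoulli(p) edge list.
rand_net <- function(n_women, n_men, p, seed) {
  set.seed(seed)
  women <- paste0("w", seq_len(n_women))
  men <- paste0("m", seq_len(n_men))
  pairs <- expand.grid(w = women, m = men, stringsAsFactors = FALSE)
  f <- runif(nrow(pairs)) < p   # woman -> man
  m <- runif(nrow(pairs)) < p   # man -> woman
  edges <- rbind(
    data.frame(sender_id = pairs$w[f], receiver_id = pairs$m[f]),
    data.frame(sender_id = pairs$m[m], receiver_id = pairs$w[m])
  )
  nodes <- data.frame(user_id = c(women, men),
                      gender = rep(c("F", "M"), c(n_women, n_men)))
  swipe_network(edges, nodes)
}

# --- brute-force oracles on raw edge lists -------------------------------

edge_list_of <- function(net) {
  ef <- which(net$M_F == 1L, arr.ind = TRUE)
  em <- which(net$M_M == 1L, arr.ind = TRUE)
  rbind(
    data.frame(sender = net$women[ef[, 1]], receiver = net$men[ef[, 2]],
               stringsAsFactors = FALSE),
    data.frame(sender = net$men[em[, 1]], receiver = net$women[em[, 2]],
               stringsAsFactors = FALSE)
  )
}

bf_indegree <- function(edges, ids) {
  vapply(ids, function(i) sum(edges$receiver == i), numeric(1))
}

bf_outdegree <- function(edges, ids) {
  vapply(ids, function(i) sum(edges$sender == i), numeric(1))
}

bf_density <- function(edges, n_women, n_men) {
  nrow(edges) / (2 * n_women * n_men)
}

bf_reciprocity <- function(edges) {
  key <- paste(edges$sender, edges$receiver)
  rev_key <- paste(edges$receiver, edges$sender)
  mean(rev_key %in% key)  # fraction of ties whose reverse exists
}

bf_centralization <- function(indeg, n_opp) {
  sum(max(indeg) - indeg) / ((length(indeg) - 1) * n_opp)
}

# Mean sender-minus-receiver standardized indegree over the ties sent by
# `senders`, computed tie by tie.
bf_tie_gap <- function(edges, senders, std_in) {
  sub <- edges[edges$sender %in% senders, , drop = FALSE]
  mean(std_in[sub$sender] - std_in[sub$receiver])
}

# --- exhaustive CUG enumeration oracle -----------------------------------

# All equally likely outcomes of independently permuting the entries of
# each row: per row, every position-subset of its ones is equally
# probable, so the joint distribution is uniform over the cartesian
# product of per-row subsets. Returns the statistic evaluated (via
# `stat_fn(M_F, M_M)`) at every outcome.
enumerate_cug <- function(net, stat_fn) {
  row_subsets <- function(M) {
    lapply(seq_len(nrow(M)), function(i) {
      k <- sum(M[i, ])
      if (k == 0L || k == ncol(M)) list(which(M[i, ] == 1L))
      else {
        cs <- utils::combn(ncol(M), k)
        lapply(seq_len(ncol(cs)), function(j) cs[, j])
      }
    })
  }
  subs <- c(row_subsets(net$M_F), row_subsets(net$M_M))
  nf <- nrow(net$M_F)
  counts <- vapply(subs, length, integer(1))
  grid <- do.call(expand.grid, lapply(counts, seq_len))
  apply(grid, 1, function(choice) {
    MF <- matrix(0L, nrow(net$M_F), ncol(net$M_F),
                 dimnames = dimnames(net$M_F))
    MM <- matrix(0L, nrow(net$M_M), ncol(net$M_M),
                 dimnames = dimnames(net$M_M))
    for (i in seq_len(nf)) MF[i, subs[[i]][[choice[i]]]] <- 1L
    for (i in seq_len(nrow(net$M_M))) {
      MM[i, subs[[nf + i]][[choice[nf + i]]]] <- 1L
    }
    stat_fn(MF, MM)
  })
}

# Brute-force men->women tie gap straight from a pair of matrices,
# iterating over individual ties (independent of the package's
# vectorised path).
bf_gap_mw_from_matrices <- function(MF, MM) {
  n_w <- ncol(MM); n_m <- nrow(MM)
  std_m <- colSums(MF) / n_w
  std_w <- colSums(MM) / n_m
  total <- 0; ties <- 0
  for (i in seq_len(n_m)) for (j in seq_len(n_w)) {
    if (MM[i, j] == 1L) {
      total <- total + (std_m[i] - std_w[j])
      ties <- ties + 1
    }
  }
  total / ties
}

# Map each sampled value onto the nearest enumerated support point;
# errors if anything falls farther than `tol` from the support.
match_to_support <- function(x, support, tol = 1e-9) {
  idx <- vapply(x, function(v) which.min(abs(support - v)), integer(1))
  stopifnot(all(abs(support[idx] - x) < tol))
  idx
}
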