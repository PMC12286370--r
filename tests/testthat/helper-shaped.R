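# Build a market with exact node counts and an exact total tie count,
# ties placed uniformly at random over the 2 * n_w * n_m possible
# directed cells. Used to reconstruct published-scale networks from
# printed user/swipe counts.
shaped_market <- function(n_women, n_men, n_ties, seed) {
  stopifnot(n_ties <= 2 * n_women * n_men)
  set.seed(seed)
  women <- sprintf("w%04d", seq_len(n_women))
  men <- sprintf("m%04d", seq_len(n_men))
  cells <- sample.int(2 * n_women * n_men, n_ties)
  half <- n_women * n_men
  is_f <- cells <= half                 # woman -> man cells
  fidx <- cells[is_f] - 1L
  midx <- cells[!is_f] - half - 1L
  edges <- rbind(
    data.frame(sender_id = women[fidx %% n_women + 1L],
               receiver_id = men[fidx %/% n_women + 1L]),
    data.frame(sender_id = men[midx %% n_men + 1L],
               receiver_id = women[midx %/% n_men + 1L])
  )
  nodes <- data.frame(user_id = c(women, men),
                      gender = rep(c("F", "M"), c(n_women, n_men)))
  swipe_network(edges, nodes)
}

# Network whose female indegree sequence has a prescribed maximum and
# total: woman 1 receives `max_in` swipes, the rest share the remainder
# as evenly as possible. Only the male sender matrix is populated.
shaped_indegree_net <- function(n_women, n_men, max_in, total_in) {
  rest <- total_in - max_in
  base <- rest %/% (n_women - 1L)
  extra <- rest %% (n_women - 1L)
  deg <- c(max_in, rep(base + 1L, extra),
           rep(base, n_women - 1L - extra))
  stopifnot(sum(deg) == total_in, all(deg <= n_men), max(deg) == max_in)
  women <- sprintf("w%04d", seq_len(n_women))
  men <- sprintf("m%04d", seq_len(n_men))
  edges <- do.call(rbind, lapply(seq_len(n_women), function(j) {
    if (deg[j] == 0L) return(NULL)
    data.frame(sender_id = men[seq_len(deg[j])], receiver_id = women[j])
  }))
  nodes <- data.frame(user_id = c(women, men),
                      gender = rep(c("F", "M"), c(n_women, n_men)))
  swipe_network(edges, nodes)
}
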