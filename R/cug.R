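#' Permute the entries within each row of a matrix
#'
#' The randomization step of the conditional uniform graph (CUG) null
#' model for directed two-mode networks: each row of an incidence matrix
#' independently receives a uniformly random permutation of its entries.
#' This is equivalent to each sender re-choosing their receivers
#' uniformly at random without replacement. Row sums (outdegrees) are
#' preserved exactly, so the null conditions on network size and the
#' outdegree distribution (and hence density); column sums (indegrees)
#' generally change.
#'
#' Uses the current RNG state; seed it (e.g. via \code{set.seed()} or
#' the \code{seed} argument of \code{\link{cug_test}}) for
#' reproducibility.
#'
#' @param m a matrix (binary in normal use, though any values work).
#' @return a matrix of the same dimension with each row independently
#'   shuffled.
#' @export
permute_rows <- function(m) {
  nc <- ncol(m)
  if (nc < 2L || nrow(m) == 0L) return(m)
  out <- m
  for (i in seq_len(nrow(m))) {
    out[i, ] <- m[i, sample.int(nc)]
  }
  out
}

#' Tie-level desirability gap
#'
#' For every tie sent by one mode, the difference between the sender's
#' and the receiver's standardized indegree (desirability). The
#' statistic is the mean of these differences over all ties in the
#' direction; a negative value means senders pursue receivers more
#' desirable than themselves (aspirational pursuit), a positive value
#' means they pursue less desirable receivers.
#'
#' With \code{weighted = TRUE} each tie is weighted by the reciprocal of
#' its sender's outdegree, so that every active sender contributes total
#' weight 1 and swipes from highly active users count less — a
#' sensitivity variant guarding against a handful of indiscriminate
#' swipers driving the mean. Weighted and unweighted versions coincide
#' when all active senders have equal outdegree.
#'
#' @param net a \code{swipe_network}.
#' @param direction \code{"men_to_women"} (ties in \code{M_M}) or
#'   \code{"women_to_men"} (ties in \code{M_F}).
#' @param weighted logical; outdegree-weighted variant.
#' @return mean sender-minus-receiver standardized-indegree difference.
#' @export
tie_gap <- function(net, direction = c("men_to_women", "women_to_men"),
                    weighted = FALSE) {
  stopifnot(inherits(net, "swipe_network"))
  direction <- match.arg(direction)
  if (direction == "men_to_women") {
    S <- net$M_M
    a <- standardize_degrees(net, "men", "in")     # senders
    b <- standardize_degrees(net, "women", "in")   # receivers
  } else {
    S <- net$M_F
    a <- standardize_degrees(net, "women", "in")
    b <- standardize_degrees(net, "men", "in")
  }
  k <- rowSums(S)
  total <- sum(k)
  if (total == 0) {
    stop("tie gap undefined: no ties in direction ", direction,
         call. = FALSE)
  }
  recv_sum <- as.numeric(S %*% b)  # per sender: sum of receiver indegrees
  if (!weighted) {
    (sum(k * a) - sum(recv_sum)) / total
  } else {
    active <- k > 0
    mean(a[active] - recv_sum[active] / k[active])
  }
}

#' Desirability gap over reciprocated ties only
#'
#' Restricts the desirability comparison to matches (mutually
#' reciprocated pairs) and computes the mean difference in standardized
#' indegree from the male point of view: man's minus woman's. Since
#' reciprocated ties are mutual, the sign carries no directional
#' meaning; the magnitude measures how (dis)similar matched partners are
#' in desirability. Standardized indegrees are computed on the full
#' network; only the averaging is restricted to matched pairs.
#'
#' @param net a \code{swipe_network} with at least one reciprocated pair.
#' @return mean over matched pairs of (man's - woman's) standardized
#'   indegree.
#' @export
reciprocal_gap <- function(net) {
  stopifnot(inherits(net, "swipe_network"))
  R <- reciprocal_matrix(net)  # women x men
  n_pairs <- sum(R)
  if (n_pairs == 0L) {
    stop("reciprocal gap undefined: no reciprocated pairs", call. = FALSE)
  }
  sw <- standardize_degrees(net, "women", "in")
  sm <- standardize_degrees(net, "men", "in")
  (sum(colSums(R) * sm) - sum(rowSums(R) * sw)) / n_pairs
}

#' Empirical p-values from a simulated null distribution
#'
#' Two one-sided empirical p-values: the proportions of simulated values
#' less-or-equal and greater-or-equal to the observed value. Values
#' exactly equal to the observed statistic count on both sides, so
#' \eqn{\Pr(\le obs) + \Pr(\ge obs) \ge 1}. No small-sample
#' \eqn{(+1)/(n+1)} correction is applied, so a statistic more extreme
#' than every simulated value reports an exact 0 on one side.
#' \code{NA} simulated values (replicates on which the statistic was
#' undefined) are dropped from the denominator.
#'
#' @param observed observed statistic (scalar).
#' @param simulated numeric vector of simulated statistic values.
#' @return named numeric vector \code{c(p_le = , p_ge = )}.
#' @export
empirical_pvalues <- function(observed, simulated) {
  simulated <- simulated[!is.na(simulated)]
  if (length(simulated) == 0L) {
    stop("no simulated values to compare against", call. = FALSE)
  }
  c(p_le = mean(simulated <= observed),
    p_ge = mean(simulated >= observed))
}

# Registry of CUG-testable statistics. Each entry computes a scalar from
# a network; statistics undefined on a given replicate signal an error
# that cug_test records as a missing replicate.
cug_statistics <- function() {
  list(
    gap_mw = function(net, weighted)
      tie_gap(net, "men_to_women", weighted = weighted),
    gap_wm = function(net, weighted)
      tie_gap(net, "women_to_men", weighted = weighted),
    reciprocal = function(net, weighted) reciprocal_gap(net),
    reciprocity = function(net, weighted) reciprocity(net),
    centralization_women = function(net, weighted)
      indegree_centralization(net, "women"),
    centralization_men = function(net, weighted)
      indegree_centralization(net, "men"),
    density = function(net, weighted) network_density(net),
    total_ties = function(net, weighted) n_ties(net)
  )
}

#' Conditional uniform graph test for directed two-mode networks
#'
#' Compares an observed network statistic with its distribution over
#' random networks conditioned on size and outdegree sequence. Each of
#' the \code{n_sims} replicates independently permutes the entries
#' within every row of \emph{both} sender matrices \code{M_F} and
#' \code{M_M} (see \code{\link{permute_rows}}), recomputes the statistic
#' on the permuted network (indegrees, and hence standardized
#' desirabilities, are recomputed from the permuted matrices), and the
#' empirical p-values \eqn{\Pr(\le obs)} and \eqn{\Pr(\ge obs)} are the
#' proportions of simulated values at least as small/large as the
#' observed one (\code{\link{empirical_pvalues}}).
#'
#' Replicates on which the statistic is undefined (e.g. a permuted
#' network with no reciprocated pair for \code{statistic =
#' "reciprocal"}) are recorded as missing, excluded from the p-value
#' denominator, and counted in \code{n_missing}.
#'
#' @param net a \code{swipe_network}.
#' @param statistic one of \code{"gap_mw"}, \code{"gap_wm"},
#'   \code{"reciprocal"}, \code{"reciprocity"},
#'   \code{"centralization_women"}, \code{"centralization_men"},
#'   \code{"density"}, \code{"total_ties"}.
#' @param n_sims number of permutation replicates (default 1,000).
#' @param seed integer seed; required.
#' @param weighted outdegree-weighted variant (gap statistics only).
#' @return an object of class \code{cug_result}: list with
#'   \code{statistic}, \code{weighted}, \code{observed}, \code{sim}
#'   (full simulated vector, \code{NA} for missing replicates),
#'   \code{sim_mean}, \code{sim_sd}, \code{p_le}, \code{p_ge},
#'   \code{n_sims}, \code{n_missing}, \code{seed}.
#' @examples
#' cfg <- market_preset("null", seed = 7)
#' net <- generate_market(cfg)$network
#' cug_test(net, "gap_mw", n_sims = 50, seed = 42)
#' @export
cug_test <- function(net, statistic, n_sims = 1000L, seed,
                     weighted = FALSE) {
  stopifnot(inherits(net, "swipe_network"))
  if (missing(seed)) {
    stop("`seed` is required: CUG tests must be reproducible",
         call. = FALSE)
  }
  stats_reg <- cug_statistics()
  if (!statistic %in% names(stats_reg)) {
    stop("unknown statistic '", statistic, "'; available: ",
         paste(names(stats_reg), collapse = ", "), call. = FALSE)
  }
  if (n_sims < 1L) stop("`n_sims` must be >= 1", call. = FALSE)
  fn <- stats_reg[[statistic]]
  observed <- fn(net, weighted)

  out_f <- rowSums(net$M_F)
  out_m <- rowSums(net$M_M)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sims), function(b) {
      pf <- permute_rows(net$M_F)
      pm <- permute_rows(net$M_M)
      # the null must hold outdegrees fixed; guard against regressions
      stopifnot(all(rowSums(pf) == out_f), all(rowSums(pm) == out_m))
      pnet <- new_swipe_network(net$women, net$men, pf, pm,
                                attrs = net$attrs, validate = FALSE)
      tryCatch(fn(pnet, weighted), error = function(e) NA_real_)
    }, numeric(1))
  })
  p <- empirical_pvalues(observed, sims)
  ok <- !is.na(sims)
  structure(
    list(statistic = statistic, weighted = isTRUE(weighted),
         observed = observed, sim = sims,
         sim_mean = mean(sims[ok]), sim_sd = stats::sd(sims[ok]),
         p_le = unname(p["p_le"]), p_ge = unname(p["p_ge"]),
         n_sims = as.integer(n_sims), n_missing = sum(!ok),
         seed = as.integer(seed)),
    class = "cug_result"
  )
}

#' @export
print.cug_result <- function(x, ...) {
  cat("Conditional uniform graph test\n")
  cat("  statistic: ", x$statistic,
      if (x$weighted) " (outdegree-weighted)", "\n", sep = "")
  cat(sprintf("  observed %.4f   sim. mean %.4f   sim. SD %.4g\n",
              x$observed, x$sim_mean, x$sim_sd))
  cat(sprintf("  Pr(<=obs) %.3f   Pr(>=obs) %.3f   (%d replicates",
              x$p_le, x$p_ge, x$n_sims))
  if (x$n_missing > 0L) cat(", ", x$n_missing, " missing", sep = "")
  cat(")\n")
  invisible(x)
}
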