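#' Degree vectors of a directed two-mode network
#'
#' Indegree counts the swipes a user received (the package's operational
#' measure of desirability); outdegree counts the swipes a user sent
#' (activity). With the dual incidence-matrix representation, the
#' indegree of women is the column sums of the male sender matrix
#' \code{M_M} and their outdegree the row sums of the female sender
#' matrix \code{M_F}; analogously for men. Isolates are included with
#' degree 0.
#'
#' @param net a \code{swipe_network}.
#' @param mode \code{"women"} or \code{"men"}.
#' @param direction \code{"in"} (received) or \code{"out"} (sent).
#' @return named numeric vector of counts, one entry per node id of the
#'   mode.
#' @export
degrees <- function(net, mode = c("women", "men"),
                    direction = c("in", "out")) {
  stopifnot(inherits(net, "swipe_network"))
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  v <- switch(paste(mode, direction),
    "women in"  = colSums(net$M_M),
    "women out" = rowSums(net$M_F),
    "men in"    = colSums(net$M_F),
    "men out"   = rowSums(net$M_M)
  )
  # colSums on a 0-column matrix returns numeric(0) without names
  ids <- if (mode == "women") net$women else net$men
  stats::setNames(as.numeric(v), ids)
}

#' Standardized degrees
#'
#' Because the two modes differ in size, raw degrees of women and men are
#' not comparable. Degrees are standardized by the maximum possible,
#' i.e. divided by the number of users of the opposite gender, giving
#' values in \eqn{[0, 1]}: a woman with standardized indegree 0.5
#' received swipes from exactly half of the male users.
#'
#' @inheritParams degrees
#' @return named numeric vector of proportions in \eqn{[0, 1]}.
#' @export
standardize_degrees <- function(net, mode = c("women", "men"),
                                direction = c("in", "out")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  opp <- if (mode == "women") length(net$men) else length(net$women)
  if (opp == 0L) {
    stop("standardized degree undefined: opposite mode is empty",
         call. = FALSE)
  }
  degrees(net, mode, direction) / opp
}

#' Summarise a degree distribution
#'
#' Computes the distribution summary used to characterise hierarchy on
#' the market: mean, standard deviation, median, skewness
#' (moment-based \eqn{g_1}), maximum and total, over all nodes of the
#' mode including isolates. A large SD relative to the mean together
#' with strong positive skewness indicates that swipes concentrate on a
#' few highly desirable users.
#'
#' @inheritParams degrees
#' @param mode \code{"women"}, \code{"men"}, or \code{"all"} (both modes
#'   pooled, as in whole-network degree averages).
#' @param standardized if \code{TRUE}, summarise degrees standardized by
#'   opposite-mode size.
#' @return a one-row data frame with columns \code{mode},
#'   \code{direction}, \code{standardized}, \code{n}, \code{mean},
#'   \code{sd}, \code{median}, \code{skewness}, \code{max}, \code{total}.
#' @export
degree_summary <- function(net, mode = c("all", "women", "men"),
                           direction = c("in", "out"),
                           standardized = FALSE) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  get1 <- function(m) {
    if (standardized) standardize_degrees(net, m, direction)
    else degrees(net, m, direction)
  }
  v <- switch(mode,
    all = c(get1("women"), get1("men")),
    women = get1("women"),
    men = get1("men")
  )
  n <- length(v)
  data.frame(
    mode = mode, direction = direction, standardized = standardized,
    n = n,
    mean = if (n) mean(v) else NA_real_,
    sd = if (n > 1L) stats::sd(v) else if (n == 1L) 0 else NA_real_,
    median = if (n) stats::median(v) else NA_real_,
    skewness = skewness_g1(v),
    max = if (n) max(v) else NA_real_,
    total = sum(v),
    stringsAsFactors = FALSE
  )
}

#' Density of a directed two-mode network
#'
#' The ratio of observed ties to all possible ties. In a directed
#' two-mode network every woman-man pair can carry up to two ties (one
#' per direction), so
#' \deqn{Density = \frac{\Sigma M_F + \Sigma M_M}{n_W \cdot n_M \cdot 2}.}
#' A density of 0.1 means 10\% of all possible swipes are present.
#'
#' @param net a \code{swipe_network}.
#' @return proportion in \eqn{[0, 1]}.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "swipe_network"))
  nw <- length(net$women); nm <- length(net$men)
  if (nw == 0L || nm == 0L) {
    stop("density undefined: a mode is empty", call. = FALSE)
  }
  (sum(net$M_F) + sum(net$M_M)) / (nw * nm * 2)
}

#' Indegree centralization of one mode
#'
#' Freeman-style centralization adapted to one mode of a directed
#' two-mode network: the sum of differences between the most central
#' (highest-indegree) node of the mode and every other node, divided by
#' the same sum in the maximally centralized configuration. Because ties
#' come only from the opposite mode and are binary, the maximal
#' configuration is the bipartite in-star in which a single node
#' receives a tie from every opposite-mode node and the rest receive
#' none, giving denominator \eqn{(n_{mode} - 1) \cdot n_{opp}}
#' (\code{method = "star"}, the default).
#'
#' \code{method = "tie_preserving"} instead normalises by the most
#' centralized configuration with the \emph{same number of ties}: the
#' central node receives \eqn{c = \min(T, n_{opp})} ties and the
#' leftover \eqn{T - c} ties are spread elsewhere, giving denominator
#' \eqn{(n_{mode} - 1) c - (T - c)}. The two variants agree when the
#' mode's total indegree equals \eqn{n_{opp}}; the star variant is the
#' default because it has a fixed \eqn{[0, 1]} range independent of tie
#' volume.
#'
#' @param net a \code{swipe_network}.
#' @param mode \code{"women"} or \code{"men"}.
#' @param method \code{"star"} (bipartite in-star denominator) or
#'   \code{"tie_preserving"}.
#' @return proportion in \eqn{[0, 1]}; 0 when all indegrees of the mode
#'   are equal, 1 for a perfect bipartite in-star.
#' @export
indegree_centralization <- function(net, mode = c("women", "men"),
                                    method = c("star", "tie_preserving")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  n_mode <- if (mode == "women") length(net$women) else length(net$men)
  n_opp <- if (mode == "women") length(net$men) else length(net$women)
  if (n_mode < 2L) {
    stop("centralization undefined: mode has fewer than 2 nodes",
         call. = FALSE)
  }
  if (n_opp == 0L) {
    stop("centralization undefined: opposite mode is empty", call. = FALSE)
  }
  ind <- degrees(net, mode, "in")
  num <- sum(max(ind) - ind)
  den <- if (method == "star") {
    (n_mode - 1) * n_opp
  } else {
    tt <- sum(ind)
    cmax <- min(tt, n_opp)
    (n_mode - 1) * cmax - (tt - cmax)
  }
  if (den == 0) return(0)
  num / den
}

#' Reciprocity of a directed two-mode network
#'
#' The fraction of ties that are part of a match (have their counterpart
#' in the opposite direction):
#' \deqn{Reciprocity = \frac{2 \Sigma M_R}{\Sigma M_F + \Sigma M_M},}
#' where \eqn{M_R} is the reciprocal matrix (see
#' \code{\link{reciprocal_matrix}}). A value of 0.25 means a quarter of
#' all swipes lead to a match.
#'
#' @param net a \code{swipe_network}.
#' @return proportion in \eqn{[0, 1]}.
#' @export
reciprocity <- function(net) {
  stopifnot(inherits(net, "swipe_network"))
  total <- sum(net$M_F) + sum(net$M_M)
  if (total == 0L) stop("reciprocity undefined: network has no ties",
                        call. = FALSE)
  2 * sum(reciprocal_matrix(net)) / total
}

#' Pooled-SD Cohen's d from group summary statistics
#'
#' Standardized mean difference \eqn{d = (\bar x_1 - \bar x_2) / s_p}
#' with the pooled standard deviation weighted by \eqn{n - 1}:
#' \eqn{s_p^2 = ((n_1 - 1) s_1^2 + (n_2 - 1) s_2^2) / (n_1 + n_2 - 2)}.
#' Exported so that effect sizes can also be computed from published
#' summary tables (means, SDs and group sizes) without raw data.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return Cohen's d (group 1 minus group 2).
#' @export
cohens_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 + n2 < 3L) stop("need n1 + n2 > 2 for pooled SD", call. = FALSE)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("Cohen's d undefined: pooled SD is zero", call. = FALSE)
  (mean1 - mean2) / sp
}

#' Cross-mode desirability gap: Cohen's d and randomization test
#'
#' Compares the desirability (standardized indegree) of women and men.
#' The effect size is pooled-SD Cohen's d with the convention
#' \eqn{d = (\bar x_{women} - \bar x_{men}) / s_p}. Because the users
#' form the entire market rather than a sample, inference uses a
#' two-sample randomization test: gender labels are permuted over the
#' combined standardized-indegree vector and the two-sided p-value is
#' the proportion of permutations whose absolute difference in group
#' means is at least the observed one. Standardization is performed once
#' with the true group sizes before label permutation.
#'
#' @param net a \code{swipe_network} with both modes non-empty.
#' @param n_permutations number of label permutations (default 10,000).
#' @param seed integer seed; required for reproducibility.
#' @return an object of class \code{gender_gap_result}: list with
#'   \code{mean_women}, \code{mean_men}, \code{d}, \code{p_value},
#'   \code{n_permutations}, \code{seed}.
#' @export
gender_gap <- function(net, n_permutations = 10000L, seed) {
  stopifnot(inherits(net, "swipe_network"))
  if (missing(seed)) stop("`seed` is required for the randomization test",
                          call. = FALSE)
  if (length(net$women) == 0L || length(net$men) == 0L) {
    stop("gender gap undefined: a mode is empty", call. = FALSE)
  }
  xw <- standardize_degrees(net, "women", "in")
  xm <- standardize_degrees(net, "men", "in")
  nw <- length(xw); nm <- length(xm)
  # the randomization statistic is the raw mean difference, so the test
  # remains defined even when the pooled SD (and hence d) degenerates
  d <- tryCatch(
    cohens_d_pooled(mean(xw), stats::sd(xw), nw,
                    mean(xm), stats::sd(xm), nm),
    error = function(e) {
      warning("Cohen's d undefined (zero pooled SD); returning NA",
              call. = FALSE)
      NA_real_
    })
  pooled <- c(xw, xm)
  obs <- abs(mean(xw) - mean(xm))
  p <- with_seed(seed, {
    hits <- 0L
    n_tot <- nw + nm
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(n_tot, nw)
      diff_b <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
      if (diff_b >= obs) hits <- hits + 1L
    }
    hits / n_permutations
  })
  structure(
    list(mean_women = mean(xw), mean_men = mean(xm), d = d, p_value = p,
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed)),
    class = "gender_gap_result"
  )
}

#' @export
print.gender_gap_result <- function(x, ...) {
  cat("Cross-mode desirability gap (standardized indegree)\n")
  cat(sprintf("  mean women %.4f  mean men %.4f\n", x$mean_women, x$mean_men))
  cat(sprintf("  Cohen's d (women - men): %.3f\n", x$d))
  cat(sprintf("  randomization p (two-sided, %d permutations): %.4g\n",
              x$n_permutations, x$p_value))
  invisible(x)
}
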