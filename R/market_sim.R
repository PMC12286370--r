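#' Configuration of a synthetic two-sided swipe market
#'
#' Collects the generative parameters of the simulator
#' (\code{\link{generate_market}}):
#' \itemize{
#'   \item \strong{sizes}: \code{n_men}, \code{n_women}.
#'   \item \strong{activity}: each sender draws an intended outdegree
#'     from a negative-binomial law with per-mode \code{mean} and
#'     \code{dispersion} (the NB size parameter \eqn{\theta};
#'     \eqn{Var = \mu + \mu^2/\theta}, so smaller values give the
#'     right-skewed, over-dispersed activity seen on real apps;
#'     \code{Inf} gives Poisson). Draws are truncated to
#'     \eqn{[0, n_{opp}]}.
#'   \item \strong{desirability}: each node gets a latent desirability
#'     score; per mode, \code{location}/\code{scale} with
#'     \code{heavy_tail = TRUE} giving a lognormal law (meanlog/sdlog —
#'     a few extremely desirable users) and \code{FALSE} a normal law.
#'   \item \strong{aspiration}: per-sending-mode coefficient
#'     \eqn{\alpha}; receivers are chosen without replacement with
#'     probability proportional to \eqn{\exp(\alpha z)} of their latent
#'     score \eqn{z}. \eqn{\alpha = 0} is uniform choice;
#'     \eqn{\alpha > 0} biases swipes toward desirable receivers
#'     (aspirational pursuit).
#'   \item \strong{reciprocation}: a receiver of a first swipe
#'     reciprocates (adds the reverse tie, forming a match) with
#'     probability \eqn{logit^{-1}(\beta_0 + \beta_1 (z_{init} -
#'     z_{recv}))}. With \eqn{\beta_1 > 0} more desirable receivers are
#'     choosier: aspirational attempts at far more desirable partners
#'     tend to be rejected (the non-reciprocity mechanism).
#' }
#'
#' @param n_men,n_women mode sizes (\eqn{\ge 1}).
#' @param activity_men,activity_women lists \code{list(mean =,
#'   dispersion =)}.
#' @param desirability_men,desirability_women lists
#'   \code{list(location =, scale =, heavy_tail =)}.
#' @param aspiration_men,aspiration_women choice coefficients
#'   \eqn{\alpha}.
#' @param recip_intercept,recip_slope logistic reciprocation parameters
#'   \eqn{\beta_0, \beta_1}.
#' @param seed integer seed driving all randomness of the generator.
#' @return an object of class \code{market_config}.
#' @export
market_config <- function(n_men, n_women,
                          activity_men = list(mean = 9, dispersion = 1),
                          activity_women = list(mean = 6, dispersion = 1),
                          desirability_men =
                            list(location = 0, scale = 0.5,
                                 heavy_tail = FALSE),
                          desirability_women =
                            list(location = 0, scale = 1,
                                 heavy_tail = TRUE),
                          aspiration_men = 0,
                          aspiration_women = 0,
                          recip_intercept = -1,
                          recip_slope = 0,
                          seed = NULL) {
  cfg <- list(n_men = as.integer(n_men), n_women = as.integer(n_women),
              activity_men = activity_men, activity_women = activity_women,
              desirability_men = desirability_men,
              desirability_women = desirability_women,
              aspiration_men = aspiration_men,
              aspiration_women = aspiration_women,
              recip_intercept = recip_intercept,
              recip_slope = recip_slope,
              seed = if (!is.null(seed)) as.integer(seed))
  validate_market_config(cfg)
  structure(cfg, class = "market_config")
}

validate_market_config <- function(cfg) {
  stopifnot(cfg$n_men >= 1L, cfg$n_women >= 1L)
  for (side in c("activity_men", "activity_women")) {
    a <- cfg[[side]]
    if (!is.list(a) || is.null(a$mean) || is.null(a$dispersion) ||
        a$mean < 0 || a$dispersion <= 0) {
      stop(side, " must be list(mean >= 0, dispersion > 0)", call. = FALSE)
    }
  }
  for (side in c("desirability_men", "desirability_women")) {
    d <- cfg[[side]]
    if (!is.list(d) || is.null(d$location) || is.null(d$scale) ||
        d$scale < 0) {
      stop(side, " must be list(location, scale >= 0[, heavy_tail])",
           call. = FALSE)
    }
  }
  if (!is.finite(cfg$recip_slope)) {
    stop("recip_slope must be finite", call. = FALSE)
  }
  invisible(cfg)
}

#' Built-in market presets
#'
#' Named generator configurations shipped as JSON files under
#' \code{inst/extdata/presets/}. \code{"brno-like"} and
#' \code{"prague-like"} emulate mid-size and large city markets with a
#' skewed gender ratio (roughly 20--25\% women), over-dispersed
#' activity, heavy-tailed female desirability, positive male aspiration
#' and gap-dependent reciprocation; \code{"null"} is the no-mechanism
#' benchmark (uniform choice, no reciprocation), which coincides with
#' the CUG row-permutation null.
#'
#' @param name preset name: \code{"brno-like"}, \code{"prague-like"} or
#'   \code{"null"}.
#' @param seed optional integer seed stored in the config.
#' @return a \code{market_config}.
#' @export
market_preset <- function(name = c("brno-like", "prague-like", "null"),
                          seed = NULL) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets",
                      paste0(gsub("-", "_", name), ".json"),
                      package = "swipenet", mustWork = TRUE)
  cfg <- read_market_config(path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' @rdname market_preset
#' @param path path to a JSON market configuration file.
#' @export
read_market_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(market_config, raw)
}

# Latent desirability scores for one mode.
draw_scores <- function(n, model) {
  heavy <- isTRUE(model$heavy_tail)
  if (heavy) stats::rlnorm(n, meanlog = model$location, sdlog = model$scale)
  else stats::rnorm(n, mean = model$location, sd = model$scale)
}

# Intended outdegrees for one mode, truncated to the opposite-mode size.
draw_activity <- function(n, model, n_opp) {
  k <- if (is.infinite(model$dispersion)) {
    stats::rpois(n, lambda = model$mean)
  } else {
    stats::rnbinom(n, mu = model$mean, size = model$dispersion)
  }
  over <- k > n_opp
  if (any(over)) {
    warning(sum(over), " intended outdegree(s) exceeded the opposite-",
            "mode size and were truncated", call. = FALSE)
    k[over] <- n_opp
  }
  k
}

# First-swipe choice matrix for one sending mode: each sender with
# intended outdegree k picks k distinct receivers, probability
# proportional to exp(alpha * receiver score).
choose_receivers <- function(k, alpha, z_recv) {
  n_send <- length(k)
  n_recv <- length(z_recv)
  w <- exp(alpha * (z_recv - max(z_recv)))  # shift guards overflow
  M <- matrix(0L, n_send, n_recv)
  for (s in seq_len(n_send)) {
    if (k[s] > 0L) {
      M[s, sample.int(n_recv, k[s], prob = w)] <- 1L
    }
  }
  M
}

#' Generate a synthetic directed two-mode swipe market
#'
#' Simulates a swipe market in three stages: (1) draw latent
#' desirability scores and intended outdegrees per user; (2) every user
#' sends their first swipes, choosing receivers without replacement with
#' probability proportional to \eqn{\exp(\alpha z)} of the receiver's
#' desirability; (3) each first swipe whose reverse tie does not already
#' exist is reciprocated with logistic probability in the
#' initiator-minus-receiver desirability difference, adding the reverse
#' tie (a match). Identical seeds give identical markets.
#'
#' @param config a \code{\link{market_config}}.
#' @param seed optional integer overriding \code{config$seed}; one of
#'   the two must be set.
#' @return an object of class \code{synthetic_market}: list with
#'   \code{network} (a \code{swipe_network}), \code{scores} (list of
#'   named vectors \code{women}, \code{men} of latent desirabilities)
#'   and \code{config}.
#' @examples
#' mkt <- generate_market(market_preset("null"), seed = 1)
#' mkt$network
#' @export
generate_market <- function(config, seed = NULL) {
  stopifnot(inherits(config, "market_config"))
  seed <- seed %||% config$seed
  if (is.null(seed)) {
    stop("a seed is required: set config$seed or pass `seed`",
         call. = FALSE)
  }
  nw <- config$n_women; nm <- config$n_men
  women <- sprintf("w%0*d", nchar(nw), seq_len(nw))
  men <- sprintf("m%0*d", nchar(nm), seq_len(nm))

  res <- with_seed(seed, {
    z_w <- draw_scores(nw, config$desirability_women)
    z_m <- draw_scores(nm, config$desirability_men)
    k_w <- draw_activity(nw, config$activity_women, nm)
    k_m <- draw_activity(nm, config$activity_men, nw)

    # stage 2: first swipes
    M_F <- choose_receivers(k_w, config$aspiration_women, z_m)
    M_M <- choose_receivers(k_m, config$aspiration_men, z_w)

    # stage 3: responses. Decisions are based on the first-swipe
    # matrices only (pairs that already swiped each other are a match
    # with no decision left to make), so the outcome is order-free.
    p_recip <- function(z_init, z_recv) {
      stats::plogis(config$recip_intercept +
                      config$recip_slope * (z_init - z_recv))
    }
    # men's first swipes answered by women: add w -> m ties into M_F
    cand <- which(t(M_M) == 1L & M_F == 0L, arr.ind = TRUE)  # women x men
    if (nrow(cand)) {
      p <- p_recip(z_m[cand[, 2L]], z_w[cand[, 1L]])
      acc <- stats::runif(nrow(cand)) < p
      M_F[cand[acc, , drop = FALSE]] <- 1L
    }
    # women's first swipes answered by men: add m -> w ties into M_M
    cand <- which(t(M_F) == 1L & M_M == 0L, arr.ind = TRUE)  # men x women
    if (nrow(cand)) {
      p <- p_recip(z_w[cand[, 2L]], z_m[cand[, 1L]])
      acc <- stats::runif(nrow(cand)) < p
      M_M[cand[acc, , drop = FALSE]] <- 1L
    }
    list(M_F = M_F, M_M = M_M, z_w = z_w, z_m = z_m)
  })

  dimnames(res$M_F) <- list(women, men)
  dimnames(res$M_M) <- list(men, women)
  config$seed <- as.integer(seed)  # record the seed actually used
  net <- new_swipe_network(women, men, res$M_F, res$M_M)
  structure(
    list(network = net,
         scores = list(women = stats::setNames(res$z_w, women),
                       men = stats::setNames(res$z_m, men)),
         config = config),
    class = "synthetic_market"
  )
}

#' @export
print.synthetic_market <- function(x, ...) {
  cat("Synthetic swipe market (seed ",
      x$config$seed %||% "unset", ")\n", sep = "")
  print(x$network)
  invisible(x)
}

#' Mechanism-recovery experiment over an aspiration grid
#'
#' Validates that the tie-gap statistic and its CUG test recover the
#' aspiration mechanism from generated data: for each value of the male
#' aspiration coefficient \eqn{\alpha} in \code{alphas}, generates
#' \code{n_reps} markets, computes the men-to-women tie gap and its CUG
#' test, and reports the mean observed gap and the rejection rate
#' (share of replicates with \eqn{\Pr(\le obs) \le} \code{level}).
#' Under \eqn{\alpha = 0} with no reciprocation the generator coincides
#' with the CUG null, so the rejection rate should sit near the nominal
#' level; larger \eqn{\alpha} should yield more negative gaps and higher
#' rejection rates.
#'
#' @param alphas numeric grid of male aspiration coefficients.
#' @param config base \code{market_config} (its \code{aspiration_men}
#'   is overridden per grid point).
#' @param n_reps markets per grid point.
#' @param n_sims CUG replicates per market.
#' @param seed integer seed for the whole experiment.
#' @param level rejection threshold on \eqn{\Pr(\le obs)}
#'   (default 0.05).
#' @return data frame with columns \code{alpha}, \code{mean_gap},
#'   \code{rejection_rate}, \code{n_reps}.
#' @export
recover_mechanism <- function(alphas, config, n_reps = 10L,
                              n_sims = 200L, seed, level = 0.05) {
  stopifnot(inherits(config, "market_config"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rows <- lapply(seq_along(alphas), function(i) {
    cfg <- config
    cfg$aspiration_men <- alphas[i]
    gaps <- numeric(n_reps)
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      # distinct sub-seeds per (alpha, rep), kept within 32-bit range
      s <- (as.integer(seed) + 7919L * i + 104729L * r) %% 2147483647L
      mkt <- generate_market(cfg, seed = s)
      gaps[r] <- tie_gap(mkt$network, "men_to_women")
      ct <- cug_test(mkt$network, "gap_mw", n_sims = n_sims, seed = s + 1L)
      rej[r] <- ct$p_le <= level
    }
    data.frame(alpha = alphas[i], mean_gap = mean(gaps),
               rejection_rate = mean(rej), n_reps = n_reps)
  })
  do.call(rbind, rows)
}
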