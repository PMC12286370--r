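# Data-cleaning rules for raw swipe markets: active-user inclusion,
# indiscriminate-reciprocator (bot) filtering, and segmentation into
# per-city markets. Every filter returns both the filtered network and a
# filter_report so node accounting stays auditable.

new_filter_report <- function(rule, removed_ids, ties_removed, params) {
  structure(
    list(rule = rule,
         removed_ids = as.character(removed_ids),
         n_removed = length(removed_ids),
         ties_removed = as.integer(ties_removed),
         params = params),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter '", x$rule, "': removed ", x$n_removed, " node(s), ",
      x$ties_removed, " tie(s)\n", sep = "")
  if (x$n_removed > 0L && x$n_removed <= 20L) {
    cat("  ids:", paste(x$removed_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

# Rebuild a network keeping only the given ids (both matrices subset
# consistently; attributes follow).
subset_network <- function(net, keep_women, keep_men) {
  M_F <- net$M_F[keep_women, keep_men, drop = FALSE]
  M_M <- net$M_M[keep_men, keep_women, drop = FALSE]
  attrs <- net$attrs[net$attrs$user_id %in% c(keep_women, keep_men), ,
                     drop = FALSE]
  rownames(attrs) <- NULL
  new_swipe_network(keep_women, keep_men, M_F, M_M, attrs = attrs,
                    validate = FALSE)
}

#' Keep only active users
#'
#' Active users are those who sent or received at least one swipe;
#' nodes with total degree zero are dropped. No ties are removed.
#'
#' @param net a \code{swipe_network}.
#' @return list with elements \code{network} (filtered) and
#'   \code{report} (a \code{filter_report}).
#' @export
filter_active <- function(net) {
  stopifnot(inherits(net, "swipe_network"))
  deg_w <- degrees(net, "women", "in") + degrees(net, "women", "out")
  deg_m <- degrees(net, "men", "in") + degrees(net, "men", "out")
  keep_w <- net$women[deg_w > 0]
  keep_m <- net$men[deg_m > 0]
  removed <- c(net$women[deg_w == 0], net$men[deg_m == 0])
  list(
    network = subset_network(net, keep_w, keep_m),
    report = new_filter_report("active_users", removed, 0L, list())
  )
}

#' Filter suspected bots (indiscriminate reciprocators)
#'
#' Dating-app bots typically pose as attractive women and accept every
#' swipe they receive. The rule removes every target-mode node whose
#' indegree is at least \code{min_received} \emph{and} whose
#' reciprocation fraction (reverse ties back to in-neighbours divided by
#' indegree) is at least \code{accept_rate}, together with all their
#' incident ties. The indegree floor protects genuinely low-traffic
#' users who happened to accept their few swipes; high-indegree users
#' who do not accept everyone are kept — high desirability alone is not
#' evidence of automation.
#'
#' @param net a \code{swipe_network}.
#' @param min_received minimum indegree for the rule to apply
#'   (default 30; the boundary counts, "at least 30").
#' @param accept_rate minimum reciprocation fraction (default 1.0,
#'   i.e. accepted all).
#' @param target_mode mode screened for bots (default \code{"women"}).
#' @return list with elements \code{network} and \code{report}.
#' @export
filter_bots <- function(net, min_received = 30, accept_rate = 1.0,
                        target_mode = c("women", "men")) {
  stopifnot(inherits(net, "swipe_network"),
            min_received >= 0, accept_rate >= 0)
  target_mode <- match.arg(target_mode)
  if (target_mode == "women") {
    recv <- net$M_M            # men -> women, senders in rows
    back <- t(net$M_F)         # women's replies, men x women
    ids <- net$women
  } else {
    recv <- net$M_F
    back <- t(net$M_M)
    ids <- net$men
  }
  indeg <- colSums(recv)
  reciprocated <- colSums(recv * back)  # replies restricted to in-neighbours
  frac <- ifelse(indeg > 0, reciprocated / indeg, 0)
  is_bot <- indeg >= min_received & frac >= accept_rate
  bots <- ids[is_bot]
  keep_w <- setdiff(net$women, bots)
  keep_m <- setdiff(net$men, bots)
  sub <- subset_network(net, keep_w, keep_m)
  list(
    network = sub,
    report = new_filter_report(
      "bot_filter", bots, n_ties(net) - n_ties(sub),
      list(min_received = min_received, accept_rate = accept_rate,
           target_mode = target_mode))
  )
}

#' Split a network into per-attribute markets
#'
#' Each city (or other label) is treated as its own dating market:
#' users had a realistic chance to be shown to each other only within a
#' city. The network is partitioned by the node attribute; ties crossing
#' labels are dropped, with the dropped count reported via
#' \code{message()} and attached as attribute \code{"cross_ties_dropped"}
#' of the returned list.
#'
#' @param net a \code{swipe_network} whose \code{attrs} table has the
#'   attribute column filled for every node.
#' @param attribute attribute column name (default \code{"city"}).
#' @return named list of \code{swipe_network}, one per label.
#' @export
split_markets <- function(net, attribute = "city") {
  stopifnot(inherits(net, "swipe_network"))
  attrs <- net$attrs
  if (!attribute %in% names(attrs)) {
    stop("attribute '", attribute, "' not present in node table",
         call. = FALSE)
  }
  lab <- stats::setNames(as.character(attrs[[attribute]]), attrs$user_id)
  missing_ids <- names(lab)[is.na(lab) | lab == ""]
  if (length(missing_ids)) {
    stop("attribute '", attribute, "' missing for node(s): ",
         paste(utils::head(missing_ids, 10L), collapse = ", "),
         call. = FALSE)
  }
  labels <- sort(unique(lab))
  out <- lapply(labels, function(l) {
    subset_network(net,
                   net$women[lab[net$women] == l],
                   net$men[lab[net$men] == l])
  })
  names(out) <- labels
  dropped <- n_ties(net) - sum(vapply(out, n_ties, numeric(1)))
  if (dropped > 0) message("dropped ", dropped, " cross-market tie(s)")
  attr(out, "cross_ties_dropped") <- as.integer(dropped)
  out
}
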