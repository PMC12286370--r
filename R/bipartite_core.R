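#' Construct a directed two-mode swipe network
#'
#' Builds the dual incidence-matrix representation of a directed bipartite
#' network from an edge list and a node table. The two node classes
#' ("modes") are women and men; ties (swipes) run only across modes but
#' carry direction, so a single incidence matrix cannot hold both
#' directions. Instead the network stores a female sender matrix
#' \code{M_F} (\eqn{n_W \times n_M}, entry \eqn{a_{ij} = 1} iff woman
#' \eqn{i} swiped man \eqn{j}) and a male sender matrix \code{M_M}
#' (\eqn{n_M \times n_W}, defined analogously).
#'
#' Repeated identical edges are collapsed to a single binary tie; the
#' number of collapsed duplicates is recorded in the object (field
#' \code{duplicates_collapsed}) and reported via \code{message()}.
#' Nodes listed in \code{nodes} but absent from \code{edges} are kept as
#' isolates (all-zero rows/columns), so degree vectors include them as
#' zeros.
#'
#' @param edges data frame (or matrix) whose first two columns are
#'   \code{sender_id} and \code{receiver_id}. May have zero rows.
#' @param nodes data frame with columns \code{user_id} and \code{gender}
#'   (coded \code{"F"}/\code{"M"}), and optionally \code{age} and
#'   \code{city}.
#' @return An object of class \code{swipe_network}: a list with elements
#'   \code{women}, \code{men} (ordered id registries), \code{M_F},
#'   \code{M_M} (binary integer matrices with id dimnames), \code{attrs}
#'   (the node attribute table) and \code{duplicates_collapsed}.
#' @examples
#' nodes <- data.frame(user_id = c("w1", "m1", "m2"),
#'                     gender  = c("F", "M", "M"))
#' edges <- data.frame(sender_id   = c("m1", "m2", "w1"),
#'                     receiver_id = c("w1", "w1", "m1"))
#' net <- swipe_network(edges, nodes)
#' net
#' @export
swipe_network <- function(edges, nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) stop("node table is empty", call. = FALSE)
  if (!all(c("user_id", "gender") %in% names(nodes))) {
    stop("node table must have columns `user_id` and `gender`", call. = FALSE)
  }
  nodes$user_id <- as.character(nodes$user_id)
  nodes$gender <- as.character(nodes$gender)
  if (anyDuplicated(nodes$user_id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$user_id[duplicated(nodes$user_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_g <- setdiff(unique(nodes$gender), c("F", "M"))
  if (length(bad_g)) {
    stop("gender must be coded F/M; found: ", paste(bad_g, collapse = ", "),
         call. = FALSE)
  }
  women <- nodes$user_id[nodes$gender == "F"]
  men <- nodes$user_id[nodes$gender == "M"]

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) >= 2L) {
    snd <- as.character(edges[[1L]])
    rcv <- as.character(edges[[2L]])
  } else if (nrow(edges) == 0L) {
    snd <- rcv <- character()
  } else {
    stop("edge list must have two columns (sender, receiver)", call. = FALSE)
  }
  unknown <- setdiff(c(snd, rcv), nodes$user_id)
  if (length(unknown)) {
    stop("edge endpoints missing from node table: ",
         paste(utils::head(unknown, 10L), collapse = ", "), call. = FALSE)
  }
  gender_of <- stats::setNames(nodes$gender, nodes$user_id)
  same <- gender_of[snd] == gender_of[rcv]
  if (any(same)) {
    i <- which(same)[1L]
    stop("same-gender edge not allowed in a two-mode network: ",
         snd[i], " -> ", rcv[i], call. = FALSE)
  }

  key <- paste(snd, rcv, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0L) {
    message("collapsed ", n_dup, " duplicate edge(s) to binary ties")
    snd <- snd[!dup]
    rcv <- rcv[!dup]
  }

  M_F <- matrix(0L, length(women), length(men), dimnames = list(women, men))
  M_M <- matrix(0L, length(men), length(women), dimnames = list(men, women))
  from_f <- gender_of[snd] == "F"
  if (any(from_f)) M_F[cbind(snd[from_f], rcv[from_f])] <- 1L
  if (any(!from_f)) M_M[cbind(snd[!from_f], rcv[!from_f])] <- 1L

  new_swipe_network(women, men, M_F, M_M, attrs = nodes,
                    duplicates_collapsed = n_dup)
}

# Low-level constructor from prebuilt incidence matrices; checks the
# structural invariants but skips edge-list plumbing. Used by the
# simulator and the permutation machinery.
new_swipe_network <- function(women, men, M_F, M_M, attrs = NULL,
                              duplicates_collapsed = 0L, validate = TRUE) {
  if (validate) {
    stopifnot(
      nrow(M_F) == length(women), ncol(M_F) == length(men),
      nrow(M_M) == length(men), ncol(M_M) == length(women),
      all(M_F %in% c(0L, 1L)), all(M_M %in% c(0L, 1L)),
      !anyDuplicated(c(women, men))
    )
  }
  if (is.null(attrs)) {
    attrs <- data.frame(user_id = c(women, men),
                        gender = rep(c("F", "M"), c(length(women), length(men))),
                        stringsAsFactors = FALSE)
  }
  structure(
    list(women = women, men = men, M_F = M_F, M_M = M_M, attrs = attrs,
         duplicates_collapsed = as.integer(duplicates_collapsed)),
    class = "swipe_network"
  )
}

#' @export
print.swipe_network <- function(x, ...) {
  cat("Directed two-mode swipe network\n")
  cat("  women:", length(x$women), " men:", length(x$men), "\n")
  cat("  ties: ", sum(x$M_F) + sum(x$M_M),
      " (women->men: ", sum(x$M_F), ", men->women: ", sum(x$M_M), ")\n",
      sep = "")
  invisible(x)
}

#' Number of nodes and ties in a swipe network
#'
#' @param net a \code{swipe_network}.
#' @return \code{n_women()}, \code{n_men()}: integer counts.
#'   \code{n_ties()}: total number of directed cross-mode ties,
#'   \eqn{\Sigma M_F + \Sigma M_M}.
#' @export
n_women <- function(net) length(net$women)

#' @rdname n_women
#' @export
n_men <- function(net) length(net$men)

#' @rdname n_women
#' @export
n_ties <- function(net) sum(net$M_F) + sum(net$M_M)

#' Reciprocal (match) matrix of a directed two-mode network
#'
#' A match is a pair of users with ties in both directions. The
#' reciprocal matrix \code{M_R} is oriented like the female sender
#' matrix: entry \eqn{(i, j) = 1} iff woman \eqn{i} swiped man \eqn{j}
#' \emph{and} man \eqn{j} swiped woman \eqn{i}, i.e. the elementwise AND
#' of \code{M_F} and \code{t(M_M)}.
#'
#' @param net a \code{swipe_network}.
#' @return binary integer matrix, \code{n_women x n_men}.
#' @examples
#' nodes <- data.frame(user_id = c("w1", "m1"), gender = c("F", "M"))
#' edges <- data.frame(sender = c("w1", "m1"), receiver = c("m1", "w1"))
#' sum(reciprocal_matrix(swipe_network(edges, nodes)))  # one match
#' @export
reciprocal_matrix <- function(net) {
  stopifnot(inherits(net, "swipe_network"))
  r <- net$M_F * t(net$M_M)
  storage.mode(r) <- "integer"
  r
}

#' Serialize a swipe network to JSON / read it back
#'
#' The on-disk format is a single JSON document bundling the two node
#' registries, the node attribute table, and the two directed edge sets
#' (as sender/receiver id pairs). \code{read_network(write_network(net,
#' path))} reproduces the registries and both incidence matrices exactly,
#' including isolates.
#'
#' @param net a \code{swipe_network}.
#' @param path file path.
#' @return \code{write_network()} returns \code{path} invisibly;
#'   \code{read_network()} returns a \code{swipe_network}.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "swipe_network"))
  ef <- which(net$M_F == 1L, arr.ind = TRUE)
  em <- which(net$M_M == 1L, arr.ind = TRUE)
  doc <- list(
    format = "swipenet-network",
    version = 1L,
    women = as.character(net$women),
    men = as.character(net$men),
    attrs = net$attrs,
    edges_women_to_men = data.frame(
      sender_id = net$women[ef[, 1L]], receiver_id = net$men[ef[, 2L]],
      stringsAsFactors = FALSE),
    edges_men_to_women = data.frame(
      sender_id = net$men[em[, 1L]], receiver_id = net$women[em[, 2L]],
      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop("failed to parse network file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!identical(doc$format, "swipenet-network")) {
    stop("'", path, "' is not a swipenet network file", call. = FALSE)
  }
  women <- as.character(doc$women %||% character())
  men <- as.character(doc$men %||% character())
  as_edge_df <- function(x) {
    if (is.null(x) || length(x) == 0L || is.null(x$sender_id)) {
      data.frame(sender_id = character(), receiver_id = character(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sender_id = as.character(x$sender_id),
                 receiver_id = as.character(x$receiver_id),
                 stringsAsFactors = FALSE)
    }
  }
  ef <- as_edge_df(doc$edges_women_to_men)
  em <- as_edge_df(doc$edges_men_to_women)
  M_F <- matrix(0L, length(women), length(men), dimnames = list(women, men))
  M_M <- matrix(0L, length(men), length(women), dimnames = list(men, women))
  if (nrow(ef)) M_F[cbind(ef$sender_id, ef$receiver_id)] <- 1L
  if (nrow(em)) M_M[cbind(em$sender_id, em$receiver_id)] <- 1L
  attrs <- as.data.frame(doc$attrs, stringsAsFactors = FALSE)
  new_swipe_network(women, men, M_F, M_M, attrs = attrs)
}

#' Read edge and node CSV files
#'
#' Thin readers for the package's CSV interchange format: the edge file
#' has header \code{sender_id,receiver_id}; the node file has header
#' \code{user_id,gender[,age,city]} with gender coded \code{F}/\code{M}.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_edges_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("sender_id", "receiver_id") %in% names(df))) {
    stop("edge CSV must have header sender_id,receiver_id", call. = FALSE)
  }
  df
}

#' @rdname read_edges_csv
#' @export
read_nodes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("user_id", "gender") %in% names(df))) {
    stop("node CSV must have header user_id,gender[,age,city]", call. = FALSE)
  }
  df$user_id <- as.character(df$user_id)
  df
}

#' Write edge and node CSV files
#'
#' @param net a \code{swipe_network}.
#' @param edges_path,nodes_path output file paths.
#' @return invisibly, a list with the two paths.
#' @export
write_edge_lists <- function(net, edges_path, nodes_path) {
  ef <- which(net$M_F == 1L, arr.ind = TRUE)
  em <- which(net$M_M == 1L, arr.ind = TRUE)
  edges <- rbind(
    data.frame(sender_id = net$women[ef[, 1L]],
               receiver_id = net$men[ef[, 2L]], stringsAsFactors = FALSE),
    data.frame(sender_id = net$men[em[, 1L]],
               receiver_id = net$women[em[, 2L]], stringsAsFactors = FALSE)
  )
  utils::write.csv(edges, edges_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(net$attrs, nodes_path, row.names = FALSE, quote = FALSE)
  invisible(list(edges = edges_path, nodes = nodes_path))
}
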