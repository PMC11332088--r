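#' Construct a multiplex directed binary network
#'
#' A `multiplex_network` holds a person roster, a set of named layers, and a
#' `J x J x M` array `G` of directed tie indicators. Rows index senders,
#' columns receivers. Three kinds of cell exist:
#'
#' * observed 0/1 cells: sender is an ego (a decider whose outgoing choices
#'   were recorded) and sender != receiver;
#' * structurally unobserved cells (`NA`): the diagonal (self-ties are
#'   excluded from the data model and the likelihood) and all cells whose
#'   sender is not an ego. Non-ego roster members ("alters") keep receiver
#'   effects and latent dyadic slots, but contribute no outgoing observations.
#'
#' Absent edges are observed zeros, not missing data: roster-based game data
#' record placed coins/tokens only, so an unlisted ego-to-alter pair means no
#' tie was placed.
#'
#' @param roster data frame with columns `id` (unique character ids) and
#'   `is_ego` (logical or 0/1); at least one ego is required.
#' @param layers character vector of unique layer names, or a data frame with
#'   columns `name` and optionally `role` (`"behavior"` or `"rating"`,
#'   metadata only).
#' @param G optional `J x J x M` array of 0/1/NA; if omitted, all observable
#'   cells are 0. The ego/diagonal mask is applied (masked cells forced `NA`).
#' @return an object of class `multiplex_network` with elements `roster`,
#'   `layers`, `G`.
#' @seealso [read_multiplex()], [to_dyad_table()], [summary.multiplex_network()]
#' @export
#' @examples
#' ros <- data.frame(id = c("a", "b", "c"), is_ego = c(TRUE, TRUE, FALSE))
#' net <- multiplex_network(ros, layers = c("give", "rate"))
#' observed_cells(net)  # 2 egos x 2 receivers x 2 layers = 8
multiplex_network <- function(roster, layers, G = NULL) {
  roster <- validate_roster(roster)
  layers <- validate_layers(layers)
  J <- nrow(roster)
  M <- nrow(layers)
  if (is.null(G)) {
    G <- array(0L, dim = c(J, J, M))
  } else {
    if (!is.array(G) || length(dim(G)) != 3L || !all(dim(G) == c(J, J, M)))
      stop("'G' must be a ", J, " x ", J, " x ", M, " array")
    vals <- G[!is.na(G)]
    if (!all(vals %in% c(0L, 1L)))
      stop("observed entries of 'G' must be exactly 0 or 1")
    storage.mode(G) <- "integer"
  }
  dimnames(G) <- list(roster$id, roster$id, layers$name)
  # structural mask: diagonal and non-ego senders are never observed
  for (m in seq_len(M)) {
    diag(G[, , m]) <- NA_integer_
    G[!roster$is_ego, , m] <- NA_integer_
  }
  structure(list(roster = roster, layers = layers, G = G),
            class = "multiplex_network")
}

validate_roster <- function(roster) {
  if (!is.data.frame(roster) || !all(c("id", "is_ego") %in% names(roster)))
    stop("'roster' must be a data frame with columns 'id' and 'is_ego'")
  ids <- as.character(roster$id)
  if (length(ids) == 0L) stop("roster is empty")
  if (anyDuplicated(ids)) stop("duplicate roster ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  is_ego <- parse_logical(roster$is_ego)
  if (anyNA(is_ego)) stop("'is_ego' must be 0/1/true/false")
  if (!any(is_ego)) stop("roster must contain at least one ego")
  data.frame(id = ids, is_ego = is_ego, stringsAsFactors = FALSE)
}

validate_layers <- function(layers) {
  if (is.character(layers))
    layers <- data.frame(name = layers, role = "behavior",
                         stringsAsFactors = FALSE)
  if (!is.data.frame(layers) || !"name" %in% names(layers))
    stop("'layers' must be a character vector or a data frame with a 'name' column")
  if (!"role" %in% names(layers)) layers$role <- "behavior"
  if (nrow(layers) < 1L) stop("at least one layer is required")
  if (anyDuplicated(layers$name)) stop("layer names must be unique")
  if (!all(layers$role %in% c("behavior", "rating")))
    stop("layer 'role' must be 'behavior' or 'rating'")
  data.frame(name = as.character(layers$name), role = as.character(layers$role),
             stringsAsFactors = FALSE)
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(ifelse(x %in% c(0, 1), x == 1, NA))
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t")] <- TRUE
  out[x %in% c("0", "false", "f")] <- FALSE
  out
}

#' @export
print.multiplex_network <- function(x, ...) {
  J <- nrow(x$roster); M <- nrow(x$layers)
  cat("Multiplex directed binary network\n")
  cat(sprintf("  %d people (%d egos, %d alters), %d layer%s\n",
              J, sum(x$roster$is_ego), sum(!x$roster$is_ego), M,
              if (M == 1) "" else "s"))
  dens <- vapply(seq_len(M), function(m) {
    g <- x$G[, , m]
    mean(g[!is.na(g)])
  }, numeric(1))
  cat(sprintf("  layers: %s\n",
              paste(sprintf("%s (obs. density %.3f)", x$layers$name, dens),
                    collapse = ", ")))
  invisible(x)
}

#' Count observed cells of a multiplex network
#'
#' Equals `(# egos) * (J - 1) * M` for any valid network.
#' @param net a `multiplex_network`.
#' @return integer count of non-missing cells in `G`.
#' @export
observed_cells <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  sum(!is.na(net$G))
}

#' Read a multiplex network from edge-list and roster files
#'
#' The edge list is a CSV with header `layer,sender,receiver,value`; the
#' `value` column is optional and defaults to 1 (one row per placed tie).
#' The roster is a CSV with header `id,is_ego` (`is_ego` in 0/1/true/false).
#' Triples absent from the edge list default to observed 0 when the sender is
#' an ego; cells with non-ego senders and the diagonal are unobserved.
#'
#' @param edge_list_path path to the edge-list CSV.
#' @param roster_path path to the roster CSV.
#' @param layers optional character vector fixing layer names and their order
#'   (useful when some layers have no edges); defaults to the layers present
#'   in the file, in order of first appearance.
#' @return a [multiplex_network()].
#' @export
read_multiplex <- function(edge_list_path, roster_path, layers = NULL) {
  roster <- utils::read.csv(roster_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  roster <- validate_roster(roster)
  edges <- utils::read.csv(edge_list_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("layer", "sender", "receiver")
  if (!all(need %in% names(edges)))
    stop("edge list must have columns 'layer', 'sender', 'receiver'")
  if (!"value" %in% names(edges)) edges$value <- "1"
  edges$value[is.na(edges$value) | edges$value == ""] <- "1"
  if (!all(edges$value %in% c("0", "1")))
    stop("edge 'value' must be 0 or 1")
  if (is.null(layers)) layers <- unique(edges$layer)
  if (length(layers) == 0L)
    stop("no layers: supply 'layers' when the edge list is empty")
  bad <- setdiff(c(edges$sender, edges$receiver), roster$id)
  if (length(bad) > 0L)
    stop("edge endpoints not in roster: ", paste(unique(bad), collapse = ", "))
  if (!all(edges$layer %in% layers))
    stop("edge layers not in layer set: ",
         paste(setdiff(edges$layer, layers), collapse = ", "))
  key <- paste(edges$layer, edges$sender, edges$receiver, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    vals <- split(edges$value, key)
    contradictory <- any(vapply(vals[dup], function(v) length(unique(v)) > 1L,
                                logical(1)))
    if (contradictory)
      stop("contradictory duplicate entries for the same (layer, sender, receiver)")
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
  }
  net <- multiplex_network(roster, layers)
  J <- nrow(roster); M <- length(layers)
  si <- match(edges$sender, roster$id)
  ri <- match(edges$receiver, roster$id)
  li <- match(edges$layer, layers)
  if (any(si == ri)) stop("self-ties (sender == receiver) are not allowed")
  if (any(!roster$is_ego[si]))
    stop("edges with non-ego senders are not observable: ",
         paste(unique(edges$sender[!roster$is_ego[si]]), collapse = ", "))
  net$G[cbind(si, ri, li)] <- as.integer(edges$value)
  net
}

#' Write a multiplex network to edge-list and roster files
#'
#' Writes one edge-list row per observed 1 cell (observed zeros are implicit)
#' and the roster with `is_ego` coded 0/1. `read_multiplex()` on the output,
#' with the network's layer names, reproduces `G` exactly.
#'
#' @param net a `multiplex_network`.
#' @param edge_list_path,roster_path output CSV paths.
#' @return `net`, invisibly.
#' @export
write_multiplex <- function(net, edge_list_path, roster_path) {
  stopifnot(inherits(net, "multiplex_network"))
  idx <- which(!is.na(net$G) & net$G == 1L, arr.ind = TRUE)
  edges <- data.frame(layer = net$layers$name[idx[, 3]],
                      sender = net$roster$id[idx[, 1]],
                      receiver = net$roster$id[idx[, 2]],
                      value = rep(1L, nrow(idx)), stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$layer, net$layers$name),
                       edges$sender, edges$receiver), , drop = FALSE]
  utils::write.csv(edges, edge_list_path, row.names = FALSE, quote = FALSE)
  ros <- data.frame(id = net$roster$id, is_ego = as.integer(net$roster$is_ego))
  utils::write.csv(ros, roster_path, row.names = FALSE, quote = FALSE)
  invisible(net)
}

#' Enumerate unordered dyads of a roster
#'
#' Maps every ordered non-self pair (j, k) to a (dyad, direction) slot.
#' Dyads are unordered pairs `{i1 < i2}` in roster order; direction 1 is
#' `i1 -> i2`, direction 2 is `i2 -> i1`. There are `J (J - 1) / 2` dyads.
#'
#' @param J roster size (>= 2).
#' @return a list with `i1`, `i2` (integer vectors of length `J(J-1)/2`),
#'   `n_dyads`, and `of`, a `J x J` matrix with `of[j, k]` the dyad id of the
#'   pair (0 on the diagonal).
#' @export
dyad_index <- function(J) {
  stopifnot(J >= 2)
  pr <- which(upper.tri(matrix(0, J, J)), arr.ind = TRUE)
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  i1 <- pr[, 1]; i2 <- pr[, 2]
  of <- matrix(0L, J, J)
  of[cbind(i1, i2)] <- seq_along(i1)
  of[cbind(i2, i1)] <- seq_along(i1)
  list(i1 = as.integer(i1), i2 = as.integer(i2),
       n_dyads = length(i1), of = of)
}

#' Long dyad-direction table of a multiplex network
#'
#' One row per (dyad, direction, layer): exactly `2 * M * J(J-1)/2` rows.
#' `value` is the tie indicator or `NA` where the cell is unobserved.
#'
#' @param net a `multiplex_network`.
#' @return data frame with columns `dyad`, `direction` (1 = lower roster
#'   index sends, 2 = reverse), `sender`, `receiver`, `layer`, `value`.
#' @export
to_dyad_table <- function(net) {
  stopifnot(inherits(net, "multiplex_network"))
  J <- nrow(net$roster); M <- nrow(net$layers)
  dy <- dyad_index(J)
  out <- expand.grid(dyad = seq_len(dy$n_dyads), direction = 1:2,
                     layer = net$layers$name, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  s <- ifelse(out$direction == 1L, dy$i1[out$dyad], dy$i2[out$dyad])
  r <- ifelse(out$direction == 1L, dy$i2[out$dyad], dy$i1[out$dyad])
  out$sender <- net$roster$id[s]
  out$receiver <- net$roster$id[r]
  li <- match(out$layer, net$layers$name)
  out$value <- net$G[cbind(s, r, li)]
  out
}

#' Rebuild a multiplex network from a dyad table
#'
#' Inverse of [to_dyad_table()] given the original roster and layers.
#' @param tab output of [to_dyad_table()].
#' @param roster,layers as in [multiplex_network()].
#' @return a `multiplex_network`.
#' @export
from_dyad_table <- function(tab, roster, layers) {
  net <- multiplex_network(roster, layers)
  s <- match(tab$sender, net$roster$id)
  r <- match(tab$receiver, net$roster$id)
  li <- match(tab$layer, net$layers$name)
  obs <- !is.na(tab$value)
  net$G[cbind(s, r, li)[obs, , drop = FALSE]] <- as.integer(tab$value[obs])
  net
}
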