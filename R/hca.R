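#' Hydrophobic residue alphabet used for cluster analysis
#'
#' The classical hydrophobic set used when projecting a protein onto the
#' alpha-helical net: Val, Ile, Leu, Met, Phe, Trp, Tyr.
#' @export
HCA_HYDROPHOBIC <- c("V", "I", "L", "M", "F", "W", "Y")

#' Build the duplicated alpha-helical net of a protein
#'
#' Hydrophobic cluster analysis draws the sequence on an alpha-helical net
#' with 3.6 residues per turn, duplicated vertically so that wrap-around
#' neighbours are visible. Residue i sits at `x = i` (sequence direction)
#' and `y = i mod 3.6` on the strip, with a duplicate at `y + 3.6`.
#' Net adjacency itself is combinatorial (sequence neighbours and the
#' i±3 / i±4 helical contacts) rather than floating-point geometry.
#'
#' @param protein Amino-acid string (standard 20 letters; `X` allowed and
#'   treated as non-hydrophobic).
#' @return An object of class `HcaNet`: list with `sequence`, `positions`
#'   (`data.frame` of `index`, `residue`, `x`, `y`, `y_dup`), `period`.
#' @export
build_net <- function(protein) {
  if (!nchar(protein)) stop("empty sequence")
  chars <- strsplit(toupper(protein), "")[[1L]]
  idx <- seq_along(chars)
  y <- (idx %% 3.6)
  structure(
    list(sequence = paste0(chars, collapse = ""),
         positions = data.frame(index = idx, residue = chars,
                                x = idx, y = y, y_dup = y + 3.6),
         period = 3.6),
    class = "HcaNet")
}

#' @export
print.HcaNet <- function(x, ...) {
  cat(sprintf("HcaNet of %d residues (period %.1f, duplicated strip)\n",
              nchar(x$sequence), x$period))
  invisible(x)
}

## adjacency rule: |i-j| in {1,3,4} and no proline strictly between
hca_adjacent <- function(chars, i, j) {
  d <- abs(i - j)
  if (!d %in% c(1L, 3L, 4L)) return(FALSE)
  lo <- min(i, j); hi <- max(i, j)
  if (hi - lo > 1L && any(chars[(lo + 1L):(hi - 1L)] == "P")) return(FALSE)
  TRUE
}

#' Extract hydrophobic clusters from a helical net
#'
#' Clusters are the connected components of the hydrophobic residues under
#' the net adjacency rule (sequence neighbours plus the i±3 and i±4 helical
#' contacts), with proline acting as a breaker: no contact crosses a
#' proline. Components are computed once on the primary strip (the
#' duplicated strip shows the same residues, so clusters are deduplicated
#' by construction).
#'
#' @param net An `HcaNet` from [build_net()].
#' @param hydrophobic Hydrophobic alphabet (default [HCA_HYDROPHOBIC]).
#' @return A list of `HcaCluster` objects: each a list with
#'   `member_indices`, `span` (first, last), `shape_ratio`, `shape_call`.
#' @export
extract_clusters <- function(net, hydrophobic = HCA_HYDROPHOBIC) {
  chars <- strsplit(net$sequence, "")[[1L]]
  hyd <- which(chars %in% hydrophobic)
  if (!length(hyd)) return(list())
  ## union-find over hydrophobic indices
  parent <- stats::setNames(hyd, hyd)
  find <- function(i) {
    while (parent[[as.character(i)]] != i) i <- parent[[as.character(i)]]
    i
  }
  for (i in hyd) {
    for (d in c(1L, 3L, 4L)) {
      j <- i + d
      if (j %in% hyd && hca_adjacent(chars, i, j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[[as.character(ri)]] <- rj
      }
    }
  }
  roots <- vapply(hyd, find, numeric(1L))
  comps <- split(hyd, roots)
  clusters <- lapply(unname(comps), function(members) {
    members <- sort(members)
    cl <- list(member_indices = members,
               span = c(members[1L], members[length(members)]))
    cl$shape_ratio <- cluster_shape_ratio(members, net$period)
    cl$shape_call <- NA_character_
    class(cl) <- "HcaCluster"
    cl
  })
  clusters[order(vapply(clusters, function(c) c$span[1L], numeric(1L)))]
}

## vertical extent: minimal circular arc (circumference = period) covering
## the members' y positions; horizontal extent: index span in turns.
cluster_shape_ratio <- function(members, period = 3.6) {
  if (length(members) < 2L) return(NA_real_)
  ys <- sort(members %% period)
  gaps <- diff(c(ys, ys[1L] + period))
  vert <- period - max(gaps)
  horiz <- (max(members) - min(members)) / period
  if (horiz == 0) return(NA_real_)
  vert / horiz
}

#' Call the shape of a hydrophobic cluster
#'
#' On the helical net, clusters belonging to beta strands are roughly
#' vertical while helical clusters are fairly horizontal. The call uses the
#' ratio of the cluster's vertical extent (circular, on the net period) to
#' its horizontal extent (sequence span in turns).
#'
#' @param cluster An `HcaCluster`.
#' @param net The `HcaNet` it came from.
#' @param upper Ratio above which the call is `strand_like` (default 1.5).
#' @param lower Ratio below which the call is `helix_like` (default 0.67).
#' @return One of `"strand_like"`, `"helix_like"`, `"indeterminate"`.
#' @export
shape_call <- function(cluster, net, upper = 1.5, lower = 0.67) {
  r <- cluster$shape_ratio
  if (is.na(r)) return("indeterminate")
  if (r > upper) return("strand_like")
  if (r < lower) return("helix_like")
  "indeterminate"
}

#' Summarize the clusters of a protein as a table
#'
#' @param protein Amino-acid string.
#' @param hydrophobic Hydrophobic alphabet.
#' @param ... Passed to [shape_call()].
#' @return `data.frame` with `first`, `last`, `n_members`, `shape_ratio`,
#'   `shape_call` per cluster, in sequence order.
#' @export
hca_cluster_table <- function(protein, hydrophobic = HCA_HYDROPHOBIC, ...) {
  net <- build_net(protein)
  cl <- extract_clusters(net, hydrophobic)
  if (!length(cl)) {
    return(data.frame(first = integer(), last = integer(),
                      n_members = integer(), shape_ratio = numeric(),
                      shape_call = character()))
  }
  data.frame(
    first = vapply(cl, function(c) c$span[1L], numeric(1L)),
    last = vapply(cl, function(c) c$span[2L], numeric(1L)),
    n_members = vapply(cl, function(c) length(c$member_indices), numeric(1L)),
    shape_ratio = vapply(cl, function(c) c$shape_ratio, numeric(1L)),
    shape_call = vapply(cl, shape_call, character(1L), net = net, ...),
    stringsAsFactors = FALSE)
}

#' Align two proteins by their hydrophobic cluster architectures
#'
#' A reproducible surrogate for visual net-to-net comparison: the ordered
#' cluster lists of the two proteins are aligned by dynamic programming on
#' (order, length, shape), since conserved cluster shapes matter more than
#' conserved residues for very distant homologues. Two aligned clusters
#' count as matched when their pair similarity (length agreement times
#' shape agreement) reaches `match_threshold`.
#'
#' @param protein_a,protein_b Amino-acid strings of at least 20 residues.
#' @param gap Gap penalty per skipped cluster (default 0.2).
#' @param match_threshold Minimum pair similarity for a match (default 0.5).
#' @param hydrophobic Hydrophobic alphabet.
#' @return A list with `matches` (`data.frame` of matched cluster indices
#'   and similarities) and `score` in [0, 1]: total matched cluster length
#'   over the mean total cluster length of the two proteins.
#' @export
cluster_alignment_score <- function(protein_a, protein_b, gap = 0.2,
                                    match_threshold = 0.5,
                                    hydrophobic = HCA_HYDROPHOBIC) {
  stopifnot(nchar(protein_a) >= 20L, nchar(protein_b) >= 20L)
  ta <- hca_cluster_table(protein_a, hydrophobic)
  tb <- hca_cluster_table(protein_b, hydrophobic)
  empty <- data.frame(a_cluster = integer(), b_cluster = integer(),
                      similarity = numeric())
  if (nrow(ta) == 0L || nrow(tb) == 0L) {
    warning("a protein with zero hydrophobic clusters; score is 0")
    return(list(matches = empty, score = 0))
  }
  sim <- function(i, j) {
    len_sim <- min(ta$n_members[i], tb$n_members[j]) /
      max(ta$n_members[i], tb$n_members[j])
    shape_sim <- if (ta$shape_call[i] == tb$shape_call[j]) 1 else 0.5
    len_sim * shape_sim
  }
  na <- nrow(ta); nb <- nrow(tb)
  M <- matrix(0, na + 1L, nb + 1L)
  M[1L, ] <- -gap * (0:nb)
  M[, 1L] <- -gap * (0:na)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      M[i + 1L, j + 1L] <- max(M[i, j] + sim(i, j),
                               M[i, j + 1L] - gap,
                               M[i + 1L, j] - gap)
    }
  }
  ## traceback
  i <- na; j <- nb
  pairs <- list()
  while (i > 0L && j > 0L) {
    if (isTRUE(all.equal(M[i + 1L, j + 1L], M[i, j] + sim(i, j)))) {
      pairs[[length(pairs) + 1L]] <- c(i, j, sim(i, j))
      i <- i - 1L; j <- j - 1L
    } else if (isTRUE(all.equal(M[i + 1L, j + 1L], M[i, j + 1L] - gap))) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  pairs <- rev(pairs)
  matches <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(a_cluster = p[1L], b_cluster = p[2L], similarity = p[3L])
  }))
  if (is.null(matches)) matches <- empty
  matches <- matches[matches$similarity >= match_threshold, , drop = FALSE]
  matched_len <- if (nrow(matches)) {
    sum(pmin(ta$n_members[matches$a_cluster], tb$n_members[matches$b_cluster]))
  } else 0
  score <- matched_len / mean(c(sum(ta$n_members), sum(tb$n_members)))
  list(matches = matches, score = min(1, max(0, score)))
}
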