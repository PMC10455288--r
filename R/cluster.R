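# Single-linkage threshold clustering and group summaries.

# connected components by breadth-first search over a logical adjacency
bfsComponents <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Single-linkage threshold clustering of a distance matrix
#'
#' Groups records into the connected components of the graph whose edges
#' join pairs with p-distance `<= t` (or `< t` when `inclusive = FALSE`).
#' Missing distances contribute no edge. This is the usual
#' barcode-gap/OTU-style chained clustering: within-group distances may
#' exceed `t` along a chain, which is why each group reports its full
#' within-range as an audit trail. Groups are ordered by decreasing size,
#' ties broken by the lexicographically smallest member, and labelled
#' `"G1"`, `"G2"`, ...
#'
#' @param dm A [PDistanceMatrix-class].
#' @param t Threshold proportion, 0 < t < 1.
#' @param inclusive Use `p <= t` edges (default) rather than `p < t`.
#' @return List of [TaxonGroup-class] objects.
#' @examples
#' m <- matrix(c(0, .01, .15, .01, 0, .16, .15, .16, 0), 3,
#'             dimnames = list(c("A","B","C"), c("A","B","C")))
#' dm <- new("PDistanceMatrix", locus = "ITS", values = m,
#'           nCompared = matrix(100L, 3, 3, dimnames = dimnames(m)), se = NULL)
#' length(thresholdCluster(dm, 0.03))  # {A,B} and {C}
#' @export
thresholdCluster <- function(dm, t, inclusive = TRUE) {
  stopifnot(is(dm, "PDistanceMatrix"), t > 0, t < 1)
  v <- distValues(dm)
  ids <- recordIds(dm)
  adj <- if (inclusive) !is.na(v) & v <= t else !is.na(v) & v < t
  diag(adj) <- TRUE
  comp <- bfsComponents(adj)
  members <- split(ids, comp)
  ord <- order(-lengths(members),
               vapply(members, function(m) sort(m)[1L], ""))
  members <- members[ord]
  groups <- vector("list", length(members))
  for (g in seq_along(members)) {
    mem <- sort(members[[g]])
    inG <- ids %in% mem
    wv <- v[inG, inG, drop = FALSE][upper.tri(diag(sum(inG)))]
    wv <- wv[!is.na(wv)]
    wr <- if (length(wv)) range(wv) else c(NA_real_, NA_real_)
    bv <- v[inG, !inG, drop = FALSE]
    if (length(bv) && any(!is.na(bv))) {
      bmin <- min(bv, na.rm = TRUE)
    } else bmin <- NA_real_
    groups[[g]] <- new("TaxonGroup", groupId = paste0("G", g),
                       memberIds = mem, locus = locus(dm),
                       withinRange = wr, nearestGroup = NA_character_,
                       betweenMin = bmin, representatives = character())
  }
  # nearest-group resolution needs the final labels
  for (g in seq_along(groups)) {
    mem <- groups[[g]]@memberIds
    inG <- ids %in% mem
    best <- NA_character_
    bestd <- Inf
    for (h in seq_along(groups)) {
      if (h == g) next
      oth <- ids %in% groups[[h]]@memberIds
      d <- suppressWarnings(min(v[inG, oth, drop = FALSE], na.rm = TRUE))
      if (is.finite(d) && d < bestd) {
        bestd <- d
        best <- groups[[h]]@groupId
      }
    }
    groups[[g]]@nearestGroup <- best
    groups[[g]]@betweenMin <- if (is.finite(bestd)) bestd else NA_real_
  }
  groups
}

#' Summarise threshold clusters in a report table
#'
#' One row per group: member count, within-group min/max as integer
#' percents, nearest group with the min/max distance to it, and — when a
#' reference group is named — the min/max distance of every group to that
#' reference (the "distance to the nominate species" column of sectorial
#' report tables). Unavailable values render as an em dash.
#'
#' @param groups List of [TaxonGroup-class] from [thresholdCluster()].
#' @param dm The same [PDistanceMatrix-class] the groups were formed on.
#' @param reference Optional group ID to report distances against.
#' @return A data.frame.
#' @export
groupSummary <- function(groups, dm, reference = NULL) {
  v <- distValues(dm)
  ids <- recordIds(dm)
  if (!is.null(reference)) {
    refIdx <- match(reference, vapply(groups, groupId, ""))
    if (is.na(refIdx)) stop("unknown reference group: ", reference)
    refIn <- ids %in% groups[[refIdx]]@memberIds
  }
  rows <- lapply(groups, function(g) {
    inG <- ids %in% g@memberIds
    near <- g@nearestGroup
    btw <- c(NA_real_, NA_real_)
    if (!is.na(near)) {
      oth <- ids %in% groups[[match(near, vapply(groups, groupId, ""))]]@memberIds
      bv <- v[inG, oth, drop = FALSE]
      if (any(!is.na(bv))) btw <- range(bv, na.rm = TRUE)
    }
    row <- data.frame(
      group = g@groupId, n = length(g@memberIds),
      within_min = formatPercent(g@withinRange[1L]),
      within_max = formatPercent(g@withinRange[2L]),
      nearest = ifelse(is.na(near), "—", near),
      between_min = formatPercent(btw[1L]),
      between_max = formatPercent(btw[2L]),
      stringsAsFactors = FALSE)
    if (!is.null(reference)) {
      rv <- v[inG, refIn, drop = FALSE]
      rv <- rv[!is.na(rv) | FALSE]
      if (identical(g@groupId, reference) || !length(rv)) {
        row$ref_min <- "—"
        row$ref_max <- "—"
      } else {
        row$ref_min <- formatPercent(min(rv))
        row$ref_max <- formatPercent(max(rv))
      }
    }
    row
  })
  do.call(rbind, rows)
}
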