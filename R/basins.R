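#' Sub-basin sets
#'
#' An abstract representation of a tessellated drainage basin: one row per
#' sub-basin with its downstream neighbour (NA for the outlet basin) and
#' drained area.  Pfafstetter codes, if absent, can be generated with
#' [pfafstetter_codes()].
#'
#' @param id Character or integer basin identifiers (unique).
#' @param downstream For each basin, the id of the basin it drains into
#'   (`NA` for the single outlet basin).
#' @param area Drained area of each basin (relative units suffice).
#' @param code Optional character Pfafstetter codes.
#' @return A data frame of class `basin_set`.
#' @export
basin_set <- function(id, downstream, area, code = NULL) {
  id <- as.character(id)
  downstream <- as.character(downstream)
  if (anyDuplicated(id)) abort("duplicated basin ids", "resghg_bad_argument")
  if (sum(is.na(downstream)) != 1L) {
    abort("basin set must have exactly one outlet basin (downstream = NA)",
          "resghg_bad_argument")
  }
  known <- is.na(downstream) | downstream %in% id
  if (!all(known)) {
    abort("downstream ids must reference basins in the set",
          "resghg_broken_topology")
  }
  bs <- data.frame(id = id, downstream = downstream,
                   area = as.numeric(area), stringsAsFactors = FALSE)
  bs$code <- if (is.null(code)) NA_character_ else as.character(code)
  # reject cycles: repeated downstream hops must terminate at the outlet
  ord <- match(bs$downstream, bs$id)
  for (i in seq_len(nrow(bs))) {
    seen <- integer(0); j <- i
    while (!is.na(j)) {
      if (j %in% seen) abort("cycle in downstream topology",
                             "resghg_broken_topology")
      seen <- c(seen, j)
      j <- ord[j]
    }
  }
  class(bs) <- c("basin_set", "data.frame")
  bs
}

# children[i]: indices of basins draining directly into basin i
basin_children <- function(bs) {
  parent <- match(bs$downstream, bs$id)
  split(seq_len(nrow(bs)), factor(parent, levels = seq_len(nrow(bs))))
}

# total upstream area (own + all ancestors') per basin
subtree_area <- function(bs) {
  kids <- basin_children(bs)
  total <- bs$area
  # process basins in decreasing depth so children accumulate first
  depth <- integer(nrow(bs))
  parent <- match(bs$downstream, bs$id)
  for (i in seq_len(nrow(bs))) {
    j <- i
    while (!is.na(parent[j])) { depth[i] <- depth[i] + 1L; j <- parent[j] }
  }
  for (i in order(depth, decreasing = TRUE)) {
    p <- parent[i]
    if (!is.na(p)) total[p] <- total[p] + total[i]
  }
  total
}

#' Generate Pfafstetter codes for a basin set
#'
#' Standard recursive Pfafstetter numbering: within each group the main
#' stem is traced upstream along the largest drained area; the four largest
#' tributaries joining the stem receive even digits (2, 4, 6, 8 in
#' upstream order) and the interbasin stem segments between them odd digits
#' (1, 3, 5, 7, 9); each multi-basin group is then subdivided recursively
#' with the next digit appended.  Codes increase in the upstream direction
#' along any drainage path, which is the property the upstream filter in
#' [upstream_subbasins()] relies on.
#'
#' @param bs A [basin_set()].
#' @return The basin set with the `code` column filled.
#' @export
pfafstetter_codes <- function(bs) {
  stopifnot(inherits(bs, "basin_set"))
  n <- nrow(bs)
  parent <- match(bs$downstream, bs$id)
  kids <- lapply(seq_len(n), function(i) which(parent == i))
  tot <- subtree_area(bs)
  codes <- character(n)

  group_subtree <- function(root, members) {
    # all basins upstream of `root` (inclusive) restricted to `members`
    out <- integer(0); frontier <- root
    memb <- rep(FALSE, n); memb[members] <- TRUE
    while (length(frontier)) {
      out <- c(out, frontier)
      frontier <- unlist(lapply(frontier, function(i) {
        k <- kids[[i]]; k[memb[k]]
      }), use.names = FALSE)
    }
    out
  }

  assign_group <- function(members, prefix) {
    if (length(members) == 1L) {
      codes[members] <<- if (nzchar(prefix)) prefix else "1"
      return(invisible())
    }
    memb <- rep(FALSE, n); memb[members] <- TRUE
    outlet <- members[is.na(parent[members]) | !memb[parent[members]]][1]
    # main stem: follow the largest-subtree child inside the group
    stem <- outlet
    repeat {
      k <- kids[[stem[length(stem)]]]
      k <- k[memb[k]]
      if (!length(k)) break
      stem <- c(stem, k[which.max(tot[k])])
    }
    on_stem <- rep(FALSE, n); on_stem[stem] <- TRUE
    # tributary roots: off-stem children of stem basins
    trib_roots <- unlist(lapply(stem, function(s) {
      k <- kids[[s]]; k[memb[k] & !on_stem[k]]
    }), use.names = FALSE)
    if (length(trib_roots)) {
      junction <- parent[trib_roots]                 # a stem basin
      jpos <- match(junction, stem)
      pick <- order(tot[trib_roots], decreasing = TRUE)[
        seq_len(min(4L, length(trib_roots)))]
      pick <- pick[order(jpos[pick], -tot[trib_roots][pick])]
    } else {
      pick <- integer(0)
    }

    if (!length(pick)) {
      # pure chain (no tributaries => members coincide with the stem):
      # chunk into at most 9 contiguous segments, numbered upstream
      segs <- split(stem, cut(seq_along(stem), min(9L, length(stem)),
                              labels = FALSE))
      for (d in seq_along(segs)) {
        assign_group(segs[[d]], paste0(prefix, d))
      }
      return(invisible())
    }

    jpos_pick <- jpos[pick]
    digit <- 1L
    prev <- 0L
    for (t in seq_along(pick)) {
      jp <- jpos_pick[t]
      seg <- if (jp > prev) stem[(prev + 1L):jp] else integer(0)
      # interbasin = segment basins plus unchosen tributaries joining them
      seg_members <- interbasin_members(seg, members, trib_roots, pick,
                                        kids, memb, on_stem, group_subtree)
      if (length(seg_members)) {
        assign_group(seg_members, paste0(prefix, digit))
      }
      digit <- digit + 1L                            # odd -> even
      assign_group(group_subtree(trib_roots[pick[t]], members),
                   paste0(prefix, digit))
      digit <- digit + 1L
      prev <- jp
    }
    if (prev < length(stem)) {
      top <- group_subtree(stem[prev + 1L], members)
      assign_group(top, paste0(prefix, digit))
    }
    invisible()
  }

  interbasin_members <- function(seg, members, trib_roots, pick,
                                 kids, memb, on_stem, group_subtree) {
    chosen <- trib_roots[pick]
    out <- integer(0)
    for (s in seg) {
      out <- c(out, s)
      k <- kids[[s]]
      k <- k[memb[k] & !on_stem[k] & !(k %in% chosen)]
      for (root in k) out <- c(out, group_subtree(root, members))
    }
    unique(out)
  }

  assign_group(seq_len(n), "")
  bs$code <- codes
  bs
}

# TRUE where code a is hierarchically lower (more downstream) than code b:
# compare digit strings position by position; the first differing digit
# decides.  Equal prefixes of unequal length compare as not-lower.
pfaf_lower <- function(a, b) {
  if (is.na(a) || is.na(b)) return(FALSE)
  la <- strsplit(a, "")[[1]]; lb <- strsplit(b, "")[[1]]
  m <- min(length(la), length(lb))
  for (i in seq_len(m)) {
    if (la[i] != lb[i]) return(la[i] < lb[i])
  }
  FALSE
}

#' Compile the upstream sub-basins of a dam's sub-basin
#'
#' Identifies every sub-basin draining into `s0` (the basin holding the
#' dam): restrict the search to the region of interest -- the coarsest
#' Pfafstetter prefix of `s0`'s code whose member set is closed under
#' upstream drainage -- discard basins with codes hierarchically lower
#' (downstream) than `s0`'s, then traverse the downstream-link topology
#' upstream from `s0`, keeping only basins actually reached.
#'
#' @param bs A [basin_set()] with codes (generated if absent).
#' @param s0 Basin id containing the dam.
#' @return Character vector of upstream basin ids (excluding `s0`).
#' @section Errors: `resghg_broken_topology` when a traversed basin lacks a
#'   downstream link inside the region of interest.
#' @export
upstream_subbasins <- function(bs, s0) {
  stopifnot(inherits(bs, "basin_set"))
  if (!s0 %in% bs$id) abort(sprintf("unknown basin '%s'", s0),
                            "resghg_bad_argument")
  if (any(is.na(bs$code))) bs <- pfafstetter_codes(bs)
  i0 <- match(s0, bs$id)
  parent <- match(bs$downstream, bs$id)
  kids_all <- lapply(seq_len(nrow(bs)), function(i) which(parent == i))

  # exhaustive upstream closure of s0 (used to pick the enclosing prefix)
  anc <- integer(0); frontier <- i0
  while (length(frontier)) {
    nxt <- unlist(kids_all[frontier], use.names = FALSE)
    anc <- c(anc, nxt); frontier <- nxt
  }

  code0 <- bs$code[i0]
  roi <- seq_len(nrow(bs))
  for (len in seq(nchar(code0), 0L)) {
    pre <- substr(code0, 1L, len)
    grp <- which(startsWith(bs$code, pre))
    inflow_closed <- all(c(i0, anc) %in% grp)
    if (inflow_closed) { roi <- grp; break }
  }

  keep <- roi[!vapply(bs$code[roi], pfaf_lower, logical(1), b = code0)]
  keep_set <- rep(FALSE, nrow(bs)); keep_set[keep] <- TRUE
  if (!keep_set[i0]) keep_set[i0] <- TRUE

  reached <- integer(0); frontier <- i0
  while (length(frontier)) {
    nxt <- unlist(kids_all[frontier], use.names = FALSE)
    nxt <- nxt[keep_set[nxt]]
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  bs$id[unique(reached)]
}
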