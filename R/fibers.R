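#' Construct a combed DNA fibre
#'
#' A fibre is one combed DNA molecule mapped to reference coordinates,
#' carrying an ordered set of labelled replication tracks. Tracks record the
#' thymidine analog (IdU for the first pulse, CldU for the second), their
#' reference interval (0-based, half-open) and whether each track end is
#' intact or interrupted by a physical break of the fibre. A broken track end
#' must coincide with the fibre boundary on that side.
#'
#' @param fiber_id character scalar identifying the molecule.
#' @param chrom reference sequence name.
#' @param start,end fibre span in bp (0-based, half-open; `start < end`).
#' @param tracks data.frame with columns `analog` ("IdU"/"CldU"), `start`,
#'   `end`, `left_intact`, `right_intact` (logical). Tracks must be pairwise
#'   disjoint and within the fibre span; they are sorted by start.
#' @return An object of class `rfd_fiber`.
#' @export
new_fiber <- function(fiber_id, chrom, start, end, tracks) {
  if (!is.data.frame(tracks)) stopf("fibre %s: tracks must be a data.frame", fiber_id)
  need <- c("analog", "start", "end", "left_intact", "right_intact")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stopf("fibre %s: tracks missing columns: %s", fiber_id,
                          paste(miss, collapse = ", "))
  if (!(length(start) == 1 && length(end) == 1 && start < end))
    stopf("fibre %s: fibre span must satisfy start < end", fiber_id)
  tracks <- tracks[order(tracks$start), , drop = FALSE]
  rownames(tracks) <- NULL
  n <- nrow(tracks)
  if (n > 0) {
    bad <- !tracks$analog %in% c("IdU", "CldU")
    if (any(bad)) stopf("fibre %s: unknown analog label '%s'", fiber_id,
                        tracks$analog[which(bad)[1]])
    if (any(tracks$start >= tracks$end))
      stopf("fibre %s: track with start >= end", fiber_id)
    if (any(tracks$start < start | tracks$end > end))
      stopf("fibre %s: track outside fibre span", fiber_id)
    if (n > 1 && any(tracks$end[-n] > tracks$start[-1]))
      stopf("fibre %s: overlapping tracks", fiber_id)
    if (any(!tracks$left_intact & tracks$start != start))
      stopf("fibre %s: left-broken track does not abut the fibre start", fiber_id)
    if (any(!tracks$right_intact & tracks$end != end))
      stopf("fibre %s: right-broken track does not abut the fibre end", fiber_id)
  }
  structure(
    list(fiber_id = as.character(fiber_id), chrom = as.character(chrom),
         start = as.numeric(start), end = as.numeric(end), tracks = tracks),
    class = "rfd_fiber")
}

#' @export
print.rfd_fiber <- function(x, ...) {
  cat(sprintf("<rfd_fiber> %s %s:%d-%d (%d tracks)\n", x$fiber_id, x$chrom,
              x$start, x$end, nrow(x$tracks)))
  invisible(x)
}

#' Read annotated fibres from a track table
#'
#' Parses the tab-separated fibre annotation format: one row per labelled
#' track with columns `fiber_id, chrom, fiber_start, fiber_end, analog,
#' track_start, track_end, left_intact, right_intact` (booleans as 0/1,
#' coordinates 0-based half-open). All fibre invariants are validated;
#' violations are rejected with a message naming the offending fibre.
#'
#' @param path path to the TSV file.
#' @return A list of [new_fiber()] objects, in order of first appearance.
#' @export
parse_fibers <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("fiber_id", "chrom", "fiber_start", "fiber_end", "analog",
            "track_start", "track_end", "left_intact", "right_intact")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("fibre table missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(tab) == 0) return(list())
  ids <- unique(tab$fiber_id)
  lapply(ids, function(id) {
    rows <- tab[tab$fiber_id == id, , drop = FALSE]
    if (length(unique(rows$chrom)) > 1 ||
        length(unique(rows$fiber_start)) > 1 || length(unique(rows$fiber_end)) > 1)
      stopf("fibre %s: inconsistent fibre coordinates across rows", id)
    new_fiber(id, rows$chrom[1], rows$fiber_start[1], rows$fiber_end[1],
              data.frame(analog = rows$analog,
                         start = rows$track_start, end = rows$track_end,
                         left_intact = as.logical(rows$left_intact),
                         right_intact = as.logical(rows$right_intact)))
  })
}

#' Write fibres back to the track-table format
#'
#' Inverse of [parse_fibers()]; `parse_fibers(write_fibers(x, f))` is the
#' identity on fibre lists.
#'
#' @param fibers list of `rfd_fiber` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fibers <- function(fibers, path) {
  rows <- lapply(fibers, function(fb) {
    if (nrow(fb$tracks) == 0) return(NULL)
    data.frame(fiber_id = fb$fiber_id, chrom = fb$chrom,
               fiber_start = fb$start, fiber_end = fb$end,
               analog = fb$tracks$analog,
               track_start = fb$tracks$start, track_end = fb$tracks$end,
               left_intact = as.integer(fb$tracks$left_intact),
               right_intact = as.integer(fb$tracks$right_intact))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(fiber_id = character(), chrom = character(),
                      fiber_start = numeric(), fiber_end = numeric(),
                      analog = character(), track_start = numeric(),
                      track_end = numeric(), left_intact = integer(),
                      right_intact = integer())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parse a fibre's tracks into chains of fork junctions.
#
# Links between consecutive tracks:
#   IdU->CldU with gap <= max_fork_gap : rightward fork junction ("R")
#   CldU->IdU with gap <= max_fork_gap : leftward fork junction ("L")
#   IdU..IdU (any gap)                 : diverging gap ("div"), valid only
#                                        when flanked by fork junctions
#   CldU..CldU (any gap)               : converging gap ("conv"), same rule
# Anything else breaks the chain. Same-analog event gaps are not bounded by
# max_fork_gap: diverging or converging forks imply the event wherever the
# gap midpoint falls.
.parse_chains <- function(fiber, max_fork_gap = 3000) {
  tr <- fiber$tracks
  n <- nrow(tr)
  if (n == 0) return(list())
  a <- ifelse(tr$analog == "IdU", "I", "C")
  link <- rep(NA_character_, max(n - 1, 0))
  if (n > 1) {
    gap_ok <- (tr$start[-1] - tr$end[-n]) <= max_fork_gap
    for (i in seq_len(n - 1)) {
      if (a[i] != a[i + 1] && gap_ok[i])
        link[i] <- if (a[i] == "I") "R" else "L"
    }
    for (i in seq_len(n - 1)) {
      if (a[i] == a[i + 1] &&
          i > 1 && link[i - 1] %in% c("R", "L") &&
          i < n - 1 && link[i + 1] %in% c("R", "L"))
        link[i] <- if (a[i] == "I") "div" else "conv"
    }
  }
  chains <- list()
  start <- 1
  for (i in seq_len(n)) {
    if (i == n || is.na(link[i])) {
      chains[[length(chains) + 1]] <-
        list(idx = start:i,
             links = if (i > start) link[start:(i - 1)] else character(0))
      start <- i + 1
    }
  }
  chains
}

# per-track directions at the left and right end implied by the chain links
.link_dirs <- function(links) {
  # direction of DNA just left / right of each link
  left_of <- vapply(links, function(l)
    switch(l, R = "R", L = "L", div = "L", conv = "R"), "")
  right_of <- vapply(links, function(l)
    switch(l, R = "R", L = "L", div = "R", conv = "L"), "")
  list(left_of = left_of, right_of = right_of)
}

#' Classify the labelled tracks of a fibre into fork structures
#'
#' Applies the dual-pulse junction grammar: an IdU track immediately
#' followed by a CldU track forms a rightward elongating fork, the converse
#' a leftward fork, and tracks closer than `max_fork_gap` chain into
#' composite patterns. A track shared by two diverging forks - the central
#' IdU of CldU-IdU-CldU - marks an initiation anchored at its centre; when
#' the origin fired before the first pulse the central IdU is split in two
#' (CldU-IdU...IdU-CldU) and the initiation is anchored at the midpoint of
#' the unlabelled gap. Symmetrically, the shared or split central CldU of
#' IdU-CldU(-CldU)-IdU marks a termination. Same-analog event gaps are not
#' bounded by `max_fork_gap`: diverging or converging forks imply the event
#' wherever the gap midpoint falls. A lone intact CldU track is an
#' initiation that fired during the second pulse (anchor at its centre). A
#' lone IdU track is direction-ambiguous and classified `unoriented`, as is
#' a lone CldU with a broken end: it may be the surviving half of an
#' elongating fork whose other track was lost with the broken fragment, and
#' only unbroken signals orient DNA.
#'
#' The junction reading is symmetric under end-to-end reflection of the
#' fibre and lets consecutive events share a track: in CldU-IdU-CldU-IdU
#' the central IdU carries an initiation and the central CldU the adjacent
#' termination, so such rows overlap by one track.
#'
#' @param fiber an `rfd_fiber`.
#' @param max_fork_gap maximum unlabelled gap (bp) between the IdU and CldU
#'   tracks of one fork (default 3000).
#' @return data.frame with one row per structure: `kind` (right_fork,
#'   left_fork, initiation, termination, unoriented), `first`/`last` (track
#'   indices into `fiber$tracks`), `anchor` (event position, NA otherwise).
#' @export
classify_structures <- function(fiber, max_fork_gap = 3000) {
  tr <- fiber$tracks
  rows <- list()
  add <- function(kind, first, last, anchor = NA_real_)
    rows[[length(rows) + 1]] <<- list(kind, first, last, anchor)
  for (ch in .parse_chains(fiber, max_fork_gap)) {
    idx <- ch$idx
    m <- length(idx)
    if (m == 1) {
      i <- idx[1]
      if (tr$analog[i] == "CldU" && tr$left_intact[i] && tr$right_intact[i])
        add("initiation", i, i, midpoint(tr$start[i], tr$end[i]))
      else add("unoriented", i, i)
      next
    }
    ld <- .link_dirs(ch$links)
    n_event <- 0
    for (j in seq_len(m - 1)) {
      l <- ch$links[j]
      if (l == "div") {
        add("initiation", idx[j] - 1, idx[j + 1] + 1,
            midpoint(tr$end[idx[j]], tr$start[idx[j + 1]]))
        n_event <- n_event + 1
      } else if (l == "conv") {
        add("termination", idx[j] - 1, idx[j + 1] + 1,
            midpoint(tr$end[idx[j]], tr$start[idx[j + 1]]))
        n_event <- n_event + 1
      }
    }
    for (j in seq_len(m)) {
      dl <- if (j > 1) ld$right_of[j - 1] else NA
      dr <- if (j < m) ld$left_of[j] else NA
      if (!is.na(dl) && !is.na(dr) && dl == "L" && dr == "R") {
        add("initiation", idx[j] - 1, idx[j] + 1,
            midpoint(tr$start[idx[j]], tr$end[idx[j]]))
        n_event <- n_event + 1
      } else if (!is.na(dl) && !is.na(dr) && dl == "R" && dr == "L") {
        add("termination", idx[j] - 1, idx[j] + 1,
            midpoint(tr$start[idx[j]], tr$end[idx[j]]))
        n_event <- n_event + 1
      }
    }
    if (n_event == 0) {
      # pure elongating fork(s): a 2-track chain with one fork junction
      add(if (ch$links[1] == "R") "right_fork" else "left_fork",
          idx[1], idx[2])
    }
  }
  if (length(rows) == 0)
    return(data.frame(kind = character(), first = integer(), last = integer(),
                      anchor = numeric()))
  out <- data.frame(kind = vapply(rows, `[[`, "", 1),
                    first = vapply(rows, function(x) as.integer(x[[2]]), 0L),
                    last = vapply(rows, function(x) as.integer(x[[3]]), 0L),
                    anchor = vapply(rows, function(x) as.numeric(x[[4]]), 0))
  out[order(out$first, out$last), , drop = FALSE]
}

#' Orient the replicated DNA of a fibre and extract events
#'
#' Assigns rightward/leftward replication direction along the fibre
#' following the midpoint rule: each labelled track carries the direction of
#' its fork; the shared track of a contiguous initiation (termination) is
#' split at the event anchor into leftward|rightward (rightward|leftward)
#' halves, as is the internal unlabelled gap of a split event; and every
#' other unlabelled interval - fibre-end gap or gap between chains - is
#' split at its midpoint, each half inheriting the direction of the fork
#' adjacent to it. The outer half of a fibre-end gap has no adjacent fork
#' and stays unassigned: direction cannot be established beyond the
#' midpoint, since the fork could have emanated from (or merged with) an
#' unseen neighbour there. Intervals flanked only by unoriented tracks are
#' unassigned; a broken track end abuts the fibre boundary, so the segment
#' stops at the break with no midpoint extension.
#'
#' @param fiber an `rfd_fiber`.
#' @param max_fork_gap passed to the junction grammar (see
#'   [classify_structures()]).
#' @return list with `segments` (data.frame `chrom,start,end,direction,
#'   fiber_id`; direction "R"/"L"; pairwise disjoint) and `events`
#'   (data.frame `kind,chrom,position,fiber_id`).
#' @export
orient_fiber <- function(fiber, max_fork_gap = 3000) {
  tr <- fiber$tracks
  seg_s <- numeric(0); seg_e <- numeric(0); seg_d <- character(0)
  ev_kind <- character(0); ev_pos <- numeric(0)
  add <- function(s, e, d) {
    if (!is.na(d) && e > s) {
      seg_s[length(seg_s) + 1] <<- s
      seg_e[length(seg_e) + 1] <<- e
      seg_d[length(seg_d) + 1] <<- d
    }
  }
  event <- function(kind, pos) {
    ev_kind[length(ev_kind) + 1] <<- kind
    ev_pos[length(ev_pos) + 1] <<- pos
  }
  prev_end <- fiber$start
  prev_out <- NA_character_
  for (ch in .parse_chains(fiber, max_fork_gap)) {
    idx <- ch$idx
    m <- length(idx)
    if (m == 1) {
      i <- idx[1]
      lone_init <- tr$analog[i] == "CldU" && tr$left_intact[i] &&
        tr$right_intact[i]
      if (lone_init) {
        anchor <- midpoint(tr$start[i], tr$end[i])
        out_l <- "L"; out_r <- "R"
      } else {
        out_l <- NA_character_; out_r <- NA_character_
      }
      mid <- midpoint(prev_end, tr$start[i])
      add(prev_end, mid, prev_out)
      add(mid, tr$start[i], out_l)
      if (lone_init) {
        add(tr$start[i], anchor, "L")
        add(anchor, tr$end[i], "R")
        event("initiation", anchor)
      }
      prev_end <- tr$end[i]
      prev_out <- out_r
      next
    }
    ld <- .link_dirs(ch$links)
    # gap before the chain: split at the midpoint; the chain-facing half
    # takes the direction at the first track's left end
    first_dir <- if (!is.na(ld$left_of[1])) {
      # direction at the left end of track 1 equals its right-end direction
      # unless track 1 hosts an event split (impossible at a chain edge)
      ld$left_of[1]
    } else NA_character_
    mid <- midpoint(prev_end, tr$start[idx[1]])
    add(prev_end, mid, prev_out)
    add(mid, tr$start[idx[1]], first_dir)
    for (j in seq_len(m)) {
      i <- idx[j]
      dl <- if (j > 1) ld$right_of[j - 1] else ld$left_of[j]
      dr <- if (j < m) ld$left_of[j] else ld$right_of[j - 1]
      if (dl == dr) {
        add(tr$start[i], tr$end[i], dl)
      } else {
        anchor <- midpoint(tr$start[i], tr$end[i])
        add(tr$start[i], anchor, dl)
        add(anchor, tr$end[i], dr)
        event(if (dl == "L") "initiation" else "termination", anchor)
      }
      if (j < m) {
        # gap at this link (zero-width when tracks abut)
        l <- ch$links[j]
        gs <- tr$end[i]; ge <- tr$start[idx[j + 1]]
        if (l %in% c("R", "L")) {
          add(gs, ge, l)
        } else {
          anchor <- midpoint(gs, ge)
          add(gs, anchor, if (l == "div") "L" else "R")
          add(anchor, ge, if (l == "div") "R" else "L")
          event(if (l == "div") "initiation" else "termination", anchor)
        }
      }
    }
    prev_end <- tr$end[idx[m]]
    prev_out <- ld$right_of[m - 1]
  }
  mid <- midpoint(prev_end, fiber$end)
  add(prev_end, mid, prev_out)
  # merge touching segments of equal direction
  if (length(seg_s) > 1) {
    keep <- logical(length(seg_s))
    j <- 1; keep[1] <- TRUE
    for (i in 2:length(seg_s)) {
      if (seg_d[i] == seg_d[j] && seg_s[i] == seg_e[j]) {
        seg_e[j] <- seg_e[i]
      } else {
        j <- i; keep[i] <- TRUE
      }
    }
    seg_s <- seg_s[keep]; seg_e <- seg_e[keep]; seg_d <- seg_d[keep]
  }
  list(
    segments = data.frame(chrom = rep(fiber$chrom, length(seg_s)),
                          start = seg_s, end = seg_e, direction = seg_d,
                          fiber_id = rep(fiber$fiber_id, length(seg_s))),
    events = data.frame(kind = ev_kind,
                        chrom = rep(fiber$chrom, length(ev_kind)),
                        position = ev_pos,
                        fiber_id = rep(fiber$fiber_id, length(ev_kind))))
}

#' Orient a list of fibres
#'
#' Convenience wrapper applying [classify_structures()] and [orient_fiber()]
#' to each fibre and binding the results.
#'
#' @inheritParams orient_fiber
#' @param fibers list of `rfd_fiber` objects.
#' @return list with pooled `segments` and `events` data.frames.
#' @export
orient_fibers <- function(fibers, max_fork_gap = 3000) {
  res <- lapply(fibers, orient_fiber, max_fork_gap = max_fork_gap)
  list(segments = do.call(rbind, c(lapply(res, `[[`, "segments"),
                                   list(make.row.names = FALSE))),
       events = do.call(rbind, c(lapply(res, `[[`, "events"),
                                 list(make.row.names = FALSE))))
}

#' Reflect a fibre end to end
#'
#' Maps every coordinate x to `start + end - x`, reverses the track order and
#' swaps the intact flags. Used for the mirror-symmetry property of the
#' orientation rules: reflection swaps rightward and leftward segment labels
#' and reflects event positions (to within 1 bp of integer midpoint
#' rounding).
#'
#' @param fiber an `rfd_fiber`.
#' @return the reflected `rfd_fiber`.
#' @export
reflect_fiber <- function(fiber) {
  tot <- fiber$start + fiber$end
  tr <- fiber$tracks
  new_fiber(fiber$fiber_id, fiber$chrom, fiber$start, fiber$end,
            data.frame(analog = rev(tr$analog),
                       start = rev(tot - tr$end), end = rev(tot - tr$start),
                       left_intact = rev(tr$right_intact),
                       right_intact = rev(tr$left_intact)))
}
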