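# Indel-event extraction, normalization, polarization and simple indel coding
# from intron alignments.
#
# Event coordinates are 0-based half-open alignment columns.  "Bearers" are
# the taxa carrying the gap; for insertion-polarity events the family marker
# is the residue-carrying ("carrier") set, since the gap is borne by everyone
# outside the inserting lineage.

# Maximal gap runs of one row, 1-based inclusive (start, end) columns.
gap_runs <- function(row) {
  g <- row == "-"
  if (!any(g)) return(matrix(integer(0), ncol = 2L))
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

is_terminal_run <- function(run, L) run[1L] == 1L || run[2L] == L

#' Left-justify slideable gap runs
#'
#' Within flanking-repeat ambiguity a gap run can occupy several column
#' ranges without changing any row's residue content.  This pass slides each
#' non-terminal gap run left, one column at a time, while the residue
#' immediately left of the run matches every other row's residue in the
#' column the run would vacate, so equivalent gaps come to occupy identical
#' columns across rows.  Residue content of every row is unchanged.
#'
#' @param aln character matrix alignment (rows = taxa).
#' @return the normalized alignment matrix.
#' @export
normalize_gaps <- function(aln) {
  aln <- as_alignment_matrix(aln)
  L <- ncol(aln)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(aln))) {
      runs <- gap_runs(aln[i, ])
      for (k in seq_len(nrow(runs))) {
        s <- runs[k, 1L]; e <- runs[k, 2L]
        if (is_terminal_run(c(s, e), L)) next
        while (s > 1L && aln[i, s - 1L] != "-") {
          x <- aln[i, s - 1L]
          others <- aln[-i, e]
          others <- others[others != "-"]
          if (length(others) == 0L || !all(others == x)) break
          aln[i, e] <- x
          aln[i, s - 1L] <- "-"
          s <- s - 1L; e <- e - 1L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  aln
}

#' Extract indel events from a normalized alignment
#'
#' Maximal gap runs are collected per taxon; runs with identical coordinates
#' become one event carried by the union of those taxa.  Leading/trailing gap
#' runs are missing data, never events.  Under the single-position rule a
#' 1-column event immediately adjacent (at most one residue column away) to a
#' longer event with the same bearer set is absorbed into it rather than
#' emitted separately.
#'
#' @param aln character matrix alignment (run \code{\link{normalize_gaps}}
#'   first).
#' @param locus locus label stored on the events.
#' @param merge_single_flank apply the single-position absorption rule
#'   (default TRUE).
#' @return data.frame of class \code{indel_events}: id, locus, start, end
#'   (0-based half-open columns), length_nt, bearers (list column of taxon
#'   vectors); attribute \code{taxa} holds the alignment's taxa.
#' @export
extract_indel_events <- function(aln, locus = "locus", merge_single_flank = TRUE) {
  aln <- as_alignment_matrix(aln)
  L <- ncol(aln)
  taxa <- rownames(aln)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(aln)))
  if (any(colSums(aln == "-") == nrow(aln)))
    stop("extract_indel_events: all-gap column present; trim the alignment")

  runs_by <- list()
  for (i in seq_len(nrow(aln))) {
    runs <- gap_runs(aln[i, ])
    keep <- !apply(runs, 1L, is_terminal_run, L = L)
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs)) {
      key <- paste(runs[, 1L], runs[, 2L], sep = "-")
      for (k in seq_along(key))
        runs_by[[key[k]]] <- c(runs_by[[key[k]]], taxa[i])
    }
  }
  if (length(runs_by) == 0L) return(empty_indel_events(locus, taxa))

  coords <- do.call(rbind, strsplit(names(runs_by), "-", fixed = TRUE))
  ev <- data.frame(start = as.integer(coords[, 1L]) - 1L,   # to 0-based
                   end = as.integer(coords[, 2L]),
                   stringsAsFactors = FALSE)
  ev$bearers <- unname(runs_by)
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]

  if (merge_single_flank && nrow(ev) > 1L) {
    repeat {
      merged <- FALSE
      lens <- ev$end - ev$start
      for (k in which(lens == 1L)) {
        bk <- sort(ev$bearers[[k]])
        for (m in seq_len(nrow(ev))) {
          if (m == k || (ev$end[m] - ev$start[m]) <= 1L) next
          if (!identical(sort(ev$bearers[[m]]), bk)) next
          gap_between <- max(ev$start[k], ev$start[m]) -
            min(ev$end[k], ev$end[m])
          if (gap_between > 1L) next
          ev$start[m] <- min(ev$start[m], ev$start[k])
          ev$end[m] <- max(ev$end[m], ev$end[k])
          ev <- ev[-k, , drop = FALSE]
          merged <- TRUE
          break
        }
        if (merged) break
      }
      if (!merged) break
    }
    ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  }

  ev$length_nt <- ev$end - ev$start
  ev$locus <- locus
  ev$id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev <- ev[, c("id", "locus", "start", "end", "length_nt", "bearers")]
  attr(ev, "taxa") <- taxa
  class(ev) <- c("indel_events", "data.frame")
  ev
}

empty_indel_events <- function(locus, taxa) {
  ev <- data.frame(id = integer(0), locus = character(0), start = integer(0),
                   end = integer(0), length_nt = integer(0))
  ev$bearers <- list()
  attr(ev, "taxa") <- taxa
  class(ev) <- c("indel_events", "data.frame")
  ev
}

# State of a taxon set over event columns: "res" (all residues), "gap"
# (all gap), else "mixed" (incl. N).
block_state <- function(aln, taxa, s0, e0) {
  sub <- aln[taxa, (s0 + 1L):e0, drop = FALSE]
  if (all(sub == "-")) "gap"
  else if (all(sub %in% c("A", "C", "G", "T"))) "res"
  else "mixed"
}

#' Polarize indel events as insertions or deletions
#'
#' Outgroup mode reads the ancestral state off the outgroup taxa: residues
#' there mean the bearers lost sequence (deletion); gaps there mean the
#' non-bearers gained it (insertion); a missing or mixed outgroup state gives
#' \code{ambiguous}.  Majority mode uses the majority state across all taxa
#' instead, with ties ambiguous.  Carrier sets (the taxa marked by the
#' derived state: bearers for deletions, residue-holders minus outgroups for
#' insertions) are attached for family-specificity tallies.
#'
#' @param events \code{indel_events} from \code{\link{extract_indel_events}}.
#' @param aln the alignment the events came from.
#' @param reference \code{"outgroup"} or \code{"majority"}.
#' @param outgroups outgroup taxon names (outgroup mode).
#' @return \code{events} with \code{polarity} and \code{carriers} columns.
#' @export
polarize_events <- function(events, aln,
                            reference = c("outgroup", "majority"),
                            outgroups = NULL) {
  reference <- match.arg(reference)
  aln <- as_alignment_matrix(aln)
  taxa <- attr(events, "taxa")
  if (is.null(taxa)) taxa <- rownames(aln)
  if (reference == "outgroup") {
    if (is.null(outgroups) || length(outgroups) == 0L)
      stop("polarize_events: outgroup mode needs outgroup taxa")
    missing_og <- setdiff(outgroups, rownames(aln))
    if (length(missing_og))
      stop("polarize_events: outgroup taxa absent from alignment: ",
           paste(missing_og, collapse = ", "))
  } else if (nrow(aln) < 3L) {
    stop("polarize_events: majority mode needs at least 3 sequences")
  }

  pol <- character(nrow(events))
  carriers <- vector("list", nrow(events))
  for (k in seq_len(nrow(events))) {
    s0 <- events$start[k]; e0 <- events$end[k]
    b <- events$bearers[[k]]
    if (reference == "outgroup") {
      st <- block_state(aln, outgroups, s0, e0)
      pol[k] <- switch(st, res = "deletion", gap = "insertion", "ambiguous")
    } else {
      per_taxon <- vapply(rownames(aln), function(t)
        block_state(aln, t, s0, e0), "")
      n_gap <- sum(per_taxon == "gap"); n_res <- sum(per_taxon == "res")
      pol[k] <- if (n_res > n_gap) "deletion"
                else if (n_gap > n_res) "insertion" else "ambiguous"
    }
    carriers[[k]] <- switch(pol[k],
      deletion = setdiff(b, outgroups),
      insertion = setdiff(setdiff(taxa, b), outgroups),
      setdiff(b, outgroups))
  }
  events$polarity <- pol
  events$carriers <- carriers
  attr(events, "outgroups") <- outgroups
  events
}

#' Indel size spectrum
#'
#' @param events \code{indel_events}.
#' @return list: \code{histogram} (length_nt, count, share_pct),
#'   \code{total}, and \code{share_le10_pct} (cumulative share of events of
#'   at most 10 nt).
#' @export
size_spectrum <- function(events) {
  if (nrow(events) == 0L)
    return(list(histogram = data.frame(length_nt = integer(0),
                                       count = integer(0),
                                       share_pct = numeric(0)),
                total = 0L, share_le10_pct = NA_real_))
  tab <- table(events$length_nt)
  hist <- data.frame(length_nt = as.integer(names(tab)),
                     count = as.integer(tab))
  hist$share_pct <- 100 * hist$count / nrow(events)
  list(histogram = hist, total = nrow(events),
       share_le10_pct = 100 * sum(hist$count[hist$length_nt <= 10L]) /
         nrow(events))
}

#' Polarity and per-locus summary of indel events
#'
#' @param events \code{indel_events} (polarity optional).
#' @return list: \code{total}, \code{by_polarity} and \code{by_locus}
#'   data.frames with counts and percentage shares.
#' @export
indel_summary <- function(events) {
  n <- nrow(events)
  by_pol <- if ("polarity" %in% names(events) && n > 0L) {
    tab <- table(factor(events$polarity,
                        levels = c("deletion", "insertion", "ambiguous")))
    data.frame(polarity = names(tab), count = as.integer(tab),
               share_pct = if (n > 0L) 100 * as.integer(tab) / n else NA_real_,
               stringsAsFactors = FALSE)
  } else NULL
  by_locus <- if (n > 0L) {
    tab <- sort(table(events$locus), decreasing = TRUE)
    data.frame(locus = names(tab), count = as.integer(tab),
               share_pct = 100 * as.integer(tab) / n, stringsAsFactors = FALSE)
  } else data.frame(locus = character(0), count = integer(0),
                    share_pct = numeric(0))
  list(total = n, by_polarity = by_pol, by_locus = by_locus)
}

#' Family-unique indel events
#'
#' An event marks family F when its carrier set matches F's sampled taxa:
#' exactly all of them in \code{strict} mode, any non-empty subset (and
#' nobody outside F) in \code{relaxed} mode.  Counts are split by polarity
#' per locus; ambiguous-polarity events are tallied separately and excluded
#' from the ins/del totals.
#'
#' @param events polarized \code{indel_events} (several loci may be
#'   row-bound; keep the \code{taxa} attribute of the richest alignment or
#'   pass \code{taxa}).
#' @param taxonomy taxonomy data.frame (taxon, family).
#' @param mode \code{"strict"} (default) or \code{"relaxed"}.
#' @param taxa the full taxon universe; defaults to the events' \code{taxa}
#'   attribute minus outgroups.
#' @return list: \code{events} (input with \code{unique_family} column),
#'   \code{by_family_locus} (family, locus, ins, del, amb, total),
#'   \code{totals} (family, ins, del, amb, total).
#' @export
family_unique <- function(events, taxonomy, mode = c("strict", "relaxed"),
                          taxa = NULL) {
  mode <- match.arg(mode)
  if (!"carriers" %in% names(events))
    stop("family_unique: run polarize_events first")
  if (is.null(taxa))
    taxa <- setdiff(attr(events, "taxa"), attr(events, "outgroups"))
  fam_by_taxon <- setNames(taxonomy$family, taxonomy$taxon)
  unknown <- setdiff(taxa, names(fam_by_taxon))
  if (length(unknown))
    stop("family_unique: taxa missing from taxonomy: ",
         paste(unknown, collapse = ", "))
  fam_taxa <- split(intersect(taxonomy$taxon, taxa),
                    fam_by_taxon[intersect(taxonomy$taxon, taxa)])

  events$unique_family <- vapply(seq_len(nrow(events)), function(k) {
    C <- intersect(events$carriers[[k]], taxa)
    if (length(C) == 0L) return(NA_character_)
    fams <- unique(fam_by_taxon[C])
    if (length(fams) != 1L) return(NA_character_)
    F <- fams[[1L]]
    ok <- if (mode == "strict") setequal(C, fam_taxa[[F]])
          else all(C %in% fam_taxa[[F]])
    if (ok) F else NA_character_
  }, "")

  marked <- events[!is.na(events$unique_family), , drop = FALSE]
  fams <- sort(unique(taxonomy$family[taxonomy$taxon %in% taxa]))
  loci <- sort(unique(events$locus))
  by_fl <- expand.grid(family = fams, locus = loci, stringsAsFactors = FALSE)
  cnt <- function(fam, loc, pol) sum(marked$unique_family == fam &
                                       marked$locus == loc &
                                       marked$polarity == pol)
  by_fl$ins <- mapply(cnt, by_fl$family, by_fl$locus,
                      MoreArgs = list(pol = "insertion"))
  by_fl$del <- mapply(cnt, by_fl$family, by_fl$locus,
                      MoreArgs = list(pol = "deletion"))
  by_fl$amb <- mapply(cnt, by_fl$family, by_fl$locus,
                      MoreArgs = list(pol = "ambiguous"))
  by_fl$total <- by_fl$ins + by_fl$del
  totals <- aggregate(by_fl[, c("ins", "del", "amb", "total")],
                      by = list(family = by_fl$family), FUN = sum)
  list(events = events, by_family_locus = by_fl, totals = totals)
}

#' Format family-unique counts as an ins/del/total table
#'
#' @param by_family_locus the \code{by_family_locus} component of
#'   \code{\link{family_unique}}.
#' @return character data.frame, families as rows, loci as columns, cells
#'   \code{"ins/del/total"} with \code{"-"} for empty cells.
#' @export
family_indel_table <- function(by_family_locus) {
  fams <- unique(by_family_locus$family)
  loci <- unique(by_family_locus$locus)
  fmt <- function(i, d, t) {
    if (t == 0L && i == 0L && d == 0L) return("-")
    sub0 <- function(x) if (x == 0L) "-" else as.character(x)
    paste(sub0(i), sub0(d), t, sep = "/")
  }
  out <- data.frame(family = fams, stringsAsFactors = FALSE)
  for (loc in loci) {
    out[[loc]] <- vapply(fams, function(f) {
      r <- by_family_locus[by_family_locus$family == f &
                             by_family_locus$locus == loc, ]
      fmt(r$ins[1L], r$del[1L], r$total[1L])
    }, "")
  }
  out
}

#' Simple indel coding (SIC) character matrix
#'
#' One binary presence/absence character per event: taxa whose gap run
#' exactly matches the event's columns score 1, taxa whose own gap run
#' strictly contains those columns score \code{?} (inapplicable), everything
#' else scores 0.
#'
#' @param events \code{indel_events}.
#' @param aln the alignment the events came from.
#' @return character matrix (taxa x events) over \{"0","1","?"\}; event ids
#'   as column names.
#' @export
encode_sic <- function(events, aln) {
  aln <- as_alignment_matrix(aln)
  taxa <- rownames(aln)
  m <- matrix("0", nrow = nrow(aln), ncol = nrow(events),
              dimnames = list(taxa, if (nrow(events)) paste0("e", events$id)))
  if (nrow(events) == 0L) return(m)
  runs_of <- lapply(seq_len(nrow(aln)), function(i) gap_runs(aln[i, ]))
  for (k in seq_len(nrow(events))) {
    s <- events$start[k] + 1L; e <- events$end[k]   # 1-based inclusive
    for (i in seq_along(taxa)) {
      runs <- runs_of[[i]]
      if (nrow(runs) == 0L) next
      exact <- any(runs[, 1L] == s & runs[, 2L] == e)
      strict <- any(runs[, 1L] <= s & runs[, 2L] >= e &
                      (runs[, 1L] < s | runs[, 2L] > e))
      if (exact) m[i, k] <- "1" else if (strict) m[i, k] <- "?"
    }
  }
  m
}
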