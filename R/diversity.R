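# Sliding-window nucleotide diversity (pi) and highly-polymorphic-region calls.

#' Read an aligned FASTA into a character matrix
#'
#' @param path aligned FASTA file (gaps as \code{-}).
#' @return character matrix, rows = sequences (rownames = taxa), columns =
#'   alignment positions, uppercase.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  as_alignment_matrix(setNames(toupper(as.character(ss)), names(ss)))
}

#' Write a character-matrix alignment as FASTA
#'
#' @param aln character matrix (rows = taxa).
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(apply(aln, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
}

as_alignment_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "character"
    return(x)
  }
  if (is.list(x)) x <- unlist(x)
  lens <- nchar(x)
  if (length(unique(lens)) != 1L)
    stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  m
}

# Per-column counts of A/C/G/T and validity (no gap/N anywhere in the column).
column_stats <- function(aln) {
  n <- nrow(aln)
  counts <- sapply(c("A", "C", "G", "T"), function(b) colSums(aln == b))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  valid <- rowSums(counts) == n
  # pairwise differences contributed by each column among its n bases
  pd <- choose(n, 2L) - rowSums(choose(counts, 2L))
  list(valid = valid, pairdiff = pd, n = n)
}

#' Nucleotide diversity (pi) of an alignment
#'
#' pi is the average proportion of differing sites over all sequence pairs:
#' \eqn{\pi = \sum_{i<j} d_{ij} / (C(n,2) L_{eff})} under
#' \code{exclude-columns} (columns containing any gap or N are dropped before
#' counting, the DnaSP complete-deletion analogue), or the mean per-pair
#' proportion over pairwise-complete sites under \code{pairwise-delete}.
#' No multiple-hit (Jukes-Cantor) correction is applied.
#'
#' @param aln character matrix (or named character vector) of equal-length
#'   aligned sequences.
#' @param gap_policy \code{"exclude-columns"} (default) or
#'   \code{"pairwise-delete"}.
#' @return pi in substitutions/site, or \code{NA} when no effective sites
#'   remain.
#' @export
nucleotide_diversity <- function(aln, gap_policy = c("exclude-columns",
                                                     "pairwise-delete")) {
  gap_policy <- match.arg(gap_policy)
  aln <- as_alignment_matrix(aln)
  n <- nrow(aln)
  if (n < 2L) stop("nucleotide_diversity: need at least 2 sequences")
  if (gap_policy == "exclude-columns") {
    cs <- column_stats(aln)
    l_eff <- sum(cs$valid)
    if (l_eff == 0L) return(NA_real_)
    sum(cs$pairdiff[cs$valid]) / (choose(n, 2L) * l_eff)
  } else {
    ok <- aln %in% c("A", "C", "G", "T")
    dim(ok) <- dim(aln)
    vals <- numeric(0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      lij <- sum(both)
      if (lij == 0L) next
      vals <- c(vals, sum(aln[i, both] != aln[j, both]) / lij)
    }
    if (length(vals) == 0L) return(NA_real_)
    mean(vals)
  }
}

#' Sliding-window nucleotide diversity profile
#'
#' One window per step; the trailing partial window is dropped.  Window
#' coordinates are 0-based half-open alignment columns.
#'
#' @param aln alignment as for \code{\link{nucleotide_diversity}}.
#' @param window window length in alignment columns (default 600).
#' @param step step in columns (default 200); \code{0 < step <= window}.
#' @param gap_policy gap handling, as for \code{\link{nucleotide_diversity}}.
#' @return data.frame of class \code{diversity_profile}: start, end, mid,
#'   n_effective_sites, pi.
#' @export
sliding_pi <- function(aln, window = 600L, step = 200L,
                       gap_policy = c("exclude-columns", "pairwise-delete")) {
  gap_policy <- match.arg(gap_policy)
  aln <- as_alignment_matrix(aln)
  L <- ncol(aln)
  if (step <= 0L || step > window) stop("sliding_pi: need 0 < step <= window")
  if (L < window) stop("sliding_pi: alignment shorter than one window")
  starts <- seq.int(0L, L - window, by = step)
  if (gap_policy == "exclude-columns") {
    cs <- column_stats(aln)
    cum_valid <- c(0L, cumsum(cs$valid))
    cum_pd <- c(0, cumsum(ifelse(cs$valid, cs$pairdiff, 0)))
    npairs <- choose(cs$n, 2L)
    l_eff <- cum_valid[starts + window + 1L] - cum_valid[starts + 1L]
    pdsum <- cum_pd[starts + window + 1L] - cum_pd[starts + 1L]
    pi <- ifelse(l_eff > 0L, pdsum / (npairs * l_eff), NA_real_)
  } else {
    l_eff <- integer(length(starts)); pi <- numeric(length(starts))
    for (w in seq_along(starts)) {
      sub <- aln[, (starts[w] + 1L):(starts[w] + window), drop = FALSE]
      pi[w] <- nucleotide_diversity(sub, gap_policy = "pairwise-delete")
      l_eff[w] <- window
    }
  }
  structure(data.frame(start = starts, end = starts + window,
                       mid = starts + window / 2,
                       n_effective_sites = as.integer(l_eff), pi = pi),
            class = c("diversity_profile", "data.frame"))
}

parse_hpr_rule <- function(rule) {
  if (is.list(rule)) return(rule)
  parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
  list(type = parts[1L],
       value = if (length(parts) > 1L) as.numeric(parts[2L]) else NA_real_)
}

#' Call highly polymorphic regions from a diversity profile
#'
#' Windows passing the rule are merged into maximal intervals when they
#' overlap or touch; each merged interval is one HPR call.  Rules:
#' \code{"zscore:k"} (pi > mean + k sd over the profile; no calls when sd is
#' zero), \code{"absolute:t"} (pi > t), \code{"top:n"} (the n highest-pi
#' windows).
#'
#' @param profile output of \code{\link{sliding_pi}}.
#' @param rule rule string (default \code{"zscore:2"}) or an equivalent
#'   \code{list(type=, value=)}.
#' @param loci optional locus annotation data.frame (label, start, end in
#'   alignment columns) used to label calls.
#' @return data.frame of class \code{hpr_calls}: start, end, peak_pi,
#'   mean_pi, n_windows, locus, region.
#' @export
call_hprs <- function(profile, rule = "zscore:2", loci = NULL) {
  if (nrow(profile) == 0L) stop("call_hprs: empty profile")
  r <- parse_hpr_rule(rule)
  pi <- profile$pi
  ok <- !is.na(pi)
  pass <- rep(FALSE, nrow(profile))
  if (r$type == "zscore") {
    mu <- mean(pi[ok]); s <- sd(pi[ok])
    if (is.na(s) || s == 0) return(empty_hpr_calls())
    pass[ok] <- pi[ok] > mu + r$value * s
  } else if (r$type == "absolute") {
    pass[ok] <- pi[ok] > r$value
  } else if (r$type == "top") {
    k <- min(as.integer(r$value), sum(ok))
    if (k > 0L) pass[order(-pi)[seq_len(k)]] <- TRUE
  } else stop("call_hprs: unknown rule type '", r$type, "'")
  if (!any(pass)) return(empty_hpr_calls())
  q <- profile[pass, , drop = FALSE]
  q <- q[order(q$start), , drop = FALSE]
  # merge overlapping/adjacent window intervals
  grp <- cumsum(c(TRUE, q$start[-1L] > cummax(q$end[-nrow(q)])))
  rows <- lapply(split(q, grp), function(g) data.frame(
    start = min(g$start), end = max(g$end), peak_pi = max(g$pi),
    mean_pi = mean(g$pi), n_windows = nrow(g),
    locus = NA_character_, region = NA_character_, stringsAsFactors = FALSE))
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  if (!is.null(loci)) {
    calls$locus <- vapply(seq_len(nrow(calls)), function(i) {
      hit <- loci$label[loci$end > calls$start[i] & loci$start < calls$end[i]]
      if (length(hit) == 0L) NA_character_ else paste(hit, collapse = "-")
    }, "")
  }
  structure(calls, class = c("hpr_calls", "data.frame"))
}

empty_hpr_calls <- function() {
  structure(data.frame(start = integer(0), end = integer(0),
                       peak_pi = numeric(0), mean_pi = numeric(0),
                       n_windows = integer(0), locus = character(0),
                       region = character(0), stringsAsFactors = FALSE),
            class = c("hpr_calls", "data.frame"))
}

#' Assign HPR calls to plastome regions
#'
#' Labels each call LSC, SSC or IR by majority base-pair overlap of its mapped
#' genome interval; ties break in the order LSC, SSC, IR.  Calls whose columns
#' are entirely unmappable get \code{NA}.
#'
#' @param calls output of \code{\link{call_hprs}}.
#' @param column_map integer vector, one genome coordinate (0-based) per
#'   alignment column, \code{NA} where unmappable; must be monotone over
#'   mapped columns.
#' @param regions a \code{\link{region_map}}.
#' @return \code{calls} with the \code{region} column filled.
#' @export
assign_region <- function(calls, column_map, regions) {
  L <- regions$genome_length
  memb <- rep(NA_character_, L)
  for (lab in c("lsc", "irb", "ssc", "ira")) {
    p <- region_pieces(regions[[lab]], L)
    for (i in seq_len(nrow(p)))
      memb[seq.int(p[i, 1L] + 1L, p[i, 2L])] <-
        if (lab %in% c("irb", "ira")) "IR" else toupper(lab)
  }
  mapped <- !is.na(column_map)
  if (any(mapped) && is.unsorted(column_map[mapped]))
    stop("assign_region: column map is not monotone")
  calls$region <- vapply(seq_len(nrow(calls)), function(i) {
    cols <- seq.int(calls$start[i] + 1L, calls$end[i])
    g <- column_map[cols]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_character_)
    tab <- table(factor(memb[g + 1L], levels = c("LSC", "SSC", "IR")))
    names(tab)[which.max(tab)]
  }, "")
  calls
}

#' Loci called as HPRs in two or more groups
#'
#' @param calls_by_group named list, one \code{\link{call_hprs}} result per
#'   group; calls must carry locus labels.
#' @return data.frame: locus, n_groups, groups (comma-separated), sorted by
#'   descending sharing count.
#' @export
shared_hprs <- function(calls_by_group) {
  rows <- list()
  for (g in names(calls_by_group)) {
    loci <- unique(calls_by_group[[g]]$locus)
    loci <- loci[!is.na(loci)]
    for (l in loci)
      rows[[length(rows) + 1L]] <- data.frame(group = g, locus = l,
                                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(locus = character(0), n_groups = integer(0),
                      groups = character(0), stringsAsFactors = FALSE))
  long <- do.call(rbind, rows)
  agg <- lapply(split(long$group, long$locus), function(gs)
    data.frame(n_groups = length(unique(gs)),
               groups = paste(sort(unique(gs)), collapse = ","),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out$locus <- names(agg)
  out <- out[out$n_groups >= 2L, c("locus", "n_groups", "groups"), drop = FALSE]
  rownames(out) <- NULL
  out[order(-out$n_groups, out$locus), , drop = FALSE]
}
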