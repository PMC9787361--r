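# Quadripartite region inference and per-region summaries.

#' Construct a quadripartite region map
#'
#' Intervals are 0-based half-open in genome coordinates.  The four intervals
#' tile the circle exactly once; an interval whose end exceeds the genome
#' length wraps the origin (unrolled coordinates).
#'
#' @param lsc,irb,ssc,ira length-2 integer vectors (start, end).
#' @param genome_length genome size in bp.
#' @return an object of class \code{region_map}.
#' @export
region_map <- function(lsc, irb, ssc, ira, genome_length) {
  m <- structure(list(lsc = as.integer(lsc), irb = as.integer(irb),
                      ssc = as.integer(ssc), ira = as.integer(ira),
                      genome_length = as.integer(genome_length)),
                 class = "region_map")
  lens <- vapply(m[c("lsc", "irb", "ssc", "ira")],
                 function(iv) iv[2L] - iv[1L], 0L)
  if (sum(lens) != genome_length)
    stop("region_map: regions do not tile the genome (",
         sum(lens), " vs ", genome_length, ")")
  if (lens[["irb"]] != lens[["ira"]])
    stop("region_map: IR copies of unequal length")
  m
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d bp: LSC [%d,%d) IRb [%d,%d) SSC [%d,%d) IRa [%d,%d)\n",
              x$genome_length, x$lsc[1], x$lsc[2], x$irb[1], x$irb[2],
              x$ssc[1], x$ssc[2], x$ira[1], x$ira[2]))
  invisible(x)
}

region_length <- function(iv) iv[2L] - iv[1L]

# Linear pieces of a region interval within [0, L)
region_pieces <- function(iv, L) {
  if (iv[2L] <= L) matrix(iv, ncol = 2L)
  else rbind(c(iv[1L], L), c(0L, iv[2L] - L))
}

# All maximal disjoint reverse-complement repeat pairs of length >= k found by
# an exact k-mer anti-diagonal scan.  Returns a data.frame
# (start1, start2, length), 0-based, start1 < start2, copies disjoint.
find_ir_candidates <- function(sequence, min_len, k = 25L) {
  L <- nchar(sequence)
  if (L < 2L * k) return(NULL)
  k <- min(k, min_len)
  n <- L - k + 1L
  kF <- substring(sequence, 1:n, k:L)
  rc <- revcomp(sequence)
  kR <- substring(rc, 1:n, k:L)
  idx <- split(seq_len(n), kR)
  hits <- idx[kF]
  ii <- rep.int(seq_len(n), lengths(hits))
  jj <- unlist(hits, use.names = FALSE)
  if (length(ii) == 0L) return(NULL)
  if (length(ii) > 5e6) stop("infer_regions: repeat structure too dense")
  # position j (1-based) in revcomp corresponds to forward start s2 = L-j-k+2
  s2 <- L - jj - k + 2L
  d <- ii + s2                      # constant along an inverted-repeat diagonal
  o <- order(d, ii)
  ii <- ii[o]; s2 <- s2[o]; d <- d[o]
  run_break <- c(TRUE, d[-1] != d[-length(d)] | ii[-1] != ii[-length(ii)] + 1L)
  run_id <- cumsum(run_break)
  f1 <- tapply(ii, run_id, min)
  f2 <- tapply(ii, run_id, max)
  len <- f2 - f1 + k
  # second-copy start for the run (smallest s2 corresponds to largest i)
  r1 <- tapply(s2, run_id, min)
  a <- pmin(f1, r1); b <- pmax(f1, r1)
  cand <- data.frame(start1 = as.integer(a - 1L), start2 = as.integer(b - 1L),
                     length = as.integer(len))
  cand <- unique(cand)
  keep <- cand$length >= min_len &
    cand$start1 + cand$length <= cand$start2 &            # disjoint
    cand$start2 + cand$length <= L
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand[order(-cand$length, cand$start1, cand$start2), , drop = FALSE]
}

#' Infer the quadripartite region map of a plastome
#'
#' Finds the maximal-length pair of disjoint reverse-complement repeats of at
#' least \code{min_ir} bp and labels them IRb/IRa; the larger single-copy
#' segment becomes the LSC and the smaller the SSC.  The IR whose downstream
#' neighbour (in rotation order) is the SSC is IRb.  Ties in repeat length are
#' broken by the lexicographically smallest (start1, start2) pair.
#'
#' @param record a \code{\link{plastome_record}}.
#' @param min_ir minimum IR length in bp (default 1000).
#' @return a \code{\link{region_map}}, or \code{NULL} with a warning when no
#'   repeat of at least \code{min_ir} bp exists (the record is IR-lacking).
#' @export
infer_regions <- function(record, min_ir = 1000L) {
  cand <- find_ir_candidates(record$sequence, min_ir)
  if (is.null(cand) || nrow(cand) == 0L) {
    warning("no IR detected in ", record$id, " (>= ", min_ir, " bp)")
    return(NULL)
  }
  best <- cand[1L, ]
  L <- nchar(record$sequence)
  len <- best$length
  c1 <- c(best$start1, best$start1 + len)   # first copy in coordinate order
  c2 <- c(best$start2, best$start2 + len)
  mid <- c(c1[2L], c2[1L])                  # segment between the copies
  out <- c(c2[2L], c1[1L] + L)              # wrapping segment
  mid_len <- region_length(mid)
  out_len <- L - 2L * len - mid_len
  if (mid_len <= out_len) {
    # mid is SSC: downstream neighbour of copy1 is SSC -> copy1 = IRb.
    # LSC is the wrapping segment, stored unrolled (start reduced mod L).
    if (out[1L] >= L) out <- out - L
    region_map(lsc = out, irb = c1, ssc = mid, ira = c2, genome_length = L)
  } else {
    # mid is LSC: downstream neighbour of copy2 wraps into out = SSC -> copy2 = IRb.
    # IRa (= copy1) stored unrolled so the rotation order LSC, IRb, SSC, IRa holds.
    region_map(lsc = mid, irb = c2, ssc = out, ira = c1 + L, genome_length = L)
  }
}

#' Rotate a record to the canonical LSC-first presentation
#'
#' Rotates the sequence, features and region map so the LSC starts at
#' position 0 and the rotation order is LSC, IRb, SSC, IRa.  Features crossing
#' the new origin become unrolled wrapping exons.
#'
#' @param record a \code{\link{plastome_record}} with regions present.
#' @return the rotated record.
#' @export
canonicalize_record <- function(record) {
  if (is.null(record$regions)) stop("canonicalize_record: regions not inferred")
  m <- record$regions
  L <- m$genome_length
  shift <- m$lsc[1L] %% L
  if (shift == 0L && m$lsc[2L] <= L) return(record)
  rot <- function(p) (p - shift) %% L
  sq <- paste0(substring(record$sequence, shift + 1L, L),
               substring(record$sequence, 1L, shift))
  feats <- lapply(record$features, function(f) {
    ex <- f$exons
    for (i in seq_len(nrow(ex))) {
      w <- ex[i, 2L] - ex[i, 1L]
      s <- rot(ex[i, 1L])
      ex[i, ] <- c(s, s + w)
    }
    f$exons <- ex
    f
  })
  shift_iv <- function(iv) {
    w <- iv[2L] - iv[1L]
    s <- rot(iv[1L])
    c(s, s + w)
  }
  m2 <- region_map(shift_iv(m$lsc), shift_iv(m$irb), shift_iv(m$ssc),
                   shift_iv(m$ira), L)
  plastome_record(record$id, record$taxon, sq, feats,
                  family = record$family, regions = m2)
}

gc_percent <- function(s) {
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) return(NA_real_)
  100 * sum(counts[c("G", "C")]) / denom
}

region_sequence <- function(record, iv) {
  L <- nchar(record$sequence)
  paste(apply(region_pieces(iv, L), 1L, function(p)
    substring(record$sequence, p[1L] + 1L, p[2L])), collapse = "")
}

#' Summarize a plastome record
#'
#' Lengths (total and per region, IR reported as one copy) and GC percentages.
#' GC\% is 100 (G+C)/(A+C+G+T); N bases are excluded from the denominator so
#' the figure reflects composition, not coverage.
#'
#' @param record a \code{\link{plastome_record}} with regions present.
#' @return one-row data.frame: id, taxon, family, total/LSC/IR/SSC lengths and
#'   total/LSC/IR/SSC GC percentages.
#' @export
summarize_plastome <- function(record) {
  if (is.null(record$regions)) stop("summarize_plastome: regions not inferred")
  m <- record$regions
  data.frame(
    id = record$id, taxon = record$taxon, family = record$family,
    total_bp = nchar(record$sequence),
    lsc_bp = region_length(m$lsc), ir_bp = region_length(m$irb),
    ssc_bp = region_length(m$ssc),
    gc_total = gc_percent(record$sequence),
    gc_lsc = gc_percent(region_sequence(record, m$lsc)),
    gc_ir = gc_percent(region_sequence(record, m$irb)),
    gc_ssc = gc_percent(region_sequence(record, m$ssc)),
    stringsAsFactors = FALSE)
}

#' Summarize a set of plastome records
#'
#' @param records list of \code{\link{plastome_record}} objects (regions
#'   present).
#' @param taxonomy optional taxonomy data.frame used to fill families.
#' @return data.frame, one row per record, mirroring the per-taxon size/GC
#'   summary table.
#' @export
plastome_summary_table <- function(records, taxonomy = NULL) {
  rows <- lapply(records, function(r) {
    if (!is.null(taxonomy) && r$taxon %in% taxonomy$taxon)
      r$family <- taxonomy$family[match(r$taxon, taxonomy$taxon)]
    summarize_plastome(r)
  })
  do.call(rbind, rows)
}
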