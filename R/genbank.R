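# GenBank-dialect flat-file I/O for annotated plastome records.
#
# Coordinates are 0-based half-open internally; the 1-based inclusive flat-file
# convention is converted at this boundary only.  An exon whose end exceeds the
# genome length is an origin-wrapping exon in unrolled coordinates.

#' Reverse complement of a DNA string
#'
#' @param s character scalar over A, C, G, T, N (case preserved as upper).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

#' Construct a gene feature
#'
#' @param name gene symbol (isoacceptor suffixes such as \code{-GUG} are
#'   significant for tRNAs).
#' @param kind one of \code{"PCG"}, \code{"tRNA"}, \code{"rRNA"}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons two-column matrix (start, end), 0-based half-open genome
#'   coordinates, ordered 5' to 3' on the plus strand; \code{end} may exceed the
#'   genome length for a feature wrapping the circular origin.
#' @param pseudo logical; a pseudogene or IR-copy fragment.
#' @return an object of class \code{gene_feature}.
#' @export
gene_feature <- function(name, kind = c("PCG", "tRNA", "rRNA"), strand = "+",
                         exons, pseudo = FALSE) {
  kind <- match.arg(kind)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene_feature: exons must be non-empty for ", name)
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("gene_feature: empty or inverted exon interval in ", name)
  structure(list(name = name, kind = kind, strand = strand,
                 exons = exons, pseudo = isTRUE(pseudo)),
            class = "gene_feature")
}

#' Construct a plastome record
#'
#' @param id accession-like identifier.
#' @param taxon taxon name.
#' @param sequence DNA string over A, C, G, T, N.
#' @param features list of \code{\link{gene_feature}} objects.
#' @param family family name or \code{NA}.
#' @param regions a \code{region_map} (see \code{\link{infer_regions}}) or
#'   \code{NULL} until inferred.
#' @return an object of class \code{plastome_record}.
#' @export
plastome_record <- function(id, taxon, sequence, features = list(),
                            family = NA_character_, regions = NULL) {
  sequence <- toupper(sequence)
  if (!is.null(regions) && regions$genome_length != nchar(sequence))
    stop("plastome_record: sequence length disagrees with region map")
  structure(list(id = id, taxon = taxon, family = family,
                 sequence = sequence, features = features, regions = regions),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s (%s), %d bp, %d features%s\n",
              x$id, x$taxon, nchar(x$sequence), length(x$features),
              if (is.null(x$regions)) "" else ", regions inferred"))
  invisible(x)
}

# Linear pieces of a (possibly origin-wrapping) exon set, as a two-column
# matrix of 0-based half-open intervals all within [0, L).
feature_pieces <- function(feature, L) {
  out <- NULL
  for (i in seq_len(nrow(feature$exons))) {
    s <- feature$exons[i, 1L]; e <- feature$exons[i, 2L]
    if (e <= L) {
      out <- rbind(out, c(s, e))
    } else {
      out <- rbind(out, c(s, L), c(0L, e - L))
    }
  }
  out
}

feature_span_length <- function(feature) {
  sum(feature$exons[, 2L] - feature$exons[, 1L])
}

# ---- location strings -------------------------------------------------------

# Parse a GenBank location string into (strand, exon matrix).  Handles
# complement(...) and join(...); join segments that are circularly contiguous
# (prev ends at genome length, next starts at 1) are merged into one unrolled
# wrapping exon.
parse_location <- function(loc, L, what = "feature") {
  strand <- "+"
  loc <- gsub("[[:space:]]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ivs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", p))[[1]]
    if (length(m) == 3L) return(as.integer(m[2:3]))
    m <- regmatches(p, regexec("^([0-9]+)$", p))[[1]]
    if (length(m) == 2L) return(rep(as.integer(m[2]), 2L))
    stop("malformed coordinates in ", what, ": '", p, "'")
  })
  ex <- do.call(rbind, ivs)
  if (any(ex[, 2L] < ex[, 1L]))
    stop("malformed coordinates in ", what, ": end before start")
  # 1-based inclusive -> 0-based half-open
  ex[, 1L] <- ex[, 1L] - 1L
  # merge circularly contiguous segments into a wrapping exon
  if (nrow(ex) >= 2L) {
    merged <- list(ex[1L, ])
    for (i in 2L:nrow(ex)) {
      prev <- merged[[length(merged)]]
      if (prev[2L] == L && ex[i, 1L] == 0L) {
        merged[[length(merged)]] <- c(prev[1L], L + ex[i, 2L])
      } else {
        merged[[length(merged) + 1L]] <- ex[i, ]
      }
    }
    ex <- do.call(rbind, merged)
  }
  list(strand = strand, exons = ex)
}

format_location <- function(strand, exons, L) {
  segs <- character(0)
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1L]; e <- exons[i, 2L]
    if (e <= L) {
      segs <- c(segs, sprintf("%d..%d", s + 1L, e))
    } else {
      segs <- c(segs, sprintf("%d..%d", s + 1L, L), sprintf("1..%d", e - L))
    }
  }
  loc <- if (length(segs) > 1L) sprintf("join(%s)", paste(segs, collapse = ",")) else segs
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

# ---- parsing ----------------------------------------------------------------

#' Parse GenBank-style flat-file plastome records
#'
#' Reads a minimal GenBank dialect (LOCUS / DEFINITION / FEATURES / ORIGIN).
#' Feature keys \code{CDS}, \code{tRNA}, \code{rRNA} and \code{gene} are
#' captured; names come from the \code{/gene} qualifier, multi-exon structure
#' from \code{join()} locations, and \code{/pseudo} marks pseudogenes.  A
#' \code{join} crossing the circular origin becomes a single unrolled exon.
#'
#' @param text character: either a file path or the record text itself (a
#'   vector of lines or a single string).
#' @return a \code{\link{plastome_record}}, or a list of them when the input
#'   holds several \code{//}-terminated records.
#' @export
parse_plastome <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  # split on record terminator
  ends <- grep("^//", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- list()
  for (r in seq_along(ends)) {
    chunk <- lines[starts[r]:ends[r]]
    if (!any(grepl("^LOCUS", chunk))) next
    recs[[length(recs) + 1L]] <- parse_one_record(chunk)
  }
  if (length(recs) == 0L) stop("parse_plastome: no LOCUS record found")
  if (length(recs) == 1L) recs[[1L]] else recs
}

parse_one_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1]]
  id <- toks[2]
  L <- suppressWarnings(as.integer(toks[3]))
  def <- grep("^DEFINITION", lines, value = TRUE)
  taxon <- if (length(def)) sub("\\.?$", "", sub("^DEFINITION\\s+", "", def[1])) else id

  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("parse_plastome: record ", id, " lacks ORIGIN sequence")
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("parse_plastome: record ", id, " has empty sequence")
  if (is.na(L)) L <- nchar(sequence)
  if (nchar(sequence) != L)
    stop("parse_plastome: record ", id, " sequence length ", nchar(sequence),
         " disagrees with LOCUS length ", L)

  fstart <- grep("^FEATURES", lines)
  features <- list()
  if (length(fstart)) {
    flines <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # group into feature blocks: key lines have text in columns 6-20
    key_idx <- grep("^\\s{1,10}[A-Za-z'_0-9]+\\s{2,}", flines)
    key_idx <- key_idx[!grepl("^\\s{21}", flines[key_idx])]
    for (ki in seq_along(key_idx)) {
      from <- key_idx[ki]
      to <- if (ki < length(key_idx)) key_idx[ki + 1L] - 1L else length(flines)
      block <- flines[from:to]
      key <- sub("^\\s*([A-Za-z'_0-9]+).*$", "\\1", block[1])
      if (!key %in% c("CDS", "tRNA", "rRNA", "gene")) next
      # location may continue over lines until first qualifier
      qual_at <- grep("^\\s+/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      loc <- paste(trimws(sub("^\\s*[A-Za-z'_0-9]+\\s+", "", block[1])),
                   paste(trimws(block[seq_len(loc_end)][-1]), collapse = ""), sep = "")
      quals <- block[grepl("^\\s+/", block)]
      gname <- regmatches(quals, regexec("/gene=\"([^\"]+)\"", quals))
      gname <- unlist(lapply(gname, function(m) if (length(m) == 2L) m[2] else NULL))
      if (length(gname) == 0L) next
      pseudo <- any(grepl("^\\s+/pseudo\\s*$", quals))
      kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     gene = infer_kind(gname[1]))
      pl <- parse_location(loc, L, what = paste0(key, " ", gname[1]))
      features[[length(features) + 1L]] <-
        gene_feature(gname[1], kind, pl$strand, pl$exons, pseudo)
    }
    # drop 'gene' duplicates of typed features at identical locations
    features <- dedupe_gene_features(features)
  }
  plastome_record(id = id, taxon = taxon, sequence = sequence, features = features)
}

infer_kind <- function(name) {
  if (grepl("^trn", name, ignore.case = TRUE)) "tRNA"
  else if (grepl("^rrn", name, ignore.case = TRUE)) "rRNA"
  else "PCG"
}

dedupe_gene_features <- function(features) {
  if (length(features) < 2L) return(features)
  sig <- vapply(features, function(f)
    paste(f$name, f$strand, paste(t(f$exons), collapse = ","), sep = "|"), "")
  features[!duplicated(sig)]
}

# ---- writing ----------------------------------------------------------------

#' Write a plastome record as a GenBank-dialect flat file
#'
#' Emits the minimal LOCUS/DEFINITION/FEATURES/ORIGIN dialect understood by
#' \code{\link{parse_plastome}}.  Used chiefly by the synthetic-data generator.
#'
#' @param record a \code{\link{plastome_record}}.
#' @param path output file, or \code{NULL} to return the text invisibly.
#' @return the record text, invisibly.
#' @export
write_plastome_genbank <- function(record, path = NULL) {
  L <- nchar(record$sequence)
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     circular PLN",
            record$id, L),
    sprintf("DEFINITION  %s.", record$taxon),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    sprintf("                     /organism=\"%s\"", record$taxon)
  )
  for (f in record$features) {
    key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA")
    out <- c(out,
             sprintf("     %-15s %s", key, format_location(f$strand, f$exons, L)),
             sprintf("                     /gene=\"%s\"", f$name))
    if (f$pseudo) out <- c(out, "                     /pseudo")
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substring(record$sequence, p, min(p + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  if (!is.null(path)) writeLines(out, path)
  invisible(paste(out, collapse = "\n"))
}

#' Read a taxon-to-family taxonomy table
#'
#' @param path TSV with header \code{taxon<TAB>family}.
#' @return data.frame with columns \code{taxon}, \code{family}; taxa unique.
#' @export
read_taxonomy <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("taxon", "family") %in% names(tab)))
    stop("read_taxonomy: expected columns 'taxon' and 'family'")
  if (anyDuplicated(tab$taxon)) stop("read_taxonomy: duplicated taxa")
  if (any(!nzchar(tab$family))) stop("read_taxonomy: empty family names")
  tab[, c("taxon", "family")]
}

family_of <- function(taxa, taxonomy) {
  fam <- taxonomy$family[match(taxa, taxonomy$taxon)]
  if (anyNA(fam)) stop("taxon not in taxonomy: ",
                       paste(taxa[is.na(fam)], collapse = ", "))
  fam
}
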