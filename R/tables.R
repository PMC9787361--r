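# Reading and summarising published-style family-specific indel tables with
# "ins/del/total" cells.

#' Read a family-specific indel table
#'
#' Parses a TSV whose first column is the family and whose remaining columns
#' hold \code{"ins/del/total"} cells (a bare \code{-} meaning none; \code{-}
#' tokens inside a cell meaning zero).  The packaged
#' \code{extdata/saxifragales_family_indels.tsv} reproduces the published
#' family-by-locus counts for the 17 intron-containing plastid genes of
#' Saxifragales (clpP and ycf3 split into their two introns a/b).
#'
#' @param path TSV path; default the packaged Saxifragales table.
#' @return long data.frame: family, locus, ins, del, total.
#' @export
read_family_indel_table <- function(path = system.file(
  "extdata", "saxifragales_family_indels.tsv", package = "plastcmp")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  loci <- setdiff(names(tab), c("family", "total"))
  parse_cell <- function(cell) {
    cell <- trimws(cell)
    if (cell == "-" || cell == "") return(c(0L, 0L, 0L))
    parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
    if (length(parts) != 3L) stop("malformed cell: '", cell, "'")
    vapply(parts, function(p) if (p == "-") 0L else as.integer(p), 0L,
           USE.NAMES = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(tab))) for (loc in loci) {
    v <- parse_cell(tab[[loc]][i])
    rows[[length(rows) + 1L]] <- data.frame(
      family = tab$family[i], locus = loc, ins = v[1L], del = v[2L],
      total = v[3L], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Summarize a family-specific indel table
#'
#' @param long output of \code{\link{read_family_indel_table}}.
#' @return list: \code{by_family} (family, ins, del, total),
#'   \code{grand_total}, \code{families_per_locus} (locus, n_families with at
#'   least one unique indel), and \code{consistent} (every cell's total equals
#'   ins + del).
#' @export
family_indel_summary <- function(long) {
  by_family <- aggregate(long[, c("ins", "del", "total")],
                         by = list(family = long$family), FUN = sum)
  fpl <- aggregate(long$total > 0L, by = list(locus = long$locus), FUN = sum)
  names(fpl)[2L] <- "n_families"
  list(by_family = by_family[order(by_family$family), ],
       grand_total = sum(long$total),
       families_per_locus = fpl,
       consistent = all(long$total == long$ins + long$del))
}
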