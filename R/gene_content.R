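# Gene- and intron-loss detection against a reference plastid inventory.

#' Reference plastid gene inventory
#'
#' The default inventory lists the 17 intron-containing plastid genes (five
#' tRNA genes and 12 protein-coding genes; clpP and ycf3 carry two introns
#' each, rps12 is the sole trans-spliced gene and only its 3' intron is
#' counted) plus the loss-prone single-exon genes infA and rpl32.
#'
#' @param path optional TSV overriding the default (columns: gene, kind,
#'   expected_introns, trans_spliced).
#' @return data.frame with columns gene, kind, expected_introns,
#'   trans_spliced.
#' @export
reference_gene_set <- function(path = NULL) {
  if (!is.null(path)) {
    ref <- read.delim(path, stringsAsFactors = FALSE)
    names(ref) <- tolower(names(ref))
    stopifnot(all(c("gene", "kind", "expected_introns", "trans_spliced") %in% names(ref)))
    if (anyDuplicated(ref$gene)) stop("reference_gene_set: duplicated gene names")
    return(ref)
  }
  ref <- rbind(
    data.frame(gene = c("trnA-UGC", "trnI-GAU", "trnK-UUU", "trnL-UAA", "trnV-UAC"),
               kind = "tRNA", expected_introns = 1L, trans_spliced = FALSE),
    data.frame(gene = c("atpF", "ndhA", "ndhB", "petB", "petD", "rpl16", "rpl2",
                        "rpoC1", "rps16"),
               kind = "PCG", expected_introns = 1L, trans_spliced = FALSE),
    data.frame(gene = c("clpP", "ycf3"), kind = "PCG", expected_introns = 2L,
               trans_spliced = FALSE),
    data.frame(gene = "rps12", kind = "PCG", expected_introns = 1L,
               trans_spliced = TRUE),
    data.frame(gene = c("infA", "rpl32"), kind = "PCG", expected_introns = 0L,
               trans_spliced = FALSE))
  ref
}

# Observed intron count for a gene given all same-name features.  For
# trans-spliced genes only the 3' exon cluster (the same-name feature with the
# most exons) is assessed; IR-duplicated copies otherwise report the maximum.
observed_introns <- function(features) {
  max(vapply(features, function(f) nrow(f$exons) - 1L, 0L))
}

gene_presence <- function(record, ref) {
  feats <- record$features
  fnames <- tolower(vapply(feats, function(f) f$name, ""))
  pseudo <- vapply(feats, function(f) f$pseudo, TRUE)
  present <- vapply(tolower(ref$gene), function(g) any(fnames == g & !pseudo), TRUE)
  pseudo_only <- vapply(tolower(ref$gene),
                        function(g) any(fnames == g) && !any(fnames == g & !pseudo),
                        TRUE)
  data.frame(gene = ref$gene, present = unname(present),
             pseudo_only = unname(pseudo_only), stringsAsFactors = FALSE)
}

#' Detect gene losses relative to the reference inventory
#'
#' A gene is present iff at least one non-pseudo feature bears its name
#' (case-insensitive; tRNA isoacceptor suffixes are significant), so
#' IR-duplicated copies never double-count.  Genes annotated only as
#' pseudogenes are reported separately, not as losses.
#'
#' @param record a \code{\link{plastome_record}}.
#' @param ref reference inventory from \code{\link{reference_gene_set}}.
#' @return list with components \code{missing} (character vector) and
#'   \code{pseudo} (genes present only as pseudo-annotations).
#' @export
detect_gene_losses <- function(record, ref = reference_gene_set()) {
  pres <- gene_presence(record, ref)
  list(missing = pres$gene[!pres$present & !pres$pseudo_only],
       pseudo = pres$gene[pres$pseudo_only])
}

#' Detect intron losses relative to the reference inventory
#'
#' Reports every reference gene whose observed intron count (exons minus one;
#' trans-spliced genes assessed on the 3' exon cluster only) falls short of
#' the expected count.  Absent genes are gene losses, not intron losses, and
#' are excluded here.
#'
#' @inheritParams detect_gene_losses
#' @return data.frame: gene, expected, observed (possibly zero rows).
#' @export
detect_intron_losses <- function(record, ref = reference_gene_set()) {
  feats <- record$features
  fnames <- tolower(vapply(feats, function(f) f$name, ""))
  pseudo <- vapply(feats, function(f) f$pseudo, TRUE)
  rows <- list()
  for (i in seq_len(nrow(ref))) {
    if (ref$expected_introns[i] == 0L) next
    g <- tolower(ref$gene[i])
    hits <- feats[fnames == g & !pseudo]
    if (length(hits) == 0L) next
    obs <- observed_introns(hits)
    if (obs < ref$expected_introns[i])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ref$gene[i], expected = ref$expected_introns[i],
        observed = obs, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(0), expected = integer(0),
                      observed = integer(0)))
  do.call(rbind, rows)
}

#' Per-record loss report
#'
#' @inheritParams detect_gene_losses
#' @return list of class \code{loss_report}: id, taxon, missing_genes,
#'   pseudo_genes, intron_losses.
#' @export
loss_report <- function(record, ref = reference_gene_set()) {
  gl <- detect_gene_losses(record, ref)
  structure(list(id = record$id, taxon = record$taxon,
                 missing_genes = gl$missing, pseudo_genes = gl$pseudo,
                 intron_losses = detect_intron_losses(record, ref)),
            class = "loss_report")
}

#' Aggregate loss reports into a family-by-gene table
#'
#' @param reports list of \code{\link{loss_report}} objects.
#' @param taxonomy taxonomy data.frame (taxon, family).
#' @return list with \code{gene_loss} and \code{intron_loss} data.frames
#'   (family, gene, n_lost, n_records, universal) where \code{universal}
#'   flags losses shared by every record of the family.
#' @export
aggregate_losses <- function(reports, taxonomy) {
  fams <- family_of(vapply(reports, function(r) r$taxon, ""), taxonomy)
  fam_sizes <- table(fams)
  tally <- function(extract) {
    rows <- list()
    for (i in seq_along(reports)) {
      for (g in extract(reports[[i]]))
        rows[[length(rows) + 1L]] <- data.frame(family = fams[i], gene = g,
                                                stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
      return(data.frame(family = character(0), gene = character(0),
                        n_lost = integer(0), n_records = integer(0),
                        universal = logical(0)))
    long <- do.call(rbind, rows)
    agg <- aggregate(rep(1L, nrow(long)),
                     by = list(family = long$family, gene = long$gene), FUN = sum)
    names(agg)[3L] <- "n_lost"
    agg$n_records <- as.integer(fam_sizes[agg$family])
    agg$universal <- agg$n_lost == agg$n_records
    agg[order(agg$family, agg$gene), ]
  }
  list(gene_loss = tally(function(r) r$missing_genes),
       intron_loss = tally(function(r) r$intron_losses$gene))
}
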