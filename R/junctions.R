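# IR junction expansion/contraction profiling and family pattern typing.
#
# The four junctions, in canonical rotation order, are
#   JLB = LSC/IRb, JSB = IRb/SSC, JSA = SSC/IRa, JLA = IRa/LSC (circular origin).
# "Expansion" means the junction lies inside the focal gene's body (the IR has
# grown into the gene); "contraction" means the gene lies entirely on the
# single-copy side.  No ancestral IR length is assumed: the classification is
# purely geometric.

default_focal_genes <- function() {
  c(JLB = "rps19", JSB = "ndhF", JSA = "ycf1", JLA = "trnH-GUG")
}

circ_dist_point <- function(pieces, p, L) {
  d <- Inf
  for (i in seq_len(nrow(pieces))) {
    s <- pieces[i, 1L]; e <- pieces[i, 2L]
    if (p >= s && p <= e) return(0L)
    d <- min(d, (s - p) %% L, (p - e) %% L)
  }
  as.integer(d)
}

overlap_bp_pieces <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    tot <- tot + max(0L, min(a[i, 2L], b[j, 2L]) - max(a[i, 1L], b[j, 1L]))
  tot
}

#' Profile gene geometry at the four IR junctions
#'
#' For every junction the focal gene's position relative to the junction is
#' summarized: bases lying on the IR side (\code{overlap_bp}), the gap to the
#' junction when the gene does not reach it (\code{distance_bp}), and a state
#' in \{spans, abuts, single-copy-side, ir-side, pseudo-fragment,
#' gene-missing\}.  Truncated IR-copy duplicates annotated as pseudogenes are
#' reported as \code{pseudo-fragment} rows at their own junction.  Overlap is
#' measured on genome coordinates irrespective of strand; strand is used only
#' to locate the 3' terminus for the \code{three_prime_in_ir} column (the
#' trnH-GUG conservation check).
#'
#' @param record a \code{\link{plastome_record}} with regions present.
#' @param focal_genes named character vector mapping junctions JLB, JSB, JSA,
#'   JLA to gene names; defaults to rps19, ndhF, ycf1, trnH-GUG.
#' @return data.frame with one row per junction (plus pseudo-fragment rows):
#'   id, taxon, junction, position, gene, state, overlap_bp, distance_bp,
#'   three_prime_in_ir.
#' @export
junction_profile <- function(record, focal_genes = default_focal_genes()) {
  if (is.null(record$regions)) stop("junction_profile: regions not inferred")
  record <- canonicalize_record(record)
  m <- record$regions
  L <- m$genome_length
  jpos <- c(JLB = m$irb[1L], JSB = m$ssc[1L], JSA = m$ira[1L], JLA = L)
  ir_of <- list(JLB = m$irb, JSB = m$irb, JSA = m$ira, JLA = m$ira)

  rows <- list()
  add_row <- function(junction, gene, state, overlap, dist, tp = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = record$id, taxon = record$taxon, junction = junction,
      position = as.integer(jpos[[junction]] %% L), gene = gene, state = state,
      overlap_bp = overlap, distance_bp = dist, three_prime_in_ir = tp,
      stringsAsFactors = FALSE)
  }

  for (J in names(jpos)) {
    gname <- focal_genes[[J]]
    hits <- Filter(function(f) identical(tolower(f$name), tolower(gname)),
                   record$features)
    main <- Filter(function(f) !f$pseudo, hits)
    if (length(main) == 0L) {
      add_row(J, gname, "gene-missing", NA_integer_, NA_integer_)
      next
    }
    p <- jpos[[J]]
    ir_pieces <- region_pieces(ir_of[[J]], L)
    # nearest non-pseudo copy to this junction
    dists <- vapply(main, function(f)
      circ_dist_point(feature_pieces(f, L), p %% L, L), 0L)
    f <- main[[which.min(dists)]]
    pieces <- feature_pieces(f, L)
    glen <- feature_span_length(f)
    ov <- overlap_bp_pieces(pieces, ir_pieces)
    tp <- NA
    if (ov > 0L) {
      # does the 3'-terminal 3 bp sit inside this IR?
      ex <- f$exons
      tp3 <- if (f$strand == "+") c(ex[nrow(ex), 2L] - 3L, ex[nrow(ex), 2L])
             else c(ex[1L, 1L], ex[1L, 1L] + 3L)
      if (tp3[1L] >= L) tp3 <- tp3 - L
      tp <- overlap_bp_pieces(region_pieces(tp3, L), ir_pieces) == 3L
    }
    if (ov > 0L && ov < glen) {
      add_row(J, gname, "spans", as.integer(ov), 0L, tp)
    } else if (ov == glen) {
      add_row(J, gname, "ir-side", as.integer(ov), 0L, tp)
    } else {
      d <- circ_dist_point(pieces, p %% L, L)
      add_row(J, gname, if (d == 0L) "abuts" else "single-copy-side", 0L, d)
    }
  }

  # pseudo-fragments of any focal gene, attributed to their nearest junction
  for (f in Filter(function(f) f$pseudo, record$features)) {
    if (!tolower(f$name) %in% tolower(unname(focal_genes))) next
    pieces <- feature_pieces(f, L)
    dists <- vapply(names(jpos), function(J)
      circ_dist_point(pieces, jpos[[J]] %% L, L), 0L)
    J <- names(jpos)[which.min(dists)]
    ov <- overlap_bp_pieces(pieces, region_pieces(ir_of[[J]], L))
    rows[[length(rows) + 1L]] <- data.frame(
      id = record$id, taxon = record$taxon, junction = J,
      position = as.integer(jpos[[J]] %% L), gene = f$name,
      state = "pseudo-fragment", overlap_bp = as.integer(ov),
      distance_bp = as.integer(min(dists)), three_prime_in_ir = NA,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

state_to_expcon <- function(state) {
  if (state == "spans") "expansion"
  else if (state %in% c("single-copy-side", "abuts")) "contraction"
  else NA_character_
}

aggregate_expcon <- function(states) {
  states <- states[!is.na(states)]
  if (length(states) == 0L) return(NA_character_)
  if (all(states == "expansion")) "expansion"
  else if (all(states == "contraction")) "contraction"
  else "mixed"
}

#' Classify family-level junction patterns
#'
#' Aggregates each family's rps19-at-JLB and ndhF-at-JSB states (all expansion
#' -> expansion; all contraction -> contraction; any deviation -> mixed; no
#' majority rule) and assigns the six-way pattern id:
#' 1 = (expansion, contraction), 2 = (contraction, expansion),
#' 3 = (mixed, expansion), 4 = (expansion, expansion),
#' 5 = (contraction, contraction), 6 = (mixed, mixed).  Combinations outside
#' the six get \code{NA}.
#'
#' @param profiles row-bound output of \code{\link{junction_profile}} over
#'   several records.
#' @param taxonomy taxonomy data.frame (taxon, family).
#' @return data.frame: family, rps19_at_JLB, ndhF_at_JSB, n_records,
#'   pattern_id.
#' @export
classify_junction_patterns <- function(profiles, taxonomy) {
  main <- profiles[profiles$state != "pseudo-fragment", , drop = FALSE]
  main$family <- taxonomy$family[match(main$taxon, taxonomy$taxon)]
  if (anyNA(main$family))
    stop("classify_junction_patterns: taxa missing from taxonomy: ",
         paste(unique(main$taxon[is.na(main$family)]), collapse = ", "))
  pattern_key <- c("expansion|contraction" = 1L, "contraction|expansion" = 2L,
                   "mixed|expansion" = 3L, "expansion|expansion" = 4L,
                   "contraction|contraction" = 5L, "mixed|mixed" = 6L)
  out <- list()
  for (fam in unique(main$family)) {
    sub <- main[main$family == fam, , drop = FALSE]
    if (nrow(sub) == 0L) { warning("empty family skipped: ", fam); next }
    st_rps <- aggregate_expcon(vapply(
      sub$state[sub$junction == "JLB"], state_to_expcon, ""))
    st_ndh <- aggregate_expcon(vapply(
      sub$state[sub$junction == "JSB"], state_to_expcon, ""))
    key <- paste(st_rps, st_ndh, sep = "|")
    out[[fam]] <- data.frame(
      family = fam, rps19_at_JLB = st_rps, ndhF_at_JSB = st_ndh,
      n_records = length(unique(sub$id)),
      pattern_id = if (key %in% names(pattern_key)) pattern_key[[key]] else NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Check the two junction features conserved across plastomes
#'
#' Flags, per record: (a) ycf1 spans JSA with 400-1870 bp inside IRa, and
#' (b) exactly the 3'-terminal 3 bp of trnH-GUG lie inside IRa at JLA.
#'
#' @param profiles row-bound output of \code{\link{junction_profile}}.
#' @return data.frame: id, taxon, ycf1_jsa_conserved, trnh_3bp_in_ira.
#' @export
check_conserved_features <- function(profiles) {
  ids <- unique(profiles$id)
  rows <- lapply(ids, function(i) {
    sub <- profiles[profiles$id == i, , drop = FALSE]
    y <- sub[sub$junction == "JSA" & sub$state == "spans" &
               tolower(sub$gene) == "ycf1", , drop = FALSE]
    a <- nrow(y) > 0L && y$overlap_bp[1L] >= 400L && y$overlap_bp[1L] <= 1870L
    h <- sub[sub$junction == "JLA" & sub$state == "spans" &
               tolower(sub$gene) == "trnh-gug", , drop = FALSE]
    b <- nrow(h) > 0L && h$overlap_bp[1L] == 3L && isTRUE(h$three_prime_in_ir[1L])
    data.frame(id = i, taxon = sub$taxon[1L], ycf1_jsa_conserved = a,
               trnh_3bp_in_ira = b, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
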