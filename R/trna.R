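# Plastid tRNA cloverleaf decomposition, structural typing and a constrained
# cloverleaf folder.
#
# Input is predictor-agnostic: a sequence plus a dot-bracket string.  Arms are
# assigned positionally (first hairpin = D-arm, second = anticodon arm, last =
# T/psi-arm; the psi-arm is identified purely by position, no modified-base
# inference).  The variable (V) region is everything between the anticodon and
# T arms; Brennan-Sundaralingam typing calls 4-5 nt type I and >= 10 nt
# type II, with the 6-9 nt gap reported explicitly as "intermediate" rather
# than silently binned.

#' Construct a tRNA structure record
#'
#' @param sequence RNA string (T is converted to U).
#' @param structure dot-bracket string of equal length, balanced.
#' @param label isotype-anticodon label, e.g. \code{"tRNA-Ser-GCU"}.
#' @param taxon taxon name.
#' @return object of class \code{trna_structure}.
#' @export
trna_structure <- function(sequence, structure, label = NA_character_,
                           taxon = NA_character_) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  if (nchar(sequence) != nchar(structure))
    stop("trna_structure: sequence and structure lengths differ")
  structure(list(taxon = taxon, label = label, sequence = sequence,
                 structure = structure), class = "trna_structure")
}

#' Read tRNA structures from a TSV
#'
#' @param path TSV with columns taxon, label, sequence, structure (one row
#'   per tRNA, tRNAscan-SE-style sequence/dot-bracket pairs).
#' @return list of \code{\link{trna_structure}} objects.
#' @export
read_trna_structures <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  stopifnot(all(c("taxon", "label", "sequence", "structure") %in% names(tab)))
  lapply(seq_len(nrow(tab)), function(i)
    trna_structure(tab$sequence[i], tab$structure[i], tab$label[i], tab$taxon[i]))
}

#' Write tRNA structures to a TSV
#'
#' @param structs list of \code{\link{trna_structure}} objects.
#' @param path output TSV.
#' @export
write_trna_structures <- function(structs, path) {
  tab <- data.frame(
    taxon = vapply(structs, `[[`, "", "taxon"),
    label = vapply(structs, `[[`, "", "label"),
    sequence = vapply(structs, `[[`, "", "sequence"),
    structure = vapply(structs, `[[`, "", "structure"),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Pair map from a dot-bracket string; NA where unpaired.
pair_map <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  pm <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("structure-parse error: unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pm[i] <- j; pm[j] <- i
    } else if (ch[i] != ".") stop("structure-parse error: bad character '", ch[i], "'")
  }
  if (length(stack)) stop("structure-parse error: unbalanced brackets")
  pm
}

# Outermost pairs directly inside [from, to].
children_pairs <- function(pm, from, to) {
  out <- list()
  i <- from
  while (i <= to) {
    if (!is.na(pm[i]) && pm[i] > i) {
      out[[length(out) + 1L]] <- c(i, pm[i])
      i <- pm[i] + 1L
    } else i <- i + 1L
  }
  out
}

# Collapse a helix chain starting at pair (i, j): follow single-child pairs,
# recording bulges (unpaired stretches inside the helix), until a terminal
# loop (hairpin) or a multiloop (>= 2 children).
chain_collapse <- function(pm, i, j) {
  n_pairs <- 1L
  bulges <- list()
  repeat {
    ch <- children_pairs(pm, i + 1L, j - 1L)
    if (length(ch) == 0L)
      return(list(kind = "hairpin", n_pairs = n_pairs, bulges = bulges,
                  loop = c(i + 1L, j - 1L)))
    if (length(ch) >= 2L)
      return(list(kind = "multiloop", n_pairs = n_pairs, bulges = bulges,
                  children = ch))
    i2 <- ch[[1L]][1L]; j2 <- ch[[1L]][2L]
    if (i2 > i + 1L)
      bulges[[length(bulges) + 1L]] <- list(side = "5p", start = i + 1L,
                                            end = i2 - 1L)
    if (j2 < j - 1L)
      bulges[[length(bulges) + 1L]] <- list(side = "3p", start = j2 + 1L,
                                            end = j - 1L)
    i <- i2; j <- j2
    n_pairs <- n_pairs + 1L
  }
}

subseq_chr <- function(s, iv) {
  if (is.null(iv) || iv[2L] < iv[1L]) return("")
  substring(s, iv[1L], iv[2L])
}

#' Decompose a tRNA dot-bracket into cloverleaf arms
#'
#' Hairpins are assigned positionally: first = D-arm, second = anticodon (AC)
#' arm, last = T (psi) arm; residues between the AC and T arms form the
#' variable region, which may itself carry a hairpin (the paired V-arm of
#' type II tRNAs).  Bulge loops interrupting the AC or T stems, an expanded
#' anticodon loop, a long variable region, and any extra hairpin are flagged
#' as anomalies.  When the anticodon loop is the canonical 7 nt its central
#' triplet is cross-checked against the label's anticodon; a mismatch is a
#' warning, not an error, since expanded loops shift the triplet.
#'
#' @param t a \code{\link{trna_structure}}.
#' @return object of class \code{arm_decomposition}: acceptor, d_arm, ac_arm,
#'   v_region, t_arm (spans, stem pair counts, loop intervals, bulges), and
#'   an \code{anomalies} character vector.
#' @export
parse_cloverleaf <- function(t) {
  pm <- pair_map(t$structure)
  n <- length(pm)
  top <- children_pairs(pm, 1L, n)
  if (length(top) == 0L) stop("structure-parse error: no pairs")

  acceptor <- NULL
  if (length(top) == 1L) {
    acc <- chain_collapse(pm, top[[1L]][1L], top[[1L]][2L])
    if (acc$kind == "hairpin")
      stop("structure-parse error: fewer than 3 hairpins")
    acceptor <- list(n_pairs = acc$n_pairs, outer = top[[1L]],
                     bulges = acc$bulges)
    arm_pairs <- acc$children
  } else {
    acceptor <- list(n_pairs = 0L, outer = c(1L, n), bulges = list())
    arm_pairs <- top
  }

  arms <- lapply(arm_pairs, function(p) {
    a <- chain_collapse(pm, p[1L], p[2L])
    if (a$kind != "hairpin")
      stop("structure-parse error: branched arm at position ", p[1L])
    a$outer <- p
    a
  })
  if (length(arms) < 3L) stop("structure-parse error: fewer than 3 hairpins")
  arms <- arms[order(vapply(arms, function(a) a$outer[1L], 0L))]

  d_arm <- arms[[1L]]
  ac_arm <- arms[[2L]]
  t_arm <- arms[[length(arms)]]
  v_iv <- c(ac_arm$outer[2L] + 1L, t_arm$outer[1L] - 1L)
  v_len <- max(0L, v_iv[2L] - v_iv[1L] + 1L)

  middle <- if (length(arms) > 3L) arms[2L + seq_len(length(arms) - 3L)] else list()
  v_stem <- NULL
  anomalies <- character(0)
  for (a in middle) {
    if (a$outer[1L] >= v_iv[1L] && a$outer[2L] <= v_iv[2L] && is.null(v_stem))
      v_stem <- a
    else anomalies <- c(anomalies, "extra-arm")
  }

  loop_len <- function(a) a$loop[2L] - a$loop[1L] + 1L
  if (length(ac_arm$bulges)) anomalies <- c(anomalies, "extra-loop-at-AC-arm")
  if (loop_len(ac_arm) > 7L) anomalies <- c(anomalies, "expanded-ANC-loop")
  if (v_len >= 10L) anomalies <- c(anomalies, "long-V-arm")
  if (length(t_arm$bulges)) anomalies <- c(anomalies, "extra-loop-at-psi-arm")

  if (!is.na(t$label) && loop_len(ac_arm) == 7L) {
    anticodon <- sub("^.*-", "", t$label)
    if (nchar(anticodon) == 3L) {
      triplet <- substring(t$sequence, ac_arm$loop[1L] + 2L, ac_arm$loop[1L] + 4L)
      if (!identical(chartr("T", "U", toupper(anticodon)), triplet))
        warning("anticodon triplet ", triplet, " does not match label ", t$label)
    }
  }

  structure(list(taxon = t$taxon, label = t$label, sequence = t$sequence,
                 dot_bracket = t$structure,
                 acceptor = acceptor, d_arm = d_arm, ac_arm = ac_arm,
                 v_region = list(interval = v_iv, length = v_len,
                                 stem = v_stem),
                 t_arm = t_arm, anomalies = unique(anomalies)),
            class = "arm_decomposition")
}

#' @export
print.arm_decomposition <- function(x, ...) {
  cat(sprintf("<arm_decomposition> %s %s: acc %dbp, D %dbp, AC %dbp/loop %dnt, V %dnt%s, T %dbp%s\n",
              x$taxon, x$label, x$acceptor$n_pairs, x$d_arm$n_pairs,
              x$ac_arm$n_pairs, x$ac_arm$loop[2L] - x$ac_arm$loop[1L] + 1L,
              x$v_region$length,
              if (!is.null(x$v_region$stem)) " (paired)" else "",
              x$t_arm$n_pairs,
              if (length(x$anomalies)) paste0("; ", paste(x$anomalies, collapse = ", "))
              else ""))
  invisible(x)
}

bulge_seq <- function(seq, bulges) {
  if (length(bulges) == 0L) return("")
  paste(vapply(bulges, function(b) substring(seq, b$start, b$end), ""),
        collapse = "")
}

#' Classify a tRNA structure
#'
#' V-arm type from the variable-region length (4-5 nt type I, >= 10 nt
#' type II, otherwise intermediate); the V-loop sequence is the terminal loop
#' of a paired V-arm, or the whole variable region when unpaired; anticodon
#' loop length; bulge-loop ("extra loop") sequences at the AC and T stems;
#' and an optional motif-catalog type code.
#'
#' @param d an \code{\link{arm_decomposition}}.
#' @param catalog optional motif catalog (see \code{\link{read_trna_catalog}})
#'   used to assign \code{type_code}.
#' @return object of class \code{structure_class}: isotype, v_arm_type,
#'   v_loop_seq, anc_loop_len, ac_loop_extra, psi_loop_extra, type_code,
#'   anomalies, signature.
#' @export
classify_structure <- function(d, catalog = NULL) {
  v_len <- d$v_region$length
  v_arm_type <- if (v_len >= 4L && v_len <= 5L) "I"
                else if (v_len >= 10L) "II" else "intermediate"
  v_loop_seq <- if (!is.null(d$v_region$stem))
    subseq_chr(d$sequence, d$v_region$stem$loop)
  else subseq_chr(d$sequence, d$v_region$interval)
  anc_loop_len <- d$ac_arm$loop[2L] - d$ac_arm$loop[1L] + 1L
  ac_extra <- bulge_seq(d$sequence, d$ac_arm$bulges)
  psi_extra <- bulge_seq(d$sequence, d$t_arm$bulges)
  cls <- structure(list(
    isotype = d$label, taxon = d$taxon,
    v_arm_type = v_arm_type, v_loop_seq = v_loop_seq,
    anc_loop_len = as.integer(anc_loop_len),
    ac_loop_extra = ac_extra, psi_loop_extra = psi_extra,
    type_code = NA_character_, anomalies = d$anomalies),
    class = "structure_class")
  cls$signature <- paste(v_arm_type, v_loop_seq, anc_loop_len,
                         if (nzchar(ac_extra)) ac_extra else "none",
                         if (nzchar(psi_extra)) psi_extra else "none",
                         sep = "|")
  if (!is.null(catalog)) cls$type_code <- match_catalog(cls, catalog)
  cls
}

#' Read a tRNA structural-type motif catalog
#'
#' @param path TSV with columns code, isotype, feature (one of v_loop,
#'   ac_loop_extra, psi_loop_extra, anc_loop_len), value; defaults to the
#'   packaged Saxifragales catalog (codes A1-H2).
#' @return data.frame.
#' @export
read_trna_catalog <- function(path = system.file(
  "extdata", "trna_type_catalog.tsv", package = "plastcmp")) {
  read.delim(path, stringsAsFactors = FALSE)
}

match_catalog <- function(cls, catalog) {
  rows <- catalog[catalog$isotype == cls$isotype, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    hit <- switch(rows$feature[i],
      v_loop = identical(cls$v_loop_seq, rows$value[i]),
      ac_loop_extra =
        if (rows$value[i] == "none") !nzchar(cls$ac_loop_extra) &&
                                       !nzchar(cls$psi_loop_extra)
        else identical(cls$ac_loop_extra, rows$value[i]),
      psi_loop_extra = identical(cls$psi_loop_extra, rows$value[i]),
      anc_loop_len = cls$anc_loop_len == as.integer(rows$value[i]),
      FALSE)
    if (isTRUE(hit)) return(rows$code[i])
  }
  NA_character_
}

#' Parse and classify a set of tRNA structures
#'
#' @param structs list of \code{\link{trna_structure}} objects.
#' @param catalog optional motif catalog.
#' @return data.frame, one row per tRNA: taxon, isotype, v_arm_type,
#'   v_loop_seq, anc_loop_len, ac_loop_extra, psi_loop_extra, type_code,
#'   anomalies, signature.
#' @export
classify_trna_set <- function(structs, catalog = NULL) {
  rows <- lapply(structs, function(t) {
    cls <- classify_structure(parse_cloverleaf(t), catalog)
    data.frame(taxon = cls$taxon, isotype = cls$isotype,
               v_arm_type = cls$v_arm_type, v_loop_seq = cls$v_loop_seq,
               anc_loop_len = cls$anc_loop_len,
               ac_loop_extra = cls$ac_loop_extra,
               psi_loop_extra = cls$psi_loop_extra,
               type_code = cls$type_code,
               anomalies = paste(cls$anomalies, collapse = ","),
               signature = cls$signature, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Family-level tRNA structural patterns
#'
#' Per family and isotype, the set of observed structure classes;
#' \code{intrafam_variable} flags families with more than one class for an
#' isotype, and \code{unique_classes} lists classes observed in exactly one
#' family across the dataset.
#'
#' @param classes output of \code{\link{classify_trna_set}}.
#' @param taxonomy taxonomy data.frame (taxon, family).
#' @return data.frame: family, isotype, n_taxa, n_types, classes,
#'   intrafam_variable, unique_classes, interfam_unique.
#' @export
catalog_variants <- function(classes, taxonomy) {
  classes$family <- taxonomy$family[match(classes$taxon, taxonomy$taxon)]
  if (anyNA(classes$family))
    stop("catalog_variants: taxa missing from taxonomy: ",
         paste(unique(classes$taxon[is.na(classes$family)]), collapse = ", "))
  key <- function(sig) sig
  rows <- list()
  for (iso in unique(classes$isotype)) {
    sub <- classes[classes$isotype == iso, , drop = FALSE]
    fam_of_sig <- split(sub$family, key(sub$signature))
    uniq_sigs <- names(fam_of_sig)[vapply(fam_of_sig,
                                          function(f) length(unique(f)) == 1L,
                                          TRUE)]
    for (fam in unique(sub$family)) {
      fs <- sub[sub$family == fam, , drop = FALSE]
      sigs <- sort(unique(fs$signature))
      uniq_here <- intersect(sigs, uniq_sigs)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, isotype = iso, n_taxa = nrow(fs),
        n_types = length(sigs), classes = paste(sigs, collapse = ";"),
        intrafam_variable = length(sigs) > 1L,
        unique_classes = paste(uniq_here, collapse = ";"),
        interfam_unique = length(uniq_here) > 0L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- constrained cloverleaf folding ----------------------------------------

#' Stem/loop bounds for the cloverleaf folder
#'
#' Canonical bounds: acceptor 7+-1 bp, D stem 3-4 bp (loop 4-11 nt), AC stem
#' 5+-1 bp (loop 5-11 nt), T stem 5+-1 bp (loop 5-9 nt), spacers 0-2 nt,
#' variable region 0-23 nt, 3' tail 0-4 nt.
#'
#' @param acceptor,s1,d_stem,d_loop,s2,ac_stem,ac_loop,v,t_stem,t_loop,tail
#'   length-2 integer ranges.
#' @return named list of ranges.
#' @export
trna_fold_bounds <- function(acceptor = c(6L, 8L), s1 = c(0L, 2L),
                             d_stem = c(3L, 4L), d_loop = c(4L, 11L),
                             s2 = c(0L, 2L), ac_stem = c(4L, 6L),
                             ac_loop = c(5L, 11L), v = c(0L, 23L),
                             t_stem = c(4L, 6L), t_loop = c(5L, 9L),
                             tail = c(0L, 4L)) {
  list(acceptor = acceptor, s1 = s1, d_stem = d_stem, d_loop = d_loop,
       s2 = s2, ac_stem = ac_stem, ac_loop = ac_loop, v = v,
       t_stem = t_stem, t_loop = t_loop, tail = tail)
}

can_pair_rna <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# Dot-bracket for a cloverleaf parameter vector.
render_cloverleaf_db <- function(L, a, s1, d, dl, s2, c_, acl, v, t, tl, tail) {
  db <- rep(".", L)
  open_at <- function(from, len) db[seq.int(from, length.out = len)] <<- "("
  close_at <- function(from, len) db[seq.int(from, length.out = len)] <<- ")"
  p <- 1L
  open_at(p, a); p <- p + a + s1
  open_at(p, d); p <- p + d + dl
  close_at(p, d); p <- p + d + s2
  open_at(p, c_); p <- p + c_ + acl
  close_at(p, c_); p <- p + c_ + v
  open_at(p, t); p <- p + t + tl
  close_at(p, t); p <- p + t
  close_at(p, a)
  paste(db, collapse = "")
}

#' Fold a sequence into a cloverleaf by constrained enumeration
#'
#' Maximizes the number of canonical (AU, GC, GU) stem pairs over all
#' cloverleaf templates within the given stem/loop bounds; ties break towards
#' the 5'-most pairing (lexicographically smallest sorted list of paired
#' positions).  This helper exists so structural typing can be exercised
#' without an external predictor; it is not a thermodynamic folder.
#'
#' @param sequence RNA (or DNA) string, typically 60-100 nt under the
#'   canonical bounds.
#' @param bounds template bounds from \code{\link{trna_fold_bounds}}.
#' @return a \code{\link{trna_structure}} with the folded dot-bracket.
#' @export
fold_trna <- function(sequence, bounds = trna_fold_bounds()) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  rng <- function(b) seq.int(b[1L], b[2L])
  stem_ok <- function(i5, j3, len) {
    # pairs (i5+k, j3-k), k = 0..len-1
    all(can_pair_rna(ch[i5 + 0:(len - 1L)], ch[j3 - 0:(len - 1L)]))
  }
  best <- NULL
  best_score <- -1L
  best_positions <- NULL
  for (tail in rng(bounds$tail)) for (a in rng(bounds$acceptor)) {
    j_acc <- L - tail                      # acceptor 3' end
    if (j_acc - a + 1L <= a) next
    if (!stem_ok(1L, j_acc, a)) next
    for (t in rng(bounds$t_stem)) for (tl in rng(bounds$t_loop)) {
      t3_end <- j_acc - a                  # last position of T stem 3'
      t5_start <- t3_end - (2L * t + tl) + 1L
      if (t5_start <= a) next
      if (!stem_ok(t5_start, t3_end, t)) next
      for (s1 in rng(bounds$s1)) for (d in rng(bounds$d_stem))
        for (dl in rng(bounds$d_loop)) {
          d5_start <- a + s1 + 1L
          d_total <- 2L * d + dl
          if (!stem_ok(d5_start, d5_start + d_total - 1L, d)) next
          for (s2 in rng(bounds$s2)) for (c_ in rng(bounds$ac_stem))
            for (acl in rng(bounds$ac_loop)) {
              ac5_start <- d5_start + d_total + s2
              ac_total <- 2L * c_ + acl
              ac_end <- ac5_start + ac_total - 1L
              v <- t5_start - ac_end - 1L
              if (v < bounds$v[1L] || v > bounds$v[2L]) next
              if (!stem_ok(ac5_start, ac_end, c_)) next
              score <- a + t + d + c_
              if (score < best_score) next
              pos <- sort(c(seq.int(1L, length.out = a),
                            seq.int(j_acc - a + 1L, length.out = a),
                            seq.int(d5_start, length.out = d),
                            seq.int(d5_start + d + dl, length.out = d),
                            seq.int(ac5_start, length.out = c_),
                            seq.int(ac5_start + c_ + acl, length.out = c_),
                            seq.int(t5_start, length.out = t),
                            seq.int(t5_start + t + tl, length.out = t)))
              if (score > best_score ||
                  (score == best_score && lex_less(pos, best_positions))) {
                best_score <- score
                best_positions <- pos
                best <- c(a = a, s1 = s1, d = d, dl = dl, s2 = s2, c_ = c_,
                          acl = acl, v = v, t = t, tl = tl, tail = tail)
              }
            }
        }
    }
  }
  if (is.null(best)) stop("fold error: no feasible cloverleaf")
  db <- render_cloverleaf_db(L, best[["a"]], best[["s1"]], best[["d"]],
                             best[["dl"]], best[["s2"]], best[["c_"]],
                             best[["acl"]], best[["v"]], best[["t"]],
                             best[["tl"]], best[["tail"]])
  trna_structure(s, db)
}

# TRUE when integer vector x sorts lexicographically before y (same length
# assumed; shorter prefix rule otherwise).
lex_less <- function(x, y) {
  if (is.null(y)) return(TRUE)
  k <- min(length(x), length(y))
  for (i in seq_len(k)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  length(x) < length(y)
}
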