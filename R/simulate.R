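# Deterministic synthetic-data generation with planted ground truth for every
# pipeline stage: family-structured taxon sets and trees, plastomes with
# configurable IR junction geometry and gene/intron losses, intron alignments
# with planted indel events, hotspot alignments, and tRNA structure sets.
#
# Every generator seeds the RNG from cfg$seed plus a small fixed offset, so a
# config determines all outputs byte-for-byte.

seeded <- function(cfg, offset) {
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulation configuration
#'
#' Defaults define the package's standard demonstration conditions: 8
#' families of 5 taxa, a 30 kb plastome template (LSC 16 kb, IR 4 kb, SSC
#' 6 kb — a 1:5 scale model of a typical 150 kb plastome that keeps every
#' junction, loss and repeat feature intact), four junction patterns with the
#' published family-signature overlaps (rps19 110 bp, ycf1 1077 bp), three
#' loss events, 60 planted indel events over the 17 intron loci, one
#' 1.6 kb diversity hotspot at a fivefold per-site rate contrast, and planted
#' family-unique tRNA structure classes.
#'
#' @param seed integer seed; fully determines all generated data.
#' @param n_families number of families (>= 2).
#' @param taxa_per_family taxa per family.
#' @param lsc,ir,ssc template region lengths in bp.
#' @param patterns junction pattern id per family (recycled).
#' @param rps19_overlap,ycf1_overlap named overrides of junction overlaps per
#'   family index (bp).
#' @param losses data.frame(family_idx, gene, type) with type
#'   \code{"gene"} or \code{"intron"}.
#' @param hotspot list(n, length, interval = c(start, end), p0, p1).
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_families = 8L, taxa_per_family = 5L,
                       lsc = 16000L, ir = 4000L, ssc = 6000L,
                       patterns = c(1L, 4L, 5L, 6L),
                       rps19_overlap = c("2" = 110L),
                       ycf1_overlap = c("1" = 1077L),
                       losses = data.frame(
                         family_idx = c(1L, 1L, 3L),
                         gene = c("infA", "rpl32", "rps16"),
                         type = c("gene", "gene", "intron")),
                       hotspot = list(n = 20L, length = 10000L,
                                      interval = c(4000L, 5600L),
                                      p0 = 0.01, p1 = 0.05)) {
  if (n_families < 2L) stop("sim_config: need at least 2 families")
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 taxa_per_family = as.integer(taxa_per_family),
                 lsc = as.integer(lsc), ir = as.integer(ir),
                 ssc = as.integer(ssc),
                 patterns = rep_len(as.integer(patterns), n_families),
                 rps19_overlap = rps19_overlap, ycf1_overlap = ycf1_overlap,
                 losses = losses, hotspot = hotspot),
            class = "sim_config")
}

family_names <- function(cfg) sprintf("Fam%02d", seq_len(cfg$n_families))

taxa_of_family <- function(cfg, f)
  sprintf("%s_sp%d", family_names(cfg)[f], seq_len(cfg$taxa_per_family))

#' Generate a family-structured taxonomy and a family-monophyletic tree
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{taxonomy} (taxon, family), \code{newick} (string with
#'   BS/PP labels; family crowns at 100/1.0), \code{tree} (parsed via
#'   \code{\link{read_tree_support}}).
#' @export
gen_taxonomy_and_tree <- function(cfg) {
  seeded(cfg, 1L)
  fams <- family_names(cfg)
  taxonomy <- do.call(rbind, lapply(seq_len(cfg$n_families), function(f)
    data.frame(taxon = taxa_of_family(cfg, f), family = fams[f],
               stringsAsFactors = FALSE)))
  join_random <- function(parts, label_fun) {
    while (length(parts) > 1L) {
      i <- sample.int(length(parts), 2L)
      merged <- sprintf("(%s,%s)%s", parts[i[1L]], parts[i[2L]], label_fun())
      parts <- c(parts[-i], merged)
    }
    parts
  }
  sub_label <- function() sprintf("%d/%.2f", sample(60:100, 1L),
                                  runif(1L, 0.9, 1.0))
  crowns <- vapply(seq_len(cfg$n_families), function(f) {
    tips <- taxa_of_family(cfg, f)
    if (length(tips) == 1L) return(tips)
    s <- join_random(tips, sub_label)
    # family crown gets full support
    sub("\\)[0-9./]*$", ")100/1.00", s)
  }, "")
  newick <- paste0(join_random(crowns, sub_label), ";")
  list(taxonomy = taxonomy, newick = newick,
       tree = read_tree_support(newick))
}

# Gene layout in the LSC interior: (name, kind, exon lengths, intron lengths)
interior_gene_plan <- function() {
  list(
    list("trnA-UGC", "tRNA", c(35L, 37L), 120L),
    list("trnI-GAU", "tRNA", c(35L, 37L), 120L),
    list("trnK-UUU", "tRNA", c(35L, 37L), 180L),
    list("trnL-UAA", "tRNA", c(35L, 37L), 120L),
    list("trnV-UAC", "tRNA", c(35L, 37L), 120L),
    list("atpF", "PCG", c(150L, 250L), 150L),
    list("ndhA", "PCG", c(180L, 200L), 150L),
    list("ndhB", "PCG", c(200L, 180L), 150L),
    list("petB", "PCG", c(6L, 400L), 150L),
    list("petD", "PCG", c(8L, 380L), 150L),
    list("rpl16", "PCG", c(9L, 330L), 150L),
    list("rpl2", "PCG", c(180L, 200L), 150L),
    list("rpoC1", "PCG", c(200L, 300L), 150L),
    list("rps16", "PCG", c(40L, 180L), 150L),
    list("clpP", "PCG", c(70L, 120L, 100L), c(120L, 120L)),
    list("ycf3", "PCG", c(80L, 120L, 90L), c(110L, 110L)),
    list("infA", "PCG", 234L, integer(0)),
    list("rpl32", "PCG", 174L, integer(0)))
}

#' Generate one annotated synthetic plastome
#'
#' Builds a genome realizing the family's junction pattern: exact IR copies
#' (IRa is the reverse complement of IRb, with boundary bases pinned so the
#' planted repeat is maximal), focal genes placed to produce the requested
#' rps19/ndhF expansion or contraction, a ycf1 span of JSA whose IR-copy
#' fragment is annotated as a pseudogene in IRb, trnH-GUG wrapping the origin
#' with its 3'-terminal 3 bp in IRa, and the configured gene/intron losses.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param family_idx family index (1-based).
#' @param taxon_idx taxon index within the family.
#' @return list: \code{record} (\code{\link{plastome_record}}), \code{text}
#'   (GenBank-dialect flat file), \code{truth} (planted regions, junction
#'   states/overlaps, losses).
#' @export
gen_plastome <- function(cfg, family_idx, taxon_idx) {
  l <- cfg$lsc; r <- cfg$ir; s <- cfg$ssc
  L <- l + 2L * r + s
  jlb <- l; jsb <- l + r; jsa <- l + r + s
  fam <- family_names(cfg)[family_idx]
  taxon <- taxa_of_family(cfg, family_idx)[taxon_idx]
  pattern <- cfg$patterns[family_idx]

  # family-level base genome
  seeded(cfg, 100L + family_idx)
  base_lsc <- strsplit(rand_dna(l), "")[[1]]
  base_irb <- strsplit(rand_dna(r), "")[[1]]
  base_ssc <- strsplit(rand_dna(s), "")[[1]]

  # junction overlaps for this family
  ov_ycf1 <- if (as.character(family_idx) %in% names(cfg$ycf1_overlap))
    cfg$ycf1_overlap[[as.character(family_idx)]] else sample(400:1870, 1L)
  ov_rps19 <- if (as.character(family_idx) %in% names(cfg$rps19_overlap))
    cfg$rps19_overlap[[as.character(family_idx)]] else sample(30:180, 1L)
  ov_ndhf <- sample(20:120, 1L)
  d_rps19 <- sample(5:60, 1L)
  d_ndhf <- sample(5:60, 1L)

  # per-pattern focal states; "mixed" splits the family half and half
  half <- taxon_idx > ceiling(cfg$taxa_per_family / 2)
  st <- switch(as.character(pattern),
    "1" = c("expansion", "contraction"),
    "2" = c("contraction", "expansion"),
    "3" = c(if (half) "contraction" else "expansion", "expansion"),
    "4" = c("expansion", "expansion"),
    "5" = c("contraction", "contraction"),
    "6" = c(if (half) "contraction" else "expansion",
            if (half) "expansion" else "contraction"),
    stop("gen_plastome: unknown pattern ", pattern))
  rps19_state <- st[1L]; ndhf_state <- st[2L]

  # per-taxon substitutions in single-copy interiors
  seeded(cfg, 1000L + family_idx * 20L + taxon_idx)
  mutate <- function(v, lo, hi, rate = 0.003) {
    if (hi <= lo) return(v)
    n <- hi - lo + 1L
    k <- rbinom(1L, n, rate)
    if (k > 0L) {
      pos <- sample(lo:hi, k)
      v[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    v
  }
  lsc_v <- mutate(base_lsc, 100L, l - 100L)
  ssc_v <- mutate(base_ssc, 100L, s - 100L)
  irb_v <- base_irb

  # pin boundary bases so the planted IR pair is exactly maximal
  lsc_v[1L] <- "A"; lsc_v[l] <- "A"
  ssc_v[1L] <- "A"; ssc_v[s] <- "A"

  seq_chr <- c(lsc_v, irb_v, ssc_v,
               strsplit(revcomp(paste(irb_v, collapse = "")), "")[[1]])
  sequence <- paste(seq_chr, collapse = "")

  feats <- list()
  add <- function(name, kind, strand, exons, pseudo = FALSE)
    feats[[length(feats) + 1L]] <<- gene_feature(name, kind, strand, exons, pseudo)

  # losses configured for this family
  gene_losses <- cfg$losses$gene[cfg$losses$family_idx == family_idx &
                                   cfg$losses$type == "gene"]
  intron_losses <- cfg$losses$gene[cfg$losses$family_idx == family_idx &
                                     cfg$losses$type == "intron"]

  # interior genes in the LSC, laid out from a fixed cursor
  cursor <- 300L
  for (g in interior_gene_plan()) {
    name <- g[[1L]]; kind <- g[[2L]]; exl <- g[[3L]]; inl <- g[[4L]]
    if (name %in% intron_losses) {
      exl <- sum(exl) + sum(inl); inl <- integer(0)
    }
    exons <- NULL; p <- cursor
    for (i in seq_along(exl)) {
      exons <- rbind(exons, c(p, p + exl[i]))
      p <- p + exl[i] + if (i <= length(inl)) inl[i] else 0L
    }
    if (!(name %in% gene_losses))
      add(name, kind, "+", exons)
    cursor <- p + 60L
  }
  # rps12: 5' exon feature and trans-spliced 3' cluster feature
  if (!("rps12" %in% gene_losses)) {
    add("rps12", "PCG", "-", rbind(c(cursor, cursor + 114L)))
    p2 <- cursor + 174L
    if ("rps12" %in% intron_losses) {
      add("rps12", "PCG", "+", rbind(c(p2, p2 + 398L)))
    } else {
      add("rps12", "PCG", "+", rbind(c(p2, p2 + 232L),
                                     c(p2 + 372L, p2 + 398L)))
    }
    cursor <- p2 + 458L
  }
  if (cursor > l - 800L)
    stop("gen_plastome: LSC template too small for the gene layout")

  # rps19 at JLB
  glen <- 279L
  if (rps19_state == "expansion") {
    if (ov_rps19 >= glen) stop("gen_plastome: rps19 overlap exceeds gene length")
    add("rps19", "PCG", "+", rbind(c(jlb - (glen - ov_rps19), jlb + ov_rps19)))
    # IR-copy fragment mirrored to the IRa end, adjacent to JLA
    add("rps19", "PCG", "-", rbind(c(L - ov_rps19, L)), pseudo = TRUE)
  } else {
    add("rps19", "PCG", "+", rbind(c(jlb - glen - d_rps19, jlb - d_rps19)))
  }

  # ndhF at JSB (in the SSC, minus strand as in real plastomes)
  nlen <- 740L
  if (ndhf_state == "expansion") {
    add("ndhF", "PCG", "-", rbind(c(jsb - ov_ndhf, jsb - ov_ndhf + nlen)))
    add("ndhF", "PCG", "+", rbind(c(jsa, jsa + ov_ndhf)), pseudo = TRUE)
  } else {
    add("ndhF", "PCG", "-", rbind(c(jsb + d_ndhf, jsb + d_ndhf + nlen)))
  }

  # ycf1 spanning JSA, IR-copy fragment pseudo in IRb next to JSB
  ylen <- 3500L
  add("ycf1", "PCG", "+", rbind(c(jsa - (ylen - ov_ycf1), jsa + ov_ycf1)))
  add("ycf1", "PCG", "-", rbind(c(jsb - ov_ycf1, jsb)), pseudo = TRUE)

  # trnH-GUG wrapping the origin, 3'-terminal 3 bp inside IRa
  add("trnH-GUG", "tRNA", "-", rbind(c(L - 3L, L + 68L)))

  id <- sprintf("SYN%03d", (family_idx - 1L) * cfg$taxa_per_family + taxon_idx)
  rec <- plastome_record(id = id, taxon = taxon, sequence = sequence,
                         features = feats, family = fam)
  truth <- list(
    id = id, taxon = taxon, family = fam, pattern = pattern,
    regions = region_map(c(0L, l), c(l, jsb), c(jsb, jsa), c(jsa, L), L),
    rps19_state = rps19_state,
    rps19_overlap = if (rps19_state == "expansion") ov_rps19 else 0L,
    rps19_distance = if (rps19_state == "expansion") 0L else d_rps19,
    ndhF_state = ndhf_state,
    ndhF_overlap = if (ndhf_state == "expansion") ov_ndhf else 0L,
    ycf1_overlap = ov_ycf1,
    gene_losses = gene_losses, intron_losses = intron_losses)
  list(record = rec, text = write_plastome_genbank(rec), truth = truth)
}

#' Generate an intron alignment with planted indel events
#'
#' The base alignment descends from a random ancestor with independent
#' per-site substitutions (no phylogenetic likelihood model: no stage here
#' estimates substitution parameters).  Events from the plan are carved in as
#' gap blocks; deletion events gap their bearers, insertion events leave
#' residues only in the carrier taxa.  Flanking bases are pinned so planted
#' gaps cannot slide (no flanking-repeat ambiguity unless a test plants it).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param locus locus name (also seeds the locus's RNG stream).
#' @param taxa row names of the alignment (include outgroups here).
#' @param plan data.frame: start (0-based column), length, carriers
#'   (semicolon-joined taxa), polarity (\code{"insertion"}/\code{"deletion"});
#'   events must not overlap unless one strictly contains the other
#'   (nesting).
#' @param length alignment length in columns (default 600).
#' @param outgroups taxa treated as outgroup (gap carriers for insertions).
#' @return list: \code{aln} (character matrix), \code{events} (planted truth:
#'   locus, start, end, length, polarity, carriers, bearers).
#' @export
gen_intron_alignment <- function(cfg, locus, taxa, plan, length = 600L,
                                 outgroups = character(0)) {
  seeded(cfg, 5000L + sum(utf8ToInt(locus)))
  n <- base::length(taxa)
  anc <- strsplit(rand_dna(length), "")[[1]]
  aln <- matrix(rep(anc, each = n), nrow = n, dimnames = list(taxa, NULL))
  # independent per-site substitutions
  nmut <- rbinom(1L, n * length, 0.01)
  if (nmut > 0L) {
    ridx <- sample.int(n, nmut, replace = TRUE)
    cidx <- sample.int(length, nmut, replace = TRUE)
    aln[cbind(ridx, cidx)] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
  }
  truth <- NULL
  if (!is.null(plan) && nrow(plan) > 0L) {
    plan <- plan[order(plan$start), , drop = FALSE]
    iv <- cbind(plan$start, plan$start + plan$length)
    for (i in seq_len(nrow(plan))) for (j in seq_len(nrow(plan))) {
      if (i >= j) next
      a <- iv[i, ]; b <- iv[j, ]
      overlaps <- a[1L] < b[2L] && b[1L] < a[2L]
      nested <- (a[1L] <= b[1L] && b[2L] <= a[2L]) ||
                (b[1L] <= a[1L] && a[2L] <= b[2L])
      if (overlaps && !nested)
        stop("gen_intron_alignment: overlapping non-nested events in plan")
    }
    for (i in seq_len(nrow(plan))) {
      s0 <- plan$start[i]; e0 <- s0 + plan$length[i]
      if (s0 < 2L || e0 > length - 2L)
        stop("gen_intron_alignment: event too close to the alignment edge")
      carriers <- strsplit(plan$carriers[i], ";", fixed = TRUE)[[1]]
      if (!all(carriers %in% taxa))
        stop("gen_intron_alignment: unknown carrier taxon")
      bearers <- if (plan$polarity[i] == "deletion") carriers
                 else setdiff(taxa, carriers)
      aln[bearers, (s0 + 1L):e0] <- "-"
      # anti-slide guards: distinct flanks around the gap block; never
      # overwrite gaps of an enclosing nested event
      g <- aln[, s0] != "-"
      aln[g, s0] <- "A"
      resid <- taxa[aln[, e0] != "-"]
      if (base::length(resid)) aln[resid, e0] <- "C"
      g <- aln[, e0 + 1L] != "-"
      aln[g, e0 + 1L] <- "G"
      truth <- rbind(truth, data.frame(
        locus = locus, start = s0, end = e0, length = plan$length[i],
        polarity = plan$polarity[i],
        carriers = paste(sort(carriers), collapse = ";"),
        bearers = paste(sort(bearers), collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(truth))
    truth <- data.frame(locus = character(0), start = integer(0),
                        end = integer(0), length = integer(0),
                        polarity = character(0), carriers = character(0),
                        bearers = character(0), stringsAsFactors = FALSE)
  list(aln = aln, events = truth)
}

#' Generate an alignment with a planted diversity hotspot
#'
#' Each taxon differs from a random ancestor independently per site, with
#' probability \code{p1} inside the planted interval and \code{p0} outside.
#'
#' @param cfg a \code{\link{sim_config}} (its \code{hotspot} element supplies
#'   defaults).
#' @param n,length,interval,p0,p1 overrides of the hotspot plan.
#' @return list: \code{aln} (character matrix, no gaps), \code{truth}
#'   (hotspot interval, 0-based half-open columns).
#' @export
gen_hotspot_alignment <- function(cfg, n = cfg$hotspot$n,
                                  length = cfg$hotspot$length,
                                  interval = cfg$hotspot$interval,
                                  p0 = cfg$hotspot$p0, p1 = cfg$hotspot$p1) {
  if (p1 <= p0) stop("gen_hotspot_alignment: need p1 > p0")
  seeded(cfg, 9000L)
  anc <- strsplit(rand_dna(length), "")[[1]]
  rate <- rep(p0, length)
  rate[(interval[1L] + 1L):interval[2L]] <- p1
  taxa <- sprintf("hs_t%02d", seq_len(n))
  aln <- matrix(rep(anc, each = n), nrow = n, dimnames = list(taxa, NULL))
  mut <- matrix(runif(n * length), nrow = n) < rep(rate, each = n)
  k <- sum(mut)
  if (k > 0L) {
    shift <- sample.int(3L, k, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    cur <- match(aln[mut], bases)
    aln[mut] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  list(aln = aln, truth = list(interval = interval))
}

# Template renderer for a cloverleaf tRNA with optional planted anomalies.
# Stems are forced complementary and drawn from {C, G} only, while unpaired
# positions are A except the anticodon and any supplied motif: A pairs
# nothing present (no U outside motifs, A-A and A-C/G are not canonical
# pairs), so the planted structure is also the unique maximal-pairing
# cloverleaf and the folder recovers it exactly.
make_cloverleaf <- function(anticodon, anc_loop_len = 7L,
                            v_mode = c("short", "paired"), v_seq = "AAAA",
                            ac_bulge = NULL, t_bulge = NULL) {
  v_mode <- match.arg(v_mode)
  rand_stem <- function(n) sample(c("C", "G"), n, replace = TRUE)
  comp <- function(x) chartr("ACGU", "UGCA", x)
  revcomp_rna <- function(x) rev(comp(x))
  seqv <- character(0); dbv <- character(0)
  put <- function(s, d) { seqv <<- c(seqv, s); dbv <<- c(dbv, rep(d, base::length(s))) }

  acc5 <- rand_stem(7L)
  put(acc5, "(")
  put(c("A", "A"), ".")
  d5 <- rand_stem(4L)
  put(d5, "("); put(rep("A", 8L), "."); put(revcomp_rna(d5), ")")
  put("A", ".")
  # anticodon arm, optionally with a bulge loop inside the 5' stem
  ac_stem <- rand_stem(5L)
  if (is.null(ac_bulge)) {
    put(ac_stem, "(")
  } else {
    put(ac_stem[1:3], "(")
    put(strsplit(ac_bulge, "")[[1]], ".")
    put(ac_stem[4:5], "(")
  }
  loop <- rep("A", anc_loop_len)
  loop[3:5] <- strsplit(chartr("T", "U", anticodon), "")[[1]]
  put(loop, ".")
  put(revcomp_rna(ac_stem), ")")
  # variable region
  if (v_mode == "short") {
    if (nzchar(v_seq)) put(strsplit(v_seq, "")[[1]], ".")
  } else {
    v5 <- rand_stem(4L)
    put(v5, "("); put(strsplit(v_seq, "")[[1]], "."); put(revcomp_rna(v5), ")")
  }
  # T (psi) arm, optionally with a bulge in the 5' stem
  t_stem <- rand_stem(5L)
  if (is.null(t_bulge)) {
    put(t_stem, "(")
  } else {
    put(t_stem[1:3], "(")
    put(strsplit(t_bulge, "")[[1]], ".")
    put(t_stem[4:5], "(")
  }
  put(rep("A", 7L), ".")
  put(revcomp_rna(t_stem), ")")
  put(revcomp_rna(acc5), ")")
  put(c("A", "C", "C", "A"), ".")            # NCCA-like 3' tail
  trna_structure(paste(seqv, collapse = ""), paste(dbv, collapse = ""))
}

# Default per-family tRNA class plan for the demonstration config: five
# family-unique classes, one intrafamilially variable isotype, shared
# defaults elsewhere.
default_trna_plan <- function(cfg) {
  fams <- family_names(cfg)
  plan <- list(
    "tRNA-Ser-GCU" = setNames(rep("B1", cfg$n_families), fams),
    "tRNA-Ser-UGA" = setNames(rep("A1", cfg$n_families), fams),
    "tRNA-Thr-UGU" = setNames(rep("D3", cfg$n_families), fams),
    "tRNA-Tyr-GUA" = setNames(rep("C2", cfg$n_families), fams),
    "tRNA-Leu-CAA" = setNames(rep("G1", cfg$n_families), fams),
    "tRNA-Val-UAC" = setNames(rep("E1", cfg$n_families), fams),
    "tRNA-Leu-UAA" = setNames(rep("F1", cfg$n_families), fams),
    "tRNA-Ser-GGA" = setNames(rep("H1", cfg$n_families), fams))
  # five family-unique classes
  plan[["tRNA-Ser-GCU"]][fams[1L]] <- "B7"
  plan[["tRNA-Ser-UGA"]][fams[2L]] <- "A6"
  plan[["tRNA-Thr-UGU"]][fams[3L]] <- "D5"
  plan[["tRNA-Tyr-GUA"]][fams[4L]] <- "C1"
  plan[["tRNA-Leu-CAA"]][fams[5L]] <- "G2"
  plan
}

# Realize one catalog code as template arguments.
code_to_template <- function(code, catalog) {
  row <- catalog[catalog$code == code, ]
  if (nrow(row) != 1L) stop("unknown catalog code: ", code)
  iso <- row$isotype
  anticodon <- sub("^.*-", "", iso)
  args <- list(anticodon = anticodon)
  if (row$feature == "v_loop") {
    args$v_mode <- "paired"; args$v_seq <- row$value
  } else if (row$feature == "anc_loop_len") {
    args$anc_loop_len <- as.integer(row$value)
  } else if (row$feature == "ac_loop_extra" && row$value != "none") {
    args$ac_bulge <- row$value
  } else if (row$feature == "psi_loop_extra") {
    args$t_bulge <- row$value
  }
  args
}

#' Generate a tRNA structure set with planted class assignments
#'
#' Every taxon receives one tRNA per planned isotype, rendered from a
#' cloverleaf template whose stems are complementary by construction; the
#' family's planted catalog code decides the V-loop motif, anticodon-loop
#' length or bulge anomaly.  Additional typical isotypes pad the set.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param taxonomy taxonomy from \code{\link{gen_taxonomy_and_tree}}.
#' @param plan named list isotype -> named character vector family -> code;
#'   default \code{default_trna_plan(cfg)}.
#' @param n_typical number of extra typical (type I, 7-nt loop) isotypes.
#' @return list: \code{structs} (list of \code{\link{trna_structure}}),
#'   \code{truth} (taxon, family, isotype, code).
#' @export
gen_trna_set <- function(cfg, taxonomy, plan = default_trna_plan(cfg),
                         n_typical = 2L) {
  catalog <- read_trna_catalog()
  seeded(cfg, 9999L)
  structs <- list(); rows <- list()
  typical_iso <- c("tRNA-Phe-GAA", "tRNA-Gly-GCC", "tRNA-Met-CAU",
                   "tRNA-Asp-GUC")[seq_len(n_typical)]
  for (i in seq_len(nrow(taxonomy))) {
    tx <- taxonomy$taxon[i]; fam <- taxonomy$family[i]
    for (iso in names(plan)) {
      code <- plan[[iso]][[fam]]
      args <- code_to_template(code, catalog)
      t <- do.call(make_cloverleaf, args)
      t$label <- iso; t$taxon <- tx
      structs[[length(structs) + 1L]] <- t
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, family = fam, isotype = iso, code = code,
        stringsAsFactors = FALSE)
    }
    for (iso in typical_iso) {
      t <- make_cloverleaf(sub("^.*-", "", iso))
      t$label <- iso; t$taxon <- tx
      structs[[length(structs) + 1L]] <- t
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, family = fam, isotype = iso, code = "typical",
        stringsAsFactors = FALSE)
    }
  }
  list(structs = structs, truth = do.call(rbind, rows))
}

# Demonstration indel plan: 60 events over the 17 intron loci; mostly strict
# family-unique insertions/deletions, a few spanning two families
# (homoplastic on the tree) and one nested pair.
demo_indel_plan <- function(cfg, taxonomy, outgroup) {
  loci <- vapply(interior_gene_plan()[1:16], `[[`, "", 1L)
  loci <- c(loci, "rps12")                 # 17 intron loci
  fams <- family_names(cfg)
  lens <- c(1L, 2L, 3L, 4L, 5L, 5L, 6L, 8L, 10L, 12L, 15L, 20L, 30L)
  plans <- setNames(vector("list", length(loci)), loci)
  slot <- setNames(rep(0L, length(loci)), loci)
  add_ev <- function(locus, carriers, polarity, len) {
    s <- 50L + 90L * slot[[locus]]
    slot[[locus]] <<- slot[[locus]] + 1L
    plans[[locus]] <<- rbind(plans[[locus]], data.frame(
      start = s, length = len, carriers = paste(carriers, collapse = ";"),
      polarity = polarity, stringsAsFactors = FALSE))
  }
  for (e in seq_len(55L)) {
    locus <- loci[((e - 1L) %% length(loci)) + 1L]
    fam <- fams[((e - 1L) %% cfg$n_families) + 1L]
    carriers <- taxonomy$taxon[taxonomy$family == fam]
    pol <- if (e %% 2L == 0L) "insertion" else "deletion"
    add_ev(locus, carriers, pol, lens[((e - 1L) %% length(lens)) + 1L])
  }
  # three cross-family (homoplastic) deletions borne by two distant taxa
  off <- max(1L, cfg$n_families %/% 2L)
  for (e in 1:3) {
    locus <- loci[e]
    f2 <- ((e - 1L + off) %% cfg$n_families) + 1L
    carriers <- c(taxonomy$taxon[taxonomy$family == fams[e]][1L],
                  taxonomy$taxon[taxonomy$family == fams[f2]][1L])
    add_ev(locus, carriers, "deletion", 6L)
  }
  # one nested pair: a long family deletion enclosing a shorter one
  encl_fam <- taxonomy$taxon[taxonomy$family ==
                               fams[(5L %% cfg$n_families) + 1L]]
  inner_fam <- taxonomy$taxon[taxonomy$family ==
                                fams[(6L %% cfg$n_families) + 1L]]
  plans[["ndhA"]] <- rbind(plans[["ndhA"]], data.frame(
    start = 430L, length = 24L, carriers = paste(encl_fam, collapse = ";"),
    polarity = "deletion", stringsAsFactors = FALSE))
  plans[["ndhA"]] <- rbind(plans[["ndhA"]], data.frame(
    start = 438L, length = 6L, carriers = paste(inner_fam, collapse = ";"),
    polarity = "deletion", stringsAsFactors = FALSE))
  plans
}

#' Generate the full demonstration dataset
#'
#' Runs every generator under one configuration and returns the data with its
#' complete truth bundle; optionally writes all files (genbank/, alignments/,
#' trna.tsv, tree.nwk, taxonomy.tsv).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param out_dir optional output directory.
#' @return list: taxonomy, newick, tree, plastomes (records), genbank_texts,
#'   intron_alignments, trna (structs), outgroup, truth (junctions, losses,
#'   indel events, trna classes, hotspot interval).
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  tt <- gen_taxonomy_and_tree(cfg)
  taxonomy <- tt$taxonomy
  outgroup <- "Outgroup_1"

  plastomes <- list(); texts <- list(); jt <- list()
  for (f in seq_len(cfg$n_families)) for (i in seq_len(cfg$taxa_per_family)) {
    g <- gen_plastome(cfg, f, i)
    plastomes[[g$record$taxon]] <- g$record
    texts[[g$record$taxon]] <- g$text
    jt[[g$record$taxon]] <- g$truth
  }

  plans <- demo_indel_plan(cfg, taxonomy, outgroup)
  alns <- list(); ev_truth <- NULL
  aln_taxa <- c(taxonomy$taxon, outgroup)
  for (locus in names(plans)) {
    g <- gen_intron_alignment(cfg, locus, aln_taxa, plans[[locus]],
                              outgroups = outgroup)
    alns[[locus]] <- g$aln
    ev_truth <- rbind(ev_truth, g$events)
  }

  hot <- gen_hotspot_alignment(cfg)
  trna <- gen_trna_set(cfg, taxonomy)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "genbank"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
    for (tx in names(texts))
      writeLines(texts[[tx]], file.path(out_dir, "genbank",
                                        paste0(tx, ".gb")))
    for (locus in names(alns))
      write_alignment(alns[[locus]],
                      file.path(out_dir, "alignments", paste0(locus, ".fasta")))
    write_alignment(hot$aln, file.path(out_dir, "alignments", "hotspot.fasta"))
    write_trna_structures(trna$structs, file.path(out_dir, "trna.tsv"))
    writeLines(tt$newick, file.path(out_dir, "tree.nwk"))
    write.table(taxonomy, file.path(out_dir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  list(cfg = cfg, taxonomy = taxonomy, newick = tt$newick, tree = tt$tree,
       plastomes = plastomes, genbank_texts = texts,
       intron_alignments = alns, hotspot = hot, trna = trna,
       outgroup = outgroup,
       truth = list(junctions = jt, indel_events = ev_truth,
                    trna_classes = trna$truth,
                    hotspot_interval = hot$truth$interval))
}
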