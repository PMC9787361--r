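# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive results from first principles with different
# code paths than the package implementation.

# Average pairwise difference proportion over gap-free columns, by explicit
# double loop over sequence pairs.
oracle_pi <- function(aln) {
  n <- nrow(aln)
  keep <- apply(aln, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep)) return(NA_real_)
  sub <- aln[, keep, drop = FALSE]
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(sub[i, ] != sub[j, ])
  tot / (n * (n - 1) / 2) / ncol(sub)
}

# Maximal gap runs per row via regex on the pasted string; grouped by exact
# coordinates; terminal runs dropped; single-position absorption applied by
# literal re-reading of the rule.
oracle_indel_events <- function(aln, merge_single_flank = TRUE) {
  L <- ncol(aln)
  taxa <- rownames(aln)
  events <- list()
  for (i in seq_len(nrow(aln))) {
    s <- paste(aln[i, ], collapse = "")
    m <- gregexpr("-+", s)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      st <- m[k]; len <- attr(m, "match.length")[k]
      if (st == 1 || st + len - 1 == L) next       # terminal run
      key <- sprintf("%d:%d", st - 1, st + len - 1) # 0-based half-open
      events[[key]] <- c(events[[key]], taxa[i])
    }
  }
  if (length(events) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      bearers = character(0)))
  co <- do.call(rbind, strsplit(names(events), ":"))
  ev <- data.frame(start = as.integer(co[, 1]), end = as.integer(co[, 2]),
                   bearers = vapply(events, function(x)
                     paste(sort(unique(x)), collapse = ";"), ""),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  if (merge_single_flank) {
    repeat {
      done <- TRUE
      for (k in seq_len(nrow(ev))) {
        if (ev$end[k] - ev$start[k] != 1) next
        partner <- which(ev$bearers == ev$bearers[k] &
                           (ev$end - ev$start) > 1 &
                           pmax(ev$start, ev$start[k]) -
                             pmin(ev$end, ev$end[k]) <= 1)
        partner <- setdiff(partner, k)
        if (length(partner)) {
          p <- partner[1]
          ev$start[p] <- min(ev$start[p], ev$start[k])
          ev$end[p] <- max(ev$end[p], ev$end[k])
          ev <- ev[-k, , drop = FALSE]
          done <- FALSE
          break
        }
      }
      if (done) break
    }
    ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

# Minimum parsimony steps by exhaustive enumeration of all internal-node
# labelings (and all resolutions of "?" leaves).
oracle_fitch_steps <- function(tree, states, alphabet = c("0", "1")) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  leaf_states <- as.character(states[tree$tip.label])
  free_leaves <- which(leaf_states == "?")
  internals <- sort(unique(edge[, 1]))
  free_nodes <- c(free_leaves, internals)
  grid <- expand.grid(rep(list(alphabet), length(free_nodes)),
                      stringsAsFactors = FALSE)
  nnode <- ntip + tree$Nnode
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- character(nnode)
    lab[seq_len(ntip)] <- leaf_states
    lab[free_nodes] <- as.character(grid[g, ])
    steps <- sum(lab[edge[, 1]] != lab[edge[, 2]])
    if (steps < best) best <- steps
  }
  as.integer(best)
}

# All maximal disjoint reverse-complement repeat pairs of a short sequence:
# for every start pair (i, j) extend the match as far as it goes
# (copy1[i..i+len) == revcomp(copy2[j..j+len))), keep left-maximal runs.
oracle_ir_pairs <- function(seq, min_len) {
  L <- nchar(seq)
  S <- strsplit(seq, "")[[1]]
  Tc <- strsplit(plastcmp::revcomp(seq), "")[[1]]
  # a length-len inverted repeat (copy1 at i, copy2 at j in S) is a common
  # substring of S and its reverse complement T: S[i..] == T[jj..] with
  # j = L - jj - len + 2 (1-based); enumerate left-maximal common runs
  out <- NULL
  for (i in seq_len(L)) for (jj in seq_len(L)) {
    if (i > 1 && jj > 1 && S[i - 1] == Tc[jj - 1]) next   # not left-maximal
    k <- 0
    while (i + k <= L && jj + k <= L && S[i + k] == Tc[jj + k]) k <- k + 1
    if (k >= min_len) {
      j <- L - jj - k + 2
      a <- min(i, j); b <- max(i, j)
      if (a + k <= b)                                      # disjoint copies
        out <- rbind(out, data.frame(start1 = a - 1, start2 = b - 1,
                                     length = k))
    }
  }
  if (is.null(out)) return(NULL)
  unique(out)
}

# Exhaustive constrained cloverleaf enumeration: builds every template
# dot-bracket within the bounds, checks complementarity with an independent
# stack parser, and keeps the best-scoring (most pairs), 5'-most structure.
oracle_fold <- function(seq, bounds) {
  s <- chartr("Tt", "Uu", toupper(seq))
  L <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  ok_pair <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  grid <- expand.grid(a = bounds$acceptor[1]:bounds$acceptor[2],
                      s1 = bounds$s1[1]:bounds$s1[2],
                      d = bounds$d_stem[1]:bounds$d_stem[2],
                      dl = bounds$d_loop[1]:bounds$d_loop[2],
                      s2 = bounds$s2[1]:bounds$s2[2],
                      c_ = bounds$ac_stem[1]:bounds$ac_stem[2],
                      acl = bounds$ac_loop[1]:bounds$ac_loop[2],
                      t = bounds$t_stem[1]:bounds$t_stem[2],
                      tl = bounds$t_loop[1]:bounds$t_loop[2],
                      tail = bounds$tail[1]:bounds$tail[2])
  fixed <- with(grid, 2 * a + s1 + 2 * d + dl + s2 + 2 * c_ + acl +
                  2 * t + tl + tail)
  grid$v <- L - fixed
  grid <- grid[grid$v >= bounds$v[1] & grid$v <= bounds$v[2], , drop = FALSE]
  best_db <- NULL; best_score <- -1; best_open <- NULL
  for (r in seq_len(nrow(grid))) {
    p <- grid[r, ]
    db <- paste0(strrep("(", p$a), strrep(".", p$s1),
                 strrep("(", p$d), strrep(".", p$dl), strrep(")", p$d),
                 strrep(".", p$s2),
                 strrep("(", p$c_), strrep(".", p$acl), strrep(")", p$c_),
                 strrep(".", p$v),
                 strrep("(", p$t), strrep(".", p$tl), strrep(")", p$t),
                 strrep(")", p$a), strrep(".", p$tail))
    stopifnot(nchar(db) == L)
    # independent stack-based pair check
    st <- integer(0); ok <- TRUE; npairs <- 0
    for (i in seq_len(L)) {
      c1 <- substring(db, i, i)
      if (c1 == "(") st <- c(st, i)
      else if (c1 == ")") {
        j <- st[length(st)]; st <- st[-length(st)]
        if (!ok_pair(ch[j], ch[i])) { ok <- FALSE; break }
        npairs <- npairs + 1
      }
    }
    if (!ok) next
    open_pos <- which(strsplit(db, "")[[1]] != ".")
    if (npairs > best_score ||
        (npairs == best_score &&
           paste(sprintf("%03d", open_pos), collapse = "") <
             paste(sprintf("%03d", best_open), collapse = ""))) {
      best_score <- npairs; best_db <- db; best_open <- open_pos
    }
  }
  best_db
}

# Interval Jaccard on 0-based half-open intervals.
jaccard_iv <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (uni == 0) return(0)
  inter / uni
}

# Random gapped alignment for extraction tests: substitutions plus random
# internal gap blocks shared by random taxon subsets.
random_gapped_alignment <- function(n, L, n_events) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  aln <- matrix(rep(anc, each = n), nrow = n,
                dimnames = list(sprintf("t%02d", seq_len(n)), NULL))
  mut <- matrix(runif(n * L) < 0.05, nrow = n)
  aln[mut] <- sample(bases, sum(mut), replace = TRUE)
  if (n_events > 0) for (k in seq_len(n_events)) {
    len <- sample(1:8, 1)
    s <- sample(2:(L - len - 1), 1)
    who <- sample(seq_len(n), sample(seq_len(max(1, n - 1)), 1))
    aln[who, s:(s + len - 1)] <- "-"
  }
  # drop all-gap columns (invalid input by contract)
  aln[, colSums(aln == "-") < n, drop = FALSE]
}

# Convenience wrappers used across test files.
rand_dna_test <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

gc_of <- function(s) plastcmp:::gc_percent(s)

make_cloverleaf_test <- function(...) plastcmp:::make_cloverleaf(...)

clade_tips_test <- function(tree, taxa)
  plastcmp:::clade_tips(tree, ape::getMRCA(tree, taxa))
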