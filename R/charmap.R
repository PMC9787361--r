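# Mapping binary/multistate characters onto a supplied rooted phylogeny:
# Hartigan/Fitch parsimony counts, monophyly tests and node annotation.
# Trees are inputs (ape "phylo" objects); no inference is performed here.

#' Read a Newick tree with optional support labels
#'
#' Internal node labels of the form \code{"BS/PP"} (e.g. \code{97/0.99}) or a
#' single value are parsed into numeric supports; a lone value greater than 1
#' is taken as a bootstrap percentage, otherwise as a posterior probability.
#'
#' @param x a file path or a Newick string.
#' @return an ape \code{phylo} with components \code{BS} and \code{PP}
#'   (numeric, one entry per internal node, \code{NA} when absent).
#' @export
read_tree_support <- function(x) {
  tree <- if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x))
    ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tree)) stop("read_tree_support: Newick parse error")
  if (anyDuplicated(tree$tip.label))
    stop("read_tree_support: duplicated leaf names")
  n_int <- tree$Nnode
  bs <- rep(NA_real_, n_int); pp <- rep(NA_real_, n_int)
  labs <- tree$node.label
  if (!is.null(labs)) {
    for (i in seq_along(labs)) {
      l <- labs[i]
      if (is.na(l) || !nzchar(l)) next
      if (grepl("/", l, fixed = TRUE)) {
        parts <- as.numeric(strsplit(l, "/", fixed = TRUE)[[1]])
        bs[i] <- parts[1L]; pp[i] <- parts[2L]
      } else {
        v <- suppressWarnings(as.numeric(l))
        if (!is.na(v)) { if (v > 1) bs[i] <- v else pp[i] <- v }
      }
    }
  }
  tree$BS <- bs
  tree$PP <- pp
  tree
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, clade_tips, tree = tree))
}

#' Test monophyly of a taxon set
#'
#' @param tree an ape \code{phylo}.
#' @param taxa character vector of leaf names (a singleton is monophyletic by
#'   convention).
#' @return list: \code{monophyletic} (logical) and \code{mrca} (node id; the
#'   leaf itself for a singleton).
#' @export
is_monophyletic <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("is_monophyletic: unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L)
    return(list(monophyletic = TRUE, mrca = match(taxa, tree$tip.label)))
  mrca <- ape::getMRCA(tree, taxa)
  list(monophyletic = setequal(clade_tips(tree, mrca), taxa), mrca = mrca)
}

# Deterministic state pick from a set: "0" preferred, then lexicographic.
pick_state <- function(set, prefer = "0") {
  if (prefer %in% set) prefer else sort(set)[1L]
}

#' Minimum parsimony steps and origin count of a character on a tree
#'
#' Bottom-up Hartigan pass (the Fitch algorithm generalized to
#' multifurcations) counts the minimum number of state changes; \code{?}
#' leaves are wildcards (any observed state).  A deterministic top-down pass
#' then fixes one most-parsimonious reconstruction, delaying changes
#' (DELTRAN-style: a child keeps its parent's state whenever its state set
#' allows), and counts independent origins of the derived state.  A second
#' pass preferring the derived state (ACCTRAN-leaning) is used only to flag
#' reconstructions whose origin count is ambiguous.
#'
#' @param tree an ape \code{phylo} (rooted; binary or multifurcating).
#' @param states named character vector of leaf states (\code{"?"} =
#'   unconstrained); every leaf must be named.
#' @param derived the derived state whose origins are counted (default
#'   \code{"1"}).
#' @param origins set FALSE to skip the reconstruction passes and return the
#'   step count only (faster for bulk scans).
#' @return list: \code{steps}, \code{origins}, \code{origin_nodes} (nodes
#'   whose subtrees acquired the derived state), \code{assignment} (state per
#'   node), \code{ambiguous} (TRUE when the two tie-break policies disagree
#'   on the origin count).
#' @export
fitch_steps <- function(tree, states, derived = "1", origins = TRUE) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("fitch_steps: no state for leaves: ", paste(miss, collapse = ", "))
  leaf_states <- as.character(states[tree$tip.label])
  alphabet <- sort(unique(leaf_states[leaf_states != "?"]))
  if (length(alphabet) == 0L) stop("fitch_steps: all states are '?'")

  sets <- vector("list", nnode)
  for (i in seq_len(ntip))
    sets[[i]] <- if (leaf_states[i] == "?") alphabet else leaf_states[i]

  edge <- tree$edge
  kids_of <- split(edge[, 2L], edge[, 1L])
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  steps <- 0L
  downpass <- function(node) {
    kids <- kids_of[[as.character(node)]]
    if (is.null(kids)) return(invisible(NULL))          # leaf
    for (k in kids) downpass(k)
    st <- unlist(sets[kids], use.names = FALSE)
    u <- unique(st)
    cnt <- tabulate(match(st, u))
    m <- max(cnt)
    sets[[node]] <<- sort(u[cnt == m])
    steps <<- steps + length(kids) - m
    invisible(NULL)
  }
  downpass(root)
  if (!origins)
    return(list(steps = as.integer(steps), origins = NA_integer_,
                origin_nodes = integer(0), assignment = NULL,
                ambiguous = NA))

  assign_pass <- function(prefer) {
    asg <- character(nnode)
    asg[root] <- pick_state(sets[[root]], prefer)
    uppass <- function(node) {
      kids <- kids_of[[as.character(node)]]
      if (is.null(kids)) return(invisible(NULL))
      for (k in kids) {
        asg[k] <<- if (asg[node] %in% sets[[k]]) asg[node]
                   else pick_state(sets[[k]], prefer)
        uppass(k)
      }
      invisible(NULL)
    }
    uppass(root)
    asg
  }
  count_origins <- function(asg) {
    orig <- if (asg[root] == derived) root else integer(0)
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; k <- edge[e, 2L]
      if (asg[p] != derived && asg[k] == derived) orig <- c(orig, k)
    }
    orig
  }
  asg <- assign_pass("0")
  origin_nodes <- count_origins(asg)
  alt <- count_origins(assign_pass(derived))
  list(steps = as.integer(steps), origins = length(origin_nodes),
       origin_nodes = origin_nodes, assignment = asg,
       ambiguous = length(origin_nodes) != length(alt))
}

#' Classify a mapped character as clade-specific, family-specific or
#' homoplastic
#'
#' A single origin makes the character clade-specific to the origin node;
#' when that clade's leaves are exactly one family's sampled taxa it is
#' additionally family-specific.  Two or more origins are homoplasy.
#' Characters whose derived state is borne by a single leaf are reported as
#' autapomorphies rather than dropped.
#'
#' @param tree an ape \code{phylo}.
#' @param states named leaf states as in \code{\link{fitch_steps}}.
#' @param taxonomy taxonomy data.frame (taxon, family).
#' @param derived derived state (default \code{"1"}).
#' @return list: category (one of \code{"family-specific"},
#'   \code{"clade-specific"}, \code{"autapomorphy"}, \code{"homoplastic"},
#'   \code{"absent"}), node, family, origins, steps, ambiguous.
#' @export
classify_character <- function(tree, states, taxonomy, derived = "1") {
  bearer_leaves <- names(states)[states == derived]
  if (length(bearer_leaves) == 0L)
    return(list(category = "absent", node = NA_integer_,
                family = NA_character_, origins = 0L, steps = 0L,
                ambiguous = FALSE))
  fit <- fitch_steps(tree, states, derived)
  if (fit$origins >= 2L)
    return(list(category = "homoplastic", node = NA_integer_,
                family = NA_character_, origins = fit$origins,
                steps = fit$steps, ambiguous = fit$ambiguous))
  node <- fit$origin_nodes[1L]
  tips <- clade_tips(tree, node)
  fam <- NA_character_
  cat <- if (length(bearer_leaves) == 1L) "autapomorphy" else "clade-specific"
  if (cat == "clade-specific") {
    fams <- unique(family_of(tips, taxonomy))
    if (length(fams) == 1L) {
      fam_taxa <- intersect(taxonomy$taxon[taxonomy$family == fams],
                            tree$tip.label)
      if (setequal(tips, fam_taxa)) { cat <- "family-specific"; fam <- fams }
    }
  }
  list(category = cat, node = node, family = fam, origins = fit$origins,
       steps = fit$steps, ambiguous = fit$ambiguous)
}

#' Attach clade-specific characters to their origin nodes
#'
#' @param tree an ape \code{phylo}.
#' @param characters character matrix (taxa x characters, entries
#'   \code{"0"}/\code{"1"}/\code{"?"}) or named list of state vectors.
#' @param taxonomy taxonomy data.frame (taxon, family).
#' @return list: \code{node_annotations} (node, character, category, family),
#'   \code{homoplastic} (character, origins), \code{autapomorphies}
#'   (character, node), \code{classifications} (full per-character list).
#' @export
annotate_nodes <- function(tree, characters, taxonomy) {
  if (is.matrix(characters)) {
    ids <- colnames(characters)
    if (is.null(ids)) ids <- paste0("c", seq_len(ncol(characters)))
    characters <- setNames(lapply(seq_len(ncol(characters)), function(j)
      setNames(characters[, j], rownames(characters))), ids)
  }
  cls <- lapply(characters, function(st)
    classify_character(tree, st, taxonomy))
  node_rows <- list(); homo_rows <- list(); auta_rows <- list()
  for (id in names(cls)) {
    c1 <- cls[[id]]
    if (c1$category %in% c("clade-specific", "family-specific")) {
      node_rows[[id]] <- data.frame(node = c1$node, character = id,
                                    category = c1$category,
                                    family = c1$family,
                                    stringsAsFactors = FALSE)
    } else if (c1$category == "homoplastic") {
      homo_rows[[id]] <- data.frame(character = id, origins = c1$origins,
                                    stringsAsFactors = FALSE)
    } else if (c1$category == "autapomorphy") {
      auta_rows[[id]] <- data.frame(character = id, node = c1$node,
                                    stringsAsFactors = FALSE)
    }
  }
  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  list(
    node_annotations = bind(node_rows,
      data.frame(node = integer(0), character = character(0),
                 category = character(0), family = character(0))),
    homoplastic = bind(homo_rows,
      data.frame(character = character(0), origins = integer(0))),
    autapomorphies = bind(auta_rows,
      data.frame(character = character(0), node = integer(0))),
    classifications = cls)
}
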