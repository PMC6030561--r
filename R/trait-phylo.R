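# Discrete ICM traits (localization pattern, architecture) on a rooted
# species tree: Newick input, leaf-state attachment, minimum-change
# (Fitch) ancestral reconstruction generalized to multifurcations by a
# unit-cost dynamic program, and mapping of change-bearing branches.

#' Read a rooted tree from Newick text or file
#'
#' Thin wrapper over `ape` with explicit validation: unbalanced
#' parentheses are reported with their character offset, duplicate leaf
#' labels are an error.
#'
#' @param x Newick string or path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "")
         else x
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("read_newick: unbalanced ')' at offset ", i)
  }
  if (depth != 0L)
    stop("read_newick: unbalanced '(' (", depth,
         " unclosed) at offset ", length(chars))
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("read_newick: parse failure")
  if (anyDuplicated(tree$tip.label))
    stop("read_newick: duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Write a tree as Newick text
#' @param tree an [ape::phylo].
#' @param path optional file path; returns the string when `NULL`.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(path)) }
  txt
}

#' Attach leaf trait states to a tree
#'
#' @param tree an [ape::phylo] (rooted).
#' @param table data frame with columns `species` and `state` (or a CSV
#'   path to one).
#' @param alphabet allowed states; defaults to the states present.
#' @param missing_policy leaves absent from the table: `"error"` or
#'   `"exclude"` (pruned, with a message).
#' @return a `trait_tree` list: `tree`, `states` (named character),
#'   `alphabet`, `excluded`.
#' @export
attach_traits <- function(tree, table, alphabet = NULL,
                          missing_policy = c("error", "exclude")) {
  missing_policy <- match.arg(missing_policy)
  if (is.character(table) && length(table) == 1) table <- read.csv(table)
  stopifnot(all(c("species", "state") %in% names(table)))
  if (is.null(alphabet)) alphabet <- sort(unique(table$state))
  bad <- which(!(table$state %in% alphabet))
  if (length(bad))
    stop("attach_traits: state not in alphabet in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(table$state[bad]), collapse = ", "))
  states <- setNames(table$state, table$species)
  missing <- setdiff(tree$tip.label, names(states))
  excluded <- character(0)
  if (length(missing)) {
    if (missing_policy == "error")
      stop("attach_traits: no state for leaves: ",
           paste(missing, collapse = ", "))
    message("attach_traits: excluding unstated leaves: ",
            paste(missing, collapse = ", "))
    tree <- ape::drop.tip(tree, missing)
    excluded <- missing
  }
  structure(list(tree = tree, states = states[tree$tip.label],
                 alphabet = alphabet, excluded = excluded),
            class = "trait_tree")
}

# Unit-cost subtree (up) and complement (down) cost tables, supporting
# multifurcations. Rows: nodes in ape numbering; cols: alphabet states.
parsimony_tables <- function(tt) {
  tree <- tt$tree
  A <- tt$alphabet
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  up <- matrix(Inf, nn, length(A), dimnames = list(NULL, A))
  for (i in seq_len(nt)) up[i, tt$states[tree$tip.label[i]]] <- 0
  children <- split(tree$edge[, 2], tree$edge[, 1])
  # postorder: process internal nodes in decreasing depth
  depth <- rep(0L, nn)
  root <- nt + 1L
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(ord))) depth[ord[k, 2]] <- depth[ord[k, 1]] + 1L
  internal <- (nt + 1L):nn
  for (v in internal[order(depth[internal], decreasing = TRUE)]) {
    kids <- children[[as.character(v)]]
    for (s in seq_along(A)) {
      tot <- 0
      for (c in kids) tot <- tot + min(up[c, s], min(up[c, ]) + 1)
      up[v, s] <- tot
    }
  }
  down <- matrix(0, nn, length(A), dimnames = list(NULL, A))
  for (v in internal[order(depth[internal])]) {
    kids <- children[[as.character(v)]]
    kid_min <- vapply(kids, function(c) min(up[c, ]), numeric(1))
    for (ci in seq_along(kids)) {
      c <- kids[ci]
      for (s in seq_along(A)) {
        best <- Inf
        for (a in seq_along(A)) {
          oth <- 0
          for (cj in seq_along(kids)) {
            if (cj == ci) next
            oth <- oth + min(up[kids[cj], a], kid_min[cj] + 1)
          }
          best <- min(best, down[v, a] + (a != s) + oth)
        }
        down[c, s] <- best
      }
    }
  }
  list(up = up, down = down, root = root, children = children,
       depth = depth, n_tips = nt)
}

#' Minimum-change ancestral state reconstruction
#'
#' Computes the parsimony score (minimum number of state changes over all
#' full labelings) and, for every node, the set of states attained by at
#' least one maximum-parsimony labeling. Multifurcations are handled
#' natively by the unit-cost dynamic program; on binary trees the score
#' equals the classical Fitch length.
#'
#' @param tt a `trait_tree` from [attach_traits()].
#' @return `tt` with added `min_changes` (integer), `node_state_sets`
#'   (list over nodes, ape numbering; tips first), and the internal cost
#'   tables.
#' @export
fitch_parsimony <- function(tt) {
  stopifnot(inherits(tt, "trait_tree"))
  if (anyNA(tt$states))
    stop("fitch_parsimony: unstated leaf present")
  tb <- parsimony_tables(tt)
  total <- tb$up + tb$down
  mc <- min(tb$up[tb$root, ])
  sets <- apply(total, 1, function(r) colnames(tb$up)[r <= mc + 1e-9],
                simplify = FALSE)
  tt$min_changes <- as.integer(round(mc))
  tt$node_state_sets <- sets
  tt$root_set <- sets[[tb$root]]
  tt$tables <- tb
  tt
}

# One maximum-parsimony labeling by top-down assignment. tie_prefer_parent
# delays changes toward the tips (DELTRAN-like); the converse accelerates
# them (ACCTRAN-like). root_state may pin the root to any MP root state.
mp_labeling <- function(tt, tie_prefer_parent = TRUE, root_state = NULL) {
  tb <- tt$tables
  A <- colnames(tb$up)
  nn <- nrow(tb$up)
  lab <- character(nn)
  root_opts <- A[tb$up[tb$root, ] <= min(tb$up[tb$root, ]) + 1e-9]
  if (!is.null(root_state)) {
    if (!root_state %in% root_opts)
      stop("mp_labeling: no maximum-parsimony labeling has root state '",
           root_state, "'")
    lab[tb$root] <- root_state
  } else lab[tb$root] <- root_opts[1]
  internal <- which(seq_len(nn) > tb$n_tips)
  for (v in internal[order(tb$depth[internal])]) {
    kids <- tb$children[[as.character(v)]]
    a <- match(lab[v], A)
    for (c in kids) {
      costs <- vapply(seq_along(A),
                      function(s) tb$up[c, s] + (s != a), numeric(1))
      best <- which(costs <= min(costs) + 1e-9)
      pick <- if (a %in% best) {
        if (tie_prefer_parent) a else best[best != a][1] %||% a
      } else best[1]
      if (is.na(pick)) pick <- best[1]
      lab[c] <- A[pick]
    }
  }
  for (i in seq_len(tb$n_tips)) lab[i] <- tt$states[tt$tree$tip.label[i]]
  lab
}

#' Map state changes onto branches
#'
#' For a reconstructed `trait_tree`, lists the branches bearing a state
#' change. `acctran` and `deltran` return one maximum-parsimony labeling
#' each (ties broken toward early or late changes respectively);
#' `all_mp` returns the union and intersection of change-bearing branches
#' over all maximum-parsimony labelings, computed exactly from the cost
#' tables.
#'
#' @param tt result of [fitch_parsimony()].
#' @param resolution `"acctran"`, `"deltran"`, or `"all_mp"`.
#' @param root_state optional root state (must be in the root MP set) for
#'   the acctran/deltran labelings.
#' @return for acctran/deltran: data frame `parent`, `child`,
#'   `from`, `to` (changed branches only) with the full labeling as
#'   attribute `labeling`; for all_mp: list `union`, `intersection` of
#'   such data frames (without states for branches whose endpoints vary).
#' @export
map_changes <- function(tt, resolution = c("acctran", "deltran", "all_mp"),
                        root_state = NULL) {
  resolution <- match.arg(resolution)
  stopifnot(!is.null(tt$tables))
  tb <- tt$tables
  A <- colnames(tb$up)
  edges <- tt$tree$edge
  if (resolution %in% c("acctran", "deltran")) {
    lab <- mp_labeling(tt, tie_prefer_parent = resolution == "deltran",
                       root_state = root_state)
    chg <- which(lab[edges[, 1]] != lab[edges[, 2]])
    out <- data.frame(parent = edges[chg, 1], child = edges[chg, 2],
                      from = lab[edges[chg, 1]], to = lab[edges[chg, 2]])
    attr(out, "labeling") <- lab
    return(out)
  }
  mc <- tt$min_changes
  kid_min <- function(c) min(tb$up[c, ])
  in_union <- logical(nrow(edges)); in_inter <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1]; v <- edges[k, 2]
    kids <- tb$children[[as.character(u)]]
    best_same <- Inf; best_diff <- Inf
    for (a in seq_along(A)) {
      oth <- 0
      for (c in kids) {
        if (c == v) next
        oth <- oth + min(tb$up[c, a], kid_min(c) + 1)
      }
      base <- tb$down[u, a] + oth
      for (b in seq_along(A)) {
        tot <- base + (a != b) + tb$up[v, b]
        if (a == b) best_same <- min(best_same, tot)
        else best_diff <- min(best_diff, tot)
      }
    }
    in_union[k] <- best_diff <= mc + 1e-9
    in_inter[k] <- best_same > mc + 1e-9
  }
  mk <- function(sel) data.frame(parent = edges[sel, 1],
                                 child = edges[sel, 2])
  list(union = mk(in_union), intersection = mk(in_inter))
}

#' Leaves descending from a node
#' @param tree an [ape::phylo].
#' @param node internal node number (ape numbering).
#' @return character vector of tip labels.
#' @export
clade_tips <- function(tree, node) {
  tree$tip.label[intersect(seq_along(tree$tip.label),
                           ape_descendants(tree, node))]
}

ape_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

#' Paths to the packaged species tree and trait table fixtures
#'
#' Package-curated encodings of the studied purple nonsulfur bacteria:
#' a rooted Newick with the three orders (Rhodospirillales,
#' Rhodobacterales, Rhizobiales) as clades and uncertain within-clade
#' placements as polytomies, plus a species-to-ICM-localization CSV.
#' These are this package's own fixtures, not a published tree file.
#'
#' @return named character vector with elements `tree` and `traits`.
#' @export
pnsb_fixture_paths <- function() {
  c(tree = system.file("extdata", "pnsb_species_tree_synthetic.nwk",
                       package = "icmap"),
    traits = system.file("extdata", "pnsb_icm_traits.csv",
                         package = "icmap"))
}
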