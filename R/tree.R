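#' Ranked species trees
#'
#' A ranked species tree is an [ape::read.tree()] `"phylo"` object whose
#' internal node labels carry integer age ranks in the form `"rank=K"`.
#' Rank 1 marks the youngest internal node class (here, Drosophilidae);
#' the root carries the highest rank (bilaterian origin, rank 7 on the
#' default tree). Ranks must be non-decreasing from the tips toward the
#' root along every path, so that the rank of a family's origin node is a
#' well-defined evolutionary age.
#'
#' @param phy A `"phylo"` object with `rank=K` node labels.
#' @return `phy`, invisibly, after validation.
#' @seealso [default_species_tree()], [assign_age()]
#' @export
validate_species_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  if (is.null(phy$node.label) || !all(grepl("^rank=\\d+$", phy$node.label)))
    stop("every internal node must be labelled 'rank=K' with integer K")
  ranks <- node_age_ranks(phy)
  ntip <- length(phy$tip.label)
  # child rank must not exceed parent rank (ages grow toward the root)
  for (k in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[k, 1L]
    child <- phy$edge[k, 2L]
    if (child > ntip && ranks[child - ntip] > ranks[parent - ntip])
      stop("age ranks must be non-decreasing from tips toward the root")
  }
  invisible(phy)
}

#' Extract the integer age rank of each internal node
#'
#' @param phy A validated ranked species tree.
#' @return Integer vector, one entry per internal node in `phy$node.label`
#'   order (node number `Ntip + i` has rank `node_age_ranks(phy)[i]`).
#' @export
node_age_ranks <- function(phy) {
  as.integer(sub("^rank=", "", phy$node.label))
}

#' Default ranked species tree
#'
#' An eight-taxon ladder tree spanning the species classically used to
#' date Drosophila microRNA families: the two focal Drosophilids
#' (`Dmel`, `Dvir`, rank 1 = Drosophilidae), then successively deeper
#' outgroups up to a cephalochordate (`Bflo`), whose most recent common
#' ancestor with the flies is the bilaterian root (rank 7). Internal
#' nodes are labelled `rank=1` ... `rank=7`.
#'
#' @return A `"phylo"` object passing [validate_species_tree()].
#' @examples
#' tr <- default_species_tree()
#' node_age_ranks(tr)
#' @export
default_species_tree <- function() {
  nwk <- paste0(
    "(((((((Dmel,Dvir)rank=1,Aaeg)rank=2,Bmor)rank=3,Tcas)rank=4,",
    "Dpul)rank=5,Cele)rank=6,Bflo)rank=7;"
  )
  phy <- ape::read.tree(text = nwk)
  validate_species_tree(phy)
  phy
}

#' Read / write a ranked species tree in Newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that
#' validate the `rank=K` node-label convention on the way in.
#'
#' @param path File path.
#' @param phy Tree to write.
#' @return `read_species_tree()` returns a validated `"phylo"` object.
#' @export
read_species_tree <- function(path) {
  phy <- ape::read.tree(path)
  validate_species_tree(phy)
  phy
}

#' @rdname read_species_tree
#' @export
write_species_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Tip species descending from a node
#'
#' @param phy Ranked species tree.
#' @param node Node number (tips are `1..Ntip`, internals follow).
#' @return Character vector of tip labels below `node` (the tip itself
#'   if `node` is a tip).
#' @export
node_species <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  phy$tip.label[.tips_below(phy, node)]
}

.tips_below <- function(phy, node) {
  ntip <- length(phy$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    cur <- todo[1L]
    todo <- todo[-1L]
    kids <- phy$edge[phy$edge[, 1L] == cur, 2L]
    tips <- c(tips, kids[kids <= ntip])
    todo <- c(todo, kids[kids > ntip])
  }
  sort(tips)
}

#' Date a microRNA family origin by parsimony
#'
#' The family origin is placed at the most recent common ancestor of all
#' species carrying a homolog (together with the reference species), and
#' the family's evolutionary age is the integer rank of that node: the
#' deeper the most distant species with a homolog, the older the family.
#' A family present only in the reference species originates on the
#' reference's terminal branch and is assigned rank 0, i.e. younger than
#' any internal rank class.
#'
#' @param presence Character vector of species in which a homolog was
#'   identified. Must be non-empty and a subset of the tree's tips.
#' @param phy Ranked species tree.
#' @param reference Reference species (a tip label); always counted as
#'   present.
#' @return A list of class `"age_assignment"` with elements
#'   `origin_node` (node number), `origin_label` (`"rank=K"` or the tip
#'   label for species-specific families), `age_rank` (integer) and
#'   `species` (the presence set used).
#' @examples
#' tr <- default_species_tree()
#' assign_age(c("Dmel", "Dvir"), tr, "Dmel")$age_rank # 1
#' assign_age(c("Dmel", "Bflo"), tr, "Dmel")$age_rank # 7
#' @export
assign_age <- function(presence, phy, reference) {
  if (length(presence) == 0L) stop("presence set is empty")
  if (!reference %in% phy$tip.label) stop("reference species not on tree")
  presence <- unique(c(presence, reference))
  missing <- setdiff(presence, phy$tip.label)
  if (length(missing))
    stop("species not on tree: ", paste(missing, collapse = ", "))
  ntip <- length(phy$tip.label)
  if (length(presence) == 1L) {
    node <- match(presence, phy$tip.label)
    res <- list(origin_node = node, origin_label = presence,
                age_rank = 0L, species = presence)
  } else {
    node <- ape::getMRCA(phy, presence)
    res <- list(origin_node = node,
                origin_label = phy$node.label[node - ntip],
                age_rank = node_age_ranks(phy)[node - ntip],
                species = presence)
  }
  class(res) <- "age_assignment"
  res
}

#' Date every family in a presence/absence table
#'
#' @param presence_table 0/1 matrix or data frame, rows = families,
#'   columns = species.
#' @param phy Ranked species tree.
#' @param reference Reference species.
#' @return Data frame with columns `family`, `origin_label`, `age_rank`.
#' @export
assign_ages <- function(presence_table, phy, reference) {
  presence_table <- as.matrix(presence_table)
  fams <- rownames(presence_table)
  if (is.null(fams)) fams <- paste0("fam", seq_len(nrow(presence_table)))
  out <- lapply(seq_len(nrow(presence_table)), function(i) {
    sp <- colnames(presence_table)[presence_table[i, ] > 0]
    a <- assign_age(sp, phy, reference)
    data.frame(family = fams[i], origin_label = a$origin_label,
               age_rank = a$age_rank, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Propagate family age to all members
#'
#' Paralogous copies of a family can postdate the family origin; each
#' locus nonetheless inherits the age of the oldest family member, and
#' loci whose own presence-based age is younger than the family age are
#' flagged as duplication-inflated.
#'
#' @param ages Data frame with columns `locus`, `family`, `age_rank`
#'   (each locus's own presence-based rank).
#' @return `ages` with added columns `family_age_rank` (max rank over the
#'   family) and `duplication_inflated` (logical).
#' @export
propagate_family_age <- function(ages) {
  stopifnot(all(c("locus", "family", "age_rank") %in% names(ages)))
  if (nrow(ages) == 0L) stop("no family members")
  fam_max <- tapply(ages$age_rank, ages$family, max)
  ages$family_age_rank <- as.integer(fam_max[as.character(ages$family)])
  ages$duplication_inflated <- ages$age_rank < ages$family_age_rank
  ages
}
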