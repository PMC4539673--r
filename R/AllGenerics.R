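#' Accessors for the core containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an orthoselect object.
#' @return `clusterId`: the cluster identifier; `speciesNames`: character
#'   vector of species; `goTerms`: GO ids of a cluster; `treePhylo`: the
#'   underlying [ape::phylo]; `branchLabels`: "parent -> child" labels,
#'   one per edge; `alignmentRows`: the gapped [Biostrings::DNAStringSet];
#'   `polyData`: the underlying `data.table`; `mkCells`: named numeric of
#'   the four MK cells; `lnL`: log-likelihood of a fit; `omegaEstimates`:
#'   named per-branch omega vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))
#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @rdname accessors
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))
#' @rdname accessors
#' @export
setGeneric("treePhylo", function(x) standardGeneric("treePhylo"))
#' @rdname accessors
#' @export
setGeneric("branchLabels", function(x) standardGeneric("branchLabels"))
#' @rdname accessors
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))
#' @rdname accessors
#' @export
setGeneric("polyData", function(x) standardGeneric("polyData"))
#' @rdname accessors
#' @export
setGeneric("mkCells", function(x) standardGeneric("mkCells"))
#' @rdname accessors
#' @export
setGeneric("lnL", function(x) standardGeneric("lnL"))
#' @rdname accessors
#' @export
setGeneric("omegaEstimates", function(x) standardGeneric("omegaEstimates"))

#' @rdname accessors
setMethod("clusterId", "OrthologCluster", function(x) x@clusterId)
#' @rdname accessors
setMethod("clusterId", "CodonAlignment", function(x) x@clusterId)
#' @rdname accessors
setMethod("speciesNames", "OrthologCluster", function(x) names(x@sequences))
#' @rdname accessors
setMethod("speciesNames", "CodonAlignment", function(x) names(x@rows))
#' @rdname accessors
setMethod("speciesNames", "SpeciesTree", function(x) x@tree$tip.label)
#' @rdname accessors
setMethod("goTerms", "OrthologCluster", function(x) x@goTerms)
#' @rdname accessors
setMethod("treePhylo", "SpeciesTree", function(x) x@tree)
#' @rdname accessors
setMethod("alignmentRows", "OrthologCluster", function(x) x@sequences)
#' @rdname accessors
setMethod("alignmentRows", "CodonAlignment", function(x) x@rows)
#' @rdname accessors
setMethod("polyData", "PolymorphismTable", function(x) data.table::copy(x@data))
#' @rdname accessors
setMethod("mkCells", "MKCounts", function(x)
  c(Dn = x@dn, Ds = x@ds, Pn = x@pn, Ps = x@ps))
#' @rdname accessors
setMethod("lnL", "CodonModelFit", function(x) x@lnL)
#' @rdname accessors
setMethod("omegaEstimates", "CodonModelFit", function(x) x@omega)

#' @rdname accessors
setMethod("branchLabels", "SpeciesTree", function(x) phyloBranchLabels(x@tree))

#' Edge labels of a labelled phylo tree
#'
#' Derives the canonical "parent -> child" label for every edge of a tree
#' whose internal nodes are all labelled.
#'
#' @param tr an [ape::phylo] with complete `node.label`.
#' @return character vector, one label per row of `tr$edge`.
#' @export
phyloBranchLabels <- function(tr) {
  labs <- c(tr$tip.label, tr$node.label)
  paste(labs[tr$edge[, 1]], "->", labs[tr$edge[, 2]])
}
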