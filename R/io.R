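#' Readers and writers for the pipeline's external formats
#'
#' FASTA ortholog clusters, Newick species trees, TSV polymorphism tables
#' and TSV GO annotation maps. All coordinates written to or read from
#' files are 0-based.
#'
#' @name io
NULL

#' Construct an ortholog cluster
#'
#' @param clusterId cluster identifier.
#' @param sequences named character vector or [Biostrings::DNAStringSet]
#'   of ungapped coding sequences, named by species.
#' @param goTerms optional character vector of GO ids.
#' @return an [OrthologCluster].
#' @export
orthologCluster <- function(clusterId, sequences, goTerms = character()) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  new("OrthologCluster", clusterId = clusterId, sequences = sequences,
      goTerms = as.character(goTerms))
}

#' Read an ortholog cluster from FASTA
#'
#' Record ids are mapped to species through `speciesMap`, a named character
#' vector whose names are regular-expression patterns and whose values are
#' species names. Every record must match exactly one species; when a
#' species has several records the longest is kept with a warning.
#'
#' @param path FASTA file with one record per transcript.
#' @param speciesMap named character: pattern -> species name.
#' @param clusterId cluster id; defaults to the file name without
#'   extension.
#' @return an [OrthologCluster].
#' @export
readClusterFasta <- function(path, speciesMap,
                             clusterId = sub("\\.[^.]*$", "", basename(path))) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- names(seqs)
  sp <- character(length(ids))
  for (k in seq_along(ids)) {
    hit <- which(vapply(names(speciesMap), grepl, logical(1), x = ids[k]))
    if (length(hit) == 0L)
      stop("record id matches no species pattern: ", ids[k])
    if (length(hit) > 1L)
      stop("record id matches multiple species patterns: ", ids[k])
    sp[k] <- speciesMap[[hit]]
  }
  keep <- integer(0)
  for (s in unique(sp)) {
    idx <- which(sp == s)
    if (length(idx) > 1L) {
      warning("species ", s, " has ", length(idx),
              " records; keeping the longest")
      idx <- idx[which.max(Biostrings::width(seqs)[idx])]
    }
    keep <- c(keep, idx)
  }
  keep <- sort(keep)
  out <- seqs[keep]
  names(out) <- sp[keep]
  out <- out[order(names(out))]
  orthologCluster(clusterId, out)
}

#' Write an ortholog cluster to FASTA
#'
#' @param cluster an [OrthologCluster].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClusterFasta <- function(cluster, path) {
  Biostrings::writeXStringSet(alignmentRows(cluster), path, width = 80L)
  invisible(path)
}

#' Promote a phylo tree to a SpeciesTree
#'
#' Validates that the tree is rooted, binary and has at least two leaves,
#' then labels any unlabelled internal nodes `n1, n2, ...` in post-order
#' (deterministic across reads), avoiding collisions with existing labels.
#'
#' @param tr an [ape::phylo].
#' @return a [SpeciesTree].
#' @export
speciesTreeFromPhylo <- function(tr) {
  stopifnot(inherits(tr, "phylo"))
  if (length(tr$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (!ape::is.binary(tr) || !ape::is.rooted(tr))
    stop("tree must be rooted and binary")
  ntip <- length(tr$tip.label)
  labs <- tr$node.label
  if (is.null(labs)) labs <- rep("", tr$Nnode)
  labs[is.na(labs)] <- ""
  post <- ape::reorder.phylo(tr, "postorder")
  internalOrder <- unique(post$edge[, 1]) - ntip
  used <- c(tr$tip.label, labs[nzchar(labs)])
  counter <- 1L
  for (v in internalOrder) {
    if (nzchar(labs[v])) next
    repeat {
      cand <- paste0("n", counter)
      counter <- counter + 1L
      if (!cand %in% used) break
    }
    labs[v] <- cand
    used <- c(used, cand)
  }
  tr$node.label <- labs
  new("SpeciesTree", tree = tr)
}

#' Read a species tree from a Newick file
#'
#' @param path Newick file with named leaves; internal labels optional
#'   (missing ones are auto-assigned, see [speciesTreeFromPhylo()]).
#' @return a [SpeciesTree].
#' @export
readSpeciesTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  speciesTreeFromPhylo(tr)
}

#' Construct a polymorphism table
#'
#' @param df data.frame/data.table with columns `species`, `cluster_id`,
#'   `column_index` (0-based alignment column), `depth`, `count_A`,
#'   `count_C`, `count_G`, `count_T`. Duplicate keys resolve to the last
#'   row with a warning.
#' @return a [PolymorphismTable].
#' @export
polymorphismTable <- function(df) {
  d <- data.table::as.data.table(df)
  need <- c("species", "cluster_id", "column_index", "depth",
            "count_A", "count_C", "count_G", "count_T")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  num <- d[, c("depth", "count_A", "count_C", "count_G", "count_T")]
  if (any(vapply(num, function(x) any(x < 0), logical(1))))
    stop("negative depth or allele count")
  dup <- duplicated(d, by = c("species", "cluster_id", "column_index"),
                    fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate (species, cluster, column) keys; last wins")
    d <- d[!dup]
  }
  data.table::setkeyv(d, c("species", "cluster_id", "column_index"))
  new("PolymorphismTable", data = d)
}

#' Read a polymorphism table from TSV
#'
#' @param path TSV with the columns listed in [polymorphismTable()].
#' @return a [PolymorphismTable].
#' @export
readPolymorphismTable <- function(path) {
  polymorphismTable(data.table::fread(path, sep = "\t"))
}

#' Write a polymorphism table to TSV
#'
#' @param poly a [PolymorphismTable].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePolymorphismTable <- function(poly, path) {
  data.table::fwrite(polyData(poly), path, sep = "\t")
  invisible(path)
}

#' Look up one polymorphism record
#'
#' @param poly a [PolymorphismTable].
#' @param species,cluster,column key (column 0-based).
#' @return list with `depth` and named `counts`, or `NULL` when the
#'   position is absent (monomorphic with unknown depth).
#' @export
polyLookup <- function(poly, species, cluster, column) {
  d <- poly@data
  idx <- which(d$species == species & d$cluster_id == cluster &
                 d$column_index == as.integer(column))
  if (!length(idx)) return(NULL)
  i <- idx[length(idx)]
  list(depth = d$depth[i],
       counts = c(A = d$count_A[i], C = d$count_C[i],
                  G = d$count_G[i], T = d$count_T[i]))
}

#' Read a GO annotation map
#'
#' @param path TSV: `cluster_id<TAB>GO:NNNNNNN;GO:NNNNNNN` (the second
#'   field may be empty).
#' @return named list: cluster id -> character vector of GO ids.
#' @export
readGoAnnotations <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  stopifnot(ncol(d) >= 2L)
  terms <- strsplit(d[[2]], ";", fixed = TRUE)
  terms <- lapply(terms, function(x) x[nzchar(x)])
  setNames(terms, d[[1]])
}

#' Write a GO annotation map
#'
#' @param annotations named list: cluster id -> GO ids.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeGoAnnotations <- function(annotations, path) {
  d <- data.frame(cluster_id = names(annotations),
                  go_terms = vapply(annotations, paste,
                                    character(1), collapse = ";"))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [CodonAlignment].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(aln, path) {
  Biostrings::writeXStringSet(alignmentRows(aln), path, width = 80L)
  invisible(path)
}

#' Read a codon alignment from FASTA
#'
#' @param path aligned FASTA whose records are named by species.
#' @param clusterId cluster id; defaults to the file name without
#'   extension.
#' @return a [CodonAlignment].
#' @export
readAlignmentFasta <- function(path,
                               clusterId = sub("\\.[^.]*$", "", basename(path))) {
  rows <- Biostrings::readDNAStringSet(path)
  rows <- rows[order(names(rows))]
  new("CodonAlignment", clusterId = clusterId, rows = rows)
}
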