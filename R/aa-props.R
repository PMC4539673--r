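#' Physicochemical amino-acid property divergence test
#'
#' For every branch of the tree, non-synonymous codon changes (between
#' marginally reconstructed ancestral and observed states) are scored by
#' the magnitude of the physicochemical property change they cause.
#' Magnitudes are binned into 8 equal-width impact classes calibrated
#' against the distribution expected when every single-nucleotide
#' non-synonymous change in the genetic code is equally likely; sliding
#' 20-codon windows are tested for excess radical change by a chi-squared
#' goodness-of-fit test.
#'
#' @name aa-props
NULL

# 31 published amino-acid property scales (AAindex accessions) used as the
# default property set: bulkiness, polarity, isoelectric point, hydropathy,
# volume and related scales. Any user-supplied table is accepted.
.defaultPropertyAccessions <- c(
  "ZIMJ680102", "GRAR740102", "ZIMJ680104", "KYTJ820101", "GRAR740103",
  "BIGC670101", "CHOC760101", "FAUJ880103", "DAYM780201", "FASG760101",
  "JOND750101", "ZIMJ680101", "CHAM820101", "CHAM830107", "FAUJ880109",
  "FAUJ880111", "FAUJ880112", "JANJ780101", "RADA880108", "ROSG850101",
  "WOEC730101", "GOLD730101", "KRIW790101", "LEVM760101", "NISK800101",
  "OOBM770101", "PONP800101", "BHAR880101", "EISD840101", "HOPT810101",
  "JOND920102")

#' Default table of 31 amino-acid property scales
#'
#' Published scales (bulkiness, polarity, isoelectric point, hydropathy,
#' volume, surface area, charge, flexibility, ...) drawn from the AAindex
#' collection shipped with the seqinr package. Every scale covers all 20
#' amino acids with finite values.
#'
#' @return numeric matrix, 20 rows (one-letter amino acids) x 31 columns
#'   (AAindex accession ids); attribute `descriptions` holds the
#'   human-readable scale names.
#' @export
defaultPropertyTable <- function() {
  if (!is.null(.osCache$propertyTable)) return(.osCache$propertyTable)
  e <- new.env()
  utils::data("aaindex", package = "seqinr", envir = e)
  aaindex <- e$aaindex
  cols <- lapply(.defaultPropertyAccessions, function(acc) {
    entry <- aaindex[[acc]]
    if (is.null(entry)) stop("AAindex accession not found: ", acc)
    v <- entry$I
    names(v) <- seqinr::a(names(v))
    if (any(is.na(v))) stop("incomplete property scale: ", acc)
    v[sort(names(v))]
  })
  tab <- do.call(cbind, cols)
  colnames(tab) <- .defaultPropertyAccessions
  attr(tab, "descriptions") <- vapply(.defaultPropertyAccessions,
                                      function(acc) aaindex[[acc]]$D,
                                      character(1))
  .osCache$propertyTable <- tab
  tab
}

.checkPropertyTable <- function(properties) {
  stopifnot(is.matrix(properties), nrow(properties) == 20L,
            !is.null(rownames(properties)), !is.null(colnames(properties)),
            all(is.finite(properties)))
  properties
}

# impact class of an absolute property change given the neutral range
.magnitudeClass <- function(delta, maxDelta, nClasses = 8L) {
  pmin(nClasses, pmax(1L, ceiling(delta / (maxDelta / nClasses))))
}

#' Neutral impact-class distribution of a property
#'
#' Enumerates every single-nucleotide non-synonymous change among the
#' sense codons (equally weighted), bins the absolute property changes
#' into 8 equal-width classes spanning `[0, max observed change]`, and
#' returns the class probabilities.
#'
#' @param property named numeric over the 20 one-letter amino acids.
#' @param code see [resolveGeneticCode()].
#' @return numeric(8) summing to 1, with attribute `maxDelta`.
#' @export
neutralMagnitudeDistribution <- function(property, code = resolveGeneticCode()) {
  code <- resolveGeneticCode(code)
  sc <- senseCodons(code)
  nb <- .codonNeighbors(code)
  ns <- nb[!nb$synonymous, ]
  aaFrom <- unname(code[sc[ns$i]])
  aaTo <- unname(code[sc[ns$j]])
  delta <- abs(property[aaTo] - property[aaFrom])
  maxDelta <- max(delta)
  if (maxDelta <= 0)
    stop("property is constant across amino acids; magnitude classes undefined")
  cls <- .magnitudeClass(delta, maxDelta)
  probs <- tabulate(cls, nbins = 8L) / length(cls)
  attr(probs, "maxDelta") <- maxDelta
  probs
}

# neutral distributions for every column of a property table, cached per
# call site (cheap enough to recompute per cluster batch)
.neutralDistributions <- function(properties, code) {
  key <- paste0("neutral_", .codeKey(code), "_",
                paste(colnames(properties), collapse = ","))
  if (!is.null(.osCache[[key]])) return(.osCache[[key]])
  nd <- lapply(seq_len(ncol(properties)), function(k)
    neutralMagnitudeDistribution(properties[, k], code))
  names(nd) <- colnames(properties)
  .osCache[[key]] <- nd
  nd
}

#' Amino-acid property change events along branches
#'
#' Reconstructs marginal ML ancestral codons under the fitted one-ratio
#' model and, for every branch and codon where the parent and child amino
#' acids differ, emits one event per property with the absolute property
#' change and its impact class. Codons with unresolved ancestral states
#' are skipped on that branch.
#'
#' @param aln a [CodonAlignment].
#' @param tree the [SpeciesTree] used for fitting.
#' @param fit a one-ratio [CodonModelFit].
#' @param properties property matrix as from [defaultPropertyTable()].
#' @param code see [resolveGeneticCode()].
#' @param minPosterior ancestral resolution threshold (default 0.5).
#' @return data.frame: branch, codon_index (0-based), aa_from, aa_to,
#'   property, delta, magnitude_class.
#' @export
branchEvents <- function(aln, tree, fit, properties = defaultPropertyTable(),
                         code = resolveGeneticCode(), minPosterior = 0.5) {
  code <- resolveGeneticCode(code)
  properties <- .checkPropertyTable(properties)
  anc <- ancestralCodons(aln, tree, fit, code, minPosterior)
  st <- anc$states
  prep <- anc$prep
  sc <- anc$codons
  labs <- rownames(st)
  nd <- .neutralDistributions(properties, code)

  recs <- list()
  for (e in seq_len(nrow(prep$edge))) {
    par <- prep$edge[e, 1]; ch <- prep$edge[e, 2]
    bl <- prep$labels[e]
    pSt <- st[par, ]; cSt <- st[ch, ]
    ok <- which(!is.na(pSt) & !is.na(cSt) & pSt != cSt)
    if (!length(ok)) next
    aaFrom <- unname(code[sc[pSt[ok]]])
    aaTo <- unname(code[sc[cSt[ok]]])
    changed <- aaFrom != aaTo
    if (!any(changed)) next
    idx <- ok[changed]
    recs[[length(recs) + 1L]] <- data.frame(
      branch = bl, codon_index = idx - 1L,
      aa_from = aaFrom[changed], aa_to = aaTo[changed],
      row.names = NULL)
  }
  if (!length(recs))
    return(data.frame(branch = character(), codon_index = integer(),
                      aa_from = character(), aa_to = character(),
                      property = character(), delta = numeric(),
                      magnitude_class = integer()))
  base <- do.call(rbind, recs)
  out <- do.call(rbind, lapply(colnames(properties), function(pn) {
    v <- properties[, pn]
    delta <- abs(v[base$aa_to] - v[base$aa_from])
    cbind(base,
          data.frame(property = pn, delta = unname(delta),
                     magnitude_class = .magnitudeClass(
                       unname(delta), attr(nd[[pn]], "maxDelta")),
                     row.names = NULL))
  }))
  rownames(out) <- NULL
  out
}

# chi-squared goodness of fit with pooling of low-expectation classes
.gofChisq <- function(observed, probs, minExpected = 1) {
  n <- sum(observed)
  expected <- probs * n
  groupsO <- as.list(observed); groupsE <- as.list(expected)
  repeat {
    ge <- vapply(groupsE, sum, numeric(1))
    if (length(ge) <= 1L || all(ge >= minExpected)) break
    iMin <- which.min(ge)
    ord <- order(ge)
    iNext <- ord[ord != iMin][1]
    groupsO[[iNext]] <- c(groupsO[[iNext]], groupsO[[iMin]])
    groupsE[[iNext]] <- c(groupsE[[iNext]], groupsE[[iMin]])
    groupsO[[iMin]] <- NULL; groupsE[[iMin]] <- NULL
  }
  o <- vapply(groupsO, sum, numeric(1))
  e <- vapply(groupsE, sum, numeric(1))
  df <- length(o) - 1L
  if (df < 1L) return(list(chi2 = NA_real_, df = 0L, p = NA_real_))
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Sliding-window goodness-of-fit scan of impact classes
#'
#' Slides a window (default 20 codons, step 1) along the alignment and
#' tests, for one property on one branch, whether the observed
#' impact-class counts deviate from the neutral expectation. Classes with
#' expected count below 1 are pooled; windows with fewer than `minEvents`
#' events are skipped.
#'
#' @param events event table from [branchEvents()].
#' @param property property (column) name.
#' @param branch branch label.
#' @param nCodons total codons in the alignment.
#' @param neutral neutral class probabilities from
#'   [neutralMagnitudeDistribution()] for this property.
#' @param window window size in codons (default 20).
#' @param step window step in codons (default 1).
#' @param minEvents minimum events per tested window (default 2).
#' @return data.frame: branch, property, window_start (0-based codon),
#'   n_events, chi2, df, p.
#' @export
windowScan <- function(events, property, branch, nCodons, neutral,
                       window = 20L, step = 1L, minEvents = 2L) {
  stopifnot(nCodons >= window)
  ev <- events[events$property == property & events$branch == branch, ]
  starts <- seq(0L, nCodons - window, by = step)
  rows <- lapply(starts, function(s) {
    inWin <- ev$codon_index >= s & ev$codon_index < s + window
    n <- sum(inWin)
    if (n < minEvents) return(NULL)
    obs <- tabulate(ev$magnitude_class[inWin], nbins = 8L)
    g <- .gofChisq(obs, neutral)
    if (g$df < 1L) return(NULL)
    data.frame(branch = branch, property = property, window_start = s,
               n_events = n, chi2 = g$chi2, df = g$df, p = g$p,
               row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(branch = character(), property = character(),
                      window_start = integer(), n_events = integer(),
                      chi2 = numeric(), df = integer(), p = numeric()))
  do.call(rbind, rows)
}

#' Branch-level positive call from the property test
#'
#' A branch is called positive when some property has a window with
#' `p < pMax` containing at least `minCodons` distinct codons whose events
#' for that property reach impact class `>= impactMin`.
#'
#' @param windows window table (as from [windowScan()], possibly
#'   concatenated over branches and properties).
#' @param events event table from [branchEvents()].
#' @param branches branch labels to report (defaults to those in
#'   `windows`/`events`).
#' @param pMax window p-value threshold (default 0.001, exclusive).
#' @param impactMin minimum radical impact class (default 6, inclusive).
#' @param minCodons minimum distinct radical codons per window (default 2).
#' @param window window size in codons (must match the scan; default 20).
#' @return data.frame: branch, positive.
#' @export
callTreesaapPositive <- function(windows, events, branches = NULL,
                                 pMax = 0.001, impactMin = 6L,
                                 minCodons = 2L, window = 20L) {
  if (is.null(branches))
    branches <- sort(unique(c(windows$branch, events$branch)))
  res <- vapply(branches, function(b) {
    w <- windows[windows$branch == b & windows$p < pMax, , drop = FALSE]
    if (!nrow(w)) return(FALSE)
    for (r in seq_len(nrow(w))) {
      ev <- events[events$branch == b & events$property == w$property[r] &
                     events$magnitude_class >= impactMin &
                     events$codon_index >= w$window_start[r] &
                     events$codon_index < w$window_start[r] + window, ,
                   drop = FALSE]
      if (length(unique(ev$codon_index)) >= minCodons) return(TRUE)
    }
    FALSE
  }, logical(1))
  data.frame(branch = branches, positive = unname(res), row.names = NULL)
}

#' Full property-divergence scan of one cluster
#'
#' Convenience wrapper: events, windows over all branch x property
#' combinations, and per-branch calls.
#'
#' @inheritParams branchEvents
#' @param window,step,minEvents window parameters, see [windowScan()].
#' @param pMax,impactMin,minCodons call thresholds, see
#'   [callTreesaapPositive()].
#' @return list with `events`, `windows` and `calls` (cluster_id, method,
#'   branch, positive).
#' @export
treesaapScan <- function(aln, tree, fit, properties = defaultPropertyTable(),
                         code = resolveGeneticCode(),
                         window = 20L, step = 1L, minEvents = 2L,
                         pMax = 0.001, impactMin = 6L, minCodons = 2L,
                         minPosterior = 0.5) {
  code <- resolveGeneticCode(code)
  properties <- .checkPropertyTable(properties)
  nCodons <- Biostrings::width(alignmentRows(aln))[1] %/% 3L
  events <- branchEvents(aln, tree, fit, properties, code, minPosterior)
  nd <- .neutralDistributions(properties, code)
  combos <- unique(events[, c("branch", "property")])
  winList <- lapply(seq_len(nrow(combos)), function(r)
    windowScan(events, combos$property[r], combos$branch[r], nCodons,
               nd[[combos$property[r]]], window, step, minEvents))
  windows <- if (length(winList)) do.call(rbind, winList)
    else data.frame(branch = character(), property = character(),
                    window_start = integer(), n_events = integer(),
                    chi2 = numeric(), df = integer(), p = numeric())
  branches <- phyloBranchLabels(
    .prepTree(tree, unroot = TRUE)$phylo)
  calls <- callTreesaapPositive(windows, events, branches,
                                pMax, impactMin, minCodons, window)
  calls <- cbind(data.frame(cluster_id = clusterId(aln), method = "treesaap"),
                 calls)
  list(events = events, windows = windows, calls = calls)
}
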