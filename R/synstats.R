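## Statistical analysis of a synapse census: per-layer percentage and
## density tables, 2x2 contingency tables of synapse type against
## postsynaptic target with expected counts under independence
## (E_ij = T_i T_j / T), enrichment ratios O/E, chi-squared tests of
## association, and rank-based layer comparisons (Kruskal-Wallis,
## Mann-Whitney). All internal arithmetic is kept at full precision;
## rounding to two decimals happens only at render time.

#' Construct a LayerCountTable
#'
#' @param counts 6 x 6 numeric matrix of per-layer counts; rows AS_head,
#'   AS_neck, AS_shaft, SS_head, SS_neck, SS_shaft; columns layers I-VI.
#' @param densities optional 2 x 6 matrix (rows AS, SS) of per-layer
#'   synapse densities, synapses per um^3.
#' @param spineProfiles optional named vector of spine-profile counts (see
#'   \code{\link{spineProfileCounts}}).
#' @return A \linkS4class{LayerCountTable}.
#' @export
layerCountTable <- function(counts, densities = NULL, spineProfiles = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- .categoryNames
  colnames(counts) <- .layerNames
  if (is.null(densities)) densities <- matrix(numeric(0), 0, 0)
  else {
    densities <- as.matrix(densities)
    rownames(densities) <- c("AS", "SS")
    colnames(densities) <- .layerNames
  }
  if (is.null(spineProfiles)) spineProfiles <- numeric(0)
  new("LayerCountTable", counts = counts, densities = densities,
      spineProfiles = spineProfiles)
}

#' @rdname layerCountTable
#' @param x a LayerCountTable.
#' @export
layerCounts <- function(x) x@counts

#' @rdname layerCountTable
#' @export
layerDensities <- function(x) x@densities

setMethod("show", "LayerCountTable", function(object) {
  cat("LayerCountTable: layer totals",
      paste(colSums(object@counts), collapse = ", "), "\n")
})

#' Read a layer count table from CSV
#'
#' Column schema: `layer` (I-VI) plus the six category columns `AS_head`,
#' `AS_neck`, `AS_shaft`, `SS_head`, `SS_neck`, `SS_shaft`; optional
#' `density_AS`, `density_SS` columns populate the density matrix.
#'
#' @param path CSV path.
#' @return A \linkS4class{LayerCountTable}.
#' @export
readLayerCounts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("layer", .categoryNames) %in% names(df)))
  df <- df[match(.layerNames, df$layer), ]
  dens <- if (all(c("density_AS", "density_SS") %in% names(df)))
    rbind(AS = df$density_AS, SS = df$density_SS) else NULL
  layerCountTable(t(as.matrix(df[, .categoryNames])), densities = dens)
}

#' Bundled reference count tables
#'
#' Per-layer synapse counts, per-layer AS/SS densities, spine
#' single/multiple-synapse tallies, shaft-spininess percentages and
#' identification bookkeeping from a published FIB/SEM census of the
#' neuropil of juvenile (P14) rat somatosensory cortex, shipped as plain
#' CSV under `extdata/`. These make the statistics stage runnable with no
#' upstream imaging.
#'
#' @param name one of `"layer_counts"` (a
#'   \linkS4class{LayerCountTable} including densities),
#'   `"spine_profiles"` (named vector of spine-profile counts),
#'   `"shaft_spininess"` (named vector of percentages) or
#'   `"bookkeeping"` (named vector: identified and truncated totals).
#' @return See `name`.
#' @examples
#' colSums(layerCounts(referenceCounts("layer_counts")))
#' @export
referenceCounts <- function(name = c("layer_counts", "spine_profiles",
                                     "shaft_spininess", "bookkeeping")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "synapseCensus",
                                  mustWork = TRUE)
  switch(name,
    layer_counts = readLayerCounts(path("layer_counts.csv")),
    spine_profiles = {
      df <- utils::read.csv(path("spine_profiles.csv"), stringsAsFactors = FALSE)
      stats::setNames(df$count, df$category)
    },
    shaft_spininess = {
      df <- utils::read.csv(path("shaft_spininess.csv"), stringsAsFactors = FALSE)
      stats::setNames(df$percent, df$group)
    },
    bookkeeping = {
      df <- utils::read.csv(path("bookkeeping.csv"), stringsAsFactors = FALSE)
      stats::setNames(df$count, df$item)
    })
}

## ---- contingency analysis ----------------------------------------------

#' 2x2 contingency table of synapse type against target
#'
#' Collapses a layer's six categories to the 2x2 table of synapse type
#' (AS, SS) against postsynaptic target (spine = head + neck, shaft).
#'
#' @param x a \linkS4class{LayerCountTable}.
#' @param layer layer label, "I".."VI".
#' @return A 2 x 2 matrix with dimnames type x target.
#' @export
contingency2x2 <- function(x, layer) {
  cm <- x@counts[, layer]
  m <- rbind(AS = c(unname(cm["AS_head"] + cm["AS_neck"]), unname(cm["AS_shaft"])),
             SS = c(unname(cm["SS_head"] + cm["SS_neck"]), unname(cm["SS_shaft"])))
  colnames(m) <- c("spine", "shaft")
  m
}

#' Expected counts under independence
#'
#' E_ij = T_i T_j / T, where T_i and T_j are the marginal totals of row i
#' and column j and T is the grand total. The expected matrix has exactly
#' the same marginals as the observed one.
#'
#' @param observed a 2-way contingency matrix of observed counts.
#' @return Matrix of expected counts, same shape and dimnames.
#' @examples
#' obs <- rbind(AS = c(spine = 825, shaft = 86), SS = c(spine = 13, shaft = 44))
#' expectedCounts(obs)["SS", "shaft"]  # 7.65
#' @export
expectedCounts <- function(observed) {
  total <- sum(observed)
  if (total <= 0) stop("contingency table has zero total")
  outer(rowSums(observed), colSums(observed)) / total
}

#' Enrichment ratio of an observed cell over its expected count
#'
#' @param observed a contingency matrix.
#' @param row,col the cell of interest (name or index).
#' @return O/E at the cell.
#' @export
enrichmentRatio <- function(observed, row = "SS", col = "shaft") {
  e <- expectedCounts(observed)[row, col]
  if (e <= 0) stop("expected count is zero at the requested cell")
  observed[row, col] / e
}

#' Chi-squared test of association
#'
#' Pearson chi-squared on a contingency table: X^2 = sum (O - E)^2 / E
#' with E_ij = T_i T_j / T; df = (r-1)(c-1); p from the chi-squared
#' distribution. Yates continuity correction (|O - E| reduced by 0.5
#' before squaring) is off by default.
#'
#' @param observed contingency matrix.
#' @param yates apply the continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
chisqAssociation <- function(observed, yates = FALSE) {
  e <- expectedCounts(observed)
  if (any(e == 0 & observed > 0))
    stop("degenerate table: zero expected count with nonzero observation")
  ht <- suppressWarnings(stats::chisq.test(observed, correct = yates))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = e)
}

## ---- rank tests ---------------------------------------------------------

.kwStatistic <- function(values, group) {
  n <- length(values)
  r <- rank(values)
  tie <- table(r)
  H <- (12 / (n * (n + 1))) *
    sum(tapply(r, group, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
  if (corr > 0) H / corr else 0
}

#' Kruskal-Wallis test with small-sample exact enumeration
#'
#' Rank-based comparison of two or more groups with tie correction. For
#' total n <= 8 the p-value is computed by exhaustive enumeration of all
#' assignments of the pooled observations to the group sizes; otherwise
#' the chi-squared approximation of \code{\link[stats]{kruskal.test}} is
#' used.
#'
#' @param groups list of numeric vectors (one per group), all non-empty.
#' @return List with `statistic` (H, tie-corrected), `df`, `p.value`,
#'   `method` ("exact" or "chisq").
#' @export
kruskalWallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) > 0L))
  values <- unlist(groups, use.names = FALSE)
  group <- factor(rep(seq_along(groups), lengths(groups)))
  H <- .kwStatistic(values, group)
  n <- length(values)
  if (n <= 8L) {
    perms <- .permutationsOf(n)
    stats <- apply(perms, 1L, function(p) .kwStatistic(values[p], group))
    p.value <- mean(stats >= H - 1e-12)
    list(statistic = H, df = length(groups) - 1L, p.value = p.value,
         method = "exact")
  } else {
    ht <- stats::kruskal.test(values, group)
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, method = "chisq")
  }
}

.permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided by default, with tie correction; exact for small samples
#' without ties (the \code{\link[stats]{wilcox.test}} rule), normal
#' approximation with continuity correction otherwise. Returns the
#' Mann-Whitney U statistic.
#'
#' @param a,b numeric samples, both non-empty.
#' @param alternative as in `wilcox.test`.
#' @return List with `statistic` (U), `p.value`.
#' @export
mannWhitney <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) > 0L, length(b) > 0L)
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

## ---- table builders -----------------------------------------------------

# per-layer percentage of each category within its layer total
.layerPercent <- function(counts) {
  tot <- colSums(counts)
  sweep(counts, 2, tot, "/") * 100
}

#' Rebuild the per-layer distribution table (percentages)
#'
#' Per-layer percentages of the six synapse-by-target categories, plus the
#' layer-averaged column. The average is the unweighted mean of the six
#' per-layer percentages, not the pooled-count percentage: layer sampling
#' effort differs, and the unweighted mean is what the reference census
#' reports. Pooled-count percentages are attached as the `pooled`
#' attribute for comparison.
#'
#' @param x a \linkS4class{LayerCountTable}.
#' @return data.frame of percentages: six category rows plus `Total`,
#'   columns I-VI and `Average`; counts in the `counts` attribute.
#' @export
buildTable1 <- function(x) {
  cm <- x@counts
  pct <- .layerPercent(cm)
  out <- as.data.frame(rbind(pct, Total = colSums(pct)))
  out$Average <- c(rowMeans(pct), 100)
  attr(out, "counts") <- cm
  attr(out, "pooled") <- rowSums(cm) / sum(cm) * 100
  out
}

#' Layer-averaged summary percentages of a census
#'
#' The headline quantities of the census: the layer-averaged AS
#' percentage, axospinous (spine-targeting) percentage, SS-on-shaft
#' percentage among SS, and head percentage among axospinous synapses
#' (ratio of the layer-averaged head and spine percentages). All averages
#' are unweighted means over layers I-VI.
#'
#' @param x a \linkS4class{LayerCountTable}.
#' @return Named numeric vector of percentages.
#' @export
censusSummary <- function(x) {
  cm <- x@counts
  tot <- colSums(cm)
  asPct <- colSums(cm[c("AS_head", "AS_neck", "AS_shaft"), ]) / tot * 100
  spinePct <- colSums(cm[c("AS_head", "AS_neck", "SS_head", "SS_neck"), ]) / tot * 100
  headPct <- colSums(cm[c("AS_head", "SS_head"), ]) / tot * 100
  ssTot <- colSums(cm[c("SS_head", "SS_neck", "SS_shaft"), ])
  ssShaftPct <- cm["SS_shaft", ] / ssTot * 100
  asTot <- colSums(cm[c("AS_head", "AS_neck", "AS_shaft"), ])
  asSpinePct <- colSums(cm[c("AS_head", "AS_neck"), ]) / asTot * 100
  c(mean_AS_pct = mean(asPct),
    mean_SS_pct = 100 - mean(asPct),
    mean_axospinous_pct = mean(spinePct),
    mean_on_shaft_pct = 100 - mean(spinePct),
    mean_AS_on_spine_pct = mean(asSpinePct),
    mean_SS_on_shaft_pct = mean(ssShaftPct),
    heads_among_axospinous_pct = mean(headPct) / mean(spinePct) * 100)
}

#' Rebuild the density table
#'
#' Per-layer densities (synapses per um^3) of all synapses, AS and SS,
#' split over spines and shafts using the per-layer target percentages
#' derived from the counts; percentages and densities as separate rows,
#' `Avg` column as the unweighted layer mean.
#'
#' @param x a \linkS4class{LayerCountTable} carrying densities.
#' @return data.frame with rows density_all, pct_spine, pct_shaft,
#'   density_spine, density_shaft and the AS/SS analogues.
#' @export
buildTable3 <- function(x) {
  if (!length(x@densities)) stop("layer count table carries no densities")
  cm <- x@counts
  dAS <- x@densities["AS", ]; dSS <- x@densities["SS", ]
  tot <- colSums(cm)
  spinePct <- colSums(cm[c("AS_head", "AS_neck", "SS_head", "SS_neck"), ]) / tot * 100
  asTot <- colSums(cm[c("AS_head", "AS_neck", "AS_shaft"), ])
  ssTot <- colSums(cm[c("SS_head", "SS_neck", "SS_shaft"), ])
  asSpinePct <- colSums(cm[c("AS_head", "AS_neck"), ]) / asTot * 100
  ssSpinePct <- colSums(cm[c("SS_head", "SS_neck"), ]) / ssTot * 100
  dAll <- dAS + dSS
  rows <- rbind(
    density_all = dAll,
    pct_spine = spinePct, pct_shaft = 100 - spinePct,
    density_spine = dAll * spinePct / 100,
    density_shaft = dAll * (100 - spinePct) / 100,
    density_AS = dAS,
    pct_AS_spine = asSpinePct, pct_AS_shaft = 100 - asSpinePct,
    density_AS_spine = dAS * asSpinePct / 100,
    density_AS_shaft = dAS * (100 - asSpinePct) / 100,
    density_SS = dSS,
    pct_SS_spine = ssSpinePct, pct_SS_shaft = 100 - ssSpinePct,
    density_SS_spine = dSS * ssSpinePct / 100,
    density_SS_shaft = dSS * (100 - ssSpinePct) / 100)
  out <- as.data.frame(rows)
  colnames(out) <- .layerNames
  out$Avg <- rowMeans(rows)
  out
}

#' Rebuild the single/multiple-synapse spine table
#'
#' Counts and percentages of spines establishing a single synapse versus
#' multiple synapses, with subcategory percentages computed within the
#' single and multiple groups respectively.
#'
#' @param profileCounts named vector of spine-profile counts in the
#'   categories of \code{\link{profileSpines}} (overflow optional).
#' @return data.frame with columns `count` and `percent`; rows
#'   `single`, `one_AS`, `one_SS`, `multiple` and the multiple
#'   subcategories.
#' @export
buildTable4 <- function(profileCounts) {
  pc <- profileCounts
  get <- function(nm) if (nm %in% names(pc)) pc[[nm]] else 0
  singles <- c(one_AS = get("one_AS"), one_SS = get("one_SS"))
  multiCats <- c("two_AS", "one_AS_one_SS", "two_AS_one_SS", "three_AS",
                 "two_SS", "three_SS", "one_AS_two_SS")
  multi <- vapply(multiCats, get, numeric(1))
  nSingle <- sum(singles); nMulti <- sum(multi)
  nAll <- nSingle + nMulti
  if (nAll == 0) stop("no spine profiles")
  rows <- rbind(
    single = c(nSingle, nSingle / nAll * 100),
    one_AS = c(singles["one_AS"], if (nSingle) singles[["one_AS"]] / nSingle * 100 else 0),
    one_SS = c(singles["one_SS"], if (nSingle) singles[["one_SS"]] / nSingle * 100 else 0),
    multiple = c(nMulti, nMulti / nAll * 100),
    cbind(multi, if (nMulti) multi / nMulti * 100 else rep(0, length(multi))))
  out <- as.data.frame(rows)
  names(out) <- c("count", "percent")
  out
}

#' Share of synapses discarded as truncated
#'
#' @param identified total number of junctions identified.
#' @param truncated number discarded because the postsynaptic structure
#'   was truncated by the stack borders.
#' @return Percentage discarded.
#' @export
truncationShare <- function(identified, truncated)
  truncated / identified * 100

#' Lower bound on the share of synapses on spiny dendrites
#'
#' Axospinous synapses plus the spiny share of shaft synapses: synapses on
#' shafts of spine-free segments cannot be proven to sit on aspiny
#' neurons, so this is a lower bound.
#'
#' @param x a \linkS4class{LayerCountTable}.
#' @param spinyShaftPercent percentage of shaft synapses whose dendrite is
#'   spiny.
#' @return Percentage of synapses attributable to spiny dendrites.
#' @export
spinyLowerBound <- function(x, spinyShaftPercent) {
  s <- censusSummary(x)
  s[["mean_axospinous_pct"]] +
    s[["mean_on_shaft_pct"]] * spinyShaftPercent / 100
}
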