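.sdConv <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(0)
  if (type == "sample") stats::sd(x)
  else sqrt(sum((x - mean(x))^2) / n)
}

.labelVector <- function(pset, label) {
  p <- particles(pset)
  if (!label %in% names(p))
    stop("label column not present in particle set: ", label)
  if (anyNA(p[[label]]))
    stop("particle ", p$particleID[which(is.na(p[[label]]))[1]],
         " lacks a value for label '", label, "'")
  p[[label]]
}

#' Per-polysome composition fractions
#'
#' For every traced polysome, the fraction of member ribosomes carrying
#' a given label value (e.g. the fraction of 2xbS20 ribosomes per
#' polysome), summarised across chains. The chain-level mean is
#' unweighted (each polysome counts once); the ribosome-weighted mean
#' (each member counts once) is reported alongside.
#'
#' @param chains a \linkS4class{PolysomeChainSet}.
#' @param pset the \linkS4class{ParticleSet} the chains index into.
#' @param label label column name; \code{value} the category counted.
#' @param sdType "population" (divide by n, default) or "sample".
#' @return list: \code{perChain} (data.frame chainID, length, fraction),
#'   \code{mean}, \code{sd} (across chains), \code{weightedMean}
#'   (ribosome-weighted), \code{nChains}.
#' @export
compositionFractions <- function(chains, pset, label, value,
                                 sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  lab <- .labelVector(pset, label)
  p <- particles(pset)
  mem <- chainMembers(chains)
  frac <- vapply(mem, function(m) {
    v <- lab[match(m, p$particleID)]
    if (anyNA(v)) stop("chain member not found in particle set")
    mean(v == value)
  }, numeric(1))
  len <- lengths(mem)
  list(perChain = data.frame(chainID = seq_along(mem) - 1L,
                             length = len, fraction = frac),
       mean = if (length(frac)) mean(frac) else NA_real_,
       sd = .sdConv(frac, sdType),
       weightedMean = if (length(frac)) sum(frac * len) / sum(len)
                      else NA_real_,
       nChains = length(mem))
}

#' Per-cell occupancy of a label value
#'
#' Fraction of particles carrying a given label value in each tomogram
#' (= cell), with the across-cell mean and standard deviation (cells
#' weighted equally). The pooled, ribosome-weighted fraction is also
#' reported.
#'
#' @inheritParams compositionFractions
#' @param pset a \linkS4class{ParticleSet}.
#' @return list: \code{perCell} (data.frame tomoID, n, fraction),
#'   \code{mean}, \code{sd} (across cells), \code{pooled}.
#' @export
occupancyByCell <- function(pset, label, value,
                            sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  lab <- .labelVector(pset, label)
  p <- particles(pset)
  tab <- tapply(lab == value, p$tomoID, mean)
  n <- tapply(lab, p$tomoID, length)
  perCell <- data.frame(tomoID = names(tab), n = as.integer(n),
                        fraction = as.numeric(tab),
                        stringsAsFactors = FALSE)
  list(perCell = perCell, mean = mean(perCell$fraction),
       sd = .sdConv(perCell$fraction, sdType),
       pooled = mean(lab == value))
}

#' Exit-to-entry distances to the closest neighbour, by class pair
#'
#' For every particle with a nearest entry-site neighbour below the
#' cut-off (default 500 A, the neighbour-distance analysis cut-off),
#' records the exit-to-entry distance annotated with the class label of
#' the leading (from) and trailing (to) particle, stratified into the
#' label-pair combinations. By default distances come from the
#' pre-resolution link set (each particle's single nearest entry
#' neighbour); set \code{resolved = TRUE} to restrict to links surviving
#' shared-neighbour resolution and cycle removal.
#'
#' @param pset a \linkS4class{ParticleSet}.
#' @param markers a \linkS4class{MarkerConfig}.
#' @param label label column used for stratification.
#' @param cutoff Angstrom, default \code{markers@distanceCutoff}.
#' @param resolved use the resolved link set instead (default FALSE).
#' @return data.frame: tomoID, from, to, leaderLabel, trailerLabel,
#'   distance (A).
#' @export
neighbourDistances <- function(pset, markers, label,
                               cutoff = markers@distanceCutoff,
                               resolved = FALSE) {
  lab <- .labelVector(pset, label)
  g <- buildLinks(pset, markers, cutoff)
  if (resolved) g <- breakCycles(resolveShared(g))
  l <- links(g)
  p <- particles(pset)
  data.frame(tomoID = l$tomoID, from = l$from, to = l$to,
             leaderLabel = lab[match(l$from, p$particleID)],
             trailerLabel = lab[match(l$to, p$particleID)],
             distance = l$distance, stringsAsFactors = FALSE)
}

#' Cell-to-cell confidence band for a distance distribution
#'
#' Bins the neighbour distances per cell into normalised frequencies and
#' returns, per bin, the empirical 5th and 95th percentiles across
#' cells, together with a point estimate (mean of the per-cell curves by
#' default, or the pooled histogram). With fewer than 3 cells a warning
#' is issued and a degenerate band (lower = upper = point) is returned.
#'
#' @param table data.frame from [neighbourDistances()] (needs columns
#'   tomoID and distance).
#' @param breaks numeric vector of bin edges in Angstrom covering the
#'   distances.
#' @param point "mean" of per-cell curves (default) or "pooled".
#' @param probs lower/upper percentiles, default c(0.05, 0.95).
#' @return data.frame: binMid, lower, upper, point (normalised
#'   frequencies summing to 1 over bins).
#' @export
cellConfidenceBand <- function(table, breaks, point = c("mean", "pooled"),
                               probs = c(0.05, 0.95)) {
  point <- match.arg(point)
  cells <- unique(table$tomoID)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  freq <- function(d) {
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    if (sum(h$counts) == 0) rep(0, length(mids)) else h$counts / sum(h$counts)
  }
  mat <- vapply(cells, function(cl) freq(table$distance[table$tomoID == cl]),
                numeric(length(mids)))
  mat <- matrix(mat, nrow = length(mids))
  pt <- if (point == "pooled") freq(table$distance) else rowMeans(mat)
  if (length(cells) < 3L) {
    warning("fewer than 3 cells: returning degenerate confidence band")
    return(data.frame(binMid = mids, lower = pt, upper = pt, point = pt))
  }
  lo <- apply(mat, 1L, stats::quantile, probs = probs[1], names = FALSE)
  hi <- apply(mat, 1L, stats::quantile, probs = probs[2], names = FALSE)
  data.frame(binMid = mids, lower = lo, upper = hi, point = pt)
}

#' Compare distance distributions between class-pair strata
#'
#' Pairwise two-sample Kolmogorov-Smirnov tests between the
#' (leaderLabel, trailerLabel) strata of a neighbour-distance table,
#' with Holm multiple-testing correction and per-stratum medians.
#' Strata with fewer than 2 observations are reported as not testable.
#'
#' @param table data.frame from [neighbourDistances()].
#' @return list: \code{strata} (data.frame stratum, n, median),
#'   \code{tests} (data.frame stratumA, stratumB, n A/B, KS statistic,
#'   p, pHolm, testable), \code{method}.
#' @export
compareStrata <- function(table) {
  stratum <- paste(table$leaderLabel, table$trailerLabel, sep = "->")
  sp <- split(table$distance, stratum)
  strata <- data.frame(stratum = names(sp), n = lengths(sp),
                       median = vapply(sp, stats::median, numeric(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  if (length(sp) < 2L)
    return(list(strata = strata,
                tests = data.frame(), method = "two-sample Kolmogorov-Smirnov, Holm-adjusted"))
  cmb <- utils::combn(names(sp), 2L)
  tests <- data.frame(stratumA = cmb[1, ], stratumB = cmb[2, ],
                      nA = lengths(sp)[cmb[1, ]], nB = lengths(sp)[cmb[2, ]],
                      statistic = NA_real_, p = NA_real_,
                      testable = FALSE, row.names = NULL,
                      stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    a <- sp[[cmb[1, i]]]; b <- sp[[cmb[2, i]]]
    if (length(a) >= 2L && length(b) >= 2L) {
      kt <- suppressWarnings(stats::ks.test(a, b))
      tests$statistic[i] <- unname(kt$statistic)
      tests$p[i] <- kt$p.value
      tests$testable[i] <- TRUE
    }
  }
  tests$pHolm <- NA_real_
  tests$pHolm[tests$testable] <- stats::p.adjust(tests$p[tests$testable],
                                                 method = "holm")
  list(strata = strata, tests = tests,
       method = "two-sample Kolmogorov-Smirnov, Holm-adjusted")
}

#' Functional-state distribution by ribosome group
#'
#' Contingency table of a grouping label (e.g. the bS20 occupancy class)
#' against a state label (e.g. functional state along the elongation
#' cycle, or Trigger-Factor bound/free), with row-normalised
#' proportions and a chi-square test of homogeneity. Degenerate tables
#' (a single group or a single state) skip the test with a notice.
#'
#' @param pset a \linkS4class{ParticleSet}.
#' @param stateLabel,groupLabel label column names.
#' @return list: \code{counts} (group x state), \code{proportions}
#'   (row-normalised), \code{test} (htest or NULL), \code{note}
#'   (character; warns when expected counts < 5 or the test is skipped).
#' @export
stateDistribution <- function(pset, stateLabel, groupLabel) {
  st <- .labelVector(pset, stateLabel)
  gr <- .labelVector(pset, groupLabel)
  counts <- table(group = gr, state = st)
  prop <- prop.table(counts, margin = 1)
  note <- character()
  test <- NULL
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    note <- "degenerate table (single group or state): test skipped"
  } else {
    test <- suppressWarnings(stats::chisq.test(counts))
    if (any(test$expected < 5))
      note <- "some expected counts < 5: chi-square approximation unreliable"
  }
  list(counts = counts, proportions = prop, test = test, note = note)
}
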