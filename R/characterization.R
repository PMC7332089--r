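#' Positional residue frequencies around the modified residue
#'
#' Empirical frequency of each of the 21 window symbols (20 residues + gap)
#' at each window position; the centre column of proline-centred windows has
#' proline frequency 1 by construction.
#'
#' @param windowSet A [SiteWindowSet-class] (all windows of one width).
#' @return A `W x 21` matrix of frequencies; each row sums to 1. The number
#'   of contributing sites is attached as attribute `nSites`.
#' @export
residueFrequencyProfile <- function(windowSet) {
  stopifnot(is(windowSet, "SiteWindowSet"))
  n <- length(windowSet)
  if (!n) stop("no windows")
  W <- windowWidth(windowSet)
  enc <- encodeWindows(windowSet@windows, W)
  freq <- t(vapply(seq_len(W), function(cc)
    tabulate(enc[, cc], nbins = 21L) / n, numeric(21L)))
  dimnames(freq) <- list(position = seq_len(W) - (W + 1L) %/% 2L,
                         symbol = ALPHABET21)
  attr(freq, "nSites") <- n
  freq
}

#' Per-site feature content
#'
#' Fraction of the non-gap window positions carrying a given binary feature
#' (from the proteome's per-residue tracks), or — for
#' `feature = "proline"` — the fraction of prolines in the site irrespective
#' of modification status. Gap (padding) positions are excluded from the
#' denominator so that terminal windows are not diluted by non-residues.
#'
#' @param windowSet A [SiteWindowSet-class].
#' @param proteome A [Proteome-class] carrying the feature tracks.
#' @param feature Track name (e.g. `"disorder"`, `"helix"`, `"sheet"`,
#'   `"low_complexity"`) or `"proline"`.
#' @param missingTrack For sites on proteins without the track: `"error"`
#'   (default) or `"skip"` (return `NA` for those sites, with a message).
#' @return Named numeric vector of per-site fractions in `[0, 1]`.
#' @export
siteContent <- function(windowSet, proteome, feature,
                        missingTrack = c("error", "skip")) {
  stopifnot(is(windowSet, "SiteWindowSet"))
  missingTrack <- match.arg(missingTrack)
  W <- windowWidth(windowSet)
  half <- (W - 1L) %/% 2L
  keys <- siteKeys(windowSet)
  if (identical(feature, "proline")) {
    chars <- strsplit(windowSet@windows, "", fixed = TRUE)
    out <- vapply(chars, function(x) {
      nonGap <- x != GAP
      sum(x == "P") / sum(nonGap)
    }, numeric(1))
    return(setNames(out, keys))
  }
  stopifnot(is(proteome, "Proteome"))
  tracks <- featureTracks(proteome, feature)
  out <- numeric(length(keys))
  nSkipped <- 0L
  for (i in seq_along(keys)) {
    id <- windowSet@proteinID[i]
    tr <- tracks[[id]]
    if (is.null(tr)) {
      if (missingTrack == "error")
        stop("no '", feature, "' track for protein '", id, "'")
      out[i] <- NA_real_
      nSkipped <- nSkipped + 1L
      next
    }
    # a non-gap window column is always a real in-range residue: padding and
    # non-canonical letters are both gaps by construction
    win <- strsplit(windowSet@windows[i], "", fixed = TRUE)[[1]]
    offs <- which(win != GAP)
    keep <- windowSet@position[i] - half - 1L + offs
    out[i] <- if (length(keep)) mean(tr[keep]) else NA_real_
  }
  if (nSkipped) message(nSkipped, " site(s) skipped: missing track")
  setNames(out, keys)
}

#' Histogram of positive sites per protein
#'
#' @param annotations Annotation data.frame (only `label == "positive"` rows
#'   are counted, deduplicated by site key).
#' @param fraction If `TRUE`, normalize counts to fractions of proteins.
#' @return Named numeric vector: for each observed number of sites `k`, the
#'   number (or fraction) of proteins with exactly `k` positive sites.
#' @export
sitesPerProteinDensity <- function(annotations, fraction = FALSE) {
  pos <- unique(annotations[annotations$label == "positive",
                            c("protein_id", "key")])
  if (!nrow(pos)) return(setNames(numeric(0), character(0)))
  perProtein <- table(pos$protein_id)
  h <- table(factor(as.integer(perProtein)))
  out <- as.numeric(h)
  if (fraction) out <- out / sum(out)
  setNames(out, names(h))
}
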