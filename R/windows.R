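#' Extract a fixed-length gapped window around one site
#'
#' Returns the `W` residues centred on `position`, padding with the gap
#' character `-` where the window extends beyond either sequence end and
#' replacing any non-canonical letter (anything outside the 20 standard
#' one-letter codes, e.g. B, Z, J, U, O, X) with a gap. The centre residue
#' itself must be canonical.
#'
#' @param sequence A single amino-acid sequence string.
#' @param position 1-based position of the candidate residue.
#' @param W Odd window length (default 13).
#' @return A window string of exactly `W` characters.
#' @export
extractWindow <- function(sequence, position, W = 13L) {
  W <- as.integer(W)
  if (W %% 2L != 1L) stop("window length W must be odd, got ", W)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > n)
    stop("position ", position, " out of range [1, ", n, "]")
  half <- (W - 1L) %/% 2L
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!chars[position] %in% AA20)
    stop("centre residue '", chars[position], "' at position ", position,
         " is not a canonical amino acid")
  idx <- (position - half):(position + half)
  win <- ifelse(idx >= 1L & idx <= n, chars[pmax(pmin(idx, n), 1L)], GAP)
  win[!win %in% AA20] <- GAP
  paste(win, collapse = "")
}

#' Enumerate candidate sites of a proteome
#'
#' Lists every position whose residue equals `targetResidue` (proline by
#' default: the benchmark assesses hydroxylation on prolines only).
#'
#' @param proteome A [Proteome-class].
#' @param targetResidue Single canonical residue letter.
#' @return A data.frame with columns `protein_id`, `position`, `key`.
#' @export
enumerateCandidateSites <- function(proteome, targetResidue = "P") {
  stopifnot(is(proteome, "Proteome"))
  if (!targetResidue %in% AA20)
    stop("targetResidue must be one of the 20 canonical residues")
  seqs <- as.character(proteome@sequences)
  hits <- gregexpr(targetResidue, seqs, fixed = TRUE)
  rows <- lapply(seq_along(seqs), function(i) {
    p <- hits[[i]]
    if (p[1] == -1L) return(NULL)
    data.frame(protein_id = names(seqs)[i], position = as.integer(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), position = integer(0))
  out$key <- if (nrow(out)) makeSiteKey(out$protein_id, out$position)
             else character(0)
  out
}

#' Extract windows for a set of sites
#'
#' @param proteome A [Proteome-class].
#' @param sites A data.frame with `protein_id` and `position` columns, e.g.
#'   from [enumerateCandidateSites].
#' @param W Odd window length (default 13).
#' @return A [SiteWindowSet-class].
#' @export
siteWindows <- function(proteome, sites, W = 13L) {
  stopifnot(is(proteome, "Proteome"),
            all(c("protein_id", "position") %in% names(sites)))
  W <- as.integer(W)
  if (W %% 2L != 1L) stop("window length W must be odd, got ", W)
  seqs <- as.character(proteome@sequences)
  wins <- vapply(seq_len(nrow(sites)), function(i) {
    extractWindow(seqs[[sites$protein_id[i]]], sites$position[i], W)
  }, character(1))
  new("SiteWindowSet", windows = wins,
      proteinID = as.character(sites$protein_id),
      position = as.integer(sites$position), W = W)
}

#' Serialize a window set to TSV
#'
#' @param windowSet A [SiteWindowSet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeWindowsTSV <- function(windowSet, path) {
  write.table(data.frame(protein_id = windowSet@proteinID,
                         position = windowSet@position,
                         window = windowSet@windows),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
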