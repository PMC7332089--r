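# Internal constants and helpers shared across modules.

# 20 canonical residues in BLOSUM row order, plus the gap symbol as the
# 21st window symbol.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP <- "-"
ALPHABET21 <- c(AA20, GAP)

#' Build a site key from protein id and position
#'
#' Site keys (`"<protein>:<position>"`) identify a candidate site everywhere
#' in the pipeline: in distance matrices, cluster assignments, splits,
#' replicas and prediction tables.
#'
#' @param proteinID Character vector of protein ids.
#' @param position Integer vector of 1-based positions.
#' @return Character vector of keys.
#' @export
makeSiteKey <- function(proteinID, position) {
  paste0(proteinID, ":", as.integer(position))
}

#' Split site keys back into protein id and position
#'
#' @param keys Character vector of `"<protein>:<position>"` keys.
#' @return A data.frame with columns `protein_id` and `position`.
#' @export
splitSiteKey <- function(keys) {
  pos <- sub("^.*:", "", keys)
  data.frame(protein_id = sub(":[0-9]+$", "", keys),
             position = as.integer(pos), stringsAsFactors = FALSE)
}

# Deterministic derived seed for stream i under a master seed; kept well
# below 2^31 so set.seed() always accepts it.
deriveSeed <- function(master, i) {
  as.integer((as.double(master) %% 1e6) * 2047 + 101 * as.double(i) %% 1e6 +
             (as.double(master) + as.double(i)) %% 7919)
}

# 21 x 21 substitution matrix over ALPHABET21: BLOSUM62 on residues, 0 on any
# pair involving a gap (gap runs are charged separately, per run).
substitutionMatrix21 <- function(matrixName = "BLOSUM62") {
  env <- new.env()
  utils::data(list = matrixName, package = "Biostrings", envir = env)
  full <- get(matrixName, envir = env)
  if (!all(AA20 %in% rownames(full)))
    stop("substitution matrix '", matrixName, "' lacks canonical residues")
  m <- matrix(0, 21L, 21L, dimnames = list(ALPHABET21, ALPHABET21))
  m[AA20, AA20] <- full[AA20, AA20]
  m
}

# Encode window strings as an n x W integer matrix over 1..21.
encodeWindows <- function(windows, W) {
  if (!length(windows)) return(matrix(integer(0), 0L, W))
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), ncol = W, byrow = TRUE)
  idx <- match(chars, ALPHABET21)
  if (anyNA(idx))
    stop("window contains characters outside the 20 canonical residues + gap")
  matrix(idx, nrow = length(windows), ncol = W)
}

# Affine penalty of the gap runs in a logical gap mask (TRUE = gap column).
gapRunPenalty <- function(mask, gapOpen, gapExtend) {
  if (!any(mask)) return(0)
  r <- rle(mask)
  runs <- r$lengths[r$values]
  sum(gapOpen + (runs - 1) * gapExtend)
}
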