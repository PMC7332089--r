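#' Construct a Proteome object
#'
#' @param sequences Named character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences (upper-cased on construction).
#' @param collagen Logical vector flagging collagen proteins; recycled or
#'   named by protein id. Defaults to all `FALSE`.
#' @param tracks Optional named list of per-residue binary feature tracks
#'   (see [Proteome-class]).
#' @return A [Proteome-class] object.
#' @export
Proteome <- function(sequences, collagen = FALSE, tracks = list()) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by protein id")
  sequences <- toupper(sequences)
  ids <- names(sequences)
  if (is.null(names(collagen))) {
    collagen <- setNames(rep_len(as.logical(collagen), length(ids)), ids)
  } else {
    cl <- setNames(rep(FALSE, length(ids)), ids)
    cl[names(collagen)] <- as.logical(collagen)
    collagen <- cl
  }
  new("Proteome", sequences = Biostrings::AAStringSet(sequences),
      collagen = collagen, tracks = tracks)
}

#' Read a proteome, its site annotations and optional feature tracks
#'
#' Loads a multi-record FASTA of protein sequences, a tab-separated site
#' annotation table (header columns `protein_id`, `position`, `residue`,
#' `label`, `source`, and optionally `confidence`, `collagen`,
#' `evidence_code`) and, if given, a feature track table (`protein_id`,
#' `feature`, `track`, where `track` is a 0/1 string aligned to the
#' sequence). Structural problems (unknown protein id, malformed or
#' out-of-range position) are hard errors naming the offending row; rows
#' whose stated residue disagrees with the sequence are rejected and
#' reported, never silently dropped.
#'
#' @param fastaPath Path to the FASTA file.
#' @param annotationPath Path to the annotation TSV.
#' @param trackPath Optional path to the feature track TSV.
#' @param filterEvidence If `TRUE`, Literature rows are kept only when their
#'   evidence code is `ECO:0000269` or `ECO:0000305` (the manual-assertion
#'   codes used for curated hydroxylation sites); dropped rows are counted in
#'   the rejection report. Off by default, as synthetic annotations carry no
#'   curation trail.
#' @return A list with elements `proteome` ([Proteome-class]),
#'   `annotations` (accepted rows, with a `key` column added) and
#'   `rejected` (rejected rows with a `reason` column).
#' @export
readProteome <- function(fastaPath, annotationPath, trackPath = NULL,
                         filterEvidence = FALSE) {
  seqs <- Biostrings::readAAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("protein_id", "position", "residue", "label", "source")
  missingCols <- setdiff(required, names(ann))
  if (length(missingCols))
    stop("annotation table lacks required column(s): ",
         paste(missingCols, collapse = ", "))

  bad <- setdiff(unique(ann$protein_id), names(seqs))
  if (length(bad))
    stop("annotation references unknown protein id '", bad[1], "'")

  posNum <- suppressWarnings(as.numeric(ann$position))
  malformed <- which(is.na(posNum) | posNum != floor(posNum))
  if (length(malformed))
    stop("malformed position in annotation row ", malformed[1],
         " ('", ann$position[malformed[1]], "')")
  ann$position <- as.integer(posNum)
  seqChar <- as.character(seqs)
  lens <- nchar(seqChar)[ann$protein_id]
  oob <- which(ann$position < 1L | ann$position > lens)
  if (length(oob))
    stop("position out of range [1, sequence length] in annotation row ",
         oob[1], " (", ann$protein_id[oob[1]], ":", ann$position[oob[1]], ")")
  if (!all(ann$label %in% c("positive", "negative")))
    stop("label column must be 'positive' or 'negative'")

  if ("confidence" %in% names(ann)) {
    ann$confidence <- suppressWarnings(as.numeric(ann$confidence))
  } else ann$confidence <- NA_real_
  if ("collagen" %in% names(ann)) {
    ann$collagen <- ann$collagen %in% c("1", "TRUE", "true", "yes")
  } else ann$collagen <- FALSE
  if (!"evidence_code" %in% names(ann)) ann$evidence_code <- NA_character_

  # residue check against the (upper-cased) sequence
  actual <- substr(seqChar[ann$protein_id], ann$position, ann$position)
  mismatch <- toupper(ann$residue) != toupper(actual)
  reason <- ifelse(mismatch, paste0("residue mismatch: annotated ",
                                    ann$residue, ", sequence has ", actual), NA)
  if (filterEvidence) {
    evBad <- ann$source == "Literature" &
      !ann$evidence_code %in% c("ECO:0000269", "ECO:0000305")
    reason[!mismatch & evBad] <- "evidence code not manual-assertion"
  }
  keep <- is.na(reason)
  rejected <- ann[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  accepted <- ann[keep, , drop = FALSE]
  accepted$residue <- toupper(accepted$residue)
  accepted$key <- makeSiteKey(accepted$protein_id, accepted$position)
  if (nrow(rejected))
    message(nrow(rejected), " annotation row(s) rejected; see $rejected")

  collagenIDs <- unique(accepted$protein_id[accepted$collagen])
  tracks <- list()
  if (!is.null(trackPath)) {
    tr <- read.delim(trackPath, stringsAsFactors = FALSE,
                     colClasses = "character")
    if (!all(c("protein_id", "feature", "track") %in% names(tr)))
      stop("track table needs columns protein_id, feature, track")
    badTr <- setdiff(unique(tr$protein_id), names(seqs))
    if (length(badTr))
      stop("track table references unknown protein id '", badTr[1], "'")
    for (i in seq_len(nrow(tr))) {
      v <- as.integer(strsplit(tr$track[i], "", fixed = TRUE)[[1]])
      tracks[[tr$feature[i]]][[tr$protein_id[i]]] <- v
    }
  }

  proteome <- Proteome(seqChar,
                       collagen = setNames(rep(TRUE, length(collagenIDs)),
                                           collagenIDs),
                       tracks = tracks)
  list(proteome = proteome, annotations = accepted, rejected = rejected)
}

#' Read a predictor output table
#'
#' Expects a TSV with header columns `protein_id`, `position`, `call` (0/1)
#' and `method`, plus optional `score` and `level` (quality-threshold label;
#' each method/level pair is treated downstream as an independent predictor).
#'
#' @param tsvPath Path to the prediction TSV.
#' @return A data.frame of predictions with a `key` column added.
#' @export
readPredictions <- function(tsvPath) {
  pr <- read.delim(tsvPath, stringsAsFactors = FALSE,
                   colClasses = "character")
  required <- c("protein_id", "position", "call", "method")
  missingCols <- setdiff(required, names(pr))
  if (length(missingCols))
    stop("prediction table lacks required column(s): ",
         paste(missingCols, collapse = ", "))
  posNum <- suppressWarnings(as.numeric(pr$position))
  malformed <- which(is.na(posNum) | posNum != floor(posNum))
  if (length(malformed))
    stop("malformed position in prediction row ", malformed[1])
  pr$position <- as.integer(posNum)
  badCall <- which(!pr$call %in% c("0", "1"))
  if (length(badCall))
    stop("call not interpretable as binary in prediction row ", badCall[1],
         " ('", pr$call[badCall[1]], "')")
  pr$call <- as.integer(pr$call)
  if ("score" %in% names(pr)) {
    pr$score <- suppressWarnings(as.numeric(pr$score))
  } else pr$score <- NA_real_
  if (!"level" %in% names(pr)) pr$level <- NA_character_
  dupKey <- paste(pr$protein_id, pr$position, pr$method, pr$level, sep = "\r")
  if (anyDuplicated(dupKey)) {
    d <- which(duplicated(dupKey))[1]
    stop("duplicate prediction for (", pr$protein_id[d], ", ", pr$position[d],
         ", ", pr$method[d], ", ", pr$level[d], ") at row ", d)
  }
  pr$key <- makeSiteKey(pr$protein_id, pr$position)
  pr
}

#' Write aggregated metric results as JSON
#'
#' Serializes a metric summary table (as produced by [aggregateMetrics] /
#' [evaluatePredictor]) to machine-readable JSON at full numeric precision,
#' so a read-back reproduces the values bit-exactly.
#'
#' @param results A data.frame with one row per (method, level, split,
#'   metric) holding `mean`, `sd`, `nReplicas` and `seed` columns. May have
#'   zero rows.
#' @param jsonPath Output path.
#' @return Invisibly, `jsonPath`.
#' @export
writeMetricsJSON <- function(results, jsonPath) {
  stopifnot(is.data.frame(results))
  jsonlite::write_json(results, jsonPath, dataframe = "rows",
                       digits = I(17), na = "null", auto_unbox = TRUE,
                       always_decimal = TRUE)
  invisible(jsonPath)
}

#' Read back a metrics JSON file
#'
#' @param jsonPath Path written by [writeMetricsJSON].
#' @return The metric summary data.frame.
#' @export
readMetricsJSON <- function(jsonPath) {
  out <- jsonlite::fromJSON(jsonPath)
  if (length(out) == 0) out <- data.frame()
  out
}

#' Write benchmark input files (FASTA, annotation TSV, track TSV)
#'
#' Emits exactly the formats [readProteome] consumes; used by the synthetic
#' generator and the pipeline to materialize a benchmark on disk.
#'
#' @param proteome A [Proteome-class].
#' @param annotations Annotation data.frame.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, a named list of the paths written.
#' @export
writeBenchmarkInputs <- function(proteome, annotations, dir,
                                 prefix = "benchmark") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fastaPath <- file.path(dir, paste0(prefix, ".fasta"))
  Biostrings::writeXStringSet(proteome@sequences, fastaPath)
  annPath <- file.path(dir, paste0(prefix, "_annotations.tsv"))
  cols <- c("protein_id", "position", "residue", "label", "source",
            "confidence", "collagen", "evidence_code")
  out <- annotations[, intersect(cols, names(annotations)), drop = FALSE]
  out$collagen <- as.integer(out$collagen)
  write.table(out, annPath, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- list(fasta = fastaPath, annotations = annPath)
  if (length(proteome@tracks)) {
    trPath <- file.path(dir, paste0(prefix, "_tracks.tsv"))
    rows <- do.call(rbind, lapply(names(proteome@tracks), function(feat) {
      tr <- proteome@tracks[[feat]]
      data.frame(protein_id = names(tr), feature = feat,
                 track = vapply(tr, paste, "", collapse = ""),
                 stringsAsFactors = FALSE)
    }))
    write.table(rows, trPath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$tracks <- trPath
  }
  invisible(paths)
}
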