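#' Parse a per-residue score file
#'
#' Reads the plain-text score-table format: a header line of column titles
#' followed by rows whose first field is the residue number and whose
#' remaining fields are numeric scores.  Whitespace- and comma-delimited
#' files are auto-detected.  Every score column beyond the first field
#' triggers independent processing in [truncateSingleModel()].
#'
#' Score semantics are fixed as "higher = removed earlier", matching
#' flexibility/variance metrics.  Conservation-style scores, where HIGH
#' values mark residues to KEEP, must be negated by the user before use.
#'
#' @param path path to the score file.
#' @return data.frame: column \code{resno} (integer residue numbers)
#'   followed by one named numeric column per score.
#' @details Errors name the offending line: non-numeric score cells,
#'   duplicate residue numbers, and rows whose width disagrees with the
#'   header are all rejected.
#' @export
parseScoreFile <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("score file needs a header line and at least one row")
  sep_comma <- grepl(",", lines[1], fixed = TRUE)
  splitRow <- function(s) {
    f <- if (sep_comma) strsplit(trimws(s), "[ \t]*,[ \t]*")[[1]] else
      strsplit(trimws(s), "[ \t]+")[[1]]
    f[nzchar(f)]
  }
  header <- splitRow(lines[1])
  if (length(header) < 2L)
    stop("header must name a residue column and at least one score column")
  rows <- lapply(lines[-1], splitRow)
  widths <- lengths(rows)
  bad <- which(widths != length(header))
  if (length(bad))
    stop("line ", bad[1] + 1L, ": ", widths[bad[1]], " fields, header has ",
         length(header))
  mat <- do.call(rbind, rows)
  resno <- suppressWarnings(as.integer(mat[, 1]))
  if (anyNA(resno))
    stop("line ", which(is.na(resno))[1] + 1L,
         ": residue number is not an integer")
  if (anyDuplicated(resno))
    stop("duplicate residue number ", resno[duplicated(resno)][1])
  out <- data.frame(resno = resno)
  for (c in 2:length(header)) {
    v <- suppressWarnings(as.numeric(mat[, c]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1] + 1L,
           ": non-numeric value '", mat[which(is.na(v))[1], c],
           "' in column '", header[c], "'")
    out[[header[c]]] <- v
  }
  out
}

#' Single-structure truncation driven by per-residue scores
#'
#' The single-homologue truncation mode: one input model is truncated over
#' the same 20 size intervals and with the same three side-chain treatments
#' as the ensemble mode, but with no subclustering, driven by each score
#' column independently — the residues removed first are those with the
#' highest values.  With the default three side-chain modes this yields 60
#' search models per score column; all columns are pooled into one list.
#'
#' @param s a sanitized single-model [ProteinStructure-class].
#' @param scores a score table ([parseScoreFile()] output or a built-in
#'   metric profile): column 1 residue numbers, columns 2..n scores.
#' @param modes side-chain treatments.
#' @param nLevels truncation levels (default 20).
#' @param reliableSet see [applySideChains()].
#' @return list of [SearchModel-class] objects
#'   (\code{|levels| * |modes|} per score column).
#' @details The score residues must match the structure exactly: a score
#'   for a residue absent from the structure, or a structure residue with
#'   no score, is an error — silent imputation would corrupt the rank
#'   order that drives the truncation.
#' @examples
#' s <- makeHelix(20)
#' tab <- bfactorProfile(s)
#' length(truncateSingleModel(s, tab))  # 60
#' @export
truncateSingleModel <- function(s, scores,
                                modes = c("allatom", "reliable", "polyala"),
                                nLevels = 20L,
                                reliableSet = .RELIABLE_SIDECHAINS) {
  stopifnot(is(s, "ProteinStructure"), is.data.frame(scores),
            ncol(scores) >= 2L)
  rids <- residueIds(s)
  sres <- as.integer(scores[[1]])
  extra <- setdiff(sres, rids)
  if (length(extra))
    stop("score file lists residue(s) absent from the structure: ",
         paste(utils::head(extra, 5), collapse = ", "))
  missing <- setdiff(rids, sres)
  if (length(missing))
    stop("structure residue(s) without a score: ",
         paste(utils::head(missing, 5), collapse = ", "))

  ladder <- truncationLadder(length(rids), nLevels)
  pool <- list()
  for (col in names(scores)[-1]) {
    prof <- data.frame(resno = sres, score = scores[[col]])
    for (li in seq_len(nrow(ladder))) {
      kept <- selectResidues(prof, ladder$nKeep[li])
      base <- subsetResidues(s, kept)
      for (mode in modes) {
        sm <- applySideChains(base, mode, reliableSet)
        pool[[length(pool) + 1L]] <- new("SearchModel",
          model = sm, nResidues = length(kept), sideChainMode = mode,
          subclusterRadius = NA_real_, clusterIndex = NA_integer_,
          scoreColumn = col,
          label = sprintf("%s_t%d_%s", col, ladder$percent[li], mode))
      }
    }
  }
  pool
}
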