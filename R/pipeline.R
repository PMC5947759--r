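# End-to-end orchestration of the two modes, with output directory,
# manifest and run log.

#' Run the ensemble mode end to end
#'
#' prepare input -> generate distance-geometry ensemble -> cluster ->
#' per used cluster: variance profile -> truncation ladder -> subclusters x
#' side-chain modes -> write search models, manifest and run log.  At the
#' defaults (20 levels, radii 1/2/3 A, three side-chain treatments) the
#' pool holds 180 search models per cluster: 540 when three clusters are
#' used.
#'
#' @param input path to a PDB file or a [ProteinStructure-class].
#' @param chain chain to select (default: first).
#' @param outDir output directory (created; marked \code{.incomplete}
#'   while the run is in progress).
#' @param nStruct ensemble size (default 500).
#' @param seed root random seed.
#' @param clustersUsed 1 (largest cluster only) or up to 3.
#' @param radii,modes,cap,nLevels pool settings, see
#'   [buildSearchModels()].
#' @param sigma,params generator settings, see [generateEnsemble()].
#' @param writeFiles write one multi-MODEL PDB per search model (default
#'   TRUE); the manifest is written either way.
#' @return invisibly, a list with \code{pool}, \code{manifest},
#'   \code{ensemble}, \code{clusters}, \code{outDir}.
#' @export
runEnsembleMode <- function(input, chain = NULL, outDir,
                            nStruct = 500L, seed = 1L, clustersUsed = 1L,
                            radii = c(1, 2, 3),
                            modes = c("allatom", "reliable", "polyala"),
                            cap = 30L, nLevels = 20L, sigma = 1.5,
                            params = constraintParams(),
                            writeFiles = TRUE) {
  s0 <- if (is.character(input)) readPDB(input) else input
  s <- prepareInput(s0, chain)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outDir, ".incomplete")
  file.create(marker)
  log <- file.path(outDir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "", file = log,
                               append = TRUE)
  cat("", file = log)
  logLine("mode: ensemble")
  logLine("seed: %d | nStruct: %d | clustersUsed: %d | cap: %d | sigma: %g",
          as.integer(seed), as.integer(nStruct), as.integer(clustersUsed),
          as.integer(cap), sigma)
  logLine("radii: %s | modes: %s", paste(radii, collapse = ","),
          paste(modes, collapse = ","))
  logLine("input residues: %d", nResidues(s))

  e <- generateEnsemble(s, n = nStruct, seed = seed, params = params,
                        sigma = sigma)
  logLine("ensemble: %d members, %d discarded, worst violation %.4f A",
          nModels(e), e@nDiscarded, max(e@maxViolations))
  cl <- clusterEnsemble(e)
  logLine("clusters: %s (cutoff %.2f A)",
          paste(vapply(cl@members, length, integer(1)), collapse = "/"),
          cl@cutoff)
  pool <- buildSearchModels(e, cl, nClustersUsed = clustersUsed,
                            radii = radii, modes = modes, cap = cap,
                            nLevels = nLevels)
  files <- writePool(pool, outDir, writeFiles)
  manifest <- searchModelManifest(pool, files)
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logLine("pool: %d search models", length(pool))
  file.remove(marker)
  invisible(list(pool = pool, manifest = manifest, ensemble = e,
                 clusters = cl, outDir = outDir))
}

#' Run the single-structure truncation mode end to end
#'
#' prepare input -> obtain per-residue scores (external score file and/or
#' built-in metrics) -> progressive score-driven truncation x side-chain
#' modes -> write search models and manifest.  Each score column yields
#' \code{|levels| * |modes|} models (60 at the defaults); all columns form
#' a single pool.
#'
#' @param input path to a PDB file or a [ProteinStructure-class].
#' @param chain chain to select (default: first).
#' @param outDir output directory.
#' @param scoreFile optional path to a score file ([parseScoreFile()]).
#' @param metrics optional character vector of built-in metric names
#'   (\code{"wcn"}, \code{"asa"}, \code{"bfac"}, \code{"variance"}).
#' @param seed seed (used by the \code{"variance"} metric).
#' @param modes,nLevels pool settings.
#' @param writeFiles write one PDB per search model (default TRUE).
#' @return invisibly, a list with \code{pool}, \code{manifest},
#'   \code{scores}, \code{outDir}.
#' @export
runSingleModelMode <- function(input, chain = NULL, outDir,
                               scoreFile = NULL, metrics = NULL,
                               seed = 1L,
                               modes = c("allatom", "reliable", "polyala"),
                               nLevels = 20L, writeFiles = TRUE) {
  if (is.null(scoreFile) && is.null(metrics))
    stop("supply a score file and/or built-in metric names")
  s0 <- if (is.character(input)) readPDB(input) else input
  s <- prepareInput(s0, chain)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(outDir, ".incomplete")
  file.create(marker)

  scores <- data.frame(resno = residueIds(s))
  if (!is.null(scoreFile)) {
    ext <- parseScoreFile(scoreFile)
    scores <- merge(scores, ext, by = 1L, all.x = TRUE, sort = TRUE)
  }
  if (!is.null(metrics))
    scores <- merge(scores, builtinMetrics(s, metrics, seed = seed),
                    by = "resno", sort = TRUE)
  if (anyNA(scores))
    stop("structure residue(s) without a score: ",
         paste(utils::head(scores$resno[!stats::complete.cases(scores)], 5),
               collapse = ", "))

  pool <- truncateSingleModel(s, scores, modes = modes, nLevels = nLevels)
  files <- writePool(pool, outDir, writeFiles)
  manifest <- searchModelManifest(pool, files)
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- file.path(outDir, "run.log")
  cat(sprintf("mode: single-model\nseed: %d\nscore columns: %s\npool: %d search models\n",
              as.integer(seed), paste(names(scores)[-1], collapse = ","),
              length(pool)), file = log)
  file.remove(marker)
  invisible(list(pool = pool, manifest = manifest, scores = scores,
                 outDir = outDir))
}

writePool <- function(pool, outDir, writeFiles) {
  if (!writeFiles) return(NULL)
  mdir <- file.path(outDir, "search_models")
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  vapply(pool, function(sm) {
    f <- file.path(mdir, paste0(sm@label, ".pdb"))
    writeModels(sm@model, f, multiModel = nModels(sm@model) > 1L)
    f
  }, character(1))
}
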