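## Trace CSV I/O (with JSON metadata sidecar) and multi-model PDB ensembles.

#' Write a trace to CSV (+ JSON sidecar)
#'
#' Columns `time_s,signal`; metadata, when present, goes to
#' `<path>.json`.
#'
#' @param trace an [OsmoticTrace-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "OsmoticTrace"))
  utils::write.csv(data.frame(time_s = trace@times, signal = trace@values),
                   path, row.names = FALSE, quote = FALSE)
  if (length(trace@meta))
    jsonlite::write_json(trace@meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace from CSV (+ optional JSON sidecar)
#'
#' @param path CSV with columns `time_s,signal`; a `<path>.json` sidecar, if
#'   present, populates the metadata.
#' @return An [OsmoticTrace-class].
#' @export
readTrace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "signal") %in% names(df)))
    stop("trace CSV must have columns time_s and signal")
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  osmoticTrace(df$time_s, df$signal, meta = meta)
}

#' Write a trajectory ensemble as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, atoms named from the ensemble's
#' `atomMeta` (CA pseudo-atoms by default).
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEnsemblePdb <- function(ensemble, path) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  meta <- ensemble@atomMeta
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    fr <- ensemble@coords[f, , , drop = TRUE]
    lines <- sprintf(
      "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(meta)), meta$atomName, "ALA",
      substr(meta$chain, 1L, 1L), meta$resNo,
      fr[, 1L], fr[, 2L], fr[, 3L], 1, 0,
      substr(meta$atomName, 1L, 1L))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory ensemble
#'
#' Each MODEL becomes one frame; the atom selection (and its order) is taken
#' from the first model.
#'
#' @param path multi-model PDB file.
#' @param labels condition label per frame (recycled).
#' @param monomer monomer id per frame (recycled).
#' @return A [TrajectoryEnsemble-class].
#' @export
ensembleFromPdb <- function(path, labels = "frame", monomer = "m1") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                       # nFrames x 3M, (x,y,z) per atom
  nF <- nrow(xyz)
  m <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(nF, m, 3L))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, by = 3L, length.out = m),
                                      drop = FALSE]
  chain <- pdb$atom$chain
  chain[is.na(chain)] <- ""
  trajectoryEnsemble(coords, labels = labels, monomer = monomer,
                     atomMeta = data.frame(chain = chain,
                                           resNo = pdb$atom$resno,
                                           atomName = trimws(pdb$atom$elety)))
}
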