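# Stage caching: every pipeline stage writes a manifest carrying a hash
# of its inputs and configuration; on re-runs a stage is skipped iff its
# manifest hash matches, so changing any threshold invalidates that stage
# and everything downstream (downstream hashes include upstream hashes).

#' Hash arbitrary configuration/input descriptors
#'
#' MD5 over the canonical JSON serialization of the arguments; used to
#' key stage manifests.
#'
#' @param ... Values describing a stage's inputs (paths are replaced by
#'   their file checksums by the caller where content matters).
#' @return Hex digest string.
#' @export
config_hash <- function(...) {
  json <- jsonlite::toJSON(lapply(list(...), unclass), digits = NA,
                           auto_unbox = TRUE, null = "null")
  paste(as.character(openssl::md5(as.character(json))), collapse = "")
}

#' MD5 checksum of a file
#' @param path File path.
#' @return Hex digest string.
#' @export
file_checksum <- function(path) {
  paste(as.character(openssl::md5(file(path))), collapse = "")
}

manifest_path <- function(dir, stage) file.path(dir, paste0(stage,
                                                            ".manifest.json"))

#' Run a pipeline stage with manifest-based caching
#'
#' Executes `fun()` and stores its result under `dir` unless a manifest
#' with the same hash already exists, in which case the stored result is
#' returned and the computation skipped.
#'
#' @param dir Cache directory (created if needed).
#' @param stage Stage name.
#' @param hash Hash of the stage's inputs and configuration
#'   ([config_hash()]).
#' @param fun Zero-argument function computing the stage result.
#' @param force Recompute even on a manifest match.
#' @return List: `result`, `cached` (logical), `hash`.
#' @export
run_stage <- function(dir, stage, hash, fun, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- manifest_path(dir, stage)
  rp <- file.path(dir, paste0(stage, ".rds"))
  if (!force && file.exists(mp) && file.exists(rp)) {
    man <- jsonlite::fromJSON(mp)
    if (identical(man$hash, hash))
      return(list(result = readRDS(rp), cached = TRUE, hash = hash))
  }
  result <- fun()
  saveRDS(result, rp)
  jsonlite::write_json(list(stage = stage, hash = hash,
                            timestamp = "cached"),
                       mp, auto_unbox = TRUE)
  list(result = result, cached = FALSE, hash = hash)
}
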