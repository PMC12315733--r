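#' Write a cohort to a plain-text directory layout
#'
#' One whitespace-delimited dense matrix per subject per modality
#' (`<id>_sc.txt`, `<id>_fc.txt`), a tab-separated `regions.tsv`
#' (region_id, hemisphere, axis_rank, x, y, z, volume) and a JSON manifest
#' `cohort.json` recording subject ids, file paths, the generating spec and
#' seed. All downstream loading goes through this layout.
#'
#' @param cohort An `sfc_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::map(cohort$subjects, function(s) {
    sc_file <- paste0(s$subject_id, "_sc.txt")
    fc_file <- paste0(s$subject_id, "_fc.txt")
    utils::write.table(s$sc, file.path(dir, sc_file),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(s$fc, file.path(dir, fc_file),
                       row.names = FALSE, col.names = FALSE)
    list(subject_id = s$subject_id, sc = sc_file, fc = fc_file)
  })
  readr::write_tsv(cohort$region_meta, file.path(dir, "regions.tsv"))
  manifest <- list(
    subjects = files,
    regions = "regions.tsv",
    spec = unclass(cohort$spec),
    seed = cohort$seed
  )
  path <- file.path(dir, "cohort.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from its manifest
#'
#' @param path Path to a `cohort.json` manifest, or its directory.
#' @return An `sfc_cohort`.
#' @export
read_cohort <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "cohort.json")
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  dir <- dirname(path)
  read_mat <- function(f) as.matrix(utils::read.table(file.path(dir, f)))
  subjects <- purrr::map(manifest$subjects, function(s) {
    sc <- unname(read_mat(s$sc))
    fc <- unname(read_mat(s$fc))
    list(subject_id = s$subject_id, sc = sc, fc = fc)
  })
  meta <- readr::read_tsv(file.path(dir, manifest$regions),
                          show_col_types = FALSE, progress = FALSE)
  spec <- manifest$spec
  if (!is.null(spec)) {
    spec <- do.call(cohort_spec, spec[names(spec) %in% names(formals(cohort_spec))])
  }
  structure(
    list(subjects = subjects, region_meta = meta, spec = spec,
         seed = manifest$seed),
    class = "sfc_cohort"
  )
}
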