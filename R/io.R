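#' Write a TAC table (TSV with JSON metadata sidecar)
#'
#' @param dataset a `sim_dataset` or a list with `tac_table` and optional
#'   `meta`, `region_info` and `ref_fits`.
#' @param path path of the TSV file to write; the sidecar is written next
#'   to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(dataset, path) {
  tt <- dataset$tac_table
  tt <- tt[order(tt$subject_id, tt$measurement_id, tt$region, tt$frame_start), ]
  utils::write.table(tt, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(meta = dataset$meta, region_info = dataset$region_info)
  if (!is.null(dataset$ref_fits)) {
    sidecar$ref_fits <- lapply(dataset$ref_fits, function(p)
      as.list(feng1tc_to_vector(p)))
  }
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a TAC table written by [write_tac_table()]
#'
#' Validates the schema (required columns, positive durations, no
#' duplicated subject/measurement/region/frame rows) and returns the table
#' with deterministic row ordering plus any sidecar metadata.
#'
#' @param path path to the TSV file.
#' @return A list with `tac_table`, `meta`, `region_info`, `ref_fits`
#'   (parameter objects, when present in the sidecar) and `frames`.
#' @export
read_tac_table <- function(path) {
  tt <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("subject_id", "measurement_id", "region", "frame_start",
                "frame_duration", "activity")
  missing_cols <- setdiff(required, names(tt))
  if (length(missing_cols)) {
    stopf("TAC table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "),
          class = "refsimba_schema_error")
  }
  if (any(tt$frame_duration <= 0)) {
    bad <- which(tt$frame_duration <= 0)
    stopf("non-positive frame_duration in rows: %s",
          paste(utils::head(bad, 10), collapse = ", "),
          class = "refsimba_validation_error")
  }
  key <- paste(tt$subject_id, tt$measurement_id, tt$region, tt$frame_start)
  if (anyDuplicated(key)) {
    stopf("duplicate (subject, measurement, region, frame_start) rows",
          class = "refsimba_validation_error")
  }
  tt <- tt[order(tt$subject_id, tt$measurement_id, tt$region, tt$frame_start), ]
  rownames(tt) <- NULL
  out <- list(tac_table = tt)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::fromJSON(readLines(sidecar_path), simplifyDataFrame = TRUE)
    out$meta <- sc$meta
    out$region_info <- sc$region_info
    if (!is.null(sc$ref_fits)) {
      out$ref_fits <- lapply(sc$ref_fits, function(v)
        feng1tc_from_vector(unlist(v)))
    }
  }
  f1 <- tt[tt$subject_id == tt$subject_id[1] &
             tt$measurement_id == tt$measurement_id[1] &
             tt$region == tt$region[1], ]
  out$frames <- frame_schedule(f1$frame_start, f1$frame_duration)
  out
}
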