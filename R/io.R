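SYNAPSE_COLUMNS <- c("id", "x_nm", "y_nm", "z_nm", "radius_nm", "type",
                     "sas_area_nm2", "shape", "target", "spine_id",
                     "spine_complete", "layer", "case", "stack")

#' Read and write synapse tables
#'
#' Tab-separated synapse tables with the documented column schema
#' (`id, x_nm, y_nm, z_nm, radius_nm, type, sas_area_nm2, shape, target,
#' spine_id, spine_complete, layer, case, stack`). Unknown columns are
#' preserved verbatim (read as text) so annotation survives a round trip;
#' `write` then `read` then `write` is byte-identical.
#'
#' @param path file path.
#' @param population a `synapse_population`.
#' @return `read_synapse_table` returns a `synapse_population`.
#' @export
read_synapse_table <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(SYNAPSE_COLUMNS, header)
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  classes <- rep("character", length(header))
  names(classes) <- header
  num_cols <- c("x_nm", "y_nm", "z_nm", "radius_nm", "sas_area_nm2")
  classes[intersect(num_cols, header)] <- "numeric"
  classes["id"] <- "integer"
  classes["spine_complete"] <- "character"
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = unname(classes), na.strings = "NA",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  bad <- which(df$sas_area_nm2 <= 0 | !is.finite(df$sas_area_nm2))
  if (length(bad) > 0) {
    stop(sprintf("nonpositive sas_area_nm2 at data row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad_r <- which(df$radius_nm < 0 | !is.finite(df$radius_nm))
  if (length(bad_r) > 0) {
    stop(sprintf("negative radius_nm at data row(s) %s",
                 paste(bad_r, collapse = ", ")), call. = FALSE)
  }
  df$spine_complete <- ifelse(is.na(df$spine_complete), NA,
                              df$spine_complete == "TRUE")
  df <- df[c(SYNAPSE_COLUMNS, setdiff(header, SYNAPSE_COLUMNS))]
  class(df) <- c("synapse_population", "data.frame")
  df
}

#' @rdname read_synapse_table
#' @export
write_synapse_table <- function(population, path) {
  df <- as.data.frame(population)
  extra <- setdiff(names(df), SYNAPSE_COLUMNS)
  df <- df[c(SYNAPSE_COLUMNS, extra)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
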