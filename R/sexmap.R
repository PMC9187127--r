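#' Read a sample-to-sex map
#'
#' Two-column TSV (header optional, detected from the second column's
#' values): sample identifier and sex code. Accepted codes: `F`, `female`,
#' `2` for females; `M`, `male`, `1` for males (PLINK convention for the
#' numeric codes). Case-insensitive.
#'
#' @param path TSV file path.
#' @return Named character vector mapping sample id to `"female"`/`"male"`.
#' @export
read_sex_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(dt) == 1L) {  # tolerate space-separated files
    dt <- data.table::fread(path, header = FALSE, colClasses = "character")
  }
  if (ncol(dt) < 2L) stop("sex map needs two columns", call. = FALSE)
  ids <- dt[[1]]; codes <- dt[[2]]
  # drop a header row if present
  if (length(ids) && tolower(codes[1]) %in% c("sex", "gender")) {
    ids <- ids[-1]; codes <- codes[-1]
  }
  norm <- normalize_sex_codes(codes)
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in sex map: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  setNames(norm, ids)
}

normalize_sex_codes <- function(codes) {
  lc <- tolower(trimws(codes))
  out <- rep(NA_character_, length(lc))
  out[lc %in% c("f", "female", "2")] <- "female"
  out[lc %in% c("m", "male", "1")] <- "male"
  if (anyNA(out)) {
    stop("unknown sex code(s): ",
         paste(unique(codes[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}
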