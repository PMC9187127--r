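#' Read and write aggregated sex-stratified count tables
#'
#' The tabular interchange format mirrors published gnomAD-style summary
#' tables: one row per (SNP, population, sex) with columns `Region`, `SNP`,
#' `Population`, `Sex`, `CallRate` (percent, optional/NA), `RR`, `RA`, `AA`
#' (genotype counts with respect to the alternate allele; `RA = NA` on a
#' male row denotes the hemizygous layout) and `MinorAllele`. Extra columns
#' are ignored on read and dropped on write. SNP identifiers of the form
#' `chrom-pos-ref-alt` (e.g. `X-2779827-G-A`) are parsed into site fields.
#'
#' @param path TSV file path.
#' @return `read_count_table()`: list of `variant_record` objects (one per
#'   SNP x population), each carrying an [ss_counts()] with the alternate
#'   allele designated as A, plus `population` and the table's
#'   `minor_allele`.
#' @export
read_count_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  need <- c("Region", "SNP", "Population", "Sex", "RR", "RA", "AA",
            "MinorAllele")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("count table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"CallRate" %in% names(dt)) dt$CallRate <- NA_real_
  for (col in c("RR", "AA")) {
    if (anyNA(dt[[col]])) stop(col, " counts cannot be NA", call. = FALSE)
  }
  if (any(dt$RR < 0 | dt$AA < 0 | (!is.na(dt$RA) & dt$RA < 0))) {
    stop("negative genotype count", call. = FALSE)
  }
  sexes <- normalize_sex_codes(dt$Sex)
  keys <- paste(dt$SNP, dt$Population, sep = "\r")
  records <- list()
  for (k in unique(keys)) {
    rows <- which(keys == k)
    sx <- sexes[rows]
    if (!all(c("female", "male") %in% sx) || length(rows) != 2L) {
      stop("SNP/population ", gsub("\r", " / ", k),
           " must have exactly one female and one male row", call. = FALSE)
    }
    fr <- dt[rows[sx == "female"], ]
    mr <- dt[rows[sx == "male"], ]
    if (is.na(fr$RA)) stop("female RA cannot be NA", call. = FALSE)
    layout <- if (is.na(mr$RA)) "hemizygous" else "diploid"
    site <- .parse_snp_id(fr$SNP)
    counts <- ss_counts(
      female = c(fr$RR, fr$RA, fr$AA),
      male = if (layout == "hemizygous") c(mr$RR, mr$AA)
             else c(mr$RR, mr$RA, mr$AA),
      male_layout = layout,
      missing_female = NA_real_, missing_male = NA_real_,
      allele_a = site$ref, allele_A = site$alt
    )
    records[[length(records) + 1L]] <- structure(
      list(chrom = site$chrom, pos = site$pos, id = fr$SNP,
           ref = site$ref, alt = site$alt, region = fr$Region,
           population = fr$Population, counts = counts,
           minor_allele = fr$MinorAllele,
           call_rate_female = fr$CallRate, call_rate_male = mr$CallRate),
      class = "variant_record"
    )
  }
  records
}

.parse_snp_id <- function(id) {
  parts <- strsplit(id, "-", fixed = TRUE)[[1]]
  if (length(parts) == 4L && grepl("^[0-9]+$", parts[2])) {
    list(chrom = parts[1], pos = as.integer(parts[2]),
         ref = parts[3], alt = parts[4])
  } else {
    list(chrom = NA_character_, pos = NA_integer_,
         ref = "R", alt = "A")
  }
}

#' @param records List of `variant_record` objects as returned by
#'   [read_count_table()].
#' @rdname read_count_table
#' @export
write_count_table <- function(records, path) {
  rows <- lapply(records, function(r) {
    x <- r$counts
    hemi <- x$male_layout == "hemizygous"
    data.table::data.table(
      Region = r$region,
      SNP = r$id,
      Population = if (is.null(r$population)) NA_character_ else r$population,
      Sex = c("F", "M"),
      CallRate = c(
        if (is.null(r$call_rate_female)) NA_real_ else r$call_rate_female,
        if (is.null(r$call_rate_male)) NA_real_ else r$call_rate_male),
      RR = c(x$female[1], x$male[1]),
      RA = c(x$female[2], if (hemi) NA_real_ else x$male[2]),
      AA = c(x$female[3], if (hemi) x$male[2] else x$male[3]),
      MinorAllele = if (is.null(r$minor_allele)) NA_character_
                    else r$minor_allele
    )
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
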