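#' X-chromosome region maps
#'
#' The X chromosome is partitioned into four regions with different male
#' ploidy: the two pseudoautosomal regions PAR1 and PAR2 (males diploid),
#' the X-transposed region PAR3/XTR (treated as hemizygous, like NPR), and
#' the non-pseudoautosomal region NPR (the complement of the three PARs).
#' A `region_map` stores the three PAR intervals for a genome build as
#' 1-based inclusive coordinates (matching VCF POS); every position not in
#' a PAR interval is NPR.
#'
#' PAR1/PAR2 default coordinates are the Genome Reference Consortium
#' published spans for each build. The PAR3/XTR span is not standardized;
#' the packaged default is an approximate ~3.91 Mb interval in Xq21.3 and
#' should be overridden via BED for exact replication work.
#'
#' @param build Genome build identifier, `"GRCh37"` or `"GRCh38"`.
#' @param override Optional path to a BED file whose name column labels
#'   intervals as `PAR1`, `PAR2` or `PAR3`; each labelled interval replaces
#'   the packaged default for that label. BED is 0-based half-open and is
#'   converted to 1-based inclusive internally.
#' @return An object of class `region_map`: a list with `build`,
#'   `chr_length`, and `intervals` (data.frame with `label`, `start`, `end`).
#' @examples
#' m <- load_region_map("GRCh37")
#' assign_region(m, 90e6)   # "PAR3"
#' assign_region(m, 155e6)  # "PAR2"
#' @export
load_region_map <- function(build = c("GRCh37", "GRCh38"), override = NULL) {
  if (!is.character(build) || length(build) != 1L ||
      !build %in% names(.region_defaults)) {
    stop("unsupported genome build: ", paste(build, collapse = ", "),
         " (supported: ", paste(names(.region_defaults), collapse = ", "), ")",
         call. = FALSE)
  }
  def <- .region_defaults[[build]]
  intervals <- def$intervals
  if (!is.null(override)) {
    ov <- read_region_bed(override)
    for (lab in unique(ov$label)) {
      intervals[intervals$label == lab, c("start", "end")] <-
        ov[ov$label == lab, c("start", "end")]
    }
  }
  map <- structure(
    list(build = build, chr_length = def$chr_length, intervals = intervals),
    class = "region_map"
  )
  validate_region_map(map)
  map
}

# GRC PAR1/PAR2 spans; PAR3/XTR approximate (see ?load_region_map).
.region_defaults <- list(
  GRCh37 = list(
    chr_length = 155270560L,
    intervals = data.frame(
      label = c("PAR1", "PAR3", "PAR2"),
      start = c(60001L, 88400001L, 154931044L),
      end   = c(2699520L, 92310000L, 155260560L),
      stringsAsFactors = FALSE
    )
  ),
  GRCh38 = list(
    chr_length = 156040895L,
    intervals = data.frame(
      label = c("PAR1", "PAR3", "PAR2"),
      start = c(10001L, 89145001L, 155701383L),
      end   = c(2781479L, 93055000L, 156030895L),
      stringsAsFactors = FALSE
    )
  )
)

validate_region_map <- function(map) {
  iv <- map$intervals
  if (!all(iv$label %in% c("PAR1", "PAR2", "PAR3"))) {
    stop("region map labels must be PAR1/PAR2/PAR3", call. = FALSE)
  }
  if (anyDuplicated(iv$label)) {
    stop("duplicate region label in map", call. = FALSE)
  }
  if (any(iv$start > iv$end) || any(iv$start < 1)) {
    stop("region intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  o <- order(iv$start)
  s <- iv$start[o]; e <- iv$end[o]
  if (any(s[-1] <= e[-length(e)])) {
    stop("overlapping PAR intervals in region map", call. = FALSE)
  }
  invisible(map)
}

#' @export
print.region_map <- function(x, ...) {
  cat("X-chromosome region map (", x$build, ", chr length ",
      format(x$chr_length, big.mark = ","), " bp)\n", sep = "")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Assign a position to its X-chromosome region
#'
#' Total function over positive positions: positions inside a PAR interval
#' (1-based, inclusive of both endpoints) get that label, everything else is
#' `"NPR"`.
#'
#' @param map A `region_map` from [load_region_map()].
#' @param position Vector of 1-based base-pair positions.
#' @return Character vector of labels in `{"PAR1","PAR2","PAR3","NPR"}`.
#' @export
assign_region <- function(map, position) {
  stopifnot(inherits(map, "region_map"))
  if (any(position < 1)) stop("positions must be >= 1", call. = FALSE)
  out <- rep("NPR", length(position))
  for (i in seq_len(nrow(map$intervals))) {
    iv <- map$intervals[i, ]
    out[position >= iv$start & position <= iv$end] <- iv$label
  }
  out
}

#' Male ploidy implied by a region label
#'
#' Males carry one allele in NPR and PAR3 (hemizygous) and two in PAR1 and
#' PAR2 (diploid).
#'
#' @param region Character vector of region labels.
#' @return `"hemizygous"` or `"diploid"` for each label.
#' @export
region_male_layout <- function(region) {
  bad <- setdiff(unique(region), c("NPR", "PAR1", "PAR2", "PAR3"))
  if (length(bad)) stop("unknown region label: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ifelse(region %in% c("PAR1", "PAR2"), "diploid", "hemizygous")
}

#' Read or write PAR interval overrides as BED
#'
#' BED uses 0-based half-open coordinates; these helpers convert to and from
#' the 1-based inclusive representation used internally.
#'
#' @param path BED file path. For reading, the 4th (name) column must label
#'   intervals as PAR1/PAR2/PAR3.
#' @return `read_region_bed`: data.frame with `label`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_region_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  labels <- gr$name
  if (is.null(labels) || any(is.na(labels)) ||
      !all(labels %in% c("PAR1", "PAR2", "PAR3"))) {
    stop("BED override names must be PAR1/PAR2/PAR3", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate label in BED override", call. = FALSE)
  }
  df <- data.frame(
    label = labels,
    start = GenomicRanges::start(gr),  # rtracklayer already 1-based here
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(df$start > df$end)) stop("invalid BED interval", call. = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)])) {
    stop("overlapping intervals in BED override", call. = FALSE)
  }
  df
}

#' @param map A `region_map` to serialize.
#' @rdname read_region_bed
#' @export
write_region_bed <- function(map, path) {
  stopifnot(inherits(map, "region_map"))
  gr <- GenomicRanges::GRanges(
    seqnames = "X",
    ranges = IRanges::IRanges(start = map$intervals$start,
                              end = map$intervals$end),
    name = map$intervals$label
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
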