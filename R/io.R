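#' Read a pedigreed heteroplasmy cohort from file
#'
#' Reads a long-format table (one row per pup; mothers without pups may
#' appear as rows with a blank \code{pup_id}) and returns a validated
#' \code{\link{het_cohort}}. Units are auto-detected: any heteroplasmy value
#' above 1 marks the whole file as percent and all values are divided by 100;
#' a percent file that also contains values below 1 is rejected as mixed.
#' The original pup measurement is always the analysis value even when a
#' remeasurement column is present.
#'
#' @param path file path.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"xlsx"} (xlsx requires
#'   the readxl package). Defaults from the file extension.
#' @param header_map optional named character vector renaming file headers to
#'   the expected ones, e.g. \code{c(pup_het = "Pup heteroplasmy (\%)")};
#'   names are the internal column names \code{mother_id}, \code{group},
#'   \code{mother_het}, \code{pup_id}, \code{pup_het}, \code{nnt},
#'   \code{pup_het_remeasured}, values the headers as they appear in the file.
#' @param aliases group-label alias map, see \code{\link{group_aliases}}.
#' @param extra_groups additional group labels to accept.
#' @param sheet sheet name or index for xlsx input.
#'
#' @return A \code{\link{het_cohort}} with heteroplasmy as fractions and
#'   \code{units_declared} recording the source unit.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                        header_map = NULL, aliases = group_aliases(),
                        extra_groups = character(), sheet = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  raw <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the 'readxl' package", call. = FALSE)
      as.data.frame(readxl::read_excel(path, sheet = sheet),
                    stringsAsFactors = FALSE)
    })

  if (!is.null(header_map)) {
    for (internal in names(header_map)) {
      j <- match(header_map[[internal]], names(raw))
      if (!is.na(j)) names(raw)[j] <- internal
    }
  }

  need <- c("mother_id", "group", "mother_het", "pup_het")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("input is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(raw$pup_id)) {
    raw$pup_id <- ifelse(is.na(raw$pup_het), "",
                         paste0(raw$mother_id, "_P", seq_len(nrow(raw))))
  }
  if (is.null(raw$nnt)) raw$nnt <- 0
  if (is.null(raw$pup_het_remeasured)) raw$pup_het_remeasured <- NA_real_

  for (col in c("mother_het", "pup_het", "pup_het_remeasured")) {
    v <- raw[[col]]
    if (is.character(v)) v[v == ""] <- NA
    v <- suppressWarnings(as.numeric(v))
    if (any(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != ""))
      stop("non-numeric values in column ", col, call. = FALSE)
    raw[[col]] <- v
  }

  hvals <- c(raw$mother_het, raw$pup_het, raw$pup_het_remeasured)
  hvals <- hvals[!is.na(hvals)]
  if (any(hvals <= 0 | hvals > 100))
    stop("heteroplasmy value(s) outside (0, 100]: ",
         paste(signif(hvals[hvals <= 0 | hvals > 100], 4), collapse = ", "),
         call. = FALSE)
  percent <- any(hvals > 1)
  if (percent && any(hvals < 1))
    stop("mixed heteroplasmy units: file contains values above 1 (percent) ",
         "and below 1; use one unit throughout", call. = FALSE)
  scale <- if (percent) 100 else 1

  raw$group <- canonical_group(raw$group, aliases, extra_groups)

  is_pup <- !(is.na(raw$pup_het) | is.na(raw$pup_id) | raw$pup_id == "")
  mothers <- unique(raw[c("mother_id", "group", "mother_het", "nnt")])
  # a mother must be described consistently across her rows
  if (anyDuplicated(mothers$mother_id)) {
    dup <- unique(mothers$mother_id[duplicated(mothers$mother_id)])
    stop("inconsistent rows for mother(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  mothers_df <- data.frame(
    mother_id = mothers$mother_id,
    group = mothers$group,
    heteroplasmy = mothers$mother_het / scale,
    nnt_carrier = as.logical(as.integer(mothers$nnt)),
    stringsAsFactors = FALSE
  )
  pups_df <- data.frame(
    pup_id = raw$pup_id[is_pup],
    mother_id = raw$mother_id[is_pup],
    heteroplasmy = raw$pup_het[is_pup] / scale,
    heteroplasmy_remeasured = raw$pup_het_remeasured[is_pup] / scale,
    stringsAsFactors = FALSE
  )

  het_cohort(mothers_df, pups_df,
             units_declared = if (percent) "percent" else "fraction",
             extra_groups = extra_groups)
}

#' Write a cohort to CSV or TSV
#'
#' Writes the long format read back by \code{\link{read_cohort}}: one row per
#' pup; mothers without pups get a row with blank pup fields. Heteroplasmy is
#' written as fractions at full precision, so a write/read round trip
#' reproduces the cohort.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "tsv")) {
  stopifnot(inherits(cohort, "het_cohort"))
  format <- match.arg(format)
  m <- cohort$mothers
  p <- cohort$pups
  idx <- match(p$mother_id, m$mother_id)
  rows <- data.frame(
    mother_id = p$mother_id,
    group = m$group[idx],
    mother_het = m$heteroplasmy[idx],
    pup_id = p$pup_id,
    pup_het = p$heteroplasmy,
    nnt = as.integer(m$nnt_carrier[idx]),
    pup_het_remeasured = p$heteroplasmy_remeasured,
    stringsAsFactors = FALSE
  )
  lone <- m[!(m$mother_id %in% p$mother_id), , drop = FALSE]
  if (nrow(lone)) {
    rows <- rbind(rows, data.frame(
      mother_id = lone$mother_id, group = lone$group,
      mother_het = lone$heteroplasmy, pup_id = "",
      pup_het = NA_real_, nnt = as.integer(lone$nnt_carrier),
      pup_het_remeasured = NA_real_, stringsAsFactors = FALSE))
  }
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}
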