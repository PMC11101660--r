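#' Read a panel definition from JSON or TSV
#'
#' JSON files carry an object with an optional `disutilities` element
#' (`delta_gpos_dneg`, `delta_gneg_dpos`) and a `pairs` array of records;
#' TSV files are tab-separated with a header row and one record per line.
#' Each record needs `disease_id`, `gene_id`, `carrier_prevalence`,
#' `penetrance`, `precision`; `test_disutility` (default 0) and per-record
#' `delta_gpos_dneg` / `delta_gneg_dpos` overrides are optional. Values are
#' validated on read and errors name the offending record.
#'
#' @param path Path to the panel file.
#' @param format `"auto"` (by extension), `"json"` or `"tsv"`.
#' @return A validated [gene_panel()].
#' @seealso [write_panel()], [breast_cancer_panel()]
#' @export
read_panel <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json",
                     tsv = , txt = , tab = "tsv",
                     stop("cannot infer format from extension of ", path,
                          "; pass format explicitly", call. = FALSE))
  }
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    pairs <- doc$pairs
    if (is.null(pairs) || !is.data.frame(pairs) || nrow(pairs) == 0) {
      stop("JSON panel must carry a non-empty 'pairs' array", call. = FALSE)
    }
    disutilities <- if (!is.null(doc$disutilities)) {
      disutility_spec(doc$disutilities$delta_gpos_dneg,
                      doc$disutilities$delta_gneg_dpos)
    }
  } else {
    pairs <- utils::read.delim(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = NA, fileEncoding = "UTF-8")
    disutilities <- NULL
  }
  numeric_cols <- intersect(
    c("carrier_prevalence", "penetrance", "precision", "test_disutility",
      "delta_gpos_dneg", "delta_gneg_dpos"), names(pairs))
  for (cl in numeric_cols) {
    v <- pairs[[cl]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad) > 0) {
        stop(sprintf("field '%s' is not numeric at record %d of %s",
                     cl, bad[1], path), call. = FALSE)
      }
      pairs[[cl]] <- vn
    } else {
      pairs[[cl]] <- as.numeric(v)  # integers read as double storage
    }
  }
  gene_panel(pairs, disutilities = disutilities)
}

#' Write a panel definition to JSON or TSV
#'
#' Numbers are serialised at full precision (shortest round-trip decimal),
#' so [read_panel()] of the written file reproduces every numeric field
#' exactly. A panel-level shared disutility spec is representable only in
#' JSON; writing a panel that has one to TSV drops it with a warning
#' (per-record delta columns survive in both formats).
#'
#' @param panel A [gene_panel()].
#' @inheritParams read_panel
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("auto", "json", "tsv")) {
  stopifnot(inherits(panel, "gene_panel"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", tsv = , txt = , tab = "tsv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "json") {
    doc <- list(pairs = panel$pairs)
    if (!is.null(panel$disutilities)) {
      doc$disutilities <- list(
        delta_gpos_dneg = panel$disutilities$delta_gpos_dneg,
        delta_gneg_dpos = panel$disutilities$delta_gneg_dpos)
    }
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    if (!is.null(panel$disutilities)) {
      warning("TSV cannot carry the panel-level disutility spec; ",
              "it is dropped (use JSON to keep it)", call. = FALSE)
    }
    df <- panel$pairs
    for (cl in names(df)) {
      if (is.numeric(df[[cl]])) {
        df[[cl]] <- vapply(df[[cl]], format_full, character(1))
      }
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

# shortest decimal that round-trips a double
format_full <- function(x) {
  if (is.na(x)) return("")
  if (x == trunc(x) && abs(x) < 1e15) {
    return(format(x, scientific = FALSE))
  }
  for (digits in 1:17) {
    s <- format(x, digits = digits, scientific = FALSE)
    if (as.numeric(s) == x) return(s)
  }
  format(x, digits = 17, scientific = FALSE)
}

#' Convert an allele frequency to a carrier prevalence
#'
#' Autosomal carrier frequency under Hardy-Weinberg equilibrium: the
#' probability of carrying at least one copy of an allele with frequency
#' \eqn{q} is \eqn{1 - (1 - q)^2}.
#'
#' @param q Allele frequency in \[0, 1\] (vectorised).
#' @return Carrier prevalence(s).
#' @examples
#' allele_freq_to_carrier_prevalence(0.00057)
#' @export
allele_freq_to_carrier_prevalence <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stop("q must be in [0, 1]", call. = FALSE)
  }
  1 - (1 - q)^2
}

#' Round to the display precision used in reports
#'
#' Two significant figures, the precision at which threshold tables are
#' conventionally reported. Core computations always keep full precision;
#' this is a formatting aid only.
#'
#' @param x Numeric vector.
#' @return `signif(x, 2)`.
#' @export
round_like_paper <- function(x) signif(x, 2)
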