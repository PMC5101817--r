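#' Write a deterministic TSV + JSON report
#'
#' Each table in `tables` is written as `<name>.tsv` and the whole set as a
#' single `report.json`. Output is deterministic for a fixed input: tables
#' are written in sorted name order, JSON keys are sorted, and every
#' numeric value is rendered at a fixed format of 6 significant digits —
#' so a write/re-read/write round trip is byte-identical.
#'
#' @param tables Named list of `data.frame`s (and/or flat named lists of
#'   scalars, which land only in the JSON).
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_report <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nms <- sort(names(tables))
  paths <- character(0)
  fmt_df <- function(df) {
    for (cn in names(df)) {
      if (is.numeric(df[[cn]])) df[[cn]] <- fmt_num(df[[cn]])
    }
    df
  }
  json <- list()
  for (nm in nms) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write.table(fmt_df(x), p, sep = "\t", quote = FALSE,
                  row.names = FALSE, na = "NA")
      paths[nm] <- p
      json[[nm]] <- fmt_json_value(x)
    } else {
      json[[nm]] <- fmt_json_value(x)
    }
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(json[sort(names(json))], jp, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  paths["report.json"] <- jp
  invisible(paths)
}

# round numerics to the fixed report precision so JSON and TSV agree
fmt_json_value <- function(x) {
  if (is.data.frame(x)) {
    for (cn in names(x)) {
      if (is.numeric(x[[cn]])) x[[cn]] <- signif(x[[cn]], 6)
    }
    x
  } else if (is.list(x)) {
    lapply(x, fmt_json_value)
  } else if (is.numeric(x)) {
    signif(x, 6)
  } else {
    x
  }
}
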