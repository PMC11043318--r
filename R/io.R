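#' Write an event dataset to CSV
#'
#' NONMEM-style CSV: columns `ID, TIME, EVID, AMT, CMT, DV, MDV, WT, TV,
#' CYCLE, OCC`; missing values (dose-record `DV`/`AMT`, PSA `CYCLE`) are
#' coded as `"."`.
#'
#' @param data An event tibble (from the generators or [read_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  cols <- c("ID", "TIME", "EVID", "AMT", "CMT", "DV", "MDV", "WT", "TV",
            "CYCLE", "OCC")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data[cols]
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "."
    x
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event dataset from CSV
#'
#' Parses and validates the NONMEM-style event CSV written by
#' [write_dataset()]: required columns, known compartment codes (1 central,
#' 2 salivary, 3 kidneys, 4 tumor, 5 remaining tissue, 6 PSA),
#' non-decreasing times within each subject (the PSA baseline may be
#' negative, i.e. before the first dose), and numeric types with `"."`
#' decoded to `NA`.
#'
#' @param path CSV file path.
#' @return A typed event tibble.
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  cols <- c("ID", "TIME", "EVID", "AMT", "CMT", "DV", "MDV", "WT", "TV",
            "CYCLE", "OCC")
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  out <- tibble::tibble(
    ID = num(raw$ID), TIME = num(raw$TIME), EVID = as.integer(num(raw$EVID)),
    AMT = num(raw$AMT), CMT = as.integer(num(raw$CMT)), DV = num(raw$DV),
    MDV = as.integer(num(raw$MDV)), WT = num(raw$WT), TV = num(raw$TV),
    CYCLE = as.integer(num(raw$CYCLE)), OCC = as.integer(num(raw$OCC))
  )
  bad_cmt <- which(!out$CMT %in% 1:6)
  if (length(bad_cmt) > 0) {
    stop("unknown CMT code in row ", bad_cmt[1], ": ", out$CMT[bad_cmt[1]],
         call. = FALSE)
  }
  non_mono <- out |>
    dplyr::group_by(.data$ID) |>
    dplyr::summarise(bad = is.unsorted(.data$TIME), .groups = "drop")
  if (any(non_mono$bad)) {
    stop("non-monotone times within subject ",
         non_mono$ID[which(non_mono$bad)[1]], call. = FALSE)
  }
  out
}
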