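# Delimited-text panel readers and writers.  Dialect is fixed: comma
# separator, header row, UTF-8, "." decimal, missing values as empty fields.

#' Read a repeated-measures panel from CSV
#'
#' Two layouts are supported.  `wide`: one row per individual, columns `id`
#' then `<process>_<occasion>` (e.g. `y_0`, `x_3`); `long`: columns
#' `id, occasion, variable, value` with one record per cell.  Empty value
#' fields are missing.  Long and wide files describing the same data produce
#' identical panels.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @return An `"lcs_panel"` object.
#' @export
read_panel <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- read.csv(path, na.strings = "", check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (layout == "wide") panel_from_wide(df) else panel_from_long(df)
}

panel_from_wide <- function(df) {
  if (!"id" %in% names(df)) stop("malformed header: no 'id' column",
                                 call. = FALSE)
  cols <- setdiff(names(df), "id")
  m <- regmatches(cols, regexec("^([A-Za-z]+)_(\\d+)$", cols))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed header: column(s) ", paste(cols[bad], collapse = ", "),
         " are not <process>_<occasion>", call. = FALSE)
  vars <- vapply(m, `[`, "", 2L)
  occs <- as.integer(vapply(m, `[`, "", 3L))
  processes <- sort(unique(vars))
  if (identical(processes, c("x", "y"))) processes <- c("x", "y")
  occasions <- sort(unique(occs))
  if (!identical(occasions, 0:(length(occasions) - 1L)))
    stop("occasions must be consecutive integers starting at 0",
         call. = FALSE)
  want <- panel_colnames(processes, occasions)
  if (!setequal(cols, want))
    stop("incomplete process/occasion grid in header", call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate id ", df$id[duplicated(df$id)][1], call. = FALSE)
  vals <- df[want]
  nonnum <- !vapply(vals, function(z) is.numeric(z) || all(is.na(z)),
                    logical(1))
  if (any(nonnum))
    stop("non-numeric values in column(s) ",
         paste(want[nonnum], collapse = ", "), call. = FALSE)
  obs <- as.matrix(as.data.frame(lapply(vals, as.numeric)))
  new_lcs_panel(unname(obs), ids = df$id, occasions = occasions,
                processes = processes)
}

panel_from_long <- function(df) {
  need <- c("id", "occasion", "variable", "value")
  if (!all(need %in% names(df)))
    stop("malformed header: long layout needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$value) && !all(is.na(df$value)))
    stop("non-numeric values in 'value'", call. = FALSE)
  key <- paste(df$id, df$occasion, df$variable, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop(sprintf("duplicate record for id %s, occasion %s, variable %s",
                 d$id, d$occasion, d$variable), call. = FALSE)
  }
  processes <- sort(unique(df$variable))
  occasions <- sort(unique(as.integer(df$occasion)))
  if (!identical(occasions, 0:(length(occasions) - 1L)))
    stop("occasions must be consecutive integers starting at 0",
         call. = FALSE)
  ids <- unique(df$id)
  cols <- panel_colnames(processes, occasions)
  obs <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(NULL, cols))
  col_of <- setNames(seq_along(cols), cols)
  row_of <- setNames(seq_along(ids), as.character(ids))
  obs[cbind(row_of[as.character(df$id)],
            col_of[paste0(df$variable, "_", df$occasion)])] <-
    as.numeric(df$value)
  new_lcs_panel(unname(obs), ids = ids, occasions = occasions,
                processes = processes)
}

#' Write a panel to CSV
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(x, path), layout)`
#' reproduces `x` (numeric values round-trip at full precision; missing
#' cells are written as empty fields).
#'
#' @param panel an `"lcs_panel"`.
#' @param path output file path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, layout = c("wide", "long")) {
  stopifnot(inherits(panel, "lcs_panel"))
  layout <- match.arg(layout)
  obs <- panel$observed
  fmt <- function(x) {             # full-precision, empty field for missing
    s <- sprintf("%.17g", x)
    s[is.na(x)] <- ""
    s
  }
  if (layout == "wide") {
    df <- data.frame(id = panel$ids,
                     as.data.frame(matrix(fmt(obs), nrow(obs)),
                                   optional = TRUE),
                     check.names = FALSE)
    names(df) <- c("id", colnames(obs))
  } else {
    cells <- expand.grid(variable = panel$processes,
                         occasion = panel$occasions,
                         stringsAsFactors = FALSE)   # time-major cell order
    df <- data.frame(
      id = rep(panel$ids, each = nrow(cells)),
      occasion = rep(cells$occasion, times = nrow(obs)),
      variable = rep(cells$variable, times = nrow(obs)),
      value = fmt(as.vector(t(obs))))
  }
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
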